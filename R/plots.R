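# ggplot2 figures for the main result types.

#' Group means of a network score with standard-error bars
#'
#' @param data Data frame with the score and group columns.
#' @param y Score column name.
#' @param group_col Group column name.
#' @return A ggplot.
#' @export
plot_group_means <- function(data, y = "network_mean", group_col = "group") {
  check_columns(data, c(y, group_col), "data")
  summ <- data %>%
    group_by(.data[[group_col]]) %>%
    summarise(mean = mean(.data[[y]]),
              se = sd(.data[[y]]) / sqrt(n()), .groups = "drop")
  ggplot(summ, aes(x = .data[[group_col]], y = .data$mean)) +
    geom_col(fill = "grey75", width = 0.6) +
    geom_errorbar(aes(ymin = .data$mean - .data$se,
                      ymax = .data$mean + .data$se), width = 0.15) +
    labs(x = NULL, y = y) +
    theme_minimal()
}

#' ROC curve for a transfer result
#'
#' @param x A `roc_result` from [roc_transfer()].
#' @param ... Unused.
#' @return A ggplot of the ROC curve with the AUC annotated.
#' @export
autoplot.roc_result <- function(x, ...) {
  thr <- sort(unique(x$scores), decreasing = TRUE)
  pts <- tibble(
    tpr = vapply(thr, function(t) mean(x$scores[x$labels] >= t), numeric(1)),
    fpr = vapply(thr, function(t) mean(x$scores[!x$labels] >= t), numeric(1)))
  pts <- bind_rows(tibble(tpr = 0, fpr = 0), pts, tibble(tpr = 1, fpr = 1))
  ggplot(pts, aes(.data$fpr, .data$tpr)) +
    geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey60") +
    geom_path() +
    annotate("text", x = 0.7, y = 0.15,
             label = sprintf("AUC = %.3f (p = %.3g)", x$auc, x$p)) +
    labs(x = "False positive rate", y = "True positive rate") +
    theme_minimal()
}

#' Permutation null of the maximal component statistic
#'
#' Histogram of the permutation distribution with the observed maximal
#' component statistic marked.
#'
#' @param x An `nbs_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.nbs_result <- function(x, ...) {
  ggplot(tibble(null_max = x$null_max), aes(.data$null_max)) +
    geom_histogram(bins = 30, fill = "grey75", colour = "grey40") +
    geom_vline(xintercept = x$observed_max, colour = "red3") +
    labs(x = sprintf("max component %s under permutation", x$statistic),
         y = "count",
         title = sprintf("observed max = %g", x$observed_max)) +
    theme_minimal()
}

#' @export
ggplot2::autoplot
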