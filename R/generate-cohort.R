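# Synthetic multi-paradigm cohort generator.
#
# All randomness is drawn inside one seeded block, in a fixed order, so a
# configuration maps to a bit-identical cohort. Every scan covariance is
# positive semi-definite by construction: a per-scan factor model carries
# subject/paradigm variation, the planted network enters as symmetric
# signal mixing between its node pairs (a congruence transform whose weight
# encodes the subject's network strength), and the global covariate
# modulation is a convex blend of the correlation matrix with the identity.

# internal constants
.diag_boost <- 1.5        # diagonal of the factor model covariance
.c_fd_slope <- 0.08       # global modulation: motion inflates connectivity
.c_age_slope <- 0.04      # global modulation: connectivity declines with age
.c_resid_sd <- 0.05
.c_center <- 0.12         # mean log-attenuation of the global modulation

#' Generate a synthetic multi-paradigm cohort
#'
#' Draws a cohort with the statistical structure the cross-paradigm analysis
#' assumes: per-subject latent connectivity shared across paradigms, a
#' planted hyperconnected subnetwork with a graded group effect, covariate
#' confounding of global connectivity and of the planted-network strength,
#' and phenotypes coupled to that strength. See [synth_config()] for the
#' model and parameters.
#'
#' @param config A [synth_config()].
#' @return A list of class `synthetic_cohort` with elements
#'   \describe{
#'     \item{scans}{named list of [scan_ts()] objects ("subject.paradigm")}
#'     \item{scan_index}{tibble mapping subject/paradigm to scan names}
#'     \item{design}{sample sheet: subject_id, group (ordered factor), age,
#'       sex, iq, site, fd, dose}
#'     \item{phenotypes}{symptom scores, months_to_conversion (highest-risk
#'       group only), follow_up_months}
#'     \item{truth}{planted [network_mask()], per-group effect sizes, the
#'       calibrated shifts, and the subject-level latent planted-network
#'       strength}
#'     \item{config}{the generating configuration}
#'   }
#' @export
#' @examples
#' cfg <- synth_config(n_nodes = 20, n_paradigms = 2, timepoints = 40,
#'                     group_sizes = c(a = 4, b = 4), effect_sizes = c(0, 1),
#'                     planted_edge_count = 5, seed = 7)
#' cohort <- generate_cohort(cfg)
#' cohort$design
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  cfg <- config
  n <- sum(cfg$group_sizes)
  n_nodes <- cfg$n_nodes
  k <- cfg$n_paradigms
  f <- cfg$shared_variance_fraction
  sf <- sqrt(f)
  sb <- sqrt(1 - f)

  mask <- cfg$planted_mask
  if (is.null(mask)) {
    # mask drawn from a seed offset so it is stable across configs that only
    # differ in downstream parameters
    mask <- plant_network(n_nodes, cfg$planted_edge_count,
                          seed = cfg$seed + 1000L,
                          connected = cfg$planted_connected)
  }
  mi <- mask$node_i + 1L
  mj <- mask$node_j + 1L
  mask_ids <- mask_edge_ids(mask, n_nodes)
  m_edges <- length(mask_ids)
  lt <- lower_tri_idx(n_nodes)

  # The planted-network strength acts as symmetric signal mixing between
  # the mask node pairs: Sigma' = M Sigma M with M = I + Theta, Theta
  # holding the mixing weight theta_e at the mask entries. A congruence
  # transform keeps any covariance positive semi-definite for any theta, so
  # strength can move both ways without leaving the correlation cone.
  mix_matrix <- function(theta) {
    # cap at the rising branch of the response (ceiling effect for the few
    # subjects in the heavy upper tail of the strength distribution)
    theta <- pmin(theta, 0.9)
    m <- diag(n_nodes)
    m[cbind(mi, mj)] <- theta
    m[cbind(mj, mi)] <- theta
    m
  }
  mixed_cor <- function(sigma, theta) {
    m <- mix_matrix(theta)
    stats::cov2cor(m %*% sigma %*% m)
  }
  # planted-edge correlations only, on the observed scale: white measurement
  # noise of variance noise_sd^2 attenuates unit-variance signal correlations
  # by 1 / (1 + noise_sd^2) (used by the calibration passes)
  attn <- 1 / (1 + cfg$noise_sd^2)
  mask_cor_of <- function(sigma, theta, c_s) {
    cm <- mixed_cor(sigma, theta)
    attn * c_s * cm[cbind(mi, mj)]
  }

  with_rng(cfg$seed, {
    w0 <- matrix(rnorm(n_nodes * cfg$base_rank, sd = cfg$base_loading_sd),
                 n_nodes, cfg$base_rank)
    sigma0 <- tcrossprod(w0) + .diag_boost * diag(n_nodes)
    ## baseline mixing weight: places the planted edges' mean Fisher-z value
    ## at mask_base_z on the base covariance
    theta0 <- stats::uniroot(function(th) {
      mean(atanh(mask_cor_of(sigma0, th, 1))) - cfg$mask_base_z
    }, c(0, 1.5), tol = 1e-6)$root
    theta_jitter <- rnorm(m_edges, 0, 0.03)

    ## sample sheet covariates (identically distributed across groups)
    group <- factor(rep(names(cfg$group_sizes), cfg$group_sizes),
                    levels = names(cfg$group_sizes), ordered = TRUE)
    subject_id <- sprintf("S%03d", seq_len(n))
    age <- rnorm(n, 20, 2)
    sex <- sample(c("F", "M"), n, replace = TRUE)
    iq <- rnorm(n, 105, 12)
    site <- sample(c("site1", "site2"), n, replace = TRUE)
    fd <- rlnorm(n, meanlog = log(0.12), sdlog = 0.4)
    dose <- ifelse(runif(n) < 0.6, 0,
                   rlnorm(n, meanlog = log(150), sdlog = 0.6))

    std <- function(x) if (sd(x) > 0) (x - mean(x)) / sd(x) else x * 0
    age_z <- std(age); fd_z <- std(fd); dose_z <- std(dose)

    ## global multiplicative modulation (convex blend weight, <= 1) and
    ## latent planted-network strength
    c_subj <- pmin(1, exp(-(.c_center - .c_fd_slope * fd_z +
                              .c_age_slope * age_z +
                              rnorm(n, 0, .c_resid_sd))))
    slopes <- cfg$covariate_model
    q_subj <- slopes$age * age_z + slopes$fd * fd_z + slopes$dose * dose_z +
      rnorm(n, 0, cfg$trait_level_sd)

    ## paradigm dropout (>= 2 paradigms always retained)
    keep <- matrix(runif(n * k) >= cfg$dropout_prob, n, k)
    for (s in seq_len(n)) {
      if (sum(keep[s, ]) < 2L) keep[s, sample.int(k, 2L)] <- TRUE
    }

    ## strength -> Fisher-z response slope (secant on the base covariance);
    ## covariate_model slopes are stated in Fisher-z units and converted to
    ## mixing-weight units through this slope
    slope_hat <- (mean(atanh(mask_cor_of(sigma0, theta0 + 0.1, 1))) -
                    mean(atanh(mask_cor_of(sigma0, theta0, 1)))) / 0.1
    theta_subj <- theta0 + sf * q_subj / slope_hat

    ## pass A: per-scan loadings, and the latent planted-edge Fisher-z mean
    ## used to calibrate the group shift
    wsp <- vector("list", n)
    m_latent <- numeric(n)
    for (s in seq_len(n)) {
      w_s <- w0 + sf * cfg$subject_topography_sd *
        matrix(rnorm(n_nodes * cfg$base_rank), n_nodes, cfg$base_rank)
      wsp[[s]] <- lapply(seq_len(k), function(p) {
        w_s + sb * cfg$paradigm_sd *
          matrix(rnorm(n_nodes * cfg$base_rank), n_nodes, cfg$base_rank)
      })
      zm <- vapply(which(keep[s, ]), function(p) {
        sig <- tcrossprod(wsp[[s]][[p]]) + .diag_boost * diag(n_nodes)
        mean(atanh(mask_cor_of(sig, theta_subj[s] + theta_jitter,
                               c_subj[s])))
      }, numeric(1))
      m_latent[s] <- mean(zm)
    }
    sd0 <- sd(m_latent)
    if (!is.finite(sd0) || sd0 <= 0) {
      abort("degenerate latent structure: planted-edge mean has zero variance")
    }
    delta_z <- cfg$effect_sizes * sd0
    ## invert the (concave) strength response, averaged over the subject
    ## theta distribution, so each group's mean Fisher-z shift is delivered
    ## despite saturation at the strong end
    probe <- if (n > 48L) {
      order(theta_subj)[round(seq(1, n, length.out = 48L))]
    } else {
      seq_len(n)
    }
    ## the response is probed on the actual per-scan loadings (a couple of
    ## paradigms per probe subject), so saturation is measured exactly where
    ## the scans are generated
    resp <- function(d) {
      mean(vapply(probe, function(s) {
        ps <- utils::head(which(keep[s, ]), 2L)
        mean(vapply(ps, function(p) {
          sig <- tcrossprod(wsp[[s]][[p]]) + .diag_boost * diag(n_nodes)
          mean(atanh(mask_cor_of(sig, theta_subj[s] + theta_jitter + d,
                                 c_subj[s])))
        }, numeric(1)))
      }, numeric(1)))
    }
    resp0 <- resp(0)
    d_hi <- 0.7
    if (resp(d_hi) - resp0 < max(delta_z)) {
      abort("requested effect sizes exceed the strength response range; reduce effect_sizes or covariate slopes")
    }
    delta_theta <- vapply(delta_z, function(dz) {
      if (dz <= 0) return(dz / slope_hat)
      stats::uniroot(function(d) resp(d) - resp0 - dz,
                     c(0, d_hi), tol = 1e-4)$root
    }, numeric(1))
    delta_theta_subj <- delta_theta[as.integer(group)]

    ## pass B: time series per retained scan
    t_max <- max(cfg$timepoints)
    n_scans <- sum(keep)
    scans <- vector("list", n_scans)
    scan_sub <- character(n_scans); scan_par <- character(n_scans)
    scan_fd_mean <- matrix(NA_real_, n, k)
    idx <- 0L
    for (s in seq_len(n)) {
      u <- matrix(rnorm(t_max * n_nodes), t_max, n_nodes)
      theta_s <- theta_subj[s] + delta_theta_subj[s] + theta_jitter
      for (p in seq_len(k)) {
        if (!keep[s, p]) next
        t_p <- cfg$timepoints[p]
        sigma <- tcrossprod(wsp[[s]][[p]]) + .diag_boost * diag(n_nodes)
        cmat <- mixed_cor(sigma, theta_s)
        cmat <- c_subj[s] * cmat
        diag(cmat) <- 1
        ch <- chol_psd(cmat)
        series <- u[seq_len(t_p), , drop = FALSE] %*% ch
        if (cfg$noise_sd > 0) {
          series <- series + cfg$noise_sd * matrix(rnorm(t_p * n_nodes),
                                                   t_p, n_nodes)
        } else {
          rnorm(1)   # keep the draw count stable across noise settings
        }
        nuis <- make_nuisance(t_p, fd[s])
        scan_fd_mean[s, p] <- attr(nuis, "fd_mean")
        idx <- idx + 1L
        scans[[idx]] <- scan_ts(t(series), subject_id[s],
                                paste0("paradigm", p),
                                sampling_interval = cfg$sampling_interval,
                                nuisance = nuis)
        scan_sub[idx] <- subject_id[s]
        scan_par[idx] <- paste0("paradigm", p)
      }
      wsp[s] <- list(NULL)   # release
    }
    names(scans) <- paste(scan_sub, scan_par, sep = ".")

    ## phenotypes coupled to realized planted-network strength
    strength <- std(m_latent + delta_z[as.integer(group)])
    cp <- cfg$phenotype_coupling
    symptom_positive <- cp * strength + rnorm(n)
    symptom_disorganization <- cp * strength + rnorm(n)
    top <- levels(group)[nlevels(group)]
    is_top <- group == top
    u_conv <- -cp * strength + rnorm(n)
    months <- 1 + 23 * pnorm(u_conv / sqrt(cp^2 + 1))
    months[!is_top] <- NA_real_
    follow_up <- runif(n, 12, 36)
    follow_up[is_top] <- pmax(follow_up[is_top], months[is_top] + 1)

    design <- tibble(
      subject_id = subject_id, group = group, age = age, sex = sex, iq = iq,
      site = site, fd = rowMeans(scan_fd_mean, na.rm = TRUE), dose = dose)
    phenotypes <- tibble(
      subject_id = subject_id,
      symptom_positive = symptom_positive,
      symptom_disorganization = symptom_disorganization,
      months_to_conversion = months,
      follow_up_months = follow_up)

    structure(list(
      scans = scans,
      scan_index = tibble(subject_id = scan_sub, paradigm = scan_par,
                          scan = names(scans)),
      design = design,
      phenotypes = phenotypes,
      truth = list(mask = mask, effect_sizes = cfg$effect_sizes,
                   delta_z = delta_z, planted_sd = sd0,
                   strength_slope = slope_hat,
                   planted_strength = as.numeric(m_latent +
                                                   delta_z[as.integer(group)])),
      config = cfg), class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d subjects, %d scans, %d nodes, planted %d edges\n",
              nrow(x$design), length(x$scans), x$config$n_nodes,
              nrow(x$truth$mask)))
  print(table(x$design$group))
  invisible(x)
}

# Linear indices of the lower triangle. Column-major traversal of the lower
# triangle of the TRANSPOSED matrix visits upper-triangle entries (i, j),
# i < j, in row-major order -- the package's canonical edge order.
lower_tri_idx <- function(n) {
  which(lower.tri(matrix(FALSE, n, n)))
}

# extract the canonical (row-major upper-triangle) edge vector
extract_edges <- function(m, lt = lower_tri_idx(nrow(m))) {
  t(m)[lt]
}

# rebuild a symmetric matrix (unit diagonal) from a canonical edge vector
devectorize_z <- function(values, n_nodes, lt = lower_tri_idx(n_nodes)) {
  mt <- diag(n_nodes)
  mt[lt] <- values       # (j, i) of the transpose <- row-major (i, j) value
  m <- t(mt)
  m[lower.tri(m)] <- mt[lt]
  m
}

# Cholesky factor with eigenvalue-clip repair for marginally indefinite
# correlation matrices; hard failure when clearly not a correlation matrix.
# The generator's construction is PSD by design, so this is a numerical
# safety net rather than a workhorse.
chol_psd <- function(r, hard_floor = -0.2) {
  ch <- tryCatch(chol(r), error = function(e) NULL)
  if (!is.null(ch)) return(ch)
  eg <- eigen(r, symmetric = TRUE)
  if (min(eg$values) < hard_floor) {
    abort(sprintf(
      "assembled matrix is not positive semi-definite (min eigenvalue %.4f); reduce the planted shift or covariate slopes",
      min(eg$values)))
  }
  vals <- pmax(eg$values, 1e-6)
  r2 <- eg$vectors %*% (vals * t(eg$vectors))
  chol(stats::cov2cor(r2))
}

# drift + six smoothed motion columns + a positive FD series
make_nuisance <- function(t_p, fd_subject) {
  drift <- seq_len(t_p) / t_p
  motion <- vapply(1:6, function(i) {
    as.numeric(stats::filter(rnorm(t_p), 0.8, method = "recursive"))
  }, numeric(t_p))
  fd_series <- fd_subject * exp(rnorm(t_p, 0, 0.3))
  out <- cbind(drift = drift, motion, fd = fd_series)
  colnames(out) <- c("drift", paste0("motion", 1:6), "fd")
  attr(out, "fd_mean") <- mean(fd_series)
  out
}
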