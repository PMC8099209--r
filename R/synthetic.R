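#' Default marginal score targets per sign
#'
#' Target stationary distributions over scores 0..4 used to calibrate each
#' sign's cutpoints. Oedema is heavily zero-inflated (90% zeros), oozing
#' nearly so; dryness and itching have the broadest spread. These emulate the
#' qualitative imbalance pattern of daily paediatric AD sign scores.
#'
#' @return Named list of six length-5 probability vectors.
#' @export
default_marginal_targets <- function() {
  list(
    dryness = c(0.30, 0.30, 0.25, 0.10, 0.05),
    oedema  = c(0.90, 0.05, 0.03, 0.015, 0.005),
    itching = c(0.25, 0.30, 0.25, 0.15, 0.05),
    oozing  = c(0.80, 0.10, 0.06, 0.03, 0.01),
    redness = c(0.40, 0.30, 0.20, 0.07, 0.03),
    sleep   = c(0.55, 0.25, 0.12, 0.06, 0.02))
}

#' Default environmental series parameters
#'
#' Each of the seven city-level series is a seasonal sinusoid (period 365
#' days) plus a stationary AR(1) deviation. `mean`/`amplitude` are in the
#' series' units, `peak_day` is the day of the seasonal maximum, `ar` the
#' lag-1 coefficient and `innovation_sd` the AR(1) innovation SD (stationary
#' SD = innovation_sd / sqrt(1 - ar^2)). Values are plausible mid-latitude
#' city magnitudes, not a reconstruction of any real series.
#'
#' @return A data.frame, one row per covariate.
#' @export
default_env_params <- function() {
  data.frame(
    covariate = .ENV_COVARIATES,
    mean = c(12, 62, 5, 9, 45, 25, 30),
    amplitude = c(14, 12, 4, 2, 15, 8, 12),
    peak_day = c(210, 210, 200, 290, 30, 30, 180),
    ar = c(0.8, 0.7, 0.3, 0.5, 0.75, 0.75, 0.7),
    innovation_sd = c(1.5, 3, 3, 1.2, 8, 4, 5),
    stringsAsFactors = FALSE)
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults mirror the emulated study conditions: 177 patients followed for
#' 510 days (about 17 months), 18.9% of sign-score cells missing completely
#' at random, strong day-to-day persistence through the previous-score
#' coefficients, a unit-SD patient random intercept, and (by default)
#' zero-effect covariates — the null-environment scenario.
#'
#' @param n_patients Number of patients.
#' @param n_days Days of follow-up.
#' @param sigma_alpha SD of the per-patient, per-sign random intercept.
#' @param beta Persistence coefficients for previous scores 0..3 (score 4 is
#'   the reference and contributes 0).
#' @param gamma Named vector of true covariate effects on the linear
#'   predictor. Environmental effects apply to the z-scored series, `tcs` to
#'   the raw 0/1 flag. Default: all zero.
#' @param marginal_targets Per-sign target stationary score distributions
#'   (see [default_marginal_targets()]).
#' @param cutpoints Optional named list of per-sign cutpoint vectors; `NULL`
#'   (default) calibrates them to `marginal_targets` via
#'   [calibrate_cutpoints()].
#' @param missing_rate MCAR missingness fraction for sign-score cells.
#' @param env_params Environmental series parameters
#'   (see [default_env_params()]).
#' @param tcs_policy `list(intercept, slope)`: the daily TCS-use probability
#'   is `plogis(intercept + slope * previous-day mean sign score)`.
#' @param burn_in Discarded initial days per patient.
#' @param seed Master seed; all stage-level substreams derive from it.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_patients = 177, n_days = 510, sigma_alpha = 1,
                             beta = c(-6, -4, -2, -0.75),
                             gamma = setNames(rep(0, 8), covariate_names()),
                             marginal_targets = default_marginal_targets(),
                             cutpoints = NULL, missing_rate = 0.189,
                             env_params = default_env_params(),
                             tcs_policy = list(intercept = -2, slope = 0.6),
                             burn_in = 30, seed = 1) {
  stopifnot(n_patients >= 1, n_days >= 1, sigma_alpha >= 0,
            length(beta) == 4, missing_rate >= 0, missing_rate < 1)
  seed <- as.integer(seed)
  if (is.null(names(gamma)) || !all(names(gamma) %in% .COVARIATES))
    stop("gamma must be named by covariates")
  gamma_full <- setNames(rep(0, length(.COVARIATES)), .COVARIATES)
  gamma_full[names(gamma)] <- gamma
  if (is.null(cutpoints)) {
    cutpoints <- lapply(marginal_targets, calibrate_cutpoints,
                        beta = beta, sigma_alpha = sigma_alpha)
  }
  for (cp in cutpoints) check_cutpoints(cp)
  structure(list(n_patients = n_patients, n_days = n_days,
                 sigma_alpha = sigma_alpha, beta = beta, gamma = gamma_full,
                 marginal_targets = marginal_targets, cutpoints = cutpoints,
                 missing_rate = missing_rate, env_params = env_params,
                 tcs_policy = tcs_policy, burn_in = burn_in, seed = seed),
            class = "generator_config")
}

#' Calibrate ordered-logistic cutpoints to a target stationary distribution
#'
#' Given the persistence coefficients and random-intercept SD, finds the four
#' cutpoints for which the stationary distribution of the autoregressive
#' ordinal chain, averaged over the random-intercept distribution by
#' Gauss-Hermite quadrature, matches the target marginal. The 4 free
#' cutpoints exactly match the target's 4 degrees of freedom; the search runs
#' on the unconstrained (c1, log-increment) scale.
#'
#' @param target Length-5 probability vector over scores 0..4.
#' @param beta Persistence coefficients (length 4; reference score 4).
#' @param sigma_alpha Random-intercept SD.
#' @param quad_order Quadrature nodes for the intercept average.
#' @return Increasing numeric vector of 4 cutpoints.
#' @export
calibrate_cutpoints <- function(target, beta, sigma_alpha, quad_order = 15) {
  stopifnot(length(target) == 5, all(target > 0), abs(sum(target) - 1) < 1e-8)
  key <- paste(format(c(target, beta, sigma_alpha, quad_order), digits = 15),
               collapse = "|")
  cached <- calib_cache[[key]]
  if (!is.null(cached)) return(cached)
  gh <- if (sigma_alpha > 0) gauss_hermite(quad_order) else list(x = 0, w = sqrt(pi))
  alphas <- sqrt(2) * sigma_alpha * gh$x
  wts <- gh$w / sqrt(pi)

  marginal_for <- function(cuts) {
    m <- numeric(5)
    for (j in seq_along(alphas)) {
      # transition matrix rows: previous score 0..4
      eta <- alphas[j] + c(beta, 0)
      Tm <- ordered_logistic_pmf(eta, cuts)
      # stationary distribution: solve pi' (T - I) = 0, sum(pi) = 1
      A <- rbind(t(Tm) - diag(5), rep(1, 5))
      pi_j <- qr.solve(A, c(rep(0, 5), 1))
      m <- m + wts[j] * pi_j
    }
    m / sum(m)
  }
  obj <- function(par) {
    cuts <- par[1] + c(0, cumsum(exp(par[2:4])))
    sum((marginal_for(cuts) - target)^2)
  }
  cf <- pmin(pmax(cumsum(target)[1:4], 1e-6), 1 - 1e-6)
  c0 <- qlogis(cf)
  par0 <- c(c0[1], log(pmax(diff(c0), 1e-3)))
  opt <- optim(par0, obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-14))
  opt <- optim(opt$par, obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-14))
  if (opt$value > 1e-8)
    warning(sprintf("cutpoint calibration residual %.2e; target may be unreachable",
                    opt$value))
  out <- opt$par[1] + c(0, cumsum(exp(opt$par[2:4])))
  calib_cache[[key]] <- out
  out
}

# session-level memoisation of calibrated cutpoints (calibration is
# deterministic, so caching does not affect results)
calib_cache <- new.env(parent = emptyenv())

#' Generate the city-level environmental series
#'
#' Seven daily series, each a seasonal sinusoid (period 365 days, peaking at
#' the configured day of year) plus a stationary AR(1) deviation, shared by
#' all patients. Deterministic given the configuration's seed.
#'
#' @param config A [generator_config()].
#' @return A data.frame with columns `day` and the seven covariates.
#' @export
generate_environment <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  seeds <- derive_seeds(config$seed, c("environment", "alphas", "scores", "tcs",
                                       "missingness"))
  generate_environment_impl(config$env_params, config$n_days, seeds[["environment"]])
}

generate_environment_impl <- function(env_params, n_days, seed) {
  with_local_seed(seed, {
    out <- data.frame(day = seq_len(n_days))
    for (i in seq_len(nrow(env_params))) {
      p <- env_params[i, ]
      seasonal <- p$mean + p$amplitude *
        cos(2 * pi * (out$day - p$peak_day) / 365)
      stat_sd <- p$innovation_sd / sqrt(1 - p$ar^2)
      e <- numeric(n_days)
      if (p$innovation_sd > 0) {
        e[1] <- rnorm(1, 0, stat_sd)
        if (n_days > 1) {
          innov <- rnorm(n_days - 1, 0, p$innovation_sd)
          for (t in 2:n_days) e[t] <- p$ar * e[t - 1] + innov[t - 1]
        }
      }
      out[[p$covariate]] <- seasonal + e
    }
    out
  })
}

#' Generate a synthetic cohort with known ground truth
#'
#' Simulates the panel forward from the mixed-effect autoregressive ordinal
#' model itself: per patient and sign an intercept `alpha ~ N(0,
#' sigma_alpha^2)`; a `burn_in`-day warm-up started from the cutpoint-implied
#' distribution (discarded); then each day's score drawn from the
#' ordered-logistic transition with location `alpha + beta[s_t] +
#' gamma . x(t)`, where environmental covariates enter z-scored by their own
#' series mean/SD and TCS enters as the raw flag. TCS use each day is
#' Bernoulli with probability `plogis(intercept + slope * previous-day mean
#' sign score)`. Missingness is applied last, MCAR at the configured rate.
#' Fully deterministic given the configuration's seed.
#'
#' @param config A [generator_config()].
#' @return A list with elements `panel` (an [ad_panel]) and `truth` (all
#'   ground-truth parameters, including the per-patient intercept matrix and
#'   the seed).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  seeds <- derive_seeds(config$seed, c("environment", "alphas", "scores", "tcs",
                                       "missingness"))
  np <- config$n_patients; nd <- config$n_days; bi <- config$burn_in
  env <- generate_environment_impl(config$env_params, nd, seeds[["environment"]])

  # z-scores of the environmental series (the scale on which gamma acts)
  env_mean <- vapply(.ENV_COVARIATES, function(cv) mean(env[[cv]]), numeric(1))
  env_sd <- vapply(.ENV_COVARIATES, function(cv) {
    s <- sd(env[[cv]]); if (is.na(s) || s == 0) 1 else s
  }, numeric(1))
  Z <- vapply(.ENV_COVARIATES,
              function(cv) (env[[cv]] - env_mean[[cv]]) / env_sd[[cv]],
              numeric(nd))
  Z <- matrix(Z, nrow = nd)
  env_effect <- drop(Z %*% config$gamma[.ENV_COVARIATES])  # per-day scalar
  g_tcs <- config$gamma[["tcs"]]

  alpha <- with_local_seed(seeds[["alphas"]],
    matrix(rnorm(np * 6, 0, config$sigma_alpha), np, 6,
           dimnames = list(NULL, .SIGNS)))

  total_days <- bi + nd
  scores <- lapply(.SIGNS, function(s) matrix(NA_integer_, np, nd))
  names(scores) <- .SIGNS
  tcs_mat <- matrix(0L, np, nd)

  # inverse-CDF ordinal draw: score = number of cutpoint CDF values below u
  draw_ordinal <- function(pmf, u) {
    cdf <- pmf %*% upper.tri(matrix(1, 5, 5), diag = TRUE) * 1
    as.integer(rowSums(cdf < u))
  }

  tcs_seeds <- derive_seeds(seeds[["tcs"]], as.character(seq_len(total_days)))
  with_local_seed(seeds[["scores"]], {
    cur <- matrix(NA_integer_, np, 6, dimnames = list(NULL, .SIGNS))
    # initial state from the cutpoint-implied pmf at eta = alpha
    for (s in .SIGNS) {
      pmf <- ordered_logistic_pmf(alpha[, s], config$cutpoints[[s]])
      cur[, s] <- draw_ordinal(pmf, runif(np))
    }
    cur_tcs <- integer(np)
    for (t in seq_len(total_days)) {
      day <- t - bi  # <= 0 during burn-in
      env_day <- if (day >= 1) day else 1L  # burn-in reuses day-1 covariates
      xeff <- env_effect[env_day]
      nxt <- cur
      for (s in .SIGNS) {
        eta <- alpha[, s] +
          ifelse(cur[, s] <= 3, config$beta[cur[, s] + 1], 0) +
          xeff + g_tcs * cur_tcs
        pmf <- ordered_logistic_pmf(eta, config$cutpoints[[s]])
        nxt[, s] <- draw_ordinal(pmf, runif(np))
      }
      # TCS decided from the day's mean sign score (acts on the next day)
      p_tcs <- plogis(config$tcs_policy$intercept +
                        config$tcs_policy$slope * rowMeans(nxt))
      new_tcs <- with_local_seed(tcs_seeds[[t]],
                                 as.integer(runif(np) < p_tcs))
      if (day >= 1) {
        for (s in .SIGNS) scores[[s]][, day] <- nxt[, s]
        tcs_mat[, day] <- new_tcs
      }
      cur <- nxt
      cur_tcs <- new_tcs
    }
  })

  ids <- sprintf("P%03d", seq_len(np))
  long <- data.frame(
    patient_id = rep(ids, each = nd),
    day = rep(seq_len(nd), times = np))
  for (s in .SIGNS) long[[s]] <- as.integer(t(scores[[s]]))
  long$tcs <- as.integer(t(tcs_mat))
  for (cv in .ENV_COVARIATES) long[[cv]] <- rep(env[[cv]], times = np)

  panel <- ad_panel(long)
  panel <- apply_missingness(panel, config$missing_rate, seeds[["missingness"]])

  truth <- list(
    n_patients = np, n_days = nd, sigma_alpha = config$sigma_alpha,
    beta = config$beta, gamma = as.list(config$gamma),
    cutpoints = config$cutpoints, marginal_targets = config$marginal_targets,
    alpha = setNames(lapply(.SIGNS, function(s) setNames(alpha[, s], ids)), .SIGNS),
    env_mean = as.list(env_mean), env_sd = as.list(env_sd),
    missing_rate = config$missing_rate, tcs_policy = config$tcs_policy,
    burn_in = config$burn_in, seed = config$seed)
  list(panel = panel, truth = truth)
}

#' Apply MCAR missingness to sign-score cells
#'
#' Each sign-score cell is independently set missing with probability `rate`;
#' covariates and the TCS flag are untouched. Deterministic given `seed`.
#'
#' @param ds An [ad_panel].
#' @param rate Missingness probability in `[0, 1)`.
#' @param seed Integer seed.
#' @return The panel with missingness applied.
#' @export
apply_missingness <- function(ds, rate, seed) {
  stopifnot(inherits(ds, "ad_panel"), rate >= 0, rate < 1)
  if (rate == 0) return(ds)
  with_local_seed(seed, {
    for (s in .SIGNS) {
      drop <- runif(nrow(ds)) < rate
      ds[[s]][drop] <- NA_integer_
    }
  })
  ds
}

#' Write / read a cohort (panel CSV + ground-truth JSON sidecar)
#'
#' The sidecar holds every ground-truth parameter and the seed at full
#' numeric precision, so it round-trips exactly.
#'
#' @param cohort A list as returned by [generate_cohort()].
#' @param dir Output directory (created if absent).
#' @param prefix File-name prefix.
#' @return `write_cohort`: named vector of paths, invisibly. `read_cohort`:
#'   a list with `panel` and `truth`.
#' @export
write_cohort <- function(cohort, dir, prefix = "cohort") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  panel_path <- file.path(dir, paste0(prefix, ".csv"))
  truth_path <- file.path(dir, paste0(prefix, "_truth.json"))
  write_panel(cohort$panel, panel_path)
  truth <- cohort$truth
  truth$alpha <- lapply(truth$alpha, as.list)  # keep patient ids as JSON keys
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = I(17))
  invisible(c(panel = panel_path, truth = truth_path))
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir, prefix = "cohort") {
  panel <- read_panel(file.path(dir, paste0(prefix, ".csv")))
  truth <- jsonlite::read_json(file.path(dir, paste0(prefix, "_truth.json")),
                               simplifyVector = TRUE)
  truth$beta <- as.numeric(truth$beta)
  truth$cutpoints <- lapply(truth$cutpoints, as.numeric)
  truth$alpha <- lapply(truth$alpha, unlist)
  list(panel = panel, truth = truth)
}
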