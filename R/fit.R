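#' Fit a mixed-effect autoregressive ordinal logistic model for one sign
#'
#' Maximises the adaptive Gauss-Hermite approximation to the marginal
#' likelihood over the previous-score coefficients beta (score 4 is the
#' reference), covariate coefficients gamma, monotone cutpoints and the
#' random-intercept SD, with a small ridge penalty on (beta, gamma) that keeps
#' estimates finite under separation. Continuous covariates are z-scored on
#' the training pairs (population SD) unless ready-made statistics are
#' supplied; the binary `tcs` flag is never scaled. Optimisation is
#' deterministic from a fixed initialisation, so refitting the same data and
#' options reproduces the estimates exactly.
#'
#' @param pairs An `ad_pairs` table from [extract_transition_pairs()].
#' @param covariates Character vector of covariate columns to include
#'   (default: the pair table's own covariate set).
#' @param quad_order Quadrature nodes for the marginal likelihood (default 9).
#' @param lambda Ridge penalty on beta and gamma (default 1e-4; 0 disables).
#' @param compute_se If `TRUE` (default), standard errors from the observed
#'   information at the optimum.
#' @param stats Optional `covariate_stats` to reuse (e.g. from a previous
#'   training window); `NULL` fits them from `pairs`.
#' @param init Optional warm-start: a previous `sign_model` or raw parameter
#'   vector.
#' @param maxit Maximum optimiser iterations.
#' @return An object of class `sign_model`.
#' @export
fit_sign_model <- function(pairs, covariates = attr(pairs, "covariates"),
                           quad_order = 9, lambda = 1e-4, compute_se = TRUE,
                           stats = NULL, init = NULL, maxit = 300) {
  stopifnot(inherits(pairs, "ad_pairs"))
  if (nrow(pairs) == 0) stop("no transition pairs to fit")
  if (length(unique(pairs$s_next)) < 2)
    stop("need at least 2 distinct outcome categories")
  covariates <- as.character(covariates %||% character(0))

  # standardise continuous covariates on the training window
  if (length(covariates) > 0) {
    attr(pairs, "covariates") <- covariates
    std <- standardize_covariates(pairs, stats)
    pairs <- std$pairs
    stats <- std$stats
  } else stats <- NULL

  blocks <- pairs_to_blocks(pairs, covariates)
  p <- length(covariates)
  npat <- length(blocks$patients)
  gh <- gauss_hermite(quad_order)

  single_patient <- npat < 2

  if (is.null(init)) {
    # cutpoints at the logit of (clamped) empirical cumulative frequencies
    freq <- tabulate(blocks$snext + 1L, nbins = 5)
    cf <- cumsum(freq / sum(freq))[1:4]
    cf <- pmin(pmax(cf, 1e-3), 1 - 1e-3)
    cf <- cummax(cf + (0:3) * 1e-6)  # enforce strict increase
    theta0 <- c(rep(0, 4 + p), qlogis(cf)[1], log(pmax(diff(qlogis(cf)), 1e-3)), 0)
  } else if (inherits(init, "sign_model")) {
    theta0 <- init$theta
    if (length(theta0) != 4 + p + 5) stop("init model has a different covariate set")
  } else {
    theta0 <- init
    stopifnot(length(theta0) == 4 + p + 5)
  }

  trace_env <- new.env(parent = emptyenv())
  trace_env$nll <- numeric(0)
  # L-BFGS-B cannot digest non-finite values: cap the objective (line
  # searches then back off) and zero a non-finite gradient
  fn <- function(th) {
    v <- agq_objective_cpp(th, blocks$sprev, blocks$snext, blocks$X,
                           blocks$pstart, gh$x, gh$w, lambda, FALSE, FALSE)$nll
    if (!is.finite(v)) v <- 1e10
    trace_env$nll <- c(trace_env$nll, v)
    v
  }
  gr <- function(th) {
    g <- agq_objective_cpp(th, blocks$sprev, blocks$snext, blocks$X,
                           blocks$pstart, gh$x, gh$w, lambda, TRUE, FALSE)$grad
    g[!is.finite(g)] <- 0
    mx <- max(abs(g))
    if (mx > 1e6) g <- g * (1e6 / mx)  # direction only, in pathological regions
    g
  }
  # box bounds keep the optimiser in a numerically sane region: |coefficients|
  # and cutpoints beyond ~30 logits are never statistically meaningful, and a
  # single cutpoint increment above exp(5) ~ 150 logits only arises while an
  # outcome category is absent from the training window
  lower <- c(rep(-30, 4 + p), -30, rep(-8, 3), -8)
  upper <- c(rep(30, 4 + p), 30, rep(5, 3), 5)
  theta0 <- pmin(pmax(theta0, lower + 1e-8), upper - 1e-8)
  opt <- optim(theta0, fn, gr, method = "L-BFGS-B", lower = lower, upper = upper,
               control = list(maxit = maxit, factr = 5e6, pgtol = 1e-6))

  est <- theta_unpack(opt$par, p)
  names(est$gamma) <- covariates

  # empirical-Bayes modes at the optimum
  res <- agq_objective_cpp(opt$par, blocks$sprev, blocks$snext, blocks$X,
                           blocks$pstart, gh$x, gh$w, lambda, FALSE, TRUE)
  alpha_hat <- setNames(as.numeric(res$modes), blocks$patients)

  gamma_se <- rep(NA_real_, p)
  se_ok <- FALSE
  if (compute_se) {
    H <- tryCatch(optimHess(opt$par, fn, gr), error = function(e) NULL)
    if (!is.null(H)) {
      V <- tryCatch(solve(H), error = function(e) NULL)
      if (!is.null(V) && all(is.finite(diag(V))) && all(diag(V) > 0)) {
        gamma_se <- sqrt(diag(V))[4 + seq_len(p)]
        se_ok <- TRUE
      }
    }
  }
  names(gamma_se) <- covariates

  ll <- -opt$value + lambda * sum(opt$par[seq_len(4 + p)]^2)  # unpenalised logLik
  structure(list(
    sign = attr(pairs, "sign"), covariates = covariates,
    beta = setNames(est$beta, paste0("beta", 0:3)),
    gamma = est$gamma, gamma_se = gamma_se,
    cutpoints = est$cutpoints, sigma_alpha = est$sigma_alpha,
    alpha_hat = alpha_hat, stats = stats, theta = opt$par,
    fit_meta = list(
      logLik = ll, penalised_nll = opt$value, quad_order = quad_order,
      lambda = lambda, n_pairs = nrow(pairs), n_patients = npat,
      converged = opt$convergence == 0, optim_message = opt$message,
      counts = opt$counts, nll_trace = trace_env$nll, se_ok = se_ok,
      single_patient = single_patient)),
    class = "sign_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.sign_model <- function(x, ...) {
  cat(sprintf("<sign_model> sign = %s; %d pairs, %d patients%s\n",
              x$sign %||% "?", x$fit_meta$n_pairs, x$fit_meta$n_patients,
              if (x$fit_meta$converged) "" else " [NOT CONVERGED]"))
  cat("  beta (prev score 0..3 vs ref 4): ",
      paste(sprintf("%.3f", x$beta), collapse = ", "), "\n", sep = "")
  cat("  cutpoints: ", paste(sprintf("%.3f", x$cutpoints), collapse = ", "), "\n", sep = "")
  cat(sprintf("  sigma_alpha = %.3f; log marginal lik = %.2f\n",
              x$sigma_alpha, x$fit_meta$logLik))
  if (length(x$gamma) > 0) {
    cat("  covariates (standardised scale):\n")
    for (j in seq_along(x$gamma))
      cat(sprintf("    %-9s %+.4f (SE %.4f)\n", names(x$gamma)[j],
                  x$gamma[j], x$gamma_se[j]))
  }
  if (x$fit_meta$single_patient)
    cat("  note: single patient; sigma_alpha is not identifiable\n")
  invisible(x)
}

#' Empirical-Bayes random-intercept estimate for one patient
#'
#' Mode of the conditional density of the patient's intercept given their
#' transition pairs and the fitted population parameters. Returns 0 (the
#' prior mean) for a patient with no pairs or when `sigma_alpha` is 0.
#'
#' @param model A fitted `sign_model`.
#' @param patient_pairs The patient's `ad_pairs` rows (covariates on the raw
#'   scale; they are standardised with the model's training statistics).
#' @return The scalar mode.
#' @export
eb_alpha <- function(model, patient_pairs) {
  stopifnot(inherits(model, "sign_model"))
  if (is.null(patient_pairs) || nrow(patient_pairs) == 0) return(0)
  if (model$sigma_alpha < 1e-8) return(0)
  eta0 <- fixed_eta(model, patient_pairs$s_t, patient_pairs, standardize = TRUE)
  obj <- function(a) {
    pmf <- ordered_logistic_pmf(eta0 + a, model$cutpoints)
    sum(log(pmf[cbind(seq_along(eta0), patient_pairs$s_next + 1)])) -
      a^2 / (2 * model$sigma_alpha^2)
  }
  stats::optimize(obj, c(-10 * model$sigma_alpha - 10, 10 * model$sigma_alpha + 10),
                  maximum = TRUE, tol = 1e-9)$maximum
}

# fixed part of the linear predictor for new data (optionally standardising
# raw covariates with the model's training stats)
fixed_eta <- function(model, s_t, covariate_rows, standardize = TRUE) {
  eta <- ifelse(s_t <= 3, model$beta[s_t + 1], 0)
  for (cv in model$covariates) {
    x <- covariate_rows[[cv]]
    if (is.null(x) || anyNA(x)) stop("missing covariate required by model: ", cv)
    if (standardize && cv %in% model$stats$covariates)
      x <- (x - model$stats$mean[[cv]]) / model$stats$sd[[cv]]
    eta <- eta + model$gamma[[cv]] * x
  }
  as.numeric(eta)
}

#' One-step-ahead ordinal forecast
#'
#' Probability mass function over scores 0..4 for the next day given today's
#' score, using the patient's empirical-Bayes intercept (0 for a patient not
#' seen in training). Covariates are supplied on their raw scale and
#' standardised internally with the model's training statistics.
#'
#' @param model A fitted `sign_model`.
#' @param patient Patient identifier (vectorised).
#' @param s_t Today's score, 0..4 (vectorised).
#' @param covariates `NULL` for a covariate-free model, else a data.frame (or
#'   named list) with one column per model covariate, recycled or row-matched
#'   to `s_t`.
#' @return A `length(s_t) x 5` matrix of forecast probabilities.
#' @export
predict_forecast <- function(model, patient, s_t, covariates = NULL) {
  stopifnot(inherits(model, "sign_model"))
  if (anyNA(s_t) || any(s_t < 0 | s_t > 4)) stop("s_t must be in 0..4")
  n <- length(s_t)
  if (length(model$covariates) > 0) {
    if (is.null(covariates)) stop("model requires covariates: ",
                                  paste(model$covariates, collapse = ", "))
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) == 1 && n > 1)
      covariates <- covariates[rep(1, n), , drop = FALSE]
  }
  alpha <- model$alpha_hat[as.character(patient)]
  alpha[is.na(alpha)] <- 0
  eta <- alpha + fixed_eta(model, s_t, covariates, standardize = TRUE)
  ordered_logistic_pmf(eta, model$cutpoints)
}

#' Save / load a fitted sign model
#'
#' Serialises every estimated quantity (coefficients, cutpoints, random
#' intercepts, standardisation statistics, fit metadata) to a flat JSON file
#' at full numeric precision, so the reloaded model reproduces forecasts
#' exactly.
#'
#' @param model A `sign_model`.
#' @param path Output (input) file path.
#' @return `write_sign_model`: `path` invisibly. `read_sign_model`: the model.
#' @export
write_sign_model <- function(model, path) {
  stopifnot(inherits(model, "sign_model"))
  x <- unclass(model)
  # named vectors go out as JSON objects so the names survive the round trip
  for (f in c("beta", "gamma", "gamma_se", "alpha_hat")) x[[f]] <- as.list(x[[f]])
  x$fit_meta$counts <- as.list(x$fit_meta$counts)
  if (!is.null(x$stats)) {
    x$stats <- unclass(x$stats)
    x$stats$mean <- as.list(x$stats$mean)
    x$stats$sd <- as.list(x$stats$sd)
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17), null = "null")
  invisible(path)
}

#' @rdname write_sign_model
#' @export
read_sign_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("beta", "gamma", "gamma_se", "alpha_hat"))
    x[[f]] <- unlist(x[[f]]) %||% setNames(numeric(0), character(0))
  x$covariates <- as.character(x$covariates %||% character(0))
  x$theta <- as.numeric(x$theta)
  if (!is.null(x$stats) && length(x$stats) > 0) {
    x$stats <- structure(list(mean = unlist(x$stats$mean),
                              sd = unlist(x$stats$sd),
                              covariates = as.character(x$stats$covariates)),
                         class = "covariate_stats")
  } else x$stats <- NULL
  structure(x, class = "sign_model")
}
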