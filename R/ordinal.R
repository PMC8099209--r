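#' Indicator encoding of the previous day's score
#'
#' The autoregressive term of the linear predictor is `sum_i beta_i 1{s_t = i}`
#' for i = 0..3; score 4 is the reference category and maps to all zeros.
#'
#' @param s_t Integer vector of scores in 0..4.
#' @return A `length(s_t) x 4` indicator matrix.
#' @export
encode_previous_score <- function(s_t) {
  if (anyNA(s_t) || any(s_t < 0 | s_t > 4 | s_t != floor(s_t)))
    stop("s_t must be integers in 0..4")
  m <- matrix(0, length(s_t), 4)
  for (i in 0:3) m[, i + 1] <- as.numeric(s_t == i)
  m
}

check_cutpoints <- function(cutpoints) {
  if (length(cutpoints) != 4 || anyNA(cutpoints) || any(diff(cutpoints) <= 0))
    stop("cutpoints must be 4 strictly increasing finite values")
  invisible(cutpoints)
}

#' Ordered-logistic probability mass function
#'
#' Category probabilities over scores 0..4 for a location parameter `eta` and
#' four increasing cutpoints: `P(s <= k) = plogis(c[k+1] - eta)`. Vectorised
#' over `eta`. Probabilities are floored at 1e-300 so logs stay finite.
#'
#' @param eta Numeric vector of location values (the linear predictor).
#' @param cutpoints Increasing numeric vector of length 4.
#' @return A `length(eta) x 5` matrix of probabilities (rows sum to 1).
#' @export
ordered_logistic_pmf <- function(eta, cutpoints) {
  check_cutpoints(cutpoints)
  cdf <- vapply(cutpoints, function(ck) plogis(ck - eta),
                numeric(length(eta)))
  cdf <- matrix(cdf, nrow = length(eta), ncol = 4)
  pmf <- cbind(cdf[, 1], cdf[, 2] - cdf[, 1], cdf[, 3] - cdf[, 2],
               cdf[, 4] - cdf[, 3], 1 - cdf[, 4])
  pmf[pmf < 1e-300] <- 1e-300
  colnames(pmf) <- as.character(0:4)
  pmf
}

# validate a forecast pmf (length 5, non-negative, sums to 1)
check_pmf <- function(pmf, tol = 1e-6) {
  if (length(pmf) != 5 || anyNA(pmf) || any(pmf < 0) || abs(sum(pmf) - 1) > tol)
    stop("invalid forecast pmf: must be 5 non-negative values summing to 1")
  invisible(pmf)
}

# Gauss-Hermite nodes/weights (physicists' convention), cached per order
gh_cache <- new.env(parent = emptyenv())
gauss_hermite <- function(order) {
  key <- as.character(order)
  if (is.null(gh_cache[[key]])) {
    stopifnot(order >= 1)
    if (order == 1) gh_cache[[key]] <- list(x = 0, w = sqrt(pi))
    else gh_cache[[key]] <- pracma::gaussHermite(order)
  }
  gh_cache[[key]]
}

# assemble the raw optimisation vector from natural parameters
theta_pack <- function(beta, gamma, cutpoints, sigma_alpha) {
  check_cutpoints(cutpoints)
  d <- log(diff(cutpoints))
  c(beta, gamma, cutpoints[1], d, log(sigma_alpha))
}

theta_unpack <- function(theta, p) {
  beta <- theta[1:4]
  gamma <- if (p > 0) theta[4 + seq_len(p)] else numeric(0)
  c1 <- theta[4 + p + 1]
  d <- theta[4 + p + 1 + 1:3]
  cutpoints <- c1 + c(0, cumsum(exp(d)))
  sigma_alpha <- exp(theta[4 + p + 5])
  list(beta = beta, gamma = gamma, cutpoints = cutpoints, sigma_alpha = sigma_alpha)
}

# group a pair table by patient for the C++ kernel: returns list with
# integer vectors and 0-based patient offsets (pairs re-sorted by patient)
pairs_to_blocks <- function(pairs, covariates) {
  ord <- order(pairs$patient_id, pairs$day)
  pairs <- pairs[ord, , drop = FALSE]
  pid <- pairs$patient_id
  runs <- rle(pid)
  pstart <- c(0L, cumsum(runs$lengths))
  X <- if (length(covariates) > 0)
    as.matrix(pairs[, covariates, drop = FALSE])
  else matrix(0, nrow(pairs), 0)
  storage.mode(X) <- "double"
  list(sprev = as.integer(pairs$s_t), snext = as.integer(pairs$s_next),
       X = X, pstart = as.integer(pstart), patients = runs$values)
}

#' Log marginal likelihood of the mixed-effect autoregressive ordinal model
#'
#' Integrates the patient random intercept out of the ordered-logistic
#' autoregressive likelihood with adaptive Gauss-Hermite quadrature centred
#' at each patient's conditional mode. With `sigma_alpha = 0` the random
#' effect degenerates and the plain ordinal log-likelihood at alpha = 0 is
#' returned.
#'
#' @param beta Numeric vector of 4 previous-score coefficients.
#' @param gamma Named numeric vector of covariate coefficients (may be empty);
#'   names select columns of `pairs`.
#' @param cutpoints Increasing numeric vector of length 4.
#' @param sigma_alpha Random-intercept SD (>= 0).
#' @param pairs An `ad_pairs` table containing any covariates named in `gamma`.
#' @param quad_order Number of quadrature nodes (default 9).
#' @return The log marginal likelihood (a scalar).
#' @export
log_marginal_likelihood <- function(beta, gamma, cutpoints, sigma_alpha, pairs,
                                    quad_order = 9) {
  stopifnot(length(beta) == 4, quad_order >= 1)
  check_cutpoints(cutpoints)
  if (is.na(sigma_alpha) || sigma_alpha < 0) stop("sigma_alpha must be >= 0")
  covs <- names(gamma)
  if (length(gamma) > 0 && is.null(covs)) stop("gamma must be named by covariate")
  blocks <- pairs_to_blocks(pairs, covs)
  if (sigma_alpha == 0) {
    eta <- ifelse(blocks$sprev <= 3, beta[blocks$sprev + 1], 0)
    if (length(gamma) > 0) eta <- eta + drop(blocks$X %*% gamma)
    pmf <- ordered_logistic_pmf(eta, cutpoints)
    return(sum(log(pmf[cbind(seq_along(eta), blocks$snext + 1)])))
  }
  gh <- gauss_hermite(quad_order)
  theta <- theta_pack(beta, gamma, cutpoints, sigma_alpha)
  res <- agq_objective_cpp(theta, blocks$sprev, blocks$snext, blocks$X,
                           blocks$pstart, gh$x, gh$w, 0, FALSE, FALSE)
  -res$nll
}
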