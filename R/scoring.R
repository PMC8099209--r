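#' Ranked probability score for an ordinal forecast
#'
#' `RPS = (1/(K-1)) * sum_k (F_k - O_k)^2` over the K-1 = 4 inner thresholds,
#' with `F` the forecast CDF and `O` the outcome's step CDF. The 1/(K-1)
#' normalisation puts the score in `[0, 1]`: 0 for a point mass on the
#' observed outcome, 1 for a point mass at the opposite end of the scale.
#' Lower is better; the score is proper for ordinal forecasts.
#'
#' @param forecast A pmf over scores 0..4 (vector) or an `n x 5` matrix of
#'   pmfs (one per row).
#' @param outcome Observed score(s) in 0..4 (recycled against matrix rows).
#' @return Numeric vector of scores in `[0, 1]`.
#' @export
rps <- function(forecast, outcome) {
  if (is.null(dim(forecast))) {
    check_pmf(forecast)
    forecast <- matrix(forecast, 1)
  }
  if (anyNA(outcome) || any(outcome < 0 | outcome > 4))
    stop("outcome must be in 0..4")
  Fm <- t(apply(forecast, 1, cumsum))[, 1:4, drop = FALSE]
  O <- outer(outcome, 0:3, "<=") * 1
  rowSums((Fm - O)^2) / 4
}

#' Brier score for a binary probabilistic forecast
#'
#' @param prob Forecast probability (or probabilities) of outcome 1, in `[0,1]`.
#' @param outcome Observed binary outcome(s), 0 or 1.
#' @return `(prob - outcome)^2`, in `[0, 1]`.
#' @export
brier <- function(prob, outcome) {
  if (anyNA(prob) || any(prob < 0 | prob > 1)) stop("prob must be in [0, 1]")
  if (anyNA(outcome) || !all(outcome %in% c(0, 1))) stop("outcome must be 0/1")
  (prob - outcome)^2
}
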