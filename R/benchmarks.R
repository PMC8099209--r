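#' Uniform benchmark forecast
#'
#' The ignorance benchmark: each of the five possible scores is predicted
#' with probability one fifth.
#'
#' @return A numeric vector of 5 probabilities.
#' @export
uniform_forecast <- function() {
  setNames(rep(0.2, 5), as.character(0:4))
}

#' Historical benchmark forecast
#'
#' Predicts each score with its relative frequency in the patient's own past
#' observations of that sign. An empty history falls back to the uniform
#' forecast; categories never observed get probability exactly 0 (no
#' smoothing — both scoring rules stay finite).
#'
#' @param history Integer vector of the patient's observed scores (0..4) up
#'   to, and excluding, the forecast day. `NA`s are dropped.
#' @return A numeric vector of 5 probabilities.
#' @export
historical_forecast <- function(history) {
  history <- history[!is.na(history)]
  if (length(history) == 0) return(uniform_forecast())
  if (any(history < 0 | history > 4)) stop("history scores must be in 0..4")
  counts <- tabulate(history + 1L, nbins = 5)
  setNames(counts / sum(counts), as.character(0:4))
}
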