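#' Probability of the binary AD symptom state from six sign forecasts
#'
#' Converts six per-sign forecast pmfs into the exact probability that the
#' derived symptom state equals 1, treating the six forecasts as independent.
#' The state factorises over disjoint sign sets: condition A
#' (itching + sleep >= 2) is computed by discrete convolution of the itching
#' and sleep pmfs, and condition B (at least 2 of redness, dryness, oedema,
#' oozing non-zero) from the four non-zero probabilities via the
#' Poisson-binomial tail, so the returned value is P(A) * P(B) exactly.
#'
#' @param forecasts A named list of six pmfs (length-5 numeric vectors) with
#'   names `itching`, `sleep`, `redness`, `dryness`, `oedema`, `oozing`.
#' @return The state probability, a scalar in `[0, 1]`.
#' @export
state_probability <- function(forecasts) {
  f <- check_state_forecasts(forecasts)
  # P(itching + sleep <= 1) = p_i0*p_s0 + p_i0*p_s1 + p_i1*p_s0
  pi0 <- f$itching[1]; pi1 <- f$itching[2]
  ps0 <- f$sleep[1]; ps1 <- f$sleep[2]
  pA <- 1 - (pi0 * ps0 + pi0 * ps1 + pi1 * ps0)
  # Poisson-binomial: P(>= 2 of 4 non-zero)
  q <- vapply(f[c("redness", "dryness", "oedema", "oozing")],
              function(p) 1 - p[1], numeric(1))
  p0 <- prod(1 - q)
  p1 <- sum(vapply(1:4, function(j) q[j] * prod((1 - q)[-j]), numeric(1)))
  pB <- 1 - p0 - p1
  max(0, min(1, pA * pB))
}

check_state_forecasts <- function(forecasts) {
  need <- c("itching", "sleep", "redness", "dryness", "oedema", "oozing")
  if (!is.list(forecasts) || !all(need %in% names(forecasts)))
    stop("forecasts must be a named list covering: ", paste(need, collapse = ", "))
  for (s in need) check_pmf(forecasts[[s]])
  forecasts[need]
}

# 5^6 joint-outcome grid and state indicator, built once per session
state_grid_cache <- new.env(parent = emptyenv())
state_grid <- function() {
  if (is.null(state_grid_cache$grid)) {
    g <- as.matrix(expand.grid(itching = 0:4, sleep = 0:4, redness = 0:4,
                               dryness = 0:4, oedema = 0:4, oozing = 0:4))
    state_grid_cache$grid <- g
    state_grid_cache$state <- derive_symptom_state(g[, "itching"], g[, "sleep"],
                                                   g[, "redness"], g[, "dryness"],
                                                   g[, "oedema"], g[, "oozing"])
  }
  list(grid = state_grid_cache$grid, state = state_grid_cache$state)
}

#' Brute-force state probability (test oracle)
#'
#' Sums the product probability over all 5^6 = 15625 joint outcomes for which
#' the derived symptom state is 1. Slower than [state_probability()] but
#' assumption-free beyond independence; used to validate the factorised
#' computation.
#'
#' @inheritParams state_probability
#' @return The state probability, a scalar in `[0, 1]`.
#' @export
state_probability_bruteforce <- function(forecasts) {
  f <- check_state_forecasts(forecasts)
  sg <- state_grid()
  g <- sg$grid
  pr <- f$itching[g[, "itching"] + 1] * f$sleep[g[, "sleep"] + 1] *
    f$redness[g[, "redness"] + 1] * f$dryness[g[, "dryness"] + 1] *
    f$oedema[g[, "oedema"] + 1] * f$oozing[g[, "oozing"] + 1]
  sum(pr[sg$state == 1])
}

# vectorised state probability over rows of six pmf matrices (internal,
# used by forward chaining); pmfs: named list of n x 5 matrices
state_probability_rows <- function(pmfs) {
  pi0 <- pmfs$itching[, 1]; pi1 <- pmfs$itching[, 2]
  ps0 <- pmfs$sleep[, 1]; ps1 <- pmfs$sleep[, 2]
  pA <- 1 - (pi0 * ps0 + pi0 * ps1 + pi1 * ps0)
  q <- cbind(1 - pmfs$redness[, 1], 1 - pmfs$dryness[, 1],
             1 - pmfs$oedema[, 1], 1 - pmfs$oozing[, 1])
  r <- 1 - q
  p0 <- r[, 1] * r[, 2] * r[, 3] * r[, 4]
  p1 <- q[, 1] * r[, 2] * r[, 3] * r[, 4] + r[, 1] * q[, 2] * r[, 3] * r[, 4] +
    r[, 1] * r[, 2] * q[, 3] * r[, 4] + r[, 1] * r[, 2] * r[, 3] * q[, 4]
  pB <- 1 - p0 - p1
  pmin(1, pmax(0, pA * pB))
}
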