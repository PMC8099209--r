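#' Learning curve of a model variant for one sign
#'
#' Per test day: the mean score across patients and its standard error
#' (SD/sqrt(n)); the daily means are then smoothed with LOWESS
#' ([stats::lowess]) and the band is smoothed mean +/- 1.96 SE. Days with a
#' single patient have an undefined SE and an omitted (NA) band.
#'
#' @param table A `score_table`.
#' @param model_variant Variant to extract (e.g. `"no-covariate"`).
#' @param sign Sign name (or `"state"` for Brier records).
#' @param smoothing_fraction LOWESS smoother span (default 0.3).
#' @param score_type `"RPS"` (default) or `"Brier"`.
#' @return A data.frame with columns `test_day`, `mean_score`, `se`, `n`,
#'   `smoothed`, `lower`, `upper`.
#' @export
learning_curve <- function(table, model_variant, sign,
                           smoothing_fraction = 0.3, score_type = "RPS") {
  stopifnot(inherits(table, "score_table"))
  d <- table[table$model_variant == model_variant & table$sign == sign &
               table$score_type == score_type, , drop = FALSE]
  if (nrow(d) == 0)
    return(data.frame(test_day = integer(), mean_score = numeric(),
                      se = numeric(), n = integer(), smoothed = numeric(),
                      lower = numeric(), upper = numeric()))
  days <- sort(unique(d$test_day))
  mu <- tapply(d$score_value, d$test_day, mean)[as.character(days)]
  n <- tapply(d$score_value, d$test_day, length)[as.character(days)]
  sdv <- tapply(d$score_value, d$test_day, sd)[as.character(days)]
  se <- ifelse(n > 1, sdv / sqrt(n), NA_real_)
  sm <- if (length(days) >= 3)
    lowess(days, mu, f = smoothing_fraction)$y else as.numeric(mu)
  data.frame(test_day = days, mean_score = as.numeric(mu), se = as.numeric(se),
             n = as.integer(n), smoothed = sm,
             lower = sm - 1.96 * as.numeric(se), upper = sm + 1.96 * as.numeric(se))
}

#' Paired score difference between two model variants
#'
#' For each sign, the mean over matched (patient, test day) records of
#' `score_A - score_B`, its standard error and a 95% normal interval. With A
#' the covariate-free model and B a covariate variant, a positive difference
#' means the covariate model predicts better.
#'
#' Loss differentials from rolling-origin forecasts are strongly dependent:
#' all patients share the city-level covariates and every forecast between
#' two refits shares the same estimated coefficients, so differentials are
#' correlated within days and serially across days. The default standard
#' error therefore follows the Diebold-Mariano construction for comparing
#' forecast accuracy: differentials are averaged within each test day and a
#' Newey-West (HAC) variance with automatic bandwidth is applied to the
#' daily series. `se_method = "days"` uses the plain SE of the daily means
#' (i.e. treats days as independent) and `se_method = "pairs"` the naive SE
#' over all record-level differences; both are narrower than the HAC choice
#' and anticonservative here, and are provided for sensitivity analysis.
#'
#' @param tableA,tableB `score_table`s (or subsets) each containing exactly
#'   one model variant of the given score type; they must cover identical
#'   (patient, test day, sign) keys.
#' @param score_type `"RPS"` (default) or `"Brier"`.
#' @param se_method `"hac"` (default), `"days"` or `"pairs"` (see Details).
#' @return A data.frame with columns `sign`, `n`, `mean_diff`, `se`, `lower`,
#'   `upper`. `mean_diff` is the mean of daily mean differentials for
#'   `"hac"`/`"days"` and the record-level mean for `"pairs"`.
#' @export
paired_score_difference <- function(tableA, tableB, score_type = "RPS",
                                    se_method = c("hac", "days", "pairs")) {
  se_method <- match.arg(se_method)
  a <- tableA[tableA$score_type == score_type, , drop = FALSE]
  b <- tableB[tableB$score_type == score_type, , drop = FALSE]
  if (length(unique(a$model_variant)) != 1 || length(unique(b$model_variant)) != 1)
    stop("each table must contain exactly one model variant; subset first")
  key <- function(d) paste(d$patient_id, d$test_day, d$sign, sep = "\r")
  ka <- key(a); kb <- key(b)
  if (anyDuplicated(ka) || anyDuplicated(kb)) stop("duplicate score keys")
  only_a <- setdiff(ka, kb); only_b <- setdiff(kb, ka)
  if (length(only_a) + length(only_b) > 0)
    stop(sprintf("unmatched keys: %d only in A, %d only in B (e.g. %s)",
                 length(only_a), length(only_b),
                 gsub("\r", "/", c(only_a, only_b)[1])))
  b <- b[match(ka, kb), , drop = FALSE]
  d <- data.frame(sign = a$sign, day = a$test_day,
                  diff = a$score_value - b$score_value)
  out <- do.call(rbind, lapply(split(d, d$sign), function(v) {
    if (se_method == "pairs") {
      m <- mean(v$diff)
      se <- if (nrow(v) > 1) sd(v$diff) / sqrt(nrow(v)) else NA_real_
    } else {
      dm <- tapply(v$diff, v$day, mean)
      m <- mean(dm)
      if (length(dm) < 2) se <- NA_real_
      else if (se_method == "days") se <- sd(dm) / sqrt(length(dm))
      else {
        # capture stderr chatter from sandwich's internal try() on
        # degenerate (e.g. constant) differential series
        se <- tryCatch({
          nw <- NA_real_
          utils::capture.output(
            nw <- suppressWarnings(
              sqrt(sandwich::NeweyWest(stats::lm(as.numeric(dm) ~ 1))[1, 1])),
            type = "message")
          nw
        }, error = function(e) NA_real_)
        if (!is.finite(se)) se <- sd(dm) / sqrt(length(dm))
      }
    }
    data.frame(n = nrow(v), mean_diff = m, se = se,
               lower = m - 1.96 * se, upper = m + 1.96 * se)
  }))
  out <- cbind(sign = rownames(out), out)
  rownames(out) <- NULL
  out
}

#' Tabulate single-covariate coefficients across signs
#'
#' Collects the covariate coefficient (on the standardised scale) and its
#' standard error from a set of fitted single-covariate models. A positive
#' coefficient means an increase in the covariate is associated with higher
#' probability of more severe next-day outcomes.
#'
#' @param models A list of fitted `sign_model`s, each with exactly one
#'   covariate. Models without a usable fit are excluded with a warning.
#' @return A data.frame with columns `sign`, `covariate`, `estimate`, `se`.
#' @export
coefficient_table <- function(models) {
  rows <- list()
  for (m in models) {
    if (!inherits(m, "sign_model") || length(m$gamma) != 1 ||
        !isTRUE(m$fit_meta$converged)) {
      warning("skipping an unfitted or non-single-covariate model")
      next
    }
    rows[[length(rows) + 1]] <- data.frame(
      sign = m$sign, covariate = names(m$gamma),
      estimate = unname(m$gamma), se = unname(m$gamma_se),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(sign = character(), covariate = character(),
                      estimate = numeric(), se = numeric())
  rownames(out) <- NULL
  out
}

#' Plot learning curves for one sign
#'
#' Smoothed mean score per test day with +/- 1.96 SE bands, one colour per
#' model variant.
#'
#' @param table A `score_table`.
#' @param sign Sign name (or `"state"`).
#' @param variants Variants to show (default: all in the table).
#' @param smoothing_fraction LOWESS span.
#' @param score_type `"RPS"` or `"Brier"`.
#' @return A ggplot object.
#' @export
plot_learning_curves <- function(table, sign, variants = NULL,
                                 smoothing_fraction = 0.3, score_type = "RPS") {
  variants <- variants %||% unique(table$model_variant)
  curves <- do.call(rbind, lapply(variants, function(v) {
    lc <- learning_curve(table, v, sign, smoothing_fraction, score_type)
    if (nrow(lc) > 0) cbind(lc, model_variant = v) else NULL
  }))
  if (is.null(curves)) stop("no records for sign ", sign)
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$test_day, y = .data$smoothed,
                                       colour = .data$model_variant,
                                       fill = .data$model_variant)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         alpha = 0.2, colour = NA, na.rm = TRUE) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Test day", y = score_type, title = sign,
                  colour = "Model", fill = "Model") +
    ggplot2::theme_minimal()
}

#' Plot paired RPS differences per sign
#'
#' @param diffs Output of [paired_score_difference()], optionally row-bound
#'   across variants with an extra `model_variant` column.
#' @return A ggplot object (positive = covariate model better when A is the
#'   covariate-free variant).
#' @export
plot_paired_differences <- function(diffs) {
  if (!"model_variant" %in% names(diffs)) diffs$model_variant <- "covariate model"
  ggplot2::ggplot(diffs, ggplot2::aes(x = .data$sign, y = .data$mean_diff,
                                      colour = .data$model_variant)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                             position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::labs(x = NULL, y = "RPS - RPScov (>0: covariates help)",
                  colour = "Variant") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 .data
NULL
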