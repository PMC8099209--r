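# Shared fixtures, generated in code. The cache keeps the heavier synthetic
# cohorts shared across test files within one run.
.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# a small fully-specified panel data.frame (no missingness unless edited)
toy_panel_df <- function(n_patients = 2, n_days = 3, seed = 1) {
  set.seed(seed)
  df <- expand.grid(day = seq_len(n_days), patient_id = sprintf("P%02d", seq_len(n_patients)))
  df <- df[, c("patient_id", "day")]
  for (s in sign_names()) df[[s]] <- sample(0:4, nrow(df), replace = TRUE)
  df$tcs <- sample(0:1, nrow(df), replace = TRUE)
  df$temp <- round(rnorm(nrow(df), 12, 5), 2)
  df$pm10 <- round(rnorm(nrow(df), 45, 10), 2)
  df
}

shared_cohort <- function() {
  memo("cohort_20x60", generate_cohort(generator_config(n_patients = 20,
                                                        n_days = 60, seed = 7)))
}

shared_model <- function() {
  memo("model_dryness", {
    pr <- extract_transition_pairs(shared_cohort()$panel, "dryness")
    fit_sign_model(pr, covariates = character(0), compute_se = FALSE)
  })
}

random_pmf <- function() {
  x <- rexp(5)
  x / sum(x)
}

random_forecast_set <- function() {
  f <- lapply(1:6, function(i) random_pmf())
  names(f) <- c("itching", "sleep", "redness", "dryness", "oedema", "oozing")
  f
}
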