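# hand-built score table for the aggregation functions
fake_table <- function(df) {
  structure(df, meta = list(n_patients = length(unique(df$patient_id)),
                            n_days = max(df$test_day),
                            failures = data.frame()),
            class = c("score_table", "data.frame"))
}

test_that("a three-day panel yields exactly test days 2 and 3", {
  ds <- ad_panel(toy_panel_df(2, 3, seed = 5))
  tab <- forward_chaining(ds, signs = "dryness", state = FALSE)
  expect_equal(sort(unique(tab$test_day)), c(2L, 3L))
  # the benchmark forecasts are training-free: uniform records always exist
  expect_equal(sum(tab$model_variant == "uniform"), 4)
  expect_true(all(tab$score_value[tab$model_variant == "uniform"] %in%
                    rps(matrix(0.2, 5, 5), 0:4)))
  # day-2 model fit has no training pairs yet: flagged, not silently dropped
  expect_true(any(attr(tab, "meta")$failures$test_day == 2))
})

test_that("score tables have unique keys and valid ranges", {
  coh <- shared_cohort()
  tab <- memo("tab_20x60", forward_chaining(
    coh$panel, variants = list("no-covariate" = character()),
    refit_stride = 7, signs = sign_names(), state = TRUE))
  keys <- paste(tab$patient_id, tab$test_day, tab$sign, tab$model_variant,
                tab$score_type)
  expect_equal(anyDuplicated(keys), 0L)
  expect_true(all(tab$score_value >= 0 & tab$score_value <= 1))
  expect_setequal(unique(tab$model_variant),
                  c("no-covariate", "uniform", "historical"))
  # state records exist and are Brier-scored
  expect_true(all(tab$score_type[tab$sign == "state"] == "Brier"))
  expect_gt(sum(tab$sign == "state"), 0)
})

test_that("refit stride changes only model scores, never the prediction keys", {
  ds <- shared_cohort()$panel
  t1 <- forward_chaining(ds, signs = "itching", refit_stride = 3, state = FALSE)
  t7 <- forward_chaining(ds, signs = "itching", refit_stride = 7, state = FALSE)
  key <- function(tb, v) sort(paste(tb$patient_id, tb$test_day)[tb$model_variant == v])
  expect_identical(key(t1, "no-covariate"), key(t7, "no-covariate"))
  expect_identical(key(t1, "historical"), key(t7, "historical"))
  # benchmark scores are identical whatever the refit schedule
  o1 <- t1[t1$model_variant == "historical", ]
  o7 <- t7[t7$model_variant == "historical", ]
  o7 <- o7[match(paste(o1$patient_id, o1$test_day), paste(o7$patient_id, o7$test_day)), ]
  expect_equal(o1$score_value, o7$score_value, tolerance = 1e-12)
})

test_that("no information from day >= T can reach a day-T score", {
  df <- toy_panel_df(8, 24, seed = 77)
  ds <- ad_panel(df)
  tab <- forward_chaining(ds, signs = "redness", refit_stride = 5, state = FALSE)
  # poison everything from day 16 onwards
  poisoned <- df
  rows <- poisoned$day >= 16
  for (s in sign_names()) poisoned[[s]][rows] <- (poisoned[[s]][rows] + 2) %% 5
  poisoned$temp[rows] <- poisoned$temp[rows] + 1000
  tab2 <- forward_chaining(ad_panel(poisoned), signs = "redness",
                           refit_stride = 5, state = FALSE)
  a <- tab[tab$test_day <= 15, ]
  b <- tab2[tab2$test_day <= 15, ]
  b <- b[match(paste(a$patient_id, a$test_day, a$model_variant),
               paste(b$patient_id, b$test_day, b$model_variant)), ]
  expect_equal(a$score_value, b$score_value, tolerance = 1e-12)
})

test_that("score tables round-trip through CSV with metadata", {
  tab <- memo("tab_20x60", forward_chaining(
    shared_cohort()$panel, variants = list("no-covariate" = character()),
    refit_stride = 7, signs = sign_names(), state = TRUE))
  f <- withr::local_tempfile(fileext = ".csv")
  write_score_table(tab, f)
  back <- read_score_table(f)
  expect_equal(as.data.frame(back), as.data.frame(tab), tolerance = 1e-12)
  expect_equal(attr(back, "meta")$refit_stride, 7)
})

test_that("learning curves summarise daily means with LOWESS and SE bands", {
  df <- expand.grid(patient_id = sprintf("P%02d", 1:6), test_day = 2:40)
  df$sign <- "dryness"; df$model_variant <- "no-covariate"
  df$score_type <- "RPS"; df$score_value <- 0.25
  lc <- learning_curve(fake_table(df), "no-covariate", "dryness")
  expect_equal(lc$mean_score, rep(0.25, 39))
  expect_equal(lc$smoothed, rep(0.25, 39), tolerance = 1e-9)
  expect_equal(lc$se, rep(0, 39))

  # single patient per day: SE undefined, band omitted
  one <- df[df$patient_id == "P01", ]
  lc1 <- learning_curve(fake_table(one), "no-covariate", "dryness")
  expect_true(all(is.na(lc1$se)))
  expect_true(all(is.na(lc1$lower)))
  expect_equal(nrow(learning_curve(fake_table(df), "nope", "dryness")), 0)
})

test_that("paired differences recover identity, constant shifts, and key errors", {
  df <- expand.grid(patient_id = sprintf("P%02d", 1:5), test_day = 2:30,
                    sign = c("dryness", "itching"), stringsAsFactors = FALSE)
  set.seed(6)
  df$model_variant <- "no-covariate"; df$score_type <- "RPS"
  df$score_value <- runif(nrow(df), 0.05, 0.5)
  a <- fake_table(df)
  b <- df; b$model_variant <- "single:temp"
  ident <- paired_score_difference(a, fake_table(b))
  expect_equal(ident$mean_diff, c(0, 0))
  expect_equal(ident$se, c(0, 0))

  shifted <- b; shifted$score_value <- shifted$score_value - 0.01
  d <- paired_score_difference(a, fake_table(shifted))
  expect_equal(d$mean_diff, c(0.01, 0.01), tolerance = 1e-12)
  expect_equal(d$se, c(0, 0), tolerance = 1e-12)
  expect_true(all(d$lower <= 0.01 + 1e-9 & d$upper >= 0.01 - 1e-9))

  # record-level and daily aggregation agree on balanced tables
  d2 <- paired_score_difference(a, fake_table(shifted), se_method = "pairs")
  expect_equal(d2$mean_diff, d$mean_diff, tolerance = 1e-12)

  expect_error(paired_score_difference(a, fake_table(b[-3, ])), "unmatched keys")
  mixed <- rbind(df, b)
  expect_error(paired_score_difference(fake_table(mixed), fake_table(b)),
               "one model variant")
})

test_that("coefficient_table collects single-covariate estimates and flags the rest", {
  pr1 <- extract_transition_pairs(shared_cohort()$panel, "dryness", "temp")
  pr2 <- extract_transition_pairs(shared_cohort()$panel, "itching", "pm10")
  m1 <- fit_sign_model(pr1); m2 <- fit_sign_model(pr2)
  tab <- coefficient_table(list(m1, m2))
  expect_equal(tab$sign, c("dryness", "itching"))
  expect_equal(tab$covariate, c("temp", "pm10"))
  expect_true(all(is.finite(tab$se)))
  m0 <- shared_model()  # no covariates: excluded with a warning
  expect_warning(tab2 <- coefficient_table(list(m1, m0)), "skipping")
  expect_equal(nrow(tab2), 1)
})

test_that("plot builders return ggplot objects", {
  tab <- memo("tab_20x60", forward_chaining(
    shared_cohort()$panel, variants = list("no-covariate" = character()),
    refit_stride = 7, signs = sign_names(), state = TRUE))
  expect_s3_class(plot_learning_curves(tab, "dryness"), "ggplot")
  d <- data.frame(sign = "dryness", n = 10, mean_diff = 0.001, se = 0.002,
                  lower = -0.003, upper = 0.005)
  expect_s3_class(plot_paired_differences(d), "ggplot")
})
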