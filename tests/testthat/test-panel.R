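test_that("read_panel parses well-formed CSVs and rejects bad cells", {
  df <- toy_panel_df(2, 3)
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, f, row.names = FALSE, na = "")
  ds <- read_panel(f)
  expect_s3_class(ds, "ad_panel")
  expect_equal(nrow(ds), 6)

  # out-of-range score names the cell
  bad <- df; bad$oedema[2] <- 5
  write.csv(bad, f, row.names = FALSE, na = "")
  expect_error(read_panel(f), "oedema.*row 2", ignore.case = TRUE)

  # day gaps are allowed; the absent day is simply not a row
  gap <- toy_panel_df(1, 3); gap$day <- c(1, 2, 4)
  write.csv(gap, f, row.names = FALSE, na = "")
  expect_equal(read_panel(f)$day, c(1L, 2L, 4L))
})

test_that("read_panel schema remaps column names from a file", {
  df <- toy_panel_df(1, 2)
  names(df)[names(df) == "patient_id"] <- "subj"
  names(df)[names(df) == "sleep"] <- "sleep_disturbance"
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, f, row.names = FALSE)
  sf <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("patient_id: subj", "sleep: sleep_disturbance"), sf)
  ds <- read_panel(f, schema = sf)
  expect_true(all(c("patient_id", "sleep") %in% names(ds)))
})

test_that("panel validation catches duplicates and bad tcs", {
  df <- toy_panel_df(1, 2)
  expect_error(ad_panel(rbind(df, df[1, ])), "duplicate")
  df2 <- toy_panel_df(1, 2); df2$tcs[1] <- 2
  expect_error(ad_panel(df2), "tcs")
})

test_that("write_panel / read_panel round-trips data and missingness", {
  ds <- shared_cohort()$panel
  f <- withr::local_tempfile(fileext = ".csv")
  write_panel(ds, f)
  back <- read_panel(f)
  expect_equal(as.data.frame(back)[, names(ds)], as.data.frame(ds),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("filter_min_observations applies the observed-day rule at the boundary", {
  # one patient with 9 observed days, one with exactly 10 (of 12 days)
  df <- toy_panel_df(2, 12)
  sset <- sign_names()
  df[df$patient_id == "P01" & df$day > 9, sset] <- NA   # 9 observed days
  df[df$patient_id == "P02" & df$day > 10, sset] <- NA  # 10 observed days
  ds <- ad_panel(df)
  out <- filter_min_observations(ds, min_days = 10)
  expect_equal(unique(out$patient_id), "P02")
  # min_days = 1 keeps everything when all patients have >= 1 observation
  expect_equal(nrow(filter_min_observations(ds, 1)), nrow(ds))
})

test_that("filter_min_observations is idempotent", {
  ds <- shared_cohort()$panel
  once <- filter_min_observations(ds, 40)
  twice <- filter_min_observations(once, 40)
  expect_identical(as.data.frame(once), as.data.frame(twice))
})

test_that("extract_transition_pairs follows the missing-pair and covariate rules", {
  df <- toy_panel_df(1, 4)
  df$dryness <- c(2, NA, 1, 1)
  ds <- ad_panel(df)
  pr <- extract_transition_pairs(ds, "dryness")
  expect_equal(nrow(pr), 1)          # only day 3 -> 4 survives
  expect_equal(pr$day, 3L)
  expect_equal(pr$s_t, 1L)

  # fully observed series of T days -> T - 1 pairs
  df2 <- toy_panel_df(1, 8)
  expect_equal(nrow(extract_transition_pairs(ad_panel(df2), "itching")), 7)

  # a missing covariate at day t drops the pair only when requested
  df3 <- toy_panel_df(1, 3)
  df3$pm10[1] <- NA
  ds3 <- ad_panel(df3)
  expect_equal(extract_transition_pairs(ds3, "redness", "pm10")$day, 2L)
  expect_equal(extract_transition_pairs(ds3, "redness")$day, c(1L, 2L))

  # gaps in days break pairs
  df4 <- toy_panel_df(1, 3); df4$day <- c(1, 2, 4)
  expect_equal(extract_transition_pairs(ad_panel(df4), "sleep")$day, 1L)

  expect_error(extract_transition_pairs(ds, "warts"), "unknown sign")
  expect_error(extract_transition_pairs(ds, "dryness", "humidity9000"),
               "unknown covariate")
})

test_that("pair extraction matches a brute-force double loop on random missingness", {
  set.seed(42)
  for (rep in 1:5) {
    df <- toy_panel_df(4, 15, seed = 100 + rep)
    for (s in sign_names()) df[[s]][runif(nrow(df)) < 0.3] <- NA
    df$temp[runif(nrow(df)) < 0.2] <- NA
    ds <- ad_panel(df)
    pr <- extract_transition_pairs(ds, "oozing", "temp")
    # oracle: double loop over patients and days
    n_expected <- 0
    for (pid in unique(df$patient_id)) {
      sub <- df[df$patient_id == pid, ]
      for (t in sub$day) {
        r1 <- sub[sub$day == t, ]; r2 <- sub[sub$day == t + 1, ]
        if (nrow(r2) == 1 && !is.na(r1$oozing) && !is.na(r2$oozing) &&
            !is.na(r1$temp))
          n_expected <- n_expected + 1
      }
    }
    expect_equal(nrow(pr), n_expected)
  }
})

test_that("derive_symptom_state implements the two-condition rule", {
  # both conditions exactly at their boundary
  expect_equal(derive_symptom_state(itching = 1, sleep = 1, redness = 1,
                                    dryness = 1, oedema = 0, oozing = 0), 1L)
  # only one of the four B-signs non-zero
  expect_equal(derive_symptom_state(itching = 4, sleep = 4, redness = 1,
                                    dryness = 0, oedema = 0, oozing = 0), 0L)
  expect_equal(derive_symptom_state(0, 0, 0, 0, 0, 0), 0L)
  expect_error(derive_symptom_state(NA, 0, 0, 0, 0, 0), "non-missing")
})

test_that("derive_symptom_state agrees with brute-force over all 5^6 combinations", {
  g <- as.matrix(expand.grid(itching = 0:4, sleep = 0:4, redness = 0:4,
                             dryness = 0:4, oedema = 0:4, oozing = 0:4))
  got <- derive_symptom_state(g[, 1], g[, 2], g[, 3], g[, 4], g[, 5], g[, 6])
  want <- as.integer((g[, 1] + g[, 2] >= 2) &
                       (rowSums(g[, 3:6] > 0) >= 2))
  expect_identical(got, want)
})

test_that("covariate standardisation uses population SD, spares tcs, and inverts", {
  df <- toy_panel_df(1, 3)
  df$temp <- c(0, 2, 99)  # day-3 value never enters (pairs use days 1, 2)
  ds <- ad_panel(df)
  pr <- extract_transition_pairs(ds, "dryness", c("temp", "tcs"))
  out <- standardize_covariates(pr)
  expect_equal(out$pairs$temp, c(-1, 1))          # population SD of {0,2} is 1
  expect_equal(out$pairs$tcs, pr$tcs)             # untouched
  # reusing stats: a value at the training mean maps to 0
  pr2 <- pr; pr2$temp <- rep(1, 2)
  expect_equal(standardize_covariates(pr2, out$stats)$pairs$temp, c(0, 0))
  # inverse restores the input
  back <- unstandardize_covariates(out$pairs, out$stats)
  expect_equal(back$temp, pr$temp, tolerance = 1e-12)
  # zero variance errors with the covariate named
  pr3 <- pr; pr3$temp <- c(5, 5)
  expect_error(standardize_covariates(pr3), "temp")
})

test_that("cross-correlogram finds the planted lag and nothing else", {
  set.seed(9)
  n <- 400
  x <- as.numeric(arima.sim(list(ar = 0.7), n + 2))
  sig <- pmin(4L, pmax(0L, as.integer(round(2 + x[seq_len(n)]))))
  df <- data.frame(patient_id = "P01", day = seq_len(n))
  for (s in sign_names()) df[[s]] <- sig
  df$temp <- x[seq_len(n) + 2]  # covariate leads the sign series by 2 days
  df$pm10 <- rnorm(n)
  ds <- ad_panel(df)

  cc <- cross_correlogram(ds, "dryness", "temp", max_lag = 4)
  expect_equal(which.max(cc$correlation) - 1, 2)  # peak at the planted lag
  expect_gt(cc$correlation[3], 0.8)

  # lag-0 identity: covariate equal to the centered sign series
  df$temp <- sig - mean(sig)
  cc0 <- cross_correlogram(ad_panel(df), "dryness", "temp", max_lag = 0)
  expect_equal(cc0$correlation[1], 1, tolerance = 1e-12)

  # independent white noise stays near zero at all lags
  ccn <- cross_correlogram(ds, "dryness", "pm10", max_lag = 3)
  expect_true(all(abs(ccn$correlation) < 0.15))
})
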