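test_that("fitting is deterministic and the optimiser only ever improves", {
  pr <- extract_transition_pairs(shared_cohort()$panel, "dryness")
  m1 <- fit_sign_model(pr, covariates = character(0), compute_se = FALSE)
  m2 <- fit_sign_model(pr, covariates = character(0), compute_se = FALSE)
  expect_identical(m1$theta, m2$theta)
  expect_true(m1$fit_meta$converged)
  # the reported optimum is the best objective value ever evaluated
  expect_equal(m1$fit_meta$penalised_nll, min(m1$fit_meta$nll_trace),
               tolerance = 1e-12)
  expect_lt(m1$fit_meta$penalised_nll, m1$fit_meta$nll_trace[1])
})

test_that("fit recovers generator parameters on a modest cohort", {
  coh <- memo("cohort_fit", generate_cohort(
    generator_config(n_patients = 60, n_days = 120, seed = 31)))
  pr <- extract_transition_pairs(coh$panel, "itching")
  m <- fit_sign_model(pr, covariates = character(0), compute_se = FALSE)
  expect_true(m$fit_meta$converged)
  truth_cuts <- generator_config(n_patients = 1, n_days = 1, seed = 1)$cutpoints$itching
  expect_lt(max(abs(m$beta - c(-6, -4, -2, -0.75))), 0.6)
  expect_lt(max(abs(m$cutpoints - truth_cuts)), 0.6)
  expect_lt(abs(m$sigma_alpha - 1), 0.35)
})

test_that("fitted persistence is monotone: higher today predicts higher tomorrow", {
  m <- shared_model()
  p_hi <- vapply(0:4, function(s) {
    pmf <- predict_forecast(m, "nobody", s)
    sum(pmf[, c("2", "3", "4")])
  }, numeric(1))
  expect_true(all(diff(p_hi) >= -1e-12))
})

test_that("single-patient data yield a flagged, penalty-shrunk fit", {
  pr <- extract_transition_pairs(shared_cohort()$panel, "dryness")
  one <- pr[pr$patient_id == pr$patient_id[1], ]
  attr(one, "sign") <- "dryness"; attr(one, "covariates") <- character(0)
  class(one) <- c("ad_pairs", "data.frame")
  m <- fit_sign_model(one, covariates = character(0), compute_se = FALSE)
  expect_true(m$fit_meta$single_patient)
  expect_lt(m$sigma_alpha, 0.5)
  one$s_next <- 1L
  expect_error(fit_sign_model(one, covariates = character(0)), "categories")
})

test_that("empirical-Bayes intercepts behave like a posterior mode", {
  m <- shared_model()
  expect_equal(eb_alpha(m, NULL), 0)
  pr <- extract_transition_pairs(shared_cohort()$panel, "dryness")
  pid <- names(which.max(m$alpha_hat))
  pp <- pr[pr$patient_id == pid, ]
  # matches the fit's internal mode for the same patient
  expect_equal(eb_alpha(m, pp), unname(m$alpha_hat[pid]), tolerance = 1e-4)
  # a patient persistently above population expectation gets alpha > 0
  hi <- pp[seq_len(min(8, nrow(pp))), ]
  hi$s_t <- 0L; hi$s_next <- 3L
  expect_gt(eb_alpha(m, hi), 0)
  # degenerate prior pins the intercept at zero
  m0 <- m; m0$sigma_alpha <- 0
  expect_equal(eb_alpha(m0, hi), 0)
})

test_that("forecasts are valid pmfs and obey the covariate contract", {
  m <- shared_model()
  set.seed(1)
  s <- sample(0:4, 500, replace = TRUE)
  pmf <- predict_forecast(m, rep("P001", 500), s)
  expect_true(all(pmf >= 0))
  expect_equal(rowSums(pmf), rep(1, 500), tolerance = 1e-9)
  # covariate-free model ignores patients it never saw (alpha = 0)
  p_unknown <- predict_forecast(m, "unknown-patient", 2)
  expect_equal(drop(p_unknown),
               drop(ordered_logistic_pmf(m$beta[3], m$cutpoints)),
               tolerance = 1e-12)

  # a model with covariates refuses to predict without them
  prc <- extract_transition_pairs(shared_cohort()$panel, "dryness", "temp")
  mc <- fit_sign_model(prc, compute_se = FALSE)
  expect_error(predict_forecast(mc, "P001", 2), "covariate")
  # and responds to them through the stored standardisation
  pa <- predict_forecast(mc, "P001", 2, data.frame(temp = 0))
  pb <- predict_forecast(mc, "P001", 2, data.frame(temp = 30))
  if (abs(mc$gamma[["temp"]]) > 1e-8) expect_false(isTRUE(all.equal(pa, pb)))
})

test_that("negating a covariate negates its coefficient", {
  pr <- extract_transition_pairs(shared_cohort()$panel, "itching", "pm10")
  m_pos <- fit_sign_model(pr, compute_se = FALSE)
  pr_neg <- pr; pr_neg$pm10 <- -pr_neg$pm10
  m_neg <- fit_sign_model(pr_neg, compute_se = FALSE)
  expect_equal(unname(m_neg$gamma[["pm10"]]), -unname(m_pos$gamma[["pm10"]]),
               tolerance = 1e-4)
})

test_that("sign models serialise to JSON and reload exactly", {
  prc <- extract_transition_pairs(shared_cohort()$panel, "dryness", "temp")
  m <- fit_sign_model(prc)
  f <- withr::local_tempfile(fileext = ".json")
  write_sign_model(m, f)
  back <- read_sign_model(f)
  for (field in c("beta", "gamma", "gamma_se", "cutpoints", "sigma_alpha",
                  "alpha_hat", "theta"))
    expect_equal(back[[field]], m[[field]], tolerance = 0)
  expect_equal(back$stats$mean, m$stats$mean, tolerance = 0)
  # reloaded model produces identical forecasts
  expect_identical(predict_forecast(back, "P001", 3, data.frame(temp = 10)),
                   predict_forecast(m, "P001", 3, data.frame(temp = 10)))
})
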