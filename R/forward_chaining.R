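#' Canonical name of a covariate-set model variant
#'
#' @param covariates Character vector of covariates (empty, one, or all).
#' @return `"no-covariate"`, `"single:<name>"`, `"all-covariates"` or a
#'   `"set:"`-prefixed name for other subsets.
#' @export
variant_name <- function(covariates) {
  covariates <- as.character(covariates)
  if (length(covariates) == 0) return("no-covariate")
  if (length(covariates) == 1) return(paste0("single:", covariates))
  if (setequal(covariates, .COVARIATES)) return("all-covariates")
  paste0("set:", paste(sort(covariates), collapse = "+"))
}

#' Forward-chaining validation of sign-score forecasts
#'
#' Rolling-origin evaluation: for each test day T (from `min_train_days + 1`
#' to the last day), every model variant is fitted on all transition pairs
#' whose outcome day lies strictly before T, then scored on the day-T score
#' of every patient whose scores at T-1 and T are both observed. Refitting
#' every day reproduces the canonical scheme; `refit_stride > 1` reuses the
#' last fit in between (training data never include day >= T either way).
#' Uniform and historical benchmark forecasts are scored on the same
#' patient-days. For days on which all six signs are observed at T-1 and T,
#' the binary symptom-state probability is derived from the six per-sign
#' forecasts and scored with the Brier score.
#'
#' A variant that cannot be fitted at some refit (e.g. no training pairs yet)
#' is recorded as a gap in the table's metadata; benchmark records are still
#' emitted.
#'
#' @param ds An [ad_panel].
#' @param variants Named list of covariate sets, e.g.
#'   `list("no-covariate" = character(), "all-covariates" = covariate_names())`.
#'   Unnamed lists are named with [variant_name()].
#' @param refit_stride Days between refits (default 1 = refit daily).
#' @param min_train_days First test day is `min_train_days + 1` (default 1).
#' @param quad_order,lambda Passed to [fit_sign_model()].
#' @param signs Signs to evaluate (default all six; state scoring requires
#'   all six).
#' @param include_benchmarks Score the uniform and historical benchmarks.
#' @param state Derive and score binary-state forecasts (needs all six signs).
#' @param verbose Print per-day progress.
#' @return A `score_table`: a data.frame with columns `patient_id`,
#'   `test_day`, `sign`, `model_variant`, `score_type`, `score_value`, with
#'   run metadata in `attr(, "meta")`.
#' @export
forward_chaining <- function(ds, variants = list("no-covariate" = character()),
                             refit_stride = 1, min_train_days = 1,
                             quad_order = 9, lambda = 1e-4,
                             signs = sign_names(), include_benchmarks = TRUE,
                             state = TRUE, verbose = FALSE) {
  stopifnot(inherits(ds, "ad_panel"), refit_stride >= 1, min_train_days >= 1)
  if (is.null(names(variants)) || any(!nzchar(names(variants))))
    names(variants) <- vapply(variants, variant_name, character(1))
  state <- state && setequal(signs, .SIGNS)

  patients <- unique(ds$patient_id)
  npat <- length(patients)
  Dmax <- max(ds$day)
  if (Dmax < min_train_days + 1) stop("panel too short for any test day")
  pidx <- match(ds$patient_id, patients)

  # patients x days score matrix per sign, covariate matrices, and per-sign
  # cumulative category counts (for the historical benchmark)
  Smat <- list()
  for (sg in signs) {
    M <- matrix(NA_integer_, npat, Dmax)
    M[cbind(pidx, ds$day)] <- ds[[sg]]
    Smat[[sg]] <- M
  }
  covs_all <- unique(unlist(variants))
  Cmat <- list()
  for (cv in covs_all) {
    M <- matrix(NA_real_, npat, Dmax)
    M[cbind(pidx, ds$day)] <- ds[[cv]]
    Cmat[[cv]] <- M
  }
  Hist <- list()
  if (include_benchmarks) {
    for (sg in signs) {
      A <- array(0, c(npat, 5, Dmax))
      for (k in 0:4) {
        obs <- !is.na(Smat[[sg]]) & Smat[[sg]] == k
        A[, k + 1, ] <- t(apply(obs, 1, cumsum))
      }
      Hist[[sg]] <- A
    }
  }

  pairs_sv <- lapply(signs, function(sg)
    lapply(variants, function(cvs) extract_transition_pairs(ds, sg, cvs)))
  names(pairs_sv) <- signs

  models <- list()   # current fit per "sign|variant"
  failures <- list()
  records <- list()
  add_block <- function(pid, day, sg, variant, type, value) {
    records[[length(records) + 1]] <<- data.frame(
      patient_id = pid, test_day = day, sign = sg, model_variant = variant,
      score_type = type, score_value = value, stringsAsFactors = FALSE)
  }

  test_days <- seq(min_train_days + 1, Dmax)
  model_variants <- names(variants)
  bench_variants <- if (include_benchmarks) c("uniform", "historical") else character(0)

  for (T in test_days) {
    refit <- ((T - test_days[1]) %% refit_stride) == 0
    # per-variant forecast storage for state derivation
    fc <- if (state)
      lapply(c(model_variants, bench_variants), function(v)
        lapply(signs, function(sg) NULL))
    if (state) names(fc) <- c(model_variants, bench_variants)
    test_sets <- list()

    for (sg in signs) {
      s_prev <- Smat[[sg]][, T - 1]
      s_now <- Smat[[sg]][, T]
      ok <- which(!is.na(s_prev) & !is.na(s_now))
      test_sets[[sg]] <- ok
      if (length(ok) == 0) next
      outcome <- s_now[ok]

      for (v in model_variants) {
        key <- paste(sg, v, sep = "|")
        cvs <- variants[[v]]
        # refit on schedule; also catch up as soon as fitting first becomes
        # feasible after a flagged gap, so the set of scored (patient, day)
        # keys does not depend on the refit stride
        if (refit || is.null(models[[key]])) {
          tp <- pairs_sv[[sg]][[v]]
          tp <- tp[tp$day <= T - 2, , drop = FALSE]
          attr(tp, "sign") <- sg; attr(tp, "covariates") <- cvs
          class(tp) <- c("ad_pairs", "data.frame")
          fit <- tryCatch({
            if (nrow(tp) == 0) stop("no training pairs yet")
            fit_sign_model(tp, covariates = cvs, quad_order = quad_order,
                           lambda = lambda, compute_se = FALSE,
                           init = models[[key]])
          }, error = function(e) e)
          if (inherits(fit, "error")) {
            failures[[length(failures) + 1]] <- data.frame(
              test_day = T, sign = sg, model_variant = v,
              message = conditionMessage(fit), stringsAsFactors = FALSE)
          } else models[[key]] <- fit
        }
        model <- models[[key]]
        if (is.null(model)) next
        covrows <- NULL
        if (length(cvs) > 0) {
          covrows <- as.data.frame(lapply(Cmat[cvs], function(M) M[ok, T - 1]))
          names(covrows) <- cvs
          complete <- stats::complete.cases(covrows)
        } else complete <- rep(TRUE, length(ok))
        if (!any(complete)) next
        pmf <- matrix(NA_real_, length(ok), 5)
        pmf[complete, ] <- predict_forecast(
          model, patients[ok[complete]], s_prev[ok[complete]],
          if (length(cvs) > 0) covrows[complete, , drop = FALSE] else NULL)
        add_block(patients[ok[complete]], T, sg, v, "RPS",
                  rps(pmf[complete, , drop = FALSE], outcome[complete]))
        if (state) fc[[v]][[sg]] <- list(idx = ok, pmf = pmf)
      }

      if (include_benchmarks) {
        upmf <- matrix(0.2, length(ok), 5)
        add_block(patients[ok], T, sg, "uniform", "RPS", rps(upmf, outcome))
        counts <- matrix(Hist[[sg]][ok, , T - 1], ncol = 5)
        tot <- rowSums(counts)
        hpmf <- counts / ifelse(tot > 0, tot, 1)
        hpmf[tot == 0, ] <- 0.2
        add_block(patients[ok], T, sg, "historical", "RPS", rps(hpmf, outcome))
        if (state) {
          fc[["uniform"]][[sg]] <- list(idx = ok, pmf = upmf)
          fc[["historical"]][[sg]] <- list(idx = ok, pmf = hpmf)
        }
      }
    }

    if (state) {
      names(test_sets) <- signs
      # patients with day-T outcome observed for all six signs
      elig <- Reduce(intersect, test_sets)
      if (length(elig) > 0) {
        st_out <- derive_symptom_state(Smat$itching[elig, T], Smat$sleep[elig, T],
                                       Smat$redness[elig, T], Smat$dryness[elig, T],
                                       Smat$oedema[elig, T], Smat$oozing[elig, T])
        for (v in c(model_variants, bench_variants)) {
          pm <- lapply(signs, function(sg) {
            b <- fc[[v]][[sg]]
            if (is.null(b)) return(NULL)
            m <- b$pmf[match(elig, b$idx), , drop = FALSE]
            m
          })
          names(pm) <- signs
          if (any(vapply(pm, is.null, logical(1)))) next
          has <- Reduce(`&`, lapply(pm, function(m) !is.na(m[, 1])))
          if (!any(has)) next
          pm <- lapply(pm, function(m) m[has, , drop = FALSE])
          probs <- state_probability_rows(pm)
          add_block(patients[elig[has]], T, "state", v, "Brier",
                    brier(probs, st_out[has]))
        }
      }
    }
    if (verbose && (T %% 25 == 0))
      message(sprintf("  test day %d/%d (%d records)", T, Dmax, length(records)))
  }

  out <- do.call(rbind, records)
  if (is.null(out))
    out <- data.frame(patient_id = character(), test_day = integer(),
                      sign = character(), model_variant = character(),
                      score_type = character(), score_value = numeric())
  rownames(out) <- NULL
  structure(out,
            meta = list(refit_stride = refit_stride,
                        min_train_days = min_train_days,
                        quad_order = quad_order, lambda = lambda,
                        variants = variants, signs = signs,
                        n_patients = npat, n_days = Dmax,
                        failures = if (length(failures)) do.call(rbind, failures)
                                   else data.frame()),
            class = c("score_table", "data.frame"))
}

#' @export
print.score_table <- function(x, ...) {
  meta <- attr(x, "meta")
  cat(sprintf("<score_table> %d records; %d patients, days up to %d\n",
              nrow(x), meta$n_patients, meta$n_days))
  cat("  variants:", paste(unique(x$model_variant), collapse = ", "), "\n")
  if (nrow(meta$failures) > 0)
    cat(sprintf("  flagged fit gaps: %d (see attr(, 'meta')$failures)\n",
                nrow(meta$failures)))
  agg <- stats::aggregate(score_value ~ model_variant + score_type, x, mean)
  for (i in seq_len(nrow(agg)))
    cat(sprintf("  mean %-6s %-16s %.4f\n", agg$score_type[i],
                agg$model_variant[i], agg$score_value[i]))
  invisible(x)
}

#' Save / load a score table as CSV (+ JSON metadata sidecar)
#'
#' @param table A `score_table`.
#' @param path CSV output path; metadata goes to `<path>.meta.json`.
#' @return `write_score_table`: `path` invisibly; `read_score_table`: the table.
#' @export
write_score_table <- function(table, path) {
  stopifnot(inherits(table, "score_table"))
  write.csv(as.data.frame(table), path, row.names = FALSE)
  meta <- attr(table, "meta")
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_score_table
#' @export
read_score_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  mpath <- paste0(path, ".meta.json")
  meta <- if (file.exists(mpath)) jsonlite::read_json(mpath, simplifyVector = TRUE)
          else list()
  if (!is.null(meta$variants)) meta$variants <- lapply(meta$variants, as.character)
  structure(df, meta = meta, class = c("score_table", "data.frame"))
}
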