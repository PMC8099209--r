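#' Construct a daily AD panel dataset
#'
#' A panel dataset holds one row per patient-day with the six ordinal AD sign
#' scores (0--4 or `NA`), an optional binary topical-corticosteroid (TCS) flag
#' and optional environmental covariates. Day indices are 1-based integers and
#' must be strictly increasing within a patient; gaps are allowed and simply
#' mean the day was not observed.
#'
#' @param data A data.frame with columns `patient_id`, `day`, the six sign
#'   columns (`dryness`, `oedema`, `itching`, `oozing`, `redness`, `sleep`),
#'   and optionally `tcs` and any of `temp`, `rh`, `rainfall`, `dtr`, `pm10`,
#'   `no2`, `o3`.
#' @return An object of class `ad_panel` (a validated data.frame).
#' @export
ad_panel <- function(data) {
  stopifnot(is.data.frame(data))
  data <- as.data.frame(data)
  required <- c("patient_id", "day", .SIGNS)
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0)
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  covs <- intersect(.COVARIATES, names(data))
  keep <- c("patient_id", "day", .SIGNS, covs)
  data <- data[, keep, drop = FALSE]

  if (anyNA(data$patient_id) || anyNA(data$day))
    stop("patient_id and day must be non-missing")
  if (!is.numeric(data$day) || any(data$day != floor(data$day)))
    stop("day must be integer-valued")
  data$day <- as.integer(data$day)
  data$patient_id <- as.character(data$patient_id)

  for (s in .SIGNS) {
    v <- data[[s]]
    bad <- which(!is.na(v) & (v < 0 | v > 4 | v != floor(v)))
    if (length(bad) > 0)
      stop(sprintf("sign score out of range {0..4} in column '%s', row %d (value %s)",
                   s, bad[1], format(v[bad[1]])))
    data[[s]] <- as.integer(v)
  }
  if ("tcs" %in% names(data)) {
    v <- data$tcs
    bad <- which(!is.na(v) & !(v %in% c(0, 1)))
    if (length(bad) > 0)
      stop(sprintf("tcs must be 0/1; row %d has value %s", bad[1], format(v[bad[1]])))
    data$tcs <- as.integer(v)
  }

  data <- data[order(data$patient_id, data$day), , drop = FALSE]
  dup <- duplicated(data[, c("patient_id", "day")])
  if (any(dup))
    stop(sprintf("duplicate patient-day: patient %s, day %d",
                 data$patient_id[which(dup)[1]], data$day[which(dup)[1]]))
  rownames(data) <- NULL
  structure(data, covariates = covs, class = c("ad_panel", "data.frame"))
}

#' @export
print.ad_panel <- function(x, ...) {
  np <- length(unique(x$patient_id))
  obs <- rowSums(!is.na(as.matrix(x[, .SIGNS]))) > 0
  cat(sprintf("<ad_panel> %d patients, %d patient-day rows (%d with >=1 observed sign)\n",
              np, nrow(x), sum(obs)))
  cat(sprintf("  days %d..%d; covariates: %s\n", min(x$day), max(x$day),
              if (length(attr(x, "covariates"))) paste(attr(x, "covariates"), collapse = ", ")
              else "none"))
  mfrac <- mean(is.na(as.matrix(x[, .SIGNS])))
  cat(sprintf("  missing sign-score cells: %.1f%%\n", 100 * mfrac))
  invisible(x)
}

#' Read a daily panel from CSV
#'
#' Reads a long-format CSV (one row per patient-day). Column names can be
#' remapped through `schema`, either a named character vector
#' (`c(canonical = "file_column")`) or the path to a YAML/JSON file holding
#' such a mapping. Empty cells are missing values.
#'
#' @param path Path to the CSV file.
#' @param schema Optional column-name mapping (named character vector or
#'   YAML/JSON file path).
#' @return An [ad_panel] object.
#' @export
read_panel <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop("malformed CSV '", path, "': ", conditionMessage(e)))
  if (!is.null(schema)) {
    if (is.character(schema) && length(schema) == 1 && file.exists(schema)) {
      schema <- if (grepl("\\.json$", schema, ignore.case = TRUE))
        unlist(jsonlite::read_json(schema, simplifyVector = TRUE))
      else unlist(yaml::read_yaml(schema))
    }
    stopifnot(is.character(schema), !is.null(names(schema)))
    for (canon in names(schema)) {
      src <- schema[[canon]]
      if (!src %in% names(df))
        stop("schema maps '", canon, "' to absent column '", src, "'")
      names(df)[names(df) == src] <- canon
    }
  }
  ad_panel(df)
}

#' Write a panel dataset to CSV
#'
#' @param ds An [ad_panel].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(ds, path) {
  stopifnot(inherits(ds, "ad_panel"))
  write.csv(as.data.frame(ds), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Drop patients with few observed days
#'
#' A patient-day counts as observed when at least one of the six sign scores
#' is non-missing. Patients with fewer than `min_days` observed days are
#' removed (the study-analogous filter uses `min_days = 10`).
#'
#' @param ds An [ad_panel].
#' @param min_days Minimum number of observed patient-days to retain a patient.
#' @return A filtered [ad_panel]; row order is preserved.
#' @export
filter_min_observations <- function(ds, min_days = 10) {
  stopifnot(inherits(ds, "ad_panel"), min_days >= 1)
  observed <- rowSums(!is.na(as.matrix(ds[, .SIGNS]))) > 0
  counts <- tapply(observed, ds$patient_id, sum)
  keep_ids <- names(counts)[counts >= min_days]
  out <- ds[ds$patient_id %in% keep_ids, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, covariates = attr(ds, "covariates"),
            class = c("ad_panel", "data.frame"))
}

#' Extract successive-day transition pairs for one sign
#'
#' Builds the training units of the autoregressive model: one row per pair of
#' calendar-consecutive days (t, t+1) of one patient where the sign score is
#' observed on both days and, if covariates are requested, every requested
#' covariate is observed at day t. Covariates enter at day t to predict the
#' score at day t+1.
#'
#' @param ds An [ad_panel].
#' @param sign One of the six sign names.
#' @param covariates Character vector of covariate names (possibly empty).
#' @return A data.frame of class `ad_pairs` with columns `patient_id`, `day`
#'   (= t), `s_t`, `s_next`, and one column per requested covariate (values at
#'   day t), sorted by patient then day.
#' @export
extract_transition_pairs <- function(ds, sign, covariates = character()) {
  stopifnot(inherits(ds, "ad_panel"))
  if (!sign %in% .SIGNS) stop("unknown sign: ", sign)
  bad <- setdiff(covariates, .COVARIATES)
  if (length(bad) > 0) stop("unknown covariate(s): ", paste(bad, collapse = ", "))
  absent <- setdiff(covariates, names(ds))
  if (length(absent) > 0)
    stop("covariate(s) not present in dataset: ", paste(absent, collapse = ", "))

  # ds is sorted by patient then day; consecutive rows of one patient with
  # day difference 1 form candidate pairs
  n <- nrow(ds)
  if (n < 2) {
    out <- data.frame(patient_id = character(), day = integer(),
                      s_t = integer(), s_next = integer())
    for (cv in covariates) out[[cv]] <- numeric()
    return(structure(out, sign = sign, covariates = covariates,
                     class = c("ad_pairs", "data.frame")))
  }
  i <- seq_len(n - 1)
  same <- ds$patient_id[i] == ds$patient_id[i + 1] & ds$day[i + 1] - ds$day[i] == 1L
  s <- ds[[sign]]
  ok <- same & !is.na(s[i]) & !is.na(s[i + 1])
  for (cv in covariates) ok <- ok & !is.na(ds[[cv]][i])
  idx <- i[ok]
  out <- data.frame(patient_id = ds$patient_id[idx], day = ds$day[idx],
                    s_t = s[idx], s_next = s[idx + 1L],
                    stringsAsFactors = FALSE)
  for (cv in covariates) out[[cv]] <- ds[[cv]][idx]
  rownames(out) <- NULL
  structure(out, sign = sign, covariates = covariates,
            class = c("ad_pairs", "data.frame"))
}

#' Derive the binary AD symptom state from the six sign scores
#'
#' The state is 1 when (a) itching + sleep disturbance >= 2 and (b) at least
#' two of redness, dryness, oedema and oozing are non-zero; otherwise 0.
#' All arguments are vectorised and must be non-missing.
#'
#' @param itching,sleep,redness,dryness,oedema,oozing Ordinal scores in 0..4.
#' @return Integer vector of 0/1 states.
#' @export
derive_symptom_state <- function(itching, sleep, redness, dryness, oedema, oozing) {
  scores <- cbind(itching, sleep, redness, dryness, oedema, oozing)
  if (anyNA(scores)) stop("derive_symptom_state requires all six scores non-missing")
  if (any(scores < 0 | scores > 4 | scores != floor(scores)))
    stop("sign scores must be integers in 0..4")
  condA <- (itching + sleep) >= 2
  condB <- ((redness > 0) + (dryness > 0) + (oedema > 0) + (oozing > 0)) >= 2
  as.integer(condA & condB)
}

#' Standardise continuous covariates of a pair table
#'
#' Continuous covariates are z-scored (population SD, denominator n) with
#' statistics computed from `pairs` or supplied from a training window; the
#' binary `tcs` flag passes through unscaled. Returned statistics can be
#' reused to transform test-time covariates without leakage.
#'
#' @param pairs An `ad_pairs` table.
#' @param stats `NULL` to fit statistics from `pairs`, or a `covariate_stats`
#'   object from a previous call.
#' @return A list with elements `pairs` (transformed table) and `stats`.
#' @export
standardize_covariates <- function(pairs, stats = NULL) {
  stopifnot(inherits(pairs, "ad_pairs"))
  covs <- attr(pairs, "covariates")
  cont <- setdiff(covs, "tcs")
  if (is.null(stats)) {
    mu <- vapply(cont, function(cv) mean(pairs[[cv]]), numeric(1))
    sdv <- vapply(cont, function(cv) {
      x <- pairs[[cv]]
      sqrt(mean((x - mean(x))^2))
    }, numeric(1))
    zero <- cont[sdv <= 0 | !is.finite(sdv)]
    if (length(zero) > 0)
      stop("zero variance for covariate(s): ", paste(zero, collapse = ", "))
    stats <- structure(list(mean = mu, sd = sdv, covariates = cont),
                       class = "covariate_stats")
  } else {
    stopifnot(inherits(stats, "covariate_stats"))
    if (!setequal(stats$covariates, cont))
      stop("stats cover different covariates than the pair table")
  }
  for (cv in cont)
    pairs[[cv]] <- (pairs[[cv]] - stats$mean[[cv]]) / stats$sd[[cv]]
  list(pairs = pairs, stats = stats)
}

#' Invert covariate standardisation
#'
#' @param pairs A standardised `ad_pairs` table.
#' @param stats The `covariate_stats` used to standardise it.
#' @return The pair table on the original covariate scale.
#' @export
unstandardize_covariates <- function(pairs, stats) {
  stopifnot(inherits(pairs, "ad_pairs"), inherits(stats, "covariate_stats"))
  for (cv in stats$covariates)
    pairs[[cv]] <- pairs[[cv]] * stats$sd[[cv]] + stats$mean[[cv]]
  pairs
}

#' Cross-correlogram between a covariate and a sign score
#'
#' For each lag l in 0..`max_lag`, computes the Pearson correlation between
#' the covariate at day t-l and the sign score at day t, pooled over patients
#' after per-patient mean-centering of the observed sign series (which removes
#' between-patient baseline differences). Used as the lag-selection diagnostic
#' for the order-1 autoregression.
#'
#' @param ds An [ad_panel] containing the covariate.
#' @param sign One of the six sign names.
#' @param covariate A covariate name present in `ds`.
#' @param max_lag Largest lag (days) to evaluate.
#' @return A data.frame with columns `lag`, `correlation` (NA when fewer than
#'   3 complete pairs exist at that lag) and `n` (pairs used).
#' @export
cross_correlogram <- function(ds, sign, covariate, max_lag) {
  stopifnot(inherits(ds, "ad_panel"), max_lag >= 0)
  if (!sign %in% .SIGNS) stop("unknown sign: ", sign)
  if (!covariate %in% names(ds)) stop("covariate not in dataset: ", covariate)

  s <- ds[[sign]]
  cent <- stats::ave(as.numeric(s), ds$patient_id,
                     FUN = function(v) v - mean(v, na.rm = TRUE))
  out <- data.frame(lag = 0:max_lag, correlation = NA_real_, n = 0L)
  for (l in 0:max_lag) {
    xs <- ys <- list()
    for (pid in unique(ds$patient_id)) {
      rows <- which(ds$patient_id == pid)
      day <- ds$day[rows]
      # match day t (sign) with day t-l (covariate) within the patient
      m <- match(day - l, day)
      has <- !is.na(m)
      y <- cent[rows][has]
      x <- ds[[covariate]][rows][m[has]]
      keep <- !is.na(x) & !is.na(y)
      xs[[pid]] <- x[keep]; ys[[pid]] <- y[keep]
    }
    x <- unlist(xs); y <- unlist(ys)
    out$n[l + 1] <- length(x)
    if (length(x) >= 3 && sd(x) > 0 && sd(y) > 0)
      out$correlation[l + 1] <- cor(x, y)
  }
  out
}
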