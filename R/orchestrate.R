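#' Read a run configuration from YAML/JSON
#'
#' A run configuration has sections `generator` (arguments of
#' [generator_config()]), `preprocessing` (`min_days`), `model`
#' (`variants`: named list of covariate sets), `validation` (`refit_stride`,
#' `min_train_days`, `quad_order`) and `seed`. Missing sections take the
#' package defaults. `run_config()` builds the same structure from R
#' arguments.
#'
#' @param path Path to a YAML or JSON configuration file.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  do.call(run_config, c(raw$generator,
                        list(min_days = raw$preprocessing$min_days,
                             variants = raw$model$variants,
                             refit_stride = raw$validation$refit_stride,
                             min_train_days = raw$validation$min_train_days,
                             quad_order = raw$validation$quad_order,
                             seed = raw$seed)))
}

#' @rdname read_run_config
#' @param ... Arguments for [generator_config()].
#' @param min_days Patient filter threshold (see [filter_min_observations()]).
#' @param variants Named list of covariate sets to validate.
#' @param refit_stride,min_train_days,quad_order Validation options
#'   (see [forward_chaining()]).
#' @param seed Master seed (overrides any generator seed).
#' @export
run_config <- function(..., min_days = 10,
                       variants = list("no-covariate" = character()),
                       refit_stride = 1, min_train_days = 1, quad_order = 9,
                       seed = 1) {
  gen_args <- Filter(Negate(is.null), list(...))
  gen_args$seed <- seed
  variants <- lapply(variants, as.character)
  if (is.null(names(variants)))
    names(variants) <- vapply(variants, variant_name, character(1))
  bad <- setdiff(unlist(variants), .COVARIATES)
  if (length(bad) > 0) stop("unknown covariates in variants: ",
                            paste(bad, collapse = ", "))
  structure(list(generator = gen_args,
                 min_days = min_days %||% 10,
                 variants = variants,
                 refit_stride = refit_stride %||% 1,
                 min_train_days = min_train_days %||% 1,
                 quad_order = quad_order %||% 9,
                 seed = seed %||% 1),
            class = "run_config")
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Simulate a cohort and write it to disk
#'
#' Generates the configured synthetic cohort and writes the long-format panel
#' CSV plus the ground-truth JSON sidecar. Rerunning with the same
#' configuration reproduces the files byte for byte.
#'
#' @param config A `run_config` (or path to one).
#' @param out_dir Output directory.
#' @return Named vector of written paths, invisibly.
#' @export
run_simulate <- function(config, out_dir) {
  config <- as_run_config(config)
  gc <- do.call(generator_config, config$generator)
  cohort <- generate_cohort(gc)
  paths <- write_cohort(cohort, out_dir)
  message(sprintf("simulated %d patients x %d days (seed %d, config %s) -> %s",
                  gc$n_patients, gc$n_days, gc$seed, config_hash(config),
                  paths[["panel"]]))
  invisible(paths)
}

as_run_config <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  config
}

#' Run the full validation pipeline on a dataset
#'
#' Applies the minimum-observation patient filter, runs forward-chaining
#' validation for every configured variant plus the benchmarks, and writes
#' the score table (CSV + metadata), per-sign learning-curve figures, the
#' paired RPS-difference table/figure for each covariate variant against the
#' covariate-free model, and — when single-covariate variants are present —
#' the single-covariate coefficient table fitted on the full filtered data.
#'
#' @param config A `run_config` (or path to one).
#' @param dataset An [ad_panel] or path to a panel CSV; `NULL` simulates one
#'   from the configuration.
#' @param out_dir Output directory.
#' @param figures Write PNG figures (default `TRUE`).
#' @return A list with the score table, paired differences, coefficient
#'   table and written paths, invisibly.
#' @export
run_validate <- function(config, dataset = NULL, out_dir, figures = TRUE) {
  config <- as_run_config(config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  ds <- if (is.null(dataset)) {
    gc <- do.call(generator_config, config$generator)
    generate_cohort(gc)$panel
  } else if (is.character(dataset)) read_panel(dataset) else dataset
  stopifnot(inherits(ds, "ad_panel"))
  ds <- filter_min_observations(ds, config$min_days)

  table <- forward_chaining(ds, variants = config$variants,
                            refit_stride = config$refit_stride,
                            min_train_days = config$min_train_days,
                            quad_order = config$quad_order)
  meta <- attr(table, "meta")
  meta$config_hash <- config_hash(config)
  meta$seed <- config$seed
  attr(table, "meta") <- meta
  paths <- c(scores = file.path(out_dir, "scores.csv"))
  write_score_table(table, paths[["scores"]])

  # paired differences of each covariate variant against the covariate-free one
  diffs <- NULL
  base_variant <- names(config$variants)[vapply(config$variants, length, 1L) == 0]
  if (length(base_variant) == 1) {
    others <- setdiff(names(config$variants), base_variant)
    diffs <- do.call(rbind, lapply(others, function(v) {
      d <- paired_score_difference(
        table[table$model_variant == base_variant & table$sign != "state", ],
        table[table$model_variant == v & table$sign != "state", ])
      if (nrow(d)) cbind(d, model_variant = v) else NULL
    }))
    if (!is.null(diffs)) {
      paths[["differences"]] <- file.path(out_dir, "paired_differences.csv")
      write.csv(diffs, paths[["differences"]], row.names = FALSE)
    }
  }

  # single-covariate coefficients on the full filtered data
  singles <- config$variants[vapply(config$variants, length, 1L) == 1]
  coefs <- NULL
  if (length(singles) > 0) {
    fits <- list()
    for (sg in meta$signs) for (cvs in singles) {
      fit <- tryCatch(
        fit_sign_model(extract_transition_pairs(ds, sg, cvs),
                       quad_order = config$quad_order),
        error = function(e) NULL)
      if (!is.null(fit)) fits[[length(fits) + 1]] <- fit
    }
    coefs <- coefficient_table(fits)
    paths[["coefficients"]] <- file.path(out_dir, "coefficients.csv")
    write.csv(coefs, paths[["coefficients"]], row.names = FALSE)
  }

  if (figures) {
    for (sg in unique(table$sign)) {
      p <- plot_learning_curves(table, sg,
                                score_type = if (sg == "state") "Brier" else "RPS")
      f <- file.path(out_dir, sprintf("learning_curve_%s.png", sg))
      ggplot2::ggsave(f, p, width = 7, height = 4.5, dpi = 120)
      paths[[paste0("fig_", sg)]] <- f
    }
    if (!is.null(diffs) && nrow(diffs) > 0) {
      f <- file.path(out_dir, "paired_differences.png")
      ggplot2::ggsave(f, plot_paired_differences(diffs),
                      width = 7, height = 4.5, dpi = 120)
      paths[["fig_differences"]] <- f
    }
  }
  message(sprintf("validation complete: %d score records -> %s",
                  nrow(table), out_dir))
  invisible(list(table = table, differences = diffs, coefficients = coefs,
                 paths = paths))
}

#' Summarise one or more score tables into a text report
#'
#' @param score_tables A `score_table`, a list of them, or paths to saved
#'   tables. With two or more tables sharing keys, a paired comparison
#'   section is included.
#' @param out_file Output text file (`NULL` returns the lines invisibly).
#' @return The report lines, invisibly.
#' @export
run_report <- function(score_tables, out_file = NULL) {
  if (inherits(score_tables, "score_table")) score_tables <- list(score_tables)
  if (length(score_tables) == 0) stop("no score tables supplied")
  score_tables <- lapply(score_tables, function(x) {
    if (is.character(x)) {
      if (!file.exists(x)) stop("score table not found: ", x)
      read_score_table(x)
    } else x
  })
  lines <- c("adforecast validation report",
             sprintf("generated %s; %d table(s)", format(Sys.time()),
                     length(score_tables)), "")
  for (i in seq_along(score_tables)) {
    tb <- score_tables[[i]]
    meta <- attr(tb, "meta")
    lines <- c(lines, sprintf("== table %d: %d records (config %s, seed %s)", i,
                              nrow(tb), meta$config_hash %||% "?",
                              meta$seed %||% "?"))
    agg <- stats::aggregate(score_value ~ sign + model_variant + score_type,
                            as.data.frame(tb), mean)
    agg <- agg[order(agg$sign, agg$model_variant), ]
    lines <- c(lines, sprintf("  %-10s %-16s mean %-5s = %.4f", agg$sign,
                              agg$model_variant, agg$score_type,
                              agg$score_value))
    nf <- tryCatch(nrow(meta$failures), error = function(e) 0)
    if (!is.null(nf) && length(nf) && nf > 0)
      lines <- c(lines, sprintf("  flagged fit gaps: %d", nf))
    lines <- c(lines, "")
  }
  if (length(score_tables) >= 2) {
    pick <- function(tb) {
      v <- setdiff(unique(tb$model_variant), c("uniform", "historical"))[1]
      tb[tb$model_variant == v & tb$sign != "state", , drop = FALSE]
    }
    cmp <- tryCatch(
      paired_score_difference(pick(score_tables[[1]]), pick(score_tables[[2]])),
      error = function(e) NULL)
    if (!is.null(cmp)) {
      lines <- c(lines, "== paired comparison (table 1 - table 2)",
                 sprintf("  %-10s diff %+0.5f (95%% CI %+0.5f..%+0.5f, n=%d)",
                         cmp$sign, cmp$mean_diff, cmp$lower, cmp$upper, cmp$n),
                 "")
    }
  }
  if (!is.null(out_file)) writeLines(lines, out_file)
  invisible(lines)
}
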