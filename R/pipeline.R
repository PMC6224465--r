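#' Validate a trial table
#'
#' Reads (or accepts) a long trial table and enforces the record contract:
#' known condition, stimulation and hemisphere labels, positive amounts
#' with `r2 > r1`, delays in {14, 28}, responses coded `SS`/`LL` or
#' missing. All row-level problems are collected and reported together.
#' Missing responses are retained (they are excluded and tallied at fit
#' time). `framing` and `k_eq` are filled in when absent.
#'
#' @param x A data frame, or the path of a delimited text file (tab- or
#'   comma-separated, with a header) containing columns `subject`,
#'   `hemisphere`, `stim_level`, `condition`, `r1`, `r2`, `delay_days`,
#'   `response`.
#' @return A typed tibble of trial records with columns `subject`,
#'   `hemisphere`, `stim_level`, `condition`, `framing`, `r1`, `r2`,
#'   `delay_days`, `pct_diff`, `k_eq`, `response`. Attribute
#'   `"cell_counts"` holds the per-cell trial counts.
#' @export
validate_trials <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    delim <- if (grepl("\\.csv$", x, ignore.case = TRUE)) "," else "\t"
    x <- readr::read_delim(x, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  }
  x <- tibble::as_tibble(x)
  req <- c("subject", "hemisphere", "stim_level", "condition",
           "r1", "r2", "delay_days", "response")
  missing_cols <- setdiff(req, names(x))
  if (length(missing_cols) > 0L) {
    stop("trial table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  problems <- character()
  flag <- function(bad, what) {
    if (any(bad)) {
      problems <<- c(problems,
                     paste0(what, " (rows ",
                            paste(head(which(bad), 5L), collapse = ", "),
                            if (sum(bad) > 5L) ", ..." else "", ")"))
    }
  }
  flag(!x$condition %in% choice_conditions(), "unknown condition label")
  flag(!x$stim_level %in% stimulation_levels(), "unknown stim_level label")
  flag(!x$hemisphere %in% c("left", "right"), "unknown hemisphere label")
  flag(!is.na(x$r1) & x$r1 <= 0, "non-positive r1")
  flag(is.na(x$r1) | is.na(x$r2), "missing amount")
  flag(!is.na(x$r1) & !is.na(x$r2) & x$r2 <= x$r1, "r2 not greater than r1")
  flag(!x$delay_days %in% c(14, 28), "delay_days outside {14, 28}")
  flag(!is.na(x$response) & !x$response %in% c("SS", "LL"),
       "response not SS/LL/missing")
  if (length(problems) > 0L) {
    stop("invalid trial table:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  x$delay_days <- as.integer(x$delay_days)
  if (!"framing" %in% names(x)) {
    x$framing <- ifelse(x$condition == "explicit_zero", "explicit_zero",
                        "standard")
  }
  if (!"pct_diff" %in% names(x)) x$pct_diff <- x$r2 / x$r1 - 1
  if (!"k_eq" %in% names(x)) x$k_eq <- k_eq(x$r1, x$r2, x$delay_days)
  out <- x[, c("subject", "hemisphere", "stim_level", "condition", "framing",
               "r1", "r2", "delay_days", "pct_diff", "k_eq", "response")]
  counts <- dplyr::count(out, .data$subject, .data$stim_level,
                         .data$condition, name = "n_trials")
  attr(out, "cell_counts") <- counts
  out
}

#' Run the full simulate-fit-metrics-statistics pipeline
#'
#' Orchestrates every stage on one study: simulate trials from `config`
#' (or validate user-supplied trials), fit all cells by multi-start
#' maximum likelihood, compute per-cell choice diagnostics, run the
#' magnitude and hidden-zero mixed ANOVAs against each available baseline,
#' and compare effect-reduction proportions with Fisher's exact test. All
#' stage outputs are written as UTF-8 tab-separated tables under
#' `out_dir`, plus a JSON run manifest; identical config + seed reproduce
#' identical outputs.
#'
#' @param out_dir Output directory (created if needed).
#' @param config A [study_config()]; also supplies the root seed.
#' @param trials Optional external trial table (data frame or file path,
#'   see [validate_trials()]); when given, simulation is skipped and no
#'   ground-truth table is written.
#' @param settings A [fit_settings()] object.
#' @return Invisibly, the run manifest: a list with the config snapshot,
#'   seed, package version, per-stage output paths and timestamps.
#' @export
run_pipeline <- function(out_dir, config = study_config(), trials = NULL,
                         settings = fit_settings()) {
  stopifnot(inherits(config, "study_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  started <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  files <- list()
  write_stage <- function(df, name) {
    path <- file.path(out_dir, paste0(name, ".tsv"))
    readr::write_tsv(df, path, progress = FALSE)
    files[[name]] <<- path
    path
  }
  truth <- NULL
  if (is.null(trials)) {
    study <- simulate_study(config)
    trials <- study$trials
    truth <- study$truth
    write_stage(trials, "trials")
    write_stage(truth, "ground_truth")
  } else {
    trials <- validate_trials(trials)
    write_stage(trials, "trials")
  }
  fits <- fit_study(trials, settings, seed = config$seed)
  write_stage(fits, "fits")
  metrics <- cell_metrics(trials, fits)
  write_stage(metrics, "metrics")
  refs <- intersect(c("sham", "pre_experiment"), unique(fits$stim_level))
  has_tms <- "tms" %in% fits$stim_level
  anovas <- list()
  reductions <- list()
  if (has_tms) {
    for (ref in refs) {
      for (eff in c("magnitude", "hidden_zero")) {
        if (!effect_condition(eff) %in% fits$condition) next
        tab <- condition_anova(fits, eff, ref)
        tab$analysis <- eff
        tab$reference <- ref
        anovas[[paste(eff, ref)]] <- tab
      }
      cmp <- tryCatch(compare_effect_reductions(fits, ref),
                      error = function(e) NULL)
      if (!is.null(cmp)) {
        reductions[[ref]] <- tibble::tibble(
          reference = ref,
          effect = cmp$counts$effect,
          n_reduced = cmp$counts$n_reduced,
          n_total = cmp$counts$n_total,
          odds_ratio = cmp$fisher$odds_ratio,
          p_value = cmp$fisher$p_value
        )
      }
    }
  }
  if (length(anovas) > 0L) {
    write_stage(dplyr::bind_rows(anovas), "anova_tables")
  }
  if (length(reductions) > 0L) {
    write_stage(dplyr::bind_rows(reductions), "effect_reductions")
  }
  manifest <- list(
    package = "hyperdisc",
    version = as.character(utils::packageVersion("hyperdisc")),
    seed = config$seed,
    config = unclass(config),
    simulated = is.null(truth) == FALSE,
    files = lapply(files, normalizePath),
    started = started,
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
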