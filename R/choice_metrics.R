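#' Classify responses as consistent with a fitted discount rate
#'
#' A response is "correct" when it agrees with the preference implied by the
#' subject's fitted discount rate: smaller-sooner when `k > k_eq` (the
#' smaller-sooner option has the higher subjective value) and larger-later
#' when `k < k_eq`. At an exact tie `k = k_eq` the model is indifferent and
#' either response counts as correct. Trials without a response yield `NA`.
#'
#' @param trials Data frame with columns `r1`, `r2`, `delay_days`,
#'   `response` (`"SS"`/`"LL"`/`NA`); a `k_eq` column is used if present and
#'   computed otherwise.
#' @param k Fitted discount rate for the same cell (scalar), or a
#'   `"discount_fit"` object.
#' @return Character vector `"correct"` / `"incorrect"` with `NA` for
#'   missing responses.
#' @export
classify_correct <- function(trials, k) {
  if (inherits(k, "discount_fit")) k <- k$k
  stopifnot(is.numeric(k), length(k) == 1L, k > 0)
  keq <- if ("k_eq" %in% names(trials)) trials$k_eq else
    k_eq(trials$r1, trials$r2, trials$delay_days)
  prefer_ss <- k > keq
  tie <- k == keq
  ok <- ifelse(tie, TRUE,
               ifelse(trials$response == "SS", prefer_ss, !prefer_ss))
  out <- ifelse(ok, "correct", "incorrect")
  out[is.na(trials$response)] <- NA_character_
  out
}

#' Proportion of smaller-sooner choices
#'
#' The fraction of responded trials on which the smaller-sooner option was
#' chosen (pSS). Under the model, pSS decreases as the choice's
#' indifference rate `k_eq` rises past the subject's discount rate.
#'
#' @param trials Data frame with a `response` column (`"SS"`/`"LL"`/`NA`).
#' @return Fraction in `[0, 1]`.
#' @export
pss <- function(trials) {
  resp <- trials$response[!is.na(trials$response)]
  if (length(resp) == 0L) {
    stop("pSS is undefined: no responded trials", call. = FALSE)
  }
  mean(resp == "SS")
}

#' pSS after a median split on the indifference rate
#'
#' Orders a cell's trials by `k_eq`, splits them into a below-median and an
#' above-median half (for the 20-choice sets: the 10 smallest and 10
#' largest `k_eq`, ties broken by stable order), and returns pSS in each
#' half. A subject whose choices track subjective value should show
#' `pss_low_keq >= pss_high_keq` in expectation.
#'
#' @param trials Data frame for one cell with columns `r1`, `r2`,
#'   `delay_days`, `response` (and optionally `k_eq`).
#' @return A tibble with columns `pss_low_keq` and `pss_high_keq` (either
#'   may be `NA` if its half has no responded trials).
#' @export
median_split_pss <- function(trials) {
  if (nrow(trials) < 2L) {
    stop("median split needs at least two trials", call. = FALSE)
  }
  keq <- if ("k_eq" %in% names(trials)) trials$k_eq else
    k_eq(trials$r1, trials$r2, trials$delay_days)
  ord <- order(keq)
  n_low <- nrow(trials) %/% 2L
  low <- trials[ord[seq_len(n_low)], , drop = FALSE]
  high <- trials[ord[(n_low + 1L):nrow(trials)], , drop = FALSE]
  half_pss <- function(x) {
    if (all(is.na(x$response))) NA_real_ else pss(x)
  }
  tibble::tibble(pss_low_keq = half_pss(low), pss_high_keq = half_pss(high))
}

#' Per-cell choice diagnostics
#'
#' Joins a trial table with its per-cell fits and computes, for every
#' subject x stimulation x condition cell: the fraction of responses
#' consistent with the fitted discount rate (`pct_correct`), the overall
#' smaller-sooner proportion (`pss`), and pSS in the below/above-median
#' `k_eq` halves.
#'
#' @param trials Long trial table (see [fit_study()]).
#' @param fits Per-cell fit table from [fit_study()].
#' @return A tibble with one row per cell: `subject`, `hemisphere`,
#'   `stim_level`, `condition`, `pct_correct`, `pss`, `pss_low_keq`,
#'   `pss_high_keq`, `n_responded`.
#' @export
cell_metrics <- function(trials, fits) {
  cells <- dplyr::distinct(fits, .data$subject, .data$hemisphere,
                           .data$stim_level, .data$condition, .data$k)
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cell <- cells[i, ]
    tr <- trials[trials$subject == cell$subject &
                   trials$stim_level == cell$stim_level &
                   trials$condition == cell$condition, , drop = FALSE]
    correct <- classify_correct(tr, cell$k)
    split <- median_split_pss(tr)
    out[[i]] <- tibble::tibble(
      subject = cell$subject, hemisphere = cell$hemisphere,
      stim_level = cell$stim_level, condition = cell$condition,
      pct_correct = mean(correct == "correct", na.rm = TRUE),
      pss = pss(tr),
      pss_low_keq = split$pss_low_keq,
      pss_high_keq = split$pss_high_keq,
      n_responded = sum(!is.na(tr$response))
    )
  }
  dplyr::bind_rows(out)
}
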