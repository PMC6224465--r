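#' Type-III mixed ANOVA with generalized eta squared
#'
#' Analyses a 2 (between-subject group, optional) x 2 x 2 (within-subject)
#' mixed design, the workhorse test of this pipeline (response typically
#' `ln k`, but also pSS or percent-correct tables). The decomposition uses
#' orthonormal within-subject contrast scores: each subject's four cell
#' values are projected onto the mean, the two within main-effect contrasts
#' and their interaction contrast; each score vector is then analysed in its
#' own stratum against the between factor with sum-to-zero coding and
#' type-III sums of squares, so within effects are tested on the unweighted
#' mean of group means when the between groups are unbalanced. Each F has
#' 1 numerator df and `n - g` denominator df (`g` = number of between
#' groups).
#'
#' Generalized eta squared for an effect is
#' `SS_effect / (SS_effect + sum of all subject-related error SS)`, the sum
#' running over the between-subject error and all three within-stratum
#' errors, which makes effect sizes comparable across between- and
#' within-subject effects.
#'
#' Within factors must have exactly two levels; the Greenhouse-Geisser
#' sphericity correction is then the identity (a single contrast per
#' effect, [gg_epsilon()] is 1 by construction) and uncorrected df are
#' reported. Tables with more within levels are rejected rather than
#' silently uncorrected.
#'
#' @param data Long data frame: one row per subject x within-cell.
#' @param dv Name of the response column.
#' @param within Character vector naming the two within-subject factor
#'   columns (each with exactly two levels).
#' @param subject Name of the subject identifier column.
#' @param between Optional name of the between-subject factor column; a
#'   single-level factor is treated as absent.
#' @return A tibble with one row per effect (`effect`, `df1`, `df2`,
#'   `statistic` (F), `ges`, `p_value`), in the order between, within-1,
#'   between:within-1, within-2, between:within-2, within-1:within-2,
#'   three-way. Attribute `"error_ss"` carries the per-stratum error sums
#'   of squares.
#' @export
mixed_anova <- function(data, dv, within, subject = "subject",
                        between = NULL) {
  stopifnot(length(within) == 2L)
  cols <- c(dv, within, subject, between)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0L) {
    stop("data is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  y <- data[[dv]]
  if (!is.numeric(y) || any(is.na(y))) {
    stop("response `", dv, "` must be numeric with no missing values",
         call. = FALSE)
  }
  w1 <- droplevels(as.factor(data[[within[1]]]))
  w2 <- droplevels(as.factor(data[[within[2]]]))
  for (w in list(w1, w2)) {
    if (nlevels(w) != 2L) {
      stop("within factors must have exactly two levels (the ",
           "Greenhouse-Geisser correction is only the identity there); `",
           within[if (identical(w, w1)) 1 else 2], "` has ", nlevels(w),
           call. = FALSE)
    }
  }
  subj <- as.factor(data[[subject]])
  n <- nlevels(subj)
  # wide subject x cell matrix, cells ordered (w1:1,w2:1),(1,2),(2,1),(2,2)
  cell <- (as.integer(w1) - 1L) * 2L + as.integer(w2)
  Y <- matrix(NA_real_, n, 4L)
  idx <- cbind(as.integer(subj), cell)
  dup <- anyDuplicated(idx)
  if (dup > 0L) {
    stop("subject '", levels(subj)[idx[dup, 1L]],
         "' has duplicated within-design cells", call. = FALSE)
  }
  Y[idx] <- y
  if (anyNA(Y)) {
    bad <- levels(subj)[which(rowSums(is.na(Y)) > 0L)[1L]]
    stop("subject '", bad, "' is missing within-design cells", call. = FALSE)
  }
  grp <- NULL
  if (!is.null(between)) {
    g_by_subj <- tapply(as.character(data[[between]]), subj, unique)
    if (any(lengths(g_by_subj) != 1L)) {
      bad <- names(g_by_subj)[lengths(g_by_subj) != 1L][1L]
      stop("subject '", bad, "' appears in more than one between group",
           call. = FALSE)
    }
    grp <- droplevels(factor(unlist(g_by_subj)))
    if (nlevels(grp) < 2L) grp <- NULL
  }
  if (n - (if (is.null(grp)) 1L else nlevels(grp)) < 1L) {
    stop("not enough subjects for a residual degree of freedom",
         call. = FALSE)
  }
  # orthonormal contrast scores (coefficients +-1/2: exact SS decomposition)
  z <- list(
    mean = (Y[, 1] + Y[, 2] + Y[, 3] + Y[, 4]) / 2,
    w1   = (Y[, 1] + Y[, 2] - Y[, 3] - Y[, 4]) / 2,
    w2   = (Y[, 1] - Y[, 2] + Y[, 3] - Y[, 4]) / 2,
    w12  = (Y[, 1] - Y[, 2] - Y[, 3] + Y[, 4]) / 2
  )
  strata <- lapply(z, anova_stratum, grp = grp)
  err_ss <- vapply(strata, function(s) s$ss_res, 0)
  err_total <- sum(err_ss)
  df2 <- strata$mean$df_res
  w12_name <- paste(within, collapse = ":")
  rows <- list()
  add_row <- function(effect, ss, stratum) {
    ms_err <- stratum$ss_res / stratum$df_res
    f <- if (ss <= 1e-12) 0 else if (ms_err == 0) Inf else ss / ms_err
    p <- if (ss <= 1e-12) 1 else pf(f, 1, stratum$df_res, lower.tail = FALSE)
    ges <- if (ss <= 1e-12) 0 else ss / (ss + err_total)
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      effect = effect, df1 = 1L, df2 = stratum$df_res,
      statistic = f, ges = ges, p_value = p
    )
  }
  if (!is.null(grp)) add_row(between, strata$mean$ss_g, strata$mean)
  add_row(within[1], strata$w1$ss_int, strata$w1)
  if (!is.null(grp)) {
    add_row(paste(between, within[1], sep = ":"), strata$w1$ss_g, strata$w1)
  }
  add_row(within[2], strata$w2$ss_int, strata$w2)
  if (!is.null(grp)) {
    add_row(paste(between, within[2], sep = ":"), strata$w2$ss_g, strata$w2)
  }
  add_row(w12_name, strata$w12$ss_int, strata$w12)
  if (!is.null(grp)) {
    add_row(paste(between, w12_name, sep = ":"), strata$w12$ss_g, strata$w12)
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "error_ss") <- err_ss
  out
}

# one contrast-score stratum: type-III intercept (within effect), between
# term, and residual. Cell-means formulas: the intercept test is on the
# unweighted mean of group means (sum-to-zero coding), which is what
# distinguishes type III from sequential SS when groups are unbalanced.
anova_stratum <- function(z, grp) {
  n <- length(z)
  if (is.null(grp)) {
    mu <- mean(z)
    list(ss_int = n * mu^2, ss_g = NA_real_,
         ss_res = sum((z - mu)^2), df_res = n - 1L)
  } else {
    m_g <- tapply(z, grp, mean)
    n_g <- tabulate(grp)
    n_groups <- nlevels(grp)
    mu_unweighted <- mean(m_g)
    fitted <- m_g[as.integer(grp)]
    list(
      ss_int = n_groups^2 * mu_unweighted^2 / sum(1 / n_g),
      ss_g = sum(n_g * (m_g - mean(z))^2),
      ss_res = sum((z - fitted)^2),
      df_res = n - n_groups
    )
  }
}

#' Greenhouse-Geisser epsilon from a contrast covariance matrix
#'
#' `epsilon = tr(M)^2 / (d * tr(M^2))` for the `d x d` covariance matrix
#' `M` of a within-effect's orthonormal contrast variables. A two-level
#' within factor has a single contrast (`d = 1`), for which epsilon is
#' identically 1 — the correction is the identity, which is why
#' [mixed_anova()] reports uncorrected df for this design.
#'
#' @param M Covariance matrix (scalar allowed for `d = 1`).
#' @return Epsilon in `(0, 1]`.
#' @export
gg_epsilon <- function(M) {
  M <- as.matrix(M)
  d <- nrow(M)
  sum(diag(M))^2 / (d * sum(M * M))
}

#' Classical paired t test
#'
#' Two-sided paired t on per-subject values: `t = mean(d) / (sd(d)/sqrt(n))`
#' with `df = n - 1`. Zero variance of the differences is a degenerate case:
#' all-zero differences give `t = 0, p = 1`; a constant nonzero difference
#' gives an infinite statistic, both with a warning.
#'
#' @param x,y Equal-length numeric vectors paired by subject (`n >= 2`).
#' @return A tibble with `statistic`, `df`, `p_value`.
#' @export
paired_t <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y),
            length(x) >= 2L, !anyNA(x), !anyNA(y))
  d <- x - y
  n <- length(d)
  if (sd(d) == 0) {
    warning("zero variance of paired differences; degenerate t test",
            call. = FALSE)
    if (mean(d) == 0) {
      return(tibble::tibble(statistic = 0, df = n - 1L, p_value = 1))
    }
    return(tibble::tibble(statistic = sign(mean(d)) * Inf, df = n - 1L,
                          p_value = 0))
  }
  tt <- t.test(x, y, paired = TRUE)
  tibble::tibble(statistic = unname(tt$statistic),
                 df = unname(tt$parameter),
                 p_value = tt$p.value)
}

effect_condition <- function(effect) {
  effect <- match.arg(effect, c("magnitude", "hidden_zero"))
  switch(effect, magnitude = "high_magnitude", hidden_zero = "explicit_zero")
}

#' Per-subject context/framing effect sizes
#'
#' The effect size of a context or framing manipulation for one subject at
#' one stimulation level is the drop in log discount rate it produces:
#' `ln k(control) - ln k(high_magnitude)` for the magnitude effect, or
#' `ln k(control) - ln k(explicit_zero)` for the hidden-zero effect.
#' Positive values mean the manipulation made the subject more patient.
#'
#' @param fits Per-cell fit table (see [fit_study()]) or any table with
#'   `subject`, `hemisphere`, `stim_level`, `condition` and the response
#'   column.
#' @param effect `"magnitude"` or `"hidden_zero"`.
#' @param dv Response column, default `"log_k"`.
#' @return A tibble `subject`, `hemisphere`, `stim_level`, `effect_size`
#'   (`NA` when a needed cell is missing).
#' @export
effect_sizes <- function(fits, effect = c("magnitude", "hidden_zero"),
                         dv = "log_k") {
  ec <- effect_condition(match.arg(effect))
  sub <- fits[fits$condition %in% c("control", ec),
              c("subject", "hemisphere", "stim_level", "condition", dv)]
  wide <- tidyr::pivot_wider(sub, names_from = "condition",
                             values_from = dplyr::all_of(dv))
  if (!all(c("control", ec) %in% names(wide))) {
    wide[setdiff(c("control", ec), names(wide))] <- NA_real_
  }
  tibble::tibble(
    subject = wide$subject, hemisphere = wide$hemisphere,
    stim_level = wide$stim_level,
    effect_size = wide$control - wide[[ec]]
  )
}

#' Count subjects whose effect shrinks under stimulation
#'
#' A subject counts as "reduced" when their context/framing effect size
#' ([effect_sizes()]) under active stimulation is strictly smaller than
#' under the chosen no-stimulation reference; exact ties count as not
#' reduced. Subjects missing any of the four needed cells are excluded and
#' reported.
#'
#' @param fits Per-cell fit table (see [fit_study()]).
#' @param effect `"magnitude"` or `"hidden_zero"`.
#' @param reference `"sham"` or `"pre_experiment"`.
#' @param dv Response column, default `"log_k"`.
#' @return A list of class `"reduction_count"`: `n_reduced`, `n_total`,
#'   `n_excluded`, `effect`, `reference`.
#' @export
count_reductions <- function(fits, effect = c("magnitude", "hidden_zero"),
                             reference = c("sham", "pre_experiment"),
                             dv = "log_k") {
  effect <- match.arg(effect)
  reference <- match.arg(reference)
  es <- effect_sizes(fits, effect, dv)
  es <- es[es$stim_level %in% c(reference, "tms"),
           c("subject", "stim_level", "effect_size")]
  wide <- tidyr::pivot_wider(es, names_from = "stim_level",
                             values_from = "effect_size")
  if (!all(c(reference, "tms") %in% names(wide))) {
    wide[setdiff(c(reference, "tms"), names(wide))] <- NA_real_
  }
  complete <- !is.na(wide[[reference]]) & !is.na(wide$tms)
  if (any(!complete)) {
    message("count_reductions: excluding ", sum(!complete),
            " subject(s) with missing cells: ",
            paste(head(wide$subject[!complete], 5L), collapse = ", "))
  }
  structure(
    list(n_reduced = sum(wide$tms[complete] < wide[[reference]][complete]),
         n_total = sum(complete), n_excluded = sum(!complete),
         effect = effect, reference = reference),
    class = "reduction_count"
  )
}

#' @export
print.reduction_count <- function(x, ...) {
  cat(sprintf("%s effect reduced under tms (vs %s): %d of %d subjects",
              x$effect, x$reference, x$n_reduced, x$n_total))
  if (x$n_excluded > 0L) cat(sprintf(" (%d excluded)", x$n_excluded))
  cat("\n")
  invisible(x)
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Exact test of association in a 2x2 contingency table using the
#' minimum-likelihood two-sided rule: the p value sums the hypergeometric
#' point probabilities of all tables (with the observed margins) whose
#' probability does not exceed the observed table's, up to a relative
#' tolerance of 1e-7. The reported effect size is the *sample*
#' (cross-product) odds ratio `(a d) / (b c)` — not the conditional-MLE
#' estimate — reported as infinite when `b c = 0` and `a d > 0`. A zero
#' margin makes the table degenerate: `p = 1` and the odds ratio is `NA`.
#'
#' @param x A 2x2 matrix (or table) of non-negative integer counts; rows
#'   are groups, columns outcomes.
#' @return A list of class `"proportion_comparison"`: `table`,
#'   `odds_ratio`, `p_value`, `method`.
#' @export
#' @examples
#' fisher_exact_2x2(matrix(c(26, 18, 1, 9), nrow = 2))
fisher_exact_2x2 <- function(x) {
  x <- as.matrix(x)
  if (!all(dim(x) == c(2L, 2L)) || any(x < 0) || any(x != round(x))) {
    stop("`x` must be a 2x2 matrix of non-negative integer counts",
         call. = FALSE)
  }
  a <- x[1, 1]; b <- x[1, 2]; c_ <- x[2, 1]; d <- x[2, 2]
  n_total <- sum(x)
  r1 <- a + b; c1 <- a + c_
  if (r1 == 0 || r1 == n_total || c1 == 0 || c1 == n_total) {
    warning("a table margin is zero; p = 1 and the odds ratio is undefined",
            call. = FALSE)
    p <- 1
    or <- NA_real_
  } else {
    support <- max(0, r1 + c1 - n_total):min(r1, c1)
    dk <- dhyper(support, c1, n_total - c1, r1)
    d_obs <- dhyper(a, c1, n_total - c1, r1)
    p <- min(1, sum(dk[dk <= d_obs * (1 + 1e-7)]))
    or <- if (b * c_ == 0) {
      if (a * d == 0) NaN else Inf
    } else {
      (a * d) / (b * c_)
    }
  }
  structure(
    list(table = x, odds_ratio = or, p_value = p,
         method = "two-sided Fisher's exact test (minimum-likelihood rule)"),
    class = "proportion_comparison"
  )
}

#' @export
print.proportion_comparison <- function(x, ...) {
  cat(x$method, "\n")
  print(x$table)
  cat(sprintf("sample odds ratio = %s, p = %.4g\n",
              format(x$odds_ratio), x$p_value))
  invisible(x)
}

#' ANOVA of one context/framing effect against one baseline
#'
#' Convenience wrapper reproducing the study's per-effect tables: restricts
#' the fit table to the control condition plus the effect's condition and
#' to the reference stimulation level plus `tms`, then runs the 2x2x2
#' [mixed_anova()] with hemisphere as the between factor. Effect rows are
#' named after the manipulation (e.g. `magnitude`, `tms`,
#' `magnitude:tms`, ...).
#'
#' @inheritParams count_reductions
#' @return A [mixed_anova()] table.
#' @export
condition_anova <- function(fits, effect = c("magnitude", "hidden_zero"),
                            reference = c("sham", "pre_experiment"),
                            dv = "log_k") {
  effect <- match.arg(effect)
  reference <- match.arg(reference)
  ec <- effect_condition(effect)
  sub <- fits[fits$condition %in% c("control", ec) &
                fits$stim_level %in% c(reference, "tms"), , drop = FALSE]
  sub[[effect]] <- factor(sub$condition, levels = c("control", ec))
  sub$tms <- factor(sub$stim_level, levels = c(reference, "tms"))
  mixed_anova(sub, dv = dv, within = c(effect, "tms"),
              between = "hemisphere")
}

#' Compare how often stimulation reduced the two effects
#'
#' Counts subjects for whom stimulation reduced the magnitude effect and
#' the hidden-zero effect ([count_reductions()]), assembles the paired
#' 2x2 reduced/not-reduced table, and tests the proportions with
#' [fisher_exact_2x2()].
#'
#' @inheritParams count_reductions
#' @return A list of class `"effect_reduction_comparison"`: `counts`
#'   (tibble with one row per effect), `fisher` (the test object),
#'   `reference`.
#' @export
compare_effect_reductions <- function(fits,
                                      reference = c("sham", "pre_experiment"),
                                      dv = "log_k") {
  reference <- match.arg(reference)
  mag <- count_reductions(fits, "magnitude", reference, dv)
  hz <- count_reductions(fits, "hidden_zero", reference, dv)
  tab <- matrix(
    c(mag$n_reduced, mag$n_total - mag$n_reduced,
      hz$n_reduced, hz$n_total - hz$n_reduced),
    nrow = 2L, byrow = TRUE,
    dimnames = list(c("magnitude", "hidden_zero"),
                    c("reduced", "not_reduced"))
  )
  structure(
    list(
      counts = tibble::tibble(
        effect = c("magnitude", "hidden_zero"),
        n_reduced = c(mag$n_reduced, hz$n_reduced),
        n_total = c(mag$n_total, hz$n_total)
      ),
      fisher = fisher_exact_2x2(tab),
      reference = reference
    ),
    class = "effect_reduction_comparison"
  )
}

#' @export
print.effect_reduction_comparison <- function(x, ...) {
  cat(sprintf("Effect reductions under tms (reference: %s)\n", x$reference))
  print(x$counts)
  print(x$fisher)
  invisible(x)
}
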