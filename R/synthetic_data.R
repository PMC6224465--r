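#' Configuration of a simulated discounting study
#'
#' Defines the generative model of a synthetic within-subject study:
#' `n_subjects` agents (split into left/right stimulation groups), three
#' stimulation levels (`pre_experiment`, `sham`, `tms`) by three
#' framing/context conditions (`control`, `high_magnitude`,
#' `explicit_zero`), 20 choices per cell. Each subject's baseline `ln k` is
#' drawn from `N(mu_logk_control, sigma_logk_between^2)`; each cell adds the
#' relevant condition/stimulation shifts plus independent
#' `N(0, sigma_logk_session^2)` session noise. The two no-stimulation levels
#' (`pre_experiment`, `sham`) are generated identically and differ only by
#' session noise, mirroring the use of two baselines in the design.
#'
#' Default effect structure: a large magnitude effect
#' (`magnitude_shift = -2` on `ln k`), a smaller explicit-zero framing
#' effect (`hidden_zero_shift = -0.4`), no main effect of stimulation
#' (`tms_main = 0`), and a positive `tms_magnitude_interaction = +1.5` that
#' selectively shrinks the magnitude effect under stimulation. Agents choose
#' with inverse temperature `alpha_by_condition`; the high-magnitude value
#' is 10x smaller because dollar-scale value differences are about 10x
#' larger there (amounts are 100x larger but percent differences 10x
#' smaller), which keeps choice consistency comparable across conditions. Hemisphere has no true effect by default;
#' `hemisphere_shift` (added to right-group `ln k`) exists for power
#' exploration.
#'
#' @param n_subjects,n_left,n_right Cohort sizes; `n_left + n_right` must
#'   equal `n_subjects` (defaults 27 = 15 + 12).
#' @param mu_logk_control Population mean of control-condition `ln k` per
#'   day.
#' @param sigma_logk_between Between-subject SD of baseline `ln k` (`>= 0`).
#' @param sigma_logk_session Within-subject, per-cell session SD of `ln k`
#'   (`>= 0`).
#' @param magnitude_shift,hidden_zero_shift Additive `ln k` shifts for the
#'   high-magnitude and explicit-zero conditions (negative = more patient).
#' @param tms_main Additive `ln k` shift for all cells under `tms`.
#' @param tms_magnitude_interaction Additive `ln k` shift for high-magnitude
#'   cells under `tms` only.
#' @param hemisphere_shift Additive `ln k` shift for right-hemisphere
#'   subjects.
#' @param alpha_by_condition Named numeric vector of agent inverse
#'   temperatures per condition (all `> 0`).
#' @param seed Integer root seed; all randomness derives from it.
#' @return A list of class `"study_config"`.
#' @export
study_config <- function(n_subjects = 27L,
                         n_left = 15L,
                         n_right = 12L,
                         mu_logk_control = log(0.01),
                         sigma_logk_between = 0.8,
                         sigma_logk_session = 0.3,
                         magnitude_shift = -2.0,
                         hidden_zero_shift = -0.4,
                         tms_main = 0,
                         tms_magnitude_interaction = 1.5,
                         hemisphere_shift = 0,
                         alpha_by_condition = c(control = 1.0,
                                                high_magnitude = 0.1,
                                                explicit_zero = 1.0),
                         seed = 1L) {
  if (n_left + n_right != n_subjects) {
    stop("`n_left` + `n_right` must equal `n_subjects`", call. = FALSE)
  }
  if (sigma_logk_between < 0 || sigma_logk_session < 0) {
    stop("standard deviations must be non-negative", call. = FALSE)
  }
  if (!all(choice_conditions() %in% names(alpha_by_condition))) {
    stop("`alpha_by_condition` must name all conditions: ",
         paste(choice_conditions(), collapse = ", "), call. = FALSE)
  }
  if (any(alpha_by_condition <= 0)) {
    stop("`alpha_by_condition` values must be positive", call. = FALSE)
  }
  structure(
    list(n_subjects = as.integer(n_subjects), n_left = as.integer(n_left),
         n_right = as.integer(n_right), mu_logk_control = mu_logk_control,
         sigma_logk_between = sigma_logk_between,
         sigma_logk_session = sigma_logk_session,
         magnitude_shift = magnitude_shift,
         hidden_zero_shift = hidden_zero_shift,
         tms_main = tms_main,
         tms_magnitude_interaction = tms_magnitude_interaction,
         hemisphere_shift = hemisphere_shift,
         alpha_by_condition = alpha_by_condition[choice_conditions()],
         seed = as.integer(seed)),
    class = "study_config"
  )
}

#' @export
print.study_config <- function(x, ...) {
  cat("Simulated-study configuration\n")
  cat(sprintf("  subjects: %d (%d left / %d right), seed %d\n",
              x$n_subjects, x$n_left, x$n_right, x$seed))
  cat(sprintf("  ln k: mu = %.3f, between-SD = %.2f, session-SD = %.2f\n",
              x$mu_logk_control, x$sigma_logk_between, x$sigma_logk_session))
  cat(sprintf(
    "  shifts: magnitude %.2f, hidden-zero %.2f, tms %.2f, tms:mag %.2f, hemi %.2f\n",
    x$magnitude_shift, x$hidden_zero_shift, x$tms_main,
    x$tms_magnitude_interaction, x$hemisphere_shift))
  cat("  alpha:", paste(names(x$alpha_by_condition),
                        format(x$alpha_by_condition), sep = "=",
                        collapse = ", "), "\n")
  invisible(x)
}

#' Draw one subject's true per-cell parameters
#'
#' Builds the 9-cell (3 stimulation levels x 3 conditions) ground truth for
#' a single subject from the current RNG state: baseline `ln k` plus
#' deterministic shifts plus per-cell session noise, and the condition's
#' agent `alpha`.
#'
#' @param config A [study_config()].
#' @param subject Subject identifier.
#' @param hemisphere `"left"` or `"right"`.
#' @return A tibble with columns `subject`, `hemisphere`, `stim_level`,
#'   `condition`, `log_k`, `alpha` (9 rows).
#' @export
draw_subject_truth <- function(config, subject = "s01", hemisphere = "left") {
  stopifnot(inherits(config, "study_config"),
            hemisphere %in% c("left", "right"))
  baseline <- rnorm(1, config$mu_logk_control, config$sigma_logk_between)
  grid <- expand.grid(stim_level = stimulation_levels(),
                      condition = choice_conditions(),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  shift <- (grid$condition == "high_magnitude") * config$magnitude_shift +
    (grid$condition == "explicit_zero") * config$hidden_zero_shift +
    (grid$stim_level == "tms") * config$tms_main +
    (grid$stim_level == "tms" & grid$condition == "high_magnitude") *
      config$tms_magnitude_interaction +
    (hemisphere == "right") * config$hemisphere_shift
  noise <- rnorm(nrow(grid), 0, config$sigma_logk_session)
  tibble::tibble(
    subject = subject, hemisphere = hemisphere,
    stim_level = grid$stim_level, condition = grid$condition,
    log_k = baseline + shift + noise,
    alpha = unname(config$alpha_by_condition[grid$condition])
  )
}

#' Ground-truth table for a whole simulated cohort
#'
#' Per-subject truths ([draw_subject_truth()]) for all subjects, with the
#' first `n_left` subjects assigned to the left group. Each subject's draw
#' uses a seed derived from the config's root seed and the subject id, so
#' the table is reproducible and identical to the truth component of
#' [simulate_study()].
#'
#' @param config A [study_config()].
#' @return A tibble with `n_subjects * 9` rows.
#' @export
draw_study_truth <- function(config) {
  stopifnot(inherits(config, "study_config"))
  ids <- sprintf("s%02d", seq_len(config$n_subjects))
  hemi <- rep(c("left", "right"), c(config$n_left, config$n_right))
  out <- vector("list", config$n_subjects)
  for (i in seq_len(config$n_subjects)) {
    out[[i]] <- withr::with_seed(
      derive_seed(config$seed, "truth", ids[i]),
      draw_subject_truth(config, ids[i], hemi[i])
    )
  }
  dplyr::bind_rows(out)
}

#' Simulate a complete discounting study
#'
#' Generates a full synthetic experiment: for every subject x stimulation x
#' condition cell, a fresh 20-choice set ([build_choice_set()]) and
#' responses sampled as Bernoulli draws of the larger-later choice
#' probability at the cell's true `(k, alpha)`. Every random stream is
#' derived from `config$seed` and the cell labels, so the same config
#' reproduces the same study exactly.
#'
#' @param config A [study_config()].
#' @return A list of class `"simulated_study"` with elements `trials` (long
#'   trial table: `subject`, `hemisphere`, `stim_level`, `condition`,
#'   `framing`, `r1`, `r2`, `delay_days`, `pct_diff`, `k_eq`, `response`),
#'   `truth` (from [draw_study_truth()]) and `config`.
#' @export
#' @examples
#' study <- simulate_study(study_config(n_subjects = 2, n_left = 1,
#'                                      n_right = 1))
#' dim(study$trials) # 2 subjects x 9 cells x 20 choices
simulate_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  truth <- draw_study_truth(config)
  trials <- vector("list", nrow(truth))
  for (i in seq_len(nrow(truth))) {
    cell <- truth[i, ]
    cell_seed <- derive_seed(config$seed, "trials", cell$subject,
                             cell$stim_level, cell$condition)
    trials[[i]] <- withr::with_seed(cell_seed, {
      cs <- build_choice_set(cell$condition)
      p_ll <- choice_probability(cs$r1, cs$r2, cs$delay_days,
                                 exp(cell$log_k), cell$alpha)
      tibble::tibble(
        subject = cell$subject, hemisphere = cell$hemisphere,
        stim_level = cell$stim_level, condition = cs$condition,
        framing = cs$framing, r1 = cs$r1, r2 = cs$r2,
        delay_days = cs$delay_days, pct_diff = cs$pct_diff,
        k_eq = k_eq(cs$r1, cs$r2, cs$delay_days),
        response = ifelse(runif(nrow(cs)) < p_ll, "LL", "SS")
      )
    })
  }
  structure(
    list(trials = dplyr::bind_rows(trials), truth = truth, config = config),
    class = "simulated_study"
  )
}

#' @export
print.simulated_study <- function(x, ...) {
  cat("Simulated discounting study\n")
  cat(sprintf("  %d subjects, %d trials (%d cells x 20 choices)\n",
              x$config$n_subjects, nrow(x$trials), nrow(x$truth)))
  cat(sprintf("  seed %d\n", x$config$seed))
  invisible(x)
}
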