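#' Hyperbolic subjective value
#'
#' `V = r / (1 + k t)`: the present subjective value of a reward of `r`
#' dollars delivered after `t` days for a decision-maker with discount rate
#' `k` per day. Undelayed rewards (`t = 0`) are undiscounted; value is
#' strictly decreasing in both `t` and `k`.
#'
#' @param r Reward in dollars, `> 0`.
#' @param t Delay in days, `>= 0`.
#' @param k Discount rate per day, `> 0`.
#' @return Subjective value in dollars (vectorized).
#' @export
#' @examples
#' subjective_value(24, 14, 1 / 70) # 20
subjective_value <- function(r, t, k) {
  if (any(r <= 0)) stop("`r` must be positive", call. = FALSE)
  if (any(k <= 0)) stop("`k` must be positive", call. = FALSE)
  if (any(t < 0)) stop("`t` must be non-negative", call. = FALSE)
  r / (1 + k * t)
}

#' Indifference discount rate of a choice
#'
#' The unique discount rate at which a hyperbolic discounter values the two
#' options of a binary choice equally: solving `r1 = r2 / (1 + k t)` gives
#' `k_eq = (r2 - r1) / (r1 t)`. A subject with `k < k_eq` prefers the
#' larger-later option, one with `k > k_eq` the smaller-sooner option.
#'
#' @param r1 Smaller-sooner amount (dollars, immediate), `> 0`.
#' @param r2 Larger-later amount (dollars), `> r1`.
#' @param delay_days Delay of `r2` in days, `> 0`.
#' @return Indifference rate per day (vectorized).
#' @export
#' @examples
#' k_eq(20, 24, 14) # 0.0142857...
k_eq <- function(r1, r2, delay_days) {
  if (any(r1 <= 0)) stop("`r1` must be positive", call. = FALSE)
  if (any(r2 <= r1)) stop("`r2` must exceed `r1`", call. = FALSE)
  if (any(delay_days <= 0)) stop("`delay_days` must be positive", call. = FALSE)
  (r2 - r1) / (r1 * delay_days)
}

#' Softmax probability of choosing the larger-later option
#'
#' Binary logistic (softmax) choice rule on the subjective-value difference:
#' `P(LL) = 1 / (1 + exp(-alpha * (V_LL - V_SS)))` with
#' `V_LL = r2 / (1 + k * delay_days)` and `V_SS = r1` (immediate, hence
#' undiscounted). At `k = k_eq` the value difference is zero and the
#' probability is 1/2 for any `alpha`.
#'
#' @param r1,r2,delay_days Choice fields as in [k_eq()].
#' @param k Discount rate per day, `> 0`.
#' @param alpha Softmax inverse temperature per dollar of value difference,
#'   `> 0`; `alpha -> 0` gives random choice, `alpha -> Inf` deterministic
#'   choice.
#' @return Probability in (0, 1) of choosing the larger-later option
#'   (vectorized). The smaller-sooner probability is its complement.
#' @export
choice_probability <- function(r1, r2, delay_days, k, alpha) {
  if (any(r1 <= 0) || any(r2 <= 0)) stop("amounts must be positive",
                                         call. = FALSE)
  if (any(k <= 0)) stop("`k` must be positive", call. = FALSE)
  plogis(alpha * value_difference(r1, r2, delay_days, k))
}

# V_LL - V_SS, written as r1 * t * (k_eq - k) / (1 + k t): algebraically
# identical to r2/(1 + k t) - r1 but exactly zero in floating point when
# k equals the k_eq computed from the same amounts
value_difference <- function(r1, r2, t, k) {
  ifelse(t > 0,
         r1 * t * ((r2 - r1) / (r1 * t) - k) / (1 + k * t),
         r2 - r1)
}

#' Negative log-likelihood of observed choices
#'
#' `-sum(log P(observed response))` under the hyperbolic-softmax model.
#' Probabilities are clipped away from 0 and 1 before the log so the
#' objective is finite everywhere in the parameter box.
#'
#' @param trials Data frame with columns `r1`, `r2`, `delay_days` and
#'   `response` coded `"SS"` / `"LL"` (no missing responses; drop them
#'   first).
#' @param k,alpha Model parameters, `> 0`.
#' @param clip Lower clip on per-trial probabilities (default `1e-12`).
#' @return Non-negative scalar.
#' @export
negative_log_likelihood <- function(trials, k, alpha, clip = 1e-12) {
  if (nrow(trials) == 0L) stop("`trials` must contain at least one trial",
                               call. = FALSE)
  if (!all(trials$response %in% c("SS", "LL"))) {
    stop("responses must be coded 'SS' or 'LL' with no missing values",
         call. = FALSE)
  }
  p_ll <- choice_probability(trials$r1, trials$r2, trials$delay_days, k, alpha)
  p_obs <- ifelse(trials$response == "LL", p_ll, 1 - p_ll)
  -sum(log(pmin(pmax(p_obs, clip), 1 - clip)))
}

#' Settings for maximum-likelihood fitting
#'
#' The estimator optimizes over `(ln k, ln alpha)` inside a box, restarting
#' a bounded quasi-Newton (L-BFGS-B) local search from points drawn
#' uniformly in the log-box; the default 50 restarts mirror the
#' multi-initialization global strategy commonly used to dodge local minima
#' in this likelihood. Bounds `k` in `[1e-6, 10]` per day and `alpha` in
#' `[1e-4, 100]` per dollar span indifference horizons from seconds to years
#' on these choice sets.
#'
#' @param n_restarts Number of local-optimizer restarts (`>= 1`).
#' @param k_bounds,alpha_bounds Length-2 numeric bounds (positive).
#' @param clip Probability clip passed to [negative_log_likelihood()].
#' @param maxit Iteration cap per local search.
#' @return A list of class `"fit_settings"`.
#' @export
fit_settings <- function(n_restarts = 50L,
                         k_bounds = c(1e-6, 10),
                         alpha_bounds = c(1e-4, 100),
                         clip = 1e-12,
                         maxit = 200L) {
  stopifnot(n_restarts >= 1L, length(k_bounds) == 2L, all(k_bounds > 0),
            k_bounds[1] < k_bounds[2], length(alpha_bounds) == 2L,
            all(alpha_bounds > 0), alpha_bounds[1] < alpha_bounds[2],
            clip > 0, clip < 0.5, maxit >= 1L)
  structure(
    list(n_restarts = as.integer(n_restarts), k_bounds = k_bounds,
         alpha_bounds = alpha_bounds, clip = clip, maxit = as.integer(maxit)),
    class = "fit_settings"
  )
}

# objective and analytic gradient in (ln k, ln alpha)
nll_logpar <- function(par, r1, r2, t, y_ll, clip) {
  k <- exp(par[1]); alpha <- exp(par[2])
  dv <- value_difference(r1, r2, t, k)
  p_ll <- plogis(alpha * dv)
  p_obs <- ifelse(y_ll, p_ll, 1 - p_ll)
  -sum(log(pmin(pmax(p_obs, clip), 1 - clip)))
}

nll_grad_logpar <- function(par, r1, r2, t, y_ll, clip) {
  k <- exp(par[1]); alpha <- exp(par[2])
  denom <- 1 + k * t
  dv <- value_difference(r1, r2, t, k)
  u <- alpha * dv
  p_ll <- plogis(u)
  resid <- p_ll - as.numeric(y_ll)
  g_lnk <- sum(resid * alpha * k * (-r2 * t / denom^2))
  g_lnalpha <- sum(resid * u)
  c(g_lnk, g_lnalpha)
}

#' Fit discount rate and choice noise for one cell
#'
#' Maximum-likelihood estimate of the hyperbolic discount rate `k` and
#' softmax inverse temperature `alpha` for one subject x condition x
#' stimulation cell. The search runs in `(ln k, ln alpha)` with box bounds
#' (see [fit_settings()]) from `n_restarts` uniform starting points and
#' keeps the lowest negative log-likelihood; trials with missing responses
#' are dropped and tallied. The returned optimum is never worse than any
#' restart's initial point.
#'
#' @param trials Data frame with columns `r1`, `r2`, `delay_days`,
#'   `response` (`"SS"`/`"LL"`, `NA` allowed and excluded); at least two
#'   responded trials.
#' @param settings A [fit_settings()] object.
#' @param seed Optional integer seed making the restart draws (and hence the
#'   fit) deterministic.
#' @return An object of class `"discount_fit"`: a list with `k`, `alpha`,
#'   `log_k`, `log_likelihood` (`<= 0`), `nll`, `n_trials`, `n_excluded`,
#'   `n_restarts_used`, `converged`, and bound-hit flags `at_k_bound`,
#'   `at_alpha_bound`.
#' @export
#' @examples
#' cs <- build_choice_set("control", seed = 1)
#' cs$response <- ifelse(k_eq(cs$r1, cs$r2, cs$delay_days) > 0.01, "LL", "SS")
#' fit_cell(cs, fit_settings(n_restarts = 10), seed = 1)
fit_cell <- function(trials, settings = fit_settings(), seed = NULL) {
  stopifnot(inherits(settings, "fit_settings"))
  if (!is.null(seed)) {
    return(withr::with_seed(seed, fit_cell(trials, settings)))
  }
  responded <- trials[!is.na(trials$response), , drop = FALSE]
  n_excluded <- nrow(trials) - nrow(responded)
  if (nrow(responded) < 2L) {
    stop("need at least two responded trials to fit a cell", call. = FALSE)
  }
  if (!all(responded$response %in% c("SS", "LL"))) {
    stop("responses must be coded 'SS' or 'LL'", call. = FALSE)
  }
  r1 <- responded$r1; r2 <- responded$r2
  t <- responded$delay_days; y_ll <- responded$response == "LL"
  lower <- c(log(settings$k_bounds[1]), log(settings$alpha_bounds[1]))
  upper <- c(log(settings$k_bounds[2]), log(settings$alpha_bounds[2]))
  best <- NULL
  any_converged <- FALSE
  best_converged <- FALSE
  for (i in seq_len(settings$n_restarts)) {
    par0 <- runif(2L, lower, upper)
    res <- tryCatch(
      optim(par0, nll_logpar, nll_grad_logpar, method = "L-BFGS-B",
            lower = lower, upper = upper,
            control = list(maxit = settings$maxit),
            r1 = r1, r2 = r2, t = t, y_ll = y_ll, clip = settings$clip),
      error = function(e) {
        list(par = par0,
             value = nll_logpar(par0, r1, r2, t, y_ll, settings$clip),
             convergence = 99L)
      }
    )
    if (res$convergence == 0L) any_converged <- TRUE
    if (is.null(best) || res$value < best$value) {
      best <- res
      best_converged <- res$convergence == 0L
    }
  }
  tol <- 1e-8
  structure(
    list(
      k = exp(best$par[1]),
      alpha = exp(best$par[2]),
      log_k = best$par[1],
      log_alpha = best$par[2],
      log_likelihood = -best$value,
      nll = best$value,
      n_trials = nrow(responded),
      n_excluded = n_excluded,
      n_restarts_used = settings$n_restarts,
      converged = any_converged && best_converged,
      at_k_bound = min(abs(best$par[1] - c(lower[1], upper[1]))) < tol,
      at_alpha_bound = min(abs(best$par[2] - c(lower[2], upper[2]))) < tol,
      settings = settings
    ),
    class = "discount_fit"
  )
}

#' @export
print.discount_fit <- function(x, ...) {
  cat("Hyperbolic-softmax ML fit\n")
  cat(sprintf("  k      = %.6g per day (ln k = %.4f)\n", x$k, x$log_k))
  cat(sprintf("  alpha  = %.6g per dollar\n", x$alpha))
  cat(sprintf("  logLik = %.4f over %d trials (%d excluded)\n",
              x$log_likelihood, x$n_trials, x$n_excluded))
  cat(sprintf("  restarts = %d, converged = %s%s\n", x$n_restarts_used,
              x$converged,
              if (x$at_k_bound || x$at_alpha_bound) " [at bound]" else ""))
  invisible(x)
}

#' Fit every subject x stimulation x condition cell of a trial table
#'
#' Applies [fit_cell()] to each cell of a long trial table. When `seed` is
#' supplied, each cell's restart stream is derived from the seed and the
#' cell's labels ([derive_seed()]), so results are reproducible and
#' independent of row order.
#'
#' @param trials Long trial table with columns `subject`, `hemisphere`,
#'   `stim_level`, `condition`, `r1`, `r2`, `delay_days`, `response`.
#' @param settings A [fit_settings()] object.
#' @param seed Optional integer root seed.
#' @return A tibble with one row per cell: `subject`, `hemisphere`,
#'   `stim_level`, `condition`, `k`, `log_k`, `alpha`, `nll`, `n_trials`,
#'   `n_excluded`, `converged`.
#' @export
fit_study <- function(trials, settings = fit_settings(), seed = NULL) {
  req <- c("subject", "hemisphere", "stim_level", "condition",
           "r1", "r2", "delay_days", "response")
  missing_cols <- setdiff(req, names(trials))
  if (length(missing_cols) > 0L) {
    stop("trial table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  cells <- dplyr::distinct(trials, .data$subject, .data$hemisphere,
                           .data$stim_level, .data$condition)
  fits <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cell <- cells[i, ]
    rows <- trials$subject == cell$subject &
      trials$stim_level == cell$stim_level &
      trials$condition == cell$condition
    cell_seed <- if (is.null(seed)) NULL else {
      derive_seed(seed, "fit", cell$subject, cell$stim_level, cell$condition)
    }
    f <- fit_cell(trials[rows, , drop = FALSE], settings, seed = cell_seed)
    fits[[i]] <- tibble::tibble(
      subject = cell$subject, hemisphere = cell$hemisphere,
      stim_level = cell$stim_level, condition = cell$condition,
      k = f$k, log_k = f$log_k, alpha = f$alpha, nll = f$nll,
      n_trials = f$n_trials, n_excluded = f$n_excluded,
      converged = f$converged
    )
  }
  dplyr::bind_rows(fits)
}
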