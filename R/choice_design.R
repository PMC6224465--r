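#' Percent-difference tiers for one condition
#'
#' Each 20-choice set is built from a fixed multiset of percent differences
#' `pct_diff = r2/r1 - 1`. The low-magnitude conditions (control and
#' explicit-zero framing) use 1%, 5%, 10%, 20%, 30% and 40% with three
#' choices each plus 50% with two choices. The high-magnitude condition uses
#' the same tier counts with every percent difference divided by ten
#' (0.1%-5%), which keeps choice difficulty comparable despite the magnitude
#' effect.
#'
#' @param condition One of [choice_conditions()].
#' @return A tibble with columns `pct_diff` (fraction) and `n_choices`;
#'   counts always sum to 20.
#' @export
#' @examples
#' percent_difference_multiset("control")
percent_difference_multiset <- function(condition) {
  condition <- match_condition(condition)
  tiers <- tibble::tibble(
    pct_diff = c(0.01, 0.05, 0.10, 0.20, 0.30, 0.40, 0.50),
    n_choices = c(3L, 3L, 3L, 3L, 3L, 3L, 2L)
  )
  if (condition == "high_magnitude") {
    tiers$pct_diff <- tiers$pct_diff / 10
  }
  tiers
}

#' Sample smaller-sooner amounts for one condition
#'
#' Amounts are drawn from N(20, 5) dollars for the control and explicit-zero
#' conditions and from N(2000, 500) for the high-magnitude condition,
#' redrawn while non-positive (truncation at zero; vanishingly rare at these
#' parameters, but the sampler must be total) and rounded to cents. Uses the
#' current RNG state; seed the generator for reproducibility.
#'
#' @param condition One of [choice_conditions()].
#' @param n Number of draws.
#' @return Numeric vector of positive dollar amounts rounded to cents.
#' @export
sample_amount <- function(condition, n = 1L) {
  condition <- match_condition(condition)
  mu <- if (condition == "high_magnitude") 2000 else 20
  sigma <- if (condition == "high_magnitude") 500 else 5
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need) > 0L) {
    out[need] <- rnorm(length(need), mu, sigma)
    need <- need[out[need] <= 0]
  }
  round(out, 2)
}

#' Build one 20-choice intertemporal choice set
#'
#' Constructs the condition's choice set: smaller-sooner amounts `r1` are
#' sampled independently per choice ([sample_amount()]), larger-later
#' amounts are `r2 = r1 * (1 + pct_diff)` rounded to cents, and delays are
#' assigned so that exactly ten choices use 14 days and ten use 28 days with
#' both delays represented in every percent-difference tier. Tier balancing:
#' the two-choice 50% tier gets one choice at each delay; of the six
#' three-choice tiers, three (chosen at random) get two 14-day choices and
#' the other three get two 28-day choices, which yields the 10/10 split by
#' construction. Rows are returned in randomized presentation order.
#'
#' @param condition One of [choice_conditions()].
#' @param seed Optional integer seed; when given, the set is a pure function
#'   of (condition, seed).
#' @return A tibble with columns `condition`, `framing`, `r1`, `r2`,
#'   `delay_days`, `pct_diff`; exactly 20 rows.
#' @export
#' @examples
#' cs <- build_choice_set("control", seed = 1)
#' validate_choice_set(cs)
build_choice_set <- function(condition, seed = NULL) {
  condition <- match_condition(condition)
  if (!is.null(seed)) {
    return(withr::with_seed(seed, build_choice_set(condition)))
  }
  tiers <- percent_difference_multiset(condition)
  three <- which(tiers$n_choices == 3L)
  heavy14 <- sample(three, length(three) / 2L)
  delays <- vector("list", nrow(tiers))
  for (j in seq_len(nrow(tiers))) {
    d <- if (tiers$n_choices[j] == 2L) {
      c(14L, 28L)
    } else if (j %in% heavy14) {
      c(14L, 14L, 28L)
    } else {
      c(14L, 28L, 28L)
    }
    delays[[j]] <- sample(d)
  }
  pct <- rep(tiers$pct_diff, tiers$n_choices)
  delay_days <- unlist(delays)
  r1 <- sample_amount(condition, length(pct))
  ord <- sample.int(length(pct))
  make_choice(r1, pct, delay_days, condition)[ord, ]
}

#' Construct choices from amounts and percent differences
#'
#' The larger-later amount is `r2 = r1 * (1 + pct_diff)` rounded to cents
#' (so a 20% difference on a $20 smaller reward gives $24.00 exactly).
#' [build_choice_set()] applies this same rule; exposing it separately
#' makes single choices easy to construct.
#'
#' @param r1 Smaller-sooner amount(s) in dollars, `> 0`.
#' @param pct_diff Percent difference(s) as fractions, `> 0`.
#' @param delay_days Delay(s), 14 or 28.
#' @param condition One of [choice_conditions()].
#' @return A tibble with columns `condition`, `framing`, `r1`, `r2`,
#'   `delay_days`, `pct_diff`.
#' @export
#' @examples
#' make_choice(20, 0.20, 14)$r2 # 24
make_choice <- function(r1, pct_diff, delay_days, condition = "control") {
  condition <- match_condition(condition)
  stopifnot(all(r1 > 0), all(pct_diff > 0), all(delay_days %in% c(14L, 28L)))
  tibble::tibble(
    condition = condition,
    framing = if (condition == "explicit_zero") "explicit_zero" else "standard",
    r1 = round(r1, 2),
    r2 = round(round(r1, 2) * (1 + pct_diff), 2),
    delay_days = as.integer(delay_days),
    pct_diff = pct_diff
  )
}

#' Validate a choice set against its design invariants
#'
#' Checks that a choice set has exactly 20 choices, the condition's
#' percent-difference multiset (tier counts 3,3,3,3,3,3,2), a 10/10 split of
#' 14- and 28-day delays with both delays present at every percent
#' difference, positive amounts with `r2 > r1`, `r2` consistent with
#' `r1 * (1 + pct_diff)` up to cent rounding, and explicit-zero framing
#' exactly for the explicit-zero condition.
#'
#' @param choice_set A tibble as returned by [build_choice_set()].
#' @return Invisibly `TRUE`; otherwise an error describing the violation.
#' @export
validate_choice_set <- function(choice_set) {
  cs <- choice_set
  req <- c("condition", "framing", "r1", "r2", "delay_days", "pct_diff")
  missing_cols <- setdiff(req, names(cs))
  if (length(missing_cols) > 0L) {
    stop("choice set is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  condition <- unique(cs$condition)
  if (length(condition) != 1L) stop("choice set mixes conditions", call. = FALSE)
  match_condition(condition)
  if (nrow(cs) != 20L) {
    stop("choice set must have exactly 20 choices, found ", nrow(cs),
         call. = FALSE)
  }
  tiers <- percent_difference_multiset(condition)
  got <- table(factor(cs$pct_diff, levels = tiers$pct_diff))
  if (any(is.na(match(cs$pct_diff, tiers$pct_diff))) ||
      !all(as.integer(got) == tiers$n_choices)) {
    stop("percent-difference multiset does not match the condition's tiers",
         call. = FALSE)
  }
  if (!all(cs$delay_days %in% c(14L, 28L))) {
    stop("delays must be 14 or 28 days", call. = FALSE)
  }
  if (sum(cs$delay_days == 14L) != 10L) {
    stop("delays must split 10/10 between 14 and 28 days", call. = FALSE)
  }
  cover <- tapply(cs$delay_days, cs$pct_diff, function(d) all(c(14L, 28L) %in% d))
  if (!all(cover)) {
    stop("every percent difference needs at least one choice at each delay",
         call. = FALSE)
  }
  if (!all(cs$r1 > 0 & cs$r2 > cs$r1)) {
    stop("amounts must satisfy r2 > r1 > 0", call. = FALSE)
  }
  if (!all(abs(cs$r2 - cs$r1 * (1 + cs$pct_diff)) <= 0.005 + 1e-9)) {
    stop("r2 inconsistent with r1 * (1 + pct_diff) beyond cent rounding",
         call. = FALSE)
  }
  expect_framing <- if (condition == "explicit_zero") "explicit_zero" else "standard"
  if (!all(cs$framing == expect_framing)) {
    stop("framing must be '", expect_framing, "' for condition '", condition,
         "'", call. = FALSE)
  }
  invisible(TRUE)
}

#' Render the on-screen text of choices
#'
#' Standard framing shows "$r1 today" versus "$r2 in t days"; explicit-zero
#' framing states the implicit zero outcomes: "$r1 today and $0 in t days"
#' versus "$0 today and $r2 in t days". Amounts are rendered with two
#' decimals.
#'
#' @param choices A data frame with columns `r1`, `r2`, `delay_days`,
#'   `framing` (one or more rows).
#' @return A tibble with character columns `sooner` and `later`.
#' @export
#' @examples
#' render_choice_text(data.frame(r1 = 20, r2 = 24, delay_days = 14,
#'                               framing = "standard"))
render_choice_text <- function(choices) {
  stopifnot(all(c("r1", "r2", "delay_days", "framing") %in% names(choices)))
  ez <- choices$framing == "explicit_zero"
  t <- as.integer(choices$delay_days)
  sooner <- ifelse(
    ez,
    sprintf("$%.2f today and $0 in %d days", choices$r1, t),
    sprintf("$%.2f today", choices$r1)
  )
  later <- ifelse(
    ez,
    sprintf("$0 today and $%.2f in %d days", choices$r2, t),
    sprintf("$%.2f in %d days", choices$r2, t)
  )
  tibble::tibble(sooner = sooner, later = later)
}
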