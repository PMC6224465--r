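#' Experimental factor levels
#'
#' The closed label sets used throughout: three framing/context conditions
#' and three stimulation levels (two no-stimulation baselines plus active
#' rTMS).
#'
#' @return A character vector of labels.
#' @export
choice_conditions <- function() {
  c("control", "high_magnitude", "explicit_zero")
}

#' @rdname choice_conditions
#' @export
stimulation_levels <- function() {
  c("pre_experiment", "sham", "tms")
}

match_condition <- function(condition) {
  if (!is.character(condition) || length(condition) != 1L ||
      !condition %in% choice_conditions()) {
    stop("`condition` must be one of: ",
         paste(choice_conditions(), collapse = ", "), call. = FALSE)
  }
  condition
}

#' Derive a child seed from a root seed and a label path
#'
#' All randomness in a simulated study flows from one root seed; per-subject
#' and per-cell streams are derived deterministically from the root seed and
#' the cell's labels, so results do not depend on iteration order. The hash
#' is a 31-bit polynomial rolling hash of the label string.
#'
#' @param seed Integer root seed.
#' @param ... Labels (coerced to character) identifying the stream.
#' @return An integer in `[1, 2^31 - 1]` usable with [set.seed()].
#' @export
derive_seed <- function(seed, ...) {
  labs <- paste(c(as.character(seed), vapply(list(...), as.character, "")),
                collapse = "/")
  h <- 7L
  m <- 2147483647
  for (ch in utf8ToInt(labs)) {
    h <- (h * 31 + ch) %% m
  }
  as.integer(h %% (m - 1)) + 1L
}
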