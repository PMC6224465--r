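# Synthetic single agents used across tests.

# Trials for one agent facing n_sets fresh 20-choice sets.
# alpha = NULL gives a deterministic threshold agent (LL iff k_agent < k_eq);
# otherwise responses are Bernoulli draws of the softmax LL probability.
agent_trials <- function(k_agent, alpha = NULL, n_sets = 3L,
                         condition = "control", seed = 1L) {
  sets <- lapply(seq_len(n_sets), function(i) {
    build_choice_set(condition, seed = derive_seed(seed, "set", i))
  })
  tr <- do.call(rbind, sets)
  keq <- k_eq(tr$r1, tr$r2, tr$delay_days)
  tr$k_eq <- keq
  if (is.null(alpha)) {
    tr$response <- ifelse(k_agent < keq, "LL", "SS")
  } else {
    p <- choice_probability(tr$r1, tr$r2, tr$delay_days, k_agent, alpha)
    tr$response <- ifelse(withr::with_seed(derive_seed(seed, "resp"),
                                           stats::runif(nrow(tr))) < p,
                          "LL", "SS")
  }
  tr
}
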