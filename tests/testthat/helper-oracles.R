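# Independent oracles, kept deliberately separate from the package's own
# computation paths.

# Dense log-spaced grid over the parameter box followed by a local polish
# from the best grid point; an independent route to the optimum NLL.
grid_polish_nll <- function(trials, k_bounds = c(1e-6, 10),
                            alpha_bounds = c(1e-4, 100), n_grid = 200L,
                            clip = 1e-12) {
  lk <- seq(log(k_bounds[1]), log(k_bounds[2]), length.out = n_grid)
  la <- seq(log(alpha_bounds[1]), log(alpha_bounds[2]), length.out = n_grid)
  y_ll <- trials$response == "LL"
  # dv[i, j]: value difference for grid k i, trial j
  dv <- outer(exp(lk), seq_len(nrow(trials)), function(k, j) {
    trials$r2[j] / (1 + k * trials$delay_days[j]) - trials$r1[j]
  })
  best_val <- Inf
  best_par <- c(NA_real_, NA_real_)
  for (j in seq_along(la)) {
    p_ll <- stats::plogis(exp(la[j]) * dv)
    p_obs <- p_ll
    p_obs[, !y_ll] <- 1 - p_ll[, !y_ll]
    nll <- -rowSums(log(pmin(pmax(p_obs, clip), 1 - clip)))
    i <- which.min(nll)
    if (nll[i] < best_val) {
      best_val <- nll[i]
      best_par <- c(lk[i], la[j])
    }
  }
  f <- function(p) {
    negative_log_likelihood(trials, exp(p[1]), exp(p[2]), clip = clip)
  }
  polish <- stats::optim(best_par, f, method = "L-BFGS-B",
                         lower = c(log(k_bounds[1]), log(alpha_bounds[1])),
                         upper = c(log(k_bounds[2]), log(alpha_bounds[2])))
  min(best_val, polish$value)
}

# Brute-force two-sided Fisher p: enumerate every table with the observed
# margins, point probabilities from binomial coefficients.
fisher_p_enumeration <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; r2 <- c_ + d; c1 <- a + c_
  n <- r1 + r2
  support <- max(0, c1 - r2):min(r1, c1)
  point <- vapply(support, function(x) {
    exp(lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(n, c1))
  }, 0)
  obs <- point[support == a]
  sum(point[point <= obs * (1 + 1e-7)])
}
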