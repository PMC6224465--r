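# Two-subject 2x2 within-design toy table with hand-worked sums of squares.
# Cells (w1, w2): s1 = (1, 2, 3, 5), s2 = (2, 4, 6, 9.5) in the order
# (a1b1, a1b2, a2b1, a2b2). Orthonormal contrast scores (coefficients
# +-1/2) give, per stratum (effect SS, error SS) as exact fractions:
#   mean: error 441/32            w1:  (841/32, 81/32)
#   w2:   (289/32, 25/32)         w1:w2: (25/32, 1/32)
# so F(w1) = 841/81, F(w2) = 289/25, F(w1:w2) = 25; total error SS =
# 548/32, hence ges = 841/1389, 289/837, 25/573, all with df (1, 1).
test_that("mixed ANOVA reproduces the hand-worked toy decomposition", {
  d <- expand.grid(subject = c("s1", "s2"), w2 = c("b1", "b2"),
                   w1 = c("a1", "a2"), KEEP.OUT.ATTRS = FALSE,
                   stringsAsFactors = FALSE)
  d$y <- c(1, 2, 2, 4, 3, 6, 5, 9.5)
  tab <- mixed_anova(d, dv = "y", within = c("w1", "w2"))
  expect_equal(tab$effect, c("w1", "w2", "w1:w2"))
  expect_equal(tab$df1, rep(1L, 3))
  expect_equal(tab$df2, rep(1, 3))
  expect_equal(tab$statistic, c(841 / 81, 289 / 25, 25))
  expect_equal(tab$ges, c(841 / 1389, 289 / 837, 25 / 573))
  expect_equal(tab$p_value, pf(c(841 / 81, 289 / 25, 25), 1, 1,
                               lower.tail = FALSE))
  expect_equal(sum(attr(tab, "error_ss")), 548 / 32)
})

test_that("a constant response yields zero F and zero effect size", {
  d <- expand.grid(subject = paste0("s", 1:4), w1 = c("a1", "a2"),
                   w2 = c("b1", "b2"), stringsAsFactors = FALSE)
  d$g <- ifelse(d$subject %in% c("s1", "s2"), "left", "right")
  d$y <- 3.7
  tab <- mixed_anova(d, dv = "y", within = c("w1", "w2"), between = "g")
  expect_equal(nrow(tab), 7L)
  expect_true(all(tab$statistic == 0))
  expect_true(all(tab$ges == 0))
  expect_true(all(tab$p_value == 1))
})

test_that("mixed ANOVA agrees with aov error strata when balanced", {
  cfg <- study_config(n_subjects = 8, n_left = 4, n_right = 4, seed = 52)
  truth <- draw_study_truth(cfg)
  tab <- condition_anova(truth, "magnitude", "sham")
  sub <- truth[truth$condition %in% c("control", "high_magnitude") &
                 truth$stim_level %in% c("sham", "tms"), ]
  sub$mag <- factor(sub$condition)
  sub$tms <- factor(sub$stim_level)
  fit <- summary(aov(log_k ~ hemisphere * mag * tms +
                       Error(factor(subject) / (mag * tms)), data = sub))
  oracle_f <- c(
    fit[["Error: factor(subject)"]][[1]]["hemisphere", "F value"],
    fit[["Error: factor(subject):mag"]][[1]][c("mag", "hemisphere:mag"),
                                             "F value"],
    fit[["Error: factor(subject):tms"]][[1]][c("tms", "hemisphere:tms"),
                                             "F value"],
    fit[["Error: factor(subject):mag:tms"]][[1]][
      c("mag:tms", "hemisphere:mag:tms"), "F value"]
  )
  got_f <- tab$statistic[match(
    c("hemisphere", "magnitude", "hemisphere:magnitude", "tms",
      "hemisphere:tms", "magnitude:tms", "hemisphere:magnitude:tms"),
    tab$effect)]
  expect_equal(got_f, unname(oracle_f), tolerance = 1e-10)
})

test_that("type-III strata match the reference implementation when unbalanced", {
  cfg <- study_config(n_subjects = 7, n_left = 4, n_right = 3,
                      hemisphere_shift = 0.6, seed = 57)
  truth <- draw_study_truth(cfg)
  tab <- condition_anova(truth, "hidden_zero", "pre_experiment")
  sub <- truth[truth$condition %in% c("control", "explicit_zero") &
                 truth$stim_level %in% c("pre_experiment", "tms"), ]
  # per-subject within-effect contrast scores, tested against hemisphere
  # with sum-to-zero coding and type-III SS
  wide <- tidyr::pivot_wider(
    sub[, c("subject", "hemisphere", "stim_level", "condition", "log_k")],
    names_from = c("condition", "stim_level"), values_from = "log_k")
  score <- (wide$control_pre_experiment + wide$control_tms -
              wide$explicit_zero_pre_experiment - wide$explicit_zero_tms) / 2
  m <- lm(score ~ g, data = data.frame(score = score,
                                       g = factor(wide$hemisphere)),
          contrasts = list(g = "contr.sum"))
  a3 <- car::Anova(m, type = 3)
  expect_equal(
    tab$statistic[tab$effect == "hidden_zero"],
    a3["(Intercept)", "F value"], tolerance = 1e-10)
  expect_equal(
    tab$statistic[tab$effect == "hemisphere:hidden_zero"],
    a3["g", "F value"], tolerance = 1e-10)
  expect_equal(tab$df2[tab$effect == "hidden_zero"], a3["Residuals", "Df"])
})

test_that("the between test matches a one-way ANOVA on subject means", {
  cfg <- study_config(n_subjects = 9, n_left = 5, n_right = 4,
                      hemisphere_shift = 0.5, seed = 61)
  truth <- draw_study_truth(cfg)
  tab <- condition_anova(truth, "magnitude", "sham")
  sub <- truth[truth$condition %in% c("control", "high_magnitude") &
                 truth$stim_level %in% c("sham", "tms"), ]
  means <- stats::aggregate(log_k ~ subject + hemisphere, sub, mean)
  oracle <- anova(lm(log_k ~ hemisphere, means))
  expect_equal(tab$statistic[tab$effect == "hemisphere"],
               oracle["hemisphere", "F value"], tolerance = 1e-10)
  expect_equal(tab$p_value[tab$effect == "hemisphere"],
               oracle["hemisphere", "Pr(>F)"], tolerance = 1e-10)
})

test_that("generalized eta squared never exceeds partial eta squared", {
  withr::with_seed(71, {
    for (i in 1:10) {
      n <- 6
      d <- expand.grid(subject = paste0("s", 1:n), w1 = c("x", "y"),
                       w2 = c("u", "v"), stringsAsFactors = FALSE)
      d$g <- ifelse(as.integer(sub("s", "", d$subject)) <= 3, "l", "r")
      d$y <- rnorm(nrow(d))
      tab <- mixed_anova(d, dv = "y", within = c("w1", "w2"), between = "g")
      err <- attr(tab, "error_ss")
      strat_err <- c(err["mean"], err["w1"], err["w1"], err["w2"],
                     err["w2"], err["w12"], err["w12"])
      ss_eff <- tab$statistic * strat_err / tab$df2
      partial <- ss_eff / (ss_eff + strat_err)
      expect_true(all(tab$ges <= partial + 1e-12))
    }
  })
})

test_that("design problems are rejected with the offending subject named", {
  d <- expand.grid(subject = c("s1", "s2", "s3"), w1 = c("a1", "a2"),
                   w2 = c("b1", "b2"), stringsAsFactors = FALSE)
  d$y <- seq_len(nrow(d))
  expect_error(mixed_anova(d[-1, ], dv = "y", within = c("w1", "w2")),
               "s1.*missing")
  d3 <- rbind(d, d[2, ])
  expect_error(mixed_anova(d3, dv = "y", within = c("w1", "w2")),
               "duplicated")
  # more than two within levels is refused, not silently uncorrected
  d4 <- expand.grid(subject = c("s1", "s2"), w1 = c("a1", "a2", "a3"),
                    w2 = c("b1", "b2"), stringsAsFactors = FALSE)
  d4$y <- seq_len(nrow(d4))
  expect_error(mixed_anova(d4, dv = "y", within = c("w1", "w2")),
               "two levels")
})

test_that("sphericity epsilon is identically one for a single contrast", {
  expect_equal(gg_epsilon(matrix(2.31)), 1)
  expect_equal(gg_epsilon(0.007), 1)
  # and below one when a 3-level factor's contrasts are heteroscedastic
  M <- diag(c(3, 1, 0.2))
  expect_lt(gg_epsilon(M), 1)
})

test_that("paired t matches hand-computed statistics", {
  x <- c(5, 7, 9.5)
  expect_equal(paired_t(x + c(1, 2, 3), x),
               tibble::tibble(statistic = 2 * sqrt(3), df = 2,
                              p_value = 2 * pt(2 * sqrt(3), 2,
                                               lower.tail = FALSE)))
  expect_warning(res <- paired_t(x, x), "zero variance")
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  # antisymmetry
  withr::with_seed(81, {
    a <- rnorm(10); b <- rnorm(10)
  })
  expect_equal(paired_t(a, b)$statistic, -paired_t(b, a)$statistic)
  expect_equal(paired_t(a, b)$p_value, paired_t(b, a)$p_value)
})

test_that("context effects are positive for patient-making manipulations", {
  truth <- draw_study_truth(study_config(n_subjects = 12, n_left = 6,
                                         n_right = 6, seed = 91))
  es <- effect_sizes(truth, "magnitude")
  expect_equal(nrow(es), 12L * 3L)
  expect_gt(mean(es$effect_size), 0)
  sham <- es$effect_size[es$stim_level == "sham"]
  tt <- paired_t(
    truth$log_k[truth$condition == "control" & truth$stim_level == "sham"],
    truth$log_k[truth$condition == "high_magnitude" &
                  truth$stim_level == "sham"])
  expect_gt(tt$statistic, 0)
  expect_equal(tt$df, 11)
  expect_equal(mean(sham), 2, tolerance = 0.5)
})

test_that("reduction counts use strict inequality and report exclusions", {
  cells <- expand.grid(subject = c("s1", "s2", "s3"),
                       stim_level = c("sham", "tms"),
                       condition = c("control", "high_magnitude",
                                     "explicit_zero"),
                       stringsAsFactors = FALSE)
  cells$hemisphere <- "left"
  cells$log_k <- 0
  cells$log_k[cells$condition == "high_magnitude"] <- -2
  # identical effects under both levels: nobody is reduced
  rc <- count_reductions(cells, "magnitude", "sham")
  expect_equal(rc$n_reduced, 0L)
  expect_equal(rc$n_total, 3L)
  # shrink s1's effect under tms only
  cells$log_k[cells$subject == "s1" & cells$stim_level == "tms" &
                cells$condition == "high_magnitude"] <- -0.5
  rc2 <- count_reductions(cells, "magnitude", "sham")
  expect_equal(rc2$n_reduced, 1L)
  # a missing cell excludes (and reports) that subject
  expect_message(
    rc3 <- count_reductions(cells[-which(cells$subject == "s2" &
                                           cells$stim_level == "tms" &
                                           cells$condition == "control")[1], ],
                            "magnitude", "sham"),
    "excluding 1")
  expect_equal(rc3$n_total, 2L)
  expect_equal(rc3$n_excluded, 1L)
})

test_that("Fisher's exact test reproduces the reported contrast", {
  tab <- matrix(c(26, 1, 18, 9), nrow = 2, byrow = TRUE)
  res <- fisher_exact_2x2(tab)
  expect_identical(res$odds_ratio, 13)
  expect_equal(round(res$p_value, 3), 0.011)
  expect_equal(res$p_value, fisher_p_enumeration(tab), tolerance = 1e-12)
})

test_that("Fisher edge cases are handled explicitly", {
  sym <- fisher_exact_2x2(matrix(c(4, 4, 4, 4), 2))
  expect_equal(sym$p_value, 1)
  expect_equal(sym$odds_ratio, 1)
  expect_warning(z <- fisher_exact_2x2(matrix(c(0, 0, 5, 7), 2,
                                              byrow = TRUE)),
                 "margin")
  expect_equal(z$p_value, 1)
  expect_true(is.na(z$odds_ratio))
  inf <- fisher_exact_2x2(matrix(c(5, 0, 3, 4), 2, byrow = TRUE))
  expect_identical(inf$odds_ratio, Inf)
  expect_error(fisher_exact_2x2(matrix(c(1.5, 2, 3, 4), 2)), "integer")
})

test_that("Fisher p equals enumeration and the reference implementation", {
  withr::with_seed(101, {
    for (i in 1:100) {
      tab <- matrix(rpois(4, 6) + 1L, 2)
      res <- fisher_exact_2x2(tab)
      expect_equal(res$p_value, fisher_p_enumeration(tab),
                   tolerance = 1e-12)
      expect_equal(res$p_value, stats::fisher.test(tab)$p.value,
                   tolerance = 1e-9)
    }
  })
})

test_that("effect-reduction comparison assembles the paired 2x2 table", {
  truth <- draw_study_truth(study_config(seed = 111))
  cmp <- compare_effect_reductions(truth, "sham")
  expect_s3_class(cmp, "effect_reduction_comparison")
  expect_equal(cmp$counts$n_total, c(27L, 27L))
  expect_equal(sum(cmp$fisher$table), 54)
  expect_gt(cmp$counts$n_reduced[1], cmp$counts$n_reduced[2])
})
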