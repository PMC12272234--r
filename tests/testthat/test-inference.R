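test_that("sign-error probability counts strictly opposite draws", {
  expect_equal(sign_error_probability(rep(1, 200)), 0)
  draws <- rep(c(-1, 1, 1, 1), 100)
  expect_equal(sign_error_probability(draws), 0.25)
  expect_equal(sign_error_probability(rep(c(-2, 2), 100)), 0.5)
  # zeros count toward neither side
  expect_equal(sign_error_probability(rep(c(1, 1, 0, -1), 100)), 0.25)
  # exactly-zero mean maps to 0.5 by convention
  expect_equal(sign_error_probability(rep(c(-3, 3), 60)), 0.5)
  expect_error(sign_error_probability(1:10), "at least 100")
})

test_that("sign-error probability respects scaling and negation symmetries", {
  set.seed(8)
  draws <- rnorm(500, 0.3, 1)
  pr <- sign_error_probability(draws)
  expect_equal(sign_error_probability(draws * 7.3), pr)
  expect_equal(sign_error_probability(-draws), pr)
})

test_that("summaries match normal-quantile oracles and the 0.025 rule", {
  set.seed(9)
  s <- summarize_draws(rnorm(2e5), "null")
  expect_equal(s$lower, qnorm(0.025), tolerance = 0.02)
  expect_equal(s$upper, qnorm(0.975), tolerance = 0.02)
  expect_equal(s$pr, 0.5, tolerance = 0.01)
  expect_false(s$significant)

  s2 <- summarize_draws(rep(0.3, 150), "const")
  expect_equal(unlist(s2[c("mean", "lower", "upper")]),
               c(mean = 0.3, lower = 0.3, upper = 0.3))
  expect_equal(s2$pr, 0)
  expect_true(s2$significant)

  # the threshold is strict: pr exactly 0.025 is not significant
  draws <- c(rep(-1, 25), rep(1, 975))
  s3 <- summarize_draws(draws, "edge")
  expect_equal(s3$pr, 0.025)
  expect_false(s3$significant)
})

test_that("contrasts are exactly linear in the anchored curve values", {
  tab <- small_design()
  m <- simulate_measures(tab, sn_trajectory(), seed = 4)
  fit <- quiet_fit(m)
  c_draws <- contrast(fit, 44, 32)
  expect_equal(c_draws, curve_at(fit, 44) - curve_at(fit, 32),
               tolerance = 1e-12)
  expect_equal(mean(contrast(fit, 40, 40)), 0)
  summ <- estimand_summaries(fit)
  expect_identical(nrow(summ), 8L)
  expect_equal(summ$mean[8], summ$mean[4] - summ$mean[1], tolerance = 1e-12)
  expect_error(curve_at(fit, 52), "outside")
})

test_that("covariate effects are recovered and require a covariate fit", {
  tab <- small_design()
  fit0 <- quiet_fit(simulate_measures(tab, sn_trajectory(), seed = 1))
  expect_error(covariate_effect(fit0), "without a covariate")

  gamma_true <- -0.05
  hits <- 0; est <- numeric(0)
  for (r in 1:12) {
    d <- simulate_design(study_design(), seed = 300 + r)
    m <- simulate_measures(d, sn_trajectory(), seed = 400 + r)
    subj <- unique(m$subject_id)
    set.seed(600 + r)
    x <- rnorm(length(subj))
    m$value <- m$value + gamma_true * x[match(m$subject_id, subj)]
    cov <- data.frame(subject_id = subj, pc1 = x)
    fit <- suppressWarnings(pspline_growth(value ~ pma_weeks, m,
                                           covariate = cov, chains = 2,
                                           warmup = 400, iter = 500,
                                           seed = r))
    s <- covariate_effect(fit)
    est <- c(est, s$mean)
    hits <- hits + (s$lower <= gamma_true && gamma_true <= s$upper)
  }
  expect_gte(hits, 10)           # ~95% nominal coverage over 12 fits
  expect_lt(mean(est), 0)
  # all-equal covariate is degenerate
  cov0 <- data.frame(subject_id = unique(tab$subject_id), pc1 = 1)
  expect_error(pspline_growth(value ~ pma_weeks,
                              simulate_measures(tab, sn_trajectory(),
                                                seed = 1),
                              covariate = cov0, seed = 1), "zero variance")
})

test_that("comparing a measure with itself is rejected as degenerate", {
  tab <- small_design()
  m <- simulate_measures(tab, sn_trajectory(), seed = 6)
  # the per-scan difference of a measure with itself is identically zero,
  # which leaves the model without any response variation
  expect_error(compare_measures(m, "intra_SN", "intra_SN",
                                chains = 2, warmup = 300, iter = 400,
                                seed = 2),
               "constant")
})

test_that("a growing trajectory gap between measures is recovered", {
  tab <- small_design(seed = 11)
  trA <- sn_trajectory()
  # second measure grows 0.10 less between 32 and 44 weeks
  trB <- true_trajectory(c(32, 36, 40, 44),
                         reference_anchors("intra_SN") -
                           c(0, 0.02, 0.06, 0.10))
  mA <- simulate_measures(tab, trA, seed = 21, measure = "A")
  mB <- simulate_measures(tab, trB, seed = 22, measure = "B")
  res <- suppressWarnings(compare_measures(rbind(mA, mB), "A", "B",
                                           chains = 2, warmup = 400,
                                           iter = 600, seed = 3))
  overall <- res$summaries[res$summaries$label == "(PMA = 44)-(PMA = 32)", ]
  expect_true(overall$lower <= 0.10 && 0.10 <= overall$upper)
})
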