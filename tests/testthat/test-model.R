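toy_data <- function() {
  set.seed(4)
  data.frame(subject_id = c("a", "a", "b", "b", "c"),
             cohort = c("f", "f", "f", "n", "n"),
             pma_weeks = c(31, 35, 33, 40, 42),
             value = rnorm(5, 0.1, 0.2))
}

toy_params <- function() {
  set.seed(14)
  list(beta = rnorm(17, 0, 0.1), tau = 0.3,
       delta = c(n = 0.05), sigma = c(f = 0.1, n = 0.12),
       a = c(a = 0.02, b = -0.01, c = 0.03),
       b = c(a = 0.001, b = 0, c = -0.002),
       sigma_a = 0.05, sigma_b = 0.01, gamma = 0.1)
}

naive_log_posterior <- function(pars, d, xcov = NULL, pr = growth_prior()) {
  B <- build_basis(d$pma_weeks)
  D <- second_difference_matrix(17)
  mu <- as.numeric(B %*% pars$beta) +
    ifelse(d$cohort == "f", 0, pars$delta["n"]) +
    pars$a[d$subject_id] + pars$b[d$subject_id] * (d$pma_weeks - 37)
  if (!is.null(pars$gamma) && !is.null(xcov))
    mu <- mu + pars$gamma * xcov[d$subject_id]
  hc <- function(x, s) log(2) + dcauchy(x, 0, s, log = TRUE)
  sum(dnorm(d$value, mu, pars$sigma[d$cohort], log = TRUE)) +
    sum(dnorm(as.numeric(D %*% pars$beta), 0, pars$tau, log = TRUE)) +
    sum(dnorm(pars$beta, 0, pr$coef_sd, log = TRUE)) +
    sum(dnorm(pars$delta, 0, pr$offset_sd, log = TRUE)) +
    (if (is.null(pars$gamma)) 0 else
      dnorm(pars$gamma, 0, pr$covariate_sd, log = TRUE)) +
    sum(dnorm(pars$a, 0, pars$sigma_a, log = TRUE)) +
    sum(dnorm(pars$b, 0, pars$sigma_b, log = TRUE)) +
    hc(pars$sigma_a, pr$sigma_a_scale) + hc(pars$sigma_b, pr$sigma_b_scale) +
    hc(pars$tau, pr$tau_scale) + sum(hc(pars$sigma, pr$sigma_scale))
}

test_that("log posterior matches an independent naive density sum", {
  d <- toy_data(); pars <- toy_params()
  xcov <- c(a = 0.5, b = -1.2, c = 0.7)
  lp <- log_posterior(pars, d, reference = "f", covariate = xcov)
  expect_true(is.finite(lp))
  expect_equal(lp, naive_log_posterior(pars, d, xcov), tolerance = 1e-10)
})

test_that("doubling a residual SD with zero residuals costs n log 2", {
  d <- toy_data()
  pars <- toy_params()
  pars$a[] <- 0; pars$b[] <- 0; pars$delta[] <- 0; pars$gamma <- NULL
  B <- build_basis(d$pma_weeks)
  d$value <- as.numeric(B %*% pars$beta)   # exact fit: residuals all zero
  p2 <- pars; p2$sigma["f"] <- 2 * pars$sigma["f"]
  lp1 <- log_posterior(pars, d, reference = "f")
  lp2 <- log_posterior(p2, d, reference = "f")
  hc <- function(x) log(2) + dcauchy(x, 0, 1, log = TRUE)
  n_f <- sum(d$cohort == "f")
  expect_equal(lp1 - lp2,
               n_f * log(2) + hc(pars$sigma["f"]) - hc(p2$sigma["f"]),
               ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("without a covariate term the density ignores covariate values", {
  d <- toy_data(); pars <- toy_params(); pars$gamma <- NULL
  lp1 <- log_posterior(pars, d, reference = "f",
                       covariate = c(a = 1, b = 2, c = 3))
  lp2 <- log_posterior(pars, d, reference = "f",
                       covariate = c(a = -9, b = 0, c = 4))
  expect_identical(lp1, lp2)
})

test_that("degenerate conjugate posterior matches the ridge closed form", {
  set.seed(2)
  n <- 60
  ages <- runif(n, 30, 44)
  dat <- data.frame(subject_id = paste0("s", 1:n), cohort = "fetal_neonatal",
                    pma_weeks = ages,
                    value = 0.1 + 0.01 * (ages - 37) + rnorm(n, 0, 0.05))
  fit <- suppressWarnings(pspline_growth(
    value ~ pma_weeks, dat, chains = 2, warmup = 300, iter = 2000, seed = 3,
    random_effects = FALSE, fix = list(tau = 50, sigma = 0.05)))
  B <- build_basis(dat$pma_weeks)
  D <- second_difference_matrix(17)
  A <- crossprod(B) / 0.05^2 + crossprod(D) / 50^2 + diag(1 / 100, 17)
  bhat <- solve(A, crossprod(B, dat$value) / 0.05^2)
  M <- do.call(rbind, fit$draws)
  bpost <- colMeans(M[, 1:17])
  mcse <- apply(M[, 1:17], 2, sd) / sqrt(nrow(M))  # draws are exact/iid here
  expect_lt(max(abs(bpost - drop(bhat)) / mcse), 3)
})

test_that("with an overwhelmed likelihood the flat directions recover the prior SD", {
  set.seed(6)
  dat <- data.frame(subject_id = paste0("s", 1:12), cohort = "fetal_neonatal",
                    pma_weeks = runif(12, 30, 44), value = rnorm(12))
  fit <- suppressWarnings(pspline_growth(
    value ~ pma_weeks, dat, chains = 2, warmup = 200, iter = 3000, seed = 7,
    random_effects = FALSE, fix = list(tau = 0.5, sigma = 1e6)))
  M <- do.call(rbind, fit$draws)[, 1:17]
  # null space of the penalty: curve level and slope
  D <- second_difference_matrix(17)
  ns <- svd(D, nv = 17)$v[, 16:17]
  for (k in 1:2) {
    s <- sd(M %*% ns[, k])
    expect_lt(abs(s - 10) / 10, 0.1)
  }
})

test_that("different seeds agree within Monte Carlo error", {
  tab <- small_design()
  m <- simulate_measures(tab, sn_trajectory(), seed = 3)
  f1 <- quiet_fit(m, seed = 101, iter = 600)
  f2 <- quiet_fit(m, seed = 202, iter = 600)
  for (a in c(32, 44)) {
    d1 <- curve_at(f1, a); d2 <- curve_at(f2, a)
    ess1 <- ess_chains(lapply(f1$draws, function(M)
      drop(M[, 1:17] %*% t(build_basis(a)))))
    ess2 <- ess_chains(lapply(f2$draws, function(M)
      drop(M[, 1:17] %*% t(build_basis(a)))))
    mcse <- sqrt(var(d1) / ess1 + var(d2) / ess2)
    expect_lt(abs(mean(d1) - mean(d2)), 3 * mcse)
  }
})

test_that("posterior summaries are invariant to relabelling and row order", {
  tab <- small_design()
  m <- simulate_measures(tab, sn_trajectory(), seed = 5)
  f0 <- quiet_fit(m, iter = 300, warmup = 200)
  # relabel subjects and shuffle rows; same data content
  m2 <- m
  map <- setNames(sprintf("zz_%03d", seq_along(unique(m$subject_id))),
                  sample(unique(m$subject_id)))
  m2$subject_id <- unname(map[m$subject_id])
  m2 <- m2[sample(nrow(m2)), ]
  f1 <- quiet_fit(m2, iter = 300, warmup = 200)
  expect_equal(estimand_summaries(f0), estimand_summaries(f1),
               tolerance = 1e-12)
})

test_that("tighter penalty priors give smoother posterior mean curves", {
  tab <- small_design()
  m <- simulate_measures(tab, sn_trajectory(), seed = 9)
  curv <- vapply(c(2, 0.2, 0.02), function(sc) {
    fit <- quiet_fit(m, prior = growth_prior(tau_scale = sc),
                     iter = 400, warmup = 300)
    M <- do.call(rbind, fit$draws)[, 1:17]
    mean(apply(M, 1, function(b)
      sum((second_difference_matrix(17) %*% b)^2)))
  }, numeric(1))
  expect_true(all(diff(curv) <= 1e-12))
})

test_that("short chains raise a convergence warning, not silent success", {
  tab <- small_design()
  m <- simulate_measures(tab, sn_trajectory(), seed = 2)
  expect_warning(
    pspline_growth(value ~ pma_weeks, m, chains = 2, warmup = 20, iter = 60,
                   seed = 1),
    class = "fcg_convergence_warning")
})

test_that("input validation catches malformed fits", {
  tab <- small_design()
  m <- simulate_measures(tab, sn_trajectory(), seed = 2)
  expect_error(pspline_growth(value ~ pma_weeks, m[1, ], seed = 1),
               "2 subjects")
  expect_error(pspline_growth(value ~ pma_weeks, m, reference = "nope",
                              seed = 1), "reference")
  m$value[3] <- NA
  expect_error(pspline_growth(value ~ pma_weeks, m, seed = 1), "non-finite")
})
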