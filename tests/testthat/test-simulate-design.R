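test_that("design simulation reproduces the scheduled visit structure", {
  d3 <- cohort_design("fetal_neonatal", 29,
                      list(c(31.2, 0.7), c(35.3, 0.8), c(43.4, 1.3)))
  tab <- simulate_design(list(d3), seed = 1)
  expect_identical(nrow(tab), 87L)
  expect_identical(length(unique(tab$subject_id)), 29L)
  expect_true(all(table(tab$subject_id) == 3))

  full <- simulate_design(study_design(), seed = 1)
  expect_identical(nrow(full), 142L)
  expect_identical(length(unique(full$subject_id)), 84L)
  expect_true(all(full$pma_weeks >= 28 & full$pma_weeks <= 48))
})

test_that("visit PMA draws follow the scheduled normals", {
  big <- cohort_design("fetal_neonatal", 600,
                       list(c(31.2, 0.7), c(35.3, 0.8), c(43.4, 1.3)))
  tab <- simulate_design(list(big), seed = 7)
  for (v in 1:3) {
    x <- tab$pma_weeks[tab$visit == v]
    mu <- c(31.2, 35.3, 43.4)[v]
    se <- c(0.7, 0.8, 1.3)[v] / sqrt(length(x))
    expect_lt(abs(mean(x) - mu), 3 * se)
  }
})

test_that("missingness drops visits and empty subjects", {
  d <- cohort_design("neonatal", 40, list(c(44.4, 1.3)),
                     missingness_rate = 0.999)
  tab <- simulate_design(list(d), seed = 3)
  # subjects who lost their only visit are absent, not left as empty rows
  expect_true(nrow(tab) < 5)
  expect_identical(nrow(tab), length(unique(tab$subject_id)))
  expect_error(simulate_design(list(), seed = 1), "empty")
})

test_that("same seed is bit-identical, different seeds differ", {
  a <- simulate_design(study_design(), seed = 42)
  b <- simulate_design(study_design(), seed = 42)
  c <- simulate_design(study_design(), seed = 43)
  expect_identical(a, b)
  expect_false(identical(a$pma_weeks, c$pma_weeks))
})

test_that("measure generator is exact in the noise-free limit", {
  tab <- small_design()
  tr <- sn_trajectory(sigma_a = 0, sigma_b = 0,
                      cohort_offsets = c(fetal_neonatal = 0, neonatal = 0,
                                         dhcp = 0),
                      cohort_sigmas = c(fetal_neonatal = 0, neonatal = 0,
                                        dhcp = 0))
  m <- simulate_measures(tab, tr, seed = 5)
  expect_equal(m$value, tr$f_true(m$pma_weeks), tolerance = 1e-12)
})

test_that("random intercepts are shared within subject", {
  tab <- data.frame(subject_id = c("s1", "s1"), cohort = "fetal_neonatal",
                    visit = 1:2, pma_weeks = c(31, 43))
  tab <- rbind(tab, data.frame(subject_id = "s2", cohort = "fetal_neonatal",
                               visit = 1, pma_weeks = 35))
  tr <- true_trajectory(c(30, 44), c(0, 0.3), sigma_a = 0.2, sigma_b = 0,
                        cohort_offsets = c(fetal_neonatal = 0),
                        cohort_sigmas = c(fetal_neonatal = 0))
  m <- simulate_measures(tab, tr, seed = 9)
  dev <- m$value - tr$f_true(m$pma_weeks)
  expect_equal(dev[1], dev[2], tolerance = 1e-12)   # same subject
  expect_false(isTRUE(all.equal(dev[1], dev[3])))   # different subject
})

test_that("group means near the anchors recover the anchor values", {
  n <- 500
  tab <- do.call(rbind, lapply(1:4, function(v)
    data.frame(subject_id = sprintf("s%03d", 1:n), cohort = "fetal_neonatal",
               visit = v, pma_weeks = c(32, 36, 40, 44)[v])))
  anchors <- c(-0.006, 0.001, 0.163, 0.283)
  tr <- true_trajectory(c(32, 36, 40, 44), anchors,
                        sigma_a = 0.05, sigma_b = 0.01,
                        cohort_offsets = c(fetal_neonatal = 0),
                        cohort_sigmas = c(fetal_neonatal = 0.1))
  m <- simulate_measures(tab, tr, seed = 21)
  for (v in 1:4) {
    x <- m$value[m$visit == v]
    expect_lt(abs(mean(x) - anchors[v]), 3 * sd(x) / sqrt(n))
  }
})

test_that("cohorts without generator parameters are rejected", {
  tab <- small_design()
  tr <- true_trajectory(c(30, 44), c(0, 0.3),
                        cohort_offsets = c(fetal_neonatal = 0),
                        cohort_sigmas = c(fetal_neonatal = 0.1))
  expect_error(simulate_measures(tab, tr, seed = 1), "no offset/sigma")
})

test_that("trajectory validation enforces its invariants", {
  expect_error(true_trajectory(c(36, 32), c(0, 1)), "strictly increasing")
  expect_error(true_trajectory(c(32, 36), c(0, 1), sigma_a = -1), ">= 0")
  expect_error(true_trajectory(c(32, 36), c(0, 1),
                               cohort_offsets = c(a = 0.1),
                               cohort_sigmas = c(a = 1)),
               "reference")
})
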