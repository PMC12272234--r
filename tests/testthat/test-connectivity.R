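test_that("frame censoring applies pooled 1-SD thresholds", {
  # constant metrics: SD = 0, non-strict comparisons keep everything
  qc <- data.frame(snr = rep(100, 6), reg_quality = rep(0.9, 6),
                   motion = rep(0.05, 6))
  expect_true(all(censor_frames(qc)))

  # one frame with motion far above the rest is the only one dropped
  set.seed(4)
  motion <- c(rnorm(9, 0.05, 0.005), NA)
  motion[10] <- mean(motion[1:9]) + 2 * sd(motion[1:9])
  qc <- data.frame(snr = rep(100, 10), reg_quality = rep(0.9, 10),
                   motion = motion)
  keep <- censor_frames(qc)
  # brute-force oracle on the 10-frame vector
  oracle <- motion <= mean(motion) + sd(motion)
  expect_identical(keep, oracle)
  expect_false(keep[10])

  qc$motion[3] <- NaN
  expect_error(censor_frames(qc), "frame\\(s\\) 3")
})

test_that("a scan with every frame censored is flagged unusable", {
  qc <- data.frame(snr = c(0, 100, 100), reg_quality = c(1, 0, 1),
                   motion = c(5, 0, 12))
  expect_error(censor_frames(qc), class = "fcg_unusable_scan")
})

test_that("run exclusion is strict at 0.2 mm and idempotent", {
  keep <- exclude_runs(c(0.05, 0.19, 0.21))
  expect_equal(keep, c(TRUE, TRUE, FALSE))
  expect_true(all(exclude_runs(c(0.2, 0.1))))      # boundary kept
  expect_error(exclude_runs(c(0.3, 0.25)), class = "fcg_unusable_scan")
  # applying the rule to the retained runs changes nothing
  ffd <- c(0.05, 0.19, 0.21)
  retained <- ffd[exclude_runs(ffd)]
  expect_true(all(exclude_runs(retained)))
})

test_that("confound regression projects exactly", {
  n <- 120
  conf <- drift_confounds(n)
  set.seed(1)
  noise <- matrix(rnorm(n * 2), n, 2)
  series <- 3 * conf[, "linear"] + noise
  res <- regress_confounds(series, conf)
  expect_lt(max(abs(crossprod(conf, res))) / max(abs(series)), 1e-8)

  # already-orthogonal input is returned unchanged
  ortho <- qr.resid(qr(conf), noise)
  expect_equal(regress_confounds(ortho, conf), ortho, tolerance = 1e-10)

  expect_error(regress_confounds(series[1:3, ], conf[1:3, ]),
               "unidentifiable")
  bad <- cbind(conf, linear2 = conf[, "linear"])
  expect_error(regress_confounds(series, bad), "linear2")
})

test_that("temporal smoothing halves amplitude at the cutoff frequency", {
  tr <- 1.95
  t <- (0:599) * tr
  x <- sin(2 * pi * 0.12 * t)
  y <- temporal_smooth(x, tr)
  mid <- 100:500  # avoid edges
  expect_equal(sd(y[mid]) / sd(x[mid]), 0.5, tolerance = 0.05)

  expect_equal(temporal_smooth(rep(2.5, 80), tr), rep(2.5, 80))
  set.seed(2)
  wn <- rnorm(3000)
  expect_lt(var(temporal_smooth(wn, tr)), var(wn))
  expect_error(temporal_smooth(wn, tr, cutoff_hz = 0.3), "Nyquist")
})

test_that("seed time courses are voxel means", {
  set.seed(3)
  V <- matrix(rnorm(50 * 5), 50, 5)
  expect_equal(seed_timecourse(V, 2), V[, 2])
  expect_equal(seed_timecourse(cbind(V[, 1], -V[, 1]), 1:2), rep(0, 50))
  expect_equal(seed_timecourse(V, 1:5), rowMeans(V))
  expect_error(seed_timecourse(V, integer(0)), "no voxels")
})

test_that("Fisher z matrix matches the atanh oracle", {
  # construct an exact empirical correlation of 0.5
  set.seed(5)
  n <- 200
  x <- scale(rnorm(n))
  zres <- scale(qr.resid(qr(cbind(1, x)), rnorm(n)))
  y <- 0.5 * x + sqrt(0.75) * zres
  Z <- fisher_z_matrix(cbind(a = drop(x), b = drop(y)))
  expect_equal(Z["a", "b"], atanh(0.5), tolerance = 1e-10)
  expect_true(is.na(Z["a", "a"]))

  # independent long series: z near zero at the null scale
  X <- simulate_timeseries(4000, diag(2), seed = 6)
  Z0 <- fisher_z_matrix(X)
  expect_lt(abs(Z0[1, 2]), 3 / sqrt(4000 - 3))

  v <- rnorm(30)
  expect_error(fisher_z_matrix(cbind(v, 2 * v + 1)), "perfectly correlated")
  expect_error(fisher_z_matrix(cbind(k = rep(1, 30), v)), "zero-variance")
  expect_error(fisher_z_matrix(X[1:3, ]), "at least 4")
})

test_that("network strengths equal brute-force pair enumeration", {
  nets <- default_networks()
  nodes <- unlist(lapply(nets, `[[`, "nodes"), use.names = FALSE)
  X <- simulate_timeseries(300, diag(11), seed = 7)
  colnames(X) <- nodes
  Z <- fisher_z_matrix(X)

  pairs_dmn <- brute_force_pairs(nets$DMN$nodes)
  expect_identical(nrow(pairs_dmn), 6L)
  expect_equal(network_strength(Z, nets$DMN),
               mean(Z[pairs_dmn]))
  pairs_sn <- brute_force_pairs(nets$SN$nodes)
  expect_identical(nrow(pairs_sn), 3L)
  expect_equal(network_strength(Z, nets$SN), mean(Z[pairs_sn]))
  cross <- brute_force_pairs(nets$DMN$nodes, nets$SN$nodes)
  expect_identical(nrow(cross), 12L)
  expect_equal(network_strength(Z, nets$DMN, nets$SN), mean(Z[cross]))
  expect_identical(nrow(brute_force_pairs(nets$DMN$nodes, nets$FPN$nodes)),
                   16L)

  # constant z-matrix: strength equals the constant
  Zc <- matrix(0.21, 11, 11, dimnames = list(nodes, nodes))
  diag(Zc) <- NA
  expect_equal(network_strength(Zc, nets$FPN), 0.21)
  expect_error(network_strength(Z[1:8, 1:8], nets$SN), "lacks node")
})

test_that("strengths are invariant to node column order", {
  nets <- default_networks()
  nodes <- unlist(lapply(nets, `[[`, "nodes"), use.names = FALSE)
  X <- simulate_timeseries(250, diag(11), seed = 9)
  colnames(X) <- nodes
  base <- fisher_z_matrix(X)
  for (s in 1:3) {
    set.seed(s)
    perm <- sample(11)
    Zp <- fisher_z_matrix(X[, perm])
    for (nm in names(nets))
      expect_equal(network_strength(Zp, nets[[nm]]),
                   network_strength(base, nets[[nm]]))
    expect_equal(network_strength(Zp, nets$DMN, nets$FPN),
                 network_strength(base, nets$DMN, nets$FPN))
  }
})

test_that("difference measures subtract per scan and report omissions", {
  tab <- data.frame(subject_id = rep(c("s1", "s2"), each = 2),
                    cohort = "fetal_neonatal",
                    pma_weeks = rep(c(32, 32), each = 2),
                    measure = rep(c("intra_DMN", "intra_SN"), 2),
                    value = c(0.14, 0.28, 0.10, 0.05))
  d <- difference_measure(tab, "intra_DMN", "intra_SN")
  expect_equal(sort(d$value), sort(c(0.14 - 0.28, 0.10 - 0.05)))
  expect_identical(attr(d, "omitted"), 0L)

  same <- difference_measure(tab, "intra_DMN", "intra_DMN")
  expect_true(all(same$value == 0))

  # 2 of 5 scans lack the second measure
  tab5 <- data.frame(subject_id = paste0("s", 1:5), cohort = "neonatal",
                     pma_weeks = 40 + 1:5, measure = "intra_DMN",
                     value = 0.1)
  tab5 <- rbind(tab5, within(tab5[1:3, ], measure <- "intra_SN"))
  d5 <- difference_measure(tab5, "intra_DMN", "intra_SN")
  expect_identical(nrow(d5), 3L)
  expect_identical(attr(d5, "omitted"), 2L)
  expect_error(difference_measure(tab5, "intra_DMN", "nope"),
               "unknown measure")
})

test_that("the scan pipeline produces six measures per usable scan", {
  design <- simulate_design(list(cohort_design("neonatal", 3,
                                               list(c(44.4, 1.3)))),
                            seed = 1)
  trajs <- lapply(stats::setNames(nm = c("intra_DMN", "intra_FPN", "intra_SN",
                                         "inter_DMN_FPN", "inter_DMN_SN",
                                         "inter_FPN_SN")),
                  function(m) true_trajectory(c(32, 44),
                                              rep(reference_anchors(m)[4], 2),
                                              cohort_offsets = c(neonatal = 0),
                                              cohort_sigmas = c(neonatal = 0.05)))
  scans <- simulate_scans(design, trajs, seed = 2, n_runs = 2,
                          frames_per_run = 120)
  tab <- compute_measure_table(scans, min_retained_frames = 50)
  expect_identical(nrow(tab), 18L)  # 3 scans x 6 measures
  expect_setequal(unique(tab$measure), names(trajs))
  rep <- attr(tab, "qc_report")
  expect_true(rep$frames_total > 0)
  expect_true(is.list(rep$scans_omitted))
})
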