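# Shared fixtures: small designs, trajectories and fits reused across tests.

small_design <- function(seed = 7) {
  simulate_design(list(
    cohort_design("fetal_neonatal", 12,
                  list(c(31.2, 0.7), c(35.3, 0.8), c(43.4, 1.3))),
    cohort_design("neonatal", 8, list(c(44.4, 1.3))),
    cohort_design("dhcp", 6, list(c(40.2, 2.1)))), seed = seed)
}

sn_trajectory <- function(...) {
  true_trajectory(c(32, 36, 40, 44), reference_anchors("intra_SN"), ...)
}

quiet_fit <- function(data, ..., chains = 2, warmup = 300, iter = 400,
                      seed = 1) {
  suppressWarnings(pspline_growth(value ~ pma_weeks, data, chains = chains,
                                  warmup = warmup, iter = iter, seed = seed,
                                  ...))
}

# Independent brute-force lister of network pairs, used as the oracle
# against network_strength's internal enumeration.
brute_force_pairs <- function(nodes_a, nodes_b = NULL) {
  out <- NULL
  if (is.null(nodes_b)) {
    for (i in seq_along(nodes_a)) for (j in seq_along(nodes_a))
      if (i < j) out <- rbind(out, c(nodes_a[i], nodes_a[j]))
  } else {
    for (x in nodes_a) for (y in nodes_b) out <- rbind(out, c(x, y))
  }
  out
}
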