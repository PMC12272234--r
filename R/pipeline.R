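# End-to-end orchestration: simulate -> connectivity -> composite -> fit ->
# report, with a YAML config, result tables, plots, and a JSON run manifest.

#' Render an anchored results table
#'
#' Formats the eight-estimand summary of one measure in the standard layout:
#' rows ordered PMA 32, 36, 40, 44 then the four changes (32-36, 36-40,
#' 40-44, 32-44), columns Mean / Lower / Upper / pr, values rounded to 3
#' decimals for display.
#'
#' @param summaries data.frame from \code{\link{estimand_summaries}} (8
#'   rows).
#' @return data.frame with \code{quantity}, \code{mean}, \code{lower},
#'   \code{upper}, \code{pr}, rounded to 3 decimals.
#' @export
render_table <- function(summaries) {
  expected <- c("PMA = 32", "PMA = 36", "PMA = 40", "PMA = 44",
                "(PMA = 36)-(PMA = 32)", "(PMA = 40)-(PMA = 36)",
                "(PMA = 44)-(PMA = 40)", "(PMA = 44)-(PMA = 32)")
  miss <- setdiff(expected, summaries$label)
  if (length(miss))
    stop("missing estimand(s): ", paste(miss, collapse = "; "))
  rows <- summaries[match(expected, summaries$label), ]
  data.frame(quantity = rows$label,
             mean = round(rows$mean, 3), lower = round(rows$lower, 3),
             upper = round(rows$upper, 3), pr = round(rows$pr, 3),
             stringsAsFactors = FALSE)
}

#' Write / read a long measure table as CSV
#'
#' @param table Long measure table.
#' @param path CSV path.
#' @return \code{read_measure_table} returns the data.frame.
#' @export
write_measure_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_measure_table
#' @export
read_measure_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Default demo configuration
#'
#' A complete pipeline configuration emulating the three-cohort study with
#' the reference anchor trajectories for all six measures. Sampler settings
#' are modest so the demo completes quickly; raise them for production-grade
#' posterior summaries.
#'
#' @param measures Measures to analyse.
#' @param timeseries Generate node time series and derive the measures
#'   through the connectivity pipeline (\code{TRUE}), or draw measure values
#'   directly from the hierarchical generator (\code{FALSE}, faster).
#' @return Nested configuration list, YAML-serializable.
#' @export
demo_config <- function(measures = c("intra_DMN", "intra_FPN", "intra_SN",
                                     "inter_DMN_FPN", "inter_DMN_SN",
                                     "inter_FPN_SN"),
                        timeseries = FALSE) {
  list(
    seed = 20240101,
    simulate = list(
      timeseries = timeseries,
      n_runs = 3, frames_per_run = 150, tr_seconds = 1.95,
      outlier_rate = 0.03,
      noise = list(sigma_a = 0.05, sigma_b = 0.01,
                   offsets = list(fetal_neonatal = 0, neonatal = 0.02,
                                  dhcp = -0.02),
                   sigmas = list(fetal_neonatal = 0.10, neonatal = 0.08,
                                 dhcp = 0.08))),
    measures = measures,
    composite = list(enabled = TRUE, var_explained_target = 0.73),
    model = list(chains = 2, warmup = 500, iter = 500, thin = 1),
    report = list(anchors = c(32, 36, 40, 44)))
}

config_trajectory <- function(cfg, measure) {
  nz <- cfg$simulate$noise
  true_trajectory(c(32, 36, 40, 44), reference_anchors(measure),
                  sigma_a = nz$sigma_a, sigma_b = nz$sigma_b,
                  cohort_offsets = unlist(nz$offsets),
                  cohort_sigmas = unlist(nz$sigmas))
}

validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML path.")
  need <- c("seed", "simulate", "measures", "model")
  miss <- setdiff(need, names(config))
  if (length(miss))
    stop("config lacks field(s): ", paste(miss, collapse = ", "))
  known_measures <- c("intra_DMN", "intra_FPN", "intra_SN",
                      "inter_DMN_FPN", "inter_DMN_SN", "inter_FPN_SN")
  bad <- setdiff(config$measures, known_measures)
  if (length(bad)) stop("unknown measure(s): ", paste(bad, collapse = ", "))
  if (!is.null(config$simulate$designs)) {
    ok <- c("fetal_neonatal", "neonatal", "dhcp")
    bad <- setdiff(vapply(config$simulate$designs, `[[`, "", "cohort"), ok)
    if (length(bad)) stop("unknown cohort(s): ", paste(bad, collapse = ", "))
  }
  config
}

#' Run the full analysis pipeline
#'
#' Executes simulate (design, measures or time series, mental health) ->
#' connectivity (when time series are generated) -> composite -> model fits
#' -> anchored reports, writing per-measure result tables (CSV), trajectory
#' plots (PNG), full-precision summaries (JSON) and a run manifest to
#' \code{out_dir}. All randomness derives from \code{config$seed}, so a
#' rerun with the same config reproduces every CSV bit for bit.
#'
#' @param config Configuration list or YAML path; see
#'   \code{\link{demo_config}}.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the measure table, per-measure summaries
#'   and the manifest.
#' @export
run_pipeline <- function(config = demo_config(), out_dir = tempfile("fcg_")) {
  config <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- derive_seeds(config$seed, 4 + 2 * length(config$measures))
  warnings_log <- character()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  designs <- stage("design", {
    if (is.null(config$simulate$designs)) study_design()
    else lapply(config$simulate$designs, function(d)
      cohort_design(d$cohort, d$n_subjects,
                    lapply(d$visits, unlist),
                    d$missingness %||% 0))
  })
  design_tab <- stage("design", simulate_design(designs, seeds[1]))

  trajectories <- lapply(stats::setNames(nm = config$measures),
                         function(m) config_trajectory(config, m))

  measure_tab <- stage("measures", {
    if (isTRUE(config$simulate$timeseries)) {
      all_traj <- lapply(stats::setNames(nm = c("intra_DMN", "intra_FPN",
                                                "intra_SN", "inter_DMN_FPN",
                                                "inter_DMN_SN",
                                                "inter_FPN_SN")),
                         function(m) config_trajectory(config, m))
      scans <- simulate_scans(design_tab, all_traj, seeds[2],
                              n_runs = config$simulate$n_runs,
                              frames_per_run = config$simulate$frames_per_run,
                              tr_seconds = config$simulate$tr_seconds,
                              outlier_rate = config$simulate$outlier_rate)
      tab <- compute_measure_table(scans)
      tab[tab$measure %in% config$measures, ]
    } else {
      ms <- derive_seeds(seeds[2], length(config$measures))
      do.call(rbind, lapply(seq_along(config$measures), function(i)
        simulate_measures(design_tab, trajectories[[i]], ms[i],
                          measure = config$measures[i])))
    }
  })
  write_measure_table(measure_tab, file.path(out_dir, "measures.csv"))

  covariate <- NULL; pc1 <- NULL
  if (isTRUE(config$composite$enabled)) {
    pc1 <- stage("composite", {
      n_fet <- sum(vapply(designs, function(d)
        if (d$cohort_name == "fetal_neonatal") d$n_subjects else 0L,
        numeric(1)))
      mh <- simulate_mental_health(
        max(n_fet, 5),
        var_explained_target = config$composite$var_explained_target %||% 0.73,
        seed = seeds[3])
      utils::write.csv(mh, file.path(out_dir, "mental_health.csv"),
                       row.names = FALSE)
      compute_pc1(mh)
    })
    covariate <- pc1_covariate(pc1)
    utils::write.csv(covariate, file.path(out_dir, "pc1_scores.csv"),
                     row.names = FALSE)
  }

  mdl <- config$model
  results <- list(); files <- c("measures.csv")
  for (i in seq_along(config$measures)) {
    m <- config$measures[i]
    sub <- measure_tab[measure_tab$measure == m, ]
    fit <- stage(paste0("fit:", m), withCallingHandlers(
      pspline_growth(value ~ pma_weeks, sub,
                     chains = mdl$chains, warmup = mdl$warmup,
                     iter = mdl$iter, thin = mdl$thin %||% 1,
                     seed = seeds[4 + i]),
      fcg_convergence_warning = function(w) {
        warnings_log <<- c(warnings_log,
                           paste0(m, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      }))
    summ <- estimand_summaries(fit,
                               anchors = config$report$anchors %||%
                                 c(32, 36, 40, 44))
    tab <- render_table(summ)
    f_csv <- sprintf("table_%s.csv", m)
    utils::write.csv(tab, file.path(out_dir, f_csv), row.names = FALSE)
    f_png <- sprintf("trajectory_%s.png", m)
    grDevices::png(file.path(out_dir, f_png), width = 900, height = 650)
    plot(fit, main = m)
    grDevices::dev.off()
    files <- c(files, f_csv, f_png)
    results[[m]] <- list(summaries = summ, diagnostics = fit$diagnostics)
  }

  # covariate-extended fits: association between the composite and each
  # intranetwork measure, estimated on the cohort with mental-health data
  if (!is.null(covariate)) {
    intra <- grep("^intra_", config$measures, value = TRUE)
    nm0 <- 4 + length(config$measures)
    cov_rows <- lapply(seq_along(intra), function(i) {
      m <- intra[i]
      sub <- measure_tab[measure_tab$measure == m, ]
      fit_c <- withCallingHandlers(
        pspline_growth(value ~ pma_weeks, sub, covariate = covariate,
                       chains = mdl$chains, warmup = mdl$warmup,
                       iter = mdl$iter, thin = mdl$thin %||% 1,
                       seed = seeds[nm0 + i]),
        fcg_convergence_warning = function(w) invokeRestart("muffleWarning"))
      cbind(measure = m, covariate_effect(fit_c))
    })
    if (length(cov_rows)) {
      utils::write.csv(do.call(rbind, cov_rows),
                       file.path(out_dir, "covariate_effects.csv"),
                       row.names = FALSE)
      files <- c(files, "covariate_effects.csv")
    }
  }

  jsonlite::write_json(
    lapply(results, function(r) r["summaries"]),
    file.path(out_dir, "summaries.json"), auto_unbox = TRUE, digits = NA)
  files <- c(files, "summaries.json",
             if (!is.null(pc1)) c("mental_health.csv", "pc1_scores.csv"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("fcgrowth")),
    r_version = R.version.string,
    seed = config$seed,
    config = config,
    files = files,
    input_md5 = as.list(tools::md5sum(file.path(out_dir, "measures.csv"))),
    convergence_warnings = warnings_log,
    counts = list(n_scans = length(unique(paste(measure_tab$subject_id,
                                                measure_tab$pma_weeks))),
                  n_subjects = length(unique(measure_tab$subject_id))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(measures = measure_tab, results = results,
                 manifest = manifest, out_dir = out_dir))
}
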