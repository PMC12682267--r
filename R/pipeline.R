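# End-to-end orchestration: simulate -> analyze -> stats, with a single
# config object, per-cell exclusion logging and CSV/report output.

#' Default pipeline run configuration
#'
#' Collects every tunable analysis decision in one place, with the
#' documented defaults: QC thresholds, detector parameters, block-histogram
#' parameters, response-classifier parameters, I/O-curve parameters, and
#' the declared comparison families for multiple-testing correction.
#'
#' @param simulation a [cohort_config()] (used by [run_simulate()]).
#' @param seed default RNG seed.
#' @return nested config list.
#' @export
default_config <- function(simulation = cohort_config(n_fi_cells = 6,
                                                      n_psp_cells = 12,
                                                      n_washon_cells = 9),
                           seed = 1) {
  list(
    simulation = simulation,
    seed = seed,
    qc = list(ra_max_MOhm = 30, require_continuous_trains = TRUE),
    detector = list(dvdt_threshold_mV_per_ms = 20,
                    min_peak_prominence_mV = 10, refractory_ms = 1),
    block = list(bin_width_mV = 2, min_separation_mV = 10, smooth_bins = 3),
    classifier = list(k_sd = 3, floor_mV = 0.3,
                      window_after_offset_ms = 300, smooth_ms = 5,
                      baseline_window_ms = 100),
    io = list(min_cells = 3),
    families = list(paired_light = TRUE, subtype_unpaired = TRUE,
                    response_distributions = TRUE, io_anova = TRUE,
                    washon = TRUE)
  )
}

#' Simulate a cohort to disk
#'
#' Thin wrapper over [generate_cohort()] that writes the bundle, the
#' ground-truth sidecar and a manifest of the seeds and parameters used.
#'
#' @param config pipeline config (see [default_config()]).
#' @param out_dir output directory for the bundle.
#' @param seed overrides `config$seed` when given.
#' @return the [generate_cohort()] result, invisibly.
#' @export
run_simulate <- function(config = default_config(), out_dir,
                         seed = NULL) {
  seed <- seed %||% config$seed
  if (is.null(config$simulation)) {
    parameter_error("config has no `simulation` section")
  }
  res <- generate_cohort(config$simulation, seed = seed, path = out_dir)
  jsonlite::write_json(list(seed = seed, simulation = config$simulation),
                       file.path(out_dir, "simulation_manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(res)
}

#' Analyze a cohort end to end
#'
#' Runs QC, feature extraction, block detection, I/O-curve construction and
#' response classification over a bundle (or an in-memory cell list), and
#' optionally writes every stage's table as CSV plus an exclusion log.
#' An empty input yields an empty (but valid) result, not an error.
#'
#' @param input bundle directory or list of [cell_recording()] objects.
#' @param config pipeline config.
#' @param out_dir optional output directory for CSV export.
#' @return list of class `msn_analysis`: `features`, `block` (per cell and
#'   condition), `io_first_spike`, `io_max_current`, `io_table_max_current`,
#'   `calls`, `washon`, `deltas` (latency/ISI at low and high
#'   depolarization), `exclusions`, `qc`.
#' @export
run_analyze <- function(input, config = default_config(), out_dir = NULL) {
  cells <- if (is.character(input)) read_sweep_bundle(input) else input
  det <- config$detector

  qc <- qc_filter(cells, ra_max_MOhm = config$qc$ra_max_MOhm,
                  require_continuous_trains = config$qc$require_continuous_trains,
                  dvdt_threshold_mV_per_ms = det$dvdt_threshold_mV_per_ms,
                  min_peak_prominence_mV = det$min_peak_prominence_mV,
                  refractory_ms = det$refractory_ms)
  cells <- qc$kept

  has_fi <- vapply(cells, function(c) length(fi_sweeps(c, "no_light")) > 0,
                   logical(1))
  fi_cells <- cells[has_fi]
  psp_cells <- cells[!has_fi]

  features <- if (length(fi_cells)) {
    do.call(rbind, lapply(fi_cells, cell_feature_table,
                          dvdt_threshold_mV_per_ms = det$dvdt_threshold_mV_per_ms,
                          min_peak_prominence_mV = det$min_peak_prominence_mV,
                          refractory_ms = det$refractory_ms))
  } else data.frame()

  blocks <- list()
  for (cell in fi_cells) {
    for (cond in c("no_light", "light")) {
      br <- tryCatch(
        detect_block_sweep(cell, cond,
                           bin_width_mV = config$block$bin_width_mV,
                           min_separation_mV = config$block$min_separation_mV,
                           smooth_bins = config$block$smooth_bins),
        error = function(e) NULL)
      if (!is.null(br)) {
        blocks[[length(blocks) + 1L]] <- data.frame(
          cell_id = cell$cell_id, condition = cond,
          lower_peak_mV = br$lower_peak_mV, upper_peak_mV = br$upper_peak_mV,
          block_sweep_index = br$block_sweep_index, bimodal = br$bimodal)
      }
    }
  }
  blocks <- if (length(blocks)) do.call(rbind, blocks) else data.frame()

  io_fs <- if (length(fi_cells)) {
    build_io_curve(fi_cells, "first_spike_anchor",
                   min_cells = config$io$min_cells, features = features)
  } else data.frame()
  io_mc <- if (length(fi_cells)) {
    build_io_curve(fi_cells, "max_current_anchor",
                   min_cells = config$io$min_cells, features = features)
  } else data.frame()
  io_tab <- if (length(fi_cells)) {
    io_curve_table(fi_cells, "max_current_anchor", features = features)
  } else data.frame()

  deltas <- list()
  excl <- list(qc = qc$discarded)
  if (length(fi_cells)) {
    for (cmp in list(c("latency_ms", "low_depol"),
                      c("mean_isi_ms", "low_depol"),
                      c("latency_ms", "high_depol"),
                      c("mean_isi_ms", "high_depol"),
                      c("frequency_hz", "high_depol"))) {
      d <- paired_deltas(fi_cells, feature = cmp[1], state = cmp[2],
                         features = features)
      deltas[[paste(cmp, collapse = "_")]] <- d
      excl[[paste(cmp, collapse = "_")]] <- attr(d, "exclusions")
    }
  }

  calls <- list()
  washon_cells <- list()
  for (cell in psp_cells) {
    tagged <- any(vapply(cell$sweeps, function(s)
      any(c("cgp_pre", "cgp_post") %in% s$pharmacology), logical(1)))
    if (tagged) {
      washon_cells[[length(washon_cells) + 1L]] <- cell
      next
    }
    groups <- split(cell$sweeps, vapply(cell$sweeps, function(s)
      paste(s$protocol$kind, s$protocol$pulse_duration_ms,
            s$protocol$n_pulses), character(1)))
    for (g in groups) {
      calls[[length(calls) + 1L]] <- classify_response(
        g, k_sd = config$classifier$k_sd,
        floor_mV = config$classifier$floor_mV,
        window_after_offset_ms = config$classifier$window_after_offset_ms,
        smooth_ms = config$classifier$smooth_ms,
        baseline_window_ms = config$classifier$baseline_window_ms)
    }
  }
  washon <- if (length(washon_cells)) washon_effect(washon_cells) else
    data.frame()

  res <- list(features = features, block = blocks,
              io_first_spike = io_fs, io_max_current = io_mc,
              io_table_max_current = io_tab,
              calls = calls, washon = washon, deltas = deltas,
              exclusions = excl, qc = qc,
              n_cells = length(cells))
  class(res) <- "msn_analysis"

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(x, f) if (length(x) && nrow(as.data.frame(x)))
      utils::write.csv(as.data.frame(x), file.path(out_dir, f),
                       row.names = FALSE)
    wr(features, "features.csv")
    wr(blocks, "block_results.csv")
    wr(io_fs, "io_curve_first_spike.csv")
    wr(io_mc, "io_curve_max_current.csv")
    if (length(calls)) wr(calls_table(calls), "response_calls.csv")
    wr(washon, "washon.csv")
    for (nm in names(deltas)) wr(deltas[[nm]], paste0("deltas_", nm, ".csv"))
    ex <- do.call(rbind, lapply(names(excl), function(nm) {
      e <- excl[[nm]]
      if (!nrow(e)) return(NULL)
      cbind(stage = nm, e)
    }))
    if (!is.null(ex)) wr(ex, "exclusions.csv")
  }
  res
}

#' Run the declared statistical comparison families
#'
#' Applies the study's statistics to an analysis result: paired Wilcoxon
#' signed-rank tests on the light/no-light deltas (with a Bonferroni
#' correction across the family), a two-way OLS ANOVA on the
#' max-current-aligned I/O table, a chi-squared test on the response-class
#' distributions across protocols, and a paired Wilcoxon test on the
#' wash-on deltas. Only families declared in `config$families` are run.
#'
#' @param analysis an `msn_analysis` from [run_analyze()].
#' @param config pipeline config.
#' @param out_dir optional directory for a key-value run report.
#' @return named list of `stat_result` objects (and the ANOVA sub-list).
#' @export
run_stats <- function(analysis, config = default_config(), out_dir = NULL) {
  stopifnot(inherits(analysis, "msn_analysis"))
  fam <- config$families
  out <- list()

  if (isTRUE(fam$paired_light) && length(analysis$deltas)) {
    family <- Filter(function(d) nrow(d) > 0, analysis$deltas)
    m <- length(family)
    for (nm in names(family)) {
      d <- family[[nm]]
      r <- wilcoxon_signed_rank(d$value_light, d$value_no_light)
      r$correction <- sprintf("bonferroni(%d)", m)
      r$adjusted_p <- bonferroni(r$p_value, m)
      out[[paste0("wilcoxon_", nm)]] <- r
    }
  }

  if (isTRUE(fam$io_anova) && length(analysis$io_table_max_current) &&
      nrow(analysis$io_table_max_current)) {
    out$anova <- tryCatch(
      suppressWarnings(anova_io_curves(analysis$io_table_max_current)),
      error = function(e) NULL)
  }

  if (isTRUE(fam$response_distributions) && length(analysis$calls)) {
    tab <- calls_table(analysis$calls)
    ct <- table(tab$protocol_label, tab$class)
    ct <- ct[, colSums(ct) > 0, drop = FALSE]
    if (nrow(ct) >= 2 && ncol(ct) >= 2) {
      out$response_chi_squared <- tryCatch(
        chi_squared_independence(as.matrix(ct)),
        error = function(e) NULL)
    }
  }

  if (isTRUE(fam$washon) && length(analysis$washon) &&
      nrow(analysis$washon)) {
    out$washon_wilcoxon <- wilcoxon_signed_rank(analysis$washon$delta_pre,
                                                analysis$washon$delta_post)
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    lines <- character()
    flat <- function(r, nm) {
      sprintf("%s\tstatistic=%g\tp=%g\tadjusted_p=%g\tn=%s",
              nm, r$statistic, r$p_value, r$adjusted_p,
              paste(r$n, collapse = ","))
    }
    for (nm in names(out)) {
      r <- out[[nm]]
      if (inherits(r, "stat_result")) {
        lines <- c(lines, flat(r, nm))
      } else if (is.list(r)) {
        for (sub in names(r)) lines <- c(lines, flat(r[[sub]],
                                                     paste(nm, sub, sep = ".")))
      }
    }
    writeLines(lines, file.path(out_dir, "stat_report.tsv"))
  }
  out
}
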