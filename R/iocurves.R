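# Paired light/no-light input-output curves and the designated-sweep
# paired comparisons.
#
# Measurements without and with optogenetic stimulation always come from
# the same current step, so every comparison is paired by construction.

#' Per-sweep feature table for a cell's current-step protocol
#'
#' Runs detection, geometry extraction and train summarization over every
#' current-step sweep of a cell and returns one row per (condition, step).
#' `step_index` is the ordinal of the step within the amplitude-ordered
#' series (shared between conditions of a pair).
#'
#' @param cell a [cell_recording()].
#' @param ... passed to [detect_aps()].
#' @return data.frame with `cell_id`, `subtype`, `step_index`,
#'   `step_amplitude_pA`, `condition` and the [train_features()] columns.
#' @export
cell_feature_table <- function(cell, ...) {
  rows <- list()
  for (cond in c("no_light", "light")) {
    sw <- fi_sweeps(cell, cond)
    for (i in seq_along(sw)) {
      s <- sw[[i]]
      aps <- extract_ap_features(s, detect_aps(s, ...))
      tf <- train_features(s, aps)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(cell_id = cell$cell_id, subtype = cell$subtype,
                   step_index = i, step_amplitude_pA = s$step_amplitude_pA,
                   condition = cond, stringsAsFactors = FALSE),
        tf)
    }
  }
  if (!length(rows)) {
    return(data.frame())
  }
  do.call(rbind, rows)
}

# features for many cells; accepts a precomputed table to avoid repeating
# detection
cohort_feature_table <- function(cells, features = NULL, ...) {
  if (!is.null(features)) return(features)
  do.call(rbind, lapply(cells, cell_feature_table, ...))
}

#' Select the paired-latency sweep of a cell
#'
#' The first step at which APs were observed in both the no-light and the
#' light condition; latency comparisons are made at this step.
#'
#' @param cell a [cell_recording()].
#' @param features optional precomputed [cell_feature_table()].
#' @param ... passed to [detect_aps()].
#' @return step ordinal, or `NA_integer_` when no step qualifies (the cell
#'   is then excluded from latency comparisons).
#' @export
select_latency_sweep <- function(cell, features = NULL, ...) {
  ft <- if (is.null(features)) cell_feature_table(cell, ...) else
    features[features$cell_id == cell$cell_id, , drop = FALSE]
  if (!nrow(ft)) return(NA_integer_)
  wide <- split(ft, ft$condition)
  if (is.null(wide$no_light) || is.null(wide$light)) return(NA_integer_)
  common <- intersect(wide$no_light$step_index[wide$no_light$n_aps >= 1],
                      wide$light$step_index[wide$light$n_aps >= 1])
  if (!length(common)) return(NA_integer_)
  min(common)
}

#' Select the low-depolarization ISI sweep
#'
#' One step above the paired-latency sweep, so that intervals between
#' multiple APs can be quantified.
#'
#' @inheritParams select_latency_sweep
#' @return step ordinal, or `NA_integer_` when the latency sweep is missing
#'   or is the last recorded step.
#' @export
select_isi_low_depol_sweep <- function(cell, features = NULL, ...) {
  lat <- select_latency_sweep(cell, features, ...)
  if (is.na(lat)) return(NA_integer_)
  ft <- if (is.null(features)) cell_feature_table(cell, ...) else
    features[features$cell_id == cell$cell_id, , drop = FALSE]
  nxt <- lat + 1L
  have <- vapply(c("no_light", "light"), function(cond) {
    any(ft$condition == cond & ft$step_index == nxt)
  }, logical(1))
  if (!all(have)) return(NA_integer_)
  nxt
}

#' Select the high-depolarization sweep
#'
#' The no-light depolarization-block sweep; all high-depolarization
#' measurements (both conditions) are taken at this step.
#'
#' @param cell a [cell_recording()].
#' @param block optional precomputed [detect_block_sweep()] result for the
#'   no-light condition.
#' @param ... passed to [detect_block_sweep()].
#' @return step ordinal, or `NA_integer_` when no block was detected (the
#'   cell is then excluded from high-depolarization comparisons).
#' @export
select_high_depol_sweep <- function(cell, block = NULL, ...) {
  if (is.null(block)) {
    block <- tryCatch(detect_block_sweep(cell, "no_light", ...),
                      error = function(e) NULL)
  }
  if (is.null(block) || is.na(block$block_sweep_index)) return(NA_integer_)
  block$block_sweep_index
}

#' Build a group input-output curve
#'
#' Aligns each cell's paired steps to a common anchor and averages firing
#' frequency per condition at each relative index. `first_spike_anchor`
#' aligns to the first step with recorded spikes in both conditions (the
#' normalization of the low-depolarization curve); `max_current_anchor`
#' aligns to the highest completed paired step (the normalization of the
#' high-depolarization curve). "Normalized to" is alignment (re-indexing),
#' not amplitude scaling: the y axis remains a frequency.
#'
#' @param cells list of [cell_recording()] objects.
#' @param alignment `"first_spike_anchor"` or `"max_current_anchor"`.
#' @param min_cells relative indices supported by fewer cells are flagged
#'   `included = FALSE` (kept in the table so exports stay complete).
#' @param features optional precomputed cohort feature table.
#' @param ... passed to [detect_aps()].
#' @return object of class `io_curve`: data.frame with `alignment`,
#'   `relative_index`, `n_cells`, per-condition mean and SEM frequency, and
#'   `included`.
#' @export
build_io_curve <- function(cells,
                           alignment = c("first_spike_anchor",
                                         "max_current_anchor"),
                           min_cells = 3, features = NULL, ...) {
  alignment <- match.arg(alignment)
  long <- io_curve_table(cells, alignment, features = features, ...)
  if (!nrow(long)) {
    out <- data.frame()
    class(out) <- c("io_curve", class(out))
    return(out)
  }
  wide <- stats::reshape(long[, c("cell_id", "relative_index", "condition",
                                  "frequency_hz")],
                         direction = "wide",
                         idvar = c("cell_id", "relative_index"),
                         timevar = "condition")
  agg <- do.call(rbind, lapply(split(wide, wide$relative_index), function(d) {
    data.frame(relative_index = d$relative_index[1],
               n_cells = nrow(d),
               mean_frequency_no_light_hz = mean(d$frequency_hz.no_light),
               mean_frequency_light_hz = mean(d$frequency_hz.light),
               sem_no_light = stats::sd(d$frequency_hz.no_light) / sqrt(nrow(d)),
               sem_light = stats::sd(d$frequency_hz.light) / sqrt(nrow(d)))
  }))
  agg <- agg[order(agg$relative_index), , drop = FALSE]
  agg$alignment <- alignment
  agg$included <- agg$n_cells >= min_cells
  rownames(agg) <- NULL
  class(agg) <- c("io_curve", class(agg))
  agg
}

#' Long-format paired frequency table for I/O analysis
#'
#' One row per (cell, relative step, condition) with the paired firing
#' frequency; the input to [anova_io_curves()].
#'
#' @inheritParams build_io_curve
#' @return data.frame: `cell_id`, `relative_index`, `condition`,
#'   `frequency_hz`.
#' @export
io_curve_table <- function(cells,
                           alignment = c("first_spike_anchor",
                                         "max_current_anchor"),
                           features = NULL, ...) {
  alignment <- match.arg(alignment)
  ft <- cohort_feature_table(cells, features, ...)
  if (is.null(ft) || !nrow(ft)) return(data.frame())
  out <- list()
  for (cell in cells) {
    cf <- ft[ft$cell_id == cell$cell_id, , drop = FALSE]
    if (!nrow(cf)) next
    paired_steps <- intersect(cf$step_index[cf$condition == "no_light"],
                              cf$step_index[cf$condition == "light"])
    if (!length(paired_steps)) next
    anchor <- if (alignment == "first_spike_anchor") {
      select_latency_sweep(cell, features = cf)
    } else {
      max(paired_steps)
    }
    if (is.na(anchor)) next
    sel <- cf[cf$step_index %in% paired_steps,
              c("cell_id", "step_index", "condition", "frequency_hz")]
    sel$relative_index <- sel$step_index - anchor
    out[[length(out) + 1L]] <- sel[, c("cell_id", "relative_index",
                                       "condition", "frequency_hz")]
  }
  if (!length(out)) return(data.frame())
  do.call(rbind, out)
}

#' Paired light/no-light deltas at the designated sweeps
#'
#' For each eligible cell, takes the designated step for the requested
#' depolarization state -- the paired-latency sweep (latency) or the ISI
#' sweep (mean ISI) at low depolarization, the no-light block sweep for all
#' features at high depolarization -- and returns the paired no-light/light
#' values from that same step together with `delta = light - no_light`.
#' Ineligible cells are reported in the `exclusions` attribute, never
#' silently dropped.
#'
#' @param cells list of [cell_recording()] objects.
#' @param feature feature column of [cell_feature_table()] to compare
#'   (e.g. `"latency_ms"`, `"mean_isi_ms"`, `"frequency_hz"`).
#' @param state `"low_depol"` or `"high_depol"`.
#' @param features optional precomputed cohort feature table.
#' @param ... passed to [detect_aps()].
#' @return data.frame: `cell_id`, `feature`, `state`, `step_index`,
#'   `value_no_light`, `value_light`, `delta`; attribute `exclusions` is a
#'   data.frame of `cell_id`, `reason`.
#' @export
paired_deltas <- function(cells, feature = "latency_ms",
                          state = c("low_depol", "high_depol"),
                          features = NULL, ...) {
  state <- match.arg(state)
  ft <- cohort_feature_table(cells, features, ...)
  rows <- list()
  excl <- list()
  for (cell in cells) {
    cf <- ft[ft$cell_id == cell$cell_id, , drop = FALSE]
    idx <- if (state == "high_depol") {
      select_high_depol_sweep(cell, ...)
    } else if (feature == "mean_isi_ms") {
      select_isi_low_depol_sweep(cell, features = cf)
    } else {
      select_latency_sweep(cell, features = cf)
    }
    if (is.na(idx)) {
      excl[[length(excl) + 1L]] <- data.frame(
        cell_id = cell$cell_id,
        reason = if (state == "high_depol") "no_block_detected" else
          "no_paired_spiking_sweep")
      next
    }
    v_nl <- cf[[feature]][cf$condition == "no_light" & cf$step_index == idx]
    v_l <- cf[[feature]][cf$condition == "light" & cf$step_index == idx]
    if (!length(v_nl) || !length(v_l) || is.na(v_nl) || is.na(v_l)) {
      excl[[length(excl) + 1L]] <- data.frame(cell_id = cell$cell_id,
                                              reason = "feature_undefined")
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      cell_id = cell$cell_id, feature = feature, state = state,
      step_index = idx, value_no_light = v_nl, value_light = v_l,
      delta = v_l - v_nl, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cell_id = character(), feature = character(),
               state = character(), step_index = integer(),
               value_no_light = numeric(), value_light = numeric(),
               delta = numeric())
  attr(out, "exclusions") <- if (length(excl)) do.call(rbind, excl) else
    data.frame(cell_id = character(), reason = character())
  out
}
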