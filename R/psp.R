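# Optogenetically evoked PSP quantification and response classification.

sweep_pulse_onset <- function(sweep) {
  if (sweep$protocol$kind == "none") {
    analysis_error("sweep has no light protocol")
  }
  sweep$protocol$pulse_onset_s
}

#' Pre-stimulus baseline membrane potential
#'
#' Mean membrane potential over the `window_ms` interval ending at the
#' (first) light-pulse onset.
#'
#' @param sweep a light-protocol [msn_sweep()].
#' @param window_ms baseline window length.
#' @return mV.
#' @export
baseline_vm <- function(sweep, window_ms = 100) {
  onset <- sweep_pulse_onset(sweep)
  fs <- sweep$sample_rate_hz
  i1 <- round((onset - window_ms / 1000) * fs) + 1L
  i2 <- round(onset * fs)
  if (i1 < 1L) {
    analysis_error("baseline window does not fit before the pulse onset")
  }
  mean(sweep$vm[i1:i2])
}

#' Mean membrane-potential change in a post-onset window
#'
#' The change-from-baseline metric: mean Vm over
#' `[onset + t0_ms, onset + t1_ms]` minus the pre-stimulus baseline. The
#' default 200-300 ms window quantifies the slow (GABA_B-receptor
#' timescale) component of the response.
#'
#' @param sweep a light-protocol [msn_sweep()].
#' @param t0_ms,t1_ms window relative to pulse onset, ms.
#' @param baseline_window_ms passed to [baseline_vm()].
#' @return mV (negative = hyperpolarization).
#' @export
delta_vm_window <- function(sweep, t0_ms = 200, t1_ms = 300,
                            baseline_window_ms = 100) {
  onset <- sweep_pulse_onset(sweep)
  fs <- sweep$sample_rate_hz
  i1 <- round((onset + t0_ms / 1000) * fs) + 1L
  i2 <- round((onset + t1_ms / 1000) * fs) + 1L
  if (i2 > length(sweep$vm) || i1 < 1L) {
    analysis_error("measurement window exceeds the sweep")
  }
  mean(sweep$vm[i1:i2]) - baseline_vm(sweep, baseline_window_ms)
}

# average several sweeps sharing a protocol into one synthetic sweep
average_sweeps <- function(sweeps) {
  if (inherits(sweeps, "msn_sweep")) sweeps <- list(sweeps)
  if (!length(sweeps)) analysis_error("no sweeps to average")
  p0 <- sweeps[[1]]$protocol
  same <- vapply(sweeps, function(s) {
    identical(s$protocol$kind, p0$kind) &&
      identical(s$protocol$pulse_duration_ms, p0$pulse_duration_ms) &&
      identical(s$protocol$n_pulses, p0$n_pulses) &&
      length(s$vm) == length(sweeps[[1]]$vm)
  }, logical(1))
  if (!all(same)) analysis_error("sweeps do not share a protocol")
  avg <- rowMeans(vapply(sweeps, `[[`, numeric(length(sweeps[[1]]$vm)), "vm"))
  out <- sweeps[[1]]
  out$vm <- avg
  out
}

# centered moving-average smoothing (reflective of nothing fancy; partial
# windows at the edges)
boxcar_smooth <- function(x, w) {
  if (w <= 1L) return(x)
  cs <- cumsum(c(0, x))
  n <- length(x)
  half <- w %/% 2L
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Classify a cell's evoked response to one stimulation protocol
#'
#' Averages the protocol's sweeps (the convention is a mean of about five
#' sweeps), lightly smooths the average, and measures the peak
#' depolarization and peak hyperpolarization relative to the pre-stimulus
#' baseline within the response window (pulse onset to last-pulse offset
#' plus `window_after_offset_ms`, long enough to capture slow GABA_B
#' hyperpolarization). A deflection counts when it exceeds
#' `theta = max(k_sd * baseline SD of the smoothed average, floor_mV)`:
#' only depolarization -> excitatory; only hyperpolarization -> inhibitory;
#' both -> mixed; neither -> none. The threshold rule is stored in the call
#' for provenance. All fields except the baseline itself are invariant
#' under a DC shift of the trace.
#'
#' @param sweeps list of sweeps sharing one protocol (one cell).
#' @param k_sd,floor_mV threshold rule parameters.
#' @param window_after_offset_ms response-window extension past the last
#'   pulse offset.
#' @param smooth_ms boxcar smoothing window applied before peak picking.
#' @param baseline_window_ms baseline window.
#' @return object of class `response_call`: `cell_id`, `protocol_kind`,
#'   `protocol_label` (`short_pulse`/`pulse_train`/`long_pulse`), `class`,
#'   `baseline_vm_mV`, `peak_depol_mV`, `peak_hyperpol_mV`,
#'   `delta_vm_200_300_mV`, `threshold_mV`, `n_sweeps`.
#' @export
classify_response <- function(sweeps, k_sd = 3, floor_mV = 0.3,
                              window_after_offset_ms = 300,
                              smooth_ms = 5, baseline_window_ms = 100) {
  avg <- average_sweeps(sweeps)
  fs <- avg$sample_rate_hz
  onset <- sweep_pulse_onset(avg)
  onsets <- pulse_onsets(avg$protocol)
  last_off <- max(onsets) + avg$protocol$pulse_duration_ms / 1000

  sm <- avg$vm
  w <- max(1L, round(smooth_ms / 1000 * fs))
  sm <- boxcar_smooth(sm, w)

  b1 <- round((onset - baseline_window_ms / 1000) * fs) + 1L
  b2 <- round(onset * fs)
  if (b1 < 1L) analysis_error("baseline window does not fit before the pulse")
  base <- mean(sm[b1:b2])
  noise_sd <- stats::sd(sm[b1:b2])
  theta <- max(k_sd * noise_sd, floor_mV)

  w1 <- round(onset * fs) + 1L
  w2 <- min(length(sm),
            round((last_off + window_after_offset_ms / 1000) * fs) + 1L)
  seg <- sm[w1:w2] - base
  peak_depol <- max(seg)
  peak_hyper <- -min(seg)

  class <- if (peak_depol > theta && peak_hyper > theta) "mixed"
  else if (peak_depol > theta) "excitatory"
  else if (peak_hyper > theta) "inhibitory"
  else "none"

  label <- if (avg$protocol$kind == "pulse_train") "pulse_train"
  else if (avg$protocol$pulse_duration_ms >= 100) "long_pulse"
  else "short_pulse"

  dvm <- tryCatch(
    delta_vm_window(avg, baseline_window_ms = baseline_window_ms),
    error = function(e) NA_real_)

  structure(list(cell_id = avg$cell_id,
                 protocol_kind = avg$protocol$kind,
                 protocol_label = label,
                 class = class,
                 baseline_vm_mV = base,
                 peak_depol_mV = peak_depol,
                 peak_hyperpol_mV = peak_hyper,
                 delta_vm_200_300_mV = dvm,
                 threshold_mV = theta,
                 n_sweeps = if (inherits(sweeps, "msn_sweep")) 1L else
                   length(sweeps)),
            class = "response_call")
}

#' @export
print.response_call <- function(x, ...) {
  cat(sprintf("<response_call> %s %s: %s (depol %.2f, hyperpol %.2f, theta %.2f mV)\n",
              x$cell_id, x$protocol_label, x$class, x$peak_depol_mV,
              x$peak_hyperpol_mV, x$threshold_mV))
  invisible(x)
}

# coerce a list of response_call objects to a data.frame
calls_table <- function(calls) {
  if (is.data.frame(calls)) return(calls)
  if (inherits(calls, "response_call")) calls <- list(calls)
  do.call(rbind, lapply(calls, function(x) {
    data.frame(cell_id = x$cell_id, protocol_label = x$protocol_label,
               class = x$class, delta_vm_200_300_mV = x$delta_vm_200_300_mV,
               peak_depol_mV = x$peak_depol_mV,
               peak_hyperpol_mV = x$peak_hyperpol_mV,
               stringsAsFactors = FALSE)
  }))
}

#' Per-class percentages from class counts
#'
#' Percentages are rounded to the nearest integer, half away from zero, and
#' computed against an explicit total (which may exceed the sum of the
#' provided class counts when some cells were reported without a class).
#'
#' @param counts named numeric vector of per-class cell counts.
#' @param total denominator (default: sum of counts).
#' @return named numeric vector of integer percentages.
#' @export
class_percentages <- function(counts, total = sum(counts)) {
  if (total <= 0) parameter_error("`total` must be positive")
  out <- round_half_up(100 * counts / total)
  names(out) <- names(counts)
  out
}

#' Breakdown of response types
#'
#' Counts and integer percentages of response classes across calls,
#' optionally grouped by MSN subtype. Counts are reported alongside the
#' percentages so the rounding is auditable.
#'
#' @param calls list of [classify_response()] results (or their
#'   data.frame).
#' @param subtype optional character vector aligned with `calls` to group
#'   by subtype.
#' @return data.frame with `group`, `class`, `n`, `percent`; attribute
#'   `total` per group.
#' @export
breakdown <- function(calls, subtype = NULL) {
  tab <- calls_table(calls)
  if (!nrow(tab)) parameter_error("no response calls given")
  tab$group <- if (is.null(subtype)) "all" else subtype
  lv <- c("excitatory", "mixed", "inhibitory", "none")
  out <- do.call(rbind, lapply(split(tab, tab$group), function(d) {
    n <- vapply(lv, function(cl) sum(d$class == cl), numeric(1))
    keep <- n > 0 | lv %in% c("excitatory", "mixed", "inhibitory")
    data.frame(group = d$group[1], class = lv[keep], n = n[keep],
               percent = class_percentages(n, total = nrow(d))[keep],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Cross-protocol response-transition table
#'
#' Joint counts of response classes across the three stimulation protocols,
#' over cells characterized under all three (the data behind a Sankey
#' diagram of changing responses). Marginals restricted to those cells
#' reproduce the per-protocol breakdowns.
#'
#' @param calls list (or data.frame) of response calls across protocols,
#'   matched by `cell_id`.
#' @return data.frame `short_pulse`, `pulse_train`, `long_pulse`, `n`
#'   (one row per observed combination); attribute `total` = number of
#'   fully characterized cells; attribute `edges` = long-format edge list
#'   for Sankey plotting.
#' @export
transition_table <- function(calls) {
  tab <- calls_table(calls)
  wide <- stats::reshape(tab[, c("cell_id", "protocol_label", "class")],
                         direction = "wide", idvar = "cell_id",
                         timevar = "protocol_label")
  names(wide) <- sub("^class\\.", "", names(wide))
  need <- c("short_pulse", "pulse_train", "long_pulse")
  missing_col <- setdiff(need, names(wide))
  for (m in missing_col) wide[[m]] <- NA_character_
  full <- wide[stats::complete.cases(wide[, need]), , drop = FALSE]
  if (!nrow(full)) {
    out <- data.frame(short_pulse = character(), pulse_train = character(),
                      long_pulse = character(), n = integer())
    attr(out, "total") <- 0L
    return(out)
  }
  combo <- interaction(full$short_pulse, full$pulse_train, full$long_pulse,
                       drop = TRUE, sep = "|")
  counts <- table(combo)
  parts <- do.call(rbind, strsplit(names(counts), "\\|"))
  out <- data.frame(short_pulse = parts[, 1], pulse_train = parts[, 2],
                    long_pulse = parts[, 3], n = as.integer(counts),
                    stringsAsFactors = FALSE)
  attr(out, "total") <- nrow(full)
  edges <- rbind(
    data.frame(from_protocol = "short_pulse", to_protocol = "pulse_train",
               from_class = full$short_pulse, to_class = full$pulse_train),
    data.frame(from_protocol = "pulse_train", to_protocol = "long_pulse",
               from_class = full$pulse_train, to_class = full$long_pulse))
  edge_tab <- stats::aggregate(list(n = rep(1L, nrow(edges))),
                               edges, FUN = sum)
  attr(out, "edges") <- edge_tab
  out
}

#' Paired wash-on effect on the slow membrane-potential change
#'
#' For each cell recorded before (`cgp_pre`) and after (`cgp_post`)
#' GABA_B-receptor blockade under the same protocol, averages each phase's
#' sweeps and computes the 200-300 ms change-from-baseline metric, paired
#' for a Wilcoxon signed-rank comparison. Deltas are baseline-relative, so
#' a DC offset between phases does not affect them.
#'
#' @param cells list of [cell_recording()] objects whose sweeps carry the
#'   `cgp_pre`/`cgp_post` pharmacology tags.
#' @param t0_ms,t1_ms measurement window (ms after pulse onset).
#' @return data.frame: `cell_id`, `delta_pre`, `delta_post`.
#' @export
washon_effect <- function(cells, t0_ms = 200, t1_ms = 300) {
  if (inherits(cells, "msn_cell")) cells <- list(cells)
  rows <- lapply(cells, function(cell) {
    pre <- Filter(function(s) "cgp_pre" %in% s$pharmacology, cell$sweeps)
    post <- Filter(function(s) "cgp_post" %in% s$pharmacology, cell$sweeps)
    if (!length(pre) || !length(post)) {
      analysis_error(sprintf("cell %s lacks a cgp_pre or cgp_post phase",
                             cell$cell_id))
    }
    if (!identical(pre[[1]]$protocol$kind, post[[1]]$protocol$kind) ||
        !identical(pre[[1]]$protocol$pulse_duration_ms,
                   post[[1]]$protocol$pulse_duration_ms)) {
      analysis_error(sprintf("cell %s: pre/post protocols differ",
                             cell$cell_id))
    }
    data.frame(cell_id = cell$cell_id,
               delta_pre = delta_vm_window(average_sweeps(pre), t0_ms, t1_ms),
               delta_post = delta_vm_window(average_sweeps(post), t0_ms, t1_ms),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
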