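# Action-potential detection and per-spike geometry.

# Five-point Savitzky-Golay (quadratic) first-derivative estimate, mV/ms.
# The smoothing suppresses sample-to-sample noise in dV/dt so the slope
# criterion does not fire on noise; threshold timing is afterwards refined
# on the raw derivative (see detect_aps).
sg5_derivative <- function(vm, sample_rate_hz) {
  n <- length(vm)
  dt_ms <- 1000 / sample_rate_hz
  dv <- numeric(n)
  if (n >= 5) {
    i <- 3:(n - 2)
    dv[i] <- (2 * vm[i + 2] + vm[i + 1] - vm[i - 1] - 2 * vm[i - 2]) /
      (10 * dt_ms)
  }
  dv
}

#' Detect action potentials in a sweep
#'
#' Events are detected where the smoothed dV/dt crosses a slope criterion
#' and the following voltage peak rises by at least `min_peak_prominence_mV`
#' above the crossing point. Events closer than `refractory_ms` are merged
#' to the larger peak. When the sweep defines a current step, detection is
#' restricted to the step window. The threshold sample of each AP is the
#' last upward crossing of the smoothed dV/dt before the peak, so on
#' noiseless template spikes threshold timing is exact to within one
#' sample.
#'
#' The detector is translation invariant: adding a DC offset to `vm`
#' changes nothing.
#'
#' @param sweep an [msn_sweep()] object (current clamp).
#' @param dvdt_threshold_mV_per_ms slope criterion for AP onset (mV/ms).
#' @param min_peak_prominence_mV minimum rise from slope crossing to peak.
#' @param refractory_ms events closer than this are merged.
#' @return data.frame with one row per AP: `threshold_time_s`, `peak_time_s`,
#'   `threshold_vm_mV`, `peak_vm_mV`, `height_mV` (peak minus threshold),
#'   plus `half_width_ms` and `rise_time_ms` filled by
#'   [extract_ap_features()] (NA here).
#' @export
detect_aps <- function(sweep, dvdt_threshold_mV_per_ms = 20,
                       min_peak_prominence_mV = 10, refractory_ms = 1) {
  fs <- sweep$sample_rate_hz
  if (fs < 10000) {
    capability_error("sample rate below 10 kHz: dV/dt cannot be estimated reliably")
  }
  vm <- sweep$vm
  n <- length(vm)
  empty <- data.frame(threshold_time_s = numeric(), peak_time_s = numeric(),
                      threshold_vm_mV = numeric(), peak_vm_mV = numeric(),
                      height_mV = numeric(), half_width_ms = numeric(),
                      rise_time_ms = numeric())
  if (n < 5) return(empty)

  dv <- sg5_derivative(vm, fs)
  thr <- dvdt_threshold_mV_per_ms
  above <- dv >= thr
  crossings <- which(above & !c(FALSE, above[-n]))
  if (!length(crossings)) return(empty)

  search_w <- max(1L, round(5e-3 * fs))   # 5 ms window to locate the peak
  repol_w <- max(1L, round(3e-3 * fs))    # repolarization check window
  peaks <- integer(0)
  for (cr in crossings) {
    hi <- min(n, cr + search_w)
    pk <- cr + which.max(vm[cr:hi]) - 1L
    if (vm[pk] - vm[cr] < min_peak_prominence_mV) next
    # a spike repolarizes: the trace must fall back within a few ms of the
    # peak, which rejects slope-criterion crossings riding the passive step
    # onset (where the membrane keeps charging)
    fall <- vm[pk] - min(vm[pk:min(n, pk + repol_w)])
    if (fall < min_peak_prominence_mV / 2) next
    peaks <- c(peaks, pk)
  }
  if (!length(peaks)) return(empty)
  peaks <- sort(unique(peaks))

  # merge peaks within the refractory period, keeping the larger
  refr <- refractory_ms / 1000 * fs
  keep <- peaks[1]
  for (pk in peaks[-1]) {
    last <- keep[length(keep)]
    if (pk - last < refr) {
      if (vm[pk] > vm[last]) keep[length(keep)] <- pk
    } else {
      keep <- c(keep, pk)
    }
  }
  peaks <- keep

  # restrict to the current-step window when one is defined
  if (!is.na(sweep$step_onset_s) && !is.na(sweep$step_offset_s) &&
      sweep$step_amplitude_pA != 0) {
    tpk <- (peaks - 1L) / fs
    peaks <- peaks[tpk >= sweep$step_onset_s & tpk <= sweep$step_offset_s]
  }
  if (!length(peaks)) return(empty)

  # threshold sample: the last upward slope-criterion crossing of the
  # smoothed derivative before the peak (robust to derivative noise during
  # the rising limb; exact to one sample on noiseless templates)
  back_w <- max(1L, round(3e-3 * fs))     # look back at most 3 ms
  thr_idx <- vapply(peaks, function(pk) {
    cand <- crossings[crossings <= pk & crossings >= pk - back_w]
    if (length(cand)) max(cand) else max(1L, pk - back_w)
  }, numeric(1))
  thr_idx <- as.integer(thr_idx)

  data.frame(threshold_time_s = (thr_idx - 1L) / fs,
             peak_time_s = (peaks - 1L) / fs,
             threshold_vm_mV = vm[thr_idx],
             peak_vm_mV = vm[peaks],
             height_mV = vm[peaks] - vm[thr_idx],
             half_width_ms = NA_real_,
             rise_time_ms = NA_real_)
}

# Linear interpolation of the time at which the rising (dir = 1) or falling
# (dir = -1) limb crosses `level`, scanning outward from the peak index.
cross_time <- function(vm, fs, peak_idx, bound_idx, level, rising) {
  idx <- if (rising) seq(peak_idx, bound_idx, by = -1L) else
    seq(peak_idx, bound_idx, by = 1L)
  below <- which(vm[idx] <= level)
  if (!length(below)) return(NA_real_)
  j <- idx[min(below)]           # first sample at/below level moving outward
  k <- if (rising) j + 1L else j - 1L  # adjacent sample above level
  if (vm[j] == level) return((j - 1L) / fs)
  frac <- (level - vm[j]) / (vm[k] - vm[j])
  ((j - 1L) + frac * (k - j)) / fs
}

#' Fill per-AP geometry (height, half-width, rise time)
#'
#' Height is threshold-to-peak. Half-width is the full width at
#' threshold + height/2, with crossing times interpolated linearly between
#' samples. Rise time is the 10%-to-90% height interval on the rising limb.
#' When a crossing cannot be found (e.g. a non-monotonic rising limb), the
#' feature is flagged `NA` rather than fabricated.
#'
#' @param sweep the sweep the APs were detected on.
#' @param aps data.frame from [detect_aps()].
#' @return the same data.frame with `half_width_ms` and `rise_time_ms`
#'   filled.
#' @export
extract_ap_features <- function(sweep, aps) {
  if (nrow(aps) == 0) return(aps)
  fs <- sweep$sample_rate_hz
  vm <- sweep$vm
  n <- length(vm)
  for (i in seq_len(nrow(aps))) {
    pk <- round(aps$peak_time_s[i] * fs) + 1L
    th <- round(aps$threshold_time_s[i] * fs) + 1L
    h <- aps$height_mV[i]
    base <- aps$threshold_vm_mV[i]
    # bounds: previous/next AP threshold or trace edge
    lo <- th
    hi <- if (i < nrow(aps)) round(aps$threshold_time_s[i + 1] * fs) else n
    half <- base + h / 2
    t_r <- cross_time(vm, fs, pk, lo, half, rising = TRUE)
    t_f <- cross_time(vm, fs, pk, hi, half, rising = FALSE)
    aps$half_width_ms[i] <- if (is.na(t_r) || is.na(t_f)) NA_real_ else
      (t_f - t_r) * 1000
    t10 <- cross_time(vm, fs, pk, lo, base + 0.1 * h, rising = TRUE)
    t90 <- cross_time(vm, fs, pk, lo, base + 0.9 * h, rising = TRUE)
    aps$rise_time_ms[i] <- if (is.na(t10) || is.na(t90)) NA_real_ else
      (t90 - t10) * 1000
  }
  aps
}

#' Per-sweep spike-train summary features
#'
#' Implements the reporting conventions used throughout the package:
#' frequency is spike count over the current-step duration; latency is from
#' step onset to the first AP's threshold crossing; the mean inter-spike
#' interval (ISI) is always the average over all successive peak-time
#' differences in the train (equivalently `(t_last - t_first)/(n - 1)`);
#' "first spike" geometry refers to the first AP, "train mean" geometry to
#' the average over all APs excluding the first.
#'
#' @param sweep the sweep.
#' @param aps data.frame from [detect_aps()] (geometry optionally filled by
#'   [extract_ap_features()]).
#' @return one-row data.frame: `n_aps`, `frequency_hz`, `latency_ms`,
#'   `mean_isi_ms`, `first_height_mV`, `first_half_width_ms`,
#'   `first_rise_time_ms`, `train_height_mV`, `train_half_width_ms`,
#'   `train_rise_time_ms`. Undefined fields (latency with no APs, mean ISI
#'   with fewer than two) are `NA`.
#' @export
train_features <- function(sweep, aps) {
  n <- nrow(aps)
  dur_s <- if (!is.na(sweep$step_onset_s) && !is.na(sweep$step_offset_s)) {
    sweep$step_offset_s - sweep$step_onset_s
  } else {
    length(sweep$vm) / sweep$sample_rate_hz
  }
  latency <- if (n >= 1 && !is.na(sweep$step_onset_s)) {
    (aps$threshold_time_s[1] - sweep$step_onset_s) * 1000
  } else NA_real_
  mean_isi <- if (n >= 2) {
    mean(diff(aps$peak_time_s)) * 1000
  } else NA_real_
  train_mean <- function(col) if (n >= 2) mean(aps[[col]][-1]) else NA_real_
  data.frame(n_aps = n,
             frequency_hz = n / dur_s,
             latency_ms = latency,
             mean_isi_ms = mean_isi,
             first_height_mV = if (n >= 1) aps$height_mV[1] else NA_real_,
             first_half_width_ms = if (n >= 1) aps$half_width_ms[1] else NA_real_,
             first_rise_time_ms = if (n >= 1) aps$rise_time_ms[1] else NA_real_,
             train_height_mV = train_mean("height_mV"),
             train_half_width_ms = train_mean("half_width_ms"),
             train_rise_time_ms = train_mean("rise_time_ms"))
}
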