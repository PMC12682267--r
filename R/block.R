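# Depolarization-block detection via the bimodal AP-height histogram.
#
# All AP heights of a cell (one condition) are pooled into a histogram;
# the higher peak is the height of full APs, the lower peak the height of
# attenuated APs. An AP is attenuated when its height falls strictly below
# the lower peak, and the block sweep is the first sweep in which at least
# half of the train's APs are attenuated.

#' AP-height histogram
#'
#' Fixed-width, right-open bins covering `[min, max]` of the heights;
#' counts conserve the number of observations. Bin edges are anchored at
#' multiples of `bin_width_mV`, not at the data minimum, so bin placement
#' does not drift with the sample.
#'
#' @param heights_mV numeric vector of AP heights (>= 1 value).
#' @param bin_width_mV bin width, default 2 mV.
#' @return object of class `height_histogram`: list with `breaks`, `counts`,
#'   `centers`, `bin_width_mV`.
#' @export
height_histogram <- function(heights_mV, bin_width_mV = 2) {
  if (length(heights_mV) == 0) {
    analysis_error("cannot build a height histogram from zero heights")
  }
  if (bin_width_mV <= 0) parameter_error("`bin_width_mV` must be > 0")
  lo <- floor(min(heights_mV) / bin_width_mV) * bin_width_mV
  n_bins <- floor((max(heights_mV) - lo) / bin_width_mV) + 1L
  breaks <- lo + bin_width_mV * (0:n_bins)
  idx <- floor((heights_mV - lo) / bin_width_mV) + 1L
  counts <- tabulate(idx, nbins = n_bins)
  structure(list(breaks = breaks, counts = counts,
                 centers = breaks[-length(breaks)] + bin_width_mV / 2,
                 bin_width_mV = bin_width_mV),
            class = "height_histogram")
}

#' Locate the two modes of a (bimodal) height histogram
#'
#' Counts are smoothed with a 3-bin moving average before the local-maximum
#' search; each candidate mode is then refined to the raw-count maximum
#' within one bin of the smoothed maximum, so the reported peak sits on the
#' most populated raw bin. Candidates are ranked by raw count (ties broken
#' toward the lower bin center); the two best candidates separated by at
#' least `min_separation_mV` are returned. If no such pair exists the
#' distribution is declared unimodal.
#'
#' Alongside the peak centers, `lower_cutoff_mV` gives the upper edge of
#' the lower-mode bin: heights inside the modal bin are part of the
#' attenuated population, so the full/attenuated boundary sits at the top
#' of that bin (see [detect_block_sweep()]).
#'
#' @param hist a [height_histogram()].
#' @param min_separation_mV minimum mode separation (default 10 mV).
#' @param smooth_bins moving-average window (odd, default 3).
#' @return list with `bimodal` (logical); when bimodal, `lower_peak_mV`,
#'   `upper_peak_mV` (bin centers) and `lower_cutoff_mV`; otherwise
#'   `peak_mV` of the single mode.
#' @export
find_bimodal_peaks <- function(hist, min_separation_mV = 10,
                               smooth_bins = 3) {
  stopifnot(inherits(hist, "height_histogram"))
  counts <- hist$counts
  n <- length(counts)
  if (n == 1L || sum(counts > 0) == 1L) {
    return(list(bimodal = FALSE, peak_mV = hist$centers[which.max(counts)]))
  }
  half <- (smooth_bins - 1L) %/% 2L
  padded <- c(rep(0, half), counts, rep(0, half))
  sm <- vapply(seq_len(n), function(i) mean(padded[i:(i + 2L * half)]),
               numeric(1))

  left <- c(-Inf, sm[-n])
  right <- c(sm[-1], -Inf)
  cand <- which(sm >= left & sm >= right & sm > 0)
  # collapse runs of equal smoothed counts to their first (lower-center) bin
  if (length(cand) > 1) {
    keep <- c(TRUE, !(diff(cand) == 1L & sm[cand[-1]] == sm[cand[-length(cand)]]))
    cand <- cand[keep]
  }
  # refine each candidate to the raw-count maximum within +/- 1 bin
  refined <- vapply(cand, function(i) {
    win <- max(1L, i - 1L):min(n, i + 1L)
    win[which.max(counts[win])]   # which.max ties -> lower index
  }, integer(1))
  refined <- unique(refined)
  ord <- order(-counts[refined], hist$centers[refined])
  refined <- refined[ord]

  if (length(refined) < 2L) {
    return(list(bimodal = FALSE, peak_mV = hist$centers[refined[1]]))
  }
  top <- refined[1]
  rest <- refined[-1]
  sep_ok <- abs(hist$centers[rest] - hist$centers[top]) >= min_separation_mV
  if (!any(sep_ok)) {
    return(list(bimodal = FALSE, peak_mV = hist$centers[top]))
  }
  second <- rest[sep_ok][1]
  bins <- c(top, second)[order(hist$centers[c(top, second)])]
  list(bimodal = TRUE,
       lower_peak_mV = hist$centers[bins[1]],
       upper_peak_mV = hist$centers[bins[2]],
       lower_cutoff_mV = hist$breaks[bins[1] + 1L])
}

#' Label AP heights as full or attenuated
#'
#' An AP is attenuated iff its height falls strictly below the lower
#' histogram peak; a height exactly at the peak is full.
#'
#' @param heights_mV numeric vector.
#' @param lower_peak_mV the lower mode from [find_bimodal_peaks()].
#' @return character vector, `"full"` or `"attenuated"`.
#' @export
classify_heights <- function(heights_mV, lower_peak_mV) {
  ifelse(heights_mV < lower_peak_mV, "attenuated", "full")
}

#' Detect the depolarization-block sweep of a cell
#'
#' Pools AP heights over all of the cell's current-step sweeps in the given
#' condition (a single sweep rarely yields a usable bimodal histogram; a
#' per-sweep histogram is available behind `per_sweep = TRUE`), finds the
#' two height modes, labels each AP against the lower mode's
#' `lower_cutoff_mV` (heights in the modal bin count as attenuated), and
#' returns the first sweep whose attenuated fraction reaches at least one
#' half. Cells with a unimodal height distribution yield an explicit
#' no-block outcome (`block_sweep_index = NA`) and are excluded from
#' high-depolarization comparisons downstream.
#'
#' @param cell a [cell_recording()].
#' @param condition `"no_light"` or `"light"`.
#' @param bin_width_mV,min_separation_mV,smooth_bins histogram/peak
#'   parameters.
#' @param per_sweep build one histogram per sweep instead of pooling.
#' @param ... passed to [detect_aps()].
#' @return object of class `block_result`: `lower_peak_mV`,
#'   `upper_peak_mV`, `attenuation_cutoff_mV`, `bin_width_mV`, `condition`,
#'   `per_sweep_fraction`
#'   (data.frame: `step_index`, `step_amplitude_pA`, `n_aps`,
#'   `attenuated_fraction`), `block_sweep_index` (step ordinal or NA),
#'   `bimodal`.
#' @export
detect_block_sweep <- function(cell, condition = c("no_light", "light"),
                               bin_width_mV = 2, min_separation_mV = 10,
                               smooth_bins = 3, per_sweep = FALSE, ...) {
  condition <- match.arg(condition)
  sw <- fi_sweeps(cell, condition)
  aps <- lapply(sw, function(s) detect_aps(s, ...))
  n_aps <- vapply(aps, nrow, integer(1))
  if (length(sw) == 0 || all(n_aps == 0)) {
    analysis_error(sprintf("cell %s has no spiking sweeps in the %s condition",
                           cell$cell_id, condition))
  }

  frac_for <- function(heights, lower_peak) {
    if (length(heights) == 0) return(NA_real_)
    mean(classify_heights(heights, lower_peak) == "attenuated")
  }

  if (!per_sweep) {
    pooled <- unlist(lapply(aps, `[[`, "height_mV"))
    hist <- height_histogram(pooled, bin_width_mV)
    pk <- find_bimodal_peaks(hist, min_separation_mV, smooth_bins)
    lower <- if (pk$bimodal) pk$lower_peak_mV else NA_real_
    upper <- if (pk$bimodal) pk$upper_peak_mV else pk$peak_mV
    cutoff <- if (pk$bimodal) pk$lower_cutoff_mV else NA_real_
    fracs <- vapply(aps, function(a) {
      if (pk$bimodal) frac_for(a$height_mV, cutoff) else NA_real_
    }, numeric(1))
  } else {
    lower <- upper <- cutoff <- NA_real_
    fracs <- vapply(aps, function(a) {
      if (nrow(a) == 0) return(NA_real_)
      h <- height_histogram(a$height_mV, bin_width_mV)
      p <- find_bimodal_peaks(h, min_separation_mV, smooth_bins)
      if (!p$bimodal) return(NA_real_)
      frac_for(a$height_mV, p$lower_cutoff_mV)
    }, numeric(1))
    pk <- list(bimodal = any(!is.na(fracs)))
  }

  block <- which(!is.na(fracs) & fracs >= 0.5)
  block_idx <- if (length(block)) min(block) else NA_integer_
  structure(list(
    lower_peak_mV = lower, upper_peak_mV = upper,
    attenuation_cutoff_mV = cutoff,
    bin_width_mV = bin_width_mV, condition = condition,
    per_sweep_fraction = data.frame(
      step_index = seq_along(sw),
      step_amplitude_pA = vapply(sw, `[[`, numeric(1), "step_amplitude_pA"),
      n_aps = n_aps,
      attenuated_fraction = fracs),
    block_sweep_index = block_idx,
    bimodal = isTRUE(pk$bimodal)),
    class = "block_result")
}

#' @export
print.block_result <- function(x, ...) {
  cat(sprintf("<block_result> %s: peaks %.1f / %.1f mV, block at step %s\n",
              x$condition, x$lower_peak_mV, x$upper_peak_mV,
              format(x$block_sweep_index)))
  invisible(x)
}
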