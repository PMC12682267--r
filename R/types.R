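#' Stimulation protocol descriptor
#'
#' Describes the optogenetic light protocol attached to a sweep: none, a
#' single pulse (e.g. 10 ms or 500 ms), or a pulse train (e.g. 5 ms pulses
#' at 20 Hz).
#'
#' @param kind one of `"none"`, `"single_pulse"`, `"pulse_train"`.
#' @param pulse_onset_s pulse (or first-pulse) onset, seconds from sweep
#'   start.
#' @param pulse_duration_ms duration of each pulse, milliseconds.
#' @param n_pulses number of pulses; 1 for a single pulse, >= 2 for a train.
#' @param train_rate_hz pulse rate in Hz; only meaningful for trains.
#' @return an object of class `stim_protocol`.
#' @export
stim_protocol <- function(kind = c("none", "single_pulse", "pulse_train"),
                          pulse_onset_s = NA_real_,
                          pulse_duration_ms = NA_real_,
                          n_pulses = NA_integer_,
                          train_rate_hz = NA_real_) {
  kind <- match.arg(kind)
  if (kind == "none") {
    p <- list(kind = kind, pulse_onset_s = NA_real_,
              pulse_duration_ms = NA_real_, n_pulses = 0L,
              train_rate_hz = NA_real_)
    class(p) <- "stim_protocol"
    return(p)
  }
  if (is.na(pulse_onset_s) || pulse_onset_s < 0) {
    parameter_error("`pulse_onset_s` must be >= 0")
  }
  if (is.na(pulse_duration_ms) || pulse_duration_ms <= 0) {
    parameter_error("`pulse_duration_ms` must be > 0")
  }
  if (kind == "single_pulse") {
    n_pulses <- 1L
    train_rate_hz <- NA_real_
  } else {
    n_pulses <- as.integer(n_pulses)
    if (is.na(n_pulses) || n_pulses < 2L) {
      parameter_error("pulse trains need `n_pulses` >= 2")
    }
    if (is.na(train_rate_hz) || train_rate_hz <= 0) {
      parameter_error("pulse trains need `train_rate_hz` > 0")
    }
    if (1000 / train_rate_hz < pulse_duration_ms) {
      parameter_error("inter-pulse interval shorter than the pulse itself")
    }
  }
  p <- list(kind = kind, pulse_onset_s = pulse_onset_s,
            pulse_duration_ms = pulse_duration_ms,
            n_pulses = n_pulses, train_rate_hz = train_rate_hz)
  class(p) <- "stim_protocol"
  p
}

#' One episodic current-clamp sweep
#'
#' A single recorded trial: the membrane-potential trace plus the command
#' current step and light-protocol metadata. Units are fixed package-wide:
#' `vm` in mV, currents in pA, times in seconds.
#'
#' @param cell_id cell identifier.
#' @param sweep_index ordinal index of the sweep within the cell.
#' @param sample_rate_hz sampling rate (nominal 50000).
#' @param vm numeric vector of membrane-potential samples, mV.
#' @param step_amplitude_pA injected current-step amplitude, pA (0 for PSP
#'   sweeps without somatic current injection).
#' @param step_onset_s,step_offset_s current-step window, seconds (nominal
#'   500 ms step).
#' @param condition `"no_light"` or `"light"`.
#' @param protocol a [stim_protocol()]; must not be `"none"` when
#'   `condition == "light"`.
#' @param pharmacology character vector of tags, a subset of
#'   `c("picrotoxin", "ttx_4ap_zd", "cgp_pre", "cgp_post")`.
#' @return an object of class `msn_sweep`.
#' @export
msn_sweep <- function(cell_id, sweep_index, sample_rate_hz, vm,
                  step_amplitude_pA = 0,
                  step_onset_s = NA_real_, step_offset_s = NA_real_,
                  condition = c("no_light", "light"),
                  protocol = stim_protocol("none"),
                  pharmacology = character()) {
  condition <- match.arg(condition)
  if (!inherits(protocol, "stim_protocol")) {
    parameter_error("`protocol` must be a stim_protocol object")
  }
  if (sample_rate_hz <= 0) parameter_error("`sample_rate_hz` must be > 0")
  if (condition == "light" && protocol$kind == "none") {
    parameter_error("a light-condition sweep needs a non-'none' protocol")
  }
  if (!is.na(step_onset_s) && !is.na(step_offset_s) &&
      step_offset_s <= step_onset_s) {
    parameter_error("`step_offset_s` must exceed `step_onset_s`")
  }
  known <- c("picrotoxin", "ttx_4ap_zd", "cgp_pre", "cgp_post")
  if (length(pharmacology) && !all(pharmacology %in% known)) {
    parameter_error(paste0("unknown pharmacology tag(s): ",
                           paste(setdiff(pharmacology, known),
                                 collapse = ", ")))
  }
  s <- list(cell_id = as.character(cell_id),
            sweep_index = as.integer(sweep_index),
            sample_rate_hz = sample_rate_hz,
            vm = as.numeric(vm),
            step_amplitude_pA = step_amplitude_pA,
            step_onset_s = step_onset_s,
            step_offset_s = step_offset_s,
            condition = condition,
            protocol = protocol,
            pharmacology = pharmacology)
  class(s) <- "msn_sweep"
  s
}

#' A recorded cell: ordered sweeps plus metadata
#'
#' @param cell_id cell identifier.
#' @param sweeps list of [msn_sweep()] objects.
#' @param subtype `"D1"`, `"D2"` or `"unknown"` (medium spiny neuron
#'   dopamine-receptor subtype).
#' @param slice_id,mouse_id provenance identifiers.
#' @param access_resistance_MOhm access (series) resistance in megaohms;
#'   the quality-control criterion discards cells above 30.
#' @param qc_flags character vector of quality flags.
#' @return an object of class `msn_cell`.
#' @export
cell_recording <- function(cell_id, sweeps,
                           subtype = c("unknown", "D1", "D2"),
                           slice_id = NA_character_,
                           mouse_id = NA_character_,
                           access_resistance_MOhm = NA_real_,
                           qc_flags = character()) {
  subtype <- match.arg(subtype)
  if (!all(vapply(sweeps, inherits, logical(1), "msn_sweep"))) {
    parameter_error("`sweeps` must be a list of msn_sweep objects")
  }
  idx <- vapply(sweeps, `[[`, integer(1), "sweep_index")
  sweeps <- sweeps[order(idx)]
  cr <- list(cell_id = as.character(cell_id),
             subtype = subtype,
             slice_id = slice_id,
             mouse_id = mouse_id,
             access_resistance_MOhm = access_resistance_MOhm,
             sweeps = sweeps,
             qc_flags = qc_flags)
  class(cr) <- "msn_cell"
  cr
}

#' @export
print.msn_sweep <- function(x, ...) {
  cat(sprintf("<msn_sweep> cell %s sweep %d: %d samples @ %g kHz, %g pA, %s\n",
              x$cell_id, x$sweep_index, length(x$vm),
              x$sample_rate_hz / 1000, x$step_amplitude_pA, x$condition))
  invisible(x)
}

#' @export
print.msn_cell <- function(x, ...) {
  cat(sprintf("<msn_cell> %s (%s): %d sweeps, Ra = %s MOhm\n",
              x$cell_id, x$subtype, length(x$sweeps),
              format(x$access_resistance_MOhm)))
  invisible(x)
}

# Sweeps of the paired current-step (f-I) protocol, as a list split by
# condition and ordered by step amplitude. Internal.
fi_sweeps <- function(cell, condition) {
  sw <- Filter(function(s) s$step_amplitude_pA > 0 &&
                 s$condition == condition, cell$sweeps)
  amp <- vapply(sw, `[[`, numeric(1), "step_amplitude_pA")
  sw[order(amp)]
}
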