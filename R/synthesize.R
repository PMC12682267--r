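# Synthetic current-clamp sweep generation with exact ground truth.
#
# Spikes are stereotyped triangular templates inserted on a passive RC step
# response rather than an ODE neuron model, so every downstream stage
# (detector, geometry, block detector, I/O curves) can be tested against
# exact known truth.

#' Action-potential template parameters
#'
#' @param threshold_vm spike threshold, mV.
#' @param full_height threshold-to-peak height of a full AP, mV.
#' @param attenuated_height_fraction height of the attenuated-AP shoulder as
#'   a fraction of `full_height` (in (0,1)).
#' @param half_width_ms full width at half height of the template.
#' @param rise_time_ms 0-to-100% rise duration of the template; the measured
#'   10-90% rise time of the linear rising limb is 0.8 times this.
#' @return list of class `ap_template_params`.
#' @export
ap_template_params <- function(threshold_vm = -45, full_height = 80,
                               attenuated_height_fraction = 0.46,
                               half_width_ms = 1.5, rise_time_ms = 0.5) {
  if (attenuated_height_fraction <= 0 || attenuated_height_fraction >= 1) {
    parameter_error("`attenuated_height_fraction` must be in (0,1)")
  }
  if (half_width_ms <= 0) parameter_error("`half_width_ms` must be > 0")
  if (rise_time_ms <= 0 || 2 * half_width_ms <= rise_time_ms) {
    parameter_error("need 0 < rise_time_ms < 2*half_width_ms")
  }
  structure(list(threshold_vm = threshold_vm, full_height = full_height,
                 attenuated_height_fraction = attenuated_height_fraction,
                 half_width_ms = half_width_ms, rise_time_ms = rise_time_ms),
            class = "ap_template_params")
}

#' Parameters of a synthetic current-step (f-I) cell
#'
#' Spike count per 500 ms sweep follows the closed-form rate rule
#' `round(gain_hz_per_pA * (I - rheobase_pA) * step_duration_s)` above
#' rheobase. From `block_onset_step_index` onward (in the no-light
#' condition) the cell is in depolarization block: the spike count drops by
#' `block_count_fraction` and all APs in the train are attenuated to
#' `full_height * attenuated_height_fraction`, emulating spike-height
#' attenuation at high depolarization. Optogenetic stimulation delays block
#' onset by
#' `light_extra_full_steps` and shifts latency/ISI by the signed deltas.
#'
#' @param resting_vm resting potential, mV.
#' @param rheobase_pA minimal spiking current, pA.
#' @param gain_hz_per_pA firing-rate gain above rheobase.
#' @param block_onset_step_index step ordinal at which depolarization block
#'   starts (no-light condition).
#' @param light_extra_full_steps extra pre-block steps under light (>= 0
#'   reproduces the resilient-spiking direction).
#' @param light_latency_delta_ms,light_isi_delta_ms signed effects of light
#'   on first-spike latency and on each inter-spike interval, ms.
#' @param noise_sd_mV Gaussian noise added to every sample.
#' @param isi_jitter_ms SD of zero-mean jitter applied to inter-spike
#'   intervals (centered within each sweep, so the mean ISI is unaffected).
#' @param block_count_fraction spike-count multiplier in blocked sweeps.
#' @param latency_base_ms latency scale; latency at current I is
#'   `latency_base_ms * rheobase / I`.
#' @param membrane_tau_ms passive membrane time constant for the RC step
#'   response.
#' @return list of class `fi_cell_params`.
#' @export
fi_cell_params <- function(resting_vm = -80, rheobase_pA = 150,
                           gain_hz_per_pA = 0.08,
                           block_onset_step_index = 8,
                           light_extra_full_steps = 1,
                           light_latency_delta_ms = -10,
                           light_isi_delta_ms = 5,
                           noise_sd_mV = 0.3,
                           isi_jitter_ms = 1,
                           block_count_fraction = 0.6,
                           latency_base_ms = 120,
                           membrane_tau_ms = 10) {
  if (rheobase_pA <= 0) parameter_error("`rheobase_pA` must be > 0")
  if (noise_sd_mV < 0) parameter_error("`noise_sd_mV` must be >= 0")
  if (light_extra_full_steps < 0) {
    parameter_error("`light_extra_full_steps` must be >= 0")
  }
  structure(list(resting_vm = resting_vm, rheobase_pA = rheobase_pA,
                 gain_hz_per_pA = gain_hz_per_pA,
                 block_onset_step_index = block_onset_step_index,
                 light_extra_full_steps = light_extra_full_steps,
                 light_latency_delta_ms = light_latency_delta_ms,
                 light_isi_delta_ms = light_isi_delta_ms,
                 noise_sd_mV = noise_sd_mV, isi_jitter_ms = isi_jitter_ms,
                 block_count_fraction = block_count_fraction,
                 latency_base_ms = latency_base_ms,
                 membrane_tau_ms = membrane_tau_ms),
            class = "fi_cell_params")
}

# passive RC response to a current step, per-sample, no spikes, no noise
rc_trace <- function(n_samples, fs, resting, dV, onset_s, offset_s, tau_ms) {
  t <- (seq_len(n_samples) - 1L) / fs
  tau <- tau_ms / 1000
  v <- rep(resting, n_samples)
  on <- t >= onset_s & t < offset_s
  v[on] <- resting + dV * (1 - exp(-(t[on] - onset_s) / tau))
  post <- t >= offset_s
  v_off <- dV * (1 - exp(-(offset_s - onset_s) / tau))
  v[post] <- resting + v_off * exp(-(t[post] - offset_s) / tau)
  v
}

# insert a triangular spike of the given height at a threshold-onset sample
insert_spike <- function(vm, idx0, height, rise_n, fall_n) {
  n <- length(vm)
  base <- vm[idx0]
  up <- idx0 + 0:rise_n
  up <- up[up <= n]
  vm[up] <- base + height * (up - idx0) / rise_n
  dn <- idx0 + rise_n + seq_len(fall_n)
  dn <- dn[dn <= n]
  vm[dn] <- base + height * (1 - (dn - idx0 - rise_n) / fall_n)
  vm
}

#' Generate one synthetic f-I cell with ground truth
#'
#' Produces paired no-light/light sweeps at successive current steps in
#' `step_increment_pA` increments (the paired step recorded a moment later
#' with a 500 ms light pulse), plus exact ground truth: true spike times,
#' full/attenuated labels per AP, and the true block step per condition.
#' Identical seeds give bit-identical output.
#'
#' @param params a [fi_cell_params()].
#' @param ap an [ap_template_params()].
#' @param n_steps number of current steps (must reach the block onset).
#' @param step_increment_pA current increment per step (default 50).
#' @param seed RNG seed.
#' @param cell_id identifier.
#' @param sample_rate_hz sampling rate.
#' @param subtype,access_resistance_MOhm cell metadata.
#' @param pre_s,step_s,post_s sweep segment durations (seconds); the current
#'   step spans `[pre_s, pre_s + step_s)`.
#' @return list with `cell` (a [cell_recording()]) and `truth` (list:
#'   per-sweep spike times and labels, true block step per condition,
#'   generator parameters, seed).
#' @export
generate_fi_cell <- function(params = fi_cell_params(),
                             ap = ap_template_params(),
                             n_steps = 10, step_increment_pA = 50,
                             seed = 1, cell_id = "cell01",
                             sample_rate_hz = 50000,
                             subtype = "unknown",
                             access_resistance_MOhm = 15,
                             pre_s = 0.1, step_s = 0.5, post_s = 0.1) {
  stopifnot(inherits(params, "fi_cell_params"),
            inherits(ap, "ap_template_params"))
  amps <- step_increment_pA * seq_len(n_steps)
  first_spike_step <- which(amps > params$rheobase_pA)[1]
  if (is.na(first_spike_step)) {
    parameter_error("no step exceeds rheobase; increase n_steps")
  }
  if (params$block_onset_step_index < first_spike_step) {
    parameter_error("block onset precedes the first suprathreshold step")
  }
  if (n_steps < params$block_onset_step_index) {
    parameter_error("`n_steps` must reach `block_onset_step_index`")
  }

  fs <- sample_rate_hz
  n_samples <- round((pre_s + step_s + post_s) * fs)
  onset <- pre_s
  offset <- pre_s + step_s
  step_ms <- step_s * 1000
  rise_n <- round(ap$rise_time_ms / 1000 * fs)
  fall_n <- round((2 * ap$half_width_ms - ap$rise_time_ms) / 1000 * fs)
  A <- ap$full_height * ap$attenuated_height_fraction

  with_seed(seed, {
    sweeps <- list()
    truth_sweeps <- list()
    sweep_counter <- 0L
    block_step <- c(no_light = params$block_onset_step_index,
                    light = params$block_onset_step_index +
                      params$light_extra_full_steps)

    for (i in seq_len(n_steps)) {
      I <- amps[i]
      supra <- I > params$rheobase_pA
      n_full <- if (supra) {
        round(params$gain_hz_per_pA * (I - params$rheobase_pA) * step_s)
      } else 0L
      lat_nl <- params$latency_base_ms * params$rheobase_pA / I

      for (cond in c("no_light", "light")) {
        sweep_counter <- sweep_counter + 1L
        blocked <- supra && i >= block_step[[cond]]
        n_sp <- if (!supra || n_full == 0L) 0L else if (blocked) {
          max(2L, round(n_full * params$block_count_fraction))
        } else n_full

        dV <- (ap$threshold_vm - 3 - params$resting_vm) *
          min(I / params$rheobase_pA, 1)
        vm <- rc_trace(n_samples, fs, params$resting_vm, dV, onset, offset,
                       params$membrane_tau_ms)

        spike_thr_t <- numeric(0)
        spike_peak_t <- numeric(0)
        labels <- character(0)
        if (n_sp >= 1L) {
          lat <- lat_nl + if (cond == "light")
            params$light_latency_delta_ms else 0
          d_isi <- if (cond == "light") params$light_isi_delta_ms else 0
          if (n_sp == 1L) {
            times_ms <- lat
          } else {
            span <- step_ms - lat_nl - 30 -
              max(params$light_isi_delta_ms, 0) * (n_sp - 1L) -
              abs(params$light_latency_delta_ms)
            isi_nom <- span / (n_sp - 1L)
            if (isi_nom <= 4) {
              parameter_error("spike train does not fit in the step window")
            }
            z <- stats::rnorm(n_sp - 1L, 0, params$isi_jitter_ms)
            z <- z - mean(z)
            times_ms <- lat + cumsum(c(0, isi_nom + d_isi + z))
          }
          heights <- rep(ap$full_height, n_sp)
          labels <- rep("full", n_sp)
          if (blocked) {
            heights <- rep(A, n_sp)
            labels <- rep("attenuated", n_sp)
          }
          thr_idx <- round((onset + times_ms / 1000) * fs) + 1L
          for (j in seq_len(n_sp)) {
            vm <- insert_spike(vm, thr_idx[j], heights[j], rise_n, fall_n)
          }
          spike_thr_t <- (thr_idx - 1L) / fs
          spike_peak_t <- (thr_idx + rise_n - 1L) / fs
        }
        if (params$noise_sd_mV > 0) {
          vm <- vm + stats::rnorm(n_samples, 0, params$noise_sd_mV)
        }
        prot <- if (cond == "light") {
          stim_protocol("single_pulse", pulse_onset_s = onset,
                        pulse_duration_ms = step_ms)
        } else stim_protocol("none")
        sweeps[[sweep_counter]] <- msn_sweep(
          cell_id = cell_id, sweep_index = sweep_counter,
          sample_rate_hz = fs, vm = vm, step_amplitude_pA = I,
          step_onset_s = onset, step_offset_s = offset,
          condition = cond, protocol = prot)
        truth_sweeps[[sweep_counter]] <- list(
          sweep_index = sweep_counter, step_index = i,
          step_amplitude_pA = I, condition = cond,
          spike_threshold_times_s = spike_thr_t,
          spike_peak_times_s = spike_peak_t,
          labels = labels)
      }
    }

    cell <- cell_recording(cell_id = cell_id, sweeps = sweeps,
                           subtype = subtype,
                           access_resistance_MOhm = access_resistance_MOhm)
    truth <- list(cell_id = cell_id,
                  sweeps = truth_sweeps,
                  block_step = as.list(block_step),
                  params = unclass(params), ap = unclass(ap),
                  n_steps = n_steps, step_increment_pA = step_increment_pA,
                  seed = seed)
    list(cell = cell, truth = truth)
  })
}

#' Normalized postsynaptic-potential kernel
#'
#' Difference of exponentials `exp(-t/tau_decay) - exp(-t/tau_rise)`
#' normalized to unit peak; zero for `t < 0`. Used for both the fast EPSP
#' kernel and the slow (hundreds of ms) GABA_B-like IPSP kernel.
#'
#' @param t_s time from kernel onset, seconds (vector).
#' @param tau_rise_ms,tau_decay_ms time constants, ms (decay > rise).
#' @return numeric vector, unit peak.
#' @export
psp_kernel <- function(t_s, tau_rise_ms, tau_decay_ms) {
  if (tau_decay_ms <= tau_rise_ms) {
    parameter_error("`tau_decay_ms` must exceed `tau_rise_ms`")
  }
  tr <- tau_rise_ms / 1000
  td <- tau_decay_ms / 1000
  t_peak <- log(td / tr) * tr * td / (td - tr)
  peak <- exp(-t_peak / td) - exp(-t_peak / tr)
  k <- ifelse(t_s >= 0, (exp(-t_s / td) - exp(-t_s / tr)) / peak, 0)
  k
}

#' PSP kernel parameters
#'
#' Defaults place the IPSP timescale inside the slow (100-500 ms)
#' GABA_B-receptor envelope. `true_class` must be consistent with which
#' amplitudes are nonzero. Amplitude defaults are placeholders: the source
#' recordings report no population amplitude statistics for evoked PSPs.
#'
#' @param epsp_amplitude_mV,epsp_tau_rise_ms,epsp_tau_decay_ms fast
#'   excitatory kernel.
#' @param ipsp_amplitude_mV,ipsp_tau_rise_ms,ipsp_tau_decay_ms slow
#'   inhibitory kernel.
#' @param ipsp_lag_ms delay of IPSP onset after each pulse onset.
#' @param true_class `"excitatory"`, `"mixed"` or `"inhibitory"`.
#' @return list of class `psp_kernel_params`.
#' @export
psp_kernel_params <- function(epsp_amplitude_mV = 2,
                              epsp_tau_rise_ms = 2, epsp_tau_decay_ms = 20,
                              ipsp_amplitude_mV = 1.5,
                              ipsp_tau_rise_ms = 60, ipsp_tau_decay_ms = 250,
                              ipsp_lag_ms = 30,
                              true_class = c("mixed", "excitatory",
                                             "inhibitory")) {
  true_class <- match.arg(true_class)
  if (epsp_amplitude_mV < 0 || ipsp_amplitude_mV < 0) {
    parameter_error("kernel amplitudes must be >= 0")
  }
  if (epsp_tau_decay_ms <= epsp_tau_rise_ms ||
      ipsp_tau_decay_ms <= ipsp_tau_rise_ms) {
    parameter_error("decay time constants must exceed rise time constants")
  }
  consistent <- switch(true_class,
    excitatory = epsp_amplitude_mV > 0 && ipsp_amplitude_mV == 0,
    inhibitory = epsp_amplitude_mV == 0 && ipsp_amplitude_mV > 0,
    mixed = epsp_amplitude_mV > 0 && ipsp_amplitude_mV > 0)
  if (!consistent) {
    parameter_error("`true_class` inconsistent with nonzero amplitudes")
  }
  structure(list(epsp_amplitude_mV = epsp_amplitude_mV,
                 epsp_tau_rise_ms = epsp_tau_rise_ms,
                 epsp_tau_decay_ms = epsp_tau_decay_ms,
                 ipsp_amplitude_mV = ipsp_amplitude_mV,
                 ipsp_tau_rise_ms = ipsp_tau_rise_ms,
                 ipsp_tau_decay_ms = ipsp_tau_decay_ms,
                 ipsp_lag_ms = ipsp_lag_ms,
                 true_class = true_class),
            class = "psp_kernel_params")
}

# pulse onset times (s) for a protocol
pulse_onsets <- function(protocol) {
  if (protocol$kind == "single_pulse") return(protocol$pulse_onset_s)
  protocol$pulse_onset_s +
    (seq_len(protocol$n_pulses) - 1L) / protocol$train_rate_hz
}

#' Generate one synthetic PSP sweep
#'
#' The noise-free trace is resting potential plus, for every light pulse, an
#' EPSP kernel at pulse onset minus an IPSP kernel delayed by
#' `ipsp_lag_ms`; superposition holds by construction, so doubling an
#' amplitude doubles the deviation at every sample.
#'
#' @param protocol a [stim_protocol()] with `kind != "none"`.
#' @param kernels a [psp_kernel_params()].
#' @param noise_sd_mV Gaussian noise SD (>= 0).
#' @param seed RNG seed.
#' @param resting_vm resting potential, mV.
#' @param sample_rate_hz sampling rate.
#' @param duration_s sweep length; default covers the last pulse plus 0.6 s.
#' @param cell_id,sweep_index,pharmacology sweep metadata.
#' @return list with `sweep` and `truth` (true class, parameters, seed).
#' @export
generate_psp_sweep <- function(protocol, kernels = psp_kernel_params(),
                               noise_sd_mV = 0.1, seed = 1,
                               resting_vm = -78, sample_rate_hz = 50000,
                               duration_s = NULL, cell_id = "cell01",
                               sweep_index = 1L,
                               pharmacology = character()) {
  if (protocol$kind == "none") {
    parameter_error("PSP sweeps need a light protocol")
  }
  if (noise_sd_mV < 0) parameter_error("`noise_sd_mV` must be >= 0")
  onsets <- pulse_onsets(protocol)
  last_end <- max(onsets) + protocol$pulse_duration_ms / 1000
  if (is.null(duration_s)) duration_s <- last_end + 0.6
  fs <- sample_rate_hz
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1L) / fs
  dev <- numeric(n)
  for (on in onsets) {
    if (kernels$epsp_amplitude_mV > 0) {
      dev <- dev + kernels$epsp_amplitude_mV *
        psp_kernel(t - on, kernels$epsp_tau_rise_ms,
                   kernels$epsp_tau_decay_ms)
    }
    if (kernels$ipsp_amplitude_mV > 0) {
      dev <- dev - kernels$ipsp_amplitude_mV *
        psp_kernel(t - on - kernels$ipsp_lag_ms / 1000,
                   kernels$ipsp_tau_rise_ms, kernels$ipsp_tau_decay_ms)
    }
  }
  vm <- resting_vm + dev
  with_seed(seed, {
    if (noise_sd_mV > 0) vm <- vm + stats::rnorm(n, 0, noise_sd_mV)
    sw <- msn_sweep(cell_id = cell_id, sweep_index = sweep_index,
                sample_rate_hz = fs, vm = vm, step_amplitude_pA = 0,
                condition = "light", protocol = protocol,
                pharmacology = pharmacology)
    list(sweep = sw,
         truth = list(true_class = kernels$true_class,
                      kernels = unclass(kernels), seed = seed))
  })
}

# standard light protocols used across the study
psp_protocols <- function(onset_s = 0.2) {
  list(
    short_pulse = stim_protocol("single_pulse", pulse_onset_s = onset_s,
                                pulse_duration_ms = 10),
    pulse_train = stim_protocol("pulse_train", pulse_onset_s = onset_s,
                                pulse_duration_ms = 5, n_pulses = 10,
                                train_rate_hz = 20),
    long_pulse = stim_protocol("single_pulse", pulse_onset_s = onset_s,
                               pulse_duration_ms = 500)
  )
}

# kernel parameter set for a given true class
class_kernels <- function(class, epsp_amplitude_mV = 2,
                          ipsp_amplitude_mV = 1.5, ...) {
  switch(class,
    excitatory = psp_kernel_params(epsp_amplitude_mV = epsp_amplitude_mV,
                                   ipsp_amplitude_mV = 0,
                                   true_class = "excitatory", ...),
    inhibitory = psp_kernel_params(epsp_amplitude_mV = 0,
                                   ipsp_amplitude_mV = ipsp_amplitude_mV,
                                   true_class = "inhibitory", ...),
    mixed = psp_kernel_params(epsp_amplitude_mV = epsp_amplitude_mV,
                              ipsp_amplitude_mV = ipsp_amplitude_mV,
                              true_class = "mixed", ...),
    parameter_error(sprintf("unknown response class '%s'", class)))
}

#' Default cohort configuration
#'
#' Study conditions for [generate_cohort()]: counts of f-I cells, PSP cells
#' with an exact per-protocol class mixture (deterministic allocation, not
#' sampled, so printed-count checks are exact), and wash-on cells recorded
#' before/after GABA_B blockade. Class mixtures are given as per-class cell
#' counts that must sum to `n_cells`.
#'
#' @param n_fi_cells number of current-step cells.
#' @param n_psp_cells number of PSP cells (each recorded under the short
#'   pulse, the 20 Hz train, and the long pulse).
#' @param mixture named list of per-protocol class-count vectors with names
#'   `short_pulse`, `pulse_train`, `long_pulse`; each a named numeric vector
#'   over `excitatory`/`mixed`/`inhibitory`.
#' @param n_washon_cells cells with cgp_pre/cgp_post long-pulse sweeps.
#' @param n_sweeps_per_protocol sweeps averaged per protocol (the source
#'   recordings average about 5).
#' @param psp_noise_sd_mV,fi_noise_sd_mV noise levels.
#' @param epsp_amplitude_mV,ipsp_amplitude_mV kernel amplitudes.
#' @param washon_ipsp_pre_mV,washon_ipsp_post_mV IPSP amplitude before and
#'   after GABA_B-receptor blockade.
#' @return config list.
#' @export
cohort_config <- function(n_fi_cells = 0, n_psp_cells = 0,
                          mixture = NULL, n_washon_cells = 0,
                          n_sweeps_per_protocol = 5,
                          psp_noise_sd_mV = 0.1, fi_noise_sd_mV = 0.3,
                          epsp_amplitude_mV = 2, ipsp_amplitude_mV = 1.5,
                          washon_ipsp_pre_mV = 1.5,
                          washon_ipsp_post_mV = 0) {
  if (is.null(mixture) && n_psp_cells > 0) {
    # realized counts follow the long-pulse-dominant pattern by default
    n_inh <- floor(n_psp_cells / 5)
    n_exc <- floor(n_psp_cells / 5)
    mixture <- list(
      short_pulse = c(excitatory = n_psp_cells - n_inh, mixed = n_inh,
                      inhibitory = 0),
      pulse_train = c(excitatory = n_psp_cells - 2 * n_inh, mixed = 2 * n_inh,
                      inhibitory = 0),
      long_pulse = c(excitatory = n_exc,
                     mixed = n_psp_cells - n_exc - n_inh,
                     inhibitory = n_inh))
  }
  list(n_fi_cells = n_fi_cells, n_psp_cells = n_psp_cells,
       mixture = mixture, n_washon_cells = n_washon_cells,
       n_sweeps_per_protocol = n_sweeps_per_protocol,
       psp_noise_sd_mV = psp_noise_sd_mV, fi_noise_sd_mV = fi_noise_sd_mV,
       epsp_amplitude_mV = epsp_amplitude_mV,
       ipsp_amplitude_mV = ipsp_amplitude_mV,
       washon_ipsp_pre_mV = washon_ipsp_pre_mV,
       washon_ipsp_post_mV = washon_ipsp_post_mV)
}

#' Generate a full synthetic cohort
#'
#' Builds f-I cells, PSP cells and wash-on cells per the configuration, with
#' deterministic class allocation (cells are assigned classes per protocol
#' in cell order, so realized counts equal the configured mixture exactly).
#' Output is a pure function of `(config, seed)`; a different seed changes
#' noise realizations but not labels.
#'
#' @param config a [cohort_config()].
#' @param seed RNG seed.
#' @param path optional directory; when given, the bundle is written with
#'   [write_sweep_bundle()] and the ground truth as `ground_truth.json`
#'   alongside it.
#' @return list with `cells` (list of [cell_recording()]) and `truth`.
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1,
                            path = NULL) {
  cells <- list()
  truth <- list(fi = list(), psp = list(), washon = list(), seed = seed)
  protocols <- psp_protocols()
  rheo_cycle <- c(150, 100, 200)
  subtype_cycle <- c("D1", "D2")

  if (config$n_fi_cells > 0) {
    for (i in seq_len(config$n_fi_cells)) {
      rheo <- rheo_cycle[(i - 1L) %% 3L + 1L]
      first_step <- which(50 * 1:20 > rheo)[1]
      par <- fi_cell_params(rheobase_pA = rheo,
                            block_onset_step_index = first_step + 4L,
                            noise_sd_mV = config$fi_noise_sd_mV)
      g <- generate_fi_cell(par, n_steps = first_step + 6L,
                            seed = seed + i,
                            cell_id = sprintf("fi%03d", i),
                            subtype = subtype_cycle[(i - 1L) %% 2L + 1L])
      cells[[length(cells) + 1L]] <- g$cell
      truth$fi[[g$cell$cell_id]] <- g$truth
    }
  }

  if (config$n_psp_cells > 0) {
    mix <- config$mixture
    for (lbl in names(protocols)) {
      m <- mix[[lbl]]
      if (is.null(m) || sum(m) != config$n_psp_cells) {
        parameter_error(sprintf(
          "mixture for '%s' must sum to n_psp_cells (%d)", lbl,
          config$n_psp_cells))
      }
    }
    alloc <- lapply(names(protocols), function(lbl) {
      m <- mix[[lbl]]
      rep(names(m), times = m)
    })
    names(alloc) <- names(protocols)
    for (i in seq_len(config$n_psp_cells)) {
      cid <- sprintf("psp%03d", i)
      sweeps <- list()
      cls <- list()
      idx <- 0L
      for (lbl in names(protocols)) {
        class_i <- alloc[[lbl]][i]
        cls[[lbl]] <- class_i
        kern <- class_kernels(class_i,
                              epsp_amplitude_mV = config$epsp_amplitude_mV,
                              ipsp_amplitude_mV = config$ipsp_amplitude_mV)
        for (r in seq_len(config$n_sweeps_per_protocol)) {
          idx <- idx + 1L
          g <- generate_psp_sweep(protocols[[lbl]], kern,
                                  noise_sd_mV = config$psp_noise_sd_mV,
                                  seed = seed + 1000L * i + 10L * idx,
                                  cell_id = cid, sweep_index = idx,
                                  pharmacology = "picrotoxin")
          sweeps[[idx]] <- g$sweep
        }
      }
      cells[[length(cells) + 1L]] <- cell_recording(
        cell_id = cid, sweeps = sweeps,
        subtype = subtype_cycle[(i - 1L) %% 2L + 1L],
        access_resistance_MOhm = 12)
      truth$psp[[cid]] <- cls
    }
  }

  if (config$n_washon_cells > 0) {
    long <- protocols$long_pulse
    for (i in seq_len(config$n_washon_cells)) {
      cid <- sprintf("wash%03d", i)
      sweeps <- list()
      idx <- 0L
      for (phase in c("cgp_pre", "cgp_post")) {
        ipsp <- if (phase == "cgp_pre") config$washon_ipsp_pre_mV else
          config$washon_ipsp_post_mV
        kern <- if (ipsp > 0) {
          psp_kernel_params(epsp_amplitude_mV = 0.5,
                            ipsp_amplitude_mV = ipsp, true_class = "mixed")
        } else {
          psp_kernel_params(epsp_amplitude_mV = 0.5, ipsp_amplitude_mV = 0,
                            true_class = "excitatory")
        }
        for (r in seq_len(config$n_sweeps_per_protocol)) {
          idx <- idx + 1L
          g <- generate_psp_sweep(long, kern,
                                  noise_sd_mV = config$psp_noise_sd_mV,
                                  seed = seed + 5000L * i + 10L * idx,
                                  cell_id = cid, sweep_index = idx,
                                  pharmacology = c("picrotoxin", "ttx_4ap_zd",
                                                   phase))
          sweeps[[idx]] <- g$sweep
        }
      }
      cells[[length(cells) + 1L]] <- cell_recording(
        cell_id = cid, sweeps = sweeps, subtype = "unknown",
        access_resistance_MOhm = 12)
      truth$washon[[cid]] <- list(ipsp_pre = config$washon_ipsp_pre_mV,
                                  ipsp_post = config$washon_ipsp_post_mV)
    }
  }

  if (!is.null(path)) {
    write_sweep_bundle(cells, path)
    jsonlite::write_json(truth, file.path(path, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  list(cells = cells, truth = truth)
}
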