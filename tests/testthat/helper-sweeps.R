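# Build small current-clamp sweeps with analytically known spike geometry,
# independent of the package's generator internals.

make_step_trace <- function(fs = 50000, dur_s = 0.7, resting = -80,
                            plateau = -50, onset = 0.1, offset = 0.6,
                            tau_ms = 10) {
  t <- (seq_len(round(dur_s * fs)) - 1) / fs
  v <- rep(resting, length(t))
  on <- t >= onset & t < offset
  v[on] <- resting + (plateau - resting) * (1 - exp(-(t[on] - onset) / (tau_ms / 1000)))
  post <- t >= offset
  v_off <- (plateau - resting) * (1 - exp(-(offset - onset) / (tau_ms / 1000)))
  v[post] <- resting + v_off * exp(-(t[post] - offset) / (tau_ms / 1000))
  v
}

add_triangle <- function(vm, fs, t_thr_s, height, rise_ms = 0.5,
                         half_width_ms = 1.5) {
  i0 <- round(t_thr_s * fs) + 1L
  rise_n <- round(rise_ms / 1000 * fs)
  fall_n <- round((2 * half_width_ms - rise_ms) / 1000 * fs)
  base <- vm[i0]
  up <- i0 + 0:rise_n
  vm[up] <- base + height * (up - i0) / rise_n
  dn <- i0 + rise_n + seq_len(fall_n)
  vm[dn] <- base + height * (1 - (dn - i0 - rise_n) / fall_n)
  vm
}

# a current-step sweep with triangular spikes at the given times (seconds
# from sweep start); heights recycled over spikes
make_spike_sweep <- function(spike_times_s, heights = 80, fs = 50000,
                             noise_sd = 0, seed = 1, step_pA = 300,
                             onset = 0.1, offset = 0.6, dur_s = 0.7,
                             resting = -80, plateau = -50,
                             rise_ms = 0.5, half_width_ms = 1.5,
                             condition = "no_light",
                             cell_id = "t1", sweep_index = 1L) {
  vm <- make_step_trace(fs, dur_s, resting, plateau, onset, offset)
  heights <- rep_len(heights, length(spike_times_s))
  for (i in seq_along(spike_times_s)) {
    vm <- add_triangle(vm, fs, spike_times_s[i], heights[i], rise_ms,
                       half_width_ms)
  }
  if (noise_sd > 0) {
    set.seed(seed)
    vm <- vm + rnorm(length(vm), 0, noise_sd)
  }
  prot <- if (condition == "light") {
    stim_protocol("single_pulse", pulse_onset_s = onset,
                  pulse_duration_ms = (offset - onset) * 1000)
  } else stim_protocol("none")
  msn_sweep(cell_id = cell_id, sweep_index = sweep_index,
            sample_rate_hz = fs, vm = vm, step_amplitude_pA = step_pA,
            step_onset_s = onset, step_offset_s = offset,
            condition = condition, protocol = prot)
}

# a flat light-protocol sweep for PSP tests
make_flat_psp_sweep <- function(level = -78, fs = 50000, dur_s = 1.3,
                                protocol = stim_protocol("single_pulse",
                                                         pulse_onset_s = 0.2,
                                                         pulse_duration_ms = 500),
                                cell_id = "p1", sweep_index = 1L,
                                pharmacology = character()) {
  msn_sweep(cell_id = cell_id, sweep_index = sweep_index,
            sample_rate_hz = fs, vm = rep(level, round(dur_s * fs)),
            step_amplitude_pA = 0, condition = "light", protocol = protocol,
            pharmacology = pharmacology)
}

# small noiseless f-I cohort with per-cell rheobase offsets
make_fi_cohort <- function(n_cells = 3, noise_sd = 0, isi_jitter = 0,
                           seed = 1, light_latency_delta = -10,
                           light_isi_delta = 5, light_extra = 1,
                           extra_steps = 6) {
  lapply(seq_len(n_cells), function(i) {
    rheo <- c(150, 100, 200)[(i - 1) %% 3 + 1]
    first <- which(50 * 1:20 > rheo)[1]
    par <- fi_cell_params(rheobase_pA = rheo,
                          block_onset_step_index = first + 4,
                          light_extra_full_steps = light_extra,
                          light_latency_delta_ms = light_latency_delta,
                          light_isi_delta_ms = light_isi_delta,
                          noise_sd_mV = noise_sd, isi_jitter_ms = isi_jitter)
    generate_fi_cell(par, n_steps = first + extra_steps, seed = seed + i,
                     cell_id = sprintf("c%03d", i))
  })
}
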