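# Ground-truth generators: determinism, closed-form spike counts, kernel
# superposition, exact class mixtures.

test_that("f-I generation is a pure function of its seed", {
  par <- fi_cell_params()
  g1 <- generate_fi_cell(par, seed = 9)
  g2 <- generate_fi_cell(par, seed = 9)
  g3 <- generate_fi_cell(par, seed = 10)
  expect_identical(g1$cell, g2$cell)
  expect_identical(g1$truth, g2$truth)
  expect_false(identical(g1$cell$sweeps[[9]]$vm, g3$cell$sweeps[[9]]$vm))
})

test_that("spike counts follow the closed-form rate rule", {
  # gain 0.08 Hz/pA, rheobase 150 pA: 400 pA -> 0.08 * 250 * 0.5 = 10 spikes
  par <- fi_cell_params(noise_sd_mV = 0, isi_jitter_ms = 0,
                        block_onset_step_index = 9)
  g <- generate_fi_cell(par, n_steps = 9, seed = 1)
  s400 <- Filter(function(s) s$step_amplitude_pA == 400 &&
                   s$condition == "no_light", g$cell$sweeps)[[1]]
  expect_identical(nrow(detect_aps(s400)), 10L)
  # below rheobase: no spikes, and the trace returns to rest after the step
  s100 <- Filter(function(s) s$step_amplitude_pA == 100 &&
                   s$condition == "no_light", g$cell$sweeps)[[1]]
  expect_identical(nrow(detect_aps(s100)), 0L)
  tail_vm <- tail(s100$vm, 100)
  expect_lt(max(abs(tail_vm - (-80))), 1.5)
})

test_that("ground-truth spike times lie inside the step and labels align", {
  cohort <- make_fi_cohort(3, noise_sd = 0.2, isi_jitter = 1, seed = 40)
  for (g in cohort) {
    for (ts in g$truth$sweeps) {
      n <- length(ts$spike_peak_times_s)
      expect_identical(length(ts$labels), n)
      if (n > 0) {
        expect_true(all(diff(ts$spike_peak_times_s) > 0))
        sw <- g$cell$sweeps[[ts$sweep_index]]
        expect_true(all(ts$spike_peak_times_s >= sw$step_onset_s))
        expect_true(all(ts$spike_peak_times_s <= sw$step_offset_s))
      }
      # attenuation starts exactly at the true block step
      cond <- ts$condition
      if (n > 0) {
        frac <- mean(ts$labels == "attenuated")
        if (ts$step_index >= g$truth$block_step[[cond]]) {
          expect_gte(frac, 0.5)
        } else {
          expect_identical(frac, 0)
        }
      }
    }
  }
})

test_that("inconsistent f-I parameters raise a parameter error", {
  expect_error(
    generate_fi_cell(fi_cell_params(rheobase_pA = 300,
                                    block_onset_step_index = 2),
                     n_steps = 10),
    class = "msnephys_parameter_error")
  expect_error(fi_cell_params(noise_sd_mV = -1),
               class = "msnephys_parameter_error")
  expect_error(psp_kernel_params(epsp_amplitude_mV = 0,
                                 true_class = "excitatory"),
               class = "msnephys_parameter_error")
})

test_that("PSP kernel superposition: doubling the amplitude doubles the trace", {
  prot <- stim_protocol("single_pulse", pulse_onset_s = 0.2,
                        pulse_duration_ms = 10)
  k1 <- psp_kernel_params(epsp_amplitude_mV = 1, ipsp_amplitude_mV = 0,
                          true_class = "excitatory")
  k2 <- psp_kernel_params(epsp_amplitude_mV = 2, ipsp_amplitude_mV = 0,
                          true_class = "excitatory")
  s1 <- generate_psp_sweep(prot, k1, noise_sd_mV = 0, seed = 1)$sweep
  s2 <- generate_psp_sweep(prot, k2, noise_sd_mV = 0, seed = 1)$sweep
  expect_equal(2 * (s1$vm - (-78)), s2$vm - (-78), tolerance = 1e-12)
  # one-kernel case: deviation never goes below rest
  expect_gte(min(s1$vm), -78)
  expect_gt(max(s1$vm), -78 + 0.9)
})

test_that("20 Hz inter-pulse decay leaves little EPSP summation", {
  # epsp tau_decay 20 ms, 50 ms inter-pulse gap = 2.5 decay constants:
  # the normalized kernel value just before the next pulse is the closed
  # form k(50 ms), about 0.12 of the peak
  prot <- stim_protocol("pulse_train", pulse_onset_s = 0.2,
                        pulse_duration_ms = 5, n_pulses = 10,
                        train_rate_hz = 20)
  k <- psp_kernel_params(epsp_amplitude_mV = 2, ipsp_amplitude_mV = 0,
                         true_class = "excitatory")
  s <- generate_psp_sweep(prot, k, noise_sd_mV = 0, seed = 1)$sweep
  fs <- s$sample_rate_hz
  dev <- s$vm - (-78)
  first_peak <- max(dev[seq(round(0.2 * fs), round(0.25 * fs))])
  pre_second <- dev[round(0.25 * fs)]   # just before pulse 2
  expect_equal(pre_second / first_peak, psp_kernel(0.05, 2, 20),
               tolerance = 0.01)
  expect_lt(pre_second / first_peak, 0.15)
  # successive peaks barely summate
  second_peak <- max(dev[seq(round(0.25 * fs), round(0.3 * fs))])
  expect_lt(second_peak / first_peak, 1.1)
})

test_that("mixed long-pulse kernels hyperpolarize the 200-300 ms window", {
  prot <- stim_protocol("single_pulse", pulse_onset_s = 0.2,
                        pulse_duration_ms = 500)
  k <- psp_kernel_params(epsp_amplitude_mV = 2, ipsp_amplitude_mV = 1.5,
                         true_class = "mixed")
  g <- generate_psp_sweep(prot, k, noise_sd_mV = 0, seed = 1)
  d <- delta_vm_window(g$sweep)
  expect_lt(d, 0)
  expect_equal(d, oracle_psp_window_mean(k, 0.2, 200, 300), tolerance = 1e-3)
})

test_that("cohort class mixtures are realized exactly and deterministically", {
  mix <- list(short_pulse = c(excitatory = 4, mixed = 2, inhibitory = 0),
              pulse_train = c(excitatory = 3, mixed = 3, inhibitory = 0),
              long_pulse = c(excitatory = 1, mixed = 3, inhibitory = 2))
  cfg <- cohort_config(n_psp_cells = 6, mixture = mix,
                       n_sweeps_per_protocol = 2)
  co1 <- generate_cohort(cfg, seed = 2)
  co2 <- generate_cohort(cfg, seed = 99)
  lab <- function(co, p) table(vapply(co$truth$psp, `[[`, character(1), p))
  for (p in names(mix)) {
    got <- lab(co1, p)
    want <- mix[[p]][mix[[p]] > 0]
    expect_identical(as.integer(got[names(want)]), as.integer(want))
    # labels identical across seeds, noise different
    expect_identical(co1$truth$psp, co2$truth$psp)
  }
  expect_false(identical(co1$cells[[1]]$sweeps[[1]]$vm,
                         co2$cells[[1]]$sweeps[[1]]$vm))
})

test_that("bad mixtures and empty cohorts are handled", {
  bad <- cohort_config(n_psp_cells = 5,
                       mixture = list(short_pulse = c(excitatory = 2,
                                                      mixed = 2,
                                                      inhibitory = 0)))
  expect_error(generate_cohort(bad, seed = 1),
               class = "msnephys_parameter_error")
  dir <- withr::local_tempdir()
  empty <- generate_cohort(cohort_config(), seed = 1, path = dir)
  expect_length(empty$cells, 0)
  expect_length(read_sweep_bundle(dir), 0)
})
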