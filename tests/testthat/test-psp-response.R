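# Evoked-PSP window metrics, response classification, breakdowns,
# transitions and the wash-on comparison.

long_prot <- stim_protocol("single_pulse", pulse_onset_s = 0.2,
                           pulse_duration_ms = 500)

test_that("baseline is the pre-onset window mean", {
  s <- make_flat_psp_sweep(level = -78)
  expect_equal(baseline_vm(s), -78)
  # linear drift of 1 mV/s: baseline = value at the window midpoint
  s2 <- s
  tt <- (seq_along(s2$vm) - 1) / s2$sample_rate_hz
  s2$vm <- -78 + tt * 1
  expect_equal(baseline_vm(s2, window_ms = 100), -78 + 0.15,
               tolerance = 1e-4)
  # noise shrinks as 1/sqrt(n)
  set.seed(1)
  reps <- vapply(1:100, function(i) {
    s3 <- s
    s3$vm <- s3$vm + rnorm(length(s3$vm), 0, 0.2)
    baseline_vm(s3)
  }, numeric(1))
  expect_lt(sd(reps), 3 * 0.2 / sqrt(0.1 * 50000))
  # a pulse at the very start of the trace cannot have a baseline
  early <- make_flat_psp_sweep(protocol = stim_protocol(
    "single_pulse", pulse_onset_s = 0.01, pulse_duration_ms = 500))
  expect_error(baseline_vm(early), class = "msnephys_analysis_error")
})

test_that("the 200-300 ms window metric matches plateaus and kernels", {
  s <- make_flat_psp_sweep()
  expect_equal(delta_vm_window(s), 0)
  # a -1.5 mV plateau covering the window
  s2 <- s
  fs <- s2$sample_rate_hz
  i1 <- round(0.35 * fs); i2 <- round(0.55 * fs)
  s2$vm[i1:i2] <- s2$vm[i1:i2] - 1.5
  expect_equal(delta_vm_window(s2), -1.5, tolerance = 1e-6)
  # window exceeding the sweep
  short <- make_flat_psp_sweep(dur_s = 0.4)
  expect_error(delta_vm_window(short), class = "msnephys_analysis_error")
  # generator mixed kernels match the analytic window mean
  k <- psp_kernel_params()
  g <- generate_psp_sweep(long_prot, k, noise_sd_mV = 0.1, seed = 5)
  expect_equal(delta_vm_window(g$sweep),
               oracle_psp_window_mean(k, 0.2, 200, 300), tolerance = 0.05)
})

test_that("flat traces classify as none; classes recover the ground truth", {
  flat <- lapply(1:5, function(i) make_flat_psp_sweep(sweep_index = i))
  expect_identical(classify_response(flat)$class, "none")
  for (cl in c("excitatory", "mixed", "inhibitory")) {
    k <- msnephys:::class_kernels(cl)
    sweeps <- lapply(1:5, function(r)
      generate_psp_sweep(long_prot, k, noise_sd_mV = 0.1,
                         seed = 40 + r)$sweep)
    call <- classify_response(sweeps)
    expect_identical(call$class, cl)
    expect_identical(call$protocol_label, "long_pulse")
  }
  # mismatched protocols refuse to average
  mix <- list(make_flat_psp_sweep(),
              make_flat_psp_sweep(protocol = stim_protocol(
                "single_pulse", pulse_onset_s = 0.2,
                pulse_duration_ms = 10), dur_s = 1.3))
  expect_error(classify_response(mix), class = "msnephys_analysis_error")
})

test_that("response calls are translation invariant except the baseline", {
  k <- psp_kernel_params()
  sweeps <- lapply(1:3, function(r)
    generate_psp_sweep(long_prot, k, noise_sd_mV = 0.1, seed = r)$sweep)
  shifted <- lapply(sweeps, function(s) { s$vm <- s$vm + 9.4; s })
  c1 <- classify_response(sweeps)
  c2 <- classify_response(shifted)
  expect_identical(c1$class, c2$class)
  expect_equal(c1$peak_depol_mV, c2$peak_depol_mV)
  expect_equal(c1$peak_hyperpol_mV, c2$peak_hyperpol_mV)
  expect_equal(c1$delta_vm_200_300_mV, c2$delta_vm_200_300_mV)
  expect_equal(c2$baseline_vm_mV, c1$baseline_vm_mV + 9.4)
})

test_that("increasing IPSP amplitude never moves the class toward excitatory", {
  rank_of <- c(excitatory = 1, none = 2, mixed = 2, inhibitory = 3)
  last_rank <- 0
  for (ipsp in c(0, 0.2, 0.8, 1.5, 3)) {
    k <- if (ipsp == 0) {
      psp_kernel_params(epsp_amplitude_mV = 1.5, ipsp_amplitude_mV = 0,
                        true_class = "excitatory")
    } else {
      psp_kernel_params(epsp_amplitude_mV = 1.5, ipsp_amplitude_mV = ipsp,
                        true_class = "mixed")
    }
    sweeps <- lapply(1:3, function(r)
      generate_psp_sweep(long_prot, k, noise_sd_mV = 0, seed = r)$sweep)
    cl <- classify_response(sweeps)$class
    expect_gte(rank_of[[cl]], last_rank)
    last_rank <- rank_of[[cl]]
  }
})

test_that("breakdown reproduces the printed worked-example percentages", {
  expect_identical(
    unname(class_percentages(c(excitatory = 10, mixed = 34,
                               inhibitory = 12), total = 57)),
    c(18, 60, 21))
  expect_identical(
    unname(class_percentages(c(excitatory = 48, mixed = 11), total = 62)),
    c(77, 18))
  expect_identical(
    unname(class_percentages(c(excitatory = 41, mixed = 21), total = 63)),
    c(65, 33))
  # single call -> 100% its class
  one <- data.frame(cell_id = "x", protocol_label = "long_pulse",
                    class = "mixed", delta_vm_200_300_mV = NA,
                    peak_depol_mV = 1, peak_hyperpol_mV = 1)
  b <- breakdown(one)
  expect_identical(b$percent[b$class == "mixed"], 100)
})

test_that("transition tables count fully characterized cells and keep marginals", {
  # constructed cohort: every long-pulse inhibitory cell is mixed under the
  # pulse train
  calls <- rbind(
    data.frame(cell_id = sprintf("c%d", 1:6),
               protocol_label = "short_pulse",
               class = c("excitatory", "excitatory", "excitatory",
                         "excitatory", "mixed", "excitatory")),
    data.frame(cell_id = sprintf("c%d", 1:6),
               protocol_label = "pulse_train",
               class = c("excitatory", "excitatory", "mixed", "mixed",
                         "mixed", "mixed")),
    data.frame(cell_id = sprintf("c%d", 1:6),
               protocol_label = "long_pulse",
               class = c("excitatory", "mixed", "mixed", "inhibitory",
                         "inhibitory", "inhibitory")),
    data.frame(cell_id = "c7", protocol_label = "short_pulse",
               class = "excitatory"))   # incomplete cell, must drop
  calls$delta_vm_200_300_mV <- NA
  calls$peak_depol_mV <- 1
  calls$peak_hyperpol_mV <- 0
  tt <- transition_table(calls)
  expect_identical(attr(tt, "total"), 6L)
  expect_identical(sum(tt$n), 6L)
  # no inhibitory-at-long-pulse cell was excitatory under the train
  expect_identical(sum(tt$n[tt$long_pulse == "inhibitory" &
                              tt$pulse_train == "excitatory"]), 0L)
  # marginals match the per-protocol distributions of the complete cells
  marg <- tapply(tt$n, tt$long_pulse, sum)
  expect_identical(as.integer(marg[c("excitatory", "mixed", "inhibitory")]),
                   c(1L, 2L, 3L))
})

test_that("wash-on removes the slow hyperpolarization and pairs cells", {
  cfg <- cohort_config(n_washon_cells = 9, n_sweeps_per_protocol = 3)
  co <- generate_cohort(cfg, seed = 12)
  w <- washon_effect(co$cells)
  expect_identical(nrow(w), 9L)
  expect_true(all(w$delta_pre < 0))
  expect_true(all(abs(w$delta_post) < abs(w$delta_pre)))
  r <- wilcoxon_signed_rank(w$delta_pre, w$delta_post)
  expect_lt(r$p_value, 0.05)
  # identical pre/post phases: zero deltas, flagged non-significant result
  same <- wilcoxon_signed_rank(w$delta_pre, w$delta_pre)
  expect_equal(same$p_value, 1)
  # a DC offset on the post phase leaves deltas unchanged
  shifted <- lapply(co$cells, function(cell) {
    cell$sweeps <- lapply(cell$sweeps, function(s) {
      if ("cgp_post" %in% s$pharmacology) s$vm <- s$vm + 5
      s
    })
    cell
  })
  w2 <- washon_effect(shifted)
  expect_equal(w2$delta_post, w$delta_post, tolerance = 1e-9)
  # unmatched phases raise
  pre_only <- cell_recording("p", list(make_flat_psp_sweep(
    pharmacology = c("ttx_4ap_zd", "cgp_pre"))),
    access_resistance_MOhm = 10)
  expect_error(washon_effect(list(pre_only)),
               class = "msnephys_analysis_error")
})
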