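# Brute-force enumeration oracles for the nonparametric tests. These stay
# independent of the implementation path (they never call wilcox.test).

# Exact two-sided signed-rank p-value by enumerating all 2^n sign patterns.
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  stopifnot(n >= 1, n <= 14, !any(duplicated(abs(d))))
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  center <- n * (n + 1) / 4
  p <- if (v_obs > center) mean(v_all >= v_obs) else mean(v_all <= v_obs)
  min(1, 2 * p)
}

# Exact two-sided Mann-Whitney p-value by enumerating all group-A rank
# subsets.
oracle_mann_whitney_p <- function(a, b) {
  na <- length(a); nb <- length(b)
  stopifnot(!any(duplicated(c(a, b))), choose(na + nb, na) <= 2e5)
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  combos <- utils::combn(na + nb, na)
  ranks_all <- rank(seq_len(na + nb))
  u_all <- apply(combos, 2, function(ix) sum(ranks_all[ix]) - na * (na + 1) / 2)
  center <- na * nb / 2
  p <- if (u_obs > center) mean(u_all >= u_obs) else mean(u_all <= u_obs)
  min(1, 2 * p)
}

# Analytic mean of the noise-free PSP kernel sum over a window, by direct
# evaluation on a fine grid (independent of the generator's sampling).
oracle_psp_window_mean <- function(kernels, onset_s, t0_ms, t1_ms,
                                   n_grid = 20001) {
  tt <- seq(onset_s + t0_ms / 1000, onset_s + t1_ms / 1000,
            length.out = n_grid)
  e <- if (kernels$epsp_amplitude_mV > 0) {
    kernels$epsp_amplitude_mV *
      psp_kernel(tt - onset_s, kernels$epsp_tau_rise_ms,
                 kernels$epsp_tau_decay_ms)
  } else 0
  i <- if (kernels$ipsp_amplitude_mV > 0) {
    kernels$ipsp_amplitude_mV *
      psp_kernel(tt - onset_s - kernels$ipsp_lag_ms / 1000,
                 kernels$ipsp_tau_rise_ms, kernels$ipsp_tau_decay_ms)
  } else 0
  mean(e - i)
}
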