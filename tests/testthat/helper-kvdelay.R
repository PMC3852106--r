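# shared fixture builders (all synthetic, generated at test time)

passive_params <- function(R_MOhm = 600, C_pF = 88, E = -82) {
  # leak-only cell: R_in = 1/g_L, tau = R*C
  sim_cell_params(C_m = C_pF, g_L = 1000 / R_MOhm, E_L = E, g_Na = 0,
                  g_Kdr = 0, g_Kir = 0, g_D = 0)
}

# delay-conductance-only cell for closed-form voltage-clamp checks
gd_only_params <- function(g_D = 1, ...) {
  sim_cell_params(g_L = 0, g_Na = 0, g_Kdr = 0, g_Kir = 0, g_D = g_D, ...)
}

# triangular synthetic AP rising to peak_V then back, on a flat baseline
toy_spike_sweep <- function(peak_V = 40, base = -80, peak_time = 0.49,
                            half_ms = 1, dt = 1e-4, T = 1) {
  n <- round(T / dt)
  t <- (seq_len(n) - 1) * dt
  v <- rep(base, n)
  tri <- pmax(0, 1 - abs(t - peak_time) / (half_ms / 1000))
  v <- v + tri * (peak_V - base)
  sweep(v, dt = dt, kind = "voltage",
        protocol = step_protocol(80, onset = 0.1, duration = 0.8))
}

oversampled_peaks <- function(sw, factor = 10, peak_min = 0,
                              lockout_ms = 2) {
  # brute-force oracle: local maxima on a spline-interpolated trace
  t <- sweep_time(sw)
  tf <- seq(t[1], t[length(t)], by = sw$dt / factor)
  vf <- stats::spline(t, sw$samples, xout = tf)$y
  cand <- which(diff(sign(diff(vf))) == -2) + 1L
  cand <- cand[vf[cand] > peak_min]
  if (!length(cand)) return(numeric(0))
  keep <- cand[1]
  for (i in cand[-1])
    if (tf[i] - tf[keep[length(keep)]] >= lockout_ms / 1000)
      keep <- c(keep, i)
  tf[keep]
}

steady_dv_for_test <- function(sw) kvdelay:::steady_dv(sw)
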