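test_that("resting potential is the window mean and matches the model steady state", {
  flat <- sweep(rep(-82.4, 5000), dt = 1e-4, kind = "voltage")
  expect_equal(measure_vrest(flat), -82.4)
  t <- (0:4999) * 1e-4
  sine <- sweep(-80 + 2 * sin(2 * pi * 20 * t), dt = 1e-4, kind = "voltage")
  expect_equal(measure_vrest(sine), -80, tolerance = 1e-3)
  expect_error(measure_vrest(flat, window = c(0, 0.01)), "window")
  p <- granule_preset("naive")
  sw <- simulate_current_clamp(p, step_protocol(0, 0, 0.1), dt = 5e-5, T = 1)
  expect_equal(measure_vrest(sw), model_rest(p), tolerance = 0.5)
})

test_that("input resistance comes from the subthreshold steady-state I-V slope", {
  # synthetic: +-10 pA -> +-5 mV = 500 MOhm
  mk <- function(amp, dv) {
    n <- 1000
    v <- rep(-80, n)
    on <- (1:n - 1) * 1e-3 >= 0.2
    v[on] <- -80 + dv
    sweep(v, dt = 1e-3, kind = "voltage",
          protocol = step_protocol(amp, onset = 0.2, duration = 0.8))
  }
  s <- sweep_set(list(mk(-10, -5), mk(10, 5)))
  expect_equal(measure_rin(s)$R_in, 500, tolerance = 1e-6)
  # passive model recovers its programmed resistance within 2%
  p <- passive_params(R_MOhm = 600)
  sws <- lapply(c(-10, -5, 5, 10), function(a)
    simulate_current_clamp(p, step_protocol(a, onset = 0.1, duration = 1),
                           dt = 5e-5, T = 1.2))
  s2 <- sweep_set(sws)
  expect_equal(measure_rin(s2)$R_in, 600, tolerance = 0.02)
  # a spiking sweep must be excluded without changing the result
  spiking <- toy_spike_sweep()
  s3 <- sweep_set(c(sws, list(sweep(spiking$samples, dt = 5e-5,
                                    kind = "voltage",
                                    protocol = step_protocol(300, 0.1, 1)))))
  expect_equal(measure_rin(s3)$R_in, measure_rin(s2)$R_in)
  expect_error(measure_rin(sweep_set(sws[1])), "insufficient")
})

test_that("membrane time constant: slow component of the double-exponential fit", {
  t <- (0:7999) * 2.5e-4  # 2 s at 4 kHz
  mk_resp <- function(f) {
    v <- rep(-80, length(t))
    on <- t >= 0.2
    v[on] <- -80 + f((t[on] - 0.2) * 1000)
    sweep(v, dt = 2.5e-4, kind = "voltage",
          protocol = step_protocol(-8, onset = 0.2, duration = 1.8))
  }
  # pure single exponential, tau 30 ms
  single <- mk_resp(function(ms) -4 * (1 - exp(-ms / 30)))
  f1 <- fit_membrane_time_constant(single)
  expect_equal(f1$tau_m, 30, tolerance = 0.02)
  expect_lt(abs(f1$amplitudes["fast"]), 0.05 * abs(f1$amplitudes["slow"]))
  # 3 ms + 30 ms mixture: slow component reported
  dbl <- mk_resp(function(ms) -1.5 * (1 - exp(-ms / 3)) -
                   3 * (1 - exp(-ms / 30)))
  f2 <- fit_membrane_time_constant(dbl)
  expect_equal(f2$tau_m, 30, tolerance = 0.05)
  expect_equal(f2$tau_fast, 3, tolerance = 0.2)
})

test_that("capacitance follows tau_m / R_0 and is recovered from the simulator", {
  expect_equal(estimate_capacitance(30, 600), 50)
  expect_equal(estimate_capacitance(60, 600), 100)
  p <- passive_params(R_MOhm = 600, C_pF = 88)
  proto <- step_protocol(-5, onset = 0.1, duration = 1.2)
  sw <- simulate_current_clamp(p, proto, dt = 5e-5, T = 1.4)
  fit <- fit_membrane_time_constant(sw)
  R0 <- steady_dv_for_test(sw) / (-5) * 1000
  expect_equal(estimate_capacitance(fit$tau_m, R0), 88, tolerance = 0.05)
})

test_that("AP detection: empty below threshold, width at -5 mV, oracle agreement", {
  sub <- sweep(rep(-80, 1000) + 5 * sin((1:1000) / 50), dt = 1e-4,
               kind = "voltage")
  expect_identical(nrow(detect_aps(sub)), 0L)
  # triangular spike crossing -5 mV for a known duration
  spk <- toy_spike_sweep(peak_V = 40, base = -80, half_ms = 2)
  # -5 mV is 75/120 of the way up a 2 ms half-width triangle
  expected_width <- 2 * 2 * (1 - 75 / 120)
  aps <- detect_aps(spk)
  expect_identical(nrow(aps), 1L)
  expect_equal(aps$width_ms, expected_width, tolerance = 0.05)
  # detection agrees with a brute-force oversampled oracle on simulator sweeps
  p <- granule_preset("naive")
  set.seed(7)
  for (amp in sample(seq(60, 220, 20), 6)) {
    sw <- simulate_current_clamp(p, step_protocol(amp, 0.1, 0.8), dt = 5e-5,
                                 T = 1)
    got <- detect_aps(sw)
    oracle <- oversampled_peaks(sw)
    expect_identical(nrow(got), length(oracle))
    if (nrow(got)) expect_lt(max(abs(got$peak_time - oracle)), sw$dt + 1e-12)
  }
})

test_that("AP threshold is stable under 10x oversampling", {
  p <- granule_preset("naive")
  proto <- step_protocol(65, onset = 0.1, duration = 1)
  coarse <- detect_aps(simulate_current_clamp(p, proto, dt = 2.5e-5, T = 1.2))
  fine <- detect_aps(simulate_current_clamp(p, proto, dt = 2.5e-6, T = 1.2))
  expect_gt(nrow(coarse), 0)
  expect_equal(coarse$threshold_V[1], fine$threshold_V[1], tolerance = 2)
})

test_that("rheobase search respects grid semantics and the delay conductance", {
  provider <- function(amp) {
    if (amp >= 63) toy_spike_sweep() else
      sweep(rep(-80, 1000), dt = 1e-4, kind = "voltage",
            protocol = step_protocol(amp, onset = 0.1, duration = 0.8))
  }
  expect_equal(find_rheobase(provider, grid = seq(0, 200, 1))$rheobase, 63)
  expect_equal(find_rheobase(provider, grid = seq(0, 200, 5))$rheobase, 65)
  expect_true(find_rheobase(provider, grid = seq(0, 50, 5))$censored)
  p <- granule_preset("naive")
  sim_provider <- function(p) function(amp)
    simulate_current_clamp(p, step_protocol(amp, onset = 0.05, duration = 1),
                           dt = 5e-5, T = 1.1)
  r_ctrl <- find_rheobase(sim_provider(p), grid = seq(20, 120, 5))
  r_dtx <- find_rheobase(sim_provider(apply_drug(p, "DTX", 1)),
                         grid = seq(20, 120, 5))
  expect_lte(r_dtx$rheobase, r_ctrl$rheobase)
})

test_that("response delay is onset-to-first-peak with censoring", {
  spk <- toy_spike_sweep(peak_time = 0.49)
  d <- measure_delay(spk)
  expect_false(d$censored)
  expect_equal(d$delay, 390, tolerance = 0.2)
  quiet <- sweep(rep(-80, 1000), dt = 1e-4, kind = "voltage",
                 protocol = step_protocol(10, onset = 0.1, duration = 0.8))
  expect_true(measure_delay(quiet)$censored)
  expect_true(is.na(measure_delay(quiet)$delay))
})

test_that("I/O curves report counts and initial frequency with flags", {
  two <- toy_spike_sweep()
  v <- two$samples
  # add a second spike 50 ms after the first
  t <- sweep_time(two)
  tri <- pmax(0, 1 - abs(t - 0.54) / 1e-3)
  two$samples <- v + tri * 120
  s <- sweep_set(list(two, toy_spike_sweep()))
  s$sweeps[[1]]$protocol <- step_protocol(120, onset = 0.1, duration = 0.8)
  io <- io_curves(s)
  expect_equal(io$initial_freq[io$I == 120], 20, tolerance = 0.01)
  expect_identical(io$ap_count[io$I == 120], 2L)
  expect_identical(io$ap_count[io$I == 80], 1L)
  expect_true(is.na(io$initial_freq[io$I == 80]))
})

test_that("first-spike jitter: SD and CV of first-AP delays", {
  mk <- function(delay_ms) toy_spike_sweep(peak_time = 0.1 + delay_ms / 1000)
  expect_equal(first_spike_jitter(lapply(c(100, 100, 100), mk))$jitter_sd, 0,
               tolerance = 1e-6)
  j <- first_spike_jitter(lapply(c(80, 100, 120), mk))
  expect_equal(j$jitter_sd, 20, tolerance = 0.01)
  expect_equal(j$jitter_cv, 0.2, tolerance = 0.01)
  expect_error(first_spike_jitter(lapply(c(100, 100), mk)), "at least 3")
})

test_that("jitter SD grows with the delay conductance while CV stays of the same order", {
  jit <- function(scale) {
    p <- granule_preset("naive")
    p$g_D <- p$g_D * scale
    p$noise_sd <- 30
    sws <- lapply(1:10, function(s)
      simulate_current_clamp(p, step_protocol(55, 0.1, 2), T = 2.2,
                             seed = 1000 * scale + s))
    first_spike_jitter(sws)
  }
  j1 <- jit(1)
  j10 <- jit(10)
  expect_gt(j10$jitter_sd, j1$jitter_sd)
  expect_gt(mean(j10$delays), mean(j1$delays))
  ratio <- j10$jitter_cv / j1$jitter_cv
  expect_gt(ratio, 0.2)
  expect_lt(ratio, 5)
})

test_that("synaptic I/O: EPSP1 input, AP output, paired-pulse ratio", {
  tr <- generate_synaptic_train(amplitude = 30, facilitation_ratio = 1.4)
  p <- passive_params(R_MOhm = 600)
  v <- simulate_injection(p, tr, dt = attr(tr, "dt"))
  res <- synaptic_io(v, tr)
  expect_equal(res$paired_pulse_ratio, 1.4, tolerance = 0.05)
  expect_false(res$ppr_flagged)
  expect_gt(res$epsp1_amplitude, 0)
  expect_false(res$epsp1_flagged)
  expect_identical(res$ap_count, 0L)
  # zero-amplitude train: undefined ratio, flagged
  tr0 <- generate_synaptic_train(amplitude = 0)
  v0 <- simulate_injection(p, tr0, dt = attr(tr0, "dt"))
  res0 <- synaptic_io(v0, tr0)
  expect_true(res0$ppr_flagged)
  expect_true(is.na(res0$paired_pulse_ratio))
  # AP contamination of the first-EPSP window is flagged
  vk <- v
  t <- sweep_time(vk)
  w <- t >= attr(tr, "pulse_times")[1] & t < attr(tr, "pulse_times")[1] + 0.01
  vk$samples[w][1:10] <- 30
  resk <- synaptic_io(vk, tr)
  expect_true(resk$epsp1_flagged)
})

test_that("delay and width are invariant under a uniform voltage offset", {
  p <- granule_preset("naive")
  proto <- step_protocol(80, onset = 0.1, duration = 1)
  sw <- simulate_current_clamp(p, proto, dt = 5e-5, T = 1.2)
  shifted <- sw
  shifted$samples <- sw$samples + 3
  a1 <- detect_aps(sw, peak_min = 0, width_level = -5)
  a2 <- detect_aps(shifted, peak_min = 3, width_level = -2)
  expect_equal(a2$peak_time, a1$peak_time)
  expect_equal(a2$width_ms, a1$width_ms, tolerance = 1e-6)
})
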