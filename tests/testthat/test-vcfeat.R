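vc_family <- function(p, steps = seq(-110, 10, 10), dur = 2.5, dt = 2e-4,
                      seed = NULL) {
  proto <- vc_step_protocol(-90, steps = steps, step_duration = dur)
  simulate_voltage_clamp(p, proto, dt = dt, seed = seed)
}

test_that("subtracting a family from itself yields zero traces and peaks", {
  p <- granule_preset("naive")
  p$g_Na <- 0
  fam <- vc_family(p, steps = c(-60, -20, 0), dur = 0.5)
  subs <- subtract_currents(fam, fam)
  for (s in subs) {
    expect_lt(max(abs(s$trace$samples)), 1e-12)
    expect_equal(s$peak, 0, tolerance = 1e-12)
  }
})

test_that("subtraction is linear: a common current cancels", {
  p <- granule_preset("naive")
  p$g_Na <- 0
  a <- vc_family(p, steps = c(-40, 0), dur = 0.3)
  b <- vc_family(apply_drug(p, "DTX", 1), steps = c(-40, 0), dur = 0.3)
  s1 <- subtract_currents(a, b)
  addc <- function(fam, c) lapply(fam, function(sw) {
    out <- sw
    out$samples <- sw$samples + c
    attributes(out) <- attributes(sw)
    out$samples <- sw$samples + c
    out
  })
  s2 <- subtract_currents(addc(a, 7.5), addc(b, 7.5))
  expect_equal(s2[[1]]$trace$samples, s1[[1]]$trace$samples,
               tolerance = 1e-12)
  expect_equal(s2[[2]]$peak, s1[[2]]$peak, tolerance = 1e-12)
})

test_that("mismatched protocols are rejected with the differing steps named", {
  p <- granule_preset("naive")
  a <- vc_family(p, steps = c(-40, 0), dur = 0.2)
  b <- vc_family(p, steps = c(-40, 10), dur = 0.2)
  expect_error(subtract_currents(a, b), "step 2")
  expect_error(subtract_currents(a, b[1]), "protocol mismatch")
})

test_that("subtraction recovers the delay-current steady state on the KA preset", {
  p <- granule_preset("KA")
  p$g_Na <- 0
  ctrl <- vc_family(p, steps = 0, dur = 4)
  drug <- vc_family(apply_drug(p, "DTX", 1), steps = 0, dur = 4)
  sub <- subtract_currents(ctrl, drug)[[1]]
  ainf <- 1 / (1 + exp((p$act$V50 - 0) / p$act$k))
  binf <- 1 / (1 + exp((0 - p$inact$V50) / p$inact$k))
  iss <- p$g_D * ainf * binf * (0 - p$E_K)
  expect_equal(tail(sub$trace$samples, 1), iss, tolerance = 0.01 * abs(iss))
})

test_that("current density scales as peak over capacitance", {
  expect_equal(current_density(14.9, 87.6), 0.17, tolerance = 0.002)
  expect_equal(current_density(0, 88), 0)
  expect_equal(current_density(10, 44), 2 * current_density(10, 88))
})

test_that("activation fit recovers a noiseless Boltzmann and its midpoint value", {
  V <- seq(-110, 10, 10)
  Vrev <- -104.3
  G <- 2 / (1 + exp((-32.3 - V) / 17.1))
  peaks <- data.frame(V = V, I = G * (V - Vrev))
  fit <- fit_activation(peaks, V_rev = Vrev)
  expect_equal(fit$V50, -32.3, tolerance = 0.1)
  expect_equal(fit$k, 17.1, tolerance = 0.1)
  # curve value at V50 is half the fitted maximum
  at_v50 <- fit$scale / (1 + exp((fit$V50 - fit$V50) / fit$k))
  expect_equal(at_v50, 0.5 * fit$scale)
  expect_error(fit_activation(data.frame(V = V, I = 0 * V), V_rev = Vrev),
               "all-zero")
})

test_that("activation fit agrees with a dense grid-search oracle", {
  V <- seq(-110, 10, 10)
  Vrev <- -104.3
  set.seed(5)
  for (i in 1:5) {
    v50 <- runif(1, -50, -25)
    k <- runif(1, 12, 20)
    G <- 1.5 / (1 + exp((v50 - V) / k)) + rnorm(length(V), 0, 0.02)
    peaks <- data.frame(V = V, I = G * (V - Vrev))
    fit <- fit_activation(peaks, V_rev = Vrev)
    # brute force over a dense (V50, k) grid with analytic best scale
    Gm <- G[abs(V - Vrev) >= 10]
    Vm <- V[abs(V - Vrev) >= 10]
    grid <- expand.grid(V50 = seq(-60, -15, 0.25), k = seq(8, 25, 0.25))
    sse <- mapply(function(v, kk) {
      b <- 1 / (1 + exp((v - Vm) / kk))
      A <- sum(b * Gm) / sum(b * b)
      sum((Gm - A * b)^2)
    }, grid$V50, grid$k)
    bestg <- grid[which.min(sse), ]
    expect_equal(fit$V50, bestg$V50, tolerance = 0.5)
    expect_equal(fit$k, bestg$k, tolerance = 0.5)
  }
})

test_that("inactivation fit recovers the decreasing Boltzmann with extreme prepulses", {
  Vp <- seq(-120, 30, 10)
  y <- 1 / (1 + exp((Vp - (-41.7)) / 14.1))
  fit <- fit_inactivation(data.frame(V_pre = Vp, I = 18 * y))
  expect_equal(fit$V50, -41.7, tolerance = 0.5)
  expect_equal(fit$k, 14.1, tolerance = 0.2)
  # fully inactivating prepulse -> ~0; most hyperpolarized -> ~1 (normalized)
  curve <- fit$scale / (1 + exp((Vp - fit$V50) / fit$k))
  expect_lt(curve[length(Vp)] / max(curve), 0.02)
  expect_gt(curve[1] / fit$scale, 0.98)
})

test_that("inactivation kinetics: mono-exponential decay fit", {
  t <- seq(0, 2.4, by = 2e-4)
  y <- 120 * exp(-t * 1000 / 250) + 3
  sw <- sweep(y, dt = 2e-4, kind = "current",
              protocol = vc_step_protocol(-90, 0, 2.5))
  fit <- fit_tau_inact(sw, from = 0)
  expect_equal(fit$tau_inact, 250, tolerance = 1 / 250)
  expect_equal(fit$offset, 3, tolerance = 0.01)
  flat <- sweep(rep(5, 1000), dt = 2e-4, kind = "current",
                protocol = vc_step_protocol(-90, 0, 0.2))
  expect_error(fit_tau_inact(flat, from = 0), "no decay")
})

test_that("simulated KA family recovers its programmed inactivation time constant", {
  p <- granule_preset("KA")
  p$g_Na <- 0
  ctrl <- vc_family(p, steps = 0, dur = 2.5)
  drug <- vc_family(apply_drug(p, "DTX", 1), steps = 0, dur = 2.5)
  sub <- subtract_currents(ctrl, drug)[[1]]
  fit <- fit_tau_inact(sub)
  expect_equal(fit$tau_inact, 378, tolerance = 0.05)
})

test_that("reversal potential: two-point line, simulator recovery, degenerate flag", {
  fit <- estimate_reversal(data.frame(V = c(-100, -80), I = c(-1, 19)),
                           range = c(-110, -50))
  expect_equal(fit$V_rev, -99)
  # tail currents from the simulator cross at the programmed E_K
  p <- granule_preset("naive")
  p$g_Na <- 0
  tp <- vc_step_protocol(-90, steps = seq(-110, 30, 20), step_duration = 0.05,
                         prepulse = list(potentials = 10, duration = 0.3))
  ctrl <- simulate_voltage_clamp(p, tp, dt = 2e-5)
  drug <- simulate_voltage_clamp(apply_drug(p, "DTX", 1), tp, dt = 2e-5)
  subs <- subtract_currents(ctrl, drug, blank_ms = 0.5, smooth_ms = 0)
  tails <- vapply(subs, function(s) {
    t <- sweep_time(s$trace)
    mean(s$trace$samples[t >= s$test_onset + 5e-4 &
                           t < s$test_onset + 1.5e-3])
  }, numeric(1))
  rf <- estimate_reversal(data.frame(V = seq(-110, 30, 20), I = tails),
                          range = c(-110, -50))
  expect_equal(rf$V_rev, p$E_K, tolerance = 2)
  expect_false(rf$wide_ci)
  # pure noise: crossing poorly determined
  set.seed(9)
  noisy <- estimate_reversal(data.frame(V = seq(-110, -50, 10),
                                        I = rnorm(7, 0, 5)),
                             range = c(-110, -50))
  expect_true(noisy$wide_ci)
})

test_that("Nernst potential matches the recording solutions and closed forms", {
  expect_equal(nernst(155, 2.5, 293.15), -104.3, tolerance = 0.05)
  expect_equal(nernst(10, 10), 0)
  expect_equal(nernst(100, 10, 293.15), -58.2, tolerance = 0.05)
})
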