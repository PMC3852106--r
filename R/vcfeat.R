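#' Isolate the drug-sensitive current by offline subtraction
#'
#' Pointwise subtraction of the post-drug current family from the control
#' family, step by step. The peak is the signed extremum of the subtracted
#' trace within the test step, after blanking the initial
#' capacitive-artifact window.
#'
#' @param ctrl,drug Lists of current [sweep()]s from matched protocols
#'   (same steps, dt, durations), e.g. [simulate_voltage_clamp()] output
#'   before and after [apply_drug()].
#' @param blank_ms Post-step blanking window in ms (default 5).
#' @param smooth_ms Boxcar width in ms applied to the subtracted trace
#'   before peak extraction (default 2; 0 disables). Counters the upward
#'   bias of a signed extremum taken over many noisy samples, in the
#'   spirit of the low-pass filtering applied to acquired currents.
#' @return List of `subtracted_current` objects, each with `trace` (a
#'   current [sweep()]), `peak` (pA), `peak_time` (s), `step_V` (mV) and
#'   `test_onset` (s).
#' @export
subtract_currents <- function(ctrl, drug, blank_ms = 5, smooth_ms = 2) {
  if (length(ctrl) != length(drug))
    stop("protocol mismatch: ", length(ctrl), " control vs ", length(drug),
         " drug sweeps")
  mism <- character(0)
  for (i in seq_along(ctrl)) {
    if (length(ctrl[[i]]) != length(drug[[i]]) ||
        abs(ctrl[[i]]$dt - drug[[i]]$dt) > 1e-12 ||
        !isTRUE(all.equal(attr(ctrl[[i]], "step_V"), attr(drug[[i]], "step_V"))))
      mism <- c(mism, sprintf("step %d (%g vs %g mV)", i,
                              attr(ctrl[[i]], "step_V"),
                              attr(drug[[i]], "step_V")))
  }
  if (length(mism))
    stop("protocol mismatch at: ", paste(mism, collapse = ", "))
  lapply(seq_along(ctrl), function(i) {
    d <- ctrl[[i]]$samples - drug[[i]]$samples
    sw <- sweep(d, dt = ctrl[[i]]$dt, kind = "current",
                protocol = ctrl[[i]]$protocol)
    t <- sweep_time(sw)
    on <- attr(ctrl[[i]], "test_onset")
    if (is.null(on)) on <- 0
    ds <- d
    w <- max(1L, round(smooth_ms / 1000 / sw$dt))
    if (w > 1L) ds <- as.numeric(stats::filter(d, rep(1 / w, w), sides = 2))
    sel <- which(t >= on + blank_ms / 1000 & !is.na(ds))
    pk <- sel[which.max(abs(ds[sel]))]
    structure(list(trace = sw, peak = ds[pk], peak_time = t[pk],
                   step_V = attr(ctrl[[i]], "step_V"),
                   prepulse_V = attr(ctrl[[i]], "prepulse_V"),
                   test_onset = on),
              class = "subtracted_current")
  })
}

#' Peak-current table of a subtracted family
#' @param subs List of `subtracted_current` objects.
#' @return data.frame with `V` (test potential, mV), `V_pre` (prepulse, mV
#'   or NA) and `I` (peak, pA).
#' @export
peak_table <- function(subs) {
  do.call(rbind, lapply(subs, function(s)
    data.frame(V = s$step_V, V_pre = s$prepulse_V, I = s$peak)))
}

#' Isochronal peak table of a subtracted family
#'
#' Locates the peak time on the family member with the largest smoothed
#' peak and reads the smoothed current of every member at that same time.
#' For noisy recordings this is preferable to per-trace extrema: the signed
#' extremum of a near-zero trace over thousands of samples is biased away
#' from zero by the noise, which distorts the small-current limbs of
#' activation/inactivation curves.
#'
#' @param subs List of `subtracted_current` objects (shared protocol).
#' @param smooth_ms Boxcar width in ms for the read-out (default 10).
#' @param blank_ms Post-step blanking window in ms.
#' @return data.frame with `V`, `V_pre`, `I` (pA at the family peak time)
#'   and attribute `"peak_time"` (s).
#' @export
family_peaks <- function(subs, smooth_ms = 10, blank_ms = 5) {
  sm <- lapply(subs, function(s) {
    w <- max(1L, round(smooth_ms / 1000 / s$trace$dt))
    x <- if (w > 1L)
      as.numeric(stats::filter(s$trace$samples, rep(1 / w, w), sides = 2))
    else s$trace$samples
    x
  })
  t <- sweep_time(subs[[1]]$trace)
  on <- max(vapply(subs, `[[`, numeric(1), "test_onset"))
  sel <- which(t >= on + blank_ms / 1000)
  amps <- vapply(sm, function(x) max(abs(x[sel]), na.rm = TRUE), numeric(1))
  ref <- which.max(amps)
  ipk <- sel[which.max(abs(sm[[ref]][sel]))]
  out <- do.call(rbind, lapply(seq_along(subs), function(i)
    data.frame(V = subs[[i]]$step_V, V_pre = subs[[i]]$prepulse_V,
               I = sm[[i]][ipk])))
  attr(out, "peak_time") <- t[ipk]
  out
}

#' Current density
#' @param peak Peak current in pA (or a `subtracted_current`).
#' @param C_m Cell capacitance in pF.
#' @return Density in pA/pF.
#' @export
current_density <- function(peak, C_m) {
  if (inherits(peak, "subtracted_current")) peak <- peak$peak
  stopifnot(C_m > 0)
  peak / C_m
}

boltz_up <- function(V, V50, k) 1 / (1 + exp((V50 - V) / k))
boltz_down <- function(V, V50, k) 1 / (1 + exp((V - V50) / k))

fit_boltzmann <- function(x, y, increasing, k0 = 15, n_restarts = 5) {
  if (all(abs(y) < 1e-12)) stop("fit error: all-zero currents/conductances")
  ymax <- max(y)
  v50_0 <- x[which.min(abs(y - ymax / 2))]
  best <- NULL
  # fixed jittered restarts (V50 offset mV, k offset mV)
  starts <- rbind(c(0, 0), c(10, 5), c(-10, -5), c(15, -4),
                  c(-15, 4))[seq_len(n_restarts), , drop = FALSE]
  form <- if (increasing) y ~ A / (1 + exp((V50 - x) / k))
          else y ~ A / (1 + exp((x - V50) / k))
  for (j in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(form,
                        start = list(A = ymax, V50 = v50_0 + starts[j, 1],
                                     k = max(1, k0 + starts[j, 2])),
                        lower = c(1e-9, -150, 0.5), upper = c(Inf, 50, 60),
                        control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) stop("Boltzmann fit did not converge")
  cf <- coef(best$fit)
  structure(list(V50 = unname(cf["V50"]), k = unname(cf["k"]),
                 scale = unname(cf["A"]), residual = best$rss,
                 direction = if (increasing) "activation" else "inactivation"),
            class = "boltzmann_fit")
}

#' Voltage dependence of activation (Boltzmann fit on conductance)
#'
#' Peak currents are transformed into conductance `G = I / (V - V_rev)` and
#' `G = G_max / (1 + exp((V50 - V)/k))` is fitted by multi-start
#' Levenberg-Marquardt least squares.
#'
#' @param peaks data.frame with columns `V` (mV) and `I` (pA), at least 5
#'   voltages spanning the rise.
#' @param V_rev Reversal potential in mV used for the driving force
#'   (fitted reversal, or the Nernst value of the solutions).
#' @param min_driving Exclude points within this many mV of `V_rev`
#'   (ill-conditioned conductance), default 10.
#' @return A `boltzmann_fit` with `V50`, `k` (> 0), `scale` (G_max, nS) and
#'   `residual`.
#' @export
fit_activation <- function(peaks, V_rev, min_driving = 10) {
  stopifnot(all(c("V", "I") %in% names(peaks)))
  ok <- abs(peaks$V - V_rev) >= min_driving
  peaks <- peaks[ok, , drop = FALSE]
  if (nrow(peaks) < 5L)
    stop("need at least 5 usable voltages spanning the activation rise")
  G <- peaks$I / (peaks$V - V_rev)
  fit_boltzmann(peaks$V, G, increasing = TRUE)
}

#' Voltage dependence of inactivation (Boltzmann fit on normalized peaks)
#'
#' Test-pulse peak currents after conditioning prepulses are normalized to
#' their maximum and fitted with the decreasing Boltzmann
#' `I/I_max = 1 / (1 + exp((V_pre - V50)/k))`.
#'
#' @param peaks data.frame with columns `V_pre` (prepulse potential, mV)
#'   and `I` (test-pulse peak, pA).
#' @return A `boltzmann_fit` (`scale` close to 1 for normalized input).
#' @export
fit_inactivation <- function(peaks) {
  stopifnot(all(c("V_pre", "I") %in% names(peaks)))
  if (nrow(peaks) < 5L) stop("need at least 5 prepulse potentials")
  Imax <- max(abs(peaks$I))
  if (Imax < 1e-12) stop("fit error: all-zero currents")
  y <- peaks$I / peaks$I[which.max(abs(peaks$I))]
  fit_boltzmann(peaks$V_pre, y, increasing = FALSE)
}

#' Inactivation time constant (mono-exponential decay fit)
#'
#' Fits `I(t) = A exp(-(t - t_peak)/tau) + C` to the subtracted current
#' from its peak to the end of the test step.
#'
#' @param sub A `subtracted_current` (typically the 0 mV step of a 2.5 s
#'   family), or a current [sweep()] plus explicit `from`/`to` (s).
#' @param from,to Fit window in s; defaults to peak time to end of trace.
#' @return An `exp_fit` with `tau_inact` (ms), `amplitude` (pA), `offset`
#'   (pA) and `residual`.
#' @export
fit_tau_inact <- function(sub, from = NULL, to = NULL) {
  if (inherits(sub, "subtracted_current")) {
    sw <- sub$trace
    if (is.null(from)) from <- sub$peak_time
  } else sw <- sub
  stopifnot(inherits(sw, "sweep"))
  t <- sweep_time(sw)
  if (is.null(from)) from <- t[which.max(abs(sw$samples))]
  if (is.null(to)) to <- max(t)
  sel <- t >= from & t <= to
  tt <- (t[sel] - from) * 1000  # ms
  yy <- sw$samples[sel]
  if (sd(yy) < 1e-9) stop("fit error: trace has no decay")
  C0 <- mean(yy[tt > 0.8 * max(tt)])
  A0 <- yy[1] - C0
  fit <- tryCatch(
    minpack.lm::nlsLM(yy ~ A * exp(-tt / tau) + C,
                      start = list(A = A0, tau = max(tt) / 4, C = C0),
                      lower = c(-Inf, 1e-3, -Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) stop("mono-exponential fit did not converge: ",
                             conditionMessage(e)))
  cf <- coef(fit)
  structure(list(tau_inact = unname(cf["tau"]), amplitude = unname(cf["A"]),
                 offset = unname(cf["C"]), residual = sum(residuals(fit)^2)),
            class = "exp_fit")
}

#' Reversal potential by linear fit of peak currents
#'
#' Linear least squares of peak current vs step potential on the configured
#' sub-range (default the hyperpolarized limb, -110 to -50 mV, avoiding
#' activation curvature); the reversal potential is the abscissa crossing
#' of the fit.
#'
#' @param peaks data.frame with columns `V` (mV) and `I` (pA).
#' @param range Fit range in mV, `c(lo, hi)`; use `c(-Inf, Inf)` for the
#'   full step set.
#' @return A `reversal_fit` with `V_rev` (mV), `slope_conductance` (nS),
#'   `se_V_rev` (delta-method standard error) and `wide_ci` flag (set when
#'   the crossing is poorly determined).
#' @export
estimate_reversal <- function(peaks, range = c(-110, -50)) {
  stopifnot(all(c("V", "I") %in% names(peaks)))
  sel <- peaks$V >= range[1] & peaks$V <= range[2]
  d <- peaks[sel, , drop = FALSE]
  if (nrow(d) < 2L) stop("need at least 2 points in the reversal fit range")
  fit <- lm(I ~ V, data = d)
  b <- coef(fit)
  if (abs(b["V"]) < 1e-12) stop("zero slope: reversal undefined")
  vrev <- -b[["(Intercept)"]] / b[["V"]]
  se <- if (nrow(d) > 2L) {
    vc <- vcov(fit)
    g <- c(-1 / b[["V"]], b[["(Intercept)"]] / b[["V"]]^2)
    sqrt(drop(t(g) %*% vc %*% g))
  } else NA_real_
  structure(list(V_rev = vrev, slope_conductance = b[["V"]],
                 se_V_rev = se, range = range,
                 wide_ci = !is.finite(se) || se > 10),
            class = "reversal_fit")
}

#' Nernst equilibrium potential for K
#'
#' `E = (R T / F) ln(K_out / K_in)`, in mV.
#'
#' @param K_in Intracellular K concentration, mM (155 for the KMe pipette
#'   solution: 135 KMeSO4 + 20 KCl).
#' @param K_out Extracellular K concentration, mM (2.5 in ACSF).
#' @param temperature Absolute temperature in K (default 293.15, room
#'   temperature).
#' @return Potential in mV.
#' @export
nernst <- function(K_in = 155, K_out = 2.5, temperature = 293.15) {
  stopifnot(K_in > 0, K_out > 0, temperature > 0)
  R <- 8.31446261815324   # J / (mol K)
  F <- 96485.33212331     # C / mol
  1000 * R * temperature / F * log(K_out / K_in)
}
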