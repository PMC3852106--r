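#' Conductance-based granule-cell model parameters
#'
#' Single-compartment model with leak, transient Na, delayed-rectifier K,
#' inward-rectifier K and the delay conductance g_D. The delay current is
#' I_D = g_D * a * b * (V - E_K) with activation gate a (steady state
#' increasing with V) and inactivation gate b (decreasing with V), both
#' Boltzmann with slope factors k > 0 and first-order kinetics.
#'
#' @param C_m Membrane capacitance in pF.
#' @param g_L,E_L Leak conductance (nS) and reversal (mV).
#' @param g_Na,E_Na Transient Na conductance (nS) and reversal (mV).
#' @param g_Kdr Delayed-rectifier K conductance (nS).
#' @param g_Kir Inward-rectifier K conductance (nS).
#' @param g_D Delay conductance (nS).
#' @param act List `(V50, k, tau_ms)` for the activation gate.
#' @param inact List `(V50, k, tau_ms)` for the inactivation gate.
#' @param E_K K reversal potential in mV.
#' @param noise_sd Injected current noise SD in pA (white, per sample).
#' @param seed Optional integer seed used when `noise_sd > 0`.
#' @return An object of class `sim_cell_params`.
#' @export
sim_cell_params <- function(C_m = 88, g_L = 1.5, E_L = -70, g_Na = 600,
                            E_Na = 60, g_Kdr = 70, g_Kir = 1.5, g_D = 0.18,
                            act = list(V50 = -32.3, k = 17.1, tau_ms = 2),
                            inact = list(V50 = -41.7, k = 14.1, tau_ms = 250),
                            E_K = -104.3, noise_sd = 0, seed = NULL) {
  g <- c(g_L, g_Na, g_Kdr, g_Kir, g_D)
  if (any(g < 0)) stop("conductances must be >= 0")
  if (act$k <= 0 || inact$k <= 0) stop("slope factors must be > 0")
  if (act$tau_ms <= 0 || inact$tau_ms <= 0) stop("time constants must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(C_m = C_m, g_L = g_L, E_L = E_L, g_Na = g_Na, E_Na = E_Na,
                 g_Kdr = g_Kdr, g_Kir = g_Kir, g_D = g_D, act = act,
                 inact = inact, E_K = E_K, noise_sd = noise_sd, seed = seed),
            class = "sim_cell_params")
}

#' Granule-cell presets
#'
#' Two parameterizations representing control ("naive") and epileptic
#' ("KA", kainate-injected) granule cells. The delay-conductance gating
#' (activation/inactivation midpoints and slopes, inactivation time
#' constant), the K Nernst potential, and the delay-conductance magnitudes
#' (back-computed from peak current density and capacitance) are the
#' measured group values; passive conductances are tuned so the presets
#' reproduce the measured resting potentials (about -82 / -84 mV) and input
#' resistances (about 600 / 450 MOhm).
#'
#' @param which `"naive"` or `"KA"`.
#' @return A [sim_cell_params()] object.
#' @export
granule_preset <- function(which = c("naive", "KA")) {
  which <- match.arg(which)
  if (which == "naive")
    sim_cell_params(C_m = 88, g_L = 1.523, E_L = -70.95, g_Na = 600,
                    g_Kdr = 70, g_Kir = 1.4325, g_D = 0.18,
                    act = list(V50 = -32.3, k = 17.1, tau_ms = 2),
                    inact = list(V50 = -41.7, k = 14.1, tau_ms = 250))
  else
    sim_cell_params(C_m = 88, g_L = 1.6139, E_L = -70.95, g_Na = 600,
                    g_Kdr = 70, g_Kir = 1.4188, g_D = 2.06,
                    act = list(V50 = -46.0, k = 17.0, tau_ms = 2),
                    inact = list(V50 = -43.8, k = 13.7, tau_ms = 378))
}

params_vector <- function(p) {
  c(p$C_m, p$g_L, p$E_L, p$g_Na, p$E_Na, p$g_Kdr, p$g_Kir, p$g_D,
    p$act$V50, p$act$k, p$act$tau_ms, p$inact$V50, p$inact$k,
    p$inact$tau_ms, p$E_K)
}

#' Save / load model parameters as YAML
#' @param p A [sim_cell_params()].
#' @param path File path.
#' @return `load_params` returns a [sim_cell_params()].
#' @export
save_params <- function(p, path) {
  stopifnot(inherits(p, "sim_cell_params"))
  yaml::write_yaml(unclass(p), path)
  invisible(path)
}

#' @rdname save_params
#' @export
load_params <- function(path) {
  l <- yaml::read_yaml(path)
  do.call(sim_cell_params, l)
}

#' Resting potential of the model
#'
#' Solves the zero of the steady-state membrane current on the
#' hyperpolarized branch (`[-120, -55]` mV, below the Na window region).
#' @param p A [sim_cell_params()].
#' @return Resting potential in mV.
#' @export
model_rest <- function(p) {
  pv <- params_vector(p)
  uniroot(function(v) ss_membrane_current(pv, v), c(-120, -55),
          tol = 1e-10)$root
}

#' Simulate a current-clamp sweep
#'
#' Integrates the model (`C_m dV/dt = -sum I_ion + I_inj + noise`) with
#' exponential-Euler gate updates and an explicit voltage update at fixed
#' step `dt`, starting from the model's resting state. Deterministic given
#' the seed.
#'
#' @param p A [sim_cell_params()].
#' @param proto A [step_protocol()].
#' @param dt Integration/sampling step in s (must be <= 50 us).
#' @param T Total simulated time in s; must cover the step.
#' @param seed Optional seed overriding `p$seed` (used when `noise_sd > 0`).
#' @return A voltage [sweep()] carrying the protocol.
#' @export
simulate_current_clamp <- function(p, proto, dt = 2.5e-5,
                                   T = proto$onset + proto$duration + 0.2,
                                   seed = NULL) {
  stopifnot(inherits(p, "sim_cell_params"), inherits(proto, "step_protocol"))
  if (dt > 5e-5 + 1e-15) stop("dt must be <= 50 us")
  if (T < proto$onset + proto$duration)
    stop("T must cover onset + duration")
  n <- round(T / dt)
  idx <- seq_len(n) - 1
  I <- rep(proto$holding, n)
  on <- idx * dt >= proto$onset & idx * dt < proto$onset + proto$duration
  I[on] <- I[on] + proto$amplitude
  if (p$noise_sd > 0) {
    sd <- if (!is.null(seed)) seed else p$seed
    if (!is.null(sd)) set.seed(sd)
    I <- I + rnorm(n, 0, p$noise_sd)
  }
  v <- sim_cc_core(params_vector(p), I, dt, model_rest(p))
  sweep(v, dt = dt, kind = "voltage", protocol = proto)
}

#' Simulate an arbitrary current-waveform injection
#'
#' Same integrator as [simulate_current_clamp()] but with a caller-supplied
#' injected-current waveform (e.g. a synaptic train).
#'
#' @param p A [sim_cell_params()].
#' @param waveform Injected current per sample, pA.
#' @param dt Step in s.
#' @param seed Optional seed for the noise.
#' @return A voltage [sweep()].
#' @export
simulate_injection <- function(p, waveform, dt = 2.5e-5, seed = NULL) {
  stopifnot(inherits(p, "sim_cell_params"))
  if (dt > 5e-5 + 1e-15) stop("dt must be <= 50 us")
  I <- as.numeric(waveform)
  if (p$noise_sd > 0) {
    sd <- if (!is.null(seed)) seed else p$seed
    if (!is.null(sd)) set.seed(sd)
    I <- I + rnorm(length(I), 0, p$noise_sd)
  }
  v <- sim_cc_core(params_vector(p), I, dt, model_rest(p))
  sweep(v, dt = dt, kind = "voltage", protocol = NULL)
}

gate_inf <- function(V, V50, k, increasing) {
  if (increasing) 1 / (1 + exp((V50 - V) / k)) else 1 / (1 + exp((V - V50) / k))
}

# analytic gate relaxation over one constant-voltage segment
relax <- function(g0, ginf, tau_s, t) ginf + (g0 - ginf) * exp(-t / tau_s)

vc_segment_currents <- function(p, V, t, state) {
  # state: list(h, n, a, b) at segment start; t: times within segment (s)
  hinf <- 1 / (1 + exp((V + 47) / 6))
  ninf <- 1 / (1 + exp(-(V + 30) / 10))
  ainf <- gate_inf(V, p$act$V50, p$act$k, TRUE)
  binf <- gate_inf(V, p$inact$V50, p$inact$k, FALSE)
  h <- relax(state$h, hinf, 0.005, t)
  n <- relax(state$n, ninf, 0.004, t)
  a <- relax(state$a, ainf, p$act$tau_ms / 1000, t)
  b <- relax(state$b, binf, p$inact$tau_ms / 1000, t)
  m <- 1 / (1 + exp(-(V + 38) / 7))
  kir <- 1 / (1 + exp((V + 80) / 12))
  I <- p$g_L * (V - p$E_L) + p$g_Na * m^3 * h * (V - p$E_Na) +
    p$g_Kdr * n^4 * (V - p$E_K) + p$g_Kir * kir * (V - p$E_K) +
    p$g_D * a * b * (V - p$E_K)
  end <- length(t)
  list(I = I, state = list(h = h[end], n = n[end], a = a[end], b = b[end]))
}

#' Simulate a voltage-clamp step family
#'
#' Ideal clamp (no series-resistance error): the command potential is
#' imposed exactly and the recorded current is the sum of the ionic
#' currents (gates relax analytically within each constant-voltage
#' segment), plus optional white noise. One current sweep per test step;
#' each sweep spans holding settle, optional prepulse, and the test step.
#'
#' @param p A [sim_cell_params()].
#' @param proto A [vc_step_protocol()].
#' @param dt Sampling interval in s.
#' @param hold_duration Settle time at holding before the (pre)pulse, s.
#' @param seed Optional seed for the current noise.
#' @return List of current [sweep()]s; each has attributes `step_V` and
#'   (when present) `prepulse_V`.
#' @export
simulate_voltage_clamp <- function(p, proto, dt = 5e-5, hold_duration = 0.1,
                                   seed = NULL) {
  stopifnot(inherits(p, "sim_cell_params"), inherits(proto, "vc_step_protocol"))
  if (!is.null(seed)) set.seed(seed) else if (!is.null(p$seed)) set.seed(p$seed)
  pre <- proto$prepulse
  n_steps <- length(proto$steps)
  prevs <- if (is.null(pre)) NULL else rep_len(pre$potentials, n_steps)
  lapply(seq_len(n_steps), function(i) {
    segs <- list(list(V = proto$holding, dur = hold_duration))
    if (!is.null(pre))
      segs <- c(segs, list(list(V = prevs[i], dur = pre$duration)))
    segs <- c(segs, list(list(V = proto$steps[i], dur = proto$step_duration)))
    V0 <- proto$holding
    state <- list(h = 1 / (1 + exp((V0 + 47) / 6)),
                  n = 1 / (1 + exp(-(V0 + 30) / 10)),
                  a = gate_inf(V0, p$act$V50, p$act$k, TRUE),
                  b = gate_inf(V0, p$inact$V50, p$inact$k, FALSE))
    I <- numeric(0)
    seg_onsets <- numeric(length(segs))
    t0 <- 0
    for (k in seq_along(segs)) {
      seg_onsets[k] <- t0
      nk <- round(segs[[k]]$dur / dt)
      t <- seq_len(nk) * dt
      out <- vc_segment_currents(p, segs[[k]]$V, t, state)
      I <- c(I, out$I)
      state <- out$state
      t0 <- t0 + nk * dt
    }
    if (p$noise_sd > 0) I <- I + rnorm(length(I), 0, p$noise_sd)
    sw <- sweep(I, dt = dt, kind = "current", protocol = proto)
    attr(sw, "step_V") <- proto$steps[i]
    attr(sw, "prepulse_V") <- if (is.null(pre)) NA_real_ else prevs[i]
    attr(sw, "test_onset") <- seg_onsets[length(segs)]
    sw
  })
}

#' Apply a channel blocker as a parameter transform
#'
#' DTX and 4-AP scale the delay conductance by `(1 - fraction_block)`;
#' barium scales the inward rectifier. Pure parameter transform; no traces
#' are touched.
#'
#' @param p A [sim_cell_params()].
#' @param drug `"DTX"`, `"4AP"` or `"barium"`.
#' @param fraction_block Blocked fraction in `[0, 1]` (default 1).
#' @return Modified [sim_cell_params()].
#' @export
apply_drug <- function(p, drug = c("DTX", "4AP", "barium"),
                       fraction_block = 1) {
  drug <- match.arg(drug)
  stopifnot(fraction_block >= 0, fraction_block <= 1)
  if (drug %in% c("DTX", "4AP")) p$g_D <- p$g_D * (1 - fraction_block)
  else p$g_Kir <- p$g_Kir * (1 - fraction_block)
  p
}

#' qPCR study design for the synthetic CT generator
#'
#' @param genes Gene names (default Kv1.1-Kv1.6 plus GAPDH).
#' @param n_cells Named integer vector, cells per group (e.g.
#'   `c(naive = 20, KA = 20)`).
#' @param baseline_CT Named per-gene baseline CT (control group).
#' @param log2_fold Named per-gene programmed log2 fold difference (case vs
#'   control; positive = more abundant in case, i.e. lower CT). The
#'   reference gene's fold is 0.
#' @param noise_sd CT noise SD in cycles.
#' @param ceiling Detection ceiling in cycles; CTs beyond it are censored.
#' @param latent_sd SD of a per-cell latent factor added (in cycles) to the
#'   CTs of `latent_genes`, producing programmed co-expression.
#' @param latent_genes Genes loading on the latent factor.
#' @return An object of class `qpcr_design`.
#' @export
qpcr_design <- function(genes = c(paste0("Kv1.", 1:6), "GAPDH"),
                        n_cells = c(naive = 20, KA = 20),
                        baseline_CT = NULL, log2_fold = NULL,
                        noise_sd = 1, ceiling = 45,
                        latent_sd = 0, latent_genes = character(0)) {
  if (any(n_cells < 1)) stop("n_cells must be >= 1")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (is.null(baseline_CT)) {
    baseline_CT <- setNames(rep(38, length(genes)), genes)
    if ("GAPDH" %in% genes) baseline_CT["GAPDH"] <- 34.8
  }
  if (is.null(log2_fold)) log2_fold <- setNames(rep(0, length(genes)), genes)
  if ("GAPDH" %in% genes) log2_fold["GAPDH"] <- 0
  structure(list(genes = genes, n_cells = n_cells, baseline_CT = baseline_CT,
                 log2_fold = log2_fold, noise_sd = noise_sd,
                 ceiling = ceiling, latent_sd = latent_sd,
                 latent_genes = latent_genes),
            class = "qpcr_design")
}

#' Generate a synthetic single-cell CT table
#'
#' CT = baseline - log2_fold * I(case group) + latent + Normal(0, sd),
#' censored at the detection ceiling (censored CTs stored as `NA` with
#' `detected = FALSE`).
#'
#' @param d A [qpcr_design()].
#' @param seed Integer seed.
#' @return A tidy data.frame with columns `sample_id`, `linked_cell_id`,
#'   `gene`, `CT`, `detected`, `group`, `level`, `melt_ok`, `primer_dimer`.
#' @export
generate_qpcr_dataset <- function(d, seed = 1) {
  stopifnot(inherits(d, "qpcr_design"))
  set.seed(seed)
  groups <- names(d$n_cells)
  rows <- list()
  cell_no <- 0
  for (gi in seq_along(groups)) {
    grp <- groups[gi]
    case <- gi > 1  # first group is the control/baseline group
    for (ci in seq_len(d$n_cells[[gi]])) {
      cell_no <- cell_no + 1
      id <- sprintf("%s_cell%03d", grp, ci)
      lat <- if (d$latent_sd > 0) rnorm(1, 0, d$latent_sd) else 0
      ct <- d$baseline_CT[d$genes] -
        (if (case) d$log2_fold[d$genes] else 0) +
        ifelse(d$genes %in% d$latent_genes, lat, 0) +
        rnorm(length(d$genes), 0, d$noise_sd)
      detected <- ct <= d$ceiling
      rows[[cell_no]] <- data.frame(
        sample_id = id, linked_cell_id = id, gene = d$genes,
        CT = ifelse(detected, ct, NA_real_), detected = detected,
        group = grp, level = "single_cell", melt_ok = TRUE,
        primer_dimer = FALSE, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a synaptic stimulation train waveform
#'
#' A train of `n_pulses` synaptic-like current transients (difference of
#' exponentials) at the given rate, with amplitudes ramped geometrically so
#' that the last/first peak ratio equals `facilitation_ratio`.
#'
#' @param n_pulses Number of pulses (default 5).
#' @param rate Pulse rate in Hz (default 100).
#' @param amplitude First-pulse peak amplitude in pA.
#' @param facilitation_ratio Last/first peak amplitude ratio (default 1.4).
#' @param dt Sample interval in s.
#' @param T Total duration in s.
#' @param onset Train onset in s.
#' @param tau_rise,tau_decay Kernel time constants in s.
#' @return Numeric waveform (pA per sample) with attributes `pulse_times`
#'   (s), `amplitudes` (pA), `dt`, `onset`.
#' @export
generate_synaptic_train <- function(n_pulses = 5, rate = 100, amplitude = 30,
                                    facilitation_ratio = 1.4, dt = 2.5e-5,
                                    T = 0.6, onset = 0.1,
                                    tau_rise = 5e-4, tau_decay = 4e-3) {
  n <- round(T / dt)
  t <- (seq_len(n) - 1) * dt
  pulse_times <- onset + (seq_len(n_pulses) - 1) / rate
  amps <- amplitude *
    facilitation_ratio^((seq_len(n_pulses) - 1) / max(1, n_pulses - 1))
  # peak-normalized difference-of-exponentials kernel
  tp <- tau_rise * tau_decay / (tau_decay - tau_rise) *
    log(tau_decay / tau_rise)
  knorm <- exp(-tp / tau_decay) - exp(-tp / tau_rise)
  w <- numeric(n)
  for (k in seq_len(n_pulses)) {
    tk <- t - pulse_times[k]
    on <- tk >= 0
    w[on] <- w[on] + amps[k] *
      (exp(-tk[on] / tau_decay) - exp(-tk[on] / tau_rise)) / knorm
  }
  attr(w, "pulse_times") <- pulse_times
  attr(w, "amplitudes") <- amps
  attr(w, "dt") <- dt
  attr(w, "onset") <- onset
  w
}

#' Generate a synthetic labeled-section image with a molecular-layer band
#'
#' A 2D intensity array emulating a fluorescence section: uniform background
#' at `base_intensity` with a horizontal band (rows around `band_position`)
#' scaled by `band_gain`, plus Gaussian noise. Returns rectangular ROI masks
#' for the band and a background reference.
#'
#' @param shape `c(nrow, ncol)` in pixels.
#' @param band_position Band center row.
#' @param band_width Band width in rows.
#' @param band_gain Band/background intensity ratio.
#' @param base_intensity Background intensity (a.u.).
#' @param noise_sd Additive Gaussian noise SD.
#' @param seed Integer seed.
#' @return List with `image` (matrix), `masks` (list of logical matrices
#'   `band`, `background`) and `band_position`.
#' @export
generate_roi_image <- function(shape = c(120, 80), band_position = 60,
                               band_width = 12, band_gain = 1.94,
                               base_intensity = 50, noise_sd = 0, seed = 1) {
  set.seed(seed)
  img <- matrix(base_intensity, nrow = shape[1], ncol = shape[2])
  half <- band_width / 2
  band_rows <- which(abs(seq_len(shape[1]) - band_position) < half)
  img[band_rows, ] <- base_intensity * band_gain
  if (noise_sd > 0) img <- img + matrix(rnorm(length(img), 0, noise_sd),
                                        nrow = shape[1])
  band_mask <- matrix(FALSE, shape[1], shape[2])
  band_mask[band_rows, ] <- TRUE
  bg_rows <- seq_len(max(1, band_position - band_width * 2))
  bg_mask <- matrix(FALSE, shape[1], shape[2])
  bg_mask[bg_rows, ] <- TRUE
  list(image = img, masks = list(band = band_mask, background = bg_mask),
       band_position = band_position)
}
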