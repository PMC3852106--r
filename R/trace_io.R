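#' Current-step stimulus protocol
#'
#' Describes a rectangular current injection used in current clamp: a holding
#' current, a step of given amplitude, onset time and duration.
#'
#' @param amplitude Step amplitude in pA.
#' @param onset Step onset in s (>= 0). Stored in seconds, not samples, so the
#'   protocol survives resampling.
#' @param duration Step duration in s (> 0).
#' @param holding Holding current in pA (default 0).
#' @return An object of class `step_protocol`.
#' @export
step_protocol <- function(amplitude, onset = 0.1, duration = 1, holding = 0) {
  stopifnot(is.numeric(amplitude), length(amplitude) == 1L, is.finite(amplitude))
  if (!is.numeric(duration) || duration <= 0) stop("duration must be > 0")
  if (!is.numeric(onset) || onset < 0) stop("onset must be >= 0")
  structure(list(amplitude = amplitude, onset = onset,
                 duration = duration, holding = holding),
            class = "step_protocol")
}

#' Voltage-clamp step protocol
#'
#' A family of voltage steps from a holding potential, optionally preceded by
#' a conditioning prepulse (used for inactivation curves and tail-current
#' reversal measurements).
#'
#' @param holding Holding potential in mV.
#' @param steps Test potentials in mV (one sweep per element).
#' @param step_duration Test-step duration in s (> 0).
#' @param prepulse Optional list with elements `potentials` (mV; length 1 or
#'   `length(steps)`) and `duration` (s), applied between holding and test.
#' @return An object of class `vc_step_protocol`.
#' @export
vc_step_protocol <- function(holding, steps, step_duration, prepulse = NULL) {
  stopifnot(is.numeric(holding), is.numeric(steps), length(steps) >= 1L)
  if (!is.numeric(step_duration) || step_duration <= 0)
    stop("step_duration must be > 0")
  if (!is.null(prepulse)) {
    stopifnot(is.list(prepulse), !is.null(prepulse$potentials),
              !is.null(prepulse$duration), prepulse$duration > 0)
    np <- length(prepulse$potentials)
    if (np != 1L && np != length(steps))
      stop("prepulse potentials must have length 1 or length(steps)")
  }
  structure(list(holding = holding, steps = as.numeric(steps),
                 step_duration = step_duration, prepulse = prepulse),
            class = "vc_step_protocol")
}

#' Single recorded sweep
#'
#' @param samples Numeric vector of membrane voltage (mV) or current (pA).
#' @param dt Sampling interval in s (> 0).
#' @param kind `"voltage"` or `"current"`.
#' @param protocol A [step_protocol()] (current injection, voltage recorded)
#'   or [vc_step_protocol()] (voltage command, current recorded). The
#'   protocol class must be consistent with `kind`.
#' @return An object of class `sweep`. Time is sample-index based (0-based),
#'   `t = index * dt`.
#' @export
sweep <- function(samples, dt, kind = c("voltage", "current"), protocol = NULL) {
  kind <- match.arg(kind)
  if (!is.numeric(dt) || dt <= 0) stop("dt must be > 0")
  if (length(samples) < 2L) stop("a sweep needs at least 2 samples")
  if (!is.null(protocol)) {
    if (kind == "voltage" && !inherits(protocol, "step_protocol"))
      stop("voltage sweeps require a step_protocol (current injection)")
    if (kind == "current" && !inherits(protocol, "vc_step_protocol"))
      stop("current sweeps require a vc_step_protocol (voltage command)")
  }
  structure(list(samples = as.numeric(samples), dt = dt, kind = kind,
                 protocol = protocol),
            class = "sweep")
}

#' @export
length.sweep <- function(x) length(x$samples)

#' Time axis of a sweep
#' @param s A [sweep()].
#' @return Numeric vector of times in s, starting at 0.
#' @export
sweep_time <- function(s) (seq_along(s$samples) - 1) * s$dt

#' Recording-level quality metrics
#'
#' @param R_seal Seal resistance in GOhm.
#' @param R_ser Series resistance in MOhm.
#' @param V_rest Resting membrane potential in mV.
#' @param ap_overshoot Logical; do action potentials overshoot 0 mV?
#' @param rin_over_rseal Ratio of input resistance to seal resistance
#'   (dimensionless; both in the same units).
#' @return An object of class `recording_qc`. Any field may be `NA` when not
#'   measured; rules requiring a missing field are then unevaluable.
#' @export
recording_qc <- function(R_seal = NA_real_, R_ser = NA_real_,
                         V_rest = NA_real_, ap_overshoot = NA,
                         rin_over_rseal = NA_real_) {
  for (r in list(R_seal, R_ser)) {
    if (!is.na(r) && r <= 0) stop("resistances must be > 0 when present")
  }
  structure(list(R_seal = R_seal, R_ser = R_ser, V_rest = V_rest,
                 ap_overshoot = ap_overshoot,
                 rin_over_rseal = rin_over_rseal),
            class = "recording_qc")
}

#' Acceptance criteria for perforated-patch recordings
#'
#' Each rule can be toggled off by setting its threshold to `NA`. The named
#' preset `"perforated"` bakes in the acceptance rules used for
#' gramicidin-perforated granule-cell recordings: series resistance below
#' 40 MOhm, resting potential below -73 mV, overshooting action potentials,
#' seal resistance above 1 GOhm and an input-to-seal resistance ratio below
#' 0.3.
#'
#' @param R_ser_max Maximum series resistance (MOhm).
#' @param V_rest_max Maximum (most depolarized acceptable) resting potential
#'   (mV).
#' @param require_overshoot Require overshooting APs (logical, `NA` disables).
#' @param R_seal_min Minimum seal resistance (GOhm).
#' @param rin_over_rseal_max Maximum input/seal resistance ratio.
#' @param preset Optional preset name; currently `"perforated"`.
#' @return An object of class `qc_criteria`.
#' @export
qc_criteria <- function(R_ser_max = NA_real_, V_rest_max = NA_real_,
                        require_overshoot = NA, R_seal_min = NA_real_,
                        rin_over_rseal_max = NA_real_, preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, "perforated")
    return(structure(list(R_ser_max = 40, V_rest_max = -73,
                          require_overshoot = TRUE, R_seal_min = 1,
                          rin_over_rseal_max = 0.3),
                     class = "qc_criteria"))
  }
  thr <- c(R_ser_max, V_rest_max, R_seal_min, rin_over_rseal_max)
  if (any(!is.na(thr) & !is.finite(thr))) stop("thresholds must be finite")
  structure(list(R_ser_max = R_ser_max, V_rest_max = V_rest_max,
                 require_overshoot = require_overshoot,
                 R_seal_min = R_seal_min,
                 rin_over_rseal_max = rin_over_rseal_max),
            class = "qc_criteria")
}

#' Apply recording quality control
#'
#' A recording is rejected iff any enabled rule is violated. A rule whose
#' required metric is missing raises an error rather than passing silently.
#'
#' @param qc A [recording_qc()].
#' @param criteria A [qc_criteria()]; default is the `"perforated"` preset.
#' @return A list with `decision` (`"accept"` or `"reject"`) and `violated`
#'   (character vector of violated rule names).
#' @export
qc_recording <- function(qc, criteria = qc_criteria(preset = "perforated")) {
  stopifnot(inherits(qc, "recording_qc"), inherits(criteria, "qc_criteria"))
  violated <- character(0)
  check <- function(enabled, value, rule, ok) {
    if (is.na(enabled)) return(invisible(NULL))
    if (is.na(value))
      stop("unevaluable rule '", rule, "': required metric is missing")
    if (!ok) violated <<- c(violated, rule)
    invisible(NULL)
  }
  check(criteria$R_ser_max, qc$R_ser, "R_ser",
        !is.na(qc$R_ser) && qc$R_ser < criteria$R_ser_max)
  check(criteria$V_rest_max, qc$V_rest, "V_rest",
        !is.na(qc$V_rest) && qc$V_rest < criteria$V_rest_max)
  check(if (isTRUE(criteria$require_overshoot)) 1 else NA,
        qc$ap_overshoot, "ap_overshoot", isTRUE(qc$ap_overshoot))
  check(criteria$R_seal_min, qc$R_seal, "R_seal",
        !is.na(qc$R_seal) && qc$R_seal > criteria$R_seal_min)
  check(criteria$rin_over_rseal_max, qc$rin_over_rseal, "rin_over_rseal",
        !is.na(qc$rin_over_rseal) &&
          qc$rin_over_rseal < criteria$rin_over_rseal_max)
  list(decision = if (length(violated)) "reject" else "accept",
       violated = violated)
}

#' A cell's recording: a set of sweeps plus metadata
#'
#' @param sweeps List of [sweep()] objects. All sweeps must share `dt` and
#'   `kind` within the set (one protocol family per set).
#' @param cell_id Character identifier.
#' @param group Experimental group: one of `"naive"`, `"KA"`, `"post-NaCl"`,
#'   `"post-KA"`, `"recovery"`.
#' @param layer Position in the granule-cell layer: `"inner"`, `"outer"` or
#'   `"unknown"`.
#' @param solution Pipette solution: `"KMe"` or `"KCl"`.
#' @param qc A [recording_qc()], or `NULL`.
#' @return An object of class `sweep_set`.
#' @export
sweep_set <- function(sweeps, cell_id = "cell", group = "naive",
                      layer = "unknown", solution = "KMe", qc = NULL) {
  group <- match.arg(group, c("naive", "KA", "post-NaCl", "post-KA", "recovery"))
  layer <- match.arg(layer, c("inner", "outer", "unknown"))
  solution <- match.arg(solution, c("KMe", "KCl"))
  stopifnot(is.list(sweeps), length(sweeps) >= 1L,
            all(vapply(sweeps, inherits, TRUE, "sweep")))
  dts <- vapply(sweeps, `[[`, numeric(1), "dt")
  kinds <- vapply(sweeps, `[[`, character(1), "kind")
  if (length(unique(kinds)) != 1L)
    stop("all sweeps in a set must share the same kind")
  if (max(dts) - min(dts) > 1e-12)
    stop("inconsistent dt across sweeps within a protocol family")
  if (!is.null(qc)) stopifnot(inherits(qc, "recording_qc"))
  structure(list(sweeps = sweeps, cell_id = cell_id, group = group,
                 layer = layer, solution = solution, qc = qc),
            class = "sweep_set")
}

#' Liquid-junction-potential correction
#'
#' Shifts all voltage samples by `-ljp`. Under the default policy the
#' correction is skipped for KCl-based recordings, for which no junction
#' correction is applied.
#'
#' @param s A [sweep_set()] of voltage sweeps.
#' @param ljp Junction potential in mV (default 10).
#' @param policy `"default"` (skip KCl sets) or `"always"`.
#' @return The corrected `sweep_set`.
#' @export
apply_ljp_correction <- function(s, ljp = 10, policy = c("default", "always")) {
  policy <- match.arg(policy)
  stopifnot(inherits(s, "sweep_set"))
  if (s$sweeps[[1]]$kind != "voltage")
    stop("LJP correction applies to voltage sweeps only")
  if (policy == "default" && s$solution == "KCl") return(s)
  s$sweeps <- lapply(s$sweeps, function(sw) {
    sw$samples <- sw$samples - ljp
    sw
  })
  if (!is.null(s$qc) && !is.na(s$qc$V_rest)) s$qc$V_rest <- s$qc$V_rest - ljp
  s
}

proto_to_list <- function(p) {
  if (is.null(p)) return(NULL)
  c(list(.class = class(p)[1]), unclass(p))
}

proto_from_list <- function(l) {
  if (is.null(l)) return(NULL)
  cls <- l$.class
  l$.class <- NULL
  if (cls == "step_protocol")
    step_protocol(l$amplitude, l$onset, l$duration, l$holding)
  else if (cls == "vc_step_protocol")
    vc_step_protocol(l$holding, unlist(l$steps), l$step_duration,
                     prepulse = if (is.null(l$prepulse)) NULL else
                       list(potentials = unlist(l$prepulse$potentials),
                            duration = l$prepulse$duration))
  else stop("unknown protocol class: ", cls)
}

#' Save a sweep set to a cell directory
#'
#' One directory per cell: a `metadata.json` sidecar (cell metadata, QC,
#' per-sweep protocol and sampling) and one CSV per sweep with columns
#' `time_s` and `value`. Samples are written at full double precision so the
#' round trip is lossless.
#'
#' @param s A [sweep_set()].
#' @param path Directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
save_sweeps <- function(s, path) {
  stopifnot(inherits(s, "sweep_set"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  meta <- list(
    cell_id = s$cell_id, group = s$group, layer = s$layer,
    solution = s$solution,
    qc = if (is.null(s$qc)) NULL else unclass(s$qc),
    sweeps = lapply(seq_along(s$sweeps), function(i) {
      sw <- s$sweeps[[i]]
      list(file = sprintf("sweep_%03d.csv", i), dt = sw$dt, kind = sw$kind,
           protocol = proto_to_list(sw$protocol))
    })
  )
  jsonlite::write_json(meta, file.path(path, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  for (i in seq_along(s$sweeps)) {
    sw <- s$sweeps[[i]]
    tab <- sprintf("%.17g,%.17g", sweep_time(sw), sw$samples)
    writeLines(c("time_s,value", tab),
               file.path(path, sprintf("sweep_%03d.csv", i)))
  }
  invisible(path)
}

#' Load a sweep set from a cell directory
#'
#' Reads the container written by [save_sweeps()]. Units are normalized to
#' mV/pA/s via the optional schema (e.g. data stored in volts).
#'
#' @param path Cell directory containing `metadata.json`.
#' @param schema Optional list with unit multipliers applied on load:
#'   `value_scale` (default 1) and `time_scale` (default 1), mapping the
#'   stored units onto mV (voltage) or pA (current) and s.
#' @return A [sweep_set()].
#' @export
load_sweeps <- function(path, schema = list()) {
  mf <- file.path(path, "metadata.json")
  if (!file.exists(mf)) stop("no metadata.json in '", path, "'")
  meta <- jsonlite::read_json(mf, simplifyVector = FALSE)
  vscale <- if (is.null(schema$value_scale)) 1 else schema$value_scale
  tscale <- if (is.null(schema$time_scale)) 1 else schema$time_scale
  if (is.null(meta$sweeps) || !length(meta$sweeps))
    stop("schema error: field 'sweeps' missing or empty in metadata")
  sweeps <- lapply(meta$sweeps, function(m) {
    for (f in c("file", "dt", "kind"))
      if (is.null(m[[f]])) stop("schema error: sweep field '", f, "' missing")
    if (is.null(m$protocol))
      stop("schema error: sweep field 'protocol' (stimulus) missing")
    tab <- read.csv(file.path(path, m$file))
    if (!all(c("time_s", "value") %in% names(tab)))
      stop("schema error: sweep table must have columns time_s, value")
    n <- nrow(tab)
    if (n >= 3L) {
      dts <- diff(tab$time_s)
      if (max(dts) - min(dts) > 1e-9)
        stop("format error: inconsistent dt within ", m$file)
    }
    sweep(tab$value * vscale, dt = m$dt * tscale, kind = m$kind,
          protocol = proto_from_list(m$protocol))
  })
  qc <- if (is.null(meta$qc)) NULL else
    recording_qc(R_seal = as_na_real(meta$qc$R_seal),
                 R_ser = as_na_real(meta$qc$R_ser),
                 V_rest = as_na_real(meta$qc$V_rest),
                 ap_overshoot = if (is.null(meta$qc$ap_overshoot)) NA else
                   meta$qc$ap_overshoot,
                 rin_over_rseal = as_na_real(meta$qc$rin_over_rseal))
  sweep_set(sweeps, cell_id = meta$cell_id, group = meta$group,
            layer = meta$layer, solution = meta$solution, qc = qc)
}

as_na_real <- function(x) if (is.null(x) || is.na(x)) NA_real_ else as.numeric(x)
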