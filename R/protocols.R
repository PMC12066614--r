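#' Stimulus waveform
#'
#' Normalized modulating pulse `a(t)` applied to the static potential
#' pattern. Two shapes: a single sine period (`one_period_sine`, duration
#' locked to `1000 / frequency` ms) and a fixed-duration sine burst
#' (`sine_burst`). An optional static bias (mV) adds a constant offset to
#' the MENP potential during the stimulus; it is normalized by the pole
#' amplitude where the drive is built, so the bias scales with the
#' amplification coefficient exactly as the oscillation does.
#'
#' @param shape `"one_period_sine"` or `"sine_burst"`.
#' @param frequency Sine frequency (Hz), > 0.
#' @param duration Stimulus duration (ms); for `one_period_sine` it must be
#'   omitted or equal `1000 / frequency`.
#' @param bias Static potential bias (mV), default 0.
#' @return An object of class `stim_waveform`.
#' @examples
#' w <- stim_waveform("one_period_sine", frequency = 100)
#' waveform_eval(w, c(0, 2.5, 5))  # 0, 1, 0
#' @export
stim_waveform <- function(shape = c("one_period_sine", "sine_burst"),
                          frequency, duration = NULL, bias = 0) {
  shape <- match.arg(shape)
  stopifnot(is.numeric(frequency), frequency > 0)
  if (shape == "one_period_sine") {
    period <- 1000 / frequency
    if (!is.null(duration) && abs(duration - period) > 1e-9) {
      stop(sprintf(
        "one_period_sine at %g Hz has duration %g ms; got %g ms",
        frequency, period, duration), call. = FALSE)
    }
    duration <- period
  } else {
    if (is.null(duration)) duration <- 100
    stopifnot(duration > 0)
  }
  structure(list(shape = shape, frequency_hz = frequency,
                 duration_ms = duration, bias_mv = bias,
                 normalized_amplitude = 1),
            class = "stim_waveform")
}

#' @export
print.stim_waveform <- function(x, ...) {
  cat(sprintf("<stim_waveform> %s, %g Hz, %g ms, bias %g mV\n", x$shape,
              x$frequency_hz, x$duration_ms, x$bias_mv))
  invisible(x)
}

#' Evaluate a waveform
#'
#' `waveform_eval()` returns the normalized oscillation
#' `a(t) = sin(2 pi f t)` inside the stimulus window and 0 outside.
#' `modulator_eval()` returns the full modulating signal
#' `a(t) + bias / reference_amplitude` (also gated by the window), i.e.
#' the dimensionless factor that multiplies `V * AC` per node.
#'
#' @param waveform A [stim_waveform()].
#' @param t Times (ms).
#' @param reference_amplitude_mv Pole amplitude normalizing the bias
#'   (default 5 mV).
#' @export
waveform_eval <- function(waveform, t) {
  on <- t >= 0 & t <= waveform$duration_ms + 1e-12
  ifelse(on, sin(2 * pi * waveform$frequency_hz * t / 1000), 0)
}

#' @rdname waveform_eval
#' @export
modulator_eval <- function(waveform, t, reference_amplitude_mv = 5) {
  on <- t >= 0 & t <= waveform$duration_ms + 1e-12
  a <- ifelse(on, sin(2 * pi * waveform$frequency_hz * t / 1000), 0)
  a + ifelse(on, waveform$bias_mv / reference_amplitude_mv, 0)
}

#' Activating function along a fiber
#'
#' Second spatial derivative of the extracellular potential along a
#' straight fiber, `AF(x) = d2 V / dx2`: positive values predict membrane
#' depolarization, negative values hyperpolarization. The profile is
#' resampled uniformly (linear interpolation) at `resample_step` and
#' differentiated with the central second difference
#' `(V[i-1] - 2 V[i] + V[i+1]) / h^2`; the two endpoints are dropped.
#'
#' @param profile Data frame with columns `arclength_um` and `v_mv`
#'   (>= 5 samples, strictly increasing arclength).
#' @param resample_step Uniform resampling step h (um), default 0.01.
#' @return A tibble of class `af_profile` with columns `arclength_um`,
#'   `af_mv_um2`.
#' @export
activating_function <- function(profile, resample_step = 0.01) {
  stopifnot(all(c("arclength_um", "v_mv") %in% names(profile)))
  s <- profile$arclength_um
  if (length(s) < 5) stop("need at least 5 samples", call. = FALSE)
  if (any(diff(s) <= 0)) stop("arclengths must be strictly increasing",
                              call. = FALSE)
  grid <- seq(min(s), max(s), by = resample_step)
  v <- approx(s, profile$v_mv, grid, ties = "ordered")$y
  n <- length(grid)
  af <- (v[-c(n - 1, n)] - 2 * v[-c(1, n)] + v[-c(1, 2)]) / resample_step^2
  out <- tibble::tibble(arclength_um = grid[2:(n - 1)], af_mv_um2 = af)
  class(out) <- c("af_profile", class(out))
  out
}

#' Detect threshold crossings in a trace
#'
#' A node "spikes" when its membrane potential first reaches
#' `rest + threshold_depolarization`; with the default rest of -65 mV and
#' the 80 mV depolarization criterion this is a crossing of +15 mV.
#'
#' @param trace A `simulation_trace`.
#' @param rest Resting potential (mV), default -65.
#' @param threshold_depolarization Depolarization threshold (mV), default
#'   80; must be > 0.
#' @return A tibble `(node_id, kind, t_cross_ms)` with one row per node
#'   that crossed (empty if none).
#' @export
detect_spikes <- function(trace, rest = -65, threshold_depolarization = 80) {
  stopifnot(threshold_depolarization > 0)
  thr <- rest + threshold_depolarization
  hit <- trace$vm_mv >= thr
  idx <- apply(hit, 1, function(r) {
    w <- which(r)
    if (length(w) == 0) NA_integer_ else w[1]
  })
  crossed <- which(!is.na(idx))
  tibble::tibble(
    node_id = trace$segments$node_id[crossed],
    kind = trace$segments$kind[crossed],
    t_cross_ms = trace$times_ms[idx[crossed]]
  )
}

DENDRITIC_KINDS <- c("basal_dendrite", "apical_dendrite")

#' Classify a stimulation outcome
#'
#' From the per-node first-crossing table: the initiation node is the
#' globally earliest crossing (ties broken toward the lowest node id); the
#' outcome is `axonal_spike` if any axonal node crossed,
#' `dendrite_confined` if only dendritic nodes crossed, and `no_spike`
#' otherwise.
#'
#' @param crossings Tibble from [detect_spikes()].
#' @param morph A [morphology()] (used only for kind lookup when the
#'   crossing table lacks a `kind` column).
#' @return A list with `outcome`, `initiation_node`, `initiation_time_ms`,
#'   `activated_kinds`.
#' @export
classify_outcome <- function(crossings, morph = NULL) {
  if (nrow(crossings) == 0) {
    return(list(outcome = "no_spike", initiation_node = NA_integer_,
                initiation_time_ms = NA_real_,
                activated_kinds = character(0)))
  }
  if (!"kind" %in% names(crossings)) {
    stopifnot(!is.null(morph))
    crossings$kind <- morph$segments$kind[match(crossings$node_id,
                                                morph$segments$node_id)]
  }
  ord <- order(crossings$t_cross_ms, crossings$node_id)
  first <- crossings[ord[1], ]
  kinds <- sort(unique(crossings$kind))
  outcome <- if (any(crossings$kind == "axon")) {
    "axonal_spike"
  } else if (all(crossings$kind %in% DENDRITIC_KINDS)) {
    "dendrite_confined"
  } else {
    "no_spike"
  }
  list(outcome = outcome, initiation_node = first$node_id,
       initiation_time_ms = first$t_cross_ms, activated_kinds = kinds)
}

run_and_classify <- function(system, static_pattern, waveform, ac, dt,
                             tail_ms, reference_amplitude_mv, rest,
                             threshold_depolarization,
                             record_stride = 1L) {
  drv <- extracellular_drive(static_pattern, waveform, ac = ac,
                             reference_amplitude_mv = reference_amplitude_mv)
  trace <- simulate_cable(system, drv,
                          duration = waveform$duration_ms + tail_ms,
                          dt = dt, record_stride = record_stride)
  crossings <- detect_spikes(trace, rest, threshold_depolarization)
  cls <- classify_outcome(crossings)
  list(trace = trace, crossings = crossings, classification = cls)
}

#' Titrate the amplification coefficient
#'
#' Finds the minimal amplification coefficient AC such that the stimulus
#' `Ve_j(t) = V_j * AC * (a(t) + bias / V0)` elicits the requested outcome:
#' the lower bound is tested first, then the upper bound is doubled until
#' success (capped at `hi_max`), then the bracket is bisected to relative
#' tolerance `rel_tol`. The returned traces and classification are those of
#' the run at the final AC.
#'
#' @param system A [cable_system()].
#' @param static_pattern Per-node static potential V (mV), node-id order.
#' @param waveform A [stim_waveform()].
#' @param success Success criterion: `"axonal_spike"` (an axonal node
#'   crosses threshold), `"any_spike"` (any node crosses), or a predicate
#'   function taking the classification list and returning `TRUE`/`FALSE`.
#' @param ac_bounds Initial bracket `c(lo, hi)`, `lo > 0`.
#' @param rel_tol Relative tolerance on AC, in `(0, 0.1]`; default 0.01.
#' @param hi_max Upper cap for the exponential bracketing, default 1e6.
#' @param dt Time step (ms).
#' @param tail_ms Silent period simulated after the stimulus to catch late
#'   spikes (ms), default 15.
#' @param reference_amplitude_mv Pole amplitude normalizing the waveform
#'   bias, default 5.
#' @param rest,threshold_depolarization Spike criterion, see
#'   [detect_spikes()].
#' @return An object of class `titration_result`: `ac` (NA when no success
#'   up to `hi_max`), `success`, `outcome`, `initiation_node`,
#'   `initiation_time_ms`, `activated_kinds`, `n_runs`, `trace`.
#' @export
titrate <- function(system, static_pattern, waveform,
                    success = "axonal_spike", ac_bounds = c(1, 64),
                    rel_tol = 0.01, hi_max = 1e6, dt = 0.025, tail_ms = 15,
                    reference_amplitude_mv = 5, rest = -65,
                    threshold_depolarization = 80) {
  stopifnot(length(ac_bounds) == 2, ac_bounds[1] > 0,
            ac_bounds[2] > ac_bounds[1], rel_tol > 0, rel_tol <= 0.1)
  pred <- if (is.function(success)) {
    success
  } else if (identical(success, "axonal_spike")) {
    function(cls) cls$outcome == "axonal_spike"
  } else if (identical(success, "any_spike")) {
    function(cls) cls$outcome != "no_spike" || length(cls$activated_kinds) > 0
  } else {
    stop("unknown success criterion", call. = FALSE)
  }
  n_runs <- 0L
  eval_at <- function(ac) {
    n_runs <<- n_runs + 1L
    r <- run_and_classify(system, static_pattern, waveform, ac, dt, tail_ms,
                          reference_amplitude_mv, rest,
                          threshold_depolarization)
    r$ok <- isTRUE(pred(r$classification))
    r
  }
  s <- search_threshold(eval_at, ac_bounds[1], ac_bounds[2], rel_tol,
                        hi_max)
  titration_result(s$threshold, s$success, s$run, n_runs)
}

# Minimal-threshold search over a monotone-ish success predicate:
# `eval_at(x)` must return a list with logical element `ok`. Tests the lower
# bound first, doubles the upper bound until success (capped at hi_max),
# then bisects geometrically to relative tolerance rel_tol. Returns the
# threshold (NA when no success up to hi_max), the success flag, and the
# evaluation at the returned point.
search_threshold <- function(eval_at, lo, hi, rel_tol = 0.01,
                             hi_max = 1e6) {
  r_lo <- eval_at(lo)
  if (isTRUE(r_lo$ok)) {
    return(list(threshold = lo, success = TRUE, run = r_lo))
  }
  r_hi <- eval_at(hi)
  while (!isTRUE(r_hi$ok) && hi < hi_max) {
    lo <- hi
    hi <- min(2 * hi, hi_max)
    r_hi <- eval_at(hi)
  }
  if (!isTRUE(r_hi$ok)) {
    return(list(threshold = NA_real_, success = FALSE, run = r_hi))
  }
  while ((hi - lo) / hi > rel_tol) {
    mid <- sqrt(lo * hi)
    r_mid <- eval_at(mid)
    if (isTRUE(r_mid$ok)) {
      hi <- mid
      r_hi <- r_mid
    } else {
      lo <- mid
    }
  }
  list(threshold = hi, success = TRUE, run = r_hi)
}

titration_result <- function(ac, success, run, n_runs) {
  cls <- run$classification
  structure(list(
    ac = ac, success = success, outcome = cls$outcome,
    initiation_node = cls$initiation_node,
    initiation_time_ms = cls$initiation_time_ms,
    activated_kinds = cls$activated_kinds,
    n_runs = n_runs, crossings = run$crossings, trace = run$trace
  ), class = "titration_result")
}

#' @export
print.titration_result <- function(x, ...) {
  if (x$success) {
    cat(sprintf(
      "<titration_result> AC = %.4g, outcome = %s (initiation node %s at %.3f ms), %d runs\n",
      x$ac, x$outcome, x$initiation_node, x$initiation_time_ms, x$n_runs))
  } else {
    cat(sprintf(
      "<titration_result> no success up to the AC cap; outcome at cap = %s, %d runs\n",
      x$outcome, x$n_runs))
  }
  invisible(x)
}

#' @export
tidy.titration_result <- function(x, ...) {
  x$crossings
}

#' @export
glance.titration_result <- function(x, ...) {
  tibble::tibble(
    ac = x$ac, success = x$success, outcome = x$outcome,
    initiation_node = x$initiation_node,
    initiation_time_ms = x$initiation_time_ms,
    n_runs = x$n_runs
  )
}

#' Resolve target selectors to segments
#'
#' Selector vocabulary: `"axon"` (axonal node nearest the axon path
#' midpoint), `"soma"` (first somatic segment), `"basal:k"` / `"apical:k"`
#' (terminal segment of the k-th basal/apical section, ordered by section
#' id), or a bare node id (integer).
#'
#' @param morph A [morphology()].
#' @param targets Character or integer vector of selectors.
#' @return A tibble of segment rows (one per target, duplicates allowed).
#' @export
resolve_targets <- function(morph, targets) {
  segs <- morph$segments
  one <- function(sel) {
    if (is.numeric(sel)) {
      row <- segs[segs$node_id == sel, ]
      if (nrow(row) == 0) stop("no node with id ", sel, call. = FALSE)
      return(row)
    }
    if (sel == "axon") {
      path <- axon_path(morph)
      total <- max(path$arclength_um) + min(path$arclength_um)
      pick <- path$node_id[which.min(abs(path$arclength_um - total / 2))]
      return(segs[segs$node_id == pick, ])
    }
    if (sel == "soma") {
      row <- segs[segs$kind == "soma", ]
      if (nrow(row) == 0) stop("morphology has no soma", call. = FALSE)
      return(row[1, ])
    }
    m <- regmatches(sel, regexec("^(basal|apical):(\\d+)$", sel))[[1]]
    if (length(m) == 3) {
      kind <- paste0(m[2], "_dendrite")
      k <- as.integer(m[3])
      secs <- morph$sections
      cand <- secs$section_id[secs$kind == kind]
      # terminal sections of that kind (no child of the same kind), by id
      has_child <- vapply(cand, function(id) {
        any(secs$parent_id %in% id & secs$kind == kind)
      }, logical(1))
      term <- sort(cand[!has_child])
      if (k > length(term)) {
        stop(sprintf("selector '%s': only %d terminal %s sections", sel,
                     length(term), kind), call. = FALSE)
      }
      rows <- segs[segs$section_id == term[k], ]
      return(rows[nrow(rows), ])  # outermost segment
    }
    stop("cannot resolve target selector '", sel, "'", call. = FALSE)
  }
  dplyr::bind_rows(lapply(targets, one))
}

# Unit tangent of a segment: direction of its section geometry at the node.
segment_direction <- function(morph, node_id) {
  seg <- morph$segments[morph$segments$node_id == node_id, ]
  g <- morph$sections$geometry[[match(seg$section_id,
                                      morph$sections$section_id)]]
  p <- interp_along(g, c(max(0, seg$arclength_um - 1e-3),
                         seg$arclength_um + 1e-3))
  d <- p[2, 1:3] - p[1, 1:3]
  d / sqrt(sum(d^2))
}

#' Multi-MENP summation experiment
#'
#' Places one nanometric MENP (Perpendicular Negative, default radius
#' 0.05 um at a 10 nm gap) at each target node, superposes their static
#' potential patterns over all segments, and titrates the amplification
#' coefficient until an action potential is detected anywhere in the
#' neuron; the outcome at that minimal AC is then classified, so a spike
#' that stays confined to a dendrite is reported as `dendrite_confined`
#' with its own threshold (the categorical "no axon stimulation" cells),
#' while an axonal crossing gives `axonal_spike`.
#'
#' @param morph A [morphology()].
#' @param membrane A [membrane_model()].
#' @param targets Target selectors (see [resolve_targets()]).
#' @param waveform A [stim_waveform()].
#' @param gap Node-to-surface distance (um), default 0.01 (10 nm).
#' @param radius MENP radius (um), default 0.05.
#' @param pole_amplitude Pole potential (mV), default 5.
#' @param system Optional pre-assembled [cable_system()] (must match
#'   `morph` and `membrane`).
#' @param ... Passed to [titrate()] (`dt`, `rel_tol`, `ac_bounds`, ...).
#' @return A `titration_result` with an extra `sources` element.
#' @export
summation_experiment <- function(morph, membrane, targets, waveform,
                                 gap = 0.01, radius = 0.05,
                                 pole_amplitude = 5, system = NULL, ...) {
  stopifnot(length(targets) >= 1)
  rows <- resolve_targets(morph, targets)
  sources <- lapply(seq_len(nrow(rows)), function(i) {
    node <- c(rows$x[i], rows$y[i], rows$z[i])
    place_source(node, segment_direction(morph, rows$node_id[i]),
                 "perpendicular_negative", gap = gap, radius = radius,
                 pole_amplitude = pole_amplitude)
  })
  if (is.null(system)) system <- cable_system(morph, membrane)
  pattern <- static_node_pattern(morph, sources)
  res <- titrate(system, pattern, waveform, success = "any_spike",
                 reference_amplitude_mv = pole_amplitude, ...)
  res$sources <- sources
  res$targets <- rows$node_id
  res
}
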