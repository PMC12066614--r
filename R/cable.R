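#' @useDynLib menpstim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Assemble the discrete cable system
#'
#' Builds, from a morphology and a membrane model, everything the implicit
#' cable integrator needs: per-segment membrane capacitance and leak,
#' symmetric node-to-node axial conductances
#' `g_ij = 1 / (Ra * (L_i / (2 A_i) + L_j / (2 A_j)))` (A = cross-section
#' area) along the segment tree, per-node channel conductances, and the
#' resting state (gates at steady state, leak reversal solved so that
#' `Vrest` is an exact equilibrium). Nodes are permuted once into a
#' parent-before-child order so each implicit step is solved exactly by
#' Hines elimination.
#'
#' @param morph A [morphology()].
#' @param membrane A [membrane_model()].
#' @return An object of class `cable_system`.
#' @export
cable_system <- function(morph, membrane = default_membrane()) {
  stopifnot(inherits(morph, "morphology"),
            inherits(membrane, "membrane_model"))
  segs <- morph$segments
  n <- nrow(segs)
  edges <- segment_edges(morph)
  adj <- vector("list", n)
  gmap <- vector("list", n)
  area_cross <- pi * (segs$diameter_um / 2 * 1e-4)^2    # cm^2
  half_res <- membrane$passive$ra_ohm_cm *
    (segs$length_um * 1e-4) / (2 * area_cross)          # Ohm, half-segment
  if (!is.null(edges)) {
    for (k in seq_len(nrow(edges))) {
      a <- edges[k, 1]; b <- edges[k, 2]
      g_ms <- 1000 / (half_res[a] + half_res[b])
      adj[[a]] <- c(adj[[a]], b); gmap[[a]] <- c(gmap[[a]], g_ms)
      adj[[b]] <- c(adj[[b]], a); gmap[[b]] <- c(gmap[[b]], g_ms)
    }
  }
  # Hines order: BFS from the first segment of the root section
  root_sec <- morph$sections$section_id[is.na(morph$sections$parent_id)]
  root <- segs$node_id[segs$section_id == root_sec][1]
  order <- integer(0)
  parent <- integer(n)      # solver-order parent, 0-based, -1 for root
  g_parent <- numeric(n)
  seen <- logical(n)
  queue <- root
  seen[root] <- TRUE
  pos <- integer(n)         # node_id -> solver index (1-based)
  while (length(queue) > 0) {
    i <- queue[1]; queue <- queue[-1]
    order <- c(order, i)
    pos[i] <- length(order)
    for (k in seq_along(adj[[i]])) {
      j <- adj[[i]][k]
      if (!seen[j]) {
        seen[j] <- TRUE
        parent[j] <- pos[i]
        g_parent[j] <- gmap[[i]][k]
        queue <- c(queue, j)
      }
    }
  }
  if (!all(seen)) stop("morphology segments are not connected",
                       call. = FALSE)
  parent_solver <- parent[order] - 1L   # 0-based
  parent_solver[1] <- -1L
  g_parent_solver <- g_parent[order]

  area_lat <- pi * segs$diameter_um * segs$length_um * 1e-8  # cm^2
  cap_uf <- membrane$passive$cm_uf_cm2 * area_lat
  g_leak_ms <- area_lat / membrane$passive$rm_kohm_cm2

  rest <- resting_state(membrane, morph)
  dist <- node_path_distance(morph)
  chans <- membrane$channels
  n_ch <- length(chans)
  erev <- vapply(chans, `[[`, numeric(1), "erev_mv")
  gates_per_channel <- vapply(chans, function(ch) length(ch$gates),
                              integer(1))
  gate_params <- do.call(rbind, lapply(chans, function(ch) {
    do.call(rbind, lapply(ch$gates, function(g) {
      c(g$exponent, g$inf_vhalf_mv, g$inf_k_mv, g$tau_min_ms, g$tau_amp_ms,
        g$tau_vhalf_mv, g$tau_ka_mv, g$tau_kb_mv)
    }))
  }))
  if (is.null(gate_params)) gate_params <- matrix(0, 0, 8)
  gbar_ms <- matrix(0, n, max(1, n_ch))
  for (c in seq_len(n_ch)) {
    gbar_ms[, c] <- channel_density(chans[[c]], segs$kind, dist) *
      area_lat * 1000
  }
  if (n_ch == 0) gbar_ms <- matrix(0, n, 0)

  structure(list(
    morphology = morph, membrane = membrane,
    n = n, order = order, pos = pos,
    parent = parent_solver, g_parent_ms = g_parent_solver,
    cap_uf = cap_uf[order], g_leak_ms = g_leak_ms[order],
    e_leak_mv = rest$e_leak_mv[order],
    erev = erev, gates_per_channel = gates_per_channel,
    gate_params = gate_params,
    gbar_ms = gbar_ms[order, , drop = FALSE],
    gate_names = rest$gate_names,
    v0_mv = rest$v0_mv[order],
    gates0 = rest$gates[order, , drop = FALSE]
  ), class = "cable_system")
}

#' @export
print.cable_system <- function(x, ...) {
  cat(sprintf(
    "<cable_system> %d nodes, %d channels (%s), Vrest = %g mV\n", x$n,
    length(x$erev), paste(vapply(x$membrane$channels, `[[`, "", "name"),
                          collapse = ", "),
    x$membrane$passive$vrest_mv))
  invisible(x)
}

#' Axial conductance matrix (node order)
#'
#' Dense symmetric matrix of node-to-node axial conductances (mS), mainly
#' for inspection and testing; the solver itself works on the tree.
#'
#' @param system A [cable_system()].
#' @return An `n x n` matrix.
#' @export
axial_conductance_matrix <- function(system) {
  n <- system$n
  m <- matrix(0, n, n)
  for (si in seq_len(n)) {
    p <- system$parent[si]
    if (p >= 0) {
      a <- system$order[si]; b <- system$order[p + 1]
      m[a, b] <- m[a, b] + system$g_parent_ms[si]
      m[b, a] <- m[b, a] + system$g_parent_ms[si]
    }
  }
  m
}

#' Extracellular drive
#'
#' Quasi-static separation of the stimulus: a static per-node potential
#' pattern (mV per unit amplification), scaled in time by the normalized
#' modulating waveform and the amplification coefficient AC, i.e.
#' `Ve_j(t) = pattern_j * AC * (a(t) + bias / reference_amplitude)`.
#'
#' @param static_pattern Numeric vector, one extracellular potential per
#'   node (mV), in node-id order (see [static_node_pattern()]).
#' @param waveform A [stim_waveform()], or `NULL` for a constant (step)
#'   drive.
#' @param ac Amplification coefficient (dimensionless), default 1.
#' @param reference_amplitude_mv Amplitude against which the waveform bias
#'   is normalized (the MENP pole amplitude), default 5 mV.
#' @return An object of class `extracellular_drive`.
#' @export
extracellular_drive <- function(static_pattern, waveform = NULL, ac = 1,
                                reference_amplitude_mv = 5) {
  stopifnot(is.numeric(static_pattern), is.numeric(ac), length(ac) == 1)
  if (!is.null(waveform)) stopifnot(inherits(waveform, "stim_waveform"))
  structure(list(static_pattern = as.numeric(static_pattern),
                 waveform = waveform, ac = ac,
                 reference_amplitude_mv = reference_amplitude_mv),
            class = "extracellular_drive")
}

#' Static extracellular pattern at the morphology nodes
#'
#' Samples the superposed source potential at every segment node: the V of
#' the titration equation, computed once per configuration and scaled in
#' time by the drive.
#'
#' @param morph A [morphology()] or [cable_system()].
#' @param sources A [menp_source()] or list of them.
#' @param max_degree Series truncation (default 51).
#' @return Numeric vector of potentials (mV), one per node.
#' @export
static_node_pattern <- function(morph, sources, max_degree = 51) {
  if (inherits(morph, "cable_system")) morph <- morph$morphology
  segs <- morph$segments
  field_potential(cbind(segs$x, segs$y, segs$z), sources,
                  max_degree = max_degree)$v_mv
}

drive_wave <- function(drive, n_steps, dt) {
  if (is.null(drive)) return(numeric(n_steps + 1))
  t <- (0:n_steps) * dt
  if (is.null(drive$waveform)) {
    rep(drive$ac, n_steps + 1)
  } else {
    drive$ac * modulator_eval(drive$waveform, t,
                              drive$reference_amplitude_mv)
  }
}

#' Run the cable simulation
#'
#' Integrates the cable system over `[0, duration]` with the drive applied
#' from `t = 0`, using backward Euler at fixed `dt` with gates advanced by
#' exponential relaxation at the frozen previous voltage. Fully
#' deterministic.
#'
#' @param system A [cable_system()].
#' @param drive An [extracellular_drive()], or `NULL` for a free run.
#' @param duration Simulated time (ms).
#' @param dt Time step (ms), default 0.025.
#' @param record_stride Record every k-th step (default 1).
#' @param i_inject_ua Optional per-node constant injected current (uA), in
#'   node-id order.
#' @param state Optional initial state (a list with `v_mv` and `gates` in
#'   node-id order) to continue from; defaults to the resting state.
#' @return An object of class `simulation_trace`: `times_ms`, `vm_mv`
#'   (node x time matrix, node-id rows), `segments`, `final_state`,
#'   `metadata`.
#' @export
simulate_cable <- function(system, drive = NULL, duration, dt = 0.025,
                           record_stride = 1L, i_inject_ua = NULL,
                           state = NULL) {
  stopifnot(inherits(system, "cable_system"), duration > 0, dt > 0)
  n_steps <- max(1L, as.integer(ceiling(duration / dt - 1e-9)))
  wave <- drive_wave(drive, n_steps, dt)
  pattern <- numeric(system$n)
  if (!is.null(drive)) {
    stopifnot(length(drive$static_pattern) == system$n)
    pattern <- drive$static_pattern[system$order]
  }
  inj <- numeric(system$n)
  if (!is.null(i_inject_ua)) {
    stopifnot(length(i_inject_ua) == system$n)
    inj <- i_inject_ua[system$order]
  }
  if (is.null(state)) {
    v0 <- system$v0_mv
    gates0 <- system$gates0
  } else {
    v0 <- state$v_mv[system$order]
    gates0 <- state$gates[system$order, , drop = FALSE]
  }
  out <- cable_run_cpp(system$parent, system$g_parent_ms, system$cap_uf,
                       system$g_leak_ms, system$e_leak_mv, system$erev,
                       as.integer(system$gates_per_channel),
                       system$gate_params, system$gbar_ms,
                       v0, gates0, pattern, wave, inj, dt,
                       as.integer(record_stride))
  inv <- order(system$pos)  # solver index -> original node rows
  vm <- out$vm[system$pos, , drop = FALSE]
  rownames(vm) <- system$morphology$segments$node_id
  final_state <- list(v_mv = out$v_final[system$pos],
                      gates = out$gates_final[system$pos, , drop = FALSE])
  structure(list(
    times_ms = out$rec_steps * dt,
    vm_mv = vm,
    segments = system$morphology$segments,
    final_state = final_state,
    metadata = list(
      dt_ms = dt, duration_ms = n_steps * dt, solver = "backward_euler",
      deterministic = TRUE, record_stride = as.integer(record_stride),
      ac = if (is.null(drive)) NA_real_ else drive$ac,
      waveform = if (!is.null(drive) && !is.null(drive$waveform)) {
        unclass(drive$waveform)
      },
      gradient_method = "analytic"
    )
  ), class = "simulation_trace")
}

#' Advance the cable state by one implicit step
#'
#' Single backward-Euler update, exposed for testing and custom loops.
#'
#' @inheritParams simulate_cable
#' @param state A list with `v_mv` and `gates` (node-id order); defaults to
#'   rest.
#' @param t Current time (ms), used to evaluate the drive waveform.
#' @return The updated state list (with `t` advanced by `dt`).
#' @export
cable_step <- function(system, state = NULL, drive = NULL, t = 0,
                       dt = 0.025) {
  if (is.null(state)) {
    inv <- order(system$pos)
    state <- list(v_mv = system$v0_mv[inv],
                  gates = system$gates0[inv, , drop = FALSE], t = t)
  }
  pattern <- numeric(system$n)
  wave <- c(0, 0)
  if (!is.null(drive)) {
    pattern <- drive$static_pattern[system$order]
    if (is.null(drive$waveform)) {
      wave <- c(drive$ac, drive$ac)
    } else {
      wave <- drive$ac * modulator_eval(drive$waveform, c(t, t + dt),
                                        drive$reference_amplitude_mv)
    }
  }
  out <- cable_run_cpp(system$parent, system$g_parent_ms, system$cap_uf,
                       system$g_leak_ms, system$e_leak_mv, system$erev,
                       as.integer(system$gates_per_channel),
                       system$gate_params, system$gbar_ms,
                       state$v_mv[system$order],
                       state$gates[system$order, , drop = FALSE],
                       pattern, wave, numeric(system$n), dt, 1L)
  list(v_mv = out$v_final[system$pos],
       gates = out$gates_final[system$pos, , drop = FALSE],
       t = (state$t %||% t) + dt)
}

#' @export
print.simulation_trace <- function(x, ...) {
  cat(sprintf(
    "<simulation_trace> %d nodes x %d samples, t in [0, %g] ms (dt = %g ms, %s)\n",
    nrow(x$vm_mv), ncol(x$vm_mv), max(x$times_ms), x$metadata$dt_ms,
    x$metadata$solver))
  cat(sprintf("  Vm range [%.2f, %.2f] mV\n", min(x$vm_mv), max(x$vm_mv)))
  invisible(x)
}

#' Tidy a simulation trace into long format
#'
#' @param x A `simulation_trace`.
#' @param ... Unused.
#' @return A tibble `(time_ms, node_id, kind, vm_mv)`.
#' @export
tidy.simulation_trace <- function(x, ...) {
  segs <- x$segments
  tibble::tibble(
    time_ms = rep(x$times_ms, each = nrow(x$vm_mv)),
    node_id = rep(segs$node_id, length(x$times_ms)),
    kind = rep(segs$kind, length(x$times_ms)),
    vm_mv = as.numeric(x$vm_mv)
  )
}

#' @rdname tidy.simulation_trace
#' @export
glance.simulation_trace <- function(x, ...) {
  tibble::tibble(
    n_nodes = nrow(x$vm_mv), n_samples = ncol(x$vm_mv),
    duration_ms = x$metadata$duration_ms, dt_ms = x$metadata$dt_ms,
    peak_vm_mv = max(x$vm_mv), min_vm_mv = min(x$vm_mv),
    solver = x$metadata$solver
  )
}

#' Export a trace as CSV plus JSON metadata
#'
#' @param trace A `simulation_trace`.
#' @param path Output CSV path (long format `time_ms, node_id, vm_mv`).
#' @param metadata_path Optional JSON path for the run metadata.
#' @export
write_trace_csv <- function(trace, path, metadata_path = NULL) {
  utils::write.csv(tidy(trace)[c("time_ms", "node_id", "vm_mv")], path,
                   row.names = FALSE)
  if (!is.null(metadata_path)) {
    jsonlite::write_json(trace$metadata, metadata_path, auto_unbox = TRUE,
                         digits = NA, null = "null")
  }
  invisible(path)
}
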