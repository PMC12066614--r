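#' Extracellular potential profile along the axon
#'
#' Samples the superposed source potential densely along the axon line, for
#' Figure-style distribution plots and activating-function analysis.
#'
#' @param morph A [morphology()] with an axon.
#' @param sources A [menp_source()] or list of them.
#' @param step Sampling step (um), default 0.01.
#' @param window Optional half-width (um) of an arclength window centred on
#'   `center` (default the whole axon).
#' @param center Arclength (um) of the window centre; default the axon
#'   node nearest the path midpoint.
#' @param max_degree Series truncation.
#' @return A tibble `(arclength_um, x, y, z, v_mv)`.
#' @export
axon_potential_profile <- function(morph, sources, step = 0.01,
                                   window = NULL, center = NULL,
                                   max_degree = 51) {
  rng <- NULL
  if (!is.null(window)) {
    if (is.null(center)) {
      path <- axon_path(morph)
      total <- max(path$arclength_um) + min(path$arclength_um)
      center <- path$arclength_um[which.min(abs(path$arclength_um -
                                                  total / 2))]
    }
    rng <- c(center - window, center + window)
  }
  line <- sample_axon_line(morph, step = step, range = rng)
  v <- field_potential(cbind(line$x, line$y, line$z), sources,
                       max_degree = max_degree)$v_mv
  dplyr::mutate(line, v_mv = v)
}

#' Summary metrics of a potential profile
#'
#' Peak absolute potential, full width at half maximum of `|V|`, and the
#' spatial extent over which `|V|` exceeds 10% of its peak.
#'
#' @param profile Tibble with `arclength_um` and `v_mv`.
#' @return A one-row tibble `(peak_abs_mv, fwhm_um, extent10_um)`.
#' @export
profile_metrics <- function(profile) {
  a <- abs(profile$v_mv)
  pk <- max(a)
  width_at <- function(frac) {
    above <- profile$arclength_um[a >= frac * pk]
    if (length(above) < 2) return(0) else diff(range(above))
  }
  tibble::tibble(peak_abs_mv = pk, fwhm_um = width_at(0.5),
                 extent10_um = width_at(0.1))
}

first_spike_label <- function(res) {
  if (is.na(res$initiation_node)) return(NA_character_)
  kind <- res$trace$segments$kind[match(res$initiation_node,
                                        res$trace$segments$node_id)]
  switch(kind, axon = "Axon", soma = "Soma",
         basal_dendrite = , apical_dendrite = "Dend", "Other")
}

table1_label <- function(res) {
  if (res$success && res$outcome == "axonal_spike") {
    if (identical(first_spike_label(res), "Axon")) {
      format(signif(res$ac, 4))
    } else {
      "Starting from dendrite"
    }
  } else if (res$outcome == "dendrite_confined") {
    "No axon stimulation"
  } else {
    "No spike"
  }
}

sweep_metadata <- function(spec, morph, membrane) {
  list(
    config_hash = rlang::hash(spec),
    morphology_hash = rlang::hash(morph$sections),
    membrane_hash = rlang::hash(membrane),
    solver = "backward_euler"
  )
}

#' Single-source size, orientation and distance sweep
#'
#' Sweeps a single MENP source over particle size, orientation and
#' distance: for each particle size, orientation and gap (1r or 2r), one source is placed at
#' the central axonal node and the amplification coefficient for an axonal
#' spike is titrated with a one-period sinusoid. Cells where no axonal
#' spike is reachable are reported categorically ("No axon stimulation"
#' when the spike stays dendrite-confined, "Starting from dendrite" when a
#' dendritic spike propagates into the axon).
#'
#' @param morph A [morphology()], default [make_ca1_like()].
#' @param membrane A [membrane_model()], default [default_membrane()].
#' @param radii Particle radii (um), default `c(0.05, 5)` (100 nm MENP and
#'   10 um cluster).
#' @param orientations Orientation set, default all three.
#' @param gap_multipliers Gaps as multiples of the radius, default
#'   `c(1, 2)` (1r and 2r).
#' @param frequency One-period sinusoid frequency (Hz), default 100.
#' @param pole_amplitude Pole potential (mV), default 5.
#' @param dt Time step (ms).
#' @param ... Passed to [titrate()].
#' @return A tibble with one row per configuration, carrying a `metadata`
#'   attribute (config hashes, solver settings).
#' @export
run_table1 <- function(morph = make_ca1_like(),
                       membrane = default_membrane(),
                       radii = c(0.05, 5),
                       orientations = c("parallel",
                                        "perpendicular_negative",
                                        "perpendicular_positive"),
                       gap_multipliers = c(1, 2), frequency = 100,
                       pole_amplitude = 5, dt = 0.025, ...) {
  system <- cable_system(morph, membrane)
  target <- resolve_targets(morph, "axon")
  node <- c(target$x, target$y, target$z)
  dir <- segment_direction(morph, target$node_id)
  wf <- stim_waveform("one_period_sine", frequency = frequency)
  grid <- expand.grid(gap_multiplier = gap_multipliers,
                      orientation = orientations, radius = radii,
                      stringsAsFactors = FALSE)
  rows <- purrr::pmap(grid, function(gap_multiplier, orientation, radius) {
    gap <- gap_multiplier * radius
    src <- place_source(node, dir, orientation, gap = gap, radius = radius,
                        pole_amplitude = pole_amplitude)
    pattern <- static_node_pattern(morph, src)
    res <- titrate(system, pattern, wf, success = "any_spike", dt = dt,
                   reference_amplitude_mv = pole_amplitude, ...)
    tibble::tibble(
      dimension = if (radius < 1) "nanometric" else "cluster",
      radius_um = radius, orientation = orientation,
      gap_label = paste0(gap_multiplier, "r"), gap_um = gap,
      ac = res$ac, outcome = res$outcome,
      first_spike = first_spike_label(res), label = table1_label(res)
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "metadata") <- c(
    sweep_metadata(list(radii = radii, orientations = orientations,
                        gap_multipliers = gap_multipliers,
                        frequency = frequency, dt = dt), morph, membrane),
    list(dt_ms = dt, frequency_hz = frequency, target_node = target$node_id))
  out
}

# dt tightened so a sine period is resolved by >= min_steps_per_period
auto_dt <- function(frequency, dt, min_steps_per_period = 40) {
  min(dt, 1000 / (frequency * min_steps_per_period))
}

#' Frequency sweep of the multi-MENP summation experiment
#'
#' Three MENPs (axon plus two basal dendrites by default) drive the neuron
#' with a fixed-duration sine burst whose frequency is swept; each row
#' reports the titrated amplification coefficient, the outcome, and the
#' location of the first spike. The time step is auto-tightened at high
#' frequency so every period keeps at least `min_steps_per_period` steps.
#'
#' @inheritParams run_table1
#' @param frequencies Sweep grid (Hz).
#' @param targets Target selectors, default `c("axon", "basal:1",
#'   "basal:2")`.
#' @param duration Burst duration (ms), default 100.
#' @param bias Static bias (mV), default 0.
#' @param min_steps_per_period Solver resolution rule, default 40.
#' @return A tibble with one row per frequency (attribute `metadata`).
#' @export
run_frequency_sweep <- function(morph = make_ca1_like(),
                                membrane = default_membrane(),
                                frequencies = c(50, 100, 250, 400, 500,
                                                600, 750, 1000, 10000),
                                targets = c("axon", "basal:1", "basal:2"),
                                duration = 100, bias = 0, dt = 0.025,
                                min_steps_per_period = 40, ...) {
  system <- cable_system(morph, membrane)
  rows <- purrr::map(frequencies, function(f) {
    dtf <- auto_dt(f, dt, min_steps_per_period)
    wf <- stim_waveform("sine_burst", frequency = f, duration = duration,
                        bias = bias)
    res <- summation_experiment(morph, membrane, targets, wf,
                                system = system, dt = dtf, ...)
    tibble::tibble(
      frequency_hz = f, ac = res$ac, outcome = res$outcome,
      first_spike = first_spike_label(res),
      initiation_node = res$initiation_node, dt_ms = dtf,
      n_runs = res$n_runs
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "metadata") <- c(
    sweep_metadata(list(frequencies = frequencies, targets = targets,
                        duration = duration, bias = bias, dt = dt),
                   morph, membrane),
    list(targets = targets, duration_ms = duration,
         min_steps_per_period = min_steps_per_period))
  out
}

#' Target-combination helpers
#'
#' `combo_targets()` builds a selector vector for the axon, the first
#' `n_dend` basal dendrites and optionally the soma;
#' `default_combinations()` lists the six canonical target combinations
#' of the segment-combination sweep.
#'
#' @param n_dend Number of basal dendrites.
#' @param axon,soma Include the axon / soma target.
#' @return A character vector of selectors (or a named list of them).
#' @export
combo_targets <- function(n_dend, axon = TRUE, soma = FALSE) {
  c(if (axon) "axon",
    if (n_dend > 0) paste0("basal:", seq_len(n_dend)),
    if (soma) "soma")
}

#' @rdname combo_targets
#' @export
default_combinations <- function() {
  list(
    "axon+2dend" = combo_targets(2),
    "axon+3dend" = combo_targets(3),
    "axon+4dend" = combo_targets(4),
    "axon+3dend+soma" = combo_targets(3, soma = TRUE),
    "axon+4dend+soma" = combo_targets(4, soma = TRUE),
    "4dend+soma" = combo_targets(4, axon = FALSE, soma = TRUE)
  )
}

#' Segment-combination sweep at a fixed frequency
#'
#' Titrates the amplification coefficient for each target-combination of
#' neuronal compartments (axon, basal dendrites, soma) at a fixed sine
#' frequency.
#'
#' @inheritParams run_frequency_sweep
#' @param combinations Named list of selector vectors; default the six
#'   canonical combinations (axon+2..4 dendrites, with/without soma,
#'   4 dendrites + soma).
#' @param frequency Sine frequency (Hz), default 500.
#' @return A tibble with one row per combination (attribute `metadata`).
#' @export
run_combination_sweep <- function(morph = make_ca1_like(),
                                  membrane = default_membrane(),
                                  combinations = default_combinations(),
                                  frequency = 500, duration = 100,
                                  bias = 0, dt = 0.025,
                                  min_steps_per_period = 40, ...) {
  system <- cable_system(morph, membrane)
  dtf <- auto_dt(frequency, dt, min_steps_per_period)
  wf <- stim_waveform("sine_burst", frequency = frequency,
                      duration = duration, bias = bias)
  rows <- purrr::imap(combinations, function(targets, name) {
    res <- summation_experiment(morph, membrane, targets, wf,
                                system = system, dt = dtf, ...)
    tibble::tibble(
      combination = name, n_sources = length(targets), ac = res$ac,
      outcome = res$outcome, first_spike = first_spike_label(res),
      dt_ms = dtf
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "metadata") <- c(
    sweep_metadata(list(combinations = combinations, frequency = frequency,
                        duration = duration, bias = bias, dt = dt),
                   morph, membrane),
    list(frequency_hz = frequency, duration_ms = duration))
  out
}

#' Static-bias sweep
#'
#' Sweeps the static potential bias added to the sine burst for several
#' target combinations, titrating the amplification coefficient at each
#' bias level. The bias is normalized by the pole amplitude and scales
#' with AC, mirroring the titration equation.
#'
#' @inheritParams run_combination_sweep
#' @param biases Bias grid (mV), default `seq(5, 40, by = 5)`.
#' @return A tibble with one row per (combination, bias).
#' @export
run_bias_sweep <- function(morph = make_ca1_like(),
                           membrane = default_membrane(),
                           combinations = list(
                             "axon+2dend" = combo_targets(2),
                             "axon+3dend+soma" = combo_targets(3, soma = TRUE),
                             "axon+4dend+soma" = combo_targets(4, soma = TRUE)
                           ),
                           biases = seq(5, 40, by = 5), frequency = 500,
                           duration = 100, dt = 0.025,
                           min_steps_per_period = 40,
                           ac_bounds = c(0.125, 64), ...) {
  system <- cable_system(morph, membrane)
  dtf <- auto_dt(frequency, dt, min_steps_per_period)
  grid <- expand.grid(bias_mv = biases,
                      combination = names(combinations),
                      stringsAsFactors = FALSE)
  rows <- purrr::pmap(grid, function(bias_mv, combination) {
    wf <- stim_waveform("sine_burst", frequency = frequency,
                        duration = duration, bias = bias_mv)
    res <- summation_experiment(morph, membrane,
                                combinations[[combination]], wf,
                                system = system, dt = dtf,
                                ac_bounds = ac_bounds, ...)
    tibble::tibble(
      combination = combination, bias_mv = bias_mv, ac = res$ac,
      outcome = res$outcome, first_spike = first_spike_label(res)
    )
  })
  out <- dplyr::bind_rows(rows)
  out <- dplyr::arrange(out, factor(.data$combination,
                                    levels = names(combinations)),
                        .data$bias_mv)
  attr(out, "metadata") <- c(
    sweep_metadata(list(combinations = combinations, biases = biases,
                        frequency = frequency, duration = duration,
                        dt = dt), morph, membrane),
    list(frequency_hz = frequency, duration_ms = duration, dt_ms = dtf))
  out
}

#' Read an experiment specification file
#'
#' YAML with keys `experiment` (one of `table1`, `frequency_sweep`,
#' `combination_sweep`, `bias_sweep`), `morphology` (either
#' `synthetic: true` with optional generator arguments, or `swc: <path>`),
#' optional `membrane: <config path>`, and any driver arguments
#' (`frequencies`, `biases`, `frequency`, `duration`, `dt`, `rel_tol`,
#' ...).
#'
#' @param path YAML file path.
#' @return A list of class `experiment_spec`.
#' @export
read_experiment_spec <- function(path) {
  spec <- yaml::read_yaml(path)
  known <- c("table1", "frequency_sweep", "combination_sweep", "bias_sweep")
  if (is.null(spec$experiment) || !spec$experiment %in% known) {
    stop("experiment spec needs `experiment:` one of ",
         paste(known, collapse = ", "), call. = FALSE)
  }
  structure(spec, class = "experiment_spec")
}

#' Run an experiment specification
#'
#' @param spec An `experiment_spec` (or path to one).
#' @return The driver's result tibble.
#' @export
run_experiment <- function(spec) {
  if (is.character(spec)) spec <- read_experiment_spec(spec)
  morph <- if (!is.null(spec$morphology$swc)) {
    read_swc(spec$morphology$swc)
  } else {
    args <- spec$morphology
    args$synthetic <- NULL
    do.call(make_ca1_like, args %||% list())
  }
  membrane <- if (!is.null(spec$membrane)) {
    load_membrane_config(spec$membrane)
  } else {
    default_membrane()
  }
  driver <- switch(spec$experiment,
                   table1 = run_table1,
                   frequency_sweep = run_frequency_sweep,
                   combination_sweep = run_combination_sweep,
                   bias_sweep = run_bias_sweep)
  args <- spec[setdiff(names(spec), c("experiment", "morphology",
                                      "membrane"))]
  do.call(driver, c(list(morph = morph, membrane = membrane), args))
}

#' Write a sweep result as CSV (+ JSON metadata bundle)
#'
#' @param result A driver result tibble.
#' @param path CSV output path.
#' @param metadata_path Optional JSON path for the metadata attribute.
#' @export
write_result_csv <- function(result, path, metadata_path = NULL) {
  utils::write.csv(result, path, row.names = FALSE)
  if (!is.null(metadata_path)) {
    jsonlite::write_json(attr(result, "metadata"), metadata_path,
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}
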