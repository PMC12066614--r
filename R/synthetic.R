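#' Synthetic CA1-like morphology
#'
#' Deterministic stand-in for a reconstructed CA1 pyramidal cell, matching
#' the compartment inventory the stimulation experiments need: one soma,
#' one straight axon, a fan of basal dendrites, a connector leading to an
#' apical trunk with terminal branches. It makes no attempt to match the
#' section count or branching statistics of a real reconstruction; section
#' lengths are chosen so axonal and basal segments have comparable size
#' (25 um at the default two segments per section).
#'
#' Layout: the soma is a 20 um cylinder along +y centred at the origin; the
#' axon runs from the soma base along -y; basal dendrites fan out from the
#' soma base at 45 degrees from the axon direction; the apical trunk leaves
#' the soma apex through a short connector and ends in two branches.
#'
#' @param n_basal Number of basal dendrites (default 4).
#' @param basal_length Basal dendrite length (um, default 150), split into
#'   `basal_sections` sections.
#' @param basal_diameter Basal dendrite tip diameter (um, default 0.6); the
#'   dendrite tapers linearly from `basal_base_diameter` at the soma.
#' @param basal_base_diameter Basal dendrite diameter at the soma (um,
#'   default 2).
#' @param basal_sections Sections per basal dendrite (default 2).
#' @param axon_length Axon length (um, default 400).
#' @param axon_diameter Axon diameter (um, default 1).
#' @param axon_sections Number of axonal sections (default 8).
#' @param soma_diameter Soma diameter and length (um, default 20).
#' @param apical_trunk_length Apical trunk length (um, default 300).
#' @param branch_angle Apical branch half-angle (degrees, default 30).
#' @param seed Optional integer; when set, adds small deterministic jitter
#'   (sd 0.5 um) to dendritic end points. Default `NULL` (no jitter).
#' @param nseg Segments per section (default 2).
#' @return A [morphology()].
#' @export
make_ca1_like <- function(n_basal = 4, basal_length = 150,
                          basal_diameter = 0.6, basal_base_diameter = 2,
                          basal_sections = 2,
                          axon_length = 400, axon_diameter = 1,
                          axon_sections = 3, soma_diameter = 20,
                          apical_trunk_length = 300, branch_angle = 30,
                          seed = NULL, nseg = 2) {
  stopifnot(n_basal >= 1, basal_sections >= 1, axon_sections >= 1)
  jit <- function(k) {
    if (is.null(seed)) return(matrix(0, k, 3))
    old <- .Random.seed_get()
    on.exit(.Random.seed_set(old))
    set.seed(seed)
    matrix(stats::rnorm(3 * k, sd = 0.5), k, 3)
  }
  rows <- list()
  add <- function(parent_id, kind, pts, diam) {
    g <- cbind(pts, diam)
    dimnames(g) <- list(NULL, c("x", "y", "z", "diam"))
    rows[[length(rows) + 1]] <<- tibble::tibble(
      section_id = length(rows) + 1L,
      parent_id = parent_id, kind = kind, geometry = list(g))
    length(rows)
  }
  base <- c(0, -soma_diameter / 2, 0)
  apex <- c(0, soma_diameter / 2, 0)
  soma_id <- add(NA_integer_, "soma", rbind(base, apex), soma_diameter)
  # axon: chain of sections along -y from the soma base
  prev <- soma_id
  # soma geometry runs base -> apex, so axon children must attach at the
  # soma *start*; attach the axon and basal fan to a zero-level junction by
  # building their first geometry point at the soma base.
  seg_len <- axon_length / axon_sections
  p0 <- base
  for (k in seq_len(axon_sections)) {
    p1 <- base + c(0, -k * seg_len, 0)
    id <- add(prev, "axon", rbind(p0, p1), axon_diameter)
    prev <- id
    p0 <- p1
  }
  # basal fan: 45 degrees off the axon direction, equally spaced azimuths
  jb <- jit(n_basal)
  for (b in seq_len(n_basal)) {
    phi <- 2 * pi * (b - 1) / n_basal
    dir <- c(sin(pi / 4) * cos(phi), -cos(pi / 4), sin(pi / 4) * sin(phi))
    prev <- soma_id
    p0 <- base
    d0 <- basal_base_diameter
    for (k in seq_len(basal_sections)) {
      frac <- k / basal_sections
      d1 <- basal_base_diameter +
        (basal_diameter - basal_base_diameter) * frac
      p1 <- base + dir * basal_length * frac
      if (k == basal_sections) p1 <- p1 + jb[b, ]
      id <- add(prev, "basal_dendrite", rbind(p0, p1), c(d0, d1))
      prev <- id
      p0 <- p1
      d0 <- d1
    }
  }
  # connector then apical trunk (4 sections) and two terminal branches
  conn_end <- apex + c(0, 30, 0)
  conn_id <- add(soma_id, "connector", rbind(apex, conn_end), 2)
  prev <- conn_id
  p0 <- conn_end
  for (k in seq_len(4)) {
    p1 <- conn_end + c(0, apical_trunk_length * k / 4, 0)
    prev <- add(prev, "apical_dendrite", rbind(p0, p1), 2)
    p0 <- p1
  }
  th <- branch_angle * pi / 180
  ja <- jit(2)
  for (s in c(-1, 1)) {
    dir <- c(s * sin(th), cos(th), 0)
    mid <- p0 + dir * 75
    tip <- p0 + dir * 150 + ja[(s + 3) / 2, ]
    b1 <- add(prev, "apical_dendrite", rbind(p0, mid), 1)
    add(b1, "apical_dendrite", rbind(mid, tip), 1)
  }
  morphology(dplyr::bind_rows(rows), nseg_default = nseg)
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
}

.Random.seed_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Straight unbranched axon
#'
#' Collinear axon along +x starting at the origin, for activating-function
#' and single-MENP experiments in the regime where the straight-fiber
#' approximation holds.
#'
#' @param length Total length (um), default 100.
#' @param diameter Diameter (um), default 1.
#' @param n_sections Number of sections (>= 3), default 50.
#' @param nseg Segments per section, default 2.
#' @return A [morphology()] whose sections are all of kind `axon`.
#' @export
make_straight_axon <- function(length = 100, diameter = 1, n_sections = 50,
                               nseg = 2) {
  stopifnot(n_sections >= 3)
  L <- length / n_sections
  rows <- lapply(seq_len(n_sections), function(k) {
    g <- cbind(x = c((k - 1) * L, k * L), y = 0, z = 0, diam = diameter)
    colnames(g) <- c("x", "y", "z", "diam")
    tibble::tibble(section_id = k,
                   parent_id = if (k == 1) NA_integer_ else k - 1L,
                   kind = "axon", geometry = list(g))
  })
  morphology(dplyr::bind_rows(rows), nseg_default = nseg)
}

#' Known-answer fixture bundle
#'
#' Small self-contained cases with analytically known behaviour, used to
#' validate the cable engine and the analysis protocols:
#' \describe{
#'   \item{`isopotential`}{a single compact passive compartment whose free
#'     decay from a perturbed voltage has the membrane time constant
#'     (28 ms by default).}
#'   \item{`finite_cable`}{a sealed passive cable with constant current
#'     injection at one end; the steady profile is
#'     `V(x) / V(0) = cosh((L - x) / lambda) / cosh(L / lambda)` with
#'     `lambda = sqrt(Rm d / (4 Ra))`.}
#'   \item{`planted_trace`}{a synthetic trace matrix with threshold
#'     crossings planted at known nodes and times.}
#'   \item{`planted_predicate`}{a step success predicate that is true iff
#'     AC >= a planted threshold, for validating the titration search.}
#' }
#'
#' @param planted_threshold Planted titration threshold, default 37.3.
#' @return A named list of fixtures; each element carries the inputs plus
#'   the expected ground truth.
#' @export
make_known_answer_cases <- function(planted_threshold = 37.3) {
  iso_morph <- make_straight_axon(length = 10, diameter = 2, n_sections = 3,
                                  nseg = 1)
  iso <- list(
    morphology = iso_morph,
    membrane = passive_membrane(),
    v_perturbed_mv = -55,
    expected_tau_ms = passive_properties()$tau_m_ms
  )

  cab_morph <- make_straight_axon(length = 1000, diameter = 1,
                                  n_sections = 200, nseg = 1)
  p <- passive_properties()
  lambda_um <- sqrt(p$rm_kohm_cm2 * 1000 * (1e-4 / 4) / p$ra_ohm_cm) * 1e4
  cab <- list(
    morphology = cab_morph,
    membrane = passive_membrane(),
    inject_node = 1L,
    i_inject_ua = 1e-5,
    lambda_um = lambda_um
  )

  times <- seq(0, 10, by = 0.1)
  vm <- matrix(-65, nrow = 6, ncol = length(times))
  planted <- tibble::tibble(node_id = c(2L, 5L),
                            t_cross_ms = c(3.0, 6.5))
  for (i in seq_len(nrow(planted))) {
    vm[planted$node_id[i], times >= planted$t_cross_ms[i]] <- 20
  }
  segs <- make_straight_axon(length = 30, n_sections = 3)$segments
  trace <- structure(list(
    times_ms = times, vm_mv = vm, segments = segs,
    final_state = NULL,
    metadata = list(dt_ms = 0.1, duration_ms = 10, solver = "planted",
                    deterministic = TRUE)
  ), class = "simulation_trace")

  list(
    isopotential = iso,
    finite_cable = cab,
    planted_trace = list(trace = trace, planted = planted),
    planted_predicate = list(
      threshold = planted_threshold,
      predicate = function(ac) ac >= planted_threshold
    )
  )
}
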