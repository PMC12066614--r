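#' Magnetoelectric nanoparticle (MENP) dipole source
#'
#' A MENP exposed to a magnetic field above saturation develops a dipolar
#' surface potential: a positive and a negative hemispherical cap at a fixed
#' potential, separated by a thin insulating equatorial band. `menp_source()`
#' builds the corresponding split-sphere Dirichlet source used by the
#' analytic exterior-Laplace field solver.
#'
#' All geometry is in micrometres and all potentials in millivolts.
#'
#' @param center Numeric length-3, sphere centre (um).
#' @param radius Sphere radius (um); 0.05 for a 100 nm particle, 5 for a
#'   10 um cluster.
#' @param axis Numeric length-3 unit vector pointing from the negative to the
#'   positive pole (normalised internally; must be non-zero).
#' @param pole_amplitude Cap potential V0 (mV); the caps sit at +V0 and -V0.
#'   Sign flips the dipole. Default 5 mV.
#' @param band_halfwidth Polar half-width of the insulating equatorial band
#'   (radians) on which the surface potential is 0; in `[0, pi/2)`. Default 0
#'   (zero-width sign discontinuity).
#' @return An object of class `menp_source`.
#' @examples
#' src <- menp_source(center = c(0, 0, 0), radius = 0.05, axis = c(0, 0, 1))
#' field_potential(data.frame(x = 0, y = 0, z = 0.5), src)
#' @export
menp_source <- function(center, radius, axis, pole_amplitude = 5,
                        band_halfwidth = 0) {
  center <- as.numeric(center)
  axis <- as.numeric(axis)
  stopifnot(length(center) == 3, length(axis) == 3)
  if (!is.numeric(radius) || length(radius) != 1 || !is.finite(radius) ||
      radius <= 0) {
    stop("`radius` must be a single positive number (um)", call. = FALSE)
  }
  nrm <- sqrt(sum(axis^2))
  if (nrm < 1e-12) stop("`axis` must be a non-zero vector", call. = FALSE)
  axis <- axis / nrm
  if (!is.finite(pole_amplitude)) {
    stop("`pole_amplitude` must be finite (mV)", call. = FALSE)
  }
  if (band_halfwidth < 0 || band_halfwidth >= pi / 2) {
    stop("`band_halfwidth` must lie in [0, pi/2)", call. = FALSE)
  }
  structure(
    list(center = center, radius = radius, axis = axis,
         pole_amplitude = pole_amplitude, band_halfwidth = band_halfwidth),
    class = "menp_source"
  )
}

#' @export
print.menp_source <- function(x, ...) {
  cat(sprintf(
    "<menp_source> R = %g um, V0 = %g mV, center = (%g, %g, %g) um\n",
    x$radius, x$pole_amplitude, x$center[1], x$center[2], x$center[3]))
  cat(sprintf("  axis = (%.4f, %.4f, %.4f), band halfwidth = %g rad\n",
              x$axis[1], x$axis[2], x$axis[3], x$band_halfwidth))
  invisible(x)
}

#' Homogeneous conductive medium
#'
#' Metadata container for the extracellular medium: an isotropic block of
#' grey-matter-like conductivity. The exterior Dirichlet potential of a
#' split-sphere source does not depend on the conductivity of a homogeneous
#' medium; `conductivity` is used only for current-density queries.
#'
#' @param conductivity Electric conductivity (S/m), default 0.333.
#' @param bounds Axis-aligned box dimensions (mm), default `c(1, 1, 1.5)`.
#' @return An object of class `conductive_medium`.
#' @export
conductive_medium <- function(conductivity = 0.333, bounds = c(1, 1, 1.5)) {
  stopifnot(is.numeric(conductivity), length(conductivity) == 1,
            conductivity > 0, length(bounds) == 3, all(bounds > 0))
  structure(list(conductivity = conductivity, bounds = as.numeric(bounds)),
            class = "conductive_medium")
}

# Legendre polynomials P_0..P_lmax at x, by the three-term recurrence.
# Returns a length(x) x (lmax + 1) matrix; column l + 1 holds P_l(x).
legendre_p <- function(lmax, x) {
  x <- as.numeric(x)
  out <- matrix(0, nrow = length(x), ncol = lmax + 1)
  out[, 1] <- 1
  if (lmax >= 1) out[, 2] <- x
  if (lmax >= 2) {
    for (l in 2:lmax) {
      out[, l + 1] <- ((2 * l - 1) * x * out[, l] - (l - 1) * out[, l - 1]) / l
    }
  }
  out
}

# Derivatives P'_0..P'_lmax via P'_l = P'_{l-2} + (2l - 1) P_{l-1},
# which is finite at x = +/-1 (unlike the (1 - x^2) form).
legendre_p_deriv <- function(lmax, x) {
  p <- legendre_p(lmax, x)
  d <- matrix(0, nrow = length(x), ncol = lmax + 1)
  if (lmax >= 1) d[, 2] <- 1
  if (lmax >= 2) {
    for (l in 2:lmax) {
      d[, l + 1] <- d[, l - 1] + (2 * l - 1) * p[, l]
    }
  }
  d
}

#' Legendre expansion of the split-sphere boundary potential
#'
#' Projects the piecewise-constant surface potential (+V0 on the upper cap,
#' -V0 on the lower cap, 0 on the insulating band) onto Legendre polynomials:
#' `A_l = ((2l + 1) / 2) * integral V_surf(u) P_l(u) du` over `u = cos(theta)`
#' in `[-1, 1]`. The boundary condition is antisymmetric, so all even-degree
#' coefficients vanish identically and only odd degrees are computed by
#' Gauss-Legendre quadrature (exact for polynomial integrands at the node
#' counts used; relative accuracy far below 1e-10).
#'
#' @param pole_amplitude Cap potential V0 (mV).
#' @param band_halfwidth Insulating band polar half-width (radians).
#' @param max_degree Highest Legendre degree retained (>= 1).
#' @return An object of class `legendre_coefficients`: a list with
#'   `degree` (0..max_degree), `a_mv` (coefficients, even degrees 0) and
#'   `max_degree`.
#' @examples
#' co <- split_sphere_coefficients(5, 0, 3)
#' co$a_mv  # 0, 7.5, 0, -4.375
#' @export
split_sphere_coefficients <- function(pole_amplitude, band_halfwidth = 0,
                                      max_degree = 51) {
  if (!is.numeric(max_degree) || length(max_degree) != 1 || max_degree < 1) {
    stop("`max_degree` must be an integer >= 1", call. = FALSE)
  }
  max_degree <- as.integer(max_degree)
  if (band_halfwidth < 0 || band_halfwidth >= pi / 2) {
    stop("`band_halfwidth` must lie in [0, pi/2)", call. = FALSE)
  }
  s <- sin(band_halfwidth)  # V = +V0 for u > s, 0 for |u| <= s, -V0 for u < -s
  # A_l = (2l+1)/2 * [ V0 * int_s^1 P_l - V0 * int_{-1}^{-s} P_l ]
  #     = (2l+1) * V0 * int_s^1 P_l(u) du   for odd l (parity), 0 for even l.
  gq <- pracma::gaussLegendre(max(64, max_degree + 16), s, 1)
  pl <- legendre_p(max_degree, gq$x)
  a <- numeric(max_degree + 1)
  odd <- seq(1, max_degree, by = 2)
  for (l in odd) {
    a[l + 1] <- (2 * l + 1) * pole_amplitude * sum(gq$w * pl[, l + 1])
  }
  structure(
    list(degree = 0:max_degree, a_mv = a, max_degree = max_degree),
    class = "legendre_coefficients"
  )
}

# Resolve `sources` into a plain list of menp_source objects.
as_source_list <- function(sources) {
  if (inherits(sources, "menp_source")) return(list(sources))
  if (is.list(sources) && all(vapply(sources, inherits, TRUE, "menp_source"))) {
    return(sources)
  }
  stop("`sources` must be a menp_source or a list of menp_source objects",
       call. = FALSE)
}

as_point_matrix <- function(points) {
  if (is.data.frame(points)) {
    cols <- intersect(c("x", "y", "z"), names(points))
    if (length(cols) != 3) {
      cols <- intersect(c("x_um", "y_um", "z_um"), names(points))
    }
    if (length(cols) != 3) {
      stop("`points` data frame needs columns x, y, z (or x_um, y_um, z_um)",
           call. = FALSE)
    }
    m <- as.matrix(points[cols])
  } else {
    m <- rbind(points)
    if (ncol(m) != 3) stop("`points` must have 3 columns", call. = FALSE)
  }
  storage.mode(m) <- "double"
  unname(m)
}

# Local spherical decomposition of points relative to one source.
# Errors if any point lies inside or on the sphere.
local_frame <- function(source, pts) {
  d <- sweep(pts, 2, source$center)
  r <- sqrt(rowSums(d^2))
  bad <- which(r <= source$radius + 1e-15)
  if (length(bad) > 0) {
    stop(sprintf(
      "point %d at (%g, %g, %g) lies inside or on the source sphere (r = %g um <= R = %g um)",
      bad[1], pts[bad[1], 1], pts[bad[1], 2], pts[bad[1], 3], r[bad[1]],
      source$radius), call. = FALSE)
  }
  u <- as.numeric(d %*% source$axis) / r
  u <- pmin(1, pmax(-1, u))
  list(d = d, r = r, u = u)
}

potential_one <- function(source, pts, max_degree) {
  lf <- local_frame(source, pts)
  co <- split_sphere_coefficients(source$pole_amplitude,
                                  source$band_halfwidth, max_degree)
  pl <- legendre_p(max_degree, lf$u)
  rr <- source$radius / lf$r
  v <- numeric(nrow(pts))
  for (l in seq(1, max_degree, by = 2)) {
    v <- v + co$a_mv[l + 1] * rr^(l + 1) * pl[, l + 1]
  }
  v
}

field_one <- function(source, pts, max_degree) {
  lf <- local_frame(source, pts)
  co <- split_sphere_coefficients(source$pole_amplitude,
                                  source$band_halfwidth, max_degree)
  pl <- legendre_p(max_degree, lf$u)
  dp <- legendre_p_deriv(max_degree, lf$u)
  r <- lf$r
  rhat <- lf$d / r
  # grad u = (axis - u * rhat) / r
  gu <- (matrix(source$axis, nrow(pts), 3, byrow = TRUE) - lf$u * rhat) / r
  grad <- matrix(0, nrow(pts), 3)
  for (l in seq(1, max_degree, by = 2)) {
    al <- co$a_mv[l + 1]
    rad <- (source$radius / r)^(l + 1)
    # d/dr term and angular term of A_l (R/r)^(l+1) P_l(u)
    grad <- grad + al * (-(l + 1) * rad / r * pl[, l + 1]) * rhat +
      al * rad * dp[, l + 1] * gu
  }
  -grad  # E = -grad V
}

#' Extracellular potential of MENP sources
#'
#' Evaluates the quasi-static extracellular potential of one or more
#' split-sphere MENP sources at a set of points, by the truncated exterior
#' harmonic series `V(r, theta) = sum_l A_l (R/r)^(l+1) P_l(cos theta)` in
#' each source's local axis frame, summed over sources (superposition holds
#' for the linear quasi-static problem). An empty source list yields zeros.
#'
#' @param points Data frame with columns `x`, `y`, `z` (or `x_um`/`y_um`/
#'   `z_um`), or a numeric matrix with 3 columns (um).
#' @param sources A [menp_source()] or list of them.
#' @param max_degree Series truncation degree (default 51).
#' @return A tibble with columns `x_um`, `y_um`, `z_um`, `v_mv`.
#' @export
field_potential <- function(points, sources = list(), max_degree = 51) {
  pts <- as_point_matrix(points)
  srcs <- if (length(sources) == 0) list() else as_source_list(sources)
  v <- numeric(nrow(pts))
  for (s in srcs) v <- v + potential_one(s, pts, max_degree)
  tibble::tibble(x_um = pts[, 1], y_um = pts[, 2], z_um = pts[, 3], v_mv = v)
}

#' Electric field of MENP sources
#'
#' Analytic gradient of the truncated potential series, `E = -grad V`,
#' summed over sources. Units mV/um (equivalently V/mm).
#'
#' @inheritParams field_potential
#' @return A tibble with columns `x_um`, `y_um`, `z_um`, `ex_mv_um`,
#'   `ey_mv_um`, `ez_mv_um`; attribute `gradient_method = "analytic"`.
#' @export
field_vector <- function(points, sources = list(), max_degree = 51) {
  pts <- as_point_matrix(points)
  srcs <- if (length(sources) == 0) list() else as_source_list(sources)
  e <- matrix(0, nrow(pts), 3)
  for (s in srcs) e <- e + field_one(s, pts, max_degree)
  out <- tibble::tibble(
    x_um = pts[, 1], y_um = pts[, 2], z_um = pts[, 3],
    ex_mv_um = e[, 1], ey_mv_um = e[, 2], ez_mv_um = e[, 3]
  )
  attr(out, "gradient_method") <- "analytic"
  out
}

#' Current density in the medium
#'
#' Ohmic current density `J = sigma * E` at the query points. With E in
#' mV/um (= V/mm = 1000 V/m) and sigma in S/m, J is returned in A/m^2.
#'
#' @inheritParams field_potential
#' @param medium A [conductive_medium()].
#' @return A tibble with `jx_a_m2`, `jy_a_m2`, `jz_a_m2` columns.
#' @export
current_density <- function(points, sources, medium = conductive_medium(),
                            max_degree = 51) {
  stopifnot(inherits(medium, "conductive_medium"))
  e <- field_vector(points, sources, max_degree)
  tibble::tibble(
    x_um = e$x_um, y_um = e$y_um, z_um = e$z_um,
    jx_a_m2 = medium$conductivity * e$ex_mv_um * 1000,
    jy_a_m2 = medium$conductivity * e$ey_mv_um * 1000,
    jz_a_m2 = medium$conductivity * e$ez_mv_um * 1000
  )
}

# Deterministic unit vector perpendicular to v: cross v with the coordinate
# axis least aligned with it.
perp_unit <- function(v) {
  ref <- diag(3)[, which.min(abs(v))]
  w <- c(v[2] * ref[3] - v[3] * ref[2],
         v[3] * ref[1] - v[1] * ref[3],
         v[1] * ref[2] - v[2] * ref[1])
  w / sqrt(sum(w^2))
}

#' Place a MENP relative to a neural segment node
#'
#' Constructs a [menp_source()] positioned against a target node using the
#' three canonical orientations:
#' \describe{
#'   \item{`perpendicular_negative`}{the vertex of the negative pole faces
#'     the node ("cathodic"); the dipole axis is collinear with the
#'     node-to-centre line and points away from the node.}
#'   \item{`perpendicular_positive`}{the positive vertex faces the node
#'     ("anodic"); axis points toward the node.}
#'   \item{`parallel`}{the dipole axis is parallel to the segment direction
#'     and the equatorial plane contains the node ("bipolar"); the centre is
#'     displaced laterally by `gap + radius`.}
#' }
#' In every case the nearest point of the sphere surface is exactly `gap`
#' from the node.
#'
#' @param target_node Numeric length-3 node position (um).
#' @param segment_direction Unit vector along the target segment.
#' @param orientation One of `"parallel"`, `"perpendicular_negative"`,
#'   `"perpendicular_positive"`.
#' @param gap Node-to-surface distance (um), >= 0 (strictly > 0 for the node
#'   to be a valid field point).
#' @param radius Sphere radius (um).
#' @param pole_amplitude Cap potential (mV), default 5.
#' @param lateral Optional unit vector giving the lateral offset direction
#'   (must be perpendicular to `segment_direction`); chosen deterministically
#'   if `NULL`.
#' @return A [menp_source()].
#' @export
place_source <- function(target_node, segment_direction, orientation,
                         gap, radius, pole_amplitude = 5, lateral = NULL) {
  target_node <- as.numeric(target_node)
  dir <- as.numeric(segment_direction)
  stopifnot(length(target_node) == 3, length(dir) == 3, gap >= 0, radius > 0)
  dir <- dir / sqrt(sum(dir^2))
  orientation <- match.arg(orientation, c("parallel", "perpendicular_negative",
                                          "perpendicular_positive"))
  if (is.null(lateral)) {
    lateral <- perp_unit(dir)
  } else {
    lateral <- as.numeric(lateral)
    lateral <- lateral / sqrt(sum(lateral^2))
    if (abs(sum(lateral * dir)) > 1e-8) {
      stop("`lateral` must be perpendicular to `segment_direction`",
           call. = FALSE)
    }
  }
  center <- target_node + (gap + radius) * lateral
  axis <- switch(orientation,
    parallel = dir,
    perpendicular_negative = lateral,   # negative vertex toward the node
    perpendicular_positive = -lateral   # positive vertex toward the node
  )
  menp_source(center = center, radius = radius, axis = axis,
              pole_amplitude = pole_amplitude)
}

#' Read / write MENP source configurations
#'
#' Sources are stored as a YAML list; each entry has keys `center_um`,
#' `radius_um`, `axis`, `pole_amplitude_mv` and optionally
#' `band_halfwidth_rad`.
#'
#' @param path File path.
#' @return `read_source_config()` returns a list of [menp_source()] objects.
#' @export
read_source_config <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(s) {
    menp_source(center = s$center_um, radius = s$radius_um, axis = s$axis,
                pole_amplitude = s$pole_amplitude_mv,
                band_halfwidth = s$band_halfwidth_rad %||% 0)
  })
}

#' @rdname read_source_config
#' @param sources List of [menp_source()] objects.
#' @export
write_source_config <- function(sources, path) {
  srcs <- as_source_list(sources)
  yaml::write_yaml(lapply(srcs, function(s) {
    list(center_um = s$center, radius_um = s$radius, axis = s$axis,
         pole_amplitude_mv = s$pole_amplitude,
         band_halfwidth_rad = s$band_halfwidth)
  }), path)
  invisible(path)
}

#' Export potential samples as CSV
#'
#' Writes the output of [field_potential()] with columns
#' `x_um, y_um, z_um, v_mv`.
#'
#' @param samples Tibble from [field_potential()].
#' @param path Output CSV path.
#' @export
write_potential_csv <- function(samples, path) {
  stopifnot(all(c("x_um", "y_um", "z_um", "v_mv") %in% names(samples)))
  utils::write.csv(samples[c("x_um", "y_um", "z_um", "v_mv")], path,
                   row.names = FALSE)
  invisible(path)
}
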