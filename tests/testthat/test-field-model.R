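# Split-sphere boundary expansion ------------------------------------------

test_that("Legendre coefficients match an independent quadrature oracle", {
  # oracle: A_l = (2l+1)/2 * int_{-1}^{1} V0*sign(u) P_l(u) du via
  # stats::integrate with explicit low-degree polynomials
  p1 <- function(u) u
  p2 <- function(u) (3 * u^2 - 1) / 2
  p3 <- function(u) (5 * u^3 - 3 * u) / 2
  oracle <- function(l, pl) {
    (2 * l + 1) / 2 *
      stats::integrate(function(u) 5 * sign(u) * pl(u), -1, 1,
                       rel.tol = 1e-12)$value
  }
  co <- split_sphere_coefficients(5, 0, 3)
  expect_equal(co$a_mv[2], oracle(1, p1), tolerance = 1e-10)
  expect_equal(co$a_mv[2], 7.5, tolerance = 1e-10)
  expect_equal(co$a_mv[3], 0)
  expect_equal(co$a_mv[4], oracle(3, p3), tolerance = 1e-10)
  expect_equal(co$a_mv[4], -4.375, tolerance = 1e-10)
  # antisymmetric boundary kills all even degrees
  co51 <- split_sphere_coefficients(5, 0, 51)
  expect_true(all(abs(co51$a_mv[seq(1, 52, by = 2)]) < 1e-12))
  expect_error(split_sphere_coefficients(5, 0, 0), "max_degree")
  expect_error(split_sphere_coefficients(5, pi / 2, 5), "band_halfwidth")
})

test_that("a finite insulating band shrinks the coefficients continuously", {
  a0 <- split_sphere_coefficients(5, 0, 1)$a_mv[2]
  ab <- split_sphere_coefficients(5, 0.2, 1)$a_mv[2]
  expect_lt(ab, a0)
  expect_gt(ab, 0)
  # independent closed form for degree 1 with band: 3 V0 int_s^1 u du
  s <- sin(0.2)
  expect_equal(ab, 3 * 5 * (1 - s^2) / 2, tolerance = 1e-10)
})

# Exterior potential ---------------------------------------------------------

test_that("potential matches point-dipole asymptotics and symmetries", {
  src <- menp_source(c(0, 0, 0), 0.05, c(0, 0, 1), 5)
  # on-axis at r = 10R the full series agrees with the degree-1 term to 1%
  r <- 0.5
  v <- field_potential(cbind(0, 0, r), src)$v_mv
  dipole <- 7.5 * (0.05 / r)^2
  expect_lt(abs(v - dipole) / dipole, 0.01)
  # equatorial plane is a null surface
  eq <- field_potential(cbind(c(0.2, -0.4, 1), c(0.3, 0.1, -2), 0), src)
  expect_true(all(abs(eq$v_mv) < 1e-12))
  # mirror antisymmetry: (theta, pi - theta) flip sign at equal r
  pts <- random_exterior_points(50, 0.05, seed = 11)
  mirror <- pts %*% diag(c(1, 1, -1))
  expect_equal(field_potential(pts, src)$v_mv,
               -field_potential(mirror, src)$v_mv, tolerance = 1e-12)
  # interior points are a domain error naming the point
  expect_error(field_potential(cbind(0, 0, 0.04), src), "inside")
})

test_that("superposition is linear and homogeneous", {
  src <- menp_source(c(0, 0, 0), 0.05, c(0, 0, 1), 5)
  twin <- menp_source(c(0, 0, 0), 0.05, c(0, 0, 1), 5)
  opposed <- menp_source(c(0, 0, 0), 0.05, c(0, 0, -1), 5)
  scaled <- menp_source(c(0, 0, 0), 0.05, c(0, 0, 1), 5 * 3.7)
  pts <- random_exterior_points(40, 0.05, seed = 7)
  v1 <- field_potential(pts, src)$v_mv
  expect_equal(field_potential(pts, list(src, twin))$v_mv, 2 * v1,
               tolerance = 1e-12)
  expect_equal(field_potential(pts, list())$v_mv, rep(0, 40))
  expect_true(all(abs(field_potential(pts, list(src, opposed))$v_mv)
                  < 1e-12))
  expect_equal(field_potential(pts, scaled)$v_mv, 3.7 * v1,
               tolerance = 1e-12)
})

test_that("maximum principle holds on random exterior clouds", {
  for (seed in 1:3) {
    src <- menp_source(c(1, -2, 0.5), 0.05, c(1, 1, 1), 5)
    pts <- sweep(random_exterior_points(200, 0.05, seed = seed), 2,
                 c(1, -2, 0.5), "+")
    expect_true(all(abs(field_potential(pts, src)$v_mv) <= 5 + 1e-9))
  }
})

test_that("series is converged at the default truncation", {
  src <- menp_source(c(0, 0, 0), 1, c(0, 0, 1), 5)
  pts <- random_exterior_points(100, 1, seed = 3, rmin = 1.1, rmax = 20)
  v51 <- field_potential(pts, src, max_degree = 51)$v_mv
  v101 <- field_potential(pts, src, max_degree = 101)$v_mv
  expect_lt(max(abs(v101 - v51) / pmax(abs(v101), 1e-6)), 1e-3)
})

test_that("potentials are invariant under joint rotation", {
  rot <- rotation_matrix(c(1, 2, 3), 0.83)
  axis <- c(0.3, -0.5, 0.81)
  src <- menp_source(c(0, 0, 0), 0.05, axis, 5)
  src_rot <- menp_source(c(0, 0, 0), 0.05, as.numeric(rot %*% axis), 5)
  pts <- random_exterior_points(60, 0.05, seed = 5)
  expect_equal(field_potential(pts %*% t(rot), src_rot)$v_mv,
               field_potential(pts, src)$v_mv, tolerance = 1e-10)
})

# Electric field -------------------------------------------------------------

test_that("field follows dipole decay and is consistent with the potential", {
  src <- menp_source(c(0, 0, 0), 0.05, c(0, 0, 1), 5)
  # on-axis far-field magnitude decays as 1/r^3: ratio 8 between 20R, 40R
  e20 <- field_vector(cbind(0, 0, 1), src)
  e40 <- field_vector(cbind(0, 0, 2), src)
  mag <- function(e) sqrt(e$ex_mv_um^2 + e$ey_mv_um^2 + e$ez_mv_um^2)
  expect_lt(abs(mag(e20) / mag(e40) - 8) / 8, 0.02)
  # analytic gradient vs central finite differences of the potential
  pts <- random_exterior_points(20, 0.05, seed = 9)
  e <- field_vector(pts, src)
  h <- 1e-5
  for (d in 1:3) {
    dp <- pts; dp[, d] <- dp[, d] + h
    dm <- pts; dm[, d] <- dm[, d] - h
    fd <- -(field_potential(dp, src)$v_mv -
              field_potential(dm, src)$v_mv) / (2 * h)
    expect_equal(as.numeric(e[[3 + d]]), fd, tolerance = 1e-5)
  }
  # equatorial far field is axial only (degree-1 geometry)
  eq <- field_vector(cbind(1, 0, 0), src)
  expect_lt(abs(eq$ex_mv_um) / abs(eq$ez_mv_um), 0.01)
  # empty superposition gives the zero field
  e0 <- field_vector(pts, list())
  expect_true(all(e0$ex_mv_um == 0 & e0$ey_mv_um == 0 & e0$ez_mv_um == 0))
})

test_that("current density scales with the medium conductivity", {
  src <- menp_source(c(0, 0, 0), 0.05, c(0, 0, 1), 5)
  pts <- cbind(0, 0, 0.5)
  j1 <- current_density(pts, src, conductive_medium(0.333))
  j2 <- current_density(pts, src, conductive_medium(0.666))
  expect_equal(2 * j1$jz_a_m2, j2$jz_a_m2)
})

# Source placement -----------------------------------------------------------

test_that("place_source realises the three orientations", {
  node <- c(1, 2, 3)
  dir <- c(1, 0, 0)
  pn <- place_source(node, dir, "perpendicular_negative", gap = 0.05,
                     radius = 0.05)
  # centre at gap + radius from the node along the lateral normal
  expect_equal(sqrt(sum((pn$center - node)^2)), 0.10, tolerance = 1e-12)
  # axis collinear with node -> centre, pointing away from the node
  away <- (pn$center - node) / 0.10
  expect_equal(as.numeric(pn$axis), away, tolerance = 1e-12)
  # negative vertex faces the node: potential there is negative
  expect_lt(field_potential(rbind(node), pn)$v_mv, 0)

  pp <- place_source(node, dir, "perpendicular_positive", gap = 0.07,
                     radius = 0.05)
  expect_gt(field_potential(rbind(node), pp)$v_mv, 0)
  expect_equal(sqrt(sum((pp$center - node)^2)) - pp$radius, 0.07,
               tolerance = 1e-9)

  pa <- place_source(node, dir, "parallel", gap = 0.03, radius = 0.05)
  # nearest surface point is exactly gap away
  expect_equal(sqrt(sum((pa$center - node)^2)) - pa$radius, 0.03,
               tolerance = 1e-9)
  # axis parallel to the segment, equatorial plane contains the node
  expect_equal(as.numeric(pa$axis), dir, tolerance = 1e-12)
  expect_lt(abs(sum((node - pa$center) * pa$axis)), 1e-12)
  expect_lt(abs(field_potential(rbind(node), pa)$v_mv), 1e-12)

  expect_error(place_source(node, dir, "sideways", 0.05, 0.05))
})

test_that("source configs round-trip through YAML", {
  srcs <- list(place_on_short_axon("perpendicular_negative", 0.05, 0.05),
               menp_source(c(1, 2, 3), 5, c(0, 1, 0), -5, 0.1))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_source_config(srcs, path)
  back <- read_source_config(path)
  expect_equal(length(back), 2)
  expect_equal(back[[1]]$center, srcs[[1]]$center, tolerance = 1e-9)
  expect_equal(back[[2]]$pole_amplitude, -5)
  expect_equal(back[[2]]$band_halfwidth, 0.1)
})

test_that("potential samples export as CSV", {
  src <- menp_source(c(0, 0, 0), 0.05, c(0, 0, 1), 5)
  samples <- field_potential(random_exterior_points(5, 0.05, seed = 1), src)
  path <- withr::local_tempfile(fileext = ".csv")
  write_potential_csv(samples, path)
  back <- utils::read.csv(path)
  expect_named(back, c("x_um", "y_um", "z_um", "v_mv"))
  expect_equal(back$v_mv, samples$v_mv, tolerance = 1e-12)
})
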