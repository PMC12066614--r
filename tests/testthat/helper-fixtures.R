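# Shared fixtures, built once per test run. Everything is generated in code;
# no files are read from outside the package.

ca1 <- make_ca1_like()
active_membrane <- default_membrane()
passive_mb <- passive_membrane()

# a small straight axon used across field/protocol tests (20 um, 40 nodes)
short_axon <- make_straight_axon(length = 20, n_sections = 20)
short_axon_center <- local({
  path <- axon_path(short_axon)
  path[which.min(abs(path$arclength_um - 10)), ]
})

# perpendicular source placement against the short axon's central node
place_on_short_axon <- function(orientation, gap, radius,
                                pole_amplitude = 5) {
  place_source(
    c(short_axon_center$x, short_axon_center$y, short_axon_center$z),
    c(1, 0, 0), orientation, gap = gap, radius = radius,
    pole_amplitude = pole_amplitude)
}

# bare cylinder chains below the make_straight_axon() section minimum
cylinder_morph <- function(length, diameter = 1, n_sections = 1, nseg = 2) {
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

random_exterior_points <- function(n, radius, seed, rmin = 1.05,
                                   rmax = 50) {
  set.seed(seed)
  r <- radius * exp(runif(n, log(rmin), log(rmax)))
  u <- runif(n, -1, 1)
  phi <- runif(n, 0, 2 * pi)
  s <- sqrt(1 - u^2)
  cbind(r * s * cos(phi), r * s * sin(phi), r * u)
}

rotation_matrix <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  c <- cos(angle); s <- sin(angle)
  outer(a, a) * (1 - c) + diag(3) * c +
    matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3) * s
}
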