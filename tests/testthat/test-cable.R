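test_that("axial conductances match the hand formula", {
  # two identical cylinders: Ra 150 Ohm cm, L 5 um, d 1 um each
  m <- cylinder_morph(length = 10, n_sections = 1, nseg = 2)
  sys <- cable_system(m, passive_mb)
  g <- axial_conductance_matrix(sys)
  A <- pi * (0.5e-4)^2                       # cm^2
  r_half <- 150 * (5e-4 / 2) / A             # Ohm
  g_hand_ms <- 1000 / (2 * r_half)
  expect_equal(g[1, 2], g_hand_ms, tolerance = 1e-12)
  expect_equal(g, t(g))
  # axial Laplacian rows sum to zero (conservation)
  lap <- diag(rowSums(g)) - g
  expect_true(all(abs(rowSums(lap)) < 1e-15))
})

test_that("disconnected morphologies are rejected at assembly", {
  secs <- tibble::tibble(
    section_id = 1:2, parent_id = c(NA_integer_, 1L), kind = "axon",
    geometry = list(cbind(x = c(0, 10), y = 0, z = 0, diam = 1),
                    cbind(x = c(50, 60), y = 0, z = 0, diam = 1)))
  m <- morphology(secs)
  m$sections$parent_id[2] <- NA_integer_   # break the tree after validation
  expect_error(cable_system(m, passive_mb), "root|connected")
})

test_that("rest is a fixed point and uniform Ve is gauge-invariant", {
  sys <- cable_system(short_axon, active_membrane)
  n <- sys$n
  tr0 <- simulate_cable(sys, NULL, duration = 5, dt = 0.025)
  expect_lt(max(abs(tr0$vm_mv + 65)), 1e-9)
  expect_equal(tr0$vm_mv[, 1], rep(-65, n), tolerance = 1e-9,
               ignore_attr = TRUE)

  wf <- stim_waveform("one_period_sine", 100)
  flat <- extracellular_drive(rep(7.3, n), wf, ac = 20)
  trf <- simulate_cable(sys, flat, duration = 15, dt = 0.025)
  expect_lt(max(abs(trf$vm_mv + 65)), 1e-9)

  # adding a constant to a non-trivial pattern leaves all traces unchanged
  pat <- static_node_pattern(short_axon,
                             place_on_short_axon("perpendicular_negative",
                                                 0.05, 0.05))
  tr1 <- simulate_cable(sys, extracellular_drive(pat, wf, ac = 3),
                        duration = 15, dt = 0.025)
  tr2 <- simulate_cable(sys, extracellular_drive(pat + 42, wf, ac = 3),
                        duration = 15, dt = 0.025)
  expect_equal(tr1$vm_mv, tr2$vm_mv, tolerance = 1e-9)
})

test_that("passive response is linear in the amplification coefficient", {
  sys <- cable_system(short_axon, passive_mb)
  pat <- static_node_pattern(short_axon,
                             place_on_short_axon("perpendicular_negative",
                                                 0.05, 0.05))
  wf <- stim_waveform("one_period_sine", 100)
  tr1 <- simulate_cable(sys, extracellular_drive(pat, wf, ac = 2),
                        duration = 15, dt = 0.025)
  tr2 <- simulate_cable(sys, extracellular_drive(pat, wf, ac = 4),
                        duration = 15, dt = 0.025)
  expect_equal(2 * (tr1$vm_mv + 65), tr2$vm_mv + 65, tolerance = 1e-6)
})

test_that("implicit integration matches a dense explicit oracle", {
  # 6-node passive cable with a step extracellular drive; oracle: classic
  # RK4 on the same ODE system at a 100x finer step
  m <- make_straight_axon(length = 30, n_sections = 3, nseg = 2)
  sys <- cable_system(m, passive_mb)
  n <- sys$n
  pat <- c(0, 0, -5, 0, 0, 0)
  drv <- extracellular_drive(pat, NULL, ac = 1)
  tr <- simulate_cable(sys, drv, duration = 2, dt = 0.01)

  g <- axial_conductance_matrix(sys)
  inv <- order(sys$pos)
  cap <- sys$cap_uf[inv]
  g_leak <- sys$g_leak_ms[inv]
  lap <- diag(rowSums(g)) - g
  rhs <- function(v) {
    (-g_leak * (v + 65) - as.numeric(lap %*% v) +
       as.numeric(g %*% pat) - rowSums(g) * pat) / cap
  }
  v <- rep(-65, n)
  h <- 1e-4
  for (i in seq_len(2 / h)) {
    k1 <- rhs(v); k2 <- rhs(v + h / 2 * k1); k3 <- rhs(v + h / 2 * k2)
    k4 <- rhs(v + h * k3)
    v <- v + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  resp_be <- tr$vm_mv[, ncol(tr$vm_mv)] + 65
  resp_rk <- v + 65
  expect_lt(max(abs(resp_be - resp_rk)) / max(abs(resp_rk)), 0.005)
})

test_that("steady passive profile matches the finite-cable closed form", {
  ka <- make_known_answer_cases()
  cab <- ka$finite_cable
  sys <- cable_system(cab$morphology, cab$membrane)
  inj <- numeric(sys$n)
  inj[cab$inject_node] <- cab$i_inject_ua
  tr <- simulate_cable(sys, NULL, duration = 150, dt = 0.05,
                       record_stride = 600, i_inject_ua = inj)
  v <- tr$vm_mv[, ncol(tr$vm_mv)] + 65
  x <- cab$morphology$segments$x
  L <- 1000
  lam <- cab$lambda_um
  closed <- cosh((L - x) / lam) / cosh(L / lam)
  expect_lt(max(abs(v / v[1] - closed / closed[1])), 0.01)
})

test_that("isopotential decay recovers the membrane time constant", {
  ka <- make_known_answer_cases()
  iso <- cable_system(ka$isopotential$morphology, ka$isopotential$membrane)
  st <- list(v_mv = rep(ka$isopotential$v_perturbed_mv, iso$n),
             gates = matrix(0, iso$n, 0))
  tr <- simulate_cable(iso, NULL, duration = 30, dt = 0.025, state = st)
  fit <- stats::lm(log(tr$vm_mv[1, ] + 65) ~ tr$times_ms)
  tau <- -1 / unname(stats::coef(fit)[2])
  expect_lt(abs(tau - ka$isopotential$expected_tau_ms) / 28, 0.01)
})

test_that("halving dt changes the peak response by less than 0.5%", {
  sys <- cable_system(short_axon, passive_mb)
  pat <- static_node_pattern(short_axon,
                             place_on_short_axon("perpendicular_negative",
                                                 0.05, 0.05))
  wf <- stim_waveform("one_period_sine", 100)
  peak <- function(dt) {
    tr <- simulate_cable(sys, extracellular_drive(pat, wf, ac = 5),
                         duration = 15, dt = dt)
    max(tr$vm_mv + 65)
  }
  p1 <- peak(0.025)
  p2 <- peak(0.0125)
  expect_lt(abs(p1 - p2) / p2, 0.005)
})

test_that("zeroed channels reduce exactly to the passive cable", {
  zeroed <- active_membrane
  zeroed$channels <- lapply(zeroed$channels, function(ch) {
    ch$gbar_s_cm2[] <- 0
    ch
  })
  pat <- static_node_pattern(short_axon,
                             place_on_short_axon("perpendicular_negative",
                                                 0.05, 0.05))
  wf <- stim_waveform("one_period_sine", 100)
  tr_zero <- simulate_cable(cable_system(short_axon, zeroed),
                            extracellular_drive(pat, wf, ac = 3),
                            duration = 15, dt = 0.025)
  tr_pass <- simulate_cable(cable_system(short_axon, passive_mb),
                            extracellular_drive(pat, wf, ac = 3),
                            duration = 15, dt = 0.025)
  expect_equal(tr_zero$vm_mv, tr_pass$vm_mv, tolerance = 1e-9)
})

test_that("single stepping agrees with the batched run", {
  sys <- cable_system(short_axon, active_membrane)
  pat <- static_node_pattern(short_axon,
                             place_on_short_axon("perpendicular_negative",
                                                 0.05, 0.05))
  drv <- extracellular_drive(pat, stim_waveform("one_period_sine", 100),
                             ac = 4)
  st <- NULL
  for (k in 0:19) st <- cable_step(sys, st, drv, t = k * 0.025, dt = 0.025)
  tr <- simulate_cable(sys, drv, duration = 0.5, dt = 0.025)
  expect_equal(st$v_mv, tr$vm_mv[, ncol(tr$vm_mv)], tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("traces stay within physiological bounds at threshold drive", {
  sys <- cable_system(ca1, active_membrane)
  wf <- stim_waveform("sine_burst", 500, 30)
  res <- summation_experiment(ca1, active_membrane,
                              c("axon", "basal:1", "basal:2"), wf,
                              system = sys)
  expect_true(all(res$trace$vm_mv > -150 & res$trace$vm_mv < 100))
})

test_that("trace export writes CSV and metadata", {
  sys <- cable_system(short_axon, passive_mb)
  tr <- simulate_cable(sys, NULL, duration = 1, dt = 0.025,
                       record_stride = 10)
  csv <- withr::local_tempfile(fileext = ".csv")
  meta <- withr::local_tempfile(fileext = ".json")
  write_trace_csv(tr, csv, meta)
  back <- utils::read.csv(csv)
  expect_named(back, c("time_ms", "node_id", "vm_mv"))
  md <- jsonlite::read_json(meta)
  expect_equal(md$solver, "backward_euler")
  expect_equal(md$dt_ms, 0.025)
  expect_true(md$deterministic)
  # tidy/glance accessors
  expect_equal(nrow(tidy(tr)), nrow(back))
  expect_equal(glance(tr)$n_nodes, sys$n)
})
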