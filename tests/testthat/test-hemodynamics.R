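# Reduced-order domain solver, 0D evaluation, partitioned coupling and
# the monolithic oracle.

test_that("uniform-tube viscous resistance matches the closed form", {
  blood <- blood_properties()
  seg <- list(length_mm = 10, r_prox_mm = 2, r_dist_mm = 2)
  expect_equal(segment_viscous_resistance(seg, blood),
               8 * 0.0035 * 0.01 / (pi * 0.002^4), tolerance = 1e-12)
  # r -> r/2 multiplies resistance by 16
  half <- list(length_mm = 10, r_prox_mm = 1, r_dist_mm = 1)
  expect_equal(segment_viscous_resistance(half, blood) /
                 segment_viscous_resistance(seg, blood), 16,
               tolerance = 1e-12)
  # taper formula reduces to the uniform one in the equal-radius limit
  near <- list(length_mm = 10, r_prox_mm = 2, r_dist_mm = 2 + 1e-9)
  expect_equal(segment_viscous_resistance(near, blood),
               segment_viscous_resistance(seg, blood), tolerance = 1e-6)
})

test_that("tapered-tube resistance agrees with numerical quadrature", {
  blood <- blood_properties()
  for (rr in list(c(2, 1), c(1.5, 0.8), c(0.9, 1.4))) {
    seg <- list(length_mm = 12, r_prox_mm = rr[1], r_dist_mm = rr[2])
    closed <- segment_viscous_resistance(seg, blood)
    r_of_s <- function(s) (rr[1] + (rr[2] - rr[1]) * s / 0.012) * 1e-3
    num <- stats::integrate(function(s)
      8 * blood$viscosity / (pi * r_of_s(s)^4), 0, 0.012,
      rel.tol = 1e-12)$value
    expect_equal(closed, num, tolerance = 1e-9)
  }
})

test_that("stenosis pressure drop is odd, zero at rest, monotone", {
  blood <- blood_properties()
  seg <- list(length_mm = 20, r_prox_mm = 2, r_dist_mm = 2)
  sten <- list(position = 0.5, severity = 0.6, length_mm = 5)
  expect_equal(stenosis_pressure_drop(sten, seg, 0, blood), 0)
  none <- list(position = 0.5, severity = 0, length_mm = 1e-12)
  expect_equal(stenosis_pressure_drop(none, seg, 3, blood), 0,
               tolerance = 1e-9)
  q <- seq(0.5, 8, by = 0.5)
  dp <- vapply(q, function(x) stenosis_pressure_drop(sten, seg, x, blood),
               numeric(1))
  expect_true(all(diff(dp) > 0))
  expect_equal(vapply(-q, function(x)
    stenosis_pressure_drop(sten, seg, x, blood), numeric(1)), -dp,
    tolerance = 1e-12)
  tight <- list(position = 0.5, severity = 0.99999, length_mm = 5)
  expect_error(stenosis_pressure_drop(
    list(position = 0.5, severity = 1, length_mm = 5), seg, 1, blood),
    "severity")
  expect_gt(stenosis_pressure_drop(tight, seg, 1, blood),
            stenosis_pressure_drop(sten, seg, 1, blood))
})

test_that("domain solve reproduces single-tube and symmetry limits", {
  tr <- tube_tree(r_mm = 2, length_mm = 10)
  pa <- 100
  pout <- c(SYS = 90, OUT = 80)
  sol <- solve_domain(tr, pa, pout)
  R <- tube_R_mmhg(2, 10)
  expect_equal(unname(sol$segment_flows["tube"]), (pa - 80) / R,
               tolerance = 1e-9)
  # equilibrium: no pressure differences, no flow
  sol0 <- solve_domain(tr, 90, c(SYS = 90, OUT = 90))
  expect_equal(max(abs(sol0$segment_flows)), 0, tolerance = 1e-12)
  # symmetric bifurcation with equal outlet pressures splits evenly
  sym <- two_outlet_tree(1.5, 1.5)
  ssol <- solve_domain(sym, 100, c(SYS = 99, O1 = 70, O2 = 70))
  expect_equal(unname(ssol$segment_flows["d1"]),
               unname(ssol$segment_flows["d2"]), tolerance = 1e-10)
  expect_error(solve_domain(sym, 100, c(SYS = 99, O1 = 70)),
               "missing node")
})

test_that("0D evaluation is the Ohm analogy with a venous offset", {
  lpm <- make_lpm(c("O1", "O2"), r_resting = c(50, 80), r_doa = 1.2,
                  state = "resting", venous_pressure = 5)
  p <- solve_0d(lpm, c(O1 = 0, O2 = 1, SYS = 10), "SYS")
  expect_equal(unname(p["O1"]), 5)          # Q = 0 -> venous pressure
  expect_equal(unname(p["O2"]), 5 + 80 * 1)
  expect_equal(unname(p["SYS"]), 1.2 * 10)  # systemic: Pv = 0
  p2 <- solve_0d(lpm, c(O1 = 0, O2 = 2, SYS = 10), "SYS")
  expect_equal(unname(p2["O2"] - 5), 2 * unname(p["O2"] - 5))
  # hyperemic state switches the resistance set
  lpm_h <- make_lpm("O1", 100, state = "hyperemia")
  expect_equal(unname(solve_0d(lpm_h, c(O1 = 1))["O1"]), 24)
  expect_error(solve_0d(lpm, c(O1 = 0)), "missing outlet")
})

test_that("coupled single tube matches the series closed form", {
  tr <- tube_tree(r_mm = 2, length_mm = 10)
  lpm <- make_lpm("OUT", r_resting = 60, r_doa = 1.25, state = "resting",
                  inlet_pressure = 100)
  sol <- couple(tr, lpm)
  R_tube <- tube_R_mmhg(2, 10)
  q_exact <- 100 / (R_tube + 60)
  expect_true(sol$converged)
  expect_lt(abs(sol$interface_flows[["OUT"]] - q_exact) / q_exact, 1e-3)
  mono <- solve_monolithic(tr, lpm)
  expect_equal(mono$interface_flows[["OUT"]], q_exact, tolerance = 1e-9)
})

test_that("partitioned coupling agrees with the monolithic oracle", {
  worst <- 0
  for (seed in 1:20) {
    ng <- 2 + seed %% 2
    spec <- if (seed %% 2) data.frame(branch = "LAD",
                                      severity = 0.3 + 0.02 * seed,
                                      position = 0.4) else NULL
    tr <- generate_synthetic_tree(ng, stenosis_spec = spec, seed = seed)
    pp <- sample_patient_parameters(seed = seed)
    lpm <- build_lpm(tr, pp)
    sol <- couple(tr, lpm)
    mono <- solve_monolithic(tr, lpm)
    outs <- c(coronary_outlets(tr), tr$systemic_outlet)
    worst <- max(worst,
                 rel_diff(sol$node_pressures[outs],
                          mono$node_pressures[outs]),
                 rel_diff(sol$interface_flows[outs],
                          mono$interface_flows[outs]))
    expect_true(sol$converged)
    tail_res <- sol$coupling_trace$residual[nrow(sol$coupling_trace)]
    expect_lt(tail_res, 1e-4)
  }
  expect_lt(worst, 1e-3)  # 10 x epsilon
})

test_that("mass is conserved at every junction of every solve", {
  for (seed in c(2, 8, 15)) {
    tr <- generate_synthetic_tree(
      3, stenosis_spec = data.frame(branch = "LAD", severity = 0.6,
                                    position = 0.5), seed = seed)
    lpm <- build_lpm(tr, sample_patient_parameters(seed = seed))
    for (sol in list(couple(tr, lpm), solve_monolithic(tr, lpm))) {
      expect_lt(sol$mass_residual, 1e-9)
      # independent recount from the reported segment flows
      seg <- tr$segments
      interior <- setdiff(intersect(seg$proximal, seg$distal), tr$inlet)
      for (nd in interior) {
        imbalance <- sum(sol$segment_flows[seg$id[seg$distal == nd]]) -
          sum(sol$segment_flows[seg$id[seg$proximal == nd]])
        expect_lt(abs(imbalance) / max(abs(sol$segment_flows)), 1e-9)
      }
    }
  }
})

test_that("raising an outlet resistance never raises its flow", {
  tr <- generate_synthetic_tree(3, seed = 6)
  lpm <- build_lpm(tr, sample_patient_parameters(seed = 6))
  base <- solve_monolithic(tr, lpm)
  for (i in c(1, 4, 7)) {
    bump <- lpm
    bump$outlets$r_hyperemia[i] <- bump$outlets$r_hyperemia[i] * 1.5
    pert <- solve_monolithic(tr, bump)
    node <- lpm$outlets$outlet_node[i]
    expect_lt(pert$interface_flows[[node]], base$interface_flows[[node]])
  }
})

test_that("subdividing a segment leaves the solution unchanged", {
  tr <- generate_synthetic_tree(2, seed = 9)
  lpm <- build_lpm(tr, sample_patient_parameters(seed = 9))
  base <- solve_monolithic(tr, lpm)
  lad_root <- tr$segments$id[tr$segments$branch == "LAD"][1]
  for (k in c(2, 5)) {
    fine <- subdivide_segment(tr, lad_root, k)
    ref <- solve_monolithic(fine, lpm)
    shared <- names(base$node_pressures)
    expect_lt(rel_diff(ref$node_pressures[shared],
                       base$node_pressures[shared]), 1e-10)
    expect_lt(rel_diff(ref$interface_flows, base$interface_flows), 1e-10)
  }
})

test_that("coupling reports non-convergence with its trace", {
  tr <- tube_tree()
  lpm <- make_lpm("OUT", r_resting = 60, inlet_pressure = 100)
  expect_error(couple(tr, lpm, cfg = coupling_config(max_iterations = 2)),
               "failed to converge")
})
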