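test_that("apparent viscosity has the Fahraeus-Lindqvist shape", {
  expect_equal(apparent_viscosity(6, 0), 1.2e-3, tolerance = 1e-10)
  expect_gt(apparent_viscosity(6, 0.45), apparent_viscosity(6, 0.2))
  D <- seq(3, 60, by = 0.25)
  mu <- apparent_viscosity(D / 2, 0.45)
  expect_true(all(mu > 0))
  dmin <- D[which.min(mu)]
  expect_gte(dmin, 5); expect_lte(dmin, 10)
  # extreme hematocrit stays finite for all diameters
  expect_true(all(is.finite(apparent_viscosity(D / 2, 1))))
})

test_that("single-segment flow matches the Poiseuille closed form", {
  net <- solve_network_flow(make_fixture_network("single", radius = 6,
                                                 length = 100), 10, 0)
  s <- network_segments(net)
  mu <- apparent_viscosity(6, s$hematocrit)
  expect_equal(s$flow, pi * (6e-6)^4 * 10 / (8 * mu * 100e-6),
               tolerance = 1e-12)
  bad <- make_fixture_network("single")
  bad$sg_R[1] <- 0
  expect_error(solve_network_flow(bad, 10, 0), "zero-radius")
})

test_that("the symmetric diamond splits the inlet flow equally", {
  net <- solved_diamond()
  s <- network_segments(net)
  expect_equal(s$flow[1], s$flow[3], tolerance = 1e-12)
  inflow <- s$flow[1] + s$flow[3]
  expect_equal(s$flow[1], inflow / 2, tolerance = 1e-12)
  expect_lte(flow_residual(net), 1e-10)
})

test_that("halving one branch radius redistributes flow as the 2x2 system", {
  net <- solve_network_flow(
    make_fixture_network("loop", radius = c(6, 6, 3, 3)), 10, 0)
  s <- network_segments(net)
  # independent oracle: two parallel two-segment chains, no cross links,
  # so each branch flow is Dp / (sum of its two segment resistances)
  res <- 8 * s$viscosity * (s$length * 1e-6) / (pi * (s$radius * 1e-6)^4)
  expect_equal(s$flow[1], 10 / (res[1] + res[2]), tolerance = 1e-10)
  expect_equal(s$flow[3], 10 / (res[3] + res[4]), tolerance = 1e-10)
  expect_gt(s$flow[1] / s$flow[3], 10)   # ~16x conductance contrast
})

test_that("hematocrit propagates and conserves red cell flux", {
  sp <- substrate_params()
  chain <- solve_network_flow(make_fixture_network("series", n_segments = 5),
                              10, 0, sp)
  expect_equal(network_segments(chain)$hematocrit, rep(sp$h_normal, 5))
  dia <- solved_diamond()
  sd_ <- network_segments(dia)
  expect_equal(sd_$hematocrit[1], sd_$hematocrit[3])
  # asymmetric split: RBC flux conserved at every interior node
  net <- solve_network_flow(
    make_fixture_network("loop", radius = c(6, 6, 4, 4)), 10, 0, sp)
  s <- network_segments(net)
  rbc <- abs(s$flow) * s$hematocrit
  expect_equal(rbc[1], rbc[2], tolerance = 1e-8)
  expect_equal(rbc[3], rbc[4], tolerance = 1e-8)
  expect_equal(rbc[1] + rbc[3],
               (abs(s$flow[1]) + abs(s$flow[3])) * sp$h_normal,
               tolerance = 1e-8)
  # stronger skimming starves the small branch more than proportionally
  s2 <- network_segments(solve_network_flow(
    make_fixture_network("loop", radius = c(6, 6, 4, 4)), 10, 0,
    substrate_params(skimming_exponent = 3)))
  expect_lt(s2$hematocrit[3], s$hematocrit[3])
})

test_that("wall shear follows the cubic-radius law", {
  net <- solved_diamond()
  s <- network_segments(net)
  expect_equal(s$shear * s$viscosity, s$wall_stress, tolerance = 1e-12)
  expect_equal(s$shear, 4 * abs(s$flow) / (pi * (s$radius * 1e-6)^3),
               tolerance = 1e-12)
  # zero flow -> zero shear (dangling segment)
  net2 <- make_fixture_network("series", n_segments = 3)
  dangle <- nanovasc:::add_node(net2, 100, 100)
  nanovasc:::add_segment(net2, 2L, dangle, 6, 100, 2L)
  net2 <- solve_network_flow(net2, 10, 0)
  s2 <- network_segments(net2)
  expect_equal(s2$shear[4], 0, tolerance = 1e-6 * max(s2$shear))
  expect_false(s2$perfused[4])
})

test_that("radius adaptation is monotone in shear and clamps radii", {
  ad <- adaptation_params()
  base <- solve_network_flow(make_fixture_network("single"), 10, 0)
  hi <- solve_network_flow(make_fixture_network("single"), 40, 0)
  r_base <- adapt_radii(base, ad, 0.1, 10, 0)$sg_R[1]
  r_hi <- adapt_radii(hi, ad, 0.1, 40, 0)$sg_R[1]
  expect_gt(r_hi, r_base)
  # extreme stimuli stay within the clamps
  big <- solve_network_flow(make_fixture_network("single"), 4000, 0)
  for (k in 1:200) {
    big <- adapt_radii(big, ad, 0.5, 4000, 0)
    big <- solve_network_flow(big, 4000, 0)
  }
  expect_lte(big$sg_R[1], ad$r_max)
  expect_gte(big$sg_R[1], ad$r_min)
})

test_that("a single segment adapts to the stimulus-balance fixed point", {
  ad <- adaptation_params()
  sp <- substrate_params()
  p_in <- 0.5   # low drive: the stimulus sum has an interior root
  stim_sum <- function(R) {
    mu <- apparent_viscosity(R, sp$h_normal)
    Q <- pi * (R * 1e-6)^4 * p_in / (8 * mu * 100e-6)
    tau_dyn <- (4 * mu * Q / (pi * (R * 1e-6)^3)) * 10
    s_wss <- log10(tau_dyn + ad$tau_ref)
    p_mm <- ad$p_mmhg_lo + (ad$p_mmhg_hi - ad$p_mmhg_lo) * 0.5
    s_p <- -ad$k_p * log10(nanovasc:::tau_expected(p_mm))
    s_m <- ad$k_m * log10(ad$q_ref / (Q * sp$h_normal) + 1)
    s_wss + s_p + s_m
  }
  # independent oracle: bisection root of the stimulus sum over R
  lo <- ad$r_min; hi <- ad$r_max
  for (k in 1:60) {
    mid <- (lo + hi) / 2
    if (stim_sum(mid) > 0) lo <- mid else hi <- mid
  }
  root <- (lo + hi) / 2
  net <- solve_network_flow(make_fixture_network("single"), p_in, 0, sp)
  for (k in 1:400) {
    net <- adapt_radii(net, ad, 0.05, p_in, 0)
    net <- solve_network_flow(net, p_in, 0, sp)
  }
  expect_equal(net$sg_R[1], root, tolerance = 0.02)
  expect_lt(abs(stim_sum(net$sg_R[1])), 0.02)
})

test_that("tumor overlap tagging matches a geometric recount", {
  sim <- baseline_run()
  snap <- sim$snapshots[["12"]]
  g <- sim$grid
  inside <- vessel_overlap_coopt(snap$net, snap$occupancy, g)
  segs <- which(snap$net$sg_alive[seq_len(snap$net$ns)])
  mid <- nanovasc:::seg_midpoints(snap$net, segs)
  cx <- pmin(pmax(floor(mid[, 1] / g$dx), 0), g$nx - 1) + 1
  cy <- pmin(pmax(floor(mid[, 2] / g$dx), 0), g$ny - 1) + 1
  expect_equal(sum(inside), sum(snap$occupancy[cbind(cx, cy)]))
  # empty and full tumors tag nothing / everything
  expect_equal(sum(vessel_overlap_coopt(snap$net,
    matrix(FALSE, g$nx, g$ny), g)), 0)
  expect_equal(sum(vessel_overlap_coopt(snap$net,
    matrix(TRUE, g$nx, g$ny), g)), length(segs))
})

test_that("global inlet/outlet flow balance holds on the grown network", {
  sim <- baseline_run()
  net <- sim$snapshots[["12"]]$net
  segs <- which(net$sg_alive[seq_len(net$ns)])
  Q <- net$sg_Q[segs]
  n1 <- net$sg_n1[segs]; n2 <- net$sg_n2[segs]
  roles <- net$nd_role[seq_len(net$nn)]
  influx <- sum(Q[roles[n1] == 1L]) - sum(Q[roles[n2] == 1L])
  outflux <- sum(Q[roles[n2] == 2L]) - sum(Q[roles[n1] == 2L])
  expect_equal(influx, outflux, tolerance = 1e-10)
  expect_lte(flow_residual(net), 1e-10)
})
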