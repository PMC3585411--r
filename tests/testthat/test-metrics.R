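test_that("tumor radius is the equivalent-circle radius", {
  g <- grid2d(2000, 25)
  expect_equal(tumor_radius(matrix(FALSE, g$nx, g$ny), g), 0)
  xc <- g$xc - 1000
  disc <- outer(xc^2, xc^2, `+`) <= 300^2
  expect_equal(tumor_radius(disc, g), 0.3, tolerance = g$dx / 300)
  # ellipse a x b -> sqrt(ab)
  ell <- outer((xc / 400)^2, (xc / 200)^2, `+`) <= 1
  expect_equal(tumor_radius(ell, g), sqrt(0.4 * 0.2), tolerance = 0.02)
  # initial nodule ~ 0.05 mm
  tum <- seed_tumor(simulation_config(), g)
  expect_equal(tumor_radius(tum$phi >= 0.5, g), 0.05, tolerance = 0.05)
})

test_that("blood area fraction sums projected areas over the class", {
  g <- grid2d(2000, 25)
  occ <- matrix(FALSE, g$nx, g$ny)
  expect_error(blood_area_fraction(make_fixture_network("single"), occ,
                                   "neo", g), "empty")
  occ[1:8, 1:8] <- TRUE    # 200 x 200 um square tumor at the origin corner
  net <- make_fixture_network("single", radius = 6, length = 100)
  expect_equal(blood_area_fraction(net, occ, "neo", g), 0)
  expect_equal(blood_area_fraction(net, occ, "pre", g),
               2 * 6 * 100 / (64 * 25^2))
})

test_that("vascular statistics match hand arithmetic", {
  sim <- baseline_run()
  g <- sim$grid
  net <- make_fixture_network("Y", radius = c(6, 5, 5))
  net <- solve_network_flow(net, 10, 0)
  occ <- matrix(TRUE, g$nx, g$ny)
  st <- vascular_stats(net, occ, "pre", g)
  s <- network_segments(net)
  expect_equal(st$n, 3L)
  expect_equal(st$mean_shear, mean(s$shear))
  expect_equal(st$sem_shear, sd(s$shear) / sqrt(3))
  expect_true(is.null(vascular_stats(net, occ, "neo", g)))
  # identical symmetric branches contribute zero spread
  expect_equal(s$shear[2], s$shear[3], tolerance = 1e-10)
})

test_that("per-area accumulation scales inversely with tumor area", {
  sim <- baseline_run()
  snap <- sim$snapshots[["12"]]
  g <- sim$grid
  st <- run_injection(snap$net, particle_spec(d = 1000, alpha_neo = 1e10,
                                              alpha_pre = 1e8), 600)
  occ <- snap$occupancy
  acc1 <- np_accumulation_per_area(snap$net, st, occ, g, scope = "total")
  big <- occ; big[] <- TRUE
  acc2 <- np_accumulation_per_area(snap$net, st, big, g, scope = "total")
  expect_equal(acc1 / acc2, sum(big) / sum(occ), tolerance = 1e-10)
  # identity: total scope equals adhered fraction / area
  expect_equal(acc1, st$adhered_frac / (sum(occ) * g$dx^2 / 1e6),
               tolerance = 1e-10)
  # tumor scope counts only in-tumor segments
  acc_t <- np_accumulation_per_area(snap$net, st, occ, g)
  expect_lte(acc_t, acc1 + 1e-12)
})

test_that("the Gompertz fitter recovers parameters and handles flat data", {
  days <- 0:24
  r <- 0.85 * exp(-4 * exp(-0.1 * days))
  fit <- gompertz_fit(days, r)
  expect_equal(fit$r1, 0.85, tolerance = 1e-6)
  expect_equal(fit$r2, -4.0, tolerance = 1e-6)
  expect_equal(fit$r3, -0.1, tolerance = 1e-6)
  # the printed parameters reproduce the printed day-24 endpoint (~0.6 mm)
  expect_equal(r[25], 0.62, tolerance = 0.05)
  flat <- gompertz_fit(days, rep(0.3, 25))
  expect_true(flat$flat)
  expect_equal(flat$r1, 0.3)
  expect_error(gompertz_fit(0:2, c(1, 2, 3)))
})

test_that("Gompertz recovery tolerates multiplicative noise", {
  days <- 0:24
  r0 <- 0.85 * exp(-4 * exp(-0.1 * days))
  set.seed(99)
  ok <- replicate(30, {
    fit <- gompertz_fit(days, r0 * exp(rnorm(25, 0, 0.02)))
    abs(fit$r1 - 0.85) / 0.85 < 0.1
  })
  expect_gte(mean(ok), 0.9)
})

test_that("network round-trips through GraphML and CSV", {
  sim <- baseline_run()
  net <- sim$snapshots[["6"]]$net
  tmp <- withr::local_tempdir()
  save_network(net, graphml = file.path(tmp, "net.graphml"),
               nodes_csv = file.path(tmp, "nodes.csv"),
               segments_csv = file.path(tmp, "segments.csv"))
  back <- load_network(file.path(tmp, "net.graphml"))
  s0 <- network_segments(net); s1 <- network_segments(back)
  expect_equal(nrow(s0), nrow(s1))
  expect_equal(sort(s0$radius), sort(s1$radius), tolerance = 1e-9)
  expect_equal(sum(s0$flow), sum(s1$flow), tolerance = 1e-9)
  nodes <- utils::read.csv(file.path(tmp, "nodes.csv"))
  expect_equal(nrow(nodes), net$nn)
  # a reloaded frozen network supports standalone injections
  st <- run_injection(back, particle_spec(d = 600, alpha_neo = 1e10,
                                          alpha_pre = 1e8), 300)
  expect_lt(st$residual, 1e-8)
})
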