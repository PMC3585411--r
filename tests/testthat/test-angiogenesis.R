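# Single-node lattice network with one tip at the center; the surrounding
# lattice is empty so every move lays down a new segment.
lone_tip <- function(nk = 21L) {
  net <- nanovasc:::new_network(list(nkx = nk, nky = nk, h = 25))
  c0 <- (nk - 1L) %/% 2L
  nanovasc:::add_node(net, c0 * 25, c0 * 25, c0, c0, 0L)
  tips <- new_tips()
  nanovasc:::tips_add(tips, 1L)
  list(net = net, tips = tips, c0 = c0)
}

test_that("sprout initiation follows TAF threshold and binomial sampling", {
  sim <- baseline_run()
  net <- nanovasc:::copy_network(sim$snapshots[["6"]]$net)
  ang <- angiogenesis_params(initiation_prob = 0.25, sprout_cooldown = 0)
  rng <- make_rng(11)
  tips <- new_tips()
  nk <- net$lattice$nkx
  # T = 0 everywhere -> no sprouts
  zero <- matrix(0, nk, nk)
  expect_equal(initiate_sprouts(net, tips, zero, ang, 0, rng), 0L)
  # uniform supra-threshold TAF: every perfused vessel node is a candidate;
  # sprout count is Binomial(n, p) -- check against 4 sigma over 40 draws
  tc <- matrix(1, nk, nk)
  segs <- which(net$sg_alive[seq_len(net$ns)])
  perf <- segs[net$sg_perfused[segs]]
  ncand <- length(unique(c(net$sg_n1[perf], net$sg_n2[perf])))
  counts <- replicate(40, {
    t2 <- new_tips()
    initiate_sprouts(net, t2, tc, ang, 0, rng)
  })
  se <- sqrt(ncand * 0.25 * 0.75 / 40)
  expect_lt(abs(mean(counts) - ncand * 0.25), 4 * se)
  expect_true(all(counts <= ncand))   # at most one per node per step
})

test_that("unbiased tips pick the four directions uniformly", {
  ang <- angiogenesis_params(chi0 = 0, rho = 0, d_motility = 1)
  rng <- make_rng(5)
  flatT <- matrix(0.5, 22, 22); flatE <- matrix(1, 22, 22)
  dirs <- integer(4)
  for (k in 1:2000) {
    f <- lone_tip()
    migrate_tips(f$net, f$tips, flatT, flatE, ang, rng, 6)
    nd2 <- which(seq_len(f$net$nn) != 1L)
    dx <- f$net$nd_ix[nd2] - f$c0; dy <- f$net$nd_iy[nd2] - f$c0
    d <- if (dx == 1) 1L else if (dx == -1) 2L else if (dy == 1) 3L else 4L
    dirs[d] <- dirs[d] + 1L
  }
  # each frequency within 3 sigma of 1/4
  se <- sqrt(0.25 * 0.75 / 2000)
  expect_true(all(abs(dirs / 2000 - 0.25) < 3 * se))
})

test_that("strong TAF gradients steer migration", {
  rng <- make_rng(6)
  # chemotaxis limit: D -> 0, gradient in +x -> +x chosen (almost) surely
  ang0 <- angiogenesis_params(chi0 = 1000, c_t = 0, rho = 0,
                              d_motility = 1e-9)
  gradT <- outer(seq(0, 1, length.out = 22), rep(1, 22))
  flatE <- matrix(1, 22, 22)
  plusx <- replicate(200, {
    f <- lone_tip()
    migrate_tips(f$net, f$tips, gradT, flatE, ang0, rng, 6)
    f$net$nd_ix[2] - f$c0
  })
  expect_true(all(plusx == 1))
  # moderate bias: mean displacement of many walkers projects on grad T
  ang1 <- angiogenesis_params(chi0 = 30, c_t = 0, rho = 0, d_motility = 1,
                              tip_max_age = 100)
  disp <- replicate(200, {
    f <- lone_tip(41L)
    for (s in 1:8)
      migrate_tips(f$net, f$tips, outer(seq(0, 1, length.out = 42),
                                        rep(1, 42)), matrix(1, 42, 42),
                   ang1, rng, 6)
    f$net$nd_ix[f$tips$node[1]] - f$c0
  })
  # one-sided test: mean projection > 0 with p < 1e-3
  tstat <- mean(disp) / (sd(disp) / sqrt(length(disp)))
  expect_gt(tstat, qnorm(1 - 1e-3))
})

test_that("branching doubles tips and anastomosis fuses them", {
  rng <- make_rng(7)
  flatT <- matrix(1, 22, 22)
  # branch_prob = 0 -> count constant; 1 -> doubles each call
  f <- lone_tip()
  ang_off <- angiogenesis_params(branch_prob = 0, branch_min_age = 0)
  expect_equal(branch_and_anastomose(f$tips, f$net, flatT, ang_off, rng), 0L)
  ang_on <- angiogenesis_params(branch_prob = 1, branch_min_age = 0,
                                max_tips = 64)
  n <- sapply(1:3, function(i)
    branch_and_anastomose(f$tips, f$net, flatT, ang_on, rng))
  expect_equal(n, c(1L, 2L, 4L))
  expect_equal(length(nanovasc:::active_tips(f$tips)), 8L)
  # two tips converging on one node: the mover fuses and both terminate
  net <- nanovasc:::new_network(list(nkx = 5, nky = 5, h = 25))
  a <- nanovasc:::add_node(net, 25, 50, 1L, 2L, 0L)
  b <- nanovasc:::add_node(net, 75, 50, 3L, 2L, 0L)
  tips <- new_tips()
  ang2 <- angiogenesis_params(chi0 = 1e4, c_t = 0, rho = 0,
                              d_motility = 1e-12)
  gx <- outer(seq(0, 1, length.out = 5), rep(1, 5))   # pulls +x
  gxm <- outer(seq(1, 0, length.out = 5), rep(1, 5))  # pulls -x
  nanovasc:::tips_add(tips, a)
  migrate_tips(net, tips, gx, matrix(1, 5, 5), ang2, rng, 6)
  expect_equal(tips$node[1], nanovasc:::node_at(net, 2L, 2L))
  nanovasc:::tips_add(tips, b)   # second tip one step east of tip 1
  ang3 <- angiogenesis_params(chi0 = 1e4, c_t = 0, rho = 0, d_motility = 0)
  migrate_tips(net, tips, gxm, matrix(1, 5, 5), ang3, rng, 6)
  expect_false(tips$alive[2])    # fused into the junction...
  expect_false(tips$alive[1])    # ...terminating the tip sitting there too
  expect_gte(nanovasc:::seg_between(net, b, nanovasc:::node_at(net, 2L, 2L)), 1L)
})

test_that("pruning spares loops and never disconnects inlet from outlet", {
  ad <- adaptation_params(prune_radius = 2.2)
  dia <- solved_diamond()
  expect_equal(prune_nonperfused(dia, ad), 0L)
  # a collapsed bridge segment is not removed when it is the only path
  chain <- make_fixture_network("series", n_segments = 3)
  chain$sg_R[2] <- 2.0
  chain <- solve_network_flow(chain, 10, 0)
  expect_equal(prune_nonperfused(chain, ad), 0L)
  expect_true(all(chain$sg_alive[1:3]))
  # a collapsed dead-end is removed
  net <- make_fixture_network("series", n_segments = 3)
  d <- nanovasc:::add_node(net, 100, 100)
  nanovasc:::add_segment(net, 2L, d, 2.0, 100, 2L)
  net <- solve_network_flow(net, 10, 0)
  expect_equal(prune_nonperfused(net, ad), 1L)
})

test_that("without a tumor the network remains the pre-existing grid", {
  cfg <- simulation_config(initial_tumor_radius = 0, end_time = 2)
  sim <- run_simulation(cfg)
  n_grid <- 2 * (cfg$domain_size / cfg$vessel_spacing + 1) *
    (cfg$domain_size / cfg$grid_spacing)
  expect_true(all(sim$history$n_seg_neo == 0))
  expect_true(all(sim$history$n_seg_pre == n_grid))
  expect_true(all(sim$history$tumor_radius == 0))
})
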