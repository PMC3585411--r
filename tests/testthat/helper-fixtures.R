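# Shared fixtures. The baseline coupled run is expensive (~20 s), so it is
# computed once per test session and reused by the integration, invariant
# and acceptance tests.

.run_cache <- new.env(parent = emptyenv())

baseline_run <- function() {
  if (is.null(.run_cache$sim)) {
    cfg <- simulation_config(end_time = 12, snapshot_days = c(6, 12),
                             rng_seed = 1L)
    .run_cache$sim <- run_simulation(cfg)
  }
  .run_cache$sim
}

# a small flow-solved diamond with optionally unequal radii
solved_diamond <- function(radius = 6, p_in = 10, p_out = 0) {
  net <- make_fixture_network("loop", radius = radius)
  solve_network_flow(net, p_in, p_out)
}

# in-tumor live segment ids of a snapshot, optionally one class
in_tumor_segs <- function(snap, grid, class = NULL) {
  net <- snap$net
  segs <- which(net$sg_alive[seq_len(net$ns)])
  inside <- vessel_overlap_coopt(net, snap$occupancy, grid)
  if (!is.null(class))
    inside <- inside & net$sg_class[segs] == (if (class == "pre") 1L else 2L)
  segs[inside]
}

# sum of attached fractions of `state` over the given segment ids
mps_sum <- function(state, ids) {
  sum(state$MpS[state$segs %in% ids])
}
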