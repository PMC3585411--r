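# The coupled growth loop: blood flow and hematocrit -> oxygen ->
# tissue classification and proliferation -> TAF and ECM -> oncotic
# pressure and interface advection -> radius adaptation and pruning ->
# stochastic angiogenesis; metrics recorded daily, full snapshots kept at
# selected days for standalone nanoparticle injections.

#' Run the coupled tumor/vasculature simulation
#'
#' Simulates tumor growth, tumor-induced angiogenesis and vascular
#' remodeling from inception to \code{config$end_time} days on the 2D
#' domain, as configured by [simulation_config()].
#'
#' @param config A [simulation_config()].
#' @param verbose Print a progress line per recorded day.
#' @return An object of class \code{nanovasc_sim}: \code{history} (one row
#'   per recorded day: tumor radius in mm, per-class blood area fractions,
#'   mean/SEM flow and shear over perfused in-tumor segments, segment and
#'   tip counts), \code{snapshots} (per snapshot day: flow-solved network
#'   copy and tumor mask), the final fields, and the resolved parameter
#'   groups.
#' @export
run_simulation <- function(config, verbose = FALSE) {
  grid <- grid2d(config$domain_size, config$grid_spacing)
  rng <- make_rng(config$rng_seed)
  net <- build_preexisting_grid(config)
  tips <- new_tips()
  tumor <- seed_tumor(config, grid)
  gp <- config$growth; ap <- config$angiogenesis; dp <- config$adaptation
  sp <- config$substrates
  ecm <- matrix(1, grid$nx, grid$ny) +
    rng_eval(rng, "ecm", function()
      matrix(stats::rnorm(grid$nx * grid$ny, 0, sp$ecm_noise_sd),
             grid$nx, grid$ny))
  ecm <- pmax(ecm, 0)
  net <- solve_network_flow(net, config$inlet_pressure,
                            config$outlet_pressure, sp, rng)
  sp <- normalize_transfer_rate(net, grid, gp, sp)
  sigma <- matrix(1, grid$nx, grid$ny)
  region <- tumor$region
  dt <- config$growth_dt
  n_steps <- as.integer(round(config$end_time / dt))
  rec_every <- max(1L, as.integer(round(1 / dt)))
  history <- vector("list", config$end_time + 1L)
  snapshots <- list()
  step_accum <- 0
  r0 <- config$initial_vessel_radius

  record <- function(day) {
    occ <- tumor$phi >= 0.5
    row <- data.frame(day = day, tumor_radius = tumor_radius(occ, grid),
                      n_seg_pre = NA_integer_, n_seg_neo = NA_integer_,
                      blood_area_neo = NA_real_, blood_area_pre = NA_real_,
                      mean_flow_neo = NA_real_, sem_flow_neo = NA_real_,
                      mean_shear_neo = NA_real_, sem_shear_neo = NA_real_,
                      mean_flow_pre = NA_real_, sem_flow_pre = NA_real_,
                      mean_shear_pre = NA_real_, sem_shear_pre = NA_real_,
                      n_tips = length(active_tips(tips)))
    segs <- alive_segs(net)
    row$n_seg_pre <- sum(net$sg_class[segs] == SEG_PRE)
    row$n_seg_neo <- sum(net$sg_class[segs] == SEG_NEO)
    if (any(occ)) {
      row$blood_area_neo <- blood_area_fraction(net, occ, "neo", grid)
      row$blood_area_pre <- blood_area_fraction(net, occ, "pre", grid)
      for (cl in c("neo", "pre")) {
        st <- vascular_stats(net, occ, cl, grid)
        if (!is.null(st)) {
          row[[paste0("mean_flow_", cl)]] <- st$mean_flow
          row[[paste0("sem_flow_", cl)]] <- st$sem_flow
          row[[paste0("mean_shear_", cl)]] <- st$mean_shear
          row[[paste0("sem_shear_", cl)]] <- st$sem_shear
        }
      }
    }
    row
  }
  history[[1]] <- record(0)

  for (k in seq_len(n_steps)) {
    day <- k * dt
    occ <- tumor$phi >= 0.5
    # hemodynamics
    net <- solve_network_flow(net, config$inlet_pressure,
                              config$outlet_pressure, sp, rng)
    # substrates
    sigma <- oxygen_field(net, grid, occ, sigma, gp, sp)
    region <- classify_tissue(sigma, occ, gp, region)
    lambda <- net_proliferation(sigma, region, gp)
    taf <- update_taf(region, net, grid, sp)
    ecm <- update_ecm(ecm, occ, net, grid, sp, dt)
    # tumor mechanics
    if (any(occ)) {
      P <- solve_pressure(lambda, ecm, occ, grid, gp)
      vel <- tumor_velocity(P, ecm, grid, gp)
      # substep the advection when growth outruns the per-step CFL bound
      nx <- grid$nx; ny <- grid$ny
      spd <- max(pmax(abs(vel$ux[1:nx, ]), abs(vel$ux[2:(nx + 1), ])) +
                   pmax(abs(vel$uy[, 1:ny]), abs(vel$uy[, 2:(ny + 1)])))
      n_sub <- max(1L, ceiling(spd * dt / (0.8 * grid$dx)))
      for (s in seq_len(n_sub))
        tumor$phi <- advance_interface(tumor$phi, vel, grid, dt / n_sub)
      # keep the stored labels consistent with the advected mask
      region <- classify_tissue(sigma, tumor$phi >= 0.5, gp, region)
      tumor$P <- P; tumor$region <- region; tumor$lambda <- lambda
      tumor$ux <- vel$ux; tumor$uy <- vel$uy
    } else P <- tumor$P
    # vascular remodeling
    segs <- alive_segs(net)
    inside <- vessel_overlap_coopt(net, occ, grid)
    # tissue-pressure term of the shrinking stimulus: confinement by the
    # packed tumor tissue, proxied by the local occupancy fraction
    sc <- seg_cells(net, grid, segs)
    tp <- tumor$phi[cbind(sc[, "cx"] + 1L, sc[, "cy"] + 1L)]
    tp[!inside] <- 0
    net <- adapt_radii(net, dp, dt, config$inlet_pressure,
                       config$outlet_pressure, tp)
    prune_nonperfused(net, dp)
    # angiogenesis
    taf_c <- corner_field(taf); ecm_c <- corner_field(ecm)
    initiate_sprouts(net, tips, taf_c, ap, day, rng)
    step_accum <- step_accum + ap$steps_per_day * dt
    while (step_accum >= 1) {
      migrate_tips(net, tips, taf_c, ecm_c, ap, rng, r0)
      branch_and_anastomose(tips, net, taf_c, ap, rng)
      step_accum <- step_accum - 1
    }
    # recording
    if (k %% rec_every == 0L) {
      d <- as.integer(round(day))
      net <- solve_network_flow(net, config$inlet_pressure,
                                config$outlet_pressure, sp, rng)
      history[[d + 1L]] <- record(d)
      if (d %in% config$snapshot_days)
        snapshots[[as.character(d)]] <-
          list(day = d, net = copy_network(net),
               occupancy = tumor$phi >= 0.5,
               area_mm2 = sum(tumor$phi >= 0.5) * grid$dx^2 / 1e6)
      if (verbose)
        message(sprintf(
          "day %2d: r = %.3f mm, segs pre/neo %d/%d, tips %d", d,
          history[[d + 1L]]$tumor_radius, history[[d + 1L]]$n_seg_pre,
          history[[d + 1L]]$n_seg_neo, history[[d + 1L]]$n_tips))
    }
  }
  structure(list(config = config, grid = grid,
                 substrates = sp,   # with resolved transfer rate
                 history = do.call(rbind, history),
                 snapshots = snapshots,
                 final = list(net = net, tumor = tumor, sigma = sigma,
                              taf = taf, ecm = ecm, tips = tips)),
            class = "nanovasc_sim")
}

#' @export
print.nanovasc_sim <- function(x, ...) {
  h <- x$history
  last <- h[nrow(h), ]
  cat(sprintf(
    "<nanovasc_sim> %g days, final radius %.3f mm, blood area neo/pre %.2f/%.3f\n",
    last$day, last$tumor_radius, last$blood_area_neo, last$blood_area_pre))
  invisible(x)
}
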