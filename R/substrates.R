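# Quasi-steady reaction-diffusion fields on the cell-centered grid: oxygen
# (vessel extravasation source, region-dependent uptake), tumor angiogenic
# factor (hypoxic production, vessel consumption), and the non-diffusible
# ECM density. Substrates are re-solved to steady state every growth step
# (molecular diffusion equilibrates in ~minutes versus ~1 day for growth).

.lap_cache <- new.env(parent = emptyenv())

# 5-point Laplacian with zero-flux (Neumann) boundaries: boundary faces
# simply carry no flux term, so the boundary-normal discrete flux is
# identically zero by construction.
neumann_laplacian <- function(grid) {
  key <- paste(grid$nx, grid$ny, grid$dx, sep = ":")
  if (!is.null(.lap_cache[[key]])) return(.lap_cache[[key]])
  nx <- grid$nx; ny <- grid$ny
  n <- nx * ny
  idx <- matrix(seq_len(n), nx, ny)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  pair <- function(a, b) {
    ii <<- c(ii, a, b, a, b); jj <<- c(jj, b, a, a, b)
    xx <<- c(xx, rep(1, 2 * length(a)), rep(-1, 2 * length(a)))
  }
  pair(as.vector(idx[-nx, ]), as.vector(idx[-1, ]))   # x-faces
  pair(as.vector(idx[, -ny]), as.vector(idx[, -1]))   # y-faces
  L <- Matrix::sparseMatrix(i = ii, j = jj, x = xx / grid$dx^2,
                            dims = c(n, n))
  .lap_cache[[key]] <- L
  L
}

#' Solve a quasi-steady reaction-diffusion equation
#'
#' Solves \code{0 = D lap(s) + source - reaction * s} on the cell-centered
#' grid with zero-Neumann boundaries, by a direct sparse factorization
#' (exact up to machine precision, comfortably below the 1e-8 residual
#' tolerance of the model).
#'
#' @param grid A [grid2d()].
#' @param d_coef Diffusivity (um^2 per unit reaction rate).
#' @param reaction Nonnegative reaction (uptake + decay) coefficient field.
#' @param source Source field.
#' @return The steady-state field (\code{nx} x \code{ny} matrix).
#' @export
solve_substrate <- function(grid, d_coef, reaction, source) {
  if (all(reaction <= 0))
    stop("all-zero reaction with pure Neumann boundaries is singular")
  L <- neumann_laplacian(grid)
  n <- grid$nx * grid$ny
  A <- -d_coef * L + Matrix::Diagonal(n, x = as.vector(reaction))
  s <- Matrix::solve(A, as.vector(source))
  matrix(as.numeric(s), grid$nx, grid$ny)
}

#' Oxygen extravasation source field
#'
#' The source is \code{transfer_rate} on vessel-indicator cells, modulated
#' by the hematocrit extravasation factor
#' \code{max(0, (H_D - h_min) / (h_normal - h_min))} (no extravasation below
#' the minimum hematocrit) and by the convective trans-wall reduction
#' \code{max(0, 1 - convective_weight * p_i / p_e)}. Where several segments
#' share a cell the largest factor applies (the indicator is binary).
#'
#' @param net A \code{vessel_network} with hematocrit distributed.
#' @param grid A [grid2d()].
#' @param substrates [substrate_params()].
#' @param transfer_rate Vessel-to-tissue transfer rate.
#' @return Source field (\code{nx} x \code{ny} matrix).
#' @export
oxygen_source <- function(net, grid, substrates, transfer_rate) {
  segs <- alive_segs(net)
  src <- matrix(0, grid$nx, grid$ny)
  if (!length(segs)) return(src)
  H <- net$sg_H[segs]
  ext <- pmax(0, (H - substrates$h_min) /
                (substrates$h_normal - substrates$h_min))
  pf <- max(0, 1 - substrates$convective_weight *
              substrates$p_i / substrates$p_e)
  sc <- seg_cells(net, grid, segs)
  lin <- sc[, "cx"] + 1L + grid$nx * sc[, "cy"]
  fac <- numeric(grid$nx * grid$ny)
  o <- order(ext)   # later writes win; sort so the max factor lands last
  fac[lin[o]] <- ext[o]
  src[] <- transfer_rate * fac * pf
  src
}

# Region-dependent oxygen reaction coefficient with linear interpolation in
# sigma over bands of half-width interp_band around each threshold.
oxygen_reaction <- function(sigma, occupancy, region, growth, substrates) {
  sp <- substrates
  q <- matrix(sp$uptake_normal, nrow(sigma), ncol(sigma))
  tum <- occupancy
  if (any(tum)) {
    sH <- growth$hypoxia_threshold; sN <- growth$necrosis_threshold
    b <- sp$interp_band
    s <- sigma[tum]
    lerp <- function(s, lo, hi, qlo, qhi)
      qlo + (qhi - qlo) * pmin(pmax((s - lo) / (hi - lo), 0), 1)
    qt <- ifelse(s >= sH + b, sp$uptake_viable,
          ifelse(s >= sH - b, lerp(s, sH - b, sH + b, sp$uptake_hypoxic,
                                   sp$uptake_viable),
          ifelse(s >= sN + b, sp$uptake_hypoxic,
          ifelse(s >= sN - b, lerp(s, sN - b, sN + b, sp$decay_necrotic,
                                   sp$uptake_hypoxic),
                 sp$decay_necrotic))))
    q[tum] <- qt
  }
  q
}

#' Solve the quasi-steady oxygen field
#'
#' @param net A \code{vessel_network} with flow and hematocrit current.
#' @param grid A [grid2d()].
#' @param occupancy Logical tumor mask.
#' @param sigma_prev Previous oxygen field (used to place the smooth uptake
#'   interpolation; pass a field of ones at start).
#' @param growth [growth_params()].
#' @param substrates [substrate_params()]; \code{transfer_rate} must be
#'   resolved (see [normalize_transfer_rate()]).
#' @return Oxygen field, nondimensional (peri-vascular value of order 1).
#' @export
oxygen_field <- function(net, grid, occupancy, sigma_prev, growth,
                         substrates) {
  q <- oxygen_reaction(sigma_prev, occupancy, NULL, growth, substrates)
  src <- oxygen_source(net, grid, substrates, substrates$transfer_rate)
  solve_substrate(grid, substrates$d_oxygen, q, src)
}

#' Normalize the vessel transfer rate
#'
#' Fixes the oxygen nondimensionalization: the transfer rate is set once so
#' that the peak oxygen level of the intact, fully perfused pre-existing
#' grid equals 1 (the far-field vessel value).
#'
#' @param net The pre-existing grid network (hematocrit distributed).
#' @param grid A [grid2d()].
#' @param growth,substrates Parameter groups.
#' @return \code{substrates} with \code{transfer_rate} filled in.
#' @export
normalize_transfer_rate <- function(net, grid, growth, substrates) {
  if (!is.na(substrates$transfer_rate)) return(substrates)
  occ <- matrix(FALSE, grid$nx, grid$ny)
  src <- oxygen_source(net, grid, substrates, 1)
  q <- oxygen_reaction(matrix(1, grid$nx, grid$ny), occ, NULL, growth,
                       substrates)
  s <- solve_substrate(grid, substrates$d_oxygen, q, src)
  substrates$transfer_rate <- 1 / max(s)
  substrates
}

#' Solve the quasi-steady TAF field
#'
#' Tumor angiogenic factor is produced by hypoxic tissue, decays naturally,
#' and is consumed by endothelial cells at vessel locations.
#'
#' @param region Region label field (see [classify_tissue()]).
#' @param net A \code{vessel_network}.
#' @param grid A [grid2d()].
#' @param substrates [substrate_params()].
#' @return TAF field (nonnegative).
#' @export
update_taf <- function(region, net, grid, substrates) {
  ind <- rasterize_vessels(net, grid)
  reaction <- substrates$taf_decay + substrates$taf_vessel_uptake * ind
  src <- substrates$taf_production * (region == REGION_HYPOXIC)
  if (!any(src > 0)) return(matrix(0, grid$nx, grid$ny))
  pmax(solve_substrate(grid, substrates$d_taf, reaction, src), 0)
}

#' Advance the ECM density field
#'
#' Local production at vessel locations and degradation inside the tumor;
#' no diffusion (matrix macromolecules are non-diffusible). Clamped
#' nonnegative.
#'
#' @param ecm Current ECM field.
#' @param occupancy Logical tumor mask.
#' @param net A \code{vessel_network}.
#' @param grid A [grid2d()].
#' @param substrates [substrate_params()].
#' @param dt Time step (days).
#' @return Updated ECM field.
#' @export
update_ecm <- function(ecm, occupancy, net, grid, substrates, dt) {
  ind <- rasterize_vessels(net, grid)
  e <- ecm + dt * (substrates$ecm_production * ind -
                     substrates$ecm_degradation * occupancy * ecm)
  pmax(e, 0)
}
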