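# Network hemodynamics: nodal pressure solve (Kirchhoff / Poiseuille),
# Fahraeus-Lindqvist apparent viscosity, hematocrit partitioning, wall
# shear, and Pries-type structural radius adaptation.

MU_PLASMA <- 1.2e-3  # Pa s

#' In-vitro apparent blood viscosity (Fahraeus-Lindqvist)
#'
#' Diameter- and hematocrit-dependent apparent viscosity after Pries'
#' in-vitro fit, scaled by a plasma viscosity of 1.2e-3 Pa s. At zero
#' hematocrit the plasma viscosity is returned; viscosity increases with
#' hematocrit and has the characteristic minimum over diameter near 7 um.
#'
#' @param radius_um Vessel radius in um (diameter is \code{2 * radius_um}).
#' @param hematocrit Discharge hematocrit in `[0, 1]`.
#' @return Apparent viscosity in Pa s.
#' @export
apparent_viscosity <- function(radius_um, hematocrit) {
  stopifnot(all(radius_um > 0), all(hematocrit >= 0), all(hematocrit <= 1))
  D <- 2 * radius_um
  # cap avoids the law's singular limit H -> 1 where its shape exponent C
  # is negative (large diameters); expm1 keeps the C -> 0 crossover exact
  H <- pmin(hematocrit, 0.99)
  mu45 <- 220 * exp(-1.3 * D) + 3.2 - 2.44 * exp(-0.06 * D^0.645)
  C <- (0.8 + exp(-0.075 * D)) * (-1 + 1 / (1 + 1e-11 * D^12)) +
    1 / (1 + 1e-11 * D^12)
  rel <- 1 + (mu45 - 1) * expm1(C * log1p(-H)) / expm1(C * log(1 - 0.45))
  MU_PLASMA * rel
}

# Graph components containing at least one pressure-boundary node; others
# (possible after pruning) are excluded from the solve and left at p_out.
flow_components <- function(net, segs) {
  g <- as_igraph(net, segs)
  igraph::components(g)$membership
}

#' Solve blood flow on the vessel network
#'
#' Nodal pressures satisfy Kirchhoff's current law with Poiseuille segment
#' conductances \code{g = pi R^4 / (8 mu L)}; inlet and outlet nodes carry
#' Dirichlet pressures. The apparent viscosity depends on hematocrit, which
#' itself depends on the flow direction, so the viscosity/hematocrit pair is
#' relaxed over a few outer iterations (the coupling is weak).
#'
#' @param net A \code{vessel_network} (updated in place and returned).
#' @param p_in,p_out Inlet and outlet pressures.
#' @param substrates [substrate_params()] supplying the inlet hematocrit.
#' @param rng Optional RNG handle (reserved for stochastic partitioning
#'   rules; the default proportional rule is deterministic).
#' @param skimming_exponent Exponent of the flow-weighted plasma skimming
#'   rule at diverging bifurcations (1 = proportional split).
#' @param outer_iter Viscosity/hematocrit relaxation iterations.
#' @return \code{net}, with nodal pressures, per-segment flows, hematocrit,
#'   viscosity, wall shear stress/rate and perfusion flags filled in.
#' @export
solve_network_flow <- function(net, p_in, p_out,
                               substrates = substrate_params(),
                               rng = NULL,
                               skimming_exponent = substrates$skimming_exponent,
                               outer_iter = 3L) {
  segs <- alive_segs(net)
  if (!length(segs)) stop("empty network")
  if (any(net$sg_R[segs] <= 0)) stop("zero-radius segment")
  inl <- inlet_nodes(net); outl <- outlet_nodes(net)
  if (!length(inl) || !length(outl)) stop("inlet and outlet sets required")
  memb <- flow_components(net, segs)
  ok_comp <- intersect(memb[inl], memb[outl])
  if (!length(ok_comp))
    stop("inlet and outlet are not connected")
  n1 <- net$sg_n1[segs]; n2 <- net$sg_n2[segs]
  Lm <- net$sg_L[segs] * 1e-6
  Rm <- net$sg_R[segs] * 1e-6
  H <- net$sg_H[segs]
  H[H <= 0] <- substrates$h_normal   # first-pass viscosity guess
  p <- rep(p_out, net$nn)
  for (it in seq_len(outer_iter)) {
    mu <- apparent_viscosity(net$sg_R[segs], H)
    g <- pi * Rm^4 / (8 * mu * Lm)
    A <- Matrix::sparseMatrix(i = c(n1, n2, n1, n2), j = c(n1, n2, n2, n1),
                              x = c(g, g, -g, -g), dims = c(net$nn, net$nn))
    fixed <- rep(FALSE, net$nn)
    fixed[inl] <- TRUE; fixed[outl] <- TRUE
    in_system <- memb %in% memb[c(inl, outl)] &
      seq_len(net$nn) %in% c(n1, n2, inl, outl)
    free <- which(in_system & !fixed)
    p <- rep(p_out, net$nn)
    p[inl] <- p_in; p[outl] <- p_out
    if (length(free)) {
      other <- setdiff(seq_len(net$nn), free)
      rhs <- -A[free, other, drop = FALSE] %*% p[other]
      # guard isolated free nodes (possible in degenerate fixtures)
      Aff <- A[free, free, drop = FALSE]
      dg <- Matrix::diag(Aff)
      if (any(dg == 0)) Aff <- Aff + Matrix::Diagonal(length(free),
                                                      x = (dg == 0) * 1)
      x <- Matrix::solve(Aff, rhs)
      # two iterative-refinement sweeps push the nodal balance to ~1e-13
      for (ir in 1:2) x <- x + Matrix::solve(Aff, rhs - Aff %*% x)
      p[free] <- as.numeric(x)
    }
    Q <- g * (p[n1] - p[n2])
    Hnew <- distribute_hematocrit_(net, segs, Q, substrates,
                                   skimming_exponent)
    if (max(abs(Hnew - H)) < 1e-10 && it > 1L) { H <- Hnew; break }
    H <- Hnew
  }
  net$nd_p[seq_len(net$nn)] <- p
  net$sg_Q[segs] <- Q
  net$sg_H[segs] <- H
  net$sg_mu[segs] <- apparent_viscosity(net$sg_R[segs], H)
  qmax <- max(abs(Q))
  net$sg_perfused[seq_len(net$ns)] <- FALSE
  net$sg_perfused[segs] <- abs(Q) > 1e-8 * qmax
  wall_shear(net)
  net
}

# Flux-weighted hematocrit propagation from the inlets. Flow directions
# admit no directed cycles (pressure strictly decreases along flow), so the
# fixed-point iteration converges in at most the longest path length.
distribute_hematocrit_ <- function(net, segs, Q, substrates, exponent = 1,
                                   tol = 1e-10, max_iter = 2000L) {
  h_in <- substrates$h_normal
  nseg <- length(segs)
  absQ <- abs(Q)
  perf <- absQ > 1e-12 * max(absQ, 1e-300)
  up <- ifelse(Q >= 0, net$sg_n1[segs], net$sg_n2[segs])
  dn <- ifelse(Q >= 0, net$sg_n2[segs], net$sg_n1[segs])
  H <- numeric(nseg)
  if (!any(perf)) return(H)
  w <- which(perf)
  nn <- net$nn
  Min <- Matrix::sparseMatrix(i = dn[w], j = seq_along(w), x = absQ[w],
                              dims = c(nn, length(w)))
  Fin <- as.numeric(Min %*% rep(1, length(w)))
  Fout <- as.numeric(Matrix::sparseMatrix(i = up[w], j = seq_along(w),
                                          x = absQ[w],
                                          dims = c(nn, length(w))) %*%
                       rep(1, length(w)))
  Se <- as.numeric(Matrix::sparseMatrix(i = up[w], j = seq_along(w),
                                        x = absQ[w]^exponent,
                                        dims = c(nn, length(w))) %*%
                     rep(1, length(w)))
  split_w <- (absQ[w]^exponent / Se[up[w]]) * (Fout[up[w]] / absQ[w])
  is_inlet <- net$nd_role[seq_len(nn)] == 1L
  Hs <- numeric(length(w))
  for (it in seq_len(max_iter)) {
    rbc <- as.numeric(Min %*% Hs)
    Hnode <- ifelse(Fin > 0, rbc / pmax(Fin, 1e-300), 0)
    Hnode[is_inlet] <- h_in
    Hs_new <- pmin(1, Hnode[up[w]] * split_w)
    if (max(abs(Hs_new - Hs)) < tol) { Hs <- Hs_new; break }
    Hs <- Hs_new
  }
  H[w] <- Hs
  H
}

#' Hematocrit distribution over a flow-solved network
#'
#' Propagates discharge hematocrit from the inlets (\code{h_normal}) along
#' flow directions, splitting red-cell flux at diverging bifurcations by a
#' flow-weighted plasma-skimming rule that conserves RBC flux at every node.
#'
#' @inheritParams solve_network_flow
#' @return \code{net} with per-segment hematocrit updated.
#' @export
distribute_hematocrit <- function(net, substrates = substrate_params(),
                                  rng = NULL,
                                  skimming_exponent = substrates$skimming_exponent) {
  segs <- alive_segs(net)
  net$sg_H[segs] <- distribute_hematocrit_(net, segs, net$sg_Q[segs],
                                           substrates, skimming_exponent)
  net
}

#' Wall shear stress and shear rate
#'
#' \code{tau_w = 4 mu |Q| / (pi R^3)} and \code{S = tau_w / mu}.
#'
#' @param net A flow-solved \code{vessel_network}.
#' @return \code{net} with \code{wall_stress} (Pa) and \code{shear} (1/s)
#'   per segment.
#' @export
wall_shear <- function(net) {
  segs <- alive_segs(net)
  Rm <- net$sg_R[segs] * 1e-6
  S <- 4 * abs(net$sg_Q[segs]) / (pi * Rm^3)
  net$sg_S[segs] <- S
  net$sg_tau[segs] <- net$sg_mu[segs] * S
  net
}

# Empirical expected wall shear stress (dyn/cm^2) at intravascular pressure
# P (mmHg), after the Pries adaptation literature.
tau_expected <- function(p_mmhg) {
  p <- pmax(p_mmhg, 10)
  100 - 86 * exp(-5000 * log10(log10(p))^5.4)
}

#' Structural radius adaptation
#'
#' Applies one explicit adaptation step
#' \code{dR = R dt (S_wss + S_p + S_m + S_s)} to all perfused segments (see
#' [adaptation_params()] for the stimulus forms); radii are clamped to
#' \code{[r_min, r_max]}. The shrinking stimulus \code{S_s} acts on
#' pre-existing segments co-opted by the tumor, proportional to the local
#' oncotic tissue pressure (normalized by its current maximum).
#'
#' @param net A flow-solved \code{vessel_network}.
#' @param adaptation [adaptation_params()].
#' @param dt Time step (days).
#' @param p_in,p_out Boundary pressures (for the mmHg mapping of S_p).
#' @param tissue_pressure Per-segment tissue pressure (same length as the
#'   live segment set), already normalized to `[0, 1]`; 0 outside the
#'   tumor. Drives the shrinking stimulus S_s on tumor-enveloped vessels.
#' @return \code{net} with updated radii.
#' @export
adapt_radii <- function(net, adaptation, dt, p_in, p_out,
                        tissue_pressure = NULL) {
  ad <- adaptation
  segs <- alive_segs(net)
  act <- net$sg_perfused[segs]
  if (!any(act)) return(net)
  i <- segs[act]
  tau_dyn <- net$sg_tau[i] * 10      # Pa -> dyn/cm^2
  s_wss <- log10(tau_dyn + ad$tau_ref)
  pbar <- (net$nd_p[net$sg_n1[i]] + net$nd_p[net$sg_n2[i]]) / 2
  frac <- (pbar - p_out) / (p_in - p_out)
  p_mm <- ad$p_mmhg_lo + (ad$p_mmhg_hi - ad$p_mmhg_lo) *
    pmin(pmax(frac, 0), 1)
  s_p <- -ad$k_p * log10(tau_expected(p_mm))
  qh <- abs(net$sg_Q[i]) * net$sg_H[i]
  s_m <- ad$k_m * log10(ad$q_ref / pmax(qh, 1e-300) + 1)
  s_s <- 0
  if (!is.null(tissue_pressure)) {
    # confinement by the growing mass acts on every vessel it envelops;
    # co-opted pre-existing vessels and immature neovessels alike
    s_s <- -ad$k_s * tissue_pressure[act]
  }
  R <- net$sg_R[i]
  R <- R + R * dt * (s_wss + s_p + s_m + s_s)
  if (any(R <= 0)) warning("negative proposed radius clamped")
  net$sg_R[i] <- pmin(pmax(R, ad$r_min), ad$r_max)
  net
}

#' Tag segments by tumor overlap
#'
#' A segment is inside the tumor when its midpoint cell is occupied.
#'
#' @param net A \code{vessel_network}.
#' @param occupancy Logical \code{nx} x \code{ny} tumor mask.
#' @param grid A [grid2d()].
#' @return Logical vector over live segments (TRUE = inside tumor).
#' @export
vessel_overlap_coopt <- function(net, occupancy, grid) {
  segs <- alive_segs(net)
  if (!length(segs)) return(logical(0))
  sc <- seg_cells(net, grid, segs)
  occupancy[cbind(sc[, "cx"] + 1L, sc[, "cy"] + 1L)]
}

#' Kirchhoff balance audit
#'
#' @param net A flow-solved \code{vessel_network}.
#' @return Maximum over interior nodes of |net nodal flow| / (total nodal
#'   throughflow), the relative conservation residual.
#' @export
flow_residual <- function(net) {
  segs <- alive_segs(net)
  n1 <- net$sg_n1[segs]; n2 <- net$sg_n2[segs]; Q <- net$sg_Q[segs]
  nn <- net$nn
  netflow <- as.numeric(Matrix::sparseMatrix(i = c(n1, n2), j = rep(1L, 2 * length(Q)),
                                             x = c(-Q, Q), dims = c(nn, 1L)))
  thru <- as.numeric(Matrix::sparseMatrix(i = c(n1, n2), j = rep(1L, 2 * length(Q)),
                                          x = c(abs(Q), abs(Q)), dims = c(nn, 1L)))
  interior <- net$nd_role[seq_len(nn)] == 0L & thru > 0
  if (!any(interior)) return(0)
  # nodes carrying under 0.1% of the peak throughflow are numerically
  # stagnant; their balance is measured against that global scale
  max(abs(netflow[interior]) / pmax(thru[interior], 1e-3 * max(thru)))
}
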