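# Continuum tumor mechanics: viable/hypoxic/necrotic classification, net
# proliferation, oncotic pressure (Poisson solve with a stress-free host),
# generalized Darcy velocity, and volume-of-fluid interface advection.

REGION_HOST <- 0L
REGION_VIABLE <- 1L
REGION_HYPOXIC <- 2L
REGION_NECROTIC <- 3L

#' Seed the initial tumor nodule
#'
#' Places a circular avascular nodule at the domain center. The occupancy
#' is a volume fraction computed by 4x4 subcell sampling; a cell counts as
#' occupied when more than half covered.
#'
#' @param config A [simulation_config()].
#' @param grid A [grid2d()].
#' @return A \code{tumor_state} list: \code{phi} (volume fraction),
#'   \code{region} (labels), \code{P} (oncotic pressure), face velocities
#'   \code{ux}, \code{uy}, and \code{lambda} (net proliferation field), all
#'   zero-initialized except \code{phi}.
#' @export
seed_tumor <- function(config, grid) {
  r <- config$initial_tumor_radius
  if (2 * r > config$domain_size) stop("tumor radius exceeds domain")
  cx <- config$domain_size / 2; cy <- cx
  nx <- grid$nx; ny <- grid$ny; dx <- grid$dx
  phi <- matrix(0, nx, ny)
  if (r > 0) {
    off <- (seq_len(4) - 0.5) / 4
    for (ox in off) for (oy in off) {
      xs <- (seq_len(nx) - 1 + ox) * dx - cx
      ys <- (seq_len(ny) - 1 + oy) * dx - cy
      phi <- phi + (outer(xs^2, ys^2, `+`) <= r^2)
    }
    phi <- phi / 16
  }
  region <- matrix(REGION_HOST, nx, ny)
  region[phi >= 0.5] <- REGION_VIABLE
  structure(list(phi = phi, region = region,
                 P = matrix(0, nx, ny),
                 ux = matrix(0, nx + 1, ny), uy = matrix(0, nx, ny + 1),
                 lambda = matrix(0, nx, ny)),
            class = "tumor_state")
}

#' Classify tumor tissue by oxygen level
#'
#' Viable where \code{sigma >= sigma_H}, hypoxic where
#' \code{sigma_N <= sigma < sigma_H}, necrotic below \code{sigma_N}; host
#' outside the occupancy. Necrotic tissue whose oxygen recovers above
#' \code{sigma_N} re-enters through the hypoxic state in that step (it
#' never jumps directly back to viable).
#'
#' @param sigma Oxygen field.
#' @param occupancy Logical tumor mask.
#' @param growth [growth_params()].
#' @param prev_region Previous label field (optional, enables the necrotic
#'   memory rule).
#' @return Integer label field (0 host, 1 viable, 2 hypoxic, 3 necrotic).
#' @export
classify_tissue <- function(sigma, occupancy, growth, prev_region = NULL) {
  sH <- growth$hypoxia_threshold; sN <- growth$necrosis_threshold
  if (!(sN < sH)) stop("thresholds out of order")
  region <- matrix(REGION_HOST, nrow(sigma), ncol(sigma))
  region[occupancy & sigma >= sH] <- REGION_VIABLE
  region[occupancy & sigma < sH] <- REGION_HYPOXIC
  region[occupancy & sigma < sN] <- REGION_NECROTIC
  if (!is.null(prev_region)) {
    stuck <- occupancy & prev_region == REGION_NECROTIC &
      region == REGION_VIABLE
    region[stuck] <- REGION_HYPOXIC
  }
  region
}

#' Net proliferation rate field
#'
#' \code{lambda = sigma - A} on viable tissue, 0 on hypoxic tissue and the
#' host, \code{-G_N} on necrotic tissue.
#'
#' @param sigma Oxygen field.
#' @param region Label field from [classify_tissue()].
#' @param growth [growth_params()].
#' @return Net proliferation rate field (1/day).
#' @export
net_proliferation <- function(sigma, region, growth) {
  lambda <- matrix(0, nrow(sigma), ncol(sigma))
  v <- region == REGION_VIABLE
  lambda[v] <- sigma[v] - growth$apoptosis_rate
  lambda[region == REGION_NECROTIC] <- -growth$necrotic_volume_loss
  lambda
}

#' Solve the oncotic pressure
#'
#' Solves \code{-mu lap(P) = lambda - chi_E lap(E)} on the tumor domain
#' with \code{P = 0} on the tumor-host interface (stress-free host),
#' enforcing \code{div(u) = lambda} for the generalized Darcy velocity.
#'
#' @param lambda Net proliferation field.
#' @param ecm ECM density field.
#' @param occupancy Logical tumor mask.
#' @param grid A [grid2d()].
#' @param growth [growth_params()].
#' @return Pressure field (zero outside the tumor).
#' @export
solve_pressure <- function(lambda, ecm, occupancy, grid, growth) {
  cells <- which(occupancy)
  if (!length(cells)) stop("empty tumor: pressure system is singular")
  nx <- grid$nx; ny <- grid$ny; dx <- grid$dx
  mu <- growth$mobility
  id <- matrix(0L, nx, ny)
  id[cells] <- seq_along(cells)
  ci <- ((cells - 1L) %% nx) + 1L
  cj <- ((cells - 1L) %/% nx) + 1L
  ii <- jj <- integer(0); xx <- numeric(0)
  for (d in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
    ni <- ci + d[1]; nj <- cj + d[2]
    inside <- ni >= 1L & ni <= nx & nj >= 1L & nj <= ny
    nb <- integer(length(cells)); nb[inside] <- id[cbind(ni[inside], nj[inside])]
    # every face contributes to the diagonal (ghost value 0 outside mask)
    ii <- c(ii, seq_along(cells)); jj <- c(jj, seq_along(cells))
    xx <- c(xx, rep(mu / dx^2, length(cells)))
    has_nb <- nb > 0L
    ii <- c(ii, which(has_nb)); jj <- c(jj, nb[has_nb])
    xx <- c(xx, rep(-mu / dx^2, sum(has_nb)))
  }
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(length(cells), length(cells)))
  lapE <- as.vector(neumann_laplacian(grid) %*% as.vector(ecm))
  rhs <- lambda[cells] - growth$haptotaxis_coeff * lapE[cells]
  P <- matrix(0, nx, ny)
  P[cells] <- as.numeric(Matrix::solve(A, rhs))
  P
}

#' Darcy tissue velocity
#'
#' Face-staggered velocity \code{u = -mu grad(P) + chi_E grad(E)} by
#' centered differences; domain-boundary faces carry zero velocity.
#'
#' @param P Oncotic pressure field (zero in the host).
#' @param ecm ECM density field.
#' @param grid A [grid2d()].
#' @param growth [growth_params()].
#' @return List with \code{ux} ((nx+1) x ny vertical-face field) and
#'   \code{uy} (nx x (ny+1) horizontal-face field), um/day.
#' @export
tumor_velocity <- function(P, ecm, grid, growth) {
  nx <- grid$nx; ny <- grid$ny; dx <- grid$dx
  mu <- growth$mobility; chi <- growth$haptotaxis_coeff
  ux <- matrix(0, nx + 1, ny); uy <- matrix(0, nx, ny + 1)
  ux[2:nx, ] <- -mu * (P[2:nx, ] - P[1:(nx - 1), ]) / dx +
    chi * (ecm[2:nx, ] - ecm[1:(nx - 1), ]) / dx
  uy[, 2:ny] <- -mu * (P[, 2:ny] - P[, 1:(ny - 1)]) / dx +
    chi * (ecm[, 2:ny] - ecm[, 1:(ny - 1)]) / dx
  list(ux = ux, uy = uy)
}

#' Advect the tumor occupancy
#'
#' First-order upwind (donor-cell) advection of the occupancy fraction with
#' the face velocities, followed by a mild anti-diffusive sharpening that
#' counteracts the upwind smearing of the interface while preserving the
#' 0.5 level set. Aborts when the advective CFL condition is violated.
#'
#' @param phi Occupancy volume-fraction field.
#' @param vel Face velocities from [tumor_velocity()].
#' @param grid A [grid2d()].
#' @param dt Time step (days).
#' @param sharpen Sharpening strength per call (0 disables).
#' @return Updated \code{phi}, clamped to `[0, 1]`.
#' @export
advance_interface <- function(phi, vel, grid, dt, sharpen = 0.15) {
  nx <- grid$nx; ny <- grid$ny; dx <- grid$dx
  ux <- vel$ux; uy <- vel$uy
  speed <- pmax(abs(ux[1:nx, ] ), abs(ux[2:(nx + 1), ])) +
    pmax(abs(uy[, 1:ny]), abs(uy[, 2:(ny + 1)]))
  if (max(speed) * dt > dx)
    stop(sprintf(
      "CFL violation in interface advection: max|u|*dt = %.3g > dx = %.3g",
      max(speed) * dt, dx))
  uW <- ux[1:nx, ]; uE <- ux[2:(nx + 1), ]
  uS <- uy[, 1:ny]; uN <- uy[, 2:(ny + 1)]
  phiW <- rbind(phi[1, ], phi[-nx, ]); phiE <- rbind(phi[-1, ], phi[nx, ])
  phiS <- cbind(phi[, 1], phi[, -ny]); phiN <- cbind(phi[, -1], phi[, ny])
  inflow <- pmax(uW, 0) * (phiW - phi) + pmax(-uE, 0) * (phiE - phi) +
    pmax(uS, 0) * (phiS - phi) + pmax(-uN, 0) * (phiN - phi)
  phi <- phi + dt / dx * inflow
  if (sharpen > 0)
    phi <- phi + sharpen * phi * (1 - phi) * (2 * phi - 1)
  pmin(pmax(phi, 0), 1)
}
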