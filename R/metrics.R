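# Reported observables: tumor radius, per-class blood area fractions, mean
# flow/shear with SEM over in-tumor segments, adhered particle fraction per
# tumor area, and the Gompertz summary fit of the radius time course.

#' Equivalent-circle tumor radius
#'
#' @param occupancy Logical tumor mask.
#' @param grid A [grid2d()].
#' @return Radius in mm (\code{sqrt(area / pi)}); 0 for an empty tumor.
#' @export
tumor_radius <- function(occupancy, grid) {
  area_um2 <- sum(occupancy) * grid$dx^2
  sqrt(area_um2 / pi) / 1000
}

#' Blood area fraction per vessel class
#'
#' Ratio of the vessel-covered area (projected area \code{2 R_u L_u}
#' summed over in-tumor segments of the class) to the tumor
#' cross-sectional area, capped at 1.
#'
#' @param net A \code{vessel_network}.
#' @param occupancy Logical tumor mask (non-empty).
#' @param class \code{"neo"} or \code{"pre"}.
#' @param grid A [grid2d()].
#' @return Dimensionless fraction in `[0, 1]`.
#' @export
blood_area_fraction <- function(net, occupancy, class, grid) {
  if (!any(occupancy)) stop("blood area fraction undefined for empty tumor")
  segs <- alive_segs(net)
  inside <- vessel_overlap_coopt(net, occupancy, grid)
  cls <- c("pre", "neo")[net$sg_class[segs]]
  sel <- inside & cls == class
  covered <- sum(2 * net$sg_R[segs][sel] * net$sg_L[segs][sel])
  min(covered / (sum(occupancy) * grid$dx^2), 1)
}

#' Mean flow and shear statistics over in-tumor segments
#'
#' Arithmetic mean and standard error (sd/sqrt(n)) of |Q| and the wall
#' shear rate over perfused in-tumor segments of one class.
#'
#' @inheritParams blood_area_fraction
#' @return One-row data frame (\code{NULL} when the class has no perfused
#'   in-tumor segment): n, mean/SEM of flow (m^3/s) and shear (1/s).
#' @export
vascular_stats <- function(net, occupancy, class, grid) {
  segs <- alive_segs(net)
  inside <- vessel_overlap_coopt(net, occupancy, grid)
  cls <- c("pre", "neo")[net$sg_class[segs]]
  sel <- inside & cls == class & net$sg_perfused[segs]
  n <- sum(sel)
  if (n == 0) return(NULL)
  q <- abs(net$sg_Q[segs][sel]); s <- net$sg_S[segs][sel]
  data.frame(class = class, n = n,
             mean_flow = mean(q),
             sem_flow = stats::sd(q) / sqrt(n),
             mean_shear = mean(s),
             sem_shear = stats::sd(s) / sqrt(n))
}

#' Adhered nanoparticle fraction per tumor area
#'
#' Total attached dose fraction (sum of MpS) over in-tumor segments,
#' divided by the tumor area in mm^2 at the injection day.
#'
#' @param net The (frozen) injected \code{vessel_network}.
#' @param state A \code{particle_state} from [run_injection()].
#' @param occupancy Logical tumor mask at the injection day.
#' @param grid A [grid2d()].
#' @param scope \code{"tumor"} counts segments whose midpoint lies in the
#'   occupancy mask; \code{"total"} counts every segment (the two are close
#'   when, as with receptor-targeted particles, adhesion concentrates on
#'   the tumor-induced vasculature, which straddles the sharp mask at the
#'   tumor boundary).
#' @return Accumulation density in 1/mm^2.
#' @export
np_accumulation_per_area <- function(net, state, occupancy, grid,
                                     scope = c("tumor", "total")) {
  scope <- match.arg(scope)
  if (scope == "total") tot <- sum(state$MpS)
  else {
    segs <- alive_segs(net)
    inside <- vessel_overlap_coopt(net, occupancy, grid)
    tot <- sum(state$MpS[state$segs %in% segs[inside]])
  }
  area_mm2 <- sum(occupancy) * grid$dx^2 / 1e6
  tot / area_mm2
}

#' Fit a Gompertz growth curve to a radius time course
#'
#' Least-squares fit of \code{r(t) = r1 exp(r2 exp(r3 t))} (asymptote
#' \code{r1}, shape \code{r2 < 0}, rate \code{r3 < 0}) by
#' Levenberg-Marquardt, with a deterministic multi-start on \code{r3}. A
#' near-constant series is returned as a flat fit (\code{r2 = r3 = 0}),
#' flagged.
#'
#' @param days Time points (days), at least 4.
#' @param radii Radii (mm), positive.
#' @return List of class \code{gompertz_fit}: \code{r1}, \code{r2},
#'   \code{r3}, \code{rss}, \code{flat}, \code{fitted}.
#' @export
gompertz_fit <- function(days, radii) {
  stopifnot(length(days) >= 4, length(radii) == length(days),
            all(radii > 0))
  if (stats::sd(radii) < 1e-12 * mean(radii)) {
    fit <- list(r1 = mean(radii), r2 = 0, r3 = 0, rss = 0, flat = TRUE,
                fitted = rep(mean(radii), length(days)))
    class(fit) <- "gompertz_fit"
    return(fit)
  }
  best <- NULL
  for (r3_0 in c(-0.05, -0.1, -0.2, -0.5)) {
    r1_0 <- max(radii) * 1.2
    r2_0 <- mean(log(radii / r1_0) / exp(r3_0 * days))
    f <- tryCatch(
      minpack.lm::nlsLM(r ~ r1 * exp(r2 * exp(r3 * t)),
                        data = data.frame(t = days, r = radii),
                        start = list(r1 = r1_0, r2 = r2_0, r3 = r3_0),
                        control = minpack.lm::nls.lm.control(
                          maxiter = 500, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(f)) next
    rss <- sum(stats::resid(f)^2)
    if (is.null(best) || rss < best$rss) {
      cf <- stats::coef(f)
      best <- list(r1 = unname(cf["r1"]), r2 = unname(cf["r2"]),
                   r3 = unname(cf["r3"]), rss = rss, flat = FALSE,
                   fitted = stats::fitted(f))
    }
  }
  if (is.null(best))
    stop("Gompertz fit did not converge from any start")
  class(best) <- "gompertz_fit"
  best
}

#' @export
print.gompertz_fit <- function(x, ...) {
  cat(sprintf("Gompertz fit: r(t) = %.4g * exp(%.4g * exp(%.4g t)), rss %.3g%s\n",
              x$r1, x$r2, x$r3, x$rss, if (x$flat) " [flat]" else ""))
  invisible(x)
}
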