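#' Parameters of the continuum tumor growth model
#'
#' Nondimensional parameters of the tissue-scale tumor model: the net
#' proliferation rate on viable tissue is \code{sigma - apoptosis_rate}
#' (oxygen \code{sigma} scaled to the peri-vascular value of 1), hypoxic
#' tissue is quiescent, and necrotic tissue loses volume at
#' \code{necrotic_volume_loss} per day.
#'
#' @param mobility Cell mobility in the Darcy law (um^2/day per unit
#'   pressure); lumps cell-cell and cell-matrix adhesion.
#' @param haptotaxis_coeff Haptotaxis coefficient chi_E coupling the cell
#'   velocity to gradients of the ECM density.
#' @param apoptosis_rate Natural apoptosis rate A (1/day) subtracted from the
#'   oxygen-driven proliferation term.
#' @param necrotic_volume_loss Nondimensional volume loss rate G_N (1/day)
#'   in necrotic regions (fluid removal and debris degradation).
#' @param hypoxia_threshold Oxygen level sigma_H below which cells are
#'   quiescent (hypoxic).
#' @param necrosis_threshold Oxygen level sigma_N below which cells die.
#' @return A list of class \code{growth_params}.
#' @export
growth_params <- function(mobility = 1,
                          haptotaxis_coeff = 2,
                          apoptosis_rate = 0.5,
                          necrotic_volume_loss = 0.5,
                          hypoxia_threshold = 0.5,
                          necrosis_threshold = 0.3) {
  stopifnot(mobility > 0, haptotaxis_coeff >= 0,
            apoptosis_rate >= 0, necrotic_volume_loss >= 0)
  if (!(necrosis_threshold > 0 && necrosis_threshold < hypoxia_threshold &&
        hypoxia_threshold < 1))
    stop("thresholds must satisfy 0 < sigma_N < sigma_H < 1")
  structure(list(mobility = mobility, haptotaxis_coeff = haptotaxis_coeff,
                 apoptosis_rate = apoptosis_rate,
                 necrotic_volume_loss = necrotic_volume_loss,
                 hypoxia_threshold = hypoxia_threshold,
                 necrosis_threshold = necrosis_threshold),
            class = "growth_params")
}

#' Parameters of the substrate (oxygen, TAF, ECM) fields
#'
#' Oxygen is treated quasi-steadily: supplied at perfused vessel locations,
#' consumed by normal and tumor tissue, decaying in necrotic regions, with a
#' constant diffusivity. Rates are relative to the normal-tissue uptake rate
#' which defines the nondimensional scale (\code{uptake_normal = 1}).
#'
#' @param d_oxygen Oxygen diffusivity (um^2, relative to unit normal uptake);
#'   the default gives a diffusion length of 200 um in normal tissue, which
#'   keeps the host normoxic under the 250 um pre-existing grid.
#' @param transfer_rate Vessel-to-tissue transfer rate; \code{NA} (default)
#'   means it is normalized at simulation start so that the peak oxygen of
#'   the intact pre-existing grid equals 1.
#' @param uptake_normal,uptake_viable,uptake_hypoxic Consumption rates of
#'   host, proliferating, and hypoxic tissue.
#' @param decay_necrotic Oxygen decay rate in necrotic tissue.
#' @param interp_band Half-width (in sigma) of the linear interpolation band
#'   smoothing the uptake rate across region thresholds.
#' @param h_normal Normal discharge hematocrit at the network inlets.
#' @param h_min Minimum hematocrit required for oxygen extravasation.
#' @param skimming_exponent Exponent of the flow-weighted plasma-skimming
#'   split at diverging bifurcations (1 = proportional; larger values
#'   starve low-flow branches of red cells, as real phase separation does).
#' @param p_i,p_e Interstitial and effective (blood minus osmotic) pressures
#'   entering the trans-wall convective reduction factor.
#' @param convective_weight Weight of the convective component of trans-wall
#'   transport; the extravasation source is reduced by
#'   \code{1 - convective_weight * p_i / p_e}.
#' @param d_taf TAF diffusivity (um^2, relative to unit decay).
#' @param taf_production TAF production rate per hypoxic cell.
#' @param taf_decay Natural TAF decay rate.
#' @param taf_vessel_uptake TAF consumption rate at vessel locations.
#' @param ecm_degradation ECM degradation rate inside the tumor (1/day).
#' @param ecm_production ECM production rate at vessel locations (1/day).
#' @param ecm_noise_sd Standard deviation of the seeded initial ECM noise.
#' @return A list of class \code{substrate_params}.
#' @export
substrate_params <- function(d_oxygen = 200^2,
                             transfer_rate = NA_real_,
                             uptake_normal = 1,
                             uptake_viable = 6,
                             uptake_hypoxic = 2,
                             decay_necrotic = 1,
                             interp_band = 0.025,
                             h_normal = 0.45,
                             h_min = 0.25,
                             skimming_exponent = 2,
                             p_i = 0,
                             p_e = 1,
                             convective_weight = 1,
                             d_taf = 200^2,
                             taf_production = 1,
                             taf_decay = 1,
                             taf_vessel_uptake = 2,
                             ecm_degradation = 0.15,
                             ecm_production = 0.01,
                             ecm_noise_sd = 0.02) {
  stopifnot(d_oxygen > 0, uptake_normal >= 0, uptake_viable >= 0,
            uptake_hypoxic >= 0, decay_necrotic >= 0,
            h_min >= 0, h_min <= h_normal, h_normal <= 1,
            d_taf > 0, taf_production >= 0, taf_decay >= 0,
            taf_vessel_uptake >= 0, p_e > 0,
            ecm_degradation >= 0, ecm_production >= 0, ecm_noise_sd >= 0)
  structure(list(d_oxygen = d_oxygen, transfer_rate = transfer_rate,
                 uptake_normal = uptake_normal, uptake_viable = uptake_viable,
                 uptake_hypoxic = uptake_hypoxic,
                 decay_necrotic = decay_necrotic, interp_band = interp_band,
                 h_normal = h_normal, h_min = h_min,
                 skimming_exponent = skimming_exponent,
                 p_i = p_i, p_e = p_e,
                 convective_weight = convective_weight,
                 d_taf = d_taf, taf_production = taf_production,
                 taf_decay = taf_decay, taf_vessel_uptake = taf_vessel_uptake,
                 ecm_degradation = ecm_degradation,
                 ecm_production = ecm_production,
                 ecm_noise_sd = ecm_noise_sd),
            class = "substrate_params")
}

#' Parameters of the stochastic lattice angiogenesis model
#'
#' Sprout tips perform a biased random walk on the field lattice. Move
#' weights are proportional to
#' \code{max(0, D + chi(T) * dT + rho * dE)} over the four neighbors, with a
#' saturating chemotactic sensitivity \code{chi(T) = chi0 / (1 + c_t * T)}.
#'
#' @param d_motility Random-motility weight D (dimensionless).
#' @param chi0 Chemotaxis coefficient scale.
#' @param c_t Chemotactic saturation constant.
#' @param rho Haptotaxis coefficient.
#' @param taf_threshold Minimum TAF level for sprout initiation and
#'   branching eligibility.
#' @param initiation_prob Per-step probability that an eligible perfused
#'   vessel node initiates a sprout.
#' @param branch_prob Per-step probability that an eligible tip branches
#'   into two.
#' @param branch_min_age Minimum tip age (migration steps) for branching.
#' @param anastomosis Whether tips fuse with vessels they run into.
#' @param steps_per_day Migration steps per day (sets the tip speed of one
#'   lattice edge per step).
#' @param tip_max_age Steps after which an unfused tip is retired.
#' @param sprout_cooldown Days before a node may sprout again.
#' @param max_tips Cap on simultaneously active tips.
#' @return A list of class \code{angiogenesis_params}.
#' @export
angiogenesis_params <- function(d_motility = 1,
                                chi0 = 100,
                                c_t = 2,
                                rho = 10,
                                taf_threshold = 0.005,
                                initiation_prob = 0.5,
                                branch_prob = 0.45,
                                branch_min_age = 2,
                                anastomosis = TRUE,
                                steps_per_day = 8,
                                tip_max_age = 80,
                                sprout_cooldown = 2,
                                max_tips = 2000) {
  stopifnot(d_motility >= 0, chi0 >= 0, rho >= 0, c_t >= 0,
            initiation_prob >= 0, initiation_prob <= 1,
            branch_prob >= 0, branch_prob <= 1,
            steps_per_day > 0, tip_max_age >= 1, max_tips >= 1)
  structure(list(d_motility = d_motility, chi0 = chi0, c_t = c_t, rho = rho,
                 taf_threshold = taf_threshold,
                 initiation_prob = initiation_prob, branch_prob = branch_prob,
                 branch_min_age = branch_min_age, anastomosis = anastomosis,
                 steps_per_day = steps_per_day, tip_max_age = tip_max_age,
                 sprout_cooldown = sprout_cooldown, max_tips = max_tips),
            class = "angiogenesis_params")
}

#' Parameters of the structural radius adaptation model
#'
#' Radii evolve as \code{dR = R * dt * (S_wss + S_p + S_m + S_s)} following
#' the structural adaptation family of Pries and co-workers: a wall shear
#' stress stimulus \code{S_wss = log10(tau_w + tau_ref)} (tau in dyn/cm^2),
#' a pressure stimulus \code{S_p = -k_p * log10(tau_e(P))} with the
#' empirical expected-shear sigmoid tau_e of the intravascular pressure, a
#' metabolic stimulus \code{S_m = k_m * log10(Q_ref / (|Q| H_D) + 1)}, and a
#' tissue-pressure shrinking stimulus \code{S_s = -k_s * P_tissue} applied
#' to pre-existing vessels co-opted by the tumor.
#'
#' @param k_p Pressure-stimulus intensity.
#' @param k_m Metabolic-stimulus intensity.
#' @param k_s Shrinking-tendency coefficient (tissue pressure stimulus).
#' @param tau_ref Reference wall shear stress (dyn/cm^2) avoiding the
#'   logarithmic singularity at zero shear.
#' @param q_ref Reference flow (m^3/s), larger than most network flows.
#' @param r_min,r_max Radius clamps (um).
#' @param prune_radius Radius floor (um) below which a segment is removed
#'   from the network (subject to an inlet-outlet connectivity check).
#' @param p_mmhg_lo,p_mmhg_hi Range (mmHg) onto which the nondimensional
#'   nodal pressures are mapped before evaluating the tau_e(P) sigmoid.
#' @return A list of class \code{adaptation_params}.
#' @export
adaptation_params <- function(k_p = 0.1,
                              k_m = 0.4,
                              k_s = 0.55,
                              tau_ref = 0.15,
                              q_ref = 1e-14,
                              r_min = 2,
                              r_max = 12,
                              prune_radius = 2.2,
                              p_mmhg_lo = 40,
                              p_mmhg_hi = 60) {
  stopifnot(tau_ref > 0, q_ref > 0, k_p >= 0, k_m >= 0, k_s >= 0,
            r_min > 0, r_max > r_min, prune_radius >= 0,
            p_mmhg_hi > p_mmhg_lo, p_mmhg_lo >= 10)
  structure(list(k_p = k_p, k_m = k_m, k_s = k_s, tau_ref = tau_ref,
                 q_ref = q_ref, r_min = r_min, r_max = r_max,
                 prune_radius = prune_radius,
                 p_mmhg_lo = p_mmhg_lo, p_mmhg_hi = p_mmhg_hi),
            class = "adaptation_params")
}

#' Nanoparticle design specification
#'
#' Describes a systemically injected spherical nanoparticle and its vascular
#' adhesion parameters. The adhesion strength \code{alpha} is proportional
#' to the product of receptor density, ligand density and zero-force
#' ligand-receptor affinity (see [derive_alpha()]); \code{beta} weights the
#' shear-dependent hydrodynamic dislodging term and \code{gamma} scales
#' inversely with the receptor surface density.
#'
#' @param d Particle diameter in nm (100, 600 and 1000 are the reference
#'   designs).
#' @param alpha_neo,alpha_pre Adhesion strength (m^-2) on neovascular and
#'   pre-existing endothelium; receptor over-expression on tumor endothelium
#'   makes \code{alpha_pre} typically 100-fold smaller.
#' @param beta Dislodging parameter (m^-2 s).
#' @param gamma Receptor-scarcity parameter (m^-delta2).
#' @param delta1,delta2 Fitted exponents of the adhesion law (0.45, 1.57).
#' @param a0 Dimensional closure of the dislodging exponent (m^2); see the
#'   methods vignette.
#' @param kappa0 Dimensionless near-wall exposure closure converting the
#'   per-area adhering density into a per-transit capture probability.
#' @return A list of class \code{particle_spec}.
#' @export
particle_spec <- function(d = 1000,
                          alpha_neo = 1e12,
                          alpha_pre = 1e10,
                          beta = 1e-4,
                          gamma = 1e4,
                          delta1 = 0.45,
                          delta2 = 1.57,
                          a0 = 500,
                          kappa0 = 200) {
  stopifnot(d > 0, alpha_neo >= 0, alpha_pre >= 0, beta >= 0, gamma >= 0,
            delta1 >= 0, delta2 >= 0, a0 >= 0, kappa0 >= 0)
  structure(list(d = d, alpha_neo = alpha_neo, alpha_pre = alpha_pre,
                 beta = beta, gamma = gamma, delta1 = delta1,
                 delta2 = delta2, a0 = a0, kappa0 = kappa0),
            class = "particle_spec")
}

#' Cell-centered 2D grid
#'
#' @param domain_um Square domain side (um).
#' @param dx_um Grid spacing (um).
#' @return List of class \code{grid2d} with fields \code{nx}, \code{ny},
#'   \code{dx} and cell-center coordinates. Scalar fields are \code{nx} x
#'   \code{ny} matrices, row index = x, 0-based lattice convention for the
#'   vessel lattice (nodes at corners \code{i * dx}).
#' @export
grid2d <- function(domain_um, dx_um) {
  nx <- domain_um / dx_um
  if (abs(nx - round(nx)) > 1e-9) stop("dx must divide the domain size")
  nx <- as.integer(round(nx))
  structure(list(nx = nx, ny = nx, dx = dx_um, domain = domain_um,
                 xc = (seq_len(nx) - 0.5) * dx_um,
                 yc = (seq_len(nx) - 0.5) * dx_um),
            class = "grid2d")
}

#' Full simulation configuration
#'
#' Collects geometry, timing, boundary pressures and all model parameter
#' groups. Defaults define the baseline study: a 2 x 2 mm tissue cross
#' section perfused by a regular 250 um vessel grid, a 50 um avascular
#' nodule seeded at the domain center, and 24 simulated days.
#'
#' @param domain_size Domain side (um), default 2000.
#' @param grid_spacing Field/lattice spacing (um); must divide
#'   \code{vessel_spacing}.
#' @param vessel_spacing Spacing of the pre-existing vessel grid (um); must
#'   divide \code{domain_size}.
#' @param initial_tumor_radius Initial nodule radius (um).
#' @param initial_vessel_radius Initial radius of every vessel (um).
#' @param end_time Simulated duration (days).
#' @param growth_dt Growth time step (days).
#' @param inlet_pressure,outlet_pressure Boundary pressures (nondimensional;
#'   the default drop is calibrated to give healthy-grid wall shear rates of
#'   a few tens per second).
#' @param snapshot_days Days at which full network/tumor snapshots are kept
#'   (for standalone particle injections).
#' @param rng_seed Integer seed controlling all stochastic components.
#' @param growth,substrates,angiogenesis,adaptation,particles Parameter
#'   groups; see the respective constructors.
#' @return A list of class \code{simulation_config}.
#' @export
simulation_config <- function(domain_size = 2000,
                              grid_spacing = 15.625,
                              vessel_spacing = 250,
                              initial_tumor_radius = 50,
                              initial_vessel_radius = 6,
                              end_time = 24,
                              growth_dt = 0.1,
                              inlet_pressure = 45,
                              outlet_pressure = 0,
                              snapshot_days = c(6, 12, 18, 24),
                              rng_seed = 1L,
                              growth = growth_params(),
                              substrates = substrate_params(),
                              angiogenesis = angiogenesis_params(),
                              adaptation = adaptation_params(),
                              particles = particle_spec()) {
  stopifnot(domain_size > 0, grid_spacing > 0, vessel_spacing > 0,
            initial_tumor_radius >= 0, initial_vessel_radius > 0,
            end_time > 0, growth_dt > 0)
  if (inlet_pressure <= outlet_pressure)
    stop("inlet_pressure must exceed outlet_pressure")
  if (abs(domain_size / vessel_spacing -
          round(domain_size / vessel_spacing)) > 1e-9)
    stop("vessel_spacing must divide domain_size exactly")
  if (abs(vessel_spacing / grid_spacing -
          round(vessel_spacing / grid_spacing)) > 1e-9)
    stop("grid_spacing must divide vessel_spacing exactly")
  if (initial_tumor_radius >= vessel_spacing / 2)
    stop("initial tumor radius must be below half the vessel spacing")
  stopifnot(inherits(growth, "growth_params"),
            inherits(substrates, "substrate_params"),
            inherits(angiogenesis, "angiogenesis_params"),
            inherits(adaptation, "adaptation_params"),
            inherits(particles, "particle_spec"))
  structure(list(domain_size = domain_size, grid_spacing = grid_spacing,
                 vessel_spacing = vessel_spacing,
                 initial_tumor_radius = initial_tumor_radius,
                 initial_vessel_radius = initial_vessel_radius,
                 end_time = end_time, growth_dt = growth_dt,
                 inlet_pressure = inlet_pressure,
                 outlet_pressure = outlet_pressure,
                 snapshot_days = snapshot_days,
                 rng_seed = as.integer(rng_seed),
                 growth = growth, substrates = substrates,
                 angiogenesis = angiogenesis, adaptation = adaptation,
                 particles = particles),
            class = "simulation_config")
}

#' Read a simulation configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [simulation_config()]; parameter
#' groups are nested maps (\code{growth:}, \code{substrates:},
#' \code{angiogenesis:}, \code{adaptation:}, \code{particles:}) whose
#' entries override the defaults of the corresponding constructor.
#'
#' @param path Path to a YAML file.
#' @return A \code{simulation_config}.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  groups <- list(growth = growth_params, substrates = substrate_params,
                 angiogenesis = angiogenesis_params,
                 adaptation = adaptation_params, particles = particle_spec)
  args <- y[setdiff(names(y), names(groups))]
  for (g in names(groups))
    if (!is.null(y[[g]])) args[[g]] <- do.call(groups[[g]], y[[g]])
  do.call(simulation_config, args)
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("<simulation_config>\n")
  cat(sprintf("  domain %g x %g um, grid %g um, vessel spacing %g um\n",
              x$domain_size, x$domain_size, x$grid_spacing, x$vessel_spacing))
  cat(sprintf("  tumor r0 %g um, vessel r0 %g um, %g days (dt %g), seed %d\n",
              x$initial_tumor_radius, x$initial_vessel_radius,
              x$end_time, x$growth_dt, x$rng_seed))
  invisible(x)
}
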