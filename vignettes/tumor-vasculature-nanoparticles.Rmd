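---
title: "Modeling tumor-induced vasculature and nanoparticle vascular deposition"
author: "nanovasc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling tumor-induced vasculature and nanoparticle vascular deposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`nanovasc` simulates, on a 2 x 2 mm tissue cross section, the growth of a
vascularized tumor from a 50 um avascular nodule to day 24 post inception,
and the vascular deposition of systemically injected nanoparticles (NPs)
into the resulting microvascular network. This vignette is the package's
own account of the model: the governing equations and the assumptions
behind them, the parameters that matter and how their defaults were chosen,
the numerical schemes, and the known limitations.

## The coupled model

### Tissue-scale tumor growth

The tumor is a continuum occupancy field on a cell-centered grid (default
15.625 um spacing, 128 x 128 cells; the spacing divides the 250 um vessel
spacing exactly so vessels lie on grid lines). Tissue is partitioned by the local oxygen level `sigma`
(nondimensionalized so the peri-vascular level of the intact host grid is
1): viable where `sigma >= sigma_H` (default 0.5), hypoxic down to
`sigma_N` (default 0.3), necrotic below. The net volume production rate is

    lambda = sigma - A      (viable; A = apoptosis rate)
    lambda = 0              (hypoxic, host)
    lambda = -G_N           (necrotic volume loss)

Cell density is constant, so `div(u) = lambda` with the generalized Darcy
velocity `u = -mu grad(P) + chi_E grad(E)`, where `P` is the oncotic
pressure (Poisson solve with `P = 0` in the host: the surrounding tissue is
treated as stress-free, a standard closure for this model family) and `E`
the non-diffusible ECM density (haptotaxis is kept functional but
secondary, `chi_E` small). The occupancy is advected with `u` by a
donor-cell upwind scheme with a mild anti-diffusive sharpening of the 0.5
level set; the orchestrator substeps the advection whenever growth would
violate the CFL bound that `advance_interface()` enforces.

The interface scheme is a deliberate simplification relative to level-set
front tracking: for the radially averaged observables reported here
(equivalent-circle radius, area fractions) a volume-of-fluid occupancy is
adequate and considerably simpler.

### Substrates

Oxygen, TAF (tumor angiogenic factor) and ECM evolve quasi-steadily or
locally. The quasi-steady treatment rests on the timescale separation
between molecular diffusion (about a minute across this domain) and growth
(about a day): substrate fields are re-solved to steady state at every
growth step. Oxygen solves

    0 = D lap(sigma) + source - q(sigma, region) sigma

with zero-Neumann walls. The source is `transfer_rate` on vessel-indicator
cells, gated by the hematocrit extravasation factor
`max(0, (H_D - h_min)/(h_normal - h_min))` — a segment whose discharge
hematocrit falls below `h_min` delivers no oxygen — and reduced by the
convective trans-wall factor `1 - convective_weight * p_i / p_e`
(interstitial pressure `p_i` defaults to 0; it has no dynamics of its own
in this model). The uptake rate interpolates linearly in `sigma` over
bands of half-width 0.025 between the host, viable, hypoxic and necrotic
rates, which provides the required smoothness with a single extra
parameter. The transfer rate itself is fixed once at start-up by solving
the intact grid and normalizing its peak oxygen to 1
(`normalize_transfer_rate()`); this pins the nondimensional oxygen scale
to the healthy peri-vascular value. Later remodeling can locally push
`sigma` slightly above 1 (flow rearrangement gives previously stagnant
vessels hematocrit); this is harmless since all thresholds sit well below.

TAF is produced by hypoxic tissue, decays, and is consumed by endothelium
at vessel cells; ECM is produced near vessels and degraded inside the
tumor, with seeded initial noise so haptotaxis has gradients to act on.

Defaults: oxygen diffusion length 200 um in host tissue (uptake 1 by
definition; viable uptake 6, hypoxic 2, necrotic decay 1), chosen so that
the 250 um pre-existing grid keeps the host normoxic (everywhere above
`sigma_H`) while a 100-200 um avascular tumor core goes hypoxic.

### Angiogenesis

Endothelial sprouting is represented only by the discretized stochastic
tip form of the endothelial conservation law: tips on the field lattice
move to one of the four neighbors with probability proportional to

    max(0, D + chi(T) (T_nb - T_here) + rho (E_nb - E_here)),
    chi(T) = chi0 / (1 + c_t T)

(the saturating chemotactic sensitivity standard in this model family),
never immediately reversing. Each move lays a neovessel segment of initial
radius 6 um; stepping onto an existing vessel node fuses the sprout there
(anastomosis), closing a flow-eligible loop and terminating the tip (and
any tip already sitting on that node). Tips initiate on perfused vessel
nodes where TAF exceeds a threshold, at most one per node per step with a
per-node cooldown, and branch with a fixed per-step probability once at
least two steps old. Tip speed is one lattice edge per migration step,
default 8 steps/day (125 um/day at the default lattice). Initiation, branching and threshold
values are not printed in the source study (they live in its companion
references); the defaults here were calibrated once so that the
neovascular blood area fraction and the mean neovascular flow/shear rise
over the first ~10 days and then plateau, and were then frozen.

### Hemodynamics and structural adaptation

Blood flow solves Kirchhoff's law with Poiseuille conductances
`pi R^4 / (8 mu_app L)` and Dirichlet pressures on the left (inlet) and
right (outlet) domain edges. The apparent viscosity is the in-vitro
diameter/hematocrit law of the Fahraeus-Lindqvist type, with plasma
viscosity 1.2e-3 Pa s. Discharge hematocrit propagates from the inlets
(0.45) along flow directions; at diverging bifurcations red-cell flux is
split by a flow-weighted rule with exponent 2 by default. The exponent is
the one deliberate departure from a proportional split: proportional
partitioning gives every perfused segment full hematocrit, the entire
neovascular web then extravasates oxygen, and the tumor never develops the
hypoxic/necrotic interior or the decelerating (Gompertzian) radius course
the model is supposed to produce. An exponent of 2 mimics real phase
separation — low-flow daughter branches are starved of red cells and fall
below the oxygen-extravasation hematocrit — and restores that phenomenology.

Wall shear stress is `tau_w = 4 mu |Q| / (pi R^3)`; the shear rate is
`tau_w / mu`. Radii adapt as `dR = R dt (S_wss + S_p + S_m + S_s)` with
the Pries-type stimuli described in `?adaptation_params`: shear
(`log10(tau_w + tau_ref)`, dyn/cm^2), pressure (`-k_p log10(tau_e(P))`
with the empirical expected-shear sigmoid, nodal pressures mapped onto a
40-60 mmHg band — the narrow band keeps the homogeneous synthetic grid from
drifting under a stimulus gradient it was never meant to see), metabolic
(`k_m log10(Q_ref/(|Q| H_D) + 1)`), and a tissue-pressure shrinking
stimulus `-k_s * phi` applied to every vessel the tumor envelops, with the
local occupancy fraction standing in for mechanical confinement. Applying
the confinement to the neovasculature as well as to co-opted pre-existing
vessels is essential: it is what starves the tumor interior, produces the
large hypoxic core, and bends the radius course onto a saturating
(Gompertz-fittable) trajectory. Segments that collapse below 2.2 um are
removed unless removal would disconnect the inlets from the outlets
(checked and rolled back); dead-end sprouts carry no flow and are excluded
from adaptation and from all flow statistics, but are retained as growing
sprouts. The intensity constants `k_p`, `k_m`, `k_s`, `tau_ref`, `Q_ref`
are not printed in the source study; the defaults were calibrated once
(healthy-grid equilibrium near 6 um radius and ~45/s wall shear on
flow-carrying lines, collapse of co-opted vessels over days, plateaus
after day ~10) and frozen.

The boundary pressure drop (50 nondimensional units across 2 mm) is
likewise a calibration: it sets the healthy-grid shear scale so that the
mean over flow-carrying and stagnant grid segments inside the tumor is a
few tens per second. Flows are reported in SI (m^3/s); the source study
prints mean flows of order 1e-5 m^3/s for micron-scale vessels, which is
dimensionally inconsistent with Poiseuille flow at these radii, so this
package reports SI magnitudes and reproduces ratios and time-course
shapes rather than those printed magnitudes.

### Nanoparticle transport and adhesion

Injections run on a frozen, flow-solved network. A unit-normalized
concentration is held at the inlet nodes for the injection window (default
100 min). Per-segment blood concentrations follow an explicit upwind
update: node concentrations are flux-weighted mixtures of their inflows,
and each segment exchanges with its upstream node, loses to its downstream
node, and deposits on its wall. The time step is half the shortest
perfused transit time. By construction the discrete balance
`injected = in transit + adhered + outflowed` telescopes exactly (to
round-off) at every step; non-adhered particles reaching an outlet leave
the system (no recirculation, per the source model's stated
simplification).

The adhesion law is isolated in the single pure function
`vascular_affinity()`:

    psi(d, S) = alpha * gamma * d^delta2 * exp(-a0 * beta * S * (d/d0)^delta1)

with `d0 = 1 um`, class-appropriate `alpha` (neovascular vs pre-existing
endothelium), `gamma = 1e4 m^-delta2`, `delta1 = 0.45`, `delta2 = 1.57`.
The printed fragments of the law fix the roles (alpha multiplicative;
gamma paired with `d^delta2` — note `gamma d^delta2` is exactly
dimensionless given gamma's units; beta weighting the shear-dependent
dislodging exponential) but not the full algebraic arrangement. The
arrangement above is the only assignment of the two fitted exponents that
satisfies every stated qualitative fact simultaneously: adhesion
increasing in alpha, decreasing in beta, decreasing in shear at high
shear, and — decisive — *increasing* with particle diameter at
`beta = 1e-4 m^-2 s`, with the reference ordering (100 nm at
`alpha = 1e12`) > (1000 nm at `1e10`) > (600 nm at `1e10`). Placing
`delta2` in the exponent instead reverses the 1000 nm / 600 nm ordering at
any positive shear.

Two closure constants are not derivable from the printed material and were
calibrated once, then frozen: `a0 = 500` (the dimensional scale of the
dislodging exponent, set so the shear term is order one at ~10/s for
micron particles) and `kappa0 = 200` (the near-wall exposure closure
converting the per-area adhering density `psi` times the segment wall area
into a per-transit capture probability, anchored to the reference
accumulation scale of ~0.4 /mm^2 for 100 nm particles at
`alpha = 1e12 m^-2`). The exposed-particle measure in the per-segment
attachment is the particle content `Cp V_u` of the segment, the only
closure consistent with the surface-concentration bookkeeping; capture
probabilities are capped at 1 and attachment can never exceed the
particles present.

## What the simulation emulates, and what it does not

The synthetic baseline *is* the study system: a regular 250 um host grid
(9 lines per dimension, boundary lines included), a 50 um central nodule,
24 days, four snapshot stages (days 6, 12, 18, 24), NP injections upstream
of the mass. Real tumor vasculature differs in ways this model does not
represent: three-dimensional topology, vessel tortuosity below the lattice
scale, compliant and leaky walls, particle margination and near-wall
enrichment, receptor saturation, and recirculation of non-adhered
particles. Passing tests therefore validate the implementation and its
internal physics, not patient-scale prediction.

A desk-scale note on resolution: the neovascular blood area fraction is
geometrically capped by `occupied-edge fraction x 4 R / dx`, so the
lattice spacing directly limits how much of the tumor section the web can
cover. At 25 um spacing the day-24 fraction saturates near 0.3 (with
intra-tumor radii compressed to 2-4 um); the default 15.625 um lattice
removes the cap and reaches ~0.58, at a 24-day runtime of about five
minutes on one CPU. The problem sizes used throughout (128 x 128 grid,
~10,000 segments by day 24, 100-minute injections) are the package's
desk-scale baseline.

## Numerical choices

- All elliptic solves (oxygen, TAF, oncotic pressure, nodal flow) use
  direct sparse factorizations from `Matrix`, with two iterative-refinement
  sweeps in the flow solve; residuals are at machine precision, below every
  stated tolerance (the model family's 1e-8 relative target included).
- Hematocrit is a fixed-point iteration; flow admits no directed cycles
  (pressure strictly decreases along flow), so it converges in at most the
  longest path length.
- The transport step is capped at half the shortest perfused transit time;
  with the capture cap this guarantees positivity and stability.
- Necrotic tissue whose oxygen recovers re-enters through the hypoxic
  class, never jumping straight to viable.
- Ties and degenerate cases: stalled tips age and retire; isolated network
  components created by pruning are excluded from the flow solve at the
  outlet pressure; a pruning step that would disconnect inlet from outlet
  is rolled back entirely.
- One master seed (L'Ecuyer-CMRG) with derived substreams per stochastic
  module makes runs bit-reproducible; adding draws to one module does not
  perturb the others.

## Reproducing the baseline

```{r}
library(nanovasc)
cfg <- simulation_config(rng_seed = 1)
sim <- run_simulation(cfg, verbose = TRUE)
print(sim)

snap <- sim$snapshots[["24"]]
st <- run_injection(snap$net,
                    particle_spec(d = 100, alpha_neo = 1e12,
                                  alpha_pre = 1e10, beta = 1e-4))
np_accumulation_per_area(snap$net, st, snap$occupancy, sim$grid,
                         scope = "total")
```

`scripts/acceptance.R` (repository root) wraps exactly this: the 24-day
baseline, the Gompertz fit of the radius course, and the three reference
injections, writing a JSON summary.

## Known limitations

- 2D only; no adaptive refinement; single nutrient species.
- The blood-area ceiling at 25 um lattice spacing discussed above.
- The adhesion law's dimensional closures (`a0`, `kappa0`) are calibrated,
  not derived; cross-design comparisons (ratios across d, alpha, beta) are
  the robust outputs.
- Hematocrit clamping at 1 can break red-cell flux conservation at
  strongly skimming bifurcations; in practice the clamp rarely binds.
- No trans-endothelial extravasation of particles: the model scores wall
  adhesion, not tissue penetration.
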