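---
title: "Methods: soft-layer electrokinetics and glycocalyx depth quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: soft-layer electrokinetics and glycocalyx depth quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glyx)
```

This vignette is the package's own account of its science: the models it
implements, the assumptions behind them, the choices made where the design
was genuinely open, and what the synthetic-data round trips do and do not
demonstrate.

## The problem

The glycocalyx is the carbohydrate-rich brush anchored to the outer cell
membrane: roughly 7–8 nm thick on red blood cells, and 2–4 µm on cultured
endothelium. Covalent grafting of hydrophilic polymers onto this layer is
the basis of immunocamouflage (hiding membrane antigens such as RhD and
CD47 from antibodies). Where along the brush the grafts land matters: an
outer-weighted shield camouflages better, and changes the cell's
electrophoretic behaviour differently, than the same number of grafts
spread through the layer. Adding an inert macromolecular crowder (here
30 kDa hyperbranched polyglycerol at 230 mg/mL) creates an oncotic
gradient that dehydrates and reversibly collapses the brush during
grafting, redirecting modification outward. The package quantifies this
redistribution along three independent lines of evidence: cell
electrophoresis, confocal z-stack imaging, and flow cytometry.

## The soft-layer electrokinetic model

A cell is represented as a flat plate carrying a penetrable charged layer
of thickness $\beta$ in a 1:1 electrolyte. Flatness is justified by scale
separation: both the Debye length $\kappa^{-1} \approx 0.8$ nm at
physiological ionic strength and $\beta = 7.8$ nm are minute against the
micron-scale cell radius, so curvature and relaxation corrections are
neglected (they are out of scope by design). The linearised
Poisson–Boltzmann equation is appropriate because the layer potentials
involved are a few tens of millivolts at most.

Two boundary-value problems are solved on $z \in [0, L]$, with $z = 0$ the
membrane:

* electrostatics: $\psi'' = \kappa^2\psi - \rho_{fix}(z)/(\varepsilon_r
  \varepsilon_0)$, with a membrane-flux condition $\psi'(0) =
  -\sigma_m/(\varepsilon_r\varepsilon_0)$ and $\psi(L) = 0$;
* hydrodynamics at unit applied field: $\eta u'' - f(z)\,u = -\rho_e(z)$
  with $\rho_e = -\varepsilon_r\varepsilon_0\kappa^2\psi$ (the mobile ion
  charge of the linearised double layer), no slip at the membrane
  ($u(0)=0$) and vanishing shear at the outer edge ($u'(L)=0$).

The Brinkman friction coefficient is $f(z) = 6\pi\eta a\, n(z)$, summed
over native segments (Stokes radius $a$, spread uniformly over
$[0,\beta]$) and grafted polymer segments (spread uniformly over a chosen
depth interval). Grafted HPG is electrically neutral, so grafting changes
$f(z)$ but not the charge — which is exactly why mobility reports on graft
*depth*: drag is weighted by the local flow speed, which grows away from
the membrane.

**Sign and frame convention.** Velocities are computed in the cell frame;
the mobility is defined once as $\mu = -u(L)$, so a negatively charged
layer yields $\mu < 0$. The convention is pinned by a test against the
Smoluchowski limit $\mu = \varepsilon_r\varepsilon_0\zeta/\eta$ for a
thin, friction-free charged layer.

### Parameters, units and defaults

| parameter | meaning | default | unit |
|---|---|---|---|
| `ionic_strength` | 1:1 electrolyte concentration | 0.145 | mol/L |
| `temperature` | absolute temperature | 298.15 | K |
| `viscosity` | solvent viscosity | 8.9e-4 | Pa·s |
| `relative_permittivity` | solvent permittivity | 78.5 | — |
| `thickness_beta` | glycocalyx thickness | 7.8e-9 | m |
| `segment_radius_a` | native segment Stokes radius | 0.5e-9 | m |
| `segment_surface_density` | native segments per area | 3e16 | m⁻² |
| `total_surface_charge` | layer charge per area | −0.0046 | C/m² |
| `cell_area` | RBC surface area | 1.4e-10 | m² |
| `z_lo_outer` | lower bound, outer scenario | 2.7e-9 | m |

The native segment density and layer charge are *inputs, not claims*: the
pair was calibrated once so that the ungrafted mobility lands at the
textbook red-cell value of about −1.08 µm·cm/(V·s) in physiological
saline. Graft segments default to the hydrodynamic radius scaling
$R_h = c\,M^{0.4}$ with $c = 5\times10^{-11}$ m, putting a 20 kDa HPG at
~2.6 nm and a 60 kDa HPG at ~4.1 nm (the compact, hyperbranched regime);
one resistive segment per molecule, both configurable.

### Numerics

Both equations are discretised with second-order central differences on a
uniform grid of 2000 nodes over $L = \beta + 10\kappa^{-1}$ (a guard
rejects domains shorter than $\beta + 8\kappa^{-1}$, where the far-field
conditions would bias $\mu$). Neumann conditions use ghost nodes;
Dirichlet rows are scaled like interior rows to keep the tridiagonal
systems well conditioned; the sparse solves go through the Matrix
package. Box profiles (native layer, graft interval, fixed charge) are
cell-averaged onto the grid so that the discrete charge integrates to the
specified surface charge exactly, independent of grid alignment. Direct
solves leave residuals near machine precision; a residual above 1e-8
raises a solver error rather than returning a silently degraded solution.
Doubling the grid changes $\mu$ by well under 0.1%.

Validation is dual-route: an independent closed-form solution for a
uniform layer (piecewise-exponential potential and velocity, matched at
$\beta$, built on numerically bounded exponential bases) is implemented in
`mobility_two_region()` and compared with the finite-difference solver
across seeded parameter sweeps in the tests and the acceptance script.

### Fitting and an identifiability caveat

`fit_scenario()` minimises the sd-weighted SSE over a chosen free
parameter set, independently under the uniform (0–$\beta$) and outer
(2.7 nm–$\beta$) scenarios, using a fixed multi-start grid refined by
L-BFGS-B on log-magnitudes (plus a golden-section polish for
one-parameter fits), so results are deterministic. If the two scenario
SSEs differ by less than 1% the fit reports "indistinguishable" rather
than forcing a winner.

One design finding deserves emphasis. With the graft Stokes radius free,
the two depth scenarios are practically confounded: the best
uniform-scenario curve reproduces an outer-generated noiseless dataset to
within ~0.1% per point, far below realistic measurement noise, because a
deeper distribution of slightly larger segments exerts almost the same
flow-weighted drag. Scenario selection under a free radius is therefore
not meaningful at a few percent noise. Freeing the layer's surface charge
instead — the natural unknown for a given blood sample, while the graft
radius is known from the polymer's hydrodynamic characterisation — leaves
the scenario shape difference (~14% in $\mu$ at $9.5\times10^5$ grafts per
cell) intact, and scenario and charge are then recovered reliably from 2%
noise. The pipeline defaults follow this choice; the radius-free
confounding stays available to the user but is documented here as a
limitation.

## Z-stack quadrant quantification

Absolute heights cannot be compared across cells (glycocalyx thickness is
heterogeneous even around one cell), so probe location is expressed in
*fractions of the detected span*, split into four equal quadrants, Q1
basal to Q4 apical.

Rules, in order:

1. **Start.** The membrane reference is the slice with maximal within-ROI
   membrane MFI (ties to the lowest index; a flat or background-level
   profile is an error). Measurements start one slice above it.
2. **Top.** Background is the mean + `k_sigma` (default 2) standard
   deviations of the probe MFI over the top 10% of slices, with a floor
   of 1% of the profile maximum — the floor guards the rule when the top
   slices are noise-dominated near zero, where a mean-plus-SD threshold
   of almost-zero values would trip on single noisy slices. The top is
   the highest slice at or above the start that exceeds this threshold.
3. **Quadrants.** The continuous span from the bottom of the start slice
   to the top of the top slice is split into four equal sub-intervals;
   each slice's signal is apportioned by the overlap of its one-slice
   extent with each quadrant. No slice is dropped for spans not divisible
   by four, which keeps the fractions unbiased for any span length and
   makes them exactly covariant under an axial mirror.
4. **Per-slice statistic.** The default reads "median fluorescent
   intensity" literally: per-slice MFI is the median over ROI pixels and
   quadrant signal is the overlap-weighted sum of per-slice MFIs. An
   integrated-intensity mode (`mode = "integrated"`) is available; for
   laterally uniform fields the two coincide up to scale. Whether the
   original figures used medians or integrals is ambiguous, so both are
   provided and the default is documented.

Height is `(top − start + 1) × z_step` (z-step defaults to 0.2 µm);
density is integrated probe intensity over the span normalised by
integrated nuclear-stain intensity as the cell-number proxy (robust at
fixture scale; connected-component nucleus counting is available behind
`count_nuclei = TRUE`). Photobleach normalisation divides the
in-glycocalyx axial profile by a same-stack outside-glycocalyx reference
profile slice by slice; any per-slice multiplicative bleaching factor
common to both cancels exactly.

ROIs are logical masks; one result per ROI, field-level summaries average
ROIs with equal weights.

## Synthetic data: what it emulates, what it does not

`gen_zstack()` builds stacks from a known axial truth: a Gaussian
membrane-stain profile; a probe density that is uniform, outer-weighted
(`z_lo` upward) or compressed toward the membrane (factor $c$, mass
conserved); an axial Gaussian PSF; scaling by a photon gain; Poisson shot
noise; Gaussian read noise; and geometric per-slice bleaching applied to
all channels, with a constant outside-reference channel carrying the same
bleaching. Everything is deterministic under the spec seed.

`gen_collapse_series()` maps crowder dose to compression and supports the
two imaging situations separately:

* **collapse mode** emulates imaging *during* crowding (stained layer
  watched as crowder is added): the probe is compressed toward the
  membrane, so height scales by $c$ and per-slice density by $1/c$ with
  total signal conserved. This drives the height/density/FITC trends and
  the compression-recovery checks.
* **regraft mode** emulates imaging *after* grafting and washout: probe
  deposited while the layer was collapsed to a fraction $c$ rides the
  re-expansion outward and occupies the outer $c$ fraction of the
  restored span. This — not membrane-ward compression — is what produces
  the dose-dependent Q1→Q4 occupancy shift: once the quadrant span is
  re-detected per dose, a mass-conserving compression alone leaves the
  fractions unchanged, so the redistribution has to be modelled where it
  physically happens, in the grafting step.

Both modes add an after-washout stack at $c = 1$, emulating the observed
reversibility.

The generators deliberately do not emulate: lateral cell morphology or
lateral PSF (the analysis is axial; the spec-level quantity is a per-slice
statistic), instrument-specific noise beyond Poisson + Gaussian,
segmentation difficulty (ROIs are given), spectral bleed-through, or
depth-dependent aberrations. Passing round trips therefore demonstrate
that the *quantification rules* are correct and stable under realistic
axial noise — not that the pipeline is robust to segmentation error or
optical artefacts in real data.

Cytometry populations are log-normal per group, `meanlog = log(truth)`
and `sdlog = cv` (CV interpreted on the log scale), with replicate MFI
the median of the acquired events (default 10000), making the replicate
MFI an unbiased estimator of the group truth.

## Camouflage statistics

Relative protection is the percent MFI reduction against the unmodified
control, $100(1 - \mathrm{MFI}_{mod}/\mathrm{MFI}_{ctrl})$ — the standard
immunocamouflage readout; since the source figures' y-axis depends on this
definition it is stated prominently. Negative protection (binding above
control) is reported and flagged, never clipped: clipping would hide
failed grafting. Fold enhancement is the crowded/non-crowded protection
ratio; group comparisons are two-tailed Welch t-tests (delegated to
`stats::t.test`; the test suite checks them against the written-out Welch
formulas). Operations accept replicate MFIs; an event-level reducer
(median of events) is provided. Whether isotype background subtraction was
applied upstream is the caller's responsibility.

## Problem sizes and reproducibility

Desk-scale sizes are used throughout and stated here as the package's own
choices: 24×24×40-voxel stacks at 0.2 µm z-spacing (300-slice fine grids
where continuous-limit agreement is asserted), 2000-node solver grids
(400–1000 during fit sweeps, where grid error is far below measurement
noise), 20-dataset recovery sweeps at 2% noise, 10000-event cytometry
with 5 replicates. Every stochastic step takes an explicit integer seed;
pipelines rerun bit-identically under the same config and seed, and
provenance (seed, config hash, package version) is written next to every
output.

## Known limitations

* The electrokinetic model is flat-plate, linearised and steady:
  curvature (Henry/relaxation) corrections, nonlinear Poisson–Boltzmann,
  charged grafts and collapse kinetics are out of scope.
* Strong-friction screening saturates: the counterion cloud leaking past
  the layer edge keeps a small friction-independent residual mobility, so
  "infinite drag" reduces $|\mu|$ by ~95–98%, not to zero.
* The closed-form validator covers a single uniform layer; layered or
  graded profiles are validated only through grid convergence.
* Quadrant fractions depend on top detection; at very low SNR the
  background rule (even with its floor) can clip dim apical signal.
* The density ratio uses integrated nuclear intensity as a cell-number
  proxy; it is linear in staining efficiency, which therefore must be
  constant across compared conditions.
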