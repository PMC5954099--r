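# glyx

Tools for asking *where* macromolecules sit within the cell-surface
glycocalyx — and what that depth distribution does to the cell's physics
and biology.

Grafting hydrophilic polymers (e.g. hyperbranched polyglycerol, HPG) onto
cells is a standard route to immunocamouflage and cell-surface
engineering. Adding an inert macromolecular crowder during grafting
osmotically dehydrates and collapses the glycocalyx, so new grafts land on
the *outer* surface of the brush instead of being spread through it. This
package implements the quantitative machinery around that phenomenon:

* **Soft-layer electrokinetics** — a flat-plate model of a cell carrying a
  charged, hydrodynamically penetrable glycocalyx. The electrostatics obey
  the linearised Poisson–Boltzmann equation
  ψ″ = κ²ψ − ρ_fix(z)/(ε_r ε₀) with ψ′(0) = −σ_m/(ε_r ε₀) and ψ(L) = 0,
  and the electroosmotic flow at unit applied field obeys Brinkman-damped
  Stokes flow η u″ − f(z) u = −ρ_e(z) with ρ_e = −ε_r ε₀ κ² ψ, u(0) = 0,
  u′(L) = 0. The friction profile is f(z) = 6πηa·n(z) summed over native
  glycocalyx segments (thickness β = 7.8 nm by default) and neutral
  polymer grafts occupying a chosen depth interval — the whole layer
  (0–β, "uniform") or its outer part (2.7 nm–β, "outer"). The
  electrophoretic mobility is µ = −u(L) in the cell frame, so a negatively
  charged layer gives µ < 0.
* **Scenario fitting** — `fit_scenario()` fits the model to measured
  mobility vs. graft number by weighted least squares under both depth
  scenarios and selects the better one; it returns a classed object with
  `print`, `summary`, `coef`, `predict`, `plot`, `residuals` and
  `simulate` methods.
* **Confocal z-stack quantification** — quadrant analysis of axial probe
  distributions (Q1 basal … Q4 apical over the detected glycocalyx span,
  starting the slice after the membrane-stain peak), glycocalyx height and
  nuclei-normalised density under crowding, and photobleach normalisation
  of axial profiles against an outside-glycocalyx reference.
* **Immunocamouflage statistics** — relative protection
  100·(1 − MFI_modified/MFI_control), crowded-vs-non-crowded fold
  enhancement, and Welch two-sample comparisons.
* **Synthetic data** — seeded generators for multichannel image stacks
  with known axial structure (PSF, Poisson + read noise, stepwise
  bleaching), mobility datasets drawn from the electrokinetic model, and
  log-normal cytometry populations, so every stage of the pipeline is
  testable without instrument data.

## Worked example

Predict mobility under outer-directed grafting, then recover the
generating scenario from a noisy synthetic dataset:

```r
library(glyx)
el  <- electrolyte()          # 0.145 M saline, 25 C
glx <- glycocalyx_model()     # beta = 7.8 nm RBC glycocalyx

mobility_curve(glx, el, c(0, 5e5, 9.5e5), "outer", n_nodes = 800)
#>   molecules_per_cell mobility_um_cm_per_V_s
#> 1                  0                 -1.080
#> 2             500000                 -0.754
#> 3             950000                 -0.593

dat <- gen_mobility_dataset(glx, el, "outer", c(0, 3e5, 6e5, 9.5e5, 1.2e6),
                            noise_sd = 0.02, seed = 11, n_nodes = 400)
fit <- fit_scenario(dat, glx, el, free_params = "total_surface_charge",
                    n_nodes = 400)
fit
#> Soft-layer mobility fit
#>   points: 5; free parameters: total_surface_charge
#>   weighted SSE: uniform 58.66, outer 4.869
#>   selected scenario: outer
```

The native cell moves at −1.08 µm·cm/(V·s); grafting 9.5×10⁵ molecules on
the outer glycocalyx cuts the magnitude to 0.59 because the grafts add
hydrodynamic drag where the electroosmotic flow is fastest. The fit
prefers the outer scenario by a 12-fold SSE margin.

Quantify a synthetic confocal stack:

```r
st    <- gen_zstack(stack_spec(seed = 8, shot_noise = FALSE,
                               psf_sigma_z = 0, photon_gain = 100))
start <- find_membrane_reference(st) + 1L
top   <- estimate_top(st, start = start)
quadrant_fractions(st, start = start, top = top)
#> Quadrant fractions (slices 7-26, median mode):
#>   Q1 0.250  Q2 0.250  Q3 0.250  Q4 0.250
glycocalyx_height(st)
#> [1] 4
```

A uniform probe spreads evenly over the four quadrants of the 4 µm layer.

End-to-end analyses (simulate → quantify → compare) run from shipped YAML
configs, either in R via `run_pipeline()` or from a shell:

```sh
Rscript inst/cli/glyx.R run --config inst/extdata/configs/collapse.yaml
```

## Documentation

The methods vignette (`vignettes/glycocalyx-crowding.Rmd`) describes the
model assumptions, parameter defaults and units, the numerical scheme,
the quantification rules, what the synthetic generators do and do not
emulate, and known limitations.
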