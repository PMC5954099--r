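## Independent oracles and shared fixtures for the test suite.

## Welch t-test written out from the formulas (oracle for welch_compare,
## which delegates to stats::t.test).
welch_formulas <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- sum((a - mean(a))^2) / (na - 1)
  vb <- sum((b - mean(b))^2) / (nb - 1)
  se2 <- va / na + vb / nb
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

## Exact quadrant fractions of a uniform density on [lo, hi] within a span
## [0, H] split into four equal quadrants (continuous integration).
uniform_quadrants <- function(lo, hi, H) {
  edges <- seq(0, H, length.out = 5)
  ov <- pmax(0, pmin(edges[-1], hi) - pmax(edges[-5], lo))
  ov / (hi - lo)
}

## Small clean stack: uniform probe, no optics or noise.
clean_uniform_stack <- function(seed = 1, n_slices = 40, glyx_height = 4,
                                photon_gain = 100, ...) {
  gen_zstack(stack_spec(seed = seed, n_slices = n_slices,
                        glyx_height = glyx_height, photon_gain = photon_gain,
                        shot_noise = FALSE, psf_sigma_z = 0,
                        read_noise_sd = 0, ...))
}

## Default electrokinetic setup shared across tests.
ek_defaults <- function() list(glx = glycocalyx_model(), el = electrolyte())
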