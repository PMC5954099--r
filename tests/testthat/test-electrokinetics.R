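## Electrokinetic model: screening, profiles, boundary-value solves,
## scenario curves and fitting.

test_that("Debye parameter matches the closed form and its scalings", {
  k <- glyx_constants()
  el <- electrolyte(ionic_strength = 0.145, temperature = 298.15,
                    relative_permittivity = 78.5)
  ## closed form evaluated independently from CODATA constants
  kappa_expected <- sqrt(2 * k$e^2 * k$N_A * 0.145 * 1000 /
                           (78.5 * k$eps0 * k$k_B * 298.15))
  expect_equal(debye_parameter(el), kappa_expected)
  expect_equal(1e9 / debye_parameter(el), 0.80, tolerance = 0.01)

  el4 <- electrolyte(ionic_strength = 4 * 0.145)
  expect_equal(debye_parameter(el4) / debye_parameter(el), 2,
               tolerance = 1e-12)

  expect_error(electrolyte(ionic_strength = 0), class = "glyx_error")
  expect_error(electrolyte(temperature = -1), class = "glyx_error")
})

test_that("layer profiles are additive, linear in graft number, and conserve charge", {
  ek <- ek_defaults()
  native <- build_profile(ek$glx, NULL, ek$el, n_nodes = 500)

  g <- graft_distribution(9.5e5, z_lo = 2.7e-9, z_hi = 7.8e-9)
  with_g <- build_profile(ek$glx, g, ek$el, n_nodes = 500)
  inside <- with_g$grid > 2.75e-9 & with_g$grid < 7.75e-9
  outside <- with_g$grid < 2.6e-9 | with_g$grid > 7.9e-9
  expect_true(all(with_g$friction_coefficient[inside] >
                    native$friction_coefficient[inside]))
  expect_equal(with_g$friction_coefficient[outside],
               native$friction_coefficient[outside])

  g2 <- graft_distribution(2 * 9.5e5, z_lo = 2.7e-9, z_hi = 7.8e-9)
  with_g2 <- build_profile(ek$glx, g2, ek$el, n_nodes = 500)
  graft_part <- with_g$friction_coefficient - native$friction_coefficient
  graft_part2 <- with_g2$friction_coefficient - native$friction_coefficient
  expect_equal(graft_part2, 2 * graft_part, tolerance = 1e-12)

  ## fixed charge integrates exactly to the layer's surface charge
  q_int <- sum(native$fixed_charge_density * native$node_weights)
  expect_equal(q_int, ek$glx$total_surface_charge, tolerance = 1e-9)

  expect_error(
    build_profile(ek$glx,
                  graft_distribution(1e5, z_lo = 5e-9, z_hi = 9e-9), ek$el),
    class = "glyx_invalid_parameter")
  expect_error(build_profile(ek$glx, NULL, ek$el, n_nodes = 50),
               class = "glyx_invalid_parameter")
})

test_that("potential solver reproduces uncharged, thin-layer and uniform-layer solutions", {
  ek <- ek_defaults()
  eps <- ek$el$relative_permittivity * glyx_constants()$eps0
  kappa <- debye_parameter(ek$el)

  ## uncharged system: identically zero potential
  glx0 <- glycocalyx_model(total_surface_charge = 0)
  psi0 <- solve_potential(build_profile(glx0, NULL, ek$el, n_nodes = 500))
  expect_equal(max(abs(psi0)), 0)

  ## all charge compressed to a thin layer: psi(0) -> sigma / (eps kappa)
  sigma <- -0.003
  thin <- glycocalyx_model(thickness_beta = 0.02e-9,
                           segment_surface_density = 0,
                           total_surface_charge = sigma)
  prof <- build_profile(thin, NULL, ek$el, L = 12 / kappa, n_nodes = 6000)
  psi <- solve_potential(prof)
  expect_equal(psi[1], sigma / (eps * kappa), tolerance = 5e-3)

  ## uniform charged layer: piecewise-exponential closed form at every node
  an <- mobility_two_region(7.8e-9, 1e13, -2e6, ek$el)
  glx_u <- glycocalyx_model(
    thickness_beta = 7.8e-9, segment_radius_a = 1e-9,
    segment_surface_density = 1e13 * 7.8e-9 / (6 * pi * ek$el$viscosity * 1e-9),
    total_surface_charge = -2e6 * 7.8e-9)
  prof_u <- build_profile(glx_u, NULL, ek$el, n_nodes = 12000)
  psi_u <- solve_potential(prof_u)
  expect_equal(psi_u, an$psi_at(prof_u$grid),
               tolerance = 1e-6)
})

test_that("mobility solver matches the Smoluchowski limit", {
  ek <- ek_defaults()
  eps <- ek$el$relative_permittivity * glyx_constants()$eps0
  kappa <- debye_parameter(ek$el)
  zeta <- -0.025
  thin <- glycocalyx_model(thickness_beta = 0.05e-9,
                           segment_radius_a = 1e-12,
                           segment_surface_density = 0,
                           total_surface_charge = zeta * eps * kappa)
  prof <- build_profile(thin, NULL, ek$el, L = 0.05e-9 + 12 / kappa,
                        n_nodes = 4000)
  sol <- solve_mobility(prof)
  expect_true(sol$converged)
  expect_equal(sol$mobility, eps * zeta / ek$el$viscosity, tolerance = 0.005)
  expect_lt(sol$mobility, 0)   # negative charge -> negative mobility
})

test_that("strong drag inside the layer screens almost all of the flow", {
  ## the counterion cloud leaking past the layer edge keeps a small
  ## friction-independent residual, so the screen saturates near zero
  ## rather than reaching it
  ek <- ek_defaults()
  mu0 <- solve_mobility(build_profile(ek$glx, NULL, ek$el, n_nodes = 2000))$mobility
  mus <- vapply(c(1e20, 1e22), function(d) {
    dense <- glycocalyx_model(segment_surface_density = d)
    solve_mobility(build_profile(dense, NULL, ek$el, n_nodes = 2000))$mobility
  }, numeric(1))
  expect_lt(abs(mus[1]), 0.05 * abs(mu0))
  expect_lt(abs(mus[2]), abs(mus[1]) + 1e-12 * abs(mu0))
})

test_that("numeric mobility matches the closed form across a seeded sweep", {
  el <- electrolyte()
  eta <- el$viscosity
  withr::with_seed(42, {
    for (i in 1:10) {
      beta <- runif(1, 3e-9, 12e-9)
      f0 <- 10^runif(1, 11, 14.5)
      rho0 <- -10^runif(1, 4.5, 6.5)
      an <- mobility_two_region(beta, f0, rho0, el)
      a_seg <- 1e-9
      glx <- glycocalyx_model(
        thickness_beta = beta, segment_radius_a = a_seg,
        segment_surface_density = f0 * beta / (6 * pi * eta * a_seg),
        total_surface_charge = rho0 * beta)
      num <- solve_mobility(build_profile(glx, NULL, el, n_nodes = 2000))
      expect_equal(num$mobility, an$mobility, tolerance = 1e-3)
    }
  })
})

test_that("domain-length guard and grid convergence hold", {
  ek <- ek_defaults()
  kappa <- debye_parameter(ek$el)
  short <- build_profile(ek$glx, NULL, ek$el,
                         L = ek$glx$thickness_beta + 5 / kappa, n_nodes = 500)
  expect_error(solve_mobility(short), class = "glyx_invalid_parameter")

  mu1 <- solve_mobility(build_profile(ek$glx, NULL, ek$el, n_nodes = 2000))$mobility
  mu2 <- solve_mobility(build_profile(ek$glx, NULL, ek$el, n_nodes = 4000))$mobility
  expect_lt(abs(mu2 / mu1 - 1), 1e-3)
})

test_that("mobility curves are monotone and order the two scenarios", {
  ek <- ek_defaults()
  grid <- c(0, 2.5e5, 5e5, 7.5e5, 9.5e5)
  mc_u <- mobility_curve(ek$glx, ek$el, grid, "uniform", n_nodes = 800)
  mc_o <- mobility_curve(ek$glx, ek$el, grid, "outer", n_nodes = 800)

  ## zero grafting: both scenarios give the native cell
  expect_equal(mc_u$mobility[1], mc_o$mobility[1])
  ## |mu| strictly decreasing with graft number under both
  expect_true(all(diff(abs(mc_u$mobility)) < 0))
  expect_true(all(diff(abs(mc_o$mobility)) < 0))
  ## outer-directed grafts shield the flow more at equal graft number
  expect_true(all(abs(mc_o$mobility[-1]) < abs(mc_u$mobility[-1])))
})

test_that("mobility magnitude is monotone in radius and native density", {
  ek <- ek_defaults()
  mus <- vapply(c(1e-9, 2.6e-9, 5e-9), function(a)
    mobility_curve(ek$glx, ek$el, 9.5e5, "outer", graft_segment_radius = a,
                   n_nodes = 600)$mobility, numeric(1))
  expect_true(all(diff(abs(mus)) < 0))
  mus_d <- vapply(c(1e16, 3e16, 9e16), function(d) {
    glx <- glycocalyx_model(segment_surface_density = d)
    solve_mobility(build_profile(glx, NULL, ek$el, n_nodes = 600))$mobility
  }, numeric(1))
  expect_true(all(diff(abs(mus_d)) < 0))
})

test_that("fit_scenario is self-consistent on noiseless data and flags degeneracy", {
  ek <- ek_defaults()
  grid <- c(0, 3e5, 6e5, 9.5e5)
  dat <- gen_mobility_dataset(ek$glx, ek$el, "uniform", grid,
                              noise_sd = 0, seed = 1, n_nodes = 400)
  fit <- fit_scenario(dat, ek$glx, ek$el, n_nodes = 400)
  expect_equal(fit$best_scenario, "uniform")
  expect_lt(fit$sse["uniform"], 1e-10 * fit$sse["outer"] + 1e-8)

  expect_error(
    fit_scenario(dat[1, ], ek$glx, ek$el,
                 free_params = c("graft_segment_radius",
                                 "total_surface_charge")),
    class = "glyx_underdetermined")
  expect_warning(
    fit_scenario(dat[c(2, 4), ], ek$glx, ek$el,
                 free_params = c("graft_segment_radius",
                                 "total_surface_charge"),
                 n_nodes = 400),
    "under-determined")
})

test_that("fit_scenario recovers scenario and surface charge from noisy data", {
  ek <- ek_defaults()
  grid <- c(0, 3e5, 6e5, 9.5e5, 1.2e6)
  dat <- gen_mobility_dataset(ek$glx, ek$el, "outer", grid,
                              noise_sd = 0.02, seed = 7, n_nodes = 400)
  fit <- fit_scenario(dat, ek$glx, ek$el,
                      free_params = "total_surface_charge", n_nodes = 400)
  expect_equal(fit$best_scenario, "outer")
  expect_equal(fit$params$outer$total_surface_charge,
               ek$glx$total_surface_charge, tolerance = 0.1)

  ## S3 surface
  expect_named(coef(fit), "total_surface_charge")
  pred <- predict(fit, molecules = grid)
  expect_equal(nrow(pred), length(grid))
  expect_length(residuals(fit), nrow(dat))
  sims <- simulate(fit, nsim = 2, seed = 3)
  expect_identical(sims, simulate(fit, nsim = 2, seed = 3))
  s <- summary(fit)
  expect_s3_class(s, "summary.glyx_fit")
  expect_output(print(s), "scenario selected: outer")
})
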