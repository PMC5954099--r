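## Generators: determinism, mass conservation, and round-trip recovery of
## the truths they encode.

test_that("stack generation is deterministic and validates its spec", {
  sp <- stack_spec(seed = 41, photon_gain = 500, read_noise_sd = 1)
  a <- gen_zstack(sp); b <- gen_zstack(sp)
  expect_identical(a$channels, b$channels)
  c <- gen_zstack(stack_spec(seed = 42, photon_gain = 500, read_noise_sd = 1))
  expect_false(identical(a$channels$probe, c$channels$probe))

  expect_error(stack_spec(glyx_height = 10, n_slices = 20),
               class = "glyx_invalid_spec")
  expect_error(stack_spec(probe_distribution = list(type = "banana")),
               class = "glyx_invalid_spec")
  expect_error(stack_spec(probe_distribution = list(type = "compressed", c = 0)),
               class = "glyx_invalid_spec")
  expect_error(stack_spec(bleach_per_slice = 0), class = "glyx_invalid_spec")
})

test_that("noiseless compression conserves probe mass and doubles density", {
  base <- gen_zstack(stack_spec(seed = 43, shot_noise = FALSE,
                                psf_sigma_z = 0, photon_gain = 100))
  half <- gen_zstack(stack_spec(seed = 43, shot_noise = FALSE,
                                psf_sigma_z = 0, photon_gain = 100),
                     compress = 0.5)
  expect_equal(sum(half$channels$probe), sum(base$channels$probe),
               tolerance = 1e-9)
  ## per-slice intensity doubles inside the compressed support
  expect_equal(max(half$channels$probe), 2 * max(base$channels$probe),
               tolerance = 1e-9)
  ## without mass conservation the amplitude stays at the base level
  half_nc <- gen_zstack(stack_spec(seed = 43, shot_noise = FALSE,
                                   psf_sigma_z = 0, photon_gain = 100),
                        compress = 0.5, conserve_mass = FALSE)
  expect_equal(max(half_nc$channels$probe), max(base$channels$probe),
               tolerance = 1e-9)
})

test_that("generated distributions round-trip through quadrant analysis", {
  st <- gen_zstack(stack_spec(seed = 44, shot_noise = FALSE, psf_sigma_z = 0,
                              photon_gain = 100))
  start <- find_membrane_reference(st) + 1L
  top <- estimate_top(st, start = start)
  q <- quadrant_fractions(st, start = start, top = top)
  expect_equal(c(q$q1, q$q2, q$q3, q$q4), rep(0.25, 4), tolerance = 1e-12)

  ## outer at z_lo = base + 0.346 * height mirrors the 2.7/7.8 geometry
  spo <- stack_spec(n_slices = 240, z_step = 0.05, membrane_z = 1.075,
                    glyx_height = 5,
                    probe_distribution = list(type = "outer",
                                              z_lo = 1.1 + 0.34615 * 5),
                    shot_noise = FALSE, psf_sigma_z = 0, photon_gain = 100,
                    seed = 45)
  sto <- gen_zstack(spo)
  start <- find_membrane_reference(sto) + 1L
  top <- estimate_top(sto, start = start)
  qo <- quadrant_fractions(sto, start = start, top = top)
  expect_equal(c(qo$q1, qo$q2, qo$q3, qo$q4),
               uniform_quadrants(2.7, 7.8, 7.8), tolerance = 0.02)
})

test_that("collapse series obey their compression map in both modes", {
  sp <- stack_spec(seed = 46, photon_gain = 2000, read_noise_sd = 0.5,
                   psf_sigma_z = 0.1)
  cm <- c("0" = 1, "60" = 0.8, "230" = 0.5)
  doses <- c(0, 60, 230)

  cl <- gen_collapse_series(sp, doses, cm, mode = "collapse")
  h <- vapply(cl$series, function(e) glycocalyx_height(e$stack), numeric(1))
  expect_equal(h / h[1], c(1, 0.8, 0.5), tolerance = 0.1)
  expect_equal(glycocalyx_height(cl$washout), h[1], tolerance = 0.1)

  rg <- gen_collapse_series(sp, doses, cm, mode = "regraft")
  q4 <- dose_response(rg$series)$q4
  expect_true(all(diff(q4) > 0))

  expect_error(gen_collapse_series(sp, doses, c("0" = 0.5, "60" = 0.8,
                                                "230" = 1)),
               class = "glyx_invalid_spec")
  expect_error(gen_collapse_series(sp, 0, c("0" = 1)),
               class = "glyx_invalid_spec")
})

test_that("mobility datasets carry the model truth and the graft levels asked for", {
  ek <- ek_defaults()
  grid <- c(0, 5e5, 9.5e5)
  noiseless <- gen_mobility_dataset(ek$glx, ek$el, "outer", grid,
                                    noise_sd = 0, seed = 1, n_nodes = 400)
  expect_true(9.5e5 %in% noiseless$molecules_per_cell)
  mc <- mobility_curve(ek$glx, ek$el, grid, "outer", n_nodes = 400)
  expect_equal(noiseless$mobility, mc$mobility)
  expect_true(all(noiseless$sd > 0))

  noisy1 <- gen_mobility_dataset(ek$glx, ek$el, "outer", grid,
                                 noise_sd = 0.02, seed = 9, n_nodes = 400)
  noisy2 <- gen_mobility_dataset(ek$glx, ek$el, "outer", grid,
                                 noise_sd = 0.02, seed = 9, n_nodes = 400)
  expect_identical(noisy1, noisy2)
})

test_that("cytometry generator is seeded and centred on the group truths", {
  t1 <- gen_cytometry(c(control = 1000, modified = 500), cv = 0.1,
                      n_events = 2000, n_replicates = 3, seed = 5)
  t2 <- gen_cytometry(c(control = 1000, modified = 500), cv = 0.1,
                      n_events = 2000, n_replicates = 3, seed = 5)
  expect_identical(t1, t2)

  tiny_cv <- gen_cytometry(c(control = 1000), cv = 1e-4,
                           n_events = 1000, n_replicates = 2, seed = 6)
  expect_equal(tiny_cv$mfi, c(1000, 1000), tolerance = 1e-4)

  half <- gen_cytometry(c(control = 1000, modified = 500), cv = 0.1,
                        n_events = 10000, n_replicates = 5, seed = 7)
  p <- relative_protection(
    mean(half$mfi[half$group == "modified"]),
    mean(half$mfi[half$group == "control"]))
  expect_equal(as.numeric(p), 50, tolerance = 0.05)

  expect_error(gen_cytometry(c(1000), cv = 0.1), class = "glyx_invalid_spec")
  expect_error(gen_cytometry(c(a = 1000), cv = 0.1, n_events = 10),
               class = "glyx_invalid_spec")
})
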