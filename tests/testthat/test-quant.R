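## Quadrant quantification, membrane/top detection, height, density and
## photobleach normalisation.

test_that("membrane reference picks the peak slice, lowest on ties, errors when flat", {
  st <- clean_uniform_stack(seed = 2)
  ## membrane_z = 1.1 um at 0.2 um slices -> slice 6
  expect_identical(find_membrane_reference(st), 6L)

  ## tie: duplicate the peak slice intensity one slice higher
  st2 <- st
  st2$channels$membrane[, , 7] <- st2$channels$membrane[, , 6]
  expect_identical(find_membrane_reference(st2), 6L)

  st3 <- st
  st3$channels$membrane[] <- 0
  expect_error(find_membrane_reference(st3), class = "glyx_no_membrane")
})

test_that("top estimation follows the probe support and errors without signal", {
  st <- clean_uniform_stack(seed = 3)          # probe slices 7..26
  expect_identical(estimate_top(st, start = 7L), 26L)

  stc <- gen_zstack(stack_spec(seed = 3, shot_noise = FALSE, psf_sigma_z = 0,
                               probe_distribution = list(type = "compressed",
                                                         c = 0.5)))
  expect_identical(estimate_top(stc, start = 7L), 16L)

  flat <- st
  flat$channels$probe[] <- 5
  expect_error(estimate_top(flat, start = 7L), class = "glyx_no_signal")
})

test_that("quadrant fractions reproduce uniform, point-mass and outer-interval geometry", {
  st <- clean_uniform_stack(seed = 4)
  q <- quadrant_fractions(st, start = 7L, top = 26L)
  expect_equal(c(q$q1, q$q2, q$q3, q$q4), rep(0.25, 4), tolerance = 1e-12)
  expect_equal(q$q1 + q$q2 + q$q3 + q$q4, 1, tolerance = 1e-9)

  ## all signal in the top quarter
  st_top <- st
  st_top$channels$probe[] <- 0
  st_top$channels$probe[, , 22:26] <- 100
  q_top <- quadrant_fractions(st_top, start = 7L, top = 26L)
  expect_equal(c(q_top$q1, q_top$q2, q_top$q3, q_top$q4), c(0, 0, 0, 1),
               tolerance = 1e-12)

  ## uniform density over depth 2.7-7.8 nm of a 7.8 nm layer, fine grid:
  ## exact continuous integration gives (0, 0.2353, 0.3824, 0.3824)
  expected <- uniform_quadrants(2.7, 7.8, 7.8)
  sp <- stack_spec(n_slices = 300, z_step = 0.05, membrane_z = 1.075,
                   glyx_height = 7.8,
                   probe_distribution = list(type = "outer",
                                             z_lo = 22 * 0.05 + 2.7),
                   shot_noise = FALSE, psf_sigma_z = 0, photon_gain = 100,
                   seed = 5)
  stf <- gen_zstack(sp)
  start <- find_membrane_reference(stf) + 1L
  top <- estimate_top(stf, start = start)
  qf <- quadrant_fractions(stf, start = start, top = top)
  expect_equal(c(qf$q1, qf$q2, qf$q3, qf$q4), expected, tolerance = 0.02)
  expect_equal(round(expected, 4), c(0, 0.2353, 0.3824, 0.3824))

  zero <- st
  zero$channels$probe[] <- 0
  expect_error(quadrant_fractions(zero, start = 7L, top = 26L),
               class = "glyx_undefined_fraction")
  expect_error(quadrant_fractions(st, start = 10L, top = 10L),
               class = "glyx_invalid_parameter")
})

test_that("quadrant fractions are covariant under an axial mirror", {
  st <- gen_zstack(stack_spec(seed = 6, photon_gain = 500,
                              probe_distribution = list(type = "outer",
                                                        z_lo = 2.4)))
  start <- 7L; top <- estimate_top(st, start = start)
  q <- quadrant_fractions(st, start = start, top = top)

  nz <- dim(st$channels$probe)[3]
  mirrored <- st
  for (ch in names(mirrored$channels))
    mirrored$channels[[ch]] <- mirrored$channels[[ch]][, , nz:1]
  qm <- quadrant_fractions(mirrored, start = nz + 1L - top,
                           top = nz + 1L - start)
  expect_equal(c(qm$q4, qm$q3, qm$q2, qm$q1), c(q$q1, q$q2, q$q3, q$q4),
               tolerance = 1e-12)
})

test_that("inner/outer split sums the expected quadrants", {
  st <- clean_uniform_stack(seed = 7)
  q <- quadrant_fractions(st, start = 7L, top = 26L)
  io <- inner_outer_shift(q)
  expect_equal(unname(io), c(0.5, 0.5), tolerance = 1e-12)
  expect_equal(sum(io), 1, tolerance = 1e-12)

  q2 <- q
  q2$q1 <- 0; q2$q2 <- 0.2353; q2$q3 <- 0.3824; q2$q4 <- 0.3823
  io2 <- inner_outer_shift(q2)
  expect_equal(unname(io2), c(0.2353, 0.7647), tolerance = 1e-4)
})

test_that("height and density follow construction and scale linearly", {
  st <- clean_uniform_stack(seed = 8)
  expect_equal(glycocalyx_height(st), 4.0)     # 20 slices at 0.2 um

  half <- gen_zstack(stack_spec(seed = 8, shot_noise = FALSE, psf_sigma_z = 0,
                                probe_distribution = list(type = "compressed",
                                                          c = 0.5)))
  expect_equal(glycocalyx_height(half), 2.0)

  ## mass-conserving collapse leaves the density ratio unchanged
  expect_equal(density_ratio(half), density_ratio(st), tolerance = 1e-9)

  ## linearity in probe and nuclei intensity
  st_p2 <- st; st_p2$channels$probe <- st_p2$channels$probe * 2
  expect_equal(density_ratio(st_p2), 2 * density_ratio(st), tolerance = 1e-12)
  st_n2 <- st; st_n2$channels$nuclei <- st_n2$channels$nuclei * 2
  expect_equal(density_ratio(st_n2), density_ratio(st) / 2, tolerance = 1e-12)

  st_nonuc <- st; st_nonuc$channels$nuclei[] <- 0
  expect_error(density_ratio(st_nonuc), class = "glyx_no_signal")
})

test_that("photobleach normalisation cancels shared bleaching exactly", {
  k <- 1:30
  inside <- data.frame(slice_index = k, mfi = 50 + 5 * sin(k / 3))
  outside <- data.frame(slice_index = k, mfi = rep(20, 30))
  base <- photobleach_normalize(inside, outside)

  bleach <- 0.97^(k - 1)
  bleached <- photobleach_normalize(
    transform(inside, mfi = mfi * bleach),
    transform(outside, mfi = mfi * bleach))
  expect_equal(base$mfi, bleached$mfi, tolerance = 1e-14)

  same <- photobleach_normalize(outside, outside)
  expect_equal(same$mfi, rep(1, 30))

  expect_error(photobleach_normalize(inside, transform(outside, mfi = 0)),
               class = "glyx_division_guard")
  expect_error(photobleach_normalize(inside, outside[1:10, ]),
               class = "glyx_invalid_parameter")
})

test_that("dose series show the crowding trends", {
  sp <- stack_spec(seed = 21, photon_gain = 2000, read_noise_sd = 0.5,
                   psf_sigma_z = 0.1)
  cm <- c("0" = 1, "120" = 0.7, "230" = 0.45)
  doses <- c(0, 120, 230)

  rg <- gen_collapse_series(sp, doses, cm, mode = "regraft")
  dr <- dose_response(rg$series)
  expect_identical(dr$dose, doses)
  expect_true(all(diff(dr$q4) > 0))            # Q1 -> Q4 shift with dose
  expect_true(230 %in% dr$dose)

  ## replicated stack at all doses: constant rows
  st <- rg$series[[1]]$stack
  rep_series <- list(list(dose = 0, stack = st), list(dose = 230, stack = st))
  dr_rep <- dose_response(rep_series)
  expect_equal(dr_rep$q4[1], dr_rep$q4[2])

  expect_error(dose_response(rep_series[1]), class = "glyx_invalid_parameter")
})
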