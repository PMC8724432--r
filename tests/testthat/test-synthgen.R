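test_that("phantom specifications validate their inclusions", {
  bg <- bg_props()
  ok <- phantom_spec(c(44, 130, 79), bg, list(
    list(center = c(17, 45, 42), radius = 7.5, height = 10, axis = "x",
         props = optical_properties(0.012, 1))))
  expect_s3_class(ok, "phantom_spec")
  expect_error(phantom_spec(c(44, 130, 79), bg, list(
    list(center = c(17, 45, 76), radius = 7.5, height = 10, axis = "x",
         props = optical_properties(0.012, 1)))),
    class = "dotcal_spec_error") # pokes out of the slab in z
  expect_error(phantom_spec(c(44, 130, 79), bg, list(
    list(center = c(17, 45, 42), radius = 7.5, height = 10, axis = "x",
         props = optical_properties(0.002, 1)))),
    class = "dotcal_spec_error") # less absorbing than background
})

test_that("build_phantom paints the baseline targets and keeps a clean twin", {
  sc <- scenario_presets("sim_baseline")
  ph <- build_phantom(sc$phantom_spec, h = 4)
  expect_equal(sort(unique(ph$task$region)), 0:2)
  # membership at the quoted points
  w1 <- interp_matrix(ph$task, rbind(c(17, 45, 42)))
  expect_equal(as.numeric(w1 %*% ph$task$mu_a), 0.012, tolerance = 1e-9)
  w0 <- interp_matrix(ph$task, rbind(c(17, 65, 42)))
  expect_equal(as.numeric(w0 %*% ph$task$mu_a), 0.004, tolerance = 1e-9)
  expect_equal(0.012 / 0.004, 3) # 3x contrast by construction
  expect_true(all(ph$reference$mu_a == 0.004))
  # no inclusions: task and twin are identical
  ph0 <- build_phantom(phantom_spec(c(44, 60, 60), bg_props()), h = 6)
  expect_identical(ph0$task$mu_a, ph0$reference$mu_a)
  expect_identical(ph0$task$region, ph0$reference$region)
})

test_that("scenario presets encode the documented geometries", {
  sc <- scenario_presets("sim_baseline")
  expect_equal(sc$phantom_spec$slab_dims, c(44, 130, 79))
  cents <- lapply(sc$phantom_spec$inclusions, `[[`, "center")
  expect_equal(cents, list(c(17, 45, 42), c(17, 85, 42)))
  expect_equal(sc$phantom_spec$inclusions[[1]]$radius, 7.5)
  expect_equal(sc$phantom_spec$inclusions[[1]]$height, 10)
  expect_equal(sc$phantom_spec$inclusions[[1]]$props$mu_a, 0.012)
  expect_equal(sc$probe$n_rows, 3)
  expect_equal(sc$probe$n_cols, 4)
  expect_equal(scenario_presets("size_R10")$phantom_spec$inclusions[[2]]$radius, 10)
  expect_equal(scenario_presets("contrast_2x")$phantom_spec$inclusions[[1]]$props$mu_a,
               0.008)
  expect_equal(scenario_presets("system_7x8")$probe$I, 56)
  expect_error(scenario_presets("nope"), class = "dotcal_lookup")
})

test_that("simulated sessions are deterministic and cancel shared gains", {
  sp <- small_phantom()
  ds <- simulate_dataset(sp$phantom, sp$probe)
  # identity gains, no noise: task equals the forward prediction exactly
  fw <- solve_cw(sp$phantom$task, sp$probe, sp$pairs, keep_fields = FALSE)
  expect_equal(ds$task$amplitude, fw$meas$amplitude)
  expect_equal(ds$reference$amplitude, ds$predicted$amplitude)

  gm <- gain_model(sp$probe, global_scale = 2, gain_sigma = 0.2,
                   noise_sigma = 0.01, seed = 9)
  d1 <- simulate_dataset(sp$phantom, sp$probe, gains = gm, seed = 9)
  d2 <- simulate_dataset(sp$phantom, sp$probe, gains = gm, seed = 9)
  expect_identical(d1$task$amplitude, d2$task$amplitude) # bit-identical
  expect_identical(d1$manifest, d2$manifest)

  # reference calibration removes the common gains to machine precision
  gm_clean <- gain_model(sp$probe, global_scale = 2, gain_sigma = 0.2,
                         noise_sigma = 0, seed = 9)
  dg <- simulate_dataset(sp$phantom, sp$probe, gains = gm_clean, seed = 9)
  cal_g <- reference_calibrate(dg$task, dg$reference, dg$predicted)
  cal_0 <- reference_calibrate(ds$task, ds$reference, ds$predicted)
  expect_equal(cal_g$amplitude, cal_0$amplitude, tolerance = 1e-12)
})

test_that("the voxel Monte Carlo conserves energy and is reproducible", {
  spec <- phantom_spec(c(30, 52, 42), bg_props())
  probe <- build_probe(1, 2, 13, 14, 30, center = c(26, 21))
  mc <- voxel_monte_carlo(spec, probe, n_photons = 1e4, seed = 42,
                          aperture_radius = 6, error_on_empty = FALSE)
  eb <- attr(mc, "energy_balance")
  total <- eb$absorbed + eb$transmitted + eb$reflected + eb$side_exit +
    eb$roulette_net
  expect_lt(abs(total - eb$launched) / eb$launched, 1e-6)
  mc2 <- voxel_monte_carlo(spec, probe, n_photons = 1e4, seed = 42,
                           aperture_radius = 6, error_on_empty = FALSE)
  expect_identical(mc$amplitude, mc2$amplitude)
  expect_error(voxel_monte_carlo(spec, probe, n_photons = 100),
               class = "dotcal_invalid_input")
})

test_that("Monte Carlo standard errors shrink like one over root N", {
  spec <- phantom_spec(c(30, 52, 42), bg_props())
  probe <- build_probe(1, 2, 13, 14, 30, center = c(26, 21))
  se_mean <- function(n, seed) {
    mc <- voxel_monte_carlo(spec, probe, n_photons = n, seed = seed,
                            aperture_radius = 6, error_on_empty = FALSE)
    mean(attr(mc, "standard_error"))
  }
  # average the ratio over a few seeds to tame sampling noise
  ratios <- vapply(1:3, function(s) se_mean(2e4, s) / se_mean(8e4, s + 10),
                   numeric(1))
  expect_equal(mean(ratios), 2, tolerance = 0.25) # 4x photons -> half the SE
})

test_that("Monte Carlo transmission agrees with the analytic slab within error bars", {
  spec <- phantom_spec(c(30, 52, 42), bg_props())
  probe <- build_probe(2, 2, 13, 14, 30, center = c(26, 21))
  pairs <- enumerate_pairs(probe)
  mc <- voxel_monte_carlo(spec, probe, n_photons = 1.2e5, seed = 17,
                          aperture_radius = 5)
  an <- analytic_slab_flux(bg_props(), probe, pairs)
  cl <- group_by_distance(pairs)
  near <- cl[[1]]$members # 4 mirror pairs at 30 mm
  far <- cl[[length(cl)]]$members # 4 diagonal pairs
  r_mc <- mean(mc$amplitude[near]) / mean(mc$amplitude[far])
  r_an <- mean(an$amplitude[near]) / mean(an$amplitude[far])
  se <- attr(mc, "standard_error")
  rel <- r_mc * sqrt(sum(se[near]^2) / sum(mc$amplitude[near])^2 +
                     sum(se[far]^2) / sum(mc$amplitude[far])^2)
  expect_lt(abs(r_mc - r_an), 3 * rel)
})

test_that("phantom YAML specs round-trip", {
  sc <- scenario_presets("size_R5")
  f <- tempfile(fileext = ".yaml")
  write_phantom_yaml(sc$phantom_spec, f)
  back <- read_phantom_yaml(f)
  expect_equal(back$slab_dims, sc$phantom_spec$slab_dims)
  expect_equal(back$inclusions[[1]]$radius, 5)
  expect_equal(back$background$mu_a, 0.004)
})
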