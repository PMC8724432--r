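test_that("build_probe produces mirrored grids with the expected counts", {
  p <- build_probe(7, 8, 13, 14, 44)
  expect_equal(p$I, 56)
  expect_equal(p$J, 56)
  expect_true(all(p$source_positions[, 1] == 0))
  expect_true(all(p$detector_positions[, 1] == 44))
  # detector k mirrors source k: same (y, z)
  expect_equal(p$source_positions[, 2:3], p$detector_positions[, 2:3])

  p34 <- build_probe(3, 4, 13, 14, 44)
  expect_equal(nrow(enumerate_pairs(p34)), 144)

  p1 <- build_probe(1, 1, 13, 14, 44)
  pr1 <- enumerate_pairs(p1)
  expect_equal(nrow(pr1), 1)
  expect_equal(pr1$distance, 44)

  expect_error(build_probe(0, 4, 13, 14, 44), class = "dotcal_invalid_geometry")
  expect_error(build_probe(3, 4, -13, 14, 44), class = "dotcal_invalid_geometry")
})

test_that("enumerate_pairs computes Euclidean distances in source-major order", {
  p <- build_probe(2, 2, 13, 14, 44)
  pr <- enumerate_pairs(p)
  # source 1 at (0,0,0); detector 4 at (44,13,14)
  expect_equal(pr$distance[pr$source_index == 1 & pr$detector_index == 4],
               sqrt(2301))
  expect_equal(pr$distance[pr$source_index == 1 & pr$detector_index == 1], 44)
  expect_equal(pr$source_index, rep(1:4, each = 4))
  expect_equal(pr$detector_index, rep(1:4, times = 4))
  # mirror symmetry: exchanging source and detector leaves distances unchanged
  D <- matrix(pr$distance, 4, 4, byrow = TRUE)
  expect_equal(D, t(D))
})

test_that("the simulation layout has no over-distance pairs and K = 12 classes", {
  p <- build_probe(3, 4, 13, 14, 44)
  pr <- enumerate_pairs(p)
  # brute-force oracle, independent of the package's grouping path
  dy <- outer(rep(0:2 * 13, each = 4), rep(0:2 * 13, each = 4), "-")
  dz <- outer(rep(0:3 * 14, times = 3), rep(0:3 * 14, times = 3), "-")
  d2 <- 44^2 + dy^2 + dz^2
  expect_equal(sort(pr$distance), sort(sqrt(as.vector(d2))))
  expect_lt(max(pr$distance), 110)
  expect_equal(max(pr$distance), sqrt(1936 + 676 + 1764))

  cl <- group_by_distance(pr)
  expect_s3_class(cl, "distance_classes")
  expect_length(cl, length(unique(round(as.vector(d2), 6))))
  expect_length(cl, 12)
  expect_equal(sum(vapply(cl, function(x) length(x$members), integer(1))), 144)
  dks <- vapply(cl, `[[`, numeric(1), "d_k")
  expect_equal(dks, sort(dks))
  expect_sd_pairs_partition(cl, pr)
})

test_that("the full 7x8 layout yields 56 distance classes", {
  pr <- enumerate_pairs(build_probe(7, 8, 13, 14, 44))
  expect_length(group_by_distance(pr), 56)
})

test_that("distance grouping is stable under sub-tolerance coordinate jitter", {
  p <- build_probe(3, 4, 13, 14, 44)
  pr <- enumerate_pairs(p)
  prj <- pr
  prj$distance <- sqrt(pr$distance^2 + 1e-8) # < 1e-6 mm^2 key tolerance
  part <- function(cl) lapply(cl, `[[`, "members")
  expect_identical(part(group_by_distance(pr)), part(group_by_distance(prj)))
  # single pair: one singleton class
  expect_length(group_by_distance(enumerate_pairs(build_probe(1, 1, 13, 14, 44))), 1)
})

test_that("apply_exclusions flags over-distance and uncovered pairs", {
  p <- build_probe(7, 8, 13, 14, 44)
  pr <- enumerate_pairs(p)
  ex <- apply_exclusions(pr, max_distance = 110)
  expect_identical(ex$excluded, pr$distance > 110) # brute-force oracle
  expect_gt(sum(ex$excluded), 0) # corner-to-corner = sqrt(17624) > 110
  expect_true(all(ex$reason[ex$excluded] == "over_max_distance"))
  expect_identical(ex$source_index, pr$source_index) # order preserved

  ex_inf <- apply_exclusions(pr, max_distance = Inf)
  expect_false(any(ex_inf$excluded))

  cov <- list(sources = c(FALSE, rep(TRUE, 55)), detectors = rep(TRUE, 56))
  ex_cov <- apply_exclusions(pr, coverage = cov, max_distance = Inf)
  expect_identical(which(ex_cov$excluded), which(pr$source_index == 1))
  expect_true(all(ex_cov$reason[ex_cov$excluded] == "uncovered"))

  expect_error(apply_exclusions(pr, coverage = list(sources = TRUE,
                                                    detectors = rep(TRUE, 56))),
               class = "dotcal_invalid_input")
})

test_that("ring peeling keeps homogeneous data intact and removes perturbed rims", {
  # translation-invariant analytic data: every class is constant
  fx <- analytic_sim_task()
  sel <- select_non_boundary(fx$probe, fx$pairs, fx$task)
  expect_equal(nrow(sel$report), 1)
  expect_equal(sum(!sel$pairs$excluded), 144)
  expect_equal(sel$report$max_cov, 0)

  # halve the outermost-ring amplitudes of a 5x6 grid: one peel recovers
  probe <- build_probe(5, 6, 13, 14, 44)
  pr <- enumerate_pairs(probe)
  an <- analytic_slab_flux(bg_props(), probe, pr)
  amp <- an$amplitude
  ring <- probe$row %in% c(1, 5) | probe$col %in% c(1, 6)
  hit <- ring[pr$source_index] | ring[pr$detector_index]
  amp[hit] <- amp[hit] * 0.5
  task <- measurement_set(pr, amp, role = "task")
  sel2 <- select_non_boundary(probe, pr, task, cov_threshold = 0.3)
  expect_equal(nrow(sel2$report), 2)
  expect_equal(sum(!sel2$pairs$excluded), 144) # 3x4 core remains
  expect_true(all(diff(sel2$report$max_cov) < 0)) # peeling monotonicity
  expect_true(all(sel2$pairs$reason[sel2$pairs$excluded] == "boundary"))
  cl <- attach_measurements(group_by_distance(sel2$pairs), task)
  expect_true(all(vapply(cl, `[[`, numeric(1), "cov") <= 0.3, na.rm = TRUE))

  # unreachable threshold on noisy data: selection failure
  set.seed(4)
  noisy <- measurement_set(pr, an$amplitude * exp(rnorm(nrow(pr), 0, 0.2)),
                           role = "task")
  expect_error(select_non_boundary(probe, pr, noisy, cov_threshold = 0),
               class = "dotcal_selection_failure")
})

test_that("probe configs and exclusion reports round-trip through files", {
  p <- build_probe(3, 4, 13, 14, 44, center = c(65, 39.5))
  f <- tempfile(fileext = ".yaml")
  write_probe_config(p, f, coverage = list(sources = rep(TRUE, 12),
                                           detectors = c(rep(TRUE, 11), FALSE)))
  back <- read_probe_config(f)
  expect_equal(back$probe$source_positions, p$source_positions)
  expect_false(back$coverage$detectors[12])

  fj <- tempfile(fileext = ".json")
  write_probe_config(p, fj)
  expect_equal(read_probe_config(fj)$probe$detector_positions,
               p$detector_positions)

  pr <- apply_exclusions(enumerate_pairs(p), max_distance = 50)
  fr <- tempfile(fileext = ".csv")
  write_exclusion_report(pr, fr)
  rep <- read.csv(fr)
  expect_equal(nrow(rep), 144)
  expect_equal(sum(rep$excluded), sum(pr$excluded))
})
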