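test_that("the adjoint Jacobian matches finite differences of the forward model", {
  s <- small_setup()
  fw <- solve_cw(s$mesh, s$probe, s$pairs)
  jac <- compute_jacobian(s$mesh, s$probe, s$pairs, forward = fw)
  # non-positive up to discrete-maximum-principle noise
  expect_lt(max(jac$J), 5e-3 * max(abs(jac$J)))
  # finite-difference oracle at interior nodes
  int <- which(s$mesh$nodes[, 1] > 10 & s$mesh$nodes[, 1] < 34 &
               s$mesh$nodes[, 2] > 15 & s$mesh$nodes[, 2] < 40 &
               s$mesh$nodes[, 3] > 12 & s$mesh$nodes[, 3] < 30)
  set.seed(5)
  for (n in sample(int, 3)) {
    m2 <- s$mesh
    eps <- m2$mu_a[n] * 0.01
    m2$mu_a[n] <- m2$mu_a[n] + eps
    fw2 <- solve_cw(m2, s$probe, s$pairs, keep_fields = FALSE)
    fd <- (log(fw2$meas$amplitude) - log(fw$meas$amplitude)) / eps
    expect_lt(max(abs(jac$J[, n] - fd) / pmax(abs(fd), 1e-9)), 0.10)
  }
  # the most sensitive node of any pair lies strictly inside the slab
  for (p in c(1, 6, 16)) {
    nmax <- which.max(abs(jac$J[p, ]))
    expect_gt(s$mesh$nodes[nmax, 1], 0)
    expect_lt(s$mesh$nodes[nmax, 1], 44)
  }
})

test_that("one Gauss-Newton step equals the dense regularized normal-equation solution", {
  s <- small_setup()
  fw <- solve_cw(s$mesh, s$probe, s$pairs)
  # perturbed data around the background prediction
  set.seed(6)
  target <- fw$meas$amplitude * exp(rnorm(16, 0, 0.05))
  cal <- measurement_set(s$pairs, target, role = "calibrated")
  st <- recon_settings(n_iterations = 1)
  im <- reconstruct_absorption(cal, s$mesh, s$probe, st)
  # dense oracle in model space: (J'J + a I)^-1 J' r
  jac <- compute_jacobian(s$mesh, s$probe, s$pairs, forward = fw)
  r <- log(target) - log(fw$meas$amplitude)
  a <- st$regularization_lambda * max(colSums(jac$J^2))
  delta <- solve(crossprod(jac$J) + diag(a, ncol(jac$J)), crossprod(jac$J, r))
  expect_equal(im$mu_a, pmax(s$mesh$mu_a + as.numeric(delta), st$mu_a_floor),
               tolerance = 1e-6)
})

test_that("consistent data produce a zero update; huge lambda freezes the background", {
  s <- small_setup()
  fw <- solve_cw(s$mesh, s$probe, s$pairs, keep_fields = FALSE)
  cal <- measurement_set(s$pairs, fw$meas$amplitude, role = "calibrated")
  # at machine-precision residuals the early-stop guard fires: expected
  suppressWarnings(
    im <- reconstruct_absorption(cal, s$mesh, s$probe,
                                 recon_settings(n_iterations = 2)))
  expect_equal(im$mu_a, rep(0.004, length(im$mu_a)), tolerance = 1e-10)

  set.seed(7)
  noisy <- measurement_set(s$pairs, fw$meas$amplitude * exp(rnorm(16, 0, 0.1)),
                           role = "calibrated")
  im_stiff <- reconstruct_absorption(noisy, s$mesh, s$probe,
                                     recon_settings(regularization_lambda = 1e12,
                                                    n_iterations = 1))
  expect_equal(im_stiff$mu_a, rep(0.004, length(im_stiff$mu_a)),
               tolerance = 1e-6)
})

test_that("a coarse two-target reconstruction recovers plausible targets", {
  sp <- small_phantom()
  ds <- simulate_dataset(sp$phantom, sp$probe)
  cal <- reference_calibrate(ds$task, ds$reference, ds$predicted)
  im <- reconstruct_absorption(cal, sp$phantom$reference, sp$probe,
                               recon_settings())
  # residual non-increasing over accepted iterations
  expect_true(all(diff(im$iteration_history$residual_norm) <= 1e-10))
  # recovered peak lies strictly between background and the true contrast
  pk <- target_peak_ratio(im, split_y = 40)
  expect_gt(pk$peak1, 0.004)
  expect_lt(pk$peak1, 0.012)
  # centroids of the above-half-max region land within a target radius
  for (half in list(c(0, 40), c(40, 80))) {
    sel <- im$mesh$nodes[, 2] > half[1] & im$mesh$nodes[, 2] <= half[2]
    mu <- im$mu_a[sel]
    hot <- mu > 0.004 + (max(mu) - 0.004) / 2
    cen <- colMeans(im$mesh$nodes[sel, , drop = FALSE][hot, , drop = FALSE])
    truth <- if (half[1] == 0) c(17, 25, 30) else c(17, 55, 30)
    expect_lt(sqrt(sum((cen - truth)^2)), 7.5)
  }
})

test_that("line-profile metrics handle analytic profiles", {
  op <- bg_props()
  mesh <- slab_mesh(c(20, 100, 40), h = 2, op)
  # two equal Gaussian bumps: ratio exactly 1, FWHM = 2 sqrt(2 ln 2) sigma
  sig <- 6
  mu <- 0.004 + 0.006 * (exp(-((mesh$nodes[, 2] - 30)^2) / (2 * sig^2)) +
                         exp(-((mesh$nodes[, 2] - 70)^2) / (2 * sig^2)))
  im <- structure(list(mu_a = mu, mesh = mesh), class = "absorption_image")
  m <- line_profile_metrics(im, line = list(x = 10, z = 20))
  expect_equal(m$contrast_ratio, 1, tolerance = 1e-6)
  expect_equal(m$peaks$fwhm, rep(2 * sqrt(2 * log(2)) * sig, 2),
               tolerance = 0.02)
  expect_equal(m$peaks$y, c(30, 70), tolerance = 0.26)

  # rectangular bump of width 15 on a flat background
  mu2 <- ifelse(abs(mesh$nodes[, 2] - 50) <= 7.5, 0.012, 0.004)
  im2 <- structure(list(mu_a = mu2, mesh = mesh), class = "absorption_image")
  m2 <- line_profile_metrics(im2, line = list(x = 10, z = 20), n_targets = 1)
  expect_equal(m2$peaks$fwhm, 15, tolerance = 1)

  # flat image: no peaks to report
  im3 <- structure(list(mu_a = rep(0.004, nrow(mesh$nodes)), mesh = mesh),
                   class = "absorption_image")
  expect_error(line_profile_metrics(im3, line = list(x = 10, z = 20)),
               class = "dotcal_metric_failure")
})

test_that("absorption images export to NIfTI and profiles to CSV", {
  sp <- small_phantom()
  mesh <- sp$phantom$task
  im <- structure(list(mu_a = mesh$mu_a, mesh = mesh),
                  class = "absorption_image")
  f <- tempfile(fileext = ".nii.gz")
  write_absorption_nifti(im, f, voxel = 2)
  vol <- RNifti::readNifti(f)
  expect_equal(dim(vol), c(23, 41, 31))
  expect_equal(max(vol), 0.012, tolerance = 1e-6)
  m <- line_profile_metrics(im, line = list(x = 17, z = 30))
  fp <- tempfile(fileext = ".csv")
  write_profile_csv(m, fp)
  expect_equal(read.csv(fp)$mu_a, m$profile$mu_a)
})
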