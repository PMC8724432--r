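test_that("reference calibration is an exact ratio operator", {
  fx <- analytic_sim_task()
  task <- fx$task
  # task == reference: calibrated equals the prediction exactly
  ref <- task; attr(ref, "role") <- "reference"
  cal <- reference_calibrate(task, ref, fx$predicted)
  expect_equal(cal$amplitude, fx$predicted$amplitude)
  expect_identical(attr(cal, "role"), "calibrated")
  # task = 2 x reference: calibrated = 2 x prediction
  t2 <- task; t2$amplitude <- 2 * task$amplitude
  expect_equal(reference_calibrate(t2, ref, fx$predicted)$amplitude,
               2 * fx$predicted$amplitude)
})

test_that("per-channel gains common to task and reference cancel exactly", {
  fx <- analytic_sim_task()
  probe <- fx$probe
  set.seed(11)
  gm <- gain_model(probe, global_scale = 3.7, gain_sigma = 0.3, seed = 11)
  g <- gm$global_scale * gm$source_gains[fx$pairs$source_index] *
    gm$detector_gains[fx$pairs$detector_index]
  task_g <- fx$task; task_g$amplitude <- fx$task$amplitude * g * 1.23
  ref_g <- fx$task; ref_g$amplitude <- fx$task$amplitude * g
  attr(ref_g, "role") <- "reference"
  cal <- reference_calibrate(task_g, ref_g, fx$predicted)
  expect_equal(cal$amplitude, 1.23 * fx$predicted$amplitude, tolerance = 1e-12)
})

test_that("division hazards and misaligned sets are rejected", {
  fx <- analytic_sim_task()
  zero_ref <- fx$task
  zero_ref$amplitude[5] <- 0
  attr(zero_ref, "role") <- "reference"
  err <- tryCatch(reference_calibrate(fx$task, zero_ref, fx$predicted),
                  error = identity)
  expect_s3_class(err, "dotcal_division_hazard")
  expect_match(conditionMessage(err), "s1,d5") # names the offending pair

  other <- fx$task[c(2:144, 1), ]
  class(other) <- class(fx$task)
  attr(other, "role") <- "reference"
  attr(other, "probe") <- fx$probe
  expect_error(reference_calibrate(fx$task, other, fx$predicted),
               class = "dotcal_invalid_input")
})

test_that("the virtual reference is the per-class maximum, idempotent and dominant", {
  fx <- analytic_sim_task()
  pr <- fx$pairs
  set.seed(21)
  amp <- fx$task$amplitude * runif(nrow(pr), 0.6, 1)
  task <- measurement_set(pr, amp, role = "task")
  classes <- group_by_distance(pr)
  est <- build_virtual_reference(task, classes)
  expect_identical(attr(est, "role"), "estimated")
  # dominance, and least-upper-bound per class by brute force
  expect_true(all(est$amplitude >= task$amplitude))
  for (cl in classes) {
    vals <- est$amplitude[cl$members]
    expect_equal(diff(range(vals)), 0) # class-constant
    expect_equal(vals[1], max(amp[cl$members]))
  }
  # idempotence
  est2 <- build_virtual_reference(
    measurement_set(pr, est$amplitude, role = "task"), classes)
  expect_equal(est2$amplitude, est$amplitude)
  # worked example: {1.0, 0.8, 0.9} inside a single distance class
  # (3x1 grid with sub-tolerance row spacing: all 9 pairs share one class)
  p1 <- enumerate_pairs(build_probe(3, 1, 1e-5, 14, 44))
  toy <- measurement_set(p1, c(1.0, 0.8, 0.9, rep(0.8, 6)), role = "task")
  expect_equal(build_virtual_reference(toy)$amplitude, rep(1, 9))
})

test_that("homogeneous noiseless data make self- and reference calibration coincide", {
  fx <- analytic_sim_task()
  est <- build_virtual_reference(fx$task, fx$classes)
  expect_equal(est$amplitude, fx$task$amplitude) # every member is the max
  cal_self <- self_calibrate(fx$task, est, fx$predicted)
  expect_equal(cal_self$amplitude, fx$predicted$amplitude)
  ref <- fx$task; attr(ref, "role") <- "reference"
  cal_ref <- reference_calibrate(fx$task, ref, fx$predicted)
  expect_equal(cal_self$amplitude, cal_ref$amplitude)
})

test_that("self-calibration is globally scale invariant and bounded by the prediction", {
  fx <- analytic_sim_task()
  set.seed(31)
  amp <- fx$task$amplitude * runif(144, 0.5, 1)
  task <- measurement_set(fx$pairs, amp, role = "task")
  cal <- self_calibrate(task, predicted = fx$predicted)
  expect_true(all(cal$amplitude <= fx$predicted$amplitude + 1e-15))
  for (c_ in c(0.01, 7.5)) {
    scaled <- task; scaled$amplitude <- c_ * task$amplitude
    expect_equal(self_calibrate(scaled, predicted = fx$predicted)$amplitude,
                 cal$amplitude, tolerance = 1e-12)
  }
})

test_that("two-target data self-calibrate strictly below the prediction on crossing pairs", {
  sp <- small_phantom()
  ds <- simulate_dataset(sp$phantom, sp$probe)
  cal <- self_calibrate(ds$task, predicted = ds$predicted)
  expect_true(all(cal$amplitude <= ds$predicted$amplitude * (1 + 1e-12)))
  # mirror pairs over a target center see it head-on: strict suppression
  src_y <- sp$probe$source_positions[ds$pairs$source_index, 2]
  head_on <- ds$pairs$source_index == ds$pairs$detector_index &
    abs(src_y - 25) < 14
  expect_true(any(head_on))
  expect_true(all(cal$amplitude[head_on] < ds$predicted$amplitude[head_on]))
})

test_that("mean relative error matches hand-computable cases", {
  fx <- analytic_sim_task()
  ref <- fx$task; attr(ref, "role") <- "reference"
  expect_equal(mean_relative_error(fx$task, ref)$overall, 0)
  est <- fx$task; est$amplitude <- 0.9 * est$amplitude
  err <- mean_relative_error(est, ref, classes = fx$classes)
  expect_equal(err$overall, 0.10)
  expect_equal(err$per_class$error, rep(0.10, 12))
  expect_equal(err$n_pairs, 144)
})

test_that("calibration reports serialize the class table and overall error", {
  fx <- analytic_sim_task()
  f <- tempfile(fileext = ".json")
  ref <- fx$task; attr(ref, "role") <- "reference"
  rep <- calibration_report(fx$task, reference = ref, path = f)
  expect_equal(nrow(rep$classes), 12)
  expect_equal(rep$overall_error, 0)
  expect_equal(rep$n_retained, 144)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$classes$n, rep$classes$n)
})
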