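#' Reconstruction settings
#'
#' @param regularization_lambda dimensionless Tikhonov parameter; at
#'   each Gauss-Newton iteration the normal equations are damped by
#'   `lambda * max(diag(J'J))`, which makes the conventional "fixed
#'   lambda of 10" meaningful across mesh resolutions
#' @param n_iterations number of Gauss-Newton iterations (default 6)
#' @param data_transform `"log_amplitude"` (Rytov-style residuals,
#'   default: CW amplitudes span decades across SD distances) or
#'   `"linear"`
#' @param background_props optional `optical_properties` initial guess;
#'   defaults to the mesh background
#' @param mu_a_floor lower clamp for the reconstructed absorption
#' @return a `recon_settings` object
#' @export
recon_settings <- function(regularization_lambda = 10, n_iterations = 6,
                           data_transform = c("log_amplitude", "linear"),
                           background_props = NULL, mu_a_floor = 1e-6) {
  if (regularization_lambda <= 0)
    dc_stop("dotcal_invalid_input", "regularization_lambda must be > 0")
  if (n_iterations < 1)
    dc_stop("dotcal_invalid_input", "n_iterations must be >= 1")
  structure(list(regularization_lambda = regularization_lambda,
                 n_iterations = n_iterations,
                 data_transform = match.arg(data_transform),
                 background_props = background_props,
                 mu_a_floor = mu_a_floor),
            class = "recon_settings")
}

# element <-> node incidence (elems x nodes, 4 entries of 1 per row)
elem_node_incidence <- function(mesh) {
  m <- nrow(mesh$elems)
  Matrix::sparseMatrix(i = rep(seq_len(m), 4), j = as.vector(mesh$elems),
                       x = 1, dims = c(m, nrow(mesh$nodes)))
}

#' Absorption sensitivity matrix (adjoint Jacobian)
#'
#' Entry (p, n) is the derivative of the log (or linear) amplitude of
#' pair p with respect to the nodal absorption `mu_a[n]`, computed by
#' the adjoint method: the product of the source field and the
#' reciprocal detector field, integrated with the exact P1 element mass
#' so that the matrix is the exact derivative of the discrete forward
#' model (up to linearization). Entries are non-positive (increasing
#' absorption cannot increase a CW amplitude) up to tiny
#' discrete-maximum-principle violations of the P1 discretization on
#' coarse meshes, which vanish under refinement.
#'
#' @param mesh the `slab_mesh` at the current absorption estimate
#' @param probe the `probe_array`
#' @param pairs `sd_pairs` rows to differentiate (typically the retained
#'   set)
#' @param forward optional `cw_forward` from [solve_cw()] on the same
#'   mesh/pairs (with `keep_fields = TRUE`); recomputed when missing
#' @param transform `"log_amplitude"` or `"linear"`
#' @return a list with `J` (pairs x nodes dense matrix), `amplitude`
#'   (model amplitudes for the pairs) and the `forward` solution used
#' @export
compute_jacobian <- function(mesh, probe, pairs, forward = NULL,
                             transform = c("log_amplitude", "linear")) {
  transform <- match.arg(transform)
  if (is.null(forward))
    forward <- solve_cw(mesh, probe, pairs, keep_fields = TRUE)
  if (is.null(forward$Phi))
    dc_stop("dotcal_invalid_input", "forward solution lacks fields; rerun solve_cw(keep_fields = TRUE)")
  sys <- forward$system
  dets <- sort(unique(pairs$detector_index))
  U <- detector_vectors(mesh, probe$detector_positions[dets, , drop = FALSE])
  Psi <- as.matrix(Matrix::solve(sys$factor, U))
  C <- elem_node_incidence(mesh)
  SPhi <- as.matrix(C %*% forward$Phi) # per-element sums of the source fields
  SPsi <- as.matrix(C %*% Psi)
  Vw <- mesh$elem_volume / 80 # (V/20) * (1/4 per node of the element)
  gam <- forward$meas$amplitude
  np <- nrow(pairs)
  J <- matrix(0, np, nrow(mesh$nodes))
  for (p in seq_len(np)) {
    s <- match(pairs$source_index[p], forward$active_sources)
    d <- match(pairs$detector_index[p], dets)
    cross <- as.numeric(C %*% (forward$Phi[, s] * Psi[, d]))
    w <- Vw * (SPhi[, s] * SPsi[, d] + cross)
    J[p, ] <- -as.numeric(Matrix::crossprod(C, w)) / (2 * sys$zeta)
  }
  if (transform == "log_amplitude") J <- J / gam
  list(J = J, amplitude = gam, forward = forward)
}

#' Tikhonov-regularized Gauss-Newton absorption reconstruction
#'
#' Iteratively fits the nodal absorption map to calibrated amplitudes.
#' Each iteration solves the damped normal equations
#' \deqn{(J^T J + \lambda\,\max(diag(J^T J))\, I)\,\delta = J^T r}
#' in data space (the two forms are algebraically identical and the
#' data-space system is tiny), updates the nodal \eqn{\mu_a}, and
#' re-solves the forward model; the Jacobian is recomputed at every
#' iteration (full Gauss-Newton). If the data residual increases on two
#' consecutive iterations the loop stops early with a warning and the
#' best iterate is returned.
#'
#' @param calibrated a `measurement_set` with role `"calibrated"` (or
#'   any set of positive amplitudes on the retained pairs)
#' @param mesh the reconstruction `slab_mesh`; its background properties
#'   are the initial homogeneous guess unless overridden in `settings`
#' @param probe the `probe_array`
#' @param settings a [recon_settings()] object
#' @return an object of class `absorption_image`: nodal `mu_a`,
#'   `wavelength`, `iteration_history` (data frame of residual norms),
#'   `settings`, and the `mesh` it lives on
#' @export
reconstruct_absorption <- function(calibrated, mesh, probe,
                                   settings = recon_settings()) {
  stopifnot(inherits(calibrated, "measurement_set"),
            inherits(settings, "recon_settings"))
  r_idx <- which(!calibrated$excluded)
  if (!length(r_idx)) dc_stop("dotcal_no_data", "no retained pairs to reconstruct from")
  amp <- calibrated$amplitude[r_idx]
  if (any(amp <= 0))
    dc_stop("dotcal_invalid_input", "calibrated amplitudes must be positive on retained pairs")
  pr <- pairs_of(calibrated)[r_idx, , drop = FALSE]
  class(pr) <- c("sd_pairs", "data.frame")
  attr(pr, "probe") <- attr(calibrated, "probe")

  wrk <- mesh
  bg <- settings$background_props
  if (!is.null(bg)) {
    wrk$mu_a <- rep(bg$mu_a, nrow(mesh$nodes))
    wrk$mu_s_prime <- rep(bg$mu_s_prime, nrow(mesh$nodes))
    wrk$props_background <- bg
  } else {
    wrk$mu_a <- rep(mesh$props_background$mu_a, nrow(mesh$nodes))
  }
  logt <- settings$data_transform == "log_amplitude"
  y <- if (logt) log(amp) else amp

  tpl <- NULL
  best <- list(mu_a = wrk$mu_a, res = Inf)
  hist <- NULL
  n_up <- 0L
  # iteration 0 evaluates the initial guess; each subsequent pass applies
  # one damped Gauss-Newton update and re-evaluates the data residual
  for (it in 0:settings$n_iterations) {
    fw <- solve_cw(wrk, probe, pr, keep_fields = TRUE, template = tpl)
    tpl <- fw$system
    model <- if (logt) log(fw$meas$amplitude) else fw$meas$amplitude
    res <- y - model
    rn <- sqrt(sum(res^2))
    hist <- rbind(hist, data.frame(iteration = it, residual_norm = rn))
    if (rn < best$res) {
      best <- list(mu_a = wrk$mu_a, res = rn)
      n_up <- 0L
    } else {
      n_up <- n_up + 1L
      if (n_up >= 2L) {
        warning("data residual increased on two consecutive iterations; stopping early")
        break
      }
    }
    if (it == settings$n_iterations) break
    jac <- compute_jacobian(wrk, probe, pr, forward = fw,
                            transform = settings$data_transform)
    J <- jac$J
    alpha <- settings$regularization_lambda * max(colSums(J^2))
    JJt <- tcrossprod(J)
    diag(JJt) <- diag(JJt) + alpha
    delta <- as.numeric(crossprod(J, solve(JJt, res)))
    wrk$mu_a <- pmax(wrk$mu_a + delta, settings$mu_a_floor)
  }
  structure(list(mu_a = best$mu_a, wavelength = attr(calibrated, "wavelength"),
                 iteration_history = hist, settings = settings, mesh = mesh),
            class = "absorption_image")
}

#' @export
print.absorption_image <- function(x, ...) {
  cat(sprintf(
    "absorption_image: %d nodes, mu_a in [%.5g, %.5g] /mm, %d iterations (final residual %.4g)\n",
    length(x$mu_a), min(x$mu_a), max(x$mu_a),
    nrow(x$iteration_history), tail(x$iteration_history$residual_norm, 1)
  ))
  invisible(x)
}

#' Line-profile metrics: peaks, FWHM, contrast ratio
#'
#' Interpolates the reconstructed absorption onto a line along y at
#' fixed (x, z), locates the target peaks, and measures each target's
#' full width at half maximum above background: the background level is
#' the median of the profile away from the peaks, the half-maximum is
#' background + (peak - background)/2, and crossings are found by
#' linear interpolation.
#'
#' @param image an `absorption_image`
#' @param line list with `x` and `z` (mm) fixing the profile line
#' @param n_targets number of peaks expected (default 2)
#' @param step profile sampling step along y (mm, default 0.5)
#' @param min_separation minimum separation between reported peaks (mm)
#' @param bg_distance profile points farther than this from every peak
#'   define the background level (mm)
#' @return a list with `peaks` (data frame `y`, `mu_a`, `fwhm`),
#'   `contrast_ratio` (first peak over second, in y order),
#'   `background`, and the sampled `profile` data frame
#' @export
line_profile_metrics <- function(image, line, n_targets = 2, step = 0.5,
                                 min_separation = 10, bg_distance = 20) {
  mesh <- image$mesh
  ys <- seq(0, mesh$dims[2], by = step)
  pts <- cbind(line$x, ys, line$z)
  v <- as.numeric(interp_matrix(mesh, pts) %*% image$mu_a)
  n <- length(v)
  is_max <- c(FALSE, v[2:(n - 1)] >= v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n], FALSE)
  is_max <- is_max & v > min(v) # a flat profile has no peaks
  cand <- which(is_max)[order(v[which(is_max)], decreasing = TRUE)]
  sel <- integer(0)
  for (i in cand) {
    if (all(abs(ys[i] - ys[sel]) >= min_separation)) sel <- c(sel, i)
    if (length(sel) == n_targets) break
  }
  if (length(sel) < n_targets)
    dc_stop("dotcal_metric_failure",
            sprintf("found %d peak(s), expected %d", length(sel), n_targets))
  sel <- sort(sel)
  far <- vapply(seq_len(n), function(i) all(abs(ys[i] - ys[sel]) > bg_distance),
                logical(1))
  bg <- if (any(far)) median(v[far]) else median(v)
  fwhm <- vapply(sel, function(pk) {
    half <- bg + (v[pk] - bg) / 2
    cross <- function(idx_seq) {
      for (i in idx_seq) {
        if (v[i] < half) {
          j <- idx_seq[which(idx_seq == i) - 1] # last point still above
          return(ys[i] + (ys[j] - ys[i]) * (half - v[i]) / (v[j] - v[i]))
        }
      }
      ys[tail(idx_seq, 1)] # never crossed: clipped at the domain edge
    }
    right <- cross(seq(pk + 1, n))
    left <- cross(seq(pk - 1, 1))
    abs(right - left)
  }, numeric(1))
  peaks <- data.frame(y = ys[sel], mu_a = v[sel], fwhm = fwhm)
  list(peaks = peaks,
       contrast_ratio = v[sel[1]] / v[sel[2]],
       background = bg,
       profile = data.frame(position_mm = ys, mu_a = v))
}

#' Two-target peak ratio over domain halves
#'
#' Splits the mesh at the inter-target midplane along y (the domain
#' midpoint by default) and returns the ratio of the maximum
#' reconstructed absorption in the lower-y half to that in the
#' upper-y half, the quantity conventionally quoted as the two-target
#' contrast ratio.
#'
#' @param image an `absorption_image`
#' @param split_y y coordinate of the midplane (default mesh midpoint)
#' @return a list with `peak1`, `peak2` (1/mm) and `ratio`
#' @export
target_peak_ratio <- function(image, split_y = NULL) {
  mesh <- image$mesh
  if (is.null(split_y)) split_y <- mesh$dims[2] / 2
  lower <- mesh$nodes[, 2] < split_y
  p1 <- max(image$mu_a[lower])
  p2 <- max(image$mu_a[!lower])
  list(peak1 = p1, peak2 = p2, ratio = p1 / p2)
}

#' Export an absorption image as NIfTI
#'
#' Resamples the nodal map onto a regular grid (1 mm by default) and
#' writes a NIfTI volume with the voxel size in its header.
#'
#' @param image an `absorption_image`
#' @param path output path (`.nii` / `.nii.gz`)
#' @param voxel grid step in mm
#' @export
write_absorption_nifti <- function(image, path, voxel = 1) {
  arr <- resample_to_grid(image$mesh, image$mu_a, voxel = voxel)
  img <- RNifti::asNifti(arr, pixdim = rep(voxel, 3))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a reconstruction line profile as CSV
#'
#' @param metrics result of [line_profile_metrics()]
#' @param path output CSV path (columns `position_mm`, `mu_a`)
#' @export
write_profile_csv <- function(metrics, path) {
  write.csv(metrics$profile, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
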