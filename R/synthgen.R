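# Synthetic slab phantoms with cylindrical absorbing inclusions, and
# simulated task/reference measurement pairs with channel-gain and
# noise corruption.

#' Specify a slab phantom with cylindrical inclusions
#'
#' @param slab_dims `(x, y, z)` extents in mm; x is the through-plate
#'   axis
#' @param background background `optical_properties`
#' @param inclusions list of cylinders, each a list with `center`
#'   (length-3, mm), `radius` (mm), `height` (mm), `axis` (`"x"`, `"y"`
#'   or `"z"`; the cylinder axis), and `props` (`optical_properties`).
#'   Inclusions must lie fully inside the slab and be at least as
#'   absorbing as the background (absorbing targets).
#' @return a `phantom_spec` object
#' @export
phantom_spec <- function(slab_dims, background, inclusions = list()) {
  stopifnot(length(slab_dims) == 3, inherits(background, "optical_properties"))
  for (inc in inclusions) {
    ax <- match(match.arg(inc$axis, c("x", "y", "z")), c("x", "y", "z"))
    lat <- setdiff(1:3, ax)
    lo <- hi <- inc$center
    lo[ax] <- lo[ax] - inc$height / 2; hi[ax] <- hi[ax] + inc$height / 2
    lo[lat] <- lo[lat] - inc$radius; hi[lat] <- hi[lat] + inc$radius
    if (any(lo < 0) || any(hi > slab_dims))
      dc_stop("dotcal_spec_error",
              sprintf("inclusion at (%s) extends outside the slab",
                      paste(inc$center, collapse = ", ")))
    if (inc$props$mu_a < background$mu_a)
      dc_stop("dotcal_spec_error",
              "inclusions must be at least as absorbing as the background")
  }
  structure(list(slab_dims = slab_dims, background = background,
                 inclusions = inclusions),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("phantom_spec: %g x %g x %g mm slab, mu_a=%g, mu_s'=%g, %d inclusion(s)\n",
              x$slab_dims[1], x$slab_dims[2], x$slab_dims[3],
              x$background$mu_a, x$background$mu_s_prime, length(x$inclusions)))
  for (inc in x$inclusions)
    cat(sprintf("  cylinder r=%g h=%g axis=%s at (%s), mu_a=%g\n",
                inc$radius, inc$height, inc$axis,
                paste(inc$center, collapse = ", "), inc$props$mu_a))
  invisible(x)
}

# membership test for one cylinder, vectorized over points
in_cylinder <- function(pts, inc) {
  ax <- match(inc$axis, c("x", "y", "z"))
  lat <- setdiff(1:3, ax)
  along <- abs(pts[, ax] - inc$center[ax]) <= inc$height / 2
  r2 <- (pts[, lat[1]] - inc$center[lat[1]])^2 +
        (pts[, lat[2]] - inc$center[lat[2]])^2
  along & r2 <= inc$radius^2
}

#' Mesh a phantom and its homogeneous twin
#'
#' Builds the slab mesh, paints the inclusions onto the nodal
#' properties (a node belongs to the first inclusion that contains it)
#' and labels the elements whose centroid falls inside an inclusion.
#' The homogeneous twin is the same mesh with the inclusions removed,
#' for reference-phantom simulation.
#'
#' @param spec a `phantom_spec`
#' @param h nominal element size in mm (default 2.5)
#' @return a list with `task` (inclusion mesh), `reference`
#'   (homogeneous twin) and the `spec`
#' @export
build_phantom <- function(spec, h = 2.5) {
  stopifnot(inherits(spec, "phantom_spec"))
  ref <- slab_mesh(spec$slab_dims, h = h, spec$background)
  task <- ref
  if (length(spec$inclusions)) {
    cent <- (ref$nodes[ref$elems[, 1], ] + ref$nodes[ref$elems[, 2], ] +
             ref$nodes[ref$elems[, 3], ] + ref$nodes[ref$elems[, 4], ]) / 4
    for (i in seq_along(spec$inclusions)) {
      inc <- spec$inclusions[[i]]
      inside <- in_cylinder(task$nodes, inc)
      fresh <- inside & task$mu_a == spec$background$mu_a
      task$mu_a[fresh] <- inc$props$mu_a
      task$mu_s_prime[fresh] <- inc$props$mu_s_prime
      task$region[in_cylinder(cent, inc) & task$region == 0L] <- i
    }
  }
  list(task = task, reference = ref, spec = spec)
}

#' Channel gain and noise model
#'
#' Emulates multi-channel inconsistency of a high-density system: the
#' recorded amplitude is
#' `global_scale * g_s(i) * g_d(j) * Gamma * (1 + noise)`, floored at
#' zero. Per-channel gains are drawn log-normally; one realization
#' represents one hardware state and is applied identically to the task
#' and reference scans of a session.
#'
#' @param probe the `probe_array` (sets the gain vector lengths)
#' @param global_scale overall positive scale factor
#' @param gain_sigma sdlog of the log-normal per-channel gains
#'   (default 0.05; 0 gives identity gains)
#' @param noise_sigma multiplicative Gaussian noise sd (default 0)
#' @param seed integer seed for the realization
#' @return a `gain_model` with `source_gains`, `detector_gains` and the
#'   parameters
#' @export
gain_model <- function(probe, global_scale = 1, gain_sigma = 0.05,
                       noise_sigma = 0, seed = 1L) {
  stopifnot(global_scale > 0, gain_sigma >= 0, noise_sigma >= 0)
  old <- .Random.seed_save()
  set.seed(seed)
  gs <- rlnorm(probe$I, 0, gain_sigma)
  gd <- rlnorm(probe$J, 0, gain_sigma)
  .Random.seed_restore(old)
  structure(list(global_scale = global_scale, source_gains = gs,
                 detector_gains = gd, gain_sigma = gain_sigma,
                 noise_sigma = noise_sigma, seed = seed),
            class = "gain_model")
}

identity_gains <- function(probe) {
  gain_model(probe, global_scale = 1, gain_sigma = 0, noise_sigma = 0)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

apply_gains <- function(meas, gains, noise) {
  g <- gains$global_scale *
    gains$source_gains[meas$source_index] *
    gains$detector_gains[meas$detector_index]
  out <- meas
  out$amplitude <- pmax(meas$amplitude * g * (1 + noise), 0)
  out
}

#' Simulate a task/reference measurement session
#'
#' Runs the chosen forward generator on the phantom and its homogeneous
#' twin and corrupts both with the same channel-gain and noise
#' realization, mirroring a single hardware state measuring both
#' objects. The clean homogeneous forward data are returned as the
#' model prediction.
#'
#' @param phantom result of [build_phantom()]
#' @param probe the `probe_array`
#' @param pairs optional `sd_pairs` (exclusions applied); defaults to
#'   all pairs
#' @param gains a [gain_model()] (default: identity, no noise)
#' @param generator `"diffusion"` (FEM forward, deterministic, default)
#'   or `"mc"` (voxel Monte Carlo)
#' @param seed seed for the noise realization (and photon paths when
#'   `generator = "mc"`)
#' @param n_photons photons per source for the MC generator
#' @return a list with measurement sets `task`, `reference` (both with
#'   gains/noise applied), `predicted` (clean homogeneous forward),
#'   `pairs`, and a `manifest` list recording generator, seed and gain
#'   parameters
#' @export
simulate_dataset <- function(phantom, probe, pairs = NULL,
                             gains = identity_gains(probe),
                             generator = c("diffusion", "mc"),
                             seed = 1L, n_photons = 1e6) {
  generator <- match.arg(generator)
  if (is.null(pairs)) pairs <- enumerate_pairs(probe)
  if (generator == "diffusion") {
    fw_task <- solve_cw(phantom$task, probe, pairs, keep_fields = FALSE)
    fw_ref <- solve_cw(phantom$reference, probe, pairs, keep_fields = FALSE)
    clean_task <- fw_task$meas$amplitude
    clean_ref <- fw_ref$meas$amplitude
  } else {
    mc_task <- voxel_monte_carlo(phantom$spec, probe, pairs = pairs,
                                 n_photons = n_photons, seed = seed)
    hom <- phantom$spec
    hom$inclusions <- list()
    mc_ref <- voxel_monte_carlo(hom, probe, pairs = pairs,
                                n_photons = n_photons, seed = seed + 1L)
    clean_task <- mc_task$amplitude
    clean_ref <- mc_ref$amplitude
    fw_ref <- solve_cw(phantom$reference, probe, pairs, keep_fields = FALSE)
  }
  old <- .Random.seed_save()
  set.seed(seed)
  noise <- if (gains$noise_sigma > 0) rnorm(nrow(pairs), 0, gains$noise_sigma) else 0
  .Random.seed_restore(old)
  task <- apply_gains(measurement_set(pairs, clean_task, role = "task"),
                      gains, noise)
  reference <- apply_gains(measurement_set(pairs, clean_ref, role = "reference"),
                           gains, noise)
  predicted <- measurement_set(pairs, fw_ref$meas$amplitude, role = "predicted")
  list(task = task, reference = reference, predicted = predicted,
       pairs = pairs,
       manifest = list(generator = generator, seed = seed,
                       n_photons = if (generator == "mc") n_photons else NULL,
                       global_scale = gains$global_scale,
                       gain_sigma = gains$gain_sigma,
                       noise_sigma = gains$noise_sigma,
                       gain_seed = gains$seed))
}

scenario_names <- c("sim_baseline", "sim_3x4", "position_1", "position_2",
                    "position_3", "size_R5", "size_R10", "contrast_2x",
                    "contrast_4x", "system_7x8")

#' Scenario presets for the robustness studies
#'
#' Fully specified phantom + probe configurations: the baseline
#' breast-size slab simulation (44 x 130 x 79 mm slab, background
#' mu_a = 0.004 /mm and mu_s' = 1 /mm, two 3x-absorbing cylinders of
#' radius 7.5 mm and height 10 mm centered at (17, 45, 42) and
#' (17, 85, 42), mirrored 3 x 4 arrays at 13/14 mm pitch centered on
#' the plates, separation 44 mm), plus position, size and contrast
#' variants and the full 7 x 8 system layout.
#'
#' @param name one of `sim_baseline`, `sim_3x4`, `position_1`,
#'   `position_2`, `position_3`, `size_R5`, `size_R10`, `contrast_2x`,
#'   `contrast_4x`, `system_7x8`
#' @return a list with `phantom_spec` and `probe`
#' @export
scenario_presets <- function(name) {
  dims <- c(44, 130, 79)
  bg <- optical_properties(0.004, 1)
  probe34 <- build_probe(3, 4, 13, 14, 44, center = c(dims[2] / 2, dims[3] / 2))
  cyl <- function(center, radius = 7.5, mu_a = 0.012)
    list(center = center, radius = radius, height = 10, axis = "x",
         props = optical_properties(mu_a, 1))
  base_centers <- list(c(17, 45, 42), c(17, 85, 42))
  two <- function(centers, radius = 7.5, mu_a = 0.012)
    lapply(centers, cyl, radius = radius, mu_a = mu_a)
  specs <- list(
    sim_baseline = two(base_centers),
    sim_3x4 = two(base_centers),
    position_1 = two(list(c(17, 55, 42), c(17, 95, 42))),
    position_2 = two(list(c(17, 45, 56), c(17, 85, 56))),
    position_3 = two(list(c(27, 45, 42), c(27, 85, 42))),
    size_R5 = two(base_centers, radius = 5),
    size_R10 = two(base_centers, radius = 10),
    contrast_2x = two(base_centers, mu_a = 0.008),
    contrast_4x = two(base_centers, mu_a = 0.016),
    system_7x8 = two(base_centers)
  )
  if (!name %in% names(specs))
    dc_stop("dotcal_lookup", sprintf(
      "unknown scenario '%s'; available: %s", name,
      paste(names(specs), collapse = ", ")))
  probe <- if (name == "system_7x8")
    build_probe(7, 8, 13, 14, 44, center = c(dims[2] / 2, dims[3] / 2))
  else probe34
  list(phantom_spec = phantom_spec(dims, bg, specs[[name]]), probe = probe)
}

#' Read or write a phantom specification as YAML
#'
#' @param spec a `phantom_spec`
#' @param path file path
#' @export
write_phantom_yaml <- function(spec, path) {
  to_list <- function(p) list(mu_a = p$mu_a, mu_s_prime = p$mu_s_prime,
                              refractive_index = p$refractive_index,
                              anisotropy_g = p$anisotropy_g)
  yaml::write_yaml(list(
    slab_dims_mm = as.numeric(spec$slab_dims),
    background = to_list(spec$background),
    inclusions = lapply(spec$inclusions, function(inc)
      list(center_mm = as.numeric(inc$center), radius_mm = inc$radius,
           height_mm = inc$height, axis = inc$axis,
           props = to_list(inc$props)))
  ), path)
  invisible(path)
}

#' @rdname write_phantom_yaml
#' @export
read_phantom_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  props <- function(p) optical_properties(p$mu_a, p$mu_s_prime,
                                          p$refractive_index %||% 1.33,
                                          p$anisotropy_g %||% 0.9)
  phantom_spec(unlist(x$slab_dims_mm), props(x$background),
               lapply(x$inclusions, function(inc)
                 list(center = unlist(inc$center_mm), radius = inc$radius_mm,
                      height = inc$height_mm, axis = inc$axis,
                      props = props(inc$props))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
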