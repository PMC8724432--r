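#' Voxel Monte Carlo simulation of slab transmission
#'
#' Desk-scale weighted-photon random walk on a 1 mm voxelization of a
#' slab phantom: exponential free paths, Henyey-Greenstein scattering
#' with the medium's anisotropy, absorption by weight attenuation,
#' Fresnel reflection at the refractive-index-mismatched outer surface,
#' and Russian roulette below a weight threshold. Sources launch as a
#' cone (120 degree divergence by default) on the x = 0 plate; a
#' detector tallies the weight exiting the opposite plate within a
#' circular aperture (1.5 mm diameter by default). This is the physics
#' cross-check for the diffusion generator; amplitudes are in units of
#' detected weight per launched photon.
#'
#' @param spec a `phantom_spec`
#' @param probe a `probe_array` whose plates coincide with the slab
#'   faces
#' @param pairs optional `sd_pairs` (defaults to all pairs)
#' @param n_photons photons launched per source (>= 1e4)
#' @param seed integer seed (R RNG; runs are reproducible)
#' @param voxel voxel edge in mm (default 1)
#' @param aperture_radius detector aperture radius in mm (default 0.75,
#'   i.e. a 1.5 mm diameter photodiode); enlarging it is a legitimate
#'   variance-reduction choice when only distance-class means are
#'   needed
#' @param cone_half_angle source divergence half-angle in degrees
#'   (default 60, a 120 degree cone)
#' @param error_on_empty raise an insufficient-photons error when a
#'   retained pair receives no weight (default TRUE)
#' @return a `measurement_set` (role `"task"`) with attributes
#'   `standard_error` (per-pair standard error of the mean),
#'   `energy_balance` (launched, absorbed, transmitted, reflected,
#'   side_exit, roulette_net) and `n_photons`
#' @export
voxel_monte_carlo <- function(spec, probe, pairs = NULL, n_photons = 1e6,
                              seed = 1L, voxel = 1,
                              aperture_radius = 0.75,
                              cone_half_angle = 60,
                              error_on_empty = TRUE) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(probe, "probe_array"))
  if (n_photons < 1e4)
    dc_stop("dotcal_invalid_input", "n_photons must be at least 1e4")
  if (is.null(pairs)) pairs <- enumerate_pairs(probe)
  if (abs(probe$plate_separation - spec$slab_dims[1]) > 1e-9)
    dc_stop("dotcal_geometry", "plate separation does not match the slab thickness")

  nvox <- as.integer(round(spec$slab_dims / voxel))
  centers <- lapply(1:3, function(a) (seq_len(nvox[a]) - 0.5) * voxel)
  region <- array(0L, dim = nvox)
  if (length(spec$inclusions)) {
    pts <- as.matrix(expand.grid(centers[[1]], centers[[2]], centers[[3]]))
    for (i in seq_along(spec$inclusions)) {
      inside <- in_cylinder(pts, spec$inclusions[[i]])
      region[inside & region == 0L] <- i
    }
  }
  props <- c(list(spec$background), lapply(spec$inclusions, `[[`, "props"))
  mu_a <- vapply(props, `[[`, numeric(1), "mu_a")
  g <- vapply(props, `[[`, numeric(1), "anisotropy_g")
  mu_s <- vapply(props, `[[`, numeric(1), "mu_s_prime") / (1 - g)

  old <- .Random.seed_save()
  set.seed(seed)
  res <- .mc_slab(as.integer(region), nvox, voxel, mu_a, mu_s, g,
                  spec$background$refractive_index,
                  probe$source_positions, probe$detector_positions,
                  cone_half_angle, aperture_radius, as.integer(n_photons))
  .Random.seed_restore(old)

  amp <- res$tally_w[cbind(pairs$source_index, pairs$detector_index)] / n_photons
  w2 <- res$tally_w2[cbind(pairs$source_index, pairs$detector_index)]
  se <- sqrt(pmax(w2 / n_photons - amp^2, 0) / n_photons)
  r <- !pairs$excluded
  if (error_on_empty && any(amp[r] == 0)) {
    bad <- which(r & amp == 0)[1]
    dc_stop("dotcal_insufficient_photons",
            sprintf("no photons detected at retained pair (s%d,d%d); increase n_photons or the aperture",
                    pairs$source_index[bad], pairs$detector_index[bad]))
  }
  out <- measurement_set(pairs, amp, role = "task")
  attr(out, "standard_error") <- se
  attr(out, "energy_balance") <- res[c("launched", "absorbed", "transmitted",
                                       "reflected", "side_exit", "roulette_net")]
  attr(out, "n_photons") <- n_photons
  out
}
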