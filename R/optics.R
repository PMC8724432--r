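#' Optical properties of a turbid medium
#'
#' Bundle of the coefficients entering the continuous-wave diffusion model:
#' absorption \eqn{\mu_a}, reduced scattering \eqn{\mu_s'}, refractive
#' index \eqn{n}, anisotropy \eqn{g} (used only by the Monte Carlo
#' generator), and the derived quantities: internal reflection coefficient
#' \eqn{R_f}, boundary factor \eqn{\zeta = (1+R_f)/(1-R_f)} and diffusion
#' coefficient \eqn{\kappa = 1/(3(\mu_a+\mu_s'))}. The speed of light is
#' set to 1 throughout: every quantity the package computes from CW
#' amplitudes is a ratio in which it cancels.
#'
#' If `R_f` is not given it is computed from the refractive index with the
#' Groenhuis polynomial fit
#' \eqn{R_f = -1.440/n^2 + 0.710/n + 0.668 + 0.0636 n}.
#'
#' @param mu_a absorption coefficient (1/mm), > 0
#' @param mu_s_prime reduced scattering coefficient (1/mm), > 0
#' @param refractive_index refractive index of the medium (default 1.33)
#' @param anisotropy_g scattering anisotropy for Monte Carlo (default 0.9)
#' @param R_f internal reflection coefficient in `[0, 1)`; computed from
#'   `refractive_index` when `NULL`
#' @return an object of class `optical_properties` with fields `mu_a`,
#'   `mu_s_prime`, `refractive_index`, `anisotropy_g`, `R_f`, `zeta`,
#'   `kappa`
#' @examples
#' op <- optical_properties(0.004, 1)
#' op$kappa # 1/(3 * 1.004)
#' @export
optical_properties <- function(mu_a, mu_s_prime, refractive_index = 1.33,
                               anisotropy_g = 0.9, R_f = NULL) {
  if (!is.numeric(mu_a) || any(mu_a <= 0))
    dc_stop("dotcal_invalid_optics", "mu_a must be positive")
  if (!is.numeric(mu_s_prime) || any(mu_s_prime <= 0))
    dc_stop("dotcal_invalid_optics", "mu_s_prime must be positive")
  if (is.null(R_f)) R_f <- groenhuis_reflection(refractive_index)
  if (any(R_f < 0) || any(R_f >= 1))
    dc_stop("dotcal_invalid_optics", "R_f must lie in [0, 1)")
  structure(list(
    mu_a = mu_a, mu_s_prime = mu_s_prime,
    refractive_index = refractive_index, anisotropy_g = anisotropy_g,
    R_f = R_f, zeta = (1 + R_f) / (1 - R_f),
    kappa = 1 / (3 * (mu_a + mu_s_prime))
  ), class = "optical_properties")
}

#' @export
print.optical_properties <- function(x, ...) {
  cat(sprintf(
    "optical_properties: mu_a=%g /mm, mu_s'=%g /mm, n=%g, g=%g, R_f=%.4f, zeta=%.4f, kappa=%.5f mm\n",
    x$mu_a[1], x$mu_s_prime[1], x$refractive_index[1], x$anisotropy_g[1],
    x$R_f[1], x$zeta[1], x$kappa[1]
  ))
  invisible(x)
}

# Groenhuis fit for the internal reflection coefficient of an
# air/tissue boundary as a function of tissue refractive index.
groenhuis_reflection <- function(n) {
  -1.440 / n^2 + 0.710 / n + 0.668 + 0.0636 * n
}

# effective attenuation coefficient sqrt(mu_a / kappa) (1/mm)
mu_eff <- function(props) sqrt(props$mu_a / props$kappa)
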