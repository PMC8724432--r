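# CW diffusion forward model on a slab mesh.
#
# Weak form of  -div(kappa grad Phi) + mu_a Phi = q0  with the Robin
# condition  Phi + 2 kappa zeta dPhi/dn = 0  (speed of light set to 1):
#   K + M + S, with
#   K_ij = int kappa grad(phi_i).grad(phi_j),
#   M_ij = int mu_a phi_i phi_j,
#   S_ij = (1/(2 zeta)) int_boundary phi_i phi_j.
# Element properties are the mean of the four nodal values.

#' Assemble the FEM system for the CW diffusion equation
#'
#' @param mesh a `slab_mesh` with nodal `mu_a` / `mu_s_prime`
#' @param template optional result of a previous call on the same mesh;
#'   geometry-derived quantities and the symbolic Cholesky factorization
#'   are then reused and only property-dependent values are recomputed
#'   (the Gauss-Newton reconstruction re-assembles every iteration)
#' @return a list with the sparse SPD matrix `A`, its Cholesky `factor`,
#'   the boundary factor `zeta`, and the reusable `geometry`
#' @keywords internal
fem_system <- function(mesh, template = NULL) {
  el <- mesh$elems
  geo <- if (!is.null(template)) template$geometry else fem_geometry(mesh)
  mu_a_e <- rowMeans(matrix(mesh$mu_a[el], ncol = 4))
  mu_s_e <- rowMeans(matrix(mesh$mu_s_prime[el], ncol = 4))
  kappa_e <- 1 / (3 * (mu_a_e + mu_s_e))
  V <- mesh$elem_volume
  n16 <- length(geo$gdot) # 16 element-matrix slots
  tx <- vector("list", n16 + 1L)
  for (n in seq_len(n16)) {
    tx[[n]] <- kappa_e * V * geo$gdot[[n]] +
      mu_a_e * V / 20 * geo$mass_w[n]
  }
  zeta <- mesh$props_background$zeta
  tx[[n16 + 1L]] <- geo$robin_x / zeta
  A <- Matrix::sparseMatrix(i = geo$ti, j = geo$tj, x = unlist(tx),
                            dims = rep(nrow(mesh$nodes), 2))
  A <- Matrix::forceSymmetric((A + Matrix::t(A)) / 2)
  fac <- tryCatch({
    if (!is.null(template))
      Matrix::update(template$factor, A)
    else
      Matrix::Cholesky(A, LDL = FALSE, perm = TRUE)
  }, error = function(e)
    dc_stop("dotcal_solver", paste("FEM system not SPD:", conditionMessage(e))))
  list(A = A, factor = fac, zeta = zeta, geometry = geo)
}

# geometry-only part of the assembly: triplet indices, basis-gradient
# dot products per element, and the Robin boundary mass (up to 1/zeta)
fem_geometry <- function(mesh) {
  el <- mesh$elems
  nd <- mesh$nodes
  p1 <- nd[el[, 1], , drop = FALSE]; p2 <- nd[el[, 2], , drop = FALSE]
  p3 <- nd[el[, 3], , drop = FALSE]; p4 <- nd[el[, 4], , drop = FALSE]
  a <- p2 - p1; b <- p3 - p1; cc <- p4 - p1
  v6 <- rowSums(a * vcross(b, cc)) # signed 6V
  g2 <- vcross(b, cc) / v6
  g3 <- vcross(cc, a) / v6
  g4 <- vcross(a, b) / v6
  g1 <- -(g2 + g3 + g4)
  G <- list(g1, g2, g3, g4)
  ti <- tj <- gdot <- vector("list", 16)
  mass_w <- numeric(16)
  n <- 0
  for (i in 1:4) for (j in 1:4) {
    n <- n + 1
    gdot[[n]] <- rowSums(G[[i]] * G[[j]])
    mass_w[n] <- if (i == j) 2 else 1
    ti[[n]] <- el[, i]; tj[[n]] <- el[, j]
  }
  bf <- mesh$boundary_faces
  bi <- bj <- bx <- vector("list", 9)
  n <- 0
  for (i in 1:3) for (j in 1:3) {
    n <- n + 1
    bi[[n]] <- bf$nodes[, i]; bj[[n]] <- bf$nodes[, j]
    bx[[n]] <- bf$area / 2 / ifelse(i == j, 6, 12)
  }
  list(ti = c(unlist(ti), unlist(bi)), tj = c(unlist(tj), unlist(bj)),
       gdot = gdot, mass_w = mass_w, robin_x = unlist(bx))
}

# load vectors: isotropic point sources one transport mean free path
# (1/mu_s') beneath each source position on the x = 0 plate
source_loads <- function(mesh, positions) {
  depth <- 1 / mesh$props_background$mu_s_prime
  pts <- positions
  pts[, 1] <- pts[, 1] + depth
  Matrix::t(interp_matrix(mesh, pts))
}

# surface sampling vectors at the detector positions (x = L plate)
detector_vectors <- function(mesh, positions) {
  Matrix::t(interp_matrix(mesh, positions))
}

check_on_plate <- function(mesh, probe) {
  tol <- 1e-6
  if (any(abs(probe$source_positions[, 1]) > tol) ||
      any(abs(probe$detector_positions[, 1] - mesh$dims[1]) > tol))
    dc_stop("dotcal_geometry",
            "probe plates do not coincide with the slab faces x = 0 and x = dims[1]")
  yz_ok <- function(p) all(p[, 2] >= -tol & p[, 2] <= mesh$dims[2] + tol &
                           p[, 3] >= -tol & p[, 3] <= mesh$dims[3] + tol)
  if (!yz_ok(probe$source_positions) || !yz_ok(probe$detector_positions))
    dc_stop("dotcal_geometry", "probe positions fall outside the slab face")
  invisible(TRUE)
}

#' Solve the CW diffusion forward problem on a slab mesh
#'
#' Finite-element solution of the diffusion equation with Robin boundary
#' conditions for every active source of a mirrored parallel-plate
#' probe. Each source is an isotropic point source one transport mean
#' free path (\eqn{1/\mu_s'}) beneath its surface position; the detector
#' reading is \eqn{\Gamma = \Phi(r_d) / (2\zeta)}, the boundary flux
#' implied by the Robin condition.
#'
#' @param mesh a `slab_mesh` (nodal properties define the medium)
#' @param probe a `probe_array` whose plates coincide with the slab
#'   faces x = 0 and x = `dims[1]`
#' @param pairs optional `sd_pairs` table (defaults to all I x J pairs);
#'   amplitudes are computed for every pair, excluded ones included
#' @param active_sources optional integer vector of sources to solve for
#'   (default all that appear in `pairs`)
#' @param keep_fields keep the nodal photon-density matrix and system
#'   factor in the result (needed by the Jacobian; default `TRUE`)
#' @param template a previous `fem_system` result on the same mesh to
#'   reuse its symbolic factorization (see [fem_system()])
#' @return a list of class `cw_forward`: `meas` (a `measurement_set`
#'   with role `"predicted"`), `Phi` (nodes x sources), `system`, and
#'   the probe/pairs used
#' @examples
#' \donttest{
#' op <- optical_properties(0.004, 1)
#' mesh <- slab_mesh(c(44, 130, 79), h = 6, op)
#' probe <- build_probe(3, 4, 13, 14, 44, center = c(65, 39.5))
#' fw <- solve_cw(mesh, probe)
#' }
#' @export
solve_cw <- function(mesh, probe, pairs = NULL, active_sources = NULL,
                     keep_fields = TRUE, template = NULL) {
  stopifnot(inherits(mesh, "slab_mesh"), inherits(probe, "probe_array"))
  check_on_plate(mesh, probe)
  if (is.null(pairs)) pairs <- enumerate_pairs(probe)
  if (is.null(active_sources)) active_sources <- sort(unique(pairs$source_index))
  sys <- fem_system(mesh, template = template)
  B <- source_loads(mesh, probe$source_positions[active_sources, , drop = FALSE])
  Phi <- as.matrix(Matrix::solve(sys$factor, B))
  colnames(Phi) <- as.character(active_sources)
  U <- detector_vectors(mesh, probe$detector_positions)
  Gd <- as.matrix(Matrix::t(U) %*% Phi) / (2 * sys$zeta) # J x n_active
  amp <- Gd[cbind(pairs$detector_index,
                  match(pairs$source_index, active_sources))]
  meas <- measurement_set(pairs, amp, role = "predicted")
  out <- list(meas = meas, probe = probe, pairs = pairs,
              active_sources = active_sources)
  if (keep_fields) {
    out$Phi <- Phi
    out$system <- sys
  }
  structure(out, class = "cw_forward")
}

#' Analytic homogeneous-slab transmission oracle
#'
#' Exact CW photon density for an infinite homogeneous slab of thickness
#' equal to the plate separation, with the same physics as the FEM
#' solver: isotropic point source at depth \eqn{1/\mu_s'} and Robin
#' boundary conditions \eqn{\Phi \pm 2\kappa\zeta\,\Phi' = 0} on both
#' faces. The solution is assembled in the lateral Fourier domain, where
#' the depth profile is a two-point boundary-value problem with a
#' closed-form sinh/cosh Green's function, and transformed back with a
#' numerically evaluated Hankel integral (this is exact for the slab,
#' unlike the extrapolated-boundary image-source series, which
#' approximates the Robin condition with a displaced Dirichlet plane
#' and is biased by a few percent at small lateral offsets). The
#' transmitted amplitude is \eqn{\Phi/(2\zeta)} on the detector plate,
#' matching the detector model of [solve_cw()]. It depends only on the
#' lateral source-detector offset and is therefore constant within a
#' distance class; lateral slab boundaries are ignored.
#'
#' @param props homogeneous `optical_properties`
#' @param probe a `probe_array`
#' @param pairs optional `sd_pairs` (default all pairs)
#' @param tol relative tolerance of the Hankel quadrature
#' @return a `measurement_set` with role `"predicted"`
#' @export
analytic_slab_flux <- function(props, probe, pairs = NULL, tol = 1e-10) {
  stopifnot(inherits(props, "optical_properties"), inherits(probe, "probe_array"))
  if (length(props$mu_a) != 1 || length(props$mu_s_prime) != 1)
    dc_stop("dotcal_unsupported_input",
            "analytic_slab_flux requires homogeneous properties")
  if (is.null(pairs)) pairs <- enumerate_pairs(probe)
  L <- probe$plate_separation
  kap <- props$kappa
  zeta <- props$zeta
  z0 <- 1 / props$mu_s_prime
  # lateral-Fourier-domain Green's function evaluated at the exit face:
  # -kappa g'' + (mu_a + kappa k^2) g = delta(z - z0),
  # g - 2 kappa zeta g' = 0 at z = 0, g + 2 kappa zeta g' = 0 at z = L
  g_exit <- function(k) {
    al <- sqrt(props$mu_a / kap + k^2)
    c1 <- 1 / (2 * kap * zeta * al)
    A0 <- cosh(al * z0) + c1 * sinh(al * z0) # left-BC solution at z0
    AL <- cosh(al * L) + c1 * sinh(al * L)
    ALp <- al * sinh(al * L) + al * c1 * cosh(al * L)
    W <- AL * (-al * c1) - ALp # Wronskian A B' - A' B at z = L (B(L)=1)
    A0 / (-kap * W)
  }
  dy <- probe$source_positions[pairs$source_index, 2] -
        probe$detector_positions[pairs$detector_index, 2]
  dz <- probe$source_positions[pairs$source_index, 3] -
        probe$detector_positions[pairs$detector_index, 3]
  rho2 <- round(dy^2 + dz^2, 9)
  u <- sort(unique(rho2))
  k_max <- max(2, 40 / L) # g decays like exp(-kL): e^-80 at the cutoff
  phi_u <- vapply(sqrt(u), function(rho) {
    stats::integrate(function(k) k * besselJ(k * rho, 0) * g_exit(k),
                     0, k_max, subdivisions = 4000L, rel.tol = tol)$value / (2 * pi)
  }, numeric(1))
  amp <- phi_u[match(rho2, u)] / (2 * zeta)
  measurement_set(pairs, amp, role = "predicted")
}
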