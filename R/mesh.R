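#' Structured tetrahedral mesh of a slab
#'
#' Discretizes the box `[0, dims[1]] x [0, dims[2]] x [0, dims[3]]`
#' (x = through-plate axis) into a regular lattice of cells, each split
#' into six tetrahedra (Kuhn triangulation, conforming across cells).
#' Nodal optical properties start homogeneous at `props`; inclusions are
#' painted on by [build_phantom()].
#'
#' @param dims slab dimensions `(x, y, z)` in mm
#' @param h nominal element size in mm (scalar or length 3); the actual
#'   spacing divides each dimension into a whole number of cells
#' @param props background `optical_properties`
#' @return an object of class `slab_mesh`: `nodes` (N x 3), `elems`
#'   (M x 4 node indices), `elem_volume`, lattice metadata (`n_cells`,
#'   `spacing`, axis node coordinates), `boundary_faces` (list with
#'   `nodes` (F x 3), `area`, `normal` (F x 3 outward unit)), per-node
#'   `mu_a` / `mu_s_prime`, per-element `region` (0 = background) and
#'   the background properties
#' @export
slab_mesh <- function(dims, h = 3, props) {
  stopifnot(length(dims) == 3, all(dims > 0), inherits(props, "optical_properties"))
  if (length(h) == 1) h <- rep(h, 3)
  n <- pmax(1L, as.integer(round(dims / h)))
  sp <- dims / n
  ax <- lapply(1:3, function(a) seq(0, dims[a], length.out = n[a] + 1L))
  nx <- n[1] + 1L; ny <- n[2] + 1L; nz <- n[3] + 1L
  nodes <- cbind(
    x = rep(ax[[1]], times = ny * nz),
    y = rep(rep(ax[[2]], each = nx), times = nz),
    z = rep(ax[[3]], each = nx * ny)
  )
  nid <- function(i, j, k) i + (j - 1L) * nx + (k - 1L) * nx * ny

  cell <- expand.grid(i = seq_len(n[1]), j = seq_len(n[2]), k = seq_len(n[3]))
  c000 <- nid(cell$i, cell$j, cell$k)
  c100 <- nid(cell$i + 1L, cell$j, cell$k)
  c010 <- nid(cell$i, cell$j + 1L, cell$k)
  c001 <- nid(cell$i, cell$j, cell$k + 1L)
  c110 <- nid(cell$i + 1L, cell$j + 1L, cell$k)
  c101 <- nid(cell$i + 1L, cell$j, cell$k + 1L)
  c011 <- nid(cell$i, cell$j + 1L, cell$k + 1L)
  c111 <- nid(cell$i + 1L, cell$j + 1L, cell$k + 1L)
  # six Kuhn tetrahedra per cell, all sharing the 000-111 diagonal
  tets <- rbind(
    cbind(c000, c100, c110, c111),
    cbind(c000, c100, c101, c111),
    cbind(c000, c010, c110, c111),
    cbind(c000, c010, c011, c111),
    cbind(c000, c001, c101, c111),
    cbind(c000, c001, c011, c111)
  )
  dimnames(tets) <- NULL
  vol <- prod(sp) / 6

  mesh <- structure(list(
    dims = dims, n_cells = n, spacing = sp,
    axis_x = ax[[1]], axis_y = ax[[2]], axis_z = ax[[3]],
    nodes = nodes, elems = tets,
    elem_volume = rep(vol, nrow(tets)),
    mu_a = rep(props$mu_a, nrow(nodes)),
    mu_s_prime = rep(props$mu_s_prime, nrow(nodes)),
    region = rep(0L, nrow(tets)),
    props_background = props
  ), class = "slab_mesh")
  mesh$boundary_faces <- boundary_faces(mesh)
  mesh
}

#' @export
print.slab_mesh <- function(x, ...) {
  cat(sprintf(
    "slab_mesh: %g x %g x %g mm, %d nodes, %d tetrahedra (spacing %s mm), %d boundary faces\n",
    x$dims[1], x$dims[2], x$dims[3], nrow(x$nodes), nrow(x$elems),
    paste(signif(x$spacing, 3), collapse = " x "), nrow(x$boundary_faces$nodes)
  ))
  invisible(x)
}

# Extract boundary triangles (faces owned by exactly one tet) with
# outward unit normals and areas.
boundary_faces <- function(mesh) {
  el <- mesh$elems
  fidx <- rbind(el[, c(2, 3, 4)], el[, c(1, 3, 4)],
                el[, c(1, 2, 4)], el[, c(1, 2, 3)])
  opp <- c(el[, 1], el[, 2], el[, 3], el[, 4]) # vertex opposite each face
  srt <- t(apply(fidx, 1, sort))
  N <- nrow(mesh$nodes)
  key <- srt[, 1] + (srt[, 2] - 1) * N + (srt[, 3] - 1) * N^2
  tab <- table(key)
  once <- as.numeric(names(tab)[tab == 1L])
  sel <- which(key %in% once)
  f <- fidx[sel, , drop = FALSE]
  o <- opp[sel]
  p1 <- mesh$nodes[f[, 1], , drop = FALSE]
  p2 <- mesh$nodes[f[, 2], , drop = FALSE]
  p3 <- mesh$nodes[f[, 3], , drop = FALSE]
  nrm <- vcross(p2 - p1, p3 - p1)
  area <- 0.5 * sqrt(rowSums(nrm^2))
  nrm <- nrm / sqrt(rowSums(nrm^2))
  # orient away from the opposite vertex (i.e., out of the domain)
  inward <- rowSums(nrm * (mesh$nodes[o, , drop = FALSE] - p1)) > 0
  nrm[inward, ] <- -nrm[inward, ]
  list(nodes = f, area = area, normal = nrm)
}

vcross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Linear interpolation weights on a slab mesh
#'
#' For each query point returns the four nodes of the containing Kuhn
#' tetrahedron and its barycentric weights (exact P1 interpolation).
#' Points are clamped to the slab.
#'
#' @param mesh a `slab_mesh`
#' @param points n x 3 matrix of coordinates (mm)
#' @return a sparse n x N weight matrix `W`; `W %*% nodal_values`
#'   interpolates
#' @export
interp_matrix <- function(mesh, points) {
  points <- matrix(points, ncol = 3)
  np <- nrow(points)
  n <- mesh$n_cells; sp <- mesh$spacing
  nx <- n[1] + 1L; ny <- n[2] + 1L
  pt <- pmin(pmax(points, 0), rep(mesh$dims - 1e-12, each = np))
  ci <- pmin(floor(pt / rep(sp, each = np)) + 1, rep(n, each = np))
  loc <- (pt - (ci - 1) * rep(sp, each = np)) / rep(sp, each = np)
  # Kuhn simplex = descending order of the local coordinates
  s1 <- pmax(loc[, 1], loc[, 2], loc[, 3])
  s3 <- pmin(loc[, 1], loc[, 2], loc[, 3])
  s2 <- loc[, 1] + loc[, 2] + loc[, 3] - s1 - s3
  a1 <- max.col(loc, ties.method = "first")
  a3 <- max.col(-loc, ties.method = "last")
  a2 <- 6L - a1 - a3
  step <- c(1L, nx, nx * ny)
  base <- 1L + (ci[, 1] - 1L) + (ci[, 2] - 1L) * nx + (ci[, 3] - 1L) * nx * ny
  verts <- cbind(base,
                 base + step[a1],
                 base + step[a1] + step[a2],
                 base + step[1] + step[2] + step[3])
  lam <- cbind(1 - s1, s1 - s2, s2 - s3, s3)
  Matrix::sparseMatrix(i = rep(seq_len(np), 4), j = as.vector(verts),
                       x = as.vector(lam),
                       dims = c(np, nrow(mesh$nodes)))
}

#' Resample nodal values onto a regular grid
#'
#' @param mesh a `slab_mesh`
#' @param values per-node vector
#' @param voxel grid step in mm (default 1)
#' @return a 3D array (x, y, z) with attributes `voxel` and `origin`
#' @export
resample_to_grid <- function(mesh, values, voxel = 1) {
  gx <- seq(0, mesh$dims[1], by = voxel)
  gy <- seq(0, mesh$dims[2], by = voxel)
  gz <- seq(0, mesh$dims[3], by = voxel)
  pts <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  W <- interp_matrix(mesh, pts)
  arr <- array(as.numeric(W %*% values), dim = c(length(gx), length(gy), length(gz)))
  attr(arr, "voxel") <- voxel
  attr(arr, "origin") <- c(0, 0, 0)
  arr
}

#' Write or read a slab mesh as legacy ASCII VTK
#'
#' Unstructured-grid VTK with the tetrahedra and nodal `mu_a` /
#' `mu_s_prime` point data. The reader restores nodes, elements and
#' nodal properties (lattice metadata is recomputed when the mesh is a
#' regular slab written by this package).
#'
#' @param mesh a `slab_mesh`
#' @param path file path
#' @export
write_mesh_vtk <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               sprintf("dotcal slab_mesh %s", paste(mesh$dims, collapse = " ")),
               "ASCII", "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nrow(mesh$nodes))), con)
  writeLines(apply(format(mesh$nodes, trim = TRUE, digits = 12), 1, paste, collapse = " "), con)
  m <- nrow(mesh$elems)
  writeLines(sprintf("CELLS %d %d", m, 5 * m), con)
  writeLines(paste(4, mesh$elems[, 1] - 1, mesh$elems[, 2] - 1,
                   mesh$elems[, 3] - 1, mesh$elems[, 4] - 1), con)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(as.character(rep(10L, m)), con)
  writeLines(sprintf("POINT_DATA %d", nrow(mesh$nodes)), con)
  for (fld in c("mu_a", "mu_s_prime")) {
    writeLines(c(sprintf("SCALARS %s double 1", fld), "LOOKUP_TABLE default"), con)
    writeLines(format(mesh[[fld]], trim = TRUE, digits = 12), con)
  }
  invisible(path)
}

#' @rdname write_mesh_vtk
#' @export
read_mesh_vtk <- function(path) {
  lines <- readLines(path)
  hdr <- function(pat) grep(pat, lines)[1]
  np <- as.integer(strsplit(lines[hdr("^POINTS")], " ")[[1]][2])
  pts <- scan(text = lines[(hdr("^POINTS") + 1):(hdr("^POINTS") + np)],
              quiet = TRUE)
  nodes <- matrix(pts, ncol = 3, byrow = TRUE)
  colnames(nodes) <- c("x", "y", "z")
  nc <- as.integer(strsplit(lines[hdr("^CELLS")], " ")[[1]][2])
  cel <- scan(text = lines[(hdr("^CELLS") + 1):(hdr("^CELLS") + nc)], quiet = TRUE)
  cel <- matrix(cel, ncol = 5, byrow = TRUE)
  elems <- cel[, 2:5] + 1L
  vals <- list()
  for (fld in c("mu_a", "mu_s_prime")) {
    at <- hdr(paste0("^SCALARS ", fld))
    vals[[fld]] <- scan(text = lines[(at + 2):(at + 1 + nrow(nodes))], quiet = TRUE)
  }
  dims <- apply(nodes, 2, max)
  props <- optical_properties(max(min(vals$mu_a), 1e-6), max(min(vals$mu_s_prime), 1e-6))
  h <- sort(unique(round(diff(sort(unique(nodes[, 1]))), 9)))
  mesh <- slab_mesh(dims, h = c(h[1],
                                min(diff(sort(unique(nodes[, 2])))),
                                min(diff(sort(unique(nodes[, 3]))))), props)
  if (nrow(mesh$nodes) != nrow(nodes) || any(abs(mesh$nodes - nodes) > 1e-6))
    dc_stop("dotcal_invalid_input", "VTK file is not a dotcal slab mesh")
  mesh$mu_a <- vals$mu_a
  mesh$mu_s_prime <- vals$mu_s_prime
  mesh$elems <- elems
  mesh
}

# per-node lumped volume (sum of adjacent element volumes / 4)
node_volumes <- function(mesh) {
  v <- numeric(nrow(mesh$nodes))
  add <- rep(mesh$elem_volume / 4, 4)
  idx <- as.vector(mesh$elems)
  vv <- rowsum(add, idx)
  v[as.integer(rownames(vv))] <- vv[, 1]
  v
}
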