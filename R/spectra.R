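# Multi-wavelength absorption -> chromophore concentration maps.

#' Load an extinction coefficient table
#'
#' CSV with columns `chromophore`, `wavelength_nm`, `epsilon`
#' (mm^-1 per uM). The packaged default covers Hb and HbO2 at 660, 750
#' and 840 nm (compiled from standard literature tabulations of
#' hemoglobin molar extinction); the table is configuration, not a
#' constant - supply your own for other wavelengths or chromophores.
#'
#' @param path CSV path; default the packaged table
#' @return a data frame with the three columns above
#' @export
load_extinction_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "extinction_hb.csv", package = "dotcal",
                        mustWork = TRUE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("chromophore", "wavelength_nm", "epsilon")
  if (!all(need %in% names(df)))
    dc_stop("dotcal_invalid_input",
            "extinction table needs columns chromophore, wavelength_nm, epsilon")
  df
}

# extinction matrix (wavelengths x chromophores) for the requested set
extinction_matrix <- function(table, wavelengths, chromophores) {
  E <- sapply(chromophores, function(ch) {
    vapply(wavelengths, function(wl) {
      hit <- table$chromophore == ch & table$wavelength_nm == wl
      if (!any(hit))
        dc_stop("dotcal_unmixing_config",
                sprintf("no extinction value for %s at %g nm", ch, wl))
      table$epsilon[which(hit)[1]]
    }, numeric(1))
  })
  E <- matrix(E, nrow = length(wavelengths),
              dimnames = list(NULL, chromophores))
  if (qr(E)$rank < ncol(E))
    dc_stop("dotcal_unmixing_config", "extinction matrix is rank deficient")
  E
}

# small non-negative least squares, Lawson-Hanson active set
nnls_small <- function(E, y) {
  p <- ncol(E)
  active <- rep(FALSE, p)
  x <- numeric(p)
  for (outer in seq_len(3 * p + 1)) {
    wgrad <- crossprod(E, y - E %*% x)
    cand <- which(!active & wgrad > 1e-12 * max(1, max(abs(wgrad))))
    if (!length(cand)) break
    active[cand[which.max(wgrad[cand])]] <- TRUE
    repeat {
      z <- numeric(p)
      z[active] <- qr.solve(E[, active, drop = FALSE], y)
      if (all(z[active] > 0)) { x <- z; break }
      neg <- active & z <= 0
      alpha <- min(x[neg] / (x[neg] - z[neg]))
      x <- x + alpha * (z - x)
      active[x <= 1e-12 & active] <- FALSE
      x[!active] <- 0
    }
  }
  x
}

#' Unmix multi-wavelength absorption into chromophore concentrations
#'
#' Solves, per node, \eqn{\mu_a(\lambda) = \sum_c \epsilon(c,\lambda)
#' C_c} by non-negative least squares, and derives total hemoglobin
#' HbT = Hb + HbO2 and oxygen saturation StO2 = HbO2/HbT (masked where
#' HbT is zero).
#'
#' @param absorption_images list of `absorption_image`s (or plain
#'   numeric nodal vectors) at two or more wavelengths
#' @param wavelengths wavelengths in nm, one per image; taken from the
#'   images when `NULL`
#' @param extinction_table data frame from [load_extinction_table()]
#' @param chromophores chromophores to unmix (default Hb and HbO2)
#' @return an object of class `chromophore_map`: per-node `Hb`, `HbO2`
#'   (uM), `HbT`, `StO2`, the per-node `residual` norm, and
#'   `wavelengths_used`
#' @export
unmix_chromophores <- function(absorption_images, wavelengths = NULL,
                               extinction_table = load_extinction_table(),
                               chromophores = c("Hb", "HbO2")) {
  vals <- lapply(absorption_images, function(im)
    if (inherits(im, "absorption_image")) im$mu_a else as.numeric(im))
  if (is.null(wavelengths))
    wavelengths <- vapply(absorption_images, function(im)
      as.numeric(attr(im, "wavelength") %||% im$wavelength %||% NA_real_), numeric(1))
  if (length(vals) < 2)
    dc_stop("dotcal_unmixing_config",
            "spectral unmixing needs at least two wavelengths")
  if (length(unique(vapply(vals, length, integer(1)))) != 1)
    dc_stop("dotcal_invalid_input", "absorption maps differ in length")
  E <- extinction_matrix(extinction_table, wavelengths, chromophores)
  A <- do.call(rbind, vals) # wavelengths x nodes
  # unconstrained solve, then per-node NNLS refit where negativity appears
  C <- qr.solve(E, A)
  neg <- which(colSums(C < 0) > 0)
  for (i in neg) C[, i] <- nnls_small(E, A[, i])
  C[C < 0] <- 0
  resid <- sqrt(colSums((A - E %*% C)^2))
  Hb <- C[match("Hb", chromophores), ]
  HbO2 <- C[match("HbO2", chromophores), ]
  HbT <- Hb + HbO2
  StO2 <- ifelse(HbT > 0, HbO2 / HbT, NA_real_)
  structure(list(Hb = Hb, HbO2 = HbO2, HbT = HbT, StO2 = StO2,
                 residual = resid, wavelengths_used = wavelengths,
                 extinction = E),
            class = "chromophore_map")
}

#' @export
print.chromophore_map <- function(x, ...) {
  cat(sprintf(
    "chromophore_map: %d nodes, wavelengths %s nm; HbT in [%.3g, %.3g] uM, StO2 mean %.3f\n",
    length(x$HbT), paste(x$wavelengths_used, collapse = "/"),
    min(x$HbT), max(x$HbT), mean(x$StO2, na.rm = TRUE)))
  invisible(x)
}

#' Tumor-to-background contrast summary
#'
#' Mean over the tumor region divided by mean over the background
#' region, for Hb, HbO2, HbT and StO2. When `tumor_region` is `NULL`
#' the tumor is defined as the nodes above background + half of
#' (max - background) of HbT, with background the median HbT, and the
#' background region is its complement.
#'
#' @param map a `chromophore_map`
#' @param tumor_region,background_region integer node index vectors
#'   (disjoint)
#' @return named numeric vector of T/B contrasts
#' @export
physiology_summary <- function(map, tumor_region = NULL,
                               background_region = NULL) {
  stopifnot(inherits(map, "chromophore_map"))
  if (is.null(tumor_region)) {
    bgl <- median(map$HbT)
    thr <- bgl + (max(map$HbT) - bgl) / 2
    tumor_region <- which(map$HbT > thr)
    background_region <- setdiff(seq_along(map$HbT), tumor_region)
  }
  if (!length(tumor_region) || !length(background_region))
    dc_stop("dotcal_region_error", "tumor/background region is empty")
  if (length(intersect(tumor_region, background_region)) &&
      !identical(sort(tumor_region), sort(background_region)))
    dc_stop("dotcal_region_error", "tumor and background regions overlap")
  ctr <- function(v) mean(v[tumor_region], na.rm = TRUE) /
    mean(v[background_region], na.rm = TRUE)
  c(Hb = ctr(map$Hb), HbO2 = ctr(map$HbO2),
    HbT = ctr(map$HbT), StO2 = ctr(map$StO2))
}
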