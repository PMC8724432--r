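#' Build a mirrored parallel-plate source/detector array
#'
#' Sources sit on the plate at x = 0, detectors on the plate at
#' x = `plate_separation`; detector k is the mirror image of source k
#' through the mid-plane (same y and z). Rows run along y with pitch
#' `row_spacing`, columns along z with pitch `col_spacing`. Grid indices
#' are row-major and 1-based: source k = (row-1)*n_cols + col.
#'
#' @param n_rows,n_cols grid dimensions (>= 1)
#' @param row_spacing,col_spacing grid pitch along y and z (mm, > 0)
#' @param plate_separation distance between the two plates (mm, > 0)
#' @param center optional length-2 numeric `(y, z)` of the grid centroid;
#'   by default the first source sits at `(0, 0, 0)`
#' @return an object of class `probe_array` with fields
#'   `source_positions`, `detector_positions` (I x 3 matrices, mm),
#'   `I`, `J`, the grid parameters, and per-element `row`/`col` indices
#' @examples
#' p <- build_probe(7, 8, 13, 14, 44)
#' p$I # 56
#' @export
build_probe <- function(n_rows, n_cols, row_spacing, col_spacing,
                        plate_separation, center = NULL) {
  args <- c(n_rows = n_rows, n_cols = n_cols, row_spacing = row_spacing,
            col_spacing = col_spacing, plate_separation = plate_separation)
  if (any(!is.finite(args)) || any(args <= 0))
    dc_stop("dotcal_invalid_geometry",
            "probe dimensions and spacings must be positive")
  if (n_rows != round(n_rows) || n_cols != round(n_cols))
    dc_stop("dotcal_invalid_geometry", "n_rows and n_cols must be integers")

  grid <- expand.grid(col = seq_len(n_cols), row = seq_len(n_rows))
  grid <- grid[order(grid$row, grid$col), , drop = FALSE]
  y <- (grid$row - 1) * row_spacing
  z <- (grid$col - 1) * col_spacing
  if (!is.null(center)) {
    y <- y - mean(range(y)) + center[1]
    z <- z - mean(range(z)) + center[2]
  }
  n <- n_rows * n_cols
  src <- cbind(x = rep(0, n), y = y, z = z)
  det <- cbind(x = rep(plate_separation, n), y = y, z = z)
  structure(list(
    plate_separation = plate_separation,
    n_rows = n_rows, n_cols = n_cols,
    row_spacing = row_spacing, col_spacing = col_spacing,
    source_positions = src, detector_positions = det,
    I = n, J = n, row = grid$row, col = grid$col
  ), class = "probe_array")
}

#' @export
print.probe_array <- function(x, ...) {
  cat(sprintf(
    "probe_array: %d x %d mirrored grids (pitch %g x %g mm), plate separation %g mm, I = J = %d\n",
    x$n_rows, x$n_cols, x$row_spacing, x$col_spacing,
    x$plate_separation, x$I
  ))
  invisible(x)
}

#' Enumerate all source-detector pairs of a probe
#'
#' Returns the full I x J pair table in deterministic source-major order
#' (all detectors of source 1, then source 2, ...), each pair carrying
#' the Euclidean source-detector distance. Exclusion flags start clear.
#'
#' @param probe a `probe_array`
#' @return a data frame of class `sd_pairs` with columns `source_index`,
#'   `detector_index`, `distance` (mm), `excluded` (logical), `reason`
#'   (character, `NA` when retained); the probe is kept as an attribute
#' @export
enumerate_pairs <- function(probe) {
  stopifnot(inherits(probe, "probe_array"))
  idx <- expand.grid(detector_index = seq_len(probe$J),
                     source_index = seq_len(probe$I))
  idx <- idx[order(idx$source_index, idx$detector_index), , drop = FALSE]
  d <- sqrt(rowSums((probe$source_positions[idx$source_index, , drop = FALSE] -
                     probe$detector_positions[idx$detector_index, , drop = FALSE])^2))
  out <- data.frame(source_index = idx$source_index,
                    detector_index = idx$detector_index,
                    distance = d, excluded = FALSE,
                    reason = NA_character_,
                    row.names = NULL)
  class(out) <- c("sd_pairs", "data.frame")
  attr(out, "probe") <- probe
  out
}

retained <- function(pairs) !pairs$excluded

#' Group source-detector pairs into distance classes
#'
#' Pairs sharing the same SD distance form one class \eqn{\Omega_k}. The
#' grouping key is the squared distance rounded to `tolerance` (mm^2),
#' which is exact for integer-mm grid pitches and robust to floating
#' point noise. Excluded pairs are left out; the classes partition the
#' retained pair set and are sorted by distance ascending.
#'
#' @param pairs an `sd_pairs` table
#' @param tolerance grouping tolerance on the squared distance (mm^2)
#' @return an object of class `distance_classes`: a list of classes, each
#'   with `d_k` (mm), `members` (row indices into `pairs`), and
#'   measurement summaries `class_max`/`cov` (`NA` until
#'   [attach_measurements()] is called)
#' @export
group_by_distance <- function(pairs, tolerance = 1e-6) {
  stopifnot(inherits(pairs, "sd_pairs"), tolerance >= 0)
  keep <- which(retained(pairs))
  if (length(keep) == 0L)
    dc_stop("dotcal_no_data", "no retained pairs to group")
  d2 <- pairs$distance[keep]^2
  key <- if (tolerance > 0) round(d2 / tolerance) else d2
  split_idx <- split(keep, key)
  d_k <- vapply(split_idx, function(i) pairs$distance[i[1]], numeric(1))
  ord <- order(d_k)
  classes <- lapply(ord, function(o) {
    list(d_k = d_k[o], members = split_idx[[o]],
         class_max = NA_real_, cov = NA_real_)
  })
  structure(classes, class = "distance_classes",
            tolerance = tolerance, n_pairs = length(keep))
}

#' @export
print.distance_classes <- function(x, ...) {
  cat(sprintf("distance_classes: K = %d classes over %d retained pairs\n",
              length(x), attr(x, "n_pairs")))
  sizes <- vapply(x, function(cl) length(cl$members), integer(1))
  cat(sprintf("  d_k: %s mm; sizes: %s\n",
              paste(signif(vapply(x, `[[`, numeric(1), "d_k"), 4), collapse = ", "),
              paste(sizes, collapse = ", ")))
  invisible(x)
}

#' Attach measured amplitudes to distance classes
#'
#' Fills each class's `class_max` (the per-distance maximum
#' \eqn{\Gamma_k^{max}}) and coefficient of variation (sd/mean of the
#' member amplitudes; `NA` for singleton classes).
#'
#' @param classes a `distance_classes` object
#' @param measurements a `measurement_set` aligned with the pair table
#'   the classes were built from
#' @return the classes with `class_max` and `cov` filled; the role of the
#'   attached data is recorded in attribute `data_role`
#' @export
attach_measurements <- function(classes, measurements) {
  stopifnot(inherits(classes, "distance_classes"),
            inherits(measurements, "measurement_set"))
  amp <- measurements$amplitude
  out <- lapply(classes, function(cl) {
    a <- amp[cl$members]
    cl$class_max <- max(a)
    cl$cov <- if (length(a) >= 2) sd(a) / mean(a) else NA_real_
    cl
  })
  attributes(out) <- attributes(classes)
  attr(out, "data_role") <- attr(measurements, "role")
  out
}

#' Apply coverage and maximum-distance exclusions
#'
#' A pair is excluded when either endpoint is not covered by the imaging
#' object, or when its SD distance exceeds `max_distance` (110 mm by
#' default). Flags carry the reason (`"uncovered"` takes precedence over
#' `"over_max_distance"`); the original pair order is preserved and
#' previously set flags are recomputed.
#'
#' @param pairs an `sd_pairs` table
#' @param coverage `NULL` (everything covered) or a list with logical
#'   vectors `sources` (length I) and `detectors` (length J), `TRUE`
#'   meaning covered
#' @param max_distance SD-distance cutoff in mm (default 110; `Inf`
#'   disables)
#' @return the pair table with `excluded`/`reason` updated
#' @export
apply_exclusions <- function(pairs, coverage = NULL, max_distance = 110) {
  stopifnot(inherits(pairs, "sd_pairs"))
  probe <- attr(pairs, "probe")
  cov_s <- rep(TRUE, probe$I)
  cov_d <- rep(TRUE, probe$J)
  if (!is.null(coverage)) {
    if (!is.null(coverage$sources)) cov_s <- as.logical(coverage$sources)
    if (!is.null(coverage$detectors)) cov_d <- as.logical(coverage$detectors)
    if (length(cov_s) != probe$I || length(cov_d) != probe$J)
      dc_stop("dotcal_invalid_input",
              sprintf("coverage mask lengths (%d, %d) do not match I = %d, J = %d",
                      length(cov_s), length(cov_d), probe$I, probe$J))
  }
  uncov <- !cov_s[pairs$source_index] | !cov_d[pairs$detector_index]
  too_far <- pairs$distance > max_distance
  pairs$excluded <- uncov | too_far
  pairs$reason <- NA_character_
  pairs$reason[too_far] <- "over_max_distance"
  pairs$reason[uncov] <- "uncovered"
  pairs
}

# Restrict a pair table to the sources/detectors of a grid margin:
# rows in [1+m, n_rows-m], cols in [1+m, n_cols-m]. Pairs touching a
# peeled-off element are flagged "boundary".
peel_margin <- function(pairs, probe, margin) {
  ok_elem <- probe$row > margin & probe$row <= probe$n_rows - margin &
             probe$col > margin & probe$col <= probe$n_cols - margin
  peel <- !(ok_elem[pairs$source_index] & ok_elem[pairs$detector_index])
  out <- pairs
  newly <- peel & !out$excluded
  out$excluded <- out$excluded | peel
  out$reason[newly] <- "boundary"
  out
}

#' Select non-boundary pairs by ring peeling under a CoV criterion
#'
#' For a homogeneous medium, pairs at the same SD distance should read
#' the same amplitude; near the object boundary they do not, inflating
#' the coefficient of variation (CoV = sd/mean) of their distance class.
#' This routine iteratively peels the outermost ring of sources and
#' detectors (shrinking the active grid by one row and one column on
#' each side per iteration, keeping the two plates mirrored) until every
#' class with at least two members has CoV below `cov_threshold`, or the
#' grid cannot shrink further.
#'
#' @param probe the `probe_array`
#' @param pairs an `sd_pairs` table (exclusions already applied)
#' @param measurements `measurement_set` aligned with `pairs`; the CoV is
#'   computed on these amplitudes (typically the task scan)
#' @param cov_threshold division threshold between boundary and
#'   non-boundary behaviour (default 0.3)
#' @return a list with `pairs` (the reduced table, peeled pairs flagged
#'   `"boundary"`), `classes` (recomputed on the retained set with
#'   measurements attached), `report` (one row per peel iteration:
#'   margin, retained pairs, worst CoV), and `data_role`
#' @export
select_non_boundary <- function(probe, pairs, measurements,
                                cov_threshold = 0.3) {
  stopifnot(inherits(probe, "probe_array"), inherits(pairs, "sd_pairs"))
  report <- NULL
  max_margin <- floor((min(probe$n_rows, probe$n_cols) - 1) / 2)
  for (margin in 0:max_margin) {
    cand <- peel_margin(pairs, probe, margin)
    if (!any(retained(cand))) break
    classes <- attach_measurements(group_by_distance(cand), measurements)
    covs <- vapply(classes, `[[`, numeric(1), "cov")
    worst <- if (all(is.na(covs))) 0 else max(covs, na.rm = TRUE)
    report <- rbind(report, data.frame(
      margin = margin, retained_pairs = sum(retained(cand)),
      n_classes = length(classes), max_cov = worst
    ))
    if (worst <= cov_threshold) {
      return(list(pairs = cand, classes = classes, report = report,
                  data_role = attr(measurements, "role")))
    }
  }
  dc_stop("dotcal_selection_failure",
          paste0("CoV threshold ", cov_threshold,
                 " not reached before the grid was exhausted; last profile:\n",
                 paste(utils::capture.output(print(report)), collapse = "\n")),
          report = report)
}

#' Read or write a probe configuration file
#'
#' YAML or JSON (chosen by extension) with keys `n_rows`, `n_cols`,
#' `row_spacing_mm`, `col_spacing_mm`, `plate_separation_mm` and an
#' optional `coverage` list of covered source/detector indices
#' (1-based).
#'
#' @param path file path (`.yaml`/`.yml` or `.json`)
#' @return `read_probe_config`: a list with `probe` (a [build_probe()]
#'   result) and `coverage` (logical masks, or `NULL`)
#' @export
read_probe_config <- function(path) {
  cfg <- read_config_file(path)
  need <- c("n_rows", "n_cols", "row_spacing_mm", "col_spacing_mm",
            "plate_separation_mm")
  miss <- setdiff(need, names(cfg))
  if (length(miss))
    dc_stop("dotcal_invalid_input",
            paste("probe config missing fields:", paste(miss, collapse = ", ")))
  probe <- build_probe(cfg$n_rows, cfg$n_cols, cfg$row_spacing_mm,
                       cfg$col_spacing_mm, cfg$plate_separation_mm,
                       center = cfg$center_yz_mm)
  coverage <- NULL
  if (!is.null(cfg$coverage)) {
    coverage <- list(sources = seq_len(probe$I) %in% unlist(cfg$coverage$sources),
                     detectors = seq_len(probe$J) %in% unlist(cfg$coverage$detectors))
  }
  list(probe = probe, coverage = coverage)
}

#' @rdname read_probe_config
#' @param probe a `probe_array`
#' @param coverage optional coverage list as in [apply_exclusions()]
#' @export
write_probe_config <- function(probe, path, coverage = NULL) {
  cfg <- list(n_rows = probe$n_rows, n_cols = probe$n_cols,
              row_spacing_mm = probe$row_spacing,
              col_spacing_mm = probe$col_spacing,
              plate_separation_mm = probe$plate_separation,
              center_yz_mm = c(mean(range(probe$source_positions[, "y"])),
                               mean(range(probe$source_positions[, "z"]))))
  if (!is.null(coverage))
    cfg$coverage <- list(sources = which(as.logical(coverage$sources)),
                         detectors = which(as.logical(coverage$detectors)))
  write_config_file(cfg, path)
  invisible(path)
}

#' Write an exclusion report
#'
#' CSV with one row per SD pair: indices, distance, exclusion flag and
#' reason.
#'
#' @param pairs an `sd_pairs` table
#' @param path output CSV path
#' @export
write_exclusion_report <- function(pairs, path) {
  df <- data.frame(source_index = pairs$source_index,
                   detector_index = pairs$detector_index,
                   distance_mm = pairs$distance,
                   excluded = pairs$excluded,
                   reason = ifelse(is.na(pairs$reason), "", pairs$reason))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_config_file <- function(path) {
  if (!file.exists(path))
    dc_stop("dotcal_invalid_input", paste("config file not found:", path))
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else
    yaml::read_yaml(path)
}

write_config_file <- function(x, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  else
    yaml::write_yaml(x, path)
  invisible(path)
}
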