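#' Construct a measurement set
#'
#' One CW amplitude per source-detector pair, tagged with a role:
#' `"task"` (scan of the object under study), `"reference"` (scan of a
#' homogeneous reference phantom), `"predicted"` (model forward data),
#' `"estimated"` (virtual homogeneous reference built from class maxima)
#' or `"calibrated"`. The table is aligned row-for-row with the
#' `sd_pairs` table it was measured on, including its exclusion mask.
#'
#' @param pairs the `sd_pairs` table the amplitudes belong to
#' @param amplitude numeric vector, one value per row of `pairs`;
#'   non-negative on retained pairs
#' @param role one of task, reference, predicted, estimated, calibrated
#' @param wavelength wavelength in nm (optional, `NA` for monochromatic
#'   work)
#' @return a data frame of class `measurement_set` with columns
#'   `source_index`, `detector_index`, `amplitude`, `excluded`; `role`,
#'   `wavelength` and the probe travel as attributes
#' @export
measurement_set <- function(pairs, amplitude,
                            role = c("task", "reference", "predicted",
                                     "estimated", "calibrated"),
                            wavelength = NA_real_) {
  role <- match.arg(role)
  stopifnot(inherits(pairs, "sd_pairs"))
  if (length(amplitude) != nrow(pairs))
    dc_stop("dotcal_invalid_input",
            "amplitude length does not match the pair table")
  if (any(!is.finite(amplitude[retained(pairs)])) ||
      any(amplitude[retained(pairs)] < 0))
    dc_stop("dotcal_invalid_input",
            "retained amplitudes must be finite and non-negative")
  out <- data.frame(source_index = pairs$source_index,
                    detector_index = pairs$detector_index,
                    amplitude = amplitude,
                    excluded = pairs$excluded)
  class(out) <- c("measurement_set", "data.frame")
  attr(out, "role") <- role
  attr(out, "wavelength") <- wavelength
  attr(out, "probe") <- attr(pairs, "probe")
  out
}

#' @export
print.measurement_set <- function(x, ...) {
  r <- !x$excluded
  cat(sprintf(
    "measurement_set (role=%s, wavelength=%s nm): %d pairs (%d retained), amplitude range [%.3g, %.3g]\n",
    attr(x, "role"), format(attr(x, "wavelength")), nrow(x), sum(r),
    min(x$amplitude[r]), max(x$amplitude[r])
  ))
  invisible(x)
}

# check that measurement sets share the same retained pair grid
check_aligned <- function(...) {
  sets <- list(...)
  a <- sets[[1]]
  for (b in sets[-1]) {
    if (nrow(a) != nrow(b) ||
        any(a$source_index != b$source_index) ||
        any(a$detector_index != b$detector_index) ||
        any(a$excluded != b$excluded))
      dc_stop("dotcal_invalid_input",
              "measurement sets do not cover the same retained pair set")
  }
  invisible(TRUE)
}

# derive an sd_pairs view from a measurement set (for class grouping)
pairs_of <- function(meas) {
  probe <- attr(meas, "probe")
  d <- sqrt(rowSums((probe$source_positions[meas$source_index, , drop = FALSE] -
                     probe$detector_positions[meas$detector_index, , drop = FALSE])^2))
  out <- data.frame(source_index = meas$source_index,
                    detector_index = meas$detector_index,
                    distance = d, excluded = meas$excluded,
                    reason = NA_character_)
  class(out) <- c("sd_pairs", "data.frame")
  attr(out, "probe") <- probe
  out
}

#' Read or write measurement tables as CSV
#'
#' Columns: `wavelength_nm`, `source_index`, `detector_index`,
#' `amplitude`, `excluded`, `role`. `write_measurements()` accepts one
#' set or a list of per-wavelength sets; `read_measurements()` returns a
#' list of `measurement_set`s (one per role/wavelength combination
#' present), rebuilt against `probe`.
#'
#' @param x a `measurement_set` or list of them
#' @param path CSV path
#' @export
write_measurements <- function(x, path) {
  if (inherits(x, "measurement_set")) x <- list(x)
  df <- do.call(rbind, lapply(x, function(m) {
    data.frame(wavelength_nm = attr(m, "wavelength"),
               source_index = m$source_index,
               detector_index = m$detector_index,
               amplitude = m$amplitude,
               excluded = m$excluded,
               role = attr(m, "role"))
  }))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_measurements
#' @param probe the `probe_array` the measurements were taken on
#' @export
read_measurements <- function(path, probe) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("source_index", "detector_index", "amplitude", "excluded", "role")
  miss <- setdiff(need, names(df))
  if (length(miss))
    dc_stop("dotcal_invalid_input",
            paste("measurement CSV missing columns:", paste(miss, collapse = ", ")))
  if (is.null(df$wavelength_nm)) df$wavelength_nm <- NA_real_
  key <- paste(df$role, df$wavelength_nm)
  lapply(split(df, key), function(g) {
    pr <- enumerate_pairs(probe)
    idx <- match(paste(pr$source_index, pr$detector_index),
                 paste(g$source_index, g$detector_index))
    if (any(is.na(idx)))
      dc_stop("dotcal_invalid_input", "measurement CSV does not cover the probe's pairs")
    pr$excluded <- as.logical(g$excluded[idx])
    measurement_set(pr, g$amplitude[idx], role = g$role[1],
                    wavelength = g$wavelength_nm[1])
  })
}
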