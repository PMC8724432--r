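# Calibration operators. All of them act pairwise on the retained pair
# set and propagate exclusions untouched; amplitudes below AMP_FLOOR are
# treated as zero and raise a division-hazard error instead of silently
# producing huge ratios.

AMP_FLOOR <- 1e-30

check_positive_denominator <- function(x, what) {
  r <- !x$excluded
  bad <- which(r & x$amplitude <= AMP_FLOOR)
  if (length(bad))
    dc_stop("dotcal_division_hazard",
            sprintf("%s amplitude is zero (<= %g) on retained pair(s) %s",
                    what, AMP_FLOOR,
                    paste(sprintf("(s%d,d%d)", x$source_index[bad],
                                  x$detector_index[bad])[seq_len(min(5, length(bad)))],
                          collapse = ", ")))
  invisible(TRUE)
}

calibrate_ratio <- function(task, denom, predicted, denom_what) {
  check_aligned(task, denom, predicted)
  check_positive_denominator(denom, denom_what)
  amp <- rep(NA_real_, nrow(task))
  r <- !task$excluded
  amp[r] <- task$amplitude[r] / denom$amplitude[r] * predicted$amplitude[r]
  amp[!r] <- task$amplitude[!r] # carried along, still flagged excluded
  out <- task
  out$amplitude <- amp
  attr(out, "role") <- "calibrated"
  out
}

#' Reference-phantom calibration
#'
#' Conventional relative calibration against a scan of a homogeneous
#' reference phantom with the task's shape and background optics:
#' \deqn{\Gamma^* = (\Gamma_{tsk} / \Gamma_{ref})\, \Gamma_{pre}}
#' pairwise over the retained pair set. Multiplicative per-channel
#' gains common to task and reference cancel exactly.
#'
#' @param task,reference,predicted aligned `measurement_set`s sharing
#'   the retained pair set: the task scan, the reference-phantom scan,
#'   and the model forward data of the homogeneous medium
#' @return a `measurement_set` with role `"calibrated"`
#' @export
reference_calibrate <- function(task, reference, predicted) {
  calibrate_ratio(task, reference, predicted, "reference")
}

#' Build the virtual homogeneous reference from task data
#'
#' For each distance class \eqn{\Omega_k} the maximum task amplitude
#' \eqn{\Gamma_k^{max}} is taken as the estimate of what a homogeneous
#' medium would have produced at that SD distance (the member that best
#' avoided the absorbing heterogeneity), and assigned to every member
#' of the class. Exclusions and any non-boundary selection must already
#' be applied: the classes are expected to partition the retained pairs
#' of `task`.
#'
#' @param task the task `measurement_set`
#' @param classes `distance_classes` built on the retained pairs of
#'   `task` (see [group_by_distance()]); built automatically when
#'   omitted
#' @return a `measurement_set` with role `"estimated"`, class-constant
#'   and pairwise `>=` the task amplitudes
#' @export
build_virtual_reference <- function(task, classes = NULL) {
  stopifnot(inherits(task, "measurement_set"))
  if (sum(!task$excluded) == 0L)
    dc_stop("dotcal_no_data", "no retained pairs to estimate a reference from")
  if (is.null(classes)) classes <- group_by_distance(pairs_of(task))
  covered <- sort(unlist(lapply(classes, `[[`, "members")))
  if (!identical(covered, which(!task$excluded)))
    dc_stop("dotcal_invalid_input",
            "distance classes do not partition the retained pairs of the task set")
  amp <- task$amplitude
  for (cl in classes) amp[cl$members] <- max(task$amplitude[cl$members])
  out <- task
  out$amplitude <- amp
  attr(out, "role") <- "estimated"
  out
}

#' Data self-calibration with the virtual reference
#'
#' Identical in form to [reference_calibrate()] but with the virtual
#' homogeneous reference in the denominator:
#' \deqn{\Gamma^{**} = (\Gamma_{tsk} / \Gamma_{est})\, \Gamma_{pre}.}
#' Since \eqn{\Gamma_{est} \ge \Gamma_{tsk}} pairwise, the calibrated
#' amplitudes never exceed the model prediction. A global scale applied
#' to the task scan cancels exactly.
#'
#' @param task the task `measurement_set`
#' @param estimated the virtual reference from
#'   [build_virtual_reference()]; built from `task` when omitted
#' @param predicted model forward data of the homogeneous medium
#' @return a `measurement_set` with role `"calibrated"`
#' @export
self_calibrate <- function(task, estimated = NULL, predicted) {
  if (is.null(estimated)) estimated <- build_virtual_reference(task)
  calibrate_ratio(task, estimated, predicted, "estimated")
}

#' Mean relative error between two measurement sets
#'
#' \deqn{error = mean(|\Gamma_{est} - \Gamma_{ref}| / \Gamma_{ref})}
#' over the retained pair set, reported overall and per distance class.
#' This is the fidelity metric of the virtual reference against a true
#' homogeneous reference.
#'
#' @param estimated,reference aligned `measurement_set`s
#' @param classes optional `distance_classes` for the per-class report
#' @return a list with `overall` (dimensionless fraction), `n_pairs`,
#'   and `per_class` (data frame `d_k`, `n`, `error`; `NULL` when no
#'   classes are given)
#' @export
mean_relative_error <- function(estimated, reference, classes = NULL) {
  check_aligned(estimated, reference)
  check_positive_denominator(reference, "reference")
  r <- !estimated$excluded
  if (!any(r)) dc_stop("dotcal_no_data", "no retained pairs")
  rel <- abs(estimated$amplitude - reference$amplitude) / reference$amplitude
  per_class <- NULL
  if (!is.null(classes)) {
    per_class <- data.frame(
      d_k = vapply(classes, `[[`, numeric(1), "d_k"),
      n = vapply(classes, function(cl) length(cl$members), integer(1)),
      error = vapply(classes, function(cl) mean(rel[cl$members]), numeric(1))
    )
  }
  list(overall = mean(rel[r]), n_pairs = sum(r), per_class = per_class)
}

#' Calibration report
#'
#' Per-distance-class summary of a self-calibration run: distance,
#' member count, class maximum, coefficient of variation, and (when a
#' true reference is available) the per-class and overall mean relative
#' error of the virtual reference. Serializable to JSON.
#'
#' @param task the task `measurement_set`
#' @param classes `distance_classes` with measurements attached (see
#'   [attach_measurements()]); attached automatically when not yet done
#' @param reference optional homogeneous reference `measurement_set`
#' @param path optional path to also write the report as JSON
#' @return a list with `classes` (data frame), `overall_error`,
#'   `n_retained`, `data_role`
#' @export
calibration_report <- function(task, classes = NULL, reference = NULL,
                               path = NULL) {
  if (is.null(classes)) classes <- group_by_distance(pairs_of(task))
  if (is.na(classes[[1]]$class_max)) classes <- attach_measurements(classes, task)
  df <- data.frame(
    d_k = vapply(classes, `[[`, numeric(1), "d_k"),
    n = vapply(classes, function(cl) length(cl$members), integer(1)),
    class_max = vapply(classes, `[[`, numeric(1), "class_max"),
    cov = vapply(classes, `[[`, numeric(1), "cov")
  )
  overall <- NA_real_
  if (!is.null(reference)) {
    est <- build_virtual_reference(task, classes)
    err <- mean_relative_error(est, reference, classes)
    df$error <- err$per_class$error
    overall <- err$overall
  }
  rep <- list(classes = df, overall_error = overall,
              n_retained = sum(!task$excluded),
              data_role = attr(task, "role"))
  if (!is.null(path))
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", pretty = TRUE)
  rep
}
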