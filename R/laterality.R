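#' Assign a lesion to the left or right hemisphere (or midline)
#'
#' The occupancy-weighted centroid of the mask is taken in world
#' coordinates (RAS+, so negative x is the left hemisphere). Centroids
#' within \code{epsilon} mm of the mid-sagittal plane are called midline;
#' the buffer absorbs registration slop and blobs straddling x = 0.
#'
#' @param mask a nonempty \code{lesion_mask}.
#' @param grid grid; defaults to the mask's.
#' @param epsilon midline half-width in mm.
#' @return \code{"left"}, \code{"right"} or \code{"midline"}.
#' @export
hemisphere_assignment <- function(mask, grid = mask$grid, epsilon = 2) {
  if (!mask$voxel_count) stop("empty mask has no laterality", call. = FALSE)
  vox <- arrayInd(mask$indices, grid$shape) - 1L
  cx <- mean(voxel_to_world(grid, vox)[, 1])
  if (cx < -epsilon) "left" else if (cx > epsilon) "right" else "midline"
}

#' Exact binomial test of hemispheric balance
#'
#' Two-sided exact binomial test of left vs right counts against an even
#' 50/50 split; midline lesions are excluded before calling.
#'
#' @param n_left,n_right lateralized lesion counts.
#' @return two-sided p-value.
#' @examples
#' laterality_test(10, 0)  # 2/1024
#' @export
laterality_test <- function(n_left, n_right) {
  if (n_left + n_right < 1)
    stop("no lateralized lesions to test", call. = FALSE)
  stats::binom.test(n_left, n_left + n_right, p = 0.5)$p.value
}

#' Per-patient laterality with stratified balance tests
#'
#' Assigns every mask a hemisphere and tests left/right balance overall and
#' within the requested strata (records columns such as
#' \code{location_label}, \code{sex}, \code{who_grade}). Midline lesions
#' are counted but excluded from each binomial test.
#'
#' @param x a \code{\link{cohort}}.
#' @param masks named list of \code{lesion_mask}.
#' @param by character vector of records columns to stratify on.
#' @param epsilon midline half-width in mm.
#' @return list with \code{per_patient} (patient_id, side) and
#'   \code{tests} (stratum, level, n_left, n_right, n_midline, p).
#' @export
laterality_summary <- function(x, masks,
                               by = c("location_label", "sex",
                                      "who_grade"),
                               epsilon = 2) {
  stopifnot(inherits(x, "cohort"))
  side <- vapply(masks, hemisphere_assignment, character(1),
                 epsilon = epsilon)
  per_patient <- data.frame(patient_id = names(masks), side = side,
                            stringsAsFactors = FALSE, row.names = NULL)
  rec <- x$records[match(per_patient$patient_id, x$records$patient_id), ]
  test_row <- function(stratum, level, sides) {
    nl <- sum(sides == "left"); nr <- sum(sides == "right")
    data.frame(stratum = stratum, level = level, n_left = nl,
               n_right = nr, n_midline = sum(sides == "midline"),
               p = if (nl + nr >= 1) laterality_test(nl, nr) else NA_real_,
               stringsAsFactors = FALSE)
  }
  tests <- test_row("overall", "all", per_patient$side)
  for (col in by) {
    for (lev in sort(unique(rec[[col]][!is.na(rec[[col]])]))) {
      sel <- !is.na(rec[[col]]) & rec[[col]] == lev
      tests <- rbind(tests, test_row(col, lev, per_patient$side[sel]))
    }
  }
  rownames(tests) <- NULL
  list(per_patient = per_patient, tests = tests)
}
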