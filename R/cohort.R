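#' The fixed 15-category lesion-location vocabulary
#'
#' Dural attachment sites used to classify meningioma location: convexity,
#' parasagittal sinus, falx, tentorium, cerebellar convexity,
#' cerebellopontine angle (CPA), sphenoid wing, parasellar/cavernous sinus,
#' tuberculum sellae/planum sphenoidale/anterior clinoid process, middle
#' fossa, olfactory groove, clival-petroclival, foramen magnum,
#' intraventricular, and others (multiple/orbital/jugular foramen).
#'
#' @return character vector of the 15 category labels, in canonical order.
#' @export
location_levels <- function() {
  c("convexity", "parasagittal_sinus", "falx", "tentorium",
    "cerebellar_convexity", "cpa", "sphenoid_wing", "parasellar_cavernous",
    "tuberculum_sellae", "middle_fossa", "olfactory_groove",
    "clival_petroclival", "foramen_magnum", "intraventricular", "others")
}

#' Immunohistochemical marker column names
#'
#' @return character vector: p53, Ki67_gt5pct (Ki67 index above 5 percent),
#'   EMA, PR, CD34.
#' @export
marker_names <- function() c("p53", "Ki67_gt5pct", "EMA", "PR", "CD34")

cohort_columns <- function() {
  c("patient_id", "age", "sex", "who_grade", "location_label", "eor",
    "recurrence", "followup_time", marker_names(), "mask_path")
}

# normalise "" / NA-ish strings to NA, keep factors out
blank_to_na <- function(x) {
  x <- as.character(x)
  x[!is.na(x) & (x == "" | x == "NA")] <- NA_character_
  x
}

check_levels <- function(x, allowed, field) {
  bad <- setdiff(unique(x[!is.na(x)]), allowed)
  if (length(bad))
    stop("invalid ", field, " value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
}

#' Assemble a validated cohort
#'
#' @param records data frame with columns \code{patient_id}, \code{age},
#'   \code{sex} (\code{male}/\code{female}), \code{who_grade}
#'   (\code{I}/\code{II}/\code{III}), \code{location_label} (one of
#'   \code{\link{location_levels}}), \code{eor} (\code{GTR}/\code{STR} or
#'   missing), \code{recurrence} (\code{yes}/\code{no} or missing),
#'   \code{followup_time} (months), the five marker columns
#'   (\code{positive}/\code{negative} or missing) and \code{mask_path}.
#'   Missing values are retained and excluded per-analysis, never imputed.
#' @param grid the shared \code{template_grid} (may be \code{NULL} for
#'   table-only analyses).
#' @return Object of class \code{cohort}: list(records, grid, n).
#' @export
cohort <- function(records, grid = NULL) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  missing_cols <- setdiff(setdiff(cohort_columns(), "mask_path"),
                          names(records))
  if (length(missing_cols))
    stop("cohort table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (!"mask_path" %in% names(records)) records$mask_path <- NA_character_
  records$patient_id <- as.character(records$patient_id)
  dup <- unique(records$patient_id[duplicated(records$patient_id)])
  if (length(dup))
    stop("duplicate patient_id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  for (col in c("sex", "who_grade", "location_label", "eor", "recurrence",
                marker_names(), "mask_path"))
    records[[col]] <- blank_to_na(records[[col]])
  records$age <- as.numeric(records$age)
  records$followup_time <- as.numeric(records$followup_time)
  if (any(!is.na(records$age) & records$age < 0))
    stop("age must be nonnegative", call. = FALSE)
  if (any(!is.na(records$followup_time) & records$followup_time < 0))
    stop("followup_time must be nonnegative", call. = FALSE)
  check_levels(records$sex, c("male", "female"), "sex")
  check_levels(records$who_grade, c("I", "II", "III"), "who_grade")
  check_levels(records$location_label, location_levels(), "location_label")
  check_levels(records$eor, c("GTR", "STR"), "eor")
  check_levels(records$recurrence, c("yes", "no"), "recurrence")
  for (m in marker_names())
    check_levels(records[[m]], c("positive", "negative"), m)
  structure(list(records = records, grid = grid, n = nrow(records)),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort> n = ", x$n, " patients; ",
      sum(!is.na(x$records$mask_path)), " with mask paths\n", sep = "")
  invisible(x)
}

#' Read a cohort covariate table from CSV
#'
#' Expects a header naming the columns of \code{\link{cohort}}. Records with
#' missing EOR (or other missing covariates) are kept and flagged missing;
#' analyses stratified on a covariate exclude its missing records.
#'
#' @param path CSV file.
#' @param grid optional \code{template_grid} carried on the cohort.
#' @return a \code{cohort}.
#' @export
read_cohort_table <- function(path, grid = NULL) {
  if (!file.exists(path))
    stop("cannot read cohort table: ", path, call. = FALSE)
  records <- utils::read.csv(path, stringsAsFactors = FALSE,
                             colClasses = "character")
  cohort(records, grid = grid)
}

#' Write a cohort covariate table to CSV
#'
#' @param x a \code{cohort}.
#' @param path output CSV file.
#' @return \code{path}, invisibly.
#' @export
write_cohort_table <- function(x, path) {
  utils::write.csv(x$records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Load the lesion masks referenced by a cohort table
#'
#' @param x a \code{cohort} whose records carry \code{mask_path}.
#' @param grid the shared grid (defaults to the cohort's).
#' @param base_dir optional directory against which relative mask paths are
#'   resolved.
#' @return named list of \code{lesion_mask}, one per record with a path.
#' @export
read_cohort_masks <- function(x, grid = x$grid, base_dir = NULL) {
  stopifnot(inherits(x, "cohort"))
  if (is.null(grid)) stop("a template grid is required", call. = FALSE)
  rec <- x$records[!is.na(x$records$mask_path), , drop = FALSE]
  masks <- vector("list", nrow(rec))
  for (i in seq_len(nrow(rec))) {
    p <- rec$mask_path[i]
    if (!is.null(base_dir) && !file.exists(p)) p <- file.path(base_dir, p)
    masks[[i]] <- read_mask_file(p, grid, patient_id = rec$patient_id[i])
  }
  names(masks) <- rec$patient_id
  masks
}
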