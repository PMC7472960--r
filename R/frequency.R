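# round half away from zero at `digits` decimals (printed-table style)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Superimpose lesion masks into a per-voxel frequency map
#'
#' counts(v) is the number of masks occupying voxel v; percentage(v) is
#' 100 * counts(v) / n with the full cohort size n as denominator, i.e. the
#' share of patients whose lesion covers that voxel.
#'
#' @param masks list of \code{lesion_mask} on one shared grid.
#' @param n cohort size (denominator); defaults to \code{length(masks)} and
#'   must be at least that.
#' @return Object of class \code{frequency_map}: \code{counts} (integer 3D
#'   array), \code{percentage} (3D array), \code{n}, \code{grid}.
#' @export
build_frequency_map <- function(masks, n = length(masks)) {
  if (!length(masks)) stop("no masks supplied", call. = FALSE)
  if (n < length(masks) || n < 1)
    stop("n must be at least the number of masks and positive",
         call. = FALSE)
  grid <- masks[[1L]]$grid
  for (m in masks)
    if (!grids_match(grid, m$grid))
      stop_grid_mismatch("masks do not share one grid")
  nvox <- prod(grid$shape)
  counts <- tabulate(unlist(lapply(masks, `[[`, "indices"),
                            use.names = FALSE), nbins = nvox)
  counts <- array(as.integer(counts), dim = grid$shape)
  structure(list(counts = counts, percentage = 100 * counts / n,
                 n = as.integer(n), grid = grid),
            class = "frequency_map")
}

#' @export
print.frequency_map <- function(x, ...) {
  cat("<frequency_map> n = ", x$n, "; max count ", max(x$counts),
      " (", format(round(max(x$percentage), 2)), "%)\n", sep = "")
  invisible(x)
}

#' Cap a percentage map for display
#'
#' Color scales for frequency heatmaps typically saturate at a low
#' percentage (e.g. 5 percent and above share one colour); this returns the
#' percentage array clipped at \code{cap} without modifying the map.
#'
#' @param map a \code{frequency_map}.
#' @param cap positive percentage at which to saturate.
#' @return 3D array of capped percentages.
#' @export
clip_for_display <- function(map, cap = 5) {
  stopifnot(inherits(map, "frequency_map"))
  if (cap <= 0) stop("cap must be positive", call. = FALSE)
  pmin(map$percentage, cap)
}

#' Cohort demographic and location summary
#'
#' Tabulates location categories, WHO grades, sex within grade groupings,
#' per-grade recurrence rates and extent-of-resection availability, with
#' percentages rounded half away from zero to one decimal and denominators
#' reported.
#'
#' @param x a \code{\link{cohort}}.
#' @return Object of class \code{cohort_summary} with data-frame components
#'   \code{locations}, \code{grades}, \code{sex_by_grade} (grade I vs
#'   grades II+III), \code{recurrence_by_grade}, \code{eor}, and \code{n}.
#' @export
location_summary <- function(x) {
  stopifnot(inherits(x, "cohort"))
  if (x$n == 0L) stop("empty cohort", call. = FALSE)
  r <- x$records
  n <- x$n
  loc_count <- as.integer(table(factor(r$location_label,
                                       levels = location_levels())))
  locations <- data.frame(
    category = location_levels(), count = loc_count,
    percent = round_half_up(100 * loc_count / n, 1))
  gl <- c("I", "II", "III")
  g_count <- as.integer(table(factor(r$who_grade, levels = gl)))
  grades <- data.frame(grade = gl, count = g_count,
                       percent = round_half_up(100 * g_count / n, 1))
  grp <- ifelse(r$who_grade == "I", "I", "II+III")
  sex_by_grade <- do.call(rbind, lapply(c("I", "II+III"), function(g) {
    sub <- r[!is.na(grp) & grp == g, ]
    nf <- sum(sub$sex == "female", na.rm = TRUE)
    nm <- sum(sub$sex == "male", na.rm = TRUE)
    data.frame(grade_group = g, n = nrow(sub), female = nf, male = nm,
               female_pct = round_half_up(100 * nf / nrow(sub), 1),
               male_pct = round_half_up(100 * nm / nrow(sub), 1))
  }))
  recurrence_by_grade <- do.call(rbind, lapply(gl, function(g) {
    sub <- r[!is.na(r$who_grade) & r$who_grade == g, ]
    ev <- sum(sub$recurrence == "yes", na.rm = TRUE)
    data.frame(grade = g, n = nrow(sub), recurrences = ev,
               rate_pct = round_half_up(100 * ev / nrow(sub), 1))
  }))
  n_gtr <- sum(r$eor == "GTR", na.rm = TRUE)
  n_str <- sum(r$eor == "STR", na.rm = TRUE)
  n_missing <- sum(is.na(r$eor))
  eor <- data.frame(
    evaluable_n = n_gtr + n_str, gtr = n_gtr, str = n_str,
    missing = n_missing,
    gtr_pct = round_half_up(100 * n_gtr / (n_gtr + n_str), 1),
    str_pct = round_half_up(100 * n_str / (n_gtr + n_str), 1))
  structure(list(n = n, locations = locations, grades = grades,
                 sex_by_grade = sex_by_grade,
                 recurrence_by_grade = recurrence_by_grade, eor = eor),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort summary (n = ", x$n, ")\n\nLocations:\n", sep = "")
  print(x$locations, row.names = FALSE)
  cat("\nWHO grades:\n")
  print(x$grades, row.names = FALSE)
  cat("\nSex by grade group:\n")
  print(x$sex_by_grade, row.names = FALSE)
  cat("\nRecurrence by grade:\n")
  print(x$recurrence_by_grade, row.names = FALSE)
  cat("\nExtent of resection (evaluable n = ", x$eor$evaluable_n, "):\n",
      sep = "")
  print(x$eor, row.names = FALSE)
  invisible(x)
}
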