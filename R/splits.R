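#' Define a two-level phenotype split
#'
#' A split maps each patient record to group A, group B, or excluded
#' (missing covariate). Group A is the first-named phenotype throughout
#' reporting.
#'
#' @param name split label used in filenames and reports.
#' @param assign function taking the cohort records data frame and
#'   returning a character vector of \code{"A"}, \code{"B"} or \code{NA}.
#' @param label_a,label_b human-readable group descriptions.
#' @return object of class \code{phenotype_split}.
#' @export
phenotype_split <- function(name, assign, label_a = "A", label_b = "B") {
  stopifnot(is.function(assign))
  structure(list(name = name, assign = assign,
                 label_a = label_a, label_b = label_b),
            class = "phenotype_split")
}

#' @rdname phenotype_split
#' @param covariate numeric covariate name.
#' @param cutoff threshold; group A is \code{covariate >= cutoff}.
#' @export
split_threshold <- function(name, covariate, cutoff) {
  phenotype_split(
    name,
    function(records) {
      v <- as.numeric(records[[covariate]])
      ifelse(is.na(v), NA_character_, ifelse(v >= cutoff, "A", "B"))
    },
    label_a = paste0(covariate, " >= ", cutoff),
    label_b = paste0(covariate, " < ", cutoff))
}

#' @rdname phenotype_split
#' @param levels_a covariate values forming group A.
#' @param levels_b covariate values forming group B; default: every other
#'   non-missing value.
#' @export
split_levels <- function(name, covariate, levels_a, levels_b = NULL) {
  phenotype_split(
    name,
    function(records) {
      v <- records[[covariate]]
      out <- rep(NA_character_, length(v))
      out[v %in% levels_a] <- "A"
      if (is.null(levels_b)) out[!is.na(v) & !(v %in% levels_a)] <- "B"
      else out[v %in% levels_b] <- "B"
      out
    },
    label_a = paste(levels_a, collapse = "/"),
    label_b = if (is.null(levels_b)) "rest"
              else paste(levels_b, collapse = "/"))
}

#' The default roster of phenotype splits
#'
#' Ten two-group comparisons: age at the median cutoff of 56 years, sex,
#' WHO grade I vs II+III, GTR vs STR, recurrence, and positivity of p53,
#' Ki67 (>5 percent), EMA, PR and CD34.
#'
#' @param age_cutoff age threshold in years.
#' @return named list of \code{\link{phenotype_split}} objects.
#' @export
default_splits <- function(age_cutoff = 56) {
  out <- list(
    age = split_threshold("age", "age", age_cutoff),
    sex = split_levels("sex", "sex", "male", "female"),
    grade = split_levels("grade", "who_grade", c("II", "III"), "I"),
    eor = split_levels("eor", "eor", "GTR", "STR"),
    recurrence = split_levels("recurrence", "recurrence", "yes", "no"))
  for (m in marker_names())
    out[[tolower(m)]] <- split_levels(tolower(m), m, "positive", "negative")
  out
}

#' Apply a split to a cohort
#'
#' @param x a \code{\link{cohort}}.
#' @param split a \code{\link{phenotype_split}}.
#' @return list with \code{groups} (character vector over records),
#'   \code{ids_a}, \code{ids_b}, \code{nA}, \code{nB},
#'   \code{excluded_n}.
#' @export
stratify_cohort <- function(x, split) {
  stopifnot(inherits(x, "cohort"), inherits(split, "phenotype_split"))
  g <- split$assign(x$records)
  if (length(g) != x$n || !all(g %in% c("A", "B", NA)))
    stop("split assignment must map every record to A, B or NA",
         call. = FALSE)
  ids_a <- x$records$patient_id[!is.na(g) & g == "A"]
  ids_b <- x$records$patient_id[!is.na(g) & g == "B"]
  if (!length(ids_a) || !length(ids_b))
    warning("split '", split$name, "' leaves an empty group", call. = FALSE)
  list(groups = g, ids_a = ids_a, ids_b = ids_b,
       nA = length(ids_a), nB = length(ids_b),
       excluded_n = sum(is.na(g)), split = split)
}
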