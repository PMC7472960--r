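#' Kaplan-Meier product-limit estimate
#'
#' At tied times, events are processed before censorings (the standard
#' convention). The returned step function starts at 1 and changes only at
#' event times.
#'
#' @param times follow-up durations (nonnegative).
#' @param events event indicators (1/TRUE = recurrence, 0/FALSE =
#'   censored).
#' @return Object of class \code{survival_curve}: data frame with columns
#'   \code{time}, \code{n_risk}, \code{n_event}, \code{n_censor},
#'   \code{survival}.
#' @examples
#' km_estimate(c(1, 2, 3), c(1, 1, 1))$survival  # 2/3, 1/3, 0
#' @export
km_estimate <- function(times, events) {
  times <- as.numeric(times)
  events <- as.integer(as.logical(events))
  if (length(times) != length(events))
    stop("times and events must have equal length", call. = FALSE)
  if (any(!is.finite(times)) || any(times < 0))
    stop("times must be nonnegative", call. = FALSE)
  sf <- survival::survfit(survival::Surv(times, events) ~ 1,
                          conf.type = "none")
  out <- data.frame(time = sf$time, n_risk = sf$n.risk,
                    n_event = sf$n.event, n_censor = sf$n.censor,
                    survival = sf$surv)
  structure(out, class = c("survival_curve", "data.frame"))
}

#' Survival probability at given times
#'
#' @param curve a \code{\link{km_estimate}} result.
#' @param t times at which to evaluate the step function.
#' @return survival probabilities (1 before the first event).
#' @export
km_survival_at <- function(curve, t) {
  ev <- curve[curve$n_event > 0, , drop = FALSE]
  vapply(t, function(tt) {
    past <- ev$time <= tt
    if (!any(past)) 1 else ev$survival[max(which(past))]
  }, numeric(1))
}

#' Two-group log-rank test
#'
#' Standard one-degree-of-freedom log-rank chi-square over the pooled
#' distinct event times with the hypergeometric variance.
#'
#' @param times_a,events_a group A durations and event indicators.
#' @param times_b,events_b group B durations and event indicators.
#' @return list with \code{statistic}, \code{df}, \code{p},
#'   \code{observed} and \code{expected} per group.
#' @export
logrank_test <- function(times_a, events_a, times_b, events_b) {
  if (!length(times_a) || !length(times_b))
    stop("both groups must be nonempty", call. = FALSE)
  events_a <- as.integer(as.logical(events_a))
  events_b <- as.integer(as.logical(events_b))
  if (sum(events_a) + sum(events_b) == 0)
    stop("no events in either group: the log-rank test is undefined",
         call. = FALSE)
  tm <- c(as.numeric(times_a), as.numeric(times_b))
  ev <- c(events_a, events_b)
  gp <- rep(c("A", "B"), c(length(times_a), length(times_b)))
  sd <- survival::survdiff(survival::Surv(tm, ev) ~ gp)
  list(statistic = unname(sd$chisq), df = 1L,
       p = stats::pchisq(sd$chisq, df = 1L, lower.tail = FALSE),
       observed = unname(sd$obs), expected = unname(sd$exp))
}

#' Recurrence-free survival comparison for a phenotype split
#'
#' Applies the split to the cohort (records with a missing covariate or
#' missing follow-up are excluded and counted), estimates the Kaplan-Meier
#' curve per group, and runs the two-group log-rank test.
#'
#' @param x a \code{\link{cohort}} with \code{recurrence} and
#'   \code{followup_time} filled in.
#' @param split a \code{\link{phenotype_split}}.
#' @return list with \code{split_name}, \code{curve_a}, \code{curve_b},
#'   \code{nA}, \code{nB}, \code{excluded_n}, \code{test} (log-rank
#'   result).
#' @export
rfs_comparison <- function(x, split) {
  strat <- stratify_cohort(x, split)
  r <- x$records
  usable <- !is.na(r$followup_time) & !is.na(r$recurrence)
  a <- usable & !is.na(strat$groups) & strat$groups == "A"
  b <- usable & !is.na(strat$groups) & strat$groups == "B"
  if (!sum(a) || !sum(b))
    stop("split '", split$name, "' leaves an empty survival group",
         call. = FALSE)
  ev <- as.integer(r$recurrence == "yes")
  list(split_name = split$name,
       curve_a = km_estimate(r$followup_time[a], ev[a]),
       curve_b = km_estimate(r$followup_time[b], ev[b]),
       nA = sum(a), nB = sum(b),
       excluded_n = x$n - sum(a) - sum(b),
       test = logrank_test(r$followup_time[a], ev[a],
                           r$followup_time[b], ev[b]))
}

#' Volume-threshold phenotype split from masks
#'
#' Builds the dichotomization of preoperative lesion size at a volume
#' cutoff (group A: volume >= cutoff), computing each patient's volume from
#' their mask.
#'
#' @param masks named list of \code{lesion_mask}.
#' @param cutoff_cm3 volume threshold in cm^3.
#' @param grid grid supplying the voxel volume; defaults to the first
#'   mask's.
#' @return a \code{\link{phenotype_split}} named \code{"volume"}.
#' @export
split_volume <- function(masks, cutoff_cm3 = 22.828,
                         grid = masks[[1L]]$grid) {
  vols <- vapply(masks, function(m) lesion_volume(m, grid)$volume_cm3,
                 numeric(1))
  phenotype_split(
    "volume",
    function(records) {
      v <- unname(vols[records$patient_id])
      ifelse(is.na(v), NA_character_,
             ifelse(v >= cutoff_cm3, "A", "B"))
    },
    label_a = paste0("volume >= ", cutoff_cm3, " cm^3"),
    label_b = paste0("volume < ", cutoff_cm3, " cm^3"))
}
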