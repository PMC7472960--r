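#' Default location category weights
#'
#' Per-category patient counts of the reference demographic surface the
#' generator emulates (a 1,107-patient single-center meningioma series);
#' used as the default sampling weights for synthetic cohorts.
#'
#' @return named integer vector over \code{\link{location_levels}};
#'   sums to 1107.
#' @export
default_location_counts <- function() {
  stats::setNames(
    c(230L, 179L, 126L, 94L, 10L, 86L, 109L, 32L, 84L, 14L, 66L, 21L, 3L,
      22L, 31L),
    location_levels())
}

reference_counts <- function() {
  list(
    n = 1107L,
    locations = default_location_counts(),
    grades = c(I = 993L, II = 101L, III = 13L),
    # female/male within grade
    sex_by_grade = list(I = c(female = 717L, male = 276L),
                        II = c(female = 60L, male = 41L),
                        III = c(female = 8L, male = 5L)),
    recurrence_by_grade = c(I = 28L, II = 8L, III = 7L),
    eor = c(GTR = 945L, STR = 105L, missing = 57L))
}

#' Planted spatial enrichment of one phenotype
#'
#' Describes an association between a categorical phenotype and a location
#' category: patients whose covariate value lies in \code{levels} have their
#' sampling weight for \code{region} multiplied by \code{odds_multiplier}.
#' Used for parameter-recovery tests of the voxel-wise comparison.
#'
#' @param covariate covariate name (\code{who_grade}, \code{sex}, or a
#'   marker of \code{\link{marker_names}}).
#' @param levels covariate values defining the enriched phenotype.
#' @param region location category name or id receiving the enrichment.
#' @param odds_multiplier positive weight multiplier.
#' @param side optional \code{"left"}/\code{"right"}: pin the enriched
#'   phenotype's lesions in a bilateral region to one hemisphere.
#' @return object of class \code{effect_spec}.
#' @export
effect_spec <- function(covariate, levels, region, odds_multiplier,
                        side = NULL) {
  if (!is.numeric(odds_multiplier) || odds_multiplier <= 0)
    stop("odds_multiplier must be > 0", call. = FALSE)
  if (is.character(region)) region <- match(region, location_levels())
  if (is.na(region) || region < 1 || region > 15)
    stop("unknown effect region", call. = FALSE)
  if (!covariate %in% c("who_grade", "sex", marker_names()))
    stop("effect covariate must be who_grade, sex, or a marker",
         call. = FALSE)
  structure(list(covariate = covariate, levels = levels,
                 region = as.integer(region),
                 odds_multiplier = as.numeric(odds_multiplier), side = side),
            class = "effect_spec")
}

#' Configuration of the synthetic cohort generator
#'
#' Defaults reproduce the marginal structure of the reference series: the
#' 15-category location weights of \code{\link{default_location_counts}},
#' grade shares 993/101/13, female share 785/1107, recurrence rates
#' 2.8/7.9/53.8 percent for grades I/II/III, extent-of-resection shares
#' 945 GTR / 105 STR / 57 missing, age normal(56, 14) clipped to 13-85
#' years, and lognormal lesion volumes with median 22,828 mm^3
#' (sdlog 1.4, back-solved from the reported confidence interval of the
#' median). Marker positivity rates are generator choices.
#'
#' @param n_patients cohort size.
#' @param seed integer seed; every random draw derives from it.
#' @param location_probs 15 nonnegative weights (normalised internally).
#' @param volume_log_mean,volume_log_sd lognormal parameters of lesion
#'   volume in mm^3.
#' @param grade_probs 3 weights for WHO grades I/II/III.
#' @param sex_female_prob probability of female sex.
#' @param age_mean,age_sd,age_range normal age model (years), clipped.
#' @param recurrence_rate_by_grade per-grade recurrence probabilities.
#' @param followup_horizon follow-up horizon in months; non-recurrent
#'   patients are censored there.
#' @param eor_probs weights for GTR / STR / missing EOR.
#' @param marker_pos_probs named positivity probabilities for the five
#'   markers.
#' @param effect optional \code{\link{effect_spec}}; \code{NULL} means the
#'   phenotype-location null holds by construction.
#' @return object of class \code{simulation_config}.
#' @export
simulation_config <- function(n_patients,
                              seed,
                              location_probs = default_location_counts(),
                              volume_log_mean = log(22828),
                              volume_log_sd = 1.4,
                              grade_probs = c(993, 101, 13),
                              sex_female_prob = 785 / 1107,
                              age_mean = 56, age_sd = 14,
                              age_range = c(13, 85),
                              recurrence_rate_by_grade =
                                c(0.028, 0.079, 0.538),
                              followup_horizon = 60,
                              eor_probs = c(945, 105, 57),
                              marker_pos_probs = c(p53 = 0.30,
                                                   Ki67_gt5pct = 0.20,
                                                   EMA = 0.85, PR = 0.60,
                                                   CD34 = 0.40),
                              effect = NULL) {
  if (n_patients < 1) stop("n_patients must be >= 1", call. = FALSE)
  if (missing(seed) || !is.finite(seed))
    stop("an integer seed is required", call. = FALSE)
  norm1 <- function(w, k, what) {
    if (length(w) != k || any(w < 0) || sum(w) <= 0)
      stop(what, " must be ", k, " nonnegative weights", call. = FALSE)
    w / sum(w)
  }
  if (any(recurrence_rate_by_grade < 0 | recurrence_rate_by_grade > 1))
    stop("recurrence rates must lie in [0, 1]", call. = FALSE)
  if (!is.null(effect) && !inherits(effect, "effect_spec"))
    stop("effect must be an effect_spec", call. = FALSE)
  structure(list(
    n_patients = as.integer(n_patients), seed = as.integer(seed),
    location_probs = norm1(location_probs, 15L, "location_probs"),
    volume_log_mean = volume_log_mean, volume_log_sd = volume_log_sd,
    grade_probs = norm1(grade_probs, 3L, "grade_probs"),
    sex_female_prob = sex_female_prob,
    age_mean = age_mean, age_sd = age_sd, age_range = age_range,
    recurrence_rate_by_grade = recurrence_rate_by_grade,
    followup_horizon = followup_horizon,
    eor_probs = norm1(eor_probs, 3L, "eor_probs"),
    marker_pos_probs = marker_pos_probs,
    effect = effect), class = "simulation_config")
}

# one deterministic substream per patient, a function of (seed, index) only
patient_seed <- function(seed, i) {
  as.integer((abs(as.numeric(seed)) %% 1000003) * 2017 +
               (as.numeric(i) * 7919) %% 2145000000) %% 2147483629L
}

# voxel indices of a solid sphere: centre in world mm, radius mm
sphere_indices <- function(grid, center, radius) {
  rng <- vector("list", 3L)
  for (a in 1:3) {
    w <- axis_world(grid, a)
    sel <- which(abs(w - center[a]) <= radius)
    if (!length(sel)) return(integer(0))
    rng[[a]] <- sel
  }
  wx <- axis_world(grid, 1L)[rng[[1]]] - center[1]
  wy <- axis_world(grid, 2L)[rng[[2]]] - center[2]
  wz <- axis_world(grid, 3L)[rng[[3]]] - center[3]
  d2 <- outer(outer(wx^2, wy^2, "+"), wz^2, "+")
  keep <- which(d2 <= radius^2, arr.ind = TRUE)
  if (!nrow(keep)) return(integer(0))
  i <- rng[[1]][keep[, 1]] ; j <- rng[[2]][keep[, 2]] ; k <- rng[[3]][keep[, 3]]
  as.integer(i + (j - 1L) * grid$shape[1] +
               (k - 1L) * grid$shape[1] * grid$shape[2])
}

nearest_voxel_index <- function(grid, center) {
  ijk <- round(world_to_voxel(grid, center))
  ijk <- pmin(pmax(ijk, 0), matrix(grid$shape - 1L, nrow = 1L))
  as.integer(1L + ijk[1] + ijk[2] * grid$shape[1] +
               ijk[3] * grid$shape[1] * grid$shape[2])
}

#' Generate a synthetic cohort of covariates and lesion masks
#'
#' Each patient draws covariates per the configuration, then a location
#' category (weights tilted by the effect spec for matching phenotypes), a
#' hemisphere for bilateral categories (fair coin unless the effect pins a
#' side), a lognormal target volume, and a solid sphere of that volume
#' centred at the category component's centroid with Gaussian jitter of one
#' voxel, clipped to the grid. Every draw comes from a per-patient stream
#' derived from \code{(seed, patient index)}, so identical configurations
#' give bit-identical cohorts regardless of generation order.
#'
#' @param config a \code{\link{simulation_config}}.
#' @param atlas a \code{\link{build_region_atlas}} result on the target grid.
#' @return list with elements \code{cohort} (a \code{\link{cohort}}) and
#'   \code{masks} (named list of \code{lesion_mask}).
#' @export
generate_cohort <- function(config, atlas) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(atlas, "region_atlas"))
  grid <- atlas$grid
  grid_volume <- prod(grid$shape) * prod(grid$spacing)
  if (exp(config$volume_log_mean) > grid_volume)
    stop("infeasible lesion volume: the configured median volume exceeds ",
         "the grid", call. = FALSE)
  n <- config$n_patients
  eff <- config$effect
  comp <- atlas$components
  ids <- sprintf("P%05d", seq_len(n))
  sex <- grade <- loc <- eorv <- character(n)
  age <- volume <- numeric(n)
  markers <- matrix(character(5L * n), nrow = n,
                    dimnames = list(NULL, marker_names()))
  masks <- vector("list", n)
  grade_levels <- c("I", "II", "III")
  for (i in seq_len(n)) {
    set.seed(patient_seed(config$seed, i))
    sex[i] <- if (stats::runif(1) < config$sex_female_prob) "female" else "male"
    age[i] <- min(max(stats::rnorm(1, config$age_mean, config$age_sd),
                      config$age_range[1]), config$age_range[2])
    grade[i] <- sample(grade_levels, 1L, prob = config$grade_probs)
    for (m in marker_names())
      markers[i, m] <- if (stats::runif(1) < config$marker_pos_probs[[m]])
        "positive" else "negative"
    eorv[i] <- sample(c("GTR", "STR", NA_character_), 1L,
                      prob = config$eor_probs)
    w <- config$location_probs
    matches_effect <- FALSE
    if (!is.null(eff)) {
      val <- switch(eff$covariate, who_grade = grade[i], sex = sex[i],
                    markers[i, eff$covariate])
      matches_effect <- val %in% eff$levels
      if (matches_effect) {
        w[eff$region] <- w[eff$region] * eff$odds_multiplier
        w <- w / sum(w)
      }
    }
    cat_id <- sample.int(15L, 1L, prob = w)
    loc[i] <- location_levels()[cat_id]
    rows <- which(comp$category_id == cat_id)
    if (length(rows) == 1L) {
      row <- rows
      coin <- stats::runif(1)  # consumed either way: stream alignment
    } else {
      coin <- stats::runif(1)
      side <- if (coin < 0.5) "right" else "left"
      if (matches_effect && !is.null(eff$side) && cat_id == eff$region)
        side <- eff$side
      row <- rows[comp$side[rows] == side]
    }
    # truncated lognormal: the far upper tail cannot exceed the physical
    # volume of the template; redraw within the patient's stream
    volume[i] <- stats::rlnorm(1, config$volume_log_mean,
                               config$volume_log_sd)
    tries <- 0L
    while (volume[i] > grid_volume && tries < 100L) {
      volume[i] <- stats::rlnorm(1, config$volume_log_mean,
                                 config$volume_log_sd)
      tries <- tries + 1L
    }
    volume[i] <- min(volume[i], grid_volume)
    center <- c(comp$x[row], comp$y[row], comp$z[row]) +
      stats::rnorm(3, 0, grid$spacing)
    radius <- (3 * volume[i] / (4 * pi))^(1 / 3)
    idx <- sphere_indices(grid, center, radius)
    if (!length(idx)) idx <- nearest_voxel_index(grid, center)
    masks[[i]] <- lesion_mask(ids[i], grid, indices = idx)
  }
  records <- data.frame(
    patient_id = ids, age = age, sex = sex, who_grade = grade,
    location_label = loc, eor = eorv, recurrence = NA_character_,
    followup_time = NA_real_, stringsAsFactors = FALSE)
  for (m in marker_names()) records[[m]] <- markers[, m]
  records$mask_path <- NA_character_
  records <- simulate_recurrence(
    records, config$recurrence_rate_by_grade, config$followup_horizon,
    seed = patient_seed(config$seed, 0L))
  names(masks) <- ids
  list(cohort = cohort(records, grid = grid), masks = masks)
}

#' Draw recurrence outcomes and follow-up times by grade
#'
#' Recurrence is a per-patient Bernoulli event with a grade-specific rate;
#' recurrent patients get an event time uniform on (0, horizon], all others
#' are censored at the horizon.
#'
#' @param records cohort records data frame; every row needs a
#'   \code{who_grade}.
#' @param rates_by_grade probabilities for grades I/II/III, each in [0, 1].
#' @param followup_horizon horizon in months.
#' @param seed integer seed.
#' @return \code{records} with \code{recurrence} and \code{followup_time}
#'   filled in.
#' @export
simulate_recurrence <- function(records, rates_by_grade, followup_horizon,
                                seed) {
  if (any(rates_by_grade < 0 | rates_by_grade > 1) ||
      length(rates_by_grade) != 3L)
    stop("rates_by_grade must be 3 probabilities in [0, 1]", call. = FALSE)
  gidx <- match(records$who_grade, c("I", "II", "III"))
  if (any(is.na(gidx)))
    stop("every record needs a WHO grade", call. = FALSE)
  set.seed(seed)
  n <- nrow(records)
  rec <- stats::runif(n) < rates_by_grade[gidx]
  tim <- ifelse(rec, stats::runif(n, 0, followup_horizon), followup_horizon)
  tim[rec] <- pmax(tim[rec], .Machine$double.eps)  # open at 0
  records$recurrence <- ifelse(rec, "yes", "no")
  records$followup_time <- tim
  records
}

#' Deterministic cohort realizing the reference marginal counts exactly
#'
#' Builds a 1,107-record covariate table in which every marginal of the
#' reference demographic surface holds with exact counts: the 15 location
#' categories, WHO grade counts 993/101/13, the female/male split within
#' each grade, per-grade recurrence counts 28/8/7, and extent of resection
#' 945 GTR / 105 STR / 57 missing. Covariates are assigned independently
#' across columns; the object exercises the summary surface, not spatial
#' analysis (no masks).
#'
#' @return a \code{\link{cohort}} with \code{n = 1107}.
#' @export
marginal_cohort <- function() {
  rc <- reference_counts()
  n <- rc$n
  loc <- rep(names(rc$locations), rc$locations)
  grade <- rep(names(rc$grades), rc$grades)
  sex <- unlist(lapply(names(rc$grades), function(g) {
    s <- rc$sex_by_grade[[g]]
    rep(c("female", "male"), c(s[["female"]], s[["male"]]))
  }), use.names = FALSE)
  recurrence <- unlist(lapply(names(rc$grades), function(g) {
    k <- rc$recurrence_by_grade[[g]]
    rep(c("yes", "no"), c(k, rc$grades[[g]] - k))
  }), use.names = FALSE)
  eor <- rep(c("GTR", "STR", NA_character_), rc$eor)
  records <- data.frame(
    patient_id = sprintf("R%04d", seq_len(n)),
    age = round(seq(13, 85, length.out = n), 1),
    sex = sex, who_grade = grade, location_label = loc, eor = eor,
    recurrence = recurrence,
    followup_time = 60,
    stringsAsFactors = FALSE)
  for (m in marker_names())
    records[[m]] <- rep_len(c("positive", "negative"), n)
  records$mask_path <- NA_character_
  cohort(records)
}
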