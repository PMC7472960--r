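skull_base_categories <- function() {
  c("sphenoid_wing", "cpa", "parasellar_cavernous", "tuberculum_sellae",
    "middle_fossa", "olfactory_groove", "clival_petroclival",
    "foramen_magnum")
}

#' Pipeline configuration
#'
#' One flat configuration drives an end-to-end run: load a real cohort
#' (covariate CSV plus NIfTI masks) or simulate a synthetic one, build the
#' frequency map, run every enabled phenotype comparison, volume and
#' laterality statistics, and survival stratifications.
#'
#' @param mode \code{"synthetic"} or \code{"real"}.
#' @param seed integer seed (mandatory in synthetic mode).
#' @param n_patients synthetic cohort size.
#' @param grid_shape,grid_spacing template grid definition.
#' @param voxel_volume_override optional per-voxel volume in mm^3.
#' @param cohort_csv,mask_dir real-mode inputs.
#' @param splits names from the default roster
#'   (\code{\link{default_splits}}) plus \code{"volume"}.
#' @param age_cutoff years; default the reference median 56.
#' @param volume_cutoff_cm3 preoperative size dichotomization.
#' @param alpha significance threshold for maps and clusters.
#' @param min_count minimum per-voxel lesion count to test.
#' @param connectivity cluster connectivity (6/18/26).
#' @param fdr store Benjamini-Hochberg adjusted maps as well.
#' @param effect optional \code{\link{effect_spec}} for synthetic mode.
#' @return object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(mode = c("synthetic", "real"),
                            seed = NULL,
                            n_patients = 200,
                            grid_shape = c(45, 54, 45),
                            grid_spacing = c(4, 4, 4),
                            voxel_volume_override = NULL,
                            cohort_csv = NULL, mask_dir = NULL,
                            splits = c("age", "sex", "grade", "eor",
                                       "recurrence", "p53", "ki67_gt5pct",
                                       "ema", "pr", "cd34", "volume"),
                            age_cutoff = 56,
                            volume_cutoff_cm3 = 22.828,
                            alpha = 0.05, min_count = 1,
                            connectivity = 26, fdr = FALSE,
                            effect = NULL) {
  mode <- match.arg(mode)
  if (mode == "synthetic" && is.null(seed))
    stop("synthetic mode requires a seed", call. = FALSE)
  if (mode == "real" && (is.null(cohort_csv)))
    stop("real mode requires cohort_csv", call. = FALSE)
  if (!length(splits))
    stop("at least one analysis split must be enabled", call. = FALSE)
  structure(list(mode = mode, seed = seed, n_patients = n_patients,
                 grid_shape = grid_shape, grid_spacing = grid_spacing,
                 voxel_volume_override = voxel_volume_override,
                 cohort_csv = cohort_csv, mask_dir = mask_dir,
                 splits = splits, age_cutoff = age_cutoff,
                 volume_cutoff_cm3 = volume_cutoff_cm3, alpha = alpha,
                 min_count = min_count, connectivity = connectivity,
                 fdr = fdr, effect = effect),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration as flat YAML
#'
#' @param path YAML file.
#' @return \code{read_pipeline_config}: a \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw <- raw[setdiff(names(raw), "effect")]
  do.call(pipeline_config, raw)
}

#' @rdname read_pipeline_config
#' @param config a \code{pipeline_config}.
#' @return \code{write_pipeline_config}: \code{path}, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  x <- x[!vapply(x, is.null, logical(1))]
  x$effect <- NULL
  yaml::write_yaml(x, path)
  invisible(path)
}

config_hash <- function(config) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  x <- unclass(config)
  x$effect <- if (is.null(x$effect)) NULL else unclass(x$effect)
  yaml::write_yaml(x[!vapply(x, is.null, logical(1))], f)
  unname(tools::md5sum(f))
}

#' Run the full lesion-mapping pipeline
#'
#' Stages run in fixed order: load or simulate the cohort; frequency map
#' and location summary; per-split p-value maps and cluster reports;
#' volume statistics; laterality; survival stratifications. A failure in
#' one split is captured in the report and does not abort the others.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return Object of class \code{report_bundle}: grid, atlas, cohort,
#'   masks, \code{frequency} map, \code{summary}, \code{pmaps} and
#'   \code{clusters} (per split), \code{volumes} (table) and
#'   \code{volume_tests}, \code{laterality}, \code{survival} (per
#'   applicable split), \code{errors} (named conditions), \code{log}
#'   (config hash, timings, memoization counts).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timings[[stage]] <<- round(t1 - t0, 3)
    t0 <<- t1
  }
  grid <- make_grid(config$grid_shape, config$grid_spacing,
                    voxel_volume_override = config$voxel_volume_override)
  atlas <- build_region_atlas(grid)
  if (config$mode == "synthetic") {
    sim <- simulation_config(n_patients = config$n_patients,
                             seed = config$seed, effect = config$effect)
    gen <- generate_cohort(sim, atlas)
    coh <- gen$cohort
    masks <- gen$masks
  } else {
    if (!file.exists(config$cohort_csv))
      stop("cannot resolve cohort table: ", config$cohort_csv,
           call. = FALSE)
    coh <- read_cohort_table(config$cohort_csv, grid = grid)
    masks <- read_cohort_masks(coh, grid, base_dir = config$mask_dir)
  }
  tick("load")
  freq <- build_frequency_map(masks, n = coh$n)
  summ <- location_summary(coh)
  tick("frequency")

  roster <- default_splits(age_cutoff = config$age_cutoff)
  roster$volume <- split_volume(masks, config$volume_cutoff_cm3, grid)
  unknown <- setdiff(config$splits, names(roster))
  if (length(unknown))
    stop("unknown split(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  pmaps <- list()
  clusters <- list()
  errors <- list()
  n_tables <- c()
  for (s in config$splits) {
    res <- tryCatch(
      compute_pvalue_map(coh, masks, roster[[s]],
                         min_count = config$min_count,
                         alpha = config$alpha, fdr = config$fdr),
      error = function(e) e)
    if (inherits(res, "error")) {
      errors[[s]] <- conditionMessage(res)
      next
    }
    pmaps[[s]] <- res
    n_tables[[s]] <- res$n_distinct_tables
    clusters[[s]] <- extract_significant_clusters(
      res, atlas, connectivity = config$connectivity)
  }
  tick("comparisons")

  vols <- volume_table(masks, grid, coh$records)
  volume_tests <- list()
  sb <- vols$location_label %in% skull_base_categories()
  volume_tests$skull_vs_nonskull <- tryCatch(
    kruskal_wallis_test(list(skull_base = vols$volume_cm3[sb],
                             non_skull_base = vols$volume_cm3[!sb])),
    error = function(e) conditionMessage(e))
  sb_groups <- split(vols$volume_cm3[sb], vols$location_label[sb])
  sb_groups <- sb_groups[vapply(sb_groups, length, 1L) > 0]
  if (length(sb_groups) >= 3L) {
    volume_tests$skull_base_omnibus <- tryCatch(
      kruskal_wallis_test(sb_groups), error = function(e)
        conditionMessage(e))
    volume_tests$skull_base_posthoc <- tryCatch(
      dunn_posthoc(sb_groups), error = function(e) conditionMessage(e))
  }
  tick("volumes")

  lat <- laterality_summary(coh, masks)
  tick("laterality")

  surv <- list()
  for (s in intersect(config$splits,
                      c("age", "grade", "ki67_gt5pct", "volume", "eor"))) {
    res <- tryCatch(rfs_comparison(coh, roster[[s]]),
                    error = function(e) e)
    if (inherits(res, "error")) errors[[paste0("rfs_", s)]] <-
        conditionMessage(res)
    else surv[[s]] <- res
  }
  tick("survival")

  structure(list(
    config = config, grid = grid, atlas = atlas, cohort = coh,
    masks = masks, frequency = freq, summary = summ, pmaps = pmaps,
    clusters = clusters, volumes = vols, volume_tests = volume_tests,
    laterality = lat, survival = surv, errors = errors,
    log = list(config_hash = config_hash(config), timings = timings,
               n_distinct_tables = n_tables,
               package_version = as.character(
                 utils::packageVersion("lesionmap")))),
    class = "report_bundle")
}

write_csv_stable <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, na = "")
}

#' Write a report bundle to disk
#'
#' Stable layout under \code{outdir}: \code{maps/} (NIfTI frequency, p and
#' optional q maps), \code{tables/} (CSV summaries, volumes, laterality,
#' clusters, survival), \code{masks/} (synthetic-mode lesion masks plus the
#' cohort CSV, making the run a drop-in real-mode input), \code{log.txt}
#' (config echo, hash, versions, timings, memoization counts).
#'
#' @param bundle a \code{\link{run_pipeline}} result.
#' @param outdir output directory (created if needed).
#' @param write_masks also export per-patient masks and the cohort CSV.
#' @return \code{outdir}, invisibly.
#' @export
write_report <- function(bundle, outdir, write_masks = FALSE) {
  stopifnot(inherits(bundle, "report_bundle"))
  maps_dir <- file.path(outdir, "maps")
  tab_dir <- file.path(outdir, "tables")
  dir.create(maps_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(tab_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create ", outdir, call. = FALSE)
  grid <- bundle$grid
  write_map_file(bundle$frequency$counts, grid,
                 file.path(maps_dir, "frequency_counts.nii.gz"),
                 datatype = "int32")
  write_map_file(bundle$frequency$percentage, grid,
                 file.path(maps_dir, "frequency_percentage.nii.gz"))
  write_map_file(array(bundle$atlas$labels, grid$shape), grid,
                 file.path(maps_dir, "region_atlas.nii.gz"),
                 datatype = "int32")
  for (s in names(bundle$pmaps)) {
    pm <- bundle$pmaps[[s]]
    write_map_file(pm$p, grid,
                   file.path(maps_dir, paste0("p_", s, ".nii.gz")))
    if (!is.null(pm$q))
      write_map_file(pm$q, grid,
                     file.path(maps_dir, paste0("q_", s, ".nii.gz")))
    write_csv_stable(as.data.frame(bundle$clusters[[s]]),
                     file.path(tab_dir, paste0("clusters_", s, ".csv")))
  }
  summ <- bundle$summary
  write_csv_stable(summ$locations, file.path(tab_dir, "locations.csv"))
  write_csv_stable(summ$grades, file.path(tab_dir, "grades.csv"))
  write_csv_stable(summ$sex_by_grade,
                   file.path(tab_dir, "sex_by_grade.csv"))
  write_csv_stable(summ$recurrence_by_grade,
                   file.path(tab_dir, "recurrence_by_grade.csv"))
  write_csv_stable(summ$eor, file.path(tab_dir, "eor.csv"))
  write_csv_stable(bundle$volumes, file.path(tab_dir, "volumes.csv"))
  write_csv_stable(bundle$laterality$tests,
                   file.path(tab_dir, "laterality.csv"))
  if (length(bundle$survival)) {
    sv <- do.call(rbind, lapply(names(bundle$survival), function(s) {
      r <- bundle$survival[[s]]
      data.frame(split = s, nA = r$nA, nB = r$nB,
                 excluded_n = r$excluded_n,
                 statistic = r$test$statistic, p = r$test$p)
    }))
    write_csv_stable(sv, file.path(tab_dir, "survival.csv"))
    for (s in names(bundle$survival)) {
      r <- bundle$survival[[s]]
      write_csv_stable(cbind(group = "A", as.data.frame(r$curve_a)),
                       file.path(tab_dir, paste0("km_", s, "_A.csv")))
      write_csv_stable(cbind(group = "B", as.data.frame(r$curve_b)),
                       file.path(tab_dir, paste0("km_", s, "_B.csv")))
    }
  }
  if (write_masks) {
    mask_dir <- file.path(outdir, "masks")
    dir.create(mask_dir, showWarnings = FALSE)
    rec <- bundle$cohort$records
    for (id in names(bundle$masks)) {
      p <- file.path(mask_dir, paste0(id, ".nii.gz"))
      write_mask_file(bundle$masks[[id]], p)
      rec$mask_path[rec$patient_id == id] <- p
    }
    write_cohort_table(cohort(rec, bundle$grid),
                       file.path(outdir, "cohort.csv"))
  } else {
    write_cohort_table(bundle$cohort, file.path(outdir, "cohort.csv"))
  }
  log_lines <- c(
    paste0("lesionmap ", bundle$log$package_version),
    paste0("config_hash: ", bundle$log$config_hash),
    paste0("run_date: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    "config:",
    utils::capture.output(utils::str(unclass(bundle$config))),
    "stage_timings_s:",
    paste0("  ", names(bundle$log$timings), ": ",
           unlist(bundle$log$timings)),
    "distinct_fisher_tables:",
    paste0("  ", names(bundle$log$n_distinct_tables), ": ",
           unlist(bundle$log$n_distinct_tables)),
    if (length(bundle$errors))
      c("errors:", paste0("  ", names(bundle$errors), ": ",
                          unlist(bundle$errors)))
    else "errors: none")
  writeLines(log_lines, file.path(outdir, "log.txt"))
  invisible(outdir)
}
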