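#' Normalized lesion volume of a mask
#'
#' Volume is the exact product of the mask's voxel count and the grid's
#' per-voxel volume (which may carry an explicit override, e.g. a reported
#' 0.08 mm^3 single-voxel volume).
#'
#' @param mask a \code{lesion_mask}.
#' @param grid grid supplying the voxel volume; defaults to the mask's.
#' @return list with \code{patient_id}, \code{voxel_count},
#'   \code{volume_mm3}, \code{volume_cm3}.
#' @examples
#' g <- make_grid(c(100, 100, 100), c(1, 1, 1), voxel_volume_override = 0.08)
#' m <- lesion_mask("p1", g, indices = seq_len(1000))
#' lesion_volume(m)$volume_cm3  # 0.08
#' @export
lesion_volume <- function(mask, grid = mask$grid) {
  v <- mask$voxel_count * grid$voxel_volume
  list(patient_id = mask$patient_id, voxel_count = mask$voxel_count,
       volume_mm3 = v, volume_cm3 = v / 1000)
}

#' Per-patient volume table for a set of masks
#'
#' @param masks list of \code{lesion_mask}.
#' @param grid grid supplying the voxel volume; defaults to the first
#'   mask's.
#' @param records optional cohort records; joins \code{location_label}.
#' @return data frame: patient_id, voxel_count, volume_mm3, volume_cm3
#'   (and location_label when records are given).
#' @export
volume_table <- function(masks, grid = masks[[1L]]$grid, records = NULL) {
  out <- do.call(rbind, lapply(masks, function(m)
    as.data.frame(lesion_volume(m, grid), stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  if (!is.null(records))
    out$location_label <-
      records$location_label[match(out$patient_id, records$patient_id)]
  out
}

as_group_list <- function(groups) {
  if (!is.list(groups) || length(groups) < 1L)
    stop("groups must be a list of numeric vectors", call. = FALSE)
  lapply(groups, as.numeric)
}

#' Kruskal-Wallis rank test across labeled groups
#'
#' Mid-rank H statistic with tie correction, referred to the chi-square
#' distribution with k - 1 degrees of freedom.
#'
#' @param groups named list of two or more numeric vectors.
#' @return list with \code{H}, \code{df}, \code{p}.
#' @examples
#' kruskal_wallis_test(list(a = c(1, 2, 3), b = c(4, 5, 6)))$H  # 3.857
#' @export
kruskal_wallis_test <- function(groups) {
  groups <- as_group_list(groups)
  if (length(groups) < 2L)
    stop("at least two groups are required", call. = FALSE)
  if (any(!vapply(groups, length, 1L)))
    stop("every group needs at least one value", call. = FALSE)
  values <- unlist(groups, use.names = FALSE)
  if (length(unique(values)) == 1L)
    stop("all values identical: the rank test is undefined", call. = FALSE)
  fac <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  kt <- stats::kruskal.test(values, fac)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value)
}

#' Dunn's post hoc pairwise comparisons after Kruskal-Wallis
#'
#' Pairwise z statistics from mean-rank differences with the pooled,
#' tie-corrected standard error; two-sided unadjusted p from the normal
#' distribution; adjusted p is Bonferroni over the k(k-1)/2 pairs
#' (\code{min(1, m * p)}).
#'
#' @param groups named list of three or more numeric vectors (use the
#'   omnibus \code{\link{kruskal_wallis_test}} for two groups).
#' @return data frame: group1, group2, z, p_unadj, p_adj.
#' @export
dunn_posthoc <- function(groups) {
  groups <- as_group_list(groups)
  k <- length(groups)
  if (k < 3L)
    stop("Dunn's post hoc needs >= 3 groups; use kruskal_wallis_test ",
         "for two", call. = FALSE)
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_len(k))
  sizes <- vapply(groups, length, 1L)
  values <- unlist(groups, use.names = FALSE)
  N <- length(values)
  rk <- rank(values)  # mid-ranks
  fac <- rep(seq_len(k), sizes)
  mean_rank <- tapply(rk, fac, mean)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  base_var <- N * (N + 1) / 12 - tie_corr
  pairs <- utils::combn(k, 2L)
  m <- ncol(pairs)
  out <- do.call(rbind, lapply(seq_len(m), function(idx) {
    i <- pairs[1L, idx]; j <- pairs[2L, idx]
    se <- sqrt(base_var * (1 / sizes[i] + 1 / sizes[j]))
    diff <- mean_rank[[i]] - mean_rank[[j]]
    # fully tied data: no separation, z defined as 0
    z <- if (se == 0) 0 else diff / se
    p <- 2 * stats::pnorm(-abs(z))
    data.frame(group1 = names(groups)[i], group2 = names(groups)[j],
               z = z, p_unadj = p, p_adj = min(1, m * p),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Pearson chi-square association for a 2x2 table
#'
#' Without continuity correction, one degree of freedom. Used for
#' categorical demographic associations such as sex by grade group.
#'
#' @param t a \code{contingency_table}, 2x2 matrix, or \code{c(a, b, c, d)}
#'   (row-wise).
#' @return list with \code{statistic}, \code{df}, \code{p}.
#' @export
chi_square_association <- function(t) {
  v <- as_abcd(t)
  m <- matrix(v, nrow = 2L, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("all margins must be positive", call. = FALSE)
  ct <- stats::chisq.test(m, correct = FALSE)
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}
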