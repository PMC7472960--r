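#' Per-voxel two-tailed Fisher's exact p-value heatmap
#'
#' Builds per-group lesion frequency maps for a two-level phenotype split,
#' then at every tested voxel forms the 2x2 table (occupying vs tumor-free
#' patients per group) and computes the two-tailed Fisher exact p. A voxel
#' is tested when at least \code{min_count} patients occupy it across both
#' groups; untested voxels carry p = 1 (their table is degenerate and p = 1
#' analytically when no lesion is present). Distinct tables are computed
#' once and reused across voxels.
#'
#' @param x a \code{\link{cohort}}.
#' @param masks named list of \code{lesion_mask} covering the cohort's
#'   patients (names are patient ids).
#' @param split a \code{\link{phenotype_split}}.
#' @param min_count minimum occupying-patient count for a voxel to be
#'   tested.
#' @param alpha display/cluster threshold stored on the map.
#' @param fdr if \code{TRUE}, additionally store Benjamini-Hochberg
#'   adjusted values over tested voxels.
#' @return Object of class \code{pvalue_map}: \code{p} (3D array in (0,1]),
#'   \code{tested} (logical 3D array), \code{alpha}, \code{q} (or
#'   \code{NULL}), group sizes \code{nA}/\code{nB}, \code{split_name},
#'   \code{n_distinct_tables}, \code{grid}.
#' @export
compute_pvalue_map <- function(x, masks, split, min_count = 1,
                               alpha = 0.05, fdr = FALSE) {
  strat <- stratify_cohort(x, split)
  if (!strat$nA || !strat$nB)
    stop("split '", split$name, "' has an empty group", call. = FALSE)
  have <- names(masks)
  ids_a <- intersect(strat$ids_a, have)
  ids_b <- intersect(strat$ids_b, have)
  if (!length(ids_a) || !length(ids_b))
    stop("split '", split$name, "' has a group without masks",
         call. = FALSE)
  grid <- masks[[1L]]$grid
  fa <- build_frequency_map(masks[ids_a], n = length(ids_a))
  fb <- build_frequency_map(masks[ids_b], n = length(ids_b))
  if (!grids_match(fa$grid, fb$grid)) stop_grid_mismatch("split groups")
  nA <- length(ids_a)
  nB <- length(ids_b)
  totals <- fa$counts + fb$counts
  tested <- totals >= min_count
  p <- array(1, dim = grid$shape)
  n_tab <- 0L
  ti <- which(tested)
  if (length(ti)) {
    fp <- fisher_p_vector(as.vector(fa$counts[ti]),
                          as.vector(fb$counts[ti]), nA, nB)
    p[ti] <- fp$p
    n_tab <- fp$n_distinct
  }
  q <- NULL
  if (fdr) {
    q <- array(1, dim = grid$shape)
    if (length(ti)) q[ti] <- adjust_bh(p[ti])
  }
  structure(list(p = p, tested = tested, alpha = alpha, q = q,
                 nA = nA, nB = nB, split_name = split$name,
                 counts_a = fa$counts, counts_b = fb$counts,
                 n_distinct_tables = n_tab, grid = grid),
            class = "pvalue_map")
}

#' @export
print.pvalue_map <- function(x, ...) {
  cat("<pvalue_map> split '", x$split_name, "' (nA = ", x$nA, ", nB = ",
      x$nB, "); ", sum(x$tested), " tested voxels, ",
      sum(x$p < x$alpha & x$tested), " below alpha = ", x$alpha, "; ",
      x$n_distinct_tables, " distinct tables\n", sep = "")
  invisible(x)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p numeric vector of p-values in [0, 1] (one per tested voxel).
#' @return adjusted values, each in \code{[p, 1]}, monotone in the sorted
#'   order.
#' @export
adjust_bh <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

connectivity_offsets <- function(connectivity) {
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18 or 26", call. = FALSE)
  off <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  deg <- rowSums(abs(off))
  max_deg <- switch(as.character(connectivity), "6" = 1L, "18" = 2L,
                    "26" = 3L)
  off <- off[deg > 0 & deg <= max_deg, , drop = FALSE]
  # keep one direction of each pair; undirected edges found once
  off[off[, 1] > 0 | (off[, 1] == 0 & off[, 2] > 0) |
        (off[, 1] == 0 & off[, 2] == 0 & off[, 3] > 0), , drop = FALSE]
}

#' Extract connected significant clusters from a p-value map
#'
#' Connected components of \code{tested & p < alpha} under 6-, 18- or
#' 26-neighbourhood connectivity, reported with voxel count, peak
#' -log10(p), world-space centroid, and the atlas category at the centroid
#' (\code{"background"} when outside every labelled region). Clusters are
#' sorted by voxel count descending, ties broken by component id.
#'
#' @param map a \code{\link{compute_pvalue_map}} result.
#' @param atlas optional \code{region_atlas} for centroid labelling.
#' @param connectivity 6, 18 or 26 (default 26, typical lesion-mapping
#'   practice).
#' @param alpha threshold; defaults to the map's stored alpha.
#' @return Object of class \code{cluster_report}: a data frame with one row
#'   per cluster (\code{cluster_id}, \code{n_voxels},
#'   \code{peak_neglog10_p}, \code{centroid_x/y/z}, \code{region}) plus a
#'   \code{connectivity} attribute. Zero rows when nothing is significant.
#' @export
extract_significant_clusters <- function(map, atlas = NULL,
                                         connectivity = 26,
                                         alpha = map$alpha) {
  stopifnot(inherits(map, "pvalue_map"))
  connectivity <- as.integer(connectivity)
  offsets <- connectivity_offsets(connectivity)
  sig <- which(map$tested & map$p < alpha)
  empty <- data.frame(cluster_id = integer(0), n_voxels = integer(0),
                      peak_neglog10_p = numeric(0),
                      centroid_x = numeric(0), centroid_y = numeric(0),
                      centroid_z = numeric(0), region = character(0))
  if (!length(sig))
    return(structure(empty, class = c("cluster_report", "data.frame"),
                     connectivity = connectivity))
  shp <- map$grid$shape
  coords <- arrayInd(sig, shp)
  edges <- NULL
  for (r in seq_len(nrow(offsets))) {
    nb <- sweep(coords, 2L, offsets[r, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= shp[1] & nb[, 2] >= 1 &
      nb[, 2] <= shp[2] & nb[, 3] >= 1 & nb[, 3] <= shp[3]
    if (!any(ok)) next
    nidx <- nb[ok, 1] + (nb[ok, 2] - 1L) * shp[1] +
      (nb[ok, 3] - 1L) * shp[1] * shp[2]
    hit <- match(nidx, sig)
    from <- which(ok)[!is.na(hit)]
    if (length(from))
      edges <- rbind(edges, cbind(from, hit[!is.na(hit)]))
  }
  g <- igraph::make_empty_graph(n = length(sig), directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)
  rows <- lapply(seq_len(comp$no), function(ci) {
    members <- which(comp$membership == ci)
    vox <- coords[members, , drop = FALSE]
    cen <- colMeans(voxel_to_world(map$grid, vox - 1L))
    region <- if (is.null(atlas)) NA_character_
              else atlas_category_at(atlas, cen)
    data.frame(cluster_id = ci, n_voxels = length(members),
               peak_neglog10_p = max(-log10(map$p[sig[members]])),
               centroid_x = cen[1], centroid_y = cen[2],
               centroid_z = cen[3], region = region)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$n_voxels, out$cluster_id), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("cluster_report", "data.frame"),
            connectivity = connectivity)
}
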