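# Seed components of the 15 location categories, in template-like world
# coordinates (mm, RAS+). Midline categories straddle x = 0; the rest carry
# mirrored left/right components. Coordinates approximate the classical
# dural attachment sites on an MNI-like grid; radii are seed-sphere radii.
atlas_component_spec <- function() {
  spec <- rbind(
    data.frame(name = "convexity",            midline = FALSE, x = 44, y =   8, z =  48, radius = 14),
    data.frame(name = "parasagittal_sinus",   midline = TRUE,  x =  0, y =  12, z =  64, radius = 12),
    data.frame(name = "falx",                 midline = TRUE,  x =  0, y =  -8, z =  48, radius = 12),
    data.frame(name = "tentorium",            midline = FALSE, x = 28, y = -56, z =   4, radius = 10),
    data.frame(name = "cerebellar_convexity", midline = FALSE, x = 36, y = -64, z = -32, radius =  8),
    data.frame(name = "cpa",                  midline = FALSE, x = 44, y = -40, z = -32, radius =  8),
    data.frame(name = "sphenoid_wing",        midline = FALSE, x = 44, y =  12, z = -12, radius = 10),
    data.frame(name = "parasellar_cavernous", midline = FALSE, x = 16, y =   4, z = -24, radius =  7),
    data.frame(name = "tuberculum_sellae",    midline = TRUE,  x =  0, y =  24, z = -16, radius =  7),
    data.frame(name = "middle_fossa",         midline = FALSE, x = 40, y = -12, z = -28, radius =  7),
    data.frame(name = "olfactory_groove",     midline = FALSE, x =  8, y =  44, z = -20, radius =  7),
    data.frame(name = "clival_petroclival",   midline = TRUE,  x =  0, y = -28, z = -40, radius =  8),
    data.frame(name = "foramen_magnum",       midline = TRUE,  x =  0, y = -36, z = -56, radius =  7),
    data.frame(name = "intraventricular",     midline = FALSE, x = 24, y = -36, z =  16, radius =  7),
    data.frame(name = "others",               midline = FALSE, x = 28, y =  44, z = -24, radius =  6))
  spec$category_id <- seq_len(nrow(spec))
  spec
}

#' Build the deterministic 15-category region atlas on a grid
#'
#' Each location category is seeded as one or two spheres at fixed world
#' coordinates: midline categories (parasagittal sinus, falx, sellar
#' structures, clival-petroclival, foramen magnum) straddle x = 0, all
#' others receive mirrored left/right components across the mid-sagittal
#' plane. A voxel takes the label of the nearest seed centre among those
#' whose radius covers it; labels are therefore disjoint and, for bilateral
#' categories, exactly mirror-symmetric on a symmetric grid.
#'
#' @param grid a \code{template_grid}; must be large enough that every
#'   category receives at least one voxel.
#' @return Object of class \code{region_atlas}: \code{grid}; \code{labels}
#'   (integer 3D array, 0 = background, 1..15 = categories in
#'   \code{\link{location_levels}} order); \code{components} (data frame of
#'   per-component name, side, world centroid and radius); \code{names}.
#' @export
build_region_atlas <- function(grid) {
  spec <- atlas_component_spec()
  stopifnot(identical(spec$name, location_levels()))
  comp <- do.call(rbind, lapply(seq_len(nrow(spec)), function(i) {
    s <- spec[i, ]
    if (s$midline)
      data.frame(category_id = s$category_id, name = s$name,
                 side = "midline", x = 0, y = s$y, z = s$z,
                 radius = s$radius)
    else
      data.frame(category_id = s$category_id, name = s$name,
                 side = c("right", "left"), x = c(s$x, -s$x),
                 y = s$y, z = s$z, radius = s$radius)
  }))
  wx <- axis_world(grid, 1L)
  wy <- axis_world(grid, 2L)
  wz <- axis_world(grid, 3L)
  nvox <- prod(grid$shape)
  best_d2 <- rep(Inf, nvox)
  labels <- integer(nvox)
  dx2 <- dy2 <- dz2 <- NULL
  for (i in seq_len(nrow(comp))) {
    d2 <- outer(outer((wx - comp$x[i])^2, (wy - comp$y[i])^2, "+"),
                (wz - comp$z[i])^2, "+")
    hit <- d2 <= comp$radius[i]^2 & d2 < best_d2
    labels[hit] <- comp$category_id[i]
    best_d2[hit] <- d2[hit]
  }
  labels <- array(labels, dim = grid$shape)
  present <- sort(unique(labels[labels > 0L]))
  if (!identical(present, spec$category_id))
    stop("grid too small: not every location category received a voxel",
         call. = FALSE)
  structure(list(grid = grid, labels = labels, components = comp,
                 names = spec$name),
            class = "region_atlas")
}

#' @export
print.region_atlas <- function(x, ...) {
  cat("<region_atlas> ", length(x$names), " categories, ",
      sum(x$labels > 0L), " labelled voxels on ",
      paste(x$grid$shape, collapse = " x "), " grid\n", sep = "")
  invisible(x)
}

#' Atlas category at a world coordinate
#'
#' @param atlas a \code{region_atlas}.
#' @param xyz length-3 world coordinate (mm).
#' @return category name, or \code{"background"}.
#' @export
atlas_category_at <- function(atlas, xyz) {
  ijk <- round(world_to_voxel(atlas$grid, xyz))
  ijk <- pmin(pmax(ijk, 0), matrix(atlas$grid$shape - 1L, nrow = 1L))
  lab <- atlas$labels[ijk[1] + 1L, ijk[2] + 1L, ijk[3] + 1L]
  if (lab == 0L) "background" else atlas$names[lab]
}
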