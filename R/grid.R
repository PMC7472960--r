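#' Construct a shared template grid
#'
#' All lesion masks and scalar maps in an analysis live on one template grid:
#' a 3D voxel lattice with a voxel-to-world affine in RAS+ orientation
#' (+x right, +y anterior, +z superior). The affine places the centre of the
#' lattice at world origin, so the mid-sagittal plane sits at world x = 0 and
#' negative world x is the left hemisphere.
#'
#' The physical volume of one voxel defaults to the product of the spacings
#' (equivalently, the absolute determinant of the affine's linear part). An
#' explicit \code{voxel_volume_override} replaces that value in all volume
#' computations without altering the geometry; this supports workflows whose
#' reported per-voxel volume differs from the stored grid spacing.
#'
#' @param shape integer vector of length 3; voxels per axis.
#' @param spacing numeric vector of length 3; voxel edge lengths in mm.
#' @param voxel_volume_override optional single positive number; per-voxel
#'   volume in mm^3 used by volume computations instead of the geometric one.
#' @return An object of class \code{template_grid} with fields \code{shape},
#'   \code{spacing}, \code{affine} (4x4 voxel-to-world, 0-based voxel
#'   indices) and \code{voxel_volume}.
#' @examples
#' g <- make_grid(c(45, 54, 45), c(4, 4, 4))
#' g$voxel_volume  # 64 mm^3
#' @export
make_grid <- function(shape, spacing, voxel_volume_override = NULL) {
  if (length(shape) != 3L || any(!is.finite(shape)) || any(shape < 1) ||
      any(shape != round(shape)))
    stop("invalid grid: `shape` must be 3 positive integers", call. = FALSE)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("invalid grid: `spacing` must be 3 positive lengths (mm)",
         call. = FALSE)
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  affine <- diag(c(spacing, 1))
  # centre of the voxel lattice at world origin (0-based index convention)
  affine[1:3, 4] <- -spacing * (shape - 1L) / 2
  vv <- prod(spacing)
  if (!is.null(voxel_volume_override)) {
    if (!is.numeric(voxel_volume_override) ||
        length(voxel_volume_override) != 1L || voxel_volume_override <= 0)
      stop("invalid grid: voxel volume override must be a positive number",
           call. = FALSE)
    vv <- as.numeric(voxel_volume_override)
  }
  structure(
    list(shape = shape, spacing = spacing, affine = affine,
         voxel_volume = vv),
    class = "template_grid")
}

#' @export
print.template_grid <- function(x, ...) {
  cat("<template_grid> ", paste(x$shape, collapse = " x "),
      " voxels @ ", paste(x$spacing, collapse = " x "),
      " mm; voxel volume ", format(x$voxel_volume), " mm^3\n", sep = "")
  invisible(x)
}

#' Convert 0-based voxel indices to world coordinates
#'
#' @param grid a \code{template_grid}.
#' @param ijk numeric matrix (n x 3) of 0-based voxel indices (or a length-3
#'   vector for one voxel).
#' @return n x 3 matrix of world coordinates in mm (RAS+).
#' @export
voxel_to_world <- function(grid, ijk) {
  if (is.vector(ijk)) ijk <- matrix(ijk, nrow = 1L)
  stopifnot(ncol(ijk) == 3L)
  sweep(ijk %*% t(grid$affine[1:3, 1:3]), 2L, grid$affine[1:3, 4], "+")
}

#' Convert world coordinates to (fractional) 0-based voxel indices
#'
#' @inheritParams voxel_to_world
#' @param xyz numeric matrix (n x 3) of world coordinates in mm.
#' @return n x 3 matrix of fractional 0-based voxel indices.
#' @export
world_to_voxel <- function(grid, xyz) {
  if (is.vector(xyz)) xyz <- matrix(xyz, nrow = 1L)
  stopifnot(ncol(xyz) == 3L)
  inv <- solve(grid$affine)
  sweep(xyz %*% t(inv[1:3, 1:3]), 2L, inv[1:3, 4], "+")
}

# world coordinates of every voxel along one axis (0-based lattice)
axis_world <- function(grid, axis) {
  idx <- seq_len(grid$shape[axis]) - 1
  grid$affine[axis, axis] * idx + grid$affine[axis, 4]
}

#' Test two grids for geometric compatibility
#'
#' Shapes must match exactly; affines within an absolute per-element
#' tolerance (default 1e-3 mm) to absorb float round-trips through file
#' headers.
#'
#' @param a,b \code{template_grid} objects (or a grid and a 4x4 affine with
#'   a shape, via \code{shape_b}/\code{affine_b}).
#' @param tol per-element absolute tolerance on the affine.
#' @return logical.
#' @export
grids_match <- function(a, b, tol = 1e-3) {
  identical(a$shape, b$shape) && all(abs(a$affine - b$affine) <= tol)
}

stop_grid_mismatch <- function(what) {
  stop("grid mismatch: ", what, call. = FALSE)
}
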