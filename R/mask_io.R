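#' Create a lesion mask from occupied voxels
#'
#' A lesion mask is the binary occupancy of one patient's segmented lesion
#' over the template grid. Occupancy is held sparsely as sorted linear voxel
#' indices (1-based, column-major); \code{\link{mask_array}} materialises the
#' dense logical array.
#'
#' @param patient_id identifier (coerced to character).
#' @param grid a \code{template_grid}.
#' @param indices integer vector of 1-based linear voxel indices, or
#'   \code{occupancy} may be given instead.
#' @param occupancy optional logical/numeric 3D array over the grid.
#' @return Object of class \code{lesion_mask} with fields \code{patient_id},
#'   \code{grid}, \code{indices}, \code{voxel_count}.
#' @export
lesion_mask <- function(patient_id, grid, indices = NULL, occupancy = NULL) {
  if (is.null(indices)) {
    if (is.null(occupancy))
      stop("one of `indices` or `occupancy` is required", call. = FALSE)
    if (!identical(dim(occupancy), as.integer(grid$shape)))
      stop_grid_mismatch("occupancy shape does not equal grid shape")
    indices <- which(occupancy != 0)
  }
  nvox <- prod(grid$shape)
  indices <- sort(unique(as.integer(indices)))
  if (length(indices) && (indices[1L] < 1L || indices[length(indices)] > nvox))
    stop("mask indices outside the grid", call. = FALSE)
  structure(
    list(patient_id = as.character(patient_id), grid = grid,
         indices = indices, voxel_count = length(indices)),
    class = "lesion_mask")
}

#' Dense occupancy array of a lesion mask
#'
#' @param mask a \code{lesion_mask}.
#' @return logical 3D array over the mask's grid.
#' @export
mask_array <- function(mask) {
  occ <- array(FALSE, dim = mask$grid$shape)
  occ[mask$indices] <- TRUE
  occ
}

#' @export
print.lesion_mask <- function(x, ...) {
  cat("<lesion_mask> patient ", x$patient_id, ": ", x$voxel_count,
      " voxels\n", sep = "")
  invisible(x)
}

# attach grid geometry to an RNifti image
as_nifti_on_grid <- function(values, grid) {
  img <- RNifti::asNifti(values)
  RNifti::pixdim(img) <- grid$spacing
  xf <- structure(grid$affine, code = 2L)
  RNifti::sform(img) <- xf
  RNifti::qform(img) <- xf
  img
}

nifti_grid_matches <- function(img, grid, tol = 1e-3) {
  d <- dim(img)
  if (length(d) != 3L || !identical(as.integer(d), grid$shape)) return(FALSE)
  xf <- unclass(RNifti::xform(img))
  all(abs(xf - grid$affine) <= tol)
}

#' Read a lesion mask from a NIfTI file
#'
#' The stored geometry must match \code{grid} (shape exactly, affine within
#' \code{tol} mm per element). Voxels with value strictly greater than
#' \code{threshold} become occupied; the default 0.5 binarises masks that
#' were blurred by interpolation during resampling.
#'
#' @param path NIfTI file (.nii or .nii.gz).
#' @param grid the expected \code{template_grid}.
#' @param threshold occupancy threshold on stored values.
#' @param patient_id identifier for the mask; defaults to the file stem.
#' @param tol affine tolerance in mm passed to the geometry check.
#' @return a \code{lesion_mask}.
#' @export
read_mask_file <- function(path, grid, threshold = 0.5,
                           patient_id = NULL, tol = 1e-3) {
  if (!file.exists(path))
    stop("cannot read mask file: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  if (!nifti_grid_matches(img, grid, tol))
    stop_grid_mismatch(paste0("mask geometry in ", basename(path),
                              " does not match the template grid"))
  if (is.null(patient_id))
    patient_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  lesion_mask(patient_id, grid, indices = which(as.array(img) > threshold))
}

#' Write a scalar map (or mask) to NIfTI on the template grid
#'
#' @param values 3D array with the grid's shape (counts, percentages,
#'   p values, or 0/1 occupancy).
#' @param grid a \code{template_grid}.
#' @param path output file (.nii or .nii.gz).
#' @param datatype NIfTI storage type; \code{"double"} round-trips scalar
#'   maps bit-exactly, \code{"uint8"} suits binary masks.
#' @return \code{path}, invisibly.
#' @export
write_map_file <- function(values, grid, path, datatype = "double") {
  if (!identical(dim(values), as.integer(grid$shape)))
    stop("map shape does not equal grid shape", call. = FALSE)
  img <- as_nifti_on_grid(values, grid)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Write a lesion mask to NIfTI
#'
#' @param mask a \code{lesion_mask}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_mask_file <- function(mask, path) {
  occ <- array(0L, dim = mask$grid$shape)
  occ[mask$indices] <- 1L
  write_map_file(occ, mask$grid, path, datatype = "uint8")
}
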