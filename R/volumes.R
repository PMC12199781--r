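#' Construct a volume grid
#'
#' A \code{volume_grid} defines the shared voxel space for an analysis:
#' array dimensions, voxel size in mm, a 4x4 voxel-to-world affine and a
#' brain mask.  Every volume, lesion mask and connectome in a pipeline
#' must live on one grid; inputs on mismatched grids are rejected rather
#' than resampled (registration is out of scope).
#'
#' @param dims integer triple, voxels per axis.
#' @param voxel_size numeric triple, voxel edge length in mm (all > 0).
#' @param affine 4x4 voxel-to-world matrix (0-based voxel indices).
#'   Defaults to a diagonal scaling by \code{voxel_size} centred so that
#'   world origin falls at the grid centre.
#' @param brain_mask logical or 0/1 array of dimension \code{dims} with at
#'   least one \code{TRUE} voxel.  Defaults to all-\code{TRUE}.
#' @return An object of class \code{volume_grid}.
#' @export
volume_grid <- function(dims, voxel_size = c(2, 2, 2), affine = NULL,
                        brain_mask = NULL) {
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(dims < 1L))
    stop("`dims` must be three integers >= 1")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("`voxel_size` must be three positive numbers")
  if (is.null(affine)) {
    affine <- diag(c(voxel_size, 1))
    affine[1:3, 4] <- -voxel_size * (dims - 1) / 2
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) || abs(det(affine)) < .Machine$double.eps)
    stop("`affine` must be an invertible 4x4 matrix")
  if (is.null(brain_mask)) brain_mask <- array(TRUE, dim = dims)
  brain_mask <- array(as.logical(brain_mask), dim = dims)
  if (!all(dim(brain_mask) == dims))
    stop("`brain_mask` dimensions must equal `dims`")
  if (!any(brain_mask)) stop("`brain_mask` must contain at least one voxel")
  structure(list(dims = dims, voxel_size = voxel_size, affine = affine,
                 brain_mask = brain_mask),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat("<volume_grid> ", paste(x$dims, collapse = " x "),
      " voxels @ ", paste(x$voxel_size, collapse = "x"), " mm; ",
      sum(x$brain_mask), " in-mask voxels\n", sep = "")
  invisible(x)
}

#' In-mask voxel indices
#'
#' The canonical ordering of brain-mask voxels used by every voxel-wise
#' statistic in the package: linear array indices in R's native
#' column-major order (first axis fastest), i.e. \code{which(brain_mask)}.
#' The ordering is deterministic; all connectome matrices and statistic
#' vectors follow it row for row.
#'
#' @param grid a \code{volume_grid}.
#' @return Integer vector of linear array indices into the grid's arrays.
#' @export
in_mask_indices <- function(grid) {
  stopifnot(inherits(grid, "volume_grid"))
  idx <- which(grid$brain_mask)
  if (length(idx) == 0L) stop("brain mask is empty")
  idx
}

#' Construct a volume
#'
#' A \code{volume} couples a data array to a grid with a declared kind:
#' \code{"binary"} (values in \{0,1\}), \code{"count"} (non-negative
#' integers) or \code{"statistic"} (any real).  Kind invariants are
#' checked at construction.
#'
#' @param data numeric array matching \code{grid$dims}.
#' @param grid a \code{volume_grid}.
#' @param kind one of \code{"binary"}, \code{"count"}, \code{"statistic"}.
#' @return An object of class \code{lnm_volume}.
#' @export
volume <- function(data, grid, kind = c("statistic", "binary", "count")) {
  kind <- match.arg(kind)
  stopifnot(inherits(grid, "volume_grid"))
  data <- array(as.numeric(data), dim = dim(as.array(data)))
  if (length(dim(data)) != 3L)
    stop("volume data must be 3-D; got ", length(dim(data)), " dimensions")
  if (!all(dim(data) == grid$dims))
    stop("volume data dimensions do not match grid dims")
  vals <- data[!is.na(data)]
  if (kind == "binary" && !all(vals %in% c(0, 1)))
    stop("binary volume contains values other than {0, 1}")
  if (kind == "count" && (any(vals < 0) || any(vals != round(vals))))
    stop("count volume contains negative or non-integer values")
  structure(list(grid = grid, data = data, kind = kind), class = "lnm_volume")
}

#' @export
print.lnm_volume <- function(x, ...) {
  cat("<volume:", x$kind, "> ", paste(dim(x$data), collapse = " x "),
      "; ", sum(x$data != 0, na.rm = TRUE), " non-zero voxels\n", sep = "")
  invisible(x)
}

#' Construct a lesion mask
#'
#' One case's lesion tracing as a binary volume.  Non-contiguous foci are
#' permitted and treated as a single seed.  The foreground must be
#' non-empty and lie inside the grid's brain mask.
#'
#' @param case_id character scalar identifying the case.
#' @param vol a binary \code{lnm_volume}.
#' @return An object of class \code{lesion_mask}.
#' @export
lesion_mask <- function(case_id, vol) {
  stopifnot(inherits(vol, "lnm_volume"))
  if (vol$kind != "binary") stop("lesion mask volume must be binary")
  fg <- which(vol$data == 1)
  if (length(fg) == 0L) stop("lesion mask '", case_id, "' has no foreground voxels")
  if (!all(vol$grid$brain_mask[fg]))
    stop("lesion mask '", case_id, "' has foreground outside the brain mask")
  structure(list(case_id = as.character(case_id), volume = vol),
            class = "lesion_mask")
}

#' @export
print.lesion_mask <- function(x, ...) {
  cat("<lesion_mask> case ", x$case_id, ": ",
      sum(x$volume$data), " voxels\n", sep = "")
  invisible(x)
}

# grids are equal when dims and affines agree within tolerance
grids_compatible <- function(a, b, tol = 1e-4) {
  all(a$dims == b$dims) && max(abs(a$affine - b$affine)) < tol
}

check_same_grid <- function(a, b, what = "input") {
  if (!grids_compatible(a, b))
    stop("grid mismatch: ", what,
         " is not on the shared grid (dims/affine differ); ",
         "inputs must already share one space")
  invisible(TRUE)
}

#' Read a NIfTI volume
#'
#' Reads a 3-D NIfTI-1 file (\code{.nii} or \code{.nii.gz}) into a
#' \code{volume}.  If a reference grid is supplied, the file's dimensions
#' and affine must match it (mismatches are errors, never resampled).
#' Integer masks round-trip bit-exactly.
#'
#' @param path path to a NIfTI-1 file.
#' @param grid optional reference \code{volume_grid} the file must match.
#' @param kind declared kind of the data (validated on load).
#' @return An \code{lnm_volume}.  Without a reference grid, the grid is
#'   reconstructed from the file header with an all-\code{TRUE} mask.
#' @export
read_volume <- function(path, grid = NULL,
                        kind = c("statistic", "binary", "count")) {
  kind <- match.arg(kind)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected a 3-D volume, got ", length(d), "-D data in ", path)
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  data <- array(as.numeric(img), dim = d)
  if (!is.null(grid)) {
    file_grid <- volume_grid(d, voxel_size = RNifti::pixdim(img)[1:3],
                             affine = aff)
    check_same_grid(grid, file_grid, what = basename(path))
  } else {
    grid <- volume_grid(d, voxel_size = RNifti::pixdim(img)[1:3], affine = aff)
  }
  volume(data, grid, kind = kind)
}

#' Write a volume to NIfTI
#'
#' Writes the volume's data with the grid's affine as sform/qform.
#' Out-of-mask voxels of statistic maps are stored as 0 by convention
#' (viewer compatibility); write the brain mask alongside with
#' \code{write_mask} so downstream users can distinguish true zeros.
#'
#' @param vol an \code{lnm_volume}.
#' @param path output path (\code{.nii} or \code{.nii.gz}).
#' @return \code{path}, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "lnm_volume"))
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$grid$voxel_size
  img <- RNifti::`sform<-`(img, structure(vol$grid$affine, code = 2L))
  img <- RNifti::`qform<-`(img, structure(vol$grid$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @param grid a \code{volume_grid} whose brain mask should be written.
#' @export
write_mask <- function(grid, path) {
  write_volume(volume(array(as.numeric(grid$brain_mask), dim = grid$dims),
                      grid, kind = "binary"), path)
}

# lift a vector defined over in_mask_indices into a full 3-D volume;
# out-of-mask voxels become `fill` (0 by default, see write_volume)
vector_to_volume <- function(values, grid, kind = "statistic", fill = 0) {
  idx <- in_mask_indices(grid)
  stopifnot(length(values) == length(idx))
  data <- array(fill, dim = grid$dims)
  data[idx] <- values
  volume(data, grid, kind = kind)
}

# world coordinates (mm) of linear array indices, 0-based voxel convention
voxel_world_coords <- function(grid, lin_idx) {
  ijk <- arrayInd(lin_idx, grid$dims) - 1L
  xyz <- cbind(ijk, 1) %*% t(grid$affine)
  xyz[, 1:3, drop = FALSE]
}
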