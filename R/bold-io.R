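#' Masked BOLD container
#'
#' One subject's 4D BOLD series held as a voxels x time matrix bound to a
#' mask, an affine, and the repetition time. Voxel rows follow the canonical
#' linearization of the mask: coordinates sorted ascending by x, then y,
#' then z (x is the primary key), so a given mask always yields the same row
#' order on every platform.
#'
#' @param data Numeric matrix, voxels x time; all entries finite.
#' @param mask_index Integer matrix, voxels x 3, in-mask (x, y, z)
#'   coordinates in canonical order (rows must match `data`).
#' @param dims Length-3 integer grid dimensions.
#' @param affine 4x4 voxel-to-world transform.
#' @param tr_seconds Repetition time in seconds (> 0).
#' @param id Optional subject identifier.
#' @return Object of class `masked_bold`.
#' @export
masked_bold <- function(data, mask_index, dims, affine = diag(4),
                        tr_seconds = 2.0, id = NULL) {
  data <- as.matrix(data)
  mask_index <- as.matrix(mask_index)
  if (nrow(data) != nrow(mask_index)) {
    stopf("data has %d rows but mask has %d voxels", nrow(data),
          nrow(mask_index))
  }
  if (any(!is.finite(data))) stopf("BOLD data contains non-finite values")
  if (!is.numeric(tr_seconds) || length(tr_seconds) != 1L || tr_seconds <= 0) {
    stopf("tr_seconds must be a positive scalar")
  }
  structure(
    list(data = data, mask_index = mask_index, dims = as.integer(dims),
         affine = affine, tr_seconds = tr_seconds, id = id),
    class = "masked_bold"
  )
}

#' @export
print.masked_bold <- function(x, ...) {
  cat(sprintf("<masked_bold%s> %d voxels x %d timepoints, TR = %gs\n",
              if (is.null(x$id)) "" else paste0(" ", x$id),
              nrow(x$data), ncol(x$data), x$tr_seconds))
  invisible(x)
}

# Canonical linearization: sort in-mask coordinates ascending by x, y, z.
mask_coords <- function(mask) {
  co <- which(mask != 0, arr.ind = TRUE)
  if (nrow(co) == 0L) stopf("mask is empty")
  co <- co[order(co[, 1], co[, 2], co[, 3]), , drop = FALSE]
  dimnames(co) <- list(NULL, c("x", "y", "z"))
  co
}

linear_index <- function(mask_index, dims) {
  mask_index[, 1] +
    (mask_index[, 2] - 1L) * dims[1] +
    (mask_index[, 3] - 1L) * dims[1] * dims[2]
}

affines_compatible <- function(a, b, tol = 1e-4) {
  all(abs(a - b) <= tol)
}

#' Load a 4D BOLD image under a mask
#'
#' Reads a NIfTI-1 4D series and a 3D mask on the same grid and returns the
#' in-mask data as a voxels x time matrix in canonical voxel order. Voxels
#' whose series has zero variance are flagged in the `zero_variance`
#' attribute of the returned object's data (they are retained, not dropped).
#'
#' @param image_path Path to the 4D NIfTI image.
#' @param mask_path Path to the 3D NIfTI mask (nonzero = in mask).
#' @param tr_seconds Repetition time; if `NULL`, taken from the image header.
#' @param id Optional subject identifier.
#' @return A [masked_bold()] object.
#' @export
load_bold_masked <- function(image_path, mask_path, tr_seconds = NULL,
                             id = NULL) {
  img <- RNifti::readNifti(image_path)
  msk <- RNifti::readNifti(mask_path)
  if (length(dim(img)) != 4L) stopf("image must be 4D, got %dD",
                                    length(dim(img)))
  if (length(dim(msk)) != 3L) stopf("mask must be 3D, got %dD",
                                    length(dim(msk)))
  if (!all(dim(img)[1:3] == dim(msk))) {
    stopf("image grid (%s) does not match mask grid (%s)",
          paste(dim(img)[1:3], collapse = "x"),
          paste(dim(msk), collapse = "x"))
  }
  if (!affines_compatible(RNifti::xform(img), RNifti::xform(msk))) {
    stopf("image and mask affines differ by more than 1e-4")
  }
  dims <- dim(img)[1:3]
  nt <- dim(img)[4]
  co <- mask_coords(msk)
  lin <- linear_index(co, dims)
  flat <- matrix(as.numeric(img), nrow = prod(dims), ncol = nt)
  data <- flat[lin, , drop = FALSE]
  if (any(!is.finite(data))) stopf("in-mask BOLD data contains non-finite values")
  if (is.null(tr_seconds)) {
    pd <- RNifti::pixdim(img)
    tr_seconds <- if (length(pd) >= 4 && pd[4] > 0) pd[4] else 1
  }
  mb <- masked_bold(data, co, dims, RNifti::xform(img), tr_seconds, id = id)
  attr(mb$data, "zero_variance") <-
    apply(mb$data, 1, function(v) all(v == v[1]))
  mb
}

#' Write a masked BOLD series as a 4D NIfTI image
#'
#' Out-of-mask voxels are written as 0.
#'
#' @param bold A [masked_bold()] object.
#' @param path Output path (`.nii`).
#' @return `path`, invisibly.
#' @export
write_bold_nifti <- function(bold, path) {
  dims <- bold$dims
  nt <- ncol(bold$data)
  arr <- array(0, dim = c(dims, nt))
  lin <- linear_index(bold$mask_index, dims)
  flat <- matrix(0, nrow = prod(dims), ncol = nt)
  flat[lin, ] <- bold$data
  arr[] <- flat
  img <- RNifti::asNifti(arr)
  RNifti::sform(img) <- structure(bold$affine, code = 2L)
  RNifti::qform(img) <- structure(bold$affine, code = 2L)
  vox <- sqrt(colSums(bold$affine[1:3, 1:3]^2))
  RNifti::pixdim(img) <- c(vox, bold$tr_seconds)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a 3D mask as NIfTI
#'
#' @param mask_index Voxels x 3 coordinate matrix.
#' @inheritParams masked_bold
#' @param path Output path.
#' @export
write_mask_nifti <- function(mask_index, dims, affine = diag(4), path) {
  arr <- array(0L, dim = dims)
  arr[linear_index(as.matrix(mask_index), dims)] <- 1L
  img <- RNifti::asNifti(arr)
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::qform(img) <- structure(affine, code = 2L)
  RNifti::pixdim(img) <- sqrt(colSums(affine[1:3, 1:3]^2))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Save a per-voxel statistic map as a 3D NIfTI image
#'
#' Values are placed at their mask coordinates (any row order, as long as it
#' matches `values`); out-of-mask voxels are written as 0. A saved map
#' reloads to 32-bit float precision.
#'
#' @param values Numeric vector, one value per mask voxel.
#' @param mask_index Voxels x 3 coordinate matrix aligned with `values`.
#' @param dims Length-3 grid dimensions.
#' @param affine 4x4 voxel-to-world transform.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_map <- function(values, mask_index, dims, affine = diag(4), path) {
  mask_index <- as.matrix(mask_index)
  if (length(values) != nrow(mask_index)) {
    stopf("map has %d values but mask has %d voxels", length(values),
          nrow(mask_index))
  }
  arr <- array(0, dim = dims)
  arr[linear_index(mask_index, dims)] <- values
  img <- RNifti::asNifti(arr)
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::qform(img) <- structure(affine, code = 2L)
  RNifti::pixdim(img) <- sqrt(colSums(affine[1:3, 1:3]^2))
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' Load a statistic map under a mask (canonical voxel order)
#'
#' @param path Path to a 3D NIfTI map.
#' @param mask_path Path to the 3D mask defining the voxel set and order.
#' @return Numeric vector of in-mask values in canonical order.
#' @export
load_map_masked <- function(path, mask_path) {
  img <- RNifti::readNifti(path)
  msk <- RNifti::readNifti(mask_path)
  if (!all(dim(img) == dim(msk))) stopf("map and mask grids differ")
  co <- mask_coords(msk)
  as.numeric(img)[linear_index(co, dim(msk))]
}
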