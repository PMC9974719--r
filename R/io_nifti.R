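#' Read and write volumes and masks as NIfTI
#'
#' Volumes are stored as 32-bit floats, masks as unsigned 8-bit integers with
#' values 0/1.  The affine written is diagonal (no rotation): spacing on the
#' diagonal, origin in the translation column.  On read, affines are
#' normalized to the package's internal convention (positive spacing,
#' ascending voxel-centre coordinates): pure axis flips encoded as negative
#' diagonal entries are undone by flipping the array; oblique (rotated)
#' affines are rejected.
#'
#' @param grid a [volume_grid()] (for `write_volume`).
#' @param mask a [structure_mask()] (for `write_mask`).
#' @param path file path, conventionally ending in `.nii.gz`.
#' @param name structure name to attach on `read_mask`.
#' @return `read_volume` returns a [volume_grid()]; `read_mask` a
#'   [structure_mask()]; the writers return `path` invisibly.
#' @export
write_volume <- function(grid, path) {
  .write_nifti(grid$data, grid$spacing, grid$origin, path, "float")
}

#' @rdname write_volume
#' @export
write_mask <- function(mask, path) {
  .write_nifti(array(as.integer(mask$data), dim = dim(mask$data)),
               mask$spacing, mask$origin, path, "uint8")
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  g <- .read_nifti(path)
  volume_grid(g$data, g$spacing, g$origin)
}

#' @rdname write_volume
#' @export
read_mask <- function(path, name = sub("\\.nii(\\.gz)?$", "", basename(path))) {
  g <- .read_nifti(path)
  if (!all(g$data %in% c(0, 1)))
    stop(sprintf("'%s' is not a binary mask (values outside {0, 1})", path),
         call. = FALSE)
  structure_mask(name, g$data == 1, g$spacing, g$origin)
}

.write_nifti <- function(data, spacing, origin, path, datatype) {
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- spacing
  m <- diag(c(spacing, 1))
  m[1:3, 4] <- origin
  img <- RNifti::`qform<-`(img, structure(m, code = 2L))
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

.read_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  a <- array(as.vector(img), dim = dim(img))
  if (length(dim(a)) != 3L)
    stop(sprintf("'%s' is not a 3-D volume", path), call. = FALSE)
  xf <- unclass(RNifti::xform(img))
  rot <- xf[1:3, 1:3]
  if (any(abs(rot[row(rot) != col(rot)]) > 1e-4 * max(abs(diag(rot)))))
    stop(sprintf("'%s' has an oblique affine; only axis-aligned volumes are supported",
                 path), call. = FALSE)
  spacing <- diag(rot)
  origin <- xf[1:3, 4]
  # normalize axis flips: negative diagonal -> flip array, move origin
  for (ax in 1:3) {
    if (spacing[ax] < 0) {
      n <- dim(a)[ax]
      idx <- rep(list(quote(expr = )), 3)
      idx[[ax]] <- n:1
      a <- do.call(`[`, c(list(a), idx, drop = FALSE))
      origin[ax] <- origin[ax] + spacing[ax] * (n - 1)
      spacing[ax] <- -spacing[ax]
    }
  }
  list(data = a, spacing = spacing, origin = origin)
}
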