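#' Create a 3-D scalar volume with physical geometry
#'
#' A `volume_grid` is the basic container used throughout the package for
#' signal images, CBF maps (ml/100 g/min) and dose grids (Gy): a 3-D numeric
#' array plus voxel spacing (mm per axis) and the physical coordinate of the
#' centre of voxel `[1, 1, 1]`.  Voxel `[i, j, k]` is centred at
#' `origin + (c(i, j, k) - 1) * spacing`.
#'
#' @param data 3-D numeric array.
#' @param spacing numeric length-3, voxel spacing in mm (all > 0).
#' @param origin numeric length-3, mm coordinate of the first voxel centre.
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(data, spacing, origin = c(0, 0, 0)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L)
    stop("'data' must be a 3-D array", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be 3 positive values (mm)", call. = FALSE)
  origin <- as.numeric(origin)
  if (length(origin) != 3L)
    stop("'origin' must have length 3", call. = FALSE)
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "volume_grid")
}

#' Create a named binary structure mask
#'
#' A `structure_mask` is a named binary volume (GTV, PTV, an organ at risk,
#' ...) sharing the geometry of the grids it is evaluated against.
#'
#' @param name label for the structure (e.g. `"gtv"`, `"brainstem"`).
#' @param data logical (or 0/1) 3-D array.
#' @param spacing,origin geometry, as in [volume_grid()].
#' @return An object of class `structure_mask`.
#' @export
structure_mask <- function(name, data, spacing, origin = c(0, 0, 0)) {
  data <- as.array(data)
  if (!is.logical(data)) {
    if (!all(data %in% c(0, 1)))
      stop("mask values must be 0/1 or logical", call. = FALSE)
    data <- array(as.logical(data), dim = dim(data))
  }
  g <- volume_grid(array(0, dim = dim(data)), spacing, origin)
  structure(list(name = as.character(name), data = data,
                 spacing = g$spacing, origin = g$origin),
            class = "structure_mask")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<volume_grid> %s voxels @ %s mm, range [%.4g, %.4g]\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing, trim = TRUE), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.structure_mask <- function(x, ...) {
  cat(sprintf("<structure_mask> '%s': %d voxels (%.2f cc) on %s grid\n",
              x$name, sum(x$data), volume_cc(x),
              paste(dim(x$data), collapse = "x")))
  invisible(x)
}

#' Structure volume in cubic centimetres
#'
#' Voxel-counting volume: number of mask voxels times the voxel volume.
#'
#' @param mask a [structure_mask()].
#' @return volume in cc.
#' @export
volume_cc <- function(mask) {
  sum(mask$data) * prod(mask$spacing) / 1000
}

# geometry comparison with a small absolute tolerance on spacing/origin
same_geometry <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

assert_same_geometry <- function(..., what = "inputs") {
  grids <- list(...)
  for (g in grids[-1])
    if (!same_geometry(grids[[1]], g))
      stop(sprintf("%s do not share one geometry (shape/spacing/origin)",
                   what), call. = FALSE)
  invisible(TRUE)
}

# physical voxel-centre coordinates along each axis
axis_coords <- function(geom) {
  d <- dim(geom$data)
  list(x = geom$origin[1] + (seq_len(d[1]) - 1) * geom$spacing[1],
       y = geom$origin[2] + (seq_len(d[2]) - 1) * geom$spacing[2],
       z = geom$origin[3] + (seq_len(d[3]) - 1) * geom$spacing[3])
}

# empty mask sharing geometry with `geom`
empty_mask_like <- function(name, geom) {
  structure_mask(name, array(FALSE, dim = dim(geom$data)),
                 geom$spacing, geom$origin)
}

mask_like <- function(name, data, geom) {
  structure_mask(name, data, geom$spacing, geom$origin)
}

#' Boolean operations on structure masks
#'
#' Set algebra on masks sharing one geometry.  `mask_subtract()` implements
#' the set difference used to derive GTV-SUB (GTV minus GTV-ASL) and PTV-SUB
#' (PTV minus PTV-ASL).
#'
#' @param a,b [structure_mask()] objects on the same geometry.
#' @param name name for the result (default derived from the operands).
#' @return A [structure_mask()].
#' @export
mask_subtract <- function(a, b, name = paste0(a$name, "-sub")) {
  assert_same_geometry(a, b, what = "masks")
  mask_like(name, a$data & !b$data, a)
}

#' @rdname mask_subtract
#' @export
mask_intersect <- function(a, b, name = paste(a$name, b$name, sep = "&")) {
  assert_same_geometry(a, b, what = "masks")
  mask_like(name, a$data & b$data, a)
}

#' @rdname mask_subtract
#' @export
mask_union <- function(a, b, name = paste(a$name, b$name, sep = "|")) {
  assert_same_geometry(a, b, what = "masks")
  mask_like(name, a$data | b$data, a)
}

#' Reflect a mask across the mid-sagittal plane
#'
#' The mid-sagittal plane is the grid's central x-plane; reflection maps
#' voxel index `i` to `nx + 1 - i`, which preserves voxel count on any grid.
#'
#' @param mask a [structure_mask()].
#' @param name name for the reflected mask.
#' @return A [structure_mask()].
#' @export
reflect_mask <- function(mask, name = paste0(mask$name, "-mirror")) {
  nx <- dim(mask$data)[1]
  mask_like(name, mask$data[nx:1, , , drop = FALSE], mask)
}
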