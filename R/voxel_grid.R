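#' Voxel grid: a 3D volume with physical spacing
#'
#' The universal carrier for images and masks in hepamorph.  `data` is a 3D
#' array (grayscale values, integer labels, or logical masks); `spacing` gives
#' the physical voxel size in micrometres per axis; the physical coordinate of
#' voxel index `i` (1-based in R) is `origin + (i - 1) * spacing`
#' (voxel-centred).
#'
#' @param data 3D array (numeric, integer or logical).
#' @param spacing numeric length-3, micrometres per voxel along each axis.
#' @param origin numeric length-3 physical offset in micrometres.
#' @param kind `"grayscale"` or `"labels"`.  Label grids must hold integers
#'   (or logicals, treated as 0/1 labels).
#' @return an object of class `voxel_grid`.
#' @export
voxel_grid <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                       kind = c("grayscale", "labels")) {
  kind <- match.arg(kind)
  if (length(dim(data)) != 3L)
    stop("voxel_grid data must be a 3D array")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three positive values (micrometres)")
  if (kind == "labels" && is.double(data)) {
    if (any(data != round(data), na.rm = TRUE))
      stop("label grids must hold integers")
    storage.mode(data) <- "integer"
  }
  structure(list(data = data, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), kind = kind),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<voxel_grid %s> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g um\n",
              x$kind, d[1], d[2], d[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' @export
dim.voxel_grid <- function(x) dim(x$data)

#' Physical volume of one voxel in cubic micrometres
#' @param grid a `voxel_grid`
#' @return scalar, um^3
#' @export
voxel_volume <- function(grid) prod(grid$spacing)

# internal checks ------------------------------------------------------------

#' @noRd
stopifnot_voxel_grid <- function(x, what = "input") {
  if (!inherits(x, "voxel_grid")) stop(what, " must be a voxel_grid")
  invisible(x)
}

#' @noRd
check_same_grid <- function(a, b, what = "grids") {
  if (!identical(dim(a$data), dim(b$data)) ||
      max(abs(a$spacing - b$spacing)) > 1e-9)
    stop(what, " must share shape and spacing")
  invisible(TRUE)
}

#' @noRd
check_isotropic <- function(grid, what = "this operation") {
  s <- grid$spacing
  if (max(s) - min(s) > 1e-9 * max(s))
    stop(what, " requires an isotropic grid; resample_isotropic() first")
  invisible(TRUE)
}

#' @noRd
as_logical_mask <- function(grid) {
  d <- grid$data
  if (is.logical(d)) return(d)
  d != 0
}

# physical <-> index conversion ----------------------------------------------

#' Convert physical coordinates (um) to 1-based voxel indices
#'
#' Coordinates map to the nearest voxel centre.  Positions outside the volume
#' raise an error.
#' @param grid a `voxel_grid`
#' @param xyz numeric matrix (n x 3) or length-3 vector of um coordinates
#' @return integer matrix (n x 3) of 1-based indices
#' @export
phys_to_index <- function(grid, xyz) {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  idx <- round(sweep(sweep(xyz, 2, grid$origin, "-"), 2, grid$spacing, "/")) + 1
  d <- dim(grid$data)
  bad <- idx[, 1] < 1 | idx[, 2] < 1 | idx[, 3] < 1 |
    idx[, 1] > d[1] | idx[, 2] > d[2] | idx[, 3] > d[3]
  if (any(bad))
    stop(sum(bad), " point(s) fall outside the volume bounds")
  storage.mode(idx) <- "integer"
  idx
}

#' @noRd
index_to_phys <- function(grid, idx) {
  if (is.null(dim(idx))) idx <- matrix(idx, nrow = 1)
  sweep(sweep(idx - 1, 2, grid$spacing, "*"), 2, grid$origin, "+")
}

#' @noRd
linear_index <- function(d, idx) {
  # 1-based (i, j, k) -> 1-based linear index in column-major order
  as.numeric(idx[, 1]) + as.numeric(d[1]) * (idx[, 2] - 1) +
    as.numeric(d[1]) * d[2] * (idx[, 3] - 1)
}

# shared wrappers over the compiled kernels ----------------------------------

#' Euclidean distance transform
#'
#' For every voxel, the exact Euclidean distance (um) to the nearest voxel of
#' the foreground mask, honouring anisotropic spacing.  Foreground voxels get
#' distance 0; if the mask is empty every distance is `Inf`.
#' @param mask a `voxel_grid` holding a logical/binary mask
#' @return a `voxel_grid` of distances in um
#' @export
distance_transform <- function(mask) {
  stopifnot_voxel_grid(mask, "mask")
  m <- as_logical_mask(mask)
  d <- cpp_edt(as.vector(m), dim(m), mask$spacing)
  voxel_grid(array(d, dim(m)), mask$spacing, mask$origin, "grayscale")
}
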