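#' 3D scalar volume with physical grid metadata
#'
#' A `volume_image` is a 3D array of intensities (Hounsfield-like units)
#' together with voxel spacing (mm) and the world position of the center of
#' voxel `(0,0,0)` (0-based indices). Orientation is always identity: the
#' world position of voxel `(i,j,k)` is `origin + c(i,j,k) * spacing`.
#'
#' @param data numeric 3D array.
#' @param spacing positive numeric 3-vector, mm per voxel along each axis.
#' @param origin numeric 3-vector, world coordinates (mm) of voxel (0,0,0).
#' @return An object of class `volume_image`.
#' @export
volume_image <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("volume data must be a 3D array, got ", length(dim(data)), " dimensions")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 strictly positive finite values")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be 3 finite values")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "volume_image")
}

#' Binary segmentation mask on a volume grid
#'
#' Same grid fields as [volume_image()]; voxel values restricted to 0/1.
#'
#' @inheritParams volume_image
#' @return An object of class `c("binary_mask", "volume_image")`.
#' @export
binary_mask <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  vals <- unique(as.vector(data))
  if (!all(vals %in% c(0, 1)))
    stop("mask values must be 0 or 1")
  img <- volume_image(array(as.integer(data), dim = dim(data)), spacing, origin)
  class(img) <- c("binary_mask", "volume_image")
  img
}

#' @export
print.volume_image <- function(x, ...) {
  cat(sprintf("<%s> %s voxels, spacing %s mm, origin %s mm\n",
              class(x)[1], paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              paste(signif(x$origin, 4), collapse = ", ")))
  invisible(x)
}

#' Grid descriptor of a volume
#'
#' @param x a `volume_image`, or a list with `dim`, `spacing`, `origin`.
#' @return list with elements `dim`, `spacing`, `origin`.
#' @export
grid_of <- function(x) {
  if (inherits(x, "volume_image"))
    return(list(dim = dim(x$data), spacing = x$spacing, origin = x$origin))
  stopifnot(is.list(x), all(c("dim", "spacing", "origin") %in% names(x)))
  list(dim = as.integer(x$dim), spacing = as.numeric(x$spacing),
       origin = as.numeric(x$origin))
}

same_grid <- function(a, b, tol = 1e-9) {
  ga <- grid_of(a); gb <- grid_of(b)
  identical(ga$dim, gb$dim) &&
    max(abs(ga$spacing - gb$spacing)) <= tol &&
    max(abs(ga$origin - gb$origin)) <= tol
}

#' World coordinates of all voxel centers of a grid
#'
#' Row order follows R's array linearization (first index fastest).
#'
#' @param grid a grid descriptor or `volume_image`.
#' @return numeric matrix `prod(dim)` x 3, world mm.
#' @export
voxel_centers <- function(grid) {
  g <- grid_of(grid)
  i <- seq_len(g$dim[1]) - 1L
  j <- seq_len(g$dim[2]) - 1L
  k <- seq_len(g$dim[3]) - 1L
  cbind(
    g$origin[1] + g$spacing[1] * rep(i, times = g$dim[2] * g$dim[3]),
    g$origin[2] + g$spacing[2] * rep(rep(j, each = g$dim[1]), times = g$dim[3]),
    g$origin[3] + g$spacing[3] * rep(k, each = g$dim[1] * g$dim[2])
  )
}

#' Convert world points to continuous 0-based voxel indices
#'
#' @param points n x 3 matrix of world mm coordinates.
#' @param grid grid descriptor or `volume_image`.
#' @return n x 3 matrix of continuous 0-based indices.
#' @export
world_to_index <- function(points, grid) {
  g <- grid_of(grid)
  points <- rbind(points)
  sweep(sweep(points, 2, g$origin, "-"), 2, g$spacing, "/")
}

#' Convert 0-based voxel indices to world coordinates
#'
#' @param idx n x 3 matrix of (possibly continuous) 0-based indices.
#' @param grid grid descriptor or `volume_image`.
#' @return n x 3 matrix of world mm coordinates.
#' @export
index_to_world <- function(idx, grid) {
  g <- grid_of(grid)
  idx <- rbind(idx)
  sweep(sweep(idx, 2, g$spacing, "*"), 2, g$origin, "+")
}

#' Trilinear sampling of a volume at world points
#'
#' Points outside the grid return `fill`.
#'
#' @param img a `volume_image`.
#' @param points n x 3 world mm coordinates.
#' @param fill value for out-of-field points.
#' @return numeric vector of sampled intensities.
#' @export
sample_trilinear <- function(img, points, fill = NA_real_) {
  idx <- world_to_index(points, img)
  cpp_trilinear(as.numeric(img$data), dim(img$data), idx, fill)
}
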