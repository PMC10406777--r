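# Tetrahedral mesh geometry: construction, barycentric coordinates, point
# location (uniform-bin accelerated, exhaustive-equivalent), rasterization
# and structured tet grids used by the phantom generator.

#' Corresponded tetrahedral mesh
#'
#' Vertices are world-mm coordinates; correspondence across a population is
#' positional (vertex i of every mesh is the same anatomical point). Tets
#' are reoriented on construction so all signed volumes are positive;
#' degenerate tets (volume below 1e-9 mm^3) are an error.
#'
#' @param vertices V x 3 numeric matrix (world mm).
#' @param tets T x 4 integer matrix of 1-based vertex indices.
#' @param surface_vertex_ids optional integer vector of boundary vertex ids.
#' @return object of class `tet_mesh`.
#' @export
tet_mesh <- function(vertices, tets, surface_vertex_ids = NULL) {
  vertices <- as.matrix(vertices); storage.mode(vertices) <- "double"
  tets <- as.matrix(tets); storage.mode(tets) <- "integer"
  stopifnot(ncol(vertices) == 3L, ncol(tets) == 4L)
  if (nrow(tets) > 0L) {
    if (min(tets) < 1L || max(tets) > nrow(vertices))
      stop("tet indices out of range")
    vol <- tet_signed_volumes(vertices, tets)
    flip <- vol < 0
    if (any(flip)) tets[flip, c(3L, 4L)] <- tets[flip, c(4L, 3L)]
    vol <- abs(vol)
    if (any(vol <= 1e-9))
      stop("degenerate tetrahedra (volume <= 1e-9 mm^3): ",
           paste(utils::head(which(vol <= 1e-9), 5), collapse = ","))
  }
  structure(list(vertices = vertices, tets = tets,
                 surface_vertex_ids = surface_vertex_ids),
            class = "tet_mesh")
}

#' @export
print.tet_mesh <- function(x, ...) {
  cat(sprintf("<tet_mesh> %d vertices, %d tetrahedra\n",
              nrow(x$vertices), nrow(x$tets)))
  invisible(x)
}

tet_signed_volumes <- function(vertices, tets) {
  a <- vertices[tets[, 1L], , drop = FALSE]
  b <- vertices[tets[, 2L], , drop = FALSE] - a
  c_ <- vertices[tets[, 3L], , drop = FALSE] - a
  d <- vertices[tets[, 4L], , drop = FALSE] - a
  (b[, 1] * (c_[, 2] * d[, 3] - c_[, 3] * d[, 2]) -
   b[, 2] * (c_[, 1] * d[, 3] - c_[, 3] * d[, 1]) +
   b[, 3] * (c_[, 1] * d[, 2] - c_[, 2] * d[, 1])) / 6
}

#' Total volume of a tetrahedral mesh
#' @param mesh a [tet_mesh()].
#' @return total volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  sum(abs(tet_signed_volumes(mesh$vertices, mesh$tets)))
}

#' Barycentric coordinates of a point in a given tetrahedron
#'
#' @param point world-mm 3-vector.
#' @param mesh a [tet_mesh()].
#' @param tet_id 1-based tetrahedron index.
#' @return list with `p` (4 barycentric components summing to 1) and `tet_id`.
#' @export
barycentric_coordinates <- function(point, mesh, tet_id) {
  stopifnot(tet_id >= 1L, tet_id <= nrow(mesh$tets))
  vi <- mesh$tets[tet_id, ]
  v4 <- mesh$vertices[vi[4L], ]
  M <- t(mesh$vertices[vi[1:3], , drop = FALSE]) - v4
  if (abs(det(M)) < 1e-12) stop("geometry error: degenerate tetrahedron ", tet_id)
  b123 <- solve(M, as.numeric(point) - v4)
  p <- c(b123, 1 - sum(b123))
  list(p = p, tet_id = as.integer(tet_id))
}

#' Locate points in a tetrahedral mesh
#'
#' Returns, per point, the containing tetrahedron and barycentric
#' coordinates, or tet 0 for points outside the mesh. Containment means all
#' barycentric components are at least `-tol`. Points on shared faces
#' resolve deterministically to the lowest incident tet index. A uniform
#' spatial bin structure accelerates the search; results are identical to
#' exhaustive scanning.
#'
#' @param points n x 3 matrix of world-mm coordinates (a single 3-vector is
#'   accepted).
#' @param mesh a [tet_mesh()].
#' @param tol containment tolerance on barycentric components.
#' @return list with `tet` (integer n-vector, 0 = outside) and `bary`
#'   (n x 4 matrix).
#' @export
locate_points <- function(points, mesh, tol = 1e-9) {
  points <- rbind(points)
  cpp_locate_points(mesh$vertices, mesh$tets, points, tol)
}

#' Locate a single point
#'
#' Convenience wrapper around [locate_points()]: returns `NULL` when the
#' point lies outside all tetrahedra.
#'
#' @inheritParams locate_points
#' @param point world-mm 3-vector.
#' @return list with `p` (barycentric) and `tet_id`, or `NULL`.
#' @export
locate_point <- function(point, mesh, tol = 1e-9) {
  res <- locate_points(matrix(point, 1L), mesh, tol)
  if (res$tet[1L] == 0L) return(NULL)
  list(p = as.numeric(res$bary[1L, ]), tet_id = res$tet[1L])
}

#' Rasterize a tetrahedral mesh to a binary mask
#'
#' A voxel is set to 1 iff its center lies inside some tetrahedron.
#'
#' @param mesh a [tet_mesh()].
#' @param grid grid descriptor or [volume_image()].
#' @return a [binary_mask()] on that grid.
#' @export
rasterize_mask <- function(mesh, grid) {
  g <- grid_of(grid)
  inside <- if (nrow(mesh$tets) == 0L) integer(prod(g$dim)) else {
    loc <- locate_points(voxel_centers(g), mesh)
    as.integer(loc$tet > 0L)
  }
  binary_mask(array(inside, dim = g$dim), g$spacing, g$origin)
}

# 5-tet decomposition of the unit cube; corner ids use bit order (x,y,z).
# Parity-flipped in alternating cells so faces match across neighbors.
tet5_template <- function(parity) {
  if (parity == 0L)
    rbind(c(0L, 1L, 2L, 4L), c(1L, 2L, 3L, 7L), c(1L, 4L, 5L, 7L),
          c(2L, 4L, 6L, 7L), c(1L, 2L, 4L, 7L))
  else
    rbind(c(0L, 1L, 3L, 5L), c(0L, 2L, 3L, 6L), c(0L, 4L, 5L, 6L),
          c(3L, 5L, 6L, 7L), c(0L, 3L, 5L, 6L))
}

#' Build a structured tetrahedral grid filling a box
#'
#' The box is divided into hexahedral cells, each split into 5 tetrahedra
#' with a fixed parity-alternating template so shared faces are conforming.
#' Total tet volume equals the box volume.
#'
#' @param lower,upper world-mm 3-vectors bounding the box.
#' @param divisions integer 3-vector of cells per axis (each >= 1).
#' @return a [tet_mesh()] with `5 * prod(divisions)` tetrahedra.
#' @export
build_tet_grid <- function(lower, upper, divisions) {
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  divisions <- as.integer(divisions)
  if (any(upper <= lower)) stop("box must have positive extent on every axis")
  if (any(divisions < 1L)) stop("divisions must be >= 1")
  nd <- divisions + 1L
  xs <- seq(lower[1], upper[1], length.out = nd[1])
  ys <- seq(lower[2], upper[2], length.out = nd[2])
  zs <- seq(lower[3], upper[3], length.out = nd[3])
  verts <- cbind(rep(xs, times = nd[2] * nd[3]),
                 rep(rep(ys, each = nd[1]), times = nd[3]),
                 rep(zs, each = nd[1] * nd[2]))
  nid <- function(i, j, k) 1L + i + nd[1] * (j + nd[2] * k)  # 0-based ijk
  tets <- vector("list", prod(divisions))
  n <- 0L
  for (k in 0:(divisions[3] - 1L))
    for (j in 0:(divisions[2] - 1L))
      for (i in 0:(divisions[1] - 1L)) {
        corners <- c(nid(i, j, k), nid(i + 1L, j, k), nid(i, j + 1L, k),
                     nid(i + 1L, j + 1L, k), nid(i, j, k + 1L),
                     nid(i + 1L, j, k + 1L), nid(i, j + 1L, k + 1L),
                     nid(i + 1L, j + 1L, k + 1L))
        tmpl <- tet5_template((i + j + k) %% 2L)
        n <- n + 1L
        tets[[n]] <- matrix(corners[tmpl + 1L], ncol = 4L)
      }
  tet_mesh(verts, do.call(rbind, tets))
}

#' Surface vertices of a tetrahedral mesh
#'
#' Boundary faces are triangular faces incident to exactly one tetrahedron;
#' the result is the sorted set of vertices touching any boundary face.
#'
#' @param mesh a [tet_mesh()].
#' @return integer vector of 1-based vertex ids.
#' @export
extract_surface_vertices <- function(mesh) {
  tt <- mesh$tets
  if (nrow(tt) == 0L) return(integer(0))
  faces <- rbind(tt[, c(1, 2, 3), drop = FALSE], tt[, c(1, 2, 4), drop = FALSE],
                 tt[, c(1, 3, 4), drop = FALSE], tt[, c(2, 3, 4), drop = FALSE])
  key <- apply(t(apply(faces, 1L, sort)), 1L, paste, collapse = "_")
  counts <- table(key)
  boundary <- names(counts)[counts == 1L]
  ids <- sort(unique(as.vector(faces[key %in% boundary, ])))
  as.integer(ids)
}

#' Attach surface vertex ids to a mesh
#'
#' @param mesh a [tet_mesh()].
#' @return the mesh with `surface_vertex_ids` populated.
#' @export
with_surface_vertices <- function(mesh) {
  if (is.null(mesh$surface_vertex_ids))
    mesh$surface_vertex_ids <- extract_surface_vertices(mesh)
  mesh
}
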