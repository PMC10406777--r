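# Per-tetrahedron Bernstein-polynomial intensity encoding. Inside each
# tetrahedron the image intensity is modeled as a degree-d barycentric
# Bernstein density D(p) = sum over i+j+k+l=d of C_{ijkl} * B^d_{ijkl}(p),
# fitted independently per tet by least squares over interior voxel centers.

#' Number of Bernstein coefficients per tetrahedron
#'
#' For degree `d` the barycentric Bernstein basis on a tetrahedron has
#' `m = (d+3)! / (3! d!)` elements.
#'
#' @param d polynomial degree (non-negative integer).
#' @return integer coefficient count.
#' @export
count_coefficients <- function(d) {
  if (length(d) != 1L || is.na(d) || d < 0 || d != round(d))
    stop("degree d must be a single non-negative integer")
  as.integer(round(choose(d + 3, 3)))
}

#' Enumerate Bernstein multi-indices of degree d
#'
#' All non-negative 4-tuples `(i,j,k,l)` with `i+j+k+l = d`, in
#' lexicographically descending order. This order is frozen: model
#' containers store coefficient rows in it.
#'
#' @param d polynomial degree.
#' @return integer matrix `m x 4`.
#' @export
enumerate_multi_indices <- function(d) {
  if (d < 0) stop("degree d must be non-negative")
  d <- as.integer(d)
  out <- matrix(0L, count_coefficients(d), 4L)
  r <- 0L
  for (i in d:0L) for (j in (d - i):0L) for (k in (d - i - j):0L) {
    r <- r + 1L
    out[r, ] <- c(i, j, k, d - i - j - k)
  }
  out
}

#' Barycentric Bernstein basis function
#'
#' `B^d_{ijkl}(p) = d!/(i! j! k! l!) * px^i py^j pz^k pw^l`. Over all
#' multi-indices of one degree the basis is a partition of unity.
#'
#' @param d degree.
#' @param idx length-4 non-negative multi-index summing to `d`.
#' @param p length-4 barycentric coordinates summing to 1.
#' @return basis value.
#' @export
bernstein_basis <- function(d, idx, p) {
  idx <- as.integer(idx)
  if (length(idx) != 4L || any(idx < 0) || sum(idx) != d)
    stop("multi-index must be 4 non-negative integers summing to d")
  coef <- exp(lfactorial(d) - sum(lfactorial(idx)))
  coef * prod(p^idx)
}

# design matrix of all basis functions at many barycentric points
bernstein_design <- function(d, bary) {
  bary <- rbind(bary)
  mi <- enumerate_multi_indices(d)
  m <- nrow(mi)
  out <- matrix(0, nrow(bary), m)
  lcoef <- lfactorial(d) - rowSums(matrix(lfactorial(mi), m, 4L))
  for (c_ in seq_len(m)) {
    out[, c_] <- exp(lcoef[c_]) *
      bary[, 1]^mi[c_, 1] * bary[, 2]^mi[c_, 2] *
      bary[, 3]^mi[c_, 3] * bary[, 4]^mi[c_, 4]
  }
  out
}

#' Intensity encoding container
#'
#' @param degree Bernstein degree `d`.
#' @param coefficients T x m matrix, rows ordered like the mesh tets,
#'   columns in [enumerate_multi_indices()] order.
#' @param mesh_ref optional topology identifier (list of vertex/tet counts).
#' @return object of class `intensity_encoding`.
#' @export
intensity_encoding <- function(degree, coefficients, mesh_ref = NULL) {
  coefficients <- as.matrix(coefficients)
  m <- count_coefficients(degree)
  if (ncol(coefficients) != m)
    stop("coefficient matrix must have m = ", m, " columns for degree ", degree)
  structure(list(degree = as.integer(degree), coefficients = coefficients,
                 mesh_ref = mesh_ref),
            class = "intensity_encoding")
}

#' @export
print.intensity_encoding <- function(x, ...) {
  cat(sprintf("<intensity_encoding> degree %d, %d tets x %d coefficients\n",
              x$degree, nrow(x$coefficients), ncol(x$coefficients)))
  invisible(x)
}

#' Evaluate the encoded density at a barycentric point
#'
#' @param enc an [intensity_encoding()].
#' @param bp a barycentric point: list with `p` (length 4) and `tet_id`.
#' @return intensity value `D(p)`.
#' @export
evaluate_density <- function(enc, bp) {
  tid <- bp$tet_id
  if (tid < 1L || tid > nrow(enc$coefficients))
    stop("tet id ", tid, " out of range")
  B <- bernstein_design(enc$degree, matrix(bp$p, 1L))
  sum(B[1L, ] * enc$coefficients[tid, ])
}

# vectorized evaluation at located points (tet vector + bary matrix)
evaluate_density_at <- function(enc, tet, bary) {
  B <- bernstein_design(enc$degree, bary)
  rowSums(B * enc$coefficients[tet, , drop = FALSE])
}

#' Fit a Bernstein intensity encoding to an image
#'
#' For each tetrahedron, the coefficients are the least-squares fit over the
#' voxel centers located inside that tet (design rows = basis values at each
#' voxel's barycentric coordinates). Under-determined tets (fewer interior
#' voxels than coefficients, or rank-deficient designs) fall back to a
#' ridge-regularized solve with penalty `1e-6 * trace(X'X)/m`; tets with no
#' interior voxel get constant coefficients equal to the mean image value
#' sampled trilinearly at their four vertices. Both fallbacks are counted in
#' a single warning.
#'
#' @param img a [volume_image()].
#' @param mesh a [tet_mesh()] overlapping the image.
#' @param d Bernstein degree (default 3).
#' @return an [intensity_encoding()].
#' @export
fit_encoding <- function(img, mesh, d = 3L) {
  m <- count_coefficients(d)
  Tn <- nrow(mesh$tets)
  loc <- locate_points(voxel_centers(img), mesh)
  sel <- which(loc$tet > 0L)
  coefs <- matrix(0, Tn, m)
  n_ridge <- 0L; n_empty <- 0L
  if (length(sel)) {
    B <- bernstein_design(d, loc$bary[sel, , drop = FALSE])
    I <- as.numeric(img$data)[sel]
    groups <- split(seq_along(sel), loc$tet[sel])
    for (gname in names(groups)) {
      rows <- groups[[gname]]
      tid <- as.integer(gname)
      X <- B[rows, , drop = FALSE]
      y <- I[rows]
      solved <- FALSE
      if (length(rows) >= m) {
        qrX <- qr(X)
        if (qrX$rank == m) {
          coefs[tid, ] <- qr.coef(qrX, y)
          solved <- TRUE
        }
      }
      if (!solved) {
        G <- crossprod(X)
        lam <- 1e-6 * sum(diag(G)) / m
        coefs[tid, ] <- solve(G + diag(lam, m), crossprod(X, y))
        n_ridge <- n_ridge + 1L
      }
    }
  }
  empty <- seq_len(Tn)[!(seq_len(Tn) %in% loc$tet[sel])]
  if (length(empty)) {
    n_empty <- length(empty)
    for (tid in empty) {
      vp <- mesh$vertices[mesh$tets[tid, ], , drop = FALSE]
      vals <- sample_trilinear(img, vp, fill = NA_real_)
      mv <- mean(vals, na.rm = TRUE)
      coefs[tid, ] <- if (is.finite(mv)) mv else 0
    }
  }
  if (n_ridge + n_empty > 0L)
    warning(sprintf(paste0("fit_encoding: %d under-determined tet(s) solved ",
                           "with ridge regularization, %d empty tet(s) filled ",
                           "from vertex samples"), n_ridge, n_empty))
  intensity_encoding(d, coefs,
                     mesh_ref = list(n_vertices = nrow(mesh$vertices),
                                     n_tets = Tn))
}

#' Rasterize an intensity encoding onto a grid
#'
#' Voxels whose centers lie inside the mesh receive `D(p)`; other voxels
#' get `fill`.
#'
#' @param enc an [intensity_encoding()].
#' @param mesh the [tet_mesh()] the encoding lives on.
#' @param grid grid descriptor or [volume_image()].
#' @param fill value for voxels outside the mesh.
#' @return a [volume_image()].
#' @export
rasterize_encoding <- function(enc, mesh, grid, fill = 0) {
  g <- grid_of(grid)
  out <- rep(fill, prod(g$dim))
  loc <- locate_points(voxel_centers(g), mesh)
  sel <- which(loc$tet > 0L)
  if (length(sel))
    out[sel] <- evaluate_density_at(enc, loc$tet[sel],
                                    loc$bary[sel, , drop = FALSE])
  volume_image(array(out, dim = g$dim), g$spacing, g$origin)
}

#' Mean absolute relative encoding error, in percent
#'
#' Over all voxel centers inside the mesh:
#' `mean(|I - D| / max(|I|, eps)) * 100` with `eps` = 1 intensity unit
#' guarding near-zero intensities.
#'
#' @param img the original [volume_image()].
#' @param enc the fitted [intensity_encoding()].
#' @param mesh the [tet_mesh()] used for the fit.
#' @param eps intensity floor for the relative normalization.
#' @return error percentage (scalar).
#' @export
encoding_error <- function(img, enc, mesh, eps = 1) {
  loc <- locate_points(voxel_centers(img), mesh)
  sel <- which(loc$tet > 0L)
  if (!length(sel)) stop("no voxel centers inside the mesh")
  I <- as.numeric(img$data)[sel]
  D <- evaluate_density_at(enc, loc$tet[sel], loc$bary[sel, , drop = FALSE])
  mean(abs(I - D) / pmax(abs(I), eps)) * 100
}
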