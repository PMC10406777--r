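# Corresponded least-squares alignment (affine, rigid), thin-plate-spline
# transforms with the 3D biharmonic kernel U(r) = r, closest-training-image
# selection, landmark subsampling, and a simplified reference-surface-to-mask
# correspondence fitter.

#' Corresponded affine fit
#'
#' Least-squares 12-parameter affine minimizing
#' `sum || A s_i + t - t_i ||^2` over positionally corresponded points.
#'
#' @param source,target V x 3 matrices, V >= 4 non-coplanar points.
#' @return list with `A` (3x3), `t` (3-vector), `rmse` (mm).
#' @export
fit_corresponded_affine <- function(source, target) {
  source <- as.matrix(source); target <- as.matrix(target)
  stopifnot(nrow(source) == nrow(target), ncol(source) == 3L)
  if (nrow(source) < 4L) stop("need at least 4 points")
  X <- cbind(source, 1)
  qrX <- qr(X)
  if (qrX$rank < 4L)
    stop("rank error: source points are coplanar or degenerate")
  beta <- qr.coef(qrX, target)           # 4 x 3
  A <- t(beta[1:3, , drop = FALSE])
  tt <- as.numeric(beta[4L, ])
  pred <- sweep(source %*% t(A), 2, tt, "+")
  list(A = A, t = tt, rmse = sqrt(mean(rowSums((pred - target)^2))))
}

#' Corresponded rigid fit (orthogonal Procrustes)
#'
#' Proper rotation (determinant +1) plus translation minimizing the
#' corresponded squared error; reflections are never returned.
#'
#' @param source,target V x 3 matrices, V >= 3 non-collinear points.
#' @return list with `R` (3x3, det +1), `t` (3-vector), `rmse` (mm).
#' @export
fit_corresponded_rigid <- function(source, target) {
  source <- as.matrix(source); target <- as.matrix(target)
  stopifnot(nrow(source) == nrow(target), ncol(source) == 3L)
  if (nrow(source) < 3L) stop("need at least 3 points")
  cs <- sweep(source, 2, colMeans(source))
  if (qr(cs)$rank < 2L) stop("rank error: source points are collinear")
  rt <- kabsch(source, target)
  pred <- apply_rigid(source, rt)
  list(R = rt$R, t = rt$t, rmse = sqrt(mean(rowSums((pred - target)^2))))
}

#' Apply a rigid or affine transform to points
#'
#' @param transform list with `R` or `A` (3x3) and `t`.
#' @param points n x 3 matrix.
#' @return transformed n x 3 matrix.
#' @export
apply_transform <- function(transform, points) {
  M <- if (!is.null(transform$R)) transform$R else transform$A
  sweep(rbind(points) %*% t(M), 2, transform$t, "+")
}

#' Select the closest training image for an instance
#'
#' For each candidate, the candidate's corresponded mesh vertices are
#' affine-registered to the instance vertices and the root-mean-square
#' corresponded residual is the distance. Optional per-candidate weights
#' multiply the distance (used for patient balancing); ties return the
#' lowest index.
#'
#' @param instance_vertices V x 3 instance mesh vertices.
#' @param training list of [training_sample()] (or any objects with a
#'   `$mesh$vertices` field) corresponded to the instance topology.
#' @param weights optional positive multipliers, one per candidate.
#' @return list with `index`, `distance` (unweighted RMS, mm) and
#'   `distances` (all candidates, unweighted).
#' @export
closest_training_image <- function(instance_vertices, training,
                                   weights = NULL) {
  if (!length(training)) stop("empty training set")
  d <- vapply(training, function(s)
    fit_corresponded_affine(s$mesh$vertices, instance_vertices)$rmse, 0)
  score <- if (is.null(weights)) d else d * weights
  idx <- which.min(score)  # which.min returns the first (lowest) index on ties
  list(index = idx, distance = d[idx], distances = d)
}

# TPS kernel matrix between two point sets, U(r) = r
tps_kernel <- function(a, b) {
  d2 <- outer(rowSums(a^2), rep(1, nrow(b))) +
    outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

#' Fit a 3D thin-plate-spline transform
#'
#' Solves the standard TPS system with the 3D biharmonic kernel `U(r) = r`
#' and regularization `lambda` added to the kernel diagonal. With
#' `lambda = 0` the transform interpolates the landmarks exactly, and the
#' warping weights satisfy the side conditions (zero sum and first moments).
#'
#' @param source,target L x 3 landmark matrices, L >= 4 non-coplanar.
#' @param lambda regularization (>= 0, default 0).
#' @return object of class `tps_transform`: `source`, `target`, `A`
#'   (4 x 3 affine: row 1 translation, rows 2-4 linear part), `W` (L x 3
#'   warping weights), `lambda`.
#' @export
fit_tps <- function(source, target, lambda = 0) {
  source <- as.matrix(source); target <- as.matrix(target)
  L <- nrow(source)
  stopifnot(nrow(target) == L, ncol(source) == 3L, lambda >= 0)
  if (L < 4L) stop("need at least 4 landmarks")
  # solve in centered, unit-scale coordinates: U(r) = r is scale-equivariant,
  # so this spans the same interpolant family with far better conditioning
  ctr <- colMeans(source)
  scl <- mean(sqrt(rowSums(sweep(source, 2, ctr)^2)))
  if (!(scl > 0)) scl <- 1
  src_n <- sweep(source, 2, ctr) / scl
  tgt_n <- sweep(target, 2, ctr) / scl
  K <- tps_kernel(src_n, src_n) + diag(lambda / scl, L)
  P <- cbind(1, src_n)
  if (qr(P)$rank < 4L) stop("rank error: landmarks are coplanar")
  Msys <- rbind(cbind(K, P), cbind(t(P), matrix(0, 4L, 4L)))
  rhs <- rbind(tgt_n, matrix(0, 4L, 3L))
  sol <- tryCatch(solve(Msys, rhs), error = function(e)
    stop("singular TPS system (coincident landmarks?); try lambda > 0"))
  sol <- sol + solve(Msys, rhs - Msys %*% sol)  # one refinement step
  structure(list(source = source, target = target,
                 W = sol[seq_len(L), , drop = FALSE],
                 A = sol[L + 1:4, , drop = FALSE],
                 norm_center = ctr, norm_scale = scl, lambda = lambda),
            class = "tps_transform")
}

#' Apply a thin-plate-spline transform to points
#'
#' @param tps a [fit_tps()] result.
#' @param points P x 3 matrix (may be empty).
#' @return P x 3 matrix of warped points.
#' @export
apply_tps <- function(tps, points) {
  points <- rbind(points)
  if (nrow(points) == 0L) return(points)
  pts_n <- sweep(points, 2, tps$norm_center) / tps$norm_scale
  src_n <- sweep(tps$source, 2, tps$norm_center) / tps$norm_scale
  out_n <- cpp_tps_apply(pts_n, src_n, tps$A, tps$W)
  sweep(out_n * tps$norm_scale, 2, tps$norm_center, "+")
}

#' Select TPS landmarks by farthest-point sampling
#'
#' Deterministic farthest-point sampling over the mesh's surface vertices,
#' seeded at the surface vertex with the lowest index.
#'
#' @param mesh a [tet_mesh()].
#' @param count number of landmarks (>= 4, at most the surface vertex count).
#' @return integer vector of vertex ids (into `mesh$vertices`).
#' @export
select_tps_landmarks <- function(mesh, count) {
  surf <- if (!is.null(mesh$surface_vertex_ids)) mesh$surface_vertex_ids
          else extract_surface_vertices(mesh)
  if (count < 4L) stop("need at least 4 landmarks")
  if (count > length(surf))
    stop("count exceeds number of surface vertices (", length(surf), ")")
  sel <- cpp_farthest_points(mesh$vertices[surf, , drop = FALSE],
                             as.integer(count), 1L)
  surf[sel]
}

# central-difference gradient of a volume, physical units (1/mm scale)
volume_gradient <- function(img) {
  a <- img$data; d <- dim(a); sp <- img$spacing
  g <- array(0, c(d, 3L))
  ix <- 2:(d[1] - 1); iy <- 2:(d[2] - 1); iz <- 2:(d[3] - 1)
  g[ix, , , 1] <- (a[ix + 1L, , ] - a[ix - 1L, , ]) / (2 * sp[1])
  g[, iy, , 2] <- (a[, iy + 1L, ] - a[, iy - 1L, ]) / (2 * sp[2])
  g[, , iz, 3] <- (a[, , iz + 1L] - a[, , iz - 1L]) / (2 * sp[3])
  g
}

# similarity (rotation + translation + isotropic scale) corresponded fit
fit_corresponded_similarity <- function(source, target) {
  cs <- colMeans(source); ct <- colMeans(target)
  S <- sweep(source, 2, cs); Tt <- sweep(target, 2, ct)
  H <- crossprod(S, Tt)
  sv <- svd(H)
  D <- diag(c(1, 1, sign(det(sv$v %*% t(sv$u)))))
  R <- sv$v %*% D %*% t(sv$u)
  s <- sum(diag(D) * sv$d) / sum(S^2)
  list(A = s * R, t = as.numeric(ct - s * R %*% cs), scale = s)
}

#' Correspond a reference surface to a segmentation mask
#'
#' A deliberately simple stand-in for full non-rigid surface registration,
#' sufficient to run the pipeline end to end on phantoms: (1) iterative
#' closest point on the mask's signed distance map with a similarity
#' transform (rotation, translation, isotropic scale); (2) per-vertex
#' projection along the distance-map gradient onto the zero level set;
#' (3) one TPS smoothing pass driven by farthest-point landmarks, replacing
#' raw projections by a smooth displacement field. Output vertex order
#' equals the reference order, so correspondence is by construction.
#'
#' @param reference a `surface_mesh`.
#' @param mask a [binary_mask()] (non-empty).
#' @param icp_max_iters ICP iteration cap (default 50).
#' @param landmark_count TPS landmark count (default `min(300, V)`).
#' @param tps_lambda TPS regularization for the smoothing pass.
#' @return a `surface_mesh` with fitted vertices.
#' @export
fit_reference_to_mask <- function(reference, mask, icp_max_iters = 50L,
                                  landmark_count = NULL, tps_lambda = 0) {
  if (sum(mask$data) == 0) stop("empty mask")
  sd <- signed_distance(mask)
  grad <- volume_gradient(sd$distance)
  g <- grid_of(mask)
  sample_grad <- function(pts) {
    idx <- world_to_index(pts, g)
    cbind(cpp_trilinear(as.numeric(grad[, , , 1]), g$dim, idx, 0),
          cpp_trilinear(as.numeric(grad[, , , 2]), g$dim, idx, 0),
          cpp_trilinear(as.numeric(grad[, , , 3]), g$dim, idx, 0))
  }
  project <- function(pts, n_steps = 3L) {
    for (s in seq_len(n_steps)) {
      dv <- sample_trilinear(sd$distance, pts, fill = 0)
      gr <- sample_grad(pts)
      nrm <- pmax(sqrt(rowSums(gr^2)), 1e-6)
      pts <- pts - (dv / nrm^2) * gr
    }
    pts
  }
  verts <- reference$vertices
  # center the reference on the mask centroid before ICP
  inside <- which(mask$data == 1L)
  centroid <- colMeans(voxel_centers(g)[inside, , drop = FALSE])
  verts <- sweep(verts, 2, centroid - colMeans(verts), "+")
  for (it in seq_len(icp_max_iters)) {
    tgt <- project(verts)
    sim <- fit_corresponded_similarity(verts, tgt)
    new_verts <- apply_transform(sim, verts)
    move <- sqrt(mean(rowSums((new_verts - verts)^2)))
    verts <- new_verts
    if (move < 1e-4 * min(mask$spacing)) break
  }
  if (is.null(landmark_count))
    landmark_count <- min(300L, nrow(verts))
  landmark_count <- max(4L, min(landmark_count, nrow(verts)))
  lm <- cpp_farthest_points(verts, landmark_count, 1L)
  tps <- fit_tps(verts[lm, , drop = FALSE],
                 project(verts[lm, , drop = FALSE]), tps_lambda)
  out <- apply_tps(tps, verts)
  surface_mesh(out, reference$faces)
}
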