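# Point distribution models by PCA over corresponded features and
# constrained Gaussian sampling of new instances: the statistical shape
# model (vertex coordinates after generalized Procrustes alignment) and the
# statistical intensity model (per-tet Bernstein coefficients), unified into
# one SSIM.

#' Point distribution model
#'
#' Mean, orthonormal eigenvector modes and eigenvalues from a PCA over
#' corresponded feature vectors. `k` is the smallest mode count whose
#' cumulative eigenvalue sum reaches `variance_fraction` of the total
#' variance.
#'
#' @param mean N-vector feature mean.
#' @param modes N x k matrix of orthonormal mode columns.
#' @param eigenvalues k positive eigenvalues, descending.
#' @param variance_fraction fraction of variance the retained modes cover.
#' @param feature_kind `"shape"` or `"intensity"`.
#' @return object of class `pdm`.
#' @export
pdm <- function(mean, modes, eigenvalues, variance_fraction, feature_kind) {
  modes <- as.matrix(modes)
  stopifnot(length(mean) == nrow(modes),
            length(eigenvalues) == ncol(modes))
  if (any(eigenvalues <= 0)) stop("eigenvalues must be positive")
  if (any(diff(eigenvalues) > 1e-12 * max(eigenvalues)))
    stop("eigenvalues must be descending")
  structure(list(mean = as.numeric(mean), modes = modes,
                 eigenvalues = as.numeric(eigenvalues),
                 variance_fraction = variance_fraction,
                 feature_kind = feature_kind),
            class = "pdm")
}

#' @export
print.pdm <- function(x, ...) {
  cat(sprintf("<pdm:%s> %d features, %d modes (%.0f%% variance)\n",
              x$feature_kind, length(x$mean), ncol(x$modes),
              100 * x$variance_fraction))
  invisible(x)
}

# Kabsch: proper rotation (det +1) + translation mapping source onto target
kabsch <- function(source, target) {
  cs <- colMeans(source); ct <- colMeans(target)
  H <- crossprod(sweep(source, 2, cs), sweep(target, 2, ct))
  sv <- svd(H)
  S <- diag(c(1, 1, sign(det(sv$v %*% t(sv$u)))))
  R <- sv$v %*% S %*% t(sv$u)
  list(R = R, t = as.numeric(ct - R %*% cs))
}

apply_rigid <- function(points, rt) {
  sweep(points %*% t(rt$R), 2, rt$t, "+")
}

#' Generalized Procrustes alignment (rigid, no scaling)
#'
#' Iteratively aligns each shape to the current mean with a proper rotation
#' plus translation (Kabsch), re-estimating the mean until it moves by less
#' than `tol` (RMS, mm) or `max_iter` rounds.
#'
#' @param shapes list of V x 3 corresponded vertex matrices.
#' @param tol mean-shape convergence tolerance, mm.
#' @param max_iter iteration cap.
#' @return list with `aligned` (list of V x 3), `mean_shape`, and
#'   `transforms` (per-shape `list(R, t)` mapping the original shape into
#'   the aligned frame).
#' @export
procrustes_align <- function(shapes, tol = 1e-7, max_iter = 100L) {
  if (length(shapes) < 2L) stop("need at least 2 shapes")
  V <- nrow(shapes[[1L]])
  if (any(vapply(shapes, nrow, 0L) != V))
    stop("all shapes must have the same vertex count")
  shapes <- lapply(shapes, function(s) { s <- as.matrix(s); storage.mode(s) <- "double"; s })
  mean_shape <- sweep(shapes[[1L]], 2, colMeans(shapes[[1L]]))
  transforms <- vector("list", length(shapes))
  aligned <- shapes
  for (it in seq_len(max_iter)) {
    for (i in seq_along(shapes)) {
      transforms[[i]] <- kabsch(shapes[[i]], mean_shape)
      aligned[[i]] <- apply_rigid(shapes[[i]], transforms[[i]])
    }
    new_mean <- Reduce(`+`, aligned) / length(aligned)
    delta <- sqrt(mean((new_mean - mean_shape)^2))
    mean_shape <- new_mean
    if (delta < tol) break
  }
  list(aligned = aligned, mean_shape = mean_shape, transforms = transforms)
}

#' Build a point distribution model by PCA
#'
#' PCA of the mean-centered feature matrix via the eigendecomposition of the
#' n x n Gram matrix (numerically equivalent to the SVD of the centered data;
#' eigenvalue = squared singular value / (n-1)). The retained mode count is
#' the smallest `k` whose cumulative eigenvalue sum reaches
#' `variance_fraction` of the total; `k <= n - 1` always.
#'
#' @param features n x N matrix, one training sample per row.
#' @param variance_fraction fraction of total variance to retain (default
#'   0.95).
#' @param feature_kind label stored on the model.
#' @return a [pdm()].
#' @export
build_pdm <- function(features, variance_fraction = 0.95,
                      feature_kind = "shape") {
  features <- as.matrix(features)
  n <- nrow(features)
  if (n < 2L) stop("need at least 2 training samples")
  if (!all(is.finite(features))) stop("non-finite feature values")
  mu <- colMeans(features)
  Xc <- sweep(features, 2, mu)
  G <- tcrossprod(Xc) / (n - 1)
  eg <- eigen(G, symmetric = TRUE)
  lam <- eg$values
  pos <- lam > max(lam) * 1e-12 & seq_along(lam) <= n - 1L
  lam <- lam[pos]
  U <- eg$vectors[, pos, drop = FALSE]
  modes <- crossprod(Xc, U)
  modes <- sweep(modes, 2, sqrt(colSums(modes^2)), "/")
  k <- which(cumsum(lam) >= variance_fraction * sum(lam) - 1e-12)[1L]
  pdm(mu, modes[, seq_len(k), drop = FALSE], lam[seq_len(k)],
      variance_fraction, feature_kind)
}

#' Draw constrained model parameters
#'
#' Each `b_i` is drawn from `Normal(0, lambda_i)`, clipped to
#' `[-clip_sigma*sqrt(lambda_i), clip_sigma*sqrt(lambda_i)]`; if the
#' Mahalanobis norm `sum(b_i^2/lambda_i)` then exceeds `M`, the whole vector
#' is scaled by `sqrt(M / sum(b_i^2/lambda_i))`. `M` defaults to the
#' `chi2_quantile` quantile of the chi-squared distribution with `k` degrees
#' of freedom.
#'
#' @param model a [pdm()].
#' @param M Mahalanobis bound; `NULL` for the chi-squared default.
#' @param clip_sigma per-mode clip bound in standard deviations (default 2.5).
#' @param chi2_quantile quantile defining the default `M` (default 0.95).
#' @return list with `b` (k-vector) and `M`.
#' @export
sample_parameters <- function(model, M = NULL, clip_sigma = 2.5,
                              chi2_quantile = 0.95) {
  lam <- model$eigenvalues
  k <- length(lam)
  if (is.null(M)) M <- qchisq(chi2_quantile, df = k)
  if (M <= 0) stop("M must be positive")
  b <- rnorm(k, 0, sqrt(lam))
  bound <- clip_sigma * sqrt(lam)
  b <- pmin(pmax(b, -bound), bound)
  mah <- sum(b^2 / lam)
  if (mah > M) b <- b * sqrt(M / mah)
  list(b = b, M = M)
}

#' Instantiate a feature vector from model parameters
#'
#' @param model a [pdm()].
#' @param b k-vector of mode weights (or a list with element `b`).
#' @return feature vector `mean + modes %*% b`.
#' @export
instantiate <- function(model, b) {
  if (is.list(b)) b <- b$b
  if (length(b) != ncol(model$modes))
    stop("parameter vector length ", length(b), " != mode count ",
         ncol(model$modes))
  as.numeric(model$mean + model$modes %*% b)
}

#' Project a feature vector onto model parameters
#'
#' @param model a [pdm()].
#' @param feature N-vector.
#' @return k-vector of mode weights.
#' @export
project_parameters <- function(model, feature) {
  as.numeric(crossprod(model$modes, feature - model$mean))
}

#' Build a statistical shape and intensity model
#'
#' Shape: generalized Procrustes alignment of the corresponded vertex sets,
#' then PCA of the flattened aligned coordinates. Intensity: per-sample
#' Bernstein encoding ([fit_encoding()]) of each training image on its own
#' mesh, then PCA of the flattened coefficient matrices. Both models retain
#' `variance_fraction` of the total variance (default 0.95).
#'
#' @param training list of training samples ([training_sample()]), all with
#'   identical tet topology and positional vertex correspondence.
#' @param d Bernstein degree (default 3).
#' @param variance_fraction retained variance fraction (default 0.95).
#' @return object of class `ssim_model`.
#' @export
build_ssim <- function(training, d = 3L, variance_fraction = 0.95) {
  if (length(training) < 2L) stop("need at least 2 training samples")
  tets0 <- training[[1L]]$mesh$tets
  V <- nrow(training[[1L]]$mesh$vertices)
  for (s in training)
    if (!identical(s$mesh$tets, tets0) || nrow(s$mesh$vertices) != V)
      stop("training samples must share mesh topology")
  pa <- procrustes_align(lapply(training, function(s) s$mesh$vertices))
  shape_feats <- do.call(rbind, lapply(pa$aligned, as.numeric))
  shape_model <- build_pdm(shape_feats, variance_fraction, "shape")
  enc_feats <- do.call(rbind, lapply(training, function(s)
    as.numeric(fit_encoding(s$image, s$mesh, d)$coefficients)))
  intensity_model <- build_pdm(enc_feats, variance_fraction, "intensity")
  structure(list(shape_model = shape_model,
                 intensity_model = intensity_model,
                 tets = tets0, degree = as.integer(d), n_vertices = V,
                 alignment = pa$transforms),
            class = "ssim_model")
}

#' @export
print.ssim_model <- function(x, ...) {
  cat(sprintf(paste0("<ssim_model> %d vertices, %d tets, degree %d; ",
                     "%d shape + %d intensity modes\n"),
              x$n_vertices, nrow(x$tets), x$degree,
              ncol(x$shape_model$modes), ncol(x$intensity_model$modes)))
  invisible(x)
}

#' Sample a random shape-intensity instance
#'
#' Shape and intensity parameters are drawn independently with
#' [sample_parameters()]. Instances whose mesh has any inverted (non-positive
#' volume) tetrahedron are rejected and redrawn, up to `max_attempts`.
#' The returned mesh is in the model's mean pose.
#'
#' @param ssim an `ssim_model`.
#' @param M_shape,M_intensity Mahalanobis bounds (`NULL` = chi-squared
#'   default per model).
#' @param clip_sigma,chi2_quantile passed to [sample_parameters()].
#' @param b_shape,b_intensity optional fixed parameter vectors overriding
#'   the random draw (used for mean instances and tests).
#' @param max_attempts rejection cap for invalid geometry.
#' @return object of class `ssim_instance`: `mesh`, `encoding`, `b_shape`,
#'   `b_intensity`, `rejections`.
#' @export
sample_instance <- function(ssim, M_shape = NULL, M_intensity = NULL,
                            clip_sigma = 2.5, chi2_quantile = 0.95,
                            b_shape = NULL, b_intensity = NULL,
                            max_attempts = 100L) {
  V <- ssim$n_vertices
  rejections <- 0L
  for (attempt in seq_len(max_attempts)) {
    bs <- if (is.null(b_shape))
      sample_parameters(ssim$shape_model, M_shape, clip_sigma, chi2_quantile)$b
    else b_shape
    verts <- matrix(instantiate(ssim$shape_model, bs), V, 3L)
    vols <- tet_signed_volumes(verts, ssim$tets)
    if (all(vols > 1e-9)) {
      bi <- if (is.null(b_intensity))
        sample_parameters(ssim$intensity_model, M_intensity, clip_sigma,
                          chi2_quantile)$b
      else b_intensity
      m <- count_coefficients(ssim$degree)
      coefs <- matrix(instantiate(ssim$intensity_model, bi),
                      nrow(ssim$tets), m)
      mesh <- tet_mesh(verts, ssim$tets)
      return(structure(list(mesh = mesh,
                            encoding = intensity_encoding(ssim$degree, coefs),
                            b_shape = bs, b_intensity = bi,
                            rejections = rejections),
                       class = "ssim_instance"))
    }
    if (!is.null(b_shape))
      stop("fixed shape parameters produce inverted tetrahedra")
    rejections <- rejections + 1L
  }
  stop("no valid instance after ", max_attempts, " attempts")
}
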