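# The augmentation pipeline: sample a constrained SSIM instance, pick the
# closest training image, "clean" the structure out of it with mirrored
# exterior intensities, TPS-warp the cleaned image, paint the instance's
# encoded intensities, and rigidly realign to the closest image.

#' Training sample (image, mask, corresponded mesh)
#'
#' @param image a [volume_image()].
#' @param mask a [binary_mask()] on the same grid.
#' @param mesh the sample's corresponded [tet_mesh()] in image world
#'   coordinates.
#' @param patient_id identifying string.
#' @return object of class `training_sample`.
#' @export
training_sample <- function(image, mask, mesh, patient_id) {
  stopifnot(inherits(image, "volume_image"), inherits(mask, "binary_mask"),
            inherits(mesh, "tet_mesh"))
  if (!same_grid(image, mask)) stop("image and mask must share one grid")
  structure(list(image = image, mask = mask, mesh = mesh,
                 patient_id = as.character(patient_id)),
            class = "training_sample")
}

#' @export
print.training_sample <- function(x, ...) {
  cat(sprintf("<training_sample> %s: %s voxels, %d mask voxels, %d tets\n",
              x$patient_id, paste(dim(x$image$data), collapse = "x"),
              sum(x$mask$data), nrow(x$mesh$tets)))
  invisible(x)
}

#' Signed Euclidean distance map with closest boundary points
#'
#' Exact Euclidean distance transform in physical mm (separable
#' lower-envelope algorithm, correct for anisotropic spacing). The boundary
#' is discretized as opposite-class voxel centers: an interior voxel's
#' distance is the (negated) distance to the nearest exterior voxel center,
#' an exterior voxel's the distance to the nearest interior voxel center.
#' `closest` holds, per voxel, the 1-based linear grid index of that nearest
#' opposite-class voxel.
#'
#' @param mask a [binary_mask()], neither empty nor all-inside.
#' @return list with `distance` (a [volume_image()], mm, negative inside)
#'   and `closest` (integer array).
#' @export
signed_distance <- function(mask) {
  g <- grid_of(mask)
  n_in <- sum(mask$data)
  if (n_in == 0) stop("empty mask")
  if (n_in == length(mask$data)) stop("mask covers the whole image")
  inside <- as.logical(mask$data)
  ft_in <- cpp_feature_transform(inside, g$dim, g$spacing)
  ft_out <- cpp_feature_transform(!inside, g$dim, g$spacing)
  d <- ifelse(inside, -sqrt(ft_out$dist2), sqrt(ft_in$dist2))
  cl <- ifelse(inside, ft_out$feat, ft_in$feat)
  list(distance = volume_image(array(d, g$dim), g$spacing, g$origin),
       closest = array(as.integer(cl), g$dim))
}

#' Clean a structure out of an image by mirrored exterior intensities
#'
#' Every interior voxel `v` is replaced by the trilinearly interpolated
#' intensity at the mirror point `v + 2*(w - v)`, where `w` is `v`'s
#' closest boundary point from [signed_distance()]. If `r` falls outside the
#' image or back inside the mask, the mirror factor is stepped down
#' (2, 1.5, 1.25, 1.125, 1.0625); if all fail, the value at `w` (an exterior
#' voxel) is used. Exterior voxels are returned unchanged, exactly.
#'
#' @param img a [volume_image()].
#' @param mask a [binary_mask()] on the same grid. An empty mask returns the
#'   image unchanged; an all-inside mask is an error.
#' @return the cleaned [volume_image()].
#' @export
clean_structure <- function(img, mask) {
  if (!same_grid(img, mask)) stop("image and mask must share one grid")
  if (sum(mask$data) == 0) return(img)
  if (sum(mask$data) == length(mask$data))
    stop("mask covers the whole image: no exterior to mirror from")
  sd <- signed_distance(mask)
  g <- grid_of(img)
  centers <- voxel_centers(g)
  idx <- which(mask$data == 1L)
  v <- centers[idx, , drop = FALSE]
  w <- centers[sd$closest[idx], , drop = FALSE]
  out <- as.numeric(img$data)
  maskv <- as.numeric(mask$data)
  vals <- rep(NA_real_, length(idx))
  pending <- seq_along(idx)
  lo <- g$origin
  hi <- g$origin + (g$dim - 1) * g$spacing
  for (f in c(2, 1.5, 1.25, 1.125, 1.0625)) {
    if (!length(pending)) break
    r <- v[pending, , drop = FALSE] + f * (w[pending, , drop = FALSE] -
                                           v[pending, , drop = FALSE])
    in_bounds <- r[, 1] >= lo[1] & r[, 1] <= hi[1] &
                 r[, 2] >= lo[2] & r[, 2] <= hi[2] &
                 r[, 3] >= lo[3] & r[, 3] <= hi[3]
    mask_at_r <- cpp_trilinear(maskv, g$dim, world_to_index(r, g), 1)
    ok <- in_bounds & mask_at_r < 0.5
    if (any(ok)) {
      vals[pending[ok]] <- cpp_trilinear(out, g$dim,
                                         world_to_index(r[ok, , drop = FALSE], g),
                                         NA_real_)
      pending <- pending[!ok]
    }
  }
  if (length(pending))  # nearest exterior voxel value
    vals[pending] <- out[sd$closest[idx[pending]]]
  out[idx] <- vals
  volume_image(array(out, g$dim), g$spacing, g$origin)
}

#' Warp a cleaned image and paint instance intensities
#'
#' Fits a TPS from instance surface landmarks (farthest-point sampled) to
#' the corresponding vertices of the closest sample's mesh, resamples the
#' cleaned image onto the closest image's grid by mapping each output voxel
#' center through the TPS with trilinear interpolation, then overwrites
#' every voxel inside the instance mesh with the instance's encoded density.
#' Out-of-field voxels are filled with the cleaned image's minimum
#' intensity. The output mask is the rasterized instance mesh.
#'
#' @param cleaned the cleaned [volume_image()] (closest image's grid).
#' @param closest the closest [training_sample()].
#' @param instance an `ssim_instance` (topology must match the closest
#'   sample's mesh).
#' @param lambda_tps TPS regularization (default 0).
#' @param landmark_count TPS landmark budget (default `min(300, surface)`).
#' @return object of class `augmented_sample` with fields `image`, `mask`,
#'   `mesh` and `provenance`.
#' @export
warp_and_paint <- function(cleaned, closest, instance, lambda_tps = 0,
                           landmark_count = 300L) {
  if (!identical(instance$mesh$tets, closest$mesh$tets))
    stop("instance and closest-sample mesh topology differ")
  imesh <- with_surface_vertices(instance$mesh)
  count <- min(landmark_count, length(imesh$surface_vertex_ids))
  ids <- select_tps_landmarks(imesh, count)
  tps <- fit_tps(imesh$vertices[ids, , drop = FALSE],
                 closest$mesh$vertices[ids, , drop = FALSE], lambda_tps)
  g <- grid_of(cleaned)
  centers <- voxel_centers(g)
  mapped <- apply_tps(tps, centers)
  fill <- min(cleaned$data)
  vals <- cpp_trilinear(as.numeric(cleaned$data), g$dim,
                        world_to_index(mapped, g), fill)
  loc <- locate_points(centers, imesh)
  sel <- which(loc$tet > 0L)
  if (length(sel))
    vals[sel] <- evaluate_density_at(instance$encoding, loc$tet[sel],
                                     loc$bary[sel, , drop = FALSE])
  mask <- binary_mask(array(as.integer(loc$tet > 0L), g$dim),
                      g$spacing, g$origin)
  structure(list(
    image = volume_image(array(vals, g$dim), g$spacing, g$origin),
    mask = mask, mesh = imesh,
    provenance = list(source_patient = closest$patient_id,
                      b_shape = instance$b_shape,
                      b_intensity = instance$b_intensity,
                      lambda_tps = lambda_tps,
                      landmark_count = count)
  ), class = "augmented_sample")
}

#' @export
print.augmented_sample <- function(x, ...) {
  cat(sprintf("<augmented_sample> from %s: %s voxels, %d mask voxels\n",
              x$provenance$source_patient,
              paste(dim(x$image$data), collapse = "x"), sum(x$mask$data)))
  invisible(x)
}

#' Rigidly realign an augmented sample to the closest image
#'
#' Fits a corresponded rigid transform from the augmented sample's instance
#' mesh to the closest sample's mesh, resamples the image through it
#' (trilinear, minimum-intensity fill) and re-rasterizes the mask from the
#' rigidly moved mesh, so the mask stays exactly consistent with the mesh.
#'
#' @param aug an `augmented_sample` from [warp_and_paint()].
#' @param closest the [training_sample()] used to create it.
#' @return the realigned `augmented_sample`.
#' @export
realign_rigid <- function(aug, closest) {
  rt <- fit_corresponded_rigid(aug$mesh$vertices, closest$mesh$vertices)
  new_mesh <- tet_mesh(apply_rigid(aug$mesh$vertices, rt), aug$mesh$tets,
                       aug$mesh$surface_vertex_ids)
  g <- grid_of(aug$image)
  centers <- voxel_centers(g)
  # pull-back: output voxel y samples the image at R^-1 (y - t)
  back <- sweep(centers, 2, rt$t) %*% rt$R
  fill <- min(aug$image$data)
  vals <- cpp_trilinear(as.numeric(aug$image$data), g$dim,
                        world_to_index(back, g), fill)
  mask <- rasterize_mask(new_mesh, g)
  prov <- aug$provenance
  prov$realign <- rt[c("R", "t", "rmse")]
  structure(list(image = volume_image(array(vals, g$dim), g$spacing, g$origin),
                 mask = mask, mesh = new_mesh, provenance = prov),
            class = "augmented_sample")
}

#' Dice similarity coefficient of two masks
#'
#' @param a,b [binary_mask()] objects on one grid.
#' @return Dice coefficient in \[0, 1\].
#' @export
dice_coefficient <- function(a, b) {
  sa <- sum(a$data); sb <- sum(b$data)
  if (sa + sb == 0) return(1)
  2 * sum(a$data * b$data) / (sa + sb)
}

#' Generate a set of augmented samples
#'
#' Repeats: draw a constrained instance from the SSIM, pick the closest
#' training image (affine RMS criterion, de-prioritizing heavily used
#' patients by multiplying each candidate's distance by
#' `1 + balance_strength * usage_count`), translate the instance to the
#' chosen sample's centroid, clean, TPS-warp and paint, and rigidly realign.
#' `balance_strength = 0` recovers the pure closest-image criterion.
#'
#' @param training list of [training_sample()].
#' @param ssim an `ssim_model` built on the same topology.
#' @param n number of samples to generate.
#' @param balance_strength patient-balancing knob (default 0.2).
#' @param lambda_tps,landmark_count passed to [warp_and_paint()].
#' @param seed optional integer seed set before sampling.
#' @return list with `samples` (augmented samples), `usage` (named
#'   per-patient counts) and `rejections` (invalid-geometry redraw count).
#' @export
generate_augmented_set <- function(training, ssim, n, balance_strength = 0.2,
                                   lambda_tps = 0, landmark_count = 300L,
                                   seed = NULL) {
  stopifnot(n >= 1)
  if (!identical(training[[1L]]$mesh$tets, ssim$tets))
    stop("model and training set mesh topology differ")
  if (!is.null(seed)) set.seed(seed)
  usage <- stats::setNames(numeric(length(training)),
                           vapply(training, `[[`, "", "patient_id"))
  samples <- vector("list", n)
  rejections <- 0L
  for (s in seq_len(n)) {
    inst <- sample_instance(ssim)
    rejections <- rejections + inst$rejections
    sel <- closest_training_image(inst$mesh$vertices, training,
                                  weights = 1 + balance_strength * usage)
    closest <- training[[sel$index]]
    usage[sel$index] <- usage[sel$index] + 1
    # place the instance at the chosen sample's centroid before warping
    shift <- colMeans(closest$mesh$vertices) - colMeans(inst$mesh$vertices)
    inst$mesh <- tet_mesh(sweep(inst$mesh$vertices, 2, shift, "+"),
                          inst$mesh$tets)
    cleaned <- clean_structure(closest$image, closest$mask)
    aug <- warp_and_paint(cleaned, closest, inst, lambda_tps, landmark_count)
    aug <- realign_rigid(aug, closest)
    aug$provenance$closest_distance <- sel$distance
    aug$provenance$sample_index <- s
    aug$provenance$seed <- seed
    samples[[s]] <- aug
  }
  list(samples = samples, usage = usage, rejections = rejections)
}
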