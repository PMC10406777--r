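# Parametric phantom populations: ellipsoid-like structures meshed from a
# spherified-cube tet grid, deformed by known smooth latent shape modes,
# filled with a smooth polynomial interior field plus a bright "cortical"
# shell, over a heterogeneous noisy background. Every stage of the pipeline
# is testable against these phantoms' known ground truth.

#' Phantom population specification
#'
#' @param grid_dim integer 3-vector of voxels (default 64^3).
#' @param spacing mm per voxel (default 1.5).
#' @param semi_axes ellipsoid semi-axes, mm.
#' @param divisions tet-grid divisions per axis of the spherified cube.
#' @param n_shape_modes,shape_amplitudes latent shape mode count and RMS
#'   displacement amplitudes (mm per unit latent).
#' @param n_intensity_modes,intensity_amplitudes latent intensity mode count
#'   and amplitudes (intensity units per unit latent).
#' @param base_level interior base intensity.
#' @param interior_gradient linear interior gradient coefficient.
#' @param cubic_coef coefficient of the degree-3 interior term.
#' @param shell_level "cortical" shell brightness (0 disables the shell and
#'   leaves the interior a polynomial of total degree <= 3).
#' @param shell_inner normalized squared radius where the shell ramp starts.
#' @param background_level,background_ramp background intensity offset and
#'   linear ramp amplitude.
#' @param noise_sd additive Gaussian noise standard deviation (default 16,
#'   about 2 percent of the phantom's ~800-unit dynamic range).
#' @param pose_rot_sd,pose_trans_sd per-sample random rigid pose (radians,
#'   mm).
#' @param seed RNG seed for [generate_population()].
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_dim = c(64L, 64L, 64L), spacing = 1.5,
                         semi_axes = c(30, 22, 18), divisions = c(4L, 4L, 4L),
                         n_shape_modes = 2L,
                         shape_amplitudes = c(3, 2.5, 2, 1.5)[seq_len(n_shape_modes)],
                         n_intensity_modes = 2L,
                         intensity_amplitudes = c(60, 40, 30, 20)[seq_len(n_intensity_modes)],
                         base_level = 300, interior_gradient = 80,
                         cubic_coef = 30, shell_level = 400, shell_inner = 0.6,
                         background_level = 50, background_ramp = 30,
                         noise_sd = 16, pose_rot_sd = 0.05, pose_trans_sd = 2,
                         seed = 0L) {
  stopifnot(all(semi_axes > 0), noise_sd >= 0, n_shape_modes >= 1L,
            n_shape_modes <= 4L, n_intensity_modes >= 1L,
            n_intensity_modes <= 4L,
            length(shape_amplitudes) == n_shape_modes,
            length(intensity_amplitudes) == n_intensity_modes)
  spacing <- rep(as.numeric(spacing), length.out = 3L)
  grid_dim <- as.integer(rep(grid_dim, length.out = 3L))
  if (any(2 * semi_axes > 0.9 * (grid_dim - 1) * spacing))
    stop("semi-axes too large for the grid")
  structure(list(grid_dim = grid_dim, spacing = spacing,
                 semi_axes = as.numeric(semi_axes),
                 divisions = as.integer(rep(divisions, length.out = 3L)),
                 n_shape_modes = as.integer(n_shape_modes),
                 shape_amplitudes = as.numeric(shape_amplitudes),
                 n_intensity_modes = as.integer(n_intensity_modes),
                 intensity_amplitudes = as.numeric(intensity_amplitudes),
                 base_level = base_level, interior_gradient = interior_gradient,
                 cubic_coef = cubic_coef, shell_level = shell_level,
                 shell_inner = shell_inner, background_level = background_level,
                 background_ramp = background_ramp, noise_sd = noise_sd,
                 pose_rot_sd = pose_rot_sd, pose_trans_sd = pose_trans_sd,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# smooth bijective cube-to-ball map: [-1,1]^3 onto the unit ball
spherify <- function(p) {
  x <- p[, 1]; y <- p[, 2]; z <- p[, 3]
  cbind(x * sqrt(pmax(1 - y^2 / 2 - z^2 / 2 + y^2 * z^2 / 3, 0)),
        y * sqrt(pmax(1 - z^2 / 2 - x^2 / 2 + z^2 * x^2 / 3, 0)),
        z * sqrt(pmax(1 - x^2 / 2 - y^2 / 2 + x^2 * y^2 / 3, 0)))
}

# reference ellipsoid mesh centered at the origin (local coordinates, mm)
phantom_reference_mesh <- function(spec) {
  cube <- build_tet_grid(c(-1, -1, -1), c(1, 1, 1), spec$divisions)
  verts <- sweep(spherify(cube$vertices), 2, spec$semi_axes, "*")
  with_surface_vertices(tet_mesh(verts, cube$tets))
}

# V x 3 displacement fields, each normalized to RMS 1 mm
phantom_shape_fields <- function(ref_local, spec) {
  q <- sweep(ref_local, 2, spec$semi_axes, "/")
  a <- spec$semi_axes
  fields <- list(
    cbind(ref_local[, 1], -0.45 * ref_local[, 2], -0.45 * ref_local[, 3]),
    cbind(a[1] * (q[, 3]^2 - 1 / 3), 0 * q[, 1], 0 * q[, 1]),
    cbind(0 * q[, 1], a[2] * (q[, 1]^2 - 1 / 3), 0 * q[, 1]),
    cbind(0 * q[, 1], 0 * q[, 1], a[3] * (q[, 2]^2 - 1 / 3))
  )[seq_len(spec$n_shape_modes)]
  lapply(fields, function(f) f / sqrt(mean(rowSums(f^2))))
}

# interior intensity at reference-local positions (rows), given latent c
phantom_interior_intensity <- function(ref_pos, spec, c_lat) {
  q <- sweep(ref_pos, 2, spec$semi_axes, "/")
  basis <- cbind(q[, 1], q[, 2], 3 * q[, 1] * q[, 3], 3 * q[, 2] * q[, 3])
  val <- spec$base_level + spec$interior_gradient * q[, 3] +
    spec$cubic_coef * 27 * q[, 1] * q[, 2] * q[, 3]
  for (j in seq_len(spec$n_intensity_modes))
    val <- val + c_lat[j] * spec$intensity_amplitudes[j] * basis[, j]
  if (spec$shell_level > 0) {
    rho2 <- rowSums(q^2)
    ramp <- pmin(pmax((rho2 - spec$shell_inner) / (1 - spec$shell_inner), 0), 1)
    val <- val + spec$shell_level * ramp^2
  }
  val
}

small_rotation <- function(angles) {
  cx <- cos(angles[1]); sx <- sin(angles[1])
  cy <- cos(angles[2]); sy <- sin(angles[2])
  cz <- cos(angles[3]); sz <- sin(angles[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

truncated_normal <- function(n, bound = 2.5) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat { x <- rnorm(1); if (abs(x) <= bound) break }
    out[i] <- x
  }
  out
}

#' Generate a phantom training population
#'
#' Builds the reference ellipsoid mesh once, then for each sample deforms it
#' by a known linear combination of smooth latent displacement fields plus a
#' random rigid pose, rasterizes its mask, and fills the image: interior
#' voxels follow a low-order polynomial field (plus bright shell) evaluated
#' at corresponded reference positions, the background is a smooth ramp, and
#' Gaussian noise is added everywhere. Correspondence across samples is by
#' construction; the ground-truth latents are returned for recovery tests.
#'
#' @param spec a [phantom_spec()].
#' @param n number of samples (>= 2).
#' @return list with `samples` (list of [training_sample()]), `reference`
#'   (the reference [tet_mesh()] in grid-centered world coordinates),
#'   `latents` (list with `shape` and `intensity` n x k matrices, `poses`),
#'   and `spec`.
#' @export
generate_population <- function(spec, n) {
  stopifnot(inherits(spec, "phantom_spec"), n >= 2)
  set.seed(spec$seed)
  g <- list(dim = spec$grid_dim, spacing = spec$spacing, origin = c(0, 0, 0))
  center <- (spec$grid_dim - 1) / 2 * spec$spacing
  ref <- phantom_reference_mesh(spec)           # local (origin-centered)
  fields <- phantom_shape_fields(ref$vertices, spec)
  centers <- voxel_centers(g)
  extent <- (spec$grid_dim - 1) * spec$spacing
  bg <- spec$background_level +
    spec$background_ramp * centers[, 1] / extent[1]
  b_shape <- matrix(truncated_normal(n * spec$n_shape_modes), n)
  c_int <- matrix(truncated_normal(n * spec$n_intensity_modes), n)
  poses <- vector("list", n)
  samples <- vector("list", n)
  for (s in seq_len(n)) {
    disp <- Reduce(`+`, Map(function(f, b, amp) b * amp * f,
                            fields, b_shape[s, ], spec$shape_amplitudes),
                   accumulate = FALSE)
    local_verts <- ref$vertices + disp
    R <- small_rotation(rnorm(3, 0, spec$pose_rot_sd))
    tr <- rnorm(3, 0, spec$pose_trans_sd)
    world_verts <- sweep(local_verts %*% t(R), 2, center + tr, "+")
    mesh <- tet_mesh(world_verts, ref$tets, ref$surface_vertex_ids)
    loc <- locate_points(centers, mesh)
    sel <- which(loc$tet > 0L)
    vals <- bg
    if (length(sel)) {
      bary <- loc$bary[sel, , drop = FALSE]
      tets <- ref$tets[loc$tet[sel], , drop = FALSE]
      ref_pos <- bary[, 1] * ref$vertices[tets[, 1], , drop = FALSE] +
                 bary[, 2] * ref$vertices[tets[, 2], , drop = FALSE] +
                 bary[, 3] * ref$vertices[tets[, 3], , drop = FALSE] +
                 bary[, 4] * ref$vertices[tets[, 4], , drop = FALSE]
      vals[sel] <- phantom_interior_intensity(ref_pos, spec, c_int[s, ])
    }
    if (spec$noise_sd > 0)
      vals <- vals + rnorm(length(vals), 0, spec$noise_sd)
    img <- volume_image(array(vals, g$dim), g$spacing, g$origin)
    mask <- binary_mask(array(as.integer(loc$tet > 0L), g$dim),
                        g$spacing, g$origin)
    poses[[s]] <- list(R = R, t = center + tr)
    samples[[s]] <- training_sample(img, mask, mesh,
                                    sprintf("phantom%02d", s))
  }
  ref_world <- tet_mesh(sweep(ref$vertices, 2, center, "+"), ref$tets,
                        ref$surface_vertex_ids)
  list(samples = samples, reference = ref_world,
       latents = list(shape = b_shape, intensity = c_int, poses = poses),
       spec = spec)
}

#' Deterministic worked-example phantom population
#'
#' A fixed fixture used throughout documentation and tests: seed 0,
#' 8 samples, 2 latent shape and 2 latent intensity modes. `size` sets the
#' cubic grid edge (default 32 voxels at 1.5 mm); the ellipsoid and the
#' tet-grid resolution scale with it.
#'
#' @param size grid edge in voxels (default 32).
#' @param n_samples number of phantoms (default 8).
#' @param ... overrides passed to [phantom_spec()].
#' @return the [generate_population()] result.
#' @export
worked_example <- function(size = 32L, n_samples = 8L, ...) {
  size <- as.integer(size)
  args <- list(grid_dim = rep(size, 3L), spacing = 1.5,
               semi_axes = c(30, 22, 18) * size / 64,
               divisions = rep(max(2L, as.integer(round(4 * size / 64))), 3L),
               n_shape_modes = 2L, n_intensity_modes = 2L,
               seed = 0L)
  spec <- do.call(phantom_spec, utils::modifyList(args, list(...)))
  generate_population(spec, n_samples)
}
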