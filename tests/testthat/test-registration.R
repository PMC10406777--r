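test_that("corresponded affine fits recover exact and noisy transforms", {
  set.seed(50)
  src <- matrix(runif(45, 0, 40), 15)
  fid <- fit_corresponded_affine(src, src)
  expect_equal(fid$A, diag(3), tolerance = 1e-9)
  expect_equal(fid$t, c(0, 0, 0), tolerance = 1e-9)
  expect_equal(fid$rmse, 0, tolerance = 1e-9)
  f2 <- fit_corresponded_affine(src, sweep(2 * src, 2, c(1, 2, 3), "+"))
  expect_equal(f2$A, 2 * diag(3), tolerance = 1e-9)
  expect_equal(f2$t, c(1, 2, 3), tolerance = 1e-9)
  # noisy pair: residual matches an explicit normal-equations solve
  tgt <- sweep(src %*% matrix(c(1.1, .2, 0, -.1, .9, .1, 0, 0, 1.2), 3), 2,
               c(4, -1, 2), "+") + matrix(rnorm(45, 0, 0.5), 15)
  f3 <- fit_corresponded_affine(src, tgt)
  X <- cbind(src, 1)
  beta <- solve(crossprod(X), crossprod(X, tgt))
  pred <- X %*% beta
  expect_equal(f3$rmse, sqrt(mean(rowSums((pred - tgt)^2))), tolerance = 1e-9)
  # coplanar sources are a rank error
  flat <- cbind(src[, 1:2], 0)
  expect_error(fit_corresponded_affine(flat, flat + 1), "rank")
})

test_that("rigid fits return proper rotations only", {
  set.seed(51)
  src <- matrix(rnorm(30, 0, 5), 10)
  fid <- fit_corresponded_rigid(src, src)
  expect_equal(fid$R, diag(3), tolerance = 1e-9)
  expect_equal(fid$rmse, 0, tolerance = 1e-9)
  R <- random_rotation(); tt <- c(-3, 7, 1)
  fr <- fit_corresponded_rigid(src, sweep(src %*% t(R), 2, tt, "+"))
  expect_equal(fr$R, R, tolerance = 1e-9)
  expect_equal(fr$t, tt, tolerance = 1e-9)
  # reflected target: best proper rotation, residual > 0, det stays +1
  frefl <- fit_corresponded_rigid(src, src %*% diag(c(-1, 1, 1)))
  expect_equal(det(frefl$R), 1, tolerance = 1e-9)
  expect_gt(frefl$rmse, 0.1)
  # composing a rigid fit with its inverse is the identity
  inv <- fit_corresponded_rigid(sweep(src %*% t(R), 2, tt, "+"), src)
  expect_equal(inv$R %*% fr$R, diag(3), tolerance = 1e-9)
  expect_equal(as.numeric(inv$R %*% fr$t + inv$t), c(0, 0, 0),
               tolerance = 1e-9)
})

test_that("closest-image selection matches brute force and breaks ties low", {
  we <- fix_we32()
  cands <- we$samples
  inst <- cands[[3]]$mesh$vertices
  sel <- closest_training_image(inst, cands)
  expect_identical(sel$index, 3L)
  expect_equal(sel$distance, 0, tolerance = 1e-9)
  # brute-force recomputation agrees on the full candidate list
  brute <- vapply(cands, function(s)
    fit_corresponded_affine(s$mesh$vertices, inst)$rmse, 0)
  expect_identical(sel$index, which.min(brute))
  expect_equal(sel$distances, brute, tolerance = 1e-12)
  # two identical candidates: the lower index wins
  dup <- cands[c(2, 5, 5)]
  inst2 <- cands[[5]]$mesh$vertices
  expect_identical(closest_training_image(inst2, dup)$index, 2L)
  expect_error(closest_training_image(inst, list()), "empty")
})

test_that("TPS interpolates exactly at lambda 0 and reproduces affine maps", {
  set.seed(52)
  src <- matrix(runif(30, 0, 50), 10)
  # identity
  t0 <- fit_tps(src, src, 0)
  expect_lt(max(abs(t0$W)), 1e-10)
  expect_lt(max(abs(apply_tps(t0, src) - src)), 1e-9)
  # random perturbation: exact landmark interpolation
  tgt <- src + matrix(rnorm(30, 0, 3), 10)
  t1 <- fit_tps(src, tgt, 0)
  expect_lt(max(abs(apply_tps(t1, src) - tgt)), 1e-6)
  # side conditions on the warping weights
  expect_lt(max(abs(colSums(t1$W))), 1e-6)
  expect_lt(max(abs(crossprod(src, t1$W))), 1e-4)
  # affine targets: zero warping energy, far field follows the affine
  A <- matrix(c(1.2, .1, 0, .05, .9, .1, 0, 0, 1.1), 3); tt <- c(5, -3, 2)
  ta <- fit_tps(src, sweep(src %*% t(A), 2, tt, "+"), 0)
  expect_lt(max(abs(ta$W)), 1e-8)
  far <- matrix(c(400, -300, 250), 1)
  expect_equal(as.numeric(apply_tps(ta, far)),
               as.numeric(far %*% t(A) + tt), tolerance = 1e-6)
  # empty input passes through
  expect_identical(nrow(apply_tps(ta, matrix(0, 0, 3))), 0L)
  # coincident landmarks make the system singular
  bad <- src; bad[2, ] <- bad[1, ]
  expect_error(fit_tps(bad, bad, 0), "lambda")
})

test_that("landmark selection is deterministic farthest-point sampling", {
  m <- fix_unit_tet()
  expect_identical(sort(select_tps_landmarks(m, 4)), 1:4)
  mesh <- suppressWarnings(worked_example())$reference
  surf <- extract_surface_vertices(mesh)
  expect_identical(sort(select_tps_landmarks(mesh, length(surf))), surf)
  # spread quality: min pairwise distance beats random subsets
  sel <- select_tps_landmarks(mesh, 10)
  min_pair <- function(ids) min(dist(mesh$vertices[ids, ]))
  fps_q <- min_pair(sel)
  set.seed(53)
  rand_q <- replicate(100, min_pair(sample(surf, 10)))
  expect_true(all(fps_q >= rand_q))
  expect_error(select_tps_landmarks(mesh, 3), "at least 4")
})

test_that("reference surfaces fit their own and scaled masks", {
  we <- fix_we32()
  s1 <- we$samples[[1]]
  surf_ids <- s1$mesh$surface_vertex_ids
  ref <- surface_mesh(s1$mesh$vertices[surf_ids, ], matrix(integer(0), 0, 3))
  # fixed point: mask rasterized from the reference itself
  fit0 <- fit_reference_to_mask(ref, s1$mask)
  moves <- sqrt(rowSums((fit0$vertices - ref$vertices)^2))
  expect_lt(mean(moves), min(s1$mask$spacing))
  # uniformly scaled target: scale recovered within 2%. The recovered
  # scale is measured against the fit to the unscaled mask so the common
  # voxelization bias of the discretized boundary cancels.
  ctr <- colMeans(s1$mesh$vertices)
  scaled_mesh <- tet_mesh(sweep(sweep(s1$mesh$vertices, 2, ctr), 2, ctr,
                                function(x, c) 1.15 * x + c),
                          s1$mesh$tets)
  scaled_mask <- rasterize_mask(scaled_mesh, grid_of(s1$mask))
  fit1 <- fit_reference_to_mask(ref, scaled_mask)
  rms_r <- function(v) sqrt(mean(rowSums(sweep(v, 2, colMeans(v))^2)))
  expect_equal(rms_r(fit1$vertices) / rms_r(fit0$vertices), 1.15,
               tolerance = 0.02)
  # analytic surface: fitted vertices lie within half a voxel of the
  # zero level set of the mask's distance map
  sdm <- signed_distance(s1$mask)
  d <- abs(sample_trilinear(sdm$distance, fit0$vertices, fill = 99))
  expect_lt(mean(d), 0.5 * min(s1$mask$spacing))
  expect_error(fit_reference_to_mask(ref,
    binary_mask(array(0L, dim(s1$mask$data)), s1$mask$spacing)), "empty")
})
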