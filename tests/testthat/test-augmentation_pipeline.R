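test_that("signed distance maps are exact Euclidean distances in mm", {
  # single-voxel mask: face neighbors sit 1 mm outside
  a <- array(0L, c(5, 5, 5)); a[3, 3, 3] <- 1L
  sd1 <- signed_distance(binary_mask(a, c(1, 1, 1)))
  expect_equal(sd1$distance$data[4, 3, 3], 1)
  expect_equal(sd1$distance$data[3, 3, 3], -1)
  expect_equal(sd1$distance$data[5, 3, 3], 2)
  expect_equal(sd1$distance$data[4, 4, 3], sqrt(2))
  # centered ball: interior value ~ -(R - r) within one voxel
  g <- list(dim = c(24L, 24L, 24L), spacing = c(1, 1, 1), origin = c(0, 0, 0))
  ctr <- voxel_centers(g)
  r <- sqrt(rowSums(sweep(ctr, 2, c(11.5, 11.5, 11.5))^2))
  R <- 8
  ball <- binary_mask(array(as.integer(r <= R), g$dim), g$spacing)
  sdb <- signed_distance(ball)
  inner <- which(r <= R - 1)
  expect_lt(max(abs(as.numeric(sdb$distance$data)[inner] + (R - r[inner]))), 1)
  expect_error(signed_distance(binary_mask(array(0L, c(4, 4, 4)))), "empty")
  expect_error(signed_distance(binary_mask(array(1L, c(4, 4, 4)))), "whole")
})

test_that("signed distance respects anisotropic spacing (brute-force oracle)", {
  set.seed(60)
  g <- list(dim = c(16L, 16L, 16L), spacing = c(1, 1, 3), origin = c(0, 0, 0))
  ctr <- voxel_centers(g)
  r <- sqrt(rowSums(sweep(ctr, 2, c(7.5, 7.5, 22.5))^2))
  mask <- binary_mask(array(as.integer(r <= 6), g$dim), g$spacing)
  sdm <- signed_distance(mask)
  inside <- as.logical(mask$data)
  d_in <- apply(ctr[inside, , drop = FALSE], 1, function(p)
    min(sqrt(colSums((t(ctr[!inside, , drop = FALSE]) - p)^2))))
  d_out <- apply(ctr[!inside, , drop = FALSE], 1, function(p)
    min(sqrt(colSums((t(ctr[inside, , drop = FALSE]) - p)^2))))
  expect_equal(as.numeric(sdm$distance$data)[inside], -d_in, tolerance = 1e-9)
  expect_equal(as.numeric(sdm$distance$data)[!inside], d_out, tolerance = 1e-9)
  # the recorded closest points achieve the reported distances
  w <- ctr[sdm$closest[inside], , drop = FALSE]
  expect_equal(sqrt(rowSums((w - ctr[inside, , drop = FALSE])^2)), d_in,
               tolerance = 1e-9)
})

test_that("cleaning mirrors exterior intensities and never touches the exterior", {
  g <- list(dim = c(32L, 8L, 8L), spacing = c(1, 1, 1), origin = c(0, 0, 0))
  # slab mask x <= 9.5 with a linear ramp background
  img <- image_from_field(g, function(x, y, z) 5 + 3 * x)
  mdat <- array(0L, g$dim); mdat[1:10, , ] <- 1L
  mask <- binary_mask(mdat, g$spacing)
  cleaned <- clean_structure(img, mask)
  expect_identical(cleaned$data[mdat == 0L], img$data[mdat == 0L])
  # interior voxel at x: nearest exterior center is x = 10; the mirror
  # lands at x + 2*(10 - x), where the ramp is analytic
  for (xi in c(4, 7, 9)) {
    x <- xi  # 0-based x index = world x here
    expect_equal(cleaned$data[xi + 1, 4, 4], 5 + 3 * (x + 2 * (10 - x)),
                 tolerance = 1e-3)
  }
  # empty mask: image returned unchanged
  empty <- binary_mask(array(0L, g$dim), g$spacing)
  expect_identical(clean_structure(img, empty)$data, img$data)
  expect_error(clean_structure(img, binary_mask(array(1L, g$dim), g$spacing)),
               "exterior")
  # constant background mirrors to the constant
  imgc <- volume_image(array(77, g$dim), g$spacing, g$origin)
  expect_equal(range(clean_structure(imgc, mask)$data), c(77, 77))
})

test_that("identity-instance warping is a near-identity of the cleaned image", {
  we <- fix_we64()
  s1 <- we$samples[[1]]
  enc <- suppressWarnings(fit_encoding(s1$image, s1$mesh, 3))
  inst <- structure(list(mesh = s1$mesh, encoding = enc,
                         b_shape = NULL, b_intensity = NULL, rejections = 0L),
                    class = "ssim_instance")
  cleaned <- clean_structure(s1$image, s1$mask)
  aug <- warp_and_paint(cleaned, s1, inst, lambda_tps = 0)
  expect_gte(dice_coefficient(aug$mask, s1$mask), 0.98)
  ext <- aug$mask$data == 0
  expect_lte(max(abs((aug$image$data - cleaned$data)[ext])), 1e-3)
  # painted region equals the direct rasterization of the encoding
  ras <- rasterize_encoding(enc, s1$mesh, grid_of(cleaned))
  inside <- aug$mask$data == 1
  expect_lt(max(abs((aug$image$data - ras$data)[inside])), 1e-6)
  # realignment of the identity case is the identity
  aug2 <- realign_rigid(aug, s1)
  expect_lt(max(abs(aug2$provenance$realign$R - diag(3))), 1e-6)
  expect_lt(max(abs(aug2$provenance$realign$t)), 1e-6)
})

test_that("constant-intensity instances paint exactly and leave no ghost", {
  we <- fix_we32()
  s1 <- we$samples[[1]]
  m <- count_coefficients(3)
  const_val <- -500  # outside the phantom's intensity range
  inst <- structure(list(
    mesh = s1$mesh,
    encoding = intensity_encoding(3, matrix(const_val, nrow(s1$mesh$tets), m)),
    b_shape = NULL, b_intensity = NULL, rejections = 0L),
    class = "ssim_instance")
  cleaned <- clean_structure(s1$image, s1$mask)
  aug <- warp_and_paint(cleaned, s1, inst, lambda_tps = 0)
  inside <- aug$mask$data == 1
  expect_equal(range(aug$image$data[inside]), rep(const_val, 2),
               tolerance = 1e-9)
  # no voxel inside the painted mask retains its original interior value
  originals <- s1$image$data[inside]
  expect_identical(sum(aug$image$data[inside] == originals), 0L)
})

test_that("rigid realignment undoes a translated instance", {
  we <- fix_we32()
  s1 <- we$samples[[1]]
  enc <- suppressWarnings(fit_encoding(s1$image, s1$mesh, 3))
  shift <- c(6, 0, 0)
  moved <- tet_mesh(sweep(s1$mesh$vertices, 2, shift, "+"), s1$mesh$tets)
  inst <- structure(list(mesh = moved, encoding = enc,
                         b_shape = NULL, b_intensity = NULL, rejections = 0L),
                    class = "ssim_instance")
  cleaned <- clean_structure(s1$image, s1$mask)
  aug <- warp_and_paint(cleaned, s1, inst, lambda_tps = 0)
  aug2 <- realign_rigid(aug, s1)
  expect_equal(aug2$provenance$realign$t, -shift,
               tolerance = 0.5 * min(s1$image$spacing))
  # the realigned mask equals the rasterization of the realigned mesh
  expect_identical(aug2$mask$data,
                   rasterize_mask(aug2$mesh, grid_of(aug2$image))$data)
  # and agrees with nearest-neighbor mask resampling to Dice >= 0.98
  g <- grid_of(aug$image)
  rt <- aug2$provenance$realign
  back <- sweep(voxel_centers(g), 2, rt$t) %*% rt$R
  nn <- round(ssimaug:::cpp_trilinear(as.numeric(aug$mask$data), g$dim,
                                      world_to_index(back, g), 0))
  nn_mask <- binary_mask(array(as.integer(nn), g$dim), g$spacing, g$origin)
  expect_gte(dice_coefficient(aug2$mask, nn_mask), 0.98)
})

test_that("augmented-set generation balances patients and is reproducible", {
  we <- fix_we32()
  ssim <- fix_ssim32()
  res <- generate_augmented_set(we$samples, ssim, n = 3, seed = 9)
  res2 <- generate_augmented_set(we$samples, ssim, n = 3, seed = 9)
  for (i in 1:3) {
    expect_identical(res$samples[[i]]$image$data, res2$samples[[i]]$image$data)
    expect_identical(res$samples[[i]]$provenance, res2$samples[[i]]$provenance)
    # mask invariant: mask equals the rasterized warped mesh
    expect_identical(res$samples[[i]]$mask$data,
                     rasterize_mask(res$samples[[i]]$mesh,
                                    grid_of(res$samples[[i]]$image))$data)
  }
  expect_equal(sum(res$usage), 3)
  # identical candidates: balance 0 always picks the first,
  # balance 1 round-robins within +/- 1
  five <- we$samples[c(1, 1, 1, 1, 1)]
  for (i in seq_along(five)) five[[i]]$patient_id <- paste0("p", i)
  r0 <- generate_augmented_set(five, ssim, n = 4, balance_strength = 0,
                               seed = 10)
  expect_identical(as.numeric(r0$usage), c(4, 0, 0, 0, 0))
  r1 <- generate_augmented_set(five, ssim, n = 20, balance_strength = 1,
                               seed = 10)
  expect_lte(diff(range(r1$usage)), 1)
})
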