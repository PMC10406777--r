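test_that("coefficient counts follow the closed form (d+3)!/(3! d!)", {
  expect_identical(count_coefficients(3), 20L)
  expect_identical(count_coefficients(0), 1L)
  expect_identical(count_coefficients(2), 10L)
  # independent enumeration oracle
  for (d in 0:5) {
    n_enum <- sum(outer(0:d, 0:d, function(i, j)
      ifelse(i + j <= d, d - i - j + 1L, 0L)))
    expect_identical(count_coefficients(d), as.integer(n_enum))
  }
  expect_error(count_coefficients(-1), "non-negative")
})

test_that("multi-index enumeration is lexicographically descending and complete", {
  expect_identical(enumerate_multi_indices(1),
                   rbind(c(1L, 0L, 0L, 0L), c(0L, 1L, 0L, 0L),
                         c(0L, 0L, 1L, 0L), c(0L, 0L, 0L, 1L)))
  mi3 <- enumerate_multi_indices(3)
  expect_identical(mi3[1, ], c(3L, 0L, 0L, 0L))
  expect_identical(nrow(mi3), 20L)
  expect_true(all(rowSums(mi3) == 3L))
  expect_identical(nrow(unique(mi3)), 20L)
})

test_that("Bernstein basis values match the multinomial formula", {
  p <- c(0.3, 0.3, 0.2, 0.2)
  expect_equal(bernstein_basis(0, c(0, 0, 0, 0), p), 1)
  expect_equal(bernstein_basis(1, c(1, 0, 0, 0), c(1, 0, 0, 0)), 1)
  expect_equal(bernstein_basis(3, c(1, 1, 1, 0), rep(0.25, 4)), 6 * 0.25^3)
  expect_error(bernstein_basis(3, c(1, 1, 0, 0), p), "summing to d")
})

test_that("the basis is a partition of unity for degrees up to 5", {
  set.seed(21)
  for (d in 0:5) for (rep in 1:10) {
    p <- rexp(4); p <- p / sum(p)
    mi <- enumerate_multi_indices(d)
    s <- sum(vapply(seq_len(nrow(mi)), function(i)
      bernstein_basis(d, mi[i, ], p), 0))
    expect_equal(s, 1, tolerance = 1e-9)
  }
})

test_that("density evaluation matches term-by-term summation and is linear", {
  set.seed(22)
  m <- count_coefficients(3)
  C1 <- matrix(rnorm(2 * m, 100, 50), 2)
  C2 <- matrix(rnorm(2 * m, 0, 30), 2)
  enc1 <- intensity_encoding(3, C1)
  enc2 <- intensity_encoding(3, C2)
  mi <- enumerate_multi_indices(3)
  for (rep in 1:5) {
    p <- rexp(4); p <- p / sum(p)
    bp <- list(p = p, tet_id = 2L)
    oracle <- sum(vapply(seq_len(m), function(i)
      C1[2, i] * bernstein_basis(3, mi[i, ], p), 0))
    expect_equal(evaluate_density(enc1, bp), oracle, tolerance = 1e-10)
    # linearity in the coefficients
    enc_mix <- intensity_encoding(3, 2 * C1 - 0.5 * C2)
    expect_equal(evaluate_density(enc_mix, bp),
                 2 * evaluate_density(enc1, bp) - 0.5 * evaluate_density(enc2, bp),
                 tolerance = 1e-9)
  }
  # constant coefficients give the constant everywhere
  encc <- intensity_encoding(3, matrix(42, 2, m))
  expect_equal(evaluate_density(encc, list(p = c(0.1, 0.2, 0.3, 0.4),
                                           tet_id = 1L)), 42)
  expect_error(evaluate_density(enc1, list(p = rep(0.25, 4), tet_id = 9L)),
               "out of range")
})

test_that("fitting reproduces constant and polynomial fields exactly", {
  fx <- fix_dense_grid()
  img_const <- image_from_field(fx$grid, function(x, y, z) rep(100, length(x)))
  enc <- fit_encoding(img_const, fx$mesh, 3)
  expect_equal(range(enc$coefficients), c(100, 100), tolerance = 1e-6)
  # linear ramp, d = 1: exact at voxel centers
  img_lin <- image_from_field(fx$grid, function(x, y, z) 5 + 2 * x - y + 3 * z)
  enc1 <- fit_encoding(img_lin, fx$mesh, 1)
  expect_lt(encoding_error(img_lin, enc1, fx$mesh), 1e-6)
  # full cubic field, d = 3: exact at voxel centers
  img_cub <- image_from_field(fx$grid, function(x, y, z)
    50 + x * y * z - 2 * x^2 + y^3 + x * z + 4 * z^2 * y - x + 2 * y)
  enc3 <- fit_encoding(img_cub, fx$mesh, 3)
  rec <- rasterize_encoding(enc3, fx$mesh, fx$grid, fill = NA)
  inside <- rasterize_mask(fx$mesh, fx$grid)$data == 1
  rel <- abs(rec$data - img_cub$data)[inside] /
    pmax(abs(img_cub$data[inside]), 1e-9)
  expect_lt(max(rel), 1e-6)
})

test_that("rasterized encodings re-fit to the same coefficients", {
  fx <- fix_dense_grid()
  set.seed(30)
  img <- image_from_field(fx$grid, function(x, y, z)
    200 + 40 * sin(x) + 25 * y * z - 10 * z^2)
  enc <- fit_encoding(img, fx$mesh, 2)
  ras <- rasterize_encoding(enc, fx$mesh, fx$grid)
  enc2 <- fit_encoding(ras, fx$mesh, 2)
  rel <- abs(enc2$coefficients - enc$coefficients) /
    pmax(abs(enc$coefficients), 1)
  expect_lt(max(rel), 1e-4)
  # constant encoding rasterizes to the constant inside the mesh
  m <- count_coefficients(2)
  encc <- intensity_encoding(2, matrix(7, nrow(fx$mesh$tets), m))
  rc <- rasterize_encoding(encc, fx$mesh, fx$grid, fill = -1)
  inside <- rasterize_mask(fx$mesh, fx$grid)$data == 1
  expect_equal(range(rc$data[inside]), c(7, 7), tolerance = 1e-9)
  expect_true(all(rc$data[!inside] == -1))
  # mesh with no overlap gives an all-fill image
  far <- build_tet_grid(c(50, 50, 50), c(51, 51, 51), c(1L, 1L, 1L))
  expect_true(all(rasterize_encoding(encc2 <- intensity_encoding(2,
    matrix(7, 5, m)), far, fx$grid, fill = 3)$data == 3))
})

test_that("the encoding error metric behaves as defined", {
  fx <- fix_dense_grid()
  img_lin <- image_from_field(fx$grid, function(x, y, z) 10 + 2 * x + y + z)
  enc <- fit_encoding(img_lin, fx$mesh, 1)
  expect_lt(encoding_error(img_lin, enc, fx$mesh), 1e-8)
  # scaling a perfect fit by 1.1 gives exactly 10% when I >= 1 everywhere
  enc110 <- intensity_encoding(1, 1.1 * enc$coefficients)
  expect_equal(encoding_error(img_lin, enc110, fx$mesh), 10, tolerance = 1e-6)
  far <- build_tet_grid(c(50, 50, 50), c(51, 51, 51), c(1L, 1L, 1L))
  expect_error(encoding_error(img_lin, enc, far), "no voxel centers")
})

test_that("encoding fidelity on the smooth phantom improves with degree", {
  we <- suppressWarnings(worked_example(noise_sd = 0))
  s1 <- we$samples[[1]]
  errs <- vapply(0:3, function(d) {
    enc <- suppressWarnings(fit_encoding(s1$image, s1$mesh, d))
    encoding_error(s1$image, enc, s1$mesh)
  }, 0)
  expect_true(all(diff(errs) <= 1e-6))
})
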