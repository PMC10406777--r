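# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

cached_fixture <- function(key, make) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- make()
  .fixtures[[key]]
}

# deterministic worked-example phantom population, 32^3
fix_we32 <- function() cached_fixture("we32", function()
  suppressWarnings(worked_example()))

# two 64^3 phantoms for pipeline-scale checks
fix_we64 <- function() cached_fixture("we64", function()
  suppressWarnings(worked_example(size = 64L, n_samples = 2L)))

fix_ssim32 <- function() cached_fixture("ssim32", function()
  suppressWarnings(build_ssim(fix_we32()$samples)))

# unit tetrahedron at the origin
fix_unit_tet <- function() {
  tet_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
           matrix(1:4, 1L))
}

# two tetrahedra sharing the face (2,3,4): 5 vertices total
fix_two_tets <- function() {
  tet_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 1)),
           rbind(1:4, c(2L, 3L, 4L, 5L)))
}

# a well-populated tet-grid mesh inside a 16^3, 0.2 mm grid
fix_dense_grid <- function() {
  list(grid = list(dim = c(16L, 16L, 16L), spacing = c(0.2, 0.2, 0.2),
                   origin = c(0, 0, 0)),
       mesh = build_tet_grid(c(0.2, 0.2, 0.2), c(2.8, 2.8, 2.8),
                             c(2L, 2L, 2L)))
}

# image whose voxel values follow fn(x, y, z) on a grid
image_from_field <- function(grid, fn) {
  ctr <- voxel_centers(grid)
  volume_image(array(fn(ctr[, 1], ctr[, 2], ctr[, 3]), grid$dim),
               grid$spacing, grid$origin)
}

random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}
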