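test_that("sphere masks reproduce printed voxel counts and the lattice oracle", {
  g2 <- voxel_grid(c(31, 37, 31), 2)
  s <- make_sphere_mask(c(0, 0, 0), 12, g2)
  expect_equal(s$n_voxels, 925L)   # 12-mm sphere on a 2-mm grid, voxel-center origin
  expect_equal(make_sphere_mask(c(0, 0, 0), 0, g2)$n_voxels, 1L)
  g15 <- voxel_grid(c(41, 41, 41), 1.5)
  s15 <- make_sphere_mask(c(0, 0, 0), 12, g15)
  expect_equal(s15$n_voxels, oracle_sphere_count(c(0, 0, 0), 12, g15))
  expect_error(make_sphere_mask(c(1000, 0, 0), 5, g2), "outside the grid")
})

test_that("sphere membership matches exhaustive enumeration for random draws", {
  set.seed(14)
  g <- voxel_grid(c(13, 15, 12), 1.5, origin_mm = c(-9, -10, -8))
  for (i in 1:25) {
    ctr <- runif(3, -6, 6)
    rad <- runif(1, 0, 8)
    got <- tryCatch(make_sphere_mask(ctr, rad, g)$n_voxels, error = function(e) 0L)
    expect_equal(got, oracle_sphere_count(ctr, rad, g))
  }
})

test_that("sphere masks centered on a voxel center are reflection symmetric", {
  g <- voxel_grid(c(15, 15, 15), 2)
  s <- make_sphere_mask(c(0, 0, 0), 7, g)
  offs <- sweep(s$voxel_indices, 2, (g$shape + 1) / 2)  # offsets about center voxel
  key <- function(m) sort(apply(m, 1, paste, collapse = ","))
  expect_equal(key(-offs), key(offs))
})

test_that("Gaussian smoothing is mass-conserving, linear, and matches dense convolution", {
  g <- voxel_grid(c(13, 13, 13), 2)
  imp <- array(0, g$shape); imp[7, 7, 7] <- 3
  m <- volume_map(imp, g)
  expect_equal(gaussian_smooth(m, 0)$values, m$values)
  sm <- gaussian_smooth(m, 6)
  expect_equal(sum(sm$values), 3, tolerance = 1e-6)  # interior impulse mass
  # dense convolution oracle
  sigma <- 6 / (2 * sqrt(2 * log(2))) / 2  # in voxels
  half <- ceiling(4 * sigma)
  ax <- dnorm(seq(-half, half), sd = sigma); ax <- ax / sum(ax)
  oracle <- array(0, g$shape)
  for (di in -half:half) for (dj in -half:half) for (dk in -half:half) {
    i <- 7 + di; j <- 7 + dj; k <- 7 + dk
    if (all(c(i, j, k) >= 1 & c(i, j, k) <= 13))
      oracle[i, j, k] <- oracle[i, j, k] +
        3 * ax[di + half + 1] * ax[dj + half + 1] * ax[dk + half + 1]
  }
  expect_equal(sm$values, oracle, tolerance = 1e-10)
  # linearity
  set.seed(8)
  a <- volume_map(array(rnorm(prod(g$shape)), g$shape), g)
  b <- volume_map(array(rnorm(prod(g$shape)), g$shape), g)
  lin <- volume_map(2 * a$values - 3 * b$values, g)
  expect_equal(gaussian_smooth(lin, 5)$values,
               2 * gaussian_smooth(a, 5)$values - 3 * gaussian_smooth(b, 5)$values,
               tolerance = 1e-10)
  # stack smoothing agrees with per-map smoothing
  stk <- volume_stack(list(a, b), kind = "other")
  sstk <- gaussian_smooth(stk, 5)
  expect_equal(array(sstk$data[1, ], g$shape), gaussian_smooth(a, 5)$values,
               tolerance = 1e-10)
})

test_that("absolute masking keeps a voxel only when all subjects clear the threshold", {
  set.seed(4)
  stk <- make_noise_stack(6, c(5, 5, 5), seed = 4)
  stk$data <- abs(stk$data)
  m0 <- absolute_mask(stk, 0)
  expect_true(all(m0$values == 1))
  m <- absolute_mask(stk, 0.05)
  oracle <- as.numeric(apply(stk$data, 2, min) >= 0.05)
  expect_equal(as.vector(m$values), oracle)
  # one subject below threshold excludes the voxel
  stk$data[3, 17] <- 0.01
  expect_equal(as.vector(absolute_mask(stk, 0.05)$values)[17], 0)
})

test_that("NIfTI round trip preserves grid geometry and float32 payloads", {
  g <- voxel_grid(c(7, 6, 5), c(1.5, 1.5, 1.5), origin_mm = c(-4.5, -3, 2))
  set.seed(2)
  vals <- array(rnorm(prod(g$shape)), g$shape)
  m <- volume_map(vals, g, kind = "other")
  f <- tempfile(fileext = ".nii.gz")
  write_volume(m, f)
  back <- read_volume(f)
  expect_equal(back$grid$shape, g$shape)
  expect_equal(back$grid$voxel_size_mm, g$voxel_size_mm)
  expect_equal(back$grid$origin_mm, g$origin_mm)
  expect_equal(back$values, m$values, tolerance = 1e-6)  # float32 precision
  # write -> read -> write is bitwise stable once quantized to float32
  f2 <- tempfile(fileext = ".nii.gz")
  write_volume(back, f2)
  expect_equal(read_volume(f2)$values, back$values)
})

test_that("4-D subject stacks round-trip as lists of 3-D maps", {
  stk <- make_noise_stack(4, c(6, 5, 4), seed = 9)
  f <- tempfile(fileext = ".nii.gz")
  write_volume_stack(stk, f)
  back <- read_volume_stack(f)
  expect_equal(dim(back$data), dim(stk$data))
  expect_equal(back$data, stk$data, tolerance = 1e-6)
  expect_equal(back$grid$voxel_size_mm, stk$grid$voxel_size_mm)
})

test_that("non-axis-aligned affines are rejected explicitly", {
  a <- array(rnorm(60), dim = c(3, 4, 5))
  img <- RNifti::asNifti(a)
  rot <- diag(4)
  th <- 0.3
  rot[1:2, 1:2] <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  img <- RNifti::`sform<-`(img, structure(rot, code = 2L))
  f <- tempfile(fileext = ".nii")
  RNifti::writeNifti(img, f)
  expect_error(read_volume(f), "unsupported orientation")
})
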