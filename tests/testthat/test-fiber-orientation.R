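test_that("FFT patch estimator recovers prescribed grating axes", {
  ## axis along x
  fv <- make_fiber_volume(c(64, 64, 64), c(1, 0, 0), wavelength = 8,
                          seed = 2)
  s <- patch_dominant_axes(fv$volume, matrix(c(32, 32, 32), 1), patch = 50)
  expect_equal(nrow(s[[1]]$axes), 1)
  expect_lt(axis_angle_deg(s[[1]]$axes[1, ], c(1, 0, 0)), 5)
  ## axis rotated 45 degrees in-plane
  ax45 <- c(1, 1, 0) / sqrt(2)
  fv45 <- make_fiber_volume(c(64, 64, 64), ax45, wavelength = 8, seed = 2)
  s45 <- patch_dominant_axes(fv45$volume, matrix(c(32, 32, 32), 1), 50)
  expect_lt(axis_angle_deg(s45[[1]]$axes[1, ], ax45), 5)
})

test_that("two orthogonal gratings of equal power give two orthogonal axes", {
  a <- make_fiber_volume(c(64, 64, 64), c(1, 0, 0), wavelength = 8,
                         seed = 2)$volume$values
  b <- make_fiber_volume(c(64, 64, 64), c(0, 1, 0), wavelength = 8,
                         seed = 9)$volume$values
  s <- patch_dominant_axes(voxel_volume(a + b),
                           matrix(c(32, 32, 32), 1), 50)[[1]]
  expect_equal(nrow(s$axes), 2)
  expect_lt(abs(axis_angle_deg(s$axes[1, ], s$axes[2, ]) - 90), 5)
  expect_lt(max(abs(s$dominance - 0.5)), 0.15)
})

test_that("white noise yields no axis above the dominance threshold", {
  wn <- voxel_volume(array(with_seed_local(3, rnorm(64^3)), c(64, 64, 64)))
  s <- patch_dominant_axes(wn, matrix(c(32, 32, 32), 1), 50)[[1]]
  expect_equal(nrow(s$axes), 0)
  expect_length(s$dominance, 0)
})

test_that("axis-field smoothing is sign-invariant and a fixed point on constants", {
  ax <- c(0, 1, 0)
  mk <- function(a, p) list(position = p, axes = rbind(a),
                            dominance = 1)
  pos <- as.matrix(expand.grid(seq(0, 20, 5), seq(0, 20, 5), 0))
  samples <- lapply(seq_len(nrow(pos)), function(i) mk(ax, pos[i, ]))
  sm <- smooth_axis_field(samples, neighbor_radius = 8, lambda_smooth = 1)
  for (s in sm) expect_lt(axis_angle_deg(s$axes[1, ], ax), 1e-6)
  ## flipping the sign of one input axis changes nothing
  samples2 <- samples
  samples2[[5]]$axes <- -samples2[[5]]$axes
  sm2 <- smooth_axis_field(samples2, neighbor_radius = 8, lambda_smooth = 1)
  for (i in seq_along(sm))
    expect_lt(axis_angle_deg(sm2[[i]]$axes[1, ], sm[[i]]$axes[1, ]), 1e-9)
})

test_that("smoothing reduces angular error of a rotating field with outliers", {
  set.seed(4)
  pos <- as.matrix(expand.grid(seq(0, 45, 5), seq(0, 45, 5), 0))
  true_axis <- function(p) {
    th <- pi / 6 * p[1] / 45
    c(cos(th), sin(th), 0)
  }
  samples <- lapply(seq_len(nrow(pos)), function(i) {
    a <- true_axis(pos[i, ])
    if (runif(1) < 0.1) a <- c(0, 0, 1)          # 10% outliers
    else {
      a <- a + rnorm(3, 0, 0.08); a <- a / sqrt(sum(a^2))
    }
    list(position = pos[i, ], axes = rbind(a), dominance = 1)
  })
  errs0 <- vapply(seq_along(samples), function(i)
    axis_angle_deg(samples[[i]]$axes[1, ], true_axis(pos[i, ])), numeric(1))
  sm <- smooth_axis_field(samples, neighbor_radius = 8, lambda_smooth = 3)
  errs1 <- vapply(seq_along(sm), function(i)
    axis_angle_deg(sm[[i]]$axes[1, ], true_axis(pos[i, ])), numeric(1))
  expect_lt(sqrt(mean(errs1^2)), sqrt(mean(errs0^2)))
})

test_that("tangential projection drops near-normal axes and fixes in-plane ones", {
  mid <- heightfield_mesh(0:10, 0:10, matrix(0, 11, 11))
  mk <- function(a) list(position = c(5, 5, 0), axes = rbind(unit3(a)),
                         dominance = 1)
  ## already tangential: unchanged
  s1 <- project_tangential(list(mk(c(1, 0, 0))), mid)
  expect_lt(axis_angle_deg(s1[[1]]$axes[1, ], c(1, 0, 0)), 1e-6)
  ## 45 degrees: projected in-plane
  s2 <- project_tangential(list(mk(c(1, 0, 1))), mid)
  expect_lt(abs(s2[[1]]$axes[1, 3]), 1e-9)
  expect_lt(axis_angle_deg(s2[[1]]$axes[1, ], c(1, 0, 0)), 1e-6)
  ## parallel to the normal: dropped
  s3 <- project_tangential(list(mk(c(0, 0, 1))), mid)
  expect_equal(nrow(s3[[1]]$axes), 0)
})

test_that("spectral interpolation reproduces constants and low-order modes", {
  m <- heightfield_mesh(seq(0, 20, 2), seq(0, 20, 2), matrix(0, 11, 11))
  pos <- as.matrix(expand.grid(seq(1, 19, 3), seq(1, 19, 3), 0))
  cs <- lapply(seq_len(nrow(pos)), function(i)
    list(position = pos[i, ], value = 3.5))
  f <- interpolate_field(cs, m, n_modes = 1)
  expect_lt(max(abs(f$values - 3.5)), 1e-6)
  ## a low-order eigenmode samples itself back
  em <- scutes:::mesh_eigenmodes(m, 4)
  mode <- em$vectors[, 3]
  nv <- scutes:::nearest_vertex(pos, m$vertices)
  ms <- lapply(seq_len(nrow(pos)), function(i)
    list(position = pos[i, ], value = mode[nv[i]]))
  fm <- interpolate_field(ms, m, n_modes = 4)
  expect_lt(max(abs(fm$values - mode)), 1e-6)
  ## more modes than samples: regularized path with warning
  few <- cs[1:3]
  expect_warning(interpolate_field(few, m, n_modes = 6), "rank")
})

test_that("end-to-end axis-field recovery stays below 10 degrees median error", {
  ## smoothly rotating in-plane axis rendered blockwise, then estimated,
  ## smoothed and interpolated onto a surface
  axis_fun <- function(xyz) {
    xyz <- rbind(xyz)
    t(vapply(seq_len(nrow(xyz)), function(i) {
      th <- pi / 5 * xyz[i, 1] / 96
      c(cos(th), sin(th), 0)
    }, numeric(3)))
  }
  fv <- make_fiber_volume(c(96, 96, 64), axis_fun, wavelength = 8,
                          noise_sd = 0.2, seed = 6, block = 32L)
  centers <- as.matrix(expand.grid(c(16, 48, 80), c(16, 48, 80), 32))
  s <- patch_dominant_axes(fv$volume, centers, patch = 30)
  s <- smooth_axis_field(s, neighbor_radius = 40, lambda_smooth = 0.5)
  errs <- vapply(seq_along(s), function(i) {
    if (nrow(s[[i]]$axes) == 0) return(NA_real_)
    axis_angle_deg(s[[i]]$axes[1, ], axis_fun(centers[i, ])[1, ])
  }, numeric(1))
  expect_true(all(is.finite(errs)))
  expect_lt(median(errs), 10)
})
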