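test_that("signal curvatures match the closed-form Gaussian-blob Hessian", {
  ## single Gaussian blob of sd s: smoothed at sigma the intensity is a
  ## Gaussian of sd t = sqrt(s^2 + sigma^2) (amplitude scales by
  ## (s^2/t^2)^(3/2)); at the centre -H = A_eff / t^2 * I
  s <- 2.5; sigma <- 1.5
  vol <- array(0, c(33, 33, 33))
  vol <- scutes:::add_blob(vol, c(17, 17, 17), s, 1)
  cv <- signal_principal_curvatures(voxel_volume(vol), sigma)
  t2 <- s^2 + sigma^2
  expected <- (s^2 / t2)^(3 / 2) / t2
  for (k in c("k1", "k2", "k3")) {
    expect_equal(cv[[k]][17, 17, 17], expected, tolerance = 0.02)
    expect_gt(cv[[k]][17, 17, 17], 0)
  }
  ## sortedness everywhere
  expect_true(all(cv$k1 >= cv$k2 - 1e-12))
  expect_true(all(cv$k2 >= cv$k3 - 1e-12))
})

test_that("a bright straight tube has one near-zero curvature along its axis", {
  vol <- array(0, c(33, 33, 33))
  for (i in 1:33)  # tube along x
    vol[i, , ] <- outer(exp(-((1:33 - 17)^2) / (2 * 2^2)),
                        exp(-((1:33 - 17)^2) / (2 * 2^2)))
  cv <- signal_principal_curvatures(voxel_volume(vol), 1.5)
  ctr <- cv$k3[17, 17, 17]          # axis curvature is the smallest
  expect_lt(abs(ctr), 0.05 * cv$k1[17, 17, 17])
  expect_gt(cv$k2[17, 17, 17], 0.5 * cv$k1[17, 17, 17])
  ## constant volume: all zero
  cz <- signal_principal_curvatures(voxel_volume(array(3, c(9, 9, 9))), 1)
  expect_lt(max(abs(c(cz$k1, cz$k2, cz$k3))), 1e-9)
})

test_that("k_s is the clamped geometric mean, permutation- and scale-covariant", {
  expect_equal(compute_ks(list(8, 1, 27)), 6)
  expect_equal(compute_ks(list(8, -1, 27)), 0)
  expect_equal(compute_ks(list(1, 1, 1)), 1)
  ## permutation invariance and scale covariance on random triples
  set.seed(1)
  for (i in 1:20) {
    k <- rnorm(3)
    p <- sample(3)
    expect_equal(compute_ks(as.list(k)), compute_ks(as.list(k[p])))
    c <- runif(1, 0.1, 10)
    expect_equal(compute_ks(as.list(c * k)), c * compute_ks(as.list(k)),
                 tolerance = 1e-12)
  }
})

test_that("cell detection recovers centroids within a voxel at high contrast", {
  ed <- make_edu_volume(c(48, 48, 48), n_cells = 8, cell_radius = 4,
                        contrast = 1, noise_sd = 0.1, seed = 7)
  cv <- signal_principal_curvatures(ed$volume, sigma = 2)
  cen <- detect_cells(compute_ks(cv), v = ed$volume)
  m <- match_centroids(cen, ed$truth$centroids, tol = 1)
  expect_equal(m$tp, 8)
  expect_equal(m$fp, 0)
  expect_lte(m$max_err, 1)
  ## threshold above the global max: nothing detected
  ks <- compute_ks(cv)
  expect_equal(nrow(detect_cells(ks, k_threshold = max(ks) + 1,
                                 v = ed$volume)), 0)
  ## zero contrast: no cells at any positive threshold
  e0 <- make_edu_volume(c(48, 48, 48), 5, contrast = 0, noise_sd = 0.05,
                        seed = 3)
  cv0 <- signal_principal_curvatures(e0$volume, sigma = 2)
  ks0 <- compute_ks(cv0)
  thr <- quantile(ks0[ks0 > 0], 0.999)  # any honest positive threshold
  cen0 <- detect_cells(ks0, k_threshold = max(ks0) * 0.99, v = e0$volume)
  expect_equal(nrow(cen0), 0)
})

test_that("curvature detection splits touching cells that plain thresholding merges", {
  ed <- make_edu_volume(c(48, 48, 48), n_cells = 0, cell_radius = 4,
                        contrast = 1, noise_sd = 0, seed = 5,
                        touching_pairs = 1L)
  cv <- signal_principal_curvatures(ed$volume, sigma = 2)  # sigma <= r/2
  cen <- detect_cells(compute_ks(cv), v = ed$volume)
  expect_equal(nrow(cen), 2)
  m <- match_centroids(cen, ed$truth$centroids, tol = 1.5)
  expect_equal(m$tp, 2)
})

test_that("clipped-box densities follow the counting identities", {
  vol <- voxel_volume(array(0, c(100, 100, 100)))
  mask_full <- array(TRUE, c(100, 100, 100))
  cen <- rbind(c(50, 50, 50), c(45, 45, 45), c(55, 55, 55), c(50, 45, 55))
  ds <- cell_density(cen, mask_full, rbind(c(50, 50, 50)), vol,
                     box_voxels = 80)
  expect_equal(ds[[1]]$count, 4L)
  expect_equal(ds[[1]]$value, 4 / 80^3)
  ## clipping the box to half its volume doubles the density for the
  ## same cells: the box at voxel 51 spans voxels 11..90 in z, and the
  ## mask removes 11..50 — exactly half
  mask_half <- mask_full; mask_half[, , 1:50] <- FALSE
  cen_top <- cen; cen_top[, 3] <- cen_top[, 3] + 10   # keep inside mask
  dh <- cell_density(cen_top, mask_half, rbind(c(50, 50, 50)), vol,
                     box_voxels = 80)
  df <- cell_density(cen_top, mask_full, rbind(c(50, 50, 50)), vol,
                     box_voxels = 80)
  expect_equal(dh[[1]]$count, df[[1]]$count)
  expect_equal(dh[[1]]$clipped_volume * 2, df[[1]]$clipped_volume)
  expect_equal(dh[[1]]$value, 2 * df[[1]]$value)
  ## no cells: densities all zero
  d0 <- cell_density(matrix(0, 0, 3), mask_full, rbind(c(50, 50, 50)), vol)
  expect_equal(d0[[1]]$value, 0)
})

test_that("disjoint boxes tiling a layer conserve the total cell count", {
  vol <- voxel_volume(array(0, c(64, 64, 64)))
  mask <- array(TRUE, c(64, 64, 64))
  set.seed(8)
  cen <- cbind(runif(40, 1, 62), runif(40, 1, 62), runif(40, 1, 62))
  ## 2x2x2 tiling with 32-voxel boxes centred in each octant
  pts <- as.matrix(expand.grid(c(16, 48), c(16, 48), c(16, 48)))
  ds <- cell_density(cen, mask, pts, vol, box_voxels = 32)
  expect_equal(sum(vapply(ds, `[[`, integer(1), "count")), 40L)
})

test_that("growth field is mean-1 and tracks density contrasts", {
  m <- heightfield_mesh(seq(0, 30, 2), seq(0, 30, 2),
                        matrix(0, 16, 16))
  samples <- lapply(seq(2, 28, 2), function(x)
    lapply(seq(2, 28, 2), function(y)
      list(position = c(x, y, 0), value = if (x < 15) 0.5 else 1.5)))
  samples <- do.call(c, samples)
  f <- growth_from_density(samples, m, n_modes = 6)
  expect_equal(mean(f$values), 1, tolerance = 1e-6)
  left <- f$mesh$vertices[, 1] < 10
  right <- f$mesh$vertices[, 1] > 20
  expect_lt(mean(f$values[left]), 1)
  expect_gt(mean(f$values[right]), 1)
  ## uniform density -> exactly flat field
  us <- lapply(samples, function(s) { s$value <- 2; s })
  fu <- growth_from_density(us, m, n_modes = 4)
  expect_lt(max(abs(fu$values - 1)), 1e-6)
  expect_error(growth_from_density(list(), m), "samples")
})
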