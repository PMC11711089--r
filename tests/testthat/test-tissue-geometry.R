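test_that("Canny localizes a noiseless planar step to sub-voxel accuracy", {
  stepv <- array(0, c(32, 32, 32)); stepv[, , 1:16] <- 1
  cl <- detect_edges_3d(voxel_volume(stepv), sigma = 1.5,
                        low = 0.05, high = 0.15)
  expect_gt(nrow(cl$points), 100)
  ## analytic step-edge: gradient magnitude peaks on the plane z = 15.5
  expect_lt(max(abs(cl$points[, 3] - 15.5)), 1)
  ## normals within 2 degrees of +-z
  ang <- acos(pmin(1, abs(cl$normals[, 3]))) * 180 / pi
  expect_lt(max(ang), 2)
  ## constant volume: empty cloud, not an error
  e <- detect_edges_3d(voxel_volume(array(1, c(8, 8, 8))), 1, 0.1, 0.2)
  expect_equal(nrow(e$points), 0)
  expect_error(detect_edges_3d(voxel_volume(stepv), 1, 0.2, 0.1), "high")
})

test_that("sphere cloud reconstructs with area within 5% of 4 pi r^2", {
  cl <- sphere_cloud(n = 2000, r = 10, seed = 1)
  m <- suppressWarnings(reconstruct_surface(cl))
  expect_lt(abs(mesh_area(m) - 4 * pi * 100) / (4 * pi * 100), 0.05)
  expect_lt(mean(scutes:::cpp_point_mesh_distance(cl$points, m$vertices,
                                                  m$triangles)), 0.5)
  expect_true(audit_surface_mesh(m)$ok)
})

test_that("planar patch cloud reconstructs onto the plane", {
  set.seed(2)
  px <- cbind(runif(800, 0, 20), runif(800, 0, 20), 0)
  nr <- matrix(rep(c(0, 0, 1), 800), ncol = 3, byrow = TRUE)
  m <- suppressWarnings(reconstruct_surface(oriented_point_cloud(px, nr)))
  expect_lt(sqrt(mean(m$vertices[, 3]^2)), 0.5)
  expect_error(reconstruct_surface(
    oriented_point_cloud(px[1:3, ], nr[1:3, ])), "4 points")
})

test_that("Laplacian smoothing: identity at 0 iters, improves staircases, shrinks spheres", {
  ## voxelized staircase approximation of the plane z = x / 4
  gx <- 0:20
  zs <- matrix(round(gx / 4), 21, 21)
  m <- heightfield_mesh(gx, gx, zs)
  expect_identical(smooth_surface(m, 0)$vertices, m$vertices)
  rms0 <- sqrt(mean((m$vertices[, 3] - m$vertices[, 1] / 4)^2))
  ms <- smooth_surface(m, 20, 0.5)
  rms1 <- sqrt(mean((ms$vertices[, 3] - ms$vertices[, 1] / 4)^2))
  expect_lt(rms1, rms0)
  expect_identical(ms$triangles, m$triangles)
  ## closed sphere shrinks under many iterations (uniform Laplacian)
  sp <- sphere_mesh(r = 10)
  r1 <- mean(sqrt(rowSums(smooth_surface(sp, 50, 0.5)$vertices^2)))
  expect_lt(r1, 10)
})

test_that("epidermis thickness: parallel planes, concentric spheres, undulating gap", {
  p1 <- heightfield_mesh(0:10, 0:10, matrix(5, 11, 11))
  p2 <- heightfield_mesh(0:10, 0:10, matrix(0, 11, 11))
  th <- epidermis_thickness(p1, p2)
  expect_lt(max(abs(th - 5)), 1e-6)
  ## concentric spheres (outward normals on the outer sphere)
  s1 <- sphere_mesh(r = 10); s2 <- sphere_mesh(r = 7)
  th2 <- epidermis_thickness(s1, s2)
  expect_lt(max(abs(th2 - 3)), 0.2)     # faceting tolerance
  ## undulating interface below a flat top
  gx <- seq(0, 40, 1)
  zu <- outer(gx, gx, function(x, y) 2 * sin(2 * pi * x / 20))
  pu <- heightfield_mesh(gx, gx, 6 + 0 * zu)
  iu <- heightfield_mesh(gx, gx, zu)
  thu <- epidermis_thickness(pu, iu)
  inner <- pu$vertices[, 1] > 3 & pu$vertices[, 1] < 37
  gap <- 6 - 2 * sin(2 * pi * pu$vertices[inner, 1] / 20)
  expect_lt(max(abs(thu[inner] - gap)), 1)
})

test_that("nested-box tetrahedralization labels shells to analytic volumes", {
  outer <- box_mesh(c(0, 0, 0), c(30, 30, 30))
  inter <- box_mesh(rep(3, 3), rep(27, 3))
  bone <- box_mesh(rep(9, 3), rep(21, 3))
  tm <- tetrahedralize(outer, inter, bone, n = 30)
  expect_true(audit_tet_mesh(tm)$ok)
  va <- tapply(tet_volumes(tm$nodes, tm$tets), tm$layer, sum)
  target <- c(epidermis = 30^3 - 24^3, dermis = 24^3 - 12^3, bone = 12^3)
  expect_lt(max(abs(va - target) / target), 0.01)
  ## every tet labelled; bone nodes fixed
  expect_false(anyNA(tm$layer))
  expect_true(any(tm$fixed))
  ## intersecting inputs rejected with a diagnostic
  bad <- box_mesh(rep(-2, 3), rep(27, 3))
  expect_error(tetrahedralize(outer, bad, bone), "intersect")
})

test_that("bilayer patch surfaces round-trip through tetrahedralization", {
  ## height-field shells of the 8x8 patch (epi 2, derm 4)
  gx <- seq(0, 8, 0.5)
  outer <- heightfield_mesh(gx, gx, matrix(6, length(gx), length(gx)))
  inter <- heightfield_mesh(gx, gx, matrix(4, length(gx), length(gx)))
  bone <- heightfield_mesh(gx, gx, matrix(0.25, length(gx), length(gx)))
  tm <- tetrahedralize(outer, inter, bone, n = 24)
  va <- tapply(tet_volumes(tm$nodes, tm$tets), tm$layer, sum)
  expect_equal(unname(va[["epidermis"]]), 8 * 8 * 2, tolerance = 0.06)
  expect_equal(unname(va[["dermis"]]), 8 * 8 * (4 - 0.25), tolerance = 0.06)
})

test_that("full nuclear pipeline recovers both boundary surfaces within 2 voxels", {
  for (noise in c(0.2)) {   # 20% of nuclear peak amplitude
    nv <- nuclear_fixture(noise_sd = noise)
    cl <- canny_on_fixture(nv)
    sp <- split_boundary_clouds(nv$volume, cl, sigma = 5)
    mo <- smooth_surface(suppressWarnings(reconstruct_surface(sp$outer)),
                         30, 0.6)
    mi <- smooth_surface(suppressWarnings(reconstruct_surface(sp$interface)),
                         30, 0.6)
    expect_lt(interior_hausdorff(mo, nv$truth$outer_surface), 2)
    expect_lt(interior_hausdorff(mi, nv$truth$interface_surface), 2)
    ## thickness recovered
    th <- epidermis_thickness(flip_surface(mo), mi)
    keep <- mo$vertices[, 1] > 6 & mo$vertices[, 1] < 57 &
            mo$vertices[, 2] > 6 & mo$vertices[, 2] < 57
    expect_equal(mean(th[keep]), 14, tolerance = 0.08)
  }
})
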