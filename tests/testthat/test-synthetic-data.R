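test_that("voxel/world coordinate conversions round-trip", {
  v <- voxel_volume(array(0, c(8, 9, 10)), spacing = c(0.5, 0.7, 1.1),
                    origin = c(-3, 2, 5))
  idx <- rbind(c(1, 1, 1), c(8, 9, 10), c(2.25, 4.5, 7.75))
  back <- world_to_voxel(v, voxel_to_world(v, idx))
  expect_lt(max(abs(back - idx)), 1e-9)
  b <- volume_bounds(v)
  expect_equal(b[1, ], c(-3, 2, 5))
  expect_equal(b[2, ], c(-3, 2, 5) + c(7 * 0.5, 8 * 0.7, 9 * 1.1))
})

test_that("generators are deterministic under a fixed seed", {
  a <- make_nuclear_volume(c(24, 24, 24), 6, 0.08, 0.02, 0.05, seed = 11)
  b <- make_nuclear_volume(c(24, 24, 24), 6, 0.08, 0.02, 0.05, seed = 11)
  expect_identical(a$volume$values, b$volume$values)
  f1 <- make_fiber_volume(c(24, 24, 24), c(0, 1, 0), 6, seed = 5)
  f2 <- make_fiber_volume(c(24, 24, 24), c(0, 1, 0), 6, seed = 5)
  expect_identical(f1$volume$values, f2$volume$values)
  e1 <- make_edu_volume(c(48, 48, 48), 4, seed = 9, noise_sd = 0.1)
  e2 <- make_edu_volume(c(48, 48, 48), 4, seed = 9, noise_sd = 0.1)
  expect_identical(e1$volume$values, e2$volume$values)
  expect_identical(e1$truth$centroids, e2$truth$centroids)
})

test_that("nuclear volume: flat interface ground truth and degenerate contrast", {
  nv <- make_nuclear_volume(c(32, 32, 32), 8, 0.08, 0.02, 0, seed = 2)
  iz <- nv$truth$interface_surface$vertices[, 3]
  expect_lt(max(abs(iz - (nv$truth$z_outer - 8))), 1e-9)
  ## equal densities: generation still works, truth still recorded
  eq <- make_nuclear_volume(c(32, 32, 32), 8, 0.05, 0.05, 0, seed = 2)
  expect_s3_class(eq$truth$interface_surface, "surface_mesh")
  ## too-small volume rejected
  expect_error(make_nuclear_volume(c(4, 4, 4), 1, 0.1, 0.05, 0, seed = 1),
               "small")
})

test_that("fiber volume: dominant spectral axis matches the prescribed axis", {
  fv <- make_fiber_volume(c(48, 48, 48), c(1, 0, 0), wavelength = 8,
                          seed = 4)
  ## analytic grating-spectrum oracle: the strongest non-DC coefficient
  ## of the raw FFT must sit on the x frequency axis
  P <- Mod(fft(fv$volume$values))^2
  P[1, 1, 1] <- 0
  pk <- arrayInd(which.max(P), dim(P))
  expect_gt(pk[1], 1)         # off-DC along x
  expect_true(pk[2] %in% c(1, 48) || pk[2] <= 2)  # on the kx axis
  expect_true(pk[3] %in% c(1, 48) || pk[3] <= 2)
  expect_error(make_fiber_volume(c(32, 32, 32), c(1, 0, 0), wavelength = 2),
               "Nyquist")
})

test_that("EdU volume: centroids respect separation and bounds", {
  ed <- make_edu_volume(c(48, 48, 48), n_cells = 10, cell_radius = 4,
                        seed = 6, touching_pairs = 1L)
  cen <- ed$truth$centroids
  expect_equal(nrow(cen), 12)
  expect_equal(sum(ed$truth$touching), 2)
  b <- volume_bounds(ed$volume)
  expect_true(all(cen >= matrix(b[1, ], 12, 3, byrow = TRUE)))
  expect_true(all(cen <= matrix(b[2, ], 12, 3, byrow = TRUE)))
  sep <- as.matrix(dist(cen[!ed$truth$touching, ]))
  diag(sep) <- Inf
  expect_gte(min(sep), 2 * 4)
  tp <- cen[ed$truth$touching, ]
  expect_equal(sqrt(sum((tp[1, ] - tp[2, ])^2)), 1.5 * 4, tolerance = 1e-9)
  ## n_cells = 0: pure noise, empty truth
  e0 <- make_edu_volume(c(32, 32, 32), 0, noise_sd = 0.1, seed = 1)
  expect_equal(nrow(e0$truth$centroids), 0)
})

test_that("bilayer patch: labels, conformity and exact volume", {
  tm <- make_bilayer_patch(3, 2, 1.5, 2.5, 1)
  expect_s3_class(tm, "layered_tet_mesh")
  expect_false(anyNA(tm$layer))
  expect_equal(sum(tet_volumes(tm$nodes, tm$tets)),
               3 * 2 * 1 * (1.5 + 2.5), tolerance = 1e-10)
  aud <- audit_tet_mesh(tm)
  expect_true(aud$ok)
  ## minimal mesh
  tm1 <- make_bilayer_patch(1, 1, 1, 1, 1)
  expect_gte(nrow(tm1$tets), 10)
  expect_true(all(levels(tm1$layer) %in%
                  c("epidermis", "dermis", "bone")))
  ## substrate nodes fixed
  expect_true(all(tm$fixed[abs(tm$nodes[, 3]) < 1e-12]))
  expect_false(any(tm$fixed[tm$nodes[, 3] > 1e-12]))
})

test_that("jaw proxy: ridges raise the dorsal bone line, labels partition", {
  flat <- make_jaw_proxy(length = 100, radius = 40, ridge_height = 0,
                         n_axial = 8, n_circ = 12)
  ridged <- make_jaw_proxy(length = 100, radius = 40, ridge_height = 6,
                           n_axial = 8, n_circ = 12)
  expect_false(anyNA(flat$layer))
  expect_false(anyNA(ridged$layer))
  rb_flat <- sqrt(rowSums(flat$nodes[flat$fixed, 2:3]^2))
  rb_ridge <- sqrt(rowSums(ridged$nodes[ridged$fixed, 2:3]^2))
  expect_lt(diff(range(rb_flat)), 1e-9)          # smooth half-cylinder
  expect_gt(max(rb_ridge) - min(rb_ridge), 4)    # elevated dorsal lines
  expect_true(audit_tet_mesh(ridged)$ok)
})

test_that("fold-surface fixtures carry exact combinatorial ground truth", {
  for (mn in list(c(2, 2), c(3, 2))) {
    fs <- make_fold_surface("polygonal_lattice",
                            list(m = mn[1], n = mn[2], R = 8))
    net <- fs$truth$network
    ## oracle: cycle-space dimension |E| - |V| + C of the declared graph
    g <- igraph::graph_from_edgelist(net$edges, directed = FALSE)
    rank <- igraph::ecount(g) - igraph::vcount(g) +
      igraph::count_components(g)
    expect_equal(net$n_cycles, mn[1] * mn[2])
    expect_equal(rank, net$n_cycles)
  }
  sm <- make_fold_surface("smooth")
  expect_equal(nrow(sm$truth$network$segments), 0)
  expect_equal(sm$truth$network$n_cycles, 0L)
  ob <- make_fold_surface("elongated_bands",
                          list(n_bands = 1, open_end_trim = 10))
  expect_equal(ob$truth$network$n_incomplete, 1L)
  expect_error(make_fold_surface("labyrinth", list(depth = 0)), "depth")
})
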