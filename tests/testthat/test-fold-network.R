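test_that("principal curvatures match sphere, plane and cylinder", {
  ## closed sphere with inward orientation: kappa = -1/r on both axes
  sp <- sphere_mesh(r = 10, inward = TRUE)
  cur <- surface_principal_curvatures(sp, ring = 2)
  expect_lt(abs(median(cur$kmin) + 0.1) / 0.1, 0.05)
  expect_lt(abs(median(cur$kmax) + 0.1) / 0.1, 0.05)
  ## plane: both zero
  pl <- heightfield_mesh(0:12, 0:12, matrix(0, 13, 13))
  cp <- surface_principal_curvatures(pl, ring = 2)
  expect_lt(max(abs(c(cp$kmin, cp$kmax))), 1e-6)
  ## half-cylinder height field z = sqrt(r^2 - x^2) (convex, outward up):
  ## kappa = (-... ) one curvature 1/r in magnitude, the other ~0; the
  ## convex direction is positive under the groove-negative convention
  r <- 20
  gx <- seq(-12, 12, 0.75)
  gy <- seq(0, 24, 0.75)
  cz <- outer(gx, gy, function(x, y) sqrt(r^2 - x^2))
  cyl <- heightfield_mesh(gx, gy, cz)
  cc <- surface_principal_curvatures(cyl, ring = 2)
  mid <- which(abs(cyl$vertices[, 1]) < 4 & cyl$vertices[, 2] > 6 &
               cyl$vertices[, 2] < 18)
  expect_lt(abs(median(cc$kmax[mid]) - 1 / r) / (1 / r), 0.05)
  expect_lt(max(abs(median(cc$kmin[mid]))), 0.2 / r)
})

test_that("fold mask covers grooves and empties on smooth or extreme thresholds", {
  fs <- make_fold_surface("polygonal_lattice", list(m = 2, n = 2, R = 10,
                                                    spacing = 1))
  cur <- surface_principal_curvatures(fs$mesh, 2)
  thr <- 0.3 * quantile(-cur$kmin, 0.999)
  mask <- fold_mask(fs$mesh, cur, thr)
  ## recall of ground-truth groove vertices (within half groove width of
  ## a generating segment, border collar excluded)
  V <- fs$mesh$vertices
  d <- scutes:::seg_distance_field(V[, 1], V[, 2], fs$truth$network$segments)
  interior <- V[, 1] > min(V[, 1]) + 3 & V[, 1] < max(V[, 1]) - 3 &
              V[, 2] > min(V[, 2]) + 3 & V[, 2] < max(V[, 2]) - 3
  groove <- which(d < 0.5 * fs$truth$groove_width & interior)
  expect_gte(mean(groove %in% mask), 0.9)
  expect_length(fold_mask(fs$mesh, cur, Inf), 0)
  sm <- make_fold_surface("smooth")
  cs <- surface_principal_curvatures(sm$mesh, 2)
  expect_length(fold_mask(sm$mesh, cs, thr), 0)
})

test_that("skeleton reduces a straight groove to a single centered polyline", {
  fs <- make_fold_surface("elongated_bands", list(n_bands = 1, spacing = 1))
  cur <- surface_principal_curvatures(fs$mesh, 2)
  mask <- fold_mask(fs$mesh, cur, 0.3 * quantile(-cur$kmin, 0.999))
  raw <- skeletonize(fs$mesh, mask, priority = cur$kmin)
  expect_gt(length(raw$vertices), 10)
  ## all skeleton vertices within one mesh edge of the groove axis
  ax_x <- fs$truth$network$segments[1, 1]
  expect_lt(max(abs(raw$positions[, 1] - ax_x)), 1.01)
  ## empty mask -> empty graph
  e <- skeletonize(fs$mesh, integer(0))
  expect_length(e$vertices, 0)
})

test_that("junction topology: a Y groove yields one degree-3 node", {
  ## three segments meeting at a point
  segs <- rbind(c(0, 0, 0, 18), c(0, 0, 16, -9), c(0, 0, -16, -9))
  gx <- seq(-22, 22, 0.8); gy <- seq(-16, 24, 0.8)
  pg <- expand.grid(x = gx, y = gy)
  dd <- scutes:::seg_distance_field(pg$x, pg$y, segs)
  zm <- matrix(-2 * exp(-(dd / 1.6)^2), length(gx), length(gy))
  m <- heightfield_mesh(gx, gy, zm)
  net <- extract_fold_network(m)
  degs <- table(c(vapply(net$edges, `[[`, numeric(1), "from"),
                  vapply(net$edges, `[[`, numeric(1), "to")))
  expect_equal(sum(degs == 3), 1)
  expect_equal(net$n_cycles, 0L)
})

test_that("topology recovery is exact across rotation and jitter perturbations", {
  base <- make_fold_surface("polygonal_lattice",
                            list(m = 2, n = 2, R = 10, spacing = 1))
  for (ang_deg in c(-2, 2)) {
    th <- ang_deg * pi / 180
    R2 <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
    vr <- base$mesh$vertices %*% t(R2)
    mr <- surface_mesh(vr, base$mesh$triangles)
    net <- extract_fold_network(mr)
    expect_equal(net$n_cycles, 4L)
    expect_equal(net$n_incomplete, 0L)
  }
  ## 1% vertex jitter (relative to mean edge length), fixed seed
  set.seed(7)
  vj <- base$mesh$vertices +
    matrix(rnorm(length(base$mesh$vertices), 0, 0.01), ncol = 3)
  netj <- extract_fold_network(surface_mesh(vj, base$mesh$triangles))
  expect_equal(netj$n_cycles, 4L)
  expect_equal(netj$n_incomplete, 0L)
})

test_that("network metrics match hand-computed honeycomb geometry", {
  fs <- make_fold_surface("polygonal_lattice",
                          list(m = 3, n = 3, R = 10, spacing = 1))
  net <- extract_fold_network(fs$mesh)
  v <- network_metrics(net)
  D <- attr(v, "diag")
  ## closed-form honeycomb geometry for 3 x 3 cells of circumradius 10:
  ## 38 lattice edges of length 10; 16 degree-3 junctions, so the
  ## simplified junction graph has 16 * 3 / 2 = 24 polyline edges of
  ## total length 380; every hexagonal domain has perimeter 60
  expect_equal(length(net$edges), 24)
  expect_equal(unname(v["domain_perimeter"]) * D, 60, tolerance = 0.1)
  expect_equal(unname(v["edge_length"]) * D, 380 / 24, tolerance = 0.12)
  ## chained boundary paths turn by 60 degrees at suppressed lattice
  ## vertices: mean turning per unit length stays below (pi/3) / 10
  expect_lt(unname(v["edge_curvature"]) / D, (pi / 3) / 10)
  expect_equal(unname(v["incomplete_length"]), 0)
  ## domain count component: 9 cycles / (area / D^2)
  expect_equal(unname(v["n_domains"]), 9 / (attr(v, "area") / D^2),
               tolerance = 1e-12)
  ## perfectly straight parallel bands: near-zero mean turning
  bs <- make_fold_surface("elongated_bands", list(n_bands = 3, spacing = 1))
  vb <- network_metrics(extract_fold_network(bs$mesh))
  expect_lt(unname(vb["edge_curvature"]) / attr(vb, "diag"), 0.01)
})

test_that("diagonal-normalized metrics are scale invariant", {
  fs <- make_fold_surface("polygonal_lattice",
                          list(m = 2, n = 2, R = 10, spacing = 1))
  net1 <- extract_fold_network(fs$mesh)
  v1 <- network_metrics(net1)
  s <- 3.7
  ms <- surface_mesh(fs$mesh$vertices * s, fs$mesh$triangles)
  net2 <- extract_fold_network(ms)
  v2 <- network_metrics(net2)
  expect_equal(net2$n_cycles, net1$n_cycles)
  expect_lt(max(abs(as.numeric(v1) - as.numeric(v2))), 1e-6)
})

test_that("cohort normalization z-scores exactly and flags zero variance", {
  set.seed(3)
  cohort <- lapply(1:6, function(i) {
    v <- structure(rnorm(5, mean = c(10, 2, 1, 0.5, 0.1)),
                   names = c("n_domains", "domain_perimeter", "edge_length",
                             "edge_curvature", "incomplete_length"),
                   class = "metrics_vector")
    v
  })
  M <- do.call(rbind, lapply(cohort, as.numeric))
  zs <- t(apply(M, 1, function(r) cohort_normalize(
    structure(r, names = colnames(M), class = "metrics_vector"), cohort)))
  expect_lt(max(abs(colMeans(zs))), 1e-10)
  expect_lt(max(abs(apply(zs, 2, sd) - 1)), 1e-10)
  ## mean vector maps to zero
  vm <- structure(colMeans(M), names = names(cohort[[1]]),
                  class = "metrics_vector")
  expect_lt(max(abs(cohort_normalize(vm, cohort))), 1e-10)
  ## zero-variance component errors with its name
  const <- lapply(cohort, function(v) { v[2] <- 5; v })
  expect_error(cohort_normalize(const[[1]], const), "domain_perimeter")
})

test_that("metrics distance is a metric on random triples", {
  set.seed(4)
  for (i in 1:20) {
    a <- rnorm(5); b <- rnorm(5); c <- rnorm(5)
    expect_equal(metrics_distance(a, a), 0)
    expect_equal(metrics_distance(a, b), metrics_distance(b, a))
    expect_lte(metrics_distance(a, c),
               metrics_distance(a, b) + metrics_distance(b, c) + 1e-12)
  }
})

test_that("polygonal and labyrinth fixtures are separated by cohort deviations", {
  mk <- function(pattern, seedjit) {
    fs <- make_fold_surface(pattern, list(m = 2, n = 2, R = 10, spacing = 1,
                                          jitter = 0.02), seed = seedjit)
    network_metrics(extract_fold_network(fs$mesh))
  }
  ## cohort = jittered polygonal replicates (the interindividual spread);
  ## a labyrinth must sit >= 3 cohort sds away in the cycle component
  poly <- lapply(1:4, function(s) mk("polygonal_lattice", s))
  laby <- mk("labyrinth", 1)
  cyc <- vapply(poly, function(v) unname(v["n_domains"]), numeric(1))
  z <- (unname(laby["n_domains"]) - mean(cyc)) / sd(cyc)
  expect_gte(abs(z), 3)
})
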