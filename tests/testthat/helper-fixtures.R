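## shared fixtures built in code

## closed axis-aligned box surface mesh with outward normals
box_mesh <- function(lo, hi) {
  v <- as.matrix(expand.grid(c(lo[1], hi[1]), c(lo[2], hi[2]),
                             c(lo[3], hi[3])))
  f <- rbind(c(1, 3, 2), c(2, 3, 4), c(5, 6, 7), c(6, 8, 7),
             c(1, 2, 5), c(2, 6, 5), c(3, 7, 4), c(4, 7, 8),
             c(1, 5, 3), c(3, 5, 7), c(2, 4, 6), c(4, 8, 6))
  surface_mesh(v, f)
}

## icosphere-ish random sphere cloud with outward normals
sphere_cloud <- function(n = 2000, r = 10, seed = 1) {
  set.seed(seed)
  d <- matrix(rnorm(3 * n), ncol = 3)
  d <- d / sqrt(rowSums(d^2))
  oriented_point_cloud(d * r, d)
}

## UV sphere mesh; `inward = TRUE` orients normals into the ball
sphere_mesh <- function(r = 10, n_theta = 24, n_phi = 48, inward = FALSE) {
  th <- seq(0, pi, length.out = n_theta)[-c(1, n_theta)]
  ph <- seq(0, 2 * pi, length.out = n_phi + 1)[-(n_phi + 1)]
  g <- expand.grid(th = th, ph = ph)
  v <- cbind(r * sin(g$th) * cos(g$ph), r * sin(g$th) * sin(g$ph),
             r * cos(g$th))
  v <- rbind(v, c(0, 0, r), c(0, 0, -r))
  np <- length(th)
  idx <- function(i, j) (j - 1) * np + i    # i: theta row, j: phi col
  tris <- NULL
  for (j in seq_len(n_phi)) {
    j2 <- j %% n_phi + 1
    for (i in seq_len(np - 1)) {
      tris <- rbind(tris,
                    c(idx(i, j), idx(i + 1, j), idx(i + 1, j2)),
                    c(idx(i, j), idx(i + 1, j2), idx(i, j2)))
    }
    tris <- rbind(tris,
                  c(nrow(v) - 1, idx(1, j), idx(1, j2)),
                  c(nrow(v), idx(np, j2), idx(np, j)))
  }
  if (inward) tris <- tris[, c(1, 3, 2)]
  surface_mesh(v, tris)
}

## nuclear-volume pipeline defaults used across tissue-geometry tests
nuclear_fixture <- function(noise_sd = 0, seed = 3) {
  make_nuclear_volume(c(64, 64, 64), epi_thickness = 14,
                      density_epi = 0.12, density_derm = 0.03,
                      noise_sd = noise_sd, seed = seed)
}

canny_on_fixture <- function(nv, sigma = 5, hq = 0.96) {
  g <- scutes:::gaussian_derivatives(nv$volume$values, nv$volume$spacing,
                                     sigma, list(c(1, 0, 0), c(0, 1, 0),
                                                 c(0, 0, 1)))
  mag <- sqrt(g[[1]]^2 + g[[2]]^2 + g[[3]]^2)
  hi <- stats::quantile(mag, hq)
  detect_edges_3d(nv$volume, sigma = sigma, low = hi / 2, high = hi)
}

## symmetric interior Hausdorff distance between a mesh and a truth mesh,
## excluding a lateral border strip where the volume truncates support
interior_hausdorff <- function(m, truth, border = 6, size = 63) {
  tv <- truth$vertices
  ti <- tv[, 1] > border & tv[, 1] < size - border &
        tv[, 2] > border & tv[, 2] < size - border
  d1 <- scutes:::cpp_point_mesh_distance(tv[ti, , drop = FALSE],
                                         m$vertices, m$triangles)
  mv <- m$vertices
  mi <- mv[, 1] > border & mv[, 1] < size - border &
        mv[, 2] > border & mv[, 2] < size - border
  d2 <- if (any(mi))
    scutes:::cpp_point_mesh_distance(mv[mi, , drop = FALSE], tv,
                                     truth$triangles) else 0
  max(max(d1), max(d2))
}

## greedy 1-1 matching of detected centroids to truth; returns counts
match_centroids <- function(detected, truth, tol = 2) {
  if (nrow(detected) == 0)
    return(list(tp = 0, fp = 0, fn = nrow(truth), max_err = NA_real_))
  used <- logical(nrow(detected))
  tp <- 0; errs <- numeric(0)
  for (i in seq_len(nrow(truth))) {
    d <- sqrt(rowSums(sweep(detected, 2, truth[i, ])^2))
    d[used] <- Inf
    j <- which.min(d)
    if (is.finite(d[j]) && d[j] <= tol) {
      used[j] <- TRUE; tp <- tp + 1; errs <- c(errs, d[j])
    }
  }
  list(tp = tp, fp = sum(!used), fn = nrow(truth) - tp,
       max_err = if (length(errs)) max(errs) else NA_real_)
}

## small flat-patch simulation fixture shared by slower tests
small_patch <- function(nx = 16, ny = 16) make_bilayer_patch(nx, ny, 1, 3, 1)

## angle between sign-free axes in degrees
axis_angle_deg <- function(a, b) scutes:::axis_angle(a, b)

unit3 <- function(v) v / sqrt(sum(v^2))

with_seed_local <- function(seed, code) scutes:::with_seed(seed, code)
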