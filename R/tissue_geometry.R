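#' Oriented point cloud
#'
#' Edge points with unit normals, the intermediate between voxel data and
#' reconstructed boundary surfaces.
#' @param points n x 3 matrix, world um.
#' @param normals n x 3 matrix of unit vectors.
#' @export
oriented_point_cloud <- function(points, normals) {
  points <- as.matrix(points); normals <- as.matrix(normals)
  stopifnot(ncol(points) == 3L, all(dim(points) == dim(normals)))
  if (nrow(normals) > 0) {
    nn <- sqrt(rowSums(normals^2))
    if (any(abs(nn - 1) > 1e-6)) stop("normals must be unit length")
  }
  structure(list(points = points, normals = normals),
            class = "oriented_point_cloud")
}

#' @export
print.oriented_point_cloud <- function(x, ...) {
  cat(sprintf("<oriented_point_cloud> %d points\n", nrow(x$points)))
  invisible(x)
}

#' 3D Canny edge detection with oriented output
#'
#' Gaussian-smooths the volume at `sigma`, computes the spectral intensity
#' gradient, applies non-maximum suppression along the gradient direction
#' and 26-connected hysteresis linking, and returns the surviving voxels
#' as an oriented point cloud. Normals are the normalized smoothed
#' intensity gradient (pointing towards increasing intensity).
#'
#' @param v a [voxel_volume].
#' @param sigma smoothing scale (um).
#' @param low,high hysteresis thresholds on gradient magnitude
#'   (intensity / um); `high > low > 0`.
#' @return an [oriented_point_cloud] (possibly empty).
#' @export
detect_edges_3d <- function(v, sigma, low, high) {
  stopifnot(high > low, low > 0)
  g <- gaussian_derivatives(v$values, v$spacing, sigma,
                            list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)))
  mag <- sqrt(g[[1]]^2 + g[[2]]^2 + g[[3]]^2)
  cand <- which(mag >= low)
  if (length(cand) == 0)
    return(oriented_point_cloud(matrix(0, 0, 3), matrix(0, 0, 3)))
  d <- dim(v$values)
  idx <- arrayInd(cand, d)
  gv <- cbind(g[[1]][cand], g[[2]][cand], g[[3]][cand])
  ## step of one voxel along the gradient, in index units
  dirv <- gv / pmax(sqrt(rowSums(gv^2)), 1e-300)
  step <- sweep(dirv, 2, v$spacing, `/`)
  step <- step / pmax(sqrt(rowSums(step^2)), 1e-300)
  m0 <- mag[cand]
  keep <- m0 >= trilinear(mag, idx + step) & m0 >= trilinear(mag, idx - step)
  nms <- array(FALSE, d); nms[cand[keep]] <- TRUE
  ## hysteresis: weak components that touch a strong voxel survive
  labs <- cpp_label_components_3d(as.vector(nms), as.integer(d))
  strong_labs <- unique(labs[nms & mag >= high])
  final <- array(labs %in% setdiff(strong_labs, 0L), d) & nms
  sel <- cand[keep][final[cand[keep]]]
  if (length(sel) == 0)
    return(oriented_point_cloud(matrix(0, 0, 3), matrix(0, 0, 3)))
  ## sub-voxel localization: parabolic fit of the gradient magnitude
  ## along the gradient direction
  idx_s <- arrayInd(sel, d)
  pick <- match(sel, cand)
  us <- step[pick, , drop = FALSE]
  m0 <- mag[sel]
  mp <- trilinear(mag, idx_s + us)
  mm <- trilinear(mag, idx_s - us)
  denom <- mm - 2 * m0 + mp
  delta <- ifelse(abs(denom) > 1e-12, 0.5 * (mm - mp) / denom, 0)
  delta <- pmin(0.6, pmax(-0.6, delta))
  pts <- voxel_to_world(v, idx_s + us * delta)
  nrm <- cbind(g[[1]][sel], g[[2]][sel], g[[3]][sel])
  nrm <- nrm / sqrt(rowSums(nrm^2))
  oriented_point_cloud(pts, nrm)
}

#' Surface reconstruction from an oriented point cloud
#'
#' Implicit reconstruction: the cloud's local tangent planes define a
#' signed distance field (Gaussian-weighted over the k nearest points)
#' sampled on a regular grid and isosurfaced with marching tetrahedra.
#' Triangles farther than `support` from any cloud point are discarded so
#' the mesh does not extrapolate past the data.
#'
#' @param cloud an [oriented_point_cloud] with at least 4 non-coplanar
#'   points.
#' @param resolution grid cell size (um); default: bounding-box diagonal
#'   / 60.
#' @param k number of neighbours defining the local plane blend.
#' @param support crop distance (um); default `3 * resolution`.
#' @param pad grid padding (um); default `4 * resolution`.
#' @return a [surface_mesh] oriented with normals along the cloud normals.
#' @export
reconstruct_surface <- function(cloud, resolution = NULL, k = 10,
                                support = NULL, pad = NULL) {
  pts <- cloud$points
  if (nrow(pts) < 4) stop("need at least 4 points for reconstruction")
  if (qr(sweep(pts, 2, colMeans(pts)))$rank < 2)
    stop("points are collinear; cannot reconstruct a surface")
  ## warn on heavily inconsistent orientation: compare each normal with
  ## the average normal of its spatial neighbourhood
  nbar <- colMeans(cloud$normals)
  if (sqrt(sum(nbar^2)) > 1e-9) {
    flip_frac <- mean((cloud$normals %*% unit(nbar)) < 0)
    if (flip_frac > 0.4 && flip_frac < 0.6)
      warning("normal orientation looks inconsistent; proceeding")
  }
  bb <- apply(pts, 2, range)
  diag_len <- sqrt(sum((bb[2, ] - bb[1, ])^2))
  if (is.null(resolution)) resolution <- diag_len / 60
  if (is.null(pad)) pad <- 4 * resolution
  if (is.null(support)) support <- 3 * resolution
  gx <- seq(bb[1, 1] - pad, bb[2, 1] + pad, by = resolution)
  gy <- seq(bb[1, 2] - pad, bb[2, 2] + pad, by = resolution)
  gz <- seq(bb[1, 3] - pad, bb[2, 3] + pad, by = resolution)
  gp <- as.matrix(expand.grid(gx, gy, gz))
  f <- cpp_oriented_cloud_sdf(gp, pts, cloud$normals, as.integer(k),
                              max(resolution, diag_len / 40))
  fa <- array(f, c(length(gx), length(gy), length(gz)))
  mt <- cpp_marching_tets(fa, c(gx[1], gy[1], gz[1]),
                          rep(resolution, 3), 0)
  if (nrow(mt$vertices) == 0) stop("empty isosurface")
  m <- surface_mesh(mt$vertices, mt$triangles)
  cen <- (m$vertices[m$triangles[, 1], ] + m$vertices[m$triangles[, 2], ] +
          m$vertices[m$triangles[, 3], ]) / 3
  dnn <- cpp_nn_distance(cen, pts, max(resolution, diag_len / 40))
  m2 <- drop_triangles(m, which(dnn > support))
  if (nrow(m2$triangles) == 0) m else m2
}

drop_triangles <- function(m, drop_idx) {
  if (length(drop_idx) == 0) return(m)
  tr <- m$triangles[-drop_idx, , drop = FALSE]
  used <- sort(unique(as.vector(tr)))
  remap <- integer(nrow(m$vertices)); remap[used] <- seq_along(used)
  surface_mesh(m$vertices[used, , drop = FALSE],
               matrix(remap[tr], ncol = 3))
}

#' Laplacian smoothing of a surface mesh
#'
#' Uniform-weight Laplacian smoothing: each interior vertex moves a
#' fraction `step` towards the mean of its 1-ring. Vertex count and
#' topology are preserved. Boundary vertices of open meshes stay fixed
#' unless `fix_boundary = FALSE`. Repeated smoothing of a closed surface
#' shrinks it (the well-known uniform-Laplacian volume loss).
#'
#' @param m a [surface_mesh].
#' @param n_iter number of iterations (0 = identity).
#' @param step relaxation factor in (0, 1].
#' @param fix_boundary keep boundary vertices in place.
#' @return the smoothed [surface_mesh].
#' @export
smooth_surface <- function(m, n_iter = 10, step = 0.5, fix_boundary = TRUE) {
  if (n_iter == 0) return(m)
  e <- mesh_edges(m)
  n <- nrow(m$vertices)
  A <- Matrix::sparseMatrix(i = c(e[, 1], e[, 2]), j = c(e[, 2], e[, 1]),
                            x = 1, dims = c(n, n))
  deg <- Matrix::rowSums(A)
  mob <- deg > 0
  if (fix_boundary) mob[boundary_vertices(m)] <- FALSE
  V <- m$vertices
  for (it in seq_len(n_iter)) {
    mean_nb <- as.matrix(A %*% V) / pmax(deg, 1)
    V[mob, ] <- V[mob, ] + step * (mean_nb[mob, ] - V[mob, ])
  }
  surface_mesh(V, m$triangles, normals = NULL)
}

#' Epidermis thickness field
#'
#' For each vertex of the outer surface, casts a ray along the inward
#' normal to the epidermis-dermis interface; where the ray misses or hits
#' at a grazing angle (interface normal deviating more than
#' `guard_angle_deg` from the ray), falls back to the nearest-point
#' distance.
#'
#' @param outer,interface [surface_mesh] objects; outer normals must point
#'   away from the tissue.
#' @param guard_angle_deg normal-deviation guard (degrees).
#' @return numeric vector of thicknesses (um), one per outer vertex.
#' @export
epidermis_thickness <- function(outer, interface, guard_angle_deg = 30) {
  n_out <- outer$normals %||% vertex_normals(outer)
  dirs <- -n_out  # inward
  hit <- cpp_ray_mesh_intersect(outer$vertices, dirs,
                                interface$vertices, interface$triangles)
  th <- hit$distance
  tn <- triangle_normals(interface)
  ok <- is.finite(th) & hit$triangle > 0
  if (any(ok)) {
    cosang <- abs(rowSums(dirs[ok, , drop = FALSE] *
                          tn[hit$triangle[ok], , drop = FALSE]))
    ok[ok] <- cosang >= cos(guard_angle_deg * pi / 180)
  }
  if (any(!ok)) {
    th[!ok] <- cpp_point_mesh_distance(outer$vertices[!ok, , drop = FALSE],
                                       interface$vertices,
                                       interface$triangles)
  }
  pmax(th, 0)
}

#' Layered tetrahedralization of nested boundary surfaces
#'
#' Fills the region inside `outer` with a structured background grid of
#' conforming tetrahedra and labels each tet by the innermost shell
#' containing its centroid: inside `bone` = bone, else inside `interface`
#' = dermis, else epidermis. Bone-region nodes are flagged fixed. Open
#' height-field surfaces are interpreted as "below the sheet = inside".
#'
#' @param outer,interface,bone [surface_mesh] objects, mutually
#'   non-intersecting and nested (outer contains interface contains bone).
#' @param n target number of grid cells along the longest axis.
#' @return a [layered_tet_mesh].
#' @export
tetrahedralize <- function(outer, interface, bone, n = 30) {
  for (pair in list(list(outer, interface, "outer/interface"),
                    list(interface, bone, "interface/bone"),
                    list(outer, bone, "outer/bone"))) {
    nv <- nrow(pair[[1]]$vertices)
    comb <- surface_mesh(rbind(pair[[1]]$vertices, pair[[2]]$vertices),
                         rbind(pair[[1]]$triangles, pair[[2]]$triangles + nv))
    ni <- cpp_self_intersections(comb$vertices, comb$vertices,
                                 comb$triangles, 0,
                                 max(apply(apply(comb$vertices, 2, range), 2,
                                           diff)) / 10)
    if (ni > 0)
      stop(sprintf("input surfaces intersect (%s): %d triangle pairs",
                   pair[[3]], ni))
  }
  bb <- apply(rbind(outer$vertices, interface$vertices, bone$vertices),
              2, range)
  h <- max(bb[2, ] - bb[1, ]) / n
  dims <- pmax(2L, as.integer(ceiling((bb[2, ] - bb[1, ]) / h)) + 1L)
  g <- structured_tet_grid(dims[1], dims[2], dims[3],
    pos = function(i, j, k) cbind(bb[1, 1] + (i - 1) * h,
                                  bb[1, 2] + (j - 1) * h,
                                  bb[1, 3] + (k - 1) * h))
  cen <- (g$nodes[g$tets[, 1], ] + g$nodes[g$tets[, 2], ] +
          g$nodes[g$tets[, 3], ] + g$nodes[g$tets[, 4], ]) / 4
  eps <- 1e-7 * h
  cen_q <- cen; cen_q[, 3] <- cen_q[, 3] - eps  # containment bias
  in_outer <- cpp_points_in_mesh(cen_q, outer$vertices, outer$triangles)
  in_inter <- cpp_points_in_mesh(cen_q, interface$vertices,
                                 interface$triangles)
  in_bone <- cpp_points_in_mesh(cen_q, bone$vertices, bone$triangles)
  keep <- in_outer
  if (!any(keep)) stop("no tetrahedra inside the outer surface")
  layer <- ifelse(in_bone[keep], "bone",
                  ifelse(in_inter[keep], "dermis", "epidermis"))
  tets <- g$tets[keep, , drop = FALSE]
  used <- sort(unique(as.vector(tets)))
  remap <- integer(nrow(g$nodes)); remap[used] <- seq_along(used)
  nodes <- g$nodes[used, , drop = FALSE]
  tets <- matrix(remap[tets], ncol = 4)
  fixed <- logical(nrow(nodes))
  fixed[unique(as.vector(tets[layer == "bone", ]))] <- TRUE
  layered_tet_mesh(nodes, tets, layer, fixed)
}

#' Largest connected component of a point cloud
#'
#' Points are binned to a voxel grid at `radius` spacing; 26-connected
#' occupied cells define components, and only points of the largest one
#' are kept. Removes small stray sheets before reconstruction.
#'
#' @param cloud an [oriented_point_cloud].
#' @param radius linking radius (um).
#' @return the filtered [oriented_point_cloud].
#' @export
largest_cloud_component <- function(cloud, radius = 2) {
  p <- cloud$points
  if (nrow(p) == 0) return(cloud)
  lo <- apply(p, 2, min)
  ci <- sweep(sweep(p, 2, lo), 2, rep(radius, 3), `/`)
  ci <- matrix(as.integer(floor(ci)) + 1L, ncol = 3)
  d <- apply(ci, 2, max)
  occ <- array(FALSE, d)
  occ[ci] <- TRUE
  labs <- cpp_label_components_3d(as.vector(occ), as.integer(d))
  pl <- labs[ci]
  big <- as.integer(names(which.max(table(pl))))
  oriented_point_cloud(p[pl == big, , drop = FALSE],
                       cloud$normals[pl == big, , drop = FALSE])
}

#' Split a two-boundary edge cloud into outer surface and interface
#'
#' Classifies each edge point by probing the smoothed intensity on the
#' low-intensity side of its normal: points with near-background
#' intensity there belong to the outer (tissue/background) surface, the
#' rest to the epidermis-dermis interface. Each cloud is then reduced to
#' its largest connected component.
#'
#' @param v the [voxel_volume] the cloud came from.
#' @param cloud an [oriented_point_cloud] from [detect_edges_3d].
#' @param sigma probing smoothing scale (um); use the detection sigma.
#' @param background_q intensity quantile separating background.
#' @return list with `outer` and `interface` clouds.
#' @export
split_boundary_clouds <- function(v, cloud, sigma, background_q = 0.15) {
  sm <- gaussian_derivatives(v$values, v$spacing, sigma)[[1]]
  ## probe on the side the normal points away from (lower intensity)
  probe <- cloud$points - cloud$normals * (3 * sigma)
  pidx <- world_to_voxel(v, probe)
  d <- dim(v$values)
  pidx <- pmin(pmax(pidx, 1), matrix(d, nrow(pidx), 3, byrow = TRUE))
  val <- trilinear(sm, pidx)
  ## background level from the dimmest decile; any probe below
  ## background + a modest fraction of the dynamic range is outside
  dim10 <- sm[sm < stats::quantile(sm, 0.10)]
  bg <- stats::median(dim10)
  thr <- bg + background_q * (stats::quantile(sm, 0.98) - bg)
  is_outer <- val < thr
  mk <- function(sel) largest_cloud_component(
    oriented_point_cloud(cloud$points[sel, , drop = FALSE],
                         cloud$normals[sel, , drop = FALSE]))
  list(outer = mk(is_outer), interface = mk(!is_outer))
}
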