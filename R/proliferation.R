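#' Signal principal curvatures of a volume
#'
#' Gaussian-smooths the intensity at scale `sigma` and computes, per
#' voxel, the eigenvalues of the negated intensity Hessian sorted
#' descending (`k1 >= k2 >= k3`). Bright blob-like voxels give three
#' positive curvatures; a bright straight tube gives one near-zero value
#' along its axis.
#'
#' @param v a [voxel_volume].
#' @param sigma smoothing scale (um).
#' @return object of class `curvature_volumes` with arrays `k1`, `k2`,
#'   `k3`, plus `sigma` and `spacing`.
#' @export
signal_principal_curvatures <- function(v, sigma) {
  H <- gaussian_derivatives(v$values, v$spacing, sigma,
                            list(c(2, 0, 0), c(0, 2, 0), c(0, 0, 2),
                                 c(1, 1, 0), c(1, 0, 1), c(0, 1, 1)))
  n <- length(v$values)
  ## closed-form eigenvalues of the symmetric 3x3 field (Smith's method),
  ## vectorized over voxels; negated Hessian = bright-blob-positive
  a11 <- -H[[1]]; a22 <- -H[[2]]; a33 <- -H[[3]]
  a12 <- -H[[4]]; a13 <- -H[[5]]; a23 <- -H[[6]]
  q <- (a11 + a22 + a33) / 3
  p2 <- (a11 - q)^2 + (a22 - q)^2 + (a33 - q)^2 +
        2 * (a12^2 + a13^2 + a23^2)
  p <- sqrt(pmax(p2 / 6, 0))
  b11 <- a11 - q; b22 <- a22 - q; b33 <- a33 - q
  detB <- b11 * (b22 * b33 - a23^2) - a12 * (a12 * b33 - a23 * a13) +
          a13 * (a12 * a23 - b22 * a13)
  r <- ifelse(p > 0, detB / (2 * p^3), 0)
  r <- pmin(1, pmax(-1, r))
  phi <- acos(r) / 3
  e1 <- q + 2 * p * cos(phi)
  e3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  e2 <- 3 * q - e1 - e3
  d <- dim(v$values)
  structure(list(k1 = array(e1, d), k2 = array(e2, d), k3 = array(e3, d),
                 sigma = sigma, spacing = v$spacing),
            class = "curvature_volumes")
}

#' @export
print.curvature_volumes <- function(x, ...) {
  cat(sprintf("<curvature_volumes> %s voxels, sigma = %g um\n",
              paste(dim(x$k1), collapse = " x "), x$sigma))
  invisible(x)
}

#' Clamped geometric mean of the signal principal curvatures
#'
#' `k_s = (k1+ k2+ k3+)^(1/3)` with `ki+ = max(ki, 0)`: positive only
#' where all three curvatures are positive (blob-like signal).
#'
#' @param c a `curvature_volumes` object, or a list/vector triple
#'   `(k1, k2, k3)`.
#' @return 3D array (or scalar for scalar input) of `k_s` values.
#' @export
compute_ks <- function(c) {
  if (inherits(c, "curvature_volumes")) {
    k1 <- c$k1; k2 <- c$k2; k3 <- c$k3
  } else {
    k1 <- c[[1]]; k2 <- c[[2]]; k3 <- c[[3]]
  }
  (pmax(k1, 0) * pmax(k2, 0) * pmax(k3, 0))^(1 / 3)
}

#' Detect cell centroids from a k_s volume
#'
#' Thresholds `k_s`, labels 26-connected components, discards components
#' below `min_voxels`, and returns one intensity-weighted centroid per
#' component (world um).
#'
#' @param ks 3D `k_s` array (see [compute_ks]).
#' @param k_threshold detection threshold; `NULL` = Otsu's threshold on
#'   the positive `k_s` values.
#' @param v the originating [voxel_volume] (for world coordinates);
#'   `NULL` assumes unit spacing, zero origin.
#' @param min_voxels minimum component size.
#' @return n x 3 matrix of centroids (um); the chosen threshold is
#'   attached as attribute `k_threshold`.
#' @export
detect_cells <- function(ks, k_threshold = NULL, v = NULL, min_voxels = 8L) {
  if (is.null(k_threshold)) k_threshold <- otsu_threshold(ks[ks > 0])
  mask <- ks > k_threshold
  d <- dim(ks)
  if (!any(mask))
    return(structure(matrix(0, 0, 3), k_threshold = k_threshold))
  labs <- cpp_label_components_3d(as.vector(mask), as.integer(d))
  tab <- tabulate(labs[labs > 0])
  keep <- which(tab >= min_voxels)
  if (length(keep) == 0)
    return(structure(matrix(0, 0, 3), k_threshold = k_threshold))
  vox <- which(labs > 0 & array(labs %in% keep, d))
  ii <- arrayInd(vox, d)
  w <- ks[vox]
  lb <- labs[vox]
  cen <- vapply(1:3, function(c)
    rowsum(ii[, c] * w, lb)[, 1] / rowsum(w, lb)[, 1], numeric(length(keep)))
  cen <- matrix(cen, ncol = 3)
  if (!is.null(v)) cen <- voxel_to_world(v, cen)
  structure(cen, k_threshold = k_threshold)
}

## Otsu's threshold on a numeric sample (256-bin histogram)
otsu_threshold <- function(x, nbins = 256L) {
  if (length(x) == 0) return(Inf)
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  h <- tabulate(pmin(nbins, 1L + floor((x - rng[1]) / diff(rng) * nbins)),
                nbins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- rng[1] + (seq_len(nbins) - 0.5) / nbins * diff(rng)
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  sb <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb[!is.finite(sb)] <- 0
  mids[which.max(sb)]
}

#' Clipped-box cell densities at sampling points
#'
#' Around each sampling point, counts detected centroids inside an
#' axis-aligned box of `box_voxels^3` voxels clipped by the layer mask,
#' and divides by the clipped volume.
#'
#' @param centroids n x 3 matrix of cell centroids (um).
#' @param layer_mask logical 3D array: which voxels belong to the layer.
#' @param sampling_points m x 3 matrix of points (um), inside the layer.
#' @param v the [voxel_volume] defining the voxel grid.
#' @param box_voxels box edge in voxels.
#' @return list of density samples: `position`, `value` (cells / um^3),
#'   `count`, `clipped_volume` (um^3).
#' @export
cell_density <- function(centroids, layer_mask, sampling_points, v,
                         box_voxels = 80L) {
  sampling_points <- rbind(sampling_points)
  d <- dim(layer_mask)
  vxv <- prod(v$spacing)
  half <- box_voxels / 2
  lapply(seq_len(nrow(sampling_points)), function(s) {
    p <- sampling_points[s, ]
    ci <- world_to_voxel(v, rbind(p))[1, ]
    lo <- pmax(1L, as.integer(ceiling(ci - half)))
    hi <- pmin(d, as.integer(floor(ci + half - 1)))
    if (any(lo > hi)) stop("sampling point outside the volume")
    sub <- layer_mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
    clip_vol <- sum(sub) * vxv
    cnt <- 0L
    if (nrow(centroids) > 0) {
      ## assign each centroid to its nearest voxel so that disjoint boxes
      ## tile space without gaps or double counting
      cvox <- pmin(pmax(round(world_to_voxel(v, centroids)), 1),
                   matrix(d, nrow(centroids), 3, byrow = TRUE))
      inbox <- cvox[, 1] >= lo[1] & cvox[, 1] <= hi[1] &
               cvox[, 2] >= lo[2] & cvox[, 2] <= hi[2] &
               cvox[, 3] >= lo[3] & cvox[, 3] <= hi[3]
      if (any(inbox))
        cnt <- sum(layer_mask[cvox[inbox, , drop = FALSE]])
    }
    list(position = p, value = if (clip_vol > 0) cnt / clip_vol else 0,
         count = as.integer(cnt), clipped_volume = clip_vol,
         box_voxels = as.integer(box_voxels))
  })
}

#' Relative growth-modulation field from proliferation densities
#'
#' Interpolates density samples onto the mesh by spectral least squares
#' ([interpolate_field]) and normalizes to mean 1 over the mesh, giving
#' the dimensionless spatial modulation of tissue growth.
#'
#' @param samples density samples from [cell_density] (or any list of
#'   `position`/`value` pairs).
#' @param mesh a [surface_mesh] or [layered_tet_mesh].
#' @param n_modes number of spectral modes.
#' @return a scalar `field_on_mesh` with mean exactly 1.
#' @export
growth_from_density <- function(samples, mesh, n_modes = 6L) {
  if (length(samples) == 0) stop("no density samples supplied")
  f <- interpolate_field(samples, mesh, n_modes)
  mu <- mean(f$values)
  if (abs(mu) < 1e-12)
    stop("density field has zero mean; cannot normalize")
  f$values <- f$values / mu
  f
}
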