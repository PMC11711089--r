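#' Dominant texture axes of cubic volume patches by 3D FFT
#'
#' For each sampling centre, a cubic patch is Hann-windowed and Fourier
#' transformed; spectral power is folded by Hermitian symmetry onto a
#' half-spectrum, a DC-centred exclusion ball removed, and up to two
#' dominant peak directions extracted with angular non-maximum
#' suppression. The returned (sign-free) axis of a peak is the direction
#' of its spatial-frequency vector: for a stripe/grating texture this is
#' the stripe normal, which is the convention the synthetic generator
#' ([make_fiber_volume]) uses for its prescribed axis field.
#'
#' @param v a [voxel_volume].
#' @param centers n x 3 matrix of world positions (um).
#' @param patch cubic patch edge in voxels (>= 8).
#' @param max_axes maximum number of axes per patch (1 or 2).
#' @param dominance_factor a peak must exceed this multiple of the median
#'   non-DC spectral power.
#' @param exclusion_deg angular exclusion cone between first and second
#'   peak (degrees).
#' @param dc_exclude radius (in frequency bins) of the DC exclusion ball.
#' @return list of axis samples; each has `position`, `axes` (0-2 x 3
#'   matrix of unit sign-free axes) and `dominance` (power fractions).
#' @export
patch_dominant_axes <- function(v, centers, patch = 50L, max_axes = 2L,
                                dominance_factor = 3, exclusion_deg = 15,
                                dc_exclude = 2) {
  patch <- as.integer(patch)
  stopifnot(patch >= 8L)
  centers <- rbind(centers)
  d <- dim(v$values)
  hw <- 0.5 * (1 - cos(2 * pi * (0:(patch - 1)) / (patch - 1)))  # Hann
  W <- hw %o% hw %o% hw
  kax <- lapply(1:3, function(a) freq_axis(patch, v$spacing[a]))
  kx <- array(rep(kax[[1]], times = patch^2), rep(patch, 3))
  ky <- array(rep(rep(kax[[2]], each = patch), times = patch), rep(patch, 3))
  kz <- array(rep(kax[[3]], each = patch^2), rep(patch, 3))
  km <- sqrt(kx^2 + ky^2 + kz^2)
  bin_r <- km * patch * v$spacing[1]   # radius in bins (isotropic spacing)
  ## half-spectrum mask (kx > 0, plus the kx = 0 half-plane) excl. DC ball
  half <- (kx > 1e-12) | (abs(kx) <= 1e-12 & ky > 1e-12) |
          (abs(kx) <= 1e-12 & abs(ky) <= 1e-12 & kz > 1e-12)
  usable <- half & bin_r > dc_exclude
  n_us <- sum(usable)
  lapply(seq_len(nrow(centers)), function(s) {
    ci <- round(world_to_voxel(v, centers[s, , drop = FALSE]))
    lo <- as.integer(ci - patch %/% 2); hi <- lo + patch - 1L
    if (any(lo < 1L) || any(hi > d))
      stop("patch does not fit inside the volume")
    cube <- v$values[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] * W
    P <- Mod(fft(cube))^2
    pmed <- median(P[usable])
    ## white-noise floor: the expected maximum of n exponential-like
    ## spectral powers is ~ median * log2(n); a real peak must beat it
    floor_abs <- dominance_factor * pmed * log2(max(n_us, 2))
    axes <- matrix(0, 0, 3); peak_bins <- numeric(0); cones <- numeric(0)
    Pm <- P; Pm[!usable] <- 0
    for (a in seq_len(max_axes)) {
      pk <- which.max(Pm)
      if (Pm[pk] <= floor_abs) break
      if (length(peak_bins) && Pm[pk] < 0.1 * peak_bins[1]) break
      peak_bins <- c(peak_bins, Pm[pk])
      ## exclusion cone: at least exclusion_deg, and wide enough to cover
      ## the window mainlobe (~2.5 frequency bins at the peak radius)
      cone_deg <- max(exclusion_deg,
                      atan2(2.5, max(bin_r[pk], 1)) * 180 / pi)
      cone <- cos(cone_deg * pi / 180)
      cones <- c(cones, cone)
      ax <- unit(c(kx[pk], ky[pk], kz[pk]))
      ## sub-bin refinement: power-weighted mean of sign-folded bin
      ## directions inside the peak cone, cone re-centred iteratively
      for (it in 1:4) {
        ca <- (kx * ax[1] + ky * ax[2] + kz * ax[3]) / pmax(km, 1e-300)
        sel <- which(usable & abs(ca) > cone & Pm > 0.02 * Pm[pk])
        wts <- Pm[sel]
        dirs <- cbind(kx[sel], ky[sel], kz[sel]) / pmax(km[sel], 1e-300)
        dirs <- dirs * sign(ca[sel])
        ax <- unit(colSums(dirs * wts))
      }
      axes <- rbind(axes, ax)
      cosang <- abs(kx * ax[1] + ky * ax[2] + kz * ax[3]) / pmax(km, 1e-300)
      Pm[cosang > cone] <- 0
    }
    ## dominance: total half-spectrum power inside each axis cone,
    ## measured on the untouched spectrum for an even footing
    powers <- vapply(seq_len(nrow(axes)), function(a) {
      ca <- abs(kx * axes[a, 1] + ky * axes[a, 2] + kz * axes[a, 3]) /
        pmax(km, 1e-300)
      sum(P[usable & ca > cones[a]])
    }, numeric(1))
    list(position = centers[s, ], axes = axes,
         dominance = if (length(powers)) powers / sum(powers) else numeric(0))
  })
}

## pack a sign-free axis into its outer-product (Frobenius-isometric
## 6-vector) and back
axis_to_q <- function(a) {
  Q <- a %o% a
  c(Q[1, 1], Q[2, 2], Q[3, 3],
    sqrt(2) * Q[1, 2], sqrt(2) * Q[1, 3], sqrt(2) * Q[2, 3])
}
q_to_axis <- function(q) {
  Q <- matrix(c(q[1], q[4] / sqrt(2), q[5] / sqrt(2),
                q[4] / sqrt(2), q[2], q[6] / sqrt(2),
                q[5] / sqrt(2), q[6] / sqrt(2), q[3]), 3, 3)
  ev <- eigen(Q, symmetric = TRUE)
  unit(ev$vectors[, 1])
}

#' Smooth a spatial axis field by exact quadratic optimization
#'
#' Minimizes `sum_i ||Q_i - Q_i^0||^2 + lambda * sum_(i~j) ||Q_i - Q_j||^2`
#' over outer-product representations `Q = a a'` (so the result is
#' invariant to sign flips of any input axis), solved exactly as one
#' sparse linear system; the principal eigen-axis is then re-extracted
#' per sample. The neighbour graph connects samples closer than
#' `neighbor_radius`.
#'
#' @param samples list of axis samples (see [patch_dominant_axes]);
#'   samples without a `family`-th axis pass through unchanged.
#' @param neighbor_radius neighbour graph radius (um).
#' @param lambda_smooth smoothing weight (>= 0).
#' @param family which axis (1 or 2) to smooth.
#' @return the sample list with smoothed axes.
#' @export
smooth_axis_field <- function(samples, neighbor_radius, lambda_smooth,
                              family = 1L) {
  stopifnot(length(samples) >= 2)
  has <- vapply(samples, function(s) nrow(s$axes) >= family, logical(1))
  idx <- which(has)
  if (length(idx) < 2) return(samples)
  pos <- t(vapply(samples[idx], `[[`, numeric(3), "position"))
  Q0 <- t(vapply(samples[idx], function(s) axis_to_q(s$axes[family, ]),
                 numeric(6)))
  n <- length(idx)
  dd <- as.matrix(stats::dist(pos))
  adj <- which(dd < neighbor_radius & upper.tri(dd), arr.ind = TRUE)
  if (nrow(adj) > 0) {
    L <- Matrix::sparseMatrix(
      i = c(adj[, 1], adj[, 2]), j = c(adj[, 2], adj[, 1]),
      x = -1, dims = c(n, n))
    Matrix::diag(L) <- -Matrix::rowSums(L)
    A <- Matrix::Diagonal(n) + lambda_smooth * L
    Q <- as.matrix(Matrix::solve(A, Q0))
  } else Q <- Q0
  for (r in seq_len(n))
    samples[[idx[r]]]$axes[family, ] <- q_to_axis(Q[r, ])
  samples
}

nearest_vertex <- function(points, vertices) {
  vapply(seq_len(nrow(points)), function(i) {
    which.min(colSums((t(vertices) - points[i, ])^2))
  }, integer(1))
}

#' Project sampled axes onto the tangent plane of a mid-plane surface
#'
#' Each axis is replaced by its normalized projection onto the tangent
#' plane at the nearest mid-plane vertex; axes within `drop_angle_deg` of
#' the surface normal are dropped from the sample.
#'
#' @param samples list of axis samples.
#' @param midplane a [surface_mesh] (e.g. the dermis mid-plane).
#' @param drop_angle_deg drop threshold: angle to the normal (degrees).
#' @return the modified sample list.
#' @export
project_tangential <- function(samples, midplane, drop_angle_deg = 5) {
  vn <- midplane$normals %||% vertex_normals(midplane)
  pos <- t(vapply(samples, `[[`, numeric(3), "position"))
  nv <- nearest_vertex(pos, midplane$vertices)
  for (s in seq_along(samples)) {
    ax <- samples[[s]]$axes
    if (nrow(ax) == 0) next
    n <- unit(vn[nv[s], ])
    keep <- logical(nrow(ax)); newax <- ax
    for (r in seq_len(nrow(ax))) {
      a <- ax[r, ]
      if (axis_angle(a, n) < drop_angle_deg) { keep[r] <- FALSE; next }
      proj <- a - sum(a * n) * n
      newax[r, ] <- unit(proj); keep[r] <- TRUE
    }
    samples[[s]]$axes <- newax[keep, , drop = FALSE]
    samples[[s]]$dominance <- samples[[s]]$dominance[keep]
  }
  samples
}

## uniform graph Laplacian eigenmodes of a mesh (surface or tet)
mesh_eigenmodes <- function(mesh, n_modes) {
  if (inherits(mesh, "surface_mesh")) {
    e <- mesh_edges(mesh); nv <- nrow(mesh$vertices)
  } else {
    tt <- mesh$tets
    e <- unique(rbind(tt[, c(1, 2)], tt[, c(1, 3)], tt[, c(1, 4)],
                      tt[, c(2, 3)], tt[, c(2, 4)], tt[, c(3, 4)]))
    e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    e <- e[!duplicated(paste(e[, 1], e[, 2])), , drop = FALSE]
    nv <- nrow(mesh$nodes)
  }
  L <- matrix(0, nv, nv)
  L[cbind(e[, 1], e[, 2])] <- -1
  L[cbind(e[, 2], e[, 1])] <- -1
  diag(L) <- -rowSums(L)
  ev <- eigen(L, symmetric = TRUE)
  ## smallest eigenvalues last in R's ordering; reverse
  ord <- rev(seq_len(nv))[seq_len(n_modes)]
  list(vectors = ev$vectors[, ord, drop = FALSE],
       values = rev(ev$values)[seq_len(n_modes)])
}

mesh_points <- function(mesh) {
  if (inherits(mesh, "surface_mesh")) mesh$vertices else mesh$nodes
}

#' Spectral least-squares interpolation of sampled data onto a mesh
#'
#' Fits the coefficients of the first `n_modes` graph-Laplacian
#' eigenmodes of the mesh to the sample values by least squares and
#' evaluates the expansion at every mesh vertex/node. Axis-valued samples
#' are fitted componentwise in outer-product space and re-extracted as
#' unit axes. Rank deficiency (including `n_modes` exceeding the sample
#' count) is ridge-regularized with a warning.
#'
#' @param samples for scalar data: list with `position` (3-vector) and
#'   `value`; for axis data: axis samples as from [patch_dominant_axes].
#' @param mesh a [surface_mesh] or [layered_tet_mesh].
#' @param n_modes number of eigenmodes.
#' @param ridge ridge penalty used on rank deficiency.
#' @param family axis family to interpolate for axis-valued samples.
#' @return object of class `field_on_mesh`: `values` is a numeric vector
#'   (scalar) or n x 3 axis matrix, one row per mesh vertex/node.
#' @export
interpolate_field <- function(samples, mesh, n_modes, ridge = 1e-8,
                              family = 1L) {
  stopifnot(length(samples) >= 1, n_modes >= 1)
  axis_data <- !is.null(samples[[1]]$axes)
  if (axis_data) {
    samples <- Filter(function(s) nrow(s$axes) >= family, samples)
    if (length(samples) == 0) stop("no samples carry the requested axis")
  }
  pos <- t(vapply(samples, `[[`, numeric(3), "position"))
  pts <- mesh_points(mesh)
  em <- mesh_eigenmodes(mesh, min(n_modes, nrow(pts)))
  sv <- nearest_vertex(pos, pts)
  B <- em$vectors[sv, , drop = FALSE]
  Y <- if (axis_data) {
    t(vapply(samples, function(s) axis_to_q(s$axes[family, ]), numeric(6)))
  } else cbind(vapply(samples, `[[`, numeric(1), "value"))
  BtB <- crossprod(B)
  rk <- qr(B)$rank
  if (rk < ncol(B)) {
    warning("spectral fit is rank deficient; ridge-regularizing")
    BtB <- BtB + diag(ridge, ncol(B))
  }
  coef <- solve(BtB, crossprod(B, Y))
  Vals <- em$vectors %*% coef
  values <- if (axis_data) {
    t(apply(Vals, 1, q_to_axis))
  } else as.numeric(Vals)
  structure(list(values = values, mesh = mesh,
                 type = if (axis_data) "axis" else "scalar",
                 n_modes = ncol(em$vectors)),
            class = "field_on_mesh")
}

#' @export
print.field_on_mesh <- function(x, ...) {
  cat(sprintf("<field_on_mesh> %s field on %d points (%d modes)\n",
              x$type, NROW(x$values), x$n_modes))
  invisible(x)
}
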