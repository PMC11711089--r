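#' Ground truth container for synthetic fixtures
#'
#' Bundles whatever a generator knows exactly: boundary surfaces, the
#' prescribed fiber axis field, cell centroids, the fold-network graph,
#' and the seed used.
#' @param ... named ground-truth components.
#' @param rng_seed integer seed the generator consumed.
#' @export
ground_truth <- function(..., rng_seed = NA_integer_) {
  structure(c(list(...), list(rng_seed = rng_seed)), class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth> fields:",
      paste(setdiff(names(x), "rng_seed"), collapse = ", "),
      sprintf("(seed %s)\n", x$rng_seed))
  invisible(x)
}

## add a truncated isotropic Gaussian blob to `vol` (array [x,y,z]),
## centre in fractional voxel indices, sd in voxels; truncated at 3 sd
add_blob <- function(vol, centre, sd_vox, amplitude) {
  d <- dim(vol); r <- ceiling(3 * sd_vox)
  lo <- pmax(1, floor(centre - r)); hi <- pmin(d, ceiling(centre + r))
  if (any(lo > hi)) return(vol)
  ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
  gx <- exp(-((ix - centre[1])^2) / (2 * sd_vox^2))
  gy <- exp(-((iy - centre[2])^2) / (2 * sd_vox^2))
  gz <- exp(-((iz - centre[3])^2) / (2 * sd_vox^2))
  vol[ix, iy, iz] <- vol[ix, iy, iz] + amplitude * (gx %o% gy %o% gz)
  vol
}

#' Synthetic nuclear-channel volume of a two-layer tissue
#'
#' Emulates a nuclear stain of embryonic skin: an epidermal slab with high
#' nuclear density over a dermal slab with lower density, separated by a
#' known (optionally undulating) interface, empty background above the
#' outer surface. Nuclei are isotropic Gaussian blobs truncated at 3 sd.
#'
#' The tissue occupies `z < z_outer`; the epidermis is the slab within
#' `epi_thickness` below the outer surface.
#'
#' @param shape integer length-3, volume size in voxels (x, y, z).
#' @param epi_thickness epidermis thickness (um).
#' @param density_epi,density_derm nuclear densities (nuclei / um^3);
#'   `density_epi >= density_derm > 0`.
#' @param noise_sd additive Gaussian noise sd (intensity units; nuclei
#'   have peak amplitude 1).
#' @param seed integer RNG seed.
#' @param spacing voxel size (um).
#' @param nucleus_sd nuclear blob sd (um).
#' @param undulation_amp,undulation_wavelength interface undulation (um);
#'   0 amplitude gives a flat interface.
#' @param margin_frac background fraction above the outer surface.
#' @return list with `volume` ([voxel_volume]) and `truth`
#'   ([ground_truth] with `outer_surface`, `interface_surface`,
#'   `z_outer`, `interface_fun`).
#' @export
make_nuclear_volume <- function(shape, epi_thickness, density_epi,
                                density_derm, noise_sd = 0, seed = 1,
                                spacing = c(1, 1, 1), nucleus_sd = 1.2,
                                undulation_amp = 0,
                                undulation_wavelength = 20,
                                margin_frac = 0.15) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, density_epi >= density_derm,
            density_derm > 0)
  ext <- (shape - 1) * spacing
  z_outer <- ext[3] * (1 - margin_frac)
  if (epi_thickness >= z_outer)
    stop("epi_thickness must be smaller than the tissue depth")
  if (any(ext < 6 * nucleus_sd))
    stop("shape too small to contain one nucleus")
  interface_fun <- function(x, y) {
    (z_outer - epi_thickness) +
      undulation_amp * sin(2 * pi * x / undulation_wavelength) *
        cos(2 * pi * y / undulation_wavelength)
  }
  vol <- array(0, shape)
  vv <- voxel_volume(vol, spacing)
  with_seed(seed, {
    area_xy <- ext[1] * ext[2]
    n_epi <- stats::rpois(1, density_epi * area_xy * epi_thickness)
    n_derm <- stats::rpois(1, density_derm * area_xy *
                             (z_outer - epi_thickness))
    sample_layer <- function(n, epi) {
      if (n == 0) return(matrix(0, 0, 3))
      x <- runif(n, 0, ext[1]); y <- runif(n, 0, ext[2])
      zi <- interface_fun(x, y)
      z <- if (epi) runif(n, zi, zi + epi_thickness) else runif(n, 0, zi)
      cbind(x, y, z)
    }
    pts <- rbind(sample_layer(n_epi, TRUE), sample_layer(n_derm, FALSE))
    if (nrow(pts) > 0) {
      idx <- world_to_voxel(vv, pts)
      for (r in seq_len(nrow(idx)))
        vol <- add_blob(vol, idx[r, ], nucleus_sd / spacing[1], 1)
    }
    if (noise_sd > 0) vol <- vol + array(rnorm(length(vol), 0, noise_sd), shape)
  })
  gx <- seq(0, ext[1], length.out = shape[1])
  gy <- seq(0, ext[2], length.out = shape[2])
  iz <- base::outer(gx, gy, FUN = interface_fun)
  outer_mesh <- heightfield_mesh(gx, gy, matrix(z_outer, shape[1], shape[2]))
  interf <- heightfield_mesh(gx, gy, iz)
  list(volume = voxel_volume(vol, spacing),
       truth = ground_truth(outer_surface = outer_mesh,
                            interface_surface = interf,
                            z_outer = z_outer,
                            epi_thickness = epi_thickness,
                            interface_fun = interface_fun,
                            rng_seed = seed))
}

## oriented band-pass transfer function on the rfft-style full grid:
## Gaussian annulus at |k| = k0 combined with an angular Gaussian around
## the (sign-free) axis direction
oriented_bandpass <- function(shape, spacing, axis, wavelength,
                              radial_rel_sd = 0.12, angular_sd_deg = 6) {
  k <- lapply(1:3, function(a) {
    n <- shape[a]
    f <- c(0:(floor(n / 2)), -((ceiling(n / 2) - 1):1)) / (n * spacing[a])
    if (n == 1) f <- 0
    f
  })
  kx <- array(rep(k[[1]], times = shape[2] * shape[3]), shape)
  ky <- array(rep(rep(k[[2]], each = shape[1]), times = shape[3]), shape)
  kz <- array(rep(k[[3]], each = shape[1] * shape[2]), shape)
  km <- sqrt(kx^2 + ky^2 + kz^2)
  k0 <- 1 / wavelength
  axis <- unit(axis)
  ca <- abs(kx * axis[1] + ky * axis[2] + kz * axis[3]) / pmax(km, 1e-300)
  ang <- acos(pmin(1, ca))
  H <- exp(-(km - k0)^2 / (2 * (radial_rel_sd * k0)^2)) *
       exp(-ang^2 / (2 * (angular_sd_deg * pi / 180)^2))
  H[km == 0] <- 0
  H
}

#' Synthetic collagen-fiber texture volume
#'
#' Band-limited oriented texture built by filtering white noise with an
#' oriented band-pass kernel: spectral power is concentrated on the
#' prescribed (sign-free) axis at spatial frequency `1/wavelength`, so a
#' 3D FFT of any interior patch has its dominant non-DC power along the
#' prescribed axis. A spatially varying axis field is rendered blockwise.
#'
#' @param shape integer length-3, voxels.
#' @param axis_field either a unit 3-vector (constant axis) or a
#'   `function(xyz)` mapping an n x 3 matrix of world positions to n x 3
#'   unit axes.
#' @param wavelength texture wavelength (um); must be at least 4 voxels.
#' @param noise_sd additive white noise sd relative to unit texture RMS.
#' @param seed integer RNG seed.
#' @param spacing voxel size (um).
#' @param block voxels per rendering block for varying fields.
#' @return list with `volume` and `truth` (field `axis_fun`).
#' @export
make_fiber_volume <- function(shape, axis_field, wavelength, noise_sd = 0,
                              seed = 1, spacing = c(1, 1, 1), block = 32L) {
  shape <- as.integer(shape)
  if (any(wavelength < 4 * spacing))
    stop("wavelength below 4 voxels is not resolvable (Nyquist guard)")
  axis_fun <- if (is.function(axis_field)) axis_field else {
    ax <- unit(axis_field); function(xyz) {
      matrix(ax, nrow = nrow(rbind(xyz)), ncol = 3, byrow = TRUE)
    }
  }
  vol <- array(0, shape)
  vv <- voxel_volume(vol, spacing)
  with_seed(seed, {
    noise <- array(rnorm(prod(shape)), shape)
    constant <- !is.function(axis_field)
    render_block <- function(ix, iy, iz) {
      bs <- c(length(ix), length(iy), length(iz))
      ctr_idx <- c(mean(ix), mean(iy), mean(iz))
      ax <- unit(axis_fun(voxel_to_world(vv, ctr_idx))[1, ])
      H <- oriented_bandpass(bs, spacing, ax, wavelength)
      F <- fft(noise[ix, iy, iz, drop = FALSE] * 1)
      tex <- Re(fft(F * H, inverse = TRUE)) / prod(bs)
      s <- stats::sd(tex); if (s > 0) tex <- tex / s
      ## deterministic grating carrier pins the spectral centroid on the
      ## prescribed axis; the filtered noise roughens it like real fibers
      wpos <- voxel_to_world(vv, as.matrix(expand.grid(ix, iy, iz)))
      phase <- runif(1, 0, 2 * pi)
      carrier <- array(cos(2 * pi * (wpos %*% ax) / wavelength + phase), bs)
      mix <- sqrt(0.6) * sqrt(2) * carrier + sqrt(0.4) * tex
      sm <- stats::sd(mix)
      if (sm > 0) mix <- mix / sm     # unit-contrast texture
      mix
    }
    if (constant) {
      vol <- render_block(1:shape[1], 1:shape[2], 1:shape[3])
    } else {
      bl <- function(n) split(1:n, ceiling((1:n) / block))
      for (ix in bl(shape[1])) for (iy in bl(shape[2]))
        for (iz in bl(shape[3]))
          vol[ix, iy, iz] <- render_block(ix, iy, iz)
    }
    if (noise_sd > 0)
      vol <- vol + array(rnorm(prod(shape), 0, noise_sd), shape)
  })
  list(volume = voxel_volume(vol, spacing),
       truth = ground_truth(axis_fun = axis_fun, wavelength = wavelength,
                            rng_seed = seed))
}

#' Synthetic EdU-like cell volume
#'
#' Bright quasi-spherical cells (isotropic Gaussian blobs, sd =
#' `cell_radius / 2`, truncated at 3 sd) at known centroids on a noisy
#' background. Centroids are drawn with a minimum separation of
#' `2 * cell_radius`; optionally, `touching_pairs` additional pairs at
#' `1.5 * cell_radius` separation are added and flagged.
#'
#' @param shape integer length-3, voxels.
#' @param n_cells number of well-separated cells (>= 0).
#' @param cell_radius cell radius (um).
#' @param contrast blob peak amplitude over the background.
#' @param noise_sd background Gaussian noise sd.
#' @param seed integer RNG seed.
#' @param spacing voxel size (um).
#' @param touching_pairs number of extra flagged close pairs.
#' @return list with `volume` and `truth` (`centroids` n x 3 um,
#'   `touching` logical per centroid).
#' @export
make_edu_volume <- function(shape, n_cells, cell_radius = 4, contrast = 1,
                            noise_sd = 0, seed = 1, spacing = c(1, 1, 1),
                            touching_pairs = 0L) {
  shape <- as.integer(shape)
  stopifnot(n_cells >= 0, touching_pairs >= 0)
  ext <- (shape - 1) * spacing
  pad <- 3 * cell_radius
  if (n_cells + touching_pairs > 0 && any(ext <= 2 * pad))
    stop("volume too small for the requested cells")
  vol <- array(0, shape)
  vv <- voxel_volume(vol, spacing)
  cents <- matrix(0, 0, 3); touching <- logical(0)
  with_seed(seed, {
    draw_point <- function() {
      cbind(runif(1, pad, ext[1] - pad), runif(1, pad, ext[2] - pad),
            runif(1, pad, ext[3] - pad))
    }
    min_sep <- 2 * cell_radius
    tries <- 0
    while (nrow(cents) < n_cells && tries < 20000) {
      p <- draw_point(); tries <- tries + 1
      if (nrow(cents) == 0 ||
          min(sqrt(rowSums(sweep(cents, 2, p)^2))) >= min_sep) {
        cents <- rbind(cents, p); touching <- c(touching, FALSE)
      }
    }
    if (nrow(cents) < n_cells)
      stop("could not place the requested number of separated cells")
    for (tp in seq_len(touching_pairs)) {
      placed <- FALSE
      for (try in 1:20000) {
        p <- draw_point()
        dirv <- unit(rnorm(3))
        q <- p + 1.5 * cell_radius * matrix(dirv, 1)
        ok_bounds <- all(q > pad) && all(q < ext - pad)
        far <- nrow(cents) == 0 ||
          (min(sqrt(rowSums(sweep(cents, 2, p)^2))) >= 1.25 * min_sep &&
           min(sqrt(rowSums(sweep(cents, 2, as.vector(q))^2))) >= 1.25 * min_sep)
        if (ok_bounds && far) {
          cents <- rbind(cents, p, q)
          touching <- c(touching, TRUE, TRUE)
          placed <- TRUE
          break
        }
      }
      if (!placed) stop("could not place the requested touching pairs")
    }
    if (nrow(cents) > 0) {
      idx <- world_to_voxel(vv, cents)
      for (r in seq_len(nrow(idx)))
        vol <- add_blob(vol, idx[r, ], (cell_radius / 2) / spacing[1],
                        contrast)
    }
    if (noise_sd > 0)
      vol <- vol + array(rnorm(prod(shape), 0, noise_sd), shape)
  })
  rownames(cents) <- NULL
  list(volume = voxel_volume(vol, spacing),
       truth = ground_truth(centroids = cents, touching = touching,
                            cell_radius = cell_radius, rng_seed = seed))
}
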