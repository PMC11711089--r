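## Spectral (FFT-based) Gaussian filtering of 3D volumes. The transfer
## function of a Gaussian of physical sd `sigma` is exp(-2 pi^2 sigma^2 k^2);
## derivatives multiply by (2 pi i k_a). Boundary handling is circular,
## adequate for fixtures whose signal decays before the border.

freq_axis <- function(n, d) {
  f <- c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1) / (n * d)
  if (n == 1) f <- 0
  f
}

freq_grids <- function(shape, spacing) {
  kx <- freq_axis(shape[1], spacing[1])
  ky <- freq_axis(shape[2], spacing[2])
  kz <- freq_axis(shape[3], spacing[3])
  list(kx = array(rep(kx, times = shape[2] * shape[3]), shape),
       ky = array(rep(rep(ky, each = shape[1]), times = shape[3]), shape),
       kz = array(rep(kz, each = shape[1] * shape[2]), shape))
}

## Gaussian-smoothed volume and, optionally, its first/second spectral
## derivatives. `orders` is a list of integer 3-vectors (dx, dy, dz);
## returns a list of arrays in the same order.
gaussian_derivatives <- function(values, spacing, sigma,
                                 orders = list(c(0, 0, 0)), pad = NULL) {
  shape <- dim(values)
  if (is.null(pad)) pad <- pmin(shape, ceiling(3 * sigma / spacing))
  pad <- as.integer(pmax(pad, 0))
  ## replicate-pad to suppress circular wrap-around of the FFT
  ix <- c(rep(1L, pad[1]), seq_len(shape[1]), rep(shape[1], pad[1]))
  iy <- c(rep(1L, pad[2]), seq_len(shape[2]), rep(shape[2], pad[2]))
  iz <- c(rep(1L, pad[3]), seq_len(shape[3]), rep(shape[3], pad[3]))
  vp <- values[ix, iy, iz, drop = FALSE]
  pshape <- dim(vp)
  F <- fft(vp)
  kg <- freq_grids(pshape, spacing)
  H <- exp(-2 * pi^2 * sigma^2 * (kg$kx^2 + kg$ky^2 + kg$kz^2))
  cx <- pad[1] + seq_len(shape[1])
  cy <- pad[2] + seq_len(shape[2])
  cz <- pad[3] + seq_len(shape[3])
  lapply(orders, function(o) {
    D <- (2i * pi * kg$kx)^o[1] * (2i * pi * kg$ky)^o[2] *
         (2i * pi * kg$kz)^o[3]
    out <- Re(fft(F * H * D, inverse = TRUE)) / prod(pshape)
    out[cx, cy, cz, drop = FALSE]
  })
}

## vectorized trilinear interpolation at fractional 1-based indices
trilinear <- function(arr, idx) {
  d <- dim(arr)
  i0 <- pmax(1L, pmin(d[1] - 1L, floor(idx[, 1])))
  j0 <- pmax(1L, pmin(d[2] - 1L, floor(idx[, 2])))
  k0 <- pmax(1L, pmin(d[3] - 1L, floor(idx[, 3])))
  fx <- pmin(1, pmax(0, idx[, 1] - i0))
  fy <- pmin(1, pmax(0, idx[, 2] - j0))
  fz <- pmin(1, pmax(0, idx[, 3] - k0))
  at <- function(di, dj, dk) arr[cbind(i0 + di, j0 + dj, k0 + dk)]
  (1 - fz) * ((1 - fy) * ((1 - fx) * at(0, 0, 0) + fx * at(1, 0, 0)) +
              fy * ((1 - fx) * at(0, 1, 0) + fx * at(1, 1, 0))) +
  fz * ((1 - fy) * ((1 - fx) * at(0, 0, 1) + fx * at(1, 0, 1)) +
        fy * ((1 - fx) * at(0, 1, 1) + fx * at(1, 1, 1)))
}
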