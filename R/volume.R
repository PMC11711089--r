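#' Voxel volume with physical spacing
#'
#' A 3D scalar field standing in for one light-sheet microscopy channel.
#' Values are stored as an `[x, y, z]` array; all public coordinates are
#' world micrometres with `world = origin + (index - 1) * spacing`.
#'
#' @param values numeric 3D array, indexed `[x, y, z]`.
#' @param spacing numeric length-3, voxel size in um along (x, y, z); all > 0.
#' @param origin numeric length-3, world position of voxel (1,1,1) in um.
#' @return An object of class `voxel_volume`.
#' @export
voxel_volume <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  stopifnot(is.array(values), length(dim(values)) == 3L)
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  stopifnot(length(spacing) == 3L, all(spacing > 0),
            length(origin) == 3L, all(is.finite(values)))
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<voxel_volume> %d x %d x %d voxels, spacing (%g, %g, %g) um\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.voxel_volume <- function(x) dim(x$values)

#' Convert voxel indices (1-based) to world coordinates in um
#'
#' @param v a [voxel_volume].
#' @param idx numeric matrix (n x 3) of fractional 1-based indices.
#' @return n x 3 matrix of world positions (um).
#' @export
voxel_to_world <- function(v, idx) {
  idx <- rbind(idx)
  sweep(sweep(idx - 1, 2, v$spacing, `*`), 2, v$origin, `+`)
}

#' Convert world coordinates (um) to fractional 1-based voxel indices
#' @rdname voxel_to_world
#' @param xyz numeric matrix (n x 3) of world positions in um.
#' @export
world_to_voxel <- function(v, xyz) {
  xyz <- rbind(xyz)
  sweep(sweep(xyz, 2, v$origin, `-`), 2, v$spacing, `/`) + 1
}

#' Physical bounds of a volume
#' @param v a [voxel_volume].
#' @return 2 x 3 matrix: rows are min/max world coordinates of voxel centres.
#' @export
volume_bounds <- function(v) {
  d <- dim(v$values)
  rbind(v$origin, v$origin + (d - 1) * v$spacing)
}

## ---- simple text/binary IO for the external interfaces ----

#' Write a volume as a multi-page TIFF with a JSON spacing sidecar
#'
#' Requires the `tiff` package. Pages are z-slices.
#' @param v a [voxel_volume]; @param path output `.tif` path.
#' @export
write_volume_tiff <- function(v, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for TIFF export")
  rng <- range(v$values)
  scl <- if (diff(rng) > 0) diff(rng) else 1
  pages <- lapply(seq_len(dim(v$values)[3]), function(k)
    (t(v$values[, , k]) - rng[1]) / scl)   # tiff wants row-major images
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  sidecar <- sub("\\.tiff?$", ".json", path)
  jsonlite::write_json(
    list(spacing_um = v$spacing, origin_um = v$origin,
         intensity_offset = rng[1], intensity_scale = scl),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
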