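#' Flat bilayer skin patch on a rigid substrate
#'
#' Rectangular epidermis-over-dermis patch whose bottom surface stands in
#' for the rigid bone substrate (nodes flagged fixed). Hexahedral cells
#' are split into six conforming tetrahedra; each tet is labelled by the
#' depth of its centroid.
#'
#' @param nx,ny in-plane element counts.
#' @param h_epi,h_derm layer thicknesses (um), > 0.
#' @param element_size in-plane element edge (um); also the target
#'   vertical element size.
#' @param clamp_sides also fix the lateral boundary nodes. A free-sided
#'   patch relieves growth-induced compression by sliding outward over
#'   the substrate (shear lag), so a small patch never folds; clamping
#'   the sides emulates a patch embedded in a laterally confined sheet.
#' @return a [layered_tet_mesh]; total volume is exactly
#'   `nx * ny * element_size^2 * (h_epi + h_derm)`.
#' @export
make_bilayer_patch <- function(nx, ny, h_epi, h_derm, element_size,
                               clamp_sides = FALSE) {
  stopifnot(nx >= 1, ny >= 1, h_epi > 0, h_derm > 0, element_size > 0)
  nz_d <- max(1L, round(h_derm / element_size))
  nz_e <- max(1L, round(h_epi / element_size))
  zlev <- c(seq(0, h_derm, length.out = nz_d + 1),
            seq(h_derm, h_derm + h_epi, length.out = nz_e + 1)[-1])
  g <- structured_tet_grid(nx + 1L, ny + 1L, length(zlev),
    pos = function(i, j, k)
      cbind((i - 1) * element_size, (j - 1) * element_size, zlev[k]))
  cen_z <- rowMeans(matrix(g$nodes[t(g$tets), 3], ncol = 4, byrow = TRUE))
  layer <- ifelse(cen_z > h_derm, "epidermis", "dermis")
  fixed <- abs(g$nodes[, 3]) < 1e-12
  if (clamp_sides) {
    lx <- nx * element_size; ly <- ny * element_size
    side <- g$nodes[, 1] < 1e-12 | g$nodes[, 1] > lx - 1e-12 |
            g$nodes[, 2] < 1e-12 | g$nodes[, 2] > ly - 1e-12
    fixed <- fixed | side
  }
  layered_tet_mesh(g$nodes, g$tets, layer, fixed)
}

#' Half-cylinder jaw proxy with optional dorsal bone ridges
#'
#' Epidermis over dermis wrapped on a rigid half-cylindrical bone surface
#' (a reduced analogue of an embryonic upper jaw). Optional pair of
#' longitudinal dorsal ridges raises the bone surface along two lines
#' flanking the dorsal midline.
#'
#' @param length cylinder length (um).
#' @param radius outer skin radius (um); must exceed the summed layer
#'   thicknesses.
#' @param ridge_height dorsal bone ridge elevation (um); 0 = smooth bone.
#' @param h_epi,h_derm layer thicknesses (um).
#' @param n_axial,n_circ,n_radial_derm,n_radial_epi element counts.
#' @param ridge_angle_deg angular positions of the two ridges away from
#'   the dorsal midline (degrees).
#' @param ridge_width_deg angular Gaussian width of each ridge (degrees).
#' @param clamp_ends also fix the axial end rings and the two lateral
#'   base lines (theta = 0, pi), confining the skin like the
#'   surrounding head tissue does; without confinement a short proxy
#'   relieves growth by sliding out of its free ends.
#' @return a [layered_tet_mesh] with bone-surface nodes flagged fixed.
#' @export
make_jaw_proxy <- function(length, radius, ridge_height = 0,
                           h_epi = 0.08 * radius, h_derm = 0.17 * radius,
                           n_axial = 24L, n_circ = 24L,
                           n_radial_derm = 2L, n_radial_epi = 1L,
                           ridge_angle_deg = 25, ridge_width_deg = 10,
                           clamp_ends = FALSE) {
  stopifnot(radius > h_epi + h_derm, length > 0, ridge_height >= 0)
  r_bone0 <- radius - h_epi - h_derm
  ridge <- function(theta) {
    if (ridge_height == 0) return(0 * theta)
    a <- ridge_angle_deg * pi / 180; w <- ridge_width_deg * pi / 180
    dev <- theta - pi / 2   # dorsal midline at theta = pi/2
    ridge_height * (exp(-((dev - a)^2) / (2 * w^2)) +
                    exp(-((dev + a)^2) / (2 * w^2)))
  }
  nr <- n_radial_derm + n_radial_epi + 1L
  pos <- function(i, j, k) {
    x <- (i - 1) / n_axial * length
    th <- (j - 1) / n_circ * pi
    rb <- r_bone0 + ridge(th)
    ri <- rb + h_derm          # dermis-epidermis interface radius
    ro <- ri + h_epi
    frac_d <- pmin(1, (k - 1) / n_radial_derm)
    frac_e <- pmax(0, (k - 1 - n_radial_derm) / n_radial_epi)
    r <- ifelse(k <= n_radial_derm + 1L, rb + frac_d * h_derm,
                ri + frac_e * h_epi)
    cbind(x, r * cos(th), r * sin(th))
  }
  g <- structured_tet_grid(n_axial + 1L, n_circ + 1L, nr, pos)
  k_of_cell <- g$cells[g$cell_of_tet, 3]
  layer <- ifelse(k_of_cell <= n_radial_derm, "dermis", "epidermis")
  kk <- ((seq_len(nrow(g$nodes)) - 1L) %/%
           ((n_axial + 1L) * (n_circ + 1L))) + 1L
  fixed <- kk == 1L
  if (clamp_ends) {
    nn <- nrow(g$nodes)
    within_layer <- (seq_len(nn) - 1L) %% ((n_axial + 1L) * (n_circ + 1L))
    i_ax <- within_layer %% (n_axial + 1L)       # 0-based axial index
    j_ci <- within_layer %/% (n_axial + 1L)      # 0-based circumferential
    fixed <- fixed | i_ax == 0L | i_ax == n_axial |
             j_ci == 0L | j_ci == n_circ
  }
  layered_tet_mesh(g$nodes, g$tets, layer, fixed)
}

## ---- fold-pattern fixtures -------------------------------------------

## honeycomb segment set for m x n full hexagonal cells, circumradius R;
## returns nodes (k x 2), edges (e x 2 indices), cycle count = m * n
hex_lattice <- function(m, n, R = 10) {
  verts <- list(); edges <- list()
  key2id <- new.env(parent = emptyenv())
  get_id <- function(p) {
    key <- sprintf("%.6f_%.6f", p[1], p[2])
    id <- key2id[[key]]
    if (is.null(id)) {
      id <- length(verts) + 1L
      verts[[id]] <<- p
      key2id[[key]] <<- id
    }
    id
  }
  for (j in seq_len(n)) for (i in seq_len(m)) {
    cx <- sqrt(3) * R * (i + 0.5 * (j %% 2))
    cy <- 1.5 * R * j
    hv <- sapply(0:5, function(k) {
      a <- pi / 6 + k * pi / 3
      get_id(c(cx + R * cos(a), cy + R * sin(a)))
    })
    for (k in 1:6)
      edges[[length(edges) + 1L]] <- sort(c(hv[k], hv[k %% 6 + 1]))
  }
  em <- unique(do.call(rbind, edges))
  list(nodes = do.call(rbind, verts), edges = em)
}

graph_cycle_rank <- function(n_nodes, edges) {
  if (nrow(edges) == 0) return(0L)
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n_nodes - igraph::vcount(g)))
  igraph::ecount(g) - igraph::vcount(g) + igraph::count_components(g)
}

## distance from grid points to a set of 2D segments
seg_distance_field <- function(px, py, segs) {
  d <- rep(Inf, length(px))
  for (r in seq_len(nrow(segs))) {
    ax <- segs[r, 1]; ay <- segs[r, 2]; bx <- segs[r, 3]; by <- segs[r, 4]
    vx <- bx - ax; vy <- by - ay
    L2 <- vx^2 + vy^2
    t <- if (L2 == 0) 0 else pmin(1, pmax(0, ((px - ax) * vx + (py - ay) * vy) / L2))
    d <- pmin(d, sqrt((px - (ax + t * vx))^2 + (py - (ay + t * vy))^2))
  }
  d
}

#' Synthetic folded surface with exactly known network topology
#'
#' Height-field meshes carved with grooves along a generated pattern;
#' the generating graph (junctions, polyline edges, cycle count,
#' incomplete edges) is recorded exactly as ground truth. Patterns:
#' \describe{
#'   \item{polygonal_lattice}{honeycomb of `m x n` full hexagonal cells
#'     (cycle count `m * n`).}
#'   \item{labyrinth}{a single serpentine groove spanning the patch
#'     border-to-border (0 cycles, long edge).}
#'   \item{elongated_bands}{parallel border-to-border grooves.}
#'   \item{smooth}{no grooves; empty network.}
#' }
#'
#' @param pattern one of the names above.
#' @param params list: `m`, `n`, `R` (lattice); `n_bands`; `depth`
#'   (groove depth, um), `width` (groove Gaussian half-width, um),
#'   `margin` (um), `spacing` (grid step, um), `open_end_trim` (um;
#'   lattice only — trim one groove short of the border to create an
#'   incomplete edge).
#' @param seed RNG seed (used only for jitter if `params$jitter > 0`).
#' @return list with `mesh` ([surface_mesh]), `truth` ([ground_truth]
#'   with `network` = list(nodes, edges, segments, n_cycles,
#'   n_incomplete, incomplete_lengths)).
#' @export
make_fold_surface <- function(pattern = c("polygonal_lattice", "labyrinth",
                                          "elongated_bands", "smooth"),
                              params = list(), seed = 1) {
  pattern <- match.arg(pattern)
  p <- utils::modifyList(list(m = 3, n = 3, R = 10, n_bands = 3,
                              depth = 2, width = 1.6, margin = 6,
                              spacing = 0.75, jitter = 0,
                              open_end_trim = 0), params)
  if (pattern != "smooth" && p$depth <= 0) stop("groove depth must be > 0")

  nodes2 <- matrix(0, 0, 2); edges <- matrix(0L, 0, 2)
  segs <- matrix(0, 0, 4)   # x1 y1 x2 y2 rendering segments
  n_cycles <- 0L; n_incomplete <- 0L; incomplete_lengths <- numeric(0)

  if (pattern == "polygonal_lattice") {
    hl <- hex_lattice(p$m, p$n, p$R)
    nodes2 <- hl$nodes; edges <- hl$edges
    segs <- cbind(nodes2[edges[, 1], 1], nodes2[edges[, 1], 2],
                  nodes2[edges[, 2], 1], nodes2[edges[, 2], 2])
    n_cycles <- graph_cycle_rank(nrow(nodes2), edges)
  } else if (pattern == "labyrinth") {
    W <- p$m * p$R * 4; H <- p$n * p$R * 3
    ys <- seq(0, H, length.out = max(4, p$n * 2))
    pts <- matrix(0, 0, 2)
    for (i in seq_along(ys)) {
      xs <- if (i %% 2 == 1) c(0, W) else c(W, 0)
      pts <- rbind(pts, c(xs[1], ys[i]), c(xs[2], ys[i]))
    }
    ## extend the two serpentine ends past the patch border so they anchor
    ends <- pts
    ends[1, 1] <- ends[1, 1] + sign(ends[1, 1] - ends[2, 1] - 1e-9) * 3 * p$margin
    nr <- nrow(ends)
    ends[nr, 1] <- ends[nr, 1] + sign(ends[nr, 1] - ends[nr - 1, 1] + 1e-9) * 3 * p$margin
    segs <- cbind(ends[-nr, 1], ends[-nr, 2], ends[-1, 1], ends[-1, 2])
    nodes2 <- pts
    edges <- cbind(1:(nrow(pts) - 1L), 2:nrow(pts))
    n_cycles <- 0L
  } else if (pattern == "elongated_bands") {
    W <- p$m * p$R * 4; H <- p$n * p$R * 3
    xs <- seq(W / (p$n_bands + 1), W * p$n_bands / (p$n_bands + 1),
              length.out = p$n_bands)
    segs <- cbind(xs, -3 * p$margin, xs, H + 3 * p$margin)
    if (p$open_end_trim > 0) {  # last band stops short of the top border
      segs[p$n_bands, 4] <- H - p$open_end_trim
      n_incomplete <- 1L
      incomplete_lengths <- (H - p$open_end_trim) - (-p$margin)
    }
    nodes2 <- rbind(cbind(xs, 0), cbind(xs, H))
    edges <- cbind(seq_len(p$n_bands), seq_len(p$n_bands) + p$n_bands)
    n_cycles <- 0L
  } else {  # smooth
    W <- p$m * p$R * 4; H <- p$n * p$R * 3
    nodes2 <- matrix(0, 0, 2)
  }

  if (pattern == "polygonal_lattice" && p$open_end_trim > 0) {
    ## shorten the last rendered segment at its second endpoint: creates a
    ## groove end dangling inside a domain -> one incomplete edge
    r <- nrow(segs)
    v <- c(segs[r, 3] - segs[r, 1], segs[r, 4] - segs[r, 2])
    L <- sqrt(sum(v^2)); tfrac <- max(0.1, 1 - p$open_end_trim / L)
    segs[r, 3:4] <- segs[r, 1:2] + tfrac * v
    n_incomplete <- 1L
    incomplete_lengths <- L * tfrac
    ## the trimmed edge leaves the cycle it bounded broken only if it was
    ## a cycle edge; recompute rank without that edge
    n_cycles <- graph_cycle_rank(nrow(nodes2), edges[-nrow(edges), , drop = FALSE])
  }

  if (pattern %in% c("labyrinth", "elongated_bands", "smooth")) {
    W <- p$m * p$R * 4; H <- p$n * p$R * 3
    xr <- c(0 - p$margin, W + p$margin); yr <- c(0 - p$margin, H + p$margin)
  } else {
    xr <- range(nodes2[, 1]) + c(-p$margin, p$margin)
    yr <- range(nodes2[, 2]) + c(-p$margin, p$margin)
  }
  gx <- seq(xr[1], xr[2], by = p$spacing)
  gy <- seq(yr[1], yr[2], by = p$spacing)
  pg <- expand.grid(x = gx, y = gy)
  z <- if (nrow(segs) > 0) {
    d <- seg_distance_field(pg$x, pg$y, segs)
    -p$depth * exp(-(d / p$width)^2)
  } else rep(0, nrow(pg))
  zm <- matrix(z, length(gx), length(gy))
  if (p$jitter > 0) {
    zm <- zm + with_seed(seed, matrix(rnorm(length(zm), 0, p$jitter),
                                      length(gx), length(gy)))
  }
  mesh <- heightfield_mesh(gx, gy, zm)
  net <- list(nodes = nodes2, edges = edges, segments = segs,
              n_cycles = as.integer(n_cycles),
              n_incomplete = as.integer(n_incomplete),
              incomplete_lengths = incomplete_lengths)
  list(mesh = mesh,
       truth = ground_truth(network = net, pattern = pattern,
                            groove_width = if (pattern == "smooth") 0 else p$width,
                            rng_seed = seed))
}
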