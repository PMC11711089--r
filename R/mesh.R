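#' Triangle surface mesh
#'
#' @param vertices n x 3 numeric matrix, world um.
#' @param triangles m x 3 integer matrix of 1-based vertex indices.
#' @param normals optional n x 3 matrix of unit vertex normals.
#' @return Object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, triangles, normals = NULL) {
  vertices <- as.matrix(vertices); storage.mode(vertices) <- "double"
  triangles <- as.matrix(triangles); storage.mode(triangles) <- "integer"
  stopifnot(ncol(vertices) == 3L, ncol(triangles) == 3L,
            min(triangles) >= 1L, max(triangles) <= nrow(vertices))
  structure(list(vertices = vertices, triangles = triangles,
                 normals = normals), class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d triangles, area %.4g um^2\n",
              nrow(x$vertices), nrow(x$triangles), mesh_area(x)))
  invisible(x)
}

#' Total surface area (um^2)
#' @param m a [surface_mesh].
#' @export
mesh_area <- function(m) sum(triangle_areas(m))

triangle_areas <- function(m) {
  v <- m$vertices; tr <- m$triangles
  a <- v[tr[, 2], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  b <- v[tr[, 3], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

triangle_normals <- function(m) {
  v <- m$vertices; tr <- m$triangles
  a <- v[tr[, 2], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  b <- v[tr[, 3], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  n <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
             a[, 3] * b[, 1] - a[, 1] * b[, 3],
             a[, 1] * b[, 2] - a[, 2] * b[, 1])
  n / pmax(sqrt(rowSums(n^2)), .Machine$double.xmin)
}

#' Area-weighted per-vertex normals
#' @param m a [surface_mesh].
#' @return n x 3 matrix of unit normals.
#' @export
vertex_normals <- function(m) {
  tn <- triangle_normals(m) * triangle_areas(m)
  n <- matrix(0, nrow(m$vertices), 3)
  for (k in 1:3) {
    for (c in 1:3)
      n[, c] <- n[, c] + tapply_add(tn[, c], m$triangles[, k], nrow(n))
  }
  n / pmax(sqrt(rowSums(n^2)), .Machine$double.xmin)
}

tapply_add <- function(vals, idx, n) {
  out <- numeric(n)
  s <- rowsum(vals, idx)
  out[as.integer(rownames(s))] <- s
  out
}

## unique undirected edges; attr "count" = incidence multiplicity
mesh_edges <- function(m) {
  tr <- m$triangles
  e <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  key <- paste(e[, 1], e[, 2])
  cnt <- table(key)
  ue <- e[!duplicated(key), , drop = FALSE]
  attr(ue, "count") <- as.integer(cnt[paste(ue[, 1], ue[, 2])])
  ue
}

#' Boundary vertex indices of an open mesh
#' @param m a [surface_mesh].
#' @export
boundary_vertices <- function(m) {
  e <- mesh_edges(m)
  be <- e[attr(e, "count") == 1L, , drop = FALSE]
  sort(unique(as.vector(be)))
}

#' Audit a surface mesh independently of its constructor
#'
#' Checks manifoldness (each edge in at most 2 triangles), consistent
#' orientation of shared edges, and absence of degenerate triangles.
#' @param m a [surface_mesh].
#' @param tol relative area below which a triangle counts as degenerate.
#' @return list with logical `ok` and a character vector of `problems`.
#' @export
audit_surface_mesh <- function(m, tol = 1e-12) {
  problems <- character()
  ar <- triangle_areas(m)
  if (any(ar <= tol * max(ar))) problems <- c(problems, "degenerate triangles")
  e <- mesh_edges(m)
  if (any(attr(e, "count") > 2L)) problems <- c(problems, "non-manifold edges")
  ## orientation: every interior edge must appear once per direction
  tr <- m$triangles
  de <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  key <- paste(de[, 1], de[, 2])
  if (anyDuplicated(key)) problems <- c(problems, "inconsistent orientation")
  list(ok = length(problems) == 0L, problems = problems)
}

#' Height-field surface mesh over a rectangular grid
#'
#' Triangulated z = f(x, y) surface; triangles are oriented so normals
#' point towards +z (outward for a skin patch viewed from above).
#'
#' @param x,y strictly increasing coordinate vectors (um).
#' @param z matrix `length(x)` x `length(y)` of heights (um).
#' @return a [surface_mesh].
#' @export
heightfield_mesh <- function(x, y, z) {
  nx <- length(x); ny <- length(y)
  stopifnot(nrow(z) == nx, ncol(z) == ny, nx >= 2, ny >= 2)
  vid <- matrix(seq_len(nx * ny), nx, ny)
  verts <- cbind(rep(x, times = ny), rep(y, each = nx), as.vector(z))
  i <- rep(1:(nx - 1), times = ny - 1)
  j <- rep(1:(ny - 1), each = nx - 1)
  v00 <- vid[cbind(i, j)]; v10 <- vid[cbind(i + 1, j)]
  v01 <- vid[cbind(i, j + 1)]; v11 <- vid[cbind(i + 1, j + 1)]
  tris <- rbind(cbind(v00, v10, v11), cbind(v00, v11, v01))
  surface_mesh(verts, tris)
}

#' Layered tetrahedral mesh
#'
#' Reference-configuration tet mesh with per-element tissue layer and a
#' fixed-node mask marking the rigid bone/substrate boundary.
#'
#' @param nodes n x 3 reference coordinates X (um).
#' @param tets m x 4 integer matrix (1-based); positively oriented.
#' @param layer factor/character per tet: "epidermis", "dermis" or "bone".
#' @param fixed logical per node; fixed nodes do not move in simulations.
#' @return Object of class `layered_tet_mesh`.
#' @export
layered_tet_mesh <- function(nodes, tets, layer, fixed) {
  nodes <- as.matrix(nodes); storage.mode(nodes) <- "double"
  tets <- as.matrix(tets); storage.mode(tets) <- "integer"
  layer <- factor(as.character(layer),
                  levels = c("epidermis", "dermis", "bone"))
  stopifnot(ncol(nodes) == 3L, ncol(tets) == 4L, length(layer) == nrow(tets),
            !anyNA(layer), length(fixed) == nrow(nodes))
  vol <- tet_volumes(nodes, tets)
  flip <- vol < 0
  if (any(flip)) {  # reorient negative tets
    tets[flip, c(3, 4)] <- tets[flip, c(4, 3)]
    vol <- abs(vol)
  }
  if (any(vol <= 0)) stop("degenerate tetrahedra in mesh")
  structure(list(nodes = nodes, tets = tets, layer = layer,
                 fixed = as.logical(fixed)), class = "layered_tet_mesh")
}

#' @export
print.layered_tet_mesh <- function(x, ...) {
  tb <- table(x$layer)
  cat(sprintf("<layered_tet_mesh> %d nodes (%d fixed), %d tets [%s]\n",
              nrow(x$nodes), sum(x$fixed), nrow(x$tets),
              paste(sprintf("%s: %d", names(tb), tb), collapse = ", ")))
  invisible(x)
}

#' Signed tetrahedron volumes
#' @param nodes n x 3 coordinates; @param tets m x 4 indices.
#' @export
tet_volumes <- function(nodes, tets) {
  a <- nodes[tets[, 2], , drop = FALSE] - nodes[tets[, 1], , drop = FALSE]
  b <- nodes[tets[, 3], , drop = FALSE] - nodes[tets[, 1], , drop = FALSE]
  c <- nodes[tets[, 4], , drop = FALSE] - nodes[tets[, 1], , drop = FALSE]
  (a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) +
   a[, 2] * (b[, 3] * c[, 1] - b[, 1] * c[, 3]) +
   a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])) / 6
}

#' Audit a tetrahedral mesh independently of its constructors
#'
#' Positive volumes, label completeness, conformity (each interior
#' triangular face shared by exactly two tets).
#' @param tm a [layered_tet_mesh].
#' @return list with `ok`, `problems`, and face statistics.
#' @export
audit_tet_mesh <- function(tm) {
  problems <- character()
  vol <- tet_volumes(tm$nodes, tm$tets)
  if (any(vol <= 0)) problems <- c(problems, "non-positive tet volumes")
  if (anyNA(tm$layer)) problems <- c(problems, "unlabelled tets")
  tt <- tm$tets
  faces <- rbind(tt[, c(1, 2, 3)], tt[, c(1, 2, 4)],
                 tt[, c(1, 3, 4)], tt[, c(2, 3, 4)])
  key <- sorted_face_key(faces)
  cnt <- table(key)
  if (any(cnt > 2)) problems <- c(problems, "face shared by > 2 tets")
  list(ok = length(problems) == 0L, problems = problems,
       n_boundary_faces = sum(cnt == 1), n_interior_faces = sum(cnt == 2))
}

#' Boundary (free-surface) triangles of a tet mesh
#'
#' Outward-oriented boundary faces; optionally restricted to faces not on
#' fixed (bone) nodes.
#' @param tm a [layered_tet_mesh].
#' @param free_only drop faces whose three nodes are all fixed.
#' @return m x 3 integer matrix of outward-oriented triangles.
#' @export
boundary_triangles <- function(tm, free_only = FALSE) {
  tt <- tm$tets
  ## faces ordered so the outward normal convention holds for positive tets
  f <- rbind(tt[, c(1, 3, 2)], tt[, c(1, 2, 4)], tt[, c(2, 3, 4)], tt[, c(1, 4, 3)])
  skey <- sorted_face_key(f)
  cnt <- table(skey)
  bf <- f[skey %in% names(cnt)[cnt == 1], , drop = FALSE]
  if (free_only) bf <- bf[!(tm$fixed[bf[, 1]] & tm$fixed[bf[, 2]] & tm$fixed[bf[, 3]]), , drop = FALSE]
  bf
}

## Kuhn 6-tet subdivision of the unit cube; conforming across a grid.
## Rows give local corner ids of an nx x ny x nz vertex grid corner cube,
## corner id = 1 + dx + 2*dy + 4*dz.
kuhn_tets <- function() {
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  corner <- function(d) 1L + d[1] + 2L * d[2] + 4L * d[3]
  out <- matrix(0L, 6, 4)
  for (p in seq_len(6)) {
    d <- c(0L, 0L, 0L); path <- corner(d)
    for (ax in perms[p, ]) { d[ax] <- 1L; path <- c(path, corner(d)) }
    out[p, ] <- path
  }
  out
}

## Structured tet grid from vertex positions on an (nx, ny, nz) lattice.
## `pos` is a function(i, j, k) -> n x 3 matrix for vectors i, j, k.
structured_tet_grid <- function(nx, ny, nz, pos) {
  vid <- array(seq_len(nx * ny * nz), c(nx, ny, nz))
  ijk <- as.matrix(expand.grid(i = 1:nx, j = 1:ny, k = 1:nz))
  nodes <- pos(ijk[, 1], ijk[, 2], ijk[, 3])
  cells <- as.matrix(expand.grid(i = 1:(nx - 1), j = 1:(ny - 1), k = 1:(nz - 1)))
  kt <- kuhn_tets()
  corner_off <- cbind(dx = c(0, 1, 0, 1, 0, 1, 0, 1),
                      dy = c(0, 0, 1, 1, 0, 0, 1, 1),
                      dz = c(0, 0, 0, 0, 1, 1, 1, 1))
  cid <- matrix(0L, nrow(cells), 8)
  for (c8 in 1:8)
    cid[, c8] <- vid[cbind(cells[, 1] + corner_off[c8, 1],
                           cells[, 2] + corner_off[c8, 2],
                           cells[, 3] + corner_off[c8, 3])]
  tets <- do.call(rbind, lapply(1:6, function(p) cid[, kt[p, ], drop = FALSE]))
  cell_of_tet <- rep(seq_len(nrow(cells)), times = 6)
  list(nodes = nodes, tets = tets, cells = cells, cell_of_tet = cell_of_tet,
       vid = vid)
}

#' Reverse the orientation of a surface mesh
#' @param m a [surface_mesh].
#' @return the mesh with flipped triangle winding (and normals, if any).
#' @export
flip_surface <- function(m) {
  surface_mesh(m$vertices, m$triangles[, c(1, 3, 2), drop = FALSE],
               normals = if (!is.null(m$normals)) -m$normals)
}

## vectorized canonical key of triangular faces (rows sorted ascending)
sorted_face_key <- function(f) {
  a <- pmin(f[, 1], f[, 2], f[, 3])
  c <- pmax(f[, 1], f[, 2], f[, 3])
  b <- f[, 1] + f[, 2] + f[, 3] - a - c
  paste(a, b, c)
}
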