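#' Write a surface mesh as ASCII PLY or OFF
#'
#' @param m a [surface_mesh]; @param path output path; format chosen by
#'   extension (`.ply` or `.off`).
#' @export
write_surface_mesh <- function(m, path) {
  nv <- nrow(m$vertices); nt <- nrow(m$triangles)
  if (grepl("\\.off$", path, ignore.case = TRUE)) {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(c("OFF", sprintf("%d %d 0", nv, nt)), con)
    utils::write.table(format(m$vertices, digits = 10, trim = TRUE), con,
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
    utils::write.table(cbind(3L, m$triangles - 1L), con, row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
  } else {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(c("ply", "format ascii 1.0",
                 sprintf("element vertex %d", nv),
                 "property float x", "property float y", "property float z",
                 sprintf("element face %d", nt),
                 "property list uchar int vertex_indices", "end_header"),
               con)
    utils::write.table(format(m$vertices, digits = 10, trim = TRUE), con,
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
    utils::write.table(cbind(3L, m$triangles - 1L), con, row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read an ASCII OFF surface mesh
#' @param path input `.off` path.
#' @return a [surface_mesh].
#' @export
read_surface_off <- function(path) {
  ln <- readLines(path)
  ln <- ln[!grepl("^\\s*(#|$)", ln)]
  stopifnot(trimws(ln[1]) == "OFF")
  hdr <- as.integer(strsplit(trimws(ln[2]), "\\s+")[[1]])
  nv <- hdr[1]; nt <- hdr[2]
  verts <- do.call(rbind, lapply(ln[3:(2 + nv)], function(s)
    as.numeric(strsplit(trimws(s), "\\s+")[[1]][1:3])))
  tris <- do.call(rbind, lapply(ln[(3 + nv):(2 + nv + nt)], function(s)
    as.integer(strsplit(trimws(s), "\\s+")[[1]][2:4]) + 1L))
  surface_mesh(verts, tris)
}

#' Write a layered tet mesh (and optional state) as legacy ASCII VTK
#'
#' Unstructured grid with per-cell integer `layer` (1 = epidermis,
#' 2 = dermis, 3 = bone) and optional per-cell scalars.
#'
#' @param tm a [layered_tet_mesh]; @param path output `.vtk` path.
#' @param x node positions (default reference).
#' @param cell_scalars optional named list of per-tet numeric vectors.
#' @export
write_vtk_tet <- function(tm, path, x = NULL, cell_scalars = list()) {
  if (is.null(x)) x <- tm$nodes
  nv <- nrow(x); nt <- nrow(tm$tets)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "layered tet mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nv)), con)
  utils::write.table(format(x, digits = 10, trim = TRUE), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELLS %d %d", nt, nt * 5), con)
  utils::write.table(cbind(4L, tm$tets - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  writeLines(c(sprintf("CELL_TYPES %d", nt),
               paste(rep(10L, nt), collapse = "\n"),
               sprintf("CELL_DATA %d", nt),
               "SCALARS layer int 1", "LOOKUP_TABLE default",
               paste(as.integer(tm$layer), collapse = "\n")), con)
  for (nm in names(cell_scalars)) {
    writeLines(c(sprintf("SCALARS %s double 1", nm),
                 "LOOKUP_TABLE default",
                 paste(format(cell_scalars[[nm]], digits = 10),
                       collapse = "\n")), con)
  }
  invisible(path)
}

#' Serialize a fold network (or ground truth) as JSON
#'
#' @param net a `fold_network`; @param path output `.json` path.
#' @export
write_network_json <- function(net, path) {
  obj <- list(
    nodes = unname(apply(net$nodes, 1, as.numeric, simplify = FALSE)),
    anchored = net$anchored,
    n_cycles = net$n_cycles,
    n_incomplete = net$n_incomplete,
    edges = lapply(net$edges, function(e)
      list(from = e$from, to = e$to, status = e$status, length = e$length,
           polyline = unname(apply(e$polyline, 1, as.numeric,
                                   simplify = FALSE)))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
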