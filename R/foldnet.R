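#' Principal curvatures of a surface mesh
#'
#' Local quadric fit over the k-ring neighbourhood of each vertex, in the
#' frame of the vertex normal. The sign convention follows the derivative
#' of the supplied normal field: with outward normals, concave grooves
#' (inward folds) have `kappa_min < 0` and convex bumps are positive;
#' meshes oriented with inward normals flip the sign accordingly.
#'
#' @param m a [surface_mesh].
#' @param ring neighbourhood ring order (>= 1).
#' @return list with per-vertex `kmin`, `kmax` (kmin <= kmax).
#' @export
surface_principal_curvatures <- function(m, ring = 2L) {
  V <- m$vertices
  n <- nrow(V)
  nrm <- m$normals %||% vertex_normals(m)
  adj <- adjacency_list(m)
  kmin <- numeric(n); kmax <- numeric(n)
  for (v in seq_len(n)) {
    nb <- kring_neighbors(adj, v, ring)
    if (length(nb) < 5) { kmin[v] <- 0; kmax[v] <- 0; next }
    nv <- unit(nrm[v, ])
    ## local tangent frame
    t1 <- if (abs(nv[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    t1 <- unit(t1 - sum(t1 * nv) * nv)
    t2 <- c(nv[2] * t1[3] - nv[3] * t1[2], nv[3] * t1[1] - nv[1] * t1[3],
            nv[1] * t1[2] - nv[2] * t1[1])
    rel <- sweep(V[nb, , drop = FALSE], 2, V[v, ])
    u <- rel %*% t1; w2 <- rel %*% t2; h <- rel %*% nv
    X <- cbind(u^2, u * w2, w2^2, u, w2)
    cf <- tryCatch(qr.solve(X, h), error = function(e) rep(0, 5))
    H2 <- matrix(c(2 * cf[1], cf[2], cf[2], 2 * cf[3]), 2, 2)
    ev <- eigen(H2, symmetric = TRUE, only.values = TRUE)$values
    ## bending toward the normal (concave) = negative curvature
    kk <- -ev
    kmin[v] <- min(kk); kmax[v] <- max(kk)
  }
  list(kmin = kmin, kmax = kmax)
}

adjacency_list <- function(m) {
  e <- mesh_edges(m)
  n <- nrow(m$vertices)
  split(c(e[, 2], e[, 1]), factor(c(e[, 1], e[, 2]), levels = seq_len(n)))
}

kring_neighbors <- function(adj, v, ring) {
  cur <- v; seen <- v
  for (r in seq_len(ring)) {
    cur <- unique(unlist(adj[cur], use.names = FALSE))
    cur <- setdiff(cur, seen)
    seen <- c(seen, cur)
    if (length(cur) == 0) break
  }
  setdiff(seen, v)
}

#' Fold mask from curvature thresholding
#'
#' Vertices with `kappa_min < -threshold`; connected components (on the
#' mesh graph) smaller than `min_component` vertices are dropped.
#'
#' @param m a [surface_mesh].
#' @param curvatures output of [surface_principal_curvatures].
#' @param threshold positive curvature threshold (1 / um).
#' @param min_component minimum component size in vertices.
#' @param border_exclude rings of vertices next to the mesh boundary to
#'   drop (the one-sided quadric fit is unreliable there).
#' @return integer vector of masked vertex indices.
#' @export
fold_mask <- function(m, curvatures, threshold, min_component = 6L,
                      border_exclude = 2L) {
  sel <- which(curvatures$kmin < -threshold)
  if (border_exclude > 0) {
    adj <- adjacency_list(m)
    collar <- boundary_vertices(m)
    frontier <- collar
    for (r in seq_len(border_exclude - 1L)) {
      frontier <- setdiff(unique(unlist(adj[frontier], use.names = FALSE)),
                          collar)
      collar <- c(collar, frontier)
    }
    sel <- setdiff(sel, collar)
  }
  if (length(sel) == 0) return(integer(0))
  e <- mesh_edges(m)
  keep_e <- e[e[, 1] %in% sel & e[, 2] %in% sel, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(keep_e[, 1]),
               to = as.character(keep_e[, 2])),
    directed = FALSE,
    vertices = data.frame(name = as.character(sel)))
  comp <- igraph::components(g)
  big <- which(comp$csize >= min_component)
  sel[comp$membership %in% big]
}

#' Skeletonize a masked surface region to centerline curves
#'
#' Iterative topology-preserving thinning on the mesh graph: mask-boundary
#' vertices are removed (least-negative curvature first) when their masked
#' 1-ring stays connected without them and they are not curve endpoints,
#' until no vertex can be removed. Output nodes are mesh vertices, edges
#' are mesh edges.
#'
#' @param m a [surface_mesh].
#' @param mask integer vertex indices (from [fold_mask]).
#' @param priority per-vertex removal priority (higher removed first);
#'   default `kappa_min` is recommended.
#' @return list: `vertices` (kept indices), `edges` (2-col matrix of kept
#'   mesh edges), `positions`.
#' @export
skeletonize <- function(m, mask, priority = NULL) {
  if (length(mask) == 0)
    return(list(vertices = integer(0), edges = matrix(0L, 0, 2),
                positions = matrix(0, 0, 3)))
  adj <- adjacency_list(m)
  n <- nrow(m$vertices)
  inmask <- logical(n); inmask[mask] <- TRUE
  if (is.null(priority)) priority <- rep(0, n)
  repeat {
    changed <- FALSE
    ## boundary candidates: masked with at least one unmasked neighbour
    cand <- mask[vapply(mask, function(v) any(!inmask[adj[[v]]]), logical(1))]
    cand <- cand[order(priority[cand], decreasing = TRUE)]
    for (v in cand) {
      mn <- adj[[v]][inmask[adj[[v]]]]
      if (length(mn) <= 1) next              # endpoint: keep
      ## local connectivity of the masked 1-ring without v
      sub <- mn
      se <- NULL
      for (a in sub) {
        common <- intersect(adj[[a]], sub)
        common <- common[common > a]
        if (length(common))
          se <- rbind(se, cbind(a, common))
      }
      if (is.null(se)) next                  # removal would disconnect
      g <- igraph::graph_from_data_frame(
        data.frame(from = as.character(se[, 1]),
                   to = as.character(se[, 2])), directed = FALSE,
        vertices = data.frame(name = as.character(sub)))
      if (igraph::count_components(g) > 1) next
      inmask[v] <- FALSE
      changed <- TRUE
    }
    mask <- which(inmask)
    if (!changed) break
  }
  kept <- which(inmask)
  e <- mesh_edges(m)
  ke <- e[inmask[e[, 1]] & inmask[e[, 2]], , drop = FALSE]
  list(vertices = kept, edges = unclass(ke)[, 1:2, drop = FALSE],
       positions = m$vertices[kept, , drop = FALSE])
}

#' Simplify a raw centerline graph into a fold network
#'
#' Merges degree-2 chains into polyline edges, prunes short spurs
#' iteratively, merges near-coincident junctions, anchors curve ends that
#' reach the mesh border, classifies edges (complete / incomplete /
#' floating) and counts cycles on the complete-edge graph.
#'
#' @param raw output of [skeletonize].
#' @param m the host [surface_mesh].
#' @param prune_len spur-pruning length (um); default 2 x mean mesh edge.
#' @param collapse_tol junction-merge distance (um); default 1 mean edge.
#' @return object of class `fold_network`: `nodes` (positions +
#'   `anchored` flag), `edges` (list with polyline, length, endpoints,
#'   status), `n_cycles`, `n_incomplete`.
#' @export
simplify_graph <- function(raw, m, prune_len = NULL, collapse_tol = NULL) {
  mean_el <- mean(sqrt(rowSums((m$vertices[mesh_edges(m)[, 1], ] -
                                m$vertices[mesh_edges(m)[, 2], ])^2)))
  if (is.null(prune_len)) prune_len <- 2 * mean_el
  if (is.null(collapse_tol)) collapse_tol <- mean_el
  border <- boundary_vertices(m)
  bpos <- m$vertices[border, , drop = FALSE]
  anchor_dist <- 4 * mean_el
  near_border <- function(vtx) {
    if (length(border) == 0) return(FALSE)
    min(sqrt(rowSums(sweep(bpos, 2, m$vertices[vtx, ])^2))) < anchor_dist
  }
  empty_net <- function() structure(
    list(nodes = matrix(0, 0, 3), anchored = logical(0), edges = list(),
         n_cycles = 0L, n_incomplete = 0L, mesh = m), class = "fold_network")
  if (length(raw$vertices) == 0 || nrow(raw$edges) == 0) return(empty_net())

  V <- m$vertices
  elen <- function(a, b) sqrt(sum((V[a, ] - V[b, ])^2))
  ## chord cleaning: thinning on a triangle mesh leaves zigzag 3-cycles;
  ## iteratively drop the longest edge of every remaining triangle
  repeat {
    gg <- igraph::graph_from_edgelist(
      matrix(as.character(raw$edges), ncol = 2), directed = FALSE)
    tri <- matrix(as.integer(igraph::V(gg)$name[igraph::triangles(gg)]),
                  ncol = 3, byrow = TRUE)
    if (nrow(tri) == 0) break
    drop <- unique(t(apply(tri, 1, function(tv) {
      pairs <- rbind(tv[c(1, 2)], tv[c(2, 3)], tv[c(1, 3)])
      lens <- apply(pairs, 1, function(p) elen(p[1], p[2]))
      sort(pairs[which.max(lens), ])
    })))
    rk <- paste(pmin(raw$edges[, 1], raw$edges[, 2]),
                pmax(raw$edges[, 1], raw$edges[, 2]))
    dk <- paste(drop[, 1], drop[, 2])
    raw$edges <- raw$edges[!(rk %in% dk), , drop = FALSE]
    if (nrow(raw$edges) == 0) return(empty_net())
  }
  ## small-loop cleaning: skeleton artifacts (e.g. at hairpin turns) form
  ## short spurious cycles far below the scale of real fold domains;
  ## break any cycle shorter than min_cycle_len at its longest edge
  min_cycle_len <- 8 * mean_el
  repeat {
    gg <- igraph::graph_from_edgelist(
      matrix(as.character(raw$edges), ncol = 2), directed = FALSE)
    igraph::E(gg)$weight <- 1
    gi <- igraph::girth(gg, circle = TRUE)
    if (!is.finite(gi$girth) || length(gi$circle) == 0) break
    cyc <- as.integer(igraph::V(gg)$name[gi$circle])
    cyc2 <- c(cyc, cyc[1])
    arclen <- sum(vapply(seq_along(cyc), function(i)
      elen(cyc2[i], cyc2[i + 1]), numeric(1)))
    if (arclen >= min_cycle_len) break
    li <- which.max(vapply(seq_along(cyc), function(i)
      elen(cyc2[i], cyc2[i + 1]), numeric(1)))
    dk <- paste(min(cyc2[li], cyc2[li + 1]), max(cyc2[li], cyc2[li + 1]))
    rk <- paste(pmin(raw$edges[, 1], raw$edges[, 2]),
                pmax(raw$edges[, 1], raw$edges[, 2]))
    raw$edges <- raw$edges[rk != dk, , drop = FALSE]
    if (nrow(raw$edges) == 0) return(empty_net())
  }
  repeat {
    g <- igraph::graph_from_edgelist(
      matrix(as.character(raw$edges), ncol = 2), directed = FALSE)
    vid <- as.integer(igraph::V(g)$name)
    deg <- igraph::degree(g)
    term <- vid[deg != 2]                      # junctions + endpoints
    ## walk chains between terminals (or around pure cycles)
    adjr <- lapply(igraph::adjacent_vertices(g, igraph::V(g)),
                   function(a) as.integer(names(a)))
    names(adjr) <- igraph::V(g)$name
    visited_e <- new.env(parent = emptyenv())
    ekey <- function(a, b) paste(min(a, b), max(a, b))
    chains <- list()
    walk <- function(start, nxt) {
      path <- c(start, nxt)
      assign(ekey(start, nxt), TRUE, envir = visited_e)
      while (!(tail(path, 1) %in% term)) {
        cur <- tail(path, 1)
        prev <- path[length(path) - 1]
        nbs <- adjr[[as.character(cur)]]
        nb <- setdiff(nbs, prev)
        if (length(nb) == 0) break
        if (length(nb) > 1) nb <- nb[1]
        if (isTRUE(get0(ekey(cur, nb), envir = visited_e))) break
        assign(ekey(cur, nb), TRUE, envir = visited_e)
        path <- c(path, nb)
        if (nb == start) break                 # closed loop
      }
      path
    }
    for (tv in term)
      for (nb in adjr[[as.character(tv)]])
        if (!isTRUE(get0(ekey(tv, nb), envir = visited_e)))
          chains[[length(chains) + 1L]] <- walk(tv, nb)
    ## pure cycles with no terminal vertex
    for (sv in vid[deg == 2]) {
      nbs <- adjr[[as.character(sv)]]
      for (nb in nbs)
        if (!isTRUE(get0(ekey(sv, nb), envir = visited_e))) {
          ch <- walk(sv, nb)
          if (tail(ch, 1) == sv) chains[[length(chains) + 1L]] <- ch
        }
    }
    if (length(chains) == 0) return(empty_net())
    chain_len <- vapply(chains, function(ch)
      sum(sqrt(rowSums((V[ch[-1], , drop = FALSE] -
                        V[ch[-length(ch)], , drop = FALSE])^2))), numeric(1))
    ## spur = chain with a free (degree-1, non-border) end
    degmap <- stats::setNames(deg, igraph::V(g)$name)
    end_free <- function(vtx) degmap[as.character(vtx)] == 1 &&
      !near_border(vtx)
    spur <- vapply(chains, function(ch)
      end_free(ch[1]) || end_free(tail(ch, 1)), logical(1)) &
      chain_len < prune_len
    if (!any(spur)) break
    drop_edges <- do.call(rbind, lapply(chains[spur], function(ch)
      cbind(ch[-length(ch)], ch[-1])))
    dk <- paste(pmin(drop_edges[, 1], drop_edges[, 2]),
                pmax(drop_edges[, 1], drop_edges[, 2]))
    rk <- paste(pmin(raw$edges[, 1], raw$edges[, 2]),
                pmax(raw$edges[, 1], raw$edges[, 2]))
    raw$edges <- raw$edges[!(rk %in% dk), , drop = FALSE]
    if (nrow(raw$edges) == 0) return(empty_net())
  }

  ## junction nodes = chain endpoints; merge near-coincident junctions
  endpts <- unique(unlist(lapply(chains, function(ch) c(ch[1], tail(ch, 1)))))
  jpos <- V[endpts, , drop = FALSE]
  grp <- seq_along(endpts)
  if (length(endpts) > 1) {
    dd <- as.matrix(stats::dist(jpos))
    gj <- igraph::graph_from_adjacency_matrix(dd < collapse_tol,
                                              mode = "undirected")
    grp <- igraph::components(gj)$membership
  }
  node_of <- stats::setNames(grp, endpts)
  nodes <- t(vapply(seq_len(max(grp)), function(k)
    colMeans(jpos[grp == k, , drop = FALSE]), numeric(3)))
  anchored <- vapply(seq_len(max(grp)), function(k)
    any(vapply(endpts[grp == k], near_border, logical(1))), logical(1))
  degmap <- stats::setNames(igraph::degree(g), igraph::V(g)$name)
  edges <- lapply(chains, function(ch) {
    a <- ch[1]; b <- tail(ch, 1)
    na <- node_of[as.character(a)]; nb <- node_of[as.character(b)]
    poly <- V[ch, , drop = FALSE]
    ## light endpoint-pinned smoothing removes the mesh-edge zigzag that
    ## would otherwise inflate arclength and turning
    if (nrow(poly) >= 5) {
      for (it in 1:6) {
        inner <- 2:(nrow(poly) - 1)
        poly[inner, ] <- 0.5 * poly[inner, ] +
          0.25 * (poly[inner - 1, ] + poly[inner + 1, ])
      }
    }
    len <- sum(sqrt(rowSums((poly[-1, , drop = FALSE] -
                             poly[-nrow(poly), , drop = FALSE])^2)))
    free_a <- degmap[as.character(a)] == 1 && !near_border(a)
    free_b <- degmap[as.character(b)] == 1 && !near_border(b)
    status <- if (!free_a && !free_b) "complete"
              else if (xor(free_a, free_b)) "incomplete" else "floating"
    list(from = unname(na), to = unname(nb), polyline = poly,
         length = len, status = status)
  })
  ## drop zero-length self-loops created by junction merging
  edges <- Filter(function(e) !(e$from == e$to && e$length < collapse_tol),
                  edges)
  st <- vapply(edges, `[[`, character(1), "status")
  comp_e <- do.call(rbind, lapply(edges[st == "complete"], function(e)
    c(e$from, e$to)))
  n_cycles <- if (is.null(comp_e)) 0L else {
    gc <- igraph::graph_from_edgelist(matrix(as.character(comp_e), ncol = 2),
                                      directed = FALSE)
    as.integer(igraph::ecount(gc) - igraph::vcount(gc) +
               igraph::count_components(gc))
  }
  structure(list(nodes = nodes, anchored = anchored, edges = edges,
                 n_cycles = n_cycles,
                 n_incomplete = sum(st == "incomplete"), mesh = m),
            class = "fold_network")
}

#' @export
print.fold_network <- function(x, ...) {
  st <- vapply(x$edges, `[[`, character(1), "status")
  cat(sprintf(
    "<fold_network> %d nodes, %d edges (%d complete, %d incomplete), %d cycles\n",
    nrow(x$nodes), length(x$edges), sum(st == "complete"),
    x$n_incomplete, x$n_cycles))
  invisible(x)
}

#' Extract the fold network of a surface in one call
#'
#' Curvature, thresholding, thinning and graph simplification chained;
#' see the individual stages for details.
#'
#' @param m a [surface_mesh].
#' @param threshold curvature threshold; `NULL` = `0.25 / mean mesh
#'   edge length`: a groove is a concave feature whose radius of
#'   curvature is below about four mesh edges. Resolution-scaled, so it
#'   works unchanged on shallow carved fixtures and on deeply creased
#'   simulation output; empty network on near-flat surfaces.
#' @param ring curvature neighbourhood ring.
#' @param min_component minimum masked component size.
#' @param prune_len,collapse_tol see [simplify_graph].
#' @return a `fold_network`.
#' @export
extract_fold_network <- function(m, threshold = NULL, ring = 2L,
                                 min_component = 6L, prune_len = NULL,
                                 collapse_tol = NULL) {
  cur <- surface_principal_curvatures(m, ring)
  if (is.null(threshold)) {
    mean_el <- mean(sqrt(rowSums((m$vertices[mesh_edges(m)[, 1], ] -
                                  m$vertices[mesh_edges(m)[, 2], ])^2)))
    scale_k <- stats::quantile(-cur$kmin, 0.999)
    flat_k <- 0.02 / mean_el           # curvature noise floor
    if (scale_k < flat_k) return(simplify_graph(
      list(vertices = integer(0), edges = matrix(0L, 0, 2)), m))
    threshold <- 0.25 / mean_el
  }
  mask <- fold_mask(m, cur, threshold, min_component)
  raw <- skeletonize(m, mask, priority = cur$kmin)
  simplify_graph(raw, m, prune_len, collapse_tol)
}

## planar faces of the complete-edge subnetwork via angular rotation
## system in the dominant (PCA) plane; returns list of face perimeters,
## outer face removed
domain_perimeters <- function(net) {
  st <- vapply(net$edges, `[[`, character(1), "status")
  ce <- which(st == "complete")
  if (length(ce) == 0 || net$n_cycles == 0) return(numeric(0))
  ## project to dominant plane
  allp <- do.call(rbind, lapply(net$edges[ce], `[[`, "polyline"))
  pc <- stats::prcomp(allp)
  proj <- function(p) sweep(p, 2, pc$center) %*% pc$rotation[, 1:2]
  ## halfedges: (edge, direction); at each node order by departure angle
  he_node <- list(); he_ang <- list(); he_edge <- integer(0)
  he_from <- integer(0)
  for (ei in ce) {
    e <- net$edges[[ei]]
    p2 <- proj(e$polyline)
    a_fwd <- atan2(p2[2, 2] - p2[1, 2], p2[2, 1] - p2[1, 1])
    nr <- nrow(p2)
    a_bwd <- atan2(p2[nr - 1, 2] - p2[nr, 2], p2[nr - 1, 1] - p2[nr, 1])
    he_edge <- c(he_edge, ei, ei)
    he_from <- c(he_from, e$from, e$to)
    he_ang <- c(he_ang, a_fwd, a_bwd)
  }
  he_ang <- unlist(he_ang)
  nhe <- length(he_edge)
  twin <- ifelse(seq_len(nhe) %% 2 == 1, seq_len(nhe) + 1, seq_len(nhe) - 1)
  ## next(h): at the head node of h (= from of twin), the halfedge
  ## clockwise-next after twin
  nxt <- integer(nhe)
  for (h in seq_len(nhe)) {
    node <- he_from[twin[h]]
    cand <- which(he_from == node)
    ref <- he_ang[twin[h]]
    da <- (he_ang[cand] - ref) %% (2 * pi)
    da[da < 1e-9] <- 2 * pi
    nxt[h] <- cand[which.min(da)]
  }
  visited <- logical(nhe)
  faces <- list()
  for (h0 in seq_len(nhe)) {
    if (visited[h0]) next
    h <- h0; face_h <- integer(0)
    repeat {
      visited[h] <- TRUE
      face_h <- c(face_h, h)
      h <- nxt[h]
      if (h == h0 || visited[h]) break
    }
    faces[[length(faces) + 1L]] <- face_h
  }
  per <- vapply(faces, function(fh)
    sum(vapply(fh, function(h) net$edges[[he_edge[h]]]$length, numeric(1))),
    numeric(1))
  ## signed area to identify the outer face (negative orientation in the
  ## rotation-system convention may vary; drop the largest-perimeter face)
  if (length(per) > 1) per <- per[-which.max(per)]
  per
}

#' Metrics vector of a fold network
#'
#' Means of: number of domains (cycles), domain perimeter, edge length,
#' edge curvature (mean absolute discrete turning per unit length) and
#' incomplete-edge length — normalized by the bounding-box diagonal `D`
#' so every component is scale invariant: lengths are divided by `D`,
#' curvature multiplied by `D`, and the domain count divided by
#' `area / D^2`.
#'
#' @param net a `fold_network`.
#' @param bbox_diagonal override the bounding-box diagonal (um);
#'   default from the host mesh.
#' @return named numeric vector of class `metrics_vector` with
#'   components `n_domains`, `domain_perimeter`, `edge_length`,
#'   `edge_curvature`, `incomplete_length`.
#' @export
network_metrics <- function(net, bbox_diagonal = NULL) {
  m <- net$mesh
  bb <- apply(m$vertices, 2, range)
  D <- bbox_diagonal %||% sqrt(sum((bb[2, ] - bb[1, ])^2))
  area <- mesh_area(m)
  st <- vapply(net$edges, `[[`, character(1), "status")
  lens <- vapply(net$edges, `[[`, numeric(1), "length")
  curv <- vapply(net$edges, function(e) polyline_turning(e$polyline),
                 numeric(1))
  per <- domain_perimeters(net)
  out <- c(
    n_domains = net$n_cycles / (area / D^2),
    domain_perimeter = if (length(per)) mean(per) / D else 0,
    edge_length = if (length(lens)) mean(lens) / D else 0,
    edge_curvature = if (length(lens)) mean(curv) * D else 0,
    incomplete_length = if (any(st == "incomplete"))
      mean(lens[st == "incomplete"]) / D else 0)
  structure(out, class = "metrics_vector", diag = D, area = area,
            total_edge_length = sum(lens))
}

## mean absolute turning angle per unit length along a polyline
polyline_turning <- function(poly) {
  if (nrow(poly) < 3) return(0)
  seg <- poly[-1, , drop = FALSE] - poly[-nrow(poly), , drop = FALSE]
  sl <- sqrt(rowSums(seg^2))
  keep <- sl > 1e-12
  seg <- seg[keep, , drop = FALSE]; sl <- sl[keep]
  if (nrow(seg) < 2) return(0)
  u <- seg / sl
  cosang <- rowSums(u[-1, , drop = FALSE] * u[-nrow(u), , drop = FALSE])
  ang <- acos(pmin(1, pmax(-1, cosang)))
  sum(ang) / sum(sl)
}

#' Cohort z-score normalization of a metrics vector
#'
#' @param v a `metrics_vector`.
#' @param cohort list of `metrics_vector`s (size >= 2).
#' @return z-scored numeric vector.
#' @export
cohort_normalize <- function(v, cohort) {
  stopifnot(length(cohort) >= 2)
  M <- do.call(rbind, lapply(cohort, as.numeric))
  colnames(M) <- names(cohort[[1]])
  mu <- colMeans(M); sdv <- apply(M, 2, sd)
  bad <- names(which(sdv <= 0))
  if (length(bad))
    stop("zero-variance cohort component(s): ", paste(bad, collapse = ", "))
  (as.numeric(v) - mu) / sdv
}

#' Euclidean distance between normalized metrics vectors
#' @param a,b numeric vectors (z-scored metrics).
#' @export
metrics_distance <- function(a, b) sqrt(sum((as.numeric(a) - as.numeric(b))^2))
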