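#' Convert (bulk, shear) moduli to (Young, Poisson) and back
#'
#' Standard isotropic relations `E = 9 K mu / (3 K + mu)`,
#' `nu = (3 K - 2 mu) / (2 (3 K + mu))`.
#'
#' @param K bulk modulus; @param mu shear modulus.
#' @return `moduli_to_elastic`: list(E, nu); `elastic_to_moduli`:
#'   list(K, mu).
#' @export
moduli_to_elastic <- function(K, mu) {
  stopifnot(K > 0, mu > 0)
  list(E = 9 * K * mu / (3 * K + mu),
       nu = (3 * K - 2 * mu) / (2 * (3 * K + mu)))
}

#' @rdname moduli_to_elastic
#' @param E Young's modulus; @param nu Poisson's ratio.
#' @export
elastic_to_moduli <- function(E, nu) {
  stopifnot(E > 0, nu > -1, nu < 0.5)
  list(K = E / (3 * (1 - 2 * nu)), mu = E / (2 * (1 + nu)))
}

#' Rule-based classification of a fold pattern
#'
#' Heuristic labels for morphospace maps: `smooth` when fold density is
#' near zero; `polygonal` when the cycle (domain) density is high and
#' few edges are incomplete; `labyrinthine` when edges are dense and
#' meandering but close few domains; `elongated_bands` otherwise (long,
#' straight, mostly parallel open folds).
#'
#' @param v a `metrics_vector` from [network_metrics].
#' @param thresholds named list: `fold_density_smooth` (total edge
#'   length x D / area below which the surface counts as smooth),
#'   `cycle_density_polygonal` (n_domains component), `curvature_bands`
#'   (edge_curvature component separating straight bands from
#'   meanders).
#' @return one of `"smooth"`, `"polygonal"`, `"labyrinthine"`,
#'   `"elongated_bands"`.
#' @export
classify_pattern <- function(v, thresholds = list()) {
  th <- utils::modifyList(list(fold_density_smooth = 0.5,
                               cycle_density_polygonal = 1.5,
                               curvature_bands = 2.0), thresholds)
  D <- attr(v, "diag"); area <- attr(v, "area")
  tel <- attr(v, "total_edge_length") %||% 0
  fold_density <- if (!is.null(D) && !is.null(area)) tel * D / area
                  else as.numeric(v["edge_length"])
  if (fold_density < th$fold_density_smooth) return("smooth")
  if (as.numeric(v["n_domains"]) >= th$cycle_density_polygonal)
    return("polygonal")
  if (as.numeric(v["edge_curvature"]) >= th$curvature_bands)
    return("labyrinthine")
  "elongated_bands"
}

#' Morphospace sweep over (bulk, shear, growth)
#'
#' Simulates the flat bilayer patch over a grid of epidermal bulk
#' modulus, epidermal shear modulus and dermal tangential growth (all
#' relative to the dermis), extracts the fold network of each steady
#' state and classifies the pattern. Cells whose (K, mu) combination is
#' outside the isotropic stability triangle, or whose simulation fails,
#' are flagged.
#'
#' @param K_vals,mu_vals,G_vals grid axes (epidermal K and mu relative
#'   to dermis; dermal tangential growth ratio).
#' @param mesh fixture [layered_tet_mesh]; default small bilayer patch.
#' @param seed simulation seed.
#' @param sim_args extra arguments passed to [simulate_growth].
#' @param thresholds classification thresholds.
#' @param progress print one line per cell.
#' @return data.frame of class `morphospace_grid`: axes, E/nu, metrics
#'   components, `label`, `ok`.
#' @export
morphospace_sweep <- function(K_vals, mu_vals, G_vals, mesh = NULL,
                              seed = 1, sim_args = list(),
                              thresholds = list(), progress = FALSE) {
  if (is.null(mesh)) mesh <- make_bilayer_patch(16, 16, 1, 3, 1)
  grid <- expand.grid(K = K_vals, mu = mu_vals, G = G_vals)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    K <- grid$K[i]; mu <- grid$mu[i]; G <- grid$G[i]
    nu_ok <- (3 * K - 2 * mu) > 0 || TRUE   # nu may be <= 0; only bound 0.5
    el <- moduli_to_elastic(K, mu)
    base <- data.frame(K = K, mu = mu, G = G, E = el$E, nu = el$nu)
    if (el$nu < 0 || el$nu >= 0.5 || el$E <= 0 || !nu_ok) {
      return(cbind(base, label = "invalid", ok = FALSE,
                   n_domains = NA, domain_perimeter = NA, edge_length = NA,
                   edge_curvature = NA, incomplete_length = NA))
    }
    res <- tryCatch({
      mat <- material_params(E_epidermis = el$E, nu_epidermis = el$nu,
                             E_dermis = 1, nu_dermis = 0.45)
      spec <- growth_spec(G_derm_plus = G, epi_ratio = 0.8)
      sim <- do.call(simulate_growth,
                     c(list(mesh = mesh, mat = mat, spec = spec,
                            seed = seed), sim_args))
      surf <- deformed_surface(sim)
      net <- extract_fold_network(surf)
      v <- network_metrics(net)
      lab <- classify_pattern(v, thresholds)
      cbind(base, label = lab, ok = sim$all_converged,
            n_domains = v[["n_domains"]],
            domain_perimeter = v[["domain_perimeter"]],
            edge_length = v[["edge_length"]],
            edge_curvature = v[["edge_curvature"]],
            incomplete_length = v[["incomplete_length"]])
    }, error = function(e)
      cbind(base, label = "failed", ok = FALSE, n_domains = NA,
            domain_perimeter = NA, edge_length = NA, edge_curvature = NA,
            incomplete_length = NA))
    if (progress)
      message(sprintf("cell %d/%d: K=%.3g mu=%.3g G=%.3g -> %s",
                      i, nrow(grid), K, mu, G, res$label[1]))
    res
  })
  out <- do.call(rbind, rows)
  class(out) <- c("morphospace_grid", "data.frame")
  out
}

#' Length-weighted alignment of fold edges with an axis
#'
#' Mean absolute cosine between polyline segment directions and a given
#' axis, weighted by segment length; 1 = perfectly aligned, ~0.64 =
#' isotropic in 3D (2/pi in-plane).
#'
#' @param net a `fold_network`.
#' @param axis 3-vector (e.g. the bone-ridge direction).
#' @param region_fn optional `function(points) -> logical` restricting
#'   to a surface region (applied to segment midpoints).
#' @return scalar in [0, 1]; `NA` if no edge segments qualify.
#' @export
edge_axis_alignment <- function(net, axis = c(1, 0, 0), region_fn = NULL) {
  axis <- unit(axis)
  num <- 0; den <- 0
  for (e in net$edges) {
    p <- e$polyline
    if (nrow(p) < 2) next
    seg <- p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE]
    mid <- (p[-1, , drop = FALSE] + p[-nrow(p), , drop = FALSE]) / 2
    sl <- sqrt(rowSums(seg^2))
    keep <- sl > 1e-12
    if (!is.null(region_fn)) keep <- keep & region_fn(mid)
    if (!any(keep)) next
    cosang <- abs((seg[keep, , drop = FALSE] %*% axis) / sl[keep])
    num <- num + sum(cosang * sl[keep])
    den <- den + sum(sl[keep])
  }
  if (den == 0) return(NA_real_)
  num / den
}
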