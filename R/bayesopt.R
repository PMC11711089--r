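#' Parameter space for mechanical-parameter optimization
#'
#' Named box bounds plus a constraint mapping from the optimized vector
#' to the full model parameter set (tied values applied before every
#' objective evaluation).
#'
#' @param bounds named list of `c(lower, upper)` pairs.
#' @param to_params `function(theta)` returning
#'   `list(mat = material_params, spec = growth_spec)`.
#' @return object of class `parameter_space`.
#' @export
parameter_space <- function(bounds, to_params) {
  stopifnot(length(bounds) >= 1, all(vapply(bounds, length, 1L) == 2L),
            all(vapply(bounds, function(b) all(is.finite(b)) && b[1] < b[2],
                       logical(1))))
  structure(list(bounds = bounds, to_params = to_params,
                 dim = length(bounds), names = names(bounds)),
            class = "parameter_space")
}

#' @export
print.parameter_space <- function(x, ...) {
  cat(sprintf("<parameter_space> %d dims: %s\n", x$dim,
              paste(x$names, collapse = ", ")))
  invisible(x)
}

#' Six-parameter control preset
#'
#' Dimensions {E_epidermis, nu_epidermis, nu_dermis, G_T_dermis_plus,
#' G_T_dermis_minus, k1}, with the ties E_dermis = 1, epidermal growth at
#' 80 percent of the dermal values, and k2 = 0.
#'
#' @param bounds optional overrides of the default box.
#' @return a [parameter_space].
#' @export
control6_space <- function(bounds = NULL) {
  b <- list(E_epidermis = c(1, 50), nu_epidermis = c(0.2, 0.49),
            nu_dermis = c(0.2, 0.49), G_derm_plus = c(1.0, 1.5),
            G_derm_minus = c(1.0, 1.5), k1 = c(0, 5))
  if (!is.null(bounds)) b[names(bounds)] <- bounds
  parameter_space(b, function(theta) {
    theta <- as.numeric(theta)
    list(mat = material_params(E_epidermis = theta[1],
                               nu_epidermis = theta[2],
                               E_dermis = 1, nu_dermis = theta[3],
                               k1 = theta[6], k2 = 0),
         spec = growth_spec(G_derm_plus = theta[4],
                            G_derm_minus = theta[5], epi_ratio = 0.8))
  })
}

#' Three-parameter EGF preset
#'
#' Epidermis-only dimensions {E_epidermis, nu_epidermis, lambda_egf};
#' dermal parameters are taken unchanged from `base`.
#'
#' @param base list(mat, spec) of the control optimum.
#' @param bounds optional overrides.
#' @return a [parameter_space].
#' @export
egf3_space <- function(base, bounds = NULL) {
  b <- list(E_epidermis = c(1, 80), nu_epidermis = c(0.2, 0.49),
            lambda_egf = c(0, 0.8))
  if (!is.null(bounds)) b[names(bounds)] <- bounds
  parameter_space(b, function(theta) {
    theta <- as.numeric(theta)
    ev <- egf_variant(base$spec, base$mat, lambda_egf = theta[3],
                      E_epi_new = theta[1], nu_epi_new = theta[2])
    ev
  })
}

## ---- Gaussian process ------------------------------------------------

sq_dists <- function(A, B) {
  outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * A %*% t(B)
}

ard_kernel <- function(A, B, ls, sf2) {
  As <- sweep(A, 2, ls, `/`); Bs <- sweep(B, 2, ls, `/`)
  sf2 * exp(-0.5 * pmax(sq_dists(As, Bs), 0))
}

#' Fit a Gaussian-process surrogate
#'
#' Anisotropic squared-exponential kernel with per-dimension lengthscales
#' on inputs rescaled to the unit cube, small nugget, constant mean;
#' hyperparameters by marginal-likelihood maximization.
#'
#' @param X n x d matrix of evaluated points (original scale).
#' @param y objective values.
#' @param bounds named list of `c(lower, upper)` per dimension.
#' @param nugget observation-noise floor.
#' @param optimize_hyper maximize the log marginal likelihood (else use
#'   lengthscales 0.3, signal variance var(y)).
#' @param hyper optional list(ls, sf2) of fixed hyperparameters.
#' @return object of class `gp_posterior`; call
#'   `predict(gp, Xnew)` for `list(mean, sd)`.
#' @export
gp_fit <- function(X, y, bounds, nugget = 1e-8, optimize_hyper = TRUE,
                   hyper = NULL) {
  X <- as.matrix(X)
  d <- ncol(X); n <- nrow(X)
  lo <- vapply(bounds, `[`, numeric(1), 1)
  hi <- vapply(bounds, `[`, numeric(1), 2)
  U <- sweep(sweep(X, 2, lo), 2, hi - lo, `/`)
  mu0 <- mean(y); yc <- y - mu0
  vy <- max(stats::var(y), 1e-12)
  nll <- function(logp) {
    ls <- exp(logp[1:d]); sf2 <- exp(logp[d + 1])
    Km <- ard_kernel(U, U, ls, sf2) + diag(nugget + 1e-10 * sf2, n)
    ch <- tryCatch(chol(Km), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    alpha <- backsolve(ch, forwardsolve(t(ch), yc))
    0.5 * sum(yc * alpha) + sum(log(diag(ch))) + 0.5 * n * log(2 * pi)
  }
  p0 <- if (is.null(hyper)) c(rep(log(0.3), d), log(vy))
        else c(log(hyper$ls), log(hyper$sf2))
  if (optimize_hyper && n >= 3) {
    op <- tryCatch(stats::optim(p0, nll, method = "L-BFGS-B",
                                lower = c(rep(log(0.03), d), log(vy) - 6),
                                upper = c(rep(log(3), d), log(vy) + 6)),
                   error = function(e) list(par = p0))
    p0 <- op$par
  }
  ls <- exp(p0[1:d]); sf2 <- exp(p0[d + 1])
  Km <- ard_kernel(U, U, ls, sf2) + diag(nugget + 1e-10 * sf2, n)
  ch <- chol(Km)
  alpha <- backsolve(ch, forwardsolve(t(ch), yc))
  structure(list(U = U, ch = ch, alpha = alpha, ls = ls, sf2 = sf2,
                 mu0 = mu0, lo = lo, hi = hi, nugget = nugget),
            class = "gp_posterior")
}

#' @export
predict.gp_posterior <- function(object, Xnew, ...) {
  Xnew <- rbind(Xnew)
  Un <- sweep(sweep(Xnew, 2, object$lo), 2, object$hi - object$lo, `/`)
  Ks <- ard_kernel(Un, object$U, object$ls, object$sf2)
  mean <- object$mu0 + as.numeric(Ks %*% object$alpha)
  v <- forwardsolve(t(object$ch), t(Ks))
  var <- pmax(object$sf2 - colSums(v^2), 0)
  list(mean = mean, sd = sqrt(var))
}

#' @export
print.gp_posterior <- function(x, ...) {
  cat(sprintf("<gp_posterior> %d points, lengthscales (%s)\n",
              nrow(x$U), paste(signif(x$ls, 3), collapse = ", ")))
  invisible(x)
}

#' Expected improvement acquisition
#'
#' `EI(x) = (best - mu) Phi(z) + sigma phi(z)`, `z = (best - mu)/sigma`;
#' zero where `sigma = 0` and `mu >= best`.
#'
#' @param posterior a `gp_posterior` (or list(mean, sd) already
#'   evaluated).
#' @param best_value incumbent (minimum observed objective).
#' @param candidates matrix of candidate points.
#' @return numeric vector of non-negative acquisition values.
#' @export
expected_improvement <- function(posterior, best_value, candidates = NULL) {
  p <- if (inherits(posterior, "gp_posterior"))
    predict(posterior, candidates) else posterior
  imp <- best_value - p$mean
  s <- p$sd
  ei <- ifelse(s > 0,
               imp * pnorm(imp / s) + s * dnorm(imp / s),
               pmax(imp, 0))
  pmax(ei, 0)
}

#' Gaussian-process Bayesian optimization
#'
#' Space-filling (Latin hypercube) initial design followed by
#' expected-improvement proposals (batch >= 1 emulates parallel
#' sampling), stopping at the evaluation budget or when the best value
#' has not improved over `stop_window` evaluations. Non-finite objective
#' values are recorded with a penalty and optimization continues.
#'
#' @param objective `function(theta)` returning a scalar (smaller is
#'   better).
#' @param space a [parameter_space].
#' @param budget maximum number of evaluations.
#' @param stop_window stall window (evaluations without improvement).
#' @param batch proposals per iteration.
#' @param seed RNG seed (controls design and candidate draws).
#' @param n_candidates EI candidate pool per iteration.
#' @param init_per_dim initial design size per dimension.
#' @return object of class `bayes_opt_record`.
#' @export
bayes_optimize <- function(objective, space, budget = 150,
                           stop_window = 50, batch = 1, seed = 1,
                           n_candidates = 1000, init_per_dim = 5) {
  d <- space$dim
  lo <- vapply(space$bounds, `[`, numeric(1), 1)
  hi <- vapply(space$bounds, `[`, numeric(1), 2)
  from_unit <- function(U) sweep(sweep(U, 2, hi - lo, `*`), 2, lo, `+`)
  n_init <- min(budget, max(d + 2, init_per_dim * d))
  stopifnot(budget >= n_init)
  X <- matrix(0, 0, d); y <- numeric(0); flagged <- logical(0)
  penalty <- function() {
    fin <- y[is.finite(y)]
    if (length(fin)) max(fin) + 3 * max(stats::sd(fin), 1) else 1e6
  }
  eval_point <- function(theta) {
    val <- tryCatch(objective(theta), error = function(e) NA_real_)
    ok <- is.finite(val)
    X <<- rbind(X, theta)
    y <<- c(y, if (ok) val else NA_real_)
    flagged <<- c(flagged, !ok)
  }
  gp_hist <- list()
  gp_hyper <- NULL
  with_seed(seed, {
    U0 <- lhs::randomLHS(n_init, d)
    for (i in seq_len(n_init)) eval_point(from_unit(U0[i, , drop = FALSE]))
    stop_reason <- "budget"
    while (length(y) < budget) {
      yy <- ifelse(is.na(y), penalty(), y)
      best <- min(yy)
      best_at <- which.min(yy)
      since <- length(yy) - best_at
      if (since >= stop_window) { stop_reason <- "stalled"; break }
      ## marginal-likelihood refits are the dominant cost; refresh the
      ## hyperparameters every few acquisitions, reuse them in between
      refit <- length(y) %% 5 == 0 || is.null(gp_hyper)
      gp <- tryCatch(
        gp_fit(X, yy, space$bounds, optimize_hyper = refit,
               hyper = if (!refit) gp_hyper),
        error = function(e) NULL)
      if (!is.null(gp) && refit) gp_hyper <- list(ls = gp$ls, sf2 = gp$sf2)
      if (is.null(gp)) {
        cand <- from_unit(lhs::randomLHS(batch, d))
        for (b in seq_len(min(batch, budget - length(y))))
          eval_point(cand[b, , drop = FALSE])
        next
      }
      gp_hist[[length(gp_hist) + 1L]] <-
        list(iter = length(y), ls = gp$ls, sf2 = gp$sf2)
      cand <- from_unit(lhs::randomLHS(n_candidates, d))
      ei <- expected_improvement(gp, best, cand)
      ord <- order(ei, decreasing = TRUE)
      picks <- matrix(cand[ord[1], ], nrow = 1)
      ## greedy batch diversification in the unit cube
      if (batch > 1) {
        for (k in ord[-1]) {
          if (nrow(picks) >= batch) break
          du <- sq_dists(
            sweep(sweep(cand[k, , drop = FALSE], 2, lo), 2, hi - lo, `/`),
            sweep(sweep(picks, 2, lo), 2, hi - lo, `/`))
          if (min(du) > 0.01) picks <- rbind(picks, cand[k, ])
        }
      }
      ## local EI polish of the top pick
      neg_ei <- function(th) -expected_improvement(gp, best, rbind(th))
      pol <- tryCatch(stats::optim(picks[1, ], neg_ei, method = "L-BFGS-B",
                                   lower = lo, upper = hi),
                      error = function(e) NULL)
      if (!is.null(pol) && -pol$value > ei[ord[1]]) picks[1, ] <- pol$par
      for (b in seq_len(min(nrow(picks), budget - length(y))))
        eval_point(picks[b, , drop = FALSE])
    }
  })
  yy <- ifelse(is.na(y), penalty(), y)
  best_trace <- cummin(yy)
  rownames(X) <- NULL
  colnames(X) <- space$names
  structure(list(X = X, y = y, y_penalized = yy, flagged = flagged,
                 best_value = min(yy), best_theta = X[which.min(yy), ],
                 best_trace = best_trace, gp_history = gp_hist,
                 stop_reason = stop_reason, space = space, seed = seed),
            class = "bayes_opt_record")
}

#' @export
print.bayes_opt_record <- function(x, ...) {
  cat(sprintf(
    "<bayes_opt_record> %d evaluations (%d failed), best %.5g (%s)\n",
    length(x$y), sum(x$flagged), x$best_value, x$stop_reason))
  cat("  best:", paste(sprintf("%s = %.4g", x$space$names, x$best_theta),
                       collapse = ", "), "\n")
  invisible(x)
}

#' Build a simulation-based objective from a target metrics vector
#'
#' Closes over the simulation chain: parameters -> growth simulation on
#' the fixture mesh -> deformed-surface fold network -> metrics ->
#' cohort z-scoring -> Euclidean distance to the target. Evaluations are
#' deterministic given the configured seed; non-converged simulations
#' yield `Inf` (recorded as penalties by [bayes_optimize]).
#'
#' @param target a `metrics_vector` (un-normalized).
#' @param cohort list of `metrics_vector`s defining the z-scoring.
#' @param space a [parameter_space] (its `to_params` builds mat/spec).
#' @param mesh fixture [layered_tet_mesh].
#' @param sim_args extra arguments for [simulate_growth].
#' @param network_args extra arguments for [extract_fold_network].
#' @param penalize_nonconverged return `Inf` (a flagged penalty) when the
#'   simulation does not reach the force tolerance. The strict mode is
#'   faithful bookkeeping; the relaxed default keeps mildly unconverged
#'   but deterministic states informative, which the optimizer needs
#'   when the inner solver budget is tight. Simulation errors are always
#'   penalized.
#' @return `function(theta) -> distance`.
#' @export
objective_from_target <- function(target, cohort, space, mesh,
                                  sim_args = list(), network_args = list(),
                                  penalize_nonconverged = FALSE) {
  tnorm <- cohort_normalize(target, cohort)
  function(theta) {
    tryCatch({
      pars <- space$to_params(theta)
      sim <- do.call(simulate_growth,
                     c(list(mesh = mesh, mat = pars$mat, spec = pars$spec),
                       sim_args))
      if (penalize_nonconverged && !sim$all_converged) return(Inf)
      surf <- deformed_surface(sim)
      net <- do.call(extract_fold_network, c(list(m = surf), network_args))
      v <- network_metrics(net)
      d <- metrics_distance(cohort_normalize(v, cohort), tnorm)
      attr(d, "converged") <- sim$all_converged
      d
    }, error = function(e) Inf)
  }
}
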