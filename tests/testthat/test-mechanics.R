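make_prob <- function(k1 = 0) {
  mesh <- make_bilayer_patch(3, 3, 1, 2, 1)
  mat <- material_params(E_epidermis = 10, nu_epidermis = 0.4,
                         nu_dermis = 0.45, k1 = k1)
  spec <- growth_spec(G_derm_plus = 1.15, G_derm_minus = 1.1)
  list(mesh = mesh, mat = mat, spec = spec,
       prob = scutes:::setup_problem(mesh, mat, spec))
}

test_that("assembled forces equal the negative energy gradient", {
  p <- make_prob(k1 = 2)
  set.seed(1)
  x <- p$mesh$nodes +
    matrix(rnorm(length(p$mesh$nodes), 0, 0.02), nrow(p$mesh$nodes))
  ef <- assemble_forces(p$prob, x, t = 0.7)
  h <- 1e-6
  for (trial in 1:15) {
    i <- sample(nrow(x), 1); c <- sample(3, 1)
    xp <- x; xp[i, c] <- xp[i, c] + h
    xm <- x; xm[i, c] <- xm[i, c] - h
    fd <- -(assemble_forces(p$prob, xp, t = 0.7)$energy -
            assemble_forces(p$prob, xm, t = 0.7)$energy) / (2 * h)
    expect_equal(ef$forces[i, c], fd,
                 tolerance = 1e-6 * max(1, abs(fd)))
  }
})

test_that("energy is frame-indifferent under 100 random rotations", {
  set.seed(2)
  Fe <- diag(3) + matrix(rnorm(9, 0, 0.05), 3)
  base <- elastic_energy_density(Fe, 1, 2, rbind(c(1, 0, 0)), k1 = 3)
  for (i in 1:100) {
    Q <- qr.Q(qr(matrix(rnorm(9), 3)))
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    expect_equal(elastic_energy_density(Q %*% Fe, 1, 2,
                                        rbind(c(1, 0, 0)), k1 = 3),
                 base, tolerance = 1e-10)
  }
})

test_that("reference state and pure growth carry zero energy and stress", {
  p <- make_prob()
  ## t = 0: F_g = I and x = X is an exact equilibrium
  ef0 <- assemble_forces(p$prob, p$mesh$nodes, t = 0)
  expect_equal(ef0$energy, 0)
  expect_lt(max(abs(ef0$forces)), 1e-12)
  expect_equal(elastic_energy_density(diag(3), 1, 2), 0)
  ## single tet deformed exactly by its growth tensor: F = F_g, Psi = 0
  frame <- diag(3)
  Fg <- growth_tensor(p$spec, "dermis", frame, t = 1)
  X <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  mesh1 <- layered_tet_mesh(X, rbind(1:4), "dermis", rep(FALSE, 4))
  prob1 <- scutes:::setup_problem(mesh1, p$mat, p$spec)
  x1 <- t(Fg %*% t(X))
  Fgc <- array(Fg, c(3, 3, 1))
  ef1 <- scutes:::cpp_energy_forces(x1, mesh1$tets, prob1$Bm, prob1$vol,
                                    prob1$mu, prob1$K, prob1$k1, prob1$k2,
                                    prob1$a1, prob1$a2, Fgc)
  expect_lt(ef1$energy, 1e-12)
  expect_lt(max(abs(ef1$forces)), 1e-9)
})

test_that("growth tensor follows the frame, schedule and modulation", {
  spec <- growth_spec(G_derm_plus = 1.2, G_derm_minus = 1.1)
  frame <- diag(3)   # a+ = x, a- = y, n = z
  expect_equal(growth_tensor(spec, "dermis", frame, t = 0), diag(3))
  Fg <- growth_tensor(spec, "dermis", frame, t = 1)
  expect_equal(diag(Fg), c(1.2, 1.1, 1))
  ## equibiaxial value with schedule 1 on a rotated frame
  th <- pi / 7
  fr2 <- rbind(c(cos(th), sin(th), 0), c(-sin(th), cos(th), 0), c(0, 0, 1))
  spec2 <- growth_spec(G_derm_plus = 1.3, G_derm_minus = 1.3)
  Fg2 <- growth_tensor(spec2, "dermis", fr2, t = 1)
  expect_equal(Fg2, diag(c(1.3, 1.3, 1)), tolerance = 1e-12)
  ## modulation 0.5 halves (g - 1), not g
  Fg3 <- growth_tensor(spec, "dermis", frame, t = 1, modulation = 0.5)
  expect_equal(diag(Fg3), c(1.1, 1.05, 1))
})

test_that("small-strain uniaxial response matches linear elasticity within 1%", {
  E <- 1; nu <- 0.3
  mu <- E / (2 * (1 + nu)); K <- E / (3 * (1 - 2 * nu))
  eps <- 1e-3
  Fe <- diag(c(1 + eps, 1 - nu * eps, 1 - nu * eps))
  psi <- elastic_energy_density(Fe, mu, K)
  expect_equal(psi, 0.5 * E * eps^2, tolerance = 0.01)
  ## stretching along the fiber costs strictly more than across it
  a <- rbind(c(1, 0, 0))
  along <- elastic_energy_density(diag(c(1.05, 1, 1)), 1, 2, a, k1 = 3)
  across <- elastic_energy_density(diag(c(1, 1.05, 1)), 1, 2, a, k1 = 3)
  expect_gt(along, across)
  expect_error(elastic_energy_density(diag(c(-1, 1, 1)), 1, 2), "inversion")
})

test_that("contact penalty is pairwise equal and opposite, zero beyond margin", {
  ## two separated single-tet bodies
  X <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
             c(0, 0, 9), c(1, 0, 9), c(0, 1, 9), c(0, 0, 10))
  mesh <- layered_tet_mesh(X, rbind(1:4, 5:8), c("dermis", "dermis"),
                           rep(FALSE, 8))
  f_far <- contact_forces(mesh, X, margin = 0.5, stiffness = 10, r_skip = 2)
  expect_equal(max(abs(f_far)), 0)
  ## bring the second tet within the margin below the first's face
  x2 <- X; x2[5:8, 3] <- x2[5:8, 3] - 8.8   # apex ~0.2 above z=1... face
  f <- contact_forces(mesh, x2, margin = 0.5, stiffness = 10, r_skip = 2)
  expect_gt(max(abs(f)), 0)
  ## Newton's third law: net force sums to zero
  expect_lt(max(abs(colSums(f))), 1e-10)
})

test_that("guarded overdamped step rejects unstable steps and relaxes a stretched tet", {
  X <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  mesh <- layered_tet_mesh(X, rbind(1:4), "dermis", c(TRUE, TRUE, TRUE, FALSE))
  mat <- material_params()
  spec <- growth_spec(G_derm_plus = 1, G_derm_minus = 1)
  prob <- scutes:::setup_problem(mesh, mat, spec)
  x <- X; x[4, 3] <- 1.4                       # stretched
  state <- list(x = x, dt = 0.05, t = 1, prob = prob)
  energies <- assemble_forces(prob, x, 1)$energy
  for (i in 1:200) {
    state <- mech_step(state)
    energies <- c(energies, state$energy)
  }
  expect_true(all(diff(energies) <= 1e-12))    # monotone decrease
  expect_lt(abs(state$x[4, 3] - 1), 0.05)     # near rest height
  expect_true(all(state$x[1:3, ] == X[1:3, ])) # fixed nodes pinned
  ## a hugely excessive dt is rejected and halved
  st2 <- list(x = x, dt = 1e4, t = 1, prob = prob)
  st2 <- mech_step(st2)
  expect_false(st2$accepted)
  expect_equal(st2$dt, 5e3)
  expect_identical(st2$x, x)
  ## zero net force: state unchanged
  st3 <- list(x = X, dt = 0.05, t = 1, prob = prob)
  st3 <- mech_step(st3)
  expect_equal(st3$x, X, tolerance = 1e-12)
})

test_that("zero growth is a fixed point of the full simulation", {
  mesh <- make_bilayer_patch(6, 6, 1, 2, 1)
  mat <- material_params(E_epidermis = 10)
  spec <- growth_spec(G_derm_plus = 1, G_derm_minus = 1,
                      G_epi_plus = 1, G_epi_minus = 1)
  sim <- simulate_growth(mesh, mat, spec, n_increments = 2, tol = 1e-5,
                         seed = 1)
  expect_true(sim$all_converged)
  expect_lt(max(abs(sim$x - mesh$nodes)), 0.01 * 1)  # << h_epi
})

test_that("EGF variant modifies only epidermal parameters and stays continuous", {
  mat <- material_params(E_epidermis = 5, nu_epidermis = 0.4)
  spec <- growth_spec(G_derm_plus = 1.2)
  ## identity when nothing changes
  ev0 <- egf_variant(spec, mat, lambda_egf = 0)
  expect_identical(ev0$mat, mat)
  expect_equal(scutes:::growth_factors_at(ev0$spec, "epidermis", 0.5),
               scutes:::growth_factors_at(spec, "epidermis", 0.5))
  ## EGF on then arrested: growth continuous, slope drops at window end
  ev <- egf_variant(spec, mat, lambda_egf = 0.3, E_epi_new = 12,
                    nu_epi_new = 0.45, egf_window = c(0, 0.5))
  g <- function(t) scutes:::growth_factors_at(ev$spec, "epidermis", t)[1]
  tt <- seq(0, 1, 0.01)
  gv <- vapply(tt, g, numeric(1))
  expect_true(all(diff(gv) > -1e-12))                 # monotone
  expect_lt(max(abs(diff(gv, lag = 1))), 0.02)        # no jumps
  slope_in <- (g(0.45) - g(0.40)) / 0.05
  slope_out <- (g(0.60) - g(0.55)) / 0.05
  expect_gt(slope_in, slope_out)
  ## dermis untouched, bit-identical
  expect_identical(ev$mat$dermis, mat$dermis)
  expect_identical(ev$spec$dermis, spec$dermis)
})
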