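test_that("homogeneous steady state solves the linear system (Cramer oracle)", {
  p <- turing_params()
  ss <- homogeneous_steady_state(p)
  # independent 2x2 solve by Cramer's rule
  a11 <- p$a - p$mu_u; a12 <- p$b; a21 <- p$d; a22 <- p$e - p$mu_v
  det <- a11 * a22 - a12 * a21
  u_star <- (-p$c * a22 + p$f * a12) / det
  v_star <- (-a11 * p$f + a21 * p$c) / det
  expect_equal(unname(ss), c(u_star, v_star), tolerance = 1e-12)
  # and the reaction rates vanish there
  rr <- reaction_rates(ss["u"], ss["v"], p)
  expect_lt(abs(rr$du), 1e-12)
  expect_lt(abs(rr$dv), 1e-12)
})

test_that("decoupled decay-only kinetics have the trivial steady state", {
  p <- rd_params(a = 0.05, b = 0, c = 0, d = 0, e = 0.02, f = 0,
                 S_u = 1, S_v = 1, mu_u = 0.1, mu_v = 0.1,
                 D_u = 0.1, D_v = 1)
  expect_equal(unname(homogeneous_steady_state(p)), c(0, 0))
})

test_that("steady states outside the clamp interior are rejected", {
  # synthesis at the fixed point above S_u
  p <- turing_params()
  p2 <- rd_params(p$a, p$b, p$c, p$d, p$e, p$f, S_u = 0.05, S_v = 0.5,
                  mu_u = p$mu_u, mu_v = p$mu_v, D_u = p$D_u, D_v = p$D_v)
  expect_error(homogeneous_steady_state(p2),
               class = "ringleaf_no_interior_steady_state")
  # singular reaction matrix
  p3 <- rd_params(a = 0.2, b = -0.1, c = 0, d = 0.1, e = 0, f = 0,
                  S_u = 1, S_v = 1, mu_u = 0.1, mu_v = 0.1,
                  D_u = 0.1, D_v = 1)
  expect_error(homogeneous_steady_state(p3),
               class = "ringleaf_no_interior_steady_state")
})

test_that("reaction rates apply the clamp to synthesis only", {
  p <- turing_params()
  # below the lower clamp: activator rate is pure decay
  rr <- reaction_rates(u = 1, v = 10, p) # a*1 + b*10 + c = -3.5 < 0
  expect_identical(rr$du, -p$mu_u * 1)
  # above the upper clamp: activator rate is S_u - decay
  rr2 <- reaction_rates(u = 5, v = 0, p) # a*5 + c = 1.9 > S_u
  expect_identical(rr2$du, p$S_u - p$mu_u * 5)
})

test_that("ring Laplacian: constant field, spike stencil, metric flux conservation", {
  expect_equal(laplacian_ring(rep(3, 10)), rep(0, 10))
  expect_equal(laplacian_ring(rep(3, 10), lengths = runif(10, 0.5, 2),
                              mode = "metric"), rep(0, 10))
  spike <- rep(0, 9); spike[5] <- 1
  expect_equal(laplacian_ring(spike),
               c(0, 0, 0, 1, -2, 1, 0, 0, 0))
  # conservative form: total content is unchanged by diffusion
  set.seed(3)
  for (rep in 1:5) {
    n <- sample(5:40, 1)
    vals <- runif(n)
    lens <- runif(n, 0.3, 2)
    term <- laplacian_ring(vals, lens, "metric")
    expect_lt(abs(sum(lens * term)), 1e-12)
  }
  expect_error(laplacian_ring(runif(5), lengths = c(1, 1, 0, 1, 1),
                              mode = "metric"),
               class = "ringleaf_invalid_geometry")
})

test_that("rd_step is exact at the steady state without diffusion", {
  p <- rd_params(a = 0.35, b = -0.4, c = 0.15, d = 0.3, e = -0.25, f = 0.05,
                 S_u = 0.5, S_v = 0.5, mu_u = 0.1, mu_v = 0.1,
                 D_u = 0, D_v = 0, dt_rd = 0.04)
  r <- make_ring(8, 1, seed = 1, init_amplitude = 0, params = p)
  out <- rd_step(r, p, n_substeps = 50)
  expect_equal(out$u, r$u, tolerance = 1e-13)
  expect_equal(out$v, r$v, tolerance = 1e-13)
})

test_that("without a Turing band a random perturbation decays toward the steady state", {
  p <- stable_params()
  d <- dispersion_relation(p, 64)
  expect_true(all(d$re_lambda < 0)) # dispersion oracle: no unstable mode
  ss <- homogeneous_steady_state(p)
  r <- make_ring(64, 10, seed = 5, init_amplitude = 0.2, params = p)
  dev0 <- max(abs(r$u - ss["u"]))
  out <- rd_step(r, p, n_substeps = 500)
  expect_lt(max(abs(out$u - ss["u"])), dev0)
})

test_that("rd_step is bit-reproducible and enforces its stability bound", {
  p <- turing_params()
  r <- make_ring(32, 5, seed = 2, init_amplitude = 0.1, params = p)
  expect_identical(unclass(rd_step(r, p, 100)), unclass(rd_step(r, p, 100)))
  p_bad <- rd_params(p$a, p$b, p$c, p$d, p$e, p$f, p$S_u, p$S_v,
                     p$mu_u, p$mu_v, p$D_u, p$D_v, dt_rd = 1)
  expect_error(rd_step(r, p_bad, 1), class = "ringleaf_config_error")
})

test_that("one Euler substep matches the matrix exponential to second order", {
  # zero diffusion, clamps inactive near the fixed point: each cell follows
  # the 2x2 linear ODE w' = J w about the steady state
  p <- rd_params(a = 0.35, b = -0.4, c = 0.15, d = 0.3, e = -0.25, f = 0.05,
                 S_u = 0.5, S_v = 0.5, mu_u = 0.1, mu_v = 0.1,
                 D_u = 0, D_v = 0, dt_rd = 0.04)
  ss <- homogeneous_steady_state(p)
  J <- matrix(c(p$a - p$mu_u, p$b, p$d, p$e - p$mu_v), 2, 2, byrow = TRUE)
  w0 <- c(0.02, -0.01)
  err_at <- function(dt) {
    pp <- rd_params(p$a, p$b, p$c, p$d, p$e, p$f, p$S_u, p$S_v,
                    p$mu_u, p$mu_v, 0, 0, dt_rd = dt)
    r <- make_ring(4, 1, seed = 1, init_amplitude = 0, params = pp)
    r$u <- r$u + w0[1]
    r$v <- r$v + w0[2]
    out <- rd_step(r, pp, 1)
    exact <- expm2_apply(J, w0, dt)
    max(abs(c(out$u[1] - ss["u"], out$v[1] - ss["v"]) - exact))
  }
  e1 <- err_at(0.04)
  e2 <- err_at(0.02)
  expect_lt(e1, 1e-4)
  expect_gt(e1 / e2, 3) # local truncation error scales ~ dt^2
  expect_lt(e1 / e2, 5)
})

test_that("dispersion relation: k = 0 limit, triangular case, eigen oracle, Turing band", {
  p <- turing_params()
  d <- dispersion_relation(p, 200)
  # k = 0 equals the leading eigenvalue of the reaction Jacobian
  J <- matrix(c(p$a - p$mu_u, p$b, p$d, p$e - p$mu_v), 2, 2, byrow = TRUE)
  expect_equal(d$re_lambda[1], max(Re(eigen(J)$values)), tolerance = 1e-12)
  # full numeric eigenvalue oracle across all modes
  oracle <- vapply(d$kappa2, function(k2) {
    Jk <- J - diag(c(p$D_u, p$D_v)) * k2
    max(Re(eigen(Jk, only.values = TRUE)$values))
  }, numeric(1))
  expect_equal(d$re_lambda, oracle, tolerance = 1e-10)
  # Turing checklist for the packaged insertion kinetics: stable uniform
  # mode, a contiguous unstable band of nonzero modes
  expect_lt(d$re_lambda[1], 0)
  unstable <- sort(unique(d$mode[d$re_lambda > 0]))
  expect_gt(length(unstable), 0)
  expect_true(all(diff(unstable) == 1)) # one contiguous band of modes

  # decoupled (b = 0): eigenvalues are exactly the diagonal entries
  p0 <- rd_params(a = 0.05, b = 0, c = 0.1, d = 0.3, e = -0.25, f = 0.05,
                  S_u = 5, S_v = 5, mu_u = 0.1, mu_v = 0.1,
                  D_u = 0.1, D_v = 1)
  d0 <- dispersion_relation(p0, 16)
  diag_max <- pmax(p0$a - p0$mu_u - p0$D_u * d0$kappa2,
                   p0$e - p0$mu_v - p0$D_v * d0$kappa2)
  expect_equal(d0$re_lambda, diag_max, tolerance = 1e-12)
})

test_that("negative concentrations are clipped and counted", {
  # strong negative forcing on v: f << 0 drives v to the floor
  p <- rd_params(a = 0.0, b = 0, c = 0.0, d = 0, e = 0, f = -1,
                 S_u = 1, S_v = 1, mu_u = 0.5, mu_v = 1.5,
                 D_u = 0, D_v = 0, dt_rd = 1)
  r <- structure(list(x = cos(1:4), y = sin(1:4),
                      u = rep(0.1, 4), v = rep(0.01, 4)),
                 class = "margin_ring")
  out <- rd_step(r, p, 2)
  expect_true(all(out$v >= 0))
  expect_gt(attr(out, "n_clipped"), 0)
})
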