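test_that("make_ring builds a regular polygon with seeded reactant noise", {
  r <- make_ring(6, 1.0, seed = 1, init_amplitude = 0.1)
  expect_s3_class(r, "margin_ring")
  expect_equal(n_cells(r), 6L)
  # regular hexagon of circumradius 1: all cells of length 1, area 3*sqrt(3)/2
  expect_equal(cell_lengths(r), rep(1, 6), tolerance = 1e-12)
  expect_equal(ring_area(r), 3 * sqrt(3) / 2, tolerance = 1e-12)
  # deterministic given the seed
  expect_identical(unclass(make_ring(6, 1.0, seed = 1)),
                   unclass(make_ring(6, 1.0, seed = 1)))
  expect_false(identical(make_ring(6, 1, seed = 1)$u,
                         make_ring(6, 1, seed = 2)$u))
})

test_that("zero-amplitude initial condition sits exactly at the steady state", {
  p <- turing_params()
  ss <- homogeneous_steady_state(p)
  r <- make_ring(3, 1.0, seed = 0, init_amplitude = 0, params = p)
  expect_equal(cell_lengths(r), rep(sqrt(3), 3), tolerance = 1e-12)
  expect_identical(r$u, rep(unname(ss["u"]), 3))
  expect_identical(r$v, rep(unname(ss["v"]), 3))
})

test_that("degenerate domains are rejected", {
  expect_error(make_ring(2, 1.0), class = "ringleaf_invalid_domain")
  expect_error(make_ring(6, 0), class = "ringleaf_invalid_domain")
  expect_error(make_ring(6, -1), class = "ringleaf_invalid_domain")
  expect_error(new_margin_ring(c(0, 1, 1), c(0, 0, 0), 1:3, 1:3),
               class = "ringleaf_invalid_domain") # coincident vertices
})

test_that("clockwise input is canonicalized to counterclockwise winding", {
  # clockwise square
  r <- new_margin_ring(x = c(0, 0, 1, 1), y = c(0, 1, 1, 0),
                       u = 1:4, v = 5:8)
  expect_gt(ring_area(r), 0)
  expect_setequal(r$u, 1:4) # state preserved as a multiset
})

test_that("growth directions: square diagonals, collinear perpendicular, regular polygon radial", {
  sq <- new_margin_ring(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1),
                        u = rep(1, 4), v = rep(1, 4))
  d <- growth_directions(sq)
  s2 <- sqrt(2) / 2
  expect_equal(d$dx, c(-s2, s2, s2, -s2), tolerance = 1e-12)
  expect_equal(d$dy, c(-s2, -s2, s2, s2), tolerance = 1e-12)

  # middle vertex of three collinear vertices: exactly perpendicular
  tri <- new_margin_ring(x = c(0, 1, 2, 1), y = c(0, 0, 0, 2),
                         u = rep(1, 4), v = rep(1, 4))
  d2 <- growth_directions(tri)
  expect_equal(d2$dx[2], 0, tolerance = 1e-12)
  expect_equal(d2$dy[2], -1, tolerance = 1e-12) # outward = away from interior

  # regular 64-gon: every direction radially outward within 1e-9
  n <- 64
  th <- 2 * pi * (0:(n - 1)) / n
  poly <- new_margin_ring(cos(th), sin(th), rep(1, n), rep(1, n))
  d3 <- growth_directions(poly)
  expect_lt(max(abs(d3$dx - cos(th))), 1e-9)
  expect_lt(max(abs(d3$dy - sin(th))), 1e-9)
})

test_that("propagate: identity at zero speed, radial expansion, locality", {
  n <- 64
  th <- 2 * pi * (0:(n - 1)) / n
  poly <- new_margin_ring(cos(th), sin(th), rep(1, n), rep(1, n))

  same <- propagate(poly, rep(0, n), dt = 1)
  expect_identical(same$x, poly$x)
  expect_identical(same$y, poly$y)

  # uniform speed s over dt: circumradius grows by s * dt within 1%
  s <- 0.05
  grown <- propagate(poly, rep(s, n), dt = 1)
  radius <- sqrt(grown$x^2 + grown$y^2)
  expect_equal(radius, rep(1 + s, n), tolerance = 0.01)

  # single positive speed displaces exactly one vertex, stretching both
  # adjacent cells
  sp <- rep(0, n)
  sp[10] <- 0.3
  local <- propagate(poly, sp, dt = 1)
  moved <- which(local$x != poly$x | local$y != poly$y)
  expect_identical(moved, 10L)
  len0 <- cell_lengths(poly)
  len1 <- cell_lengths(local)
  expect_gt(len1[9], len0[9])
  expect_gt(len1[10], len0[10])
  expect_equal(len1[-c(9, 10)], len0[-c(9, 10)])
})

test_that("propagate rejects negative speeds and bad dt", {
  r <- make_ring(6, 1)
  expect_error(propagate(r, rep(-1, 6), 1),
               class = "ringleaf_contract_violation")
  expect_error(propagate(r, rep(0, 5), 1),
               class = "ringleaf_contract_violation")
  expect_error(propagate(r, rep(0, 6), 0),
               class = "ringleaf_contract_violation")
})

test_that("antiparallel adjacent normals fall back to the longer cell's normal", {
  # a degenerate 'ring' folded flat at vertex 2: cells (1->2) and (2->3)
  # run in exactly opposite directions, so their normals cancel
  r <- structure(list(x = c(0, 2, 1, 1), y = c(0, 0, 0, 2),
                      u = rep(1, 4), v = rep(1, 4)),
                 class = "margin_ring")
  d <- growth_directions(r)
  expect_identical(attr(d, "n_degenerate"), 1L)
  # longer adjacent cell is (1->2), outward normal (0, -1)
  expect_equal(c(d$dx[2], d$dy[2]), c(0, -1), tolerance = 1e-12)
})

test_that("divide_cells: identity below threshold, midpoint split with exact inheritance", {
  r <- make_ring(6, 1)
  expect_identical(divide_cells(r, L_div = 2), r)

  # one long cell: daughters of half length carry exactly the mother state
  sq <- new_margin_ring(x = c(0, 3, 3, 0), y = c(0, 0, 2, 2),
                        u = c(0.7, 0.1, 0.2, 0.3),
                        v = c(0.2, 0.4, 0.5, 0.6))
  out <- divide_cells(sq, L_div = 2.5)
  expect_equal(n_cells(out), 6L) # both length-3 cells divided
  expect_equal(sum(cell_lengths(out)), sum(cell_lengths(sq)),
               tolerance = 1e-14)
  expect_equal(sort(unique(out$u)), sort(unique(sq$u)))
  expect_equal(sum(out$u == 0.7), 2L) # daughters inherit (0.7, 0.2)
  expect_equal(out$v[out$u == 0.7], c(0.2, 0.2))

  # division is not recursive within one call
  long <- new_margin_ring(x = c(0, 5, 5, 0), y = c(0, 0, 1, 1),
                          u = 1:4, v = 1:4)
  once <- divide_cells(long, L_div = 2)
  expect_equal(n_cells(once), 6L) # the two 5-cells split once each
  twice <- divide_cells(once, L_div = 2)
  expect_equal(n_cells(twice), 10L) # 2.5-daughters divide on the next call
})

test_that("divide_cells conserves arc length and the reactant multiset", {
  set.seed(42)
  for (rep in 1:5) {
    n <- sample(6:30, 1)
    r <- make_ring(n, 5, seed = rep, init_amplitude = 0.3)
    r <- propagate(r, runif(n, 0, 1), 1) # roughen so lengths differ
    L_div <- unname(stats::quantile(cell_lengths(r), 0.5))
    out <- divide_cells(r, L_div)
    n_over <- sum(cell_lengths(r) > L_div)
    expect_equal(n_cells(out), n + n_over)
    expect_equal(sum(cell_lengths(out)), sum(cell_lengths(r)),
                 tolerance = 1e-12)
    expect_equal(sort(unique(out$u)), sort(unique(r$u)))
  }
})

test_that("enclosed area is nondecreasing under outward propagation (convex rings)", {
  set.seed(11)
  for (rep in 1:5) {
    n <- sample(c(8, 16, 32), 1)
    th <- 2 * pi * (0:(n - 1)) / n
    r <- new_margin_ring(cos(th), sin(th), runif(n), runif(n))
    sp <- runif(n, 0, 0.1)
    expect_gte(ring_area(propagate(r, sp, 1)), ring_area(r))
  }
})

test_that("arc positions are cell midpoints normalized to [0, 1)", {
  sq <- new_margin_ring(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1),
                        u = rep(1, 4), v = rep(0, 4))
  expect_equal(arc_positions(sq), c(0.125, 0.375, 0.625, 0.875))
})
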