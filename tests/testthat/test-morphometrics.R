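test_that("detect_peaks finds sampled sine maxima and honours prominence", {
  n <- 200
  # phase offset so each cycle has a unique sampled maximum (no exact ties)
  u <- sin(2 * pi * 4 * (0:(n - 1) + 0.2) / n)
  pk <- detect_peaks(u, min_prominence = 0.1)
  expect_length(pk, 4)
  per_cycle_argmax <- vapply(0:3, function(k) {
    idx <- which(floor((0:(n - 1)) / 50) == k)
    idx[which.max(u[idx])]
  }, integer(1))
  expect_setequal(pk, per_cycle_argmax)
  expect_length(detect_peaks(rep(2, 50)), 0)
  # sub-prominence ripples are rejected
  ripple <- 0.01 * sin(2 * pi * 10 * (0:199) / 200)
  expect_length(detect_peaks(ripple, min_prominence = 0.1), 0)
})

test_that("an exact two-cell plateau resolves to the lowest cell index", {
  u <- c(0, 1, 1, 0, 0.2, 0, 0, 0)
  pk <- detect_peaks(u, min_prominence = 0.1)
  expect_true(2L %in% pk)
  expect_false(3L %in% pk)
  # plateau wrapping through index 1 still yields one peak
  u2 <- c(1, 0, 0.2, 0, 0, 1)
  pk2 <- detect_peaks(u2, min_prominence = 0.1)
  expect_identical(sum(u2[pk2] == 1), 1L)
})

test_that("genealogy recovers the scripted events of the synthetic fixtures", {
  ins <- make_fixture("insertion_kymo")
  g <- build_genealogy(ins, min_prominence = 0.2)
  truth <- attr(ins, "ground_truth")
  got <- g$events[g$events$type != "disappearance", ]
  expect_identical(nrow(got), nrow(truth))
  expect_true(all(got$type == "insertion"))
  expect_equal(sort(got$position), sort(truth$position), tolerance = 0.01)

  spl <- make_fixture("splitting_kymo")
  g2 <- build_genealogy(spl, min_prominence = 0.2)
  ev2 <- g2$events[g2$events$type != "disappearance", ]
  expect_identical(nrow(ev2), 1L)
  expect_identical(ev2$type, "splitting")
  # the daughter is born next to the 0.25 parent, offset by the scripted
  # separation at the snapshot where the pair first resolves
  expect_lt(abs(ev2$position - 0.25), 0.06)

  static <- make_fixture("static_peaks")
  g3 <- build_genealogy(static, min_prominence = 0.2)
  expect_identical(nrow(g3$events), 0L)
  expect_identical(max(g3$counts$n_peaks), 4L)
})

test_that("peak count changes are fully accounted for by recorded events", {
  traj <- run_simulation(tiny_config(n_growth_steps = 400L))
  g <- build_genealogy(traj)
  births <- sum(g$events$type %in% c("insertion", "splitting", "ambiguous"))
  deaths <- sum(g$events$type == "disappearance")
  initial <- sum(g$peaks$birth_type == "initial")
  final <- g$counts$n_peaks[nrow(g$counts)]
  expect_identical(initial + births - deaths, final)
})

test_that("branch orders on the ideal genealogy reproduce the narrated cascade", {
  # event 2: exactly the two primaries flanking the main axis
  g2 <- glance(ideal_insertion_tree(2))
  expect_identical(g2$terminal, 1L)
  expect_identical(g2$primary, 2L)
  expect_identical(g2$secondary, 0L)
  # secondaries first appear at event 4
  expect_identical(glance(ideal_insertion_tree(3))$secondary, 0L)
  expect_gt(glance(ideal_insertion_tree(4))$secondary, 0L)
  # total leaflets across events 1..6 follow 2^n - 1
  for (n in 1:6) {
    expect_identical(glance(ideal_insertion_tree(n))$total,
                     as.integer(total_leaflets(n)))
  }
})

test_that("kymograph resamples by nearest cell onto arc bins", {
  static <- make_fixture("static_peaks")
  # constant field: all entries equal that constant
  traj_const <- static
  for (i in seq_along(traj_const$snapshots)) {
    traj_const$snapshots[[i]]$ring$u <-
      rep(0.7, n_cells(traj_const$snapshots[[i]]$ring))
  }
  km <- kymograph(traj_const, n_grid = 32)
  expect_identical(dim(km), c(10L, 32L))
  expect_true(all(km == 0.7))
  # a single peak at arc 0.25 lands in bin floor(0.25 * n_grid) (1-based)
  # n_grid chosen so the 0.25 bin centre is interior (no edge ties)
  single <- scripted_peak_traj_for_tests(0.25, n_snapshots = 3)
  km2 <- kymograph(single, n_grid = 38)
  expect_true(all(apply(unclass(km2), 1, which.max) ==
                    floor(0.25 * 38) + 1L))
  expect_error(kymograph(static, n_grid = 4),
               class = "ringleaf_contract_violation")
})

test_that("doubling plateaus ignore brief mid-wave pauses", {
  counts <- c(rep(1, 20), 2, 3, rep(4, 20), 5, 6, 7, rep(8, 20))
  fake <- structure(list(counts = tibble::tibble(
    snapshot = seq_along(counts), time = seq_along(counts),
    n_peaks = counts)), class = "peak_genealogy")
  de <- doubling_events(fake, min_run = 10)
  expect_identical(de$n_peaks, c(1, 4, 8))
  expect_identical(de$doubling, c(FALSE, FALSE, TRUE))
})

test_that("bulge_activator reports the outermost vertex and its activator quantile", {
  # square with one strongly protruded vertex adjacent to low-u cells
  r1 <- new_margin_ring(x = c(0, 1, 1, 0) - 0.5, y = c(0, 0, 1, 1) - 0.5,
                        u = c(1, 1, 1, 1), v = rep(0, 4))
  r2 <- new_margin_ring(x = c(0, 1, 5, 0) - 0.5, y = c(0, 0, 5, 1) - 0.5,
                        u = c(0.9, 0.1, 0.1, 0.9), v = rep(0, 4))
  traj <- structure(list(snapshots = list(
    list(step = 0L, time = 0, ring = r1),
    list(step = 1L, time = 1, ring = r2))),
    class = "ringleaf_trajectory")
  ba <- bulge_activator(traj)
  expect_identical(ba$vertex, 3L)
  expect_equal(ba$u_at_bulge, 0.1)
  expect_lt(ba$u_quantile, 0.5)
})
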