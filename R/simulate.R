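#' Full simulation configuration
#'
#' Bundles the reaction-diffusion parameters, the growth-coupling law, the
#' initial ring, and the run schedule. One growth step consists of
#' `rd_substeps` explicit-Euler RD substeps followed by one boundary
#' propagation and one division sweep; many RD substeps per growth step let
#' the pattern relax faster than the domain deforms.
#'
#' @param rd An [rd_params()] object.
#' @param growth A [growth_params()] object.
#' @param n_cells_init Initial cell count (default 6, a hexagonal seed ring).
#' @param radius_init Initial circumradius.
#' @param init_amplitude Width of the uniform random perturbation of the
#'   initial reactant state around the homogeneous steady state.
#' @param rd_substeps RD substeps per growth step (>= 1).
#' @param n_growth_steps Number of growth steps to run.
#' @param snapshot_every Record a snapshot every this many growth steps.
#' @param seed Integer seed; the initial condition is the only stochastic
#'   element, so `(config, seed)` fully reproduces a run.
#' @param max_cells Stop early (cleanly) if the ring exceeds this many
#'   cells; guards runaway growth.
#' @return A `sim_config` object.
#' @export
sim_config <- function(rd, growth,
                       n_cells_init = 6L, radius_init = 1,
                       init_amplitude = 0.1,
                       rd_substeps = 25L, n_growth_steps = 1000L,
                       snapshot_every = 5L, seed = 1L,
                       max_cells = 5000L) {
  if (!inherits(rd, "rd_params"))
    abort("`rd` must be an rd_params object.", class = "ringleaf_config_error")
  if (!inherits(growth, "growth_params"))
    abort("`growth` must be a growth_params object.",
          class = "ringleaf_config_error")
  counts <- c(n_cells_init = n_cells_init, rd_substeps = rd_substeps,
              n_growth_steps = n_growth_steps, snapshot_every = snapshot_every,
              max_cells = max_cells)
  if (any(counts < 1) || any(counts != round(counts)))
    abort("All counts in sim_config must be positive integers.",
          class = "ringleaf_config_error")
  if (radius_init <= 0 || init_amplitude < 0)
    abort("radius_init must be > 0 and init_amplitude >= 0.",
          class = "ringleaf_config_error")
  if (rd$dt_rd > rd_stability_limit(rd))
    abort(sprintf(
      "dt_rd = %g violates the explicit-Euler stability bound %g.",
      rd$dt_rd, rd_stability_limit(rd)), class = "ringleaf_config_error")
  structure(list(rd = rd, growth = growth,
                 n_cells_init = as.integer(n_cells_init),
                 radius_init = as.numeric(radius_init),
                 init_amplitude = as.numeric(init_amplitude),
                 rd_substeps = as.integer(rd_substeps),
                 n_growth_steps = as.integer(n_growth_steps),
                 snapshot_every = as.integer(snapshot_every),
                 seed = as.integer(seed),
                 max_cells = as.integer(max_cells)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %d-cell seed ring, %d growth steps x %d RD substeps, seed %d\n",
    x$n_cells_init, x$n_growth_steps, x$rd_substeps, x$seed))
  print(x$rd)
  print(x$growth)
  invisible(x)
}

# stable short hash of a config (polynomial rolling hash of its deparse)
config_hash <- function(config) {
  s <- paste(deparse(unclass(config)), collapse = "")
  bytes <- utf8ToInt(s)
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run a seeded growth + reaction-diffusion simulation
#'
#' Iterates, per growth step: (1) `rd_substeps` RD substeps, (2) vertex
#' speeds from the growth law, (3) boundary propagation, (4) cell division.
#' Snapshots of the full ring (geometry + reactants) are recorded every
#' `snapshot_every` steps, plus the initial state.
#'
#' @param config A [sim_config()].
#' @param seed Optional seed overriding `config$seed`.
#' @return A `ringleaf_trajectory`: list with `snapshots` (each a list of
#'   `step`, `time`, `ring`), `config`, `seed`, `config_hash`, and a
#'   `warnings` counter vector (negative-concentration clips, degenerate
#'   growth directions).
#' @export
run_simulation <- function(config, seed = NULL) {
  if (!inherits(config, "sim_config"))
    abort("`config` must be a sim_config.", class = "ringleaf_config_error")
  seed <- if (is.null(seed)) config$seed else as.integer(seed)
  ring <- make_ring(config$n_cells_init, config$radius_init, seed = seed,
                    init_amplitude = config$init_amplitude,
                    params = config$rd)
  snaps <- vector("list", config$n_growth_steps %/% config$snapshot_every + 1L)
  snaps[[1]] <- list(step = 0L, time = 0, ring = ring)
  isnap <- 1L
  n_clipped <- 0L
  n_degenerate <- 0L
  dt_g <- config$growth$dt_growth
  for (s in seq_len(config$n_growth_steps)) {
    ring <- tryCatch(
      rd_step(ring, config$rd, config$rd_substeps),
      ringleaf_numerical_blowup = function(e) {
        abort(sprintf("%s (growth step %d, %d cells)", conditionMessage(e),
                      s, n_cells(ring)),
              class = "ringleaf_numerical_blowup")
      })
    n_clipped <- n_clipped + attr(ring, "n_clipped")
    attr(ring, "n_clipped") <- NULL
    sp <- vertex_speeds(ring, config$growth)
    dirs_before <- attr(growth_directions(ring), "n_degenerate")
    n_degenerate <- n_degenerate + dirs_before
    ring <- propagate(ring, sp, dt_g)
    ring <- divide_cells(ring, config$growth$L_div)
    if (s %% config$snapshot_every == 0L) {
      isnap <- isnap + 1L
      snaps[[isnap]] <- list(step = s, time = s * dt_g, ring = ring)
    }
    if (n_cells(ring) > config$max_cells) break
  }
  structure(list(snapshots = snaps[seq_len(isnap)],
                 config = config, seed = seed,
                 config_hash = config_hash(config),
                 warnings = c(n_clipped = n_clipped,
                              n_degenerate_directions = n_degenerate)),
            class = "ringleaf_trajectory")
}

#' @export
print.ringleaf_trajectory <- function(x, ...) {
  last <- x$snapshots[[length(x$snapshots)]]
  cat(sprintf(
    "<ringleaf_trajectory> %d snapshots, %d -> %d cells, seed %d, config %s\n",
    length(x$snapshots), n_cells(x$snapshots[[1]]$ring),
    n_cells(last$ring), x$seed, x$config_hash))
  invisible(x)
}

#' Classify whole-run pattern behavior of a parameter set
#'
#' Runs `n_seeds` seeded simulations of `config`, tracks the peak genealogy
#' of each, and reports the majority label: `no_pattern` if no peaks ever
#' form; `stationary_pattern` if peaks form but no birth events occur;
#' `insertion` or `splitting` if at least `majority` of the classified
#' birth events are of that type; otherwise `irregular`.
#'
#' @param config A [sim_config()].
#' @param n_seeds Number of seeds (consecutive from `config$seed`).
#' @param min_prominence,max_match_shift Passed to [build_genealogy()].
#' @param majority Fraction of events required for a regime label
#'   (default 0.8).
#' @return A list with `label` and `tally`, a tibble of per-seed event
#'   counts (`seed`, `n_peaks_final`, `insertion`, `splitting`,
#'   `ambiguous`, `label`).
#' @export
classify_behavior <- function(config, n_seeds = 5L,
                              min_prominence = 0.1, max_match_shift = 0.1,
                              majority = 0.8) {
  if (n_seeds < 1) abort("n_seeds must be >= 1.",
                         class = "ringleaf_config_error")
  seeds <- config$seed + seq_len(n_seeds) - 1L
  rows <- purrr::map(seeds, function(sd) {
    res <- tryCatch({
      traj <- run_simulation(config, seed = sd)
      gen <- build_genealogy(traj, min_prominence = min_prominence,
                             max_match_shift = max_match_shift)
      ev <- gen$events$type
      npk <- max(glance(gen)$n_peaks_final, 0L)
      tibble(seed = sd, n_peaks_final = npk,
             insertion = sum(ev == "insertion"),
             splitting = sum(ev == "splitting"),
             ambiguous = sum(ev == "ambiguous"),
             error = NA_character_)
    }, error = function(e) {
      tibble(seed = sd, n_peaks_final = NA_integer_, insertion = 0L,
             splitting = 0L, ambiguous = 0L,
             error = conditionMessage(e))
    })
    res
  })
  tally <- dplyr::bind_rows(rows)
  lab <- function(row) {
    if (!is.na(row$error)) return("error")
    if (is.na(row$n_peaks_final) || row$n_peaks_final == 0) return("no_pattern")
    n_ev <- row$insertion + row$splitting
    if (n_ev == 0) return("stationary_pattern")
    if (row$insertion / n_ev >= majority) return("insertion")
    if (row$splitting / n_ev >= majority) return("splitting")
    "irregular"
  }
  tally$label <- vapply(seq_len(nrow(tally)),
                        function(i) lab(tally[i, ]), character(1))
  counted <- table(tally$label[tally$label != "error"])
  label <- if (length(counted)) names(which.max(counted)) else "error"
  list(label = label, tally = tally)
}

#' Peak count at pattern onset on a fixed ring
#'
#' Integrates the RD system on a fixed (non-growing) regular ring from a
#' small random perturbation until the activator deviation first reaches
#' `onset * u_star`, then counts activator peaks. At onset the pattern is
#' still governed by the linearized dynamics, so the count measures linear
#' mode selection and is directly comparable to the
#' [dispersion_relation()] argmax; integrating much longer instead measures
#' nonlinear (coarsened) wavelength selection.
#'
#' @inheritParams homogeneous_steady_state
#' @param n_cells Ring size (number of compartments).
#' @param seed Integer seed.
#' @param init_amplitude Width of the initial uniform perturbation
#'   (small, so that many e-folds of linear growth sharpen the mode choice).
#' @param onset Relative activator deviation defining pattern onset.
#' @param min_prominence Peak prominence threshold for the count.
#' @param max_substeps Integration cap.
#' @return A one-row tibble: `seed`, `n_peaks`, `n_substeps_used`.
#' @export
fixed_ring_peak_count <- function(params, n_cells = 200L, seed = 1L,
                                  init_amplitude = 0.01, onset = 1,
                                  min_prominence = 0.05,
                                  max_substeps = 200000L) {
  ss <- homogeneous_steady_state(params)
  ring <- make_ring(n_cells, n_cells / (2 * pi), seed = seed,
                    init_amplitude = init_amplitude, params = params)
  thr <- onset * abs(ss[["u"]])
  used <- max_substeps
  chunk <- 25L
  done <- 0L
  while (done < max_substeps) {
    ring <- rd_step(ring, params, chunk)
    done <- done + chunk
    if (max(abs(ring$u - ss[["u"]])) >= thr) { used <- done; break }
  }
  tibble(seed = seed, n_peaks = length(detect_peaks(ring$u, min_prominence)),
         n_substeps_used = used)
}
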