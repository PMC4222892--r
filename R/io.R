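#' Load a simulation configuration from a YAML file
#'
#' The file has three blocks: `rd` (reaction-diffusion parameters), `growth`
#' (velocity law) and `sim` (run schedule). Every key is validated; unknown
#' keys are rejected by name, missing `rd` coefficients are an error, and
#' schedule keys fall back to the [sim_config()] defaults. A `dt_rd` above
#' the explicit-Euler stability bound is rejected with the bound in the
#' message.
#'
#' @param path Path to a YAML configuration file.
#' @return A validated [sim_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    abort(sprintf("Config file not found: %s", path),
          class = "ringleaf_config_error")
  raw <- yaml::read_yaml(path)
  known_blocks <- c("rd", "growth", "sim")
  unknown <- setdiff(names(raw), known_blocks)
  if (length(unknown))
    abort(sprintf("Unknown config block(s): %s.",
                  paste(unknown, collapse = ", ")),
          class = "ringleaf_config_error")
  check_keys <- function(block, allowed, nm) {
    unknown <- setdiff(names(block), allowed)
    if (length(unknown))
      abort(sprintf("Unknown key(s) in `%s`: %s.", nm,
                    paste(unknown, collapse = ", ")),
            class = "ringleaf_config_error")
  }
  rd_keys <- c("a", "b", "c", "d", "e", "f", "S_u", "S_v", "mu_u", "mu_v",
               "D_u", "D_v", "dt_rd", "coupling_mode")
  gr_keys <- c("mode", "k_g", "g0", "k_h", "reactant_select", "L_div",
               "dt_growth")
  sim_keys <- c("n_cells_init", "radius_init", "init_amplitude",
                "rd_substeps", "n_growth_steps", "snapshot_every", "seed",
                "max_cells")
  check_keys(raw$rd, rd_keys, "rd")
  check_keys(raw$growth, gr_keys, "growth")
  check_keys(raw$sim, sim_keys, "sim")
  required_rd <- setdiff(rd_keys, c("dt_rd", "coupling_mode"))
  missing <- setdiff(required_rd, names(raw$rd))
  if (length(missing))
    abort(sprintf("Missing required rd key(s): %s.",
                  paste(missing, collapse = ", ")),
          class = "ringleaf_config_error")
  rd <- do.call(rd_params, raw$rd)
  growth <- do.call(growth_params, as.list(raw$growth))
  do.call(sim_config, c(list(rd = rd, growth = growth), as.list(raw$sim)))
}

#' Write a simulation configuration to YAML
#'
#' Inverse of [load_config()]: the written file round-trips to an
#' identical configuration.
#'
#' @param config A [sim_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  rd <- unclass(config$rd)
  growth <- unclass(config$growth)
  sim <- unclass(config)[c("n_cells_init", "radius_init", "init_amplitude",
                           "rd_substeps", "n_growth_steps", "snapshot_every",
                           "seed", "max_cells")]
  yaml::write_yaml(list(rd = rd, growth = growth, sim = sim), path,
                   precision = 12)
  invisible(path)
}

#' Packaged insertion-regime configuration
#'
#' The calibrated defaults for the pattern-dependent-expansion regime: a
#' spiky (weakly saturated) activator whose peaks drive margin expansion,
#' producing regular peak doubling by insertion from a 6-cell seed ring.
#'
#' @return A [sim_config()].
#' @export
insertion_config <- function() {
  load_config(system.file("extdata", "insertion.yaml", package = "ringleaf",
                          mustWork = TRUE))
}

#' Packaged splitting-regime configuration
#'
#' The calibrated defaults for the expansion-inhibition regime: a strongly
#' saturated (plateau-forming) activator inhibits an otherwise constant
#' margin expansion, so the reactant-free regions bulge outward and the
#' branching proceeds by repeated peak splitting.
#'
#' @return A [sim_config()].
#' @export
splitting_config <- function() {
  load_config(system.file("extdata", "splitting.yaml", package = "ringleaf",
                          mustWork = TRUE))
}

#' Write a trajectory to CSV
#'
#' One row per vertex per snapshot: `snapshot`, `step`, `time`, `vertex`,
#' `x`, `y`, `u`, `v`, where `u`, `v` belong to the cell anchored at the
#' vertex (the segment from this vertex to the next). Floats are printed
#' with 9 significant digits, which round-trips the geometry to plotting
#' precision.
#'
#' @param trajectory A [run_simulation()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  df <- tidy(trajectory)
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(z) signif(z, 9))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trajectory written by [write_trajectory_csv()]
#'
#' Rebuilds the snapshot list (geometry and reactant state). The
#' configuration is not stored in the CSV; the result carries `config =
#' NULL` and supports all morphometric analyses.
#'
#' @param path CSV path.
#' @return A `ringleaf_trajectory`.
#' @export
read_trajectory_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("snapshot", "step", "time", "vertex", "x", "y", "u", "v")
  missing <- setdiff(need, names(df))
  if (length(missing))
    abort(sprintf("Trajectory CSV is missing column(s): %s.",
                  paste(missing, collapse = ", ")),
          class = "ringleaf_schema_error")
  snaps <- lapply(split(df, df$snapshot), function(d) {
    d <- d[order(d$vertex), ]
    list(step = d$step[1], time = d$time[1],
         ring = structure(list(x = d$x, y = d$y, u = d$u, v = d$v),
                          class = "margin_ring"))
  })
  snaps <- snaps[order(as.integer(names(snaps)))]
  names(snaps) <- NULL
  structure(list(snapshots = snaps, config = NULL, seed = NA_integer_,
                 config_hash = NA_character_,
                 warnings = c(n_clipped = NA_integer_,
                              n_degenerate_directions = NA_integer_)),
            class = "ringleaf_trajectory")
}

#' Write run metadata as JSON
#'
#' Records everything needed to reproduce a run bit-identically: the full
#' configuration, the seed, the package version, and the warning counters.
#'
#' @param trajectory A [run_simulation()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_metadata <- function(trajectory, path) {
  cfg <- trajectory$config
  meta <- list(
    package = "ringleaf",
    version = as.character(utils::packageVersion("ringleaf")),
    seed = trajectory$seed,
    config_hash = trajectory$config_hash,
    warnings = as.list(trajectory$warnings),
    config = list(rd = unclass(cfg$rd), growth = unclass(cfg$growth),
                  sim = unclass(cfg)[c("n_cells_init", "radius_init",
                                       "init_amplitude", "rd_substeps",
                                       "n_growth_steps", "snapshot_every",
                                       "seed", "max_cells")]))
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write ring outlines as an SVG drawing
#'
#' One closed polyline per selected snapshot, scaled into a square canvas;
#' later snapshots are drawn darker. Intended for quick visual inspection
#' of the growth profile.
#'
#' @param trajectory A [run_simulation()] result (or a single
#'   `margin_ring`).
#' @param path Output path.
#' @param which Indices of snapshots to draw (default: 8 spread evenly).
#' @param size Canvas size in pixels.
#' @return `path`, invisibly.
#' @export
write_ring_svg <- function(trajectory, path, which = NULL, size = 600) {
  rings <- if (inherits(trajectory, "margin_ring")) list(trajectory)
  else {
    snaps <- trajectory$snapshots
    if (is.null(which))
      which <- unique(round(seq(1, length(snaps), length.out = 8)))
    lapply(snaps[which], `[[`, "ring")
  }
  xs <- unlist(lapply(rings, `[[`, "x"))
  ys <- unlist(lapply(rings, `[[`, "y"))
  rng <- range(c(xs, ys))
  scale <- (size * 0.9) / diff(rng)
  tr <- function(z) (z - rng[1]) * scale + size * 0.05
  lines <- vapply(seq_along(rings), function(i) {
    r <- rings[[i]]
    pts <- paste(sprintf("%.2f,%.2f", tr(r$x), tr(size / scale - r$y)),
                 collapse = " ")
    shade <- round(200 - 170 * (i - 1) / max(1, length(rings) - 1))
    sprintf(paste0('<polygon points="%s" fill="none" ',
                   'stroke="rgb(%d,%d,%d)" stroke-width="1"/>'),
            pts, shade, shade, shade)
  }, character(1))
  svg <- c(sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" ',
                          'width="%d" height="%d" viewBox="0 0 %d %d">'),
                   size, size, size, size),
           lines, "</svg>")
  writeLines(svg, path)
  invisible(path)
}

#' Write a kymograph as CSV
#'
#' Long format: `snapshot`, `time`, `arc` (bin centre), `u`.
#'
#' @param kymo A [kymograph()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_kymograph_csv <- function(kymo, path) {
  df <- tidy(kymo)
  df$u <- signif(df$u, 9)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# --- synthetic fixtures ----------------------------------------------------

# trajectory whose activator field is a sum of von-Mises-like bumps at
# scripted arc positions; geometry is a unit circle with n_cells cells
scripted_trajectory <- function(position_list, n_cells = 200L,
                                bump_width = 0.02, height = 1) {
  th <- 2 * pi * (seq_len(n_cells) - 1) / n_cells
  mid <- (seq_len(n_cells) - 0.5) / n_cells
  snaps <- lapply(seq_along(position_list), function(si) {
    u <- rep(0, n_cells)
    for (p in position_list[[si]]) {
      d <- cyclic_dist(mid, p)
      u <- u + height * exp(-(d / bump_width)^2 / 2)
    }
    list(step = si - 1L, time = si - 1,
         ring = structure(list(x = cos(th), y = sin(th), u = u,
                               v = rep(0, n_cells)),
                          class = "margin_ring"))
  })
  structure(list(snapshots = snaps, config = NULL, seed = NA_integer_,
                 config_hash = "fixture",
                 warnings = c(n_clipped = 0L, n_degenerate_directions = 0L)),
            class = "ringleaf_trajectory")
}

#' Deterministic synthetic fixtures with known ground truth
#'
#' Builds small objects whose correct analysis results are known by
#' construction, for exercising the morphometrics independently of the
#' simulator:
#' * `static_peaks` -- a trajectory with four peaks fixed in place
#'   (ground truth: zero events);
#' * `insertion_kymo` -- two stationary peaks at arc 0.0 and 0.5, with new
#'   peaks appearing mid-gap at 0.25 and 0.75 (two insertion events);
#' * `splitting_kymo` -- one peak at 0.25 splitting into a separating pair
#'   (one splitting event), plus a stationary reference peak at 0.75;
#' * `noisy_ring` -- a 64-cell ring with seeded uniform random reactants.
#'
#' The scripted event list is attached as attribute `"ground_truth"`.
#'
#' @param kind One of `"static_peaks"`, `"insertion_kymo"`,
#'   `"splitting_kymo"`, `"noisy_ring"`.
#' @param seed Integer seed (used by `noisy_ring`).
#' @return A `ringleaf_trajectory`, or a `margin_ring` for `noisy_ring`.
#' @export
make_fixture <- function(kind = c("static_peaks", "insertion_kymo",
                                  "splitting_kymo", "noisy_ring"),
                         seed = 1L) {
  kind <- tryCatch(match.arg(kind), error = function(e)
    abort(paste0("Unknown fixture kind; valid kinds: static_peaks, ",
                 "insertion_kymo, splitting_kymo, noisy_ring."),
          class = "ringleaf_config_error"))
  if (kind == "noisy_ring") {
    return(make_ring(64, 10, seed = seed, init_amplitude = 0.2))
  }
  if (kind == "static_peaks") {
    pos <- rep(list(c(0.1, 0.35, 0.6, 0.85)), 10)
    tr <- scripted_trajectory(pos)
    attr(tr, "ground_truth") <- tibble(snapshot = integer(0),
                                       type = character(0),
                                       position = numeric(0))
    return(tr)
  }
  if (kind == "insertion_kymo") {
    pos <- c(rep(list(c(0.0, 0.5)), 5),
             rep(list(c(0.0, 0.25, 0.5, 0.75)), 5))
    tr <- scripted_trajectory(pos)
    attr(tr, "ground_truth") <- tibble(snapshot = c(6L, 6L),
                                       type = "insertion",
                                       position = c(0.25, 0.75))
    return(tr)
  }
  # splitting_kymo: peak at 0.25 becomes a pair separating by 0.01/snapshot
  offs <- c(0, 0, 0, 0, 0, 0.01, 0.02, 0.03, 0.04, 0.05)
  pos <- lapply(seq_along(offs), function(i) {
    if (offs[i] == 0) c(0.25, 0.75)
    else c(0.25 - offs[i], 0.25 + offs[i], 0.75)
  })
  tr <- scripted_trajectory(pos)
  attr(tr, "ground_truth") <- tibble(snapshot = 6L, type = "splitting",
                                     position = 0.25)
  tr
}
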