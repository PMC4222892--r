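#' Tidy a simulation trajectory
#'
#' @param x A `ringleaf_trajectory`.
#' @param ... Unused.
#' @return A tibble with one row per vertex per snapshot: `snapshot`,
#'   `step`, `time`, `vertex`, `x`, `y`, `u`, `v` (reactants of the cell
#'   anchored at the vertex).
#' @method tidy ringleaf_trajectory
#' @export
tidy.ringleaf_trajectory <- function(x, ...) {
  purrr::map_dfr(seq_along(x$snapshots), function(si) {
    sn <- x$snapshots[[si]]
    r <- sn$ring
    tibble(snapshot = si, step = sn$step, time = sn$time,
           vertex = seq_along(r$x), x = r$x, y = r$y, u = r$u, v = r$v)
  })
}

#' One-row summary of a trajectory
#'
#' @param x A `ringleaf_trajectory`.
#' @param ... Unused.
#' @return A tibble: `n_snapshots`, `n_cells_initial`, `n_cells_final`,
#'   `arc_length_final`, `area_final`, `seed`, `config_hash`,
#'   `n_clipped`, `n_degenerate_directions`.
#' @method glance ringleaf_trajectory
#' @export
glance.ringleaf_trajectory <- function(x, ...) {
  first <- x$snapshots[[1]]$ring
  last <- x$snapshots[[length(x$snapshots)]]$ring
  tibble(n_snapshots = length(x$snapshots),
         n_cells_initial = n_cells(first),
         n_cells_final = n_cells(last),
         arc_length_final = sum(cell_lengths(last)),
         area_final = ring_area(last),
         seed = x$seed,
         config_hash = x$config_hash,
         n_clipped = unname(x$warnings["n_clipped"]),
         n_degenerate_directions =
           unname(x$warnings["n_degenerate_directions"]))
}

#' Tidy a peak genealogy
#'
#' @param x A `peak_genealogy`.
#' @param what Which table to return: `"events"` (default), `"peaks"`,
#'   `"tracks"`, or `"counts"`.
#' @param ... Unused.
#' @return The requested tibble.
#' @method tidy peak_genealogy
#' @export
tidy.peak_genealogy <- function(x, what = c("events", "peaks", "tracks",
                                            "counts"), ...) {
  what <- match.arg(what)
  x[[what]]
}

#' One-row summary of a peak genealogy
#'
#' @param x A `peak_genealogy`.
#' @param ... Unused.
#' @return A tibble: `n_snapshots`, `n_peaks_tracked`, `n_peaks_final`,
#'   `n_insertion`, `n_splitting`, `n_disappearance`, `n_ambiguous`.
#' @method glance peak_genealogy
#' @export
glance.peak_genealogy <- function(x, ...) {
  ev <- x$events$type
  tibble(n_snapshots = max(x$counts$snapshot),
         n_peaks_tracked = nrow(x$peaks),
         n_peaks_final = x$counts$n_peaks[nrow(x$counts)],
         n_insertion = sum(ev == "insertion"),
         n_splitting = sum(ev == "splitting"),
         n_disappearance = sum(ev == "disappearance"),
         n_ambiguous = sum(ev == "ambiguous"))
}

#' One-row summary of a branch tree
#'
#' @param x A `branch_tree`.
#' @param ... Unused.
#' @return A tibble with leaflet counts by order (`terminal`, `primary`,
#'   `secondary`, `tertiary_plus`, `total`; base excluded) and
#'   `n_ambiguous` order assignments.
#' @method glance branch_tree
#' @export
glance.branch_tree <- function(x, ...) {
  dplyr::bind_cols(tree_counts(x),
                   tibble(n_ambiguous = attr(x, "n_ambiguous") %||% 0L))
}

#' Tidy an ideal insertion tree
#'
#' @param x An `ideal_insertion_tree`.
#' @param ... Unused.
#' @return Its branch-tree tibble (one row per peak with axis and order).
#' @method tidy ideal_insertion_tree
#' @export
tidy.ideal_insertion_tree <- function(x, ...) x$tree

#' One-row summary of an ideal insertion tree
#'
#' @param x An `ideal_insertion_tree`.
#' @param ... Unused.
#' @return A tibble: `n_events` plus leaflet counts by order.
#' @method glance ideal_insertion_tree
#' @export
glance.ideal_insertion_tree <- function(x, ...) {
  dplyr::bind_cols(tibble(n_events = x$n_events), tree_counts(x$tree))
}

#' Tidy a kymograph into long format
#'
#' @param x A `ringleaf_kymograph`.
#' @param ... Unused.
#' @return A tibble: `snapshot`, `time`, `arc` (bin centre), `u`.
#' @method tidy ringleaf_kymograph
#' @export
tidy.ringleaf_kymograph <- function(x, ...) {
  tibble(snapshot = rep(seq_len(nrow(x)), times = ncol(x)),
         time = rep(attr(x, "time"), times = ncol(x)),
         arc = rep(attr(x, "arc"), each = nrow(x)),
         u = as.vector(unclass(x)[seq_len(nrow(x)), , drop = FALSE]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
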