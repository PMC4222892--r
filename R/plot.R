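#' Plot a kymograph as a grayscale space-time raster
#'
#' Time runs upward, normalized arc position rightward; the activator value
#' is mapped to a grayscale fill (light = high), the conventional rendering
#' of spatiotemporal plots of margin patterns.
#'
#' @param object A [kymograph()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ringleaf_kymograph
#' @export
autoplot.ringleaf_kymograph <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$arc, y = .data$time,
                                   fill = .data$u)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::labs(x = "arc position (fraction of perimeter)", y = "time",
                  fill = "activator u") +
    ggplot2::theme_minimal()
}

#' Plot ring outlines of a trajectory
#'
#' Draws the margin polygon at selected snapshots, coloured by the
#' activator value of each cell, overlaying the growth profile of the
#' simulated leaf.
#'
#' @param object A [run_simulation()] result.
#' @param which Snapshot indices to draw (default: 6 spread evenly).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ringleaf_trajectory
#' @export
autoplot.ringleaf_trajectory <- function(object, which = NULL, ...) {
  n <- length(object$snapshots)
  if (is.null(which)) which <- unique(round(seq(1, n, length.out = 6)))
  df <- purrr::map_dfr(which, function(si) {
    r <- object$snapshots[[si]]$ring
    tibble(snapshot = si, vertex = c(seq_along(r$x), 1L),
           x = c(r$x, r$x[1]), y = c(r$y, r$y[1]), u = c(r$u, r$u[1]))
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   group = .data$snapshot,
                                   colour = .data$u)) +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::labs(colour = "activator u") +
    ggplot2::theme_minimal()
}

#' Plot the tracked peak count over time with event marks
#'
#' A step plot of the number of tracked activator peaks per snapshot, with
#' insertion and splitting events marked at their times; the staircase of
#' doublings (1, 2, 4, 8, ...) is the signature of the regular branching
#' cascade.
#'
#' @param genealogy A [build_genealogy()] result.
#' @return A ggplot object.
#' @export
plot_peak_counts <- function(genealogy) {
  cnt <- genealogy$counts
  ev <- genealogy$events
  ev <- ev[ev$type %in% c("insertion", "splitting"), , drop = FALSE]
  p <- ggplot2::ggplot(cnt, ggplot2::aes(x = .data$time,
                                         y = .data$n_peaks)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "time", y = "tracked activator peaks") +
    ggplot2::theme_minimal()
  if (nrow(ev)) {
    p <- p + ggplot2::geom_vline(
      data = ev,
      ggplot2::aes(xintercept = .data$time, colour = .data$type),
      alpha = 0.4, linetype = 2) +
      ggplot2::labs(colour = "event")
  }
  p
}

#' Plot leaflet counts against the ideal-model prediction
#'
#' Compares the simulated leaflet counts per doubling event (points) with
#' the closed-form ideal counts `T_n = 2^n - 1` and `P_n = 4n - 6`
#' (lines).
#'
#' @param counts A [leaflet_count_series()] result.
#' @return A ggplot object.
#' @export
plot_leaflet_counts <- function(counts) {
  sim <- tidyr::pivot_longer(
    counts[, c("event_index", "total", "primary")],
    c("total", "primary"), names_to = "order", values_to = "count")
  nmax <- max(counts$event_index)
  ns <- seq(1, max(2, nmax))
  ideal <- dplyr::bind_rows(
    tibble(event_index = ns, order = "total", count = total_leaflets(ns)),
    tibble(event_index = ns, order = "primary",
           count = primary_leaflets(ns)))
  ggplot2::ggplot(sim, ggplot2::aes(x = .data$event_index,
                                    y = .data$count,
                                    colour = .data$order)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line(data = ideal, linetype = 2) +
    ggplot2::labs(x = "insertion event n", y = "leaflets",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
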