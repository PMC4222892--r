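#' Detect activator peaks on the cyclic chain of cells
#'
#' A peak is a cell that is a strict local maximum of the field in cyclic
#' order (plateaus of equal values are treated as a single candidate,
#' resolved to the lowest cell index) and whose topographic prominence --
#' height above the higher of the two saddles separating it from higher
#' terrain on either side -- is at least `min_prominence`. The global
#' maximum takes its prominence over the global minimum.
#'
#' @param u Per-cell field (length >= 3), or a `margin_ring`.
#' @param min_prominence Minimal topographic prominence.
#' @return Integer vector of peak cell indices in increasing order (possibly
#'   empty).
#' @export
detect_peaks <- function(u, min_prominence = 0.1) {
  if (inherits(u, "margin_ring")) u <- u$u
  n <- length(u)
  if (n < 3) abort("Need >= 3 cells.", class = "ringleaf_invalid_domain")
  if (length(unique(u)) == 1L) return(integer(0))
  # collapse cyclic plateaus: runs of equal consecutive values
  r <- rle(u)
  vals <- r$values
  starts <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  if (length(vals) > 1 && vals[1] == vals[length(vals)]) {
    # merge the run wrapping through index 1; its start is the wrapped one
    starts[1] <- starts[length(starts)]
    vals <- vals[-length(vals)]
    starts <- starts[-length(starts)]
  }
  m <- length(vals)
  if (m < 2) return(integer(0))
  jm <- c(m, 1:(m - 1L))
  jp <- c(2:m, 1L)
  cand <- which(vals > vals[jm] & vals > vals[jp])
  if (!length(cand)) return(integer(0))
  keep <- vapply(cand, function(ci) {
    h <- vals[ci]
    lo_l <- h
    i <- ci
    repeat {
      i <- if (i == 1L) m else i - 1L
      if (i == ci) break
      lo_l <- min(lo_l, vals[i])
      if (vals[i] > h) break
    }
    lo_r <- h
    i <- ci
    repeat {
      i <- if (i == m) 1L else i + 1L
      if (i == ci) break
      lo_r <- min(lo_r, vals[i])
      if (vals[i] > h) break
    }
    (h - max(lo_l, lo_r)) >= min_prominence
  }, logical(1))
  sort(starts[cand[keep]])
}

# minimal cyclic distance between positions on [0, 1)
cyclic_dist <- function(a, b) {
  d <- abs(a - b) %% 1
  pmin(d, 1 - d)
}

# peak positions (normalized arc midpoints) and heights for one snapshot
snapshot_peaks <- function(ring, min_prominence) {
  idx <- detect_peaks(ring$u, min_prominence)
  tibble(cell = idx, position = arc_positions(ring)[idx],
         height = ring$u[idx])
}

#' Track activator peaks through a trajectory
#'
#' Builds a peak genealogy: peaks are matched between consecutive snapshots
#' by nearest normalized arc position within a match radius, and every
#' unmatched new peak is recorded as a birth event classified by where it
#' appears relative to the persisting peaks:
#' * in the interior third of the gap between its two flanking persisting
#'   peaks -- an `insertion` (a peak nucleating mid-gap);
#' * in an outer third, next to a persisting peak (which shifts away as the
#'   pair separates) -- a `splitting`, sharing that nearest flank as parent;
#' * with fewer than one persisting peak to measure against -- `ambiguous`.
#'
#' The match radius is `min(max_match_shift, 0.35 / n_peaks)`: it tightens
#' automatically once many peaks crowd the ring, where a fixed arc fraction
#' would span whole gaps. A peak that vanishes is recorded as a
#' `disappearance`; if a peak reappears within `grace` snapshots and the
#' match radius of a disappeared one, the identity is re-linked and the
#' disappearance cancelled (prominence flicker, not a real death).
#'
#' @param trajectory A [run_simulation()] result (>= 2 snapshots).
#' @param min_prominence Peak prominence threshold.
#' @param max_match_shift Maximal arc-fraction shift for identity matching.
#' @param grace Snapshots a disappeared peak may wait before its identity
#'   expires.
#' @return A `peak_genealogy`: list with tibbles `peaks` (`id`,
#'   `birth_snapshot`, `birth_type`, `parent_id`, `older_flank_id`,
#'   `birth_position`), `events` (`snapshot`, `time`, `type`, `position`,
#'   `peak_id`, `parent_id`), `tracks` (`snapshot`, `time`, `id`,
#'   `position`, `height`), and `counts` (`snapshot`, `time`, `n_peaks`).
#' @export
build_genealogy <- function(trajectory, min_prominence = 0.1,
                            max_match_shift = 0.1, grace = 5L) {
  snaps <- trajectory$snapshots
  if (length(snaps) < 2)
    abort("Need >= 2 snapshots.", class = "ringleaf_contract_violation")

  next_id <- 0L
  live <- tibble(id = integer(0), position = numeric(0),
                 birth_snapshot = integer(0))
  dead <- tibble(id = integer(0), position = numeric(0),
                 birth_snapshot = integer(0), died_at = integer(0),
                 event_row = integer(0))
  peaks <- list()
  events <- list()
  tracks <- list()
  counts <- list()

  for (si in seq_along(snaps)) {
    sn <- snaps[[si]]
    pk <- snapshot_peaks(sn$ring, min_prominence)
    cur <- pk$position
    matched_prev <- rep(NA_integer_, nrow(pk)) # row into live
    if (nrow(live) > 0 && nrow(pk) > 0) {
      shift <- min(max_match_shift, 0.35 / nrow(live))
      dmat <- outer(cur, live$position, cyclic_dist)
      repeat {
        mn <- suppressWarnings(min(dmat))
        if (!is.finite(mn) || mn > shift) break
        w <- which(dmat == mn, arr.ind = TRUE)[1, , drop = TRUE]
        matched_prev[w[1]] <- w[2]
        dmat[w[1], ] <- Inf
        dmat[, w[2]] <- Inf
      }
    }

    new_live <- tibble(id = rep(NA_integer_, nrow(pk)), position = cur,
                       birth_snapshot = rep(NA_integer_, nrow(pk)))
    ok <- !is.na(matched_prev)
    new_live$id[ok] <- live$id[matched_prev[ok]]
    new_live$birth_snapshot[ok] <- live$birth_snapshot[matched_prev[ok]]

    # deaths: previously-live peaks with no match
    died <- setdiff(seq_len(nrow(live)), matched_prev[ok])
    for (dd in died) {
      events[[length(events) + 1L]] <- tibble(
        snapshot = si, time = sn$time, type = "disappearance",
        position = live$position[dd], peak_id = live$id[dd],
        parent_id = NA_integer_)
      dead <- dplyr::bind_rows(dead, tibble(
        id = live$id[dd], position = live$position[dd],
        birth_snapshot = live$birth_snapshot[dd], died_at = si,
        event_row = length(events)))
    }
    dead <- dead[si - dead$died_at <= grace, , drop = FALSE]

    # births: resurrection first, then event classification
    born_rows <- which(!ok)
    persisting <- new_live$position[ok]
    drop_events <- integer(0)
    for (b in born_rows) {
      if (nrow(dead) > 0) {
        dd <- cyclic_dist(cur[b], dead$position)
        # a lone reforming peak keeps its identity wherever it reappears
        shift_d <- if (length(persisting) == 0) 0.5 else
          min(max_match_shift, 0.35 / max(1L, nrow(live)))
        wd <- which.min(dd)
        if (length(wd) && dd[wd] <= shift_d) {
          new_live$id[b] <- dead$id[wd]
          new_live$birth_snapshot[b] <- dead$birth_snapshot[wd]
          drop_events <- c(drop_events, dead$event_row[wd])
          dead <- dead[-wd, , drop = FALSE]
          next
        }
      }
      next_id <- next_id + 1L
      new_live$id[b] <- next_id
      new_live$birth_snapshot[b] <- si
      if (si == 1L || length(persisting) < 1L) {
        type <- if (si == 1L) "initial" else "ambiguous"
        parent <- NA_integer_
        older_flank <- NA_integer_
      } else {
        rel <- (persisting - cur[b]) %% 1
        gap_ahead <- min(rel)
        gap_behind <- 1 - max(rel)
        id_ahead <- new_live$id[ok][which.min(rel)]
        id_behind <- new_live$id[ok][which.max(rel)]
        fr <- gap_behind / (gap_behind + gap_ahead)
        if (fr > 1 / 3 && fr < 2 / 3) {
          type <- "insertion"
          parent <- NA_integer_
        } else {
          type <- "splitting"
          parent <- if (gap_behind <= gap_ahead) id_behind else id_ahead
        }
        bs <- new_live$birth_snapshot[ok]
        age_behind <- bs[which.max(rel)]
        age_ahead <- bs[which.min(rel)]
        older_flank <- if (age_behind == age_ahead) {
          min(id_behind, id_ahead) # tie: earlier identity
        } else if (age_behind < age_ahead) id_behind else id_ahead
      }
      peaks[[length(peaks) + 1L]] <- tibble(
        id = next_id, birth_snapshot = si, birth_type = type,
        parent_id = parent, older_flank_id = older_flank,
        birth_position = cur[b])
      if (type != "initial") {
        events[[length(events) + 1L]] <- tibble(
          snapshot = si, time = sn$time, type = type, position = cur[b],
          peak_id = next_id, parent_id = parent)
      }
    }
    if (length(drop_events)) events[drop_events] <- list(NULL)

    # initial peaks recorded at snapshot 1 (no event)
    if (si == 1L) {
      for (b in seq_len(nrow(pk))) {
        if (is.na(new_live$id[b])) {
          next_id <- next_id + 1L
          new_live$id[b] <- next_id
          new_live$birth_snapshot[b] <- 1L
          peaks[[length(peaks) + 1L]] <- tibble(
            id = next_id, birth_snapshot = 1L, birth_type = "initial",
            parent_id = NA_integer_, older_flank_id = NA_integer_,
            birth_position = cur[b])
        }
      }
    }

    live <- new_live
    tracks[[si]] <- tibble(snapshot = si, time = sn$time, id = new_live$id,
                           position = cur, height = pk$height)
    counts[[si]] <- tibble(snapshot = si, time = sn$time,
                           n_peaks = nrow(new_live))
  }

  events <- events[!vapply(events, is.null, logical(1))]
  structure(list(
    peaks = if (length(peaks)) dplyr::bind_rows(peaks) else
      tibble(id = integer(0), birth_snapshot = integer(0),
             birth_type = character(0), parent_id = integer(0),
             older_flank_id = integer(0), birth_position = numeric(0)),
    events = if (length(events)) dplyr::bind_rows(events) else
      tibble(snapshot = integer(0), time = numeric(0), type = character(0),
             position = numeric(0), peak_id = integer(0),
             parent_id = integer(0)),
    tracks = dplyr::bind_rows(tracks),
    counts = dplyr::bind_rows(counts)),
    class = "peak_genealogy")
}

#' @export
print.peak_genealogy <- function(x, ...) {
  tb <- table(x$events$type)
  cat(sprintf("<peak_genealogy> %d peaks tracked over %d snapshots; events: %s\n",
              nrow(x$peaks), max(x$counts$snapshot),
              paste(names(tb), tb, collapse = ", ")))
  invisible(x)
}

#' Peak-count doubling events of a genealogy
#'
#' Extracts the plateau sequence of the tracked peak count (values that
#' stay constant for at least `min_run` consecutive snapshots, consecutive
#' duplicates collapsed) and labels each plateau that exactly doubles its
#' predecessor as a doubling event.
#'
#' @param genealogy A [build_genealogy()] result.
#' @param min_run Snapshots a count must persist to be a plateau. The
#'   default (10) is an order of magnitude longer than the brief pauses a
#'   doubling wave makes partway through, but far shorter than genuine
#'   inter-event plateaus.
#' @return A tibble with `plateau` (index), `n_peaks`, `snapshot` (first
#'   snapshot of the plateau), and `doubling` (logical: exactly twice the
#'   previous plateau count).
#' @export
doubling_events <- function(genealogy, min_run = 10L) {
  cnt <- genealogy$counts$n_peaks
  r <- rle(cnt)
  keep <- r$lengths >= min_run & r$values > 0
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  vals <- r$values[keep]
  snaps <- starts[keep]
  if (length(vals) > 1) {
    dup <- c(FALSE, vals[-1] == vals[-length(vals)])
    vals <- vals[!dup]
    snaps <- snaps[!dup]
  }
  tibble(plateau = seq_along(vals), n_peaks = vals, snapshot = snaps,
         doubling = c(FALSE, vals[-1] == 2 * vals[-length(vals)]))
}

#' Assign branch orders from a peak genealogy
#'
#' Reconstructs the axis hierarchy of the simulated leaf: the first-emerged
#' peak is the terminal leaflet capping the main (proximodistal) axis; its
#' first birth partner is the base of the primordium (on the main axis,
#' excluded from leaflet counts); every later peak founds a new axis as a
#' child of the axis owning the OLDER of its two flanking peaks at birth.
#' Children of the main axis are primary leaflets, their children secondary,
#' and so on.
#'
#' @param genealogy A [build_genealogy()] result (or the peaks tibble of
#'   an [ideal_insertion_tree()]).
#' @return A `branch_tree`: tibble with one row per peak: `peak_id`,
#'   `birth_snapshot`, `axis_id`, `parent_axis`, `order` (0 = main axis,
#'   1 = primary, ...), `role` (`terminal`, `base`, `leaflet`), and
#'   `ambiguous` (flag: order assigned through an ambiguous event). The
#'   count of ambiguous events is attached as attribute `"n_ambiguous"`.
#' @export
assign_branch_orders <- function(genealogy) {
  pk <- if (inherits(genealogy, "peak_genealogy")) genealogy$peaks
        else genealogy
  if (nrow(pk) < 1)
    abort("Genealogy contains no peaks.", class = "ringleaf_contract_violation")
  pk <- dplyr::arrange(pk, .data$birth_snapshot, .data$id)
  out <- tibble(peak_id = pk$id, birth_snapshot = pk$birth_snapshot,
                axis_id = NA_integer_, parent_axis = NA_integer_,
                order = NA_integer_, role = NA_character_,
                ambiguous = FALSE)
  axis_order <- c(`0` = 0L) # axis_id -> order, axis 0 is the main axis
  next_axis <- 1L
  peak_axis <- setNames(integer(0), character(0)) # peak id -> owning axis
  n_ambiguous <- 0L
  for (i in seq_len(nrow(out))) {
    id <- out$peak_id[i]
    if (i == 1L) {
      out$axis_id[i] <- 0L
      out$order[i] <- 0L
      out$role[i] <- "terminal"
      peak_axis[as.character(id)] <- 0L
      next
    }
    if (i == 2L) {
      out$axis_id[i] <- 0L
      out$order[i] <- 0L
      out$role[i] <- "base"
      peak_axis[as.character(id)] <- 0L
      next
    }
    flank <- pk$older_flank_id[i]
    amb <- is.na(flank) || !as.character(flank) %in% names(peak_axis)
    if (amb) {
      n_ambiguous <- n_ambiguous + 1L
      owner <- 0L # degrade gracefully: attach to the main axis, flagged
    } else {
      owner <- peak_axis[[as.character(flank)]]
    }
    ax <- next_axis
    next_axis <- next_axis + 1L
    axis_order[as.character(ax)] <- axis_order[[as.character(owner)]] + 1L
    out$axis_id[i] <- ax
    out$parent_axis[i] <- owner
    out$order[i] <- axis_order[[as.character(ax)]]
    out$role[i] <- "leaflet"
    out$ambiguous[i] <- amb
    peak_axis[as.character(id)] <- ax
  }
  attr(out, "n_ambiguous") <- n_ambiguous
  class(out) <- c("branch_tree", class(out))
  out
}

#' Leaflet counts by order after each doubling event
#'
#' Combines a genealogy's doubling plateaus with its branch tree: after
#' each plateau the axes founded so far are counted by order. The terminal
#' leaflet counts as one; the base peak is excluded; `total` is all
#' leaflets (terminal + primary + higher orders).
#'
#' @param genealogy A [build_genealogy()] result.
#' @param tree Optionally a precomputed [assign_branch_orders()] result.
#' @param min_run Passed to [doubling_events()].
#' @return A tibble with one row per plateau: `event_index` (doubling
#'   events completed so far, i.e. `log2(n_peaks)` when the cascade is
#'   exact), `n_peaks`, `snapshot`, `terminal`, `primary`, `secondary`,
#'   `tertiary_plus`, `total`, `uncertain` (any ambiguous order
#'   assignments among the counted peaks).
#' @export
leaflet_count_series <- function(genealogy, tree = NULL, min_run = 10L) {
  if (is.null(tree)) tree <- assign_branch_orders(genealogy)
  ev <- doubling_events(genealogy, min_run = min_run)
  purrr::map_dfr(seq_len(nrow(ev)), function(i) {
    upto <- ev$snapshot[i]
    tr <- tree[tree$birth_snapshot <= upto, , drop = FALSE]
    dplyr::bind_cols(
      tibble(event_index = i - 1L, n_peaks = ev$n_peaks[i], snapshot = upto),
      tree_counts(tr),
      tibble(uncertain = any(tr$ambiguous)))
  })
}

#' Space-time kymograph of the activator field
#'
#' Resamples each snapshot's per-cell activator onto `n_grid` equal
#' arc-fraction bins by nearest-cell lookup (the cell whose arc interval
#' contains the bin centre), giving a time-by-position matrix directly
#' comparable to spatiotemporal plots of a growing margin.
#'
#' @param trajectory A [run_simulation()] result.
#' @param n_grid Number of arc bins (>= 8).
#' @return A `ringleaf_kymograph`: numeric matrix (snapshots x bins) of
#'   activator values with attributes `time` (row times) and `arc`
#'   (bin-centre arc fractions).
#' @export
kymograph <- function(trajectory, n_grid = 100L) {
  if (n_grid < 8) abort("n_grid must be >= 8.",
                        class = "ringleaf_contract_violation")
  snaps <- trajectory$snapshots
  mat <- matrix(NA_real_, nrow = length(snaps), ncol = n_grid)
  centres <- (seq_len(n_grid) - 0.5) / n_grid
  for (si in seq_along(snaps)) {
    ring <- snaps[[si]]$ring
    len <- cell_lengths(ring)
    edges <- cumsum(len) / sum(len) # upper arc edge of each cell
    cell_of <- findInterval(centres, c(0, head(edges, -1)),
                            rightmost.closed = FALSE)
    mat[si, ] <- ring$u[cell_of]
  }
  structure(mat, time = vapply(snaps, `[[`, numeric(1), "time"),
            arc = centres, class = "ringleaf_kymograph")
}

#' @export
print.ringleaf_kymograph <- function(x, ...) {
  cat(sprintf("<ringleaf_kymograph> %d snapshots x %d arc bins, u in [%.3g, %.3g]\n",
              nrow(x), ncol(x), min(x), max(x)))
  invisible(x)
}

#' Locate the outermost bulge of the final margin and its activator level
#'
#' Finds the vertex of the last snapshot with the maximal radial distance
#' from the initial ring's centroid (the cumulative outward displacement of
#' the margin) and reports the mean activator of its two adjacent cells,
#' together with that value's quantile within the final activator field.
#' In an expansion-inhibition run the fastest-growing margin regions are
#' the activator troughs, so the outermost bulge should sit at a low
#' activator quantile.
#'
#' @param trajectory A [run_simulation()] result.
#' @return A one-row tibble: `vertex`, `radius`, `u_at_bulge`,
#'   `u_quantile` (fraction of cells with activator below the bulge
#'   value), `u_min`, `u_max`.
#' @export
bulge_activator <- function(trajectory) {
  first <- trajectory$snapshots[[1]]$ring
  cx <- mean(first$x)
  cy <- mean(first$y)
  ring <- trajectory$snapshots[[length(trajectory$snapshots)]]$ring
  rad <- sqrt((ring$x - cx)^2 + (ring$y - cy)^2)
  w <- which.max(rad)
  n <- length(ring$u)
  prev_cell <- if (w == 1L) n else w - 1L
  u_b <- (ring$u[prev_cell] + ring$u[w]) / 2
  tibble(vertex = w, radius = rad[w], u_at_bulge = u_b,
         u_quantile = mean(ring$u < u_b),
         u_min = min(ring$u), u_max = max(ring$u))
}
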