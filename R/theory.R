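#' Ideal insertion model of the branching cascade
#'
#' The purely combinatorial abstraction of regular peak doubling: start
#' with one peak (the future terminal leaflet) on the ring; event 1 adds
#' its antipodal partner (the base of the primordium); every subsequent
#' event inserts one new peak at the midpoint of every inter-peak gap, so
#' the peak count doubles exactly. Each new peak founds an axis attached to
#' the axis of the OLDER of its two flanking peaks. This generative process
#' is the single source of truth for the closed-form leaflet counts
#' ([total_leaflets()], [primary_leaflets()]) and for the per-primary
#' secondary profiles ([secondary_profile()]).
#'
#' @param n_events Number of insertion events (>= 0).
#' @return A list of class `ideal_insertion_tree` with `peaks` (tibble:
#'   `id`, `birth_snapshot` = birth event, `position` on the unit circle,
#'   `older_flank_id`), `tree` (the [assign_branch_orders()] result), and
#'   `n_events`.
#' @export
ideal_insertion_tree <- function(n_events) {
  if (!is.numeric(n_events) || length(n_events) != 1 || n_events < 0 ||
      n_events != round(n_events)) {
    abort("`n_events` must be a single integer >= 0.",
          class = "ringleaf_domain_error")
  }
  n_events <- as.integer(n_events)
  pos <- 0
  birth <- 0L
  ids <- 1L
  next_id <- 2L
  if (n_events >= 1L) {
    pos <- c(pos, 0.5)
    birth <- c(birth, 1L)
    ids <- c(ids, 2L)
    next_id <- 3L
  }
  older_flank <- rep(NA_integer_, length(ids))
  if (n_events >= 2L) {
    for (ev in 2:n_events) {
      ord <- order(pos)
      p_s <- pos[ord]
      id_s <- ids[ord]
      b_s <- birth[ord]
      m <- length(p_s)
      nxt <- c(2:m, 1L)
      gap_mid <- ((p_s + c(p_s[-1], p_s[1] + 1)) / 2) %% 1
      new_pos <- gap_mid
      older <- ifelse(b_s < b_s[nxt], id_s,
                      ifelse(b_s > b_s[nxt], id_s[nxt],
                             pmin(id_s, id_s[nxt])))
      new_ids <- next_id + seq_len(m) - 1L
      next_id <- next_id + m
      pos <- c(pos, new_pos)
      ids <- c(ids, new_ids)
      birth <- c(birth, rep(ev, m))
      older_flank <- c(older_flank, older)
    }
  }
  peaks <- tibble(id = ids, birth_snapshot = birth, birth_type =
                    ifelse(birth <= 1L, "initial", "insertion"),
                  parent_id = NA_integer_, older_flank_id = older_flank,
                  birth_position = pos)
  tree <- assign_branch_orders(peaks)
  structure(list(peaks = peaks, tree = tree, n_events = n_events),
            class = "ideal_insertion_tree")
}

#' @export
print.ideal_insertion_tree <- function(x, ...) {
  cat(sprintf("<ideal_insertion_tree> %d events, %d peaks\n",
              x$n_events, nrow(x$peaks)))
  invisible(x)
}

# leaflet counts by order of a branch tree (base excluded); the terminal
# peak counts as a leaflet only once the base exists to oppose it, so a
# lone initial peak yields zero leaflets (T_0 = 0)
tree_counts <- function(tree) {
  terminal <- as.integer(any(tree$role == "terminal") &&
                           any(tree$role == "base"))
  primary <- sum(tree$order == 1L, na.rm = TRUE)
  secondary <- sum(tree$order == 2L, na.rm = TRUE)
  tertiary_plus <- sum(tree$order >= 3L, na.rm = TRUE)
  tibble(terminal = terminal, primary = primary, secondary = secondary,
         tertiary_plus = tertiary_plus,
         total = terminal + primary + secondary + tertiary_plus)
}

#' Leaflet counts of the ideal tree, by order
#'
#' @param n_events Number of insertion events.
#' @return A one-row tibble: `n_events`, `terminal`, `primary`,
#'   `secondary`, `tertiary_plus`, `total`.
#' @export
ideal_leaflet_counts <- function(n_events) {
  tr <- ideal_insertion_tree(n_events)$tree
  dplyr::bind_cols(tibble(n_events = as.integer(n_events)), tree_counts(tr))
}

#' Total leaflet count after n insertion events (closed form)
#'
#' After `n` events there are `2^n` peaks; subtracting the one peak that is
#' the base of the leaf primordium gives `T_n = 2^n - 1` leaflets of all
#' orders.
#'
#' @param n Vector of event counts (>= 0).
#' @return Integer-valued numeric vector `2^n - 1`.
#' @export
total_leaflets <- function(n) {
  if (any(n < 0) || any(n != round(n)))
    abort("`n` must contain integers >= 0.", class = "ringleaf_domain_error")
  2^n - 1
}

#' Primary leaflet count after n insertion events (closed form)
#'
#' Event 2 creates the first two primary leaflets (one on each side of the
#' main axis); every later event adds four more on the recently extended
#' region of the main axis: `P_1 = 0`, `P_2 = 2`, `P_n = P_{n-1} + 4`,
#' giving the closed form `P_n = 4 n - 6` for `n >= 2`.
#'
#' @param n Vector of event counts (>= 1).
#' @return Numeric vector of primary-leaflet counts.
#' @export
primary_leaflets <- function(n) {
  if (any(n < 1) || any(n != round(n)))
    abort("`n` must contain integers >= 1.", class = "ringleaf_domain_error")
  ifelse(n == 1, 0, 4 * n - 6)
}

#' Secondary (and higher) leaflet counts per primary leaflet
#'
#' Reads each primary axis's subtree off the ideal insertion tree and
#' reports the half-leaf profile: the primaries lying on one side of the
#' main axis (birth positions in (0, 0.5)), ordered from the base of the
#' leaf towards the tip. The consistency identity
#' `1 + sum over all primaries of (1 + subtree) = T_n` (terminal plus, per
#' primary, the primary itself and its descendants) holds exactly.
#'
#' @param n Number of insertion events (>= 2).
#' @return A tibble with one row per half-leaf primary: `position` (1 =
#'   nearest the base), `birth_event`, `secondaries` (order-2 descendants),
#'   `subtree` (all descendants of any order), `leaflets_on_primary`
#'   (subtree + the primary itself).
#' @export
secondary_profile <- function(n) {
  if (length(n) != 1 || n < 2 || n != round(n))
    abort("`n` must be a single integer >= 2.", class = "ringleaf_domain_error")
  it <- ideal_insertion_tree(n)
  tr <- it$tree
  pk <- it$peaks
  # descendants per axis
  kids <- split(tr$axis_id, tr$parent_axis)
  subtree_size <- function(ax) {
    ch <- kids[[as.character(ax)]]
    if (is.null(ch)) return(0L)
    sum(vapply(ch, function(a) 1L + subtree_size(a), integer(1)))
  }
  prim <- tr[!is.na(tr$order) & tr$order == 1L, , drop = FALSE]
  prim_pos <- pk$birth_position[match(prim$peak_id, pk$id)]
  half <- prim_pos > 0 & prim_pos < 0.5
  prim_h <- prim[half, , drop = FALSE]
  pos_h <- prim_pos[half]
  # terminal sits at position 0, base at 0.5: order from base to tip
  ordb <- order(-pos_h)
  prim_h <- prim_h[ordb, , drop = FALSE]
  sec <- vapply(prim_h$axis_id, function(ax) {
    ch <- kids[[as.character(ax)]]
    if (is.null(ch)) 0L else length(ch)
  }, integer(1))
  sub <- vapply(prim_h$axis_id, subtree_size, integer(1))
  tibble(position = seq_len(nrow(prim_h)),
         birth_event = prim_h$birth_snapshot,
         secondaries = sec, subtree = sub,
         leaflets_on_primary = sub + 1L)
}

#' Compare observed leaflet counts with model predictions
#'
#' Joins an observed-count table to a predicted series on the shared key
#' column (`stage` or `position`) and reports residuals
#' (`predicted - observed`) with summary absolute-error statistics.
#'
#' @param observed Data frame with a key column (`stage` or `position`)
#'   and a `count` column.
#' @param predicted Data frame with the same key column and a `count`
#'   column (e.g. built from [total_leaflets()] or [secondary_profile()]).
#' @return A tibble with the key, `observed`, `predicted`, `residual`;
#'   summary statistics (`mae`, `max_abs_error`, `n`) attached as
#'   attribute `"summary"`.
#' @export
compare_counts <- function(observed, predicted) {
  check <- function(df, nm) {
    if (!is.data.frame(df) || nrow(df) == 0) {
      abort(sprintf("`%s` must be a non-empty data frame.", nm),
            class = "ringleaf_schema_error")
    }
    key <- intersect(c("stage", "position"), names(df))
    missing <- character(0)
    if (!length(key)) missing <- c(missing, "stage|position")
    if (!"count" %in% names(df)) missing <- c(missing, "count")
    if (length(missing)) {
      abort(sprintf("`%s` is missing required column(s): %s.", nm,
                    paste(missing, collapse = ", ")),
            class = "ringleaf_schema_error")
    }
    key[1]
  }
  key_o <- check(observed, "observed")
  key_p <- check(predicted, "predicted")
  if (key_o != key_p)
    abort(sprintf("Key columns differ: observed has `%s`, predicted `%s`.",
                  key_o, key_p), class = "ringleaf_schema_error")
  obs <- dplyr::select(as_tibble(observed), !!key_o, observed = "count")
  prd <- dplyr::select(as_tibble(predicted), !!key_o, predicted = "count")
  out <- dplyr::inner_join(obs, prd, by = key_o)
  out$residual <- out$predicted - out$observed
  attr(out, "summary") <- tibble(mae = mean(abs(out$residual)),
                                 max_abs_error = max(abs(out$residual)),
                                 n = nrow(out))
  out
}
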