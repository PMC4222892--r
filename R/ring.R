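#' Closed ring of margin cells
#'
#' A `margin_ring` discretizes the leaf margin as a closed polygon. Each
#' polygon segment ("cell") is one reaction compartment carrying an
#' activator/inhibitor pair `(u, v)`. Cell `i` connects vertex `i` to vertex
#' `i + 1` (cyclically), vertices are ordered counterclockwise, and the
#' outward normal of a cell is its direction vector rotated by -90 degrees.
#'
#' @param n_cells Number of cells (polygon segments), at least 3.
#' @param radius Circumradius of the initial regular polygon (> 0).
#' @param seed Integer seed for the random initial reactant state.
#' @param init_amplitude Width of the uniform perturbation applied to both
#'   reactants around the homogeneous steady state of `params`. Zero gives
#'   cells exactly at the steady state.
#' @param params An [rd_params()] object; its interior steady state centres
#'   the initial condition. Defaults to the packaged insertion-regime set.
#'
#' @return A `margin_ring`: list with numeric fields `x`, `y` (vertex
#'   coordinates) and `u`, `v` (per-cell reactant state).
#' @examples
#' r <- make_ring(6, 1, seed = 1)
#' cell_lengths(r)
#' @export
make_ring <- function(n_cells, radius, seed = 1L, init_amplitude = 0.1,
                      params = insertion_config()$rd) {
  if (!is.numeric(n_cells) || length(n_cells) != 1 || n_cells < 3 ||
      n_cells != round(n_cells)) {
    abort("`n_cells` must be a single integer >= 3 (a polygon needs 3 cells).",
          class = "ringleaf_invalid_domain")
  }
  if (!is.numeric(radius) || length(radius) != 1 || radius <= 0) {
    abort("`radius` must be a single positive length.",
          class = "ringleaf_invalid_domain")
  }
  if (init_amplitude < 0) {
    abort("`init_amplitude` must be >= 0.", class = "ringleaf_invalid_domain")
  }
  n <- as.integer(n_cells)
  ss <- homogeneous_steady_state(params)
  th <- 2 * pi * (seq_len(n) - 1) / n
  set.seed(seed)
  new_margin_ring(
    x = radius * cos(th),
    y = radius * sin(th),
    u = ss[["u"]] + runif(n, -init_amplitude / 2, init_amplitude / 2),
    v = ss[["v"]] + runif(n, -init_amplitude / 2, init_amplitude / 2)
  )
}

#' Low-level margin_ring constructor
#'
#' Validates the closed-ring invariants (>= 3 cells, positive cell lengths)
#' and enforces canonical counterclockwise winding, reversing the vertex
#' order if the polygon is supplied clockwise.
#'
#' @param x,y Vertex coordinates (equal length, >= 3).
#' @param u,v Per-cell reactant values, one per vertex (cell `i` starts at
#'   vertex `i`).
#' @return A `margin_ring`.
#' @export
new_margin_ring <- function(x, y, u, v) {
  n <- length(x)
  if (n < 3 || length(y) != n || length(u) != n || length(v) != n) {
    abort("A margin_ring needs >= 3 vertices and matching u, v lengths.",
          class = "ringleaf_invalid_domain")
  }
  r <- structure(list(x = as.numeric(x), y = as.numeric(y),
                      u = as.numeric(u), v = as.numeric(v)),
                 class = "margin_ring")
  if (ring_area(r) < 0) {
    # reverse to canonical counterclockwise winding; cell i (vertex i -> i+1)
    # keeps its state by reversing cells in step with vertices
    idx <- c(1L, n:2L)
    cell_idx <- c(n:1L)
    r$x <- r$x[idx]; r$y <- r$y[idx]
    r$u <- r$u[cell_idx]; r$v <- r$v[cell_idx]
  }
  if (any(cell_lengths(r) <= 0)) {
    abort("Every cell length must be > 0 (coincident vertices).",
          class = "ringleaf_invalid_domain")
  }
  r
}

#' @export
print.margin_ring <- function(x, ...) {
  cat(sprintf("<margin_ring> %d cells, arc length %.4g, area %.4g\n",
              n_cells(x), sum(cell_lengths(x)), ring_area(x)))
  invisible(x)
}

#' Number of cells of a margin ring
#' @param ring A `margin_ring`.
#' @return Integer cell count (equal to the vertex count).
#' @export
n_cells <- function(ring) length(ring$x)

#' Per-cell segment lengths
#' @inheritParams n_cells
#' @return Numeric vector; entry `i` is the length of the segment from
#'   vertex `i` to vertex `i + 1` (cyclic).
#' @export
cell_lengths <- function(ring) {
  n <- length(ring$x)
  j <- c(2:n, 1L)
  sqrt((ring$x[j] - ring$x)^2 + (ring$y[j] - ring$y)^2)
}

#' Signed polygon area (shoelace)
#'
#' Positive for counterclockwise winding. Only meaningful as an area for
#' non-self-intersecting rings; self-intersection is permitted and never
#' repaired.
#' @inheritParams n_cells
#' @return Signed area.
#' @export
ring_area <- function(ring) {
  n <- length(ring$x)
  j <- c(2:n, 1L)
  sum(ring$x * ring$y[j] - ring$x[j] * ring$y) / 2
}

# outward unit normal of each cell: direction vector rotated -90 degrees,
# i.e. (dy, -dx) / len, outward under counterclockwise winding
cell_normals <- function(ring) {
  n <- length(ring$x)
  j <- c(2:n, 1L)
  dx <- ring$x[j] - ring$x
  dy <- ring$y[j] - ring$y
  len <- sqrt(dx^2 + dy^2)
  list(nx = dy / len, ny = -dx / len, len = len)
}

#' Outward growth direction at each vertex
#'
#' The direction of boundary propagation at a vertex is the sum of the
#' outward unit normals of its two adjacent cells, renormalized to unit
#' length so that speed is controlled solely by the reactant law. In the
#' degenerate case of exactly antiparallel adjacent normals (zero sum) the
#' direction falls back to the normal of the longer adjacent cell and a
#' warning counter is raised.
#'
#' @inheritParams n_cells
#' @return A tibble with one row per vertex: `vertex`, `dx`, `dy` (unit
#'   direction components). The number of antiparallel fallbacks is attached
#'   as attribute `"n_degenerate"`.
#' @export
growth_directions <- function(ring) {
  cn <- cell_normals(ring)
  n <- length(ring$x)
  k <- c(n, 1:(n - 1L)) # incoming cell of vertex i is cell i-1
  sx <- cn$nx[k] + cn$nx
  sy <- cn$ny[k] + cn$ny
  m <- sqrt(sx^2 + sy^2)
  bad <- which(m < 1e-12)
  if (length(bad)) {
    longer_in <- cn$len[k][bad] >= cn$len[bad]
    pick <- ifelse(longer_in, k[bad], bad)
    sx[bad] <- cn$nx[pick]
    sy[bad] <- cn$ny[pick]
    m[bad] <- 1
  }
  out <- tibble(vertex = seq_len(n), dx = sx / m, dy = sy / m)
  attr(out, "n_degenerate") <- length(bad)
  out
}

#' Displace ring vertices along their growth directions
#'
#' Boundary propagation: each vertex moves by `dt * speed` along its outward
#' growth direction. Reactant states and the vertex count are unchanged.
#'
#' @inheritParams n_cells
#' @param speeds Non-negative per-vertex speeds (length = vertex count).
#' @param dt Time step (> 0).
#' @return The displaced `margin_ring`.
#' @export
propagate <- function(ring, speeds, dt) {
  n <- length(ring$x)
  if (length(speeds) != n) {
    abort("`speeds` must have one entry per vertex.",
          class = "ringleaf_contract_violation")
  }
  if (any(speeds < 0)) {
    abort("Negative vertex speeds are a contract violation; clip upstream.",
          class = "ringleaf_contract_violation")
  }
  if (!is.numeric(dt) || dt <= 0) {
    abort("`dt` must be > 0.", class = "ringleaf_contract_violation")
  }
  d <- growth_directions(ring)
  ring$x <- ring$x + dt * speeds * d$dx
  ring$y <- ring$y + dt * speeds * d$dy
  ring
}

#' Divide cells exceeding a length threshold
#'
#' Every cell longer than `L_div` is split at its midpoint into two daughter
#' cells that inherit the mother's reactant state exactly. At most one
#' division per cell per call; daughters that still exceed the threshold
#' divide on the next call.
#'
#' @inheritParams n_cells
#' @param L_div Division length threshold (> 0).
#' @return A `margin_ring` with `n + k` cells, `k` the number of cells that
#'   exceeded the threshold.
#' @export
divide_cells <- function(ring, L_div) {
  if (!is.numeric(L_div) || L_div <= 0) {
    abort("`L_div` must be > 0.", class = "ringleaf_contract_violation")
  }
  len <- cell_lengths(ring)
  over <- len > L_div
  if (!any(over)) return(ring)
  n <- length(ring$x)
  j <- c(2:n, 1L)
  # interleave midpoints after the leading vertex of each dividing cell
  reps <- ifelse(over, 2L, 1L)
  pos <- rep(seq_len(n), reps)
  x <- ring$x[pos]; y <- ring$y[pos]
  u <- ring$u[pos]; v <- ring$v[pos]
  second <- which(duplicated(pos))
  x[second] <- (ring$x[pos[second]] + ring$x[j[pos[second]]]) / 2
  y[second] <- (ring$y[pos[second]] + ring$y[j[pos[second]]]) / 2
  structure(list(x = x, y = y, u = u, v = v), class = "margin_ring")
}

#' Normalized arc positions of cell midpoints
#'
#' Arc length is accumulated from vertex 1 and normalized to `[0, 1)`; the
#' position of cell `i` is its midpoint along the perimeter.
#' @inheritParams n_cells
#' @return Numeric vector in `[0, 1)`, one entry per cell.
#' @export
arc_positions <- function(ring) {
  len <- cell_lengths(ring)
  tot <- sum(len)
  (cumsum(len) - len / 2) / tot
}

#' @method as_tibble margin_ring
#' @export
as_tibble.margin_ring <- function(x, ...) {
  tibble(vertex = seq_along(x$x), x = x$x, y = x$y, u = x$u, v = x$v)
}
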