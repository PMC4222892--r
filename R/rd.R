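#' Parameters of the linear activator-inhibitor model
#'
#' The reaction kinetics are the bounded-linear-synthesis family: each
#' reactant is produced at a rate that is linear in both reactants, clamped
#' to a non-negative saturation ceiling, and removed by first-order decay,
#'
#' \deqn{du/dt = clamp(a u + b v + c, 0, S_u) - \mu_u u + D_u \nabla^2 u}
#' \deqn{dv/dt = clamp(d u + e v + f, 0, S_v) - \mu_v v + D_v \nabla^2 v}
#'
#' With an autocatalytic activator (`a > mu_u`), cross-activation of the
#' inhibitor (`d > 0`), inhibition of the activator (`b < 0`) and a much
#' faster-diffusing inhibitor (`D_v >> D_u`) this supports diffusion-driven
#' (Turing) instability; the clamps are the only nonlinearity and set the
#' pattern amplitude.
#'
#' @param a,b,c Activator synthesis coefficients.
#' @param d,e,f Inhibitor synthesis coefficients.
#' @param S_u,S_v Synthesis saturation ceilings (>= 0).
#' @param mu_u,mu_v First-order decay rates (> 0).
#' @param D_u,D_v Diffusion coefficients (>= 0; `D_v > D_u` for the Turing
#'   regime).
#' @param dt_rd Explicit-Euler reaction-diffusion time step (> 0), must
#'   respect [rd_stability_limit()].
#' @param coupling_mode `"topological"` (each cell one compartment at unit
#'   spacing; the default, because domain growth is realized by cell
#'   division) or `"metric"` (finite-volume Laplacian using geometric cell
#'   lengths).
#' @return An `rd_params` object.
#' @export
rd_params <- function(a, b, c, d, e, f,
                      S_u, S_v, mu_u, mu_v, D_u, D_v,
                      dt_rd = 0.04,
                      coupling_mode = c("topological", "metric")) {
  coupling_mode <- match.arg(coupling_mode)
  num1 <- function(z, nm) {
    if (!is.numeric(z) || length(z) != 1 || !is.finite(z)) {
      abort(sprintf("`%s` must be a single finite number.", nm),
            class = "ringleaf_config_error")
    }
    as.numeric(z)
  }
  p <- list(a = num1(a, "a"), b = num1(b, "b"), c = num1(c, "c"),
            d = num1(d, "d"), e = num1(e, "e"), f = num1(f, "f"),
            S_u = num1(S_u, "S_u"), S_v = num1(S_v, "S_v"),
            mu_u = num1(mu_u, "mu_u"), mu_v = num1(mu_v, "mu_v"),
            D_u = num1(D_u, "D_u"), D_v = num1(D_v, "D_v"),
            dt_rd = num1(dt_rd, "dt_rd"), coupling_mode = coupling_mode)
  if (p$S_u < 0 || p$S_v < 0)
    abort("Saturation ceilings S_u, S_v must be >= 0.",
          class = "ringleaf_config_error")
  if (p$mu_u <= 0 || p$mu_v <= 0)
    abort("Decay rates mu_u, mu_v must be > 0.",
          class = "ringleaf_config_error")
  if (p$D_u < 0 || p$D_v < 0)
    abort("Diffusion coefficients must be >= 0.",
          class = "ringleaf_config_error")
  if (p$dt_rd <= 0)
    abort("dt_rd must be > 0.", class = "ringleaf_config_error")
  structure(p, class = "rd_params")
}

#' @export
print.rd_params <- function(x, ...) {
  cat("<rd_params>\n")
  cat(sprintf("  synthesis u: clamp(%g u + %g v + %g, 0, %g), decay %g\n",
              x$a, x$b, x$c, x$S_u, x$mu_u))
  cat(sprintf("  synthesis v: clamp(%g u + %g v + %g, 0, %g), decay %g\n",
              x$d, x$e, x$f, x$S_v, x$mu_v))
  cat(sprintf("  D_u %g, D_v %g, dt_rd %g, coupling %s\n",
              x$D_u, x$D_v, x$dt_rd, x$coupling_mode))
  invisible(x)
}

#' Interior homogeneous steady state of the reaction terms
#'
#' Solves the 2x2 linear system `(a - mu_u) u + b v + c = 0`,
#' `d u + (e - mu_v) v + f = 0` and checks that both unclamped synthesis
#' rates at the fixed point lie inside `[0, S)`: at or above the lower
#' clamp (a trivial fixed point with zero synthesis is legitimate) and
#' strictly below the saturation ceiling.
#'
#' @param params An [rd_params()] object.
#' @return Named numeric vector `c(u = , v = )`.
#' @export
homogeneous_steady_state <- function(params) {
  A <- matrix(c(params$a - params$mu_u, params$b,
                params$d, params$e - params$mu_v),
              2, 2, byrow = TRUE)
  if (abs(det(A)) < 1e-12) {
    abort("Reaction system is singular: no unique interior steady state.",
          class = "ringleaf_no_interior_steady_state")
  }
  ss <- solve(A, -c(params$c, params$f))
  syn_u <- params$a * ss[1] + params$b * ss[2] + params$c
  syn_v <- params$d * ss[1] + params$e * ss[2] + params$f
  if (syn_u < 0 || syn_u >= params$S_u || syn_v < 0 || syn_v >= params$S_v) {
    abort(paste0("Fixed point lies outside the clamp interior ",
                 sprintf("(synthesis u = %.4g not in [0, %g), v = %.4g not in [0, %g)).",
                         syn_u, params$S_u, syn_v, params$S_v)),
          class = "ringleaf_no_interior_steady_state")
  }
  c(u = ss[1], v = ss[2])
}

#' Reaction rates (no diffusion)
#'
#' Element-wise `du/dt`, `dv/dt` from the clamped-linear kinetics; the clamp
#' applies to synthesis only, decay is always active.
#'
#' @param u,v Per-cell reactant values (equal length).
#' @inheritParams homogeneous_steady_state
#' @return A list with numeric fields `du`, `dv`.
#' @export
reaction_rates <- function(u, v, params) {
  syn_u <- pmin(pmax(params$a * u + params$b * v + params$c, 0), params$S_u)
  syn_v <- pmin(pmax(params$d * u + params$e * v + params$f, 0), params$S_v)
  list(du = syn_u - params$mu_u * u, dv = syn_v - params$mu_v * v)
}

#' Cyclic Laplacian on the ring of cells
#'
#' Topological mode treats each cell as one compartment at unit spacing:
#' `value[i-1] - 2 value[i] + value[i+1]`. Metric mode is the conservative
#' finite-volume form with inter-cell spacing `(len_i + len_j) / 2` and
#' division by `len_i`, so that `sum(len * term)` vanishes exactly (flux
#' conservation). Both are returned before multiplication by the diffusion
#' coefficient.
#'
#' @param values Per-cell field (length >= 3).
#' @param lengths Per-cell lengths, required in metric mode.
#' @param mode `"topological"` or `"metric"`.
#' @return Numeric vector of per-cell diffusion terms.
#' @export
laplacian_ring <- function(values, lengths = NULL,
                           mode = c("topological", "metric")) {
  mode <- match.arg(mode)
  n <- length(values)
  if (n < 3) abort("Need >= 3 cells.", class = "ringleaf_invalid_geometry")
  jm <- c(n, 1:(n - 1L))
  jp <- c(2:n, 1L)
  if (mode == "topological") {
    return(values[jm] - 2 * values + values[jp])
  }
  if (is.null(lengths) || any(lengths <= 0)) {
    abort("Metric mode requires positive per-cell lengths.",
          class = "ringleaf_invalid_geometry")
  }
  h_m <- (lengths + lengths[jm]) / 2
  h_p <- (lengths + lengths[jp]) / 2
  flux_m <- (values - values[jm]) / h_m # flux entering from the left face
  flux_p <- (values[jp] - values) / h_p # flux entering from the right face
  (flux_p - flux_m) / lengths
}

#' Explicit-Euler stability limit for the RD step
#'
#' Upper bound on `dt_rd` for the forward-Euler scheme: the cyclic Laplacian
#' has spectral radius 4 (topological, unit spacing) or `4 / min_len^2`
#' (metric), and the decay adds `max(mu_u, mu_v)`.
#'
#' @inheritParams homogeneous_steady_state
#' @param min_len Smallest cell length, used in metric mode only.
#' @return The maximal stable `dt`.
#' @export
rd_stability_limit <- function(params, min_len = 1) {
  Dmax <- max(params$D_u, params$D_v)
  spacing2 <- if (params$coupling_mode == "metric") min_len^2 else 1
  2 / (4 * Dmax / spacing2 + max(params$mu_u, params$mu_v))
}

#' Advance the reactant fields by forward-Euler substeps
#'
#' Performs `n_substeps` explicit Euler updates of reactions plus diffusion
#' on the ring's cells. Negative concentrations produced by a step are
#' clipped to zero and counted; NaN/Inf triggers a numerical-blowup error
#' naming the first offending cell and substep.
#'
#' @param ring A [make_ring()] object carrying the current `u`, `v`.
#' @inheritParams homogeneous_steady_state
#' @param n_substeps Number of Euler substeps (>= 1).
#' @return The ring with updated `u`, `v`; the number of negative-value
#'   clips is attached as attribute `"n_clipped"`.
#' @export
rd_step <- function(ring, params, n_substeps = 1L) {
  lens <- if (params$coupling_mode == "metric") cell_lengths(ring) else NULL
  min_len <- if (is.null(lens)) 1 else min(lens)
  dt <- params$dt_rd
  if (dt > rd_stability_limit(params, min_len)) {
    abort(sprintf("dt_rd = %g exceeds the explicit-Euler stability limit %g.",
                  dt, rd_stability_limit(params, min_len)),
          class = "ringleaf_config_error")
  }
  u <- ring$u
  v <- ring$v
  n <- length(u)
  jm <- c(n, 1:(n - 1L))
  jp <- c(2:n, 1L)
  clipped <- 0L
  topo <- params$coupling_mode == "topological"
  for (s in seq_len(n_substeps)) {
    if (topo) {
      lap_u <- u[jm] - 2 * u + u[jp]
      lap_v <- v[jm] - 2 * v + v[jp]
    } else {
      lap_u <- laplacian_ring(u, lens, "metric")
      lap_v <- laplacian_ring(v, lens, "metric")
    }
    syn_u <- pmin(pmax(params$a * u + params$b * v + params$c, 0), params$S_u)
    syn_v <- pmin(pmax(params$d * u + params$e * v + params$f, 0), params$S_v)
    u <- u + dt * (syn_u - params$mu_u * u + params$D_u * lap_u)
    v <- v + dt * (syn_v - params$mu_v * v + params$D_v * lap_v)
    bad <- !is.finite(u) | !is.finite(v)
    if (any(bad)) {
      abort(sprintf("Numerical blowup at cell %d, substep %d.",
                    which(bad)[1], s),
            class = "ringleaf_numerical_blowup")
    }
    neg <- u < 0
    if (any(neg)) { clipped <- clipped + sum(neg); u[neg] <- 0 }
    neg <- v < 0
    if (any(neg)) { clipped <- clipped + sum(neg); v[neg] <- 0 }
  }
  ring$u <- u
  ring$v <- v
  attr(ring, "n_clipped") <- clipped
  ring
}

#' Linear growth rate of each discrete ring mode
#'
#' Linearizes the kinetics about the interior steady state (clamps ignored,
#' valid nearby) and returns, for each discrete mode `k = 0 .. n_cells - 1`
#' of the cyclic chain, the larger real part of the eigenvalues of
#' `[[a - mu_u - D_u k2, b], [d, e - mu_v - D_v k2]]` with
#' `k2 = 2 - 2 cos(2 pi k / n_cells)` (topological spacing). A Turing
#' regime shows `Re(lambda) < 0` at `k = 0` and `> 0` on a band of nonzero
#' modes.
#'
#' @inheritParams homogeneous_steady_state
#' @param n_cells Number of cells of the ring.
#' @return A tibble with columns `k`, `mode` (spatial frequency
#'   `min(k, n_cells - k)`, i.e. the number of pattern repeats), `kappa2`,
#'   and `re_lambda`.
#' @export
dispersion_relation <- function(params, n_cells) {
  homogeneous_steady_state(params) # propagate no-interior-steady-state
  k <- 0:(n_cells - 1L)
  kap2 <- 2 - 2 * cos(2 * pi * k / n_cells)
  fu <- params$a - params$mu_u
  gv <- params$e - params$mu_v
  tr <- (fu - params$D_u * kap2) + (gv - params$D_v * kap2)
  dt2 <- (fu - params$D_u * kap2) * (gv - params$D_v * kap2) -
    params$b * params$d
  disc <- tr^2 - 4 * dt2
  re_lambda <- ifelse(disc >= 0, (tr + sqrt(pmax(disc, 0))) / 2, tr / 2)
  tibble(k = k, mode = pmin(k, n_cells - k), kappa2 = kap2,
         re_lambda = re_lambda)
}

#' Fastest-growing pattern mode
#'
#' Convenience wrapper around [dispersion_relation()]: the spatial mode
#' number (number of pattern repeats on the ring) with the largest linear
#' growth rate.
#'
#' @inheritParams dispersion_relation
#' @return A one-row tibble with `mode`, `re_lambda`.
#' @export
dominant_mode <- function(params, n_cells) {
  d <- dispersion_relation(params, n_cells)
  best <- d[which.max(d$re_lambda), ]
  tibble(mode = best$mode, re_lambda = best$re_lambda)
}
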