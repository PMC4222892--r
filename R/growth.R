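#' Parameters coupling the pattern to margin growth
#'
#' Two velocity laws map the reactant field to vertex speeds:
#' * `expansion` — speed is proportional to the mean selected reactant of
#'   the two cells adjacent to the vertex: `k_g * rbar`. Growth is
#'   concentrated under the pattern peaks.
#' * `inhibition` — the margin expands at a constant base speed that the
#'   pattern suppresses: `max(0, g0 - k_h * rbar)`. Growth is fastest in the
#'   troughs and the clamp at zero forbids margin retraction.
#'
#' @param mode `"expansion"` or `"inhibition"`.
#' @param k_g Speed per unit reactant in expansion mode (>= 0).
#' @param g0 Constant base speed in inhibition mode (>= 0).
#' @param k_h Inhibition strength in inhibition mode (>= 0).
#' @param reactant_select Which reactant drives or inhibits growth, `"u"`
#'   (default, the activator) or `"v"`.
#' @param L_div Cell-division length threshold (> 0).
#' @param dt_growth Growth time step (> 0).
#' @return A `growth_params` object.
#' @export
growth_params <- function(mode = c("expansion", "inhibition"),
                          k_g = 0, g0 = 0, k_h = 0,
                          reactant_select = c("u", "v"),
                          L_div = 1, dt_growth = 1) {
  mode <- match.arg(mode)
  reactant_select <- match.arg(reactant_select)
  if (k_g < 0 || g0 < 0 || k_h < 0)
    abort("k_g, g0, k_h must be >= 0.", class = "ringleaf_config_error")
  if (L_div <= 0) abort("L_div must be > 0.", class = "ringleaf_config_error")
  if (dt_growth <= 0)
    abort("dt_growth must be > 0.", class = "ringleaf_config_error")
  structure(list(mode = mode, k_g = as.numeric(k_g), g0 = as.numeric(g0),
                 k_h = as.numeric(k_h), reactant_select = reactant_select,
                 L_div = as.numeric(L_div), dt_growth = as.numeric(dt_growth)),
            class = "growth_params")
}

#' @export
print.growth_params <- function(x, ...) {
  law <- if (x$mode == "expansion") {
    sprintf("speed = %g * mean(%s)", x$k_g, x$reactant_select)
  } else {
    sprintf("speed = max(0, %g - %g * mean(%s))", x$g0, x$k_h,
            x$reactant_select)
  }
  cat(sprintf("<growth_params> %s mode: %s; L_div %g, dt_growth %g\n",
              x$mode, law, x$L_div, x$dt_growth))
  invisible(x)
}

#' Per-vertex boundary speeds from the reactant field
#'
#' The speed at the vertex shared by cells `i - 1` and `i` is computed from
#' the mean of the selected reactant over those two cells, under the law of
#' `gp$mode`. Speeds are always >= 0.
#'
#' @param ring A `margin_ring` carrying the current reactant state.
#' @param gp A [growth_params()] object.
#' @return Numeric vector of non-negative speeds, one per vertex.
#' @export
vertex_speeds <- function(ring, gp) {
  r <- if (gp$reactant_select == "u") ring$u else ring$v
  n <- length(r)
  k <- c(n, 1:(n - 1L))
  rbar <- (r[k] + r) / 2
  if (gp$mode == "expansion") {
    gp$k_g * rbar
  } else {
    pmax(0, gp$g0 - gp$k_h * rbar)
  }
}
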