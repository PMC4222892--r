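# Small parameter sets used across test files.

# Turing-capable set (the calibrated insertion-regime kinetics)
turing_params <- function(dt_rd = 0.04) {
  rd_params(a = 0.35, b = -0.4, c = 0.15, d = 0.3, e = -0.25, f = 0.05,
            S_u = 0.5, S_v = 0.5, mu_u = 0.1, mu_v = 0.1,
            D_u = 0.3, D_v = 6, dt_rd = dt_rd)
}

# same kinetics, equal diffusivities: no Turing band, pattern decays
stable_params <- function() {
  rd_params(a = 0.35, b = -0.4, c = 0.15, d = 0.3, e = -0.25, f = 0.05,
            S_u = 0.5, S_v = 0.5, mu_u = 0.1, mu_v = 0.1,
            D_u = 0.3, D_v = 0.3, dt_rd = 0.04)
}

# a cheap config for determinism / identity checks
tiny_config <- function(n_growth_steps = 40L, ...) {
  sim_config(rd = turing_params(),
             growth = growth_params("expansion", k_g = 0.01),
             n_growth_steps = n_growth_steps, snapshot_every = 5L,
             seed = 7L, ...)
}

# closed-form 2x2 matrix exponential action via eigendecomposition
expm2_apply <- function(M, w, t) {
  eg <- eigen(M)
  as.numeric(Re(eg$vectors %*% diag(exp(eg$values * t)) %*%
                  solve(eg$vectors) %*% w))
}

# trajectory of a unit-circle ring with a single Gaussian activator bump
# fixed at `position`, for kymograph resampling checks
scripted_peak_traj_for_tests <- function(position, n_snapshots = 3,
                                         n_cells = 200L) {
  th <- 2 * pi * (seq_len(n_cells) - 1) / n_cells
  mid <- (seq_len(n_cells) - 0.5) / n_cells
  d <- abs(mid - position) %% 1
  d <- pmin(d, 1 - d)
  u <- exp(-(d / 0.02)^2 / 2)
  snaps <- lapply(seq_len(n_snapshots), function(si) {
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
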