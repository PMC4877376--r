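# Shared fixtures and independent oracles for the test suite.

# brute-force crossing oracle: sample-level sign-change scan, no
# interpolation (independent of detect_crossings' implementation)
oracle_upward_crossings <- function(time, v, threshold) {
  idx <- which(diff(v >= threshold) == 1)
  time[idx + 1]
}

# central-difference Jacobian of the minimal RHS
numeric_jacobian <- function(state, params, h = 1e-6) {
  J <- matrix(0, 2, 2)
  for (j in 1:2) {
    up <- state
    dn <- state
    up[j] <- up[j] + h
    dn[j] <- dn[j] - h
    J[, j] <- (minimal_rhs(up, params) - minimal_rhs(dn, params)) / (2 * h)
  }
  J
}

# independent oracle for the unstimulated equilibrium calcium level:
# coarse scan of the current balance at v = k_w refined by bisection
oracle_w_star <- function(params) {
  bal <- function(w) {
    f_cubic(params$k_w, params) + j_kca_min(params$k_w, w, params) +
      j_stim_min(params$k_w, params)
  }
  grid <- seq(0, 30, by = 0.01)
  vals <- vapply(grid, bal, numeric(1))
  i <- which(diff(sign(vals)) != 0)[1]
  lo <- grid[i]
  hi <- grid[i + 1]
  for (k in 1:60) {
    mid <- (lo + hi) / 2
    if (sign(bal(mid)) == sign(bal(lo))) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# the full default minimal-model frequency map is reused by several
# expensive checks; compute it at most once per test run
minimal_map_cache <- new.env(parent = emptyenv())
cached_minimal_map <- function() {
  if (is.null(minimal_map_cache$map)) {
    minimal_map_cache$map <- frequency_map(minimal_params())
  }
  minimal_map_cache$map
}
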