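# Shared fixtures and independent closed-form oracles for the constant-rate
# (homogeneous) birth-death process, used to check every solver in the
# tempo-free limit s = 0, theta = 0.

core_params <- function() cet_params(0.51, 0.5, 0.01, 1)
homog_params <- function() cet_params(0.51, 0.5, 0, 0)
default_grid <- function() log_tempo_grid()
# narrow grid for homogeneous-limit moment tests: without mean reversion the
# per-node mean exp(r e^x t) overflows at the far positive end of the
# default grid, and the nodes are uncoupled anyway
narrow_grid <- function() log_tempo_grid(-2, 2, 101)

x_index <- function(grid, x0) which.min(abs(grid$x - x0))

# generating function of a linear birth-death process started from one
# species, G(t, z)
bdp_gf <- function(t, z, lam, mu) {
  r <- lam - mu
  if (r == 0) return(1 - (1 - z) / (1 + lam * t * (1 - z)))
  E <- exp(-r * t)
  (mu * (1 - z) - (mu - lam * z) * E) / (lam * (1 - z) - (mu - lam * z) * E)
}

bdp_p0 <- function(t, lam, mu) {
  mu * (exp((lam - mu) * t) - 1) / (lam * exp((lam - mu) * t) - mu)
}

# P(n | t), n >= 0: extinction atom plus a geometric body
bdp_pn <- function(t, n_max, lam, mu) {
  p0 <- bdp_p0(t, lam, mu)
  eta <- lam * (exp((lam - mu) * t) - 1) / (lam * exp((lam - mu) * t) - mu)
  c(p0, (1 - p0) * (1 - eta) * eta^(0:(n_max - 1)))
}

bdp_m2 <- function(t, lam, mu) {
  r <- lam - mu
  n_mean <- exp(r * t)
  v <- n_mean * (n_mean - 1) * (lam + mu) / r
  v + n_mean^2 - n_mean
}

tv_dist <- function(a, b) 0.5 * sum(abs(a - b))

# minimal hand-built simulated tree for deterministic pipeline checks:
# root (1) splits at t = 2 into a tip that survives (2) and a branch (3)
# that splits at t = 6 into two surviving tips (4, 5); horizon T = 10
toy_tree <- function() {
  nodes <- tibble::tibble(
    id = 1:5,
    parent = c(NA, 1L, 1L, 3L, 3L),
    t_birth = c(0, 2, 2, 6, 6),
    t_end = c(2, 10, 6, 10, 10),
    x_birth = c(0, 0.5, 0.5, -0.2, -0.2),
    x_end = c(0.5, 1.0, -0.2, 0.3, -0.8),
    w = c(2.5, 9, 4, 4.2, 3.9),
    status = c("speciated", "extant", "speciated", "extant", "extant")
  )
  snaps <- tibble::tibble(
    id = c(1L, 2L, 3L, 2L, 4L, 5L),
    time = c(1, 4, 4, 8, 8, 8),
    x = c(0.1, 0.6, 0.2, 0.9, 0.0, -0.5)
  )
  structure(nodes, class = c("cet_tree", class(tibble::tibble())),
            survived = TRUE, n_extant = 3L, truncated = FALSE,
            early_stop = FALSE, snapshots = snaps, T = 10,
            params = core_params(), x0 = 0)
}
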