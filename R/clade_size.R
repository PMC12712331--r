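#' Clade-size distribution by contour inversion of the generating function
#'
#' Recovers the clade-size probabilities \eqn{P_n(t, x_0)} from the
#' generating function by evaluating \eqn{G} at the \eqn{M} damped roots of
#' unity \eqn{z_k = \rho e^{2\pi i k / M}} (a single batched PDE solve,
#' halved by conjugate symmetry) and applying the discrete Fourier
#' inversion
#' \deqn{P_n = \rho^{-n} \frac{1}{M} \sum_k G(z_k) e^{-2\pi i k n / M}.}
#' With the default damped contour \eqn{\rho = 10^{-8/M}}, mass that
#' aliases from clade sizes beyond \eqn{M} is attenuated by \eqn{\rho^M =
#' 10^{-8}}; probabilities beyond the truncation are carried as a lumped
#' `tail_mass` attribute rather than silently dropped. For window queries
#' at sizes close to \eqn{M}, a milder damping (larger `rho`) limits the
#' round-off amplification of the \eqn{\rho^{-n}} factor; see
#' `historical_member_weights()`.
#'
#' @param t Clade age (myr).
#' @param x0 Starting log-tempo (must be a grid node).
#' @param params A [cet_params()].
#' @param grid A [log_tempo_grid()].
#' @param M Number of contour points; a power of two. Probabilities are
#'   resolved for \eqn{n < M}.
#' @param radius Contour radius \eqn{\rho \in (0, 1]}; default
#'   \eqn{10^{-8/M}}.
#' @param dt Time step of the PDE solve (myr).
#' @param conditional If `TRUE`, condition on survival (drop \eqn{P_0} and
#'   renormalise) before returning.
#' @param batch_size Passed to [solve_gf()].
#' @return A tibble of class `cet_clade_dist` with columns `n` (0 to
#'   `M - 1`) and `p`, and attributes `tail_mass`, `M`, `radius`, `t`,
#'   `x0`, `conditional` and `params`.
#' @examples
#' d <- invert_gf(50, 0, cet_params(), log_tempo_grid(n_x = 101), M = 256)
#' sum(d$p) + attr(d, "tail_mass")
#' @export
invert_gf <- function(t, x0, params, grid, M = 4096L, radius = NULL,
                      dt = 0.25, conditional = FALSE, batch_size = 8192L) {
  M <- as.integer(M)
  if (M < 2L || bitwAnd(M, M - 1L) != 0L) {
    stop("M must be a power of two", call. = FALSE)
  }
  if (is.null(radius)) radius <- 10^(-8 / M)
  if (radius <= 0 || radius > 1) stop("radius must lie in (0, 1]",
                                      call. = FALSE)
  k <- 0:(M %/% 2)
  z <- radius * exp(2i * pi * k / M)
  gf <- solve_gf(z, t, params, grid, dt = dt, batch_size = batch_size)
  g_half <- gf_at(gf, x0)
  g_full <- complex(length.out = M)
  g_full[k + 1] <- g_half
  if (M > 2) g_full[M:(M %/% 2 + 2)] <- Conj(g_half[2:(M %/% 2)])
  p <- Re(fft(g_full)) / M * radius^(-(0:(M - 1)))
  neg <- min(p)
  if (neg < -1e-8) {
    warning(sprintf("inversion produced negative probabilities (min %.3g)",
                    neg), call. = FALSE)
  }
  abs_sum <- sum(abs(p))
  p <- pmax(p, 0)
  tot <- sum(p)
  if (abs_sum - tot > 1e-3 || tot > 1 + 1e-3) {
    stop(sprintf(
      "generating-function inversion failed (sum P = %.6g, negative mass %.3g)",
      tot, abs_sum - tot), call. = FALSE)
  }
  out <- new_clade_dist(tibble(n = 0:(M - 1), p = p),
                        tail_mass = max(0, 1 - tot), M = M, radius = radius,
                        t = t, x0 = x0, conditional = FALSE, params = params)
  if (conditional) condition_on_survival(out) else out
}

new_clade_dist <- function(tbl, tail_mass, M, radius, t, x0, conditional,
                           params) {
  structure(tbl,
            tail_mass = tail_mass, M = M, radius = radius, t = t, x0 = x0,
            conditional = conditional, params = params,
            class = c("cet_clade_dist", class(tibble())))
}

#' Condition a clade-size distribution on survival
#'
#' Sets \eqn{P_0} to zero and renormalises the remaining probabilities and
#' the tail mass by \eqn{1 - P_0}, matching the convention of reporting
#' size distributions for clades that survive to the horizon.
#'
#' @param dist A `cet_clade_dist` tibble from [invert_gf()].
#' @return The survival-conditioned `cet_clade_dist`.
#' @export
condition_on_survival <- function(dist) {
  stopifnot(inherits(dist, "cet_clade_dist"))
  if (isTRUE(attr(dist, "conditional"))) return(dist)
  p0 <- dist$p[dist$n == 0]
  if (p0 >= 1 - 1e-12) {
    stop("cannot condition on survival: P0 is (numerically) 1",
         call. = FALSE)
  }
  p <- dist$p
  p[dist$n == 0] <- 0
  p <- p / (1 - p0)
  new_clade_dist(tibble(n = dist$n, p = p),
                 tail_mass = attr(dist, "tail_mass") / (1 - p0),
                 M = attr(dist, "M"), radius = attr(dist, "radius"),
                 t = attr(dist, "t"), x0 = attr(dist, "x0"),
                 conditional = TRUE, params = attr(dist, "params"))
}

#' @export
glance.cet_clade_dist <- function(x, ...) {
  tibble(
    mean_size = sum(x$n * x$p),
    p0 = x$p[x$n == 0],
    tail_mass = attr(x, "tail_mass"),
    M = attr(x, "M"),
    t = attr(x, "t"),
    x0 = attr(x, "x0"),
    conditional = attr(x, "conditional")
  )
}

#' Sister-group imbalance of a crown group
#'
#' Models the two basal sister groups of a crown group as independent draws
#' \eqn{N_1, N_2} from the survival-conditioned clade-size distribution
#' (both conditioned non-extinct, the crown-group reading) and computes (i)
#' the probability density of the proportion \eqn{N_1 / (N_1 + N_2)} of
#' total diversity held by one sister chosen at random and (ii) exceedance
#' probabilities \eqn{P(\max / \min \ge k)}. Both are computed
#' deterministically from the complementary CDF in a single pass over
#' clade sizes. Exceedance queries that touch the lumped tail mass return
#' interval bounds (`p_lower`, `p_upper`) rather than a silent point
#' estimate; `p_mid` is their midpoint.
#'
#' @param t Crown-group age (myr). Ignored when `dist` is supplied.
#' @param x0 Starting log-tempo of each sister.
#' @param params,grid Model parameters and grid.
#' @param M Contour size for the underlying inversion.
#' @param k_thresholds Imbalance ratios \eqn{k} for exceedance queries.
#' @param n_bins Number of proportion bins for the density.
#' @param dist Optional precomputed survival-conditioned `cet_clade_dist`
#'   (overrides `t`, `x0`, `M`).
#' @param dt Time step of the PDE solve.
#' @return A list of class `cet_imbalance` with elements `density` (tibble:
#'   `proportion`, `density`), `exceedance` (tibble: `k`, `p_lower`,
#'   `p_upper`, `p_mid`) and `tail_mass`.
#' @export
sister_imbalance <- function(t = 500, x0 = 0, params = cet_params(),
                             grid = log_tempo_grid(), M = 65536L,
                             k_thresholds = c(2, 5, 10, 20), n_bins = 100L,
                             dist = NULL, dt = 0.25) {
  if (is.null(dist)) {
    dist <- invert_gf(t, x0, params, grid, M = M, dt = dt,
                      conditional = TRUE)
  }
  stopifnot(inherits(dist, "cet_clade_dist"))
  if (!isTRUE(attr(dist, "conditional"))) {
    dist <- condition_on_survival(dist)
  }
  tail_mass <- attr(dist, "tail_mass")
  if (tail_mass > 0.02) {
    warning(sprintf(
      "tail mass %.3g > 0.02: exceedance values are interval bounds",
      tail_mass), call. = FALSE)
  }
  q <- dist$p
  M_eff <- length(q)
  n <- dist$n
  # S[m] = P(N >= m), m = 1..M_eff; the lumped tail sits at sizes >= M_eff
  S <- rev(cumsum(rev(q)))[-1] # P(N >= 1), ..., P(N >= M_eff - 1)
  S <- c(S, 0) + tail_mass     # append P(N >= M_eff) = tail
  nn <- n[-1] # positive sizes on the grid
  qq <- q[-1]
  exceed <- purrr::map_dfr(k_thresholds, function(k) {
    if (k <= 1) {
      return(tibble(k = k, p_lower = 1, p_upper = 1, p_mid = 1))
    }
    m_req <- ceiling(k * nn)
    known <- m_req <= M_eff
    p_known <- 2 * sum(qq[known] * S[m_req[known]])
    # N1 on-grid but k*N1 beyond truncation, or N1 itself in the tail: the
    # partner must then lie in the tail, so each term is at most tail_mass
    unresolved <- 2 * tail_mass * (sum(qq[!known]) + tail_mass)
    tibble(k = k, p_lower = p_known,
           p_upper = min(1, p_known + unresolved),
           p_mid = min(1, p_known + unresolved / 2))
  })
  # bins centred on 0, 1/n_bins, ..., 1 so that the point masses of small
  # clades (proportion 1/2, 1/3, ...) fall at bin centres, never on edges;
  # this keeps the binned density exactly symmetric under p -> 1 - p
  width <- 1 / n_bins
  edges <- seq(-width / 2, 1 + width / 2, by = width)
  n_bins <- length(edges) - 1L
  bin_p <- numeric(n_bins)
  # S_at(m) = P(N2 >= m), counting the lumped tail as mass at infinity
  S_at <- function(m) {
    ifelse(m <= 0, 1, ifelse(m <= M_eff, S[pmax(pmin(m, M_eff), 1)],
                             tail_mass))
  }
  # P(p <= c | N1 = n) and P(p < c | N1 = n), summed over the N1 law.
  # p = n/(n + N2) <= c  <=>  N2 >= n(1 - c)/c.
  F_le <- function(c) {
    if (c <= 0) return(0)
    if (c >= 1) return(sum(qq))
    sum(qq * S_at(ceiling(nn * (1 - c) / c - 1e-9)))
  }
  F_lt <- function(c) {
    if (c <= 0) return(0)
    if (c > 1) return(sum(qq))
    sum(qq * S_at(floor(nn * (1 - c) / c + 1e-9) + 1))
  }
  centers <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  # mirror-symmetric interval convention: [lo, hi) below one half,
  # (lo, hi] above it, [lo, hi] for the central bin, so that point masses
  # (proportions 1/2, 1/3, 3/8, ...) are binned symmetrically under
  # p -> 1 - p no matter where they fall
  for (b in seq_len(n_bins)) {
    lo <- edges[b]
    hi <- edges[b + 1]
    bin_p[b] <- if (centers[b] < 0.5 - 1e-12) {
      F_lt(hi) - F_lt(lo)
    } else if (centers[b] > 0.5 + 1e-12) {
      F_le(hi) - F_le(lo)
    } else {
      F_le(hi) - F_lt(lo)
    }
    if (bin_p[b] < 0) bin_p[b] <- 0
  }
  # pairs whose first draw lies in the lumped tail have proportion ~ 1
  # (their partner is almost surely far smaller); the mirrored case (second
  # draw in the tail) already lands in the first bin through the CDF. Both
  # tail-vs-tail pairs are split evenly.
  bin_p[n_bins] <- bin_p[n_bins] + tail_mass * (1 - tail_mass) +
    tail_mass^2 / 2
  bin_p[1] <- bin_p[1] + tail_mass^2 / 2
  density <- tibble(
    proportion = (edges[-1] + edges[-(n_bins + 1)]) / 2,
    density = bin_p / diff(edges)
  )
  structure(list(density = density, exceedance = exceed,
                 tail_mass = tail_mass, t = attr(dist, "t"),
                 x0 = attr(dist, "x0"), params = attr(dist, "params")),
            class = "cet_imbalance")
}

#' @export
print.cet_imbalance <- function(x, ...) {
  cat(sprintf("sister-group imbalance (t = %s, x0 = %s, tail mass %.3g)\n",
              format(x$t), format(x$x0), x$tail_mass))
  print(x$exceedance)
  invisible(x)
}

#' @export
tidy.cet_imbalance <- function(x, ...) x$density

#' @export
glance.cet_imbalance <- function(x, ...) {
  dplyr::mutate(x$exceedance, tail_mass = x$tail_mass)
}
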