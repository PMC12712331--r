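#' Drift-diffusion operators on the log-tempo grid
#'
#' All deterministic equations of the model share two canonical spatial
#' forms. The backward form acts on functions of the starting log-tempo,
#' \deqn{\partial f/\partial t = e^x\,(R(f) - \theta x\,\partial f/\partial x
#'   + \theta s^2\, \partial^2 f/\partial x^2),}
#' and the forward (density) form acts on probability densities,
#' \deqn{\partial u/\partial t = c\,e^x u + \theta\,\partial(x e^x
#'   u)/\partial x + \theta s^2\, \partial^2 (e^x u)/\partial x^2.}
#'
#' `build_backward_operator()` returns the drift-diffusion part of the
#' backward form *without* the \eqn{e^x} time-scaling (which the steppers
#' fold into the implicit matrix together with any reaction term): second
#' order central differences for the diffusion, central differences for the
#' \eqn{-\theta x} drift with a first-order upwind fallback at nodes where
#' the cell Peclet number \eqn{|x|\,dx / s^2} exceeds 2, and a reflecting
#' (zero-flux) ghost-node closure at both ends.
#'
#' `build_forward_operator()` is constructed as the discrete adjoint of the
#' \eqn{e^x}-scaled backward operator with respect to the `dx`-weighted
#' inner product, plus an optional diagonal growth term \eqn{c\,e^x}. The
#' adjoint construction makes two key identities hold exactly in floating
#' point: total mass is conserved when `growth_rate = 0`, and a forward
#' solve started from a point mass integrates to the backward mean solution.
#'
#' @param grid A [log_tempo_grid()].
#' @param params A [cet_params()].
#' @param growth_rate Coefficient \eqn{c} of the diagonal growth term
#'   \eqn{c e^x u} of the forward form (e.g. `params$r` for the
#'   unnormalised tempo-density equation). Default 0.
#' @param self_scaling If `FALSE`, the \eqn{e^x} factors are frozen to 1,
#'   giving the plain Ornstein-Uhlenbeck operator; used for diagnostic
#'   comparisons against the classical OU stationary law.
#' @return A list of class `cet_operator` with elements `matrix` (a sparse
#'   tridiagonal `Matrix`), `form` (`"backward"` or `"forward"`), `grid`,
#'   `params`, and `ex` (the \eqn{e^x} node weights, all 1 when
#'   `self_scaling = FALSE`).
#' @examples
#' op <- build_backward_operator(log_tempo_grid(), cet_params())
#' range(as.numeric(op$matrix %*% rep(1, op$grid$n_x))) # annihilates constants
#' @export
build_backward_operator <- function(grid, params) {
  stopifnot(inherits(grid, "cet_grid"), inherits(params, "cet_params"))
  D <- backward_diffusion_matrix(grid, params)
  structure(list(matrix = D, form = "backward", grid = grid, params = params,
                 ex = exp(grid$x)),
            class = "cet_operator")
}

# Tridiagonal drift-diffusion matrix D with D f ~ -theta x f' + theta s^2 f''
# and reflecting ghost closure; no e^x factor.
backward_diffusion_matrix <- function(grid, params) {
  n <- grid$n_x
  dx <- grid$dx
  x <- grid$x
  th <- params$theta
  s2 <- params$s^2
  lower <- numeric(n) # entry (i, i-1)
  diago <- numeric(n)
  upper <- numeric(n) # entry (i, i+1)
  diff_c <- th * s2 / dx^2
  peclet <- if (s2 > 0) abs(x) * dx / s2 else rep(Inf, n)
  for (i in seq_len(n)) {
    v <- -th * x[i] # coefficient of f' in the drift term
    if (!is.finite(peclet[i]) || peclet[i] > 2) {
      # first-order upwind: forward difference when v > 0, backward when v < 0
      if (v > 0) {
        lo <- 0; up <- v / dx; di <- -v / dx
      } else {
        lo <- -v / dx; up <- 0; di <- v / dx
      }
    } else {
      lo <- -v / (2 * dx); up <- v / (2 * dx); di <- 0
    }
    lower[i] <- lo + diff_c
    upper[i] <- up + diff_c
    diago[i] <- di - 2 * diff_c
  }
  # reflecting ghost nodes: fold the out-of-range coefficient back inside
  upper[1] <- upper[1] + lower[1]
  lower[1] <- 0
  lower[n] <- lower[n] + upper[n]
  upper[n] <- 0
  Matrix::bandSparse(n, n, k = c(-1, 0, 1),
                     diagonals = list(lower[-1], diago, upper[-n]))
}

#' @rdname build_backward_operator
#' @export
build_forward_operator <- function(grid, params, growth_rate = 0,
                                   self_scaling = TRUE) {
  stopifnot(inherits(grid, "cet_grid"), inherits(params, "cet_params"))
  D <- backward_diffusion_matrix(grid, params)
  ex <- if (self_scaling) exp(grid$x) else rep(1, grid$n_x)
  E <- Matrix::Diagonal(x = ex)
  A <- Matrix::t(D) %*% E
  if (growth_rate != 0) A <- A + growth_rate * E
  structure(list(matrix = methods::as(A, "CsparseMatrix"), form = "forward",
                 grid = grid, params = params, ex = ex,
                 growth_rate = growth_rate),
            class = "cet_operator")
}

# Full backward linear operator e^x (c + D) as a sparse matrix.
backward_full_matrix <- function(op, reaction_rate = 0) {
  n <- op$grid$n_x
  E <- Matrix::Diagonal(x = op$ex)
  M <- E %*% (op$matrix + reaction_rate * Matrix::Diagonal(n))
  methods::as(M, "CsparseMatrix")
}

# Extract the three diagonals of a tridiagonal sparse matrix in the layout
# the C++ marcher expects (sub[1] and sup[n] unused).
tridiag_parts <- function(M) {
  n <- nrow(M)
  list(
    sub = c(0, M[cbind(2:n, 1:(n - 1))]),
    dia = Matrix::diag(M),
    sup = c(M[cbind(1:(n - 1), 2:n)], 0)
  )
}

#' Advance a field with the theta-scheme
#'
#' Marches \eqn{\partial f/\partial t = L f} for a tridiagonal operator `L`
#' (already including any \eqn{e^x} scaling and diagonal terms) using the
#' theta-method: Crank-Nicolson (`theta = 0.5`, second order) by default,
#' backward Euler at `theta = 1`. The first `n_implicit` steps can be forced
#' to backward Euler to damp the staircase modes excited by point-mass
#' initial data. With `renorm = TRUE` each column is renormalised to unit
#' mass after every step (used by the normalised tempo-density equation),
#' and `stop_tol` then allows early exit once the per-myr L1 change drops
#' below tolerance.
#'
#' @param field Numeric vector or matrix over the grid (columns are
#'   independent problems).
#' @param L Sparse tridiagonal operator matrix.
#' @param dt Time step (myr).
#' @param n_steps Number of steps.
#' @param theta Implicitness weight in \eqn{[0.5, 1]}.
#' @param n_implicit Number of initial backward-Euler steps.
#' @param renorm Renormalise columns to unit `dx`-mass after each step.
#' @param dx Grid spacing (needed when `renorm = TRUE`).
#' @param stop_tol Early-exit stationarity tolerance (0 = never).
#' @return A list with `field` (same shape as input), `steps` taken and the
#'   last stationarity `residual` (NA unless `renorm` and `stop_tol > 0`).
#' @keywords internal
#' @export
march_theta <- function(field, L, dt, n_steps, theta = 0.5, n_implicit = 0L,
                        renorm = FALSE, dx = 1, stop_tol = 0) {
  f <- as.matrix(field)
  parts <- tridiag_parts(L)
  out <- cpp_march_tridiag(f, parts$sub, parts$dia, parts$sup, dt,
                           as.integer(n_steps), theta,
                           as.integer(n_implicit), renorm, dx, stop_tol)
  if (is.vector(field)) out$field <- as.numeric(out$field)
  out
}

#' Single IMEX step: implicit linear part, explicit pointwise reaction
#'
#' Advances one time step of \eqn{\partial f/\partial t = L f + R(f)},
#' treating the stiff linear part with the theta-scheme and the pointwise
#' reaction explicitly (evaluated at the current field).
#'
#' @param field Numeric vector over the grid.
#' @param reaction_fn Function mapping field values to pointwise reaction
#'   values, or `NULL` for none.
#' @param dt Time step.
#' @param L Sparse tridiagonal operator (full, including any scaling).
#' @param theta Implicitness weight.
#' @param reaction_method `"trapezoid"` (default) evaluates the reaction at
#'   a forward-Euler predictor as well, i.e. one fixed-point correction
#'   toward the Crank-Nicolson reaction average (second order);
#'   `"explicit"` uses the current field only (first order).
#' @return The advanced field (numeric vector).
#' @keywords internal
#' @export
step_imex <- function(field, reaction_fn, dt, L, theta = 0.5,
                      reaction_method = c("trapezoid", "explicit")) {
  reaction_method <- match.arg(reaction_method)
  if (any(!is.finite(field))) {
    stop(sprintf("non-finite field entering step (max |field| = %g)",
                 max(abs(field))), call. = FALSE)
  }
  n <- length(field)
  rhs <- field + (1 - theta) * dt * as.numeric(L %*% field)
  if (!is.null(reaction_fn)) {
    r0 <- reaction_fn(field)
    if (reaction_method == "trapezoid") {
      pred <- field + dt * r0 # forward-Euler predictor for the reaction
      rhs <- rhs + dt * (r0 + reaction_fn(pred)) / 2
    } else {
      rhs <- rhs + dt * r0
    }
  }
  M1 <- Matrix::Diagonal(n) - theta * dt * L
  out <- as.numeric(Matrix::solve(M1, rhs))
  if (any(!is.finite(out))) {
    stop(sprintf("non-finite field after step (dt = %g, max |field| = %g)",
                 dt, max(abs(field))), call. = FALSE)
  }
  out
}

# Split a horizon t into an integer number of steps no coarser than dt.
step_plan <- function(t, dt) {
  if (t <= 0) return(list(n = 0L, dt = dt))
  n <- max(1L, as.integer(ceiling(t / dt - 1e-9)))
  list(n = n, dt = t / n)
}
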