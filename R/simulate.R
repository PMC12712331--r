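#' Simulate one clade of the covariant-tempo birth-death process
#'
#' Forward Monte Carlo realisation of the model: each species carries a
#' log-tempo \eqn{x} evolving by the self-scaled Ornstein-Uhlenbeck
#' diffusion \eqn{dx = -\theta e^x x\,dt + \sqrt{2\theta s^2 e^x}\,dW}
#' (Euler-Maruyama with an adaptive step, reflected at the grid bounds to
#' match the PDE boundary policy), speciates at rate \eqn{e^x \lambda} and
#' goes extinct at rate \eqn{e^x \mu}; daughters inherit the parental
#' tempo. Branch terminations are sampled exactly in molecular time: in
#' the length variable \eqn{w = \int e^x dt} events form a Poisson process
#' of constant rate \eqn{\lambda + \mu}, so each branch draws its total
#' molecular length from that exponential law and terminates when the
#' accumulated \eqn{w} reaches it — the per-branch molecular lengths are
#' exact by construction and the time-discretisation error affects only
#' the tempo path and the time/length mapping.
#'
#' @param params A [cet_params()].
#' @param x0 Founder log-tempo.
#' @param T Horizon (myr).
#' @param dt Baseline Euler-Maruyama step (myr); shrunk adaptively where
#'   the local tempo makes the OU update stiff.
#' @param seed Optional integer seed (`set.seed` is called when given).
#' @param cap Species cap; the returned tree is flagged `truncated` when
#'   reached and processing stops.
#' @param x_bound Reflecting bound for |x|; default 10, matching the
#'   default PDE grid.
#' @param snapshot_times Times at which to record the log-tempo of every
#'   branch alive (used for ancestor tracing).
#' @param stop_at_survivor Stop as soon as one lineage is known to reach
#'   `T` (exact early exit for survival estimation; the returned tree is
#'   then partial).
#' @return A tibble of class `cet_tree` with one row per branch: `id`,
#'   `parent`, `t_birth`, `t_end`, `x_birth`, `x_end`, `w` (molecular
#'   length in myr-equivalents) and `status` (`"extinct"`, `"speciated"`,
#'   `"extant"`, or `"pending"` for branches left unprocessed after an
#'   early stop). Attributes: `survived`, `n_extant`, `truncated`,
#'   `early_stop`, `snapshots` (tibble `id`, `time`, `x`), `T`, `params`.
#' @export
simulate_clade <- function(params, x0 = 0, T = 500, dt = 0.1, seed = NULL,
                           cap = 1e6, x_bound = 10,
                           snapshot_times = numeric(0),
                           stop_at_survivor = FALSE) {
  stopifnot(inherits(params, "cet_params"))
  if (!is.null(seed)) set.seed(seed)
  if (cap < 1) stop("cap must be >= 1", call. = FALSE)
  raw <- cpp_simulate_clade(params$lambda_rate, params$mu_rate,
                            params$theta, params$s, x0, T, dt,
                            as.integer(cap), x_bound, stop_at_survivor,
                            sort(snapshot_times))
  status <- rep("pending", length(raw$status))
  done <- raw$status >= 0L
  status[done] <- c("extinct", "speciated", "extant")[raw$status[done] + 1L]
  nodes <- tibble(
    id = seq_along(raw$parent),
    parent = ifelse(is.na(raw$parent), NA_integer_, raw$parent + 1L),
    t_birth = raw$t_birth, t_end = raw$t_end,
    x_birth = raw$x_birth, x_end = raw$x_end,
    w = raw$w, status = status
  )
  snaps <- tibble(
    id = raw$snap_node + 1L,
    time = sort(snapshot_times)[raw$snap_id + 1L],
    x = raw$snap_x
  )
  structure(nodes, class = c("cet_tree", class(tibble())),
            survived = raw$survived, n_extant = raw$n_extant,
            truncated = raw$truncated, early_stop = raw$early_stop,
            snapshots = snaps, T = T, params = params, x0 = x0)
}

#' @export
glance.cet_tree <- function(x, ...) {
  tibble(
    n_branches = nrow(x),
    n_extant = attr(x, "n_extant"),
    survived = attr(x, "survived"),
    truncated = attr(x, "truncated"),
    T = attr(x, "T")
  )
}

#' Simulate an ensemble of clades
#'
#' Independent replicates of [simulate_clade()], aggregated into the
#' summaries the deterministic solvers predict: final-size histogram,
#' survival fraction, completed-branch duration and molecular-length
#' samples, and (optionally) species- and lineage-through-time curves.
#' Replicates draw their random numbers sequentially from a single stream
#' seeded once, so results are reproducible from `seed`.
#'
#' @inheritParams simulate_clade
#' @param n_reps Number of replicates.
#' @param seed Integer seed for the whole ensemble.
#' @param t_eval Optional times for species/lineage-through-time curves.
#' @param survival_only If `TRUE`, use the exact early-exit search per
#'   replicate and return only the survival indicator (fast).
#' @param max_branch_samples Cap on stored per-branch samples.
#' @return A list of class `cet_ensemble`: `sizes` (final species counts,
#'   NA where `survival_only`), `survived` (logical), `durations` and
#'   `molecular` (completed-branch samples), `ltt` and `lineages`
#'   (replicate x time matrices, when `t_eval` given), `t_eval`,
#'   `n_truncated`, `n_reps`, `params`.
#' @export
simulate_ensemble <- function(params, x0 = 0, T = 500, n_reps = 1000L,
                              seed = 1L, dt = 0.1, cap = 1e6,
                              t_eval = NULL, survival_only = FALSE,
                              max_branch_samples = 2e5) {
  stopifnot(n_reps >= 1)
  set.seed(seed)
  sizes <- numeric(n_reps)
  survived <- logical(n_reps)
  n_trunc <- 0L
  durations <- molecular <- vector("list", n_reps)
  n_samp <- 0
  ltt <- lineages <- NULL
  if (!is.null(t_eval)) {
    ltt <- matrix(0, n_reps, length(t_eval))
    lineages <- matrix(0, n_reps, length(t_eval))
  }
  for (rep in seq_len(n_reps)) {
    tree <- simulate_clade(params, x0, T, dt = dt, cap = cap,
                           stop_at_survivor = survival_only)
    survived[rep] <- attr(tree, "survived")
    sizes[rep] <- if (survival_only) NA_real_ else attr(tree, "n_extant")
    if (attr(tree, "truncated")) n_trunc <- n_trunc + 1L
    if (!survival_only && n_samp < max_branch_samples) {
      done <- tree$status %in% c("extinct", "speciated")
      durations[[rep]] <- tree$t_end[done] - tree$t_birth[done]
      molecular[[rep]] <- tree$w[done]
      n_samp <- n_samp + sum(done)
    }
    if (!is.null(t_eval) && !survival_only) {
      cur <- tree_ltt(tree, t_eval)
      ltt[rep, ] <- cur$species
      lineages[rep, ] <- cur$lineages
    }
  }
  if (n_trunc > 0.01 * n_reps) {
    warning(sprintf("%d of %d replicates hit the species cap", n_trunc,
                    n_reps), call. = FALSE)
  }
  structure(list(sizes = sizes, survived = survived,
                 durations = unlist(durations), molecular = unlist(molecular),
                 ltt = ltt, lineages = lineages, t_eval = t_eval,
                 n_truncated = n_trunc, n_reps = n_reps, params = params,
                 x0 = x0, T = T),
            class = "cet_ensemble")
}

#' @export
print.cet_ensemble <- function(x, ...) {
  cat(sprintf("ensemble of %d clades (T = %g, x0 = %g): %.1f%% survived\n",
              x$n_reps, x$T, x$x0, 100 * mean(x$survived)))
  invisible(x)
}

# species- and lineage-through-time counts for one completed tree
tree_ltt <- function(tree, t_eval) {
  has_descendant <- tree$status == "extant"
  ord <- order(tree$t_birth, decreasing = TRUE)
  for (i in ord) {
    if (has_descendant[i] && !is.na(tree$parent[i])) {
      has_descendant[tree$parent[i]] <- TRUE
    }
  }
  species <- lineages <- numeric(length(t_eval))
  for (k in seq_along(t_eval)) {
    tt <- t_eval[k]
    alive <- tree$t_birth <= tt &
      (is.na(tree$t_end) | tree$t_end > tt | (tree$status == "extant" & tt == attr(tree, "T")))
    alive[is.na(alive)] <- FALSE
    species[k] <- sum(alive)
    lineages[k] <- sum(alive & has_descendant)
  }
  list(species = species, lineages = lineages)
}

#' Tip-weighted mean ancestral tempo from simulated clades
#'
#' For an ensemble of surviving simulated clades with recorded snapshots,
#' computes the expected log-tempo, at each snapshot time, of the ancestor
#' of a randomly chosen extant species (species chosen uniformly across
#' all tips of all clades). Each branch alive at a snapshot contributes
#' its recorded log-tempo weighted by its number of extant descendant
#' tips.
#'
#' @param trees A list of `cet_tree` objects with identical
#'   `snapshot_times`.
#' @param snapshot_times The snapshot times used in the simulations.
#' @return A tibble with columns `time`, `mean_x` (tip-weighted pooled
#'   mean), `n_tips`, and `se` (between-clade standard error of the
#'   weighted mean).
#' @export
ancestral_tempo_mc <- function(trees, snapshot_times) {
  per_tree <- purrr::map_dfr(seq_along(trees), function(ti) {
    tree <- trees[[ti]]
    snaps <- attr(tree, "snapshots")
    n_tips_under <- integer(nrow(tree))
    n_tips_under[tree$status == "extant"] <- 1L
    ord <- order(tree$t_birth, decreasing = TRUE)
    for (i in ord) {
      p <- tree$parent[i]
      if (!is.na(p)) n_tips_under[p] <- n_tips_under[p] + n_tips_under[i]
    }
    dplyr::mutate(snaps, tips = n_tips_under[.data$id], clade = ti) |>
      dplyr::filter(.data$tips > 0)
  })
  by_clade <- dplyr::group_by(per_tree, .data$time, .data$clade) |>
    dplyr::summarise(m = sum(.data$x * .data$tips), w = sum(.data$tips),
                     .groups = "drop")
  dplyr::group_by(by_clade, .data$time) |>
    dplyr::summarise(
      mean_x = sum(.data$m) / sum(.data$w),
      n_tips = sum(.data$w),
      n_clades = dplyr::n(),
      # delta-method SE of the ratio of clade-level sums, clades iid
      se = sqrt(sum((.data$m - (sum(.data$m) / sum(.data$w)) * .data$w)^2) /
                  (sum(.data$w)^2) * dplyr::n() / max(dplyr::n() - 1, 1)),
      .groups = "drop"
    )
}

#' Write a simulated tree as Newick, with optional NHX annotations
#'
#' Branch lengths are either durations in myr (`length_mode = "time"`, an
#' ultrametric tree for fully extant clades) or molecular lengths in
#' myr-equivalents (`length_mode = "molecular"`, generally not
#' ultrametric). NHX comments carry the other length measure and the
#' log-tempos at the start and end of each branch.
#'
#' @param tree A `cet_tree` from [simulate_clade()].
#' @param length_mode `"time"` or `"molecular"`.
#' @param nhx Attach `[&&NHX:...]` annotations.
#' @param force Write even if the tree was truncated at the species cap.
#' @param digits Significant digits for branch lengths.
#' @return A single Newick string (terminated by `;`).
#' @export
tree_to_newick <- function(tree, length_mode = c("time", "molecular"),
                           nhx = TRUE, force = FALSE, digits = 10) {
  length_mode <- match.arg(length_mode)
  stopifnot(inherits(tree, "cet_tree"))
  if (attr(tree, "truncated") && !force) {
    stop("tree was truncated at the species cap; pass force = TRUE to write anyway",
         call. = FALSE)
  }
  if (any(tree$status == "pending")) {
    stop("tree contains unprocessed branches (early-stopped simulation)",
         call. = FALSE)
  }
  len <- if (length_mode == "time") tree$t_end - tree$t_birth else tree$w
  alt <- if (length_mode == "time") tree$w else tree$t_end - tree$t_birth
  n <- nrow(tree)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    p <- tree$parent[i]
    if (!is.na(p)) children[[p]] <- c(children[[p]], i)
  }
  fmt <- function(v) formatC(v, digits = digits, format = "g")
  ann <- if (nhx) {
    sprintf("[&&NHX:xb=%s:xe=%s:alt=%s]", fmt(tree$x_birth),
            fmt(tree$x_end), fmt(alt))
  } else {
    rep("", n)
  }
  piece <- character(n)
  # children are always born after their parent, so reverse birth order
  # guarantees children are assembled first
  for (i in order(tree$t_birth, decreasing = TRUE)) {
    kids <- children[[i]]
    core <- if (length(kids) == 0) {
      sprintf("t%d", i)
    } else {
      sprintf("(%s)", paste(piece[kids], collapse = ","))
    }
    piece[i] <- sprintf("%s:%s%s", core, fmt(len[i]), ann[i])
  }
  root <- which(is.na(tree$parent))
  paste0(piece[root], ";")
}
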