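#' Write a result table as TSV with self-describing metadata
#'
#' Writes a tab-separated table preceded by `#`-prefixed metadata lines
#' (model parameters, seed, package version), the convention of common
#' genomics tabular formats, so any emitted table can be re-interpreted on
#' its own. No timestamp is written: output for a fixed seed is
#' byte-reproducible across runs.
#'
#' @param table A data frame.
#' @param path Destination path.
#' @param params Optional [cet_params()] recorded in the header.
#' @param seed Optional seed recorded in the header.
#' @param extra Named list of extra metadata entries.
#' @return `path`, invisibly.
#' @export
write_table <- function(table, path, params = NULL, seed = NULL,
                        extra = list()) {
  meta <- sprintf("# cetempo_version=%s",
                  as.character(utils::packageVersion("cetempo")))
  if (!is.null(params)) {
    meta <- c(meta, sprintf(
      "# lambda=%.17g mu=%.17g theta=%.17g s=%.17g r=%.17g",
      params$lambda_rate, params$mu_rate, params$theta, params$s, params$r))
  }
  if (!is.null(seed)) meta <- c(meta, sprintf("# seed=%d", seed))
  for (key in names(extra)) {
    meta <- c(meta, sprintf("# %s=%s", key, format(extra[[key]])))
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(meta, con)
  if (ncol(table) > 0) {
    utils::write.table(table, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  }
  invisible(path)
}

#' Read a TSV table written by [write_table()]
#'
#' @param path Path to the file.
#' @return A tibble; `#` metadata lines are returned in the `metadata`
#'   attribute as a character vector.
#' @export
read_table_tsv <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path),
                               call. = FALSE)
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  out <- if (length(body) == 0) {
    tibble()
  } else {
    as_tibble(utils::read.table(text = body, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE))
  }
  attr(out, "metadata") <- sub("^# ?", "", meta)
  out
}

#' Reproduce the numbers behind one summary figure panel
#'
#' Each panel id maps to a deterministic (or, for the
#' survival-conditioned diversification panel, seeded stochastic) table of
#' the quantities plotted in the corresponding summary figure of the
#' model: clade-size distribution (`"1a"`), sister-group imbalance
#' (`"1b"`), diversification curves (`"2a"`, `"2b"`), tempo-distribution
#' dynamics and equilibria (`"3a"`, `"3b"`), historical-tempo trajectories
#' (`"4a"`, `"4b"`) and branch duration/molecular-change densities
#' (`"5a"`, `"5b"`). The numbers are the contract; plotting is left to
#' [autoplot()] methods.
#'
#' @param figure_id One of `"1a"`, `"1b"`, `"2a"`, `"2b"`, `"3a"`,
#'   `"3b"`, `"4a"`, `"4b"`, `"5a"`, `"5b"`.
#' @param config A [cet_config()]; `t_max`, grid, parameters, `dt` and
#'   `seed` are taken from it.
#' @param ... Panel-specific overrides: `M` (contour size, panels 1a/1b/4b),
#'   `n_reps` (panel 2b), `n_T` (panel 4b, default the experienced clade
#'   size), `ages` (panels 4a/4b), `x0_set` (panels 2/3/5).
#' @return A tibble (with panel-appropriate class for [autoplot()]).
#' @export
run_figure <- function(figure_id, config = cet_config(), ...) {
  opts <- list(...)
  params <- config$params
  grid <- config$grid
  T <- config$t_max
  dt <- config$dt
  x0_set <- opts$x0_set %||% c(-2, 0, 2)
  switch(
    as.character(figure_id),
    "1a" = invert_gf(T, 0, params, grid, M = opts$M %||% 4096L, dt = dt,
                     conditional = TRUE),
    "1b" = {
      imb <- sister_imbalance(T, 0, params, grid, M = opts$M %||% 16384L,
                              dt = dt)
      imb$density
    },
    "2a" = diversification_curves(T, x0_set, params, grid,
                                  conditional = FALSE, dt = dt),
    "2b" = diversification_curves(T, x0_set, params, grid,
                                  conditional = TRUE,
                                  n_reps = opts$n_reps %||% 1000L,
                                  seed = config$seed, dt = dt),
    "3a" = {
      t_grid <- opts$t_grid %||% seq(0, T, length.out = 26)
      purrr::map_dfr(x0_set, function(x0) {
        dplyr::mutate(
          tidy(evolve_tempo_density(x0, t_grid, params, grid, dt = dt)),
          x0 = x0)
      })
    },
    "3b" = {
      r_set <- opts$r_set %||% c(0, 0.005, 0.01, 0.02)
      purrr::map_dfr(r_set, function(r) {
        p_r <- cet_params(params$mu_rate + r, params$mu_rate,
                          params$theta, params$s)
        eq <- equilibrium_density(p_r, grid, tol = opts$tol %||% 1e-8)
        tibble(r = r, mean = attr(eq, "mean"), sd = attr(eq, "sd"))
      })
    },
    "4a" = tempo_trajectory(T, params, grid,
                            ages = opts$ages %||% seq(0, T, by = 25),
                            mode = "ancestor", dt = dt),
    "4b" = {
      n_T <- opts$n_T %||% round(experienced_size(T, 0, params, grid,
                                                  dt = dt))
      tempo_trajectory(T, params, grid,
                       ages = opts$ages %||% seq(0, T, by = 50),
                       mode = "member", n_T = n_T, M = opts$M, dt = dt)
    },
    "5a" = branch_duration_density(x0_set,
                                   opts$t_grid %||%
                                     seq(0, 40, length.out = 201),
                                   params, grid),
    "5b" = molecular_change_density(opts$w_grid %||%
                                      seq(0, 8, length.out = 201),
                                    params, x0 = x0_set),
    stop(sprintf("unknown figure id '%s'", figure_id), call. = FALSE)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
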