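test_that("with no birth or death a single branch accrues molecular length", {
  p0 <- cet_params(1e-12, 0, 0.01, 1) # effectively event-free
  tr <- simulate_clade(p0, 0.5, 10, dt = 0.1, seed = 1)
  expect_equal(nrow(tr), 1)
  expect_equal(tr$status, "extant")
  expect_equal(tr$t_end, 10)
  expect_gt(tr$w, 0)
  expect_equal(attr(tr, "n_extant"), 1L)
})

test_that("homogeneous extinction fraction matches the closed form", {
  ens <- simulate_ensemble(homog_params(), 0, 50, n_reps = 10000L, seed = 2,
                           dt = 0.25, cap = 1e5, survival_only = TRUE)
  p0 <- bdp_p0(50, 0.51, 0.5)
  expect_lt(abs((1 - mean(ens$survived)) - p0),
            2 * sqrt(p0 * (1 - p0) / 10000))
})

test_that("simulated size histogram matches the inverted distribution", {
  g <- default_grid()
  p <- core_params()
  ens <- simulate_ensemble(p, 0, 50, n_reps = 4000L, seed = 3, dt = 0.1,
                           cap = 1e5)
  d <- invert_gf(50, 0, p, g, M = 4096L, dt = 0.25)
  emp <- tabulate(ens$sizes + 1, nbins = 4096) / 4000
  tv <- 0.5 * sum(abs(emp - d$p)) + 0.5 * attr(d, "tail_mass")
  expect_lt(tv, 3 / sqrt(4000))
  # mean size against the mean equation, within Monte Carlo error
  n_pde <- mean_species(50, p, g, dt = 0.1)$n_expected[x_index(g, 0)]
  expect_lt(abs(mean(ens$sizes) - n_pde),
            2 * stats::sd(ens$sizes) / sqrt(4000))
})

test_that("survival at 500 myr matches the extinction solve", {
  g <- default_grid()
  p <- core_params()
  ens <- simulate_ensemble(p, 0, 500, n_reps = 2000L, seed = 4, dt = 0.1,
                           survival_only = TRUE)
  p_surv <- 1 - extinction_prob(500, p, g, dt = 0.5)$p_extinct[x_index(g, 0)]
  expect_lt(abs(mean(ens$survived) - p_surv),
            2 * sqrt(p_surv * (1 - p_surv) / 2000))
})

test_that("halving the simulator step leaves ensemble summaries unchanged", {
  p <- core_params()
  e1 <- simulate_ensemble(p, 0, 50, n_reps = 2000L, seed = 5, dt = 0.2,
                          cap = 1e5)
  e2 <- simulate_ensemble(p, 0, 50, n_reps = 2000L, seed = 6, dt = 0.1,
                          cap = 1e5)
  se_mean <- sqrt(stats::var(e1$sizes) / 2000 + stats::var(e2$sizes) / 2000)
  expect_lt(abs(mean(e1$sizes) - mean(e2$sizes)), 3 * se_mean)
  se_surv <- sqrt(2 * mean(e1$survived) / 2000)
  expect_lt(abs(mean(e1$survived) - mean(e2$survived)), 3 * se_surv)
})

test_that("with no mean reversion high-tempo lineages take over", {
  pr <- cet_params(0.51, 0.5, 0, 1)
  set.seed(8)
  tev <- c(10, 30, 60, 100)
  num <- den <- numeric(length(tev))
  for (i in 1:500) {
    x0 <- max(min(stats::rnorm(1), 3), -3)
    tr <- simulate_clade(pr, x0, 100, dt = 0.25, cap = 1e5)
    cur <- cetempo:::tree_ltt(tr, tev)
    num <- num + exp(x0) * cur$species
    den <- den + cur$species
  }
  expect_true(all(diff(num / den) > 0))
})

test_that("newick output round-trips and respects the length mode", {
  p <- core_params()
  set.seed(10)
  repeat {
    tr <- simulate_clade(p, 0, 60, dt = 0.1, cap = 1e4)
    if (attr(tr, "n_extant") >= 3 && attr(tr, "n_extant") < 60) break
  }
  nwk <- tree_to_newick(tr, "time", nhx = FALSE)
  ph <- ape::read.tree(text = nwk)
  expect_equal(ape::Ntip(ph), sum(tr$status != "speciated"))
  # extant root-to-tip distances all equal the horizon (ultrametric)
  dep <- ape::node.depth.edgelength(ph)[seq_len(ape::Ntip(ph))] + ph$root.edge
  extant_tips <- paste0("t", tr$id[tr$status == "extant"])
  expect_lt(max(abs(dep[match(extant_tips, ph$tip.label)] - 60)), 1e-6)
  # total branch time preserved through the round trip
  expect_lt(abs(sum(ph$edge.length) + ph$root.edge -
                  sum(tr$t_end - tr$t_birth)), 1e-6)
  # molecular mode need not be ultrametric
  ph2 <- ape::read.tree(text = tree_to_newick(tr, "molecular", nhx = FALSE))
  dep2 <- ape::node.depth.edgelength(ph2)[seq_len(ape::Ntip(ph2))] +
    ph2$root.edge
  expect_gt(diff(range(dep2[match(extant_tips, ph2$tip.label)])), 1e-3)
  # NHX annotations carry tempo and the alternative length
  expect_match(tree_to_newick(tr, "time", nhx = TRUE), "&&NHX:xb=",
               fixed = TRUE)
})

test_that("truncated or partial trees are refused unless forced", {
  p <- core_params()
  set.seed(12)
  repeat {
    tr <- simulate_clade(p, 2, 200, dt = 0.1, cap = 50)
    if (attr(tr, "truncated")) break
  }
  expect_error(tree_to_newick(tr), "truncated")
  set.seed(13)
  repeat {
    tr2 <- simulate_clade(p, 0, 100, dt = 0.1, stop_at_survivor = TRUE)
    if (attr(tr2, "early_stop")) break
  }
  expect_error(tree_to_newick(tr2, force = TRUE), "unprocessed")
})

test_that("snapshots record each live branch once per time", {
  p0 <- cet_params(1e-12, 0, 0.01, 1)
  tr <- simulate_clade(p0, 0, 20, dt = 0.1, seed = 3,
                       snapshot_times = c(5, 15))
  snaps <- attr(tr, "snapshots")
  expect_equal(nrow(snaps), 2)
  expect_equal(snaps$time, c(5, 15))
  expect_true(all(abs(snaps$x) <= 10))
  expect_equal(glance(tr)$n_extant, 1L)
})
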