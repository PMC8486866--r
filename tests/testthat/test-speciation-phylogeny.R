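test_that("trait-gap clustering implements the 3-sigma_mu species rule", {
  p <- study_params()          # sigma_mu = 0.02, so the gap limit is 0.06
  st <- community_state(z = c(0, 0.01, 0.02), N = rep(100, 3), pop_id = 1:3)
  out <- assign_species(st, p)
  expect_equal(length(unique(out$state$species_id)), 1L)
  expect_equal(nrow(out$events), 0L)

  st2 <- community_state(z = c(0, 0.1), N = c(100, 50), pop_id = 1:2)
  out2 <- assign_species(st2, p, time = 42)
  expect_equal(length(unique(out2$state$species_id)), 2L)
  expect_equal(out2$events$time, 42)
  expect_equal(out2$events$parent, 1L)
  # heavier cluster keeps the parental label
  expect_equal(out2$state$species_id[1], 1L)

  one <- community_state(z = 0.3, N = 10)
  expect_equal(assign_species(one, p)$state$species_id, 1L)
})

test_that("gap clustering agrees with single-linkage clustering", {
  threshold <- 0.06
  for (seed in 1:30) {
    set.seed(seed)
    n <- sample(2:12, 1)
    z <- rnorm(n, 0, 0.2)
    cl <- trait_gap_clusters(z, threshold)
    hc <- stats::hclust(stats::dist(z), method = "single")
    ref <- stats::cutree(hc, h = threshold)
    # same partition up to label permutation
    expect_equal(length(unique(cl)), length(unique(ref)))
    tab <- table(cl, ref)
    expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
  }
})

test_that("multi-way splits emit one event per new cluster at the same time", {
  p <- study_params()
  st <- community_state(z = c(-0.5, 0, 0.5), N = c(10, 100, 10), pop_id = 1:3)
  out <- assign_species(st, p, time = 7)
  expect_equal(length(unique(out$state$species_id)), 3L)
  expect_equal(nrow(out$events), 2L)
  expect_equal(out$events$time, c(7, 7))
  expect_equal(out$events$parent, c(1L, 1L))
  expect_false(any(duplicated(out$events$child)))
  # most abundant cluster (the center) keeps the parental id
  expect_equal(out$state$species_id[2], 1L)
})

test_that("patristic distances trace most recent common ancestors", {
  phy <- make_fixture("three_species_tree")
  expect_equal(patristic_distance(phy, 1, 1), 0)
  expect_equal(patristic_distance(phy, 1, 3), 40)   # split at 80, present 100
  expect_equal(patristic_distance(phy, 1, 2), 160)  # split at 20
  expect_equal(patristic_distance(phy, 2, 3), 160)
  expect_equal(patristic_distance(phy, 3, 1), patristic_distance(phy, 1, 3))
  expect_error(patristic_distance(phy, 1, 99), "unknown")

  two <- make_fixture("two_species_tree")
  expect_equal(patristic_distance(two, 1, 2), 2 * (100 - 60))
})

test_that("Newick export round-trips all pairwise distances", {
  # single-species tree is a valid one-tip Newick
  single <- phylogeny(data.frame(time = numeric(0), parent = integer(0),
                                 child = integer(0)),
                      extant = 1L, time = 50)
  tr <- ape::read.tree(text = to_newick(single))
  expect_equal(tr$tip.label, "S1")
  expect_equal(tr$edge.length, 50)

  for (fix in list(make_fixture("three_species_tree"),
                   random_phylogeny(8, seed = 2),
                   random_phylogeny(12, seed = 5))) {
    tr <- ape::read.tree(text = to_newick(fix))
    got <- stats::cophenetic(tr)
    ids <- as.integer(sub("S", "", rownames(got)))
    want <- outer(seq_along(ids), seq_along(ids), Vectorize(function(i, j)
      patristic_distance(fix, ids[i], ids[j])))
    expect_equal(unname(got), want, tolerance = 1e-9)
    expect_true(ape::is.ultrametric(tr, tol = 1e-9))
  }
})

test_that("phylogeny prunes extinct lineages through ancestry chains", {
  # species 2 splits from 1 at t=10, species 3 from 2 at t=30, and 2 dies:
  # the reconstructed (1,3) divergence is still 10
  ev <- data.frame(time = c(10, 30), parent = c(1L, 2L), child = c(2L, 3L))
  phy <- phylogeny(ev, extant = c(1L, 3L), time = 100)
  expect_equal(patristic_distance(phy, 1, 3), 2 * (100 - 10))
  tr <- ape::read.tree(text = to_newick(phy))
  expect_equal(sort(tr$tip.label), c("S1", "S3"))
})

test_that("gamma statistic matches the published formula and ape's implementation", {
  # hand-checked example: n = 3 tips, both internode intervals equal
  expect_equal(gamma_statistic(c(0, 1), time = 2), -sqrt(3) / 5, tolerance = 1e-10)
  expect_equal(oracle_gamma(c(0, 1), 2), gamma_statistic(c(0, 1), 2),
               tolerance = 1e-12)
  expect_error(gamma_statistic(c(5), time = 10), "at least 3")

  for (seed in c(3, 8, 13)) {
    phy <- random_phylogeny(10, seed = seed)
    bt <- branching_times(phy)
    expect_length(bt, 9)
    g <- gamma_statistic(bt, phy$time)
    expect_equal(g, oracle_gamma(bt, phy$time), tolerance = 1e-10)
    # independent route: ape's gammaStat on the exported tree
    tr <- ape::read.tree(text = to_newick(phy))
    expect_equal(g, ape::gammaStat(tr), tolerance = 1e-8)
  }
  # late-burst trees have positive gamma
  expect_gt(gamma_statistic(c(0, 90, 91, 92), time = 100), 0)
})

test_that("pure-birth branching times center gamma near zero", {
  set.seed(2024)
  n <- 20
  gs <- replicate(300, {
    # Yule process: interval with k lineages ~ Exp(k); root at time 0
    g <- stats::rexp(n - 1, rate = 2:n)
    bt <- cumsum(c(0, g[-(n - 1)]))
    gamma_statistic(bt, bt[n - 1] + g[n - 1])
  })
  expect_lt(abs(mean(gs)), 3 / sqrt(300))  # gamma is asymptotically N(0,1)
})

test_that("event-log replay rebuilds the phylogeny incrementally", {
  cfg <- simulation_config(study_params(sigma_con = 0.5), n_steps = 300,
                           metric_interval = 100, base_seed = 5)
  res <- run_radiation(cfg, 1)
  rebuilt <- phylogeny(res$events, res$phylogeny$extant, res$phylogeny$time)
  expect_equal(to_newick(rebuilt), to_newick(res$phylogeny))
  # every internal split corresponds to a registered event time
  bt <- branching_times(res$phylogeny)
  expect_true(all(bt %in% c(0, res$events$time)))
})
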