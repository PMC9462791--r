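test_that("Yule simulation is well-formed, seeded, and matches the growth law", {
  ## two tips: a single cherry
  tr2 <- simulate_yule(2, 1, seed = 1)
  expect_equal(ape::Ntip(tr2), 2)
  expect_equal(tr2$Nnode, 1)

  ## deterministic under seed
  expect_equal(ape::write.tree(simulate_yule(9, 2, seed = 42)),
               ape::write.tree(simulate_yule(9, 2, seed = 42)))

  ## expected height: reaching n tips from 2 takes sum_{j=2}^{n-1} 1/(j b),
  ## plus the final Exp(n b) extension -> E[height] = (H_n - 1)/b
  n <- 8; b <- 1.5
  hts <- vapply(1:400, function(i) {
    max(ape::node.depth.edgelength(simulate_yule(n, b, seed = 10000 + i)))
  }, numeric(1))
  expected <- (sum(1 / (1:n)) - 1) / b
  expect_lt(abs(mean(hts) - expected), 4 * sd(hts) / sqrt(length(hts)))

  ## trees are ultrametric and valid
  expect_true(ape::is.ultrametric(simulate_yule(12, 1, seed = 3), tol = 1e-8))
})

test_that("alignment simulation records a truthful event list", {
  tr <- scale_branch_lengths(simulate_yule(10, 1, seed = 2), 0.3)
  m <- rate_model("JTT", gamma_shape = 0.8, n_cat = 4)

  ## no planting: plain CTMC, no planted flags
  sim <- simulate_alignment(tr, m, 40, seed = 5)
  expect_false(any(sim$events$planted))
  ## events are exactly the parent/child state differences
  for (k in sample(nrow(sim$events), 5)) {
    e <- sim$events[k, ]
    par <- sim$tree$edge[sim$tree$edge[, 2] == e$branch, 1]
    expect_equal(sim$node_states[par, e$site], e$anc)
    expect_equal(sim$node_states[e$branch, e$site], e$der)
  }

  ## planting with probability 1: every non-root branch ends in the target
  simP <- simulate_alignment(tr, m, 10,
                             planted = list(sites = 3L, prob = 1, target = "R"),
                             seed = 6)
  non_root <- simP$tree$edge[, 2]
  expect_true(all(simP$node_states[non_root, 3] == "R"))

  ## true convergent-pair count at the planted site equals brute force over
  ## the recorded event list
  simQ <- simulate_alignment(tr, m, 10,
                             planted = list(sites = 3L, prob = 0.4, target = "R"),
                             seed = 7)
  tab <- branch_pair_table(simQ$events, simQ$tree, sites = 3)
  ev3 <- simQ$events[simQ$events$site == 3, ]
  pairs <- comparable_pairs(simQ$tree)
  brute <- 0
  for (i in seq_len(nrow(pairs))) {
    d1 <- ev3$der[ev3$branch == pairs[i, 1]]
    d2 <- ev3$der[ev3$branch == pairs[i, 2]]
    if (length(d1) && length(d2) && d1 == d2) brute <- brute + 1
  }
  expect_equal(sum(tab$C), brute)
})

test_that("compound-pair simulation matches the transition kernel", {
  tr <- ape::read.tree(text = "(A:0.8,B:0.0001);")
  rates <- c(q13 = 2, q24 = 2, q12 = 0.5, q34 = 0.5, q21 = 0.3, q31 = 0.3,
             q42 = 0.3, q43 = 0.3)

  ## all rates zero: everything stays ancestral
  z <- simulate_correlated_pair(tr, c(q13 = 0), seed = 1)
  expect_true(all(z$x == 0) && all(z$y == 0))
  expect_equal(z$n_transitions, 0)

  ## strongly asymmetric gain: most tips have site 1 derived
  tr50 <- scale_branch_lengths(simulate_yule(50, 1, seed = 9), 0.6)
  s <- simulate_correlated_pair(tr50, c(q13 = 8, q24 = 8, q12 = 0.1, q34 = 0.1),
                                seed = 2)
  expect_gt(mean(s$x), 0.6)

  ## single-branch occupancy vs the matrix exponential, 4000 replicates
  set.seed(11)
  ends <- vapply(1:4000, function(i) {
    simulate_correlated_pair(tr, rates)$node_states[1]
  }, integer(1))
  P <- as.matrix(Matrix::expm(nkaevol:::pagel_generator(rates) * 0.8))
  freq <- tabulate(ends, 4) / 4000
  mc_se <- sqrt(P[1, ] * (1 - P[1, ]) / 4000)
  expect_true(all(abs(freq - P[1, ]) < 4 * mc_se + 1e-3))
})

test_that("background panels have clade-structured divergence profiles", {
  bgs <- simulate_backgrounds(8, 30, seed = 14)
  expect_equal(dim(bgs$profile), c(8, 30))
  ## focal sites fixed at the ancestral states
  expect_true(all(site_states(bgs$aln, 111) == "Q"))
  expect_true(all(site_states(bgs$aln, 122) == "N"))
  ## every variant site is variant, and its alignment column matches the
  ## recorded profile
  for (j in seq_along(bgs$variant_labels)) {
    col <- site_states(bgs$aln, bgs$variant_labels[j])
    expect_gt(length(unique(col)), 1)
    expect_equal(unname(as.integer(col != col[which(bgs$profile[, j] == 0)[1]])),
                 unname(bgs$profile[, j]))
  }
  ## sites on the same branch share identical profiles (correlated groups)
  dup <- which(duplicated(bgs$site_branch))
  if (length(dup)) {
    j <- dup[1]; k <- which(bgs$site_branch == bgs$site_branch[j])[1]
    expect_equal(bgs$profile[, j], bgs$profile[, k], ignore_attr = TRUE)
  }
})

test_that("assay generation round-trips through the analysis exactly at zero noise", {
  bgs <- simulate_backgrounds(8, 20, seed = 3)
  panel <- simulate_construct_panel(rownames(bgs$profile))
  ds <- simulate_assay_dataset(panel, bgs, noise_sd = 0, activity_cv = 0,
                               seed = 4)
  curve <- standard_curve(ds$standards$conc_mM, ds$standards$absorbance)
  w1 <- ds$wells[ds$wells$construct == panel$construct[1] &
                 ds$wells$replicate == 1, ]
  norm <- normalize_assay(w1, curve)
  ## IC50 recovered to 1e-6 through absorbance -> percent -> 4PL
  fit <- fit_ic50(norm$percent$log10_conc, norm$percent$percent)
  expect_equal(fit$log10_ic50, unname(ds$truth$ic50[panel$construct[1]]),
               tolerance = 1e-6)
  ## activity recovered exactly
  expect_equal(norm$activity, unname(ds$truth$panel$activity_true[1]),
               tolerance = 1e-8)

  ## no epistatic effect: all deltas vanish at zero noise
  cmp <- enumerate_comparisons(
    data.frame(ds$truth$panel[, c("construct", "background", "site", "to")],
               activity = ds$truth$panel$activity_true))
  expect_equal(max(cmp$delta), 0, tolerance = 1e-9)
})

test_that("planted epistasis gives deltas proportional to causal divergence", {
  bgs <- simulate_backgrounds(8, 20, seed = 5)
  panel <- simulate_construct_panel(rownames(bgs$profile))
  panel$activity <- 10
  cmp <- enumerate_comparisons(panel)
  div <- divergence_matrix(bgs$aln, cmp, variant_sites(bgs$aln))
  causal <- plant_causal_sites(bgs, div, 5)
  expect_true(all(causal %in% bgs$variant_labels))

  ## expectation k x effect over 200 noisy replicates
  cnt <- rowSums(div[, as.character(causal), drop = FALSE])
  sims <- replicate(200, simulate_epistasis_deltas(div, causal, signal = 4,
                                                   noise_sd = 1))
  expect_equal(rowMeans(sims), 4 * cnt, tolerance = 0.35)

  ## the full activity-level generator shows the same proportionality
  ds <- simulate_assay_dataset(panel, bgs, causal_sites = causal,
                               causal_effect = 0.3, noise_sd = 0,
                               activity_cv = 0, seed = 6)
  cmp2 <- enumerate_comparisons(
    data.frame(ds$truth$panel[, c("construct", "background", "site", "to")],
               activity = ds$truth$panel$activity_true))
  ccount <- ds$truth$causal_count
  expected <- 100 * 0.3 * abs(ccount[cmp2$bg1] - ccount[cmp2$bg2])
  expect_equal(unname(cmp2$delta), unname(expected), tolerance = 1e-8)
})
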