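test_that("substitution effects are percent changes with a positivity guard", {
  expect_equal(substitution_effect(10, 15), 50)
  expect_equal(substitution_effect(10, 10), 0)
  expect_equal(substitution_effect(8, 2), -75)
  expect_error(substitution_effect(0, 5), "positive")
})

test_that("comparison enumeration matches hand enumeration", {
  ## two backgrounds given the same state at 122: exactly one comparison
  panel <- data.frame(construct = c("b1wt", "b2wt", "b1m", "b2m"),
                      background = c("b1", "b2", "b1", "b2"),
                      site = c(NA, NA, 122, 122),
                      to = c(NA, NA, "D", "D"),
                      activity = c(10, 20, 5, 18))
  cmp <- enumerate_comparisons(panel)
  expect_equal(nrow(cmp), 1)
  expect_equal(cmp$E1, -50); expect_equal(cmp$E2, -10)
  expect_equal(cmp$delta, 40)

  ## same substitution twice on one background: no comparison
  dup <- panel[c(1, 3, 3), ]; dup$construct <- c("b1wt", "m1", "m2")
  expect_equal(nrow(enumerate_comparisons(dup)), 0)

  ## 5-construct toy panel: hand enumeration gives C(3,2) = 3 comparisons
  p5 <- data.frame(construct = paste0("c", 1:6),
                   background = c("b1", "b2", "b3", "b1", "b2", "b3"),
                   site = c(NA, NA, NA, 111, 111, 111),
                   to = c(NA, NA, NA, "R", "R", "R"),
                   activity = c(10, 10, 10, 12, 8, 10))
  cmp5 <- enumerate_comparisons(p5)
  expect_equal(nrow(cmp5), 3)
  expect_setequal(paste(cmp5$bg1, cmp5$bg2),
                  c("b1 b2", "b1 b3", "b2 b3"))

  ## the default study-shaped panel yields 4 + 7 = 11 comparisons
  panel11 <- simulate_construct_panel(paste0("BG", 1:8))
  panel11$activity <- 10
  cmp11 <- enumerate_comparisons(panel11)
  expect_equal(nrow(cmp11), 11)
  expect_equal(sum(cmp11$site == 111), 4)
  expect_equal(sum(cmp11$site == 122), 7)
})

test_that("divergence binarization counts differing sites", {
  aln <- nka_alignment(c(b1 = "QNARK", b2 = "QNARK", b3 = "QDA-K"), "b1")
  expect_equal(sum(binarize_divergence(aln, "b1", "b2", 1:5)), 0)
  v <- binarize_divergence(aln, "b1", "b3", 1:5)
  ## hand count: site 2 N vs D, site 4 R vs gap -> distance 2
  expect_equal(unname(v), c(0, 1, 0, 1, 0))
  expect_equal(sum(v), 2)
  ## variant sites: gaps count as a state
  expect_setequal(variant_sites(aln), c(2, 4))
})

test_that("site grouping finds connected components of the correlation graph", {
  div <- cbind(a = c(1, 1, 0, 0, 1, 0), b = c(1, 1, 0, 0, 1, 0),
               c = c(0, 0, 1, 1, 0, 1), d = c(1, 0, 1, 0, 0, 1),
               e = c(0, 1, 1, 1, 1, 0), f = c(1, 1, 1, 1, 1, 1))
  colnames(div) <- c(201, 202, 203, 204, 205, 206)
  g <- group_sites(div, 0.8)
  reps <- vapply(g, function(x) x$representative, numeric(1))
  ## duplicated columns 201/202 share a group; 203 = 1 - 201 also joins
  ## (|r| = 1); hand r matrix puts 204, 205 alone; constant 206 alone
  grp1 <- g[[which(vapply(g, function(x) 201 %in% x$sites, logical(1)))]]
  expect_setequal(grp1$sites, c(201, 202, 203))
  expect_equal(grp1$representative, 201)
  expect_equal(length(g), 4)
  ## hand-computed r matrix agrees with the adjacency used
  ## (columns 1..5 = sites 201, 202, 203, 204, 205)
  cc <- cor(div[, 1:5])
  expect_true(abs(cc[1, 2]) > 0.8 && abs(cc[1, 3]) > 0.8)
  expect_true(all(abs(cc[4, c(1, 2, 3, 5)]) < 0.8))
  expect_error(group_sites(div[1, , drop = FALSE]), ">= 2 comparisons")
})

test_that("nested selection puts a perfectly explanatory group first", {
  set.seed(10)
  bgs <- simulate_backgrounds(8, 24, seed = 21)
  panel <- simulate_construct_panel(rownames(bgs$profile))
  panel$activity <- 10
  cmp <- enumerate_comparisons(panel)
  div <- divergence_matrix(bgs$aln, cmp, variant_sites(bgs$aln))
  causal <- plant_causal_sites(bgs, div, 4)
  delta <- simulate_epistasis_deltas(div, causal, signal = 6, noise_sd = 0)
  scan <- nested_anova_select(delta, div, cmp$site)
  ## the causal group is ranked first and already gives R^2 = 1
  expect_true(all(causal %in% scan$groups[[1]]$sites))
  expect_equal(scan$table$R2[scan$table$model == 1], 1, tolerance = 1e-9)
  ## R^2 never decreases along the nesting
  expect_true(all(diff(scan$table$R2) >= -1e-12))
})

test_that("selection on pure-noise deltas usually stops at the covariate model", {
  bgs <- simulate_backgrounds(8, 24, seed = 33)
  panel <- simulate_construct_panel(rownames(bgs$profile))
  panel$activity <- 10
  cmp <- enumerate_comparisons(panel)
  div <- divergence_matrix(bgs$aln, cmp, variant_sites(bgs$aln))
  picks <- vapply(1:200, function(i) {
    set.seed(4000 + i)
    delta <- rnorm(nrow(div))
    nested_anova_select(delta, div, cmp$site, criterion = "LRT")$best
  }, numeric(1))
  expect_gt(mean(picks == 0), 0.5)
})

test_that("the ascertainment-aware permutation null is honest", {
  bgs <- simulate_backgrounds(8, 24, seed = 8)
  panel <- simulate_construct_panel(rownames(bgs$profile))
  panel$activity <- 10
  cmp <- enumerate_comparisons(panel)
  div <- divergence_matrix(bgs$aln, cmp, variant_sites(bgs$aln))

  ## constant delta: every null equals the observed, p = 1
  perm0 <- permutation_null(rep(3, nrow(div)), div, cmp$site, n_perm = 100,
                            seed = 1)
  expect_equal(perm0$p_value, 1)
  expect_true(all(perm0$null_r2 == perm0$observed_r2))

  ## add-one rule: p can never be 0 and honours the 1/(n+1) bound
  causal <- plant_causal_sites(bgs, div, 4)
  delta <- simulate_epistasis_deltas(div, causal, signal = 8, noise_sd = 0.5,
                                     seed = 2)
  perm <- permutation_null(delta, div, cmp$site, n_perm = 199, seed = 3)
  expect_gte(perm$p_value, 1 / 200)
  if (all(perm$null_r2 < perm$observed_r2)) {
    expect_equal(perm$p_value, 1 / 200)
  }

  ## deterministic under seed; stable under comparison relabeling
  perm2 <- permutation_null(delta, div, cmp$site, n_perm = 199, seed = 3)
  expect_equal(perm$p_value, perm2$p_value)
  ord <- sample(nrow(div))
  perm3 <- permutation_null(delta[ord], div[ord, ], cmp$site[ord],
                            n_perm = 2000, seed = 4)
  perm4 <- permutation_null(delta, div, cmp$site, n_perm = 2000, seed = 4)
  expect_lt(abs(perm3$p_value - perm4$p_value), 0.05)
})

test_that("divergence-effect correlation matches hand covariance arithmetic", {
  div <- cbind(`301` = c(1, 0, 1, 0, 1), `302` = c(1, 1, 0, 0, 1))
  cnt <- rowSums(div)
  delta <- 10 * cnt
  out <- divergence_effect_correlation(delta, div, c(301, 302), n_perm = 200,
                                       seed = 1)
  expect_equal(out$r, 1, tolerance = 1e-12)

  delta2 <- c(3, 1, 4, 1, 5)
  out2 <- divergence_effect_correlation(delta2, div, c(301, 302), n_perm = 200,
                                        seed = 1)
  byhand <- sum((delta2 - mean(delta2)) * (cnt - mean(cnt))) /
    sqrt(sum((delta2 - mean(delta2))^2) * sum((cnt - mean(cnt))^2))
  expect_equal(out2$r, byhand, tolerance = 1e-12)
  ## zero-variance count flagged
  outz <- divergence_effect_correlation(delta2, div, 301, n_perm = 200)
  expect_false(is.na(outz$r))
  constant <- cbind(`301` = rep(1, 5))
  expect_true(is.na(divergence_effect_correlation(delta2, constant, 301,
                                                  n_perm = 100)$r))
})
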