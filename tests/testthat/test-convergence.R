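# hand-built calls object for a 4-tip tree ((A,B),(C,D)): internal nodes
# 5 (root), 6 = mrca(A,B), 7 = mrca(C,D)
toy_tree <- function() ape::read.tree(text = "((A:0.2,B:0.3):0.15,(C:0.25,D:0.1):0.05);")

toy_calls <- function(states, pp = NULL) {
  if (is.null(pp)) pp <- matrix(0.95, nrow(states), ncol(states))
  pp[is.na(states)] <- 0.5
  dimnames(states) <- list(5:7, NULL)
  dimnames(pp) <- dimnames(states)
  list(states = states, pp = pp, threshold = 0.8)
}

test_that("substitution extraction matches hand enumeration and masks missing", {
  tr <- toy_tree()
  aln <- nka_alignment(c(A = "QR", B = "ER", C = "QL", D = "QR"), "A")
  ## internal states: root QR, node6 QR, node7 QR
  calls <- toy_calls(matrix(c("Q", "R", "Q", "R", "Q", "R"), 3, 2, byrow = TRUE))
  ev <- extract_substitutions(calls, aln, tr, exclude_sites = integer(0))
  ## hand enumeration: B gains E at site 1 (Q->E), C gains L at site 2 (R->L)
  expect_equal(nrow(ev), 2)
  expect_setequal(paste(ev$site, ev$anc, ev$der),
                  c("1 Q E", "2 R L"))
  ## parent equal to child: no event anywhere for D (branch 4)
  expect_false(4 %in% ev$branch)

  ## masking: uncalled parent produces no event at that site
  st <- matrix(c("Q", "R", NA, "R", "Q", "R"), 3, 2, byrow = TRUE)
  ev2 <- extract_substitutions(toy_calls(st), aln, tr, exclude_sites = integer(0))
  expect_false(any(ev2$branch %in% c(1, 2) & ev2$site == 1))

  ## excluded site range drops events
  aln2 <- nka_alignment(c(A = "QR", B = "ER", C = "QL", D = "QR"), "A",
                        offset = 809)                   # sites 810, 811
  ev3 <- extract_substitutions(calls, aln2, tr)          # default excludes 810-840
  expect_false(810 %in% ev3$site)
  expect_false(811 %in% ev3$site)
})

test_that("pair classification follows the convergence/divergence definitions", {
  ev <- function(site, anc, der) data.frame(branch = 1, site = site,
                                            anc = anc, der = der)
  ## parallel substitution: convergent
  expect_equal(unname(classify_pair(ev(111, "Q", "R"), ev(111, "Q", "R"))), c(1, 0))
  ## same start, different end: divergent
  expect_equal(unname(classify_pair(ev(111, "Q", "R"), ev(111, "Q", "L"))), c(0, 1))
  ## different start, same derived state: still convergent
  expect_equal(unname(classify_pair(ev(111, "E", "R"), ev(111, "Q", "R"))), c(1, 0))
  ## different start, different end: neither class
  expect_equal(unname(classify_pair(ev(111, "E", "H"), ev(111, "Q", "R"))), c(0, 0))
  ## disjoint sites contribute nothing
  expect_equal(unname(classify_pair(ev(111, "Q", "R"), ev(122, "N", "D"))), c(0, 0))
})

test_that("(C+1)/(D+1) and its monotonicity", {
  expect_equal(cd_ratio(0, 0), 1)
  expect_equal(cd_ratio(3, 1), 2)
  expect_equal(cd_ratio(7, 3), 2)
  expect_error(cd_ratio(-1, 0), "non-negative")
  ## monotone increasing in C, decreasing in D, bounded below
  for (C in 0:4) for (D in 0:4) {
    expect_gte(cd_ratio(C, D), 1 / (D + 1))
    expect_gt(cd_ratio(C + 1, D), cd_ratio(C, D))
    expect_lt(cd_ratio(C, D + 1), cd_ratio(C, D))
  }
})

test_that("comparable pairs exclude exactly sisters and ancestor-descendants", {
  ## balanced 8-tip tree; oracle via mrca/parent logic from ape
  tr <- ape::read.tree(
    text = "(((A:1,B:1):1,(C:1,D:1):1):1,((E:1,F:1):1,(G:1,H:1):1):1);")
  pairs <- comparable_pairs(tr)
  branches <- tr$edge[, 2]
  par <- setNames(tr$edge[, 1], tr$edge[, 2])
  keep <- 0
  for (i in seq_along(branches)) for (j in seq_len(i - 1)) {
    b1 <- branches[i]; b2 <- branches[j]
    sis <- par[[as.character(b1)]] == par[[as.character(b2)]]
    anc <- ape::mrca(tr, full = TRUE)[b1, b2] %in% c(b1, b2)
    if (!sis && !anc) keep <- keep + 1
  }
  expect_equal(nrow(pairs), keep)
  ## and the hand count for this symmetric shape: 14 branches, C(14,2)=91,
  ## minus 7 sister pairs, minus ancestor-descendant pairs (each of the 6
  ## internal non-root branches is ancestral to the branches below it:
  ## 4*(2) tips-below-cherry + 2*(2+4) = hand total 20)
  expect_equal(nrow(pairs), 91 - 7 - 20)
})

test_that("pair distance is the connecting path minus the focal branches", {
  tr <- toy_tree()
  nd <- ape::dist.nodes(tr)
  ## cousin tips A and C: path A-6-5-7-C; exclude focal terminal branches
  ## leaves 0.15 + 0.05 by hand
  expect_equal(pair_distance(tr, 1, 3), 0.2)
  ## symmetric
  expect_equal(pair_distance(tr, 3, 1), pair_distance(tr, 1, 3))
  ## tip A vs internal branch 7: path A-6-5-7, leaves 0.15 by hand
  expect_equal(pair_distance(tr, 1, 7), 0.15)
  ## ancestor-descendant errors
  expect_error(pair_distance(tr, 6, 1), "ancestor-descendant")
})

test_that("branch pair table agrees with per-pair classification", {
  tr <- toy_tree()
  aln <- nka_alignment(c(A = "RR", B = "ER", C = "RL", D = "QR"), "A")
  calls <- toy_calls(matrix(c("Q", "R", "Q", "R", "Q", "R"), 3, 2, byrow = TRUE))
  ev <- extract_substitutions(calls, aln, tr, exclude_sites = integer(0))
  tab <- branch_pair_table(ev, tr)
  ## A (Q->R at 1) vs C (Q->R at 1, R->L at 2): one convergence
  rowAC <- tab[tab$b1 == 1 & tab$b2 == 3, ]
  expect_equal(rowAC$C, 1); expect_equal(rowAC$D, 0)
  ## A (Q->R) vs D (no events): nothing
  rowAD <- tab[tab$b1 == 1 & tab$b2 == 4, ]
  expect_equal(rowAD$C + rowAD$D, 0)
  expect_equal(rowAD$ratio, 1)
  ## distances match pair_distance
  for (r in seq_len(nrow(tab))) {
    expect_equal(tab$distance[r], pair_distance(tr, tab$b1[r], tab$b2[r]))
  }
})

test_that("running trend reduces to window means and is seed-reproducible", {
  pairs <- data.frame(b1 = 1, b2 = 2,
                      C = 0, D = 0,
                      distance = seq(0, 0.09, by = 0.01),
                      ratio = rep(2, 10))
  tr1 <- running_trend(pairs, window = 0.05, step = 0.01, n_boot = 50, seed = 1)
  ## constant ratios: flat trend, zero-width interval
  expect_true(all(tr1$mean == 2))
  expect_true(all(tr1$lo == 2 & tr1$hi == 2))

  pairs$ratio <- c(1, 3, 2, 2, 1, 4, 2, 0.5, 1, 2)
  tr2 <- running_trend(pairs, window = 0.05, step = 0.01, n_boot = 50, seed = 9)
  tr3 <- running_trend(pairs, window = 0.05, step = 0.01, n_boot = 50, seed = 9)
  expect_identical(tr2, tr3)
  ## window mean at centre 0.02 covers distances 0..0.045 -> first 5 ratios
  expect_equal(tr2$mean[tr2$distance == 0.02], mean(pairs$ratio[1:5]))
})

test_that("convergence-distance logistic regression matches a grid oracle", {
  outcome <- c(1, 0, 1, 0, 1, 0)
  distance <- c(0.1, 0.3, 0.2, 0.5, 0.45, 0.6)
  fit <- convergence_distance_regression(outcome, distance)
  oracle <- grid_logistic(outcome, distance)
  expect_equal(unname(fit$slope), unname(oracle["slope"]), tolerance = 1e-4)

  ## degenerate outcomes are rejected
  expect_error(convergence_distance_regression(rep(1, 6), distance),
               "both outcome classes")

  ## under independence the slope is near zero and rejections near nominal
  set.seed(42)
  rej <- 0
  for (i in 1:40) {
    d <- runif(300); o <- rbinom(300, 1, 0.4)
    f <- convergence_distance_regression(o, d)
    if (f$p_value < 0.05) rej <- rej + 1
  }
  expect_lte(rej, 8)   # 40 null replicates: expect ~2 rejections
})

test_that("planted convergent evolution is recovered through the full path", {
  ## Recovery through ASR is all-or-nothing per replicate: when planted
  ## conversions cluster in one region of the tree, the reconstruction
  ## explains the tips with a single deeper substitution and the parallel
  ## events merge. Aggregated over replicates, at least half of the true
  ## convergent pairs survive reconstruction and PP > 0.8 masking.
  m <- rate_model("JTT", gamma_shape = 0.7, n_cat = 4)
  tot_true <- 0; tot_rec <- 0
  for (k in 1:10) {
    tr <- scale_branch_lengths(simulate_yule(32, 1, seed = k), 0.05)
    sim <- simulate_alignment(tr, m, 60,
                              planted = list(sites = 10L, prob = 0.08,
                                             target = "R"),
                              seed = 100 + k)
    true_tab <- branch_pair_table(sim$events, sim$tree, sites = 10)
    calls <- call_states(marginal_asr(sim$aln, tr, m), 0.8)
    ev <- extract_substitutions(calls, sim$aln, sim$tree,
                                exclude_sites = integer(0))
    rec_tab <- branch_pair_table(ev, sim$tree, sites = 10)
    tot_true <- tot_true + sum(true_tab$C)
    tot_rec <- tot_rec + sum(rec_tab$C)
  }
  expect_gt(tot_true, 20)
  expect_gte(tot_rec, 0.5 * tot_true)
})
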