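# Independent oracles used across test files. These deliberately avoid the
# package's pruning code paths: posteriors and likelihoods are computed by
# exhaustive enumeration over internal-node state assignments.

AA <- nkaevol:::AA_STATES

# Exhaustive marginal posteriors and log-likelihood for a rooted 4-tip tree
# ((A,B),(C,D)) with internal nodes 5 (root), 6, 7 under a rate_model.
# Only needs transition matrices, taken from the (independently verifiable)
# matrix exponential.
enum_asr_4tip <- function(tree, aln, model, site) {
  tree <- ape::reorder.phylo(tree, "postorder")
  tipc <- vapply(tree$tip.label, function(l) match(aln$seq[l, site], AA), 1L)
  joint <- array(0, dim = c(20, 20, 20))
  for (cc in seq_len(model$n_cat)) {
    P <- lapply(seq_len(nrow(tree$edge)), function(e) {
      Matrix::expm(model$Q * model$rates[cc] * tree$edge.length[e])
    })
    for (r in 1:20) for (u in 1:20) for (v in 1:20) {
      asg <- c(tipc, r, u, v)
      pr <- model$freqs[r]
      for (e in seq_len(nrow(tree$edge))) {
        pr <- pr * P[[e]][asg[tree$edge[e, 1]], asg[tree$edge[e, 2]]]
      }
      joint[r, u, v] <- joint[r, u, v] + model$weights[cc] * pr
    }
  }
  list(root = apply(joint, 1, sum) / sum(joint),
       n6 = apply(joint, 2, sum) / sum(joint),
       n7 = apply(joint, 3, sum) / sum(joint),
       loglik = log(sum(joint)))
}

# Exhaustive log-likelihood of the 4-state compound chain on any small
# rooted tree (enumerates internal assignments; fine up to ~5 tips).
enum_pagel_loglik <- function(tree, x, y, rates, root_prior) {
  tree <- ape::reorder.phylo(tree, "postorder")
  n_tip <- ape::Ntip(tree)
  internal <- (n_tip + 1):(n_tip + tree$Nnode)
  Q <- nkaevol:::pagel_generator(rates)
  P <- lapply(seq_len(nrow(tree$edge)), function(e) {
    as.matrix(Matrix::expm(Q * tree$edge.length[e]))
  })
  tip_state <- vapply(tree$tip.label, function(l) {
    1L + 2L * x[[l]] + y[[l]]
  }, 1L)
  grid <- as.matrix(expand.grid(rep(list(1:4), length(internal))))
  total <- 0
  for (g in seq_len(nrow(grid))) {
    asg <- integer(n_tip + tree$Nnode)
    asg[seq_len(n_tip)] <- tip_state
    asg[internal] <- grid[g, ]
    pr <- root_prior[asg[n_tip + 1]]
    for (e in seq_len(nrow(tree$edge))) {
      pr <- pr * P[[e]][asg[tree$edge[e, 1]], asg[tree$edge[e, 2]]]
    }
    total <- total + pr
  }
  log(total)
}

# Grid-search ML logistic regression (coarse-to-fine refinement), as an
# independent check of the glm-based slope.
grid_logistic <- function(outcome, distance) {
  nll <- function(a, b) {
    eta <- a + b * distance
    -sum(outcome * eta - log1p(exp(eta)))
  }
  a_rng <- c(-10, 10); b_rng <- c(-10, 10)
  for (iter in 1:8) {
    a_grid <- seq(a_rng[1], a_rng[2], length.out = 31)
    b_grid <- seq(b_rng[1], b_rng[2], length.out = 31)
    vals <- outer(a_grid, b_grid, Vectorize(nll))
    ix <- which(vals == min(vals), arr.ind = TRUE)[1, ]
    a0 <- a_grid[ix[1]]; b0 <- b_grid[ix[2]]
    da <- diff(a_rng) / 10; db <- diff(b_rng) / 10
    a_rng <- c(a0 - da, a0 + da); b_rng <- c(b0 - db, b0 + db)
  }
  c(intercept = a0, slope = b0)
}

# toy assay wells for one construct-replicate
toy_wells <- function(percent, conc = 10^-(3:8), bg = 0.1, signal = 0.25) {
  data.frame(
    well_type = c(rep("ouabain", length(conc)), "control", "background"),
    conc_M = c(conc, NA, NA),
    absorbance = c(bg + signal * percent / 100, bg + signal, bg))
}

# manual mid-rank Spearman correlation (independent of stats::cor)
manual_spearman <- function(a, b) {
  mr <- function(v) {
    vapply(v, function(x) mean(which(sort(v) == x)), numeric(1))
  }
  ra <- mr(a); rb <- mr(b)
  sum((ra - mean(ra)) * (rb - mean(rb))) /
    sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
}
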