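#' Recode a site to binary ancestral/derived states
#'
#' Tips equal to the reconstructed state of the clade's most recent common
#' ancestor are coded 0 (ancestral), any other residue 1 (derived); gaps
#' and missing residues are `NA`.
#'
#' @param aln An [nka_alignment()].
#' @param site Reference site label.
#' @param mrca_state Reconstructed amino acid of the clade MRCA at that
#'   site (e.g. from [call_states()]). If `NA`, the site cannot be coded.
#' @return Named integer vector (0/1/NA) over the alignment's sequences.
#' @export
recode_binary <- function(aln, site, mrca_state) {
  if (is.na(mrca_state)) stop("MRCA state missing at site ", site, "; site skipped")
  st <- site_states(aln, site)
  out <- ifelse(st %in% AA_STATES, as.integer(st != mrca_state), NA_integer_)
  setNames(out, names(st))
}

#' Binary matrix over many sites
#'
#' @param aln An [nka_alignment()].
#' @param mrca_states Named vector of MRCA amino acids, names = site
#'   labels; sites whose MRCA state is `NA` are skipped.
#' @return Integer matrix (sequences x sites, 0/1/NA), columns named by
#'   site label.
#' @export
binary_site_matrix <- function(aln, mrca_states) {
  sites <- as.integer(names(mrca_states))
  ok <- !is.na(mrca_states)
  m <- vapply(which(ok), function(i) recode_binary(aln, sites[i], mrca_states[i]),
              integer(nrow(aln$seq)))
  colnames(m) <- sites[ok]
  rownames(m) <- aln$ids
  m
}

#' Filter uninformative binary sites
#'
#' Retains sites with at least two derived tips (no singletons) and at
#' most 80% missing data ("more than 80% gaps" are excluded, exactly 80%
#' is kept).
#'
#' @param bin Matrix from [binary_site_matrix()].
#' @param max_missing Maximum tolerated missing fraction (default 0.8).
#' @return Character vector of retained column names (site labels).
#' @export
filter_sites <- function(bin, max_missing = 0.8) {
  keep <- vapply(colnames(bin), function(s) {
    x <- bin[, s]
    sum(x == 1, na.rm = TRUE) >= 2 && mean(is.na(x)) <= max_missing
  }, logical(1))
  colnames(bin)[keep]
}

## Compound 4-state chain over a pair of binary sites.
## States 1=(0,0), 2=(0,1), 3=(1,0), 4=(1,1); double transitions are
## structural zeros. Rate names follow the usual q_{from,to} convention.
PAGEL_RATES <- c("q12", "q13", "q21", "q24", "q31", "q34", "q42", "q43")

pagel_generator <- function(rates) {
  q <- setNames(numeric(8), PAGEL_RATES)
  q[names(rates)] <- rates
  Q <- matrix(0, 4, 4)
  Q[1, 2] <- q["q12"]; Q[1, 3] <- q["q13"]
  Q[2, 1] <- q["q21"]; Q[2, 4] <- q["q24"]
  Q[3, 1] <- q["q31"]; Q[3, 4] <- q["q34"]
  Q[4, 2] <- q["q42"]; Q[4, 3] <- q["q43"]
  diag(Q) <- -rowSums(Q)
  Q
}

## Constraint sets. Each maps a free-parameter vector to the 8 rates.
## base-null: two sites evolve independently (4 free rates).
## base-alt: all 8 rates free.
## restricted: reversals to the ancestral state are fixed at zero;
##   restricted-alt has the 4 forward rates free, restricted-null
##   additionally ties q13=q24 and q12=q34 (2 free rates).
pagel_constraints <- function(constraint) {
  switch(constraint,
    "base-null" = list(
      free = c("a1", "b1", "a2", "b2"),
      expand = function(th) c(q13 = th[["a1"]], q24 = th[["a1"]],
                              q31 = th[["b1"]], q42 = th[["b1"]],
                              q12 = th[["a2"]], q34 = th[["a2"]],
                              q21 = th[["b2"]], q43 = th[["b2"]])),
    "base-alt" = list(
      free = PAGEL_RATES,
      expand = function(th) th),
    "restricted-null" = list(
      free = c("a1", "a2"),
      expand = function(th) c(q13 = th[["a1"]], q24 = th[["a1"]],
                              q12 = th[["a2"]], q34 = th[["a2"]])),
    "restricted-alt" = list(
      free = c("q13", "q24", "q12", "q34"),
      expand = function(th) th),
    stop("unknown constraint set: ", constraint))
}

## tip partial for compound state; NA coordinates integrate over the
## compatible compound states
pagel_tip_partial <- function(a, b) {
  va <- if (is.na(a)) c(TRUE, TRUE) else c(a == 0, a == 1)
  vb <- if (is.na(b)) c(TRUE, TRUE) else c(b == 0, b == 1)
  as.numeric(c(va[1] & vb[1], va[1] & vb[2], va[2] & vb[1], va[2] & vb[2]))
}

pagel_loglik <- function(rates, tree_post, tip_part, root_prior) {
  Q <- pagel_generator(rates)
  n_tip <- dim(tip_part)[3]
  res <- cpp_pruning(Q, tree_post$edge, tree_post$edge.length, n_tip,
                     n_tip + tree_post$Nnode, n_tip + 1L, tip_part,
                     root_prior, 1, 1, FALSE)
  as.numeric(res$site_loglik)
}

#' Fit a Pagel-type correlated-evolution model for two binary sites
#'
#' Maximum-likelihood fit of the compound 4-state continuous-time Markov
#' chain for a pair of binary (ancestral-0/derived-1) site states on a
#' phylogeny, under one of four constraint sets: `base-null`
#' (independent, 4 rates), `base-alt` (dependent, 8 rates),
#' `restricted-null` (no reversals, rates tied across background state, 2
#' rates) and `restricted-alt` (no reversals, 4 rates). Because the
#' binary coding is defined relative to the reconstructed ancestor, the
#' root state is fixed at (0,0) by default. Optimization is multi-start
#' bounded search in log-rate space.
#'
#' @param x,y Named 0/1/NA vectors over the tree's tips (focal and
#'   partner site).
#' @param tree A rooted `phylo`, typically rescaled with
#'   [scale_branch_lengths()].
#' @param constraint One of `"base-null"`, `"base-alt"`,
#'   `"restricted-null"`, `"restricted-alt"`.
#' @param n_starts Number of random multi-starts (log-uniform over the
#'   rate bounds) in addition to a fixed default start and any `init`.
#' @param seed Optional seed for the random starts.
#' @param root Root treatment: `"fixed00"` (mass on compound state (0,0)),
#'   or `"uniform"`.
#' @param bounds Rate bounds for the box-constrained search.
#' @param init Optional named vector of free parameters used as an extra
#'   start (e.g. the null fit's rates when fitting the alternative).
#' @return Object of class `pagel_fit` with `rates` (all 8, tied/zero
#'   entries resolved), `par` (free parameters), `loglik`, `df` (number of
#'   free parameters), `constraint`, `convergence`.
#' @export
fit_pagel <- function(x, y, tree, constraint = "restricted-null",
                      n_starts = 25, seed = NULL, root = c("fixed00", "uniform"),
                      bounds = c(1e-4, 1e3), init = NULL) {
  root <- match.arg(root)
  stop_if_not(all(tree$tip.label %in% names(x)) && all(tree$tip.label %in% names(y)),
              "x and y must be named by tip label")
  cs <- pagel_constraints(constraint)
  tree_post <- ape::reorder.phylo(tree, "postorder")
  n_tip <- ape::Ntip(tree_post)
  tp <- array(0, dim = c(4, 1, n_tip))
  for (i in seq_len(n_tip)) {
    lab <- tree_post$tip.label[i]
    tp[, 1, i] <- pagel_tip_partial(x[[lab]], y[[lab]])
  }
  root_prior <- if (root == "fixed00") c(1, 0, 0, 0) else rep(0.25, 4)

  lb <- log(bounds[1]); ub <- log(bounds[2])
  obj <- function(lth) {
    th <- setNames(exp(lth), cs$free)
    v <- -pagel_loglik(cs$expand(th), tree_post, tp, root_prior)
    if (!is.finite(v)) v <- 1e10   # impossible region (numerical underflow)
    v
  }
  if (!is.null(seed)) set.seed(seed)
  k <- length(cs$free)
  starts <- list(rep(log(0.1), k))
  if (!is.null(init)) starts <- c(starts, list(pmin(pmax(log(init[cs$free]), lb), ub)))
  for (i in seq_len(n_starts)) starts <- c(starts, list(runif(k, lb, ub)))

  best <- NULL
  for (s in starts) {
    o <- tryCatch(
      optim(s, obj, method = "L-BFGS-B", lower = lb, upper = ub,
            control = list(maxit = 500)),
      error = function(e) NULL)
    if (is.null(o)) next
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best)) stop("Pagel optimization failed in all starts (constraint ",
                          constraint, ")")
  th <- setNames(exp(best$par), cs$free)
  rates8 <- setNames(numeric(8), PAGEL_RATES)
  rr <- cs$expand(th)
  rates8[names(rr)] <- rr
  structure(list(rates = rates8, par = th, loglik = -best$value,
                 df = k, constraint = constraint, root = root,
                 convergence = best$convergence, n_starts = length(starts)),
            class = "pagel_fit")
}

#' @export
print.pagel_fit <- function(x, ...) {
  cat(sprintf("Pagel compound-chain fit (%s): lnL = %.4f, %d free rates\n",
              x$constraint, x$loglik, x$df))
  print(signif(x$rates, 4))
  invisible(x)
}

#' @export
logLik.pagel_fit <- function(object, ...) {
  structure(object$loglik, df = object$df, class = "logLik")
}

#' @export
coef.pagel_fit <- function(object, ...) object$rates

#' Likelihood-ratio test between nested Pagel fits
#'
#' @param null,alt `pagel_fit` objects with nested constraint sets
#'   (base-null in base-alt, df 4; restricted-null in restricted-alt,
#'   df 2). The statistic is floored at 0.
#' @return List `statistic, df, p_value`.
#' @export
pagel_lrt <- function(null, alt) {
  nesting <- list("base-null" = "base-alt", "restricted-null" = "restricted-alt")
  stop_if_not(identical(nesting[[null$constraint]], alt$constraint),
              "fits are not a nested null/alternative pair")
  if (alt$loglik < null$loglik - 1e-6) {
    stop(sprintf("optimization failure: lnL(alt) = %.6f < lnL(null) = %.6f",
                 alt$loglik, null$loglik))
  }
  df <- alt$df - null$df
  stat <- max(0, 2 * (alt$loglik - null$loglik))
  list(statistic = stat, df = df, p_value = pchisq(stat, df, lower.tail = FALSE))
}

#' Independent-vs-dependent evolution test for one site pair
#'
#' Convenience wrapper: fits the null and alternative models of the
#' chosen set (the null solution seeds one start of the alternative, so
#' the nesting inequality holds by construction) and runs the LRT.
#'
#' @inheritParams fit_pagel
#' @param type `"restricted"` (df 2) or `"base"` (df 4).
#' @return List with `null`, `alt` (`pagel_fit`s) and the [pagel_lrt()]
#'   result.
#' @export
pagel_test <- function(x, y, tree, type = c("restricted", "base"),
                       n_starts = 10, seed = NULL, root = "fixed00") {
  type <- match.arg(type)
  null_c <- paste0(type, "-null"); alt_c <- paste0(type, "-alt")
  null <- fit_pagel(x, y, tree, null_c, n_starts = n_starts, seed = seed, root = root)
  init <- null$rates[pagel_constraints(alt_c)$free]
  init[init <= 0] <- 1e-4
  alt <- fit_pagel(x, y, tree, alt_c, n_starts = n_starts, seed = seed,
                   root = root, init = init)
  c(list(null = null, alt = alt), pagel_lrt(null, alt))
}

#' Top-ranked sites by association p-value
#'
#' Sites in the top `quantile` by -log(p) (smallest p-values); ties are
#' broken by ascending site label so the returned set is deterministic.
#'
#' @param p Named vector of p-values (names = site labels).
#' @param quantile Fraction of sites to keep (0.05 = "top 5%").
#' @return Character vector of selected site labels.
#' @export
rank_sites <- function(p, quantile = 0.05) {
  n_top <- max(1L, floor(length(p) * quantile + 1e-9))
  ord <- order(p, as.numeric(names(p)))
  names(p)[ord][seq_len(n_top)]
}
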