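#' Marginal ancestral state reconstruction
#'
#' Computes, for every internal node and alignment column, the marginal
#' posterior distribution over the 20 amino acids under a fixed tree and a
#' [rate_model()] with discrete-gamma rate heterogeneity. The algorithm is
#' the standard pruning up-pass followed by a down-pass (outside
#' probabilities), with the rate categories integrated out; the root prior
#' is the model's equilibrium frequencies, matching the marginal
#' reconstruction framework of maximum-likelihood ASR programs. Gaps and
#' `X` are treated as missing data (uniform partial likelihoods);
#' ambiguity codes expand to their possibility sets.
#'
#' @param aln An [nka_alignment()]; rownames must contain every tip label.
#' @param tree A rooted `phylo` with branch lengths in expected
#'   substitutions/site.
#' @param model A [rate_model()].
#' @return An object of class `asr_fit`: `pp`, a 3-d array
#'   (internal node x site column x 20 states) of posterior probabilities;
#'   `loglik`; `site_loglik`; plus the inputs. Internal nodes are indexed
#'   by their ape node ids (`Ntip+1 ...`).
#' @export
marginal_asr <- function(aln, tree, model) {
  validate_phylogeny(tree)
  miss <- setdiff(tree$tip.label, aln$ids)
  if (length(miss)) stop("tips absent from alignment: ", paste(miss, collapse = ", "))
  tree <- ape::reorder.phylo(tree, "postorder")
  n_tip <- ape::Ntip(tree)
  n_node <- n_tip + tree$Nnode
  n_sites <- ncol(aln$seq)

  tp <- array(0, dim = c(20, n_sites, n_tip))
  for (i in seq_len(n_tip)) {
    row <- aln$seq[tree$tip.label[i], ]
    tp[, , i] <- vapply(row, aa_partial, numeric(20))
  }

  res <- cpp_pruning(model$Q, tree$edge, tree$edge.length, n_tip, n_node,
                     root_node(tree), tp, model$freqs, model$rates,
                     model$weights, TRUE)

  pp <- marginal_posteriors(tree, res, model)
  structure(list(pp = pp, loglik = sum(res$site_loglik),
                 site_loglik = as.numeric(res$site_loglik),
                 tree = tree, alignment = aln, model = model),
            class = "asr_fit")
}

## Down-pass: combine per-category outside probabilities with the up-pass
## partials returned by cpp_pruning and mix categories in log space.
marginal_posteriors <- function(tree, res, model) {
  n_tip <- ape::Ntip(tree)
  n_node <- n_tip + tree$Nnode
  internal <- (n_tip + 1L):n_node
  n_cat <- model$n_cat
  edges <- tree$edge            # postorder
  n_sites <- dim(res$up[[1]])[2]
  k <- dim(res$up[[1]])[1]

  ## log joint per node/site/state, accumulated over categories
  logjoint <- array(-Inf, dim = c(length(internal), n_sites, k))

  for (cc in seq_len(n_cat)) {
    up <- res$up[[cc]]          # k x n_sites x n_node
    usc <- res$scalers[[cc]]    # n_node x n_sites
    P <- res$P[[cc]]            # k x k x n_edge
    down <- array(NA_real_, dim = c(k, n_sites, n_node))
    dsc <- matrix(0, n_node, n_sites)
    rt <- root_node(tree)
    down[, , rt] <- matrix(model$freqs, k, n_sites)

    for (e in rev(seq_len(nrow(edges)))) {   # preorder
      par <- edges[e, 1]; chi <- edges[e, 2]
      sib <- which(edges[, 1] == par); sib <- sib[sib != e]
      tmp <- down[, , par, drop = FALSE][, , 1]
      if (n_sites == 1) tmp <- matrix(tmp, k, 1)
      sc <- dsc[par, ]
      for (s in sib) {
        cs <- edges[s, 2]
        tmp <- tmp * (P[, , s] %*% up[, , cs])
        sc <- sc + usc[cs, ]
      }
      dn <- crossprod(P[, , e], tmp)
      m <- apply(dn, 2, max)
      pos <- m > 0
      dn[, pos] <- sweep(dn[, pos, drop = FALSE], 2, m[pos], "/")
      down[, , chi] <- dn
      dsc[chi, ] <- sc + ifelse(pos, log(m), 0)
    }

    lw <- log(model$weights[cc])
    for (vi in seq_along(internal)) {
      v <- internal[vi]
      lj <- log(up[, , v]) + log(down[, , v]) +
        rep(usc[v, ] + dsc[v, ] + lw, each = k)   # k x n_sites
      cur <- matrix(logjoint[vi, , ], n_sites, k)
      logjoint[vi, , ] <- apply_logsum(cur, t(matrix(lj, k, n_sites)))
    }
  }

  ## normalize over states
  pp <- array(0, dim = dim(logjoint),
              dimnames = list(internal, NULL, AA_STATES))
  for (vi in seq_along(internal)) {
    lj <- logjoint[vi, , , drop = FALSE][1, , ]
    if (n_sites == 1) lj <- matrix(lj, 1, k)
    mx <- apply(lj, 1, max)
    w <- exp(lj - mx)
    pp[vi, , ] <- w / rowSums(w)
  }
  pp
}

## elementwise log(exp(a)+exp(b)) for matrices
apply_logsum <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log(exp(a - m) + exp(b - m))
  out[!is.finite(m)] <- -Inf
  out
}

#' @export
print.asr_fit <- function(x, ...) {
  cat(sprintf("Marginal ASR: %d internal nodes x %d sites, lnL = %.4f\n",
              dim(x$pp)[1], dim(x$pp)[2], x$loglik))
  invisible(x)
}

#' @export
logLik.asr_fit <- function(object, ...) {
  structure(object$loglik, df = NA, class = "logLik")
}

#' Call ancestral states above a posterior-probability threshold
#'
#' States whose maximum posterior probability does not exceed the
#' threshold are reported missing (`NA`) and are skipped by downstream
#' substitution calling.
#'
#' @param fit An `asr_fit`.
#' @param threshold Posterior probability that must be exceeded
#'   (strictly) for a state to be called; the convergence analyses use
#'   0.8. `0` calls the argmax state everywhere.
#' @return List with `states` (internal node x site character matrix,
#'   `NA` = missing) and `pp` (matrix of the maximum posterior
#'   probabilities).
#' @export
call_states <- function(fit, threshold = 0.8) {
  stop_if_not(threshold >= 0 && threshold < 1, "threshold must be in [0, 1)")
  pp <- fit$pp
  n_node <- dim(pp)[1]; n_sites <- dim(pp)[2]
  states <- matrix(NA_character_, n_node, n_sites,
                   dimnames = list(dimnames(pp)[[1]], NULL))
  maxpp <- matrix(NA_real_, n_node, n_sites,
                  dimnames = dimnames(states))
  for (v in seq_len(n_node)) {
    p <- pp[v, , , drop = FALSE][1, , ]
    if (n_sites == 1) p <- matrix(p, 1, 20)
    j <- max.col(p, ties.method = "first")
    mx <- p[cbind(seq_len(n_sites), j)]
    ok <- mx > threshold
    states[v, ok] <- AA_STATES[j[ok]]
    maxpp[v, ] <- mx
  }
  list(states = states, pp = maxpp, threshold = threshold)
}

#' Maximum-likelihood gamma shape with fixed branch lengths
#'
#' One-dimensional bounded optimization of the pruning log-likelihood over
#' the gamma shape parameter; everything else in the model is held fixed.
#'
#' @inheritParams marginal_asr
#' @param interval Search interval for the shape.
#' @return List with `shape`, `loglik`, and `flat` (TRUE when the
#'   likelihood surface gave no interior optimum and the upper bound was
#'   returned, with a warning).
#' @export
fit_gamma_shape <- function(aln, tree, model, interval = c(0.05, 20)) {
  n_var <- sum(apply(aln$seq, 2, function(col) {
    r <- col[col %in% AA_STATES]
    length(unique(r)) > 1
  }))
  stop_if_not(n_var >= 2, "need at least 2 variable sites")
  if (model$n_cat == 1) {
    warning("single rate category: shape is not identifiable, returning NA")
    return(list(shape = NA_real_, loglik = asr_loglik(aln, tree, model), flat = TRUE))
  }
  obj <- function(a) {
    m <- rate_model(model$name, freqs = model$freqs, gamma_shape = a,
                    n_cat = model$n_cat)
    -asr_loglik(aln, tree, m)
  }
  opt <- optimize(obj, interval = interval)
  flat <- opt$minimum > 0.98 * interval[2]
  if (flat) warning("likelihood flat in gamma shape; returning upper bound region")
  list(shape = opt$minimum, loglik = -opt$objective, flat = flat)
}

#' Pruning log-likelihood of an alignment on a tree
#'
#' @inheritParams marginal_asr
#' @return Total log-likelihood (sum over sites).
#' @export
asr_loglik <- function(aln, tree, model) {
  tree <- ape::reorder.phylo(tree, "postorder")
  n_tip <- ape::Ntip(tree)
  n_node <- n_tip + tree$Nnode
  tp <- array(0, dim = c(20, ncol(aln$seq), n_tip))
  for (i in seq_len(n_tip)) {
    tp[, , i] <- vapply(aln$seq[tree$tip.label[i], ], aa_partial, numeric(20))
  }
  res <- cpp_pruning(model$Q, tree$edge, tree$edge.length, n_tip, n_node,
                     root_node(tree), tp, model$freqs, model$rates,
                     model$weights, FALSE)
  sum(res$site_loglik)
}
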