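#' Substitutions implied by ancestral state calls
#'
#' A substitution is recorded on a branch at a site when the states at
#' both ends of the branch are called (tips are taken from the alignment;
#' internal states from [call_states()], i.e. only posterior probabilities
#' above the threshold) and differ. Sites in `exclude_sites` (by default
#' the putative alternatively-spliced region, reference positions 810-840)
#' are dropped. A branch is identified by its child node id.
#'
#' @param calls Result of [call_states()] on an [marginal_asr()] fit.
#' @param aln The tip alignment used for the reconstruction.
#' @param tree The (rooted) tree; branch = child node id.
#' @param exclude_sites Integer site labels to exclude (default 810:840).
#' @return Data frame with columns `branch`, `column`, `site`, `anc`,
#'   `der`, `pp_anc`, `pp_der` (tip states have posterior 1).
#' @export
extract_substitutions <- function(calls, aln, tree, exclude_sites = 810:840) {
  n_tip <- ape::Ntip(tree)
  n_node <- n_tip + tree$Nnode
  n_sites <- ncol(aln$seq)

  ## combined state matrix over all nodes: tips from alignment (non-residue
  ## characters are missing), internal nodes from the thresholded calls
  states <- matrix(NA_character_, n_node, n_sites)
  pps <- matrix(NA_real_, n_node, n_sites)
  for (i in seq_len(n_tip)) {
    row <- aln$seq[tree$tip.label[i], ]
    row[!row %in% AA_STATES] <- NA
    states[i, ] <- row
    pps[i, ] <- 1
  }
  ids <- as.integer(rownames(calls$states))
  states[ids, ] <- calls$states
  pps[ids, ] <- calls$pp

  keep_col <- !(aln$site_labels %in% exclude_sites)
  out <- list()
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1]; chi <- tree$edge[e, 2]
    a <- states[par, ]; d <- states[chi, ]
    hit <- which(!is.na(a) & !is.na(d) & a != d & keep_col)
    if (length(hit)) {
      out[[length(out) + 1L]] <- data.frame(
        branch = chi, column = hit, site = aln$site_labels[hit],
        anc = a[hit], der = d[hit],
        pp_anc = pps[par, hit], pp_der = pps[chi, hit])
    }
  }
  if (!length(out)) {
    return(data.frame(branch = integer(), column = integer(),
                      site = integer(), anc = character(), der = character(),
                      pp_anc = numeric(), pp_der = numeric()))
  }
  do.call(rbind, out)
}

#' Comparable branch pairs
#'
#' All unordered pairs of branches except sister branches (same parent)
#' and ancestor-descendant pairs (one branch lies on the path from the
#' other to the root).
#'
#' @param tree A rooted `phylo`.
#' @return Two-column integer matrix of branch (child node) id pairs.
#' @export
comparable_pairs <- function(tree) {
  branches <- tree$edge[, 2]
  parent <- integer(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  rt <- root_node(tree)
  anc_set <- lapply(seq_len(max(tree$edge)), function(v) {
    out <- integer(0)
    while (v != rt) { v <- parent[v]; out <- c(out, v) }
    out
  })
  pairs <- t(combn(sort(branches), 2))
  keep <- vapply(seq_len(nrow(pairs)), function(i) {
    b1 <- pairs[i, 1]; b2 <- pairs[i, 2]
    if (parent[b1] == parent[b2]) return(FALSE)          # sisters
    !(b1 %in% anc_set[[b2]] || b2 %in% anc_set[[b1]])    # ancestor-descendant
  }, logical(1))
  pairs[keep, , drop = FALSE]
}

#' Convergence/divergence classification for one branch pair
#'
#' For every site substituted on both branches: substitutions to the same
#' derived amino acid count as a convergence; substitutions away from a
#' common ancestral amino acid to different derived states count as a
#' divergence. Pairs with different ancestral and different derived states
#' fall in neither class. Note that convergence requires only a shared
#' derived state, not a shared starting state.
#'
#' @param ev1,ev2 Event tables (rows of [extract_substitutions()]) for the
#'   two branches.
#' @return Integer vector `c(C = ..., D = ...)`.
#' @export
classify_pair <- function(ev1, ev2) {
  shared <- intersect(ev1$site, ev2$site)
  C <- 0L; D <- 0L
  for (s in shared) {
    e1 <- ev1[ev1$site == s, ][1, ]
    e2 <- ev2[ev2$site == s, ][1, ]
    if (e1$der == e2$der) C <- C + 1L
    else if (e1$anc == e2$anc) D <- D + 1L
  }
  c(C = C, D = D)
}

#' The (C+1)/(D+1) convergence statistic
#'
#' @param C,D Non-negative convergence and divergence counts.
#' @return `(C + 1) / (D + 1)`.
#' @export
cd_ratio <- function(C, D) {
  stop_if_not(all(C >= 0) && all(D >= 0), "counts must be non-negative")
  (C + 1) / (D + 1)
}

#' Distance between two branches
#'
#' Sum of branch lengths on the path connecting the child nodes of the two
#' branches, excluding the two focal branch lengths themselves (the "sum
#' of internal branch lengths between two proteins").
#'
#' @param tree A `phylo`.
#' @param b1,b2 Branch (child node) ids forming a comparable pair.
#' @param node_dist Optional precomputed `ape::dist.nodes(tree)` matrix.
#' @return Distance in substitutions/site.
#' @export
pair_distance <- function(tree, b1, b2, node_dist = NULL) {
  parent <- integer(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  is_anc <- function(a, d) {
    rt <- root_node(tree)
    while (d != rt) { d <- parent[d]; if (d == a) return(TRUE) }
    FALSE
  }
  if (is_anc(b1, b2) || is_anc(b2, b1)) {
    stop("ancestor-descendant pair: not a comparable pair")
  }
  if (is.null(node_dist)) node_dist <- ape::dist.nodes(tree)
  bl <- tree$edge.length[match(c(b1, b2), tree$edge[, 2])]
  node_dist[b1, b2] - sum(bl)
}

#' Branch-pair convergence table
#'
#' Enumerates all comparable branch pairs, classifies shared substitution
#' sites, and attaches the pair distance and (C+1)/(D+1) ratio.
#'
#' @param events Event table from [extract_substitutions()].
#' @param tree The tree.
#' @param sites Optional site labels to restrict the classification to
#'   (e.g. `c(111, 122)`); default uses all sites in `events`.
#' @return Data frame `b1, b2, C, D, distance, ratio`.
#' @export
branch_pair_table <- function(events, tree, sites = NULL) {
  if (!is.null(sites)) events <- events[events$site %in% sites, , drop = FALSE]
  pairs <- comparable_pairs(tree)
  nd <- ape::dist.nodes(tree)
  bl <- setNames(tree$edge.length, tree$edge[, 2])
  ev_by_branch <- split(events, events$branch)
  res <- data.frame(b1 = pairs[, 1], b2 = pairs[, 2], C = 0L, D = 0L,
                    distance = NA_real_)
  for (i in seq_len(nrow(pairs))) {
    b1 <- pairs[i, 1]; b2 <- pairs[i, 2]
    e1 <- ev_by_branch[[as.character(b1)]]
    e2 <- ev_by_branch[[as.character(b2)]]
    if (!is.null(e1) && !is.null(e2)) {
      cd <- classify_pair(e1, e2)
      res$C[i] <- cd["C"]; res$D[i] <- cd["D"]
    }
    res$distance[i] <- nd[b1, b2] - bl[as.character(b1)] - bl[as.character(b2)]
  }
  res$ratio <- cd_ratio(res$C, res$D)
  res
}

#' Running average of the convergence ratio along the distance axis
#'
#' Windowed mean of the (C+1)/(D+1) ratio with percentile bootstrap
#' confidence intervals from resampling the pairs within each window.
#'
#' @param pairs Data frame from [branch_pair_table()].
#' @param window Window width on the distance axis (0.05
#'   substitutions/site in the convergence analyses).
#' @param step Distance between successive window centres.
#' @param n_boot Number of bootstrap resamples per window (100 by
#'   default).
#' @param seed Optional integer seed for reproducible bootstrap bands.
#' @param level Confidence level for the percentile interval.
#' @return Data frame `distance, mean, lo, hi, n`; windows with no pairs
#'   are omitted.
#' @export
running_trend <- function(pairs, window = 0.05, step = 0.01, n_boot = 100,
                          seed = NULL, level = 0.95) {
  if (!is.null(seed)) set.seed(seed)
  d <- pairs$distance; r <- pairs$ratio
  centers <- seq(min(d), max(d), by = step)
  a <- (1 - level) / 2
  rows <- lapply(centers, function(ct) {
    inw <- which(abs(d - ct) <= window / 2)
    if (!length(inw)) return(NULL)
    x <- r[inw]
    bm <- vapply(seq_len(n_boot), function(i) {
      mean(x[sample.int(length(x), replace = TRUE)])
    }, numeric(1))
    data.frame(distance = ct, mean = mean(x),
               lo = unname(quantile(bm, a)), hi = unname(quantile(bm, 1 - a)),
               n = length(inw))
  })
  do.call(rbind, rows)
}

#' Logistic regression of convergence outcome on branch-pair distance
#'
#' Events are coded 1 for convergence and 0 for divergence; the slope is
#' the log-odds change per unit distance, with a Wald p-value. Complete
#' separation (or non-convergence) is flagged and the p-value marked
#' unreliable.
#'
#' @param outcome 0/1 vector (1 = convergent event).
#' @param distance Pair distance for each event.
#' @return List with `slope`, `p_value`, `intercept`, `flagged`, `fit`.
#' @export
convergence_distance_regression <- function(outcome, distance) {
  stop_if_not(length(unique(outcome)) == 2,
              "both outcome classes must be present")
  fit <- suppressWarnings(glm(outcome ~ distance, family = binomial()))
  co <- summary(fit)$coefficients
  flagged <- !fit$converged || any(abs(co[, "Estimate"]) > 15)
  list(slope = co["distance", "Estimate"],
       p_value = co["distance", "Pr(>|z|)"],
       intercept = co["(Intercept)", "Estimate"],
       flagged = flagged, fit = fit)
}
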