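#' Percent effect of a substitution on activity
#'
#' `E = (mutant - wildtype) / wildtype * 100`, the percent change in
#' protein activity relative to the wild-type enzyme of the same
#' background.
#'
#' @param wt,mut Wild-type and mutant activity (wild-type must be > 0).
#' @return Percent change.
#' @export
substitution_effect <- function(wt, mut) {
  if (any(wt <= 0)) stop("wild-type activity must be positive; construct excluded")
  (mut - wt) / wt * 100
}

#' Enumerate same-state cross-background comparisons
#'
#' Finds every unordered pair of backgrounds on which the same derived
#' amino acid state was introduced at the same focal site, and computes
#' the two effects `E` and their absolute difference `delta`. Reverse
#' substitutions contribute the effect of their introduced (final)
#' state, so a construct panel row is identified by (background, site,
#' to-state).
#'
#' @param panel Data frame with one row per construct: columns
#'   `background`, `site` (focal site, `NA` for wild type), `to`
#'   (introduced state, `NA` for wild type) and `activity` (mean across
#'   replicates).
#' @return Data frame `site, state, bg1, bg2, E1, E2, delta`.
#' @export
enumerate_comparisons <- function(panel) {
  wt <- panel[is.na(panel$to), , drop = FALSE]
  stop_if_not(!anyDuplicated(wt$background), "one wild-type row per background")
  wt_act <- setNames(wt$activity, wt$background)
  mut <- panel[!is.na(panel$to), , drop = FALSE]
  out <- list()
  for (key in unique(paste(mut$site, mut$to))) {
    rows <- mut[paste(mut$site, mut$to) == key, , drop = FALSE]
    rows <- rows[!duplicated(rows$background), , drop = FALSE]
    if (nrow(rows) < 2) next
    idx <- t(combn(nrow(rows), 2))
    for (i in seq_len(nrow(idx))) {
      r1 <- rows[idx[i, 1], ]; r2 <- rows[idx[i, 2], ]
      E1 <- substitution_effect(wt_act[[r1$background]], r1$activity)
      E2 <- substitution_effect(wt_act[[r2$background]], r2$activity)
      out[[length(out) + 1L]] <- data.frame(
        site = r1$site, state = r1$to, bg1 = r1$background,
        bg2 = r2$background, E1 = E1, E2 = E2, delta = abs(E1 - E2))
    }
  }
  if (!length(out)) {
    return(data.frame(site = integer(), state = character(), bg1 = character(),
                      bg2 = character(), E1 = numeric(), E2 = numeric(),
                      delta = numeric()))
  }
  do.call(rbind, out)
}

#' Variant sites among a set of backgrounds
#'
#' Site labels whose column holds more than one distinct state among the
#' given sequences (a gap counts as a state of its own).
#'
#' @param aln An [nka_alignment()].
#' @param ids Sequence ids (default: all).
#' @return Integer vector of variant site labels.
#' @export
variant_sites <- function(aln, ids = aln$ids) {
  cols <- which(!is.na(aln$site_labels))
  v <- vapply(cols, function(j) length(unique(aln$seq[ids, j])) > 1, logical(1))
  aln$site_labels[cols[v]]
}

#' Binary divergence vector for a background pair
#'
#' For each variant site, 1 if the two wild-type sequences differ (gap vs
#' residue counts as different), 0 if identical.
#'
#' @param aln An [nka_alignment()].
#' @param bg1,bg2 Sequence ids of the two backgrounds.
#' @param sites Variant site labels (from [variant_sites()] on the panel).
#' @return Named 0/1 integer vector over `sites`.
#' @export
binarize_divergence <- function(aln, bg1, bg2, sites) {
  cols <- site_column(aln, sites)
  setNames(as.integer(aln$seq[bg1, cols] != aln$seq[bg2, cols]), sites)
}

#' Divergence matrix for a set of comparisons
#'
#' @param aln An [nka_alignment()].
#' @param comparisons Data frame from [enumerate_comparisons()].
#' @param sites Variant site labels.
#' @return Integer matrix (comparisons x sites).
#' @export
divergence_matrix <- function(aln, comparisons, sites) {
  m <- t(vapply(seq_len(nrow(comparisons)), function(i) {
    binarize_divergence(aln, comparisons$bg1[i], comparisons$bg2[i], sites)
  }, integer(length(sites))))
  colnames(m) <- sites
  m
}

#' Group correlated sites by divergence profile
#'
#' Connected components of the graph joining site columns whose pairwise
#' Pearson |r| exceeds the threshold; at high thresholds this recovers
#' the classes of sites that partition the pairwise divergences
#' identically. Zero-variance columns (sites divergent in every or no
#' comparison) each form their own group. The representative is the
#' lowest site label in the group.
#'
#' @param div Matrix from [divergence_matrix()] (comparisons x sites).
#' @param r_threshold Absolute-correlation threshold (0.8 in the main
#'   analysis, 0.99 in the robustness analysis).
#' @return List of `site_group` lists: `sites`, `representative`.
#' @export
group_sites <- function(div, r_threshold = 0.8) {
  stop_if_not(nrow(div) >= 2, "need >= 2 comparisons")
  ns <- ncol(div)
  vr <- apply(div, 2, var)
  adj <- matrix(FALSE, ns, ns)
  pos <- which(vr > 0)
  if (length(pos) > 1) {
    cc <- suppressWarnings(cor(div[, pos, drop = FALSE]))
    adj[pos, pos] <- abs(cc) > r_threshold
  }
  diag(adj) <- TRUE
  ## connected components by BFS
  comp <- rep(NA_integer_, ns)
  cid <- 0L
  for (i in seq_len(ns)) {
    if (!is.na(comp[i])) next
    cid <- cid + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      nb <- which(adj[v, ] & is.na(comp))
      queue <- c(queue, nb)
    }
  }
  labels <- as.integer(colnames(div))
  lapply(split(seq_len(ns), comp), function(ix) {
    list(sites = labels[ix], representative = min(labels[ix]))
  })
}

## marginal R^2 of delta ~ covariate + group representative indicator
marginal_r2 <- function(delta, rep_col, covariate) {
  tss <- sum((delta - mean(delta))^2)
  if (tss == 0) return(0)          # constant response explains nothing
  X <- cbind(1, covariate, rep_col)
  fit <- lm.fit(X, delta)
  1 - sum(fit$residuals^2) / tss
}

## R^2 of delta ~ covariate + chosen representative columns
model_r2 <- function(delta, rep_cols, covariate) {
  tss <- sum((delta - mean(delta))^2)
  if (tss == 0) return(0)
  X <- cbind(1, covariate, rep_cols)
  qr_ <- qr(X)
  res <- qr.resid(qr_, delta)
  1 - sum(res^2) / tss
}

#' Nested ANOVA selection of site groups explaining effect differences
#'
#' Orders the site groups by the marginal variance in `delta` (the
#' absolute difference of same-state substitution effects across
#' backgrounds) explained by each group's representative divergence
#' indicator, with the mutated site (111 vs 122) as a covariate in every
#' model; then fits forward-nested linear models adding one group at a
#' time and selects the best model by AIC or by LRT (adding groups while
#' the addition is significant at 0.05). Nesting stops before the model
#' saturates.
#'
#' @param delta Per-comparison effect differences.
#' @param div Divergence matrix (comparisons x sites).
#' @param covariate Mutated-site covariate per comparison (e.g. factor
#'   111/122).
#' @param groups Optional precomputed [group_sites()] result.
#' @param r_threshold Grouping threshold when `groups` is NULL.
#' @param criterion `"AIC"` or `"LRT"`.
#' @return Object of class `epistasis_scan`: `table` (model, n_sites,
#'   R2, AIC, p_LRT), `best` (selected model index; 0 = covariate-only),
#'   `selected_sites`, `groups` (ordered), plus inputs.
#' @export
nested_anova_select <- function(delta, div, covariate, groups = NULL,
                                r_threshold = 0.8, criterion = c("AIC", "LRT")) {
  criterion <- match.arg(criterion)
  if (is.null(groups)) groups <- group_sites(div, r_threshold)
  cov_num <- model_covariate(covariate)
  reps <- vapply(groups, function(g) g$representative, numeric(1))
  rep_cols <- div[, as.character(reps), drop = FALSE]
  ord <- order(-vapply(seq_along(groups), function(i) {
    marginal_r2(delta, rep_cols[, i], cov_num)
  }, numeric(1)))
  groups <- groups[ord]
  rep_cols <- rep_cols[, ord, drop = FALSE]

  n <- length(delta)
  max_groups <- min(length(groups), n - 3L)  # keep residual df >= 1
  r2_of <- function(fit) {
    tss <- sum((delta - mean(delta))^2)
    if (tss == 0) 0 else 1 - sum(resid(fit)^2) / tss
  }
  fits <- vector("list", max_groups + 1)
  fits[[1]] <- lm(delta ~ cov_num)
  tab <- data.frame(model = 0L, n_sites = 0L, R2 = r2_of(fits[[1]]),
                    AIC = AIC(fits[[1]]), p_LRT = NA_real_)
  for (k in seq_len(max_groups)) {
    X <- rep_cols[, seq_len(k), drop = FALSE]
    fits[[k + 1]] <- lm(delta ~ cov_num + X)
    a <- anova(fits[[k]], fits[[k + 1]])
    tab <- rbind(tab, data.frame(
      model = k,
      n_sites = sum(vapply(groups[seq_len(k)], function(g) length(g$sites), numeric(1))),
      R2 = r2_of(fits[[k + 1]]),
      AIC = AIC(fits[[k + 1]]),
      p_LRT = a$`Pr(>F)`[2]))
  }
  best <- if (criterion == "AIC") {
    tab$model[which.min(tab$AIC)]
  } else {
    k <- 0L
    while (k < max_groups && !is.na(tab$p_LRT[k + 2]) && tab$p_LRT[k + 2] < 0.05) k <- k + 1L
    k
  }
  selected_sites <- if (best >= 1) {
    sort(unlist(lapply(groups[seq_len(best)], function(g) g$sites)))
  } else integer(0)
  structure(list(table = tab, best = best, selected_sites = selected_sites,
                 groups = groups, criterion = criterion,
                 saturated = max_groups < length(groups)),
            class = "epistasis_scan")
}

#' @export
print.epistasis_scan <- function(x, ...) {
  cat(sprintf("Nested group selection (%s): best model uses %d group(s), %d site(s), R2 = %.3f\n",
              x$criterion, x$best, length(x$selected_sites),
              x$table$R2[x$table$model == x$best]))
  print(x$table, row.names = FALSE)
  invisible(x)
}

model_covariate <- function(covariate) {
  if (is.numeric(covariate)) as.numeric(factor(covariate)) else as.numeric(factor(covariate))
}

## full ascertainment for one delta vector: rank groups by marginal R^2,
## return R^2 of the model with the best n_best groups
ascertained_r2 <- function(delta, rep_cols, cov_num, n_best = 2) {
  mr2 <- vapply(seq_len(ncol(rep_cols)), function(i) {
    marginal_r2(delta, rep_cols[, i], cov_num)
  }, numeric(1))
  take <- order(-mr2)[seq_len(min(n_best, ncol(rep_cols)))]
  model_r2(delta, rep_cols[, take, drop = FALSE], cov_num)
}

#' Permutation null for the ascertained best-groups R-squared
#'
#' Permutes `delta` across comparisons and, for every permutation,
#' repeats the full ascertainment (re-ranking the groups by marginal
#' variance explained and taking the best `n_best`), yielding a null
#' distribution of R-squared values that accounts for the selection step.
#' The p-value uses the add-one rule and so is never 0.
#'
#' @inheritParams nested_anova_select
#' @param n_perm Number of permutations (the full analysis uses 10,000).
#' @param n_best Number of groups retained by the ascertainment (2).
#' @param seed Optional seed.
#' @return List `observed_r2, p_value, null_r2`.
#' @export
permutation_null <- function(delta, div, covariate, groups = NULL,
                             r_threshold = 0.8, n_perm = 10000, n_best = 2,
                             seed = NULL) {
  stop_if_not(n_perm >= 100, "n_perm must be >= 100")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(groups)) groups <- group_sites(div, r_threshold)
  cov_num <- model_covariate(covariate)
  reps <- vapply(groups, function(g) g$representative, numeric(1))
  rep_cols <- div[, as.character(reps), drop = FALSE]
  obs <- ascertained_r2(delta, rep_cols, cov_num, n_best)
  null <- vapply(seq_len(n_perm), function(i) {
    ascertained_r2(sample(delta), rep_cols, cov_num, n_best)
  }, numeric(1))
  list(observed_r2 = obs,
       p_value = (1 + sum(null >= obs - 1e-12)) / (1 + n_perm),
       null_r2 = null)
}

#' Correlation of effect differences with divergence at a site set
#'
#' Pearson correlation between `delta` and the number of differing sites
#' (within the given set) per comparison, with a permutation p-value
#' (permuting `delta`, add-one rule). With the full variant-site set this
#' reproduces the all-sites divergence analysis.
#'
#' @param delta Effect differences per comparison.
#' @param div Divergence matrix (comparisons x variant sites).
#' @param sites Site labels to count divergence over.
#' @param n_perm Permutations for the p-value.
#' @param seed Optional seed.
#' @return List `r, p_value, divergence_count`.
#' @export
divergence_effect_correlation <- function(delta, div, sites, n_perm = 10000,
                                          seed = NULL) {
  stop_if_not(length(sites) >= 1, "site set must be nonempty")
  cnt <- rowSums(div[, as.character(sites), drop = FALSE])
  if (var(cnt) == 0 || var(delta) == 0) {
    return(list(r = NA_real_, p_value = NA_real_, divergence_count = cnt))
  }
  r <- cor(delta, cnt)
  if (!is.null(seed)) set.seed(seed)
  null <- vapply(seq_len(n_perm), function(i) cor(sample(delta), cnt), numeric(1))
  list(r = r, p_value = (1 + sum(null >= r - 1e-12)) / (1 + n_perm),
       divergence_count = cnt)
}
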