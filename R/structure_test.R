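#' Median CA-distance permutation test for spatial clustering
#'
#' Tests whether a candidate site set (e.g. the top 5% of sites most
#' strongly co-evolving with a focal resistance site) lies closer to the
#' focal site in the structure than random site sets of the same size
#' drawn from the universe of variable sites. The statistic is the median
#' alpha-carbon distance from the focal site to the candidates; the
#' p-value is the proportion of random subsets whose median is less than
#' or equal to the observed one (ties counted, add-one rule).
#'
#' @param struct A [read_structure()] result.
#' @param focal Focal residue number (structure numbering).
#' @param candidates Candidate residue numbers.
#' @param universe Universe of variable residues the null samples from
#'   (must contain the candidates; the focal site is not sampled).
#' @param n_perm Number of random samples (1000 in the structural
#'   analysis).
#' @param seed Optional seed.
#' @param site_map Optional two-column data frame (`alignment_site`,
#'   `structure_residue`) translating alignment site labels to structure
#'   residue numbers before testing; unmappable sites are dropped with a
#'   warning.
#' @return Object of class `proximity_test` (also `htest`-like): `
#'   statistic` (observed median, angstroms), `p_value`, `n_perm`, sizes.
#' @export
median_distance_test <- function(struct, focal, candidates, universe,
                                 n_perm = 1000, seed = NULL, site_map = NULL) {
  if (!is.null(site_map)) {
    tr <- function(s) site_map$structure_residue[match(s, site_map$alignment_site)]
    focal <- tr(focal); candidates <- tr(candidates); universe <- tr(universe)
  }
  drop_unmapped <- function(x, what) {
    ok <- !is.na(x) & x %in% struct$resno
    if (any(!ok)) warning(sum(!ok), " unmappable ", what, " site(s) dropped")
    x[ok]
  }
  candidates <- drop_unmapped(candidates, "candidate")
  universe <- drop_unmapped(universe, "universe")
  if (!length(candidates) || !length(universe)) stop("no mappable sites left")
  stop_if_not(all(candidates %in% universe), "candidates must be a subset of the universe")
  universe <- setdiff(universe, focal)

  d_all <- setNames(ca_distance(struct, focal, universe), universe)
  obs <- median(d_all[as.character(candidates)])
  if (!is.null(seed)) set.seed(seed)
  m <- length(candidates)
  null <- vapply(seq_len(n_perm), function(i) {
    median(d_all[sample.int(length(d_all), m)])
  }, numeric(1))
  p <- (1 + sum(null <= obs + 1e-12)) / (1 + n_perm)
  structure(list(statistic = obs, p_value = p, n_perm = n_perm,
                 n_candidates = m, n_universe = length(universe),
                 null = null, focal = focal),
            class = "proximity_test")
}

#' @export
print.proximity_test <- function(x, ...) {
  cat(sprintf("Median CA-distance test: focal %s, %d candidates / %d universe\n",
              x$focal, x$n_candidates, x$n_universe))
  cat(sprintf("  observed median = %.2f A, permutation p = %.4g (%d samples)\n",
              x$statistic, x$p_value, x$n_perm))
  invisible(x)
}

#' Hypergeometric overlap (enrichment) test
#'
#' Upper-tail probability that two site sets drawn from a universe of
#' size `N` share at least the observed number of sites.
#'
#' @param A,B Site sets (vectors) or set sizes with `k` given.
#' @param N Universe size.
#' @param k Overlap size; computed as `length(intersect(A, B))` when the
#'   sets themselves are given.
#' @return Object of class `overlap_test`: `k, p_value, size_a, size_b,
#'   N`.
#' @export
overlap_test <- function(A, B, N, k = NULL) {
  if (is.null(k)) {
    k <- length(intersect(A, B))
    a <- length(unique(A)); b <- length(unique(B))
  } else {
    a <- A; b <- B
  }
  stop_if_not(a <= N && b <= N && k <= min(a, b), "inconsistent set sizes")
  p <- phyper(k - 1, a, N - a, b, lower.tail = FALSE)
  structure(list(k = k, p_value = p, size_a = a, size_b = b, N = N),
            class = "overlap_test")
}

#' @export
print.overlap_test <- function(x, ...) {
  cat(sprintf("Hypergeometric overlap: |A|=%d, |B|=%d, N=%d, overlap=%d, P(X>=k)=%.4g\n",
              x$size_a, x$size_b, x$N, x$k, x$p_value))
  invisible(x)
}
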