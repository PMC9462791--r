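#' Linear phosphate standard curve
#'
#' Fits absorbance = intercept + slope * mM Pi by least squares; the
#' inverse map converts background-corrected absorbances to phosphate
#' concentrations.
#'
#' @param conc_mM Standard phosphate concentrations (the assay uses 0 to
#'   1.2 mM).
#' @param absorbance Measured absorbances.
#' @return List `slope`, `intercept`, `to_mM` (function absorbance ->
#'   mM Pi on the background-corrected scale).
#' @export
standard_curve <- function(conc_mM, absorbance) {
  stop_if_not(length(conc_mM) >= 3, "standard curve needs >= 3 points")
  fit <- lm(absorbance ~ conc_mM)
  slope <- unname(coef(fit)[2]); intercept <- unname(coef(fit)[1])
  stop_if_not(slope > 0, "standard curve slope must be positive")
  list(slope = slope, intercept = intercept,
       to_mM = function(abs_corrected) abs_corrected / slope,
       fit = fit)
}

#' Normalize one construct-replicate of the ouabain assay
#'
#' Converts raw well absorbances to (a) percent non-inhibited activity per
#' ouabain concentration, using the no-ouabain control and the
#' background-inhibition control, and (b) a baseline activity measure in
#' nmol Pi per mg protein per minute, via the phosphate standard curve.
#' Technical duplicates at the same concentration are averaged before any
#' statistics.
#'
#' @param wells Data frame with columns `well_type`
#'   (`ouabain`/`control`/`background`), `conc_M` and `absorbance` (one
#'   construct, one biological replicate).
#' @param curve A [standard_curve()].
#' @param protein_mg Protein amount per well in mg (0.1 mg = 100 ug).
#' @param time_min Incubation time in minutes (20).
#' @param volume_ml Nominal reaction volume used to convert mM to nmol
#'   (1 mL by default, i.e. mM is read as umol per well volume).
#' @return List with `percent` (data frame `conc_M, log10_conc,
#'   percent`), `activity` (nmol Pi/mg/min) and `pi_mM` at the control.
#' @export
normalize_assay <- function(wells, curve, protein_mg = 0.1, time_min = 20,
                            volume_ml = 1) {
  bg <- mean(wells$absorbance[wells$well_type == "background"])
  ctl <- mean(wells$absorbance[wells$well_type == "control"])
  stop_if_not(is.finite(bg) && is.finite(ctl), "control/background wells required")
  if (ctl <= bg) stop("control does not exceed background: inactive enzyme")
  dose <- wells[wells$well_type == "ouabain", , drop = FALSE]
  agg <- aggregate(absorbance ~ conc_M, data = dose, FUN = mean)
  agg <- agg[order(-agg$conc_M), ]
  percent <- 100 * (agg$absorbance - bg) / (ctl - bg)
  pi_mM <- curve$to_mM(ctl - bg)
  ## mM * volume -> umol; *1000 -> nmol; per mg protein per minute
  activity <- pi_mM * volume_ml * 1000 / (protein_mg * time_min)
  list(percent = data.frame(conc_M = agg$conc_M,
                            log10_conc = log10(agg$conc_M),
                            percent = percent),
       activity = activity, pi_mM = pi_mM)
}

#' Fixed-asymptote four-parameter logistic IC50 fit
#'
#' Least-squares fit of `y = 100 / (1 + 10^(s * (x - m)))` to percent
#' activity `y` against log10 molar ouabain concentration `x`, i.e. a 4PL
#' curve with the top asymptote fixed at 100 and the bottom at 0; `m` is
#' the log10 IC50 and `s` the (positive) Hill slope. Fitting uses
#' Levenberg-Marquardt least squares (\pkg{minpack.lm}) multi-started
#' over slopes 0.5, 1 and 2. A fit is censored (IC50 not measurable,
#' recorded as `NA`) when the response never falls to half-inhibition
#' within the tested range: the mean response at the highest
#' concentration exceeds 40%, the fitted IC50 lies at or above the
#' highest tested concentration, or the fit fails.
#'
#' @param log10_conc Log10 molar concentrations.
#' @param percent Percent non-inhibited activity.
#' @param slope_starts Multi-start values for the slope.
#' @return Object of class `ic50_fit`: `log10_ic50`, `slope`, `rss`,
#'   `censored`, `n`.
#' @export
fit_ic50 <- function(log10_conc, percent, slope_starts = c(0.5, 1, 2)) {
  stop_if_not(length(unique(log10_conc)) >= 4, "need >= 4 concentrations")
  x <- log10_conc; y <- percent
  xmax <- max(x)
  top_resp <- mean(y[x == xmax])
  best <- NULL
  for (s0 in slope_starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ 100 / (1 + 10^(s * (x - m))),
                        start = list(m = mean(x), s = s0),
                        lower = c(m = min(x) - 6, s = 1e-3),
                        upper = c(m = max(x) + 6, s = 50),
                        control = minpack.lm::nls.lm.control(maxiter = 200,
                                                             ftol = 1e-10)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(resid(fit)^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(m = coef(fit)["m"], s = coef(fit)["s"], rss = rss)
    }
  }
  censored <- is.null(best) || top_resp > 40 || best$m >= xmax
  structure(list(log10_ic50 = if (censored) NA_real_ else unname(best$m),
                 slope = if (is.null(best)) NA_real_ else unname(best$s),
                 rss = if (is.null(best)) NA_real_ else best$rss,
                 censored = censored, n = length(y)),
            class = "ic50_fit")
}

#' @export
print.ic50_fit <- function(x, ...) {
  if (x$censored) cat("IC50 fit: censored (no measurable IC50 in tested range)\n")
  else cat(sprintf("IC50 fit: log10 IC50 = %.4f, slope = %.3f, RSS = %.3g\n",
                   x$log10_ic50, x$slope, x$rss))
  invisible(x)
}

#' @export
coef.ic50_fit <- function(object, ...) {
  c(log10_ic50 = object$log10_ic50, slope = object$slope)
}

#' @export
predict.ic50_fit <- function(object, newdata = NULL, ...) {
  stop_if_not(!object$censored, "censored fit has no curve")
  x <- if (is.null(newdata)) seq(-8, -3, length.out = 50) else newdata
  100 / (1 + 10^(object$slope * (x - object$log10_ic50)))
}

#' Replicate-level IC50 summary for one construct
#'
#' Fits each biological replicate separately and reports the mean and
#' standard error of log10 IC50 across replicates (censored replicates
#' are reported but excluded from the mean).
#'
#' @param df Data frame with columns `replicate`, `log10_conc`,
#'   `percent`.
#' @return List with `fits` (per replicate), `mean`, `se`, `n_censored`.
#' @export
ic50_by_replicate <- function(df) {
  fits <- lapply(split(df, df$replicate), function(d) {
    fit_ic50(d$log10_conc, d$percent)
  })
  vals <- vapply(fits, function(f) f$log10_ic50, numeric(1))
  ok <- !is.na(vals)
  list(fits = fits,
       mean = if (any(ok)) mean(vals[ok]) else NA_real_,
       se = if (sum(ok) > 1) sd(vals[ok]) / sqrt(sum(ok)) else NA_real_,
       n_censored = sum(!ok))
}

#' Paired t-tests with Bonferroni correction
#'
#' Two-sided paired t-test of mutant against wild-type replicate values,
#' with the Bonferroni multiplier for the family of substitutions tested
#' (15 in the construct panel). Zero-variance differences are guarded:
#' all-zero differences give p = 1; identical nonzero differences give
#' p = 0 with `infinite_t = TRUE`.
#'
#' @param wt,mut Equal-length replicate vectors, paired by replicate id.
#' @param n_tests Bonferroni family size.
#' @return List `p_value, p_adjusted, t, estimate, infinite_t`.
#' @export
paired_t_bonferroni <- function(wt, mut, n_tests = 15) {
  stop_if_not(length(wt) == length(mut) && length(wt) >= 2,
              "need >= 2 paired replicates")
  d <- mut - wt
  if (sd(d) == 0) {
    p <- if (all(d == 0)) 1 else 0
    return(list(p_value = p, p_adjusted = min(1, p * n_tests),
                t = if (all(d == 0)) 0 else Inf * sign(d[1]),
                estimate = mean(d), infinite_t = !all(d == 0)))
  }
  tt <- t.test(mut, wt, paired = TRUE)
  list(p_value = tt$p.value, p_adjusted = min(1, tt$p.value * n_tests),
       t = unname(tt$statistic), estimate = unname(tt$estimate),
       infinite_t = FALSE)
}

#' Two-way ANOVA for background dependence of a substitution
#'
#' Tests the background x state interaction: whether introducing the same
#' amino acid state changes the response (log10 IC50 or activity)
#' differently on different wild-type backgrounds. Reverse substitutions
#' are handled by coding each construct by the state it carries at the
#' focal site (presence/absence of the derived state), which aligns the
#' sign of a reverse substitution with the forward direction.
#'
#' @param response Numeric response per construct-replicate.
#' @param background Factor of background ids.
#' @param state Factor/logical: whether the construct carries the derived
#'   state at the focal site.
#' @param n_tests Bonferroni family size (5 informative cases in the
#'   panel).
#' @return List `p_interaction, p_adjusted, table` (the ANOVA table).
#' @export
epistasis_anova <- function(response, background, state, n_tests = 5) {
  background <- factor(background); state <- factor(state)
  stop_if_not(nlevels(background) >= 2 && nlevels(state) == 2,
              "need >= 2 backgrounds and exactly 2 states")
  counts <- table(background, state)
  if (any(counts == 0)) stop("empty design cell")
  fit <- aov(response ~ background * state)
  tab <- summary(fit)[[1]]
  row <- grep("background:state", rownames(tab))
  p <- tab[row, "Pr(>F)"]
  list(p_interaction = p, p_adjusted = min(1, p * n_tests), table = tab)
}

#' Exact binomial test of substitution effect direction
#'
#' Two-sided exact binomial test (2 x the smaller tail probability,
#' capped at 1) at success probability 1/2 for counts of
#' activity-decreasing vs activity-increasing substitutions.
#'
#' @param n_decrease,n_increase Non-negative counts.
#' @return List `p_value, n_decrease, n_increase`.
#' @export
direction_binomial <- function(n_decrease, n_increase) {
  n <- n_decrease + n_increase
  stop_if_not(n >= 1, "need at least one observation")
  k <- n_decrease
  lower <- pbinom(k, n, 0.5)
  upper <- pbinom(k - 1, n, 0.5, lower.tail = FALSE)
  p <- min(1, 2 * min(lower, upper))
  list(p_value = p, n_decrease = n_decrease, n_increase = n_increase)
}

#' Chi-squared test of p-value uniformity
#'
#' Goodness-of-fit of a set of p-values to the uniform distribution using
#' equal-width bins on the unit interval.
#'
#' @param p P-values.
#' @param n_bins Number of bins (5 for the 15-substitution panel, giving
#'   expected count 3 per bin).
#' @return List `statistic, df, p_value, counts`.
#' @export
pvalue_uniformity <- function(p, n_bins = 5) {
  stop_if_not(length(p) >= 5, "need >= 5 p-values")
  stop_if_not(all(p >= 0 & p <= 1), "p-values must lie in [0, 1]")
  breaks <- seq(0, 1, length.out = n_bins + 1)
  counts <- as.numeric(table(cut(p, breaks, include.lowest = TRUE)))
  expected <- length(p) / n_bins
  stat <- sum((counts - expected)^2 / expected)
  list(statistic = stat, df = n_bins - 1,
       p_value = pchisq(stat, n_bins - 1, lower.tail = FALSE),
       counts = counts)
}

#' Spearman correlation of derived-state count with CTS resistance
#'
#' Rank correlation (midranks for ties) between the number of derived
#' states at the key resistance sites (0, 1 or 2 at positions 111 and
#' 122) and log10 IC50 across wild-type enzymes, optionally with a
#' permutation p-value for small panels.
#'
#' @param n_derived Integer vector of derived-state counts.
#' @param log10_ic50 Matching resistance values.
#' @param n_perm If > 0, number of permutations for the p-value
#'   (two-sided, add-one rule); otherwise the asymptotic \code{cor.test}
#'   p-value is used.
#' @param seed Optional permutation seed.
#' @return List `rho, p_value, method`.
#' @export
derived_state_resistance_correlation <- function(n_derived, log10_ic50,
                                                 n_perm = 0, seed = NULL) {
  stop_if_not(length(n_derived) >= 4, "need >= 4 enzymes")
  if (var(n_derived) == 0 || var(log10_ic50) == 0) {
    return(list(rho = NA_real_, p_value = NA_real_, method = "undefined (zero variance)"))
  }
  rho <- cor(n_derived, log10_ic50, method = "spearman")
  if (n_perm > 0) {
    if (!is.null(seed)) set.seed(seed)
    null <- vapply(seq_len(n_perm), function(i) {
      cor(n_derived, sample(log10_ic50), method = "spearman")
    }, numeric(1))
    p <- (1 + sum(abs(null) >= abs(rho) - 1e-12)) / (1 + n_perm)
    method <- "spearman (permutation)"
  } else {
    p <- suppressWarnings(cor.test(n_derived, log10_ic50, method = "spearman"))$p.value
    method <- "spearman (asymptotic)"
  }
  list(rho = rho, p_value = p, method = method)
}
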