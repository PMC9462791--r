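#' Amino-acid substitution model with gamma rate heterogeneity
#'
#' Builds a 20-state continuous-time Markov model from an empirical
#' exchangeability matrix (JTT by default, taken from \pkg{phangorn}),
#' equilibrium frequencies (model frequencies, or empirical "+F"
#' frequencies supplied by the caller), and a discrete-gamma rate mixture.
#' The generator is normalized so the expected substitution rate at
#' equilibrium is 1, i.e. branch lengths are in expected substitutions per
#' site.
#'
#' @param model Name of the exchangeability set; one of `"JTT"`, `"LG"`,
#'   `"WAG"`.
#' @param freqs Equilibrium frequencies in the standard PAML amino-acid
#'   order (ARNDCQEGHILKMFPSTWYV). `NULL` uses the model's own
#'   frequencies; pass empirical frequencies for a "+F" model.
#' @param gamma_shape Shape of the gamma distribution of among-site rate
#'   variation (mean fixed at 1). `Inf` or `n_cat = 1` gives a single rate.
#' @param n_cat Number of discrete gamma categories (4 for the usual "G4").
#' @return An object of class `rate_model`: exchangeabilities `S`,
#'   frequencies `freqs`, normalized generator `Q`, category `rates` and
#'   `weights`, and the shape.
#' @examples
#' m <- rate_model("JTT", gamma_shape = 0.5)
#' rowSums(m$Q)            # ~0: proper generator
#' sum(m$rates * m$weights) # 1: mean relative rate
#' @export
rate_model <- function(model = "JTT", freqs = NULL, gamma_shape = 1, n_cat = 4) {
  ex <- empirical_exchangeabilities(model)
  S <- ex$S
  if (is.null(freqs)) freqs <- ex$freqs
  stop_if_not(length(freqs) == 20 && all(freqs >= 0),
              "freqs must be 20 non-negative values")
  freqs <- freqs / sum(freqs)
  Q <- S %*% diag(freqs)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  scale <- -sum(freqs * diag(Q))
  Q <- Q / scale
  dimnames(Q) <- list(AA_STATES, AA_STATES)
  if (n_cat == 1 || is.infinite(gamma_shape)) {
    rates <- 1
    weights <- 1
    if (n_cat == 1 && !is.infinite(gamma_shape) && gamma_shape != 1) {
      warning("single rate category requested; gamma shape ignored")
    }
  } else {
    rates <- discrete_gamma_rates(gamma_shape, n_cat)
    weights <- rep(1 / n_cat, n_cat)
  }
  structure(list(name = model, S = S, freqs = setNames(freqs, AA_STATES),
                 Q = Q, gamma_shape = gamma_shape, n_cat = length(rates),
                 rates = rates, weights = weights),
            class = "rate_model")
}

#' @export
print.rate_model <- function(x, ...) {
  cat(sprintf("Amino-acid rate model: %s%s\n", x$name,
              if (x$n_cat > 1) sprintf(" + G%d (shape %.4g)", x$n_cat, x$gamma_shape) else ""))
  cat(sprintf("  category rates: %s\n", paste(signif(x$rates, 4), collapse = ", ")))
  invisible(x)
}

## Exchangeabilities from phangorn's shipped empirical models. phangorn
## stores the lower triangle column-major plus the model frequencies.
empirical_exchangeabilities <- function(model = c("JTT", "LG", "WAG")) {
  model <- match.arg(model)
  obj <- get(paste0(".", model), envir = asNamespace("phangorn"))
  S <- matrix(0, 20, 20, dimnames = list(AA_STATES, AA_STATES))
  S[lower.tri(S)] <- obj$Q
  S <- S + t(S)
  list(S = S, freqs = setNames(as.numeric(obj$bf), AA_STATES))
}

#' Discrete-gamma relative rates (equal-probability categories)
#'
#' Mean rate of each of `k` equal-probability bins of a Gamma(shape, shape)
#' distribution (mean 1). The category means average exactly to 1.
#'
#' @param shape Gamma shape parameter (> 0).
#' @param k Number of categories.
#' @return Numeric vector of `k` increasing relative rates.
#' @export
discrete_gamma_rates <- function(shape, k) {
  stop_if_not(shape > 0 && k >= 1, "shape must be > 0 and k >= 1")
  if (k == 1) return(1)
  b <- qgamma(seq(0, 1, length.out = k + 1), shape = shape, rate = shape)
  # E[X; X in bin] for mean-1 gamma: pgamma(b, shape+1, shape)
  inc <- pgamma(b, shape = shape + 1, rate = shape)
  k * diff(inc)
}
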