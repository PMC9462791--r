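---
title: "Methods: convergence and epistasis analyses for CTS-resistant Na,K-ATPases"
author: "nkaevol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: convergence and epistasis analyses for CTS-resistant Na,K-ATPases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nkaevol)
```

# Scope

Cardiotonic steroids (CTS) inhibit the Na,K-ATPase by binding its
alpha-subunit (ATP1A); resistance in CTS-adapted animals evolves
repeatedly through substitutions at a small set of sites, most
prominently 111 and 122 in the H1-H2 extracellular loop. `nkaevol`
implements the computational machinery for studying that system:

1. marginal ancestral sequence reconstruction (ASR) on a fixed phylogeny;
2. counting of convergent vs divergent substitutions across branch pairs,
   with the $(C+1)/(D+1)$ statistic, distance trends, and a logistic
   regression of convergence on divergence;
3. Pagel-type correlated-evolution tests for binary site states;
4. dose-response (IC50) and enzyme-activity statistics for engineered
   constructs;
5. localization of the background sites behind *epistatic*
   (background-dependent) substitution effects;
6. spatial clustering and set-overlap tests on a protein structure;
7. seeded synthetic-data generators with recorded ground truth for all of
   the above.

Every quantitative claim in this vignette is recomputed by the test suite
or by `scripts/acceptance.R`; nothing here reports a number the code does
not produce.

# Ancestral reconstruction

## Model

Sites evolve independently under a reversible 20-state continuous-time
Markov chain built from an empirical exchangeability matrix $S$ (JTT by
default, taken from **phangorn**) and equilibrium frequencies $\pi$
(model frequencies, or empirical "+F" frequencies): $Q_{ij} = S_{ij}
\pi_j$, normalized so branch lengths are expected substitutions per site.
Rate heterogeneity uses the discrete-gamma approximation with $k$
equal-probability categories (default $k = 4$, "G4"); category rates are
the within-bin means of a mean-one gamma, so they average exactly to 1.

## Algorithm

`marginal_asr()` runs the pruning algorithm (up-pass) and a down-pass
computing, for every internal node, the *marginal* posterior over the 20
states given all tip data, integrating over rate categories in log space.
The root prior is $\pi$, which matches the marginal-reconstruction
framework of standard ML ASR software. The per-category transition
matrices come from an eigendecomposition of $Q$ (with a matrix-exponential
fallback when the decomposition is ill-conditioned), and partial
likelihoods are rescaled per node and site, with cumulative log scalers
carried through both passes, so the implementation is stable on large
trees. The core loops are in C++ (Rcpp/RcppArmadillo), as in the R
phylogenetics packages this code follows.

Design choices worth stating:

* **Gaps and `X` are missing data** (uniform partial likelihoods), and a
  gap state is never reconstructed at an ancestor. How to treat
  alignment gaps at ancestors is genuinely open; treating them as missing
  is the conventional conservative choice and is applied consistently in
  substitution calling (a branch whose parent or child state is uncalled
  contributes no event at that site).
* **Ambiguity codes** (B, Z, J) expand to uniform partials over their
  possibility sets.
* **Thresholded calls**: `call_states()` reports a state only where its
  posterior probability strictly exceeds the threshold (default 0.8);
  everything else is missing. On data simulated from the model, more than
  80% of thresholded calls match the true simulated ancestral states
  (checked over >1000 node-site pairs), which is the calibration property
  the threshold is meant to buy.
* `fit_gamma_shape()` estimates the gamma shape by 1-D bounded
  optimization of the pruning likelihood with branch lengths fixed; a
  flat likelihood returns the upper search bound with a warning.

Correctness is anchored to an exhaustive-enumeration oracle: on 4-tip
trees the pruning posteriors and likelihoods equal brute-force sums over
all internal state assignments to $10^{-8}$.

# Convergence counting

Substitutions are called per branch as (parent state, child state) pairs
where both ends are called and differ; sites in the putative
alternatively-spliced region (reference positions 810-840) are excluded
by default. All branch pairs are compared except sister branches and
ancestor-descendant pairs. At a site substituted on both branches of a
pair: substitutions **to the same derived state** are convergences
(the ancestral states need not match — parallel and convergent changes
are counted together); substitutions **from the same ancestral state to
different derived states** are divergences. A pair with different
ancestral *and* different derived states is counted in neither class:
the two definitions above are the only ones given for the counting
scheme, and this third cell satisfies neither.

Each comparable pair contributes $(C+1)/(D+1)$. The distance between two
branches is the sum of branch lengths on the path connecting their child
nodes *excluding the two focal branch lengths* — i.e. the internal path
separating the two proteins. The trend of $(C+1)/(D+1)$ against distance
is a running average (window 0.05 substitutions/site; step 0.01, a
choice — only the window width is prescribed) with percentile bootstrap
bands from resampling pairs within each window (100 resamples).
`convergence_distance_regression()` codes convergences 1 and divergences
0 and fits a binomial GLM on distance; complete separation is flagged and
the Wald p-value marked unreliable.

Under our event model a branch carries at most one substitution per site
(one ancestral state, one derived state), so "multiple hits" within a
branch cannot occur by construction.

# Correlated evolution of binary site states

Extant states at a site are recoded 0/1 relative to the reconstructed
state of the clade's most recent common ancestor; gaps are missing.
Singleton sites and sites with more than 80% missing data are excluded
(exactly 80% is kept). Branch lengths are rescaled to a mean of 0.1
substitutions/site before fitting.

A pair of binary sites evolves as a compound 4-state chain with states
$(0,0), (0,1), (1,0), (1,1)$ and no simultaneous double transitions. Two
model families are fitted:

* **base**: independent null with 4 rates (each site's gain and loss
  rates do not depend on the other site) against a dependent alternative
  with all 8 rates free — LRT with df = 4;
* **restricted**: reversal rates to the ancestral state fixed at zero
  (sensible when the tree's branches are so short that double hits or
  reversals at a site are unlikely), giving a 4-rate dependent model, and
  an independent null that additionally ties the gain rate of each site
  across the other site's state ($q_{13} = q_{24}$, $q_{12} = q_{34}$) —
  LRT with df = 2.

The published description labels the 4-parameter no-reversal model the
"null independent model" and then derives the 2-parameter form; the
constraint counts and df = 2 only cohere if the 2-parameter model is the
null and the 4-parameter model the alternative, which is what we
implement.

Because the binary coding is anchored to the reconstructed ancestor, the
root's compound state is known to be $(0,0)$ by construction, so the root
prior puts mass 1 there by default (a uniform prior is available; with
the uniform prior our maximized likelihoods agree with
`phytools::fitPagel` to ~1e-3). Optimization is multi-start L-BFGS-B in
log-rate space over $[10^{-4}, 10^3]$; the default of 25 random starts
mirrors the heavy multi-start setting of the original analysis, and
`pagel_test()` additionally seeds the alternative fit with the null
solution so the nesting inequality holds by construction. The LRT
statistic is floored at 0. Ranking takes the top 5% of sites by
$-\log p$, ties broken by site label; no FDR correction is applied, as
ranking (not calibrated error control) is the goal.

Calibration (recomputed by the acceptance checks): across 300 null
simulations on a 100-tip tree the restricted LRT rejects at or below the
binomial upper bound for nominal 0.05 — the test is, if anything,
conservative, which is expected: the chi-squared reference distribution
is asymptotic and the fixed-root, no-reversal constraints bind at the
boundary. Under strong dependence ($q_{24}/q_{13} = 10$, 200 tips) power
exceeds 0.8. Simulations that produce a monomorphic trait (no variation
to fit) are replaced by the next seed, so calibration counts condition on
testable data.

# Assay statistics

Raw wells are normalized per construct and biological replicate:
technical duplicates are averaged first; percent non-inhibited activity
is $100 (A_{\mathrm{well}} - A_{\mathrm{bg}}) / (A_{\mathrm{ctl}} -
A_{\mathrm{bg}})$ with the no-ouabain control and the background
(KCl-free + $10^{-2}$ M ouabain) wells; baseline activity converts the
control's corrected absorbance to phosphate via a linear standard curve
(0-1.2 mM Pi) and scales by protein mass (0.1 mg), incubation (20 min)
and a nominal 1 mL reaction volume — the volume convention only rescales
all activities by a constant and cancels from every downstream percent
or difference statistic.

`fit_ic50()` fits $y = 100 / (1 + 10^{s(x - m)})$ — the four-parameter
logistic with asymptotes fixed at 100 and 0 — by Levenberg-Marquardt
least squares (**minpack.lm**, the same routine used for the original
fits), multi-started over slopes 0.5, 1, 2 with the slope constrained
positive. A fit is *censored* (IC50 unmeasurable, as for catalytically
dead constructs) when the response never reaches half-inhibition inside
the tested range ($10^{-8}$ to $10^{-3}$ M): operationally, the mean
response at the highest concentration exceeds 40%, the fitted $m$ lies at
or above the highest tested concentration, or the fit fails. The 40%
cut-off is the detection limit implied by 5-point assay noise: a curve
whose true IC50 sits exactly at the top of the range reads 50% there, and
one standard deviation of headroom keeps such curves censored more than
90% of the time. At assay noise of 5 percentage points and 3 replicates,
the mean absolute error of recovered log10 IC50 is well under 0.2.

The construct-level tests mirror the original analysis exactly:
two-sided paired t-tests with Bonferroni correction (family of 15
substitutions), a two-way background x state ANOVA for
background-dependence — constructs are coded by the state they carry at
the focal site, which automatically aligns a reverse substitution's sign
with the forward direction — with Bonferroni over the 5 informative
cases, an exact two-sided binomial test of effect direction (2 x smaller
tail, capped at 1), a chi-squared uniformity test of the t-test p-values
(5 equal-width bins for 15 p-values; binning is configurable since none
is prescribed), and Spearman correlations (midranks; optional permutation
p for small panels).

# Localizing the sites behind background-dependent effects

The effect of introducing a derived state is $E = (\mathrm{mut} -
\mathrm{wt})/\mathrm{wt} \times 100$; for every unordered pair of
backgrounds given the same derived state at the same site, $\Delta =
|E_1 - E_2|$. The study-shaped panel yields 11 such comparisons (4 at
site 111, 7 at 122). Each variant site among the wild-type backgrounds
contributes a 0/1 divergence indicator per comparison (gap vs residue
counts as different).

Because only 8 backgrounds generate the comparisons, many sites have
identical or near-identical divergence profiles. Sites are therefore
grouped by connected components of the graph joining columns with
$|r| > 0.8$ (0.99 in the robustness variant); zero-variance columns form
their own groups; the representative is the lowest site label. Connected
components are the deterministic formalization of "sites grouped by how
they partition the pairwise divergences": at high thresholds components
coincide with exact profile-equivalence classes.

`nested_anova_select()` ranks groups by the marginal variance in $\Delta$
explained by each representative indicator — with the mutated-site
covariate (111 vs 122) included in *every* model, the simplest reading of
"with the mutated site as a covariate" — then adds groups in that order
to forward-nested linear models, reporting LRT p-values, AIC and $R^2$,
and stopping before saturation. We model $\Delta$ as the response and
divergence as the predictor; the original methods text once says the
binarized divergence was the dependent variable, but every reported
quantity ("% of variance among construct comparisons explained", the
permutation of $\Delta$) is only defined with $\Delta$ as the response,
so that is what we implement.

Because the two best groups are *ascertained* (selected for explaining
the most variance), significance comes from `permutation_null()`:
$\Delta$ is permuted across comparisons (10,000 times in the full
analysis) and the complete ascertainment — re-ranking all groups,
refitting the best-two model — is repeated per permutation. P-values use
the add-one rule, $(1 + \#\{R^2_{\mathrm{null}} \ge
R^2_{\mathrm{obs}}\})/(1 + N)$, and are never exactly zero.
`divergence_effect_correlation()` correlates $\Delta$ with the divergence
count restricted to a site set (e.g. the selected 16 sites), with the
same one-sided permutation p.

On synthetic panels with $\Delta$ generated as signal x (divergence at a
planted site set) + Gaussian noise at signal:noise 5, the selection
recovers at least half of the planted sites with permutation p < 0.05 in
over 80% of seeded runs.

# Structure tests

`median_distance_test()` takes alpha-carbon coordinates (PDB input via
**bio3d**; altlocs resolved to highest occupancy), computes the median
CA-CA distance from a focal site to a candidate set, and compares it to
medians of random same-size subsets of the variable-site universe
(default 1000 samples); ties count toward the null ("less than or equal"
— the conservative direction) and the add-one rule applies. The
alignment-to-structure residue mapping is an explicit two-column table;
no automatic alignment is attempted, precisely to avoid silent
off-by-one numbering bugs. `overlap_test()` is the exact hypergeometric
upper tail; both tests match exhaustive enumeration on universes small
enough to enumerate.

The universe size behind the published overlap p-values (the functional
panel's 113 variant sites vs the 417 retained correlated-evolution
sites) is not stated in the source analyses, so `N` is a required,
explicit argument here.

# Synthetic data

The generators are first-class, tested code, and every one is
deterministic under a seed:

* `simulate_yule()` — forward-time pure-birth trees (exponential waiting
  times, uniformly chosen splitter); mean tree height matches the
  analytic $\,(H_n - 1)/\lambda$ law.
* `simulate_alignment()` — per-site CTMC simulation down the tree with
  gamma categories; *planted convergence* converts each non-root branch
  to a target state at focal sites with a fixed probability, which gives
  exact countable ground truth (a per-branch conversion probability, not
  a selection model — that is the point: truth is enumerable).
* `simulate_correlated_pair()` — exact Gillespie simulation of the
  compound chain (double transitions impossible by construction);
  single-branch occupancy matches the matrix exponential.
* `simulate_backgrounds()` — wild-type panels evolved on a background
  tree, each variant site mutating once on a random branch, so divergence
  profiles are clade indicators and collapse into correlated groups, the
  structure the real 113-site/24-group panel shows. Independent
  coin-flip profiles would make every site its own group and no grouping
  method could then bundle causal sites — the tree is what makes the
  localization problem well-posed.
* `simulate_assay_dataset()` — absorbance-level dose-response wells
  (noise Gaussian on the percent scale, truncated to [-20, 120]) and
  activities whose background dependence is `causal_effect` per derived
  causal site, so effect differences are proportional to causal
  divergence; the whole raw-assay normalization path is exercised.
* `plant_causal_sites()` — plants the causal set on the branch whose
  divergence indicator varies most across the panel's comparisons: a
  planted signal that does not divide the comparisons would be
  undetectable by any method, so recovery claims are defined against
  detectable plantings.

What the generators deliberately do **not** emulate: selection (planted
convergence is a mechanical conversion), codon-level mutation bias,
among-site rate correlation, alignment error, or plate-reader artifacts.
Passing recovery tests therefore demonstrates correctness of the
machinery under the stated models, not robustness to real-data
pathologies.

# Pipeline, sizes and numerical conventions

`run_pipeline()` drives all stages on generated inputs and writes CSVs
plus a JSON manifest (configuration, seed, versions, filter counts); a
rerun with the same configuration is byte-identical. Stage sub-seeds are
derived deterministically from the global seed so stages are individually
reproducible. Defaults keep a full run at desk scale (32 tips, 120
sites, 8 backgrounds, 6 correlated-evolution screens) — a few seconds —
while the statistical calibration runs (300-simulation type-I error,
200-simulation power, 100-panel localization) live in the test suite and
acceptance script with problem sizes chosen to estimate each rate to a
few percent.

Numerical conventions collected in one place: likelihood underflow is
handled by per-node rescaling with log scalers (and the optimizer treats
non-finite likelihoods as a large penalty, which is where box-bounded
random starts can land); LRT statistics are floored at 0; permutation
and bootstrap p-values/intervals use add-one and percentile rules; site
ranking and group representatives break ties by ascending site label;
`(C+1)/(D+1)` is defined for all counts including $C = D = 0$; reference
site labels are 1-based in sheep numbering (the numbering reference and
offset are user-configurable, since the field also uses pig numbering at
times) while internal column indices are 0/1-based R conventions hidden
behind `site_column()`.

# Known limitations

* Marginal ASR point calls discard ancestral uncertainty; convergence
  counts do not integrate over posteriors (by design, matching the
  thresholded-call approach), so masked sites lower both $C$ and $D$.
  Moreover, when truly parallel substitutions cluster in one region of
  the tree, the reconstruction tends to explain the tips with a single
  deeper substitution, merging the parallel events — convergence counts
  from reconstructed ancestors are conservative in exactly this way, and
  the planted-recovery test asserts aggregate (not per-replicate)
  recovery for this reason.
* The Pagel machinery covers binary traits only, and likelihoods are not
  expected to reproduce BayesTraits numerics bit-for-bit (different
  optimizer, root handling options).
* The epistasis analysis can only resolve sites to correlated groups;
  with 8 backgrounds, profile-identical sites are fundamentally
  indistinguishable.
* The eight-background reanalysis of the published panel requires the
  GenBank construct sequences and supplementary effect tables, which are
  not redistributable inside the package; the corresponding acceptance
  check documents exactly which inputs it needs and fails cleanly without
  them.
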