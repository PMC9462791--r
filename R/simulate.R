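#' Simulate a Yule (pure-birth) tree
#'
#' Forward-time simulation: starting from two lineages at the root, each
#' waiting time to the next speciation is exponential with rate
#' `n_lineages * birth_rate` and a uniformly chosen lineage splits. After
#' the target tip count is reached the process runs for one more
#' exponential waiting time so terminal branches have positive length.
#' Branch lengths are in time units; rescale (e.g. with
#' [scale_branch_lengths()]) to interpret them as expected
#' substitutions/site.
#'
#' @param n_tips Number of tips (>= 2).
#' @param birth_rate Speciation rate.
#' @param seed Optional seed.
#' @return A rooted ultrametric `phylo`.
#' @export
simulate_yule <- function(n_tips, birth_rate = 1, seed = NULL) {
  stop_if_not(n_tips >= 2, "n_tips must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  ## lineage bookkeeping: id, parent, start time; root = id 1 at t = 0
  parent <- c(NA_integer_, 1L, 1L)
  t_start <- c(0, 0, 0)
  end_time <- rep(NA_real_, 3)
  active <- c(2L, 3L)
  t <- 0
  while (length(active) < n_tips) {
    t <- t + rexp(1, length(active) * birth_rate)
    split <- active[sample.int(length(active), 1)]
    end_time[split] <- t
    id1 <- length(parent) + 1L; id2 <- id1 + 1L
    parent <- c(parent, split, split)
    t_start <- c(t_start, t, t)
    end_time <- c(end_time, NA, NA)
    active <- c(setdiff(active, split), id1, id2)
  }
  t_end <- t + rexp(1, length(active) * birth_rate)
  end_time[active] <- t_end

  ## map to ape ids: tips 1..n, root n+1, internals follow
  is_tip <- seq_along(parent) %in% active
  tip_ids <- which(is_tip)
  int_ids <- which(!is_tip)               # includes root (id 1)
  map <- integer(length(parent))
  map[tip_ids] <- seq_len(n_tips)
  map[int_ids] <- n_tips + seq_along(int_ids)  # root (first) -> n+1
  edge <- cbind(map[parent[-1]], map[-1])
  tree <- list(edge = edge,
               edge.length = end_time[-1] - t_start[-1],
               tip.label = paste0("t", seq_len(n_tips)),
               Nnode = length(int_ids))
  class(tree) <- "phylo"
  tree <- ape::reorder.phylo(tree, "cladewise")
  validate_phylogeny(tree)
  tree
}

#' Simulate an amino-acid alignment on a tree, with optional planted
#' convergence
#'
#' Each site evolves independently down the tree under the
#' [rate_model()]'s continuous-time Markov chain (a gamma rate category
#' is drawn per site). At planted focal sites, every non-root branch
#' independently converts the end-of-branch state to the target amino
#' acid with the given probability, giving exact, countable convergent
#' ground truth. True node states and the implied per-branch event list
#' are recorded.
#'
#' @param tree Rooted `phylo` with branch lengths in substitutions/site.
#' @param model A [rate_model()].
#' @param n_sites Number of alignment columns.
#' @param planted Optional list `list(sites =, prob =, target =)`:
#'   column indices (1-based), per-branch conversion probability, and
#'   target state.
#' @param seed Optional seed.
#' @return List: `aln` (an [nka_alignment()] numbered 1..n_sites),
#'   `node_states` (character matrix, all nodes x sites), `events`
#'   (branch/site/anc/der with a `planted` flag), `site_rates`.
#' @export
simulate_alignment <- function(tree, model, n_sites, planted = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tree <- ape::reorder.phylo(tree, "postorder")
  n_tip <- ape::Ntip(tree)
  n_node <- n_tip + tree$Nnode
  cat_idx <- sample.int(model$n_cat, n_sites, replace = TRUE, prob = model$weights)
  site_rates <- model$rates[cat_idx]

  states <- matrix(NA_integer_, n_node, n_sites)
  rt <- root_node(tree)
  states[rt, ] <- sample.int(20, n_sites, replace = TRUE, prob = model$freqs)

  planted_sites <- if (is.null(planted)) integer(0) else planted$sites
  target_idx <- if (is.null(planted)) NA_integer_ else match(planted$target, AA_STATES)
  planted_hit <- matrix(FALSE, n_node, n_sites)

  edges <- tree$edge
  for (e in rev(seq_len(nrow(edges)))) {      # preorder: parents first
    par <- edges[e, 1]; chi <- edges[e, 2]; len <- tree$edge.length[e]
    for (cc in unique(cat_idx)) {
      sel <- which(cat_idx == cc)
      P <- cpp_pmat(model$Q, model$rates[cc] * len)
      ps <- states[par, sel]
      states[chi, sel] <- vapply(ps, function(s) {
        sample.int(20, 1, prob = P[s, ])
      }, integer(1))
    }
    if (length(planted_sites)) {
      conv <- runif(length(planted_sites)) < planted$prob
      if (any(conv)) {
        states[chi, planted_sites[conv]] <- target_idx
        planted_hit[chi, planted_sites[conv]] <- TRUE
      }
    }
  }

  ## implied event list (one ancestral->derived call per branch per site)
  ev <- list()
  for (e in seq_len(nrow(edges))) {
    par <- edges[e, 1]; chi <- edges[e, 2]
    hit <- which(states[par, ] != states[chi, ])
    if (length(hit)) {
      ev[[length(ev) + 1L]] <- data.frame(
        branch = chi, site = hit,
        anc = AA_STATES[states[par, hit]], der = AA_STATES[states[chi, hit]],
        planted = planted_hit[chi, hit])
    }
  }
  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(branch = integer(), site = integer(), anc = character(),
               der = character(), planted = logical())

  tip_seq <- apply(states[seq_len(n_tip), , drop = FALSE], 1,
                   function(r) paste(AA_STATES[r], collapse = ""))
  names(tip_seq) <- tree$tip.label
  aln <- nka_alignment(tip_seq, reference_id = tree$tip.label[1])
  node_states <- matrix(AA_STATES[states], n_node, n_sites)
  list(aln = aln, node_states = node_states, events = events,
       site_rates = site_rates, tree = tree)
}

#' Simulate a correlated pair of binary sites (compound 4-state chain)
#'
#' Exact stochastic (Gillespie) simulation of the compound chain along
#' every branch, so double transitions never occur within a jump. States
#' are 1=(0,0), 2=(0,1), 3=(1,0), 4=(1,1).
#'
#' @param tree Rooted `phylo`.
#' @param rates Named rate vector (subset of
#'   `q12,q13,q21,q24,q31,q34,q42,q43`).
#' @param root_state Compound state at the root (1 by default: both sites
#'   ancestral).
#' @param seed Optional seed.
#' @return List: `x`, `y` (named 0/1 tip vectors), `node_states`
#'   (compound state per node), `n_transitions`.
#' @export
simulate_correlated_pair <- function(tree, rates, root_state = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  Q <- pagel_generator(rates)
  tree <- ape::reorder.phylo(tree, "postorder")
  n_tip <- ape::Ntip(tree)
  n_node <- n_tip + tree$Nnode
  st <- integer(n_node)
  st[root_node(tree)] <- as.integer(root_state)
  n_trans <- 0L
  edges <- tree$edge
  for (e in rev(seq_len(nrow(edges)))) {
    s <- st[edges[e, 1]]
    t_left <- tree$edge.length[e]
    repeat {
      exit <- -Q[s, s]
      if (exit <= 0) break
      w <- rexp(1, exit)
      if (w > t_left) break
      t_left <- t_left - w
      probs <- Q[s, ]; probs[s] <- 0
      s <- sample.int(4, 1, prob = probs)
      n_trans <- n_trans + 1L
    }
    st[edges[e, 2]] <- s
  }
  tips <- st[seq_len(n_tip)]
  x <- setNames(as.integer(tips >= 3), tree$tip.label)        # site 1 derived
  y <- setNames(as.integer(tips %in% c(2L, 4L)), tree$tip.label) # site 2 derived
  list(x = x, y = y, node_states = st, n_transitions = n_trans)
}

#' Synthetic wild-type backgrounds for the construct panel
#'
#' Generates an alignment of wild-type ATP1A1-like backgrounds related by
#' a species tree: the two focal resistance sites (111, 122) are fixed at
#' the ancestral states Q and N, and each variant background site mutates
#' exactly once, on a uniformly chosen branch of the background tree, so
#' its derived state marks the tips of one clade. Sites that hit the same
#' branch therefore share identical divergence profiles — reproducing the
#' strong site correlations that real divergent backgrounds show (the
#' experimental panel's 113 variant sites collapse into 24 correlated
#' groups) — and the mutated branch of every site is recorded as ground
#' truth.
#'
#' @param n_backgrounds Number of wild-type species backgrounds (the
#'   study used eight plus a published ninth).
#' @param n_variant Number of variant background sites.
#' @param seed Optional seed.
#' @return List: `aln` (an [nka_alignment()]; variant sites are labelled
#'   from 200 upward, focal sites at 111 and 122), `profile`
#'   (backgrounds x variant sites 0/1 matrix), `variant_labels`,
#'   `site_branch` (branch each site mutated on), `tree`.
#' @export
simulate_backgrounds <- function(n_backgrounds = 8, n_variant = 30,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ids <- paste0("BG", seq_len(n_backgrounds))
  tree <- simulate_yule(n_backgrounds, 1)
  tree$tip.label <- ids
  ## tips below every branch (branch = child node id)
  desc <- ape::prop.part(tree)  # tip sets, indexed by internal node - Ntip
  tips_below <- function(v) {
    if (v <= n_backgrounds) return(v)
    desc[[v - n_backgrounds]]
  }
  L <- 260                      # columns 1..260 cover sites 111/122 and 200+
  base <- sample(AA_STATES, L, replace = TRUE)
  base[111] <- "Q"; base[122] <- "N"
  seqs <- matrix(rep(base, each = n_backgrounds), n_backgrounds, L,
                 dimnames = list(ids, NULL))
  variant_labels <- 200:(199 + n_variant)
  branches <- tree$edge[, 2]
  site_branch <- sample(branches, n_variant, replace = TRUE)
  profile <- matrix(0L, n_backgrounds, n_variant,
                    dimnames = list(ids, variant_labels))
  for (j in seq_len(n_variant)) {
    profile[tips_below(site_branch[j]), j] <- 1L
    col <- variant_labels[j]
    derived <- sample(setdiff(AA_STATES, base[col]), 1)
    seqs[profile[, j] == 1, col] <- derived
  }
  aln <- nka_alignment(apply(seqs, 1, paste, collapse = ""), reference_id = ids[1])
  list(aln = aln, profile = profile, variant_labels = variant_labels,
       site_branch = site_branch, tree = tree)
}

#' Study-shaped construct panel
#'
#' Wild-type rows plus engineered substitutions at the focal sites,
#' shaped like the experimental design: by default two states at site
#' 111 (R on three backgrounds, H on two) and two at site 122 (D on
#' four, H on two), yielding 4 + 7 = 11 same-state cross-background
#' comparisons.
#'
#' @param backgrounds Background ids.
#' @param design List of lists `list(site =, to =, on = indices)`.
#' @return Panel data frame (`construct, background, site, to`), without
#'   activities.
#' @export
simulate_construct_panel <- function(backgrounds,
                                     design = list(
                                       list(site = 111, to = "R", on = 1:3),
                                       list(site = 111, to = "H", on = 4:5),
                                       list(site = 122, to = "D", on = c(1, 4, 6, 7)),
                                       list(site = 122, to = "H", on = c(2, 8)))) {
  rows <- data.frame(construct = paste0(backgrounds, "_wt"),
                     background = backgrounds,
                     site = NA_integer_, to = NA_character_)
  for (d in design) {
    bgs <- backgrounds[d$on]
    rows <- rbind(rows, data.frame(
      construct = paste0(bgs, "_", d$site, d$to),
      background = bgs, site = d$site, to = d$to))
  }
  rows
}

#' Simulate a full assay dataset with epistatic ground truth
#'
#' Generates replicate dose-response and activity data for a construct
#' panel. Wild-type baseline activities are drawn per background;
#' a mutant's activity multiplier is `1 + effect_main + causal_effect *
#' (number of derived causal sites in its background)`, so the
#' difference in a substitution's effect across two backgrounds is
#' proportional to their divergence at the causal sites. Percent
#' dose-response curves come from the fixed-asymptote logistic at the
#' six ouabain concentrations with Gaussian noise (truncated to the
#' physically plausible band -20..120); well absorbances are
#' reconstructed through the linear
#' phosphate standard curve so the raw-assay normalization path is
#' exercised end to end.
#'
#' @param panel From [simulate_construct_panel()].
#' @param bgs From [simulate_backgrounds()].
#' @param causal_sites Variant-site labels whose divergence carries the
#'   background dependence.
#' @param causal_effect Activity-multiplier increment per derived causal
#'   site.
#' @param effect_main Named main effect of each introduced state (e.g.
#'   `c("111R" = -0.2)`); unnamed scalar applies to all.
#' @param ic50_true Named log10 IC50 per construct, or `NULL` to draw
#'   uniformly between -7 and -4.
#' @param slope True Hill slope of the inhibition curve.
#' @param noise_sd Gaussian noise of the percent responses (percentage
#'   points; 5 in the recovery analyses).
#' @param activity_cv Coefficient of variation of replicate activities.
#' @param n_rep Biological replicates per construct (3).
#' @param baseline_mean,baseline_cv Lognormal-ish baseline activity
#'   distribution across backgrounds (nmol Pi/mg/min).
#' @param seed Optional seed.
#' @return List: `wells` (long table in the [read_assay_table()] layout),
#'   `standards` (standard-curve table), `truth` (activities, effects,
#'   deltas, IC50s, causal sites, panel, alignment).
#' @export
simulate_assay_dataset <- function(panel, bgs, causal_sites = integer(0),
                                   causal_effect = 0, effect_main = -0.2,
                                   ic50_true = NULL, slope = 1, noise_sd = 5,
                                   activity_cv = 0.05, n_rep = 3,
                                   baseline_mean = 10, baseline_cv = 0.4,
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  backgrounds <- unique(panel$background)
  baseline <- setNames(baseline_mean * exp(rnorm(length(backgrounds), 0, baseline_cv) -
                                           baseline_cv^2 / 2), backgrounds)
  causal_count <- if (length(causal_sites)) {
    rowSums(bgs$profile[, as.character(causal_sites), drop = FALSE])
  } else setNames(rep(0, length(backgrounds)), backgrounds)

  conc <- 10^-(3:8)
  std_conc <- c(1.2, 1, 0.8, 0.6, 0.4, 0.2, 0)
  std_slope <- 0.5; bg_abs <- 0.1
  protein_mg <- 0.1; time_min <- 20; volume_ml <- 1

  if (is.null(ic50_true)) {
    ic50_true <- setNames(runif(nrow(panel), -7, -4), panel$construct)
  }
  main_of <- function(site, to) {
    if (is.null(names(effect_main))) return(effect_main[1])
    key <- paste0(site, to)
    if (key %in% names(effect_main)) effect_main[[key]] else 0
  }

  wells <- list(); act_true <- numeric(nrow(panel))
  for (i in seq_len(nrow(panel))) {
    con <- panel$construct[i]; b <- panel$background[i]
    mult <- if (is.na(panel$to[i])) 1 else
      1 + main_of(panel$site[i], panel$to[i]) + causal_effect * causal_count[[b]]
    act_true[i] <- baseline[[b]] * max(mult, 0.02)
    for (r in seq_len(n_rep)) {
      act_r <- act_true[i] * exp(rnorm(1, 0, activity_cv) - activity_cv^2 / 2)
      ## invert the normalization: activity -> Pi mM -> control absorbance
      pi_mM <- act_r * protein_mg * time_min / (1000 * volume_ml)
      signal <- pi_mM * std_slope
      pct <- 100 / (1 + 10^(slope * (log10(conc) - ic50_true[[con]])))
      pct <- pmin(pmax(pct + rnorm(length(conc), 0, noise_sd), -20), 120)
      wells[[length(wells) + 1L]] <- data.frame(
        construct = con, background = b,
        substitution = if (is.na(panel$to[i])) "wt" else
          paste0(panel$site[i], panel$to[i]),
        replicate = r,
        conc_M = c(conc, NA, NA),
        absorbance = c(bg_abs + signal * pct / 100, bg_abs + signal, bg_abs),
        well_type = c(rep("ouabain", length(conc)), "control", "background"))
    }
  }
  wells <- do.call(rbind, wells)
  wells$absorbance <- pmax(wells$absorbance, 0)
  standards <- data.frame(conc_mM = std_conc,
                          absorbance = bg_abs + std_slope * std_conc)
  panel$activity_true <- act_true
  list(wells = wells, standards = standards,
       truth = list(panel = panel, baseline = baseline,
                    causal_sites = causal_sites, causal_effect = causal_effect,
                    causal_count = causal_count, ic50 = ic50_true,
                    slope = slope, noise_sd = noise_sd,
                    std_slope = std_slope, bg_abs = bg_abs,
                    protein_mg = protein_mg, time_min = time_min,
                    volume_ml = volume_ml, alignment = bgs$aln))
}

#' Directly simulated effect differences with planted causal sites
#'
#' Generates the per-comparison effect difference as `signal *
#' (divergence count at the causal sites) + Gaussian noise` — the
#' reduced-form model behind the site-localization recovery analyses.
#'
#' @param div Divergence matrix (comparisons x variant sites).
#' @param causal_sites Planted causal site labels (columns of `div`).
#' @param signal Effect per causal-site difference.
#' @param noise_sd Gaussian noise SD.
#' @param seed Optional seed.
#' @return Numeric vector of deltas.
#' @export
simulate_epistasis_deltas <- function(div, causal_sites, signal, noise_sd,
                                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cnt <- rowSums(div[, as.character(causal_sites), drop = FALSE])
  signal * cnt + rnorm(nrow(div), 0, noise_sd)
}

#' Synthetic alpha-carbon structure
#'
#' A smooth self-avoiding-ish random walk in 3-D with ~3.8-angstrom
#' steps, standing in for a protein backbone in structure-test
#' simulations. Clearly synthetic: not derived from any deposited
#' structure.
#'
#' @param n_residues Number of CA positions.
#' @param seed Optional seed.
#' @return A `ca_structure` with residues numbered 1..n.
#' @export
simulate_structure <- function(n_residues, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  step <- matrix(rnorm(3 * n_residues), ncol = 3)
  step <- 3.8 * step / sqrt(rowSums(step^2))
  ## smooth the direction changes to mimic secondary structure
  for (i in 2:n_residues) step[i, ] <- 0.6 * step[i - 1, ] + 0.4 * step[i, ]
  xyz <- apply(step, 2, cumsum)
  out <- data.frame(resno = seq_len(n_residues),
                    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  attr(out, "chain") <- "A"
  class(out) <- c("ca_structure", "data.frame")
  out
}

#' Choose a detectable planted causal site set
#'
#' Selects, among the branches of the background tree, the one whose
#' divergence indicator varies most across the panel's comparisons, and
#' returns (up to) `n_sites` variant sites that mutated on it. A causal
#' set must divide the comparisons to be detectable at all; planting on
#' the most informative branch makes the planted signal well-defined
#' rather than an accident of the branch draw.
#'
#' @param bgs A [simulate_backgrounds()] result.
#' @param div Divergence matrix over the panel's comparisons.
#' @param n_sites Maximum number of causal sites.
#' @return Integer vector of site labels.
#' @export
plant_causal_sites <- function(bgs, div, n_sites = 5) {
  branches <- unique(bgs$site_branch)
  branch_var <- vapply(branches, function(b) {
    s <- bgs$variant_labels[bgs$site_branch == b][1]
    var(div[, as.character(s)])
  }, numeric(1))
  br <- branches[which.max(branch_var)]
  head(bgs$variant_labels[bgs$site_branch == br], n_sites)
}
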