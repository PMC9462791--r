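#' Pipeline configuration
#'
#' Collects the tuning constants of the full analysis. Defaults are the
#' values used throughout the ATP1A study design: posterior-probability
#' threshold 0.8 for ancestral calls, excluded alternatively-spliced
#' region 810-840, running-average window 0.05 substitutions/site,
#' correlation-grouping threshold 0.8, 10,000 permutations, top 5%
#' quantile for correlated sites, and branch lengths rescaled to mean
#' 0.1 for the correlated-evolution fits.
#'
#' @param ... Overrides of the defaults; unknown names are an error.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    pp_threshold = 0.8,
    exclude_sites = 810:840,
    window = 0.05,
    step = 0.01,
    n_boot = 100,
    r_threshold = 0.8,
    n_perm = 10000,
    top_quantile = 0.05,
    target_mean_bl = 0.1,
    ## synthetic stage sizes (kept modest so a full run is quick)
    n_tips = 32,
    birth_rate = 1,
    n_sites = 120,
    gamma_shape = 0.7,
    tree_depth_scale = 0.5,
    n_pagel_sites = 6,
    n_backgrounds = 8,
    n_variant = 30,
    n_causal = 5,
    causal_effect = 0.25,
    pagel_n_starts = 5,
    n_struct_perm = 1000
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  ## validity
  stop_if_not(cfg$pp_threshold >= 0 && cfg$pp_threshold < 1, "pp_threshold in [0,1)")
  stop_if_not(cfg$window > 0 && cfg$step > 0, "window/step must be positive")
  stop_if_not(cfg$top_quantile > 0 && cfg$top_quantile <= 1, "top_quantile in (0,1]")
  stop_if_not(cfg$n_perm >= 100, "n_perm >= 100")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$exclude_sites) && length(y$exclude_sites) == 2) {
    y$exclude_sites <- y$exclude_sites[1]:y$exclude_sites[2]
  }
  do.call(pipeline_config, y)
}

## deterministic stage sub-seed derived from the global seed
stage_seed <- function(cfg, stage) {
  (cfg$seed * 1000L + sum(utf8ToInt(stage))) %% .Machine$integer.max
}

#' Run the analysis pipeline on synthetic data
#'
#' Orchestrates every stage end to end on generated inputs with known
#' ground truth: `simulate` writes the inputs (alignment FASTA, Newick
#' tree, assay CSV), `asr` reconstructs ancestral states, `convergence`
#' builds the branch-pair convergence table and distance trend, `pagel`
#' screens sites for correlated evolution with the focal site,
#' `ic50` fits the dose-response curves, `epistasis` runs the
#' site-localization analysis, and `structure` the proximity test.
#' Stage outputs are CSV files in `out_dir` plus a JSON manifest holding
#' the configuration, seed and filter counts; a rerun with the same
#' config reproduces the outputs.
#'
#' @param cfg A [pipeline_config()].
#' @param out_dir Output directory (created if missing).
#' @param stages Subset of stages to run (dependencies are computed in
#'   memory regardless; `"all"` for everything).
#' @return Invisible list of in-memory stage results.
#' @export
run_pipeline <- function(cfg = pipeline_config(), out_dir = tempfile("nkaevol_run_"),
                         stages = "all") {
  all_stages <- c("simulate", "asr", "convergence", "pagel", "ic50",
                  "epistasis", "structure")
  if (identical(stages, "all")) stages <- all_stages
  stop_if_not(all(stages %in% all_stages), "unknown stage name")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  note <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  res <- list()

  ## ---- simulate ----
  model <- rate_model("JTT", gamma_shape = cfg$gamma_shape)
  tree <- simulate_yule(cfg$n_tips, cfg$birth_rate, seed = stage_seed(cfg, "tree"))
  tree$edge.length <- tree$edge.length * cfg$tree_depth_scale / max(ape::node.depth.edgelength(tree))
  sim <- simulate_alignment(tree, model, cfg$n_sites,
                            planted = list(sites = c(20L, 40L), prob = 0.08,
                                           target = "R"),
                            seed = stage_seed(cfg, "alignment"))
  bgs <- simulate_backgrounds(cfg$n_backgrounds, cfg$n_variant,
                              seed = stage_seed(cfg, "backgrounds"))
  panel <- simulate_construct_panel(rownames(bgs$profile))
  causal <- bgs$variant_labels[seq_len(cfg$n_causal)]
  assay <- simulate_assay_dataset(panel, bgs, causal_sites = causal,
                                  causal_effect = cfg$causal_effect,
                                  seed = stage_seed(cfg, "assay"))
  if ("simulate" %in% stages) {
    write_alignment(sim$aln, file.path(out_dir, "alignment.fasta"))
    ape::write.tree(sim$tree, file.path(out_dir, "tree.nwk"))
    write_alignment(bgs$aln, file.path(out_dir, "backgrounds.fasta"))
    write.csv(assay$wells, file.path(out_dir, "assay_wells.csv"), row.names = FALSE)
    write.csv(assay$standards, file.path(out_dir, "assay_standards.csv"),
              row.names = FALSE)
    note("simulate: %d tips, %d sites, %d assay wells", cfg$n_tips, cfg$n_sites,
         nrow(assay$wells))
  }
  res$simulate <- list(sim = sim, bgs = bgs, panel = panel, assay = assay,
                       causal = causal)

  ## ---- asr ----
  fit <- marginal_asr(sim$aln, sim$tree, model)
  calls <- call_states(fit, cfg$pp_threshold)
  if ("asr" %in% stages) {
    anc <- apply(calls$states, 1, function(r) {
      r[is.na(r)] <- "X"; paste(r, collapse = "")
    })
    names(anc) <- paste0("node", rownames(calls$states))
    write_alignment(anc, file.path(out_dir, "ancestral_calls.fasta"))
    write.csv(data.frame(node = rep(rownames(calls$pp), ncol(calls$pp)),
                         site = rep(seq_len(ncol(calls$pp)), each = nrow(calls$pp)),
                         max_pp = as.vector(calls$pp)),
              file.path(out_dir, "ancestral_pp.csv"), row.names = FALSE)
    note("asr: %.1f%% of node-site states called at PP > %.2f",
         100 * mean(!is.na(calls$states)), cfg$pp_threshold)
  }
  res$asr <- list(fit = fit, calls = calls)

  ## ---- convergence ----
  events <- extract_substitutions(calls, sim$aln, sim$tree,
                                  exclude_sites = cfg$exclude_sites)
  pairs <- branch_pair_table(events, sim$tree)
  trend <- running_trend(pairs, cfg$window, cfg$step, cfg$n_boot,
                         seed = stage_seed(cfg, "trend"))
  if ("convergence" %in% stages) {
    write.csv(events, file.path(out_dir, "substitution_events.csv"), row.names = FALSE)
    write.csv(pairs, file.path(out_dir, "branch_pairs.csv"), row.names = FALSE)
    write.csv(trend, file.path(out_dir, "convergence_trend.csv"), row.names = FALSE)
    note("convergence: %d events, %d comparable pairs", nrow(events), nrow(pairs))
  }
  res$convergence <- list(events = events, pairs = pairs, trend = trend)

  ## ---- pagel ----
  if ("pagel" %in% stages) {
    rt <- as.character(root_node(sim$tree))
    mrca_states <- setNames(sim$node_states[as.integer(rt), ], sim$aln$site_labels)
    bin <- binary_site_matrix(sim$aln, mrca_states)
    retained <- filter_sites(bin)
    note("pagel: %d of %d sites retained after singleton/gap filter",
         length(retained), ncol(bin))
    focal_site <- "20"
    partners <- setdiff(head(retained, cfg$n_pagel_sites + 1), focal_site)
    partners <- head(partners, cfg$n_pagel_sites)
    stree <- scale_branch_lengths(sim$tree, cfg$target_mean_bl)
    ptab <- do.call(rbind, lapply(partners, function(s) {
      tst <- pagel_test(bin[, focal_site], bin[, s], stree,
                        type = "restricted", n_starts = cfg$pagel_n_starts,
                        seed = stage_seed(cfg, paste0("pagel", s)))
      data.frame(site = s, lnL_null = tst$null$loglik, lnL_alt = tst$alt$loglik,
                 LRT = tst$statistic, df = tst$df, p = tst$p_value,
                 neglog10_p = -log10(max(tst$p_value, .Machine$double.xmin)))
    }))
    ptab$top <- ptab$site %in% rank_sites(setNames(ptab$p, ptab$site),
                                          cfg$top_quantile)
    write.csv(ptab, file.path(out_dir, "correlated_sites.csv"), row.names = FALSE)
    res$pagel <- ptab
  }

  ## ---- ic50 ----
  curve <- standard_curve(assay$standards$conc_mM, assay$standards$absorbance)
  key <- interaction(assay$wells$construct, assay$wells$replicate, drop = TRUE)
  norm <- lapply(split(assay$wells, key), normalize_assay, curve = curve)
  ic50_tab <- do.call(rbind, lapply(split(names(norm), sub("\\.[0-9]+$", "", names(norm))),
    function(ks) {
      df <- do.call(rbind, lapply(ks, function(k) {
        cbind(norm[[k]]$percent, replicate = sub("^.*\\.", "", k))
      }))
      s <- ic50_by_replicate(data.frame(replicate = df$replicate,
                                        log10_conc = df$log10_conc,
                                        percent = df$percent))
      data.frame(construct = sub("\\.[0-9]+$", "", ks[1]),
                 log10_ic50 = s$mean, se = s$se, n_censored = s$n_censored)
    }))
  activity_tab <- data.frame(
    construct = sub("\\.[0-9]+$", "", names(norm)),
    replicate = sub("^.*\\.", "", names(norm)),
    activity = vapply(norm, function(x) x$activity, numeric(1)))
  if ("ic50" %in% stages) {
    write.csv(ic50_tab, file.path(out_dir, "ic50.csv"), row.names = FALSE)
    write.csv(activity_tab, file.path(out_dir, "activity.csv"), row.names = FALSE)
    note("ic50: %d constructs fitted, %d with censored replicates",
         nrow(ic50_tab), sum(ic50_tab$n_censored > 0))
  }
  res$ic50 <- list(ic50 = ic50_tab, activity = activity_tab)

  ## ---- epistasis ----
  act_mean <- tapply(activity_tab$activity, activity_tab$construct, mean)
  panel2 <- panel
  panel2$activity <- as.numeric(act_mean[panel2$construct])
  comp <- enumerate_comparisons(panel2)
  vs <- variant_sites(bgs$aln)
  div <- divergence_matrix(bgs$aln, comp, vs)
  scan <- nested_anova_select(comp$delta, div, comp$site,
                              r_threshold = cfg$r_threshold)
  perm <- permutation_null(comp$delta, div, comp$site,
                           r_threshold = cfg$r_threshold,
                           n_perm = cfg$n_perm,
                           seed = stage_seed(cfg, "epistasis"))
  if ("epistasis" %in% stages) {
    write.csv(comp, file.path(out_dir, "comparisons.csv"), row.names = FALSE)
    write.csv(scan$table, file.path(out_dir, "model_selection.csv"), row.names = FALSE)
    note("epistasis: %d comparisons, %d variant sites, best model R2 = %.3f, perm p = %.4g",
         nrow(comp), length(vs), scan$table$R2[scan$table$model == scan$best],
         perm$p_value)
  }
  res$epistasis <- list(comparisons = comp, scan = scan, perm = perm,
                        divergence = div)

  ## ---- structure ----
  if ("structure" %in% stages) {
    struct <- simulate_structure(260, seed = stage_seed(cfg, "structure"))
    cand <- res$epistasis$scan$selected_sites
    if (length(cand) >= 2) {
      prox <- median_distance_test(struct, 111, cand, vs,
                                   n_perm = cfg$n_struct_perm,
                                   seed = stage_seed(cfg, "proximity"))
      write.csv(data.frame(focal = 111, median_A = prox$statistic,
                           p = prox$p_value, n_candidates = prox$n_candidates,
                           n_universe = prox$n_universe),
                file.path(out_dir, "proximity_test.csv"), row.names = FALSE)
      res$structure <- prox
      note("structure: median CA distance %.1f A, p = %.4g", prox$statistic,
           prox$p_value)
    }
  }

  manifest <- list(config = unclass(cfg), stages = stages,
                   package_version = as.character(utils::packageVersion("nkaevol")),
                   log = log_lines)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(log_lines, file.path(out_dir, "pipeline.log"))
  invisible(res)
}
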