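#' Pipeline configuration with study defaults
#'
#' All analysis thresholds default to the study's values: HAMA cut 18, FD
#' cutoff 0.2 mm, HAMD remission cutoff 7, quality minimum 4, edge-level p
#' 0.001, component alpha 0.05, 1000 permutations, 10 mm assignment radius,
#' 50% probe background fraction, |z| > 3 gene selection, FDR 0.05.
#' Simulation-scale parameters (regions, subjects, genes, surrogate/bootstrap
#' counts) default to a desk-scale profile and are freely adjustable.
#'
#' @param ... named overrides of any default field.
#' @return list of class `tx_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    # analysis thresholds (study defaults)
    hama_cut = 18, fd_max = 0.2, hamd_remission = 7, quality_min = 4,
    edge_p = 0.001, alpha = 0.05, n_perm = 1000, max_dist_mm = 10,
    min_probe_fraction = 0.5, z_thresh = 3, fdr_alpha = 0.05,
    n_components = 5, n_surrogates = 1000, n_boot = 1000,
    protected_covariates = c("hamd", "hama", "age", "sex"),
    nuisance_covariates = c("sex", "age", "fd", "education"),
    # synthetic-data scale
    n_regions = 40, n_group1 = 60, n_group2 = 60, n_timepoints = 150,
    sites = c("siteA", "siteB"),
    delta = 0.3, network_pairs = list(c("SC", "VN"), c("SC", "DAN")),
    n_donors = 6, n_genes = 300, n_planted_genes = 20,
    spatial_corr_length = 30,
    n_terms = 15, term_size_range = c(10, 40),
    # seeds per stage
    seeds = list(simulate = 11, nbs = 12, network = 13, surrogates = 14,
                 bootstrap = 15, genesets = 16, expression = 17, match = 18),
    # optional external inputs (skip the corresponding stage)
    inputs = list(atlas = NULL, fc_stack = NULL, subjects = NULL,
                  expression = NULL, region_scores = NULL, gmt = NULL)
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = c("tx_config", "list"))
}

#' Validate a pipeline configuration
#'
#' Range checks on thresholds, presence checks on seeds and external input
#' paths. Failures and warnings are returned in the report, not thrown.
#'
#' @param config a `tx_config`.
#' @return list: `ok` (logical), `failures`, `warnings` (character vectors).
#' @export
validate_config <- function(config) {
  fail <- character(0)
  warn <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) fail <<- c(fail, msg)
  chk(config$alpha > 0 && config$alpha < 1, "alpha must be in (0, 1)")
  chk(config$edge_p > 0 && config$edge_p < 1, "edge_p must be in (0, 1)")
  chk(config$fd_max > 0, "fd_max must be positive")
  chk(config$hama_cut >= 0, "hama_cut must be non-negative")
  chk(config$n_perm >= 1, "n_perm must be >= 1")
  chk(config$max_dist_mm > 0, "max_dist_mm must be positive")
  chk(config$min_probe_fraction >= 0 && config$min_probe_fraction <= 1,
      "min_probe_fraction must be in [0, 1]")
  chk(config$z_thresh > 0, "z_thresh must be positive")
  chk(config$fdr_alpha > 0 && config$fdr_alpha < 1, "fdr_alpha must be in (0, 1)")
  chk(config$n_components >= 1, "n_components must be >= 1")
  chk(config$n_regions >= 14, "n_regions must be >= 14")
  need_seeds <- c("simulate", "nbs", "network", "surrogates", "bootstrap",
                  "genesets", "expression", "match")
  missing_seeds <- setdiff(need_seeds, names(config$seeds))
  if (length(missing_seeds)) {
    warn <- c(warn, paste0("missing seed(s) auto-filled in manifest: ",
                           paste(missing_seeds, collapse = ", ")))
  }
  for (nm in names(config$inputs)) {
    p <- config$inputs[[nm]]
    if (!is.null(p) && !file.exists(p)) {
      fail <- c(fail, paste0("external input '", nm, "' does not exist: ", p))
    }
  }
  list(ok = length(fail) == 0, failures = fail, warnings = warn)
}

#' Run the full analysis pipeline
#'
#' simulate -> fc -> harmonize -> groupdiff (edge NBS + network tests) ->
#' net-t -> expression -> pls (surrogate permutation + bootstrap z) ->
#' enrich. Stages whose inputs are supplied in `config$inputs` are skipped.
#' Writes all artifacts plus a manifest JSON under `outdir`.
#'
#' @param config a `tx_config` (see [pipeline_config()]).
#' @param outdir output directory.
#' @return invisibly, the manifest (also written to `manifest.json`).
#' @export
run_all <- function(config = pipeline_config(), outdir = tempfile("txconn_run")) {
  rep <- validate_config(config)
  if (!rep$ok) stop("invalid config: ", paste(rep$failures, collapse = "; "))
  # auto-fill any missing seeds deterministically
  need_seeds <- c("simulate", "nbs", "network", "surrogates", "bootstrap",
                  "genesets", "expression", "match")
  for (i in seq_along(need_seeds)) {
    if (is.null(config$seeds[[need_seeds[i]]])) {
      config$seeds[[need_seeds[i]]] <- 1000L + i
    }
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  artifacts <- list()
  put <- function(key, fname) {
    artifacts[[key]] <<- fname
    file.path(outdir, fname)
  }

  ## ---- simulate / load inputs ----
  effect <- effect_spec(network_pairs = config$network_pairs,
                        delta = config$delta,
                        n_planted_genes = config$n_planted_genes,
                        spatial_corr_length = config$spatial_corr_length)
  if (!is.null(config$inputs$atlas)) {
    atlas <- read_atlas(config$inputs$atlas)
  } else {
    atlas <- generate_atlas(config$n_regions, seed = config$seeds$simulate)
    write_atlas(atlas, put("atlas", "atlas.tsv"))
  }
  if (!is.null(config$inputs$fc_stack)) {
    if (is.null(config$inputs$subjects)) {
      stop("stage 'simulate' skipped but no subjects table given: supply ",
           "inputs$subjects alongside inputs$fc_stack")
    }
    fc <- read_fc_stack(config$inputs$fc_stack, format = "long")
    covs <- utils::read.table(config$inputs$subjects, sep = "\t",
                              header = TRUE, stringsAsFactors = FALSE)
    covs <- covs[match(names(fc), covs$subject_id), , drop = FALSE]
    if (any(is.na(covs$subject_id))) {
      stop("subjects table does not cover all subjects in the FC stack")
    }
    group <- assign_groups(covs, hama_cut = config$hama_cut)
  } else {
    cohort <- generate_cohort(
      atlas, config$n_group1, config$n_group2, config$n_timepoints,
      sites = config$sites, effect = effect, seed = config$seeds$simulate
    )
    covs_all <- cohort_covariates(cohort)
    incl <- apply_inclusion_criteria(covs_all, fd_max = config$fd_max,
                                     hamd_min_exclusive = config$hamd_remission,
                                     quality_min = config$quality_min)
    keep_ids <- incl$included$subject_id
    cohort$subjects <- Filter(function(s) s$subject_id %in% keep_ids,
                              cohort$subjects)
    covs <- incl$included
    utils::write.table(covs, put("subjects", "subjects.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    group <- assign_groups(covs, hama_cut = config$hama_cut)
    ## ---- fc ----
    fc <- cohort_fc(cohort)
    ## ---- harmonize ----
    if (length(unique(covs$site)) > 1) {
      fc <- combat_harmonize(fc, covs$site,
                             covs[, config$protected_covariates, drop = FALSE])
      names(fc) <- covs$subject_id
    }
    write_fc_stack(fc, put("fc", "fc_long.tsv"), format = "long")
  }

  ## ---- groupdiff ----
  nuis <- covs[, config$nuisance_covariates, drop = FALSE]
  nbs <- nbs_correct(fc, group, nuis, edge_p = config$edge_p,
                     alpha = config$alpha, n_perm = config$n_perm,
                     seed = config$seeds$nbs)
  write_nbs_json(nbs, put("nbs", "nbs_result.json"))
  net_stack <- lapply(fc, network_average, atlas = atlas)
  nett <- network_ttest(net_stack, group, nuis, n_perm = config$n_perm,
                        alpha = config$alpha, seed = config$seeds$network)
  utils::write.table(
    data.frame(cell = paste(rownames(nett$t)[row(nett$t)[upper.tri(nett$t, diag = TRUE)]],
                            colnames(nett$t)[col(nett$t)[upper.tri(nett$t, diag = TRUE)]],
                            sep = "-"),
               t = nett$t[upper.tri(nett$t, diag = TRUE)],
               p_fwe = nett$p_fwe[upper.tri(nett$p_fwe, diag = TRUE)]),
    put("network", "network_stats.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE
  )

  ## ---- net t-value ----
  scores_all <- net_t_value(nbs, region_ids = atlas$region_id)
  lh <- atlas$region_id[atlas$hemisphere == "L"]
  scores_lh <- scores_all[as.character(lh)]
  write_region_scores(scores_lh, put("net_t", "net_t_left.tsv"))

  ## ---- expression ----
  if (!is.null(config$inputs$expression)) {
    expr <- read_expression(config$inputs$expression)
    planted <- character(0)
  } else {
    donor <- generate_donor_expression(
      atlas, n_donors = config$n_donors, n_genes = config$n_genes,
      target_map = scores_all, effect = effect,
      seed = config$seeds$expression
    )
    expr <- process_expression(donor, atlas,
                               min_fraction = config$min_probe_fraction,
                               max_dist_mm = config$max_dist_mm)
    # genes can drop out during probe filtering
    planted <- intersect(donor$planted_genes, colnames(expr))
    write_expression(expr, put("expression", "expression.tsv"))
  }

  ## ---- pls ----
  common <- intersect(rownames(expr), names(scores_lh))
  X <- unclass(expr)[common, , drop = FALSE]
  y <- scores_lh[common]
  centroids <- as.matrix(atlas[match(as.integer(common), atlas$region_id),
                               c("x", "y", "z")])
  model <- simpls_fit(X, y, K = config$n_components, quiet = TRUE)
  sel <- select_component(model)
  surr <- surrogate_maps(y, centroids, N = config$n_surrogates,
                         seed = config$seeds$surrogates)
  ptest <- permutation_test(X, y, surr, K = config$n_components)
  gw <- bootstrap_gene_weights(X, y, K = config$n_components,
                               B = config$n_boot,
                               seed = config$seeds$bootstrap)
  utils::write.table(gw, put("gene_weights", "gene_weights.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  sel_genes <- select_genes(gw, z_thresh = config$z_thresh)
  write_gene_list(sel_genes$positive, put("genes_pos", "genes_positive.txt"))
  write_gene_list(sel_genes$negative, put("genes_neg", "genes_negative.txt"))
  pls_summary <- list(
    y_varexp = model$y_varexp, x_varexp = model$x_varexp,
    selected_component = sel, observed = ptest$observed, p_perm = ptest$p,
    score_y_correlation = stats::cor(model$scores[, sel], y),
    n_regions = length(y), n_genes = ncol(X),
    counts = as.list(sel_genes$counts)
  )
  jsonlite::write_json(pls_summary, put("pls", "pls_summary.json"),
                       auto_unbox = TRUE, digits = NA)

  ## ---- enrich ----
  if (!is.null(config$inputs$gmt)) {
    sets <- read_gmt(config$inputs$gmt)
  } else {
    sets <- generate_gene_sets(colnames(X), planted,
                               n_terms = config$n_terms,
                               term_size_range = config$term_size_range,
                               seed = config$seeds$genesets)
    write_gmt(sets, put("gmt", "gene_sets.gmt"))
  }
  ora <- hypergeom_ora(c(sel_genes$positive, sel_genes$negative),
                       colnames(X), sets)
  utils::write.table(ora, put("enrichment", "enrichment.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  ## ---- manifest ----
  cfg_for_hash <- unclass(config)
  cfg_json <- jsonlite::toJSON(cfg_for_hash, auto_unbox = TRUE, digits = NA,
                               null = "null")
  manifest <- list(
    package = "txconn",
    version = as.character(utils::packageVersion("txconn")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config_hash = fnv1a_hash(as.character(cfg_json)),
    seeds = config$seeds,
    artifacts = artifacts,
    summary = list(
      n_included = if (!is.null(covs)) nrow(covs) else NA,
      n_significant_components = length(nbs$significant),
      selected_component = sel,
      p_perm = ptest$p,
      n_genes_selected = unname(sel_genes$counts["total"]),
      top_term = if (nrow(ora)) ora$term[1L] else NA
    )
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
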