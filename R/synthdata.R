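#' Effect specification for synthetic cohorts and expression data
#'
#' Bundles the planted "ground truth" of a simulation: which between-network
#' FC edges are perturbed and by how much (correlation-scale delta added to
#' group 2), how many genes are spatially coupled to the resulting regional
#' map, the spatial autocorrelation length of the expression field, and
#' per-site affine effects acting on the latent correlation scale.
#'
#' @param network_pairs list of length-2 character vectors naming network
#'   pairs to perturb, e.g. `list(c("SC","VN"), c("SC","DAN"))`.
#' @param delta correlation-scale difference added to group-2 subjects on the
#'   perturbed edges.
#' @param n_planted_genes number of genes spatially coupled to the target map.
#' @param spatial_corr_length squared-exponential kernel length scale in mm.
#' @param site_offsets named numeric vector, additive per-site offset applied
#'   to the latent off-diagonal correlations (NULL = all 0).
#' @param site_scales named numeric vector, multiplicative per-site scale on
#'   the latent off-diagonal correlations (NULL = all 1).
#' @return an object of class `tx_effect`.
#' @export
effect_spec <- function(network_pairs = list(c("SC", "VN"), c("SC", "DAN")),
                        delta = 0.3,
                        n_planted_genes = 20,
                        spatial_corr_length = 30,
                        site_offsets = NULL,
                        site_scales = NULL) {
  stopifnot(is.list(network_pairs))
  for (p in network_pairs) {
    if (length(p) != 2L || !all(p %in% tx_networks())) {
      stop("each network pair must be two of: ", paste(tx_networks(), collapse = ", "))
    }
  }
  if (spatial_corr_length <= 0) stop("spatial_corr_length must be > 0")
  structure(
    list(
      network_pairs = network_pairs,
      delta = delta,
      n_planted_genes = as.integer(n_planted_genes),
      spatial_corr_length = spatial_corr_length,
      site_offsets = site_offsets,
      site_scales = site_scales
    ),
    class = "tx_effect"
  )
}

#' Generate synthetic atlas metadata
#'
#' Regions are assigned to the seven canonical networks by `proportions`
#' (largest-remainder apportionment, at least two regions per network) and
#' given centroids in a bounded stereotaxic box. Within each network half the
#' regions (rounded up) are placed in the left hemisphere (x < 0).
#'
#' @param n_regions total number of regions (>= 14, two per network).
#' @param network_proportions optional numeric vector of length 7 (order of
#'   [tx_networks()]) summing to 1; NULL = uniform.
#' @param seed integer seed.
#' @return data.frame of class `tx_atlas` with columns region_id (0-based,
#'   contiguous), name, x, y, z (mm), network, hemisphere.
#' @export
generate_atlas <- function(n_regions = 160, network_proportions = NULL, seed = 1) {
  nets <- tx_networks()
  if (n_regions < 2L * length(nets)) {
    stop("n_regions must be >= ", 2L * length(nets),
         " to place at least two regions in each of the 7 networks")
  }
  if (is.null(network_proportions)) {
    network_proportions <- rep(1 / length(nets), length(nets))
  }
  if (length(network_proportions) != length(nets) ||
      abs(sum(network_proportions) - 1) > 1e-8) {
    stop("network_proportions must have length 7 and sum to 1")
  }
  # largest-remainder apportionment with a floor of 2 per network
  raw <- network_proportions * n_regions
  counts <- pmax(2L, floor(raw))
  while (sum(counts) > n_regions) {
    i <- which(counts > 2L)[which.max(counts[counts > 2L] - raw[counts > 2L])]
    counts[i] <- counts[i] - 1L
  }
  rem <- raw - counts
  while (sum(counts) < n_regions) {
    i <- which.max(rem)
    counts[i] <- counts[i] + 1L
    rem[i] <- rem[i] - 1
  }
  with_seed(seed, {
    network <- rep(nets, counts)
    n <- length(network)
    hemi <- unlist(lapply(counts, function(k) {
      rep(c("L", "R"), c(ceiling(k / 2), floor(k / 2)))
    }), use.names = FALSE)
    # x sign pinned by hemisphere; y, z uniform in a brain-sized box
    xmag <- stats::runif(n, 5, 70)
    x <- ifelse(hemi == "L", -xmag, xmag)
    y <- stats::runif(n, -100, 70)
    z <- stats::runif(n, -45, 75)
    atlas <- data.frame(
      region_id = 0:(n - 1L),
      name = sprintf("%s_%s_%03d", network, hemi, seq_len(n)),
      x = x, y = y, z = z,
      network = network,
      hemisphere = hemi,
      stringsAsFactors = FALSE
    )
    class(atlas) <- c("tx_atlas", "data.frame")
    atlas
  })
}

## Latent region-by-region correlation for one (group, site) cell.
## Block structure: fc_within inside networks, fc_between across, +delta on
## the perturbed network pairs (group 2 only), then a per-site affine map of
## the off-diagonal entries. Repaired to nearest PD when needed.
cohort_cor_matrix <- function(atlas, fc_within, fc_between, perturb_pairs,
                              delta, site_offset = 0, site_scale = 1,
                              repair = TRUE) {
  n <- nrow(atlas)
  net <- atlas$network
  C <- matrix(fc_between, n, n)
  for (k in unique(net)) {
    idx <- which(net == k)
    C[idx, idx] <- fc_within
  }
  if (length(perturb_pairs) > 0 && delta != 0) {
    for (p in perturb_pairs) {
      a <- which(net == p[1L]); b <- which(net == p[2L])
      C[a, b] <- C[a, b] + delta
      C[b, a] <- C[b, a] + delta
    }
  }
  off <- site_scale * C + site_offset
  off <- pmin(pmax(off, -0.95), 0.95)
  C <- off
  diag(C) <- 1
  ev_min <- min(eigen(C, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < 1e-6) {
    if (!repair) {
      stop("latent correlation matrix is not positive definite (min eigenvalue ",
           format(ev_min), "); rerun with repair = TRUE to apply nearest-PD ",
           "eigenvalue clipping")
    }
    C <- nearest_pd(C, eps = 1e-6)
  }
  C
}

#' Generate a two-group multi-site synthetic cohort
#'
#' Subjects carry regional time series drawn from a multivariate normal with
#' block network correlation structure. Group 2 ("anxious" group) receives the
#' effect's `delta` on the perturbed between-network edges. Site effects act
#' as affine transforms of the latent correlations. Clinical scores are drawn
#' so that group labels are recoverable from the HAMA > 18 rule.
#'
#' @param atlas a `tx_atlas`.
#' @param n_group1,n_group2 subjects per group (group 2 carries the effect and
#'   HAMA > 18).
#' @param n_timepoints time points per subject (warn if < 2 * n_regions).
#' @param sites character vector of site labels (subjects assigned cyclically).
#' @param effect a [effect_spec()].
#' @param seed integer seed.
#' @param fc_within,fc_between baseline within-/between-network correlations.
#' @param age_shift additive mean age difference of group 2 (years).
#' @param repair repair non-PD latent correlation by eigenvalue clipping
#'   (default TRUE); if FALSE a non-PD matrix is an error.
#' @return object of class `tx_cohort`: list with `subjects` (list of
#'   `tx_subject` records), `atlas`, and `config`.
#' @export
generate_cohort <- function(atlas, n_group1, n_group2, n_timepoints = 200,
                            sites = "site1", effect = effect_spec(),
                            seed = 1, fc_within = 0.5, fc_between = 0.1,
                            age_shift = 8, repair = TRUE) {
  stopifnot(inherits(atlas, "tx_atlas"))
  if (n_timepoints < 2) stop("n_timepoints must be >= 2")
  if (length(sites) < 1) stop("at least one site is required")
  R <- nrow(atlas)
  if (n_timepoints < 2 * R) {
    warning("n_timepoints < 2 * n_regions: per-subject correlation estimates ",
            "may be rank-deficient/noisy")
  }
  offsets <- effect$site_offsets
  scales <- effect$site_scales
  if (is.null(offsets)) offsets <- stats::setNames(rep(0, length(sites)), sites)
  if (is.null(scales)) scales <- stats::setNames(rep(1, length(sites)), sites)

  n_total <- n_group1 + n_group2
  group <- rep(c(1L, 2L), c(n_group1, n_group2))
  site <- rep_len(sites, n_total)

  # one Cholesky factor per (group, site) cell
  chol_cache <- list()
  for (g in 1:2) {
    for (s in sites) {
      C <- cohort_cor_matrix(
        atlas, fc_within, fc_between,
        perturb_pairs = if (g == 2L) effect$network_pairs else list(),
        delta = effect$delta,
        site_offset = offsets[[s]], site_scale = scales[[s]],
        repair = repair
      )
      chol_cache[[paste(g, s)]] <- chol(C)
    }
  }

  with_seed(seed, {
    subjects <- vector("list", n_total)
    for (i in seq_len(n_total)) {
      g <- group[i]
      U <- chol_cache[[paste(g, site[i])]]
      ts <- matrix(stats::rnorm(n_timepoints * R), n_timepoints, R) %*% U
      colnames(ts) <- atlas$region_id
      hama <- if (g == 2L) {
        max(19L, round(stats::rnorm(1, 25, 4)))
      } else {
        min(18L, max(0L, round(stats::rnorm(1, 13, 4))))
      }
      hamd <- max(8L, round(stats::rnorm(1, if (g == 2L) 23 else 19, 4)))
      subjects[[i]] <- structure(list(
        subject_id = sprintf("sub%04d", i),
        site = site[i],
        age = min(65, max(18, round(stats::rnorm(1, 30 + (g == 2L) * age_shift, 11)))),
        sex = if (stats::runif(1) < (if (g == 2L) 0.69 else 0.58)) "F" else "M",
        education = min(22, max(0, round(stats::rnorm(1, 12, 3)))),
        fd = stats::rlnorm(1, log(0.06), 0.5),
        hamd = hamd,
        hama = hama,
        quality_score = sample(4:5, 1),
        group = g,
        timeseries = ts
      ), class = "tx_subject")
    }
    structure(
      list(
        subjects = subjects,
        atlas = atlas,
        config = list(
          n_group1 = n_group1, n_group2 = n_group2,
          n_timepoints = n_timepoints, sites = sites, effect = effect,
          fc_within = fc_within, fc_between = fc_between, seed = seed
        )
      ),
      class = "tx_cohort"
    )
  })
}

#' Covariate table of a cohort
#'
#' @param cohort a `tx_cohort` or list of `tx_subject`.
#' @return data.frame with one row per subject.
#' @export
cohort_covariates <- function(cohort) {
  subjects <- if (inherits(cohort, "tx_cohort")) cohort$subjects else cohort
  do.call(rbind, lapply(subjects, function(s) {
    data.frame(
      subject_id = s$subject_id, site = s$site, age = s$age, sex = s$sex,
      education = s$education, fd = s$fd, hamd = s$hamd, hama = s$hama,
      quality_score = s$quality_score,
      stringsAsFactors = FALSE
    )
  }))
}

#' Generate donor microarray-style expression tables
#'
#' Emulates multi-donor post-mortem sampling: tissue samples are placed near
#' region centroids with Gaussian jitter, probes measure a latent regional
#' gene profile with noise, a planted subset of genes is spatially coupled to
#' `target_map`, decoy genes follow an independent spatially autocorrelated
#' Gaussian process, a fraction of probes is flagged below background in most
#' samples, and some genes carry a second, noisier probe.
#'
#' @param atlas a `tx_atlas`.
#' @param n_donors number of donors (default 6; only `n_rh_donors` of them
#'   have right-hemisphere samples, default 2).
#' @param n_genes total genes.
#' @param target_map numeric vector over atlas regions (the map planted genes
#'   track); names or order must follow `atlas$region_id`.
#' @param effect a [effect_spec()] (uses `n_planted_genes`,
#'   `spatial_corr_length`).
#' @param seed integer seed.
#' @param samples_per_region Poisson mean of samples per region per donor.
#' @param jitter_sd isotropic Gaussian jitter of sample coordinates (mm).
#' @param coupling coefficient `a` linking planted genes to the standardized
#'   target map.
#' @param gp_noise_sd sd of the spatially autocorrelated noise field added to
#'   planted genes (decoys are pure unit-variance GP fields).
#' @param probe_noise_sd measurement noise of a good probe.
#' @param two_probe_frac fraction of genes carrying a second (noisier) probe.
#' @param low_quality_frac fraction of probes flagged above background in only
#'   ~35% of samples (others ~90%).
#' @param n_rh_donors number of donors that also have right-hemisphere samples.
#' @return list of class `tx_donor_data`: `donors` (per-donor list with
#'   `samples` data.frame, `intensities` and `above_bg` matrices),
#'   `probes` (probe_id, gene_symbol), `reference` (samples x genes RNA-seq
#'   style reference), `regional_truth` (regions x genes latent profile),
#'   `planted_genes`, `config`.
#' @export
generate_donor_expression <- function(atlas, n_donors = 6, n_genes = 500,
                                      target_map, effect = effect_spec(),
                                      seed = 1, samples_per_region = 1,
                                      jitter_sd = 3, coupling = 1,
                                      gp_noise_sd = 0.3, probe_noise_sd = 0.2,
                                      two_probe_frac = 0.1,
                                      low_quality_frac = 0.1,
                                      n_rh_donors = 2) {
  stopifnot(inherits(atlas, "tx_atlas"))
  R <- nrow(atlas)
  if (length(target_map) != R) {
    stop("target_map must have one value per atlas region")
  }
  n_planted <- effect$n_planted_genes
  if (n_planted > n_genes) stop("n_planted_genes exceeds n_genes")
  if (effect$spatial_corr_length <= 0) stop("kernel length must be positive")

  D <- coord_dist(as.matrix(atlas[, c("x", "y", "z")]))
  K <- sq_exp_kernel(D, effect$spatial_corr_length)
  genes <- sprintf("g%04d", seq_len(n_genes))
  tz <- as.numeric(scale(target_map))

  with_seed(seed, {
    planted <- sort(sample(genes, n_planted))
    truth <- matrix(0, R, n_genes, dimnames = list(atlas$region_id, genes))
    for (g in seq_len(n_genes)) {
      field <- gp_sample(K)
      field <- field / stats::sd(field)
      truth[, g] <- if (genes[g] %in% planted) {
        coupling * tz + gp_noise_sd * field
      } else {
        field
      }
    }

    # probe design: every gene has one good probe; a fraction gets a second,
    # attenuated + noisier probe (lower reference correlation)
    two_probe <- sample(genes, round(two_probe_frac * n_genes))
    probes <- data.frame(
      probe_id = sprintf("probe_%05d", seq_len(n_genes + length(two_probe))),
      gene_symbol = c(genes, two_probe),
      quality = c(rep("good", n_genes), rep("poor", length(two_probe))),
      stringsAsFactors = FALSE
    )
    n_probes <- nrow(probes)
    low_q <- sample(probes$probe_id, round(low_quality_frac * n_probes))
    p_above <- ifelse(probes$probe_id %in% low_q, 0.35, 0.9)

    donors <- vector("list", n_donors)
    ref_rows <- list()
    for (d in seq_len(n_donors)) {
      has_rh <- d <= n_rh_donors
      keep_regions <- which(atlas$hemisphere == "L" | has_rh)
      counts <- stats::rpois(length(keep_regions), samples_per_region)
      # guarantee at least one sample per donor
      if (sum(counts) == 0) counts[sample(length(counts), 1)] <- 1L
      reg_idx <- rep(keep_regions, counts)
      n_samp <- length(reg_idx)
      coords <- as.matrix(atlas[reg_idx, c("x", "y", "z")]) +
        matrix(stats::rnorm(3 * n_samp, 0, jitter_sd), n_samp, 3)
      samples <- data.frame(
        donor_id = sprintf("donor%02d", d),
        sample_id = sprintf("d%02d_s%04d", d, seq_len(n_samp)),
        x = coords[, 1], y = coords[, 2], z = coords[, 3],
        structure_class = ifelse(atlas$network[reg_idx] == "SC",
                                 "subcortex", "cortex"),
        hemisphere = atlas$hemisphere[reg_idx],
        region_true = atlas$region_id[reg_idx],
        stringsAsFactors = FALSE
      )
      base <- truth[reg_idx, , drop = FALSE]            # samples x genes
      ref <- base + matrix(stats::rnorm(n_samp * n_genes, 0, 0.05),
                           n_samp, n_genes)
      colnames(ref) <- genes
      rownames(ref) <- samples$sample_id
      intens <- matrix(0, n_samp, n_probes,
                       dimnames = list(samples$sample_id, probes$probe_id))
      for (p in seq_len(n_probes)) {
        gcol <- base[, probes$gene_symbol[p]]
        if (probes$quality[p] == "good") {
          intens[, p] <- gcol + stats::rnorm(n_samp, 0, probe_noise_sd)
        } else {
          intens[, p] <- 0.3 * gcol + stats::rnorm(n_samp, 0, 3 * probe_noise_sd)
        }
      }
      above <- matrix(stats::rbinom(n_samp * n_probes, 1,
                                    rep(p_above, each = n_samp)) == 1L,
                      n_samp, n_probes,
                      dimnames = list(samples$sample_id, probes$probe_id))
      donors[[d]] <- list(samples = samples, intensities = intens,
                          above_bg = above)
      ref_rows[[d]] <- ref
    }
    structure(
      list(
        donors = donors,
        probes = probes[, c("probe_id", "gene_symbol")],
        reference = do.call(rbind, ref_rows),
        regional_truth = truth,
        planted_genes = planted,
        config = list(n_donors = n_donors, n_genes = n_genes,
                      samples_per_region = samples_per_region,
                      jitter_sd = jitter_sd, coupling = coupling,
                      gp_noise_sd = gp_noise_sd,
                      probe_noise_sd = probe_noise_sd, seed = seed)
      ),
      class = "tx_donor_data"
    )
  })
}

#' Generate a gene-set collection with one planted term
#'
#' The planted term contains every planted gene plus at most 25% random
#' filler (so planted genes are >= 80% of the term); decoy terms are uniform
#' draws from the universe. With no planted genes only decoys are emitted.
#'
#' @param gene_universe character vector of gene symbols.
#' @param planted_genes subset of the universe (may be empty).
#' @param n_terms total number of terms (including the planted one when
#'   present).
#' @param term_size_range length-2 integer range of decoy term sizes.
#' @param seed integer seed.
#' @return object of class `tx_genesets`: named list of
#'   `list(description, genes)`.
#' @export
generate_gene_sets <- function(gene_universe, planted_genes = character(),
                               n_terms = 20, term_size_range = c(10, 50),
                               seed = 1) {
  if (!all(planted_genes %in% gene_universe)) {
    stop("planted_genes must be a subset of gene_universe")
  }
  if (max(term_size_range) > length(gene_universe)) {
    stop("term sizes exceed the size of the gene universe")
  }
  with_seed(seed, {
    sets <- list()
    if (length(planted_genes) > 0) {
      n_fill <- min(floor(length(planted_genes) / 4),
                    length(setdiff(gene_universe, planted_genes)))
      fill <- sample(setdiff(gene_universe, planted_genes), n_fill)
      sets[["PLANTED_SET"]] <- list(
        description = "planted term containing the spatially coupled genes",
        genes = sort(unique(c(planted_genes, fill)))
      )
    }
    n_decoy <- n_terms - length(sets)
    for (k in seq_len(n_decoy)) {
      sz <- sample(term_size_range[1]:term_size_range[2], 1)
      sets[[sprintf("DECOY_%03d", k)]] <- list(
        description = "decoy term drawn uniformly from the universe",
        genes = sort(sample(gene_universe, sz))
      )
    }
    structure(sets, class = "tx_genesets")
  })
}
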