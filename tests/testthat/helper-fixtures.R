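# Fixtures built in code (no binary files): tiny deterministic atlases,
# hand-crafted donor tables, and small cohorts shared across test files.

# Atlas with explicit centroids, one region per row; defaults give well
# separated centroids so nearest-centroid assignment is unambiguous.
toy_atlas <- function(networks = c("SMN", "VAN", "VN", "DAN", "DMN", "FPN", "SC"),
                      hemisphere = rep("L", length(networks)),
                      x = NULL) {
  n <- length(networks)
  if (is.null(x)) x <- ifelse(hemisphere == "L", -40, 40)
  atlas <- data.frame(
    region_id = 0:(n - 1L),
    name = sprintf("r%02d", seq_len(n)),
    x = x,
    y = seq(0, by = 40, length.out = n),
    z = 0,
    network = networks,
    hemisphere = hemisphere,
    stringsAsFactors = FALSE
  )
  class(atlas) <- c("tx_atlas", "data.frame")
  atlas
}

# Donor table in the generate_donor_expression() layout, built from explicit
# matrices. `coords` rows align with samples.
toy_donor <- function(donor_id, coords, intensities, above_bg,
                      structure_class = "cortex", hemisphere = "L",
                      region_true = NA_integer_) {
  n <- nrow(coords)
  samples <- data.frame(
    donor_id = donor_id,
    sample_id = sprintf("%s_s%03d", donor_id, seq_len(n)),
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    structure_class = rep_len(structure_class, n),
    hemisphere = rep_len(hemisphere, n),
    region_true = rep_len(region_true, n),
    stringsAsFactors = FALSE
  )
  rownames(intensities) <- samples$sample_id
  rownames(above_bg) <- samples$sample_id
  list(samples = samples, intensities = intensities, above_bg = above_bg)
}

# Small null/planted cohort used by several group-difference tests.
small_cohort <- function(seed, delta = 0, n = 20, R = 21, T_ = 100,
                         sites = "s1", fc_within = 0.5, fc_between = 0.1) {
  a <- generate_atlas(R, seed = 1)
  eff <- effect_spec(delta = delta)
  co <- suppressWarnings(generate_cohort(a, n, n, T_, sites = sites,
                                         effect = eff, seed = seed,
                                         fc_within = fc_within,
                                         fc_between = fc_between))
  list(atlas = a, cohort = co, covs = cohort_covariates(co))
}

# Classical pooled-variance two-sample t (independent oracle for the edge GLM).
pooled_t <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  sp2 <- ((n1 - 1) * var(x1) + (n2 - 1) * var(x2)) / (n1 + n2 - 2)
  (mean(x2) - mean(x1)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}
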