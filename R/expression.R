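#' Filter probes by above-background intensity fraction
#'
#' Keeps a probe iff the fraction of samples (pooled over donors) in which it
#' is flagged above background is at least `min_fraction`. The 50% boundary is
#' inclusive (kept).
#'
#' @param donor_tables list of donor tables (each with an `above_bg` logical
#'   matrix, samples x probes), e.g. `tx_donor_data$donors`.
#' @param probes data.frame with probe_id, gene_symbol.
#' @param min_fraction minimum pooled above-background fraction (default 0.5).
#' @return probe data.frame restricted to surviving probes, with an
#'   `above_fraction` column.
#' @export
filter_probes_by_intensity <- function(donor_tables, probes, min_fraction = 0.5) {
  if (inherits(donor_tables, "tx_donor_data")) {
    probes <- donor_tables$probes
    donor_tables <- donor_tables$donors
  }
  flags <- do.call(rbind, lapply(donor_tables, `[[`, "above_bg"))
  if (is.null(flags)) stop("donor tables carry no above-background flags")
  frac <- colMeans(flags)
  keep <- names(frac)[frac >= min_fraction]
  if (length(keep) == 0) {
    stop("no probes exceed the background threshold of ", min_fraction)
  }
  out <- probes[probes$probe_id %in% keep, , drop = FALSE]
  out$above_fraction <- frac[out$probe_id]
  rownames(out) <- NULL
  out
}

#' Select one probe per gene
#'
#' With a reference profile (samples x genes matrix standing in for RNA-seq),
#' keeps per gene the probe whose pooled intensities have maximal Spearman
#' correlation with the gene's reference vector; without a reference, the
#' probe with the highest mean intensity. Ties break by lexicographically
#' smaller probe_id. Genes whose probes were all filtered out upstream are
#' simply absent.
#'
#' @param donor_tables list of donor tables with `intensities` matrices (or a
#'   `tx_donor_data`).
#' @param probes surviving probe table (probe_id, gene_symbol).
#' @param reference optional samples x genes numeric matrix, rows aligned with
#'   the pooled sample order of `donor_tables`.
#' @return probe data.frame with one row per retained gene, plus the selection
#'   criterion value in `criterion`.
#' @export
select_probe_per_gene <- function(donor_tables, probes, reference = NULL) {
  if (inherits(donor_tables, "tx_donor_data")) {
    if (is.null(reference)) reference <- donor_tables$reference
    donor_tables <- donor_tables$donors
  }
  intens <- do.call(rbind, lapply(donor_tables, `[[`, "intensities"))
  intens <- intens[, probes$probe_id, drop = FALSE]
  crit <- numeric(nrow(probes))
  if (!is.null(reference)) {
    if (nrow(reference) != nrow(intens)) {
      stop("reference profile rows must align with pooled samples")
    }
    for (k in seq_len(nrow(probes))) {
      g <- probes$gene_symbol[k]
      crit[k] <- if (g %in% colnames(reference)) {
        stats::cor(intens[, k], reference[, g], method = "spearman")
      } else {
        NA_real_
      }
    }
  } else {
    crit <- colMeans(intens)
  }
  ord <- order(probes$gene_symbol, -crit, probes$probe_id)
  picked <- probes[ord, , drop = FALSE]
  picked$criterion <- crit[ord]
  picked <- picked[!duplicated(picked$gene_symbol), , drop = FALSE]
  picked <- picked[order(picked$gene_symbol), , drop = FALSE]
  rownames(picked) <- NULL
  picked
}

#' Assign tissue samples to atlas regions by nearest centroid
#'
#' Each sample goes to the nearest region centroid (Euclidean distance) if
#' within `max_dist_mm`, else it stays unassigned (region_id NA). Distance
#' ties break toward the smaller region_id.
#'
#' @param samples data.frame with sample_id and x, y, z columns (one donor or
#'   pooled), or a `tx_donor_data` (all donors pooled).
#' @param atlas a `tx_atlas`.
#' @param max_dist_mm maximum assignment distance (default 10).
#' @return data.frame sample_id, region_id (NA if unassigned), distance.
#' @export
assign_samples_to_regions <- function(samples, atlas, max_dist_mm = 10) {
  if (inherits(samples, "tx_donor_data")) {
    samples <- do.call(rbind, lapply(samples$donors, `[[`, "samples"))
  }
  cent <- as.matrix(atlas[, c("x", "y", "z")])
  pts <- as.matrix(samples[, c("x", "y", "z")])
  # squared distances via the expansion |a-b|^2 = |a|^2 + |b|^2 - 2 a.b
  d2 <- outer(rowSums(pts^2), rowSums(cent^2), "+") - 2 * pts %*% t(cent)
  d2[d2 < 0] <- 0
  # ties toward smaller region_id: atlas rows are already in region_id order,
  # and which.min returns the first minimum
  nearest <- apply(d2, 1L, which.min)
  dist <- sqrt(d2[cbind(seq_len(nrow(pts)), nearest)])
  region <- atlas$region_id[nearest]
  region[dist > max_dist_mm] <- NA_integer_
  data.frame(
    sample_id = samples$sample_id,
    region_id = region,
    distance = dist,
    stringsAsFactors = FALSE
  )
}

## Scaled robust sigmoid of a vector: sigmoid((x - median) / (IQR / 1.35)),
## then min-max rescaled to [0, 1]. Constant input maps to 0.5.
scaled_robust_sigmoid <- function(x) {
  iqr <- stats::IQR(x)
  if (iqr == 0 || !is.finite(iqr)) {
    return(rep(0.5, length(x)))
  }
  s <- 1 / (1 + exp(-(x - stats::median(x)) / (iqr / 1.35)))
  rng <- range(s)
  if (rng[1] == rng[2]) rep(0.5, length(x)) else (s - rng[1]) / (rng[2] - rng[1])
}

#' Normalize and aggregate donor samples into a region-by-gene matrix
#'
#' Left-hemisphere samples only. Per donor and structure class, each gene is
#' passed through a scaled robust sigmoid across samples (constant genes map
#' to 0.5); samples are then averaged within region per donor, and finally
#' regions are averaged across the donors that have data there. Output rows
#' are the left-hemisphere atlas regions; regions without any sample are
#' dropped and recorded in the `missing_regions` attribute.
#'
#' @param assignment output of [assign_samples_to_regions()] over the pooled
#'   samples.
#' @param donor_tables list of donor tables (or `tx_donor_data`).
#' @param atlas a `tx_atlas`.
#' @param probes one-probe-per-gene table from [select_probe_per_gene()].
#' @return `tx_expression`: numeric matrix (rownames = region_id, colnames =
#'   gene symbols) with attribute `missing_regions`.
#' @export
normalize_and_aggregate <- function(assignment, donor_tables, atlas, probes) {
  if (inherits(donor_tables, "tx_donor_data")) donor_tables <- donor_tables$donors
  lh_regions <- atlas$region_id[atlas$hemisphere == "L"]
  genes <- probes$gene_symbol
  assign_map <- stats::setNames(assignment$region_id, assignment$sample_id)

  per_donor <- list()
  for (dt in donor_tables) {
    samp <- dt$samples
    keep <- samp$hemisphere == "L"
    samp <- samp[keep, , drop = FALSE]
    if (nrow(samp) == 0) next
    X <- dt$intensities[samp$sample_id, probes$probe_id, drop = FALSE]
    colnames(X) <- genes
    # normalization within donor x structure class
    for (cl in unique(samp$structure_class)) {
      rows <- which(samp$structure_class == cl)
      if (length(rows) >= 2) {
        X[rows, ] <- apply(X[rows, , drop = FALSE], 2L, scaled_robust_sigmoid)
      } else {
        X[rows, ] <- 0.5
      }
    }
    reg <- assign_map[samp$sample_id]
    ok <- !is.na(reg) & reg %in% lh_regions
    if (!any(ok)) next
    X <- X[ok, , drop = FALSE]
    reg <- reg[ok]
    agg <- rowsum(X, group = reg) / as.vector(table(reg))
    per_donor[[length(per_donor) + 1L]] <- agg
  }
  if (length(per_donor) == 0) {
    stop("no assigned left-hemisphere samples: cannot build expression matrix")
  }
  # cross-donor average over donors having data in each region
  all_regions <- sort(unique(unlist(lapply(per_donor, rownames))))
  acc <- matrix(0, length(all_regions), length(genes),
                dimnames = list(all_regions, genes))
  cnt <- matrix(0, length(all_regions), length(genes),
                dimnames = list(all_regions, genes))
  for (agg in per_donor) {
    acc[rownames(agg), ] <- acc[rownames(agg), ] + agg
    cnt[rownames(agg), ] <- cnt[rownames(agg), ] + 1
  }
  out <- acc / cnt
  out <- out[order(as.integer(rownames(out))), , drop = FALSE]
  missing <- setdiff(as.character(lh_regions), rownames(out))
  structure(out, missing_regions = as.integer(missing), class = "tx_expression")
}

#' Run the full expression-processing pipeline
#'
#' Probe intensity filter, probe selection, spatial assignment, normalization
#' and aggregation, in that fixed order.
#'
#' @param donor_data a `tx_donor_data`.
#' @param atlas a `tx_atlas`.
#' @param min_fraction probe above-background threshold.
#' @param max_dist_mm sample assignment radius (mm).
#' @param use_reference use the RNA-seq style reference for probe selection.
#' @return `tx_expression` matrix.
#' @export
process_expression <- function(donor_data, atlas, min_fraction = 0.5,
                               max_dist_mm = 10, use_reference = TRUE) {
  stopifnot(inherits(donor_data, "tx_donor_data"))
  surv <- filter_probes_by_intensity(donor_data$donors, donor_data$probes,
                                     min_fraction)
  picked <- select_probe_per_gene(
    donor_data$donors, surv,
    reference = if (use_reference) donor_data$reference else NULL
  )
  assignment <- assign_samples_to_regions(donor_data, atlas, max_dist_mm)
  normalize_and_aggregate(assignment, donor_data$donors, atlas, picked)
}
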