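#' Write / read atlas metadata as TSV
#'
#' Columns: region_id, name, x, y, z, network, hemisphere.
#'
#' @param atlas a `tx_atlas`.
#' @param path file path.
#' @return invisibly the path (write) / a `tx_atlas` (read).
#' @export
write_atlas <- function(atlas, path) {
  utils::write.table(atlas, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_atlas
#' @export
read_atlas <- function(path) {
  atlas <- utils::read.table(path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
  need <- c("region_id", "name", "x", "y", "z", "network", "hemisphere")
  if (!all(need %in% names(atlas))) {
    stop("atlas TSV must have columns: ", paste(need, collapse = ", "))
  }
  class(atlas) <- c("tx_atlas", "data.frame")
  atlas
}

#' Write a cohort to disk
#'
#' One covariate TSV, one T x R time-series TSV per subject (header =
#' region_ids), and a manifest JSON recording files, seed and config.
#'
#' @param cohort a `tx_cohort`.
#' @param dir output directory (created if needed).
#' @return invisibly the manifest path.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cov <- cohort_covariates(cohort)
  cov_path <- file.path(dir, "subjects.tsv")
  utils::write.table(cov, cov_path, sep = "\t", quote = FALSE, row.names = FALSE)
  ts_files <- character(length(cohort$subjects))
  for (i in seq_along(cohort$subjects)) {
    s <- cohort$subjects[[i]]
    ts_files[i] <- file.path(dir, paste0("ts_", s$subject_id, ".tsv"))
    utils::write.table(s$timeseries, ts_files[i], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  manifest <- list(
    covariates = basename(cov_path),
    timeseries = basename(ts_files),
    subject_ids = vapply(cohort$subjects, `[[`, "", "subject_id"),
    seed = cohort$config$seed,
    config = cohort$config[setdiff(names(cohort$config), "effect")]
  )
  mpath <- file.path(dir, "cohort_manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE)
  invisible(mpath)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing `cohort_manifest.json`.
#' @param atlas the `tx_atlas` the time series were generated from.
#' @return a `tx_cohort`.
#' @export
read_cohort <- function(dir, atlas) {
  manifest <- jsonlite::read_json(file.path(dir, "cohort_manifest.json"),
                                  simplifyVector = TRUE)
  cov <- utils::read.table(file.path(dir, manifest$covariates), sep = "\t",
                           header = TRUE, stringsAsFactors = FALSE)
  subjects <- vector("list", nrow(cov))
  for (i in seq_len(nrow(cov))) {
    ts <- as.matrix(utils::read.table(file.path(dir, manifest$timeseries[i]),
                                      sep = "\t", header = TRUE,
                                      check.names = FALSE))
    rec <- as.list(cov[i, ])
    rec$timeseries <- ts
    subjects[[i]] <- structure(rec, class = "tx_subject")
  }
  structure(list(subjects = subjects, atlas = atlas,
                 config = manifest$config),
            class = "tx_cohort")
}

#' Write / read an FC stack
#'
#' `format = "wide"` writes one R x R TSV per subject into a directory;
#' `format = "long"` writes a single TSV with columns subject_id, i, j, z
#' (upper triangle, 1-based region row/column indices).
#'
#' @param fc_stack named list of `tx_fc`.
#' @param path directory (wide) or file (long).
#' @param format `"wide"` or `"long"`.
#' @return invisibly the path.
#' @export
write_fc_stack <- function(fc_stack, path, format = c("long", "wide")) {
  format <- match.arg(format)
  if (format == "wide") {
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(fc_stack)) {
      utils::write.table(unclass(fc_stack[[nm]]),
                         file.path(path, paste0("fc_", nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE,
                         col.names = FALSE)
    }
  } else {
    R <- nrow(fc_stack[[1L]])
    pairs <- edge_pairs(R)
    rows <- lapply(names(fc_stack), function(nm) {
      data.frame(subject_id = nm, i = pairs$i, j = pairs$j,
                 z = ut_vec(fc_stack[[nm]]), stringsAsFactors = FALSE)
    })
    utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_fc_stack
#' @param n_regions number of regions (long format only; inferred from the
#'   maximum j if omitted).
#' @export
read_fc_stack <- function(path, format = c("long", "wide"), n_regions = NULL) {
  format <- match.arg(format)
  if (format == "wide") {
    files <- sort(list.files(path, pattern = "^fc_.*\\.tsv$", full.names = TRUE))
    out <- lapply(files, function(f) {
      m <- as.matrix(utils::read.table(f, sep = "\t", header = FALSE))
      dimnames(m) <- NULL
      structure(m, class = c("tx_fc", "matrix", "array"))
    })
    names(out) <- sub("^fc_(.*)\\.tsv$", "\\1", basename(files))
    out
  } else {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    if (is.null(n_regions)) n_regions <- max(df$j)
    split_rows <- split(df, df$subject_id)
    # preserve file order of subjects
    split_rows <- split_rows[unique(df$subject_id)]
    lapply(split_rows, function(d) {
      m <- matrix(0, n_regions, n_regions)
      m[cbind(d$i, d$j)] <- d$z
      m <- m + t(m)
      structure(m, class = c("tx_fc", "matrix", "array"))
    })
  }
}

#' Write / read an expression matrix as TSV
#'
#' Rows are region_ids (first column `region_id`), columns gene symbols.
#'
#' @param expr a `tx_expression` matrix.
#' @param path file path.
#' @return invisibly the path (write) / a `tx_expression` (read).
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(region_id = rownames(expr), as.data.frame(unclass(expr)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression
#' @export
read_expression <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$region_id
  structure(m, class = "tx_expression")
}

#' Write / read regional scores (e.g. net t-values) as TSV
#'
#' @param scores named numeric vector (names = region_id).
#' @param path file path.
#' @return invisibly the path (write) / named numeric vector (read).
#' @export
write_region_scores <- function(scores, path) {
  utils::write.table(
    data.frame(region_id = names(scores), score = as.numeric(scores)),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_region_scores
#' @export
read_region_scores <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  stats::setNames(df$score, df$region_id)
}

#' Serialize an NBS result to JSON
#'
#' Components as edge lists (1-based region indices), p-values, thresholds and
#' the permutation null distribution.
#'
#' @param nbs a `tx_nbs`.
#' @param path file path.
#' @return invisibly the path.
#' @export
write_nbs_json <- function(nbs, path) {
  obj <- list(
    components = lapply(nbs$components, function(e) {
      list(edges = as.matrix(e))
    }),
    sizes = nbs$sizes,
    p_values = nbs$p_values,
    significant = nbs$significant,
    thresholds = nbs$thresholds,
    null_max_size = nbs$null_max_size
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write gene lists as plain text (one symbol per line)
#'
#' @param genes character vector.
#' @param path file path.
#' @return invisibly the path.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(genes, path)
  invisible(path)
}
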