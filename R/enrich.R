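#' Read a GMT gene-set file
#'
#' Standard GMT: one term per line, tab-separated `name`, `description`,
#' then gene symbols (case-sensitive). Duplicate genes within a term are
#' deduplicated (with a message); duplicate term names are an error.
#'
#' @param path file path.
#' @return `tx_genesets`: named list of `list(description, genes)`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (ln in seq_along(lines)) {
    fields <- strsplit(lines[ln], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3) {
      stop("malformed GMT line ", ln, ": fewer than 3 tab-separated fields")
    }
    name <- fields[1L]
    if (name %in% names(sets)) stop("duplicate term name at line ", ln, ": ", name)
    genes <- fields[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      message("term '", name, "': duplicated genes deduplicated")
      genes <- unique(genes)
    }
    sets[[name]] <- list(description = fields[2L], genes = genes)
  }
  structure(sets, class = "tx_genesets")
}

#' Write a gene-set collection to GMT
#'
#' @param sets a `tx_genesets`.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, sets[[nm]]$description, sets[[nm]]$genes), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric over-representation analysis
#'
#' One-sided (enrichment) test per term: with population size N, term size K
#' (after intersecting with the population), selection size n and overlap k,
#' p = P(X >= k) for X ~ Hypergeometric(N, K, n). Terms smaller than
#' `min_term` or larger than `max_term` (default half the population) are
#' skipped. BH-FDR q-values are appended and results sorted by q then p.
#'
#' @param selected character vector of selected genes (subset of population).
#' @param population character vector, the analysis universe.
#' @param sets a `tx_genesets`.
#' @param min_term minimum term size after intersection (default 3).
#' @param max_term maximum term size (default floor(N / 2)).
#' @return data.frame: term, N, K, n, k, p, q, overlap (comma-separated).
#' @export
hypergeom_ora <- function(selected, population, sets, min_term = 3,
                          max_term = NULL) {
  population <- unique(population)
  N <- length(population)
  if (N == 0) stop("empty population")
  selected <- unique(intersect(selected, population))
  n <- length(selected)
  if (is.null(max_term)) max_term <- floor(N / 2)
  rows <- list()
  for (nm in names(sets)) {
    genes <- intersect(sets[[nm]]$genes, population)
    K <- length(genes)
    if (K < min_term || K > max_term) next
    hits <- intersect(selected, genes)
    k <- length(hits)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    rows[[nm]] <- data.frame(
      term = nm, N = N, K = K, n = n, k = k, p = p,
      overlap = paste(sort(hits), collapse = ","),
      stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0) {
    return(data.frame(term = character(0), N = integer(0), K = integer(0),
                      n = integer(0), k = integer(0), p = numeric(0),
                      q = numeric(0), overlap = character(0)))
  }
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out <- out[order(out$q, out$p), c("term", "N", "K", "n", "k", "p", "q", "overlap")]
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' q_(i) = min_{j >= i} m * p_(j) / j, capped at 1, returned in the input
#' order.
#'
#' @param pvalues numeric vector in [0, 1].
#' @return numeric vector of q-values.
#' @export
bh_fdr <- function(pvalues) {
  p <- as.numeric(pvalues)
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1] and be non-missing")
  }
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(m * p[o] / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}
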