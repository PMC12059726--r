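#' Canonical network labels
#'
#' Fixed ordering of the seven functional networks used throughout the
#' package: somatomotor (SMN), ventral attention (VAN), visual (VN), dorsal
#' attention (DAN), default mode (DMN), frontoparietal (FPN) and subcortical
#' (SC).
#'
#' @return Character vector of length 7.
#' @export
tx_networks <- function() {
  c("SMN", "VAN", "VN", "DAN", "DMN", "FPN", "SC")
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, evaluates `expr`, then restores the caller's RNG state, so
#' seeded generators behave as pure functions of their arguments.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing integer")
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Nearest positive-definite correlation repair
#'
#' Clips eigenvalues below `eps`, reconstructs, and rescales to unit diagonal.
#'
#' @param mat symmetric matrix.
#' @param eps eigenvalue floor (default 1e-6).
#' @return positive-definite correlation matrix.
#' @export
nearest_pd <- function(mat, eps = 1e-6) {
  mat <- (mat + t(mat)) / 2
  e <- eigen(mat, symmetric = TRUE)
  if (min(e$values) >= eps) {
    return(mat)
  }
  vals <- pmax(e$values, eps)
  out <- e$vectors %*% (vals * t(e$vectors))
  out <- stats::cov2cor(out)
  (out + t(out)) / 2
}

#' Squared-exponential spatial kernel
#'
#' @param D distance matrix (mm).
#' @param length_scale kernel length scale (mm), must be > 0.
#' @return covariance matrix exp(-D^2 / (2 * length_scale^2)).
#' @export
sq_exp_kernel <- function(D, length_scale) {
  if (!is.numeric(length_scale) || length_scale <= 0) {
    stop("kernel length scale must be positive")
  }
  exp(-(D^2) / (2 * length_scale^2))
}

## Draw one sample from a zero-mean GP with covariance K (jittered Cholesky).
gp_sample <- function(K, jitter = 1e-8) {
  n <- nrow(K)
  L <- chol(K + diag(jitter * max(diag(K)), n))
  as.numeric(crossprod(L, stats::rnorm(n)))
}

#' Edge index pairs for an R-region upper triangle
#'
#' Column-major upper-triangle ordering, matching `upper.tri()` extraction.
#'
#' @param n_regions number of regions.
#' @return data.frame with integer columns `i`, `j` (i < j, 1-based).
#' @export
edge_pairs <- function(n_regions) {
  idx <- which(upper.tri(matrix(0, n_regions, n_regions)), arr.ind = TRUE)
  data.frame(i = idx[, 1L], j = idx[, 2L])
}

## Upper-triangle vector of a symmetric matrix (column-major order).
ut_vec <- function(mat) mat[upper.tri(mat)]

## Rebuild a symmetric matrix (zero diagonal) from its upper-triangle vector.
sym_from_ut <- function(v, n_regions, dimnames_ = NULL) {
  m <- matrix(0, n_regions, n_regions, dimnames = dimnames_)
  m[upper.tri(m)] <- v
  m + t(m)
}

## Euclidean distance matrix between rows of a coordinate matrix.
coord_dist <- function(xyz) {
  as.matrix(stats::dist(xyz))
}

## FNV-1a 32-bit hash of a character scalar, returned as hex. Used for
## config fingerprints in manifests (no external digest dependency).
fnv1a_hash <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    # xor only touches the low byte (b < 256); keep h a double to avoid
    # 32-bit integer overflow in the modular multiply
    low <- bitwXor(as.integer(h %% 256), as.integer(b %% 256))
    h <- h - (h %% 256) + low
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
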