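#' SIMPLS partial least squares regression (univariate response)
#'
#' de Jong's SIMPLS: components are extracted by deflating the
#' predictor-response cross-product vector directly against the orthonormal
#' basis of X-loadings. Predictors are z-scored across rows (regions) and the
#' response is z-scored; each component's score is sign-fixed so that it
#' correlates positively with the response.
#'
#' @param X numeric region x gene matrix.
#' @param y numeric response (net t-value per region), length nrow(X).
#' @param K number of components (default 5; truncated to rank(X) with a
#'   warning).
#' @param quiet suppress the rank-truncation warning and constant-column
#'   warnings (used internally by the bootstrap).
#' @return object of class `tx_pls`: `weights` (genes x K, on z-scored X),
#'   `scores` (regions x K, unit norm, mutually orthogonal), `loadings`
#'   (genes x K), `y_loadings` (K), `y_varexp` (K, fractions of response
#'   variance), `x_varexp` (K), `K`, plus the centering/scaling used.
#' @export
simpls_fit <- function(X, y, K = 5, quiet = FALSE) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  if (length(y) != n) stop("rows of X must align with y")
  if (stats::sd(y) == 0) stop("constant response: PLS undefined")
  mu <- colMeans(X)
  sdx <- apply(X, 2L, stats::sd)
  zero_sd <- sdx == 0
  if (any(zero_sd) && !quiet) {
    warning(sum(zero_sd), " constant predictor column(s) set to 0")
  }
  sdx[zero_sd] <- 1
  Xs <- sweep(sweep(X, 2L, mu, "-"), 2L, sdx, "/")
  ys <- as.numeric(scale(y))
  rk <- qr(Xs)$rank
  if (K > rk) {
    if (!quiet) warning("K = ", K, " exceeds rank(X) = ", rk, "; truncated")
    K <- rk
  }
  p <- ncol(Xs)
  W <- matrix(0, p, K)        # weights
  Tm <- matrix(0, n, K)       # scores (unit norm)
  P <- matrix(0, p, K)        # X loadings
  q <- numeric(K)             # y loadings
  V <- matrix(0, p, K)        # orthonormal basis of loadings
  s <- crossprod(Xs, ys)      # p x 1 cross-product
  ssy <- sum(ys^2)
  ssx <- sum(Xs^2)
  for (a in seq_len(K)) {
    r <- s                                   # univariate y: direction = s
    t_a <- Xs %*% r
    t_a <- t_a - mean(t_a)
    nt <- sqrt(sum(t_a^2))
    if (nt < 1e-12) { K <- a - 1L; break }
    t_a <- t_a / nt
    r <- r / nt
    p_a <- crossprod(Xs, t_a)
    q_a <- sum(ys * t_a)
    # sign fix: score correlates positively with y
    if (q_a < 0) {
      r <- -r; t_a <- -t_a; p_a <- -p_a; q_a <- -q_a
    }
    v <- p_a
    if (a > 1) {
      v <- v - V[, seq_len(a - 1), drop = FALSE] %*%
        crossprod(V[, seq_len(a - 1), drop = FALSE], p_a)
    }
    v <- v / sqrt(sum(v^2))
    s <- s - v %*% crossprod(v, s)
    W[, a] <- r; Tm[, a] <- t_a; P[, a] <- p_a; q[a] <- q_a; V[, a] <- v
  }
  if (K < 1) stop("no usable PLS component (X deflated to zero)")
  W <- W[, seq_len(K), drop = FALSE]
  Tm <- Tm[, seq_len(K), drop = FALSE]
  P <- P[, seq_len(K), drop = FALSE]
  q <- q[seq_len(K)]
  rownames(W) <- rownames(P) <- colnames(X)
  structure(
    list(
      weights = W, scores = Tm, loadings = P, y_loadings = q,
      y_varexp = q^2 / ssy, x_varexp = colSums(P^2) / ssx, K = K,
      x_center = mu, x_scale = sdx, y_mean = mean(y), y_sd = stats::sd(y)
    ),
    class = "tx_pls"
  )
}

#' Select the PLS component explaining most response variance
#'
#' Argmax of the per-component response-variance fractions; ties break to the
#' smallest index. (Scores are already sign-fixed at fit time so the selected
#' score correlates non-negatively with the response.)
#'
#' @param model a `tx_pls`.
#' @return integer component index.
#' @export
select_component <- function(model) {
  stopifnot(inherits(model, "tx_pls"))
  which.max(model$y_varexp)
}

## Smoothed empirical variogram: the semivariance cloud
## v_ij = 0.5 (y_i - y_j)^2 is averaged with Gaussian kernel weights around
## each evaluation distance. `W` is the pair x eval-point weight matrix from
## `variogram_weights()` (columns sum to 1).
variogram_weights <- function(D, nbins = 20, max_quantile = 0.75) {
  h <- D[upper.tri(D)]
  pts <- seq(min(h), stats::quantile(h, max_quantile), length.out = nbins)
  bw <- 1.5 * diff(pts[1:2])
  W <- exp(-((outer(h, pts, "-")) / bw)^2 / 2)
  W <- sweep(W, 2L, colSums(W), "/")
  list(W = W, h = pts)
}

empirical_variogram <- function(y, D, vw) {
  v <- 0.5 * (outer(y, y, "-")^2)[upper.tri(D)]
  list(gamma = as.numeric(crossprod(vw$W, v)), h = vw$h)
}

#' Variogram-matched spatially autocorrelated surrogate maps
#'
#' Generative null maps preserving the spatial autocorrelation of `y`: each
#' surrogate permutes `y`, smooths it with a distance-decay kernel
#' (exponential or Gaussian) over the k nearest regions — k and the decay
#' scale grid-searched to minimize the (relative) mismatch between the
#' kernel-smoothed empirical variogram of `y` and that of the surrogate —
#' and is then affine-rescaled via the weighted regression
#' `gamma_emp ~ alpha + beta * gamma_surr`
#' (surrogate = sqrt(beta) * smoothed + sqrt(alpha) * white noise).
#'
#' @param y numeric regional map (length >= 10).
#' @param centroids matrix of region coordinates (rows aligned with y).
#' @param N number of surrogates (>= 100 recommended for inference).
#' @param seed integer seed.
#' @param kernel_grid list with `k` (neighbour counts), `scale` (decay
#'   multipliers) and `gaussian` (logical vector of kernel shapes); NULL for
#'   defaults.
#' @param nbins number of variogram evaluation distances (default 20).
#' @param resample rank-remap every surrogate onto the observed values of `y`
#'   (default TRUE), preserving its histogram exactly; a spatially white map
#'   then yields plain permutations. FALSE keeps the Gaussian affine form.
#' @return object of class `tx_surrogates`: `maps` (N x R matrix),
#'   `diagnostics` (data.frame with per-surrogate kernel choice, alpha, beta
#'   and the final map's mean relative variogram error), `variogram`
#'   (empirical curve).
#' @export
surrogate_maps <- function(y, centroids, N, seed, kernel_grid = NULL,
                           nbins = 20, resample = TRUE) {
  y <- as.numeric(y)
  R <- length(y)
  if (R < 10) stop("at least 10 regions are required for a stable variogram")
  centroids <- as.matrix(centroids)
  if (nrow(centroids) != R) stop("centroids must align with y")
  D <- coord_dist(centroids)
  if (is.null(kernel_grid)) {
    # k = 0 is the identity (pure permutation) candidate: it lets the kernel
    # degenerate when y carries no spatial autocorrelation
    kernel_grid <- list(
      k = unique(pmin(R - 1L, c(0L, 5L, 10L, 20L, 30L, 45L, R - 1L))),
      scale = c(0.5, 1, 2, 4),
      gaussian = c(FALSE, TRUE)
    )
  }
  if (is.null(kernel_grid$gaussian)) kernel_grid$gaussian <- FALSE
  vw <- variogram_weights(D, nbins)
  emp <- empirical_variogram(y, D, vw)
  wts <- 1 / pmax(emp$gamma, 1e-12)   # fit on the relative scale
  ord <- apply(D, 1L, order)          # ord[1, ] is self (distance 0)
  # smoothing matrices depend only on distances: precompute one per candidate
  candidates <- expand.grid(k = kernel_grid$k, sc = kernel_grid$scale,
                            gaussian = kernel_grid$gaussian)
  # k = 0 is kernel-shape/scale independent: keep a single copy
  if (any(candidates$k == 0L)) {
    candidates <- rbind(candidates[candidates$k == 0L, ][1L, ],
                        candidates[candidates$k > 0L, ])
  }
  smoothers <- lapply(seq_len(nrow(candidates)), function(ci) {
    k <- candidates$k[ci]; sc <- candidates$sc[ci]
    gauss <- candidates$gaussian[ci]
    if (k == 0L) return(diag(R))
    W <- matrix(0, R, R)
    for (i in seq_len(R)) {
      nb <- ord[seq_len(k + 1L), i]   # self + k nearest
      dk <- sc * D[i, nb[k + 1L]] + 1e-12
      w <- if (gauss) exp(-(D[i, nb] / dk)^2) else exp(-D[i, nb] / dk)
      W[i, nb] <- w / sum(w)
    }
    W
  })
  with_seed(seed, {
    maps <- matrix(0, N, R)
    diag_rows <- vector("list", N)
    ysort <- sort(y)
    for (b in seq_len(N)) {
      yp <- sample(y)
      noise <- stats::rnorm(R)       # one draw, shared across candidates
      best <- NULL
      for (ci in seq_len(nrow(candidates))) {
        sm <- as.numeric(smoothers[[ci]] %*% yp)
        if (stats::sd(sm) == 0) next
        smz <- as.numeric(scale(sm))
        vs <- empirical_variogram(smz, D, vw)
        fit <- stats::lm.fit(cbind(1, vs$gamma) * sqrt(wts),
                             emp$gamma * sqrt(wts))
        alpha <- fit$coefficients[1L]; beta <- fit$coefficients[2L]
        cand <- sqrt(max(beta, 0)) * smz + sqrt(max(alpha, 0)) * noise
        if (resample) {
          # rank-remap onto the observed values: preserves y's histogram
          # exactly (a spatially white map then yields a plain permutation)
          cand <- ysort[rank(cand, ties.method = "first")]
        } else {
          cand <- cand + mean(y)
        }
        vfin <- empirical_variogram(cand, D, vw)
        relerr <- mean(abs(vfin$gamma - emp$gamma) / pmax(emp$gamma, 1e-12))
        if (is.null(best) || relerr < best$rel_error) {
          best <- list(rel_error = relerr, alpha = alpha, beta = beta,
                       k = candidates$k[ci], sc = candidates$sc[ci],
                       gaussian = candidates$gaussian[ci], map = cand)
        }
      }
      maps[b, ] <- best$map
      diag_rows[[b]] <- data.frame(k = best$k, scale = best$sc,
                                   gaussian = best$gaussian,
                                   alpha = best$alpha, beta = best$beta,
                                   rel_error = best$rel_error)
    }
    structure(
      list(maps = maps, diagnostics = do.call(rbind, diag_rows),
           variogram = emp, seed = seed),
      class = "tx_surrogates"
    )
  })
}

#' Spatial-autocorrelation-corrected permutation test of the PLS component
#'
#' The observed statistic is the response variance explained by the selected
#' (best) component. For each surrogate map the model is refit and the best
#' component re-selected (selection-aware null). p uses the
#' (1 + exceedances) / (1 + N) estimator.
#'
#' @param X region x gene expression matrix.
#' @param y regional response map.
#' @param surrogates a `tx_surrogates` for `y` (or an N x R numeric matrix).
#' @param K number of PLS components.
#' @return list: `p`, `observed`, `selected`, `null` (length N), `K`.
#' @export
permutation_test <- function(X, y, surrogates, K = 5) {
  maps <- if (inherits(surrogates, "tx_surrogates")) surrogates$maps else surrogates
  model <- simpls_fit(X, y, K, quiet = TRUE)
  idx <- select_component(model)
  observed <- model$y_varexp[idx]
  null <- apply(maps, 1L, function(ys) {
    m <- tryCatch(simpls_fit(X, ys, K, quiet = TRUE), error = function(e) NULL)
    if (is.null(m)) return(NA_real_)
    m$y_varexp[select_component(m)]
  })
  null <- null[!is.na(null)]
  list(
    p = (1 + sum(null >= observed)) / (1 + length(null)),
    observed = observed, selected = idx, null = null, K = K
  )
}

#' Bootstrap z-scores for PLS gene weights
#'
#' Regions are resampled with replacement; the model is refit with the same
#' K; the refitted component whose weights correlate maximally (in absolute
#' value) with the original selected component is matched and sign-aligned;
#' the bootstrap SD of each gene's weight is the SE, and z = original weight /
#' SE. Genes are ranked by z (descending).
#'
#' @param X region x gene matrix.
#' @param y regional response.
#' @param K number of components.
#' @param B bootstrap draws (default 1000, minimum 100 recommended).
#' @param seed integer seed.
#' @param selected optional component index (default: best by response
#'   variance).
#' @return data.frame of class `tx_gene_weights`: gene, weight, se, z, rank,
#'   sign; attributes `selected`, `K`, `n_redraws`.
#' @export
bootstrap_gene_weights <- function(X, y, K = 5, B = 1000, seed = 1,
                                   selected = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  model <- simpls_fit(X, y, K, quiet = TRUE)
  K <- model$K
  if (is.null(selected)) selected <- select_component(model)
  w0 <- model$weights[, selected]
  with_seed(seed, {
    Wb <- matrix(NA_real_, ncol(X), B)
    n_redraws <- 0L
    for (b in seq_len(B)) {
      repeat {
        ib <- sample.int(n, replace = TRUE)
        if (length(unique(ib)) >= K + 1L && stats::sd(y[ib]) > 0) break
        n_redraws <- n_redraws + 1L
      }
      mb <- tryCatch(simpls_fit(X[ib, , drop = FALSE], y[ib], K, quiet = TRUE),
                     error = function(e) NULL)
      if (is.null(mb)) { n_redraws <- n_redraws + 1L; next }
      cors <- suppressWarnings(
        as.numeric(stats::cor(mb$weights, w0))
      )
      cors[is.na(cors)] <- 0
      j <- which.max(abs(cors))
      Wb[, b] <- mb$weights[, j] * sign(cors[j] + 1e-300)
    }
    se <- apply(Wb, 1L, stats::sd, na.rm = TRUE)
    z <- w0 / se
    z[se == 0 | !is.finite(se)] <- NA_real_
    out <- data.frame(
      gene = colnames(X), weight = w0, se = se, z = z,
      rank = rank(-z, ties.method = "first", na.last = "keep"),
      sign = sign(w0),
      stringsAsFactors = FALSE
    )
    rownames(out) <- NULL
    attr(out, "selected") <- selected
    attr(out, "K") <- K
    attr(out, "n_redraws") <- n_redraws
    class(out) <- c("tx_gene_weights", "data.frame")
    out
  })
}

#' Threshold gene weights by bootstrap |z|
#'
#' Genes with |z| strictly greater than `z_thresh` are retained and split by
#' the sign of z; each list is sorted by |z| descending.
#'
#' @param table a `tx_gene_weights` data.frame.
#' @param z_thresh threshold (default 3).
#' @return list: `positive`, `negative` (character vectors), `counts`.
#' @export
select_genes <- function(table, z_thresh = 3) {
  z <- table$z
  ok <- !is.na(z) & abs(z) > z_thresh
  pos <- table[ok & z > 0, , drop = FALSE]
  neg <- table[ok & z < 0, , drop = FALSE]
  pos <- pos[order(-abs(pos$z)), , drop = FALSE]
  neg <- neg[order(-abs(neg$z)), , drop = FALSE]
  list(
    positive = pos$gene,
    negative = neg$gene,
    counts = c(total = sum(ok), positive = nrow(pos), negative = nrow(neg))
  )
}
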