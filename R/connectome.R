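#' Fisher-z functional connectivity matrix
#'
#' Pearson correlation between every pair of regional time series, clipped to
#' +/-(1 - 1e-7) and Fisher z-transformed (atanh). Diagonal is zeroed.
#' Constant columns yield zero edges with a warning.
#'
#' @param timeseries T x R numeric matrix (rows = time points).
#' @param subject_id optional identifier stored as an attribute.
#' @return R x R symmetric matrix of class `tx_fc`.
#' @export
compute_fc <- function(timeseries, subject_id = NULL) {
  ts <- as.matrix(timeseries)
  if (nrow(ts) < 3) stop("at least 3 time points are required")
  sds <- apply(ts, 2L, stats::sd)
  const <- sds == 0 | !is.finite(sds)
  if (any(const)) {
    warning(sum(const), " constant column(s); their edges are set to 0")
  }
  r <- suppressWarnings(stats::cor(ts))
  r[!is.finite(r)] <- 0   # constant columns produce NA correlations
  r <- pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7)
  z <- atanh(r)
  diag(z) <- 0
  z <- (z + t(z)) / 2
  dimnames(z) <- list(colnames(timeseries), colnames(timeseries))
  structure(z, subject_id = subject_id, class = c("tx_fc", "matrix", "array"))
}

#' FC matrices for every subject of a cohort
#'
#' @param cohort a `tx_cohort` or list of `tx_subject`.
#' @return list of `tx_fc`, named by subject_id.
#' @export
cohort_fc <- function(cohort) {
  subjects <- if (inherits(cohort, "tx_cohort")) cohort$subjects else cohort
  out <- lapply(subjects, function(s) compute_fc(s$timeseries, s$subject_id))
  names(out) <- vapply(subjects, `[[`, "", "subject_id")
  out
}

## Stack a list of FC matrices into a subjects x edges matrix (upper triangle,
## column-major), plus the region count.
fc_to_edges <- function(fc_stack) {
  if (is.array(fc_stack) && length(dim(fc_stack)) == 3) {
    fc_stack <- lapply(seq_len(dim(fc_stack)[3]), function(k) fc_stack[, , k])
  }
  R <- nrow(fc_stack[[1L]])
  Y <- t(vapply(fc_stack, ut_vec, numeric(R * (R - 1) / 2)))
  rownames(Y) <- names(fc_stack)
  list(edges = Y, n_regions = R)
}

## Rebuild a list of symmetric FC matrices from an edge matrix.
edges_to_fc <- function(Y, n_regions) {
  out <- lapply(seq_len(nrow(Y)), function(i) sym_from_ut(Y[i, ], n_regions))
  names(out) <- rownames(Y)
  out
}

## Iterative solve for the parametric empirical-Bayes ComBat shrinkage
## (Johnson et al. 2007): gamma* under a normal prior, delta^2* under an
## inverse-gamma prior, alternated to convergence.
combat_it_sol <- function(sdat, g_hat, d_hat, g_bar, t2, a_prior, b_prior,
                          conv = 1e-4) {
  n <- colSums(!is.na(sdat))
  g_old <- g_hat
  d_old <- d_hat
  change <- 1
  while (change > conv) {
    g_new <- (t2 * n * g_hat + d_old * g_bar) / (t2 * n + d_old)
    sum2 <- colSums(sweep(sdat, 2L, g_new, "-")^2, na.rm = TRUE)
    d_new <- (0.5 * sum2 + b_prior) / (n / 2 + a_prior - 1)
    change <- max(abs(g_new - g_old) / abs(g_old + 1e-12),
                  abs(d_new - d_old) / abs(d_old + 1e-12))
    g_old <- g_new
    d_old <- d_new
  }
  list(gamma_star = g_old, delta_star = d_old)
}

#' Empirical-Bayes ComBat harmonization of an FC stack
#'
#' Removes per-site location and scale effects from vectorized edges while
#' protecting biological covariates: the design matrix contains site
#' indicators plus the protected covariates, per-site effects are shrunk with
#' parametric empirical-Bayes priors (normal for location, inverse-gamma for
#' scale), and the protected effects plus grand mean are restored afterwards.
#' With a single site the data are returned unchanged.
#'
#' @param fc_stack list of `tx_fc` matrices (or 3-D array R x R x n).
#' @param site_labels character/factor vector, one per subject.
#' @param protected_covariates data.frame or matrix of covariates to protect
#'   (e.g. HAMD, HAMA, age, sex); factors/characters are expanded to dummies.
#'   NULL for none.
#' @return list of harmonized FC matrices (same names/order).
#' @export
combat_harmonize <- function(fc_stack, site_labels, protected_covariates = NULL) {
  st <- fc_to_edges(fc_stack)
  Y <- st$edges                      # n x E
  n <- nrow(Y)
  site <- factor(site_labels)
  if (length(site) != n) stop("site_labels must match the number of subjects")
  if (nlevels(site) < 2) {
    return(edges_to_fc(Y, st$n_regions))
  }
  tab <- table(site)
  if (any(tab < 2)) {
    stop("every site needs at least 2 subjects (offending: ",
         paste(names(tab)[tab < 2], collapse = ", "), ")")
  }
  batch <- stats::model.matrix(~ site - 1)           # n x B one-hot
  B <- ncol(batch)
  X_cov <- NULL
  if (!is.null(protected_covariates)) {
    cov_df <- as.data.frame(protected_covariates)
    X_cov <- stats::model.matrix(~ ., data = cov_df)[, -1, drop = FALSE]
  }
  design <- cbind(batch, X_cov)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    bad <- colnames(design)[qrd$pivot[(qrd$rank + 1):ncol(design)]]
    stop("collinear design columns in ComBat: ", paste(bad, collapse = ", "))
  }
  beta <- solve(crossprod(design), crossprod(design, Y))   # (B+q) x E
  grand <- as.numeric(crossprod(tab / n, beta[seq_len(B), , drop = FALSE]))
  stand_mean <- matrix(grand, n, ncol(Y), byrow = TRUE)
  if (!is.null(X_cov)) {
    stand_mean <- stand_mean +
      X_cov %*% beta[-seq_len(B), , drop = FALSE]
  }
  resid <- Y - design %*% beta
  var_pooled <- colSums(resid^2) / n
  var_pooled[var_pooled < 1e-12] <- 1e-12
  Z <- (Y - stand_mean) / matrix(sqrt(var_pooled), n, ncol(Y), byrow = TRUE)

  Zadj <- Z
  for (b in levels(site)) {
    idx <- which(site == b)
    Zb <- Z[idx, , drop = FALSE]
    g_hat <- colMeans(Zb)
    d_hat <- apply(Zb, 2L, stats::var)
    g_bar <- mean(g_hat)
    t2 <- stats::var(g_hat)
    # method-of-moments inverse-gamma hyperparameters
    m <- mean(d_hat); s2 <- stats::var(d_hat)
    a_prior <- (2 * s2 + m^2) / s2
    b_prior <- (m * s2 + m^3) / s2
    eb <- combat_it_sol(Zb, g_hat, d_hat, g_bar, t2, a_prior, b_prior)
    Zadj[idx, ] <- sweep(Zb, 2L, eb$gamma_star, "-") /
      matrix(sqrt(eb$delta_star), length(idx), ncol(Z), byrow = TRUE)
  }
  Yadj <- Zadj * matrix(sqrt(var_pooled), n, ncol(Y), byrow = TRUE) + stand_mean
  out <- edges_to_fc(Yadj, st$n_regions)
  if (is.list(fc_stack) && !is.null(names(fc_stack))) names(out) <- names(fc_stack)
  out
}

#' Average an FC matrix to the 7x7 network level
#'
#' Cell (a, b) is the mean Fisher-z over all region pairs (i in a, j in b,
#' i != j); within-network cells use unordered pairs. Networks with fewer
#' than two regions get an NA within-network cell.
#'
#' @param fc R x R symmetric FC matrix.
#' @param atlas a `tx_atlas` covering the rows of `fc`.
#' @return 7 x 7 symmetric matrix (order of [tx_networks()]) of class
#'   `tx_netmat`.
#' @export
network_average <- function(fc, atlas) {
  nets <- tx_networks()
  if (nrow(fc) != nrow(atlas)) stop("atlas must cover all rows of fc")
  M <- matrix(NA_real_, length(nets), length(nets), dimnames = list(nets, nets))
  idx <- lapply(nets, function(k) which(atlas$network == k))
  names(idx) <- nets
  for (a in seq_along(nets)) {
    for (b in a:length(nets)) {
      ia <- idx[[a]]; ib <- idx[[b]]
      if (a == b) {
        if (length(ia) < 2) next
        block <- fc[ia, ia, drop = FALSE]
        M[a, a] <- mean(block[upper.tri(block)])
      } else {
        M[a, b] <- M[b, a] <- mean(fc[ia, ib])
      }
    }
  }
  structure(M, class = c("tx_netmat", "matrix", "array"))
}
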