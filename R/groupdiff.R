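#' Apply the cohort inclusion criteria
#'
#' Excludes subjects with mean framewise displacement above `fd_max`, HAMD at
#' or below `hamd_min_exclusive` (remission), quality score below
#' `quality_min`, or a missing HAMD/HAMA assessment. All reasons are recorded
#' per excluded subject.
#'
#' @param subjects data.frame with columns subject_id, fd, hamd, hama,
#'   quality_score (e.g. from [cohort_covariates()]), or a `tx_cohort`.
#' @param fd_max head-motion cutoff in mm (exclude if FD > fd_max).
#' @param hamd_min_exclusive exclude if HAMD <= this value.
#' @param quality_min exclude if quality score < this value.
#' @return list with `included` (data.frame) and `excluded` (data.frame with a
#'   `reasons` column, ";"-separated).
#' @export
apply_inclusion_criteria <- function(subjects, fd_max = 0.2,
                                     hamd_min_exclusive = 7, quality_min = 4) {
  if (inherits(subjects, "tx_cohort")) subjects <- cohort_covariates(subjects)
  reasons <- vector("list", nrow(subjects))
  add <- function(idx, msg) {
    for (i in which(idx)) reasons[[i]] <<- c(reasons[[i]], msg)
  }
  fd <- subjects$fd
  hamd <- subjects$hamd
  hama <- subjects$hama
  q <- subjects$quality_score
  add(!is.na(fd) & fd > fd_max, "head motion (FD above cutoff)")
  add(is.na(fd), "missing FD")
  add(!is.na(hamd) & hamd <= hamd_min_exclusive, "remission (HAMD at or below cutoff)")
  add(is.na(hamd), "missing HAMD")
  add(is.na(hama), "missing HAMA")
  add(!is.na(q) & q < quality_min, "quality score below cutoff")
  bad <- lengths(reasons) > 0
  excluded <- subjects[bad, , drop = FALSE]
  if (nrow(excluded)) {
    excluded$reasons <- vapply(reasons[bad], paste, "", collapse = "; ")
  } else {
    excluded$reasons <- character(0)
  }
  list(included = subjects[!bad, , drop = FALSE], excluded = excluded)
}

#' Assign anxiety groups from HAMA scores
#'
#' HAMA > 18 is the anxious group ("ANX+"); HAMA <= 18 is "ANX-".
#'
#' @param subjects data.frame with a `hama` column (or `tx_cohort`).
#' @param hama_cut threshold (strictly greater assigns ANX+), default 18.
#' @return factor with levels `ANX-`, `ANX+`.
#' @export
assign_groups <- function(subjects, hama_cut = 18) {
  if (inherits(subjects, "tx_cohort")) subjects <- cohort_covariates(subjects)
  hama <- subjects$hama
  if (any(is.na(hama))) {
    stop("missing HAMA for: ",
         paste(subjects$subject_id[is.na(hama)], collapse = ", "),
         " (should have been excluded upstream)")
  }
  factor(ifelse(hama > hama_cut, "ANX+", "ANX-"), levels = c("ANX-", "ANX+"))
}

## Build the GLM design [intercept, group, covariates]; errors on rank
## deficiency naming the collinear column.
build_design <- function(group, covariates, n) {
  g <- if (is.factor(group)) as.numeric(group) - 1 else as.numeric(group)
  if (length(unique(g)) < 2) stop("group indicator is constant: degenerate design")
  X <- cbind(intercept = 1, group = g)
  if (!is.null(covariates)) {
    cov_df <- as.data.frame(covariates)
    Xc <- stats::model.matrix(~ ., data = cov_df)[, -1, drop = FALSE]
    X <- cbind(X, Xc)
  }
  if (nrow(X) != n) stop("design rows must match the number of subjects")
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    bad <- colnames(X)[qrx$pivot[(qrx$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  X
}

## Mass-univariate OLS t-statistics for one design column across the columns
## of Y. Returns the t vector (and fitted/residual pieces when asked).
ols_t <- function(X, Y, coef = 2L, pieces = FALSE) {
  XtXinv <- chol2inv(chol(crossprod(X)))
  Bh <- XtXinv %*% crossprod(X, Y)
  res <- Y - X %*% Bh
  df <- nrow(X) - ncol(X)
  sigma2 <- colSums(res^2) / df
  se <- sqrt(XtXinv[coef, coef] * sigma2)
  tval <- Bh[coef, ] / se
  # numerically-zero residual variance means a perfect (degenerate) fit
  tval[se < 1e-10 | !is.finite(tval)] <- 0
  if (pieces) list(t = tval, df = df, fitted = X %*% Bh, residuals = res)
  else list(t = tval, df = df)
}

#' Edge-wise GLM group contrast
#'
#' Ordinary least squares of each Fisher-z edge on
#' `[intercept, group, covariates]`; reports the group t-statistic and
#' two-tailed p per edge.
#'
#' @param fc_stack list of `tx_fc` (or 3-D array).
#' @param group two-level factor or 0/1 vector (effect = level 2 minus 1).
#' @param covariates data.frame of nuisance covariates (sex, age, fd,
#'   education) or NULL.
#' @return object of class `tx_edge_stats`: list with `t` and `p` (R x R
#'   symmetric matrices), `df`, `t_vec`, `p_vec`, `pairs`, `contrast`.
#' @export
edge_glm_ttest <- function(fc_stack, group, covariates = NULL) {
  st <- fc_to_edges(fc_stack)
  Y <- st$edges
  n <- nrow(Y)
  p_cov <- if (is.null(covariates)) 0 else ncol(as.data.frame(covariates))
  if (n <= p_cov + 2) stop("need n > number of covariates + 2 subjects")
  X <- build_design(group, covariates, n)
  fit <- ols_t(X, Y)
  pvec <- 2 * stats::pt(abs(fit$t), fit$df, lower.tail = FALSE)
  R <- st$n_regions
  structure(
    list(
      t = sym_from_ut(fit$t, R),
      p = sym_from_ut(pvec, R),
      df = fit$df,
      t_vec = fit$t, p_vec = pvec, pairs = edge_pairs(R),
      contrast = "group (level 2 - level 1), OLS with covariates"
    ),
    class = "tx_edge_stats"
  )
}

## Connected components of the suprathreshold graph. `keep` is a logical
## vector over edges; `weight` an optional per-edge mass (|t| - t_critical)
## for the intensity statistic. Returns per-component edge counts, the
## chosen component statistic, and the edge membership.
supra_components <- function(keep, pairs, n_regions, weight = NULL) {
  if (!any(keep)) {
    return(list(sizes = integer(0), stat = numeric(0), edges = list()))
  }
  el <- cbind(pairs$i[keep], pairs$j[keep])
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n_regions - igraph::vcount(g)))
  comp <- igraph::components(g)
  edge_comp <- comp$membership[el[, 1L]]
  lev <- sort(unique(edge_comp))
  f <- factor(edge_comp, levels = lev)
  sizes <- as.integer(table(f))
  stat <- if (is.null(weight)) {
    as.numeric(sizes)
  } else {
    as.numeric(tapply(weight[keep], f, sum))
  }
  edges <- lapply(lev, function(k) {
    data.frame(i = el[edge_comp == k, 1L], j = el[edge_comp == k, 2L])
  })
  list(sizes = sizes, stat = stat, edges = edges)
}

#' NBS-corrected edge contrast
#'
#' Thresholds the observed |t| map at the two-tailed `edge_p` critical value,
#' finds connected components of the suprathreshold graph, and builds the
#' null distribution of the maximum component statistic by Freedman-Lane
#' permutation: residuals of the covariates-only reduced model are permuted,
#' the full model is refit, and the max component statistic recorded.
#' Component p-values use the (1 + exceedances) / (1 + n_perm) estimator.
#'
#' The component statistic is either `"intensity"` (sum of |t| - t_critical
#' over the component's edges; continuous, hence exactly calibrated — the
#' default) or `"size"` (edge count, the historical NBS default; its
#' discreteness makes the test conservative at strict edge thresholds).
#'
#' @inheritParams edge_glm_ttest
#' @param edge_p two-tailed edge-level threshold (default 0.001).
#' @param alpha component-level significance level (default 0.05).
#' @param n_perm number of permutations (default 1000; < 100 warns).
#' @param seed integer seed (required).
#' @param statistic component statistic, `"intensity"` or `"size"`.
#' @return object of class `tx_nbs`: `components` (edge lists), `sizes`
#'   (edge counts), `stat` (component statistic), `p_values`, `significant`
#'   (p < alpha), `null_max_size` (null distribution of the max statistic),
#'   `thresholds`, `edge_stats`.
#' @export
nbs_correct <- function(fc_stack, group, covariates = NULL, edge_p = 0.001,
                        alpha = 0.05, n_perm = 1000, seed,
                        statistic = c("intensity", "size")) {
  if (missing(seed)) stop("a seed is required for reproducible permutations")
  if (n_perm < 100) warning("n_perm < 100 gives a coarse null distribution")
  statistic <- match.arg(statistic)
  st <- fc_to_edges(fc_stack)
  Y <- st$edges
  n <- nrow(Y)
  R <- st$n_regions
  pairs <- edge_pairs(R)
  X <- build_design(group, covariates, n)
  fit <- ols_t(X, Y)
  tcrit <- stats::qt(1 - edge_p / 2, fit$df)
  wgt <- function(tv) if (statistic == "intensity") abs(tv) - tcrit else NULL
  obs <- supra_components(abs(fit$t) >= tcrit, pairs, R, wgt(fit$t))

  # Freedman-Lane: permute reduced-model residuals (covariates only)
  Xred <- X[, -2L, drop = FALSE]
  Hred <- Xred %*% chol2inv(chol(crossprod(Xred))) %*% t(Xred)
  fitted_red <- Hred %*% Y
  resid_red <- Y - fitted_red
  null_max <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      perm <- sample.int(n)
      Yp <- fitted_red + resid_red[perm, , drop = FALSE]
      tp <- ols_t(X, Yp)$t
      cs <- supra_components(abs(tp) >= tcrit, pairs, R, wgt(tp))$stat
      if (length(cs)) max(cs) else 0
    }, numeric(1))
  })
  pvals <- vapply(obs$stat, function(s) {
    (1 + sum(null_max >= s)) / (1 + n_perm)
  }, numeric(1))
  structure(
    list(
      components = obs$edges,
      sizes = obs$sizes,
      stat = obs$stat,
      p_values = pvals,
      significant = which(pvals < alpha),
      null_max_size = null_max,
      thresholds = list(edge_p = edge_p, alpha = alpha, n_perm = n_perm,
                        t_critical = tcrit, seed = seed,
                        statistic = statistic),
      edge_stats = structure(
        list(t = sym_from_ut(fit$t, R), df = fit$df, t_vec = fit$t,
             pairs = pairs),
        class = "tx_edge_stats"
      )
    ),
    class = "tx_nbs"
  )
}

#' Network-level contrast with max-statistic permutation correction
#'
#' GLM group contrast on each of the 28 unique 7x7 network cells, with
#' family-wise correction by the Freedman-Lane permutation null of the
#' maximum |t| over cells.
#'
#' @param net_stack list of `tx_netmat` (7x7 per subject).
#' @inheritParams nbs_correct
#' @return list: `t`, `p_uncorrected`, `p_fwe` (7x7 matrices), `df`,
#'   `null_max_t`, `significant` (data.frame of cells with p_fwe < alpha).
#' @export
network_ttest <- function(net_stack, group, covariates = NULL, n_perm = 1000,
                          alpha = 0.05, seed) {
  if (missing(seed)) stop("a seed is required for reproducible permutations")
  nets <- rownames(net_stack[[1L]])
  K <- nrow(net_stack[[1L]])
  ut <- upper.tri(matrix(0, K, K), diag = TRUE)
  cells <- which(ut, arr.ind = TRUE)
  Y <- t(vapply(net_stack, function(m) m[ut], numeric(sum(ut))))
  ok <- colSums(is.na(Y)) == 0
  n <- nrow(Y)
  X <- build_design(group, covariates, n)
  fit <- ols_t(X, Y[, ok, drop = FALSE])
  tobs <- rep(NA_real_, ncol(Y)); tobs[ok] <- fit$t
  p_unc <- 2 * stats::pt(abs(tobs), fit$df, lower.tail = FALSE)

  Xred <- X[, -2L, drop = FALSE]
  Hred <- Xred %*% chol2inv(chol(crossprod(Xred))) %*% t(Xred)
  fitted_red <- Hred %*% Y[, ok, drop = FALSE]
  resid_red <- Y[, ok, drop = FALSE] - fitted_red
  null_max <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      perm <- sample.int(n)
      Yp <- fitted_red + resid_red[perm, , drop = FALSE]
      max(abs(ols_t(X, Yp)$t))
    }, numeric(1))
  })
  p_fwe <- vapply(tobs, function(tt) {
    if (is.na(tt)) NA_real_ else (1 + sum(null_max >= abs(tt))) / (1 + n_perm)
  }, numeric(1))
  mk <- function(v) {
    m <- matrix(NA_real_, K, K, dimnames = list(nets, nets))
    m[ut] <- v
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    m
  }
  sig <- which(!is.na(p_fwe) & p_fwe < alpha)
  list(
    t = mk(tobs), p_uncorrected = mk(p_unc), p_fwe = mk(p_fwe), df = fit$df,
    null_max_t = null_max,
    significant = data.frame(
      net_a = nets[cells[sig, 1L]], net_b = nets[cells[sig, 2L]],
      t = tobs[sig], p_fwe = p_fwe[sig]
    ),
    thresholds = list(alpha = alpha, n_perm = n_perm, seed = seed)
  )
}

#' Regional net t-value
#'
#' Per region, the sum of its positive edge t-values minus the sum of the
#' absolute values of its negative edge t-values — algebraically the plain row
#' sum of the t matrix. By default all edges of the region contribute;
#' `edges = "nbs"` restricts to edges in significant NBS components.
#'
#' @param edge_stats `tx_edge_stats` (or `tx_nbs`, whose embedded stats are
#'   used).
#' @param region_subset optional integer vector of region_ids (e.g. the left
#'   hemisphere) to report; scores still sum over all partner regions.
#' @param edges `"all"` (default) or `"nbs"` (requires a `tx_nbs` input).
#' @param region_ids region ids labelling the rows of the t matrix (default
#'   0-based).
#' @return named numeric vector of net t-values.
#' @export
net_t_value <- function(edge_stats, region_subset = NULL, edges = c("all", "nbs"),
                        region_ids = NULL) {
  edges <- match.arg(edges)
  nbs <- NULL
  if (inherits(edge_stats, "tx_nbs")) {
    nbs <- edge_stats
    edge_stats <- edge_stats$edge_stats
  }
  tmat <- edge_stats$t
  R <- nrow(tmat)
  if (is.null(region_ids)) region_ids <- 0:(R - 1L)
  if (edges == "nbs") {
    if (is.null(nbs)) stop("edges = 'nbs' needs a tx_nbs object")
    mask <- matrix(0, R, R)
    for (k in nbs$significant) {
      e <- nbs$components[[k]]
      mask[cbind(e$i, e$j)] <- 1
      mask[cbind(e$j, e$i)] <- 1
    }
    tmat <- tmat * mask
  }
  diag(tmat) <- 0
  score <- rowSums(pmax(tmat, 0)) - rowSums(abs(pmin(tmat, 0)))
  names(score) <- region_ids
  if (!is.null(region_subset)) score <- score[as.character(region_subset)]
  score
}

#' Propensity-score matching on covariates
#'
#' Logistic regression of group on the covariates gives propensity scores;
#' greedy nearest-neighbour 1:1 matching without replacement on the logit
#' scale, with a caliper of `caliper_sd` standard deviations of the logit.
#' Treated subjects are visited in an order randomized by `seed`.
#'
#' @param subjects data.frame with subject_id and the covariate columns.
#' @param group two-level factor (level 2 = treated).
#' @param covariates character vector of covariate column names.
#' @param caliper_sd caliper width in SDs of the logit propensity.
#' @param seed integer seed.
#' @return data.frame with columns treated, control, distance.
#' @export
propensity_match <- function(subjects, group, covariates = c("age", "sex"),
                             caliper_sd = 0.2, seed = 1) {
  g <- if (is.factor(group)) as.numeric(group) - 1 else as.numeric(group)
  if (length(unique(g)) < 2) stop("both groups must be non-empty")
  df <- subjects[, covariates, drop = FALSE]
  df$.g <- g
  fit <- suppressWarnings(stats::glm(.g ~ ., data = df, family = stats::binomial()))
  logit <- stats::predict(fit, type = "link")
  if (any(abs(logit) > 15) || !fit$converged) {
    stop("complete (or quasi-complete) separation in the propensity model")
  }
  caliper <- caliper_sd * stats::sd(logit)
  treated <- which(g == 1)
  control <- which(g == 0)
  with_seed(seed, {
    treated <- sample(treated)
    used <- rep(FALSE, length(control))
    rows <- list()
    for (tr in treated) {
      d <- abs(logit[control] - logit[tr])
      d[used] <- Inf
      j <- which.min(d)
      if (is.finite(d[j]) && d[j] <= caliper) {
        used[j] <- TRUE
        rows[[length(rows) + 1L]] <- data.frame(
          treated = subjects$subject_id[tr],
          control = subjects$subject_id[control[j]],
          distance = d[j],
          stringsAsFactors = FALSE
        )
      }
    }
    if (length(rows)) do.call(rbind, rows) else
      data.frame(treated = character(0), control = character(0),
                 distance = numeric(0))
  })
}

#' Paired edge contrast with sign-flip NBS correction
#'
#' Within-pair FC differences are adjusted for the within-pair FD difference
#' (Freedman-Lane style: the tested effect is the intercept of the difference
#' model), t-tested per edge, thresholded, and corrected by the permutation
#' null of the maximum suprathreshold component size under random sign flips
#' of the reduced-model residuals.
#'
#' @param fc_stack named list of `tx_fc` for all subjects involved.
#' @param pairs data.frame with `treated` and `control` subject_id columns
#'   (from [propensity_match()]).
#' @param fd named numeric vector of per-subject FD (names = subject_id), or
#'   NULL to skip FD adjustment.
#' @inheritParams nbs_correct
#' @return `tx_nbs` object (paired contrast).
#' @export
paired_edge_ttest <- function(fc_stack, pairs, fd = NULL, n_perm = 1000,
                              edge_p = 0.001, alpha = 0.05, seed,
                              statistic = c("intensity", "size")) {
  if (missing(seed)) stop("a seed is required for reproducible permutations")
  if (nrow(pairs) < 3) stop("at least 3 matched pairs are required")
  statistic <- match.arg(statistic)
  st <- fc_to_edges(fc_stack)
  Y <- st$edges
  R <- st$n_regions
  epairs <- edge_pairs(R)
  D <- Y[pairs$treated, , drop = FALSE] - Y[pairs$control, , drop = FALSE]
  m <- nrow(D)
  if (!is.null(fd)) {
    xfd <- as.numeric(fd[pairs$treated]) - as.numeric(fd[pairs$control])
    xfd <- xfd - mean(xfd)
    if (stats::sd(xfd) == 0) fd <- NULL   # no FD variation to adjust for
  }
  if (!is.null(fd)) {
    X <- cbind(intercept = 1, fd_diff = xfd)
    # reduced model: FD difference only (intercept is the tested effect)
    Xred <- X[, 2L, drop = FALSE]
    Hred <- Xred %*% chol2inv(chol(crossprod(Xred))) %*% t(Xred)
  } else {
    X <- cbind(intercept = 1)[rep(1, m), , drop = FALSE]
    colnames(X) <- "intercept"
    Hred <- matrix(0, m, m)
  }
  fitted_red <- Hred %*% D
  resid_red <- D - fitted_red
  fit <- ols_t(X, D, coef = 1L)
  tcrit <- stats::qt(1 - edge_p / 2, fit$df)
  wgt <- function(tv) if (statistic == "intensity") abs(tv) - tcrit else NULL
  obs <- supra_components(abs(fit$t) >= tcrit, epairs, R, wgt(fit$t))
  null_max <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      s <- sample(c(-1, 1), m, replace = TRUE)
      Dp <- fitted_red + resid_red * s
      tp <- ols_t(X, Dp, coef = 1L)$t
      cs <- supra_components(abs(tp) >= tcrit, epairs, R, wgt(tp))$stat
      if (length(cs)) max(cs) else 0
    }, numeric(1))
  })
  pvals <- vapply(obs$stat, function(s) (1 + sum(null_max >= s)) / (1 + n_perm),
                  numeric(1))
  structure(
    list(
      components = obs$edges, sizes = obs$sizes, stat = obs$stat,
      p_values = pvals,
      significant = which(pvals < alpha), null_max_size = null_max,
      thresholds = list(edge_p = edge_p, alpha = alpha, n_perm = n_perm,
                        t_critical = tcrit, seed = seed,
                        statistic = statistic),
      edge_stats = structure(
        list(t = sym_from_ut(fit$t, R), df = fit$df, t_vec = fit$t,
             pairs = epairs),
        class = "tx_edge_stats"
      )
    ),
    class = "tx_nbs"
  )
}
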