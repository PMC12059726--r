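test_that("inclusion criteria exclude at the stated boundaries", {
  subj <- data.frame(
    subject_id = paste0("s", 1:7),
    fd = c(0.21, 0.2, 0.1, 0.1, 0.1, NA, 0.1),
    hamd = c(10, 8, 7, 10, 10, 10, NA),
    hama = c(20, 20, 20, NA, 20, 20, 20),
    quality_score = c(5, 4, 5, 5, 3, 5, 5)
  )
  res <- apply_inclusion_criteria(subj)
  expect_setequal(res$included$subject_id, c("s2"))
  ex <- setNames(res$excluded$reasons, res$excluded$subject_id)
  expect_match(ex[["s1"]], "head motion")
  expect_match(ex[["s3"]], "remission")
  expect_match(ex[["s4"]], "missing HAMA")
  expect_match(ex[["s5"]], "quality")
  expect_match(ex[["s6"]], "missing FD")
  expect_match(ex[["s7"]], "missing HAMD")
})

test_that("groups split at HAMA 18 / 19", {
  subj <- data.frame(subject_id = c("a", "b", "c"), hama = c(19, 18, 0))
  expect_equal(as.character(assign_groups(subj)), c("ANX+", "ANX-", "ANX-"))
  subj$hama[2] <- NA
  expect_error(assign_groups(subj), "missing HAMA")
})

test_that("edge GLM equals the classical two-sample t without covariates", {
  # 6-subject toy with 3 regions
  set.seed(3)
  fc <- lapply(1:6, function(i) {
    m <- matrix(0, 3, 3)
    m[upper.tri(m)] <- rnorm(3) + (i > 3) * c(1, 0, -0.5)
    m + t(m)
  })
  names(fc) <- paste0("s", 1:6)
  grp <- factor(rep(c("g1", "g2"), each = 3))
  es <- edge_glm_ttest(fc, grp)
  edges <- txconn:::fc_to_edges(fc)$edges
  for (e in 1:3) {
    expect_equal(es$t_vec[e], pooled_t(edges[1:3, e], edges[4:6, e]),
                 tolerance = 1e-10)
  }
  expect_equal(es$df, 4)
  # p consistent with t and df
  expect_equal(es$p_vec, 2 * pt(abs(es$t_vec), 4, lower.tail = FALSE))
  # constant group -> degenerate design
  expect_error(edge_glm_ttest(fc, rep(1, 6)), "constant")
  # collinear covariates named
  covs <- data.frame(age = c(1, 2, 3, 4, 5, 6), age2 = 2 * c(1, 2, 3, 4, 5, 6))
  expect_error(edge_glm_ttest(fc, grp, covs), "age2")
})

test_that("edge t-map is equivariant under region relabeling", {
  fx <- small_cohort(seed = 51, n = 8, R = 14, T_ = 80)
  fc <- cohort_fc(fx$cohort)
  grp <- assign_groups(fx$covs)
  t1 <- edge_glm_ttest(fc, grp)$t
  perm <- sample(14)
  fc_p <- lapply(fc, function(m) {
    structure(unclass(m)[perm, perm], class = class(m))
  })
  t2 <- edge_glm_ttest(fc_p, grp)$t
  expect_equal(t2, t1[perm, perm], tolerance = 1e-10)
})

test_that("net t-value matches hand computation and the row-sum identity", {
  tmat <- matrix(0, 3, 3)
  tmat[1, 2] <- 2; tmat[1, 3] <- -1; tmat[2, 3] <- 0.5
  tmat <- tmat + t(tmat)
  es <- structure(list(t = tmat), class = "tx_edge_stats")
  expect_equal(unname(net_t_value(es)), c(1, 2.5, -0.5))
  # all-zero map
  es0 <- structure(list(t = matrix(0, 3, 3)), class = "tx_edge_stats")
  expect_equal(unname(net_t_value(es0)), c(0, 0, 0))
  # identity: equals the plain row sum, exactly
  set.seed(9)
  tm <- matrix(rnorm(64), 8, 8); tm <- tm + t(tm); diag(tm) <- 0
  esr <- structure(list(t = tm), class = "tx_edge_stats")
  expect_equal(unname(net_t_value(esr)), rowSums(tm), tolerance = 1e-14)
  # subsetting picks the requested regions, sums stay over all partners
  expect_equal(net_t_value(esr, region_subset = c(0, 3)),
               setNames(rowSums(tm)[c(1, 4)], c(0, 3)))
})

test_that("NBS finds the planted component and reports honest p-values", {
  a <- generate_atlas(21, seed = 1)
  eff <- effect_spec(network_pairs = list(c("SC", "VN")), delta = 0.4)
  co <- suppressWarnings(generate_cohort(a, 40, 40, 150, effect = eff, seed = 61))
  covs <- cohort_covariates(co)
  grp <- assign_groups(covs)
  fc <- cohort_fc(co)
  nuis <- covs[, c("sex", "age", "fd", "education")]
  nbs <- nbs_correct(fc, grp, nuis, n_perm = 200, seed = 62)
  expect_gt(length(nbs$significant), 0)
  # the significant component contains SC-VN edges
  net <- a$network
  comp <- nbs$components[[nbs$significant[1]]]
  pairs_net <- cbind(net[comp$i], net[comp$j])
  expect_true(any((pairs_net[, 1] == "SC" & pairs_net[, 2] == "VN") |
                  (pairs_net[, 2] == "SC" & pairs_net[, 1] == "VN")))
  expect_true(all(nbs$p_values > 0 & nbs$p_values <= 1))
  expect_length(nbs$null_max_size, 200)
  # determinism
  nbs2 <- nbs_correct(fc, grp, nuis, n_perm = 200, seed = 62)
  expect_identical(nbs$null_max_size, nbs2$null_max_size)
  expect_identical(nbs$p_values, nbs2$p_values)
  # p monotone non-increasing in the component statistic for the fixed null
  if (length(nbs$stat) > 1) {
    ord <- order(nbs$stat)
    expect_true(all(diff(nbs$p_values[ord]) <= 0))
  }
  # the size statistic remains available and monotone too
  nbs_sz <- nbs_correct(fc, grp, nuis, n_perm = 200, seed = 62,
                        statistic = "size")
  expect_gt(length(nbs_sz$significant), 0)
  if (length(nbs_sz$sizes) > 1) {
    ord <- order(nbs_sz$sizes)
    expect_true(all(diff(nbs_sz$p_values[ord]) <= 0))
  }
  sub <- c(1:10, 41:50)   # both groups represented
  expect_warning(nbs_correct(fc[sub], grp[sub], NULL, n_perm = 50, seed = 1),
                 "n_perm")
  expect_error(nbs_correct(fc, grp, nuis, n_perm = 100), "seed")
})

test_that("no suprathreshold edges yields an empty component list", {
  fx <- small_cohort(seed = 71, n = 5, R = 14, T_ = 60)
  fc <- cohort_fc(fx$cohort)
  grp <- assign_groups(fx$covs)
  # absurdly strict edge threshold: nothing survives
  nbs <- nbs_correct(fc, grp, NULL, edge_p = 1e-12, n_perm = 100, seed = 2)
  expect_length(nbs$components, 0)
  expect_length(nbs$p_values, 0)
})

test_that("Freedman-Lane with no covariates reduces to label permutation", {
  set.seed(5)
  n <- 10
  Y <- matrix(rnorm(n * 4), n, 4)
  g <- rep(0:1, each = 5)
  X <- cbind(1, g)
  perm <- sample(n)
  # FL with intercept-only reduced model: Y* = ybar + (Y - ybar)[perm, ]
  Yp <- matrix(colMeans(Y), n, 4, byrow = TRUE) +
    (Y - matrix(colMeans(Y), n, 4, byrow = TRUE))[perm, ]
  t_fl <- txconn:::ols_t(X, Yp)$t
  # label permutation: permute g by the inverse permutation
  inv <- order(perm)
  t_lab <- txconn:::ols_t(cbind(1, g[inv]), Y)$t
  expect_equal(t_fl, t_lab, tolerance = 1e-10)
})

test_that("network-level test flags the planted cell and honors determinism", {
  a <- generate_atlas(21, seed = 1)
  eff <- effect_spec(network_pairs = list(c("SC", "VN")), delta = 0.4)
  co <- suppressWarnings(generate_cohort(a, 40, 40, 150, effect = eff, seed = 81))
  covs <- cohort_covariates(co)
  grp <- assign_groups(covs)
  nstack <- lapply(cohort_fc(co), network_average, atlas = a)
  nuis <- covs[, c("sex", "age", "fd", "education")]
  nt <- network_ttest(nstack, grp, nuis, n_perm = 200, seed = 82)
  expect_lt(nt$p_fwe["SC", "VN"], 0.05)
  expect_identical(
    nt$null_max_t,
    network_ttest(nstack, grp, nuis, n_perm = 200, seed = 82)$null_max_t
  )
  # constant matrices -> all t = 0
  const <- lapply(1:10, function(i) {
    m <- matrix(0.4, 7, 7, dimnames = list(tx_networks(), tx_networks()))
    structure(m, class = c("tx_netmat", "matrix", "array"))
  })
  nt0 <- network_ttest(const, rep(0:1, 5), NULL, n_perm = 50, seed = 3)
  expect_true(all(nt0$t == 0, na.rm = TRUE))
})

test_that("propensity matching balances covariates within the caliper", {
  # identical covariate values in both groups: everyone matches at distance 0
  subj <- data.frame(subject_id = paste0("s", 1:20),
                     age = rep(30:39, 2), sex = rep(c("F", "M"), 10))
  g <- rep(c(0, 1), each = 10)
  pm <- propensity_match(subj, g, seed = 1)
  expect_equal(nrow(pm), 10)
  expect_true(all(pm$distance < 1e-8))
  # shifted ages: matching reduces the standardized mean difference below 0.1
  set.seed(4)
  n <- 150
  age <- c(rnorm(n, 33, 9), rnorm(n, 37, 9))
  subj2 <- data.frame(subject_id = paste0("t", 1:(2 * n)), age = age,
                      sex = sample(c("F", "M"), 2 * n, replace = TRUE))
  g2 <- rep(c(0, 1), each = n)
  pm2 <- propensity_match(subj2, g2, seed = 2)
  expect_gt(nrow(pm2), 50)
  at <- subj2$age[match(pm2$treated, subj2$subject_id)]
  ac <- subj2$age[match(pm2$control, subj2$subject_id)]
  smd <- abs(mean(at) - mean(ac)) / sd(subj2$age)
  expect_lt(smd, 0.1)
  # interleaved but offset ages with a tiny caliper: every cross-group
  # distance exceeds the caliper, so nothing matches
  subj3 <- data.frame(subject_id = paste0("u", 1:22),
                      age = c(20 + (0:10) * 1.7, 20.85 + (0:10) * 1.7))
  g3 <- rep(c(0, 1), each = 11)
  pm3 <- propensity_match(subj3, g3, covariates = "age", caliper_sd = 0.001,
                          seed = 3)
  expect_equal(nrow(pm3), 0)
  # complete separation errors
  subj4 <- data.frame(subject_id = paste0("v", 1:20), age = c(20:29, 50:59))
  expect_error(propensity_match(subj4, rep(c(0, 1), each = 10),
                                covariates = "age", seed = 1),
               "separation")
})

test_that("paired contrast: identical pairs give zero t, planted effects recover", {
  fx <- small_cohort(seed = 91, n = 8, R = 14, T_ = 80)
  fc <- cohort_fc(fx$cohort)
  ids <- names(fc)
  # identical members in every pair -> all t = 0
  pairs_same <- data.frame(treated = ids[1:5], control = ids[1:5])
  fd <- setNames(fx$covs$fd, fx$covs$subject_id)
  res0 <- paired_edge_ttest(fc, pairs_same, fd = fd, n_perm = 50, seed = 1)
  expect_true(all(res0$edge_stats$t_vec == 0))
  expect_error(paired_edge_ttest(fc, pairs_same[1:2, ], fd = fd,
                                 n_perm = 50, seed = 1), "3 matched pairs")

  # planted paired effect on one edge block is recovered
  set.seed(10)
  n_pairs <- 25; R <- 10
  fc2 <- list()
  for (i in 1:n_pairs) {
    base <- matrix(0, R, R)
    base[upper.tri(base)] <- rnorm(R * (R - 1) / 2, 0, 0.2)
    m1 <- base; m1[1, 2] <- m1[1, 2] + 0.6   # treated member gets the effect
    fc2[[paste0("t", i)]] <- m1 + t(m1)
    m2 <- base + matrix(rnorm(R * R, 0, 0.02), R, R)
    m2[lower.tri(m2, diag = TRUE)] <- 0
    fc2[[paste0("c", i)]] <- m2 + t(m2)
  }
  pairs2 <- data.frame(treated = paste0("t", 1:n_pairs),
                       control = paste0("c", 1:n_pairs))
  res <- paired_edge_ttest(fc2, pairs2, fd = NULL, n_perm = 200, seed = 4)
  expect_gt(length(res$significant), 0)
  comp <- res$components[[res$significant[1]]]
  expect_true(any(comp$i == 1 & comp$j == 2))
  # determinism
  res_b <- paired_edge_ttest(fc2, pairs2, fd = NULL, n_perm = 200, seed = 4)
  expect_identical(res$null_max_size, res_b$null_max_size)
})

test_that("paired null keeps the family-wise error near alpha", {
  # 40 null replicates; FWER should stay below the exact binomial upper bound
  rejections <- vapply(1:40, function(s) {
    set.seed(s + 200)
    n_pairs <- 12; R <- 10
    fc <- list()
    for (i in 1:n_pairs) {
      for (who in c("t", "c")) {
        m <- matrix(0, R, R)
        m[upper.tri(m)] <- rnorm(R * (R - 1) / 2, 0, 0.3)
        fc[[paste0(who, i)]] <- m + t(m)
      }
    }
    pairs <- data.frame(treated = paste0("t", 1:n_pairs),
                        control = paste0("c", 1:n_pairs))
    res <- paired_edge_ttest(fc, pairs, fd = NULL, n_perm = 100, seed = s)
    length(res$significant) > 0
  }, logical(1))
  expect_lte(mean(rejections), 0.125)  # 5/40, binomial 95% bound at p = 0.05
})
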