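test_that("generate_atlas satisfies its invariants and examples", {
  a <- generate_atlas(160, seed = 1)
  expect_equal(nrow(a), 160)
  expect_equal(a$region_id, 0:159)
  expect_true(all(tx_networks() %in% a$network))
  expect_true(all(table(a$network) >= 2))
  expect_setequal(unique(a$hemisphere), c("L", "R"))
  expect_true(all(a$x[a$hemisphere == "L"] < 0))
  expect_true(all(a$x[a$hemisphere == "R"] > 0))

  # uniform proportions at n = 14 force exactly 2 per network
  a14 <- generate_atlas(14, network_proportions = rep(1 / 7, 7), seed = 0)
  expect_true(all(table(a14$network) == 2))

  # determinism
  expect_identical(generate_atlas(40, seed = 7), generate_atlas(40, seed = 7))
  expect_error(generate_atlas(10, seed = 1), "n_regions")
})

test_that("null cohorts have no planted group difference", {
  fx <- small_cohort(seed = 4, delta = 0)
  grp <- vapply(fx$cohort$subjects, `[[`, 1, "group")
  fc <- cohort_fc(fx$cohort)
  st <- txconn:::fc_to_edges(fc)
  diff <- colMeans(st$edges[grp == 2, ]) - colMeans(st$edges[grp == 1, ])
  expect_lt(max(abs(mean(diff))), 0.05)
})

test_that("planted delta appears on SC-VN edges at the stated size", {
  # Monte-Carlo over 20 seeds: mean empirical r difference within 0.3 +/- 0.05
  a <- generate_atlas(21, seed = 1)
  sc <- which(a$network == "SC"); vn <- which(a$network == "VN")
  eff <- effect_spec(network_pairs = list(c("SC", "VN")), delta = 0.3)
  diffs <- vapply(1:20, function(s) {
    co <- suppressWarnings(generate_cohort(a, 100, 100, 200, effect = eff,
                                           seed = s))
    grp <- vapply(co$subjects, `[[`, 1, "group")
    rs <- vapply(co$subjects, function(su) {
      mean(cor(su$timeseries)[sc, vn])
    }, numeric(1))
    mean(rs[grp == 2]) - mean(rs[grp == 1])
  }, numeric(1))
  expect_lt(abs(mean(diffs) - 0.3), 0.05)
})

test_that("site offsets shift the pre-harmonization grand-mean FC", {
  a <- generate_atlas(21, seed = 1)
  eff <- effect_spec(delta = 0, site_offsets = c(sA = 0.2, sB = 0),
                     site_scales = c(sA = 1, sB = 1))
  gaps <- vapply(1:5, function(s) {
    co <- suppressWarnings(generate_cohort(a, 40, 40, 200,
                                           sites = c("sA", "sB"),
                                           effect = eff, seed = s))
    covs <- cohort_covariates(co)
    st <- txconn:::fc_to_edges(cohort_fc(co))
    mean(st$edges[covs$site == "sA", ]) - mean(st$edges[covs$site == "sB", ])
  }, numeric(1))
  # atanh is mildly convex over the affected range, so the Fisher-z gap sits
  # slightly above the r-scale offset of 0.2
  expect_lt(abs(mean(gaps) - 0.2), 0.08)
})

test_that("cohort structure: HAMA recoverable, warning when T < 2R, PD repair", {
  fx <- small_cohort(seed = 2)
  covs <- fx$covs
  grp <- vapply(fx$cohort$subjects, `[[`, 1, "group")
  expect_true(all((covs$hama > 18) == (grp == 2)))
  expect_warning(
    generate_cohort(fx$atlas, 3, 3, 30, effect = effect_spec(delta = 0), seed = 1),
    "rank-deficient|noisy"
  )
  # an inadmissible delta drives the block matrix non-PD; repair = FALSE errors
  eff_big <- effect_spec(network_pairs = list(c("SC", "VN")), delta = 0.85)
  a160 <- generate_atlas(160, seed = 1)
  expect_error(
    suppressWarnings(generate_cohort(a160, 2, 2, 400, effect = eff_big,
                                     seed = 1, repair = FALSE)),
    "nearest-PD"
  )
  # determinism
  c1 <- generate_cohort(fx$atlas, 4, 4, 60, effect = effect_spec(delta = 0.2),
                        seed = 5)
  c2 <- generate_cohort(fx$atlas, 4, 4, 60, effect = effect_spec(delta = 0.2),
                        seed = 5)
  expect_identical(c1$subjects, c2$subjects)
})

test_that("donor expression plants genes on the target map", {
  a <- generate_atlas(30, seed = 3)
  tm <- seq(-2, 2, length.out = 30)
  # noise -> 0 limit: planted regional truth tracks the map at rho -> 1
  eff <- effect_spec(n_planted_genes = 5, spatial_corr_length = 30)
  dd0 <- generate_donor_expression(a, n_donors = 2, n_genes = 20,
                                   target_map = tm, effect = eff, seed = 1,
                                   gp_noise_sd = 1e-6)
  for (g in dd0$planted_genes) {
    expect_gt(cor(dd0$regional_truth[, g], tm, method = "spearman"), 0.99)
  }
  # decoy correlation with the map is zero in expectation (Monte-Carlo, 50 seeds)
  cors <- vapply(1:50, function(s) {
    dd <- generate_donor_expression(a, n_donors = 1, n_genes = 4,
                                    target_map = tm,
                                    effect = effect_spec(n_planted_genes = 1),
                                    seed = s)
    decoys <- setdiff(colnames(dd$regional_truth), dd$planted_genes)
    mean(cor(dd$regional_truth[, decoys], tm))
  }, numeric(1))
  expect_lt(abs(mean(cors)), 0.1)
  # determinism
  d1 <- generate_donor_expression(a, 2, 15, tm, eff, seed = 9)
  d2 <- generate_donor_expression(a, 2, 15, tm, eff, seed = 9)
  expect_identical(d1, d2)
  expect_error(
    generate_donor_expression(a, n_donors = 2, n_genes = 3, target_map = tm,
                              effect = effect_spec(), seed = 1),
    "n_planted_genes"
  )
})

test_that("jitter calibrated for ~10% assignment drops gives ~10% unassigned", {
  # P(|N3(0, s^2 I)| > 10) = 0.1 at s = 10 / sqrt(qchisq(0.9, 3)) ~= 4.0
  a <- generate_atlas(30, seed = 3)
  s10 <- 10 / sqrt(qchisq(0.9, 3))
  drops <- vapply(1:10, function(s) {
    dd <- generate_donor_expression(a, n_donors = 3, n_genes = 5,
                                    target_map = rnorm(30),
                                    effect = effect_spec(n_planted_genes = 2),
                                    seed = s, samples_per_region = 3,
                                    jitter_sd = s10)
    asg <- assign_samples_to_regions(dd, a)
    mean(is.na(asg$region_id))
  }, numeric(1))
  expect_lt(abs(mean(drops) - 0.1), 0.05)
})

test_that("gene-set generation plants one dominated term and decoys", {
  universe <- sprintf("g%03d", 1:100)
  planted <- universe[1:20]
  gs <- generate_gene_sets(universe, planted, n_terms = 10,
                           term_size_range = c(5, 20), seed = 3)
  expect_length(gs, 10)
  expect_true("PLANTED_SET" %in% names(gs))
  pl <- gs$PLANTED_SET$genes
  expect_true(all(planted %in% pl))
  expect_gte(mean(pl %in% planted), 0.8)
  # planted term attains the minimal ORA p when the selection is the planted set
  ora <- hypergeom_ora(planted, universe, gs)
  expect_equal(ora$term[1], "PLANTED_SET")
  expect_equal(min(ora$p), ora$p[ora$term == "PLANTED_SET"])
  # no planted genes -> no planted term
  gs0 <- generate_gene_sets(universe, character(), n_terms = 5,
                            term_size_range = c(5, 20), seed = 3)
  expect_false("PLANTED_SET" %in% names(gs0))
  expect_error(generate_gene_sets(universe, "not_there", seed = 1), "subset")
  expect_error(generate_gene_sets(universe[1:5], universe[1], n_terms = 2,
                                  term_size_range = c(2, 10), seed = 1),
               "exceed")
  expect_identical(gs, generate_gene_sets(universe, planted, n_terms = 10,
                                          term_size_range = c(5, 20), seed = 3))
})

test_that("decoy terms stay above q = 0.05 under random selection", {
  universe <- sprintf("g%03d", 1:200)
  gs <- generate_gene_sets(universe, character(), n_terms = 15,
                           term_size_range = c(10, 40), seed = 1)
  clean <- vapply(1:50, function(s) {
    sel <- with_seed(s, sample(universe, 25))
    ora <- hypergeom_ora(sel, universe, gs)
    all(ora$q >= 0.05)
  }, logical(1))
  expect_gte(mean(clean), 0.9)
})

test_that("planted-gene spatial coupling is monotone in the effect size", {
  a <- generate_atlas(30, seed = 3)
  tm <- as.numeric(scale(seq_len(30)^1.3))
  mean_cor <- vapply(c(0.2, 0.6, 1.5), function(cc) {
    mean(vapply(1:8, function(s) {
      dd <- generate_donor_expression(a, 1, 10, tm,
                                      effect_spec(n_planted_genes = 5),
                                      seed = s, coupling = cc,
                                      gp_noise_sd = 0.5)
      mean(cor(dd$regional_truth[, dd$planted_genes], tm))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_cor) > 0))
})
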