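# The diversity-panel generator: determinism, structure, the hemi-SNP
# mechanism, expression and trait calibration.

test_that("the generator is fully deterministic under a seed", {
  p1 <- simulate_panel(seed = 41, n_accessions = 50, models_per_genome = 20,
                       sites_per_model = 2)
  p2 <- simulate_panel(seed = 41, n_accessions = 50, models_per_genome = 20,
                       sites_per_model = 2)
  expect_identical(p1$pileup, p2$pileup)
  expect_identical(p1$expression, p2$expression)
  expect_identical(p1$trait, p2$trait)
  expect_identical(p1$truth$causal_sites, p2$truth$causal_sites)
  p3 <- simulate_panel(seed = 42, n_accessions = 50, models_per_genome = 20,
                       sites_per_model = 2)
  expect_false(identical(p1$trait, p3$trait))
  # the caller's RNG stream is untouched
  set.seed(1); before <- rnorm(1)
  set.seed(1); invisible(simulate_genotypes(n_accessions = 10,
                                            models_per_genome = 5,
                                            sites_per_model = 2, seed = 9))
  expect_identical(rnorm(1), before)
})

test_that("genotype structure follows the admixture and Fst settings", {
  sim <- simulate_genotypes(n_accessions = 150, models_per_genome = 60,
                            sites_per_model = 3, fst = 0.3, admixed = FALSE,
                            seed = 44)
  Q <- estimate_q(sim$genotypes, k = 2)
  lab <- max.col(Q)
  acc <- max(mean(lab == sim$labels), mean(3 - lab == sim$labels))
  expect_gte(acc, 0.95)
  expect_true(all(rowSums(sim$admixture) == 1))
  # fst = 0: no detectable structure, the estimator warns
  sim0 <- simulate_genotypes(n_accessions = 100, models_per_genome = 60,
                             sites_per_model = 3, fst = 0, seed = 45)
  expect_warning(estimate_q(sim0$genotypes, k = 2), "eigengap")
})

test_that("sites within a CDS model are linked, across models they are not", {
  sim <- simulate_genotypes(n_accessions = 300, models_per_genome = 40,
                            sites_per_model = 4, fst = 0, seed = 46)
  st <- sim$site_table
  G <- sim$genotypes
  r2 <- cor(G)^2
  same <- outer(st$model_id, st$model_id, "==") & upper.tri(r2)
  diff <- (!outer(st$model_id, st$model_id, "==")) & upper.tri(r2)
  expect_gt(mean(r2[same], na.rm = TRUE), 10 * mean(r2[diff], na.rm = TRUE))
})

test_that("low coverage drives calls missing at the Poisson rate", {
  sim <- simulate_genotypes(n_accessions = 60, models_per_genome = 20,
                            sites_per_model = 2, seed = 47)
  pile <- simulate_pileups(sim, depth_mean = 8, seed = 47)
  calls <- call_matrix_from_pileup(pile)
  expect_equal(mean(is.na(calls)), ppois(10, 8), tolerance = 0.02)
})

test_that("hemi-SNPs appear only through cross-mapping and increase with it", {
  hemi_frac <- vapply(c(0, 0.15, 0.25, 0.35), function(rate) {
    sim <- simulate_genotypes(n_accessions = 100, models_per_genome = 40,
                              sites_per_model = 3, seed = 48)
    pile <- simulate_pileups(sim, cross_mapping_rate = rate,
                             discriminating_frac = 0, seed = 48)
    calls <- filter_sites(call_matrix_from_pileup(pile))
    mean(apply(calls, 1, classify_snp) == "hemi")
  }, numeric(1))
  # no cross-mapping: no ambiguity codes beyond the sequencing-error floor
  expect_lt(hemi_frac[1], 0.01)
  expect_true(all(diff(hemi_frac) >= 0))
  expect_gt(hemi_frac[4], 0.5)
})

test_that("expression backgrounds, silent genes and the causal gene behave", {
  go <- simulate_genotypes(n_accessions = 5, models_per_genome = 10,
                           sites_per_model = 2, seed = 49)$gene_order
  # degenerate spread -> constant matrix
  E0 <- simulate_expression(go, 20, sdlog_between = 0, sdlog_within = 0,
                            silent_frac = 0, seed = 50)
  expect_equal(max(E0) - min(E0), 0)
  z <- rbinom(200, 1, 0.5)
  E <- simulate_expression(go, 200, causal_model = go$model_id[3],
                           causal_genotype = z, seed = 51)
  tr <- attr(E, "expr_truth")
  # silent models fail the expression floor
  expect_false(any(tr$silent_models %in% expression_filter(E)))
  # the causal gene is bimodal: carriers express lower by the shift
  cm <- E[go$model_id[3], ]
  expect_equal(mean(log(cm[z == 1])) - mean(log(cm[z == 0])), -1.5,
               tolerance = 0.2)
})

test_that("trait simulation matches the target heritability", {
  sim <- simulate_genotypes(n_accessions = 383, models_per_genome = 20,
                            sites_per_model = 2, seed = 52)
  Z <- sim$genotypes
  eff <- setNames(c(1, -0.8), colnames(Z)[c(3, 17)])
  y1 <- simulate_trait(Z, eff, h2 = 1, seed = 52)
  expect_equal(unname(drop(y1)), unname(drop(Z[, names(eff)] %*% eff)),
               ignore_attr = TRUE)
  y <- simulate_trait(Z, eff, h2 = 0.6, seed = 52)
  expect_lt(abs(attr(y, "trait_truth")$h2_realized - 0.6), 0.02)
  expect_error(simulate_trait(Z, setNames(numeric(0), character(0)),
                              h2 = 0.5),
               "degenerate genetic variance")
})

test_that("the default panel records consistent ground truth", {
  panel <- small_panel()
  tr <- panel$truth
  expect_length(tr$causal_sites, 2)
  expect_true(all(tr$causal_sites %in% colnames(tr$genotypes)))
  expect_true(startsWith(tr$causal_model, "C2"))
  expect_lt(tr$expression_slope, 0)
  expect_true(tr$latent_site %in% colnames(tr$genotypes))
  expect_false(startsWith(tr$latent_site, tr$causal_model))
  expect_equal(tr$trait_truth$h2_realized, tr$h2_target, tolerance = 0.03)
  expect_gt(tr$snp_predictable_frac, tr$gem_predictable_frac)
})
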