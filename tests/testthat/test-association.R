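# Mixed-model association, GEM regression, genomic control, thresholds,
# Manhattan tables.

test_that("null REML recovers variance components from kinship-distributed traits", {
  set.seed(14)
  n <- 300
  G <- matrix(rbinom(n * 3000, 1, runif(3000, 0.1, 0.9)), n, 3000,
              dimnames = list(sprintf("a%03d", 1:n), NULL))
  K <- kinship(G)
  L <- t(chol(unclass(K) + diag(1e-6, n)))
  h2s <- replicate(20, {
    g <- drop(L %*% rnorm(n))
    g <- g / sd(g) * sqrt(0.8)
    y <- setNames(g + rnorm(n, 0, sqrt(0.2)), rownames(G))
    suppressWarnings(fit_null_mlm(y, K = K)$h2)
  })
  expect_lt(abs(mean(h2s) - 0.8), 0.1)

  # pure-noise trait: no kinship signal
  y0 <- setNames(rnorm(n), rownames(G))
  h20 <- suppressWarnings(fit_null_mlm(y0, K = K)$h2)
  expect_lt(h20, 0.1)

  expect_error(fit_null_mlm(setNames(rep(1, n), rownames(G)), K = K),
               "constant")
  notK <- unclass(K); notK[1, 2] <- notK[1, 2] + 1   # asymmetric/non-PSD
  notK <- (notK + t(notK)) / 2
  notK[1, 1] <- -2
  expect_error(fit_null_mlm(y0, K = structure(notK, dimnames = dimnames(K))),
               "positive semidefinite")
})

test_that("with identity relatedness and no Q the scan equals OLS", {
  set.seed(15)
  n <- 30; m <- 50
  G <- matrix(rbinom(n * m, 1, 0.4), n, m,
              dimnames = list(sprintf("a%02d", 1:n), sprintf("s%02d", 1:m)))
  y <- setNames(rnorm(n) + G[, 3], rownames(G))
  scan <- suppressWarnings(snp_association(y, G))
  ols <- vapply(seq_len(m), function(j) {
    summary(lm(y ~ G[, j]))$coefficients[2, 4]
  }, numeric(1))
  expect_equal(scan$p_value[match(colnames(G), scan$id)], ols,
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("markers with missing calls are tested on their observed subset", {
  set.seed(16)
  n <- 60
  G <- matrix(rbinom(n * 10, 1, 0.5), n, 10,
              dimnames = list(sprintf("a%02d", 1:n), sprintf("s%02d", 1:10)))
  y <- setNames(rnorm(n) + 0.8 * G[, 1], rownames(G))
  Gm <- G
  Gm[1:10, 4] <- NA
  scan <- suppressWarnings(snp_association(y, Gm))
  # marker 4's p equals OLS on the 50 observed accessions
  obs <- 11:60
  pref <- summary(lm(y[obs] ~ G[obs, 4]))$coefficients[2, 4]
  expect_equal(scan$p_value[scan$id == "s04"], pref, tolerance = 1e-8)
  expect_equal(scan$n_used[scan$id == "s04"], 50)
  # all-missing markers are skipped with a warning
  Gm[, 7] <- NA
  expect_warning(scan2 <- snp_association(y, Gm), "all-missing")
  expect_false("s07" %in% scan2$id)
})

test_that("per-marker REML agrees with P3D on complete data", {
  set.seed(17)
  n <- 50
  G <- matrix(rbinom(n * 8, 1, 0.5), n, 8,
              dimnames = list(sprintf("a%02d", 1:n), sprintf("s%02d", 1:8)))
  bigG <- matrix(rbinom(n * 500, 1, 0.5), n, 500,
                 dimnames = list(rownames(G), NULL))
  K <- kinship(bigG)
  y <- setNames(rnorm(n) + G[, 2], rownames(G))
  s1 <- snp_association(y, G, K = K)
  s2 <- snp_association(y, G, K = K, per_marker_reml = TRUE)
  expect_equal(s1$minus_log10_p, s2$minus_log10_p, tolerance = 0.15)
})

test_that("genomic control deflates inflated scans and leaves deflated ones", {
  expect_equal(genomic_control(rep(0.5, 100))$lambda, 1, tolerance = 1e-9)
  set.seed(18)
  chi0 <- rchisq(20001, 1)
  infl <- genomic_control(pchisq(2 * chi0, 1, lower.tail = FALSE))
  expect_equal(infl$lambda, 2, tolerance = 0.05)
  # adjusted chi-squared equals original / lambda
  chi_adj <- qchisq(infl$p_adjusted, 1, lower.tail = FALSE)
  chi_in <- 2 * chi0
  expect_equal(chi_adj, chi_in / infl$lambda, tolerance = 1e-6)
  # lambda of the adjusted scan is exactly 1
  expect_equal(genomic_control(infl$p_adjusted)$lambda, 1, tolerance = 1e-9)
  # deflated scans untouched
  pd <- pchisq(0.8 * chi0, 1, lower.tail = FALSE)
  defl <- genomic_control(pd)
  expect_lt(defl$lambda, 1)
  expect_identical(defl$p_adjusted, pd)
  expect_error(genomic_control(numeric(0)), "empty")
  expect_error(genomic_control(c(0.5, 0)), "0, 1")
})

test_that("significance lines follow Bonferroni and Benjamini-Hochberg", {
  expect_equal(bonferroni_threshold(0.05, 1), -log10(0.05))
  expect_equal(round(bonferroni_threshold(0.05, 256397), 1), 6.7)
  expect_equal(round(bonferroni_threshold(0.05, 53889), 2), 6.03)
  expect_equal(fdr_line(rep(1e-9, 100)), 9)
  expect_equal(fdr_line(c(0.001, 0.02, 0.03, 0.9)), -log10(0.03))
  set.seed(19)
  expect_identical(fdr_line(runif(200)), Inf)
})

test_that("GEM regression recovers exact linear signals and reports the fit", {
  set.seed(20)
  n <- 80
  E <- matrix(rlnorm(40 * n, log(5), 0.5), 40, n,
              dimnames = list(sprintf("C2m%03d", 1:40), sprintf("a%02d", 1:n)))
  y <- setNames(2 * E[5, ], colnames(E))
  scan <- gem_association(y, E, gc = FALSE)
  hit <- scan[scan$id == "C2m005", ]
  expect_equal(hit$slope, 2, tolerance = 1e-8)
  expect_equal(hit$r2, 1, tolerance = 1e-8)
  expect_equal(which.max(scan$minus_log10_p), which(scan$id == "C2m005"))
  # intercept + slope * RPKM reproduces the trait on the regression line
  expect_equal(hit$intercept + hit$slope * E[5, 1], unname(y[1]),
               tolerance = 1e-6)
})

test_that("Q covariates reduce GEM inflation under structured expression", {
  sim <- simulate_genotypes(n_accessions = 150, models_per_genome = 60,
                            sites_per_model = 3, fst = 0.25, seed = 23)
  E <- simulate_expression(sim$gene_order, 150, admixture = sim$admixture,
                           structured_frac = 0.5, structure_loading_sd = 1,
                           seed = 23)
  q1 <- sim$admixture[, 1]
  y <- setNames(2 * q1 + rnorm(150, 0, 0.5), rownames(sim$genotypes))
  colnames(E) <- names(y)
  lam0 <- attr(gem_association(y, E, Q = NULL), "lambda_gc")
  Q <- suppressWarnings(estimate_q(sim$genotypes, k = 2))
  lamQ <- attr(gem_association(y, E, Q = Q), "lambda_gc")
  expect_gt(lam0, 1.2)
  expect_lt(lamQ, lam0)
})

test_that("Manhattan tables order markers and duplicate unassigned hemi-SNPs", {
  go <- polyAT:::validate_gene_order(data.frame(
    model_id = c("A1m001", "A1m002", "C1m001"),
    chromosome = c("A1", "A1", "C1"),
    order_index = c(1, 2, 1),
    cds_length = 500,
    homoeologue = c("C1m001", NA, "A1m001"),
    stringsAsFactors = FALSE))
  scan <- structure(data.frame(
    id = c("A1m001:5", "A1m002:9", "C1m001:2"),
    model_id = c("A1m001", "A1m002", "C1m001"),
    chromosome = factor(c("A1", "A1", "C1"), at_chromosomes()),
    order_index = c(1, 2, 1),
    minus_log10_p = c(3, 1, 7),
    p_value = 10^-c(3, 1, 7),
    effect_size = 1, maf = 0.2,
    snp_class = c("simple", "simple", "hemi"),
    assigned = c(TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE
  ), m_tested = 3, type = "snp", class = c("at_scan", "data.frame"))
  tab <- manhattan_table(scan, go)
  # the unassigned hemi-SNP appears at both homoeologous positions, pale
  expect_equal(nrow(tab), 4)
  dup <- tab[tab$id == "C1m001:2", ]
  expect_setequal(as.character(dup$chromosome), c("A1", "C1"))
  expect_true(all(!dup$dark))
  # A1 rows precede C1 rows; assigned simple SNPs are dark
  expect_equal(as.character(tab$chromosome), c("A1", "A1", "A1", "C1"))
  expect_true(all(tab$dark[tab$id == "A1m001:5"]))
  bad <- scan; bad$model_id[1] <- "nope"
  expect_error(manhattan_table(bad, go), "absent from gene order")
})

test_that("scan power grows with simulated effect size", {
  set.seed(27)
  n <- 150
  G <- matrix(rbinom(n * 60, 1, 0.5), n, 60,
              dimnames = list(sprintf("a%03d", 1:n), sprintf("s%02d", 1:60)))
  peaks <- vapply(c(0.2, 0.6, 1.2), function(b) {
    y <- setNames(b * G[, 1] + rnorm(n), rownames(G))
    scan <- suppressWarnings(snp_association(y, G))
    scan$minus_log10_p[scan$id == "s01"]
  }, numeric(1))
  expect_true(all(diff(peaks) > 0))
})
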