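# Genotype encoding, JC69 distances, dendrogram, Q estimation, kinship, LD.

test_that("dosage encoding maps states onto the alternate-allele axis", {
  calls <- rbind(
    two = c("A", "R", "A", "A", "R"),
    union3 = c("A", "G", "R", "A", "A"),
    missing = c("A", NA, "G", "A", "G")
  )
  colnames(calls) <- sprintf("a%d", 1:5)
  enc <- encode_genotypes(calls)
  expect_equal(unname(enc$dosage[, "two"]), c(0, 1, 0, 0, 1))
  expect_equal(unname(enc$dosage[, "union3"]), c(0, 1, 0.5, 0, 0))
  expect_true(is.na(enc$dosage["a2", "missing"]))
  # legend covers every observed state
  expect_setequal(names(enc$legend$union3), c("A", "G", "R"))
  # >3 states must be pre-filtered
  bad <- rbind(x = c("A", "C", "G", "T", "A"))
  colnames(bad) <- sprintf("a%d", 1:5)
  expect_error(encode_genotypes(bad), "3 states")
})

test_that("JC69 distance matches the closed form and flags saturation", {
  expect_equal(jc69_distance(rep("A", 10), rep("A", 10)), 0)
  x <- c(rep("A", 19), "G"); y <- rep("A", 20)
  expect_equal(jc69_distance(x, y), -0.75 * log(1 - 4 * 0.05 / 3))
  expect_equal(jc69_distance(x, y), 0.0517, tolerance = 1e-3)
  xs <- c(rep("G", 8), "A", "A"); ys <- rep("A", 10)
  expect_identical(jc69_distance(xs, ys), Inf)   # p = 0.8: saturated
  expect_error(jc69_distance(c(NA, "A"), c("A", NA)), "no shared")
})

test_that("jc69_matrix agrees with ape on resolved-base data", {
  set.seed(8)
  # sequences diverged from a common ancestor, well below saturation
  anc <- sample(c("A", "C", "G", "T"), 200, replace = TRUE)
  calls <- vapply(1:6, function(i) {
    mut <- runif(200) < 0.15
    out <- anc
    out[mut] <- sample(c("A", "C", "G", "T"), sum(mut), replace = TRUE)
    out
  }, character(200))
  colnames(calls) <- sprintf("t%d", 1:6)
  d <- jc69_matrix(calls)
  dna <- ape::as.DNAbin(t(matrix(tolower(calls), nrow(calls), ncol(calls),
                                 dimnames = dimnames(calls))))
  ref <- as.matrix(ape::dist.dna(dna, model = "JC69"))
  expect_equal(d[colnames(ref), colnames(ref)], ref, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("dendrogram topology is forced by the distances and is deterministic", {
  d <- matrix(c(0, .1, .5, .1, 0, .5, .5, .5, 0), 3, 3,
              dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  tr <- build_dendrogram(d)
  # x and y must be sisters
  pair <- ape::extract.clade(tr, ape::getMRCA(tr, c("x", "y")))$tip.label
  expect_setequal(pair, c("x", "y"))
  tr2 <- build_dendrogram(d[c(3, 1, 2), c(3, 1, 2)])
  expect_equal(suppressWarnings(ape::dist.topo(tr, tr2))[1], 0)
  d2 <- d; d2[1, 2] <- d2[2, 1] <- 0   # identical accessions
  h <- hclust(as.dist(d2), method = "average")
  expect_equal(h$height[1], 0)
  expect_error(build_dendrogram(matrix(c(0, Inf, Inf, 0), 2)), "non-finite")
})

test_that("Q estimation recovers subpopulations and admixture", {
  sim <- simulate_genotypes(n_accessions = 120, models_per_genome = 60,
                            sites_per_model = 3, fst = 0.3, admixed = FALSE,
                            seed = 4)
  Q <- estimate_q(sim$genotypes, k = 2)
  expect_equal(rowSums(Q), rep(1, nrow(Q)), tolerance = 1e-9,
               ignore_attr = TRUE)
  lab <- max.col(Q)
  acc <- max(mean(lab == sim$labels), mean(3 - lab == sim$labels))
  expect_gte(acc, 0.95)
  # the two subpopulations are well separated on the Q simplex
  sep <- abs(mean(Q[sim$labels == 1, 1]) - mean(Q[sim$labels == 2, 1]))
  expect_gt(sep, 0.5)

  # a 50/50 admixed accession placed midway lands near (0.5, 0.5)
  set.seed(9)
  S <- 400
  p1 <- runif(S, 0.05, 0.95); p2 <- runif(S, 0.05, 0.95)
  G <- rbind(
    matrix(rbinom(40 * S, 1, rep(p1, each = 40)), 40),
    matrix(rbinom(40 * S, 1, rep(p2, each = 40)), 40),
    matrix(rbinom(S, 1, (p1 + p2) / 2), 1)
  )
  rownames(G) <- c(sprintf("p1_%02d", 1:40), sprintf("p2_%02d", 1:40), "mix")
  Qm <- estimate_q(G, k = 2)
  expect_lt(abs(Qm["mix", 1] - 0.5), 0.1)

  expect_error(estimate_q(G, k = 1), "k must be")
  expect_error(estimate_q(G[, 1:5], k = 2), "too few markers")
})

test_that("a homogeneous panel triggers the weak-eigengap warning", {
  set.seed(12)
  G <- matrix(rbinom(80 * 400, 1, 0.4), 80, 400)
  rownames(G) <- sprintf("a%02d", 1:80)
  expect_warning(estimate_q(G, k = 2), "eigengap")
})

test_that("kinship is symmetric PSD with unit mean diagonal", {
  fit <- small_fit()
  K <- fit$K
  expect_equal(unclass(K), t(unclass(K)))
  expect_equal(mean(diag(K)), 1)
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-8)
  # duplicated accessions get the maximal off-diagonal entry
  G <- fit$enc$dosage
  G2 <- rbind(G, dup = G[1, ])
  rownames(G2) <- c(rownames(G), "dup")
  K2 <- suppressWarnings(kinship(G2))
  off <- K2[upper.tri(K2)]
  expect_equal(K2["dup", rownames(G)[1]], max(off))
})

test_that("kinship off-diagonals vanish for independent genotypes", {
  set.seed(21)
  G <- matrix(rbinom(100 * 5000, 1, 0.5), 100, 5000)
  rownames(G) <- sprintf("a%03d", 1:100)
  K <- kinship(G)
  off <- abs(K[upper.tri(K)])
  # centering induces E[K_ij] = -1/(n-1); beyond that only O(1/sqrt(m)) noise
  expect_lt(mean(off), 0.02)
  expect_lt(quantile(off, 0.99), 0.05)
})

test_that("LD scan picks one site per model and bounds r2 in [0,1]", {
  fit <- small_fit()
  ld <- suppressWarnings(ld_scan(fit$enc, fit$markers$annotations, seed = 1))
  all_r2 <- unlist(lapply(ld$pairs, `[[`, "r2"))
  expect_true(all(all_r2 >= 0 & all_r2 <= 1 | is.na(all_r2)))
  # one site per model
  mods <- sub(":[0-9]+$", "", ld$selected_sites)
  expect_false(anyDuplicated(mods) > 0)
  # determinism under the seed
  ld2 <- suppressWarnings(ld_scan(fit$enc, fit$markers$annotations, seed = 1))
  expect_identical(ld$selected_sites, ld2$selected_sites)
  ld3 <- suppressWarnings(ld_scan(fit$enc, fit$markers$annotations, seed = 2))
  expect_false(identical(ld$selected_sites, ld3$selected_sites))
})

test_that("duplicated markers give r2 = 1 and independent markers ~ 1/(n-1)", {
  set.seed(31)
  n <- 300
  G <- matrix(rbinom(n * 40, 1, 0.5), n, 40)
  G[, 2] <- G[, 1]   # same polymorphism scored in two models
  colnames(G) <- sprintf("A1m%03d:10", 1:40)
  rownames(G) <- sprintf("a%03d", 1:n)
  ann <- data.frame(site_id = colnames(G),
                    model_id = sprintf("A1m%03d", 1:40),
                    snp_class = "simple", genome_assigned = TRUE,
                    maf = colMeans(G), chromosome = "A1",
                    order_index = 1:40, stringsAsFactors = FALSE)
  ld <- ld_scan(G, ann, seed = 1)
  pr <- ld$pairs$A1
  dup <- pr$r2[(pr$site_i == colnames(G)[1] & pr$site_j == colnames(G)[2]) |
                 (pr$site_i == colnames(G)[2] & pr$site_j == colnames(G)[1])]
  expect_equal(dup, 1)
  indep <- pr$r2[!(pr$site_i %in% colnames(G)[1:2] &
                     pr$site_j %in% colnames(G)[1:2])]
  expect_equal(mean(indep), 1 / (n - 1), tolerance = 0.35)
})
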