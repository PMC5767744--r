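# Base calling, site filtering, classification, genome assignment, MAF.

test_that("call_base follows the depth/noise-threshold rule branches", {
  # depth must be in excess of 10
  expect_true(is.na(call_base(c(A = 8), depth = 8)))
  expect_true(is.na(call_base(c(A = 10), depth = 10)))
  expect_equal(call_base(c(A = 11), depth = 11), "A")
  # one base at frequency >= 0.2 -> resolved call; minor base at 0.15 ignored
  expect_equal(call_base(c(A = 34, C = 6), depth = 40), "A")
  # two bases >= 0.2 -> IUPAC two-base code
  expect_equal(call_base(c(A = 24, G = 16), depth = 40), "R")
  expect_equal(call_base(c(C = 20, T = 20), depth = 40), "Y")
  # three bases >= 0.2 -> not representable, missing
  expect_true(is.na(call_base(c(A = 12, C = 10, G = 8), depth = 30)))
  # no informative reads -> missing
  expect_true(is.na(call_base(c(A = 0), depth = 40)))
  expect_error(call_base(c(N = 5), depth = 20), "unknown base key")
  expect_error(call_base(c(A = -1), depth = 20), "negative")
})

test_that("vectorized calling agrees exactly with a brute-force oracle", {
  # independent scalar re-implementation of the rule branches
  oracle <- function(counts, depth, params) {
    if (depth <= params$min_depth_exclusive) return(NA_character_)
    tot <- sum(counts)
    if (tot == 0) return(NA_character_)
    fr <- counts / tot
    above <- names(counts)[fr >= params$noise_freq & counts > 0]
    if (length(above) == 1) return(above)
    if (length(above) == 2) {
      codes <- c(AG = "R", CT = "Y", CG = "S", AT = "W", GT = "K", AC = "M")
      return(unname(codes[paste0(min(above), max(above))]))
    }
    NA_character_
  }
  params <- calling_params()
  set.seed(11)
  for (rep in 1:20) {
    n_acc <- sample(2:5, 1); n_site <- sample(3:10, 1)
    depth <- matrix(rpois(n_acc * n_site, 15), n_acc, n_site)
    mats <- lapply(1:4, function(i)
      matrix(rbinom(n_acc * n_site, depth, 0.25), n_acc, n_site))
    # clip so counts sum <= depth
    tot <- Reduce(`+`, mats)
    over <- tot > depth
    mats[[1]][over] <- pmax(mats[[1]][over] - (tot - depth)[over], 0)
    got <- polyAT:::call_base_matrix(mats[[1]], mats[[2]], mats[[3]],
                                     mats[[4]], depth, params)
    want <- matrix(NA_character_, n_acc, n_site)
    for (i in seq_len(n_acc)) for (j in seq_len(n_site)) {
      want[i, j] <- oracle(c(A = mats[[1]][i, j], C = mats[[2]][i, j],
                             G = mats[[3]][i, j], T = mats[[4]][i, j]),
                           depth[i, j], params)
    }
    expect_identical(got, want)
  }
})

test_that("raising the noise threshold never creates an ambiguity code", {
  set.seed(5)
  for (rep in 1:200) {
    depth <- rpois(1, 40) + 11
    counts <- as.vector(rmultinom(1, depth, runif(4, 0.05, 1)))
    names(counts) <- c("A", "C", "G", "T")
    lo <- call_base(counts, depth, calling_params(noise_freq = 0.2))
    hi <- call_base(counts, depth, calling_params(noise_freq = 0.35))
    if (!is.na(lo) && lo %in% c("A", "C", "G", "T")) {
      expect_true(is.na(hi) || hi == lo)
    }
  }
})

test_that("site filters drop high-missingness, multi-allelic and monomorphic sites", {
  n <- 100
  calls <- rbind(
    miss30 = c(rep(NA, 30), rep(c("A", "G"), 35)),
    miss24 = c(rep(NA, 24), rep(c("A", "G"), 38)),
    four_states = rep(c("A", "G", "R", "T"), 25),
    three_states = rep(c("A", "G", "R"), length.out = n),
    mono = rep("A", n)
  )
  colnames(calls) <- sprintf("a%03d", 1:n)
  out <- filter_sites(calls)
  expect_setequal(rownames(out), c("miss24", "three_states"))
  ex <- attr(out, "exclusions")
  expect_equal(unname(ex["excess_missing"]), 1)
  expect_equal(unname(ex["too_many_alleles"]), 1)
  expect_equal(unname(ex["monomorphic"]), 1)
})

test_that("hemi/simple classification and genome assignment follow marker class", {
  expect_equal(classify_snp(c("A", "G", "A")), "simple")
  expect_equal(classify_snp(c("A", "R")), "hemi")
  expect_equal(classify_snp(c("R", "G", "K")), "hemi")
  expect_error(classify_snp(c("A", "A", NA)), "monomorphic")

  go <- polyAT:::validate_gene_order(data.frame(
    model_id = c("A8m001", "C3m001"), chromosome = c("A8", "C3"),
    order_index = c(1, 1), cds_length = 500, homoeologue = NA_character_,
    stringsAsFactors = FALSE))
  ids <- c("A8m001:10", "A8m001:20", "C3m001:5")
  cls <- c("simple", "hemi", "hemi")
  got <- assign_genome(ids, cls, go, linkage_evidence = "C3m001:5")
  expect_equal(got, c(TRUE, FALSE, TRUE))
  expect_error(assign_genome("Zz:1", "simple", go), "absent from gene order")
})

test_that("minor allele frequency is the second most frequent state", {
  x <- c(rep("A", 380), rep("R", 3))
  expect_equal(compute_maf(x), 3 / 383)
  expect_false(compute_maf(x) > 0.01)   # fails the MAF floor
  expect_equal(compute_maf(rep(c("A", "G"), 50)), 0.5)
  expect_error(compute_maf(rep("A", 10)), "monomorphic")
  expect_error(compute_maf(c(NA_character_, NA)), "missing")
  # ties report the tied frequency
  expect_equal(compute_maf(c("A", "A", "G", "G", "R")), 2 / 5)
})

test_that("calling is invariant to pileup row order", {
  panel <- small_panel()
  mk1 <- call_matrix_from_pileup(panel$pileup)
  set.seed(3)
  perm <- sample(nrow(panel$pileup))
  mk2 <- call_matrix_from_pileup(panel$pileup[perm, ])
  expect_identical(mk1, mk2)
})

test_that("call_snps annotates sites consistently with the calls", {
  fit <- small_fit()
  ann <- fit$markers$annotations
  calls <- fit$markers$calls
  expect_identical(ann$site_id, rownames(calls))
  expect_true(all(ann$maf >= 0 & ann$maf <= 0.5))
  # simple markers are always genome-assigned
  expect_true(all(ann$genome_assigned[ann$snp_class == "simple"]))
  # every hemi-assigned site carries linkage evidence
  hemi_assigned <- ann$site_id[ann$snp_class == "hemi" & ann$genome_assigned]
  expect_true(all(hemi_assigned %in% fit$panel$linkage_evidence))
  # re-derive class from the call states
  recls <- apply(calls, 1, classify_snp)
  expect_identical(unname(recls), ann$snp_class)
})
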