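# Shared fixtures, built in code and memoised across test files.

.panel_cache <- new.env(parent = emptyenv())

# small panel for module tests: 100 accessions, 80 models, 3 sites/model
small_panel <- function(seed = 1, ...) {
  key <- paste(seed, paste(deparse(substitute(list(...))), collapse = ""),
               sep = "|")
  got <- get0(key, envir = .panel_cache)
  if (is.null(got)) {
    got <- simulate_panel(seed = seed, n_accessions = 100,
                          models_per_genome = 40, sites_per_model = 3, ...)
    assign(key, got, envir = .panel_cache)
  }
  got
}

# called markers + structure for the small panel, memoised
small_fit <- function(seed = 1) {
  key <- paste0("fit|", seed)
  got <- get0(key, envir = .panel_cache)
  if (is.null(got)) {
    panel <- small_panel(seed)
    mk <- call_snps(panel$pileup, panel$gene_order,
                    linkage_evidence = panel$linkage_evidence)
    enc <- encode_genotypes(mk$calls)
    Q <- suppressWarnings(estimate_q(enc, k = 2))
    K <- suppressWarnings(kinship(enc))
    got <- list(panel = panel, markers = mk, enc = enc, Q = Q, K = K)
    assign(key, got, envir = .panel_cache)
  }
  got
}

# minimal hand-built marker set: one fully penetrant biallelic marker plus
# noise markers, for prediction tests
toy_markers <- function(n = 60, m_noise = 40, seed = 7) {
  set.seed(seed)
  acc <- sprintf("acc%02d", seq_len(n))
  z <- rbinom(n, 1, 0.5)
  calls <- matrix(NA_character_, m_noise + 1, n,
                  dimnames = list(c("A1m001:10",
                                    sprintf("A2m%03d:5", seq_len(m_noise))),
                                  acc))
  calls[1, ] <- ifelse(z == 1, "G", "A")
  for (j in seq_len(m_noise)) {
    calls[j + 1, ] <- sample(c("A", "G"), n, replace = TRUE)
  }
  go <- data.frame(
    model_id = c("A1m001", sprintf("A2m%03d", seq_len(m_noise))),
    chromosome = c("A1", rep("A2", m_noise)),
    order_index = c(1, seq_len(m_noise)),
    cds_length = 900,
    stringsAsFactors = FALSE
  )
  go <- polyAT:::validate_gene_order(go)
  ann <- annotate_markers(calls, go)
  list(calls = calls, annotations = ann, gene_order = go, z = z, acc = acc)
}
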