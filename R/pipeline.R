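# End-to-end pipeline: compose the stages on simulated or on-disk inputs and
# write a deterministic artifact tree.

#' Default pipeline configuration
#'
#' Every threshold mirrors the platform defaults: depth in excess of 10,
#' missingness below 0.25, at most 3 alleles, noise frequency 0.2, MAF floor
#' 0.01, expression floor 0.4 RPKM, alpha 0.05. The default input block
#' simulates the bundled panel; set `$input` to a list of file paths
#' (`pileup`, `gene_order`, `expression`, `trait`, `linkage`) to run on real
#' data.
#'
#' @param out_dir Output directory.
#' @param seed Master seed.
#' @param ... Overrides merged into the defaults.
#' @return A configuration list.
#' @export
run_config <- function(out_dir = "at_run", seed = 1, ...) {
  cfg <- list(
    out_dir = out_dir,
    seed = seed,
    simulate = list(),         # passed to simulate_panel(); NULL disables
    input = NULL,              # list of file paths; overrides simulate
    calling = list(),          # passed to calling_params()
    k = 2,
    alpha = 0.05,
    maf_min = 0.01,
    min_mean_rpkm = 0.4,
    gc_on_snp = FALSE,
    per_marker_reml = FALSE,
    do_loo = TRUE,
    fast_loo = TRUE
  )
  dots <- list(...)
  cfg[names(dots)] <- dots
  cfg
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the whole Associative Transcriptomics workflow
#'
#' Simulates (or reads) a panel, calls and annotates SNP markers, estimates
#' structure, kinship and LD, runs the SNP and GEM association scans with
#' their Bonferroni and FDR lines, builds Manhattan tables, optionally runs
#' take-one-out validation, and writes every artifact plus a log of
#' per-filter exclusion counts to `config$out_dir`. Reruns with the same
#' configuration produce identical outputs.
#'
#' @param config A list from [run_config()], or a path to a YAML file with
#'   the same fields.
#' @return (Invisibly) a list with the in-memory results and the output
#'   directory.
#' @export
run_all <- function(config = run_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- run_config()
  cfg[names(config)] <- config
  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out, "run_log.txt")
  cat(sprintf("polyAT run, seed %d\n", cfg$seed), file = logf)
  note <- function(...) cat(sprintf(...), "\n", file = logf, append = TRUE)

  inputs <- stage("inputs", {
    if (!is.null(cfg$input)) {
      for (f in unlist(cfg$input)) {
        if (!file.exists(f)) stop("missing input file: ", f)
      }
      list(
        gene_order = read_gene_order(cfg$input$gene_order),
        pileup = read_pileup(cfg$input$pileup),
        expression = read_expression(cfg$input$expression),
        trait = read_traits(cfg$input$trait),
        linkage_evidence = if (is.null(cfg$input$linkage)) character() else
          readLines(cfg$input$linkage),
        truth = NULL
      )
    } else {
      panel <- do.call(simulate_panel, c(list(seed = cfg$seed), cfg$simulate))
      write_gene_order(panel$gene_order, file.path(out, "gene_order.tsv"))
      write_traits(panel$trait, file.path(out, "trait.csv"))
      panel
    }
  })
  note("inputs: %d accessions phenotyped", sum(!is.na(inputs$trait)))

  params <- do.call(calling_params, cfg$calling)
  markers <- stage("snp_calling", {
    call_snps(inputs$pileup, inputs$gene_order, params,
              inputs$linkage_evidence)
  })
  write_site_calls(markers$calls, file.path(out, "marker_matrix.tsv"))
  write_tsv_raw(markers$annotations, file.path(out, "marker_annotations.tsv"))
  note("snp_calling: %s",
       paste(names(markers$log), markers$log, sep = "=", collapse = ", "))

  enc <- stage("encoding", encode_genotypes(markers$calls))
  Q <- stage("structure", estimate_q(enc, k = cfg$k, seed = cfg$seed))
  K <- stage("kinship", kinship(enc))
  write_tsv_raw(data.frame(accession_id = rownames(Q), unclass(Q)),
                file.path(out, "q_matrix.tsv"))
  write_tsv_raw(data.frame(accession_id = rownames(K), unclass(K),
                           check.names = FALSE),
                file.path(out, "kinship.tsv"))
  tree <- stage("dendrogram", build_dendrogram(jc69_matrix(markers$calls)))
  write_newick(tree, file.path(out, "dendrogram.nwk"))

  ld <- stage("ld", ld_scan(enc, markers$annotations, maf_min = cfg$maf_min,
                            seed = cfg$seed))
  write_tsv_raw(data.frame(chromosome = names(ld$chromosome_means),
                           mean_r2 = fmt_fixed(ld$chromosome_means, 6)),
                file.path(out, "ld_means.tsv"))
  note("ld: genome mean r2 = %.4f over %d selected sites",
       ld$genome_mean_r2, length(ld$selected_sites))

  null <- stage("null_mlm", fit_null_mlm(inputs$trait, K = K, Q = Q))
  note("null_mlm: h2 = %.4f (sigma_g2 %.4g, sigma_e2 %.4g)",
       null$h2, null$sigma_g2, null$sigma_e2)

  snp_scan <- stage("snp_association", {
    snp_association(inputs$trait, enc, annotations = markers$annotations,
                    Q = Q, K = K, null = null, maf_min = cfg$maf_min,
                    per_marker_reml = cfg$per_marker_reml,
                    gc = cfg$gc_on_snp)
  })
  gem_scan <- stage("gem_association", {
    gem_association(inputs$trait, inputs$expression, Q = Q,
                    gene_order = inputs$gene_order,
                    min_mean = cfg$min_mean_rpkm)
  })
  write_scan(snp_scan, file.path(out, "snp_scan.tsv"))
  write_scan(gem_scan, file.path(out, "gem_scan.tsv"))
  write_tsv_raw(manhattan_table(snp_scan, inputs$gene_order),
                file.path(out, "snp_manhattan.tsv"))
  write_tsv_raw(manhattan_table(gem_scan, inputs$gene_order),
                file.path(out, "gem_manhattan.tsv"))
  thresholds <- list(
    snp_bonferroni = bonferroni_threshold(cfg$alpha,
                                          attr(snp_scan, "m_tested")),
    snp_fdr = fdr_line(snp_scan$p_value),
    snp_m_tested = attr(snp_scan, "m_tested"),
    gem_bonferroni = bonferroni_threshold(cfg$alpha,
                                          attr(gem_scan, "m_tested")),
    gem_fdr = fdr_line(gem_scan$p_value),
    gem_m_tested = attr(gem_scan, "m_tested"),
    gem_lambda = attr(gem_scan, "lambda_gc"),
    h2 = null$h2
  )
  jsonlite::write_json(lapply(thresholds, function(v)
    if (is.numeric(v) && !is.finite(v)) "Inf" else v),
    file.path(out, "thresholds.json"), auto_unbox = TRUE, digits = NA)
  note("snp scan: %d markers, bonferroni %.2f; gem scan: %d models, lambda %.3f",
       thresholds$snp_m_tested, thresholds$snp_bonferroni,
       thresholds$gem_m_tested, thresholds$gem_lambda)

  loo_snp <- loo_gem <- NULL
  if (isTRUE(cfg$do_loo)) {
    mode <- if (isTRUE(cfg$fast_loo)) "fast" else "full"
    loo_snp <- stage("loo_snp", {
      take_one_out_snp(inputs$trait, markers, Q = Q, K = K,
                       alpha = cfg$alpha, maf_min = cfg$maf_min, mode = mode)
    })
    loo_gem <- stage("loo_gem", {
      take_one_out_gem(inputs$trait, inputs$expression, Q = Q,
                       alpha = cfg$alpha, min_mean = cfg$min_mean_rpkm,
                       mode = mode)
    })
    write_tsv_raw(loo_snp$report, file.path(out, "loo_snp.tsv"))
    write_tsv_raw(loo_gem$report, file.path(out, "loo_gem.tsv"))
    note("loo: snp R2 = %.3f, gem R2 = %.3f", loo_snp$r2, loo_gem$r2)
  }

  invisible(list(out_dir = out, markers = markers, Q = Q, K = K, ld = ld,
                 null = null, snp_scan = snp_scan, gem_scan = gem_scan,
                 thresholds = thresholds, loo_snp = loo_snp,
                 loo_gem = loo_gem, truth = inputs$truth))
}

#' Platform bookkeeping arithmetic
#'
#' Recomputes the headline bookkeeping quantities of a transcriptome
#' genotyping platform from its mapping statistics: total sequenced bases,
#' the missing-call percentage over the marker-by-accession call matrix, the
#' SNP density along the reference (kb per SNP), and the fraction of the
#' reference transcriptome covered by read mapping.
#'
#' @param n_accessions Panel size.
#' @param n_snps Markers scored across the panel.
#' @param n_missing_calls Missing entries of the marker x accession matrix.
#' @param reference_bases Aggregate reference transcriptome length (bases).
#' @param mapped_reference_bases Reference bases covered by mapped reads.
#' @param mean_reads_per_accession Mean reads generated per accession.
#' @param read_length_bases Read length (bases).
#' @return A list: `total_sequenced_bases`, `missing_call_pct`,
#'   `snp_density_kb`, `mapped_transcriptome_pct`.
#' @export
platform_bookkeeping <- function(n_accessions, n_snps, n_missing_calls,
                                 reference_bases, mapped_reference_bases,
                                 mean_reads_per_accession,
                                 read_length_bases) {
  list(
    total_sequenced_bases =
      n_accessions * mean_reads_per_accession * read_length_bases,
    missing_call_pct = 100 * n_missing_calls / (n_snps * n_accessions),
    snp_density_kb = reference_bases / n_snps / 1000,
    mapped_transcriptome_pct = 100 * mapped_reference_bases / reference_bases
  )
}
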