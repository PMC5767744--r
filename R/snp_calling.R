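# SNP calling from per-accession pileup summaries.
#
# The calling rules for polyploid transcriptome SNPs: a site call needs read
# depth in excess of the depth cutoff; a base contributes to the call only if
# its within-accession frequency reaches the noise threshold; two bases above
# the threshold give a two-base IUPAC ambiguity code (the hemi-SNP allele,
# produced by reads cross-mapped from the homoeologous gene); sites are kept
# when missingness is below the cutoff, they carry at most the allowed number
# of distinct call states, and they are polymorphic.

#' Calling parameters for polyploid transcriptome SNPs
#'
#' @param min_depth_exclusive Required read depth, exclusive: a call is made
#'   only when `depth > min_depth_exclusive` (default 10, i.e. depth >= 11).
#' @param noise_freq Minimum within-accession base frequency for a base to
#'   enter the call (default 0.2). Two bases at or above it yield an IUPAC
#'   ambiguity code; three or more yield a missing call.
#' @param max_missing_frac Sites with a missing-call fraction at or above this
#'   are excluded (default 0.25, exclusive: missing fraction must be < 0.25).
#' @param max_alleles Maximum number of distinct non-missing call states at a
#'   site (default 3; a resolved base and an ambiguity code count as distinct
#'   alleles, as each call state is one fixed allele in inbred material).
#' @param maf_min_exclusive Minor-allele-frequency floor used downstream for
#'   association and LD (default 0.01, exclusive: MAF > 0.01).
#' @return A list of class `calling_params`.
#' @export
calling_params <- function(min_depth_exclusive = 10, noise_freq = 0.2,
                           max_missing_frac = 0.25, max_alleles = 3,
                           maf_min_exclusive = 0.01) {
  stopifnot(noise_freq > 0, noise_freq < 0.5,
            max_missing_frac > 0, max_missing_frac < 1,
            max_alleles >= 2, min_depth_exclusive >= 0)
  structure(list(min_depth_exclusive = min_depth_exclusive,
                 noise_freq = noise_freq,
                 max_missing_frac = max_missing_frac,
                 max_alleles = max_alleles,
                 maf_min_exclusive = maf_min_exclusive),
            class = "calling_params")
}

#' Call the base state of one accession at one site
#'
#' @param counts Named non-negative counts for bases A, C, G, T (missing names
#'   treated as zero; unknown names are an error).
#' @param depth Count of quality-passing reads covering the site.
#' @param params A [calling_params()] object.
#' @return A single state: a resolved base, a two-base IUPAC code, or
#'   `NA_character_` for missing (insufficient depth, no informative reads, or
#'   three or more bases above the noise threshold).
#' @examples
#' call_base(c(A = 24, G = 16), depth = 40)  # "R"
#' call_base(c(A = 34, C = 6), depth = 40)   # "A"
#' call_base(c(A = 8), depth = 8)            # NA: depth not in excess of 10
#' @export
call_base <- function(counts, depth, params = calling_params()) {
  bad <- setdiff(names(counts), .BASES)
  if (length(bad)) stop("unknown base key: ", paste(bad, collapse = ", "))
  if (any(counts < 0)) stop("negative base count")
  full <- setNames(numeric(4), .BASES)
  full[names(counts)] <- counts
  m <- call_base_matrix(matrix(full["A"]), matrix(full["C"]),
                        matrix(full["G"]), matrix(full["T"]),
                        depth = matrix(depth), params = params)
  m[1, 1]
}

# Vectorized calling over aligned count matrices (accessions x sites).
call_base_matrix <- function(A, C, G, T, depth, params = calling_params()) {
  informative <- A + C + G + T
  denom <- ifelse(informative > 0, informative, 1)
  above <- array(0L, dim = dim(A))
  hi1 <- array("", dim = dim(A)); hi2 <- array("", dim = dim(A))
  for (b in .BASES) {
    cnt <- switch(b, A = A, C = C, G = G, T = T)
    ok <- cnt / denom >= params$noise_freq & cnt > 0
    above <- above + ok
    hi2[ok & above == 2L] <- b
    hi1[ok & above == 1L] <- b
  }
  out <- array(NA_character_, dim = dim(A))
  one <- above == 1L
  out[one] <- hi1[one]
  two <- above == 2L
  if (any(two)) out[two] <- iupac2(hi1[two], hi2[two])
  out[depth <= params$min_depth_exclusive | informative == 0] <- NA_character_
  dimnames(out) <- dimnames(A)
  out
}

#' Build a site-call matrix from a pileup table
#'
#' Pivots the long pileup into per-base count matrices and applies
#' [call_base()] to every (site, accession) cell. Output row order is by site
#' id, column order by accession id, so the result is independent of pileup
#' row order.
#'
#' @param pileup A pileup `data.frame` ([read_pileup()]).
#' @param params A [calling_params()] object.
#' @return Character matrix (sites x accessions) with ids `model:position`.
#' @export
call_matrix_from_pileup <- function(pileup, params = calling_params()) {
  site <- paste(pileup$model, pileup$position, sep = ":")
  sites <- sort(unique(site))
  accs <- sort(unique(pileup$accession))
  i <- match(site, sites)
  j <- match(pileup$accession, accs)
  idx <- cbind(i, j)
  mk <- function(col) {
    m <- matrix(0, nrow = length(sites), ncol = length(accs),
                dimnames = list(sites, accs))
    m[idx] <- col
    m
  }
  depth <- matrix(0, length(sites), length(accs), dimnames = list(sites, accs))
  depth[idx] <- pileup$depth
  call_base_matrix(mk(pileup$A), mk(pileup$C), mk(pileup$G), mk(pileup$T),
                   depth = depth, params = params)
}

#' Filter candidate sites on missingness, allele count and polymorphism
#'
#' Retains sites with (i) missing fraction strictly below
#' `params$max_missing_frac`, (ii) at most `params$max_alleles` distinct
#' non-missing call states, and (iii) at least two distinct states
#' (polymorphic).
#'
#' @inheritParams call_matrix_from_pileup
#' @param calls Character matrix (sites x accessions).
#' @return The retained rows of `calls`, with an `"exclusions"` attribute
#'   giving per-filter exclusion counts.
#' @export
filter_sites <- function(calls, params = calling_params()) {
  miss_frac <- rowMeans(is.na(calls))
  n_states <- apply(calls, 1, function(x) length(unique(x[!is.na(x)])))
  keep_miss <- miss_frac < params$max_missing_frac
  keep_alle <- n_states <= params$max_alleles
  keep_poly <- n_states >= 2
  keep <- keep_miss & keep_alle & keep_poly
  out <- calls[keep, , drop = FALSE]
  attr(out, "exclusions") <- c(
    candidate_sites = nrow(calls),
    excess_missing = sum(!keep_miss),
    too_many_alleles = sum(keep_miss & !keep_alle),
    monomorphic = sum(keep_miss & keep_alle & !keep_poly),
    retained = sum(keep)
  )
  out
}

#' Classify a polymorphic site as a simple SNP or a hemi-SNP
#'
#' A hemi-SNP is a polymorphism in which at least one allele is a two-base
#' mixture (IUPAC ambiguity code) caused by fixed differences between
#' homoeologues plus cross-mapped reads; a simple SNP is a polymorphism
#' between resolved bases only.
#'
#' @param states Character vector of call states at one site (one per
#'   accession, `NA` = missing), or the unique states.
#' @return `"hemi"` if any observed state is an ambiguity code, else
#'   `"simple"`. Monomorphic input is an error.
#' @export
classify_snp <- function(states) {
  u <- unique(states[!is.na(states)])
  if (length(u) < 2) stop("cannot classify a monomorphic site")
  if (any(is_ambiguity_code(u))) "hemi" else "simple"
}

#' Decide whether a marker can be assigned to a subgenome
#'
#' Simple SNPs are assigned with confidence to the genome of the CDS model in
#' which they are scored. Hemi-SNPs may reside in either homoeologue, so they
#' are assigned only when direct linkage-map evidence places them (e.g. from a
#' doubled-haploid mapping population); otherwise they are rendered as pale
#' points in Manhattan output.
#'
#' @param site_ids Character vector `model:position`.
#' @param snp_class `"simple"`/`"hemi"` per site.
#' @param gene_order Gene-order table ([read_gene_order()]).
#' @param linkage_evidence Character vector of linkage-mapped site ids.
#' @return Logical vector: genome-assigned or not.
#' @export
assign_genome <- function(site_ids, snp_class, gene_order,
                          linkage_evidence = character()) {
  model <- sub(":[0-9]+$", "", site_ids)
  hit <- match(model, gene_order$model_id)
  if (any(is.na(hit))) {
    stop("site(s) in models absent from gene order: ",
         paste(head(unique(model[is.na(hit)]), 3), collapse = ", "))
  }
  ifelse(snp_class == "simple", TRUE, site_ids %in% linkage_evidence)
}

#' Minor allele frequency of a site
#'
#' The frequency of the second-most-frequent non-missing call state among
#' non-missing calls. Ties are broken by reporting the tied frequency.
#'
#' @param states Character vector of call states (`NA` = missing).
#' @return MAF in `[0, 0.5]`.
#' @export
compute_maf <- function(states) {
  x <- states[!is.na(states)]
  if (!length(x)) stop("all calls missing")
  tab <- sort(table(x), decreasing = TRUE)
  if (length(tab) < 2) stop("monomorphic site has no minor allele")
  unname(tab[2] / length(x))
}

#' Call, filter, classify and annotate SNP markers from pileups
#'
#' The full SNP-identification stage: per-accession base calling, site
#' filtering, simple/hemi classification, genome assignment and MAF
#' annotation. MAF filtering is not applied here -- all retained polymorphic
#' sites are scored and annotated; association and LD apply the MAF floor.
#'
#' @inheritParams call_matrix_from_pileup
#' @inheritParams assign_genome
#' @return A list of class `at_markers`:
#'   \describe{
#'     \item{calls}{site-call matrix (sites x accessions)}
#'     \item{annotations}{`data.frame` with `site_id`, `model_id`,
#'       `snp_class`, `genome_assigned`, `maf`, `chromosome`, `order_index`}
#'     \item{log}{per-filter exclusion counts}
#'   }
#' @export
call_snps <- function(pileup, gene_order, params = calling_params(),
                      linkage_evidence = character()) {
  calls <- call_matrix_from_pileup(pileup, params)
  calls <- filter_sites(calls, params)
  log <- attr(calls, "exclusions")
  ann <- annotate_markers(calls, gene_order, linkage_evidence)
  structure(list(calls = calls, annotations = ann, log = log),
            class = "at_markers")
}

#' Annotate a filtered site-call matrix
#'
#' @inheritParams assign_genome
#' @param calls Filtered site-call matrix.
#' @return Marker annotation `data.frame` (see [call_snps()]).
#' @export
annotate_markers <- function(calls, gene_order,
                             linkage_evidence = character()) {
  site_ids <- rownames(calls)
  model <- sub(":[0-9]+$", "", site_ids)
  hit <- match(model, gene_order$model_id)
  if (any(is.na(hit))) {
    stop("site(s) in models absent from gene order: ",
         paste(head(unique(model[is.na(hit)]), 3), collapse = ", "))
  }
  snp_class <- apply(calls, 1, classify_snp)
  maf <- apply(calls, 1, compute_maf)
  assigned <- assign_genome(site_ids, snp_class, gene_order, linkage_evidence)
  data.frame(
    site_id = site_ids,
    model_id = model,
    snp_class = snp_class,
    genome_assigned = assigned,
    maf = maf,
    chromosome = gene_order$chromosome[hit],
    order_index = gene_order$order_index[hit],
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' @export
print.at_markers <- function(x, ...) {
  cat("Polyploid SNP marker set\n")
  cat(sprintf("  %d sites x %d accessions\n", nrow(x$calls), ncol(x$calls)))
  tab <- table(x$annotations$snp_class)
  cat(sprintf("  simple: %d  hemi: %d (%.1f%% hemi)\n",
              tab["simple"] %||% 0, tab["hemi"] %||% 0,
              100 * (tab["hemi"] %||% 0) / nrow(x$calls)))
  cat(sprintf("  genome-assigned: %d  MAF > 0.01: %d\n",
              sum(x$annotations$genome_assigned),
              sum(x$annotations$maf > 0.01)))
  cat("  filter log: ",
      paste(names(x$log), x$log, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a
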