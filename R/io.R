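# Readers and writers for every text format the pipeline touches.
#
# All files are UTF-8 and tab-delimited except traits (CSV). Missing site
# calls are serialized as "N", missing trait values as an empty field.
# Floats are written with fixed 4 decimals, p-values in scientific notation,
# so write -> read -> write is byte-stable.

fmt_fixed <- function(x, digits = 4) {
  ifelse(is.na(x), "NA", formatC(x, format = "f", digits = digits))
}

fmt_p <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, format = "e", digits = 6))
}

write_tsv_raw <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
}

stop_line <- function(path, line, msg) {
  stop(sprintf("%s: line %d: %s", path, line, msg), call. = FALSE)
}

## ---- gene order -----------------------------------------------------------

#' Read or write an ordered CDS gene-model reference table
#'
#' The gene-order table is the Manhattan x-axis: one row per CDS model with
#' its chromosome (A1--A10, C1--C9), order index along the chromosome, CDS
#' length in bases and (optionally) the model id of its homoeologue on the
#' other subgenome. The `genome` column (A or C) is derived from the
#' chromosome prefix.
#'
#' @param path File path of a tab-delimited table with columns `model_id`,
#'   `chromosome`, `order_index`, `cds_length` and optionally `homoeologue`.
#' @return A `data.frame` with the columns above plus `genome`, validated:
#'   unique model ids, strictly increasing `order_index` within chromosome,
#'   `cds_length >= 3`.
#' @export
read_gene_order <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("model_id", "chromosome", "order_index", "cds_length")
  if (!all(need %in% names(df))) {
    stop("gene order file must have columns: ", paste(need, collapse = ", "))
  }
  if (!"homoeologue" %in% names(df)) df$homoeologue <- NA_character_
  df$homoeologue[df$homoeologue == ""] <- NA_character_
  validate_gene_order(df)
}

validate_gene_order <- function(df) {
  df$chromosome <- chrom_factor(df$chromosome)
  if (anyDuplicated(df$model_id)) stop("duplicate model_id in gene order")
  if (any(df$cds_length < 3)) stop("cds_length must be >= 3")
  if (any(df$order_index < 1 | df$order_index != round(df$order_index))) {
    stop("order_index must be a positive integer")
  }
  for (ch in levels(droplevels(df$chromosome))) {
    oi <- df$order_index[df$chromosome == ch]
    if (length(oi) && any(diff(sort(oi)) < 1)) {
      stop("order_index not strictly increasing on ", ch)
    }
  }
  df$genome <- genome_of_chromosome(df$chromosome)
  df[order(df$chromosome, df$order_index), , drop = FALSE]
}

#' @rdname read_gene_order
#' @param gene_order A validated gene-order `data.frame`.
#' @export
write_gene_order <- function(gene_order, path) {
  out <- data.frame(
    model_id = gene_order$model_id,
    chromosome = as.character(gene_order$chromosome),
    order_index = gene_order$order_index,
    cds_length = gene_order$cds_length,
    homoeologue = ifelse(is.na(gene_order$homoeologue), "",
                         gene_order$homoeologue),
    stringsAsFactors = FALSE
  )
  write_tsv_raw(out, path)
  invisible(path)
}

## ---- pileups --------------------------------------------------------------

#' Read a per-accession base-count pileup table
#'
#' One row per (accession, CDS model, position): the count of quality-passing
#' reads covering the site (`depth`) and the per-base read counts. Counts are
#' already base-quality filtered upstream, so `A + C + G + T <= depth`.
#'
#' @param path Tab-delimited file with header
#'   `accession`, `model`, `position`, `depth`, `A`, `C`, `G`, `T`.
#' @return A validated `data.frame` in input row order.
#' @export
read_pileup <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("accession", "model", "position", "depth", "A", "C", "G", "T")
  if (!all(need %in% names(df))) {
    stop("pileup file must have columns: ", paste(need, collapse = ", "))
  }
  validate_pileup(df, path = path)
}

validate_pileup <- function(df, path = "<pileup>") {
  counts <- as.matrix(df[, .BASES, drop = FALSE])
  bad <- which(!complete.cases(df[, c("position", "depth", .BASES)]))
  if (length(bad)) stop_line(path, bad[1] + 1L, "malformed row (missing value)")
  bad <- which(df$depth < 0)
  if (length(bad)) stop_line(path, bad[1] + 1L, "negative depth")
  bad <- which(rowSums(counts < 0) > 0)
  if (length(bad)) stop_line(path, bad[1] + 1L, "negative base count")
  bad <- which(df$position < 1 | df$position != round(df$position))
  if (length(bad)) stop_line(path, bad[1] + 1L, "position must be >= 1")
  bad <- which(rowSums(counts) > df$depth)
  if (length(bad)) stop_line(path, bad[1] + 1L, "base counts exceed depth")
  df
}

#' @rdname read_pileup
#' @param pileup A pileup `data.frame` as returned by [read_pileup()] or
#'   [simulate_pileups()].
#' @export
write_pileup <- function(pileup, path) {
  write_tsv_raw(pileup[, c("accession", "model", "position", "depth", .BASES)],
                path)
  invisible(path)
}

## ---- site-call matrix -----------------------------------------------------

#' Read or write a site-call matrix
#'
#' Sites in rows (ids `model:position`), accessions in columns. States are
#' resolved bases, two-base IUPAC ambiguity codes (hemi-SNP alleles), or `N`
#' for missing; `N` is parsed to `NA`.
#'
#' @param path Tab-delimited file; first column `site_id`, remaining columns
#'   one per accession.
#' @return Character matrix with site ids as rownames, accession ids as
#'   colnames, and `NA` for missing calls.
#' @export
read_site_calls <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "site_id") stop("first column must be site_id")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$site_id
  m[m == "N"] <- NA_character_
  validate_site_calls(m)
}

validate_site_calls <- function(m) {
  states <- unique(m[!is.na(m)])
  bad <- setdiff(states, .CALL_ALPHABET)
  if (length(bad)) stop("states outside the call alphabet: ",
                        paste(bad, collapse = ", "))
  m
}

#' @rdname read_site_calls
#' @param calls Character matrix of call states (sites x accessions).
#' @export
write_site_calls <- function(calls, path) {
  out <- calls
  out[is.na(out)] <- "N"
  df <- data.frame(site_id = rownames(calls), out, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_raw(df, path)
  invisible(path)
}

## ---- expression matrix ----------------------------------------------------

#' Read or write an RPKM expression matrix
#'
#' CDS models in rows, accessions in columns, values in reads per kilobase of
#' transcript per million aligned reads (RPKM). All values must be finite and
#' non-negative.
#'
#' @param path Tab-delimited file; first column `model_id`.
#' @return Numeric matrix (models x accessions).
#' @export
read_expression <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "model_id") stop("first column must be model_id")
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- df$model_id
  validate_expression(m)
}

validate_expression <- function(m) {
  if (any(!is.finite(m))) stop("RPKM values must be finite")
  if (any(m < 0)) stop("RPKM values must be non-negative")
  m
}

#' @rdname read_expression
#' @param rpkm Numeric matrix of RPKM values (models x accessions).
#' @export
write_expression <- function(rpkm, path) {
  df <- data.frame(model_id = rownames(rpkm),
                   apply(rpkm, 2, fmt_fixed),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_raw(df, path)
  invisible(path)
}

## ---- traits ---------------------------------------------------------------

#' Read or write a trait table
#'
#' CSV with columns `accession_id` and `value` (trait-specific units, e.g.
#' percent erucic acid or the gamma/alpha-tocopherol ratio). An empty value
#' field means the accession was not phenotyped; such accessions are dropped
#' per analysis, not at read time.
#'
#' @param path CSV file path.
#' @return Named numeric vector (names = accession ids, `NA` = missing).
#' @export
read_traits <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("accession_id", "value") %in% names(df))) {
    stop("trait file must have columns accession_id, value")
  }
  if (anyDuplicated(df$accession_id)) stop("duplicate accession_id in traits")
  setNames(as.numeric(df$value), df$accession_id)
}

#' @rdname read_traits
#' @param trait Named numeric vector of trait values.
#' @export
write_traits <- function(trait, path) {
  df <- data.frame(accession_id = names(trait),
                   value = ifelse(is.na(trait), "", fmt_fixed(trait)),
                   stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## ---- association scans ----------------------------------------------------

.SCAN_COLS <- c("id", "chromosome", "order_index", "minus_log10_p",
                "effect_size", "maf", "snp_class", "assigned", "p_value")

#' Read or write an association scan table
#'
#' One row per tested marker (SNP site or GEM model): chromosome, order index,
#' -log10 P, effect size, MAF (NA for GEMs), class and genome-assignability
#' flag. The scan-level genomic inflation factor is stored in a
#' `# lambda_gc:` header line and round-trips as the `lambda_gc` attribute.
#' Rows must be sorted by (chromosome, order_index); [write_scan()] refuses
#' unsorted input.
#'
#' @param path Tab-delimited file path.
#' @return A `data.frame` with attribute `lambda_gc`.
#' @export
read_scan <- function(path) {
  first <- readLines(path, n = 1)
  lambda <- NA_real_
  skip <- 0
  if (startsWith(first, "# lambda_gc:")) {
    lambda <- as.numeric(sub("# lambda_gc:", "", first))
    skip <- 1
  }
  df <- read.delim(path, stringsAsFactors = FALSE, skip = skip)
  df$chromosome <- chrom_factor(df$chromosome)
  df$assigned <- as.logical(df$assigned)
  attr(df, "lambda_gc") <- lambda
  df
}

#' @rdname read_scan
#' @param scan A scan `data.frame` (or an `at_scan` object) sorted by
#'   (chromosome, order_index).
#' @export
write_scan <- function(scan, path) {
  df <- as.data.frame(scan)
  missing_cols <- setdiff(.SCAN_COLS, names(df))
  for (cc in missing_cols) df[[cc]] <- NA
  ord <- order(chrom_factor(as.character(df$chromosome)), df$order_index)
  if (!identical(ord, seq_len(nrow(df)))) {
    stop("scan must be sorted by (chromosome, order_index) before writing")
  }
  out <- data.frame(
    id = df$id,
    chromosome = as.character(df$chromosome),
    order_index = df$order_index,
    minus_log10_p = fmt_fixed(df$minus_log10_p),
    effect_size = fmt_fixed(df$effect_size),
    maf = fmt_fixed(df$maf),
    snp_class = ifelse(is.na(df$snp_class), "NA", df$snp_class),
    assigned = df$assigned,
    p_value = fmt_p(df$p_value),
    stringsAsFactors = FALSE
  )
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  lambda <- attr(scan, "lambda_gc")
  if (!is.null(lambda) && !is.na(lambda)) {
    writeLines(sprintf("# lambda_gc: %.6f", lambda), con)
  }
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## ---- trees ----------------------------------------------------------------

#' Write a dendrogram to a newick file
#'
#' @param tree An [ape::phylo] tree, e.g. from [build_dendrogram()].
#' @param path Output newick file.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}
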