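# Shared alphabets and chromosome layout for the A/C allopolyploid reference.

#' Chromosome names of the allopolyploid reference, in genome order
#'
#' A1--A10 followed by C1--C9, the x-axis order used for Manhattan tables and
#' scan files. Plain string sorting would interleave A10 with A1/A2, so all
#' chromosome columns in the package are factors with these levels.
#'
#' @return Character vector of the 19 chromosome names.
#' @export
at_chromosomes <- function() {
  c(paste0("A", 1:10), paste0("C", 1:9))
}

# resolved bases
.BASES <- c("A", "C", "G", "T")

# two-base IUPAC ambiguity codes, keyed by the sorted base pair
.IUPAC2 <- c(
  "AG" = "R", "CT" = "Y", "CG" = "S", "AT" = "W", "GT" = "K", "AC" = "M"
)
.IUPAC2_DECODE <- list(
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
  W = c("A", "T"), K = c("G", "T"), M = c("A", "C")
)

.CALL_ALPHABET <- c(.BASES, names(.IUPAC2_DECODE))

iupac2 <- function(b1, b2) {
  key <- paste0(pmin(b1, b2), pmax(b1, b2))
  code <- .IUPAC2[key]
  if (any(is.na(code))) stop("not a valid base pair: ", key[is.na(code)][1])
  unname(code)
}

is_ambiguity_code <- function(state) {
  state %in% names(.IUPAC2_DECODE)
}

chrom_factor <- function(x) {
  bad <- !is.na(x) & !(x %in% at_chromosomes())
  if (any(bad)) {
    stop("unknown chromosome name(s): ", paste(unique(x[bad]), collapse = ", "))
  }
  factor(x, levels = at_chromosomes())
}

genome_of_chromosome <- function(chromosome) {
  substr(as.character(chromosome), 1, 1)
}

# restore the caller's RNG state after using a local seed
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_seed) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (has_seed) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}
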