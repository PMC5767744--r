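# Population structure and relatedness: numeric genotype encoding, JC69
# distances and dendrogram, a PCA-to-simplex admixture (Q) estimator, the
# kinship matrix for the mixed model, and per-chromosome linkage
# disequilibrium.

#' Encode call states as numeric alternate-allele dosages
#'
#' Per marker, the most frequent state is the reference (dosage 0). With two
#' states the other gets dosage 1. With three states where one is the IUPAC
#' union of the two resolved bases (e.g. A, G, R), the union code gets 0.5
#' and the resolved non-reference base gets 1. A third state that is not the
#' union of the other two is masked as missing (its dosage is not defined on
#' a single alternate-allele axis).
#'
#' @param calls Site-call matrix (sites x accessions).
#' @return A list of class `at_genotypes`:
#'   \describe{
#'     \item{dosage}{numeric matrix, accessions x markers, `NA` = missing}
#'     \item{legend}{per-marker named state-to-dosage maps}
#'   }
#' @export
encode_genotypes <- function(calls) {
  n_states <- apply(calls, 1, function(x) length(unique(x[!is.na(x)])))
  if (any(n_states > 3)) {
    stop("markers with more than 3 states must be filtered before encoding")
  }
  legend <- apply(calls, 1, encode_legend, simplify = FALSE)
  dosage <- matrix(NA_real_, nrow = ncol(calls), ncol = nrow(calls),
                   dimnames = list(colnames(calls), rownames(calls)))
  for (j in seq_len(nrow(calls))) {
    dosage[, j] <- unname(legend[[j]][calls[j, ]])
  }
  structure(list(dosage = dosage, legend = legend), class = "at_genotypes")
}

encode_legend <- function(states) {
  tab <- sort(table(states[!is.na(states)]), decreasing = TRUE)
  u <- names(tab)
  if (length(u) == 2) return(setNames(c(0, 1), u))
  # three states: look for one that is the IUPAC union of the other two;
  # u is frequency-ordered, so rest[1] is the more frequent resolved base
  for (i in seq_along(u)) {
    rest <- u[-i]
    if (all(rest %in% .BASES) &&
        identical(u[i], unname(.IUPAC2[paste0(min(rest), max(rest))]))) {
      leg <- setNames(rep(NA_real_, 3), u)
      leg[rest[1]] <- 0
      leg[rest[2]] <- 1
      leg[u[i]] <- 0.5
      return(leg)
    }
  }
  # no union structure: reference 0, next 1, third masked
  setNames(c(0, 1, NA_real_), u)
}

#' Jukes-Cantor (JC69) distance between two call-state vectors
#'
#' `d = -(3/4) * log(1 - (4/3) * p)` with `p` the mismatch proportion over
#' shared non-missing sites. Saturated pairs (`p >= 0.75`, outside the model
#' domain) are flagged with `Inf`.
#'
#' @param x,y Character vectors of call states (`NA` = missing).
#' @return The JC69 distance (0 for identical vectors, `Inf` at saturation).
#' @export
jc69_distance <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (!any(ok)) stop("no shared non-missing sites")
  p <- mean(x[ok] != y[ok])
  jc69_from_p(p)
}

jc69_from_p <- function(p) {
  out <- p
  out[] <- Inf
  ok <- !is.na(p) & p < 0.75
  out[ok] <- -0.75 * log(1 - 4 * p[ok] / 3)
  out[is.na(p)] <- NA_real_
  out
}

#' All-pairs JC69 distance matrix
#'
#' Mismatch proportions are computed with per-state indicator cross-products,
#' so the cost is a handful of dense matrix products rather than a loop over
#' accession pairs.
#'
#' @param calls Site-call matrix (sites x accessions).
#' @return A symmetric `dist`-convertible matrix of JC69 distances with
#'   `Inf` flagging saturated pairs.
#' @export
jc69_matrix <- function(calls) {
  states <- unique(calls[!is.na(calls)])
  n <- ncol(calls)
  match_counts <- matrix(0, n, n)
  for (s in states) {
    ind <- (!is.na(calls)) & calls == s
    storage.mode(ind) <- "double"
    match_counts <- match_counts + crossprod(ind)
  }
  notna <- !is.na(calls)
  storage.mode(notna) <- "double"
  shared <- crossprod(notna)
  if (any(shared == 0)) stop("accession pair with no shared non-missing sites")
  p <- 1 - match_counts / shared
  d <- jc69_from_p(p)
  diag(d) <- 0
  dimnames(d) <- list(colnames(calls), colnames(calls))
  d
}

#' Hierarchical clustering dendrogram of accessions
#'
#' Agglomerates a distance matrix (average linkage by default, the UPGMA
#' ultrametric; neighbor-joining selectable) and returns an [ape::phylo]
#' tree whose leaves are the accessions.
#'
#' @param d Symmetric distance matrix or `dist` object; all finite.
#' @param method `"average"` (UPGMA, default) or `"nj"` (neighbor joining).
#' @return An [ape::phylo] tree.
#' @export
build_dendrogram <- function(d, method = c("average", "nj")) {
  method <- match.arg(method)
  m <- as.matrix(d)
  if (any(!is.finite(m))) stop("non-finite distance")
  if (method == "nj") return(ape::nj(as.dist(m)))
  ape::as.phylo(hclust(as.dist(m), method = "average"))
}

impute_dosage <- function(dosage) {
  mu <- colMeans(dosage, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  idx <- which(is.na(dosage), arr.ind = TRUE)
  if (nrow(idx)) dosage[idx] <- mu[idx[, 2]]
  dosage
}

#' Estimate an admixture (Q) matrix by PCA-to-simplex projection
#'
#' A light-weight structure estimator in the spirit of PCA-based admixture
#' tools: mean-impute and column-center the dosage matrix, take the top
#' `k - 1` principal coordinates, pick `k` archetypal accessions (the most
#' extreme member of each k-means cluster in PC space), and map every
#' accession onto the `(k-1)`-simplex spanned by the archetypes by
#' least squares under the constraints `q >= 0`, `sum(q) = 1`.
#'
#' With `k = "auto"` the subpopulation number is chosen by the largest
#' eigengap among the first 10 eigenvalues. When the eigengap supporting the
#' chosen `k` is no larger than the average gap among the leading
#' eigenvalues, there is no detectable structure and a warning is issued.
#'
#' @param genotypes An `at_genotypes` object or a numeric dosage matrix
#'   (accessions x markers).
#' @param k Number of subpopulations (>= 2), or `"auto"`.
#' @param seed Seed for the k-means archetype search (local RNG; the caller's
#'   RNG state is untouched).
#' @return Matrix of class `at_q` (accessions x k), rows on the simplex;
#'   attributes `eigenvalues` (first 10) and `k`.
#' @export
estimate_q <- function(genotypes, k = 2, seed = 1) {
  G <- if (inherits(genotypes, "at_genotypes")) genotypes$dosage else genotypes
  if (ncol(G) < nrow(G) / 10) {
    stop("too few markers to estimate structure (need >= accessions/10)")
  }
  X <- scale(impute_dosage(G), center = TRUE, scale = FALSE)
  sv <- svd(X, nu = 10, nv = 0)
  ev <- (sv$d^2)[seq_len(min(10, length(sv$d)))]
  gaps <- -diff(ev)
  if (identical(k, "auto")) {
    k <- which.max(gaps) + 1L
  }
  if (!is.numeric(k) || k < 2) stop("k must be >= 2 (or \"auto\")")
  k <- as.integer(k)
  # for genuine k-subpopulation structure the (k-1)-th eigenvalue stands
  # clear of the noise bulk; adjacent ratios near 1 mean no structure
  if (k - 1 < length(ev) && ev[k - 1] < 1.3 * ev[k]) {
    warning("weak eigengap at k = ", k,
            ": little detectable population structure")
  }
  scores <- sv$u[, seq_len(k - 1), drop = FALSE] %*%
    diag(sv$d[seq_len(k - 1)], k - 1)
  km <- with_seed(seed, kmeans(scores, centers = k, nstart = 10))
  # archetype = the most extreme member of each cluster (furthest from origin)
  arch_idx <- vapply(seq_len(k), function(cl) {
    members <- which(km$cluster == cl)
    members[which.max(rowSums(scores[members, , drop = FALSE]^2))]
  }, integer(1))
  A <- t(scores[arch_idx, , drop = FALSE])        # (k-1) x k
  Q <- t(apply(scores, 1, simplex_project, A = A))
  # order columns deterministically by archetype position
  ord <- order(A[1, ])
  Q <- Q[, ord, drop = FALSE]
  dimnames(Q) <- list(rownames(G), paste0("Q", seq_len(k)))
  structure(Q, eigenvalues = ev, k = k, class = c("at_q", "matrix", "array"))
}

# least squares q minimizing ||s - A q|| with q >= 0, sum(q) = 1,
# by enumeration of active sets (k is small)
simplex_project <- function(s, A) {
  k <- ncol(A)
  best <- NULL
  best_obj <- Inf
  for (sz in seq_len(k)) {
    for (S in combn_list(k, sz)) {
      As <- A[, S, drop = FALSE]
      # minimize ||s - As q||^2 s.t. sum(q) = 1 via KKT
      M <- crossprod(As)
      M <- M + diag(1e-10, nrow(M))
      one <- rep(1, length(S))
      Minv_b <- solve(M, crossprod(As, s))
      Minv_1 <- solve(M, one)
      lambda <- (sum(one * Minv_b) - 1) / sum(one * Minv_1)
      q <- Minv_b - lambda * Minv_1
      if (any(q < -1e-9)) next
      q <- pmax(q, 0); q <- q / sum(q)
      r <- s - As %*% q
      obj <- sum(r^2)
      if (obj < best_obj - 1e-12) {
        best_obj <- obj
        best <- setNames(numeric(k), seq_len(k))
        best[S] <- q
      }
    }
  }
  best
}

combn_list <- function(n, k) {
  m <- combn(n, k)
  lapply(seq_len(ncol(m)), function(i) m[, i])
}

#' Kinship matrix from genotype dosages
#'
#' Mean-imputes missing dosages, column-standardizes (zero-variance markers
#' are dropped with a warning), forms `K = G G' / m` over the `m` retained
#' markers, and rescales so the mean diagonal equals 1. The result is
#' symmetric and positive semidefinite by construction.
#'
#' @inheritParams estimate_q
#' @return Symmetric `at_kinship` matrix (accessions x accessions).
#' @export
kinship <- function(genotypes) {
  G <- if (inherits(genotypes, "at_genotypes")) genotypes$dosage else genotypes
  X <- impute_dosage(G)
  sds <- apply(X, 2, sd)
  zero <- sds < .Machine$double.eps^0.5
  if (any(zero)) {
    warning(sum(zero), " zero-variance marker(s) dropped from kinship")
    X <- X[, !zero, drop = FALSE]
    sds <- sds[!zero]
  }
  X <- scale(X, center = TRUE, scale = sds)
  K <- tcrossprod(X) / ncol(X)
  K <- K / mean(diag(K))
  dimnames(K) <- list(rownames(G), rownames(G))
  structure(K, class = c("at_kinship", "matrix", "array"))
}

#' Per-chromosome linkage disequilibrium scan
#'
#' Restricts markers to genome-assigned sites with MAF above the floor,
#' selects one SNP at random per CDS model (to damp the contribution of many
#' linked SNPs in the same gene), and computes all within-chromosome pairwise
#' r-squared values (squared Pearson correlation of dosages,
#' pairwise-complete). The genome mean is the mean over all retained
#' within-chromosome pairs.
#'
#' @param genotypes An `at_genotypes` object or dosage matrix with markers in
#'   columns named by site id.
#' @param annotations Marker annotation table ([call_snps()]).
#' @param maf_min Exclusive MAF floor (default 0.01).
#' @param seed Seed for the random SNP-per-model selection (local RNG).
#' @return A list of class `at_ld`: `pairs` (per-chromosome data.frames of
#'   site pairs and r2), `chromosome_means`, `genome_mean_r2`,
#'   `selected_sites`.
#' @export
ld_scan <- function(genotypes, annotations, maf_min = 0.01, seed = 1) {
  G <- if (inherits(genotypes, "at_genotypes")) genotypes$dosage else genotypes
  ann <- annotations[annotations$genome_assigned & annotations$maf > maf_min, ]
  ann <- ann[ann$site_id %in% colnames(G), ]
  picked <- with_seed(seed, {
    unlist(lapply(split(ann$site_id, ann$model_id), function(s) {
      if (length(s) == 1) s else sample(s, 1)
    }), use.names = FALSE)
  })
  ann <- ann[match(picked, ann$site_id), ]
  pairs <- list()
  means <- c()
  for (ch in levels(droplevels(factor(ann$chromosome, at_chromosomes())))) {
    ids <- ann$site_id[ann$chromosome == ch]
    if (length(ids) < 2) {
      warning("chromosome ", ch, " has < 2 retained sites; skipped")
      next
    }
    r <- cor(G[, ids, drop = FALSE], use = "pairwise.complete.obs")
    r2 <- r^2
    ut <- which(upper.tri(r2), arr.ind = TRUE)
    pairs[[ch]] <- data.frame(
      site_i = ids[ut[, 1]], site_j = ids[ut[, 2]],
      r2 = r2[ut], stringsAsFactors = FALSE
    )
    means[ch] <- mean(r2[ut], na.rm = TRUE)
  }
  all_r2 <- unlist(lapply(pairs, `[[`, "r2"), use.names = FALSE)
  structure(list(pairs = pairs,
                 chromosome_means = means,
                 genome_mean_r2 = mean(all_r2, na.rm = TRUE),
                 selected_sites = picked),
            class = "at_ld")
}

#' @export
print.at_ld <- function(x, ...) {
  cat("Linkage disequilibrium scan (one random SNP per CDS model)\n")
  cat(sprintf("  %d chromosomes, %d selected sites, genome mean r2 = %.4f\n",
              length(x$pairs), length(x$selected_sites), x$genome_mean_r2))
  invisible(x)
}
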