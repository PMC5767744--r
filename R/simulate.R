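# Synthetic allopolyploid diversity-panel generator. Emulates the
# statistical structure the platform assumes: an inbred (fully homozygous)
# panel with k-subpopulation admixture, Balding-Nichols allele-frequency
# drift, homoeologue cross-mapping that turns transcriptome SNPs into
# hemi-SNPs, log-normal expression with one expression-variant causal gene,
# and traits mixing major-effect loci, a polygenic tail and an
# expression-mediated component at a target heritability.

#' Simulate true panel genotypes with admixed population structure
#'
#' Sites get an ancestral allele frequency from Uniform(0.05, 0.95) and
#' per-subpopulation frequencies from the Balding-Nichols Beta drift model at
#' the given Fst. Each accession draws its admixture proportions, then one
#' allele per site from its admixture-weighted frequency; the panel is inbred
#' (doubled-haploid-like), so genotypes are homozygous 0/1 dosages.
#'
#' @param n_accessions Panel size (default 383).
#' @param models_per_genome CDS models per subgenome (default 190, spread
#'   over A1--A10 / C1--C9; A and C models are homoeologue-paired 1:1 by
#'   index).
#' @param sites_per_model Candidate SNP sites per model (default 4).
#' @param k Number of subpopulations (default 2).
#' @param fst Balding-Nichols drift (default 0.1). `fst = 0` gives an
#'   unstructured panel.
#' @param admix_shape Beta/Dirichlet shape of the admixture draw (default
#'   0.25: most accessions near-unadmixed, a minority mixed).
#' @param admixed If `FALSE`, accessions are assigned whole to alternating
#'   subpopulations (no admixture).
#' @param linkage_within Probability that a site shares its model's latent
#'   genealogy (default 0.85): sites within one CDS model are tightly
#'   linked, as in transcriptome data, which is why LD analysis picks one
#'   SNP per model. 0 gives fully independent sites.
#' @param seed Integer seed (local RNG).
#' @return A list of class `at_sim_genotypes`: `genotypes` (accessions x
#'   sites 0/1 matrix), `admixture` (accessions x k), `labels`
#'   (argmax subpopulation), `site_table` (site id, model, position, ref and
#'   alt base), `gene_order`, `subpop_freqs`.
#' @export
simulate_genotypes <- function(n_accessions = 383, models_per_genome = 190,
                               sites_per_model = 4, k = 2, fst = 0.1,
                               admix_shape = 0.25, admixed = TRUE,
                               linkage_within = 0.85, seed = 1) {
  stopifnot(n_accessions > 0, models_per_genome > 0, sites_per_model > 0,
            k >= 1, fst >= 0, fst < 1)
  with_seed(seed, {
    gene_order <- sim_gene_order(models_per_genome)
    site_table <- sim_sites(gene_order, sites_per_model)
    S <- nrow(site_table)
    p_anc <- runif(S, 0.05, 0.95)
    if (fst > 0) {
      a <- p_anc * (1 - fst) / fst
      b <- (1 - p_anc) * (1 - fst) / fst
      P <- vapply(seq_len(k), function(s) rbeta(S, a, b), numeric(S))
    } else {
      P <- matrix(p_anc, S, k)
    }
    if (admixed) {
      if (k == 2) {
        q1 <- rbeta(n_accessions, admix_shape, admix_shape)
        A <- cbind(q1, 1 - q1)
      } else {
        A <- matrix(stats::rgamma(n_accessions * k, shape = admix_shape),
                    n_accessions, k)
        A <- A / rowSums(A)
      }
    } else {
      lab <- rep_len(seq_len(k), n_accessions)
      A <- matrix(0, n_accessions, k)
      A[cbind(seq_len(n_accessions), lab)] <- 1
    }
    freq <- A %*% t(P)                       # accessions x sites
    # inbred allele draw through a latent uniform; sites of one model share
    # the model-level latent with probability linkage_within (within-model LD)
    mod_idx <- match(site_table$model_id, unique(site_table$model_id))
    Um <- matrix(runif(n_accessions * max(mod_idx)), n_accessions)
    U <- matrix(runif(n_accessions * S), n_accessions, S)
    shared <- matrix(runif(n_accessions * S) < linkage_within,
                     n_accessions, S)
    U[shared] <- Um[cbind(row(U)[shared], rep(mod_idx, each = n_accessions)[shared])]
    Z <- (U < freq) + 0L
    acc_ids <- sprintf("acc%03d", seq_len(n_accessions))
    dimnames(Z) <- list(acc_ids, site_table$site_id)
    rownames(A) <- acc_ids
    structure(list(
      genotypes = Z, admixture = A, labels = max.col(A),
      site_table = site_table, gene_order = gene_order,
      subpop_freqs = P, fst = fst, seed = seed
    ), class = "at_sim_genotypes")
  })
}

sim_gene_order <- function(models_per_genome) {
  chromA <- paste0("A", 1:10); chromC <- paste0("C", 1:9)
  per_chrom <- function(chroms, n) {
    base <- n %/% length(chroms)
    extra <- n %% length(chroms)
    rep(chroms, times = base + (seq_along(chroms) <= extra))
  }
  chrom <- c(per_chrom(chromA, models_per_genome),
             per_chrom(chromC, models_per_genome))
  chrom <- chrom[order(chrom_factor(chrom))]
  idx <- unlist(lapply(table(chrom_factor(chrom)), seq_len), use.names = FALSE)
  model_id <- sprintf("%sm%03d", chrom, idx)
  lenA <- pmax(300, pmin(6000, round(rlnorm(models_per_genome, log(1200), 0.35))))
  # homoeologues share length up to mild divergence; pair A and C by index
  isA <- startsWith(chrom, "A")
  cds_length <- integer(length(chrom))
  cds_length[isA] <- lenA
  cds_length[!isA] <- pmax(300, round(lenA[seq_len(sum(!isA))] *
                                        exp(rnorm(sum(!isA), 0, 0.05))))
  homoeologue <- rep(NA_character_, length(chrom))
  nA <- sum(isA); nC <- sum(!isA); npair <- min(nA, nC)
  homoeologue[which(isA)[seq_len(npair)]] <- model_id[which(!isA)[seq_len(npair)]]
  homoeologue[which(!isA)[seq_len(npair)]] <- model_id[which(isA)[seq_len(npair)]]
  validate_gene_order(data.frame(
    model_id = model_id, chromosome = chrom, order_index = idx,
    cds_length = cds_length, homoeologue = homoeologue,
    stringsAsFactors = FALSE
  ))
}

sim_sites <- function(gene_order, sites_per_model) {
  out <- do.call(rbind, lapply(seq_len(nrow(gene_order)), function(i) {
    n <- min(sites_per_model, gene_order$cds_length[i])
    pos <- sort(sample.int(gene_order$cds_length[i], n))
    data.frame(model_id = gene_order$model_id[i], position = pos,
               stringsAsFactors = FALSE)
  }))
  out$site_id <- paste(out$model_id, out$position, sep = ":")
  out$ref <- sample(.BASES, nrow(out), replace = TRUE)
  out$alt <- vapply(out$ref, function(r) sample(setdiff(.BASES, r), 1), "")
  rownames(out) <- NULL
  out
}

# split e errors uniformly over the 3 non-source bases (vectorized
# binomial chain: multinomial(e, 1/3, 1/3, 1/3))
split_errors <- function(e) {
  e1 <- rbinom(length(e), e, 1 / 3)
  e2 <- rbinom(length(e), e - e1, 1 / 2)
  cbind(e1, e2, e - e1 - e2)
}

#' Simulate per-accession pileups with homoeologue cross-mapping
#'
#' Per (accession, site): Poisson read depth; a `cross_mapping_rate` fraction
#' of reads carries the base of the homoeologous site (fixed per site, drawn
#' to differ from the reference base with probability `homoeo_div`); the
#' rest carry the accession's own allele; each read is corrupted to a
#' uniformly chosen other base with probability `error_rate`. Counts are
#' emitted post-quality, so they sum to the depth. At sites whose
#' homoeologue is fixed for another base, carriers see a two-base mixture --
#' the hemi-SNP mechanism; `cross_mapping_rate = 0` switches it off.
#'
#' @param sim An `at_sim_genotypes` object.
#' @param depth_mean Mean read depth (default 50).
#' @param error_rate Per-read error rate (default 0.005).
#' @param cross_mapping_rate Fraction of reads cross-mapped from the
#'   homoeologue, in `[0, 0.5]` (default 0.3).
#' @param homoeo_div Probability that the homoeologous site is fixed for a
#'   base different from the reference base (default 0.5).
#' @param discriminating_frac Fraction of models whose reads map uniquely to
#'   the correct homoeologue (cross-mapping rate 0 there; default 0.2).
#'   Polymorphisms in such models surface as simple SNPs, the rest mostly as
#'   hemi-SNPs.
#' @param discriminating_models Explicit model ids mapping discriminately;
#'   overrides `discriminating_frac` when non-`NULL`.
#' @param seed Integer seed (local RNG).
#' @return A pileup `data.frame` (see [read_pileup()]) with attribute
#'   `homoeo_base` (the per-site homoeologue base).
#' @export
simulate_pileups <- function(sim, depth_mean = 50, error_rate = 0.005,
                             cross_mapping_rate = 0.3, homoeo_div = 0.5,
                             discriminating_frac = 0.2,
                             discriminating_models = NULL, seed = 1) {
  stopifnot(cross_mapping_rate >= 0, cross_mapping_rate <= 0.5,
            error_rate >= 0, error_rate < 1, depth_mean > 0)
  with_seed(seed, {
    st <- sim$site_table
    Z <- sim$genotypes
    n <- nrow(Z); S <- ncol(Z)
    # fixed homoeologue base per site
    divergent <- runif(S) < homoeo_div
    homoeo <- st$ref
    homoeo[divergent] <- vapply(st$ref[divergent],
                                function(r) sample(setdiff(.BASES, r), 1), "")
    own_base <- matrix(ifelse(Z == 1, rep(st$alt, each = n),
                              rep(st$ref, each = n)), n, S)
    own_idx <- match(own_base, .BASES)
    hom_idx <- rep(match(homoeo, .BASES), each = n)
    # discriminately mapping models receive no cross-mapped reads
    models <- unique(st$model_id)
    discr <- if (is.null(discriminating_models)) {
      sample(models, round(discriminating_frac * length(models)))
    } else discriminating_models
    site_rate <- ifelse(st$model_id %in% discr, 0, cross_mapping_rate)
    depth <- matrix(rpois(n * S, depth_mean), n, S)
    cross <- matrix(rbinom(n * S, depth, rep(site_rate, each = n)), n, S)
    own_n <- depth - cross
    err_own <- rbinom(n * S, as.vector(own_n), error_rate)
    err_crs <- rbinom(n * S, as.vector(cross), error_rate)
    counts <- matrix(0L, n * S, 4)
    add_at <- function(counts, idx, val) {
      flat <- cbind(seq_len(n * S), idx)
      counts[flat] <- counts[flat] + val
      counts
    }
    counts <- add_at(counts, as.vector(own_idx), as.vector(own_n) - err_own)
    counts <- add_at(counts, hom_idx, as.vector(cross) - err_crs)
    # errors land uniformly on the three other bases
    others <- rbind(c(2, 3, 4), c(1, 3, 4), c(1, 2, 4), c(1, 2, 3))
    for (src in list(list(idx = as.vector(own_idx), e = err_own),
                     list(idx = hom_idx, e = err_crs))) {
      sp <- split_errors(src$e)
      for (jj in 1:3) {
        counts <- add_at(counts, others[src$idx, jj], sp[, jj])
      }
    }
    df <- data.frame(
      accession = rep(rownames(Z), times = S),
      model = rep(st$model_id, each = n),
      position = rep(st$position, each = n),
      depth = as.vector(depth),
      A = counts[, 1], C = counts[, 2], G = counts[, 3], T = counts[, 4],
      stringsAsFactors = FALSE
    )
    attr(df, "homoeo_base") <- setNames(homoeo, st$site_id)
    df
  })
}

#' Simulate an RPKM expression matrix with one expression-variant gene
#'
#' Background expression is log-normal: each model draws a baseline
#' log-abundance, each accession a value around it. A `silent_frac` of
#' models is near-silent (panel mean below the 0.4 RPKM floor). The causal
#' model's log-abundance is shifted by `causal_shift` in carriers of the
#' expression-variant allele, making its RPKM bimodal across the panel.
#'
#' @param gene_order Gene-order table naming the models.
#' @param n_accessions Number of accessions.
#' @param causal_model Model id of the expression-variant gene (or `NULL`).
#' @param causal_genotype 0/1 vector over accessions: carriers of the
#'   low/high-expression allele (required when `causal_model` is set).
#' @param meanlog,sdlog_between,sdlog_within Log-normal parameters: grand
#'   mean of baselines, between-model and within-model (accession) spread.
#' @param silent_frac Fraction of near-silent models (default 0.1).
#' @param causal_shift Log-scale expression shift in carriers (default -1.5,
#'   i.e. carriers express about 22% of the baseline).
#' @param admixture Optional accession x k admixture matrix; enables
#'   subpopulation-structured expression.
#' @param structured_frac Fraction of models whose baseline expression
#'   differs between subpopulations (default 0.3) -- differential expression
#'   between crop-type groups, the source of inflation that genomic control
#'   corrects in GEM scans.
#' @param structure_loading_sd Log-scale spread of the per-model
#'   subpopulation loading (default 0.4).
#' @param seed Integer seed (local RNG).
#' @return RPKM matrix (models x accessions) with attribute `expr_truth`.
#' @export
simulate_expression <- function(gene_order, n_accessions, causal_model = NULL,
                                causal_genotype = NULL, meanlog = log(5),
                                sdlog_between = 1, sdlog_within = 0.3,
                                silent_frac = 0.1, causal_shift = -1.5,
                                admixture = NULL, structured_frac = 0.3,
                                structure_loading_sd = 0.4, seed = 1) {
  with_seed(seed, {
    models <- gene_order$model_id
    M <- length(models)
    mu <- rnorm(M, meanlog, sdlog_between)
    silent <- sample(setdiff(seq_len(M), match(causal_model, models)),
                     floor(silent_frac * M))
    mu[silent] <- log(0.05)
    names(mu) <- models
    cell_mu <- matrix(mu, M, n_accessions)
    structured <- integer(0)
    if (!is.null(admixture) && structured_frac > 0) {
      structured <- sample(setdiff(seq_len(M),
                                   c(silent, match(causal_model, models))),
                           floor(structured_frac * M))
      loading <- rnorm(length(structured), 0, structure_loading_sd)
      q1 <- admixture[, 1] - mean(admixture[, 1])
      cell_mu[structured, ] <- cell_mu[structured, ] +
        outer(loading, q1)
    }
    if (!is.null(causal_model)) {
      stopifnot(causal_model %in% models,
                length(causal_genotype) == n_accessions)
      ci <- match(causal_model, models)
      cell_mu[ci, ] <- meanlog + causal_shift * causal_genotype
    }
    E <- matrix(rlnorm(M * n_accessions, cell_mu, sdlog_within),
                M, n_accessions)
    dimnames(E) <- list(models, sprintf("acc%03d", seq_len(n_accessions)))
    attr(E, "expr_truth") <- list(causal_model = causal_model,
                                  causal_shift = causal_shift,
                                  causal_genotype = causal_genotype,
                                  silent_models = models[silent],
                                  structured_models = models[structured])
    E
  })
}

#' Simulate a trait from genotypes and expression at a target heritability
#'
#' The genetic value is `sum_j effect_j * dosage_j + slope * causal RPKM`.
#' Residual noise is variance-matched on the realized genetic values:
#' `sigma_e^2 = var(g) * (1 - h2) / h2`, so the realized heritability equals
#' the target up to the sampling noise of the residual draw.
#'
#' @param genotypes 0/1 dosage matrix (accessions x sites) or an
#'   `at_sim_genotypes` object.
#' @param effects Named numeric vector of per-site effects (trait units per
#'   dosage); names are site ids.
#' @param h2 Target narrow-sense heritability in (0, 1).
#' @param expression Optional RPKM matrix (models x accessions).
#' @param causal_model,expression_slope Expression-mediated component: trait
#'   units per RPKM of `causal_model` (e.g. negative for a gene whose low
#'   expression raises the trait).
#' @param seed Integer seed (local RNG).
#' @return Named trait vector with attribute `trait_truth` (components and
#'   realized variance fractions).
#' @export
simulate_trait <- function(genotypes, effects, h2, expression = NULL,
                           causal_model = NULL, expression_slope = NULL,
                           seed = 1) {
  stopifnot(h2 > 0, h2 <= 1)
  Z <- if (inherits(genotypes, "at_sim_genotypes")) genotypes$genotypes
       else genotypes
  g <- rep(0, nrow(Z))
  if (length(effects)) {
    bad <- setdiff(names(effects), colnames(Z))
    if (length(bad)) stop("effect site(s) not in genotypes: ", bad[1])
    g <- drop(Z[, names(effects), drop = FALSE] %*% effects)
  }
  expr_comp <- 0
  if (!is.null(causal_model)) {
    stopifnot(!is.null(expression), !is.null(expression_slope))
    expr_comp <- expression_slope * expression[causal_model, rownames(Z)]
    g <- g + expr_comp
  }
  vg <- var(g)
  if (!is.finite(vg) || vg < .Machine$double.eps) {
    stop("degenerate genetic variance: no effective causal component")
  }
  noise <- if (h2 == 1) rep(0, length(g)) else
    with_seed(seed, rnorm(length(g), 0, sqrt(vg * (1 - h2) / h2)))
  y <- setNames(drop(g + noise), rownames(Z))
  vt <- var(y)
  attr(y, "trait_truth") <- list(
    effects = effects, causal_model = causal_model,
    expression_slope = expression_slope, h2_target = h2,
    h2_realized = vg / (vg + var(noise)),
    var_frac_expression = if (is.null(causal_model)) 0 else
      var(expr_comp) / vt,
    var_frac_sites = if (length(effects)) {
      vapply(names(effects), function(s)
        var(Z[, s] * effects[s]) / vt, numeric(1))
    } else numeric(0)
  )
  y
}

#' Simulate a complete diversity panel with ground truth
#'
#' One call generates everything the pipeline consumes -- gene order,
#' pileups, expression, trait, linkage evidence -- plus a `truth` record for
#' recovery tests. The default architecture: two major biallelic loci on
#' chromosomes A8 and C3 explaining 30% and 20% of trait variance, one
#' expression-variant gene on C2 with a negative expression slope (15%), a
#' polygenic tail bringing the total genetic fraction to the target
#' heritability of 0.794, k = 2 admixed subpopulations at Fst 0.1, and a
#' homoeologue cross-mapping rate of 0.3 producing hemi-SNPs.
#'
#' @inheritParams simulate_genotypes
#' @inheritParams simulate_pileups
#' @param h2 Target heritability (default 0.794).
#' @param major_fracs Trait-variance fractions of the two major loci
#'   (default `c(0.30, 0.20)`, placed on A8 and C3).
#' @param major_chroms Chromosomes hosting the major loci.
#' @param expression_frac Trait-variance fraction of the expression-mediated
#'   component (default 0.15).
#' @param expression_slope_sign Sign of the causal expression slope
#'   (default -1).
#' @param n_polygenic Number of small-effect background sites (default 150).
#' @param linkage_frac Fraction of sites with direct linkage-map evidence,
#'   allowing hemi-SNPs there to be genome-assigned (default 0.3).
#' @param seed Integer master seed; stage seeds are derived from it.
#' @return A list of class `at_panel`: `gene_order`, `pileup`, `expression`,
#'   `trait`, `linkage_evidence`, `truth` (class `panel_truth`).
#' @export
simulate_panel <- function(seed = 1, n_accessions = 383,
                           models_per_genome = 190, sites_per_model = 4,
                           k = 2, fst = 0.1, depth_mean = 50,
                           error_rate = 0.005, cross_mapping_rate = 0.3,
                           homoeo_div = 0.5, discriminating_frac = 0.2,
                           h2 = 0.794,
                           major_fracs = c(0.30, 0.20),
                           major_chroms = c("A8", "C3"),
                           expression_frac = 0.15,
                           expression_slope_sign = -1,
                           n_polygenic = 150, linkage_frac = 0.3) {
  sim <- simulate_genotypes(n_accessions, models_per_genome, sites_per_model,
                            k = k, fst = fst, seed = seed)
  Z <- sim$genotypes
  st <- sim$site_table
  go <- sim$gene_order
  # which models map discriminately is decided here so causal loci can be
  # placed among the markers that survive as genome-assignable simple SNPs
  # (the platform's causal peaks are made of genome-assigned markers)
  discr <- with_seed(seed + 500L,
                     sample(go$model_id,
                            round(discriminating_frac * nrow(go))))
  pile <- simulate_pileups(sim, depth_mean, error_rate, cross_mapping_rate,
                           homoeo_div, discriminating_models = discr,
                           seed = seed + 1000L)

  pick <- with_seed(seed + 2000L, {
    freq <- colMeans(Z)
    # major loci: common sites in discriminating models on the named
    # chromosomes (falling back to any common site there)
    majors <- vapply(major_chroms, function(ch) {
      mods <- go$model_id[go$chromosome == ch]
      cand <- st$site_id[st$model_id %in% intersect(mods, discr) &
                           freq >= 0.3 & freq <= 0.7]
      if (!length(cand)) {
        cand <- st$site_id[st$model_id %in% mods & freq >= 0.3 & freq <= 0.7]
      }
      if (!length(cand)) stop("no common site available on ", ch)
      sample(cand, 1)
    }, "")
    poly <- sample(setdiff(colnames(Z), majors),
                   min(n_polygenic, ncol(Z) - length(majors)))
    # expression-variant gene on C2. Its regulatory allele is the genotype
    # at a common site of a neighbouring C2 model: the causal gene itself
    # carries no associated SNP, but the variant is in LD with the scored
    # markers around it (the SNP peak flanking the expression candidate).
    c2 <- go$model_id[go$chromosome == "C2"]
    causal_model <- sample(c2[seq(2, length(c2) - 1)], 1)
    ci <- match(causal_model, c2)
    neigh <- c2[setdiff(seq(max(1, ci - 3), min(length(c2), ci + 3)), ci)]
    cand <- st$site_id[st$model_id %in% intersect(neigh, discr) &
                         freq >= 0.3 & freq <= 0.7]
    if (!length(cand)) {
      cand <- st$site_id[st$model_id %in% neigh & freq >= 0.3 & freq <= 0.7]
    }
    if (!length(cand)) {
      cand <- st$site_id[st$model_id %in% setdiff(c2, causal_model) &
                           freq >= 0.2 & freq <= 0.8]
    }
    latent_site <- sample(cand, 1)
    list(majors = majors, poly = poly, causal_model = causal_model,
         latent_site = latent_site, latent = unname(Z[, latent_site]))
  })
  expr <- simulate_expression(go, n_accessions,
                              causal_model = pick$causal_model,
                              causal_genotype = pick$latent,
                              admixture = sim$admixture,
                              seed = seed + 3000L)
  effects <- with_seed(seed + 4000L, {
    e_major <- sqrt(major_fracs) / apply(Z[, pick$majors, drop = FALSE], 2, sd)
    names(e_major) <- pick$majors
    u <- sample(c(-1, 1), length(pick$poly), replace = TRUE)
    sds <- apply(Z[, pick$poly, drop = FALSE], 2, sd)
    raw <- u / pmax(sds, 0.05)
    P <- drop(Z[, pick$poly, drop = FALSE] %*% raw)
    poly_frac <- max(h2 - sum(major_fracs) - expression_frac, 0)
    e_poly <- raw * sqrt(poly_frac / max(var(P), .Machine$double.eps))
    names(e_poly) <- pick$poly
    c(e_major, e_poly)
  })
  slope <- expression_slope_sign * sqrt(expression_frac) /
    sd(expr[pick$causal_model, ])
  trait <- simulate_trait(sim, effects, h2, expression = expr,
                          causal_model = pick$causal_model,
                          expression_slope = slope, seed = seed + 5000L)
  linkage <- with_seed(seed + 6000L,
                       sample(st$site_id, round(linkage_frac * nrow(st))))
  # variance fractions accessible to each marker type: SNPs can tag the
  # major loci and (through the latent site) the expression component;
  # GEM prediction sees the expression component only
  tt <- attr(trait, "trait_truth")
  comp_major <- drop(Z[, pick$majors, drop = FALSE] %*%
                       effects[pick$majors])
  comp_expr <- slope * expr[pick$causal_model, rownames(Z)]
  vt <- var(drop(trait))
  truth <- structure(list(
    seed = seed,
    admixture = sim$admixture, labels = sim$labels,
    subpop_freqs = sim$subpop_freqs,
    genotypes = Z, site_table = st,
    causal_sites = pick$majors,
    causal_effects = effects[pick$majors],
    major_fracs = setNames(major_fracs, major_chroms),
    polygenic_sites = pick$poly,
    causal_model = pick$causal_model,
    expression_slope = slope,
    expression_frac = expression_frac,
    latent_expression_allele = pick$latent,
    latent_site = pick$latent_site,
    snp_predictable_frac = var(comp_major + comp_expr) / vt,
    gem_predictable_frac = var(comp_expr) / vt,
    h2_target = h2,
    trait_truth = tt,
    cross_mapping_rate = cross_mapping_rate
  ), class = "panel_truth")
  structure(list(
    gene_order = go, pileup = pile, expression = expr,
    trait = trait, linkage_evidence = linkage, truth = truth
  ), class = "at_panel")
}

#' @export
print.at_panel <- function(x, ...) {
  cat("Synthetic allopolyploid diversity panel\n")
  cat(sprintf("  %d accessions, %d gene models, %d candidate sites\n",
              nrow(x$truth$admixture), nrow(x$gene_order),
              nrow(x$truth$site_table)))
  cat(sprintf("  causal loci: %s; causal expression model: %s (slope %.3f)\n",
              paste(x$truth$causal_sites, collapse = ", "),
              x$truth$causal_model, x$truth$expression_slope))
  cat(sprintf("  target h2 = %.3f (realized %.3f), cross-mapping rate %.2f\n",
              x$truth$h2_target, x$truth$trait_truth$h2_realized,
              x$truth$cross_mapping_rate))
  invisible(x)
}
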