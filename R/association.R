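# The Associative Transcriptomics core: REML null mixed model (Q + K),
# generalized-least-squares SNP association reusing the null variance
# components across markers (P3D/EMMAX style), fixed-effect GEM regression,
# genomic control, and significance thresholds.

## ---- accession alignment --------------------------------------------------

align_accessions <- function(trait, ...) {
  others <- list(...)
  ids <- names(trait)[!is.na(trait)]
  if (is.null(ids)) stop("trait vector must be named by accession id")
  for (obj in others) {
    if (is.null(obj)) next
    nm <- if (is.matrix(obj)) rownames(obj) else names(obj)
    ids <- ids[ids %in% nm]
  }
  if (length(ids) < 3) stop("fewer than 3 accessions shared across inputs")
  ids
}

design_matrix <- function(n, Q = NULL, ids = NULL) {
  X <- matrix(1, n, 1, dimnames = list(ids, "(Intercept)"))
  if (!is.null(Q)) {
    Qm <- as.matrix(Q)
    if (!is.null(ids)) Qm <- Qm[ids, , drop = FALSE]
    # drop one admixture column: rows sum to 1, collinear with the intercept
    X <- cbind(X, Qm[, -1, drop = FALSE])
  }
  X
}

## ---- REML null model ------------------------------------------------------

# restricted log-likelihood profiled over delta = sigma_e2 / sigma_g2,
# in the eigenbasis of K
reml_ll <- function(log10_delta, d, ystar, Xstar, logdet_XtX) {
  delta <- 10^log10_delta
  n <- length(ystar); p <- ncol(Xstar)
  w <- 1 / (d + delta)
  sw <- sqrt(w)
  fit <- lm.fit(Xstar * sw, ystar * sw)
  rss <- sum(fit$residuals^2)
  sigma_g2 <- rss / (n - p)
  -0.5 * ((n - p) * log(2 * pi * sigma_g2) + (n - p) +
            sum(log(d + delta)) +
            determinant(crossprod(Xstar * sw), logarithm = TRUE)$modulus) +
    0.5 * logdet_XtX
}

#' Fit the null mixed linear model and estimate variance components
#'
#' Fits `y = X beta + u + e` with `u ~ N(0, sigma_g2 K)` and
#' `e ~ N(0, sigma_e2 I)` by REML, where `X` holds the intercept and the
#' admixture covariates (Q matrix, one column dropped). The kinship matrix is
#' spectrally decomposed once and the restricted likelihood is profiled over
#' `delta = sigma_e2 / sigma_g2` on a log10 grid over `[1e-5, 1e5]` refined
#' by golden-section search. The decomposition and `delta` are cached in the
#' returned object so per-marker association can reuse them
#' ("population parameters previously determined").
#'
#' The pseudo-heritability `h2 = sigma_g2 / (sigma_g2 + sigma_e2)` is the
#' SNP-based narrow-sense heritability estimate.
#'
#' @param trait Named numeric vector (accession ids; `NA` dropped).
#' @param K Kinship matrix ([kinship()]), or `NULL` for an identity
#'   relatedness structure (the model then degenerates to OLS).
#' @param Q Admixture matrix ([estimate_q()]) or `NULL`.
#' @return An object of class `at_mlm` with elements `sigma_g2`, `sigma_e2`,
#'   `h2`, `delta`, `beta`, `logLik`, `accessions`, plus the cached rotation.
#' @export
fit_null_mlm <- function(trait, K = NULL, Q = NULL) {
  ids <- align_accessions(trait, K, Q)
  y <- trait[ids]
  if (sd(y) < .Machine$double.eps^0.5) stop("trait is constant")
  n <- length(y)
  X <- design_matrix(n, Q, ids)
  if (is.null(K)) {
    eig <- list(values = rep(1, n), vectors = diag(n))
  } else {
    Km <- unclass(K)[ids, ids]
    eig <- eigen(Km, symmetric = TRUE)
    if (min(eig$values) < -1e-8 * max(abs(eig$values))) {
      stop("K is not positive semidefinite")
    }
    eig$values <- pmax(eig$values, 0)
  }
  U <- eig$vectors; d <- eig$values
  ystar <- drop(crossprod(U, y))
  Xstar <- crossprod(U, X)
  logdet_XtX <- determinant(crossprod(X), logarithm = TRUE)$modulus
  grid <- seq(-5, 5, by = 0.1)
  ll <- vapply(grid, reml_ll, numeric(1), d = d, ystar = ystar,
               Xstar = Xstar, logdet_XtX = logdet_XtX)
  i <- which.max(ll)
  if (i == 1L || i == length(grid)) {
    warning("REML optimum at the delta grid boundary (delta = 10^",
            grid[i], ")")
    opt <- list(maximum = grid[i], objective = ll[i])
  } else {
    opt <- optimize(reml_ll, lower = grid[i - 1], upper = grid[i + 1],
                    maximum = TRUE, tol = 1e-8, d = d, ystar = ystar,
                    Xstar = Xstar, logdet_XtX = logdet_XtX)
  }
  delta <- 10^opt$maximum
  w <- 1 / (d + delta)
  sw <- sqrt(w)
  fit <- lm.fit(Xstar * sw, ystar * sw)
  p <- ncol(X)
  sigma_g2 <- sum(fit$residuals^2) / (n - p)
  sigma_e2 <- delta * sigma_g2
  beta <- setNames(fit$coefficients, colnames(X))
  structure(list(
    sigma_g2 = sigma_g2, sigma_e2 = sigma_e2,
    h2 = sigma_g2 / (sigma_g2 + sigma_e2),
    delta = delta, beta = beta,
    logLik = unname(opt$objective),
    accessions = ids, y = y, X = X,
    U = U, d = d, identity_K = is.null(K),
    K = if (is.null(K)) NULL else unclass(K)[ids, ids]
  ), class = "at_mlm")
}

#' @export
print.at_mlm <- function(x, digits = 4, ...) {
  cat("Null mixed linear model (REML)\n")
  cat(sprintf("  n = %d accessions, %d fixed effect(s)\n",
              length(x$y), ncol(x$X)))
  cat(sprintf("  sigma_g2 = %.*g  sigma_e2 = %.*g  h2 = %.3f\n",
              digits, x$sigma_g2, digits, x$sigma_e2, x$h2))
  invisible(x)
}

#' @export
summary.at_mlm <- function(object, ...) {
  out <- list(
    n = length(object$y),
    beta = object$beta,
    sigma_g2 = object$sigma_g2,
    sigma_e2 = object$sigma_e2,
    h2 = object$h2,
    delta = object$delta,
    logLik = object$logLik
  )
  class(out) <- "summary.at_mlm"
  out
}

#' @export
print.summary.at_mlm <- function(x, ...) {
  cat("Variance components (REML)\n")
  cat(sprintf("  genetic  sigma_g2 = %.6g\n", x$sigma_g2))
  cat(sprintf("  residual sigma_e2 = %.6g\n", x$sigma_e2))
  cat(sprintf("  pseudo-heritability h2 = %.4f\n", x$h2))
  cat("Fixed effects:\n")
  print(x$beta)
  invisible(x)
}

#' @export
coef.at_mlm <- function(object, ...) object$beta

#' @export
residuals.at_mlm <- function(object, ...) {
  drop(object$y - object$X %*% object$beta)
}

## ---- p-value helpers (log scale, underflow-safe) --------------------------

t_logp <- function(t, df) {
  log(2) + pt(-abs(t), df, log.p = TRUE)
}

logp_to_mlog10 <- function(logp) -logp / log(10)

chisq_from_logp <- function(logp) {
  qchisq(logp, df = 1, lower.tail = FALSE, log.p = TRUE)
}

gc_log <- function(logp) {
  chi <- chisq_from_logp(logp)
  lambda <- median(chi, na.rm = TRUE) / qchisq(0.5, df = 1)
  adj <- logp
  if (!is.na(lambda) && lambda > 1) {
    adj <- pchisq(chi / lambda, df = 1, lower.tail = FALSE, log.p = TRUE)
  }
  list(lambda = lambda, logp = adj)
}

#' Genomic control of a p-value vector
#'
#' The genomic inflation factor is the median of the implied 1-df chi-squared
#' statistics divided by the null median `qchisq(0.5, 1)` (about 0.4549).
#' When `lambda > 1` every chi-squared is deflated by `lambda` and p-values
#' are recomputed; a deflated scan (`lambda <= 1`) is left unchanged.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @return A list with `lambda` and `p_adjusted`.
#' @export
genomic_control <- function(p_values) {
  if (!length(p_values)) stop("empty p-value vector")
  if (any(p_values <= 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in (0, 1]")
  }
  res <- gc_log(log(p_values))
  list(lambda = res$lambda,
       p_adjusted = if (!is.na(res$lambda) && res$lambda > 1)
         exp(res$logp) else p_values)
}

#' Bonferroni significance line
#'
#' @param alpha Family-wise error rate (default 0.05).
#' @param m_tests Number of markers actually tested (post-filter).
#' @return The threshold on the `-log10 P` scale: `-log10(alpha / m)`.
#' @examples
#' bonferroni_threshold(0.05, 256397)  # ~6.71, plotted as 6.7
#' bonferroni_threshold(0.05, 53889)   # ~6.03
#' @export
bonferroni_threshold <- function(alpha = 0.05, m_tests) {
  stopifnot(alpha > 0, alpha < 1, m_tests >= 1)
  -log10(alpha / m_tests)
}

#' Benjamini-Hochberg 5% FDR plotting line
#'
#' The largest `p(i) <= (i/m) q` under the Benjamini-Hochberg step-up rule;
#' the line is drawn at `-log10` of that p-value. If no p-value passes, the
#' line does not exist and `Inf` is returned as the flag.
#'
#' @param p_values Numeric vector of p-values.
#' @param q FDR level (default 0.05).
#' @return `-log10` threshold, or `Inf` when nothing passes.
#' @export
fdr_line <- function(p_values, q = 0.05) {
  if (!length(p_values)) stop("empty p-value vector")
  p <- sort(p_values[!is.na(p_values)])
  m <- length(p)
  pass <- which(p <= (seq_len(m) / m) * q)
  if (!length(pass)) return(Inf)
  -log10(p[max(pass)])
}

## ---- SNP association ------------------------------------------------------

# weighted residualization: returns projector pieces for FWL slopes
fwl_stats <- function(yw, Xw, Gw) {
  qr_X <- qr(Xw)
  ey <- qr.resid(qr_X, yw)
  EG <- qr.resid(qr_X, Gw)
  gss <- colSums(EG^2)
  gy <- drop(crossprod(EG, ey))
  beta <- ifelse(gss > .Machine$double.eps^0.5 * nrow(Gw), gy / gss, NA_real_)
  rss <- sum(ey^2) - beta^2 * gss
  df <- length(yw) - ncol(Xw) - 1
  se <- sqrt(pmax(rss, 0) / df / gss)
  tstat <- beta / se
  list(beta = beta, se = se, t = tstat, df = df,
       rss0 = sum(ey^2), gss = gss)
}

#' Mixed-linear-model SNP association scan
#'
#' Tests each marker with a generalized-least-squares effect estimate and a
#' Wald t-test under the variance structure of the null model (variance
#' components fixed across markers; GAPIT/EMMAX "P3D" behaviour). With
#' `K = NULL` and no Q the test reduces exactly to ordinary least squares.
#' Accessions with a missing call at a marker are dropped for that marker
#' only (the marker's test then runs on the observed subset of the
#' covariance, with Cholesky factors cached per missingness pattern).
#'
#' @param trait Named numeric trait vector.
#' @param genotypes `at_genotypes` object or dosage matrix
#'   (accessions x markers).
#' @param annotations Optional marker annotation table ([call_snps()]): used
#'   to apply the MAF floor and attach chromosome, order, class and the
#'   genome-assignability flag for dark/pale Manhattan rendering.
#' @param Q,K Structure covariates and kinship, as in [fit_null_mlm()].
#' @param null Optional prefitted `at_mlm` (cached rotation reused).
#' @param maf_min Exclusive MAF floor applied when `annotations` are given
#'   (default 0.01).
#' @param per_marker_reml Refit the variance components for every marker
#'   (slow; default `FALSE` uses the null-model components for all markers).
#' @param gc Apply genomic control to the scan (default `FALSE` for SNP
#'   scans; GEM scans apply it by default).
#' @return An `at_scan` data.frame sorted by (chromosome, order_index):
#'   columns `id`, `model_id`, `chromosome`, `order_index`, `minus_log10_p`,
#'   `p_value`, `effect_size`, `maf`, `snp_class`, `assigned`, `n_used`;
#'   attributes `lambda_gc`, `m_tested`, `type`.
#' @export
snp_association <- function(trait, genotypes, annotations = NULL, Q = NULL,
                            K = NULL, null = NULL, maf_min = 0.01,
                            per_marker_reml = FALSE, gc = FALSE) {
  G <- if (inherits(genotypes, "at_genotypes")) genotypes$dosage else genotypes
  if (is.null(null)) null <- fit_null_mlm(trait, K = K, Q = Q)
  ids <- null$accessions
  G <- G[ids, , drop = FALSE]
  if (!is.null(annotations)) {
    keep <- annotations$site_id[annotations$maf > maf_min]
    G <- G[, colnames(G) %in% keep, drop = FALSE]
  }
  m <- ncol(G)
  if (!m) stop("no markers to test after filtering")
  all_missing <- colSums(!is.na(G)) == 0
  if (any(all_missing)) {
    warning(sum(all_missing), " all-missing marker(s) skipped")
    G <- G[, !all_missing, drop = FALSE]
    m <- ncol(G)
  }
  n <- length(null$y)
  w <- 1 / (null$d + null$delta)
  sw <- sqrt(w)
  yw <- drop(crossprod(null$U, null$y)) * sw
  Xw <- crossprod(null$U, null$X) * sw

  beta <- se <- tstat <- rep(NA_real_, m)
  dfree <- rep(NA_real_, m)
  n_used <- colSums(!is.na(G))
  complete <- n_used == n

  if (per_marker_reml) {
    for (j in seq_len(m)) {
      st <- marker_reml_test(null, G[, j])
      beta[j] <- st$beta; se[j] <- st$se; tstat[j] <- st$t; dfree[j] <- st$df
    }
  } else {
    if (any(complete)) {
      Gw <- (crossprod(null$U, G[, complete, drop = FALSE])) * sw
      st <- fwl_stats(yw, Xw, Gw)
      beta[complete] <- st$beta; se[complete] <- st$se
      tstat[complete] <- st$t; dfree[complete] <- st$df
    }
    if (any(!complete)) {
      V <- if (null$identity_K) {
        diag(null$sigma_g2 + null$sigma_e2, n)
      } else {
        null$sigma_g2 * null$K + diag(null$sigma_e2, n)
      }
      chol_cache <- new.env(parent = emptyenv())
      for (j in which(!complete)) {
        obs <- which(!is.na(G[, j]))
        key <- paste(obs, collapse = ",")
        L <- get0(key, envir = chol_cache)
        if (is.null(L)) {
          L <- chol(V[obs, obs])
          assign(key, L, envir = chol_cache)
        }
        ys <- backsolve(L, null$y[obs], transpose = TRUE)
        Xs <- backsolve(L, null$X[obs, , drop = FALSE], transpose = TRUE)
        gs <- backsolve(L, G[obs, j], transpose = TRUE)
        st <- fwl_stats(ys, Xs, cbind(gs))
        beta[j] <- st$beta; se[j] <- st$se; tstat[j] <- st$t; dfree[j] <- st$df
      }
    }
  }
  logp <- t_logp(tstat, dfree)
  lambda <- NA_real_
  if (gc) {
    res <- gc_log(logp)
    lambda <- res$lambda
    logp <- res$logp
  }
  build_scan(
    id = colnames(G), logp = logp, effect = beta, n_used = n_used,
    annotations = annotations, type = "snp", lambda = lambda,
    m_tested = m, extra = NULL
  )
}

# exact per-marker REML (complete-data path uses the cached eigenbasis; rows
# with a missing call drop to a subset eigendecomposition)
marker_reml_test <- function(null, g) {
  obs <- which(!is.na(g))
  if (length(obs) == length(g) || null$identity_K) {
    if (length(obs) == length(g)) {
      U <- null$U; d <- null$d
      y <- null$y; X <- cbind(null$X, marker = g)
    } else {
      y <- null$y[obs]; X <- cbind(null$X[obs, , drop = FALSE], marker = g[obs])
      U <- diag(length(obs)); d <- rep(1, length(obs))
    }
  } else {
    eig <- eigen(null$K[obs, obs], symmetric = TRUE)
    U <- eig$vectors; d <- pmax(eig$values, 0)
    y <- null$y[obs]; X <- cbind(null$X[obs, , drop = FALSE], marker = g[obs])
  }
  ystar <- drop(crossprod(U, y)); Xstar <- crossprod(U, X)
  ldet <- determinant(crossprod(X), logarithm = TRUE)$modulus
  opt <- optimize(reml_ll, c(-5, 5), maximum = TRUE, tol = 1e-6,
                  d = d, ystar = ystar, Xstar = Xstar, logdet_XtX = ldet)
  w <- 1 / (d + 10^opt$maximum)
  sw <- sqrt(w)
  st <- fwl_stats(ystar * sw, Xstar[, -ncol(X), drop = FALSE] * sw,
                  cbind(Xstar[, ncol(X)] * sw))
  list(beta = st$beta, se = st$se, t = st$t, df = st$df)
}

build_scan <- function(id, logp, effect, n_used, annotations, type,
                       lambda, m_tested, extra = NULL, p_raw = NULL) {
  df <- data.frame(
    id = id,
    model_id = sub(":[0-9]+$", "", id),
    minus_log10_p = logp_to_mlog10(logp),
    p_value = if (is.null(p_raw)) exp(logp) else p_raw,
    effect_size = effect,
    n_used = n_used,
    stringsAsFactors = FALSE
  )
  if (!is.null(extra)) df <- cbind(df, extra)
  if (!is.null(annotations)) {
    hit <- match(df$id, annotations$site_id)
    df$chromosome <- annotations$chromosome[hit]
    df$order_index <- annotations$order_index[hit]
    df$maf <- annotations$maf[hit]
    df$snp_class <- annotations$snp_class[hit]
    df$assigned <- annotations$genome_assigned[hit]
  } else if (!all(c("chromosome", "order_index") %in% names(df))) {
    df$chromosome <- factor(NA, levels = at_chromosomes())
    df$order_index <- NA_integer_
    df$maf <- NA_real_
    df$snp_class <- NA_character_
    df$assigned <- NA
  }
  df <- df[order(df$chromosome, df$order_index, df$id), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, lambda_gc = lambda, m_tested = m_tested, type = type,
            class = c("at_scan", "data.frame"))
}

## ---- GEM association ------------------------------------------------------

#' Gene-expression-marker (GEM) association scan
#'
#' For every CDS model passing the expression floor, fits the fixed-effect
#' linear model `trait ~ RPKM + Q` by ordinary least squares and reports the
#' marginal RPKM coefficient (slope, in trait units per RPKM), an intercept
#' for the marginal prediction line (`mean(trait) - slope * mean(RPKM)`), the
#' model R-squared and the RPKM-coefficient p-value. Genomic control is then
#' applied to the p-value vector (adjustment only when `lambda > 1`).
#'
#' @param trait Named numeric trait vector.
#' @param rpkm RPKM matrix (models x accessions).
#' @param Q Optional admixture covariates.
#' @param gene_order Optional gene-order table used to place models on the
#'   Manhattan axis.
#' @param min_mean Expression floor passed to [expression_filter()].
#' @param gc Apply genomic control (default `TRUE`).
#' @return An `at_scan` data.frame (`type = "gem"`) with extra columns
#'   `slope`, `intercept`, `r2` and `p_raw` (pre-adjustment p-value);
#'   `p_value` and `minus_log10_p` are post-adjustment. Attribute
#'   `lambda_gc` is the observed inflation factor.
#' @export
gem_association <- function(trait, rpkm, Q = NULL, gene_order = NULL,
                            min_mean = 0.4, gc = TRUE) {
  keep <- expression_filter(rpkm, min_mean)
  E <- t(rpkm[keep, , drop = FALSE])    # accessions x models
  ids <- align_accessions(trait, E, Q)
  y <- trait[ids]
  E <- E[ids, , drop = FALSE]
  n <- length(y)
  X <- design_matrix(n, Q, ids)
  st <- fwl_stats(y, X, E)
  ok <- !is.na(st$beta)
  if (any(!ok)) {
    warning(sum(!ok), " zero-variance GEM(s) skipped")
  }
  slope <- st$beta[ok]
  tss <- sum((y - mean(y))^2)
  rss <- st$rss0 - slope^2 * st$gss[ok]
  r2 <- pmin(pmax(1 - rss / tss, 0), 1)
  logp <- t_logp(st$t[ok], st$df)
  p_raw <- exp(logp)
  lambda <- NA_real_
  if (gc) {
    res <- gc_log(logp)
    lambda <- res$lambda
    logp <- res$logp
  }
  models <- colnames(E)[ok]
  extra <- data.frame(
    slope = slope,
    intercept = mean(y) - slope * colMeans(E[, ok, drop = FALSE]),
    r2 = r2,
    p_raw = p_raw
  )
  ann <- NULL
  scan <- build_scan(id = models, logp = logp, effect = slope,
                     n_used = n, annotations = NULL, type = "gem",
                     lambda = lambda, m_tested = length(models),
                     extra = extra)
  if (!is.null(gene_order)) {
    hit <- match(scan$model_id, gene_order$model_id)
    if (any(is.na(hit))) stop("GEM model(s) absent from gene order")
    scan$chromosome <- gene_order$chromosome[hit]
    scan$order_index <- gene_order$order_index[hit]
    scan$assigned <- TRUE
    o <- order(scan$chromosome, scan$order_index)
    attrs <- attributes(scan)
    scan <- scan[o, , drop = FALSE]
    rownames(scan) <- NULL
    attr(scan, "lambda_gc") <- attrs$lambda_gc
    attr(scan, "m_tested") <- attrs$m_tested
    attr(scan, "type") <- attrs$type
    class(scan) <- c("at_scan", "data.frame")
  }
  scan
}

## ---- Manhattan table ------------------------------------------------------

#' Ordered Manhattan plot table with homoeologous shadows
#'
#' Positions every marker on the genome-order x-axis (chromosomes A1..A10
#' then C1..C9, models by order index). Genome-assigned markers are dark
#' points at the position of their host CDS model. Markers that cannot be
#' assigned (unmapped hemi-SNPs) are pale and are drawn at BOTH homoeologous
#' gene-model positions when the host model has a homoeologue -- the
#' polymorphism may reside in either copy, and the duplicate pale peak is the
#' homoeologous "shadow" of the true one.
#'
#' @param scan An `at_scan` object.
#' @param gene_order Gene-order table; its optional `homoeologue` column
#'   defines the A/C pairing used for shadows.
#' @return A data.frame sorted by (chromosome, order_index): `id`, `x_rank`
#'   (global gene-order rank), `chromosome`, `order_index`, `minus_log10_p`,
#'   `dark`.
#' @export
manhattan_table <- function(scan, gene_order) {
  go <- gene_order[order(gene_order$chromosome, gene_order$order_index), ]
  go$x_rank <- seq_len(nrow(go))
  hit <- match(scan$model_id, go$model_id)
  if (any(is.na(hit))) {
    stop("marker model(s) absent from gene order: ",
         paste(head(unique(scan$model_id[is.na(hit)]), 3), collapse = ", "))
  }
  assigned <- scan$assigned
  assigned[is.na(assigned)] <- FALSE
  base <- data.frame(
    id = scan$id,
    x_rank = go$x_rank[hit],
    chromosome = go$chromosome[hit],
    order_index = go$order_index[hit],
    minus_log10_p = scan$minus_log10_p,
    dark = assigned,
    stringsAsFactors = FALSE
  )
  shadow_src <- which(!assigned & !is.na(go$homoeologue[hit]))
  if (length(shadow_src)) {
    par_hit <- match(go$homoeologue[hit[shadow_src]], go$model_id)
    okp <- !is.na(par_hit)
    if (any(okp)) {
      shadows <- data.frame(
        id = scan$id[shadow_src[okp]],
        x_rank = go$x_rank[par_hit[okp]],
        chromosome = go$chromosome[par_hit[okp]],
        order_index = go$order_index[par_hit[okp]],
        minus_log10_p = scan$minus_log10_p[shadow_src[okp]],
        dark = FALSE,
        stringsAsFactors = FALSE
      )
      base <- rbind(base, shadows)
    }
  }
  base <- base[order(base$x_rank, base$id), , drop = FALSE]
  rownames(base) <- NULL
  base
}

## ---- at_scan methods ------------------------------------------------------

#' @export
print.at_scan <- function(x, n = 6, ...) {
  type <- attr(x, "type") %||% "snp"
  m <- attr(x, "m_tested") %||% nrow(x)
  cat(sprintf("Association scan (%s): %d markers tested\n",
              toupper(type), m))
  lambda <- attr(x, "lambda_gc")
  if (!is.null(lambda) && !is.na(lambda)) {
    cat(sprintf("  genomic inflation lambda = %.3f%s\n", lambda,
                if (lambda > 1) " (p-values adjusted)" else " (no adjustment)"))
  }
  cat(sprintf("  Bonferroni -log10 P line (alpha = 0.05): %.2f\n",
              bonferroni_threshold(0.05, m)))
  top <- x[order(-x$minus_log10_p), , drop = FALSE]
  cat("Top markers:\n")
  print.data.frame(head(as.data.frame(top), n), digits = 4)
  invisible(x)
}

#' @export
summary.at_scan <- function(object, alpha = 0.05, ...) {
  m <- attr(object, "m_tested") %||% nrow(object)
  bonf <- bonferroni_threshold(alpha, m)
  fdr <- fdr_line(object$p_value)
  hits <- object[object$minus_log10_p > bonf, , drop = FALSE]
  out <- list(type = attr(object, "type"), m_tested = m,
              lambda_gc = attr(object, "lambda_gc"),
              bonferroni = bonf, fdr_line = fdr,
              n_above_bonferroni = nrow(hits),
              top = hits[order(-hits$minus_log10_p), ])
  class(out) <- "summary.at_scan"
  out
}

#' @export
print.summary.at_scan <- function(x, ...) {
  cat(sprintf("%s scan: %d markers, %d above the Bonferroni line (%.2f)\n",
              toupper(x$type), x$m_tested, x$n_above_bonferroni,
              x$bonferroni))
  cat(sprintf("  5%% FDR line: %s\n",
              if (is.finite(x$fdr_line)) sprintf("%.2f", x$fdr_line)
              else "none (no marker passes)"))
  if (!is.null(x$lambda_gc) && !is.na(x$lambda_gc)) {
    cat(sprintf("  lambda_gc = %.3f\n", x$lambda_gc))
  }
  invisible(x)
}

#' Manhattan plot of an association scan
#'
#' Dark points are genome-assigned markers, pale points unassigned ones
#' (including homoeologous shadows). Horizontal lines mark the Bonferroni
#' threshold (light blue) and, when it exists, the 5% FDR line (dark blue,
#' broken).
#'
#' @param x An `at_scan` object.
#' @param gene_order Gene-order table for the x-axis.
#' @param alpha Family-wise level for the Bonferroni line.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.at_scan <- function(x, gene_order, alpha = 0.05, ...) {
  tab <- manhattan_table(x, gene_order)
  chrom_cols <- setNames(rep(c("black", "red3"), length.out = 19),
                         at_chromosomes())
  col <- chrom_cols[as.character(tab$chromosome)]
  pale <- grepl("red", col)
  col <- ifelse(tab$dark, col, ifelse(pale, "#FF9999", "grey70"))
  plot(tab$x_rank, tab$minus_log10_p, pch = 20, cex = 0.5, col = col,
       xlab = "gene models in genomic order",
       ylab = expression(-log[10] ~ italic(P)), ...)
  abline(h = bonferroni_threshold(alpha, attr(x, "m_tested")),
         col = "lightblue3", lty = 2)
  fdr <- fdr_line(x$p_value)
  if (is.finite(fdr)) abline(h = fdr, col = "darkblue", lty = 3)
  invisible(tab)
}
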