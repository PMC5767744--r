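# Take-one-out validation of top markers: each accession is removed in turn,
# the association scan is rerun on the remainder, markers above the
# Bonferroni line are selected, and the left-out trait is predicted from
# allelic effects (SNPs) or from the regression line (GEMs). The regression
# of predicted on observed values summarizes predictive power.

#' Allelic effects of a marker
#'
#' The mean trait value of the training accessions carrying each call state.
#' States unseen in training fall back to the overall training mean.
#'
#' @param states Character vector of call states for the training accessions.
#' @param trait Numeric trait values aligned to `states`.
#' @return Named numeric vector of per-state means with attribute
#'   `"fallback"` (the overall training mean).
#' @export
allelic_effects <- function(states, trait) {
  ok <- !is.na(states) & !is.na(trait)
  if (!any(ok)) stop("empty training set")
  if (length(unique(states[ok])) < 2) {
    stop("marker needs >= 2 states in the training set")
  }
  eff <- tapply(trait[ok], states[ok], mean)
  structure(as.vector(eff), names = names(eff), fallback = mean(trait[ok]))
}

predict_from_allelic_effects <- function(effects, state) {
  if (is.na(state) || !(state %in% names(effects))) {
    attr(effects, "fallback")
  } else {
    unname(effects[state])
  }
}

loo_report <- function(obs, pred, n_markers, fallback, mode, type) {
  # Predictive power is judged on rounds where markers were actually
  # selected. A fallback prediction is the round's training mean, which is
  # mechanically anti-correlated with the held-out value ((S - y_i)/(n-1)),
  # so including such rounds would manufacture spurious R2 on null traits.
  use <- !fallback
  if (sum(use) >= 3 && sd(pred[use]) > 0) {
    sm <- summary(lm(pred[use] ~ obs[use]))
    r2 <- sm$r.squared
    pval <- if (is.null(sm$fstatistic)) NA_real_ else
      unname(pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
                lower.tail = FALSE))
  } else {
    r2 <- 0
    pval <- NA_real_
  }
  structure(list(
    report = data.frame(accession_id = names(obs), observed = unname(obs),
                        predicted = unname(pred), n_markers = n_markers,
                        fallback = fallback, stringsAsFactors = FALSE),
    r2 = r2,
    p_value = pval,
    mode = mode, type = type,
    fallback_fraction = mean(fallback)
  ), class = "at_loo")
}

#' Take-one-out validation of SNP markers
#'
#' For each phenotyped accession in turn: drop it, rerun the mixed-model SNP
#' association on the remainder, select the markers above the Bonferroni
#' line of that round, and predict the left-out trait as the unweighted mean
#' over selected markers of each marker's allelic-effect value for the
#' left-out genotype. Rounds in which no marker passes fall back to the
#' training mean and are flagged. Kinship and structure covariates are
#' genotype-only panel quantities estimated once and subset per round; the
#' left-out accession's trait value never enters fitting or selection.
#'
#' @param trait Named numeric trait vector (>= 30 phenotyped accessions).
#' @param markers An `at_markers` object ([call_snps()]), or a list with
#'   `calls` and `annotations`.
#' @param Q,K Structure covariates and kinship for the association model.
#' @param alpha Bonferroni family-wise level (default 0.05).
#' @param maf_min Exclusive MAF floor (default 0.01).
#' @param mode `"full"` (default): reselect markers in every round.
#'   `"fast"`: fix the selection from the full-panel scan and only refit
#'   allelic effects per round.
#' @return An `at_loo` object: per-accession observed/predicted table,
#'   overall `r2` (OLS of predicted on observed, over the rounds in which at
#'   least one marker was selected; 0 when no round selects any) and its
#'   p-value.
#' @export
take_one_out_snp <- function(trait, markers, Q = NULL, K = NULL,
                             alpha = 0.05, maf_min = 0.01,
                             mode = c("full", "fast")) {
  mode <- match.arg(mode)
  calls <- markers$calls
  ann <- markers$annotations
  enc <- encode_genotypes(calls)
  ids <- align_accessions(trait, enc$dosage, Q, K)
  if (length(ids) < 30) stop("take-one-out needs >= 30 phenotyped accessions")
  y <- trait[ids]
  G <- enc$dosage[ids, , drop = FALSE]
  Qm <- if (is.null(Q)) NULL else as.matrix(Q)[ids, , drop = FALSE]
  Km <- if (is.null(K)) NULL else unclass(K)[ids, ids]

  fixed_sel <- NULL
  if (mode == "fast") {
    scan <- snp_association(y, G, annotations = ann, Q = Qm, K = Km,
                            maf_min = maf_min)
    thr <- bonferroni_threshold(alpha, attr(scan, "m_tested"))
    fixed_sel <- scan$id[scan$minus_log10_p > thr]
  }

  pred <- setNames(rep(NA_real_, length(ids)), ids)
  n_sel <- integer(length(ids))
  fell <- logical(length(ids))
  for (r in seq_along(ids)) {
    train <- ids[-r]
    sel <- fixed_sel
    if (mode == "full") {
      Ksub <- if (is.null(Km)) NULL else
        structure(Km[train, train], class = c("at_kinship", "matrix", "array"))
      scan <- snp_association(y[train], G[train, , drop = FALSE],
                              annotations = ann,
                              Q = if (is.null(Qm)) NULL else
                                Qm[train, , drop = FALSE],
                              K = Ksub, maf_min = maf_min)
      thr <- bonferroni_threshold(alpha, attr(scan, "m_tested"))
      sel <- scan$id[scan$minus_log10_p > thr]
    }
    n_sel[r] <- length(sel)
    if (!length(sel)) {
      pred[r] <- mean(y[train])
      fell[r] <- TRUE
      next
    }
    vals <- vapply(sel, function(s) {
      eff <- allelic_effects(calls[s, train], y[train])
      predict_from_allelic_effects(eff, calls[s, ids[r]])
    }, numeric(1))
    pred[r] <- mean(vals)
  }
  loo_report(y, pred, n_sel, fell, mode, "snp")
}

#' Take-one-out validation of GEM markers
#'
#' As [take_one_out_snp()], but reselects GEMs above the GEM Bonferroni line
#' in every round and predicts the left-out trait as the unweighted mean over
#' selected GEMs of `intercept + slope * RPKM` evaluated at the left-out
#' accession's expression.
#'
#' @inheritParams take_one_out_snp
#' @param Q Optional admixture covariates for the per-round GEM regressions.
#' @param rpkm RPKM matrix (models x accessions).
#' @param min_mean Expression floor (default 0.4 RPKM).
#' @param gc Apply genomic control within each round's scan (default `TRUE`).
#' @return An `at_loo` object.
#' @export
take_one_out_gem <- function(trait, rpkm, Q = NULL, alpha = 0.05,
                             min_mean = 0.4, gc = TRUE,
                             mode = c("full", "fast")) {
  mode <- match.arg(mode)
  ids <- align_accessions(trait, t(rpkm), Q)
  if (length(ids) < 30) stop("take-one-out needs >= 30 phenotyped accessions")
  y <- trait[ids]
  E <- rpkm[, ids, drop = FALSE]
  Qm <- if (is.null(Q)) NULL else as.matrix(Q)[ids, , drop = FALSE]

  scan_round <- function(train_ids) {
    gem_association(y[train_ids], E[, train_ids, drop = FALSE],
                    Q = if (is.null(Qm)) NULL else
                      Qm[train_ids, , drop = FALSE],
                    min_mean = min_mean, gc = gc)
  }
  fixed <- NULL
  if (mode == "fast") {
    scan <- scan_round(ids)
    thr <- bonferroni_threshold(alpha, attr(scan, "m_tested"))
    fixed <- scan[scan$minus_log10_p > thr, , drop = FALSE]
  }

  pred <- setNames(rep(NA_real_, length(ids)), ids)
  n_sel <- integer(length(ids))
  fell <- logical(length(ids))
  for (r in seq_along(ids)) {
    train <- ids[-r]
    sel <- if (mode == "full") {
      scan <- scan_round(train)
      thr <- bonferroni_threshold(alpha, attr(scan, "m_tested"))
      scan[scan$minus_log10_p > thr, , drop = FALSE]
    } else {
      # fast mode: refit the regression lines of the fixed selection
      if (nrow(fixed)) {
        scan <- gem_association(y[train],
                                E[fixed$id, train, drop = FALSE],
                                Q = if (is.null(Qm)) NULL else
                                  Qm[train, , drop = FALSE],
                                min_mean = -Inf, gc = FALSE)
        scan
      } else {
        fixed
      }
    }
    n_sel[r] <- nrow(sel)
    if (!nrow(sel)) {
      pred[r] <- mean(y[train])
      fell[r] <- TRUE
      next
    }
    pred[r] <- mean(sel$intercept + sel$slope * E[sel$id, ids[r]])
  }
  loo_report(y, pred, n_sel, fell, mode, "gem")
}

#' @export
print.at_loo <- function(x, ...) {
  cat(sprintf("Take-one-out %s prediction (%s mode)\n",
              toupper(x$type), x$mode))
  cat(sprintf("  %d rounds; mean markers selected per round: %.1f\n",
              nrow(x$report), mean(x$report$n_markers)))
  cat(sprintf("  predicted vs observed R2 = %.3f (P = %s)\n", x$r2,
              format.pval(x$p_value, digits = 3)))
  if (x$fallback_fraction > 0) {
    cat(sprintf("  fallback (no marker selected) in %.1f%% of rounds\n",
                100 * x$fallback_fraction))
  }
  invisible(x)
}

#' Predicted-versus-observed scatter of a take-one-out report
#'
#' @param x An `at_loo` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.at_loo <- function(x, ...) {
  plot(x$report$observed, x$report$predicted,
       xlab = "observed trait", ylab = "predicted trait",
       pch = 20, col = ifelse(x$report$fallback, "grey60", "black"), ...)
  abline(lm(predicted ~ observed, data = x$report), col = "red3")
  mtext(sprintf("R2 = %.2f", x$r2), side = 3, adj = 1, line = 0.2)
  invisible(x)
}
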