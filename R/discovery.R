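#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment with monotonicity enforcement over the non-missing
#' entries; missing p-values pass through as missing and do not enter the
#' denominator.
#'
#' @param pvals Numeric vector of p-values in (0, 1], NA allowed.
#' @return Adjusted q-values, same length and order.
#' @export
bh_fdr <- function(pvals) {
  ok <- !is.na(pvals)
  if (any(pvals[ok] <= 0 | pvals[ok] > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Select the significant gene set at an FDR threshold
#'
#' @param results A [fit_all_genes()] table.
#' @param alpha FDR threshold (default 0.05, the primary threshold).
#' @param label Set label.
#' @return List of class `gene_set`: `label`, `gene_ids`, `sign` (+1/-1 per
#'   gene from the coefficient), `n_up`, `n_down`.
#' @export
select_significant <- function(results, alpha = 0.05, label = "significant") {
  sel <- !is.na(results$q_fdr) & results$q_fdr < alpha
  ids <- results$gene_id[sel]
  sgn <- ifelse(results$coef[sel] >= 0, 1L, -1L)
  out <- list(label = label, gene_ids = ids,
              sign = stats::setNames(sgn, ids),
              n_up = sum(sgn > 0), n_down = sum(sgn < 0))
  class(out) <- "gene_set"
  out
}

#' Intersect two gene sets, carrying both signs
#'
#' @param a,b `gene_set` objects.
#' @return List of class `gene_set_overlap`: `gene_ids`, `sign_a`, `sign_b`.
#' @export
intersect_sets <- function(a, b) {
  ids <- intersect(a$gene_ids, b$gene_ids)
  out <- list(label = paste(a$label, b$label, sep = " & "),
              gene_ids = ids,
              sign_a = a$sign[ids], sign_b = b$sign[ids])
  class(out) <- "gene_set_overlap"
  out
}

#' Reversal statistics over the CTG / response coefficient planes
#'
#' Correlates the per-gene CTG-repeat and compound-response coefficients over
#' all shared genes and over the significant overlap, and reports the
#' fraction of overlap genes whose coefficients have opposite signs - the
#' signature of disease-associated dysregulation normalising in responders.
#'
#' @param ctg_results,response_results [fit_all_genes()] tables for the CTG
#'   and RESPONSE models.
#' @param overlap A `gene_set_overlap` from [intersect_sets()].
#' @return List of class `reversal_report`: `overlap_ids`, `pearson_r_all`,
#'   `n_all`, `pearson_r_overlap`, `sign_opposition_fraction`.
#' @export
reversal_stats <- function(ctg_results, response_results, overlap) {
  shared <- intersect(ctg_results$gene_id[!is.na(ctg_results$coef)],
                      response_results$gene_id[!is.na(response_results$coef)])
  cc <- ctg_results$coef[match(shared, ctg_results$gene_id)]
  cr <- response_results$coef[match(shared, response_results$gene_id)]
  r_all <- if (length(shared) >= 2) stats::cor(cc, cr) else NA_real_

  ids <- intersect(overlap$gene_ids, shared)
  oc <- ctg_results$coef[match(ids, ctg_results$gene_id)]
  or <- response_results$coef[match(ids, response_results$gene_id)]
  r_ov <- if (length(ids) >= 2) stats::cor(oc, or) else NA_real_
  frac <- if (length(ids)) mean(sign(oc) == -sign(or)) else NA_real_

  out <- list(overlap_ids = ids,
              pearson_r_all = r_all, n_all = length(shared),
              pearson_r_overlap = r_ov,
              sign_opposition_fraction = frac)
  class(out) <- "reversal_report"
  out
}

#' Response effects after residualising out the CTG-repeat effect
#'
#' Confounding check: stage 1 fits, per gene, intercept + timepoint +
#' CTG/100 with a patient random intercept and extracts the conditional
#' residuals (observed minus fixed and random effects); stage 2 fits the
#' zero-at-baseline response covariate on those residuals, again with a
#' patient random intercept. A high correlation between the residualised
#' and full-model response coefficients shows the response association is
#' not a CTG artefact.
#'
#' @inheritParams fit_all_genes
#' @param scores Compound response scores.
#' @return List: `coef_full`, `coef_residualized` (per-gene vectors, NA for
#'   non-converged genes), `pearson_r`, `n`.
#' @export
residualized_response_effects <- function(expr, samples, scores,
                                          theta_max = 1e4) {
  logcpm <- expr$logcpm
  weights <- expr$weights
  if (!identical(colnames(logcpm), samples$sample_id)) {
    idx <- match(samples$sample_id, colnames(logcpm))
    logcpm <- logcpm[, idx, drop = FALSE]
    weights <- weights[, idx, drop = FALSE]
  }
  full <- fit_all_genes(list(logcpm = logcpm, weights = weights),
                        samples, scores, "RESPONSE", theta_max)

  d1 <- build_design(samples, NULL, "CTG")
  stage1 <- lmm_fit_batch_cpp(logcpm, weights, d1$X,
                              as.integer(d1$group) - 1L, d1$coef - 1L,
                              theta_max, TRUE)
  resid <- stage1$resid_conditional
  dimnames(resid) <- dimnames(logcpm)

  cbt <- as.numeric(samples$timepoint == "T10M")
  resp <- scores$compound_response[match(samples$patient_id, scores$patient_id)] * cbt
  X2 <- cbind(intercept = 1, response = resp)
  if (qr(X2)$rank < ncol(X2)) {
    stop("stage-2 design is rank deficient (all scores zero?)", call. = FALSE)
  }
  stage2 <- lmm_fit_batch_cpp(resid, weights, X2,
                              as.integer(d1$group) - 1L, 1L, theta_max, FALSE)
  ok <- full$converged & stage2$converged
  r <- stats::cor(full$coef[ok], stage2$coef[ok])
  list(coef_full = stats::setNames(full$coef, full$gene_id),
       coef_residualized = stats::setNames(stage2$coef, rownames(logcpm)),
       pearson_r = r, n = sum(ok))
}

#' Per-patient expression changes
#'
#' `delta[p, g] = logcpm(T10M) - logcpm(T0)` for every patient and gene.
#'
#' @param expr A `weighted_expression` (or any list with a `logcpm` matrix).
#' @param samples Sample sheet (paired).
#' @return Patient x gene matrix of log2-CPM changes.
#' @export
per_patient_delta <- function(expr, samples) {
  logcpm <- expr$logcpm
  patients <- unique(samples$patient_id)
  s0 <- samples$sample_id[match(paste(patients, "T0"),
                                paste(samples$patient_id, samples$timepoint))]
  s1 <- samples$sample_id[match(paste(patients, "T10M"),
                                paste(samples$patient_id, samples$timepoint))]
  if (anyNA(s0) || anyNA(s1)) {
    stop("unpaired patients in sample sheet", call. = FALSE)
  }
  delta <- t(logcpm[, s1, drop = FALSE] - logcpm[, s0, drop = FALSE])
  rownames(delta) <- patients
  delta
}

#' Cluster patients and genes on expression changes
#'
#' Genes are z-scaled (centered, unit variance) across patients, then both
#' axes are clustered with complete linkage on Euclidean distances. Leaf
#' order is deterministic for a fixed input order; zero-variance genes are
#' dropped with a warning.
#'
#' @param delta Patient x gene matrix from [per_patient_delta()].
#' @param gene_subset Genes to cluster on (e.g. a significant set).
#' @param k Number of patient clusters to report (default 2).
#' @return List: `patient_order`, `gene_order`, `patient_hclust`,
#'   `gene_hclust`, `patient_cluster` (cutree at `k`).
#' @export
cluster_deltas <- function(delta, gene_subset = colnames(delta), k = 2) {
  stopifnot(length(gene_subset) >= 1, nrow(delta) >= 2)
  m <- delta[, gene_subset, drop = FALSE]
  v <- apply(m, 2, stats::var)
  if (any(v == 0)) {
    warning("dropping zero-variance gene(s): ",
            paste(colnames(m)[v == 0], collapse = ", "))
    m <- m[, v > 0, drop = FALSE]
  }
  z <- scale(m)   # per-gene centre and scale
  hp <- stats::hclust(stats::dist(z), method = "complete")
  if (ncol(z) >= 2) {
    hg <- stats::hclust(stats::dist(t(z)), method = "complete")
    gene_order <- colnames(z)[hg$order]
  } else {
    hg <- NULL
    gene_order <- colnames(z)
  }
  list(patient_order = rownames(z)[hp$order],
       gene_order = gene_order,
       patient_hclust = hp, gene_hclust = hg,
       patient_cluster = stats::cutree(hp, k = min(k, nrow(z))))
}

#' Pearson correlation with nominal two-sided p-value
#'
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors, length >= 3, non-degenerate.
#' @return List with `r`, `p`, `n`.
#' @export
pearson_corr_test <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 paired observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("degenerate (zero-variance) input", call. = FALSE)
  }
  r <- stats::cor(x, y)
  if (abs(r) >= 1) return(list(r = r, p = 0, n = n))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tstat), n - 2), n = n)
}
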