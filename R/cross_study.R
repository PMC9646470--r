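#' Two-sample Wilcoxon rank-sum test
#'
#' Midranks for ties; the exact null distribution is used when the combined
#' sample size is at most 12 and there are no ties, otherwise the normal
#' approximation with continuity and tie corrections.
#'
#' @param x,y Numeric vectors (each length >= 2).
#' @return List with `rank_sum` (sum of ranks of `x` in the pooled sample),
#'   `p` (two-sided) and `exact` (logical).
#' @export
wilcoxon_two_sample <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) {
    stop("each group needs >= 2 observations", call. = FALSE)
  }
  ranks <- rank(c(x, y))
  rank_sum <- sum(ranks[seq_along(x)])
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y)) <= 12 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE)
  )
  list(rank_sum = rank_sum, p = wt$p.value, exact = exact)
}

#' Per-gene case-minus-control mean differences
#'
#' The effect size used for cross-study comparison of an unpaired
#' case/control cohort on normalized log expression.
#'
#' @param cohort An `external_cohort` (list with `logexpr` and `label`).
#' @return Named numeric vector, `mean(case) - mean(control)` per gene.
#' @export
group_mean_difference <- function(cohort) {
  stopifnot(all(cohort$label %in% c("case", "control")))
  if (sum(cohort$label == "case") < 2 || sum(cohort$label == "control") < 2) {
    stop("each group needs >= 2 samples", call. = FALSE)
  }
  rowMeans(cohort$logexpr[, cohort$label == "case", drop = FALSE]) -
    rowMeans(cohort$logexpr[, cohort$label == "control", drop = FALSE])
}

#' Per-gene Wilcoxon tests of an external case/control cohort
#'
#' @param cohort An `external_cohort`.
#' @return Data frame: `gene_id`, `rank_sum`, `p`.
#' @export
wilcoxon_all_genes <- function(cohort) {
  is_case <- cohort$label == "case"
  res <- apply(cohort$logexpr, 1, function(v) {
    w <- wilcoxon_two_sample(v[is_case], v[!is_case])
    c(w$rank_sum, w$p)
  })
  data.frame(gene_id = rownames(cohort$logexpr),
             rank_sum = res[1, ], p = res[2, ],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Effect-size concordance between the discovery and an external cohort
#'
#' Pearson correlation between internal per-gene coefficients (e.g. the
#' CTG-repeat effects) and external per-gene effect sizes (e.g. case/control
#' mean differences), over the shared gene ids.
#'
#' @param internal,external Named numeric vectors of per-gene effect sizes.
#' @return List: `pearson_r`, `n_shared`, `scatter` (data frame of shared
#'   ids with both effect sizes).
#' @export
effect_size_concordance <- function(internal, external) {
  shared <- intersect(names(internal)[!is.na(internal)],
                      names(external)[!is.na(external)])
  if (length(shared) < 3) stop("fewer than 3 shared genes", call. = FALSE)
  scatter <- data.frame(gene_id = shared,
                        internal = unname(internal[shared]),
                        external = unname(external[shared]),
                        stringsAsFactors = FALSE)
  list(pearson_r = stats::cor(scatter$internal, scatter$external),
       n_shared = length(shared), scatter = scatter)
}
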