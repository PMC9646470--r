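#' Filter genes with low read counts
#'
#' Keeps a gene when its counts-per-million reach `min_count / median library
#' size * 1e6` in at least `n*` samples, where `n*` is the smallest group
#' size `s` when `s <= 10` and `10 + (s - 10) * 0.7` otherwise, and when its
#' total count reaches `min_total_count`. CPM here uses raw counts over raw
#' library sizes, without pseudocounts; the CPM comparison carries a small
#' relative slack (1e-10) so float-boundary genes are kept.
#'
#' @param counts Integer gene x sample matrix (row/column names required).
#' @param groups Per-sample group labels (e.g. timepoint before/after
#'   therapy).
#' @param min_count Count threshold referred to the median library size.
#' @param min_total_count Minimum total count across samples.
#' @param lib_sizes Optional per-sample library sizes; defaults to column
#'   sums.
#' @return Character vector of kept gene ids, in input order.
#' @export
filter_low_counts <- function(counts, groups, min_count = 50,
                              min_total_count = 15, lib_sizes = NULL) {
  check_count_matrix(counts)
  if (length(groups) != ncol(counts)) {
    stop("need one group label per sample", call. = FALSE)
  }
  tab <- table(groups)
  if (any(tab == 0)) stop("a group has zero samples", call. = FALSE)
  if (is.null(lib_sizes)) lib_sizes <- colSums(counts)

  s <- min(tab)
  n_star <- if (s <= 10) s else 10 + (s - 10) * 0.7
  cpm_cutoff <- min_count / stats::median(lib_sizes) * 1e6
  cpm <- sweep(counts, 2, lib_sizes, `/`) * 1e6
  tol <- 1e-10
  keep_cpm <- rowSums(cpm >= cpm_cutoff * (1 - tol)) >= n_star - 1e-14
  keep_total <- rowSums(counts) >= min_total_count - 1e-14
  rownames(counts)[keep_cpm & keep_total]
}

#' Normalized log2 counts per million
#'
#' `log2((count + 0.5) / (lib_size + 1) * 1e6)`, the offset log-CPM used as
#' the response variable of every downstream mixed model.
#'
#' @param counts Gene x sample count matrix.
#' @param lib_sizes Optional per-sample library sizes; defaults to column
#'   sums.
#' @return Matrix of the same shape.
#' @export
compute_logcpm <- function(counts, lib_sizes = NULL) {
  if (is.null(lib_sizes)) lib_sizes <- colSums(counts)
  if (any(lib_sizes <= 0)) stop("library sizes must be positive", call. = FALSE)
  t(log2(t(counts + 0.5) / (lib_sizes + 1) * 1e6))
}

#' Mean-variance precision weights for log-CPM
#'
#' Estimates a per-observation precision weight from the mean-variance trend
#' of log-expression: per gene, least squares of log-CPM on `design` yields a
#' residual standard deviation; the square root of that sd is smoothed
#' against average log2 count by lowess (span `span`); each observation's
#' sqrt-sd is then predicted from its fitted log2 count by piecewise-linear
#' interpolation (constant beyond the trend's range) and the weight is the
#' predicted value to the power -4. Genes should already be filtered for low
#' counts, where the trend is unreliable.
#'
#' @param counts Filtered gene x sample count matrix.
#' @param design Design matrix for the least-squares trend fit; defaults to
#'   intercept + group indicator when `groups` is given.
#' @param groups Optional per-sample two-level labels used to build the
#'   default design.
#' @param span Lowess span of the trend.
#' @param lib_sizes Optional per-sample library sizes; defaults to column
#'   sums.
#' @return A list of class `weighted_expression` with `logcpm` and `weights`
#'   matrices (identical dimnames) and the `trend` (x, y of the lowess fit).
#' @export
estimate_precision_weights <- function(counts, design = NULL, groups = NULL,
                                       span = 0.5, lib_sizes = NULL) {
  check_count_matrix(counts)
  if (is.null(lib_sizes)) lib_sizes <- colSums(counts)
  n <- ncol(counts)
  if (is.null(design)) {
    if (is.null(groups)) stop("give either a design or group labels", call. = FALSE)
    design <- cbind(1, as.numeric(factor(groups)) - 1)
  }
  design <- as.matrix(design)
  p <- qr(design)$rank
  if (n < ncol(design) + 1) {
    stop("fewer samples than design columns + 1", call. = FALSE)
  }
  if (n - p < 2) stop("need >= 2 residual degrees of freedom", call. = FALSE)

  logcpm <- compute_logcpm(counts, lib_sizes)
  fit <- stats::lm.fit(design, t(logcpm))
  res_sd <- sqrt(colSums(fit$residuals^2) / (n - p))
  sqrt_sd <- sqrt(res_sd)
  avg_logcount <- rowMeans(logcpm) + mean(log2(lib_sizes + 1)) - log2(1e6)

  trend <- stats::lowess(avg_logcount, sqrt_sd, f = span)
  trend_fun <- stats::approxfun(trend$x, trend$y, rule = 2, ties = mean)

  ## per-observation fitted log2 count from the gene's fitted log-CPM
  fitted_logcpm <- t(design %*% fit$coefficients)
  fitted_count <- 2^fitted_logcpm * rep(lib_sizes + 1, each = nrow(counts)) / 1e6
  pred_sqrt_sd <- trend_fun(log2(fitted_count))
  pred_sqrt_sd <- pmax(pred_sqrt_sd, 1e-6)   # weights stay finite and positive
  weights <- matrix(pred_sqrt_sd^-4, nrow(counts), n, dimnames = dimnames(counts))

  out <- list(logcpm = logcpm, weights = weights,
              trend = trend, avg_logcount = avg_logcount, sqrt_sd = sqrt_sd)
  class(out) <- "weighted_expression"
  out
}

check_count_matrix <- function(counts) {
  if (!is.matrix(counts)) stop("counts must be a matrix", call. = FALSE)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must carry gene and sample ids as dimnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(counts))) {
    stop("duplicate gene ids in count matrix", call. = FALSE)
  }
  if (anyDuplicated(colnames(counts))) {
    stop("duplicate sample ids in count matrix", call. = FALSE)
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  invisible(counts)
}
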