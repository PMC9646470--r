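#' Build the design matrix for one of the three per-gene models
#'
#' All three models share an intercept and a timepoint indicator (`cbt`: 0
#' at baseline, 1 after 10 months of therapy), which absorbs global
#' between-timepoint differences. The covariate of interest is
#' * `"CBT"` - none beyond the timepoint indicator itself;
#' * `"CTG"` - the patient's modal CTG-repeat length / 100 (identical on
#'   both of a patient's rows, so coefficients read "per 100 repeats");
#' * `"RESPONSE"` - the compound response score on T10M rows and exactly 0
#'   at baseline, so its coefficient captures response-associated change.
#'
#' @param samples Sample sheet: `sample_id`, `patient_id`, `timepoint`, and
#'   `ctg_length` for the CTG model.
#' @param scores [compound_response()] output; required for the RESPONSE
#'   model.
#' @param model `"CBT"`, `"CTG"` or `"RESPONSE"`.
#' @return List of class `lmm_design`: `X` (rows in sample-sheet order),
#'   `group` (patient factor), `coef` (index of the covariate of interest),
#'   `model`.
#' @export
build_design <- function(samples, scores = NULL,
                         model = c("CBT", "CTG", "RESPONSE")) {
  model <- match.arg(model)
  tab <- table(samples$patient_id, samples$timepoint)
  if (!all(dim(tab) == c(length(unique(samples$patient_id)), 2)) || any(tab != 1)) {
    bad <- rownames(tab)[rowSums(tab != 1) > 0]
    stop("unpaired patients (need exactly one T0 and one T10M sample): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  cbt <- as.numeric(samples$timepoint == "T10M")
  X <- cbind(intercept = 1, cbt = cbt)
  coef_idx <- 2L
  if (model == "CTG") {
    ctg_by_patient <- tapply(samples$ctg_length, samples$patient_id,
                             function(x) length(unique(x)))
    if (any(ctg_by_patient != 1)) {
      stop("ctg_length differs within a patient", call. = FALSE)
    }
    X <- cbind(X, ctg = samples$ctg_length / 100)
    coef_idx <- 3L
  } else if (model == "RESPONSE") {
    if (is.null(scores)) stop("RESPONSE model needs compound response scores",
                              call. = FALSE)
    idx <- match(samples$patient_id, scores$patient_id)
    if (anyNA(idx)) {
      stop("missing compound response score for patient(s): ",
           paste(unique(samples$patient_id[is.na(idx)]), collapse = ", "),
           call. = FALSE)
    }
    X <- cbind(X, response = scores$compound_response[idx] * cbt)
    coef_idx <- 3L
  }
  if (qr(X)$rank < ncol(X)) {
    stop("design matrix is rank deficient for model ", model, call. = FALSE)
  }
  out <- list(X = X, group = factor(samples$patient_id), coef = coef_idx,
              model = model)
  class(out) <- "lmm_design"
  out
}

#' Fit one weighted random-intercept linear mixed model by REML
#'
#' Fits `y = X beta + (1 | patient) + eps` with known per-observation
#' precision weights (`Var(eps_i) = sigma2 / w_i`). The REML criterion is
#' profiled over the residual variance and maximised over `theta =
#' tau2/sigma2` on `[0, theta_max]` by Brent's method with an analytic
#' gradient polish. Satterthwaite degrees of freedom use analytic
#' derivatives of each coefficient's squared standard error and the analytic
#' observed information of the REML surface; fits clamped at `tau2 = 0` fall
#' back to the ordinary-least-squares residual df and carry `boundary =
#' TRUE`.
#'
#' @param y Numeric response (one value per sample).
#' @param X Design matrix or an `lmm_design`.
#' @param weights Positive precision weights, one per observation.
#' @param group Grouping factor (patient); taken from `X` when it is an
#'   `lmm_design`.
#' @param theta_max Upper search bound for `tau2/sigma2`.
#' @return List of class `lmm_fit`: `beta`, `cov_beta`, `se`, `t`, `df`,
#'   `p`, `sigma2`, `tau2`, `reml_loglik`, `converged`, `boundary`, `blup`,
#'   `resid_conditional`, `n_obs`, `n_groups`.
#' @export
fit_lmm_reml <- function(y, X, weights, group = NULL, theta_max = 1e4) {
  if (inherits(X, "lmm_design")) {
    group <- X$group
    X <- X$X
  }
  X <- as.matrix(X)
  if (is.null(group)) stop("a grouping factor is required", call. = FALSE)
  group <- as.factor(group)
  n <- length(y)
  stopifnot(nrow(X) == n, length(weights) == n, length(group) == n)
  if (!all(is.finite(y))) stop("non-finite response values", call. = FALSE)
  if (!all(is.finite(weights)) || any(weights <= 0)) {
    stop("weights must be finite and strictly positive", call. = FALSE)
  }
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient", call. = FALSE)
  if (n <= ncol(X) + 1) stop("too few observations for the design", call. = FALSE)

  fit <- lmm_fit_one_cpp(as.numeric(y), as.numeric(weights), X,
                         as.integer(group) - 1L, theta_max)
  if (!isTRUE(fit$converged)) {
    stop("REML fit did not converge", call. = FALSE)
  }
  fit$beta <- drop(fit$beta)
  names(fit$beta) <- colnames(X)
  dimnames(fit$cov_beta) <- list(colnames(X), colnames(X))
  fit$se <- drop(fit$se); fit$t <- drop(fit$t)
  fit$df <- drop(fit$df); fit$p <- drop(fit$p)
  names(fit$se) <- names(fit$t) <- names(fit$df) <- names(fit$p) <- colnames(X)
  fit$blup <- stats::setNames(drop(fit$blup), levels(group))
  class(fit) <- "lmm_fit"
  fit
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("Weighted random-intercept LMM (REML)\n")
  cat(sprintf("  n_obs = %d, n_groups = %d, sigma2 = %.4g, tau2 = %.4g%s\n",
              x$n_obs, x$n_groups, x$sigma2, x$tau2,
              if (isTRUE(x$boundary)) " (boundary)" else ""))
  print(data.frame(beta = x$beta, se = x$se, t = x$t, df = x$df, p = x$p))
  invisible(x)
}

#' Satterthwaite t-test for one fixed-effect coefficient
#'
#' Returns the t statistic, the Satterthwaite degrees of freedom `2 *
#' (se^2)^2 / Var(se^2)` and the two-sided p-value for one coefficient of a
#' converged [fit_lmm_reml()] fit.
#'
#' @param fit An `lmm_fit`.
#' @param coef_index Column index or name of the coefficient.
#' @return List with `t`, `df`, `p`.
#' @export
satterthwaite_test <- function(fit, coef_index) {
  stopifnot(inherits(fit, "lmm_fit"))
  if (is.character(coef_index)) coef_index <- match(coef_index, names(fit$beta))
  list(t = unname(fit$t[coef_index]), df = unname(fit$df[coef_index]),
       p = unname(fit$p[coef_index]))
}

#' Fit the per-gene mixed model across all genes
#'
#' Runs the weighted random-intercept REML fit gene by gene for the chosen
#' model and reports, for the covariate of interest, the coefficient (log2
#' scale; per 100 repeats for the CTG model), its standard error,
#' Satterthwaite t/df/p, the BH-adjusted q-value and the fold change
#' `2^coef`. Non-converged genes keep a row with missing statistics and are
#' excluded from the FDR denominator.
#'
#' @param expr A `weighted_expression` (or list with `logcpm` and `weights`
#'   matrices).
#' @param samples Sample sheet aligned to the expression columns by
#'   `sample_id`.
#' @param scores Compound response scores (RESPONSE model only).
#' @param model `"CBT"`, `"CTG"` or `"RESPONSE"`.
#' @param theta_max Upper bound for `tau2/sigma2`.
#' @return Data frame: `gene_id`, `coef`, `se`, `t`, `df`, `p`, `q_fdr`,
#'   `fold_change`, `converged`, `boundary`.
#' @export
fit_all_genes <- function(expr, samples, scores = NULL,
                          model = c("CBT", "CTG", "RESPONSE"),
                          theta_max = 1e4) {
  model <- match.arg(model)
  logcpm <- expr$logcpm
  weights <- expr$weights
  stopifnot(identical(dim(logcpm), dim(weights)))
  if (!identical(colnames(logcpm), samples$sample_id)) {
    idx <- match(samples$sample_id, colnames(logcpm))
    if (anyNA(idx) || length(idx) != ncol(logcpm)) {
      stop("expression columns and sample sheet ids are misaligned", call. = FALSE)
    }
    logcpm <- logcpm[, idx, drop = FALSE]
    weights <- weights[, idx, drop = FALSE]
  }
  design <- build_design(samples, scores, model)
  res <- lmm_fit_batch_cpp(logcpm, weights, design$X,
                           as.integer(design$group) - 1L,
                           design$coef - 1L, theta_max, FALSE)
  out <- data.frame(
    gene_id = rownames(logcpm),
    coef = res$coef, se = res$se, t = res$t, df = res$df, p = res$p,
    q_fdr = bh_fdr(ifelse(res$converged, res$p, NA_real_)),
    fold_change = 2^res$coef,
    converged = res$converged, boundary = res$boundary,
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(out, "model") <- model
  out
}
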