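#' Canonical tab-separated table writing
#'
#' Fixed column order as given, tab delimiter, `NA` for missing, reals at 6
#' significant digits (integer-valued cells written without a decimal
#' point), so that write(read(x)) round-trips byte-identically for
#' canonically formatted files.
#'
#' @param x Data frame.
#' @param path Output path.
#' @export
write_table_canonical <- function(x, path) {
  out <- x
  for (j in seq_along(out)) {
    col <- out[[j]]
    if (is.double(col)) {
      txt <- ifelse(is.na(col), "NA",
                    ifelse(col == round(col) & abs(col) < 1e15,
                           sprintf("%.0f", col),
                           formatC(col, digits = 6, format = "g")))
      out[[j]] <- txt
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Checked tab-separated table reading
#'
#' @param path Input path.
#' @param schema Named character vector mapping required column names to
#'   types (`"character"`, `"integer"`, `"double"`).
#' @param id_col Optional column checked for duplicates.
#' @return Data frame.
#' @export
read_table_checked <- function(path, schema = NULL, id_col = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- utils::read.table(path, sep = "\t", header = TRUE, na.strings = "NA",
                         stringsAsFactors = FALSE, check.names = FALSE,
                         quote = "", comment.char = "")
  if (!is.null(schema)) {
    miss <- setdiff(names(schema), names(x))
    if (length(miss)) {
      stop("schema error in ", basename(path), ": missing column(s) ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    for (col in names(schema)) {
      want <- schema[[col]]
      v <- x[[col]]
      all_missing <- is.logical(v) && all(is.na(v))   # read.table's all-NA type
      if (want %in% c("integer", "double") && !is.numeric(v) && !all_missing) {
        stop("schema error in ", basename(path), ": column '", col,
             "' is not numeric", call. = FALSE)
      }
      if (want == "integer") x[[col]] <- as.integer(v)
      if (want == "double") x[[col]] <- as.double(v)
    }
  }
  if (!is.null(id_col) && anyDuplicated(x[[id_col]])) {
    dup <- unique(x[[id_col]][duplicated(x[[id_col]])])
    stop("duplicate ", id_col, " in ", basename(path), ": ",
         paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
  }
  x
}

#' Write a gene x sample matrix as TSV (gene rows, header of sample ids)
#' @param m Matrix with dimnames.
#' @param path Output path.
#' @param id_name Name of the leading id column.
#' @export
write_matrix_tsv <- function(m, path, id_name = "gene_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_name
  write_table_canonical(df, path)
}

#' Read a gene x sample matrix written by [write_matrix_tsv()]
#' @param path Input path.
#' @param id_name Name of the leading id column.
#' @export
read_matrix_tsv <- function(path, id_name = "gene_id") {
  df <- read_table_checked(path, id_col = id_name)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

## deterministic per-stage child seeds fanned out from the global seed
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)) * 131L)
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

#' Run the full analysis pipeline on a simulated or provided cohort
#'
#' simulate (optional) -> filter -> log-CPM + precision weights -> compound
#' response scores -> the three per-gene mixed models -> significant sets,
#' overlap and reversal statistics -> external-cohort concordance.
#'
#' @param config List. Recognised entries: `truth` (a [truth_config()];
#'   triggers simulation) or `counts`/`samples`/`outcomes`/`measures`
#'   (in-memory inputs in the generator's layout), `alpha_fdr` (default
#'   0.05), `min_count` (default 50), `external` (logical, default TRUE:
#'   simulate and compare an external case/control cohort; needs `truth`),
#'   `n_external` (per-group size, default 20), `seed` (mandatory for any
#'   stochastic step), `outdir` (optional: stage outputs written as TSV).
#' @return List of class `dmrev_report`: the stage outputs plus a `report`
#'   list of headline numbers (gene counts, set sizes with up/down splits,
#'   overlap size, reversal statistics, concordance, convergence failures,
#'   seeds used).
#' @export
run_pipeline <- function(config) {
  if (is.null(config$seed)) stop("config$seed is mandatory", call. = FALSE)
  alpha <- config$alpha_fdr %||% 0.05
  stopifnot(alpha > 0, alpha < 1)
  min_count <- config$min_count %||% 50
  seeds <- list(simulate = stage_seed(config$seed, "simulate"),
                external = stage_seed(config$seed, "external"))

  if (!is.null(config$truth)) {
    cfg <- config$truth
    cfg$seed <- seeds$simulate
    sim <- generate_cohort(cfg)
  } else {
    sim <- config[c("counts", "samples", "outcomes", "measures")]
    if (is.null(sim$counts) || is.null(sim$samples) || is.null(sim$outcomes) ||
        is.null(sim$measures)) {
      stop("config needs either a truth block or counts/samples/outcomes/measures",
           call. = FALSE)
    }
    check_sample_sheet(sim$samples)
  }

  ## expression preparation
  groups <- sim$samples$timepoint
  kept <- filter_low_counts(sim$counts, groups, min_count = min_count)
  expr <- estimate_precision_weights(sim$counts[kept, , drop = FALSE],
                                     groups = groups)

  ## clinical scoring
  deltas <- oriented_deltas(sim$outcomes, sim$measures)
  scores <- compound_response(deltas)

  ## per-gene models
  res_cbt <- fit_all_genes(expr, sim$samples, model = "CBT")
  res_ctg <- fit_all_genes(expr, sim$samples, model = "CTG")
  res_resp <- fit_all_genes(expr, sim$samples, scores, model = "RESPONSE")

  ## discovery
  set_cbt <- select_significant(res_cbt, alpha, "CBT")
  set_ctg <- select_significant(res_ctg, alpha, "CTG")
  set_resp <- select_significant(res_resp, alpha, "RESPONSE")
  overlap <- intersect_sets(set_ctg, set_resp)
  reversal <- reversal_stats(res_ctg, res_resp, overlap)

  ## cross-study validation
  concordance <- NULL
  if (isTRUE(config$external %||% TRUE) && !is.null(sim$truth)) {
    n_ext <- config$n_external %||% 20
    ext <- generate_external_cohort(sim$truth, n_ext, n_ext, seeds$external)
    eff_ext <- group_mean_difference(ext)
    eff_int <- stats::setNames(res_ctg$coef, res_ctg$gene_id)
    ctg_kept <- intersect(sim$truth$ctg_set, res_ctg$gene_id)
    concordance <- list(
      all = effect_size_concordance(eff_int, eff_ext),
      ctg_set = if (length(ctg_kept) >= 3) {
        effect_size_concordance(eff_int[ctg_kept], eff_ext[ctg_kept])
      }
    )
  }

  report <- list(
    seed = config$seed, stage_seeds = seeds,
    n_genes_input = nrow(sim$counts),
    n_genes_filtered = length(kept),
    n_patients = length(unique(sim$samples$patient_id)),
    alpha_fdr = alpha,
    cbt = c(n = length(set_cbt$gene_ids), up = set_cbt$n_up, down = set_cbt$n_down),
    ctg = c(n = length(set_ctg$gene_ids), up = set_ctg$n_up, down = set_ctg$n_down),
    response = c(n = length(set_resp$gene_ids), up = set_resp$n_up,
                 down = set_resp$n_down),
    overlap_n = length(overlap$gene_ids),
    reversal = list(pearson_r_all = reversal$pearson_r_all,
                    pearson_r_overlap = reversal$pearson_r_overlap,
                    sign_opposition_fraction = reversal$sign_opposition_fraction),
    concordance_r_all = if (!is.null(concordance)) concordance$all$pearson_r,
    concordance_r_ctg_set = if (!is.null(concordance) &&
                                !is.null(concordance$ctg_set)) {
      concordance$ctg_set$pearson_r
    },
    n_nonconverged = sum(!res_cbt$converged) + sum(!res_ctg$converged) +
      sum(!res_resp$converged)
  )

  out <- list(sim = sim, kept_genes = kept, expr = expr, scores = scores,
              results = list(CBT = res_cbt, CTG = res_ctg, RESPONSE = res_resp),
              sets = list(CBT = set_cbt, CTG = set_ctg, RESPONSE = set_resp),
              overlap = overlap, reversal = reversal,
              concordance = concordance, report = report)
  class(out) <- "dmrev_report"

  if (!is.null(config$outdir)) write_pipeline_outputs(out, config$outdir)
  out
}

check_sample_sheet <- function(samples) {
  need <- c("sample_id", "patient_id", "timepoint")
  miss <- setdiff(need, names(samples))
  if (length(miss)) {
    stop("schema error in sample sheet: missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!all(samples$timepoint %in% c("T0", "T10M"))) {
    stop("schema error in sample sheet: timepoint must be T0 or T10M",
         call. = FALSE)
  }
  invisible(samples)
}

write_pipeline_outputs <- function(run, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  sim <- run$sim
  write_matrix_tsv(sim$counts, file.path(outdir, "counts.tsv"))
  write_table_canonical(sim$samples, file.path(outdir, "samples.tsv"))
  write_table_canonical(sim$outcomes, file.path(outdir, "outcomes.tsv"))
  write_table_canonical(sim$measures, file.path(outdir, "measures.tsv"))
  if (!is.null(sim$truth)) {
    truth_df <- data.frame(
      gene_id = sim$truth$gene_ids,
      baseline_log2_mean = sim$truth$baseline_log2_mean,
      cbt_effect = sim$truth$cbt_effect,
      ctg_effect_per100 = sim$truth$ctg_effect_per100,
      response_effect = sim$truth$response_effect,
      dispersion = sim$truth$dispersion,
      random_intercept_sd = sim$truth$random_intercept_sd,
      stringsAsFactors = FALSE
    )
    write_table_canonical(truth_df, file.path(outdir, "truth.tsv"))
  }
  write_matrix_tsv(run$expr$logcpm, file.path(outdir, "logcpm.tsv"))
  write_matrix_tsv(run$expr$weights, file.path(outdir, "weights.tsv"))
  write_table_canonical(as.data.frame(run$scores),
                        file.path(outdir, "response_scores.tsv"))
  for (m in names(run$results)) {
    write_table_canonical(run$results[[m]],
                          file.path(outdir, paste0("results_",
                                                   tolower(m), ".tsv")))
  }
  overlap_df <- data.frame(gene_id = run$overlap$gene_ids,
                           sign_ctg = as.integer(run$overlap$sign_a),
                           sign_response = as.integer(run$overlap$sign_b),
                           stringsAsFactors = FALSE)
  write_table_canonical(overlap_df, file.path(outdir, "overlap.tsv"))
  invisible(outdir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.dmrev_report <- function(x, ...) {
  r <- x$report
  cat("dmrev pipeline report (seed ", r$seed, ")\n", sep = "")
  cat(sprintf("  genes: %d input, %d after low-count filter; %d patients\n",
              r$n_genes_input, r$n_genes_filtered, r$n_patients))
  cat(sprintf("  CBT:      %d significant (%d up / %d down)\n",
              r$cbt["n"], r$cbt["up"], r$cbt["down"]))
  cat(sprintf("  CTG:      %d significant (%d up / %d down)\n",
              r$ctg["n"], r$ctg["up"], r$ctg["down"]))
  cat(sprintf("  response: %d significant (%d up / %d down)\n",
              r$response["n"], r$response["up"], r$response["down"]))
  cat(sprintf("  overlap: %d genes; sign opposition %.3f; overlap r %.3f\n",
              r$overlap_n, r$reversal$sign_opposition_fraction,
              r$reversal$pearson_r_overlap))
  if (!is.null(r$concordance_r_ctg_set)) {
    cat(sprintf("  external concordance (CTG set): r = %.3f\n",
                r$concordance_r_ctg_set))
  }
  invisible(x)
}
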