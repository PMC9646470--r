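#!/usr/bin/env Rscript
# Stage 5: reversal biomarker discovery. Intersects the CTG- and
# response-associated gene sets, quantifies the anticorrelation of their
# coefficients (disease-shifted expression normalising in responders),
# checks that the response effects survive residualising out the CTG
# effect, clusters patients on their expression changes, and correlates
# per-gene expression change with the compound response.

library(dmrev)
outdir <- "results/discovery"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

res <- lapply(c(cbt = "cbt", ctg = "ctg", response = "response"), function(m) {
  read_table_checked(sprintf("results/models/results_%s.tsv", m),
                     schema = c(gene_id = "character", coef = "double",
                                p = "double", q_fdr = "double"),
                     id_col = "gene_id")
})
expr <- list(logcpm = read_matrix_tsv("results/expression/logcpm.tsv"),
             weights = read_matrix_tsv("results/expression/weights.tsv"))
samples <- read_table_checked("results/cohort/samples.tsv")
scores <- read_table_checked("results/clinical/response_scores.tsv",
                             schema = c(patient_id = "character",
                                        compound_response = "double"))

set_ctg <- select_significant(res$ctg, 0.05, "CTG")
set_resp <- select_significant(res$response, 0.05, "RESPONSE")
overlap <- intersect_sets(set_ctg, set_resp)
rev <- reversal_stats(res$ctg, res$response, overlap)

cat(sprintf("overlap of CTG and response sets: %d genes\n",
            length(overlap$gene_ids)))
cat(sprintf("coefficient correlation: r = %.3f over the overlap, r = %.3f over all %d genes\n",
            rev$pearson_r_overlap, rev$pearson_r_all, rev$n_all))
cat(sprintf("sign opposition over the overlap: %.3f\n",
            rev$sign_opposition_fraction))

overlap_df <- data.frame(gene_id = overlap$gene_ids,
                         sign_ctg = as.integer(overlap$sign_a),
                         sign_response = as.integer(overlap$sign_b))
write_table_canonical(overlap_df, file.path(outdir, "overlap.tsv"))

# confounding check: response effects after regressing out the CTG effect
rr <- residualized_response_effects(expr, samples, scores)
cat(sprintf("residualised vs full response coefficients: r = %.3f over %d genes\n",
            rr$pearson_r, rr$n))

# patient heterogeneity: cluster expression changes over the therapy set
set_cbt <- select_significant(res$cbt, 0.05, "CBT")
if (length(set_cbt$gene_ids) >= 2) {
  delta <- per_patient_delta(expr, samples)
  cl <- cluster_deltas(delta, set_cbt$gene_ids, k = 2)
  split_sizes <- table(cl$patient_cluster)
  cat(sprintf("patient clustering on %d therapy genes: %s split at k = 2\n",
              length(set_cbt$gene_ids), paste(split_sizes, collapse = "/")))
  orders <- data.frame(axis = c(rep("patient", length(cl$patient_order)),
                                rep("gene", length(cl$gene_order))),
                       id = c(cl$patient_order, cl$gene_order),
                       position = c(seq_along(cl$patient_order),
                                    seq_along(cl$gene_order)))
  write_table_canonical(orders, file.path(outdir, "cluster_orders.tsv"))
}

# per-biomarker correlation between expression change and clinical response
delta <- per_patient_delta(expr, samples)
corr <- do.call(rbind, lapply(overlap$gene_ids, function(g) {
  ct <- pearson_corr_test(delta[scores$patient_id, g],
                          scores$compound_response)
  data.frame(gene_id = g, pearson_r = ct$r, p = ct$p)
}))
if (!is.null(corr)) {
  write_table_canonical(corr, file.path(outdir, "biomarker_correlations.tsv"))
  cat(sprintf("%d of %d overlap genes nominally correlated (p < 0.05) with compound response\n",
              sum(corr$p < 0.05), nrow(corr)))
}
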