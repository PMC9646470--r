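#!/usr/bin/env Rscript
# Stage 4: the three per-gene weighted random-intercept mixed models.
#   timepoint model:  logCPM ~ cbt + (1 | patient)
#   CTG model:        logCPM ~ cbt + ctg/100 + (1 | patient)
#   response model:   logCPM ~ cbt + response * I(T10M) + (1 | patient)
# REML fits with voom-style precision weights carried over; Satterthwaite
# p-values, BH-adjusted per model.

library(dmrev)
outdir <- "results/models"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

expr <- list(logcpm = read_matrix_tsv("results/expression/logcpm.tsv"),
             weights = read_matrix_tsv("results/expression/weights.tsv"))
samples <- read_table_checked("results/cohort/samples.tsv",
                              schema = c(sample_id = "character",
                                         patient_id = "character",
                                         timepoint = "character",
                                         ctg_length = "integer"))
scores <- read_table_checked("results/clinical/response_scores.tsv",
                             schema = c(patient_id = "character",
                                        compound_response = "double"))

for (model in c("CBT", "CTG", "RESPONSE")) {
  res <- fit_all_genes(expr, samples, scores, model)
  write_table_canonical(res, file.path(outdir, sprintf("results_%s.tsv",
                                                       tolower(model))))
  sig <- select_significant(res, 0.05, model)
  cat(sprintf("%-8s: %4d significant at FDR < 0.05 (%d up, %d down), %d non-converged\n",
              model, length(sig$gene_ids), sig$n_up, sig$n_down,
              sum(!res$converged)))
}
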