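#!/usr/bin/env Rscript
# Stage 2: low-count filtering and precision weighting. Genes must reach 50
# reads (referred to the median library size) in enough samples; the
# retained genes get log2-CPM values and per-observation inverse-variance
# weights from the fitted mean-variance trend.

library(dmrev)
indir <- "results/cohort"
outdir <- "results/expression"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

counts <- read_matrix_tsv(file.path(indir, "counts.tsv"))
storage.mode(counts) <- "integer"
samples <- read_table_checked(file.path(indir, "samples.tsv"),
                              schema = c(sample_id = "character",
                                         patient_id = "character",
                                         timepoint = "character",
                                         ctg_length = "integer"),
                              id_col = "sample_id")

kept <- filter_low_counts(counts, samples$timepoint, min_count = 50)
cat(sprintf("low-count filter: %d of %d genes kept (min.count = 50)\n",
            length(kept), nrow(counts)))

expr <- estimate_precision_weights(counts[kept, ], groups = samples$timepoint)
cat(sprintf("precision weights: range %.3g - %.3g (ratio %.1f)\n",
            min(expr$weights), max(expr$weights),
            max(expr$weights) / min(expr$weights)))

write_matrix_tsv(expr$logcpm, file.path(outdir, "logcpm.tsv"))
write_matrix_tsv(expr$weights, file.path(outdir, "weights.tsv"))
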