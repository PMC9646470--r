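#!/usr/bin/env Rscript
# Stage 3: compound response scoring. Per-patient instrument changes are
# sign-oriented (positive = improvement), RMS-scaled to a common unit, and
# averaged into one compound response score per patient; the flagged
# control instrument is excluded.

library(dmrev)
indir <- "results/cohort"
outdir <- "results/clinical"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

outcomes <- read_table_checked(file.path(indir, "outcomes.tsv"),
                               schema = c(patient_id = "character",
                                          measure_id = "character",
                                          timepoint = "character",
                                          value = "double"))
measures <- read_table_checked(file.path(indir, "measures.tsv"),
                               schema = c(measure_id = "character",
                                          orientation = "integer",
                                          is_control = "integer"),
                               id_col = "measure_id")

deltas <- oriented_deltas(outcomes, measures)
scores <- compound_response(deltas)
write_table_canonical(as.data.frame(scores),
                      file.path(outdir, "response_scores.tsv"))

cat(sprintf("%d patients scored on %d instruments (control excluded)\n",
            nrow(scores), ncol(deltas)))
cat(sprintf("compound response range: %.2f to %.2f (mean %.2f)\n",
            min(scores$compound_response), max(scores$compound_response),
            mean(scores$compound_response)))
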