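#!/usr/bin/env Rscript
# Stage 6: cross-study validation. Simulates an independent unpaired
# case/control cohort from the same ground truth (fresh draws, case-like
# repeat lengths), computes per-gene Wilcoxon tests and case-minus-control
# mean differences on normalized log expression, and correlates those
# external effect sizes with the discovery cohort's CTG coefficients.

library(dmrev)
seed <- 20260930L
outdir <- "results/cross_study"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

# regenerate the truth deterministically from stage 1's configuration
cfg <- truth_config(libsize_scale = 1, seed = seed)
truth <- generate_cohort(cfg)$truth

ext <- generate_external_cohort(truth, n_cases = 20, n_controls = 20,
                                seed = seed + 1L)
eff_ext <- group_mean_difference(ext)
wt <- wilcoxon_all_genes(ext)
cat(sprintf("external cohort: 20 DM1-like cases vs 20 controls, %d genes\n",
            nrow(ext$logexpr)))
cat(sprintf("genes with Wilcoxon p < 0.05: %d\n", sum(wt$p < 0.05)))

res_ctg <- read_table_checked("results/models/results_ctg.tsv",
                              schema = c(gene_id = "character",
                                         coef = "double"),
                              id_col = "gene_id")
eff_int <- setNames(res_ctg$coef, res_ctg$gene_id)

conc_all <- effect_size_concordance(eff_int, eff_ext)
ctg_genes <- intersect(truth$ctg_set, names(eff_int))
conc_ctg <- effect_size_concordance(eff_int[ctg_genes], eff_ext[ctg_genes])
cat(sprintf("effect-size concordance: r = %.3f over all %d shared genes\n",
            conc_all$pearson_r, conc_all$n_shared))
cat(sprintf("                         r = %.3f over the %d CTG-set genes\n",
            conc_ctg$pearson_r, conc_ctg$n_shared))

write_table_canonical(conc_all$scatter, file.path(outdir, "concordance.tsv"))
write_table_canonical(wt, file.path(outdir, "wilcoxon.tsv"))
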