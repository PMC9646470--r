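test_that("BH adjustment matches hand computation and the step-up oracle", {
  expect_equal(bh_fdr(c(0.01, 0.04, 0.03, 0.002)),
               c(0.02, 0.04, 0.04, 0.008), tolerance = 1e-12)
  expect_equal(bh_fdr(0.05), 0.05)
  withr::with_seed(201, {
    for (i in 1:200) {
      p <- runif(sample(1:60, 1))^sample(1:3, 1)
      q <- bh_fdr(p)
      expect_equal(q, bh_brute(p), tolerance = 1e-14)
      expect_true(all(q >= p - 1e-15))
      expect_true(all(q <= 1))
    }
  })
  # missing entries pass through, the rest adjusts over m non-missing
  q <- bh_fdr(c(0.01, NA, 0.04, 0.03, 0.002))
  expect_true(is.na(q[2]))
  expect_equal(q[-2], c(0.02, 0.04, 0.04, 0.008), tolerance = 1e-12)
  expect_error(bh_fdr(c(0.5, 0)), "0, 1")
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("significant-set construction respects alpha and records signs", {
  res <- data.frame(gene_id = paste0("g", 1:6),
                    coef = c(1, -2, 0.5, -0.1, 3, -4),
                    q_fdr = c(0.01, 0.2, 0.001, NA, 0.049, 0.9),
                    converged = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE))
  set <- select_significant(res, alpha = 0.05)
  expect_setequal(set$gene_ids, c("g1", "g3", "g5"))
  expect_identical(set$n_up, 3L)
  expect_identical(set$n_down, 0L)
  empty <- select_significant(res[0, ], alpha = 0.05)
  expect_length(empty$gene_ids, 0)
  all_set <- select_significant(res, alpha = 1.0000001)
  expect_setequal(all_set$gene_ids, res$gene_id[!is.na(res$q_fdr)])
})

test_that("set intersection carries both signs and obeys set identities", {
  a <- list(label = "A", gene_ids = c("g1", "g2", "g3"),
            sign = c(g1 = 1L, g2 = -1L, g3 = 1L))
  b <- list(label = "B", gene_ids = c("g2", "g3", "g4"),
            sign = c(g2 = 1L, g3 = -1L, g4 = 1L))
  class(a) <- class(b) <- "gene_set"
  ov <- intersect_sets(a, b)
  expect_setequal(ov$gene_ids, c("g2", "g3"))
  expect_identical(unname(ov$sign_a[ov$gene_ids]), c(-1L, 1L))
  expect_identical(unname(ov$sign_b[ov$gene_ids]), c(1L, -1L))
  # disjoint and subset cases
  c0 <- list(label = "C", gene_ids = "g9", sign = c(g9 = 1L)); class(c0) <- "gene_set"
  expect_length(intersect_sets(a, c0)$gene_ids, 0)
  expect_setequal(intersect_sets(a, a)$gene_ids, a$gene_ids)
  expect_identical(length(intersect_sets(a, b)$gene_ids) +
                     length(setdiff(a$gene_ids, b$gene_ids)),
                   length(a$gene_ids))
})

test_that("reversal statistics report anticorrelation and sign opposition", {
  ctg <- data.frame(gene_id = c("g1", "g2", "g3"), coef = c(0.2, -0.1, 0.4))
  rsp <- data.frame(gene_id = c("g1", "g2", "g3"), coef = c(-0.3, 0.2, -0.8))
  ov <- list(gene_ids = c("g1", "g2"))
  rep1 <- reversal_stats(ctg, rsp, ov)
  expect_equal(rep1$sign_opposition_fraction, 1)
  expect_identical(rep1$n_all, 3L)
  # exact negation gives r = -1 over all genes
  rsp2 <- ctg; rsp2$coef <- -ctg$coef
  rep2 <- reversal_stats(ctg, rsp2, ov)
  expect_equal(rep2$pearson_r_all, -1, tolerance = 1e-12)
  # overlap below 2 genes: correlation missing, fraction still computed
  rep3 <- reversal_stats(ctg, rsp, list(gene_ids = "g1"))
  expect_true(is.na(rep3$pearson_r_overlap))
  expect_equal(rep3$sign_opposition_fraction, 1)
})

test_that("per-patient deltas are the T10M - T0 log-CPM differences", {
  sim <- generate_cohort(small_cohort_config(seed = 205))
  expr <- list(logcpm = compute_logcpm(sim$counts))
  d <- per_patient_delta(expr, sim$samples)
  s0 <- paste0(rownames(d), "_T0"); s1 <- paste0(rownames(d), "_T10M")
  expect_equal(d, t(expr$logcpm[, s1] - expr$logcpm[, s0]),
               ignore_attr = TRUE)
  # identical timepoints give zeros; swapping labels negates
  same <- expr
  same$logcpm[, s1] <- same$logcpm[, s0]
  expect_true(all(per_patient_delta(same, sim$samples) == 0))
  flipped <- sim$samples
  flipped$timepoint <- ifelse(flipped$timepoint == "T0", "T10M", "T0")
  expect_equal(per_patient_delta(expr, flipped), -d, ignore_attr = TRUE)
  expect_error(per_patient_delta(expr, sim$samples[-1, ]), "unpaired")
})

test_that("per-patient deltas track the planted change in expectation", {
  withr::with_seed(206, {
    # planted fractions mirror the default study conditions; a much larger
    # planted fraction would shift all deltas through library composition
    cfg <- truth_config(n_genes = 2000, n_cbt_genes = 100, n_ctg_genes = 120,
                        n_response_genes = 60, n_reversal_genes = 20,
                        libsize_scale = 1, seed = 206)
    reps <- lapply(1:25, function(i) {
      cfg$seed <- 206 + i
      sim <- generate_cohort(cfg)
      expr <- list(logcpm = compute_logcpm(sim$counts))
      list(delta = per_patient_delta(expr, sim$samples), truth = sim$truth)
    })
    # compare each replicate against its own truth, averaging the bias
    bias <- unlist(lapply(reps, function(rp) {
      tr <- rp$truth
      expected <- outer(tr$latent_response, tr$response_effect) +
        matrix(tr$cbt_effect, length(tr$patient_ids), length(tr$gene_ids),
               byrow = TRUE)
      idx <- tr$cbt_effect != 0 | tr$response_effect != 0
      (rp$delta[, idx] - expected[, idx])
    }))
    expect_lt(abs(mean(bias)), 0.05)
  })
})

test_that("delta clustering recovers a planted two-group structure", {
  withr::with_seed(207, {
    n_gene <- 30
    up <- matrix(rnorm(10 * n_gene, mean = 2, sd = 0.3), 10, n_gene)
    down <- matrix(rnorm(8 * n_gene, mean = -2, sd = 0.3), 8, n_gene)
    delta <- rbind(up, down)
    dimnames(delta) <- list(paste0("p", 1:18), paste0("g", 1:n_gene))
    cl <- cluster_deltas(delta, k = 2)
    grp <- cl$patient_cluster
    expect_length(unique(grp[1:10]), 1)
    expect_length(unique(grp[11:18]), 1)
    expect_false(grp[1] == grp[18])
    # shuffling patients yields the same partition
    perm <- sample(18)
    cl2 <- cluster_deltas(delta[perm, ], k = 2)
    agree <- outer(cl$patient_cluster[rownames(delta)],
                   cl$patient_cluster[rownames(delta)], "==") ==
      outer(cl2$patient_cluster[rownames(delta)],
            cl2$patient_cluster[rownames(delta)], "==")
    expect_true(all(agree))
    # z-scaling makes clustering invariant to per-gene affine maps
    delta2 <- sweep(sweep(delta, 2, runif(n_gene, 0.5, 4), `*`),
                    2, rnorm(n_gene, 0, 5), `+`)
    cl3 <- cluster_deltas(delta2, k = 2)
    expect_identical(cl$patient_cluster, cl3$patient_cluster)
    # single gene and zero-variance genes
    single <- cluster_deltas(delta, gene_subset = "g1")
    expect_identical(single$gene_order, "g1")
    delta3 <- cbind(delta, flat = 0)
    expect_warning(cluster_deltas(delta3), "zero-variance")
  })
})

test_that("the Pearson test matches its closed form", {
  r1 <- pearson_corr_test(1:3, c(2, 1, 3))
  expect_equal(r1$r, 0.5, tolerance = 1e-12)
  expect_equal(r1$p, 2 / 3, tolerance = 1e-10)
  expect_equal(pearson_corr_test(1:5, 1:5)$r, 1)
  expect_equal(pearson_corr_test(1:5, 1:5)$p, 0)
  expect_equal(pearson_corr_test(1:5, -(1:5))$r, -1)
  withr::with_seed(208, {
    x <- rnorm(20); y <- rnorm(20)
    mine <- pearson_corr_test(x, y)
    ref <- cor.test(x, y)
    expect_equal(mine$r, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
  })
  expect_error(pearson_corr_test(1:2, 2:3), "at least 3")
  expect_error(pearson_corr_test(rep(1, 5), 1:5), "degenerate")
})

test_that("residualising out the CTG effect barely moves response effects", {
  withr::with_seed(209, {
    cfg <- truth_config(n_genes = 800, n_cbt_genes = 80, n_ctg_genes = 80,
                        n_response_genes = 80, n_reversal_genes = 40,
                        libsize_scale = 1, seed = 209)
    sim <- generate_cohort(cfg)
    kept <- filter_low_counts(sim$counts, sim$samples$timepoint)
    expr <- estimate_precision_weights(sim$counts[kept, ],
                                       groups = sim$samples$timepoint)
    scores <- compound_response(oriented_deltas(sim$outcomes, sim$measures))
    rr <- residualized_response_effects(expr, sim$samples, scores)
    expect_gt(rr$pearson_r, 0.9)
    # pure-CTG genes have residualised response effects centred on zero
    tr <- sim$truth
    pure_ctg <- setdiff(tr$ctg_set, tr$reversal_set)
    v <- rr$coef_residualized[intersect(pure_ctg, names(rr$coef_residualized))]
    expect_lt(abs(mean(v, na.rm = TRUE)), 0.1)
    # degenerate scores propagate the stage-2 rank error
    zero <- scores
    zero$compound_response[] <- 0
    expect_error(residualized_response_effects(expr, sim$samples, zero),
                 "rank deficient")
  })
})
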