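make_sheet <- function(n, ctg = NULL) {
  data.frame(
    sample_id = paste0(rep(paste0("p", seq_len(n)), each = 2), "_",
                       c("T0", "T10M")),
    patient_id = rep(paste0("p", seq_len(n)), each = 2),
    timepoint = rep(c("T0", "T10M"), n),
    ctg_length = rep(ctg %||% rep(300L, n), each = 2)
  )
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("the three design builders encode the models", {
  ss <- make_sheet(3, ctg = c(400L, 150L, 820L))
  d_cbt <- build_design(ss, model = "CBT")
  expect_identical(colnames(d_cbt$X), c("intercept", "cbt"))
  expect_identical(d_cbt$X[, "cbt"], rep(c(0, 1), 3))

  d_ctg <- build_design(ss, model = "CTG")
  expect_identical(unname(d_ctg$X[1:2, "ctg"]), c(4, 4))   # per-100, both rows
  expect_identical(d_ctg$coef, 3L)

  scores <- data.frame(patient_id = paste0("p", 1:3),
                       compound_response = c(1.2, -0.5, 0.3))
  d_r <- build_design(ss, scores, model = "RESPONSE")
  expect_identical(unname(d_r$X[1:2, "response"]), c(0, 1.2))  # zero at baseline
  expect_true(all(d_r$X[ss$timepoint == "T0", "response"] == 0))

  # degenerate response scores collapse onto the CBT column space
  zero <- data.frame(patient_id = paste0("p", 1:3), compound_response = 0)
  expect_error(build_design(ss, zero, model = "RESPONSE"), "rank deficient")
  # missing score and unpaired patients are named
  expect_error(build_design(ss, scores[1:2, ], model = "RESPONSE"), "p3")
  expect_error(build_design(ss[-1, ], model = "CBT"), "p1")
})

test_that("balanced equal-weight fits reproduce the paired t-test exactly", {
  withr::with_seed(101, {
    for (i in 1:10) {
      n <- sample(5:20, 1)
      d <- make_paired(n)
      fit <- fit_lmm_reml(d$y, d$X, d$w, d$patient)
      or <- paired_t_oracle(d$y, d$cbt, n)
      expect_equal(unname(fit$beta[2]), or$beta, tolerance = 1e-10)
      expect_equal(unname(fit$se[2]), or$se, tolerance = 1e-10)
      expect_equal(unname(fit$df[2]), or$df, tolerance = 1e-8)
      expect_equal(unname(fit$p[2]), or$p, tolerance = 1e-10)
    }
  })
  # the 3-patient worked example: pre (10,10,10), post (11,12,13)
  y <- c(10, 11, 10, 12, 10, 13)
  fit <- fit_lmm_reml(y, cbind(1, rep(c(0, 1), 3)), rep(1, 6), rep(1:3, each = 2))
  expect_equal(unname(fit$beta[2]), 2)
  expect_equal(unname(fit$se[2]), 1 / sqrt(3), tolerance = 1e-9)
  expect_equal(unname(fit$t[2]), 3.4641, tolerance = 1e-4)
  expect_equal(unname(fit$df[2]), 2, tolerance = 1e-8)
  expect_equal(unname(fit$p[2]), 0.0742, tolerance = 1e-3)
})

test_that("weighted unbalanced fits match lmerTest", {
  skip_if_not_installed("lmerTest")
  withr::with_seed(102, {
    for (i in 1:5) {
      m <- sample(8:16, 1)
      grp <- rep(seq_len(m), each = 2)
      cbt <- rep(c(0, 1), m)
      x2 <- rnorm(m)[grp]
      w <- runif(2 * m, 0.3, 3)
      y <- 1 + 0.4 * cbt + 0.5 * x2 + rnorm(m, sd = 1)[grp] +
        rnorm(2 * m, sd = 0.6) / sqrt(w)
      X <- cbind(1, cbt = cbt, x2 = x2)
      fit <- fit_lmm_reml(y, X, w, grp)
      ref <- lmerTest::lmer(y ~ cbt + x2 + (1 | grp), weights = w, REML = TRUE)
      sm <- coef(summary(ref))
      expect_equal(unname(fit$beta), unname(sm[, "Estimate"]), tolerance = 1e-6)
      expect_equal(unname(fit$se), unname(sm[, "Std. Error"]), tolerance = 1e-6)
      expect_equal(unname(fit$df), unname(sm[, "df"]), tolerance = 1e-4)
      expect_equal(unname(fit$p), unname(sm[, "Pr(>|t|)"]), tolerance = 1e-6)
    }
  })
})

test_that("independent-error data hit the tau2 = 0 boundary and reduce to WLS", {
  withr::with_seed(103, {
    n_boundary <- 0
    for (i in 1:40) {
      m <- 8
      grp <- rep(seq_len(m), each = 2)
      cbt <- rep(c(0, 1), m)
      w <- runif(2 * m, 0.5, 2)
      y <- 1 + 0.3 * cbt + rnorm(2 * m) / sqrt(w)   # no patient effect
      X <- cbind(1, cbt)
      fit <- fit_lmm_reml(y, X, w, grp)
      if (fit$boundary) {
        n_boundary <- n_boundary + 1
        # weighted least squares closed form
        Winv <- diag(w)
        A <- solve(t(X) %*% Winv %*% X)
        beta <- A %*% t(X) %*% Winv %*% y
        r <- y - X %*% beta
        s2 <- drop(t(r) %*% Winv %*% r) / (2 * m - 2)
        expect_equal(unname(fit$beta), unname(drop(beta)), tolerance = 1e-8)
        expect_equal(unname(fit$se), unname(sqrt(diag(s2 * A))), tolerance = 1e-8)
        expect_equal(unname(fit$df), rep(2 * m - 2, 2))
        expect_equal(unname(fit$tau2), 0)
      }
    }
    # boundary hits are common when the truth has no patient variance
    expect_gt(n_boundary, 10)
  })
})

test_that("the REML optimum beats a dense theta grid", {
  withr::with_seed(104, {
    grid <- c(0, exp(seq(log(1e-4), log(1e4), length.out = 200)))
    for (i in 1:10) {
      m <- sample(4:10, 1)
      grp <- rep(seq_len(m), each = 2)
      cbt <- rep(c(0, 1), m)
      w <- runif(2 * m, 0.3, 3)
      y <- rnorm(m, sd = runif(1, 0, 2))[grp] + 0.5 * cbt +
        rnorm(2 * m, sd = 0.7) / sqrt(w)
      X <- cbind(1, cbt)
      fit <- fit_lmm_reml(y, X, w, grp)
      ll <- dmrev:::lmm_profile_loglik_cpp(y, w, X, as.integer(grp) - 1L, grid)
      expect_gte(fit$reml_loglik, max(ll, na.rm = TRUE) - 1e-6)
    }
  })
})

test_that("fits are scale-equivariant", {
  withr::with_seed(105, {
    d <- make_paired(9)
    f1 <- fit_lmm_reml(d$y, d$X, d$w, d$patient)
    cc <- 3.7
    f2 <- fit_lmm_reml(cc * d$y, d$X, d$w, d$patient)
    expect_equal(f2$beta, cc * f1$beta, tolerance = 1e-8)
    expect_equal(f2$sigma2, cc^2 * f1$sigma2, tolerance = 1e-8)
    expect_equal(f2$tau2, cc^2 * f1$tau2, tolerance = 1e-6)
    expect_equal(f2$t, f1$t, tolerance = 1e-8)
    expect_equal(f2$df, f1$df, tolerance = 1e-6)
    expect_equal(f2$p, f1$p, tolerance = 1e-8)
  })
})

test_that("half-weight duplication is handled as precision weighting", {
  # splitting an observation into two half-weight copies keeps every
  # quadratic form intact; only the residual-df count shifts, exactly as in
  # the reference mixed-model implementation, so the fit moves by O(1/n)
  skip_if_not_installed("lmerTest")
  withr::with_seed(106, {
    m <- 10
    grp <- rep(seq_len(m), each = 2)
    cbt <- rep(c(0, 1), m)
    w <- runif(2 * m, 0.5, 2)
    y <- 1 + 0.5 * cbt + rnorm(m)[grp] + rnorm(2 * m) / sqrt(w)
    X <- cbind(1, cbt)
    y2 <- c(y, y[1]); w2 <- c(w, w[1] / 2); w2[1] <- w[1] / 2
    X2 <- rbind(X, X[1, ]); g2 <- c(grp, grp[1])
    f1 <- fit_lmm_reml(y, X, w, grp)
    f2 <- fit_lmm_reml(y2, X2, w2, g2)
    expect_equal(unname(f2$beta), unname(f1$beta), tolerance = 0.05)
    # and the duplicated fit still matches the reference implementation
    ref <- lmerTest::lmer(y2 ~ 0 + X2 + (1 | g2), weights = w2, REML = TRUE)
    expect_equal(unname(f2$beta), unname(lme4::fixef(ref)), tolerance = 1e-6)
    expect_equal(unname(f2$se), unname(coef(summary(ref))[, "Std. Error"]),
                 tolerance = 1e-6)
  })
})

test_that("Satterthwaite df interpolate between the paired and OLS limits", {
  # strong patient variance: df equals n_patients - 1
  withr::with_seed(107, {
    d <- make_paired(12, tau_sd = 3, sigma = 0.4)
    fit <- fit_lmm_reml(d$y, d$X, d$w, d$patient)
    expect_equal(unname(fit$df[2]), 11, tolerance = 1e-6)
    st <- satterthwaite_test(fit, "cbt")
    expect_identical(st$df, unname(fit$df[2]))
    expect_equal(st$p, 2 * pt(-abs(st$t), st$df), tolerance = 1e-12)
  })
  # p decreases monotonically in |t| at fixed df
  ts <- seq(0.1, 5, by = 0.3)
  ps <- 2 * pt(-ts, 7)
  expect_true(all(diff(ps) < 0))
})

test_that("fit_all_genes is per-gene independent with correct fold changes", {
  withr::with_seed(108, {
    sim <- generate_cohort(small_cohort_config(seed = 108))
    kept <- filter_low_counts(sim$counts, sim$samples$timepoint)
    expr <- estimate_precision_weights(sim$counts[kept, ],
                                       groups = sim$samples$timepoint)
    res <- fit_all_genes(expr, sim$samples, model = "CBT")
    expect_identical(res$gene_id, rownames(expr$logcpm))
    expect_equal(res$fold_change, 2^res$coef, tolerance = 1e-12)
    # permuting gene order permutes results identically
    perm <- sample(nrow(expr$logcpm))
    expr_p <- list(logcpm = expr$logcpm[perm, ], weights = expr$weights[perm, ])
    res_p <- fit_all_genes(expr_p, sim$samples, model = "CBT")
    expect_equal(res_p$coef, res$coef[perm], tolerance = 1e-12)
    expect_equal(res_p$p, res$p[perm], tolerance = 1e-12)
  })
  # the published CBT fold-change band maps back to log2 coefficients
  expect_equal(2^log2(0.64), 0.64, tolerance = 1e-12)
  expect_equal(2^1, 2)
})

test_that("planted therapy effects are recovered without bias", {
  withr::with_seed(109, {
    cfg <- truth_config(n_genes = 1500, n_cbt_genes = 200, n_ctg_genes = 0,
                        n_response_genes = 0, n_reversal_genes = 0,
                        libsize_scale = 1, seed = 109)
    sim <- generate_cohort(cfg)
    kept <- filter_low_counts(sim$counts, sim$samples$timepoint)
    expr <- estimate_precision_weights(sim$counts[kept, ],
                                       groups = sim$samples$timepoint)
    res <- fit_all_genes(expr, sim$samples, model = "CBT")
    tr <- sim$truth
    planted <- intersect(tr$cbt_set, res$gene_id)
    est <- res$coef[match(planted, res$gene_id)]
    truth <- tr$cbt_effect[match(planted, tr$gene_ids)]
    expect_gt(length(planted), 150)
    expect_lt(abs(mean(est - truth)), 0.05)
  })
})

test_that("invalid model inputs are rejected", {
  d <- make_paired(5)
  expect_error(fit_lmm_reml(d$y, cbind(d$X, d$X[, 2]), d$w, d$patient),
               "rank deficient")
  expect_error(fit_lmm_reml(c(d$y[-1], NA), d$X, d$w, d$patient), "non-finite")
  expect_error(fit_lmm_reml(d$y, d$X, -d$w, d$patient), "positive")
  ss <- make_sheet(4)
  expr <- list(logcpm = matrix(0, 2, 8, dimnames = list(c("a", "b"), paste0("x", 1:8))),
               weights = matrix(1, 2, 8))
  expect_error(fit_all_genes(expr, ss, model = "CBT"), "misaligned")
})
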