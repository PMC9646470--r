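# shared fixtures, all generated in code

# balanced paired dataset with strong patient-level variance (keeps the REML
# optimum interior, where the paired t-test equivalence holds exactly)
make_paired <- function(n_patients, beta_cbt = 0.7, tau_sd = 2, sigma = 0.5) {
  patient <- rep(seq_len(n_patients), each = 2)
  cbt <- rep(c(0, 1), n_patients)
  y <- 1 + stats::rnorm(n_patients, sd = tau_sd)[patient] + beta_cbt * cbt +
    stats::rnorm(2 * n_patients, sd = sigma)
  list(y = y, X = cbind(intercept = 1, cbt = cbt), cbt = cbt,
       patient = patient, w = rep(1, 2 * n_patients))
}

paired_t_oracle <- function(y, cbt, n_patients) {
  d <- y[cbt == 1] - y[cbt == 0]
  se <- stats::sd(d) / sqrt(n_patients)
  t <- mean(d) / se
  list(beta = mean(d), se = se, t = t, df = n_patients - 1,
       p = 2 * stats::pt(-abs(t), n_patients - 1))
}

# tiny default-structure cohort for quick unit tests
small_cohort_config <- function(seed = 1, ...) {
  truth_config(n_genes = 400, n_cbt_genes = 40, n_ctg_genes = 40,
               n_response_genes = 30, n_reversal_genes = 20,
               libsize_scale = 1, seed = seed, ...)
}

# independent brute-force BH step-up (oracle for bh_fdr)
bh_brute <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    rank_i <- which(ord == i)
    cand <- p[ord[rank_i:m]] * m / seq(rank_i, m)
    q[i] <- min(1, min(cand))
  }
  q
}

# exhaustive-enumeration two-sample Wilcoxon p (oracle, no ties assumed)
wilcox_enum_oracle <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled)
  m <- length(x)
  obs <- sum(rank(pooled)[seq_len(m)])
  combs <- utils::combn(n, m)
  stats_all <- apply(combs, 2, function(ix) sum(rank(pooled)[ix]))
  mu <- m * (n + 1) / 2
  mean(abs(stats_all - mu) >= abs(obs - mu) - 1e-12)
}
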