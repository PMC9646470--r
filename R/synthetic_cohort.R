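#' Configuration for the synthetic paired-cohort generator
#'
#' Defines the study conditions emulated by [generate_cohort()]: a paired
#' (baseline / 10-month) blood RNA-seq cohort of DM1 patients with
#' negative-binomial counts, per-patient random intercepts, CTG-repeat-length
#' dependent gene effects, response-dependent reversal effects, and a
#' multi-instrument clinical outcome panel driven by a latent therapy
#' response.
#'
#' Effect sizes are magnitudes on the log2 scale; each planted gene receives
#' a random sign, except reversal genes, whose response effect sign is forced
#' opposite to their CTG effect sign. The CTG effect is parameterised per 100
#' repeats, matching how coefficients are reported downstream.
#'
#' @param n_patients Number of patients (two samples each).
#' @param n_genes Number of genes in the expressed background.
#' @param n_cbt_genes,n_ctg_genes,n_response_genes Sizes of the planted
#'   effect sets (therapy/timepoint effect, CTG-length effect, compound
#'   response effect).
#' @param n_reversal_genes Number of genes planted in *both* the CTG and the
#'   response set with opposing signs; must not exceed either set size.
#' @param ctg_range Range (inclusive) of modal CTG-repeat lengths; lengths
#'   are drawn log-uniformly. The lower bound must be >= 50, the expanded
#'   disease-allele threshold.
#' @param cbt_log2fc_range Magnitude range of timepoint (therapy) effects,
#'   log2 scale.
#' @param ctg_log2fc_per100_range Magnitude range of CTG effects, log2 per
#'   100 repeats.
#' @param response_log2fc_range Magnitude range of response effects, log2
#'   per unit latent response.
#' @param latent_response_range Range of the uniform latent therapy response.
#' @param baseline_log2cpm_mean,baseline_log2cpm_sd Normal distribution of
#'   baseline gene abundance, log2 CPM scale.
#' @param libsize_log_mean,libsize_log_sd Log-normal library-size parameters
#'   (natural-log scale) before scaling.
#' @param libsize_scale Multiplier applied to library sizes; the default
#'   1/100 gives desk-scale libraries, 1 gives full sequencing depth.
#' @param nb_dispersion_range Range of per-gene NB dispersions (variance =
#'   mean + phi * mean^2), drawn log-uniformly.
#' @param random_intercept_sd_range Range of per-gene patient random
#'   intercept standard deviations (log2 scale), drawn uniformly.
#' @param n_measures Number of outcome instruments, including the single
#'   pure-noise control instrument that is always emitted.
#' @param measure_loading_range Range of instrument loadings on the latent
#'   response.
#' @param measure_noise_sd Instrument noise standard deviation.
#' @param n_lower_is_better Number of instruments stored in
#'   lower-is-better units (orientation -1).
#' @param seed Integer seed; together with the configuration it fully
#'   determines all generator output.
#'
#' @return A list of class `truth_config`.
#' @export
truth_config <- function(n_patients = 27,
                         n_genes = 10000,
                         n_cbt_genes = 500,
                         n_ctg_genes = 600,
                         n_response_genes = 300,
                         n_reversal_genes = 100,
                         ctg_range = c(120, 900),
                         cbt_log2fc_range = c(0.2, 1.2),
                         ctg_log2fc_per100_range = c(0.1, 0.3),
                         response_log2fc_range = c(0.15, 0.5),
                         latent_response_range = c(-1.5, 2.75),
                         baseline_log2cpm_mean = 5,
                         baseline_log2cpm_sd = 2,
                         libsize_log_mean = log(3e7),
                         libsize_log_sd = 0.3,
                         libsize_scale = 1 / 100,
                         nb_dispersion_range = c(0.01, 0.3),
                         random_intercept_sd_range = c(0.1, 0.5),
                         n_measures = 12,
                         measure_loading_range = c(0.5, 1.5),
                         measure_noise_sd = 0.5,
                         n_lower_is_better = 4,
                         seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "truth_config"
  validate_truth_config(cfg)
  cfg
}

validate_truth_config <- function(cfg) {
  stopifnot(cfg$n_patients >= 2, cfg$n_genes >= 1)
  sizes <- c(cfg$n_cbt_genes, cfg$n_ctg_genes, cfg$n_response_genes)
  if (any(sizes > cfg$n_genes)) {
    stop("configuration error: an effect set is larger than n_genes", call. = FALSE)
  }
  if (cfg$n_ctg_genes + cfg$n_response_genes - cfg$n_reversal_genes +
      cfg$n_cbt_genes > cfg$n_genes) {
    stop("configuration error: effect sets do not fit into n_genes", call. = FALSE)
  }
  if (cfg$n_reversal_genes > min(cfg$n_ctg_genes, cfg$n_response_genes)) {
    stop("configuration error: n_reversal_genes exceeds a parent set", call. = FALSE)
  }
  if (cfg$ctg_range[1] < 50) {
    stop("configuration error: ctg_range must start at >= 50 repeats", call. = FALSE)
  }
  if (any(cfg$nb_dispersion_range <= 0)) {
    stop("configuration error: NB dispersions must be strictly positive", call. = FALSE)
  }
  if (any(cfg$random_intercept_sd_range < 0)) {
    stop("configuration error: random-intercept sd must be >= 0", call. = FALSE)
  }
  if (cfg$n_measures < 2) {
    stop("configuration error: need at least one instrument beyond the control",
         call. = FALSE)
  }
  if (cfg$n_lower_is_better >= cfg$n_measures) {
    stop("configuration error: n_lower_is_better must leave room for +1 measures",
         call. = FALSE)
  }
  invisible(cfg)
}

runif_range <- function(n, range) stats::runif(n, range[1], range[2])

log_uniform <- function(n, range) {
  exp(stats::runif(n, log(range[1]), log(range[2])))
}

#' Generate a paired synthetic cohort with planted ground truth
#'
#' Draws, deterministically given `config$seed`: per-gene baselines,
#' dispersions, random-intercept sds and planted effects; per-patient CTG
#' lengths, latent responses and random intercepts; library sizes; NB counts
#' for both timepoints; and a clinical outcome panel whose oriented
#' changes equal `loading * latent_response + noise` (one flagged pure-noise
#' control instrument included).
#'
#' The expected log2-CPM of gene g in patient p at timepoint t is
#' `mu_g + u_gp + delta_g * I(t = T10M) + gamma_g * CTG_p / 100 +
#'  rho_g * r_p * I(t = T10M)`, converted to an NB mean via the sample's
#' library size.
#'
#' @param config A [truth_config()].
#' @return A list with elements `counts` (integer gene x sample matrix),
#'   `samples` (sample sheet: sample_id, patient_id, timepoint, ctg_length),
#'   `outcomes` (long outcome table), `measures` (orientation / control
#'   flags) and `truth` (a `cohort_truth` list holding every draw).
#' @export
generate_cohort <- function(config) {
  validate_truth_config(config)
  withr_seed <- get_seed_state()
  on.exit(restore_seed_state(withr_seed), add = TRUE)
  set.seed(config$seed)

  G <- config$n_genes
  P <- config$n_patients
  gene_ids <- sprintf("g%05d", seq_len(G))
  patient_ids <- sprintf("p%02d", seq_len(P))

  ## per-gene parameters
  mu <- stats::rnorm(G, config$baseline_log2cpm_mean, config$baseline_log2cpm_sd)
  phi <- log_uniform(G, config$nb_dispersion_range)
  tau <- runif_range(G, config$random_intercept_sd_range)

  ## disjoint effect sets; the CTG and response sets share exactly the
  ## reversal genes
  n_extra_ctg <- config$n_ctg_genes - config$n_reversal_genes
  n_extra_resp <- config$n_response_genes - config$n_reversal_genes
  picked <- sample.int(G, config$n_reversal_genes + n_extra_ctg + n_extra_resp +
                         config$n_cbt_genes)
  rev_set <- picked[seq_len(config$n_reversal_genes)]
  off <- config$n_reversal_genes
  ctg_only <- picked[seq_len(n_extra_ctg) + off]; off <- off + n_extra_ctg
  resp_only <- picked[seq_len(n_extra_resp) + off]; off <- off + n_extra_resp
  cbt_set <- picked[seq_len(config$n_cbt_genes) + off]
  ctg_set <- c(rev_set, ctg_only)
  resp_set <- c(rev_set, resp_only)

  delta <- gamma <- rho <- numeric(G)
  delta[cbt_set] <- sample(c(-1, 1), length(cbt_set), replace = TRUE) *
    runif_range(length(cbt_set), config$cbt_log2fc_range)
  gamma[ctg_set] <- sample(c(-1, 1), length(ctg_set), replace = TRUE) *
    runif_range(length(ctg_set), config$ctg_log2fc_per100_range)
  rho[resp_only] <- sample(c(-1, 1), length(resp_only), replace = TRUE) *
    runif_range(length(resp_only), config$response_log2fc_range)
  rho[rev_set] <- -sign(gamma[rev_set]) *
    runif_range(length(rev_set), config$response_log2fc_range)

  ## per-patient parameters
  ctg_len <- round(log_uniform(P, config$ctg_range))
  latent_response <- runif_range(P, config$latent_response_range)
  u <- matrix(stats::rnorm(G * P), G, P) * tau   # per-(gene, patient) intercepts
  dimnames(u) <- list(gene_ids, patient_ids)

  ## samples and library sizes
  samples <- data.frame(
    sample_id = paste0(rep(patient_ids, each = 2), "_", c("T0", "T10M")),
    patient_id = rep(patient_ids, each = 2),
    timepoint = rep(c("T0", "T10M"), P),
    ctg_length = rep(ctg_len, each = 2),
    stringsAsFactors = FALSE
  )
  S <- nrow(samples)
  lib <- stats::rlnorm(S, config$libsize_log_mean, config$libsize_log_sd) *
    config$libsize_scale

  ## expected log2 CPM per gene x sample
  after <- as.numeric(samples$timepoint == "T10M")
  pat_idx <- match(samples$patient_id, patient_ids)
  eta <- mu +
    u[, pat_idx, drop = FALSE] +
    outer(delta, after) +
    outer(gamma, ctg_len[pat_idx] / 100) +
    outer(rho, latent_response[pat_idx] * after)
  mu_count <- sweep(2^eta / 1e6, 2, lib, `*`)
  counts <- matrix(stats::rnbinom(G * S, mu = mu_count, size = rep(1 / phi, S)),
                   G, S, dimnames = list(gene_ids, samples$sample_id))

  ## outcome panel: oriented deltas driven by the latent response
  M <- config$n_measures
  measure_ids <- sprintf("m%02d", seq_len(M))
  control_id <- measure_ids[M]
  loading <- runif_range(M, config$measure_loading_range)
  loading[M] <- 0                                     # pure-noise control
  orientation <- rep(1L, M)
  orientation[seq_len(config$n_lower_is_better)] <- -1L
  oriented_delta <- outer(latent_response, loading) +
    matrix(stats::rnorm(P * M, sd = config$measure_noise_sd), P, M)
  baseline_value <- matrix(stats::rnorm(P * M, mean = 50, sd = 10), P, M)
  raw_delta <- sweep(oriented_delta, 2, as.numeric(orientation), `*`)

  outcomes <- data.frame(
    patient_id = rep(patient_ids, times = 2 * M),
    measure_id = rep(rep(measure_ids, each = P), 2),
    timepoint = rep(c("T0", "T10M"), each = P * M),
    value = c(as.vector(baseline_value), as.vector(baseline_value + raw_delta)),
    stringsAsFactors = FALSE
  )
  measures <- data.frame(
    measure_id = measure_ids,
    orientation = orientation,
    is_control = as.integer(measure_ids == control_id),
    stringsAsFactors = FALSE
  )

  truth <- list(
    gene_ids = gene_ids, patient_ids = patient_ids,
    baseline_log2_mean = mu, cbt_effect = delta, ctg_effect_per100 = gamma,
    response_effect = rho, dispersion = phi, random_intercept_sd = tau,
    cbt_set = sort(gene_ids[cbt_set]), ctg_set = sort(gene_ids[ctg_set]),
    response_set = sort(gene_ids[resp_set]), reversal_set = sort(gene_ids[rev_set]),
    ctg_length = stats::setNames(ctg_len, patient_ids),
    latent_response = stats::setNames(latent_response, patient_ids),
    random_intercepts = u, library_sizes = stats::setNames(lib, samples$sample_id),
    measure_loading = stats::setNames(loading, measure_ids),
    ctg_range = config$ctg_range,
    config = config
  )
  class(truth) <- "cohort_truth"

  list(counts = counts, samples = samples, outcomes = outcomes,
       measures = measures, truth = truth)
}

#' Simulate an independent external case/control cohort from the same truth
#'
#' Emulates a published unpaired DM1 vs control comparison on normalized
#' log-scale expression: cases carry the truth's CTG effects at freshly drawn
#' case-like repeat lengths, controls sit at baseline. Draws are independent
#' of the paired cohort (own seed).
#'
#' Per-sample noise sd combines the truth's biological components,
#' `sqrt(tau_g^2 + phi_g / log(2)^2)`, i.e. the patient-level spread plus the
#' NB overdispersion mapped to the log2 scale.
#'
#' @param truth A `cohort_truth` from [generate_cohort()].
#' @param n_cases,n_controls Group sizes (both >= 2).
#' @param seed Integer seed.
#' @return A list of class `external_cohort` with `logexpr` (gene x sample)
#'   and `label` (`"case"`/`"control"` per sample).
#' @export
generate_external_cohort <- function(truth, n_cases = 20, n_controls = 20,
                                     seed = 1L) {
  stopifnot(inherits(truth, "cohort_truth"))
  if (n_cases < 2 || n_controls < 2) {
    stop("both groups need >= 2 samples (two-sample Wilcoxon undefined otherwise)",
         call. = FALSE)
  }
  saved <- get_seed_state()
  on.exit(restore_seed_state(saved), add = TRUE)
  set.seed(seed)

  G <- length(truth$gene_ids)
  bio_sd <- sqrt(truth$random_intercept_sd^2 + truth$dispersion / log(2)^2)
  ctg_cases <- log_uniform(n_cases, truth$ctg_range)
  case_mat <- truth$baseline_log2_mean +
    outer(truth$ctg_effect_per100, ctg_cases / 100) +
    matrix(stats::rnorm(G * n_cases), G, n_cases) * bio_sd
  ctrl_mat <- truth$baseline_log2_mean +
    matrix(stats::rnorm(G * n_controls), G, n_controls) * bio_sd
  logexpr <- cbind(case_mat, ctrl_mat)
  dimnames(logexpr) <- list(truth$gene_ids,
                            c(sprintf("case%02d", seq_len(n_cases)),
                              sprintf("ctrl%02d", seq_len(n_controls))))
  out <- list(logexpr = logexpr,
              label = rep(c("case", "control"), c(n_cases, n_controls)),
              ctg_cases = ctg_cases)
  class(out) <- "external_cohort"
  out
}

#' Emulate the trial's stratified patient-sampling procedure
#'
#' Applies, in order: configured completeness filters, exclusion of variant
#' (interrupted) repeats, the within-one-IQR-of-the-mean window on each
#' baseline variable, then stratified random selection by site with at most
#' `max_per_delta` candidates sharing the same response delta.
#'
#' @param candidates Data frame with columns `patient_id`, `site`, the
#'   baseline variable columns named in `baseline_vars`, the response-delta
#'   column named in `delta_var`, and optionally a logical/0-1
#'   `variant_repeat` column.
#' @param config List of sampling rules: `baseline_vars` (default
#'   `c("dm1_activ_c", "six_mwt", "ctg_length")`), `delta_var` (default
#'   `"delta_dm1_activ_c"`), `complete_vars` (columns that must be
#'   non-missing; default the baseline + delta columns), `n_target` (default
#'   30) and `max_per_delta` (default 2).
#' @param seed Integer seed for the stratified random draw.
#' @return List with `selected` (patient ids) and `audit` (data frame of
#'   counts surviving each filter step).
#' @export
sample_patients <- function(candidates, config = list(), seed = 1L) {
  defaults <- list(
    baseline_vars = c("dm1_activ_c", "six_mwt", "ctg_length"),
    delta_var = "delta_dm1_activ_c",
    complete_vars = NULL,
    n_target = 30L,
    max_per_delta = 2L
  )
  config <- utils::modifyList(defaults, config)
  if (is.null(config$complete_vars)) {
    config$complete_vars <- c(config$baseline_vars, config$delta_var)
  }
  need <- unique(c("patient_id", "site", config$baseline_vars, config$delta_var))
  miss <- setdiff(need, names(candidates))
  if (length(miss)) {
    stop("candidate table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }

  audit <- data.frame(step = "input", n = nrow(candidates),
                      stringsAsFactors = FALSE)
  keep <- candidates

  ok <- stats::complete.cases(keep[, config$complete_vars, drop = FALSE])
  keep <- keep[ok, , drop = FALSE]
  audit <- rbind(audit, data.frame(step = "complete", n = nrow(keep)))

  if ("variant_repeat" %in% names(keep)) {
    keep <- keep[!as.logical(keep$variant_repeat), , drop = FALSE]
  }
  audit <- rbind(audit, data.frame(step = "no_variant_repeat", n = nrow(keep)))

  for (v in config$baseline_vars) {
    if (nrow(keep) == 0) break
    x <- keep[[v]]
    ctr <- mean(x)
    iqr <- stats::IQR(x)
    keep <- keep[x >= ctr - iqr & x <= ctr + iqr, , drop = FALSE]
  }
  audit <- rbind(audit, data.frame(step = "iqr_window", n = nrow(keep)))

  if (nrow(keep) == 0) stop("no eligible patients after filters", call. = FALSE)

  saved <- get_seed_state()
  on.exit(restore_seed_state(saved), add = TRUE)
  set.seed(seed)

  ## round-robin over sites in random within-site order, capping identical
  ## response deltas at max_per_delta
  sites <- split(seq_len(nrow(keep)), keep$site)
  sites <- lapply(sites, function(ix) ix[sample.int(length(ix))])
  delta_used <- integer(0)
  selected <- character(0)
  progress <- TRUE
  while (length(selected) < config$n_target && progress) {
    progress <- FALSE
    for (s in names(sites)) {
      if (length(selected) >= config$n_target) break
      while (length(sites[[s]])) {
        i <- sites[[s]][1]
        sites[[s]] <- sites[[s]][-1]
        key <- as.character(keep[[config$delta_var]][i])
        cnt <- if (key %in% names(delta_used)) delta_used[[key]] else 0L
        if (cnt < config$max_per_delta) {
          delta_used[key] <- cnt + 1L
          selected <- c(selected, keep$patient_id[i])
          progress <- TRUE
          break
        }
      }
    }
  }
  audit <- rbind(audit, data.frame(step = "selected", n = length(selected)))
  list(selected = selected, audit = audit)
}

## RNG bookkeeping so seeded generators do not disturb the caller's stream
get_seed_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_seed_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}
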