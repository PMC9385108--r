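#' Simulation configuration
#'
#' Bundles every knob of the synthetic cohort generator. Defaults emulate a
#' modest single-institution cancer cohort: ~439 subjects genotyped on a
#' panel of common SNPs (MAF 0.05-0.5, Hardy-Weinberg consistent, no missing
#' calls), block linkage disequilibrium, right-censored survival over an
#' ~11-year administrative follow-up window with sparse random dropout, and
#' the standard clinical covariates (age at diagnosis, stage, MSI status,
#' tumor location, chemotherapy, radiotherapy).
#'
#' @param n_subjects number of subjects.
#' @param n_snps number of SNPs on the panel.
#' @param maf_range range the per-SNP target minor allele frequency is drawn
#'   from; must lie within \[0.05, 0.5\].
#' @param ld_block_sizes integer vector; the first `sum(ld_block_sizes)` SNPs
#'   are grouped into LD blocks of these sizes, the remainder are
#'   independent. `NULL` for a fully independent panel.
#' @param ld_block_r2 target pairwise dosage r-squared within each block
#'   (recycled across blocks). A target of 1 makes the block's markers exact
#'   copies (they then share one MAF).
#' @param age_mean,age_sd,age_range age at diagnosis: truncated normal, years.
#' @param stage_probs probabilities of tumor stages 1-4 (must sum to 1).
#' @param msi_rate,location_rate,chemo_rate,radio_rate Bernoulli rates of the
#'   binary covariates (MSI-high, rectal location, adjuvant chemotherapy,
#'   radiotherapy).
#' @param gamma named log-hazard coefficients of the covariates in the
#'   generative proportional-hazards model (applied to mean-centered values).
#' @param weibull_scale,weibull_shape baseline Weibull hazard
#'   h0(t) = scale * shape * t^(shape-1).
#' @param horizon administrative censoring horizon in years.
#' @param dropout_rate exponential random-dropout rate per year (0 = none).
#' @param seed integer seed; mandatory, all `simulate_*` output is
#'   bit-reproducible given the config.
#' @return A list of class `mdr_sim_config`.
#' @export
sim_config <- function(n_subjects = 439,
                       n_snps = 100,
                       maf_range = c(0.05, 0.5),
                       ld_block_sizes = NULL,
                       ld_block_r2 = 0.9,
                       age_mean = 61, age_sd = 10, age_range = c(20, 75),
                       stage_probs = c(0.15, 0.35, 0.35, 0.15),
                       msi_rate = 0.12,
                       location_rate = 0.5,
                       chemo_rate = 0.55,
                       radio_rate = 0.25,
                       gamma = c(age = 0.02, stage = 0.35, msi = -0.4,
                                 location = 0.15, chemo = -0.25, radio = 0.1),
                       weibull_scale = 0.05,
                       weibull_shape = 1.2,
                       horizon = 11,
                       dropout_rate = 0.03,
                       seed) {
  if (missing(seed)) abort("seed is mandatory")
  seed <- as.integer(seed)
  if (is.na(seed) || seed < 0L || seed > .Machine$integer.max - 10L) {
    abort("seed must be a non-negative integer below 2^31 - 10")
  }
  if (n_subjects < 1) abort("n_subjects must be >= 1")
  if (n_snps < 1) abort("n_snps must be >= 1")
  if (maf_range[1] < 0.05 - 1e-12 || maf_range[2] > 0.5 + 1e-12 ||
      maf_range[1] > maf_range[2]) {
    abort("maf_range must lie within [0.05, 0.5]")
  }
  if (!is.null(ld_block_sizes)) {
    if (any(ld_block_sizes < 2)) abort("LD blocks need at least 2 SNPs")
    if (sum(ld_block_sizes) > n_snps) {
      abort("LD blocks larger than the panel: sum(ld_block_sizes) > n_snps")
    }
    ld_block_r2 <- rep_len(ld_block_r2, length(ld_block_sizes))
    if (any(ld_block_r2 < 0 | ld_block_r2 > 1)) abort("ld_block_r2 must be in [0, 1]")
  }
  if (abs(sum(stage_probs) - 1) > 1e-8 || any(stage_probs < 0) ||
      length(stage_probs) != 4) {
    abort("stage_probs must be 4 non-negative probabilities summing to 1")
  }
  rates <- c(msi_rate, location_rate, chemo_rate, radio_rate)
  if (any(rates < 0 | rates > 1)) abort("covariate rates must be in [0, 1]")
  if (weibull_scale <= 0 || weibull_shape <= 0) abort("Weibull parameters must be > 0")
  if (horizon < 0 || dropout_rate < 0) abort("censoring parameters must be >= 0")
  structure(list(
    n_subjects = as.integer(n_subjects), n_snps = as.integer(n_snps),
    maf_range = maf_range, ld_block_sizes = ld_block_sizes,
    ld_block_r2 = ld_block_r2, age_mean = age_mean, age_sd = age_sd,
    age_range = age_range, stage_probs = stage_probs, msi_rate = msi_rate,
    location_rate = location_rate, chemo_rate = chemo_rate,
    radio_rate = radio_rate, gamma = gamma, weibull_scale = weibull_scale,
    weibull_shape = weibull_shape, horizon = horizon,
    dropout_rate = dropout_rate, seed = seed
  ), class = "mdr_sim_config")
}

#' Covariate names used throughout the package
#' @return Character vector of the six clinical covariate column names.
#' @export
covariate_names <- function() c("age", "stage", "msi", "location", "chemo", "radio")

# Latent-Gaussian correlation giving a target allele-level correlation r for
# two thresholded standard normals at minor allele frequencies p1, p2.
calibrate_latent_rho <- function(r, p1, p2) {
  if (r <= 0) return(0)
  if (r >= 1 - 1e-12) return(1)
  q1 <- qnorm(p1); q2 <- qnorm(p2)
  f <- function(rho) {
    p11 <- mvtnorm::pmvnorm(upper = c(q1, q2),
                            corr = matrix(c(1, rho, rho, 1), 2))[1]
    (p11 - p1 * p2) / sqrt(p1 * (1 - p1) * p2 * (1 - p2)) - r
  }
  stats::uniroot(f, c(0, 1 - 1e-9), tol = 1e-9)$root
}

#' Simulate a genotype matrix
#'
#' Draws each SNP under Hardy-Weinberg equilibrium at its target MAF: two
#' independent latent haplotypes per subject, an allele being the minor one
#' when its latent Gaussian falls below the MAF quantile. Within an LD block
#' the latent Gaussians are equicorrelated (Gaussian copula), with the latent
#' correlation calibrated so the empirical pairwise dosage r-squared
#' approximates the block target; blocks and the remaining SNPs are mutually
#' independent. A block target of exactly 1 yields exact-copy markers.
#'
#' @param config an [sim_config()] object.
#' @return An [mdr_geno] object; `snp_info` records gene labels, allele
#'   letters and the target MAF of each marker.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "mdr_sim_config"))
  set.seed(config$seed)
  n <- config$n_subjects; m <- config$n_snps
  maf <- runif(m, config$maf_range[1], config$maf_range[2])

  block_of <- rep(0L, m)
  if (!is.null(config$ld_block_sizes)) {
    block_of[seq_len(sum(config$ld_block_sizes))] <-
      rep(seq_along(config$ld_block_sizes), config$ld_block_sizes)
  }
  # markers of one LD block share a target MAF: unequal frequencies cap the
  # attainable dosage r^2 (r^2 = 1 strictly requires equality), and tightly
  # linked markers in strong LD carry near-identical frequencies anyway
  if (!is.null(config$ld_block_sizes)) {
    for (b in seq_along(config$ld_block_sizes)) {
      maf[block_of == b] <- maf[which(block_of == b)[1]]
    }
  }

  dosage <- matrix(0L, n, m)
  draw_block <- function(cols, rho) {
    s <- length(cols)
    q <- qnorm(maf[cols])
    hap <- matrix(0L, n, s)
    for (h in 1:2) {
      z <- matrix(rnorm(n * s), n, s)
      if (s > 1 && rho > 0) {
        if (rho >= 1 - 1e-12) {
          z <- z[, rep(1L, s), drop = FALSE]
        } else {
          sigma <- matrix(rho, s, s); diag(sigma) <- 1
          z <- z %*% chol(sigma)
        }
      }
      hap <- hap + (sweep(z, 2, q, `<`)) * 1L
    }
    hap
  }
  if (any(block_of > 0L)) {
    for (b in seq_along(config$ld_block_sizes)) {
      cols <- which(block_of == b)
      r2 <- config$ld_block_r2[b]
      rho <- if (r2 >= 1 - 1e-12) 1 else
        calibrate_latent_rho(sqrt(r2), maf[cols[1]], maf[cols[1]])
      dosage[, cols] <- draw_block(cols, rho)
    }
  }
  indep <- which(block_of == 0L)
  if (length(indep)) dosage[, indep] <- draw_block(indep, 0)

  pairs <- t(combn(c("A", "C", "G", "T"), 2))
  pick <- pairs[sample.int(nrow(pairs), m, replace = TRUE), , drop = FALSE]
  flip <- sample(c(TRUE, FALSE), m, replace = TRUE)
  major <- ifelse(flip, pick[, 1], pick[, 2])
  minor <- ifelse(flip, pick[, 2], pick[, 1])
  gene <- ifelse(block_of > 0L,
                 sprintf("GENE%02d", block_of),
                 sprintf("GENE%02d", max(block_of) + 1L + (seq_len(m) - 1L) %/% 5L))
  mdr_geno(dosage,
           snp_info = tibble::tibble(
             snp_id = sprintf("rs%06d", seq_len(m)),
             gene = gene, major_allele = major, minor_allele = minor,
             target_maf = maf),
           subjects = sprintf("S%04d", seq_len(n)))
}

#' Simulate clinical covariates
#'
#' Age is truncated-normal; stage is categorical over 1-4; MSI status, tumor
#' location, chemotherapy and radiotherapy are Bernoulli. All rates come from
#' the config and draws are deterministic under its seed.
#'
#' @param config an [sim_config()] object.
#' @return A tibble with `subject_id` and the [covariate_names()] columns.
#' @export
simulate_covariates <- function(config) {
  stopifnot(inherits(config, "mdr_sim_config"))
  set.seed(config$seed + 1L)
  n <- config$n_subjects
  plo <- stats::pnorm(config$age_range[1], config$age_mean, config$age_sd)
  phi <- stats::pnorm(config$age_range[2], config$age_mean, config$age_sd)
  age <- qnorm(runif(n, plo, phi), config$age_mean, config$age_sd)
  tibble::tibble(
    subject_id = sprintf("S%04d", seq_len(n)),
    age = age,
    stage = sample(1:4, n, replace = TRUE, prob = config$stage_probs),
    msi = rbinom(n, 1, config$msi_rate),
    location = rbinom(n, 1, config$location_rate),
    chemo = rbinom(n, 1, config$chemo_rate),
    radio = rbinom(n, 1, config$radio_rate)
  )
}

#' Planted risk-effect presets
#'
#' Defines the ground-truth high-risk genotype cells used by the survival
#' generator. `dominant` marks minor-allele carriers (dosage 1 or 2) of one
#' SNP high-risk, `recessive` marks homozygous carriers (dosage 2). The
#' `xor2`/`xor3` presets mark cells with an odd number of heterozygous SNPs
#' high-risk; at MAF 0.5 the heterozygote indicator has frequency 1/2, so
#' these interactions carry no marginal dosage-risk correlation -- the pure
#' epistasis case MDR exists to detect.
#'
#' @param name one of `"dominant"`, `"recessive"`, `"xor2"`, `"xor3"`,
#'   `"custom"`.
#' @param snp_indices column indices of the involved SNPs (1 for
#'   dominant/recessive, 2 for xor2, 3 for xor3).
#' @param log_hr log hazard ratio of the high-risk cells; must be finite.
#' @param high_cells for `name = "custom"`, an integer matrix with one row
#'   per high-risk cell and one column per SNP (entries 0/1/2).
#' @return A list of class `mdr_effect` with elements `snp_indices`,
#'   `high_cells`, `log_hr`, `model_name`.
#' @export
planted_effect <- function(name = c("dominant", "recessive", "xor2", "xor3", "custom"),
                           snp_indices, log_hr = log(2), high_cells = NULL) {
  name <- match.arg(name)
  if (!is.finite(log_hr)) abort("log_hr must be finite")
  snp_indices <- as.integer(snp_indices)
  k_needed <- switch(name, dominant = 1L, recessive = 1L, xor2 = 2L, xor3 = 3L,
                     custom = length(snp_indices))
  if (length(snp_indices) != k_needed) {
    abort(sprintf("preset '%s' needs %d SNP index(es)", name, k_needed))
  }
  k <- length(snp_indices)
  all_cells <- as.matrix(expand.grid(rep(list(0:2), k)))
  colnames(all_cells) <- NULL
  cells <- switch(
    name,
    dominant  = matrix(c(1L, 2L), ncol = 1),
    recessive = matrix(2L, ncol = 1),
    xor2      = all_cells[rowSums(all_cells == 1L) %% 2L == 1L, , drop = FALSE],
    xor3      = all_cells[rowSums(all_cells == 1L) %% 2L == 1L, , drop = FALSE],
    custom    = {
      if (is.null(high_cells)) abort("custom preset needs high_cells")
      hc <- as.matrix(high_cells)
      if (ncol(hc) != k || !all(hc %in% 0:2)) {
        abort("high_cells must have one 0/1/2 column per SNP")
      }
      hc
    })
  storage.mode(cells) <- "integer"
  structure(list(snp_indices = snp_indices, high_cells = cells,
                 log_hr = log_hr, model_name = name),
            class = "mdr_effect")
}

# 1-based index of each subject's genotype cell among the 3^k cells of the
# SNPs in `cols` (first SNP varies fastest).
cell_index <- function(dosage, cols = seq_len(ncol(dosage))) {
  d <- dosage[, cols, drop = FALSE]
  idx <- rep(1L, nrow(d))
  mult <- 1L
  for (j in seq_len(ncol(d))) {
    idx <- idx + d[, j] * mult
    mult <- mult * 3L
  }
  idx
}

# TRUE for subjects whose genotype cell is in the effect's high-risk set.
effect_indicator <- function(effect, geno) {
  d <- geno_dosage(geno, allow_missing = FALSE)
  idx <- cell_index(d, effect$snp_indices)
  hi <- cell_index(effect$high_cells)
  idx %in% hi
}

#' Simulate right-censored survival times
#'
#' Event times follow a proportional-hazards Weibull model
#' `h(t) = scale * shape * t^(shape-1) * exp(log_hr * high + gamma' z)`,
#' where `high` indicates membership in the planted effect's high-risk cells
#' and `z` are the mean-centered covariates. Censoring is the minimum of the
#' administrative horizon and an exponential dropout time; the recorded time
#' is the earlier of event and censoring.
#'
#' @param geno an [mdr_geno] object.
#' @param covariates covariate tibble from [simulate_covariates()], row order
#'   matching `geno`.
#' @param effect an [planted_effect()] object, or `NULL` for no genetic
#'   effect.
#' @param config an [sim_config()] object.
#' @return A tibble `subject_id`, `time_years`, `event` (1 = death).
#' @export
simulate_survival <- function(geno, covariates, effect, config) {
  stopifnot(inherits(config, "mdr_sim_config"))
  if (!is.null(effect) && !is.finite(effect$log_hr)) abort("log_hr must be finite")
  set.seed(config$seed + 2L)
  n <- nrow(geno_dosage(geno))
  high <- if (is.null(effect)) rep(FALSE, n) else effect_indicator(effect, geno)
  centers <- c(age = config$age_mean,
               stage = sum(1:4 * config$stage_probs),
               msi = config$msi_rate, location = config$location_rate,
               chemo = config$chemo_rate, radio = config$radio_rate)
  z <- as.matrix(covariates[, covariate_names()])
  z <- sweep(z, 2, centers[covariate_names()])
  gam <- config$gamma[covariate_names()]
  gam[is.na(gam)] <- 0
  eta <- as.vector(z %*% gam) + ifelse(high, if (is.null(effect)) 0 else effect$log_hr, 0)
  u <- runif(n)
  t_event <- (-log(u) / (config$weibull_scale * exp(eta)))^(1 / config$weibull_shape)
  t_drop <- if (config$dropout_rate > 0) rexp(n, config$dropout_rate) else rep(Inf, n)
  t_cens <- pmin(config$horizon, t_drop)
  tibble::tibble(
    subject_id = if (inherits(geno, "mdr_geno")) geno$subjects else sprintf("S%04d", seq_len(n)),
    time_years = pmax(pmin(t_event, t_cens), 1e-8),
    event = as.integer(t_event <= t_cens)
  )
}

#' Dichotomize survival at a horizon
#'
#' Subjects with an event on or before the horizon are cases (`status5y` 1);
#' subjects followed to at least the horizon are controls (`status5y` 0);
#' subjects censored alive before the horizon have unknown status and are
#' excluded from binary-outcome analyses (`included5y` 0, status `NA`).
#'
#' @param survival tibble with `time_years` and `event` columns.
#' @param horizon dichotomization horizon in years (> 0), default 5.
#' @return The input tibble with `status5y` and `included5y` columns added.
#' @export
dichotomize_survival <- function(survival, horizon = 5) {
  if (horizon <= 0) abort("horizon must be > 0")
  tm <- survival$time_years; ev <- survival$event
  status <- dplyr::case_when(
    ev == 1 & tm <= horizon ~ 1L,
    tm >= horizon ~ 0L,
    TRUE ~ NA_integer_
  )
  dplyr::mutate(survival, status5y = status,
                included5y = as.integer(!is.na(status)))
}

#' Simulate a complete analysis-ready cohort
#'
#' Convenience wrapper chaining [simulate_genotypes()],
#' [simulate_covariates()], [simulate_survival()] and
#' [dichotomize_survival()].
#'
#' @param config an [sim_config()] object.
#' @param effect an [planted_effect()] object or `NULL`.
#' @param horizon dichotomization horizon in years.
#' @return A list of class `mdr_cohort`: `geno` ([mdr_geno]) and `pheno`
#'   (tibble of survival, binary status and covariates), plus the generating
#'   `config` and `effect`.
#' @export
simulate_cohort <- function(config, effect = NULL, horizon = 5) {
  geno <- simulate_genotypes(config)
  cov <- simulate_covariates(config)
  surv <- simulate_survival(geno, cov, effect, config)
  pheno <- dplyr::left_join(dichotomize_survival(surv, horizon), cov,
                            by = "subject_id")
  structure(list(geno = geno, pheno = pheno, config = config, effect = effect),
            class = "mdr_cohort")
}

#' @export
print.mdr_cohort <- function(x, ...) {
  cat(sprintf("<mdr_cohort> %d subjects, %d SNPs, %d events (%d excluded at 5y)\n",
              nrow(x$pheno), ncol(x$geno$dosage), sum(x$pheno$event),
              sum(x$pheno$included5y == 0)))
  invisible(x)
}
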