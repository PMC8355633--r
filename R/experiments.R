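# Monte-Carlo experiments over the generative model: type-I error
# calibration, power, effect recovery and causal-probe ranking. The first
# three need only the causal SNP-probe pair, so they use a reduced-output
# path over the same cohort simulators (full genotype draw, regression at
# the causal SNP); the ranking experiment runs the complete
# table -> harmonize -> SMR path.

# Summary statistics of the causal pair for one replicate: identical to
# the corresponding entries of simulate_eqtl_study()/simulate_gwas_study()
# under the same config (same sub-streams, same draws).
causal_pair_stats <- function(config) {
  maf <- sim_maf(config)
  ci <- config$causal_index
  n_probes_sim <- 1L + config$n_null_probes

  eq <- with_stream(config$seed, .stream_offsets[["eqtl"]], {
    G <- sim_dosages(config$n_eqtl, maf, config$ld_rho)
    noise <- matrix(stats::rnorm(config$n_eqtl * n_probes_sim),
                    config$n_eqtl, n_probes_sim)
    expr <- config$b_zx * G[, ci] + noise[, 1]
    marginal_ols(expr, G[, ci, drop = FALSE])
  })
  gw <- with_stream(config$seed, .stream_offsets[["gwas"]], {
    G <- sim_dosages(config$n_gwas, maf, config$ld_rho)
    trait <- config$b_xy * config$b_zx * G[, ci] + stats::rnorm(config$n_gwas)
    marginal_ols(trait, G[, ci, drop = FALSE])
  })
  list(beta_eqtl = eq$beta[1], se_eqtl = eq$se[1],
       beta_gwas = gw$beta[1], se_gwas = gw$se[1],
       z_eqtl = eq$beta[1] / eq$se[1], z_gwas = gw$beta[1] / gw$se[1])
}

rep_config <- function(config, seed, r) {
  config$seed <- derive_seed(seed, 100L + r)
  config
}

# Conditions shared by the calibration / power / recovery experiments:
# few cis SNPs, no null probes, strong instrument, large cohorts.
experiment_config <- function(b_xy, n = 5000, seed = NULL) {
  sim_config(m_snps = 5, causal_index = 3, b_zx = 0.5, b_xy = b_xy,
             n_eqtl = n, n_gwas = n, n_null_probes = 0,
             n_probes_total = 1000, seed = seed)
}

#' Type-I error of the SMR test under the null
#'
#' Simulates replicates with no expression-to-trait effect (`b_xy = 0`)
#' and a strong eQTL instrument, applies the SMR test to the causal
#' SNP-probe pair of each replicate, and reports the fraction rejected at
#' level `alpha`. A well-calibrated test with a strong instrument should
#' reject close to `alpha` (very slightly below, since the statistic is
#' bounded by the squared GWAS Z score).
#'
#' @param n_reps Number of replicates.
#' @param alpha Nominal test level.
#' @param n Cohort size for both studies.
#' @param seed Integer seed for the whole experiment.
#' @return List: `rejection_rate`, `median_abs_z_eqtl`, `n_reps`, `alpha`.
#' @export
smr_type1_error <- function(n_reps = 2000, alpha = 0.05, n = 5000,
                            seed = 1L) {
  base <- experiment_config(b_xy = 0, n = n, seed = seed)
  p <- ze <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    s <- causal_pair_stats(rep_config(base, seed, r))
    p[r] <- p_smr(t_smr(s$z_gwas, s$z_eqtl))
    ze[r] <- s$z_eqtl
  }
  list(rejection_rate = mean(p < alpha),
       median_abs_z_eqtl = stats::median(abs(ze)),
       n_reps = n_reps, alpha = alpha)
}

#' Empirical power curve over expression-to-trait effect sizes
#'
#' For each value of `b_xy` on the grid, simulates replicates at cohort
#' size `n` with a strong instrument and reports the fraction of causal
#' pairs significant at level `alpha`.
#'
#' @param b_xy_grid Effect sizes to sweep.
#' @param n_reps Replicates per grid point.
#' @inheritParams smr_type1_error
#' @return Tibble with columns `b_xy`, `power`, `n_reps`.
#' @export
smr_power_curve <- function(b_xy_grid = c(0, 0.1, 0.2, 0.4), n_reps = 1000,
                            alpha = 0.05, n = 5000, seed = 1L) {
  power <- vapply(seq_along(b_xy_grid), function(i) {
    base <- experiment_config(b_xy = b_xy_grid[i], n = n,
                              seed = derive_seed(seed, 10L + i))
    rej <- vapply(seq_len(n_reps), function(r) {
      s <- causal_pair_stats(rep_config(base, base$seed, r))
      p_smr(t_smr(s$z_gwas, s$z_eqtl)) < alpha
    }, logical(1))
    mean(rej)
  }, numeric(1))
  tibble::tibble(b_xy = b_xy_grid, power = power, n_reps = n_reps)
}

#' Wald-ratio recovery of the true expression-to-trait effect
#'
#' Simulates replicates at the configured true `b_xy`, computes the Wald
#' ratio at the causal pair in each, and summarizes the distribution of
#' the estimates. With a strong instrument the median estimate should sit
#' within a few percent of the truth.
#'
#' @param b_xy True expression-to-trait effect.
#' @inheritParams smr_type1_error
#' @return List: `median_bxy`, `true_bxy`, `estimates`, `n_reps`.
#' @export
smr_effect_recovery <- function(b_xy = 0.3, n_reps = 500, n = 5000,
                                seed = 1L) {
  base <- experiment_config(b_xy = b_xy, n = n, seed = seed)
  est <- vapply(seq_len(n_reps), function(r) {
    s <- causal_pair_stats(rep_config(base, seed, r))
    wald_ratio(s$beta_gwas, s$se_gwas, s$beta_eqtl, s$se_eqtl)$b_xy
  }, numeric(1))
  list(median_bxy = stats::median(est), true_bxy = b_xy,
       estimates = est, n_reps = n_reps)
}

#' Causal-probe ranking through the full pipeline
#'
#' Each replicate generates a complete GWAS + eQTL study pair under the
#' default generator (50 cis SNPs, 9 null probes, flipped allele labels),
#' runs SNP intersection, allele alignment and the SMR test over all
#' pairs, and records whether the causal probe attains the smallest
#' p-value among probes.
#'
#' @param n_reps Number of replicates.
#' @param config Base [sim_config()]; its seed is re-derived per replicate.
#' @param seed Integer experiment seed.
#' @return List: `top_rate` (fraction of replicates where the causal probe
#'   ranks first), `n_reps`.
#' @export
smr_causal_rank_experiment <- function(n_reps = 200, config = sim_config(),
                                       seed = 1L) {
  hits <- vapply(seq_len(n_reps), function(r) {
    pair <- generate_dataset_pair(rep_config(config, seed, r))
    md <- align_alleles(intersect_snps(pair$gwas, pair$eqtl))
    res <- run_smr(md)
    best <- res |>
      dplyr::group_by(.data$probe_id) |>
      dplyr::summarise(lp = min(.data$log10_p), .groups = "drop") |>
      dplyr::arrange(.data$lp)
    best$probe_id[1] == pair$truth$causal_probe_id
  }, logical(1))
  list(top_rate = mean(hits), n_reps = n_reps)
}
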