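#' Z score of a marginal association
#'
#' Standardizes an effect estimate by its standard error, `z = beta / se`.
#' Both GWAS and eQTL summary statistics are put on this scale before the
#' SMR statistic is formed.
#'
#' @param beta Numeric vector of effect sizes (regression coefficients).
#' @param se Numeric vector of standard errors; all must be positive.
#' @return Numeric vector `beta / se`.
#' @examples
#' z_score(1, 0.5)       # 2
#' z_score(-0.42, 0.07)  # -6
#' @export
z_score <- function(beta, se) {
  if (any(!is.finite(se)) || any(se <= 0)) {
    stop("`se` must be finite and > 0", call. = FALSE)
  }
  beta / se
}

#' SMR test statistic
#'
#' The squared-Z ratio statistic
#' \deqn{T = \frac{Z_{GWAS}^2 \, Z_{eQTL}^2}{Z_{GWAS}^2 + Z_{eQTL}^2}}
#' i.e. half the harmonic mean of the two squared Z scores. Under the null
#' hypothesis of no expression-mediated effect (and a valid instrument) it
#' is referred to a chi-square distribution with one degree of freedom.
#' When both arguments are zero the limit convention `T = 0` applies.
#'
#' @param z_gwas,z_eqtl Numeric vectors of Z scores (recycled to a common
#'   length).
#' @return Numeric vector of statistics in `[0, min(z_gwas^2, z_eqtl^2)]`.
#' @examples
#' t_smr(2, 2)  # 2
#' t_smr(3, 4)  # 5.76
#' @export
t_smr <- function(z_gwas, z_eqtl) {
  a2 <- z_gwas^2
  b2 <- z_eqtl^2
  denom <- a2 + b2
  t <- ifelse(denom == 0, 0, a2 * b2 / denom)
  # guard the fully-degenerate 0/0 produced by Inf inputs
  t[is.nan(t)] <- 0
  t
}

#' Chi-square p-value of the SMR statistic
#'
#' Upper-tail probability of a chi-square distribution with one degree of
#' freedom evaluated at `t`.
#'
#' @param t Numeric vector of non-negative statistics.
#' @param log.p If `TRUE` return the natural log of the p-value, which is
#'   exact far beyond the ~1e-308 underflow limit of the linear scale.
#' @return Numeric vector of upper-tail probabilities (or their logs).
#' @examples
#' p_smr(0)        # 1
#' p_smr(3.841459) # ~0.05
#' @export
p_smr <- function(t, log.p = FALSE) {
  if (any(!is.finite(t)) || any(t < 0)) {
    stop("`t` must be finite and >= 0", call. = FALSE)
  }
  stats::pchisq(t, df = 1, lower.tail = FALSE, log.p = log.p)
}

#' Probe-count Bonferroni significance threshold
#'
#' Family-wise error control across an expression panel: the level `alpha`
#' divided by the number of probes in the eQTL dataset a merged dataset was
#' built from. With the probe counts of the four source panels used in the
#' study (33,323 blood; 28,522 brain; 7,350 CD4; 5,829 CD8) this yields the
#' per-dataset thresholds 1.5e-6, 1.8e-6, 6.8e-6 and 8.6e-6 (two significant
#' figures).
#'
#' @param alpha Family-wise significance level in (0, 1]; default 0.05.
#' @param n_probes Number of probes (tests); positive integer.
#' @return `alpha / n_probes`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_probes) {
  if (!is.numeric(alpha) || length(alpha) != 1 || is.na(alpha) ||
      alpha <= 0 || alpha > 1) {
    stop("`alpha` must be a single value in (0, 1]", call. = FALSE)
  }
  if (!is.numeric(n_probes) || any(is.na(n_probes)) || any(n_probes < 1)) {
    stop("`n_probes` must be >= 1", call. = FALSE)
  }
  alpha / n_probes
}

#' Wald ratio estimate of the expression-to-trait effect
#'
#' Two-stage ratio estimate `b_xy = beta_gwas / beta_eqtl`: the change in
#' the trait per unit increase in expression, with the SNP as instrument.
#' Its standard error follows the first-order delta method
#' `|b_xy| * sqrt((se_gwas/beta_gwas)^2 + (se_eqtl/beta_eqtl)^2)`; the
#' `beta_gwas = 0` boundary case degenerates to `se_gwas / |beta_eqtl|`.
#'
#' @param beta_gwas,se_gwas Marginal SNP-trait effect and standard error.
#' @param beta_eqtl,se_eqtl Marginal SNP-expression effect and standard
#'   error. `beta_eqtl` must be nonzero.
#' @return A list with numeric components `b_xy` and `se_bxy` (vectorized).
#' @examples
#' wald_ratio(0.2, 0.05, 0.4, 0.05)
#' @export
wald_ratio <- function(beta_gwas, se_gwas, beta_eqtl, se_eqtl) {
  if (any(se_gwas <= 0) || any(se_eqtl <= 0)) {
    stop("standard errors must be > 0", call. = FALSE)
  }
  if (any(beta_eqtl == 0)) {
    stop("`beta_eqtl` must be nonzero: ratio undefined", call. = FALSE)
  }
  b_xy <- beta_gwas / beta_eqtl
  se_bxy <- ifelse(
    beta_gwas == 0,
    se_gwas / abs(beta_eqtl),
    abs(b_xy) * sqrt((se_gwas / beta_gwas)^2 + (se_eqtl / beta_eqtl)^2)
  )
  list(b_xy = b_xy, se_bxy = se_bxy)
}

#' Select instrument SNP-probe pairs from a merged dataset
#'
#' `"all_pairs"` tests every harmonized SNP-probe pair. `"top_per_probe"`
#' is the conventional published-SMR behaviour: per probe, the single pair
#' with the smallest eQTL p-value among those passing `p_cut` (ties broken
#' by larger `|z_eqtl|`, then lexicographic `snp_id`).
#'
#' @param dataset A [merged dataset][intersect_snps], allele-aligned.
#' @param mode `"all_pairs"` (default) or `"top_per_probe"`.
#' @param p_cut eQTL significance cutoff applied in `"top_per_probe"` mode;
#'   default `5e-8`.
#' @return A tibble of selected harmonized pairs.
#' @export
select_instruments <- function(dataset, mode = c("all_pairs", "top_per_probe"),
                               p_cut = 5e-8) {
  mode <- match.arg(mode)
  stopifnot(inherits(dataset, "smr_merged"))
  pairs <- dataset$pairs
  if (mode == "all_pairs" || nrow(pairs) == 0) {
    return(pairs)
  }
  pairs |>
    dplyr::filter(.data$pvalue_eqtl <= p_cut) |>
    dplyr::arrange(.data$probe_id, .data$pvalue_eqtl,
                   dplyr::desc(abs(.data$z_eqtl)), .data$snp_id) |>
    dplyr::distinct(.data$probe_id, .keep_all = TRUE)
}

#' Run the SMR test over a merged dataset
#'
#' For each selected instrument pair computes the Z scores, the statistic
#' [t_smr()], its chi-square df-1 p-value, the Wald ratio effect estimate,
#' and the significance call against the probe-count Bonferroni threshold.
#' P-values are carried in log space internally so extreme associations
#' survive serialization; `log10_p` is reported alongside `p_smr`.
#'
#' @param dataset An allele-aligned merged dataset.
#' @param alpha Family-wise level for the Bonferroni threshold.
#' @param n_probes Multiple-testing denominator. Defaults to the probe
#'   count of the source eQTL panel carried by `dataset` (the convention
#'   matching printed per-panel thresholds); pass the tested-pair count
#'   instead if per-test correction is wanted.
#' @param mode,p_cut Instrument selection, see [select_instruments()].
#' @return A tibble of class `smr_result` sorted by ascending p-value with
#'   columns `probe_id, gene_name, snp_id, chrom, pos, z_gwas, z_eqtl,
#'   t_smr, p_smr, log10_p, b_xy, se_bxy, significant`; attributes
#'   `threshold`, `n_probes`, `alpha`, `label`.
#' @export
run_smr <- function(dataset, alpha = 0.05, n_probes = NULL,
                    mode = c("all_pairs", "top_per_probe"), p_cut = 5e-8) {
  stopifnot(inherits(dataset, "smr_merged"))
  if (!isTRUE(dataset$aligned)) {
    stop("dataset must be allele-aligned first (see align_alleles())",
         call. = FALSE)
  }
  if (is.null(n_probes)) n_probes <- dataset$n_probes
  threshold <- bonferroni_threshold(alpha, n_probes)
  sel <- select_instruments(dataset, mode = mode, p_cut = p_cut)

  if (nrow(sel) == 0) {
    res <- empty_smr_result()
  } else {
    zg <- z_score(sel$beta_gwas, sel$se_gwas)
    ze <- z_score(sel$beta_eqtl, sel$se_eqtl)
    t <- t_smr(zg, ze)
    log_p <- p_smr(t, log.p = TRUE)
    ok_ratio <- sel$beta_eqtl != 0
    b_xy <- se_bxy <- rep(NA_real_, nrow(sel))
    if (any(ok_ratio)) {
      wr <- wald_ratio(sel$beta_gwas[ok_ratio], sel$se_gwas[ok_ratio],
                       sel$beta_eqtl[ok_ratio], sel$se_eqtl[ok_ratio])
      b_xy[ok_ratio] <- wr$b_xy
      se_bxy[ok_ratio] <- wr$se_bxy
    }
    res <- tibble::tibble(
      probe_id = sel$probe_id,
      gene_name = sel$gene_name,
      snp_id = sel$snp_id,
      chrom = sel$chrom,
      pos = sel$pos,
      z_gwas = zg,
      z_eqtl = ze,
      t_smr = t,
      p_smr = exp(log_p),
      log10_p = log_p / log(10),
      b_xy = b_xy,
      se_bxy = se_bxy,
      significant = log_p < log(threshold)
    )
    res <- dplyr::arrange(res, .data$log10_p, .data$probe_id, .data$snp_id)
  }
  attr(res, "threshold") <- threshold
  attr(res, "n_probes") <- n_probes
  attr(res, "alpha") <- alpha
  attr(res, "label") <- dataset$label
  class(res) <- c("smr_result", class(res))
  res
}

empty_smr_result <- function() {
  tibble::tibble(
    probe_id = character(), gene_name = character(), snp_id = character(),
    chrom = character(), pos = double(), z_gwas = double(),
    z_eqtl = double(), t_smr = double(), p_smr = double(),
    log10_p = double(), b_xy = double(), se_bxy = double(),
    significant = logical()
  )
}

#' Aggregate significant SMR results into gene-level risk calls
#'
#' Groups significant SNP-probe results by gene symbol and reports, per
#' gene, the number of distinct supporting SNPs, the SNP ids, the best
#' (smallest) p-value and the probe attaining it. A gene backed by several
#' significant SNPs (e.g. five cis SNPs all pointing at one locus) appears
#' once with `n_snps` = 5.
#'
#' @param results An `smr_result` tibble from [run_smr()] (or any tibble
#'   with `gene_name`, `snp_id`, `probe_id`, `p_smr`, `log10_p`,
#'   `significant` columns).
#' @return A tibble with columns `gene_name, n_snps, snp_ids, probe_id,
#'   best_p, best_log10_p`, sorted by ascending best p-value.
#' @export
call_risk_genes <- function(results) {
  sig <- dplyr::filter(results, .data$significant)
  if (nrow(sig) == 0) {
    return(tibble::tibble(
      gene_name = character(), n_snps = integer(), snp_ids = character(),
      probe_id = character(), best_p = double(), best_log10_p = double()
    ))
  }
  sig |>
    dplyr::group_by(.data$gene_name) |>
    dplyr::arrange(.data$log10_p, .by_group = TRUE) |>
    dplyr::summarise(
      n_snps = dplyr::n_distinct(.data$snp_id),
      snp_ids = paste(unique(.data$snp_id), collapse = ","),
      probe_id = dplyr::first(.data$probe_id),
      best_p = dplyr::first(.data$p_smr),
      best_log10_p = dplyr::first(.data$log10_p),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$best_log10_p)
}

#' Per-dataset threshold report
#'
#' @param labels Dataset labels.
#' @param n_probes Probe counts, one per label.
#' @param alpha Family-wise level.
#' @return Tibble `dataset, n_probes, threshold`.
#' @export
threshold_report <- function(labels, n_probes, alpha = 0.05) {
  stopifnot(length(labels) == length(n_probes))
  tibble::tibble(
    dataset = as.character(labels),
    n_probes = as.integer(n_probes),
    threshold = bonferroni_threshold(alpha, n_probes)
  )
}
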