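#' Configuration of the two-cohort generative model
#'
#' The simulator emulates the structure of a two-sample SMR design: two
#' disjoint cohorts genotyped at the same `m_snps` cis SNPs, an expression
#' trait driven by one causal SNP (`expression = b_zx * dosage + noise`),
#' and a quantitative trait driven (optionally, `b_xy = 0` being the null)
#' by the genetic component of that expression. Both cohorts are reduced
#' to per-SNP marginal least-squares summary statistics, exactly the data
#' shape public GWAS and eQTL deposits provide.
#'
#' Defaults encode the reference study conditions used throughout the test
#' suite: 50 cis SNPs, MAF uniform on 0.05-0.5, adjacent-SNP LD 0.5, a
#' strong instrument (`b_zx = 0.5` expression-SD per allele at cohort size
#' 5000), expression-to-trait effect 0.3, 9 null probes next to the causal
#' one, and an emulated panel of 1000 probes for thresholding.
#'
#' @param m_snps Number of cis SNPs.
#' @param maf_range Minor-allele-frequency interval frequencies are drawn
#'   from, once per configuration and shared by both cohorts.
#' @param ld_rho Adjacent-SNP correlation of the latent autoregressive
#'   haplotype process, in `[0, 1)`.
#' @param causal_index 1-based index of the SNP driving expression;
#'   defaults to the middle of the cis window.
#' @param b_zx SNP-to-expression effect, expression SDs per allele.
#' @param b_xy Expression-to-trait effect, trait SDs per expression SD;
#'   0 is the no-effect null.
#' @param n_eqtl,n_gwas Cohort sizes (disjoint samples), at least 10.
#' @param n_probes_total Probe count of the emulated expression panel,
#'   used as the Bonferroni denominator downstream.
#' @param n_null_probes Additional probes with pure-noise expression.
#' @param flip_fraction Fraction of SNPs whose GWAS rows are reported on
#'   the opposite effect allele (label-swapped, sign-negated), exercising
#'   harmonization downstream.
#' @param seed Integer seed making every derived table reproducible;
#'   `NULL` uses the ambient RNG state.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(m_snps = 50, maf_range = c(0.05, 0.5), ld_rho = 0.5,
                       causal_index = NULL, b_zx = 0.5, b_xy = 0.3,
                       n_eqtl = 5000, n_gwas = 5000, n_probes_total = 1000,
                       n_null_probes = 9, flip_fraction = 0.3, seed = NULL) {
  if (is.null(causal_index)) causal_index <- max(1, ceiling(m_snps / 2))
  stopifnot(
    m_snps >= 1,
    length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
    maf_range[1] <= maf_range[2],
    ld_rho >= 0, ld_rho < 1,
    causal_index >= 1, causal_index <= m_snps,
    n_eqtl >= 10, n_gwas >= 10,
    n_probes_total >= 1 + n_null_probes, n_null_probes >= 0,
    flip_fraction >= 0, flip_fraction <= 1
  )
  structure(
    list(m_snps = as.integer(m_snps), maf_range = as.numeric(maf_range),
         ld_rho = ld_rho, causal_index = as.integer(causal_index),
         b_zx = b_zx, b_xy = b_xy, n_eqtl = as.integer(n_eqtl),
         n_gwas = as.integer(n_gwas),
         n_probes_total = as.integer(n_probes_total),
         n_null_probes = as.integer(n_null_probes),
         flip_fraction = flip_fraction,
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "sim_config"
  )
}

#' @rdname sim_config
#' @param path YAML file of `key: value` pairs matching the `sim_config()`
#'   arguments (unknown keys are rejected).
#' @export
sim_config_from_yaml <- function(path) {
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(sim_config)))
  if (length(unknown) > 0) {
    stop("unknown simulation config key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  do.call(sim_config, vals)
}

# Independent sub-streams derived from the config seed keep the cohorts,
# the shared allele frequencies and the allele-label assignment mutually
# independent yet individually reproducible. Arithmetic stays below 2^53
# so the derivation is exact in doubles.
.stream_offsets <- c(maf = 1L, eqtl = 2L, gwas = 3L, alleles = 4L)

derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) %% 2147483647 * 48271 + offset) %% 2147483647)
}

with_stream <- function(seed, offset, code) {
  s <- derive_seed(seed, offset)
  if (is.null(s)) code else withr::with_seed(s, code)
}

sim_maf <- function(config) {
  with_stream(config$seed, .stream_offsets[["maf"]],
              stats::runif(config$m_snps, config$maf_range[1],
                           config$maf_range[2]))
}

# One haplotype per row: a first-order autoregressive latent Gaussian
# thresholded at qnorm(maf_j) per site, so marginal allele frequencies are
# exact and LD decays geometrically with distance. Two independent
# haplotypes per individual give Hardy-Weinberg dosages.
sim_haplotypes <- function(n, maf, rho) {
  m <- length(maf)
  z <- matrix(0, n, m)
  z[, 1] <- stats::rnorm(n)
  if (m > 1) {
    sd_innov <- sqrt(1 - rho^2)
    for (j in 2:m) {
      z[, j] <- rho * z[, j - 1] + sd_innov * stats::rnorm(n)
    }
  }
  thresh <- stats::qnorm(maf)
  (z < matrix(thresh, n, m, byrow = TRUE)) + 0L
}

sim_dosages <- function(n, maf, rho) {
  sim_haplotypes(n, maf, rho) + sim_haplotypes(n, maf, rho)
}

#' Simulate genotype dosages for one cohort
#'
#' Draws an `n x m_snps` dosage matrix (0/1/2) under Hardy-Weinberg
#' equilibrium with autoregressive linkage disequilibrium between adjacent
#' SNPs. Allele frequencies are derived once from the configuration seed,
#' so both cohorts share them; the `cohort` argument selects the random
#' sub-stream, making the two cohorts disjoint independent draws.
#'
#' @param config A [sim_config()].
#' @param n Cohort size; defaults to the configured size for `cohort`.
#' @param cohort `"eqtl"` or `"gwas"`.
#' @return Integer dosage matrix with SNP ids as column names.
#' @export
simulate_genotypes <- function(config, n = NULL,
                               cohort = c("eqtl", "gwas")) {
  cohort <- match.arg(cohort)
  stopifnot(inherits(config, "sim_config"))
  if (is.null(n)) n <- if (cohort == "eqtl") config$n_eqtl else config$n_gwas
  maf <- sim_maf(config)
  g <- with_stream(config$seed, .stream_offsets[[cohort]],
                   sim_dosages(n, maf, config$ld_rho))
  colnames(g) <- snp_ids(config)
  g
}

snp_ids <- function(config) sprintf("rs%06d", seq_len(config$m_snps))
probe_ids <- function(config) {
  sprintf("PRB%04d", seq_len(1L + config$n_null_probes))
}
gene_names <- function(config) {
  sprintf("GENE%04d", seq_len(1L + config$n_null_probes))
}

# Marginal simple-regression summary statistics of y on each column of G:
# slope, its standard error and the two-sided t-test p-value, vectorized
# across SNPs. Monomorphic columns yield non-finite entries.
marginal_ols <- function(y, G) {
  n <- length(y)
  gm <- colMeans(G)
  ym <- mean(y)
  sxx <- colSums(G^2) - n * gm^2
  sxy <- as.vector(crossprod(G, y)) - n * gm * ym
  syy <- sum(y^2) - n * ym^2
  beta <- sxy / sxx
  rss <- pmax(syy - beta * sxy, 0)
  se <- sqrt(rss / (n - 2) / sxx)
  p <- 2 * stats::pt(-abs(beta / se), df = n - 2)
  list(beta = beta, se = se, pvalue = p)
}

# Allele labels per SNP, drawn from the non-palindromic transition pairs
# so strict harmonization never discards simulated variants, plus the
# per-SNP indicator of GWAS label swapping.
sim_alleles <- function(config) {
  pairs <- rbind(c("A", "G"), c("G", "A"), c("A", "C"), c("C", "A"),
                 c("T", "G"), c("G", "T"), c("T", "C"), c("C", "T"))
  with_stream(config$seed, .stream_offsets[["alleles"]], {
    idx <- sample.int(nrow(pairs), config$m_snps, replace = TRUE)
    flip <- stats::runif(config$m_snps) < config$flip_fraction
    list(effect = pairs[idx, 1], other = pairs[idx, 2], flip = flip)
  })
}

snp_site_tibble <- function(config, alleles, for_gwas) {
  ea <- alleles$effect
  oa <- alleles$other
  if (for_gwas) {
    # flipped SNPs are reported on the opposite allele in the GWAS table
    ea <- ifelse(alleles$flip, alleles$other, alleles$effect)
    oa <- ifelse(alleles$flip, alleles$effect, alleles$other)
  }
  tibble::tibble(
    snp_id = snp_ids(config),
    chrom = "1",
    pos = 10000 + 1000 * seq_len(config$m_snps),
    effect_allele = ea,
    other_allele = oa
  )
}

#' Simulate an eQTL summary-statistics study
#'
#' Generates the eQTL cohort's genotypes, one causal expression probe
#' (`expression = b_zx * dosage[causal SNP] + N(0,1) noise`) plus
#' `n_null_probes` pure-noise probes, regresses each probe on each SNP,
#' and returns the per-pair marginal statistics as a study table. The
#' reported probe count is `n_probes_total`, emulating a panel of which
#' the simulated probes are the cis excerpt.
#'
#' @param config A [sim_config()].
#' @param study_label Label for the emitted table.
#' @return An `smr_study_table` of type `"eqtl"`.
#' @export
simulate_eqtl_study <- function(config, study_label = "simEqtl") {
  stopifnot(inherits(config, "sim_config"))
  maf <- sim_maf(config)
  alleles <- sim_alleles(config)
  n <- config$n_eqtl
  n_probes_sim <- 1L + config$n_null_probes

  sim <- with_stream(config$seed, .stream_offsets[["eqtl"]], {
    G <- sim_dosages(n, maf, config$ld_rho)
    expr <- matrix(stats::rnorm(n * n_probes_sim), n, n_probes_sim)
    expr[, 1] <- config$b_zx * G[, config$causal_index] + expr[, 1]
    list(G = G, expr = expr)
  })

  sites <- snp_site_tibble(config, alleles, for_gwas = FALSE)
  rows <- vector("list", n_probes_sim)
  pid <- probe_ids(config)
  gname <- gene_names(config)
  for (k in seq_len(n_probes_sim)) {
    ols <- marginal_ols(sim$expr[, k], sim$G)
    rows[[k]] <- tibble::tibble(
      sites,
      beta = ols$beta, se = ols$se, pvalue = ols$pvalue,
      probe_id = pid[k], gene_name = gname[k]
    )
  }
  rec <- dplyr::bind_rows(rows)
  rec <- rec[is.finite(rec$se) & rec$se > 0, , drop = FALSE]
  new_study_table(rec, study_label, "eqtl",
                  n_probes = config$n_probes_total, n_input = nrow(rec))
}

#' Simulate a GWAS summary-statistics study
#'
#' Draws the independent GWAS cohort from the same genetic model,
#' regenerates the genetic component of expression
#' (`b_zx * dosage[causal SNP]`), forms the trait as
#' `b_xy * genetic_component + N(0,1) noise`, and regresses the trait on
#' each SNP. SNPs selected for label flipping are reported on the opposite
#' effect allele with negated effect size.
#'
#' @param config A [sim_config()].
#' @param study_label Label for the emitted table.
#' @return An `smr_study_table` of type `"gwas"`.
#' @export
simulate_gwas_study <- function(config, study_label = "simGwas") {
  stopifnot(inherits(config, "sim_config"))
  maf <- sim_maf(config)
  alleles <- sim_alleles(config)
  n <- config$n_gwas

  sim <- with_stream(config$seed, .stream_offsets[["gwas"]], {
    G <- sim_dosages(n, maf, config$ld_rho)
    genetic_expr <- config$b_zx * G[, config$causal_index]
    trait <- config$b_xy * genetic_expr + stats::rnorm(n)
    list(G = G, trait = trait)
  })

  ols <- marginal_ols(sim$trait, sim$G)
  rec <- tibble::tibble(
    snp_site_tibble(config, alleles, for_gwas = TRUE),
    beta = ifelse(alleles$flip, -ols$beta, ols$beta),
    se = ols$se,
    pvalue = ols$pvalue
  )
  rec <- rec[is.finite(rec$se) & rec$se > 0, , drop = FALSE]
  new_study_table(rec, study_label, "gwas", n_input = nrow(rec))
}

#' Generate a matched GWAS + eQTL study pair with ground truth
#'
#' Runs both cohort simulators under one configuration and returns the
#' pair of study tables together with the truth record needed to score
#' recovery: causal SNP and probe, the true effects, the per-SNP flip
#' indicators and the shared allele frequencies.
#'
#' @param config A [sim_config()].
#' @param gwas_label,eqtl_label Study labels.
#' @return A list with elements `gwas`, `eqtl` (study tables) and `truth`.
#' @export
generate_dataset_pair <- function(config, gwas_label = "simGwas",
                                  eqtl_label = "simEqtl") {
  stopifnot(inherits(config, "sim_config"))
  alleles <- sim_alleles(config)
  truth <- list(
    causal_snp_id = snp_ids(config)[config$causal_index],
    causal_probe_id = probe_ids(config)[1],
    causal_gene = gene_names(config)[1],
    b_zx = config$b_zx,
    b_xy = config$b_xy,
    flipped = stats::setNames(alleles$flip, snp_ids(config)),
    maf = stats::setNames(sim_maf(config), snp_ids(config))
  )
  list(
    gwas = simulate_gwas_study(config, study_label = gwas_label),
    eqtl = simulate_eqtl_study(config, study_label = eqtl_label),
    truth = truth
  )
}

#' Write a study table or truth record as TSV
#'
#' Emits the same dialect [read_gwas_table()] / [read_eqtl_table()] read
#' with their default column maps.
#'
#' @param study An `smr_study_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_study_table <- function(study, path) {
  stopifnot(inherits(study, "smr_study_table"))
  readr::write_tsv(study$records, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_study_table
#' @param truth A truth record from [generate_dataset_pair()].
#' @export
write_truth_record <- function(truth, path) {
  tab <- tibble::tibble(
    snp_id = names(truth$flipped),
    maf = unname(truth$maf),
    flipped = unname(truth$flipped),
    causal_snp = names(truth$flipped) == truth$causal_snp_id,
    causal_probe_id = truth$causal_probe_id,
    causal_gene = truth$causal_gene,
    b_zx = truth$b_zx,
    b_xy = truth$b_xy
  )
  readr::write_tsv(tab, path, progress = FALSE)
  invisible(path)
}
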