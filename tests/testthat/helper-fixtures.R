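# Fixture builders: small summary-statistic tables written to tempfiles in
# the dialect the default column maps read, plus independent oracles used
# across the suite.

gwas_fixture_df <- function(snp_id, beta, se,
                            effect_allele = "A", other_allele = "G",
                            pvalue = 2 * pnorm(-abs(beta / se)),
                            chrom = "1",
                            pos = seq_along(snp_id) * 1000) {
  tibble::tibble(snp_id = snp_id, chrom = chrom, pos = pos,
                 effect_allele = effect_allele,
                 other_allele = other_allele,
                 beta = beta, se = se, pvalue = pvalue)
}

eqtl_fixture_df <- function(snp_id, probe_id, beta, se,
                            gene_name = paste0("G_", probe_id), ...) {
  df <- gwas_fixture_df(snp_id = snp_id, beta = beta, se = se, ...)
  df$probe_id <- probe_id
  df$gene_name <- gene_name
  df
}

write_fixture <- function(df, path = withr::local_tempfile(fileext = ".tsv",
                                                           .local_envir = parent.frame())) {
  readr::write_tsv(df, path, progress = FALSE)
  path
}

make_gwas <- function(df, ...) read_gwas_table(write_fixture(df), ...)
make_eqtl <- function(df, ...) read_eqtl_table(write_fixture(df), ...)

# merged + aligned dataset from two fixture data frames
make_dataset <- function(gwas_df, eqtl_df, policy = "strict", ...) {
  align_alleles(intersect_snps(make_gwas(gwas_df), make_eqtl(eqtl_df), ...),
                policy = policy)
}

# Upper-tail probability of the chi-square distribution with one degree of
# freedom by direct numerical integration of its density -- independent of
# pchisq(), which the implementation uses.
chisq1_tail_oracle <- function(t) {
  stats::integrate(function(x) exp(-x / 2) / sqrt(2 * pi * x),
                   lower = t, upper = Inf,
                   rel.tol = 1e-10, abs.tol = 1e-14)$value
}

# half the harmonic mean of the squared Z scores
t_smr_oracle <- function(a, b) 0.5 * 2 / (1 / a^2 + 1 / b^2)
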