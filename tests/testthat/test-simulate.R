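test_that("configuration invariants are enforced", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(ld_rho = 1))
  expect_error(sim_config(causal_index = 51))
  expect_error(sim_config(n_eqtl = 5))
  expect_error(sim_config(maf_range = c(0.2, 0.6)))
  expect_error(sim_config(flip_fraction = 1.2))

  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("m_snps: 12", "seed: 9", "b_xy: 0.0"), path)
  cfg <- sim_config_from_yaml(path)
  expect_equal(cfg$m_snps, 12L)
  expect_equal(cfg$b_xy, 0)
  writeLines("nonsense_key: 1", path)
  expect_error(sim_config_from_yaml(path), "unknown")
})

test_that("the same seed reproduces genotypes and tables exactly", {
  cfg <- sim_config(m_snps = 8, n_eqtl = 60, n_gwas = 50,
                    n_null_probes = 2, seed = 123)
  expect_identical(simulate_genotypes(cfg), simulate_genotypes(cfg))
  e1 <- simulate_eqtl_study(cfg)
  e2 <- simulate_eqtl_study(cfg)
  expect_identical(e1$records, e2$records)
  g1 <- simulate_gwas_study(cfg)
  expect_identical(g1$records, simulate_gwas_study(cfg)$records)
  p1 <- generate_dataset_pair(cfg)
  p2 <- generate_dataset_pair(cfg)
  expect_identical(p1$gwas$records, p2$gwas$records)
  expect_identical(p1$truth, p2$truth)
  # cohorts are distinct draws
  expect_false(identical(simulate_genotypes(cfg, n = 50, cohort = "eqtl"),
                         simulate_genotypes(cfg, n = 50, cohort = "gwas")))
  # a different seed changes the data
  cfg2 <- sim_config(m_snps = 8, n_eqtl = 60, n_gwas = 50,
                     n_null_probes = 2, seed = 124)
  expect_false(identical(e1$records, simulate_eqtl_study(cfg2)$records))
})

test_that("genotypes match the configured allele frequencies and LD structure", {
  # fixed maf 0.5, no LD: sample allele frequency within 3 binomial SEs
  cfg <- sim_config(m_snps = 4, maf_range = c(0.5, 0.5), ld_rho = 0,
                    n_eqtl = 2000, seed = 7)
  g <- simulate_genotypes(cfg)
  expect_true(all(g %in% 0:2))
  freq <- colMeans(g) / 2
  se3 <- 3 * sqrt(0.5 * 0.5 / (2 * 2000))
  expect_true(all(abs(freq - 0.5) < se3))

  # strong AR(1) LD: adjacent dosage correlation beats non-adjacent,
  # averaged over replicates
  adj <- far <- numeric(50)
  for (r in 1:50) {
    cfgr <- sim_config(m_snps = 6, maf_range = c(0.3, 0.3), ld_rho = 0.9,
                       n_eqtl = 300, seed = 1000 + r)
    gr <- simulate_genotypes(cfgr)
    cm <- cor(gr)
    adj[r] <- mean(cm[cbind(1:5, 2:6)])
    far[r] <- mean(cm[cbind(1:2, 5:6)])
  }
  expect_gt(mean(adj), mean(far))
  expect_gt(mean(adj), 0.5)
})

test_that("eQTL summary statistics are calibrated under the null and powered otherwise", {
  # b_zx = 0: causal-SNP p-values uniform across replicates (KS test)
  pvals <- vapply(1:200, function(r) {
    cfg <- sim_config(m_snps = 3, causal_index = 2, b_zx = 0,
                      n_eqtl = 150, n_gwas = 10, n_null_probes = 0,
                      n_probes_total = 1, seed = 2000 + r)
    st <- simulate_eqtl_study(cfg)
    st$records$pvalue[st$records$snp_id == "rs000002"]
  }, numeric(1))
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)

  # strong instrument: causal-SNP |Z| large at n = 5000
  zs <- vapply(1:10, function(r) {
    cfg <- sim_config(m_snps = 3, causal_index = 2, b_zx = 0.5,
                      n_eqtl = 5000, n_gwas = 10, n_null_probes = 0,
                      n_probes_total = 1, seed = 3000 + r)
    rec <- simulate_eqtl_study(cfg)$records
    with(rec[rec$snp_id == "rs000002", ], abs(beta / se))
  }, numeric(1))
  expect_gt(median(zs), 5)

  # probe bookkeeping: 1 causal + n_null probes, panel size reported
  cfg <- sim_config(m_snps = 4, n_eqtl = 80, n_null_probes = 3,
                    n_probes_total = 77, seed = 5)
  st <- simulate_eqtl_study(cfg)
  expect_equal(length(unique(st$records$probe_id)), 4)
  expect_equal(st$n_probes, 77L)
  expect_equal(nrow(st$records), 16)
})

test_that("GWAS Z scores are standard-normal under the null and enriched at the causal SNP", {
  z <- unlist(lapply(1:30, function(r) {
    cfg <- sim_config(m_snps = 10, b_xy = 0, ld_rho = 0.2, n_eqtl = 10,
                      n_gwas = 400, n_null_probes = 0, n_probes_total = 1,
                      seed = 4000 + r)
    rec <- simulate_gwas_study(cfg)$records
    # undo reporting flips: calibration concerns |Z| symmetry around 0
    rec$beta / rec$se
  }))
  expect_lt(abs(mean(z)), 3 / sqrt(length(z)) * 1.5 + 0.05)
  expect_gt(var(z), 0.85)
  expect_lt(var(z), 1.15)

  # with b_xy != 0 the causal SNP outranks null SNPs in |Z|
  wins <- vapply(1:20, function(r) {
    cfg <- sim_config(m_snps = 10, causal_index = 5, b_xy = 0.4,
                      ld_rho = 0, n_eqtl = 10, n_gwas = 2000,
                      n_null_probes = 0, n_probes_total = 1,
                      seed = 5000 + r)
    rec <- simulate_gwas_study(cfg)$records
    az <- abs(rec$beta / rec$se)
    rank(-az)[rec$snp_id == "rs000005"] <= 2
  }, logical(1))
  expect_gt(mean(wins), 0.8)
})

test_that("allele flipping exercises harmonization at the configured rate", {
  # flip fraction 0: alignment flips nothing
  cfg0 <- sim_config(m_snps = 20, n_eqtl = 50, n_gwas = 50,
                     flip_fraction = 0, n_null_probes = 0, seed = 8,
                     causal_index = 10, n_probes_total = 100)
  pair0 <- generate_dataset_pair(cfg0)
  md0 <- align_alleles(intersect_snps(pair0$gwas, pair0$eqtl))
  expect_false(any(md0$pairs$flipped))
  expect_equal(md0$n_dropped_palindromic + md0$n_dropped_mismatch, 0L)

  # flip fraction 0.5: observed fraction within 3 binomial SEs
  cfg5 <- sim_config(m_snps = 400, n_eqtl = 50, n_gwas = 50,
                     flip_fraction = 0.5, n_null_probes = 0, seed = 9,
                     causal_index = 10, n_probes_total = 1000)
  pair5 <- generate_dataset_pair(cfg5)
  md5 <- align_alleles(intersect_snps(pair5$gwas, pair5$eqtl))
  obs <- mean(md5$pairs$flipped)
  expect_lt(abs(obs - 0.5), 3 * sqrt(0.25 / 400))
  # flips recorded in the truth record agree with harmonization
  expect_equal(md5$pairs$flipped,
               unname(pair5$truth$flipped[md5$pairs$snp_id]))
})

test_that("the reduced-output experiment path matches the full study tables", {
  cfg <- sim_config(m_snps = 6, causal_index = 4, n_eqtl = 300,
                    n_gwas = 250, n_null_probes = 2, n_probes_total = 50,
                    seed = 77)
  fast <- smrlink:::causal_pair_stats(cfg)
  pair <- generate_dataset_pair(cfg)
  erec <- pair$eqtl$records
  erec <- erec[erec$snp_id == "rs000004" & erec$probe_id == "PRB0001", ]
  grec <- pair$gwas$records
  grec <- grec[grec$snp_id == "rs000004", ]
  expect_equal(fast$beta_eqtl, erec$beta, tolerance = 1e-12)
  expect_equal(fast$se_eqtl, erec$se, tolerance = 1e-12)
  flip_sign <- if (pair$truth$flipped[["rs000004"]]) -1 else 1
  expect_equal(fast$beta_gwas, flip_sign * grec$beta, tolerance = 1e-12)
  expect_equal(fast$se_gwas, grec$se, tolerance = 1e-12)
})

test_that("study tables and truth records write in the dialect the readers consume", {
  cfg <- sim_config(m_snps = 5, n_eqtl = 60, n_gwas = 40,
                    n_null_probes = 1, n_probes_total = 10,
                    causal_index = 2, seed = 55)
  pair <- generate_dataset_pair(cfg)
  dir <- withr::local_tempdir()
  write_study_table(pair$gwas, file.path(dir, "gwas.tsv"))
  write_study_table(pair$eqtl, file.path(dir, "eqtl.tsv"))
  write_truth_record(pair$truth, file.path(dir, "truth.tsv"))
  g <- read_gwas_table(file.path(dir, "gwas.tsv"))
  e <- read_eqtl_table(file.path(dir, "eqtl.tsv"))
  expect_equal(nrow(g$records), nrow(pair$gwas$records))
  expect_equal(g$records$beta, pair$gwas$records$beta, tolerance = 1e-12)
  expect_equal(nrow(e$records), nrow(pair$eqtl$records))
  tr <- readr::read_tsv(file.path(dir, "truth.tsv"), show_col_types = FALSE)
  expect_equal(sum(tr$causal_snp), 1)
  expect_equal(tr$snp_id[tr$causal_snp], "rs000002")
})
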