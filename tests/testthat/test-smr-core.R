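test_that("z_score is the beta/se quotient and rejects bad standard errors", {
  expect_equal(z_score(1.0, 0.5), 2.0)
  expect_equal(z_score(0, 0.3), 0)
  expect_equal(z_score(-0.42, 0.07), -6.0)
  expect_equal(z_score(c(1, -1), c(0.5, 0.25)), c(2, -4))
  expect_error(z_score(1, 0), "se")
  expect_error(z_score(1, -0.1), "se")
})

test_that("t_smr matches the half-harmonic-mean oracle and its bounds", {
  expect_equal(t_smr(2, 2), 2.0)
  expect_equal(t_smr(0, 5), 0)
  expect_equal(t_smr(0, 0), 0)
  expect_equal(t_smr(3, 4), 5.76)

  set.seed(41)
  a <- rnorm(1e4, sd = 3)
  b <- rnorm(1e4, sd = 3)
  t <- t_smr(a, b)
  expect_equal(t, t_smr_oracle(a, b), tolerance = 1e-12)
  expect_true(all(t <= pmin(a^2, b^2) + 1e-12))
  expect_true(all(t >= 0))
  # symmetry and sign invariance
  expect_equal(t, t_smr(b, a))
  expect_equal(t, t_smr(-a, b))
  # monotone in |a|: scaling one argument up never decreases the statistic
  expect_true(all(t_smr(2 * a, b) >= t - 1e-12))
})

test_that("p_smr is the chi-square df-1 upper tail, strictly decreasing", {
  expect_equal(p_smr(0), 1.0)
  # independent numerical-integration oracle at the 0.95 / 0.999 quantiles
  expect_equal(p_smr(3.841459), chisq1_tail_oracle(3.841459),
               tolerance = 1e-10)
  expect_lt(abs(p_smr(3.841459) - 0.05), 1e-4)
  expect_lt(abs(p_smr(10.8276) - 1e-3), 1e-5)
  tt <- seq(0, 40, by = 0.5)
  expect_true(all(diff(p_smr(tt)) < 0))
  # log-scale form agrees and survives far underflow
  expect_equal(p_smr(50, log.p = TRUE), log(p_smr(50)), tolerance = 1e-10)
  expect_lt(p_smr(1500, log.p = TRUE), -700)
  expect_error(p_smr(-1), ">= 0")
})

test_that("bonferroni thresholds reproduce the per-panel values", {
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(signif(bonferroni_threshold(0.05, 33323), 2), 1.5e-6)
  expect_equal(signif(bonferroni_threshold(0.05, 28522), 2), 1.8e-6)
  expect_error(bonferroni_threshold(0.05, 0), ">= 1")
  expect_error(bonferroni_threshold(0, 10), "alpha")
  tr <- threshold_report(c("a", "b"), c(100, 200), alpha = 0.05)
  expect_equal(tr$threshold, 0.05 / c(100, 200))
})

test_that("wald_ratio computes the delta-method ratio estimate", {
  wr <- wald_ratio(0.2, 0.05, 0.4, 0.05)
  expect_equal(wr$b_xy, 0.5)
  expect_equal(wr$se_bxy,
               0.5 * sqrt((0.05 / 0.2)^2 + (0.05 / 0.4)^2))
  wr0 <- wald_ratio(0, 0.05, 0.4, 0.05)
  expect_equal(wr0$b_xy, 0)
  expect_equal(wr0$se_bxy, 0.125)
  expect_error(wald_ratio(0.1, 0.05, 0, 0.05), "nonzero")
  expect_error(wald_ratio(0.1, 0, 0.4, 0.05), "> 0")
})

test_that("instrument selection modes behave and match a brute-force argmin", {
  gdf <- gwas_fixture_df(paste0("rs", 1:5), beta = rep(0.2, 5), se = 0.1)
  edf <- eqtl_fixture_df(rep(paste0("rs", 1:5), 2),
                         probe_id = rep(c("p1", "p2"), each = 5),
                         beta = c(0.9, 0.1, 0.2, 0.3, 0.1,
                                  0.05, 0.85, 0.1, 0.2, 0.1),
                         se = 0.1)
  md <- make_dataset(gdf, edf)
  expect_equal(nrow(select_instruments(md, "all_pairs")), 10)

  top <- select_instruments(md, "top_per_probe", p_cut = 5e-8)
  expect_equal(nrow(top), 2)
  expect_equal(top$snp_id[top$probe_id == "p1"], "rs1")  # |z| = 9
  expect_equal(top$snp_id[top$probe_id == "p2"], "rs2")  # |z| = 8.5

  # cutoff excludes probes with no sufficiently strong eQTL
  weak <- make_dataset(gdf, eqtl_fixture_df(
    paste0("rs", 1:2), probe_id = "p1", beta = c(0.9, 0.3), se = 0.1,
    pvalue = c(1e-9, 1e-4)))
  sel <- select_instruments(weak, "top_per_probe", p_cut = 5e-8)
  expect_equal(nrow(sel), 1)
  expect_equal(sel$pvalue_eqtl, 1e-9)

  # random fixture vs exhaustive per-probe argmin oracle
  set.seed(51)
  n <- 300
  edf_r <- eqtl_fixture_df(
    snp_id = paste0("rs", sample(1:40, n, replace = TRUE)),
    probe_id = paste0("p", sample(1:6, n, replace = TRUE)),
    beta = rnorm(n, sd = 2), se = runif(n, 0.05, 0.5))
  edf_r <- edf_r[!duplicated(edf_r[, c("snp_id", "probe_id")]), ]
  gdf_r <- gwas_fixture_df(paste0("rs", 1:40), beta = rnorm(40), se = 0.1)
  md_r <- make_dataset(gdf_r, edf_r, policy = "lenient")
  cut <- 0.05
  got <- select_instruments(md_r, "top_per_probe", p_cut = cut)
  pr <- md_r$pairs[md_r$pairs$pvalue_eqtl <= cut, ]
  for (pb in unique(pr$probe_id)) {
    sub <- pr[pr$probe_id == pb, ]
    best <- sub[order(sub$pvalue_eqtl, -abs(sub$z_eqtl), sub$snp_id)[1], ]
    expect_equal(got$snp_id[got$probe_id == pb], best$snp_id)
  }
  expect_setequal(got$probe_id, unique(pr$probe_id))
})

test_that("run_smr produces calibrated, correctly flagged, sorted results", {
  # single strong pair: z = 6 on both sides => t = 18
  md <- make_dataset(gwas_fixture_df("rs1", beta = 0.6, se = 0.1),
                     eqtl_fixture_df("rs1", probe_id = "p1",
                                     beta = 0.6, se = 0.1))
  res <- run_smr(md, n_probes = 1000)
  expect_equal(res$t_smr, 18)
  expect_equal(res$p_smr, chisq1_tail_oracle(18), tolerance = 1e-8)
  expect_equal(res$p_smr, 2.2e-5, tolerance = 1e-2)
  expect_equal(attr(res, "threshold"), 5e-5)
  expect_true(res$significant)
  expect_equal(res$b_xy, 1)

  # refusing unaligned input
  raw <- intersect_snps(make_gwas(gwas_fixture_df("rs1", beta = 1, se = 1)),
                        make_eqtl(eqtl_fixture_df("rs1", probe_id = "p1",
                                                  beta = 1, se = 1)))
  expect_error(run_smr(raw), "aligned")

  # flags are exactly {p < threshold}, results sorted by p
  set.seed(61)
  md_r <- make_dataset(
    gwas_fixture_df(paste0("rs", 1:30), beta = rnorm(30, sd = 0.5),
                    se = runif(30, 0.05, 0.2)),
    eqtl_fixture_df(rep(paste0("rs", 1:30), 3),
                    probe_id = rep(paste0("p", 1:3), each = 30),
                    beta = rnorm(90, sd = 1), se = runif(90, 0.05, 0.3)))
  res_r <- run_smr(md_r, n_probes = 50)
  expect_identical(res_r$significant,
                   res_r$p_smr < bonferroni_threshold(0.05, 50))
  expect_false(is.unsorted(res_r$p_smr))
  expect_true(all(res_r$t_smr <= pmin(res_r$z_gwas^2, res_r$z_eqtl^2) + 1e-12))

  # no pair passing the threshold means zero significant calls
  res_none <- run_smr(md_r, n_probes = 1e15)
  expect_false(any(res_none$significant))
  expect_equal(nrow(call_risk_genes(res_none)), 0)
})

test_that("risk-gene calls aggregate significant results per gene", {
  base <- tibble::tibble(
    probe_id = c("p1", "p1", "p1", "p1", "p1", "p2", "p3"),
    gene_name = c(rep("SNCA_like", 5), "GENE_B", "GENE_B"),
    snp_id = paste0("rs", 1:7),
    chrom = "4", pos = 1:7,
    z_gwas = 6, z_eqtl = 6, t_smr = 18,
    p_smr = c(5e-9, 4e-8, 3e-8, 2e-8, 1e-8, 1e-7, 9e-8),
    log10_p = log10(c(5e-9, 4e-8, 3e-8, 2e-8, 1e-8, 1e-7, 9e-8)),
    b_xy = 1, se_bxy = 0.1,
    significant = c(rep(TRUE, 5), TRUE, FALSE))
  calls <- call_risk_genes(base)
  expect_equal(nrow(calls), 2)
  one <- calls[calls$gene_name == "SNCA_like", ]
  expect_equal(one$n_snps, 5L)
  expect_equal(one$best_p, 5e-9)
  expect_equal(one$snp_ids, "rs1,rs5,rs4,rs3,rs2")
  expect_equal(calls$gene_name[1], "SNCA_like")  # sorted by best p
  expect_equal(calls$n_snps, c(5L, 1L))
})
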