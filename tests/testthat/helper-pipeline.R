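# 2 GWAS x 4 eQTL synthetic inputs, small cohorts; panels get distinct
# probe counts so every dataset has its own threshold.
make_pipeline_inputs <- function(dir) {
  gwas_paths <- c(GA = file.path(dir, "gwas_a.tsv"),
                  GB = file.path(dir, "gwas_b.tsv"))
  for (i in 1:2) {
    cfg <- sim_config(m_snps = 30, causal_index = 15, n_eqtl = 50,
                      n_gwas = 300, n_null_probes = 0, n_probes_total = 10,
                      seed = 100 + i)
    write_study_table(simulate_gwas_study(cfg), gwas_paths[i])
  }
  panel_sizes <- c(E1 = 400L, E2 = 300L, E3 = 200L, E4 = 100L)
  eqtl_inputs <- list()
  for (i in 1:4) {
    lab <- names(panel_sizes)[i]
    cfg <- sim_config(m_snps = 30, causal_index = 15, n_eqtl = 300,
                      n_gwas = 50, n_null_probes = 2,
                      n_probes_total = panel_sizes[[i]], seed = 200 + i)
    path <- file.path(dir, paste0("eqtl_", lab, ".tsv"))
    write_study_table(simulate_eqtl_study(cfg), path)
    eqtl_inputs[[lab]] <- list(path = path, n_probes = panel_sizes[[i]])
  }
  list(gwas = as.list(gwas_paths), eqtl = eqtl_inputs,
       panel_sizes = panel_sizes)
}
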