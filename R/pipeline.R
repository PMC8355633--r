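#' Pipeline configuration
#'
#' Describes a full integration run: every GWAS input is crossed with
#' every eQTL input (N x M merged datasets, e.g. 2 GWAS x 4 eQTL panels
#' giving eight datasets), each harmonized and tested, followed by the
#' threshold report, the per-dataset risk-gene report and the gene-overlap
#' matrices.
#'
#' @param gwas_inputs Named character vector or list: label -> file path.
#' @param eqtl_inputs Named list: label -> either a file path, or a list
#'   with `path` and optionally `n_probes` (integer panel size, or
#'   `"infer"` to count distinct probes in the file; the panel size is the
#'   Bonferroni denominator downstream).
#' @param alpha Family-wise significance level.
#' @param instrument_mode,p_cut See [select_instruments()].
#' @param ambiguity_policy See [align_alleles()].
#' @param overlap_definition See [overlap_rate_matrix()].
#' @param output_dir Directory all outputs are written to.
#' @param delim Field delimiter of the input tables.
#' @param seed Optional integer seed recorded in the manifest (used by
#'   simulation front-ends; the pipeline itself is deterministic).
#' @return A list of class `smr_pipeline_config`.
#' @export
pipeline_config <- function(gwas_inputs, eqtl_inputs, alpha = 0.05,
                            instrument_mode = c("all_pairs", "top_per_probe"),
                            p_cut = 5e-8,
                            ambiguity_policy = c("strict", "lenient"),
                            overlap_definition = c("min_fraction", "jaccard"),
                            output_dir = "smr_output", delim = "\t",
                            seed = NULL) {
  instrument_mode <- match.arg(instrument_mode)
  ambiguity_policy <- match.arg(ambiguity_policy)
  overlap_definition <- match.arg(overlap_definition)
  gwas_inputs <- as.list(gwas_inputs)
  eqtl_inputs <- lapply(eqtl_inputs, function(e) {
    if (is.character(e) && length(e) == 1) e <- list(path = e)
    if (is.null(e$n_probes) || identical(e$n_probes, "infer")) {
      e$n_probes <- NULL
    } else {
      e$n_probes <- as.integer(e$n_probes)
    }
    e
  })
  labels <- c(names(gwas_inputs), names(eqtl_inputs))
  if (is.null(names(gwas_inputs)) || is.null(names(eqtl_inputs)) ||
      any(labels == "") || anyDuplicated(labels)) {
    stop("gwas and eqtl inputs must carry unique nonempty labels",
         call. = FALSE)
  }
  structure(
    list(gwas_inputs = gwas_inputs, eqtl_inputs = eqtl_inputs,
         alpha = alpha, instrument_mode = instrument_mode, p_cut = p_cut,
         ambiguity_policy = ambiguity_policy,
         overlap_definition = overlap_definition,
         output_dir = output_dir, delim = delim,
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "smr_pipeline_config"
  )
}

#' @rdname pipeline_config
#' @param path YAML config file with keys `gwas` (label -> path map),
#'   `eqtl` (label -> path, or label -> {path, n_probes}), and optionally
#'   any of the remaining `pipeline_config()` arguments.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) {
    stop("config file does not exist: ", path, call. = FALSE)
  }
  y <- yaml::read_yaml(path)
  if (is.null(y$gwas) || is.null(y$eqtl)) {
    stop("pipeline config must provide `gwas` and `eqtl` input maps",
         call. = FALSE)
  }
  args <- list(gwas_inputs = y$gwas, eqtl_inputs = y$eqtl)
  extra <- intersect(names(y), c("alpha", "instrument_mode", "p_cut",
                                 "ambiguity_policy", "overlap_definition",
                                 "output_dir", "delim", "seed"))
  unknown <- setdiff(names(y), c("gwas", "eqtl", extra))
  if (length(unknown) > 0) {
    stop("unknown pipeline config key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  do.call(pipeline_config, c(args, y[extra]))
}

#' Run the full GWAS x eQTL SMR pipeline
#'
#' For every GWAS x eQTL input combination: reads both tables, intersects
#' SNPs, aligns alleles, runs the SMR test, and writes the merged dataset
#' (`<label>_merged.tsv`) and results (`<label>_results.tsv`). Afterwards
#' writes `thresholds.tsv` (dataset, probe count, Bonferroni threshold),
#' `risk_genes.tsv` (the per-dataset discovery report: gene, supporting
#' SNP count and ids, best p-value), the gene-overlap matrices with
#' heatmaps (one per GWAS across its eQTL panels, plus the same-eQTL
#' GWAS-vs-GWAS comparison), and `manifest.json` listing every output with
#' its row count and a hash of the configuration. Given identical inputs
#' and configuration the run is deterministic: every table is reproduced
#' byte for byte.
#'
#' @param config An [pipeline_config()] object (or path to a YAML file).
#' @param quiet Suppress progress messages.
#' @return The manifest, invisibly.
#' @export
run_smr_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "smr_pipeline_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)

  for (lab in names(config$gwas_inputs)) {
    p <- config$gwas_inputs[[lab]]
    if (!file.exists(p)) {
      stop("GWAS input '", lab, "' not readable: ", p, call. = FALSE)
    }
  }
  for (lab in names(config$eqtl_inputs)) {
    p <- config$eqtl_inputs[[lab]]$path
    if (is.null(p) || !file.exists(p)) {
      stop("eQTL input '", lab, "' not readable: ",
           if (is.null(p)) "(no path)" else p, call. = FALSE)
    }
  }

  gwas_tables <- lapply(names(config$gwas_inputs), function(lab) {
    t <- read_gwas_table(config$gwas_inputs[[lab]], delim = config$delim,
                         study_label = lab)
    say("read GWAS %s: %d rows (%d dropped)", lab, nrow(t$records),
        t$n_dropped)
    t
  })
  names(gwas_tables) <- names(config$gwas_inputs)
  eqtl_tables <- lapply(names(config$eqtl_inputs), function(lab) {
    inp <- config$eqtl_inputs[[lab]]
    t <- read_eqtl_table(inp$path, delim = config$delim, study_label = lab,
                         n_probes = inp$n_probes)
    say("read eQTL %s: %d rows, %d probes (%d dropped)", lab,
        nrow(t$records), t$n_probes, t$n_dropped)
    t
  })
  names(eqtl_tables) <- names(config$eqtl_inputs)

  outputs <- list()
  add_output <- function(name, path, n_rows) {
    outputs[[name]] <<- list(path = basename(path), n_rows = n_rows)
  }

  merged_list <- list()
  summaries <- list()
  discovery <- list()
  for (glab in names(gwas_tables)) {
    for (elab in names(eqtl_tables)) {
      lab <- paste(glab, elab, sep = "_")
      md <- intersect_snps(gwas_tables[[glab]], eqtl_tables[[elab]],
                           label = lab)
      md <- align_alleles(md, policy = config$ambiguity_policy)
      say("%s: %d pairs, %d SNPs, %d genes (dropped %d palindromic, %d irreconcilable)",
          lab, nrow(md$pairs), md$n_snps, md$n_genes,
          md$n_dropped_palindromic, md$n_dropped_mismatch)
      merged_path <- file.path(out, paste0(lab, "_merged.tsv"))
      write_merged_dataset(md, merged_path)
      add_output(paste0(lab, "_merged"), merged_path, nrow(md$pairs))
      merged_list[[lab]] <- md
      summaries[[lab]] <- summarize_merge(md)

      res <- run_smr(md, alpha = config$alpha,
                     mode = config$instrument_mode, p_cut = config$p_cut)
      res_path <- file.path(out, paste0(lab, "_results.tsv"))
      write_results_table(res, res_path)
      add_output(paste0(lab, "_results"), res_path, nrow(res))
      say("%s: %d tests, threshold %.3g, %d significant", lab, nrow(res),
          attr(res, "threshold"), sum(res$significant))

      calls <- call_risk_genes(res)
      discovery[[lab]] <- if (nrow(calls) == 0) {
        tibble::tibble(dataset = lab, n_genes = 0L, gene_name = "-",
                       n_snps = 0L, snp_ids = "-", best_p = NA_real_)
      } else {
        tibble::tibble(dataset = lab, n_genes = nrow(calls),
                       gene_name = calls$gene_name, n_snps = calls$n_snps,
                       snp_ids = calls$snp_ids, best_p = calls$best_p)
      }
    }
  }

  thr <- threshold_report(
    labels = names(merged_list),
    n_probes = vapply(merged_list, function(m) m$n_probes, numeric(1)),
    alpha = config$alpha)
  thr_path <- file.path(out, "thresholds.tsv")
  readr::write_tsv(thr, thr_path, progress = FALSE)
  add_output("thresholds", thr_path, nrow(thr))

  disc <- dplyr::bind_rows(discovery)
  disc_path <- file.path(out, "risk_genes.tsv")
  readr::write_tsv(disc, disc_path, progress = FALSE)
  add_output("risk_genes", disc_path, nrow(disc))

  sets <- gene_sets(merged_list)
  elabs <- names(eqtl_tables)
  glabs <- names(gwas_tables)
  # per GWAS: overlap across its eQTL panels
  if (length(elabs) >= 2) {
    for (glab in glabs) {
      labs <- paste(glab, elabs, sep = "_")
      om <- overlap_rate_matrix(sets[labs],
                                definition = config$overlap_definition)
      prefix <- file.path(out, paste0("overlap_", glab))
      paths <- render_overlap_report(om, prefix)
      for (nm in names(paths)) {
        add_output(paste0("overlap_", glab, "_", nm), paths[[nm]],
                   length(om$labels))
      }
    }
  }
  # per eQTL panel: overlap between the GWAS-specific datasets
  if (length(glabs) >= 2) {
    same_eqtl <- dplyr::bind_rows(lapply(elabs, function(elab) {
      labs <- paste(glabs, elab, sep = "_")
      om <- overlap_rate_matrix(sets[labs],
                                definition = config$overlap_definition)
      combs <- utils::combn(seq_along(labs), 2)
      dplyr::bind_rows(apply(combs, 2, function(ij) {
        i <- ij[1]; j <- ij[2]
        tibble::tibble(eqtl = elab, dataset_a = labs[i],
                       dataset_b = labs[j],
                       n_a = om$set_sizes[[i]], n_b = om$set_sizes[[j]],
                       n_overlap = om$counts[i, j], rate = om$rates[i, j])
      }))
    }))
    se_path <- file.path(out, "overlap_same_eqtl.tsv")
    readr::write_tsv(same_eqtl, se_path, progress = FALSE)
    add_output("overlap_same_eqtl", se_path, nrow(same_eqtl))
  }

  manifest <- list(
    config_hash = rlang::hash(unclass(config)),
    n_gwas = length(glabs),
    n_eqtl = length(elabs),
    n_datasets = length(merged_list),
    datasets = lapply(summaries, as.list),
    n_significant = lapply(
      stats::setNames(names(discovery), names(discovery)),
      function(lab) sum(discovery[[lab]]$gene_name != "-")),
    outputs = outputs
  )
  man_path <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  say("wrote %d outputs to %s", length(outputs) + 1L, out)
  invisible(manifest)
}
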