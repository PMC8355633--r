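#' Intersect SNPs between a GWAS and an eQTL study
#'
#' Builds the merged dataset the SMR test consumes: one row per eQTL
#' `(snp_id, probe_id)` pair whose SNP also occurs in the GWAS table, each
#' carrying both studies' effect sizes and standard errors. Matching is by
#' rsID alone (build-agnostic); coordinates are taken from the eQTL side.
#' The probe count carried forward for thresholding is the source eQTL
#' panel's, not the post-merge count.
#'
#' @param gwas,eqtl `smr_study_table` objects from [read_gwas_table()] /
#'   [read_eqtl_table()] (or [simulate_gwas_study()] and friends).
#' @param label Dataset label; defaults to `"<gwas>_<eqtl>"`.
#' @return An object of class `smr_merged`: list with `pairs` (tibble),
#'   `label`, `n_probes`, `n_snps`, `n_genes`, `aligned = FALSE` and an
#'   alignment drop log (zeros until [align_alleles()] runs).
#' @export
intersect_snps <- function(gwas, eqtl, label = NULL) {
  stopifnot(inherits(gwas, "smr_study_table"), gwas$type == "gwas",
            inherits(eqtl, "smr_study_table"), eqtl$type == "eqtl")
  if (is.null(label)) label <- paste(gwas$study_label, eqtl$study_label,
                                     sep = "_")
  g <- gwas$records
  if (anyDuplicated(g$snp_id)) {
    g <- g |>
      dplyr::arrange(.data$snp_id, .data$pvalue) |>
      dplyr::distinct(.data$snp_id, .keep_all = TRUE)
  }
  g <- g |>
    dplyr::select(snp_id = "snp_id",
                  effect_allele_gwas = "effect_allele",
                  other_allele_gwas = "other_allele",
                  beta_gwas = "beta", se_gwas = "se",
                  pvalue_gwas = "pvalue")
  e <- eqtl$records |>
    dplyr::select("snp_id", "chrom", "pos", "probe_id", "gene_name",
                  effect_allele_eqtl = "effect_allele",
                  other_allele_eqtl = "other_allele",
                  beta_eqtl = "beta", se_eqtl = "se",
                  pvalue_eqtl = "pvalue")
  pairs <- dplyr::inner_join(e, g, by = "snp_id")
  if (nrow(pairs) == 0) {
    warning("no SNPs shared between ", gwas$study_label, " and ",
            eqtl$study_label, call. = FALSE)
  }
  new_merged(pairs, label, eqtl$n_probes, aligned = FALSE)
}

new_merged <- function(pairs, label, n_probes, aligned,
                       n_dropped_palindromic = 0L,
                       n_dropped_mismatch = 0L) {
  structure(
    list(
      pairs = pairs,
      label = label,
      n_probes = n_probes,
      n_snps = dplyr::n_distinct(pairs$snp_id),
      n_genes = dplyr::n_distinct(pairs$gene_name),
      aligned = aligned,
      n_dropped_palindromic = n_dropped_palindromic,
      n_dropped_mismatch = n_dropped_mismatch
    ),
    class = "smr_merged"
  )
}

#' @export
print.smr_merged <- function(x, ...) {
  cat(sprintf(
    "<smr_merged> %s: %d pairs (%d SNPs, %d genes), panel of %d probes, %s\n",
    x$label, nrow(x$pairs), x$n_snps, x$n_genes, x$n_probes,
    if (x$aligned) "aligned" else "unaligned"))
  if (x$n_dropped_palindromic + x$n_dropped_mismatch > 0) {
    cat(sprintf("  alignment drops: %d palindromic, %d irreconcilable\n",
                x$n_dropped_palindromic, x$n_dropped_mismatch))
  }
  invisible(x)
}

complement_allele <- function(x) chartr("ACGT", "TGCA", x)

is_palindromic <- function(a1, a2) a2 == complement_allele(a1)

#' Align GWAS effect alleles to the eQTL reference
#'
#' The eQTL effect allele is the agreed reference, so the downstream Wald
#' ratio reads as trait change per expression-increasing allele. For each
#' pair: if the GWAS effect allele matches the eQTL effect allele the row
#' is kept as is; if it matches the eQTL other allele the GWAS effect is
#' sign-flipped; failing both, the GWAS alleles are strand-complemented
#' and re-tried; otherwise the pair is irreconcilable and dropped. Under
#' the default `"strict"` policy, strand-ambiguous palindromic variants
#' (A/T, C/G) are dropped outright since their strand cannot be resolved
#' from labels; `"lenient"` keeps them, resolved by label match alone.
#' Aligning an already-aligned dataset is a no-op.
#'
#' @param dataset An `smr_merged` dataset from [intersect_snps()].
#' @param policy `"strict"` (default) or `"lenient"`.
#' @return The dataset with `pairs` gaining `effect_allele`,
#'   `other_allele`, `z_gwas`, `z_eqtl`, `flipped` columns (per-study
#'   allele columns removed), `aligned = TRUE`, and drop counts populated.
#' @export
align_alleles <- function(dataset, policy = c("strict", "lenient")) {
  policy <- match.arg(policy)
  stopifnot(inherits(dataset, "smr_merged"))
  if (isTRUE(dataset$aligned)) {
    return(dataset)
  }
  p <- dataset$pairs

  ea_g <- p$effect_allele_gwas
  oa_g <- p$other_allele_gwas
  ea_e <- p$effect_allele_eqtl
  oa_e <- p$other_allele_eqtl

  direct <- ea_g == ea_e & oa_g == oa_e
  swapped <- ea_g == oa_e & oa_g == ea_e
  cea <- complement_allele(ea_g)
  coa <- complement_allele(oa_g)
  direct_c <- !direct & !swapped & cea == ea_e & coa == oa_e
  swapped_c <- !direct & !swapped & cea == oa_e & coa == ea_e

  flipped <- swapped | swapped_c
  resolvable <- direct | swapped | direct_c | swapped_c
  palindromic <- is_palindromic(ea_e, oa_e) | is_palindromic(ea_g, oa_g)

  keep <- if (policy == "strict") resolvable & !palindromic else resolvable
  n_pal <- if (policy == "strict") sum(palindromic & resolvable) else 0L
  n_mis <- sum(!resolvable)

  out <- p[keep, , drop = FALSE]
  flip <- flipped[keep]
  out$beta_gwas <- ifelse(flip, -out$beta_gwas, out$beta_gwas)
  out$flipped <- flip
  out$effect_allele <- out$effect_allele_eqtl
  out$other_allele <- out$other_allele_eqtl
  out$z_gwas <- out$beta_gwas / out$se_gwas
  out$z_eqtl <- out$beta_eqtl / out$se_eqtl
  out <- dplyr::select(
    out, "snp_id", "chrom", "pos", "probe_id", "gene_name",
    "effect_allele", "other_allele", "beta_gwas", "se_gwas", "pvalue_gwas",
    "beta_eqtl", "se_eqtl", "pvalue_eqtl", "z_gwas", "z_eqtl", "flipped")

  new_merged(out, dataset$label, dataset$n_probes, aligned = TRUE,
             n_dropped_palindromic = as.integer(n_pal),
             n_dropped_mismatch = as.integer(n_mis))
}

#' Summarize a merged dataset
#'
#' @param dataset An `smr_merged` dataset.
#' @return A one-row tibble with `label, n_pairs, n_snps, n_genes,
#'   n_probes, aligned, n_dropped_palindromic, n_dropped_mismatch`.
#' @export
summarize_merge <- function(dataset) {
  stopifnot(inherits(dataset, "smr_merged"))
  tibble::tibble(
    label = dataset$label,
    n_pairs = nrow(dataset$pairs),
    n_snps = dataset$n_snps,
    n_genes = dataset$n_genes,
    n_probes = dataset$n_probes,
    aligned = dataset$aligned,
    n_dropped_palindromic = dataset$n_dropped_palindromic,
    n_dropped_mismatch = dataset$n_dropped_mismatch
  )
}

#' Persist / load a merged dataset as TSV
#'
#' @param dataset An aligned `smr_merged` dataset.
#' @param path Output path.
#' @return `write_merged_dataset()` returns `path` invisibly;
#'   `read_merged_dataset()` rebuilds the `smr_merged` object (the probe
#'   count and label travel in `# key: value` header comments).
#' @export
write_merged_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "smr_merged"))
  header <- c(
    sprintf("# label: %s", dataset$label),
    sprintf("# n_probes: %d", dataset$n_probes),
    sprintf("# aligned: %s", dataset$aligned)
  )
  writeLines(header, path)
  readr::write_tsv(dataset$pairs, path, append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(path)
}

#' @rdname write_merged_dataset
#' @export
read_merged_dataset <- function(path) {
  if (!file.exists(path)) {
    stop("merged dataset file does not exist: ", path, call. = FALSE)
  }
  head_lines <- readLines(path, n = 10)
  meta_lines <- grep("^# ", head_lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    kv <- strsplit(sub("^# ", "", ln), ": ", fixed = TRUE)[[1]]
    meta[[kv[1]]] <- kv[2]
  }
  pairs <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                           progress = FALSE,
                           col_types = readr::cols(
                             chrom = readr::col_character(),
                             snp_id = readr::col_character()))
  aligned <- identical(meta$aligned, "TRUE")
  if (aligned && nrow(pairs) > 0) pairs$flipped <- as.logical(pairs$flipped)
  new_merged(pairs, meta$label %||% "merged",
             as.integer(meta$n_probes %||% dplyr::n_distinct(pairs$probe_id)),
             aligned = aligned)
}
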