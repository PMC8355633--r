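#' Column mappings for summary-statistics tables
#'
#' Public GWAS and eQTL deposits use heterogeneous headers, so parsing is
#' configuration-driven: a column map names, for each canonical field, the
#' header it carries in a given file. `gwas_columns()` / `eqtl_columns()`
#' return the generic preset (the dialect the bundled simulator writes);
#' override individual entries for other layouts.
#'
#' @param snp,chrom,pos,effect_allele,other_allele,beta,se,pvalue Column
#'   names in the file for the respective fields.
#' @param n Optional sample-size column (`NULL` if absent).
#' @param probe,gene eQTL-only columns: probe identifier and gene symbol.
#' @return A named list of column names.
#' @export
gwas_columns <- function(snp = "snp_id", chrom = "chrom", pos = "pos",
                         effect_allele = "effect_allele",
                         other_allele = "other_allele",
                         beta = "beta", se = "se", pvalue = "pvalue",
                         n = NULL) {
  list(snp = snp, chrom = chrom, pos = pos, effect_allele = effect_allele,
       other_allele = other_allele, beta = beta, se = se, pvalue = pvalue,
       n = n)
}

#' @rdname gwas_columns
#' @export
eqtl_columns <- function(snp = "snp_id", chrom = "chrom", pos = "pos",
                         effect_allele = "effect_allele",
                         other_allele = "other_allele",
                         beta = "beta", se = "se", pvalue = "pvalue",
                         probe = "probe_id", gene = "gene_name",
                         n = NULL) {
  c(gwas_columns(snp, chrom, pos, effect_allele, other_allele, beta, se,
                 pvalue, n),
    list(probe = probe, gene = gene))
}

new_study_table <- function(records, study_label, type,
                            n_probes = NULL, n_input = nrow(records),
                            drop_reasons = integer()) {
  structure(
    list(
      records = records,
      study_label = study_label,
      type = type,
      n_probes = n_probes,
      n_input = n_input,
      n_dropped = sum(drop_reasons),
      drop_reasons = drop_reasons
    ),
    class = "smr_study_table"
  )
}

#' @export
print.smr_study_table <- function(x, ...) {
  cat(sprintf("<smr_study_table> %s (%s): %d records", x$study_label,
              x$type, nrow(x$records)))
  if (!is.null(x$n_probes)) cat(sprintf(", %d probes", x$n_probes))
  if (x$n_dropped > 0) {
    cat(sprintf("; dropped %d/%d rows [%s]", x$n_dropped, x$n_input,
                paste(names(x$drop_reasons), x$drop_reasons,
                      sep = "=", collapse = ", ")))
  }
  cat("\n")
  invisible(x)
}

# Shared parse-and-validate core. Parsing is total: every input row either
# becomes a record or increments a named drop counter; nothing fails
# silently. Missing p-values are tolerated (recomputed from |beta/se| under
# a standard normal reference); missing beta or se is not.
parse_summary_table <- function(path, column_map, delim, extra_fields) {
  if (!file.exists(path)) {
    stop("input file does not exist: ", path, call. = FALSE)
  }
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
  needed <- unlist(column_map[!vapply(column_map, is.null, logical(1))])
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    stop("mapped column(s) absent from ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }

  num <- function(x) suppressWarnings(as.numeric(x))
  rec <- tibble::tibble(
    snp_id = raw[[column_map$snp]],
    chrom = as.character(raw[[column_map$chrom]]),
    pos = num(raw[[column_map$pos]]),
    effect_allele = toupper(raw[[column_map$effect_allele]]),
    other_allele = toupper(raw[[column_map$other_allele]]),
    beta = num(raw[[column_map$beta]]),
    se = num(raw[[column_map$se]]),
    pvalue = num(raw[[column_map$pvalue]])
  )
  if (!is.null(column_map$n)) rec$n <- num(raw[[column_map$n]])
  for (f in names(extra_fields)) {
    rec[[f]] <- raw[[extra_fields[[f]]]]
  }

  drop <- c(missing_id = 0L, bad_beta = 0L, bad_se = 0L,
            bad_pvalue = 0L, same_alleles = 0L)
  bad_id <- is.na(rec$snp_id) | rec$snp_id == ""
  for (f in names(extra_fields)) {
    bad_id <- bad_id | is.na(rec[[f]]) | rec[[f]] == ""
  }
  drop["missing_id"] <- sum(bad_id)
  bad_beta <- !bad_id & !is.finite(rec$beta)
  drop["bad_beta"] <- sum(bad_beta)
  bad_se <- !bad_id & !bad_beta & (!is.finite(rec$se) | rec$se <= 0)
  drop["bad_se"] <- sum(bad_se)
  keep0 <- !(bad_id | bad_beta | bad_se)
  # missing p, and p printed as 0 (underflow in the source), are recomputed
  # from the Z score rather than dropping the row; the result is clamped
  # away from zero so the (0, 1] invariant survives |Z| beyond ~38
  na_p <- keep0 & (is.na(rec$pvalue) | (!is.na(rec$pvalue) & rec$pvalue == 0))
  rec$pvalue[na_p] <- pmax(
    2 * stats::pnorm(-abs(rec$beta[na_p] / rec$se[na_p])),
    .Machine$double.xmin)
  bad_p <- keep0 & (is.na(rec$pvalue) | rec$pvalue <= 0 | rec$pvalue > 1)
  drop["bad_pvalue"] <- sum(bad_p)
  same_al <- keep0 & !bad_p & rec$effect_allele == rec$other_allele
  drop["same_alleles"] <- sum(same_al)

  list(records = rec[keep0 & !bad_p & !same_al, , drop = FALSE],
       n_input = nrow(rec), drop_reasons = drop)
}

#' Read a GWAS summary-statistics table
#'
#' Parses a delimited text file (gzip-transparent) into a validated study
#' table. Rows violating the record invariants (non-positive or
#' unparseable standard error, unparseable effect size, p-value outside
#' (0, 1], identical alleles, missing identifiers) are dropped and counted
#' per reason; a missing p-value, or one printed as 0 (underflow in the
#' source), is recomputed from `|beta/se|` under a normal reference
#' instead of being dropped.
#'
#' @param path Path to the file.
#' @param column_map Mapping from canonical fields to file headers, see
#'   [gwas_columns()].
#' @param delim Field delimiter, default tab.
#' @param study_label Label for the study (e.g. `"GUB"`).
#' @return An object of class `smr_study_table` with elements `records`
#'   (tibble), `study_label`, `n_input`, `n_dropped`, `drop_reasons`.
#' @export
read_gwas_table <- function(path, column_map = gwas_columns(),
                            delim = "\t", study_label = "gwas") {
  p <- parse_summary_table(path, column_map, delim, extra_fields = list())
  new_study_table(p$records, study_label, "gwas",
                  n_input = p$n_input, drop_reasons = p$drop_reasons)
}

#' Read an eQTL summary-statistics table
#'
#' As [read_gwas_table()], with per-row probe id and gene symbol. Duplicate
#' `(snp_id, probe_id)` rows are collapsed: exact duplicates silently, and
#' conflicting duplicates by keeping the smallest-p row (ties by larger
#' `|beta/se|`, then file order), with the number of conflicts counted in
#' `drop_reasons["duplicate_key"]`.
#'
#' @inheritParams read_gwas_table
#' @param column_map See [eqtl_columns()].
#' @param n_probes Probe count of the source expression panel, used later
#'   as the Bonferroni denominator. `NULL` (default) infers the distinct
#'   probe count from the file; pass the panel size when the file is a
#'   subset of a larger panel.
#' @return An `smr_study_table` whose `n_probes` is populated.
#' @export
read_eqtl_table <- function(path, column_map = eqtl_columns(),
                            delim = "\t", study_label = "eqtl",
                            n_probes = NULL) {
  p <- parse_summary_table(path, column_map, delim,
                           extra_fields = list(probe_id = column_map$probe,
                                               gene_name = column_map$gene))
  rec <- p$records
  n_before <- nrow(rec)
  rec <- rec |>
    dplyr::mutate(.ord = dplyr::row_number()) |>
    dplyr::arrange(.data$snp_id, .data$probe_id, .data$pvalue,
                   dplyr::desc(abs(.data$beta / .data$se)), .data$.ord) |>
    dplyr::distinct(.data$snp_id, .data$probe_id, .keep_all = TRUE) |>
    dplyr::arrange(.data$.ord) |>
    dplyr::select(-".ord")
  drop <- c(p$drop_reasons, duplicate_key = n_before - nrow(rec))
  inferred <- dplyr::n_distinct(rec$probe_id)
  if (is.null(n_probes)) {
    n_probes <- inferred
  } else if (n_probes < inferred) {
    stop("supplied n_probes (", n_probes, ") is smaller than the ",
         inferred, " distinct probes in ", path, call. = FALSE)
  }
  new_study_table(rec, study_label, "eqtl", n_probes = as.integer(n_probes),
                  n_input = p$n_input, drop_reasons = drop)
}

#' Write / read an SMR results table
#'
#' Results are persisted as delimited text with full double precision, so
#' a write-then-read round trip reproduces every numeric field to better
#' than 1e-12 relative tolerance.
#'
#' @param results An `smr_result` tibble (possibly empty) from [run_smr()].
#' @param path Output path; `.gz` suffix compresses transparently.
#' @return `write_results_table()` returns `path` invisibly;
#'   `read_results_table()` returns the results tibble.
#' @export
write_results_table <- function(results, path) {
  cols <- names(empty_smr_result())
  stopifnot(all(cols %in% names(results)))
  readr::write_tsv(results[cols], path, progress = FALSE)
  invisible(path)
}

#' @rdname write_results_table
#' @export
read_results_table <- function(path) {
  if (!file.exists(path)) {
    stop("results file does not exist: ", path, call. = FALSE)
  }
  readr::read_tsv(
    path,
    col_types = readr::cols(
      probe_id = readr::col_character(),
      gene_name = readr::col_character(),
      snp_id = readr::col_character(),
      chrom = readr::col_character(),
      pos = readr::col_double(),
      z_gwas = readr::col_double(),
      z_eqtl = readr::col_double(),
      t_smr = readr::col_double(),
      p_smr = readr::col_double(),
      log10_p = readr::col_double(),
      b_xy = readr::col_double(),
      se_bxy = readr::col_double(),
      significant = readr::col_logical()
    ),
    progress = FALSE
  )
}
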