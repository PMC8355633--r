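#' Gene sets of a collection of merged datasets
#'
#' Extracts the distinct gene symbols of each dataset, keyed by its label,
#' the unit of comparison for the cross-dataset overlap analyses.
#'
#' @param datasets A list of `smr_merged` datasets, or a named list of
#'   character vectors (taken as the gene sets directly).
#' @return Named list of character vectors of distinct gene names.
#' @export
gene_sets <- function(datasets) {
  if (all(vapply(datasets, is.character, logical(1)))) {
    if (is.null(names(datasets)) || any(names(datasets) == "")) {
      stop("character gene sets must be named", call. = FALSE)
    }
    return(lapply(datasets, unique))
  }
  stopifnot(all(vapply(datasets, inherits, logical(1), "smr_merged")))
  sets <- lapply(datasets, function(d) unique(d$pairs$gene_name))
  names(sets) <- vapply(datasets, function(d) d$label, character(1))
  if (anyDuplicated(names(sets))) {
    stop("dataset labels must be unique", call. = FALSE)
  }
  sets
}

#' Overlap between two gene sets
#'
#' @param a,b Character vectors of gene names.
#' @return List with `n_overlap` (exact intersection cardinality), `n_a`,
#'   `n_b` (distinct sizes).
#' @export
overlap_counts <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  list(n_overlap = length(intersect(a, b)), n_a = length(a),
       n_b = length(b))
}

overlap_rate <- function(a, b, definition) {
  oc <- overlap_counts(a, b)
  denom <- switch(definition,
                  jaccard = length(union(a, b)),
                  min_fraction = min(oc$n_a, oc$n_b))
  if (denom == 0) 0 else oc$n_overlap / denom
}

#' Pairwise gene-overlap matrices
#'
#' Computes, over every pair of datasets, the intersection size and the
#' overlap rate. Two rate definitions are supported: `"min_fraction"`
#' (default), the intersection over the smaller set — the reading under
#' which two near-nested sets overlap at ~100% — and `"jaccard"`,
#' intersection over union. Both are symmetric, lie in `[0, 1]`, and
#' satisfy jaccard <= min_fraction. The rate of two empty sets is defined
#' as 0, with a warning.
#'
#' @param sets Named list of gene sets, see [gene_sets()]; at least two.
#' @param definition `"min_fraction"` or `"jaccard"`.
#' @return Object of class `smr_overlap`: list with `labels`, `counts`
#'   (integer matrix), `rates` (numeric matrix), `set_sizes`, `definition`.
#' @export
overlap_rate_matrix <- function(sets,
                                definition = c("min_fraction", "jaccard")) {
  definition <- match.arg(definition)
  sets <- gene_sets(sets)
  if (length(sets) < 2) {
    stop("need at least two gene sets", call. = FALSE)
  }
  labels <- names(sets)
  k <- length(sets)
  counts <- matrix(0L, k, k, dimnames = list(labels, labels))
  rates <- matrix(0, k, k, dimnames = list(labels, labels))
  warned <- FALSE
  for (i in seq_len(k)) {
    for (j in i:k) {
      oc <- overlap_counts(sets[[i]], sets[[j]])
      counts[i, j] <- counts[j, i] <- oc$n_overlap
      if (min(oc$n_a, oc$n_b) == 0 && !warned) {
        warning("overlap rate of an empty gene set defined as 0",
                call. = FALSE)
        warned <- TRUE
      }
      rates[i, j] <- rates[j, i] <- overlap_rate(sets[[i]], sets[[j]],
                                                 definition)
    }
  }
  structure(
    list(labels = labels, counts = counts, rates = rates,
         set_sizes = vapply(sets, length, integer(1)),
         definition = definition),
    class = "smr_overlap"
  )
}

#' @export
print.smr_overlap <- function(x, ...) {
  cat(sprintf("<smr_overlap> %d datasets, rate definition: %s\n",
              length(x$labels), x$definition))
  print(round(x$rates, 3))
  invisible(x)
}

#' Write an overlap report (matrix TSVs and a heatmap)
#'
#' Writes `<prefix>_counts.tsv` and `<prefix>_rates.tsv` (label column
#' plus one column per dataset) and `<prefix>_heatmap.png`, a heatmap of
#' the rate matrix annotated with the rates.
#'
#' @param matrix An `smr_overlap` object.
#' @param prefix Output path prefix.
#' @return Named character vector of the written paths, invisibly.
#' @export
render_overlap_report <- function(matrix, prefix) {
  stopifnot(inherits(matrix, "smr_overlap"))
  paths <- c(counts = paste0(prefix, "_counts.tsv"),
             rates = paste0(prefix, "_rates.tsv"),
             heatmap = paste0(prefix, "_heatmap.png"))
  write_matrix_tsv(matrix$counts, paths[["counts"]])
  write_matrix_tsv(matrix$rates, paths[["rates"]])
  pheatmap::pheatmap(
    matrix$rates, cluster_rows = FALSE, cluster_cols = FALSE,
    display_numbers = TRUE, number_format = "%.2f",
    breaks = seq(0, 1, length.out = 101),
    main = sprintf("Gene overlap rate (%s)", matrix$definition),
    filename = paths[["heatmap"]], silent = TRUE)
  invisible(paths)
}

write_matrix_tsv <- function(m, path) {
  tab <- tibble::as_tibble(m, rownames = "dataset")
  readr::write_tsv(tab, path, progress = FALSE)
  invisible(path)
}

#' @rdname render_overlap_report
#' @param path A matrix TSV written by `render_overlap_report()`.
#' @return `read_matrix_tsv()` returns the numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(tab[, -1])
  rownames(m) <- tab$dataset
  m
}
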