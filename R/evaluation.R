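#' Read a driver-gene list
#'
#' Plain text, one gene symbol per line; blank lines and `#` comments are
#' ignored.
#'
#' @param path path to the file.
#' @param uppercase normalize symbols to upper case.
#' @return Character vector of unique gene symbols.
#' @export
read_gene_list <- function(path, uppercase = FALSE) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (uppercase) lines <- toupper(lines)
  unique(lines)
}

#' Assemble a benchmark bundle
#'
#' Groups the driver-gene reference sets used to score a ranking: several
#' general driver sets (each membership adds 1 to a gene's relevance), an
#' optional cancer-type-specific driver set (membership adds 4, so a specific
#' driver weighs as much as presence in four general sets) and an optional
#' likely-false-positive set (membership subtracts 1).
#'
#' @param general named list of character vectors (general driver sets).
#' @param specific optional character vector (cancer-type-specific drivers).
#' @param false_positives optional character vector.
#' @param uppercase normalize all symbols to upper case before matching.
#' @return A `benchmark_bundle`.
#' @export
benchmark_bundle <- function(general, specific = NULL,
                             false_positives = NULL, uppercase = FALSE) {
  stopifnot(is.list(general), length(general) >= 1L)
  if (is.null(names(general)) || any(!nzchar(names(general)))) {
    names(general) <- paste0("set", seq_along(general))
  }
  norm <- function(x) if (uppercase && !is.null(x)) toupper(x) else x
  structure(list(general = lapply(general, norm),
                 specific = norm(specific),
                 false_positives = norm(false_positives),
                 uppercase = uppercase),
            class = "benchmark_bundle")
}

#' Union of the general driver sets
#'
#' Recomputed from the bundle's current general sets (never stored).
#'
#' @param bundle a [benchmark_bundle()].
#' @return Character vector of known driver symbols.
#' @export
union_drivers <- function(bundle) {
  stopifnot(inherits(bundle, "benchmark_bundle"))
  unique(unlist(bundle$general, use.names = FALSE))
}

#' @export
print.benchmark_bundle <- function(x, ...) {
  cat("benchmark_bundle:", length(x$general), "general set(s) (union",
      length(union_drivers(x)), "genes),",
      if (is.null(x$specific)) "no" else length(x$specific), "specific,",
      if (is.null(x$false_positives)) "no" else length(x$false_positives),
      "false-positive genes\n")
  invisible(x)
}

ranking_genes <- function(ranking) {
  if (inherits(ranking, "gene_ranking")) ranking$gene
  else as.character(ranking)
}

#' Benchmark relevance of genes
#'
#' A gene's relevance is the number of general driver sets containing it,
#' plus 4 when it is a cancer-type-specific driver, minus 1 when it is a
#' likely false positive; a gene in no set has relevance 0. With four general
#' sets the range is `[-1, 8]`. Negative values are retained (no clipping).
#'
#' @param gene character vector of gene symbols.
#' @param bundle a [benchmark_bundle()].
#' @return Integer vector of relevances, one per input gene.
#' @export
relevance <- function(gene, bundle) {
  stopifnot(inherits(bundle, "benchmark_bundle"))
  if (bundle$uppercase) gene <- toupper(gene)
  rel <- integer(length(gene))
  for (s in bundle$general) rel <- rel + (gene %in% s)
  if (!is.null(bundle$specific)) rel <- rel + 4L * (gene %in% bundle$specific)
  if (!is.null(bundle$false_positives)) {
    rel <- rel - (gene %in% bundle$false_positives)
  }
  rel
}

#' Precision of the top of a ranking
#'
#' Fraction of the top-`p` ranked genes contained in the union of the
#' bundle's general driver sets.
#'
#' @param ranking a `gene_ranking` (or a character vector already in rank
#'   order).
#' @param bundle a [benchmark_bundle()].
#' @param p cutoff position, `1 <= p <= length(ranking)`.
#' @return Precision in `[0, 1]`.
#' @export
precision_at <- function(ranking, bundle, p) {
  g <- ranking_genes(ranking)
  if (length(p) != 1L || p < 1L || p > length(g)) {
    stop("'p' must be between 1 and the ranking length (", length(g), ")")
  }
  top <- g[seq_len(p)]
  if (bundle$uppercase) top <- toupper(top)
  mean(top %in% union_drivers(bundle))
}

#' Discounted cumulative gain of the top of a ranking
#'
#' `DCG_p = sum over positions i = 1..p of rel(gene_i) / log2(i + 1)`:
#' relevance credited with a logarithmic position discount, so placing strong
#' drivers early is rewarded.
#'
#' @inheritParams precision_at
#' @return The DCG value (can decrease with `p` when false-positive genes with
#'   negative relevance enter the list).
#' @export
dcg_at <- function(ranking, bundle, p) {
  g <- ranking_genes(ranking)
  if (length(p) != 1L || p < 1L || p > length(g)) {
    stop("'p' must be between 1 and the ranking length (", length(g), ")")
  }
  i <- seq_len(p)
  sum(relevance(g[i], bundle) / log2(i + 1))
}

#' Precision and DCG curves
#'
#' Evaluates [precision_at()] and [dcg_at()] for each cutoff, e.g. to plot
#' method comparisons over the top-N range.
#'
#' @inheritParams precision_at
#' @param p_values integer vector of cutoffs (default: every position).
#' @return data.frame with columns `p`, `precision`, `dcg`.
#' @export
evaluation_curves <- function(ranking, bundle,
                              p_values = seq_along(ranking_genes(ranking))) {
  data.frame(
    p = p_values,
    precision = vapply(p_values, function(p)
      precision_at(ranking, bundle, p), numeric(1)),
    dcg = vapply(p_values, function(p)
      dcg_at(ranking, bundle, p), numeric(1)))
}
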