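#' Gene score vector
#'
#' A named numeric vector of per-gene scores tagged with its kind: `wf`
#' (weighted mutation frequency), `nwf` (max-normalized wf), `r` (received
#' neighbor influence), `nr` (max-normalized r) or `ms` (final mutation
#' score, `nwf + nr`).
#'
#' @param x named numeric vector (names are gene symbols).
#' @param kind one of `"wf"`, `"nwf"`, `"r"`, `"nr"`, `"ms"`.
#' @return A `gene_scores` object.
#' @export
gene_scores <- function(x, kind) {
  stopifnot(is.numeric(x), !is.null(names(x)), all(nzchar(names(x))))
  kind <- match.arg(kind, c("wf", "nwf", "r", "nr", "ms"))
  structure(x, kind = kind, class = c("gene_scores", "numeric"))
}

#' @export
print.gene_scores <- function(x, ...) {
  cat("gene_scores (", attr(x, "kind"), "): ", length(x), " genes\n", sep = "")
  print(utils::head(sort(unclass(x), decreasing = TRUE), 10L))
  invisible(x)
}

score_kind <- function(x) attr(x, "kind")

#' Default mutation weight table
#'
#' Per-variant-class weights used to score individual mutations. These
#' defaults are a package choice guided by expected functional impact:
#' truncating and splice-disrupting classes weigh 1.0, in-frame coding changes
#' 0.5, and untranslated-region variants 0.2. They are intended to be
#' overridden to match the goal of the analysis (see [read_weight_table()]).
#'
#' @return Named numeric vector mapping `Variant_Classification` to weight.
#' @export
default_mutation_weights <- function() {
  c(Nonsense_Mutation = 1.0,
    Frame_Shift_Del = 1.0,
    Frame_Shift_Ins = 1.0,
    Nonstop_Mutation = 1.0,
    Splice_Site = 1.0,
    Translation_Start_Site = 1.0,
    Missense_Mutation = 0.5,
    In_Frame_Del = 0.5,
    In_Frame_Ins = 0.5,
    "3'UTR" = 0.2,
    "5'UTR" = 0.2)
}

#' Read a mutation weight table
#'
#' Two-column TSV (variant_class, weight), `#` comments allowed, no header
#' required (a `variant_class<TAB>weight` header line is recognized and
#' skipped). Weights must be non-negative.
#'
#' @param path path to the TSV file.
#' @return Named numeric vector of weights.
#' @export
read_weight_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          comment.char = "#", quote = "",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("weight table needs two columns: variant_class, weight")
  if (identical(tolower(df[1, 1]), "variant_class")) df <- df[-1, , drop = FALSE]
  w <- as.numeric(df[[2]])
  if (anyNA(w)) stop("non-numeric weight in weight table")
  if (any(w < 0)) stop("mutation weights must be non-negative")
  stats::setNames(w, as.character(df[[1]]))
}

#' Build the weighted mutation matrix
#'
#' For every (patient, gene) pair with at least one mutation, the entry is the
#' arithmetic mean of the weights of that pair's mutations. Pairs without
#' mutations carry an implicit zero and are not stored.
#'
#' @param table a [mutation_table()].
#' @param weights named numeric vector of per-variant-class weights; every
#'   variant class present in `table` must have an entry.
#' @return An object of class `wmm` with components `entries` (data.frame
#'   `patient`, `gene`, `wmm`), `patients` and `genes` (the table's
#'   universes).
#' @export
build_wmm <- function(table, weights = default_mutation_weights()) {
  stopifnot(inherits(table, "mutation_table"))
  rec <- table$records
  unknown <- setdiff(unique(rec$variant_class), names(weights))
  if (length(unknown) > 0L) {
    stop("no weight defined for variant class(es): ",
         paste(unknown, collapse = ", "))
  }
  if (nrow(rec) == 0L) {
    entries <- data.frame(patient = character(), gene = character(),
                          wmm = numeric())
  } else {
    w <- unname(weights[rec$variant_class])
    key <- paste(rec$patient, rec$gene, sep = "\r")
    means <- tapply(w, key, mean)
    split_key <- strsplit(names(means), "\r", fixed = TRUE)
    entries <- data.frame(
      patient = vapply(split_key, `[`, character(1), 1L),
      gene = vapply(split_key, `[`, character(1), 2L),
      wmm = unname(means))
  }
  structure(list(entries = entries,
                 patients = patients(table),
                 genes = genes(table)),
            class = "wmm")
}

#' @export
print.wmm <- function(x, ...) {
  cat("weighted mutation matrix:", length(x$patients), "patients x",
      length(x$genes), "genes,", nrow(x$entries), "non-zero entries\n")
  invisible(x)
}

#' Export a weighted mutation matrix as a dense TSV
#'
#' Patients as rows, genes as columns, 0 for pairs without mutations.
#'
#' @param wmm a `wmm` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_wmm <- function(wmm, path) {
  m <- matrix(0, nrow = length(wmm$patients), ncol = length(wmm$genes),
              dimnames = list(wmm$patients, wmm$genes))
  if (nrow(wmm$entries) > 0L) {
    m[cbind(wmm$entries$patient, wmm$entries$gene)] <- wmm$entries$wmm
  }
  utils::write.table(data.frame(patient = rownames(m), m,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Weighted mutation frequency per gene
#'
#' `wf(g)` is the sum of gene `g`'s weighted-mutation-matrix column over all
#' patients divided by the number of patients; pairs without mutations
#' contribute zero. Every gene of the mutation data receives a score.
#'
#' @param wmm a `wmm` object with at least one patient.
#' @return [gene_scores()] of kind `wf`.
#' @export
weighted_frequency <- function(wmm) {
  stopifnot(inherits(wmm, "wmm"))
  n_pat <- length(wmm$patients)
  if (n_pat == 0L) stop("weighted mutation matrix has no patients")
  wf <- stats::setNames(numeric(length(wmm$genes)), wmm$genes)
  if (nrow(wmm$entries) > 0L) {
    sums <- tapply(wmm$entries$wmm, wmm$entries$gene, sum)
    wf[names(sums)] <- sums / n_pat
  }
  gene_scores(wf, "wf")
}

#' Maximum-value normalization
#'
#' Divides every score by the maximum score. When the maximum is 0 (or the
#' scores are all zero) the formula would divide by zero; by convention all
#' outputs are then 0 and a warning is raised. The kind is mapped
#' `wf -> nwf`, `r -> nr`.
#'
#' @param scores non-empty [gene_scores()] (or a named numeric vector).
#' @return [gene_scores()] with values in `[0, 1]`; when any value is
#'   positive, the maximum is exactly 1.
#' @export
normalize_max <- function(scores) {
  stopifnot(length(scores) > 0L)
  kind <- if (inherits(scores, "gene_scores")) score_kind(scores) else "wf"
  out_kind <- switch(kind, wf = "nwf", r = "nr", kind)
  m <- max(scores)
  x <- unclass(scores)
  attributes(x) <- list(names = names(scores))
  if (m <= 0) {
    warning("maximum score is 0; returning all-zero normalized scores")
    x[] <- 0
  } else {
    x <- x / m
  }
  gene_scores(x, out_kind)
}
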