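#' Construct a mutation table
#'
#' A mutation table is the long-form record set extracted from a MAF file:
#' one row per somatic mutation event, with the patient (sample barcode), the
#' mutated gene symbol and the MAF `Variant_Classification`. Duplicate
#' (patient, gene, variant_class) rows are retained: multiple mutations of the
#' same type in the same gene of the same patient are distinct events.
#'
#' @param records data.frame with at least the character columns `patient`,
#'   `gene` and `variant_class`. Extra columns (e.g. carried over from a MAF
#'   file) are kept and written back by [write_maf()]. Rows with an empty or
#'   missing patient or gene are dropped with a message.
#' @return An object of class `mutation_table` wrapping the record
#'   data.frame.
#' @seealso [read_maf()], [filter_variant_classes()], [remove_hypermutated()]
#' @export
mutation_table <- function(records) {
  stopifnot(is.data.frame(records))
  need <- c("patient", "gene", "variant_class")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols) > 0L) {
    stop("mutation records are missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  for (col in need) records[[col]] <- as.character(records[[col]])
  bad <- is.na(records$patient) | !nzchar(records$patient) |
    is.na(records$gene) | !nzchar(records$gene)
  if (any(bad)) {
    message("dropping ", sum(bad), " record(s) with empty patient or gene")
    records <- records[!bad, , drop = FALSE]
  }
  rownames(records) <- NULL
  structure(list(records = records), class = "mutation_table")
}

#' @export
print.mutation_table <- function(x, ...) {
  cat("mutation_table:", nrow(x$records), "mutation records,",
      length(patients(x)), "patients,", length(genes(x)), "genes\n")
  invisible(x)
}

#' Patients and genes of a mutation table
#'
#' The patient and gene universes are always recomputed from the current
#' records, so filtering operations keep them consistent.
#'
#' @param x a `mutation_table`.
#' @return Character vector of unique patient barcodes / gene symbols.
#' @export
patients <- function(x) UseMethod("patients")

#' @export
patients.mutation_table <- function(x) unique(x$records$patient)

#' @rdname patients
#' @export
genes <- function(x) UseMethod("genes")

#' @export
genes.mutation_table <- function(x) unique(x$records$gene)

#' Read a MAF file
#'
#' Reads a tab-separated Mutation Annotation Format file. Lines starting with
#' `#` (e.g. `#version`) are treated as comments. The columns `Hugo_Symbol`,
#' `Tumor_Sample_Barcode` and `Variant_Classification` are required; any
#' further columns are kept verbatim.
#'
#' @param path path to a MAF file.
#' @return A [mutation_table()].
#' @export
read_maf <- function(path) {
  if (!file.exists(path)) stop("cannot read MAF file: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          comment.char = "#", quote = "",
                          colClasses = "character", check.names = FALSE)
  req <- c("Hugo_Symbol", "Tumor_Sample_Barcode", "Variant_Classification")
  absent <- setdiff(req, names(df))
  if (length(absent) > 0L) {
    stop("MAF file is missing required column(s): ",
         paste(absent, collapse = ", "))
  }
  names(df)[match(req, names(df))] <- c("gene", "patient", "variant_class")
  mutation_table(df)
}

#' Write a mutation table as a MAF-like TSV
#'
#' The three core columns are written under their standard MAF names; any
#' extra columns carried by the table are preserved. Records are written in
#' their current order, so a table produced by a seeded generator round-trips
#' byte-identically.
#'
#' @param table a `mutation_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_maf <- function(table, path) {
  stopifnot(inherits(table, "mutation_table"))
  df <- table$records
  core <- c("gene", "patient", "variant_class")
  names(df)[match(core, names(df))] <-
    c("Hugo_Symbol", "Tumor_Sample_Barcode", "Variant_Classification")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Default somatic variant-class whitelist
#'
#' The eleven variant classifications retained by the preprocessing routine:
#' exonic and splice-relevant consequences plus UTRs. Silent mutations and
#' intronic/intergenic records are excluded.
#'
#' @return Character vector of `Variant_Classification` values.
#' @export
default_variant_whitelist <- function() {
  c("3'UTR", "5'UTR",
    "Frame_Shift_Del", "Frame_Shift_Ins",
    "In_Frame_Del", "In_Frame_Ins",
    "Missense_Mutation", "Nonsense_Mutation", "Nonstop_Mutation",
    "Splice_Site", "Translation_Start_Site")
}

#' Keep only whitelisted variant classes
#'
#' @param table a `mutation_table`.
#' @param allowed non-empty character vector of variant classes to keep;
#'   defaults to [default_variant_whitelist()].
#' @param ignore_case match variant classes case-insensitively (for messy MAF
#'   dialects); default is exact, case-sensitive matching.
#' @return A `mutation_table` containing exactly the records whose
#'   `variant_class` is in `allowed`; patients/genes that lose all records
#'   disappear from the universes.
#' @export
filter_variant_classes <- function(table,
                                   allowed = default_variant_whitelist(),
                                   ignore_case = FALSE) {
  stopifnot(inherits(table, "mutation_table"))
  if (length(allowed) == 0L) stop("'allowed' must be non-empty")
  vc <- table$records$variant_class
  keep <- if (ignore_case) tolower(vc) %in% tolower(allowed) else vc %in% allowed
  mutation_table(table$records[keep, , drop = FALSE])
}

#' Remove hypermutated samples
#'
#' A sample is hypermutated when its total mutation count exceeds
#' `Q3 + 4.5 * IQR` of the per-patient mutation-count distribution (strictly
#' greater, i.e. "more than"). Quartiles use linear interpolation between
#' order statistics (`stats::quantile` type 7). Counts are computed on the
#' table as given, so the caller controls whether variant-class filtering has
#' already been applied (the pipeline filters first).
#'
#' @param table a `mutation_table` with at least one patient.
#' @return A list with components `table` (the filtered `mutation_table`),
#'   `removed` (character vector of removed patient barcodes), `threshold`
#'   (the numeric cutoff) and `counts` (named per-patient mutation counts of
#'   the input).
#' @export
remove_hypermutated <- function(table) {
  stopifnot(inherits(table, "mutation_table"))
  if (length(patients(table)) == 0L) stop("mutation table has no patients")
  counts <- c(table(table$records$patient))
  q3 <- stats::quantile(counts, 0.75, type = 7, names = FALSE)
  iqr <- stats::IQR(counts, type = 7)
  threshold <- q3 + 4.5 * iqr
  removed <- names(counts)[counts > threshold]
  keep <- !(table$records$patient %in% removed)
  out <- mutation_table(table$records[keep, , drop = FALSE])
  message("hypermutation threshold Q3 + 4.5*IQR = ", format(threshold),
          "; removed ", length(removed), " of ", length(counts), " samples")
  list(table = out, removed = removed, threshold = threshold, counts = counts)
}

#' Write the removed-sample report
#'
#' @param result the list returned by [remove_hypermutated()].
#' @param path output TSV path (columns: patient, count, threshold).
#' @return `path`, invisibly.
#' @export
write_hypermutation_report <- function(result, path) {
  df <- data.frame(patient = result$removed,
                   count = unname(result$counts[result$removed]),
                   threshold = rep(result$threshold, length(result$removed)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
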