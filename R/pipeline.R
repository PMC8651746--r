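`%||%` <- function(a, b) if (is.null(a)) b else a

log_msg <- function(verbose, ...) if (verbose) message(...)

#' Run the full gene-prioritization pipeline
#'
#' Executes the method end to end: MAF preprocessing (variant-class
#' whitelist, hypermutated-sample removal), weighted mutation scoring,
#' optional overlap-coefficient network enrichment of each input network,
#' consensus (union) of the networks, the directed spreading-strength network,
#' neighbor mutation influence, and the final ranking by
#' `ms = nwf + nr`.
#'
#' @param maf a [mutation_table()] or a path to a MAF file.
#' @param networks non-empty list of undirected igraphs and/or edge-list
#'   paths.
#' @param weights named numeric vector of variant-class weights
#'   (default [default_mutation_weights()]).
#' @param variant_whitelist variant classes to keep, or `NULL` to skip the
#'   filter; default [default_variant_whitelist()].
#' @param remove_hypermutated_samples apply the `Q3 + 4.5 * IQR` outlier rule
#'   after variant filtering (default `TRUE`).
#' @param ignore_case_variants case-insensitive variant-class matching for the
#'   whitelist.
#' @param enrich apply per-network link prediction before the union: each
#'   network is scored with [score_all_pairs()] and thresholded with
#'   [enrich_network()].
#' @param pathways named list of gene sets used by [select_gamma()] when
#'   `enrich = TRUE` and no `gamma` is given.
#' @param n_random random sets per pathway for the threshold calibration.
#' @param gamma optional fixed enrichment threshold (skips calibration).
#' @param keep_original_edges passed to [enrich_network()].
#' @param include_source passed to [build_gssn()].
#' @param restrict_to_mutated limit the output ranking to genes present in the
#'   mutation data (default: union of mutated and network genes).
#' @param seed seed for the threshold calibration draws.
#' @param out_dir optional directory; when given, writes `ranking.tsv`,
#'   `gssn.tsv`, `removed_samples.tsv` and `run_log.txt`.
#' @param verbose emit per-stage progress messages.
#' @return A list with `ranking` (data.frame `rank`, `gene`, `nwf`, `nr`,
#'   `ms`), `scores` (the `wf`/`nwf`/`r`/`nr`/`ms` [gene_scores()]), `ugn`,
#'   `gssn`, `removed`, `threshold` and `gamma` (per-network thresholds used,
#'   or `NULL`).
#' @export
run_discage <- function(maf, networks,
                        weights = default_mutation_weights(),
                        variant_whitelist = default_variant_whitelist(),
                        remove_hypermutated_samples = TRUE,
                        ignore_case_variants = FALSE,
                        enrich = FALSE, pathways = NULL, n_random = 10,
                        gamma = NULL, keep_original_edges = FALSE,
                        include_source = FALSE,
                        restrict_to_mutated = FALSE,
                        seed = NULL, out_dir = NULL, verbose = TRUE) {
  if (!is.list(networks) || length(networks) == 0L) {
    stop("at least one gene interaction network is required")
  }
  table <- if (is.character(maf)) read_maf(maf) else maf
  stopifnot(inherits(table, "mutation_table"))
  log_msg(verbose, "read ", nrow(table$records), " mutation records (",
          length(patients(table)), " patients, ", length(genes(table)),
          " genes)")

  if (!is.null(variant_whitelist)) {
    table <- filter_variant_classes(table, variant_whitelist,
                                    ignore_case = ignore_case_variants)
    log_msg(verbose, "variant-class whitelist kept ", nrow(table$records),
            " records")
  }
  removed <- character(); threshold <- NA_real_; hyper <- NULL
  if (remove_hypermutated_samples) {
    hyper <- withCallingHandlers(
      remove_hypermutated(table),
      message = function(m) if (!verbose) invokeRestart("muffleMessage"))
    table <- hyper$table
    removed <- hyper$removed
    threshold <- hyper$threshold
  }

  wmm <- build_wmm(table, weights)
  wf <- weighted_frequency(wmm)
  nwf <- normalize_max(wf)

  nets <- lapply(networks, function(x)
    if (is.character(x)) read_edge_list(x) else x)
  gammas <- NULL
  if (enrich) {
    if (is.null(gamma) && is.null(pathways)) {
      stop("network enrichment needs either 'pathways' (to calibrate gamma) or a fixed 'gamma'")
    }
    gammas <- numeric(length(nets))
    nets <- lapply(seq_along(nets), function(k) {
      wgn <- score_all_pairs(nets[[k]])
      g <- gamma %||% select_gamma(wgn, pathways, n_random = n_random,
                                   seed = seed)$gamma
      gammas[k] <<- g
      e <- enrich_network(nets[[k]], wgn, g,
                          keep_original_edges = keep_original_edges)
      log_msg(verbose, "network ", k, ": gamma = ", format(g), ", ",
              igraph::ecount(nets[[k]]), " edges -> ",
              igraph::ecount(e), " enriched edges")
      e
    })
  }

  ugn <- union_networks(nets)
  log_msg(verbose, "consensus network: ", igraph::vcount(ugn), " genes, ",
          igraph::ecount(ugn), " edges")
  gssn <- build_gssn(ugn, nwf, include_source = include_source)
  log_msg(verbose, "max raw spreading strength = ",
          format(if (igraph::ecount(gssn) > 0)
            max(igraph::E(gssn)$ss) else 0))
  infl <- neighbor_influence(gssn)
  ms <- final_scores(nwf, infl$nr)
  if (restrict_to_mutated) {
    keep <- names(ms) %in% genes(table)
    ms <- gene_scores(unclass(ms)[keep], "ms")
  }
  ranking <- rank_genes(ms)
  nwf_all <- stats::setNames(numeric(nrow(ranking)), ranking$gene)
  nwf_all[intersect(names(nwf), ranking$gene)] <-
    unclass(nwf)[intersect(names(nwf), ranking$gene)]
  nr_all <- stats::setNames(numeric(nrow(ranking)), ranking$gene)
  nr_all[intersect(names(infl$nr), ranking$gene)] <-
    unclass(infl$nr)[intersect(names(infl$nr), ranking$gene)]
  ranking$nwf <- unname(nwf_all[ranking$gene])
  ranking$nr <- unname(nr_all[ranking$gene])
  ranking <- ranking[, c("rank", "gene", "nwf", "nr", "ms")]
  class(ranking) <- c("gene_ranking", "data.frame")
  attr(ranking, "tie_policy") <- "lexicographic by gene symbol"

  result <- list(ranking = ranking,
                 scores = list(wf = wf, nwf = nwf, r = infl$r, nr = infl$nr,
                               ms = ms),
                 ugn = ugn, gssn = gssn,
                 removed = removed, threshold = threshold, gamma = gammas)
  if (!is.null(out_dir)) write_run_artifacts(result, hyper, out_dir,
                                             maf, networks)
  result
}

write_run_artifacts <- function(result, hyper, out_dir, maf, networks) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(as.data.frame(result$ranking),
                     file.path(out_dir, "ranking.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_gssn(result$gssn, file.path(out_dir, "gssn.tsv"))
  if (!is.null(hyper)) {
    write_hypermutation_report(hyper, file.path(out_dir, "removed_samples.tsv"))
  }
  input_files <- c(if (is.character(maf)) maf,
                   unlist(Filter(is.character, networks)))
  checksums <- if (length(input_files) > 0)
    paste0(names(tools::md5sum(input_files)), " md5=",
           tools::md5sum(input_files)) else character()
  log <- c(paste0("genes_ranked\t", nrow(result$ranking)),
           paste0("patients_removed\t", length(result$removed)),
           paste0("hypermutation_threshold\t", format(result$threshold)),
           paste0("gamma\t", paste(format(result$gamma), collapse = ",")),
           paste0("input\t", checksums))
  writeLines(log, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' Frequency-only baseline ranking
#'
#' Ranks the same gene universe by the normalized weighted mutation frequency
#' alone (no network influence), with the same lexicographic tie policy. Used
#' as the comparison baseline when measuring what the network adds.
#'
#' @param nwf [gene_scores()] of kind `nwf`.
#' @param universe optional gene universe; genes without a score get 0.
#' @return A `gene_ranking`.
#' @export
frequency_ranking <- function(nwf, universe = names(nwf)) {
  x <- stats::setNames(numeric(length(universe)), universe)
  common <- intersect(names(nwf), universe)
  x[common] <- unclass(nwf)[common]
  rank_genes(gene_scores(x, "ms"))
}

#' Planted-driver recovery benchmark
#'
#' Repeatedly simulates a cohort plus networks with planted driver modules,
#' runs the full pipeline and a frequency-only baseline, and measures for each
#' replicate the fraction of planted drivers recovered in the top-k of each
#' ranking (k = number of planted drivers). Because the planted drivers are
#' individually low-frequency but network-coherent, the gap between the two
#' recoveries measures what the network influence contributes.
#'
#' @param config a [fixture_config()]; each replicate uses a seed derived
#'   from `config$seed` and the replicate index.
#' @param n_seeds number of simulation replicates.
#' @return A list with `per_seed` (data.frame: seed, recovery of the network
#'   method and of the frequency baseline), `mean_network` and
#'   `mean_frequency`.
#' @export
driver_recovery_benchmark <- function(config = fixture_config(),
                                      n_seeds = 20L) {
  stopifnot(inherits(config, "fixture_config"), n_seeds >= 1L)
  rec_net <- numeric(n_seeds)
  rec_freq <- numeric(n_seeds)
  seeds <- config$seed + 7919L * seq_len(n_seeds)
  for (s in seq_len(n_seeds)) {
    cfg <- config
    cfg$seed <- seeds[s]
    cohort <- simulate_cohort(cfg)
    nets <- simulate_networks(cfg)
    res <- run_discage(cohort$table, nets$networks, verbose = FALSE)
    k <- length(cohort$drivers)
    rec_net[s] <- mean(utils::head(res$ranking$gene, k) %in% cohort$drivers)
    freq <- frequency_ranking(res$scores$nwf,
                              universe = res$ranking$gene)
    rec_freq[s] <- mean(utils::head(freq$gene, k) %in% cohort$drivers)
  }
  list(per_seed = data.frame(seed = seeds, network = rec_net,
                             frequency = rec_freq),
       mean_network = mean(rec_net),
       mean_frequency = mean(rec_freq))
}
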