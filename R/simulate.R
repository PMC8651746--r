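#' Configuration for the synthetic-cohort generator
#'
#' Defines a toy study: a cohort of patients with a long-tail mutation
#' landscape (a few frequently mutated genes, many infrequently mutated ones),
#' a handful of planted "driver modules" — connected gene groups whose members
#' are each mutated at low frequency but which are collectively enriched and
#' network-adjacent — plus hypermutated outlier samples, and noisy replicate
#' interaction networks over the same genes.
#'
#' Driver events are drawn per patient and module: with probability
#' `driver_mutation_rate` one uniformly chosen gene of the module is mutated,
#' so each individual driver gene is hit in roughly
#' `driver_mutation_rate / module_size` of patients — deliberately close to
#' the background rate, which is what makes the planted drivers hard for a
#' frequency-only ranking and recoverable through their network coherence.
#'
#' @param n_patients cohort size.
#' @param n_genes gene universe size.
#' @param n_driver_modules,module_size number and size of planted driver
#'   modules (`n_driver_modules * module_size <= n_genes` required at
#'   generation time).
#' @param background_mutation_rate per patient-gene probability of a passenger
#'   mutation.
#' @param driver_mutation_rate per patient-module probability of one driver
#'   event in that module.
#' @param hypermutator_fraction fraction of patients whose background rate is
#'   inflated by `hypermutator_factor` (outliers the preprocessing should
#'   remove).
#' @param hypermutator_factor background-rate multiplier for hypermutators.
#' @param variant_class_distribution named probability vector over variant
#'   classes (must sum to 1); the default mixes the whitelisted classes with
#'   some Silent and Intron records so that variant-class filtering is
#'   exercised.
#' @param n_networks number of noisy network replicates.
#' @param edge_noise fraction of each replicate's edges removed and replaced
#'   by random pairs.
#' @param seed integer seed fixing the full generation stream.
#' @return A `fixture_config` list.
#' @export
fixture_config <- function(n_patients = 60L,
                           n_genes = 80L,
                           n_driver_modules = 3L,
                           module_size = 5L,
                           background_mutation_rate = 0.02,
                           driver_mutation_rate = 0.25,
                           hypermutator_fraction = 0.05,
                           hypermutator_factor = 25,
                           variant_class_distribution = NULL,
                           n_networks = 2L,
                           edge_noise = 0.1,
                           seed = 1L) {
  if (is.null(variant_class_distribution)) {
    variant_class_distribution <- c(
      Missense_Mutation = 0.45, Nonsense_Mutation = 0.10,
      Frame_Shift_Del = 0.05, Frame_Shift_Ins = 0.05,
      Splice_Site = 0.05, In_Frame_Del = 0.03, In_Frame_Ins = 0.02,
      "3'UTR" = 0.05, "5'UTR" = 0.05,
      Silent = 0.10, Intron = 0.05)
  }
  stopifnot(abs(sum(variant_class_distribution) - 1) < 1e-8,
            all(variant_class_distribution >= 0),
            background_mutation_rate >= 0, background_mutation_rate <= 1,
            driver_mutation_rate >= 0, driver_mutation_rate <= 1,
            hypermutator_fraction >= 0, hypermutator_fraction <= 1)
  structure(list(n_patients = as.integer(n_patients),
                 n_genes = as.integer(n_genes),
                 n_driver_modules = as.integer(n_driver_modules),
                 module_size = as.integer(module_size),
                 background_mutation_rate = background_mutation_rate,
                 driver_mutation_rate = driver_mutation_rate,
                 hypermutator_fraction = hypermutator_fraction,
                 hypermutator_factor = hypermutator_factor,
                 variant_class_distribution = variant_class_distribution,
                 n_networks = as.integer(n_networks),
                 edge_noise = edge_noise,
                 seed = as.integer(seed)),
            class = "fixture_config")
}

fixture_gene_names <- function(config) {
  sprintf("G%03d", seq_len(config$n_genes))
}

# Module membership is drawn from the seed with an isolated RNG excursion so
# cohort and network generation see identical modules without disturbing their
# own streams. Drivers sit at random positions in the gene universe: planting
# them at fixed (e.g. leading) positions would correlate the truth with the
# ranking's lexicographic tie policy and bias method comparisons.
fixture_modules <- function(config) {
  gene_names <- fixture_gene_names(config)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(config$seed + 2L)
  chosen <- sample(gene_names,
                   config$n_driver_modules * config$module_size)
  unname(split(chosen, rep(seq_len(config$n_driver_modules),
                           each = config$module_size)))
}

#' Generate a synthetic mutation cohort
#'
#' Draws a seeded cohort according to a [fixture_config()]: background
#' passenger mutations per patient-gene, one low-frequency driver event per
#' patient-module with the configured probability, and hypermutated outlier
#' patients with an inflated background rate. Variant classes are sampled
#' from the configured distribution. Generation order is fixed by the seed,
#' so the emitted records (and a MAF written from them) are byte-identical
#' across runs.
#'
#' @param config a [fixture_config()].
#' @return A list with `table` (a [mutation_table()]), `drivers` (the planted
#'   driver genes), `modules` (list of driver modules) and `hypermutators`
#'   (the inflated patients).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "fixture_config"))
  if (config$n_driver_modules * config$module_size > config$n_genes) {
    stop("infeasible config: module_size * n_driver_modules exceeds n_genes")
  }
  set.seed(config$seed)
  gene_names <- fixture_gene_names(config)
  patient_names <- sprintf("P%03d", seq_len(config$n_patients))
  modules <- fixture_modules(config)
  drivers <- unlist(modules)
  n_hyper <- round(config$hypermutator_fraction * config$n_patients)
  hypermutators <- if (n_hyper > 0) sample(patient_names, n_hyper) else character()
  dist <- config$variant_class_distribution

  rows <- vector("list", config$n_patients)
  for (i in seq_len(config$n_patients)) {
    pat <- patient_names[i]
    rate <- config$background_mutation_rate *
      if (pat %in% hypermutators) config$hypermutator_factor else 1
    rate <- min(rate, 1)
    hit <- gene_names[stats::runif(config$n_genes) < rate]
    for (mod in modules) {
      if (stats::runif(1) < config$driver_mutation_rate) {
        hit <- c(hit, sample(mod, 1L))
      }
    }
    if (length(hit) == 0L) next
    rows[[i]] <- data.frame(
      patient = pat,
      gene = hit,
      variant_class = sample(names(dist), length(hit),
                             replace = TRUE, prob = dist))
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  records <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(patient = character(), gene = character(),
               variant_class = character())
  list(table = mutation_table(records),
       drivers = drivers,
       modules = modules,
       hypermutators = sort(hypermutators))
}

rewire_edges <- function(edges_df, node_names, noise) {
  m <- nrow(edges_df)
  n_swap <- floor(noise * m)
  if (n_swap == 0L || m == 0L) return(edges_df)
  existing <- function(d) paste(pmin(d$from, d$to), pmax(d$from, d$to), sep = "\t")
  drop <- sample.int(m, n_swap)
  kept <- edges_df[-drop, , drop = FALSE]
  keys <- existing(kept)
  added <- 0L
  new_from <- character(n_swap); new_to <- character(n_swap)
  guard <- 0L
  while (added < n_swap && guard < 50L * n_swap) {
    guard <- guard + 1L
    pair <- sample(node_names, 2L)
    k <- paste(min(pair), max(pair), sep = "\t")
    if (!(k %in% keys)) {
      added <- added + 1L
      new_from[added] <- pair[1L]; new_to[added] <- pair[2L]
      keys <- c(keys, k)
    }
  }
  rbind(kept, data.frame(from = new_from[seq_len(added)],
                         to = new_to[seq_len(added)]))
}

#' Generate synthetic interaction networks and pathway sets
#'
#' Builds a scale-free background graph (preferential attachment, the typical
#' degree structure of protein-interaction networks) over the cohort's genes,
#' overlays each planted driver module as a clique so that drivers are
#' network-adjacent, and emits `n_networks` noisy replicates in which a
#' fraction `edge_noise` of edges is replaced by random pairs. Also returns a
#' pathway collection containing the driver modules (coherent sets) plus an
#' equal number of random same-size gene sets, for exercising threshold
#' calibration.
#'
#' @param config a [fixture_config()].
#' @return A list with `networks` (list of undirected igraphs), `base` (the
#'   noise-free graph) and `pathways` (named list of gene sets; module sets
#'   are named `module_*`, random ones `random_*`).
#' @export
simulate_networks <- function(config) {
  stopifnot(inherits(config, "fixture_config"))
  if (config$n_driver_modules * config$module_size > config$n_genes) {
    stop("infeasible config: module_size * n_driver_modules exceeds n_genes")
  }
  set.seed(config$seed + 1L)
  gene_names <- fixture_gene_names(config)
  modules <- fixture_modules(config)

  base <- igraph::sample_pa(config$n_genes, m = 2, directed = FALSE)
  # detach module genes from the preferential-attachment hub positions
  igraph::V(base)$name <- sample(gene_names)
  base_df <- igraph::as_data_frame(base, what = "edges")
  mod_edges <- do.call(rbind, lapply(modules, function(mod) {
    pr <- utils::combn(mod, 2L)
    data.frame(from = pr[1L, ], to = pr[2L, ])
  }))
  base_net <- gene_network(rbind(base_df[, c("from", "to")], mod_edges),
                           nodes = gene_names)

  base_edges <- igraph::as_data_frame(base_net, what = "edges")[, c("from", "to")]
  networks <- lapply(seq_len(config$n_networks), function(k) {
    gene_network(rewire_edges(base_edges, gene_names, config$edge_noise),
                 nodes = gene_names)
  })

  random_sets <- lapply(seq_along(modules), function(m) {
    sort(sample(gene_names, config$module_size))
  })
  pathways <- c(stats::setNames(modules,
                                paste0("module_", seq_along(modules))),
                stats::setNames(random_sets,
                                paste0("random_", seq_along(random_sets))))
  list(networks = networks, base = base_net, pathways = pathways)
}

#' Write a full synthetic fixture set to disk
#'
#' Emits the MAF, one edge list per network, a GMT pathway file and a
#' plain-text truth file of planted drivers, all in canonical order.
#'
#' @param config a [fixture_config()].
#' @param out_dir output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_fixtures <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- simulate_cohort(config)
  nets <- simulate_networks(config)
  paths <- c(maf = file.path(out_dir, "cohort.maf"),
             gmt = file.path(out_dir, "pathways.gmt"),
             truth = file.path(out_dir, "drivers.txt"))
  write_maf(cohort$table, paths[["maf"]])
  write_gmt(nets$pathways, paths[["gmt"]])
  writeLines(sort(cohort$drivers), paths[["truth"]])
  for (k in seq_along(nets$networks)) {
    p <- file.path(out_dir, sprintf("network_%d.tsv", k))
    write_edge_list(nets$networks[[k]], p)
    paths[[sprintf("network_%d", k)]] <- p
  }
  invisible(paths)
}
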