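# Independent brute-force oracles: plain base-R set arithmetic over record
# lists and edge tables. Deliberately share no code (and no igraph) with the
# package implementation.

oracle_nbrs <- function(edges, v) {
  unique(c(edges$to[edges$from == v], edges$from[edges$to == v]))
}

oracle_edge_weight <- function(edges, a, b) {
  hit <- (edges$from == a & edges$to == b) | (edges$from == b & edges$to == a)
  if (!any(hit)) 0 else edges$weight[hit][1]
}

oracle_ssc <- function(edges, a, b) {
  na <- unique(c(a, oracle_nbrs(edges, a)))
  nb <- unique(c(b, oracle_nbrs(edges, b)))
  length(intersect(na, nb)) / min(length(na), length(nb))
}

oracle_ss <- function(edges, i, j, include_source = FALSE) {
  p_ij <- oracle_edge_weight(edges, i, j)
  r_i <- sum(vapply(oracle_nbrs(edges, i), function(g)
    oracle_edge_weight(edges, i, g), numeric(1)))
  excluded <- oracle_nbrs(edges, i)
  if (!include_source) excluded <- c(excluded, i)
  outward <- setdiff(oracle_nbrs(edges, j), excluded)
  r_out <- if (length(outward) == 0) 0 else
    sum(vapply(outward, function(g) oracle_edge_weight(edges, j, g),
               numeric(1)))
  (1 + r_i * r_out) * p_ij
}

# full Step 4-6 trace: raw ss on both directions of every edge, global-max
# normalization, received influence, final scores
oracle_trace <- function(edges, nodes, nwf) {
  nwf_full <- setNames(numeric(length(nodes)), nodes)
  nwf_full[intersect(names(nwf), nodes)] <- nwf[intersect(names(nwf), nodes)]
  arcs <- data.frame(from = character(), to = character(), ss = numeric())
  if (nrow(edges) > 0) {
    for (k in seq_len(nrow(edges))) {
      a <- edges$from[k]; b <- edges$to[k]
      arcs <- rbind(arcs,
                    data.frame(from = c(a, b), to = c(b, a),
                               ss = c(oracle_ss(edges, a, b),
                                      oracle_ss(edges, b, a))))
    }
  }
  mx <- if (nrow(arcs) > 0) max(arcs$ss) else 0
  arcs$nss <- if (mx > 0) arcs$ss / mx else rep(0, nrow(arcs))
  r <- setNames(numeric(length(nodes)), nodes)
  for (k in seq_len(nrow(arcs))) {
    r[arcs$to[k]] <- r[arcs$to[k]] + nwf_full[arcs$from[k]] * arcs$nss[k]
  }
  nr <- if (max(r) > 0) r / max(r) else r * 0
  ms <- nwf_full + nr
  list(arcs = arcs, r = r, nr = nr, ms = ms)
}

oracle_wmm <- function(records, weights) {
  pairs <- unique(records[, c("patient", "gene")])
  vals <- numeric(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    sel <- records$patient == pairs$patient[k] & records$gene == pairs$gene[k]
    vals[k] <- mean(weights[records$variant_class[sel]])
  }
  pairs$wmm <- vals
  pairs
}

oracle_wf <- function(records, weights) {
  n_pat <- length(unique(records$patient))
  pairs <- oracle_wmm(records, weights)
  sapply(split(pairs$wmm, pairs$gene), sum) / n_pat
}

# random fixtures -----------------------------------------------------------

random_graph_df <- function(n_nodes, p_edge = 0.25, weighted = TRUE) {
  nodes <- sprintf("n%02d", seq_len(n_nodes))
  if (n_nodes < 2) {
    return(list(nodes = nodes,
                edges = data.frame(from = character(), to = character(),
                                   weight = numeric())))
  }
  pairs <- t(combn(nodes, 2))
  keep <- runif(nrow(pairs)) < p_edge
  edges <- data.frame(from = pairs[keep, 1], to = pairs[keep, 2])
  edges$weight <- if (weighted) round(runif(nrow(edges), 0.1, 1), 3) else
    rep(1, nrow(edges))
  list(nodes = nodes, edges = edges)
}

random_records <- function(n_patients, n_genes, classes, max_events = 40) {
  n <- sample.int(max_events, 1)
  data.frame(patient = sample(sprintf("p%02d", seq_len(n_patients)), n,
                              replace = TRUE),
             gene = sample(sprintf("g%02d", seq_len(n_genes)), n,
                           replace = TRUE),
             variant_class = sample(classes, n, replace = TRUE))
}

# small MAF writer for parser tests
write_toy_maf <- function(df, path, comment = TRUE) {
  lines <- c(if (comment) "#version 2.4",
             paste("Hugo_Symbol", "Tumor_Sample_Barcode",
                   "Variant_Classification", "Extra", sep = "\t"),
             paste(df$gene, df$patient, df$variant_class, "x", sep = "\t"))
  writeLines(lines, path)
  path
}

path_abc <- function() {
  gene_network(data.frame(from = c("a", "b"), to = c("b", "c")))
}
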