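#' Build an undirected gene network from an edge table
#'
#' Canonicalizes an edge table into an undirected igraph: self-loops are
#' dropped (with a message), each unordered pair is stored once, and duplicate
#' edges are collapsed keeping the weight of the last occurrence. Missing
#' weights default to 1.
#'
#' @param edges data.frame whose first two columns are gene symbols; an
#'   optional third numeric column is the edge weight.
#' @param nodes optional character vector of additional (possibly isolated)
#'   nodes to include.
#' @return An undirected igraph with an edge attribute `weight`.
#' @export
gene_network <- function(edges, nodes = NULL) {
  stopifnot(is.data.frame(edges))
  if (nrow(edges) > 0L && ncol(edges) < 2L) {
    stop("edge table needs at least two columns")
  }
  if (nrow(edges) == 0L) {
    g <- igraph::make_empty_graph(n = 0, directed = FALSE)
    if (length(nodes) > 0L) {
      g <- igraph::add_vertices(g, length(unique(nodes)), name = unique(nodes))
    }
    return(g)
  }
  a <- as.character(edges[[1]])
  b <- as.character(edges[[2]])
  w <- if (ncol(edges) >= 3L) as.numeric(edges[[3]]) else rep(1, length(a))
  nodes <- unique(c(a, b, nodes))
  loops <- a == b
  if (any(loops)) {
    message("dropping ", sum(loops), " self-loop(s)")
    a <- a[!loops]; b <- b[!loops]; w <- w[!loops]
  }
  from <- pmin(a, b); to <- pmax(a, b)
  key <- paste(from, to, sep = "\t")
  last <- !duplicated(key, fromLast = TRUE)
  d <- data.frame(from = from[last], to = to[last], weight = w[last])
  verts <- unique(c(d$from, d$to, nodes))
  igraph::graph_from_data_frame(d, directed = FALSE, vertices = verts)
}

#' Read a gene network from an edge-list TSV
#'
#' Two columns (gene A, gene B) with an optional third weight column, no
#' header, `#` comments allowed. Duplicates and self-loops are canonicalized
#' by [gene_network()].
#'
#' @param path path to the edge list.
#' @return An undirected igraph; an empty file yields an empty network with a
#'   warning.
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) stop("cannot read edge list: ", path)
  df <- tryCatch(
    utils::read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                      quote = "", stringsAsFactors = FALSE),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e))) NULL else stop(e)
    })
  if (is.null(df)) {
    warning("empty edge list: ", path)
    return(gene_network(data.frame(from = character(), to = character())))
  }
  if (ncol(df) < 2L) stop("edge list needs at least two columns: ", path)
  gene_network(df)
}

#' Write a network as an edge-list TSV
#'
#' Edges are written in canonical (lexicographic) order for byte-stable
#' output; a third column carries the weight when the network is weighted.
#'
#' @param net an igraph.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  d <- igraph::as_data_frame(net, what = "edges")
  if (nrow(d) > 0L) {
    from <- pmin(d$from, d$to); to <- pmax(d$from, d$to)
    d$from <- from; d$to <- to
    d <- d[order(d$from, d$to), , drop = FALSE]
  }
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Consensus (union) of gene networks
#'
#' The union gene network (UGN) contains every node and every edge occurring
#' in any input network; the weight of an edge is the fraction of input
#' networks that contain it, i.e. values lie in `{1/N, 2/N, ..., 1}`. Edges
#' present in more networks are considered more reliable and weigh more.
#'
#' @param networks non-empty list of undirected igraphs.
#' @return An undirected, weighted igraph (the UGN).
#' @export
union_networks <- function(networks) {
  if (!is.list(networks) || length(networks) == 0L) {
    stop("'networks' must be a non-empty list of networks")
  }
  stopifnot(all(vapply(networks, igraph::is_igraph, logical(1))))
  if (any(vapply(networks, igraph::is_directed, logical(1)))) {
    stop("all input networks must be undirected")
  }
  n <- length(networks)
  pair_tabs <- lapply(networks, function(g) {
    d <- igraph::as_data_frame(g, what = "edges")
    if (nrow(d) == 0L) return(character())
    unique(paste(pmin(d$from, d$to), pmax(d$from, d$to), sep = "\t"))
  })
  counts <- table(unlist(pair_tabs))
  verts <- unique(unlist(lapply(networks, function(g)
    igraph::V(g)$name)))
  if (length(counts) == 0L) {
    d <- data.frame(from = character(), to = character(), weight = numeric())
  } else {
    parts <- strsplit(names(counts), "\t", fixed = TRUE)
    d <- data.frame(from = vapply(parts, `[`, character(1), 1L),
                    to = vapply(parts, `[`, character(1), 2L),
                    weight = as.numeric(counts) / n)
  }
  igraph::graph_from_data_frame(d, directed = FALSE, vertices = verts)
}

closed_neighborhood <- function(net, v) {
  union(igraph::neighbors(net, v)$name, v)
}

#' Szymkiewicz-Simpson (overlap) coefficient on closed neighborhoods
#'
#' `ssc(gi, gj) = |N*(gi) n N*(gj)| / min(|N*(gi)|, |N*(gj)|)` where
#' `N*(g) = N(g) u {g}`. Closing the neighborhoods makes a direct link between
#' the two genes count towards their similarity.
#'
#' @param net an undirected igraph.
#' @param gi,gj gene symbols; must be nodes of `net`.
#' @return Coefficient in `[0, 1]`.
#' @export
overlap_coefficient <- function(net, gi, gj) {
  vn <- igraph::V(net)$name
  if (!(gi %in% vn) || !(gj %in% vn)) {
    stop("gene(s) not in network: ",
         paste(setdiff(c(gi, gj), vn), collapse = ", "))
  }
  ni <- closed_neighborhood(net, gi)
  nj <- closed_neighborhood(net, gj)
  length(intersect(ni, nj)) / min(length(ni), length(nj))
}

#' Overlap coefficients for all node pairs (link prediction)
#'
#' Scores every pair of nodes by the closed-neighborhood overlap coefficient
#' and returns the weighted network `wGN` of pairs with a positive
#' coefficient. Only pairs within distance 2 are enumerated: any other pair
#' has disjoint closed neighborhoods and coefficient 0, so the result equals
#' the all-pairs computation.
#'
#' @param net an undirected igraph.
#' @return A weighted undirected igraph on the same node set whose edge
#'   weights are the overlap coefficients.
#' @export
score_all_pairs <- function(net) {
  vn <- igraph::V(net)$name
  nv <- length(vn)
  if (nv == 0L) return(net)
  adj <- lapply(igraph::as_adj_list(net, mode = "all"),
                function(x) x$name)
  names(adj) <- vn
  nstar <- mapply(function(v, nb) unique(c(v, nb)), vn, adj,
                  SIMPLIFY = FALSE)
  deg_star <- lengths(nstar)

  # candidate pairs at distance <= 2: direct edges plus co-neighbors
  ed <- igraph::as_data_frame(net, what = "edges")
  cand_from <- ed$from; cand_to <- ed$to
  for (v in vn) {
    nb <- adj[[v]]
    if (length(nb) >= 2L) {
      pr <- utils::combn(sort(nb), 2L)
      cand_from <- c(cand_from, pr[1L, ])
      cand_to <- c(cand_to, pr[2L, ])
    }
  }
  if (length(cand_from) == 0L) {
    return(igraph::graph_from_data_frame(
      data.frame(from = character(), to = character(), weight = numeric()),
      directed = FALSE, vertices = vn))
  }
  from <- pmin(cand_from, cand_to); to <- pmax(cand_from, cand_to)
  key <- paste(from, to, sep = "\t")
  keep <- !duplicated(key) & from != to
  from <- from[keep]; to <- to[keep]
  ssc <- vapply(seq_along(from), function(k) {
    a <- nstar[[from[k]]]; b <- nstar[[to[k]]]
    length(intersect(a, b)) / min(length(a), length(b))
  }, numeric(1))
  pos <- ssc > 0
  igraph::graph_from_data_frame(
    data.frame(from = from[pos], to = to[pos], weight = ssc[pos]),
    directed = FALSE, vertices = vn)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated fields `name`, `description`,
#' then the member gene symbols.
#'
#' @param path path to the GMT file.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) stop("malformed GMT line: ", substr(l, 1, 40))
    unique(f[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1),
    USE.NAMES = FALSE)
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description description field (recycled).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "na") {
  stopifnot(!is.null(names(sets)), all(nzchar(names(sets))))
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, description, sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

set_mean_ssc <- function(wgn, members, include_zero_pairs = FALSE) {
  sub <- igraph::induced_subgraph(wgn, members)
  w <- igraph::E(sub)$weight
  if (include_zero_pairs) {
    n_pairs <- choose(length(members), 2)
    if (n_pairs == 0) return(0)
    return(sum(w) / n_pairs)
  }
  if (length(w) == 0L) return(0)
  mean(w)
}

#' Calibrate the enrichment threshold from known pathways
#'
#' For each pathway, the mean overlap coefficient over its internal links in
#' `wgn` is compared with `n_random` random gene sets of the same size drawn
#' uniformly (without replacement) from the network's nodes. The threshold
#' `gamma` is the median of all random-set means pooled across pathways:
#' predicted links stronger than what random gene sets achieve are considered
#' worth keeping.
#'
#' @param wgn the weighted network produced by [score_all_pairs()].
#' @param pathways named list of gene sets (e.g. from [read_gmt()]); each is
#'   intersected with the network's nodes and skipped (with a warning) when
#'   fewer than 2 member genes remain.
#' @param n_random number of random same-size sets per pathway (default 10).
#' @param seed optional integer seed for the random draws.
#' @param include_zero_pairs if `TRUE`, set means are computed over all member
#'   pairs counting absent links as 0 rather than over present links only.
#' @return A list with `gamma` (the threshold), `report` (data.frame with one
#'   row per usable pathway: size in network, real mean, median random mean)
#'   and `random_means` (the pooled random-set means).
#' @export
select_gamma <- function(wgn, pathways, n_random = 10, seed = NULL,
                         include_zero_pairs = FALSE) {
  stopifnot(n_random >= 1)
  vn <- igraph::V(wgn)$name
  if (length(vn) == 0L) stop("network is empty")
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  pooled <- numeric()
  for (nm in names(pathways)) {
    members <- intersect(pathways[[nm]], vn)
    if (length(members) < 2L) {
      warning("pathway '", nm, "' has fewer than 2 genes in the network; skipped")
      next
    }
    real_mean <- set_mean_ssc(wgn, members, include_zero_pairs)
    rand_means <- vapply(seq_len(n_random), function(i) {
      set_mean_ssc(wgn, sample(vn, length(members)), include_zero_pairs)
    }, numeric(1))
    pooled <- c(pooled, rand_means)
    rows[[nm]] <- data.frame(pathway = nm, n_genes = length(members),
                             real_mean = real_mean,
                             random_mean_median = stats::median(rand_means))
  }
  if (length(pooled) == 0L) stop("no usable pathway (>= 2 genes in network)")
  list(gamma = stats::median(pooled),
       report = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       random_means = pooled)
}

#' Extract the enriched gene network
#'
#' Keeps exactly the predicted links whose overlap coefficient strictly
#' exceeds `gamma`, yielding the unweighted enriched network `eGN`. Original
#' edges whose coefficient falls at or below `gamma` are not retained unless
#' `keep_original_edges = TRUE`.
#'
#' @param gn the original network (used for the node universe and,
#'   optionally, its edges).
#' @param wgn the overlap-coefficient network from [score_all_pairs()].
#' @param gamma non-negative threshold.
#' @param keep_original_edges also retain all edges of `gn` regardless of
#'   their coefficient.
#' @return An unweighted undirected igraph over the union of both node sets.
#' @export
enrich_network <- function(gn, wgn, gamma, keep_original_edges = FALSE) {
  stopifnot(gamma >= 0)
  d <- igraph::as_data_frame(wgn, what = "edges")
  d <- d[d$weight > gamma, c("from", "to"), drop = FALSE]
  if (keep_original_edges) {
    d0 <- igraph::as_data_frame(gn, what = "edges")[, c("from", "to")]
    d <- rbind(d, d0)
  }
  if (nrow(d) > 0L) {
    from <- pmin(d$from, d$to); to <- pmax(d$from, d$to)
    keep <- !duplicated(paste(from, to, sep = "\t"))
    d <- data.frame(from = from[keep], to = to[keep])
  }
  verts <- unique(c(igraph::V(gn)$name, igraph::V(wgn)$name))
  igraph::graph_from_data_frame(d, directed = FALSE, vertices = verts)
}
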