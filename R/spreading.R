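edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\t")

# shared internals: adjacency lists, node strengths and an edge-weight lookup
# for a weighted undirected network
spreading_env <- function(ugn) {
  vn <- igraph::V(ugn)$name
  ed <- igraph::as_data_frame(ugn, what = "edges")
  if (is.null(ed$weight)) ed$weight <- rep(1, nrow(ed))
  wmap <- stats::setNames(ed$weight, edge_key(ed$from, ed$to))
  adj <- lapply(igraph::as_adj_list(ugn, mode = "all"), function(x) x$name)
  names(adj) <- vn
  strength <- stats::setNames(numeric(length(vn)), vn)
  if (nrow(ed) > 0L) {
    s <- tapply(c(ed$weight, ed$weight), c(ed$from, ed$to), sum)
    strength[names(s)] <- s
  }
  list(nodes = vn, edges = ed, wmap = wmap, adj = adj, strength = strength)
}

raw_ss <- function(env, gi, gj, include_source = FALSE) {
  p_ij <- env$wmap[[edge_key(gi, gj)]]
  excluded <- if (include_source) env$adj[[gi]] else c(env$adj[[gi]], gi)
  outward <- setdiff(env$adj[[gj]], excluded)
  r_out <- if (length(outward) == 0L) 0 else
    sum(env$wmap[edge_key(gj, outward)])
  (1 + env$strength[[gi]] * r_out) * p_ij
}

#' Asymmetric spreading strength across one edge
#'
#' Quantifies how strongly a mutation in `gi` spreads to its neighbor `gj`:
#' `ss(gi, gj) = (1 + r_i * r_j_out) * p_ij`, where `r_i` is the total edge
#' weight incident to `gi`, `r_j_out` is the total weight of `gj`'s edges
#' leading outward — to neighbors of `gj` that are neither `gi` nor adjacent
#' to `gi` — and `p_ij` is the weight of the edge itself. The `1` accounts for
#' the direct spread along the edge; the product term captures onward spread
#' through `gj` into parts of the network `gi` does not reach directly. The
#' measure is generally asymmetric: `ss(gi, gj) != ss(gj, gi)`.
#'
#' @param ugn weighted undirected igraph (the consensus network); missing
#'   weights are taken as 1.
#' @param gi,gj adjacent genes; the measure is defined only across edges.
#' @param include_source if `TRUE`, `gi` itself is not excluded from `gj`'s
#'   outward neighbor set, so the `gi`--`gj` edge weight is counted as
#'   outward spread (the literal set difference `N(gj) \ N(gi)` contains
#'   `gi`); the default excludes it, restricting the product term to genuinely
#'   indirect neighbors. Kept for sensitivity analysis.
#' @return The (unnormalized) spreading strength, a non-negative real.
#' @export
spreading_strength <- function(ugn, gi, gj, include_source = FALSE) {
  vn <- igraph::V(ugn)$name
  if (!(gi %in% vn) || !(gj %in% vn)) {
    stop("gene(s) not in network: ", paste(setdiff(c(gi, gj), vn), collapse = ", "))
  }
  if (igraph::get_edge_ids(ugn, c(gi, gj)) == 0) {
    stop("spreading strength is defined only across edges; '",
         gi, "' and '", gj, "' are not adjacent")
  }
  env <- spreading_env(ugn)
  unname(raw_ss(env, gi, gj, include_source))
}

#' Build the gene spreading strength network (GSSN)
#'
#' Computes the spreading strength in both directions across every edge of
#' the consensus network, normalizes all values by the global maximum (the
#' all-zero case yields all zeros, as in [normalize_max()]), and returns a
#' directed weighted network whose arc weights are the normalized spreading
#' strengths `nss`. Each node is annotated with its normalized weighted
#' mutation frequency (`nwf`; genes absent from the mutation data get 0), so
#' the GSSN carries everything needed to propagate mutation influence.
#'
#' @param ugn weighted undirected igraph; isolated nodes are kept (with no
#'   arcs).
#' @param nwf [gene_scores()] of kind `nwf` (or any named numeric vector).
#' @param include_source passed to [spreading_strength()].
#' @return A directed igraph with edge attribute `weight` (= nss), edge
#'   attribute `ss` (raw values) and vertex attribute `nwf`.
#' @export
build_gssn <- function(ugn, nwf, include_source = FALSE) {
  stopifnot(igraph::vcount(ugn) > 0)
  env <- spreading_env(ugn)
  ed <- env$edges
  if (nrow(ed) > 0L) {
    fw <- vapply(seq_len(nrow(ed)), function(k)
      raw_ss(env, ed$from[k], ed$to[k], include_source), numeric(1))
    bw <- vapply(seq_len(nrow(ed)), function(k)
      raw_ss(env, ed$to[k], ed$from[k], include_source), numeric(1))
    arcs <- data.frame(from = c(ed$from, ed$to),
                       to = c(ed$to, ed$from),
                       ss = c(fw, bw))
    mx <- max(arcs$ss)
    arcs$weight <- if (mx <= 0) 0 * arcs$ss else arcs$ss / mx
  } else {
    arcs <- data.frame(from = character(), to = character(),
                       ss = numeric(), weight = numeric())
  }
  g <- igraph::graph_from_data_frame(arcs, directed = TRUE,
                                     vertices = env$nodes)
  scores <- stats::setNames(numeric(length(env$nodes)), env$nodes)
  common <- intersect(names(nwf), env$nodes)
  scores[common] <- unclass(nwf)[common]
  igraph::V(g)$nwf <- unname(scores[igraph::V(g)$name])
  g
}

#' Mutation influence received from network neighbors
#'
#' For every gene, sums the mutation scores of its neighbors weighted by how
#' strongly each neighbor spreads into it:
#' `r(g) = sum over in-neighbors k of nwf(k) * nss(k -> g)`, followed by
#' maximum-value normalization to `nr`.
#'
#' @param gssn the directed network from [build_gssn()].
#' @return A list with [gene_scores()] components `r` (raw influence) and
#'   `nr` (max-normalized; all zeros when no gene receives influence).
#' @export
neighbor_influence <- function(gssn) {
  vn <- igraph::V(gssn)$name
  nwf <- stats::setNames(igraph::V(gssn)$nwf, vn)
  arcs <- igraph::as_data_frame(gssn, what = "edges")
  r <- stats::setNames(numeric(length(vn)), vn)
  if (nrow(arcs) > 0L) {
    contrib <- unname(nwf[arcs$from]) * arcs$weight
    s <- tapply(contrib, arcs$to, sum)
    r[names(s)] <- s
  }
  r <- gene_scores(r, "r")
  nr <- if (max(r) <= 0) {
    gene_scores(stats::setNames(numeric(length(r)), names(r)), "nr")
  } else {
    normalize_max(r)
  }
  list(r = r, nr = nr)
}

#' Final mutation score
#'
#' `ms(g) = nwf(g) + nr(g)` over the union of both gene universes; a gene
#' missing from either score contributes 0 for it (a gene outside the network
#' keeps `ms = nwf`; an unmutated network gene keeps `ms = nr`). Values lie
#' in `[0, 2]`.
#'
#' @param nwf,nr [gene_scores()] (named numeric vectors).
#' @return [gene_scores()] of kind `ms`.
#' @export
final_scores <- function(nwf, nr) {
  universe <- union(names(nwf), names(nr))
  ms <- stats::setNames(numeric(length(universe)), universe)
  ms[names(nwf)] <- ms[names(nwf)] + unclass(nwf)
  ms[names(nr)] <- ms[names(nr)] + unclass(nr)
  gene_scores(ms, "ms")
}

#' Rank genes by final mutation score
#'
#' Sorts genes by decreasing `ms`; ties are broken by lexicographic gene
#' symbol order, a deterministic package convention.
#'
#' @param ms non-empty [gene_scores()] (any kind; usually `ms`).
#' @return A `gene_ranking`: data.frame with columns `rank`, `gene`, `ms`,
#'   sorted by decreasing score.
#' @export
rank_genes <- function(ms) {
  stopifnot(length(ms) > 0L)
  ord <- order(-unclass(ms), names(ms), method = "radix")
  out <- data.frame(rank = seq_along(ms),
                    gene = names(ms)[ord],
                    ms = unname(unclass(ms)[ord]))
  structure(out, class = c("gene_ranking", "data.frame"),
            tie_policy = "lexicographic by gene symbol")
}

#' @export
print.gene_ranking <- function(x, n = 10L, ...) {
  cat("gene_ranking:", nrow(x), "genes (ties broken",
      attr(x, "tie_policy"), ")\n")
  print.data.frame(utils::head(x, n))
  invisible(x)
}

#' Export a GSSN as a directed edge-list TSV
#'
#' Columns: source, target, nss (normalized spreading strength), sorted for
#' byte-stable output.
#'
#' @param gssn the network from [build_gssn()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gssn <- function(gssn, path) {
  d <- igraph::as_data_frame(gssn, what = "edges")[, c("from", "to", "weight")]
  d <- d[order(d$from, d$to), , drop = FALSE]
  names(d) <- c("source", "target", "nss")
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
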