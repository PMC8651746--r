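test_that("edge tables are canonicalized: loops dropped, duplicates collapsed", {
  expect_message(
    net <- gene_network(data.frame(from = c("a", "b", "c"),
                                   to = c("b", "a", "c"))),
    "self-loop")
  expect_equal(igraph::ecount(net), 1L)
  expect_setequal(igraph::V(net)$name, c("a", "b", "c"))

  # duplicate edge keeps the weight of the last occurrence
  net2 <- gene_network(data.frame(from = c("a", "b"), to = c("b", "a"),
                                  w = c(0.3, 0.9)))
  expect_equal(igraph::E(net2)$weight, 0.9)
})

test_that("edge-list reader handles weights, empty files and short rows", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("a\tb\t0.5", "b\tc\t1"), p)
  net <- read_edge_list(p)
  expect_equal(igraph::ecount(net), 2L)
  expect_setequal(igraph::E(net)$weight, c(0.5, 1))

  writeLines(character(), p)
  expect_warning(empty <- read_edge_list(p), "empty")
  expect_equal(igraph::vcount(empty), 0L)

  writeLines(c("a", "b"), p)
  expect_error(read_edge_list(p), "two columns")
})

test_that("union weights are occurrence fractions in {k/N}", {
  n1 <- gene_network(data.frame(from = c("a", "b"), to = c("b", "c")))
  n2 <- gene_network(data.frame(from = c("a", "c"), to = c("b", "d")))
  u <- union_networks(list(n1, n2))
  d <- igraph::as_data_frame(u)
  key <- paste(pmin(d$from, d$to), pmax(d$from, d$to))
  w <- setNames(d$weight, key)
  expect_equal(w[["a b"]], 1.0)   # in both networks
  expect_equal(w[["b c"]], 0.5)   # only in n1
  expect_equal(w[["c d"]], 0.5)   # only in n2
  expect_setequal(igraph::V(u)$name, c("a", "b", "c", "d"))

  # single network: identity with all weights 1
  u1 <- union_networks(list(n1))
  expect_true(all(igraph::E(u1)$weight == 1))
  # disjoint networks: all weights 1/2
  n3 <- gene_network(data.frame(from = "x", to = "y"))
  expect_true(all(igraph::E(union_networks(list(n1, n3)))$weight == 0.5))
  expect_error(union_networks(list()), "non-empty")
})

test_that("union outcome is order-invariant (commutative/associative)", {
  set.seed(41)
  nets <- lapply(1:3, function(i) {
    g <- random_graph_df(8, 0.3, weighted = FALSE)
    gene_network(g$edges[, 1:2], nodes = g$nodes)
  })
  canon <- function(u) {
    d <- igraph::as_data_frame(u)
    d <- data.frame(from = pmin(d$from, d$to), to = pmax(d$from, d$to),
                    weight = d$weight)
    d[order(d$from, d$to), ]
  }
  ref <- canon(union_networks(nets))
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    expect_equal(canon(union_networks(nets[perm])), ref,
                 ignore_attr = TRUE)
  }
})

test_that("overlap coefficient uses closed neighborhoods", {
  tri <- gene_network(data.frame(from = c("a", "b", "c"),
                                 to = c("b", "c", "a")))
  expect_equal(overlap_coefficient(tri, "a", "b"), 1.0)

  pair <- gene_network(data.frame(from = "a", to = "b"))
  expect_equal(overlap_coefficient(pair, "a", "b"), 1.0)

  two <- gene_network(data.frame(from = c("a", "c"), to = c("b", "d")))
  expect_equal(overlap_coefficient(two, "a", "c"), 0.0)
  expect_error(overlap_coefficient(two, "a", "zz"), "zz")
})

test_that("ssc is symmetric and positive across direct edges", {
  set.seed(43)
  for (i in 1:10) {
    g <- random_graph_df(12, 0.25, weighted = FALSE)
    net <- gene_network(g$edges[, 1:2], nodes = g$nodes)
    ed <- igraph::as_data_frame(net)
    for (k in seq_len(min(nrow(ed), 10))) {
      a <- ed$from[k]; b <- ed$to[k]
      sab <- overlap_coefficient(net, a, b)
      expect_identical(sab, overlap_coefficient(net, b, a))
      da <- length(igraph::neighbors(net, a)) + 1
      db <- length(igraph::neighbors(net, b)) + 1
      expect_gte(sab, 2 / min(da, db))
    }
  }
})

test_that("score_all_pairs predicts distance-2 links and matches the naive oracle", {
  # path a-b-c: the non-edge (a,c) shares b, |N*|=2 each -> ssc = 1/2
  wgn <- score_all_pairs(path_abc())
  d <- igraph::as_data_frame(wgn)
  key <- setNames(d$weight, paste(pmin(d$from, d$to), pmax(d$from, d$to)))
  expect_equal(key[["a c"]], 0.5)
  expect_equal(key[["a b"]], 1.0)   # direct edge, N*(a) subset of N*(b)

  k4 <- gene_network(data.frame(from = c("a", "a", "a", "b", "b", "c"),
                                to = c("b", "c", "d", "c", "d", "d")))
  expect_true(all(igraph::E(score_all_pairs(k4))$weight == 1))
  expect_equal(igraph::ecount(score_all_pairs(k4)), 6L)

  empty <- gene_network(data.frame(from = character(), to = character()))
  expect_equal(igraph::ecount(score_all_pairs(empty)), 0L)

  # oracle: all-pairs double loop with set intersections
  set.seed(47)
  for (i in 1:8) {
    g <- random_graph_df(sample(5:30, 1), 0.2, weighted = FALSE)
    net <- gene_network(g$edges[, 1:2], nodes = g$nodes)
    got <- igraph::as_data_frame(score_all_pairs(net))
    got_map <- setNames(got$weight,
                        paste(pmin(got$from, got$to), pmax(got$from, got$to)))
    nodes <- g$nodes
    for (a_i in seq_along(nodes)) {
      for (b_i in seq_len(a_i - 1L)) {
        a <- nodes[b_i]; b <- nodes[a_i]
        ref <- oracle_ssc(g$edges, a, b)
        key <- paste(min(a, b), max(a, b))
        if (ref > 0) {
          expect_equal(unname(got_map[[key]]), ref, tolerance = 1e-12)
        } else {
          expect_false(key %in% names(got_map))
        }
      }
    }
  }
})

test_that("gamma is the median of pooled random-set means and is seeded", {
  set.seed(51)
  g <- random_graph_df(20, 0.3, weighted = FALSE)
  net <- gene_network(g$edges[, 1:2], nodes = g$nodes)
  wgn <- score_all_pairs(net)
  pw <- list(pw1 = g$nodes[1:5], pw2 = g$nodes[6:11])
  cal1 <- select_gamma(wgn, pw, n_random = 10, seed = 99)
  cal2 <- select_gamma(wgn, pw, n_random = 10, seed = 99)
  expect_identical(cal1$gamma, cal2$gamma)
  expect_length(cal1$random_means, 20L)
  expect_equal(cal1$gamma, median(cal1$random_means))
  expect_equal(nrow(cal1$report), 2L)

  # pathways with < 2 genes in the network are skipped with a warning
  expect_warning(
    cal3 <- select_gamma(wgn, c(pw, list(tiny = "absent_gene")), seed = 1),
    "tiny")
  expect_equal(nrow(cal3$report), 2L)
})

test_that("enrichment keeps exactly the links above gamma", {
  net <- path_abc()
  wgn <- score_all_pairs(net)   # weights: ab 1, bc 1, ac 0.5
  e <- enrich_network(net, wgn, gamma = 0.75)
  d <- igraph::as_data_frame(e)
  expect_equal(nrow(d), 2L)
  expect_null(d$weight)  # eGN is unweighted
  expect_false(any(paste(d$from, d$to) %in% c("a c", "c a")))

  expect_equal(igraph::ecount(enrich_network(net, wgn, gamma = 0)), 3L)
  expect_equal(igraph::ecount(enrich_network(net, wgn, gamma = 1)), 0L)
  # escape hatch: original edges can be retained regardless of their ssc
  keep <- enrich_network(net, wgn, gamma = 1, keep_original_edges = TRUE)
  expect_equal(igraph::ecount(keep), 2L)
})
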