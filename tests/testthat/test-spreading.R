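test_that("spreading strength matches hand values on the 3-path", {
  net <- path_abc()
  expect_equal(spreading_strength(net, "a", "b"), 2)
  expect_equal(spreading_strength(net, "b", "a"), 1)
  expect_equal(spreading_strength(net, "b", "c"), 1)
  expect_equal(spreading_strength(net, "c", "b"), 2)
  # asymmetric across the same edge
  expect_false(spreading_strength(net, "a", "b") ==
                 spreading_strength(net, "b", "a"))
  expect_error(spreading_strength(net, "a", "c"), "not adjacent")
})

test_that("leaf-leaf edges and stars follow the closed forms", {
  pair <- gene_network(data.frame(from = "a", to = "b"))
  expect_equal(spreading_strength(pair, "a", "b"), 1)
  expect_equal(spreading_strength(pair, "b", "a"), 1)

  k <- 5
  leaves <- paste0("l", seq_len(k))
  star <- gene_network(data.frame(from = "c", to = leaves))
  # leaf -> center: (1 + 1 * (k-1)) * 1 = k; center -> leaf: (1 + k*0) = 1
  expect_equal(spreading_strength(star, "l1", "c"), k)
  expect_equal(spreading_strength(star, "c", "l1"), 1)
})

test_that("the literal outward-set reading counts the source edge", {
  # on the 3-path, N(b) \ N(a) = {a, c} literally includes the source a
  net <- path_abc()
  expect_equal(spreading_strength(net, "a", "b", include_source = TRUE),
               (1 + 1 * 2) * 1)
  expect_equal(oracle_ss(igraph::as_data_frame(net), "a", "b",
                         include_source = TRUE), 3)
})

test_that("the GSSN normalizes both arcs of every edge by the global max", {
  net <- path_abc()
  nwf <- gene_scores(c(a = 1, b = 0, c = 0.5), "nwf")
  gssn <- build_gssn(net, nwf)
  d <- igraph::as_data_frame(gssn)
  arcs <- setNames(d$weight, paste(d$from, d$to))
  expect_equal(arcs[["a b"]], 1.0)
  expect_equal(arcs[["b a"]], 0.5)
  expect_equal(arcs[["b c"]], 0.5)
  expect_equal(arcs[["c b"]], 1.0)
  raw <- setNames(d$ss, paste(d$from, d$to))
  expect_equal(unname(raw[c("a b", "b a", "b c", "c b")]), c(2, 1, 1, 2))

  # single edge: both arcs raw 1, normalized to 1
  pair <- gene_network(data.frame(from = "a", to = "b"))
  g2 <- build_gssn(pair, gene_scores(c(a = 1), "nwf"))
  expect_equal(igraph::E(g2)$weight, c(1, 1))

  # isolated node is kept, without arcs, with nwf 0
  iso <- gene_network(data.frame(from = "a", to = "b"), nodes = "z")
  g3 <- build_gssn(iso, gene_scores(c(a = 1), "nwf"))
  expect_true("z" %in% igraph::V(g3)$name)
  expect_equal(igraph::degree(g3, "z"), c(z = 0))
  expect_equal(igraph::V(g3)$nwf[igraph::V(g3)$name == "z"], 0)
})

test_that("neighbor influence sums nwf-weighted incoming arcs", {
  gssn <- build_gssn(path_abc(), gene_scores(c(a = 1, b = 0, c = 0.5), "nwf"))
  infl <- neighbor_influence(gssn)
  expect_equal(unclass(infl$r), c(a = 0, b = 1.5, c = 0), ignore_attr = TRUE)
  expect_equal(unclass(infl$nr), c(a = 0, b = 1, c = 0), ignore_attr = TRUE)

  # no mutations -> no influence, all-zero without error
  zero <- build_gssn(path_abc(), gene_scores(c(a = 0), "nwf"))
  infl0 <- neighbor_influence(zero)
  expect_true(all(unclass(infl0$r) == 0) && all(unclass(infl0$nr) == 0))

  # isolated mutated gene receives nothing
  iso <- gene_network(data.frame(from = "a", to = "b"), nodes = "z")
  infl_iso <- neighbor_influence(build_gssn(iso, gene_scores(c(z = 1), "nwf")))
  expect_equal(unname(unclass(infl_iso$r)["z"]), 0)
})

test_that("final scores add nwf and nr over the union universe", {
  ms <- final_scores(gene_scores(c(a = 1), "nwf"),
                     gene_scores(c(a = 1), "nr"))
  expect_equal(as.numeric(ms), 2)

  # gene absent from the network keeps ms = nwf
  ms2 <- final_scores(gene_scores(c(a = 0.3, only_mut = 0.7), "nwf"),
                      gene_scores(c(a = 0.2), "nr"))
  expect_equal(unclass(ms2)[["only_mut"]], 0.7)
  expect_equal(unclass(ms2)[["a"]], 0.5)
  expect_true(all(unclass(ms2) >= 0 & unclass(ms2) <= 2))
})

test_that("ranking sorts by score with lexicographic tie-breaks", {
  rk <- rank_genes(gene_scores(c(a = 1.0, b = 1.5, c = 0.5), "ms"))
  expect_equal(rk$gene, c("b", "a", "c"))
  expect_equal(rk$rank, 1:3)
  expect_true(all(diff(rk$ms) <= 0))

  ties <- rank_genes(gene_scores(c(z = 1, a = 1, m = 1), "ms"))
  expect_equal(ties$gene, c("a", "m", "z"))
  single <- rank_genes(gene_scores(c(only = 0.2), "ms"))
  expect_equal(nrow(single), 1L)
})

test_that("spreading chain matches the independent oracle on random graphs", {
  set.seed(61)
  for (i in 1:25) {
    g <- random_graph_df(sample(4:25, 1), 0.3, weighted = TRUE)
    if (nrow(g$edges) == 0) next
    net <- gene_network(g$edges, nodes = g$nodes)
    mutated <- sample(g$nodes, max(1, length(g$nodes) %/% 3))
    nwf <- gene_scores(setNames(round(runif(length(mutated)), 3), mutated),
                       "nwf")
    edges <- igraph::as_data_frame(net)
    ref <- oracle_trace(edges, g$nodes, unclass(nwf))

    gssn <- build_gssn(net, nwf)
    d <- igraph::as_data_frame(gssn)
    got_ss <- setNames(d$ss, paste(d$from, d$to))
    ref_ss <- setNames(ref$arcs$ss, paste(ref$arcs$from, ref$arcs$to))
    expect_equal(got_ss[sort(names(got_ss))], ref_ss[sort(names(ref_ss))],
                 tolerance = 1e-12)
    got_nss <- setNames(d$weight, paste(d$from, d$to))
    ref_nss <- setNames(ref$arcs$nss, paste(ref$arcs$from, ref$arcs$to))
    expect_equal(got_nss[sort(names(got_nss))], ref_nss[sort(names(ref_nss))],
                 tolerance = 1e-12)

    infl <- neighbor_influence(gssn)
    nodes <- sort(g$nodes)
    expect_equal(unclass(infl$r)[nodes], ref$r[nodes], tolerance = 1e-12,
                 ignore_attr = TRUE)
    ms <- final_scores(nwf, infl$nr)
    expect_equal(unclass(ms)[nodes], ref$ms[nodes], tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("vertex-transitive graphs give symmetric spreading strengths", {
  # unit-weight cycle: every node looks alike, so ss is equal both ways
  n <- 6
  cyc <- gene_network(data.frame(from = paste0("v", 1:n),
                                 to = paste0("v", c(2:n, 1))))
  d <- igraph::as_data_frame(cyc)
  for (k in seq_len(nrow(d))) {
    expect_equal(spreading_strength(cyc, d$from[k], d$to[k]),
                 spreading_strength(cyc, d$to[k], d$from[k]))
  }
})

test_that("raising nwf or an edge weight never lowers r or ss", {
  set.seed(67)
  for (i in 1:10) {
    g <- random_graph_df(10, 0.3, weighted = TRUE)
    if (nrow(g$edges) < 2) next
    net <- gene_network(g$edges, nodes = g$nodes)
    nwf_vals <- setNames(round(runif(length(g$nodes)), 3), g$nodes)
    infl1 <- neighbor_influence(build_gssn(net, gene_scores(nwf_vals, "nwf")))
    bumped <- nwf_vals
    pick <- sample(g$nodes, 1)
    bumped[pick] <- bumped[pick] + 0.5
    infl2 <- neighbor_influence(build_gssn(net, gene_scores(bumped, "nwf")))
    expect_true(all(unclass(infl2$r) - unclass(infl1$r) >= -1e-12))

    # raising one edge weight never lowers any raw ss
    e_pick <- sample.int(nrow(g$edges), 1)
    heavier <- g$edges
    heavier$weight[e_pick] <- heavier$weight[e_pick] + 1
    net2 <- gene_network(heavier, nodes = g$nodes)
    ss1 <- igraph::as_data_frame(build_gssn(net, gene_scores(nwf_vals, "nwf")))
    ss2 <- igraph::as_data_frame(build_gssn(net2, gene_scores(nwf_vals, "nwf")))
    m1 <- setNames(ss1$ss, paste(ss1$from, ss1$to))
    m2 <- setNames(ss2$ss, paste(ss2$from, ss2$to))
    common <- intersect(names(m1), names(m2))
    expect_true(all(m2[common] - m1[common] >= -1e-12))
  }
})
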