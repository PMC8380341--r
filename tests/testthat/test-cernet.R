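make_de <- function(ids, classes, directions) {
  data.frame(feature_id = ids, class = classes,
             mean_case = 1, mean_ctrl = 1,
             log2fc = ifelse(directions == "up", 2,
                             ifelse(directions == "down", -2, 0)),
             p = ifelse(directions == "ns", 0.9, 1e-6), q = NA_real_,
             direction = directions, stringsAsFactors = FALSE)
}

make_pairs <- function(mirna, target, class, passes = TRUE) {
  data.frame(mirna_id = mirna, target_id = target, class = class,
             site_type = "8mer", start = 1L, end = 9L,
             context_score = 80, energy = -20, passes = passes,
             stringsAsFactors = FALSE)
}

test_that("build_edges keeps only passing, DE, anticorrelated pairs", {
  de <- make_de(c("mir1", "g1", "g2", "g3"),
                c("miRNA", "mRNA", "mRNA", "mRNA"),
                c("down", "up", "down", "ns"))
  pairs <- make_pairs("mir1", c("g1", "g2", "g3"), "mRNA")
  e <- build_edges(de, pairs)
  expect_identical(e$partner_id, "g1")      # g2 co-directional, g3 ns
  expect_identical(e$mirna_direction, "down")
  # permissive mode admits the co-directional pair but never the ns one
  ep <- build_edges(de, pairs, require_anticorrelation = FALSE)
  expect_setequal(ep$partner_id, c("g1", "g2"))
  # non-passing pairs are invisible
  e0 <- build_edges(de, make_pairs("mir1", "g1", "mRNA", passes = FALSE))
  expect_identical(nrow(e0), 0L)
  expect_identical(nrow(build_edges(de, pairs[0, ])), 0L)
  expect_error(build_edges(de, make_pairs("mir9", "g1", "mRNA")), "absent")
})

test_that("one miRNA with 2 sponges and 3 mRNAs yields 6 triads", {
  de <- make_de(c("mir1", "l1", "l2", "g1", "g2", "g3"),
                c("miRNA", "lncRNA", "lncRNA", "mRNA", "mRNA", "mRNA"),
                c("down", "up", "up", "up", "up", "up"))
  pairs <- rbind(make_pairs("mir1", c("l1", "l2"), "lncRNA"),
                 make_pairs("mir1", c("g1", "g2", "g3"), "mRNA"))
  tri <- assemble_triads(build_edges(de, pairs))
  expect_identical(nrow(tri), 6L)
  expect_true(all(tri$pattern == "up-down-up"))
})

test_that("triads and quads match brute-force enumeration on random instances", {
  set.seed(23)
  for (rep in 1:50) {
    edges <- random_edge_table(n_mirna = sample(2:6, 1), n_lnc = sample(1:6, 1),
                               n_circ = sample(1:6, 1), n_mrna = sample(2:10, 1),
                               p_edge = runif(1, 0.1, 0.5))
    tri <- assemble_triads(edges)
    expect_setequal(triad_key(tri), oracle_triads(edges))
    integ <- integrate_networks(tri)
    got <- if (nrow(integ$quads)) {
      paste(integ$quads$lncRNA_id, integ$quads$circRNA_id,
            integ$quads$mirna_id, integ$quads$mrna_id)
    } else character(0)
    expect_setequal(got, oracle_quads(tri))
    # miRNA-only sharing is a superset of the strict rule
    loose <- integrate_networks(tri, share_mrna = FALSE)
    expect_gte(nrow(loose$quads), nrow(integ$quads))
  }
})

test_that("quads require the shared miRNA by default and decompose into triads", {
  tri <- data.frame(
    sponge_id = c("L1", "C1", "L2", "C2"),
    sponge_class = c("lncRNA", "circRNA", "lncRNA", "circRNA"),
    sponge_direction = "up",
    mirna_id = c("m1", "m1", "m2", "m3"),
    mirna_direction = "down",
    mrna_id = c("G1", "G1", "G9", "G9"),
    mrna_direction = "up", pattern = "up-down-up", stringsAsFactors = FALSE)
  integ <- integrate_networks(tri)
  expect_identical(nrow(integ$quads), 1L)
  expect_identical(integ$quads$lncRNA_id, "L1")
  expect_identical(integ$quads$circRNA_id, "C1")
  # L2/C2 share only the mRNA: no quad
  expect_false(any(integ$quads$lncRNA_id == "L2"))
})

test_that("direction flip maps up-down-up triads onto down-up-down bijectively", {
  set.seed(31)
  edges <- random_edge_table(p_edge = 0.4)
  flip <- c(up = "down", down = "up")
  flipped <- edges
  flipped$mirna_direction <- unname(flip[edges$mirna_direction])
  flipped$partner_direction <- unname(flip[edges$partner_direction])
  t1 <- assemble_triads(edges)
  t2 <- assemble_triads(flipped)
  expect_identical(nrow(t1), nrow(t2))
  expect_setequal(triad_key(t1), triad_key(t2))
  expect_identical(sum(t1$pattern == "up-down-up"),
                   sum(t2$pattern == "down-up-down"))
})

test_that("removing an edge never increases triad, quad, or degree counts", {
  set.seed(37)
  edges <- random_edge_table(p_edge = 0.4)
  tri <- assemble_triads(edges)
  integ <- integrate_networks(tri)
  net <- cerna_network(edges, tri, integ$quads)
  for (drop in sample(nrow(edges), min(10, nrow(edges)))) {
    sub <- edges[-drop, , drop = FALSE]
    tri2 <- assemble_triads(sub)
    integ2 <- integrate_networks(tri2)
    net2 <- cerna_network(sub, tri2, integ2$quads)
    expect_lte(nrow(tri2), nrow(tri))
    expect_lte(nrow(integ2$quads), nrow(integ$quads))
    common <- intersect(net2$nodes$id, net$nodes$id)
    expect_true(all(net2$nodes$degree[match(common, net2$nodes$id)] <=
                      net$nodes$degree[match(common, net$nodes$id)]))
  }
})

test_that("hub_ranking sorts by distinct-miRNA degree with lexicographic ties", {
  edges <- rbind(
    data.frame(mirna_id = c("m1", "m2", "m3"), mirna_direction = "down",
               partner_id = "geneB", partner_class = "mRNA",
               partner_direction = "up", stringsAsFactors = FALSE),
    data.frame(mirna_id = c("m1", "m2"), mirna_direction = "down",
               partner_id = "geneA", partner_class = "mRNA",
               partner_direction = "up", stringsAsFactors = FALSE),
    data.frame(mirna_id = c("m1", "m2"), mirna_direction = "down",
               partner_id = "geneC", partner_class = "mRNA",
               partner_direction = "up", stringsAsFactors = FALSE))
  net <- cerna_network(edges)
  hubs <- hub_ranking(net, 10)
  expect_identical(hubs$mrna_id, c("geneB", "geneA", "geneC"))
  expect_identical(hubs$degree, c(3L, 2L, 2L))
  expect_identical(nrow(hub_ranking(net, 2)), 2L)
  expect_error(hub_ranking(net, 0), "top_k")
  # counting oracle on a random instance
  set.seed(41)
  re <- random_edge_table(p_edge = 0.5)
  rnet <- cerna_network(re)
  h <- hub_ranking(rnet, 1000)
  mr <- re[re$partner_class == "mRNA", ]
  for (i in seq_len(nrow(h))) {
    expect_identical(h$degree[i],
                     length(unique(mr$mirna_id[mr$partner_id == h$mrna_id[i]])))
  }
})

test_that("export round-trips: SIF and GraphML reconstruct the same graph", {
  set.seed(43)
  edges <- random_edge_table(p_edge = 0.4)
  tri <- assemble_triads(edges)
  net <- cerna_network(edges, tri)
  d <- withr::local_tempdir()
  export_network(net, d)
  sif <- read_sif(file.path(d, "network.sif"))
  expect_identical(nrow(sif), nrow(net$edges))
  expect_setequal(paste(sif$source, sif$target),
                  paste(net$edges$mirna_id, net$edges$partner_id))
  expect_true(all(sif$interaction %in% c("mir_mrna", "mir_lnc", "mir_circ")))
  g <- igraph::read_graph(file.path(d, "network.graphml"), format = "graphml")
  expect_equal(igraph::vcount(g), nrow(net$nodes))
  expect_equal(igraph::ecount(g), nrow(net$edges))
  vn <- igraph::V(g)$name
  expect_setequal(vn, net$nodes$id)
  idx <- match(net$nodes$id, vn)
  expect_identical(igraph::V(g)$class[idx], net$nodes$class)
  expect_identical(igraph::V(g)$direction[idx], net$nodes$direction)
  expect_equal(igraph::V(g)$degree[idx], net$nodes$degree)
  expect_true(igraph::isomorphic(g, as_igraph(net)))
  expect_error(export_network(net, d, formats = "xlsx"), "format")
})

test_that("an empty network exports valid empty files", {
  net <- cerna_network(random_edge_table(p_edge = 0)[0, ])
  d <- withr::local_tempdir()
  export_network(net, d)
  expect_identical(nrow(read_sif(file.path(d, "network.sif"))), 0L)
  g <- igraph::read_graph(file.path(d, "network.graphml"), format = "graphml")
  expect_equal(igraph::vcount(g), 0)
})

test_that("one-edge network writes exactly one SIF line", {
  e <- data.frame(mirna_id = "m1", mirna_direction = "down",
                  partner_id = "g1", partner_class = "mRNA",
                  partner_direction = "up", stringsAsFactors = FALSE)
  d <- withr::local_tempdir()
  export_network(cerna_network(e), d, formats = "sif")
  expect_identical(readLines(file.path(d, "network.sif")),
                   "m1\tmir_mrna\tg1")
})
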