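# PPI graph hygiene, subgraph induction, degree ranking, edge enrichment
# and CRC extraction.

mk_graph <- function(edges, ...) {
  ppi_graph(data.frame(gene_a = edges[, 1], gene_b = edges[, 2],
                       stringsAsFactors = FALSE), ...)
}

test_that("graph construction drops self-loops and duplicates and keeps invariants", {
  e <- rbind(c("a", "b"), c("b", "a"), c("c", "c"), c("a", "c"))
  expect_warning(expect_warning(g <- mk_graph(e), "self-loop"), "duplicate")
  expect_equal(nrow(g$edges), 2)
  expect_true(all(g$edges$gene_a < g$edges$gene_b))
  # sum of degrees = 2 x edge count
  expect_equal(sum(integration_rank(g)$degree), 2 * nrow(g$edges))
})

test_that("induced subgraphs filter edges exactly and compose monotonically", {
  set.seed(87)
  nodes <- sprintf("n%02d", 1:30)
  pr <- t(combn(nodes, 2))
  keep <- runif(nrow(pr)) < 0.15
  g <- mk_graph(pr[keep, , drop = FALSE], nodes = nodes)
  expect_equal(length(ppi_induced_subgraph(g, c("zz1", "zz2"))$nodes), 0)
  full <- ppi_induced_subgraph(g, nodes)
  expect_equal(nrow(full$edges), nrow(g$edges))

  for (rep in 1:20) {
    sel <- sample(nodes, sample(3:20, 1))
    sub <- ppi_induced_subgraph(g, sel)
    # brute-force edge filter
    want <- sum(g$edges$gene_a %in% sel & g$edges$gene_b %in% sel)
    expect_equal(nrow(sub$edges), want)
    # idempotent; monotone under gene-set inclusion
    expect_equal(nrow(ppi_induced_subgraph(sub, sel)$edges), want)
    sub2 <- ppi_induced_subgraph(g, sel[-1])
    expect_true(nrow(sub2$edges) <= nrow(sub$edges))
    expect_true(all(sub2$nodes %in% sub$nodes))
    expect_equal(sum(integration_rank(sub)$degree), 2 * nrow(sub$edges))
  }
})

test_that("edge enrichment reproduces closed-form binomial tails", {
  # 4 selected nodes, all 6 edges present, background density 1/2
  nodes <- sprintf("v%d", 1:4)
  g <- mk_graph(t(combn(nodes, 2)), background_n_nodes = 100,
                background_n_edges = choose(100, 2) / 2)
  r <- edge_enrichment(g, nodes)
  expect_equal(r$rho, 0.5)
  expect_equal(r$p, 0.5^6, tolerance = 1e-12)
  expect_equal(r$expected, 3)
  # zero observed edges: P(X >= 0) = 1
  g0 <- ppi_graph(data.frame(gene_a = "x1", gene_b = "x2"),
                  nodes = c("x1", "x2", "y1", "y2"),
                  background_n_nodes = 50, background_n_edges = 100)
  expect_equal(edge_enrichment(g0, c("y1", "y2"))$p, 1.0)
  # p decreases monotonically in the observed edge count
  ps <- vapply(0:6, function(m)
    stats::pbinom(m - 1, 6, 0.2, lower.tail = FALSE), numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("edge-enrichment type-I error under a null ER selection is calibrated", {
  # 190 candidate pairs at density 0.3 keep the binomial tail fine-grained
  # enough that the exact rejection probability at alpha = 0.05 is 0.0499
  set.seed(11)
  nodes <- sprintf("n%02d", 1:40)
  pr <- t(combn(nodes, 2))
  rej <- replicate(500, {
    er <- runif(nrow(pr)) < 0.3
    g <- mk_graph(pr[er, , drop = FALSE], nodes = nodes)
    sel <- sample(nodes, 20)
    edge_enrichment(g, sel)$p <= 0.05
  })
  ci <- 0.05 + c(-1, 1) * 1.96 * sqrt(0.05 * 0.95 / 500)
  expect_gte(mean(rej), ci[1])
  expect_lte(mean(rej), ci[2])
})

test_that("integration ranking orders by degree with lexicographic ties", {
  star <- mk_graph(cbind("HUB", sprintf("l%d", 1:5)))
  rk <- integration_rank(star)
  expect_equal(rk$node[1], "HUB")
  expect_equal(rk$degree[1], 5)
  expect_equal(rk$node[-1], sort(sprintf("l%d", 1:5)))
  empty <- ppi_graph(data.frame(gene_a = character(), gene_b = character()))
  expect_equal(nrow(integration_rank(empty)), 0)

  set.seed(91)
  nodes <- sprintf("n%02d", 1:25)
  pr <- t(combn(nodes, 2))
  g <- mk_graph(pr[runif(nrow(pr)) < 0.2, , drop = FALSE], nodes = nodes)
  rk <- integration_rank(g)
  want <- vapply(rk$node, function(v)
    sum(g$edges$gene_a == v | g$edges$gene_b == v), numeric(1))
  expect_equal(rk$degree, unname(as.integer(want)))
  expect_true(all(diff(rk$degree) <= 0))
})

test_that("CRC extraction returns the hub plus exactly its direct neighbours", {
  star <- mk_graph(cbind("HUB", sprintf("l%d", 1:5)))
  crc <- extract_crc(star, "HUB")
  expect_equal(crc$crc_members, sort(c("HUB", sprintf("l%d", 1:5))))
  iso <- ppi_graph(data.frame(gene_a = "a", gene_b = "b"),
                   nodes = c("a", "b", "lone"))
  expect_equal(extract_crc(iso, "lone")$crc_members, "lone")
  expect_error(extract_crc(star, "nope"), "nope")
})

test_that("hypergeometric CRC conservation matches enumeration", {
  univ <- sprintf("u%02d", 1:30)
  same <- crc_conservation(univ[1:8], univ[1:8], univ)
  expect_equal(same$overlap, 8)
  expect_equal(same$p, oracle_hyper_upper(8, 8, 8, 30), tolerance = 1e-12)
  disj <- crc_conservation(univ[1:5], univ[6:10], univ)
  expect_equal(disj$overlap, 0)
  expect_equal(disj$p, 1, tolerance = 1e-12)
  set.seed(97)
  for (rep in 1:30) {
    a <- sample(univ, sample(2:15, 1)); b <- sample(univ, sample(2:15, 1))
    got <- crc_conservation(a, b, univ)
    expect_equal(got$p, oracle_hyper_upper(got$overlap, length(unique(a)),
                                           length(unique(b)), 30),
                 tolerance = 1e-11)
  }
})

test_that("the planted hub dominates integration on generator PPI graphs", {
  s <- synth_fixture()
  edges <- utils::read.delim(file.path(s$dir, "ppi_edges.tsv"),
                             stringsAsFactors = FALSE)
  g <- ppi_graph(edges)
  sub <- ppi_induced_subgraph(g, s$truth$union_targets)
  rk <- integration_rank(sub)
  expect_lte(rk$rank[rk$node == s$truth$hub], 2)
  crc <- extract_crc(sub, s$truth$hub)
  expect_equal(crc$crc_members, s$truth$crc_members)
})
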