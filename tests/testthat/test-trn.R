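# Enhancer-gene links, upregulation filtering, and enrichment statistics.

test_that("nearest-gene links use centers, tie rules, and drop unannotated chroms", {
  tss <- data.frame(gene = c("B", "A"), chrom = "chr1", pos = c(100, 300),
                    strand = "+", stringsAsFactors = FALSE)
  enh <- interval_set(data.frame(chrom = c("chr1", "chr1", "chrZ"),
                                 start = c(80, 150, 0),
                                 end = c(120, 250, 50)))
  expect_warning(links <- assign_nearest(enh, tss), "unannotated")
  expect_equal(nrow(links), 2)
  expect_equal(links$gene, c("B", "A"))  # center 200 ties -> "A" < "B"
  expect_equal(links$mode, rep("nearest", 2))
})

test_that("curated links honor many-to-many overlap and the all-pairs oracle", {
  inter <- data.frame(chrom = "chr1", start = c(100, 100, 500),
                      end = c(200, 200, 600), gene = c("G1", "G2", "G3"),
                      score = 1:3, stringsAsFactors = FALSE)
  enh <- interval_set(data.frame(chrom = "chr1", start = 150, end = 160))
  links <- assign_curated(enh, inter)
  expect_equal(sort(links$gene), c("G1", "G2"))  # one element, two targets
  far <- interval_set(data.frame(chrom = "chr1", start = 900, end = 950))
  expect_equal(nrow(assign_curated(far, inter)), 0)

  set.seed(61)
  genome <- c(chr1 = 5e4)
  enh <- random_intervals(40, genome)
  inter <- as.data.frame(random_intervals(30, genome))[, c("chrom", "start", "end")]
  inter$gene <- sprintf("G%02d", seq_len(nrow(inter)))
  inter$score <- runif(nrow(inter))
  links <- assign_curated(enh, inter)
  want <- 0
  for (i in seq_len(nrow(enh))) for (j in seq_len(nrow(inter)))
    if (enh$start[i] < inter$end[j] && inter$start[j] < enh$end[i])
      want <- want + 1
  expect_equal(nrow(links), want)
})

test_that("the upregulation filter keeps FDR < threshold AND positive log2FC", {
  links <- data.frame(chrom = "chr1", start = c(0, 100, 200, 300),
                      end = c(50, 150, 250, 350),
                      gene = c("UP", "DOWN", "NS", "MISSING"),
                      mode = "nearest", distance = 0, score = NA,
                      stringsAsFactors = FALSE)
  de <- data.frame(gene = c("UP", "DOWN", "NS"),
                   log2FoldChange = c(2, -2, 2), padj = c(0.04, 0.04, 0.06))
  trn <- build_trn(links, de)
  expect_equal(trn$genes, "UP")
  expect_equal(nrow(trn$links), 1)
  # monotone in thresholds: relaxing never shrinks the gene set
  relaxed <- build_trn(links, de, fdr_max = 0.1, lfc_min = -3)
  expect_true(all(trn$genes %in% relaxed$genes))
  set.seed(67)
  de2 <- data.frame(gene = sprintf("g%03d", 1:100),
                    log2FoldChange = rnorm(100), padj = runif(100))
  links2 <- data.frame(chrom = "chr1", start = 1:100 * 10,
                       end = 1:100 * 10 + 5, gene = de2$gene,
                       mode = "nearest", distance = 0, score = NA)
  for (f1 in c(0.01, 0.05, 0.2)) for (f2 in c(0.1, 0.5)) {
    g_tight <- build_trn(links2, de2, f1, 0.5)$genes
    g_loose <- build_trn(links2, de2, f1 + f2, 0.0)$genes
    expect_true(all(g_tight %in% g_loose))
  }
})

test_that("TRN Venn regions sum to the union and match set algebra", {
  t1 <- list(genes = c("a", "b", "c")); class(t1) <- "trn"
  t2 <- list(genes = c("b", "c", "d")); class(t2) <- "trn"
  t3 <- list(genes = c("c", "e")); class(t3) <- "trn"
  ov <- trn_overlap(list(X = t1, Y = t2, Z = t3))
  expect_equal(sum(ov), 5)  # |union|
  expect_equal(unname(ov[["X+Y+Z"]]), 1)  # only "c"
  expect_equal(unname(ov[["X"]]), 1)      # only "a"
  same <- trn_overlap(list(P = t1, Q = t1))
  expect_equal(unname(same[["P+Q"]]), 3)
  expect_equal(unname(same[["P"]]) + unname(same[["Q"]]), 0)
  disj <- trn_overlap(list(P = list(genes = "x"), Q = list(genes = "y")))
  expect_equal(unname(disj[["P+Q"]]), 0)

  set.seed(71)
  for (rep in 1:20) {
    sets <- lapply(1:3, function(i) sample(letters, sample(5:15, 1)))
    names(sets) <- c("A", "B", "C")
    ov <- trn_overlap(sets)
    expect_equal(sum(ov), length(unique(unlist(sets))))
    expect_equal(unname(ov[["A+B+C"]]),
                 length(Reduce(intersect, sets)))
    expect_equal(unname(ov[["A+B"]]),
                 length(setdiff(intersect(sets$A, sets$B), sets$C)))
  }
})

test_that("running-sum ES matches hand-worked cases and the loop oracle", {
  # 4-gene ranking, set = top gene, classic (exponent 0) mode:
  # running sum 1, 2/3, 1/3, 0 -> ES = 1 at position 1
  scores <- c(g1 = 4, g2 = 3, g3 = 2, g4 = 1)
  r <- preranked_enrichment(scores, "g1", weight = 0, n_perm = 100, seed = 1)
  expect_equal(r$es, 1.0)
  # saturation: set = all genes
  rall <- preranked_enrichment(scores, names(scores), n_perm = 100, seed = 1)
  expect_equal(rall$es, 1.0)
  # mid-list single hit, exponent 0: running sum -1/3, 2/3 - 1/3, ...
  r2 <- preranked_enrichment(scores, "g2", weight = 0, n_perm = 100, seed = 1)
  expect_equal(r2$es, 1 - 1 / 3)

  set.seed(73)
  for (rep in 1:50) {
    n <- sample(10:80, 1)
    sc <- sort(rnorm(n, 0, 2), decreasing = TRUE)
    names(sc) <- sprintf("g%03d", 1:n)
    hit <- rep(FALSE, n); hit[sample.int(n, sample(2:(n - 2), 1))] <- TRUE
    w <- sample(0:1, 1)
    r <- preranked_enrichment(sc, names(sc)[hit], weight = w, n_perm = 10,
                              seed = 5)
    expect_equal(r$es, oracle_es(sc, hit, w), tolerance = 1e-12)
  }
})

test_that("ES agrees with the fgsea statistic at weight 1", {
  set.seed(79)
  for (rep in 1:20) {
    n <- 50
    sc <- sort(rnorm(n, 0, 2), decreasing = TRUE)
    names(sc) <- sprintf("g%03d", 1:n)
    idx <- sort(sample.int(n, 8))
    mine <- preranked_enrichment(sc, names(sc)[idx], weight = 1, n_perm = 10,
                                 seed = 5)$es
    ref <- fgsea::calcGseaStat(sc, idx, gseaParam = 1)
    expect_equal(mine, ref, tolerance = 1e-9)
  }
})

test_that("permutation p is seeded-reproducible and small for a planted top set", {
  set.seed(83)
  n <- 100
  sc <- sort(rnorm(n), decreasing = TRUE)
  names(sc) <- sprintf("g%03d", 1:n)
  planted <- names(sc)[1:10]  # the very top of the ranking
  r1 <- preranked_enrichment(sc, planted, n_perm = 1000, seed = 7)
  r2 <- preranked_enrichment(sc, planted, n_perm = 1000, seed = 7)
  expect_identical(r1, r2)
  expect_lte(r1$p, 0.01)
})

test_that("hypergeometric ORA matches exhaustive enumeration for N <= 30", {
  # closed forms first
  out <- ora_hypergeometric(letters[1:5],
                            list(T1 = letters[1:5]), letters[1:20])
  expect_equal(out$p, 1 / choose(20, 5), tolerance = 1e-12)
  sat <- ora_hypergeometric(letters[1:4], list(ALL = letters[1:4]),
                            letters[1:4])
  expect_equal(sat$p, 1.0)
  expect_error(ora_hypergeometric("a", list(T = "a"), character(0)), "universe")

  # full sweep of (N, K, n, k): phyper-based path vs choose()-based oracle
  for (N in c(5, 12, 21, 30)) {
    univ <- sprintf("u%02d", 1:N)
    for (K in 0:N) for (n in 0:N) {
      term <- univ[seq_len(K)]
      for (k in max(0, K + n - N):min(K, n)) {
        query <- c(univ[seq_len(k)],
                   if (n - k > 0) univ[K + seq_len(n - k)] else character(0))
        got <- ora_hypergeometric(query, list(T = term), univ)$p
        expect_equal(got, oracle_hyper_upper(k, K, n, N), tolerance = 1e-11)
      }
    }
  }
})
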