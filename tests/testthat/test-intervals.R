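# Interval model, BED-family I/O and arithmetic against per-bp oracles.

test_that("BED6 and narrowPeak parsing maps fields per the UCSC/ENCODE layout", {
  f <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200\tpk1\t5\t."), f)
  iv <- read_intervals(f, "bed")
  expect_equal(nrow(iv), 1)
  expect_equal(iv$start, 100)
  expect_equal(iv$end, 200)
  expect_equal(iv$name, "pk1")
  expect_equal(iv$score, 5)

  writeLines(character(0), f)
  expect_equal(nrow(read_intervals(f, "bed")), 0)

  np <- tempfile(fileext = ".narrowPeak")
  writeLines("chr2\t10\t60\tp1\t900\t+\t7.5\t12.2\t9.31\t25", np)
  ivn <- read_intervals(np, "narrowPeak")
  expect_equal(ivn$score, 9.31)  # q-value exposed as score
  expect_equal(ivn$signalValue, 7.5)
  expect_equal(ivn$peak, 25)
})

test_that("malformed lines are rejected with their line number", {
  f <- tempfile()
  writeLines(c("chr1\t0\t10", "chr1\t50\t40"), f)
  expect_error(read_intervals(f, "bed"), "line 2")
  writeLines(c("chr1\tzero\t10"), f)
  expect_error(read_intervals(f, "bed"), "line 1")
  writeLines(c("chr1\t0\t10"), f)
  expect_error(read_intervals(f, "bed", genome = c(chrX = 100)), "unknown chrom")
  expect_equal(nrow(read_intervals(f, "bed", genome = c(chrX = 100),
                                   on_unknown_chrom = "skip")), 0)
})

test_that("read -> write -> read round trips are bit-exact for BED6 and narrowPeak", {
  set.seed(101)
  genome <- c(chr1 = 1e5, chr2 = 8e4)
  iv <- random_intervals(50, genome)
  iv$name <- sprintf("pk%02d", seq_len(nrow(iv)))
  iv$score <- round(runif(50, 0, 100), 3)
  iv$strand <- sample(c("+", "-", "."), 50, replace = TRUE)
  f1 <- tempfile(); f2 <- tempfile()
  write_intervals(iv, f1, "bed")
  back <- read_intervals(f1, "bed", genome = genome)
  expect_equal(back$start, iv$start)
  expect_equal(back$end, iv$end)
  expect_equal(back$score, iv$score)
  write_intervals(back, f2, "bed")
  expect_identical(readLines(f1), readLines(f2))

  np <- iv
  np$display_score <- sample(0:1000, 50)
  np$signalValue <- round(runif(50, 0, 30), 4)
  np$pValue <- round(runif(50, 0, 50), 4)
  np$qValue <- round(runif(50, 0, 40), 4)
  np$peak <- sample(0:100, 50)
  f3 <- tempfile(); f4 <- tempfile()
  write_intervals(np, f3, "narrowPeak")
  back <- read_intervals(f3, "narrowPeak", genome = genome)
  write_intervals(back, f4, "narrowPeak")
  expect_identical(readLines(f3), readLines(f4))
  expect_equal(back$qValue, np$qValue)
})

test_that("merge joins across gaps and matches the per-bp oracle", {
  genome <- c(chr1 = 1e4, chr2 = 1e4)
  empty <- interval_set(genome = genome)
  expect_equal(nrow(merge_intervals(empty, 10)), 0)

  # half-open abutment merges at gap 0
  ab <- interval_set(data.frame(chrom = "chr1", start = c(100, 200),
                                end = c(200, 300)), genome)
  m <- merge_intervals(ab, 0)
  expect_equal(nrow(m), 1)
  expect_equal(c(m$start, m$end), c(100, 300))

  set.seed(7)
  for (rep in 1:25) {
    s <- random_intervals(30, genome)
    gap <- sample(c(0, 5, 25, 100), 1)
    got <- merge_intervals(s, gap)
    want <- oracle_merge(s, gap, genome)
    expect_equal(got$chrom, want$chrom)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    # idempotence
    again <- merge_intervals(got, gap)
    expect_equal(again$start, got$start)
    expect_equal(again$end, got$end)
  }
})

test_that("subtract semantics: whole-peak removal and per-bp residuals", {
  genome <- c(chr1 = 1e4)
  a <- interval_set(data.frame(chrom = "chr1", start = 0, end = 100), genome)
  b <- interval_set(data.frame(chrom = "chr1", start = 50, end = 60), genome)
  expect_equal(nrow(subtract_intervals(a, interval_set(genome = genome))), 1)
  expect_equal(nrow(subtract_intervals(a, b, "whole_peak")), 0)
  bp <- subtract_intervals(a, b, "basepair")
  expect_equal(bp$start, c(0, 60))
  expect_equal(bp$end, c(50, 100))

  set.seed(13)
  genome2 <- c(chr1 = 5e4, chr2 = 5e4)
  for (rep in 1:25) {
    a <- random_intervals(40, genome2)
    b <- random_intervals(40, genome2)
    got <- subtract_intervals(a, b, "basepair")
    want <- oracle_subtract_bp(a, b, genome2)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    # covered-bp bookkeeping: covered(a \ b) == covered(a) - covered(a & b)
    inter <- oracle_runs(Map(`&`, oracle_cover(a, genome2),
                             oracle_cover(b, genome2)))
    expect_equal(oracle_covered_bp(got, genome2),
                 oracle_covered_bp(merge_intervals(a, 0), genome2) -
                   sum(inter$end - inter$start))
  }
})

test_that("center extension honors the flank, the 1-bp degenerate case and bounds", {
  genome <- c(chr1 = 100)
  iv <- interval_set(data.frame(chrom = "chr1", start = c(0, 40),
                                end = c(10, 60)), genome)
  e <- extend_from_center(iv, 150)
  expect_equal(e$start, c(0, 0))
  expect_equal(e$end, c(100, 100))  # clipped to chromosome length
  e0 <- extend_from_center(iv, 0)
  expect_equal(e0$start, c(5, 50))
  expect_equal(e0$end, c(6, 51))

  iv2 <- interval_set(data.frame(chrom = "chr1", start = 100, end = 200))
  e2 <- extend_from_center(iv2, 150)
  expect_equal(c(e2$start, e2$end), c(0, 300))

  set.seed(29)
  genome3 <- c(chr1 = 2e4, chr2 = 1e4)
  for (rep in 1:20) {
    s <- random_intervals(30, genome3)
    fl <- sample(c(0, 10, 150, 5000), 1)
    e <- extend_from_center(s, fl)
    expect_true(all(e$start >= 0))
    expect_true(all(e$end <= genome3[e$chrom]))
    ctr <- floor((s$start + s$end) / 2)
    expect_equal(e$start, pmax(ctr - fl, 0))
  }
})

test_that("nearest TSS matches the all-pairs oracle with deterministic ties", {
  tss <- data.frame(gene = c("B", "A"), chrom = "chr1", pos = c(400, 700),
                    strand = c("+", "-"), stringsAsFactors = FALSE)
  pk <- interval_set(data.frame(chrom = "chr1", start = 450, end = 550))
  r <- nearest_tss(pk, tss)
  expect_equal(r$gene, "B")
  expect_equal(r$distance, -100)

  # exact center hit and equidistant tie -> lexicographically smaller gene
  tss2 <- data.frame(gene = c("ZZ", "AA"), chrom = "chr1", pos = c(400, 600),
                     strand = "+", stringsAsFactors = FALSE)
  pk2 <- interval_set(data.frame(chrom = "chr1", start = 450, end = 550))
  expect_equal(nearest_tss(pk2, tss2)$gene, "AA")
  pk3 <- interval_set(data.frame(chrom = "chr1", start = 350, end = 450))
  expect_equal(nearest_tss(pk3, tss2)$distance, 0)

  # chromosome absent from annotation -> flagged NA
  pk4 <- interval_set(data.frame(chrom = "chrZ", start = 0, end = 10))
  expect_true(is.na(nearest_tss(pk4, tss)$gene))

  set.seed(31)
  genome <- c(chr1 = 5e4, chr2 = 5e4)
  peaks <- random_intervals(100, genome)
  tssr <- data.frame(gene = sprintf("G%02d", 1:20),
                     chrom = sample(names(genome), 20, replace = TRUE),
                     pos = sample.int(5e4, 20), strand = "+",
                     stringsAsFactors = FALSE)
  got <- nearest_tss(peaks, tssr)
  want <- oracle_nearest(peaks, tssr)
  expect_equal(got$gene, want$gene)
  expect_equal(got$distance, want$distance)
})
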