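# Stitching, signal scoring and the slope-1 tangent super-enhancer cutoff.

test_that("stitching merges within the gap and equals merge when exclusion is off", {
  genome <- c(chr1 = 1e5)
  pk <- interval_set(data.frame(chrom = "chr1", start = c(0, 5000),
                                end = c(1000, 6000)), genome)
  st <- stitch(pk, enhancer_config(stitch_gap = 12500))
  expect_equal(nrow(st), 1)
  expect_equal(c(st$start, st$end), c(0, 6000))
  expect_equal(st$constituents, 2L)
  st2 <- stitch(pk, enhancer_config(stitch_gap = 1000))
  expect_equal(nrow(st2), 2)

  set.seed(3)
  for (rep in 1:10) {
    pks <- random_intervals(50, genome, max_width = 800)
    st <- stitch(pks, enhancer_config(stitch_gap = 12500))
    m <- merge_intervals(pks, 12500)
    expect_equal(st$start, m$start)
    expect_equal(st$end, m$end)
  }
})

test_that("TSS exclusion removes peaks fully contained in the promoter window", {
  genome <- c(chr1 = 1e5)
  tss <- data.frame(gene = "G1", chrom = "chr1", pos = 50000, strand = "+")
  pk <- interval_set(data.frame(
    chrom = "chr1", start = c(49500, 48000, 10000),
    end = c(50500, 52500, 11000)), genome)
  st <- stitch(pk, enhancer_config(stitch_gap = 0, tss_exclusion_window = 2000),
               tss)
  # only the peak fully inside 48000-52000 is dropped; the straddler stays
  expect_equal(sort(st$start), c(10000, 48000))
})

test_that("region signal is the per-bp ChIP minus input sum, floored when asked", {
  genome <- c(chr1 = 1e4)
  reg <- interval_set(data.frame(chrom = "chr1", start = 100, end = 200),
                      genome)
  chip <- interval_set(data.frame(chrom = "chr1", start = 0, end = 1e4,
                                  score = 2), genome, validate = FALSE)
  inp <- interval_set(data.frame(chrom = "chr1", start = 0, end = 1e4,
                                 score = 1), genome, validate = FALSE)
  r <- score_regions(reg, chip, inp)
  expect_equal(r$signal, 100)
  expect_equal(score_regions(reg, chip, inp, stat = "mean")$signal, 1)
  r2 <- score_regions(reg, inp, chip)  # input exceeds chip everywhere
  expect_equal(r2$signal, 0)
  expect_equal(score_regions(reg, inp, chip, floor_at_zero = FALSE)$signal,
               -100)

  # random piecewise tracks vs per-bp accumulation oracle
  set.seed(17)
  for (rep in 1:10) {
    regs <- merge_intervals(random_intervals(20, genome, max_width = 300), 0)
    cuts <- sort(c(0, sample.int(1e4 - 1, 30), 1e4))
    vals <- round(runif(length(cuts) - 1, 0, 5), 2)
    track <- interval_set(data.frame(chrom = "chr1", start = cuts[-length(cuts)],
                                     end = cuts[-1], score = vals),
                          genome, validate = FALSE)
    got <- score_regions(regs, track, NULL, floor_at_zero = FALSE)
    perbp <- numeric(1e4)
    for (i in seq_len(nrow(track)))
      perbp[(track$start[i] + 1):track$end[i]] <- track$score[i]
    want <- vapply(seq_len(nrow(regs)), function(i)
      sum(perbp[(regs$start[i] + 1):regs$end[i]]), numeric(1))
    expect_equal(got$signal, want, tolerance = 1e-10)
  }
})

test_that("signal on a chromosome with no track coverage is zero with a warning", {
  genome <- c(chr1 = 1e3, chr2 = 1e3)
  regs <- interval_set(data.frame(chrom = c("chr1", "chr2"), start = 0,
                                  end = 100), genome)
  chip <- interval_set(data.frame(chrom = "chr1", start = 0, end = 1e3,
                                  score = 3), genome, validate = FALSE)
  expect_warning(r <- score_regions(regs, chip, NULL), "no signal")
  expect_equal(r$signal[r$chrom == "chr2"], 0)
})

test_that("tangent cutoff matches the all-index search oracle and is scale-free", {
  mk <- function(signals) {
    n <- length(signals)
    score_like <- data.frame(
      chrom = "chr1", start = seq_len(n) * 1000, end = seq_len(n) * 1000 + 500,
      name = sprintf("r%d", seq_len(n)), constituents = 1L, signal = signals,
      stringsAsFactors = FALSE)
    ord <- order(-signals)
    score_like$rank <- match(seq_len(n), ord)
    score_like$scaled_rank <- (n - score_like$rank) / (n - 1)
    rng <- range(signals)
    score_like$scaled_signal <- if (rng[2] > rng[1])
      (signals - rng[1]) / (rng[2] - rng[1]) else 0
    score_like$is_super <- NA
    score_like
  }
  # one extreme outlier: exactly that region is super
  r <- call_super_enhancers(mk(c(1:9, 100)))
  expect_equal(sum(r$is_super), 1)
  expect_true(r$is_super[r$signal == 100])
  # perfectly linear curve: slope never exceeds 1 -> oracle agrees (none)
  rl <- call_super_enhancers(mk(1:10))
  orl <- oracle_se_cutoff(1:10)
  expect_equal(sum(rl$is_super), sum(1:10 > orl$cutoff))
  # identical signals: degenerate, no supers
  expect_warning(rd <- call_super_enhancers(mk(rep(5, 6))), "identical")
  expect_equal(sum(rd$is_super), 0)

  set.seed(23)
  for (rep in 1:100) {
    n <- sample(3:200, 1)
    base <- sort(rexp(n, rate = 1 / 50))
    if (runif(1) < 0.5)  # hockey-stick: inflate a random top fraction
      base[n - seq_len(sample.int(max(1, n %/% 5), 1)) + 1] <-
        base[n] * runif(1, 5, 30)
    r <- call_super_enhancers(mk(base))
    o <- oracle_se_cutoff(base)
    expect_equal(attr(r, "cutoff_value"), o$cutoff)
    expect_equal(r$is_super, r$signal > o$cutoff)
    # positive affine rescale leaves the super set unchanged
    r2 <- call_super_enhancers(mk(base * 3.7 + 11))
    expect_equal(r2$is_super, r$is_super)
  }
})

test_that("differential enhancers behave as peak-level subtraction", {
  genome <- c(chr1 = 1e5)
  set.seed(5)
  a <- random_intervals(30, genome)
  expect_equal(nrow(differential_enhancers(a, a)), 0)
  b <- interval_set(data.frame(chrom = "chr1", start = 9e4, end = 9.1e4),
                    genome)
  d <- differential_enhancers(a, b)
  keep <- !(a$start < 9.1e4 & a$end > 9e4)
  expect_equal(d$start, a$start[keep])
})

test_that("super-enhancer gene assignment picks the nearest TSS of the region center", {
  tss <- data.frame(gene = c("NEAR", "FAR"), chrom = "chr1",
                    pos = c(1250, 9000), strand = "+")
  ranked <- data.frame(chrom = "chr1", start = 1000, end = 1500,
                       signal = 10, stringsAsFactors = FALSE)
  out <- assign_se_to_gene(ranked, tss)
  expect_equal(out$gene, "NEAR")
  expect_equal(out$distance, 0)
})
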