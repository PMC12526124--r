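# Independent brute-force oracles: plain base-R loops over per-bp boolean
# arrays, all-pairs scans and exact enumeration. Deliberately naive and
# separate from the implementation they check.

# random interval set on a toy genome (uses the ambient RNG state)
random_intervals <- function(n, genome, max_width = 400) {
  chroms <- sample(names(genome), n, replace = TRUE)
  w <- sample.int(max_width, n)
  s <- vapply(seq_len(n), function(i)
    sample.int(genome[[chroms[i]]] - w[i], 1) - 1, numeric(1))
  interval_set(data.frame(chrom = chroms, start = s, end = s + w,
                          stringsAsFactors = FALSE),
               genome = genome, validate = FALSE)
}

# per-bp boolean coverage, one logical vector per chromosome
oracle_cover <- function(set, genome) {
  cov <- lapply(genome, function(len) logical(len))
  for (i in seq_len(nrow(set))) {
    ch <- set$chrom[i]
    cov[[ch]][(set$start[i] + 1):set$end[i]] <- TRUE
  }
  cov
}

# boolean runs -> interval data.frame
oracle_runs <- function(cov) {
  out <- list()
  for (ch in names(cov)) {
    r <- rle(cov[[ch]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    for (j in which(r$values))
      out[[length(out) + 1]] <- data.frame(chrom = ch, start = starts[j],
                                           end = ends[j],
                                           stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric()))
  df <- do.call(rbind, out)
  df[order(df$chrom, df$start), , drop = FALSE]
}

# merge with gap bridging: cover, then fill gaps <= max_gap between runs
oracle_merge <- function(set, max_gap, genome) {
  cov <- oracle_cover(set, genome)
  if (max_gap > 0) {
    for (ch in names(cov)) {
      v <- cov[[ch]]
      r <- rle(v)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      for (j in seq_along(r$values)) {
        if (!r$values[j] && j > 1 && j < length(r$values) &&
            r$lengths[j] <= max_gap)
          v[starts[j]:ends[j]] <- TRUE
      }
      cov[[ch]] <- v
    }
  }
  oracle_runs(cov)
}

oracle_subtract_bp <- function(a, b, genome) {
  ca <- oracle_cover(a, genome)
  cb <- oracle_cover(b, genome)
  oracle_runs(Map(function(x, y) x & !y, ca, cb))
}

oracle_covered_bp <- function(set, genome) {
  sum(vapply(oracle_cover(set, genome), sum, numeric(1)))
}

# all-pairs nearest TSS with the lexicographic tie rule
oracle_nearest <- function(set, tss) {
  n <- nrow(set)
  gene <- rep(NA_character_, n); dist <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    ctr <- floor((set$start[i] + set$end[i]) / 2)
    t <- tss[tss$chrom == set$chrom[i], , drop = FALSE]
    if (nrow(t) == 0) next
    best <- NULL
    for (j in seq_len(nrow(t))) {
      d <- t$pos[j] - ctr
      if (is.null(best) || abs(d) < abs(best$d) ||
          (abs(d) == abs(best$d) && t$gene[j] < best$g))
        best <- list(d = d, g = t$gene[j])
    }
    gene[i] <- best$g; dist[i] <- best$d
  }
  data.frame(gene = gene, distance = dist, stringsAsFactors = FALSE)
}

# all-index tangent search: test each index of the ascending scaled curve as
# the first slope > 1 crossing; returns cutoff on the original scale
oracle_se_cutoff <- function(signals) {
  s <- sort(signals)
  n <- length(s)
  if (s[1] == s[n]) return(list(cutoff = NA_real_, super = rep(FALSE, n)))
  y <- (s - s[1]) / (s[n] - s[1])
  x <- (seq_len(n) - 1) / (n - 1)
  cut_idx <- NA
  for (i in seq_len(n)) {
    lo <- max(1, i - 1); hi <- min(n, i + 1)
    sl <- (y[hi] - y[lo]) / (x[hi] - x[lo])
    if (sl > 1) { cut_idx <- i; break }
  }
  cutoff <- if (is.na(cut_idx)) s[n] else s[cut_idx]
  list(cutoff = cutoff, super_signal_above = cutoff)
}

# exact hypergeometric mass via binomial coefficients (no dhyper)
oracle_hyper_mass <- function(x, K, N, n) {
  exp(lchoose(K, x) + lchoose(N - K, n - x) - lchoose(N, n))
}

# two-sided Fisher p for every observed x at fixed margins, by enumeration
oracle_fisher_all_x <- function(K, n, N) {
  lo <- max(0, n - (N - K)); hi <- min(K, n)
  xs <- lo:hi
  dens <- oracle_hyper_mass(xs, K, N, n)
  vapply(seq_along(xs), function(i)
    min(1, sum(dens[dens <= dens[i] * (1 + 1e-7)])), numeric(1))
}

# upper-tail hypergeometric by enumeration
oracle_hyper_upper <- function(k, K, n, N) {
  hi <- min(K, n)
  if (k > hi) return(0)
  sum(oracle_hyper_mass(k:hi, K, N, n))
}

# running-sum enrichment statistic by explicit loop
oracle_es <- function(scores_desc, hit, weight) {
  n <- length(scores_desc)
  nh <- sum(hit)
  w <- abs(scores_desc)^weight
  tot <- sum(w[hit])
  rs <- 0; best <- 0
  for (i in seq_len(n)) {
    rs <- rs + if (hit[i]) {
      if (tot > 0) w[i] / tot else 1 / nh
    } else -1 / (n - nh)
    if (abs(rs) > abs(best)) best <- rs
  }
  unname(best)
}

# convenience: noise-free default synthetic dataset shared across tests
synth_fixture <- local({
  cache <- NULL
  function(seed = 42) {
    if (!is.null(cache) && cache$seed == seed) return(cache)
    d <- file.path(tempdir(), sprintf("regcircuit_synth_%d", seed))
    truth <- generate_synthetic_data(synth_config(seed = seed), d)
    cache <<- list(seed = seed, dir = d, truth = truth)
    cache
  }
})
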