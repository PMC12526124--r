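# Pairwise TF co-binding: nucleosome-scale center extension, overlap
# tabulation over a fixed-width genomic-bin universe, and Fisher exact
# significance.

#' Tile a genome into fixed-width bins
#'
#' Non-overlapping bins of \code{bin_width}; the last bin per chromosome may
#' be short.
#'
#' @param genome named chromosome-length vector.
#' @param bin_width bp > 0.
#' @return interval_set of bins.
#' @export
tile_genome <- function(genome, bin_width = 1000) {
  stopifnot(bin_width > 0)
  dfs <- lapply(names(genome), function(ch) {
    len <- genome[[ch]]
    s <- seq(0, len - 1, by = bin_width)
    data.frame(chrom = ch, start = s, end = pmin(s + bin_width, len),
               stringsAsFactors = FALSE)
  })
  interval_set(do.call(rbind, dfs), genome = genome, validate = FALSE)
}

#' Build a 2x2 bin-overlap table for two peak sets
#'
#' Both sets are extended bilaterally \code{extend} bp from the peak center
#' (slightly more than one nucleosomal unit at the 150 bp default), the
#' genome is tiled into \code{bin_width} bins, and each bin is classified by
#' whether it intersects the extended sets.
#'
#' @param a,b interval_set on \code{genome}.
#' @param genome named chromosome-length vector.
#' @param bin_width bin width in bp (default 1000).
#' @param extend center-extension flank in bp (default 150; 0 keeps peaks
#'   as-is).
#' @return list of class \code{overlap_table}: n_both, n_a_only, n_b_only,
#'   n_neither, universe_size, bin_width, extend.
#' @export
build_overlap_table <- function(a, b, genome, bin_width = 1000, extend = 150) {
  bins <- tile_genome(genome, bin_width)
  ea <- if (extend > 0) extend_from_center(a, extend) else a
  eb <- if (extend > 0) extend_from_center(b, extend) else b
  in_a <- .overlaps_any(bins, ea)
  in_b <- .overlaps_any(bins, eb)
  structure(list(
    n_both = sum(in_a & in_b),
    n_a_only = sum(in_a & !in_b),
    n_b_only = sum(!in_a & in_b),
    n_neither = sum(!in_a & !in_b),
    universe_size = nrow(bins),
    bin_width = bin_width,
    extend = extend
  ), class = "overlap_table")
}

#' Fisher exact test on a 2x2 overlap table
#'
#' Two-sided p by summing, over the hypergeometric distribution fixed at the
#' table margins, the probabilities of all tables at most as probable as the
#' observed one (with the conventional 1e-7 relative tolerance for ties).
#' The odds ratio is the sample odds ratio
#' (n_both * n_neither) / (n_a_only * n_b_only), Inf when the denominator is
#' 0 with a nonzero numerator. Degenerate margins give p = 1 and NA odds
#' ratio.
#'
#' @param t \code{overlap_table} (or list with the four cells).
#' @return list(odds_ratio, p_two_sided).
#' @export
fisher_overlap_test <- function(t) {
  m <- c(t$n_both, t$n_a_only, t$n_b_only, t$n_neither)
  stopifnot(all(m >= 0))
  N <- sum(m)
  K <- t$n_both + t$n_a_only    # bins hit by a
  nn <- t$n_both + t$n_b_only   # bins hit by b (draws)
  if (K == 0 || nn == 0 || K == N || nn == N)
    return(list(odds_ratio = NA_real_, p_two_sided = 1.0, degenerate = TRUE))
  lo <- max(0, nn - (N - K)); hi <- min(K, nn)
  support <- lo:hi
  dens <- stats::dhyper(support, K, N - K, nn)
  obs <- stats::dhyper(t$n_both, K, N - K, nn)
  p <- sum(dens[dens <= obs * (1 + 1e-7)])
  p <- min(p, 1.0)
  odds <- if (t$n_a_only == 0 || t$n_b_only == 0) {
    if (t$n_both * t$n_neither > 0) Inf else NA_real_
  } else (t$n_both * t$n_neither) / (t$n_a_only * t$n_b_only)
  if (!is.na(odds) && t$n_both == 0) odds <- 0
  list(odds_ratio = odds, p_two_sided = p, degenerate = FALSE)
}

#' Pairwise TF co-binding matrix
#'
#' Tests every unordered pair of TF peak sets over the binned universe and
#' reports directional peak-level overlap fractions (fraction of extended a
#' peaks intersecting any extended b peak, and vice versa), the odds ratio,
#' raw Fisher p and BH-adjusted p across pairs.
#'
#' @param tf_sets named list of interval_set, one per TF (>= 2).
#' @param genome named chromosome-length vector.
#' @param bin_width,extend as in \code{build_overlap_table}.
#' @return Long-format data.frame: tf_a, tf_b, frac_a_in_b, frac_b_in_a,
#'   n_both, odds_ratio, p, p_adj, bin_width, extend.
#' @export
pairwise_cobinding <- function(tf_sets, genome, bin_width = 1000,
                               extend = 150) {
  stopifnot(length(tf_sets) >= 2, !is.null(names(tf_sets)))
  tfs <- names(tf_sets)
  ext <- lapply(tf_sets, function(s)
    if (extend > 0) extend_from_center(s, extend) else s)
  pairs <- utils::combn(tfs, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    ta <- pairs[1, i]; tb <- pairs[2, i]
    tab <- build_overlap_table(tf_sets[[ta]], tf_sets[[tb]], genome,
                               bin_width = bin_width, extend = extend)
    ft <- fisher_overlap_test(tab)
    data.frame(
      tf_a = ta, tf_b = tb,
      frac_a_in_b = mean(.overlaps_any(ext[[ta]], ext[[tb]])),
      frac_b_in_a = mean(.overlaps_any(ext[[tb]], ext[[ta]])),
      n_both = tab$n_both,
      odds_ratio = ft$odds_ratio,
      p = ft$p_two_sided,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out$bin_width <- bin_width
  out$extend <- extend
  out
}
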