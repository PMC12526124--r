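# ROSE-style enhancer calling: stitch constituent H3K27ac peaks, score
# stitched regions by input-subtracted signal, and call super-enhancers at
# the slope-1 tangent point of the scaled rank curve.

#' Enhancer-calling configuration
#'
#' Defaults follow the published ROSE defaults: 12.5 kb stitching, TSS
#' exclusion off, ChIP - input signal floored at zero.
#'
#' @param stitch_gap bp gap bridged when stitching constituent peaks.
#' @param tss_exclusion_window bp; peaks fully inside +/- window of a TSS are
#'   dropped before stitching. 0 disables the filter.
#' @param signal_floor_at_zero floor region signal at 0 after input
#'   subtraction.
#' @return list of class \code{enhancer_config}.
#' @export
enhancer_config <- function(stitch_gap = 12500, tss_exclusion_window = 0,
                            signal_floor_at_zero = TRUE) {
  stopifnot(stitch_gap >= 0, tss_exclusion_window >= 0)
  structure(list(stitch_gap = stitch_gap,
                 tss_exclusion_window = tss_exclusion_window,
                 signal_floor_at_zero = signal_floor_at_zero),
            class = "enhancer_config")
}

#' Stitch constituent peaks into enhancer regions
#'
#' Peaks within \code{cfg$stitch_gap} of each other are merged; with TSS
#' exclusion on, peaks fully contained within +/- window of any TSS are
#' removed first. With exclusion off this is exactly
#' \code{merge_intervals(peaks, stitch_gap)}.
#'
#' @param peaks interval_set of constituent peaks (e.g. H3K27ac).
#' @param cfg \code{enhancer_config}.
#' @param tss TSS table, required when exclusion window > 0.
#' @return interval_set of stitched regions with a \code{constituents} column.
#' @export
stitch <- function(peaks, cfg = enhancer_config(), tss = NULL) {
  if (nrow(peaks) == 0) stop("stitch: empty peak set")
  kept <- peaks
  if (cfg$tss_exclusion_window > 0) {
    if (is.null(tss)) stop("stitch: tss table required when exclusion window > 0")
    excl <- interval_set(data.frame(
      chrom = tss$chrom,
      start = pmax(tss$pos - cfg$tss_exclusion_window, 0),
      end = tss$pos + cfg$tss_exclusion_window,
      stringsAsFactors = FALSE
    ), genome = genome_of(peaks), validate = FALSE)
    gra <- as_granges(kept); gre <- as_granges(excl)
    contained <- GenomicRanges::countOverlaps(gra, gre, type = "within",
                                              ignore.strand = TRUE) > 0
    kept <- kept[!contained, , drop = FALSE]
    attr(kept, "genome") <- genome_of(peaks)
    class(kept) <- unique(c("interval_set", class(kept)))
    if (nrow(kept) == 0) return(interval_set(genome = genome_of(peaks)))
  }
  stitched <- merge_intervals(kept, cfg$stitch_gap)
  n_in <- GenomicRanges::countOverlaps(as_granges(stitched), as_granges(kept),
                                       ignore.strand = TRUE)
  stitched$constituents <- as.integer(n_in)
  stitched$name <- sprintf("stitched_%d", seq_len(nrow(stitched)))
  stitched
}

# sum of track value * overlap width over each region; uncovered bp are 0
.region_track_sum <- function(regions_gr, track) {
  out <- numeric(length(regions_gr))
  if (nrow(track) == 0) return(out)
  tgr <- as_granges(track)
  hits <- GenomicRanges::findOverlaps(regions_gr, tgr, ignore.strand = TRUE)
  if (length(hits) == 0) return(out)
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  ov <- IRanges::pintersect(IRanges::ranges(regions_gr)[q],
                            IRanges::ranges(tgr)[s])
  contrib <- IRanges::width(ov) * track$score[s]
  sums <- tapply(contrib, q, sum)
  out[as.integer(names(sums))] <- as.numeric(sums)
  out
}

#' Score and rank stitched regions by input-subtracted signal
#'
#' Signal for a region is the per-bp sum of ChIP coverage minus the per-bp
#' sum of input coverage over the region (piecewise-constant bedGraph tracks;
#' uncovered bases contribute 0), floored at 0 when configured. Ranks are by
#' descending signal; \code{scaled_rank} and \code{scaled_signal} are min-max
#' scaled to [0, 1].
#'
#' @param regions interval_set of stitched regions.
#' @param chip_signal,input_signal bedGraph interval_sets (value in score).
#' @param floor_at_zero floor negative signal at 0.
#' @param stat "sum" (default) or "mean" (per-bp mean difference).
#' @return data.frame of ranked enhancers: region coordinates,
#'   constituents, signal, rank, scaled_rank, scaled_signal, is_super (NA
#'   until \code{call_super_enhancers}).
#' @export
score_regions <- function(regions, chip_signal, input_signal = NULL,
                          floor_at_zero = TRUE, stat = c("sum", "mean")) {
  stat <- match.arg(stat)
  if (nrow(regions) == 0) stop("score_regions: no regions")
  rgr <- as_granges(regions)
  covered_chroms <- union(unique(chip_signal$chrom),
                          if (is.null(input_signal)) character(0)
                          else unique(input_signal$chrom))
  orphan <- !(regions$chrom %in% covered_chroms)
  if (any(orphan))
    warning(sprintf("score_regions: %d region(s) on chromosome(s) with no signal; signal set to 0",
                    sum(orphan)))
  sig <- .region_track_sum(rgr, chip_signal)
  if (!is.null(input_signal)) sig <- sig - .region_track_sum(rgr, input_signal)
  if (stat == "mean") sig <- sig / (regions$end - regions$start)
  if (floor_at_zero) sig <- pmax(sig, 0)
  df <- data.frame(
    chrom = regions$chrom, start = regions$start, end = regions$end,
    name = if ("name" %in% names(regions)) regions$name
           else sprintf("region_%d", seq_len(nrow(regions))),
    constituents = if ("constituents" %in% names(regions))
      regions$constituents else NA_integer_,
    signal = sig,
    stringsAsFactors = FALSE
  )
  ord <- order(-df$signal, df$chrom, df$start)
  rank <- integer(nrow(df)); rank[ord] <- seq_len(nrow(df))
  df$rank <- rank
  n <- nrow(df)
  rng <- range(df$signal)
  df$scaled_rank <- if (n == 1) 1 else (n - df$rank) / (n - 1)
  df$scaled_signal <- if (rng[2] > rng[1])
    (df$signal - rng[1]) / (rng[2] - rng[1]) else rep(0, n)
  df$is_super <- NA
  class(df) <- c("ranked_enhancers", "data.frame")
  df
}

# discrete slope of the scaled signal curve (ascending order) by central
# differences; one-sided at the ends
.scaled_curve_slopes <- function(y_scaled) {
  n <- length(y_scaled)
  x <- (seq_len(n) - 1) / (n - 1)
  slope <- numeric(n)
  slope[1] <- (y_scaled[2] - y_scaled[1]) / (x[2] - x[1])
  slope[n] <- (y_scaled[n] - y_scaled[n - 1]) / (x[n] - x[n - 1])
  if (n > 2) {
    i <- 2:(n - 1)
    slope[i] <- (y_scaled[i + 1] - y_scaled[i - 1]) / (x[i + 1] - x[i - 1])
  }
  slope
}

#' Call super-enhancers at the slope-1 tangent point
#'
#' Regions are sorted by ascending signal and both axes min-max scaled to
#' [0, 1]; scanning from low signal, the cutoff is the scaled signal at the
#' first index whose discrete slope (central differences) exceeds 1. Regions
#' with scaled signal strictly above the cutoff are flagged super. Ties
#' resolve toward fewer super-enhancers; the call is invariant under positive
#' affine rescaling of all signals.
#'
#' @param ranked \code{ranked_enhancers} data.frame from
#'   \code{score_regions}.
#' @return The input with \code{is_super} filled, carrying attributes
#'   \code{cutoff_value} (original signal scale) and \code{cutoff_scaled}.
#' @export
call_super_enhancers <- function(ranked) {
  n <- nrow(ranked)
  if (n < 3) stop("call_super_enhancers: need >= 3 regions")
  s <- sort(ranked$signal)
  if (s[1] == s[n]) {
    warning("call_super_enhancers: all signals identical; no super-enhancers")
    ranked$is_super <- FALSE
    attr(ranked, "cutoff_value") <- NA_real_
    attr(ranked, "cutoff_scaled") <- NA_real_
    return(ranked)
  }
  y <- (s - s[1]) / (s[n] - s[1])
  slope <- .scaled_curve_slopes(y)
  cross <- which(slope > 1)
  if (length(cross) == 0) {
    cutoff_scaled <- 1
    cutoff_value <- s[n]
  } else {
    i <- cross[1]
    cutoff_scaled <- y[i]
    cutoff_value <- s[i]
  }
  ranked$is_super <- ranked$signal > cutoff_value
  attr(ranked, "cutoff_value") <- cutoff_value
  attr(ranked, "cutoff_scaled") <- cutoff_scaled
  ranked
}

#' Condition-unique (gained) enhancers
#'
#' Constituent peaks of the restored condition not present in the absent
#' condition, via \code{subtract_intervals}. The default whole-peak mode
#' keeps a restored-condition peak only if it has zero bp overlap with any
#' absent-condition peak.
#'
#' @param restored_peaks,absent_peaks interval_set on the same genome.
#' @param mode "whole_peak" (default) or "basepair".
#' @return interval_set of gained/unique constituent enhancer peaks.
#' @export
differential_enhancers <- function(restored_peaks, absent_peaks,
                                   mode = c("whole_peak", "basepair")) {
  out <- subtract_intervals(restored_peaks, absent_peaks, mode = match.arg(mode))
  attr(out, "label") <- "gained_constituent_enhancers"
  out
}

#' Assign enhancers to the gene of the nearest TSS
#'
#' @param ranked \code{ranked_enhancers} data.frame (or any data.frame with
#'   chrom/start/end).
#' @param tss TSS table.
#' @return The input with gene and distance columns appended.
#' @export
assign_se_to_gene <- function(ranked, tss) {
  iv <- interval_set(ranked[, c("chrom", "start", "end")], validate = FALSE)
  nt <- nearest_tss(iv, tss)
  ranked$gene <- nt$gene
  ranked$distance <- nt$distance
  ranked
}
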