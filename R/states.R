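# Rule-based chromatin-state classification of TF binding sites and
# promoter-level integration with super-enhancers.
#
# The four states: active promoter (H3K4me3+), active enhancer independent of
# the remodeler (H3K4me1+ and H3K27ac+ in the subunit-absent condition),
# active enhancer dependent on it (H3K4me1+ and H3K27ac+ only in the restored
# condition), and poised enhancer (H3K4me1+ only). A fifth catch-all
# "unclassified" keeps the partition exhaustive.

TF_STATES <- c("active_promoter", "active_enhancer_smarcb1_independent",
               "active_enhancer_smarcb1_dependent", "poised_enhancer",
               "unclassified")

.overlaps_any <- function(x, y) {
  if (nrow(x) == 0) return(logical(0))
  if (is.null(y) || nrow(y) == 0) return(rep(FALSE, nrow(x)))
  GenomicRanges::countOverlaps(as_granges(x), as_granges(y),
                               ignore.strand = TRUE) > 0
}

#' Classify TF peaks into four chromatin states
#'
#' Precedence per peak: (1) overlaps H3K4me3 -> active_promoter; else
#' (2) H3K4me1 and absent-condition H3K27ac -> smarcb1-independent enhancer;
#' else (3) H3K4me1 and restored-condition H3K27ac -> smarcb1-dependent
#' enhancer; else (4) H3K4me1 only -> poised enhancer; else unclassified.
#' Overlap is >= 1 shared bp. Every peak receives exactly one state.
#'
#' @param tf_peaks interval_set of TF binding sites.
#' @param h3k4me3,h3k4me1 promoter / enhancer-priming mark peak sets.
#' @param k27ac_absent,k27ac_restored H3K27ac peaks in the two conditions.
#' @return data.frame: peak coordinates, state, evidence (semicolon-joined
#'   overlapping mark labels).
#' @export
classify_tf_peaks <- function(tf_peaks, h3k4me3, h3k4me1, k27ac_absent,
                              k27ac_restored) {
  n <- nrow(tf_peaks)
  me3 <- .overlaps_any(tf_peaks, h3k4me3)
  me1 <- .overlaps_any(tf_peaks, h3k4me1)
  aca <- .overlaps_any(tf_peaks, k27ac_absent)
  acr <- .overlaps_any(tf_peaks, k27ac_restored)
  state <- rep("unclassified", n)
  state[me1] <- "poised_enhancer"
  state[me1 & acr] <- "active_enhancer_smarcb1_dependent"
  state[me1 & aca] <- "active_enhancer_smarcb1_independent"
  state[me3] <- "active_promoter"
  ev <- cbind(H3K4me3 = me3, H3K4me1 = me1, H3K27ac_absent = aca,
              H3K27ac_restored = acr)
  evidence <- apply(ev, 1, function(r) paste(colnames(ev)[r], collapse = ";"))
  if (n == 0) evidence <- character(0)
  data.frame(chrom = tf_peaks$chrom, start = tf_peaks$start,
             end = tf_peaks$end,
             name = tf_peaks$name, state = factor(state, levels = TF_STATES),
             evidence = evidence, stringsAsFactors = FALSE)
}

#' Call TF/SMARCA4-flagged active promoters
#'
#' A promoter is an H3K4me3 peak whose center lies within +/- \code{window}
#' bp of an annotated TSS (the peak center is the anchor). SMARCA4 and
#' per-TF occupancy flags are set by >= 1 bp overlap with the respective
#' peak sets.
#'
#' @param h3k4me3 interval_set of H3K4me3 peaks.
#' @param tss TSS table.
#' @param window bp on each side of the TSS (default 2000).
#' @param smarca4 optional interval_set of SMARCA4 (ATPase) peaks.
#' @param tf_peaks named list of interval_set, one per TF.
#' @return data.frame of class \code{promoter_set}: promoter coordinates,
#'   gene, tss distance, smarca4 flag, one bound_<TF> flag per TF.
#' @export
call_active_promoters <- function(h3k4me3, tss, window = 2000,
                                  smarca4 = NULL, tf_peaks = list()) {
  stopifnot(window > 0)
  nt <- nearest_tss(h3k4me3, tss)
  keep <- !is.na(nt$distance) & abs(nt$distance) <= window
  prom <- h3k4me3[keep, , drop = FALSE]
  attr(prom, "genome") <- genome_of(h3k4me3)
  class(prom) <- unique(c("interval_set", class(prom)))
  out <- data.frame(chrom = prom$chrom, start = prom$start, end = prom$end,
                    gene = nt$gene[keep], tss_distance = nt$distance[keep],
                    stringsAsFactors = FALSE)
  out$smarca4 <- if (is.null(smarca4)) rep(FALSE, nrow(out)) else
    .overlaps_any(prom, smarca4)
  for (tf in names(tf_peaks))
    out[[paste0("bound_", tf)]] <- .overlaps_any(prom, tf_peaks[[tf]])
  rownames(out) <- NULL
  class(out) <- c("promoter_set", "data.frame")
  out
}

#' Super-enhancer / promoter overlap
#'
#' Fraction of super-enhancers containing (>= 1 bp overlap) a promoter that
#' passes the required flags, e.g. SMARCA4-bound and bound by a given TF.
#'
#' @param ses \code{ranked_enhancers} rows to assess (typically
#'   \code{is_super} rows).
#' @param promoters \code{promoter_set} from \code{call_active_promoters}.
#' @param require character vector of flag columns that must all be TRUE for
#'   a promoter to qualify ("smarca4", "bound_<TF>", ...). Empty = any
#'   promoter.
#' @return list(count_overlapping, fraction, per_se) where per_se carries an
#'   \code{overlaps_promoter} flag per input region.
#' @export
se_promoter_overlap <- function(ses, promoters, require = character(0)) {
  if (nrow(ses) == 0)
    return(list(count_overlapping = 0L, fraction = NA_real_,
                per_se = cbind(ses, overlaps_promoter = logical(0))))
  qual <- rep(TRUE, nrow(promoters))
  for (fl in require) {
    if (!fl %in% names(promoters))
      stop("se_promoter_overlap: no promoter flag column '", fl, "'")
    qual <- qual & promoters[[fl]]
  }
  pq <- promoters[qual, , drop = FALSE]
  se_iv <- interval_set(ses[, c("chrom", "start", "end")], validate = FALSE)
  pq_iv <- interval_set(pq[, c("chrom", "start", "end")], validate = FALSE)
  flags <- .overlaps_any(se_iv, pq_iv)
  ses$overlaps_promoter <- flags
  list(count_overlapping = sum(flags), fraction = mean(flags), per_se = ses)
}
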