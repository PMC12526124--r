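# Genomic interval data model and arithmetic.
#
# Coordinates are BED-convention 0-based half-open everywhere: an interval
# [start, end) covers bases start .. end-1. All set arithmetic is delegated to
# IRanges/GenomicRanges behind this surface; conversion adds 1 to start.

#' Construct a validated interval set
#'
#' An interval set is a data.frame with columns \code{chrom}, \code{start},
#' \code{end} (0-based half-open), and optional \code{name}, \code{score},
#' \code{strand}, carrying the genome (named vector of chromosome lengths) as
#' an attribute. It is the container for every peak set in the pipeline.
#'
#' @param df data.frame with at least chrom/start/end columns.
#' @param genome optional named numeric vector of chromosome lengths (bp).
#' @param validate check invariants (start >= 0, end > start, bounds).
#' @return A data.frame of class \code{interval_set}.
#' @export
interval_set <- function(df = data.frame(chrom = character(), start = integer(),
                                         end = integer()),
                         genome = NULL, validate = TRUE) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  df$chrom <- as.character(df$chrom)
  df$start <- as.numeric(df$start)
  df$end <- as.numeric(df$end)
  if (!"name" %in% names(df)) df$name <- rep(NA_character_, nrow(df))
  if (!"score" %in% names(df)) df$score <- rep(NA_real_, nrow(df))
  if (!"strand" %in% names(df)) df$strand <- rep(".", nrow(df))
  if (validate) {
    if (any(!nzchar(df$chrom))) stop("interval_set: empty chrom id")
    if (any(is.na(df$start) | is.na(df$end))) stop("interval_set: NA coordinates")
    if (any(df$start < 0)) stop("interval_set: start < 0")
    if (any(df$end <= df$start)) {
      i <- which(df$end <= df$start)[1]
      stop(sprintf("interval_set: end <= start at row %d (%s:%s-%s)",
                   i, df$chrom[i], df$start[i], df$end[i]))
    }
    if (!is.null(genome)) {
      unknown <- setdiff(unique(df$chrom), names(genome))
      if (length(unknown) > 0)
        stop("interval_set: chrom(s) not in genome: ",
             paste(unknown, collapse = ", "))
      if (any(df$end > genome[df$chrom]))
        stop("interval_set: interval exceeds chromosome length")
    }
  }
  attr(df, "genome") <- genome
  class(df) <- unique(c("interval_set", class(df)))
  df
}

#' @export
print.interval_set <- function(x, ...) {
  g <- attr(x, "genome")
  cat(sprintf("interval_set: %d intervals on %d chromosome(s)%s\n",
              nrow(x), length(unique(x$chrom)),
              if (is.null(g)) "" else sprintf(" (genome: %d seqs)", length(g))))
  print.data.frame(utils::head(as.data.frame(x), 10), ...)
  if (nrow(x) > 10) cat(sprintf("... and %d more\n", nrow(x) - 10))
  invisible(x)
}

genome_of <- function(x) attr(x, "genome")

# interval_set -> GRanges (1-based closed)
as_granges <- function(x) {
  g <- genome_of(x)
  gr <- GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1, end = x$end),
    strand = ifelse(x$strand %in% c("+", "-"), x$strand, "*")
  )
  if (!is.null(g)) {
    GenomeInfoDb::seqlevels(gr) <- names(g)
    GenomeInfoDb::seqlengths(gr) <- g
  }
  gr
}

# GRanges -> interval_set (back to 0-based half-open)
from_granges <- function(gr, genome = NULL) {
  interval_set(data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  ), genome = genome, validate = FALSE)
}

interval_centers <- function(x) floor((x$start + x$end) / 2)

#' Read a genome file
#'
#' Two tab-separated columns: chromosome id, length in bp.
#'
#' @param path file path.
#' @param header whether the file carries a header line.
#' @return Named numeric vector of chromosome lengths.
#' @export
read_genome <- function(path, header = FALSE) {
  tab <- utils::read.delim(path, header = header, stringsAsFactors = FALSE)
  stats::setNames(as.numeric(tab[[2]]), as.character(tab[[1]]))
}

#' Write a genome file
#' @param genome named numeric vector of chromosome lengths.
#' @param path output path.
#' @export
write_genome <- function(genome, path) {
  writeLines(paste(names(genome), format(genome, scientific = FALSE, trim = TRUE),
                   sep = "\t"), path)
}

#' Read a TSS table
#'
#' Tab-separated with header: gene, chrom, pos (0-based bp), strand.
#'
#' @param path file path.
#' @return data.frame with columns gene, chrom, pos, strand.
#' @export
read_tss <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "chrom", "pos") %in% names(tab)))
  if (!"strand" %in% names(tab)) tab$strand <- "+"
  tab$pos <- as.numeric(tab$pos)
  tab
}

#' Write a TSS table
#' @param tss data.frame (gene, chrom, pos, strand).
#' @param path output path.
#' @export
write_tss <- function(tss, path) {
  utils::write.table(tss[, c("gene", "chrom", "pos", "strand")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
}

.format_bed_fields <- function(v) {
  # as.character keeps integers unpadded and numerics at full precision,
  # which makes object -> file -> object round trips exact
  out <- as.character(v)
  out[is.na(v)] <- "."
  out
}

.parse_num <- function(txt, lineno, what) {
  v <- suppressWarnings(as.numeric(txt))
  bad <- is.na(v) & !(txt %in% c(".", "NA"))
  if (any(bad))
    stop(sprintf("malformed %s at line %d: '%s'", what, lineno[bad][1],
                 txt[bad][1]))
  v
}

#' Read a BED-family interval file
#'
#' Supports BED3-6, ENCODE narrowPeak (10 col), broadPeak (9 col) and bedGraph
#' (4 col; the value lands in \code{score}). For narrowPeak/broadPeak the
#' q-value column is exposed as \code{score} and all ENCODE columns are kept
#' so the file round-trips exactly. Input ordering is preserved.
#'
#' @param path file path.
#' @param format one of "bed", "narrowPeak", "broadPeak", "bedgraph".
#' @param genome optional named chromosome-length vector for bounds checks.
#' @param on_unknown_chrom "error" (default) or "skip" for intervals on a
#'   chromosome absent from \code{genome}.
#' @return An \code{interval_set}.
#' @export
read_intervals <- function(path, format = c("bed", "narrowPeak", "broadPeak",
                                            "bedgraph"),
                           genome = NULL,
                           on_unknown_chrom = c("error", "skip")) {
  format <- match.arg(format)
  on_unknown_chrom <- match.arg(on_unknown_chrom)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lineno <- seq_along(lines)
  keep <- nzchar(lines) & !grepl("^(track|browser|#)", lines)
  lines <- lines[keep]; lineno <- lineno[keep]
  if (length(lines) == 0) return(interval_set(genome = genome))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(parts)
  need <- switch(format, bed = 3, bedgraph = 4, broadPeak = 9, narrowPeak = 10)
  if (any(ncols < need))
    stop(sprintf("malformed line %d: %d field(s), %s needs >= %d",
                 lineno[ncols < need][1], ncols[ncols < need][1], format, need))
  col <- function(i) vapply(parts, function(p) if (length(p) >= i) p[i] else ".",
                            character(1))
  chrom <- col(1)
  start <- .parse_num(col(2), lineno, "start")
  end <- .parse_num(col(3), lineno, "end")
  if (any(is.na(start) | is.na(end)))
    stop(sprintf("malformed coordinate at line %d",
                 lineno[is.na(start) | is.na(end)][1]))
  bad <- end <= start
  if (any(bad))
    stop(sprintf("end <= start at line %d (%s:%s-%s)", lineno[bad][1],
                 chrom[bad][1], start[bad][1], end[bad][1]))
  df <- data.frame(chrom = chrom, start = start, end = end,
                   stringsAsFactors = FALSE)
  if (format == "bed") {
    maxc <- max(ncols)
    if (maxc >= 4) df$name <- col(4)
    if (maxc >= 5) df$score <- .parse_num(col(5), lineno, "score")
    if (maxc >= 6) df$strand <- col(6)
  } else if (format == "bedgraph") {
    df$score <- .parse_num(col(4), lineno, "value")
  } else {
    df$name <- col(4)
    df$display_score <- .parse_num(col(5), lineno, "score")
    df$strand <- col(6)
    df$signalValue <- .parse_num(col(7), lineno, "signalValue")
    df$pValue <- .parse_num(col(8), lineno, "pValue")
    df$qValue <- .parse_num(col(9), lineno, "qValue")
    df$score <- df$qValue
    if (format == "narrowPeak") df$peak <- .parse_num(col(10), lineno, "peak")
  }
  if (!is.null(genome)) {
    unknown <- !(df$chrom %in% names(genome))
    if (any(unknown)) {
      if (on_unknown_chrom == "error")
        stop(sprintf("unknown chrom '%s' at line %d", df$chrom[unknown][1],
                     lineno[unknown][1]))
      df <- df[!unknown, , drop = FALSE]
    }
  }
  interval_set(df, genome = genome)
}

#' Write a BED-family interval file
#'
#' @param x interval_set.
#' @param path output path.
#' @param format one of "bed", "narrowPeak", "broadPeak", "bedgraph". For
#'   "bed", the column count follows the available fields (BED6 when strand
#'   is present).
#' @export
write_intervals <- function(x, path, format = c("bed", "narrowPeak",
                                                "broadPeak", "bedgraph")) {
  format <- match.arg(format)
  fmt_coord <- function(v) format(v, scientific = FALSE, trim = TRUE)
  if (nrow(x) == 0) { writeLines(character(0), path); return(invisible(path)) }
  if (format == "bed") {
    out <- paste(x$chrom, fmt_coord(x$start), fmt_coord(x$end),
                 .format_bed_fields(x$name), .format_bed_fields(x$score),
                 x$strand, sep = "\t")
  } else if (format == "bedgraph") {
    out <- paste(x$chrom, fmt_coord(x$start), fmt_coord(x$end),
                 .format_bed_fields(x$score), sep = "\t")
  } else {
    ds <- if ("display_score" %in% names(x)) x$display_score else rep(0, nrow(x))
    sv <- if ("signalValue" %in% names(x)) x$signalValue else rep(0, nrow(x))
    pv <- if ("pValue" %in% names(x)) x$pValue else rep(-1, nrow(x))
    qv <- if ("qValue" %in% names(x)) x$qValue else x$score
    out <- paste(x$chrom, fmt_coord(x$start), fmt_coord(x$end),
                 .format_bed_fields(x$name), .format_bed_fields(ds), x$strand,
                 .format_bed_fields(sv), .format_bed_fields(pv),
                 .format_bed_fields(qv), sep = "\t")
    if (format == "narrowPeak") {
      pk <- if ("peak" %in% names(x)) x$peak else rep(-1, nrow(x))
      out <- paste(out, .format_bed_fields(pk), sep = "\t")
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Merge intervals, joining across gaps
#'
#' Returns the union of covered base pairs with intervals separated by at most
#' \code{max_gap} bp joined. Half-open abutting intervals merge at gap 0.
#'
#' @param x interval_set.
#' @param max_gap maximum gap (bp >= 0) bridged when joining.
#' @return Sorted interval_set of disjoint intervals (pairwise separation
#'   > max_gap).
#' @export
merge_intervals <- function(x, max_gap = 0) {
  stopifnot(max_gap >= 0)
  if (nrow(x) == 0) return(interval_set(genome = genome_of(x)))
  gr <- as_granges(x)
  GenomicRanges::strand(gr) <- "*"
  red <- GenomicRanges::reduce(gr, min.gapwidth = max_gap + 1,
                               ignore.strand = TRUE)
  red <- GenomicRanges::sort(red, ignore.strand = TRUE)
  from_granges(red, genome = genome_of(x))
}

#' Subtract one interval set from another
#'
#' \code{whole_peak} keeps intervals of \code{a} with zero bp overlap with any
#' interval of \code{b} (the peak-level uniqueness used for condition-unique
#' enhancers); \code{basepair} returns the residual covered bases of \code{a}
#' after removing bases covered by \code{b} (disjoint merged fragments).
#'
#' @param a,b interval_set on the same genome.
#' @param mode "whole_peak" or "basepair".
#' @return interval_set.
#' @export
subtract_intervals <- function(a, b, mode = c("whole_peak", "basepair")) {
  mode <- match.arg(mode)
  if (nrow(a) == 0) return(interval_set(genome = genome_of(a)))
  if (nrow(b) == 0) {
    if (mode == "whole_peak") return(a)
    return(merge_intervals(a, 0))
  }
  gra <- as_granges(a); grb <- as_granges(b)
  GenomicRanges::strand(gra) <- "*"; GenomicRanges::strand(grb) <- "*"
  if (mode == "whole_peak") {
    hits <- GenomicRanges::countOverlaps(gra, grb, ignore.strand = TRUE)
    out <- a[hits == 0, , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "genome") <- genome_of(a)
    class(out) <- unique(c("interval_set", class(out)))
    return(out)
  }
  res <- GenomicRanges::setdiff(gra, grb, ignore.strand = TRUE)
  res <- GenomicRanges::sort(res, ignore.strand = TRUE)
  from_granges(res, genome = genome_of(a))
}

#' Extend intervals symmetrically from their centers
#'
#' Each interval becomes [center - flank, center + flank) with
#' center = floor((start + end) / 2), clipped to chromosome bounds when a
#' genome is attached. With flank 0 the result is the 1-bp interval
#' [center, center + 1) (zero-width intervals are not representable).
#'
#' @param x interval_set.
#' @param flank bp (>= 0) added on each side of the center.
#' @return interval_set with the same rows/metadata, new coordinates.
#' @export
extend_from_center <- function(x, flank) {
  stopifnot(flank >= 0)
  if (nrow(x) == 0) return(x)
  ctr <- interval_centers(x)
  s <- ctr - flank
  e <- if (flank == 0) ctr + 1 else ctr + flank
  s <- pmax(s, 0)
  g <- genome_of(x)
  if (!is.null(g)) e <- pmin(e, as.numeric(g[x$chrom]))
  out <- x
  out$start <- s
  out$end <- pmax(e, s + 1)
  attr(out, "genome") <- g
  out
}

#' Nearest TSS per interval
#'
#' For each interval, finds the TSS minimising |pos - center|. Distance is
#' signed as tss_pos - center in genomic coordinates; with
#' \code{strand_aware = TRUE} the sign is flipped for minus-strand genes.
#' Ties (equal |distance|) are broken by the lexicographically smaller gene
#' id. Intervals on chromosomes absent from the TSS table get NA gene and
#' distance.
#'
#' @param x interval_set.
#' @param tss TSS table (gene, chrom, pos, strand).
#' @param strand_aware flip distance sign for minus-strand genes.
#' @return data.frame with columns of \code{x} plus gene and distance.
#' @export
nearest_tss <- function(x, tss, strand_aware = FALSE) {
  out <- as.data.frame(x)
  out$gene <- NA_character_
  out$distance <- NA_real_
  if (nrow(x) == 0) return(out)
  ctr <- interval_centers(x)
  for (ch in unique(x$chrom)) {
    t <- tss[tss$chrom == ch, , drop = FALSE]
    idx <- which(x$chrom == ch)
    if (nrow(t) == 0) next
    t <- t[order(t$pos, t$gene), , drop = FALSE]
    pos <- t$pos
    for (i in idx) {
      c0 <- ctr[i]
      d <- abs(pos - c0)
      mind <- min(d)
      cand <- which(d == mind)
      gi <- cand[order(t$gene[cand])[1]]
      sgn_d <- pos[gi] - c0
      if (strand_aware && t$strand[gi] == "-") sgn_d <- -sgn_d
      out$gene[i] <- t$gene[gi]
      out$distance[i] <- sgn_d
    }
  }
  out
}
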