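# Enhancer-to-gene assignment, upregulation filtering into transcriptional
# regulatory networks (TRNs), and gene-set enrichment utilities (preranked
# running-sum statistic and hypergeometric over-representation).

#' Read a differential-expression results table
#'
#' Tab-separated with header columns gene, log2FoldChange, padj (extra
#' columns ignored). One row per gene.
#'
#' @param path file path.
#' @return data.frame (gene, log2FoldChange, padj).
#' @export
read_de_table <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("gene", "log2FoldChange", "padj")
  if (!all(need %in% names(tab)))
    stop("DE table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(tab$gene)) stop("DE table: duplicated gene ids")
  tab[, need]
}

#' Read a curated element-to-gene interaction table
#'
#' Tab-separated with header: chrom, start, end, gene, score. Each row maps
#' a regulatory element to a target gene (many-to-many permitted).
#'
#' @param path file path.
#' @return data.frame (chrom, start, end, gene, score).
#' @export
read_interactions <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "gene")
  if (!all(need %in% names(tab)))
    stop("interaction table must have columns: ", paste(need, collapse = ", "))
  if (!"score" %in% names(tab)) tab$score <- NA_real_
  bad <- which(is.na(tab$start) | is.na(tab$end) | tab$end <= tab$start)
  if (length(bad) > 0)
    stop(sprintf("malformed interaction row %d (data line %d)", bad[1],
                 bad[1] + 1))
  tab
}

#' Read a GMT gene-set collection
#'
#' Standard tab format: set name, description, then member genes.
#'
#' @param path file path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad) > 0)
    stop(sprintf("malformed GMT line %d: fewer than 3 fields", bad[1]))
  stats::setNames(lapply(parts, function(p) p[-(1:2)]),
                  vapply(parts, `[`, character(1), 1))
}

#' Write a GMT gene-set collection
#' @param sets named list of character vectors.
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  writeLines(vapply(names(sets), function(nm)
    paste(c(nm, nm, sets[[nm]]), collapse = "\t"), character(1)), path)
}

#' Assign enhancers to the single-nearest gene
#'
#' One link per enhancer, to the gene whose TSS is nearest the enhancer
#' center; equidistant ties go to the lexicographically smaller gene id.
#' Enhancers on chromosomes absent from the annotation are dropped with a
#' warning.
#'
#' @param enhancers interval_set.
#' @param tss TSS table.
#' @return data.frame of links: chrom, start, end, gene, mode ("nearest"),
#'   distance, score (NA).
#' @export
assign_nearest <- function(enhancers, tss) {
  nt <- nearest_tss(enhancers, tss)
  drop <- is.na(nt$gene)
  if (any(drop))
    warning(sprintf("assign_nearest: dropped %d enhancer(s) on unannotated chromosome(s)",
                    sum(drop)))
  nt <- nt[!drop, , drop = FALSE]
  data.frame(chrom = nt$chrom, start = nt$start, end = nt$end,
             gene = nt$gene, mode = "nearest", distance = nt$distance,
             score = NA_real_, stringsAsFactors = FALSE)
}

#' Assign enhancers to genes via a curated interaction table
#'
#' Emits a link (enhancer, gene) for every enhancer overlapping (>= 1 bp) a
#' regulatory element mapped to that gene; many-to-many allowed.
#'
#' @param enhancers interval_set.
#' @param interactions data.frame (chrom, start, end, gene, score) as from
#'   \code{read_interactions}.
#' @return data.frame of links: chrom, start, end, gene, mode ("curated"),
#'   distance (NA), score (interaction score).
#' @export
assign_curated <- function(enhancers, interactions) {
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      gene = character(), mode = character(),
                      distance = numeric(), score = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(enhancers) == 0 || nrow(interactions) == 0) return(empty)
  el_iv <- interval_set(interactions[, c("chrom", "start", "end")],
                        validate = FALSE)
  hits <- GenomicRanges::findOverlaps(as_granges(enhancers),
                                      as_granges(el_iv),
                                      ignore.strand = TRUE)
  if (length(hits) == 0) return(empty)
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  out <- data.frame(chrom = enhancers$chrom[q], start = enhancers$start[q],
                    end = enhancers$end[q], gene = interactions$gene[s],
                    mode = "curated", distance = NA_real_,
                    score = interactions$score[s], stringsAsFactors = FALSE)
  unique(out)
}

#' Build a transcriptional regulatory network
#'
#' Restricts enhancer-gene links to target genes with significantly
#' increased expression: FDR < \code{fdr_max} and log2 fold change strictly
#' greater than \code{lfc_min} (restored vs absent). Genes absent from the
#' DE table are treated as non-significant.
#'
#' @param links data.frame of enhancer-gene links (from
#'   \code{assign_nearest} / \code{assign_curated}).
#' @param de DE table (gene, log2FoldChange, padj).
#' @param fdr_max FDR threshold (exclusive; default 0.05).
#' @param lfc_min log2FC lower bound (exclusive; default 0 = any
#'   upregulation).
#' @param tf optional TF label carried on the network.
#' @return list of class \code{trn}: tf, links (filtered), genes (sorted
#'   unique upregulated targets).
#' @export
build_trn <- function(links, de, fdr_max = 0.05, lfc_min = 0, tf = NA_character_) {
  idx <- match(links$gene, de$gene)
  fdr <- de$padj[idx]
  lfc <- de$log2FoldChange[idx]
  keep <- !is.na(fdr) & !is.na(lfc) & fdr < fdr_max & lfc > lfc_min
  kept <- links[keep, , drop = FALSE]
  rownames(kept) <- NULL
  structure(list(tf = tf, links = kept,
                 genes = sort(unique(kept$gene)),
                 fdr_max = fdr_max, lfc_min = lfc_min),
            class = "trn")
}

#' @export
print.trn <- function(x, ...) {
  cat(sprintf("TRN%s: %d links -> %d upregulated target genes (FDR < %g, log2FC > %g)\n",
              if (is.na(x$tf)) "" else paste0(" [", x$tf, "]"),
              nrow(x$links), length(x$genes), x$fdr_max, x$lfc_min))
  invisible(x)
}

#' Venn-style overlap of TRN gene sets
#'
#' Exclusive region counts for 2 or more TRNs; region labels are
#' "+"-joined TF combinations. Counts over all regions sum to the size of
#' the union.
#'
#' @param trns named list of \code{trn} objects (or plain gene-id vectors).
#' @return Named integer vector of exclusive region counts.
#' @export
trn_overlap <- function(trns) {
  stopifnot(length(trns) >= 2, !is.null(names(trns)))
  sets <- lapply(trns, function(t) if (inherits(t, "trn")) t$genes else t)
  univ <- sort(unique(unlist(sets)))
  memb <- vapply(sets, function(s) univ %in% s, logical(length(univ)))
  if (length(univ) == 1) memb <- matrix(memb, nrow = 1,
                                        dimnames = list(NULL, names(sets)))
  key <- apply(memb, 1, function(r) paste(names(sets)[r], collapse = "+"))
  combos <- unlist(lapply(seq_along(sets), function(k)
    utils::combn(names(sets), k, paste, collapse = "+")))
  counts <- stats::setNames(integer(length(combos)), combos)
  tb <- table(key)
  counts[names(tb)] <- as.integer(tb)
  counts
}

# running-sum enrichment statistic for hit positions in a ranked list
.es_stat <- function(scores_desc, hit, weight = 1) {
  n <- length(scores_desc)
  nh <- sum(hit)
  if (nh == 0 || nh == n) return(if (nh == n) 1.0 else NA_real_)
  w <- abs(scores_desc)^weight
  wh <- w * hit
  tot <- sum(wh)
  inc <- if (tot > 0) wh / tot else hit / nh
  dec <- (1 - hit) / (n - nh)
  rs <- cumsum(inc - dec)
  unname(rs[which.max(abs(rs))])
}

#' Preranked gene-set enrichment (running-sum statistic)
#'
#' ES is the maximum deviation of the running sum over the descending-score
#' ranking: hits increment by |score|^weight normalised over hits, misses
#' decrement by 1/(N - n_hits). Significance is by gene-label permutation
#' (hit positions resampled uniformly), one-sided toward the observed ES
#' sign and conditional on permutation statistics of that sign — the
#' standard treatment for a signed max-deviation statistic, keeping null
#' p-values uniform — with the (1 + b) / (n_same_sign + 1) correction.
#' Reproducible bit-exact for a given seed.
#'
#' @param scores named numeric vector (e.g. signed log2FC); sorted internally
#'   in decreasing order.
#' @param gene_set character vector of member genes.
#' @param weight exponent on |score| for hit increments: 1 (default,
#'   weighted) or 0 (classic, equal steps).
#' @param n_perm number of permutations (>= 100 recommended).
#' @param seed RNG seed (required for reproducibility).
#' @return list(es, p, n_hits, n_perm).
#' @export
preranked_enrichment <- function(scores, gene_set, weight = 1, n_perm = 1000,
                                 seed = 1) {
  stopifnot(!is.null(names(scores)))
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  hit <- names(s) %in% gene_set
  nh <- sum(hit)
  if (nh == 0) stop("preranked_enrichment: gene set does not intersect ranking")
  es <- .es_stat(s, hit, weight = weight)
  n <- length(s)
  if (nh == n)
    return(list(es = 1.0, p = 1.0, n_hits = nh, n_perm = 0L))
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(i) {
    h <- logical(n)
    h[sample.int(n, nh)] <- TRUE
    .es_stat(s, h, weight = weight)
  }, numeric(1))
  same_sign <- if (es >= 0) perm[perm >= 0] else perm[perm < 0]
  b <- if (es >= 0) sum(same_sign >= es) else sum(same_sign <= es)
  list(es = es, p = (1 + b) / (length(same_sign) + 1), n_hits = nh,
       n_perm = n_perm)
}

#' Hypergeometric over-representation analysis
#'
#' For each term set (intersected with the universe), the upper-tail
#' hypergeometric probability P(X >= k) of observing k query genes in the
#' term, with BH adjustment across terms.
#'
#' @param query character vector of genes (must lie within the universe).
#' @param annotation named list of term gene sets (GMT collection).
#' @param universe character vector of background genes.
#' @return data.frame: term, k (overlap), K (term size in universe),
#'   n (query size), N (universe size), p, bh_adj.
#' @export
ora_hypergeometric <- function(query, annotation, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("ora_hypergeometric: empty universe")
  query <- unique(query)
  if (!all(query %in% universe))
    stop("ora_hypergeometric: query genes outside universe")
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(annotation), function(term) {
    tset <- intersect(unique(annotation[[term]]), universe)
    K <- length(tset)
    k <- length(intersect(query, tset))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = term, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$bh_adj <- stats::p.adjust(out$p, method = "BH")
  out[order(out$p), , drop = FALSE]
}
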