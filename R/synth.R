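# Synthetic two-condition epigenome with planted ground truth.
#
# Emulates the study design every stage consumes: a toy genome with a regular
# gene grid; restored-condition-specific enhancer peaks (some clustered into
# super-enhancers), shared enhancers active in both conditions, poised
# (H3K4me1-only) regions; TF peaks enhancer-localised in the restored
# condition and promoter-localised in the absent condition; promoter-anchored
# super-enhancers in the absent condition; a DE table with planted
# upregulation of enhancer targets; a curated element-to-gene table; gene
# sets; and a PPI edge list with a planted hub wired to the planted targets.
# All geometry keeps planted elements on the downstream side of their gene's
# TSS and inside half the gene spacing, so nearest-TSS assignment and
# 12.5 kb stitching recover the planted structure exactly.

#' Synthetic-data configuration
#'
#' Defaults define the study conditions: 2 chromosomes of 1 Mb, 200 genes on
#' a regular grid, 40 restored-specific enhancers (6 of them 3-peak
#' super-enhancer clusters at 25x signal, the rest at 5x over a background of
#' 1), 30 shared enhancers, 10 poised regions, 4 promoter-anchored
#' super-enhancers in the absent condition, three TFs binding planted
#' enhancers with probability 0.8 in the restored condition and promoters
#' with probability 0.8 in the absent condition, all planted targets
#' upregulated at log2FC ~ N(2, 0.25) with FDR < 0.05, and an
#' Erdos-Renyi PPI background (200 nodes, density 0.03) with the hub wired
#' to the planted targets.
#'
#' @param seed integer RNG seed (mandatory; all randomness flows from it).
#' @param n_chroms,chrom_length toy genome shape.
#' @param n_genes genes on a regular TSS grid.
#' @param n_condition_specific_enhancers restored-only enhancer slots
#'   (includes the SE clusters).
#' @param n_super_enhancers how many of those slots are 3-peak SE clusters.
#' @param n_shared_enhancers enhancers active in both conditions.
#' @param n_poised H3K4me1-only regions.
#' @param n_promoter_ses absent-condition promoter-anchored SE clusters.
#' @param tfs TF names.
#' @param tf_enhancer_binding_prob per-TF probability of binding each planted
#'   enhancer in the restored condition.
#' @param tf_promoter_binding_prob probability an absent-condition TF peak is
#'   promoter-localised (vs background).
#' @param tf_promoter_binding_prob_restored probability a promoter also
#'   carries a restored-condition TF peak (exercises the promoter state).
#' @param n_tf_absent_peaks absent-condition peaks per TF.
#' @param n_tf_background_peaks restored-condition unclassified peaks per TF.
#' @param enhancer_signal_multiplier,superenhancer_signal_multiplier ChIP
#'   track fold over the background level of 1.0.
#' @param frac_targets_upregulated fraction of planted enhancer target genes
#'   actually upregulated (1 = noise-free).
#' @param de_noise_sd log2FC noise sd.
#' @param ppi_n_nodes,ppi_density Erdos-Renyi PPI background.
#' @param planted_hub_degree neighbours wired to the hub (NULL = all planted
#'   upregulated targets).
#' @return list of class \code{synth_config}.
#' @export
synth_config <- function(seed,
                         n_chroms = 2, chrom_length = 1e6, n_genes = 200,
                         n_condition_specific_enhancers = 40,
                         n_super_enhancers = 6,
                         n_shared_enhancers = 30,
                         n_poised = 10,
                         n_promoter_ses = 4,
                         tfs = c("FRA2", "TEAD1", "ZIC2"),
                         tf_enhancer_binding_prob = 0.8,
                         tf_promoter_binding_prob = 0.8,
                         tf_promoter_binding_prob_restored = 0.3,
                         n_tf_absent_peaks = 50,
                         n_tf_background_peaks = 5,
                         enhancer_signal_multiplier = 5,
                         superenhancer_signal_multiplier = 25,
                         frac_targets_upregulated = 1.0,
                         de_noise_sd = 0.25,
                         ppi_n_nodes = 200, ppi_density = 0.03,
                         planted_hub_degree = NULL) {
  if (missing(seed)) stop("synth_config: seed is mandatory")
  cfg <- as.list(environment())
  probs <- c(tf_enhancer_binding_prob, tf_promoter_binding_prob,
             tf_promoter_binding_prob_restored, frac_targets_upregulated)
  stopifnot(all(probs >= 0 & probs <= 1), chrom_length > 0, n_genes > 0,
            n_super_enhancers <= n_condition_specific_enhancers)
  class(cfg) <- "synth_config"
  cfg
}

# piecewise-constant bedGraph: peaks (interval_set-like df) with values over
# a flat background; peaks must be disjoint
.build_track <- function(peaks, values, genome, background = 1.0) {
  rows <- list()
  for (ch in names(genome)) {
    len <- genome[[ch]]
    sel <- which(peaks$chrom == ch)
    sel <- sel[order(peaks$start[sel])]
    pos <- 0
    for (i in sel) {
      if (peaks$start[i] > pos)
        rows[[length(rows) + 1]] <- data.frame(chrom = ch, start = pos,
                                               end = peaks$start[i],
                                               score = background)
      rows[[length(rows) + 1]] <- data.frame(chrom = ch, start = peaks$start[i],
                                             end = peaks$end[i],
                                             score = values[i])
      pos <- peaks$end[i]
    }
    if (pos < len)
      rows[[length(rows) + 1]] <- data.frame(chrom = ch, start = pos,
                                             end = len, score = background)
  }
  interval_set(do.call(rbind, rows), genome = genome, validate = FALSE)
}

.np_fields <- function(df, prefix) {
  df$name <- sprintf("%s_%d", prefix, seq_len(nrow(df)))
  df$display_score <- rep(0, nrow(df))
  df$strand <- rep(".", nrow(df))
  df$signalValue <- round(stats::runif(nrow(df), 2, 20), 3)
  df$pValue <- round(stats::runif(nrow(df), 5, 30), 3)
  df$qValue <- round(stats::runif(nrow(df), 3, 20), 3)
  df$score <- df$qValue
  df$peak <- floor((df$end - df$start) / 2)
  df
}

#' Generate a complete synthetic input set with planted ground truth
#'
#' Writes every file the pipeline reads (genome, TSS table, histone-mark
#' broadPeak and TF/SMARCA4 narrowPeak files for both conditions, ChIP and
#' input bedGraphs, DE table, curated interaction table, GMT gene sets, PPI
#' edge list) plus a \code{truth.json} manifest, and returns the ground
#' truth. Identical (config, seed) produce byte-identical outputs.
#'
#' @param cfg \code{synth_config}.
#' @param outdir writable output directory (created if needed).
#' @return Invisible list of class \code{ground_truth} (also serialised to
#'   \code{truth.json}): planted enhancer coordinates per condition, per-peak
#'   state labels, per-TF targets, SE regions and genes, upregulated target
#'   set, hub and CRC neighbour set, and emitted file paths.
#' @export
generate_synthetic_data <- function(cfg, outdir) {
  stopifnot(inherits(cfg, "synth_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  set.seed(cfg$seed)
  genome <- stats::setNames(rep(cfg$chrom_length, cfg$n_chroms),
                            paste0("chr", seq_len(cfg$n_chroms)))

  # gene grid: equal split across chroms, TSS on a regular lattice
  gpc <- ceiling(cfg$n_genes / cfg$n_chroms)
  spacing <- floor(cfg$chrom_length / (gpc + 1))
  gene_rows <- list()
  k <- 0
  for (ci in seq_len(cfg$n_chroms)) {
    for (j in seq_len(gpc)) {
      if (k >= cfg$n_genes) break
      k <- k + 1
      gene_rows[[k]] <- data.frame(
        gene = sprintf("GENE%03d", k), chrom = names(genome)[ci],
        pos = j * spacing, strand = if (j %% 2 == 0) "-" else "+",
        slot = j, stringsAsFactors = FALSE)
    }
  }
  genes <- do.call(rbind, gene_rows)
  tss <- genes[, c("gene", "chrom", "pos", "strand")]

  # enhancer-bearing slots: odd grid positions only, so neighbouring planted
  # elements sit > 12.5 kb apart and never stitch across genes; all elements
  # go downstream (+ coordinates) of their TSS within half the gene spacing
  slot_genes <- genes[genes$slot %% 2 == 1, , drop = FALSE]
  need <- cfg$n_condition_specific_enhancers + cfg$n_shared_enhancers +
    cfg$n_poised
  if (need > nrow(slot_genes))
    stop(sprintf("infeasible config: %d planted elements > %d available slots",
                 need, nrow(slot_genes)))
  half <- floor(spacing / 2)
  if (half < 4600)  # planted element centers reach 4.35 kb downstream
    stop("infeasible config: gene spacing too tight to host distal enhancers")
  picked <- slot_genes[sample.int(nrow(slot_genes), need), , drop = FALSE]
  cs_genes <- picked[seq_len(cfg$n_condition_specific_enhancers), ,
                     drop = FALSE]
  sh_genes <- picked[cfg$n_condition_specific_enhancers +
                       seq_len(cfg$n_shared_enhancers), , drop = FALSE]
  po_genes <- picked[cfg$n_condition_specific_enhancers +
                       cfg$n_shared_enhancers + seq_len(cfg$n_poised), ,
                     drop = FALSE]
  se_idx <- sample.int(nrow(cs_genes), cfg$n_super_enhancers)

  empty_pk <- data.frame(chrom = character(), start = numeric(),
                         end = numeric(), gene = character(),
                         stringsAsFactors = FALSE)
  mk_peak <- function(g, off, width) {
    data.frame(chrom = g$chrom, start = g$pos + off, end = g$pos + off + width,
               gene = g$gene, stringsAsFactors = FALSE)
  }
  # single-peak enhancers: one 600-1000 bp peak 2.6-3.2 kb downstream
  single_enh <- function(gdf) {
    if (nrow(gdf) == 0) return(empty_pk)
    do.call(rbind, lapply(seq_len(nrow(gdf)), function(i) {
      mk_peak(gdf[i, ], 2600 + sample.int(600, 1),
              600 + sample.int(400, 1))
    }))
  }
  cs_nonse <- if (length(se_idx) > 0) cs_genes[-se_idx, , drop = FALSE]
    else cs_genes
  cs_single <- single_enh(cs_nonse)
  sh_peaks <- single_enh(sh_genes)
  po_peaks <- single_enh(po_genes)
  # SE clusters: three 500-700 bp peaks spanning ~2.4-4.6 kb downstream
  se_cluster <- if (length(se_idx) == 0) empty_pk else
    do.call(rbind, lapply(se_idx, function(i) {
    g <- cs_genes[i, ]
    do.call(rbind, lapply(c(2400, 3200, 4000), function(off)
      mk_peak(g, off, 500 + sample.int(200, 1))))
  }))
  se_genes <- cs_genes$gene[se_idx]
  cs_peaks <- rbind(cs_single, se_cluster)
  cs_peaks <- cs_peaks[order(cs_peaks$chrom, cs_peaks$start), , drop = FALSE]

  # absent-condition promoter-anchored SE clusters on even-slot genes
  prom_se_genes <- genes[genes$slot %% 2 == 0, , drop = FALSE]
  prom_se_genes <- prom_se_genes[sample.int(nrow(prom_se_genes),
                                            cfg$n_promoter_ses), ,
                                 drop = FALSE]
  prom_se_peaks <- do.call(rbind, lapply(seq_len(nrow(prom_se_genes)),
                                         function(i) {
    g <- prom_se_genes[i, ]
    do.call(rbind, lapply(c(-1100, -300, 500), function(off)
      mk_peak(g, off, 600)))
  }))

  k27_restored <- rbind(cs_peaks, sh_peaks)
  k27_restored <- k27_restored[order(k27_restored$chrom, k27_restored$start), ]
  k27_absent <- rbind(sh_peaks, prom_se_peaks)
  k27_absent <- k27_absent[order(k27_absent$chrom, k27_absent$start), ]

  # H3K4me1 primes every distal element (both conditions); H3K4me3 marks
  # every promoter (TSS +/- 1 kb)
  me1_src <- rbind(cs_peaks, sh_peaks, po_peaks)
  me1 <- data.frame(chrom = me1_src$chrom, start = me1_src$start - 300,
                    end = me1_src$end + 300, stringsAsFactors = FALSE)
  me1 <- me1[order(me1$chrom, me1$start), ]
  me3 <- data.frame(chrom = genes$chrom, start = pmax(genes$pos - 1000, 0),
                    end = genes$pos + 1000, gene = genes$gene,
                    stringsAsFactors = FALSE)
  # polycomb-repressed regions: decorative, consumed by nothing downstream
  k27me3_genes <- genes[genes$slot %% 2 == 0, , drop = FALSE]
  k27me3_genes <- k27me3_genes[sample.int(nrow(k27me3_genes), 10), ,
                               drop = FALSE]
  k27me3 <- data.frame(chrom = k27me3_genes$chrom,
                       start = k27me3_genes$pos + 5500,
                       end = k27me3_genes$pos + 7500, stringsAsFactors = FALSE)

  # SMARCA4: absent = promoters (all promoter-SE genes + 60% of others);
  # restored = 80% of planted distal enhancers
  other_prom <- setdiff(genes$gene, prom_se_genes$gene)
  sm_abs_genes <- c(prom_se_genes$gene,
                    other_prom[stats::runif(length(other_prom)) < 0.6])
  gidx <- match(sm_abs_genes, genes$gene)
  smarca4_absent <- data.frame(chrom = genes$chrom[gidx],
                               start = pmax(genes$pos[gidx] - 400, 0),
                               end = genes$pos[gidx] + 400,
                               stringsAsFactors = FALSE)
  keep_r <- stats::runif(nrow(cs_peaks)) < 0.8
  smarca4_restored <- data.frame(chrom = cs_peaks$chrom[keep_r],
                                 start = cs_peaks$start[keep_r],
                                 end = cs_peaks$end[keep_r],
                                 stringsAsFactors = FALSE)

  # TF peaks. Restored: enhancer-localised (cs -> dependent state, shared ->
  # independent, poised slots, some promoters, a few unmarked background
  # sites). Absent: promoter-localised at the configured rate.
  empty_slots <- slot_genes[!(slot_genes$gene %in% picked$gene), , drop = FALSE]
  tf_restored <- list(); tf_absent <- list(); state_truth <- list()
  cobinding <- list()
  lab <- function(df, label) {
    df$label <- rep(label, nrow(df))
    df
  }
  enh_units <- rbind(
    lab(cs_peaks, "active_enhancer_smarcb1_dependent"),
    lab(sh_peaks, "active_enhancer_smarcb1_independent"),
    lab(po_peaks, "poised_enhancer"))
  for (tf in cfg$tfs) {
    bind <- stats::runif(nrow(enh_units)) <
      ifelse(enh_units$label == "poised_enhancer", 0.5,
             cfg$tf_enhancer_binding_prob)
    eu <- enh_units[bind, , drop = FALSE]
    ctr <- floor((eu$start + eu$end) / 2) +
      sample(-100:100, nrow(eu), replace = TRUE)
    peaks <- data.frame(chrom = eu$chrom, start = ctr - 150, end = ctr + 150,
                        truth_state = eu$label, target = eu$gene,
                        stringsAsFactors = FALSE)
    pbind <- stats::runif(nrow(genes)) < cfg$tf_promoter_binding_prob_restored
    pg <- genes[pbind, , drop = FALSE]
    ppk <- data.frame(chrom = pg$chrom, start = pg$pos - 150,
                      end = pg$pos + 150, truth_state = "active_promoter",
                      target = pg$gene, stringsAsFactors = FALSE)
    bg <- empty_slots[sample.int(nrow(empty_slots),
                                 min(cfg$n_tf_background_peaks,
                                     nrow(empty_slots))), , drop = FALSE]
    bpk <- data.frame(chrom = bg$chrom, start = bg$pos + 7000,
                      end = bg$pos + 7300, truth_state = "unclassified",
                      target = NA_character_, stringsAsFactors = FALSE)
    all_pk <- rbind(peaks, ppk, bpk)
    all_pk <- all_pk[order(all_pk$chrom, all_pk$start), , drop = FALSE]
    all_pk$name <- sprintf("%s_r_%d", tf, seq_len(nrow(all_pk)))
    tf_restored[[tf]] <- all_pk
    state_truth[[tf]] <- all_pk[, c("name", "chrom", "start", "end",
                                    "truth_state", "target")]
    # absent condition: each peak promoter-located with the configured
    # probability, else at an unmarked background site
    at_prom <- stats::runif(cfg$n_tf_absent_peaks) <
      cfg$tf_promoter_binding_prob
    other <- setdiff(genes$gene, prom_se_genes$gene)
    prom_pool <- c(prom_se_genes$gene,
                   sample(other, min(36, length(other))))
    rows <- lapply(seq_len(cfg$n_tf_absent_peaks), function(i) {
      if (at_prom[i]) {
        g <- genes[match(sample(prom_pool, 1), genes$gene), ]
        data.frame(chrom = g$chrom, start = g$pos - 150, end = g$pos + 150,
                   stringsAsFactors = FALSE)
      } else {
        g <- empty_slots[sample.int(nrow(empty_slots), 1), ]
        data.frame(chrom = g$chrom, start = g$pos + 6000 + sample.int(2000, 1),
                   end = NA, stringsAsFactors = FALSE)
      }
    })
    ab <- do.call(rbind, rows)
    ab$end[is.na(ab$end)] <- ab$start[is.na(ab$end)] + 300
    ab <- ab[order(ab$chrom, ab$start), , drop = FALSE]
    tf_absent[[tf]] <- ab
  }
  for (i in seq_along(cfg$tfs))
    for (j in seq_along(cfg$tfs))
      if (i < j) cobinding[[length(cobinding) + 1]] <-
    c(cfg$tfs[i], cfg$tfs[j])

  # signal tracks: piecewise-constant, background 1.0, input flat 1.0
  is_se_peak <- logical(nrow(k27_restored))
  se_span <- if (length(se_idx) == 0) empty_pk else
    do.call(rbind, lapply(se_idx, function(i) {
    g <- cs_genes[i, ]
    data.frame(chrom = g$chrom, start = g$pos + 2400, end = g$pos + 4700,
               gene = g$gene, stringsAsFactors = FALSE)
  }))
  for (i in seq_len(nrow(k27_restored)))
    is_se_peak[i] <- any(se_span$chrom == k27_restored$chrom[i] &
                           k27_restored$start[i] >= se_span$start &
                           k27_restored$end[i] <= se_span$end)
  vals_r <- ifelse(is_se_peak, cfg$superenhancer_signal_multiplier,
                   cfg$enhancer_signal_multiplier)
  chip_restored <- .build_track(k27_restored, vals_r, genome)
  is_pse <- seq_len(nrow(k27_absent)) > nrow(sh_peaks)  # promoter-SE rows
  ka <- k27_absent[order(k27_absent$chrom, k27_absent$start), ]
  is_pse <- logical(nrow(ka))
  for (i in seq_len(nrow(ka)))
    is_pse[i] <- any(prom_se_peaks$chrom == ka$chrom[i] &
                       prom_se_peaks$start == ka$start[i] &
                       prom_se_peaks$end == ka$end[i])
  vals_a <- ifelse(is_pse, cfg$superenhancer_signal_multiplier,
                   cfg$enhancer_signal_multiplier)
  chip_absent <- .build_track(ka, vals_a, genome)
  input_track <- .build_track(
    data.frame(chrom = character(), start = numeric(), end = numeric()),
    numeric(0), genome)

  # DE table: planted targets (genes of restored-specific enhancers) are
  # upregulated with FDR < 0.05; everything else is null
  target_pool <- cs_genes$gene
  n_up <- round(cfg$frac_targets_upregulated * length(target_pool))
  up_genes <- sort(sample(target_pool, n_up))
  lfc <- stats::rnorm(nrow(genes), 0, cfg$de_noise_sd)
  fdr <- stats::runif(nrow(genes), 0.05, 0.999)
  up <- genes$gene %in% up_genes
  lfc[up] <- stats::rnorm(sum(up), 2, cfg$de_noise_sd)
  fdr[up] <- stats::runif(sum(up), 0.001, 0.049)
  de <- data.frame(gene = genes$gene, log2FoldChange = round(lfc, 4),
                   padj = signif(fdr, 4), stringsAsFactors = FALSE)

  # curated element -> gene table: one element per planted distal enhancer
  el <- rbind(cs_peaks[, c("chrom", "start", "end", "gene")],
              sh_peaks[, c("chrom", "start", "end", "gene")])
  interactions <- data.frame(chrom = el$chrom, start = el$start - 500,
                             end = el$end + 500, gene = el$gene,
                             score = round(stats::runif(nrow(el), 5, 50), 2),
                             stringsAsFactors = FALSE)
  interactions <- interactions[order(interactions$chrom, interactions$start), ]

  # gene sets: the planted target set plus random decoys
  gmt <- list(PLANTED_TARGETS = up_genes,
              SHARED_ENHANCER_GENES = sort(sh_genes$gene))
  for (i in 1:3)
    gmt[[sprintf("RANDOM_SET_%d", i)]] <- sort(sample(genes$gene, 15))

  # PPI: Erdos-Renyi background over the gene universe + planted hub wired
  # to the planted upregulated targets
  hub <- se_genes[se_genes %in% up_genes][1]
  if (is.na(hub)) hub <- up_genes[1]
  nodes <- genes$gene[seq_len(min(cfg$ppi_n_nodes, nrow(genes)))]
  pr <- t(utils::combn(nodes, 2))
  er <- stats::runif(nrow(pr)) < cfg$ppi_density
  edges <- data.frame(gene_a = pr[er, 1], gene_b = pr[er, 2],
                      stringsAsFactors = FALSE)
  wire <- setdiff(up_genes, hub)
  if (!is.null(cfg$planted_hub_degree))
    wire <- sort(sample(wire, min(cfg$planted_hub_degree, length(wire))))
  hub_edges <- data.frame(gene_a = pmin(hub, wire), gene_b = pmax(hub, wire),
                          stringsAsFactors = FALSE)
  edges <- rbind(edges, hub_edges)
  edges <- edges[!duplicated(paste(edges$gene_a, edges$gene_b)), ]
  edges <- edges[order(edges$gene_a, edges$gene_b), ]
  edges$score <- round(stats::runif(nrow(edges), 0.4, 1), 3)

  # per-TF planted TRN targets: upregulated genes of cs enhancers the TF binds
  tf_targets <- lapply(cfg$tfs, function(tf) {
    st <- state_truth[[tf]]
    sort(intersect(unique(st$target[st$truth_state ==
                                      "active_enhancer_smarcb1_dependent"]),
                   up_genes))
  })
  names(tf_targets) <- cfg$tfs
  union_targets <- sort(unique(unlist(tf_targets)))
  # CRC truth: hub neighbours within the union-target induced subgraph
  in_net <- union_targets
  nb <- edges[(edges$gene_a == hub & edges$gene_b %in% in_net) |
                (edges$gene_b == hub & edges$gene_a %in% in_net), ]
  crc_members <- sort(unique(c(hub, nb$gene_a, nb$gene_b)))

  # ---- write files ----
  p <- function(f) file.path(outdir, f)
  write_genome(genome, p("genome.txt"))
  write_tss(tss, p("tss.tsv"))
  wr_broad <- function(df, f) {
    iv <- interval_set(df[, c("chrom", "start", "end")], genome = genome,
                       validate = FALSE)
    write_intervals(interval_set(.np_fields(iv, sub("\\..*$", "", f)),
                                 genome = genome, validate = FALSE),
                    p(f), format = "broadPeak")
  }
  wr_narrow <- function(df, f, prefix) {
    iv <- interval_set(df[, c("chrom", "start", "end")], genome = genome,
                       validate = FALSE)
    iv <- .np_fields(iv, prefix)
    if ("name" %in% names(df)) iv$name <- df$name
    write_intervals(interval_set(iv, genome = genome, validate = FALSE),
                    p(f), format = "narrowPeak")
  }
  wr_broad(k27_restored, "h3k27ac_restored.broadPeak")
  wr_broad(ka, "h3k27ac_absent.broadPeak")
  wr_broad(me1, "h3k4me1.broadPeak")
  wr_broad(me3[, c("chrom", "start", "end")], "h3k4me3.broadPeak")
  wr_broad(k27me3, "h3k27me3.broadPeak")
  wr_narrow(smarca4_absent, "smarca4_absent.narrowPeak", "SMARCA4_a")
  wr_narrow(smarca4_restored, "smarca4_restored.narrowPeak", "SMARCA4_r")
  for (tf in cfg$tfs) {
    wr_narrow(tf_restored[[tf]], sprintf("tf_%s_restored.narrowPeak", tf), tf)
    wr_narrow(tf_absent[[tf]], sprintf("tf_%s_absent.narrowPeak", tf), tf)
  }
  write_intervals(chip_restored, p("chip_restored.bedGraph"), "bedgraph")
  write_intervals(chip_absent, p("chip_absent.bedGraph"), "bedgraph")
  write_intervals(input_track, p("input.bedGraph"), "bedgraph")
  utils::write.table(de, p("de_table.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(interactions, p("interactions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_gmt(gmt, p("gene_sets.gmt"))
  utils::write.table(edges, p("ppi_edges.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  truth <- structure(list(
    genome = as.list(genome),
    gained_enhancer_peaks = cs_peaks,
    shared_enhancer_peaks = sh_peaks,
    poised_regions = po_peaks,
    se_regions = se_span,
    se_genes = sort(se_genes),
    promoter_se_genes = sort(prom_se_genes$gene),
    state_labels = state_truth,
    cobinding_pairs = cobinding,
    upregulated_targets = up_genes,
    tf_targets = tf_targets,
    union_targets = union_targets,
    hub = hub,
    crc_members = crc_members,
    tfs = as.list(cfg$tfs),
    seed = cfg$seed,
    files = list(outdir = outdir)
  ), class = "ground_truth")
  json_truth <- unclass(truth)
  json_truth$files <- NULL  # no absolute paths: outputs stay byte-identical
  jsonlite::write_json(json_truth, p("truth.json"), auto_unbox = TRUE,
                       dataframe = "columns", digits = NA, pretty = TRUE)
  invisible(truth)
}

.prf <- function(pred, truth) {
  pred <- unique(pred); truth <- unique(truth)
  tp <- length(intersect(pred, truth))
  list(precision = if (length(pred) == 0) NA_real_ else tp / length(pred),
       recall = if (length(truth) == 0) NA_real_ else tp / length(truth),
       n_pred = length(pred), n_truth = length(truth))
}

.region_key <- function(df) sprintf("%s:%d-%d", df$chrom, df$start, df$end)

#' Compare pipeline outputs with the planted ground truth
#'
#' Per-stage precision/recall: gained constituent enhancers (exact
#' coordinates), super-enhancer regions (reciprocal >= 1 bp overlap with
#' planted SE spans), chromatin-state labels (per-peak accuracy), TRN gene
#' sets, and CRC membership. Supply whichever stages exist.
#'
#' @param results list with any of: gained (interval_set), se_regions
#'   (data.frame of called SE regions), states (named list of
#'   classify_tf_peaks outputs, by TF), trn_genes (character), crc_members
#'   (character).
#' @param truth \code{ground_truth} from \code{generate_synthetic_data}.
#' @return Nested list of precision/recall (and accuracy for states) per
#'   supplied stage.
#' @export
truth_compare <- function(results, truth) {
  out <- list()
  if (!is.null(results$gained))
    out$gained <- .prf(.region_key(results$gained),
                       .region_key(truth$gained_enhancer_peaks))
  if (!is.null(results$se_regions)) {
    pred <- interval_set(results$se_regions[, c("chrom", "start", "end")],
                         validate = FALSE)
    tr <- interval_set(truth$se_regions[, c("chrom", "start", "end")],
                       validate = FALSE)
    hit_pred <- .overlaps_any(pred, tr)
    hit_tr <- .overlaps_any(tr, pred)
    out$se <- list(precision = if (nrow(pred) == 0) NA_real_ else mean(hit_pred),
                   recall = if (nrow(tr) == 0) NA_real_ else mean(hit_tr),
                   n_pred = nrow(pred), n_truth = nrow(tr))
  }
  if (!is.null(results$states)) {
    accs <- lapply(names(results$states), function(tf) {
      got <- results$states[[tf]]
      want <- truth$state_labels[[tf]]
      if (is.null(want)) stop("truth_compare: no planted labels for ", tf)
      m <- match(got$name, want$name)
      if (anyNA(m)) stop("truth_compare: unmatched peak names for ", tf)
      mean(as.character(got$state) == want$truth_state[m])
    })
    names(accs) <- names(results$states)
    out$states <- list(per_tf_accuracy = accs,
                       accuracy = mean(unlist(accs)))
  }
  if (!is.null(results$trn_genes))
    out$trn <- .prf(results$trn_genes, truth$upregulated_targets)
  if (!is.null(results$crc_members))
    out$crc <- .prf(results$crc_members, truth$crc_members)
  if (length(out) == 0) stop("truth_compare: no recognised stage outputs supplied")
  out
}
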