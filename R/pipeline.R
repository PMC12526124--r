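# Config-driven orchestration: enhancers -> states -> cobind -> trn ->
# network -> report, with per-stage provenance (parameters, input/output
# checksums, seed, package version) and checksum-based stage caching.

#' Build a validated run configuration
#'
#' Accepts a YAML file path or a list. Required input paths: genome, tss,
#' h3k27ac_restored, h3k27ac_absent, h3k4me1, h3k4me3, chip_restored,
#' chip_absent, input_track, tf_restored (named per TF), de_table,
#' interactions, gmt, ppi. Optional: smarca4_absent, tf_absent. Parameters
#' default to the study values: 12.5 kb stitching, 150 bp extension, 1 kb
#' bins, FDR < 0.05, +/- 2 kb promoter window.
#'
#' @param config list or YAML path.
#' @param ... overrides applied on top of the config (flags beat file).
#' @return list of class \code{run_config}.
#' @export
run_config <- function(config, ...) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  over <- list(...)
  config[names(over)] <- over
  defaults <- list(stitch_gap = 12500, tss_exclusion_window = 0,
                   extend = 150, bin_width = 1000,
                   fdr_max = 0.05, lfc_min = 0, promoter_window = 2000,
                   n_perm = 1000, seed = 1, hub = NULL,
                   trn_mode = "both", network_input = "union")
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  need <- c("genome", "tss", "h3k27ac_restored", "h3k27ac_absent", "h3k4me1",
            "h3k4me3", "chip_restored", "input_track", "tf_restored",
            "de_table", "interactions", "gmt", "ppi", "outdir")
  missing_keys <- setdiff(need, names(config))
  if (length(missing_keys) > 0)
    stop("run_config: missing entries: ", paste(missing_keys, collapse = ", "))
  paths <- c(config[c("genome", "tss", "h3k27ac_restored", "h3k27ac_absent",
                      "h3k4me1", "h3k4me3", "chip_restored", "input_track",
                      "de_table", "interactions", "gmt", "ppi")],
             config$tf_restored,
             config[intersect(c("chip_absent", "smarca4_absent"),
                              names(config))])
  absent <- !vapply(paths, file.exists, logical(1))
  if (any(absent))
    stop("run_config: input file(s) not found: ",
         paste(unlist(paths[absent]), collapse = ", "))
  class(config) <- "run_config"
  config
}

#' Convenience run configuration for a synthetic dataset directory
#'
#' Points every input at the files \code{generate_synthetic_data} emits.
#'
#' @param synth_dir directory written by \code{generate_synthetic_data}.
#' @param outdir pipeline output directory.
#' @param tfs TF names matching the generator's.
#' @param ... parameter overrides for \code{run_config}.
#' @return \code{run_config}.
#' @export
run_config_synth <- function(synth_dir, outdir,
                             tfs = c("FRA2", "TEAD1", "ZIC2"), ...) {
  p <- function(f) file.path(synth_dir, f)
  run_config(list(
    genome = p("genome.txt"), tss = p("tss.tsv"),
    h3k27ac_restored = p("h3k27ac_restored.broadPeak"),
    h3k27ac_absent = p("h3k27ac_absent.broadPeak"),
    h3k4me1 = p("h3k4me1.broadPeak"), h3k4me3 = p("h3k4me3.broadPeak"),
    chip_restored = p("chip_restored.bedGraph"),
    chip_absent = p("chip_absent.bedGraph"),
    input_track = p("input.bedGraph"),
    smarca4_absent = p("smarca4_absent.narrowPeak"),
    tf_restored = stats::setNames(
      as.list(p(sprintf("tf_%s_restored.narrowPeak", tfs))), tfs),
    tf_absent = stats::setNames(
      as.list(p(sprintf("tf_%s_absent.narrowPeak", tfs))), tfs),
    de_table = p("de_table.tsv"), interactions = p("interactions.tsv"),
    gmt = p("gene_sets.gmt"), ppi = p("ppi_edges.tsv"),
    outdir = outdir), ...)
}

.md5 <- function(paths) {
  v <- tools::md5sum(unlist(paths))
  stats::setNames(as.character(v), unlist(paths))
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# a stage is current when its provenance exists, recorded input checksums
# still match (a changed raw input makes the stage stale -> rerun), and its
# own outputs are untouched (a changed output is corruption -> error naming
# the file)
.stage_current <- function(prov_path) {
  if (!file.exists(prov_path)) return(FALSE)
  prov <- jsonlite::read_json(prov_path)
  for (f in names(prov$inputs)) {
    fp <- if (file.exists(f)) f else file.path(dirname(prov_path), f)
    if (!file.exists(fp)) return(FALSE)
    if (!identical(as.character(tools::md5sum(fp)), prov$inputs[[f]]))
      return(FALSE)
  }
  for (f in names(prov$outputs)) {
    fp <- file.path(dirname(prov_path), f)
    if (!file.exists(fp)) return(FALSE)
    if (!identical(as.character(tools::md5sum(fp)), prov$outputs[[f]]))
      stop(sprintf("checksum mismatch for '%s': stage '%s' output changed on disk",
                   fp, prov$stage))
  }
  TRUE
}

# outputs are recorded by basename (resolved against the provenance file's
# directory at check time) so two runs into different directories produce
# byte-identical provenance
.write_prov <- function(prov_path, stage, params, inputs, outputs) {
  out_md5 <- .md5(outputs)
  names(out_md5) <- basename(names(out_md5))
  in_md5 <- .md5(inputs)
  here <- normalizePath(dirname(prov_path))
  rel <- dirname(normalizePath(names(in_md5))) == here
  names(in_md5)[rel] <- basename(names(in_md5)[rel])
  jsonlite::write_json(list(
    stage = stage, params = params,
    inputs = as.list(in_md5), outputs = as.list(out_md5),
    package_version = as.character(utils::packageVersion("regcircuit"))
  ), prov_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run the full analysis pipeline
#'
#' Executes the six stages in dependency order — enhancers (stitching,
#' scoring, SE calling, differential enhancers), states (TF chromatin-state
#' classification and active promoters), cobind (pairwise Fisher
#' co-binding), trn (enhancer-gene links, upregulation filter, ORA/GSEA),
#' network (PPI projection, integration ranking, CRC extraction) and report.
#' Each stage writes its tables plus a provenance JSON; up-to-date stages
#' (matching input and output checksums) are skipped on rerun. A stage
#' failure aborts with the stage name; downstream stages are not run.
#'
#' @param cfg \code{run_config}.
#' @param force rerun all stages even if up to date.
#' @return Invisible run manifest: per-stage status (run/skipped) and output
#'   paths.
#' @export
run_all <- function(cfg, force = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  o <- function(f) file.path(cfg$outdir, f)
  manifest <- list()
  run_stage <- function(stage, inputs, outputs, params, fn) {
    prov <- o(sprintf("provenance_%s.json", stage))
    status <- tryCatch({
      if (!force && .stage_current(prov)) "skipped" else {
        fn()
        .write_prov(prov, stage, params, inputs, outputs)
        "run"
      }
    }, error = function(e)
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE))
    manifest[[stage]] <<- list(status = status, outputs = unlist(outputs))
    invisible(NULL)
  }
  genome <- read_genome(cfg$genome)
  tss <- read_tss(cfg$tss)
  params_common <- cfg[c("stitch_gap", "tss_exclusion_window", "extend",
                         "bin_width", "fdr_max", "lfc_min", "promoter_window",
                         "n_perm", "seed", "trn_mode", "network_input")]

  # -- stage 1: enhancers ----------------------------------------------------
  enh_out <- list(o("enhancers_restored.tsv"), o("enhancers_absent.tsv"),
                  o("gained_enhancers.bed"))
  run_stage("enhancers",
            cfg[c("h3k27ac_restored", "h3k27ac_absent", "chip_restored",
                  "chip_absent", "input_track", "genome", "tss")],
            enh_out, params_common, function() {
    pk_r <- read_intervals(cfg$h3k27ac_restored, "broadPeak", genome)
    pk_a <- read_intervals(cfg$h3k27ac_absent, "broadPeak", genome)
    chip_r <- read_intervals(cfg$chip_restored, "bedgraph", genome)
    inp <- read_intervals(cfg$input_track, "bedgraph", genome)
    ecfg <- enhancer_config(cfg$stitch_gap, cfg$tss_exclusion_window)
    score_and_call <- function(pk, chip) {
      st <- stitch(pk, ecfg, tss)
      rk <- call_super_enhancers(score_regions(st, chip, inp))
      rk <- assign_se_to_gene(rk, tss)
      rk$cutoff_value <- attr(rk, "cutoff_value")
      rk
    }
    .write_tsv(score_and_call(pk_r, chip_r), enh_out[[1]])
    if (!is.null(cfg$chip_absent)) {
      chip_a <- read_intervals(cfg$chip_absent, "bedgraph", genome)
      .write_tsv(score_and_call(pk_a, chip_a), enh_out[[2]])
    } else .write_tsv(data.frame(), enh_out[[2]])
    gained <- differential_enhancers(pk_r, pk_a)
    write_intervals(gained, enh_out[[3]], "bed")
  })

  # -- stage 2: states -------------------------------------------------------
  st_out <- c(lapply(names(cfg$tf_restored), function(tf)
    o(sprintf("states_%s.tsv", tf))), list(o("active_promoters.tsv")))
  run_stage("states",
            c(cfg$tf_restored,
              cfg[c("h3k4me3", "h3k4me1", "h3k27ac_restored",
                    "h3k27ac_absent")],
              cfg[intersect("smarca4_absent", names(cfg))]),
            st_out, params_common, function() {
    me3 <- read_intervals(cfg$h3k4me3, "broadPeak", genome)
    me1 <- read_intervals(cfg$h3k4me1, "broadPeak", genome)
    aca <- read_intervals(cfg$h3k27ac_absent, "broadPeak", genome)
    acr <- read_intervals(cfg$h3k27ac_restored, "broadPeak", genome)
    tfs_r <- lapply(cfg$tf_restored, read_intervals, format = "narrowPeak",
                    genome = genome)
    for (i in seq_along(tfs_r))
      .write_tsv(classify_tf_peaks(tfs_r[[i]], me3, me1, aca, acr),
                 st_out[[i]])
    sm <- if (!is.null(cfg$smarca4_absent))
      read_intervals(cfg$smarca4_absent, "narrowPeak", genome) else NULL
    tfs_a <- if (!is.null(cfg$tf_absent))
      lapply(cfg$tf_absent, read_intervals, format = "narrowPeak",
             genome = genome) else tfs_r
    .write_tsv(call_active_promoters(me3, tss, cfg$promoter_window, sm,
                                     tfs_a),
               st_out[[length(st_out)]])
  })

  # -- stage 3: cobind -------------------------------------------------------
  run_stage("cobind", c(cfg$tf_restored, cfg["genome"]),
            list(o("cobinding.tsv")), params_common, function() {
    tfs_r <- lapply(cfg$tf_restored, read_intervals, format = "narrowPeak",
                    genome = genome)
    .write_tsv(pairwise_cobinding(tfs_r, genome, cfg$bin_width, cfg$extend),
               o("cobinding.tsv"))
  })

  # -- stage 4: trn ----------------------------------------------------------
  trn_out <- list(o("trn_links_nearest.tsv"), o("trn_links_curated.tsv"),
                  o("trn_genes.tsv"), o("trn_per_tf.tsv"),
                  o("trn_overlap.tsv"), o("ora.tsv"), o("gsea.tsv"))
  run_stage("trn",
            cfg[c("h3k27ac_restored", "h3k27ac_absent", "de_table",
                  "interactions", "gmt", "tss")],
            trn_out, params_common, function() {
    pk_r <- read_intervals(cfg$h3k27ac_restored, "broadPeak", genome)
    pk_a <- read_intervals(cfg$h3k27ac_absent, "broadPeak", genome)
    gained <- differential_enhancers(pk_r, pk_a)
    de <- read_de_table(cfg$de_table)
    inter <- read_interactions(cfg$interactions)
    gmt <- read_gmt(cfg$gmt)
    links_n <- assign_nearest(gained, tss)
    links_c <- assign_curated(gained, inter)
    trn_n <- build_trn(links_n, de, cfg$fdr_max, cfg$lfc_min)
    trn_c <- build_trn(links_c, de, cfg$fdr_max, cfg$lfc_min)
    .write_tsv(trn_n$links, trn_out[[1]])
    .write_tsv(trn_c$links, trn_out[[2]])
    mode_genes <- if (cfg$trn_mode == "nearest") trn_n$genes
      else if (cfg$trn_mode == "curated") trn_c$genes
      else sort(union(trn_n$genes, trn_c$genes))
    .write_tsv(data.frame(gene = mode_genes), trn_out[[3]])
    # per-TF TRNs: gained enhancers bound by each TF (curated links)
    tfs_r <- lapply(cfg$tf_restored, read_intervals, format = "narrowPeak",
                    genome = genome)
    per_tf <- lapply(names(tfs_r), function(tf) {
      bound <- gained[.overlaps_any(gained, tfs_r[[tf]]), , drop = FALSE]
      attr(bound, "genome") <- genome
      class(bound) <- unique(c("interval_set", class(bound)))
      tr <- build_trn(assign_curated(bound, inter), de, cfg$fdr_max,
                      cfg$lfc_min, tf = tf)
      tr
    })
    names(per_tf) <- names(tfs_r)
    per_tf_df <- do.call(rbind, lapply(per_tf, function(t)
      if (length(t$genes) > 0)
        data.frame(tf = t$tf, gene = t$genes, stringsAsFactors = FALSE)
      else NULL))
    if (is.null(per_tf_df))
      per_tf_df <- data.frame(tf = character(), gene = character())
    .write_tsv(per_tf_df, trn_out[[4]])
    ov <- trn_overlap(per_tf)
    .write_tsv(data.frame(region = names(ov), n_genes = as.integer(ov)),
               trn_out[[5]])
    union_genes <- sort(unique(unlist(lapply(per_tf, `[[`, "genes"))))
    .write_tsv(ora_hypergeometric(union_genes, gmt, de$gene), trn_out[[6]])
    scores <- stats::setNames(de$log2FoldChange, de$gene)
    gsea <- do.call(rbind, lapply(names(gmt), function(term) {
      r <- preranked_enrichment(scores, gmt[[term]], n_perm = cfg$n_perm,
                                seed = cfg$seed)
      data.frame(term = term, es = r$es, p = r$p, n_hits = r$n_hits,
                 stringsAsFactors = FALSE)
    }))
    .write_tsv(gsea, trn_out[[7]])
  })

  # -- stage 5: network ------------------------------------------------------
  net_out <- list(o("network_nodes.tsv"), o("network_edges.tsv"),
                  o("network_enrichment.json"), o("crc_members.tsv"))
  run_stage("network", c(cfg["ppi"], list(trn = o("trn_per_tf.tsv"))),
            net_out, params_common, function() {
    ppi <- read_ppi(cfg$ppi)
    per_tf <- utils::read.delim(o("trn_per_tf.tsv"),
                                stringsAsFactors = FALSE)
    genes_by_tf <- split(per_tf$gene, per_tf$tf)
    genes <- if (cfg$network_input == "intersection")
      Reduce(intersect, genes_by_tf) else sort(unique(per_tf$gene))
    sub <- ppi_induced_subgraph(ppi, genes)
    rk <- integration_rank(sub)
    enr <- edge_enrichment(ppi, genes)
    hub <- cfg$hub
    hub_auto <- is.null(hub)
    if (hub_auto) hub <- rk$node[1]
    crc <- extract_crc(sub, hub)
    rk$in_crc <- rk$node %in% crc$crc_members
    .write_tsv(rk, net_out[[1]])
    .write_tsv(sub$edges, net_out[[2]])
    jsonlite::write_json(c(enr, list(hub = hub, hub_autoselected = hub_auto)),
                         net_out[[3]], auto_unbox = TRUE, digits = NA)
    .write_tsv(data.frame(node = crc$crc_members,
                          is_hub = crc$crc_members == hub), net_out[[4]])
  })

  # -- stage 6: report -------------------------------------------------------
  run_stage("report",
            list(enh = enh_out[[1]], cob = o("cobinding.tsv"),
                 trn = o("trn_genes.tsv"), net = o("network_nodes.tsv")),
            list(o("report.json")), params_common, function() {
    enh <- utils::read.delim(enh_out[[1]], stringsAsFactors = FALSE)
    cob <- utils::read.delim(o("cobinding.tsv"), stringsAsFactors = FALSE)
    trn_genes <- utils::read.delim(o("trn_genes.tsv"),
                                   stringsAsFactors = FALSE)
    nodes <- utils::read.delim(o("network_nodes.tsv"),
                               stringsAsFactors = FALSE)
    enr <- jsonlite::read_json(o("network_enrichment.json"))
    jsonlite::write_json(list(
      n_enhancers = nrow(enh), n_super_enhancers = sum(enh$is_super),
      se_cutoff_signal = enh$cutoff_value[1],
      max_cobinding_minus_log10_p = max(-log10(pmax(cob$p, 1e-300))),
      n_trn_genes = nrow(trn_genes),
      n_network_nodes = nrow(nodes),
      ppi_p = enr$p, hub = enr$hub,
      params = params_common
    ), o("report.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })

  manifest
  invisible(manifest)
}
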