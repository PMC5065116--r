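# Pipeline orchestration: run every stage in order (partition -> assemble /
# classify -> quantify -> differential expression -> interactome sets -> SSP)
# from a single config, with per-stage TSV outputs and a summary report.

#' Assemble a pipeline configuration
#'
#' Exactly one of `simulate` (a [sim_config()]) or `references` (in-memory
#' reference panels + sample read sets for pre-loaded real data) must be
#' supplied; every stage threshold lives here so a run is fully described by
#' its config.
#'
#' @param simulate a [sim_config()] describing a synthetic experiment.
#' @param references optional list with elements `design` (a
#'   `design_matrix`), `rrna`, `s16`, `culture` (named list: species ->
#'   named sequence vector), `host`, `fungal_proteins`, `plant_proteins`,
#'   `sheet` (sample sheet with `sample_id`, `symbiont`, `host`,
#'   `replicate`, `sample_type`), and `reads` (named list of read sets).
#' @param align an [align_params()].
#' @param assembler_k,assembler_min_support de novo assembly settings.
#' @param assembler_auto_cutoff_frac coverage-cutoff fraction passed to
#'   [assemble_unassigned()] (suppresses error bubbles in deep pools).
#' @param min_contig_len de novo contigs shorter than this are discarded
#'   before classification.
#' @param de a [de_params()].
#' @param hydropathy a [hydropathy_params()].
#' @param orf_min_len_aa minimum ORF length for translation steps.
#' @param out_dir optional output directory for stage TSVs.
#' @param log_level `"info"` or `"quiet"`.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = NULL, references = NULL,
                            align = align_params(),
                            assembler_k = 31L, assembler_min_support = 2L,
                            assembler_auto_cutoff_frac = 0.05,
                            min_contig_len = 200L,
                            de = de_params(),
                            hydropathy = hydropathy_params(),
                            orf_min_len_aa = 30L,
                            out_dir = NULL, log_level = c("info", "quiet")) {
  if (is.null(simulate) == is.null(references))
    stop("exactly one of `simulate` / `references` must be given")
  structure(list(simulate = simulate, references = references, align = align,
                 assembler_k = as.integer(assembler_k),
                 assembler_min_support = as.integer(assembler_min_support),
                 assembler_auto_cutoff_frac = assembler_auto_cutoff_frac,
                 min_contig_len = as.integer(min_contig_len),
                 de = de, hydropathy = hydropathy,
                 orf_min_len_aa = as.integer(orf_min_len_aa),
                 out_dir = out_dir, log_level = match.arg(log_level)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Scalar fields of [sim_config()], [align_params()], [de_params()] and
#' [hydropathy_params()] may be overridden under keys `simulate`, `align`,
#' `de`, `hydropathy`; assembler settings under `assembler: {k, min_support}`.
#'
#' @param path YAML file.
#' @return `pipeline_config`.
#' @export
load_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- do.call(sim_config, if (is.null(y$simulate)) list() else y$simulate)
  args <- list(simulate = sim)
  if (!is.null(y$align)) args$align <- do.call(align_params, y$align)
  if (!is.null(y$de)) args$de <- do.call(de_params, y$de)
  if (!is.null(y$hydropathy))
    args$hydropathy <- do.call(hydropathy_params, y$hydropathy)
  if (!is.null(y$assembler$k)) args$assembler_k <- y$assembler$k
  if (!is.null(y$assembler$min_support))
    args$assembler_min_support <- y$assembler$min_support
  if (!is.null(y$out_dir)) args$out_dir <- y$out_dir
  do.call(pipeline_config, args)
}

pipe_log <- function(config, ...) {
  if (identical(config$log_level, "info"))
    message(format(Sys.time(), "%H:%M:%S"), " | ", ...)
  invisible(NULL)
}

#' Run the full pipeline
#'
#' Stages, in order: data (simulate or ingest), tiered partition per sample,
#' pooled de novo assembly + contig classification + read re-assignment,
#' per-species quantification, per-pair differential expression against the
#' species' free-living mycelium baseline, interactome set derivation, and
#' SSP classification of upregulated genes. Reruns with the same config are
#' byte-identical.
#'
#' @param config a [pipeline_config()].
#' @return list of class `run_report`; see the elements written by each
#'   stage (`partition`, `contigs`, `counts`, `de`, `sets`, `ssp`,
#'   `summary`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()

  # ---- stage 0: data --------------------------------------------------------
  if (!is.null(config$simulate)) {
    pipe_log(config, "simulate: generating synthetic experiment")
    ex <- simulate_experiment(config$simulate)
    design <- config$simulate$design
    culture <- setNames(
      lapply(design$symbionts, function(s) culture_reference(ex$panel, s)),
      design$symbionts)
    refs <- list(rrna = ex$panel$rrna, s16 = ex$panel$s16,
                 culture = culture, host = host_reference(ex$panel),
                 fungal_proteins = ex$panel$fungal_protein_panel,
                 plant_proteins = ex$panel$plant_protein_panel)
    sheet <- ex$sheet
    reads <- ex$reads
    panel <- ex$panel
  } else {
    refs <- config$references
    design <- refs$design
    sheet <- refs$sheet
    reads <- refs$reads
    panel <- NULL
  }
  all_culture <- unlist(unname(lapply(refs$culture, function(x) x)))

  # ---- stage 1: tiered partition -------------------------------------------
  pipe_log(config, "partition: ", nrow(sheet), " samples")
  k <- config$align$k
  idx_rrna <- build_kmer_index(refs$rrna, k)
  idx_s16 <- build_kmer_index(refs$s16, k)
  idx_host <- build_kmer_index(refs$host, k)
  idx_culture <- lapply(refs$culture, build_kmer_index, k = k)
  idx_all_culture <- build_kmer_index(all_culture, k)
  partitions <- list()
  for (i in seq_len(nrow(sheet))) {
    sid <- sheet$sample_id[i]
    sym <- sheet$symbiont[i]
    sym_idx <- if (sym %in% names(idx_culture)) idx_culture[[sym]]
               else idx_all_culture
    tiers <- tier_spec(idx_rrna, idx_s16, sym_idx, idx_host)
    partitions[[sid]] <- partition_reads(reads[[sid]], tiers, config$align)
  }

  # ---- stage 2: assembly + classification ----------------------------------
  unassigned <- do.call(rbind, lapply(names(partitions), function(sid) {
    a <- partitions[[sid]]$assignments
    r <- reads[[sid]][a$bin == "unassigned", c("id", "seq")]
    if (nrow(r)) r$sample_id <- sid
    r
  }))
  pipe_log(config, "assemble: ", NROW(unassigned), " pooled unassigned reads")
  contigs <- assemble_unassigned(
    unassigned, k = config$assembler_k,
    min_support = config$assembler_min_support,
    auto_cutoff_frac = config$assembler_auto_cutoff_frac)
  contigs <- contigs[nchar(contigs$seq) >= max(config$min_contig_len,
                                               config$align$k), , drop = FALSE]
  rownames(contigs) <- NULL
  if (nrow(contigs)) {
    contigs <- classify_contigs(contigs, refs$fungal_proteins,
                                refs$plant_proteins, config$align)
  } else contigs$taxon <- character(0)
  pipe_log(config, "classify: ", nrow(contigs), " contigs (",
           sum(contigs$taxon == "fungal"), " fungal, ",
           sum(contigs$taxon == "plant"), " plant)")
  contig_idx <- if (nrow(contigs))
    build_kmer_index(setNames(contigs$seq, contigs$contig_id), k) else NULL
  for (sid in names(partitions))
    partitions[[sid]] <- reassign_unassigned(partitions[[sid]], reads[[sid]],
                                             contigs, config$align,
                                             index = contig_idx)
  part_summary <- partition_summary(partitions, sheet)

  # ---- stage 3: quantification per species ---------------------------------
  denovo_fungal <- contigs[contigs$taxon == "fungal", , drop = FALSE]
  counts_by_species <- list()
  for (s in names(refs$culture)) {
    s_samples <- sheet$sample_id[sheet$symbiont == s]
    if (length(s_samples) == 0) next
    universe <- c(refs$culture[[s]],
                  setNames(denovo_fungal$seq, denovo_fungal$contig_id))
    fungal_reads <- lapply(s_samples, function(sid) {
      a <- partitions[[sid]]$assignments
      keep <- a$bin %in% c("symbiont", "denovo_fungal")
      reads[[sid]]$seq[keep]
    })
    names(fungal_reads) <- s_samples
    counts_by_species[[s]] <- count_reads(fungal_reads, universe,
                                          config$align)
    pipe_log(config, "quantify: ", s, " (", length(universe), " contigs x ",
             length(s_samples), " samples)")
  }

  # ---- stage 4: differential expression per pair ---------------------------
  de_by_pair <- list()
  pairs <- design_pairs(design)
  for (i in seq_len(nrow(pairs))) {
    s <- pairs$symbiont[i]; h <- pairs$host[i]
    key <- paste(s, h, sep = "|")
    grp_b <- sheet$sample_id[sheet$symbiont == s & sheet$host == h]
    grp_a <- sheet$sample_id[sheet$symbiont == s & sheet$sample_type == "mycelium"]
    if (length(grp_a) < 2 || length(grp_b) < 2) {
      warning("pair ", key, " lacks >= 2 replicates in a group; skipped")
      next
    }
    de_by_pair[[key]] <- differential(counts_by_species[[s]], grp_a, grp_b,
                                      config$de)
  }
  pipe_log(config, "de: ", length(de_by_pair), " pair contrasts")

  # ---- stage 5: interactome sets -------------------------------------------
  pair_sets <- lapply(de_by_pair, upregulated_set)
  species_sets <- list()
  for (key in names(pair_sets)) {
    s <- strsplit(key, "|", fixed = TRUE)[[1]][1]
    species_sets[[s]] <- union(species_sets[[s]], pair_sets[[key]])
  }
  universe_seqs <- lapply(names(refs$culture), function(s)
    c(refs$culture[[s]], setNames(denovo_fungal$seq, denovo_fungal$contig_id)))
  names(universe_seqs) <- names(refs$culture)
  proteins <- lapply(names(species_sets), function(s) {
    ids <- species_sets[[s]]
    longest_orfs(universe_seqs[[s]][ids], config$orf_min_len_aa)
  })
  names(proteins) <- names(species_sets)
  clusters <- homology_clusters(species_sets, proteins, config$align)
  sets <- derive_sets(clusters, design, pair_sets)
  # Venn over per-species compatible upregulated sets, mapped to clusters
  compat_sets <- list()
  for (key in names(pair_sets)) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    if (design$compatibility[parts[1], parts[2]] == "compatible")
      compat_sets[[parts[1]]] <- union(compat_sets[[parts[1]]],
                                       pair_sets[[key]])
  }
  m <- clusters$membership
  cluster_sets <- lapply(names(compat_sets), function(s) {
    unique(m$cluster[m$species == s & m$contig %in% compat_sets[[s]]])
  })
  names(cluster_sets) <- names(compat_sets)
  venn <- if (length(cluster_sets) >= 2) venn_counts(cluster_sets) else NULL
  pipe_log(config, "sets: ",
           length(unique(sets$common_compatible$cluster)), " common-compatible, ",
           length(unique(sets$common_incompatible$cluster)), " common-incompatible, ",
           nrow(sets$unique), " unique")

  # ---- stage 6: SSP classification of upregulated genes --------------------
  ssp_tables <- list()
  for (s in names(species_sets)) {
    pr <- proteins[[s]]
    pr <- pr[!is.na(pr)]
    if (length(pr) == 0) next
    tab <- ssp_report(pr, config$hydropathy)
    tab$species <- s
    ssp_tables[[s]] <- tab
  }
  ssp <- if (length(ssp_tables)) do.call(rbind, ssp_tables) else NULL
  pipe_log(config, "ssp: ", if (is.null(ssp)) 0 else sum(ssp$is_ssp),
           " SSPs among upregulated genes")

  report <- structure(list(
    partition = part_summary,
    contigs = contigs,
    counts = counts_by_species,
    de = de_by_pair,
    clusters = clusters,
    sets = sets,
    venn = venn,
    ssp = ssp,
    sheet = sheet,
    panel = panel,
    config = config,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    class = "run_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report:", nrow(x$sheet), "samples,",
      nrow(x$contigs), "de novo contigs,",
      length(x$de), "pair contrasts\n")
  cat(sprintf("  common-compatible clusters: %d | common-incompatible: %d | unique genes: %d\n",
              length(unique(x$sets$common_compatible$cluster)),
              length(unique(x$sets$common_incompatible$cluster)),
              nrow(x$sets$unique)))
  if (!is.null(x$ssp))
    cat("  SSPs among upregulated genes:", sum(x$ssp$is_ssp), "\n")
  invisible(x)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, file)
    write.table(df, file.path(out_dir, file), sep = "\t", quote = FALSE,
                row.names = FALSE)
  wt(report$partition, "partition_summary.tsv")
  if (nrow(report$contigs)) {
    write_fasta(setNames(report$contigs$seq, report$contigs$contig_id),
                file.path(out_dir, "denovo_contigs.fasta"))
    wt(report$contigs[, setdiff(names(report$contigs), "seq")], "contigs.tsv")
  }
  for (s in names(report$counts)) {
    cm <- report$counts[[s]]$counts
    wt(data.frame(contig = rownames(cm), cm, check.names = FALSE),
       sprintf("counts_%s.tsv", s))
  }
  for (key in names(report$de))
    wt(report$de[[key]], sprintf("de_%s.tsv", gsub("\\|", "_", key)))
  wt(report$clusters$membership, "clusters.tsv")
  wt(report$sets$common_compatible, "common_compatible.tsv")
  wt(report$sets$common_incompatible, "common_incompatible.tsv")
  wt(report$sets$unique, "unique_genes.tsv")
  if (!is.null(report$venn)) wt(report$venn, "venn_compatible.tsv")
  if (!is.null(report$ssp)) wt(report$ssp, "ssp_report.tsv")
  invisible(out_dir)
}

#' Heatmap-ready log2 expression matrix grouped by functional category
#'
#' @param norm normalized count matrix (genes x samples).
#' @param genes gene ids to include; absent ids are reported in the
#'   `skipped` attribute rather than failing.
#' @param func_map named character vector gene id -> functional category.
#' @param pseudocount added before log2.
#' @return numeric matrix of `log2(normalized + pseudocount)`, rows ordered
#'   by (category, gene id), with a `category` attribute and a `skipped`
#'   attribute listing absent genes.
#' @export
expression_matrix_export <- function(norm, genes, func_map, pseudocount = 1) {
  present <- genes[genes %in% rownames(norm)]
  skipped <- setdiff(genes, present)
  categ <- func_map[present]
  categ[is.na(categ)] <- "unknown"
  ord <- order(categ, present)
  out <- log2(norm[present[ord], , drop = FALSE] + pseudocount)
  attr(out, "category") <- unname(categ[ord])
  attr(out, "skipped") <- skipped
  out
}

#' Principal-component sample scores
#'
#' Column-centered SVD of the samples x genes matrix; returns per-sample
#' scores with explained-variance fractions. The sign of each component is
#' fixed so its largest-magnitude loading is positive. A constant matrix
#' yields all-zero scores with explained variance flagged undefined.
#'
#' @param norm matrix (genes x samples), typically log2 normalized counts.
#' @return list with `scores` (samples x components), `explained`
#'   (fractions, or `NA` when undefined).
#' @export
pca_coords <- function(norm) {
  x <- t(as.matrix(norm))
  if (nrow(x) < 2) stop("need >= 2 samples")
  centered <- scale(x, center = TRUE, scale = FALSE)
  if (all(abs(centered) < 1e-12)) {
    k <- min(dim(x))
    return(list(scores = matrix(0, nrow(x), k,
                                dimnames = list(rownames(x), paste0("PC", seq_len(k)))),
                explained = rep(NA_real_, k)))
  }
  p <- prcomp(x, center = TRUE, scale. = FALSE)
  flip <- apply(p$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  scores <- sweep(p$x, 2, flip, "*")
  explained <- p$sdev^2 / sum(p$sdev^2)
  list(scores = scores, explained = explained)
}
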