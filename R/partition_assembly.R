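# Tiered read partitioning against four reference sets, de novo assembly of
# the unassigned pool, and translated-similarity classification of the new
# contigs into fungal / plant / other.

#' Define the ordered partition tiers
#'
#' The canonical order is 1) fungal rRNA, 2) bacterial 16S, 3) symbiont
#' pure-culture contigs, 4) host ESTs: each read is claimed by the first
#' tier whose mapping passes the threshold, mirroring the sequential mapping
#' workflow. Tier names map to partition bins `rRNA`, `16S`, `symbiont`,
#' `host`.
#'
#' @param rrna,s16,symbiont,host named character vectors of reference
#'   sequences, or prebuilt [build_kmer_index()] objects when the same tier
#'   is reused across samples (an empty tier is skipped with a warning at
#'   partition time).
#' @return object of class `tier_spec`.
#' @export
tier_spec <- function(rrna, s16, symbiont, host) {
  tiers <- list(rRNA = rrna, `16S` = s16, symbiont = symbiont, host = host)
  structure(list(tiers = tiers), class = "tier_spec")
}

PARTITION_BINS <- c("rRNA", "16S", "symbiont", "host",
                    "denovo_fungal", "denovo_plant", "other")

#' Partition reads against the reference tiers
#'
#' Maps every read against each tier's k-mer index in tier order; the first
#' tier whose best mapping passes the mismatch threshold claims the read.
#' Reads claimed by no tier form the unassigned pool (later assembled de
#' novo).
#'
#' @param reads read-set data.frame (`id`, `seq`, ...).
#' @param tiers a [tier_spec()].
#' @param params an [align_params()]; all tier indices use `params$k`.
#' @return object of class `partition_result`: data.frame `assignments`
#'   (`id`, `bin`, `ref`), plus `bin_counts`.
#' @export
partition_reads <- function(reads, tiers, params = align_params()) {
  stopifnot(inherits(tiers, "tier_spec"), is.data.frame(reads))
  n <- nrow(reads)
  bin <- rep("unassigned", n)
  ref <- rep(NA_character_, n)
  remaining <- seq_len(n)
  for (tname in names(tiers$tiers)) {
    refs <- tiers$tiers[[tname]]
    prebuilt <- inherits(refs, "kmer_index")
    if ((prebuilt && length(refs$refs) == 0) ||
        (!prebuilt && length(refs) == 0)) {
      warning("tier '", tname, "' has an empty reference set; skipped")
      next
    }
    if (length(remaining) == 0) break
    idx <- if (prebuilt) refs else build_kmer_index(refs, params$k)
    if (idx$k != params$k) stop("tier '", tname, "' index k != params$k")
    hits <- map_reads(reads$seq[remaining], idx, params)
    mapped <- !is.na(hits$ref)
    bin[remaining[mapped]] <- tname
    ref[remaining[mapped]] <- hits$ref[mapped]
    remaining <- remaining[!mapped]
  }
  assignments <- data.frame(id = reads$id, bin = bin, ref = ref,
                            stringsAsFactors = FALSE)
  counts <- table(factor(bin, levels = c(names(tiers$tiers), "unassigned")))
  structure(list(assignments = assignments, bin_counts = counts),
            class = "partition_result")
}

#' @export
print.partition_result <- function(x, ...) {
  cat("partition_result over", nrow(x$assignments), "reads\n")
  print(x$bin_counts)
  invisible(x)
}

#' De novo assembly of a read pool into unitigs
#'
#' Builds the de Bruijn graph of canonical read k-mers (k-mers seen fewer
#' than `min_support` times are dropped, suppressing error-only paths) and
#' reports maximal non-branching paths (unitigs) as contigs, oriented as the
#' lexicographically smaller of contig/reverse-complement, ordered by
#' decreasing length then sequence. Note that terminal k-mers covered by a
#' single read are pruned when `min_support > 1`.
#'
#' @param reads read-set data.frame or character vector of sequences.
#' @param k odd assembly k-mer size (< read length).
#' @param min_support minimum k-mer multiplicity retained.
#' @param auto_cutoff_frac when > 0, additionally prune k-mers whose count
#'   falls below this fraction of the typical (occurrence-weighted median)
#'   k-mer coverage. Duplicated sequencing errors form bubbles at high
#'   coverage; with bubble popping out of scope, this coverage cutoff is the
#'   standard lightweight remedy. `0` disables it (pure `min_support`
#'   behavior).
#' @return data.frame of contigs: `contig_id`, `seq`, `support`.
#' @export
assemble_unassigned <- function(reads, k = 31L, min_support = 2L,
                                auto_cutoff_frac = 0) {
  seqs <- if (is.data.frame(reads)) reads$seq else as.character(reads)
  if (length(seqs) == 0)
    return(data.frame(contig_id = character(), seq = character(),
                      support = integer(), stringsAsFactors = FALSE))
  res <- .cpp_assemble(toupper(seqs), as.integer(k), as.integer(min_support),
                       auto_cutoff_frac)
  if (nrow(res) == 0)
    return(data.frame(contig_id = character(), seq = character(),
                      support = integer(), stringsAsFactors = FALSE))
  data.frame(contig_id = sprintf("contig%05d", seq_len(nrow(res))),
             seq = res$sequence, support = res$support,
             stringsAsFactors = FALSE)
}

#' Classify contigs as fungal, plant, or other
#'
#' Scores each contig's best six-frame local protein alignment against a
#' fungal and a plant protein panel. The call is the panel with the higher
#' score, provided it passes the identity and coverage thresholds; ties and
#' below-threshold contigs are called `other`.
#'
#' @param contigs contig data.frame from [assemble_unassigned()].
#' @param fungal_proteins,plant_proteins named character vectors of panel
#'   proteins.
#' @param params an [align_params()] (protein thresholds used).
#' @return the contig data.frame with added columns `taxon`,
#'   `fungal_score`, `plant_score`.
#' @export
classify_contigs <- function(contigs, fungal_proteins, plant_proteins,
                             params = align_params()) {
  if (length(fungal_proteins) == 0 || length(plant_proteins) == 0)
    stop("protein panels must be non-empty")
  mat <- score_matrix(params$score_matrix)
  # batch score-only pass shortlists the best panel protein per frame; the
  # full alignment is recomputed only for the winner
  best_panel_score <- function(frames, panel) {
    best <- list(score = 0, identity = 0, coverage = 0)
    for (fr in frames) {
      if (nchar(fr) < 10) next
      sc <- .cpp_sw_score_batch(fr, panel, paste(rownames(mat), collapse = ""),
                                mat, params$protein_gap)
      if (max(sc) > best$score) {
        sim <- protein_similarity(fr, panel[[which.max(sc)]], mat,
                                  params$protein_gap)
        if (sim$score > best$score) best <- sim
      }
    }
    best
  }
  n <- nrow(contigs)
  taxon <- character(n); fscore <- numeric(n); pscore <- numeric(n)
  for (i in seq_len(n)) {
    frames <- six_frame_translate(contigs$seq[i])
    bf <- best_panel_score(frames, fungal_proteins)
    bp <- best_panel_score(frames, plant_proteins)
    fscore[i] <- bf$score; pscore[i] <- bp$score
    passes <- function(x) x$identity >= params$min_identity &&
      x$coverage >= params$min_coverage
    taxon[i] <- if (bf$score > bp$score && passes(bf)) "fungal"
                else if (bp$score > bf$score && passes(bp)) "plant"
                else "other"
  }
  contigs$taxon <- taxon
  contigs$fungal_score <- fscore
  contigs$plant_score <- pscore
  contigs
}

#' Per-sample partition fraction summary
#'
#' Tabulates bin counts and fractions per sample from a set of partition
#' results; the symbiont total combines reference-mapped (`symbiont`) and de
#' novo fungal reads, mirroring the three-way fungal / plant / other
#' accounting.
#'
#' @param results named list of `partition_result` objects (one per sample;
#'   names are sample ids). Assignments may contain `denovo_fungal` /
#'   `denovo_plant` bins if [reassign_unassigned()] was applied.
#' @param sheet sample sheet data.frame with a `sample_id` column.
#' @return data.frame, one row per sample, with per-bin fractions, a
#'   `symbiont_total` fraction, and `n_reads`.
#' @export
partition_summary <- function(results, sheet) {
  unknown <- setdiff(names(results), sheet$sample_id)
  if (length(unknown))
    stop("partition results for unknown sample id(s): ",
         paste(unknown, collapse = ", "))
  rows <- lapply(names(results), function(sid) {
    a <- results[[sid]]$assignments
    n <- nrow(a)
    bins <- c(PARTITION_BINS, "unassigned")
    counts <- table(factor(a$bin, levels = bins))
    frac <- as.numeric(counts) / n
    names(frac) <- paste0("frac_", bins)
    out <- data.frame(sample_id = sid, n_reads = n, stringsAsFactors = FALSE)
    cbind(out, as.data.frame(as.list(frac)))
  })
  out <- do.call(rbind, rows)
  out$symbiont_total <- out$frac_symbiont + out$frac_denovo_fungal
  rownames(out) <- NULL
  out
}

#' Re-assign unassigned reads to classified de novo contigs
#'
#' After assembly and classification, unassigned reads that map to a
#' fungal-called contig move to bin `denovo_fungal`, plant-called to
#' `denovo_plant`, and the rest to `other`.
#'
#' @param result a `partition_result`.
#' @param reads the read set the result was computed from.
#' @param contigs classified contig data.frame (with `taxon`).
#' @param params an [align_params()].
#' @param index optional prebuilt contig `kmer_index` (reused across
#'   samples).
#' @return updated `partition_result`.
#' @export
reassign_unassigned <- function(result, reads, contigs,
                                params = align_params(), index = NULL) {
  un <- result$assignments$bin == "unassigned"
  if (!any(un)) return(result)
  if (nrow(contigs) == 0 || all(nchar(contigs$seq) < params$k)) {
    result$assignments$bin[un] <- "other"
    return(result)
  }
  idx <- if (!is.null(index)) index
         else build_kmer_index(setNames(contigs$seq, contigs$contig_id),
                               params$k)
  hits <- map_reads(reads$seq[un], idx, params)
  taxon <- contigs$taxon[match(hits$ref, contigs$contig_id)]
  newbin <- ifelse(is.na(hits$ref), "other",
                   ifelse(taxon == "fungal", "denovo_fungal",
                          ifelse(taxon == "plant", "denovo_plant", "other")))
  result$assignments$bin[un] <- newbin
  result$assignments$ref[un] <- hits$ref
  result$bin_counts <- table(factor(result$assignments$bin,
                                    levels = c(PARTITION_BINS, "unassigned")))
  result
}
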