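# Truth-labelled synthetic data emulating the statistical structure of a
# compatible vs incompatible ectomycorrhizal inoculation experiment: reference
# panels per fungal species, a host transcript set, rRNA/16S decoys, planted
# cross-species ortholog families, pair-specific genes, responsive (fold
# change) genes, and proteins with/without SSP features.

AA20 <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F",
          "P","S","T","W","Y","V")

# residues with Kyte-Doolittle hydropathy <= -0.4 (safe filler: cannot form
# a transmembrane-like hydrophobic stretch)
AA_HYDROPHILIC <- c("R","K","D","E","N","Q","H","P","S","T","G","W","Y")

#' Synthetic experiment configuration
#'
#' Defaults encode the study conditions the generator emulates: a 4 symbiont
#' x 3 host design with 9 compatible / 3 incompatible pairings, replicate
#' structure 3 (compatible) / 2 (incompatible), fungal read fractions 0.51
#' (compatible) vs 0.061 (incompatible), and planted gene structure (common
#' ortholog families, pair-unique genes, SSP-positive/negative proteins).
#'
#' @param seed integer seed; fixed seed implies byte-identical outputs.
#' @param design a `design_matrix`; default the bundled 4 x 3 grid.
#' @param reps_compatible,reps_incompatible replicates per pairing.
#' @param n_mycelium free-living mycelium reference samples per symbiont.
#' @param n_control uninoculated control samples per host.
#' @param n_common_compatible,n_common_incompatible planted ortholog family
#'   counts (one member per symbiont species each).
#' @param n_unique_per_pair planted pair-specific genes per (symbiont, host).
#' @param n_background background genes per symbiont species.
#' @param n_novel background genes per species withheld from the culture
#'   reference (recoverable only by de novo assembly).
#' @param n_host_transcripts,n_host_novel host gene counts (total / withheld
#'   from the EST reference).
#' @param n_ssp_pos,n_ssp_neg planted SSP-positive proteins and negatives
#'   (each negative violates exactly one criterion) per species.
#' @param cds_len_aa typical protein length of generated genes.
#' @param utr_len untranslated flank length (nt) on each side of a CDS.
#' @param n_rrna,rrna_len,n_16s,s16_len decoy panel sizes/lengths.
#' @param frac_fungal_compatible,frac_fungal_incompatible fungal read
#'   fraction by compatibility.
#' @param frac_rrna,frac_16s,frac_contaminant decoy/contaminant read
#'   fractions.
#' @param reads_per_sample,read_len,error_rate read simulation parameters
#'   (substitution-only error model).
#' @param divergence nucleotide divergence between ortholog family members.
#' @param panel_protein_divergence amino-acid divergence of the fungal/plant
#'   protein panels used for contig classification (emulates a related-species
#'   protein database).
#' @param fold_change planted expression fold change of responsive genes.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       design = NULL,
                       reps_compatible = 3L, reps_incompatible = 2L,
                       n_mycelium = 4L, n_control = 2L,
                       n_common_compatible = 10L, n_common_incompatible = 4L,
                       n_unique_per_pair = 3L,
                       n_background = 30L, n_novel = 6L,
                       n_host_transcripts = 40L, n_host_novel = 4L,
                       n_ssp_pos = 4L, n_ssp_neg = 4L,
                       cds_len_aa = 150L, utr_len = 30L,
                       n_rrna = 6L, rrna_len = 900L,
                       n_16s = 6L, s16_len = 800L,
                       frac_fungal_compatible = 0.51,
                       frac_fungal_incompatible = 0.061,
                       frac_rrna = 0.05, frac_16s = 0.02,
                       frac_contaminant = 0,
                       reads_per_sample = 50000L, read_len = 100L,
                       error_rate = 0.005,
                       divergence = 0.05,
                       panel_protein_divergence = 0.10,
                       fold_change = 8) {
  if (is.null(design)) design <- suillus_pinus_design()
  cfg <- list(seed = as.integer(seed), design = design,
              reps_compatible = as.integer(reps_compatible),
              reps_incompatible = as.integer(reps_incompatible),
              n_mycelium = as.integer(n_mycelium),
              n_control = as.integer(n_control),
              n_common_compatible = as.integer(n_common_compatible),
              n_common_incompatible = as.integer(n_common_incompatible),
              n_unique_per_pair = as.integer(n_unique_per_pair),
              n_background = as.integer(n_background),
              n_novel = as.integer(n_novel),
              n_host_transcripts = as.integer(n_host_transcripts),
              n_host_novel = as.integer(n_host_novel),
              n_ssp_pos = as.integer(n_ssp_pos), n_ssp_neg = as.integer(n_ssp_neg),
              cds_len_aa = as.integer(cds_len_aa), utr_len = as.integer(utr_len),
              n_rrna = as.integer(n_rrna), rrna_len = as.integer(rrna_len),
              n_16s = as.integer(n_16s), s16_len = as.integer(s16_len),
              frac_fungal_compatible = frac_fungal_compatible,
              frac_fungal_incompatible = frac_fungal_incompatible,
              frac_rrna = frac_rrna, frac_16s = frac_16s,
              frac_contaminant = frac_contaminant,
              reads_per_sample = as.integer(reads_per_sample),
              read_len = as.integer(read_len), error_rate = error_rate,
              divergence = divergence,
              panel_protein_divergence = panel_protein_divergence,
              fold_change = fold_change)
  fr <- c(cfg$frac_rrna, cfg$frac_16s, cfg$frac_contaminant,
          cfg$frac_fungal_compatible, cfg$frac_fungal_incompatible,
          cfg$error_rate, cfg$divergence)
  if (any(fr < 0 | fr > 1)) stop("all fractions/rates must lie in [0,1]")
  for (f in c(cfg$frac_fungal_compatible, cfg$frac_fungal_incompatible))
    if (f + cfg$frac_rrna + cfg$frac_16s + cfg$frac_contaminant > 1)
      stop("fungal + rRNA + 16S + contaminant fractions exceed 1")
  counts <- c(cfg$reps_compatible, cfg$reps_incompatible, cfg$n_mycelium,
              cfg$reads_per_sample, cfg$read_len, cfg$cds_len_aa)
  if (any(counts < 1)) stop("counts must be positive")
  if (cfg$n_novel + cfg$n_ssp_pos + cfg$n_ssp_neg > cfg$n_background)
    stop("n_background too small for planted novel + SSP genes")
  class(cfg) <- "sim_config"
  cfg
}

# deterministic per-stream seed derived from the config seed and a label
stream_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * (seq_len(nchar(label)) %% 31 + 1))
  (seed * 7919 + h * 104729) %% 2147483647
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

rand_protein <- function(n_aa) paste(sample(AA20, n_aa, replace = TRUE),
                                     collapse = "")

# codon table keyed by amino acid (stop codons excluded), as a padded matrix
# for vectorized synonymous-codon draws
codons_by_aa <- function() {
  gc <- Biostrings::GENETIC_CODE
  by_aa <- split(names(gc), gc)[AA20]
  width <- max(lengths(by_aa))
  mat <- matrix(NA_character_, length(by_aa), width,
                dimnames = list(names(by_aa), NULL))
  for (a in names(by_aa)) mat[a, seq_along(by_aa[[a]])] <- by_aa[[a]]
  list(mat = mat, n = lengths(by_aa))
}

# reverse-translate a protein, drawing a random synonymous codon per residue
reverse_translate <- function(protein, codon_tab) {
  aa <- match(strsplit(protein, "")[[1]], rownames(codon_tab$mat))
  pick <- floor(runif(length(aa)) * codon_tab$n[aa]) + 1L
  paste(codon_tab$mat[cbind(aa, pick)], collapse = "")
}

# mutate a CDS at nucleotide rate `rate`, rejecting substitutions that create
# an in-frame stop codon (keeps planted ORFs intact)
mutate_cds <- function(cds, rate) {
  chars <- strsplit(cds, "")[[1]]
  n <- length(chars)
  hits <- which(runif(n) < rate)
  stops <- c("TAA", "TAG", "TGA")
  for (p in hits) {
    alt <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
    codon_i <- (p - 1) %/% 3
    cd <- chars[(codon_i * 3 + 1):(codon_i * 3 + 3)]
    cd[(p - 1) %% 3 + 1] <- alt
    if (paste(cd, collapse = "") %in% stops) next
    chars[p] <- alt
  }
  paste(chars, collapse = "")
}

# mutate a protein at amino-acid rate `rate`
mutate_protein <- function(protein, rate) {
  chars <- strsplit(protein, "")[[1]]
  hits <- which(runif(length(chars)) < rate)
  for (p in hits) chars[p] <- sample(setdiff(AA20, chars[p]), 1)
  paste(chars, collapse = "")
}

# ---- planted SSP protein templates -----------------------------------------

# signal peptide prefix: M + n-region (K/R early) + hydrophobic h-region +
# A-X-A cleavage site; cleavage falls after residue 15
ssp_signal_prefix <- function() {
  nreg <- c(sample(c("K", "R"), 1), sample(AA_HYDROPHILIC, 2, replace = TRUE))
  hreg <- sample(c("L", "I"), 8, replace = TRUE)
  cleave <- c("A", sample(c("G", "S", "T"), 1), "A")
  paste(c("M", nreg, hreg, cleave), collapse = "")
}

# hydrophilic mature region: no >=19-residue hydrophobic stretch, no KDEL end
ssp_mature <- function(n_aa) {
  m <- sample(AA_HYDROPHILIC, n_aa, replace = TRUE)
  m[n_aa] <- "G"
  paste(m, collapse = "")
}

# planted proteins: positives satisfy all four SSP criteria by construction;
# each negative violates exactly the named criterion
planted_ssp_protein <- function(kind) {
  switch(kind,
    positive = paste0(ssp_signal_prefix(), ssp_mature(sample(80:150, 1))),
    len = paste0(ssp_signal_prefix(), ssp_mature(320)),
    signal_peptide = paste0("M", ssp_mature(sample(80:150, 1))),
    tm = {
      mat <- ssp_mature(sample(100:150, 1))
      ins <- sample(60:80, 1)  # beyond any signal-peptide window
      paste0(ssp_signal_prefix(),
             substr(mat, 1, ins), strrep("L", 25),
             substr(mat, ins + 1, nchar(mat)))
    },
    er_retention = {
      mat <- ssp_mature(sample(80:146, 1))
      paste0(ssp_signal_prefix(), mat, "KDEL")
    },
    stop("unknown planted SSP kind: ", kind))
}

FUNC_CATEGORIES <- c("G-protein signaling", "glycoside hydrolase",
                     "cytochrome P450", "secretory", "FAD/NAD(P) binding",
                     "nucleus-associated", "proteinase", "unknown")

# ---- reference panel --------------------------------------------------------

#' Generate a synthetic reference panel
#'
#' Builds, deterministically under the config seed: per-symbiont-species
#' transcript sets with planted ortholog families (`n_common_compatible` +
#' `n_common_incompatible`, one member per species, nucleotide identity
#' >= 1 - divergence), pair-specific ("unique") genes, background genes
#' (some withheld from the culture reference to exercise de novo assembly),
#' planted SSP-positive/negative proteins, a host transcript set, rRNA and
#' 16S decoy panels, diverged protein panels for contig classification, and
#' a functional-category truth map.
#'
#' @param config a [sim_config()].
#' @return object of class `reference_panel` with elements `transcripts`
#'   (truth table, one row per transcript), `rrna`, `s16`, `contaminant`,
#'   `fungal_protein_panel`, `plant_protein_panel`, and `config`.
#' @export
generate_reference_panel <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stream_seed(config$seed, "panel"))
  codon_tab <- codons_by_aa()
  design <- config$design
  species <- design$symbionts
  rows <- list()

  add_row <- function(id, species, type, family, pair_host, novel, protein,
                      ssp_truth = NA, ssp_violation = NA_character_) {
    # proteins begin with M, so the CDS starts with ATG by construction
    cds <- paste0(reverse_translate(protein, codon_tab), "TAA")
    seq <- paste0(rand_dna(config$utr_len), cds, rand_dna(config$utr_len))
    list(transcript_id = id, species = species, type = type,
         family = family, pair_host = pair_host, novel = novel,
         seq = seq, cds_start = config$utr_len + 1L,
         cds_end = config$utr_len + nchar(cds),
         protein = protein, ssp_truth = ssp_truth,
         ssp_violation = ssp_violation,
         func_category = sample(FUNC_CATEGORIES, 1))
  }

  # ortholog families: ancestor protein, per-species nucleotide divergence
  fam_specs <- c(rep("common_compatible", config$n_common_compatible),
                 rep("common_incompatible", config$n_common_incompatible))
  for (i in seq_along(fam_specs)) {
    fam_id <- sprintf("fam%02d_%s", i,
                      ifelse(fam_specs[i] == "common_compatible", "C", "I"))
    anc_protein <- paste0("M", rand_protein(config$cds_len_aa - 1))
    anc_cds <- reverse_translate(anc_protein, codon_tab)
    category <- sample(FUNC_CATEGORIES, 1)
    for (s in species) {
      # keep the start codon fixed so every family member retains its ORF
      tail_mut <- mutate_cds(substr(anc_cds, 4, nchar(anc_cds)),
                             config$divergence)
      cds <- paste0("ATG", tail_mut)
      prot <- as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                                 if.fuzzy.codon = "X"))
      full <- paste0(cds, "TAA")
      seq <- paste0(rand_dna(config$utr_len), full, rand_dna(config$utr_len))
      rows[[length(rows) + 1]] <- list(
        transcript_id = sprintf("%s_%s", s, fam_id), species = s,
        type = fam_specs[i], family = fam_id, pair_host = NA_character_,
        novel = FALSE, seq = seq, cds_start = config$utr_len + 1L,
        cds_end = config$utr_len + nchar(full),
        protein = prot, ssp_truth = NA,
        ssp_violation = NA_character_, func_category = category)
    }
  }

  # pair-unique genes: species- and host-specific, unrelated sequences; the
  # first gene of every pair carries an SSP-positive protein (effectors
  # concentrate among pair-specific upregulated genes)
  for (s in species) for (h in design$hosts) {
    for (j in seq_len(config$n_unique_per_pair)) {
      id <- sprintf("%s_%s_uniq%02d", s, h, j)
      if (j == 1L) {
        prot <- planted_ssp_protein("positive")
        rows[[length(rows) + 1]] <- add_row(id, s, "unique", NA_character_, h,
                                            FALSE, prot, ssp_truth = TRUE)
      } else {
        prot <- paste0("M", rand_protein(config$cds_len_aa - 1))
        rows[[length(rows) + 1]] <- add_row(id, s, "unique", NA_character_, h,
                                            FALSE, prot)
      }
    }
  }

  # background genes: SSP-planted first, novels last
  ssp_kinds <- c(rep("positive", config$n_ssp_pos),
                 rep_len(c("len", "signal_peptide", "tm", "er_retention"),
                         config$n_ssp_neg))
  for (s in species) {
    for (j in seq_len(config$n_background)) {
      id <- sprintf("%s_bg%03d", s, j)
      novel <- j > config$n_background - config$n_novel
      if (j <= length(ssp_kinds) && !novel) {
        kind <- ssp_kinds[j]
        prot <- planted_ssp_protein(kind)
        rows[[length(rows) + 1]] <- add_row(
          id, s, "background", NA_character_, NA_character_, novel, prot,
          ssp_truth = (kind == "positive"),
          ssp_violation = ifelse(kind == "positive", NA_character_, kind))
      } else {
        prot <- paste0("M", rand_protein(config$cds_len_aa - 1))
        rows[[length(rows) + 1]] <- add_row(id, s, "background",
                                            NA_character_, NA_character_,
                                            novel, prot)
      }
    }
  }

  # host transcripts
  for (j in seq_len(config$n_host_transcripts)) {
    id <- sprintf("host_g%03d", j)
    novel <- j > config$n_host_transcripts - config$n_host_novel
    prot <- paste0("M", rand_protein(config$cds_len_aa - 1))
    rows[[length(rows) + 1]] <- add_row(id, "host", "host", NA_character_,
                                        NA_character_, novel, prot)
  }

  transcripts <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  rownames(transcripts) <- NULL

  rrna <- setNames(vapply(seq_len(config$n_rrna),
                          function(i) rand_dna(config$rrna_len), ""),
                   sprintf("rRNA%02d", seq_len(config$n_rrna)))
  s16 <- setNames(vapply(seq_len(config$n_16s),
                         function(i) rand_dna(config$s16_len), ""),
                  sprintf("16S%02d", seq_len(config$n_16s)))
  contaminant <- setNames(vapply(1:5, function(i) rand_dna(600), ""),
                          sprintf("contam%02d", 1:5))

  # classification panels: diverged proteins, as a related-species database
  fungal_idx <- transcripts$species != "host"
  fungal_panel <- setNames(
    vapply(transcripts$protein[fungal_idx],
           mutate_protein, "", rate = config$panel_protein_divergence),
    paste0("fp_", transcripts$transcript_id[fungal_idx]))
  plant_panel <- setNames(
    vapply(transcripts$protein[!fungal_idx],
           mutate_protein, "", rate = config$panel_protein_divergence),
    paste0("pp_", transcripts$transcript_id[!fungal_idx]))

  structure(list(transcripts = transcripts, rrna = rrna, s16 = s16,
                 contaminant = contaminant,
                 fungal_protein_panel = fungal_panel,
                 plant_protein_panel = plant_panel,
                 config = config),
            class = "reference_panel")
}

#' @export
print.reference_panel <- function(x, ...) {
  tx <- x$transcripts
  cat(sprintf(paste0("reference_panel: %d fungal transcripts (%d species), ",
                     "%d host transcripts, %d rRNA + %d 16S decoys\n"),
              sum(tx$species != "host"),
              length(unique(tx$species[tx$species != "host"])),
              sum(tx$species == "host"), length(x$rrna), length(x$s16)))
  invisible(x)
}

#' Extract reference sequence sets from a panel
#'
#' `culture_reference` returns the per-species pure-culture transcript FASTA
#' analog (novel genes withheld); `host_reference` the host EST analog.
#'
#' @param panel a `reference_panel`.
#' @param species symbiont species id.
#' @return named character vector of sequences.
#' @export
culture_reference <- function(panel, species) {
  tx <- panel$transcripts
  keep <- tx$species == species & !tx$novel
  setNames(tx$seq[keep], tx$transcript_id[keep])
}

#' @rdname culture_reference
#' @export
host_reference <- function(panel) {
  tx <- panel$transcripts
  keep <- tx$species == "host" & !tx$novel
  setNames(tx$seq[keep], tx$transcript_id[keep])
}

# ---- read simulation --------------------------------------------------------

sample_bin_sizes <- function(config, compatibility, sample_type) {
  n <- config$reads_per_sample
  n_rrna <- round(config$frac_rrna * n)
  n_16s <- round(config$frac_16s * n)
  n_cont <- round(config$frac_contaminant * n)
  if (sample_type == "mycelium") {
    n_fungal <- n - n_rrna - n_16s - n_cont
    n_host <- 0L
  } else if (sample_type == "control") {
    n_fungal <- 0L
    n_host <- n - n_rrna - n_16s - n_cont
  } else {
    frac <- if (compatibility == "compatible") config$frac_fungal_compatible
            else config$frac_fungal_incompatible
    n_fungal <- round(frac * n)
    n_host <- n - n_rrna - n_16s - n_cont - n_fungal
  }
  c(rRNA = n_rrna, `16S` = n_16s, contaminant = n_cont,
    fungal = n_fungal, host = n_host)
}

draw_reads <- function(seqs, weights, n, config, id_prefix, truth_bin) {
  if (n == 0 || length(seqs) == 0)
    return(data.frame(id = character(), seq = character(), qual = character(),
                      truth_bin = character(), truth_transcript = character(),
                      truth_strand = character(), stringsAsFactors = FALSE))
  L <- config$read_len
  if (any(nchar(seqs) < L))
    stop("config error: read length exceeds a source sequence length")
  idx <- sample.int(length(seqs), n, replace = TRUE, prob = weights)
  src <- unname(seqs[idx])
  start <- floor(runif(n, 1, nchar(src) - L + 2))
  reads <- substring(src, start, start + L - 1)
  rc <- runif(n) < 0.5
  reads[rc] <- .cpp_revcomp(reads[rc])
  # vectorized substitution errors: process the r-th error of every read in
  # one pass (multiple errors per read are rare)
  nerr <- rbinom(n, L, config$error_rate)
  alt <- matrix(c("C", "G", "T", "A", "G", "T", "A", "C", "T", "A", "C", "G"),
                nrow = 4, byrow = TRUE,
                dimnames = list(c("A", "C", "G", "T"), NULL))
  for (r in seq_len(max(nerr, 0))) {
    i <- which(nerr >= r)
    if (!length(i)) break
    p <- sample.int(L, length(i), replace = TRUE)
    old <- substring(reads[i], p, p)
    known <- old %in% rownames(alt)
    i <- i[known]; p <- p[known]; old <- old[known]
    if (!length(i)) next
    new <- alt[cbind(match(old, rownames(alt)),
                     sample.int(3, length(i), replace = TRUE))]
    substring(reads[i], p, p) <- new
  }
  data.frame(id = sprintf("%s_%06d", id_prefix, seq_len(n)),
             seq = reads, qual = strrep("I", L),
             truth_bin = truth_bin,
             truth_transcript = names(seqs)[idx],
             truth_strand = ifelse(rc, "-", "+"),
             stringsAsFactors = FALSE)
}

#' Simulate one sample's read set with truth labels
#'
#' Bin sizes are exact (stratified): fungal reads = `round(fraction * n)`
#' with the fraction set by compatibility, likewise rRNA/16S/contaminant;
#' the remainder is host. Within the fungal bin, planted responsive genes
#' (common families in their matching condition; pair-unique genes in their
#' own pair) are over-sampled by the configured fold change. Reads are drawn
#' uniformly over transcript positions, 50% reverse-complement, with
#' substitution-only errors.
#'
#' @param panel a `reference_panel`.
#' @param symbiont symbiont species id, or `"none"` for an uninoculated
#'   control.
#' @param host host species id, or `"none"` for free-living mycelium.
#' @param replicate replicate index (enters the random stream and read ids).
#' @param config the [sim_config()] used to build the panel.
#' @return read-set data.frame with columns `id`, `seq`, `qual`,
#'   `truth_bin` (rRNA/16S/contaminant/fungal/host), `truth_transcript`,
#'   `truth_strand`.
#' @export
simulate_sample_reads <- function(panel, symbiont, host, replicate = 1L,
                                  config = panel$config) {
  stopifnot(inherits(panel, "reference_panel"))
  design <- config$design
  sample_type <- if (symbiont == "none") "control"
                 else if (host == "none") "mycelium"
                 else "pair"
  compatibility <- NA_character_
  if (sample_type == "pair") {
    if (!(symbiont %in% design$symbionts) || !(host %in% design$hosts))
      stop("pair (", symbiont, ", ", host, ") not in the design")
    compatibility <- design$compatibility[symbiont, host]
  }
  sid <- sample_id_for(symbiont, host, replicate)
  set.seed(stream_seed(config$seed, sid))

  sizes <- sample_bin_sizes(config, compatibility, sample_type)
  tx <- panel$transcripts
  parts <- list()
  parts$rrna <- draw_reads(panel$rrna, NULL, sizes["rRNA"], config,
                           paste0(sid, "_rr"), "rRNA")
  parts$s16 <- draw_reads(panel$s16, NULL, sizes["16S"], config,
                          paste0(sid, "_16"), "16S")
  parts$cont <- draw_reads(panel$contaminant, NULL, sizes["contaminant"],
                           config, paste0(sid, "_ct"), "contaminant")
  if (sizes["fungal"] > 0) {
    fx <- tx[tx$species == symbiont, , drop = FALSE]
    w <- rep(1, nrow(fx))
    if (sample_type == "pair") {
      responsive <-
        (compatibility == "compatible" & fx$type == "common_compatible") |
        (compatibility == "incompatible" & fx$type == "common_incompatible") |
        (fx$type == "unique" & fx$pair_host == host)
      w[responsive] <- config$fold_change
    }
    parts$fungal <- draw_reads(setNames(fx$seq, fx$transcript_id), w,
                               sizes["fungal"], config,
                               paste0(sid, "_fg"), "fungal")
  }
  if (sizes["host"] > 0) {
    hx <- tx[tx$species == "host", , drop = FALSE]
    parts$host <- draw_reads(setNames(hx$seq, hx$transcript_id), NULL,
                             sizes["host"], config, paste0(sid, "_ho"), "host")
  }
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

sample_id_for <- function(symbiont, host, replicate) {
  if (symbiont == "none") sprintf("ctrl_%s_r%d", host, replicate)
  else if (host == "none") sprintf("%s_myc_r%d", symbiont, replicate)
  else sprintf("%s_%s_r%d", symbiont, host, replicate)
}

#' Build the full synthetic experiment
#'
#' Generates the reference panel, the sample sheet implied by the design
#' (pair samples with the configured replicate structure, mycelium reference
#' samples per symbiont, uninoculated controls per host), and every sample's
#' truth-labelled read set.
#'
#' @param config a [sim_config()].
#' @return list with `panel`, `sheet` (sample sheet data.frame with
#'   `sample_id`, `symbiont`, `host`, `replicate`, `compatibility`,
#'   `sample_type`), and `reads` (named list of read sets).
#' @export
simulate_experiment <- function(config = sim_config()) {
  panel <- generate_reference_panel(config)
  design <- config$design
  rows <- list()
  pairs <- design_pairs(design)
  for (i in seq_len(nrow(pairs))) {
    nrep <- if (pairs$compatibility[i] == "compatible") config$reps_compatible
            else config$reps_incompatible
    for (r in seq_len(nrep))
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = sample_id_for(pairs$symbiont[i], pairs$host[i], r),
        symbiont = pairs$symbiont[i], host = pairs$host[i], replicate = r,
        compatibility = pairs$compatibility[i], sample_type = "pair",
        stringsAsFactors = FALSE)
  }
  for (s in design$symbionts) for (r in seq_len(config$n_mycelium))
    rows[[length(rows) + 1]] <- data.frame(
      sample_id = sample_id_for(s, "none", r), symbiont = s, host = "none",
      replicate = r, compatibility = NA_character_,
      sample_type = "mycelium", stringsAsFactors = FALSE)
  for (h in design$hosts) for (r in seq_len(config$n_control))
    rows[[length(rows) + 1]] <- data.frame(
      sample_id = sample_id_for("none", h, r), symbiont = "none", host = h,
      replicate = r, compatibility = NA_character_,
      sample_type = "control", stringsAsFactors = FALSE)
  sheet <- do.call(rbind, rows)
  sheet$fastq <- NA_character_

  reads <- lapply(seq_len(nrow(sheet)), function(i)
    simulate_sample_reads(panel, sheet$symbiont[i], sheet$host[i],
                          sheet$replicate[i], config))
  names(reads) <- sheet$sample_id
  list(panel = panel, sheet = sheet, reads = reads)
}

#' Write machine-readable truth tables
#'
#' Emits TSVs under `out_dir`: `truth_transcripts.tsv` (per-transcript
#' origin, type, family, novelty, functional category),
#' `truth_families.tsv` (ortholog family membership),
#' `truth_de.tsv` (planted responsive genes with condition and fold change),
#' and `truth_ssp.tsv` (planted SSP labels and violated criterion).
#'
#' @param panel a `reference_panel`.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_truth <- function(panel, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tx <- panel$transcripts
  cfg <- panel$config
  wt <- function(df, file) {
    path <- file.path(out_dir, file)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  p1 <- wt(tx[, c("transcript_id", "species", "type", "family", "pair_host",
                  "novel", "func_category")], "truth_transcripts.tsv")
  fam <- tx[!is.na(tx$family), c("family", "species", "transcript_id")]
  p2 <- wt(fam, "truth_families.tsv")
  de <- rbind(
    data.frame(transcript_id = tx$transcript_id[tx$type == "common_compatible"],
               condition = "compatible",
               fold_change = cfg$fold_change, stringsAsFactors = FALSE),
    data.frame(transcript_id = tx$transcript_id[tx$type == "common_incompatible"],
               condition = "incompatible",
               fold_change = cfg$fold_change, stringsAsFactors = FALSE),
    data.frame(transcript_id = tx$transcript_id[tx$type == "unique"],
               condition = paste0("pair:", tx$pair_host[tx$type == "unique"]),
               fold_change = cfg$fold_change, stringsAsFactors = FALSE))
  p3 <- wt(de, "truth_de.tsv")
  ssp <- tx[!is.na(tx$ssp_truth),
            c("transcript_id", "species", "ssp_truth", "ssp_violation")]
  p4 <- wt(ssp, "truth_ssp.tsv")
  invisible(c(p1, p2, p3, p4))
}
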