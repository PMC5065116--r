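test_that("generation is byte-identical under a fixed seed", {
  cfg <- tiny_config()
  p1 <- generate_reference_panel(cfg)
  p2 <- generate_reference_panel(cfg)
  expect_identical(p1$transcripts, p2$transcripts)
  expect_identical(p1$rrna, p2$rrna)
  r1 <- simulate_sample_reads(p1, "Sa", "Pm", 1, cfg)
  r2 <- simulate_sample_reads(p2, "Sa", "Pm", 1, cfg)
  expect_identical(r1, r2)
  # different seed changes the data
  p3 <- generate_reference_panel(tiny_config(seed = 43L))
  expect_false(identical(p1$transcripts$seq, p3$transcripts$seq))
})

test_that("planted ortholog families have one member per species", {
  p <- tiny_panel()
  cfg <- p$config
  fams <- p$transcripts[!is.na(p$transcripts$family), ]
  for (f in unique(fams$family)) {
    members <- fams[fams$family == f, ]
    expect_setequal(members$species, cfg$design$symbionts)
  }
  expect_equal(length(unique(fams$family)),
               cfg$n_common_compatible + cfg$n_common_incompatible)
})

test_that("ortholog divergence bounds nucleotide identity", {
  p <- tiny_panel()
  cfg <- p$config
  fams <- p$transcripts[p$transcripts$type == "common_compatible", ]
  f <- fams[fams$family == fams$family[1], ]
  cds <- substr(f$seq, f$cds_start, f$cds_end)
  a <- strsplit(cds[1], "")[[1]]; b <- strsplit(cds[2], "")[[1]]
  ident <- mean(a == b)
  # both members diverged independently from the ancestor at rate <= divergence
  expect_gte(ident, 1 - 2 * cfg$divergence - 0.05)
  # divergence 0 -> identical family members
  p0 <- generate_reference_panel(tiny_config(seed = 5L, divergence = 0))
  f0 <- p0$transcripts[p0$transcripts$type == "common_compatible", ]
  f0 <- f0[f0$family == f0$family[1], ]
  cds0 <- substr(f0$seq, f0$cds_start, f0$cds_end)
  expect_true(all(cds0 == cds0[1]))
})

test_that("stratified sampling gives exact bin counts and label conservation", {
  cfg <- tiny_config(reads_per_sample = 1000L, frac_rrna = 0.1,
                     frac_16s = 0.02)
  p <- generate_reference_panel(cfg)
  rd <- simulate_sample_reads(p, "Sa", "Pm", 1, cfg)  # compatible pair
  expect_equal(nrow(rd), 1000L)
  tab <- table(rd$truth_bin)
  expect_equal(unname(tab["rRNA"]), 100L)
  expect_equal(unname(tab["16S"]), 20L)
  expect_equal(unname(tab["fungal"]), round(0.51 * 1000))
  expect_equal(sum(tab), 1000L)
  # incompatible pair fungal fraction
  rd2 <- simulate_sample_reads(p, "Sa", "Pt", 1, cfg)
  expect_equal(unname(table(rd2$truth_bin)["fungal"]), round(0.061 * 1000))
  # control: no fungal reads
  rd3 <- simulate_sample_reads(p, "none", "Pm", 1, cfg)
  expect_false("fungal" %in% rd3$truth_bin)
  # mycelium: no host reads
  rd4 <- simulate_sample_reads(p, "Sa", "none", 1, cfg)
  expect_false("host" %in% rd4$truth_bin)
})

test_that("error-free reads are exact substrings of their source", {
  cfg <- tiny_config(error_rate = 0, reads_per_sample = 300L)
  p <- generate_reference_panel(cfg)
  rd <- simulate_sample_reads(p, "Sg", "Ps", 1, cfg)
  src <- c(setNames(p$transcripts$seq, p$transcripts$transcript_id),
           p$rrna, p$s16)
  for (i in sample(nrow(rd), 50)) {
    s <- src[[rd$truth_transcript[i]]]
    probe <- if (rd$truth_strand[i] == "-") revcomp(rd$seq[i]) else rd$seq[i]
    expect_true(grepl(probe, s, fixed = TRUE))
  }
})

test_that("planted fold change is recovered from read counts", {
  cfg <- tiny_config(reads_per_sample = 20000L)
  p <- generate_reference_panel(cfg)
  rd <- simulate_sample_reads(p, "Sa", "Pm", 1, cfg)
  tx <- p$transcripts[p$transcripts$species == "Sa", ]
  fung <- rd[rd$truth_bin == "fungal", ]
  counts <- table(factor(fung$truth_transcript, levels = tx$transcript_id))
  responsive <- tx$type == "common_compatible" |
    (tx$type == "unique" & !is.na(tx$pair_host) & tx$pair_host == "Pm")
  ratio <- mean(counts[responsive]) / mean(counts[!responsive])
  expect_lt(abs(ratio / cfg$fold_change - 1), 0.2)
})

test_that("decoy panels share no mapping k-mers with transcripts", {
  p <- tiny_panel()
  k <- 21
  kmers <- function(s) {
    n <- nchar(s)
    if (n < k) return(character())
    substring(s, 1:(n - k + 1), k:n)
  }
  tx_kmers <- unlist(lapply(p$transcripts$seq, kmers))
  decoy_kmers <- unlist(lapply(c(p$rrna, p$s16), kmers))
  expect_length(intersect(tx_kmers, c(decoy_kmers, revcomp(decoy_kmers))), 0)
})

test_that("planted SSP proteins satisfy or violate exactly the named criteria", {
  p <- tiny_panel()
  planted <- p$transcripts[!is.na(p$transcripts$ssp_truth), ]
  expect_gt(nrow(planted), 0)
  for (i in seq_len(nrow(planted))) {
    cl <- classify_ssp(planted$protein[i])
    expect_equal(cl$is_ssp, planted$ssp_truth[i])
    if (!planted$ssp_truth[i]) {
      crit <- c(len = cl$len_ok, signal_peptide = cl$signal_peptide,
                tm = cl$no_tm, er_retention = cl$no_er_retention)
      expect_equal(sum(!crit), 1L)
      expect_false(crit[[planted$ssp_violation[i]]])
    }
  }
})

test_that("truth tables round-trip through TSV", {
  p <- tiny_panel()
  dir <- tempfile()
  paths <- write_truth(p, dir)
  expect_true(all(file.exists(file.path(
    dir, c("truth_transcripts.tsv", "truth_families.tsv",
           "truth_de.tsv", "truth_ssp.tsv")))))
  fam <- read.delim(file.path(dir, "truth_families.tsv"))
  expect_setequal(unique(fam$family),
                  unique(na.omit(p$transcripts$family)))
  tx <- read.delim(file.path(dir, "truth_transcripts.tsv"))
  expect_equal(tx$transcript_id, p$transcripts$transcript_id)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(frac_fungal_compatible = 0.9, frac_rrna = 0.2),
               "exceed 1")
  expect_error(sim_config(frac_rrna = -0.1), "\\[0,1\\]")
  expect_error(sim_config(reads_per_sample = 0), "positive")
  expect_error(sim_config(n_background = 5, n_novel = 10), "too small")
  # read length exceeding transcripts
  cfg <- tiny_config(read_len = 5000L)
  p <- suppressWarnings(generate_reference_panel(tiny_config()))
  expect_error(simulate_sample_reads(p, "Sa", "Pm", 1, cfg), "config error")
})
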