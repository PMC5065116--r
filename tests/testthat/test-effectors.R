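test_that("ORFs are extracted with faithful coordinates on both strands", {
  orfs <- extract_orfs("ATGAAATAA", min_len_aa = 2)
  expect_equal(nrow(orfs), 1)
  expect_equal(orfs$protein, "MK")
  expect_equal(orfs$frame, "F1")
  expect_false(orfs$partial)
  # no ATG anywhere in start-required mode
  expect_equal(nrow(extract_orfs(strrep("C", 60), min_len_aa = 2)), 0)
  # reverse-strand ORF round-trips through its reported coordinates
  set.seed(40)
  prot <- paste0("M", rand_prot_str(40))
  cds <- paste(vapply(strsplit(prot, "")[[1]], function(a) {
    gc <- Biostrings::GENETIC_CODE
    names(gc)[gc == a][1]
  }, ""), collapse = "")
  contig <- paste0(rand_dna_str(15), revcomp(paste0(cds, "TAA")),
                   rand_dna_str(15))
  orfs <- extract_orfs(contig, min_len_aa = 30)
  rowr <- orfs[startsWith(orfs$frame, "R") & !orfs$partial, ]
  expect_gte(nrow(rowr), 1)
  best <- rowr[which.max(nchar(rowr$protein)), ]
  sub <- substr(contig, best$start + 1, best$end)
  retrans <- as.character(Biostrings::translate(
    Biostrings::reverseComplement(Biostrings::DNAString(sub))))
  expect_equal(sub("\\*$", "", retrans), best$protein)
  expect_equal(best$protein, prot)
})

test_that("signal peptides require n-region charge, h-region, and cleavage", {
  # M + n-region KRS + 8-residue Leu h-region + A-S-A: cleavage after 15
  sp <- predict_signal_peptide(paste0("MKRS", strrep("L", 8), "ASA",
                                      strrep("D", 60)))
  expect_true(sp$present)
  expect_equal(sp$cleavage, 15)
  # poly-aspartate N-terminus: nothing to find
  expect_false(predict_signal_peptide(strrep("D", 80))$present)
  # h-region present but no K/R in residues 1-5
  expect_false(predict_signal_peptide(paste0("MDDD", strrep("L", 8), "ASA",
                                             strrep("D", 60)))$present)
  # h-region too short
  expect_false(predict_signal_peptide(paste0("MKRS", strrep("L", 4), "ASA",
                                             strrep("D", 60)))$present)
  # too short a protein is never called
  expect_false(predict_signal_peptide("MKRLLLLLLLLAS")$present)
})

test_that("hydropathy windows call transmembrane segments outside the SP", {
  prot <- paste0(strrep("D", 49), strrep("L", 25), strrep("D", 60))
  tm <- detect_tm(prot)
  expect_equal(nrow(tm), 1)
  expect_true(tm$start <= 55 && tm$end >= 70)  # overlaps the Leu stretch
  expect_gte(tm$max_mean, 1.6)
  expect_equal(nrow(detect_tm(strrep("D", 100))), 0)
  # long hydrophobic h-region inside the signal peptide is masked
  sp_prot <- paste0("MKRS", strrep("L", 12), "ASA", strrep("D", 80))
  cl <- predict_signal_peptide(sp_prot)$cleavage
  expect_equal(nrow(detect_tm(sp_prot, sp_cleavage = cl)), 0)
  expect_gt(nrow(detect_tm(sp_prot, sp_cleavage = NA)), 0)
  # shorter than the window: empty
  expect_equal(nrow(detect_tm("LLLLL")), 0)
})

test_that("motif scans follow their consensus definitions", {
  m <- scan_motifs(paste0(strrep("G", 40), "KDEL"))
  expect_true(m$er_retention)
  expect_false(scan_motifs("KDELGGGG")$er_retention)  # not C-terminal
  expect_true(scan_motifs(paste0(strrep("G", 20), "HDEL"))$er_retention)
  expect_equal(scan_motifs("NASA")$n_glyc_sites, 1L)
  expect_length(scan_motifs("NPSA")$n_glyc_sites, 0)  # X != P rule
  expect_true(scan_motifs("PKKKRKV")$nls)
  expect_false(scan_motifs("GAGAGAG")$nls)
  # RXLR within the post-cleavage window only
  prot <- paste0(strrep("G", 15), "RSLR", strrep("G", 80))
  expect_true(scan_motifs(prot, sp_cleavage = 15)$rxlr)
  far <- paste0(strrep("G", 100), "RSLR")
  expect_false(scan_motifs(far, sp_cleavage = 15)$rxlr)
})

test_that("the four SSP criteria gate conjunctively", {
  sp_prefix <- paste0("MKRS", strrep("L", 8), "ASA")
  good <- paste0(sp_prefix, strrep("D", 100), "G")
  cl <- classify_ssp(good)
  expect_true(cl$is_ssp)
  expect_true(cl$len_ok && cl$signal_peptide && cl$no_tm && cl$no_er_retention)
  # criterion (a): size >= 300
  big <- paste0(sp_prefix, strrep("D", 300))
  expect_false(classify_ssp(big)$is_ssp)
  expect_false(classify_ssp(big)$len_ok)
  # criterion (d): ER retention
  kdel <- paste0(sp_prefix, strrep("D", 100), "KDEL")
  cl_k <- classify_ssp(kdel)
  expect_false(cl_k$is_ssp)
  expect_false(cl_k$no_er_retention)
  expect_true(cl_k$len_ok && cl_k$signal_peptide && cl_k$no_tm)
  # monotonicity: appending residues past 299 flips len_ok only
  grown <- paste0(good, strrep("G", 300 - nchar(good)))
  cl_g <- classify_ssp(grown)
  expect_false(cl_g$len_ok)
  expect_false(cl_g$is_ssp)
})

test_that("external predictor overrides plug into the call", {
  prot <- paste0(strrep("D", 100))  # no signal peptide heuristically
  cl <- classify_ssp(prot, overrides = list(signal_peptide = TRUE,
                                            cleavage = 20L))
  expect_true(cl$signal_peptide)
  expect_true(cl$is_ssp)
  cl2 <- classify_ssp(prot, overrides = list(signal_peptide = TRUE,
                                             tm_segments = 2L))
  expect_false(cl2$no_tm)
  expect_false(cl2$is_ssp)
})

test_that("ssp_report tabulates one row per protein with all criteria", {
  p <- tiny_panel()
  planted <- p$transcripts[!is.na(p$transcripts$ssp_truth), ]
  tab <- ssp_report(setNames(planted$protein, planted$transcript_id))
  expect_equal(nrow(tab), nrow(planted))
  expect_equal(tab$is_ssp, planted$ssp_truth)
  expect_true(all(c("len_ok", "signal_peptide", "no_tm", "no_er_retention",
                    "n_glyc", "rxlr", "nls") %in% names(tab)))
})
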