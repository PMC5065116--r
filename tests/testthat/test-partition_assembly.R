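test_that("tier precedence claims multi-tier reads in workflow order", {
  set.seed(10)
  shared <- rand_dna_str(200)
  rrna <- c(rr1 = shared)
  symb <- c(sy1 = paste0(rand_dna_str(100), shared))  # also contains it
  s16 <- c(ss1 = rand_dna_str(200))
  host <- c(ho1 = rand_dna_str(200))
  reads <- data.frame(id = "x", seq = substr(shared, 50, 149),
                      stringsAsFactors = FALSE)
  pr <- partition_reads(reads, tier_spec(rrna, s16, symb, host))
  expect_equal(pr$assignments$bin, "rRNA")
  # remove the rRNA tier copy: now the symbiont tier claims it
  pr2 <- partition_reads(reads, tier_spec(c(rr1 = rand_dna_str(200)), s16,
                                          symb, host))
  expect_equal(pr2$assignments$bin, "symbiont")
})

test_that("unmatched reads fall through to the unassigned pool and bins sum", {
  set.seed(11)
  tiers <- tier_spec(c(a = rand_dna_str(200)), c(b = rand_dna_str(200)),
                     c(c = rand_dna_str(200)), c(d = rand_dna_str(200)))
  reads <- data.frame(id = sprintf("r%d", 1:20),
                      seq = c(substr(tiers$tiers$symbiont, 1, 100),
                              replicate(19, rand_dna_str(100))),
                      stringsAsFactors = FALSE)
  pr <- partition_reads(reads, tiers)
  expect_equal(sum(pr$bin_counts), 20)
  expect_equal(unname(pr$bin_counts["symbiont"]), 1)
  expect_equal(unname(pr$bin_counts["unassigned"]), 19)
  # empty tier skipped with warning
  expect_warning(
    partition_reads(reads, tier_spec(setNames(character(), character()),
                                     tiers$tiers$`16S`, tiers$tiers$symbiont,
                                     tiers$tiers$host)),
    "empty")
})

test_that("assembler reconstructs a transcript from error-free tiling reads", {
  set.seed(12)
  tx <- rand_dna_str(300)
  reads <- substring(tx, 1:(300 - 69), 70:300)
  ctg <- assemble_unassigned(reads, k = 31, min_support = 1)
  expect_equal(nrow(ctg), 1)
  expect_true(ctg$seq[1] %in% c(tx, revcomp(tx)))
  # idempotence: assembling the contig's own tiling reads returns it
  reads2 <- substring(ctg$seq[1], 1:(300 - 69), 70:300)
  ctg2 <- assemble_unassigned(reads2, k = 31, min_support = 1)
  expect_equal(sort(ctg2$seq), sort(ctg$seq))
})

test_that("assembler separates transcripts sharing no k-mers", {
  set.seed(13)
  tx1 <- rand_dna_str(250); tx2 <- rand_dna_str(250)
  reads <- c(substring(tx1, 1:(250 - 69), 70:250),
             substring(tx2, 1:(250 - 69), 70:250))
  ctg <- assemble_unassigned(reads, k = 31, min_support = 1)
  expect_equal(nrow(ctg), 2)
  expect_setequal(ctg$seq, c(min(tx1, revcomp(tx1)), min(tx2, revcomp(tx2))))
  expect_equal(nrow(assemble_unassigned(character(), 31)), 0)
})

test_that("deterministic contig orientation and ordering", {
  set.seed(14)
  tx <- rand_dna_str(300)
  reads <- substring(tx, 1:(300 - 69), 70:300)
  c1 <- assemble_unassigned(reads, 31, 1)
  c2 <- assemble_unassigned(rev(reads), 31, 1)
  expect_identical(c1$seq, c2$seq)
  expect_true(all(c1$seq <= revcomp(c1$seq)))
})

test_that("contig classification follows the best passing panel", {
  p <- tiny_panel()
  fung <- p$fungal_protein_panel
  plant <- p$plant_protein_panel
  tx <- p$transcripts
  # contig = exact fungal CDS -> fungal; exact host CDS -> plant
  f_tx <- tx[tx$species == "Sa", ][1, ]
  h_tx <- tx[tx$species == "host", ][1, ]
  contigs <- data.frame(
    contig_id = c("c1", "c2", "c3"),
    seq = c(f_tx$seq, h_tx$seq, rand_dna_str(400)),
    support = c(5L, 5L, 5L), stringsAsFactors = FALSE)
  set.seed(15)
  cc <- classify_contigs(contigs, fung, plant)
  expect_equal(cc$taxon[1], "fungal")
  expect_equal(cc$taxon[2], "plant")
  expect_equal(cc$taxon[3], "other")
  expect_error(classify_contigs(contigs, character(), plant), "non-empty")
})

test_that("a crafted contig scoring higher on one panel gets that call", {
  set.seed(16)
  prot <- rand_prot_str(120)
  cds <- vapply(strsplit(prot, "")[[1]], function(a) {
    gc <- Biostrings::GENETIC_CODE
    names(gc)[gc == a][1]
  }, "")
  contig <- paste0("ATG", paste(cds, collapse = ""), "TAA")
  plant_panel <- c(pp1 = prot)                   # identical: high score
  fungal_panel <- c(fp1 = rand_prot_str(120))    # unrelated: low score
  cc <- classify_contigs(data.frame(contig_id = "c", seq = contig,
                                    support = 5L, stringsAsFactors = FALSE),
                         fungal_panel, plant_panel)
  expect_equal(cc$taxon, "plant")
  expect_gt(cc$plant_score, cc$fungal_score)
})

test_that("partition summary fractions are consistent", {
  set.seed(17)
  ref <- c(sy = rand_dna_str(300))
  reads <- data.frame(id = paste0("r", 1:10),
                      seq = substring(ref, 1:10, 100:109),
                      stringsAsFactors = FALSE)
  pr <- partition_reads(reads, tier_spec(c(a = rand_dna_str(200)),
                                         c(b = rand_dna_str(200)),
                                         ref, c(d = rand_dna_str(200))))
  sheet <- data.frame(sample_id = "s1", stringsAsFactors = FALSE)
  summ <- partition_summary(list(s1 = pr), sheet)
  frac_cols <- grep("^frac_", names(summ))
  expect_equal(sum(summ[1, frac_cols]), 1, tolerance = 1e-9)
  expect_equal(summ$frac_symbiont, 1)
  expect_error(partition_summary(list(zz = pr), sheet), "unknown sample")
})

test_that("reference-covered reads partition to their truth bins", {
  # error-free study-condition sample; agreement must be near-perfect
  cfg <- sim_config(seed = 21L, error_rate = 0, reads_per_sample = 4000L)
  p <- generate_reference_panel(cfg)
  rd <- simulate_sample_reads(p, "Sa", "Pm", 1, cfg)
  tiers <- tier_spec(p$rrna, p$s16, culture_reference(p, "Sa"),
                     host_reference(p))
  pr <- partition_reads(rd, tiers)
  tx <- p$transcripts
  covered_tx <- tx$transcript_id[!tx$novel]
  covered <- rd$truth_bin %in% c("rRNA", "16S") |
    (rd$truth_transcript %in% covered_tx)
  expected <- c(rRNA = "rRNA", `16S` = "16S", fungal = "symbiont",
                host = "host")[rd$truth_bin]
  agree <- pr$assignments$bin[covered] == expected[covered]
  expect_gte(mean(agree), 0.99)
})
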