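make_de <- function(contigs, calls) {
  structure(data.frame(contig = contigs, call = calls,
                       stringsAsFactors = FALSE),
            class = c("de_result", "data.frame"))
}

test_that("upregulated_set extracts up calls only", {
  de <- make_de(paste0("g", 1:5), c("up", "down", "up", "ns", "up"))
  expect_setequal(upregulated_set(de), c("g1", "g3", "g5"))
  expect_length(upregulated_set(make_de("g1", "ns")), 0)
})

test_that("tightening thresholds never grows the upregulated set", {
  set.seed(30)
  m <- matrix(rpois(40 * 6, 100), 40, 6,
              dimnames = list(paste0("g", 1:40),
                              c(paste0("a", 1:3), paste0("b", 1:3))))
  m[1:8, 4:6] <- rpois(24, 100 * 6)
  loose <- differential(m, paste0("a", 1:3), paste0("b", 1:3),
                        de_params(p_threshold = 0.05, fdr = 0.2,
                                  lfc_threshold = 1))
  tight <- differential(m, paste0("a", 1:3), paste0("b", 1:3),
                        de_params(p_threshold = 0.01, fdr = 0.05,
                                  lfc_threshold = 2))
  expect_true(all(upregulated_set(tight) %in% upregulated_set(loose)))
})

test_that("homology clustering links cross-species proteins above threshold", {
  set.seed(31)
  shared <- rand_prot_str(120)
  sets <- list(sp1 = c("x1", "x2"), sp2 = c("y1"), sp3 = c("z1"))
  proteins <- list(sp1 = c(x1 = shared, x2 = rand_prot_str(120)),
                   sp2 = c(y1 = shared),
                   sp3 = c(z1 = rand_prot_str(120)))
  cl <- homology_clusters(sets, proteins)
  m <- cl$membership
  expect_equal(m$cluster[m$contig == "x1"], m$cluster[m$contig == "y1"])
  expect_false(m$cluster[m$contig == "x2"] %in%
                 m$cluster[m$contig %in% c("x1", "y1")])
  # no cross-species similarity anywhere -> all singletons
  cl2 <- homology_clusters(
    list(sp1 = "a", sp2 = "b"),
    list(sp1 = c(a = rand_prot_str(100)), sp2 = c(b = rand_prot_str(100))))
  expect_equal(length(unique(cl2$membership$cluster)), 2)
  # contig with no ORF -> flagged singleton
  cl3 <- homology_clusters(list(sp1 = "a", sp2 = "b"),
                           list(sp1 = c(a = NA_character_),
                                sp2 = c(b = shared)))
  expect_true(cl3$membership$no_orf[cl3$membership$contig == "a"])
})

test_that("transitive chains form one component (A~B, B~C, A!~C)", {
  set.seed(32)
  base <- rand_prot_str(150)
  ab <- strsplit(base, "")[[1]]
  # B shares its first half with A and its second half with C; A and C are
  # unrelated, so only the chain links them
  a_prot <- paste0(paste(ab[1:75], collapse = ""), rand_prot_str(75))
  c_prot <- paste0(rand_prot_str(75), paste(ab[76:150], collapse = ""))
  sets <- list(A = "ga", B = "gb", C = "gc")
  proteins <- list(A = c(ga = a_prot), B = c(gb = base), C = c(gc = c_prot))
  cl <- homology_clusters(sets, proteins,
                          align_params(min_identity = 0.9, min_coverage = 0.4))
  m <- cl$membership
  expect_equal(length(unique(m$cluster)), 1)
  # cross-check the component structure with the brute-force oracle
  edges <- rbind(c(which(m$contig == "ga"), which(m$contig == "gb")),
                 c(which(m$contig == "gb"), which(m$contig == "gc")))
  oracle <- cc_oracle(3, edges)
  expect_equal(length(unique(oracle)), length(unique(m$cluster)))
})

test_that("derive_sets matches exhaustive enumeration on random instances", {
  set.seed(33)
  for (rep_i in 1:15) {
    n_sp <- sample(2:4, 1)
    species <- paste0("S", seq_len(n_sp))
    hosts <- c("H1", "H2")
    comp <- matrix(sample(c("compatible", "incompatible"), n_sp * 2,
                          replace = TRUE),
                   n_sp, 2, dimnames = list(species, hosts))
    # ensure each label occurs somewhere to exercise both quantifiers
    comp[1, 1] <- "compatible"; comp[n_sp, 2] <- "incompatible"
    design <- design_matrix(comp)
    genes_per_sp <- 5
    membership <- do.call(rbind, lapply(species, function(sp)
      data.frame(species = sp, contig = paste0(sp, "_g", 1:genes_per_sp),
                 stringsAsFactors = FALSE)))
    membership$cluster <- sample(1:6, nrow(membership), replace = TRUE)
    membership$no_orf <- FALSE
    clusters <- structure(list(membership = membership),
                          class = "homology_clusters")
    pair_sets <- list()
    for (sp in species) for (h in hosts) {
      pool <- membership$contig[membership$species == sp]
      pair_sets[[paste(sp, h, sep = "|")]] <-
        sample(pool, sample(0:4, 1))
    }
    got <- suppressWarnings(derive_sets(clusters, design, pair_sets))
    want <- suppressWarnings(derive_sets_oracle(membership, design, pair_sets))
    expect_setequal(unique(got$common_compatible$cluster),
                    want$common_compatible)
    expect_setequal(unique(got$common_incompatible$cluster),
                    want$common_incompatible)
    got_u <- paste(got$unique$symbiont, got$unique$host, got$unique$contig)
    want_u <- if (nrow(want$unique)) paste(want$unique[, 1], want$unique[, 2],
                                           want$unique[, 3]) else character()
    expect_setequal(got_u, want_u)
  }
})

test_that("common members and unique members are disjoint per species", {
  set.seed(34)
  comp <- matrix(c("compatible", "compatible", "incompatible", "compatible"),
                 2, 2, dimnames = list(c("S1", "S2"), c("H1", "H2")))
  design <- design_matrix(comp)
  membership <- data.frame(
    species = c("S1", "S1", "S2", "S2"),
    contig = c("a1", "a2", "b1", "b2"),
    cluster = c(1, 2, 1, 3), no_orf = FALSE, stringsAsFactors = FALSE)
  clusters <- structure(list(membership = membership),
                        class = "homology_clusters")
  pair_sets <- list("S1|H1" = c("a1", "a2"), "S1|H2" = character(),
                    "S2|H1" = character(), "S2|H2" = c("b1", "b2"))
  sets <- suppressWarnings(derive_sets(clusters, design, pair_sets))
  common_members <- sets$common_compatible$contig
  expect_length(intersect(common_members, sets$unique$contig), 0)
})

test_that("venn regions count inclusion-exclusion cells", {
  v <- venn_counts(list(A = c(1, 2), B = c(2, 3)))
  expect_equal(v$count[v$region == "A"], 1L)
  expect_equal(v$count[v$region == "B"], 1L)
  expect_equal(v$count[v$region == "A&B"], 1L)
  # identical sets: all mass in the intersection
  v2 <- venn_counts(list(A = 1:4, B = 1:4, C = 1:4))
  expect_equal(v2$count[v2$region == "A&B&C"], 4L)
  expect_true(all(v2$count[v2$region != "A&B&C"] == 0L))
  # disjoint sets
  v3 <- venn_counts(list(A = 1:2, B = 3:4))
  expect_equal(v3$count[v3$region == "A&B"], 0L)
  expect_error(venn_counts(list(A = 1)), "at least 2")
  expect_error(venn_counts(setNames(replicate(7, 1:2, simplify = FALSE),
                                    letters[1:7])), "unsupported|6")
})
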