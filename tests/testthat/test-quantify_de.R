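test_that("read counting increments unique best hits and tallies ties", {
  set.seed(20)
  a <- rand_dna_str(300); b <- rand_dna_str(300)
  universe <- c(A = a, B = b, Bdup = b)  # B and Bdup are identical
  reads <- list(s1 = c(substr(a, 11, 110), substr(a, 51, 150),
                       substr(a, 101, 200),    # 3 unique to A
                       substr(b, 11, 110)))    # tied between B and Bdup
  cm <- count_reads(reads, universe)
  expect_equal(unname(cm$counts["A", "s1"]), 3L)
  expect_equal(unname(cm$counts["B", "s1"]), 0L)
  expect_equal(unname(cm$ambiguous["s1"]), 1L)
  # no reads -> zero matrix
  cm0 <- count_reads(list(s1 = character()), universe)
  expect_true(all(cm0$counts == 0))
})

test_that("size factors implement median-of-ratios", {
  m <- matrix(c(10, 20, 10, 20), 2, dimnames = list(c("g1", "g2"),
                                                    c("s1", "s2")))
  expect_equal(unname(size_factors(m)), c(1, 1))
  m2 <- matrix(c(10, 100, 20, 200), 2,
               dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_equal(unname(size_factors(m2)), c(1 / sqrt(2), sqrt(2)))
  # single sample
  m3 <- matrix(5:6, 2, 1, dimnames = list(c("g1", "g2"), "s1"))
  expect_equal(unname(size_factors(m3)), 1)
  # genes with zeros are excluded from the reference; all-zero fails
  m4 <- matrix(c(0, 3, 5, 0), 2, dimnames = list(c("g1", "g2"),
                                                 c("s1", "s2")))
  expect_error(size_factors(m4), "normalization undefined|pseudocount")
})

test_that("scaling one sample scales its size factor proportionally", {
  # the geometric-mean reference rescales globally when a sample is scaled,
  # so the invariance is on factor ratios: sample 3's factor grows by c
  # relative to every other sample's
  set.seed(21)
  m <- matrix(rpois(60, 50) + 1, 10, 6,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
  sf <- size_factors(m)
  m2 <- m; m2[, 3] <- m2[, 3] * 4L
  sf2 <- size_factors(m2)
  rel <- (sf2 / sf) / (sf2[1] / sf[1])
  expect_equal(unname(rel[3]), 4, tolerance = 1e-9)
  expect_equal(unname(rel[-3]), rep(1, 5), tolerance = 1e-9)
  # normalized counts are unchanged for the unscaled samples
  expect_equal(normalize_counts(m2, sf2)[, -3] / normalize_counts(m, sf)[, -3],
               matrix(sf[1] / sf2[1], 10, 5,
                      dimnames = dimnames(m[, -3])), tolerance = 1e-9)
})

test_that("size factors agree with the reference implementation", {
  set.seed(22)
  # odd contig count: the ratio-space and log-space medians coincide exactly
  m <- matrix(rpois(210, 80) + 1, 21, 10,
              dimnames = list(paste0("g", 1:21), paste0("s", 1:10)))
  expect_equal(unname(size_factors(m)),
               unname(DESeq2::estimateSizeFactorsForMatrix(m)),
               tolerance = 1e-8)
})

test_that("welch_t reproduces the textbook statistic and handles degeneracy", {
  wt <- welch_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(wt$t, -3.674, tolerance = 1e-3)
  expect_equal(wt$df, 4)
  # identical groups
  expect_equal(welch_t(c(2, 2), c(2, 2)), list(t = 0, df = 2, p = 1))
  # zero-variance unequal groups -> p -> 0
  wt2 <- welch_t(c(2, 2), c(5, 5))
  expect_true(is.infinite(wt2$t) && wt2$p == 0)
  expect_error(welch_t(1, c(1, 2)), ">= 2")
  # agreement with stats::t.test and the hand formula on random draws
  set.seed(23)
  for (i in 1:20) {
    a <- rnorm(sample(3:8, 1)); b <- rnorm(sample(3:8, 1), mean = 0.5)
    wt <- welch_t(a, b)
    tt <- t.test(a, b)
    expect_equal(wt$t, unname(tt$statistic), tolerance = 1e-10)
    expect_equal(wt$df, unname(tt$parameter), tolerance = 1e-10)
    expect_equal(wt$p, tt$p.value, tolerance = 1e-10)
    or <- welch_oracle(a, b)
    expect_equal(wt$t, or$t, tolerance = 1e-10)
    expect_equal(wt$df, or$df, tolerance = 1e-10)
  }
})

test_that("bh_adjust equals the step-up definition and p.adjust", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.5)), c(0.04, 0.04, 0.04, 0.5))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(numeric(0)), numeric(0))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(24)
  for (i in 1:1000) {
    p <- runif(sample(1:50, 1))
    q <- bh_adjust(p)
    expect_equal(q, bh_oracle(p), tolerance = 1e-12)
    expect_equal(q, p.adjust(p, "BH"), tolerance = 1e-12)
  }
})

test_that("differential calls planted changes and respects the gates", {
  set.seed(25)
  n_a <- 4; n_b <- 3
  base <- rpois(50 * (n_a + n_b), 200)
  m <- matrix(base, 50, n_a + n_b,
              dimnames = list(paste0("g", 1:50),
                              c(paste0("a", 1:n_a), paste0("b", 1:n_b))))
  m[1, (n_a + 1):(n_a + n_b)] <- rpois(n_b, 200 * 8)   # planted 8-fold up
  m[2, ] <- 0                                          # untested
  de <- differential(m, paste0("a", 1:n_a), paste0("b", 1:n_b))
  expect_equal(de$call[1], "up")
  expect_equal(de$call[2], "untested")
  expect_true(all(de$call[-c(1, 2)] %in% c("ns", "down")))
  expect_true(all(is.finite(de$log2fc[de$call != "untested"])))
  # identical counts across groups -> ns with log2fc 0
  m2 <- matrix(100, 10, 4, dimnames = list(paste0("g", 1:10),
                                           c("a1", "a2", "b1", "b2")))
  de2 <- differential(m2, c("a1", "a2"), c("b1", "b2"))
  expect_true(all(de2$call == "ns"))
  expect_true(all(de2$log2fc == 0))
  # zero counts in one condition still give finite log2fc via pseudocount
  m3 <- m2; m3[1, c("b1", "b2")] <- 0
  de3 <- differential(m3, c("a1", "a2"), c("b1", "b2"))
  expect_true(is.finite(de3$log2fc[1]))
  expect_error(differential(m2, "a1", c("b1", "b2")), "replicates")
})

test_that("null data keeps the q<0.05 call rate controlled", {
  # no planted effects: identical expected expression in both groups
  set.seed(26)
  n_genes <- 200
  frac <- replicate(10, {
    m <- matrix(rpois(n_genes * 7, 150), n_genes, 7,
                dimnames = list(paste0("g", 1:n_genes),
                                c(paste0("a", 1:4), paste0("b", 1:3))))
    de <- differential(m, paste0("a", 1:4), paste0("b", 1:3))
    mean(de$q < 0.05, na.rm = TRUE)
  })
  se <- sqrt(0.05 * 0.95 / n_genes)
  expect_lte(mean(frac), 0.05 + 2 * se)
})
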