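# Per-contig read counting, median-of-ratios size-factor normalization, and
# the differential-expression gating used throughout the analysis: Welch
# t-test (P < 0.01), >= 2-fold change, Benjamini-Hochberg FDR 5%.

#' Count uniquely best-mapped reads per contig
#'
#' Maps each sample's reads against the contig universe; a read increments
#' its best contig's count only when that best placement is unique across
#' contigs (fewest mismatches at a single reference). Reads tied across
#' several contigs are dropped and tallied as ambiguous.
#'
#' @param reads_by_sample named list (sample id -> read-set data.frame or
#'   character vector of sequences).
#' @param universe named character vector of contig sequences.
#' @param params an [align_params()].
#' @return list of class `count_matrix`: integer matrix `counts` (contigs x
#'   samples), `ambiguous` (per-sample tally), `unmapped` (per-sample tally).
#' @export
count_reads <- function(reads_by_sample, universe, params = align_params()) {
  stopifnot(is.list(reads_by_sample), !is.null(names(reads_by_sample)))
  samples <- names(reads_by_sample)
  counts <- matrix(0L, nrow = length(universe), ncol = length(samples),
                   dimnames = list(names(universe), samples))
  ambiguous <- setNames(integer(length(samples)), samples)
  unmapped <- setNames(integer(length(samples)), samples)
  if (length(universe)) {
    idx <- build_kmer_index(universe, params$k)
    for (s in samples) {
      rs <- reads_by_sample[[s]]
      seqs <- if (is.data.frame(rs)) rs$seq else as.character(rs)
      if (length(seqs) == 0) next
      hits <- map_reads(seqs, idx, params)
      ok <- !is.na(hits$ref) & hits$n_best_refs == 1L
      ambiguous[s] <- sum(!is.na(hits$ref) & hits$n_best_refs > 1L)
      unmapped[s] <- sum(is.na(hits$ref))
      tab <- table(hits$ref[ok])
      counts[names(tab), s] <- counts[names(tab), s] + as.integer(tab)
    }
  }
  structure(list(counts = counts, ambiguous = ambiguous, unmapped = unmapped),
            class = "count_matrix")
}

#' Median-of-ratios size factors
#'
#' For each contig with nonzero counts in every sample, the reference is the
#' geometric mean of its counts across samples; a sample's size factor is the
#' median over those contigs of count / reference.
#'
#' @param counts integer matrix (contigs x samples) or a `count_matrix`.
#' @return named numeric vector of positive size factors.
#' @export
size_factors <- function(counts) {
  if (inherits(counts, "count_matrix")) counts <- counts$counts
  counts <- as.matrix(counts)
  if (ncol(counts) == 1) return(setNames(1, colnames(counts)))
  all_nonzero <- rowSums(counts == 0) == 0
  if (!any(all_nonzero))
    stop("no contig has nonzero counts in every sample; ",
         "normalization undefined (consider a pseudocount mode)")
  ref <- exp(rowMeans(log(counts[all_nonzero, , drop = FALSE])))
  sf <- apply(counts[all_nonzero, , drop = FALSE], 2,
              function(col) median(col / ref))
  if (any(sf <= 0)) stop("non-positive size factor computed")
  sf
}

#' Normalize counts by size factors
#'
#' @param counts matrix or `count_matrix`.
#' @param sf size factors; computed if missing.
#' @return numeric matrix of normalized counts.
#' @export
normalize_counts <- function(counts, sf = NULL) {
  if (inherits(counts, "count_matrix")) counts <- counts$counts
  if (is.null(sf)) sf <- size_factors(counts)
  sweep(counts, 2, sf, "/")
}

#' Welch two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and a two-sided p value. Zero-variance degenerate inputs are handled:
#' equal constant groups give t = 0, p = 1; unequal constant groups give
#' t = +/-Inf, p = 0.
#'
#' @param a,b numeric vectors (each length >= 2).
#' @return list with `t`, `df`, `p`.
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs >= 2 observations")
  ma <- mean(a); mb <- mean(b)
  va <- var(a); vb <- var(b)
  na <- length(a); nb <- length(b)
  se2 <- va / na + vb / nb
  if (se2 == 0) {
    if (ma == mb) return(list(t = 0, df = na + nb - 2, p = 1))
    return(list(t = sign(ma - mb) * Inf, df = na + nb - 2, p = 0))
  }
  t <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Benjamini-Hochberg step-up adjusted q values
#'
#' `q(i) = min over j >= i of p(j) * m / j` on the sorted p values, mapped
#' back to the original order and capped at 1.
#'
#' @param p numeric vector of p values in `[0, 1]`.
#' @return numeric vector of adjusted q values, same order as input.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p values must lie in [0, 1] and be non-missing")
  m <- length(p)
  ord <- order(p)
  q_sorted <- p[ord] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

#' Differential-expression parameters
#'
#' @param p_threshold Welch-test p gate (default 0.01).
#' @param lfc_threshold log2 fold-change gate (default 1, i.e. 2-fold).
#' @param fdr Benjamini-Hochberg FDR level (default 0.05).
#' @param pseudocount added to normalized means for fold change only.
#' @param use_p_gate,use_q_gate flags to disable either significance gate.
#' @return list of class `de_params`.
#' @export
de_params <- function(p_threshold = 0.01, lfc_threshold = 1, fdr = 0.05,
                      pseudocount = 1, use_p_gate = TRUE, use_q_gate = TRUE) {
  if (p_threshold <= 0 || lfc_threshold <= 0 || pseudocount <= 0)
    stop("thresholds and pseudocount must be positive")
  if (fdr <= 0 || fdr >= 1) stop("fdr must lie in (0, 1)")
  structure(list(p_threshold = p_threshold, lfc_threshold = lfc_threshold,
                 fdr = fdr, pseudocount = pseudocount,
                 use_p_gate = use_p_gate, use_q_gate = use_q_gate),
            class = "de_params")
}

#' Differential expression between two sample groups
#'
#' Counts are size-factor normalized (factors estimated over the two groups
#' jointly); per contig, a Welch t-test compares replicate expression values
#' and the log2 fold change is computed on group means with a pseudocount. A
#' contig is called `up` (higher in `group_b`, the treatment) when log2FC >=
#' `lfc_threshold` and it passes the enabled p and q gates; `down`
#' symmetrically; otherwise `ns`. Contigs with zero counts everywhere are
#' reported as `untested`.
#'
#' By default the t-test runs on `log2(normalized + pseudocount)` values:
#' the log transform stabilizes the count-scale variance so the two groups
#' contribute comparably to the Welch degrees of freedom, which otherwise
#' degenerate towards 1 with few replicates whenever one group's variance
#' dominates (making stringent p thresholds unreachable regardless of
#' depth). `test_scale = "observed"` tests raw normalized counts instead.
#'
#' @param counts matrix or `count_matrix` (contigs x samples).
#' @param group_a,group_b character vectors of sample ids (baseline /
#'   treatment); each needs >= 2 replicates.
#' @param params a [de_params()].
#' @param sf optional externally supplied size factors.
#' @param test_scale `"log2"` (default) or `"observed"`.
#' @return data.frame of class `de_result`: `contig`, `base_mean_a`,
#'   `base_mean_b`, `log2fc`, `t`, `p`, `q`, `call`.
#' @export
differential <- function(counts, group_a, group_b, params = de_params(),
                         sf = NULL, test_scale = c("log2", "observed")) {
  test_scale <- match.arg(test_scale)
  if (inherits(counts, "count_matrix")) counts <- counts$counts
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs >= 2 replicates (got ", length(group_a), " vs ",
         length(group_b), ")")
  missing <- setdiff(c(group_a, group_b), colnames(counts))
  if (length(missing)) stop("samples absent from count matrix: ",
                            paste(missing, collapse = ", "))
  sub <- counts[, c(group_a, group_b), drop = FALSE]
  norm <- normalize_counts(sub, sf)
  na_ <- norm[, group_a, drop = FALSE]
  nb_ <- norm[, group_b, drop = FALSE]
  tested <- rowSums(sub) > 0
  n <- nrow(sub)
  res <- data.frame(contig = rownames(sub),
                    base_mean_a = rowMeans(na_), base_mean_b = rowMeans(nb_),
                    log2fc = NA_real_, t = NA_real_, p = NA_real_,
                    q = NA_real_, call = "untested",
                    stringsAsFactors = FALSE)
  pc <- params$pseudocount
  res$log2fc <- log2((res$base_mean_b + pc) / (res$base_mean_a + pc))
  ta <- na_; tb <- nb_
  if (test_scale == "log2") {
    ta <- log2(na_ + pc)
    tb <- log2(nb_ + pc)
  }
  for (i in which(tested)) {
    wt <- welch_t(ta[i, ], tb[i, ])
    res$t[i] <- wt$t
    res$p[i] <- wt$p
  }
  res$q[tested] <- bh_adjust(res$p[tested])
  gate <- rep(TRUE, n)
  if (params$use_p_gate) gate <- gate & res$p < params$p_threshold
  if (params$use_q_gate) gate <- gate & res$q < params$fdr
  call <- ifelse(res$log2fc >= params$lfc_threshold & gate, "up",
                 ifelse(res$log2fc <= -params$lfc_threshold & gate, "down",
                        "ns"))
  res$call <- ifelse(tested, call, "untested")
  res$call[is.na(res$call)] <- "ns"
  class(res) <- c("de_result", class(res))
  res
}
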