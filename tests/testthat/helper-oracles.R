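# Independent brute-force oracles used to cross-check the implementation.

# exhaustive Smith-Waterman dynamic program (score only, linear gap)
sw_oracle <- function(a, b, mat, gap) {
  A <- strsplit(toupper(a), "")[[1]]
  B <- strsplit(toupper(b), "")[[1]]
  if (!length(A) || !length(B)) return(0)
  H <- matrix(0, length(A) + 1, length(B) + 1)
  best <- 0
  for (i in seq_along(A)) {
    for (j in seq_along(B)) {
      H[i + 1, j + 1] <- max(0,
                             H[i, j] + mat[A[i], B[j]],
                             H[i, j + 1] - gap,
                             H[i + 1, j] - gap)
      best <- max(best, H[i + 1, j + 1])
    }
  }
  best
}

# Benjamini-Hochberg step-up straight from the definition:
# on sorted p, q(i) = min_{j >= i} p(j) * m / j, capped at 1
bh_oracle <- function(p) {
  m <- length(p)
  if (m == 0) return(numeric(0))
  ord <- order(p)
  ps <- p[ord]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(ps[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[ord] <- q
  out
}

# connected components by repeated neighbour expansion over an edge list
cc_oracle <- function(n, edges) {
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    if (length(edges)) {
      for (r in seq_len(nrow(edges))) {
        i <- edges[r, 1]; j <- edges[r, 2]
        m <- min(comp[i], comp[j])
        if (comp[i] != m || comp[j] != m) {
          comp[comp == comp[i] | comp == comp[j]] <- m
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

# derive common/unique sets by direct enumeration over the definitions
derive_sets_oracle <- function(membership, design, pair_sets) {
  pair_keys <- strsplit(names(pair_sets), "|", fixed = TRUE)
  sym <- vapply(pair_keys, `[[`, "", 1)
  hst <- vapply(pair_keys, `[[`, "", 2)
  lab <- design$compatibility[cbind(sym, hst)]
  up_union <- function(species, labels = c("compatible", "incompatible")) {
    unique(unlist(pair_sets[sym == species & lab %in% labels]))
  }
  common <- function(label) {
    species_with <- design$symbionts[apply(design$compatibility == label, 1, any)]
    keep <- vapply(sort(unique(membership$cluster)), function(cl) {
      mem <- membership[membership$cluster == cl, ]
      all(vapply(species_with, function(sp)
        any(mem$contig[mem$species == sp] %in% up_union(sp, label)), TRUE))
    }, TRUE)
    sort(unique(membership$cluster))[keep]
  }
  uniq <- list()
  for (i in seq_along(pair_sets)) {
    for (ctg in pair_sets[[i]]) {
      row <- membership[membership$species == sym[i] &
                          membership$contig == ctg, ]
      if (nrow(row) == 0) next
      mem <- membership[membership$cluster == row$cluster[1], ]
      other_up <- FALSE
      for (r in seq_len(nrow(mem))) {
        if (mem$species[r] == sym[i]) next
        if (mem$contig[r] %in% up_union(mem$species[r])) other_up <- TRUE
      }
      if (!other_up)
        uniq[[length(uniq) + 1]] <- c(sym[i], hst[i], ctg)
    }
  }
  list(common_compatible = common("compatible"),
       common_incompatible = common("incompatible"),
       unique = if (length(uniq)) do.call(rbind, uniq) else
         matrix(character(), ncol = 3))
}

# textbook Welch statistic
welch_oracle <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df)
}

rand_dna_str <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                         replace = TRUE), collapse = "")

rand_prot_str <- function(n) paste(sample(c("A", "R", "N", "D", "C", "Q", "E",
                                            "G", "H", "I", "L", "K", "M", "F",
                                            "P", "S", "T", "W", "Y", "V"), n,
                                          replace = TRUE), collapse = "")
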