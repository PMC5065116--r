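# Cross-pair comparative logic: per-pair upregulated gene sets, cross-species
# homology clustering of their translated products, and derivation of common
# (shared across all species) and unique (single-pair) gene sets.

#' Extract the upregulated gene set of one pair's contrast
#'
#' @param de a `de_result` from [differential()].
#' @return character vector of contig ids with call `up`.
#' @export
upregulated_set <- function(de) {
  stopifnot(inherits(de, "de_result") ||
              all(c("contig", "call") %in% names(de)))
  de$contig[de$call == "up"]
}

#' Longest ORF translation per contig
#'
#' Scans all six frames and returns the longest ORF protein for each contig.
#' Complete (start-to-stop) ORFs are preferred over partial ones running
#' into the contig end: an open-ended readthrough frame can spuriously
#' outgrow the true coding frame by a few residues. Contigs with no ORF of
#' at least `min_len_aa` return `NA` (flagged singletons downstream).
#'
#' @param seqs named character vector of contig nucleotide sequences.
#' @param min_len_aa minimum ORF length in residues.
#' @return named character vector of proteins (`NA` where none).
#' @export
longest_orfs <- function(seqs, min_len_aa = 30L) {
  vapply(seqs, function(s) {
    orfs <- extract_orfs(s, min_len_aa = min_len_aa)
    if (nrow(orfs) == 0) return(NA_character_)
    if (any(!orfs$partial)) orfs <- orfs[!orfs$partial, , drop = FALSE]
    orfs$protein[which.max(nchar(orfs$protein))]
  }, "", USE.NAMES = TRUE)
}

#' Cross-species homology clustering of upregulated genes
#'
#' Builds a graph whose vertices are (species, contig) members of the
#' supplied per-species gene sets; edges connect members of *different*
#' species whose longest-ORF proteins align with identity >=
#' `params$min_identity` over coverage >= `params$min_coverage` of the
#' shorter protein. Clusters are the connected components (single-linkage).
#'
#' @param sets named list (species -> character vector of contig ids).
#' @param proteins named list (species -> named character vector of
#'   longest-ORF proteins for that species' contigs).
#' @param params an [align_params()].
#' @return object of class `homology_clusters`: data.frame `membership`
#'   (`species`, `contig`, `cluster`, `no_orf` flag).
#' @export
homology_clusters <- function(sets, proteins, params = align_params()) {
  members <- do.call(rbind, lapply(names(sets), function(sp) {
    if (length(sets[[sp]]) == 0) return(NULL)
    data.frame(species = sp, contig = sets[[sp]], stringsAsFactors = FALSE)
  }))
  if (is.null(members) || nrow(members) == 0) {
    return(structure(list(membership = data.frame(
      species = character(), contig = character(), cluster = integer(),
      no_orf = logical(), stringsAsFactors = FALSE)),
      class = "homology_clusters"))
  }
  key <- paste(members$species, members$contig, sep = "::")
  prot <- vapply(seq_len(nrow(members)), function(i) {
    p <- proteins[[members$species[i]]]
    if (is.null(p) || !(members$contig[i] %in% names(p))) NA_character_
    else unname(p[members$contig[i]])
  }, "")
  no_orf <- is.na(prot)
  mat <- score_matrix(params$score_matrix)

  n <- nrow(members)
  edges <- integer(0)
  if (n > 1) {
    alpha <- paste(rownames(mat), collapse = "")
    for (i in seq_len(n - 1)) {
      if (no_orf[i]) next
      js <- seq((i + 1), n)
      js <- js[!no_orf[js] & members$species[js] != members$species[i]]
      if (!length(js)) next
      # score-only prefilter: an edge needs identity*min_len worth of score,
      # so anything scoring below a weak floor cannot pass the full check
      sc <- .cpp_sw_score_batch(prot[i], prot[js], alpha, mat,
                                params$protein_gap)
      for (jj in js[sc > 0]) {
        sim <- protein_similarity(prot[i], prot[jj], mat, params$protein_gap)
        if (sim$identity >= params$min_identity &&
            sim$coverage >= params$min_coverage)
          edges <- c(edges, i, jj)
      }
    }
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)$membership
  membership <- data.frame(species = members$species, contig = members$contig,
                           cluster = as.integer(comp), no_orf = no_orf,
                           stringsAsFactors = FALSE)
  rownames(membership) <- NULL
  structure(list(membership = membership), class = "homology_clusters")
}

#' @export
print.homology_clusters <- function(x, ...) {
  m <- x$membership
  cat(sprintf("homology_clusters: %d members in %d cluster(s)\n",
              nrow(m), length(unique(m$cluster))))
  invisible(x)
}

#' Derive common and unique interactome gene sets
#'
#' A cluster is *common-compatible* when it has at least one member in the
#' compatible-upregulated set of every symbiont species that has a
#' compatible pairing in the design (likewise common-incompatible over
#' incompatible pairings; species lacking a pairing of that label are
#' excluded from the quantifier with a warning). A gene is *unique* to its
#' (symbiont, host) pair when it is upregulated there and its cluster
#' contains no other species' upregulated member.
#'
#' @param clusters a `homology_clusters` built over the union of all
#'   per-pair upregulated sets (per species).
#' @param design a `design_matrix`.
#' @param pair_sets named list keyed `"symbiont|host"` -> character vector
#'   of upregulated contig ids for that pair's contrast.
#' @return object of class `interactome_sets`: `common_compatible` and
#'   `common_incompatible` (data.frames of cluster id + members), `unique`
#'   (data.frame `symbiont`, `host`, `contig`).
#' @export
derive_sets <- function(clusters, design, pair_sets) {
  m <- clusters$membership
  pair_keys <- strsplit(names(pair_sets), "|", fixed = TRUE)
  pair_df <- data.frame(symbiont = vapply(pair_keys, `[[`, "", 1),
                        host = vapply(pair_keys, `[[`, "", 2),
                        stringsAsFactors = FALSE)
  pair_df$compatibility <- design$compatibility[cbind(pair_df$symbiont,
                                                      pair_df$host)]

  # per-species upregulated union, per label
  label_sets <- function(label) {
    keep <- which(pair_df$compatibility == label)
    sets <- list()
    for (i in keep) {
      sp <- pair_df$symbiont[i]
      sets[[sp]] <- union(sets[[sp]], pair_sets[[i]])
    }
    sets
  }

  common_for <- function(label) {
    species_with_label <- design$symbionts[
      apply(design$compatibility == label, 1, any)]
    absent <- setdiff(design$symbionts, species_with_label)
    if (length(absent))
      warning("species without any ", label, " pairing excluded from the ",
              label, " quantifier: ", paste(absent, collapse = ", "))
    sets <- label_sets(label)
    cl_ids <- sort(unique(m$cluster))
    hits <- vapply(cl_ids, function(cl) {
      mem <- m[m$cluster == cl, , drop = FALSE]
      all(vapply(species_with_label, function(sp)
        any(mem$contig[mem$species == sp] %in% sets[[sp]]), TRUE))
    }, TRUE)
    res <- m[m$cluster %in% cl_ids[hits], c("cluster", "species", "contig")]
    rownames(res) <- NULL
    res
  }

  common_compatible <- common_for("compatible")
  common_incompatible <- common_for("incompatible")

  # unique genes: upregulated in exactly this pair's species, with no other
  # species' upregulated member in the same cluster
  all_species_sets <- list()
  for (i in seq_len(nrow(pair_df))) {
    sp <- pair_df$symbiont[i]
    all_species_sets[[sp]] <- union(all_species_sets[[sp]], pair_sets[[i]])
  }
  uniq <- list()
  for (i in seq_len(nrow(pair_df))) {
    sp <- pair_df$symbiont[i]; h <- pair_df$host[i]
    for (ctg in pair_sets[[i]]) {
      row <- m[m$species == sp & m$contig == ctg, , drop = FALSE]
      if (nrow(row) == 0) next
      mem <- m[m$cluster == row$cluster[1], , drop = FALSE]
      others <- mem[mem$species != sp, , drop = FALSE]
      other_up <- any(vapply(seq_len(nrow(others)), function(j)
        others$contig[j] %in% all_species_sets[[others$species[j]]], TRUE))
      if (!other_up)
        uniq[[length(uniq) + 1]] <- data.frame(symbiont = sp, host = h,
                                               contig = ctg,
                                               stringsAsFactors = FALSE)
    }
  }
  unique_df <- if (length(uniq)) do.call(rbind, uniq)
               else data.frame(symbiont = character(), host = character(),
                               contig = character(), stringsAsFactors = FALSE)
  structure(list(common_compatible = common_compatible,
                 common_incompatible = common_incompatible,
                 unique = unique_df),
            class = "interactome_sets")
}

#' @export
print.interactome_sets <- function(x, ...) {
  cat(sprintf(paste0("interactome_sets: %d common-compatible cluster(s), ",
                     "%d common-incompatible cluster(s), %d unique gene(s)\n"),
              length(unique(x$common_compatible$cluster)),
              length(unique(x$common_incompatible$cluster)),
              nrow(x$unique)))
  invisible(x)
}

#' Venn region counts over cluster-mapped gene sets
#'
#' @param sets named list (2 to 6 sets) of ids (typically cluster ids).
#' @return data.frame with one row per non-empty inclusion-exclusion
#'   region: `region` (e.g. `"A&B"`) and `count`.
#' @export
venn_counts <- function(sets) {
  k <- length(sets)
  if (k < 2) stop("need at least 2 sets")
  if (k > 6) stop("more than 6 sets unsupported")
  ids <- unique(unlist(sets))
  memb <- vapply(sets, function(s) ids %in% s, logical(length(ids)))
  if (length(ids) == 1) memb <- matrix(memb, nrow = 1,
                                       dimnames = list(NULL, names(sets)))
  region <- apply(memb, 1, function(r) paste(names(sets)[r], collapse = "&"))
  combos <- unlist(lapply(seq_len(k), function(i)
    utils::combn(names(sets), i, paste, collapse = "&")))
  counts <- table(factor(region, levels = combos))
  data.frame(region = names(counts), count = as.integer(counts),
             stringsAsFactors = FALSE)
}
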