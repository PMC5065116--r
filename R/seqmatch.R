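# Lightweight sequence-matching engine: k-mer indexed ungapped read mapping,
# Smith-Waterman local protein alignment, six-frame translation. These stand
# in for the production aligners (bowtie / BLASTX) at desk scale; thresholds
# are exposed because the corresponding production settings are unstated.

#' Alignment parameter set
#'
#' @param k nucleotide seed k-mer size (odd, >= 11).
#' @param max_mm_frac maximum mismatch fraction for an accepted read mapping.
#' @param protein_gap linear gap penalty (positive) for protein alignment.
#' @param min_identity minimum protein identity for a homology call.
#' @param min_coverage minimum aligned coverage of the shorter protein.
#' @param score_matrix substitution matrix name (`"BLOSUM62"`, `"BLOSUM50"`)
#'   or a matrix as returned by [read_score_matrix()].
#' @return list of class `align_params`.
#' @export
align_params <- function(k = 21L, max_mm_frac = 0.05, protein_gap = 8,
                         min_identity = 0.35, min_coverage = 0.5,
                         score_matrix = "BLOSUM62") {
  k <- as.integer(k)
  if (k < 11L || k %% 2L == 0L) stop("k must be odd and >= 11")
  if (max_mm_frac < 0 || max_mm_frac > 1) stop("max_mm_frac must be in [0,1]")
  if (min_identity < 0 || min_identity > 1 || min_coverage < 0 || min_coverage > 1)
    stop("identity/coverage thresholds must be in [0,1]")
  structure(list(k = k, max_mm_frac = max_mm_frac, protein_gap = protein_gap,
                 min_identity = min_identity, min_coverage = min_coverage,
                 score_matrix = score_matrix),
            class = "align_params")
}

#' Build a k-mer index over reference sequences
#'
#' Every length-`k` substring of every reference (forward strand; reverse
#' strand queried via reverse complement) is indexed. k-mers spanning `N`
#' are excluded; references shorter than `k` are skipped with a warning.
#'
#' @param refs named character vector of reference sequences.
#' @param k k-mer size (<= 31).
#' @return object of class `kmer_index`.
#' @export
build_kmer_index <- function(refs, k = 21L) {
  k <- as.integer(k)
  if (length(refs) && is.null(names(refs))) stop("references must be named")
  short <- nchar(refs) < k
  if (any(short)) {
    warning(sum(short), " reference(s) shorter than k skipped: ",
            paste(head(names(refs)[short], 3), collapse = ", "))
  }
  ptr <- .cpp_build_index(names(refs), unname(toupper(refs)), k)
  structure(list(ptr = ptr, k = k, refs = refs), class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  cat(sprintf("kmer_index: k=%d over %d reference(s), %g indexed positions\n",
              x$k, length(x$refs), .cpp_index_size(x$ptr)))
  invisible(x)
}

#' Look up a k-mer in an index
#'
#' @param index a `kmer_index`.
#' @param kmer query of length `k`; reverse-strand occurrences are reported
#'   with strand `"-"`.
#' @return data.frame with `ref`, `offset` (0-based), `strand`.
#' @export
kmer_lookup <- function(index, kmer) {
  stopifnot(inherits(index, "kmer_index"))
  .cpp_index_lookup(index$ptr, toupper(kmer))
}

#' Map reads against a k-mer index (seed and ungapped extend)
#'
#' Seed k-mers are taken at non-overlapping offsets along the read (both
#' orientations); each seed hit implies a full-length ungapped placement,
#' scored by mismatch count (`N` never matches). The best placement (fewest
#' mismatches; ties broken by reference name, then offset, then `+` strand)
#' is reported; a read is unmapped when no placement has mismatch fraction
#' <= `max_mm_frac`.
#'
#' @param reads character vector of read sequences (names optional) or a
#'   read-set data.frame with columns `id`, `seq`.
#' @param index a `kmer_index`.
#' @param params an [align_params()] object.
#' @return data.frame with one row per read: `read`, `ref` (`NA` if
#'   unmapped), `strand`, `offset` (0-based), `mismatches`, `identity`,
#'   `n_best_refs` (distinct references tied at the best score).
#' @export
map_reads <- function(reads, index, params = align_params(k = index$k)) {
  stopifnot(inherits(index, "kmer_index"))
  if (is.data.frame(reads)) {
    ids <- reads$id; seqs <- reads$seq
  } else {
    seqs <- unname(reads)
    ids <- if (is.null(names(reads))) paste0("read", seq_along(reads)) else names(reads)
  }
  if (params$k != index$k) stop("params$k must match the index k")
  res <- .cpp_map_reads(index$ptr, toupper(seqs), params$max_mm_frac)
  cbind(data.frame(read = ids, stringsAsFactors = FALSE), res)
}

#' @rdname map_reads
#' @export
map_read <- function(reads, index, params = align_params(k = index$k)) {
  map_reads(reads, index, params)
}

# ---- protein alignment ------------------------------------------------------

#' Read a flat-text substitution score matrix
#'
#' NCBI-style format: optional `#` comment lines, a header row of residue
#' letters, then one row per residue with integer scores.
#'
#' @param path file path.
#' @return numeric matrix with residue dimnames.
#' @export
read_score_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  rows <- strsplit(trimws(lines[-1]), "\\s+")
  m <- t(vapply(rows, function(r) as.numeric(r[-1]), numeric(length(header))))
  rownames(m) <- vapply(rows, `[[`, "", 1)
  colnames(m) <- header
  m
}

#' Fetch a bundled substitution matrix by name
#'
#' @param name `"BLOSUM50"` or `"BLOSUM62"`, or a matrix (returned as-is).
#' @return numeric substitution matrix.
#' @export
score_matrix <- function(name = "BLOSUM62") {
  if (is.matrix(name)) return(name)
  path <- system.file("extdata", paste0(name, ".txt"), package = "symbiotrx")
  if (!nzchar(path)) stop("unknown score matrix: ", name)
  read_score_matrix(path)
}

#' Smith-Waterman local protein alignment (linear gap)
#'
#' Dynamic-program local alignment over the 20-letter alphabet (plus
#' ambiguity code `X`, which scores as `X` does in the substitution matrix
#' and never as an identity). The score is the maximum over all local
#' alignments and is never negative.
#'
#' @param a,b protein sequences.
#' @param matrix substitution matrix or its name (see [score_matrix()]).
#' @param gap positive linear gap penalty per gapped residue.
#' @return list with `score`, 1-based inclusive spans `a_start`,`a_end`,
#'   `b_start`,`b_end` (`NA` when the best local alignment is empty).
#' @export
local_protein_align <- function(a, b, matrix = "BLOSUM62", gap = 8) {
  m <- score_matrix(matrix)
  stopifnot(identical(rownames(m), colnames(m)))
  .cpp_sw_align(toupper(a), toupper(b), paste(rownames(m), collapse = ""),
                m, gap)
}

#' Identity and coverage of the best local alignment
#'
#' Convenience wrapper used by contig classification and homology
#' clustering: aligns, then reports the identity over the aligned span
#' (matches / alignment columns of the shorter span, ungapped approximation)
#' and the coverage of the shorter input.
#'
#' @inheritParams local_protein_align
#' @return list with `score`, `identity` (matches / alignment columns) and
#'   `coverage` (aligned span of the shorter input / its length).
#' @export
protein_similarity <- function(a, b, matrix = "BLOSUM62", gap = 8) {
  al <- local_protein_align(a, b, matrix, gap)
  if (al$score <= 0 || is.na(al$a_start))
    return(list(score = 0, identity = 0, coverage = 0))
  span <- if (nchar(a) <= nchar(b)) {
    (al$a_end - al$a_start + 1) / nchar(a)
  } else {
    (al$b_end - al$b_start + 1) / nchar(b)
  }
  list(score = al$score,
       identity = al$matches / al$align_len,
       coverage = span)
}

#' Batch local-alignment scores of one query against many subjects
#'
#' Score-only Smith-Waterman (no traceback), used to shortlist candidates
#' before the full alignment of [protein_similarity()].
#'
#' @param a query protein.
#' @param subjects character vector of subject proteins.
#' @inheritParams local_protein_align
#' @return numeric vector of best local scores, one per subject.
#' @export
sw_score_batch <- function(a, subjects, matrix = "BLOSUM62", gap = 8) {
  m <- score_matrix(matrix)
  .cpp_sw_score_batch(toupper(a), toupper(subjects),
                      paste(rownames(m), collapse = ""), m, gap)
}

# ---- translation ------------------------------------------------------------

#' Six-frame translation
#'
#' Translates frames +1..+3 of the sequence and -1..-3 of its reverse
#' complement with the standard codon table; stop codons are rendered `*`
#' and codons containing `N` as `X`. Sequences shorter than 3 nt return six
#' empty frames.
#'
#' @param seq nucleotide sequence.
#' @return named character vector of the six frames
#'   (`F1`,`F2`,`F3`,`R1`,`R2`,`R3`).
#' @export
six_frame_translate <- function(seq) {
  seq <- toupper(seq)
  if (nchar(seq) < 3)
    return(setNames(rep("", 6), c("F1", "F2", "F3", "R1", "R2", "R3")))
  rc <- revcomp(seq)
  one <- function(s, off) {
    sub <- substr(s, off, off + (nchar(s) - off + 1) %/% 3 * 3 - 1)
    if (nchar(sub) < 3) return("")
    as.character(Biostrings::translate(Biostrings::DNAString(sub),
                                       if.fuzzy.codon = "X"))
  }
  out <- c(one(seq, 1), one(seq, 2), one(seq, 3),
           one(rc, 1), one(rc, 2), one(rc, 3))
  setNames(out, c("F1", "F2", "F3", "R1", "R2", "R3"))
}
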