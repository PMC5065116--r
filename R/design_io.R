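# Experimental-design and sequence file handling: the symbiont x host
# compatibility grid, sample sheets, and FASTA/FASTQ read sets.

#' Construct a symbiont x host design matrix
#'
#' The design records, for every symbiont (fungal) species crossed with every
#' host (pine) species, whether the pairing forms functional ectomycorrhizae
#' (`"compatible"`) or fails to (`"incompatible"`), together with the number
#' of biological replicates sequenced for that pairing.
#'
#' @param compatibility character matrix with symbiont species as rows and
#'   host species as columns; entries `"compatible"` or `"incompatible"`.
#' @param replicates integer matrix of the same shape, or `NULL` to apply the
#'   default replicate structure (3 for compatible pairings, 2 for
#'   incompatible ones).
#' @return An object of class `design_matrix`.
#' @export
design_matrix <- function(compatibility, replicates = NULL) {
  if (!is.matrix(compatibility) || !is.character(compatibility))
    stop("`compatibility` must be a character matrix")
  symbionts <- rownames(compatibility)
  hosts <- colnames(compatibility)
  if (is.null(symbionts) || is.null(hosts))
    stop("compatibility matrix must have row (symbiont) and column (host) names")
  if (anyDuplicated(symbionts)) stop("duplicate symbiont species ids")
  if (anyDuplicated(hosts)) stop("duplicate host species ids")
  bad <- matrix(!(compatibility %in% c("compatible", "incompatible")),
                nrow(compatibility))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("invalid compatibility label %s at row '%s', column '%s'",
                 dQuote(compatibility[idx[1], idx[2]]),
                 symbionts[idx[1]], hosts[idx[2]]))
  }
  if (is.null(replicates)) {
    replicates <- ifelse(compatibility == "compatible", 3L, 2L)
    dimnames(replicates) <- dimnames(compatibility)
  }
  replicates <- matrix(as.integer(replicates), nrow(compatibility),
                       dimnames = dimnames(compatibility))
  if (any(is.na(replicates)) || any(replicates < 1L))
    stop("replicate counts must be integers >= 1")
  structure(list(symbionts = symbionts, hosts = hosts,
                 compatibility = compatibility, replicates = replicates),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("design_matrix: %d symbiont x %d host species pairings\n",
              length(x$symbionts), length(x$hosts)))
  print(x$compatibility)
  invisible(x)
}

#' Load a design matrix from a TSV grid
#'
#' The file is a tab-separated grid: the header row names the host species,
#' the first column names the symbiont species, and each cell is
#' `"compatible"` or `"incompatible"`. Lines starting with `#` are ignored.
#' Row and column order are preserved.
#'
#' @param path path to the TSV file.
#' @param replicates optional replicate-count matrix (see [design_matrix()]).
#' @return A `design_matrix`.
#' @export
load_design <- function(path, replicates = NULL) {
  if (!file.exists(path)) stop("design file not found: ", path)
  tab <- tryCatch(
    read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
               row.names = 1, check.names = FALSE, stringsAsFactors = FALSE),
    error = function(e) stop("malformed design TSV: ", conditionMessage(e)))
  if (nrow(tab) == 0 || ncol(tab) == 0)
    stop("design file has no symbiont rows or host columns")
  m <- as.matrix(tab)
  m[] <- trimws(tolower(m))
  design_matrix(m, replicates = replicates)
}

#' Count species pairings by compatibility status
#'
#' @param design a `design_matrix`.
#' @param status `"compatible"`, `"incompatible"`, or `"all"`.
#' @return Integer count of cells with the given label.
#' @export
count_pairs <- function(design, status = c("all", "compatible", "incompatible")) {
  stopifnot(inherits(design, "design_matrix"))
  status <- match.arg(status)
  if (status == "all") return(length(design$compatibility))
  sum(design$compatibility == status)
}

#' List the (symbiont, host) pairs of a design
#'
#' @param design a `design_matrix`.
#' @param status optional filter label.
#' @return data.frame with columns `symbiont`, `host`, `compatibility`,
#'   `replicates`.
#' @export
design_pairs <- function(design, status = c("all", "compatible", "incompatible")) {
  status <- match.arg(status)
  grid <- expand.grid(symbiont = design$symbionts, host = design$hosts,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$compatibility <- design$compatibility[cbind(grid$symbiont, grid$host)]
  grid$replicates <- design$replicates[cbind(grid$symbiont, grid$host)]
  if (status != "all") grid <- grid[grid$compatibility == status, , drop = FALSE]
  rownames(grid) <- NULL
  grid
}

#' Load and validate a sample sheet
#'
#' Columns: `sample_id`, `symbiont` (`none` for uninoculated controls),
#' `host`, `replicate`, `fastq`. Every referenced (symbiont, host) pair must
#' exist in the design.
#'
#' @param path TSV path.
#' @param design a `design_matrix` used for validation.
#' @return data.frame, one row per sample.
#' @export
load_sample_sheet <- function(path, design) {
  sheet <- read.delim(path, sep = "\t", comment.char = "#",
                      stringsAsFactors = FALSE)
  validate_sample_sheet(sheet, design)
}

#' @rdname load_sample_sheet
#' @param sheet an in-memory sample-sheet data.frame.
#' @export
validate_sample_sheet <- function(sheet, design) {
  need <- c("sample_id", "symbiont", "host", "replicate")
  missing <- setdiff(need, names(sheet))
  if (length(missing)) stop("sample sheet lacks columns: ",
                            paste(missing, collapse = ", "))
  if (anyDuplicated(sheet$sample_id))
    stop("duplicate sample_id in sample sheet")
  inoc <- !(sheet$symbiont %in% c("none", NA)) & sheet$host != "none"
  bad <- inoc & !(sheet$symbiont %in% design$symbionts &
                    sheet$host %in% design$hosts)
  if (any(bad))
    stop("sample(s) reference species absent from the design: ",
         paste(sheet$sample_id[bad], collapse = ", "))
  sheet
}

# ---- sequence I/O -----------------------------------------------------------

#' Read sequences from FASTA or FASTQ
#'
#' Lowercase bases are uppercased; records containing `*` or gap characters
#' are rejected. Record order is preserved.
#'
#' @param path input file (may be gzip-compressed).
#' @param format `"fasta"` or `"fastq"`; default guesses from the extension.
#' @return A read set: data.frame with columns `id`, `seq`, and `qual`
#'   (`NA` for FASTA input).
#' @export
read_seqs <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(sub("\\.gz$", "", basename(path)))
    format <- if (grepl("\\.(fq|fastq)$", ext)) "fastq" else "fasta"
  }
  if (format == "fasta") {
    ss <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                   error = function(e) stop("FASTA parse error in ", path, ": ",
                                            conditionMessage(e)))
    seqs <- toupper(as.character(ss))
    qual <- rep(NA_character_, length(seqs))
  } else {
    ss <- tryCatch(Biostrings::readDNAStringSet(path, format = "fastq",
                                                with.qualities = TRUE),
                   error = function(e) stop("FASTQ parse error in ", path, ": ",
                                            conditionMessage(e)))
    quals <- S4Vectors::mcols(ss)$qualities
    if (any(Biostrings::width(quals) != Biostrings::width(ss)))
      stop("FASTQ parse error in ", path, ": quality length != sequence length")
    seqs <- toupper(as.character(ss))
    qual <- as.character(quals)
  }
  if (any(nchar(seqs) == 0)) stop("empty sequence record in ", path)
  if (any(grepl("[*-]", seqs)))
    stop("sequences containing '*' or gap characters rejected: ", path)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("non-nucleotide characters in record(s): ",
         paste(head(names(ss)[bad], 3), collapse = ", "))
  data.frame(id = sub("\\s.*$", "", names(ss)), seq = unname(seqs),
             qual = unname(qual), stringsAsFactors = FALSE)
}

#' Write a read set to FASTA (80-column wrapped)
#'
#' @param reads read-set data.frame (`id`, `seq`) or a named character vector.
#' @param path output path.
#' @export
write_fasta <- function(reads, path) {
  reads <- as_read_df(reads)
  ss <- Biostrings::BStringSet(setNames(reads$seq, reads$id))
  Biostrings::writeXStringSet(ss, path, width = 80L, format = "fasta")
  invisible(path)
}

#' Write a read set to FASTQ (4-line records, Phred+33)
#'
#' Missing qualities are written as the maximum score `I`.
#'
#' @inheritParams write_fasta
#' @export
write_fastq <- function(reads, path) {
  reads <- as_read_df(reads)
  qual <- reads$qual
  if (is.null(qual)) qual <- rep(NA_character_, nrow(reads))
  qual[is.na(qual)] <- vapply(nchar(reads$seq[is.na(qual)]),
                              function(n) strrep("I", n), "")
  ss <- Biostrings::DNAStringSet(setNames(reads$seq, reads$id))
  q <- Biostrings::PhredQuality(Biostrings::BStringSet(qual))
  Biostrings::writeXStringSet(ss, path, format = "fastq",
                              qualities = Biostrings::BStringSet(q))
  invisible(path)
}

as_read_df <- function(reads) {
  if (is.character(reads)) {
    if (is.null(names(reads))) stop("sequence vector must be named")
    reads <- data.frame(id = names(reads), seq = unname(reads),
                        qual = NA_character_, stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(reads), all(c("id", "seq") %in% names(reads)))
  reads
}

#' Reverse-complement nucleotide sequences
#'
#' @param x character vector of A/C/G/T/N sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) .cpp_revcomp(x)

#' The published 4 x 3 Suillus-Pinus pairing design
#'
#' Loads the compatibility grid shipped with the package: four *Suillus*
#' species (Sa, Sg, Ss, Sd) crossed with three *Pinus* hosts (Pm, Ps, Pt);
#' the three white-pine specialists are incompatible with *P. taeda* only,
#' giving 9 compatible and 3 incompatible pairings.
#'
#' @return A `design_matrix`.
#' @export
suillus_pinus_design <- function() {
  load_design(system.file("extdata", "design_suillus_pinus.tsv",
                          package = "symbiotrx", mustWork = TRUE))
}
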