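# ORF extraction and small-secreted-protein (SSP) classification by four
# criteria: (a) < 300 residues, (b) N-terminal signal peptide, (c) no
# transmembrane domain, (d) no C-terminal ER-retention motif. Signal-peptide
# and TM detection use transparent published-scale heuristics (von
# Heijne-style (-3,-1) rule; Kyte-Doolittle hydropathy windows) with every
# threshold exposed; outputs of external predictors can be substituted via
# the `overrides` argument of [classify_ssp()].

#' Kyte-Doolittle hydropathy scale
#'
#' @return named numeric vector, one value per residue (X and * score 0).
#' @export
kd_scale <- function() {
  c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
    G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
    P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2,
    X = 0, `*` = 0)
}

#' Hydropathy / transmembrane-scan parameters
#'
#' @param window sliding-window width (odd).
#' @param tm_threshold minimum window-mean hydropathy calling a
#'   transmembrane segment.
#' @param n_mask N-terminal length excluded from TM calls when a signal
#'   peptide is predicted.
#' @param scale residue hydropathy scale.
#' @return list of class `hydropathy_params`.
#' @export
hydropathy_params <- function(window = 19L, tm_threshold = 1.6,
                              n_mask = 40L, scale = kd_scale()) {
  window <- as.integer(window)
  if (window %% 2L == 0L) stop("window must be odd")
  if (n_mask < 0) stop("n_mask must be >= 0")
  structure(list(window = window, tm_threshold = tm_threshold,
                 n_mask = as.integer(n_mask), scale = scale),
            class = "hydropathy_params")
}

#' Extract ORFs from a contig
#'
#' Scans all six frames for ATG-to-stop open reading frames (ORFs running
#' into the contig end are flagged partial). Coordinates are 0-based
#' half-open on the forward contig strand.
#'
#' @param seq contig nucleotide sequence.
#' @param min_len_aa minimum protein length (excluding the stop) reported.
#' @param start_required when `FALSE`, also report stop-to-stop fragments.
#' @return data.frame: `protein`, `frame` (`F1..F3`,`R1..R3`), `start`,
#'   `end` (forward-strand, 0-based half-open, including the stop codon when
#'   present), `partial`.
#' @export
extract_orfs <- function(seq, min_len_aa = 30L, start_required = TRUE) {
  seq <- toupper(seq)
  L <- nchar(seq)
  out <- list()
  frames <- six_frame_translate(seq)
  for (fi in seq_along(frames)) {
    fname <- names(frames)[fi]
    prot <- frames[[fi]]
    if (!nzchar(prot)) next
    off <- as.integer(substr(fname, 2, 2))  # frame offset 1..3
    rev <- startsWith(fname, "R")
    chars <- strsplit(prot, "")[[1]]
    n <- length(chars)
    i <- 1
    while (i <= n) {
      if (!start_required || chars[i] == "M") {
        j <- i
        while (j <= n && chars[j] != "*") j <- j + 1
        partial <- j > n
        aa_len <- (if (partial) n else j - 1) - i + 1
        if (aa_len >= min_len_aa) {
          protein <- paste(chars[i:(i + aa_len - 1)], collapse = "")
          # nt coordinates within the translated strand (1-based)
          nt_start <- off + (i - 1) * 3
          nt_end <- nt_start + aa_len * 3 - 1 + (if (partial) 0 else 3)
          if (!rev) {
            start0 <- nt_start - 1; end0 <- nt_end
          } else {
            start0 <- L - nt_end; end0 <- L - nt_start + 1
          }
          out[[length(out) + 1]] <- data.frame(
            protein = protein, frame = fname, start = start0, end = end0,
            partial = partial, stringsAsFactors = FALSE)
        }
        i <- if (start_required) i + 1 else j + 1
      } else i <- i + 1
    }
  }
  if (!length(out))
    return(data.frame(protein = character(), frame = character(),
                      start = integer(), end = integer(),
                      partial = logical(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  # nested ORFs sharing a stop: keep the longest per (frame, end)
  res <- res[order(res$frame, res$end, -nchar(res$protein)), ]
  res <- res[!duplicated(res[, c("frame", "end")]), ]
  rownames(res) <- NULL
  res
}

#' Predict an N-terminal signal peptide
#'
#' Heuristic composed of three requirements: an n-region with at least one
#' K/R in residues 1-5; an h-region of >= 7 contiguous residues within
#' positions 2-25 whose mean Kyte-Doolittle hydropathy is >= 2.0; and a
#' (-3,-1) cleavage site with small residues (A/G/S/C/T) at both positions,
#' with cleavage falling in positions 15-35. Proteins shorter than 15
#' residues are never called.
#'
#' @param protein amino-acid sequence.
#' @return list with `present` and `cleavage` (last residue of the signal
#'   peptide; `NA` when absent).
#' @export
predict_signal_peptide <- function(protein) {
  protein <- toupper(protein)
  n <- nchar(protein)
  if (n < 15) return(list(present = FALSE, cleavage = NA_integer_))
  chars <- strsplit(protein, "")[[1]]
  kd <- kd_scale()[chars]
  kd[is.na(kd)] <- 0

  if (!any(chars[1:min(5, n)] %in% c("K", "R")))
    return(list(present = FALSE, cleavage = NA_integer_))

  # h-region: any 7-residue window inside positions 2-25 with mean KD >= 2
  hi <- min(25, n)
  h_ok <- FALSE
  for (s in 2:(hi - 6)) {
    if (s + 6 > hi) break
    if (mean(kd[s:(s + 6)]) >= 2.0) { h_ok <- TRUE; break }
  }
  if (!h_ok) return(list(present = FALSE, cleavage = NA_integer_))

  small <- c("A", "G", "S", "C", "T")
  for (cl in 15:min(35, n)) {
    if (chars[cl] %in% small && chars[cl - 2] %in% small)
      return(list(present = TRUE, cleavage = cl))
  }
  list(present = FALSE, cleavage = NA_integer_)
}

#' Detect transmembrane segments by sliding-window hydropathy
#'
#' Reports maximal runs of window positions whose mean hydropathy is at
#' least the threshold. Windows overlapping a predicted signal peptide
#' (positions up to `sp_cleavage`) are excluded, so a signal peptide's
#' h-region is not miscalled as a membrane span.
#'
#' @param protein amino-acid sequence.
#' @param params a [hydropathy_params()].
#' @param sp_cleavage signal-peptide cleavage position or `NA`.
#' @return data.frame of segments: `start`, `end` (1-based residue span of
#'   the contributing windows), `max_mean`.
#' @export
detect_tm <- function(protein, params = hydropathy_params(),
                      sp_cleavage = NA) {
  protein <- toupper(protein)
  n <- nchar(protein)
  w <- params$window
  empty <- data.frame(start = integer(), end = integer(),
                      max_mean = numeric(), stringsAsFactors = FALSE)
  if (n < w) return(empty)
  chars <- strsplit(protein, "")[[1]]
  kd <- params$scale[chars]
  kd[is.na(kd)] <- 0
  means <- as.numeric(stats::filter(kd, rep(1 / w, w), sides = 2))
  centers <- seq_len(n)
  ok <- !is.na(means) & means >= params$tm_threshold
  if (!is.na(sp_cleavage)) {
    win_start <- centers - (w - 1) / 2
    ok <- ok & win_start > sp_cleavage
  }
  if (!any(ok)) return(empty)
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  keep <- which(runs$values)
  half <- (w - 1) / 2
  do.call(rbind, lapply(keep, function(r) {
    ctr <- starts[r]:ends[r]
    data.frame(start = max(1L, min(ctr) - half),
               end = min(n, max(ctr) + half),
               max_mean = max(means[ctr]), stringsAsFactors = FALSE)
  }))
}

#' Scan sequence motifs reported for SSP effectors
#'
#' ER retention: C-terminal `[KH]DEL`. N-glycosylation sequon: `N-X-[ST]`
#' with X != P, any position. RXLR: `R-X-L-R` within 60 residues after the
#' signal-peptide cleavage (or from position 2 when no signal peptide).
#' NLS: monopartite importin-alpha consensus `K(K/R)X(K/R)`.
#'
#' @param protein amino-acid sequence.
#' @param sp_cleavage cleavage position or `NA`.
#' @param rxlr_window search width after cleavage for RXLR.
#' @return list with `er_retention`, `n_glyc_sites` (integer positions),
#'   `rxlr`, `nls`.
#' @export
scan_motifs <- function(protein, sp_cleavage = NA, rxlr_window = 60L) {
  protein <- toupper(protein)
  n <- nchar(protein)
  er <- grepl("[KH]DEL$", protein)
  glyc <- gregexpr("(?=N[^P*](S|T))", protein, perl = TRUE)[[1]]
  glyc <- as.integer(glyc[glyc > 0])
  from <- if (is.na(sp_cleavage)) 2L else sp_cleavage + 1L
  to <- min(n, from + rxlr_window - 1L)
  rxlr <- FALSE
  if (to - from + 1 >= 4)
    rxlr <- grepl("R.LR", substr(protein, from, to))
  nls <- grepl("K[KR].[KR]", protein)
  list(er_retention = er, n_glyc_sites = glyc, rxlr = rxlr, nls = nls)
}

#' Classify a protein as a small secreted protein (SSP)
#'
#' Applies the four criteria conjunctively: length < 300 residues; signal
#' peptide present; no transmembrane segment (outside the signal peptide);
#' no C-terminal ER-retention motif. Motif annotations (N-glycosylation
#' sequons, RXLR, NLS) are reported but do not gate the call.
#'
#' @param protein amino-acid sequence.
#' @param hp a [hydropathy_params()].
#' @param overrides optional named list plugging in external predictor
#'   results: any of `signal_peptide` (logical), `cleavage` (integer),
#'   `tm_segments` (integer count).
#' @return list of class `ssp_call`: `len_ok`, `signal_peptide`, `no_tm`,
#'   `no_er_retention`, `is_ssp`, `length`, `cleavage`, `n_tm`, motif
#'   annotations.
#' @export
classify_ssp <- function(protein, hp = hydropathy_params(),
                         overrides = list()) {
  protein <- toupper(protein)
  n <- nchar(protein)
  len_ok <- n < 300
  sp <- predict_signal_peptide(protein)
  if (!is.null(overrides$signal_peptide)) {
    sp$present <- overrides$signal_peptide
    sp$cleavage <- if (!is.null(overrides$cleavage)) overrides$cleavage
                   else sp$cleavage
  }
  tm <- detect_tm(protein, hp, sp_cleavage = sp$cleavage)
  n_tm <- if (!is.null(overrides$tm_segments)) overrides$tm_segments
          else nrow(tm)
  motifs <- scan_motifs(protein, sp_cleavage = sp$cleavage)
  call <- list(len_ok = len_ok,
               signal_peptide = isTRUE(sp$present),
               no_tm = n_tm == 0,
               no_er_retention = !motifs$er_retention,
               length = n, cleavage = sp$cleavage, n_tm = n_tm,
               n_glyc_sites = motifs$n_glyc_sites,
               rxlr = motifs$rxlr, nls = motifs$nls)
  call$is_ssp <- call$len_ok && call$signal_peptide && call$no_tm &&
    call$no_er_retention
  class(call) <- "ssp_call"
  call
}

#' @export
print.ssp_call <- function(x, ...) {
  cat(sprintf(paste0("ssp_call: %s (len %d %s, signal peptide %s, TM %d, ",
                     "ER retention %s)\n"),
              if (x$is_ssp) "SSP" else "not SSP", x$length,
              if (x$len_ok) "ok" else ">=300",
              if (x$signal_peptide) "yes" else "no", x$n_tm,
              if (x$no_er_retention) "absent" else "present"))
  invisible(x)
}

#' SSP report over a protein set
#'
#' @param proteins named character vector of protein sequences.
#' @param hp a [hydropathy_params()].
#' @return data.frame, one row per protein, with the per-criterion booleans,
#'   motif annotations, and the final `is_ssp` call.
#' @export
ssp_report <- function(proteins, hp = hydropathy_params()) {
  rows <- lapply(names(proteins), function(id) {
    cl <- classify_ssp(proteins[[id]], hp)
    data.frame(protein_id = id, length = cl$length, len_ok = cl$len_ok,
               signal_peptide = cl$signal_peptide,
               cleavage = ifelse(is.na(cl$cleavage), NA_integer_, cl$cleavage),
               no_tm = cl$no_tm, no_er_retention = cl$no_er_retention,
               n_glyc = length(cl$n_glyc_sites), rxlr = cl$rxlr, nls = cl$nls,
               is_ssp = cl$is_ssp, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
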