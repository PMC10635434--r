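IUPAC_CODES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

#' Define an IUPAC consensus motif
#'
#' @param id motif identifier (e.g. "TCS").
#' @param consensus IUPAC consensus string, length >= 4.
#' @param max_mismatches mismatches tolerated when scanning (default 0).
#' @return an object of class `motif`.
#' @export
motif <- function(id, consensus, max_mismatches = 0) {
  consensus <- toupper(consensus)
  if (nchar(consensus) < 4) stop("motif consensus must be at least 4 nt")
  letters <- strsplit(consensus, "")[[1]]
  if (!all(letters %in% names(IUPAC_CODES)))
    stop("invalid IUPAC letter in consensus: ",
         paste(setdiff(letters, names(IUPAC_CODES)), collapse = ""))
  stopifnot(max_mismatches >= 0)
  structure(list(id = id, consensus = consensus,
                 max_mismatches = as.integer(max_mismatches)),
            class = "motif")
}

#' Reverse complement of a DNA string (IUPAC-aware)
#' @param x character scalar.
#' @return character scalar.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", toupper(x))
  paste(rev(strsplit(comp, "")[[1]]), collapse = "")
}

# mismatch counts of `consensus` against every offset of `seqv` (letter vector);
# an N in the sequence never matches any consensus letter.
consensus_mismatch_counts <- function(seqv, consensus) {
  w <- nchar(consensus)
  L <- length(seqv)
  if (L < w) return(integer(0))
  cl <- strsplit(consensus, "")[[1]]
  n_pos <- L - w + 1L
  mism <- integer(n_pos)
  for (j in seq_len(w)) {
    ok <- seqv[j:(j + n_pos - 1L)] %in% IUPAC_CODES[[cl[j]]]
    mism <- mism + !ok
  }
  mism
}

#' Scan a promoter for IUPAC consensus motifs on both strands
#'
#' Reports every position, on either strand, where a motif's consensus
#' matches with at most its allowed number of mismatches. Minus-strand hits
#' are given in forward coordinates (0-based start of the matched window)
#' with strand "-"; the `match` column always holds the forward-strand
#' subsequence of the window. An N in the promoter never matches.
#'
#' @param promoter character scalar over A/C/G/T/N (case-insensitive).
#' @param motifs a [motif()] or list of motifs.
#' @return data.frame with columns `motif`, `start` (0-based), `strand`,
#'   `match`.
#' @export
scan_motifs <- function(promoter, motifs) {
  if (inherits(motifs, "motif")) motifs <- list(motifs)
  promoter <- toupper(promoter)
  seqv <- strsplit(promoter, "")[[1]]
  if (!all(seqv %in% c("A", "C", "G", "T", "N")))
    stop("promoter contains invalid characters")
  L <- length(seqv)
  hits <- list()
  for (m in motifs) {
    w <- nchar(m$consensus)
    if (L < w) stop("promoter shorter than motif ", m$id)
    for (strand in c("+", "-")) {
      cons <- if (strand == "+") m$consensus else revcomp(m$consensus)
      mism <- consensus_mismatch_counts(seqv, cons)
      at <- which(mism <= m$max_mismatches) - 1L  # 0-based
      if (length(at))
        hits[[length(hits) + 1L]] <- data.frame(
          motif = m$id, start = at, strand = strand,
          match = vapply(at, function(p)
            substr(promoter, p + 1L, p + w), character(1)))
    }
  }
  if (!length(hits))
    return(data.frame(motif = character(), start = integer(),
                      strand = character(), match = character()))
  out <- do.call(rbind, hits)
  out <- out[order(out$start, out$strand, out$motif), ]
  rownames(out) <- NULL
  out
}

#' Ablate a motif occurrence by point mutations
#'
#' Substitutes every position of the hit window by a transversion
#' (A<->C, G<->T), destroying the consensus match while leaving the rest of
#' the promoter — including other motif occurrences — untouched. The
#' variant is re-scanned; if the motif still matches at the locus (possible
#' when the consensus contains N positions, which match any base) an error
#' is raised.
#'
#' @param promoter character scalar.
#' @param hit one row of a [scan_motifs()] result (or a list with `start`,
#'   `strand`).
#' @param motif the [motif()] that produced the hit.
#' @return the variant promoter string (same length as input).
#' @export
mutate_motif_site <- function(promoter, hit, motif) {
  promoter <- toupper(promoter)
  w <- nchar(motif$consensus)
  start <- hit$start
  if (start < 0 || start + w > nchar(promoter))
    stop("hit does not lie within the promoter")
  window <- substr(promoter, start + 1, start + w)
  mutated <- chartr("ACGT", "CATG", window)
  variant <- paste0(substr(promoter, 1, start), mutated,
                    substr(promoter, start + w + 1, nchar(promoter)))
  re <- scan_motifs(variant, motif)
  if (any(re$start == start))
    stop("substitution rule failed to ablate the motif at position ", start,
         " (consensus positions matching any base cannot be destroyed)")
  variant
}

#' Compare reporter fluorescence between promoter genotypes
#'
#' Welch two-sample t-test on replicate-level mean population fluorescence.
#'
#' @param measurements data.frame with columns `genotype` and
#'   `fluorescence` (one row per replicate).
#' @param group_a,group_b promoter genotypes to compare.
#' @return list with `mean_diff` (a - b), `t`, `df`, `p`.
#' @export
compare_reporter <- function(measurements, group_a, group_b) {
  stopifnot(is.data.frame(measurements),
            all(c("genotype", "fluorescence") %in% names(measurements)))
  a <- measurements$fluorescence[measurements$genotype == group_a]
  b <- measurements$fluorescence[measurements$genotype == group_b]
  if (length(a) < 3 || length(b) < 3)
    stop("each genotype needs at least 3 replicates")
  if (any(!is.finite(c(a, b)))) stop("fluorescence must be finite")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b))
      return(list(mean_diff = 0, t = 0, df = NA_real_, p = 1))
    stop("zero variance in both groups with unequal means; more replicates needed")
  }
  tt <- stats::t.test(a, b)
  list(mean_diff = mean(a) - mean(b), t = unname(tt$statistic),
       df = unname(tt$parameter), p = tt$p.value)
}
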