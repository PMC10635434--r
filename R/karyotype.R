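#' Read a windowed depth table from TSV
#'
#' Expects columns `chromosome`, `window_start` (0-based), `window_end`
#' (half-open), `depth` (mean reads per base in window).
#'
#' @param path file path.
#' @return a `depth_table` data.frame.
#' @export
read_depth_table <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("chromosome", "window_start", "window_end", "depth")
  if (!all(need %in% names(x)))
    stop("depth table must have columns: ", paste(need, collapse = ", "))
  validate_depth_table(x)
  class(x) <- c("depth_table", "data.frame")
  x
}

#' Write a depth table to TSV
#' @param x a `depth_table`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_depth_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_depth_table <- function(x) {
  if (any(x$depth < 0)) stop("depth must be non-negative")
  if (any(x$window_end <= x$window_start)) stop("windows must have positive width")
  by_chr <- split(x, x$chromosome)
  for (d in by_chr) {
    d <- d[order(d$window_start), ]
    if (any(d$window_start[-1] < d$window_end[-nrow(d)]))
      stop("overlapping windows on chromosome ", d$chromosome[1])
  }
  invisible(TRUE)
}

#' Relative chromosome copy number from windowed depth
#'
#' Normalises each chromosome's median window depth by the genome-wide
#' median over all retained windows:
#' `r_c = median(depth on c) / median(depth genome-wide)`. Median (not mean)
#' normalisation keeps the baseline robust both to a single aneuploid
#' chromosome and to local depth spikes in repeat-rich subtelomeres.
#'
#' Chromosomes shorter than `min_length` (mitochondrial and short contigs)
#' are dropped silently; chromosomes with fewer than `min_windows` windows
#' are dropped with a warning.
#'
#' @param depth a `depth_table` (see [read_depth_table()]).
#' @param min_windows minimum windows per chromosome (default 10).
#' @param min_length minimum chromosome span in bp (default 1e5).
#' @param exclude_self when TRUE, each chromosome's baseline is the median
#'   over the windows of all *other* chromosomes (leave-one-out). At high
#'   population aneuploidy frequencies the aneuploid chromosome's own
#'   windows otherwise inflate the genome-wide median slightly; use this
#'   convention for population frequency rescaling. Default FALSE (plain
#'   genome-wide median).
#' @return a `karyotype_profile` data.frame with columns `chromosome`, `r`
#'   (genome-median-normalised relative copy number).
#' @export
relative_copy_number <- function(depth, min_windows = 10, min_length = 1e5,
                                 exclude_self = FALSE) {
  stopifnot(is.data.frame(depth))
  validate_depth_table(depth)
  span <- tapply(depth$window_end, depth$chromosome, max)
  keep_len <- names(span)[span >= min_length]
  depth <- depth[depth$chromosome %in% keep_len, , drop = FALSE]
  nw <- table(depth$chromosome)
  few <- names(nw)[nw < min_windows]
  if (length(few)) {
    warning("excluding chromosome(s) with fewer than ", min_windows,
            " windows: ", paste(few, collapse = ", "))
    depth <- depth[!depth$chromosome %in% few, , drop = FALSE]
  }
  if (!nrow(depth)) stop("no chromosomes left after filtering")
  g_med <- stats::median(depth$depth)
  if (g_med <= 0) stop("genome-wide median depth is zero")
  med <- tapply(depth$depth, depth$chromosome, stats::median)
  if (exclude_self) {
    base <- vapply(names(med), function(ch)
      stats::median(depth$depth[depth$chromosome != ch]), numeric(1))
    r <- as.numeric(med) / base
  } else {
    r <- as.numeric(med) / g_med
  }
  out <- data.frame(chromosome = names(med), r = r, row.names = NULL)
  # keep input chromosome order
  out <- out[order(match(out$chromosome, unique(depth$chromosome))), ]
  rownames(out) <- NULL
  class(out) <- c("karyotype_profile", "data.frame")
  out
}

#' Call integer aneuploidies from a karyotype profile
#'
#' A chromosome's copy call is `round(r_c * baseline_ploidy)` when the
#' rounding residual is within `tolerance * baseline_ploidy`; otherwise the
#' chromosome is flagged ambiguous and no call is made. A chromosome is
#' aneuploid when its call differs from the baseline ploidy.
#'
#' @param profile a `karyotype_profile` from [relative_copy_number()].
#' @param baseline_ploidy baseline copies per chromosome (1 or 2).
#' @param tolerance fraction of baseline allowed as rounding residual
#'   (default 0.25).
#' @return data.frame with columns `chromosome`, `r`, `call` (integer or NA),
#'   `ambiguous`, `aneuploid`.
#' @export
call_aneuploidies <- function(profile, baseline_ploidy, tolerance = 0.25) {
  stopifnot(baseline_ploidy %in% c(1L, 2L))
  x <- as.data.frame(profile)
  raw <- x$r * baseline_ploidy
  call <- round(raw)
  ambiguous <- abs(raw - call) > tolerance * baseline_ploidy
  call[ambiguous] <- NA_integer_
  data.frame(chromosome = x$chromosome, r = x$r, call = as.integer(call),
             ambiguous = ambiguous,
             aneuploid = !ambiguous & call != baseline_ploidy)
}

#' Population aneuploidy frequency from relative coverage
#'
#' Under the single-extra-copy assumption, the fraction of haploid genome
#' equivalents carrying an extra copy of chromosome c is
#' `f_c = clip(r_c - 1, 0, 1)`, and the per-cell frequency is
#' `f_cell = clip(f_c * P, 0, 1)` with `P = h + 2(1 - h)` the mean genome
#' equivalents per cell.
#'
#' @param profile a `karyotype_profile`.
#' @param haploid_fraction population haploid fraction h in \[0, 1\].
#' @return data.frame with columns `chromosome`, `r`, `f_c`, `f_cell`.
#' @export
population_chromosome_frequency <- function(profile, haploid_fraction) {
  stopifnot(haploid_fraction >= 0, haploid_fraction <= 1)
  x <- as.data.frame(profile)
  P <- haploid_fraction + 2 * (1 - haploid_fraction)
  f_c <- pmin(pmax(x$r - 1, 0), 1)
  data.frame(chromosome = x$chromosome, r = x$r, f_c = f_c,
             f_cell = pmin(pmax(f_c * P, 0), 1))
}

#' Assemble an aneuploidy-frequency trajectory across time points
#'
#' Joins per-time-point karyotype profiles into a long table of
#' per-chromosome frequencies and flags chromosomes whose per-cell frequency
#' ever exceeds 0.10 as high-frequency.
#'
#' @param profiles list of `karyotype_profile`s, time-ordered.
#' @param generations numeric vector of generations elapsed, strictly
#'   increasing, one per profile.
#' @param haploid_fractions numeric vector of population haploid fractions,
#'   one per profile.
#' @param high_freq_threshold per-cell frequency above which a chromosome is
#'   flagged (default 0.10).
#' @return an `aneuploidy_trajectory` data.frame with columns `generations`,
#'   `chromosome`, `r`, `f_c`, `f_cell`, `high_frequency`.
#' @export
assemble_trajectory <- function(profiles, generations, haploid_fractions,
                                high_freq_threshold = 0.10) {
  if (length(profiles) != length(generations) ||
      length(profiles) != length(haploid_fractions))
    stop("profiles, generations and haploid_fractions must have equal length")
  if (any(diff(generations) <= 0))
    stop("generations must be strictly increasing")
  rows <- Map(function(p, g, h) {
    f <- population_chromosome_frequency(p, h)
    cbind(generations = g, f)
  }, profiles, generations, haploid_fractions)
  out <- do.call(rbind, rows)
  hi <- tapply(out$f_cell, out$chromosome, function(v) any(v > high_freq_threshold))
  out$high_frequency <- as.logical(hi[out$chromosome])
  rownames(out) <- NULL
  class(out) <- c("aneuploidy_trajectory", "data.frame")
  out
}
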