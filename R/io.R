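#' Read and write fluorescence samples (one intensity per line)
#'
#' @param path file path.
#' @return a `fluorescence_sample` numeric vector.
#' @export
read_fluorescence <- function(path) {
  x <- scan(path, what = numeric(), quiet = TRUE)
  if (any(x <= 0)) stop("intensities must be positive")
  structure(x, class = "fluorescence_sample")
}

#' @rdname read_fluorescence
#' @param x numeric intensities.
#' @export
write_fluorescence <- function(x, path) {
  writeLines(format(as.numeric(x), digits = 15, trim = TRUE, scientific = FALSE), path)
  invisible(path)
}

#' Read and write competition time series TSV
#'
#' Columns: `transfer`, `od_after_dilution`, `od`, `query_count`,
#' `competitor_count`; optional genotype columns (`replicate`, `ploidy`,
#' `mating_type`, `cell_type`) pass through untouched.
#'
#' @param path file path.
#' @return a `competition_series` data.frame.
#' @export
read_competition_tsv <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("transfer", "od_after_dilution", "od", "query_count",
            "competitor_count")
  if (!all(need %in% names(x)))
    stop("competition table must have columns: ", paste(need, collapse = ", "))
  class(x) <- c("competition_series", "data.frame")
  x
}

#' @rdname read_competition_tsv
#' @param x a `competition_series`.
#' @export
write_competition_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write gene x sample count matrices as TSV
#'
#' First column `gene`, remaining columns one per sample.
#'
#' @param path file path.
#' @return integer matrix with gene rownames.
#' @export
read_counts_tsv <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(x[, -1, drop = FALSE])
  rownames(m) <- x[[1]]
  storage.mode(m) <- "integer"
  m
}

#' @rdname read_counts_tsv
#' @param counts matrix genes x samples.
#' @export
write_counts_tsv <- function(counts, path) {
  df <- data.frame(gene = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read promoter sequences from FASTA
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_promoters_fasta <- function(path) {
  s <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(s), names(s))
}

#' Write promoter sequences to FASTA
#' @param seqs named character vector.
#' @param path output file.
#' @export
write_promoters_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read a gene annotation from GFF3
#'
#' Imports gene-type features and returns the table expected by
#' [genome_model()] (1-based inclusive coordinates).
#'
#' @param path GFF3 file.
#' @param feature_type feature type to keep (default "gene").
#' @return data.frame `id`, `chromosome`, `start`, `end`, `strand`.
#' @export
read_genes_gff <- function(path, feature_type = "gene") {
  g <- rtracklayer::import(path)
  g <- g[g$type == feature_type]
  id <- if (!is.null(g$ID)) g$ID else as.character(seq_along(g))
  data.frame(id = id,
             chromosome = as.character(GenomicRanges::seqnames(g)),
             start = GenomicRanges::start(g), end = GenomicRanges::end(g),
             strand = as.character(GenomicRanges::strand(g)))
}

#' Read a motif table (TSV: id, iupac, max_mismatches)
#'
#' @param path file path.
#' @return list of [motif()] objects.
#' @export
read_motifs_tsv <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("id", "iupac")
  if (!all(need %in% names(x)))
    stop("motif table must have columns id and iupac")
  mm <- if ("max_mismatches" %in% names(x)) x$max_mismatches else 0
  Map(motif, x$id, x$iupac, mm)
}
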