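#' Genome model for simulation
#'
#' A light-weight description of a genome: chromosome names and lengths plus
#' a gene table in 1-based inclusive coordinates. Stands in for a reference
#' assembly when generating synthetic depth and expression data.
#'
#' @param chromosomes data.frame with columns `name`, `length` (bp).
#' @param genes data.frame with columns `id`, `chromosome`, `start`, `end`,
#'   `strand`; may be empty for depth-only simulations.
#' @return an object of class `genome_model`.
#' @export
genome_model <- function(chromosomes,
                         genes = data.frame(id = character(), chromosome = character(),
                                            start = integer(), end = integer(),
                                            strand = character())) {
  stopifnot(is.data.frame(chromosomes),
            all(c("name", "length") %in% names(chromosomes)))
  if (nrow(chromosomes) == 0L) stop("genome has no chromosomes")
  if (anyDuplicated(chromosomes$name)) stop("chromosome names must be unique")
  if (any(chromosomes$length <= 0)) stop("chromosome lengths must be positive")
  stopifnot(is.data.frame(genes),
            all(c("id", "chromosome", "start", "end", "strand") %in% names(genes)))
  if (nrow(genes)) {
    if (anyDuplicated(genes$id)) stop("gene ids must be unique")
    if (!all(genes$chromosome %in% chromosomes$name))
      stop("gene on unknown chromosome")
    if (any(genes$start > genes$end)) stop("gene start must be <= end")
    len <- chromosomes$length[match(genes$chromosome, chromosomes$name)]
    if (any(genes$start < 1L) || any(genes$end > len))
      stop("gene interval outside chromosome bounds")
  }
  structure(list(chromosomes = chromosomes, genes = genes),
            class = "genome_model")
}

#' @export
print.genome_model <- function(x, ...) {
  cat("<genome_model> ", nrow(x$chromosomes), " chromosomes, ",
      nrow(x$genes), " genes, ", sum(x$chromosomes$length), " bp\n", sep = "")
  invisible(x)
}

#' Default 16-chromosome toy genome
#'
#' A compact yeast-like genome used by examples and tests: 16 chromosomes of
#' varying length and a configurable number of genes per chromosome placed on
#' a regular grid. Chromosome XV carries the focal transporter gene
#' `AGT1` in its subtelomeric region, mirroring the organisation the
#' expression module is designed to analyse.
#'
#' @param n_chromosomes number of chromosomes.
#' @param chr_length length of each chromosome (bp); recycled.
#' @param genes_per_chr genes placed per chromosome.
#' @param focal_gene id given to the last gene of chromosome XV (placed
#'   within 20 kb of the right end).
#' @return a [genome_model()].
#' @export
toy_genome <- function(n_chromosomes = 16L, chr_length = 2e5,
                       genes_per_chr = 20L, focal_gene = "AGT1") {
  nm <- paste0("chr", utils::as.roman(seq_len(n_chromosomes)))
  chrom <- data.frame(name = nm,
                      length = rep_len(chr_length, n_chromosomes))
  genes <- do.call(rbind, lapply(seq_len(n_chromosomes), function(i) {
    L <- chrom$length[i]
    start <- floor(seq(1000, L - 2500, length.out = genes_per_chr))
    data.frame(id = sprintf("g%02d_%03d", i, seq_len(genes_per_chr)),
               chromosome = nm[i], start = as.integer(start),
               end = as.integer(start + 1499L),
               strand = rep(c("+", "-"), length.out = genes_per_chr))
  }))
  xv <- which(chrom$name == "chrXV")
  if (length(xv) && !is.null(focal_gene)) {
    idx <- which(genes$chromosome == "chrXV")
    last <- idx[length(idx)]
    L <- chrom$length[xv]
    genes$id[last] <- focal_gene
    genes$start[last] <- as.integer(L - 8000L)
    genes$end[last] <- as.integer(L - 6200L)
  }
  genome_model(chrom, genes)
}

#' Latent composition of a mixed-ploidy population
#'
#' Holds the quantities the pipeline tries to recover: the haploid fraction
#' `h`, per-chromosome extra-copy cell frequencies `a_c`, and the G1 fraction
#' `alpha` of the asynchronous culture.
#'
#' @param haploid_fraction proportion of haploid cells, in \[0, 1\].
#' @param aneuploidy_freqs named numeric vector, chromosome -> frequency of
#'   cells carrying one extra copy, each in \[0, 1\].
#' @param g1_fraction proportion of cells in G1, in \[0, 1\].
#' @return an object of class `population_composition`.
#' @export
population_composition <- function(haploid_fraction = 0,
                                   aneuploidy_freqs = numeric(),
                                   g1_fraction = 0.6) {
  chk01 <- function(x, what) {
    if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
      stop(what, " must lie in [0, 1]")
  }
  chk01(haploid_fraction, "haploid_fraction")
  chk01(g1_fraction, "g1_fraction")
  if (length(aneuploidy_freqs)) {
    if (is.null(names(aneuploidy_freqs)) || any(!nzchar(names(aneuploidy_freqs))))
      stop("aneuploidy_freqs must be named by chromosome")
    chk01(aneuploidy_freqs, "aneuploidy_freqs")
  }
  structure(list(haploid_fraction = haploid_fraction,
                 aneuploidy_freqs = aneuploidy_freqs,
                 g1_fraction = g1_fraction),
            class = "population_composition")
}

#' Simulation configuration
#'
#' Collects the nuisance parameters of all generators. Defaults state the
#' conditions the analysis is designed for: moderately overdispersed
#' negative-binomial sequencing depth and expression counts (size 20), an
#' 8 percent coefficient of variation on cytometry peaks, 13,000 cells
#' sampled per competition time point, dosage attenuation calibrated so a
#' doubled chromosome yields a median expression fold change of 1.58, a
#' 2.3-fold maltose induction of the focal transporter, and a 1.69-fold
#' cell-type-specific cis boost on it.
#'
#' @param seed master integer seed (see [substream_seed()]).
#' @param depth_mean expected reads per window at relative copy number 1.
#' @param depth_dispersion negative-binomial size for depth (20: moderate
#'   overdispersion).
#' @param cytometry_cv coefficient of variation of each DNA-content peak.
#' @param cytometry_mu mean fluorescence of the 1C peak (arbitrary units).
#' @param sampling_depth cells drawn per cytometry/competition sample.
#' @param expression_dispersion negative-binomial size for expression
#'   counts (100, i.e. dispersion 0.01, typical of deeply sequenced
#'   biological-triplicate yeast RNA-seq).
#' @param attenuation dosage attenuation exponent in (0, 1]; expression of a
#'   gene on a chromosome at dosage d scales as d^attenuation.
#' @param induction_fold condition-induction multiplier in maltose.
#' @param cis_boost cell-type-specific multiplier on the focal gene in
#'   haploid-like samples in maltose.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       depth_mean = 100,
                       depth_dispersion = 20,
                       cytometry_cv = 0.08,
                       cytometry_mu = 100,
                       sampling_depth = 13000,
                       expression_dispersion = 100,
                       attenuation = log2(1.58),
                       induction_fold = 2.3,
                       cis_boost = 1.69) {
  if (depth_mean <= 0) stop("depth_mean must be positive")
  if (depth_dispersion <= 0 || expression_dispersion <= 0)
    stop("dispersion (NB size) must be positive")
  if (attenuation <= 0 || attenuation > 1) stop("attenuation must be in (0, 1]")
  if (induction_fold <= 0 || cis_boost <= 0) stop("fold parameters must be positive")
  structure(list(seed = as.integer(seed), depth_mean = depth_mean,
                 depth_dispersion = depth_dispersion,
                 cytometry_cv = cytometry_cv, cytometry_mu = cytometry_mu,
                 sampling_depth = sampling_depth,
                 expression_dispersion = expression_dispersion,
                 attenuation = attenuation, induction_fold = induction_fold,
                 cis_boost = cis_boost),
            class = "sim_config")
}
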