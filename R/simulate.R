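#' Expected relative coverage of each chromosome in a mixed population
#'
#' In a population with haploid fraction `h`, cells carry on average
#' `P = h + 2(1 - h)` genome equivalents; a chromosome with extra-copy cell
#' frequency `a_c` contributes `P + a_c` copies on average, so its expected
#' coverage relative to the genome baseline is `(P + a_c) / P`.
#'
#' @param composition a [population_composition()].
#' @param chromosomes chromosome names to report.
#' @return named numeric vector of expected relative coverages.
#' @export
expected_relative_coverage <- function(composition, chromosomes) {
  stopifnot(inherits(composition, "population_composition"))
  P <- composition$haploid_fraction + 2 * (1 - composition$haploid_fraction)
  a <- rep(0, length(chromosomes))
  names(a) <- chromosomes
  known <- intersect(names(composition$aneuploidy_freqs), chromosomes)
  a[known] <- composition$aneuploidy_freqs[known]
  (P + a) / P
}

#' Simulate windowed sequencing depth for a mixed-ploidy population
#'
#' Tiles each chromosome with non-overlapping windows and draws
#' negative-binomial read depth with mean proportional to the chromosome's
#' expected copy number per haploid genome equivalent. The genome-wide
#' baseline window mean is `config$depth_mean`.
#'
#' @param genome a [genome_model()].
#' @param composition a [population_composition()].
#' @param window window size in bp (>= 100); trailing partial windows are
#'   dropped.
#' @param config a [sim_config()].
#' @return a `depth_table` data.frame with columns `chromosome`,
#'   `window_start` (0-based), `window_end` (half-open), `depth`.
#' @export
simulate_depth <- function(genome, composition, window = 1000, config = sim_config()) {
  stopifnot(inherits(genome, "genome_model"),
            inherits(composition, "population_composition"))
  if (window < 100) stop("window must be at least 100 bp")
  chrom <- genome$chromosomes
  short <- chrom$name[chrom$length < window]
  if (length(short))
    stop("window (", window, " bp) exceeds length of chromosome ", short[1])
  r <- expected_relative_coverage(composition, chrom$name)
  tabs <- with_substream(config$seed, "depth", {
    lapply(seq_len(nrow(chrom)), function(i) {
      n <- chrom$length[i] %/% window
      start <- (seq_len(n) - 1L) * as.integer(window)
      depth <- stats::rnbinom(n, size = config$depth_dispersion,
                              mu = config$depth_mean * r[[i]])
      data.frame(chromosome = chrom$name[i], window_start = start,
                 window_end = start + as.integer(window), depth = depth)
    })
  })
  out <- do.call(rbind, tabs)
  class(out) <- c("depth_table", "data.frame")
  out
}

#' Simulate a DNA-content flow-cytometry sample
#'
#' Each cell's fluorescence is drawn from a Gaussian centred at `mu * k`,
#' `k` in `{1, 2, 4}`, with standard deviation `cv * mu * k`. Component
#' weights follow the shared-G1-fraction mixing of haploids and diploids:
#' `w_1C = h * alpha`, `w_2C = h(1 - alpha) + (1 - h) alpha`,
#' `w_4C = (1 - h)(1 - alpha)` (haploid G2 and diploid G1 share the 2C peak).
#'
#' @param composition a [population_composition()].
#' @param n_cells number of cells (>= 1).
#' @param config a [sim_config()]; uses `cytometry_mu` and `cytometry_cv`.
#' @return a `fluorescence_sample`: numeric vector of positive intensities.
#' @export
simulate_cytometry <- function(composition, n_cells, config = sim_config()) {
  stopifnot(inherits(composition, "population_composition"), n_cells >= 1)
  if (config$cytometry_cv <= 0) stop("cytometry_cv must be positive")
  w <- ploidy_mixture_weights(composition$haploid_fraction,
                              composition$g1_fraction)
  k <- c(1, 2, 4)
  x <- with_substream(config$seed, "cytometry", {
    comp <- sample.int(3L, n_cells, replace = TRUE, prob = w)
    v <- stats::rnorm(n_cells, mean = config$cytometry_mu * k[comp],
                      sd = config$cytometry_cv * config$cytometry_mu * k[comp])
    while (any(bad <- v <= 0))
      v[bad] <- stats::rnorm(sum(bad), config$cytometry_mu * k[comp[bad]],
                             config$cytometry_cv * config$cytometry_mu * k[comp[bad]])
    v
  })
  structure(x, class = "fluorescence_sample")
}

#' 1C/2C/4C mixture weights from haploid and G1 fractions
#'
#' @param h haploid fraction.
#' @param alpha G1 fraction (shared across ploidies).
#' @return numeric length-3 vector `(w_1C, w_2C, w_4C)` summing to 1.
#' @export
ploidy_mixture_weights <- function(h, alpha) {
  c(h * alpha, h * (1 - alpha) + (1 - h) * alpha, (1 - h) * (1 - alpha))
}

#' Simulate a pairwise competition assay time series
#'
#' The latent log ratio of query to competitor follows
#' `ln r(t) = ln r(0) + s * g(t)` with `g(t)` the cumulative generations
#' after `t` transfers. At each time point `sampling_depth` cells are drawn
#' and classified, giving binomial query counts; `sampling_depth = Inf`
#' returns noiseless expected counts (scaled to one million cells). The OD
#' columns are consistent with `gens_per_transfer` doublings per transfer.
#'
#' @param s selection coefficient per generation (any real).
#' @param n_transfers number of transfers after the initial time point.
#' @param gens_per_transfer generations elapsed per transfer; `log2(10)` for
#'   the 1:10 serial-transfer regime, `log2(100)` for 1:100 daily dilutions.
#' @param initial_ratio query/competitor ratio at time 0.
#' @param sampling_depth cells sampled per time point (>= 100, or `Inf`).
#' @param config a [sim_config()].
#' @return a `competition_series` data.frame with columns `transfer`,
#'   `od_after_dilution`, `od`, `query_count`, `competitor_count`.
#' @export
simulate_competition <- function(s, n_transfers = 4, gens_per_transfer = log2(10),
                                 initial_ratio = 1, sampling_depth = 13000,
                                 config = sim_config()) {
  if (!is.infinite(sampling_depth) && sampling_depth < 100)
    stop("sampling_depth must be at least 100 cells")
  t <- 0:n_transfers
  g <- t * gens_per_transfer
  p <- 1 / (1 + exp(-(log(initial_ratio) + s * g)))  # query fraction
  if (is.infinite(sampling_depth)) {
    q <- p * 1e6
    comp <- (1 - p) * 1e6
  } else {
    q <- with_substream(config$seed, "competition",
                        stats::rbinom(length(t), size = sampling_depth, prob = p))
    comp <- sampling_depth - q
  }
  od0 <- 0.1
  out <- data.frame(transfer = t,
                    od_after_dilution = od0,
                    od = od0 * 2^ifelse(t == 0, 0, gens_per_transfer),
                    query_count = q, competitor_count = comp)
  class(out) <- c("competition_series", "data.frame")
  out
}

#' Simulate a gene-level expression count matrix under dosage and induction
#'
#' Counts are negative binomial with mean
#' `baseline * dosage^attenuation * induction * cis_boost * library_size`,
#' where dosage is the copy number of the gene's chromosome relative to the
#' sample's baseline ploidy. Condition-induced genes (including the focal
#' transporter) are multiplied by `induction_fold` in maltose. The focal
#' gene escapes dosage attenuation (it responds with full dosage) and, in
#' haploid-like (baseline-ploidy-1) samples grown in maltose, receives the
#' additional cell-type-specific `cis_boost`.
#'
#' @param genome a [genome_model()] with a gene table.
#' @param samples data.frame with columns `sample`, `strain`, `condition`
#'   (one of "glucose", "maltose"), `ploidy` (baseline genome copies, 1 or 2).
#' @param karyotypes numeric matrix samples x chromosomes of chromosome copy
#'   numbers; rownames must match `samples$sample`.
#' @param focal_gene id of the focal transporter gene.
#' @param induced_genes character vector of maltose-induced gene ids
#'   (defaults to the focal gene alone).
#' @param config a [sim_config()].
#' @return integer matrix genes x samples of raw counts.
#' @export
simulate_expression <- function(genome, samples, karyotypes, focal_gene,
                                induced_genes = focal_gene,
                                config = sim_config()) {
  stopifnot(inherits(genome, "genome_model"), is.data.frame(samples),
            all(c("sample", "strain", "condition", "ploidy") %in% names(samples)))
  genes <- genome$genes
  if (!focal_gene %in% genes$id) stop("focal gene not in genome: ", focal_gene)
  bad <- setdiff(unique(samples$condition), c("glucose", "maltose"))
  if (length(bad)) stop("unknown condition label: ", bad[1])
  karyotypes <- as.matrix(karyotypes)
  if (is.null(rownames(karyotypes)) ||
      !all(samples$sample %in% rownames(karyotypes)))
    stop("karyotypes must have rownames covering all samples")
  if (!all(genes$chromosome %in% colnames(karyotypes)))
    stop("karyotypes must have a column for every gene-bearing chromosome")
  n_g <- nrow(genes); n_s <- nrow(samples)
  with_substream(config$seed, "expression", {
    baseline <- stats::rlnorm(n_g, meanlog = log(500), sdlog = 1)
    libsize <- stats::rlnorm(n_s, meanlog = 0, sdlog = 0.15)
    mu <- matrix(0, n_g, n_s, dimnames = list(genes$id, samples$sample))
    for (j in seq_len(n_s)) {
      copies <- karyotypes[samples$sample[j], genes$chromosome]
      dosage <- copies / samples$ploidy[j]
      expo <- ifelse(genes$id == focal_gene, 1, config$attenuation)
      m <- baseline * dosage^expo
      if (samples$condition[j] == "maltose") {
        m[genes$id %in% induced_genes] <-
          m[genes$id %in% induced_genes] * config$induction_fold
        if (samples$ploidy[j] == 1)
          m[genes$id == focal_gene] <- m[genes$id == focal_gene] * config$cis_boost
      }
      mu[, j] <- m * libsize[j]
    }
    counts <- matrix(stats::rnbinom(n_g * n_s, size = config$expression_dispersion,
                                    mu = mu),
                     n_g, n_s, dimnames = dimnames(mu))
    counts
  })
}

#' Simulate mating-type genotyping of single colonies
#'
#' Colonies are a multinomial draw: haploid with probability
#' `haploid_fraction` (split between MATa and MATalpha by `mata_skew`),
#' heterozygous diploid (MATa/alpha) otherwise. The default skew of 1
#' reflects populations in which every genotyped haploid was MATa.
#'
#' @param haploid_fraction proportion of haploid cells in \[0, 1\].
#' @param n_colonies number of colonies genotyped (>= 1).
#' @param mata_skew probability a haploid colony is MATa.
#' @param config a [sim_config()].
#' @return named integer vector `(MATa, MATalpha, MATa/alpha)`.
#' @export
simulate_colony_genotypes <- function(haploid_fraction, n_colonies,
                                      mata_skew = 1, config = sim_config()) {
  stopifnot(n_colonies >= 1, haploid_fraction >= 0, haploid_fraction <= 1,
            mata_skew >= 0, mata_skew <= 1)
  p <- c(haploid_fraction * mata_skew, haploid_fraction * (1 - mata_skew),
         1 - haploid_fraction)
  cnt <- with_substream(config$seed, "colonies",
                        stats::rmultinom(1, size = n_colonies, prob = p))
  stats::setNames(as.integer(cnt), c("MATa", "MATalpha", "MATa/alpha"))
}

#' Simulate a promoter sequence with planted motif instances
#'
#' Generates a uniform-random A/C/G/T background and writes the given motif
#' instances at stated positions; minus-strand plants are written as the
#' reverse complement of the instance.
#'
#' @param length promoter length in bp.
#' @param planted list of plants, each a list with elements `seq` (concrete
#'   A/C/G/T instance), `pos` (0-based start in promoter coordinates), and
#'   `strand` ("+" or "-").
#' @param config a [sim_config()].
#' @return a single character string.
#' @export
simulate_promoter <- function(length, planted = list(), config = sim_config()) {
  stopifnot(length >= 1)
  if (base::length(planted)) {
    iv <- t(vapply(planted, function(p) {
      w <- nchar(p$seq)
      if (p$pos < 0 || p$pos + w > length)
        stop("planted motif does not fit within promoter")
      c(p$pos, p$pos + w)
    }, numeric(2)))
    iv <- iv[order(iv[, 1]), , drop = FALSE]
    if (any(iv[-1, 1] < iv[-nrow(iv), 2]))
      stop("planted motifs overlap")
  }
  seqv <- with_substream(config$seed, "promoter",
                         sample(c("A", "C", "G", "T"), length, replace = TRUE))
  for (p in planted) {
    inst <- if (identical(p$strand, "-")) revcomp(p$seq) else p$seq
    seqv[(p$pos + 1):(p$pos + nchar(inst))] <- strsplit(inst, "")[[1]]
  }
  paste(seqv, collapse = "")
}

#' Simulate the 8-genotype factorial fitness panel
#'
#' Builds replicate fitness records for the full cross of ploidy (1 or 2)
#' and MAT-locus configuration (a, alpha, a/alpha, MAT-null). Cell type is
#' haploid-like unless the genotype is heterozygous a/alpha; a genotype
#' expresses mating-type-specific genes when its MAT configuration is a or
#' alpha. The true selection coefficient of a replicate is
#' `cell_type_effect * haploid_like + ploidy_effect * (ploidy == 1) +
#' mating_effect * expresses_any + noise`, with Gaussian replicate noise.
#'
#' @param cell_type_effect fitness difference of haploid-like cell types
#'   (default 0.188 per generation).
#' @param ploidy_effect fitness difference of ploidy 1 vs 2 (default 0.023).
#' @param mating_effect fitness difference of expressing any
#'   mating-type-specific genes (default 0.01).
#' @param n_total total number of replicate records spread round-robin over
#'   the 8 genotypes (default 90).
#' @param noise_sd replicate-to-replicate standard deviation (default 0.02,
#'   typical competition-assay repeatability).
#' @param config a [sim_config()].
#' @return data.frame with columns `replicate`, `ploidy`, `mating_type`,
#'   `cell_type`, `s`.
#' @export
simulate_fitness_panel <- function(cell_type_effect = 0.188,
                                   ploidy_effect = 0.023,
                                   mating_effect = 0.01,
                                   n_total = 90, noise_sd = 0.02,
                                   config = sim_config()) {
  panel <- expand.grid(ploidy = c(1L, 2L),
                       mating_type = c("a", "alpha", "a/alpha", "null"),
                       stringsAsFactors = FALSE)
  idx <- rep(seq_len(nrow(panel)), length.out = n_total)
  d <- panel[idx, ]
  d$cell_type <- ifelse(d$mating_type == "a/alpha", "diploid-like",
                        "haploid-like")
  truth <- cell_type_effect * (d$cell_type == "haploid-like") +
    ploidy_effect * (d$ploidy == 1L) +
    mating_effect * (d$mating_type %in% c("a", "alpha"))
  d$s <- truth + with_substream(config$seed, "panel",
                                stats::rnorm(n_total, sd = noise_sd))
  d$replicate <- seq_len(n_total)
  rownames(d) <- NULL
  d[, c("replicate", "ploidy", "mating_type", "cell_type", "s")]
}

#' Simulate a complete aneuploid expression study
#'
#' Convenience wrapper building the standard design the expression module
#' analyses: a wild-type diploid and evolved haploid strains carrying a
#' disomy of chromosome XV, grown in glucose and maltose with replicate
#' libraries, with the focal transporter gene maltose-induced and
#' cis-boosted in haploid-like samples.
#'
#' @param config a [sim_config()].
#' @param genes_per_chr genes per chromosome in the toy genome.
#' @param reps replicate libraries per strain and condition (default 3,
#'   biological triplicates).
#' @param strains evolved strain labels.
#' @param focal_gene focal transporter gene id.
#' @return list with `genome`, `samples`, `karyotypes`, `counts`,
#'   `chrxv_genes` (non-focal genes on the disomic chromosome),
#'   `focal_gene`, and `groups` (strain_condition label per sample).
#' @export
simulate_expression_study <- function(config = sim_config(),
                                      genes_per_chr = 30L, reps = 3L,
                                      strains = c("hap1", "hap2"),
                                      focal_gene = "AGT1") {
  g <- toy_genome(genes_per_chr = genes_per_chr, focal_gene = focal_gene)
  samples <- expand.grid(strain = c("WT", strains),
                         condition = c("glucose", "maltose"),
                         rep = seq_len(reps), stringsAsFactors = FALSE)
  samples$sample <- paste(samples$strain, samples$condition, samples$rep,
                          sep = "_")
  samples$ploidy <- ifelse(samples$strain == "WT", 2L, 1L)
  chrs <- g$chromosomes$name
  kar <- matrix(0, nrow(samples), length(chrs),
                dimnames = list(samples$sample, chrs))
  for (i in seq_len(nrow(samples))) {
    kar[i, ] <- samples$ploidy[i]
    if (samples$strain[i] != "WT") kar[i, "chrXV"] <- 2
  }
  counts <- simulate_expression(g, samples, kar, focal_gene, config = config)
  list(genome = g, samples = samples, karyotypes = kar, counts = counts,
       chrxv_genes = setdiff(g$genes$id[g$genes$chromosome == "chrXV"],
                             focal_gene),
       focal_gene = focal_gene,
       groups = paste(samples$strain, samples$condition, sep = "_"))
}
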