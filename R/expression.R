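#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over reference genes of
#' the ratio of the sample's count to the gene's geometric mean across
#' samples; reference genes are those with a positive count in every
#' sample. Size-normalised counts are `count / factor`.
#'
#' @param counts non-negative integer matrix genes x samples.
#' @return named numeric vector of size factors (one per sample).
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop("size factors need at least 2 samples")
  if (any(counts < 0)) stop("counts must be non-negative")
  ref <- rowSums(counts > 0) == ncol(counts)
  if (!any(ref))
    stop("no gene has a nonzero count in every sample; filter or subset first")
  lgm <- rowMeans(log(counts[ref, , drop = FALSE]))
  f <- apply(counts[ref, , drop = FALSE], 2,
             function(col) exp(stats::median(log(col) - lgm)))
  stats::setNames(f, colnames(counts))
}

#' Divide counts by their size factors
#' @param counts genes x samples matrix.
#' @param factors size factors; computed by [size_factors()] when NULL.
#' @return normalised matrix.
#' @export
normalize_counts <- function(counts, factors = NULL) {
  counts <- as.matrix(counts)
  if (is.null(factors)) factors <- size_factors(counts)
  sweep(counts, 2, factors, "/")
}

#' Log2 fold change between two sample groups
#'
#' `LFC = log2((meanA + pseudo) / (meanB + pseudo))` of size-normalised
#' group means. The pseudo-count (default 0.5) keeps fold changes finite
#' for genes with zero counts in one group.
#'
#' @param counts raw counts, genes x samples.
#' @param groups character/factor vector, one label per sample.
#' @param group_a,group_b labels of the contrast A vs B.
#' @param factors optional precomputed size factors.
#' @param pseudo pseudo-count on normalised means.
#' @return a `fold_change_table` data.frame: `gene`, `lfc`, `mean_a`,
#'   `mean_b`.
#' @export
fold_change <- function(counts, groups, group_a, group_b, factors = NULL,
                        pseudo = 0.5) {
  counts <- as.matrix(counts)
  stopifnot(length(groups) == ncol(counts))
  if (!group_a %in% groups) stop("unknown group: ", group_a)
  if (!group_b %in% groups) stop("unknown group: ", group_b)
  norm <- normalize_counts(counts, factors)
  ma <- rowMeans(norm[, groups == group_a, drop = FALSE])
  mb <- rowMeans(norm[, groups == group_b, drop = FALSE])
  out <- data.frame(gene = rownames(counts) %||% seq_len(nrow(counts)),
                    lfc = log2((ma + pseudo) / (mb + pseudo)),
                    mean_a = ma, mean_b = mb, row.names = NULL)
  class(out) <- c("fold_change_table", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Benjamini-Hochberg step-up adjustment
#'
#' In-package implementation of the BH procedure: order p-values, compute
#' `p_(i) * m / i`, and enforce monotonicity from the largest rank down.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  adj <- pmin(1, cummin(m / (m:1) * p[o]))
  adj[order(o)]
}

#' Filter differentially expressed genes
#'
#' Keeps genes with `|LFC| >= lfc_threshold` (default 1, i.e. 2-fold in
#' either direction) and BH-adjusted p-value `<= alpha` (default 0.01).
#'
#' @param table a `fold_change_table` from [fold_change()].
#' @param p_values raw p-values, one per gene in table order.
#' @param lfc_threshold minimum `|LFC|`.
#' @param alpha maximum BH-adjusted p-value.
#' @return the filtered table with columns `p` and `p_adj` appended.
#' @export
deg_filter <- function(table, p_values, lfc_threshold = 1, alpha = 0.01) {
  stopifnot(is.data.frame(table), "lfc" %in% names(table))
  if (length(p_values) != nrow(table))
    stop("p_values length does not match table")
  table$p <- p_values
  table$p_adj <- bh_adjust(p_values)
  table[abs(table$lfc) >= lfc_threshold & table$p_adj <= alpha, , drop = FALSE]
}

#' Welch two-group test per gene on log-normalised counts
#'
#' A simple built-in test supplying p-values to [deg_filter()] when an
#' external differential-expression table is unavailable. It is a Welch
#' t-test on `log2(normalised count + 0.5)` and is not equivalent to a
#' negative-binomial testing framework; use it for screening only.
#'
#' @inheritParams fold_change
#' @return numeric p-values, one per gene.
#' @export
welch_test_genes <- function(counts, groups, group_a, group_b, factors = NULL) {
  norm <- log2(normalize_counts(as.matrix(counts), factors) + 0.5)
  a <- norm[, groups == group_a, drop = FALSE]
  b <- norm[, groups == group_b, drop = FALSE]
  if (ncol(a) < 2 || ncol(b) < 2) stop("each group needs >= 2 replicates")
  apply(cbind(a, b), 1, function(v) {
    va <- v[seq_len(ncol(a))]; vb <- v[-seq_len(ncol(a))]
    if (stats::sd(va) == 0 && stats::sd(vb) == 0)
      return(if (mean(va) == mean(vb)) 1 else 0)
    stats::t.test(va, vb)$p.value
  })
}

#' Dosage null expectations for a focal gene
#'
#' Evaluates observed expression of a gene in evolved sample groups against
#' two null models built from size-normalised group means:
#' \describe{
#'   \item{induction}{expected(evolved, maltose) = mean(evolved, glucose)
#'     x mean(WT, maltose) / mean(WT, glucose) — the ancestral
#'     condition-induction applied to the evolved glucose level.}
#'   \item{copy_number}{expected(evolved, condition) = mean(WT, condition)
#'     x copy_ratio — the wild-type level scaled by relative copy number
#'     (default 2-fold).}
#' }
#' The excess is `observed / expected - 1`.
#'
#' @param counts raw counts, genes x samples.
#' @param samples data.frame with columns `sample`, `strain`, `condition`;
#'   rows in column order of `counts`.
#' @param gene focal gene id (rowname of `counts`).
#' @param model "induction" or "copy_number".
#' @param copy_ratio relative copy number multiplier for the copy-number
#'   model.
#' @param wt_strain label of the ancestral strain (default "WT").
#' @param factors optional precomputed size factors.
#' @return data.frame with columns `strain`, `condition`, `model`,
#'   `expected`, `observed`, `excess`.
#' @export
null_expectation <- function(counts, samples, gene,
                             model = c("induction", "copy_number"),
                             copy_ratio = 2, wt_strain = "WT", factors = NULL) {
  model <- match.arg(model)
  counts <- as.matrix(counts)
  stopifnot(nrow(samples) == ncol(counts),
            all(c("sample", "strain", "condition") %in% names(samples)))
  if (!gene %in% rownames(counts)) stop("gene not found: ", gene)
  norm <- normalize_counts(counts, factors)[gene, ]
  gmean <- function(strain, condition) {
    sel <- samples$strain == strain & samples$condition == condition
    if (!any(sel)) stop("no samples for ", strain, "/", condition)
    mean(norm[sel])
  }
  evolved <- setdiff(unique(samples$strain), wt_strain)
  if (!length(evolved)) stop("no evolved strains present")
  wt_glc <- gmean(wt_strain, "glucose")
  wt_mal <- gmean(wt_strain, "maltose")
  if (wt_glc == 0 || wt_mal == 0) stop("wild-type group mean is zero")
  rows <- list()
  for (st in evolved) {
    if (model == "induction") {
      ev_glc <- gmean(st, "glucose")
      if (ev_glc == 0) stop("evolved glucose group mean is zero for ", st)
      expd <- ev_glc * (wt_mal / wt_glc)
      rows[[length(rows) + 1]] <-
        data.frame(strain = st, condition = "maltose", model = model,
                   expected = expd, observed = gmean(st, "maltose"),
                   excess = gmean(st, "maltose") / expd - 1)
    } else {
      for (cond in c("glucose", "maltose")) {
        expd <- gmean(wt_strain, cond) * copy_ratio
        rows[[length(rows) + 1]] <-
          data.frame(strain = st, condition = cond, model = model,
                     expected = expd, observed = gmean(st, cond),
                     excess = gmean(st, cond) / expd - 1)
      }
    }
  }
  do.call(rbind, rows)
}

#' One-sample test of a gene class against a null fold change
#'
#' One-sided (or two-sided) one-sample t-test of the class members' LFCs
#' against `null_lfc` — 0 for induced/subtelomeric classes, 1 (i.e. 2-fold)
#' for genes on a doubled chromosome. The class median is reported on both
#' the log2 and fold scales.
#'
#' @param table a `fold_change_table`.
#' @param class_genes character vector of gene ids in the class (>= 10).
#' @param null_lfc null log2 fold change.
#' @param alternative "greater" (default; class exceeds the null), "less",
#'   or "two.sided".
#' @return list with `median_lfc`, `median_fold`, `t`, `df`, `p`, `n`.
#' @export
gene_class_comparison <- function(table, class_genes, null_lfc = 0,
                                  alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  v <- table$lfc[table$gene %in% class_genes]
  if (length(v) < 10) stop("gene class has fewer than 10 members in table")
  tt <- stats::t.test(v, mu = null_lfc, alternative = alternative)
  list(median_lfc = stats::median(v), median_fold = 2^stats::median(v),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, n = length(v))
}

#' Flag subtelomeric genes
#'
#' A gene is subtelomeric when it falls within `margin` bp of either end of
#' its contig. Specific contig ends (e.g. an rDNA-adjacent end) can be
#' excluded via `excluded_ends`.
#'
#' @param start,end 1-based inclusive gene coordinates (vectorised).
#' @param contig_length contig length(s) in bp.
#' @param margin distance from the contig end (default 20000).
#' @param chromosome optional chromosome of each gene, needed when
#'   `excluded_ends` is given.
#' @param excluded_ends optional data.frame with columns `chromosome` and
#'   `end` ("left"/"right") naming contig ends that never count.
#' @return logical vector.
#' @export
subtelomeric_flag <- function(start, end, contig_length, margin = 20000,
                              chromosome = NULL, excluded_ends = NULL) {
  stopifnot(all(start >= 1), all(end <= contig_length), all(start <= end))
  left <- start <= margin
  right <- end >= contig_length - margin
  if (!is.null(excluded_ends)) {
    stopifnot(!is.null(chromosome))
    skip_l <- chromosome %in%
      excluded_ends$chromosome[excluded_ends$end == "left"]
    skip_r <- chromosome %in%
      excluded_ends$chromosome[excluded_ends$end == "right"]
    left <- left & !skip_l
    right <- right & !skip_r
  }
  left | right
}

#' Percentile rank of a gene's fold change within a class
#'
#' Fraction of the other class members with strictly lower LFC; ties count
#' one half. The focal gene is excluded from the denominator.
#'
#' @param table a `fold_change_table`.
#' @param gene focal gene id.
#' @param class_genes character vector of class gene ids (including or
#'   excluding the focal gene; class size >= 2).
#' @return fraction in \[0, 1\].
#' @export
percentile_rank <- function(table, gene, class_genes) {
  if (!gene %in% table$gene) stop("gene not found: ", gene)
  others <- setdiff(intersect(class_genes, table$gene), gene)
  if (length(others) < 1) stop("class needs at least one other gene")
  g <- table$lfc[table$gene == gene]
  v <- table$lfc[table$gene %in% others]
  (sum(v < g) + 0.5 * sum(v == g)) / length(v)
}

#' Relative fold change by the delta-delta-Ct method
#'
#' Per replicate, the target Ct is normalised by the mean Ct of the
#' reference genes (arithmetic mean of Cts, i.e. geometric-mean combination
#' of expression); the fold change of the test condition relative to the
#' calibrator is `2^-(mean dCt_test - mean dCt_calibrator)`.
#'
#' @param target_ct named list of numeric replicate Ct vectors, one per
#'   condition.
#' @param reference_cts list of reference genes, each a named list like
#'   `target_ct`.
#' @param test,calibrator condition names.
#' @return list with `fold`, `ddct`, `dct` (per-condition means).
#' @export
ddct <- function(target_ct, reference_cts, test, calibrator) {
  if (!length(reference_cts)) stop("at least one reference gene required")
  for (cond in c(test, calibrator)) {
    if (is.null(target_ct[[cond]])) stop("missing condition: ", cond)
    for (r in reference_cts)
      if (is.null(r[[cond]])) stop("missing condition in reference: ", cond)
  }
  all_ct <- c(unlist(target_ct), unlist(lapply(reference_cts, unlist)))
  if (any(all_ct <= 0 | all_ct >= 45)) stop("Ct values must lie in (0, 45)")
  dct_mean <- function(cond) {
    ref <- rowMeans(vapply(reference_cts, function(r) r[[cond]],
                           numeric(length(reference_cts[[1]][[cond]]))))
    mean(target_ct[[cond]] - ref)
  }
  d_test <- dct_mean(test)
  d_cal <- dct_mean(calibrator)
  list(fold = 2^(-(d_test - d_cal)), ddct = d_test - d_cal,
       dct = c(test = d_test, calibrator = d_cal))
}

#' Flag samples that stochastically lost an expected aneuploidy
#'
#' For each sample expected to carry the aneuploidy, computes the median
#' ratio of its normalised expression over the wild-type group mean across
#' the chromosome's genes; samples with a median ratio below `threshold`
#' (default 1.2) are flagged for exclusion.
#'
#' @param counts raw counts, genes x samples.
#' @param samples data.frame with `sample`, `strain`, `condition`.
#' @param chr_genes gene ids on the aneuploid chromosome.
#' @param expected_samples sample names expected to carry the aneuploidy.
#' @param wt_strain ancestral strain label.
#' @param threshold minimum median ratio (default 1.2).
#' @return data.frame with `sample`, `median_ratio`, `flagged`.
#' @export
flag_lost_aneuploidy <- function(counts, samples, chr_genes, expected_samples,
                                 wt_strain = "WT", threshold = 1.2) {
  counts <- as.matrix(counts)
  norm <- normalize_counts(counts)
  keep <- rownames(norm) %in% chr_genes
  if (!any(keep)) stop("no chromosome genes found in counts")
  out <- lapply(expected_samples, function(sm) {
    cond <- samples$condition[samples$sample == sm]
    wt <- samples$sample[samples$strain == wt_strain & samples$condition == cond]
    wt_mean <- rowMeans(norm[keep, wt, drop = FALSE])
    ratio <- stats::median(norm[keep, sm] / pmax(wt_mean, .Machine$double.eps))
    data.frame(sample = sm, median_ratio = ratio, flagged = ratio < threshold)
  })
  do.call(rbind, out)
}
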