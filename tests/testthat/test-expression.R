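# Normalisation, fold changes, BH, null models, classes, ranks, ddCt.

test_that("median-of-ratios size factors match the independent oracle", {
  m <- matrix(rpois(40, 50), 10, 4)
  expect_equal(unname(size_factors(cbind(m[, 1], m[, 1]))), c(1, 1))

  m2 <- cbind(a = m[, 1], b = m[, 1] * 2L)
  f <- size_factors(m2)
  expect_equal(unname(f[2] / f[1]), 2, tolerance = 1e-12)

  # oracle 1: direct reimplementation on a random NB matrix
  set.seed(5)
  cnt <- matrix(rnbinom(600, mu = 80, size = 10), 100, 6,
                dimnames = list(paste0("g", 1:100), paste0("s", 1:6)))
  f <- size_factors(cnt)
  lg <- log(cnt[rowSums(cnt > 0) == 6, , drop = FALSE])
  oracle <- exp(apply(lg - rowMeans(lg), 2, median))
  expect_equal(f, oracle)

  # oracle 2: DESeq2's estimator
  expect_equal(unname(f),
               unname(DESeq2::estimateSizeFactorsForMatrix(cnt)),
               tolerance = 1e-10)

  # normalisation fixed point: factors of normalised matrix ~ 1
  expect_equal(unname(size_factors(normalize_counts(cnt))), rep(1, 6),
               tolerance = 0.05)

  expect_error(size_factors(matrix(c(0, 1, 1, 0), 2, 2)), "nonzero")
})

test_that("fold change is antisymmetric and reflects constructed ratios", {
  cnt <- matrix(c(100, 100, 200, 200,
                  50, 50, 50, 50), 2, 4, byrow = TRUE,
                dimnames = list(c("up", "flat"), paste0("s", 1:4)))
  grp <- c("B", "B", "A", "A")
  fc <- fold_change(cnt, grp, "A", "B", factors = rep(1, 4))
  expect_equal(fc$lfc[fc$gene == "up"], log2(200.5 / 100.5), tolerance = 1e-12)
  expect_equal(fc$lfc[fc$gene == "flat"], 0)
  ba <- fold_change(cnt, grp, "B", "A", factors = rep(1, 4))
  expect_equal(fc$lfc, -ba$lfc)
  expect_error(fold_change(cnt, grp, "A", "C"), "unknown group")
})

test_that("BH adjustment equals the step-up enumeration oracle", {
  set.seed(13)
  for (len in c(1, 10, 100, 1000)) {
    p <- runif(len)^2
    expect_equal(bh_adjust(p), enumerate_bh(p))
    expect_equal(bh_adjust(p), p.adjust(p, "BH"))
  }
  # constructed 10-gene example with ties
  p <- c(0.001, 0.001, 0.02, 0.03, 0.5, 0.9, 1, 0.04, 0.2, 0.0005)
  expect_equal(bh_adjust(p), enumerate_bh(p))
})

test_that("DEG filter applies the 2-fold and BH 0.01 rules", {
  tab <- data.frame(gene = paste0("g", 1:4),
                    lfc = c(2, 0.9, -1.5, 1.2))
  p <- c(1e-9, 1e-9, 1e-9, 0.5)
  out <- deg_filter(tab, p)
  # g2 excluded by fold threshold despite tiny p; g4 by adjusted p
  expect_equal(out$gene, c("g1", "g3"))
  out2 <- deg_filter(tab, rep(1, 4))
  expect_equal(nrow(out2), 0)
  expect_error(deg_filter(tab, p[1:3]), "length")
})

test_that("null expectations implement both dosage models", {
  # direct arithmetic: WT glc 100, WT mal 230, evolved glc 200, observed 690
  cnt <- matrix(c(100, 230, 200, 690), 1, 4,
                dimnames = list("AGT1", c("wg", "wm", "eg", "em")))
  cnt <- rbind(cnt, ref = c(1000, 1000, 1000, 1000))  # anchors size factors
  samples <- data.frame(sample = c("wg", "wm", "eg", "em"),
                        strain = c("WT", "WT", "ev", "ev"),
                        condition = c("glucose", "maltose", "glucose", "maltose"))
  ne <- null_expectation(cnt, samples, "AGT1", "induction",
                         factors = rep(1, 4))
  expect_equal(ne$expected, 460)
  expect_equal(ne$excess, 0.5, tolerance = 1e-12)

  # copy-number model null case: evolved exactly 2x WT in both conditions
  cnt2 <- matrix(c(100, 230, 200, 460), 1, 4,
                 dimnames = list("AGT1", c("wg", "wm", "eg", "em")))
  cnt2 <- rbind(cnt2, ref = 1000)
  ne2 <- null_expectation(cnt2, samples, "AGT1", "copy_number",
                          factors = rep(1, 4))
  expect_equal(ne2$excess, c(0, 0), tolerance = 1e-12)
  expect_error(null_expectation(cnt2, samples, "nope", "induction",
                                factors = rep(1, 4)), "not found")
})

test_that("simulated cis boost is recovered as excess over both null models", {
  # end-to-end dosage recovery, 20 seeds
  excess <- vapply(1:20, function(i) {
    w <- simulate_expression_study(sim_config(seed = i))
    ne1 <- null_expectation(w$counts, w$samples, w$focal_gene, "induction")
    ne2 <- null_expectation(w$counts, w$samples, w$focal_gene, "copy_number")
    mean(c(ne1$excess, ne2$excess[ne2$condition == "maltose"]))
  }, numeric(1))
  expect_lt(abs(mean(excess) - 0.69), 0.08)
})

test_that("aneuploid gene class shows attenuated dosage response", {
  w <- simulate_expression_study(sim_config(seed = 17), genes_per_chr = 40)
  fc <- fold_change(w$counts, w$groups, "hap1_maltose", "WT_maltose")
  cls <- gene_class_comparison(fc, w$chrxv_genes, null_lfc = 1,
                               alternative = "greater")
  # median fold strictly between 1 and 2 and near the calibrated 1.58
  expect_gt(cls$median_fold, 1.3)
  expect_lt(cls$median_fold, 1.9)
  # attenuated class is *not* significantly above the 2-fold null
  expect_gt(cls$p, 0.4)

  # attenuation = 1 restores the full 2-fold dosage response
  w2 <- simulate_expression_study(sim_config(seed = 18, attenuation = 1),
                                  genes_per_chr = 40)
  fc2 <- fold_change(w2$counts, w2$groups, "hap1_maltose", "WT_maltose")
  cls2 <- gene_class_comparison(fc2, w2$chrxv_genes, null_lfc = 1)
  expect_equal(cls2$median_fold, 2, tolerance = 0.1)

  # class centred exactly at the null: one-sided p = 0.5
  flat <- data.frame(gene = paste0("g", 1:20),
                     lfc = rep(c(-0.1, 0.1), 10))
  expect_equal(gene_class_comparison(flat, flat$gene, null_lfc = 0)$p, 0.5)
  expect_error(gene_class_comparison(flat, flat$gene[1:5], 0), "fewer than 10")
})

test_that("subtelomeric flags use the 20 kb contig-end rule", {
  expect_true(subtelomeric_flag(1, 500, 1e6))
  expect_false(subtelomeric_flag(5e5, 501000, 1e6))
  expect_true(subtelomeric_flag(979999, 980500, 1e6))  # end within 20 kb
  # excluded rDNA-adjacent end
  skip_tab <- data.frame(chromosome = "chrXII", end = "left")
  expect_false(subtelomeric_flag(1, 500, 1e6, chromosome = "chrXII",
                                 excluded_ends = skip_tab))
  expect_true(subtelomeric_flag(999000, 999500, 1e6, chromosome = "chrXII",
                                excluded_ends = skip_tab))
})

test_that("percentile rank excludes the focal gene and halves ties", {
  tab <- data.frame(gene = paste0("g", 1:5), lfc = c(5, 4, 3, 2, 1))
  expect_equal(percentile_rank(tab, "g1", tab$gene), 1)
  expect_equal(percentile_rank(tab, "g3", tab$gene), 0.5)
  # enumeration oracle on random classes with ties
  set.seed(23)
  for (i in 1:10) {
    n <- sample(5:30, 1)
    tab <- data.frame(gene = paste0("g", 1:n),
                      lfc = sample(round(rnorm(n), 1), n, replace = TRUE))
    g <- sample(tab$gene, 1)
    oracle <- {
      others <- tab$lfc[tab$gene != g]
      x <- tab$lfc[tab$gene == g]
      (sum(others < x) + 0.5 * sum(others == x)) / length(others)
    }
    expect_equal(percentile_rank(tab, g, tab$gene), oracle)
  }
})

test_that("ddCt folds match hand-computed arithmetic", {
  # all equal: fold 1
  t1 <- list(glucose = c(20, 20), maltose = c(20, 20))
  refs <- list(ACT1 = list(glucose = c(15, 15), maltose = c(15, 15)))
  expect_equal(ddct(t1, refs, "maltose", "glucose")$fold, 1)
  # target drops 1 cycle: fold 2
  t2 <- list(glucose = c(20, 20), maltose = c(19, 19))
  expect_equal(ddct(t2, refs, "maltose", "glucose")$fold, 2)
  # two references with offsets: averaged reference Ct
  refs2 <- list(ACT1 = list(glucose = c(15, 15), maltose = c(16, 16)),
                ARP2 = list(glucose = c(17, 17), maltose = c(16, 16)))
  # mean ref glc = 16, mal = 16; dCt glc = 4, mal = 3 -> fold 2
  expect_equal(ddct(t2, refs2, "maltose", "glucose")$fold, 2)
  expect_error(ddct(t2, refs, "ethanol", "glucose"), "missing condition")
  expect_error(ddct(list(glucose = 50, maltose = 20), refs, "maltose",
                    "glucose"), "\\(0, 45\\)")
})

test_that("samples that lost the aneuploidy are flagged", {
  w <- simulate_expression_study(sim_config(seed = 19))
  # fabricate a loss: overwrite one haploid maltose library with WT-like values
  lost <- "hap1_maltose_1"
  kar2 <- w$karyotypes
  kar2[lost, "chrXV"] <- 1
  cnt2 <- simulate_expression(w$genome, w$samples, kar2, w$focal_gene,
                              config = sim_config(seed = 19))
  fl <- flag_lost_aneuploidy(cnt2, w$samples, w$chrxv_genes,
                             expected_samples = c(lost, "hap1_maltose_2"))
  expect_true(fl$flagged[fl$sample == lost])
  expect_false(fl$flagged[fl$sample == "hap1_maltose_2"])
})
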