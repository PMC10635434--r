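# Generators: determinism, closed-form moments, round trips.

test_that("generators are bit-identical under a fixed seed and sub-streams are independent", {
  cfg <- sim_config(seed = 42)
  comp <- population_composition(0.3, c(chrI = 0.2), g1_fraction = 0.6)
  g <- tiny_genome()

  d1 <- simulate_depth(g, comp, config = cfg)
  d2 <- simulate_depth(g, comp, config = cfg)
  expect_identical(d1, d2)

  c1 <- simulate_cytometry(comp, 1000, cfg)
  expect_identical(c1, simulate_cytometry(comp, 1000, cfg))

  k1 <- simulate_competition(0.1, config = cfg)
  expect_identical(k1, simulate_competition(0.1, config = cfg))

  # interleaving another generator call does not perturb a stream
  d3 <- simulate_depth(g, comp, config = cfg)
  invisible(simulate_cytometry(comp, 500, cfg))
  expect_identical(d3, simulate_depth(g, comp, config = cfg))

  # global RNG state is untouched
  set.seed(7); before <- .Random.seed
  invisible(simulate_depth(g, comp, config = cfg))
  expect_identical(before, .Random.seed)
})

test_that("simulated depth matches closed-form coverage expectations", {
  g <- tiny_genome(n_chr = 6)
  # uniform diploid: window means ~ depth_mean everywhere
  d <- simulate_depth(g, population_composition(0), config = sim_config(seed = 1))
  mean_by_chr <- tapply(d$depth, d$chromosome, mean)
  expect_true(all(abs(mean_by_chr - 100) < 3 * sqrt(100 + 100^2 / 20) /
                    sqrt(500)))

  # analytic expectation oracle over 50 seeds: relative coverage of chrI.
  # A 16-chromosome genome keeps the aneuploid chromosome from shifting the
  # genome-wide median appreciably (1/16 of windows).
  g16 <- tiny_genome(n_chr = 16, len = 2e5)
  exp_cov <- function(h, a) {
    P <- h + 2 * (1 - h)
    (P + a) / P
  }
  for (case in list(list(h = 0.5, a = 0, want = 1),
                    list(h = 0, a = 0.5, want = 1.25),
                    list(h = 1, a = 0.5, want = 1.5))) {
    expect_equal(exp_cov(case$h, case$a), case$want)
    comp <- population_composition(case$h, c(chrI = case$a))
    r_hat <- mean(vapply(1:50, function(i) {
      dd <- simulate_depth(g16, comp, config = sim_config(seed = i))
      p <- relative_copy_number(dd)
      p$r[p$chromosome == "chrI"]
    }, numeric(1)))
    expect_lt(abs(r_hat - case$want), 0.02)
  }

  # haploid clone with an extra chromosome: ~2x genome median on that chromosome
  comp <- population_composition(1, c(chrII = 1))
  p <- relative_copy_number(simulate_depth(g, comp, config = sim_config(seed = 3)))
  expect_equal(p$r[p$chromosome == "chrII"], 2, tolerance = 0.05)

  expect_error(simulate_depth(g, population_composition(0), window = 50),
               "100 bp")
  expect_error(simulate_depth(g, population_composition(0), window = 6e5),
               "chrI")
})

test_that("cytometry component weights follow the shared-G1 mixing", {
  expect_equal(ploidy_mixture_weights(1, 1), c(1, 0, 0))
  expect_equal(ploidy_mixture_weights(0, 0.6), c(0, 0.6, 0.4))
  expect_equal(ploidy_mixture_weights(0.3, 0.5), c(0.15, 0.50, 0.35))

  # multinomial oracle: empirical component fractions within 3 SE at n = 10,000
  n <- 10000
  s <- simulate_cytometry(population_composition(0.3, g1_fraction = 0.5), n,
                          sim_config(seed = 8))
  # with cv = 0.08 the 1C/2C/4C components are separated by > 4 sd; classify
  # by fixed cut points
  frac <- c(mean(s < 150), mean(s >= 150 & s < 300), mean(s >= 300))
  w <- c(0.15, 0.50, 0.35)
  se <- sqrt(w * (1 - w) / n)
  expect_true(all(abs(frac - w) < 3 * se))

  # degenerate: all mass at 1C
  s1 <- simulate_cytometry(population_composition(1, g1_fraction = 1), 2000,
                           sim_config(seed = 9))
  expect_true(all(s1 < 150))
  expect_error(simulate_cytometry(population_composition(0), 100,
                                  sim_config(cytometry_cv = 0)),
               "cytometry_cv")
})

test_that("competition series follows the log-linear ratio model", {
  # neutral, noiseless: constant log ratio
  cs <- simulate_competition(0, n_transfers = 4, sampling_depth = Inf)
  lr <- log(cs$query_count / cs$competitor_count)
  expect_equal(diff(lr), rep(0, 4))

  # s = 0.25 at 3.32 gens/transfer: +0.83 per transfer
  cs <- simulate_competition(0.25, n_transfers = 4,
                             gens_per_transfer = log2(10),
                             sampling_depth = Inf)
  lr <- log(cs$query_count / cs$competitor_count)
  expect_equal(diff(lr), rep(0.25 * log2(10), 4), tolerance = 1e-10)

  # OD columns encode the dilution regime
  expect_equal(generations_from_od(cs$od_after_dilution[-1], cs$od[-1]),
               rep(log2(10), 4))
  expect_error(simulate_competition(0.1, sampling_depth = 50), "at least 100")
})

test_that("colony genotyping is a multinomial draw with configurable skew", {
  expect_equal(unname(simulate_colony_genotypes(1, 40, config = sim_config(seed = 2))[["MATa/alpha"]]), 0)
  expect_equal(unname(simulate_colony_genotypes(0, 40, config = sim_config(seed = 2))[["MATa/alpha"]]), 40)
  # binomial oracle: h = 0.74, n = 55 -> expected 40.7 haploids
  hap <- vapply(1:500, function(i) {
    x <- simulate_colony_genotypes(0.74, 55, config = sim_config(seed = i))
    sum(x[c("MATa", "MATalpha")])
  }, numeric(1))
  se <- sqrt(55 * 0.74 * 0.26) / sqrt(500)
  expect_lt(abs(mean(hap) - 40.7), 2 * se)
  # default skew: every haploid is MATa
  x <- simulate_colony_genotypes(0.74, 55, config = sim_config(seed = 1))
  expect_equal(unname(x[["MATalpha"]]), 0)
})

test_that("promoter simulation plants motifs and rejects overlaps", {
  tcs <- motif("TCS", "CATTCC")
  p <- simulate_promoter(700, list(list(seq = "CATTCC", pos = 100, strand = "+")),
                         sim_config(seed = 5))
  expect_equal(nchar(p), 700)
  expect_equal(substr(p, 101, 106), "CATTCC")
  hits <- scan_motifs(p, tcs)
  expect_true(any(hits$start == 100 & hits$strand == "+"))

  # minus-strand plant is written as reverse complement
  p2 <- simulate_promoter(700, list(list(seq = "CATTCC", pos = 300, strand = "-")),
                          sim_config(seed = 5))
  expect_equal(substr(p2, 301, 306), revcomp("CATTCC"))
  expect_true(any(scan_motifs(p2, tcs)$start == 300 &
                    scan_motifs(p2, tcs)$strand == "-"))

  expect_error(simulate_promoter(700, list(
    list(seq = "CATTCC", pos = 100, strand = "+"),
    list(seq = "CATTCC", pos = 103, strand = "+"))), "overlap")
  expect_error(simulate_promoter(100, list(
    list(seq = "CATTCC", pos = 98, strand = "+"))), "fit")

  # background hit rate of a 6-mer on both strands ~ 2 (L - 5) / 4^6
  n_hits <- mean(vapply(1:60, function(i) {
    nrow(scan_motifs(simulate_promoter(700, config = sim_config(seed = i)), tcs))
  }, numeric(1)))
  expected <- 2 * (700 - 5) / 4^6
  expect_lt(abs(n_hits - expected), 3 * sqrt(expected / 60))
})

test_that("generator outputs round-trip through writers and readers", {
  tmp <- withr::local_tempdir()
  g <- tiny_genome()
  d <- simulate_depth(g, population_composition(0.2, c(chrI = 0.1)),
                      config = sim_config(seed = 4))
  f <- file.path(tmp, "depth.tsv")
  write_depth_table(d, f)
  expect_equal(as.data.frame(read_depth_table(f)), as.data.frame(d))

  s <- simulate_cytometry(population_composition(0.5), 600, sim_config(seed = 4))
  f <- file.path(tmp, "fluor.txt")
  write_fluorescence(s, f)
  expect_equal(as.numeric(read_fluorescence(f)), as.numeric(s), tolerance = 1e-12)

  cs <- simulate_competition(0.1, config = sim_config(seed = 4))
  f <- file.path(tmp, "comp.tsv")
  write_competition_tsv(cs, f)
  expect_equal(as.data.frame(read_competition_tsv(f)), as.data.frame(cs))

  study <- simulate_expression_study(sim_config(seed = 4), genes_per_chr = 5,
                                     reps = 2)
  f <- file.path(tmp, "counts.tsv")
  write_counts_tsv(study$counts, f)
  expect_equal(read_counts_tsv(f), study$counts)

  pr <- c(p1 = simulate_promoter(300, config = sim_config(seed = 4)))
  f <- file.path(tmp, "prom.fa")
  write_promoters_fasta(pr, f)
  expect_equal(read_promoters_fasta(f), pr)
})
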