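# Small genomes and deterministic fixtures shared across test files.

tiny_genome <- function(n_chr = 4, len = 5e5, genes_per_chr = 5) {
  toy_genome(n_chromosomes = n_chr, chr_length = len,
             genes_per_chr = genes_per_chr, focal_gene = NULL)
}

# depth table built directly (no simulation): constant depth per chromosome
flat_depth <- function(depths, n_windows = 20, window = 10000) {
  do.call(rbind, lapply(names(depths), function(ch) {
    start <- (seq_len(n_windows) - 1L) * window
    data.frame(chromosome = ch, window_start = start,
               window_end = start + window, depth = depths[[ch]])
  }))
}

# exact Mann-Whitney two-sided p-value by full enumeration of group labels
enumerate_mwu_p <- function(a, b) {
  pooled <- c(a, b)
  m <- length(a)
  idx <- utils::combn(length(pooled), m)
  u_obs <- ploidyshift:::mwu_statistic(a, b)
  u_all <- apply(idx, 2, function(i)
    ploidyshift:::mwu_statistic(pooled[i], pooled[-i]))
  mu <- m * length(b) / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# step-up BH by direct definition: smallest q such that p_(i) <= q i / m
enumerate_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) adj[i] <- min(ranked[i:m] * m / (i:m))
  pmin(1, adj)[order(o)]
}

# naive motif scanner: position-by-position IUPAC comparison on both strands
naive_scan <- function(promoter, m) {
  codes <- ploidyshift:::IUPAC_CODES
  seqv <- strsplit(toupper(promoter), "")[[1]]
  hits <- data.frame(motif = character(), start = integer(),
                     strand = character())
  for (strand in c("+", "-")) {
    cons <- if (strand == "+") m$consensus else revcomp(m$consensus)
    cl <- strsplit(cons, "")[[1]]
    w <- length(cl)
    for (p in 0:(length(seqv) - w)) {
      mm <- 0
      for (j in seq_len(w))
        if (!seqv[p + j] %in% codes[[cl[j]]]) mm <- mm + 1
      if (mm <= m$max_mismatches)
        hits <- rbind(hits, data.frame(motif = m$id, start = p,
                                       strand = strand))
    }
  }
  hits
}
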