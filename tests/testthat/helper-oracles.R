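# Independent oracles, written scalar-style straight from the published
# definitions; deliberately share no code with the package internals.

# Weir & Cockerham (1984) single-locus variance components, general-r
# transcription (here r = 2), from raw dosage vectors of each population.
oracle_wc_site <- function(g_by_pop) {
  r <- length(g_by_pop)
  n <- vapply(g_by_pop, function(g) sum(!is.na(g)), numeric(1))
  if (any(n < 2)) return(c(a = NA_real_, b = NA_real_, c = NA_real_))
  p <- vapply(g_by_pop, function(g) sum(g, na.rm = TRUE) /
                (2 * sum(!is.na(g))), numeric(1))
  h <- vapply(g_by_pop, function(g) mean(g[!is.na(g)] == 1), numeric(1))
  nbar <- sum(n) / r
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) *
       (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
       ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

# ratio-of-sums F_ST over all sites of two dosage matrices (samples x sites)
oracle_wc_fst <- function(callsA, callsB) {
  num <- 0; den <- 0
  for (s in seq_len(ncol(callsA))) {
    comp <- oracle_wc_site(list(callsA[, s], callsB[, s]))
    if (any(is.na(comp))) next
    num <- num + comp["a"]
    den <- den + sum(comp)
  }
  unname(num / den)
}

# brute-force per-site nucleotide diversity: expand diploids to haplotypes
# and average pairwise differences over all haplotype pairs
oracle_pi_site <- function(g) {
  g <- g[!is.na(g)]
  if (length(g) < 2) return(NA_real_)
  hap <- unlist(lapply(g, function(d) c(rep(1L, d), rep(0L, 2L - d))))
  n <- length(hap)
  diff <- 0L; pairs <- 0L
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      diff <- diff + (hap[i] != hap[j])
      pairs <- pairs + 1L
    }
  }
  diff / pairs
}

# squared Pearson correlation from first principles over complete pairs
oracle_r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2) return(NA_real_)
  sxx <- sum((x - mean(x))^2)
  syy <- sum((y - mean(y))^2)
  if (sxx == 0 || syy == 0) return(NA_real_)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  (sxy / sqrt(sxx * syy))^2
}

# random small genotype table with matching two-population map
rand_gmat <- function(n_samples, n_sites, miss = 0.1, contig_len = 1000L) {
  calls <- matrix(sample(0:2, n_samples * n_sites, replace = TRUE),
                  n_samples, n_sites)
  calls[matrix(runif(n_samples * n_sites) < miss,
               n_samples, n_sites)] <- NA_integer_
  pos <- sort(sample.int(contig_len, n_sites))
  sites <- data.frame(contig = "c1", pos = pos, ref = "A", alt = "T",
                      stringsAsFactors = FALSE)
  ids <- sprintf("s%02d", seq_len(n_samples))
  G <- genotype_matrix(calls, sites,
                       contig_lengths = c(c1 = contig_len),
                       sample_ids = ids)
  half <- ceiling(n_samples / 2)
  popmap <- setNames(rep(c("A", "B"), c(half, n_samples - half)), ids)
  list(G = G, popmap = popmap)
}

# one window spanning a whole contig
whole_contig_window <- function(G) {
  len <- G$contig_lengths[[1]]
  data.frame(contig = names(G$contig_lengths)[1], start = 1L,
             end = as.integer(len), length = as.integer(len))
}

bundled_morpho <- function() {
  read_morpho_table(system.file("extdata", "acerana_morphometry.tsv",
                                package = "sweepscan"))
}
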