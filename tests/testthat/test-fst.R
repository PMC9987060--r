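two_pop_gmat <- function(callsA, callsB, pos = NULL) {
  calls <- rbind(callsA, callsB)
  nA <- nrow(callsA)
  ids <- sprintf("s%02d", seq_len(nrow(calls)))
  if (is.null(pos)) pos <- seq_len(ncol(calls)) * 100L
  G <- genotype_matrix(calls,
                       data.frame(contig = "c1", pos = pos,
                                  ref = "A", alt = "T"),
                       contig_lengths = c(c1 = max(pos) + 100),
                       sample_ids = ids)
  pm <- setNames(rep(c("A", "B"), c(nA, nrow(calls) - nA)), ids)
  list(G = G, popmap = pm)
}

test_that("variance components match the published-formula oracle", {
  set.seed(20)
  for (rep_i in 1:20) {
    nA <- sample(2:3, 1); nB <- sample(2:3, 1)
    S <- sample(2:5, 1)
    tp <- two_pop_gmat(matrix(sample(0:2, nA * S, TRUE), nA, S),
                       matrix(sample(0:2, nB * S, TRUE), nB, S))
    fa <- site_frequencies(tp$G, "A", tp$popmap)
    fb <- site_frequencies(tp$G, "B", tp$popmap)
    comp <- site_fst_components(fa, fb)
    for (s in seq_len(S)) {
      ora <- oracle_wc_site(list(tp$G$calls[tp$popmap == "A", s],
                                 tp$G$calls[tp$popmap == "B", s]))
      expect_equal(unlist(comp[s, ]), ora, tolerance = 1e-12,
                   ignore_attr = TRUE)
    }
  }
})

test_that("fixed difference gives F_ST = 1; identical full-het sites give a <= 0", {
  tp <- two_pop_gmat(matrix(0L, 10, 1), matrix(2L, 10, 1))
  fa <- site_frequencies(tp$G, "A", tp$popmap)
  fb <- site_frequencies(tp$G, "B", tp$popmap)
  comp <- site_fst_components(fa, fb)
  expect_equal(comp$a / (comp$a + comp$b + comp$c), 1)

  # both populations all heterozygous at p = 0.5 -> zero among-population
  # variance; hand evaluation gives a = 0, b = -1/4, c = 1/2
  tp2 <- two_pop_gmat(matrix(1L, 6, 1), matrix(1L, 6, 1))
  fa2 <- site_frequencies(tp2$G, "A", tp2$popmap)
  fb2 <- site_frequencies(tp2$G, "B", tp2$popmap)
  comp2 <- site_fst_components(fa2, fb2)
  expect_lte(comp2$a, 0)
  expect_equal(comp2$a, 0)
  expect_equal(comp2$b, -0.25)
  expect_equal(comp2$c, 0.5)
  expect_equal(comp2$a / (comp2$a + comp2$b + comp2$c), 0)
})

test_that("ratio-of-sums window F_ST equals per-site ratio for one site", {
  set.seed(31)
  tp <- two_pop_gmat(matrix(sample(0:2, 8, TRUE), 4, 2),
                     matrix(sample(0:2, 8, TRUE), 4, 2))
  w1 <- data.frame(contig = "c1", start = 50L, end = 150L, length = 101L)
  wf <- windowed_fst(tp$G, tp$popmap, "A", "B", w1, min_snps = 1)
  expect_equal(wf$n_snps, 1L)
  parts <- site_fst_components(site_frequencies(tp$G, "A", tp$popmap),
                               site_frequencies(tp$G, "B", tp$popmap))
  expect_equal(wf$fst,
               parts$a[1] / (parts$a[1] + parts$b[1] + parts$c[1]))
})

test_that("split of one population estimates F_ST near zero", {
  cfg <- sim_config(seed = 9, contigs = c(chr1 = 1e6), n_sites = 5000,
                    populations = data.frame(label = "X", n = 40L, F = 0.05),
                    sweeps = NULL, missing_rate = 0)
  sim <- simulate_population(cfg)
  pm <- setNames(rep(c("A", "B"), each = 20), sim$G$samples)
  fst <- genomewide_fst(sim$G, pm, "A", "B")
  expect_lt(abs(fst), 0.01)
  w <- enumerate_windows(sim$G$contig_lengths)
  wf <- windowed_fst(sim$G, pm, "A", "B", w)
  expect_lt(abs(mean(wf$fst, na.rm = TRUE)), 0.01)
})

test_that("Balding-Nichols F = 0.2 is recovered; Hudson agrees with W-C", {
  cfg <- sim_config(seed = 11, contigs = c(chr1 = 2e6), n_sites = 20000,
                    populations = data.frame(label = c("A", "B"),
                                             n = c(20L, 20L), F = c(0.2, 0.2)),
                    sweeps = NULL, missing_rate = 0)
  sim <- simulate_population(cfg)
  fst_wc <- genomewide_fst(sim$G, sim$popmap, "A", "B")
  fst_h <- genomewide_fst(sim$G, sim$popmap, "A", "B", estimator = "hudson")
  expect_gte(fst_wc, 0.17)
  expect_lte(fst_wc, 0.23)
  expect_lt(abs(fst_wc - fst_h), 0.02)
  w <- enumerate_windows(sim$G$contig_lengths)
  wf <- windowed_fst(sim$G, sim$popmap, "A", "B", w)
  hf <- windowed_fst(sim$G, sim$popmap, "A", "B", w, estimator = "hudson")
  expect_gte(cor(wf$fst, hf$fst, use = "complete.obs"), 0.95)
})

test_that("all-masked windows warn cleanly", {
  set.seed(4)
  tp <- two_pop_gmat(matrix(sample(0:2, 12, TRUE), 3, 4),
                     matrix(sample(0:2, 12, TRUE), 3, 4))
  w <- whole_contig_window(tp$G)
  expect_warning(wf <- windowed_fst(tp$G, tp$popmap, "A", "B", w,
                                    min_snps = 100),
                 "masked")
  expect_true(all(is.na(wf$fst)))
})

test_that("pairwise matrix: symmetry, zero diagonal, drifted pop ranks top", {
  pops <- data.frame(label = c("P1", "P2", "P3"), n = c(15L, 15L, 15L),
                     F = c(0.05, 0.05, 0.3))
  cfg <- sim_config(seed = 23, contigs = c(chr1 = 1e6), n_sites = 6000,
                    populations = pops, sweeps = NULL, missing_rate = 0)
  sim <- simulate_population(cfg)
  m <- pairwise_fst_matrix(sim$G, sim$popmap)
  expect_equal(m$fst, t(m$fst))
  expect_equal(unname(diag(m$fst)), rep(0, 3))
  expect_equal(names(which.max(m$mean_fst)), "P3")
  expect_equal(unname(m$class["P3"]), "high")

  # genome-wide fixed difference at every site -> 1
  tp <- two_pop_gmat(matrix(0L, 5, 6), matrix(2L, 5, 6))
  m2 <- pairwise_fst_matrix(tp$G, tp$popmap)
  expect_equal(m2$fst["A", "B"], 1)
})
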