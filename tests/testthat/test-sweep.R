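test_that("top-5% selection flags 50 of 1000 per statistic; ties included", {
  set.seed(8)
  fst <- runif(1000)
  lnr <- runif(1000)
  thr_f <- quantile(fst, 0.95, type = 7, names = FALSE)
  expect_equal(sum(fst >= thr_f), 50)

  # perfectly rank-correlated statistics attain the 50-window upper bound
  sel <- select_sweep_windows(fst, fst)
  expect_equal(sum(sel$selected), 50)

  # intersection of independent tails can only shrink the 5%
  sel2 <- select_sweep_windows(fst, lnr)
  expect_lte(sum(sel2$selected), 50)

  expect_error(select_sweep_windows(runif(10), runif(10)), ">= 20")
})

test_that("independent uniforms: mean intersection ~ 1000 * 0.05^2 = 2.5", {
  set.seed(3)
  sizes <- replicate(500, {
    sum(select_sweep_windows(runif(1000), runif(1000))$selected)
  })
  expect_equal(mean(sizes), 2.5, tolerance = 0.5 / 2.5)
})

test_that("masked windows are excluded from thresholds and never selected", {
  set.seed(15)
  fst <- c(runif(100), rep(NA_real_, 20))
  lnr <- c(runif(100), rep(NA_real_, 20))
  sel <- select_sweep_windows(fst, lnr)
  expect_false(any(sel$selected[101:120]))
  expect_equal(sum(sel$selected & fst >= sel$thresholds["fst"] &
                     lnr >= sel$thresholds["lnratio"]),
               sum(sel$selected))
})

test_that("region merging: overlap and bookends merge, contigs never do", {
  w <- data.frame(contig = c("c1", "c1"), start = c(1L, 10001L),
                  end = c(100000L, 110000L))
  r <- merge_regions(w, c(TRUE, TRUE))
  expect_equal(nrow(r), 1)
  expect_equal(c(r$start, r$end), c(1L, 110000L))
  expect_equal(r$n_windows, 2L)

  # bookended windows ([1,100] then [101,200]) merge into one region
  wb <- data.frame(contig = "c1", start = c(1L, 101L), end = c(100L, 200L))
  rb <- merge_regions(wb, c(TRUE, TRUE))
  expect_equal(nrow(rb), 1)
  expect_equal(c(rb$start, rb$end), c(1L, 200L))

  w2 <- data.frame(contig = c("c1", "c2"), start = c(1L, 1L),
                   end = c(100L, 100L))
  expect_equal(nrow(merge_regions(w2, c(TRUE, TRUE))), 2)

  # disjoint windows: count and bp conserved
  w3 <- data.frame(contig = "c1", start = c(1L, 301L, 601L),
                   end = c(100L, 400L, 700L))
  r3 <- merge_regions(w3, rep(TRUE, 3))
  expect_equal(nrow(r3), 3)
  expect_equal(sum(r3$end - r3$start + 1), 300)

  # idempotence: merging merged regions changes nothing
  again <- merge_regions(r3[, c("contig", "start", "end")],
                         rep(TRUE, nrow(r3)))
  expect_equal(again[, c("contig", "start", "end")],
               r3[, c("contig", "start", "end")])
})

test_that("gene-region overlap needs >= 1 shared bp (1-based inclusive)", {
  region <- data.frame(contig = "c1", start = 1L, end = 110000L)
  genes <- data.frame(
    gene_id = c("inside", "bookended"),
    contig = "c1",
    start = c(50000L, 110001L),
    end = c(60000L, 120000L),
    strand = "+")
  gm <- genes_in_regions(region, genes)
  expect_equal(gm$genes, "inside")
  expect_equal(gm$regions$gene_ids[[1]], "inside")

  # constructed truth: 10 tiled genes, 4 inside planted regions
  tiles <- data.frame(gene_id = sprintf("g%02d", 1:10), contig = "c1",
                      start = seq(1L, by = 1000L, length.out = 10),
                      end = seq(500L, by = 1000L, length.out = 10),
                      strand = "+")
  planted <- data.frame(contig = "c1", start = c(1L, 8001L),
                        end = c(3000L, 9000L))
  gm2 <- genes_in_regions(planted, tiles)
  expect_length(gm2$genes, 4)   # g01-g03 and g09
  expect_setequal(gm2$genes, c("g01", "g02", "g03", "g09"))
})

test_that("shared genes: all-way intersection and Venn partition", {
  sets <- list(X = c("a", "b", "c"), Y = c("b", "c", "d"), Z = c("c", "e"))
  sh <- shared_genes(sets)
  expect_equal(sh$intersection, "c")
  expect_equal(unname(sh$venn["X&Y&Z"]), 1L)
  expect_equal(unname(sh$venn["X&Y"]), 1L)    # b, exclusive of Z
  expect_equal(sum(sh$venn), 5L)              # a b c d e partitioned

  same <- list(A = c("x", "y"), B = c("y", "x"))
  expect_setequal(shared_genes(same)$intersection, c("x", "y"))

  disjoint <- list(A = "p", B = "q", C = "r")
  sh3 <- shared_genes(disjoint)
  expect_length(sh3$intersection, 0)
  expect_equal(unname(sh3$venn["A&B&C"]), 0L)
})

test_that("full scan recovers planted sweeps on a small fixture", {
  cfg <- sim_config(seed = 7, contigs = c(chr1 = 5e5), n_sites = 4000,
                    sweeps = data.frame(pop = "JL", contig = "chr1",
                                        start = 200001L, end = 300000L,
                                        eps = 0.02))
  sim <- simulate_population(cfg)
  Gf <- filter_sites(sim$G)
  res <- sweep_scan(Gf, sim$popmap, "SZ", "JL", genes = sim$genes)
  expect_true(any(res$windows$selected))
  rec <- evaluate_recovery(res$regions, sim$truth$regions)
  expect_gte(rec["recall"], 0.8)
  expect_gte(rec["precision"], 0.5)
  # selected windows sit inside reported regions
  selw <- res$windows[res$windows$selected, ]
  expect_true(all(selw$start >= min(res$regions$start)))
  expect_true(all(res$windows$fst[res$windows$selected] >=
                    res$thresholds["fst"]))
  # gene truth respected
  expect_true(all(sim$truth$gene_ids %in% res$genes))
})
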