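test_that("peak-TSS histogram reflects planted placements", {
  ann <- toy_annotation()
  # peaks exactly at both TSSs -> a single spike at 0
  at_tss <- data.frame(chrom = "chr1", summit = c(10000, 59999))
  h <- peak_tss_histogram(at_tss, ann, binsize = 100, range = 1000)
  expect_equal(sum(h$counts), 2L)
  zero_bin <- findInterval(0, h$breaks, rightmost.closed = TRUE)
  expect_equal(h$counts[zero_bin], 2L)

  # peaks planted uniformly around a TSS are flat within sampling error
  withr::with_seed(51, {
    u <- data.frame(chrom = "chr1",
                    summit = 10000 + sample(-9999:9999, 4000, replace = TRUE))
    hu <- peak_tss_histogram(u, ann, binsize = 2000, range = 8000)
    inner <- hu$counts
    expect_lt(max(abs(inner - mean(inner))) / mean(inner), 0.25)
  })

  # promoter-planted excess shows up in the central bins
  spec <- small_spec(seed = 13, category_factors = c("0-2k|upstream" = 8))
  g <- make_genome(spec)
  pk <- plant_peaks(spec, g$annotation, n_peaks = 800)
  hp <- peak_tss_histogram(pk$peaks, g$annotation, binsize = 2000,
                           range = 10000)
  central <- hp$counts[hp$mids > -2000 & hp$mids < 2000]
  flank <- hp$counts[abs(hp$mids) > 6000]
  expect_gt(mean(central), 2 * mean(flank))
})

test_that("histogram counts are conserved and reflect under mirroring", {
  withr::with_seed(52, {
    d <- sample(-480:480, 300, replace = TRUE)
    d <- d[d %% 20 != 0]  # off bin boundaries: reflection is exact there
    h <- peakodds:::new_distance_histogram(d, binsize = 20, range = 500)
    expect_equal(sum(h$counts), length(d))
    hm <- peakodds:::new_distance_histogram(-d, binsize = 20, range = 500)
    expect_equal(hm$counts, rev(h$counts))
  })
})

test_that("best occurrence per gene minimises corrected p with 5'-most ties", {
  occ <- data.frame(gene_id = c("g1", "g1", "g1", "g2", "g3", "g3"),
                    motif = c("AP1", "AP1", "AP1", "AP1", "SP1", "SP1"),
                    pos = c(500, 100, 900, 250, 40, 10),
                    corrected_p = c(0.01, 0.001, 0.001, 0.2, 0.05, 0.05))
  sel <- select_best_motif_per_gene(occ)
  expect_equal(sel[sel$gene_id == "g1", ]$pos, 100)   # best p, 5'-most tie
  expect_equal(sel[sel$gene_id == "g2", ]$pos, 250)   # single hit -> itself
  expect_equal(sel[sel$gene_id == "g3", ]$pos, 10)    # pure tie -> 5'-most
  expect_equal(nrow(sel), 3L)
  # deterministic across repeated calls and row order
  sel2 <- select_best_motif_per_gene(occ[sample(nrow(occ)), ])
  expect_equal(sel2[order(sel2$gene_id)]$pos, sel[order(sel$gene_id)]$pos)
})

test_that("intermotif distances capture planted offsets and the cutoff", {
  mk_sel <- function(qpos) {
    rbind(data.frame(gene_id = sprintf("g%d", seq_along(qpos)), motif = "RelA",
                     pos = 1000, corrected_p = 1e-4),
          data.frame(gene_id = sprintf("g%d", seq_along(qpos)), motif = "AP1",
                     pos = qpos, corrected_p = 1e-3))
  }
  # constant offset -> single spike at +100
  h <- intermotif_distances(mk_sel(rep(1100, 50)), "RelA", "AP1")
  expect_equal(sum(h$counts), 50L)
  expect_equal(h$mids[which.max(h$counts)], 105)

  # symmetric +/-100 planting -> bimodal spikes
  withr::with_seed(53, {
    qpos <- 1000 + sample(c(-100, 100), 80, replace = TRUE)
    hb <- intermotif_distances(mk_sel(qpos), "RelA", "AP1", binsize = 20)
    top2 <- order(hb$counts, decreasing = TRUE)[1:2]
    expect_setequal(sign(hb$mids[top2]), c(-1, 1))
    expect_true(all(abs(abs(hb$mids[top2]) - 100) <= 20))
  })

  # pairs beyond the cutoff are excluded
  h600 <- intermotif_distances(mk_sel(rep(1600, 10)), "RelA", "AP1",
                               max_distance = 500)
  expect_equal(sum(h600$counts), 0L)

  expect_warning(
    empty <- intermotif_distances(mk_sel(1100)[1, ], "RelA", "AP1"),
    "no shared genes")
  expect_equal(sum(empty$counts), 0L)
})

test_that("planted spacings are recovered as histogram modes", {
  withr::with_seed(54, {
    for (delta in c(-200, -100, -50, 50, 100, 200)) {
      qpos <- 2000 + delta + sample(-5:5, 60, replace = TRUE)
      sel <- rbind(data.frame(gene_id = sprintf("g%d", 1:60), motif = "datum",
                              pos = 2000, corrected_p = 1e-4),
                   data.frame(gene_id = sprintf("g%d", 1:60), motif = "query",
                              pos = qpos, corrected_p = 1e-3))
      h <- intermotif_distances(sel, "datum", "query", binsize = 25)
      mode_mid <- h$mids[which.max(h$counts)]
      expect_lt(abs(mode_mid - delta), 25)
    }
  })
})

test_that("chi-squared co-occurrence matches the closed form", {
  pres <- matrix(c(rep(c(TRUE, TRUE), 30), rep(c(TRUE, FALSE), 10),
                   rep(c(FALSE, TRUE), 10), rep(c(FALSE, FALSE), 30)),
                 ncol = 2, byrow = TRUE, dimnames = list(NULL, c("m1", "m2")))
  cell <- cooccurrence_chi2(pres, c("m1", "m2"))
  expect_equal(cell$chi2, 20)  # E = 20 per cell, sum((O-E)^2/E) = 4 * 5
  expect_equal(cell$direction, "enriched")
  # agrees with the uncorrected Pearson test
  expect_equal(cell$chi2,
               unname(stats::chisq.test(table(pres[, 1], pres[, 2]),
                                        correct = FALSE)$statistic))

  # identical presence vectors reach the maximum chi2 = N
  ident <- cbind(m1 = rep(c(TRUE, FALSE), each = 25),
                 m2 = rep(c(TRUE, FALSE), each = 25))
  expect_equal(cooccurrence_chi2(ident, c("m1", "m2"))$chi2, 50)

  # degenerate margins give 0 / neither
  degen <- cbind(m1 = rep(TRUE, 20), m2 = rep(c(TRUE, FALSE), 10))
  cd <- cooccurrence_chi2(degen, c("m1", "m2"))
  expect_equal(cd$chi2, 0)
  expect_equal(cd$direction, "neither")
  expect_error(cooccurrence_chi2(degen[1, , drop = FALSE], c("m1", "m2")),
               class = "peakodds_invalid_input")
})

test_that("chi-squared is symmetric under motif swap and joint relabeling", {
  withr::with_seed(55, {
    for (i in 1:20) {
      pres <- cbind(a = runif(200) < 0.4, b = runif(200) < 0.6)
      c1 <- cooccurrence_chi2(pres, c("a", "b"))$chi2
      c2 <- cooccurrence_chi2(pres, c("b", "a"))$chi2
      c3 <- cooccurrence_chi2(!pres, c("a", "b"))$chi2
      expect_equal(c1, c2)
      expect_equal(c1, c3)
    }
  })
})

test_that("independent presences rarely exceed the chi2 critical value", {
  withr::with_seed(56, {
    stats <- replicate(100, {
      pres <- cbind(a = runif(5000) < 0.3, b = runif(5000) < 0.5)
      cooccurrence_chi2(pres, c("a", "b"))$chi2
    })
    expect_gte(mean(stats < 3.84), 0.9)
  })
})

test_that("the pairwise co-occurrence matrix covers all motif pairs", {
  withr::with_seed(57, {
    pres <- cbind(a = runif(100) < 0.5, b = runif(100) < 0.5,
                  c = runif(100) < 0.5)
    m <- cooccurrence_matrix(pres)
    expect_equal(nrow(m), 3L)
    expect_true(all(m$chi2 >= 0))
  })
})
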