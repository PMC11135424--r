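test_that("exon windows clip at the chromosome start and keep strand", {
  ex <- GRanges("chr1", IRanges(1001, 1100), strand = "+")
  w <- exonWindow(ex, 5000)
  expect_equal(start(w), 1L)
  expect_equal(end(w), 6100L)
  ex2 <- GRanges("chr1", IRanges(10001, 10100), strand = "-")
  w2 <- exonWindow(ex2, 1000)
  expect_equal(c(start(w2), end(w2)), c(9001L, 11100L))
  expect_equal(as.character(strand(w2)), "-")
  expect_error(exonWindow(ex, 0), "positive")
})

test_that("window overlap respects half-open BED abutment", {
  # BED window [0, 6100) vs peaks [5900, 6000) and [6100, 6200)
  ex <- GRanges("chr1", IRanges(1001, 1100), strand = "+")
  inside <- GRanges("chr1", IRanges(5901, 6000))
  abutting <- GRanges("chr1", IRanges(6101, 6200))
  expect_true(isBound(ex, inside, 5000))
  expect_false(isBound(ex, abutting, 5000))
  expect_false(suppressWarnings(isBound(ex, GRanges("chr9", IRanges(1, 10)), 5000)))
})

test_that("enrichment matches the quoted 8/10 vs 2/10 worked example", {
  # 10 fg exons (8 bound) and 10 bg exons (2 bound), far apart
  mk <- function(n, offset) GRanges("chr1",
                                    IRanges(offset + (0:(n - 1)) * 100000,
                                            width = 100), strand = "+")
  fg <- mk(10, 1e6)
  bg <- mk(10, 5e7)
  peaks <- c(exonWindow(fg[1:8], 100), exonWindow(bg[1:2], 100))
  strand(peaks) <- "*"
  res <- enrichmentVsBackground(fg, bg, peaks, window_bp = 1000)
  expect_equal(res@n_fg_bound, 8L)
  expect_equal(res@n_bg_bound, 2L)
  expect_equal(res@ratio, 4)
  expect_equal(res@p_value, 0.023, tolerance = 1e-2)
  expect_equal(res@p_value, fisherOracleP(8, 2, 2, 8), tolerance = 1e-10)
  # swapping fg and bg inverts the ratio
  swapped <- enrichmentVsBackground(bg, fg, peaks, window_bp = 1000)
  expect_equal(swapped@ratio, 1 / res@ratio)
  # identical sets: ratio 1, p 1
  same <- enrichmentVsBackground(fg, fg, peaks, window_bp = 1000)
  expect_equal(same@ratio, 1)
  expect_equal(same@p_value, 1)
})

test_that("Fisher p equals exhaustive enumeration on all small tables", {
  for (a in c(0, 1, 3, 7)) for (b in c(0, 2, 5)) {
    for (cc in c(1, 4)) for (d in c(0, 3, 8)) {
      if (a + cc == 0 || b + d == 0 || a + b == 0 || cc + d == 0) next
      tab <- matrix(c(a, b, cc, d), 2)
      expect_equal(fisher.test(tab)$p.value, fisherOracleP(a, b, cc, d),
                   tolerance = 1e-10)
    }
  }
})

test_that("directional occupancy follows transcription direction", {
  plus <- GRanges("chr1", IRanges(10000, 10150), strand = "+")
  minus <- GRanges("chr1", IRanges(10000, 10150), strand = "-")
  peak_right <- GRanges("chr1", IRanges(10351, 10450))  # 200 bp past 3' end
  occ_p <- directionalOccupancy(plus, peak_right, 5000)
  expect_true(occ_p$downstream)
  expect_false(occ_p$upstream)
  # same genomic arrangement on the minus strand flips the call
  occ_m <- directionalOccupancy(minus, peak_right, 5000)
  expect_false(occ_m$downstream)
  expect_true(occ_m$upstream)
  # a peak overlapping the exon body counts for neither flank
  body <- GRanges("chr1", IRanges(10100, 10400))
  occ_b <- directionalOccupancy(plus, body, 5000)
  expect_false(occ_b$downstream)
  expect_false(occ_b$upstream)
})

test_that("uniform peak placement produces no directional excess", {
  cfg <- simConfig(seed = 31, n_genes = 500, n_true_events = 0,
                   peak_bg_rate = 40, genome_len = 1.3e7)
  ann <- simulateAnnotation(cfg, sequence = FALSE)
  jc <- simulateJunctionCounts(cfg, ann)
  pk <- simulatePeaks(ann, jc$truth, cfg)
  occ <- directionalOccupancy(annotationEvents(ann), pk$peaks, 5000)
  d_only <- sum(occ$downstream & !occ$upstream)
  u_only <- sum(occ$upstream & !occ$downstream)
  # two-sided sign test on discordant exons
  p <- binom.test(d_only, d_only + u_only, 0.5)$p.value
  expect_gt(p, 0.01)
})

test_that("uniform peaks keep the enrichment ratio near 1", {
  cfg <- simConfig(seed = 32, n_genes = 500, n_true_events = 150,
                   prob_up = 1, peak_fg_prob = 0, peak_bg_rate = 40,
                   genome_len = 1.3e7)
  ann <- simulateAnnotation(cfg, sequence = FALSE)
  jc <- suppressWarnings(simulateJunctionCounts(cfg, ann))
  pk <- simulatePeaks(ann, jc$truth, cfg)
  fg <- annotationEvents(ann)[jc$truth$true_event]
  res <- enrichmentVsBackground(fg, annotationExons(ann), pk$peaks, 5000)
  expect_lt(abs(res@ratio - 1), 0.15)
})

test_that("null enrichment p-values are calibrated across datasets", {
  cfg0 <- simConfig(seed = 33, n_genes = 300, n_true_events = 100,
                    prob_up = 1, peak_fg_prob = 0, peak_bg_rate = 40,
                    genome_len = 8e6)
  ann <- simulateAnnotation(cfg0, sequence = FALSE)
  jc <- suppressWarnings(simulateJunctionCounts(cfg0, ann))
  fg <- annotationEvents(ann)[jc$truth$true_event]
  bg <- annotationExons(ann)
  ps <- vapply(seq_len(200), function(i) {
    cfg <- simConfig(seed = 33 + i, n_genes = 300, n_true_events = 100,
                     prob_up = 1, peak_fg_prob = 0, peak_bg_rate = 40,
                     genome_len = 8e6)
    pk <- simulatePeaks(ann, jc$truth, cfg)
    enrichmentVsBackground(fg, bg, pk$peaks, 5000)@p_value
  }, numeric(1))
  # the exact test is discrete and mildly super-uniform under the null, so
  # calibration is checked as bounds on the empirical CDF rather than a KS
  # equality test: never anti-conservative, and not degenerate either
  for (alpha in c(0.01, 0.05, 0.1, 0.2))
    expect_lte(mean(ps < alpha),
               alpha + 2 * sqrt(alpha * (1 - alpha) / length(ps)))
  expect_gt(mean(ps < 0.5), 0.2)
})

test_that("gene-set enrichment matches the hypergeometric tail", {
  universe <- sprintf("g%02d", 1:20)
  sets <- list(hit = universe[3:7], other = universe[10:13],
               outside = c("zz1", "zz2"))
  query <- universe[1:8]
  expect_warning(res <- genesetEnrichment(query, sets, universe), "disjoint")
  expect_equal(nrow(res), 2)
  k <- length(intersect(query, sets$hit))
  expect_equal(res$p_value[res$set == "hit"],
               hyperUpperOracle(k, 5, 20, 8), tolerance = 1e-12)
  expect_true(all(res$p_value <= 1))
  expect_equal(res$q_value, p.adjust(res$p_value, "BH"))
  expect_error(genesetEnrichment(c(query, "nope"), sets, universe), "subset")
})
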