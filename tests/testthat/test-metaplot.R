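flatTrack <- function(value = 2, len = 1e5) {
  GRanges("chr1", IRanges(1, len), score = value)
}

test_that("profiles have the documented 101-bin layout", {
  ex <- GRanges("chr1", IRanges(50000, 50150), strand = "+")
  m <- profileExons(ex, flatTrack())
  expect_equal(ncol(m), 101)
  expect_equal(attr(m, "offsets"), seq(-2500, 2500, 50))
  expect_true(all(m == 2))
})

test_that("minus-strand profiles are reported in transcription direction", {
  # bump 500 bp 3' of a minus-strand exon lies at lower coordinates
  ex <- GRanges("chr1", IRanges(50000, 50100), strand = "-")
  mid <- floor((50000 + 50100) / 2)
  bump_at <- mid - 500
  track <- c(GRanges("chr1", IRanges(1, bump_at - 10), score = 1),
             GRanges("chr1", IRanges(bump_at - 9, bump_at + 10), score = 9),
             GRanges("chr1", IRanges(bump_at + 11, 1e5), score = 1))
  m <- profileExons(ex, track)
  expect_equal(unname(which.max(m[1, ])), which(attr(m, "offsets") == 500))
})

test_that("profiles near the contig start are clipped and flagged", {
  ex <- GRanges("chr1", IRanges(300, 400), strand = "+")
  m <- profileExons(ex, flatTrack())
  expect_true(attr(m, "clipped")[1])
  expect_false(anyNA(m[1, attr(m, "offsets") > 0]))
})

test_that("per-exon bin sums and per-bin means agree (conservation)", {
  cfg <- simConfig(seed = 41, n_genes = 20, n_true_events = 10, prob_up = 1,
                   peak_fg_prob = 1, peak_bg_rate = 0, genome_len = 8e5)
  ann <- simulateAnnotation(cfg, sequence = FALSE)
  jc <- suppressWarnings(simulateJunctionCounts(cfg, ann))
  pk <- simulatePeaks(ann, jc$truth, cfg)
  tr <- simulateSignalTrack(ann, pk$peaks, cfg)
  m <- profileExons(annotationEvents(ann), tr)
  expect_equal(mean(rowSums(m)), sum(colMeans(m)), tolerance = 1e-9)
})

test_that("profiles are invariant under genome mirroring with strand flip", {
  cfg <- simConfig(seed = 42, n_genes = 15, n_true_events = 10, prob_up = 1,
                   peak_fg_prob = 1, peak_bg_rate = 0, genome_len = 8e5,
                   n_chrom = 1L)
  ann <- simulateAnnotation(cfg, sequence = FALSE)
  jc <- suppressWarnings(simulateJunctionCounts(cfg, ann))
  pk <- simulatePeaks(ann, jc$truth, cfg)
  tr <- simulateSignalTrack(ann, pk$peaks, cfg)
  L <- unname(seqlengths(annotationExons(ann))["chr1"])
  ev <- annotationEvents(ann)
  m1 <- profileExons(ev, tr)
  tr_m <- mirrorRanges(tr, L)
  ev_m <- mirrorRanges(ev, L)
  m2 <- profileExons(ev_m, tr_m)
  expect_equal(unname(m1), unname(m2), tolerance = 1e-12)
})

test_that("per-bin Wilcoxon matches the exhaustive rank-permutation oracle", {
  mk <- function(v) {
    m <- matrix(v, ncol = 1)
    attr(m, "offsets") <- 0
    m
  }
  cmp <- compareProfiles(mk(c(1, 2, 3)), mk(c(4, 5, 6)))
  expect_equal(cmp@p[1], 0.1)
  expect_equal(cmp@p[1], wilcoxOracleP(c(1, 2, 3), c(4, 5, 6)))
  set.seed(7)
  for (i in 1:10) {
    a <- round(runif(sample(3:6, 1)), 3)
    b <- round(runif(sample(3:6, 1)), 3)
    expect_equal(compareProfiles(mk(a), mk(b))@p[1], wilcoxOracleP(a, b),
                 tolerance = 1e-12)
  }
  same <- compareProfiles(mk(c(1, 2, 3)), mk(c(1, 2, 3)))
  expect_equal(same@p[1], 1)
})

test_that("direction split requires both groups", {
  ev <- GRanges("chr1", IRanges(c(1e4, 2e4), width = 100), strand = "+",
                direction = c("included-in-mutant", "included-in-mutant"))
  expect_error(includedVsExcludedProfile(ev, flatTrack()), "empty group")
})

test_that("paused sites sit at signal maxima above the quantile threshold", {
  ex <- GRanges("chr1", IRanges(49900, 50100), strand = "+")
  peak_pos <- 51000
  track <- c(GRanges("chr1", IRanges(1, peak_pos - 1), score = 1),
             GRanges("chr1", IRanges(peak_pos, peak_pos + 50), score = 10),
             GRanges("chr1", IRanges(peak_pos + 51, 1e5), score = 1))
  sites <- findPausedSites(track, ex, window_bp = 5000, q = 0.9)
  expect_length(sites, 1)
  expect_equal(start(sites), peak_pos)
  # flat track: nothing exceeds the genome-wide quantile
  expect_length(findPausedSites(flatTrack(), ex, 5000, 0.9), 0)
})
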