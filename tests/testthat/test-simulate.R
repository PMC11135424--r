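test_that("annotation layout matches the configuration", {
  cfg <- simConfig(seed = 5, n_genes = 10, exons_per_gene = 3,
                   genome_len = 6e5)
  ann <- simulateAnnotation(cfg)
  expect_length(annotationExons(ann), 30)
  expect_length(annotationEvents(ann), 10)
  expect_setequal(unique(annotationExons(ann)$role),
                  c("constitutive", "cassette"))
  expect_true(all(c("+", "-") %in% as.character(strand(annotationGenes(ann)))))
  # exons of a transcript never overlap and sit inside the gene span
  ex <- annotationExons(ann)
  for (g in unique(ex$gene_id)) {
    e <- sort(ex[ex$gene_id == g])
    expect_true(all(start(e)[-1] > end(e)[-length(e)]))
  }
  expect_error(simulateAnnotation(simConfig(seed = 5, n_genes = 50,
                                            genome_len = 1e5)),
               "too small")
})

test_that("junction counts converge to true PSI at high depth", {
  cfg <- simConfig(seed = 7, n_genes = 60, n_true_events = 0,
                   genome_len = 2.5e6, dispersion = 0, read_depth = 1e5)
  ann <- simulateAnnotation(cfg, sequence = FALSE)
  jc <- suppressWarnings(simulateJunctionCounts(cfg, ann))
  expect_true(all(jc$truth$psi_control == jc$truth$psi_mutant))
  psi <- computePsi(jc$counts)$group
  m <- merge(psi, jc$truth, by = "event_id")
  expect_lt(max(abs(m$psi - m$psi_control)), 0.01)
})

test_that("effects beyond the PSI range are clamped and recorded", {
  cfg <- simConfig(seed = 8, n_genes = 50, n_true_events = 50,
                   genome_len = 2e6, delta_psi_effect = 0.6, prob_up = 1)
  ann <- simulateAnnotation(cfg, sequence = FALSE)
  expect_warning(jc <- simulateJunctionCounts(cfg, ann), "clamped")
  expect_true(any(jc$truth$clamped))
  expect_true(all(jc$truth$psi_mutant <= 0.99 & jc$truth$psi_mutant >= 0.01))
})

test_that("planted peaks sit downstream of excluded exons, strand-aware", {
  cfg <- simConfig(seed = 9, n_genes = 40, n_true_events = 30, prob_up = 1,
                   peak_fg_prob = 1, peak_bg_rate = 0, genome_len = 1.6e6)
  ann <- simulateAnnotation(cfg, sequence = FALSE)
  jc <- suppressWarnings(simulateJunctionCounts(cfg, ann))
  pk <- simulatePeaks(ann, jc$truth, cfg)
  excl <- jc$truth$event_id[jc$truth$true_event & jc$truth$delta_psi > 0]
  expect_setequal(pk$peaks$event_id, excl)
  expect_equal(length(pk$peaks), length(excl))  # exactly one peak each
  ev <- annotationEvents(ann)[pk$peaks$event_id]
  plus <- as.character(strand(ev)) == "+"
  expect_true(all(start(pk$peaks)[plus] > end(ev)[plus]))
  expect_true(all(end(pk$peaks)[!plus] < start(ev)[!plus]))
  # offsets respect the configured range
  off <- ifelse(plus, start(pk$peaks) - end(ev) - 1,
                start(ev) - end(pk$peaks) - 1)
  expect_true(all(off >= 0 & off <= cfg@peak_offset_range))
})

test_that("planted peak count stays within binomial bounds", {
  cfg <- simConfig(seed = 10, n_genes = 220, n_true_events = 200,
                   prob_up = 1, peak_fg_prob = 0.5, peak_bg_rate = 0,
                   genome_len = 7e6)
  ann <- simulateAnnotation(cfg, sequence = FALSE)
  jc <- suppressWarnings(simulateJunctionCounts(cfg, ann))
  n_excl <- sum(jc$truth$true_event & jc$truth$delta_psi > 0)
  pk <- simulatePeaks(ann, jc$truth, cfg)
  n_planted <- sum(pk$peaks$planted)
  ci <- qbinom(c(0.005, 0.995), n_excl, 0.5)
  expect_gte(n_planted, ci[1])
  expect_lte(n_planted, ci[2])
})

test_that("signal track is flat at 1 without bumps and noise", {
  cfg <- simConfig(seed = 11, n_genes = 15, genome_len = 8e5,
                   stall_amplitude = 0, track_noise_sd = 0, peak_fg_prob = 1,
                   n_true_events = 10, prob_up = 1)
  ann <- simulateAnnotation(cfg, sequence = FALSE)
  jc <- suppressWarnings(simulateJunctionCounts(cfg, ann))
  pk <- simulatePeaks(ann, jc$truth, cfg)
  tr <- simulateSignalTrack(ann, pk$peaks, cfg)
  expect_true(all(tr$score == 1))
  # full genome covered exactly once
  expect_equal(sum(width(tr)), sum(seqlengths(annotationExons(ann))))
  expect_true(all(width(reduce(granges(tr))) ==
                    seqlengths(annotationExons(ann))))
})

test_that("stalling bumps match the analytic Gaussian average", {
  cfg <- simConfig(seed = 12, n_genes = 40, n_true_events = 30, prob_up = 1,
                   peak_fg_prob = 1, peak_bg_rate = 0, track_noise_sd = 0,
                   genome_len = 1.6e6)
  ann <- simulateAnnotation(cfg, sequence = FALSE)
  jc <- suppressWarnings(simulateJunctionCounts(cfg, ann))
  pk <- simulatePeaks(ann, jc$truth, cfg)
  tr <- simulateSignalTrack(ann, pk$peaks, cfg)
  ev <- annotationEvents(ann)
  bump <- ev[ev$event_id %in% pk$peaks$event_id]
  plain <- ev[!ev$event_id %in% pk$peaks$event_id]
  mid_val <- trackValue(tr, as.character(seqnames(bump)),
                        floor((start(bump) + end(bump)) / 2))
  expect_true(all(mid_val > 2.5))  # bump center far above background
  mean_bump <- mean(rowMeans(profileExons(bump, tr)))
  mean_plain <- mean(rowMeans(profileExons(plain, tr)))
  sigma <- cfg@stall_sd
  analytic <- cfg@stall_amplitude * sigma * sqrt(2 * pi) *
    (pnorm(2525 / sigma) - pnorm(-2525 / sigma)) / 5050
  expect_lt(abs((mean_bump - mean_plain) - analytic), 0.05 * analytic)
})

test_that("noise-free screen plates give unit fold changes off the controls", {
  cfg <- simConfig(seed = 13, ct_noise_sd = 0, screen_effect = 0,
                   screen_pos_effect = 0, screen_n_hits = 0,
                   screen_undetected_frac = 0)
  sp <- simulateScreenPlate(cfg)
  fc <- splicechrom:::screenFoldChanges(sp$plate)
  expect_true(all(abs(fc$psi_fc_exon5 - 1) < 1e-12))
  expect_true(all(abs(fc$psi_fc_exon21 - 1) < 1e-12))
  expect_true(all(fc$detected))
})

test_that("null methylation simulation shows no group difference", {
  cfg <- simConfig(seed = 14, n_cpgs = 500L, meth_coverage = 100,
                   meth_beta_a = c(12, 8), meth_beta_b = c(12, 8))
  mm <- simulateMethylationCounts(cfg)
  cm <- compareMethylation(mm$counts)
  expect_lt(abs(cm$mean_diff), 0.02)
})

test_that("zero-coverage CpGs are emitted and receive no beta", {
  cfg <- simConfig(seed = 15, n_cpgs = 300L, meth_coverage = 1)
  mm <- simulateMethylationCounts(cfg)
  withb <- computeBetas(mm$counts)
  zero <- withb$m_count + withb$u_count == 0
  expect_gt(sum(zero), 0)
  expect_true(all(is.na(withb$beta[zero])))
})

test_that("peakFgProbForRatio solves the planted-ratio algebra", {
  p <- peakFgProbForRatio(2.25, 8, 5000, 150, 300, 500, 4500)
  q <- 1 - exp(-8 / 1e6 * (2 * 5000 + 150 + 300))
  f <- 1 - (1 - p) * (1 - q)
  measured <- f / ((4000 * q + 500 * f) / 4500)
  expect_equal(measured, 2.25, tolerance = 1e-10)
  expect_error(peakFgProbForRatio(50, 8), "unattainable")
})
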