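test_that("PSI follows the effective-length-normalized formula", {
  counts <- data.frame(event_id = c("e1", "e2", "e3"), group = "control",
                       replicate = 1,
                       inc_reads = c(30, 0, 5), skp_reads = c(10, 7, 0),
                       len_inc = 2, len_skp = 1)
  psi <- computePsi(counts)$replicate$psi
  expect_equal(psi, c(15 / 25, 0, 1))
})

test_that("PSI is invariant to common scaling of both effective lengths", {
  base <- data.frame(event_id = "e", group = "g", replicate = 1,
                     inc_reads = 37, skp_reads = 18, len_inc = 2, len_skp = 1)
  scaled <- transform(base, len_inc = len_inc * 7, len_skp = len_skp * 7)
  expect_equal(computePsi(base)$replicate$psi,
               computePsi(scaled)$replicate$psi)
})

test_that("replicates without informative reads are excluded with a warning", {
  counts <- data.frame(event_id = "e", group = c("control", "control"),
                       replicate = 1:2,
                       inc_reads = c(0, 10), skp_reads = c(0, 10),
                       len_inc = 1, len_skp = 1)
  expect_warning(res <- computePsi(counts), "zero informative")
  expect_true(is.na(res$replicate$psi[1]))
  expect_equal(res$group$psi, 0.5)  # pooled over the informative replicate
})

test_that("the event LRT matches direct likelihood evaluation", {
  # identical groups: statistic 0, p 1
  expect_equal(testEvent(50, 50, 50, 50)$p_value, 1)
  # closed-form check at theta1 = 0.5, theta2 = 0.9, shared 0.7
  res <- testEvent(50, 50, 90, 10)
  ll <- function(i, s, p) i * log(p) + s * log(1 - p)
  stat <- 2 * (ll(50, 50, 0.5) + ll(90, 10, 0.9) -
                 ll(140, 60, 0.7))
  expect_equal(res$statistic, stat, tolerance = 1e-12)
  expect_equal(res$p_value, pchisq(stat, 1, lower.tail = FALSE))
  # grid-search oracle agrees on assorted tables
  for (tab in list(c(3, 9, 14, 2), c(20, 5, 11, 30), c(1, 1, 40, 2))) {
    expect_equal(testEvent(tab[1], tab[2], tab[3], tab[4])$statistic,
                 lrtOracleStat(tab[1], tab[2], tab[3], tab[4]),
                 tolerance = 1e-4)
  }
  # symmetry under group relabeling
  expect_equal(testEvent(50, 50, 90, 10)$p_value,
               testEvent(90, 10, 50, 50)$p_value)
  # no informative reads -> NA
  expect_true(is.na(testEvent(0, 0, 5, 5)$p_value))
})

test_that("event calling applies BH jointly with all three filters", {
  events <- data.frame(
    event_id = c("a", "b", "c"),
    gene_id = c("g1", "g2", "g3"),
    delta_psi = c(0.12, 0.12, -0.3),
    p_value = c(0.01, 0.02, 0.04),
    gene_tpm = c(5, 0.4, 5)
  )
  called <- callEvents(events)
  # hand-computed BH step-up: q = (0.03, 0.03, 0.04)
  expect_equal(called$fdr, c(0.03, 0.03, 0.04))
  expect_equal(called$called, c(TRUE, FALSE, TRUE))  # b fails TPM > 1
  expect_equal(called$direction,
               c("included-in-mutant", "ns", "excluded-in-mutant"))

  # dPSI filter is strict: |dPSI| must exceed 0.1
  edge <- callEvents(data.frame(event_id = "e", gene_id = "g",
                                delta_psi = 0.1, p_value = 1e-5,
                                gene_tpm = 10))
  expect_false(edge$called)
  expect_equal(nrow(callEvents(events[0, ])), 0)
})

test_that("direction summary partitions called events", {
  events <- data.frame(
    event_id = letters[1:5], gene_id = letters[1:5], event_type = "SE",
    delta_psi = c(0.3, 0.4, 0.2, -0.5, 0.2),
    p_value = c(1e-5, 1e-5, 1e-5, 1e-5, 0.9), gene_tpm = 10
  )
  s <- summarizeDirection(callEvents(events))
  expect_equal(s$n_called, 4)
  expect_equal(s$frac_included, 0.75)
  expect_equal(s$frac_excluded, 0.25)
  empty <- summarizeDirection(callEvents(events[0, ]))
  expect_true(is.na(empty$frac_included))
})

test_that("DE/AS overlap test agrees with hypergeometric enumeration", {
  universe <- sprintf("g%02d", 1:20)
  as_genes <- universe[1:8]
  de_genes <- universe[5:9]
  res <- overlapDeAs(as_genes, de_genes, universe)
  expect_equal(res$overlap, 4)
  expect_equal(res$p_value, fisherOracleP(4, 4, 1, 11), tolerance = 1e-10)
  expect_equal(overlapDeAs(universe[1:3], universe[10:12], universe)$overlap, 0)
  expect_equal(overlapDeAs(as_genes, as_genes, universe)$overlap, 8)
  expect_error(overlapDeAs(c(as_genes, "zz"), de_genes, universe), "subset")
})

test_that("called direction tracks the planted effect sign", {
  cfg <- simConfig(seed = 21, n_genes = 120, n_true_events = 60, prob_up = 1,
                   read_depth = 300, dispersion = 0, genome_len = 4e6,
                   tpm_low_frac = 0)
  ann <- simulateAnnotation(cfg, sequence = FALSE)
  jc <- suppressWarnings(simulateJunctionCounts(cfg, ann))
  called <- callEvents(testSplicing(jc$counts, jc$expression))
  s <- summarizeDirection(called)
  expect_gt(s$frac_included, 0.95)
})
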