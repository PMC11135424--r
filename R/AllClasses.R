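#' Simulation configuration
#'
#' Holds every tunable parameter of the synthetic-data generators. Identical
#' configurations (same seed included) produce bit-identical outputs. Defaults
#' reproduce the study design the generators emulate: two control and three
#' mutant replicates, a |dPSI| effect of 0.3 on a minority of cassette exons
#' with 59% of true effects increasing inclusion in the mutant, and a
#' downstream peak-planting probability calibrated so mis-spliced exons carry
#' binding ~2.25x as often as all exons within a 5-kb window.
#'
#' @slot seed integer; master RNG seed. Each generator derives its own stream
#'   from it, so generators may be called in any order.
#' @slot n_genes,exons_per_gene,genome_len,n_chrom gene/genome layout. Each
#'   gene carries one cassette exon flanked by constitutive exons.
#' @slot exon_len_range,intron_len_range,gene_spacing_range bp ranges sampled
#'   uniformly. Introns default to 7.5-9 kb so a peak planted downstream of a
#'   cassette exon cannot fall inside the 5-kb window of a neighbouring exon.
#' @slot n_rep_control,n_rep_mutant replicate counts per group.
#' @slot psi_null_shape Beta(a, b) parameters for baseline PSI.
#' @slot n_true_events number of events given a true group difference.
#' @slot delta_psi_effect true |dPSI| (mutant - control) for true events.
#' @slot prob_up probability a true effect increases inclusion in the mutant.
#' @slot read_depth mean informative reads per event and replicate (Poisson).
#' @slot dispersion beta-binomial overdispersion rho in [0, 1); 0 = binomial.
#' @slot len_inc,len_skp effective lengths of inclusion/skipping forms.
#' @slot tpm_low_frac fraction of genes assigned TPM < 1 to exercise the
#'   expression filter.
#' @slot peak_bg_rate background peaks per Mbp (Poisson).
#' @slot peak_fg_prob probability a true excluded-in-control exon receives a
#'   planted downstream peak. Default 0.145 is derived in closed form so the
#'   foreground-vs-all-exons bound-proportion ratio is 2.25 under the default
#'   design; see [peakFgProbForRatio()].
#' @slot peak_offset_range planted peak start offset ~ Uniform(0, range) bp
#'   downstream of the exon 3' end, in transcription direction.
#' @slot peak_width peak width in bp.
#' @slot stall_amplitude,stall_sd Gaussian elongation-stalling bump height
#'   (signal units above the unit background) and sd in bp.
#' @slot track_bin signal-track emission bin in bp.
#' @slot track_noise_sd per-bin Gaussian noise sd of the signal track.
#' @slot motif_rate_fg,motif_rate_bg planted motifs per kb in foreground and
#'   background windows.
#' @slot motif_window_bp length of each simulated sequence window.
#' @slot screen_n_factors total screen entries including both controls.
#' @slot screen_n_hits number of spiked true hits.
#' @slot screen_effect,screen_pos_effect PSI fold-change shift of spiked hits
#'   and of the positive control.
#' @slot screen_n_replicates biological replicates per screen entry.
#' @slot screen_n_technical technical replicates per well; emitted Ct values
#'   are technical means, so their noise is `ct_noise_sd / sqrt(n_technical)`.
#' @slot ct_noise_sd Gaussian per-well Ct noise sd (cycles).
#' @slot detection_ct Ct at or above which an amplicon counts as undetected.
#' @slot screen_undetected_frac fraction of library factors simulated below
#'   the detection limit.
#' @slot meth_beta_a,meth_beta_b Beta parameters of per-CpG methylation for
#'   the two conditions.
#' @slot n_cpgs,meth_coverage CpG count and mean coverage (Poisson).
#' @seealso [simConfig()]
#' @export
setClass("SimConfig", representation(
  seed = "integer",
  n_genes = "integer",
  exons_per_gene = "integer",
  genome_len = "numeric",
  n_chrom = "integer",
  exon_len_range = "numeric",
  intron_len_range = "numeric",
  gene_spacing_range = "numeric",
  n_rep_control = "integer",
  n_rep_mutant = "integer",
  psi_null_shape = "numeric",
  n_true_events = "integer",
  delta_psi_effect = "numeric",
  prob_up = "numeric",
  read_depth = "numeric",
  dispersion = "numeric",
  len_inc = "numeric",
  len_skp = "numeric",
  tpm_low_frac = "numeric",
  peak_bg_rate = "numeric",
  peak_fg_prob = "numeric",
  peak_offset_range = "numeric",
  peak_width = "integer",
  stall_amplitude = "numeric",
  stall_sd = "numeric",
  track_bin = "integer",
  track_noise_sd = "numeric",
  motif_rate_fg = "numeric",
  motif_rate_bg = "numeric",
  motif_window_bp = "integer",
  screen_n_factors = "integer",
  screen_n_hits = "integer",
  screen_effect = "numeric",
  screen_pos_effect = "numeric",
  screen_n_replicates = "integer",
  screen_n_technical = "integer",
  ct_noise_sd = "numeric",
  detection_ct = "numeric",
  screen_undetected_frac = "numeric",
  meth_beta_a = "numeric",
  meth_beta_b = "numeric",
  n_cpgs = "integer",
  meth_coverage = "numeric"
))

setValidity("SimConfig", function(object) {
  msg <- character(0)
  chk <- function(cond, what) if (!cond) msg <<- c(msg, what)
  chk(length(object@seed) == 1L && !is.na(object@seed), "seed must be a single integer")
  chk(object@n_genes >= 1L, "n_genes must be >= 1")
  chk(object@exons_per_gene >= 3L, "exons_per_gene must be >= 3")
  chk(object@genome_len > 0, "genome_len must be positive")
  chk(object@n_chrom >= 1L, "n_chrom must be >= 1")
  chk(length(object@exon_len_range) == 2L && all(object@exon_len_range > 0),
      "exon_len_range must be two positive values")
  chk(length(object@intron_len_range) == 2L && all(object@intron_len_range > 0),
      "intron_len_range must be two positive values")
  chk(object@n_rep_control >= 1L && object@n_rep_mutant >= 1L,
      "need at least one replicate per group")
  chk(all(object@psi_null_shape > 0), "psi_null_shape parameters must be positive")
  chk(object@n_true_events >= 0L && object@n_true_events <= object@n_genes,
      "n_true_events must be between 0 and n_genes")
  chk(object@delta_psi_effect > 0 && object@delta_psi_effect < 1,
      "delta_psi_effect must lie in (0, 1)")
  chk(object@prob_up >= 0 && object@prob_up <= 1, "prob_up must lie in [0, 1]")
  chk(object@read_depth > 0, "read_depth must be positive")
  chk(object@dispersion >= 0 && object@dispersion < 1,
      "dispersion must lie in [0, 1)")
  chk(object@len_inc >= 1 && object@len_skp >= 1, "effective lengths must be >= 1")
  chk(object@tpm_low_frac >= 0 && object@tpm_low_frac < 1,
      "tpm_low_frac must lie in [0, 1)")
  chk(object@peak_bg_rate >= 0, "peak_bg_rate must be >= 0")
  chk(object@peak_fg_prob >= 0 && object@peak_fg_prob <= 1,
      "peak_fg_prob must lie in [0, 1]")
  chk(object@peak_offset_range >= 0, "peak_offset_range must be >= 0")
  chk(object@peak_width >= 1L, "peak_width must be >= 1")
  chk(object@stall_amplitude >= 0, "stall_amplitude must be >= 0")
  chk(object@stall_sd > 0, "stall_sd must be positive")
  chk(object@track_bin >= 1L, "track_bin must be >= 1")
  chk(object@track_noise_sd >= 0, "track_noise_sd must be >= 0")
  chk(object@motif_rate_fg >= 0 && object@motif_rate_bg >= 0,
      "motif rates must be >= 0")
  chk(object@motif_window_bp >= 50L, "motif_window_bp must be >= 50")
  chk(object@screen_n_factors >= 3L,
      "screen_n_factors must be >= 3 (two controls plus a library)")
  chk(object@screen_n_hits >= 0L &&
        object@screen_n_hits <= object@screen_n_factors - 2L,
      "screen_n_hits must fit in the library")
  chk(object@screen_n_replicates >= 1L, "screen_n_replicates must be >= 1")
  chk(object@screen_n_technical >= 1L, "screen_n_technical must be >= 1")
  chk(object@ct_noise_sd >= 0, "ct_noise_sd must be >= 0")
  chk(object@screen_undetected_frac >= 0 && object@screen_undetected_frac < 1,
      "screen_undetected_frac must lie in [0, 1)")
  chk(length(object@meth_beta_a) == 2L && all(object@meth_beta_a > 0) &&
        length(object@meth_beta_b) == 2L && all(object@meth_beta_b > 0),
      "methylation Beta parameters must be two positive values per condition")
  chk(object@n_cpgs >= 1L, "n_cpgs must be >= 1")
  chk(object@meth_coverage >= 0, "meth_coverage must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Create a simulation configuration
#'
#' @param seed master RNG seed (integer).
#' @param ... named [SimConfig-class] slot overrides.
#' @return A validated [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(seed = 1, n_genes = 20, genome_len = 1e6)
#' @export
simConfig <- function(seed = 1L, ...) {
  defaults <- list(
    seed = as.integer(seed),
    n_genes = 1500L,
    exons_per_gene = 3L,
    genome_len = 4e7,
    n_chrom = 2L,
    exon_len_range = c(120, 180),
    intron_len_range = c(7500, 9000),
    gene_spacing_range = c(2000, 5000),
    n_rep_control = 2L,
    n_rep_mutant = 3L,
    psi_null_shape = c(2, 2),
    n_true_events = 500L,
    delta_psi_effect = 0.3,
    prob_up = 0.59,
    read_depth = 100,
    dispersion = 0.05,
    len_inc = 2,
    len_skp = 1,
    tpm_low_frac = 0.1,
    peak_bg_rate = 8,
    peak_fg_prob = 0.145,
    peak_offset_range = 2000,
    peak_width = 300L,
    stall_amplitude = 2,
    stall_sd = 300,
    track_bin = 25L,
    track_noise_sd = 0.05,
    motif_rate_fg = 1.5,
    motif_rate_bg = 0.5,
    motif_window_bp = 1000L,
    screen_n_factors = 73L,
    screen_n_hits = 5L,
    screen_effect = 0.5,
    screen_pos_effect = 0.2,
    screen_n_replicates = 2L,
    screen_n_technical = 3L,
    ct_noise_sd = 0.1,
    detection_ct = 35,
    screen_undetected_frac = 0.05,
    meth_beta_a = c(12, 8),
    meth_beta_b = c(14, 6),
    n_cpgs = 200L,
    meth_coverage = 50
  )
  override <- list(...)
  bad <- setdiff(names(override), names(defaults))
  if (length(bad))
    stop("unknown SimConfig parameter(s): ", paste(bad, collapse = ", "))
  values <- defaults
  values[names(override)] <- override
  # keep the default effect count feasible for small custom designs
  if (!"n_true_events" %in% names(override))
    values$n_true_events <- min(values$n_true_events,
                                as.integer(values$n_genes))
  int_slots <- c("seed", "n_genes", "exons_per_gene", "n_chrom",
                 "n_rep_control", "n_rep_mutant", "n_true_events",
                 "peak_width", "track_bin", "motif_window_bp",
                 "screen_n_factors", "screen_n_hits", "screen_n_replicates",
                 "n_cpgs")
  for (s in int_slots) values[[s]] <- as.integer(values[[s]])
  do.call(new, c(list(Class = "SimConfig"), values))
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig (seed ", object@seed, ")\n", sep = "")
  cat("  genome: ", object@n_genes, " genes x ", object@exons_per_gene,
      " exons on ", object@n_chrom, " chromosome(s), ",
      format(object@genome_len, big.mark = ","), " bp\n", sep = "")
  cat("  splicing: ", object@n_true_events, " true events, |dPSI| = ",
      object@delta_psi_effect, ", depth ", object@read_depth,
      ", dispersion ", object@dispersion, ", ", object@n_rep_control, "v",
      object@n_rep_mutant, " replicates\n", sep = "")
  cat("  peaks: bg ", object@peak_bg_rate, "/Mbp, planted prob ",
      object@peak_fg_prob, ", offset <= ", object@peak_offset_range,
      " bp\n", sep = "")
  cat("  track: bump amplitude ", object@stall_amplitude, " (sd ",
      object@stall_sd, " bp), noise sd ", object@track_noise_sd, "\n", sep = "")
  cat("  screen: ", object@screen_n_factors, " factors, ",
      object@screen_n_hits, " spiked hits (effect ", object@screen_effect,
      ")\n", sep = "")
  cat("  methylation: ", object@n_cpgs, " CpGs, coverage ",
      object@meth_coverage, "\n", sep = "")
})

#' Simulated gene annotation
#'
#' Container returned by [simulateAnnotation()]: the genome sequence (optional),
#' all exons, gene bodies, and the cassette exon of each gene (one
#' alternative-splicing event per gene).
#'
#' @slot genome [Biostrings::DNAStringSet] or `NULL` when built without
#'   sequence.
#' @slot exons [GenomicRanges::GRanges] with `gene_id`, `transcript_id`,
#'   `exon_rank` (transcription order) and `role`
#'   (`constitutive`/`cassette`) metadata.
#' @slot genes [GenomicRanges::GRanges] of gene spans.
#' @slot events [GenomicRanges::GRanges] of cassette exons, named by
#'   `event_id`.
#' @export
setClass("SimAnnotation", representation(
  genome = "ANY",
  exons = "GRanges",
  genes = "GRanges",
  events = "GRanges"
))

setValidity("SimAnnotation", function(object) {
  if (!is.null(object@genome) && !is(object@genome, "DNAStringSet"))
    return("genome must be NULL or a DNAStringSet")
  if (is.null(object@events$event_id))
    return("events must carry an event_id column")
  TRUE
})

#' @describeIn SimAnnotation-class all exons of the annotation.
#' @param x a `SimAnnotation`.
#' @export
annotationExons <- function(x) x@exons

#' @describeIn SimAnnotation-class gene spans.
#' @export
annotationGenes <- function(x) x@genes

#' @describeIn SimAnnotation-class cassette exons (one event per gene).
#' @export
annotationEvents <- function(x) x@events

#' @describeIn SimAnnotation-class genome sequence (may be `NULL`).
#' @export
annotationGenome <- function(x) x@genome

setMethod("show", "SimAnnotation", function(object) {
  cat("SimAnnotation: ", length(object@genes), " genes, ",
      length(object@exons), " exons, ", length(object@events),
      " cassette events on ",
      length(unique(as.character(seqnames(object@exons)))),
      " chromosome(s)\n", sep = "")
  cat("  genome sequence: ",
      if (is.null(object@genome)) "absent" else
        paste(format(sum(width(object@genome)), big.mark = ","), "bp"),
      "\n", sep = "")
})

#' Binding-enrichment comparison
#'
#' Result of [enrichmentVsBackground()]: a 2x2 bound/unbound comparison of a
#' foreground exon set against a background set within a fixed window, with
#' the bound-proportion ratio (relative risk), the odds ratio, and the
#' two-sided p-value.
#'
#' @slot window_bp half-window size in bp.
#' @slot n_fg_bound,n_fg_total,n_bg_bound,n_bg_total 2x2 counts.
#' @slot ratio ratio of bound proportions (foreground / background).
#' @slot odds_ratio sample odds ratio of the 2x2 table.
#' @slot p_value two-sided p-value.
#' @slot test `"fisher"` (default) or `"t"`.
#' @export
setClass("BindingComparison", representation(
  window_bp = "numeric",
  n_fg_bound = "integer",
  n_fg_total = "integer",
  n_bg_bound = "integer",
  n_bg_total = "integer",
  ratio = "numeric",
  odds_ratio = "numeric",
  p_value = "numeric",
  test = "character"
))

setValidity("BindingComparison", function(object) {
  if (object@n_fg_bound > object@n_fg_total ||
      object@n_bg_bound > object@n_bg_total)
    return("bound counts cannot exceed totals")
  if (!is.na(object@p_value) &&
      (object@p_value < 0 || object@p_value > 1))
    return("p_value must lie in [0, 1]")
  if (!is.na(object@ratio) && object@ratio < 0)
    return("ratio must be >= 0")
  TRUE
})

setMethod("show", "BindingComparison", function(object) {
  cat("BindingComparison (window ", object@window_bp, " bp, ",
      object@test, " test)\n", sep = "")
  cat(sprintf("  foreground: %d/%d bound (%.1f%%)\n", object@n_fg_bound,
              object@n_fg_total,
              100 * object@n_fg_bound / object@n_fg_total))
  cat(sprintf("  background: %d/%d bound (%.1f%%)\n", object@n_bg_bound,
              object@n_bg_total,
              100 * object@n_bg_bound / object@n_bg_total))
  cat(sprintf("  ratio = %.3g, odds ratio = %.3g, p = %.3g\n",
              object@ratio, object@odds_ratio, object@p_value))
})

#' @describeIn BindingComparison-class coerce to a one-row data.frame.
#' @param x a `BindingComparison`.
#' @param ... ignored.
#' @export
setMethod("as.data.frame", "BindingComparison", function(x, ...) {
  data.frame(window_bp = x@window_bp, n_fg_bound = x@n_fg_bound,
             n_fg_total = x@n_fg_total, n_bg_bound = x@n_bg_bound,
             n_bg_total = x@n_bg_total, ratio = x@ratio,
             odds_ratio = x@odds_ratio, p_value = x@p_value, test = x@test)
})

#' Binned metaplot comparison of two exon groups
#'
#' Result of [compareProfiles()]: per-bin means, standard errors and group
#' sizes of two exon-anchored signal profiles, with a two-sided Wilcoxon
#' rank-sum p-value per bin and Benjamini-Hochberg q-values across bins.
#'
#' @slot offsets bin centers in bp relative to the anchor (downstream
#'   positive, in transcription direction).
#' @slot mean_a,sem_a,n_a,mean_b,sem_b,n_b per-bin summaries per group.
#' @slot p,q per-bin Wilcoxon p-values and BH q-values.
#' @slot labels names of groups A and B.
#' @export
setClass("BinProfileComparison", representation(
  offsets = "numeric",
  mean_a = "numeric",
  sem_a = "numeric",
  n_a = "integer",
  mean_b = "numeric",
  sem_b = "numeric",
  n_b = "integer",
  p = "numeric",
  q = "numeric",
  labels = "character"
))

setValidity("BinProfileComparison", function(object) {
  n <- length(object@offsets)
  lens <- c(length(object@mean_a), length(object@sem_a), length(object@mean_b),
            length(object@sem_b), length(object@p), length(object@q))
  if (any(lens != n)) return("all per-bin vectors must share length")
  if (any(object@sem_a < 0, na.rm = TRUE) || any(object@sem_b < 0, na.rm = TRUE))
    return("sem must be >= 0")
  qq <- object@q[!is.na(object@q)]
  if (any(qq < 0 | qq > 1)) return("q must lie in [0, 1]")
  TRUE
})

setMethod("show", "BinProfileComparison", function(object) {
  nb <- length(object@offsets)
  cat("BinProfileComparison: ", nb, " bins (",
      min(object@offsets), "..", max(object@offsets), " bp), groups ",
      object@labels[1], " (n=", object@n_a[1], ") vs ", object@labels[2],
      " (n=", object@n_b[1], ")\n", sep = "")
  cat("  bins with q < 0.05: ", sum(object@q < 0.05, na.rm = TRUE),
      "\n", sep = "")
})

#' @describeIn BinProfileComparison-class coerce to a per-bin data.frame.
#' @param x a `BinProfileComparison`.
#' @param ... ignored.
#' @export
setMethod("as.data.frame", "BinProfileComparison", function(x, ...) {
  data.frame(offset = x@offsets, mean_a = x@mean_a, sem_a = x@sem_a,
             n_a = x@n_a, mean_b = x@mean_b, sem_b = x@sem_b, n_b = x@n_b,
             p = x@p, q = x@q)
})

#' Position weight matrix of an RNA-binding-protein motif
#'
#' Per-position base probabilities over A/C/G/T (RNA motifs DNA-encoded) with
#' a 0-order background model. Scanning is by log-odds score on the sense
#' strand; see [scanPwm()].
#'
#' @slot id motif identifier.
#' @slot matrix 4 x L probability matrix, rows A, C, G, T; every column sums
#'   to 1 (tolerance 1e-6).
#' @slot background named base frequencies used as the default scan
#'   background.
#' @export
setClass("PwmMotif", representation(
  id = "character",
  matrix = "matrix",
  background = "numeric"
))

setValidity("PwmMotif", function(object) {
  m <- object@matrix
  if (nrow(m) != 4L) return("matrix must have 4 rows (A, C, G, T)")
  if (ncol(m) < 4L) return("motif length must be >= 4")
  if (any(m < 0)) return("probabilities must be >= 0")
  if (any(abs(colSums(m) - 1) > 1e-6))
    return("each matrix column must sum to 1 (tolerance 1e-6)")
  if (length(object@background) != 4L || any(object@background <= 0) ||
      abs(sum(object@background) - 1) > 1e-6)
    return("background must be 4 positive frequencies summing to 1")
  TRUE
})

#' Construct a PWM motif
#'
#' @param id motif identifier.
#' @param matrix 4 x L (rows A, C, G, T) or L x 4 probability matrix.
#' @param background base frequencies (A, C, G, T); default uniform.
#' @return A [PwmMotif-class] object.
#' @examples
#' m <- matrix(c(.97, .01, .01, .01), nrow = 4, ncol = 6)
#' pwmMotif("polyA", m)
#' @export
pwmMotif <- function(id, matrix, background = rep(0.25, 4)) {
  if (ncol(matrix) == 4L && nrow(matrix) != 4L) matrix <- t(matrix)
  rownames(matrix) <- c("A", "C", "G", "T")
  background <- setNames(as.numeric(background), c("A", "C", "G", "T"))
  new("PwmMotif", id = as.character(id), matrix = matrix,
      background = background)
}

#' @describeIn PwmMotif-class motif length in bases.
#' @param x a `PwmMotif`.
#' @export
motifLength <- function(x) ncol(x@matrix)

#' @describeIn PwmMotif-class consensus sequence (most probable base per
#'   position).
#' @export
motifConsensus <- function(x) {
  paste(rownames(x@matrix)[apply(x@matrix, 2, which.max)], collapse = "")
}

setMethod("show", "PwmMotif", function(object) {
  cat("PwmMotif ", object@id, ": length ", motifLength(object),
      ", consensus ", motifConsensus(object), "\n", sep = "")
})
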