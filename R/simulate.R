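#' @title Synthetic-data generators
#' @description Seeded generators for every input the analysis stages consume:
#' genome + annotation, junction counts with expression, peak intervals,
#' signal tracks, screen plates, methylation counts and motif windows. Each
#' generator derives an independent RNG stream from `config@seed` (a fixed
#' small offset per generator), so outputs are bit-identical under a seed and
#' independent of call order.
#' @name synthetic-data
NULL

seedFor <- function(config, offset) {
  # keep derived seeds within 32-bit integer range
  as.integer((as.numeric(config@seed) + offset) %% .Machine$integer.max)
}

randomDna <- function(len, chunk = 1e6) {
  parts <- character(0)
  left <- len
  while (left > 0) {
    k <- min(chunk, left)
    parts <- c(parts, paste(sample(c("A", "C", "G", "T"), k, replace = TRUE),
                            collapse = ""))
    left <- left - k
  }
  DNAString(paste(parts, collapse = ""))
}

#' Simulate a genome and multi-exon gene annotation
#'
#' Places `n_genes` genes sequentially on `n_chrom` chromosomes, each with
#' `exons_per_gene` exons on a random strand; the middle exon is the cassette
#' (alternative) exon, flanked by constitutive exons. Intron lengths default
#' to 7.5-9 kb so downstream-planted peaks stay outside neighbouring exons'
#' 5-kb windows.
#'
#' @param config a [SimConfig-class].
#' @param sequence generate the genome sequence? Coordinates are drawn before
#'   any sequence bases, so annotation coordinates are identical either way.
#' @return A [SimAnnotation-class].
#' @examples
#' ann <- simulateAnnotation(simConfig(seed = 1, n_genes = 5,
#'                                     genome_len = 2e5))
#' annotationEvents(ann)
#' @export
simulateAnnotation <- function(config, sequence = TRUE) {
  stopifnot(is(config, "SimConfig"))
  set.seed(seedFor(config, 0L))
  n <- config@n_genes
  k <- config@exons_per_gene
  clen <- floor(config@genome_len / config@n_chrom)
  chrom_names <- paste0("chr", seq_len(config@n_chrom))

  exon_w <- matrix(round(runif(n * k, config@exon_len_range[1],
                               config@exon_len_range[2])), nrow = n)
  intron_w <- matrix(round(runif(n * (k - 1), config@intron_len_range[1],
                                 config@intron_len_range[2])), nrow = n)
  spacing <- round(runif(n, config@gene_spacing_range[1],
                         config@gene_spacing_range[2]))
  strands <- sample(c("+", "-"), n, replace = TRUE)

  gene_chrom <- character(n)
  gene_start <- numeric(n)
  cur_chrom <- 1L
  cur_pos <- 1
  for (i in seq_len(n)) {
    span <- sum(exon_w[i, ]) + sum(intron_w[i, ])
    if (cur_pos + spacing[i] + span > clen - 100) {
      cur_chrom <- cur_chrom + 1L
      cur_pos <- 1
      if (cur_chrom > config@n_chrom)
        stop("genome_len too small to place ", n, " genes without overlap")
      if (cur_pos + spacing[i] + span > clen - 100)
        stop("genome_len too small to place ", n, " genes without overlap")
    }
    gene_chrom[i] <- chrom_names[cur_chrom]
    gene_start[i] <- cur_pos + spacing[i]
    cur_pos <- gene_start[i] + span
  }

  cassette_idx <- as.integer(ceiling(k / 2))
  ex_chrom <- rep(gene_chrom, each = k)
  ex_strand <- rep(strands, each = k)
  ex_start <- ex_end <- numeric(n * k)
  for (i in seq_len(n)) {
    pos <- gene_start[i]
    for (j in seq_len(k)) {
      ii <- (i - 1L) * k + j
      ex_start[ii] <- pos
      ex_end[ii] <- pos + exon_w[i, j] - 1
      if (j < k) pos <- ex_end[ii] + 1 + intron_w[i, j]
    }
  }
  gene_id <- sprintf("G%05d", seq_len(n))
  tx_id <- sprintf("T%05d", seq_len(n))
  genomic_rank <- rep(seq_len(k), n)
  # exon_rank counts in transcription order
  ex_rank <- ifelse(rep(strands, each = k) == "+", genomic_rank,
                    k + 1L - genomic_rank)
  role <- ifelse(genomic_rank == cassette_idx, "cassette", "constitutive")

  exons <- GRanges(ex_chrom, IRanges(ex_start, ex_end), strand = ex_strand,
                   gene_id = rep(gene_id, each = k),
                   transcript_id = rep(tx_id, each = k),
                   exon_rank = as.integer(ex_rank), role = role)
  genes <- GRanges(gene_chrom,
                   IRanges(gene_start,
                           gene_start + rowSums(exon_w) + rowSums(intron_w) - 1),
                   strand = strands, gene_id = gene_id)
  ev <- exons[exons$role == "cassette"]
  ev$event_id <- sprintf("EV%05d", seq_len(n))
  names(ev) <- ev$event_id

  genome <- NULL
  if (sequence) {
    genome <- DNAStringSet(lapply(seq_len(config@n_chrom),
                                  function(i) randomDna(clen)))
    names(genome) <- chrom_names
  }
  sl <- setNames(rep(clen, config@n_chrom), chrom_names)
  for (gr_name in c("exons", "genes", "ev")) {
    gr <- get(gr_name)
    seqlengths(gr) <- sl[seqlevels(gr)]
    assign(gr_name, gr)
  }
  new("SimAnnotation", genome = genome, exons = exons, genes = genes,
      events = ev)
}

#' Simulate junction counts, expression and splicing ground truth
#'
#' For each cassette event, a baseline PSI is drawn from
#' `Beta(psi_null_shape)`. `n_true_events` events get a true mutant - control
#' difference of `delta_psi_effect` (inclusion-increasing with probability
#' `prob_up`), clamped into (0.01, 0.99) with the clamping recorded. Per
#' replicate, the realized PSI is beta-binomially overdispersed
#' (`dispersion` = rho; rho = 0 recovers the binomial) and reads are split
#' between inclusion and skipping forms with the effective-length-weighted
#' inclusion probability. Gene TPM values are emitted with a configurable
#' fraction below 1 to exercise the expression filter.
#'
#' @param config a [SimConfig-class].
#' @param annotation a [SimAnnotation-class] from [simulateAnnotation()].
#' @return list with `counts` (event/replicate junction counts with exon
#'   coordinates), `expression` (gene_id, tpm) and `truth` (per-event true
#'   PSI, effect flag, clamping flag).
#' @export
simulateJunctionCounts <- function(config, annotation) {
  stopifnot(is(config, "SimConfig"), is(annotation, "SimAnnotation"))
  set.seed(seedFor(config, 1L))
  ev <- annotation@events
  nE <- length(ev)
  if (config@n_true_events > nE)
    stop("n_true_events exceeds number of events")

  true_idx <- if (config@n_true_events > 0)
    sort(sample.int(nE, config@n_true_events)) else integer(0)
  base <- rbeta(nE, config@psi_null_shape[1], config@psi_null_shape[2])
  base <- pmin(pmax(base, 0.01), 0.99)
  up <- runif(nE) < config@prob_up
  psi_c <- base
  psi_m <- base
  delta <- ifelse(up, config@delta_psi_effect, -config@delta_psi_effect)
  psi_m[true_idx] <- base[true_idx] + delta[true_idx]
  clamped <- psi_m < 0.01 | psi_m > 0.99
  psi_m <- pmin(pmax(psi_m, 0.01), 0.99)
  if (any(clamped))
    warning(sum(clamped), " event(s) clamped to keep PSI inside (0.01, 0.99)")

  groups <- c(rep("control", config@n_rep_control),
              rep("mutant", config@n_rep_mutant))
  rep_id <- c(seq_len(config@n_rep_control), seq_len(config@n_rep_mutant))
  nR <- length(groups)
  rho <- config@dispersion

  psi_grid <- ifelse(rep(groups, each = nE) == "control",
                     rep(psi_c, nR), rep(psi_m, nR))
  if (rho > 0) {
    conc <- (1 - rho) / rho
    psi_rep <- rbeta(nE * nR, psi_grid * conc, (1 - psi_grid) * conc)
    # guard against exact 0/1 from extreme beta draws
    psi_rep <- pmin(pmax(psi_rep, 1e-6), 1 - 1e-6)
  } else {
    psi_rep <- psi_grid
  }
  theta <- psi_rep * config@len_inc /
    (psi_rep * config@len_inc + (1 - psi_rep) * config@len_skp)
  n_reads <- rpois(nE * nR, config@read_depth)
  inc <- rbinom(nE * nR, n_reads, theta)
  skp <- n_reads - inc

  counts <- data.frame(
    event_id = rep(ev$event_id, nR),
    gene_id = rep(ev$gene_id, nR),
    chrom = rep(as.character(seqnames(ev)), nR),
    start = rep(start(ev), nR),
    end = rep(end(ev), nR),
    strand = rep(as.character(strand(ev)), nR),
    event_type = "SE",
    group = rep(groups, each = nE),
    replicate = rep(rep_id, each = nE),
    inc_reads = inc,
    skp_reads = skp,
    len_inc = config@len_inc,
    len_skp = config@len_skp,
    stringsAsFactors = FALSE
  )

  gene_ids <- annotation@genes$gene_id
  nG <- length(gene_ids)
  n_low <- round(config@tpm_low_frac * nG)
  low <- if (n_low > 0) sample.int(nG, n_low) else integer(0)
  tpm <- rlnorm(nG, meanlog = log(20), sdlog = 1)
  tpm[low] <- runif(n_low, 0.1, 0.9)
  expression <- data.frame(gene_id = gene_ids, tpm = tpm,
                           stringsAsFactors = FALSE)

  truth <- data.frame(
    event_id = ev$event_id,
    gene_id = ev$gene_id,
    true_event = seq_len(nE) %in% true_idx,
    psi_control = psi_c,
    psi_mutant = psi_m,
    delta_psi = psi_m - psi_c,
    clamped = clamped,
    stringsAsFactors = FALSE
  )
  truth$clamped[!truth$true_event] <- FALSE
  list(counts = counts, expression = expression, truth = truth)
}

#' Simulate factor-binding peaks around excluded exons
#'
#' Background peaks fall as a Poisson process (`peak_bg_rate` per Mbp)
#' uniformly over the genome. Each true excluded-in-control exon (true event
#' with dPSI > 0, i.e. included in the mutant) receives, with probability
#' `peak_fg_prob`, one planted peak starting Uniform(0, `peak_offset_range`)
#' bp downstream of its 3' end in transcription direction.
#'
#' @param annotation a [SimAnnotation-class].
#' @param truth the `truth` component of [simulateJunctionCounts()].
#' @param config a [SimConfig-class].
#' @return list with `peaks` (`GRanges`, metadata `name`, `planted`,
#'   `event_id`) and `truth` (per-event planted flag and offset).
#' @export
simulatePeaks <- function(annotation, truth, config) {
  stopifnot(is(annotation, "SimAnnotation"), is(config, "SimConfig"))
  set.seed(seedFor(config, 2L))
  ev <- annotation@events[truth$event_id]
  excl <- which(truth$true_event & truth$delta_psi > 0)
  w <- config@peak_width

  planted <- rep(FALSE, length(ev))
  offs <- rep(NA_real_, length(ev))
  planted[excl] <- runif(length(excl)) < config@peak_fg_prob
  pidx <- which(planted)
  offs[pidx] <- round(runif(length(pidx), 0, config@peak_offset_range))

  sl <- seqlengths(annotation@exons)
  fg <- GRanges(planted = logical(0), event_id = character(0))
  if (length(pidx)) {
    e <- ev[pidx]
    plus <- as.character(strand(e)) == "+"
    pstart <- ifelse(plus, end(e) + 1 + offs[pidx],
                     start(e) - 1 - offs[pidx] - w + 1)
    pstart <- pmax(1, pstart)
    fg <- GRanges(seqnames(e), IRanges(pstart, width = w), strand = "*",
                  planted = TRUE, event_id = e$event_id)
  }

  bg_list <- list()
  for (ch in names(sl)) {
    nbg <- rpois(1, config@peak_bg_rate * sl[[ch]] / 1e6)
    if (nbg > 0) {
      starts <- sort(sample.int(sl[[ch]] - w, nbg, replace = TRUE))
      g <- GRanges(factor(ch, levels = names(sl)),
                   IRanges(starts, width = w), strand = "*",
                   planted = FALSE, event_id = NA_character_)
      bg_list[[ch]] <- g
    }
  }
  bg <- if (length(bg_list)) do.call(c, unname(bg_list)) else
    GRanges(planted = logical(0), event_id = character(0))

  seqlevels(fg) <- names(sl)
  seqlevels(bg) <- names(sl)
  peaks <- sort(c(fg, bg), ignore.strand = TRUE)
  end(peaks) <- pmin(end(peaks), sl[as.character(seqnames(peaks))])
  seqlengths(peaks) <- sl[seqlevels(peaks)]
  peaks$name <- sprintf("peak%05d", seq_along(peaks))
  ptruth <- data.frame(event_id = truth$event_id, peak_planted = planted,
                       peak_offset = offs, stringsAsFactors = FALSE)
  list(peaks = peaks, truth = ptruth)
}

gaussianBump <- function(x, center, amplitude, sd) {
  amplitude * exp(-((x - center)^2) / (2 * sd^2))
}

#' Simulate an elongation-signal track with stalling bumps
#'
#' Emits a binned (`track_bin` bp) signal track around every exon: a unit
#' background plus, at exons whose event carries a planted peak, a Gaussian
#' stalling bump (`stall_amplitude` above background, sd `stall_sd`) centered
#' on the exon midpoint, plus per-bin Gaussian noise (`track_noise_sd`).
#' Away from exons the track is exactly 1.0.
#'
#' @param annotation a [SimAnnotation-class].
#' @param peaks the `peaks` component of [simulatePeaks()] (its `event_id`
#'   metadata marks which exons stall).
#' @param config a [SimConfig-class].
#' @param region_half half-width in bp of the noisy region emitted around
#'   each exon center; default covers a +/-2.5 kb metaplot window.
#' @return A sorted `GRanges` with `score`, suitable for [writeBedGraph()].
#' @export
simulateSignalTrack <- function(annotation, peaks, config,
                                region_half = 3100) {
  stopifnot(is(annotation, "SimAnnotation"), is(config, "SimConfig"))
  set.seed(seedFor(config, 3L))
  bin <- config@track_bin
  sl <- seqlengths(annotation@exons)
  ev <- annotation@events
  bump_events <- unique(peaks$event_id[!is.na(peaks$event_id)])
  bump_centers <- floor((start(ev) + end(ev)) / 2)[ev$event_id %in% bump_events]
  bump_chrom <- as.character(seqnames(ev))[ev$event_id %in% bump_events]
  centers_all <- floor((start(annotation@exons) + end(annotation@exons)) / 2)
  chrom_all <- as.character(seqnames(annotation@exons))

  out <- list()
  for (ch in names(sl)) {
    cen <- centers_all[chrom_all == ch]
    if (!length(cen)) {
      g <- GRanges(ch, IRanges(1, sl[[ch]]), score = 1.0)
      seqlevels(g) <- names(sl)
      out[[ch]] <- g
      next
    }
    regions <- reduce(GRanges(ch, IRanges(pmax(1, cen - region_half),
                                          pmin(sl[[ch]], cen + region_half))))
    # align region boundaries to the bin grid
    start(regions) <- pmax(1, floor((start(regions) - 1) / bin) * bin + 1)
    end(regions) <- pmin(sl[[ch]], ceiling(end(regions) / bin) * bin)
    bins <- unlist(tile(regions, width = bin))
    mids <- (start(bins) + end(bins)) / 2
    val <- rep(1.0, length(bins))
    bc <- bump_centers[bump_chrom == ch]
    for (cc in bc) {
      near <- which(abs(mids - cc) <= 10 * config@stall_sd)
      if (length(near))
        val[near] <- val[near] + gaussianBump(mids[near], cc,
                                              config@stall_amplitude,
                                              config@stall_sd)
    }
    if (config@track_noise_sd > 0)
      val <- val + rnorm(length(val), 0, config@track_noise_sd)
    val <- pmax(val, 0)
    bins$score <- val
    gap <- gaps(reduce(bins), start = 1, end = sl[[ch]])
    gap <- gap[strand(gap) == "*"]
    if (length(gap)) gap$score <- 1.0
    g <- sort(c(bins, gap))
    seqlevels(g) <- names(sl)
    out[[ch]] <- g
  }
  track <- do.call(c, unname(out))
  seqlengths(track) <- sl[seqlevels(track)]
  track
}

#' Simulate a dual-readout qPCR screen plate
#'
#' Emulates an siRNA splicing-factor screen read out by qPCR on two cassette
#' exons of one target gene: amplicons `exon5`, `exon21`, `total` and
#' `reference` per factor and biological replicate. Spiked hits shift both
#' exon readouts by `screen_effect` (fold change 1 + effect); the positive
#' control `SMCHD1` shifts them by `screen_pos_effect`; the negative control
#' is `GFP`. A configurable subset of library factors is emitted above the
#' detection limit to exercise the expression filter. Each emitted Ct is the
#' mean of `screen_n_technical` technical replicates with per-well Gaussian
#' noise `ct_noise_sd`, mirroring the standard practice of averaging
#' technical triplicates before analysis.
#'
#' @param config a [SimConfig-class].
#' @return list with `plate` (factor_id, amplicon, replicate, ct) and
#'   `truth` (role, spiked, undetected, true fold-change effect).
#' @export
simulateScreenPlate <- function(config) {
  stopifnot(is(config, "SimConfig"))
  set.seed(seedFor(config, 4L))
  n_lib <- config@screen_n_factors - 2L
  lib_ids <- sprintf("SF%03d", seq_len(n_lib))
  ids <- c("GFP", "SMCHD1", lib_ids)
  spiked <- if (config@screen_n_hits > 0)
    sort(sample(lib_ids, config@screen_n_hits)) else character(0)
  n_undet <- round(config@screen_undetected_frac * n_lib)
  undet <- if (n_undet > 0)
    sort(sample(setdiff(lib_ids, spiked), n_undet)) else character(0)

  effect <- setNames(rep(0, length(ids)), ids)
  effect["SMCHD1"] <- config@screen_pos_effect
  effect[spiked] <- config@screen_effect

  ct_ref <- 20
  ct_total <- 25
  base_incl_rq <- 0.2  # baseline inclusion/total ratio
  amplicons <- c("exon5", "exon21", "total", "reference")
  reps <- seq_len(config@screen_n_replicates)
  grid <- expand.grid(factor_id = ids, amplicon = amplicons, replicate = reps,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  fc <- 1 + effect[grid$factor_id]
  ct <- ifelse(grid$amplicon == "reference", ct_ref,
        ifelse(grid$amplicon == "total", ct_total,
               ct_total - log2(base_incl_rq) - log2(fc)))
  is_undet_row <- grid$factor_id %in% undet & grid$amplicon != "reference"
  ct[is_undet_row] <- config@detection_ct + 2
  # each reported Ct is the mean of the technical replicates of that well
  ct <- ct + rnorm(nrow(grid), 0,
                   config@ct_noise_sd / sqrt(config@screen_n_technical))
  plate <- data.frame(grid, ct = ct, stringsAsFactors = FALSE)
  plate <- plate[order(plate$factor_id, plate$amplicon, plate$replicate), ]
  rownames(plate) <- NULL

  truth <- data.frame(
    factor_id = ids,
    role = c("neg_control", "pos_control", rep("library", n_lib)),
    spiked = ids %in% spiked,
    undetected = ids %in% undet,
    effect = as.numeric(effect),
    stringsAsFactors = FALSE
  )
  list(plate = plate, truth = truth)
}

#' Simulate per-CpG bisulfite methylation count tables
#'
#' Two conditions with per-CpG methylation drawn from condition-specific Beta
#' distributions; methylated counts are Binomial(coverage, theta) with
#' Poisson coverage (zero-coverage CpGs are emitted and get no beta value
#' downstream).
#'
#' @param config a [SimConfig-class].
#' @param conditions names of the two conditions.
#' @return list with `counts` (chrom, pos, condition, m_count, u_count) and
#'   `truth` (per-CpG true theta per condition).
#' @export
simulateMethylationCounts <- function(config,
                                      conditions = c("condA", "condB")) {
  stopifnot(is(config, "SimConfig"), length(conditions) == 2L)
  set.seed(seedFor(config, 5L))
  n <- config@n_cpgs
  pos <- sort(sample.int(1e6, n))
  theta_a <- rbeta(n, config@meth_beta_a[1], config@meth_beta_a[2])
  theta_b <- rbeta(n, config@meth_beta_b[1], config@meth_beta_b[2])
  cov_a <- rpois(n, config@meth_coverage)
  cov_b <- rpois(n, config@meth_coverage)
  m_a <- rbinom(n, cov_a, theta_a)
  m_b <- rbinom(n, cov_b, theta_b)
  counts <- data.frame(
    chrom = "chr1",
    pos = c(pos, pos),
    condition = rep(conditions, each = n),
    m_count = c(m_a, m_b),
    u_count = c(cov_a - m_a, cov_b - m_b),
    stringsAsFactors = FALSE
  )
  truth <- data.frame(chrom = "chr1", pos = pos, theta_a = theta_a,
                      theta_b = theta_b, stringsAsFactors = FALSE)
  names(truth)[3:4] <- paste0("theta_", conditions)
  list(counts = counts, truth = truth)
}

plantMotifInstances <- function(seq_chars, pwm, n_instances) {
  # instances are the motif consensus so a planted site is a guaranteed hit
  # at the default scan threshold; density differences carry the signal
  L <- motifLength(pwm)
  len <- length(seq_chars)
  inst <- strsplit(motifConsensus(pwm), "")[[1]]
  planted <- 0L
  if (n_instances > 0 && len >= L) {
    cand <- sample.int(len - L + 1L, min(n_instances * 3L, len - L + 1L))
    chosen <- integer(0)
    for (p in cand) {
      if (length(chosen) >= n_instances) break
      if (!any(abs(chosen - p) < L)) chosen <- c(chosen, p)
    }
    for (p in chosen) seq_chars[p:(p + L - 1L)] <- inst
    planted <- length(chosen)
  }
  list(seq = seq_chars, planted = planted)
}

#' Simulate motif-planted sequence windows
#'
#' Random uniform-composition sequence windows with PWM instances planted at
#' Poisson rates `motif_rate_fg` (foreground) and `motif_rate_bg`
#' (background) per kb; instances are sampled position-wise from the PWM and
#' never overlap each other.
#'
#' @param config a [SimConfig-class].
#' @param pwm a [PwmMotif-class] to plant.
#' @param n_fg,n_bg window counts per set.
#' @return list with `fg`, `bg` (`DNAStringSet`) and `truth` (per-window
#'   planted instance counts).
#' @export
simulateMotifWindows <- function(config, pwm, n_fg = 200, n_bg = 200) {
  stopifnot(is(config, "SimConfig"), is(pwm, "PwmMotif"))
  set.seed(seedFor(config, 6L))
  len <- config@motif_window_bp
  make_set <- function(nw, rate, prefix) {
    seqs <- character(nw)
    planted <- integer(nw)
    for (i in seq_len(nw)) {
      chars <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
      k <- rpois(1, rate * len / 1000)
      res <- plantMotifInstances(chars, pwm, k)
      seqs[i] <- paste(res$seq, collapse = "")
      planted[i] <- res$planted
    }
    set <- DNAStringSet(seqs)
    names(set) <- sprintf("%s%04d", prefix, seq_len(nw))
    list(set = set, planted = planted)
  }
  fg <- make_set(n_fg, config@motif_rate_fg, "fg")
  bg <- make_set(n_bg, config@motif_rate_bg, "bg")
  truth <- data.frame(
    window = c(names(fg$set), names(bg$set)),
    set = rep(c("fg", "bg"), c(n_fg, n_bg)),
    planted = c(fg$planted, bg$planted),
    stringsAsFactors = FALSE
  )
  list(fg = fg$set, bg = bg$set, truth = truth)
}

#' Write every simulated input to a directory
#'
#' Runs all generators under one configuration and writes their outputs in
#' the standard formats: genome FASTA, annotation GTF, junction-count /
#' expression / ground-truth TSVs, peak BED, signal bedGraph, screen-plate
#' TSV, methylation TSV and motif-window FASTAs. Outputs are bit-identical
#' across runs with the same configuration.
#'
#' @param config a [SimConfig-class].
#' @param dir output directory (created if needed).
#' @param pwm motif planted in the sequence windows; default the first motif
#'   of the packaged synthetic motif file.
#' @param sequence write the genome FASTA and motif windows?
#' @return Named character vector of the files written, invisibly.
#' @export
writeSimulation <- function(config, dir, pwm = NULL, sequence = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(dir, f)
  tsv <- function(df, f) {
    write.table(df, path(f), sep = "\t", quote = FALSE, row.names = FALSE)
    path(f)
  }
  ann <- simulateAnnotation(config, sequence = sequence)
  jc <- simulateJunctionCounts(config, ann)
  pk <- simulatePeaks(ann, jc$truth, config)
  tr <- simulateSignalTrack(ann, pk$peaks, config)
  sp <- simulateScreenPlate(config)
  mc <- simulateMethylationCounts(config)
  files <- c(
    gtf = writeGtfExons(annotationExons(ann), path("annotation.gtf")),
    counts = tsv(jc$counts, "junction_counts.tsv"),
    expression = tsv(jc$expression, "expression.tsv"),
    truth_events = tsv(jc$truth, "truth_events.tsv"),
    peaks = writeBed(pk$peaks, path("peaks.bed")),
    truth_peaks = tsv(pk$truth, "truth_peaks.tsv"),
    track = writeBedGraph(tr, path("signal.bedgraph")),
    plate = tsv(sp$plate, "screen_plate.tsv"),
    truth_screen = tsv(sp$truth, "truth_screen.tsv"),
    methylation = tsv(mc$counts, "methylation_counts.tsv"),
    truth_methylation = tsv(mc$truth, "truth_methylation.tsv")
  )
  if (sequence) {
    writeXStringSet(annotationGenome(ann), path("genome.fa"))
    if (is.null(pwm))
      pwm <- readMemeMotifs(system.file("extdata",
                                        "synthetic_rbp_motifs.meme",
                                        package = "splicechrom"))[[1]]
    mw <- simulateMotifWindows(config, pwm, n_fg = 20, n_bg = 20)
    writeXStringSet(mw$fg, path("motif_windows_fg.fa"))
    writeXStringSet(mw$bg, path("motif_windows_bg.fa"))
    files <- c(files, genome = path("genome.fa"),
               motif_fg = path("motif_windows_fg.fa"),
               motif_bg = path("motif_windows_bg.fa"))
  }
  invisible(files)
}

#' Peak-planting probability for a target enrichment ratio
#'
#' Closed-form calibration of `peak_fg_prob`: with background peaks Poisson at
#' `bg_rate_per_mbp`, an exon of width `exon_bp` is background-bound within a
#' `window_bp` half-window with probability
#' `q = 1 - exp(-rate * (2 * window_bp + exon_bp + peak_width))`. If the
#' foreground (`n_fg` planted exons) is part of the `n_total`-exon background
#' universe, the planted probability solving
#' `ratio = f * n_total / ((n_total - n_fg) * q + n_fg * f)` for the
#' foreground bound probability `f = 1 - (1 - p)(1 - q)` is returned.
#'
#' @param ratio target bound-proportion ratio (foreground vs all exons).
#' @param bg_rate_per_mbp background peak rate per Mbp.
#' @param window_bp half-window in bp.
#' @param exon_bp typical exon width in bp.
#' @param peak_width peak width in bp.
#' @param n_fg,n_total foreground size and exon-universe size.
#' @return The planting probability `p`.
#' @examples
#' peakFgProbForRatio(2.25, 8, 5000, 150, 300, 500, 4500)
#' @export
peakFgProbForRatio <- function(ratio, bg_rate_per_mbp, window_bp = 5000,
                               exon_bp = 150, peak_width = 300,
                               n_fg = 500, n_total = 4500) {
  q <- 1 - exp(-bg_rate_per_mbp / 1e6 * (2 * window_bp + exon_bp + peak_width))
  f <- ratio * (n_total - n_fg) * q / (n_total - ratio * n_fg)
  if (f <= q || f >= 1)
    stop("target ratio unattainable for this background rate and design")
  1 - (1 - f) / (1 - q)
}
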