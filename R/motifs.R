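#' Read motifs from MEME minimal-format text
#'
#' Parses `MOTIF` blocks with their `letter-probability matrix` sections and
#' the optional `Background letter frequencies` line (uniform when absent).
#' Motifs are DNA-encoded RNA-binding-protein motifs over A/C/G/T.
#'
#' @param path MEME-format motif file.
#' @return Named list of [PwmMotif-class] objects.
#' @export
readMemeMotifs <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  bg <- rep(0.25, 4)
  bg_idx <- grep("^Background letter frequencies", lines)
  if (length(bg_idx)) {
    toks <- strsplit(trimws(lines[bg_idx[1] + 1]), "[ \t]+")[[1]]
    freq <- suppressWarnings(as.numeric(toks[c(FALSE, TRUE)]))
    names(freq) <- toks[c(TRUE, FALSE)]
    if (all(c("A", "C", "G", "T") %in% names(freq)))
      bg <- unname(freq[c("A", "C", "G", "T")])
  }
  motif_idx <- grep("^MOTIF", lines)
  if (!length(motif_idx)) stop("no MOTIF blocks found in ", path)
  motifs <- list()
  for (mi in motif_idx) {
    id <- strsplit(trimws(lines[mi]), "[ \t]+")[[1]][2]
    li <- mi + 1
    while (li <= length(lines) &&
           !grepl("^letter-probability matrix", lines[li])) li <- li + 1
    if (li > length(lines))
      stop("motif ", id, ": missing letter-probability matrix")
    header <- lines[li]
    w <- suppressWarnings(as.integer(sub(".*w=\\s*(\\d+).*", "\\1", header)))
    if (is.na(w)) stop("motif ", id, ": cannot parse matrix width")
    rows <- lines[(li + 1):(li + w)]
    m <- t(vapply(rows, function(r)
      as.numeric(strsplit(trimws(r), "[ \t]+")[[1]][1:4]), numeric(4)))
    motifs[[id]] <- pwmMotif(id, t(m), background = bg)
  }
  motifs
}

#' Extract exon-plus-flank sequences for motif scanning
#'
#' Returns the exon body extended by `flank_bp` on each side. Minus-strand
#' sequences are reverse-complemented so scanning runs in sense (pre-mRNA)
#' orientation. Regions clipped at a contig boundary are flagged.
#'
#' @param exons stranded `GRanges`.
#' @param genome named `DNAStringSet`.
#' @param flank_bp flank in bp on each side of the exon.
#' @return `DNAStringSet` named after the exons, with a logical `clipped`
#'   metadata column.
#' @export
extractFlankSequences <- function(exons, genome, flank_bp = 10000) {
  if (!is(genome, "DNAStringSet") || is.null(names(genome)))
    stop("genome must be a named DNAStringSet")
  st <- as.character(strand(exons))
  if (any(st == "*")) stop("exons must be stranded (+/-)")
  chroms <- as.character(seqnames(exons))
  if (!all(chroms %in% names(genome)))
    stop("exon chromosome(s) missing from genome: ",
         paste(setdiff(chroms, names(genome)), collapse = ", "))
  clen <- width(genome)[match(chroms, names(genome))]
  s <- pmax(1, start(exons) - flank_bp)
  e <- pmin(clen, end(exons) + flank_bp)
  clipped <- (start(exons) - flank_bp < 1) | (end(exons) + flank_bp > clen)
  seqs <- DNAStringSet(lapply(seq_along(exons), function(i)
    subseq(genome[[chroms[i]]], s[i], e[i])))
  minus <- st == "-"
  if (any(minus)) seqs[minus] <- reverseComplement(seqs[minus])
  names(seqs) <- if (!is.null(names(exons))) names(exons) else
    sprintf("exon%05d", seq_along(exons))
  mcols(seqs)$clipped <- clipped
  seqs
}

pwmLogOdds <- function(pwm, background = NULL, pseudo = 1e-4) {
  bg <- if (is.null(background)) pwm@background else
    setNames(as.numeric(background), c("A", "C", "G", "T"))
  p <- (pwm@matrix + pseudo) / (1 + 4 * pseudo)
  bgn <- (bg + pseudo) / (1 + 4 * pseudo)
  log2(p / bgn)
}

#' Scan a sequence with a PWM
#'
#' Log-odds score against the background model at every sense-strand offset;
#' a hit is an offset scoring at least `threshold` times the maximum
#' attainable score. Windows containing non-ACGT bases are skipped.
#'
#' @param seq a `DNAString`, `character(1)`, or vector of characters.
#' @param pwm a [PwmMotif-class].
#' @param threshold hit threshold as a fraction of the maximum attainable
#'   log-odds score.
#' @param background optional base frequencies (A, C, G, T) overriding the
#'   motif's background model.
#' @return data.frame with 1-based `pos` and `score` per hit.
#' @examples
#' m <- pwmMotif("gcgc",
#'               matrix(c(0, 0, 1, 0,  0, 1, 0, 0), nrow = 4)[, c(1, 2, 1, 2)])
#' scanPwm("AAGCGCAA", m)
#' @export
scanPwm <- function(seq, pwm, threshold = 0.8, background = NULL) {
  lo <- pwmLogOdds(pwm, background)
  L <- ncol(lo)
  chars <- if (is(seq, "XString")) strsplit(as.character(seq), "")[[1]]
           else if (length(seq) == 1L) strsplit(as.character(seq), "")[[1]]
           else as.character(seq)
  idx <- match(chars, c("A", "C", "G", "T"))
  n <- length(idx)
  if (n < L) return(data.frame(pos = integer(0), score = numeric(0)))
  npos <- n - L + 1L
  scores <- numeric(npos)
  for (j in seq_len(L))
    scores <- scores + lo[cbind(idx[seq_len(npos) + j - 1L], j)]
  cutoff <- threshold * sum(apply(lo, 2, max))
  hit <- which(!is.na(scores) & scores >= cutoff)
  data.frame(pos = hit, score = scores[hit])
}

countPwmHits <- function(seqs, pwm, threshold = 0.8, background = NULL) {
  vapply(seq_along(seqs), function(i)
    nrow(scanPwm(seqs[[i]], pwm, threshold, background)), integer(1))
}

#' Motif enrichment between two sequence sets
#'
#' For each PWM, counts hit-containing windows in the foreground and
#' background sets and tests the window-level 2x2 table with Fisher's exact
#' two-sided test, BH-corrected across motifs. The density enrichment ratio
#' (hits per bp, fg/bg) is reported alongside. The scan background model is
#' the background set's base composition (0-order), recomputed per run.
#'
#' @param fg_seqs,bg_seqs `DNAStringSet` (or character vectors) of windows.
#' @param pwms a [PwmMotif-class] or list thereof.
#' @param threshold hit threshold passed to [scanPwm()].
#' @return data.frame, one row per motif: window counts, hit densities,
#'   `enrichment_ratio`, `p_value`, `q_value`.
#' @export
compareMotifSets <- function(fg_seqs, bg_seqs, pwms, threshold = 0.8) {
  if (!length(fg_seqs) || !length(bg_seqs))
    stop("both sequence sets must be non-empty")
  if (is(pwms, "PwmMotif")) pwms <- setNames(list(pwms), pwms@id)
  fg_seqs <- as(fg_seqs, "DNAStringSet")
  bg_seqs <- as(bg_seqs, "DNAStringSet")
  comp <- letterFrequency(bg_seqs, c("A", "C", "G", "T"), as.prob = FALSE)
  bg_model <- colSums(comp) / sum(comp)
  fg_bp <- sum(width(fg_seqs))
  bg_bp <- sum(width(bg_seqs))
  rows <- lapply(pwms, function(pwm) {
    fg_hits <- countPwmHits(fg_seqs, pwm, threshold, bg_model)
    bg_hits <- countPwmHits(bg_seqs, pwm, threshold, bg_model)
    tab <- matrix(c(sum(fg_hits > 0), sum(fg_hits == 0),
                    sum(bg_hits > 0), sum(bg_hits == 0)), nrow = 2)
    dens_fg <- sum(fg_hits) / fg_bp
    dens_bg <- sum(bg_hits) / bg_bp
    data.frame(motif_id = pwm@id,
               fg_windows_hit = tab[1, 1], fg_windows = length(fg_seqs),
               bg_windows_hit = tab[1, 2], bg_windows = length(bg_seqs),
               fg_hits = sum(fg_hits), fg_bp = fg_bp,
               bg_hits = sum(bg_hits), bg_bp = bg_bp,
               fg_density = dens_fg, bg_density = dens_bg,
               enrichment_ratio = if (dens_bg > 0) dens_fg / dens_bg else
                 NA_real_,
               p_value = fisher.test(tab, alternative = "two.sided")$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out
}

#' Motifs significant in every dataset
#'
#' Intersects the significantly enriched motifs (by `q_value`) of several
#' [compareMotifSets()] results — the cross-dataset filtering step that
#' narrows candidate RNA-binding proteins.
#'
#' @param ... two or more data.frames from [compareMotifSets()].
#' @param q_threshold significance cutoff on `q_value`.
#' @return Character vector of motif ids significant in all inputs.
#' @export
sharedMotifs <- function(..., q_threshold = 0.05) {
  results <- list(...)
  if (length(results) < 2L) stop("need at least two result sets")
  sig <- lapply(results, function(r)
    r$motif_id[!is.na(r$q_value) & r$q_value < q_threshold &
                 r$enrichment_ratio > 1])
  Reduce(intersect, sig)
}
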