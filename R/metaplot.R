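#' Binned signal profiles around exon anchors
#'
#' For each exon, averages the signal track in `bin_bp` bins covering
#' offsets `-half_size..+half_size` around the anchor (default the exon
#' midpoint), giving `2 * half_size / bin_bp + 1` bins (101 for the
#' defaults). Minus-strand profiles are reversed so positive offsets always
#' point downstream in transcription direction. Track gaps read as 0; bins
#' clipped at a contig boundary average the remaining bases and the exon is
#' flagged.
#'
#' @param exons stranded `GRanges`.
#' @param track `GRanges` with `score`, or `RleList`.
#' @param half_size half-window in bp (multiple of `bin_bp`).
#' @param bin_bp bin width in bp.
#' @param anchor `"center"` (default), `"start"` (5' end in transcription
#'   direction) or `"end"` (3' end).
#' @param normalize `"none"` (raw track means, default) or `"zscore"`
#'   (per-exon standardization).
#' @return Numeric matrix (exons x bins) with bin-center offsets as column
#'   names, plus attributes `offsets` and `clipped`.
#' @export
profileExons <- function(exons, track, half_size = 2500, bin_bp = 50,
                         anchor = c("center", "start", "end"),
                         normalize = c("none", "zscore")) {
  anchor <- match.arg(anchor)
  normalize <- match.arg(normalize)
  if (half_size %% bin_bp != 0)
    stop("half_size must be a multiple of bin_bp")
  st <- as.character(strand(exons))
  if (any(st == "*")) stop("exons must be stranded (+/-)")
  cov <- trackCoverage(track)
  offsets <- seq(-half_size, half_size, by = bin_bp)
  nb <- length(offsets)
  half_bin <- floor(bin_bp / 2)

  plus <- st == "+"
  mid <- switch(anchor,
    center = floor((start(exons) + end(exons)) / 2),
    start = ifelse(plus, start(exons), end(exons)),
    end = ifelse(plus, end(exons), start(exons)))

  # anchor convention that mirrors exactly: the midpoint rounds down on the
  # plus strand and up on the minus strand, and even-width bins place their
  # extra base downstream in transcription direction on both strands
  if (anchor == "center")
    mid <- ifelse(plus, mid, ceiling((start(exons) + end(exons)) / 2))

  n <- length(exons)
  mat <- matrix(NA_real_, nrow = n, ncol = nb)
  clipped <- logical(n)
  chroms <- as.character(seqnames(exons))
  # genomic offset of each bin: flipped for minus-strand exons
  for (ch in unique(chroms)) {
    idx <- which(chroms == ch)
    rle <- if (ch %in% names(cov)) cov[[ch]] else Rle(0, 1)
    sgn <- ifelse(plus[idx], 1, -1)
    centers <- rep(mid[idx], each = nb) +
      rep(sgn, each = nb) * rep(offsets, length(idx))
    lshift <- rep(ifelse(plus[idx], half_bin, bin_bp - 1 - half_bin),
                  each = nb)
    bstart <- centers - lshift
    bend <- bstart + bin_bp - 1
    max_end <- max(bend)
    if (max_end > length(rle)) rle <- c(rle, Rle(0, max_end - length(rle)))
    cs <- pmax(1, bstart)
    ce <- pmax(0, bend)
    valid <- ce >= cs
    vals <- rep(NA_real_, length(cs))
    if (any(valid)) {
      v <- Views(rle, start = cs[valid], end = ce[valid])
      vals[valid] <- viewMeans(v)
    }
    m <- matrix(vals, nrow = nb)
    was_clipped <- matrix(bstart < 1, nrow = nb)
    mat[idx, ] <- t(m)
    clipped[idx] <- colSums(was_clipped) > 0 | colSums(matrix(!valid, nrow = nb)) > 0
  }
  if (normalize == "zscore") {
    mu <- rowMeans(mat, na.rm = TRUE)
    sdv <- apply(mat, 1, sd, na.rm = TRUE)
    sdv[sdv == 0 | is.na(sdv)] <- 1
    mat <- (mat - mu) / sdv
  }
  colnames(mat) <- offsets
  rownames(mat) <- if (!is.null(names(exons))) names(exons) else NULL
  attr(mat, "offsets") <- offsets
  attr(mat, "clipped") <- clipped
  mat
}

wilcoxBinP <- function(a, b, exact_limit = 400) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) == 0L || length(b) == 0L) return(NA_real_)
  if (all(a == a[1]) && all(b == b[1]) && a[1] == b[1]) return(1)
  use_exact <- length(a) * length(b) <= exact_limit &&
    !anyDuplicated(c(a, b))
  suppressWarnings(wilcox.test(a, b, alternative = "two.sided",
                               exact = use_exact)$p.value)
}

#' Compare binned profiles of two exon groups
#'
#' Per-bin two-sided Wilcoxon rank-sum test between the per-exon bin values
#' of groups A and B (exact null distribution when `n * m <= 400` and there
#' are no ties, tie-corrected normal approximation otherwise), with BH
#' correction across bins.
#'
#' @param mat_a,mat_b matrices from [profileExons()] with identical bin
#'   layouts and >= 3 exons each.
#' @param labels group names.
#' @return A [BinProfileComparison-class].
#' @export
compareProfiles <- function(mat_a, mat_b, labels = c("A", "B")) {
  off_a <- attr(mat_a, "offsets")
  off_b <- attr(mat_b, "offsets")
  if (is.null(off_a)) off_a <- as.numeric(colnames(mat_a))
  if (is.null(off_b)) off_b <- as.numeric(colnames(mat_b))
  if (!identical(off_a, off_b)) stop("bin layouts differ between groups")
  if (nrow(mat_a) < 3L || nrow(mat_b) < 3L)
    stop("need >= 3 exons per group")
  nb <- length(off_a)
  p <- vapply(seq_len(nb), function(j) wilcoxBinP(mat_a[, j], mat_b[, j]),
              numeric(1))
  sem <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2L) return(NA_real_)
    sd(x) / sqrt(length(x))
  }
  new("BinProfileComparison",
      offsets = as.numeric(off_a),
      mean_a = colMeans(mat_a, na.rm = TRUE),
      sem_a = apply(mat_a, 2, sem),
      n_a = rep(nrow(mat_a), nb),
      mean_b = colMeans(mat_b, na.rm = TRUE),
      sem_b = apply(mat_b, 2, sem),
      n_b = rep(nrow(mat_b), nb),
      p = p,
      q = p.adjust(p, method = "BH"),
      labels = labels)
}

#' Metaplot comparison of included vs excluded exons
#'
#' Splits called events by direction (`included-in-mutant` vs
#' `excluded-in-mutant`) and compares their signal profiles bin by bin.
#'
#' @param events `GRanges` of called cassette exons with a `direction`
#'   metadata column.
#' @param track signal track (`GRanges` with `score`, or `RleList`).
#' @param ... passed to [profileExons()].
#' @return A [BinProfileComparison-class] with groups
#'   `included-in-mutant` (A) and `excluded-in-mutant` (B).
#' @export
includedVsExcludedProfile <- function(events, track, ...) {
  if (is.null(events$direction)) stop("events must carry a direction column")
  inc <- events[events$direction == "included-in-mutant"]
  exc <- events[events$direction == "excluded-in-mutant"]
  if (!length(inc) || !length(exc))
    stop("empty group: need events in both directions")
  compareProfiles(profileExons(inc, track, ...),
                  profileExons(exc, track, ...),
                  labels = c("included-in-mutant", "excluded-in-mutant"))
}

weightedRleQuantile <- function(cov, prob) {
  vals <- unlist(lapply(cov, runValue), use.names = FALSE)
  lens <- unlist(lapply(cov, runLength), use.names = FALSE)
  ord <- order(vals)
  vals <- vals[ord]
  cum <- cumsum(as.numeric(lens[ord]))
  vals[which(cum >= prob * cum[length(cum)])[1]]
}

#' Locate paused-polymerase sites near exons
#'
#' Operational definition: within each exon's `window_bp` window, the
#' position of maximal signal, retained when that maximum exceeds the
#' genome-wide signal quantile `q`.
#'
#' @param track signal track (`GRanges` with `score`, or `RleList`).
#' @param exons stranded `GRanges` anchoring the search windows.
#' @param window_bp half-window in bp.
#' @param q signal quantile (weighted by run length) a maximum must exceed.
#' @return `GRanges` of width-1 sites with `height` and `exon_index`
#'   metadata.
#' @export
findPausedSites <- function(track, exons, window_bp = 5000, q = 0.9) {
  cov <- trackCoverage(track)
  thr <- weightedRleQuantile(cov, q)
  win <- exonWindow(exons, window_bp)
  chroms <- as.character(seqnames(win))
  out <- list()
  for (ch in unique(chroms)) {
    if (!ch %in% names(cov)) next
    idx <- which(chroms == ch)
    rle <- cov[[ch]]
    s <- pmax(1, start(win)[idx])
    e <- pmin(length(rle), end(win)[idx])
    ok <- e >= s
    if (!any(ok)) next
    v <- Views(rle, start = s[ok], end = e[ok])
    mx <- viewMaxs(v)
    wm <- viewWhichMaxs(v)
    keep <- mx > thr
    if (!any(keep)) next
    out[[ch]] <- GRanges(ch, IRanges(wm[keep], width = 1),
                         height = mx[keep],
                         exon_index = idx[ok][keep])
  }
  if (!length(out))
    return(GRanges(height = numeric(0), exon_index = integer(0)))
  sort(do.call(c, unname(out)), ignore.strand = TRUE)
}
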