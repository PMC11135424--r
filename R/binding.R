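#' Symmetric window around an exon
#'
#' Extends an exon by `window_bp` on both sides, clipping at the chromosome
#' start; strand is preserved.
#'
#' @param exons `GRanges`.
#' @param window_bp half-window size in bp (> 0).
#' @return `GRanges` of windows.
#' @examples
#' ex <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 1100), "+")
#' exonWindow(ex, 5000)  # clipped at base 1
#' @export
exonWindow <- function(exons, window_bp) {
  if (length(window_bp) != 1L || is.na(window_bp) || window_bp <= 0)
    stop("window_bp must be a single positive number")
  sl <- seqlengths(exons)[as.character(seqnames(exons))]
  new_end <- end(exons) + window_bp
  if (!all(is.na(sl))) new_end <- pmin(new_end, ifelse(is.na(sl), new_end, sl))
  gr <- GRanges(seqnames(exons), IRanges(pmax(1, start(exons) - window_bp),
                                         new_end),
                strand = strand(exons))
  mcols(gr) <- mcols(exons)
  seqlengths(gr) <- seqlengths(exons)[seqlevels(gr)]
  gr
}

#' Is any peak within the exon window?
#'
#' `TRUE` iff at least one peak overlaps the `window_bp` window around the
#' exon by >= 1 bp. Peaks are undirected: strand is ignored.
#'
#' @param exons `GRanges`.
#' @param peaks `GRanges` of peak intervals.
#' @param window_bp half-window in bp.
#' @return Logical vector along `exons`.
#' @export
isBound <- function(exons, peaks, window_bp) {
  countOverlaps(exonWindow(exons, window_bp), peaks,
                ignore.strand = TRUE) > 0
}

#' Binding enrichment of a foreground exon set over a background
#'
#' Counts bound/unbound exons (deduplicated by coordinates) in each set
#' within a window and compares them. The headline statistic is the ratio of
#' bound proportions (relative risk), the scale on which "binds X-times more
#' often" is reported; the odds ratio is returned alongside. The default
#' two-sided test is Fisher's exact; `test = "t"` performs a two-sample
#' Student t-test on the 0/1 bound indicators instead.
#'
#' @param fg_exons,bg_exons foreground and background exon `GRanges`. The
#'   background may contain the foreground (e.g. "all expressed exons") or be
#'   disjoint (e.g. non-mis-spliced exons of the same genes).
#' @param peaks peak `GRanges`.
#' @param window_bp half-window in bp.
#' @param test `"fisher"` (default) or `"t"`.
#' @return A [BindingComparison-class].
#' @export
enrichmentVsBackground <- function(fg_exons, bg_exons, peaks,
                                   window_bp = 5000,
                                   test = c("fisher", "t")) {
  test <- match.arg(test)
  if (!length(fg_exons) || !length(bg_exons))
    stop("foreground and background exon sets must be non-empty")
  fg <- unique(granges(fg_exons))
  bg <- unique(granges(bg_exons))
  fgb <- isBound(fg, peaks, window_bp)
  bgb <- isBound(bg, peaks, window_bp)
  tab <- matrix(c(sum(fgb), sum(!fgb), sum(bgb), sum(!bgb)), nrow = 2,
                dimnames = list(bound = c("yes", "no"),
                                set = c("fg", "bg")))
  p_fg <- mean(fgb)
  p_bg <- mean(bgb)
  ratio <- if (p_bg > 0) p_fg / p_bg else NA_real_
  odds <- (tab[1, 1] * tab[2, 2]) / (tab[2, 1] * tab[1, 2])
  pv <- if (test == "fisher") {
    fisher.test(tab, alternative = "two.sided")$p.value
  } else {
    if (length(fgb) < 2L || length(bgb) < 2L ||
        (sd(fgb) == 0 && sd(bgb) == 0)) NA_real_
    else t.test(as.numeric(fgb), as.numeric(bgb))$p.value
  }
  new("BindingComparison", window_bp = as.numeric(window_bp),
      n_fg_bound = sum(fgb), n_fg_total = length(fgb),
      n_bg_bound = sum(bgb), n_bg_total = length(bgb),
      ratio = ratio, odds_ratio = odds, p_value = pv, test = test)
}

flankRanges <- function(exons, window_bp, side = c("downstream", "upstream")) {
  side <- match.arg(side)
  st <- as.character(strand(exons))
  if (any(st == "*"))
    stop("exons must be stranded (+/-) for directional occupancy")
  plus <- st == "+"
  right <- if (side == "downstream") plus else !plus
  starts <- ifelse(right, end(exons) + 1, pmax(1, start(exons) - window_bp))
  ends <- ifelse(right, end(exons) + window_bp, pmax(0, start(exons) - 1))
  empty <- ends < starts  # exon at contig start has no left flank
  starts[empty] <- 1; ends[empty] <- 0
  GRanges(seqnames(exons), IRanges(starts, ends), strand = strand(exons))
}

#' Strand-aware upstream/downstream peak occupancy
#'
#' For each exon, flags whether any peak overlaps the downstream flank
#' (`[end, end + window)` on `+`, mirrored on `-`) or the upstream flank.
#' Peaks overlapping the exon body are excluded from both flanks so the two
#' flags partition flanking occupancy.
#'
#' @param exons stranded `GRanges`.
#' @param peaks peak `GRanges`.
#' @param window_bp flank width in bp.
#' @return data.frame with logical `upstream` and `downstream` per exon.
#' @seealso [directionalEnrichment()]
#' @export
directionalOccupancy <- function(exons, peaks, window_bp = 5000) {
  body_hits <- findOverlaps(exons, peaks, ignore.strand = TRUE)
  body_key <- paste(queryHits(body_hits), subjectHits(body_hits))
  flag <- function(side) {
    fl <- flankRanges(exons, window_bp, side)
    keep <- width(fl) > 0
    hits <- findOverlaps(fl, peaks, ignore.strand = TRUE)
    ok <- !(paste(queryHits(hits), subjectHits(hits)) %in% body_key)
    out <- rep(FALSE, length(exons))
    out[unique(queryHits(hits)[ok])] <- TRUE
    out & keep
  }
  data.frame(upstream = flag("upstream"), downstream = flag("downstream"))
}

#' Test downstream vs upstream occupancy excess
#'
#' Fisher's exact two-sided test of the 2x2 table (downstream bound/unbound
#' vs upstream bound/unbound) from [directionalOccupancy()].
#'
#' @param occupancy data.frame from [directionalOccupancy()].
#' @return list with counts, the downstream/upstream bound ratio and
#'   `p_value`.
#' @export
directionalEnrichment <- function(occupancy) {
  nd <- sum(occupancy$downstream)
  nu <- sum(occupancy$upstream)
  n <- nrow(occupancy)
  tab <- matrix(c(nd, n - nd, nu, n - nu), nrow = 2,
                dimnames = list(bound = c("yes", "no"),
                                flank = c("downstream", "upstream")))
  list(n_exons = n, n_downstream = nd, n_upstream = nu,
       ratio = if (nu > 0) nd / nu else NA_real_,
       p_value = fisher.test(tab, alternative = "two.sided")$p.value)
}

#' Hypergeometric gene-set enrichment
#'
#' One-sided upper-tail hypergeometric test per gene set (equivalent to a
#' one-sided Fisher test of overlap), BH-corrected across sets. Sets are
#' intersected with the universe first; sets disjoint from the universe are
#' skipped with a warning.
#'
#' @param query_genes character vector, subset of `universe`.
#' @param gene_sets named list of character vectors.
#' @param universe character vector of eligible genes.
#' @return data.frame with per-set `set_size` (within universe), `overlap`,
#'   `p_value`, `q_value`.
#' @export
genesetEnrichment <- function(query_genes, gene_sets, universe) {
  query_genes <- unique(query_genes)
  universe <- unique(universe)
  if (!all(query_genes %in% universe))
    stop("query genes must be a subset of the universe")
  N <- length(universe)
  nq <- length(query_genes)
  rows <- lapply(names(gene_sets), function(nm) {
    s <- intersect(unique(gene_sets[[nm]]), universe)
    if (!length(s)) {
      warning("gene set '", nm, "' is disjoint from the universe; skipped")
      return(NULL)
    }
    k <- length(intersect(query_genes, s))
    p <- phyper(k - 1, length(s), N - length(s), nq, lower.tail = FALSE)
    data.frame(set = nm, set_size = length(s), overlap = k, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    return(data.frame(set = character(0), set_size = integer(0),
                      overlap = integer(0), p_value = numeric(0),
                      q_value = numeric(0)))
  out$q_value <- p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out
}
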