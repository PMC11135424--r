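#' Read a BED file of genomic intervals
#'
#' BED coordinates (0-based half-open) are converted to the 1-based closed
#' convention of [GenomicRanges::GRanges]. Missing strand becomes `*`
#' (undirected), missing scores become `NA`. Lines starting with `track`,
#' `browser` or `#` are ignored.
#'
#' @param path BED3/BED6 file.
#' @return A `GRanges` with `name` and `score` metadata columns.
#' @examples
#' f <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t200\tp1\t5\t-", f)
#' readBed(f)
#' @seealso [writeBed()]
#' @export
readBed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (!length(idx))
    return(GRanges(name = character(0), score = numeric(0)))
  fields <- strsplit(trimws(lines[idx]), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop("malformed BED line ", idx[which(nf < 3L)[1]],
         ": fewer than 3 fields")
  chrom <- vapply(fields, `[[`, "", 1L)
  start0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start0) | is.na(end))
  if (length(bad))
    stop("malformed BED line ", idx[bad[1]], ": non-numeric coordinates")
  if (any(start0 < 0))
    stop("malformed BED line ", idx[which(start0 < 0)[1]], ": negative start")
  ge <- which(start0 >= end)
  if (length(ge))
    stop("BED line ", idx[ge[1]], ": start >= end")
  name <- ifelse(nf >= 4L, vapply(fields, function(f) f[min(4L, length(f))], ""),
                 NA_character_)
  name[name == "."] <- NA_character_
  score_chr <- ifelse(nf >= 5L,
                      vapply(fields, function(f) f[min(5L, length(f))], ""),
                      NA_character_)
  score <- suppressWarnings(as.numeric(ifelse(score_chr == ".", NA, score_chr)))
  strand_chr <- ifelse(nf >= 6L,
                       vapply(fields, function(f) f[min(6L, length(f))], ""),
                       ".")
  ok <- strand_chr %in% c("+", "-", ".")
  if (!all(ok))
    stop("malformed BED line ", idx[which(!ok)[1]], ": invalid strand '",
         strand_chr[which(!ok)[1]], "'")
  strand_chr[strand_chr == "."] <- "*"
  GRanges(chrom, IRanges(start0 + 1, end), strand = strand_chr,
          name = name, score = score)
}

#' Write intervals as BED
#'
#' Emits the minimal number of columns (3-6) needed to preserve the present
#' fields, so that read -> write -> read round-trips are exact.
#'
#' @param gr a `GRanges`, optionally with `name`/`score` metadata.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeBed <- function(gr, path) {
  n <- length(gr)
  name <- if (!is.null(gr$name)) gr$name else rep(NA_character_, n)
  score <- if (!is.null(gr$score)) gr$score else rep(NA_real_, n)
  strand_chr <- as.character(strand(gr))
  has_strand <- any(strand_chr != "*")
  has_score <- any(!is.na(score))
  has_name <- any(!is.na(name))
  ncol <- if (has_strand) 6L else if (has_score) 5L else if (has_name) 4L else 3L
  strand_chr[strand_chr == "*"] <- "."
  cols <- list(as.character(seqnames(gr)),
               formatNum(start(gr) - 1L),
               formatNum(end(gr)))
  if (ncol >= 4L) cols <- c(cols, list(ifelse(is.na(name), ".", name)))
  if (ncol >= 5L)
    cols <- c(cols, list(ifelse(is.na(score), ".", formatNum(score))))
  if (ncol >= 6L) cols <- c(cols, list(strand_chr))
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

# element-wise numeric formatting so mixed vectors round-trip exactly
formatNum <- function(x) {
  vapply(x, function(v) format(v, trim = TRUE, scientific = FALSE), "")
}

#' Read a bedGraph signal track
#'
#' Runs must be non-overlapping within each chromosome (flat track); bases
#' outside any run read as 0. Values are taken as already library-size
#' normalized; `scale_factor` multiplies all values on read.
#'
#' @param path 4-column bedGraph file.
#' @param scale_factor multiplier applied to every value.
#' @return A `GRanges` with a numeric `score` column, sorted by position.
#' @seealso [writeBedGraph()], [trackCoverage()]
#' @export
readBedGraph <- function(path, scale_factor = 1) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (!length(idx)) return(GRanges(score = numeric(0)))
  fields <- strsplit(trimws(lines[idx]), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 4L))
    stop("malformed bedGraph line ", idx[which(nf < 4L)[1]],
         ": fewer than 4 fields")
  chrom <- vapply(fields, `[[`, "", 1L)
  start0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  value <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 4L)))
  if (any(is.na(start0) | is.na(end)))
    stop("malformed bedGraph line ",
         idx[which(is.na(start0) | is.na(end))[1]], ": non-numeric coordinates")
  if (any(is.na(value)))
    stop("bedGraph line ", idx[which(is.na(value))[1]], ": non-numeric value")
  if (any(!is.finite(value)))
    stop("bedGraph line ", idx[which(!is.finite(value))[1]],
         ": non-finite value")
  if (any(start0 >= end))
    stop("bedGraph line ", idx[which(start0 >= end)[1]], ": start >= end")
  gr <- GRanges(chrom, IRanges(start0 + 1, end),
                score = value * scale_factor)
  gr <- sort(gr)
  for (ch in unique(as.character(seqnames(gr)))) {
    g <- gr[seqnames(gr) == ch]
    if (length(g) > 1L && any(start(g)[-1] <= end(g)[-length(g)]))
      stop("overlapping bedGraph runs on ", ch,
           ": tracks must be flat (non-overlapping runs)")
  }
  gr
}

#' Write a signal track as bedGraph
#'
#' @param gr a `GRanges` with a numeric `score` column.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeBedGraph <- function(gr, path) {
  if (is.null(gr$score)) stop("track must carry a score column")
  gr <- sort(gr)
  writeLines(paste(as.character(seqnames(gr)),
                   formatNum(start(gr) - 1L),
                   formatNum(end(gr)),
                   formatNum(gr$score),
                   sep = "\t"),
             path)
  invisible(path)
}

#' Convert a bedGraph-style track to per-chromosome run-length coverage
#'
#' @param track a `GRanges` with `score`, or an `RleList` (returned as-is).
#' @return A named `RleList` of per-base signal, 0 in gaps.
#' @export
trackCoverage <- function(track) {
  if (is(track, "RleList")) return(track)
  if (!is(track, "GRanges") || is.null(track$score))
    stop("track must be a GRanges with a score column or an RleList")
  coverage(track, weight = "score")
}

#' Query a signal track at single positions
#'
#' @param track `GRanges` with `score` or `RleList`.
#' @param chrom chromosome name(s).
#' @param pos 1-based position(s).
#' @return Numeric signal values; 0 outside any run or beyond the track.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100), score = 2)
#' trackValue(gr, "chr1", c(50, 150))
#' @export
trackValue <- function(track, chrom, pos) {
  cov <- trackCoverage(track)
  chrom <- rep_len(as.character(chrom), length(pos))
  vapply(seq_along(pos), function(i) {
    if (!chrom[i] %in% names(cov)) return(0)
    r <- cov[[chrom[i]]]
    if (pos[i] < 1 || pos[i] > length(r)) return(0)
    as.numeric(r[pos[i]])
  }, numeric(1))
}

#' Read exon records from a GTF annotation
#'
#' Imports via `rtracklayer` and keeps `exon` features only. GTF 1-based
#' closed coordinates match the internal `GRanges` convention, so no shift is
#' applied. Exons must carry `gene_id` and an orientation (`+`/`-`): exons
#' drive strand-aware upstream/downstream logic, so undirected exons are
#' rejected.
#'
#' @param path GTF file.
#' @return A `GRanges` of exons with `gene_id` and `transcript_id` metadata,
#'   ordered by transcript then start.
#' @export
readGtfExons <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  gr <- rtracklayer::import(path, format = "gtf")
  ex <- gr[gr$type == "exon"]
  if (!length(ex)) {
    mcols(ex) <- DataFrame(gene_id = character(0),
                           transcript_id = character(0))
    return(ex)
  }
  if (is.null(ex$gene_id) || anyNA(ex$gene_id))
    stop("exon without gene_id attribute")
  if (any(as.character(strand(ex)) == "*"))
    stop("exon with unknown strand: exons must be oriented (+/-)")
  tx <- if (!is.null(ex$transcript_id)) ex$transcript_id else ex$gene_id
  ord <- order(tx, start(ex))
  ex <- ex[ord]
  mcols(ex) <- mcols(ex)[, intersect(c("gene_id", "transcript_id", "exon_rank",
                                       "role"), colnames(mcols(ex))),
                         drop = FALSE]
  ex
}

#' Write exons as a GTF file
#'
#' Emits one `exon` feature line per range with `gene_id` and `transcript_id`
#' attributes (GTF2.2), deterministically.
#'
#' @param exons `GRanges` with `gene_id` and `transcript_id` metadata.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeGtfExons <- function(exons, path) {
  if (is.null(exons$gene_id)) stop("exons must carry gene_id")
  tx <- if (!is.null(exons$transcript_id)) exons$transcript_id else
    exons$gene_id
  attrs <- sprintf('gene_id "%s"; transcript_id "%s";', exons$gene_id, tx)
  if (!is.null(exons$exon_rank))
    attrs <- paste0(attrs, sprintf(' exon_number "%d";',
                                   as.integer(exons$exon_rank)))
  if (!is.null(exons$role))
    attrs <- paste0(attrs, sprintf(' exon_role "%s";', exons$role))
  writeLines(paste(as.character(seqnames(exons)), "splicechrom", "exon",
                   format(start(exons), trim = TRUE, scientific = FALSE),
                   format(end(exons), trim = TRUE, scientific = FALSE),
                   ".", as.character(strand(exons)), ".", attrs,
                   sep = "\t"),
             path)
  invisible(path)
}
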