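# Small shared fixtures built in code.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(Biostrings)
})

smallConfig <- function(seed = 11, ...) {
  simConfig(seed = seed, n_genes = 30, n_true_events = 10, genome_len = 1.5e6,
            ...)
}

packagedMotifs <- function() {
  readMemeMotifs(system.file("extdata", "synthetic_rbp_motifs.meme",
                             package = "splicechrom"))
}

# mirror a set of ranges through the point L+1-x per chromosome and flip
# strands: the genome read right-to-left
mirrorRanges <- function(gr, chrom_len) {
  new_start <- chrom_len + 1 - end(gr)
  new_end <- chrom_len + 1 - start(gr)
  st <- as.character(strand(gr))
  st[st == "+"] <- "p"; st[st == "-"] <- "+"; st[st == "p"] <- "-"
  out <- GenomicRanges::GRanges(seqnames(gr),
                                IRanges::IRanges(new_start, new_end),
                                strand = st)
  mcols(out) <- mcols(gr)
  out
}
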