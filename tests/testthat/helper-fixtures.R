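# Shared fixtures and brute-force per-base oracles. The oracles work on plain
# logical per-bp vectors so they stay independent of the interval machinery
# they check.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

tiny_genome <- function(lens = c(chr1 = 1000)) cs_genome(lens)

# random genome of n_chrom chromosomes, each <= max_len bp
random_genome <- function(n_chrom = 2, max_len = 10000) {
  lens <- sample(500:max_len, n_chrom, replace = TRUE)
  names(lens) <- paste0("chr", seq_len(n_chrom))
  cs_genome(lens)
}

# random interval set on a genome (1-based closed GRanges)
random_intervals <- function(genome, n = 20, max_w = 400) {
  ch <- sample(names(genome$seqlengths), n, replace = TRUE)
  len <- genome$seqlengths[ch]
  w <- pmin(sample(1:max_w, n, replace = TRUE), len)
  s <- vapply(seq_len(n), function(i) sample.int(len[i] - w[i] + 1, 1), integer(1))
  GRanges(ch, IRanges(s, width = w), seqlengths = genome$seqlengths)
}

# per-bp logical occupancy vectors, one per chromosome
bp_mask <- function(gr, genome) {
  lapply(setNames(nm = names(genome$seqlengths)), function(ch) {
    v <- logical(genome$seqlengths[[ch]])
    sel <- gr[seqnames(gr) == ch]
    for (i in seq_along(sel)) v[start(sel)[i]:end(sel)[i]] <- TRUE
    v
  })
}

# logical per-bp masks -> GRanges (for comparing interval results to oracles)
mask_to_gr <- function(masks) {
  pieces <- lapply(names(masks), function(ch) {
    r <- rle(masks[[ch]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    keep <- r$values
    if (!any(keep)) return(NULL)
    GRanges(factor(ch, levels = names(masks)), IRanges(starts[keep], ends[keep]))
  })
  pieces <- Filter(Negate(is.null), pieces)
  if (!length(pieces)) return(GRanges())
  do.call(c, pieces)
}

# strip seqinfo/mcols so interval sets can be compared structurally
bare <- function(gr) {
  r <- ranges(gr)
  names(r) <- NULL
  GRanges(as.character(seqnames(gr)), r)
}

write_lines <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# small deterministic dataset reused by several acceptance-style tests
small_config <- function(seed = 42) {
  sim_config(seed = seed, n_chrom = 2, chrom_length = 3e5, n_genes = 60,
             n_tes = 15, library_size = 5e4, n_nucleosomes = 60)
}
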