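#' Construct a genome object
#'
#' A genome is an ordered set of chromosome lengths plus, optionally, the
#' chromosome sequences. It anchors coordinate validation for every reader
#' and analysis function in the package.
#'
#' @param seqlengths Named numeric vector of chromosome lengths in bp
#'   (all > 0, unique non-empty names).
#' @param sequence Optional [Biostrings::DNAStringSet] whose names and widths
#'   match `seqlengths`.
#' @return An object of class `cs_genome`: a list with elements `seqlengths`
#'   and `sequence` (NULL when no sequence is attached).
#' @examples
#' gn <- cs_genome(c(chr1 = 1000, chr2 = 800))
#' genome_length(gn)
#' @export
cs_genome <- function(seqlengths, sequence = NULL) {
  if (is.null(names(seqlengths)) || anyDuplicated(names(seqlengths)) ||
      any(!nzchar(names(seqlengths)))) {
    stop("seqlengths must have unique, non-empty names")
  }
  if (any(seqlengths <= 0)) stop("chromosome lengths must be > 0")
  seqlengths <- setNames(as.numeric(seqlengths), names(seqlengths))
  if (!is.null(sequence)) {
    if (!methods::is(sequence, "DNAStringSet")) {
      sequence <- Biostrings::DNAStringSet(sequence)
    }
    if (!setequal(names(sequence), names(seqlengths))) {
      stop("sequence names do not match seqlengths names")
    }
    sequence <- sequence[names(seqlengths)]
    w <- Biostrings::width(sequence)
    if (any(w != seqlengths)) {
      stop("sequence lengths do not match declared chromosome lengths")
    }
  }
  structure(list(seqlengths = seqlengths, sequence = sequence),
            class = "cs_genome")
}

#' @rdname cs_genome
#' @param x A `cs_genome`.
#' @export
genome_length <- function(x) sum(x$seqlengths)

#' @export
print.cs_genome <- function(x, ...) {
  cat(sprintf("<cs_genome> %d chromosome(s), %.0f bp total%s\n",
              length(x$seqlengths), genome_length(x),
              if (is.null(x$sequence)) "" else ", with sequence"))
  invisible(x)
}

#' Read chromosome sizes from a two-column TSV
#'
#' @param path Path to a TSV with columns chromosome name and length.
#' @param fasta Optional FASTA path; when supplied, sequences are attached
#'   and checked against the declared lengths.
#' @return A [cs_genome].
#' @export
read_chrom_sizes <- function(path, fasta = NULL) {
  tab <- read.table(path, sep = "\t", header = FALSE,
                    colClasses = c("character", "numeric"))
  seqs <- if (!is.null(fasta)) Biostrings::readDNAStringSet(fasta) else NULL
  if (!is.null(seqs)) names(seqs) <- sub("\\s.*$", "", names(seqs))
  cs_genome(setNames(tab[[2]], tab[[1]]), sequence = seqs)
}

#' Build a genome directly from a FASTA file
#'
#' @param path FASTA path.
#' @return A [cs_genome] with sequence attached.
#' @export
read_genome_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  cs_genome(setNames(Biostrings::width(seqs), names(seqs)), sequence = seqs)
}

# GRanges helpers ------------------------------------------------------------

# Seqinfo for a cs_genome; used so GRanges operations know chromosome bounds.
.genome_seqinfo <- function(genome) {
  GenomeInfoDb::Seqinfo(seqnames = names(genome$seqlengths),
                        seqlengths = as.integer(genome$seqlengths))
}

# Empty GRanges on this genome.
.empty_gr <- function(genome) {
  GenomicRanges::GRanges(seqinfo = .genome_seqinfo(genome))
}

# GRanges spanning every chromosome end to end.
.whole_genome_gr <- function(genome) {
  GenomicRanges::GRanges(names(genome$seqlengths),
                         IRanges::IRanges(1L, as.integer(genome$seqlengths)),
                         seqinfo = .genome_seqinfo(genome))
}

# Validate that a GRanges lies within genome bounds; returns it with seqinfo.
.validate_gr <- function(gr, genome, what = "interval") {
  unknown <- setdiff(as.character(unique(GenomeInfoDb::seqnames(gr))),
                     names(genome$seqlengths))
  if (length(unknown)) {
    stop(sprintf("%s(s) on unknown chromosome(s): %s", what,
                 paste(unknown, collapse = ", ")))
  }
  GenomeInfoDb::seqlevels(gr) <- names(genome$seqlengths)
  lens <- genome$seqlengths[as.character(GenomeInfoDb::seqnames(gr))]
  bad <- GenomicRanges::start(gr) < 1 | GenomicRanges::end(gr) > lens
  if (any(bad)) {
    stop(sprintf("%d %s(s) extend outside chromosome bounds", sum(bad), what))
  }
  GenomeInfoDb::seqlengths(gr) <- as.integer(genome$seqlengths)
  gr
}
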