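# Overlap arithmetic between island sets and genome features. Everything is
# carried by IRanges/GenomicRanges set operations on merged interval sets.

#' Fraction of the genome covered by a set of intervals
#'
#' @param islands [GenomicRanges::GRanges] (merged internally).
#' @param genome A [cs_genome].
#' @return Covered bp / total genome bp, in \[0, 1\].
#' @export
genome_coverage <- function(islands, genome) {
  merged <- GenomicRanges::reduce(GenomicRanges::granges(islands),
                                  ignore.strand = TRUE)
  sum(GenomicRanges::width(merged)) / sum(genome$seqlengths)
}

#' Base-pair overlap between two interval sets
#'
#' @param a,b [GenomicRanges::GRanges]; each set is merged internally.
#' @return Total length of the intersection, in bp.
#' @export
pairwise_overlap_bp <- function(a, b) {
  ra <- GenomicRanges::reduce(GenomicRanges::granges(a), ignore.strand = TRUE)
  rb <- GenomicRanges::reduce(GenomicRanges::granges(b), ignore.strand = TRUE)
  sum(GenomicRanges::width(
    GenomicRanges::intersect(ra, rb, ignore.strand = TRUE)))
}

#' Regions shared by every mark
#'
#' @param mark_sets List (length >= 2) of [GenomicRanges::GRanges], one per
#'   mark.
#' @return List with `regions` (the n-way intersection, merged) and
#'   `total_bp` (its summed length).
#' @export
shared_regions <- function(mark_sets) {
  if (length(mark_sets) < 2) stop("need at least two mark sets")
  merged <- lapply(mark_sets, function(x) {
    GenomicRanges::reduce(GenomicRanges::granges(x), ignore.strand = TRUE)
  })
  inter <- Reduce(function(a, b) {
    GenomicRanges::intersect(a, b, ignore.strand = TRUE)
  }, merged)
  list(regions = inter, total_bp = sum(GenomicRanges::width(inter)))
}

#' Annotate features with per-mark island overlap
#'
#' A feature is marked iff it overlaps any island of that mark by at least
#' `min_overlap` bp; one island can mark several features (assignment is
#' non-exclusive).
#'
#' @param islands_by_mark Named list of island [GenomicRanges::GRanges], one
#'   per mark.
#' @param catalog A [feature_catalog].
#' @param min_overlap Minimum overlap in bp to call a feature marked.
#' @return A list of class `marked_feature_table`: `marked` (features x marks
#'   logical matrix), `feature_class` (factor gene/TE/intergenic per row),
#'   `counts` (marked-feature counts per mark x class), `coverage` (genome
#'   coverage fraction per mark) and `genome`.
#' @export
annotate_features <- function(islands_by_mark, catalog, min_overlap = 1) {
  stopifnot(min_overlap >= 1)
  if (is.null(names(islands_by_mark)) || any(!nzchar(names(islands_by_mark)))) {
    stop("islands_by_mark must be a named list")
  }
  feats <- c(GenomicRanges::granges(catalog$genes),
             GenomicRanges::granges(catalog$tes),
             GenomicRanges::granges(catalog$intergenic))
  cls <- factor(rep(c("gene", "TE", "intergenic"),
                    c(length(catalog$genes), length(catalog$tes),
                      length(catalog$intergenic))),
                levels = c("gene", "TE", "intergenic"))
  marked <- vapply(islands_by_mark, function(isl) {
    GenomicRanges::countOverlaps(feats, isl, minoverlap = min_overlap,
                                 ignore.strand = TRUE) > 0
  }, logical(length(feats)))
  marked <- matrix(marked, nrow = length(feats),
                   dimnames = list(names(feats), names(islands_by_mark)))
  counts <- t(vapply(names(islands_by_mark), function(m) {
    tapply(marked[, m], cls, sum)
  }, numeric(nlevels(cls))))
  coverage <- vapply(islands_by_mark, genome_coverage,
                     numeric(1), genome = catalog$genome)
  structure(list(marked = marked, feature_class = setNames(cls, names(feats)),
                 counts = counts, coverage = coverage,
                 genome = catalog$genome),
            class = "marked_feature_table")
}

#' @export
print.marked_feature_table <- function(x, ...) {
  cat(sprintf("<marked_feature_table> %d features x %d marks\n",
              nrow(x$marked), ncol(x$marked)))
  print(x$counts)
  invisible(x)
}

#' @export
#' @method as.data.frame marked_feature_table
as.data.frame.marked_feature_table <- function(x, ...) {
  data.frame(feature_id = rownames(x$marked),
             feature_class = as.character(x$feature_class),
             x$marked, row.names = NULL, check.names = FALSE)
}
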