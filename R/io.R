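# Readers and writers for the plain-text interval formats the pipeline
# consumes. BED-family files are 0-based half-open on disk and converted to
# 1-based closed GRanges at this boundary; GFF3 is 1-based closed already.

.split_bed_lines <- function(path, min_fields) {
  lines <- readLines(path)
  keep <- nzchar(lines) & !startsWith(lines, "#") & !startsWith(lines, "track")
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  lineno <- which(keep)
  nf <- lengths(fields)
  if (any(nf < min_fields)) {
    stop(sprintf("parse error at line %d: expected >= %d tab-separated fields",
                 lineno[which(nf < min_fields)[1]], min_fields))
  }
  list(fields = fields, lineno = lineno)
}

.bed_coords <- function(fields, lineno) {
  start0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- is.na(start0) | is.na(end0)
  if (any(bad)) {
    stop(sprintf("parse error at line %d: non-numeric coordinates",
                 lineno[which(bad)[1]]))
  }
  empty <- start0 >= end0
  if (any(empty)) {
    stop(sprintf("validation error at line %d: start >= end (empty interval)",
                 lineno[which(empty)[1]]))
  }
  list(start0 = start0, end0 = end0)
}

#' Read a BED3/BED6 file as genomic intervals
#'
#' Duplicated records are retained. Records on chromosomes absent from the
#' genome, or extending outside it, are errors.
#'
#' @param path BED3 or BED6 text file (0-based half-open coordinates).
#' @param genome A [cs_genome].
#' @return A [GenomicRanges::GRanges] (1-based closed), with `name` and
#'   `score` metadata columns when the file has 6 columns.
#' @export
read_bed <- function(path, genome) {
  parsed <- .split_bed_lines(path, 3L)
  if (!length(parsed$fields)) return(.empty_gr(genome))
  chrom <- vapply(parsed$fields, `[[`, "", 1L)
  co <- .bed_coords(parsed$fields, parsed$lineno)
  has6 <- all(lengths(parsed$fields) >= 6L)
  strand <- if (has6) vapply(parsed$fields, `[[`, "", 6L) else rep("*", length(chrom))
  strand[!strand %in% c("+", "-")] <- "*"
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(co$start0 + 1, co$end0),
                               strand = strand)
  if (has6) {
    mcols(gr)$name <- vapply(parsed$fields, `[[`, "", 4L)
    mcols(gr)$score <- suppressWarnings(as.numeric(vapply(parsed$fields, `[[`, "", 5L)))
  }
  .validate_gr(gr, genome, "BED record")
}

#' Read gene and TE annotations from GFF3
#'
#' Records of the requested feature types are collapsed by their `ID`
#' attribute: multiple records sharing an ID (e.g. exons of one gene) become a
#' single interval spanning min(start)..max(end). Records lacking an ID get a
#' synthesized one, with a warning.
#'
#' @param path GFF3 file (1-based inclusive coordinates).
#' @param genome A [cs_genome].
#' @param gene_types,te_types GFF3 `type` values treated as genes / TEs.
#' @return A [feature_catalog] with genes, TEs and derived intergenic space.
#' @export
read_gff3 <- function(path, genome, gene_types = "gene",
                      te_types = c("transposable_element", "repeat_region")) {
  gr <- rtracklayer::import(path, format = "gff3")
  pick <- function(types, label) {
    sel <- gr[as.character(gr$type) %in% types]
    if (!length(sel)) return(.empty_gr(genome))
    ids <- as.character(sel$ID)
    missing <- is.na(ids) | !nzchar(ids)
    if (any(missing)) {
      warning(sprintf("%d %s record(s) lack an ID attribute; IDs synthesized",
                      sum(missing), label))
      ids[missing] <- sprintf("%s_noid_%04d", label, seq_len(sum(missing)))
    }
    # span union per ID (handles multi-exon records)
    spl <- split(sel, ids)
    spans <- unlist(range(spl, ignore.strand = FALSE))
    out <- GenomicRanges::granges(spans)
    names(out) <- names(spl)
    mcols(out) <- NULL
    .validate_gr(out, genome, label)
  }
  feature_catalog(genes = pick(gene_types, "gene"),
                  tes = pick(te_types, "TE"),
                  genome = genome)
}

#' Assemble a feature catalog from gene and TE intervals
#'
#' Intergenic space is derived as the per-chromosome complement of the merged
#' gene-union-TE set, so the three classes tile each chromosome without gaps.
#' Overlaps between genes and TEs are permitted.
#'
#' @param genes,tes Named [GenomicRanges::GRanges] of gene / TE spans.
#' @param genome A [cs_genome].
#' @return A list of class `feature_catalog` with elements `genes`, `tes`,
#'   `intergenic` (names `intergenic_#####`) and `genome`.
#' @export
feature_catalog <- function(genes, tes, genome) {
  genes <- .validate_gr(genes, genome, "gene")
  tes <- .validate_gr(tes, genome, "TE")
  if (is.null(names(genes))) names(genes) <- sprintf("gene_%05d", seq_along(genes))
  if (is.null(names(tes))) names(tes) <- sprintf("TE_%05d", seq_along(tes))
  inter <- derive_intergenic(genes, tes, genome)
  structure(list(genes = genes, tes = tes, intergenic = inter, genome = genome),
            class = "feature_catalog")
}

#' @export
print.feature_catalog <- function(x, ...) {
  cat(sprintf("<feature_catalog> %d genes, %d TEs, %d intergenic segments\n",
              length(x$genes), length(x$tes), length(x$intergenic)))
  invisible(x)
}

#' Derive intergenic space as the complement of genes and TEs
#'
#' @param genes,tes [GenomicRanges::GRanges] of features.
#' @param genome A [cs_genome].
#' @return A [GenomicRanges::GRanges] of the per-chromosome complement of the
#'   merged union of `genes` and `tes`; chromosomes fully covered by features
#'   contribute nothing.
#' @export
derive_intergenic <- function(genes, tes, genome) {
  feats <- GenomicRanges::reduce(
    c(GenomicRanges::granges(genes), GenomicRanges::granges(tes)),
    ignore.strand = TRUE)
  inter <- GenomicRanges::setdiff(.whole_genome_gr(genome), feats,
                                  ignore.strand = TRUE)
  if (length(inter)) names(inter) <- sprintf("intergenic_%05d", seq_along(inter))
  inter
}

# Tag libraries ---------------------------------------------------------------

#' Construct a tag set from 5-prime positions
#'
#' @param chrom Chromosome per tag.
#' @param pos 1-based 5' position per tag.
#' @param genome A [cs_genome].
#' @return An object of class `tag_set`: per-chromosome sorted integer
#'   position vectors plus `library_size`.
#' @export
tag_set <- function(chrom, pos, genome) {
  stopifnot(length(chrom) == length(pos))
  unknown <- setdiff(unique(chrom), names(genome$seqlengths))
  if (length(unknown)) stop("tags on unknown chromosome(s): ",
                            paste(unknown, collapse = ", "))
  pos <- as.integer(round(pos))
  if (length(pos) && (any(pos < 1) || any(pos > genome$seqlengths[chrom]))) {
    stop("tag positions outside chromosome bounds")
  }
  by_chr <- lapply(setNames(nm = names(genome$seqlengths)),
                   function(ch) sort(pos[chrom == ch]))
  structure(list(pos = by_chr, library_size = length(pos),
                 seqlengths = genome$seqlengths),
            class = "tag_set")
}

#' @export
print.tag_set <- function(x, ...) {
  cat(sprintf("<tag_set> %d tags on %d chromosome(s)\n",
              x$library_size, length(x$pos)))
  invisible(x)
}

#' Read aligned tags from a BED-like file
#'
#' Each line is one aligned read; the 5' end is taken strand-aware (start for
#' `+`, end - 1 in 0-based terms for `-`) and optionally shifted toward the
#' fragment midpoint: `+shift` on the plus strand, `-shift` on the minus
#' strand. Shifted positions falling off the chromosome are clamped with a
#' warning.
#'
#' @param path BED-like text file (>= 3 columns; strand in column 6 when
#'   present, `+` assumed otherwise).
#' @param genome A [cs_genome].
#' @param shift Constant fragment shift in bp (default 73, half a 146 bp
#'   nucleosomal fragment).
#' @param dedup Drop duplicate (chromosome, position) tags after shifting.
#' @return A [tag_set].
#' @export
read_tags <- function(path, genome, shift = 73, dedup = FALSE) {
  parsed <- .split_bed_lines(path, 3L)
  if (!length(parsed$fields)) return(tag_set(character(), integer(), genome))
  chrom <- vapply(parsed$fields, `[[`, "", 1L)
  co <- .bed_coords(parsed$fields, parsed$lineno)
  has6 <- all(lengths(parsed$fields) >= 6L)
  strand <- if (has6) vapply(parsed$fields, `[[`, "", 6L) else rep("+", length(chrom))
  plus <- strand != "-"
  # 1-based 5' position: + reads start at start0+1; - reads end at end0
  pos <- ifelse(plus, co$start0 + 1 + shift, co$end0 - shift)
  unknown <- setdiff(unique(chrom), names(genome$seqlengths))
  if (length(unknown)) stop("tags on unknown chromosome(s): ",
                            paste(unknown, collapse = ", "))
  lens <- genome$seqlengths[chrom]
  clamped <- pos < 1 | pos > lens
  if (any(clamped)) {
    warning(sprintf("%d shifted tag position(s) clamped to chromosome bounds",
                    sum(clamped)))
    pos <- pmax(1, pmin(pos, lens))
  }
  if (dedup) {
    keep <- !duplicated(paste0(chrom, ":", pos))
    chrom <- chrom[keep]; pos <- pos[keep]
  }
  tag_set(chrom, pos, genome)
}

# bedGraph --------------------------------------------------------------------

#' Write a value track as bedGraph
#'
#' Runs of adjacent intervals with equal value are merged; intervals with
#' value 0 are suppressed unless `keep_zeros = TRUE`. Overlapping input
#' intervals are an error.
#'
#' @param track A [GenomicRanges::GRanges] with a numeric `score` column.
#' @param path Output path.
#' @param keep_zeros Emit zero-valued intervals too.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, keep_zeros = FALSE) {
  if (is.null(mcols(track)$score)) stop("track must carry a 'score' column")
  track <- GenomicRanges::sort(GenomicRanges::granges(track, use.mcols = TRUE),
                               ignore.strand = TRUE)
  if (length(track) > 1) {
    self <- GenomicRanges::findOverlaps(track, drop.self = TRUE,
                                        drop.redundant = TRUE,
                                        ignore.strand = TRUE)
    if (length(self)) stop("overlapping intervals in bedGraph track")
  }
  df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(track)),
                   start0 = GenomicRanges::start(track) - 1,
                   end0 = GenomicRanges::end(track),
                   value = mcols(track)$score)
  # merge runs of adjacent equal-valued intervals
  if (nrow(df) > 1) {
    new_run <- c(TRUE, df$chrom[-1] != df$chrom[-nrow(df)] |
                   df$start0[-1] != df$end0[-nrow(df)] |
                   df$value[-1] != df$value[-nrow(df)])
    run <- cumsum(new_run)
    df <- data.frame(chrom = tapply(df$chrom, run, `[`, 1),
                     start0 = tapply(df$start0, run, min),
                     end0 = tapply(df$end0, run, max),
                     value = tapply(df$value, run, `[`, 1))
  }
  if (!keep_zeros) df <- df[df$value != 0, , drop = FALSE]
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph file
#'
#' @param path bedGraph text file.
#' @param genome A [cs_genome].
#' @return [GenomicRanges::GRanges] with a `score` column.
#' @export
read_bedgraph <- function(path, genome) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  .validate_gr(gr, genome, "bedGraph record")
}

#' Write called islands as BED6+4
#'
#' Columns: chrom, start (0-based), end, name, score, strand, fold, p, q,
#' treatment count.
#'
#' @param islands GRanges from [call_islands()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_islands <- function(islands, path) {
  df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(islands)),
                   start0 = GenomicRanges::start(islands) - 1,
                   end0 = GenomicRanges::end(islands),
                   name = sprintf("island_%05d", seq_along(islands)),
                   score = round(mcols(islands)$score, 3),
                   strand = ".",
                   fold = signif(mcols(islands)$fold, 6),
                   p = signif(mcols(islands)$p, 6),
                   q = signif(mcols(islands)$q, 6),
                   treatment_count = mcols(islands)$treatment_count)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
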