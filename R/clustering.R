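# Positional clustering of within-gene marking: a binary occupancy matrix
# over upstream/body/downstream bins, complete-linkage clustering, and
# per-cluster expression summaries.

#' Binary positional-occupancy matrix of one mark over genes
#'
#' Rows are marked genes, columns are bins spanning the upstream flank, the
#' length-normalized gene body, and the downstream flank (default 10/10/10 =
#' 30 bins). A bin is 1 iff at least one island bp overlaps its span. Body
#' bins use fractional binning: a bp contributes to the bin containing its
#' rescaled midpoint. Minus-strand genes are flipped so bin 1 is 5'-most.
#' Genes with no overlapping island are absent from the matrix; genes shorter
#' than 10 bp are skipped with a warning.
#'
#' @param islands [GenomicRanges::GRanges] of one mark's islands.
#' @param genes Named, stranded [GenomicRanges::GRanges] of gene spans.
#' @param genome A [cs_genome].
#' @param flank Flank length in bp (default 500).
#' @param bins Integer triple: upstream, body, downstream bin counts.
#' @return Integer 0/1 matrix, marked genes x `sum(bins)`.
#' @export
positional_matrix <- function(islands, genes, genome, flank = 500,
                              bins = c(10, 10, 10)) {
  stopifnot(length(bins) == 3, all(bins > 0), flank %% bins[1] == 0,
            flank %% bins[3] == 0)
  if (is.null(names(genes))) stop("genes must be named")
  short <- GenomicRanges::width(genes) < 10
  if (any(short)) {
    warning(sprintf("%d gene(s) shorter than 10 bp skipped", sum(short)))
    genes <- genes[!short]
  }
  # per-chromosome logical island coverage
  merged <- GenomicRanges::reduce(GenomicRanges::granges(islands),
                                  ignore.strand = TRUE)
  cov <- lapply(setNames(nm = names(genome$seqlengths)), function(ch) {
    v <- logical(genome$seqlengths[[ch]])
    sel <- merged[GenomeInfoDb::seqnames(merged) == ch]
    for (i in seq_along(sel)) {
      v[GenomicRanges::start(sel)[i]:GenomicRanges::end(sel)[i]] <- TRUE
    }
    v
  })
  nb <- sum(bins)
  occ_bins <- function(covv, pos, bin, nbins) {
    ok <- pos >= 1 & pos <= length(covv)
    out <- logical(nbins)
    if (any(ok)) {
      hit <- tapply(covv[pos[ok]], factor(bin[ok], levels = seq_len(nbins)), any)
      out[which(hit)] <- TRUE
    }
    out
  }
  mat <- t(vapply(seq_along(genes), function(i) {
    ch <- as.character(GenomeInfoDb::seqnames(genes)[i])
    covv <- cov[[ch]]
    s <- GenomicRanges::start(genes)[i]
    e <- GenomicRanges::end(genes)[i]
    L <- e - s + 1
    up <- occ_bins(covv, (s - flank):(s - 1),
                   rep(seq_len(bins[1]), each = flank / bins[1]), bins[1])
    body_bin <- pmin(floor(((seq_len(L) - 0.5) / L) * bins[2]) + 1, bins[2])
    body <- occ_bins(covv, s:e, body_bin, bins[2])
    down <- occ_bins(covv, (e + 1):(e + flank),
                     rep(seq_len(bins[3]), each = flank / bins[3]), bins[3])
    v <- c(up, body, down)
    if (as.character(GenomicRanges::strand(genes)[i]) == "-") v <- rev(v)
    as.integer(v)
  }, integer(nb)))
  rownames(mat) <- names(genes)
  mat[rowSums(mat) > 0, , drop = FALSE]
}

#' Complete-linkage clustering of a positional matrix
#'
#' Agglomerative clustering of the binary rows, dendrogram cut at `k`
#' clusters, labels renumbered by descending cluster size (ties by first
#' occurrence). The procedure is deterministic for a given matrix.
#'
#' @param mat Binary matrix from [positional_matrix()].
#' @param k Number of clusters (default 6); `k > nrow(mat)` is an error.
#' @param metric Row distance: `euclidean` (default; the square root of the
#'   Hamming distance on 0/1 rows), `jaccard`, or `hamming`.
#' @return Object of class `positional_clusters`: `labels` (named integer,
#'   1..k), `k`, `metric`, `archetypes` (k x ncol mean bin matrix, one row
#'   per cluster), `sizes`, and the underlying `hclust` tree.
#' @export
cluster_positional <- function(mat, k = 6,
                               metric = c("euclidean", "jaccard", "hamming")) {
  metric <- match.arg(metric)
  if (nrow(mat) < k) stop("fewer rows than clusters")
  d <- switch(metric,
              euclidean = dist(mat, method = "euclidean"),
              jaccard = dist(mat, method = "binary"),
              hamming = dist(mat, method = "manhattan"))
  hc <- hclust(d, method = "complete")
  raw <- cutree(hc, k = k)
  # renumber by descending size; ties broken by first appearance
  tab <- table(raw)
  ord <- order(-as.numeric(tab), as.numeric(names(tab)))
  remap <- setNames(seq_len(k), names(tab)[ord])
  labels <- setNames(as.integer(remap[as.character(raw)]), rownames(mat))
  archetypes <- t(vapply(seq_len(k), function(cl) {
    colMeans(mat[labels == cl, , drop = FALSE])
  }, numeric(ncol(mat))))
  rownames(archetypes) <- paste0("C", seq_len(k))
  structure(list(labels = labels, k = k, metric = metric,
                 archetypes = archetypes,
                 sizes = as.integer(table(labels)), hclust = hc),
            class = "positional_clusters")
}

#' @export
print.positional_clusters <- function(x, ...) {
  cat(sprintf("<positional_clusters> %d rows in %d clusters (%s, complete linkage)\n",
              length(x$labels), x$k, x$metric))
  cat("sizes:", paste(x$sizes, collapse = ", "), "\n")
  invisible(x)
}

#' Expression summaries per positional cluster
#'
#' Five-number summary and mean per cluster plus the unmarked-gene group, and
#' the fraction of genes above the high-expression threshold (default
#' FPKM > 20).
#'
#' @param clusters A [positional_clusters][cluster_positional] result.
#' @param expr Named numeric FPKM vector covering clustered and unmarked
#'   genes.
#' @param unmarked_genes IDs of genes not marked (the complement of the
#'   matrix rows).
#' @param threshold High-expression cutoff (default 20 FPKM).
#' @return data.frame with one row per cluster (`C1`..`Ck`) and one for
#'   `unmarked`: n, five-number summary, mean, `frac_high`.
#' @export
cluster_expression <- function(clusters, expr, unmarked_genes,
                               threshold = 20) {
  groups <- setNames(paste0("C", clusters$labels), names(clusters$labels))
  groups <- c(groups, setNames(rep("unmarked", length(unmarked_genes)),
                               unmarked_genes))
  groups <- factor(groups, levels = c(paste0("C", seq_len(clusters$k)),
                                      "unmarked"))
  out <- expression_by_group(expr, groups, test = FALSE)
  out$frac_high <- vapply(levels(groups), function(g) {
    x <- expr[names(groups)[groups == g]]
    if (!length(x)) return(NA_real_)
    mean(x > threshold)
  }, numeric(1))
  out
}
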