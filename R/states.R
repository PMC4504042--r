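# Per-cytosine methylation calling, the per-gene mark matrix, combinatorial
# chromatin-state assignment, FPKM, and expression summaries by group.

#' Default mark-name constants
#'
#' Activating marks: H3K4me2 and H3K9_14Ac. Repressive marks: H3K9me2,
#' H3K9me3 and H3K27me3.
#' @name mark_names
#' @export
ACTIVE_MARKS <- c("H3K4me2", "H3K9_14Ac")

#' @rdname mark_names
#' @export
REPRESSIVE_MARKS <- c("H3K9me2", "H3K9me3", "H3K27me3")

#' Call methylated cytosines from bisulfite counts
#'
#' A site is called methylated iff it is covered by at least `min_reads`
#' reads and at least `min_fraction` of them support methylation.
#'
#' @param sites data.frame with columns `chrom`, `pos` (0-based), `strand`,
#'   `context` (CpG/CHG/CHH), `count_meth`, `count_total`.
#' @param min_reads Minimum read depth (default 3).
#' @param min_fraction Minimum methylated-read fraction (default 0.20).
#' @return `sites` with a logical `called` column appended.
#' @export
call_methylation <- function(sites, min_reads = 3, min_fraction = 0.20) {
  req <- c("chrom", "pos", "strand", "context", "count_meth", "count_total")
  if (!all(req %in% names(sites))) {
    stop("sites must have columns: ", paste(req, collapse = ", "))
  }
  if (any(sites$count_meth < 0) || any(sites$count_total < 0)) {
    stop("negative read counts")
  }
  if (any(sites$count_meth > sites$count_total)) {
    stop("count_meth exceeds count_total")
  }
  sites$called <- sites$count_total >= min_reads &
    sites$count_total > 0 &
    sites$count_meth / pmax(sites$count_total, 1) >= min_fraction
  sites
}

#' Features containing called methylated sites
#'
#' @param sites Output of [call_methylation()].
#' @param features Named [GenomicRanges::GRanges] (e.g. gene bodies).
#' @param min_sites Minimum number of called sites overlapping the feature
#'   body for the feature to count as methylated (default 1).
#' @return Character vector of methylated feature IDs.
#' @export
methylated_features <- function(sites, features, min_sites = 1) {
  called <- sites[sites$called, , drop = FALSE]
  if (!nrow(called)) return(character())
  pts <- GenomicRanges::GRanges(called$chrom,
                                IRanges::IRanges(called$pos + 1, width = 1))
  names(features)[GenomicRanges::countOverlaps(
    features, pts, ignore.strand = TRUE) >= min_sites]
}

#' Build the per-gene boolean mark matrix
#'
#' Combines histone-mark calls from [annotate_features()] (gene rows only)
#' with gene-level methylation into one boolean matrix; genes absent from any
#' input default to FALSE. Methylated IDs not in the gene universe are
#' dropped with a warning.
#'
#' @param marked A [marked_feature_table][annotate_features] or a logical
#'   genes-by-marks matrix with rownames.
#' @param methylated_genes Character vector of methylated gene IDs.
#' @return Logical matrix, genes x (marks, "mC").
#' @export
build_mark_matrix <- function(marked, methylated_genes = character()) {
  if (inherits(marked, "marked_feature_table")) {
    m <- marked$marked[marked$feature_class == "gene", , drop = FALSE]
  } else {
    m <- as.matrix(marked)
    if (is.null(rownames(m))) stop("mark matrix must have gene rownames")
  }
  storage.mode(m) <- "logical"
  unknown <- setdiff(methylated_genes, rownames(m))
  if (length(unknown)) {
    warning(sprintf("%d methylated gene ID(s) not in the gene universe; dropped",
                    length(unknown)))
  }
  cbind(m, mC = rownames(m) %in% methylated_genes)
}

#' Assign combinatorial chromatin states
#'
#' CS1 (activating): at least one activating mark and no repressive mark.
#' CS2 (repressive): at least one repressive mark and no activating mark.
#' CS3 (mixed): both present. Genes with neither are `unmarked`. Gene-body
#' methylation is not part of the state logic; it is reported alongside as a
#' parallel stratifier.
#'
#' @param mark_matrix Logical genes-by-marks matrix (from
#'   [build_mark_matrix()]; an `mC` column, if present, is ignored).
#' @param active,repressive Column names of the activating / repressive marks.
#' @return Named factor with levels CS1, CS2, CS3, unmarked.
#' @export
assign_state <- function(mark_matrix, active = ACTIVE_MARKS,
                         repressive = REPRESSIVE_MARKS) {
  mark_matrix <- rbind(mark_matrix)  # accept a single row vector
  missing <- setdiff(c(active, repressive), colnames(mark_matrix))
  if (length(missing)) {
    stop("mark matrix lacks column(s): ", paste(missing, collapse = ", "))
  }
  a <- rowSums(mark_matrix[, active, drop = FALSE]) > 0
  r <- rowSums(mark_matrix[, repressive, drop = FALSE]) > 0
  state <- ifelse(a & !r, "CS1", ifelse(r & !a, "CS2",
                  ifelse(a & r, "CS3", "unmarked")))
  factor(setNames(state, rownames(mark_matrix)),
         levels = c("CS1", "CS2", "CS3", "unmarked"))
}

#' Fragments per kilobase per million mapped fragments
#'
#' FPKM = count / ((length / 1000) * (library / 1e6)).
#'
#' @param counts Per-gene fragment counts.
#' @param gene_lengths Gene lengths in bp (> 0).
#' @param library Total mapped fragments (defaults to `sum(counts)`).
#' @return Numeric FPKM vector (names preserved from `counts`).
#' @export
compute_fpkm <- function(counts, gene_lengths, library = sum(counts)) {
  stopifnot(length(counts) == length(gene_lengths))
  if (any(gene_lengths <= 0)) stop("gene lengths must be > 0")
  if (library <= 0) stop("library size must be > 0")
  setNames(counts / ((gene_lengths / 1000) * (library / 1e6)), names(counts))
}

#' Expression summaries per group
#'
#' Five-number summary, mean and n per group, plus (optionally) a
#' Mann-Whitney test of each group against all other genes, BH-adjusted
#' across groups. Empty groups are reported with n = 0 and NA summaries.
#'
#' @param expr Named numeric expression vector.
#' @param groups Named factor/character mapping genes to groups; every
#'   grouped gene must have an expression value.
#' @param test Run the rank-based group-vs-rest test.
#' @return data.frame with one row per group: `group`, `n`, `min`, `q1`,
#'   `median`, `q3`, `max`, `mean` and, when `test`, `p` and `q`.
#' @export
expression_by_group <- function(expr, groups, test = TRUE) {
  groups <- as.factor(groups)
  if (is.null(names(groups))) stop("groups must be named by gene ID")
  vals <- expr[names(groups)]
  if (anyNA(vals)) stop("expression missing for some grouped genes")
  summ <- lapply(levels(groups), function(g) {
    x <- vals[groups == g]
    if (!length(x)) {
      return(data.frame(group = g, n = 0L, min = NA_real_, q1 = NA_real_,
                        median = NA_real_, q3 = NA_real_, max = NA_real_,
                        mean = NA_real_))
    }
    qs <- stats::quantile(x, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
    data.frame(group = g, n = length(x), min = qs[1], q1 = qs[2],
               median = qs[3], q3 = qs[4], max = qs[5], mean = mean(x))
  })
  out <- do.call(rbind, summ)
  if (test) {
    out$p <- vapply(levels(groups), function(g) {
      x <- vals[groups == g]
      y <- vals[groups != g]
      if (!length(x) || !length(y)) return(NA_real_)
      if (length(unique(c(x, y))) == 1) return(1)
      suppressWarnings(wilcox.test(x, y)$p.value)
    }, numeric(1))
    out$q <- p.adjust(out$p, method = "BH")
  }
  rownames(out) <- NULL
  out
}
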