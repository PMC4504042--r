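# Two-condition differential marking: gained/lost/stable classification,
# count-based differential binding, expression fold change, and the
# correlation between the two.

#' Classify per-feature mark changes between two conditions
#'
#' For each mark: gained = unmarked in A and marked in B; lost = marked in A
#' and unmarked in B. Percentages are reported against both conventions the
#' counts support: lost as a fraction of A-marked features, gained as a
#' fraction of A-unmarked features, with denominators emitted explicitly.
#'
#' @param marked_a,marked_b [marked_feature_table][annotate_features] objects
#'   (or logical matrices) over the same feature universe and marks.
#' @return List with `status` (features x marks character matrix with values
#'   gained/lost/stable-marked/stable-unmarked) and `venn` (per-mark
#'   data.frame of counts, denominators and percentages).
#' @export
classify_changes <- function(marked_a, marked_b) {
  ma <- if (inherits(marked_a, "marked_feature_table")) marked_a$marked else as.matrix(marked_a)
  mb <- if (inherits(marked_b, "marked_feature_table")) marked_b$marked else as.matrix(marked_b)
  if (!identical(dim(ma), dim(mb)) ||
      !identical(rownames(ma), rownames(mb)) ||
      !identical(colnames(ma), colnames(mb))) {
    stop("feature universes or marks differ between conditions")
  }
  status <- matrix(ifelse(ma & mb, "stable-marked",
                   ifelse(ma & !mb, "lost",
                   ifelse(!ma & mb, "gained", "stable-unmarked"))),
                   nrow = nrow(ma), dimnames = dimnames(ma))
  venn <- do.call(rbind, lapply(colnames(ma), function(m) {
    a <- ma[, m]; b <- mb[, m]
    n_marked_a <- sum(a); n_unmarked_a <- sum(!a)
    lost <- sum(a & !b); gained <- sum(!a & b)
    data.frame(mark = m,
               marked_a = n_marked_a, marked_b = sum(b),
               stable_marked = sum(a & b), lost = lost, gained = gained,
               stable_unmarked = sum(!a & !b),
               pct_lost_of_marked_a = if (n_marked_a) 100 * lost / n_marked_a else NA_real_,
               pct_gained_of_unmarked_a = if (n_unmarked_a) 100 * gained / n_unmarked_a else NA_real_)
  }))
  rownames(venn) <- NULL
  list(status = status, venn = venn)
}

#' Differential ChIP binding over peak regions
#'
#' For each region, with `a`/`b` the tag counts in conditions A/B and
#' `T_A`/`T_B` the library sizes: log2 fold change =
#' log2(((b + 1) / T_B) / ((a + 1) / T_A)); the p-value is a two-sided
#' binomial test of `b` successes in `a + b` trials at success probability
#' `T_B / (T_A + T_B)`; q-values are Benjamini-Hochberg over the tested
#' regions.
#'
#' @param regions [GenomicRanges::GRanges] of peak regions.
#' @param tags_a,tags_b [tag_set] libraries for the two conditions (both
#'   non-empty).
#' @return data.frame with columns `chrom`, `start`, `end`, `count_a`,
#'   `count_b`, `log2fc`, `p`, `q`.
#' @export
differential_binding <- function(regions, tags_a, tags_b) {
  if (tags_a$library_size == 0 || tags_b$library_size == 0) {
    stop("empty tag library")
  }
  count_in <- function(tags) {
    vapply(seq_along(regions), function(i) {
      ch <- as.character(GenomeInfoDb::seqnames(regions)[i])
      pos <- tags$pos[[ch]]
      if (is.null(pos)) return(0L)
      s <- GenomicRanges::start(regions)[i]
      e <- GenomicRanges::end(regions)[i]
      findInterval(e, pos) - findInterval(s - 1L, pos)
    }, integer(1))
  }
  a <- count_in(tags_a)
  b <- count_in(tags_b)
  TA <- tags_a$library_size
  TB <- tags_b$library_size
  log2fc <- log2(((b + 1) / TB) / ((a + 1) / TA))
  pr <- TB / (TA + TB)
  p <- vapply(seq_along(a), function(i) {
    if (a[i] + b[i] == 0) return(1)
    binom.test(b[i], a[i] + b[i], p = pr)$p.value
  }, numeric(1))
  data.frame(chrom = as.character(GenomeInfoDb::seqnames(regions)),
             start = GenomicRanges::start(regions),
             end = GenomicRanges::end(regions),
             count_a = a, count_b = b, log2fc = log2fc,
             p = p, q = p.adjust(p, method = "BH"))
}

#' Expression log2 fold change between conditions
#'
#' log2((fpkm_b + pseudo) / (fpkm_a + pseudo)), matched by gene name when
#' names are present.
#'
#' @param fpkm_a,fpkm_b Non-negative per-gene FPKM vectors over a shared gene
#'   universe.
#' @param pseudo Pseudocount (default 1).
#' @return Named numeric log2 fold-change vector.
#' @export
expression_fold_change <- function(fpkm_a, fpkm_b, pseudo = 1) {
  if (!is.null(names(fpkm_a)) && !is.null(names(fpkm_b))) {
    if (!setequal(names(fpkm_a), names(fpkm_b))) stop("gene universes differ")
    fpkm_b <- fpkm_b[names(fpkm_a)]
  } else if (length(fpkm_a) != length(fpkm_b)) {
    stop("gene universes differ")
  }
  if (any(fpkm_a < 0) || any(fpkm_b < 0)) stop("negative FPKM values")
  log2((fpkm_b + pseudo) / (fpkm_a + pseudo))
}

#' Correlate differential binding with differential expression
#'
#' Sample Pearson correlation between binding and expression log2 fold
#' changes over differentially marked features, plus the least-squares trend
#' line.
#'
#' @param binding_lfc,expr_lfc Numeric vectors of matched log2 fold changes
#'   (non-finite pairs are dropped; at least 3 finite pairs required).
#' @return List with `r` (NA when either variable has zero variance), `n`,
#'   `slope`, `intercept`.
#' @export
correlate_diff <- function(binding_lfc, expr_lfc) {
  stopifnot(length(binding_lfc) == length(expr_lfc))
  ok <- is.finite(binding_lfc) & is.finite(expr_lfc)
  x <- binding_lfc[ok]; y <- expr_lfc[ok]
  if (length(x) < 3) stop("need at least 3 finite fold-change pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, n = length(x),
                slope = NA_real_, intercept = NA_real_))
  }
  fit <- coef(lm(y ~ x))
  list(r = stats::cor(x, y), n = length(x),
       slope = unname(fit[2]), intercept = unname(fit[1]))
}
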