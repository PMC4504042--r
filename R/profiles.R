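# Metagene profiles over length-normalized genes with fixed flanks,
# expression-quantile stratification, and dinucleotide preference inside vs
# outside nucleosomal intervals.

# Turn a track into per-chromosome per-bp density vectors.
# tag_set -> tags per bp per 1e6 library tags; numeric list / RleList -> as-is.
.track_coverage <- function(track, genome) {
  chroms <- names(genome$seqlengths)
  if (inherits(track, "tag_set")) {
    if (track$library_size == 0) stop("empty tag library")
    scale <- track$library_size / 1e6
    out <- lapply(chroms, function(ch) {
      tabulate(track$pos[[ch]], nbins = genome$seqlengths[[ch]]) / scale
    })
  } else if (methods::is(track, "RleList")) {
    out <- lapply(chroms, function(ch) as.numeric(track[[ch]]))
  } else if (is.list(track)) {
    if (!all(chroms %in% names(track))) stop("track missing chromosomes")
    out <- lapply(chroms, function(ch) as.numeric(track[[ch]]))
  } else {
    stop("track must be a tag_set, RleList, or named list of numeric vectors")
  }
  names(out) <- chroms
  bad <- vapply(chroms, function(ch) {
    length(out[[ch]]) != genome$seqlengths[[ch]]
  }, logical(1))
  if (any(bad)) stop("track length does not match chromosome length")
  out
}

# 60-bin (default) vector for one gene; NA where flank runs off the chromosome
.gene_profile <- function(cov, start, end, strand, flank, n_body, n_flank) {
  fw <- flank / n_flank
  len <- length(cov)
  bin_mean <- function(pos, bin, nbins) {
    ok <- pos >= 1 & pos <= len
    out <- rep(NA_real_, nbins)
    if (any(ok)) {
      m <- tapply(cov[pos[ok]], factor(bin[ok], levels = seq_len(nbins)), mean)
      out[!is.na(m)] <- m[!is.na(m)]
    }
    out
  }
  up_pos <- (start - flank):(start - 1)
  up <- bin_mean(up_pos, rep(seq_len(n_flank), each = fw), n_flank)
  L <- end - start + 1
  body_pos <- start:end
  body_bin <- pmin(floor(((seq_len(L) - 0.5) / L) * n_body) + 1, n_body)
  body <- bin_mean(body_pos, body_bin, n_body)
  down_pos <- (end + 1):(end + flank)
  down <- bin_mean(down_pos, rep(seq_len(n_flank), each = fw), n_flank)
  v <- c(up, body, down)
  if (strand == "-") rev(v) else v
}

#' Metagene enrichment profile over length-normalized genes
#'
#' Each gene body is rescaled to `n_body_bins` bins (a bp contributes to the
#' bin containing its rescaled midpoint); flanks are binned at fixed width
#' `flank / n_flank_bins`. Minus-strand genes are reversed so bin 1 is always
#' the 5' end. Tag tracks are expressed as tags per bp per million library
#' tags; coverage tracks are used as given. Flank bins falling outside the
#' chromosome are ignored for that gene.
#'
#' @param track A [tag_set], `RleList`, or named list of per-chromosome
#'   numeric per-bp vectors.
#' @param genes [GenomicRanges::GRanges] of gene spans (strand-aware). Genes
#'   shorter than `n_body_bins` bp are skipped with a warning.
#' @param genome A [cs_genome].
#' @param flank Flank length in bp; must be a multiple of `n_flank_bins`.
#' @param n_body_bins,n_flank_bins Bin counts for body and each flank.
#' @return Object of class `metagene_profile`: `density` (length
#'   `2 * n_flank_bins + n_body_bins`, mean over genes), `n_genes`,
#'   `n_skipped`, and the binning parameters.
#' @export
metagene_profile <- function(track, genes, genome, flank = 500,
                             n_body_bins = 40, n_flank_bins = 10) {
  stopifnot(flank > 0, n_body_bins > 0, n_flank_bins > 0)
  if (flank %% n_flank_bins != 0) stop("flank must be a multiple of n_flank_bins")
  cov <- .track_coverage(track, genome)
  short <- GenomicRanges::width(genes) < n_body_bins
  if (any(short)) {
    warning(sprintf("%d gene(s) shorter than n_body_bins bp skipped", sum(short)))
    genes <- genes[!short]
  }
  if (!length(genes)) stop("no usable genes for metagene profile")
  nb <- 2 * n_flank_bins + n_body_bins
  mat <- t(vapply(seq_along(genes), function(i) {
    ch <- as.character(GenomeInfoDb::seqnames(genes)[i])
    .gene_profile(cov[[ch]], GenomicRanges::start(genes)[i],
                  GenomicRanges::end(genes)[i],
                  as.character(GenomicRanges::strand(genes)[i]),
                  flank, n_body_bins, n_flank_bins)
  }, numeric(nb)))
  structure(list(density = colMeans(mat, na.rm = TRUE),
                 flank = flank, n_body_bins = n_body_bins,
                 n_flank_bins = n_flank_bins,
                 n_genes = length(genes), n_skipped = sum(short)),
            class = "metagene_profile")
}

#' @export
print.metagene_profile <- function(x, ...) {
  cat(sprintf("<metagene_profile> %d bins (%d flank / %d body / %d flank), %d genes\n",
              length(x$density), x$n_flank_bins, x$n_body_bins,
              x$n_flank_bins, x$n_genes))
  invisible(x)
}

#' Split genes into expression quantile groups
#'
#' Genes are ranked by expression (ties broken by gene ID so the split is
#' stable) and divided into `k` groups of as-equal-as-possible size, `Q1`
#' lowest to `Qk` highest.
#'
#' @param expr Named numeric vector of per-gene expression.
#' @param k Number of groups (>= 2; fewer genes than `k` is an error).
#' @return A named factor with levels `Q1`..`Qk`, in the input gene order.
#' @export
expression_quantiles <- function(expr, k) {
  stopifnot(k >= 2)
  if (length(expr) < k) stop("fewer genes than quantile groups")
  if (is.null(names(expr))) names(expr) <- as.character(seq_along(expr))
  ord <- order(expr, names(expr), method = "radix")
  n <- length(expr)
  grp <- integer(n)
  grp[ord] <- ceiling(seq_len(n) * k / n)
  factor(setNames(paste0("Q", grp), names(expr)),
         levels = paste0("Q", seq_len(k)))
}

#' Metagene profiles stratified by expression quantile
#'
#' @inheritParams metagene_profile
#' @param expr Named numeric expression vector covering `names(genes)`.
#' @param k Number of quantile groups; `k = 1` profiles all genes together.
#' @return List with `profiles` (one [metagene_profile] per group, lowest
#'   first) and `quantiles` (the gene-to-group factor).
#' @export
occupancy_by_quantile <- function(track, genes, genome, expr, k = 5,
                                  flank = 500, n_body_bins = 40,
                                  n_flank_bins = 10) {
  if (is.null(names(genes))) stop("genes must be named")
  expr <- expr[names(genes)]
  if (anyNA(expr)) stop("expression missing for some genes")
  if (k == 1) {
    q <- factor(setNames(rep("Q1", length(genes)), names(genes)), levels = "Q1")
  } else {
    q <- expression_quantiles(expr, k)
  }
  profiles <- lapply(levels(q), function(lv) {
    metagene_profile(track, genes[names(q)[q == lv]], genome,
                     flank, n_body_bins, n_flank_bins)
  })
  names(profiles) <- levels(q)
  list(profiles = profiles, quantiles = q)
}

# DNAStringSet of interval sequences
.extract_seqs <- function(genome, gr) {
  if (is.null(genome$sequence)) stop("genome has no sequence attached")
  gr <- .validate_gr(GenomicRanges::granges(gr), genome, "interval")
  seqs <- lapply(seq_along(gr), function(i) {
    ch <- as.character(GenomeInfoDb::seqnames(gr)[i])
    Biostrings::subseq(genome$sequence[[ch]],
                       GenomicRanges::start(gr)[i], GenomicRanges::end(gr)[i])
  })
  do.call(c, lapply(seqs, Biostrings::DNAStringSet))
}

#' Dinucleotide frequency inside vs outside nucleosomal intervals
#'
#' Occurrences are counted with a sliding window of step 1 within each
#' interval (dinucleotides spanning interval junctions are not counted);
#' the denominator is the number of unambiguous dinucleotide positions, so
#' windows containing N are skipped.
#'
#' @param genome A [cs_genome] with sequence attached.
#' @param inside,outside [GenomicRanges::GRanges] of nucleosomal /
#'   nucleosome-depleted intervals.
#' @param dinucs Dinucleotides to report (over A/C/G/T).
#' @return A data.frame with columns `dinucleotide`, `inside`, `outside`
#'   (frequencies in \[0, 1\]).
#' @export
dinucleotide_preference <- function(genome, inside, outside,
                                    dinucs = c("AT", "TA", "TT", "GC", "CG")) {
  dinucs <- toupper(dinucs)
  if (any(!grepl("^[ACGT]{2}$", dinucs))) {
    stop("dinucs must be 2-letter strings over A/C/G/T")
  }
  freq_of <- function(gr) {
    counts <- colSums(Biostrings::oligonucleotideFrequency(
      .extract_seqs(genome, gr), width = 2))
    total <- sum(counts)
    if (total == 0) return(setNames(rep(0, length(dinucs)), dinucs))
    counts[dinucs] / total
  }
  data.frame(dinucleotide = dinucs,
             inside = as.numeric(freq_of(inside)),
             outside = as.numeric(freq_of(outside)))
}
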