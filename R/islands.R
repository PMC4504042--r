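# SICER-style broad-domain island calling: tag counts in fixed W-bp windows,
# Poisson eligibility against the genome-wide background, gap-tolerant
# assembly of eligible windows into islands, and island-level significance
# against a control library with Benjamini-Hochberg FDR control.

#' Island-calling parameters
#'
#' @param w Window length in bp.
#' @param g Gap size in bp; must be a non-negative multiple of `w`. Eligible
#'   window runs separated by at most `g` bp of ineligible windows are merged.
#' @param fdr Island-level q-value threshold.
#' @param p_window Per-window Poisson eligibility p-value threshold.
#' @param effective_genome_fraction Fraction of the genome tags can map to,
#'   in (0, 1]; scales the background window mean.
#' @return A list of class `island_params`.
#' @examples
#' island_params(w = 200, g = 600, fdr = 1e-2)   # broad marks
#' island_params(w = 200, g = 200, fdr = 1e-2)   # punctate marks
#' @export
island_params <- function(w = 200, g = 600, fdr = 0.01, p_window = 0.2,
                          effective_genome_fraction = 1) {
  stopifnot(w > 0, g >= 0, fdr > 0, fdr <= 1,
            p_window > 0, p_window < 1,
            effective_genome_fraction > 0, effective_genome_fraction <= 1)
  if (g %% w != 0) stop("g must be a multiple of w")
  structure(list(w = as.integer(w), g = as.integer(g), fdr = fdr,
                 p_window = p_window,
                 effective_genome_fraction = effective_genome_fraction),
            class = "island_params")
}

#' Poisson upper-tail probability P(X >= k)
#'
#' Computed via the survival function so it is stable for large `k`.
#'
#' @param k Non-negative integer count (vectorized).
#' @param lambda Poisson mean, > 0 (vectorized).
#' @return P(X >= k) under Poisson(`lambda`); 1 when `k` = 0.
#' @export
poisson_upper_tail <- function(k, lambda) {
  if (any(lambda <= 0)) stop("lambda must be > 0")
  if (any(k < 0)) stop("k must be >= 0")
  ppois(k - 1, lambda, lower.tail = FALSE)
}

# number of W-bp windows per chromosome: tags past the last full window are
# assigned to the final window, so nwin = floor(len / w), at least 1.
.n_windows <- function(seqlengths, w) {
  setNames(pmax(1L, as.integer(floor(seqlengths / w))), names(seqlengths))
}

#' Count tags in consecutive fixed-width windows
#'
#' Window `i` covers `[(i-1)*w + 1, i*w]` (1-based); the final window absorbs
#' any trailing partial window so every tag is counted exactly once.
#'
#' @param tags A [tag_set].
#' @param genome A [cs_genome].
#' @param w Window length in bp.
#' @param effective_genome_fraction See [island_params()].
#' @return A list of class `window_counts`: per-chromosome integer count
#'   vectors, `w`, `library_size`, and the background mean `lambda_bg` =
#'   library_size * w / (genome length * effective_genome_fraction).
#' @export
count_windows <- function(tags, genome, w = 200, effective_genome_fraction = 1) {
  stopifnot(w > 0)
  nwin <- .n_windows(genome$seqlengths, w)
  counts <- lapply(seq_along(nwin), function(i) {
    ch <- names(genome$seqlengths)[i]
    pos <- tags$pos[[ch]]
    if (is.null(pos) || !length(pos)) return(integer(nwin[i]))
    tabulate(pmin(ceiling(pos / w), nwin[i]), nbins = nwin[i])
  })
  names(counts) <- names(genome$seqlengths)
  lambda_bg <- tags$library_size * w /
    (sum(genome$seqlengths) * effective_genome_fraction)
  structure(list(counts = counts, w = as.integer(w),
                 library_size = tags$library_size, lambda_bg = lambda_bg,
                 seqlengths = genome$seqlengths),
            class = "window_counts")
}

#' Flag windows eligible for island membership
#'
#' A window is eligible iff its Poisson upper-tail p-value against the
#' background mean is at most `p_window`.
#'
#' @param counts A [window_counts][count_windows] object.
#' @param p_window Eligibility threshold.
#' @return Per-chromosome logical vectors.
#' @export
eligible_windows <- function(counts, p_window = 0.2) {
  if (counts$library_size == 0 || counts$lambda_bg <= 0) {
    return(lapply(counts$counts, function(x) rep(FALSE, length(x))))
  }
  lapply(counts$counts, function(x) {
    poisson_upper_tail(x, counts$lambda_bg) <= p_window
  })
}

#' Assemble eligible windows into gap-tolerant island candidates
#'
#' Maximal runs of eligible windows are merged when separated by at most `g`
#' bp of ineligible windows; merged spans include the intervening gap.
#'
#' @param mask Per-chromosome logical eligibility vectors (as from
#'   [eligible_windows()]).
#' @param w Window length in bp.
#' @param g Gap size in bp (multiple of `w`).
#' @param genome A [cs_genome].
#' @return A sorted [GenomicRanges::GRanges] of candidate island spans.
#' @export
assemble_islands <- function(mask, w, g, genome) {
  if (g %% w != 0) stop("g must be a multiple of w")
  max_gap_windows <- g %/% w
  nwin <- .n_windows(genome$seqlengths, w)
  pieces <- lapply(seq_along(mask), function(i) {
    idx <- which(mask[[i]])
    if (!length(idx)) return(NULL)
    run <- cumsum(c(TRUE, diff(idx) - 1L > max_gap_windows))
    first <- tapply(idx, run, min)
    last <- tapply(idx, run, max)
    len <- genome$seqlengths[[names(mask)[i]]]
    data.frame(chrom = names(mask)[i],
               start = (first - 1) * w + 1,
               end = ifelse(last == nwin[i], len, last * w))
  })
  df <- do.call(rbind, pieces)
  if (is.null(df)) return(.empty_gr(genome))
  gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end),
                               seqinfo = .genome_seqinfo(genome))
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

# smallest count k with P(X >= k | lambda) <= p_window
.eligibility_threshold <- function(lambda, p_window) {
  stats::qpois(1 - p_window, lambda) + 1L
}

# Upper-tail P(T >= t) for T = sum of n_e Poisson(lam) counts truncated to
# >= kstar plus n_g Poisson(lam) counts truncated to < kstar. This is the
# exact null of an island's tag total given its eligibility mask: counts are
# independent across windows and eligibility is a per-window function of the
# count, so conditioning on the mask truncates each member window's Poisson.
.truncated_poisson_tail <- function(t, lam, n_e, n_g, kstar) {
  hi <- max(kstar + 1, stats::qpois(1e-14, lam, lower.tail = FALSE)) + 2L
  supp <- 0:hi
  base <- stats::dpois(supp, lam)
  pmf_e <- base * (supp >= kstar)
  pmf_g <- base * (supp < kstar)
  se <- sum(pmf_e); sg <- sum(pmf_g)
  if (se > 0) pmf_e <- pmf_e / se
  if (sg > 0) pmf_g <- pmf_g / sg
  # cheap screen: islands far inside the bulk of the null cannot approach any
  # BH threshold; a normal approximation of the truncated sum suffices there
  m1e <- sum(supp * pmf_e); v1e <- sum(supp^2 * pmf_e) - m1e^2
  m1g <- sum(supp * pmf_g); v1g <- sum(supp^2 * pmf_g) - m1g^2
  mu <- n_e * m1e + n_g * m1g
  sd_t <- sqrt(max(n_e * v1e + n_g * v1g, 1e-12))
  z <- (t - 0.5 - mu) / sd_t
  if (z < 2) return(max(stats::pnorm(z, lower.tail = FALSE), 0.023))
  out <- 1
  for (i in seq_len(n_e)) out <- stats::convolve(out, rev(pmf_e), type = "open")
  for (i in seq_len(n_g)) out <- stats::convolve(out, rev(pmf_g), type = "open")
  out[out < 0] <- 0  # FFT round-off
  # support of out is 0..(length(out) - 1)
  if (t <= 0) return(1)
  if (t > length(out) - 1) return(0)
  min(1, sum(out[(t + 1):length(out)]))
}

# sum a per-window statistic over each island's member windows, per chromosome
.island_window_sums <- function(islands, wc, fun = identity) {
  w <- wc$w
  vapply(seq_along(islands), function(i) {
    ch <- as.character(GenomeInfoDb::seqnames(islands)[i])
    x <- wc$counts[[ch]]
    from <- (GenomicRanges::start(islands)[i] - 1) %/% w + 1
    to <- min(ceiling(GenomicRanges::end(islands)[i] / w), length(x))
    sum(fun(x[from:to]))
  }, numeric(1))
}

#' Score island candidates against a control library
#'
#' Per island: `score` is the sum over eligible member windows of
#' -ln P(X >= count | lambda_bg); `fold` is the library-size-normalized
#' treatment/control ratio with pseudocount 1 on both counts. The island
#' p-value tests the treatment tag total against a Poisson null with
#' control-scaled per-window mean (c + 1) * T / C / n (pseudocount 1 on the
#' control count), floored at the global background rate `lambda_bg` so a
#' downward-fluctuating control cannot manufacture enrichment, and
#' adjusted for window-eligibility selection: because island
#' member windows were selected by their own counts, the null of the total is
#' the sum of truncated Poissons (eligible windows conditioned at or above
#' the eligibility threshold, gap windows below it), which keeps null islands
#' calibrated. `q` is Benjamini-Hochberg adjusted over all islands. With no
#' usable control the background mean `lambda_bg` replaces the control-scaled
#' mean and the result carries `attr(, "control") == "background-only"`.
#'
#' @param islands Candidate spans from [assemble_islands()].
#' @param treatment,control [window_counts][count_windows] objects computed
#'   with identical `w` over the same genome (`control` may be NULL).
#' @param p_window Eligibility threshold used for the score term.
#' @return `islands` with metadata columns `treatment_count`,
#'   `control_count`, `score`, `fold`, `p`, `q`.
#' @export
score_islands <- function(islands, treatment, control = NULL, p_window = 0.2) {
  if (!length(islands)) return(.decorate_islands(islands))
  lam <- treatment$lambda_bg
  t_cnt <- .island_window_sums(islands, treatment)
  score <- .island_window_sums(islands, treatment, fun = function(x) {
    p <- poisson_upper_tail(x, lam)
    ifelse(p <= p_window, -log(p), 0)
  })
  kstar <- .eligibility_threshold(lam, p_window)
  n_elig <- .island_window_sums(islands, treatment, fun = function(x) x >= kstar)
  w <- treatment$w
  n_member <- pmin(ceiling(GenomicRanges::end(islands) / w),
                   .n_windows(treatment$seqlengths, w)[
                     as.character(GenomeInfoDb::seqnames(islands))]) -
    (GenomicRanges::start(islands) - 1) %/% w
  no_control <- is.null(control) || control$library_size == 0
  if (no_control) {
    c_cnt <- rep(NA_real_, length(islands))
    fold <- rep(NA_real_, length(islands))
    lam_w <- rep(lam, length(islands))
  } else {
    if (control$w != treatment$w) stop("treatment and control window sizes differ")
    c_cnt <- .island_window_sums(islands, control)
    TT <- treatment$library_size
    CC <- control$library_size
    fold <- ((t_cnt + 1) / TT) / ((c_cnt + 1) / CC)
    # the control-scaled per-window mean is floored at the global background
    # rate: a downward fluctuation of the control count must not manufacture
    # enrichment (the same guard as the lambda_local floor in MACS)
    lam_w <- pmax(lam, ((c_cnt + 1) * TT / CC) / n_member)
  }
  p <- vapply(seq_along(islands), function(i) {
    .truncated_poisson_tail(t_cnt[i], lam_w[i], n_elig[i],
                            n_member[i] - n_elig[i], kstar)
  }, numeric(1))
  mcols(islands)$treatment_count <- t_cnt
  mcols(islands)$control_count <- c_cnt
  mcols(islands)$score <- score
  mcols(islands)$fold <- fold
  mcols(islands)$p <- p
  mcols(islands)$q <- p.adjust(p, method = "BH")
  if (no_control) attr(islands, "control") <- "background-only"
  islands
}

.decorate_islands <- function(gr) {
  for (col in c("treatment_count", "control_count", "score", "fold", "p", "q")) {
    mcols(gr)[[col]] <- numeric(0)
  }
  gr
}

#' Call enriched islands from treatment and control tag libraries
#'
#' End-to-end composition: window counting, Poisson eligibility, gap-tolerant
#' assembly, control-based scoring, and FDR filtering at `params$fdr`.
#'
#' @param tags Treatment [tag_set].
#' @param control Control [tag_set] (or NULL for background-only testing).
#' @param genome A [cs_genome].
#' @param params An [island_params()] configuration.
#' @return Sorted, disjoint [GenomicRanges::GRanges] of islands with
#'   `q <= params$fdr`, carrying the columns described in [score_islands()].
#' @export
call_islands <- function(tags, control, genome, params = island_params()) {
  wc_t <- count_windows(tags, genome, params$w, params$effective_genome_fraction)
  mask <- eligible_windows(wc_t, params$p_window)
  cands <- assemble_islands(mask, params$w, params$g, genome)
  if (!length(cands)) return(.decorate_islands(cands))
  wc_c <- if (is.null(control)) NULL else {
    count_windows(control, genome, params$w, params$effective_genome_fraction)
  }
  scored <- score_islands(cands, wc_t, wc_c, params$p_window)
  out <- scored[mcols(scored)$q <= params$fdr]
  GenomicRanges::sort(out, ignore.strand = TRUE)
}
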