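# Seeded synthetic-data generators: genome + annotation, planted enriched
# islands, chromatin states with mark islands per gene/TE, tag libraries,
# expression and bisulfite counts, and paired two-condition datasets. Every
# generator takes an explicit seed (derived from config$seed by fixed
# offsets) so components can be regenerated independently and full datasets
# are byte-identical under a fixed seed.

#' Simulation configuration
#'
#' Defaults describe a compact, densely annotated 2 Mb genome: 300 genes and
#' 60 TEs with ~1.5 kb intergenic spacers, lognormal gene lengths (median
#' ~1.5 kb), 50% GC with GC-elevated nucleosomal intervals, 200k-tag ChIP
#' libraries at 8-fold island enrichment, state-coupled lognormal expression
#' (CS1 high, CS3 intermediate, CS2 low), and ~17x bisulfite depth.
#'
#' @param seed Master seed; per-component seeds are derived by fixed offsets.
#' @param n_chrom,chrom_length Number and length (bp) of chromosomes.
#' @param n_genes,n_tes Feature counts.
#' @param gene_meanlog,gene_sdlog,gene_min Gene-length lognormal parameters
#'   and floor (bp).
#' @param te_meanlog,te_sdlog,te_min TE-length lognormal parameters and floor.
#' @param intergenic_mean Mean inter-feature spacer (bp; gamma, shape 4).
#' @param gc,nucleosome_gc Background and nucleosomal-interval GC content.
#' @param n_nucleosomes,nucleosome_width Designated nucleosomal intervals.
#' @param library_size ChIP tags per library.
#' @param fold Island enrichment fold.
#' @param state_probs Probabilities of CS1/CS2/CS3/unmarked per gene.
#' @param expr_meanlog Named meanlog per state (CS1/CS2/CS3/unmarked).
#' @param expr_sdlog Lognormal sdlog for expression.
#' @param rna_library RNA-seq mapped fragments.
#' @param meth_depth Mean bisulfite read depth per site.
#' @param meth_sites_per_feature Mean cytosine sites per feature.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_chrom = 2, chrom_length = 1e6,
                       n_genes = 300, n_tes = 60,
                       gene_meanlog = log(1500), gene_sdlog = 0.45,
                       gene_min = 400,
                       te_meanlog = log(800), te_sdlog = 0.4, te_min = 200,
                       intergenic_mean = 1500,
                       gc = 0.5, nucleosome_gc = 0.68,
                       n_nucleosomes = 200, nucleosome_width = 147,
                       library_size = 2e5, fold = 8,
                       state_probs = c(CS1 = 0.35, CS2 = 0.20,
                                       CS3 = 0.15, unmarked = 0.30),
                       expr_meanlog = c(CS1 = 3, CS2 = 0,
                                        CS3 = 1.5, unmarked = 1.5),
                       expr_sdlog = 0.7,
                       rna_library = 5e5,
                       meth_depth = 17, meth_sites_per_feature = 6) {
  stopifnot(n_chrom >= 1, chrom_length > 0, fold >= 1,
            abs(sum(state_probs) - 1) < 1e-9)
  structure(as.list(environment()), class = "sim_config")
}

# fixed per-component seed offsets (keep well below 2^31)
.sub_seed <- function(config, offset) (config$seed %% 1000000L) * 1000L + offset

#' Simulate a genome with gene/TE annotation and sequence
#'
#' Genes and TEs are interleaved along each chromosome, separated by
#' gamma-distributed spacers with the configured mean; leftover space remains
#' as a trailing unannotated (intergenic) arm. Sequence is random at the
#' configured GC, with elevated GC inside designated nucleosomal intervals.
#'
#' @param config A [sim_config()].
#' @param seed Seed (default derived from `config$seed`).
#' @return List with `genome` (a [cs_genome] with sequence), `catalog`
#'   (a [feature_catalog]), and `nucleosomes` (GRanges of GC-elevated
#'   intervals).
#' @export
simulate_genome <- function(config = sim_config(),
                            seed = .sub_seed(config, 101L)) {
  set.seed(seed)
  n_feat <- config$n_genes + config$n_tes
  is_gene <- sample(rep(c(TRUE, FALSE), c(config$n_genes, config$n_tes)))
  len <- ifelse(is_gene,
                pmax(config$gene_min,
                     round(rlnorm(n_feat, config$gene_meanlog, config$gene_sdlog))),
                pmax(config$te_min,
                     round(rlnorm(n_feat, config$te_meanlog, config$te_sdlog))))
  gaps <- round(rgamma(n_feat, shape = 4, scale = config$intergenic_mean / 4))
  chrom_of <- sort(rep_len(seq_len(config$n_chrom), n_feat))
  chroms <- sprintf("chr%d", seq_len(config$n_chrom))
  starts <- integer(n_feat)
  for (ci in seq_len(config$n_chrom)) {
    idx <- which(chrom_of == ci)
    s <- cumsum(c(gaps[idx[1]] + 1,
                  head(len[idx], -1) + gaps[idx][-1]))
    if (length(idx) && (s[length(s)] + len[idx[length(idx)]] - 1 >
                        config$chrom_length)) {
      stop("features do not fit on chromosome; increase chrom_length")
    }
    starts[idx] <- s
  }
  strand <- sample(c("+", "-"), n_feat, replace = TRUE)
  seqlengths <- setNames(rep(config$chrom_length, config$n_chrom), chroms)
  gr <- GenomicRanges::GRanges(chroms[chrom_of],
                               IRanges::IRanges(starts, width = len),
                               strand = strand)
  names(gr) <- ifelse(is_gene,
                      sprintf("gene_%04d", cumsum(is_gene)),
                      sprintf("TE_%04d", cumsum(!is_gene)))
  # nucleosomal intervals (GC-elevated), then sequence
  nuc_start <- sort(sample(seq_len(config$chrom_length - config$nucleosome_width),
                           config$n_nucleosomes, replace = FALSE))
  nuc <- GenomicRanges::GRanges(
    sample(chroms, config$n_nucleosomes, replace = TRUE),
    IRanges::IRanges(nuc_start, width = config$nucleosome_width))
  base_p <- function(gc) c(A = (1 - gc) / 2, C = gc / 2,
                           G = gc / 2, T = (1 - gc) / 2)
  seqs <- Biostrings::DNAStringSet(vapply(chroms, function(ch) {
    x <- sample(names(base_p(config$gc)), config$chrom_length,
                replace = TRUE, prob = base_p(config$gc))
    sel <- nuc[GenomeInfoDb::seqnames(nuc) == ch]
    for (i in seq_along(sel)) {
      span <- GenomicRanges::start(sel)[i]:GenomicRanges::end(sel)[i]
      x[span] <- sample(names(base_p(config$nucleosome_gc)), length(span),
                        replace = TRUE, prob = base_p(config$nucleosome_gc))
    }
    paste(x, collapse = "")
  }, character(1)))
  genome <- cs_genome(seqlengths, sequence = seqs)
  catalog <- feature_catalog(genes = gr[is_gene], tes = gr[!is_gene],
                             genome = genome)
  nuc <- .validate_gr(nuc, genome, "nucleosome interval")
  list(genome = genome, catalog = catalog, nucleosomes = nuc)
}

#' Plant enriched islands with a minimum separation
#'
#' Islands are placed uniformly per chromosome subject to a minimum
#' inter-island gap, so planted domains remain resolvable as distinct
#' islands under gap-tolerant assembly.
#'
#' @param genome A [cs_genome].
#' @param n Number of islands.
#' @param min_len,max_len Island length range in bp.
#' @param min_gap Minimum separation between islands (bp).
#' @param seed Seed.
#' @return Sorted [GenomicRanges::GRanges] of planted islands.
#' @export
plant_islands <- function(genome, n = 60, min_len = 600, max_len = 3000,
                          min_gap = 1000, seed = 1) {
  set.seed(seed)
  lens <- round(runif(n, min_len, max_len))
  share <- genome$seqlengths / sum(genome$seqlengths)
  n_per <- diff(round(c(0, cumsum(share * n))))
  pieces <- list()
  off <- 0L
  for (i in seq_along(n_per)) {
    k <- n_per[i]
    if (k == 0) next
    li <- lens[off + seq_len(k)]
    slack <- genome$seqlengths[i] - sum(li) - (k + 1) * min_gap
    if (slack < 0) stop("islands do not fit with the requested separation")
    cuts <- sort(runif(k, 0, slack))
    starts <- round(cuts + min_gap * seq_len(k) + cumsum(c(0, head(li, -1))) + 1)
    pieces[[i]] <- GenomicRanges::GRanges(names(genome$seqlengths)[i],
                                          IRanges::IRanges(starts, width = li),
                                          seqlengths = genome$seqlengths)
    off <- off + k
  }
  gr <- .validate_gr(do.call(c, pieces), genome, "planted island")
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

# archetype spans for one gene, in 5'->3' orientation of the + strand:
# C1 downstream flank; C2 body+down; C3 body; C4 all; C5 upstream; C6 up+body
.archetype_span <- function(start, end, strand, arch, flank = 500) {
  up <- c(start - flank, start - 1)
  down <- c(end + 1, end + flank)
  if (strand == "-") { tmp <- up; up <- down; down <- tmp }
  body <- c(start, end)
  lim <- switch(arch,
                `1` = down,
                `2` = range(c(body, down)),
                `3` = body,
                `4` = range(c(up, body, down)),
                `5` = up,
                `6` = range(c(up, body)))
  lim
}

#' Simulate chromatin states and mark islands over a feature catalog
#'
#' Each gene draws a chromatin state (CS1/CS2/CS3/unmarked); marks are then
#' placed consistently with the state (activating marks for CS1, repressive
#' for CS2, both for CS3). Gene islands for most marks cover the gene body
#' with random flank extensions; H3K27me3 gene islands instead follow one of
#' six positional archetypes over the upstream flank, body and downstream
#' flank. TEs carry predominantly repressive marks.
#'
#' @param catalog A [feature_catalog].
#' @param config A [sim_config()].
#' @param seed Seed.
#' @return List of class `chromatin_truth`: `states` (named factor per gene),
#'   `marks` (gene x mark logical matrix), `te_marks` (TE x mark logical
#'   matrix), `archetype` (named integer, NA when H3K27me3 absent), and
#'   `islands` (named list of GRanges per mark, each with a `feature_id`
#'   metadata column).
#' @export
simulate_chromatin <- function(catalog, config = sim_config(),
                               seed = .sub_seed(config, 202L)) {
  set.seed(seed)
  genes <- catalog$genes
  tes <- catalog$tes
  marks <- c(ACTIVE_MARKS, REPRESSIVE_MARKS)
  states <- factor(sample(names(config$state_probs), length(genes),
                          replace = TRUE, prob = config$state_probs),
                   levels = c("CS1", "CS2", "CS3", "unmarked"))
  names(states) <- names(genes)
  draw_active <- function(n) {
    m <- cbind(H3K4me2 = runif(n) < 0.85, H3K9_14Ac = runif(n) < 0.70)
    m[rowSums(m) == 0, 1] <- TRUE
    m
  }
  draw_repressive <- function(n) {
    m <- cbind(H3K9me2 = runif(n) < 0.35, H3K9me3 = runif(n) < 0.45,
               H3K27me3 = runif(n) < 0.70)
    m[rowSums(m) == 0, 3] <- TRUE
    m
  }
  gm <- matrix(FALSE, length(genes), length(marks),
               dimnames = list(names(genes), marks))
  has_a <- states %in% c("CS1", "CS3")
  has_r <- states %in% c("CS2", "CS3")
  if (any(has_a)) gm[has_a, ACTIVE_MARKS] <- draw_active(sum(has_a))
  if (any(has_r)) gm[has_r, REPRESSIVE_MARKS] <- draw_repressive(sum(has_r))
  te_p <- c(H3K4me2 = 0.05, H3K9_14Ac = 0.05, H3K9me2 = 0.50,
            H3K9me3 = 0.55, H3K27me3 = 0.45)
  tm <- vapply(marks, function(m) runif(length(tes)) < te_p[[m]],
               logical(length(tes)))
  tm <- matrix(tm, nrow = length(tes), dimnames = list(names(tes), marks))
  archetype <- setNames(rep(NA_integer_, length(genes)), names(genes))
  k27 <- which(gm[, "H3K27me3"])
  archetype[k27] <- sample(1:6, length(k27), replace = TRUE)
  lens <- catalog$genome$seqlengths
  mk_island <- function(ch, lim, id) {
    GenomicRanges::GRanges(ch, IRanges::IRanges(max(1, lim[1]),
                                                min(lens[[ch]], lim[2])),
                           feature_id = id, seqlengths = lens)
  }
  islands <- lapply(setNames(nm = marks), function(m) {
    out <- list()
    for (i in which(gm[, m])) {
      ch <- as.character(GenomeInfoDb::seqnames(genes)[i])
      s <- GenomicRanges::start(genes)[i]; e <- GenomicRanges::end(genes)[i]
      lim <- if (m == "H3K27me3") {
        .archetype_span(s, e, as.character(GenomicRanges::strand(genes)[i]),
                        as.character(archetype[i]))
      } else {
        c(s - round(runif(1, 100, 300)), e + round(runif(1, 100, 300)))
      }
      out[[length(out) + 1]] <- mk_island(ch, lim, names(genes)[i])
    }
    for (i in which(tm[, m])) {
      ch <- as.character(GenomeInfoDb::seqnames(tes)[i])
      lim <- c(GenomicRanges::start(tes)[i] - round(runif(1, 0, 150)),
               GenomicRanges::end(tes)[i] + round(runif(1, 0, 150)))
      out[[length(out) + 1]] <- mk_island(ch, lim, names(tes)[i])
    }
    if (!length(out)) return(.empty_gr(catalog$genome))
    gr <- do.call(c, out)
    GenomicRanges::sort(gr, ignore.strand = TRUE)
  })
  structure(list(states = states, marks = gm, te_marks = tm,
                 archetype = archetype, islands = islands),
            class = "chromatin_truth")
}

#' Simulate treatment and control ChIP tag libraries
#'
#' Tags follow an inhomogeneous Poisson process: rate `background` outside
#' islands and `background * fold` inside; the background rate is chosen so
#' the expected treatment library equals `library_size`. The control library
#' is background-only (uniform) at the same expected size.
#'
#' @param genome A [cs_genome].
#' @param islands [GenomicRanges::GRanges] of enriched regions (may be
#'   empty/NULL for a flat library).
#' @param fold Enrichment fold (>= 1).
#' @param library_size Expected tags per library.
#' @param seed Seed.
#' @param background_rate Optional explicit background rate (tags/bp);
#'   overrides the `library_size`-derived rate for the treatment.
#' @return List with `treatment` and `control` [tag_set]s.
#' @export
simulate_tags <- function(genome, islands = NULL, fold = 8,
                          library_size = 2e5, seed = 1,
                          background_rate = NULL) {
  stopifnot(fold >= 1, library_size >= 0)
  set.seed(seed)
  gl <- sum(genome$seqlengths)
  merged <- if (is.null(islands) || !length(islands)) .empty_gr(genome) else {
    GenomicRanges::reduce(GenomicRanges::granges(islands), ignore.strand = TRUE)
  }
  a_bp <- sum(GenomicRanges::width(merged))
  bg <- if (is.null(background_rate)) {
    library_size / (gl + (fold - 1) * a_bp)
  } else background_rate
  draw <- function(segments, rates) {
    counts <- rpois(length(segments), rates * GenomicRanges::width(segments))
    if (!sum(counts)) return(tag_set(character(), integer(), genome))
    idx <- rep(seq_along(segments), counts)
    pos <- GenomicRanges::start(segments)[idx] +
      floor(runif(sum(counts)) * GenomicRanges::width(segments)[idx])
    tag_set(as.character(GenomeInfoDb::seqnames(segments))[idx], pos, genome)
  }
  whole <- .whole_genome_gr(genome)
  if (library_size == 0) {
    empty <- tag_set(character(), integer(), genome)
    return(list(treatment = empty, control = empty))
  }
  bg_seg <- GenomicRanges::setdiff(whole, merged, ignore.strand = TRUE)
  segs <- c(bg_seg, merged)
  rates <- c(rep(bg, length(bg_seg)), rep(bg * fold, length(merged)))
  treatment <- draw(segs, rates)
  control <- draw(whole, rep(library_size / gl, length(whole)))
  list(treatment = treatment, control = control)
}

#' Simulate expression and bisulfite methylation coupled to chromatin state
#'
#' Per-gene true FPKM is lognormal with a state-specific meanlog (CS1 high,
#' CS3 intermediate, CS2 low); fragment counts are Poisson around the
#' expected coverage. Methylation preferentially targets repressively marked
#' genes and TEs: methylated features carry high beta-distributed per-site
#' methylation levels, others near-zero levels; per-site depth is Poisson.
#'
#' @param catalog A [feature_catalog].
#' @param truth A [chromatin_truth][simulate_chromatin].
#' @param config A [sim_config()].
#' @param seed Seed.
#' @return List with `expression` (data.frame gene_id, length, counts, fpkm),
#'   `methylation` (data.frame chrom, pos (0-based), strand, context,
#'   count_meth, count_total), and `methylated_truth` (feature IDs drawn
#'   methylated).
#' @export
simulate_expression_and_methylation <- function(catalog, truth,
                                                config = sim_config(),
                                                seed = .sub_seed(config, 303L)) {
  set.seed(seed)
  genes <- catalog$genes
  st <- as.character(truth$states[names(genes)])
  fpkm_true <- rlnorm(length(genes), config$expr_meanlog[st], config$expr_sdlog)
  len <- GenomicRanges::width(genes)
  counts <- rpois(length(genes),
                  fpkm_true * (len / 1000) * (config$rna_library / 1e6))
  expression <- data.frame(gene_id = names(genes), length = len,
                           counts = counts,
                           fpkm = compute_fpkm(counts, len,
                                               library = config$rna_library),
                           fpkm_true = fpkm_true)
  feats <- c(GenomicRanges::granges(genes), GenomicRanges::granges(catalog$tes))
  rep_gene <- rowSums(truth$marks[, REPRESSIVE_MARKS, drop = FALSE]) > 0
  p_meth <- c(ifelse(rep_gene, 0.6, 0.1), rep(0.7, length(catalog$tes)))
  is_meth <- runif(length(feats)) < p_meth
  rows <- lapply(seq_along(feats), function(i) {
    n_sites <- rpois(1, config$meth_sites_per_feature) + 1L
    w <- GenomicRanges::width(feats)[i]
    offs <- sort(sample.int(w, min(n_sites, w)))
    level <- if (is_meth[i]) rbeta(length(offs), 8, 2) else rbeta(length(offs), 0.5, 12)
    total <- rpois(length(offs), config$meth_depth)
    data.frame(chrom = as.character(GenomeInfoDb::seqnames(feats)[i]),
               pos = GenomicRanges::start(feats)[i] + offs - 2L,  # 0-based
               strand = sample(c("+", "-"), length(offs), replace = TRUE),
               context = sample(c("CpG", "CHG", "CHH"), length(offs),
                                replace = TRUE, prob = c(0.5, 0.25, 0.25)),
               count_meth = rbinom(length(offs), total, level),
               count_total = total)
  })
  list(expression = expression,
       methylation = do.call(rbind, rows),
       methylated_truth = names(feats)[is_meth])
}

#' Simulate a paired two-condition dataset with planted gains and losses
#'
#' Condition B differs from condition A only at the planted changes for one
#' mark: `n_gained` features acquire an island, `n_lost` marked features lose
#' theirs. Expression of affected genes shifts by `expr_log2fc` (gains) or
#' `-expr_log2fc` (losses); use a negative `expr_log2fc` for a repressive
#' mark.
#'
#' @param catalog A [feature_catalog].
#' @param truth A [chromatin_truth][simulate_chromatin].
#' @param mark Mark to perturb.
#' @param n_gained,n_lost Numbers of planted gains / losses (genes).
#' @param expr_log2fc Expression shift coupled to a gain (log2).
#' @param config A [sim_config()].
#' @param seed Seed.
#' @return List with `islands_a`, `islands_b`, `tags_a`, `tags_b` (each a
#'   treatment/control pair), `expression_a`, `expression_b`, and `planted`
#'   (gained / lost gene IDs).
#' @export
simulate_condition_pair <- function(catalog, truth, mark = "H3K9_14Ac",
                                    n_gained = 50, n_lost = 50,
                                    expr_log2fc = 2,
                                    config = sim_config(),
                                    seed = .sub_seed(config, 404L)) {
  set.seed(seed)
  genes <- catalog$genes
  marked <- names(genes)[truth$marks[, mark]]
  unmarked <- setdiff(names(genes), marked)
  if (n_gained > length(unmarked) || n_lost > length(marked)) {
    stop("not enough features for the requested gains/losses")
  }
  gained <- sample(unmarked, n_gained)
  lost <- sample(marked, n_lost)
  islands_a <- truth$islands[[mark]]
  keep <- is.na(mcols(islands_a)$feature_id) |
    !(mcols(islands_a)$feature_id %in% lost)
  new_isl <- genes[gained]
  new_gr <- GenomicRanges::granges(new_isl)
  mcols(new_gr)$feature_id <- gained
  islands_b <- GenomicRanges::sort(c(islands_a[keep], new_gr),
                                   ignore.strand = TRUE)
  # expression: condition A true FPKM per state; B shifted at planted changes
  st <- as.character(truth$states[names(genes)])
  fpkm_a <- rlnorm(length(genes), config$expr_meanlog[st], config$expr_sdlog)
  names(fpkm_a) <- names(genes)
  fpkm_b <- fpkm_a
  fpkm_b[gained] <- fpkm_a[gained] * 2^expr_log2fc
  fpkm_b[lost] <- fpkm_a[lost] * 2^(-expr_log2fc)
  len <- setNames(GenomicRanges::width(genes), names(genes))
  mk_expr <- function(fpkm) {
    counts <- rpois(length(fpkm), fpkm * (len / 1000) * (config$rna_library / 1e6))
    data.frame(gene_id = names(fpkm), length = as.integer(len), counts = counts,
               fpkm = compute_fpkm(counts, len, library = config$rna_library))
  }
  expression_a <- mk_expr(fpkm_a)
  expression_b <- mk_expr(fpkm_b)
  tags_a <- simulate_tags(catalog$genome, islands_a, config$fold,
                          config$library_size, seed = seed + 7L)
  tags_b <- simulate_tags(catalog$genome, islands_b, config$fold,
                          config$library_size, seed = seed + 11L)
  list(mark = mark, islands_a = islands_a, islands_b = islands_b,
       tags_a = tags_a, tags_b = tags_b,
       expression_a = expression_a, expression_b = expression_b,
       planted = list(gained = gained, lost = lost))
}

#' Simulate a complete single-condition dataset
#'
#' Convenience wrapper: genome and annotation, chromatin truth, one
#' treatment/control tag-library pair per mark, and expression plus
#' methylation tables.
#'
#' @param config A [sim_config()].
#' @return List with `genome`, `catalog`, `nucleosomes`, `truth`, `tags`
#'   (named list per mark of treatment/control pairs), `expression`,
#'   `methylation`, `methylated_truth`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  gsim <- simulate_genome(config)
  truth <- simulate_chromatin(gsim$catalog, config)
  tags <- lapply(seq_along(truth$islands), function(i) {
    simulate_tags(gsim$genome, truth$islands[[i]], config$fold,
                  config$library_size, seed = .sub_seed(config, 500L + i))
  })
  names(tags) <- names(truth$islands)
  em <- simulate_expression_and_methylation(gsim$catalog, truth, config)
  c(gsim, list(truth = truth, tags = tags,
               expression = em$expression, methylation = em$methylation,
               methylated_truth = em$methylated_truth))
}

#' Write a simulated dataset to plain-text files
#'
#' Emits chromosome sizes (TSV), genome FASTA, annotation GFF3, one tag BED
#' per mark and condition role (1 bp reads at the tag position), an
#' expression TSV and a methylation TSV — all readable back through the
#' package's own readers.
#'
#' @param dataset Output of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gn <- dataset$genome
  write.table(data.frame(names(gn$seqlengths), as.integer(gn$seqlengths)),
              file.path(dir, "chrom_sizes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  Biostrings::writeXStringSet(gn$sequence, file.path(dir, "genome.fa"))
  feats <- c(GenomicRanges::granges(dataset$catalog$genes),
             GenomicRanges::granges(dataset$catalog$tes))
  mcols(feats)$type <- rep(c("gene", "transposable_element"),
                           c(length(dataset$catalog$genes),
                             length(dataset$catalog$tes)))
  mcols(feats)$ID <- names(feats)
  rtracklayer::export(feats, file.path(dir, "features.gff3"), format = "gff3")
  write_tag_bed <- function(ts, path) {
    rows <- do.call(rbind, lapply(names(ts$pos), function(ch) {
      if (!length(ts$pos[[ch]])) return(NULL)
      data.frame(chrom = ch, start0 = ts$pos[[ch]] - 1L, end0 = ts$pos[[ch]],
                 name = ".", score = 0L, strand = "+")
    }))
    if (is.null(rows)) rows <- data.frame()
    write.table(rows, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  for (m in names(dataset$tags)) {
    write_tag_bed(dataset$tags[[m]]$treatment,
                  file.path(dir, sprintf("%s_treatment.bed", m)))
    write_tag_bed(dataset$tags[[m]]$control,
                  file.path(dir, sprintf("%s_control.bed", m)))
  }
  write.table(dataset$expression, file.path(dir, "expression.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(dataset$methylation, file.path(dir, "methylation.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
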