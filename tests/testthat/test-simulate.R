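# Properties of the seeded generators: determinism, conservation of feature
# and tag counts, calibrated enrichment, and file round-trips.

test_that("the full dataset is deterministic under a fixed seed", {
  cfg <- small_config()
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$catalog$genes, d2$catalog$genes)
  expect_identical(d1$truth$states, d2$truth$states)
  expect_identical(d1$tags$H3K27me3$treatment$pos, d2$tags$H3K27me3$treatment$pos)
  expect_identical(d1$expression, d2$expression)
  expect_identical(d1$methylation, d2$methylation)
  expect_identical(as.character(d1$genome$sequence), as.character(d2$genome$sequence))
  # a different seed changes the data
  d3 <- simulate_dataset(small_config(seed = 43))
  expect_false(identical(d1$methylation, d3$methylation))
})

test_that("feature counts, lengths and spacing follow the configuration", {
  cfg <- sim_config(seed = 9, n_chrom = 2, chrom_length = 5e5, n_genes = 100,
                    n_tes = 30, n_nucleosomes = 50)
  sim <- simulate_genome(cfg)
  cat_ <- sim$catalog
  expect_length(cat_$genes, 100)
  expect_length(cat_$tes, 30)
  expect_true(all(width(cat_$genes) >= cfg$gene_min))
  expect_true(all(width(cat_$tes) >= cfg$te_min))
  # features never overlap
  feats <- c(granges(cat_$genes), granges(cat_$tes))
  expect_equal(sum(width(GenomicRanges::reduce(feats, ignore.strand = TRUE))),
               sum(width(feats)))
  # inter-feature spacers (excluding the trailing chromosome arm) average
  # close to the configured mean
  gaps <- unlist(lapply(names(sim$genome$seqlengths), function(ch) {
    f <- sort(feats[seqnames(feats) == ch], ignore.strand = TRUE)
    c(start(f)[1] - 1, start(f)[-1] - end(f)[-length(f)] - 1)
  }))
  expect_true(all(gaps >= 0))
  expect_lt(abs(mean(gaps) - cfg$intergenic_mean), 0.2 * cfg$intergenic_mean)
  # nucleosomal intervals have elevated GC
  gc_of <- function(gr) {
    s <- Biostrings::extractAt(sim$genome$sequence[[as.character(
      seqnames(gr)[1])]], ranges(gr[1]))
    f <- Biostrings::letterFrequency(s, c("GC"), as.prob = TRUE)
    mean(f)
  }
  nuc_gc <- mean(vapply(seq_along(sim$nucleosomes), function(i) {
    gc_of(sim$nucleosomes[i]) }, numeric(1)))
  expect_gt(nuc_gc, 0.6)
})

test_that("planted islands respect length bounds and minimum separation", {
  gn <- cs_genome(c(chr1 = 4e5, chr2 = 4e5))
  isl <- plant_islands(gn, n = 40, min_len = 600, max_len = 3000,
                       min_gap = 1000, seed = 12)
  expect_length(isl, 40)
  expect_true(all(width(isl) >= 600 & width(isl) <= 3000))
  for (ch in c("chr1", "chr2")) {
    x <- isl[seqnames(isl) == ch]
    if (length(x) > 1) {
      expect_true(all(start(x)[-1] - end(x)[-length(x)] - 1 >= 1000))
    }
  }
})

test_that("tag libraries are calibrated in size and island enrichment", {
  gn <- cs_genome(c(chr1 = 3e5, chr2 = 3e5))
  isl <- plant_islands(gn, n = 40, min_len = 1000, max_len = 2500,
                       min_gap = 1000, seed = 14)
  tl <- simulate_tags(gn, isl, fold = 8, library_size = 1e5, seed = 15)
  expect_lt(abs(tl$treatment$library_size - 1e5) / 1e5, 0.05)
  expect_lt(abs(tl$control$library_size - 1e5) / 1e5, 0.05)
  # fraction of treatment tags inside islands matches 8A/(G + 7A)
  A <- sum(width(isl)); G <- genome_length(gn)
  want <- 8 * A / (G + 7 * A)
  n_in <- sum(countOverlaps(
    GRanges(rep(names(tl$treatment$pos), lengths(tl$treatment$pos)),
            IRanges(unlist(tl$treatment$pos), width = 1)), isl) > 0)
  expect_lt(abs(n_in / tl$treatment$library_size - want), 0.05)
  expect_gt(want, 0.4)
  # control is not enriched: island fraction close to A/G
  n_in_c <- sum(countOverlaps(
    GRanges(rep(names(tl$control$pos), lengths(tl$control$pos)),
            IRanges(unlist(tl$control$pos), width = 1)), isl) > 0)
  expect_lt(abs(n_in_c / tl$control$library_size - A / G), 0.05)
  # zero library yields empty tag sets
  z <- simulate_tags(gn, isl, fold = 8, library_size = 0, seed = 16)
  expect_equal(z$treatment$library_size, 0)
  expect_equal(z$control$library_size, 0)
})

test_that("expression and methylation tables are internally consistent", {
  cfg <- small_config()
  gsim <- simulate_genome(cfg)
  truth <- simulate_chromatin(gsim$catalog, cfg)
  em <- simulate_expression_and_methylation(gsim$catalog, truth, cfg)
  ex <- em$expression
  expect_setequal(ex$gene_id, names(gsim$catalog$genes))
  # the fpkm column is exactly the FPKM formula applied to counts
  expect_equal(ex$fpkm, unname(compute_fpkm(ex$counts, ex$length,
                                            library = cfg$rna_library)))
  me <- em$methylation
  expect_true(all(me$count_meth <= me$count_total))
  expect_true(all(me$pos >= 0))
  # truly methylated features show much higher methylation fractions
  sites <- call_methylation(me)
  feats <- c(granges(gsim$catalog$genes), granges(gsim$catalog$tes))
  names(feats) <- c(names(gsim$catalog$genes), names(gsim$catalog$tes))
  called <- methylated_features(sites, feats)
  truth_ids <- em$methylated_truth
  tp <- length(intersect(called, truth_ids)) / length(truth_ids)
  expect_gt(tp, 0.9)
})

test_that("written dataset files round-trip through the package readers", {
  cfg <- small_config()
  ds <- simulate_dataset(cfg)
  dir <- tempfile()
  write_dataset(ds, dir)
  # chromosome sizes and FASTA
  gn2 <- read_chrom_sizes(file.path(dir, "chrom_sizes.tsv"),
                          fasta = file.path(dir, "genome.fa"))
  expect_equal(gn2$seqlengths, ds$genome$seqlengths)
  expect_equal(as.character(gn2$sequence), as.character(ds$genome$sequence))
  # annotation
  cat2 <- read_gff3(file.path(dir, "features.gff3"), ds$genome)
  expect_equal(bare(cat2$genes[names(ds$catalog$genes)]),
               bare(ds$catalog$genes))
  # tags: 1 bp reads at shift 0 reproduce the in-memory tag positions
  ts0 <- ds$tags$H3K4me2$treatment
  ts2 <- read_tags(file.path(dir, "H3K4me2_treatment.bed"), ds$genome, shift = 0)
  expect_equal(ts2$library_size, ts0$library_size)
  expect_equal(lapply(ts2$pos, sort), lapply(ts0$pos, sort))
  # expression and methylation tables
  ex2 <- read.table(file.path(dir, "expression.tsv"), header = TRUE, sep = "\t")
  expect_equal(ex2$counts, ds$expression$counts)
  me2 <- read.table(file.path(dir, "methylation.tsv"), header = TRUE, sep = "\t")
  expect_equal(me2$count_meth, ds$methylation$count_meth)
})
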