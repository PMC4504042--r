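# Readers, coordinate conversion, and the gene/TE/intergenic partition.

test_that("read_bed maps BED records to 1-based closed intervals", {
  gn <- tiny_genome()
  path <- write_lines("chr1\t0\t100", ".bed")
  gr <- read_bed(path, gn)
  expect_equal(start(gr), 1)
  expect_equal(end(gr), 100)
  expect_equal(as.character(strand(gr)), "*")
})

test_that("read_bed rejects empty and malformed records with line numbers", {
  gn <- tiny_genome()
  expect_error(read_bed(write_lines("chr1\t100\t100", ".bed"), gn),
               "line 1.*empty")
  expect_error(read_bed(write_lines(c("chr1\t0\t50", "chr1\tx\t90"), ".bed"), gn),
               "line 2")
  expect_error(read_bed(write_lines("chr9\t0\t50", ".bed"), gn),
               "unknown chromosome")
  expect_error(read_bed(write_lines("chr1\t900\t2000", ".bed"), gn),
               "outside chromosome bounds")
})

test_that("read_bed keeps duplicate records", {
  gn <- tiny_genome()
  path <- write_lines(c("chr1\t0\t100", "chr1\t200\t300", "chr1\t0\t100"), ".bed")
  expect_length(read_bed(path, gn), 3)
})

test_that("read_gff3 converts coordinates and collapses shared IDs to spans", {
  gn <- tiny_genome()
  gff <- write_lines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t1\t100\t.\t+\t.\tID=gA",
    "chr1\tsrc\texon\t1\t40\t.\t+\t.\tParent=gA",
    "chr1\tsrc\tgene\t301\t400\t.\t-\t.\tID=gB",
    "chr1\tsrc\tgene\t451\t500\t.\t-\t.\tID=gB",
    "chr1\tsrc\ttransposable_element\t601\t700\t.\t+\t.\tID=t1"), ".gff3")
  cat_ <- read_gff3(gff, gn)
  expect_setequal(names(cat_$genes), c("gA", "gB"))
  # 1-based GFF start 1 stays 1 in the internal 1-based representation
  expect_equal(start(cat_$genes["gA"]), 1)
  expect_equal(end(cat_$genes["gA"]), 100)
  # two records sharing an ID span min(start)..max(end)
  expect_equal(start(cat_$genes["gB"]), 301)
  expect_equal(end(cat_$genes["gB"]), 500)
  # unrequested types (exon) are excluded from the catalog
  expect_length(cat_$tes, 1)
  expect_equal(names(cat_$tes), "t1")
})

test_that("derive_intergenic is the complement of the feature union", {
  gn <- tiny_genome()
  genes <- GRanges("chr1", IRanges(101, 200))
  tes <- GRanges("chr1", IRanges(501, 600))
  inter <- derive_intergenic(genes, tes, gn)
  expect_equal(as.data.frame(ranges(inter))[, c("start", "end")],
               data.frame(start = c(1, 201, 601), end = c(100, 500, 1000)))
  # features tiling the chromosome leave nothing
  full <- GRanges("chr1", IRanges(1, 1000))
  expect_length(derive_intergenic(full, GRanges(), gn), 0)
  # overlapping gene and TE: complement of the union, no double subtraction
  ov_genes <- GRanges("chr1", IRanges(101, 300))
  ov_tes <- GRanges("chr1", IRanges(201, 400))
  inter2 <- derive_intergenic(ov_genes, ov_tes, gn)
  expect_equal(sum(width(inter2)), 1000 - 300)
})

test_that("derive_intergenic matches the per-base complement oracle", {
  set.seed(7)
  for (i in 1:20) {
    gn <- random_genome()
    genes <- random_intervals(gn, n = 8)
    tes <- random_intervals(gn, n = 4)
    inter <- derive_intergenic(genes, tes, gn)
    feat <- bp_mask(c(genes, tes), gn)
    oracle <- mask_to_gr(lapply(feat, `!`))
    expect_equal(bare(inter), bare(oracle))
  }
})

test_that("catalog classes tile each chromosome without gaps", {
  cfg <- small_config()
  cat_ <- simulate_genome(cfg)$catalog
  covered <- GenomicRanges::reduce(
    c(granges(cat_$genes), granges(cat_$tes), granges(cat_$intergenic)),
    ignore.strand = TRUE)
  expect_equal(sum(width(covered)), genome_length(cat_$genome))
})

test_that("read_tags applies the strand-aware 5' rule and shift", {
  gn <- tiny_genome()
  path <- write_lines(c("chr1\t100\t136\tr1\t0\t+",
                        "chr1\t100\t136\tr2\t0\t-"), ".bed")
  ts <- read_tags(path, gn, shift = 0)
  # + read 5' at 0-based 100 -> 1-based 101; - read 5' at 0-based 135 -> 136
  expect_equal(ts$pos$chr1, c(101, 136))
  expect_equal(ts$library_size, 2)
  shifted <- read_tags(path, gn, shift = 10)
  expect_equal(shifted$pos$chr1, c(111, 126))
  # library size conserved under shift
  expect_equal(shifted$library_size, ts$library_size)
})

test_that("read_tags clamps out-of-bounds shifted positions with a warning", {
  gn <- tiny_genome()
  path <- write_lines("chr1\t0\t36\tr1\t0\t-", ".bed")
  expect_warning(ts <- read_tags(path, gn, shift = 73), "clamped")
  expect_equal(ts$pos$chr1, 1)
})

test_that("bedGraph writing merges equal-value runs and round-trips", {
  gn <- tiny_genome()
  track <- GRanges("chr1", IRanges(c(1, 201), c(200, 400)), score = c(1, 1),
                   seqlengths = c(chr1 = 1000))
  path <- tempfile(fileext = ".bedGraph")
  write_bedgraph(track, path)
  lines <- readLines(path)
  expect_length(lines, 1)
  expect_equal(strsplit(lines, "\t")[[1]], c("chr1", "0", "400", "1"))
  back <- read_bedgraph(path, gn)
  expect_equal(bare(back), GRanges("chr1", IRanges(1, 400)))
  expect_equal(back$score, 1)
  # zero values suppressed by default, kept on request
  z <- GRanges("chr1", IRanges(c(1, 501), c(100, 600)), score = c(0, 2))
  p2 <- tempfile(fileext = ".bedGraph")
  write_bedgraph(z, p2)
  expect_length(readLines(p2), 1)
  write_bedgraph(z, p2, keep_zeros = TRUE)
  expect_length(readLines(p2), 2)
  # overlapping intervals refused
  bad <- GRanges("chr1", IRanges(c(1, 50), c(100, 150)), score = c(1, 2))
  expect_error(write_bedgraph(bad, tempfile()), "overlapping")
})

test_that("gff3 round-trip preserves 1-based feature spans", {
  cfg <- small_config()
  sim <- simulate_genome(cfg)
  dir <- tempfile()
  ds <- list(genome = sim$genome, catalog = sim$catalog,
             tags = list(), expression = data.frame(), methylation = data.frame())
  write_dataset(ds, dir)
  back <- read_gff3(file.path(dir, "features.gff3"), sim$genome)
  expect_equal(bare(back$genes[names(sim$catalog$genes)]),
               bare(sim$catalog$genes))
  expect_equal(bare(back$tes[names(sim$catalog$tes)]),
               bare(sim$catalog$tes))
})
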