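# Window counting, Poisson eligibility, gap-tolerant assembly, and
# island scoring against a control library.

# independent oracle: direct pmf summation P(X >= k) = 1 - sum_{i<k} pmf(i)
pois_tail_oracle <- function(k, lambda) {
  if (k == 0) return(1)
  i <- 0:(k - 1)
  1 - sum(exp(-lambda) * lambda^i / factorial(i))
}

# independent oracle: paint eligible windows on a bp vector, close gaps <= g,
# read off runs
assemble_oracle <- function(mask, w, g, len) {
  bp <- logical(len)
  for (i in which(mask)) bp[((i - 1) * w + 1):min(i * w, len)] <- TRUE
  r <- rle(bp)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  # close internal FALSE runs of length <= g
  for (j in seq_along(r$values)) {
    if (!r$values[j] && j > 1 && j < length(r$values) && r$lengths[j] <= g) {
      bp[starts[j]:ends[j]] <- TRUE
    }
  }
  r2 <- rle(bp)
  e2 <- cumsum(r2$lengths); s2 <- e2 - r2$lengths + 1
  data.frame(start = s2[r2$values], end = e2[r2$values])
}

test_that("poisson_upper_tail matches direct pmf summation", {
  expect_equal(poisson_upper_tail(0, 5), 1)
  expect_equal(poisson_upper_tail(4, 1), pois_tail_oracle(4, 1), tolerance = 1e-12)
  expect_equal(poisson_upper_tail(4, 1), 1 - (8 / 3) * exp(-1), tolerance = 1e-12)
  expect_equal(poisson_upper_tail(2, 2), pois_tail_oracle(2, 2), tolerance = 1e-12)
  expect_equal(poisson_upper_tail(2, 2), 1 - 3 * exp(-2), tolerance = 1e-12)
  # stable at large k
  expect_gt(poisson_upper_tail(1000, 500), 0)
  expect_error(poisson_upper_tail(3, 0), "lambda")
})

test_that("count_windows bins tags and conserves the library size", {
  gn <- tiny_genome(c(chr1 = 1000))
  ts <- tag_set(rep("chr1", 3), c(10, 150, 250), gn)
  wc <- count_windows(ts, gn, w = 200)
  expect_equal(wc$counts$chr1, c(2, 1, 0, 0, 0))
  # empty tag set
  wc0 <- count_windows(tag_set(character(), integer(), gn), gn, 200)
  expect_equal(sum(wc0$counts$chr1), 0)
  # conservation on random tags across chromosomes, trailing partial window
  gn2 <- cs_genome(c(chr1 = 1050, chr2 = 990))
  set.seed(1)
  ch <- sample(c("chr1", "chr2"), 10000, replace = TRUE)
  pos <- ceiling(runif(10000) * gn2$seqlengths[ch])
  wc2 <- count_windows(tag_set(ch, pos, gn2), gn2, 200)
  expect_equal(sum(unlist(wc2$counts)), 10000)
})

test_that("window eligibility follows the Poisson threshold", {
  gn <- tiny_genome(c(chr1 = 1000))
  wc <- count_windows(tag_set(character(), integer(), gn), gn, 200)
  expect_false(any(unlist(eligible_windows(wc, 0.2))))
  # lambda_bg = 1: count 4 eligible at 0.02 (p ~ 0.019), count 3 not (~0.080)
  wc$lambda_bg <- 1
  wc$library_size <- 5L
  wc$counts$chr1 <- c(4L, 3L, 0L, 0L, 0L)
  el <- eligible_windows(wc, 0.02)
  expect_equal(el$chr1, c(TRUE, FALSE, FALSE, FALSE, FALSE))
  # lowering p_window never adds eligible windows
  expect_true(all(unlist(eligible_windows(wc, 0.005)) <= unlist(el)))
})

test_that("assemble_islands merges runs separated by at most g bp", {
  gn <- tiny_genome(c(chr1 = 2000))
  # eligible windows 1 and 5: gap = 3 windows = 600 bp
  mask <- list(chr1 = c(TRUE, FALSE, FALSE, FALSE, TRUE, rep(FALSE, 5)))
  one <- assemble_islands(mask, 200, 600, gn)
  expect_equal(bare(one), GRanges("chr1", IRanges(1, 1000)))
  two <- assemble_islands(mask, 200, 200, gn)
  expect_equal(bare(two), GRanges("chr1", IRanges(c(1, 801), c(200, 1000))))
  # single eligible window -> island of length w
  single <- assemble_islands(list(chr1 = c(FALSE, TRUE, rep(FALSE, 8))), 200, 600, gn)
  expect_equal(width(single), 200)
  expect_error(assemble_islands(mask, 200, 300, gn), "multiple")
})

test_that("assemble_islands matches exhaustive merge oracle on small genomes", {
  set.seed(11)
  for (i in 1:50) {
    nw <- sample(5:50, 1)
    w <- 100
    g <- sample(0:4, 1) * w
    len <- nw * w
    gn <- cs_genome(c(chrA = len))
    mask <- list(chrA = runif(nw) < 0.3)
    got <- assemble_islands(mask, w, g, gn)
    want <- assemble_oracle(mask$chrA, w, g, len)
    expect_equal(data.frame(start = start(got), end = end(got)), want)
  }
})

test_that("island fold change uses library normalization with pseudocount 1", {
  gn <- tiny_genome(c(chr1 = 2000))
  trt <- tag_set(rep("chr1", 100), c(rep(100, 50), rep(1500, 50)), gn)
  ctl <- tag_set(rep("chr1", 100), c(rep(100, 5), rep(1500, 95)), gn)
  wt <- count_windows(trt, gn, 200)
  wcc <- count_windows(ctl, gn, 200)
  isl <- GRanges("chr1", IRanges(1, 200))
  sc <- score_islands(isl, wt, wcc)
  expect_equal(sc$treatment_count, 50)
  expect_equal(sc$control_count, 5)
  expect_equal(sc$fold, (51 / 100) / (6 / 100))  # = 8.5
  # t = c with equal libraries: no enrichment
  sc2 <- score_islands(isl, wt, wt)
  expect_equal(sc2$fold, 1)
  expect_gt(sc2$p, 0.4)
})

test_that("island q-values match a textbook Benjamini-Hochberg oracle", {
  gn <- cs_genome(c(chr1 = 1e5))
  planted <- plant_islands(gn, 5, 600, 2000, 1000, seed = 3)
  tl <- simulate_tags(gn, planted, fold = 6, library_size = 2e4, seed = 4)
  wt <- count_windows(tl$treatment, gn, 200)
  wcc <- count_windows(tl$control, gn, 200)
  cands <- assemble_islands(eligible_windows(wt, 0.2), 200, 600, gn)
  sc <- score_islands(cands, wt, wcc)
  p <- sc$p
  m <- length(p)
  o <- order(p)
  bh <- numeric(m)
  bh[o] <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
  expect_equal(sc$q, bh)
  expect_true(all(sc$q >= sc$p))
})

test_that("raising the FDR threshold never removes an island", {
  gn <- cs_genome(c(chr1 = 2e5))
  planted <- plant_islands(gn, 8, 600, 2000, 1000, seed = 5)
  tl <- simulate_tags(gn, planted, fold = 8, library_size = 4e4, seed = 6)
  strict <- call_islands(tl$treatment, tl$control, gn,
                         island_params(200, 600, fdr = 1e-4))
  loose <- call_islands(tl$treatment, tl$control, gn,
                        island_params(200, 600, fdr = 1e-2))
  expect_true(all(countOverlaps(strict, loose, type = "equal") == 1))
  expect_gte(length(loose), length(strict))
})

test_that("zero-tag treatment yields no islands", {
  gn <- tiny_genome(c(chr1 = 10000))
  empty <- tag_set(character(), integer(), gn)
  ctl <- tag_set(rep("chr1", 100), sample.int(10000, 100, replace = TRUE), gn)
  out <- call_islands(empty, ctl, gn, island_params(200, 600, 1e-2))
  expect_length(out, 0)
  expect_true(all(c("score", "fold", "p", "q") %in% names(mcols(out))))
})

test_that("accepted parameter presets validate and invalid ones do not", {
  broad <- island_params(w = 200, g = 600, fdr = 1e-2)
  punctate <- island_params(w = 200, g = 200, fdr = 1e-2)
  expect_equal(broad$g, 600L)
  expect_equal(punctate$g, 200L)
  expect_error(island_params(w = 200, g = 500), "multiple")
  expect_error(island_params(fdr = 0), "fdr")
})
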