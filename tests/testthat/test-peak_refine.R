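test_that("loess smoothing reproduces constants and ramps, localizes bumps", {
  expect_equal(smoothSignal(rep(3.5, 100)), rep(3.5, 100), tolerance = 1e-9)
  ramp <- seq(0, 10, length.out = 200)
  expect_equal(smoothSignal(ramp), ramp, tolerance = 1e-6)
  expect_error(smoothSignal(rep(1, 5)), "short")

  set.seed(61)
  n <- 5000
  y <- 50 * exp(-((seq_len(n) - 2500)^2) / (2 * 250^2)) + stats::rnorm(n, 0, 3)
  sm <- smoothSignal(pmax(y, 0))
  expect_lt(abs(which.max(sm) - 2500), 25)
})

test_that("extrema detection: monotone, alternation, plateaus, oracle", {
  expect_equal(nrow(findExtrema(1:50)), 0)

  ex <- findExtrema(c(0, 1, 0, 2, 0))
  expect_equal(ex$pos[ex$kind == "peak"], c(2L, 4L))
  expect_equal(ex$pos[ex$kind == "valley"], 3L)

  # plateau collapses to its midpoint
  pl <- findExtrema(c(0, 1, 1, 1, 0))
  expect_equal(pl$pos, 3L)
  expect_equal(pl$kind, "peak")

  set.seed(62)
  for (i in 1:100) {
    y <- as.numeric(stats::filter(stats::rnorm(300), rep(1 / 20, 20),
                                  circular = TRUE))
    ex <- findExtrema(y)
    oc <- oracle_extrema(y)
    expect_equal(ex$pos, oc$pos)
    expect_equal(ex$kind, oc$kind)
    # peaks and valleys alternate
    if (nrow(ex) > 1) expect_true(all(ex$kind[-1] != ex$kind[-nrow(ex)]))
    # 9-position mean score
    j <- sample(nrow(ex), 1)
    expect_equal(ex$score[j],
                 mean(y[max(1, ex$pos[j] - 4):min(300, ex$pos[j] + 4)]))
  }
})

test_that("amplitude/valley filtering follows the merge rule and its oracle", {
  one <- data.frame(pos = 10L, kind = "peak", score = 5)
  expect_equal(filterPeaks(one, 0.6, 0.3)$pos, 10L)

  # two equal peaks, valley at 80% of them: not deeper than 30% -> merged
  ex <- data.frame(pos = c(10L, 20L, 30L), kind = c("peak", "valley", "peak"),
                   score = c(100, 80, 100))
  expect_equal(nrow(filterPeaks(ex, 0.5, 0.30)), 1)
  # valley at 65%: deeper than 30% of the weaker flank -> separated
  ex$score[2] <- 65
  expect_equal(nrow(filterPeaks(ex, 0.5, 0.30)), 2)

  set.seed(63)
  for (i in 1:100) {
    k <- sample(2:8, 1)
    scores_p <- stats::runif(k, 1, 100)
    scores_v <- stats::runif(k - 1, 0, 90)
    pos <- sort(sample.int(1000, 2 * k - 1))
    ex <- data.frame(pos = pos,
                     kind = rep_len(c("peak", "valley"), 2 * k - 1),
                     score = as.vector(rbind(scores_p,
                                             c(scores_v, NA)))[1:(2 * k - 1)])
    pf <- sample(c(0.5, 0.55, 0.6), 1)
    vd <- sample(c(0.3, 0.35), 1)
    got <- filterPeaks(ex, pf, vd)
    expect_equal(sort(got$pos), sort(oracle_filter(ex, pf, vd)))
  }
})

test_that("grid consensus keeps only peaks surviving all combinations", {
  # a secondary peak at 52% of the max survives only the 0.50 cutoff
  ex <- data.frame(pos = c(100L, 150L, 200L),
                   kind = c("peak", "valley", "peak"),
                   score = c(100, 10, 52))
  out <- consensusOverGrid(ex)
  expect_equal(out$pos, 100L)
  # at 65% it survives every combination (valley is deep)
  ex$score[3] <- 65
  expect_equal(sort(consensusOverGrid(ex)$pos), c(100L, 200L))

  # enlarging the grid can only shrink the consensus
  set.seed(64)
  for (i in 1:50) {
    k <- sample(3:7, 1)
    pos <- sort(sample.int(2000, 2 * k - 1))
    ex <- data.frame(pos = pos,
                     kind = rep_len(c("peak", "valley"), 2 * k - 1),
                     score = stats::runif(2 * k - 1, 0, 100))
    small <- filterParams(peak_fraction_grid = c(0.5, 0.6),
                          valley_depth_grid = 0.3)
    big <- filterParams(peak_fraction_grid = c(0.5, 0.55, 0.6),
                        valley_depth_grid = c(0.3, 0.35))
    out_small <- consensusOverGrid(ex, small)
    out_big <- consensusOverGrid(ex, big)
    ok <- vapply(out_big$pos, function(p)
      nrow(out_small) > 0 && min(abs(out_small$pos - p)) <= 50, logical(1))
    expect_true(all(ok))
  }
})

test_that("mutual nearest-neighbour pairing: geometry and oracle", {
  gr <- function(p) GenomicRanges::GRanges("chr1",
                                           IRanges::IRanges(p, width = 1))
  same <- pairReplicates(gr(c(100, 900)), gr(c(100, 900)))
  expect_equal(peakAccuracy(same$pairs), c(0, 0))
  expect_equal(peakPositions(same$pairs), c(100L, 900L))

  # two replicate peak summits 194 bp apart: centre at the median
  # position, accuracy is the half distance
  fig <- pairReplicates(gr(1000), gr(1194))
  expect_equal(peakPositions(fig$pairs), 1097L)
  expect_equal(peakAccuracy(fig$pairs), 97)

  set.seed(65)
  for (i in 1:100) {
    a <- sort(sample.int(50000, sample(1:12, 1)))
    b <- sort(sample.int(50000, sample(1:12, 1)))
    res <- pairReplicates(gr(a), gr(b))
    oc <- oracle_mutual_nn(a, b)
    expect_equal(length(res$pairs), nrow(oc))
    expect_equal(sort(S4Vectors::mcols(res$pairs)$posRep1), sort(a[oc[, 1]]))
    # one-to-one: no peak used twice, and nothing lost
    expect_equal(length(res$pairs) + length(res$unmatched1), length(a))
    expect_equal(length(res$pairs) + length(res$unmatched2), length(b))
    expect_false(anyDuplicated(S4Vectors::mcols(res$pairs)$posRep2) > 0)
  }
})

test_that("9-bp scores rank peaks into balanced quartiles", {
  v1 <- numeric(1000); v2 <- numeric(1000)
  pos <- seq(100, 800, by = 100)
  v1[pos] <- seq(10, 80, by = 10); v2[pos] <- seq(10, 80, by = 10) + 1
  peaks <- ConsensusPeaks("chr1", pos, accuracy = rep(5, 8))
  sc <- scorePeaks(peaks, CoverageTrack(v1), CoverageTrack(v2))
  expect_equal(as.vector(table(peakQuartile(sc))), rep(2L, 4))
  expect_equal(S4Vectors::mcols(sc)$score,
               (seq(10, 80, by = 10) * 2 + 1) / 2)
  expect_equal(as.character(peakQuartile(sc))[8], "Q4")

  # all-equal scores: stable position order keeps sizes balanced
  v1[] <- 0; v1[pos] <- 7
  eq <- scorePeaks(peaks, CoverageTrack(v1), CoverageTrack(v1))
  expect_equal(as.vector(table(peakQuartile(eq))), rep(2L, 4))
  expect_equal(as.character(peakQuartile(eq)),
               rep(c("Q1", "Q2", "Q3", "Q4"), each = 2))
})

test_that("replicate jitter at 120 bp gives the expected pairing distances", {
  set.seed(66)
  truth <- sort(sample.int(5000000, 60))
  truth <- truth[c(TRUE, diff(truth) > 5000)]
  a <- sort(round(truth + stats::rnorm(length(truth), 0, 120)))
  b <- sort(round(truth + stats::rnorm(length(truth), 0, 120)))
  gr <- function(p) GenomicRanges::GRanges("chr1",
                                           IRanges::IRanges(p, width = 1))
  res <- pairReplicates(gr(a), gr(b))
  d <- 2 * peakAccuracy(res$pairs)
  expect_gte(length(d), 50)
  expect_gte(stats::median(d), 100)
  expect_lte(stats::median(d), 400)
  # qualitative ordering of the pairing-distance distribution
  expect_gt(mean(d < 500), mean(d < 250))
  expect_gt(mean(d < 250), mean(d < 100))
})
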