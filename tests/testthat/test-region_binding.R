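test_that("summit window scoring: constants, spikes, edge tie-breaks", {
  tr <- CoverageTrack(rep(2, 5000))
  reg <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 4000))
  sc <- summitScore(reg, tr)
  expect_equal(S4Vectors::mcols(sc)$score, 2000)
  expect_equal(S4Vectors::mcols(sc)$summitStart, 1001L)  # leftmost tie

  v <- numeric(5000); v[3000] <- 5
  sc2 <- summitScore(reg, CoverageTrack(v))
  expect_equal(S4Vectors::mcols(sc2)$score, 5)
  expect_equal(S4Vectors::mcols(sc2)$summitStart, 2001L)  # max(start, p-999)
})

test_that("summit score equals exhaustive search and ignores outside signal", {
  set.seed(21)
  for (i in 1:100) {
    len <- sample(1200:4000, 1)
    v <- stats::rpois(len, 1) * stats::runif(len)
    tr <- CoverageTrack(v)
    s <- sample.int(len - 1100, 1)
    e <- s + sample(1000:1099, 1)
    reg <- GenomicRanges::GRanges("chr1", IRanges::IRanges(s, e))
    got <- summitScore(reg, tr, regionParams(summit_window_bp = 1000))
    oc <- oracle_summit(v[s:e], 1000)
    expect_equal(S4Vectors::mcols(got)$score, oc$score)
    expect_equal(S4Vectors::mcols(got)$summitStart, s + oc$start - 1L)
  }
  # adding signal outside the region must not change the score
  v2 <- stats::rpois(3000, 1)
  reg <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 2500))
  base <- summitScore(reg, CoverageTrack(v2))
  v2[1:900] <- v2[1:900] + 50
  v2[2700:3000] <- v2[2700:3000] + 50
  shifted <- summitScore(reg, CoverageTrack(v2))
  expect_equal(S4Vectors::mcols(base)$score, S4Vectors::mcols(shifted)$score)
})

test_that("replicate concordance keeps regions whose summit the other replicate saw", {
  v <- numeric(20000); v[5000:5200] <- 10; v[15000:15200] <- 8
  tr <- CoverageTrack(v)
  r1 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(4000, 14000),
                                                        c(6500, 16500)))
  same <- concordantRegions(r1, r1, tr, tr)
  expect_length(same$rep1, 2)
  expect_length(same$merged, 2)

  r2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(18000, 19000))
  disj <- concordantRegions(r1, r2, tr, tr)
  expect_length(disj$rep1, 0)
  expect_length(disj$merged, 0)

  # rep2 overlaps rep1's region body but not its summit window -> dropped
  body_only <- GenomicRanges::GRanges("chr1", IRanges::IRanges(6300, 6500))
  conc <- concordantRegions(r1[1], body_only, tr, tr)
  expect_length(conc$rep1, 0)
})

test_that("region grouping matches transitive-closure oracle", {
  p <- regionParams(group_gap_bp = 100000)
  two <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 52000),
                                                         c(2000, 54000)))
  expect_equal(unique(S4Vectors::mcols(groupRegions(two, p))$group), 1L)
  far <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 153000),
                                                         c(2000, 155000)))
  expect_equal(S4Vectors::mcols(groupRegions(far, p))$group, c(1L, 2L))

  set.seed(31)
  for (i in 1:100) {
    n <- sample(2:12, 1)
    gr <- randomRegions(n, chrom_len = 500000, min_w = 100, max_w = 5000)
    gap <- sample(c(1000, 10000, 50000), 1)
    got <- groupRegions(gr, regionParams(group_gap_bp = gap))
    oc <- oracle_groups(GenomicRanges::start(got), GenomicRanges::end(got),
                        gap)
    expect_equal(S4Vectors::mcols(got)$group, oc)
  }
})

test_that("standalone PRC2 filter: activity plus distance from PRC1", {
  suz <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1000, 50000),
                                                         c(2000, 52000)))
  k27 <- suz
  none <- GenomicRanges::GRanges()
  all_kept <- standalonePRC2Regions(suz, k27, none,
                                    regionParams(standalone_distance_bp = 10000))
  expect_length(all_kept, 2)

  mel <- GenomicRanges::GRanges("chr1", IRanges::IRanges(7000, 8000))  # 5 kb off
  kept <- standalonePRC2Regions(suz, k27, mel,
                                regionParams(standalone_distance_bp = 10000))
  expect_equal(GenomicRanges::start(kept), 50000L)

  set.seed(41)
  for (i in 1:100) {
    suz <- randomRegions(sample(1:8, 1), 200000)
    k27 <- randomRegions(sample(1:8, 1), 200000)
    mel <- randomRegions(sample(0:6, 1), 200000)
    d <- sample(c(5000, 20000), 1)
    got <- standalonePRC2Regions(suz, k27, mel,
                                 regionParams(standalone_distance_bp = d))
    oc <- oracle_standalone(suz, k27, mel, d)
    expect_equal(GenomicRanges::start(got), GenomicRanges::start(suz)[oc])
  }
})

test_that("stand-in caller finds a planted block and stays quiet on pure noise", {
  set.seed(51)
  n <- 100000
  bg <- stats::rpois(n, 2)
  chip <- bg + c(numeric(40000), rep(30, 2000), numeric(n - 42000))
  got <- callEnrichedRegions(CoverageTrack(chip),
                             CoverageTrack(stats::rpois(n, 2)))
  expect_length(got, 1)
  expect_lt(abs(GenomicRanges::start(got) - 40000), 1000)
  expect_gt(GenomicRanges::width(got), 1000)

  quiet <- callEnrichedRegions(CoverageTrack(stats::rpois(n, 2)),
                               CoverageTrack(stats::rpois(n, 2)))
  expect_length(quiet, 0)
})
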