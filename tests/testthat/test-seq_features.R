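test_that("di-nucleotide map: self-subtraction, forced composition, oracle", {
  set.seed(91)
  seqs <- randomSeqs(6, 300)
  self <- dinucleotideMap(seqs, seqs, window = 50)
  expect_true(all(abs(self$diff) < 1e-12))
  # frequencies sum to 1 at every window before subtraction
  expect_true(all(abs(colSums(self$freq_regions) - 1) < 1e-9))

  polyA <- rep(paste(rep("A", 200), collapse = ""), 5)
  ctrl <- randomSeqs(20, 200)
  m <- dinucleotideMap(polyA, ctrl, window = 40)
  expect_true(all(abs(m$diff["AA", ] - (1 - m$freq_controls["AA", ])) < 1e-12))

  reg <- randomSeqs(10, 500)
  con <- randomSeqs(10, 500)
  got <- dinucleotideMap(reg, con, window = 50)
  oc <- oracle_dinuc_window(reg, 50) - oracle_dinuc_window(con, 50)
  expect_equal(unname(got$diff), unname(oc), tolerance = 1e-12)
})

test_that("N-only windows are masked, not zero", {
  seqs <- c(paste(c(rep("N", 60), randomSeqs(1, 140)), collapse = ""))
  m <- dinucFrequencies <- dinucleotideMap(seqs, randomSeqs(2, 200),
                                           window = 40)
  expect_true(anyNA(m$freq_regions))
})

test_that("oriented tract profiles are strand-symmetric", {
  set.seed(92)
  s <- randomSeqs(1, 400)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  a <- polyTractProfile(c(s, s), c("right", "right"), "AAAAA", window = 50)
  b <- polyTractProfile(c(s, rc), c("right", "left"), "AAAAA", window = 50)
  expect_equal(a$values, b$values)

  # A5 profile of a set equals the T5 profile with orientations flipped,
  # mirrored in offset
  seqs <- randomSeqs(8, 400)
  sides <- sample(c("left", "right"), 8, replace = TRUE)
  flipped <- ifelse(sides == "left", "right", "left")
  a5 <- polyTractProfile(seqs, sides, "AAAAA", window = 50)
  t5 <- polyTractProfile(seqs, flipped, "TTTTT", window = 50)
  expect_equal(a5$values, rev(t5$values), tolerance = 1e-12)

  expect_warning(polyTractProfile(seqs[1:2], c("right", "?"), "AAAAA"),
                 "unknown")
})

test_that("overlapping tract matches are counted", {
  s <- paste0(paste(rep("C", 50), collapse = ""),
              paste(rep("A", 7), collapse = ""),   # contains 3 A5 starts
              paste(rep("C", 43), collapse = ""))
  pr <- polyTractProfile(s, "right", "AAAAA", window = 100)
  expect_equal(max(slider <- pr$values), 3)
})

test_that("CpG window counts match direct enumeration", {
  expect_equal(cpgWindowCount("CGCGCG", window = 6)$values, 3)
  expect_true(all(cpgWindowCount(strrep("A", 100))$values == 0))
  set.seed(93)
  s <- randomSeqs(1, 300)
  expect_equal(cpgWindowCount(s, window = 40)$values,
               oracle_cpg_window(s, 40))
})

test_that("motif centrality peaks where the motif was planted and is flat on noise", {
  set.seed(94)
  len <- 1001
  centre_at <- (len - 8) %/% 2 + 1
  planted <- vapply(randomSeqs(30, len), function(s) {
    substr(s, centre_at, centre_at + 7) <- "AAACGAAA"; s
  }, character(1), USE.NAMES = FALSE)
  pwm <- consensusPWM("AAACGAAA")
  mc <- motifCentrality(planted, pwm, rolling = 50)
  expect_lt(abs(mc$offsets[which.max(mc$profiles$all)]), 30)
  # unsmoothed profile sums to the quartile share of matches
  expect_equal(sum(mc$raw$all), 1, tolerance = 1e-9)
  expect_true(all(mc$profiles$all >= 0))

  noise <- randomSeqs(200, len)
  flat <- suppressWarnings(motifCentrality(noise, pwm, rolling = 500))
  p <- flat$profiles$all
  expect_lte(max(p) / mean(p), 1.5)
})

test_that("quartile labels split the centrality profiles", {
  set.seed(95)
  len <- 501
  seqs <- vapply(randomSeqs(12, len), function(s) {
    substr(s, 247, 254) <- "AAACGAAA"; s
  }, character(1), USE.NAMES = FALSE)
  q <- rep(c("Q4", "Q1"), each = 6)
  mc <- motifCentrality(seqs, consensusPWM("AAACGAAA"), quartiles = q,
                        rolling = 50)
  expect_setequal(names(mc$profiles), c("Q1", "Q4"))
  expect_equal(sum(mc$raw$Q4), 1, tolerance = 1e-9)
})

test_that("metaprofiles equal the brute-force windowed mean", {
  tr <- CoverageTrack(rep(4.5, 2000))
  reg <- GenomicRanges::GRanges("chr1", IRanges::IRanges(800, 1200))
  mp <- metaProfile(tr, reg, half_width = 100)
  expect_true(all(mp$values == 4.5))
  expect_equal(length(mp$values), 200)

  set.seed(96)
  v <- stats::runif(5000)
  tr <- CoverageTrack(v)
  # single region: the profile is the raw window
  one <- GenomicRanges::GRanges("chr1", IRanges::IRanges(2000, 2400))
  mp1 <- metaProfile(tr, one, half_width = 150)
  expect_equal(mp1$values, v[(2200 - 150):(2200 + 149)])

  for (i in 1:20) {
    centers <- sample(500:4500, 8)
    reg <- GenomicRanges::GRanges("chr1", IRanges::IRanges(centers, centers))
    got <- metaProfile(tr, reg, half_width = 200)
    oc <- oracle_metaprofile(tr, centers, rep("chr1", 8), 200)
    expect_equal(got$values, oc)
  }

  # regions falling off the chromosome are excluded and counted
  edge <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(50, 2000),
                                                          c(60, 2000)))
  mpe <- metaProfile(tr, edge, half_width = 200)
  expect_equal(mpe$n_excluded, 1L)
  expect_equal(mpe$n_regions, 1L)
})

test_that("control windows avoid excluded loci and are deterministic", {
  set.seed(97)
  genome <- Biostrings::DNAStringSet(c(chr1 = randomSeqs(1, 50000)))
  ex <- GenomicRanges::GRanges("chr1", IRanges::IRanges(20000, 30000))
  a <- sampleControlSequences(genome, 10, width = 1000, exclude = ex,
                              seed = 5)
  b <- sampleControlSequences(genome, 10, width = 1000, exclude = ex,
                              seed = 5)
  expect_equal(as.character(a), as.character(b))
  expect_length(a, 10)
})
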