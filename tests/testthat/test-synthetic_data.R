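test_that("spec validation rejects impossible configurations", {
  expect_error(genomeSpec(background_gc = 1.2), "fractions")
  expect_error(genomeSpec(n_genes = 3, n_pte_loci = 10), "gene")
  expect_error(trackSpec("MEL18", replicate_position_jitter_sd = -1), "jitter")
  expect_error(trackSpec("MEL18", nb_dispersion = 0), "dispersion")
  # loci that cannot fit without overlap are refused
  expect_error(generateGenome(genomeSpec(n_chromosomes = 1L,
                                         chrom_length = 150000L,
                                         n_pte_loci = 10L,
                                         n_genes = 10L)),
               "overlap|placed")
})

test_that("a genome without planted loci is plain background", {
  spec <- genomeSpec(n_chromosomes = 1L, chrom_length = 200000L,
                     n_genes = 4L, n_pte_loci = 0L, n_prc2_only_loci = 0L,
                     seed = 3L)
  g <- generateGenome(spec)
  expect_equal(nrow(g$truth$pte), 0)
  gc <- Biostrings::letterFrequency(g$genome[[1]], "GC", as.prob = TRUE)
  expect_lt(abs(gc - spec$background_gc), 0.01)
})

test_that("genome generation is byte-identical under one seed", {
  spec <- genomeSpec(n_chromosomes = 1L, chrom_length = 600000L,
                     n_genes = 6L, n_pte_loci = 3L, n_prc2_only_loci = 1L,
                     seed = 7L)
  a <- generateGenome(spec)
  b <- generateGenome(spec)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(a$truth$pte, b$truth$pte)

  f1 <- withr::local_tempfile(fileext = ".fa")
  f2 <- withr::local_tempfile(fileext = ".fa")
  writeGenome(a$genome, f1); writeGenome(b$genome, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("planted cores carry excess AA/TT di-nucleotides", {
  fx <- smallFixture()
  sim <- fx$sim
  aatt <- function(s) {
    f <- Biostrings::dinucleotideFrequency(Biostrings::DNAString(s),
                                           as.prob = TRUE)
    f[["AA"]] + f[["TT"]]
  }
  cores <- vapply(seq_len(nrow(sim$truth$pte)), function(i)
    aatt(as.character(Biostrings::subseq(
      sim$genome[[sim$truth$pte$chrom[i]]],
      sim$truth$pte$position[i] - 500, sim$truth$pte$position[i] + 499))),
    numeric(1))
  set.seed(101)
  bg <- vapply(1:1000, function(i) {
    ch <- sample(names(sim$genome), 1)
    st <- sample.int(Biostrings::width(sim$genome)[1] - 1000, 1)
    aatt(as.character(Biostrings::subseq(sim$genome[[ch]], st, st + 999)))
  }, numeric(1))
  p <- stats::wilcox.test(cores, bg, alternative = "greater")$p.value
  expect_lt(p, 0.01)
})

test_that("each planted core carries the consensus motif near its centre", {
  fx <- smallFixture()
  sim <- fx$sim
  hits <- vapply(seq_len(nrow(sim$truth$pte)), function(i) {
    s <- Biostrings::subseq(sim$genome[[sim$truth$pte$chrom[i]]],
                            sim$truth$pte$position[i] - 600,
                            sim$truth$pte$position[i] + 600)
    fwd <- Biostrings::countPattern("AAACGAAA", s)
    rev <- Biostrings::countPattern(
      "AAACGAAA", Biostrings::reverseComplement(s))
    fwd + rev
  }, numeric(1))
  expect_true(all(hits >= 1))
})

test_that("tracks conserve normalized mass and respect their seeds", {
  fx <- smallFixture()
  for (nm in names(fx$sim$tracks))
    for (tr in fx$sim$tracks[[nm]]) {
      tot <- sum(vapply(names(seqlengths(tr)),
                        function(ch) sum(trackSignal(tr, ch)), numeric(1)))
      expect_lt(abs(tot / 1e6 - 1), 0.05)
    }

  g <- generateGenome(fx$gspec)
  t1 <- simulateTracks(g, specs = list(MEL18 = trackSpec("MEL18")),
                       seed = 5L, gspec = fx$gspec)
  t2 <- simulateTracks(g, specs = list(MEL18 = trackSpec("MEL18")),
                       seed = 5L, gspec = fx$gspec)
  expect_identical(t1$tracks$MEL18[[1]]@signal, t2$tracks$MEL18[[1]]@signal)
  expect_error(simulateTracks(g, n_replicates = 1L), "two")
})

test_that("zero-amplitude ChIP is indistinguishable from input", {
  fx <- smallFixture()
  g <- generateGenome(fx$gspec)
  tr <- simulateTracks(g, specs = list(
    MEL18 = trackSpec("MEL18", peak_amplitude_range = c(0, 0)),
    INPUT = trackSpec("INPUT")), seed = 9L, gspec = fx$gspec)
  wsum <- function(track) {
    v <- trackSignal(track, "chr1")
    colSums(matrix(v[1:(2000 * floor(length(v) / 2000))], nrow = 2000))
  }
  ks <- stats::ks.test(wsum(tr$tracks$MEL18[[1]]), wsum(tr$tracks$INPUT[[1]]))
  expect_gt(ks$p.value, 0.05)
})

test_that("simulated counts are long-tailed with suppressed PTE targets", {
  fx <- smallFixture()
  truth <- fx$sim$truth
  genes <- simulateCounts(truth, seed = 2L)
  expect_equal(nrow(genes), nrow(truth$genes))
  expect_true(all(genes$count >= 0))

  forced <- simulateCounts(truth, fraction_low = 1.0, seed = 2L)
  ranks <- rank(forced$count)
  targets <- forced$gene_id %in% truth$pte$target_gene
  expect_true(all(ranks[targets] <= nrow(forced) / 2 + 1))

  expect_identical(simulateCounts(truth, seed = 4L),
                   simulateCounts(truth, seed = 4L))
})

test_that("fixtures round-trip through the I/O layer unchanged", {
  fx <- smallFixture()
  dir <- withr::local_tempdir()
  writePTEData(fx$sim, dir)
  sl <- stats::setNames(Biostrings::width(fx$sim$genome),
                        names(fx$sim$genome))
  back <- readBedGraph(file.path(dir, "MEL18_rep1.bedGraph"), sl)
  expect_equal(back@signal, fx$sim$tracks$MEL18[[1]]@signal,
               tolerance = 1e-9)
  regs <- readRegions(file.path(dir, "MEL18_rep1_regions.bed"))
  expect_equal(GenomicRanges::start(regs),
               GenomicRanges::start(fx$sim$regions$MEL18[[1]]))
  genes <- readGeneTable(file.path(dir, "genes.tsv"))
  expect_equal(genes$gene_id, fx$sim$truth$genes$gene_id)
  expect_equal(genes$count, fx$sim$truth$genes$count)
  genome <- readGenome(file.path(dir, "genome.fa"))
  expect_equal(as.character(genome), as.character(fx$sim$genome))
})
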