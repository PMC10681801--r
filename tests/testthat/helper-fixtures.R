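# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

# The reference study-condition fixture: default genome spec (4 x 2 Mb,
# 24 PTE loci, 12 PRC2-only loci, jitter 120 bp), seed 1, plus the full
# pipeline run on the MEL18 replicates.
acceptanceFixture <- function() {
  if (!is.null(.fixture_cache$acc)) return(.fixture_cache$acc)
  gspec <- genomeSpec(seed = 1L)
  specs <- list(MEL18 = trackSpec("MEL18"),
                H3K27me3 = trackSpec("H3K27me3"),
                INPUT = trackSpec("INPUT"))
  sim <- simulatePTEData(gspec, specs = specs, seed = 1L)
  res <- runPTEPipeline(sim$tracks$MEL18[[1]], sim$tracks$MEL18[[2]],
                        sim$regions$MEL18[[1]], sim$regions$MEL18[[2]],
                        genes = sim$truth$genes,
                        k27_regions = sim$regions$H3K27me3[[1]])
  .fixture_cache$acc <- list(gspec = gspec, sim = sim, result = res)
  .fixture_cache$acc
}

# A small, fast fixture for module-level tests.
smallFixture <- function() {
  if (!is.null(.fixture_cache$small)) return(.fixture_cache$small)
  gspec <- genomeSpec(n_chromosomes = 2L, chrom_length = 600000L,
                      n_genes = 10L, n_pte_loci = 6L,
                      n_prc2_only_loci = 2L, seed = 7L)
  specs <- list(MEL18 = trackSpec("MEL18"),
                H3K27me3 = trackSpec("H3K27me3"),
                INPUT = trackSpec("INPUT"))
  sim <- simulatePTEData(gspec, specs = specs, seed = 7L)
  .fixture_cache$small <- list(gspec = gspec, sim = sim)
  .fixture_cache$small
}

# TSS positions with a guaranteed minimum spacing (so promoter-window
# H3K27me3 marks of neighbouring genes never bleed into each other)
spacedTSS <- function(ng, slot = 21000L, jitter = 15000L)
  as.integer(seq(5000L, by = slot, length.out = ng) +
               sample.int(jitter, ng, replace = TRUE))

randomSeqs <- function(n, len, probs = rep(0.25, 4))
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE, prob = probs),
          collapse = ""), character(1))

randomTrack <- function(len = 500, chrom = "chr1", zero_runs = TRUE) {
  v <- stats::rpois(len, 2) * stats::runif(len)
  if (zero_runs) v[sample.int(len, len / 3)] <- 0
  CoverageTrack(stats::setNames(list(v), chrom))
}

randomRegions <- function(n, chrom_len = 100000, min_w = 50, max_w = 2000,
                          chrom = "chr1") {
  if (n == 0) return(GenomicRanges::GRanges())
  w <- sample(min_w:max_w, n, replace = TRUE)
  s <- sample.int(chrom_len - max_w, n, replace = TRUE)
  GenomicRanges::sort(GenomicRanges::GRanges(
    chrom, IRanges::IRanges(s, width = w)))
}
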