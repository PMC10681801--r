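## Bound-region scoring and replicate concordance.
##
## A significantly enriched region gets a binding score: the largest sum
## of signal within a fixed-width window (default 1000 bp) fully inside
## the region -- the "summit window". Regions are carried forward only
## when the summit window is corroborated by the other replicate, and
## "standalone" PRC2 regions are SUZ12+H3K27me3 regions far from any
## MEL18 region.

#' Parameters for region-level scoring and filtering
#'
#' @param summit_window_bp width of the summit window (bp).
#' @param group_gap_bp regions closer than this are grouped for peak
#'   refinement (bp).
#' @param standalone_distance_bp minimum gap from any MEL18 region for a
#'   PRC2 region to count as standalone. Two conventions are in use:
#'   100 kb (the strict definition) and 10 kb (the co-binding census);
#'   both are the same filter with a different distance.
#' @param min_region_len minimum region length (bp) for the stand-in
#'   caller.
#' @return a named list of validated parameters.
#' @export
regionParams <- function(summit_window_bp = 1000L, group_gap_bp = 100000L,
                         standalone_distance_bp = 100000L,
                         min_region_len = 1000L) {
  p <- list(summit_window_bp = as.integer(summit_window_bp),
            group_gap_bp = as.integer(group_gap_bp),
            standalone_distance_bp = as.integer(standalone_distance_bp),
            min_region_len = as.integer(min_region_len))
  if (any(unlist(p) <= 0)) stop("all region parameters must be positive")
  p
}

#' Score regions by their maximal summit window
#'
#' For each region, finds the `summit_window_bp`-wide window fully inside
#' the region with the largest signal sum. Ties go to the leftmost
#' window. Regions shorter than the window use the whole region as their
#' summit window.
#'
#' @param regions `GRanges` of enriched regions (within track bounds).
#' @param track a [CoverageTrack-class].
#' @param params from [regionParams()].
#' @return `regions` with metadata columns `score` (summit-window signal
#'   sum), `summitStart`, `summitEnd` (1-based inclusive).
#' @export
summitScore <- function(regions, track, params = regionParams()) {
  w <- params$summit_window_bp
  sl <- seqlengths(track)
  n <- length(regions)
  score <- numeric(n); sstart <- integer(n); send <- integer(n)
  for (i in seq_len(n)) {
    chrom <- as.character(seqnames(regions)[i])
    s <- start(regions)[i]; e <- end(regions)[i]
    if (e < s) stop("zero-length region")
    if (!chrom %in% names(sl) || s < 1 || e > sl[[chrom]])
      stop("region ", i, " outside track bounds")
    v <- track@signal[[chrom]][s:e]
    len <- length(v)
    if (len <= w) {
      score[i] <- sum(v); sstart[i] <- s; send[i] <- e
    } else {
      cs <- cumsum(c(0, v))
      sums <- cs[(w + 1):(len + 1)] - cs[1:(len - w + 1)]
      k <- which.max(sums)  # leftmost maximum
      score[i] <- sums[k]
      sstart[i] <- s + k - 1L
      send[i] <- sstart[i] + w - 1L
    }
  }
  mcols(regions)$score <- score
  mcols(regions)$summitStart <- sstart
  mcols(regions)$summitEnd <- send
  regions
}

#' Keep regions whose summit window is corroborated by the replicate
#'
#' A region from one replicate is kept iff its summit window overlaps
#' (by at least 1 bp) a significantly enriched region of the other
#' replicate. The kept sets of both replicates, plus their merged union,
#' are returned; merged regions are scored on both replicate tracks.
#'
#' @param regions1,regions2 per-replicate enriched regions (`GRanges`).
#' @param track1,track2 per-replicate [CoverageTrack-class] objects.
#' @param params from [regionParams()].
#' @return list with elements `rep1`, `rep2` (kept, summit-scored on own
#'   track) and `merged` (union of kept loci, with `score_rep1`,
#'   `score_rep2` summit scores).
#' @export
concordantRegions <- function(regions1, regions2, track1, track2,
                              params = regionParams()) {
  s1 <- summitScore(regions1, track1, params)
  s2 <- summitScore(regions2, track2, params)
  summitGR <- function(s)
    GRanges(seqnames(s), IRanges(mcols(s)$summitStart, mcols(s)$summitEnd))
  keep1 <- IRanges::overlapsAny(summitGR(s1), regions2)
  keep2 <- IRanges::overlapsAny(summitGR(s2), regions1)
  merged <- GenomicRanges::reduce(suppressWarnings(
    c(granges(s1[keep1]), granges(s2[keep2]))))
  if (length(merged)) {
    m1 <- summitScore(merged, track1, params)
    m2 <- summitScore(merged, track2, params)
    mcols(merged)$score_rep1 <- mcols(m1)$score
    mcols(merged)$score_rep2 <- mcols(m2)$score
  }
  list(rep1 = s1[keep1], rep2 = s2[keep2], merged = merged)
}

#' Group regions separated by no more than a gap
#'
#' Single-linkage chaining: consecutive regions on the same chromosome
#' whose edge-to-edge gap is at most `group_gap_bp` join the same group.
#' Groups never span chromosomes.
#'
#' @param regions sorted `GRanges`.
#' @param params from [regionParams()].
#' @return `regions` with an integer `group` metadata column.
#' @export
groupRegions <- function(regions, params = regionParams()) {
  if (length(regions) == 0) {
    mcols(regions)$group <- integer(0)
    return(regions)
  }
  regions <- GenomicRanges::sort(regions, ignore.strand = TRUE)
  chrom <- as.character(seqnames(regions))
  n <- length(regions)
  gap <- rep(Inf, n)
  if (n > 1) {
    same <- chrom[-1] == chrom[-n]
    # running max of ends handles nested regions; reset per chromosome
    run_end <- end(regions)
    for (i in 2:n)
      if (same[i - 1]) {
        gap[i] <- max(0, start(regions)[i] - run_end[i - 1] - 1)
        run_end[i] <- max(run_end[i], run_end[i - 1])
      }
  }
  mcols(regions)$group <- cumsum(gap > params$group_gap_bp)
  regions
}

#' Gap distance between a query and its nearest subject region
#'
#' Edge-to-edge gap in bp; overlapping or adjacent regions have distance
#' 0; `Inf` when the subject has no region on the query's chromosome.
#' @param query,subject `GRanges`.
#' @return numeric vector, one distance per query region.
#' @export
nearestRegionDistance <- function(query, subject) {
  out <- rep(Inf, length(query))
  if (length(subject) == 0 || length(query) == 0) return(out)
  hit <- GenomicRanges::distanceToNearest(query, subject,
                                          ignore.strand = TRUE)
  out[S4Vectors::queryHits(hit)] <- mcols(hit)$distance
  out
}

#' Standalone PRC2 regions: active PRC2 far from any PRC1 region
#'
#' Returns SUZ12 regions that overlap an H3K27me3 region (catalytically
#' active PRC2) and whose gap to the nearest MEL18 region exceeds
#' `params$standalone_distance_bp`. Use 100 kb for the strict standalone
#' set and 10 kb for the PRC1-free co-binding census.
#'
#' @param suz12_regions,k27_regions,mel18_regions `GRanges`.
#' @param params from [regionParams()].
#' @return the qualifying subset of `suz12_regions`, with a
#'   `mel18_distance` metadata column.
#' @export
standalonePRC2Regions <- function(suz12_regions, k27_regions, mel18_regions,
                                  params = regionParams()) {
  active <- IRanges::overlapsAny(suz12_regions, k27_regions)
  d <- nearestRegionDistance(suz12_regions, mel18_regions)
  out <- suz12_regions[active & d > params$standalone_distance_bp]
  mcols(out)$mel18_distance <- d[active & d > params$standalone_distance_bp]
  out
}

#' Stand-in enriched-region caller (Poisson window test)
#'
#' A deliberately simple substitute for an external broad-peak caller so
#' the pipeline is self-contained: fixed non-overlapping windows are
#' tested for enrichment of the ChIP track over the input track with a
#' Poisson upper-tail test, Benjamini-Hochberg corrected; significant
#' windows are merged and short regions dropped. This is plumbing for
#' fixtures, not a model of fragment shifts or local background
#' hierarchies.
#'
#' @param chip,input [CoverageTrack-class] tracks on the same genome.
#' @param window window size in bp (tiled, non-overlapping).
#' @param qvalue BH-corrected significance cutoff.
#' @param count_scale factor converting normalized signal sums to
#'   pseudo-counts before the Poisson test.
#' @param merge_gap merge significant windows closer than this (bp).
#' @param params from [regionParams()]; supplies `min_region_len`.
#' @return `GRanges` of enriched regions.
#' @export
callEnrichedRegions <- function(chip, input, window = 200L, qvalue = 0.05,
                                count_scale = 1, merge_gap = 200L,
                                params = regionParams()) {
  stopifnot(identical(seqlengths(chip), seqlengths(input)))
  tile_sums <- function(v, w) {
    n <- length(v)
    nt <- ceiling(n / w)
    idx <- rep(seq_len(nt), each = w, length.out = n)
    as.numeric(tapply(v, idx, sum))
  }
  all_gr <- list()
  tot_chip <- sum(vapply(chip@signal, sum, numeric(1)))
  tot_input <- sum(vapply(input@signal, sum, numeric(1)))
  scale_io <- if (tot_input > 0) tot_chip / tot_input else 1
  for (chrom in names(chip@signal)) {
    x <- tile_sums(chip@signal[[chrom]], window) * count_scale
    lam <- tile_sums(input@signal[[chrom]], window) * count_scale * scale_io
    lam <- pmax(lam, mean(lam))  # floor at genome average, avoid lambda 0
    p <- stats::ppois(ceiling(x) - 1, lam, lower.tail = FALSE)
    q <- stats::p.adjust(p, method = "BH")
    sig <- which(q < qvalue)
    if (length(sig)) {
      st <- (sig - 1L) * window + 1L
      en <- pmin(sig * window, length(chip@signal[[chrom]]))
      all_gr[[chrom]] <- GRanges(chrom, IRanges(st, en))
    }
  }
  if (!length(all_gr)) return(GRanges())
  out <- GenomicRanges::reduce(suppressWarnings(do.call(c, unname(all_gr))),
                               min.gapwidth = merge_gap + 1L)
  out[width(out) >= params$min_region_len]
}
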