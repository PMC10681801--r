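## Discrete peak refinement.
##
## Within each group of bound regions the signal of every region is
## smoothed by local polynomial regression (loess, span 0.1), local
## maxima/valleys are located, each extremum is scored by the mean
## smoothed signal over nine positions, and peaks are kept when they
## reach 50-60% of the group's highest peak and are separated by valleys
## deeper than 30-35% of the flanking peak scores. Only peaks surviving
## every parameter combination are retained; replicate peak lists are
## then paired by mutual nearest neighbours, each pair giving a
## consensus position (median), a location accuracy (half distance) and
## a final score (9-bp raw-signal sum).

#' Smoothing parameters
#' @param span fraction of the positions in a stretch used for each
#'   local fit (loess span).
#' @param degree local polynomial degree, 1 or 2.
#' @param bin_size signal is averaged into bins of this many bp before
#'   fitting; 1 = off.
#' @param auto_bin_above stretches longer than this many positions are
#'   automatically binned to 10 bp as a runtime guard.
#' @return named list of validated parameters.
#' @export
smoothParams <- function(span = 0.1, degree = 2L, bin_size = 1L,
                         auto_bin_above = 200000L) {
  if (span <= 0 || span > 1) stop("span must be in (0, 1]")
  if (!degree %in% c(1L, 2L)) stop("degree must be 1 or 2")
  list(span = span, degree = as.integer(degree),
       bin_size = as.integer(bin_size),
       auto_bin_above = as.integer(auto_bin_above))
}

#' Peak/valley filtering parameter grid
#' @param peak_fraction_grid minimum peak score as a fraction of the
#'   highest peak in the group; a peak must pass every value.
#' @param valley_depth_grid required valley depth as a fraction of the
#'   flanking peak scores.
#' @param match_radius_bp two peaks from different grid combinations are
#'   the same peak if within this distance.
#' @return named list.
#' @export
filterParams <- function(peak_fraction_grid = c(0.50, 0.55, 0.60),
                         valley_depth_grid = c(0.30, 0.35),
                         match_radius_bp = 50L) {
  if (any(peak_fraction_grid <= 0 | peak_fraction_grid >= 1) ||
      any(valley_depth_grid <= 0 | valley_depth_grid >= 1))
    stop("grid fractions must be in (0, 1)")
  list(peak_fraction_grid = sort(peak_fraction_grid),
       valley_depth_grid = sort(valley_depth_grid),
       match_radius_bp = as.integer(match_radius_bp))
}

#' Loess-smooth a signal stretch
#'
#' Locally weighted polynomial regression (tricube weights, no
#' robustness iterations) over one contiguous stretch of per-bp signal.
#' The effective span is widened when `span * length` would give fewer
#' points than the polynomial needs. Long stretches are pre-averaged
#' into bins and the fit interpolated back to full length.
#'
#' @param y numeric vector of per-bp signal (length >= 10).
#' @param params from [smoothParams()].
#' @return numeric vector, same length as `y`.
#' @export
smoothSignal <- function(y, params = smoothParams()) {
  n <- length(y)
  if (n < 10) stop("stretch too short to smooth (", n, " < 10 positions)")
  bin <- params$bin_size
  if (bin == 1L && n > params$auto_bin_above) bin <- 10L
  if (bin > 1L) {
    nb <- ceiling(n / bin)
    idx <- rep(seq_len(nb), each = bin, length.out = n)
    yb <- as.numeric(tapply(y, idx, mean))
    xb <- as.numeric(tapply(seq_len(n), idx, mean))
    sm <- smoothCore(xb, yb, params$span, params$degree)
    out <- stats::approx(xb, sm, xout = seq_len(n), rule = 2)$y
    return(out)
  }
  smoothCore(seq_len(n), y, params$span, params$degree)
}

smoothCore <- function(x, y, span, degree) {
  n <- length(y)
  span_eff <- max(span, (degree + 2) / n)
  fit <- stats::loess(y ~ x, span = span_eff, degree = degree,
                      family = "gaussian",
                      control = stats::loess.control(
                        surface = "interpolate", statistics = "approximate"))
  as.numeric(stats::fitted(fit))
}

#' Locate local maxima and minima
#'
#' Strict local extrema of a smoothed vector; plateaus (runs of equal
#' values) collapse to their midpoint. Each extremum is scored by the
#' mean of the vector over nine positions centred on it (truncated at
#' the edges). Peaks and valleys alternate by construction.
#'
#' @param y numeric vector (length >= 3), typically [smoothSignal()]
#'   output.
#' @return data.frame with columns `pos` (1-based index), `kind`
#'   ("peak"/"valley") and `score` (9-position mean).
#' @export
findExtrema <- function(y) {
  n <- length(y)
  if (n < 3) stop("need at least 3 positions")
  r <- rle(y)
  k <- length(r$values)
  empty <- data.frame(pos = integer(0), kind = character(0),
                      score = numeric(0))
  if (k < 3) return(empty)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  i <- 2:(k - 1)
  v <- r$values
  is_peak <- v[i] > v[i - 1] & v[i] > v[i + 1]
  is_valley <- v[i] < v[i - 1] & v[i] < v[i + 1]
  sel <- which(is_peak | is_valley)
  if (!length(sel)) return(empty)
  runs <- i[sel]
  pos <- as.integer(floor((starts[runs] + ends[runs]) / 2))
  kind <- ifelse(is_peak[sel], "peak", "valley")
  score <- vapply(pos, function(p) {
    mean(y[max(1, p - 4):min(n, p + 4)])
  }, numeric(1))
  data.frame(pos = pos, kind = kind, score = score)
}

#' Filter peaks by relative amplitude and valley depth
#'
#' Two-stage rule over the extrema of one region group:
#' \enumerate{
#'   \item keep peaks scoring at least `peak_fraction` of the highest
#'     peak score in the group;
#'   \item walk the kept peaks left to right and merge neighbours unless
#'     some valley between them is deep enough: a valley separates two
#'     peaks when its score is at most `(1 - valley_depth)` times the
#'     weaker flanking peak's score. A merged cluster is represented by
#'     its highest-scoring member.
#' }
#' Peaks with different `region` ids (discontiguous stretches of one
#' group) are never merged.
#'
#' @param extrema data.frame from [findExtrema()] (columns `pos`,
#'   `kind`, `score`, optional `region` id).
#' @param peak_fraction fraction of the maximum peak score required.
#' @param valley_depth required fractional valley depth.
#' @param group_max optional group-level maximum peak score, when the
#'   group spans several `extrema` data frames.
#' @return data.frame of kept peaks (`pos`, `score`).
#' @export
filterPeaks <- function(extrema, peak_fraction, valley_depth,
                        group_max = NULL) {
  pk <- extrema[extrema$kind == "peak", , drop = FALSE]
  if (nrow(pk) == 0) return(data.frame(pos = integer(0), score = numeric(0)))
  if (is.null(group_max)) group_max <- max(pk$score)
  if (is.null(extrema$region)) extrema$region <- 1L
  pk <- extrema[extrema$kind == "peak" &
                  extrema$score >= peak_fraction * group_max, , drop = FALSE]
  if (nrow(pk) == 0) return(data.frame(pos = integer(0), score = numeric(0)))
  pk <- pk[order(pk$pos), , drop = FALSE]
  va <- extrema[extrema$kind == "valley", , drop = FALSE]
  # sequential merge: cluster representative = highest member, rightmost
  # member governs the next valley lookup
  rep_pos <- pk$pos[1]; rep_score <- pk$score[1]
  last_pos <- pk$pos[1]; last_region <- pk$region[1]
  out_pos <- integer(0); out_score <- numeric(0)
  if (nrow(pk) > 1) for (j in 2:nrow(pk)) {
    p <- pk$pos[j]; s <- pk$score[j]; rg <- pk$region[j]
    between <- va$score[va$pos > last_pos & va$pos < p & va$region == rg &
                          last_region == rg]
    separated <- if (rg != last_region) TRUE
      else if (!length(between)) FALSE
      else min(between) <= (1 - valley_depth) * min(rep_score, s)
    if (separated) {
      out_pos <- c(out_pos, rep_pos); out_score <- c(out_score, rep_score)
      rep_pos <- p; rep_score <- s
    } else if (s > rep_score) {
      rep_pos <- p; rep_score <- s
    }
    last_pos <- p; last_region <- rg
  }
  data.frame(pos = c(out_pos, rep_pos), score = c(out_score, rep_score))
}

#' Peaks kept at every filter-grid combination
#'
#' Runs [filterPeaks()] for each (peak_fraction, valley_depth)
#' combination and keeps only peaks found at all of them; peaks from
#' different combinations are identified when within
#' `match_radius_bp`. Reported positions come from the strictest
#' combination (largest peak fraction, then largest valley depth).
#'
#' @param extrema extrema of one group (see [filterPeaks()]).
#' @param fparams from [filterParams()].
#' @param group_max see [filterPeaks()].
#' @return data.frame of consensus-kept peaks (`pos`, `score`).
#' @export
consensusOverGrid <- function(extrema, fparams = filterParams(),
                              group_max = NULL) {
  grid <- expand.grid(pf = fparams$peak_fraction_grid,
                      vd = fparams$valley_depth_grid)
  # strictest last-sorted: order so the strictest is first
  grid <- grid[order(-grid$pf, -grid$vd), ]
  kept <- lapply(seq_len(nrow(grid)), function(i)
    filterPeaks(extrema, grid$pf[i], grid$vd[i], group_max = group_max))
  base <- kept[[1]]
  if (nrow(base) == 0) return(base)
  ok <- vapply(seq_len(nrow(base)), function(i) {
    all(vapply(kept[-1], function(k)
      nrow(k) > 0 && min(abs(k$pos - base$pos[i])) <= fparams$match_radius_bp,
      logical(1)))
  }, logical(1))
  base[ok, , drop = FALSE]
}

#' Refine one replicate track to discrete peak positions
#'
#' Applies smoothing, extrema detection and grid-consensus filtering to
#' every region of every group. The relative-amplitude threshold is
#' taken over all peaks of a group; smoothing and valley logic operate
#' within each contiguous region.
#'
#' @param regions grouped regions from [groupRegions()] (metadata column
#'   `group`).
#' @param track a [CoverageTrack-class].
#' @param sparams from [smoothParams()].
#' @param fparams from [filterParams()].
#' @return `GRanges` of width-1 peak positions with metadata `score`
#'   (9-position mean of smoothed signal) and `group`.
#' @export
refinePeaks <- function(regions, track, sparams = smoothParams(),
                        fparams = filterParams()) {
  stopifnot(!is.null(mcols(regions)$group))
  out <- list()
  for (g in unique(mcols(regions)$group)) {
    sub <- regions[mcols(regions)$group == g]
    chrom <- as.character(seqnames(sub))[1]
    ex_list <- lapply(seq_along(sub), function(i) {
      v <- trackSignal(track, chrom)[start(sub)[i]:end(sub)[i]]
      ex <- findExtrema(smoothSignal(v, sparams))
      if (nrow(ex)) {
        ex$pos <- ex$pos + start(sub)[i] - 1L
        ex$region <- i
      }
      ex
    })
    ex <- do.call(rbind, ex_list[vapply(ex_list, nrow, integer(1)) > 0])
    if (is.null(ex) || nrow(ex) == 0) next
    pk <- consensusOverGrid(ex, fparams)
    if (nrow(pk))
      out[[as.character(g)]] <- GRanges(chrom, IRanges(pk$pos, width = 1L),
                                        score = pk$score, group = g)
  }
  if (!length(out)) return(GRanges())
  GenomicRanges::sort(suppressWarnings(do.call(c, unname(out))),
                      ignore.strand = TRUE)
}

#' Pair replicate peak lists by mutual nearest neighbours
#'
#' For each chromosome, a peak of replicate 1 and a peak of replicate 2
#' are paired when each is the other's nearest peak (ties to the
#' leftmost) and they are within `max_distance`. Each pair yields a
#' consensus position (median of the two, rounded down) and an accuracy
#' (half the distance). Pairing is one-to-one; unmatched peaks are
#' returned, not dropped silently.
#'
#' @param peaks1,peaks2 `GRanges` of width-1 peak positions.
#' @param max_distance maximum pairing distance in bp (default
#'   unbounded; the pipeline restricts pairing to region groups).
#' @return list with `pairs` (a [ConsensusPeaks-class] with
#'   `posRep1`/`posRep2`) and `unmatched1`, `unmatched2` (`GRanges`).
#' @export
pairReplicates <- function(peaks1, peaks2, max_distance = Inf) {
  chroms <- union(as.character(seqnames(peaks1)),
                  as.character(seqnames(peaks2)))
  pc <- pa <- p1 <- p2 <- numeric(0)
  chlab <- character(0)
  um1 <- um2 <- list()
  for (chrom in chroms) {
    a <- sort(start(peaks1[seqnames(peaks1) == chrom]))
    b <- sort(start(peaks2[seqnames(peaks2) == chrom]))
    if (!length(a) || !length(b)) {
      if (length(a)) um1[[chrom]] <- GRanges(chrom, IRanges(a, width = 1L))
      if (length(b)) um2[[chrom]] <- GRanges(chrom, IRanges(b, width = 1L))
      next
    }
    nn_ab <- vapply(a, function(p) which.min(abs(b - p)), integer(1))
    nn_ba <- vapply(b, function(p) which.min(abs(a - p)), integer(1))
    mutual <- which(nn_ba[nn_ab] == seq_along(a) &
                      abs(b[nn_ab] - a) <= max_distance)
    if (length(mutual)) {
      ai <- a[mutual]; bi <- b[nn_ab[mutual]]
      pc <- c(pc, floor((ai + bi) / 2))
      pa <- c(pa, abs(ai - bi) / 2)
      p1 <- c(p1, ai); p2 <- c(p2, bi)
      chlab <- c(chlab, rep(chrom, length(mutual)))
    }
    rest1 <- setdiff(seq_along(a), mutual)
    rest2 <- setdiff(seq_along(b), if (length(mutual)) nn_ab[mutual] else integer(0))
    if (length(rest1)) um1[[chrom]] <- GRanges(chrom, IRanges(a[rest1], width = 1L))
    if (length(rest2)) um2[[chrom]] <- GRanges(chrom, IRanges(b[rest2], width = 1L))
  }
  pairs <- if (length(pc))
    ConsensusPeaks(chlab, as.integer(pc), pa, posRep1 = p1, posRep2 = p2)
  else new("ConsensusPeaks", GRanges())
  mkgr <- function(l)
    if (length(l)) suppressWarnings(do.call(c, unname(l))) else GRanges()
  list(pairs = pairs, unmatched1 = mkgr(um1), unmatched2 = mkgr(um2))
}

#' Score consensus peaks and assign quartiles
#'
#' The final peak score is the sum of raw (unsmoothed) signal within a
#' 9-bp window centred on the consensus position, computed on each
#' replicate track; the replicate mean ranks the peaks. Quartiles are
#' rank-based with Q4 the highest quartile, sizes differing by at most
#' one, and ties broken by genomic position (stable).
#'
#' @param peaks a [ConsensusPeaks-class].
#' @param track1,track2 replicate [CoverageTrack-class] objects.
#' @return `peaks` with `scoreRep1`, `scoreRep2`, `score`, `quartile`
#'   and logical `edgeTruncated` metadata columns.
#' @export
scorePeaks <- function(peaks, track1, track2) {
  n <- length(peaks)
  win9 <- function(track, chrom, pos) {
    v <- trackSignal(track, chrom)
    sum(v[max(1, pos - 4):min(length(v), pos + 4)])
  }
  s1 <- s2 <- numeric(n); trunc <- logical(n)
  for (i in seq_len(n)) {
    chrom <- as.character(seqnames(peaks)[i])
    pos <- start(peaks)[i]
    s1[i] <- win9(track1, chrom, pos)
    s2[i] <- win9(track2, chrom, pos)
    trunc[i] <- pos <= 4 || pos > length(trackSignal(track1, chrom)) - 4
  }
  if (any(trunc))
    warning(sum(trunc), " peak(s) within 4 bp of a chromosome edge; ",
            "9-bp window truncated")
  mcols(peaks)$scoreRep1 <- s1
  mcols(peaks)$scoreRep2 <- s2
  sc <- (s1 + s2) / 2
  mcols(peaks)$score <- sc
  mcols(peaks)$edgeTruncated <- trunc
  if (n) {
    ord <- order(sc, seq_len(n))  # ties: earlier position = lower rank
    q <- integer(n)
    q[ord] <- ceiling(seq_len(n) * 4 / n)
    mcols(peaks)$quartile <- factor(paste0("Q", q),
                                    levels = paste0("Q", 1:4))
  }
  peaks
}
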