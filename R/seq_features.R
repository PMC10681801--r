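## DNA sequence-feature statistics around peaks: di-nucleotide
## difference maps, oriented homopolymer tract profiles, CpG windows,
## PWM motif-centrality profiles and generic coverage metaprofiles.
## All sliding statistics use step 1 and report values at window
## centres as offsets relative to the sequence/peak centre.

DINUCS <- paste0(rep(c("A", "C", "G", "T"), each = 4),
                 c("A", "C", "G", "T"))

seqCodes <- function(seq) {
  # A=1 C=2 G=3 T=4, NA otherwise (N etc.)
  x <- strsplit(toupper(as.character(seq)), "")[[1]]
  c(A = 1L, C = 2L, G = 3L, T = 4L)[x]
}

slideSum <- function(x, w) {
  # sums of consecutive windows of length w (NA treated as 0)
  x[is.na(x)] <- 0
  cs <- cumsum(c(0, x))
  cs[(w + 1):(length(x) + 1)] - cs[1:(length(x) - w + 1)]
}

centerOffsets <- function(n_windows, L, window) {
  # offset of each window centre relative to the sequence centre
  (seq_len(n_windows) + (window - 1) / 2) - (L + 1) / 2
}

#' Di-nucleotide frequency difference map
#'
#' For each 100-bp sliding window (step 1) and each of the 16
#' di-nucleotides, the mean frequency over a set of peak-centred
#' sequences minus the mean over a control set. Frequencies at each
#' window are relative to the valid (non-N) di-nucleotide count, so the
#' 16 rows of either set sum to 1 per window before subtraction.
#'
#' @param sequences `DNAStringSet` (or character) of equal-length
#'   peak-centred sequences.
#' @param controls control sequences of the same length.
#' @param window sliding window width in bp.
#' @return list of class `DinucMap`: `offsets` (window centres relative
#'   to the sequence centre), `diff` (16 x windows matrix), and the two
#'   per-set frequency matrices `freq_regions`, `freq_controls`.
#' @export
dinucleotideMap <- function(sequences, controls, window = 100L) {
  fr <- dinucFrequencies(sequences, window)
  fc <- dinucFrequencies(controls, window)
  stopifnot(identical(dim(fr$freq), dim(fc$freq)))
  structure(list(offsets = fr$offsets, diff = fr$freq - fc$freq,
                 freq_regions = fr$freq, freq_controls = fc$freq,
                 window = window),
            class = "DinucMap")
}

dinucFrequencies <- function(sequences, window) {
  seqs <- as.character(sequences)
  L <- unique(nchar(seqs))
  if (length(L) != 1) stop("sequences must all have the same length")
  if (window > L) stop("window longer than sequences")
  counts <- matrix(0, nrow = 16, ncol = L - 1, dimnames = list(DINUCS, NULL))
  for (s in seqs) {
    code <- seqCodes(s)
    c1 <- code[-L]; c2 <- code[-1]
    ok <- which(!is.na(c1) & !is.na(c2))
    if (length(ok)) {
      lin <- (ok - 1L) * 16L + (c1[ok] - 1L) * 4L + c2[ok]
      tab <- tabulate(lin, nbins = 16L * (L - 1L))
      counts <- counts + matrix(tab, nrow = 16)
    }
  }
  wd <- window - 1L  # dinucleotide starts inside a window of `window` bases
  nw <- (L - 1) - wd + 1
  num <- t(apply(counts, 1, slideSum, w = wd))
  den <- slideSum(colSums(counts), wd)
  freq <- sweep(num, 2, den, "/")
  freq[, den == 0] <- NA  # all-N windows masked
  list(offsets = centerOffsets(nw, L, window), freq = freq)
}

#' Oriented homopolymer tract profile
#'
#' Counts occurrences of a short tract (overlapping matches included)
#' per sliding window across peak-centred sequences, after orienting
#' every sequence so its target gene lies to the right (sequences whose
#' gene is on the left are reverse-complemented). The mean over
#' sequences is reported per window. Control sequences, when given, are
#' profiled without orientation.
#'
#' @param sequences equal-length peak-centred sequences.
#' @param gene_side character vector, `"left"`/`"right"` per sequence;
#'   sequences with any other value are skipped with a warning.
#' @param tract tract string, e.g. `"AAAAA"`.
#' @param window sliding window width (bp).
#' @param controls optional control sequences (unoriented).
#' @return list of class `PositionProfile`: `offsets`, `values` (mean
#'   tract count per window), `n_regions`, `feature`, and `control`
#'   (profile list or NULL).
#' @export
polyTractProfile <- function(sequences, gene_side, tract = "AAAAA",
                             window = 100L, controls = NULL) {
  seqs <- as.character(sequences)
  stopifnot(length(gene_side) == length(seqs))
  ok <- gene_side %in% c("left", "right")
  if (!all(ok)) {
    warning(sum(!ok), " sequence(s) with unknown gene side skipped")
    seqs <- seqs[ok]; gene_side <- gene_side[ok]
  }
  if (!length(seqs)) stop("no oriented sequences to profile")
  oriented <- ifelse(
    gene_side == "left",
    as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs))),
    seqs)
  prof <- tractWindowProfile(oriented, tract, window)
  ctrl <- if (!is.null(controls))
    tractWindowProfile(as.character(controls), tract, window)
  structure(c(prof, list(feature = tract, control = ctrl)),
            class = "PositionProfile")
}

tractWindowProfile <- function(seqs, tract, window) {
  L <- unique(nchar(seqs))
  if (length(L) != 1) stop("sequences must all have the same length")
  k <- nchar(tract)
  hits <- numeric(L - k + 1)
  pat <- Biostrings::DNAString(tract)
  for (s in seqs) {
    m <- Biostrings::matchPattern(pat, Biostrings::DNAString(s))
    st <- BiocGenerics::start(m)
    if (length(st)) hits[st] <- hits[st] + 1
  }
  wt <- window - k + 1L  # tract starts inside a window of `window` bases
  if (wt < 1) stop("window shorter than the tract")
  nw <- (L - k + 1) - wt + 1
  values <- slideSum(hits / length(seqs), wt)
  list(offsets = centerOffsets(nw, L, window), values = values,
       n_regions = length(seqs), window = window)
}

#' CpG count in sliding windows
#'
#' Number of CpG (the di-nucleotide `CG`) occurrences per sliding
#' window along one sequence.
#'
#' @param sequence a `DNAString`/character sequence.
#' @param window window width in bp.
#' @return list of class `PositionProfile` with `offsets` (window
#'   centres relative to the sequence centre) and `values`.
#' @export
cpgWindowCount <- function(sequence, window = 100L) {
  code <- seqCodes(sequence)
  L <- length(code)
  if (window > L) stop("window longer than sequence")
  is_cg <- as.numeric(code[-L] == 2L & code[-1] == 3L)
  wd <- window - 1L
  nw <- (L - 1) - wd + 1
  structure(list(offsets = centerOffsets(nw, L, window),
                 values = slideSum(is_cg, wd),
                 n_regions = 1L, feature = "CpG", window = window),
            class = "PositionProfile")
}

#' Build a position weight matrix from a consensus string
#'
#' @param consensus DNA string, e.g. `"AAACGAAA"`.
#' @param match_prob probability mass on the consensus base at each
#'   position; the remainder is spread over the other three bases.
#' @param background background base frequencies (A, C, G, T).
#' @param threshold minimum log2-odds score for a match.
#' @return list of class `PWM`: `mat` (4 x length probability matrix,
#'   columns sum to 1), `background`, `threshold`.
#' @export
consensusPWM <- function(consensus, match_prob = 0.94,
                         background = rep(0.25, 4), threshold = 5.0) {
  code <- seqCodes(consensus)
  if (anyNA(code)) stop("consensus must be ACGT only")
  if (length(code) < 4) stop("motif must be at least 4 bp")
  mat <- matrix((1 - match_prob) / 3, nrow = 4, ncol = length(code),
                dimnames = list(c("A", "C", "G", "T"), NULL))
  mat[cbind(code, seq_along(code))] <- match_prob
  structure(list(mat = mat, background = stats::setNames(background,
                                                         c("A", "C", "G", "T")),
                 threshold = threshold),
            class = "PWM")
}

#' Swap two columns of a PWM (scrambled-motif control)
#'
#' @param pwm a [consensusPWM()] object.
#' @param i,j column indices to swap.
#' @return a `PWM` with the two positions exchanged.
#' @export
swapPWMColumns <- function(pwm, i, j) {
  pwm$mat[, c(i, j)] <- pwm$mat[, c(j, i)]
  pwm
}

pwmScores <- function(code, lodds) {
  # log-odds score of the motif starting at every position; NA where Ns
  k <- ncol(lodds)
  n <- length(code)
  if (n < k) return(numeric(0))
  sc <- numeric(n - k + 1)
  na <- logical(n - k + 1)
  for (p in seq_len(k)) {
    idx <- code[p:(n - k + p)]
    na <- na | is.na(idx)
    contrib <- lodds[, p][idx]
    contrib[is.na(contrib)] <- 0
    sc <- sc + contrib
  }
  sc[na] <- -Inf
  sc
}

bestPWMMatch <- function(seq, pwm) {
  # best-scoring match start (plus-strand coordinates of the hit's left
  # edge); ties prefer the plus strand, then the leftmost position
  lodds <- log2(sweep(pwm$mat, 1, pwm$background, "/"))
  code <- seqCodes(seq)
  fwd <- pwmScores(code, lodds)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  rev_sc <- rev(pwmScores(seqCodes(rc), lodds))  # align to plus coords
  best <- max(c(fwd, rev_sc), -Inf)
  if (!is.finite(best) || best < pwm$threshold) return(NA_integer_)
  ties_f <- which(fwd == best)
  if (length(ties_f)) return(ties_f[1])
  which(rev_sc == best)[1]
}

#' Motif-centrality profiles per peak quartile
#'
#' For each peak-centred sequence the single best-scoring PWM match
#' (either strand, log2-odds against the background, at or above the
#' threshold) contributes a count at its start position. Counts are
#' aggregated within each score quartile, normalized to that quartile's
#' total number of matches, and smoothed by a centred rolling mean
#' (partial windows at the edges), so each unsmoothed quartile profile
#' sums to 1 when the quartile has any match.
#'
#' @param sequences equal-length peak-centred sequences.
#' @param pwm a [consensusPWM()] object.
#' @param quartiles factor/character of quartile labels per sequence
#'   (e.g. from [peakQuartile()]); a single common label is allowed.
#' @param rolling rolling-mean width in positions.
#' @return list of class `MotifCentrality`: `offsets` (match starts
#'   relative to the sequence centre), `profiles` (named list of
#'   smoothed per-quartile vectors), `raw` (unsmoothed), `n_matches`
#'   per quartile.
#' @export
motifCentrality <- function(sequences, pwm, quartiles = "all",
                            rolling = 500L) {
  seqs <- as.character(sequences)
  L <- unique(nchar(seqs))
  if (length(L) != 1) stop("sequences must all have the same length")
  if (ncol(pwm$mat) >= L) stop("motif must be shorter than the sequences")
  quartiles <- rep_len(as.character(quartiles), length(seqs))
  starts <- vapply(seqs, bestPWMMatch, integer(1), pwm = pwm,
                   USE.NAMES = FALSE)
  np <- L - ncol(pwm$mat) + 1
  labs <- sort(unique(quartiles))
  raw <- profiles <- stats::setNames(vector("list", length(labs)), labs)
  n_matches <- stats::setNames(integer(length(labs)), labs)
  for (q in labs) {
    st <- starts[quartiles == q & !is.na(starts)]
    n_matches[[q]] <- length(st)
    v <- numeric(np)
    if (length(st)) {
      tb <- tabulate(st, nbins = np)
      v <- tb / sum(tb)
    } else {
      warning("no motif matches in quartile ", q, "; flat zero profile")
    }
    raw[[q]] <- v
    profiles[[q]] <- rollingMean(v, rolling)
  }
  structure(list(offsets = seq_len(np) - (L + 1) / 2 +
                   (ncol(pwm$mat) - 1) / 2,
                 profiles = profiles, raw = raw, n_matches = n_matches,
                 rolling = rolling),
            class = "MotifCentrality")
}

rollingMean <- function(x, w) {
  # centred rolling mean with partial windows at the edges
  n <- length(x)
  half <- floor(w / 2)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + (w - half - 1), n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Average coverage profile over aligned region centres
#'
#' Mean track signal at each offset in `[-half_width, +half_width)`
#' across the centres of the given regions. Regions whose window would
#' leave the chromosome are excluded and counted.
#'
#' @param track a [CoverageTrack-class].
#' @param regions `GRanges`; window centres are the region midpoints.
#' @param half_width half window width in bp.
#' @param flip_strand when TRUE, windows of minus-strand regions are
#'   reversed before averaging.
#' @return list of class `PositionProfile` with `offsets`, `values`,
#'   `n_regions` (used) and `n_excluded`.
#' @export
metaProfile <- function(track, regions, half_width = 5000L,
                        flip_strand = FALSE) {
  sl <- seqlengths(track)
  centers <- floor((start(regions) + end(regions)) / 2)
  chroms <- as.character(seqnames(regions))
  wlen <- 2L * half_width
  acc <- numeric(wlen)
  used <- 0L; excluded <- 0L
  for (i in seq_along(regions)) {
    lo <- centers[i] - half_width
    hi <- centers[i] + half_width - 1L
    if (lo < 1 || hi > sl[[chroms[i]]]) { excluded <- excluded + 1L; next }
    w <- trackSignal(track, chroms[i])[lo:hi]
    if (flip_strand && as.character(strand(regions)[i]) == "-") w <- rev(w)
    acc <- acc + w
    used <- used + 1L
  }
  structure(list(offsets = seq(-half_width, half_width - 1L),
                 values = if (used) acc / used else acc,
                 n_regions = used, n_excluded = excluded,
                 feature = track@assay),
            class = "PositionProfile")
}

#' Sample control sequence windows
#'
#' Seeded uniform sampling of non-overlapping fixed-width windows that
#' avoid an exclusion set (typically the peak-centred fragments).
#'
#' @param genome named `DNAStringSet`.
#' @param n number of control windows.
#' @param width window width (bp).
#' @param exclude `GRanges` to avoid (no overlap allowed).
#' @param seed integer seed (local RNG; does not disturb the caller's
#'   RNG state).
#' @return `DNAStringSet` of `n` control sequences (fewer, with a
#'   warning, if the genome cannot host them).
#' @export
sampleControlSequences <- function(genome, n, width = 10000L,
                                   exclude = GRanges(), seed = 1L) {
  sl <- Biostrings::width(genome)
  names(sl) <- names(genome)
  picked <- GRanges()
  out <- character(0)
  state <- withr_seed(seed)
  on.exit(restore_seed(state))
  tries <- 0L
  while (length(out) < n && tries < 50L * n) {
    tries <- tries + 1L
    chrom <- sample(names(genome), 1, prob = sl)
    if (sl[[chrom]] < width) next
    st <- sample.int(sl[[chrom]] - width + 1L, 1)
    cand <- GRanges(chrom, IRanges(st, width = width))
    if (length(exclude) &&
        suppressWarnings(IRanges::overlapsAny(cand, exclude))) next
    if (length(picked) &&
        suppressWarnings(IRanges::overlapsAny(cand, picked))) next
    picked <- suppressWarnings(c(picked, cand))
    out <- c(out, as.character(Biostrings::subseq(genome[[chrom]], st,
                                                  st + width - 1L)))
  }
  if (length(out) < n)
    warning("only ", length(out), " of ", n, " control windows placed")
  Biostrings::DNAStringSet(out)
}

withr_seed <- function(seed) {
  state <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
  set.seed(seed)
  state
}

restore_seed <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
}

#' Extract equal-width sequences centred on peaks
#'
#' @param genome named `DNAStringSet`.
#' @param peaks `GRanges`/[ConsensusPeaks-class] of width-1 positions.
#' @param half_width half fragment width (bp); fragments are
#'   `2 * half_width` long. Peaks too close to a chromosome edge are
#'   dropped with a warning.
#' @return named `DNAStringSet` (names = peak index kept).
#' @export
peakSequences <- function(genome, peaks, half_width = 5000L) {
  sl <- Biostrings::width(genome)
  names(sl) <- names(genome)
  chroms <- as.character(seqnames(peaks))
  pos <- start(peaks)
  lo <- pos - half_width
  hi <- pos + half_width - 1L
  keep <- lo >= 1 & hi <= sl[chroms]
  if (any(!keep))
    warning(sum(!keep), " peak(s) too close to a chromosome edge dropped")
  out <- vapply(which(keep), function(i)
    as.character(Biostrings::subseq(genome[[chroms[i]]], lo[i], hi[i])),
    character(1))
  stats::setNames(Biostrings::DNAStringSet(out), which(keep))
}
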