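#' @import methods
#' @importFrom S4Vectors SimpleList mcols mcols<- metadata metadata<- DataFrame
#' @importFrom BiocGenerics start end width strand
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges seqnames granges
#' @importFrom GenomeInfoDb seqlengths
NULL

#' CoverageTrack: depth-normalized per-base ChIP-seq signal
#'
#' Holds one signal value per base pair per chromosome, in SPMR/RPKM-like
#' units (see [simulateTracks()] for the exact normalization used by the
#' synthetic generator). Dense numeric vectors are used rather than
#' run-length or interval structures: at desk scale a genome costs about
#' 8 bytes per base pair and every downstream scoring step indexes by
#' position.
#'
#' @slot signal named list of non-negative numeric vectors, one per
#'   chromosome; position i holds the signal over base i (1-based).
#' @slot assay character label, e.g. "MEL18"; free-form.
#'
#' @seealso [CoverageTrack()], [trackSignal()], [readBedGraph()]
#' @export
setClass("CoverageTrack",
  representation(signal = "list", assay = "character"),
  prototype(signal = list(), assay = NA_character_)
)

setValidity("CoverageTrack", function(object) {
  sig <- object@signal
  if (length(sig) && is.null(names(sig)))
    return("signal vectors must be named by chromosome")
  for (chrom in names(sig)) {
    v <- sig[[chrom]]
    if (!is.numeric(v))
      return(sprintf("signal for %s is not numeric", chrom))
    if (anyNA(v))
      return(sprintf("signal for %s contains NA", chrom))
    if (any(v < 0))
      return(sprintf("signal for %s contains negative values", chrom))
  }
  TRUE
})

#' Construct a CoverageTrack
#'
#' @param signal named list of per-chromosome numeric vectors (1 value/bp),
#'   or a single numeric vector together with `chrom`.
#' @param assay optional assay label carried along for display.
#' @param chrom chromosome name when `signal` is a bare vector.
#' @return A [CoverageTrack-class] object.
#' @examples
#' tr <- CoverageTrack(list(chr1 = c(0, 1, 2, 1, 0)))
#' trackSignal(tr, "chr1")
#' @export
CoverageTrack <- function(signal, assay = NA_character_, chrom = "chr1") {
  if (is.numeric(signal)) {
    signal <- stats::setNames(list(as.numeric(signal)), chrom)
  }
  new("CoverageTrack", signal = lapply(signal, as.numeric), assay = assay)
}

#' @describeIn CoverageTrack chromosome lengths of the track
#' @param x,object a `CoverageTrack`
#' @export
setMethod("seqlengths", "CoverageTrack", function(x) {
  vapply(x@signal, length, integer(1))
})

#' Extract the per-bp signal of one chromosome
#'
#' @param track a [CoverageTrack-class]
#' @param chrom chromosome name; must exist in the track.
#' @return numeric vector, one value per base pair.
#' @export
trackSignal <- function(track, chrom) {
  stopifnot(is(track, "CoverageTrack"))
  if (!chrom %in% names(track@signal))
    stop("chromosome '", chrom, "' not in track (has: ",
         paste(names(track@signal), collapse = ", "), ")")
  track@signal[[chrom]]
}

setMethod("show", "CoverageTrack", function(object) {
  sl <- seqlengths(object)
  tot <- sum(vapply(object@signal, sum, numeric(1)))
  cat("CoverageTrack", if (!is.na(object@assay)) sprintf("[%s]", object@assay),
      "\n  chromosomes:", length(sl),
      sprintf("(%.1f Mb total)", sum(sl) / 1e6),
      "\n  total signal:", format(tot, digits = 4), "\n")
})

#' ConsensusPeaks: replicate-paired discrete binding sites
#'
#' A `GRanges` subclass in which each range is a single base pair, the
#' consensus position of a peak paired between two replicates (the median
#' of the two replicate positions). Metadata columns:
#' \describe{
#'   \item{accuracy}{half the distance between the paired replicate peaks,
#'     in bp; the location confidence of the site.}
#'   \item{scoreRep1, scoreRep2}{9-bp window signal sums per replicate
#'     (filled by [scorePeaks()]).}
#'   \item{score}{mean of the replicate scores, used for ranking.}
#'   \item{quartile}{`Q1`..`Q4` score quartile, `Q4` highest.}
#' }
#'
#' @seealso [pairReplicates()], [scorePeaks()], [highConfidencePTEs()]
#' @export
setClass("ConsensusPeaks", contains = "GRanges")

setValidity("ConsensusPeaks", function(object) {
  if (length(object)) {
    if (any(width(object) != 1L))
      return("consensus peaks must be width-1 positions")
    if (!"accuracy" %in% names(mcols(object)))
      return("missing 'accuracy' metadata column")
    if (any(mcols(object)$accuracy < 0))
      return("accuracy must be >= 0")
  }
  TRUE
})

#' Construct a ConsensusPeaks object
#'
#' @param chrom chromosome names (recycled).
#' @param position 1-based consensus positions.
#' @param accuracy half inter-replicate peak distance in bp.
#' @param ... further metadata columns (e.g. `score`, `quartile`).
#' @return A [ConsensusPeaks-class] object sorted by position.
#' @export
ConsensusPeaks <- function(chrom, position, accuracy, ...) {
  gr <- GRanges(chrom, IRanges(position, width = 1L),
                accuracy = as.numeric(accuracy), ...)
  gr <- GenomicRanges::sort(gr)
  new("ConsensusPeaks", gr)
}

#' @describeIn ConsensusPeaks consensus positions (integer vector)
#' @param x a `ConsensusPeaks`
#' @export
peakPositions <- function(x) {
  stopifnot(is(x, "ConsensusPeaks"))
  start(x)
}

#' @describeIn ConsensusPeaks location accuracies in bp
#' @export
peakAccuracy <- function(x) {
  stopifnot(is(x, "ConsensusPeaks"))
  mcols(x)$accuracy
}

#' @describeIn ConsensusPeaks score quartile labels (factor Q1..Q4) or NULL
#' @export
peakQuartile <- function(x) {
  stopifnot(is(x, "ConsensusPeaks"))
  mcols(x)$quartile
}

setMethod("show", "ConsensusPeaks", function(object) {
  cat("ConsensusPeaks with", length(object), "paired peaks\n")
  if (length(object)) {
    acc <- mcols(object)$accuracy
    cat(sprintf("  median accuracy: %.0f bp; <=300 bp: %d\n",
                stats::median(acc), sum(acc <= 300)))
    if (!is.null(mcols(object)$quartile))
      print(table(quartile = mcols(object)$quartile))
  }
  methods::callNextMethod()
})
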