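## The CCND2-like screen and the high-confidence PTE rule.

#' Screen parameters
#'
#' @param mel18_min_rpkm minimum MEL18 summit RPKM in the discovery cell
#'   line (criterion i).
#' @param reference_ratio MEL18/SUZ12 signal ratio at the reference
#'   locus; candidate loci must exceed it (criterion ii). Supply a
#'   number, or compute it from a named region's scores with
#'   [referenceRatio()].
#' @param tig3_min_rpkm minimum MEL18 and SUZ12 summit RPKM in the
#'   second cell line (criterion iii).
#' @param hc_quartiles quartiles eligible for high-confidence PTE
#'   status.
#' @param hc_max_accuracy maximum location accuracy in bp; "better than
#'   +/-301 bp" means accuracy at most 300.
#' @return named list.
#' @export
screenParams <- function(mel18_min_rpkm = 3000, reference_ratio = NULL,
                         tig3_min_rpkm = 2000,
                         hc_quartiles = c("Q4", "Q3"),
                         hc_max_accuracy = 300) {
  stopifnot(mel18_min_rpkm > 0, tig3_min_rpkm > 0, hc_max_accuracy > 0)
  list(mel18_min_rpkm = mel18_min_rpkm, reference_ratio = reference_ratio,
       tig3_min_rpkm = tig3_min_rpkm, hc_quartiles = hc_quartiles,
       hc_max_accuracy = hc_max_accuracy)
}

#' MEL18/SUZ12 ratio at a reference locus
#'
#' @param mel18_score,suz12_score summit-window scores of the reference
#'   (CCND2-like) locus.
#' @return their ratio; `Inf` when the SUZ12 score is 0.
#' @export
referenceRatio <- function(mel18_score, suz12_score) {
  if (suz12_score == 0) return(Inf)
  mel18_score / suz12_score
}

#' Screen scored regions for CCND2-like PTE candidates
#'
#' A locus passes when it (i) has a strong MEL18 signal in the discovery
#' cell line (summit RPKM above `mel18_min_rpkm`), (ii) has a MEL18/SUZ12
#' signal ratio above the reference locus ratio, and (iii) shows strong
#' binding of both MEL18 and SUZ12 (both above `tig3_min_rpkm`) in the
#' second cell line. Summit windows of the default 1000 bp make the
#' summit sum numerically equal to the window's RPKM on an SPMR track,
#' so thresholds are portable.
#'
#' @param scores data.frame with one row per region and numeric columns
#'   `mel18_a`, `suz12_a` (discovery cell line) and `mel18_b`, `suz12_b`
#'   (second cell line); extra columns (e.g. region ids) pass through.
#' @param params from [screenParams()]; `reference_ratio` must be set.
#' @return `scores` with per-criterion logical columns `pass_signal`,
#'   `pass_ratio`, `pass_celline_b`, a MEL18/SUZ12 `ratio` column, and
#'   the overall `candidate` flag.
#' @export
ccnd2LikeScreen <- function(scores, params = screenParams()) {
  need <- c("mel18_a", "suz12_a", "mel18_b", "suz12_b")
  miss <- setdiff(need, names(scores))
  if (length(miss)) stop("missing score column(s): ",
                         paste(miss, collapse = ", "))
  if (is.null(params$reference_ratio) || params$reference_ratio <= 0)
    stop("params$reference_ratio must be a positive number (see referenceRatio)")
  ratio <- ifelse(scores$suz12_a == 0, Inf,
                  scores$mel18_a / scores$suz12_a)
  if (any(scores$suz12_a == 0))
    message(sum(scores$suz12_a == 0),
            " region(s) with SUZ12 score 0: ratio set to +Inf")
  scores$ratio <- ratio
  scores$pass_signal <- scores$mel18_a > params$mel18_min_rpkm
  scores$pass_ratio <- ratio > params$reference_ratio
  scores$pass_celline_b <- scores$mel18_b > params$tig3_min_rpkm &
    scores$suz12_b > params$tig3_min_rpkm
  scores$candidate <- scores$pass_signal & scores$pass_ratio &
    scores$pass_celline_b
  scores
}

#' Flag high-confidence PTEs
#'
#' A consensus peak is a putative high-confidence PTE when its score
#' quartile is high (Q4 or Q3 by default) and its position is defined
#' with accuracy better than +/-301 bp (accuracy <= 300).
#'
#' @param peaks a scored, quartiled [ConsensusPeaks-class] (see
#'   [scorePeaks()]).
#' @param params from [screenParams()].
#' @return `peaks` with a logical `highConfidence` metadata column.
#' @export
highConfidencePTEs <- function(peaks, params = screenParams()) {
  if (is.null(peakQuartile(peaks)))
    stop("peaks must be quartiled first (scorePeaks)")
  mcols(peaks)$highConfidence <-
    as.character(peakQuartile(peaks)) %in% params$hc_quartiles &
    peakAccuracy(peaks) <= params$hc_max_accuracy
  peaks
}
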