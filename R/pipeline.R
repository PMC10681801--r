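## Stage orchestration: regions -> groups -> refined peaks -> pairing ->
## scores/quartiles -> high-confidence PTEs -> target genes, with
## per-stage counts collected into a run report. Stage outputs are pure
## functions of (inputs, parameters, seed).

#' Run the PTE discovery pipeline on coverage tracks
#'
#' Takes two replicate PRC1 (MEL18) tracks with their enriched-region
#' calls, applies replicate concordance and grouping, refines each
#' replicate to discrete peaks, pairs them into consensus peaks, scores
#' and quartiles them, flags high-confidence PTEs and, when a gene
#' table and H3K27me3 regions are given, assigns target genes and
#' transcription groups.
#'
#' @param track1,track2 replicate [CoverageTrack-class] objects.
#' @param regions1,regions2 per-replicate enriched regions (`GRanges`).
#' @param genes optional gene table (with `count` for transcription
#'   groups).
#' @param k27_regions optional `GRanges` of H3K27me3 regions.
#' @param rparams,sparams,fparams,scparams module parameter blocks (see
#'   [regionParams()], [smoothParams()], [filterParams()],
#'   [screenParams()]).
#' @param pair_max_distance maximum replicate pairing distance (bp).
#' @param tss_window H3K27me3 promoter window for target assignment.
#' @return list of class `ptePipelineResult`: `regions` (concordant,
#'   grouped), `peaks1`, `peaks2` (refined per replicate), `peaks`
#'   (scored [ConsensusPeaks-class] with `highConfidence`), `unmatched1`,
#'   `unmatched2`, `assignments`, `genes` (with groups), and `counts`
#'   (per-stage in/out tallies).
#' @export
runPTEPipeline <- function(track1, track2, regions1, regions2,
                           genes = NULL, k27_regions = NULL,
                           rparams = regionParams(),
                           sparams = smoothParams(),
                           fparams = filterParams(),
                           scparams = screenParams(),
                           pair_max_distance = 5000L,
                           tss_window = 1000L) {
  conc <- concordantRegions(regions1, regions2, track1, track2, rparams)
  grouped <- groupRegions(conc$merged, rparams)
  pk1 <- refinePeaks(grouped, track1, sparams, fparams)
  pk2 <- refinePeaks(grouped, track2, sparams, fparams)
  paired <- pairReplicates(pk1, pk2, max_distance = pair_max_distance)
  peaks <- scorePeaks(paired$pairs, track1, track2)
  peaks <- highConfidencePTEs(peaks, scparams)
  assignments <- NULL
  if (!is.null(genes) && !is.null(k27_regions) && length(peaks)) {
    hc <- peaks[mcols(peaks)$highConfidence]
    assignments <- assignTargets(hc, genes, k27_regions,
                                 tss_window = tss_window)
    if (!is.null(genes$count)) genes <- transcriptionGroups(genes)
  }
  res <- list(regions = grouped, peaks1 = pk1, peaks2 = pk2,
              peaks = peaks, unmatched1 = paired$unmatched1,
              unmatched2 = paired$unmatched2,
              assignments = assignments, genes = genes,
              counts = c(regions_rep1 = length(regions1),
                         regions_rep2 = length(regions2),
                         regions_concordant = length(conc$merged),
                         groups = if (length(grouped))
                           max(mcols(grouped)$group) else 0L,
                         peaks_rep1 = length(pk1),
                         peaks_rep2 = length(pk2),
                         peaks_paired = length(peaks),
                         peaks_high_confidence = if (length(peaks))
                           sum(mcols(peaks)$highConfidence) else 0L))
  class(res) <- "ptePipelineResult"
  res
}

#' @export
print.ptePipelineResult <- function(x, ...) {
  cat("PTE pipeline result\n")
  for (nm in names(x$counts))
    cat(sprintf("  %-22s %d\n", nm, x$counts[[nm]]))
  if (!is.null(x$assignments))
    cat(sprintf("  %-22s %d\n", "targets_assigned",
                sum(x$assignments$assigned)))
  invisible(x)
}

#' Compare recovered peaks with a planted truth table
#'
#' @param result a `ptePipelineResult`.
#' @param truth the `truth` element of a [simulatePTEData()] fixture.
#' @param max_error maximum |consensus position - planted position| for
#'   a planted PTE to count as recovered (bp).
#' @return list: `recovery` (fraction of planted PTEs recovered),
#'   `position_errors` (bp, one per recovered PTE), `amplitude_score_rho`
#'   (Spearman correlation of planted amplitude and 9-bp score),
#'   `false_per_mb` (peaks with no planted PTE within `max_error`, per
#'   Mb), `prc2_only_calls` (peaks inside planted PRC2-only loci),
#'   `assignment_accuracy` (fraction of recovered high-confidence PTEs
#'   assigned to their planted target gene, NA without assignments).
#' @export
evaluateAgainstTruth <- function(result, truth, max_error = 360) {
  peaks <- result$peaks
  pte <- truth$pte
  pos_err <- rep(NA_real_, nrow(pte))
  matched_peak <- rep(NA_integer_, nrow(pte))
  for (i in seq_len(nrow(pte))) {
    same <- which(as.character(seqnames(peaks)) == pte$chrom[i])
    if (!length(same)) next
    d <- abs(start(peaks)[same] - pte$position[i])
    j <- which.min(d)
    if (d[j] <= max_error) {
      pos_err[i] <- d[j]
      matched_peak[i] <- same[j]
    }
  }
  recovered <- !is.na(matched_peak)
  rho <- NA_real_
  if (sum(recovered) >= 3)
    rho <- stats::cor(pte$amplitude[recovered],
                      mcols(peaks)$score[matched_peak[recovered]],
                      method = "spearman")
  genome_mb <- sum(seqlengths_of_result(result)) / 1e6
  false_peaks <- setdiff(seq_along(peaks), matched_peak[recovered])
  prc2_calls <- if (length(peaks))
    sum(IRanges::overlapsAny(granges(peaks), truth$prc2_only)) else 0L
  acc <- NA_real_
  if (!is.null(result$assignments) && any(recovered)) {
    hc_idx <- which(mcols(peaks)$highConfidence)
    a <- result$assignments
    ok <- vapply(which(recovered), function(i) {
      k <- match(matched_peak[i], hc_idx)
      if (is.na(k)) return(NA)  # recovered but not high-confidence
      a$assigned[k] && a$gene_id[k] == pte$target_gene[i]
    }, logical(1))
    acc <- mean(ok, na.rm = TRUE)
  }
  list(recovery = mean(recovered),
       position_errors = pos_err[recovered],
       amplitude_score_rho = rho,
       false_per_mb = length(false_peaks) / genome_mb,
       prc2_only_calls = prc2_calls,
       assignment_accuracy = acc)
}

seqlengths_of_result <- function(result) {
  # genome span proxy: extent of the grouped regions' chromosomes
  gr <- result$regions
  if (!length(gr)) return(0)
  tapply(end(gr), as.character(seqnames(gr)), max)
}
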