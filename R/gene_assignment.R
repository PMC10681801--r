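## Target-gene assignment and transcription groups.
##
## Each PTE is assigned to the nearest TSS to its left and right; the
## H3K27me3 status of a window around each TSS decides which of the two
## genes is the likely target: prefer the closer TSS when its chromatin
## carries H3K27me3; fall back to the farther TSS when only that one
## does; otherwise take the closer TSS.

#' Assign each peak to its likely target gene
#'
#' @param peaks a [ConsensusPeaks-class] or `GRanges` of width-1
#'   positions.
#' @param genes gene table data.frame (`gene_id`, `chrom`, `tss`,
#'   `strand`, ...; see [readGeneTable()]).
#' @param k27_regions `GRanges` of significant H3K27me3 regions.
#' @param tss_window a TSS counts as H3K27me3-marked when `tss` +/- this
#'   many bp overlaps a H3K27me3 region.
#' @return data.frame with one row per peak: `pte_id`, `chrom`,
#'   `position`, `gene_id`, `distance` (bp, point-to-point), `category`
#'   (`closer_tss_k27`, `farther_tss_k27`, `no_k27_closest`) and
#'   `assigned`. Peaks on chromosomes without any TSS are reported with
#'   `assigned = FALSE`, never dropped.
#' @export
assignTargets <- function(peaks, genes, k27_regions, tss_window = 1000L) {
  n <- length(peaks)
  tss_gr <- GRanges(genes$chrom,
                    IRanges(pmax(1L, genes$tss - tss_window),
                            genes$tss + tss_window))
  marked <- IRanges::overlapsAny(tss_gr, k27_regions)
  out <- data.frame(pte_id = sprintf("pte_%03d", seq_len(n)),
                    chrom = as.character(seqnames(peaks)),
                    position = start(peaks),
                    gene_id = NA_character_, distance = NA_real_,
                    category = NA_character_, assigned = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    chrom <- out$chrom[i]; pos <- out$position[i]
    on_chr <- which(genes$chrom == chrom)
    if (!length(on_chr)) next
    d <- genes$tss[on_chr] - pos
    left <- on_chr[d <= 0]; right <- on_chr[d > 0]
    li <- if (length(left)) left[which.max(genes$tss[left])] else NA
    ri <- if (length(right)) right[which.min(genes$tss[right])] else NA
    cand <- c(li, ri); cand <- cand[!is.na(cand)]
    dist <- abs(genes$tss[cand] - pos)
    o <- order(dist, genes$tss[cand])  # tie: leftmost TSS
    closer <- cand[o[1]]
    farther <- if (length(cand) > 1) cand[o[2]] else NA
    if (marked[closer]) {
      pick <- closer; cat_ <- "closer_tss_k27"
    } else if (!is.na(farther) && marked[farther]) {
      pick <- farther; cat_ <- "farther_tss_k27"
    } else {
      pick <- closer; cat_ <- "no_k27_closest"
    }
    out$gene_id[i] <- genes$gene_id[pick]
    out$distance[i] <- abs(genes$tss[pick] - pos)
    out$category[i] <- cat_
    out$assigned[i] <- TRUE
  }
  out
}

#' Per-gene summary of PTE assignments
#'
#' @param assignments output of [assignTargets()].
#' @return list with `genes` (data.frame: `gene_id`, `n_pte`,
#'   `min_distance`, `categories`) and cohort summaries
#'   `fraction_multi_pte` (genes with >1 PTE) and `distance_quantiles`.
#' @export
genePTESummary <- function(assignments) {
  a <- assignments[assignments$assigned, , drop = FALSE]
  if (nrow(a) == 0)
    return(list(genes = data.frame(gene_id = character(0),
                                   n_pte = integer(0),
                                   min_distance = numeric(0),
                                   categories = character(0)),
                fraction_multi_pte = NA_real_,
                distance_quantiles = NULL))
  sp <- split(a, a$gene_id)
  genes <- data.frame(
    gene_id = names(sp),
    n_pte = vapply(sp, nrow, integer(1)),
    min_distance = vapply(sp, function(x) min(x$distance), numeric(1)),
    categories = vapply(sp, function(x)
      paste(sort(unique(x$category)), collapse = ","), character(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  list(genes = genes,
       fraction_multi_pte = mean(genes$n_pte > 1),
       distance_quantiles = stats::quantile(genes$min_distance,
                                            c(0.25, 0.5, 0.75)))
}

#' Rank genes into transcription groups G1-G4
#'
#' Quartiles of RNA signal over the full gene universe, G1 lowest and
#' G4 highest; tied counts share the lower group (minimum rank), so an
#' all-zero table is all G1.
#'
#' @param genes gene table with a `count` column.
#' @return `genes` with a `group` factor column (G1..G4).
#' @export
transcriptionGroups <- function(genes) {
  stopifnot(all(genes$count >= 0))
  n <- nrow(genes)
  r <- rank(genes$count, ties.method = "min")
  g <- ceiling(r * 4 / n)
  genes$group <- factor(paste0("G", g), levels = paste0("G", 1:4))
  genes
}

#' Overlap of target-gene sets between cell lines
#'
#' @param genes_a,genes_b character vectors of target gene ids, or gene
#'   tables with `gene_id` and optional `group` columns (from
#'   [transcriptionGroups()]); `genes_b` is conventionally the smaller
#'   (second cell line) set.
#' @param denominator `"smaller"` (default: fraction of the smaller
#'   set's genes found in the other), `"a"` or `"b"`.
#' @return list with `overlap_fraction`, `n_common`, and `transitions`
#'   (a G-group contingency table over common genes when groups are
#'   available, else NULL).
#' @export
crossCellLineOverlap <- function(genes_a, genes_b,
                                 denominator = c("smaller", "a", "b")) {
  denominator <- match.arg(denominator)
  ids <- function(x) if (is.data.frame(x)) x$gene_id else as.character(x)
  ia <- unique(ids(genes_a)); ib <- unique(ids(genes_b))
  common <- intersect(ia, ib)
  den <- switch(denominator,
                smaller = min(length(ia), length(ib)),
                a = length(ia), b = length(ib))
  frac <- if (den == 0) NA_real_ else length(common) / den
  trans <- NULL
  if (is.data.frame(genes_a) && is.data.frame(genes_b) &&
      !is.null(genes_a$group) && !is.null(genes_b$group) && length(common)) {
    ga <- genes_a$group[match(common, genes_a$gene_id)]
    gb <- genes_b$group[match(common, genes_b$gene_id)]
    trans <- table(from = ga, to = gb)
  }
  list(overlap_fraction = frac, n_common = length(common),
       transitions = trans)
}
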