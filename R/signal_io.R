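## Readers/writers for the plain-text formats the pipeline touches.
## All on-disk interval formats are 0-based half-open (BED/bedGraph);
## in memory everything is 1-based (GRanges / track vectors).

#' Read a bedGraph file into a CoverageTrack
#'
#' Expands run-length bedGraph records to a dense per-bp vector. Positions
#' not covered by any record are 0. Overlapping records are rejected: a
#' coverage track assigns one value per base.
#'
#' @param path bedGraph file (4 columns: chrom, start, end, value;
#'   0-based half-open). Track/browser header lines are ignored.
#' @param seqlengths named integer vector of chromosome lengths; defines
#'   the chromosomes and vector lengths of the result. Records on
#'   chromosomes absent from `seqlengths`, or extending past a chromosome
#'   end, are an error (names are compared verbatim, no "chr" fixing).
#' @param assay optional assay label for the track.
#' @return A [CoverageTrack-class].
#' @examples
#' f <- tempfile(fileext = ".bedGraph")
#' writeLines("chr1\t0\t5\t2", f)
#' trackSignal(readBedGraph(f, c(chr1 = 10L)), "chr1")
#' @export
readBedGraph <- function(path, seqlengths, assay = NA_character_) {
  stopifnot(!is.null(names(seqlengths)))
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|browser|#)", lines) & nzchar(lines)]
  sig <- lapply(seqlengths, function(n) numeric(n))
  if (length(lines)) {
    gr <- tryCatch(
      rtracklayer::import(path, format = "bedGraph"),
      error = function(e) stop("malformed bedGraph '", path, "': ",
                               conditionMessage(e)))
    bad <- !as.character(seqnames(gr)) %in% names(seqlengths)
    if (any(bad))
      stop("bedGraph chromosome(s) not in seqlengths: ",
           paste(unique(as.character(seqnames(gr))[bad]), collapse = ", "),
           " (known: ", paste(names(seqlengths), collapse = ", "), ")")
    chroms <- as.character(seqnames(gr))
    starts <- start(gr); ends <- end(gr)
    scores <- as.numeric(mcols(gr)$score)
    for (chrom in unique(chroms)) {
      sel <- chroms == chrom
      s <- starts[sel]; e <- ends[sel]; sc <- scores[sel]
      if (max(e) > seqlengths[[chrom]])
        stop("record beyond end of ", chrom, " in ", path)
      o <- order(s)
      s <- s[o]; e <- e[o]; sc <- sc[o]
      if (length(s) > 1 && any(s[-1] <= e[-length(e)]))
        stop("overlapping bedGraph records on ", chrom, " in ", path)
      v <- sig[[chrom]]
      w <- e - s + 1L
      v[sequence(w) + rep(s - 1L, w)] <- rep(sc, w)
      sig[[chrom]] <- v
    }
  }
  CoverageTrack(sig, assay = assay)
}

#' Write a CoverageTrack as run-length-encoded bedGraph
#'
#' Adjacent equal values are merged into one record; zero runs are
#' omitted (an all-zero track writes an empty data section), so
#' `readBedGraph(writeBedGraph(x))` round-trips exactly.
#'
#' @param track a [CoverageTrack-class]
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeBedGraph <- function(track, path) {
  stopifnot(is(track, "CoverageTrack"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (chrom in names(track@signal)) {
    r <- rle(track@signal[[chrom]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths  # 0-based
    keep <- r$values != 0
    if (any(keep))
      writeLines(sprintf("%s\t%d\t%d\t%s", chrom, starts[keep], ends[keep],
                         format(r$values[keep], trim = TRUE, digits = 15,
                                scientific = FALSE)),
                 con)
  }
  invisible(path)
}

#' Read a BED3+ interval file
#'
#' @param path BED file (3 to 6+ columns, 0-based half-open on disk).
#' @return A `GRanges` sorted by (chrom, start); strand defaults to `*`
#'   when absent; a numeric `score` column is kept when present.
#' @export
readRegions <- function(path) {
  n <- length(readLines(path))
  if (n == 0) return(GRanges())
  gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                 error = function(e) stop("malformed BED '", path, "': ",
                                          conditionMessage(e)))
  if (any(width(gr) < 1))
    stop("BED record with start >= end in ", path)
  gr <- GenomeInfoDb::sortSeqlevels(gr)
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

#' Write intervals as BED6
#'
#' Scores are rounded to integers per BED convention; use TSV sidecars
#' for lossless scores.
#'
#' @param gr a `GRanges`; `score` and `name` metadata columns are used
#'   when present.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeRegions <- function(gr, path) {
  if (length(gr) == 0) {
    file.create(path)
    return(invisible(path))
  }
  nm <- if (!is.null(mcols(gr)$name)) mcols(gr)$name else
    sprintf("region_%d", seq_along(gr))
  sc <- if (!is.null(mcols(gr)$score)) round(as.numeric(mcols(gr)$score)) else 0L
  st <- as.character(strand(gr))
  st[st == "*"] <- "."
  writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t%s",
                     as.character(seqnames(gr)), start(gr) - 1L, end(gr),
                     nm, sc, st),
             path)
  invisible(path)
}

#' Read a genome FASTA
#'
#' @param path FASTA file; sequences are uppercased, `N` allowed.
#' @return A `DNAStringSet` named by the first word of each header.
#' @export
readGenome <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  Biostrings::DNAStringSet(toupper(x))
}

#' Write a genome FASTA
#'
#' @param genome a named `DNAStringSet`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGenome <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Read a gene table (TSV with header)
#'
#' Expected columns: `gene_id`, `chrom`, `tss` (1-based position),
#' `strand` (+/-), `count` (non-negative RNA-seq signal). Extra columns
#' pass through.
#'
#' @param path TSV path.
#' @return A `data.frame`, one row per gene.
#' @export
readGeneTable <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "")
  need <- c("gene_id", "chrom", "tss", "strand", "count")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("gene table missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene_id in ", path, ": ",
         paste(unique(df$gene_id[duplicated(df$gene_id)]), collapse = ", "))
  if (any(df$count < 0)) stop("negative counts in ", path)
  df
}

#' Write a gene table
#' @param genes data.frame with at least gene_id/chrom/tss/strand/count.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGeneTable <- function(genes, path) {
  utils::write.table(genes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
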