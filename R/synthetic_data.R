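## Synthetic genome, coverage tracks and RNA counts with the signal
## structure the PTE analysis assumes: sharp high-amplitude,
## replicate-jittered PRC1 peaks at planted PTE loci; broad CpG-coupled
## PRC2/H3K27me3 domains offset to the flanks; AA/TT-enriched peak
## cores with CpG-rich flanks; strand-biased poly(dA)5 tracts pointing
## at the target gene; one embedded consensus motif near each core
## centre; and a long-tailed gene-expression distribution. Every
## generator is deterministic given its seed, and one global seed fans
## out to per-track seeds through a fixed counter scheme so adding a
## track never perturbs the others.

#' Synthetic genome specification
#'
#' Defaults define the package's reference fixture: 4 chromosomes of
#' 2 Mb, 60 genes, 24 planted PTE loci and 12 PRC2-only loci -- large
#' enough for quartile statistics (6 peaks per quartile), small enough
#' to simulate in seconds.
#'
#' @param n_chromosomes,chrom_length genome shape.
#' @param n_genes total genes (must be >= n_pte_loci; one designated
#'   target gene per PTE).
#' @param n_pte_loci,n_prc2_only_loci planted locus counts.
#' @param background_gc background GC fraction.
#' @param cpg_island_gc GC fraction of the CpG-island flanks.
#' @param pte_core_aa_tt_boost probability of repeating the previous
#'   base when it is A or T inside a PTE core; elevates AA/TT
#'   di-nucleotide frequency above composition alone.
#' @param polyA_strand_bias fraction of planted poly(dA)5 tracts laid on
#'   the strand pointing at the target gene (the rest are poly(dT)5 in
#'   the oriented frame).
#' @param motif_consensus motif embedded once near each PTE core centre.
#' @param motif_placement_sd SD (bp) of the motif offset from the core
#'   centre.
#' @param core_width,flank_width PTE core and CpG flank widths (bp).
#' @param n_tracts_per_core planted 5-mer tracts per core.
#' @param seed integer seed.
#' @return validated spec (named list).
#' @export
genomeSpec <- function(n_chromosomes = 4L, chrom_length = 2000000L,
                       n_genes = 60L, n_pte_loci = 24L,
                       n_prc2_only_loci = 12L, background_gc = 0.41,
                       cpg_island_gc = 0.65, pte_core_aa_tt_boost = 0.15,
                       polyA_strand_bias = 0.8,
                       motif_consensus = "AAACGAAA",
                       motif_placement_sd = 100L,
                       core_width = 1000L, flank_width = 1000L,
                       n_tracts_per_core = 10L, seed = 1L) {
  spec <- as.list(environment())
  lens <- c(spec$n_chromosomes, spec$chrom_length, spec$core_width,
            spec$flank_width)
  if (any(lens <= 0)) stop("lengths and counts must be positive")
  fr <- c(background_gc, cpg_island_gc, pte_core_aa_tt_boost,
          polyA_strand_bias)
  if (any(fr < 0 | fr > 1)) stop("fractions must be in [0, 1]")
  if (n_genes < n_pte_loci) stop("need at least one gene per PTE locus")
  spec
}

#' Track specification for the synthetic generator
#'
#' @param assay one of MEL18, SUZ12, RING2, H3K27me3, INPUT, MNASE.
#' @param peak_amplitude_range range (RPKM over the central kb) from
#'   which planted peak amplitudes are drawn; the default spans a
#'   4-fold range above the screen's 3000-RPKM gate. Sharp peaks only
#'   apply to PRC1 assays (MEL18/RING2).
#' @param peak_width_sd Gaussian peak SD in bp (PRC1 assays).
#' @param domain_width width of each broad PRC2/H3K27me3 plateau (bp).
#' @param replicate_position_jitter_sd per-replicate SD (bp) of the
#'   planted peak position.
#' @param noise_model `"negative_binomial"` (default; overdispersion is
#'   what real tracks show) or `"poisson"`.
#' @param nb_dispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2).
#' @param total_reads simulated library size before normalization.
#' @param fragment_length simulated fragment length (bp).
#' @return validated spec (named list).
#' @export
trackSpec <- function(assay = c("MEL18", "SUZ12", "RING2", "H3K27me3",
                                "INPUT", "MNASE"),
                      peak_amplitude_range = c(2000, 8000),
                      peak_width_sd = 250, domain_width = 1500,
                      replicate_position_jitter_sd = 120,
                      noise_model = c("negative_binomial", "poisson"),
                      nb_dispersion = 0.3, total_reads = 2e6,
                      fragment_length = 180L) {
  assay <- match.arg(assay)
  noise_model <- match.arg(noise_model)
  if (replicate_position_jitter_sd < 0) stop("jitter sd must be >= 0")
  if (any(peak_amplitude_range < 0)) stop("amplitudes must be >= 0")
  if (nb_dispersion <= 0) stop("nb_dispersion must be positive")
  as.list(environment())
}

markovSeq <- function(n, gc, repeat_boost = 0, cg_boost = 0) {
  # first-order chain: optionally repeat A/T (AA/TT enrichment) or
  # follow C with G (CpG enrichment); otherwise draw iid at given GC
  base_p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  letters4 <- c("A", "C", "G", "T")
  out <- character(n)
  prev <- sample(letters4, 1, prob = base_p)
  out[1] <- prev
  if (n > 1) for (i in 2:n) {
    u <- stats::runif(1)
    if (repeat_boost > 0 && prev %in% c("A", "T") && u < repeat_boost) {
      out[i] <- prev
    } else if (cg_boost > 0 && prev == "C" && u < cg_boost) {
      out[i] <- "G"
    } else {
      out[i] <- sample(letters4, 1, prob = base_p)
    }
    prev <- out[i]
  }
  paste(out, collapse = "")
}

iidSeq <- function(n, gc) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

spliceIn <- function(seq, at, insert) {
  # overwrite (not insert) 'insert' into 'seq' starting at 1-based 'at'
  substr(seq, at, at + nchar(insert) - 1L) <- insert
  seq
}

#' Generate a synthetic genome with planted PTE and PRC2-only loci
#'
#' Background sequence is i.i.d. at `background_gc`. Each planted PTE
#' locus consists of a core (`core_width` bp) generated with an AA/TT
#' repeat boost, one embedded `motif_consensus` instance placed at
#' N(core centre, `motif_placement_sd`) in the oriented frame, planted
#' 5-bp A/T tracts biased to the strand pointing at the designated
#' target gene, and CpG-rich flanks on both sides. When the target gene
#' lies left of the peak the whole oriented core+tract+motif cassette is
#' reverse-complemented into the genome, so oriented statistics are
#' strand-symmetric. PRC2-only loci are CpG-rich segments without motif
#' or tract planting. Deterministic given `spec$seed`.
#'
#' @param spec from [genomeSpec()].
#' @return list with `genome` (`DNAStringSet`), `truth` (list: `pte`
#'   data.frame with chrom/position/amplitude/target gene/gene side,
#'   `prc2_only` `GRanges`, `genes` gene table without counts).
#' @export
generateGenome <- function(spec = genomeSpec()) {
  set.seed(spec$seed)
  chroms <- sprintf("chr%d", seq_len(spec$n_chromosomes))
  seqs <- stats::setNames(
    vapply(chroms, function(x) iidSeq(spec$chrom_length, spec$background_gc),
           character(1)),
    chroms)

  half_locus <- spec$core_width / 2 + spec$flank_width
  n_loci <- spec$n_pte_loci + spec$n_prc2_only_loci
  # lay loci on a jittered lattice so they never overlap and sit farther
  # apart than the 100-kb region-grouping gap: each planted locus is its
  # own peak group, as for well-separated Polycomb target loci
  margin <- 50000L
  positions <- placeLoci(n_loci, spec$n_chromosomes, spec$chrom_length,
                         margin = margin, min_gap = 110000L)
  pte_idx <- seq_len(spec$n_pte_loci)
  prc2_idx <- setdiff(seq_len(n_loci), pte_idx)

  gene_ids <- sprintf("gene_%03d", seq_len(spec$n_genes))
  pte <- data.frame(pte_locus = sprintf("pte_locus_%02d", pte_idx),
                    chrom = positions$chrom[pte_idx],
                    position = positions$pos[pte_idx],
                    amplitude = rep(NA_real_, spec$n_pte_loci),
                    target_gene = gene_ids[pte_idx],
                    gene_side = sample(c("left", "right"),
                                       spec$n_pte_loci, replace = TRUE),
                    stringsAsFactors = FALSE)
  # amplitudes span the track spec's range; fixed here so every track
  # (and replicate) shares the planted truth
  pte$amplitude <- stats::runif(spec$n_pte_loci, 0, 1)

  for (i in seq_len(nrow(pte))) {
    cassette <- pteCassette(spec)
    if (pte$gene_side[i] == "left")
      cassette <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(cassette)))
    at <- pte$position[i] - floor(nchar(cassette) / 2)
    seqs[[pte$chrom[i]]] <- spliceIn(seqs[[pte$chrom[i]]], at, cassette)
  }
  prc2_only <- GRanges(positions$chrom[prc2_idx],
                       IRanges(positions$pos[prc2_idx] - half_locus,
                               positions$pos[prc2_idx] + half_locus))
  for (i in seq_along(prc2_only)) {
    wd <- width(prc2_only)[i]
    island <- markovSeq(wd, spec$cpg_island_gc, cg_boost = 0.3)
    seqs[[as.character(seqnames(prc2_only))[i]]] <-
      spliceIn(seqs[[as.character(seqnames(prc2_only))[i]]],
               start(prc2_only)[i], island)
  }

  genes <- placeGenes(spec, pte, positions, gene_ids, margin)
  list(genome = Biostrings::DNAStringSet(seqs),
       truth = list(pte = pte, prc2_only = prc2_only, genes = genes))
}

placeLoci <- function(n, n_chrom, chrom_length, margin, min_gap) {
  if (n == 0)
    return(data.frame(chrom = character(0), pos = integer(0),
                      stringsAsFactors = FALSE))
  per_chrom <- rep(ceiling(n / n_chrom), n_chrom)
  chrom <- rep(sprintf("chr%d", seq_len(n_chrom)), per_chrom)[seq_len(n)]
  pos <- integer(n)
  k <- max(table(chrom))
  usable <- chrom_length - 2 * margin
  slot <- floor(usable / k)
  if (slot < min_gap) stop("planted loci cannot be placed without overlap")
  j <- unlist(lapply(table(chrom)[unique(chrom)], seq_len), use.names = FALSE)
  jitter <- sample.int(max(1L, slot - min_gap), n, replace = TRUE)
  pos <- margin + (j - 1L) * slot + jitter
  ord <- sample.int(n)  # shuffle which locus class sits where
  data.frame(chrom = chrom[ord], pos = pos[ord],
             stringsAsFactors = FALSE)
}

pteCassette <- function(spec) {
  # oriented frame: target gene to the right
  core <- markovSeq(spec$core_width, 0.36,
                    repeat_boost = spec$pte_core_aa_tt_boost)
  # plant 5-bp tracts right of the peak centre in the oriented frame
  # (between the peak and its target gene), biased to poly(dA)
  n_tr <- spec$n_tracts_per_core
  n_a <- stats::rbinom(1, n_tr, spec$polyA_strand_bias)
  tracts <- c(rep("AAAAA", n_a), rep("TTTTT", n_tr - n_a))
  half <- floor(spec$core_width / 2)
  at <- half + sort(sample.int(half - 5L, n_tr))
  # keep planted tracts disjoint
  at <- at[c(TRUE, diff(at) >= 6)]
  for (i in seq_along(at))
    core <- spliceIn(core, at[i], tracts[i])
  moff <- round(stats::rnorm(1, 0, spec$motif_placement_sd))
  mpos <- max(1L, min(spec$core_width - nchar(spec$motif_consensus),
                      spec$core_width / 2 + moff))
  core <- spliceIn(core, mpos, spec$motif_consensus)
  left <- markovSeq(spec$flank_width, spec$cpg_island_gc, cg_boost = 0.3)
  right <- markovSeq(spec$flank_width, spec$cpg_island_gc, cg_boost = 0.3)
  paste0(left, core, right)
}

placeGenes <- function(spec, pte, positions, gene_ids, margin) {
  n <- spec$n_genes
  chrom <- character(n); tss <- integer(n); strand <- character(n)
  # target genes: TSS 2-8 kb from their PTE on the designated side,
  # pointing away from the PTE
  for (i in seq_len(nrow(pte))) {
    d <- sample(2000:8000, 1)
    if (pte$gene_side[i] == "right") {
      tss[i] <- pte$position[i] + d; strand[i] <- "+"
    } else {
      tss[i] <- pte$position[i] - d; strand[i] <- "-"
    }
    chrom[i] <- pte$chrom[i]
  }
  # remaining genes: uniform, >= 15 kb from any planted locus so they
  # never usurp a PTE's nearest-TSS slot
  occupied <- GRanges(c(pte$chrom, positions$chrom),
                      IRanges(c(pte$position, positions$pos) - 15000,
                              c(pte$position, positions$pos) + 15000))
  i <- nrow(pte) + 1L
  while (i <= n) {
    ch <- sample(sprintf("chr%d", seq_len(spec$n_chromosomes)), 1)
    p <- sample(seq(margin, spec$chrom_length - margin), 1)
    if (!IRanges::overlapsAny(GRanges(ch, IRanges(p, p)), occupied)) {
      chrom[i] <- ch; tss[i] <- p
      strand[i] <- sample(c("+", "-"), 1)
      i <- i + 1L
    }
  }
  data.frame(gene_id = gene_ids, chrom = chrom, tss = tss,
             strand = strand, stringsAsFactors = FALSE)
}

trackSeed <- function(global_seed, counter) {
  # counter-based fan-out; stays far below .Machine$integer.max
  (global_seed * 10007L + counter * 101L) %% 2000000011L
}

#' Simulate replicate coverage tracks and enriched-region calls
#'
#' For each requested track spec and replicate, builds the expected
#' per-bp signal density (PRC1 assays: Gaussian peaks at planted PTE
#' positions, position jittered independently per replicate, area
#' proportional to planted amplitude; PRC2/H3K27me3 assays: two
#' flat-topped plateaus over the CpG flanks of each PTE plus plateaus
#' over PRC2-only loci; INPUT/MNASE: background only), samples per-bp
#' read starts under the noise model, extends them by the fragment
#' length, and normalizes so the genome-wide track sum is exactly 1e6
#' -- making any 1-kb window sum that window's RPKM and summit-window
#' scores directly comparable to the screen thresholds.
#'
#' Also emits per-replicate "significantly enriched region" intervals
#' derived from the planted truth (PRC1: peak +/- 1250 bp; PRC2/K27:
#' core+flank spans plus PRC2-only loci and, for H3K27me3, the target
#' TSS promoters), each at least 1000 bp.
#'
#' @param sim output of [generateGenome()].
#' @param specs named list of [trackSpec()]s; default MEL18 + SUZ12 +
#'   H3K27me3 + INPUT.
#' @param n_replicates replicates per assay (>= 2; replicate pairing is
#'   defined for two).
#' @param seed global seed, fanned out per track.
#' @param gspec the [genomeSpec()] used (for locus geometry).
#' @return list with `tracks` (nested list `tracks[[assay]][[rep]]` of
#'   [CoverageTrack-class]) and `regions` (nested list of `GRanges`).
#' @export
simulateTracks <- function(sim, specs = NULL, n_replicates = 2L, seed = 1L,
                           gspec = genomeSpec()) {
  if (n_replicates < 2) stop("pairing requires at least two replicates")
  if (is.null(specs))
    specs <- list(MEL18 = trackSpec("MEL18"), SUZ12 = trackSpec("SUZ12"),
                  H3K27me3 = trackSpec("H3K27me3"),
                  INPUT = trackSpec("INPUT"))
  sl <- Biostrings::width(sim$genome)
  names(sl) <- names(sim$genome)
  truth <- sim$truth
  tracks <- list(); regions <- list()
  counter <- 0L
  for (nm in names(specs)) {
    sp <- specs[[nm]]
    tracks[[nm]] <- list(); regions[[nm]] <- list()
    for (r in seq_len(n_replicates)) {
      counter <- counter + 1L
      set.seed(trackSeed(seed, counter))
      built <- buildTrack(sp, truth, sl, gspec)
      tracks[[nm]][[r]] <- built$track
      regions[[nm]][[r]] <- built$regions
    }
  }
  list(tracks = tracks, regions = regions)
}

buildTrack <- function(sp, truth, sl, gspec) {
  amp_lo <- sp$peak_amplitude_range[1]
  amp_hi <- sp$peak_amplitude_range[2]
  dens <- lapply(sl, function(n) numeric(n))
  region_list <- list()
  half_locus <- gspec$core_width / 2 + gspec$flank_width
  if (sp$assay %in% c("MEL18", "RING2")) {
    for (i in seq_len(nrow(truth$pte))) {
      ch <- truth$pte$chrom[i]
      centre <- truth$pte$position[i] +
        round(stats::rnorm(1, 0, sp$replicate_position_jitter_sd))
      amp <- amp_lo + truth$pte$amplitude[i] * (amp_hi - amp_lo)
      lo <- max(1L, centre - 4L * sp$peak_width_sd)
      hi <- min(sl[[ch]], centre + 4L * sp$peak_width_sd)
      x <- lo:hi
      bump <- stats::dnorm(x, centre, sp$peak_width_sd)
      # scale so the central 1-kb sum equals amp (its RPKM target)
      csum <- sum(stats::dnorm((centre - 499):(centre + 500), centre,
                               sp$peak_width_sd))
      dens[[ch]][x] <- dens[[ch]][x] + bump * amp / csum
      region_list[[length(region_list) + 1L]] <-
        GRanges(ch, IRanges(max(1L, truth$pte$position[i] - 1250L),
                            truth$pte$position[i] + 1250L))
    }
  }
  if (sp$assay %in% c("SUZ12", "H3K27me3")) {
    plateau <- function(ch, centre, wd, amp_per_kb) {
      lo <- max(1L, centre - floor(wd / 2))
      hi <- min(sl[[ch]], centre + floor(wd / 2))
      ramp <- 200L
      x <- lo:hi
      edge <- pmin(1, pmin(x - lo + 1, hi - x + 1) / ramp)
      dens[[ch]][x] <<- dens[[ch]][x] + amp_per_kb / 1000 * edge
    }
    for (i in seq_len(nrow(truth$pte))) {
      ch <- truth$pte$chrom[i]; p <- truth$pte$position[i]
      off <- floor((gspec$core_width + sp$domain_width) / 2)
      amp <- 0.35 * (amp_lo + truth$pte$amplitude[i] * (amp_hi - amp_lo))
      plateau(ch, p - off, sp$domain_width, amp)
      plateau(ch, p + off, sp$domain_width, amp)
      region_list[[length(region_list) + 1L]] <-
        GRanges(ch, IRanges(max(1L, p - half_locus), p + half_locus))
      if (sp$assay == "H3K27me3") {
        # Polycomb domain covers the target promoter too
        g <- truth$genes[truth$genes$gene_id == truth$pte$target_gene[i], ]
        plateau(g$chrom, g$tss, 3000L, amp)
        region_list[[length(region_list) + 1L]] <-
          GRanges(g$chrom, IRanges(max(1L, g$tss - 1500L), g$tss + 1500L))
      }
    }
    for (i in seq_along(truth$prc2_only)) {
      ch <- as.character(seqnames(truth$prc2_only))[i]
      ce <- floor((start(truth$prc2_only)[i] + end(truth$prc2_only)[i]) / 2)
      plateau(ch, ce, width(truth$prc2_only)[i], 0.35 * amp_hi)
      region_list[[length(region_list) + 1L]] <- truth$prc2_only[i]
    }
  }
  if (sp$assay == "MNASE") {
    # mild nucleosome-sized enrichment over PTE cores (light digestion)
    for (i in seq_len(nrow(truth$pte))) {
      ch <- truth$pte$chrom[i]; p <- truth$pte$position[i]
      x <- max(1L, p - 500L):min(sl[[ch]], p + 500L)
      dens[[ch]][x] <- dens[[ch]][x] + 1000 / 1000
    }
  }
  # background floor everywhere, then convert the density (RPKM per bp)
  # into expected read starts, sample noise, extend, normalize
  genome_len <- sum(sl)
  peak_mass <- sum(vapply(dens, sum, numeric(1)))
  bg_per_bp <- max(0, (1e6 - peak_mass)) / genome_len
  frag <- sp$fragment_length
  track_sig <- list()
  for (ch in names(sl)) {
    mu_rpkm <- dens[[ch]] + bg_per_bp
    mu_reads <- mu_rpkm * sp$total_reads / 1e6
    starts <- if (sp$noise_model == "poisson")
      stats::rpois(length(mu_reads), mu_reads)
    else
      stats::rnbinom(length(mu_reads), mu = mu_reads,
                     size = 1 / sp$nb_dispersion)
    cov <- boxExtend(starts, frag)
    track_sig[[ch]] <- cov
  }
  tot_cov <- sum(vapply(track_sig, sum, numeric(1)))
  track_sig <- lapply(track_sig, function(v) v * 1e6 / tot_cov)
  regions <- if (length(region_list))
    GenomicRanges::reduce(suppressWarnings(do.call(c, region_list)))
  else GRanges()
  if (length(regions)) {
    short <- width(regions) < 1000L
    if (any(short)) {
      pad <- ceiling((1000L - width(regions)[short]) / 2)
      regions[short] <- GRanges(
        seqnames(regions)[short],
        IRanges(pmax(1L, start(regions)[short] - pad),
                end(regions)[short] + pad))
    }
  }
  list(track = CoverageTrack(track_sig, assay = sp$assay),
       regions = GenomicRanges::sort(regions))
}

boxExtend <- function(starts, frag) {
  # coverage from per-bp read-start counts, reads extended frag bp to
  # the right (truncated at the chromosome end)
  cs <- cumsum(starts)
  n <- length(starts)
  lag <- c(rep(0, frag), cs[1:(n - frag)])
  cs - lag
}

#' Simulate a long-tailed gene-expression table
#'
#' Log-normal counts; a configurable fraction of PTE target genes is
#' drawn from the low tail (below the cohort median), mirroring the
#' predominance of transcriptionally inactive PTE targets.
#'
#' @param truth the `truth` element of [generateGenome()] output.
#' @param fraction_low fraction of PTE target genes forced into the low
#'   tail.
#' @param meanlog,sdlog log-normal parameters of the cohort.
#' @param seed integer seed.
#' @return the gene table with a `count` column.
#' @export
simulateCounts <- function(truth, fraction_low = 0.8, meanlog = 3,
                           sdlog = 2, seed = 1L) {
  genes <- truth$genes
  if (nrow(genes) == 0) stop("gene table is empty")
  set.seed(seed)
  counts <- stats::rlnorm(nrow(genes), meanlog, sdlog)
  med <- stats::median(counts)
  is_target <- genes$gene_id %in% truth$pte$target_gene
  force_low <- is_target & stats::runif(nrow(genes)) < fraction_low
  counts[force_low] <- stats::runif(sum(force_low), 0, med * 0.5)
  genes$count <- round(counts, 2)
  genes
}

#' One-call synthetic data set
#'
#' Genome, truth, tracks, regions and counts with a single seed; the
#' package's reference fixture when called with defaults.
#'
#' @param gspec from [genomeSpec()]; its seed drives the genome.
#' @param specs,n_replicates see [simulateTracks()].
#' @param seed seed for tracks and counts.
#' @return list: `genome`, `truth` (with `genes` including counts),
#'   `tracks`, `regions`.
#' @export
simulatePTEData <- function(gspec = genomeSpec(), specs = NULL,
                            n_replicates = 2L, seed = gspec$seed) {
  sim <- generateGenome(gspec)
  tr <- simulateTracks(sim, specs = specs, n_replicates = n_replicates,
                       seed = seed, gspec = gspec)
  sim$truth$genes <- simulateCounts(sim$truth, seed = seed + 1L)
  list(genome = sim$genome, truth = sim$truth, tracks = tr$tracks,
       regions = tr$regions)
}

#' Write a simulated data set to files
#'
#' FASTA genome, bedGraph tracks, BED6 region and truth files and the
#' TSV gene table -- the on-disk fixture layout consumed by the I/O
#' module.
#'
#' @param sim output of [simulatePTEData()].
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
writePTEData <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeGenome(sim$genome, file.path(dir, "genome.fa"))
  for (nm in names(sim$tracks))
    for (r in seq_along(sim$tracks[[nm]])) {
      writeBedGraph(sim$tracks[[nm]][[r]],
                    file.path(dir, sprintf("%s_rep%d.bedGraph", nm, r)))
      writeRegions(sim$regions[[nm]][[r]],
                   file.path(dir, sprintf("%s_rep%d_regions.bed", nm, r)))
    }
  writeGeneTable(sim$truth$genes, file.path(dir, "genes.tsv"))
  truth_gr <- GRanges(sim$truth$pte$chrom,
                      IRanges(sim$truth$pte$position, width = 1L),
                      name = sim$truth$pte$pte_locus)
  writeRegions(truth_gr, file.path(dir, "pte_truth.bed"))
  writeRegions(sim$truth$prc2_only, file.path(dir, "prc2_only_truth.bed"))
  invisible(dir)
}
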