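# Independent brute-force oracles. Deliberately naive: exhaustive loops
# and direct counting, no shared code with the implementations.

oracle_summit <- function(values, w) {
  # max sum over every window of width w; leftmost tie
  n <- length(values)
  if (n <= w) return(list(score = sum(values), start = 1L))
  best <- -Inf; at <- 1L
  for (s in 1:(n - w + 1)) {
    sc <- sum(values[s:(s + w - 1)])
    if (sc > best + 1e-9) { best <- sc; at <- s }
  }
  list(score = best, start = at)
}

oracle_groups <- function(starts, ends, gap) {
  # transitive closure of pairwise "within gap" over sorted regions
  n <- length(starts)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    d <- max(0, max(starts[i], starts[j]) - min(ends[i], ends[j]) - 1)
    adj[i, j] <- d <= gap
  }
  grp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n))
      if (adj[i, j] && grp[j] > grp[i]) { grp[j] <- grp[i]; changed <- TRUE }
    if (!changed) break
  }
  match(grp, unique(grp))
}

oracle_gap_distance <- function(s1, e1, s2, e2) {
  if (e1 >= s2 && e2 >= s1) return(0)  # overlap
  max(0, max(s2 - e1, s1 - e2) - 1)
}

oracle_standalone <- function(suz, k27, mel, dist) {
  keep <- logical(length(suz))
  for (i in seq_along(suz)) {
    ov <- FALSE
    for (j in seq_along(k27))
      if (GenomicRanges::start(suz)[i] <= GenomicRanges::end(k27)[j] &&
          GenomicRanges::end(suz)[i] >= GenomicRanges::start(k27)[j] &&
          as.character(GenomicRanges::seqnames(suz)[i]) ==
            as.character(GenomicRanges::seqnames(k27)[j])) ov <- TRUE
    dmin <- Inf
    for (j in seq_along(mel))
      if (as.character(GenomicRanges::seqnames(suz)[i]) ==
          as.character(GenomicRanges::seqnames(mel)[j]))
        dmin <- min(dmin, oracle_gap_distance(
          GenomicRanges::start(suz)[i], GenomicRanges::end(suz)[i],
          GenomicRanges::start(mel)[j], GenomicRanges::end(mel)[j]))
    keep[i] <- ov && dmin > dist
  }
  keep
}

oracle_extrema <- function(y) {
  # strict neighbour comparison; assumes no ties (continuous input)
  pos <- integer(0); kind <- character(0)
  for (i in 2:(length(y) - 1)) {
    if (y[i] > y[i - 1] && y[i] > y[i + 1]) { pos <- c(pos, i); kind <- c(kind, "peak") }
    if (y[i] < y[i - 1] && y[i] < y[i + 1]) { pos <- c(pos, i); kind <- c(kind, "valley") }
  }
  data.frame(pos = pos, kind = kind)
}

oracle_filter <- function(extrema, pf, vd) {
  # direct transcription of the rule: threshold, then scan clusters
  pk <- extrema[extrema$kind == "peak", ]
  pk <- pk[order(pk$pos), ]
  va <- extrema[extrema$kind == "valley", ]
  thr <- pf * max(pk$score)
  pk <- pk[pk$score >= thr, ]
  if (nrow(pk) == 0) return(integer(0))
  clusters <- list(1L)
  for (j in seq_len(nrow(pk))[-1]) {
    cur <- clusters[[length(clusters)]]
    prev <- cur[length(cur)]
    vs <- va$score[va$pos > pk$pos[prev] & va$pos < pk$pos[j]]
    best_cur <- max(pk$score[cur])
    deep <- length(vs) > 0 &&
      min(vs) <= (1 - vd) * min(best_cur, pk$score[j])
    if (deep) clusters[[length(clusters) + 1]] <- j
    else clusters[[length(clusters)]] <- c(cur, j)
  }
  sapply(clusters, function(cl) pk$pos[cl[which.max(pk$score[cl])]])
}

oracle_mutual_nn <- function(a, b, maxd = Inf) {
  # all mutual nearest pairs by full distance matrix; leftmost ties
  if (!length(a) || !length(b)) return(cbind(integer(0), integer(0)))
  d <- abs(outer(a, b, "-"))
  pairs <- NULL
  for (i in seq_along(a)) {
    j <- which.min(d[i, ])
    if (which.min(d[, j]) == i && d[i, j] <= maxd)
      pairs <- rbind(pairs, c(i, j))
  }
  if (is.null(pairs)) cbind(integer(0), integer(0)) else pairs
}

oracle_assign <- function(pos, chrom, genes, marked) {
  # full scan over every TSS on the chromosome
  on <- which(genes$chrom == chrom)
  if (!length(on)) return(NULL)
  left <- on[genes$tss[on] <= pos]
  right <- on[genes$tss[on] > pos]
  li <- if (length(left)) left[which.max(genes$tss[left])] else NA
  ri <- if (length(right)) right[which.min(genes$tss[right])] else NA
  cand <- stats::na.omit(c(li, ri))
  d <- abs(genes$tss[cand] - pos)
  o <- order(d, genes$tss[cand])
  closer <- cand[o[1]]
  farther <- if (length(cand) > 1) cand[o[2]] else NA
  if (marked[closer]) list(gene = closer, category = "closer_tss_k27")
  else if (!is.na(farther) && marked[farther])
    list(gene = farther, category = "farther_tss_k27")
  else list(gene = closer, category = "no_k27_closest")
}

oracle_dinuc_window <- function(seqs, win) {
  # frequencies of the dinucleotides inside every window of `win` bases,
  # by direct substring counting
  L <- nchar(seqs[1])
  dinucs <- paste0(rep(c("A", "C", "G", "T"), each = 4),
                   c("A", "C", "G", "T"))
  nw <- L - win + 1
  freq <- matrix(0, 16, nw, dimnames = list(dinucs, NULL))
  for (w in seq_len(nw)) {
    counts <- stats::setNames(numeric(16), dinucs)
    total <- 0
    for (s in seqs) {
      for (j in w:(w + win - 2)) {
        dn <- substr(s, j, j + 1)
        if (dn %in% dinucs) { counts[dn] <- counts[dn] + 1; total <- total + 1 }
      }
    }
    freq[, w] <- counts / total
  }
  freq
}

oracle_cpg_window <- function(seq, win) {
  L <- nchar(seq)
  nw <- L - win + 1
  sapply(seq_len(nw), function(w) {
    sum(sapply(w:(w + win - 2), function(j) substr(seq, j, j + 1) == "CG"))
  })
}

oracle_metaprofile <- function(track, centers, chroms, half) {
  rows <- NULL
  for (i in seq_along(centers)) {
    v <- trackSignal(track, chroms[i])
    lo <- centers[i] - half; hi <- centers[i] + half - 1
    if (lo < 1 || hi > length(v)) next
    rows <- rbind(rows, v[lo:hi])
  }
  colMeans(rows)
}
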