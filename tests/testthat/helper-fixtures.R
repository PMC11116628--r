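# Shared fixtures and independent oracle implementations used by the
# property-style tests. Oracles are deliberately written in a different style
# from the package code paths they check.

sig_df <- function(start, svlen, chrom = "chr1", read = NULL, source = "cigar") {
  n <- length(start)
  if (is.null(read)) read <- sprintf("r%03d", seq_len(n))
  del_signatures(chrom = rep(chrom, n), start = start, svlen = svlen,
                 end = start + svlen, read_name = read,
                 source = rep(source, n))
}

# Minimal SAM writer for fixtures: records are lists with qname, flag, chrom,
# pos (1-based), mapq, cigar, and optional sa.
write_sam_fixture <- function(records, path = tempfile(fileext = ".sam"),
                              chrom_lengths = c(chr1 = 1e6, chr2 = 1e6)) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
                   as.integer(chrom_lengths)))
  lines <- vapply(records, function(r) {
    tags <- if (!is.null(r$sa)) paste0("\tSA:Z:", r$sa) else ""
    sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t*\t*%s",
            r$qname, r$flag, r$chrom, r$pos, r$mapq, r$cigar, tags)
  }, character(1))
  writeLines(c(hdr, lines), path)
  path
}

rec <- function(qname, chrom = "chr1", pos = 1, mapq = 60, cigar = "100M",
                flag = 0L, sa = NULL) {
  list(qname = qname, flag = flag, chrom = chrom, pos = pos, mapq = mapq,
       cigar = cigar, sa = sa)
}

# Oracle 1: coverage clustering == components of the touch-or-overlap
# relation on [start, end) spans (the closed form of maximal positive depth
# runs). Sweep over spans sorted by start, starting a new component whenever
# the next span starts strictly after the running maximum end.
oracle_touch_components <- function(start, end) {
  ord <- order(start, end)
  comp <- integer(length(start))
  cur <- 0L
  max_end <- -Inf
  for (i in ord) {
    if (start[i] > max_end) cur <- cur + 1L
    comp[i] <- cur
    max_end <- max(max_end, end[i])
  }
  comp
}

# Oracle 2: independent re-simulation of the sliding-window sweep, written
# as window-by-window set arithmetic over the start multiset.
oracle_sliding_window <- function(starts, window) {
  starts <- sort(starts)
  assigned <- rep(NA_integer_, length(starts))
  cid <- 0L
  while (anyNA(assigned)) {
    cid <- cid + 1L
    first <- which(is.na(assigned))[1]
    w <- starts[first]
    repeat {
      in_win <- is.na(assigned) & starts >= w & starts < w + window
      if (!any(in_win)) break
      assigned[in_win] <- cid
      w <- w + window
    }
  }
  assigned
}

# Oracle 3: brute-force greedy agglomeration by mean length with the
# documented tie-breaks, as explicit set bookkeeping.
oracle_agglomerate <- function(svlen, start, rate_threshold = 0.2) {
  groups <- lapply(seq_along(svlen), identity)
  repeat {
    if (length(groups) <= 2L) break
    best <- NULL
    for (i in seq_along(groups)) for (j in seq_along(groups)) {
      if (i >= j) next
      gi <- groups[[i]]; gj <- groups[[j]]
      key <- c(abs(mean(svlen[gi]) - mean(svlen[gj])),
               length(gi) + length(gj),
               mean(svlen[c(gi, gj)]),
               min(start[c(gi, gj)]))
      if (is.null(best) || isTRUE(compare_keys(key, best$key) < 0))
        best <- list(key = key, i = i, j = j)
    }
    groups[[best$i]] <- c(groups[[best$i]], groups[[best$j]])
    groups[[best$j]] <- NULL
  }
  if (length(groups) == 2L) {
    m1 <- mean(svlen[groups[[1]]]); m2 <- mean(svlen[groups[[2]]])
    if (abs(m1 - m2) / max(m1, m2) < rate_threshold)
      groups <- list(c(groups[[1]], groups[[2]]))
  }
  lapply(groups, sort)
}

compare_keys <- function(a, b) {
  d <- sign(a - b)
  nz <- which(d != 0)
  if (length(nz) == 0) 0 else d[nz[1]]
}

# canonical form of a clustering for comparison: sorted list of sorted
# member index sets
canon_groups <- function(groups) {
  groups <- unname(lapply(groups, function(g) sort(as.integer(g))))
  groups[order(vapply(groups, `[`, integer(1), 1L))]
}
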