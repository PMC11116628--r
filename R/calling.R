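# Support filtering and final call determination.

#' Support of a candidate cluster
#'
#' The number of candidate deletion sites (signatures) in the cluster. With
#' `unique_reads = TRUE` signatures sharing a read name count once.
#'
#' @param cc A `cand_cluster`.
#' @param unique_reads Count distinct reads instead of signatures.
#' @return Integer support.
#' @export
support_of <- function(cc, unique_reads = FALSE) {
  n <- nrow(cc$members)
  if (n == 0L) stop("candidate cluster must be nonempty")
  if (unique_reads) length(unique(cc$members$read_name)) else n
}

#' Filter the candidate clusters of one locus by read support
#'
#' Two cases, depending on how many candidate clusters layer 2 produced for
#' the large cluster: a lone candidate cluster is kept iff its support is at
#' least `min_support`; when there are two (two alleles at one locus), each is
#' kept independently iff its support is at least `min_support / 2`
#' (real-valued half, no rounding). The halved threshold keeps heterozygous
#' alleles, whose reads split between two clusters, from being filtered away.
#'
#' @param cands List of one or two `cand_cluster` objects.
#' @param cfg A [calling_config()].
#' @return Possibly empty sub-list of `cands`.
#' @export
filter_candidates <- function(cands, cfg = calling_config()) {
  stopifnot(length(cands) %in% c(1L, 2L))
  thr <- if (length(cands) == 2L) cfg$min_support / 2 else cfg$min_support
  keep <- vapply(cands, function(cc) {
    support_of(cc, cfg$unique_reads) >= thr
  }, logical(1))
  cands[keep]
}

#' Final deletion call from a candidate cluster
#'
#' Computes the mean position and mean length over members and picks the
#' member closest to that average — L1 distance
#' `|start - mean_start| + |svlen - mean_len|`, ties broken by smaller start,
#' then smaller svlen, then read name. The call takes the winner's exact
#' coordinates (no synthesized positions), with `end = start + svlen`.
#'
#' @param cc A nonempty `cand_cluster`.
#' @param unique_reads Passed to [support_of()].
#' @return One-row data.frame: `chrom`, `start`, `svlen`, `end`, `support`.
#' @export
select_representative <- function(cc, unique_reads = FALSE) {
  m <- cc$members
  stopifnot(nrow(m) >= 1L)
  d <- abs(m$start - cc$mean_start) + abs(m$svlen - cc$mean_len)
  w <- order(d, m$start, m$svlen, m$read_name)[1L]
  data.frame(chrom = m$chrom[w], start = m$start[w], svlen = m$svlen[w],
             end = m$start[w] + m$svlen[w],
             support = support_of(cc, unique_reads),
             stringsAsFactors = FALSE)
}

#' Run the full deletion-calling pipeline
#'
#' Signature extraction, layer-1 and layer-2 clustering, support filtering
#' and representative selection in order. Calls from different loci are never
#' merged, even if their coordinates overlap.
#'
#' @param input Alignment file path (BAM/SAM), or an already-collected
#'   signature data.frame.
#' @param extraction A [extraction_config()].
#' @param clustering A [clustering_config()]; if its `chrom_lengths` is `NULL`
#'   and `input` is a file, contig lengths are taken from the alignment
#'   header.
#' @param calling A [calling_config()].
#' @param layer2_enabled Ablation hook; see [layer2()].
#' @param threads Accepted for interface compatibility (results are identical
#'   for any value).
#' @return Calls data.frame (`chrom`, `start`, `svlen`, `end`, `support`,
#'   `id`), sorted by `(chrom, start, svlen)`.
#' @export
call_deletions <- function(input,
                           extraction = extraction_config(),
                           clustering = clustering_config(),
                           calling = calling_config(),
                           layer2_enabled = TRUE,
                           threads = 1L) {
  if (is.character(input)) {
    if (is.null(clustering$chrom_lengths)) {
      clustering$chrom_lengths <- alignment_chrom_lengths(input)
    }
    sigs <- collect_signatures(input, extraction)
  } else {
    sigs <- input
  }
  large_clusters <- layer1(sigs, clustering, threads = threads)
  cands_per_locus <- layer2(large_clusters, clustering, enabled = layer2_enabled)
  kept <- unlist(lapply(cands_per_locus, filter_candidates, cfg = calling),
                 recursive = FALSE)
  if (length(kept) == 0L) {
    calls <- data.frame(chrom = character(), start = numeric(),
                        svlen = numeric(), end = numeric(),
                        support = integer(), stringsAsFactors = FALSE)
  } else {
    calls <- do.call(rbind, lapply(kept, select_representative,
                                   unique_reads = calling$unique_reads))
  }
  calls <- calls[order(calls$chrom, calls$start, calls$svlen), , drop = FALSE]
  rownames(calls) <- NULL
  calls$id <- sprintf("DEL%05d", seq_len(nrow(calls)))
  calls
}
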