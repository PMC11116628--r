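# Deletion signatures: intra-read (CIGAR 'D') and inter-read (split
# alignment) evidence, plus the within-read merge of fragmented deletions.

#' Empty deletion-signature table
#'
#' Signatures are the unit record of deletion evidence: one read's support for
#' one deletion, `(chrom, start, svlen, end)` plus provenance. Coordinates are
#' 0-based half-open. For merged CIGAR signatures `end` is the second
#' constituent's end, so `end - start` may exceed `svlen`; `svlen` is the
#' deletion length used everywhere downstream.
#'
#' @param chrom,start,svlen,end,read_name,source Column values.
#' @return A data.frame with those six columns.
#' @export
del_signatures <- function(chrom = character(), start = numeric(),
                           svlen = numeric(), end = numeric(),
                           read_name = character(), source = character()) {
  data.frame(chrom = chrom, start = start, svlen = svlen, end = end,
             read_name = read_name, source = source, stringsAsFactors = FALSE)
}

#' Extract deletion signatures from one alignment's CIGAR
#'
#' Walks the CIGAR left to right, tracking the reference position through the
#' reference-consuming ops (M, D, N, =, X), and emits one signature per `D`
#' run strictly longer than `cfg$min_cigar_del`.
#'
#' @param chrom Chromosome name.
#' @param ref_start 0-based reference start of the alignment.
#' @param cigar CIGAR string.
#' @param read_name Read name recorded on the signatures.
#' @param cfg An [extraction_config()].
#' @return Signature data.frame in reference order; malformed CIGARs yield an
#'   empty table with a warning.
#' @export
extract_cigar_signatures <- function(chrom, ref_start, cigar, read_name,
                                     cfg = extraction_config()) {
  cig <- tryCatch(parse_cigar(cigar), error = function(e) {
    warning("skipping record ", read_name, ": ", conditionMessage(e),
            call. = FALSE)
    NULL
  })
  if (is.null(cig)) return(del_signatures())
  refpos <- ref_start
  starts <- numeric(); lens <- numeric()
  for (i in seq_along(cig$ops)) {
    op <- cig$ops[i]; len <- cig$lengths[i]
    if (op == "D" && len > cfg$min_cigar_del) {
      starts <- c(starts, refpos); lens <- c(lens, len)
    }
    if (op %in% REF_OPS) refpos <- refpos + len
  }
  del_signatures(chrom = rep(chrom, length(starts)), start = starts,
                 svlen = lens, end = starts + lens,
                 read_name = rep(read_name, length(starts)),
                 source = rep("cigar", length(starts)))
}

#' Merge fragmented same-read deletion signatures
#'
#' Sequencing errors can break one deletion into several nearby `D` runs on a
#' single read. A single left-to-right pass merges an adjacent pair when the
#' reference gap `start2 - end1` is in `(0, max_merge_gap]`; the merged
#' signature `(chrom, start1, svlen1 + svlen2, end2)` is immediately eligible
#' to merge with the next (cascading). Pairs with gap <= 0 (overlap/abut) or
#' gap above the bound are left untouched.
#'
#' @param sigs Signatures from one read and one chromosome, sorted ascending
#'   by `start`.
#' @param cfg An [extraction_config()].
#' @return Merged signature data.frame.
#' @export
merge_intra_read <- function(sigs, cfg = extraction_config()) {
  n <- nrow(sigs)
  if (n <= 1L) return(sigs)
  if (length(unique(sigs$read_name)) > 1L || length(unique(sigs$chrom)) > 1L)
    stop("merge_intra_read expects signatures from one read on one chromosome")
  if (is.unsorted(sigs$start)) stop("signatures must be sorted by start")
  out <- vector("list", n)
  m <- 0L
  cur <- sigs[1L, ]
  for (i in 2:n) {
    gap <- sigs$start[i] - cur$end
    if (gap > 0 && gap <= cfg$max_merge_gap) {
      cur$svlen <- cur$svlen + sigs$svlen[i]
      cur$end <- sigs$end[i]
    } else {
      m <- m + 1L; out[[m]] <- cur
      cur <- sigs[i, ]
    }
  }
  m <- m + 1L; out[[m]] <- cur
  res <- do.call(rbind, out[seq_len(m)])
  rownames(res) <- NULL
  res
}

#' Deletion signatures from a read's split segments
#'
#' For each pair of read-adjacent segments (consecutive after sorting by
#' `read_start`) on the same chromosome and strand, the implied deletion
#' length is `Distance = (ref_start2 - ref_end1) - (read_start2 - read_end1)`
#' (reference gap minus read gap). A pair with `Distance` inside
#' `[min_split_del, max_split_del]` yields the signature
#' `(chrom, ref_end1, Distance, ref_start2)`; other pairs are skipped
#' silently.
#'
#' @param segs Split-segment data.frame (see [split_segments()]) for one read,
#'   sorted by `read_start`.
#' @param cfg An [extraction_config()].
#' @return Signature data.frame with `source = "split"`. Note `end` here is
#'   the second segment's reference start, which equals `start + svlen` only
#'   when the read gap is zero.
#' @export
extract_split_signatures <- function(segs, cfg = extraction_config()) {
  n <- nrow(segs)
  if (n < 2L) return(del_signatures())
  if (is.unsorted(segs$read_start)) stop("segments must be sorted by read_start")
  out <- del_signatures()
  for (i in seq_len(n - 1L)) {
    a <- segs[i, ]; b <- segs[i + 1L, ]
    if (a$chrom != b$chrom || a$orient != b$orient) next
    # with read coordinates in original-read orientation, a minus-strand pair
    # is the mirror image of the forward geometry: the read-earlier segment
    # sits reference-later, so the reference-gap roles swap
    if (a$orient == "+") {
      dist_ref <- b$ref_start - a$ref_end
      del_start <- a$ref_end; del_end <- b$ref_start
    } else {
      dist_ref <- a$ref_start - b$ref_end
      del_start <- b$ref_end; del_end <- a$ref_start
    }
    dist_read <- b$read_start - a$read_end
    d <- dist_ref - dist_read
    if (d >= cfg$min_split_del && d <= cfg$max_split_del) {
      out <- rbind(out, del_signatures(
        chrom = a$chrom, start = del_start, svlen = d, end = del_end,
        read_name = a$read_name, source = "split"
      ))
    }
  }
  rownames(out) <- NULL
  out
}

#' Collect all deletion signatures from an alignment file
#'
#' Composition of the extraction steps: records are read and filtered, CIGAR
#' signatures are extracted per record and merged within each (read,
#' chromosome), split signatures are computed from each read's segment set,
#' and everything is pooled. Output order is a deterministic function of
#' content (sorted by chrom, start, svlen, read_name, source), independent of
#' record order in the file.
#'
#' @param path BAM or SAM path.
#' @param cfg An [extraction_config()].
#' @return Signature data.frame.
#' @export
collect_signatures <- function(path, cfg = extraction_config()) {
  aln <- read_alignments(path, cfg)
  if (nrow(aln) == 0L) return(del_signatures())
  per_read <- split(aln, aln$read_name)
  parts <- lapply(per_read, function(recs) {
    cig_sigs <- do.call(rbind, lapply(seq_len(nrow(recs)), function(k) {
      extract_cigar_signatures(recs$chrom[k], recs$ref_start[k],
                               recs$cigar[k], recs$read_name[k], cfg)
    }))
    merged <- del_signatures()
    if (!is.null(cig_sigs) && nrow(cig_sigs) > 0L) {
      merged <- do.call(rbind, lapply(split(cig_sigs, cig_sigs$chrom),
        function(s) merge_intra_read(s[order(s$start, s$end), , drop = FALSE], cfg)))
    }
    if (nrow(recs) == 1L && is.na(recs$sa[1])) return(merged)  # no split evidence
    segs <- split_segments(recs, cfg)
    rbind(merged, extract_split_signatures(segs, cfg))
  })
  sigs <- do.call(rbind, parts)
  if (is.null(sigs) || nrow(sigs) == 0L) return(del_signatures())
  sigs <- sigs[order(sigs$chrom, sigs$start, sigs$svlen, sigs$read_name,
                     sigs$source), , drop = FALSE]
  rownames(sigs) <- NULL
  sigs
}
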