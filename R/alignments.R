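# Alignment input: SAM/BAM reading via Rsamtools, CIGAR arithmetic, and
# assembly of split-read segments in original-read orientation.

CIGAR_OPS <- c("M", "I", "D", "N", "S", "H", "P", "=", "X")
REF_OPS <- c("M", "D", "N", "=", "X")    # consume reference
QUERY_OPS <- c("M", "I", "S", "=", "X")  # consume query (soft clips included)

#' Parse a CIGAR string into op/length vectors
#'
#' @param cigar A single CIGAR string, e.g. `"100M50D100M"`.
#' @return A list with integer `lengths` and character `ops`, or `NULL` for
#'   `"*"`/empty input. Unknown op codes raise an error (callers skip the
#'   record with a warning).
#' @keywords internal
parse_cigar <- function(cigar) {
  if (is.na(cigar) || cigar == "*" || !nzchar(cigar)) return(NULL)
  m <- gregexpr("\\d+|\\D", cigar)[[1]]
  tok <- regmatches(cigar, list(m))[[1]]
  is_len <- grepl("^\\d", tok)
  if (length(tok) %% 2L != 0L || !all(is_len == rep(c(TRUE, FALSE), length(tok) / 2)))
    stop("malformed CIGAR: ", cigar)
  ops <- tok[!is_len]
  if (!all(ops %in% CIGAR_OPS)) {
    stop("malformed CIGAR (unknown op ", paste(setdiff(ops, CIGAR_OPS), collapse = ""),
         "): ", cigar)
  }
  list(lengths = as.integer(tok[is_len]), ops = ops)
}

cigar_ref_span <- function(cig) sum(cig$lengths[cig$ops %in% REF_OPS])
cigar_query_len <- function(cig) {
  # full original read length: aligned query + soft AND hard clips
  sum(cig$lengths[cig$ops %in% c(QUERY_OPS, "H")])
}

#' Read and filter alignment records
#'
#' Reads a BAM (or plain-text SAM, converted on the fly) and returns one row
#' per surviving alignment record. Unmapped records, secondary alignments
#' (flag 0x100) and records with MAPQ below `cfg$min_mapq` are removed;
#' supplementary records (0x800) are retained as split-read evidence.
#'
#' @param path Path to a coordinate-sorted BAM (indexed for region queries) or
#'   a SAM text file.
#' @param cfg An [extraction_config()].
#' @param region Optional `GRanges`-style region string passed to the BAM
#'   index, e.g. `"chr1:1-2000000"`; requires a `.bai` index.
#' @return A data.frame with columns `read_name`, `flag`, `chrom`,
#'   `ref_start` (0-based), `mapq`, `cigar`, `orient`, `is_supplementary`,
#'   `sa` (SA tag or `NA`), ordered by read name so records of one read are
#'   contiguous.
#' @export
read_alignments <- function(path, cfg = extraction_config(), region = NULL) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  bam <- sam_as_bam(path)
  param_args <- list(
    what = c("qname", "flag", "rname", "strand", "pos", "mapq", "cigar"),
    tag = "SA",
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE)
  )
  if (!is.null(region)) {
    if (!file.exists(paste0(bam, ".bai")))
      stop("region query requires a BAM index: ", paste0(bam, ".bai"))
    param_args$which <- region  # a GRanges (or anything ScanBamParam accepts)
  }
  param <- do.call(Rsamtools::ScanBamParam, param_args)
  res <- Rsamtools::scanBam(bam, param = param)
  qname <- unlist(lapply(res, function(x) x$qname), use.names = FALSE)
  flag <- unlist(lapply(res, function(x) x$flag), use.names = FALSE)
  rname <- unlist(lapply(res, function(x) as.character(x$rname)), use.names = FALSE)
  strand <- unlist(lapply(res, function(x) as.character(x$strand)), use.names = FALSE)
  pos <- unlist(lapply(res, function(x) x$pos), use.names = FALSE)
  mapq <- unlist(lapply(res, function(x) x$mapq), use.names = FALSE)
  cigar <- unlist(lapply(res, function(x) x$cigar), use.names = FALSE)
  sa <- unlist(lapply(res, function(x) {
    s <- x$tag$SA
    if (is.null(s)) rep(NA_character_, length(x$qname)) else as.character(s)
  }), use.names = FALSE)
  aln <- data.frame(
    read_name = qname, flag = flag, chrom = rname,
    ref_start = pos - 1L, mapq = mapq, cigar = cigar,
    orient = ifelse(strand == "-", "-", "+"),
    is_supplementary = bitwAnd(flag, 0x800L) > 0L,
    sa = sa, stringsAsFactors = FALSE
  )
  keep <- !is.na(aln$mapq) & aln$mapq >= cfg$min_mapq & !is.na(aln$ref_start)
  aln <- aln[keep, , drop = FALSE]
  aln <- aln[order(aln$read_name, aln$chrom, aln$ref_start, aln$flag), , drop = FALSE]
  rownames(aln) <- NULL
  aln
}

# Convert a .sam fixture to a temporary BAM; pass BAM through untouched.
sam_as_bam <- function(path) {
  if (!grepl("\\.sam$", path, ignore.case = TRUE)) return(path)
  dest <- tempfile(fileext = "")
  suppressMessages(
    Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                     indexDestination = FALSE)
  )
}

#' Chromosome lengths from an alignment header
#'
#' @param path BAM or SAM path.
#' @return Named numeric vector of contig lengths.
#' @export
alignment_chrom_lengths <- function(path) {
  bam <- sam_as_bam(path)
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  stats::setNames(as.numeric(hdr), names(hdr))
}

#' Split segments of one read, in original-read orientation
#'
#' Builds one segment per alignment record (primary + supplementary) of a
#' read. Query intervals of reverse-strand records are flipped with the full
#' read length so read-adjacency ordering is meaningful. When a read has only
#' its primary record but carries an SA tag, segments are reconstructed from
#' the tag instead (records below the MAPQ threshold are dropped either way).
#'
#' @param recs Data.frame rows (as from [read_alignments()]) for one read.
#' @param cfg An [extraction_config()] (MAPQ filter for SA-derived segments).
#' @return Data.frame with columns `chrom`, `ref_start`, `ref_end`,
#'   `read_start`, `read_end` (all 0-based half-open), `orient`, `read_name`,
#'   sorted by `read_start`.
#' @export
split_segments <- function(recs, cfg = extraction_config()) {
  rn <- recs$read_name[1]
  rows <- list()
  add_segment <- function(chrom, pos0, orient, cigar_str, mapq) {
    cig <- parse_cigar(cigar_str)
    if (is.null(cig) || mapq < cfg$min_mapq) return(invisible(NULL))
    lead <- 0L
    i <- 1L
    while (i <= length(cig$ops) && cig$ops[i] %in% c("S", "H")) {
      lead <- lead + cig$lengths[i]; i <- i + 1L
    }
    aligned_q <- sum(cig$lengths[cig$ops %in% c("M", "I", "=", "X")])
    total <- cigar_query_len(cig)
    rs <- lead; re <- lead + aligned_q
    if (orient == "-") {
      tmp <- rs; rs <- total - re; re <- total - tmp
    }
    rows[[length(rows) + 1L]] <<- data.frame(
      chrom = chrom, ref_start = pos0, ref_end = pos0 + cigar_ref_span(cig),
      read_start = rs, read_end = re, orient = orient, read_name = rn,
      stringsAsFactors = FALSE
    )
  }
  use_sa <- nrow(recs) == 1L && !is.na(recs$sa[1]) && nzchar(recs$sa[1])
  for (k in seq_len(nrow(recs))) {
    add_segment(recs$chrom[k], recs$ref_start[k], recs$orient[k],
                recs$cigar[k], recs$mapq[k])
  }
  if (use_sa) {
    for (ent in strsplit(recs$sa[1], ";", fixed = TRUE)[[1]]) {
      if (!nzchar(ent)) next
      f <- strsplit(ent, ",", fixed = TRUE)[[1]]
      add_segment(f[1], as.integer(f[2]) - 1L, f[3], f[4], as.integer(f[5]))
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(chrom = character(), ref_start = numeric(),
                      ref_end = numeric(), read_start = numeric(),
                      read_end = numeric(), orient = character(),
                      read_name = character(), stringsAsFactors = FALSE))
  }
  segs <- do.call(rbind, rows)
  segs <- segs[order(segs$read_start, segs$ref_start), , drop = FALSE]
  rownames(segs) <- NULL
  segs
}
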