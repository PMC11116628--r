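# VCF 4.2 output for deletion calls, and re-reading of such files for
# evaluation. The anchor-base convention is used: POS is the 1-based position
# of the base immediately before the deletion, so POS equals the 0-based
# deletion start numerically; END = POS + SVLEN magnitude is the 1-based
# inclusive last deleted base.

#' Write deletion calls as VCF 4.2
#'
#' One `<DEL>` record per call with `SVTYPE=DEL`, negative `SVLEN`, `END` and
#' `SUPPORT` in INFO, `FILTER = PASS` and a `./.` placeholder sample column
#' (no genotyping is performed). The file is written to a temporary path and
#' renamed into place, so a failure leaves no partial VCF.
#'
#' @param calls Calls data.frame (see [call_deletions()]), sorted by
#'   `(chrom, start)`.
#' @param path Output path.
#' @param reference Optional reference FASTA path or `DNAStringSet`; provides
#'   the anchor REF base (falls back to `"N"` with a warning when a
#'   chromosome is absent, silently when no reference is given).
#' @param chrom_lengths Optional named vector for `##contig` header lines.
#' @param sample Sample column name.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, path, reference = NULL, chrom_lengths = NULL,
                      sample = "SAMPLE") {
  if (nrow(calls) > 0) {
    ord <- order(calls$chrom, calls$start)
    if (any(ord != seq_len(nrow(calls))))
      stop("calls must be sorted by (chrom, start)")
  }
  ref <- NULL
  if (!is.null(reference)) {
    ref <- if (is.character(reference)) {
      Biostrings::readDNAStringSet(reference)
    } else reference
    names(ref) <- sub("\\s.*$", "", names(ref))
  }
  hdr <- c(
    "##fileformat=VCFv4.2",
    paste0("##source=delclust-", as.character(utils::packageVersion("delclust"))),
    '##ALT=<ID=DEL,Description="Deletion">',
    '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="Type of structural variant">',
    '##INFO=<ID=SVLEN,Number=1,Type=Integer,Description="Length of the variant (negative for deletions)">',
    '##INFO=<ID=END,Number=1,Type=Integer,Description="1-based inclusive end of the deleted interval">',
    '##INFO=<ID=SUPPORT,Number=1,Type=Integer,Description="Number of supporting deletion signatures">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype (not called)">'
  )
  if (!is.null(chrom_lengths)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", names(chrom_lengths),
                          as.integer(chrom_lengths)))
  }
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                        "INFO", "FORMAT", sample), collapse = "\t"))
  recs <- character(0)
  if (nrow(calls) > 0) {
    pos <- as.integer(calls$start)         # 1-based anchor base == 0-based start
    refbase <- vapply(seq_len(nrow(calls)), function(k) {
      chrom <- calls$chrom[k]
      if (is.null(ref) || pos[k] < 1L) return("N")
      if (!chrom %in% names(ref)) {
        warning("chromosome ", chrom, " absent from reference; REF set to N",
                call. = FALSE)
        return("N")
      }
      as.character(Biostrings::subseq(ref[[chrom]], pos[k], pos[k]))
    }, character(1))
    support <- if ("support" %in% names(calls)) calls$support else rep(NA, nrow(calls))
    ids <- if ("id" %in% names(calls)) calls$id else sprintf("DEL%05d", seq_len(nrow(calls)))
    info <- sprintf("SVTYPE=DEL;SVLEN=%d;END=%d%s",
                    -as.integer(calls$svlen),
                    pos + as.integer(calls$svlen),
                    ifelse(is.na(support), "",
                           sprintf(";SUPPORT=%d", as.integer(support))))
    recs <- paste(calls$chrom, pos, ids, refbase, "<DEL>", ".", "PASS", info,
                  "GT", "./.", sep = "\t")
  }
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".vcf.tmp")
  writeLines(c(hdr, recs), tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' Read deletion calls back from a VCF
#'
#' Accepts the VCFs this package writes (and any deletion VCF carrying SVLEN
#' or END in INFO, with the same anchor-base convention).
#'
#' @param path VCF path.
#' @return Calls data.frame with 0-based `start`, positive `svlen`, `end`,
#'   `support` (NA when absent) and `id`.
#' @export
read_vcf_calls <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    return(data.frame(chrom = character(), start = numeric(), svlen = numeric(),
                      end = numeric(), support = numeric(), id = character(),
                      stringsAsFactors = FALSE))
  }
  svlen <- suppressWarnings(as.numeric(vcfR::extract.info(v, "SVLEN")))
  endi <- suppressWarnings(as.numeric(vcfR::extract.info(v, "END")))
  support <- suppressWarnings(as.numeric(vcfR::extract.info(v, "SUPPORT")))
  pos <- as.numeric(fix$POS)
  len <- ifelse(!is.na(svlen), abs(svlen), endi - pos)
  data.frame(chrom = fix$CHROM, start = pos, svlen = len, end = pos + len,
             support = support, id = fix$ID, stringsAsFactors = FALSE)
}
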