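# Truvari-style benchmarking of a deletion call set against a truth set:
# breakpoint-distance plus size-similarity matching, overall and stratified
# by the standard deletion-length bands. This is a lightweight emulation of
# Truvari's default matching (refdist + size ratio); reciprocal overlap,
# sequence comparison and genotype checks are not emulated.

#' Expand a truth table into one row per truth allele
#'
#' Homozygous loci and single-haplotype (het_same) loci contribute one truth
#' allele; heterozygous loci with two different allele lengths contribute two.
#'
#' @param truth Truth data.frame (`chrom`, `start`, `len1`, `len2`,
#'   `zygosity`).
#' @return Data.frame with `chrom`, `start`, `svlen`.
#' @export
expand_truth <- function(truth) {
  if (nrow(truth) == 0L) {
    return(data.frame(chrom = character(), start = numeric(),
                      svlen = numeric(), stringsAsFactors = FALSE))
  }
  a1 <- data.frame(chrom = truth$chrom, start = truth$start,
                   svlen = truth$len1, stringsAsFactors = FALSE)
  two <- truth$zygosity == "het_difflen" & truth$len2 > 0 &
    truth$len2 != truth$len1
  a2 <- data.frame(chrom = truth$chrom[two], start = truth$start[two],
                   svlen = truth$len2[two], stringsAsFactors = FALSE)
  out <- rbind(a1, a2)
  out <- out[order(out$chrom, out$start, out$svlen), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Match calls to truth alleles and report precision/recall/F1
#'
#' Greedy one-to-one matching: a call may match a truth allele on the same
#' chromosome when their starts differ by at most `refdist` and their size
#' similarity `min(len)/max(len)` is at least `pctsize`. Candidate pairs are
#' taken in order of increasing start distance, so each truth allele is
#' claimed by its closest eligible call.
#'
#' @param calls Calls data.frame (`chrom`, `start`, `svlen`), or a VCF path.
#' @param truth Truth alleles (`chrom`, `start`, `svlen`) as from
#'   [expand_truth()], a truth data.frame with `len1`/`len2` columns, or a
#'   VCF/TSV path.
#' @param cfg A [match_config()].
#' @return List of class `eval_report`: `tp`, `fp`, `fn`, `precision`,
#'   `recall`, `f1` (undefined ratios are `NA`), and the matched pair table.
#' @export
match_calls <- function(calls, truth, cfg = match_config()) {
  calls <- as_call_table(calls)
  truth <- as_truth_alleles(truth)
  nc <- nrow(calls); nt <- nrow(truth)
  pairs <- NULL
  if (nc > 0 && nt > 0) {
    cand <- list()
    for (ti in seq_len(nt)) {
      same <- which(calls$chrom == truth$chrom[ti] &
                    abs(calls$start - truth$start[ti]) <= cfg$refdist)
      for (ci in same) {
        ratio <- min(calls$svlen[ci], truth$svlen[ti]) /
          max(calls$svlen[ci], truth$svlen[ti])
        if (ratio >= cfg$pctsize) {
          cand[[length(cand) + 1L]] <- c(
            dist = abs(calls$start[ci] - truth$start[ti]), ci = ci, ti = ti)
        }
      }
    }
    if (length(cand)) {
      cand <- do.call(rbind, cand)
      cand <- cand[order(cand[, "dist"], cand[, "ci"], cand[, "ti"]), ,
                   drop = FALSE]
      used_c <- logical(nc); used_t <- logical(nt)
      keep <- logical(nrow(cand))
      for (k in seq_len(nrow(cand))) {
        ci <- cand[k, "ci"]; ti <- cand[k, "ti"]
        if (!used_c[ci] && !used_t[ti]) {
          used_c[ci] <- TRUE; used_t[ti] <- TRUE; keep[k] <- TRUE
        }
      }
      pairs <- as.data.frame(cand[keep, , drop = FALSE])
    }
  }
  tp <- if (is.null(pairs)) 0L else nrow(pairs)
  fp <- nc - tp
  fn <- nt - tp
  precision <- if (nc > 0) tp / nc else NA_real_
  recall <- if (nt > 0) tp / nt else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && (precision + recall) > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  structure(list(tp = tp, fp = fp, fn = fn, precision = precision,
                 recall = recall, f1 = f1, pairs = pairs),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("TP %d  FP %d  FN %d  precision %s  recall %s  F1 %s\n",
              x$tp, x$fp, x$fn, fmt_frac(x$precision), fmt_frac(x$recall),
              fmt_frac(x$f1)))
  invisible(x)
}

fmt_frac <- function(x) if (is.na(x)) "NA" else sprintf("%.4f", x)

#' Per-length-band precision/recall/F1
#'
#' Calls and truth alleles are assigned to the band containing their length
#' (half-open `[lo, hi)`; the last band is open-ended, and any length outside
#' all bands falls into it) and matched within band.
#'
#' @param calls,truth As in [match_calls()].
#' @param cfg A [match_config()].
#' @param bands List of `c(lo, hi)` length bands, sorted and disjoint.
#' @return Named list of `eval_report`, one per band.
#' @export
stratify_by_length <- function(calls, truth, cfg = match_config(),
                               bands = list(c(50, 200), c(200, 500),
                                            c(500, 1000), c(1000, 2000),
                                            c(2000, Inf))) {
  calls <- as_call_table(calls)
  truth <- as_truth_alleles(truth)
  los <- vapply(bands, `[`, numeric(1), 1L)
  band_of <- function(len) pmin(pmax(findInterval(len, los), 1L), length(bands))
  cb <- band_of(calls$svlen)
  tb <- band_of(truth$svlen)
  reports <- lapply(seq_along(bands), function(b) {
    match_calls(calls[cb == b, , drop = FALSE],
                truth[tb == b, , drop = FALSE], cfg)
  })
  names(reports) <- vapply(bands, function(b) {
    if (is.finite(b[2])) sprintf("[%g,%g)", b[1], b[2]) else sprintf("[%g,+)", b[1])
  }, character(1))
  reports
}

as_call_table <- function(x) {
  if (is.character(x)) x <- read_vcf_calls(x)
  stopifnot(all(c("chrom", "start", "svlen") %in% names(x)))
  x
}

as_truth_alleles <- function(x) {
  if (is.character(x)) {
    x <- if (grepl("\\.vcf(\\.gz)?$", x)) read_vcf_calls(x) else read_truth(x)
  }
  if (all(c("len1", "zygosity") %in% names(x))) x <- expand_truth(x)
  stopifnot(all(c("chrom", "start", "svlen") %in% names(x)))
  x
}

#' Read a truth TSV written by [simulate()]
#'
#' @param path TSV path with columns `chrom`, `start`, `len1`, `len2`,
#'   `zygosity`.
#' @return Truth data.frame.
#' @export
read_truth <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
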