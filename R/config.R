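#' Signature-extraction configuration
#'
#' Thresholds used while turning alignments into deletion signatures.
#'
#' @param min_mapq Minimum mapping quality; alignment records below this are
#'   discarded (applies per record, so a low-quality supplementary record is
#'   dropped even when its primary passes).
#' @param min_cigar_del Exclusive lower bound (bp) on CIGAR `D` runs that count
#'   as deletion evidence; a run must be strictly longer than this.
#' @param max_merge_gap Inclusive upper bound (bp) on the reference gap between
#'   two same-read signatures for them to be merged into one.
#' @param min_split_del,max_split_del Inclusive bounds (bp) on the implied
#'   deletion length (`Distance`) between two read-adjacent split segments.
#' @return A list of class `extraction_config`.
#' @export
extraction_config <- function(min_mapq = 20, min_cigar_del = 30,
                              max_merge_gap = 30, min_split_del = 50,
                              max_split_del = 100000) {
  stopifnot(
    is.numeric(min_mapq), min_mapq >= 0,
    is.numeric(min_cigar_del), min_cigar_del >= 0,
    is.numeric(max_merge_gap), max_merge_gap >= 0,
    is.numeric(min_split_del), min_split_del >= 0,
    min_split_del < max_split_del
  )
  structure(list(
    min_mapq = min_mapq, min_cigar_del = min_cigar_del,
    max_merge_gap = max_merge_gap, min_split_del = min_split_del,
    max_split_del = max_split_del
  ), class = "extraction_config")
}

#' Two-layer clustering configuration
#'
#' @param size_split Length threshold (bp) separating small from large
#'   candidate deletion sites; `svlen >= size_split` is large.
#' @param window Sliding-window width (bp) for layer-1 clustering of large
#'   sites.
#' @param rate_threshold Layer-2 merge criterion: the two final sub-clusters
#'   are merged when their length-difference rate is strictly below this.
#' @param chrom_lengths Optional named numeric vector of chromosome lengths
#'   (bp), used to clip coverage profiles and to emit VCF contig headers.
#' @return A list of class `clustering_config`.
#' @export
clustering_config <- function(size_split = 2000, window = 1500,
                              rate_threshold = 0.20, chrom_lengths = NULL) {
  stopifnot(
    is.numeric(size_split), size_split > 0,
    is.numeric(window), window > 0,
    is.numeric(rate_threshold), rate_threshold > 0, rate_threshold < 1
  )
  if (!is.null(chrom_lengths)) {
    stopifnot(is.numeric(chrom_lengths), !is.null(names(chrom_lengths)))
  }
  structure(list(
    size_split = size_split, window = window,
    rate_threshold = rate_threshold, chrom_lengths = chrom_lengths
  ), class = "clustering_config")
}

#' Support-filter configuration
#'
#' The default of 10 supporting signatures suits ~69X noisy (CLR-style) long
#' reads; documented presets are 10/5/3/2/2 for ~69X/35X/20X/10X/5X CLR and
#' 3/2/1 for 28X/10X/5X HiFi (CCS) coverage.
#'
#' @param min_support Threshold `T`: a lone candidate cluster needs support
#'   `>= T`; when a locus yields two candidate clusters (two alleles), each
#'   needs support `>= T/2` (real-valued half).
#' @param unique_reads If `TRUE`, support counts distinct read names rather
#'   than signatures.
#' @return A list of class `calling_config`.
#' @export
calling_config <- function(min_support = 10, unique_reads = FALSE) {
  stopifnot(is.numeric(min_support), min_support >= 1,
            is.logical(unique_reads), length(unique_reads) == 1L)
  structure(list(min_support = min_support, unique_reads = unique_reads),
            class = "calling_config")
}

#' Call-vs-truth matching configuration (Truvari-style defaults)
#'
#' @param refdist Maximum breakpoint-start distance (bp) for a match.
#' @param pctsize Minimum size similarity `min(len)/max(len)` for a match.
#' @return A list of class `match_config`.
#' @export
match_config <- function(refdist = 500, pctsize = 0.7) {
  stopifnot(is.numeric(refdist), refdist >= 0,
            is.numeric(pctsize), pctsize > 0, pctsize <= 1)
  structure(list(refdist = refdist, pctsize = pctsize),
            class = "match_config")
}

#' Synthetic-alignment simulation configuration
#'
#' Defaults emulate a noisy long-read (CLR-style) sequencing run: 8 kb reads
#' and deletion lengths drawn from the five standard benchmarking bands.
#'
#' @param seed Integer seed; all outputs are byte-reproducible from it.
#' @param n_chroms Number of synthetic chromosomes.
#' @param chrom_length Length (bp) of each chromosome.
#' @param n_deletions Deletion loci per chromosome.
#' @param length_bands List of `c(lo, hi)` bands (bp, half-open) the implanted
#'   lengths cycle through.
#' @param coverage Total fold coverage (split evenly across two haplotypes).
#' @param read_length Read length (bp).
#' @param frag_prob Probability that a spanning read's single `D` op is
#'   emitted as two `D` ops separated by a 10 bp matched gap, mimicking
#'   sequencing-error fragmentation of one deletion.
#' @param het_frac Fraction of loci made heterozygous with two different
#'   allele lengths (the second allele is twice the first).
#' @param split_rep_threshold Deletions at least this long (bp) are emitted as
#'   primary + supplementary split records instead of a `D` op.
#' @param spacing Minimum gap (bp) between the end of one locus and the start
#'   of the next (kept at 3x the clustering window so loci never interact).
#' @param noise_frac Extra sub-threshold (MAPQ 10) records to inject, as a
#'   fraction of the real read count.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1, n_chroms = 1, chrom_length = 1e6,
                       n_deletions = 10,
                       length_bands = list(c(50, 200), c(200, 500),
                                           c(500, 1000), c(1000, 2000),
                                           c(2000, 10000)),
                       coverage = 20, read_length = 8000, frag_prob = 0,
                       het_frac = 0, split_rep_threshold = 2000,
                       spacing = 4500, noise_frac = 0) {
  stopifnot(
    is.numeric(seed), length(seed) == 1L,
    n_chroms >= 1, chrom_length > 0, n_deletions >= 0,
    coverage > 0, read_length > 0,
    frag_prob >= 0, frag_prob <= 1, het_frac >= 0, het_frac <= 1,
    split_rep_threshold > 0, spacing >= 0, noise_frac >= 0
  )
  los <- vapply(length_bands, `[`, numeric(1), 1L)
  his <- vapply(length_bands, `[`, numeric(1), 2L)
  stopifnot(all(los < his), !is.unsorted(los, strictly = TRUE),
            all(his[-length(his)] <= los[-1]))
  structure(list(
    seed = seed, n_chroms = n_chroms, chrom_length = chrom_length,
    n_deletions = n_deletions, length_bands = length_bands,
    coverage = coverage, read_length = read_length, frag_prob = frag_prob,
    het_frac = het_frac, split_rep_threshold = split_rep_threshold,
    spacing = spacing, noise_frac = noise_frac
  ), class = "sim_config")
}
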