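# Deterministic synthetic-alignment generator. Alignments are synthesized
# directly from the implanted truth (CIGAR, flags and SA tags computed from
# the known deletion coordinates) rather than by running an aligner, which
# keeps fixtures hermetic and byte-reproducible from the seed. Reads tile
# each of two haplotypes; a deletion shorter than `split_rep_threshold`
# appears as a D op in spanning reads (optionally fragmented into two D runs
# separated by a short matched gap), a longer one as primary + supplementary
# same-strand split records whose implied Distance equals the implanted
# length.

#' Generate a truth table of deletion loci
#'
#' Loci cycle through the configured length bands; the first
#' `round(het_frac * n)` loci are heterozygous with a second allele of twice
#' the first allele's length, the rest homozygous. Starts are placed left to
#' right with at least `cfg$spacing` between the end of one locus and the
#' start of the next, read-length margins at both chromosome ends, and
#' seed-determined jitter in between.
#'
#' @param cfg A [sim_config()]. RNG state is the caller's (see [simulate()]).
#' @return Truth data.frame: `chrom`, `start` (0-based), `len1`, `len2`
#'   (0 = no deletion on haplotype 2), `zygosity`.
#' @export
generate_truth <- function(cfg) {
  out <- list()
  for (ci in seq_len(cfg$n_chroms)) {
    chrom <- paste0("chr", ci)
    n <- cfg$n_deletions
    if (n == 0L) next
    nb <- length(cfg$length_bands)
    band <- cfg$length_bands[((seq_len(n) - 1L) %% nb) + 1L]
    len1 <- vapply(band, function(b) b[1] + floor(stats::runif(1) * (b[2] - b[1])),
                   numeric(1))
    n_het <- round(cfg$het_frac * n)
    zyg <- rep("hom", n)
    len2 <- len1
    if (n_het > 0L) {
      zyg[seq_len(n_het)] <- "het_difflen"
      len2[seq_len(n_het)] <- 2 * len1[seq_len(n_het)]
    }
    maxlen <- pmax(len1, len2)
    margin <- cfg$read_length
    avail <- cfg$chrom_length - 2 * margin - sum(maxlen) - (n - 1) * cfg$spacing
    if (avail < 0) {
      stop("cannot place ", n, " deletions on a ", cfg$chrom_length,
           " bp chromosome with spacing ", cfg$spacing,
           "; reduce n_deletions or lengths")
    }
    u <- stats::runif(n + 1L)
    extra <- floor(avail * u / sum(u))
    starts <- numeric(n)
    pos <- margin + extra[1L]
    for (k in seq_len(n)) {
      starts[k] <- pos
      pos <- pos + maxlen[k] + cfg$spacing + extra[k + 1L]
    }
    out[[ci]] <- data.frame(chrom = chrom, start = starts, len1 = len1,
                            len2 = len2, zygosity = zyg,
                            stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) {
    return(data.frame(chrom = character(), start = numeric(), len1 = numeric(),
                      len2 = numeric(), zygosity = character(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# ops as a two-column matrix: length, op code (character kept separately)
ops_to_cigar <- function(lens, ops) paste0(lens, ops, collapse = "")

# Alignment records (SAM fields) for all reads of one haplotype of one
# chromosome. `dels` has columns start, len (sorted by start). Reads tile
# the haplotype (reference minus deletions) every `step` bp from `phase`.
hap_records <- function(chrom, chrom_len, dels, hap, cov_hap, rl, phase,
                        frag_prob, split_thr, read_prefix = NULL) {
  nd <- nrow(dels)
  hap_len <- chrom_len - if (nd) sum(dels$len) else 0
  if (hap_len < rl) stop("haplotype shorter than read length")
  step <- max(1L, as.integer(floor(rl / cov_hap)))
  h0s <- seq.int(phase, hap_len - rl, by = step)
  before <- if (nd) cumsum(c(0, dels$len))[seq_len(nd)] else numeric(0)
  hjs <- if (nd) dels$start - before else numeric(0)
  if (is.null(read_prefix)) read_prefix <- sprintf("%s_h%d", chrom, hap)
  recs <- vector("list", length(h0s))
  for (ri in seq_along(h0s)) {
    h0 <- h0s[ri]
    qname <- sprintf("%s_r%05d", read_prefix, ri)
    inner <- which(hjs > h0 & hjs < h0 + rl)
    ref0 <- h0 + if (nd) sum(dels$len[hjs <= h0]) else 0
    # build segments: each a list(ref_start, read_from, lens, ops)
    segs <- list()
    cur <- list(ref_start = ref0, read_from = 0, lens = numeric(0), ops = character(0))
    prev_rel <- 0
    refpos <- ref0
    for (j in inner) {
      rel <- hjs[j] - h0
      mlen <- rel - prev_rel
      if (mlen > 0) {
        cur$lens <- c(cur$lens, mlen); cur$ops <- c(cur$ops, "M")
        refpos <- refpos + mlen
      }
      if (dels$len[j] >= split_thr) {
        cur$read_to <- rel
        segs[[length(segs) + 1L]] <- cur
        refpos <- refpos + dels$len[j]
        cur <- list(ref_start = refpos, read_from = rel,
                    lens = numeric(0), ops = character(0))
      } else {
        cur$lens <- c(cur$lens, dels$len[j]); cur$ops <- c(cur$ops, "D")
        refpos <- refpos + dels$len[j]
      }
      prev_rel <- rel
    }
    if (rl - prev_rel > 0) {
      cur$lens <- c(cur$lens, rl - prev_rel); cur$ops <- c(cur$ops, "M")
    }
    cur$read_to <- rl
    segs[[length(segs) + 1L]] <- cur
    segs <- lapply(segs, fragment_dels, frag_prob = frag_prob)
    # render SAM fields
    fields <- lapply(seq_along(segs), function(si) {
      s <- segs[[si]]
      lead <- s$read_from; trail <- rl - s$read_to
      lens <- s$lens; ops <- s$ops
      if (lead > 0) { lens <- c(lead, lens); ops <- c("S", ops) }
      if (trail > 0) { lens <- c(lens, trail); ops <- c(ops, "S") }
      list(qname = qname, flag = if (si == 1L) 0L else 2048L, chrom = chrom,
           pos = s$ref_start + 1, cigar = ops_to_cigar(lens, ops))
    })
    if (length(fields) > 1L) {
      sa_of <- function(f) sprintf("%s,%d,+,%s,60,0;", f$chrom, f$pos, f$cigar)
      for (si in seq_along(fields)) {
        others <- fields[-si]
        fields[[si]]$sa <- paste0(vapply(others, sa_of, character(1)),
                                  collapse = "")
      }
    }
    recs[[ri]] <- fields
  }
  unlist(recs, recursive = FALSE)
}

# With probability frag_prob, split a D op of length L >= 100 into
# floor(L/2) D + 10 M + (L - 10 - floor(L/2)) D, borrowing the 10 matched
# bases from the following M so query-consuming ops still sum to the read
# length.
fragment_dels <- function(seg, frag_prob) {
  if (frag_prob <= 0) return(seg)
  i <- 1L
  while (i <= length(seg$ops)) {
    L <- seg$lens[i]
    if (seg$ops[i] == "D" && L >= 100 &&
        i < length(seg$ops) && seg$ops[i + 1L] == "M" && seg$lens[i + 1L] > 11 &&
        stats::runif(1) < frag_prob) {
      l1 <- floor(L / 2); l2 <- L - 10 - l1
      seg$lens <- append(seg$lens, c(10, l2), after = i)
      seg$ops <- append(seg$ops, c("M", "D"), after = i)
      seg$lens[i] <- l1
      seg$lens[i + 3L] <- seg$lens[i + 3L] - 10
      i <- i + 3L
    }
    i <- i + 1L
  }
  seg
}

sam_record_line <- function(f, mapq = 60L) {
  tags <- if (!is.null(f$sa)) paste0("\tSA:Z:", f$sa) else ""
  sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t*\t*%s",
          f$qname, f$flag, f$chrom, f$pos, mapq, f$cigar, tags)
}

#' Build a heterozygous different-length deletion locus
#'
#' Constructs the truth record and the spanning reads for one locus at which
#' the two homologous chromosomes carry deletions of different lengths — the
#' configuration layer-2 clustering exists to resolve. The two haplotypes are
#' tiled identically, so exactly half the locus reads carry each allele,
#' interleaved deterministically in coordinate order.
#'
#' @param cfg A [sim_config()].
#' @param chrom Chromosome name.
#' @param start 0-based deletion start.
#' @param len1,len2 Allele lengths (bp); must differ.
#' @return List with `truth` (one-row data.frame) and `records` (list of SAM
#'   field lists, one per alignment record).
#' @export
make_het_locus <- function(cfg, chrom, start, len1, len2) {
  stopifnot(len1 > 0, len2 > 0)
  if (len1 == len2) stop("make_het_locus requires two different allele lengths")
  truth <- data.frame(chrom = chrom, start = start, len1 = len1, len2 = len2,
                      zygosity = "het_difflen", stringsAsFactors = FALSE)
  cov_hap <- cfg$coverage / 2
  recs <- c(
    hap_records(chrom, cfg$chrom_length, data.frame(start = start, len = len1),
                1L, cov_hap, cfg$read_length, 0L, cfg$frag_prob,
                cfg$split_rep_threshold),
    hap_records(chrom, cfg$chrom_length, data.frame(start = start, len = len2),
                2L, cov_hap, cfg$read_length, 0L, cfg$frag_prob,
                cfg$split_rep_threshold)
  )
  # keep only reads that span the locus (their CIGAR carries the D run, or a
  # soft clip for split representation); pure-M reads elsewhere are dropped
  keep <- vapply(recs, function(f) grepl("[DS]", f$cigar), logical(1))
  list(truth = truth, records = recs[keep])
}

#' Simulate a reference, truth set and alignment file
#'
#' All outputs are byte-reproducible from `cfg$seed`. The reference is i.i.d.
#' uniform ACGT (the caller uses no sequence-level information). Outputs:
#' `reference.fa` (+ `.fai`), `truth.tsv`, `truth.vcf` (same anchor-base
#' convention as the caller's VCF), and `reads.sam` (coordinate-sorted;
#' optionally also BAM + index).
#'
#' @param cfg A [sim_config()].
#' @param outdir Output directory (created if needed).
#' @param truth Optional truth data.frame (as from [generate_truth()]) to use
#'   instead of generating one — lets tests implant specific loci.
#' @param write_bam Also convert to indexed BAM.
#' @return List with output `paths`, the `truth` table and `cfg`.
#' @export
simulate <- function(cfg = sim_config(), outdir = tempfile("sim"),
                     truth = NULL, write_bam = FALSE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  withr::with_seed(cfg$seed, {
    if (is.null(truth)) truth <- generate_truth(cfg)
    chroms <- paste0("chr", seq_len(cfg$n_chroms))
    chrom_lengths <- stats::setNames(rep(cfg$chrom_length, cfg$n_chroms), chroms)
    # reference
    seqs <- Biostrings::DNAStringSet(vapply(chroms, function(ch) {
      paste(sample(c("A", "C", "G", "T"), cfg$chrom_length, replace = TRUE),
            collapse = "")
    }, character(1)))
    names(seqs) <- chroms
    ref_path <- file.path(outdir, "reference.fa")
    Biostrings::writeXStringSet(seqs, ref_path, width = 80L)
    Rsamtools::indexFa(ref_path)
    # reads
    cov_hap <- cfg$coverage / 2
    step <- max(1L, as.integer(floor(cfg$read_length / cov_hap)))
    all_recs <- list()
    for (ch in chroms) {
      tt <- truth[truth$chrom == ch, , drop = FALSE]
      tt <- tt[order(tt$start), , drop = FALSE]
      d1 <- data.frame(start = tt$start, len = tt$len1)
      d1 <- d1[d1$len > 0, , drop = FALSE]
      d2 <- data.frame(start = tt$start, len = tt$len2)
      d2 <- d2[d2$len > 0, , drop = FALSE]
      all_recs <- c(all_recs,
        hap_records(ch, cfg$chrom_length, d1, 1L, cov_hap, cfg$read_length,
                    0L, cfg$frag_prob, cfg$split_rep_threshold),
        hap_records(ch, cfg$chrom_length, d2, 2L, cov_hap, cfg$read_length,
                    as.integer(floor(step / 2)), cfg$frag_prob,
                    cfg$split_rep_threshold))
    }
    lines <- vapply(all_recs, sam_record_line, character(1))
    if (cfg$noise_frac > 0) {
      n_noise <- round(cfg$noise_frac * length(all_recs))
      for (k in seq_len(n_noise)) {
        ch <- chroms[1 + (k - 1) %% length(chroms)]
        pos <- 1 + floor(stats::runif(1) * (cfg$chrom_length - 1000))
        lines <- c(lines, sam_record_line(list(
          qname = sprintf("noise_r%05d", k), flag = 0L, chrom = ch,
          pos = pos, cigar = "1000M"), mapq = 10L))
      }
    }
    # coordinate-sort the full record set (including noise)
    parts <- strsplit(lines, "\t", fixed = TRUE)
    fields_chrom <- vapply(parts, `[`, character(1), 3L)
    fields_pos <- as.integer(vapply(parts, `[`, character(1), 4L))
    lines <- lines[order(match(fields_chrom, chroms), fields_pos)]
    sam_path <- file.path(outdir, "reads.sam")
    hdr <- c("@HD\tVN:1.6\tSO:coordinate",
             sprintf("@SQ\tSN:%s\tLN:%d", chroms, as.integer(chrom_lengths)),
             "@PG\tID:delclust\tPN:delclust")
    writeLines(c(hdr, lines), sam_path)
    bam_path <- NULL
    if (write_bam) {
      bam_path <- suppressMessages(
        Rsamtools::asBam(sam_path, file.path(outdir, "reads"),
                         overwrite = TRUE, indexDestination = TRUE))
    }
    # truth outputs
    tsv_path <- file.path(outdir, "truth.tsv")
    utils::write.table(truth, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    alleles <- expand_truth(truth)
    tv <- data.frame(chrom = alleles$chrom, start = alleles$start,
                     svlen = alleles$svlen, end = alleles$start + alleles$svlen,
                     support = NA, id = sprintf("TRUTH%04d", seq_len(nrow(alleles))),
                     stringsAsFactors = FALSE)
    tv <- tv[order(tv$chrom, tv$start, tv$svlen), , drop = FALSE]
    tv$id <- sprintf("TRUTH%04d", seq_len(nrow(tv)))
    vcf_path <- file.path(outdir, "truth.vcf")
    write_vcf(tv, vcf_path, reference = seqs, chrom_lengths = chrom_lengths)
    list(paths = list(reference = ref_path, sam = sam_path, bam = bam_path,
                      truth_tsv = tsv_path, truth_vcf = vcf_path),
         truth = truth, chrom_lengths = chrom_lengths, config = cfg)
  })
}
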