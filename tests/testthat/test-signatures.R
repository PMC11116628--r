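test_that("CIGAR walk emits one signature per D run above the length gate", {
  cfg <- extraction_config()
  s <- extract_cigar_signatures("chr1", 1000, "100M50D100M", "r1", cfg)
  expect_equal(s[, c("start", "svlen", "end")],
               data.frame(start = 1100, svlen = 50, end = 1150))
  expect_equal(s$source, "cigar")

  # a 20 bp run is not > 30
  expect_equal(nrow(extract_cigar_signatures("chr1", 1000, "100M20D100M", "r1", cfg)), 0L)

  # soft clips consume no reference; multiple D runs in reference order
  s <- extract_cigar_signatures("chr1", 0, "10S50M40D50M60D50M", "r1", cfg)
  expect_equal(s$start, c(50, 140))
  expect_equal(s$svlen, c(40, 60))
  expect_equal(s$end, c(90, 200))

  # boundary: exactly 30 is excluded, 31 kept
  expect_equal(nrow(extract_cigar_signatures("chr1", 0, "10M30D10M", "r", cfg)), 0L)
  expect_equal(nrow(extract_cigar_signatures("chr1", 0, "10M31D10M", "r", cfg)), 1L)
})

test_that("malformed CIGARs are skipped with a warning", {
  expect_warning(
    s <- extract_cigar_signatures("chr1", 0, "10M5Q10M", "bad"),
    "skipping record"
  )
  expect_equal(nrow(s), 0L)
})

test_that("intra-read merge follows the gap rule, cascades, and is idempotent", {
  cfg <- extraction_config()
  m <- merge_intra_read(sig_df(c(100, 170), c(50, 40), read = c("r", "r")), cfg)
  expect_equal(m[, c("start", "svlen", "end")],
               data.frame(start = 100, svlen = 90, end = 210))

  # gap = 0 excluded by the strict inequality
  s0 <- sig_df(c(100, 150), c(50, 40), read = c("r", "r"))
  expect_equal(merge_intra_read(s0, cfg), s0)

  # gap = 31 above the bound
  s31 <- sig_df(c(100, 181), c(50, 40), read = c("r", "r"))
  expect_equal(merge_intra_read(s31, cfg), s31)

  # cascade: the merged signature merges again with the next
  m3 <- merge_intra_read(sig_df(c(100, 170, 230), c(50, 40, 60),
                                read = rep("r", 3)), cfg)
  expect_equal(m3[, c("start", "svlen", "end")],
               data.frame(start = 100, svlen = 150, end = 290))

  # idempotence
  expect_equal(merge_intra_read(m3, cfg), m3)

  # overlapping signatures (gap < 0) are kept separately
  ov <- sig_df(c(100, 140), c(50, 40), read = c("r", "r"))
  expect_equal(merge_intra_read(ov, cfg), ov)

  expect_error(merge_intra_read(sig_df(c(200, 100), c(50, 50),
                                       read = c("r", "r")), cfg), "sorted")
})

test_that("split-pair Distance arithmetic and gates match the worked example", {
  cfg <- extraction_config()
  segs <- data.frame(
    chrom = "c1", ref_start = c(1000, 2500), ref_end = c(2000, 3500),
    read_start = c(0, 1010), read_end = c(1000, 2010),
    orient = c("+", "+"), read_name = "r1", stringsAsFactors = FALSE)
  s <- extract_split_signatures(segs, cfg)
  expect_equal(s[, c("chrom", "start", "svlen", "end")],
               data.frame(chrom = "c1", start = 2000, svlen = 490, end = 2500))
  expect_equal(s$source, "split")

  # Distance 35 below the [50, 100000] gate
  segs2 <- segs; segs2$ref_start[2] <- 2045; segs2$ref_end[2] <- 3045
  expect_equal(nrow(extract_split_signatures(segs2, cfg)), 0L)

  # opposite orientation pair emits nothing
  segs3 <- segs; segs3$orient[2] <- "-"
  expect_equal(nrow(extract_split_signatures(segs3, cfg)), 0L)

  # different chromosome pair emits nothing
  segs4 <- segs; segs4$chrom[2] <- "c2"
  expect_equal(nrow(extract_split_signatures(segs4, cfg)), 0L)
})

test_that("alignment reader filters MAPQ/unmapped and keeps read groups", {
  path <- write_sam_fixture(list(
    rec("good", pos = 1000, mapq = 60, cigar = "200M"),
    rec("low", pos = 2000, mapq = 10, cigar = "200M"),
    rec("unmapped", chrom = "chr1", pos = 0, mapq = 0, cigar = "*", flag = 4L)
  ))
  aln <- read_alignments(path)
  expect_equal(aln$read_name, "good")

  # primary + supplementary of one read stay grouped; secondary excluded
  path2 <- write_sam_fixture(list(
    rec("r1", pos = 1000, cigar = "100M100S"),
    rec("r1", pos = 5000, cigar = "100S100M", flag = 2048L),
    rec("r1", pos = 9000, cigar = "100S100M", flag = 256L)
  ))
  aln2 <- read_alignments(path2)
  expect_equal(nrow(aln2), 2L)
  expect_equal(aln2$is_supplementary, c(FALSE, TRUE))

  # empty file -> empty stream, no error
  empty <- write_sam_fixture(list())
  expect_equal(nrow(read_alignments(empty)), 0L)
  expect_error(read_alignments(tempfile()), "not found")
})

test_that("collect_signatures pools CIGAR and split evidence deterministically", {
  # one read with a D op, one split read with implied Distance 490
  records <- list(
    rec("cig_read", pos = 1001, cigar = "100M50D100M"),
    rec("split_read", pos = 1001, cigar = "1000M1010S",
        sa = "chr1,2501,+,1010S1000M,60,0;"),
    rec("split_read", pos = 2501, cigar = "1010S1000M", flag = 2048L,
        sa = "chr1,1001,+,1000M1010S,60,0;")
  )
  path <- write_sam_fixture(records)
  sigs <- collect_signatures(path)
  expect_equal(nrow(sigs), 2L)
  expect_equal(sigs$source, c("cigar", "split"))
  expect_equal(sigs$start, c(1100, 2000))
  expect_equal(sigs$svlen, c(50, 490))

  # invariance under permutation of file record order
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    sigs_p <- collect_signatures(write_sam_fixture(records[perm]))
    expect_identical(sigs_p, sigs)
  }
})

test_that("split segments from a lone primary record use the SA tag", {
  path <- write_sam_fixture(list(
    rec("r1", pos = 1001, cigar = "1000M1010S",
        sa = "chr1,2501,+,1010S1000M,60,0;")
  ))
  sigs <- collect_signatures(path)
  expect_equal(nrow(sigs), 1L)
  expect_equal(sigs$svlen, 490)

  # SA segment below the MAPQ threshold is dropped -> no pair, no signature
  path2 <- write_sam_fixture(list(
    rec("r1", pos = 1001, cigar = "1000M1010S",
        sa = "chr1,2501,+,1010S1000M,10,0;")
  ))
  expect_equal(nrow(collect_signatures(path2)), 0L)
})

test_that("reverse-strand split segments are expressed in read orientation", {
  # same deletion geometry as the forward case, both segments on the minus
  # strand: query intervals must be flipped so read-adjacency still pairs them
  path <- write_sam_fixture(list(
    rec("r1", pos = 1001, cigar = "1000M1010S", flag = 16L,
        sa = "chr1,2501,-,1010S1000M,60,0;"),
    rec("r1", pos = 2501, cigar = "1010S1000M", flag = 2064L,
        sa = "chr1,1001,-,1000M1010S,60,0;")
  ))
  segs <- split_segments(read_alignments(path))
  expect_equal(nrow(segs), 2L)
  # flipped: the ref-later segment comes first on the original read
  expect_equal(segs$ref_start[segs$read_start == 0], 2500)
  sigs <- collect_signatures(path)
  expect_equal(sigs$svlen, 490)
})

test_that("lowering thresholds never decreases the signature count", {
  withr::with_seed(11, {
    records <- lapply(seq_len(40), function(k) {
      dlen <- sample(10:120, 1)
      rec(sprintf("r%02d", k), pos = sample(1e5, 1), mapq = sample(0:60, 1),
          cigar = sprintf("100M%dD100M", dlen))
    })
  })
  path <- write_sam_fixture(records)
  n_at <- function(mapq, mindel) {
    nrow(collect_signatures(path, extraction_config(min_mapq = mapq,
                                                    min_cigar_del = mindel)))
  }
  counts_mapq <- vapply(c(60, 40, 20, 0), n_at, numeric(1), mindel = 30)
  expect_true(all(diff(counts_mapq) >= 0))
  counts_del <- vapply(c(100, 50, 30, 10), n_at, numeric(1), mapq = 20)
  expect_true(all(diff(counts_del) >= 0))
})

test_that("error-free spanning reads each yield exactly one exact signature", {
  truth <- data.frame(chrom = "chr1", start = c(30000, 60000),
                      len1 = c(150, 1200), len2 = c(150, 1200),
                      zygosity = "hom")
  res <- simulate(sim_config(seed = 5, chrom_length = 1e5, n_deletions = 2,
                             coverage = 10, read_length = 5000),
                  truth = truth)
  sigs <- collect_signatures(res$paths$sam)
  expect_true(all(sigs$svlen %in% truth$len1))
  expect_true(all(sigs$start %in% truth$start))
  # one signature per (read, locus)
  expect_equal(anyDuplicated(sigs[, c("read_name", "start")]), 0L)
})
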