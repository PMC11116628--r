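test_that("size partition is exhaustive, disjoint, with ties going large", {
  s <- sig_df(c(0, 10, 20, 30), c(100, 1999, 2000, 5000))
  p <- partition_by_size(s)
  expect_equal(p$small$svlen, c(100, 1999))
  expect_equal(p$large$svlen, c(2000, 5000))
  expect_equal(nrow(p$small) + nrow(p$large), nrow(s))

  p2 <- partition_by_size(sig_df(c(0, 1), c(50, 50)))
  expect_equal(nrow(p2$large), 0L)
  p3 <- partition_by_size(sig_df(numeric(0), numeric(0)))
  expect_equal(nrow(p3$small), 0L)
  expect_equal(nrow(p3$large), 0L)
})

test_that("sliding-window sweep clusters with chained window extension", {
  s <- sig_df(c(10000, 10500, 11200, 50000), rep(3000, 4))
  cl <- cluster_sliding_window(s)
  expect_length(cl, 2L)
  expect_equal(nrow(cl[[1]]$members), 3L)
  expect_equal(nrow(cl[[2]]$members), 1L)

  # chained extension: window [1500,3000) is nonempty so 2900 joins
  s2 <- sig_df(c(0, 1400, 2900), rep(3000, 3))
  expect_length(cluster_sliding_window(s2), 1L)
  # the ablation hook reverts to one-window clusters
  expect_length(cluster_sliding_window(s2, extend = FALSE), 2L)

  expect_length(cluster_sliding_window(sig_df(5, 2500)), 1L)
  expect_error(cluster_sliding_window(sig_df(c(100, 50), c(2500, 2500))),
               "sorted")
})

test_that("coverage peaks group exactly the sites in one positive depth run", {
  s <- sig_df(c(100, 100, 100, 400, 400), c(50, 50, 50, 60, 60))
  cl <- cluster_coverage(s)
  expect_length(cl, 2L)
  expect_equal(vapply(cl, function(x) nrow(x$members), numeric(1)), c(3, 2))

  # overlapping spans form one maximal positive run
  s2 <- sig_df(c(100, 140), c(50, 60))
  expect_length(cluster_coverage(s2), 1L)

  expect_length(cluster_coverage(sig_df(numeric(0), numeric(0))), 0L)

  # spans beyond the chromosome end are clipped with a warning
  cfg <- clustering_config(chrom_lengths = c(chr1 = 150))
  expect_warning(cl3 <- cluster_coverage(sig_df(100, 100), cfg), "clipping")
  expect_length(cl3, 1L)
})

test_that("layer 1 combines both methods per chromosome", {
  s <- rbind(sig_df(rep(1000, 5), rep(100, 5)),
             sig_df(rep(50000, 4), rep(3000, 4)))
  cl <- layer1(s)
  expect_length(cl, 2L)
  expect_equal(vapply(cl, `[[`, character(1), "size_class"),
               c("small", "large"))

  # clusters never span chromosomes
  s2 <- rbind(sig_df(rep(1000, 3), rep(100, 3), chrom = "chr1"),
              sig_df(rep(1000, 3), rep(100, 3), chrom = "chr2"))
  cl2 <- layer1(s2)
  expect_length(cl2, 2L)
  expect_equal(sort(vapply(cl2, `[[`, character(1), "chrom")),
               c("chr1", "chr2"))

  # only large sites: the coverage path contributes nothing
  s3 <- sig_df(c(1000, 1100), c(2500, 2600))
  cl3 <- layer1(s3)
  expect_length(cl3, 1L)
  expect_equal(cl3[[1]]$size_class, "large")

  # member multiset conserved; every signature in exactly one cluster
  withr::with_seed(21, {
    s4 <- sig_df(sample(1e5, 60), sample(c(60:300, 2000:4000), 60))
  })
  cl4 <- layer1(s4)
  pooled <- do.call(rbind, lapply(cl4, `[[`, "members"))
  expect_equal(nrow(pooled), nrow(s4))
  key <- function(d) sort(paste(d$start, d$svlen, d$read_name))
  expect_equal(key(pooled), key(s4))
})

test_that("length-difference rate matches the defining formula", {
  expect_equal(length_difference_rate(108, 216), 0.5)
  expect_equal(length_difference_rate(100, 100), 0)
  expect_equal(length_difference_rate(80, 100), 0.2)
  expect_equal(length_difference_rate(216, 108), 0.5) # symmetric
  expect_error(length_difference_rate(0, 100))
})

test_that("agglomerative layer 2 reproduces hand-worked merges", {
  mk <- function(svlens, starts = seq(0, by = 10, length.out = length(svlens))) {
    delclust:::new_sig_cluster("chr1", sig_df(starts, svlens), "small")
  }
  # {100,110,300}: 100 and 110 merge; rate 195/300 >= 0.2 keeps two clusters
  cc <- hierarchical_cluster(mk(c(100, 110, 300)))
  expect_length(cc, 2L)
  expect_equal(sort(cc[[1]]$members$svlen), c(100, 110))
  expect_equal(cc[[2]]$members$svlen, 300)
  expect_equal(cc[[1]]$mean_len, 105)

  # {100,105,110,112}: final rate 8.5/111 < 0.2 merges everything
  cc2 <- hierarchical_cluster(mk(c(100, 105, 110, 112)))
  expect_length(cc2, 1L)
  expect_equal(nrow(cc2[[1]]$members), 4L)

  # degenerate singleton
  cc3 <- hierarchical_cluster(mk(500))
  expect_length(cc3, 1L)
  expect_equal(cc3[[1]]$mean_len, 500)

  # homogeneous lengths collapse to one candidate cluster
  cc4 <- hierarchical_cluster(mk(c(100, 100, 100)))
  expect_length(cc4, 1L)

  # exactly 0.20 stays split ("less than 20%" is strict)
  cc5 <- hierarchical_cluster(mk(c(80, 100)))
  expect_length(cc5, 2L)
  cc6 <- hierarchical_cluster(mk(c(81, 100)))
  expect_length(cc6, 1L)
})

test_that("raising the rate threshold never increases candidate clusters", {
  withr::with_seed(31, {
    for (k in 1:20) {
      n <- sample(2:6, 1)
      cl <- delclust:::new_sig_cluster(
        "chr1", sig_df(sort(sample(1e4, n)), sample(50:5000, n)), "small")
      counts <- vapply(c(0.05, 0.2, 0.5, 0.9), function(r) {
        length(hierarchical_cluster(cl, clustering_config(rate_threshold = r)))
      }, numeric(1))
      expect_true(all(diff(counts) <= 0))
    }
  })
})

test_that("layer-1 clustering is invariant under input permutation", {
  withr::with_seed(41, {
    s <- sig_df(sample(1e5, 50), sample(c(60:500, 2000:6000), 50))
    canon <- function(cl) canon_groups(lapply(cl, function(x) x$members$start))
    ref <- canon(layer1(s))
    for (k in 1:5) {
      expect_equal(canon(layer1(s[sample(nrow(s)), ])), ref)
    }
  })
})
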