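# Two-layer clustering of deletion signatures.
#
# Layer 1 groups signatures by position into "large clusters": large events
# (svlen >= size_split) with a sliding window over sorted starts, small events
# with maximal positive runs of a per-base deletion-depth profile. Layer 2
# agglomerates each large cluster by deletion length into at most two
# candidate clusters (one per haplotype).

#' Partition signatures into small and large size classes
#'
#' @param sigs Signature data.frame.
#' @param cfg A [clustering_config()]; the boundary is `size_split`, with
#'   `svlen >= size_split` assigned to the large class.
#' @return List with elements `small` and `large` (exhaustive, disjoint).
#' @export
partition_by_size <- function(sigs, cfg = clustering_config()) {
  large <- sigs$svlen >= cfg$size_split
  list(small = sigs[!large, , drop = FALSE],
       large = sigs[large, , drop = FALSE])
}

new_sig_cluster <- function(chrom, members, size_class) {
  rownames(members) <- NULL
  structure(list(chrom = chrom, members = members, size_class = size_class),
            class = "sig_cluster")
}

#' @export
print.sig_cluster <- function(x, ...) {
  cat(sprintf("<sig_cluster %s %s: %d member(s), starts %s..%s>\n",
              x$chrom, x$size_class, nrow(x$members),
              format(min(x$members$start)), format(max(x$members$start))))
  invisible(x)
}

#' Sliding-window clustering of large candidate deletion sites
#'
#' The window opens at the first unclustered site's start and captures every
#' site whose start lies in `[w, w + window)`. While the window that begins at
#' the previous window's end still contains a site, those sites join the same
#' cluster and the sweep advances another window (chained extension); an empty
#' window closes the cluster, and the next cluster opens at the next site's
#' start.
#'
#' @param sites Signature data.frame, one chromosome, sorted ascending by
#'   `start`.
#' @param cfg A [clustering_config()].
#' @param extend If `FALSE`, every new window starts a new cluster (ablation
#'   hook for the alternative reading of the sweep rule).
#' @return List of `sig_cluster` objects (size_class `"large"`).
#' @export
cluster_sliding_window <- function(sites, cfg = clustering_config(),
                                   extend = TRUE) {
  n <- nrow(sites)
  if (n == 0L) return(list())
  if (length(unique(sites$chrom)) > 1L)
    stop("cluster_sliding_window expects a single chromosome")
  if (is.unsorted(sites$start)) stop("sites must be sorted by start")
  starts <- sites$start
  clusters <- list()
  i <- 1L
  while (i <= n) {
    from <- i
    w <- starts[i]
    repeat {
      hi <- w + cfg$window
      if (i <= n && starts[i] < hi) {
        while (i <= n && starts[i] < hi) i <- i + 1L
        if (!extend && i <= n) break
        w <- hi
      } else break
    }
    clusters[[length(clusters) + 1L]] <-
      new_sig_cluster(sites$chrom[1], sites[from:(i - 1L), , drop = FALSE],
                      "large")
  }
  clusters
}

#' Coverage-peak clustering of small candidate deletion sites
#'
#' Builds a deletion-depth profile in which each signature increments
#' positions `[start, end)` by one (difference array + prefix sum). Each
#' maximal run of positions with depth >= 1 — a "peak" — yields one cluster
#' holding every site whose span intersects it; by construction each site's
#' span lies inside exactly one run.
#'
#' @param sites Signature data.frame, one chromosome, all small-class.
#' @param cfg A [clustering_config()]; if `chrom_lengths` names this
#'   chromosome, spans beyond the chromosome end are clipped with a warning.
#' @return List of `sig_cluster` objects (size_class `"small"`).
#' @export
cluster_coverage <- function(sites, cfg = clustering_config()) {
  n <- nrow(sites)
  if (n == 0L) return(list())
  chrom <- sites$chrom[1]
  if (length(unique(sites$chrom)) > 1L)
    stop("cluster_coverage expects a single chromosome")
  start <- sites$start
  end <- pmax(sites$end, start + 1)
  clen <- cfg$chrom_lengths[chrom]
  if (!is.null(cfg$chrom_lengths) && !is.na(clen) && any(end > clen)) {
    warning("clipping ", sum(end > clen), " signature span(s) to the ",
            chrom, " chromosome end", call. = FALSE)
    end <- pmin(end, clen)
    end <- pmax(end, start + 1)
  }
  off <- min(start)
  width <- max(end) - off
  d <- integer(width + 1L)
  s1 <- as.integer(start - off) + 1L
  e1 <- as.integer(end - off) + 1L
  for (k in seq_len(n)) {
    d[s1[k]] <- d[s1[k]] + 1L
    d[e1[k]] <- d[e1[k]] - 1L
  }
  depth <- cumsum(d[seq_len(width)])
  r <- rle(depth > 0L)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  peak_starts <- off + run_start[r$values] - 1L
  peak_id <- findInterval(start, peak_starts)
  lapply(split(seq_len(n), peak_id), function(idx) {
    new_sig_cluster(chrom, sites[idx, , drop = FALSE], "small")
  }) |> unname()
}

#' Layer-1 clustering: size-stratified large clusters
#'
#' Per chromosome (chromosomes are independent work items), small-class
#' signatures are clustered by coverage peaks and large-class signatures by
#' the sliding window; the two methods run on disjoint inputs, so their
#' results are simply pooled. Output order is deterministic: by chromosome,
#' then by the minimum member start.
#'
#' @param sigs Signature data.frame (any number of chromosomes).
#' @param cfg A [clustering_config()].
#' @param threads Accepted for interface compatibility; results are required
#'   to be identical for any thread count, and the implementation processes
#'   chromosomes serially.
#' @return List of `sig_cluster` objects.
#' @export
layer1 <- function(sigs, cfg = clustering_config(), threads = 1L) {
  stopifnot(is.numeric(threads), threads >= 1)
  if (nrow(sigs) == 0L) return(list())
  clusters <- list()
  for (chrom in sort(unique(sigs$chrom))) {
    cs <- sigs[sigs$chrom == chrom, , drop = FALSE]
    parts <- partition_by_size(cs, cfg)
    small_cl <- cluster_coverage(parts$small, cfg)
    large <- parts$large[order(parts$large$start, parts$large$svlen,
                               parts$large$read_name), , drop = FALSE]
    large_cl <- cluster_sliding_window(large, cfg)
    both <- c(small_cl, large_cl)
    if (length(both) > 1L) {
      key <- vapply(both, function(cl) min(cl$members$start), numeric(1))
      both <- both[order(key)]
    }
    clusters <- c(clusters, both)
  }
  clusters
}

#' Length-difference rate between two deletion lengths
#'
#' `|len1 - len2| / max(len1, len2)`: the layer-2 criterion deciding whether
#' two length sub-clusters at one locus represent the same deletion. For the
#' motivating heterozygous case of allele lengths 108 and 216 it is 0.5, so
#' the alleles stay separate.
#'
#' @param len1,len2 Positive deletion lengths (bp).
#' @return Fraction in `[0, 1)`.
#' @export
length_difference_rate <- function(len1, len2) {
  stopifnot(len1 > 0, len2 > 0)
  abs(len1 - len2) / max(len1, len2)
}

new_cand_cluster <- function(chrom, members) {
  rownames(members) <- NULL
  structure(list(chrom = chrom, members = members,
                 mean_start = mean(members$start),
                 mean_len = mean(members$svlen)),
            class = "cand_cluster")
}

#' @export
print.cand_cluster <- function(x, ...) {
  cat(sprintf("<cand_cluster %s: %d member(s), mean start %.1f, mean len %.1f>\n",
              x$chrom, nrow(x$members), x$mean_start, x$mean_len))
  invisible(x)
}

#' Layer-2 agglomerative clustering of one large cluster by deletion length
#'
#' Each member starts as a singleton; a cluster's length is the arithmetic
#' mean of its members' `svlen`. The pair with the smallest absolute
#' mean-length difference is merged repeatedly until two clusters remain
#' (ties broken by smaller combined member count, then smaller combined mean
#' length, then smaller smallest member start). The two survivors are merged
#' into one candidate cluster when their length-difference rate is strictly
#' below `cfg$rate_threshold`; otherwise both are returned — one per
#' haplotype allele.
#'
#' @param cluster A `sig_cluster` (nonempty).
#' @param cfg A [clustering_config()].
#' @return List of one or two `cand_cluster` objects, ordered by
#'   `(mean_start, mean_len)`.
#' @export
hierarchical_cluster <- function(cluster, cfg = clustering_config()) {
  members <- cluster$members
  n <- nrow(members)
  stopifnot(n >= 1L)
  if (n == 1L) return(list(new_cand_cluster(cluster$chrom, members)))
  groups <- as.list(seq_len(n))
  means <- members$svlen
  sizes <- rep(1L, n)
  min_starts <- members$start
  while (length(groups) > 2L) {
    k <- length(groups)
    best <- NULL
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      d <- abs(means[i] - means[j])
      comb_size <- sizes[i] + sizes[j]
      comb_mean <- (means[i] * sizes[i] + means[j] * sizes[j]) / comb_size
      comb_min <- min(min_starts[i], min_starts[j])
      key <- c(d, comb_size, comb_mean, comb_min)
      if (is.null(best) || lex_less(key, best$key)) best <- list(key = key, i = i, j = j)
    }
    i <- best$i; j <- best$j
    groups[[i]] <- c(groups[[i]], groups[[j]])
    means[i] <- mean(members$svlen[groups[[i]]])
    sizes[i] <- length(groups[[i]])
    min_starts[i] <- min(members$start[groups[[i]]])
    groups[[j]] <- NULL
    means <- means[-j]; sizes <- sizes[-j]; min_starts <- min_starts[-j]
  }
  if (length(groups) == 2L &&
      length_difference_rate(means[1], means[2]) < cfg$rate_threshold) {
    groups <- list(c(groups[[1]], groups[[2]]))
  }
  cands <- lapply(groups, function(idx) {
    new_cand_cluster(cluster$chrom, members[sort(idx), , drop = FALSE])
  })
  if (length(cands) == 2L) {
    key1 <- c(cands[[1]]$mean_start, cands[[1]]$mean_len)
    key2 <- c(cands[[2]]$mean_start, cands[[2]]$mean_len)
    if (lex_less(key2, key1)) cands <- cands[c(2L, 1L)]
  }
  cands
}

# strict lexicographic comparison of equal-length numeric keys
lex_less <- function(a, b) {
  for (t in seq_along(a)) {
    if (a[t] < b[t]) return(TRUE)
    if (a[t] > b[t]) return(FALSE)
  }
  FALSE
}

#' Layer-2 clustering over all layer-1 clusters
#'
#' @param clusters List of `sig_cluster` objects from [layer1()].
#' @param cfg A [clustering_config()].
#' @param enabled If `FALSE`, each large cluster passes through as a single
#'   candidate cluster (ablation hook showing why length-based separation of
#'   heterozygous alleles is needed).
#' @return List (one element per large cluster) of lists of `cand_cluster`.
#' @export
layer2 <- function(clusters, cfg = clustering_config(), enabled = TRUE) {
  lapply(clusters, function(cl) {
    if (!enabled) return(list(new_cand_cluster(cl$chrom, cl$members)))
    hierarchical_cluster(cl, cfg)
  })
}
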