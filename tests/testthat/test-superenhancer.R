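test_that("stitching excludes TSS-contained peaks and merges within the distance", {
  params <- se_params()
  genes <- data.frame(gene_id = "g1", chrom = "chr1", strand = "+",
                      tss = 10000, start = 10000, end = 12000)

  # single isolated peak far from any TSS
  one <- genomic_intervals("chr1", 100000, 101000)
  got <- stitch_peaks(one, genes, params)
  expect_equal(got[, c("start", "end")],
               data.frame(start = 100000, end = 101000))
  expect_equal(got$n_constituents, 1)

  # peak fully inside [tss - 2500, tss + 2500) is removed
  inside <- genomic_intervals("chr1", 9000, 10500)
  expect_equal(nrow(stitch_peaks(inside, genes, params)), 0L)
  # a peak merely overlapping the window survives
  partial <- genomic_intervals("chr1", 9000, 13000)
  expect_equal(nrow(stitch_peaks(partial, genes, params)), 1L)

  # gap rule: 4 kb gap stitches, 14 kb gap does not
  peaks <- genomic_intervals("chr1", c(0, 5000, 20000),
                             c(1000, 6000, 21000))
  got <- stitch_peaks(peaks, NULL, params)
  expect_equal(got$start, c(0, 20000))
  expect_equal(got$end, c(6000, 21000))
  expect_equal(got$n_constituents, c(2, 1))
})

test_that("stitching equals the brute-force oracle and is monotone in distance", {
  skip_if_not_installed("igraph")
  set.seed(21)
  for (rep in 1:20) {
    n <- sample(5:60, 1)
    peaks <- random_intervals(n, max_pos = 200000, max_len = 3000)
    tss <- sample.int(200000, sample(0:10, 1)) - 1
    genes <- if (length(tss)) {
      data.frame(gene_id = sprintf("g%d", seq_along(tss)), chrom = "chr1",
                 tss = tss)
    } else {
      NULL
    }
    w <- sample(c(500, 2500), 1)
    d <- sample(c(2000, 12500, 30000), 1)
    params <- se_params(tss_exclusion_halfwidth = w, stitch_distance = d)
    got <- stitch_peaks(peaks, genes, params)
    # half-open TSS windows: the oracle uses containment in [tss-w, tss+w)
    exp <- oracle_stitch(peaks, if (length(tss)) tss else numeric(), w, d)
    expect_equal(got[, c("chrom", "start", "end")], exp)

    # enlarging the stitch distance never increases the cluster count
    larger <- stitch_peaks(peaks, genes,
                           se_params(tss_exclusion_halfwidth = w,
                                     stitch_distance = d + 20000))
    expect_lte(nrow(larger), nrow(got))
  }
})

test_that("consensus clusters are the merged concatenation of inputs", {
  a <- genomic_intervals("chr1", c(0, 30000), c(10000, 40000))
  b <- genomic_intervals("chr1", c(5000, 80000), c(15000, 90000))
  got <- consensus_clusters(list(a, b))
  expect_equal(got$start, c(0, 30000, 80000))
  expect_equal(got$end, c(15000, 40000, 90000))
  # idempotence on identical inputs
  expect_equal(consensus_clusters(list(a, a))[, c("start", "end")],
               a[, c("start", "end")])
  expect_equal(got, merge_intervals(rbind(a[, 1:3], b[, 1:3]), gap = 0))
})

test_that("cluster quantification counts >= 1 bp overlaps and averages replicates", {
  clusters <- genomic_intervals("chr1", c(0, 1000), c(1000, 2000))
  design <- data.frame(sample_id = c("s1", "s2"),
                       condition = c("a", "a"), replicate = 1:2)
  libs <- c(s1 = 1e6, s2 = 1e6)
  frag_in <- data.frame(chrom = "chr1", start = 100, end = 300)
  frag_span <- data.frame(chrom = "chr1", start = 900, end = 1100)
  q <- quantify_clusters(clusters,
                         fragments = list(s1 = frag_in, s2 = frag_span),
                         lib_sizes = libs, design = design)
  # one fragment at library 1e6 -> signal 1; the spanning fragment counts
  # in both clusters
  expect_equal(unname(q$sample_signal[, "s1"]), c(1, 0))
  expect_equal(unname(q$sample_signal[, "s2"]), c(1, 1))
  expect_equal(unname(q$condition_signal[, "a"]), c(1, 0.5))

  set.seed(22)
  for (rep in 1:10) {
    cl <- merge_intervals(random_intervals(20, max_pos = 50000))
    frags <- random_intervals(300, max_pos = 52000, max_len = 400)
    q <- quantify_clusters(cl, fragments = list(s1 = frags),
                           lib_sizes = c(s1 = 1e6),
                           design = data.frame(sample_id = "s1",
                                               condition = "a"))
    expect_equal(unname(q$sample_signal[, 1]), oracle_count(cl, frags))
  }
  expect_error(quantify_clusters(clusters,
                                 fragments = list(s1 = frag_in,
                                                  s2 = frag_in),
                                 lib_sizes = c(s1 = 0, s2 = 1e6),
                                 design = design), "library")
})

test_that("tangent threshold matches the exhaustive scan and reacts to outliers", {
  expect_warning(v <- rose_threshold(rep(5, 10)), "degenerate")
  expect_equal(v, 5)

  sig <- (1:100)^2
  expect_equal(rose_threshold(sig), oracle_rose(sig))
  set.seed(23)
  for (rep in 1:20) {
    sig <- runif(sample(10:200, 1))^sample(1:4, 1) * 100
    expect_equal(rose_threshold(sig), oracle_rose(sig))
    with_outlier <- c(sig, max(sig) * 1000)
    expect_gte(rose_threshold(with_outlier), rose_threshold(sig))
  }
})

test_that("fixed-threshold SE calls use an inclusive boundary", {
  quant <- structure(list(
    regions = genomic_intervals("chr1", c(0, 1, 2), c(1, 2, 3)),
    sample_signal = NULL,
    condition_signal = matrix(c(75, 59.9, 60), ncol = 1,
                              dimnames = list(NULL, "ctrl")),
    design = data.frame(sample_id = "s1", condition = "ctrl")),
    class = "stitched_quant")
  calls <- call_superenhancers(quant, se_params(fixed_threshold = 60))
  expect_equal(unname(calls$is_se[, "ctrl"]), c(TRUE, FALSE, TRUE))
})

test_that("SE change classes follow the +/-0.15 log2 thresholds", {
  sig <- matrix(c(100, 100, 100, 100 * 2^0.2, 100 * 2^-0.2, 100),
                ncol = 2, dimnames = list(NULL, c("ctrl", "trt")))
  quant <- structure(list(
    regions = genomic_intervals("chr1", c(0, 1, 2), c(1, 2, 3)),
    sample_signal = NULL, condition_signal = sig,
    design = data.frame(sample_id = c("s1", "s2"),
                        condition = c("ctrl", "trt"))),
    class = "stitched_quant")
  calls <- call_superenhancers(quant, se_params(pseudosignal = 1e-9))
  ch <- classify_se_change(calls, "ctrl", "trt")
  expect_equal(as.character(ch$change_class),
               c("increased", "decreased", "sustained"))
  # clusters below threshold in both conditions stay unclassified
  low <- quant
  low$condition_signal <- sig / 10
  ch_low <- classify_se_change(call_superenhancers(low), "ctrl", "trt")
  expect_true(all(is.na(ch_low$change_class)))
})
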