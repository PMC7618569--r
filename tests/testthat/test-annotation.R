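random_genes <- function(n, max_pos = 1e6, chroms = "chr1") {
  data.frame(gene_id = sprintf("g%03d", sample.int(999, n)),
             chrom = sample(chroms, n, replace = TRUE),
             tss = sample.int(max_pos, n) - 1,
             stringsAsFactors = FALSE)
}

test_that("nearest gene assignment respects distance 0 inside and the 100 kb cap", {
  genes <- data.frame(gene_id = c("gA", "gB"), chrom = "chr1",
                      tss = c(150, 300000))
  region <- genomic_intervals("chr1", 100, 200)
  got <- nearest_gene(region, genes)
  expect_equal(got$gene_id, "gA")
  expect_equal(got$distance, 0)

  # nearest TSS 150 kb away: no assignment at the default 100 kb cap
  far <- genomic_intervals("chr1", 149800, 150000)
  got <- nearest_gene(far, data.frame(gene_id = "gA", chrom = "chr1",
                                      tss = 299999))
  expect_true(is.na(got$gene_id))
  # exactly at the cap the gene is still assigned
  at_cap <- nearest_gene(genomic_intervals("chr1", 0, 100),
                         data.frame(gene_id = "gA", chrom = "chr1",
                                    tss = 100099))
  expect_equal(at_cap$distance, 100000)
})

test_that("nearest gene and feature match all-pairs oracles and mirror symmetry", {
  set.seed(31)
  L <- 1e6
  for (rep in 1:30) {
    regions <- random_intervals(15, max_pos = L - 2000, max_len = 1500)
    genes <- random_genes(25, max_pos = L)
    genes <- genes[!duplicated(genes$gene_id), ]
    got <- nearest_gene(regions, genes, max_distance = 1e5,
                        promoter_halfwidth = 2500)
    sorted <- got  # nearest_gene sorts regions internally
    regions_sorted <- regions[order(regions$chrom, regions$start,
                                    regions$end), ]
    for (i in seq_len(nrow(regions_sorted))) {
      exp <- oracle_nearest(regions_sorted[i, ], genes, 1e5)
      expect_identical(sorted$gene_id[i], exp$gene)
      if (!is.na(exp$gene)) expect_equal(sorted$distance[i], exp$dist)
      expect_equal(sorted$feature[i],
                   oracle_feature(regions_sorted[i, ], genes, 2500))
    }
    # mirroring the chromosome preserves every assigned distance
    mirrored_regions <- data.frame(chrom = regions_sorted$chrom,
                                   start = L - regions_sorted$end,
                                   end = L - regions_sorted$start)
    mirrored_genes <- genes
    mirrored_genes$tss <- L - 1 - genes$tss
    got_m <- nearest_gene(mirrored_regions, mirrored_genes,
                          max_distance = 1e5)
    expect_equal(sort(got_m$distance, na.last = TRUE),
                 sort(sorted$distance, na.last = TRUE))
  }
})

test_that("promoter annotation uses half-open TSS windows", {
  genes <- data.frame(gene_id = "g", chrom = "chr1", tss = 10000)
  has_tss <- genomic_intervals("chr1", 9900, 10100)
  expect_equal(annotate_feature(has_tss, genes), "promoter")
  far <- genomic_intervals("chr1", 60000, 60500)
  expect_equal(annotate_feature(far, genes), "distal")
  # window is [tss - w, tss + w): region starting exactly at tss + w is
  # distal, region ending at tss - w is too (half-open region end)
  expect_equal(annotate_feature(genomic_intervals("chr1", 12500, 12600),
                                genes), "distal")
  expect_equal(annotate_feature(genomic_intervals("chr1", 7400, 7500),
                                genes), "distal")
  expect_equal(annotate_feature(genomic_intervals("chr1", 7400, 7501),
                                genes), "promoter")
})

test_that("Venn cells partition the union for 2 and 3 sets", {
  got <- gene_set_overlap(list(A = "a", B = "b"))
  expect_equal(got[["A"]], 1L)
  expect_equal(got[["B"]], 1L)
  expect_equal(got[["A&B"]], 0L)

  same <- gene_set_overlap(list(A = letters[1:5], B = letters[1:5],
                                C = letters[1:5]))
  expect_equal(same[["A&B&C"]], 5L)
  expect_equal(sum(same), 5L)

  set.seed(32)
  for (rep in 1:20) {
    sets <- lapply(1:3, function(i) sample(letters, sample(5:20, 1)))
    names(sets) <- c("X", "Y", "Z")
    got <- gene_set_overlap(sets)
    expect_equal(sum(got), length(unique(unlist(sets))))
    # brute-force membership tabulation
    u <- unique(unlist(sets))
    key <- vapply(u, function(g) paste(
      names(sets)[vapply(sets, function(s) g %in% s, logical(1))],
      collapse = "&"), character(1))
    for (cell in names(got)) {
      expect_equal(got[[cell]], sum(key == cell))
    }
  }
  expect_error(gene_set_overlap(list(a = "x", b = "y", c = "z", d = "w")),
               "2 or 3")
})

test_that("hypergeometric enrichment matches the closed form and filters by size", {
  universe <- sprintf("g%03d", 1:20)
  coll <- gene_set_collection(list(hit = universe[1:5]), universe)
  res <- enrich(universe[1:5], coll, min_size = 2, max_size = 500)
  expect_equal(res$p, 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(res$k, 5L)

  # saturated query: the whole universe gives p = 1
  res <- enrich(universe, coll, min_size = 2)
  expect_equal(res$p, 1)

  # sets below min_size or above max_size are not tested
  coll2 <- gene_set_collection(list(small = universe[1:10],
                                    ok = universe[1:12]), universe)
  res <- enrich(universe[1:5], coll2, min_size = 12, max_size = 15)
  expect_equal(res$set, "ok")

  expect_warning(enrich(c(universe[1:3], "not_there"), coll,
                        min_size = 2),
                 "outside the universe")
})

test_that("randomised null p-values from the enrichment tail are uniform", {
  set.seed(33)
  N <- 1000
  universe <- sprintf("g%04d", seq_len(N))
  m <- 100
  coll <- gene_set_collection(list(s = universe[1:m]), universe)
  n_draw <- 2000
  pr <- numeric(n_draw)
  for (i in seq_len(n_draw)) {
    q <- sample(universe, 150)
    k <- enrich(q, coll, min_size = 1)$k
    # randomised tail: exactly uniform when the hypergeometric null holds
    pk <- phyper(k - 1, m, N - m, 150, lower.tail = FALSE)
    pk1 <- phyper(k, m, N - m, 150, lower.tail = FALSE)
    pr[i] <- pk1 + runif(1) * (pk - pk1)
  }
  expect_gt(ks.test(pr, "punif")$p.value, 0.01)
})

test_that("gene set files round trip through the GMT-like format", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\tdesc\tg2\tg4"), path)
  sets <- read_gene_sets(path)
  expect_equal(sets$setA, c("g1", "g2", "g3"))
  expect_equal(sets$setB, c("g2", "g4"))
  writeLines("broken_line_only_name", path)
  expect_error(read_gene_sets(path), "line 1")
})
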