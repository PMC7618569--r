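test_that("generate_genome places sorted, unique, in-bounds genes deterministically", {
  expect_equal(nrow(generate_genome(0, 1e6)), 0L)
  expect_error(generate_genome(10, 0), "positive")

  g1 <- generate_genome(10, 1e6, seed = 5)
  g2 <- generate_genome(10, 1e6, seed = 5)
  expect_identical(g1, g2)

  g <- generate_genome(100, 2e6, seed = 1)
  expect_true(all(g$tss >= 0 & g$tss < 2e6))
  expect_false(anyDuplicated(g$gene_id) > 0)
  expect_true(all(diff(g$tss) > 0))
  # TSS sits at the 5' end of the body on each strand
  expect_true(all(g$tss[g$strand == "+"] == g$start[g$strand == "+"]))
  expect_true(all(g$tss[g$strand == "-"] == g$end[g$strand == "-"] - 1))
  # gene bodies are valid and non-overlapping
  expect_true(all(g$start < g$end))
  expect_true(all(g$start[-1] >= g$end[-nrow(g)]))
})

test_that("generate_truth plants effects count-based and clusters within stitching reach", {
  design <- simulation_design(c("ctrl", "trt"), n_replicates = 3, seed = 2)
  genome <- generate_genome(50, 2e7, seed = 2)

  # null planting
  t0 <- generate_truth(genome, 100, 0, design,
                       effect_spec = list(trt = c(0, 0, 1)),
                       chrom_length = 2e7)
  expect_true(all(t0$effects == 0))

  # exact numbers of up/down regions
  t1 <- generate_truth(genome, 1000, 0, design,
                       effect_spec = list(trt = c(0.1, 0.05, 1)),
                       chrom_length = 6e8)
  expect_equal(sum(t1$effects[, "trt"] > 0), 100)
  expect_equal(sum(t1$effects[, "trt"] < 0), 50)
  expect_true(all(t1$effects[, "ctrl"] == 0))
  # one truth label per region; base signals positive
  expect_equal(nrow(t1$effects), nrow(t1$regions))
  expect_true(all(t1$regions$base_signal > 0))

  # planted clusters: pairwise neighbour gaps within the stitch distance,
  # and membership partitions the flagged regions
  t2 <- generate_truth(genome, 20, 2, design, se_size = 4,
                       chrom_length = 2e7)
  expect_equal(length(unlist(t2$se_members)), 8L)
  expect_false(anyDuplicated(unlist(t2$se_members)) > 0)
  for (ids in t2$se_members) {
    r <- t2$regions[match(ids, t2$regions$region_id), ]
    r <- r[order(r$start), ]
    expect_true(all(r$start[-1] - r$end[-nrow(r)] <= 12500))
  }
  expect_error(generate_truth(genome, 10, 5, design, chrom_length = 1e5),
               "cannot fit")
})

test_that("simulate_counts draws NB counts with the planted means", {
  design <- simulation_design(c("a", "b"), n_replicates = 5000,
                              dispersion = 0, seed = 3,
                              library_sizes = NULL, mean_libsize = 2e7)
  genome <- generate_genome(0, 1e6)
  truth <- generate_truth(genome, 10, 0, design, chrom_length = 1e6,
                          background_signal = c(50, 50))
  cm <- simulate_counts(truth, design)
  # Poisson draws at alpha = 0: normalised sample mean over 10,000
  # replicates within 2% of the planted mean
  norm_mean <- rowMeans(normalize_cpm(cm))
  expect_true(all(abs(norm_mean / truth$regions$base_signal - 1) < 0.02))

  # determinism
  cm2 <- simulate_counts(truth, design)
  expect_identical(cm$counts, cm2$counts)

  bad <- design
  bad$dispersion <- -0.1
  expect_error(simulate_counts(truth, bad), "dispersion")
})

test_that("simulate_replicate_peaks reproduces detection probabilities", {
  genome <- generate_genome(0, 1e6)
  design <- simulation_design(c("a", "b"), n_replicates = 5, seed = 4)

  t_all <- generate_truth(genome, 50, 0, design, chrom_length = 1e7,
                          detection_prob = 1)
  peaks <- simulate_replicate_peaks(t_all, design, jitter = 0)
  for (pc in peaks) {
    expect_equal(pc$intervals$start, sort(t_all$regions$start))
  }

  t_none <- generate_truth(genome, 50, 0, design, chrom_length = 1e7,
                           detection_prob = 0)
  peaks0 <- simulate_replicate_peaks(t_none, design, jitter = 0)
  expect_true(all(vapply(peaks0, function(p) nrow(p$intervals),
                         numeric(1)) == 0))

  # per-region replicate support ~ Binomial(5, 0.6): mean within 1% of 3
  design1 <- simulation_design("a", n_replicates = 5, seed = 5)
  t6 <- generate_truth(genome, 10000, 0, design1, chrom_length = 6e8,
                       detection_prob = 0.6)
  peaks6 <- simulate_replicate_peaks(t6, design1, jitter = 0)
  support <- rowSums(vapply(peaks6, function(p) {
    t6$regions$region_id %in% p$intervals$name
  }, logical(nrow(t6$regions))))
  expect_lt(abs(mean(support) - 3), 0.03)

  expect_error(simulate_replicate_peaks(t_all, design, jitter = 10000),
               "jitter")
})

test_that("simulated fragments realise the count matrix exactly", {
  design <- simulation_design(c("a", "b"), n_replicates = 2, seed = 6)
  genome <- generate_genome(0, 1e6)
  truth <- generate_truth(genome, 30, 0, design, chrom_length = 1e7)
  cm <- simulate_counts(truth, design)
  frags <- simulate_fragments(truth, cm)
  recount <- count_regions(
    data.frame(chrom = truth$regions$chrom, start = truth$regions$start,
               end = truth$regions$end, name = truth$regions$region_id),
    frags, lib_sizes = setNames(design$samples$lib_size,
                                design$samples$sample_id),
    design = design$samples)
  ord <- order(truth$regions$start)
  expect_equal(unname(recount$counts),
               unname(cm$counts[ord, colnames(recount$counts)]))
})

test_that("truth files are written as plain text and parse back", {
  design <- simulation_design(c("a", "b"), n_replicates = 2, seed = 7)
  truth <- generate_truth(generate_genome(0, 1e6), 20, 1, design,
                          se_size = 3, chrom_length = 1e7)
  dir <- withr::local_tempdir()
  paths <- write_truth(truth, dir)
  expect_true(all(file.exists(paths)))
  bed <- read_bed(paths[["regions"]])
  expect_equal(nrow(bed), nrow(truth$regions))
  parsed <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_equal(sort(unlist(parsed$se_members, use.names = FALSE)),
               sort(unlist(truth$se_members, use.names = FALSE)))
  dsg <- yaml::read_yaml(paths[["design"]])
  expect_equal(dsg$dispersion, design$dispersion)
})
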