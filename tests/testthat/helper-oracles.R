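# Brute-force oracles, independent of the package's sweep/GRanges code
# paths: transitive-closure merging via graph components, all-pairs
# distance scans, exhaustive threshold scans, hand-computed ranks.

random_intervals <- function(n, chroms = "chr1", max_pos = 10000,
                             max_len = 500) {
  start <- sample.int(max_pos, n, replace = TRUE) - 1L
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start,
             end = start + sample.int(max_len, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# Transitive-closure merge: connect every pair whose gap is <= `gap`, take
# connected components, span each component.
oracle_merge <- function(df, gap = 0) {
  out <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                    stringsAsFactors = FALSE)
  for (ch in unique(df$chrom)) {
    d <- df[df$chrom == ch, , drop = FALSE]
    n <- nrow(d)
    adj <- outer(seq_len(n), seq_len(n), function(i, j) {
      pmax(d$start[i], d$start[j]) - pmin(d$end[i], d$end[j]) <= gap
    })
    comp <- igraph::components(
      igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    )$membership
    for (k in unique(comp)) {
      out <- rbind(out, data.frame(chrom = ch,
                                   start = as.numeric(min(d$start[comp ==
                                                                    k])),
                                   end = as.numeric(max(d$end[comp ==
                                                                k]))))
    }
  }
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

overlaps_1bp <- function(s1, e1, s2, e2) s1 < e2 & e1 > s2

# Merge-all-then-count-overlapping-replicates consensus oracle.
oracle_consensus <- function(replicate_dfs, min_support) {
  all_iv <- do.call(rbind, lapply(replicate_dfs, function(d)
    d[, c("chrom", "start", "end")]))
  cand <- oracle_merge(all_iv, gap = 0)
  support <- integer(nrow(cand))
  for (d in replicate_dfs) {
    for (i in seq_len(nrow(cand))) {
      hit <- any(d$chrom == cand$chrom[i] &
                   overlaps_1bp(d$start, d$end, cand$start[i], cand$end[i]))
      support[i] <- support[i] + as.integer(hit)
    }
  }
  cand$support <- support
  out <- cand[support >= min_support, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# O(n*m) fragment-overlap counting.
oracle_count <- function(regions, fragments) {
  vapply(seq_len(nrow(regions)), function(i) {
    sum(fragments$chrom == regions$chrom[i] &
          overlaps_1bp(fragments$start, fragments$end,
                       regions$start[i], regions$end[i]))
  }, numeric(1))
}

# TSS-exclusion + transitive-closure stitching oracle.
oracle_stitch <- function(peaks, tss, halfwidth, stitch_distance) {
  if (length(tss)) {
    contained <- vapply(seq_len(nrow(peaks)), function(i) {
      any(peaks$start[i] >= tss - halfwidth &
            peaks$end[i] <= tss + halfwidth)
    }, logical(1))
    peaks <- peaks[!contained, , drop = FALSE]
  }
  oracle_merge(peaks, gap = stitch_distance)
}

# Exhaustive scan for the tangent threshold.
oracle_rose <- function(signals) {
  y <- sort(signals)
  n <- length(y)
  best_d <- -Inf
  best <- NA_real_
  for (i in seq_len(n)) {
    d <- (y[i] - y[1]) / (y[n] - y[1]) - (i - 1) / (n - 1)
    if (d >= best_d) {  # >= : ties go to the larger signal
      best_d <- d
      best <- y[i]
    }
  }
  best
}

# All-pairs nearest-TSS scan with the package's stated distance convention.
oracle_nearest <- function(region, genes, max_distance) {
  same <- genes[genes$chrom == region$chrom, , drop = FALSE]
  best_d <- Inf
  best_g <- NA_character_
  for (i in seq_len(nrow(same))) {
    tss <- same$tss[i]
    d <- if (tss >= region$start && tss < region$end) {
      0
    } else if (tss < region$start) {
      region$start - tss
    } else {
      tss - (region$end - 1)
    }
    if (d < best_d || (d == best_d && same$gene_id[i] < best_g)) {
      best_d <- d
      best_g <- same$gene_id[i]
    }
  }
  if (best_d > max_distance) list(gene = NA_character_, dist = NA_real_)
  else list(gene = best_g, dist = best_d)
}

oracle_feature <- function(region, genes, w) {
  same <- genes[genes$chrom == region$chrom, , drop = FALSE]
  hit <- any(region$start < same$tss + w & region$end > same$tss - w)
  if (hit) "promoter" else "distal"
}

# Hypergeometric upper tail from the combinatorial definition.
oracle_hyper_tail <- function(k, m, N, n) {
  xs <- k:min(m, n)
  sum(choose(m, xs) * choose(N - m, n - xs)) / choose(N, n)
}

# Dunn z from hand-computed average ranks and the tie-corrected variance.
oracle_dunn_z <- function(values, group, g1, g2) {
  ord <- order(values)
  r <- numeric(length(values))
  i <- 1
  sorted <- values[ord]
  while (i <= length(values)) {
    j <- i
    while (j < length(values) && sorted[j + 1] == sorted[i]) j <- j + 1
    r[ord[i:j]] <- mean(i:j)
    i <- j + 1
  }
  N <- length(values)
  tie_sizes <- as.numeric(table(values))
  T <- sum(tie_sizes^3 - tie_sizes) / (12 * (N - 1))
  n1 <- sum(group == g1)
  n2 <- sum(group == g2)
  (mean(r[group == g1]) - mean(r[group == g2])) /
    sqrt((N * (N + 1) / 12 - T) * (1 / n1 + 1 / n2))
}

# Simulated expression archetypes: `k` response shapes across cell lines,
# each gene following its archetype's condition profile in every line plus
# i.i.d. noise.
simulate_archetypes <- function(n_per_cluster = 50, k = 6, n_lines = 3,
                                n_conditions = 3, n_reps = 3, noise = 0.3,
                                seed = 1) {
  set.seed(seed)
  shapes <- rbind(
    c(0, 2, 2), c(0, -2, -2), c(0, 2, 0),
    c(0, -2, 0), c(0, 0, 2), c(0, 0, -2),
    c(0, 2, -2), c(0, -2, 2)
  )[seq_len(k), , drop = FALSE]
  genes <- k * n_per_cluster
  labels <- rep(seq_len(k), each = n_per_cluster)
  cols <- expand.grid(rep = seq_len(n_reps), condition = seq_len(n_conditions),
                      line = seq_len(n_lines))
  x <- matrix(0, nrow = genes, ncol = nrow(cols))
  for (j in seq_len(nrow(cols))) {
    x[, j] <- shapes[labels, cols$condition[j]] + rnorm(genes, 0, noise)
  }
  rownames(x) <- sprintf("g%03d", seq_len(genes))
  colnames(x) <- sprintf("L%d_c%d_r%d", cols$line, cols$condition, cols$rep)
  list(x = x, labels = labels,
       grouping = setNames(paste0("L", cols$line), colnames(x)))
}
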