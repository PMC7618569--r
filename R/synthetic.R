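# Synthetic H3K27ac landscapes with planted truth. The generator emulates the
# statistical structure of treated-vs-control ChIP-seq experiments: negative-
# binomially dispersed replicate counts over peak regions, clustered
# high-signal regions forming super-enhancers, per-condition multiplicative
# effects on subsets of regions, replicate-to-replicate peak presence/absence,
# and library-size variation. Coordinates are 0-based half-open throughout.

#' Describe a simulated experiment
#'
#' Fixes the conditions (reference first), replication, library sizes,
#' negative-binomial dispersion and seed of a simulation. Library sizes
#' default to roughly 20 million fragments with +/-20% sample-to-sample
#' variation, drawn reproducibly from `seed`.
#'
#' @param conditions Character vector of condition names; the first is the
#'   reference (all planted effects are zero there).
#' @param n_replicates Replicates per condition (>= 2 for any tested
#'   condition).
#' @param library_sizes Optional named integer vector (sample -> total
#'   fragments). Sample names are `<condition>_r<replicate>`.
#' @param dispersion Negative-binomial dispersion alpha >= 0 in the
#'   `variance = mu + alpha * mu^2` parameterisation; `0` gives Poisson
#'   counts.
#' @param seed Integer seed controlling every random draw of the simulation.
#' @param ref_libsize Reference library size at which `base_signal` is the
#'   expected fragment count; the default of one million makes `base_signal`
#'   a CPM-scale quantity.
#' @param mean_libsize Mean of the default library-size draw.
#' @return An object of class `simulation_design` with a `samples` data frame
#'   (`sample_id`, `condition`, `replicate`, `lib_size`).
#' @export
simulation_design <- function(conditions = c("DMSO", "PB"),
                              n_replicates = 5,
                              library_sizes = NULL,
                              dispersion = 0.1,
                              seed = 1L,
                              ref_libsize = 1e6,
                              mean_libsize = 2e7) {
  stopifnot(length(conditions) >= 1L, !anyDuplicated(conditions))
  if (n_replicates < 2L) {
    stop("n_replicates must be >= 2 for a tested condition", call. = FALSE)
  }
  if (dispersion < 0) stop("dispersion must be >= 0", call. = FALSE)
  samples <- expand.grid(replicate = seq_len(n_replicates),
                         condition = conditions,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  samples <- samples[, c("condition", "replicate")]
  samples$sample_id <- paste0(samples$condition, "_r", samples$replicate)
  if (is.null(library_sizes)) {
    samples$lib_size <- with_seed(seed + 1000L, {
      round(mean_libsize * stats::runif(nrow(samples), 0.8, 1.2))
    })
  } else {
    if (!all(samples$sample_id %in% names(library_sizes))) {
      stop("library_sizes must name every sample", call. = FALSE)
    }
    samples$lib_size <- as.numeric(library_sizes[samples$sample_id])
  }
  if (any(samples$lib_size <= 0)) {
    stop("library sizes must be positive", call. = FALSE)
  }
  structure(
    list(conditions = conditions, n_replicates = as.integer(n_replicates),
         samples = samples[, c("sample_id", "condition", "replicate",
                               "lib_size")],
         dispersion = dispersion, seed = as.integer(seed),
         ref_libsize = ref_libsize),
    class = "simulation_design"
  )
}

#' @export
print.simulation_design <- function(x, ...) {
  cat("simulation_design:", length(x$conditions), "conditions x",
      x$n_replicates, "replicates, dispersion", x$dispersion,
      ", seed", x$seed, "\n")
  invisible(x)
}

#' Generate a synthetic gene annotation
#'
#' Draws `n_genes` transcription start sites uniformly on a single synthetic
#' chromosome and lays out non-overlapping gene bodies around them. On the
#' `+` strand the TSS is the body start; on the `-` strand it is `end - 1`.
#'
#' @param n_genes Number of genes (>= 0).
#' @param chrom_length Chromosome length in bp (> 0).
#' @param seed Integer seed; the output is deterministic given the seed.
#' @param chrom Chromosome name.
#' @return Data frame with columns `gene_id`, `chrom`, `strand`, `tss`,
#'   `start`, `end`, sorted by TSS.
#' @export
generate_genome <- function(n_genes, chrom_length, seed = 1L,
                            chrom = "chrS") {
  if (chrom_length <= 0) stop("chrom_length must be positive", call. = FALSE)
  if (n_genes < 0) stop("n_genes must be >= 0", call. = FALSE)
  empty <- data.frame(gene_id = character(), chrom = character(),
                      strand = character(), tss = numeric(),
                      start = numeric(), end = numeric(),
                      stringsAsFactors = FALSE)
  if (n_genes == 0L) return(empty)
  if (n_genes > chrom_length) {
    stop("cannot place more genes than base pairs", call. = FALSE)
  }
  with_seed(seed, {
    tss <- sort(sample.int(chrom_length, n_genes) - 1)
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    len <- round(stats::runif(n_genes, 1000, 10000))
    # Each gene body is confined to the cell between midpoints to its
    # neighbouring TSSs, which guarantees non-overlap.
    left <- c(0, floor((tss[-n_genes] + tss[-1]) / 2) + 1)
    right <- c(floor((tss[-n_genes] + tss[-1]) / 2), chrom_length)
    start <- ifelse(strand == "+", tss, pmin(pmax(tss + 1 - len, left), tss))
    end <- ifelse(strand == "+", pmax(pmin(tss + len, right), tss + 1),
                  tss + 1)
    data.frame(
      gene_id = sprintf("gene_%04d", seq_len(n_genes)),
      chrom = chrom, strand = strand, tss = tss,
      start = start, end = end, stringsAsFactors = FALSE
    )
  })
}

#' Plant a peak landscape with known truth
#'
#' Places `n_background` isolated peak regions and `n_se` super-enhancer
#' clusters (each a run of `se_size` peaks separated by `se_gap` bp, within
#' stitching reach of their neighbours) on the chromosome, assigns each
#' region a baseline signal and per-condition log2 fold-change effects, and
#' records everything as recoverable truth.
#'
#' Effects on background regions are planted count-based: for condition `c`
#' with `effect_spec[[c]] = c(fraction_up, fraction_down, lfc)`, exactly
#' `round(fraction_up * n_background)` regions get `+lfc` and
#' `round(fraction_down * n_background)` get `-lfc`, so truth tables are
#' deterministic. Super-enhancer effects are given per cluster via
#' `se_effect` and applied to every member region.
#'
#' @param genome Gene table from [generate_genome()] (may be empty).
#' @param n_background Number of isolated background peak regions.
#' @param n_se Number of planted super-enhancer clusters.
#' @param design A [simulation_design()]; its seed drives placement and
#'   planting.
#' @param effect_spec Named list, condition -> numeric
#'   `c(fraction_up, fraction_down, lfc)` applied to background regions.
#'   Conditions omitted (and the reference) have zero effects.
#' @param se_effect Named list, condition -> numeric vector of per-cluster
#'   log2 fold changes (recycled across the `n_se` clusters).
#' @param chrom_length Chromosome length in bp.
#' @param se_size Peaks per super-enhancer cluster.
#' @param se_gap Gap between neighbouring cluster members (bp); must be
#'   within the stitching distance used downstream.
#' @param peak_width,se_peak_width Width of background and cluster member
#'   peaks (bp).
#' @param background_signal,se_signal Length-2 ranges from which per-region
#'   baseline signals (CPM scale at the reference library size) are drawn
#'   uniformly.
#' @param detection_prob Probability that a replicate peak caller reports a
#'   given region (scalar or per-region vector).
#' @param tss_halfwidth Half-width of the TSS windows that super-enhancer
#'   cluster members must avoid (so planted clusters survive TSS exclusion).
#' @param chrom Chromosome name.
#' @return An object of class `synthetic_truth`: list with `regions` (data
#'   frame: `region_id`, `chrom`, `start`, `end`, `base_signal`,
#'   `detection_prob`, `se_id`), `effects` (region x condition log2FC
#'   matrix), `se_members` (list se_id -> region_ids) and `design`.
#' @export
generate_truth <- function(genome, n_background, n_se, design,
                           effect_spec = list(),
                           se_effect = list(),
                           chrom_length = 5e7,
                           se_size = 8L, se_gap = 3000L,
                           peak_width = 800L, se_peak_width = 2000L,
                           background_signal = c(2, 8),
                           se_signal = c(15, 30),
                           detection_prob = 0.9,
                           tss_halfwidth = 2500L,
                           chrom = "chrS") {
  stopifnot(inherits(design, "simulation_design"))
  n_background <- as.integer(n_background)
  n_se <- as.integer(n_se)
  if (n_background < 0 || n_se < 0) stop("negative counts", call. = FALSE)
  for (cn in names(effect_spec)) {
    es <- effect_spec[[cn]]
    if (!cn %in% design$conditions) {
      stop("effect_spec names an unknown condition: ", cn, call. = FALSE)
    }
    if (cn == design$conditions[1L]) {
      stop("reference condition must have zero effects", call. = FALSE)
    }
    if (es[1L] + es[2L] > 1) {
      stop("fraction_up + fraction_down must be <= 1", call. = FALSE)
    }
  }
  se_span <- se_size * se_peak_width + (se_size - 1L) * se_gap
  n_slots <- n_background + n_se
  slot_len <- if (n_slots > 0) floor(chrom_length / n_slots) else 0
  if (n_slots > 0 && slot_len < se_span + 2L * se_peak_width) {
    stop("super-enhancer clusters cannot fit on the chromosome; ",
         "increase chrom_length", call. = FALSE)
  }

  with_seed(design$seed + 2000L, {
    slot_idx <- sample.int(n_slots)
    se_slots <- slot_idx[seq_len(n_se)]
    bg_slots <- slot_idx[n_se + seq_len(n_background)]

    tss_windows <- if (nrow(genome)) {
      cbind(genome$tss - tss_halfwidth, genome$tss + tss_halfwidth)
    } else {
      matrix(numeric(), ncol = 2)
    }
    contained_in_tss <- function(start, end) {
      if (!nrow(tss_windows)) return(rep(FALSE, length(start)))
      vapply(seq_along(start), function(i) {
        any(start[i] >= tss_windows[, 1] & end[i] <= tss_windows[, 2])
      }, logical(1))
    }

    # Super-enhancer clusters: one per slot, re-drawing the in-slot offset
    # until no member peak sits fully inside a TSS window.
    se_regions <- vector("list", n_se)
    for (i in seq_len(n_se)) {
      base <- (se_slots[i] - 1L) * slot_len
      placed <- FALSE
      for (try in seq_len(100L)) {
        offset <- floor(stats::runif(1, 0, slot_len - se_span))
        starts <- base + offset +
          (seq_len(se_size) - 1L) * (se_peak_width + se_gap)
        ends <- starts + se_peak_width
        if (!any(contained_in_tss(starts, ends))) {
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop("could not place super-enhancer cluster ", i,
             " clear of TSS windows", call. = FALSE)
      }
      se_regions[[i]] <- data.frame(chrom = chrom, start = starts,
                                    end = ends, se_id = sprintf("se_%02d", i),
                                    stringsAsFactors = FALSE)
    }

    bg <- if (n_background > 0) {
      base <- (bg_slots - 1L) * slot_len
      offset <- floor(stats::runif(n_background, 0, slot_len - peak_width))
      data.frame(chrom = chrom, start = base + offset,
                 end = base + offset + peak_width, se_id = NA_character_,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(chrom = character(), start = numeric(), end = numeric(),
                 se_id = character(), stringsAsFactors = FALSE)
    }

    regions <- rbind(do.call(rbind, se_regions), bg)
    regions <- regions[order(regions$start), , drop = FALSE]
    n_regions <- nrow(regions)
    regions$region_id <- sprintf("region_%05d", seq_len(n_regions))
    is_se <- !is.na(regions$se_id)
    regions$base_signal <- numeric(n_regions)
    regions$base_signal[is_se] <-
      stats::runif(sum(is_se), se_signal[1], se_signal[2])
    regions$base_signal[!is_se] <-
      stats::runif(sum(!is_se), background_signal[1], background_signal[2])
    regions$detection_prob <- rep_len(detection_prob, n_regions)
    if (any(regions$detection_prob < 0 | regions$detection_prob > 1)) {
      stop("detection_prob must be in [0, 1]", call. = FALSE)
    }

    effects <- matrix(0, nrow = n_regions, ncol = length(design$conditions),
                      dimnames = list(regions$region_id, design$conditions))
    bg_ids <- regions$region_id[!is_se]
    for (cn in names(effect_spec)) {
      es <- effect_spec[[cn]]
      n_up <- round(es[1L] * length(bg_ids))
      n_down <- round(es[2L] * length(bg_ids))
      picked <- sample(bg_ids, n_up + n_down)
      effects[picked[seq_len(n_up)], cn] <- abs(es[3L])
      if (n_down > 0) {
        effects[picked[n_up + seq_len(n_down)], cn] <- -abs(es[3L])
      }
    }
    se_members <- split(regions$region_id[is_se], regions$se_id[is_se])
    for (cn in names(se_effect)) {
      lfc <- rep_len(se_effect[[cn]], n_se)
      for (i in seq_len(n_se)) {
        effects[se_members[[sprintf("se_%02d", i)]], cn] <- lfc[i]
      }
    }

    structure(
      list(regions = regions[, c("region_id", "chrom", "start", "end",
                                 "base_signal", "detection_prob", "se_id")],
           effects = effects,
           se_members = se_members,
           se_effect = lapply(se_effect, rep_len, n_se),
           design = design),
      class = "synthetic_truth"
    )
  })
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("synthetic_truth:", nrow(x$regions), "regions,",
      length(x$se_members), "planted super-enhancer clusters\n")
  invisible(x)
}

#' Simulate replicate fragment counts over the planted regions
#'
#' Draws, for region `r` and sample `s`, a negative-binomial count with mean
#' `base_signal[r] * 2^effect[r, condition(s)] * lib_size[s] / ref_libsize`
#' and variance `mu + alpha * mu^2`; `alpha = 0` gives Poisson draws. The
#' draw is reproducible from the design seed.
#'
#' @param truth A [generate_truth()] object.
#' @param design A [simulation_design()]; defaults to the one stored in
#'   `truth`.
#' @return A [count_matrix()] (regions x samples).
#' @export
simulate_counts <- function(truth, design = truth$design) {
  stopifnot(inherits(truth, "synthetic_truth"),
            inherits(design, "simulation_design"))
  if (design$dispersion < 0) stop("dispersion must be >= 0", call. = FALSE)
  regions <- truth$regions
  samples <- design$samples
  mu <- outer(regions$base_signal, rep(1, nrow(samples))) *
    2^truth$effects[, samples$condition, drop = FALSE] *
    matrix(samples$lib_size / design$ref_libsize,
           nrow = nrow(regions), ncol = nrow(samples), byrow = TRUE)
  counts <- with_seed(design$seed + 3000L, {
    if (design$dispersion == 0) {
      matrix(stats::rpois(length(mu), lambda = mu), nrow = nrow(mu))
    } else {
      matrix(stats::rnbinom(length(mu), mu = mu,
                            size = 1 / design$dispersion),
             nrow = nrow(mu))
    }
  })
  dimnames(counts) <- list(regions$region_id, samples$sample_id)
  count_matrix(counts,
               lib_sizes = stats::setNames(samples$lib_size,
                                           samples$sample_id),
               design = samples[, c("sample_id", "condition", "replicate")])
}

#' Simulate per-replicate peak calls
#'
#' Emulates replicate-to-replicate variability of a peak caller: each
#' replicate reports region `r` with probability `detection_prob[r]`, with
#' both boundaries jittered by independent uniform offsets in
#' `[-jitter, jitter]` (clipped to keep a positive-width, non-negative
#' interval).
#'
#' @param truth A [generate_truth()] object.
#' @param design A [simulation_design()].
#' @param jitter Maximum boundary offset in bp; must be smaller than the
#'   narrowest region.
#' @return Named list of [peak_collection()] objects, one per sample.
#' @export
simulate_replicate_peaks <- function(truth, design = truth$design,
                                     jitter = 100L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  regions <- truth$regions
  if (nrow(regions) && jitter >= min(regions$end - regions$start)) {
    stop("jitter must be smaller than the narrowest region", call. = FALSE)
  }
  samples <- design$samples
  with_seed(design$seed + 4000L, {
    out <- vector("list", nrow(samples))
    names(out) <- samples$sample_id
    for (s in seq_len(nrow(samples))) {
      found <- stats::runif(nrow(regions)) < regions$detection_prob
      iv <- regions[found, c("chrom", "start", "end", "region_id"),
                    drop = FALSE]
      names(iv)[4L] <- "name"
      if (nrow(iv) && jitter > 0) {
        iv$start <- pmax(0, iv$start +
                           round(stats::runif(nrow(iv), -jitter, jitter)))
        iv$end <- pmax(iv$start + 1,
                       iv$end + round(stats::runif(nrow(iv), -jitter,
                                                   jitter)))
      }
      out[[s]] <- peak_collection(samples$sample_id[s],
                                  samples$condition[s],
                                  samples$replicate[s],
                                  canonical_intervals(iv))
    }
    out
  })
}

#' Simulate fragment intervals realising a count matrix
#'
#' Places, for each region and sample, exactly the counted number of
#' fragments uniformly within the region (fragment length capped at the
#' region width), so that interval-overlap counting over the planted regions
#' reproduces the counts.
#'
#' @param truth A [generate_truth()] object.
#' @param counts A [count_matrix()] over the truth regions.
#' @param fragment_length Fragment length in bp.
#' @param seed Integer seed.
#' @return Named list (sample -> interval data frame of fragments).
#' @export
simulate_fragments <- function(truth, counts, fragment_length = 200L,
                               seed = truth$design$seed) {
  stopifnot(inherits(truth, "synthetic_truth"), inherits(counts,
                                                         "count_matrix"))
  regions <- truth$regions
  stopifnot(identical(rownames(counts$counts), regions$region_id))
  with_seed(seed + 5000L, {
    out <- vector("list", ncol(counts$counts))
    names(out) <- colnames(counts$counts)
    for (s in seq_along(out)) {
      k <- counts$counts[, s]
      ridx <- rep.int(seq_len(nrow(regions)), k)
      flen <- pmin(fragment_length, regions$end[ridx] - regions$start[ridx])
      start <- regions$start[ridx] + floor(stats::runif(
        length(ridx), 0, regions$end[ridx] - regions$start[ridx] - flen + 1))
      out[[s]] <- sort_intervals(data.frame(
        chrom = regions$chrom[ridx], start = start, end = start + flen,
        stringsAsFactors = FALSE))
    }
    out
  })
}

#' Write a synthetic truth to disk as plain text
#'
#' Writes the planted regions as BED6 (`name` = region id, `score` = base
#' signal), the effects and memberships as JSON, and the design as YAML.
#'
#' @param truth A [generate_truth()] object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  regions <- truth$regions
  bed <- data.frame(chrom = regions$chrom, start = regions$start,
                    end = regions$end, name = regions$region_id,
                    score = regions$base_signal, strand = NA_character_)
  paths <- c(
    regions = file.path(dir, "regions.bed"),
    truth = file.path(dir, "truth.json"),
    design = file.path(dir, "design.yaml")
  )
  write_bed(bed, paths[["regions"]])
  jsonlite::write_json(
    list(effects = as.data.frame(truth$effects),
         region_id = rownames(truth$effects),
         se_members = truth$se_members,
         detection_prob = truth$regions$detection_prob),
    paths[["truth"]], digits = NA, auto_unbox = TRUE)
  yaml::write_yaml(
    list(conditions = truth$design$conditions,
         n_replicates = truth$design$n_replicates,
         dispersion = truth$design$dispersion,
         seed = truth$design$seed,
         ref_libsize = truth$design$ref_libsize,
         library_sizes = as.list(stats::setNames(
           truth$design$samples$lib_size, truth$design$samples$sample_id))),
    paths[["design"]])
  invisible(paths)
}
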