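# ROSE-style super-enhancer calling: stitch H3K27ac peaks into clusters
# (excluding TSS-proximal peaks), quantify normalised signal per cluster,
# and call super-enhancers either at the tangent point of the ranked signal
# curve or at a fixed threshold shared across conditions.

#' Super-enhancer parameters
#'
#' @param tss_exclusion_halfwidth Half-width (bp) of the window around each
#'   TSS; peaks fully contained in a window are removed before stitching
#'   (default 2500, i.e. +/- 2.5 kb).
#' @param stitch_distance Maximum gap (bp) at which neighbouring peaks are
#'   stitched into one cluster (default 12500).
#' @param fixed_threshold Normalised total signal at or above which a
#'   cluster is a super-enhancer (default 60).
#' @param change_lfc Absolute log2 fold change in total cluster signal above
#'   which a super-enhancer is called increased/decreased rather than
#'   sustained (default 0.15).
#' @param pseudosignal Positive constant added to both signals in the ratio
#'   for stability at zero (default 1).
#' @return A list of class `se_params`.
#' @export
se_params <- function(tss_exclusion_halfwidth = 2500,
                      stitch_distance = 12500,
                      fixed_threshold = 60,
                      change_lfc = 0.15,
                      pseudosignal = 1) {
  stopifnot(tss_exclusion_halfwidth >= 0, stitch_distance >= 0,
            fixed_threshold >= 0, change_lfc > 0, pseudosignal > 0)
  structure(list(tss_exclusion_halfwidth = tss_exclusion_halfwidth,
                 stitch_distance = stitch_distance,
                 fixed_threshold = fixed_threshold,
                 change_lfc = change_lfc,
                 pseudosignal = pseudosignal),
            class = "se_params")
}

#' Stitch peaks into enhancer clusters
#'
#' Removes peaks fully contained within any `[tss - w, tss + w)` window
#' (peaks merely overlapping a window are kept), then transitively merges
#' the remaining peaks whose gap is at most the stitching distance. The
#' cluster interval spans the first constituent's start to the last's end.
#'
#' @param peaks Interval data frame of (consensus) peaks.
#' @param genes Gene table with `chrom` and `tss` columns (e.g. from
#'   [generate_genome()]); may be empty or `NULL` for no TSS exclusion.
#' @param params An [se_params()] object.
#' @return Interval data frame of clusters with an `n_constituents` column.
#' @export
stitch_peaks <- function(peaks, genes = NULL, params = se_params()) {
  validate_intervals(peaks, what = "peaks")
  peaks <- sort_intervals(peaks[, c("chrom", "start", "end"), drop = FALSE])
  if (nrow(peaks) && !is.null(genes) && nrow(genes)) {
    w <- params$tss_exclusion_halfwidth
    win <- data.frame(chrom = genes$chrom,
                      start = pmax(0, genes$tss - w),
                      end = genes$tss + w)
    hits <- GenomicRanges::findOverlaps(gi_to_granges(peaks),
                                        gi_to_granges(sort_intervals(win)),
                                        type = "within")
    drop <- unique(S4Vectors::queryHits(hits))
    if (length(drop)) peaks <- peaks[-drop, , drop = FALSE]
  }
  clusters <- merge_intervals(peaks, gap = params$stitch_distance)
  clusters$n_constituents <- if (nrow(clusters)) {
    GenomicRanges::countOverlaps(gi_to_granges(clusters),
                                 gi_to_granges(peaks))
  } else {
    integer()
  }
  clusters
}

#' Consensus clusters across conditions
#'
#' Merges (gap 0) the concatenation of per-condition stitched cluster sets
#' into a single consensus region set, so the same regions are quantified
#' in every condition.
#'
#' @param stitched List of stitched cluster data frames (one per condition
#'   or sample).
#' @return Interval data frame of consensus cluster regions.
#' @export
consensus_clusters <- function(stitched) {
  stopifnot(is.list(stitched), length(stitched) >= 1L)
  all_iv <- do.call(rbind, lapply(stitched, function(d)
    d[, c("chrom", "start", "end"), drop = FALSE]))
  merge_intervals(all_iv, gap = 0)
}

#' Quantify normalised signal over clusters
#'
#' Computes each cluster's total signal per sample — fragments overlapping
#' the cluster by >= 1 bp (a fragment spanning two clusters counts in both),
#' scaled to CPM by the sample's total library size — and the per-condition
#' mean over that condition's replicates.
#'
#' @param clusters Interval data frame of cluster regions.
#' @param fragments Named list (sample -> fragment interval data frame), or
#'   `NULL` when `counts` is given.
#' @param counts Optional precomputed cluster x sample count matrix.
#' @param lib_sizes Named numeric vector, sample -> total fragments.
#' @param design Design data frame (`sample_id`, `condition`).
#' @return An object of class `stitched_quant`: list with `regions`,
#'   `sample_signal` (cluster x sample CPM matrix), `condition_signal`
#'   (cluster x condition matrix of replicate means) and `design`.
#' @export
quantify_clusters <- function(clusters, fragments = NULL, counts = NULL,
                              lib_sizes, design) {
  validate_intervals(clusters, what = "clusters")
  clusters <- sort_intervals(clusters)
  if (is.null(counts)) {
    if (is.null(fragments)) {
      stop("provide fragments or counts", call. = FALSE)
    }
    cm <- count_regions(clusters, fragments, lib_sizes, design)
    counts <- cm$counts
  } else {
    counts <- as.matrix(counts)
    stopifnot(nrow(counts) == nrow(clusters))
    if (!all(colnames(counts) %in% names(lib_sizes))) {
      stop("lib_sizes must name every sample", call. = FALSE)
    }
  }
  if (any(lib_sizes[colnames(counts)] <= 0)) {
    stop("library sizes must be > 0", call. = FALSE)
  }
  signal <- sweep(counts, 2L, 1e6 / lib_sizes[colnames(counts)], `*`)
  design <- design[match(colnames(signal), design$sample_id), , drop = FALSE]
  conds <- unique(design$condition)
  cond_signal <- vapply(conds, function(cn) {
    rowMeans(signal[, design$condition == cn, drop = FALSE])
  }, numeric(nrow(signal)))
  if (is.null(dim(cond_signal))) {
    cond_signal <- matrix(cond_signal, ncol = length(conds),
                          dimnames = list(rownames(signal), conds))
  }
  structure(list(regions = clusters, sample_signal = signal,
                 condition_signal = cond_signal, design = design),
            class = "stitched_quant")
}

#' @export
print.stitched_quant <- function(x, ...) {
  cat("stitched_quant:", nrow(x$regions), "clusters x",
      ncol(x$sample_signal), "samples\n")
  invisible(x)
}

#' Tangent threshold on the ranked signal curve
#'
#' Ranks the signals ascending and scales both rank and signal to `[0, 1]`;
#' the threshold is the signal value at the rank where a slope-one line is
#' tangent to the curve, i.e. where scaled signal minus scaled rank is
#' maximal (ties broken towards the larger signal). A single extreme
#' outlier inflates this threshold — the motivation for fixing a shared
#' threshold across conditions instead.
#'
#' @param signals Numeric vector of per-cluster signals (>= 3 distinct
#'   values for a meaningful tangent).
#' @return The threshold signal value. All-equal input returns that value
#'   with a warning.
#' @export
rose_threshold <- function(signals) {
  signals <- signals[is.finite(signals)]
  if (!length(signals)) stop("no signals", call. = FALSE)
  y <- sort(signals)
  n <- length(y)
  if (y[1] == y[n]) {
    warning("all signals equal; tangent threshold is degenerate")
    return(y[1])
  }
  xs <- (seq_len(n) - 1) / (n - 1)
  ys <- (y - y[1]) / (y[n] - y[1])
  d <- ys - xs
  y[max(which(d == max(d)))]
}

#' Call super-enhancers at a fixed threshold
#'
#' A cluster is a super-enhancer in a condition when its average normalised
#' total signal is at or above the fixed threshold (>= 60 normalised units
#' by default); the same threshold is applied to every condition so calls
#' are comparable across conditions.
#'
#' @param quant A [quantify_clusters()] object.
#' @param params An [se_params()] object.
#' @return An object of class `se_calls`: list with `regions`,
#'   `condition_signal` and logical matrix `is_se` (cluster x condition).
#' @export
call_superenhancers <- function(quant, params = se_params()) {
  stopifnot(inherits(quant, "stitched_quant"))
  is_se <- quant$condition_signal >= params$fixed_threshold
  structure(list(regions = quant$regions,
                 condition_signal = quant$condition_signal,
                 is_se = is_se, params = params),
            class = "se_calls")
}

#' @export
print.se_calls <- function(x, ...) {
  cat("se_calls:", nrow(x$regions), "clusters;",
      paste(sprintf("%s: %d SE", colnames(x$is_se), colSums(x$is_se)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Classify super-enhancer signal change between two conditions
#'
#' For clusters that are super-enhancers in at least one of the two
#' conditions, computes `log2((signal_alt + ps) / (signal_ref + ps))` and
#' classifies the change as `increased` (> `change_lfc`), `decreased`
#' (< `-change_lfc`) or `sustained` (the remainder). Clusters that are not
#' super-enhancers in either condition get `NA`.
#'
#' @param calls A [call_superenhancers()] object.
#' @param cond_ref,cond_alt Condition names (change is alt vs ref).
#' @param params An [se_params()]; defaults to the one stored in `calls`.
#' @return Data frame with cluster coordinates, per-condition signals and
#'   SE flags, `log2fc_signal` and factor `change_class`.
#' @export
classify_se_change <- function(calls, cond_ref, cond_alt,
                               params = calls$params) {
  stopifnot(inherits(calls, "se_calls"))
  for (cn in c(cond_ref, cond_alt)) {
    if (!cn %in% colnames(calls$condition_signal)) {
      stop("condition not quantified: ", cn, call. = FALSE)
    }
  }
  sig_ref <- calls$condition_signal[, cond_ref]
  sig_alt <- calls$condition_signal[, cond_alt]
  in_comparison <- calls$is_se[, cond_ref] | calls$is_se[, cond_alt]
  lfc <- log2((sig_alt + params$pseudosignal) /
                (sig_ref + params$pseudosignal))
  cls <- ifelse(lfc > params$change_lfc, "increased",
                ifelse(lfc < -params$change_lfc, "decreased", "sustained"))
  cls[!in_comparison] <- NA_character_
  lfc[!in_comparison] <- NA_real_
  out <- calls$regions
  out$sig_ref <- sig_ref
  out$sig_alt <- sig_alt
  out$is_se_ref <- calls$is_se[, cond_ref]
  out$is_se_alt <- calls$is_se[, cond_alt]
  out$log2fc_signal <- lfc
  out$change_class <- factor(cls, levels = c("increased", "sustained",
                                             "decreased"))
  rownames(out) <- NULL
  out
}
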