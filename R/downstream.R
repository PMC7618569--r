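# Downstream statistics: expression response clustering, survival-gene-set
# mapping with a Kruskal-Wallis / Dunn comparison, fold-enrichment
# transforms, ddCt quantification and the caliper tumour-volume formula.

#' Z-score scaling within sample groups
#'
#' Scales each gene to mean 0 and (population) standard deviation 1 within
#' each sample group (e.g. within each cell line), so response shapes are
#' comparable across lines before clustering. Zero-variance gene/group
#' combinations map to 0.
#'
#' @param values Numeric matrix, genes x samples (CPM scale).
#' @param grouping Named character vector or factor, sample -> group; must
#'   cover every column, each group with >= 2 samples.
#' @return Matrix of the same shape, z-scored within group.
#' @export
zscore_within_group <- function(values, grouping) {
  values <- as.matrix(values)
  if (is.null(colnames(values))) {
    stop("values must have sample column names", call. = FALSE)
  }
  if (!all(colnames(values) %in% names(grouping))) {
    stop("grouping must cover every sample", call. = FALSE)
  }
  grouping <- as.character(grouping[colnames(values)])
  out <- values
  for (g in unique(grouping)) {
    j <- which(grouping == g)
    if (length(j) < 2L) {
      stop("group of size 1: ", g, call. = FALSE)
    }
    x <- values[, j, drop = FALSE]
    mu <- rowMeans(x)
    sdev <- sqrt(rowMeans((x - mu)^2))  # population sd
    z <- (x - mu) / ifelse(sdev > 0, sdev, 1)
    z[sdev == 0, ] <- 0
    out[, j] <- z
  }
  out
}

#' Select genes by significance across comparisons
#'
#' A gene is significant in one comparison when `fdr < fdr_max` and
#' `|log2fc| > lfc_min`. `mode = "all"` keeps genes significant in every
#' comparison (e.g. in all three cell lines); `mode = "any"` keeps genes
#' significant in at least one.
#'
#' @param results Named list of result data frames with `region_id` (or
#'   `gene_id`), `log2fc` and `fdr` columns.
#' @param lfc_min Absolute log2 fold-change threshold (default 0.5).
#' @param fdr_max FDR threshold (default 0.05).
#' @param mode `"all"` (intersection) or `"any"` (union).
#' @return Character vector of selected gene/region ids.
#' @export
select_de_union <- function(results, lfc_min = 0.5, fdr_max = 0.05,
                            mode = c("all", "any")) {
  mode <- match.arg(mode)
  stopifnot(is.list(results), length(results) >= 1L)
  sig <- lapply(results, function(r) {
    id <- if (!is.null(r$gene_id)) r$gene_id else r$region_id
    id[r$fdr < fdr_max & abs(r$log2fc) > lfc_min]
  })
  out <- sig[[1L]]
  for (s in sig[-1L]) {
    out <- if (mode == "all") intersect(out, s) else union(out, s)
  }
  sort(unique(out))
}

#' K-means clustering of response profiles
#'
#' Lloyd's algorithm with squared-Euclidean distance, `n_init` random
#' restarts and the best within-cluster sum of squares kept; deterministic
#' for a given seed.
#'
#' @param scaled Numeric matrix, genes x samples (typically z-scored, see
#'   [zscore_within_group()]).
#' @param k Number of clusters, in `[1, nrow(scaled)]`.
#' @param seed Integer seed.
#' @param n_init Number of random restarts (default 25).
#' @return Object of class `response_clusters`: list with `labels` (named
#'   integer vector), `centroids` (k x samples), `k`, `seed`, `inertia`.
#' @export
kmeans_cluster <- function(scaled, k, seed = 1L, n_init = 25L) {
  scaled <- as.matrix(scaled)
  if (k < 1L || k > nrow(scaled)) {
    stop("k must be in [1, number of genes]", call. = FALSE)
  }
  fit <- with_seed(seed, {
    # Lloyd restarts that land on an empty cluster are discarded by
    # stats::kmeans anyway; silence just that warning.
    withCallingHandlers(
      stats::kmeans(scaled, centers = k, nstart = n_init,
                    iter.max = 100L, algorithm = "Lloyd"),
      warning = function(w) {
        if (grepl("empty cluster", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      }
    )
  })
  structure(list(labels = stats::setNames(fit$cluster, rownames(scaled)),
                 centroids = fit$centers, k = as.integer(k),
                 seed = as.integer(seed), inertia = fit$tot.withinss),
            class = "response_clusters")
}

#' @export
print.response_clusters <- function(x, ...) {
  cat("response_clusters: k =", x$k, "; sizes:",
      paste(tabulate(x$labels, x$k), collapse = ", "),
      "; inertia", signif(x$inertia, 4), "\n")
  invisible(x)
}

#' Fold enrichment with a standard-error interval
#'
#' Transforms a log2 fold change and its standard error to the fold scale:
#' `fold = 2^log2fc`, interval endpoints `2^(log2fc -/+ se)`.
#'
#' @param log2fc Numeric vector of log2 fold changes.
#' @param se Numeric vector of their standard errors.
#' @return Data frame with `fold`, `lower`, `upper`.
#' @export
fold_enrichment <- function(log2fc, se) {
  stopifnot(length(log2fc) == length(se), all(se >= 0))
  data.frame(fold = 2^log2fc, lower = 2^(log2fc - se),
             upper = 2^(log2fc + se))
}

#' Survival gene-set definition
#'
#' Two externally derived gene lists — genes whose high expression is
#' associated with poor survival, and genes whose low expression is — plus
#' the remaining tested genes as background. Genes appearing in both lists
#' are excluded from both with a warning.
#'
#' @param high_poor,low_poor Character vectors of gene ids.
#' @return Object of class `survival_gene_sets`.
#' @export
survival_gene_sets <- function(high_poor, low_poor) {
  high_poor <- unique(as.character(high_poor))
  low_poor <- unique(as.character(low_poor))
  both <- intersect(high_poor, low_poor)
  if (length(both)) {
    warning(length(both),
            " gene(s) in both survival lists excluded from both")
    high_poor <- setdiff(high_poor, both)
    low_poor <- setdiff(low_poor, both)
  }
  structure(list(high_poor = high_poor, low_poor = low_poor),
            class = "survival_gene_sets")
}

#' Compare fold-change distributions of survival gene sets
#'
#' Maps the survival gene lists onto differential-expression results and
#' compares the log2 fold-change distributions of the `high_poor`,
#' `low_poor` and `background` groups: a Kruskal-Wallis omnibus test
#' followed by Dunn pairwise z statistics on the joint ranks with
#' tie-corrected pooled variance, Benjamini-Hochberg adjusted across pairs.
#'
#' @param results Result data frame with `gene_id` (or `region_id`) and
#'   `log2fc`.
#' @param sets A [survival_gene_sets()].
#' @return List with `kruskal_p`, `group_sizes`, and `pairs` (data frame:
#'   `group1`, `group2`, `z`, `p`, `fdr`). Pairs involving an empty group
#'   are skipped with a warning.
#' @export
survival_distribution_test <- function(results, sets) {
  stopifnot(inherits(sets, "survival_gene_sets"))
  id <- if (!is.null(results$gene_id)) results$gene_id else results$region_id
  group <- rep("background", nrow(results))
  group[id %in% sets$high_poor] <- "high_poor"
  group[id %in% sets$low_poor] <- "low_poor"
  dunn_test(results$log2fc, group,
            levels = c("high_poor", "low_poor", "background"))
}

#' Kruskal-Wallis omnibus and Dunn pairwise rank comparison
#'
#' Ranks all values jointly (average ranks for ties); the Dunn statistic
#' for groups `i`, `j` is the difference of mean ranks scaled by
#' `sqrt((N(N+1)/12 - T) (1/n_i + 1/n_j))`, with tie correction
#' `T = sum(t^3 - t) / (12 (N - 1))`. Pairwise p-values are two-sided
#' normal, BH-adjusted across pairs.
#'
#' @param values Numeric vector.
#' @param group Group label per value.
#' @param levels Optional group ordering.
#' @return List with `kruskal_p`, `group_sizes`, `pairs`.
#' @export
dunn_test <- function(values, group, levels = unique(group)) {
  keep <- is.finite(values) & !is.na(group)
  values <- values[keep]
  group <- factor(group[keep], levels = levels)
  sizes <- table(group)
  present <- names(sizes)[sizes > 0]
  if (length(present) < 2L) {
    stop("need >= 2 non-empty groups", call. = FALSE)
  }
  if (any(sizes == 0)) {
    warning("empty group(s) skipped: ",
            paste(names(sizes)[sizes == 0], collapse = ", "))
  }
  kw <- stats::kruskal.test(values, factor(as.character(group),
                                           levels = present))
  r <- rank(values)
  N <- length(values)
  mean_rank <- tapply(r, group, mean)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  sigma2 <- N * (N + 1) / 12 - tie_corr
  combos <- utils::combn(present, 2L)
  z <- p <- numeric(ncol(combos))
  for (i in seq_len(ncol(combos))) {
    g1 <- combos[1L, i]; g2 <- combos[2L, i]
    if (sigma2 <= 0) {
      z[i] <- 0  # every value tied: no rank information
    } else {
      z[i] <- (mean_rank[[g1]] - mean_rank[[g2]]) /
        sqrt(sigma2 * (1 / sizes[[g1]] + 1 / sizes[[g2]]))
    }
    p[i] <- 2 * stats::pnorm(-abs(z[i]))
  }
  list(kruskal_p = kw$p.value,
       group_sizes = stats::setNames(as.integer(sizes), names(sizes)),
       pairs = data.frame(group1 = combos[1L, ], group2 = combos[2L, ],
                          z = z, p = p, fdr = bh_adjust(p),
                          stringsAsFactors = FALSE))
}

#' Relative quantification by the ddCt method
#'
#' Averages replicate Ct values, normalises each gene to the housekeeping
#' gene within the same sample (`dCt = Ct_gene - Ct_housekeeping`), then to
#' a calibrator sample (`ddCt = dCt_sample - dCt_calibrator`), and reports
#' `fold = 2^(-ddCt)`; the calibrator's fold change is 1 by construction.
#'
#' @param ct Long-format data frame with columns `gene`, `sample`, `ct`
#'   (replicate rows allowed and averaged).
#' @param housekeeping Housekeeping gene id (default `"TBP"`); must be
#'   measured in every sample.
#' @param calibrator Calibrator sample id.
#' @return List with matrices `dct`, `ddct`, `fold` (genes x samples).
#' @export
ddct_fold_change <- function(ct, housekeeping = "TBP", calibrator) {
  stopifnot(all(c("gene", "sample", "ct") %in% names(ct)))
  if (any(ct$ct <= 0)) stop("Ct values must be positive", call. = FALSE)
  avg <- tapply(ct$ct, list(ct$gene, ct$sample), mean)
  if (!housekeeping %in% rownames(avg) ||
      anyNA(avg[housekeeping, ])) {
    stop("housekeeping gene must be measured in every sample",
         call. = FALSE)
  }
  if (!calibrator %in% colnames(avg)) {
    stop("calibrator sample not found: ", calibrator, call. = FALSE)
  }
  dct <- sweep(avg, 2L, avg[housekeeping, ], `-`)
  ddct <- sweep(dct, 1L, dct[, calibrator], `-`)
  list(dct = dct, ddct = ddct, fold = 2^(-ddct))
}

#' Caliper tumour volume
#'
#' `V = (4/3) * pi * ((d1 + d2) / 4)^3` from two perpendicular diameters in
#' mm; the result is in mm^3 and depends only on `d1 + d2`.
#'
#' @param d1,d2 Perpendicular tumour diameters in mm (>= 0).
#' @return Tumour volume(s) in mm^3.
#' @export
tumor_volume <- function(d1, d2) {
  if (any(d1 < 0) || any(d2 < 0)) {
    stop("diameters must be non-negative", call. = FALSE)
  }
  (4 / 3) * pi * ((d1 + d2) / 4)^3
}
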