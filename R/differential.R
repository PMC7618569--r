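# Differential occupancy testing. The engine is a negative-binomial Wald
# test on library-size-normalised counts with a common method-of-moments
# dispersion: the classification thresholds, not estimator internals, carry
# the downstream logic, so a transparent and fast test is preferred over a
# full GLM fit.

#' Negative-binomial Wald test between two conditions
#'
#' For each region, counts are normalised to CPM, a common dispersion
#' `alpha` is estimated by method of moments (the median over regions of the
#' truncated per-region estimate `(s2 - fbar * m) / m^2`, where `s2` is the
#' pooled within-condition variance of the normalised counts, `m` the mean
#' and `fbar` the mean CPM scale factor, so that the Poisson component of
#' the variance is removed before solving for `alpha`), and a Wald statistic
#' is formed for the log2 fold change
#' `log2((mean_b + c) / (mean_a + c))` with pseudocount `c` (CPM units). The
#' standard error comes from the NB delta method with the common dispersion;
#' p-values are two-sided normal, and `fdr` is the Benjamini-Hochberg
#' adjustment across regions.
#'
#' @param m A [count_matrix()].
#' @param cond_a Reference condition name.
#' @param cond_b Alternative condition name (fold changes are b vs a).
#' @param pseudo_cpm Pseudocount added to both means, in CPM.
#' @return Data frame with columns `region_id`, `mean_norm_a`,
#'   `mean_norm_b`, `log2fc`, `se_log2fc`, `p`, `fdr`. The dispersion
#'   estimate is attached as attribute `"dispersion"`.
#' @export
nb_test <- function(m, cond_a, cond_b, pseudo_cpm = 0.5) {
  stopifnot(inherits(m, "count_matrix"))
  cond <- m$design$condition
  for (cn in c(cond_a, cond_b)) {
    if (!cn %in% cond) stop("condition not in design: ", cn, call. = FALSE)
    if (sum(cond == cn) < 2L) {
      stop("need >= 2 replicates in condition ", cn, call. = FALSE)
    }
  }
  norm <- normalize_cpm(m)
  f <- 1e6 / m$lib_sizes
  ia <- which(cond == cond_a)
  ib <- which(cond == cond_b)
  na <- length(ia); nb <- length(ib)
  ma <- rowMeans(norm[, ia, drop = FALSE])
  mb <- rowMeans(norm[, ib, drop = FALSE])
  va <- row_vars(norm[, ia, drop = FALSE])
  vb <- row_vars(norm[, ib, drop = FALSE])

  # Common dispersion: pooled within-condition variance, Poisson part
  # removed via the mean CPM scale factor, truncated at zero, median-pooled.
  pooled_var <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  pooled_mean <- (ma + mb) / 2
  fbar <- mean(f[c(ia, ib)])
  est <- (pooled_var - fbar * pooled_mean) / pooled_mean^2
  est <- est[is.finite(est) & pooled_mean > 0]
  alpha <- if (length(est)) stats::median(pmax(0, est)) else 0

  # Delta-method variance of the group means on the CPM scale:
  # var(norm_s) = f_s * mu + alpha * mu^2.
  var_mean_a <- (ma * sum(f[ia]) + alpha * ma^2 * na) / na^2
  var_mean_b <- (mb * sum(f[ib]) + alpha * mb^2 * nb) / nb^2
  log2fc <- log2((mb + pseudo_cpm) / (ma + pseudo_cpm))
  se <- sqrt(var_mean_a / (ma + pseudo_cpm)^2 +
               var_mean_b / (mb + pseudo_cpm)^2) / log(2)
  z <- ifelse(se > 0, log2fc / se, 0)
  p <- 2 * stats::pnorm(-abs(z))
  out <- data.frame(
    region_id = rownames(m$counts),
    mean_norm_a = ma, mean_norm_b = mb,
    log2fc = log2fc, se_log2fc = se,
    p = p, fdr = bh_adjust(p),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "dispersion") <- alpha
  attr(out, "conditions") <- c(a = cond_a, b = cond_b)
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate adjustment with monotonicity enforcement;
#' input order is preserved.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of adjusted p-values (FDR), same order.
#' @export
bh_adjust <- function(pvals) {
  if (length(pvals) == 0L) return(numeric())
  if (anyNA(pvals) || any(pvals < 0 | pvals > 1)) {
    stop("p-values must be in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Three-tier differential mark classification
#'
#' Applies the fixed thresholds used throughout the analysis: a region is
#' `increased` if `log2fc > lfc_min` and `fdr < fdr_sig`, `decreased` if
#' `log2fc < -lfc_min` and `fdr < fdr_sig`, `not_significant` if
#' `fdr > fdr_ns`, and `unclassified` otherwise (the rule gap between the
#' significance and the no-change tier). Every region receives exactly one
#' class.
#'
#' @param results Data frame from [nb_test()] (needs `log2fc` and `fdr`).
#' @param lfc_min Absolute log2 fold-change threshold (default 0.5).
#' @param fdr_sig FDR below which a sufficiently large change is called
#'   (default 0.05).
#' @param fdr_ns FDR above which a region is called not significant
#'   (default 0.5); must exceed `fdr_sig`.
#' @return `results` with an added factor column `mark_class` with levels
#'   `increased`, `decreased`, `not_significant`, `unclassified`.
#' @export
classify_marks <- function(results, lfc_min = 0.5, fdr_sig = 0.05,
                           fdr_ns = 0.5) {
  if (fdr_ns <= fdr_sig) stop("fdr_ns must exceed fdr_sig", call. = FALSE)
  stopifnot(all(c("log2fc", "fdr") %in% names(results)))
  cls <- rep("unclassified", nrow(results))
  cls[results$fdr > fdr_ns] <- "not_significant"
  cls[results$log2fc > lfc_min & results$fdr < fdr_sig] <- "increased"
  cls[results$log2fc < -lfc_min & results$fdr < fdr_sig] <- "decreased"
  results$mark_class <- factor(cls, levels = c("increased", "decreased",
                                               "not_significant",
                                               "unclassified"))
  results
}

#' Direction-pattern grouping across conditions
#'
#' Groups regions by the direction of change across several
#' treatment-vs-control comparisons. Each comparison contributes a state:
#' `up` for `increased`, `down` for `decreased`, and `ns` otherwise
#' (`not_significant` and `unclassified` both count as `ns`). For three
#' comparisons the 27 possible patterns are numbered canonically:
#' `group_id = 9*s1 + 3*s2 + s3 + 1` with `up = 0`, `ns = 1`, `down = 2` and
#' the first condition as the most significant digit, so `(up, up, up)` is
#' group 1 and `(ns, ns, ns)` group 14.
#'
#' @param results Named list of classified result data frames (one per
#'   comparison, see [classify_marks()]), all covering the same regions;
#'   list order defines digit significance.
#' @return Data frame with `region_id`, one `state_<condition>` column per
#'   comparison, and `group_id`.
#' @seealso [direction_group_sizes()] for the full (possibly empty) group
#'   size table.
#' @export
direction_grouping <- function(results) {
  stopifnot(is.list(results), length(results) >= 1L,
            !is.null(names(results)))
  ids <- results[[1L]]$region_id
  states <- matrix(NA_integer_, nrow = length(ids), ncol = length(results))
  for (j in seq_along(results)) {
    r <- results[[j]]
    if (is.null(r$mark_class)) {
      stop("results must be classified (run classify_marks)", call. = FALSE)
    }
    idx <- match(ids, r$region_id)
    if (anyNA(idx)) {
      stop("region missing in comparison ", names(results)[j], call. = FALSE)
    }
    cls <- as.character(r$mark_class)[idx]
    states[, j] <- ifelse(cls == "increased", 0L,
                          ifelse(cls == "decreased", 2L, 1L))
  }
  k <- length(results)
  group_id <- as.integer(states %*% (3^((k - 1):0)) + 1L)
  out <- data.frame(region_id = ids, stringsAsFactors = FALSE)
  lab <- c("up", "ns", "down")
  for (j in seq_along(results)) {
    out[[paste0("state_", names(results)[j])]] <- lab[states[, j] + 1L]
  }
  out$group_id <- group_id
  out
}

#' @rdname direction_grouping
#' @param patterns Output of [direction_grouping()].
#' @param n_conditions Number of comparisons (defaults to the number of
#'   state columns).
#' @return Named integer vector of length `3^n_conditions`, including empty
#'   groups.
#' @export
direction_group_sizes <- function(patterns,
                                  n_conditions =
                                    sum(startsWith(names(patterns),
                                                   "state_"))) {
  n_groups <- 3L^n_conditions
  tab <- tabulate(patterns$group_id, nbins = n_groups)
  names(tab) <- as.character(seq_len(n_groups))
  tab
}
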