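#' Region-by-sample fragment counts with design
#'
#' Container pairing a non-negative integer count matrix (regions in rows,
#' samples in columns) with per-sample total library sizes and a
#' condition/replicate design. Library sizes are the samples' total fragment
#' counts (genome-wide), not the column sums of the matrix.
#'
#' @param counts Numeric matrix of counts with region row names and sample
#'   column names.
#' @param lib_sizes Named numeric vector, sample -> total fragments (> 0).
#' @param design Data frame with columns `sample_id`, `condition` and
#'   optionally `replicate`, one row per sample.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, lib_sizes, design) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have region row names and sample column names",
         call. = FALSE)
  }
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (!all(colnames(counts) %in% names(lib_sizes))) {
    stop("lib_sizes must name every sample", call. = FALSE)
  }
  lib_sizes <- lib_sizes[colnames(counts)]
  if (any(lib_sizes <= 0)) stop("library sizes must be > 0", call. = FALSE)
  stopifnot(all(c("sample_id", "condition") %in% names(design)))
  if (!all(colnames(counts) %in% design$sample_id)) {
    stop("design must cover every sample", call. = FALSE)
  }
  design <- design[match(colnames(counts), design$sample_id), , drop = FALSE]
  rownames(design) <- NULL
  structure(list(counts = counts, lib_sizes = lib_sizes, design = design),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "regions x", ncol(x$counts),
      "samples (", paste(unique(x$design$condition), collapse = ", "), ")\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Counts-per-million normalisation
#'
#' Scales each count by `1e6 / library size` of its sample, i.e. normalises
#' for library size based on the total number of fragments in the sample.
#'
#' @param m A [count_matrix()].
#' @return Numeric matrix of CPM values, same dimnames as the counts.
#' @export
normalize_cpm <- function(m) {
  stopifnot(inherits(m, "count_matrix"))
  if (any(m$lib_sizes <= 0)) stop("library sizes must be > 0", call. = FALSE)
  sweep(m$counts, 2L, 1e6 / m$lib_sizes, `*`)
}

#' Count fragments overlapping regions
#'
#' Tabulates, for each region and sample, the number of fragments with
#' >= 1 bp overlap; a fragment spanning several regions is counted once in
#' each.
#'
#' @param regions Interval data frame.
#' @param fragments Named list (sample -> interval data frame of fragments).
#' @param lib_sizes Named numeric vector, sample -> total fragments.
#' @param design Design data frame (`sample_id`, `condition`, ...).
#' @return A [count_matrix()] over the regions (row names are
#'   `chrom:start-end` unless the regions carry a `name` column).
#' @export
count_regions <- function(regions, fragments, lib_sizes, design) {
  validate_intervals(regions)
  regions <- sort_intervals(regions)
  ids <- if (!is.null(regions$name) && !anyNA(regions$name)) {
    regions$name
  } else {
    sprintf("%s:%s-%s", regions$chrom, regions$start, regions$end)
  }
  gr <- gi_to_granges(regions)
  counts <- matrix(0L, nrow = nrow(regions), ncol = length(fragments),
                   dimnames = list(ids, names(fragments)))
  for (s in seq_along(fragments)) {
    frag <- fragments[[s]]
    validate_intervals(frag, what = "fragments")
    if (nrow(frag) == 0L) next
    counts[, s] <- GenomicRanges::countOverlaps(gr, gi_to_granges(frag))
  }
  count_matrix(counts, lib_sizes = lib_sizes, design = design)
}

#' Write / read a counts table as TSV
#'
#' Plain-text interchange: first column `region_id`, one column per sample.
#'
#' @param m A [count_matrix()].
#' @param path Output path.
#' @return `write_counts_tsv` invisibly returns `path`; `read_counts_tsv`
#'   returns the counts as a plain matrix (library sizes and design are not
#'   stored in the TSV).
#' @export
write_counts_tsv <- function(m, path) {
  stopifnot(inherits(m, "count_matrix"))
  df <- data.frame(region_id = rownames(m$counts), m$counts,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}
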