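# Genomic intervals are plain data frames with 0-based half-open coordinates
# (columns chrom, start, end, and optionally name, score, strand). GRanges is
# used internally for merging and overlap queries; the 0-based convention is
# preserved at the package surface.

#' Construct a genomic interval table
#'
#' Builds the package's canonical interval representation: a data frame with
#' 0-based half-open coordinates, sorted by `(chrom, start, end)`.
#'
#' @param chrom Character vector of chromosome names.
#' @param start Integer vector of 0-based inclusive start positions.
#' @param end Integer vector of exclusive end positions (`end > start`).
#' @param name Optional character vector of interval names.
#' @param score Optional numeric vector of scores.
#' @param strand Optional strand vector (`"+"`, `"-"` or `NA`).
#'
#' @return A data frame with columns `chrom`, `start`, `end`, `name`, `score`,
#'   `strand`, sorted by coordinate.
#' @export
#' @examples
#' genomic_intervals("chr1", c(0, 500), c(100, 900))
genomic_intervals <- function(chrom, start, end, name = NA_character_,
                              score = NA_real_, strand = NA_character_) {
  n <- length(chrom)
  df <- data.frame(
    chrom = as.character(chrom),
    start = as.numeric(start),
    end = as.numeric(end),
    name = rep_len(as.character(name), n),
    score = rep_len(as.numeric(score), n),
    strand = rep_len(as.character(strand), n),
    stringsAsFactors = FALSE
  )
  validate_intervals(df)
  sort_intervals(df)
}

validate_intervals <- function(df, what = "intervals") {
  needed <- c("chrom", "start", "end")
  if (!all(needed %in% names(df))) {
    stop(what, " must have columns chrom, start, end", call. = FALSE)
  }
  if (nrow(df) == 0L) return(invisible(df))
  if (anyNA(df$start) || anyNA(df$end)) {
    stop(what, ": missing coordinates", call. = FALSE)
  }
  bad <- which(df$start < 0 | df$start >= df$end)
  if (length(bad)) {
    stop(what, ": invalid coordinates (need 0 <= start < end) at row ",
         bad[1L], call. = FALSE)
  }
  invisible(df)
}

sort_intervals <- function(df) {
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# Canonicalise an arbitrary interval data frame: ensure the optional columns
# exist and the rows are sorted. Used so round-trips through BED are stable.
canonical_intervals <- function(df) {
  if (is.null(df$name)) df$name <- rep_len(NA_character_, nrow(df))
  if (is.null(df$score)) df$score <- rep_len(NA_real_, nrow(df))
  if (is.null(df$strand)) df$strand <- rep_len(NA_character_, nrow(df))
  df$name <- as.character(df$name)
  df$score <- as.numeric(df$score)
  df$strand <- as.character(df$strand)
  sort_intervals(df[, c("chrom", "start", "end", "name", "score", "strand")])
}

# 0-based half-open -> GRanges (1-based closed).
gi_to_granges <- function(df) {
  if (nrow(df) == 0L) {
    return(GenomicRanges::GRanges())
  }
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

granges_to_gi <- function(gr) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = as.numeric(GenomicRanges::start(gr)) - 1,
    end = as.numeric(GenomicRanges::end(gr)),
    stringsAsFactors = FALSE
  )
  sort_intervals(df)
}

#' Read a BED or broadPeak file
#'
#' Accepts 3 to 9 tab-separated columns (broadPeak is treated as a BED
#' superset). Coordinates are kept 0-based half-open. `track`/`browser` lines
#' and comments are skipped. Malformed coordinates raise an error naming the
#' offending line.
#'
#' @param path Path to a BED/broadPeak file.
#' @return An interval data frame (see [genomic_intervals()]).
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (!length(idx)) {
    return(canonical_intervals(
      data.frame(chrom = character(), start = numeric(), end = numeric())
    ))
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  ncol <- lengths(fields)
  if (any(ncol < 3L)) {
    stop("line ", idx[which(ncol < 3L)[1L]], ": fewer than 3 columns",
         call. = FALSE)
  }
  get_col <- function(j) vapply(fields, function(f) {
    if (length(f) >= j) f[[j]] else NA_character_
  }, character(1))
  start <- suppressWarnings(as.numeric(get_col(2L)))
  end <- suppressWarnings(as.numeric(get_col(3L)))
  bad <- which(is.na(start) | is.na(end) | start %% 1 != 0 | end %% 1 != 0)
  if (length(bad)) {
    stop("line ", idx[bad[1L]], ": malformed coordinates", call. = FALSE)
  }
  bad <- which(start < 0 | start >= end)
  if (length(bad)) {
    stop("line ", idx[bad[1L]], ": invalid interval (need 0 <= start < end)",
         call. = FALSE)
  }
  name <- get_col(4L)
  name[name %in% "."] <- NA_character_
  score_raw <- get_col(5L)
  score <- suppressWarnings(as.numeric(score_raw))
  bad <- which(!is.na(score_raw) & score_raw != "." & is.na(score))
  if (length(bad)) {
    stop("line ", idx[bad[1L]], ": malformed score", call. = FALSE)
  }
  strand <- get_col(6L)
  strand[!strand %in% c("+", "-")] <- NA_character_
  canonical_intervals(data.frame(
    chrom = get_col(1L), start = start, end = end,
    name = name, score = score, strand = strand,
    stringsAsFactors = FALSE
  ))
}

#' Write intervals as BED or broadPeak
#'
#' Rows are sorted by coordinate before writing. BED output uses 3 columns
#' when no interval carries a name, score or strand, otherwise 6. broadPeak
#' output always has 9 columns, with `signalValue` taken from `score` and
#' `pValue`/`qValue` set to -1.
#'
#' @param intervals Interval data frame.
#' @param path Output path.
#' @param format `"bed"` (default) or `"broadPeak"`.
#' @return Invisibly, the path written.
#' @export
write_bed <- function(intervals, path, format = c("bed", "broadPeak")) {
  format <- match.arg(format)
  df <- canonical_intervals(validate_intervals(intervals))
  name <- ifelse(is.na(df$name), ".", df$name)
  score <- ifelse(is.na(df$score), 0, df$score)
  strand <- ifelse(is.na(df$strand), ".", df$strand)
  if (format == "bed") {
    bed6 <- any(!is.na(df$name)) || any(!is.na(df$score)) ||
      any(!is.na(df$strand))
    out <- if (bed6) {
      paste(df$chrom, format_coord(df$start), format_coord(df$end),
            name, score, strand, sep = "\t")
    } else {
      paste(df$chrom, format_coord(df$start), format_coord(df$end), sep = "\t")
    }
  } else {
    out <- paste(df$chrom, format_coord(df$start), format_coord(df$end),
                 name, 0L, strand, score, -1, -1, sep = "\t")
  }
  writeLines(out, path)
  invisible(path)
}

format_coord <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' Merge overlapping or nearby intervals
#'
#' Transitively merges intervals whose gap (`next.start - prev.end` in
#' half-open coordinates) is at most `gap`; with `gap = 0`, overlapping and
#' book-ended intervals are unioned. Chromosomes are processed independently.
#'
#' @param intervals Interval data frame (need not be sorted).
#' @param gap Maximum separation (bp) at which two intervals are still merged.
#' @return A sorted interval data frame of pairwise non-overlapping regions,
#'   adjacent regions separated by more than `gap`.
#' @export
#' @examples
#' merge_intervals(genomic_intervals("chr1", c(0, 5), c(10, 15)))
merge_intervals <- function(intervals, gap = 0) {
  stopifnot(length(gap) == 1L, gap >= 0)
  validate_intervals(intervals)
  if (nrow(intervals) == 0L) {
    return(sort_intervals(
      data.frame(chrom = character(), start = numeric(), end = numeric())
    ))
  }
  gr <- GenomicRanges::reduce(gi_to_granges(intervals),
                              min.gapwidth = gap + 1)
  granges_to_gi(gr)
}

#' Bundle one replicate's peaks
#'
#' Light container pairing a sample's identity with its peak intervals, as
#' produced by a peak caller for one biological replicate.
#'
#' @param sample_id Sample identifier.
#' @param condition Condition label.
#' @param replicate Replicate number.
#' @param intervals Interval data frame of called peaks.
#' @return An object of class `peak_collection`.
#' @export
peak_collection <- function(sample_id, condition, replicate, intervals) {
  validate_intervals(intervals)
  structure(
    list(sample_id = as.character(sample_id),
         condition = as.character(condition),
         replicate = as.integer(replicate),
         intervals = sort_intervals(intervals)),
    class = "peak_collection"
  )
}

#' @export
print.peak_collection <- function(x, ...) {
  cat("peak_collection:", x$sample_id,
      sprintf("(%s, replicate %d) with %d peaks\n",
              x$condition, x$replicate, nrow(x$intervals)))
  invisible(x)
}

peak_intervals <- function(x) {
  if (inherits(x, "peak_collection")) x$intervals else x
}

#' Replicate-consensus peaks
#'
#' Builds the consensus peak set of a condition: all replicate peaks are
#' merged (gap 0) into candidate regions; each replicate supports a candidate
#' if at least one of its peaks overlaps it by >= 1 bp (contributing at most
#' one unit of support); candidates supported by at least `min_support`
#' replicates are kept with the merged-region coordinates. This reproduces
#' occupancy rules such as "present in at least three of five replicates"
#' (`min_support = 3`) or "at least two of four" (`min_support = 2`).
#'
#' @param replicates List of [peak_collection()] objects (or plain interval
#'   data frames).
#' @param min_support Minimum number of supporting replicates, in
#'   `[1, length(replicates)]`.
#' @return Interval data frame of consensus regions with a `support` column.
#' @export
consensus_peaks <- function(replicates, min_support) {
  stopifnot(is.list(replicates), length(replicates) >= 1L)
  if (length(min_support) != 1L || min_support < 1 ||
      min_support > length(replicates)) {
    stop("min_support must be in [1, number of replicates]", call. = FALSE)
  }
  ivs <- lapply(replicates, peak_intervals)
  for (iv in ivs) validate_intervals(iv)
  all_iv <- do.call(rbind, lapply(ivs, function(d)
    d[, c("chrom", "start", "end"), drop = FALSE]))
  candidates <- merge_intervals(all_iv, gap = 0)
  if (nrow(candidates) == 0L) {
    candidates$support <- integer()
    return(candidates)
  }
  cand_gr <- gi_to_granges(candidates)
  support <- rep(0L, nrow(candidates))
  for (iv in ivs) {
    if (nrow(iv) == 0L) next
    hit <- GenomicRanges::countOverlaps(cand_gr, gi_to_granges(iv)) > 0L
    support <- support + as.integer(hit)
  }
  out <- candidates[support >= min_support, , drop = FALSE]
  out$support <- support[support >= min_support]
  rownames(out) <- NULL
  out
}
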