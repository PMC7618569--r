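# Proximal-gene assignment and gene-set enrichment. Distances are measured
# from the TSS to the nearest region boundary (0 when the TSS lies inside
# the region); strand affects only where the TSS is, never the sign of a
# distance.

#' Assign the most proximal gene to each region
#'
#' For each region, the distance to a gene is 0 when its TSS lies within
#' `[start, end)` and otherwise the gap between the TSS and the nearest
#' covered base (`start - tss` to the left, `tss - end + 1` to the right).
#' The minimising gene is assigned if its distance is at most
#' `max_distance`; ties go to the lexicographically smallest `gene_id`.
#' Regions with no TSS within reach get `NA`.
#'
#' @param regions Interval data frame (a `name` column, if complete, is used
#'   as `region_id`).
#' @param genes Gene table with `gene_id`, `chrom`, `tss` columns.
#' @param max_distance Maximum assignment distance in bp (default 100 kb).
#' @param promoter_halfwidth Promoter window half-width passed to
#'   [annotate_feature()] for the `feature` column.
#' @return Data frame with `region_id`, `gene_id`, `distance`, `feature`.
#' @export
nearest_gene <- function(regions, genes, max_distance = 1e5,
                         promoter_halfwidth = 2500) {
  validate_intervals(regions, what = "regions")
  regions <- sort_intervals(regions)
  ids <- region_ids(regions)
  gene_id <- rep(NA_character_, nrow(regions))
  distance <- rep(NA_real_, nrow(regions))
  by_chrom <- split(seq_len(nrow(genes)), genes$chrom)
  for (i in seq_len(nrow(regions))) {
    gi <- by_chrom[[regions$chrom[i]]]
    if (is.null(gi)) next
    tss <- genes$tss[gi]
    d <- pmax(regions$start[i] - tss, tss - regions$end[i] + 1, 0)
    d_min <- min(d)
    if (d_min > max_distance) next
    cand <- genes$gene_id[gi][d == d_min]
    gene_id[i] <- min(cand)
    distance[i] <- d_min
  }
  data.frame(region_id = ids, gene_id = gene_id, distance = distance,
             feature = annotate_feature(regions, genes,
                                        promoter_halfwidth),
             stringsAsFactors = FALSE)
}

region_ids <- function(regions) {
  if (!is.null(regions$name) && !anyNA(regions$name)) {
    as.character(regions$name)
  } else {
    sprintf("%s:%s-%s", regions$chrom, regions$start, regions$end)
  }
}

#' Promoter / distal feature annotation
#'
#' A region is a `promoter` when it overlaps any window
#' `[tss - w, tss + w)` by >= 1 bp, and `distal` otherwise.
#'
#' @param regions Interval data frame.
#' @param genes Gene table with `chrom` and `tss` columns.
#' @param promoter_halfwidth Window half-width `w` in bp (default 2500).
#' @return Character vector (`"promoter"`/`"distal"`), one per region (in
#'   sorted region order).
#' @export
annotate_feature <- function(regions, genes, promoter_halfwidth = 2500) {
  validate_intervals(regions, what = "regions")
  regions <- sort_intervals(regions)
  out <- rep("distal", nrow(regions))
  if (!nrow(regions) || is.null(genes) || !nrow(genes)) return(out)
  w <- promoter_halfwidth
  win <- sort_intervals(data.frame(chrom = genes$chrom,
                                   start = pmax(0, genes$tss - w),
                                   end = genes$tss + w))
  hit <- GenomicRanges::countOverlaps(gi_to_granges(regions),
                                      gi_to_granges(win)) > 0
  out[hit] <- "promoter"
  out
}

#' Venn cell counts for two or three gene sets
#'
#' Tabulates every intersection cell of 2 or 3 labelled sets; the cells
#' partition the union, so the counts sum to its size.
#'
#' @param sets Named list of 2 or 3 character vectors.
#' @return Named integer vector: one entry per non-empty label combination
#'   (e.g. `"A"`, `"A&B"`, `"A&B&C"`), covering all `2^k - 1` cells.
#' @export
gene_set_overlap <- function(sets) {
  k <- length(sets)
  if (k < 2L || k > 3L) {
    stop("gene_set_overlap supports 2 or 3 sets", call. = FALSE)
  }
  if (is.null(names(sets)) || anyDuplicated(names(sets))) {
    stop("sets must have unique names", call. = FALSE)
  }
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 0L) {
    member <- matrix(logical(), ncol = k, dimnames = list(NULL, names(sets)))
  }
  combos <- expand.grid(rep(list(c(TRUE, FALSE)), k))[-(2L^k), , drop = FALSE]
  counts <- integer(nrow(combos))
  labels <- character(nrow(combos))
  for (i in seq_len(nrow(combos))) {
    pattern <- as.logical(combos[i, ])
    counts[i] <- sum(apply(member, 1L, function(r) all(r == pattern)))
    labels[i] <- paste(names(sets)[pattern], collapse = "&")
  }
  stats::setNames(counts, labels)
}

#' Gene-set collection with a universe
#'
#' @param sets Named list of character vectors of gene ids.
#' @param universe Character vector: all genes eligible for testing. Sets
#'   are restricted to the universe.
#' @return Object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, universe) {
  if (is.null(names(sets)) || anyDuplicated(names(sets))) {
    stop("sets must have unique names", call. = FALSE)
  }
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("empty universe", call. = FALSE)
  sets <- lapply(sets, function(s) intersect(unique(s), universe))
  structure(list(sets = sets, universe = universe),
            class = "gene_set_collection")
}

#' Read gene sets from a GMT-like TSV
#'
#' One set per line: name, description, then tab-separated member gene ids.
#'
#' @param path Path to the file.
#' @return Named list of character vectors.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad)) {
    stop("line ", bad[1L], ": need name, description and >= 1 member",
         call. = FALSE)
  }
  stats::setNames(lapply(fields, function(f) f[-(1:2)]),
                  vapply(fields, `[[`, character(1), 1L))
}

#' Hypergeometric gene-set enrichment
#'
#' Over-representation analysis: for each set of size `m` (after
#' restriction to the universe and the size filter), the p-value is the
#' hypergeometric upper tail `P(X >= k)` of drawing `k` set members in a
#' query of size `n` from a universe of size `N`. FDR is Benjamini-Hochberg
#' across the tested sets; results are ordered by FDR then p, and the
#' `top` column flags the `top_n` most significant sets with `fdr < 0.05`.
#'
#' @param query Character vector of genes of interest; genes outside the
#'   universe are dropped with a warning.
#' @param collection A [gene_set_collection()].
#' @param min_size,max_size Set-size filter applied after restriction to
#'   the universe (defaults 20 and 500).
#' @param top_n How many significant sets to flag (default 10).
#' @return Data frame with `set`, `k`, `m`, `n`, `N`, `p`, `fdr`, `top`.
#' @export
enrich <- function(query, collection, min_size = 20, max_size = 500,
                   top_n = 10) {
  stopifnot(inherits(collection, "gene_set_collection"))
  universe <- collection$universe
  query <- unique(as.character(query))
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the universe dropped")
    query <- intersect(query, universe)
  }
  sizes <- lengths(collection$sets)
  keep <- sizes >= min_size & sizes <= max_size
  sets <- collection$sets[keep]
  N <- length(universe)
  n <- length(query)
  k <- vapply(sets, function(s) length(intersect(s, query)), integer(1))
  m <- lengths(sets)
  p <- stats::phyper(k - 1, m, N - m, n, lower.tail = FALSE)
  out <- data.frame(set = names(sets), k = k, m = m, n = n, N = N,
                    p = p, fdr = bh_adjust(p), stringsAsFactors = FALSE)
  out <- out[order(out$fdr, out$p, out$set), , drop = FALSE]
  out$top <- seq_len(nrow(out)) <= top_n & out$fdr < 0.05
  rownames(out) <- NULL
  out
}
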