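# BEDPE chromatin-loop ingestion, loop filtering, and peak-anchored loop
# statistics per detection-probability group.

#' Read chromatin loops from a BEDPE file
#'
#' Parses the first six columns (chrom1, start1, end1, chrom2, start2, end2;
#' 0-based half-open) into a [LoopSet]. Anchors are normalised so anchor1
#' lies upstream of anchor2; inter-chromosomal rows are skipped and their
#' count reported in a message. Per-replicate loop counts are taken from the
#' columns named by `count_cols` (1-based column indices).
#'
#' @param path path to a BEDPE file.
#' @param count_cols integer vector of count column indices (e.g. `c(8, 9)`
#'   for two replicate counts); `NULL` yields a zero-column count matrix.
#' @return a [LoopSet].
#' @export
readBedpe <- function(path, count_cols = NULL) {
  assertThat(file.exists(path), paste0("BEDPE file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (!length(idx)) {
    return(new("LoopSet", anchor1 = GRanges(), anchor2 = GRanges(),
               counts = matrix(numeric(0), nrow = 0,
                               ncol = length(count_cols))))
  }
  fields <- strsplit(lines[idx], "[ \t]+")
  need <- max(6L, if (length(count_cols)) max(count_cols) else 0L)
  short <- which(lengths(fields) < need)
  if (length(short)) {
    stop("BEDPE parse error at line ", idx[short[1]], " of ", path,
         ": fewer than ", need, " columns", call. = FALSE)
  }
  col <- function(j) vapply(fields, `[[`, character(1), j)
  num <- function(j, what) {
    v <- suppressWarnings(as.numeric(col(j)))
    bad <- which(!is.finite(v))
    if (length(bad)) {
      stop("BEDPE parse error at line ", idx[bad[1]], " of ", path,
           ": ", what, " does not parse as a number", call. = FALSE)
    }
    v
  }
  c1 <- col(1); s1 <- num(2, "start1"); e1 <- num(3, "end1")
  c2 <- col(4); s2 <- num(5, "start2"); e2 <- num(6, "end2")
  bad <- which(s1 >= e1 | s2 >= e2 | s1 < 0 | s2 < 0)
  if (length(bad)) {
    stop("BEDPE validation error at line ", idx[bad[1]], " of ", path,
         ": requires 0 <= start < end for both anchors", call. = FALSE)
  }
  counts <- if (length(count_cols)) {
    matrix(vapply(count_cols, function(j) num(j, paste0("count column ", j)),
                  numeric(length(idx))), ncol = length(count_cols))
  } else matrix(numeric(0), nrow = length(idx), ncol = 0)

  intra <- c1 == c2
  if (any(!intra)) {
    message(sum(!intra), " inter-chromosomal BEDPE row(s) skipped")
  }
  c1 <- c1[intra]; s1 <- s1[intra]; e1 <- e1[intra]
  s2 <- s2[intra]; e2 <- e2[intra]
  counts <- counts[intra, , drop = FALSE]
  # normalise anchor order
  swap <- s2 < s1
  tmpS <- s1[swap]; tmpE <- e1[swap]
  s1[swap] <- s2[swap]; e1[swap] <- e2[swap]
  s2[swap] <- tmpS; e2[swap] <- tmpE
  new("LoopSet",
      anchor1 = GRanges(c1, IRanges(s1 + 1, e1)),
      anchor2 = GRanges(c1, IRanges(s2 + 1, e2)),
      counts = counts)
}

#' Filter loops by replicate presence, size and mean count
#'
#' Keeps loops that are (when required) present with a positive count in
#' every replicate count column, span strictly more than `min_size` bp from
#' the start of the first anchor to the end of the second, and have a mean
#' count of at least `min_mean_count` (inclusive).
#'
#' @param loops a [LoopSet].
#' @param require_both_replicates require count > 0 in every count column.
#' @param min_size minimum loop size in bp (strict).
#' @param min_mean_count minimum mean replicate count (inclusive).
#' @return the filtered [LoopSet].
#' @export
filterLoops <- function(loops, require_both_replicates = TRUE,
                        min_size = 5000, min_mean_count = 2) {
  if (!length(loops)) return(loops)
  keep <- rep(TRUE, length(loops))
  if (require_both_replicates || min_mean_count > 0) {
    assertThat(ncol(loopCounts(loops)) >= 1L,
               "count-based filters require count columns (see readBedpe count_cols)")
  }
  if (require_both_replicates) {
    keep <- keep & apply(loopCounts(loops) > 0, 1, all)
  }
  keep <- keep & loopSizes(loops) > min_size
  if (ncol(loopCounts(loops))) {
    keep <- keep & rowMeans(loopCounts(loops)) >= min_mean_count
  }
  new("LoopSet", anchor1 = loops@anchor1[keep], anchor2 = loops@anchor2[keep],
      counts = loopCounts(loops)[keep, , drop = FALSE])
}

#' Peak-anchored loop statistics per probability group
#'
#' A loop is assigned to a probability group when at least one of its anchors
#' overlaps (>= 1 bp) a peak of that group; a loop whose two anchors hit
#' peaks of two different groups counts in both. Per group the function
#' reports the number of loops, loops per peak, the percentage of the
#' group's peaks involved in at least one loop, and the per-loop strength
#' (mean of the replicate counts) and size (with log10).
#'
#' @param loops a (filtered) [LoopSet].
#' @param peaks_by_group named list of disjoint `GRanges`, one per group.
#' @return list with `summary` (`data.frame`) and `per_group` (per-group
#'   strength/size vectors).
#' @export
peakAnchoredStats <- function(loops, peaks_by_group) {
  assertThat(is.list(peaks_by_group) && length(peaks_by_group) >= 1L,
             "need at least one peak group")
  a1 <- anchors(loops, 1L)
  a2 <- anchors(loops, 2L)
  strength <- if (ncol(loopCounts(loops))) rowMeans(loopCounts(loops))
              else rep(NA_real_, length(loops))
  sizes <- loopSizes(loops)
  perGroup <- list()
  rows <- lapply(names(peaks_by_group), function(g) {
    pk <- peaks_by_group[[g]]
    nPeaks <- length(pk)
    inGroup <- if (nPeaks) {
      overlapsAny(a1, pk, ignore.strand = TRUE) |
        overlapsAny(a2, pk, ignore.strand = TRUE)
    } else rep(FALSE, length(loops))
    nLoops <- sum(inGroup)
    anchorsOfGroup <- c(granges(a1[inGroup]), granges(a2[inGroup]))
    peaksInLoops <- if (nPeaks) sum(overlapsAny(pk, anchorsOfGroup,
                                                ignore.strand = TRUE)) else 0L
    perGroup[[g]] <<- list(strength = strength[inGroup],
                           size = sizes[inGroup],
                           log10_size = log10(sizes[inGroup]))
    data.frame(group = g, n_loops = nLoops, n_peaks = nPeaks,
               loops_per_peak = if (nPeaks) nLoops / nPeaks else 0,
               percent_peaks_in_loops = if (nPeaks) 100 * peaksInLoops / nPeaks
                                        else 0,
               mean_strength = if (nLoops) mean(strength[inGroup]) else NA_real_,
               mean_log10_size = if (nLoops) mean(log10(sizes[inGroup]))
                                 else NA_real_)
  })
  list(summary = do.call(rbind, rows), per_group = perGroup)
}
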