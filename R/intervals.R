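# Interval and fragment I/O plus the interval algebra used throughout.
# Coordinates are BED (0-based half-open) on disk and GRanges (1-based closed)
# in memory; conversion happens only at the file boundary.

# Parse a BED-like file to a data.table of (chrom, start0, end), skipping
# comment/track/browser lines, with line-numbered errors.
.readBedTable <- function(path, what = "BED") {
  assertThat(length(path) == 1L && file.exists(path),
             paste0(what, " file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (!length(idx)) {
    return(data.table::data.table(chrom = character(0), start0 = numeric(0),
                                  end = numeric(0)))
  }
  fields <- strsplit(lines[idx], "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    bad <- idx[which(nf < 3L)[1]]
    stop(what, " parse error at line ", bad, " of ", path,
         ": fewer than 3 columns", call. = FALSE)
  }
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3L)))
  bad <- which(!is.finite(start0) | !is.finite(end) |
               start0 != floor(start0) | end != floor(end))
  if (length(bad)) {
    stop(what, " parse error at line ", idx[bad[1]], " of ", path,
         ": coordinates do not parse as integers", call. = FALSE)
  }
  bad <- which(start0 < 0 | start0 >= end)
  if (length(bad)) {
    stop(what, " validation error at line ", idx[bad[1]], " of ", path,
         ": requires 0 <= start < end", call. = FALSE)
  }
  data.table::data.table(chrom = chrom, start0 = start0, end = end)
}

# Build a GRanges from parsed BED records, binding and checking a genome
# when given, else using lexicographic chromosome order.
.bedToGRanges <- function(tab, genome = NULL, path = "input") {
  if (is.null(genome)) {
    gr <- GRanges(tab$chrom, IRanges(tab$start0 + 1, tab$end))
    seqlevels(gr) <- sort(seqlevels(gr))
    return(gr)
  }
  unknown <- setdiff(unique(tab$chrom), seqlevels(genome))
  assertThat(length(unknown) == 0,
             paste0(path, ": chromosome(s) not in genome: ",
                    paste(head(unknown, 3), collapse = ", ")))
  lens <- seqlengths(genome)[tab$chrom]
  bad <- which(tab$end > lens)
  assertThat(length(bad) == 0,
             paste0(path, ": interval end exceeds chromosome length (record ",
                    if (length(bad)) bad[1] else "", ")"))
  GRanges(tab$chrom, IRanges(tab$start0 + 1, tab$end), seqinfo = genome)
}

#' Read genomic intervals from a BED file
#'
#' Reads the first three columns of a BED file into a sorted `GRanges`.
#' Extra columns are ignored; lines starting with `#`, `track` or `browser`
#' are skipped. Malformed coordinates raise an error naming the line.
#'
#' @param path path to a BED3+ file (0-based half-open coordinates).
#' @param genome optional `Seqinfo` (see [readGenome()]); when supplied,
#'   chromosome names and bounds are validated and its ordering is used.
#' @return sorted `GRanges`.
#' @export
readIntervals <- function(path, genome = NULL) {
  tab <- .readBedTable(path, "BED")
  sort(.bedToGRanges(tab, genome, path))
}

#' Read a fragment file into a FragmentSet
#'
#' Reads a BED3 file of deduplicated fragment intervals. Fragments are a
#' multiset: duplicate identical records are retained and each counts toward
#' the depth.
#'
#' @inheritParams readIntervals
#' @param target target label for the sample.
#' @param replicateId replicate identifier.
#' @return a [FragmentSet]; `depth()` equals the number of records.
#' @export
readFragments <- function(path, target = "sample", replicateId = basename(path),
                          genome = NULL) {
  tab <- .readBedTable(path, "fragment BED")
  FragmentSet(.bedToGRanges(tab, genome, path), target = target,
              replicateId = replicateId)
}

#' Construct a FragmentSet from a GRanges
#'
#' @param fragments `GRanges` of fragment intervals (strand is ignored).
#' @param target character(1) target label.
#' @param replicateId character(1) replicate identifier.
#' @return a [FragmentSet].
#' @export
FragmentSet <- function(fragments, target = "sample", replicateId = "rep1") {
  strand(fragments) <- "*"
  new("FragmentSet", fragments = fragments, target = as.character(target),
      replicateId = as.character(replicateId))
}

#' Write intervals or scored peaks to disk
#'
#' Plain `GRanges` are written as BED3. A [ScoredPeakSet] is written in
#' narrowPeak-style 10-column format: chrom, start, end, name, score
#' (`int(min(1000, 10 * -log10 q))`), strand `"."`, signal (max window fold
#' enrichment), `-log10 p`, `-log10 q`, summit offset from the peak start.
#'
#' @param x a `GRanges` or `ScoredPeakSet`.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeIntervals <- function(x, path) {
  if (is(x, "ScoredPeakSet")) {
    gr <- peakRanges(x)
    m <- mcols(gr)
    neglog <- function(v) ifelse(v <= 0, 320, -log10(v)) # guard underflow
    tab <- data.frame(chrom = as.character(seqnames(gr)),
                      start = start(gr) - 1L, end = end(gr),
                      name = if (length(gr)) paste0("peak_", seq_along(gr)) else character(0),
                      score = as.integer(pmin(1000, round(10 * neglog(m$qValue)))),
                      strand = rep(".", length(gr)),
                      signal = round(m$signal, 5),
                      pLog = round(neglog(m$pValue), 5),
                      qLog = round(neglog(m$qValue), 5),
                      summit = m$summit - start(gr))
  } else {
    assertThat(is(x, "GRanges"), "writeIntervals() expects a GRanges or ScoredPeakSet")
    tab <- data.frame(chrom = as.character(seqnames(x)),
                      start = start(x) - 1L, end = end(x))
  }
  ok <- tryCatch({
    data.table::fwrite(tab, path, sep = "\t", col.names = FALSE, quote = FALSE,
                       scipen = 50)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("failed to write ", path, ": ", conditionMessage(ok),
                        call. = FALSE)
  invisible(path)
}

#' Merge overlapping or nearby intervals
#'
#' Collapses intervals that overlap or lie within `gap` bases of each other
#' into maximal disjoint regions. With `gap = 0`, book-ended intervals
#' (one ending exactly where the next starts) are merged, matching the
#' behaviour of standard genome-arithmetic merging.
#'
#' @param x `GRanges`.
#' @param gap non-negative integer: maximum separation (bp) still merged.
#' @return sorted, disjoint `GRanges`.
#' @export
mergeIntervals <- function(x, gap = 0L) {
  assertThat(length(gap) == 1L && is.finite(gap) && gap >= 0,
             "gap must be a single non-negative integer")
  reduce(sort(x), min.gapwidth = as.integer(gap) + 1L, ignore.strand = TRUE)
}

#' Count query intervals overlapping a subject set
#'
#' An interval of `a` counts once if it shares at least one base with any
#' interval of `b` (half-open BED semantics on disk; equivalently >= 1
#' overlapping position in memory).
#'
#' @param a,b `GRanges`.
#' @return list with `count` (number of `a` intervals hitting `b`) and
#'   `hits` (logical vector over `a`).
#' @export
intersectCount <- function(a, b) {
  hits <- overlapsAny(a, b, ignore.strand = TRUE)
  list(count = sum(hits), hits = hits)
}

#' Remove fragments overlapping suspect (blacklist) regions
#'
#' Drops every fragment sharing at least one base with any suspect interval
#' (whole-read removal, not clipping); the depth is updated accordingly.
#'
#' @param frags a [FragmentSet].
#' @param suspect `GRanges` of suspect-list regions.
#' @return a filtered [FragmentSet].
#' @export
subtractFragments <- function(frags, suspect) {
  keep <- !overlapsAny(fragments(frags), suspect, ignore.strand = TRUE)
  FragmentSet(fragments(frags)[keep], target = target(frags),
              replicateId = replicateId(frags))
}

# For each query interval, the number of sets with >= 1 overlapping interval.
.countOverlappingSets <- function(query, sets) {
  if (!length(sets)) return(integer(length(query)))
  m <- vapply(sets, function(s) overlapsAny(query, s, ignore.strand = TRUE),
              logical(length(query)))
  as.integer(rowSums(matrix(m, nrow = length(query))))
}

#' Segment several interval sets at their union breakpoints
#'
#' Each input set is merged internally, then the union of all sets is cut at
#' every interval boundary so that each resulting segment is fully inside or
#' fully outside every input set. The per-segment membership matrix records
#' which sets cover each segment; reconstructing a set's covered bases from
#' its flagged segments reproduces it exactly.
#'
#' @param sets list of `GRanges`.
#' @param labels character vector of unique labels, one per set.
#' @return an [OverlapMatrix].
#' @export
overlapMatrix <- function(sets, labels = names(sets)) {
  assertThat(is.list(sets) && length(sets) >= 1L, "need at least one interval set")
  if (is.null(labels)) labels <- paste0("set", seq_along(sets))
  assertThat(length(labels) == length(sets), "one label per set required")
  assertThat(!anyDuplicated(labels), "duplicate set labels")
  merged <- lapply(sets, mergeIntervals)
  lvls <- unique(unlist(lapply(merged, seqlevels)))
  merged <- lapply(merged, function(g) { seqlevels(g) <- lvls; g })
  segs <- sort(disjoin(do.call(c, unname(merged)), ignore.strand = TRUE))
  mem <- vapply(merged, function(g) overlapsAny(segs, g, ignore.strand = TRUE),
                logical(length(segs)))
  mem <- matrix(mem, nrow = length(segs), ncol = length(sets),
                dimnames = list(NULL, labels))
  new("OverlapMatrix", segments = segs, membership = mem,
      setLabels = as.character(labels))
}

#' Regions called in at least x of k datasets
#'
#' Extracts the exact segments covered by at least `x` of the input sets and
#' merges neighbouring (book-ended) segments with gap 0, yielding the set of
#' unique regions supported by at least `x` datasets.
#'
#' @param m an [OverlapMatrix] (or a list of `GRanges`, segmented on the fly).
#' @param x integer threshold, `1 <= x <= k`.
#' @return sorted, disjoint `GRanges`.
#' @export
regionsAtLeast <- function(m, x) {
  if (is.list(m)) m <- overlapMatrix(m)
  assertThat(is(m, "OverlapMatrix"), "m must be an OverlapMatrix or list of GRanges")
  k <- length(m@setLabels)
  assertThat(length(x) == 1L && x >= 1L && x <= k,
             paste0("x must be in 1..", k))
  sel <- m@segments[rowSums(m@membership) >= x]
  mergeIntervals(sel, gap = 0L)
}
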