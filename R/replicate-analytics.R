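# Decay curves, concordance, per-peak detection frequency, probability
# groups (including the USR group), the rarity ladder, and FrIP.

#' Decay curve: regions called in at least / exactly x datasets
#'
#' For n peak sets, `at_least[x]` is the number of unique regions covered by
#' at least x sets (segment extraction plus gap-0 merge, see
#' [regionsAtLeast()]); `exactly[x]` is obtained by the count subtraction
#' `at_least[x] - at_least[x + 1]`. Because merging can fuse regions, the
#' subtraction can in principle go negative; such values are clipped to zero
#' with a warning.
#'
#' @param peak_sets list of n `GRanges`.
#' @return `data.frame` with columns `x`, `at_least`, `exactly`.
#' @export
decayCurve <- function(peak_sets) {
  n <- length(peak_sets)
  assertThat(n >= 1L, "need at least one peak set")
  m <- overlapMatrix(peak_sets, paste0("set", seq_len(n)))
  atLeast <- vapply(seq_len(n), function(x) length(regionsAtLeast(m, x)),
                    integer(1))
  exactly <- atLeast - c(atLeast[-1], 0L)
  if (any(exactly < 0L)) {
    warning(sum(exactly < 0L), " exactly-x count(s) were negative after ",
            "merge-induced region fusion and were clipped to 0", call. = FALSE)
    exactly <- pmax(exactly, 0L)
  }
  data.frame(x = seq_len(n), at_least = atLeast, exactly = exactly)
}

#' Concordance across replicates
#'
#' Regions called in every one of the n sets, expressed as a percentage of
#' all unique regions called in at least one set.
#'
#' @param peak_sets list of n >= 2 `GRanges`.
#' @return list with `concordant_regions` (`GRanges`) and `percent_of_total`
#'   (numeric, `NA` when all sets are empty).
#' @export
concordance <- function(peak_sets) {
  assertThat(length(peak_sets) >= 2L, "need at least two peak sets")
  m <- overlapMatrix(peak_sets, paste0("set", seq_along(peak_sets)))
  conc <- regionsAtLeast(m, length(peak_sets))
  total <- length(regionsAtLeast(m, 1L))
  list(concordant_regions = conc,
       percent_of_total = if (total == 0) NA_real_ else 100 * length(conc) / total)
}

#' Per-peak detection frequency across strict replicate calls
#'
#' For each reference peak, the number of replicates whose strict
#' (q < 0.05) peak set overlaps it by at least one base.
#'
#' @param iceberg_peaks `GRanges` of reference peaks.
#' @param strict_replicate_sets list of per-replicate `GRanges`.
#' @return integer vector of counts in `0..n`, parallel to `iceberg_peaks`.
#' @export
detectionFrequency <- function(iceberg_peaks, strict_replicate_sets) {
  .countOverlappingSets(iceberg_peaks, strict_replicate_sets)
}

#' Assign detection-probability groups
#'
#' Peaks never called in any single replicate at strict stringency
#' (count 0) form the USR group ("undetectable in single replicates").
#' Remaining peaks are binned by detection percentage `100 * count / n` into
#' five right-closed 20-point bins; at n = 25 these are the groups
#' 1-5 (<=20%), 6-10 (21-40%), 11-15 (41-60%), 16-20 (61-80%) and
#' 21-25 (81-100%).
#'
#' @param counts integer detection counts in `0..n`.
#' @param n number of replicates.
#' @return factor of group labels, ordered USR, then the five bins.
#' @export
assignProbabilityGroups <- function(counts, n) {
  assertThat(n >= 1L, "n must be >= 1")
  assertThat(all(counts >= 0L), "counts must be non-negative")
  if (any(counts > n)) stop("detection count exceeds n", call. = FALSE)
  binHi <- function(b) floor(n * b / 5)            # largest count in bin b
  binLo <- function(b) binHi(b - 1) + 1L           # smallest count in bin b
  labels <- vapply(1:5, function(b) {
    pct <- if (b == 1L) "<=20%" else sprintf("%d-%d%%", 20L * (b - 1L) + 1L, 20L * b)
    sprintf("%d-%d (%s)", binLo(b), binHi(b), pct)
  }, character(1))
  bin <- ceiling(5 * counts / n)                   # right-closed percentage bins
  grp <- ifelse(counts == 0L, "USR", labels[pmax(bin, 1L)])
  factor(grp, levels = c("USR", labels))
}

#' Rarity ladder: progressively relaxed undetectability tiers
#'
#' Starting from reference peaks never called in a single replicate at
#' strict stringency (q < 0.05, the USR tier), the ladder keeps peaks that
#' remain undetectable at p < 0.001, then those called fewer than 5 times at
#' the loosest stringency (p < 0.01), and finally those called in exactly
#' one replicate at p < 0.01 - the rarest binding events. Tiers are nested
#' by construction.
#'
#' @param iceberg_peaks reference `GRanges`.
#' @param strict_sets per-replicate `GRanges` at q < 0.05.
#' @param p001_sets per-replicate `GRanges` at p < 0.001.
#' @param p01_sets per-replicate `GRanges` at p < 0.01.
#' @return list with `tiers` (`data.frame` of tier, description, count) and
#'   `peaks` (list of the four nested `GRanges`).
#' @export
rarityLadder <- function(iceberg_peaks, strict_sets, p001_sets, p01_sets) {
  q05 <- detectionFrequency(iceberg_peaks, strict_sets)
  p001 <- detectionFrequency(iceberg_peaks, p001_sets)
  p01 <- detectionFrequency(iceberg_peaks, p01_sets)
  t1 <- q05 == 0L
  t2 <- t1 & p001 == 0L
  t3 <- t2 & p01 < 5L
  t4 <- t3 & p01 == 1L
  list(
    tiers = data.frame(
      tier = 1:4,
      description = c("USR (q < 0.05 count 0)",
                      "undetectable at p < 0.001",
                      "called < 5 times at p < 0.01",
                      "called exactly once at p < 0.01"),
      count = c(sum(t1), sum(t2), sum(t3), sum(t4))),
    peaks = list(usr_q05 = iceberg_peaks[t1],
                 undetectable_p001 = iceberg_peaks[t2],
                 lt5_at_p01 = iceberg_peaks[t3],
                 exactly1_at_p01 = iceberg_peaks[t4]))
}

#' Fraction of fragments in peaks (FrIP / I-FrIP)
#'
#' Fraction of a sample's fragments overlapping (>= 1 bp) any peak of the
#' reference set. Computed against an aggregated reference peak set this is
#' the I-FrIP, a depth-robust measure of replicate efficiency.
#'
#' @param frags a [FragmentSet] with positive depth.
#' @param peaks `GRanges` of reference peaks.
#' @return numeric in `[0, 1]`.
#' @export
frip <- function(frags, peaks) {
  assertThat(depth(frags) > 0, "fragment set has zero depth")
  if (!length(peaks)) return(0)
  mean(overlapsAny(fragments(frags), peaks, ignore.strand = TRUE))
}
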