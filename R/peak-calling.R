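# Poisson local-background peak caller. Sliding windows are scored against
# the maximum of a genome-wide and several local background rates estimated
# from the control (IgG) track, scaled to the treatment depth.

#' Peak-calling parameters
#'
#' Assembles and validates the tuning parameters of [callPeaks()].
#'
#' Windows of `window` bp advance by `step` bp; a fragment is counted in every
#' window it overlaps by at least one base. The background rate of a window is
#' the maximum of the genome-wide rate and the rates estimated from the
#' control in windows of each `local_scales` size centred on it ("local
#' lambda"), all scaled to the treatment depth, with `pseudocount` added to
#' control counts so empty control windows never produce a zero rate.
#' Significant windows are merged when closer than `merge_gap` bp and merged
#' peaks shorter than `min_length` bp are dropped.
#'
#' @param window window width in bp.
#' @param step window stride in bp (`window >= step > 0`).
#' @param local_scales local background window sizes in bp (each `>= window`).
#' @param merge_gap maximum gap between significant windows merged into one peak.
#' @param min_length minimum peak length in bp.
#' @param pseudocount added to control window counts before rate scaling.
#' @param threshold_mode `"q"` (Benjamini-Hochberg FDR) or `"p"` (raw Poisson
#'   p-value).
#' @param threshold significance cutoff; defaults to 0.05 in q mode and 0.01
#'   in p mode.
#' @return a named list of validated parameters.
#' @examples
#' peakCallParams()
#' peakCallParams(threshold_mode = "p", threshold = 1e-3)
#' @export
peakCallParams <- function(window = 50L, step = 25L,
                           local_scales = c(1000L, 10000L),
                           merge_gap = 100L, min_length = 50L,
                           pseudocount = 0.5,
                           threshold_mode = c("q", "p"), threshold = NULL) {
  threshold_mode <- match.arg(threshold_mode)
  if (is.null(threshold)) threshold <- if (threshold_mode == "q") 0.05 else 0.01
  assertThat(step > 0 && window >= step, "requires window >= step > 0")
  assertThat(threshold > 0 && threshold < 1, "threshold must be in (0, 1)")
  assertThat(all(local_scales >= window), "local_scales must each be >= window")
  assertThat(merge_gap >= 0 && min_length >= 0 && pseudocount >= 0,
             "merge_gap, min_length and pseudocount must be non-negative")
  list(window = as.integer(window), step = as.integer(step),
       local_scales = as.integer(local_scales),
       merge_gap = as.integer(merge_gap), min_length = as.integer(min_length),
       pseudocount = pseudocount, threshold_mode = threshold_mode,
       threshold = threshold)
}

#' Benjamini-Hochberg q-values
#'
#' Standard step-up false-discovery-rate adjustment with monotonicity
#' enforcement; the input order is preserved in the output.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return numeric vector of q-values, parallel to `p`.
#' @examples
#' benjaminiHochberg(c(0.01, 0.04))
#' @export
benjaminiHochberg <- function(p) {
  assertThat(is.numeric(p), "p must be numeric")
  if (!length(p)) return(numeric(0))
  assertThat(all(is.finite(p)) && all(p > 0) && all(p <= 1),
             "p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

# Sliding windows across all chromosomes of a genome.
.genomeWindows <- function(genome, window, step) {
  lens <- seqlengths(genome)
  assertThat(length(lens) > 0 && all(!is.na(lens)),
             "genome must define at least one chromosome with a length")
  chroms <- GRanges(names(lens), IRanges(1L, unname(lens)), seqinfo = genome)
  unlist(GenomicRanges::slidingWindows(chroms, width = window, step = step))
}

#' Call peaks with a Poisson local-background model
#'
#' Scores sliding windows by their treatment fragment-overlap counts against
#' a Poisson background whose rate is the maximum of the genome-wide rate and
#' local rates estimated from the control at the window scale and at each
#' `local_scales` size, scaled to the treatment depth (see
#' [peakCallParams()]). The window-scale control term suppresses point
#' artifacts present in both treatment and control, which the larger local
#' scales would dilute. Window p-values are the
#' Poisson survival probability `P(X >= count)`; q-values are
#' Benjamini-Hochberg across all tested windows. Significant windows are
#' merged within `merge_gap` and short peaks dropped. The summit is the
#' midpoint of the highest-count window in the peak.
#'
#' Rates estimated in a window of size s are rescaled by the effective-length
#' ratio `(window + L) / (s + L)`, where L is the mean fragment length, so
#' that overlap-based counts at every scale estimate the same per-window
#' expectation. Without a control (`control = NULL`), background rates are
#' estimated from the treatment itself.
#'
#' @param treatment a [FragmentSet].
#' @param control a [FragmentSet] (IgG) or `NULL` for a treatment-derived
#'   background.
#' @param genome a `Seqinfo` with chromosome lengths.
#' @param params parameters from [peakCallParams()].
#' @return a [ScoredPeakSet].
#' @export
callPeaks <- function(treatment, control = NULL, genome,
                      params = peakCallParams()) {
  win <- scoreWindows(treatment, control, genome, params)
  pval <- mcols(win)$pValue
  qval <- mcols(win)$qValue
  tCount <- mcols(win)$count
  fold <- mcols(win)$fold

  sig <- if (params$threshold_mode == "q") qval < params$threshold
         else pval < params$threshold
  sigWin <- granges(win[sig])
  peaks <- reduce(sigWin, min.gapwidth = params$merge_gap + 1L)
  peaks <- peaks[width(peaks) >= params$min_length]

  if (length(peaks)) {
    hit <- findOverlaps(sigWin, peaks)
    dt <- data.table::data.table(peak = subjectHits(hit),
                                 p = pval[sig][queryHits(hit)],
                                 q = qval[sig][queryHits(hit)],
                                 cnt = tCount[sig][queryHits(hit)],
                                 fold = fold[sig][queryHits(hit)],
                                 mid = ((start(sigWin) + end(sigWin)) %/% 2L)[queryHits(hit)])
    agg <- dt[, list(pValue = min(p), qValue = min(q), signal = max(fold),
                     summit = mid[which.max(cnt)]), by = "peak"]
    agg <- agg[order(agg$peak), ]
    mcols(peaks) <- DataFrame(pValue = agg$pValue, qValue = agg$qValue,
                              signal = agg$signal,
                              summit = pmin(pmax(agg$summit, start(peaks)),
                                            end(peaks)))
  } else {
    mcols(peaks) <- DataFrame(pValue = numeric(0), qValue = numeric(0),
                              signal = numeric(0), summit = integer(0))
  }
  new("ScoredPeakSet", peaks = peaks, params = params,
      treatmentDepth = depth(treatment),
      controlDepth = if (is.null(control)) 0 else depth(control))
}

#' Score sliding windows against the Poisson local background
#'
#' The window-level engine behind [callPeaks()]: computes per-window
#' treatment fragment counts, the local background rate, the Poisson
#' survival p-value and the Benjamini-Hochberg q-value across all tested
#' windows, without any merging or thresholding.
#'
#' @inheritParams callPeaks
#' @return `GRanges` of windows with metadata columns `count`, `lambda`,
#'   `fold`, `pValue`, `qValue`.
#' @export
scoreWindows <- function(treatment, control = NULL, genome,
                         params = peakCallParams()) {
  assertThat(is(treatment, "FragmentSet") && depth(treatment) > 0,
             "treatment must be a non-empty FragmentSet")
  if (!is.null(control)) {
    assertThat(is(control, "FragmentSet"), "control must be a FragmentSet or NULL")
    if (depth(control) == 0) {
      stop("control has zero depth; pass control = NULL to use the uniform ",
           "treatment-derived background (pseudo-control mode)", call. = FALSE)
    }
  }
  win <- .genomeWindows(genome, params$window, params$step)
  tFrags <- fragments(treatment)
  bgFrags <- if (is.null(control)) tFrags else fragments(control)
  tDepth <- depth(treatment)
  bgDepth <- length(bgFrags)
  ratio <- tDepth / bgDepth
  fragLen <- mean(width(bgFrags))
  genomeLen <- sum(as.numeric(seqlengths(genome)))
  w <- params$window

  tCount <- countOverlaps(win, tFrags)
  lambda <- rep(bgDepth * ratio * (w + fragLen) / genomeLen, length(win))
  # With a control, include the window scale itself: point artifacts shared
  # with the control would be diluted at the larger local scales. Without a
  # control the background is the treatment, so small scales would estimate
  # the signal as its own background; only the largest scale is used then.
  scales <- if (is.null(control)) max(params$local_scales)
            else unique(c(w, params$local_scales))
  for (s in scales) {
    scaleWin <- suppressWarnings(trim(resize(win, width = s, fix = "center")))
    cnt <- countOverlaps(scaleWin, bgFrags)
    lambda <- pmax(lambda, (cnt + params$pseudocount) * ratio *
                             (w + fragLen) / (s + fragLen))
  }
  pval <- ppois(tCount - 1, lambda, lower.tail = FALSE)
  pval <- pmax(pval, 1e-320) # survival underflows to 0 at extreme enrichment
  mcols(win) <- DataFrame(count = tCount, lambda = lambda,
                          fold = tCount / lambda, pValue = pval,
                          qValue = benjaminiHochberg(pval))
  win
}

#' Filter called peaks at a stricter significance threshold
#'
#' Retains peaks whose p-value (or q-value) is below `cutoff`. Peaks are not
#' re-merged: one call is made at the loosest needed stringency and
#' thresholded downward, so sets at nested thresholds are nested by
#' construction.
#'
#' @param result a [ScoredPeakSet].
#' @param mode `"q"` or `"p"`.
#' @param cutoff significance cutoff in (0, 1].
#' @return a filtered [ScoredPeakSet].
#' @export
thresholdPeaks <- function(result, mode = c("q", "p"), cutoff) {
  mode <- match.arg(mode)
  assertThat(is(result, "ScoredPeakSet"), "result must be a ScoredPeakSet")
  assertThat(length(cutoff) == 1L && cutoff > 0 && cutoff <= 1,
             "cutoff must be in (0, 1]")
  vals <- if (mode == "q") mcols(result@peaks)$qValue else mcols(result@peaks)$pValue
  keep <- if (cutoff == 1) rep(TRUE, length(vals)) else vals < cutoff
  params <- result@params
  params$threshold_mode <- mode
  params$threshold <- cutoff
  new("ScoredPeakSet", peaks = result@peaks[keep], params = params,
      treatmentDepth = result@treatmentDepth, controlDepth = result@controlDepth)
}
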