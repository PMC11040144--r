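#' Fragment depth of a sample
#'
#' Number of fragments in a [FragmentSet] (its sequencing depth after
#' filtering and deduplication).
#'
#' @param x a `FragmentSet`.
#' @return integer(1).
#' @export
setGeneric("depth", function(x) standardGeneric("depth"))

#' @describeIn depth fragment count of the set.
#' @export
setMethod("depth", "FragmentSet", function(x) length(x@fragments))

#' Extract fragment intervals
#'
#' @param x a `FragmentSet`.
#' @return the underlying `GRanges`.
#' @export
setGeneric("fragments", function(x) standardGeneric("fragments"))

#' @describeIn fragments the fragment `GRanges`.
#' @export
setMethod("fragments", "FragmentSet", function(x) x@fragments)

#' Target label of a sample
#' @param x a `FragmentSet`.
#' @return character(1).
#' @export
setGeneric("target", function(x) standardGeneric("target"))

#' @describeIn target target label.
#' @export
setMethod("target", "FragmentSet", function(x) x@target)

#' Replicate identifier of a sample
#' @param x a `FragmentSet`.
#' @return character(1).
#' @export
setGeneric("replicateId", function(x) standardGeneric("replicateId"))

#' @describeIn replicateId replicate identifier.
#' @export
setMethod("replicateId", "FragmentSet", function(x) x@replicateId)

#' Extract peak intervals
#'
#' Scored peak ranges of a [ScoredPeakSet] or final peaks of an
#' [IcebergResult], as a `GRanges`.
#'
#' @param x a `ScoredPeakSet` or `IcebergResult`.
#' @return `GRanges` (with score metadata columns for `ScoredPeakSet`).
#' @export
setGeneric("peakRanges", function(x) standardGeneric("peakRanges"))

#' @describeIn peakRanges scored peak ranges.
#' @export
setMethod("peakRanges", "ScoredPeakSet", function(x) x@peaks)

#' @describeIn peakRanges final aggregated peaks.
#' @export
setMethod("peakRanges", "IcebergResult", function(x) x@peaks)

#' @export
setMethod("length", "FragmentSet", function(x) length(x@fragments))

#' @export
setMethod("length", "ScoredPeakSet", function(x) length(x@peaks))

#' @export
setMethod("length", "IcebergResult", function(x) length(x@peaks))

#' Segments of an overlap matrix
#' @param x an `OverlapMatrix`.
#' @return disjoint, sorted `GRanges`.
#' @export
setGeneric("segments", function(x) standardGeneric("segments"))

#' @describeIn segments the disjoint segmentation.
#' @export
setMethod("segments", "OverlapMatrix", function(x) x@segments)

#' Membership flags of an overlap matrix
#' @param x an `OverlapMatrix`.
#' @return logical matrix (segments x input sets).
#' @export
setGeneric("membership", function(x) standardGeneric("membership"))

#' @describeIn membership the per-segment membership matrix.
#' @export
setMethod("membership", "OverlapMatrix", function(x) x@membership)

#' Per-peak provenance of an ICEBERG run
#' @param x an `IcebergResult`.
#' @return `DataFrame` with columns `nAggregates` and `nSupport`.
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @describeIn provenance provenance table aligned with [peakRanges()].
#' @export
setMethod("provenance", "IcebergResult", function(x) x@provenance)

#' Per-aggregate peak calls of an ICEBERG run
#' @param x an `IcebergResult`.
#' @return list of [ScoredPeakSet], one per aggregate.
#' @export
setGeneric("aggregatePeakSets", function(x) standardGeneric("aggregatePeakSets"))

#' @describeIn aggregatePeakSets aggregate calls.
#' @export
setMethod("aggregatePeakSets", "IcebergResult", function(x) x@aggregatePeaks)

#' Relaxed per-replicate peak calls of an ICEBERG run
#'
#' The individual-replicate calls made at the support stringency (p < 0.01
#' by default). Stricter per-replicate tiers (q < 0.05, p < 0.001) are
#' obtained from these with [thresholdPeaks()].
#'
#' @param x an `IcebergResult`.
#' @return list of [ScoredPeakSet], one per replicate.
#' @export
setGeneric("supportPeakSets", function(x) standardGeneric("supportPeakSets"))

#' @describeIn supportPeakSets relaxed per-replicate calls.
#' @export
setMethod("supportPeakSets", "IcebergResult", function(x) x@supportPeaks)

#' Model coefficients in ascending degree
#' @param object a `PolynomialModel`.
#' @param ... ignored.
#' @return numeric vector, intercept first.
#' @export
setMethod("coef", "PolynomialModel", function(object, ...) object@coefficients)

#' Loop anchors
#' @param x a `LoopSet`.
#' @param which `1` or `2`: first (upstream) or second anchor.
#' @return `GRanges` of anchors.
#' @export
setGeneric("anchors", function(x, which = 1L) standardGeneric("anchors"))

#' @describeIn anchors anchors of the loops.
#' @export
setMethod("anchors", "LoopSet", function(x, which = 1L) {
  if (which == 1L) x@anchor1 else x@anchor2
})

#' Loop counts
#' @param x a `LoopSet`.
#' @return numeric matrix of per-replicate loop counts.
#' @export
setGeneric("loopCounts", function(x) standardGeneric("loopCounts"))

#' @describeIn loopCounts per-replicate count matrix.
#' @export
setMethod("loopCounts", "LoopSet", function(x) x@counts)

#' @export
setMethod("length", "LoopSet", function(x) length(x@anchor1))

#' Loop sizes
#'
#' Linear genomic distance spanned by each loop: from the start of the first
#' anchor to the end of the second anchor.
#'
#' @param x a `LoopSet`.
#' @return integer vector of sizes in bp.
#' @export
setGeneric("loopSizes", function(x) standardGeneric("loopSizes"))

#' @describeIn loopSizes sizes in bp.
#' @export
setMethod("loopSizes", "LoopSet", function(x) {
  if (!length(x)) return(integer(0))
  end(x@anchor2) - start(x@anchor1) + 1L
})

setMethod("show", "FragmentSet", function(object) {
  cat("FragmentSet:", object@target, "/", object@replicateId,
      "-", length(object), "fragments on",
      length(seqlevelsInUse(object@fragments)), "sequence(s)\n")
})

setMethod("show", "ScoredPeakSet", function(object) {
  cat("ScoredPeakSet:", length(object), "peaks",
      sprintf("(mode %s < %g; treatment %d / control %d fragments)\n",
              object@params$threshold_mode, object@params$threshold,
              as.integer(object@treatmentDepth), as.integer(object@controlDepth)))
})

setMethod("show", "OverlapMatrix", function(object) {
  cat("OverlapMatrix:", length(object@segments), "segments over",
      length(object@setLabels), "sets:",
      paste(object@setLabels, collapse = ", "), "\n")
})

setMethod("show", "PolynomialModel", function(object) {
  terms <- sprintf("%+.6gx^%d", object@coefficients, seq_along(object@coefficients) - 1L)
  cat("PolynomialModel (order ", object@order, "): y = ",
      paste(terms, collapse = " "), "\n  R^2 = ",
      format(object@rSquared, digits = 6), ", fit domain [",
      object@fitDomain[1], ", ", object@fitDomain[2], "]\n", sep = "")
})

setMethod("show", "IcebergResult", function(object) {
  cat("IcebergResult:", length(object), "final peaks from",
      length(object@aggregatePeaks), "aggregates and",
      length(object@supportPeaks), "replicates",
      sprintf("(seed %d)\n", object@seed))
})

setMethod("show", "LoopSet", function(object) {
  cat("LoopSet:", length(object), "intra-chromosomal loops,",
      ncol(object@counts), "count column(s)\n")
})
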