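#' @importClassesFrom GenomicRanges GRanges
#' @importFrom GenomicRanges GRanges granges seqnames countOverlaps findOverlaps
#'   reduce disjoin coverage resize start end width strand strand<-
#' @importFrom IRanges IRanges overlapsAny subsetByOverlaps slice ranges trim
#' @importFrom GenomeInfoDb Seqinfo seqlengths seqlevels "seqlevels<-" seqinfo keepSeqlevels
#'   seqlevelsInUse
#' @importFrom S4Vectors DataFrame mcols mcols<- queryHits subjectHits Rle runValue
#' @importFrom BiocGenerics unlist
NULL

#' FragmentSet: a replicate's deduplicated sequenced fragments
#'
#' Holds the aligned, deduplicated fragment intervals of one sample (one
#' replicate of a target, or an IgG control) as a [GenomicRanges::GRanges],
#' together with the target label and replicate identifier. Fragments are a
#' multiset: identical intervals are retained, mirroring duplicate-keeping at
#' the peak-calling stage after upstream deduplication.
#'
#' @slot fragments `GRanges` of strandless fragment intervals.
#' @slot target character(1) target label (e.g. `"H3K4me3"`).
#' @slot replicateId character(1) replicate identifier.
#' @export
setClass("FragmentSet",
  representation(fragments = "GRanges", target = "character",
                 replicateId = "character"),
  validity = function(object) {
    if (length(object@target) != 1L) return("target must be a single string")
    if (length(object@replicateId) != 1L) return("replicateId must be a single string")
    TRUE
  })

#' ScoredPeakSet: called enrichment regions with significance scores
#'
#' Result of [callPeaks()]: disjoint, sorted peak intervals with per-peak
#' Poisson p-value, Benjamini-Hochberg q-value, summit position and maximum
#' window fold-enrichment, plus the calling parameters and library depths.
#'
#' @slot peaks `GRanges` with metadata columns `pValue`, `qValue`, `signal`,
#'   `summit` (1-based genomic position of the summit).
#' @slot params list of peak-calling parameters (see [peakCallParams()]).
#' @slot treatmentDepth,controlDepth numeric(1) fragment counts of the
#'   treatment and control libraries used for the call.
#' @export
setClass("ScoredPeakSet",
  representation(peaks = "GRanges", params = "list",
                 treatmentDepth = "numeric", controlDepth = "numeric"),
  validity = function(object) {
    need <- c("pValue", "qValue", "signal", "summit")
    if (!all(need %in% names(mcols(object@peaks))))
      return(paste("peaks must carry metadata columns:", paste(need, collapse = ", ")))
    p <- mcols(object@peaks)$pValue
    q <- mcols(object@peaks)$qValue
    if (length(p) && (any(p <= 0) || any(p > 1))) return("pValue outside (0, 1]")
    if (length(q) && any(q < p - 1e-12)) return("qValue below pValue")
    s <- mcols(object@peaks)$summit
    if (length(s) && (any(s < start(object@peaks)) || any(s > end(object@peaks))))
      return("summit outside its peak")
    TRUE
  })

#' OverlapMatrix: union-breakpoint segmentation of several interval sets
#'
#' Segments the union of k interval sets at every breakpoint so that each
#' disjoint segment is either fully covered or fully uncovered by each input
#' set, with a per-segment logical membership matrix. The analogue of a
#' multi-set intersection matrix; the substrate for "called in at least x
#' datasets" region extraction ([regionsAtLeast()]) and decay curves.
#'
#' @slot segments disjoint, sorted `GRanges`; every base covered by >= 1 input
#'   set lies in exactly one segment.
#' @slot membership logical matrix, one row per segment, one column per input
#'   set; `TRUE` iff the set covers the whole segment.
#' @slot setLabels character vector of k unique input labels.
#' @export
setClass("OverlapMatrix",
  representation(segments = "GRanges", membership = "matrix",
                 setLabels = "character"),
  validity = function(object) {
    if (nrow(object@membership) != length(object@segments))
      return("membership rows must match number of segments")
    if (ncol(object@membership) != length(object@setLabels))
      return("membership columns must match number of labels")
    if (anyDuplicated(object@setLabels)) return("set labels must be unique")
    if (!is.logical(object@membership)) return("membership must be logical")
    TRUE
  })

#' PolynomialModel: a least-squares polynomial saturation model
#'
#' A polynomial y(x) = c0 + c1 x + ... + ck x^k fitted to a peak-discovery
#' build curve (or supplied directly from published coefficients), with its
#' goodness of fit and the x-range it was fitted on.
#'
#' @slot coefficients numeric vector of length order + 1, ascending degree
#'   (intercept first).
#' @slot order integer(1) polynomial degree.
#' @slot rSquared numeric(1) coefficient of determination (NA when the model
#'   was supplied rather than fitted).
#' @slot fitDomain numeric(2) range of x used in the fit.
#' @export
setClass("PolynomialModel",
  representation(coefficients = "numeric", order = "integer",
                 rSquared = "numeric", fitDomain = "numeric"),
  validity = function(object) {
    if (length(object@coefficients) != object@order + 1L)
      return("coefficients must have length order + 1")
    if (object@order < 0L) return("order must be >= 0")
    TRUE
  })

#' IcebergResult: the final aggregated peak set with provenance
#'
#' Output of [runIceberg()]. Carries the final peak intervals, per-peak
#' provenance (how many aggregates called each peak and how many individual
#' replicates support it at relaxed stringency), the per-aggregate scored peak
#' sets, the per-replicate relaxed support sets, the resolved configuration
#' and the seed, so a run is fully reconstructible.
#'
#' @slot peaks final `GRanges` (sorted, disjoint).
#' @slot provenance `DataFrame` aligned with `peaks`: columns `nAggregates`,
#'   `nSupport`.
#' @slot aggregatePeaks list of k [ScoredPeakSet] (aggregate calls).
#' @slot supportPeaks list of n [ScoredPeakSet]: relaxed per-replicate calls,
#'   from which stricter per-replicate tiers can be derived with
#'   [thresholdPeaks()].
#' @slot config resolved configuration list (see [icebergConfig()]).
#' @slot seed integer(1) global seed of the run.
#' @export
setClass("IcebergResult",
  representation(peaks = "GRanges", provenance = "DataFrame",
                 aggregatePeaks = "list", supportPeaks = "list",
                 config = "list", seed = "integer"),
  validity = function(object) {
    if (nrow(object@provenance) != length(object@peaks))
      return("provenance must have one row per peak")
    TRUE
  })

#' LoopSet: chromatin loops with per-replicate counts
#'
#' Intra-chromosomal loops parsed from BEDPE: two anchors per loop (anchor1
#' upstream of anchor2 on the same chromosome) and a per-replicate count
#' matrix. Loop size is the linear genomic distance from the start of the
#' first anchor to the end of the second.
#'
#' @slot anchor1,anchor2 `GRanges`, parallel, same chromosome per loop,
#'   anchor1 ordered before anchor2.
#' @slot counts numeric matrix, one row per loop, one column per replicate.
#' @export
setClass("LoopSet",
  representation(anchor1 = "GRanges", anchor2 = "GRanges", counts = "matrix"),
  validity = function(object) {
    n <- length(object@anchor1)
    if (length(object@anchor2) != n) return("anchor1/anchor2 lengths differ")
    if (nrow(object@counts) != n) return("counts must have one row per loop")
    if (n && any(as.character(seqnames(object@anchor1)) !=
                 as.character(seqnames(object@anchor2))))
      return("loops must be intra-chromosomal")
    TRUE
  })
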