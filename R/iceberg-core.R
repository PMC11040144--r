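# The ICEBERG decision rule: majority vote across aggregate peak calls plus a
# relaxed individual-replicate support filter.

#' ICEBERG run configuration
#'
#' Defaults mirror the published pipeline: three independent equal-depth
#' splits pooled into three aggregates, aggregate peaks called at q < 0.05
#' against the full aggregate IgG, a 2-of-3 majority vote, and a support
#' filter requiring each candidate to be called in at least one individual
#' replicate at p < 0.01 against the downsampled IgG.
#'
#' @param n_splits number of aggregate splits (default 3).
#' @param majority_min minimum number of aggregates that must call a region
#'   (default 2).
#' @param depth equal-depth downsampling target; `NULL` uses the smallest
#'   replicate depth.
#' @param aggregate_mode,aggregate_cutoff stringency of aggregate calls
#'   (default q < 0.05).
#' @param support_mode,support_cutoff stringency of individual-replicate
#'   support calls (default p < 0.01).
#' @param igg_individual_depth depth of the IgG control used for individual
#'   replicate calls; `NA` means the smaller of 5 million and the pooled IgG
#'   depth, `NULL` means the full pooled IgG.
#' @param caller_params base caller parameters (window geometry etc.); the
#'   threshold fields are overridden per call.
#' @return a named configuration list.
#' @export
icebergConfig <- function(n_splits = 3L, majority_min = 2L, depth = NULL,
                          aggregate_mode = "q", aggregate_cutoff = 0.05,
                          support_mode = "p", support_cutoff = 0.01,
                          igg_individual_depth = NA,
                          caller_params = peakCallParams()) {
  assertThat(majority_min >= 1L && majority_min <= n_splits,
             "requires 1 <= majority_min <= n_splits")
  assertThat(aggregate_cutoff > 0 && aggregate_cutoff < 1 &&
               support_cutoff > 0 && support_cutoff < 1,
             "cutoffs must lie in (0, 1)")
  list(n_splits = as.integer(n_splits), majority_min = as.integer(majority_min),
       depth = depth, aggregate_mode = aggregate_mode,
       aggregate_cutoff = aggregate_cutoff, support_mode = support_mode,
       support_cutoff = support_cutoff,
       igg_individual_depth = igg_individual_depth,
       caller_params = caller_params)
}

#' Regions called by a majority of aggregates
#'
#' Applies [regionsAtLeast()] across the k aggregate peak sets: exact
#' segments covered by at least `majority_min` aggregates, merged with gap 0.
#' Candidate coordinates come from this majority-region geometry, not from
#' any single aggregate's peak boundaries.
#'
#' @param aggregate_peaksets list of k `GRanges` (or [ScoredPeakSet]s).
#' @param majority_min minimum number of covering aggregates.
#' @return sorted, disjoint `GRanges`.
#' @export
majorityRegions <- function(aggregate_peaksets, majority_min = 2L) {
  sets <- lapply(aggregate_peaksets, function(s)
    if (is(s, "ScoredPeakSet")) granges(peakRanges(s)) else s)
  assertThat(length(sets) >= majority_min && majority_min >= 1L,
             "requires 1 <= majority_min <= number of aggregate sets")
  regionsAtLeast(overlapMatrix(sets, paste0("aggregate", seq_along(sets))),
                 majority_min)
}

#' Filter candidates by relaxed individual-replicate support
#'
#' Retains candidate regions sharing at least one base with at least one
#' interval of at least one relaxed (p < 0.01) per-replicate peak set.
#' Candidates are not trimmed to the supporting peaks' boundaries.
#'
#' @param candidates `GRanges` of candidate regions.
#' @param relaxed_replicate_sets list of per-replicate `GRanges` called at
#'   the support stringency.
#' @return the supported subset of `candidates`.
#' @export
supportFilter <- function(candidates, relaxed_replicate_sets) {
  if (!length(relaxed_replicate_sets)) return(candidates[rep(FALSE, length(candidates))])
  supported <- Reduce(`|`, lapply(relaxed_replicate_sets, function(s)
    overlapsAny(candidates, s, ignore.strand = TRUE)))
  candidates[supported]
}

#' Run the full ICEBERG aggregation pipeline
#'
#' Pipeline: equal-depth downsampling of every replicate, repeated
#' `n_splits` times with independent seeded draws; pooling of each split
#' into an aggregate; aggregate peak calls against the full pooled IgG at
#' the aggregate stringency; majority vote across aggregates
#' ([majorityRegions()]); relaxed peak calls on every individual replicate
#' against the downsampled IgG; and the support filter
#' ([supportFilter()]). The result carries full provenance and is
#' deterministic given (inputs, seed).
#'
#' @param replicates list of treatment [FragmentSet]s.
#' @param igg_replicates list of IgG control [FragmentSet]s.
#' @param genome a `Seqinfo`.
#' @param config an [icebergConfig()].
#' @param seed integer seed for all randomness in the run.
#' @return an [IcebergResult].
#' @export
runIceberg <- function(replicates, igg_replicates, genome,
                       config = icebergConfig(), seed = 1L) {
  assertThat(length(replicates) >= 1L, "need at least one replicate")
  assertThat(length(igg_replicates) >= 1L, "need at least one IgG replicate")
  if (length(replicates) == 1L) {
    warning("only one replicate: aggregates are resamples of a single ",
            "replicate and the majority vote loses its meaning", call. = FALSE)
  }
  if (config$n_splits < 3L) {
    warning("fewer than 3 splits: the majority vote is weaker than the ",
            "published default", call. = FALSE)
  }

  plan <- aggregationPlan(replicates, depth = config$depth,
                          n_splits = config$n_splits, seed = seed)
  splits <- buildSplits(replicates, plan)
  aggregates <- lapply(seq_along(splits), function(s)
    poolFragments(splits[[s]], label = paste0("aggregate", s)))

  iggDepth <- config$igg_individual_depth
  ctl <- aggregateControl(
    igg_replicates,
    downsample_to = if (is.null(iggDepth)) NULL
                    else if (is.na(iggDepth)) {
                      pooled <- sum(vapply(igg_replicates,
                                           function(r) length(fragments(r)),
                                           integer(1)))
                      min(5e6, pooled)
                    } else iggDepth,
    seed = seed)

  aggParams <- config$caller_params
  aggParams$threshold_mode <- config$aggregate_mode
  aggParams$threshold <- config$aggregate_cutoff
  aggregatePeaks <- lapply(aggregates, function(a)
    callPeaks(a, ctl$aggregate, genome, aggParams))

  candidates <- majorityRegions(aggregatePeaks, config$majority_min)

  supParams <- config$caller_params
  supParams$threshold_mode <- config$support_mode
  supParams$threshold <- config$support_cutoff
  supportCalls <- lapply(replicates, function(r)
    callPeaks(r, ctl$individual, genome, supParams))
  supportSets <- lapply(supportCalls, function(s) granges(peakRanges(s)))

  final <- supportFilter(candidates, supportSets)

  nAgg <- .countOverlappingSets(final, lapply(aggregatePeaks, peakRanges))
  nSup <- .countOverlappingSets(final, supportSets)

  new("IcebergResult", peaks = final,
      provenance = DataFrame(nAggregates = as.integer(nAgg),
                             nSupport = as.integer(nSup)),
      aggregatePeaks = aggregatePeaks, supportPeaks = supportCalls,
      config = config, seed = as.integer(seed))
}
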