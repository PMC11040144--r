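# Equal-depth downsampling, split construction, aggregate pooling (including
# the IgG aggregate) and build-curve generation.

#' Define an aggregation plan
#'
#' Fixes the shared downsampling depth, the number of independent
#' downsampling rounds ("splits"), and the seed for an aggregation run. The
#' depth defaults to the smallest replicate so every replicate can contribute
#' equally; splits are independent samples (not disjoint partitions) because
#' the smallest replicate cannot be partitioned several ways at that depth.
#'
#' @param replicates list of [FragmentSet] replicates.
#' @param depth fragments sampled per replicate; `NULL` uses the minimum
#'   replicate depth.
#' @param n_splits number of independent downsampling rounds (default 3).
#' @param seed integer seed; all per-(replicate, split) child seeds are
#'   derived from it with [childSeed()].
#' @return a list with `n_replicates`, `depth`, `n_splits`, `seed`,
#'   `replicate_ids`.
#' @export
aggregationPlan <- function(replicates, depth = NULL, n_splits = 3L, seed = 1L) {
  assertThat(length(replicates) >= 1L, "need at least one replicate")
  depths <- vapply(replicates, function(r) length(fragments(r)), integer(1))
  if (is.null(depth)) depth <- min(depths)
  assertThat(depth >= 1 && depth <= min(depths),
             paste0("depth must be <= the smallest replicate depth (",
                    min(depths), ")"))
  assertThat(n_splits >= 1L, "n_splits must be >= 1")
  ids <- vapply(replicates, replicateId, character(1))
  assertThat(!anyDuplicated(ids), "replicate ids must be unique")
  list(n_replicates = length(replicates), depth = as.integer(depth),
       n_splits = as.integer(n_splits), seed = as.integer(seed),
       replicate_ids = ids)
}

#' Downsample a fragment set to a fixed depth
#'
#' Uniform sample of exactly `m` fragments without replacement, drawn from a
#' seeded RNG stream; metadata is preserved and the same `(frags, m, seed)`
#' always yields the same output.
#'
#' @param frags a [FragmentSet].
#' @param m target depth, `m <= depth(frags)`.
#' @param seed integer seed.
#' @return a [FragmentSet] of depth `m`.
#' @export
downsampleFragments <- function(frags, m, seed) {
  d <- depth(frags)
  if (m > d) {
    stop("cannot downsample replicate '", replicateId(frags), "' to ", m,
         " fragments: depth is only ", d, call. = FALSE)
  }
  idx <- withSeed(seed, sample.int(d, m))
  FragmentSet(fragments(frags)[idx], target = target(frags),
              replicateId = replicateId(frags))
}

#' Independently downsample every replicate for each split
#'
#' For each of the plan's `n_splits` rounds, every replicate is downsampled
#' to the plan depth with a child seed derived from
#' `(plan seed, replicate id, split index)`. Splits may share fragments; a
#' replicate already at the plan depth contributes identical content to all
#' splits.
#'
#' @param replicates list of [FragmentSet].
#' @param plan an [aggregationPlan()].
#' @return list of `n_splits` lists, each holding the n downsampled
#'   [FragmentSet]s.
#' @export
buildSplits <- function(replicates, plan) {
  lapply(seq_len(plan$n_splits), function(s) {
    lapply(seq_along(replicates), function(i) {
      downsampleFragments(replicates[[i]], plan$depth,
                          childSeed(plan$seed, "downsample",
                                    plan$replicate_ids[i], s))
    })
  })
}

#' Pool fragment sets into one aggregate
#'
#' Multiset union of the input fragments: the aggregate depth is always the
#' sum of the input depths.
#'
#' @param sets non-empty list of [FragmentSet].
#' @param label replicate identifier for the pooled set.
#' @return a [FragmentSet].
#' @export
poolFragments <- function(sets, label = "aggregate") {
  assertThat(is.list(sets) && length(sets) >= 1L, "need at least one set to pool")
  gr <- do.call(c, lapply(sets, fragments))
  FragmentSet(gr, target = target(sets[[1]]), replicateId = label)
}

#' Expected depth of a pooled aggregate
#'
#' Read-accounting for an aggregation plan without materialising fragments:
#' pooling `n` equal-depth sets of `m` fragments yields an `n * m` aggregate.
#'
#' @param n_replicates number of pooled replicates.
#' @param depth fragments per replicate after equal-depth downsampling.
#' @return numeric(1) aggregate depth.
#' @examples
#' aggregateDepth(25, 4e6) # 100 million fragments
#' @export
aggregateDepth <- function(n_replicates, depth) {
  assertThat(n_replicates >= 1 && depth >= 1, "need positive counts")
  as.numeric(n_replicates) * as.numeric(depth)
}

#' Build the aggregate IgG control and its individual-call copy
#'
#' All IgG replicates are pooled into the aggregate IgG used as the control
#' for aggregate peak calls. A downsampled copy (default 5 million fragments,
#' the scale of a single replicate library) is used as the control when
#' calling peaks on individual replicates, so individual calls are not
#' dominated by a control far deeper than the treatment.
#'
#' @param igg_replicates list of IgG [FragmentSet]s.
#' @param downsample_to depth of the individual-call control, or `NULL` to
#'   reuse the full aggregate.
#' @param seed integer seed for the downsampling draw.
#' @return list with `aggregate` (full pooled IgG) and `individual`
#'   (downsampled copy) [FragmentSet]s.
#' @export
aggregateControl <- function(igg_replicates, downsample_to = NULL, seed = 1L) {
  assertThat(length(igg_replicates) >= 1L, "need at least one IgG replicate")
  agg <- poolFragments(igg_replicates, label = "IgG_aggregate")
  indiv <- if (is.null(downsample_to)) {
    agg
  } else {
    assertThat(downsample_to <= depth(agg),
               paste0("downsample_to exceeds pooled IgG depth (", depth(agg), ")"))
    downsampleFragments(agg, as.integer(downsample_to),
                        childSeed(seed, "igg-downsample"))
  }
  list(aggregate = agg, individual = indiv)
}

#' Peak-discovery build curves under cumulative replicate aggregation
#'
#' For each of `n_orders` seeded random replicate orders and each split,
#' replicates are pooled cumulatively one at a time; after every addition,
#' peaks are called against the aggregate IgG and counted. The endpoint of
#' every curve is the full aggregate's peak count, which is invariant to the
#' order of addition.
#'
#' @param replicates list of [FragmentSet].
#' @param igg_aggregate the full aggregate IgG [FragmentSet].
#' @param plan an [aggregationPlan()].
#' @param genome a `Seqinfo`.
#' @param params caller parameters (defaults to q < 0.05).
#' @param n_orders number of random replicate orders (default 5).
#' @return `data.frame` with columns `order_id`, `split_id`,
#'   `replicates_added`, `peak_count`.
#' @export
buildCurves <- function(replicates, igg_aggregate, plan, genome,
                        params = peakCallParams(), n_orders = 5L) {
  splits <- buildSplits(replicates, plan)
  n <- plan$n_replicates
  rows <- list()
  for (o in seq_len(n_orders)) {
    ord <- withSeed(childSeed(plan$seed, "build-order", o), sample.int(n))
    for (s in seq_len(plan$n_splits)) {
      for (x in seq_len(n)) {
        pool <- poolFragments(splits[[s]][ord[seq_len(x)]],
                              label = sprintf("order%d_split%d_x%d", o, s, x))
        res <- callPeaks(pool, igg_aggregate, genome, params)
        rows[[length(rows) + 1L]] <- data.frame(
          order_id = o, split_id = s, replicates_added = x,
          peak_count = length(res))
      }
    }
  }
  do.call(rbind, rows)
}
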