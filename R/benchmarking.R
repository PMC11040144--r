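# Precision/recall/F1 of peak sets and replicate-combination strategies
# against an aggregated gold-standard peak set.

#' Precision and recall of a called peak set against a gold standard
#'
#' Precision is the fraction of called intervals overlapping (>= 1 bp) at
#' least one gold interval; recall is the fraction of gold intervals
#' overlapping at least one called interval. A called interval spanning two
#' gold intervals counts once in the precision numerator, and vice versa, so
#' the measure is asymmetric by construction. An empty called set has
#' undefined precision (`NA`) and recall 0.
#'
#' @param called `GRanges` of called peaks.
#' @param gold non-empty `GRanges` gold standard.
#' @return list with `precision` and `recall`.
#' @export
precisionRecall <- function(called, gold) {
  assertThat(length(gold) > 0, "gold standard peak set is empty")
  if (!length(called)) return(list(precision = NA_real_, recall = 0))
  list(precision = intersectCount(called, gold)$count / length(called),
       recall = intersectCount(gold, called)$count / length(gold))
}

#' F1 score
#'
#' Harmonic mean of precision and recall,
#' `F1 = 2 * P * R / (P + R)`, with `F1 = 0` when `P + R = 0`.
#'
#' @param precision,recall numerics in `[0, 1]`.
#' @return numeric F1 in `[0, 1]`.
#' @examples
#' f1Score(0.94, 0.023)
#' @export
f1Score <- function(precision, recall) {
  assertThat(all(is.finite(c(precision, recall))) &&
               all(c(precision, recall) >= 0) && all(c(precision, recall) <= 1),
             "precision and recall must lie in [0, 1]")
  s <- precision + recall
  ifelse(s == 0, 0, 2 * precision * recall / s)
}

#' Enumerate replicate combinations and their k-of-m overlap sets
#'
#' Builds duplicate or triplicate (or general m-replicate) combinations of
#' peak sets and evaluates each with the k-of-m majority overlap
#' ([regionsAtLeast()]). Duplicates enumerate all C(n, 2) pairs; larger
#' combinations can be capped at a seeded random selection of distinct
#' combinations (the published benchmark uses > 50 random triplicates). No
#' combination repeats a replicate.
#'
#' @param peak_sets list of n `GRanges`.
#' @param m combination size (2 for duplicates, 3 for triplicates).
#' @param k minimum number of member sets that must cover a region
#'   (`1 <= k <= m`).
#' @param select `"all"` or an integer count of random distinct combinations
#'   to draw.
#' @param seed integer seed for the random selection.
#' @return list of entries, each with `ids` (member indices) and `regions`
#'   (`GRanges`).
#' @export
combineReplicates <- function(peak_sets, m = 2L, k = m, select = "all",
                              seed = 1L) {
  n <- length(peak_sets)
  assertThat(m >= 1L && m <= n, "requires 1 <= m <= number of sets")
  assertThat(k >= 1L && k <= m, "requires 1 <= k <= m")
  combos <- combn(n, m, simplify = FALSE)
  if (!identical(select, "all")) {
    count <- as.integer(select)
    assertThat(count >= 1L, "select must be 'all' or a positive count")
    if (count > length(combos)) {
      warning("requested ", count, " combinations but only ", length(combos),
              " exist; using all", call. = FALSE)
      count <- length(combos)
    }
    idx <- withSeed(childSeed(seed, "combo-select", n, m),
                    sample.int(length(combos), count))
    combos <- combos[sort(idx)]
  }
  lapply(combos, function(ix) {
    list(ids = ix, regions = regionsAtLeast(peak_sets[ix], k))
  })
}

#' Benchmark replicate/peak-calling strategies against a gold standard
#'
#' Evaluates every combination produced by a list of strategies with
#' [precisionRecall()] and [f1Score()], returning one row per combination
#' plus per-strategy summaries (mean and standard deviation of F1;
#' combinations with undefined precision are excluded from the means and
#' counted in `n_excluded`).
#'
#' @param strategy_sets named list; each element is a list of entries with
#'   `ids` and `regions` as returned by [combineReplicates()] (a plain list
#'   of `GRanges` is also accepted).
#' @param gold non-empty `GRanges` gold standard.
#' @return list with `results` and `summary` data frames.
#' @export
benchmarkTable <- function(strategy_sets, gold) {
  assertThat(length(gold) > 0, "gold standard peak set is empty")
  rows <- list()
  for (strat in names(strategy_sets)) {
    entries <- strategy_sets[[strat]]
    for (i in seq_along(entries)) {
      e <- entries[[i]]
      if (is(e, "GRanges")) e <- list(ids = i, regions = e)
      pr <- precisionRecall(e$regions, gold)
      f1 <- if (is.na(pr$precision)) NA_real_ else f1Score(pr$precision, pr$recall)
      rows[[length(rows) + 1L]] <- data.frame(
        strategy = strat, combination = paste(e$ids, collapse = "+"),
        n_called = length(e$regions), n_gold = length(gold),
        precision = pr$precision, recall = pr$recall, f1 = f1)
    }
  }
  results <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(results, results$strategy), function(d) {
    ok <- !is.na(d$f1)
    data.frame(strategy = d$strategy[1], n = sum(ok),
               n_excluded = sum(!ok),
               mean_f1 = if (any(ok)) mean(d$f1[ok]) else NA_real_,
               sd_f1 = if (sum(ok) > 1) sd(d$f1[ok]) else NA_real_)
  }))
  rownames(summ) <- NULL
  list(results = results, summary = summ)
}
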