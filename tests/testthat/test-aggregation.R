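toy_reps <- function(depths, L = 10000) {
  lapply(seq_along(depths), function(i) {
    gr <- GRanges("c", IRanges(seq_len(depths[i]) * 3L, width = 100L))
    FragmentSet(gr, target = "toy", replicateId = paste0("rep", i))
  })
}

test_that("downsampling is exact, deterministic, and a subset of the input", {
  fs <- toy_reps(10)[[1]]
  expect_equal(depth(downsampleFragments(fs, 10, 1)), 10L)
  # full-depth downsample keeps the same multiset
  expect_setequal(as.character(fragments(downsampleFragments(fs, 10, 5))),
                  as.character(fragments(fs)))
  d5 <- downsampleFragments(fs, 5, 7)
  expect_equal(depth(d5), 5L)
  expect_true(all(as.character(fragments(d5)) %in% as.character(fragments(fs))))
  expect_identical(fragments(downsampleFragments(fs, 5, 7)),
                   fragments(downsampleFragments(fs, 5, 7)))
  expect_error(downsampleFragments(fs, 11, 1), "rep1")
})

test_that("downsampling is uniform over fragments", {
  fs <- toy_reps(10)[[1]]
  picks <- vapply(1:1000, function(i)
    start(fragments(downsampleFragments(fs, 1, i))), numeric(1))
  counts <- table(factor(picks, levels = start(fragments(fs))))
  # each fragment expected 100 times, 4 sigma binomial tolerance
  sigma <- sqrt(1000 * 0.1 * 0.9)
  expect_true(all(abs(counts - 100) <= 4 * sigma))
})

test_that("plans validate depth against the smallest replicate", {
  reps <- toy_reps(c(10, 8))
  plan <- aggregationPlan(reps, n_splits = 3, seed = 1)
  expect_equal(plan$depth, 8L)
  expect_error(aggregationPlan(reps, depth = 9), "smallest")
  splits <- buildSplits(reps, plan)
  expect_length(splits, 3)
  for (s in splits) expect_equal(vapply(s, depth, integer(1)), c(8L, 8L))
  # replicate at exactly the plan depth contributes identical content everywhere
  second <- lapply(splits, function(s) sort(fragments(s[[2]])))
  expect_identical(second[[1]], second[[2]])
  expect_identical(second[[2]], second[[3]])
})

test_that("pooling sums depths and aggregate accounting matches the published scale", {
  reps <- toy_reps(c(10, 8, 5))
  pool <- poolFragments(reps)
  expect_equal(depth(pool), 23L)
  expect_equal(depth(poolFragments(reps[1])), 10L)
  expect_equal(aggregateDepth(25, 4e6), 1e8)
  expect_equal(aggregateDepth(10, 5e6), 5e7)
})

test_that("IgG aggregation pools everything and downsamples the individual-call copy", {
  igg <- toy_reps(c(7, 7, 7))
  ctl <- aggregateControl(igg, downsample_to = 5, seed = 2)
  expect_equal(depth(ctl$aggregate), 21L)
  expect_equal(depth(ctl$individual), 5L)
  ctl2 <- aggregateControl(igg)
  expect_identical(fragments(ctl2$individual), fragments(ctl2$aggregate))
  expect_equal(depth(aggregateControl(igg[1])$aggregate), 7L)
  expect_error(aggregateControl(igg, downsample_to = 22), "exceeds")
})

test_that("build curves end at the order-invariant full-pool peak count", {
  se <- small_experiment()
  reps <- se$sim$replicates[1:4]
  igg <- aggregateControl(se$sim$igg)$aggregate
  plan <- aggregationPlan(reps, n_splits = 2, seed = 5)
  curves <- buildCurves(reps, igg, plan, se$genome, n_orders = 2)
  expect_equal(nrow(curves), 2 * 2 * 4)
  expect_true(all(curves$peak_count >= 0))
  # per (order, split) x is strictly increasing 1..n
  for (o in 1:2) for (s in 1:2) {
    expect_equal(curves$replicates_added[curves$order_id == o &
                                           curves$split_id == s], 1:4)
  }
  # the endpoint depends only on the split, not the order
  finals <- curves[curves$replicates_added == 4, ]
  for (s in 1:2) {
    expect_equal(length(unique(finals$peak_count[finals$split_id == s])), 1L)
  }
  # mean over orders is non-decreasing with replicates added
  avg <- tapply(curves$peak_count, curves$replicates_added, mean)
  expect_true(all(diff(avg) >= 0))
})

test_that("child seeds are stable, distinct, and within integer range", {
  expect_identical(childSeed(1, "a", 1), childSeed(1, "a", 1))
  expect_false(childSeed(1, "a", 1) == childSeed(1, "a", 2))
  expect_false(childSeed(1, "a", 1) == childSeed(2, "a", 1))
  seeds <- vapply(1:100, function(i) childSeed(42, "x", i), integer(1))
  expect_true(all(seeds >= 0 & seeds < 2^31))
  expect_equal(length(unique(seeds)), 100L)
})
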