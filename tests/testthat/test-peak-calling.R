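test_that("Benjamini-Hochberg matches the brute-force step-up definition", {
  expect_equal(benjaminiHochberg(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(benjaminiHochberg(0.05), 0.05)
  expect_equal(benjaminiHochberg(c(0.5, 0.5)), c(0.5, 0.5))
  expect_error(benjaminiHochberg(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(benjaminiHochberg(c(0.5, 1.5)), "\\(0, 1\\]")

  # brute force: q_i = min over {j : p_j >= p_i} of m * p_j / rank_j
  bh_oracle <- function(p) {
    m <- length(p)
    ord <- order(p)
    ranks <- integer(m)
    ranks[ord] <- seq_len(m)
    vapply(seq_len(m), function(i) {
      j <- which(p >= p[i])
      min(pmin(m * p[j] / ranks[j], 1))
    }, numeric(1))
  }
  withr::with_seed(99, {
    for (rep in 1:20) {
      p <- runif(sample(c(1, 5, 100, 1000), 1))
      expect_equal(benjaminiHochberg(p), bh_oracle(p), tolerance = 1e-12)
    }
  })
})

test_that("window p-values are exact Poisson tails", {
  # one isolated 50 bp window with 10 overlapping fragments against a
  # control giving a window-scale rate; check p equals the Poisson survival
  g <- makeGenome("c", 20000)
  tr <- frag_set(rep(5000, 10), rep(5040, 10))
  ct <- frag_set(rep(5000, 3), rep(5040, 3))
  sw <- scoreWindows(tr, ct, g)
  hot <- sw[which.max(S4Vectors::mcols(sw)$count)]
  cnt <- S4Vectors::mcols(hot)$count
  lam <- S4Vectors::mcols(hot)$lambda
  expect_equal(S4Vectors::mcols(hot)$pValue,
               ppois(cnt - 1, lam, lower.tail = FALSE))
  # the documented single-window oracle: count 10 against lambda 2
  expect_equal(ppois(9, 2, lower.tail = FALSE), 1 - ppois(9, 2), tolerance = 1e-12)
})

test_that("null data produces (almost) no significant windows at q < 0.05", {
  g <- makeGenome("c", 1e6)
  fracs <- withr::with_seed(7, {
    vapply(1:5, function(i) {
      tr <- FragmentSet(GRanges("c", IRanges(sample.int(1e6 - 200, 1e4), width = 170)))
      ct <- FragmentSet(GRanges("c", IRanges(sample.int(1e6 - 200, 1e4), width = 170)))
      sw <- scoreWindows(tr, ct, g)
      mean(S4Vectors::mcols(sw)$qValue < 0.05)
    }, numeric(1))
  })
  expect_true(all(fracs <= 0.05))
  pk <- withr::with_seed(7, {
    tr <- FragmentSet(GRanges("c", IRanges(sample.int(1e6 - 200, 1e4), width = 170)))
    ct <- FragmentSet(GRanges("c", IRanges(sample.int(1e6 - 200, 1e4), width = 170)))
    callPeaks(tr, ct, g)
  })
  expect_lte(length(pk), 2)
})

test_that("a planted spike yields exactly one covering peak", {
  g <- makeGenome("c", 1e5)
  sim <- withr::with_seed(7, {
    bgT <- GRanges("c", IRanges(sample.int(1e5 - 200, 1000), width = 170))
    spike <- GRanges("c", IRanges(sample(50000:50200, 200, replace = TRUE),
                                  width = 170))
    bgC <- GRanges("c", IRanges(sample.int(1e5 - 200, 1000), width = 170))
    list(t = FragmentSet(c(bgT, spike)), c = FragmentSet(bgC))
  })
  res <- callPeaks(sim$t, sim$c, g)
  expect_equal(length(res), 1L)
  expect_true(overlapsAny(peakRanges(res), GRanges("c", IRanges(50001, 50200))))
  # summit sits inside the spiked region
  expect_true(S4Vectors::mcols(peakRanges(res))$summit >= 50001 - 200 &&
                S4Vectors::mcols(peakRanges(res))$summit <= 50400)
})

test_that("thresholding filters without re-merging and sets are nested", {
  se <- small_experiment()
  call <- callPeaks(se$sim$replicates[[1]], se$sim$igg[[1]], se$genome,
                    peakCallParams(threshold_mode = "p", threshold = 0.01))
  q05 <- thresholdPeaks(call, "q", 0.05)
  p001 <- thresholdPeaks(call, "p", 0.001)
  expect_true(all(overlapsAny(peakRanges(q05), peakRanges(call))))
  expect_lte(length(p001), length(call))
  expect_lte(length(q05), length(call))
  # stricter p-set is a subset of the call's peaks (identical coordinates)
  expect_true(all(as.character(peakRanges(p001)) %in%
                    as.character(peakRanges(call))))
  expect_equal(length(thresholdPeaks(call, "p", 1)), length(call))
  tiny <- min(S4Vectors::mcols(peakRanges(call))$pValue) / 2
  expect_equal(length(thresholdPeaks(call, "p", max(tiny, 1e-320))), 0L)
  expect_error(thresholdPeaks(call, "q", 0), "\\(0, 1\\]")
})

test_that("depth scaling leaves fold-enrichment ranks unchanged", {
  g <- makeGenome("c", 50000)
  tr <- withr::with_seed(3, FragmentSet(
    GRanges("c", IRanges(c(sample.int(49000, 500), rep(20000, 60)), width = 150))))
  ct <- withr::with_seed(4, FragmentSet(
    GRanges("c", IRanges(sample.int(49000, 500), width = 150))))
  doubleSet <- function(fs) FragmentSet(rep(fragments(fs), 2))
  par <- peakCallParams(pseudocount = 0)
  sw1 <- scoreWindows(tr, ct, g, par)
  sw2 <- scoreWindows(doubleSet(tr), doubleSet(ct), g, par)
  # counts and rates both double exactly, so fold enrichment is unchanged
  expect_equal(S4Vectors::mcols(sw2)$fold, S4Vectors::mcols(sw1)$fold)
})

test_that("zero-depth control and empty genome are rejected with guidance", {
  g <- makeGenome("c", 10000)
  tr <- frag_set(c(0, 100), c(50, 200))
  empty <- FragmentSet(GRanges())
  expect_error(callPeaks(tr, empty, g), "pseudo-control")
  expect_error(callPeaks(empty, NULL, g), "non-empty")
})
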