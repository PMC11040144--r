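test_that("BED reading sorts records, skips headers and validates coordinates", {
  tf <- withr::local_tempfile()
  writeLines(c("chr1\t100\t200", "chr1\t0\t50", "chr1\t40\t90"), tf)
  got <- readIntervals(tf)
  expect_length(got, 3)
  expect_equal(start(got), c(1L, 41L, 101L))

  writeLines(character(0), tf)
  expect_length(readIntervals(tf), 0)

  writeLines(c("# a comment", "track name=x", "chr1\t5\t10"), tf)
  expect_length(readIntervals(tf), 1)

  writeLines("chr1\t100\t50", tf)
  expect_error(readIntervals(tf), "line 1.*start < end")
  writeLines(c("chr1\t0\t10", "chr1\tfoo\t20"), tf)
  expect_error(readIntervals(tf), "line 2")
  writeLines("chr1\t10", tf)
  expect_error(readIntervals(tf), "fewer than 3")
})

test_that("genome binding validates names and bounds", {
  g <- makeGenome(c("chr1", "chr2"), c(1000, 500))
  tf <- withr::local_tempfile()
  writeLines("chr3\t0\t10", tf)
  expect_error(readIntervals(tf, g), "chr3")
  writeLines("chr2\t0\t600", tf)
  expect_error(readIntervals(tf, g), "exceeds")
  expect_error(makeGenome(c("a", "a"), c(1, 2)), "unique")
  expect_error(makeGenome("a", 0), "positive")
})

test_that("fragment reading keeps duplicates and counts depth", {
  tf <- withr::local_tempfile()
  writeLines(rep("chr1\t0\t100", 10), tf)
  fs <- readFragments(tf, target = "t", replicateId = "r1")
  expect_equal(depth(fs), 10L)
  writeLines(c("# header", "chr1\t0\t10", "chr1\t0\t10", "chr1\t5\t15",
               "chr1\t20\t30", "chr1\t20\t30"), tf)
  expect_equal(depth(readFragments(tf)), 5L)
})

test_that("write/read round-trips are identity and narrowPeak scores follow the formula", {
  tf <- withr::local_tempfile()
  s <- sort(gr0(c(0, 50, 500), c(10, 70, 900)))
  writeIntervals(s, tf)
  expect_equal(runs_of(readIntervals(tf)), runs_of(s))

  writeIntervals(GRanges(), tf)
  expect_length(readIntervals(tf), 0)

  pk <- gr0(100, 400)
  S4Vectors::mcols(pk) <- S4Vectors::DataFrame(pValue = 1e-4, qValue = 0.01,
                                               signal = 5.5, summit = 250L)
  sps <- new("ScoredPeakSet", peaks = pk, params = peakCallParams(),
             treatmentDepth = 100, controlDepth = 100)
  writeIntervals(sps, tf)
  row <- strsplit(readLines(tf), "\t")[[1]]
  expect_length(row, 10)
  expect_equal(as.integer(row[5]), 20L) # int(min(1000, 10 * -log10(0.01)))
  expect_equal(row[6], ".")
  # summit at 0-based position 249 in a peak starting at 0-based 100
  expect_equal(as.integer(row[10]), 149L)
})

test_that("merging collapses overlaps and book-ended intervals", {
  expect_length(mergeIntervals(GRanges()), 0)
  expect_same_runs(mergeIntervals(gr0(c(0, 5), c(10, 20))), cbind(1, 20))
  # book-ended at gap 0
  expect_same_runs(mergeIntervals(gr0(c(0, 5), c(5, 10))), cbind(1, 10))
  # separated by 1 base: kept apart at gap 0, merged at gap 1
  apart <- gr0(c(0, 6), c(5, 10))
  expect_length(mergeIntervals(apart, 0), 2)
  expect_length(mergeIntervals(apart, 1), 1)
  expect_error(mergeIntervals(apart, -1), "non-negative")
})

test_that("overlap counting uses half-open >= 1 base semantics", {
  a <- gr0(0, 10)
  expect_equal(intersectCount(a, gr0(9, 20))$count, 1)
  expect_equal(intersectCount(a, gr0(10, 20))$count, 0)
  b <- sort(gr0(c(0, 100), c(10, 200)))
  expect_equal(intersectCount(b, b)$count, 2)
  expect_equal(suppressWarnings(
    intersectCount(b, GRanges("other", IRanges(1, 1000)))$count), 0)
})

test_that("suspect-list subtraction drops whole overlapping fragments", {
  fs <- frag_set(c(0, 10, 20, 30, 40, 50, 60, 70, 80, 90),
                 c(5, 15, 25, 35, 45, 55, 65, 75, 85, 95))
  expect_equal(depth(subtractFragments(fs, GRanges())), 10L)
  expect_equal(depth(subtractFragments(fs, gr0(0, 100))), 0L)
  # suspect region overlapping exactly the first three fragments
  expect_equal(depth(subtractFragments(fs, gr0(0, 22))), 7L)
})

test_that("overlap matrix segments at breakpoints with exact membership", {
  m1 <- overlapMatrix(list(gr0(0, 10)), "A")
  expect_length(segments(m1), 1)
  expect_true(all(membership(m1)))

  m <- overlapMatrix(list(A = gr0(0, 10), B = gr0(5, 15)))
  expect_equal(unname(runs_of(segments(m))), unname(cbind(c(1, 6, 11), c(5, 10, 15))))
  expect_equal(unname(membership(m)),
               matrix(c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE), ncol = 2))

  dup <- overlapMatrix(list(gr0(c(0, 50), c(10, 60)), gr0(c(0, 50), c(10, 60))),
                       c("x", "y"))
  expect_true(all(membership(dup)))
  expect_error(overlapMatrix(list(gr0(0, 1), gr0(0, 1)), c("a", "a")), "duplicate")
})

test_that("regions at least x matches the worked example and bounds", {
  sets <- list(A = gr0(0, 10), B = gr0(5, 15), C = gr0(20, 30))
  m <- overlapMatrix(sets)
  expect_same_runs(regionsAtLeast(m, 1), cbind(c(1, 21), c(15, 30)))
  expect_same_runs(regionsAtLeast(m, 2), cbind(6, 10))
  expect_length(regionsAtLeast(m, 3), 0)
  expect_error(regionsAtLeast(m, 0), "1\\.\\.3")
  expect_error(regionsAtLeast(m, 4), "1\\.\\.3")
  # identical sets: any x gives the merged set
  idn <- list(gr0(c(0, 50), c(10, 60)), gr0(c(0, 50), c(10, 60)))
  expect_same_runs(regionsAtLeast(idn, 2), cbind(c(1, 51), c(10, 60)))
})

test_that("interval algebra agrees with the per-base oracle on random instances", {
  withr::with_seed(42, {
    for (rep in 1:25) {
      L <- sample(2000:10000, 1)
      k <- sample(2:4, 1)
      sets <- random_sets(k, L, max_iv = 30L, max_w = 300L)
      gap <- sample(0:30, 1)
      expect_same_runs(mergeIntervals(sets[[1]], gap),
                       ora_merge(sets[[1]], L, gap))
      expect_equal(intersectCount(sets[[1]], sets[[2]])$hits,
                   ora_hits(sets[[1]], sets[[2]], L))
      m <- overlapMatrix(sets)
      for (x in seq_len(k)) {
        expect_same_runs(regionsAtLeast(m, x), ora_at_least(sets, L, x))
      }
      # membership reconstruction: flagged segments reproduce each input
      for (j in seq_len(k)) {
        rec <- mergeIntervals(segments(m)[membership(m)[, j]], 0)
        expect_same_runs(rec, ora_merge(sets[[j]], L, 0))
      }
    }
  })
})

test_that("base coverage of at-least regions is monotone in x", {
  withr::with_seed(7, {
    sets <- random_sets(4, 5000)
    m <- overlapMatrix(sets)
    covs <- lapply(1:4, function(x) sum(width(regionsAtLeast(m, x))))
    expect_true(all(diff(unlist(covs)) <= 0))
    for (x in 1:3) {
      hi <- regionsAtLeast(m, x + 1)
      lo <- regionsAtLeast(m, x)
      # every base of the stricter set is inside the looser set
      expect_equal(sum(width(GenomicRanges::intersect(hi, lo))), sum(width(hi)))
    }
  })
})
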