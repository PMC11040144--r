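test_that("truth generation is deterministic with disjoint, in-bounds intervals", {
  cfg <- syntheticConfig(genome = makeGenome("chrS", 4e5), n_sites = 50,
                         n_hotspots = 3, n_replicates = 2, n_igg = 1,
                         background_fragments = 1000, seed = 99)
  t1 <- generateTruth(cfg)
  t2 <- generateTruth(cfg)
  expect_identical(t1, t2)
  expect_length(t1, 53)
  expect_equal(sum(S4Vectors::mcols(t1)$artifact), 3L)
  expect_true(all(width(t1) == cfg$site_width))
  expect_length(GenomicRanges::reduce(t1), 53) # pairwise disjoint
  expect_true(all(end(t1) <= 4e5))
  p <- S4Vectors::mcols(t1)$probability
  expect_true(all(is.na(p[S4Vectors::mcols(t1)$artifact])))
  expect_true(all(p[!S4Vectors::mcols(t1)$artifact] >= 0 &
                    p[!S4Vectors::mcols(t1)$artifact] <= 1))

  degenerate <- syntheticConfig(genome = makeGenome("chrS", 4e5),
                                probability_mixture = list(c(1, 0.5, 0.5)),
                                n_sites = 20, n_replicates = 2, n_igg = 1,
                                background_fragments = 1000, seed = 1)
  td <- generateTruth(degenerate)
  expect_true(all(S4Vectors::mcols(td)$probability[
    !S4Vectors::mcols(td)$artifact] == 0.5))
})

test_that("impossible placements fail with guidance", {
  tight <- syntheticConfig(genome = makeGenome("c", 2000), n_sites = 10,
                           site_width = 300, n_hotspots = 0,
                           n_replicates = 1, n_igg = 1,
                           background_fragments = 10, seed = 1)
  expect_error(generateTruth(tight), "larger genome")
})

test_that("replicates are seed-stable and respect the zero-occupancy contract", {
  g <- makeGenome("chrS", 3e5)
  base <- syntheticConfig(genome = g, n_sites = 30, n_hotspots = 2,
                          n_replicates = 2, n_igg = 1,
                          background_fragments = 3000, seed = 77)
  r1 <- simulateReplicate(generateTruth(base), base, 1)
  r1b <- simulateReplicate(generateTruth(base), base, 1)
  expect_identical(fragments(r1), fragments(r1b))
  expect_false(identical(fragments(r1),
                         fragments(simulateReplicate(generateTruth(base), base, 2))))
  expect_true(all(width(fragments(r1)) >= base$fragment_length$min))

  off <- syntheticConfig(genome = g, n_sites = 30, n_hotspots = 2,
                         probability_mixture = list(c(1, 0, 0)),
                         n_replicates = 1, n_igg = 1,
                         background_fragments = 3000, seed = 77)
  truthOff <- generateTruth(off)
  rep0 <- simulateReplicate(truthOff, off, 1)
  ctl0 <- simulateControl(truthOff, off, 1)
  # with p = 0 everywhere, treatment is distributed like the control:
  # background plus hotspots only (counts differ only by Poisson draws)
  sites <- truthOff[!S4Vectors::mcols(truthOff)$artifact]
  hs <- truthOff[S4Vectors::mcols(truthOff)$artifact]
  siteCov <- sum(overlapsAny(fragments(rep0), sites))
  expect_lt(siteCov / depth(rep0), 0.05) # background-level coverage only
  expect_gt(sum(overlapsAny(fragments(rep0), hs)), 0)
})

test_that("controls share hotspot load with treatment but carry no site signal", {
  g <- makeGenome("chrS", 3e5)
  cfg <- syntheticConfig(genome = g, n_sites = 20, n_hotspots = 3,
                         probability_mixture = list(c(1, 1, 1)),
                         n_replicates = 1, n_igg = 1,
                         background_fragments = 3000,
                         hotspot_fragments_mean = 80, seed = 31)
  truth <- generateTruth(cfg)
  hs <- truth[S4Vectors::mcols(truth)$artifact]
  sites <- truth[!S4Vectors::mcols(truth)$artifact]
  ratios <- vapply(1:10, function(i) {
    tr <- simulateReplicate(truth, cfg, i)
    ct <- simulateControl(truth, cfg, i)
    sum(overlapsAny(fragments(ct), hs)) / sum(overlapsAny(fragments(tr), hs))
  }, numeric(1))
  expect_true(all(ratios > 0.5 & ratios < 2))
  ct <- simulateControl(truth, cfg, 1)
  expect_identical(fragments(ct), fragments(simulateControl(truth, cfg, 1)))
  # control site coverage is background-level despite p = 1 sites
  expect_lt(mean(overlapsAny(fragments(ct), sites)), 0.1)
})
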