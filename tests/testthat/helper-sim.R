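# Lazily computed, cached fixtures shared across test files. The large
# planted-spectrum experiment (default configuration: 2 Mb genome, 200
# sites, 25 replicates, 10 IgG, seed 1234) takes a couple of minutes and is
# computed at most once per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Full default-scale planted-spectrum experiment plus the ICEBERG run and
# the strict per-replicate tier.
planted_experiment <- function() {
  cached("planted", {
    cfg <- syntheticConfig()
    sim <- simulateExperiment(cfg)
    res <- runIceberg(sim$replicates, sim$igg, cfg$genome, seed = cfg$seed)
    sites <- sim$truth[!S4Vectors::mcols(sim$truth)$artifact]
    hotspots <- sim$truth[S4Vectors::mcols(sim$truth)$artifact]
    strict <- lapply(supportPeakSets(res), function(s)
      granges(peakRanges(thresholdPeaks(s, "q", 0.05))))
    list(cfg = cfg, sim = sim, res = res, sites = sites,
         hotspots = hotspots, strict = strict)
  })
}

# Two independent demo-pipeline runs with the same seed, for determinism
# checks and output-layout assertions.
demo_pair <- function() {
  cached("demo_pair", {
    out1 <- file.path(tempdir(), "iceberg_demo_a")
    out2 <- file.path(tempdir(), "iceberg_demo_b")
    suppressMessages(suppressWarnings({
      r1 <- runDemo(out1, seed = 5)
      runDemo(out2, seed = 5)
    }))
    list(out1 = out1, out2 = out2, r1 = r1)
  })
}

# Compact experiment for cheap end-to-end unit tests.
small_experiment <- function(seed = 11L) {
  cached(paste0("small", seed), {
    g <- makeGenome("chrS", 6e5)
    cfg <- syntheticConfig(genome = g, n_sites = 60, background_fragments = 12000,
                           n_hotspots = 2, n_replicates = 6, n_igg = 3,
                           seed = seed)
    sim <- simulateExperiment(cfg)
    list(cfg = cfg, sim = sim, genome = g)
  })
}
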