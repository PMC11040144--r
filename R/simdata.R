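# Seeded generator of multi-replicate fragment data with a planted per-site
# detection-probability spectrum, uniform background, and artifact hotspots
# shared between treatment and IgG controls.

#' Synthetic experiment configuration
#'
#' Defaults emulate a compact multi-replicate CUT&RUN experiment: one 2 Mb
#' chromosome carrying 200 binding sites whose per-replicate occupancy
#' probabilities are drawn from a two-component mixture (a quarter of sites
#' near-always detectable, the rest rare to moderately detectable), uniform
#' background fragments, and a few artifact hotspots that deposit fragments
#' in treatment and IgG alike. Every stochastic quantity is driven by child
#' seeds of `seed`, so output is reproducible.
#'
#' @param genome a `Seqinfo` (default one 2 Mb chromosome).
#' @param n_sites number of planted binding sites.
#' @param probability_mixture list of `(weight, p_low, p_high)` components;
#'   each site draws its occupancy probability uniformly within one
#'   component's range. Weights must sum to 1.
#' @param site_width site width in bp.
#' @param signal_fragments_mean mean fragment count per active site per
#'   replicate (Poisson).
#' @param fragment_length list with `mean`, `sd`, `min` of sampled fragment
#'   lengths in bp.
#' @param background_fragments uniform background fragments per replicate.
#' @param n_hotspots number of artifact hotspots.
#' @param hotspot_fragments_mean mean hotspot fragment count per replicate
#'   (Poisson), deposited regardless of site activity and shared with IgG.
#' @param n_replicates,n_igg number of treatment and IgG replicates.
#' @param depth_jitter multiplicative range of per-replicate efficiency
#'   applied to site signal.
#' @param seed integer master seed.
#' @return a named configuration list.
#' @export
syntheticConfig <- function(genome = makeGenome("chrS", 2e6),
                            n_sites = 200L,
                            probability_mixture = list(c(0.25, 0.8, 1.0),
                                                       c(0.75, 0.02, 0.3)),
                            site_width = 300L,
                            signal_fragments_mean = 40,
                            fragment_length = list(mean = 170, sd = 30, min = 50),
                            background_fragments = 50000L,
                            n_hotspots = 3L,
                            hotspot_fragments_mean = 60,
                            n_replicates = 25L,
                            n_igg = 10L,
                            depth_jitter = c(0.8, 1.2),
                            seed = 1234L) {
  w <- vapply(probability_mixture, `[`, numeric(1), 1)
  assertThat(abs(sum(w) - 1) < 1e-8, "mixture weights must sum to 1")
  for (comp in probability_mixture) {
    assertThat(length(comp) == 3L && comp[2] >= 0 && comp[3] <= 1 &&
                 comp[2] <= comp[3],
               "each mixture component is (weight, p_low, p_high) with 0 <= p_low <= p_high <= 1")
  }
  assertThat(n_sites >= 1 && site_width >= 1 && background_fragments >= 1 &&
               n_replicates >= 1 && n_igg >= 1,
             "counts must be positive")
  assertThat(depth_jitter[1] > 0 && depth_jitter[2] >= depth_jitter[1],
             "depth_jitter must be an increasing positive range")
  list(genome = genome, n_sites = as.integer(n_sites),
       probability_mixture = probability_mixture,
       site_width = as.integer(site_width),
       signal_fragments_mean = signal_fragments_mean,
       fragment_length = fragment_length,
       background_fragments = as.integer(background_fragments),
       n_hotspots = as.integer(n_hotspots),
       hotspot_fragments_mean = hotspot_fragments_mean,
       n_replicates = as.integer(n_replicates), n_igg = as.integer(n_igg),
       depth_jitter = depth_jitter, seed = as.integer(seed))
}

#' Generate the planted truth table
#'
#' Places `n_sites` binding sites and `n_hotspots` artifact hotspots
#' uniformly on the genome without mutual overlap (rejection sampling,
#' capped at 10000 tries per interval) and assigns each site an occupancy
#' probability drawn from the configured mixture and a signal strength
#' lambda. Deterministic given the config seed.
#'
#' @param config a [syntheticConfig()].
#' @return `GRanges` with metadata columns `probability`, `lambda` and
#'   `artifact` (hotspots flagged `TRUE`, probability and lambda `NA`).
#' @export
generateTruth <- function(config) {
  genome <- config$genome
  lens <- seqlengths(genome)
  total <- config$n_sites + config$n_hotspots
  w <- config$site_width
  withSeed(childSeed(config$seed, "truth"), {
    assertThat(all(lens >= w), "genome chromosome shorter than site width")
    chrP <- character(total)
    stP <- integer(total)
    for (i in seq_len(total)) {
      ok <- FALSE
      for (try in seq_len(10000L)) {
        chr <- sample(names(lens), 1L, prob = as.numeric(lens))
        st <- sample.int(lens[[chr]] - w + 1L, 1L)
        prev <- which(chrP[seq_len(i - 1L)] == chr)
        if (!length(prev) ||
            all(st + w - 1L < stP[prev] | st > stP[prev] + w - 1L)) {
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        stop("could not place ", total, " disjoint intervals; ",
             "use a larger genome or fewer sites", call. = FALSE)
      }
      chrP[i] <- chr
      stP[i] <- st
    }
    placed <- GRanges(chrP, IRanges(stP, width = w), seqinfo = genome)
    isSite <- c(rep(TRUE, config$n_sites), rep(FALSE, config$n_hotspots))
    weights <- vapply(config$probability_mixture, `[`, numeric(1), 1)
    compIdx <- sample.int(length(weights), config$n_sites, replace = TRUE,
                          prob = weights)
    pLo <- vapply(config$probability_mixture, `[`, numeric(1), 2)[compIdx]
    pHi <- vapply(config$probability_mixture, `[`, numeric(1), 3)[compIdx]
    prob <- runif(config$n_sites, pLo, pHi)
    probability <- rep(NA_real_, total)
    lambda <- rep(NA_real_, total)
    probability[isSite] <- prob
    lambda[isSite] <- config$signal_fragments_mean
    mcols(placed) <- DataFrame(probability = probability, lambda = lambda,
                               artifact = !isSite)
    sort(placed)
  })
}

# Sample `n` fragments centred near `centers` with jittered positions and
# lengths, clipped to the genome.
.sampleFragments <- function(centers, n, posSd, config, chrLen, chrom, genome) {
  if (n == 0) return(GRanges(seqinfo = genome))
  ctr <- round(rnorm(n, mean = centers, sd = posSd))
  len <- pmax(round(rnorm(n, config$fragment_length$mean,
                          config$fragment_length$sd)),
              config$fragment_length$min)
  st <- pmax(1, pmin(ctr - len %/% 2, chrLen - len + 1))
  en <- pmin(chrLen, st + len - 1)
  GRanges(chrom, IRanges(st, en), seqinfo = genome)
}

# Background + hotspot fragments common to treatment and IgG simulation;
# runs inside an already-seeded stream.
.simulateCommon <- function(truth, config) {
  genome <- config$genome
  lens <- seqlengths(genome)
  out <- list()
  # uniform background across chromosomes, proportional to length
  nBg <- config$background_fragments
  chrAssign <- sample(names(lens), nBg, replace = TRUE, prob = as.numeric(lens))
  for (chr in unique(chrAssign)) {
    n <- sum(chrAssign == chr)
    chrLen <- lens[[chr]]
    len <- pmax(round(rnorm(n, config$fragment_length$mean,
                            config$fragment_length$sd)),
                config$fragment_length$min)
    st <- pmax(1, pmin(round(runif(n, 1, chrLen)), chrLen - len + 1))
    en <- pmin(chrLen, st + len - 1)
    out[[length(out) + 1L]] <- GRanges(chr, IRanges(st, en), seqinfo = genome)
  }
  hot <- truth[mcols(truth)$artifact]
  for (i in seq_along(hot)) {
    n <- rpois(1L, config$hotspot_fragments_mean)
    chr <- as.character(seqnames(hot[i]))
    out[[length(out) + 1L]] <- .sampleFragments(
      rep((start(hot[i]) + end(hot[i])) %/% 2, n), n,
      posSd = config$site_width / 4, config, lens[[chr]], chr, genome)
  }
  do.call(c, out)
}

#' Simulate one treatment replicate
#'
#' Each planted site is active in this replicate with its occupancy
#' probability, independently across replicates; an active site emits
#' Poisson-distributed fragments (rate `lambda * depth jitter`) centred on
#' the site with positional jitter sd `site_width / 4` and sampled fragment
#' lengths. Uniform background and hotspot fragments are added on top. All
#' draws come from a child-seeded stream keyed by the replicate index.
#'
#' @param truth output of [generateTruth()].
#' @param config the matching [syntheticConfig()].
#' @param replicate_index integer replicate number.
#' @return a [FragmentSet] labelled `rep<index>`.
#' @export
simulateReplicate <- function(truth, config, replicate_index) {
  genome <- config$genome
  lens <- seqlengths(genome)
  withSeed(childSeed(config$seed, "replicate", replicate_index), {
    jitter <- runif(1, config$depth_jitter[1], config$depth_jitter[2])
    sites <- truth[!mcols(truth)$artifact]
    active <- rbinom(length(sites), 1L, mcols(sites)$probability) == 1L
    parts <- list()
    for (i in which(active)) {
      n <- rpois(1L, mcols(sites)$lambda[i] * jitter)
      chr <- as.character(seqnames(sites[i]))
      parts[[length(parts) + 1L]] <- .sampleFragments(
        rep((start(sites[i]) + end(sites[i])) %/% 2, n), n,
        posSd = config$site_width / 4, config, lens[[chr]], chr, genome)
    }
    parts[[length(parts) + 1L]] <- .simulateCommon(truth, config)
    FragmentSet(do.call(c, parts), target = "synthetic",
                replicateId = paste0("rep", replicate_index))
  })
}

#' Simulate one IgG control replicate
#'
#' Background and hotspot fragments only - no site signal - with the same
#' generative parameters as the treatment background, from a child-seeded
#' stream keyed by the control index.
#'
#' @inheritParams simulateReplicate
#' @param igg_index integer control number.
#' @return a [FragmentSet] labelled `igg<index>`.
#' @export
simulateControl <- function(truth, config, igg_index) {
  withSeed(childSeed(config$seed, "igg", igg_index), {
    FragmentSet(.simulateCommon(truth, config), target = "IgG",
                replicateId = paste0("igg", igg_index))
  })
}

#' Simulate a full multi-replicate experiment
#'
#' Convenience wrapper generating the truth table, all treatment replicates
#' and all IgG controls of a configuration.
#'
#' @param config a [syntheticConfig()].
#' @return list with `truth`, `replicates` (list of [FragmentSet]) and
#'   `igg` (list of [FragmentSet]).
#' @export
simulateExperiment <- function(config = syntheticConfig()) {
  truth <- generateTruth(config)
  list(truth = truth,
       replicates = lapply(seq_len(config$n_replicates), function(i)
         simulateReplicate(truth, config, i)),
       igg = lapply(seq_len(config$n_igg), function(i)
         simulateControl(truth, config, i)))
}
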