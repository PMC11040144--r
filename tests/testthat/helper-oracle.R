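# Per-base boolean-array oracle for the interval algebra, plus small
# fixture constructors. The oracle works on a single chromosome of known
# length, representing coverage as a logical vector over positions 1..L.

library(GenomicRanges)

# GRanges on one chromosome from 0-based half-open (start0, end) rows.
gr0 <- function(starts0, ends, chrom = "c", genome = NULL) {
  GRanges(chrom, IRanges(starts0 + 1, ends),
          seqinfo = if (is.null(genome)) NULL else genome)
}

# Coverage of a single-chromosome GRanges as a logical vector over 1..L.
ora_bool <- function(gr, L) {
  v <- logical(L)
  for (i in seq_along(gr)) v[start(gr)[i]:end(gr)[i]] <- TRUE
  v
}

# Runs of TRUE as a two-column matrix of (start, end), 1-based closed.
ora_runs <- function(v) {
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

# Merge with gap: fill FALSE runs of length <= gap flanked by TRUE.
ora_merge <- function(gr, L, gap = 0L) {
  v <- ora_bool(gr, L)
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  fill <- !r$values & r$lengths <= gap &
    seq_along(r$values) > 1 & seq_along(r$values) < length(r$values)
  for (i in which(fill)) v[starts[i]:ends[i]] <- TRUE
  ora_runs(v)
}

# Regions covered by at least x of the sets (book-ended runs fuse naturally).
ora_at_least <- function(sets, L, x) {
  cov <- Reduce(`+`, lapply(sets, function(g) as.integer(ora_bool(g, L))))
  ora_runs(cov >= x)
}

# Which intervals of `a` share >= 1 base with the coverage of `b`.
ora_hits <- function(a, b, L) {
  vb <- ora_bool(b, L)
  vapply(seq_along(a), function(i) any(vb[start(a)[i]:end(a)[i]]), logical(1))
}

# GRanges -> (start, end) matrix for comparison against oracle runs.
runs_of <- function(gr) {
  m <- cbind(start = start(gr), end = end(gr))
  m[order(m[, 1]), , drop = FALSE]
}

expect_same_runs <- function(gr, oracle_runs) {
  if (nrow(oracle_runs) == 0) {
    expect_length(gr, 0)
  } else {
    expect_equal(unname(runs_of(gr)), unname(oracle_runs))
  }
}

# Random single-chromosome instance for property tests.
random_sets <- function(k, L, max_iv = 50L, max_w = 400L) {
  lapply(seq_len(k), function(i) {
    n <- sample.int(max_iv, 1L)
    st <- sample.int(L - 1L, n, replace = TRUE)
    w <- sample.int(max_w, n, replace = TRUE)
    sort(GRanges("c", IRanges(st, width = pmin(w, L - st + 1L))))
  })
}

frag_set <- function(starts0, ends, id = "rep1", target = "toy") {
  FragmentSet(gr0(starts0, ends), target = target, replicateId = id)
}
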