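#' @import methods
#' @importFrom stats ppois rbinom rnorm rpois runif sd lm coef fitted cor setNames
#' @importFrom utils head combn
#' @importFrom data.table data.table fread fwrite
NULL

.datatable.aware <- TRUE

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG state afterwards. Keeps every stochastic operation in the package
# insulated from the global stream.
withSeed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

#' Derive a child seed from a parent seed and a label
#'
#' Deterministic, platform-stable derivation of per-task seeds from one global
#' seed. Each (label, index) pair gets its own reproducible RNG stream, so
#' adding or reordering stages never perturbs the randomness of another stage.
#'
#' The label parts are hashed with a 31-multiplier polynomial rolling hash over
#' UTF-8 bytes, reduced modulo a prime below 2^31 and mixed with the parent
#' seed. Pure integer-exact double arithmetic; identical on all platforms.
#'
#' @param seed integer parent seed.
#' @param ... character or numeric label parts identifying the task
#'   (e.g. replicate id, split index, purpose string).
#' @return A single integer in `[0, 2^31 - 2]`, usable with [set.seed()].
#' @examples
#' childSeed(1L, "replicate", 3)
#' @export
childSeed <- function(seed, ...) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  parts <- paste(vapply(list(...), function(p) paste(as.character(p), collapse = ","),
                        character(1)), collapse = "/")
  mod <- 2147483629 # prime < 2^31; 31 * mod < 2^53 so doubles stay exact
  h <- 0
  for (b in utf8ToInt(parts)) h <- (h * 31 + b) %% mod
  as.integer((h + as.double(seed) %% mod) %% mod)
}

# Internal validation helper: stop with the calling function's message.
assertThat <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)
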