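#' Read a chromosome-sizes table into a Seqinfo genome model
#'
#' Parses a two-column tab-separated file (`name<TAB>length`) into a
#' [GenomeInfoDb::Seqinfo] object. Chromosome order follows order of
#' appearance in the file and is stable for the whole run; lengths must be
#' positive and names unique.
#'
#' @param path path to a chrom.sizes file.
#' @return a `Seqinfo`.
#' @examples
#' tf <- tempfile()
#' writeLines(c("chr1\t2000000", "chr2\t500000"), tf)
#' readGenome(tf)
#' @export
readGenome <- function(path) {
  assertThat(file.exists(path), paste0("genome file not found: ", path))
  tab <- data.table::fread(path, header = FALSE, sep = "\t",
                           col.names = c("name", "length"),
                           colClasses = list(character = 1), select = 1:2)
  makeGenome(tab$name, tab$length)
}

#' Construct a genome model from names and lengths
#'
#' @param names character vector of unique chromosome names.
#' @param lengths positive integer chromosome lengths in bp.
#' @return a `Seqinfo`.
#' @examples
#' makeGenome("chr1", 2e6)
#' @export
makeGenome <- function(names, lengths) {
  assertThat(length(names) == length(lengths) && length(names) > 0,
             "names and lengths must be non-empty and parallel")
  assertThat(!anyDuplicated(names), "chromosome names must be unique")
  lengths <- as.numeric(lengths)
  assertThat(all(is.finite(lengths) & lengths > 0 & lengths == floor(lengths)),
             "chromosome lengths must be positive integers")
  Seqinfo(seqnames = as.character(names), seqlengths = as.integer(lengths))
}
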