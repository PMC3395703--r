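#' Derive a reproducible sub-seed from a global seed and labels
#'
#' Stable string hashing (polynomial rolling hash mod 2^31 - 1) so that each
#' pipeline stage and library gets an independent but reproducible RNG stream
#' from a single global seed.
#'
#' @param seed integer global seed.
#' @param ... character labels (stage name, library id, ...).
#' @return a single integer in [1, 2^31 - 2].
#' @export
deriveSeed <- function(seed, ...) {
  labels <- paste(c(as.character(seed), unlist(list(...))), collapse = "/")
  h <- 7
  m <- 2147483647
  for (v in utf8ToInt(labels)) h <- (h * 131 + v) %% m
  as.integer(h %% (m - 2L) + 1L)
}

# Evaluate expr with a local RNG seeded at `seed`, restoring the caller's
# RNG state afterwards.
withSeed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

phred_to_char <- function(q) {
  intToUtf8(pmin(pmax(q, 0L), 93L) + 33L)
}

char_to_phred <- function(s) {
  utf8ToInt(s) - 33L
}

#' Write a PyroReadSet as Sanger FASTQ
#'
#' @param reads a [PyroReadSet-class]
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
writeFastq <- function(reads, path) {
  qchars <- vapply(as.list(readQualities(reads)), phred_to_char, "")
  qual <- Biostrings::PhredQuality(qchars)
  Biostrings::writeXStringSet(readSequences(reads), path, format = "fastq",
                              qualities = Biostrings::BStringSet(qual))
  invisible(path)
}

#' Read a FASTQ file into a PyroReadSet
#'
#' @param path FASTQ file (Sanger Phred+33).
#' @param libraryId library label to attach to all reads.
#' @return a [PyroReadSet-class]; orientation and taxon labels are NA.
#' @export
readFastqLibrary <- function(path, libraryId = NA_character_) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  quals <- lapply(as.character(S4Vectors::mcols(x)$qualities), char_to_phred)
  pyroReadSet(x, quals, libraryId = libraryId)
}
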