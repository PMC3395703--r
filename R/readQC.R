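#' Quality-control parameters
#'
#' Thresholds for read trimming and filtering. Defaults follow the workflow
#' this package models: reads shorter than 250 bp after trimming are excluded
#' (boundary inclusive: a 250 bp read is retained), the sequencing primer must
#' match exactly (IUPAC-aware) at its expected position, MIDs must match
#' exactly, and 3' confidence trimming uses a sliding window of 10 bases with
#' mean Phred >= 20.
#'
#' @param minLengthBp minimum post-trim read length (primer included, MID
#'   stripped); default 250.
#' @param trimWindow sliding window size for confidence trimming; default 10.
#' @param trimMeanPhred minimum window mean Phred; default 20.
#' @param midMismatches mismatches allowed when matching MID prefixes; default 0.
#' @param primerMismatches mismatches allowed in the primer check; default 0.
#' @return a list of class \code{QCParams}.
#' @export
qcParams <- function(minLengthBp = 250L, trimWindow = 10L, trimMeanPhred = 20,
                     midMismatches = 0L, primerMismatches = 0L) {
  if (minLengthBp <= 0) stop("minLengthBp must be positive")
  structure(list(minLengthBp = as.integer(minLengthBp),
                 trimWindow = as.integer(trimWindow),
                 trimMeanPhred = trimMeanPhred,
                 midMismatches = as.integer(midMismatches),
                 primerMismatches = as.integer(primerMismatches)),
            class = "QCParams")
}

# Hamming distance between two equal-length strings, IUPAC-aware on `pattern`.
iupac_mismatches <- function(pattern, subject) {
  Biostrings::neditStartingAt(Biostrings::DNAString(pattern),
                              Biostrings::DNAString(subject),
                              starting.at = 1L, fixed = "subject")
}

#' Locate a degenerate primer in a read
#'
#' IUPAC-aware search (M matches A or C, K matches G or T, ...) for the
#' leftmost occurrence of \code{primer} in \code{sequence} with at most
#' \code{allowedMismatches} mismatches.
#'
#' @param sequence DNA string to search.
#' @param primer IUPAC primer string.
#' @param allowedMismatches maximum mismatches (default 0).
#' @return 1-based start position of the leftmost qualifying match, or
#'   \code{NA_integer_} if none.
#' @export
matchPrimer <- function(sequence, primer, allowedMismatches = 0L) {
  if (nchar(sequence) < nchar(primer)) return(NA_integer_)
  m <- Biostrings::matchPattern(Biostrings::DNAString(toupper(primer)),
                                Biostrings::DNAString(toupper(sequence)),
                                max.mismatch = allowedMismatches,
                                fixed = "subject")
  if (length(m) == 0L) NA_integer_ else min(Biostrings::start(m))
}

# Does `primer` match `sequence` starting at position 1?
primer_at_start <- function(sequence, primer, allowed = 0L) {
  if (nchar(sequence) < nchar(primer)) return(FALSE)
  iupac_mismatches(primer, substr(sequence, 1L, nchar(primer))) <= allowed
}

#' Demultiplex reads by MID barcode
#'
#' Assigns each read to the unique library whose MID matches the read prefix
#' within \code{midMismatches}; reads matching no MID, or more than one
#' (ambiguous), are left unassigned. The MID is stripped from assigned reads.
#'
#' @param reads a [PyroReadSet-class].
#' @param mapping data.frame with columns \code{libraryId} and \code{mid};
#'   MIDs must be distinct.
#' @param params a [qcParams()] list.
#' @return list with \code{libraries} (named list of [PyroReadSet-class], one
#'   per library that received reads) and \code{unassigned} (count).
#' @export
demultiplexReads <- function(reads, mapping, params = qcParams()) {
  if (anyDuplicated(mapping$mid)) stop("duplicate MID in mapping")
  seqs <- as.character(readSequences(reads))
  mids <- as.character(mapping$mid)
  hits <- sapply(mids, function(m) {
    pre <- substr(seqs, 1L, nchar(m))
    if (params$midMismatches == 0L) pre == m
    else nchar(pre) == nchar(m) &
      vapply(pre, function(p) {
        sum(strsplit(p, "")[[1]] != strsplit(m, "")[[1]])
      }, 1L) <= params$midMismatches
  })
  hits <- matrix(hits, nrow = length(seqs))
  nhit <- rowSums(hits)
  assigned_lib <- ifelse(nhit == 1L, mapping$libraryId[max.col(hits, "first")],
                         NA_character_)
  libraries <- list()
  for (lib in unique(mapping$libraryId)) {
    idx <- which(!is.na(assigned_lib) & assigned_lib == lib)
    if (!length(idx)) next
    sub <- reads[idx]
    midlen <- nchar(mapping$mid[match(lib, mapping$libraryId)])
    sub@sequences <- Biostrings::subseq(sub@sequences, start = midlen + 1L)
    sub@qualities <- IntegerList(lapply(as.list(sub@qualities),
                                        function(q) q[-seq_len(midlen)]))
    sub@readInfo$libraryId <- lib
    sub@readInfo$mid <- mapping$mid[match(lib, mapping$libraryId)]
    libraries[[lib]] <- sub
  }
  list(libraries = libraries, unassigned = sum(nhit != 1L))
}

# 3' trim point for one quality vector: keep through the end of the last
# sliding window whose mean Phred >= threshold; 0 if no window qualifies.
trim_point <- function(q, window, threshold) {
  n <- length(q)
  if (n == 0L) return(0L)
  if (n <= window) return(if (mean(q) >= threshold) n else 0L)
  cs <- cumsum(as.numeric(q))
  means <- (cs[window:n] - c(0, cs)[1:(n - window + 1L)]) / window
  ok <- which(means >= threshold)
  if (!length(ok)) 0L else min(max(ok) + window - 1L, n)
}

#' Confidence-trim reads at the 3' end
#'
#' Sliding-window quality trimming: each read is truncated at the end of the
#' last window (size \code{trimWindow}) whose mean Phred is at least
#' \code{trimMeanPhred}. Trimming never lengthens a read and is idempotent.
#'
#' @param reads a [PyroReadSet-class].
#' @param params a [qcParams()] list.
#' @return trimmed [PyroReadSet-class]; zero-length reads are kept (they are
#'   removed later by the length filter).
#' @export
trimReads <- function(reads, params = qcParams()) {
  quals <- as.list(readQualities(reads))
  keep_to <- vapply(quals, trim_point, 1L,
                    window = params$trimWindow,
                    threshold = params$trimMeanPhred)
  reads@sequences <- Biostrings::subseq(reads@sequences, start = 1L,
                                        width = keep_to)
  reads@qualities <- IntegerList(mapply(function(q, k) q[seq_len(k)],
                                        quals, keep_to, SIMPLIFY = FALSE))
  reads
}

#' Filter trimmed reads on primer correctness and length
#'
#' A read is retained iff a sequencing primer (forward or reverse) matches at
#' its expected position (the read start, after MID removal) within
#' \code{primerMismatches}, and its post-trim length (primer included) is at
#' least \code{minLengthBp}. Retained reads get their orientation set from the
#' matching primer. The rejection tally partitions all rejected reads: the
#' primer check is applied first, then the length cut.
#'
#' @param reads trimmed [PyroReadSet-class].
#' @param params a [qcParams()] list.
#' @param primers primer pair, see [defaultPrimers()].
#' @return list with \code{retained} ([PyroReadSet-class]) and \code{tally}
#'   (named integer: retained, primer, length).
#' @export
filterReads <- function(reads, params = qcParams(), primers = defaultPrimers()) {
  seqs <- as.character(readSequences(reads))
  fwd_ok <- vapply(seqs, primer_at_start, TRUE,
                   primer = primers$forward, allowed = params$primerMismatches)
  rev_ok <- !fwd_ok & vapply(seqs, primer_at_start, TRUE,
                             primer = primers$reverse,
                             allowed = params$primerMismatches)
  has_primer <- fwd_ok | rev_ok
  long_enough <- nchar(seqs) >= params$minLengthBp
  keep <- has_primer & long_enough
  tally <- c(retained = sum(keep),
             primer = sum(!has_primer),
             length = sum(has_primer & !long_enough))
  retained <- reads[keep]
  retained@readInfo$orientation <- unname(ifelse(fwd_ok[keep], "forward",
                                                 "reverse"))
  list(retained = retained, tally = tally)
}

#' Run the full QC chain on a raw multiplexed read set
#'
#' Demultiplex, trim, and filter; convenience wrapper returning per-library
#' retained reads plus a QC report.
#'
#' @param reads raw [PyroReadSet-class] (MIDs still attached).
#' @param mapping library-to-MID data.frame.
#' @param params a [qcParams()] list.
#' @param primers primer pair.
#' @return list with \code{libraries} (named list of retained
#'   [PyroReadSet-class]) and \code{report} (data.frame of per-library tallies
#'   plus the unassigned count as attribute \code{unassigned}).
#' @export
runQC <- function(reads, mapping, params = qcParams(),
                  primers = defaultPrimers()) {
  dm <- demultiplexReads(reads, mapping, params)
  out <- list()
  rows <- list()
  for (lib in names(dm$libraries)) {
    trimmed <- trimReads(dm$libraries[[lib]], params)
    fl <- filterReads(trimmed, params, primers)
    out[[lib]] <- fl$retained
    rows[[lib]] <- data.frame(libraryId = lib, input = length(trimmed),
                              t(fl$tally))
  }
  report <- do.call(rbind, rows)
  attr(report, "unassigned") <- dm$unassigned
  list(libraries = out, report = report)
}

#' Orient reads to the forward strand
#'
#' Reverse reads are reverse-complemented (qualities reversed) so that all
#' reads run 5'-3' on the template's forward strand; required before assembly,
#' clustering and classification. For forward-oriented output the forward
#' reads start at the forward primer while former reverse reads end at the
#' (reverse-complemented) reverse primer site.
#'
#' @param reads [PyroReadSet-class] with orientation set (post QC).
#' @return [PyroReadSet-class] on the forward strand.
#' @export
orientReads <- function(reads) {
  ori <- readInfo(reads)$orientation
  if (anyNA(ori)) stop("orientation not set; run filterReads first")
  rev_idx <- which(ori == "reverse")
  if (length(rev_idx)) {
    reads@sequences[rev_idx] <-
      Biostrings::reverseComplement(reads@sequences[rev_idx])
    reads@qualities[rev_idx] <-
      IntegerList(lapply(as.list(reads@qualities[rev_idx]), rev))
  }
  reads
}
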