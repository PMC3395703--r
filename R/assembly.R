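#' Assembly parameters
#'
#' Thresholds for greedy contig assembly: a read joins a contig only when it
#' overlaps the current consensus by at least \code{minOverlapBp} at a gapped
#' identity of at least \code{minIdentity}; contigs with fewer than
#' \code{minReadsPerContig} reads, or lacking at least one forward and one
#' reverse read, are excluded afterwards.
#'
#' @param minIdentity minimum overlap identity (default 0.98).
#' @param minOverlapBp minimum overlap length in bp (default 50).
#' @param minReadsPerContig minimum member reads for a retained contig
#'   (default 20).
#' @param requireBothOrientations require >= 1 forward and >= 1 reverse read
#'   (default TRUE).
#' @return list of class \code{AssemblyParams}.
#' @export
assemblyParams <- function(minIdentity = 0.98, minOverlapBp = 50L,
                           minReadsPerContig = 20L,
                           requireBothOrientations = TRUE) {
  if (minIdentity <= 0 || minIdentity > 1) stop("minIdentity must be in (0, 1]")
  if (minOverlapBp < 1) stop("minOverlapBp must be >= 1")
  structure(list(minIdentity = minIdentity,
                 minOverlapBp = as.integer(minOverlapBp),
                 minReadsPerContig = as.integer(minReadsPerContig),
                 requireBothOrientations = requireBothOrientations),
            class = "AssemblyParams")
}

.cache <- new.env(parent = emptyenv())

overlap_subst_matrix <- function() {
  if (is.null(.cache$subst))
    .cache$subst <- Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -2)
  .cache$subst
}

overlap_align <- function(a, b) {
  Biostrings::pairwiseAlignment(a, b, type = "overlap",
                                substitutionMatrix = overlap_subst_matrix(),
                                gapOpening = 4, gapExtension = 2)
}

#' Best semi-global overlap between two sequences
#'
#' Aligns two forward-strand sequences end-gap-free (semi-global) and reports
#' the aligned overlap length (alignment columns, internal gaps included) and
#' its identity, defined as matches divided by aligned columns so that
#' internal gaps count as mismatches.
#'
#' @param a,b DNA strings (character or \code{DNAString}); reverse reads must
#'   already be on the forward strand.
#' @return list with \code{overlap} (integer columns) and \code{identity}
#'   (fraction).
#' @export
overlapIdentity <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  if (!nchar(a) || !nchar(b)) stop("sequences must be non-empty")
  aln <- overlap_align(a, b)
  cols <- Biostrings::nchar(aln)
  if (cols == 0L) return(list(overlap = 0L, identity = 0))
  list(overlap = as.integer(cols),
       identity = Biostrings::nmatch(aln) / cols)
}

# --- consensus bookkeeping -------------------------------------------------
# A contig under construction is a 5 x L count matrix (rows A,C,G,T,-) plus a
# parallel quality-sum matrix; the consensus string is the per-column majority
# base with ties broken by summed quality, then alphabetically; columns where
# the gap row wins strictly are dropped from the consensus.

BASE_ROWS <- c("A", "C", "G", "T", "-")

new_contig_state <- function(seq, qual, read_id, orientation) {
  ch <- strsplit(seq, "")[[1]]
  L <- length(ch)
  counts <- matrix(0L, nrow = 5L, ncol = L, dimnames = list(BASE_ROWS, NULL))
  qsum <- matrix(0, nrow = 5L, ncol = L, dimnames = list(BASE_ROWS, NULL))
  idx <- cbind(match(ch, BASE_ROWS), seq_len(L))
  counts[idx] <- 1L
  qsum[idx] <- qual
  list(counts = counts, qsum = qsum, consensus = seq,
       members = read_id, forward = orientation == "forward")
}

# Majority base per column; ties -> higher summed quality -> alphabetical
# (A<C<G<T, gap last). Encoded as one score so max.col("first") applies the
# whole tie-break chain: count dominates, then quality sum (< 2^20 scaled).
column_picks <- function(state) {
  score <- t(state$counts) * 2^20 + t(pmin(state$qsum, 2^20 - 1))
  max.col(score, ties.method = "first")
}

consensus_from_state <- function(state) {
  pick <- column_picks(state)
  keep <- pick != 5L
  paste(BASE_ROWS[pick[keep]], collapse = "")
}

# Column index in the count matrix for each consensus position (gap-majority
# columns are skipped in the consensus string but kept in the matrices).
consensus_columns <- function(state) {
  which(column_picks(state) != 5L)
}

# Merge a read into the contig state given its alignment to the current
# consensus. Read insertions relative to the consensus are dropped; deletions
# are counted in the gap row; overhangs extend the matrices.
merge_read <- function(state, seq, qual, read_id, orientation, aln) {
  cons_cols <- consensus_columns(state)
  p <- Biostrings::pattern(aln)   # aligned range in the read
  s <- Biostrings::subject(aln)   # aligned range in the consensus
  ps <- Biostrings::start(p); pe <- Biostrings::end(p)
  ss <- Biostrings::start(s); se <- Biostrings::end(s)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ch <- strsplit(seq, "")[[1]]
  L <- length(ch)

  # aligned region: map read chars onto matrix columns
  col_of <- cons_cols[ss - 1L + cumsum(sa != "-")]
  in_cols <- sa != "-"
  cols <- col_of[in_cols]
  bases <- pa[in_cols]
  read_pos <- ps - 1L + cumsum(pa != "-")
  rq <- ifelse(pa[in_cols] == "-", mean(qual), qual[read_pos[in_cols]])
  idx <- cbind(match(bases, BASE_ROWS), cols)
  state$counts[idx] <- state$counts[idx] + 1L
  state$qsum[idx] <- state$qsum[idx] + rq

  # right overhang: read extends past the consensus end
  if (pe < L && (ss - 1L + sum(sa != "-")) == length(cons_cols)) {
    ext <- ch[(pe + 1L):L]
    extq <- qual[(pe + 1L):L]
    ne <- length(ext)
    add_counts <- matrix(0L, 5L, ne, dimnames = list(BASE_ROWS, NULL))
    add_q <- matrix(0, 5L, ne, dimnames = list(BASE_ROWS, NULL))
    eidx <- cbind(match(ext, BASE_ROWS), seq_len(ne))
    add_counts[eidx] <- 1L
    add_q[eidx] <- extq
    state$counts <- cbind(state$counts, add_counts)
    state$qsum <- cbind(state$qsum, add_q)
  }
  # left overhang: read extends before the consensus start
  if (ps > 1L && ss == 1L) {
    ext <- ch[1:(ps - 1L)]
    extq <- qual[1:(ps - 1L)]
    ne <- length(ext)
    add_counts <- matrix(0L, 5L, ne, dimnames = list(BASE_ROWS, NULL))
    add_q <- matrix(0, 5L, ne, dimnames = list(BASE_ROWS, NULL))
    eidx <- cbind(match(ext, BASE_ROWS), seq_len(ne))
    add_counts[eidx] <- 1L
    add_q[eidx] <- extq
    state$counts <- cbind(add_counts, state$counts)
    state$qsum <- cbind(add_q, state$qsum)
  }
  state$members <- c(state$members, read_id)
  state$forward <- c(state$forward, orientation == "forward")
  state$consensus <- consensus_from_state(state)
  state
}

#' Greedy consensus assembly of oriented reads
#'
#' Seeds contigs with the longest unplaced read, then scans the remaining
#' reads in descending length order (ties broken by read id) and joins a read
#' to the open contig whenever its semi-global overlap with the current
#' consensus spans at least \code{minOverlapBp} columns at identity at least
#' \code{minIdentity}. The consensus is recomputed by per-column majority vote
#' after every merge (ties resolved by summed base quality, then
#' alphabetically). Contigs are built in a single pass, without re-merging.
#' Reads that end up alone remain in the unassembled pool, so every input
#' read is in exactly one contig or unassembled. Deterministic.
#'
#' @param reads forward-oriented [PyroReadSet-class] (see [orientReads()]).
#' @param params an [assemblyParams()] list.
#' @return list with \code{contigs} (a [ContigSet-class]) and
#'   \code{unassembled} (character read ids).
#' @export
assembleContigs <- function(reads, params = assemblyParams()) {
  n <- length(reads)
  if (n == 0L)
    return(list(contigs = emptyContigSet(), unassembled = character()))
  seqs <- as.character(readSequences(reads))
  quals <- as.list(readQualities(reads))
  ori <- readInfo(reads)$orientation
  ids <- names(reads)
  ord <- order(-nchar(seqs), ids)
  placed <- logical(n)
  states <- list()
  for (si in ord) {
    if (placed[si]) next
    placed[si] <- TRUE
    state <- new_contig_state(seqs[si], quals[[si]], ids[si], ori[si])
    for (ri in ord) {
      if (placed[ri]) next
      aln <- overlap_align(seqs[ri], state$consensus)
      cols <- Biostrings::nchar(aln)
      if (cols < params$minOverlapBp) next
      if (Biostrings::nmatch(aln) / cols < params$minIdentity) next
      placed[ri] <- TRUE
      state <- merge_read(state, seqs[ri], quals[[ri]], ids[ri], ori[ri], aln)
    }
    states[[length(states) + 1L]] <- state
  }
  multi <- vapply(states, function(s) length(s$members) > 1L, TRUE)
  unassembled <- unlist(lapply(states[!multi], `[[`, "members"))
  states <- states[multi]
  if (!length(states))
    return(list(contigs = emptyContigSet(),
                unassembled = as.character(unassembled)))
  cons <- vapply(states, `[[`, "", "consensus")
  names(cons) <- sprintf("contig%03d", seq_along(states))
  info <- DataFrame(
    nReads = vapply(states, function(s) length(s$members), 1L),
    nForward = vapply(states, function(s) sum(s$forward), 1L),
    nReverse = vapply(states, function(s) sum(!s$forward), 1L),
    row.names = names(cons)
  )
  members <- CharacterList(lapply(states, `[[`, "members"))
  names(members) <- names(cons)
  contigs <- new("ContigSet", consensus = Biostrings::DNAStringSet(cons),
                 contigInfo = info, members = members)
  list(contigs = contigs,
       unassembled = as.character(if (is.null(unassembled)) character()
                                  else unassembled))
}

emptyContigSet <- function() {
  new("ContigSet", consensus = Biostrings::DNAStringSet(),
      contigInfo = DataFrame(nReads = integer(), nForward = integer(),
                             nReverse = integer()),
      members = CharacterList())
}

#' Apply the read-support filter to assembled contigs
#'
#' Retains contigs with at least \code{minReadsPerContig} member reads and,
#' when \code{requireBothOrientations}, at least one forward and one reverse
#' read.
#'
#' @param contigs a [ContigSet-class].
#' @param params an [assemblyParams()] list.
#' @return the filtered [ContigSet-class].
#' @export
filterContigs <- function(contigs, params = assemblyParams()) {
  info <- contigInfo(contigs)
  keep <- info$nReads >= params$minReadsPerContig
  if (params$requireBothOrientations)
    keep <- keep & info$nForward >= 1L & info$nReverse >= 1L
  new("ContigSet", consensus = consensusSequences(contigs)[keep],
      contigInfo = info[keep, , drop = FALSE],
      members = contigMembers(contigs)[keep])
}
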