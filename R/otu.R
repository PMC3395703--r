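#' OTU clustering parameters
#'
#' @param otuIdentity sequence identity defining an OTU (default 0.97).
#' @param linkage hierarchical linkage: "complete" (default), "average" or
#'   "single".
#' @return list of class \code{ClusterParams}.
#' @export
clusterParams <- function(otuIdentity = 0.97,
                          linkage = c("complete", "average", "single")) {
  if (otuIdentity <= 0 || otuIdentity > 1) stop("otuIdentity must be in (0, 1]")
  structure(list(otuIdentity = otuIdentity, linkage = match.arg(linkage)),
            class = "ClusterParams")
}

# Pairwise distance = 1 - overlap identity, computed on the mutual overlap
# region (free end gaps) so length differences do not inflate distances.
pairwise_overlap_dist <- function(seqs) {
  n <- length(seqs)
  d <- matrix(0, n, n)
  if (n > 1L) {
    sset <- Biostrings::DNAStringSet(seqs)
    for (i in seq_len(n - 1L)) {
      alns <- Biostrings::pairwiseAlignment(
        sset[(i + 1L):n], sset[[i]], type = "overlap",
        substitutionMatrix = overlap_subst_matrix(),
        gapOpening = 4, gapExtension = 2)
      cols <- Biostrings::nchar(alns)
      id <- ifelse(cols > 0, Biostrings::nmatch(alns) / cols, 0)
      d[i, (i + 1L):n] <- d[(i + 1L):n, i] <- 1 - id
    }
  }
  d
}

#' Cluster reads into OTUs by linkage clustering
#'
#' Dereplicates identical sequences, computes pairwise distances as one minus
#' the gapped identity over the mutual overlap (end gaps free), performs
#' hierarchical clustering with the requested linkage and cuts the tree at
#' \code{1 - otuIdentity}, so that e.g. two reads at exactly 97% identity fall
#' in one OTU at the default threshold.
#'
#' @param reads a forward-oriented [PyroReadSet-class] or named character
#'   vector/\code{DNAStringSet} of sequences.
#' @param params a [clusterParams()] list.
#' @return list with \code{otu} (named integer vector: OTU index per read) and
#'   \code{sizes} (reads per OTU).
#' @export
clusterOTUs <- function(reads, params = clusterParams()) {
  nm <- if (is(reads, "PyroReadSet")) names(reads) else names(reads)
  seqs <- if (is(reads, "PyroReadSet")) as.character(readSequences(reads))
          else as.character(reads)
  names(seqs) <- nm
  if (!length(seqs)) stop("no reads to cluster")
  if (is.null(names(seqs))) names(seqs) <- sprintf("read%04d", seq_along(seqs))
  uniq <- unique(seqs)
  rep_of <- match(seqs, uniq)
  if (length(uniq) == 1L) {
    otu <- stats::setNames(rep(1L, length(seqs)), names(seqs))
  } else {
    d <- pairwise_overlap_dist(uniq)
    hc <- stats::hclust(stats::as.dist(d), method = params$linkage)
    grp <- stats::cutree(hc, h = 1 - params$otuIdentity + 1e-12)
    otu <- stats::setNames(as.integer(grp[rep_of]), names(seqs))
  }
  list(otu = otu, sizes = as.integer(table(otu)))
}

#' Fraction of singleton OTUs
#'
#' The fraction of OTUs represented by exactly one read in a library; the
#' workflow this package models reports 45 +/- 5% singletons per library.
#'
#' @param partition result of [clusterOTUs()] (or an integer vector of OTU
#'   sizes).
#' @return fraction in [0, 1].
#' @export
singletonFraction <- function(partition) {
  sizes <- if (is.list(partition)) partition$sizes else as.integer(partition)
  if (!length(sizes)) stop("empty OTU partition")
  mean(sizes == 1L)
}

# ---- naive-Bayes k-mer classifier -----------------------------------------

#' Classifier parameters
#'
#' @param kmerSize word size (default 8).
#' @param nBootstrap bootstrap resamples (default 100); each resample draws
#'   one eighth of the read's words.
#' @param confidenceThreshold minimum bootstrap agreement to keep a rank
#'   (default 0.80).
#' @return list of class \code{ClassifierParams}.
#' @export
classifierParams <- function(kmerSize = 8L, nBootstrap = 100L,
                             confidenceThreshold = 0.80) {
  if (confidenceThreshold < 0)
    stop("confidenceThreshold must be non-negative")
  structure(list(kmerSize = as.integer(kmerSize),
                 nBootstrap = as.integer(nBootstrap),
                 confidenceThreshold = confidenceThreshold),
            class = "ClassifierParams")
}

# integer word indices (1-based, base-4) of all overlapping k-mers
kmer_indices <- function(seq, k) {
  b <- match(strsplit(seq, "")[[1]], c("A", "C", "G", "T")) - 1L
  n <- length(b)
  if (n < k || anyNA(b)) {
    if (anyNA(b)) b[is.na(b)] <- 0L  # tolerate stray ambiguity codes
    if (n < k) return(integer())
  }
  idx <- b[1:(n - k + 1L)]
  for (j in 2:k) idx <- idx * 4L + b[j:(n - k + j)]
  idx + 1L
}

#' Train the bootstrap naive-Bayes k-mer classifier
#'
#' RDP-style training on a labelled reference set: for each genus the
#' conditional word probability is \code{(m + Pw) / (M + 1)}, where \code{m}
#' is the number of the genus' reference sequences containing the word,
#' \code{M} the genus' sequence count, and \code{Pw = (n + 0.5) / (N + 1)} the
#' word prior over all \code{N} reference sequences.
#'
#' @param reference a [MockCommunity-class] (sequences + lineages) used as the
#'   training set.
#' @param params a [classifierParams()] list.
#' @return a classifier object (list) for [classifyReads()].
#' @export
trainClassifier <- function(reference, params = classifierParams()) {
  if (length(reference) == 0L) stop("empty reference set")
  k <- params$kmerSize
  tx <- taxonomy(reference)
  genera <- unique(tx$genus)
  G <- length(genera)
  nw <- 4L^k
  seqs <- as.character(refSequences(reference))
  words <- lapply(seqs, kmer_indices, k = k)
  N <- length(seqs)
  prior_counts <- integer(nw)
  for (w in words) {
    uw <- unique(w)
    prior_counts[uw] <- prior_counts[uw] + 1L
  }
  Pw <- (prior_counts + 0.5) / (N + 1)
  W <- matrix(0, nrow = G, ncol = nw)
  for (g in seq_len(G)) {
    gi <- which(tx$genus == genera[g])
    M <- length(gi)
    m <- integer(nw)
    for (i in gi) {
      uw <- unique(words[[i]])
      m[uw] <- m[uw] + 1L
    }
    W[g, ] <- log((m + Pw) / (M + 1))
  }
  lineage <- as.data.frame(tx[match(genera, tx$genus), TAXONOMIC_RANKS])
  rownames(lineage) <- genera
  list(W = W, genera = genera, lineage = lineage, params = params)
}

#' Classify reads with bootstrap confidence
#'
#' Naive-Bayes classification over k-mer words with uniform genus priors: each
#' read is scored against every genus as the summed log word probability of
#' its overlapping words; \code{nBootstrap} resamples of one eighth of the
#' words estimate per-rank bootstrap agreement, and the assigned lineage is
#' truncated at the deepest rank whose agreement reaches the confidence
#' threshold. Reads failing at the domain rank are labelled
#' \code{"unclassified"}.
#'
#' @param reads forward-oriented [PyroReadSet-class], \code{DNAStringSet} or
#'   character vector.
#' @param classifier result of [trainClassifier()].
#' @return data.frame with one row per read: assignment and confidence at each
#'   rank (NA beyond the truncation point), plus \code{lineage} (semicolon
#'   string) and \code{depth} (deepest confident rank, or "unclassified").
#' @export
classifyReads <- function(reads, classifier) {
  seqs <- if (is(reads, "PyroReadSet")) as.character(readSequences(reads))
          else as.character(reads)
  p <- classifier$params
  W <- classifier$W
  lineage <- classifier$lineage
  G <- nrow(W)
  B <- p$nBootstrap
  ranks <- TAXONOMIC_RANKS
  rank_labels <- lapply(ranks, function(r) lineage[[r]])
  names(rank_labels) <- ranks
  n <- length(seqs)
  assign_mat <- matrix(NA_character_, n, length(ranks),
                       dimnames = list(names(seqs), ranks))
  conf_mat <- matrix(NA_real_, n, length(ranks))
  for (i in seq_len(n)) {
    wi <- kmer_indices(seqs[i], p$kmerSize)
    if (!length(wi)) next
    Wsub <- W[, wi, drop = FALSE]
    full <- rowSums(Wsub)
    winner <- which.max(full)
    m <- max(1L, length(wi) %/% 8L)
    samp <- sample.int(length(wi), m * B, replace = TRUE)
    tW <- t(Wsub)
    boot <- rowsum(tW[samp, , drop = FALSE], group = rep(seq_len(B), each = m))
    best <- max.col(boot, ties.method = "first")
    for (r in seq_along(ranks)) {
      lab <- rank_labels[[r]][winner]
      conf_mat[i, r] <- mean(rank_labels[[r]][best] == lab)
      assign_mat[i, r] <- lab
    }
  }
  # truncate at the deepest rank with agreement >= threshold
  out <- data.frame(read_id = if (is.null(names(seqs)))
                      sprintf("read%05d", seq_len(n)) else names(seqs),
                    stringsAsFactors = FALSE)
  for (r in seq_along(ranks)) {
    out[[ranks[r]]] <- assign_mat[, r]
    out[[paste0(ranks[r], "_conf")]] <- conf_mat[, r]
  }
  ok <- !is.na(conf_mat)
  pass <- ok & conf_mat >= p$confidenceThreshold
  depth <- apply(pass, 1L, function(z) {
    w <- which(z)
    # confident prefix only: deepest rank such that all shallower ranks pass
    d <- 0L
    for (j in seq_along(z)) { if (isTRUE(z[j])) d <- j else break }
    d
  })
  for (r in seq_along(ranks)) out[[ranks[r]]][depth < r] <- NA_character_
  out$depth <- ifelse(depth == 0L, "unclassified", ranks[pmax(depth, 1L)])
  out$lineage <- vapply(seq_len(n), function(i) {
    if (depth[i] == 0L) "unclassified"
    else paste(assign_mat[i, seq_len(depth[i])], collapse = ";")
  }, "")
  out
}

#' Tabulate read counts into an abundance table
#'
#' Aggregates per-library read assignments at a taxonomic rank (or per OTU)
#' into a taxon x library count matrix wrapped in a
#' \code{SummarizedExperiment} with assays \code{counts} and \code{relab}
#' (relative abundance in percent; columns sum to 100). Reads not resolved at
#' the requested rank are tallied as \code{"unclassified"}.
#'
#' @param labels character vector: the taxon (or OTU) label of each read; NA
#'   values are recoded as "unclassified".
#' @param libraryIds character vector parallel to \code{labels}.
#' @return a \code{SummarizedExperiment}.
#' @export
abundanceTable <- function(labels, libraryIds) {
  if (!length(labels)) stop("no reads to tabulate")
  if (length(labels) != length(libraryIds))
    stop("labels and libraryIds must be parallel")
  labels[is.na(labels)] <- "unclassified"
  counts <- as.matrix(table(labels, libraryIds))
  if (any(colSums(counts) == 0)) stop("empty library in tabulation")
  class(counts) <- "matrix"
  relab <- sweep(counts, 2, colSums(counts), "/") * 100
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts, relab = relab))
}

#' @rdname abundanceTable
#' @details \code{tabulateAbundance} is the rank-aware wrapper: it takes a
#'   [classifyReads()] result and aggregates at the requested rank.
#' @param assignments data.frame from [classifyReads()].
#' @param rank one of domain, phylum, class, order, family, genus.
#' @export
tabulateAbundance <- function(assignments, libraryIds,
                              rank = c("phylum", "domain", "class", "order",
                                       "family", "genus")) {
  rank <- match.arg(rank)
  abundanceTable(assignments[[rank]], libraryIds)
}

#' Relative-abundance assay accessor
#' @param se a \code{SummarizedExperiment} built by [abundanceTable()].
#' @return matrix of relative abundances (%).
#' @export
relAbundance <- function(se) SummarizedExperiment::assay(se, "relab")
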