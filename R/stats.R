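#' Shannon diversity of an abundance vector
#'
#' H' = -sum(p_i log p_i) in natural log units (nats) on renormalised
#' proportions; zero entries are dropped. Also reports richness (count of
#' positive entries). H' never exceeds log(richness), with equality iff the
#' community is uniform.
#'
#' @param abundances non-negative abundance vector (any scale).
#' @param base logarithm base; default \code{exp(1)} (nats).
#' @return list with \code{shannon} and \code{richness}.
#' @export
shannonIndex <- function(abundances, base = exp(1)) {
  if (any(abundances < 0)) stop("abundances must be non-negative")
  x <- abundances[abundances > 0]
  if (!length(x)) stop("all-zero abundance vector")
  p <- x / sum(x)
  list(shannon = as.numeric(vegan::diversity(p, index = "shannon", base = base)),
       richness = length(x))
}

#' Sorensen incidence similarity between two OTU sets
#'
#' 2|A n B| / (|A| + |B|) on presence/absence. Two empty sets return 0 with a
#' warning (the index is undefined there).
#'
#' @param setA,setB character vectors of OTU (or T-RF) labels.
#' @return similarity in [0, 1].
#' @export
sorensenIndex <- function(setA, setB) {
  a <- unique(setA); b <- unique(setB)
  if (!length(a) && !length(b)) {
    warning("both sets empty; Sorensen undefined, returning 0")
    return(0)
  }
  2 * length(intersect(a, b)) / (length(a) + length(b))
}

#' Pareto-Lorenz functional organisation (Fo)
#'
#' Ranks OTUs by decreasing abundance and reads the cumulative relative
#' abundance held by the most abundant 20% of OTUs off the Pareto-Lorenz
#' polyline, with linear interpolation when 20% of the OTU count is not an
#' integer. Fo is 0.2 for a perfectly even community and approaches 1 under
#' extreme dominance; values around 0.25, 0.45 and 0.80 indicate low, medium
#' and high functional organisation.
#'
#' @param abundances abundance vector (>= 2 positive entries; any scale —
#'   the statistic is scale-invariant).
#' @param topFraction ranked-OTU fraction at which the curve is read
#'   (default 0.20).
#' @return Fo as a fraction in [0, 1].
#' @export
paretoLorenzFo <- function(abundances, topFraction = 0.20) {
  x <- abundances[abundances > 0]
  if (length(x) < 2L) stop("need at least 2 OTUs with positive abundance")
  p <- sort(x / sum(x), decreasing = TRUE)
  n <- length(p)
  # Lorenz polyline through (i/n, cum_i), i = 0..n
  xs <- seq(0, n) / n
  ys <- c(0, cumsum(p))
  as.numeric(stats::approx(xs, ys, xout = topFraction)$y)
}

#' Across-replicate standard deviations by abundance class
#'
#' Computes the per-taxon sample standard deviation of relative abundance (in
#' percentage points) across replicate libraries, excludes taxa recovered at
#' fewer than one read on average over the libraries, assigns each taxon to an
#' abundance bin by its mean relative abundance, and summarises the mean and
#' maximum SD per bin. Default bins follow the >10% / <10% / <2% / <0.3%
#' convention (right-open).
#'
#' @param se \code{SummarizedExperiment} from [abundanceTable()] with
#'   replicate libraries as columns (>= 2).
#' @param binEdges increasing interior bin edges on the percent scale.
#' @return list with \code{perTaxon} (taxon, mean, sd, bin) and \code{perBin}
#'   (bin, nTaxa, meanSD, maxSD).
#' @export
replicateSD <- function(se, binEdges = c(0.3, 2, 10)) {
  counts <- SummarizedExperiment::assay(se, "counts")
  relab <- SummarizedExperiment::assay(se, "relab")
  if (ncol(relab) < 2L) stop("need at least 2 replicate columns")
  keep <- rowMeans(counts) >= 1
  relab <- relab[keep, , drop = FALSE]
  mean_ab <- rowMeans(relab)
  sd_ab <- apply(relab, 1, stats::sd)
  edges <- c(0, binEdges, Inf)
  labels <- c(paste0("<", binEdges, "%"), paste0(">", binEdges[length(binEdges)], "%"))
  bin <- cut(mean_ab, breaks = edges, labels = labels, right = FALSE)
  per_taxon <- data.frame(taxon = rownames(relab), meanAbundance = mean_ab,
                          sdAbundance = sd_ab, bin = as.character(bin),
                          row.names = NULL)
  per_bin <- do.call(rbind, lapply(labels, function(lb) {
    s <- per_taxon$sdAbundance[per_taxon$bin == lb]
    data.frame(bin = lb, nTaxa = length(s),
               meanSD = if (length(s)) mean(s) else NA_real_,
               maxSD = if (length(s)) max(s) else NA_real_)
  }))
  list(perTaxon = per_taxon, perBin = per_bin)
}

#' Spike-in recovery regression
#'
#' Computes recovered spike percentages (100 x spike reads / total reads) per
#' library, per-amendment-level mean and SD, and an ordinary least squares fit
#' of the recovered fraction on the nominal amendment fraction over all
#' libraries (zero-amendment libraries included), reporting slope, intercept
#' and R-squared. Perfect semi-quantitative recovery gives slope 1, intercept
#' 0, R-squared 1.
#'
#' @param nominal nominal amendment fraction per library (>= 3 distinct
#'   levels).
#' @param spikeReads spike-assigned read count per library.
#' @param totalReads total retained reads per library (all > 0).
#' @return list with \code{slope}, \code{intercept}, \code{rSquared},
#'   \code{perLevel} (data.frame nominalPct, meanRecoveredPct, sdRecoveredPct,
#'   meanReads, sdReads) and \code{perLibrary}.
#' @export
spikeRecovery <- function(nominal, spikeReads, totalReads) {
  if (length(unique(nominal)) < 3L) stop("need >= 3 distinct amendment levels")
  if (any(totalReads <= 0)) stop("zero total reads in a library")
  rec_frac <- spikeReads / totalReads
  fit <- stats::lm(rec_frac ~ nominal)
  # R^2 computed directly; a response with (near-)zero variance has no
  # association and reports 0 rather than a 0/0 artifact
  ss_tot <- sum((rec_frac - mean(rec_frac))^2)
  ss_res <- sum(stats::residuals(fit)^2)
  r2 <- if (ss_tot <= .Machine$double.eps * sum(rec_frac^2) || ss_tot == 0) 0
        else 1 - ss_res / ss_tot
  per_library <- data.frame(nominal = nominal, spikeReads = spikeReads,
                            totalReads = totalReads,
                            recoveredPct = 100 * rec_frac)
  lev <- sort(unique(nominal))
  per_level <- do.call(rbind, lapply(lev, function(l) {
    i <- nominal == l
    data.frame(nominalPct = 100 * l,
               meanRecoveredPct = mean(per_library$recoveredPct[i]),
               sdRecoveredPct = stats::sd(per_library$recoveredPct[i]),
               meanReads = mean(spikeReads[i]),
               sdReads = stats::sd(spikeReads[i]))
  }))
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       rSquared = r2,
       perLevel = per_level, perLibrary = per_library)
}

#' Fingerprint-level diversity and evenness helpers
#'
#' \code{fingerprintDiversity} applies the RFU threshold of an in-vivo
#' fingerprint (or the 20-read contig rule already applied upstream for
#' in-silico fingerprints) and returns Shannon H' and richness over the
#' retained T-RF abundances; \code{fingerprintFo} the Pareto-Lorenz Fo.
#'
#' @param fp a [Fingerprint-class].
#' @return see [shannonIndex()] / [paretoLorenzFo()].
#' @export
fingerprintDiversity <- function(fp) {
  tab <- as.data.frame(trfTable(fp))
  tab <- tab[tab$abundance >= fp@rfuThreshold & !tab$pseudo, , drop = FALSE]
  shannonIndex(tab$abundance)
}

#' @rdname fingerprintDiversity
#' @export
fingerprintFo <- function(fp) {
  tab <- as.data.frame(trfTable(fp))
  tab <- tab[tab$abundance >= fp@rfuThreshold & !tab$pseudo, , drop = FALSE]
  paretoLorenzFo(tab$abundance)
}
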