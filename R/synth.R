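#' Default amplification primers
#'
#' The bacterial 16S primer pair used throughout: Ba27f
#' (5'-AGAGTTTGATCMTGGCTCAG-3') and Ba519r (5'-TATTACCGCGGCKGCTG-3'), given as
#' IUPAC strings (M = A/C, K = G/T).
#'
#' @return named list with \code{forward} and \code{reverse} character strings.
#' @export
defaultPrimers <- function() {
  list(forward = "AGAGTTTGATCMTGGCTCAG", reverse = "TATTACCGCGGCKGCTG")
}

#' Standard 454 multiplex identifier (MID) barcodes
#'
#' A panel of twelve 10-nt Roche-style MID barcodes for library multiplexing.
#'
#' @return named character vector MID1..MID12.
#' @export
rocheMIDs <- function() {
  c(MID1 = "ACGAGTGCGT", MID2 = "ACGCTCGACA", MID3 = "AGACGCACTC",
    MID4 = "AGCACTGTAG", MID5 = "ATCAGACACG", MID6 = "ATATCGCGAG",
    MID7 = "CGTGTCTCTA", MID8 = "CTCGCGTGTC", MID9 = "TAGTATCAGC",
    MID10 = "TCTCTATGCG", MID11 = "TGATACGTCT", MID12 = "TACTGAGCTA")
}

# One concrete realisation of a degenerate IUPAC primer.
realize_primer <- function(iupac) {
  map <- Biostrings::IUPAC_CODE_MAP
  ch <- strsplit(toupper(iupac), "")[[1]]
  paste(vapply(ch, function(b) {
    opts <- strsplit(map[[b]], "")[[1]]
    if (length(opts) == 1L) opts else sample(opts, 1L)
  }, ""), collapse = "")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Count IUPAC-aware occurrences of a (possibly degenerate) pattern.
count_iupac <- function(pattern, sequence) {
  Biostrings::countPattern(Biostrings::DNAString(pattern),
                           Biostrings::DNAString(sequence),
                           fixed = "subject")
}

DEFAULT_PHYLA <- c("Proteobacteria", "Firmicutes", "Spirochaetes",
                   "Bacteroidetes", "Actinobacteria", "Chloroflexi",
                   "Acidobacteria", "Verrucomicrobia")

# Build one reference template: forward primer realisation, a genus signature
# block, random internal sequence, optional forced restriction site, and the
# reverse-complement of a reverse primer realisation at the 3' end. Regenerates
# until both primer sites are unique (IUPAC-aware).
build_template <- function(len, primers, signature, force_site, site = "CCGG",
                           signature_offset = 101L, max_tries = 25L) {
  fwd <- realize_primer(primers$forward)
  rev_rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(realize_primer(primers$reverse))))
  lf <- nchar(fwd); lr <- nchar(rev_rc)
  for (try in seq_len(max_tries)) {
    internal_len <- len - lf - lr
    internal <- random_dna(internal_len)
    # splice the genus signature at a fixed offset past the primer
    sig_at <- signature_offset - lf
    substr(internal, sig_at, sig_at + nchar(signature) - 1L) <- signature
    if (force_site) {
      pos <- sample(seq(120L, internal_len - 120L), 1L)
      substr(internal, pos, pos + nchar(site) - 1L) <- site
    }
    seqn <- paste0(fwd, internal, rev_rc)
    if (count_iupac(primers$forward, seqn) == 1L &&
        count_iupac(as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(primers$reverse))), seqn) == 1L)
      return(seqn)
  }
  stop("failed to build a template with unique primer sites")
}

#' Generate a mock community with ground-truth fractions
#'
#' Builds \code{nTaxa} reference amplicon templates (forward primer site
#' through the reverse-complemented reverse primer site, 450-550 nt between the
#' primer 5' ends) with template fractions drawn from a symmetric Dirichlet
#' distribution and sorted in descending order. Each genus carries a 60-nt
#' signature block at a fixed offset so that the k-mer classifier has learnable
#' taxonomic structure, and each template contains a forced internal
#' restriction site with probability \code{siteProb}. Phyla are assigned
#' round-robin from \code{phyla}, emulating a community with several dominant
#' lineages and a rare tail.
#'
#' @param nTaxa number of taxa (>= 2).
#' @param dominance Dirichlet concentration parameter; \code{Inf} gives exactly
#'   uniform fractions, small values give skewed communities. Default 1.
#' @param seed integer seed; the community is deterministic given the seed.
#' @param nPhyla number of phyla to spread taxa over.
#' @param siteProb probability that a template receives a forced internal
#'   restriction site.
#' @param ampliconRange min/max distance (nt) between the primer 5' ends.
#' @param primers primer pair, see [defaultPrimers()].
#' @param phyla phylum name pool.
#' @return a [MockCommunity-class].
#' @export
buildMockCommunity <- function(nTaxa = 25L, dominance = 1, seed = 1L,
                               nPhyla = 6L, siteProb = 0.9,
                               ampliconRange = c(450L, 550L),
                               primers = defaultPrimers(),
                               phyla = DEFAULT_PHYLA) {
  if (nTaxa < 2L) stop("nTaxa must be >= 2")
  nPhyla <- min(nPhyla, length(phyla), nTaxa)
  withSeed(seed, {
    fr <- if (is.infinite(dominance)) rep(1 / nTaxa, nTaxa)
          else rgamma(nTaxa, shape = dominance)
    fr <- sort(fr / sum(fr), decreasing = TRUE)
    ids <- sprintf("tax%02d", seq_len(nTaxa))
    phy <- phyla[((seq_len(nTaxa) - 1L) %% nPhyla) + 1L]
    wpi <- stats::ave(seq_len(nTaxa), phy, FUN = seq_along)  # index within phylum
    fam_i <- ceiling(wpi / 2)                # two genera per family
    taxdf <- DataFrame(
      domain = "Bacteria",
      phylum = phy,
      class = paste0(phy, "_cl"),
      order = paste0(phy, "_or", fam_i),
      family = paste0(phy, "_f", fam_i),
      genus = paste0("g_", ids),
      row.names = ids
    )
    # 5'-to-5' primer distance d means template length d + nchar(reverse primer)
    lens <- sample(seq(ampliconRange[1], ampliconRange[2]), nTaxa,
                   replace = TRUE) + nchar(primers$reverse)
    sigs <- vapply(seq_len(nTaxa), function(i) random_dna(60L), "")
    force_site <- runif(nTaxa) < siteProb
    seqs <- vapply(seq_len(nTaxa), function(i) {
      build_template(lens[i], primers, sigs[i], force_site[i])
    }, "")
    names(seqs) <- ids
    mockCommunity(seqs, taxdf, fr)
  })
}

#' Build a spike-in taxon analogous to a quantified pure-culture template
#'
#' Generates a single-taxon community for use as an external spike (a marine
#' Vibrionaceae-like lineage not expected in an aquifer sediment pool).
#'
#' @param seed integer seed.
#' @param primers primer pair.
#' @return single-taxon [MockCommunity-class].
#' @export
buildSpikeTaxon <- function(seed = 99L, primers = defaultPrimers()) {
  withSeed(seed, {
    taxdf <- DataFrame(
      domain = "Bacteria", phylum = "Proteobacteria",
      class = "Gammaproteobacteria", order = "Vibrionales",
      family = "Vibrionaceae", genus = "Aliivibrio",
      row.names = "spike_afischeri"
    )
    seqn <- build_template(520L + nchar(primers$reverse), primers,
                           random_dna(60L), force_site = TRUE)
    mockCommunity(stats::setNames(c(seqn), "spike_afischeri"), taxdf, 1)
  })
}

#' Amend a template pool with a defined spike fraction
#'
#' Returns the base community with its fractions scaled by \code{1 - fraction}
#' and the spike taxon added at exactly \code{fraction}, mirroring a
#' qPCR-quantified template amendment. A zero fraction returns the base pool
#' unchanged.
#'
#' @param base base [MockCommunity-class].
#' @param design a [SpikeDesign-class].
#' @param fraction one of \code{design@amendmentFractions}.
#' @return a [MockCommunity-class] whose fractions sum to 1.
#' @export
spikePool <- function(base, design, fraction) {
  if (!any(abs(design@amendmentFractions - fraction) < 1e-12))
    stop("fraction is not part of the spike design")
  spike_id <- taxonIds(design@spike)
  if (spike_id %in% taxonIds(base))
    stop("spike taxon is already present in the base community")
  if (fraction == 0) return(base)
  seqs <- c(refSequences(base), refSequences(design@spike))
  taxdf <- rbind(taxonomy(base), taxonomy(design@spike))
  fr <- c(fractions(base) * (1 - fraction), stats::setNames(fraction, spike_id))
  mockCommunity(seqs, taxdf, fr)
}

# Quality profile: quadratic 3' decay on a 500-nt scale plus Gaussian noise.
simulate_qualities <- function(len, model) {
  pos <- seq_len(len)
  mu <- model@phredStart -
    (model@phredStart - model@phredEnd) * pmin(pos / 500, 1)^2
  q <- mu + if (model@phredNoiseSd > 0) rnorm(len, 0, model@phredNoiseSd) else 0
  as.integer(pmin(pmax(round(q), 2L), 40L))
}

# Corrupt one read (character vector) under the error model. 454-style:
# substitutions anywhere; indels at indelRate, multiplied inside homopolymer
# runs of length >= 3; insertions duplicate the current base (overcall),
# deletions drop it (undercall).
corrupt_read <- function(ch, model) {
  n <- length(ch)
  r <- rle(ch)
  runlen <- rep(r$lengths, r$lengths)
  pind <- model@indelRate * ifelse(runlen >= 3L, model@homopolymerMultiplier, 1)
  u <- runif(n)
  del <- u < pind / 2
  ins <- !del & u < pind
  sub <- runif(n) < model@substitutionRate & !del
  if (any(sub)) {
    bases <- c("A", "C", "G", "T")
    ch[sub] <- vapply(ch[sub],
                      function(b) sample(bases[bases != b], 1L), "")
  }
  rep(ch, 1L + ins - del)
}

#' Simulate a barcoded bidirectional pyrotag library
#'
#' Draws \code{depth} reads multinomially from the pool's template fractions.
#' Each read is forward or reverse with probability 1/2: a forward read is
#' MID + forward primer + template prefix, a reverse read is MID + reverse
#' primer + reverse-complement template prefix. The post-primer length is
#' Gaussian (mean \code{meanLength}, sd \code{sdLength}), truncated to
#' [150, template length]; a fraction \code{shortReadRate} of reads is drawn
#' from a short-read length mode instead (mean 180 nt), which is the knob used
#' to emulate 2-step PCR libraries (about 5x the 1-step short-read rate).
#' Reads are then corrupted under the [ErrorModel-class] and given matched
#' position-decaying quality strings. Deterministic for a fixed seed.
#'
#' @param pool a [MockCommunity-class].
#' @param depth number of reads (>= 1).
#' @param mid MID barcode string prepended to every read.
#' @param model an [ErrorModel-class].
#' @param seed integer seed.
#' @param libraryId library label recorded per read.
#' @param shortReadRate probability of a short-mode read (default 0.02).
#' @param meanLength,sdLength post-primer read length distribution (nt).
#' @param primers primer pair.
#' @return a [PyroReadSet-class] with truth taxon labels and orientations.
#' @export
simulateReads <- function(pool, depth, mid, model = errorModel(),
                          seed = 1L, libraryId = "lib1",
                          shortReadRate = 0.02, meanLength = 400,
                          sdLength = 60, primers = defaultPrimers()) {
  if (length(pool) == 0L) stop("empty template pool")
  if (depth < 1L) stop("depth must be >= 1")
  withSeed(seed, {
    ids <- taxonIds(pool)
    taxa <- sample(ids, depth, replace = TRUE, prob = fractions(pool))
    orient <- sample(c("forward", "reverse"), depth, replace = TRUE)
    fwd_templates <- as.character(refSequences(pool))
    rev_templates <- as.character(
      Biostrings::reverseComplement(refSequences(pool)))
    names(rev_templates) <- ids
    plen <- c(forward = nchar(primers$forward), reverse = nchar(primers$reverse))
    short <- runif(depth) < shortReadRate
    post <- round(ifelse(short, rnorm(depth, 180, 40),
                         rnorm(depth, meanLength, sdLength)))
    noise_free <- model@substitutionRate == 0 && model@indelRate == 0
    seqs <- character(depth)
    quals <- vector("list", depth)
    for (i in seq_len(depth)) {
      tmpl <- if (orient[i] == "forward") fwd_templates[[taxa[i]]]
              else rev_templates[[taxa[i]]]
      len <- min(max(post[i] + plen[[orient[i]]], 150L), nchar(tmpl))
      body <- substr(tmpl, 1L, len)
      read <- paste0(mid, body)
      if (!noise_free) {
        ch <- corrupt_read(strsplit(read, "")[[1]], model)
        read <- paste(ch, collapse = "")
      }
      seqs[i] <- read
      quals[[i]] <- simulate_qualities(nchar(read), model)
    }
    names(seqs) <- sprintf("%s_r%05d", libraryId, seq_len(depth))
    pyroReadSet(seqs, quals, libraryId = libraryId, mid = mid,
                orientation = orient, taxonId = taxa)
  })
}

#' Write ground-truth and mapping tables
#'
#' \code{writeGroundTruth} writes a TSV of taxon id, semicolon-joined lineage
#' and true template fraction; \code{writeMappingFile} writes the
#' library-to-MID mapping (libraryId, mid, replicateGroup).
#'
#' @param community a [MockCommunity-class].
#' @param path output TSV path.
#' @return invisibly, \code{path}.
#' @export
writeGroundTruth <- function(community, path) {
  tx <- as.data.frame(taxonomy(community))
  df <- data.frame(
    taxon_id = taxonIds(community),
    lineage = apply(tx[, TAXONOMIC_RANKS], 1, paste, collapse = ";"),
    true_fraction = as.numeric(fractions(community))
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeGroundTruth
#' @param mapping data.frame with columns libraryId, mid, replicateGroup.
#' @export
writeMappingFile <- function(mapping, path) {
  stopifnot(all(c("libraryId", "mid", "replicateGroup") %in% names(mapping)))
  utils::write.table(mapping, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Rescale a community to a fixed phylum abundance profile
#'
#' Scales each phylum's taxon fractions so that the phylum totals match the
#' supplied profile (normalised to sum to 1), keeping within-phylum
#' proportions. Phyla are matched to profile entries by decreasing total
#' abundance. Used to pin down study conditions such as "a dominant phylum
#' near 30%" independently of the Dirichlet draw.
#'
#' @param community a [MockCommunity-class].
#' @param profile numeric vector of target phylum totals, one per phylum in
#'   the community.
#' @return a [MockCommunity-class] with rescaled fractions.
#' @export
reweightPhyla <- function(community, profile) {
  phy <- taxonomy(community)$phylum
  fr <- fractions(community)
  totals <- tapply(fr, phy, sum)
  if (length(profile) != length(totals))
    stop("profile must have one entry per phylum")
  profile <- sort(profile / sum(profile), decreasing = TRUE)
  names(profile) <- names(sort(totals, decreasing = TRUE))
  scale <- profile[phy] / totals[phy]
  mockCommunity(refSequences(community), taxonomy(community),
                as.numeric(fr * scale))
}
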