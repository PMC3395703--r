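#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importFrom IRanges IntegerList CharacterList
#' @importFrom Biostrings DNAStringSet DNAString
NULL

TAXONOMIC_RANKS <- c("domain", "phylum", "class", "order", "family", "genus")

#' Mock community of reference 16S templates with known fractions
#'
#' A \code{MockCommunity} bundles full-length reference amplicon templates
#' (forward primer site through the reverse-complemented reverse primer site),
#' their ranked taxonomy, and the true template fraction of each taxon in the
#' pool. It is the ground truth against which read simulation, classification
#' and spike-in recovery are evaluated.
#'
#' @slot sequences \code{DNAStringSet} of reference templates, named by taxon id.
#' @slot taxonomy \code{DataFrame} with one row per taxon and the columns
#'   \code{domain}, \code{phylum}, \code{class}, \code{order}, \code{family},
#'   \code{genus}.
#' @slot fractions numeric vector of true template fractions, named by taxon id;
#'   non-negative and summing to 1.
#'
#' @seealso [buildMockCommunity()], [spikePool()], [simulateReads()]
#' @export
setClass("MockCommunity",
  representation(
    sequences = "DNAStringSet",
    taxonomy  = "DataFrame",
    fractions = "numeric"
  )
)

setValidity("MockCommunity", function(object) {
  msg <- character()
  n <- length(object@sequences)
  if (nrow(object@taxonomy) != n)
    msg <- c(msg, "taxonomy must have one row per sequence")
  if (length(object@fractions) != n)
    msg <- c(msg, "fractions must have one entry per sequence")
  if (!all(TAXONOMIC_RANKS %in% colnames(object@taxonomy)))
    msg <- c(msg, "taxonomy must contain columns domain..genus")
  if (any(object@fractions < 0))
    msg <- c(msg, "fractions must be non-negative")
  if (n > 0 && abs(sum(object@fractions) - 1) > 1e-9)
    msg <- c(msg, "fractions must sum to 1")
  if (n > 0 && (is.null(names(object@sequences)) ||
                !identical(names(object@sequences), names(object@fractions))))
    msg <- c(msg, "sequence and fraction names must agree")
  if (length(msg)) msg else TRUE
})

#' Construct a MockCommunity
#'
#' @param sequences named \code{DNAStringSet} (or named character vector) of
#'   reference templates.
#' @param taxonomy \code{DataFrame} or data.frame with columns
#'   \code{domain..genus}, one row per taxon.
#' @param fractions numeric template fractions; normalised to sum to 1.
#' @return A [MockCommunity-class] object.
#' @export
mockCommunity <- function(sequences, taxonomy, fractions) {
  if (is.character(sequences)) sequences <- DNAStringSet(sequences)
  taxonomy <- as(taxonomy, "DataFrame")
  fractions <- fractions / sum(fractions)
  names(fractions) <- names(sequences)
  rownames(taxonomy) <- names(sequences)
  new("MockCommunity", sequences = sequences, taxonomy = taxonomy,
      fractions = fractions)
}

#' @describeIn MockCommunity-class number of taxa
#' @param x,object a \code{MockCommunity}
#' @export
setMethod("length", "MockCommunity", function(x) length(x@sequences))

#' Accessors for MockCommunity
#'
#' \code{refSequences} returns the reference templates, \code{taxonomy} the
#' ranked lineage table, \code{fractions} the true template fractions and
#' \code{taxonIds} the taxon identifiers.
#'
#' @param object a [MockCommunity-class]
#' @return see description.
#' @export
setGeneric("refSequences", function(object) standardGeneric("refSequences"))
#' @rdname refSequences
#' @export
setMethod("refSequences", "MockCommunity", function(object) object@sequences)

#' @rdname refSequences
#' @export
setGeneric("taxonomy", function(object) standardGeneric("taxonomy"))
#' @rdname refSequences
#' @export
setMethod("taxonomy", "MockCommunity", function(object) object@taxonomy)

#' @rdname refSequences
#' @export
setGeneric("fractions", function(object) standardGeneric("fractions"))
#' @rdname refSequences
#' @export
setMethod("fractions", "MockCommunity", function(object) object@fractions)

#' @rdname refSequences
#' @export
setGeneric("taxonIds", function(object) standardGeneric("taxonIds"))
#' @rdname refSequences
#' @export
setMethod("taxonIds", "MockCommunity", function(object) names(object@sequences))

setMethod("show", "MockCommunity", function(object) {
  cat(sprintf("MockCommunity with %d taxa (%d phyla)\n", length(object),
              length(unique(object@taxonomy$phylum))))
  if (length(object)) {
    top <- head(order(object@fractions, decreasing = TRUE), 3)
    cat("  top fractions:",
        paste(sprintf("%s=%.3f", names(object@fractions)[top],
                      object@fractions[top]), collapse = ", "), "\n")
    cat(sprintf("  template widths: %d-%d nt\n",
                min(Biostrings::width(object@sequences)),
                max(Biostrings::width(object@sequences))))
  }
})

#' Spike-in experimental design
#'
#' Describes a quantified spike-in experiment: an external taxon (absent from
#' the base community) added to the template pool at defined amendment
#' fractions, with one simulation seed per replicate series.
#'
#' @slot spike single-taxon [MockCommunity-class] holding the spike template.
#' @slot amendmentFractions numeric fractions in [0, 1); default
#'   \code{c(0, 0.002, 0.02, 0.20)} (i.e. 0, 0.2, 2 and 20 percent).
#' @slot replicateSeeds integer seeds, one per replicate series.
#' @export
setClass("SpikeDesign",
  representation(
    spike = "MockCommunity",
    amendmentFractions = "numeric",
    replicateSeeds = "integer"
  )
)

setValidity("SpikeDesign", function(object) {
  msg <- character()
  if (length(object@spike) != 1L)
    msg <- c(msg, "spike must hold exactly one taxon")
  if (any(object@amendmentFractions < 0 | object@amendmentFractions >= 1))
    msg <- c(msg, "amendment fractions must lie in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' @rdname SpikeDesign-class
#' @param spike single-taxon [MockCommunity-class].
#' @param amendmentFractions numeric amendment fractions.
#' @param replicateSeeds integer vector of replicate seeds.
#' @export
spikeDesign <- function(spike, amendmentFractions = c(0, 0.002, 0.02, 0.20),
                        replicateSeeds = c(101L, 202L)) {
  new("SpikeDesign", spike = spike,
      amendmentFractions = amendmentFractions,
      replicateSeeds = as.integer(replicateSeeds))
}

setMethod("show", "SpikeDesign", function(object) {
  cat(sprintf("SpikeDesign: taxon '%s' at fractions %s, %d replicate series\n",
              taxonIds(object@spike),
              paste(object@amendmentFractions, collapse = "/"),
              length(object@replicateSeeds)))
})

#' 454-style read error model
#'
#' Per-base substitution and indel probabilities, a homopolymer multiplier
#' applied to the indel rate inside base runs of length >= 3 (the dominant 454
#' error mode), and a positional quality profile with 3' decay used to write
#' matched Phred strings.
#'
#' @slot substitutionRate per-base substitution probability.
#' @slot indelRate per-base insertion/deletion probability outside homopolymers.
#' @slot homopolymerMultiplier factor (>= 1) applied to \code{indelRate} inside
#'   homopolymer runs of length >= 3.
#' @slot phredStart mean Phred score at the 5' end.
#' @slot phredEnd mean Phred score at the 3' end of a full-length read.
#' @slot phredNoiseSd per-base Gaussian noise on the quality profile.
#' @export
setClass("ErrorModel",
  representation(
    substitutionRate = "numeric",
    indelRate = "numeric",
    homopolymerMultiplier = "numeric",
    phredStart = "numeric",
    phredEnd = "numeric",
    phredNoiseSd = "numeric"
  )
)

setValidity("ErrorModel", function(object) {
  msg <- character()
  if (object@substitutionRate < 0 || object@substitutionRate > 1 ||
      object@indelRate < 0 || object@indelRate > 1)
    msg <- c(msg, "rates must lie in [0, 1]")
  if (object@homopolymerMultiplier < 1)
    msg <- c(msg, "homopolymerMultiplier must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @rdname ErrorModel-class
#' @param substitutionRate,indelRate,homopolymerMultiplier,phredStart,phredEnd,phredNoiseSd
#'   see slot documentation.
#' @export
errorModel <- function(substitutionRate = 0.002, indelRate = 0.001,
                       homopolymerMultiplier = 6, phredStart = 37,
                       phredEnd = 18, phredNoiseSd = 3) {
  new("ErrorModel", substitutionRate = substitutionRate, indelRate = indelRate,
      homopolymerMultiplier = homopolymerMultiplier, phredStart = phredStart,
      phredEnd = phredEnd, phredNoiseSd = phredNoiseSd)
}

#' @rdname ErrorModel-class
#' @details \code{perfectErrorModel()} returns a zero-noise model (no
#'   substitutions or indels, flat Phred 40), useful for ground-truth checks.
#' @export
perfectErrorModel <- function() {
  errorModel(substitutionRate = 0, indelRate = 0, homopolymerMultiplier = 1,
             phredStart = 40, phredEnd = 40, phredNoiseSd = 0)
}

setMethod("show", "ErrorModel", function(object) {
  cat(sprintf(
    "ErrorModel: sub=%.4g indel=%.4g (x%.3g in homopolymers), Phred %g->%g (sd %g)\n",
    object@substitutionRate, object@indelRate, object@homopolymerMultiplier,
    object@phredStart, object@phredEnd, object@phredNoiseSd))
})

#' A set of pyrotag reads with per-base qualities
#'
#' Container for simulated or parsed 454 amplicon reads: sequences, per-base
#' Phred qualities, and per-read metadata (library, MID, orientation, and the
#' true source taxon when simulated). Orientation is \code{NA} until primer
#' identification during quality filtering, except for simulated reads where it
#' is known.
#'
#' @slot sequences \code{DNAStringSet} named by read id.
#' @slot qualities \code{IntegerList} of per-base Phred scores, parallel to
#'   \code{sequences}.
#' @slot readInfo \code{DataFrame} with columns \code{libraryId}, \code{mid},
#'   \code{orientation} ("forward"/"reverse"/NA) and \code{taxonId} (truth
#'   label or NA).
#' @export
setClass("PyroReadSet",
  representation(
    sequences = "DNAStringSet",
    qualities = "IntegerList",
    readInfo  = "DataFrame"
  )
)

setValidity("PyroReadSet", function(object) {
  msg <- character()
  n <- length(object@sequences)
  if (length(object@qualities) != n || nrow(object@readInfo) != n)
    msg <- c(msg, "sequences, qualities and readInfo must be parallel")
  if (n > 0 && !identical(Biostrings::width(object@sequences),
                          lengths(object@qualities, use.names = FALSE)))
    msg <- c(msg, "each read must have one quality per base")
  need <- c("libraryId", "mid", "orientation", "taxonId")
  if (!all(need %in% colnames(object@readInfo)))
    msg <- c(msg, "readInfo must contain libraryId, mid, orientation, taxonId")
  if (length(msg)) msg else TRUE
})

#' @rdname PyroReadSet-class
#' @param sequences named \code{DNAStringSet} or character vector.
#' @param qualities list/\code{IntegerList} of per-base Phred scores.
#' @param libraryId,mid,orientation,taxonId per-read metadata, recycled.
#' @export
pyroReadSet <- function(sequences, qualities,
                        libraryId = NA_character_, mid = NA_character_,
                        orientation = NA_character_, taxonId = NA_character_) {
  if (is.character(sequences)) sequences <- DNAStringSet(sequences)
  n <- length(sequences)
  qualities <- IntegerList(qualities)
  info <- DataFrame(
    libraryId = rep(libraryId, length.out = n),
    mid = rep(mid, length.out = n),
    orientation = rep(orientation, length.out = n),
    taxonId = rep(taxonId, length.out = n),
    row.names = names(sequences)
  )
  new("PyroReadSet", sequences = sequences, qualities = qualities,
      readInfo = info)
}

#' @describeIn PyroReadSet-class number of reads
#' @param x a \code{PyroReadSet}
#' @export
setMethod("length", "PyroReadSet", function(x) length(x@sequences))

#' @describeIn PyroReadSet-class read identifiers
#' @export
setMethod("names", "PyroReadSet", function(x) names(x@sequences))

#' @describeIn PyroReadSet-class subset reads by index, name or logical mask
#' @param i index vector
#' @param j,...,drop ignored
#' @export
setMethod("[", "PyroReadSet", function(x, i, j, ..., drop = FALSE) {
  initialize(x, sequences = x@sequences[i], qualities = x@qualities[i],
             readInfo = x@readInfo[i, , drop = FALSE])
})

#' Read sequences and metadata accessors
#'
#' \code{readSequences} returns the read \code{DNAStringSet},
#' \code{readQualities} the per-base Phred \code{IntegerList} and
#' \code{readInfo} the per-read metadata \code{DataFrame}.
#'
#' @param object a [PyroReadSet-class]
#' @return see description.
#' @export
setGeneric("readSequences", function(object) standardGeneric("readSequences"))
#' @rdname readSequences
#' @export
setMethod("readSequences", "PyroReadSet", function(object) object@sequences)

#' @rdname readSequences
#' @export
setGeneric("readQualities", function(object) standardGeneric("readQualities"))
#' @rdname readSequences
#' @export
setMethod("readQualities", "PyroReadSet", function(object) object@qualities)

#' @rdname readSequences
#' @export
setGeneric("readInfo", function(object) standardGeneric("readInfo"))
#' @rdname readSequences
#' @export
setMethod("readInfo", "PyroReadSet", function(object) object@readInfo)

setMethod("show", "PyroReadSet", function(object) {
  n <- length(object)
  cat(sprintf("PyroReadSet with %d reads", n))
  if (n) {
    w <- Biostrings::width(object@sequences)
    cat(sprintf(" (width %d-%d, median %d)", min(w), max(w),
                as.integer(stats::median(w))))
    libs <- unique(object@readInfo$libraryId)
    cat(sprintf("; %d librar%s", length(libs),
                if (length(libs) == 1L) "y" else "ies"))
  }
  cat("\n")
})

#' Combine PyroReadSets
#' @param reads list of \code{PyroReadSet}s
#' @return a single \code{PyroReadSet}
#' @export
combinePyroReads <- function(reads) {
  reads <- reads[vapply(reads, length, 1L) > 0]
  if (!length(reads)) stop("no reads to combine")
  new("PyroReadSet",
      sequences = do.call(c, unname(lapply(reads, readSequences))),
      qualities = do.call(c, unname(lapply(reads, readQualities))),
      readInfo  = do.call(rbind, unname(lapply(reads, readInfo))))
}

#' Assembled amplicon contigs with read provenance
#'
#' Consensus sequences from greedy overlap assembly, each carrying its member
#' read ids and forward/reverse read counts (required for the paper-style
#' both-orientation filter and for read-weighted T-RF abundances).
#'
#' @slot consensus \code{DNAStringSet} named by contig id.
#' @slot contigInfo \code{DataFrame} with columns \code{nReads},
#'   \code{nForward}, \code{nReverse}.
#' @slot members \code{CharacterList} of member read ids per contig.
#' @export
setClass("ContigSet",
  representation(
    consensus = "DNAStringSet",
    contigInfo = "DataFrame",
    members = "CharacterList"
  )
)

setValidity("ContigSet", function(object) {
  msg <- character()
  n <- length(object@consensus)
  if (nrow(object@contigInfo) != n || length(object@members) != n)
    msg <- c(msg, "consensus, contigInfo and members must be parallel")
  if (n > 0) {
    with_counts <- object@contigInfo$nForward + object@contigInfo$nReverse
    if (!identical(as.integer(with_counts), as.integer(object@contigInfo$nReads)))
      msg <- c(msg, "nForward + nReverse must equal nReads")
    if (!identical(as.integer(object@contigInfo$nReads),
                   lengths(object@members, use.names = FALSE)))
      msg <- c(msg, "nReads must equal the member list length")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn ContigSet-class number of contigs
#' @param x,object a \code{ContigSet}
#' @export
setMethod("length", "ContigSet", function(x) length(x@consensus))

#' Contig accessors
#' @param object a [ContigSet-class]
#' @return \code{consensusSequences}: the consensus \code{DNAStringSet};
#'   \code{contigInfo}: read-count \code{DataFrame}; \code{contigMembers}:
#'   member read ids.
#' @export
setGeneric("consensusSequences", function(object) standardGeneric("consensusSequences"))
#' @rdname consensusSequences
#' @export
setMethod("consensusSequences", "ContigSet", function(object) object@consensus)

#' @rdname consensusSequences
#' @export
setGeneric("contigInfo", function(object) standardGeneric("contigInfo"))
#' @rdname consensusSequences
#' @export
setMethod("contigInfo", "ContigSet", function(object) object@contigInfo)

#' @rdname consensusSequences
#' @export
setGeneric("contigMembers", function(object) standardGeneric("contigMembers"))
#' @rdname consensusSequences
#' @export
setMethod("contigMembers", "ContigSet", function(object) object@members)

setMethod("show", "ContigSet", function(object) {
  cat(sprintf("ContigSet with %d contigs\n", length(object)))
  if (length(object)) {
    cat(sprintf("  reads per contig: %s\n",
                paste(object@contigInfo$nReads, collapse = ", ")))
  }
})

#' Restriction enzyme definition
#'
#' Recognition site and cut offset on the labelled (forward) strand. The
#' default is MspI (C^CGG): recognition sequence CCGG, cut after the first
#' base, so a terminal fragment ends on the first C of the site.
#'
#' @slot name enzyme name.
#' @slot site recognition sequence (ACGT).
#' @slot cutOffset bases after the site start at which the labelled strand is
#'   cut; 0 <= cutOffset <= nchar(site).
#' @export
setClass("RestrictionEnzyme",
  representation(name = "character", site = "character", cutOffset = "integer"))

setValidity("RestrictionEnzyme", function(object) {
  msg <- character()
  if (object@cutOffset < 0 || object@cutOffset > nchar(object@site))
    msg <- c(msg, "cutOffset must lie within the recognition site")
  if (grepl("[^ACGT]", object@site))
    msg <- c(msg, "recognition site must be plain ACGT")
  if (length(msg)) msg else TRUE
})

#' @rdname RestrictionEnzyme-class
#' @param name,site,cutOffset see slots.
#' @export
restrictionEnzyme <- function(name = "MspI", site = "CCGG", cutOffset = 1L) {
  new("RestrictionEnzyme", name = name, site = toupper(site),
      cutOffset = as.integer(cutOffset))
}

#' @rdname RestrictionEnzyme-class
#' @export
mspI <- function() restrictionEnzyme("MspI", "CCGG", 1L)

setMethod("show", "RestrictionEnzyme", function(object) {
  cat(sprintf("RestrictionEnzyme %s: %s, cut after base %d\n",
              object@name, object@site, object@cutOffset))
})

#' A T-RFLP fingerprint
#'
#' A set of terminal restriction fragments (T-RFs) for one sample, either
#' predicted in silico from contigs or measured (emulated) in vivo. Each T-RF
#' carries its length in bp from the 5' base of the labelled forward primer,
#' an abundance (relative %, or signal in RFU for in-vivo fingerprints), a
#' pseudo-T-RF flag, and for pseudo fragments the length of the primary
#' fragment they descend from.
#'
#' @slot sampleId sample label.
#' @slot trf \code{DataFrame} with columns \code{lengthBp}, \code{abundance},
#'   \code{pseudo}, \code{parentLengthBp}, \code{origin}.
#' @slot rfuThreshold signal threshold (default 100 RFU) applied to in-vivo
#'   fingerprints before any statistics.
#' @export
setClass("Fingerprint",
  representation(sampleId = "character", trf = "DataFrame",
                 rfuThreshold = "numeric"))

setValidity("Fingerprint", function(object) {
  msg <- character()
  need <- c("lengthBp", "abundance", "pseudo", "parentLengthBp", "origin")
  if (!all(need %in% colnames(object@trf)))
    msg <- c(msg, "trf must contain lengthBp, abundance, pseudo, parentLengthBp, origin")
  if (nrow(object@trf)) {
    if (any(object@trf$lengthBp < 1)) msg <- c(msg, "T-RF lengths must be >= 1")
    if (any(object@trf$abundance < 0)) msg <- c(msg, "abundances must be >= 0")
    if (anyDuplicated(object@trf$lengthBp))
      msg <- c(msg, "T-RF lengths must be unique within a fingerprint")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname Fingerprint-class
#' @param sampleId sample label.
#' @param lengthBp,abundance,pseudo,parentLengthBp,origin T-RF columns.
#' @param rfuThreshold signal threshold for in-vivo statistics.
#' @export
fingerprint <- function(sampleId, lengthBp, abundance,
                        pseudo = FALSE, parentLengthBp = NA_integer_,
                        origin = "in_silico", rfuThreshold = 100) {
  n <- length(lengthBp)
  trf <- DataFrame(
    lengthBp = as.integer(lengthBp),
    abundance = as.numeric(abundance),
    pseudo = rep(pseudo, length.out = n),
    parentLengthBp = rep(as.integer(parentLengthBp), length.out = n),
    origin = rep(origin, length.out = n)
  )
  trf <- trf[order(trf$lengthBp), , drop = FALSE]
  new("Fingerprint", sampleId = sampleId, trf = trf,
      rfuThreshold = rfuThreshold)
}

#' @describeIn Fingerprint-class number of T-RFs
#' @param x,object a \code{Fingerprint}
#' @export
setMethod("length", "Fingerprint", function(x) nrow(x@trf))

#' T-RF table accessor
#' @param object a [Fingerprint-class]
#' @return the T-RF \code{DataFrame}.
#' @export
setGeneric("trfTable", function(object) standardGeneric("trfTable"))
#' @rdname trfTable
#' @export
setMethod("trfTable", "Fingerprint", function(object) object@trf)

setMethod("show", "Fingerprint", function(object) {
  cat(sprintf("Fingerprint '%s' (%s): %d T-RFs", object@sampleId,
              if (nrow(object@trf)) object@trf$origin[1] else "empty",
              nrow(object@trf)))
  if (nrow(object@trf)) {
    np <- sum(object@trf$pseudo)
    if (np) cat(sprintf(" (%d pseudo)", np))
    cat("\n  lengths:", paste(utils::head(object@trf$lengthBp, 12), collapse = " "),
        if (nrow(object@trf) > 12) "..." else "")
  }
  cat("\n")
})
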