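#' In-silico restriction digest of a labelled amplicon
#'
#' Predicts terminal restriction fragment (T-RF) lengths for a sequence
#' measured from the 5' base of the labelled forward primer. The primary T-RF
#' ends at the first recognition-site occurrence: its length is the 0-based
#' site index plus the enzyme's cut offset (MspI C^CGG therefore ends the
#' fragment on the first C of the site). With \code{includePseudo}, every
#' subsequent site yields a pseudo-T-RF at the analogous coordinate — the
#' fragment that appears when the first site escapes digestion. A sequence
#' without any site yields one uncut fragment of full length.
#'
#' @param sequence DNA string starting at the labelled primer's 5' base.
#' @param enzyme a [RestrictionEnzyme-class]; default MspI.
#' @param includePseudo also report pseudo-T-RFs from downstream sites
#'   (default TRUE).
#' @return data.frame with columns \code{lengthBp}, \code{pseudo},
#'   \code{parentLengthBp} (the primary fragment length for pseudo rows).
#' @export
digestSequence <- function(sequence, enzyme = mspI(), includePseudo = TRUE) {
  sequence <- toupper(as.character(sequence))
  if (!nchar(sequence)) stop("empty sequence")
  starts <- Biostrings::start(Biostrings::matchPattern(
    Biostrings::DNAString(enzyme@site), Biostrings::DNAString(sequence)))
  if (!length(starts)) {
    return(data.frame(lengthBp = nchar(sequence), pseudo = FALSE,
                      parentLengthBp = NA_integer_))
  }
  lens <- starts - 1L + enzyme@cutOffset
  lens <- lens[lens >= 1L]
  if (!length(lens)) {
    return(data.frame(lengthBp = nchar(sequence), pseudo = FALSE,
                      parentLengthBp = NA_integer_))
  }
  if (!includePseudo) lens <- lens[1L]
  data.frame(lengthBp = as.integer(lens),
             pseudo = c(FALSE, rep(TRUE, length(lens) - 1L)),
             parentLengthBp = c(NA_integer_, rep(as.integer(lens[1L]),
                                                 length(lens) - 1L)))
}

#' Predict an in-silico fingerprint from retained contigs
#'
#' Digests each contig consensus (which must begin at the forward primer, as
#' assembly is anchored there) and weights its primary T-RF by the contig's
#' member-read count. Equal-length T-RFs are merged by summing abundance and
#' abundances are normalised to 100%. Secondary sites are carried along as
#' pseudo rows with zero abundance so that downstream matching can recognise
#' pseudo-T-RF candidates.
#'
#' @param contigs a retained [ContigSet-class] (see [filterContigs()]).
#' @param enzyme a [RestrictionEnzyme-class].
#' @param sampleId label for the fingerprint.
#' @param primers primer pair used to check the contig anchor.
#' @return list with \code{fingerprint} (a [Fingerprint-class], origin
#'   \code{in_silico}) and \code{skipped} (number of contigs lacking the
#'   primer anchor, skipped with a warning).
#' @export
predictFingerprint <- function(contigs, enzyme = mspI(), sampleId = "sample",
                               primers = defaultPrimers()) {
  cons <- as.character(consensusSequences(contigs))
  nreads <- contigInfo(contigs)$nReads
  anchored <- vapply(cons, primer_at_start, TRUE, primer = primers$forward)
  skipped <- sum(!anchored)
  if (skipped) warning(sprintf("%d contig(s) lack the forward primer anchor; skipped",
                               skipped))
  cons <- cons[anchored]
  nreads <- nreads[anchored]
  if (!length(cons)) stop("no anchored contigs to digest")
  rows <- list()
  for (i in seq_along(cons)) {
    dg <- digestSequence(cons[i], enzyme, includePseudo = TRUE)
    dg$abundance <- ifelse(dg$pseudo, 0, nreads[i])
    rows[[i]] <- dg
  }
  tab <- do.call(rbind, rows)
  prim <- tab[!tab$pseudo, , drop = FALSE]
  agg <- stats::aggregate(abundance ~ lengthBp, prim, sum)
  agg$abundance <- 100 * agg$abundance / sum(agg$abundance)
  pse <- tab[tab$pseudo & !(tab$lengthBp %in% agg$lengthBp), , drop = FALSE]
  pse <- pse[!duplicated(pse$lengthBp), , drop = FALSE]
  fp <- fingerprint(sampleId,
                    lengthBp = c(agg$lengthBp, pse$lengthBp),
                    abundance = c(agg$abundance, rep(0, nrow(pse))),
                    pseudo = c(rep(FALSE, nrow(agg)), rep(TRUE, nrow(pse))),
                    parentLengthBp = c(rep(NA_integer_, nrow(agg)),
                                       pse$parentLengthBp),
                    origin = "in_silico", rfuThreshold = 0)
  list(fingerprint = fp, skipped = skipped)
}

#' Electropherogram emulation parameters
#'
#' @param driftBp maximum absolute integer fragment-size drift (capillary
#'   sizing error), default 3 bp.
#' @param signalPerRead fluorescence signal units per percent abundance.
#' @param noiseSd Gaussian signal noise (RFU).
#' @param rfuThreshold peak detection threshold (default 100 RFU).
#' @param partialFraction fraction of a parent peak's signal emitted as its
#'   pseudo-T-RF (incomplete digestion); default 0.
#' @return list of class \code{ElectrophoresisParams}.
#' @export
electrophoresisParams <- function(driftBp = 3L, signalPerRead = 100,
                                  noiseSd = 0, rfuThreshold = 100,
                                  partialFraction = 0) {
  structure(list(driftBp = as.integer(driftBp), signalPerRead = signalPerRead,
                 noiseSd = noiseSd, rfuThreshold = rfuThreshold,
                 partialFraction = partialFraction),
            class = "ElectrophoresisParams")
}

#' Emulate an in-vivo electropherogram from an in-silico fingerprint
#'
#' Shifts each primary T-RF by an integer drift drawn uniformly within
#' \code{[-driftBp, driftBp]} (predicted vs measured fragment sizes typically
#' differ by a few bp), scales abundance to signal units, adds Gaussian noise,
#' and discards peaks below the RFU threshold. With a positive
#' \code{partialFraction}, pseudo rows of the input fingerprint are emitted at
#' that fraction of their parent peak's signal, emulating incomplete
#' digestion. Deterministic for a fixed seed.
#'
#' @param truth an in-silico [Fingerprint-class] (pseudo rows optional).
#' @param params an [electrophoresisParams()] list.
#' @param seed integer seed.
#' @return an in-vivo [Fingerprint-class] (abundances in RFU).
#' @export
emulateElectropherogram <- function(truth, params = electrophoresisParams(),
                                    seed = 1L) {
  tab <- as.data.frame(trfTable(truth))
  withSeed(seed, {
    prim <- tab[!tab$pseudo, , drop = FALSE]
    sig <- prim$abundance * params$signalPerRead
    out <- data.frame(lengthBp = prim$lengthBp, signal = sig)
    pse <- tab[tab$pseudo, , drop = FALSE]
    if (nrow(pse) && params$partialFraction > 0) {
      parent_sig <- sig[match(pse$parentLengthBp, prim$lengthBp)]
      out <- rbind(out, data.frame(lengthBp = pse$lengthBp,
                                   signal = params$partialFraction * parent_sig))
    }
    if (params$driftBp > 0)
      out$lengthBp <- out$lengthBp +
        sample(seq(-params$driftBp, params$driftBp), nrow(out), replace = TRUE)
    if (params$noiseSd > 0)
      out$signal <- out$signal + rnorm(nrow(out), 0, params$noiseSd)
    # merge fragments that drifted onto the same length
    out <- stats::aggregate(signal ~ lengthBp, out, sum)
    out <- out[out$signal >= params$rfuThreshold & out$lengthBp >= 1, ,
               drop = FALSE]
    fingerprint(truth@sampleId, out$lengthBp, out$signal, pseudo = FALSE,
                origin = "in_vivo", rfuThreshold = params$rfuThreshold)
  })
}

#' Match observed against predicted T-RFs
#'
#' Pairs in-vivo (observed) with in-silico (predicted) primary T-RFs one to
#' one, greedily by smallest length difference within \code{toleranceBp}
#' (ties resolved toward the smaller fragment), which is optimal for
#' non-crossing 1-D matching. Observed fragments left unmatched are flagged as
#' candidate pseudo-T-RFs when they lie within tolerance of a predicted
#' secondary restriction site; the flag records the parent primary fragment.
#'
#' @param observed in-vivo [Fingerprint-class]; only peaks at or above its RFU
#'   threshold are considered.
#' @param predicted in-silico [Fingerprint-class] (pseudo rows used for
#'   pseudo-T-RF candidate flagging).
#' @param toleranceBp maximum |length difference| for a pairing (default 3).
#' @return list with \code{pairs} (data.frame observedBp, predictedBp,
#'   deltaBp), \code{unmatchedObserved} (data.frame observedBp, pseudoOf —
#'   parent primary length or NA), and \code{unmatchedPredicted} (integer
#'   lengths).
#' @export
matchFingerprints <- function(observed, predicted, toleranceBp = 3L) {
  if (toleranceBp < 0) stop("toleranceBp must be >= 0")
  obs <- as.data.frame(trfTable(observed))
  obs <- obs[obs$abundance >= observed@rfuThreshold, , drop = FALSE]
  pred <- as.data.frame(trfTable(predicted))
  prim <- pred[!pred$pseudo, , drop = FALSE]
  pse <- pred[pred$pseudo, , drop = FALSE]
  no <- nrow(obs); np <- nrow(prim)
  pairs <- data.frame(observedBp = integer(), predictedBp = integer(),
                      deltaBp = integer())
  if (no && np) {
    cand <- expand.grid(oi = seq_len(no), pi = seq_len(np))
    cand$delta <- abs(obs$lengthBp[cand$oi] - prim$lengthBp[cand$pi])
    cand <- cand[cand$delta <= toleranceBp, , drop = FALSE]
    cand <- cand[order(cand$delta, obs$lengthBp[cand$oi]), , drop = FALSE]
    used_o <- logical(no); used_p <- logical(np)
    for (r in seq_len(nrow(cand))) {
      oi <- cand$oi[r]; pi <- cand$pi[r]
      if (used_o[oi] || used_p[pi]) next
      used_o[oi] <- used_p[pi] <- TRUE
      pairs <- rbind(pairs, data.frame(
        observedBp = obs$lengthBp[oi], predictedBp = prim$lengthBp[pi],
        deltaBp = obs$lengthBp[oi] - prim$lengthBp[pi]))
    }
  } else {
    used_o <- logical(no); used_p <- logical(np)
  }
  un_obs <- obs$lengthBp[!used_o]
  pseudo_of <- rep(NA_integer_, length(un_obs))
  if (length(un_obs) && nrow(pse)) {
    for (i in seq_along(un_obs)) {
      dd <- abs(un_obs[i] - pse$lengthBp)
      j <- which.min(dd)
      if (length(j) && dd[j] <= toleranceBp)
        pseudo_of[i] <- pse$parentLengthBp[j]
    }
  }
  list(pairs = pairs,
       unmatchedObserved = data.frame(observedBp = un_obs, pseudoOf = pseudo_of),
       unmatchedPredicted = prim$lengthBp[!used_p])
}
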