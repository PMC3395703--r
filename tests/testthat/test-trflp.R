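# Build a sequence with MspI sites exactly at the positions giving the
# requested fragment lengths (cut after the first C of CCGG).
seq_with_cuts <- function(total_len, cut_lengths, seed = 1) {
  withr::with_seed(seed, {
    repeat {
      s <- random_dna_str(total_len)
      repeat {
        hit <- regexpr("CCGG", s, fixed = TRUE)
        if (hit == -1) break
        substr(s, hit, hit) <- "T"
      }
      ok <- TRUE
      for (L in cut_lengths) substr(s, L, L + 3) <- "CCGG"
      # placing a site may recreate an accidental one; verify before use
      hits <- gregexpr("CCGG", s, fixed = TRUE)[[1]]
      hits <- as.integer(hits[hits > 0])
      if (identical(hits, as.integer(cut_lengths))) break
    }
    s
  })
}

test_that("digestion reproduces the 208 bp primary / 285 bp secondary site pair", {
  s <- seq_with_cuts(520, c(208, 285))
  dg <- digestSequence(s)
  expect_equal(dg$lengthBp, c(208L, 285L))
  expect_equal(dg$pseudo, c(FALSE, TRUE))
  expect_equal(dg$parentLengthBp, c(NA_integer_, 208L))
  # without pseudo fragments only the primary cut is reported
  expect_equal(digestSequence(s, includePseudo = FALSE)$lengthBp, 208L)
})

test_that("an uncut sequence yields one full-length fragment", {
  s <- seq_with_cuts(500, integer(0), seed = 3)
  dg <- digestSequence(s)
  expect_equal(dg$lengthBp, 500L)
  expect_false(dg$pseudo)
  expect_error(digestSequence(""), "empty")
})

test_that("digestion matches the brute-force positional scan on random 2-kb sequences", {
  withr::with_seed(5, {
    for (i in 1:25) {
      s <- random_dna_str(2000)
      got <- digestSequence(s)$lengthBp
      expect_identical(got, as.integer(oracle_digest(s)))
    }
  })
})

test_that("fingerprint prediction weights T-RFs by read counts and merges equal lengths", {
  s1 <- paste0("AGAGTTTGATCATGGCTCAG", substr(seq_with_cuts(480, 141, 7), 21, 480))
  s2 <- paste0("AGAGTTTGATCCTGGCTCAG", substr(seq_with_cuts(480, 333, 11), 21, 480))
  mk <- function(seqs, nreads) {
    nf <- pmax(1L, nreads %/% 2L); nr <- nreads - nf
    ids <- sprintf("c%d", seq_along(seqs))
    names(seqs) <- ids
    new("ContigSet", consensus = Biostrings::DNAStringSet(seqs),
        contigInfo = S4Vectors::DataFrame(nReads = nreads, nForward = nf,
                                          nReverse = nr, row.names = ids),
        members = IRanges::CharacterList(lapply(nreads, function(n)
          sprintf("r%d", seq_len(n)))))
  }
  # sites re-placed after primer splice: recompute true fragment lengths
  l1 <- digestSequence(s1)$lengthBp[1]
  l2 <- digestSequence(s2)$lengthBp[1]
  pf <- predictFingerprint(mk(c(s1, s2), c(60L, 40L)), sampleId = "x")
  tab <- as.data.frame(trfTable(pf$fingerprint))
  prim <- tab[!tab$pseudo, ]
  expect_equal(prim$lengthBp, sort(c(l1, l2)))
  expect_equal(prim$abundance[match(c(l1, l2), prim$lengthBp)], c(60, 40))
  expect_equal(sum(prim$abundance), 100, tolerance = 1e-9)

  # two contigs with the same fragment length merge into one T-RF
  pf2 <- predictFingerprint(mk(c(s1, s1), c(30L, 20L)), sampleId = "y")
  tab2 <- as.data.frame(trfTable(pf2$fingerprint))
  expect_equal(sum(!tab2$pseudo), 1L)
  expect_equal(tab2$abundance[!tab2$pseudo], 100)

  # a contig without the primer anchor is skipped with a warning
  expect_warning(
    pf3 <- predictFingerprint(mk(c(s1, substr(seq_with_cuts(400, 200, 13), 1, 400)),
                                 c(30L, 20L)), sampleId = "z"),
    "anchor")
  expect_equal(pf3$skipped, 1L)
})

test_that("electropherogram emulation applies drift, threshold and determinism", {
  fp <- fingerprint("s", c(129L, 159L, 486L), c(50, 30, 20))
  # no drift, no noise, threshold 0: identical fragment list
  p0 <- electrophoresisParams(driftBp = 0, signalPerRead = 1, noiseSd = 0,
                              rfuThreshold = 0)
  ev <- emulateElectropherogram(fp, p0, seed = 2)
  expect_equal(trfTable(ev)$lengthBp, c(129L, 159L, 486L))
  expect_equal(trfTable(ev)$abundance, c(50, 30, 20))

  # a peak scaled below 100 RFU is absent
  p1 <- electrophoresisParams(driftBp = 0, signalPerRead = 4, noiseSd = 0,
                              rfuThreshold = 100)
  ev1 <- emulateElectropherogram(fp, p1, seed = 2)
  expect_equal(trfTable(ev1)$lengthBp, c(129L, 159L))  # 20*4 = 80 < 100

  # drift stays within the configured range; fixed seed reruns identically
  p2 <- electrophoresisParams(driftBp = 3, signalPerRead = 10, noiseSd = 5)
  ev2a <- emulateElectropherogram(fp, p2, seed = 9)
  ev2b <- emulateElectropherogram(fp, p2, seed = 9)
  expect_identical(as.data.frame(trfTable(ev2a)), as.data.frame(trfTable(ev2b)))
  expect_true(all(abs(trfTable(ev2a)$lengthBp - c(129, 159, 486)) <= 3))
})

test_that("matching pairs fragments within tolerance and flags pseudo-T-RFs", {
  # single-pair case
  obs <- fingerprint("o", 129L, 500, origin = "in_vivo")
  pred <- fingerprint("p", 127L, 100)
  m <- matchFingerprints(obs, pred, toleranceBp = 3)
  expect_equal(m$pairs$deltaBp, 2L)
  expect_equal(nrow(m$unmatchedObserved), 0L)

  # the worked pseudo-T-RF case: observed 282 near predicted secondary 285
  pred2 <- fingerprint("p2", c(208L, 285L), c(100, 0),
                       pseudo = c(FALSE, TRUE),
                       parentLengthBp = c(NA, 208L))
  obs2 <- fingerprint("o2", c(204L, 282L), c(800, 400), origin = "in_vivo")
  m2 <- matchFingerprints(obs2, pred2, toleranceBp = 4)
  expect_equal(m2$pairs$observedBp, 204L)
  expect_equal(m2$pairs$predictedBp, 208L)
  expect_equal(m2$unmatchedObserved$observedBp, 282L)
  expect_equal(m2$unmatchedObserved$pseudoOf, 208L)

  # empty predicted list leaves everything unmatched
  m3 <- matchFingerprints(obs2, fingerprint("e", integer(), numeric()), 3)
  expect_equal(m3$unmatchedObserved$observedBp, c(204L, 282L))
  expect_equal(nrow(m3$pairs), 0L)
})

test_that("peaks below the fingerprint RFU threshold are ignored in matching", {
  obs <- fingerprint("o", c(129L, 160L), c(550, 80), origin = "in_vivo",
                     rfuThreshold = 100)
  pred <- fingerprint("p", c(129L, 159L), c(60, 40))
  m <- matchFingerprints(obs, pred, toleranceBp = 3)
  expect_equal(m$pairs$observedBp, 129L)
  expect_equal(m$unmatchedPredicted, 159L)
})

test_that("zero-drift emulation round-trips through matching at tolerance 0", {
  withr::with_seed(21, {
    lens <- sort(sample(100:500, 8))
    fp <- fingerprint("rt", lens, runif(8, 200, 900))
  })
  ev <- emulateElectropherogram(fp, electrophoresisParams(
    driftBp = 0, signalPerRead = 1, noiseSd = 0, rfuThreshold = 0), seed = 4)
  m <- matchFingerprints(ev, fp, toleranceBp = 0)
  expect_equal(nrow(m$pairs), 8L)
  expect_true(all(m$pairs$deltaBp == 0))
  expect_equal(nrow(m$unmatchedObserved), 0L)
  expect_length(m$unmatchedPredicted, 0)
})

test_that("partial digestion emits a pseudo peak that the matcher attributes to its parent", {
  # in-silico truth: one dominant contig with a secondary site, plus a second
  # ordinary contig; 30% partial digestion
  truth <- fingerprint("pd", c(208L, 285L, 390L), c(70, 0, 30),
                       pseudo = c(FALSE, TRUE, FALSE),
                       parentLengthBp = c(NA, 208L, NA))
  ev <- emulateElectropherogram(truth, electrophoresisParams(
    driftBp = 0, signalPerRead = 10, noiseSd = 0, rfuThreshold = 100,
    partialFraction = 0.3), seed = 6)
  expect_true(285L %in% trfTable(ev)$lengthBp)
  expect_equal(trfTable(ev)$abundance[trfTable(ev)$lengthBp == 285L], 0.3 * 700)
  m <- matchFingerprints(ev, truth, toleranceBp = 3)
  expect_equal(m$unmatchedObserved$observedBp, 285L)
  expect_equal(m$unmatchedObserved$pseudoOf, 208L)
})
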