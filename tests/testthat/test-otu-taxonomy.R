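# Small labelled reference with two genera per family for classifier tests.
ref_community <- function(nTaxa = 12, seed = 41) {
  buildMockCommunity(nTaxa = nTaxa, dominance = Inf, seed = seed, nPhyla = 6)
}

test_that("OTU clustering groups by the 97% identity cut with the chosen linkage", {
  # identical reads -> one OTU
  s <- random_dna_str(300)
  part <- clusterOTUs(c(a = s, b = s, c = s))
  expect_equal(unname(part$otu), c(1L, 1L, 1L))

  # two groups at ~90% between, identical within -> two OTUs
  withr::with_seed(43, {
    g1 <- random_dna_str(300)
    g2 <- mutate_positions(g1, sample(300, 30))
  })
  part2 <- clusterOTUs(c(a = g1, b = g1, c = g2, d = g2))
  expect_equal(length(unique(part2$otu)), 2L)
  expect_equal(unname(part2$otu["a"]), unname(part2$otu["b"]))
  expect_equal(unname(part2$otu["c"]), unname(part2$otu["d"]))
  expect_false(part2$otu[["a"]] == part2$otu[["c"]])
})

test_that("complete linkage at the 3% cut matches the brute-force agglomerative oracle", {
  # A~B 97%, B~C 97%, A~C 94% by construction
  withr::with_seed(47, {
    B <- random_dna_str(300)
    pos <- sample(300, 18)
    A <- mutate_positions(B, pos[1:9])
    C <- mutate_positions(B, pos[10:18])
  })
  part <- clusterOTUs(c(A = A, B = B, C = C))
  # complete linkage can merge {A,B} or {B,C}, never all three
  expect_equal(length(unique(part$otu)), 2L)
  expect_equal(sort(part$sizes), c(1L, 2L))
  expect_true(part$otu[["B"]] == part$otu[["A"]] ||
              part$otu[["B"]] == part$otu[["C"]])

  d <- 1 - outer(c(A = A, B = B, C = C), c(A = A, B = B, C = C),
                 Vectorize(function(x, y) overlapIdentity(x, y)$identity))
  oracle <- oracle_complete_linkage(d, h = 0.03 + 1e-9)
  # the two 0.03 merges are tied, so {A,B} and {B,C} are both valid complete-
  # linkage outcomes; the oracle must agree on the structure: one pair
  # containing B plus a singleton, never the 3-cluster
  expect_equal(sort(table(oracle), method = "radix"), sort(part$sizes),
               ignore_attr = TRUE)
  expect_true(oracle[2] == oracle[1] || oracle[2] == oracle[3])
  expect_false(oracle[1] == oracle[3])
})

test_that("raising the OTU identity threshold never decreases the OTU count", {
  withr::with_seed(53, {
    for (case in 1:10) {
      base <- random_dna_str(250)
      seqs <- vapply(1:8, function(i)
        mutate_positions(base, sample(250, sample(0:20, 1))), "")
      names(seqs) <- sprintf("r%d", 1:8)
      counts <- vapply(c(0.90, 0.95, 0.97, 0.99, 1.0), function(th)
        length(unique(clusterOTUs(seqs, clusterParams(otuIdentity = th))$otu)),
        1L)
      expect_true(all(diff(counts) >= 0))
    }
  })
})

test_that("singleton fraction counts one-read OTUs", {
  expect_equal(singletonFraction(list(sizes = c(2L, 3L, 5L))), 0)
  expect_equal(singletonFraction(list(sizes = rep(1L, 4))), 1)
  expect_equal(singletonFraction(list(sizes = c(1L, 1L, 1L, rep(2L, 7)))), 0.3)
})

test_that("an exact substring of one reference is classified to its genus with confidence 1", {
  comm <- ref_community()
  cls <- trainClassifier(comm)
  tmpl <- as.character(refSequences(comm))[[3]]
  withr::with_seed(59,
    a <- classifyReads(c(q = substr(tmpl, 50, 400)), cls))
  expect_equal(a$genus, "g_tax03")
  expect_equal(a$genus_conf, 1.0)
  expect_equal(a$depth, "genus")
  expect_equal(a$lineage,
               paste(as.vector(as.matrix(taxonomy(comm)[3, ])), collapse = ";"))
  expect_error(classifyReads("ACGT", list()), NULL)
})

test_that("random DNA is not confidently classified to genus level", {
  comm <- ref_community()
  cls <- trainClassifier(comm)
  withr::with_seed(61, {
    reads <- setNames(replicate(10, random_dna_str(350)),
                      sprintf("rnd%d", 1:10))
    a <- classifyReads(reads, cls)
  })
  # no discriminating signature words: bootstrap splits across genera
  expect_true(all(a$depth != "genus"))
})

test_that("chimeric reads between two same-family genera truncate at family or above", {
  comm <- ref_community()
  tx <- as.data.frame(taxonomy(comm))
  fams <- split(rownames(tx), tx$family)
  pair <- fams[[which(lengths(fams) == 2)[1]]]
  t1 <- as.character(refSequences(comm)[[pair[1]]])
  t2 <- as.character(refSequences(comm)[[pair[2]]])
  same_family <- tx[pair[1], "family"]
  n_trunc <- 0
  for (s in 1:20) {
    withr::with_seed(700 + s, {
      # junction near the middle so both halves contribute comparable numbers
      # of diagnostic words to the bootstrap
      cut1 <- sample(222:238, 1)
      chimera <- paste0(substr(t1, 1, cut1), substr(t2, cut1 + 1, 460))
      a <- classifyReads(setNames(chimera, "chi"), trainClassifier(comm))
    })
    rank_depth <- match(a$depth, c("domain", "phylum", "class", "order",
                                   "family", "genus"), nomatch = 0)
    if (rank_depth <= 5) n_trunc <- n_trunc + 1
    if (rank_depth >= 5) expect_equal(a$family, same_family)
  }
  expect_gte(n_trunc, 19)
})

test_that("confidence threshold extremes give full-depth and unclassified output", {
  comm <- ref_community(nTaxa = 6)
  tmpl <- substr(as.character(refSequences(comm))[[1]], 1, 300)
  withr::with_seed(67, {
    full <- classifyReads(c(q = tmpl),
                          trainClassifier(comm, classifierParams(
                            confidenceThreshold = 0)))
    none <- classifyReads(c(q = tmpl),
                          trainClassifier(comm, classifierParams(
                            confidenceThreshold = 1.01)))
  })
  expect_equal(full$depth, "genus")
  expect_false(is.na(full$genus))
  expect_equal(none$depth, "unclassified")
  expect_equal(none$lineage, "unclassified")
})

test_that("abundance tables normalise per library and reject empty libraries", {
  labels <- c(rep("X", 80), rep("Y", 20))
  se <- abundanceTable(labels, rep("L1", 100))
  expect_equal(unname(relAbundance(se)["X", "L1"]), 80)
  expect_equal(unname(relAbundance(se)["Y", "L1"]), 20)
  expect_equal(unname(colSums(relAbundance(se))), 100, tolerance = 1e-9)
  expect_error(abundanceTable(character(), character()), "no reads")
  expect_error(tabulateAbundance(data.frame(phylum = "P"), "L1",
                                 rank = "species"), "arg")
})

test_that("error-free libraries recover genus fractions within multinomial 3 sigma", {
  comm <- buildMockCommunity(nTaxa = 8, seed = 71)
  reads <- simulateReads(comm, 2000, "ACGAGTGCGT", perfectErrorModel(),
                         seed = 73)
  qc <- runQC(reads, data.frame(libraryId = "L1", mid = "ACGAGTGCGT"))
  o <- orientReads(qc$libraries$L1)
  cls <- trainClassifier(comm)
  withr::with_seed(79, a <- classifyReads(o, cls))
  se <- tabulateAbundance(a, rep("L1", nrow(a)), rank = "genus")
  rel <- relAbundance(se)[, 1] / 100
  n <- length(o)
  for (tid in taxonIds(comm)) {
    p <- unname(fractions(comm)[tid])
    got <- rel[paste0("g_", tid)]
    if (is.na(got)) got <- 0
    expect_lt(abs(got - p), max(3 * sqrt(p * (1 - p) / n), 3 / n),
              label = sprintf("taxon %s: |%.4f - %.4f|", tid, got, p))
  }
})
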