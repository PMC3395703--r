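# Error-free oriented reads tiled across a template: forward reads are
# prefixes, reverse reads are suffixes, mimicking post-QC oriented input.
tile_reads <- function(template, n, seed, min_len = 250, id_prefix = "r") {
  withr::with_seed(seed, {
    lens <- pmin(pmax(round(rnorm(n, 400, 50)), min_len), nchar(template))
    ori <- rep(c("forward", "reverse"), length.out = n)
    seqs <- ifelse(ori == "forward",
                   substr(template, 1, lens),
                   substr(template, nchar(template) - lens + 1,
                          nchar(template)))
    names(seqs) <- sprintf("%s%03d", id_prefix, seq_len(n))
    pyroReadSet(seqs, lapply(nchar(seqs), function(k) rep(40L, k)),
                orientation = ori)
  })
}

test_that("overlapIdentity agrees with the exhaustive offset-scan oracle", {
  a <- random_dna_str(120)
  expect_equal(overlapIdentity(a, a), list(overlap = 120L, identity = 1.0))

  # constructed 60-bp exact overlap, random elsewhere
  withr::with_seed(7, {
    core <- random_dna_str(60)
    x <- paste0(random_dna_str(80), core)
    y <- paste0(core, random_dna_str(80))
    ov <- overlapIdentity(x, y)
    expect_equal(ov$overlap, 60L)
    expect_equal(ov$identity, 1.0)

    # 100-bp overlap with 3 substitutions -> identity 0.97
    core2 <- random_dna_str(100)
    x2 <- paste0(random_dna_str(50), core2)
    y2 <- paste0(mutate_positions(core2, c(20, 50, 80)), random_dna_str(50))
    ov2 <- overlapIdentity(x2, y2)
    oracle <- oracle_best_overlap(x2, y2, minOverlap = 50)
    expect_equal(ov2$identity, 0.97)
    expect_equal(ov2$identity, oracle$identity)
    expect_equal(ov2$overlap, oracle$overlap)
  })
  expect_error(overlapIdentity("", "ACGT"), "non-empty")
})

test_that("error-free reads from one template assemble into one faithful contig", {
  withr::with_seed(11, template <- random_dna_str(520))
  reads <- tile_reads(template, 30, seed = 13)
  asm <- assembleContigs(reads)
  expect_equal(length(asm$contigs), 1L)
  expect_length(asm$unassembled, 0)
  cons <- as.character(consensusSequences(asm$contigs)[[1]])
  # consensus reconstructs the template exactly (superstring of all reads)
  expect_equal(cons, template)
  info <- contigInfo(asm$contigs)
  expect_equal(info$nReads, 30L)
  expect_equal(info$nForward + info$nReverse, 30L)
})

test_that("templates at 95% identity do not cross-join at the 98% threshold", {
  withr::with_seed(17, {
    t1 <- random_dna_str(500)
    t2 <- mutate_positions(t1, sample(500, 25))  # 95% identical
  })
  r1 <- tile_reads(t1, 25, seed = 19, id_prefix = "a")
  r2 <- tile_reads(t2, 25, seed = 23, id_prefix = "b")
  reads <- combinePyroReads(list(r1, r2))
  asm <- assembleContigs(reads)
  expect_equal(length(asm$contigs), 2L)
  for (m in as.list(contigMembers(asm$contigs))) {
    expect_true(all(startsWith(m, "a")) || all(startsWith(m, "b")))
  }
})

test_that("majority vote recovers the template from 1% substitution noise", {
  n_ok <- 0
  for (s in 1:20) {
    withr::with_seed(100 + s, {
      template <- random_dna_str(500)
      reads <- tile_reads(template, 20, seed = 200 + s)
      # add 1% substitution noise
      noisy <- vapply(as.character(readSequences(reads)), function(x) {
        k <- rbinom(1, nchar(x), 0.01)
        if (k == 0) x else mutate_positions(x, sample(nchar(x), k))
      }, "")
      names(noisy) <- names(reads)
      reads@sequences <- Biostrings::DNAStringSet(noisy)
    })
    asm <- assembleContigs(reads)
    # reads whose noise pushed them below the identity threshold stay out of
    # the dominant contig (single-pass greedy, no re-merging); the property
    # under test is that its majority-vote consensus is near-perfect
    main <- which.max(contigInfo(asm$contigs)$nReads)
    expect_gte(contigInfo(asm$contigs)$nReads[main], 12)
    cons <- as.character(consensusSequences(asm$contigs)[[main]])
    id <- overlapIdentity(cons, template)$identity
    if (id >= 0.995) n_ok <- n_ok + 1
  }
  expect_equal(n_ok, 20)
})

test_that("contig filtering applies the 20-read and both-orientation rules exactly", {
  mk_contig <- function(nf, nr) {
    n <- nf + nr
    new("ContigSet",
        consensus = Biostrings::DNAStringSet(c(c1 = random_dna_str(400))),
        contigInfo = S4Vectors::DataFrame(nReads = n, nForward = nf,
                                          nReverse = nr, row.names = "c1"),
        members = IRanges::CharacterList(list(c1 = sprintf("r%d", 1:n))))
  }
  expect_equal(length(filterContigs(mk_contig(10, 9))), 0L)   # 19 reads
  expect_equal(length(filterContigs(mk_contig(25, 0))), 0L)   # no reverse
  expect_equal(length(filterContigs(mk_contig(10, 10))), 1L)  # boundary
  expect_equal(length(filterContigs(mk_contig(1, 19))), 1L)
})

test_that("assembly conserves reads and is deterministic", {
  withr::with_seed(29, {
    t1 <- random_dna_str(500)
    t2 <- random_dna_str(480)
  })
  reads <- combinePyroReads(list(tile_reads(t1, 12, 31, id_prefix = "a"),
                                 tile_reads(t2, 4, 37, id_prefix = "b")))
  asm1 <- assembleContigs(reads)
  asm2 <- assembleContigs(reads)
  placed <- unlist(as.list(contigMembers(asm1$contigs)))
  expect_setequal(c(placed, asm1$unassembled), names(reads))
  expect_equal(length(placed) + length(asm1$unassembled), length(reads))
  expect_identical(as.character(consensusSequences(asm1$contigs)),
                   as.character(consensusSequences(asm2$contigs)))
  expect_identical(as.list(contigMembers(asm1$contigs)),
                   as.list(contigMembers(asm2$contigs)))
})

test_that("greedy co-membership matches the overlap-graph oracle on small instances", {
  for (s in 1:5) {
    withr::with_seed(300 + s, {
      k <- sample(2:3, 1)
      templates <- replicate(k, random_dna_str(500))
    })
    per <- sample(3:4, k, replace = TRUE)
    sets <- lapply(seq_len(k), function(i)
      tile_reads(templates[i], per[i], seed = 400 + 10 * s + i,
                 id_prefix = letters[i]))
    reads <- combinePyroReads(sets)
    stopifnot(length(reads) <= 12)
    asm <- assembleContigs(reads)
    # greedy membership as a partition vector
    memb <- setNames(rep(NA_integer_, length(reads)), names(reads))
    mem <- as.list(contigMembers(asm$contigs))
    for (ci in seq_along(mem)) memb[mem[[ci]]] <- ci
    memb[asm$unassembled] <- seq(1000, length.out = length(asm$unassembled))
    oracle <- oracle_overlap_components(as.character(readSequences(reads)))
    # same partition: co-membership agreement for every pair
    for (i in 1:(length(reads) - 1)) for (j in (i + 1):length(reads)) {
      expect_equal(unname(memb[i] == memb[j]),
                   unname(oracle[i] == oracle[j]),
                   info = sprintf("seed %d pair %d-%d", s, i, j))
    }
  }
})
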