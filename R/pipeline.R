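PIPELINE_STAGES <- c("simulate", "qc", "assemble", "classify", "digest", "stats")

#' Assemble a full pipeline configuration
#'
#' Collects every stage's parameter block with the workflow's canonical
#' defaults (250 bp length cut; 98% identity / 50 bp overlap / 20 reads and
#' both orientations for contigs; 97% OTU identity; 80% classifier
#' confidence; 100 RFU electropherogram threshold; top-20% Pareto-Lorenz
#' fraction; +/-3 bp fingerprint matching tolerance) plus the simulation
#' layout (community, libraries, depths) and a single global seed from which
#' per-stage, per-library sub-seeds are derived.
#'
#' @param seed global integer seed.
#' @param community list of [buildMockCommunity()] arguments.
#' @param libraries data.frame with columns \code{libraryId}, \code{mid},
#'   \code{replicateGroup}, \code{depth}.
#' @param simulate list: \code{shortReadRate}, \code{meanLength},
#'   \code{sdLength}.
#' @param errorModel list of [errorModel()] arguments.
#' @param qc,assembly,cluster,classifier,electrophoresis parameter lists from
#'   the respective constructors.
#' @param enzyme list: \code{name}, \code{site}, \code{cutOffset}.
#' @param rank taxonomic rank for abundance tabulation.
#' @param matchToleranceBp fingerprint matching tolerance (bp).
#' @param foTopFraction ranked-OTU fraction for the Pareto-Lorenz Fo.
#' @return nested list of class \code{PipelineConfig}.
#' @export
pipelineConfig <- function(seed = 1L,
                           community = list(nTaxa = 25L, dominance = 1,
                                            nPhyla = 6L),
                           libraries = data.frame(
                             libraryId = c("libA", "libB", "libC"),
                             mid = unname(rocheMIDs()[1:3]),
                             replicateGroup = "technical",
                             depth = 800L),
                           simulate = list(shortReadRate = 0.02,
                                           meanLength = 400, sdLength = 60),
                           errorModel = list(substitutionRate = 0.002,
                                             indelRate = 0.001,
                                             homopolymerMultiplier = 6),
                           qc = qcParams(),
                           assembly = assemblyParams(),
                           cluster = clusterParams(),
                           classifier = classifierParams(),
                           electrophoresis = electrophoresisParams(),
                           enzyme = list(name = "MspI", site = "CCGG",
                                         cutOffset = 1L),
                           rank = "phylum",
                           matchToleranceBp = 3L,
                           foTopFraction = 0.20) {
  cfg <- list(seed = as.integer(seed), community = community,
              libraries = as.data.frame(libraries), simulate = simulate,
              errorModel = errorModel, qc = unclass(qc),
              assembly = unclass(assembly), cluster = unclass(cluster),
              classifier = unclass(classifier),
              electrophoresis = unclass(electrophoresis), enzyme = enzyme,
              rank = rank, matchToleranceBp = as.integer(matchToleranceBp),
              foTopFraction = foTopFraction)
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Write / read a pipeline configuration (lossless YAML round trip)
#'
#' @param config a [pipelineConfig()] object.
#' @param path YAML file path.
#' @return \code{writePipelineConfig}: invisibly, the path;
#'   \code{readPipelineConfig}: the restored \code{PipelineConfig}.
#' @export
writePipelineConfig <- function(config, path) {
  x <- unclass(config)
  x$libraries <- as.list(as.data.frame(config$libraries))
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname writePipelineConfig
#' @export
readPipelineConfig <- function(path) {
  x <- yaml::read_yaml(path)
  x$libraries <- as.data.frame(x$libraries, stringsAsFactors = FALSE)
  do.call(pipelineConfig, x[setdiff(names(x), character())])
}

stage_file <- function(dir, ...) file.path(dir, paste0(...))

require_artifact <- function(path, stage, needed_from) {
  if (!all(file.exists(path)))
    stop(sprintf("stage '%s' requires outputs of stage '%s' (missing: %s)",
                 stage, needed_from,
                 paste(basename(path[!file.exists(path)]), collapse = ", ")))
}

read_reference_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  parts <- strsplit(names(x), " ")
  ids <- vapply(parts, `[[`, "", 1L)
  lin <- vapply(parts, `[[`, "", 2L)
  lintab <- do.call(rbind, strsplit(lin, ";"))
  colnames(lintab) <- TAXONOMIC_RANKS
  fr <- as.numeric(vapply(parts, `[[`, "", 3L))
  names(x) <- ids
  mockCommunity(x, DataFrame(lintab, row.names = ids), fr)
}

write_reference_fasta <- function(community, path) {
  tx <- as.data.frame(taxonomy(community))
  lin <- apply(tx[, TAXONOMIC_RANKS], 1, paste, collapse = ";")
  seqs <- refSequences(community)
  names(seqs) <- paste(taxonIds(community), lin,
                       signif(fractions(community), 8))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Run the pyrotag/T-RFLP pipeline
#'
#' Executes the requested stages in order — simulate, qc, assemble, classify,
#' digest, stats — handing artifacts over via files in \code{outputDir}, and
#' returns a manifest recording every output file with an MD5 checksum, the
#' per-stage object counts, the derived sub-seeds, and the full parameter
#' echo. Rerunning with the same configuration reproduces identical checksums
#' for all deterministic stages. A stage whose upstream artifacts are missing
#' raises a dependency error naming the stage.
#'
#' @param config a [pipelineConfig()] object.
#' @param outputDir output directory (created if needed).
#' @param stages subset of stages to run (default: all six).
#' @return list with \code{manifest} (data.frame stage, file, md5, n),
#'   \code{config} echo, and in-memory \code{results} per stage.
#' @export
runPipeline <- function(config, outputDir, stages = PIPELINE_STAGES) {
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  stages <- PIPELINE_STAGES[PIPELINE_STAGES %in% stages]
  dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
  libs <- config$libraries
  manifest <- list()
  results <- list()
  note <- function(stage, file, n) {
    manifest[[length(manifest) + 1L]] <<- data.frame(
      stage = stage, file = basename(file),
      md5 = unname(tools::md5sum(file)), n = n)
  }

  cfg_path <- stage_file(outputDir, "config.yaml")
  writePipelineConfig(config, cfg_path)
  note("config", cfg_path, NA_integer_)

  if ("simulate" %in% stages) {
    comm <- do.call(buildMockCommunity,
                    c(config$community,
                      list(seed = deriveSeed(config$seed, "community"))))
    model <- do.call(errorModel, config$errorModel)
    all_reads <- list()
    for (i in seq_len(nrow(libs))) {
      lib <- libs$libraryId[i]
      all_reads[[lib]] <- simulateReads(
        comm, depth = libs$depth[i], mid = libs$mid[i], model = model,
        seed = deriveSeed(config$seed, "simulate", lib), libraryId = lib,
        shortReadRate = config$simulate$shortReadRate,
        meanLength = config$simulate$meanLength,
        sdLength = config$simulate$sdLength)
    }
    raw <- combinePyroReads(all_reads)
    f_raw <- stage_file(outputDir, "raw_reads.fastq")
    writeFastq(raw, f_raw); note("simulate", f_raw, length(raw))
    f_ref <- stage_file(outputDir, "reference_synthetic.fasta")
    write_reference_fasta(comm, f_ref); note("simulate", f_ref, length(comm))
    f_truth <- stage_file(outputDir, "ground_truth.tsv")
    writeGroundTruth(comm, f_truth); note("simulate", f_truth, length(comm))
    f_map <- stage_file(outputDir, "mapping.tsv")
    writeMappingFile(libs[, c("libraryId", "mid", "replicateGroup")], f_map)
    note("simulate", f_map, nrow(libs))
    results$simulate <- list(community = comm, nReads = length(raw))
  }

  if ("qc" %in% stages) {
    f_raw <- stage_file(outputDir, "raw_reads.fastq")
    f_map <- stage_file(outputDir, "mapping.tsv")
    require_artifact(c(f_raw, f_map), "qc", "simulate")
    raw <- readFastqLibrary(f_raw)
    mapping <- utils::read.delim(f_map)
    params <- do.call(qcParams, config$qc)
    qc <- runQC(raw, mapping, params)
    for (lib in names(qc$libraries)) {
      f <- stage_file(outputDir, "qc_", lib, ".fastq")
      writeFastq(qc$libraries[[lib]], f)
      note("qc", f, length(qc$libraries[[lib]]))
      fo <- stage_file(outputDir, "qc_", lib, "_orient.tsv")
      utils::write.table(
        data.frame(read_id = names(qc$libraries[[lib]]),
                   orientation = readInfo(qc$libraries[[lib]])$orientation),
        fo, sep = "\t", quote = FALSE, row.names = FALSE)
      note("qc", fo, length(qc$libraries[[lib]]))
    }
    f_rep <- stage_file(outputDir, "qc_report.tsv")
    rep_df <- qc$report
    rep_df$unassigned_total <- attr(qc$report, "unassigned")
    utils::write.table(rep_df, f_rep, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    note("qc", f_rep, nrow(rep_df))
    results$qc <- qc
  }

  load_qc_library <- function(lib, stage) {
    f <- stage_file(outputDir, "qc_", lib, ".fastq")
    fo <- stage_file(outputDir, "qc_", lib, "_orient.tsv")
    require_artifact(c(f, fo), stage, "qc")
    reads <- readFastqLibrary(f, libraryId = lib)
    ori <- utils::read.delim(fo)
    reads@readInfo$orientation <- ori$orientation[match(names(reads),
                                                        ori$read_id)]
    reads
  }

  if ("assemble" %in% stages) {
    params <- do.call(assemblyParams, config$assembly)
    results$assemble <- list()
    for (lib in libs$libraryId) {
      reads <- orientReads(load_qc_library(lib, "assemble"))
      asm <- assembleContigs(reads, params)
      kept <- filterContigs(asm$contigs, params)
      f <- stage_file(outputDir, "contigs_", lib, ".fasta")
      cons <- consensusSequences(kept)
      info <- contigInfo(kept)
      names(cons) <- sprintf("%s reads=%d fwd=%d rev=%d", names(cons),
                             info$nReads, info$nForward, info$nReverse)
      Biostrings::writeXStringSet(cons, f)
      note("assemble", f, length(kept))
      fm <- stage_file(outputDir, "contigs_", lib, "_members.tsv")
      mem <- contigMembers(kept)
      memdf <- data.frame(
        contig = rep(names(mem), lengths(mem)),
        read_id = unlist(mem, use.names = FALSE))
      utils::write.table(memdf, fm, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      note("assemble", fm, nrow(memdf))
      results$assemble[[lib]] <- list(contigs = kept,
                                      unassembled = length(asm$unassembled))
    }
  }

  if ("classify" %in% stages) {
    f_ref <- stage_file(outputDir, "reference_synthetic.fasta")
    require_artifact(f_ref, "classify", "simulate")
    reference <- read_reference_fasta(f_ref)
    cls <- trainClassifier(reference, do.call(classifierParams,
                                              config$classifier))
    all_assign <- list()
    for (lib in libs$libraryId) {
      reads <- orientReads(load_qc_library(lib, "classify"))
      a <- withSeed(deriveSeed(config$seed, "classify", lib),
                    classifyReads(reads, cls))
      a$libraryId <- lib
      all_assign[[lib]] <- a
      f <- stage_file(outputDir, "taxonomy_", lib, ".tsv")
      utils::write.table(a[, c("read_id", "lineage", "depth")], f,
                         sep = "\t", quote = FALSE, row.names = FALSE)
      note("classify", f, nrow(a))
    }
    assign_df <- do.call(rbind, all_assign)
    se <- tabulateAbundance(assign_df, assign_df$libraryId,
                            rank = config$rank)
    f_ab <- stage_file(outputDir, "abundance_", config$rank, ".tsv")
    ab <- data.frame(taxon = rownames(relAbundance(se)),
                     relAbundance(se), check.names = FALSE)
    utils::write.table(ab, f_ab, sep = "\t", quote = FALSE, row.names = FALSE)
    note("classify", f_ab, nrow(ab))
    f_ct <- stage_file(outputDir, "abundance_counts_", config$rank, ".tsv")
    cts <- SummarizedExperiment::assay(se, "counts")
    utils::write.table(data.frame(taxon = rownames(cts), cts,
                                  check.names = FALSE),
                       f_ct, sep = "\t", quote = FALSE, row.names = FALSE)
    note("classify", f_ct, nrow(cts))
    results$classify <- list(assignments = assign_df, abundance = se)
  }

  if ("digest" %in% stages) {
    enz <- restrictionEnzyme(config$enzyme$name, config$enzyme$site,
                             config$enzyme$cutOffset)
    results$digest <- list()
    for (lib in libs$libraryId) {
      f_ct <- stage_file(outputDir, "contigs_", lib, ".fasta")
      require_artifact(f_ct, "digest", "assemble")
      cons <- Biostrings::readDNAStringSet(f_ct)
      if (!length(cons)) next
      tags <- strsplit(names(cons), " ")
      ids <- vapply(tags, `[[`, "", 1L)
      nread <- as.integer(sub("reads=", "", vapply(tags, `[[`, "", 2L)))
      nf <- as.integer(sub("fwd=", "", vapply(tags, `[[`, "", 3L)))
      nr <- as.integer(sub("rev=", "", vapply(tags, `[[`, "", 4L)))
      names(cons) <- ids
      cset <- new("ContigSet", consensus = cons,
                  contigInfo = DataFrame(nReads = nread, nForward = nf,
                                         nReverse = nr, row.names = ids),
                  members = CharacterList(lapply(nread, function(n)
                    character(n))))
      pf <- predictFingerprint(cset, enz, sampleId = lib)
      f <- stage_file(outputDir, "fingerprint_", lib, ".tsv")
      tab <- as.data.frame(trfTable(pf$fingerprint))
      utils::write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
      note("digest", f, nrow(tab))
      results$digest[[lib]] <- pf$fingerprint
    }
  }

  if ("stats" %in% stages) {
    f_ab <- stage_file(outputDir, "abundance_", config$rank, ".tsv")
    require_artifact(f_ab, "stats", "classify")
    ab <- utils::read.delim(f_ab, check.names = FALSE)
    relab <- as.matrix(ab[, -1, drop = FALSE])
    rownames(relab) <- ab$taxon
    div <- data.frame(
      libraryId = colnames(relab),
      shannonH = apply(relab, 2, function(x) shannonIndex(x)$shannon),
      richness = apply(relab, 2, function(x) shannonIndex(x)$richness),
      fo = apply(relab, 2, function(x) paretoLorenzFo(
        x, topFraction = config$foTopFraction)))
    f_div <- stage_file(outputDir, "diversity.tsv")
    utils::write.table(div, f_div, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    note("stats", f_div, nrow(div))
    results$stats <- list(diversity = div)
    if (ncol(relab) >= 2L) {
      f_ct <- stage_file(outputDir, "abundance_counts_", config$rank, ".tsv")
      require_artifact(f_ct, "stats", "classify")
      ctab <- utils::read.delim(f_ct, check.names = FALSE)
      counts <- as.matrix(ctab[, -1, drop = FALSE])
      rownames(counts) <- ctab$taxon
      sdres <- tryCatch({
        se <- SummarizedExperiment::SummarizedExperiment(
          assays = list(counts = counts, relab = relab))
        replicateSD(se)
      }, error = function(e) NULL)
      if (!is.null(sdres)) {
        f_sd <- stage_file(outputDir, "replicate_sd.tsv")
        utils::write.table(sdres$perBin, f_sd, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        note("stats", f_sd, nrow(sdres$perBin))
        results$stats$replicateSD <- sdres
      }
    }
    # side-by-side in-silico fingerprint summary when digests exist
    fp_files <- Sys.glob(stage_file(outputDir, "fingerprint_*.tsv"))
    if (length(fp_files)) {
      fps <- lapply(fp_files, utils::read.delim)
      fo_fp <- vapply(fps, function(tab) {
        x <- tab$abundance[!tab$pseudo & tab$abundance > 0]
        if (length(x) >= 2) paretoLorenzFo(x, config$foTopFraction)
        else NA_real_
      }, 1)
      cmp <- data.frame(
        libraryId = sub("^fingerprint_(.*)\\.tsv$", "\\1",
                        basename(fp_files)),
        foContigs = fo_fp)
      cmp$foPyrotag <- div$fo[match(cmp$libraryId, div$libraryId)]
      f_cmp <- stage_file(outputDir, "fo_comparison.tsv")
      utils::write.table(cmp, f_cmp, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      note("stats", f_cmp, nrow(cmp))
      results$stats$foComparison <- cmp
    }
  }

  manifest <- do.call(rbind, manifest)
  f_man <- stage_file(outputDir, "manifest.tsv")
  utils::write.table(manifest, f_man, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(manifest = manifest, config = config, results = results)
}

#' Generate on-disk demo datasets for the four study scenarios
#'
#' Writes FASTQ libraries, ground truth, mapping files and a YAML of expected
#' statistic ranges for one of four scenarios: \code{replicates} (three
#' biological-style libraries from jittered template pools plus three
#' technical-style libraries from one fixed pool), \code{spiking} (four
#' amendment levels times two replicate series), \code{pseudo_trf} (a
#' community whose dominant template carries a secondary restriction site so
#' that partial digestion produces an in-vivo-only pseudo-T-RF), and
#' \code{two_step} (paired libraries differing only in a 5x short-read rate).
#' Byte-identical for a fixed seed.
#'
#' @param scenario one of "replicates", "spiking", "pseudo_trf", "two_step".
#' @param seed integer seed.
#' @param dir output directory.
#' @param depth reads per library.
#' @return invisibly, a list describing the written files.
#' @export
makeFixtures <- function(scenario = c("replicates", "spiking", "pseudo_trf",
                                      "two_step"),
                         seed = 1L, dir, depth = 1200L) {
  scenario <- match.arg(scenario)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  model <- errorModel()
  mids <- rocheMIDs()
  written <- list(scenario = scenario, files = character())
  add <- function(f) written$files <<- c(written$files, f)
  emit <- function(reads, lib) {
    f <- file.path(dir, paste0(lib, ".fastq"))
    writeFastq(reads, f); add(f)
  }
  base <- buildMockCommunity(nTaxa = 20L, dominance = 1,
                             seed = deriveSeed(seed, scenario, "community"))

  if (scenario == "replicates") {
    mapping <- data.frame(
      libraryId = c(paste0("bio", 1:3), paste0("tech", 1:3)),
      mid = unname(mids[1:6]),
      replicateGroup = rep(c("biological", "technical"), each = 3))
    for (i in 1:3) {
      # biological replicate: jitter the template pool (extract-to-extract
      # variability), technical replicate: same pool, new library
      jit <- withSeed(deriveSeed(seed, "biojitter", i),
                      fractions(base) * exp(rnorm(length(base), 0, 0.15)))
      bio <- mockCommunity(refSequences(base), taxonomy(base), jit)
      emit(simulateReads(bio, depth, mapping$mid[i], model,
                         seed = deriveSeed(seed, "bio", i),
                         libraryId = mapping$libraryId[i]),
           mapping$libraryId[i])
      emit(simulateReads(base, depth, mapping$mid[i + 3], model,
                         seed = deriveSeed(seed, "tech", i),
                         libraryId = mapping$libraryId[i + 3]),
           mapping$libraryId[i + 3])
    }
    expected <- list(maxTechnicalPhylumSDPct = 2.0,
                     maxBiologicalPhylumSDPct = 4.3)
  } else if (scenario == "spiking") {
    design <- spikeDesign(buildSpikeTaxon(deriveSeed(seed, "spike")),
                          replicateSeeds = c(deriveSeed(seed, "series", 1),
                                             deriveSeed(seed, "series", 2)))
    levels <- design@amendmentFractions
    mapping <- data.frame(
      libraryId = sprintf("spk%s_r%d", rep(c("0", "02", "2", "20"), 2),
                          rep(1:2, each = 4)),
      mid = unname(mids[1:8]),
      replicateGroup = rep(c("series1", "series2"), each = 4))
    mapping$amendmentFraction <- rep(levels, 2)
    k <- 0L
    for (r in 1:2) for (l in seq_along(levels)) {
      k <- k + 1L
      pool <- spikePool(base, design, levels[l])
      emit(simulateReads(pool, depth, mapping$mid[k], model,
                         seed = deriveSeed(seed, "spiking", r, l),
                         libraryId = mapping$libraryId[k]),
           mapping$libraryId[k])
    }
    expected <- list(minRSquared = 0.99, slopeRange = c(0.9, 1.1))
  } else if (scenario == "pseudo_trf") {
    base <- pseudoTrfCommunity(deriveSeed(seed, "ptrf"))
    mapping <- data.frame(libraryId = "ptrf1", mid = unname(mids[1]),
                          replicateGroup = "fingerprint")
    emit(simulateReads(base, depth, mapping$mid[1], model,
                       seed = deriveSeed(seed, "ptrf", "reads"),
                       libraryId = "ptrf1"), "ptrf1")
    expected <- list(primaryTrfBp = 208, pseudoTrfBp = 285)
  } else { # two_step
    mapping <- data.frame(libraryId = c("step1", "step2"),
                          mid = unname(mids[1:2]),
                          replicateGroup = c("onestep", "twostep"))
    emit(simulateReads(base, depth, mapping$mid[1], model,
                       seed = deriveSeed(seed, "step", 1),
                       libraryId = "step1", shortReadRate = 0.02), "step1")
    emit(simulateReads(base, depth, mapping$mid[2], model,
                       seed = deriveSeed(seed, "step", 2),
                       libraryId = "step2", shortReadRate = 0.10), "step2")
    expected <- list(shortReadRateRatio = 5)
  }
  f_map <- file.path(dir, "mapping.tsv")
  utils::write.table(mapping, f_map, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  add(f_map)
  f_truth <- file.path(dir, "ground_truth.tsv")
  writeGroundTruth(base, f_truth); add(f_truth)
  f_ref <- file.path(dir, "reference_synthetic.fasta")
  write_reference_fasta(base, f_ref); add(f_ref)
  f_exp <- file.path(dir, "expected_ranges.yaml")
  yaml::write_yaml(expected, f_exp); add(f_exp)
  invisible(written)
}

# A small community whose dominant taxon carries an MspI site at fragment
# coordinate 208 and a secondary site at 285 (the worked pseudo-T-RF pair).
pseudoTrfCommunity <- function(seed = 1L) {
  comm <- buildMockCommunity(nTaxa = 4L, dominance = Inf, seed = seed,
                             siteProb = 0)
  seqs <- as.character(refSequences(comm))
  s <- seqs[[1]]
  # scrub accidental sites, then place CCGG so cuts fall at 208 and 285 bp
  repeat {
    hits <- gregexpr("CCGG", s, fixed = TRUE)[[1]]
    if (hits[1] == -1) break
    substr(s, hits[1], hits[1]) <- "T"
  }
  substr(s, 208L, 211L) <- "CCGG"   # 0-based index 207 + offset 1 -> 208 bp
  substr(s, 285L, 288L) <- "CCGG"   # secondary site -> 285 bp pseudo-T-RF
  seqs[[1]] <- s
  fr <- c(0.55, rep(0.15, 3))
  mockCommunity(seqs, taxonomy(comm), fr)
}
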