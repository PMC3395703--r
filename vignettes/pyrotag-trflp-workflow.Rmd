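---
title: "Cross-validating pyrotag libraries and T-RFLP fingerprints: methods and design"
author: "pyrotagkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-validating pyrotag libraries and T-RFLP fingerprints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pyrotagkit)
```

# Scope and model

`pyrotagkit` models the analysis chain used to cross-validate barcoded 454
amplicon ("pyrotag") sequencing of bacterial 16S rRNA genes against T-RFLP
fingerprinting of the same amplicon pools, and to quantify two properties of
amplicon sequencing: the reproducibility of relative read abundances across
replicate libraries, and the linear recovery of templates spiked into the
pool at known fractions. All wet-lab steps (extraction, PCR chemistry,
emulsion PCR, the sequencer's own signal processing) are out of scope; the
package starts from reads with per-base qualities and from known template
fractions, which a simulator supplies with full ground truth.

The workflow is: simulate (or read) barcoded bidirectional libraries →
demultiplex, trim and filter → either (a) classify reads and tabulate
abundances, or (b) assemble forward/reverse reads into contigs, predict
terminal restriction fragments (T-RFs) in silico and compare them with an
(emulated) in-vivo electropherogram → compute community statistics.

# The simulator: what it emulates, and what it does not

`buildMockCommunity()` generates a pool of reference amplicon templates
emulating a moderately diverse sediment community: `nTaxa` (default 25) taxa
whose fractions are a symmetric Dirichlet draw (concentration `dominance`,
default 1, sorted descending — with 25 taxa the most abundant taxon sits
around 10–15%, i.e. several dominant lineages and a long rare tail), spread
round-robin over 6 phyla with two genera per family. Each template runs from
the forward primer (Ba27f, `AGAGTTTGATCMTGGCTCAG`) to the
reverse-complemented reverse primer (Ba519r, `TATTACCGCGGCKGCTG`) with a
450–550 nt distance between the primer 5′ ends, contains a forced internal
MspI site with probability 0.9, and carries a 60-nt genus "signature" block
at a fixed offset. The signature is what gives the k-mer classifier a
learnable taxonomy over otherwise random DNA; it is the simulator's
substitute for real phylogenetic signal. `reweightPhyla()` can pin the phylum
totals to a fixed profile when a study condition requires it (e.g. "dominant
phylum near 30%").

`simulateReads()` draws reads multinomially from the template fractions —
i.e. template molecules are assumed well-mixed and amplification unbiased;
per-library template molecule counts are not modelled. Orientation is
Bernoulli(1/2); a read is MID + primer + a template prefix (forward) or MID +
primer + reverse-complemented template prefix (reverse). Post-primer lengths
are Gaussian (mean 400 nt, sd 60, truncated to [150, template length]), with
a separate short-read mode (mean 180 nt) entered with probability
`shortReadRate`: 0.02 by default and 0.10 to emulate 2-step-PCR libraries,
which carry roughly five times more sub-250-bp reads. The error model is
454-flavoured: substitutions at 0.002/base, indels at 0.001/base multiplied
by 6 inside homopolymer runs of length ≥ 3 (insertions duplicate the current
base, deletions drop it), and Phred qualities decaying quadratically from 37
to 18 on a 500-nt scale with sd-3 noise. Error rates and qualities are
*independent* — qualities shape trimming, they do not modulate where errors
fall. Not modelled: chimeras, MID-specific amplification bias, flowgram-level
artefacts. Passing tests on these simulations therefore demonstrate the
correctness and internal consistency of the pipeline under multinomial
sampling with 454-like noise, not robustness to PCR chimeras or primer bias
in real extracts.

# Quality control

Reads are demultiplexed by exact MID prefix match by default (a read matching
no MID, or more than one within the allowed mismatches, is unassigned; the
MID is stripped). Trimming is 3′-only: the read is cut at the end of the last
sliding window (size 10) whose mean Phred is ≥ 20. The published workflow
used an external trimmer whose internals are not specified; windowed
mean-quality trimming matches its intent (confidence-based trimming) and is
idempotent and monotone, which the tests verify. After trimming, a read is
retained iff a primer matches IUPAC-aware at the read start (exact by
default) and the read is at least 250 bp long. Two conventions had to be
fixed: the length cut is *inclusive* (a 250 bp read survives, "shorter than
250 bp" is excluded), and length is measured post-trim with the primer
included but the MID removed. Both are configurable (`qcParams()`).

# Assembly

`assembleContigs()` is a deterministic greedy consensus assembler. Reads
(already oriented to the forward strand) are processed longest-first with
id-lexicographic tie-breaks; the longest unplaced read seeds a contig and
every remaining read joins if its semi-global overlap with the *current*
consensus spans ≥ 50 columns at gapped identity ≥ 0.98 (matches / aligned
columns, internal gaps counting as mismatches, end gaps free — computed with
`Biostrings::pairwiseAlignment(type = "overlap")`). "Sequence similarity" was
decided to be consensus-based gapped identity because the original
assembler's measure is undocumented; pairwise-to-consensus matches common
amplicon assembler practice. The consensus is recomputed per-column after
each merge: majority base, ties broken by summed base quality then
alphabetically; columns where the gap row wins are dropped; read insertions
relative to the consensus are discarded (at the modelled indel rates a shared
insertion column is vanishingly rare; the package does not realign).
Contigs are built in a single pass — no post-hoc contig merging — and reads
that end up alone stay in the unassembled pool. `filterContigs()` applies the
read-support rule: ≥ 20 member reads and at least one read in each
orientation. The 20-read cut-off is fixed by default (a library-size-specific
threshold is a known limitation of the modelled workflow) but exposed.

# OTUs and taxonomy

OTU clustering dereplicates identical sequences, computes pairwise distances
as 1 − overlap identity on the mutual overlap region (so that a short read
nested in a long one is not penalised for length), clusters hierarchically
and cuts at 1 − 0.97. The linkage is *complete* by default: the source
workflow says only "linkage clustering", and complete linkage is the
conservative reading (it never lumps reads below the threshold); `single` and
`average` are available as flags.

The classifier is a deliberately minimal RDP-style bootstrap naive Bayes:
8-mer word presence, genus conditionals `(m + Pw)/(M + 1)` against a word
prior `Pw = (n + 0.5)/(N + 1)`, uniform genus priors, and 100 bootstrap
resamples each drawing ⌊words/8⌋ words; the reported lineage is truncated at
the deepest rank whose bootstrap agreement reaches 0.80. Reads that fail at
the domain rank are "unclassified". Fidelity to the original training corpus
is a non-goal: the intended training set is the simulator's own reference
community, and tests exercise the classifier's *behaviour* (perfect-signal
reads classify to genus at confidence 1; random DNA and balanced chimeras
truncate above genus; threshold 0 forces full depth, threshold > 1 forces
unclassified). Reverse reads are reverse-complemented before classification
(orient-then-classify): the source workflow classified "combined forward and
reverse reads" without stating the orientation handling, and a k-mer
classifier has no strand invariance, so orienting first is the only
consistent choice.

# In-silico T-RFLP

T-RF lengths are counted from the 5′ base of the labelled forward primer; a
cut at recognition-site offset `cutOffset` (MspI: C^CGG, offset 1) yields a
primary fragment of length (0-based site index + offset). Downstream sites
give *pseudo-T-RFs* — fragments observed when the first site escapes
digestion. The fragment-length convention of the reference prediction tool is
not printed anywhere authoritative, so the cut offset is exposed
(`restrictionEnzyme()`) for calibration; under this convention the worked
secondary-site example (primary cut at 208 bp, secondary at 285 bp)
reproduces exactly. `predictFingerprint()` weights each retained contig's
primary T-RF by member-read count, merges equal lengths and normalises to
100%; secondary sites travel along as zero-abundance pseudo rows so that the
matcher can attribute in-vivo-only peaks. `emulateElectropherogram()` adds
the in-vivo artefacts the comparison has to survive: integer size drift
(default ±3 bp), signal scaling, Gaussian noise, the 100 RFU peak threshold,
and optional partial digestion emitting pseudo peaks at a configurable
fraction of the parent signal. `matchFingerprints()` pairs observed with
predicted primary fragments greedily by smallest |Δbp| within tolerance (ties
toward the smaller fragment — optimal for 1-D non-crossing matchings), and
flags unmatched observed peaks lying within tolerance of a predicted
secondary site as pseudo-T-RF candidates with their parent fragment. One
caveat is documented rather than modelled: in-vivo fingerprinting may use a
longer amplicon (e.g. a 907r reverse primer) than the pyrotag contigs cover,
so restriction sites beyond the contig end are invisible to the prediction.

# Statistics

Shannon H′ is computed in natural logarithms on renormalised proportions
(zeros dropped; the log base is a flag, since conventions differ). Sørensen
similarity is incidence-based, 2|A∩B|/(|A|+|B|), matching its use for OTU
overlap between replicates. The Pareto-Lorenz functional organisation Fo is
the cumulative relative abundance of the most abundant 20% of OTUs, read off
the Lorenz polyline with linear interpolation at non-integer ranks (0.20 for
a perfectly even community; ~0.25/0.45/0.80 mark low/medium/high
organisation). Replicate SDs are sample standard deviations of relative
abundance in percentage points (not counts), computed per taxon across
replicate libraries after excluding taxa averaging under one read per
library, and binned by mean abundance into right-open bins <0.3% / <2% /
<10% / >10%. Spike recovery regresses recovered on nominal fraction on the
linear proportion scale by OLS with zero-amendment libraries included, which
is how a single R² across all levels (including 0%) is defined; a response
with zero variance reports R² = 0 rather than a 0/0 artefact.

# Pipeline, seeds and numerical choices

`runPipeline()` executes the six stages (simulate, qc, assemble, classify,
digest, stats) with file-based hand-offs, records every output file with an
MD5 checksum in a manifest alongside the full parameter echo, and derives all
per-stage, per-library seeds from one global seed by stable string hashing
(`deriveSeed()`, polynomial rolling hash mod 2³¹−1) so that streams are
independent but reproducible — identical configurations reproduce identical
checksums, which the tests assert. `makeFixtures()` writes the four demo
scenarios (replicate series, spiking series, pseudo-T-RF community, 1- vs
2-step short-read rates) as FASTQ + ground truth + expected-range files.
Degenerate inputs fail loudly rather than silently: empty pools, empty
libraries, all-zero abundance vectors, single-column replicate tables and
fingerprints without an anchored primer all raise errors (or a counted
warning, for skipped contigs).

Problem sizes in the test-suite simulations are scaled to what the
statistics need rather than to sequencing-run scale: reproducibility is
checked on three 10,000-read technical replicates (the depth at which the
modelled workflow reports a 2-percentage-point maximum phylum-level SD),
spike recovery on duplicate 8,000-read series over amendment fractions
0/0.002/0.02/0.20, assembly recovery on 150–200-read libraries, and
stochastic properties (multinomial consistency, recovery linearity) on 10–50
seeded repetitions of the relevant generator.

# Known limitations

* The simulator's taxonomy is synthetic; classifier accuracy on it says
  nothing about accuracy against a real reference database.
* Consensus assembly drops read insertions and does not realign or re-merge
  contigs; at indel rates far above the 454-like defaults the consensus can
  degrade.
* Fingerprint matching is one-to-one; co-migrating populations sharing a
  T-RF are merged upstream (by length) rather than resolved.
* qPCR quantification of spike templates is modelled as exact knowledge of
  the amendment fraction.
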