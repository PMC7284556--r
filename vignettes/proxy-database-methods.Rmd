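---
title: "Building and evaluating proxy protein search databases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and evaluating proxy protein search databases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proxydb)
library(tibble)
```

## The problem

Tandem mass spectrometry identifies peptides by matching spectra against a
protein sequence database. For organisms without a curated proteome — most
tree nuts among them — that database must be *constructed* from whatever
sequence is available: a genome (via six-frame translation), or an assembled
transcriptome (via ORF extraction). The choices made along the way — how
reads are trimmed and normalized before assembly, how ORFs are extracted,
how databases are deduplicated and sized — propagate directly into which
peptides can be identified downstream, which matters acutely when the
proteins of interest are highly abundant seed-storage families (vicilins,
legumins, 11S globulins) targeted for allergen marker development.

proxydb implements that construction and evaluation workflow end to end at
the peptide level, with a seeded synthetic-data generator so every claim the
package makes can be exercised on a desk without external downloads or a
search engine.

## Database construction

**Six-frame translation** (`six_frame_translate()`) translates each input
sequence in all six reading frames and splits each frame's translation at
stop codons, keeping every maximal stop-free segment of at least `min_len`
residues (default 7 aa, about the shortest tryptic peptide a search engine
scores usefully). Codons containing ambiguity codes translate to `X`;
segments are split **only at stops, not at X runs**, because an `X` blocks
exact peptide matching locally without invalidating flanking sequence.
Segment ids (`source|frame|nt_start`) keep accessions unique and traceable,
and segment coordinates are forward-strand, half-open, including the
terminating stop codon when present — re-translating the recorded interval
reproduces the segment, which the test suite verifies.

**Genome chunking** (`split_genome_chunks()`) splits large genome sequences
before translation. The upstream chunking tool this mirrors does not
document its defaults, so we fix chunk size 100,000 nt and overlap 120 nt:
any window of up to `overlap + 1` nt lies wholly within some chunk, so no
peptide of up to 40 residues (120 nt) can be lost at a chunk boundary. The
property is proved by stepping arithmetic and checked exhaustively on random
genomes in the tests.

**ORF extraction** (`extract_orfs()`) reports, per frame, the maximal ORF in
each stop-delimited segment: from the first ATG after the previous stop when
`require_start = TRUE`, or from the segment start (open 5' end) when
`require_start = FALSE` — the latter models truncated transcripts whose
coding region begins upstream of the assembled fragment. The default
`min_aa = 100` matches common ORF-finder defaults; the coding-likelihood
scoring of full Transdecoder-style tools is out of scope.

**Database assembly** (`protein_db()`, `dedup_exact()`,
`concat_databases()`, `pad_to_target()`). Deduplication removes only
byte-identical sequences, keeping the first occurrence; absorbing exact
substrings into longer records (which clustering tools at 100% identity may
also do) is deliberately not the default since the two behaviors differ in
what peptides survive. Databases are compared fairly by **residue-equalized
sizing**: filler (e.g. bacterial) records are appended until the next whole
record would overshoot the target, then a prefix of the next record
(`_trunc`) lands the total residue count exactly on target. Exactness is the
documented choice — sizing practice in this field reports matched residue
counts without stating the mechanism used to land on them. Provenance tags (`subject`, `contaminant`,
`filler`) travel with every record so peptide accounting can exclude
non-subject sequence.

## Peptide-level evaluation

**Digestion** (`tryptic_digest()`, `digest_database()`) enumerates fully
tryptic peptides (cleavage C-terminal of K/R, suppressed before proline as
Mascot-style trypsin does) with up to 2 missed cleavages, length bounds
6–60 aa. The bounds are configurable to off; they are our defaults, not a
claim about any particular search engine configuration. At zero missed
cleavages the peptides partition the protein, and the count of m-missed
peptides equals (segments − m); both identities are tested against a
brute-force enumerator.

**Masses** (`peptide_mass()`) are monoisotopic, with carbamidomethyl
(+57.02146 Da) fixed on every cysteine and oxidation (+15.99491 Da) variable
on methionine — the modification set under which the workflow's search
results are interpreted.

**Identification filtering** (`filter_identifications()`) applies the two
experiment-level rules in order: drop peptides with fewer than 2 spectral
counts, then drop peptides all of whose parsimony-assigned proteins retain
fewer than 2 supporting peptides. The steps run **once, not to a fixpoint**
— the rule as commonly stated names the order but not iteration, so single
application is the documented default and `iterate = TRUE` is available. A
second full pass can remove more (the first pass may drop a protein's
support below threshold); this is asserted explicitly in tests as the chosen
semantics.

**Parsimony inference** (`parsimony_proteins()`) is minimum set cover.
The default is greedy — repeatedly take the protein covering the most
uncovered peptides, ties broken by more total matched peptides then
lexicographic id — which scales to real identification sets.
`method = "exact"` enumerates subsets in increasing size and certifies a
minimum for small instances. *Known limitation:* greedy set cover is not
guaranteed optimal; on adversarial instances it can retain one more protein
than the certified minimum (we observe this on roughly 1% of dense random
instances at desk scale), which is inherent to the algorithm rather than a
defect of this implementation. Applications needing certified minima on
small sets should pass `method = "exact"`.

**Classifying database-unique peptides.** A peptide identified against one
database but absent from another is diagnosed by precedence
(`detect_sav()`): *exact* (present fully tryptically), *internal SAV* (a
same-length reference tryptic peptide at Hamming distance exactly 1 — the
variant position is reported), *flanking cleavage SAV* (exact substring that
fails the tryptic boundary test: the variation sits in the adjacent cleavage
site), or *absent*. Insertions and deletions are out of scope — only single
amino acid variations are modeled. `terminal_fragment_check()` flags
peptides abutting a translated transcript's terminus, the signature of a
fragmented or misassembled transcript; such peptides are typically not fully
tryptic in the reference sense.

## Read processing

**Quality trimming** (`quality_trim()`) removes leading/trailing bases below
the phred threshold, then cuts at the first sliding window (default width 4)
whose mean falls below it, dropping reads shorter than 36 bases. The
workflow's two regimes of interest are strict (phred 35) and relaxed (phred
5) trimming; only the threshold is prescribed upstream, so the step order is
our documented choice matching common Trimmomatic usage.

**Normalization** (`normalize_reads()`) counts canonical kmers (k = 25,
lexicographic minimum of kmer and reverse complement) over the read set and,
per read pair, (1) eliminates pairs whose kmer-coverage percent standard
deviation exceeds `max_pct_stdev`, and (2) keeps survivors with probability
`min(1, target_cov / median)`. The statistic is
`100 * sample sd / mean` of the read's kmer coverages, with the lower-middle
median convention; the normalizer this models does not document its exact
formula, so ours is fixed and stated here. Pairs are decided jointly (mean
of medians, max of pct_stdevs) to avoid orphaned mates. One uniform draw is
consumed per pair in input order regardless of the aberrant-filter outcome,
making kept sets at different thresholds directly comparable under one seed
— the threshold-monotonicity the tests assert would otherwise be confounded
by stream drift.

Why the aberrant filter matters: a read with one substitution error carries
a block of singleton kmers inside otherwise high-coverage kmers; with
`max_pct_stdev = 100` such mixed profiles (more than half the kmers
aberrant) are eliminated, while `10000` effectively retains everything. On
synthetic reads the error-containing fraction among kept reads is
consistently lower at 100 than at 10,000, which is the mechanism behind
preferring the stricter setting.

## Assembly quality metrics

`n50()` is definitional (sort descending, first length where the cumulative
sum reaches half the total). `contiguity_coverage()` counts reference
proteins covered along at least 90% of their length by a *single* transcript
at 100% identity, implemented as the longest exact common substring between
the protein and any six-frame translation segment of any one transcript
(binary search over substring length against the segment set). Multi-segment
union coverage and mismatch tolerance are deliberately excluded: the
upstream coverage estimate is a single-top-hit calculation, and "100%
sequence similarity" leaves no room for mismatches.

## The synthetic generator

`simulate_proteome()` draws proteins from a log-normal length model (median
about 300 aa, floor 30 aa), initial methionine, K+R frequency 12% so tryptic
peptides of useful length exist, with a few storage-like records drawn 1.5×
longer at 10× abundance — emulating the two-tier abundance structure of nut
seed proteomes. `simulate_genome()` back-translates with uniform synonymous
codons (no codon-bias model; exact-match testing does not need one) and can
insert GT..AG introns between codons, so peptides spanning exon junctions
vanish from the genome's six-frame translation exactly as expected.
`simulate_transcriptome()` introduces amino-acid-changing single-nucleotide
variants per residue at `sav_rate` and truncates transcripts with
probability `fragmentation_rate` (a uniform 0.2–0.8 fraction removed from a
random end at nucleotide resolution) — fragmentation and SAVs are the two
transcript pathologies the evaluation modules diagnose, and truncation
naturally produces terminal, non-tryptic peptides. `simulate_reads()`
produces 85 bp paired reads with substitution errors at 0.1% per base by
default (typical of Illumina data; 0.3% is used in the enrichment
experiments to make effects visible at small scale), with errors assigned
phred ~ Uniform(2, 20) versus Uniform(30, 40) for correct bases — crude, but
sufficient for strict and relaxed trimming to behave differently.
`simulate_observations()` samples peptides from the true proteome's digest
with probability `1 − exp(−depth × abundance)` and spectral counts
`1 + Poisson(depth × abundance)`, then intersects the observed set with each
candidate database's fully tryptic index. No spectra are modeled; chimeric
misassembly beyond truncation and indel errors are not simulated. Passing
tests on this generator therefore demonstrate the *construction and
evaluation logic*, not robustness to every pathology of real assemblies.

All generators are deterministic under their seeds.

## Worked example

```{r example}
cfg <- sim_config(seed = 42, n_proteins = 60)
pr <- simulate_proteome(cfg)
tr <- simulate_transcriptome(pr$db, cfg)
orfs <- extract_orfs(tr$transcripts, min_aa = 30, require_start = FALSE)
tx_db <- dedup_exact(protein_db(tibble(id = orfs$id, seq = orfs$aa_seq)))
obs <- simulate_observations(pr$db, pr$abundance,
                             list(proteome = pr$db, transcriptome = tx_db),
                             seed = 42)
sapply(obs$observations, nrow)
cmp <- compare_peptide_sets(obs$observations)
cmp
```

Peptides identified only against the proteome concentrate where transcripts
were truncated; `detect_sav()` and `terminal_fragment_check()` attribute
transcriptome-only peptides to variants and fragment termini respectively.

## Numerical and scale choices

Problem sizes in the tests and acceptance script are chosen to exercise
every property at desk scale: 300-protein proteomes for the peptide-yield
comparison, about a dozen proteins at 100× read coverage for the
normalization enrichment, 1,000-case oracle sweeps for translation,
digestion, cover and N50 identities. Empty inputs, K/R-free proteins,
reads shorter than k, single-kmer reads and zero-deficit padding all have
defined behavior covered by tests. Ties in the greedy cover are broken
deterministically; the downsampling stream is seeded and consumed in input
order; all generator randomness is isolated so library code never perturbs
the caller's RNG state.
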