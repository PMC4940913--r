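---
title: "Counting GBS tags with indexing trees: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting GBS tags with indexing trees: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tagtally)
```

## The problem

In genotyping-by-sequencing (GBS) and RAD-seq, genomic DNA is digested
with one or two restriction enzymes, ligated to barcoded adapters, and
sequenced so that each read begins with an in-line sample barcode, the
cut-site remnant of the rare-cutting enzyme, and then the *tag*: the
genomic sequence adjacent to the cut site. Because the sequenced
fragments are a random sample of cut-site-adjacent loci, per-allele read
depth is the central quality statistic: a sample with 20 reads for one
allele and none for the other is a credible homozygote, while one read
versus zero may simply be an under-sampled heterozygote, and depth
ratios are what allow allele-dosage estimation in polyploids.

tagtally extracts exactly this quantity. Given a key file (which FASTQ
file and barcode correspond to which sample) and a tag set (which
marker and allele each expected tag sequence belongs to), it streams
FASTQ and produces a samples-by-tags matrix of integer read counts,
optionally a 0/1/2 diploid genotype matrix, per-sample demultiplexed
FASTQ for archiving, and a cross-project marker database with stable
universal names.

## The matching model

Matching is **exact and prefix-anchored**. Two recursive indexing trees
(tries over the A/C/G/T alphabet) are built before any FASTQ record is
touched: one over barcode+remnant concatenations, one over tag
sequences. For each read the barcode tree is walked from the first
nucleotide, one base at a time; on success the tag tree is walked from
the first base after the remnant (or from the remnant itself for
variable-site enzymes such as ApeKI, whose tags retain the variable
base). A full two-stage match increments exactly one (sample, tag)
cell; anything else is tallied as discarded. Three consequences of the
model are worth stating explicitly:

* **No mismatch tolerance.** A read with a sequencing error in the
  barcode/remnant/tag region is discarded rather than rescued; the
  assumption is that an erroneous read is unlikely to match any known
  tag, and quality scores are ignored for the same reason. Counts
  therefore underestimate depth slightly (by roughly the per-read error
  probability over the matched prefix), uniformly across alleles.
* **Bounded cost.** The walk examines at most as many nucleotides as
  the longest stored sequence, regardless of how many sequences are
  stored. This is asserted in the tests with an instrumented node-visit
  counter, and is what keeps per-read cost nearly flat from 100 to
  10,000 tags.
* **Longest match wins.** When one stored sequence is a proper prefix
  of another, the deepest terminal reached is reported. A read carrying
  the longer tag would otherwise be credited to the shorter one. Both
  insertion orders are tested to yield the same result.

Reads containing `N` fail at the decision point, as `N` labels an
unknown base and exact matching has no licence to guess.

## Genotype coding

When every marker is biallelic, per-sample allele counts `(c0, c1)`
are coded: both positive → heterozygous `1`; only allele `"0"` seen →
`0`; only allele `"1"` seen → `2`; neither → missing, exported blank.
Allele `"0"` is the alphabetically smaller tag except in input formats
where the user fixes the order by column or row. The coding itself uses
presence/absence with no depth threshold; `min_depth` optionally blanks
homozygous calls whose total depth falls below a cutoff, because a
shallow homozygote is indistinguishable from an under-sampled
heterozygote. The default is 0 (off): the coding rule is the contract,
and depth filtering is an analysis decision best made downstream with
the counts in hand.

Counts are plain integers with no ceiling; values far above 127
serialise exactly as computed, which matters for polyploid dosage and
bulked samples.

## Tunable parameters

| Parameter | Where | Default | Why |
|---|---|---|---|
| `min_overlap` | `split_fastq()`, `find_adapter_trim()` | 6 nt | chance of trimming random 3' sequence at any one position is 4^-6 ≈ 2.4×10^-4 |
| `min_depth` | `call_genotypes()` | 0 (off) | depth filtering is opt-in; the printed coding rule is the default contract |
| `max_alleles` | allele-block reader | 8 | loci with more distinct alleles than any credible ploidy are likely collapsed paralogs |
| universal-name padding | `consolidate()` | 6 digits | matches the customary `Prefix000102` layout; numbers past 999999 extend naturally |

## Demultiplexing choices

`split_fastq()` removes the barcode but **retains the cut-site
remnant**: downstream tools expect reads to start at the remnant, and
it is what lets a split file be re-counted in blank-barcode mode — the
package's two entry points must agree, and the test suite asserts
cell-for-cell equality between counting the multiplexed file and
counting its split products. Trimming order is barcode strip → chimera
truncation → adapter trim. A full restriction site inside a read
indicates a re-ligation chimera of two fragments, so sequence *after*
the leftmost internal site (searched from the first post-remnant
position) is removed while the site itself is kept — reading the rule
literally keeps trimming idempotent. The chimera site list per enzyme
pair is explicit in the registry; for PstI–MspI and NsiI–MspI it is the
two reconstituted recognition sites only, since the 3' overhangs of
PstI/NsiI cannot ligate to MspI's 5' overhang and no hybrid junction
can form. The barcode is appended to the end of the header comment
(`:<barcode>`), or an Illumina-style `1:N:0:<barcode>` comment is
created when the header has none; a blank barcode adds nothing, which
is again what idempotent re-splitting requires.

## Marker consolidation

Across projects, two markers are the same marker exactly when their
complete sorted sets of allele sequences are identical. A truncated tag
is a different tag: tag length carries information about the protocol
and read trimming, and merging truncations would conflate loci that are
only compatible, not identical. Matching is a binary search over
lexicographically sorted allele-set keys, checked in the tests against
a quadratic all-pairs oracle on 5,000 markers. Markers sharing *some*
but not all alleles are never merged silently; they get a new universal
name and a row in the conflict report (`db_conflicts()`), because no
printed rule adjudicates partial overlap and silent resolution in
either direction would be wrong for someone. The merged bracket
notation (`CCGATTAG[C/T]AGGGGTT`) is the storage format: compact,
re-importable, and readable by eye. FASTA export writes IUPAC codes at
substitution sites; alleles of unequal length cannot be expressed
positionwise, so allele 0's full sequence stands for the marker there.

## The synthetic-data generator

`generate_fixture()` emulates one multiplexed single-enzyme-pair GBS
lane fragment: by default 96 barcodes of mixed 4–8 nt length, 1,000
biallelic markers with 40–80 nt tags, and per-(sample, tag) depths
drawn from a negative binomial (mean 1, size 0.5), giving ≈192,000
reads in expectation — small enough to generate in seconds, large
enough that every code path (mixed barcode lengths, variable tag
lengths, depth heterogeneity, adapter read-through, chimeras) is
exercised. The negative binomial is a fixture choice that mimics the
strong depth dispersion of real GBS libraries, not a scientific claim.

The generator guarantees that planted truth is exact: tags and fillers
are drawn free of full restriction sites and of incidental adapter
content reaching into the barcode+remnant+tag core (a genuine GBS
fragment cannot contain an internal full site — the enzyme would have
cut there), no tag is a prefix of another, and when substitution errors
are injected, a mutated read is re-drawn if the error would recreate a
*different* registered barcode+remnant+tag combination — so errors can
only lose reads, never misassign them, and the truth table is exact by
construction rather than approximately right.

What the generator does **not** emulate: indels and structural errors,
quality-score profiles (the matcher ignores them), PCR duplicates,
barcode hopping, and variable read lengths. Passing the planted-truth
tests therefore demonstrates that the bookkeeping — matching, pooling,
tallying, trimming — is exact under the stated error model; it does not
certify genotype accuracy on real data, which is governed by depth and
library quality, not by this software.

## Numerical and degenerate-input choices

* Sequences are uppercased on ingest; `N` never matches; quality
  strings are carried, truncated in lockstep with sequences, never
  interpreted.
* Reads shorter than barcode+remnant+shortest-tag are ordinary
  no-matches, not errors; truncated FASTQ records (a final record with
  fewer than four lines) are errors with the file and record index.
* Counting holds only the two trees and the counts matrix in memory and
  streams FASTQ in 100,000-read chunks, so memory is independent of
  FASTQ size and no intermediate files are written; `.gz` input is
  decompressed on the fly.
* Tag columns are named `marker_variableBases_alleleName` (e.g.
  `TP1_A_0`); the name parses back from the right, so marker names may
  contain underscores. A deletion allele renders its variable field as
  `-`. The field order is a fixed arbitrary choice.
* Ties in cut-site search cannot occur at one position for the shipped
  site lists; were a registry extended so they could, the first site in
  registry order wins.
* The counting and splitting tests use fixtures of roughly 1,500 to
  200,000 reads; the oracle-equivalence suite uses 1,000 random tries
  of up to 200 tags against 10,000 reads each. These sizes were chosen
  so the full suite runs on a laptop in minutes while still exceeding
  the scale at which indexing bugs (prefix collisions, chunk
  boundaries, pooling) could hide.

## Known limitations

* Single-read, prefix-anchored: no paired-end awareness, no
  mismatch-tolerant matching, no de-novo SNP discovery — by design;
  discovery pipelines and this extractor are complementary.
* Catalog and allele-block dialects are validated against
  fixture files shaped like the producing programs' documented output;
  exotic column layouts from other versions of those programs may need
  the CSV routes instead.
* The interactive prompting style of shell tools in this niche is
  replaced by a flag-driven CLI (`inst/cli/tagtally.R`) whose error
  messages list the registered alternatives (enzymes, adapter sets), so
  a mistyped name is still a one-step fix.
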