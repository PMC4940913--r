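# tagtally

Per-allele read counts and numeric genotypes from multiplexed
genotyping-by-sequencing (GBS) and RAD-seq FASTQ files, by exact
prefix matching against recursive indexing trees — plus barcode
demultiplexing with adapter/chimera trimming and MD5 manifests, and
cross-project marker consolidation under stable universal names.

## Who this is for

In GBS/RAD-seq, each read starts with an in-line sample barcode, the
cut-site remnant of the restriction enzyme, and a *tag* — the genomic
sequence adjacent to the cut site, one tag per allele. Per-allele read
depth is the statistic that separates credible homozygotes from
under-sampled heterozygotes and underlies allele-dosage estimation in
polyploids, yet most discovery pipelines make it awkward to extract.
tagtally is for researchers who already have a set of markers (from
any of seven supported formats: paired-tag FASTA, alignment SAM,
catalog/allele files from de-novo pipelines, or three CSV layouts) and
want accurate, uncapped, spreadsheet-ready counts for those markers on
any set of samples — without re-running discovery, intermediate files,
or a compute cluster.

## The algorithm

Before any FASTQ record is read, two indexing trees (tries over
A/C/G/T) are built: one over barcode+remnant concatenations, one over
tag sequences. Each read is matched by walking the tree from its first
nucleotide one base at a time; a read beginning with an expected
barcode and cut-site remnant continues into the tag tree from the
first post-remnant base (from the remnant itself for variable-site
enzymes such as ApeKI). The number of bases examined per read is
bounded by the length of the longest stored sequence irrespective of
how many sequences are stored, so per-read cost is nearly flat from
10² to 10⁴ tags. Matching is exact (no mismatch tolerance, quality
scores ignored, `N` never matches); when one stored sequence is a
prefix of another, the longest match wins. Counts are plain integers
with no ceiling. Genotypes, when all markers are biallelic, follow the
standard coding: both alleles seen → `1`, only allele "0" → `0`, only
allele "1" → `2`, neither → blank.

## Worked example

The package ships a seeded generator that writes a multiplexed FASTQ
with known ground truth, so the example is fully self-contained:

```r
library(tagtally)

sp <- fixture_spec(n_samples = 6, n_markers = 4, depth_mean = 4, seed = 7)
fx <- generate_fixture(sp, dir = tempfile())

key    <- read_key_file(fx$key)            # File / Barcode / Sample
counts <- count_tags(key, fx$tags, "PstI-MspI")
counts
#> # A tibble: 6 × 9
#>   sample M0001_G_0 M0001_T_1 M0002_A_0 M0002_T_1 M0003_G_0 M0003_T_1 M0004_A_0
#> * <chr>      <int>     <int>     <int>     <int>     <int>     <int>     <int>
#> 1 S001           2         2         4         6         0         0         2
#> 2 S002           3         7         0         8         2         5         0
#> 3 S003           0         2         0         0         4         0         1
#> 4 S004           0         9         4         2         4         0        16
#> 5 S005           1         0         9         1        10         0         0
#> 6 S006           0         9         0         2         3        19         0
#> # ℹ 1 more variable: M0004_C_1 <int>

glance(counts)
#> # A tibble: 1 × 6
#>   n_samples n_tags n_markers total_reads matched_reads discarded_reads
#>       <int>  <int>     <int>       <int>         <int>           <int>
#> 1         6      8         4         161           161             0

call_genotypes(counts)
#> # A tibble: 6 × 5
#>   sample M0001 M0002 M0003 M0004
#> * <chr>  <int> <int> <int> <int>
#> 1 S001       1     1    NA     1
#> 2 S002       1     2     1     2
#> 3 S003       2    NA     0     1
#> 4 S004       2     1     0     0
#> 5 S005       0     1     0     2
#> 6 S006       2     2     1    NA
```

Column `M0001_G_0` is marker M0001, variable-site base G, allele "0"
(the alphabetically smaller tag); each cell is the number of reads of
that allele in that sample. In the genotype table, sample S001 at
M0001 has reads for both alleles (2 and 2), hence heterozygous `1`;
S003 at M0002 saw neither allele, hence missing (blank on export).
`write_counts_csv()` / `write_genotypes_csv()` produce the CSV files;
`split_fastq()` and `md5_manifest()` handle demultiplexing for archive
deposit; `consolidate()` / `export_merged_csv()` / `export_fasta()`
manage the cross-project marker database. A flag-driven command-line
wrapper with `count`, `split` and `manage` subcommands is installed at
`inst/cli/tagtally.R`.

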