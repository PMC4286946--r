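---
title: "Methods: small non-coding RNA profiling and piRNA cluster prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small non-coding RNA profiling and piRNA cluster prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

`pirnapipe` implements a complete small non-coding RNA (sncRNA) profiling
workflow of the kind used to characterise PIWI-interacting RNAs (piRNAs)
in germline cells — read cleaning, unique-tag collapsing, genome mapping,
hierarchical ncRNA annotation, cross-sample expression comparison and
probabilistic piRNA cluster prediction — together with a synthetic
genome/library simulator that generates data with known ground truth for
validating every stage.

This vignette documents the statistical model behind each stage, the
default parameter values and why they were chosen, and the package's
deliberate limitations.

```{r setup}
library(pirnapipe)
```

## 1. The synthetic genome and library model

Real sncRNA profiling starts from sequencing libraries of germline and
somatic cells aligned to a reference genome with curated annotation.
The simulator replaces both with a controlled synthetic system.

### Genome

`genome_spec()` / `build_genome()` generate random chromosome sequences
(default one chromosome of 1 Mb, uniform base composition) and plant
non-overlapping features at uniformly random positions:

* **Dispersed repeat copies** (default 30 × 300 nt) drawn from two family
  consensus sequences (LINE/CR1-like and LTR/ERVL-like, 70/30) with 8%
  per-base divergence. Divergence makes multi-mapping and ambiguous
  subtype assignment arise naturally rather than by fiat.
* **Gene models** (default 10), each
  exon(300)–intron(500)–exon(300)–intron(500)–exon(300).
* **Structural RNA loci**: tRNA (75 nt), rRNA (800 nt), snRNA (150 nt),
  snoRNA (100 nt), scRNA (300 nt) and miRNA (22 nt) loci.
* **piRNA clusters** (default 3 × 2 kb), each annotated as a repeat
  (LINE/CR1) interval but carrying unique sequence — modelling an old,
  diverged repeat remnant. This is what makes cluster-derived tags map
  uniquely, as piRNA cluster tags typically do, while still annotating as
  repeat-derived.

Placement uses uniform gap sampling; a spec whose features would occupy
more than 80% of the genome is rejected with an error naming the
offending category. The whole genome is a deterministic function of the
spec, including its seed.

### Libraries

`library_profile()` describes one library as a mixture over eight read
classes (cluster piRNA, genic piRNA, miRNA-like, rRNA/tRNA fragments,
intron/exon fragments, random background) with per-class length
distributions. The four presets — `pgc_profile()`, `stagex_profile()`,
`gsc_profile()`, `cef_profile()` — encode the study design this package
emulates: a primordial germ cell (PGC) library dominated by
repeat/cluster-derived piRNAs, a stage X blastoderm intermediate, and two
somatic libraries (gonadal stromal cells, embryonic fibroblasts)
dominated by miRNAs and rRNA fragments.

Defaults worth noting:

* **Length distributions.** The piRNA class peaks at 26 nt with 84% of
  its mass in 26–32 nt; the miRNA class peaks sharply at 22 nt. These
  were calibrated *a priori* so that a piRNA-rich library has a
  unique-tag length mode of 26 nt while its count-weighted (total-read)
  mode stays at 22 nt — the qualitative signature reported for germline
  sncRNA libraries (many distinct piRNA species, but miRNA reads
  amplified by high copy number).
* **Ping-pong signature.** piRNA-class reads are edited to start with T
  (U on the RNA) with probability 0.9 and to carry A at position 10 with
  probability 0.45. Edits introduce at most 2 mismatches, so edited reads
  still map under the default contract (at most
  `floor(0.10 * 26) = 2` mismatches for the shortest piRNA).
* **Strand bias.** Cluster reads come from the cluster's main strand with
  probability 0.9, giving an expected strand-bias score of 9 — comfortably
  above the 1.3 acceptance threshold, so planted clusters satisfy the
  cluster-detection criteria by construction.
* **Artefacts.** 15% of reads run through into a 33-nt 3′ adapter
  (read length capped at 50 nt) and 10% of reads draw per-base Phred
  scores from a low-quality component (mean Q8 versus Q35). These are
  exactly the artefacts the cleaning stage must remove.

```{r}
genome <- build_genome(genome_spec(chrom_length = 2e5, repeat_copies = 10,
                                   gene_models = 4, pirna_clusters = 2,
                                   seed = 7))
genome
lib <- simulate_library(genome, pgc_profile(depth = 20000), seed = 11)
lib
```

## 2. Read cleaning and unique-tag collapsing

`clean_reads()` produces "clean reads" in three steps, in this order:

1. **Adapter trimming**: the earliest position where the read suffix
   matches the adapter prefix over ≥ 6 bases with ≤ 10% mismatches.
2. **Length window**: the trimmed insert must be 18–44 nt. Shorter
   products are adapter dimers or degradation; longer ones are outside
   the sncRNA size selection.
3. **Quality filter**: mean Phred of the *insert* (not the adapter) must
   be ≥ 13, the conventional "mean Q < 13 discarded" rule. Reads
   containing N are discarded.

`collapse_tags()` then collapses clean reads across samples into unique
*tags* — one row per distinct sequence with one count column per sample.
Per sample, counts sum to the clean-read total by construction; this
conservation identity is asserted throughout the test suite.

```{r}
cl <- clean_reads(lib)
cl$stats
tags <- collapse_tags(list(pgc = cl))
head(tags, 3)
```

## 3. Mapping: the identity/coverage contract

`map_tags()` reports every genomic placement, on both strands, where an
ungapped alignment of at least `ceil(0.95 * L)` consecutive tag bases
(L = tag length) carries at most `floor(0.10 * m)` mismatches (m =
aligned length). This reproduces a BLAST-style "identity ≥ 90%, coverage
≥ 95%" filter. For 18–44-nt tags these thresholds admit 2–4 mismatches
and no meaningful gaps, so alignment is ungapped by design.

Candidates come from an exact k-mer seed index over the concatenated
genome. The default `seed_length = 12` finds every qualifying alignment
that contains an exact 12-mer run — which covers all reads the simulator
emits, whose mismatches sit at positions 1 and 10. Lowering
`seed_length` to 6 makes the search *provably exhaustive* for the
default thresholds (pigeonhole: the worst case, a 20-nt window with 2
mismatches, still contains an exact 6-mer run); the acceptance tests
verify 100% agreement with a brute-force oracle at `seed_length = 6`.

Per diagonal the best window is chosen by maximal aligned length, then
minimal mismatches. Loci are reported 0-based half-open, deduplicated and
sorted; `max_loci` (default 500) caps the reported list while the true
locus count and an overflow flag are always returned. ELAND3-like TSV
import/export (`write_eland3()`, `read_eland3()`) provides
interoperability with external cluster scanners.

## 4. Hierarchical annotation

`annotate_tags()` assigns each mapped tag a single category. Every
(locus, feature) pair where the feature covers at least 50% of the locus
is collected, and the tag receives the highest-priority category over all
pairs:

```{r}
category_priority()
```

Exon and intron assignments split into sense/antisense by comparing the
locus strand with the gene strand (sense wins ties). Repeat-derived tags
record their repeat subtype, with `Ambi` when loci overlap more than one
family. Tags overlapping no feature are `unannotated`. The fixed-priority
rule ("count once, to the highest class") guarantees one category per
tag — percentages over categories always total 100%.

`summarize_distributions()` derives the per-category and per-length
(18–44 nt) tables, both count-weighted ("total reads") and unweighted
("unique reads").

## 5. Expression: RPKM and 2-fold upregulation

Tag expression is RPKM with the tag's own length as the "transcript"
length and the sample's clean-read total as the library size:

$$\mathrm{RPKM} = \frac{C \times 10^9}{L \times N}$$

The cross-sample comparison for a focal sample is

$$\mathrm{FC} = \frac{\mathrm{RPKM}_{\mathrm{focal}}}
{\max(\overline{\mathrm{RPKM}}_{\mathrm{others}},\ \delta)},
\qquad \delta = 0.01$$

with a tag called *upregulated* when FC ≥ 2. The pseudocount δ guards
tags absent from every reference sample; δ = 0.01 was pinned by
recomputing a published 40-row fold-change table from its printed RPKM
values — all rows reproduce within 1% (printed-rounding noise), including
the zero-denominator rows where FC = RPKM/0.01. That table ships in
`inst/extdata/` and is asserted in the acceptance tests:

```{r}
ref <- reference_table("pgc_top_pirnas")
fc <- fold_change(as.matrix(ref[, 7:10]), 1)
max(abs(fc - ref$fold_change) / ref$fold_change)
```

`upregulation_table()` reports per-category upregulated counts with
percentages rounded half-up to two decimals at report time only.

## 6. piRNA cluster prediction

`scan_clusters()` is a proTRAC-style probabilistic scan:

1. Slide a 5-kb window in 2.5-kb steps over each chromosome. A window is
   a candidate when the Poisson upper tail
   $P(X \ge n \mid \lambda w) \le 0.05$, where λ is the genome-wide locus
   rate (total mapped loci / genome length).
2. Merge overlapping significant windows; trim each merged interval to
   its outermost loci.
3. Accept a cluster only if **all** of the following hold:
   * ≥ 6 distinct loci;
   * trimmed-interval density still significant at α = 0.05;
   * strand-bias score `max(W+, W-) / max(min(W+, W-), 1)` ≥ 1.3;
   * ≥ 75% (weighted) of loci in the typical piRNA length range 26–32 nt;
   * ≥ 75% (weighted) of loci whose tag has T at position 1 **or** A at
     position 10 (the 1U/10A ping-pong signature, `one_u_ten_a()`).

Loci are weighted 1/n, where n is the tag's genome-wide locus count, so
infrequently mapped (unique) reads dominate the statistics — multi-mapped
repeat reads cannot fake a cluster. The distinct-locus count used for the
≥ 6 threshold and the density p-value is unweighted. Acceptance is a
conservative conjunction; each criterion is also reported per candidate
so any single one can be inspected or relaxed.

`call_pirnas()` then calls a tag a putative piRNA when at least one of
its loci lies fully inside an accepted cluster, and reports the origin
(annotation category) distribution of the calls.

## 7. End-to-end runs

`pipeline_config()` + `run_pipeline()` orchestrate everything from one
structured config. Samples are FASTQ paths or simulator profiles; the
genome is a model or a spec. `demo_config()` ships the four-sample study
design. The result bundles library statistics, the tag expression set,
the upregulation table, per-sample distributions, clusters and piRNA
calls, the simulation truth, and a manifest (package/R versions,
parameters, seed, file checksums). Reruns of one config are
byte-identical on disk; all randomness flows from the single config seed.

```{r, eval = FALSE}
res <- run_pipeline(demo_config(depth = 50000, seed = 1,
                                outdir = "pirnapipe-demo"))
res$upregulation
```

Stages always recompute when `run_pipeline()` is called; there is no
content-hash cache. Intermediates are persisted as plain text (FASTQ,
FASTA, BED, GFF3, TSV, JSON), and every stage can equally be driven from
its persisted files (`read_fastq()`, `read_genome()`, `read_eland3()`),
which is how stage idempotence is tested.

## 8. What the simulator does and does not emulate

Emulated: class mixtures and length modes of germline versus somatic
sncRNA libraries; ping-pong 1U/10A enrichment; cluster strand bias;
repeat family structure with divergence; adapter read-through; a
two-component quality model; and the conservation identities the real
pipeline must satisfy.

Deliberately not emulated: sequencing error inside the insert (edits are
confined to the 1U/10A positions); RNA secondary-structure or
expression-level biases; miRNA isoform (isomiR) heterogeneity; realistic
chromosome-scale repeat landscapes; and any database-dependent annotation
(miRBase/Rfam e-value search is replaced by genome-interval overlap).
Problem sizes (1 Mb genome, tens of thousands of reads) are the package's
own choice: large enough for stable statistics, small enough for a
test-suite-friendly runtime.
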