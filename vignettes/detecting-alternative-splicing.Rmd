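---
title: "Detecting alternative splicing from spliced EST alignments"
author: "estsplice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting alternative splicing from spliced EST alignments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(estsplice)
```

## The problem

When a eukaryotic gene's pre-mRNA can be spliced in more than one way, the
resulting isoforms leave distinct footprints in EST/cDNA-to-genome
alignments: two ESTs from the same locus that disagree about where an
intron starts, ends, or whether it is removed at all, are direct evidence
for alternative splicing (AS). `estsplice` turns a set of spliced
alignments (BLAT's PSL format) plus a genome (FASTA) and optional gene
models (GFF3) into a catalogue of classified AS events, and then asks the
three downstream questions that matter for interpreting them: are the
splice sites of alternative events weaker than constitutive ones, do
retained introns and skipped exons differ in length and base composition,
and what does each event do to the predicted protein?

The package is aimed at compact, GC-rich genomes in the green-algal style:
median exons around 132 bp, median introns around 232 bp, genome GC near
64%, GT..AG introns whose 3' ends are enriched in C rather than carrying a
classical polypyrimidine tract. Nothing in the code is specific to that
setting, but the simulator's defaults emulate it.

## Event model

A *transcriptional unit* (cluster) is a connected component of
same-strand, coordinate-overlapping alignments. Within a cluster, every
inter-block gap of an alignment is a putative intron with a *donor* (5',
GT) and *acceptor* (3', AG) boundary in transcript orientation. Five event
types are recognized:

* **IR** (intron retention): an intron spliced by some ESTs while another
  EST's single alignment block reads straight through it, extending at
  least `overhang` (default 10) nt beyond both boundaries. The overhang
  guards against truncated alignments that merely end inside an intron.
* **ES** (exon skipping): an internal exon of one EST, flanked by introns
  whose outer boundaries are joined by a single longer intron of another
  EST. Consecutively skipped exons form one event.
* **Alt5' / Alt3'**: introns sharing their acceptor (donor) while
  differing at the donor (acceptor) by at least the alignment resolution;
  one event per shared-boundary group.
* **AltB**: overlapping introns differing at both boundaries that are not
  explained by exon skipping.

Intron pairs that constitute a detected ES event necessarily share one
boundary with the skip intron; they are excluded from the Alt5'/Alt3'/AltB
groupings so that each event is reported under exactly one type, with ES
taking precedence. Event *granularity* is: one event per retained intron,
per skipped-exon run, per shared-boundary group, and per overlap-connected
AltB group. Counts therefore depend on this grouping rule, which is fixed
and documented rather than asserted to match any external catalogue.

The *prevalent* form of an event is the one supported by the strictly
largest number of distinct ESTs; exact ties are flagged and excluded from
prevalent/non-prevalent contrasts.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `min_identity` | 0.95 | fraction | alignment identity filter |
| `min_coverage` | 0.80 | fraction | EST length aligned |
| `min_intron`, `max_intron` | 40, 10000 | nt | plausible intron size |
| `overhang` | 10 | nt | IR read-through evidence |
| `min_support` | 1 | ESTs | support per splice form |
| `nmd_distance` | 50 | nt | PTC-to-last-junction rule |
| `short_intron_max` | 150 | nt | short in-frame intron subgroup |

The alignment filters are deliberately permissive defaults typical of EST
pipelines; every one of them is exposed both in `run_pipeline()` and in
the command-line wrapper, and every run writes all of them to
`run_config.txt` so any number in any report can be traced to the
thresholds that produced it. ESTs with several equally good alignments are
dropped entirely rather than assigned, because cross-mapping between
paralogs is a classic source of spurious "events"; dominated secondary
alignments are dropped while the best one is kept.

Coordinates are 1-based closed intervals everywhere inside the package —
the convention of the IRanges/GenomicRanges containers it builds on — and
are converted only at file boundaries (PSL and BED are 0-based half-open;
GFF3 matches the internal convention).

## Splice-site strength

Donor and acceptor models are log-odds position weight matrices in bits,
trained on constitutive introns (introns of clusters with no detected
event). Windows are 3 exonic + 6 intronic nt (donor) and 14 intronic + 3
exonic nt (acceptor), covering the invariant GT/AG; a pseudocount of 0.5
is added to every count. The background base distribution is estimated
from the training windows themselves, not assumed uniform, because in a
64% GC genome a uniform background would systematically reward AT-rich
positions. Absolute scores depend on these conventions (window width,
log base, background), so only *orderings* and significance levels are
comparable across studies; the package asserts directions, not absolute
motif-score values. Group comparisons default to the two-sided Wilcoxon
rank-sum test, with Welch's t-test available, since score distributions
are skewed mixtures; the choice is logged.

## Length, GC, and ORF impact

Feature contrasts compare retained introns and skipped exons (event
spans) against the introns and internal exons of clusters with no
detected event. Exons and introns of alternatively spliced clusters that
lie outside event spans are excluded from both sides: they are neither
clean constitutive material nor part of an event, and including them
would dilute both groups. These contrasts use Welch's t-test, the
conventional choice for composition comparisons. The short in-frame
intron subgroup is retained introns whose length is a multiple of three
below 150 nt (no external threshold exists; the value is configurable).

For protein impact, analysis is restricted to clusters with exactly one
event, an annotated start codon, and an untied prevalence call; each
form's representative transcript is the supporting EST with the largest
aligned length. The ORF is scanned from the annotated ATG to the first
in-frame stop. An event is *in the CDS* when its span intersects the
genomic footprint of the prevalent form's CDS (start codon through stop,
introns included — a retained intron interrupts the CDS even though it
overlaps no coding exon base). A premature termination codon (PTC) is a
non-prevalent stop genomically upstream, in transcript orientation, of
the prevalent stop; the transcript is an NMD candidate when the PTC lies
more than 50 nt upstream of the last exon-exon junction *of the
transcript that carries it* (the mammalian rule; the convention does not
specify the isoform, so the package fixes it to the PTC-bearing one and
documents that choice). Frame-preserving variants with no new stop are
reported with a `no_stop` flag rather than a guessed length.

## The simulator and what it does (not) show

`simulate_genome()` writes a single-chromosome genome of non-overlapping
multi-exon genes with planted events of all five types at configurable
per-gene rates, and `sample_ests()` draws EST alignments from the
isoforms. Design choices, fixed once:

* Exon/intron lengths are log-normal (sdlog 0.4) around medians 132 and
  232 nt — strictly positive and right-skewed like real length
  distributions; only medians are externally anchored.
* Introns selected for retention are drawn shorter (median 127 nt) and
  less GC-rich (57% vs 62%), the contrast the feature module is meant to
  recover; exonic GC is 64%.
* Introns are GT..AG with positions −10..−3 before the AG drawn with
  P(C) = 0.45, emulating the C-rich 3' end; planted boundary shifts are
  3–12 nt and no planted intron is shorter than 40 nt, so planted events
  always survive the default filters.
* ESTs are full-length by default (2–4 per isoform), with the canonical
  isoform receiving one extra EST so the constitutive form is prevalent,
  as is overwhelmingly the case in real EST data. Options provide partial
  ESTs, substitution errors, and flipped strand labels (to exercise
  dinucleotide strand inference). Coding sequence is stop-free random
  codons from the annotated ATG to a planted stop near the transcript
  end, so ORF analysis is well-defined on every gene.
* `simulate_ptc_genes()` builds three-exon IR genes whose retained intron
  carries an in-frame stop placed so the truncated ORF is a uniformly
  drawn 40–60% shorter fraction of the full one (mean one half), with all
  upstream in-frame stops in the variant frame neutralized; it is the
  controlled input for the PTC/NMD analyses.
* `simulate_site_set()` draws splice-site windows from a fixed donor or
  acceptor motif; "prevalent" and "non-prevalent" sites are degraded by
  replacing non-invariant positions with background draws at rates 0.30
  and 0.60, sized so the planted between-group score gaps are on the
  order of one to two bits — the magnitude of published prevalent versus
  constitutive contrasts — and reliably detectable at n = 200.

Because ESTs are (by default) error-free, full-length, and uniformly
sampled, a perfect recall/precision result on simulated data shows the
*classifier logic* is correct under complete junction coverage — it does
not show robustness to truncated alignments, sequencing error, chimeras,
paralog cross-mapping, or expression-biased sampling, which real EST data
exhibit. The error-rate, partial-length, and strand-flip options probe
the first of these; the rest are out of scope.

Problem sizes in the tests and the acceptance script (200 simulated genes
for recovery, 150 for feature contrasts, 200 sites per strength group,
50 PTC genes, 200 randomized small clusters for oracle equivalence) were
chosen so each check has clear statistical power while the whole suite
runs in well under a minute per analysis.

## Numerical and degenerate-input choices

* Identity is matches/(matches+mismatches); an alignment with no aligned
  bases scores 0.
* `wilcox.test` is called with `exact = FALSE` (ties are ubiquitous in
  score data); two identical zero-variance groups return p = 1 rather
  than an error, as does `feature_contrast` on identical groups.
* Non-ACGT bases score 0 (background-neutral) in PWM windows and are
  excluded from both numerator and denominator of GC content; sequences
  with no ACGT bases yield NA with a warning.
* Single-block alignments have no strand information; they are attached
  to a cluster only when contained in exactly one cluster span, and
  dropped otherwise.
* Empty inputs propagate as empty, well-formed tables (an empty PSL file
  is a valid run, not an error).

## Known limitations

* Event counting depends on the grouping granularity above; comparing raw
  event counts across tools requires harmonizing that rule first.
* The "constitutive" training and baseline sets are EST-confirmed introns
  of event-free clusters, not all annotated introns; sparsely covered
  loci contribute neither side.
* NMD candidacy is a positional rule, not a prediction of decay
  efficiency.
* The splice-graph export (DOT, plus TSV/BED event tables) is a
  machine-readable summary; the package does no figure rendering.
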