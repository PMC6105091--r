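---
title: "Integrating transcript assemblies into a consolidated annotation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrating transcript assemblies into a consolidated annotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txloom)
```

## The problem

RNA-seq assemblers reconstruct transcript structures from short reads, and
no single assembler is reliably best: tools differ in how they handle low
coverage, retained introns, ragged transcript ends and tandemly duplicated
genes, and their relative ranking changes between organisms and datasets.
Different tools, however, tend to fail on *different* transcripts, so a set
of competing assemblies is collectively more complete than any one of them.
`txloom` exploits this complementarity: it pools transcript models from many
assemblies (or samples, or sequencing technologies), removes redundancy and
artifacts, scores every model against its local competitors under a
user-defined notion of what a good gene model looks like, and emits one
primary transcript plus well-supported splice variants per locus.

The pipeline has three stages, mirrored by three function families:

1. **prepare** (`prepare_run()`): validation and standardization;
2. **evidence** (`evidence_store()`, `load_junctions()`, `load_orfs()`,
   `load_homology()`): collection of external support;
3. **pick** (`pick_run()`): locus building, scoring, chimera resolution and
   final selection.

A fourth family (`compare_run()`, `class_code()`, `zscore_rank()`) measures
any annotation against a reference, and a seeded generator
(`fixture_spec()`, `run_fixture_pipeline()`) builds synthetic benchmarks.

## Coordinates and data model

All coordinates are 0-based, half-open internally; GTF/GFF3's 1-based
inclusive convention is converted only at file boundaries. A transcript is
an exon chain (sorted, non-overlapping intervals) with an optional CDS;
introns are derived as the gaps between consecutive exons. The *intron
chain* — the ordered intron list — is the identity used for full
transcript-level matches; it deliberately ignores terminal-exon ends, which
are the least reproducible part of any assembly.

## Stage 1: preparation

`prepare_run()` reads any mix of GTF/GFF3/BED12 inputs and applies, in
order:

* a minimum cDNA length filter (default **200 bp**, the conventional floor
  under which models are rarely usable as gene evidence);
* intron classification: each intron's donor/acceptor dinucleotides are read
  from the genome and checked against the canonical U2/U12 set
  (GT–AG, GC–AG, AT–AC, plus reverse complements for the minus strand).
  A multiexonic model whose canonical introns all sit on the opposite strand
  is flipped; a model with canonical introns on *both* strands is discarded
  (it cannot be a single transcript); a monoexonic model from a
  non-strand-specific assembly has its strand stripped. The flip rule is
  deliberately conservative: we flip only when there is at least one
  canonical intron on the opposite strand and none on the annotated strand.
* exact-duplicate removal on (chrom, strand, exon chain), with the survivor
  chosen by input-file order then id — deterministic, and biased toward the
  assemblies the user listed first;
* coordinate sorting (chrom, start, end, id — the ordering used everywhere
  in the package). Sorting is performed in memory: at the scale this
  package targets (up to a few hundred thousand models) this is well within
  a desktop footprint, and keeping one code path makes byte-level
  determinism trivial to guarantee.

Each surviving multiexonic transcript is tagged with its canonical-intron
proportion, which later feeds the scoring stage.

## Stage 2: evidence

Three kinds of external support are loaded into a single
`evidence_store()`:

* **trusted junctions** — genomic introns from a junction caller, as BED;
  strandless rows match introns on either strand;
* **ORFs** — open reading frames on the prepared cDNAs, as transcript-space
  BED12 or GFF3. All ORFs per transcript are kept: the *number* of
  cDNA-disjoint ORFs is the primary chimera signal. Reverse-strand ORFs are
  dropped by default because preparation has already oriented the
  transcripts — a reverse ORF is a conflict, not evidence. When completeness
  flags are absent, they are resolved against the cDNA sequence (ATG at the
  ORF start; TAA/TAG/TGA in the final codon).
* **homology** — protein similarity hits as a tabular digest
  (query, target, e-value, bit score, HSP coordinates). Hits are grouped by
  (query, target) and ranked by e-value.

The store persists to a single file (`save_store()`/`load_store()`) and
restores bit-exactly; lookups for unknown ids return empty lists rather
than failing, so partial evidence is always usable.

## Scoring

`compute_metrics()` produces, per transcript, 26 named metrics covering
cDNA/CDS/UTR structure, splicing canonicity, locus-relative fractions
(share of the locus's distinct exons and introns), retained introns,
junction validation and homology support. Two definitions the package had
to fix itself:

* a **retained intron** is an exon of one transcript that fully contains an
  intron of a co-located transcript whose two flanking exons both overlap
  that exon; `retained_fraction` is the retained exon bases over the cDNA
  length;
* `end_distance_from_junction` is the cDNA distance from the stop codon to
  the last splice junction (0 for monoexonic models) — a proxy for
  nonsense-mediated-decay candidacy.

Scores are **relative within a group**: for each metric directive the group
values are rescaled to `[0, multiplier]` (`max` rewards the largest value,
`min` the smallest, `target` the closest to a stated target, with
`epsilon = 1e-9` guarding the target denominator). When every transcript has
the same value the metric is uninformative and everyone receives the full
multiplier — an uninformative metric should never penalize. The transcript
score is the sum over directives. This relative design means scores are not
comparable across distant loci, which is fine everywhere it is used, and is
the reason fragment filtering carries its own exemption rule (below).

The scoring configuration (YAML, `read_scoring_config()`) has four
sections: `requirements` (hard filters; a boolean expression over typed
atoms, checked against known metric names at load time),
`not_fragmentary`, `scoring` and `as_rules`. `default_scoring_config()`
encodes the package's stance — prioritize complete protein-coding models:
CDS length and fraction, completeness, validated and canonical junctions
and homology coverage are rewarded; retained introns and stop codons far
from the last junction are penalized; a single hard requirement imposes the
200 bp floor. There is deliberately no automatic weight training; the
configuration is the user's statement of intent.

## Stage 3: picking

Per superlocus (transcripts whose spans, extended by a 200 bp flank,
overlap transitively on compatible strands):

1. **requirements filter** — failing transcripts are excluded from every
   later phase, including isoform rescue;
2. **chimera resolution** — a transcript with two or more cDNA-disjoint
   ORFs is a candidate fusion. Homology can veto: if one protein's HSPs
   cover at least 20% of two ORFs, those ORFs are taken to be one gene.
   Otherwise the model is split at the cDNA midpoint between consecutive
   ORF clusters, each part receiving its ORF's projection as CDS and a
   `.split<k>` id suffix;
3. **subloci** — multiexonic models group by sharing at least one identical
   intron, monoexonic ones by exonic overlap, never mixed. Each sublocus is
   scored and contributes one winner;
4. **primary selection** — greedy pruning over the winners: take the best
   scorer (ties: longer cDNA, then id), discard everything directly
   intersecting it, repeat. Read-through models therefore cannot suppress
   their neighbors: each iteration seeds a new locus;
5. **alternative splicing** — candidates assignable to exactly one locus
   are rescored in the context of that locus and accepted in score order
   while (a) their class code against the primary is in the valid set
   (default `j`, `J`, `h`, `G`), (b) their intron chain is new to the
   locus, (c) their score is at least **50%** of the primary's, and (d) the
   isoform cap (default 5, a package choice — generous enough for real
   loci, small enough to stop noise accumulation) is not exceeded;
6. **fragment filtering** — a locus whose primary classifies as intronic
   (`i`/`I`), flank-proximal (`p`/`P`) or antisense (`x`/`X`) against a
   higher-scoring neighbor within 2 kb is flagged and, by default, removed.
   Because scores are locus-relative, a real neighboring gene could be
   mistaken for a fragment; the `not_fragmentary` expression (default: a
   complete ORF of at least 300 bp) exempts credible genes regardless of
   score.

Every output transcript id traces to an input id (possibly with a
`.split<k>` suffix); genes are renumbered positionally. Reruns are
byte-identical: all orderings are total and no step consults a random
number.

## Comparison

`compare_run()` evaluates a prediction against a reference at six levels —
base, exon, intron, intron chain, transcript, gene — reporting recall
(reference features recovered), precision (predicted features correct) and
F1. Transcript-level matches require an identical intron chain; monoexonic
pairs match at 80% or higher reciprocal overlap, a threshold the package
defines because chain identity is meaningless for single exons. Each
prediction gets one TMAP row (best match = highest junction F1, ties by
nucleotide F1) and each reference transcript one REFMAP row. The class-code
table is documented in `?class_code`; it is a re-derivation of the code
families popularized by cuffcompare-style tools, with one consequential
choice validated during development: a truncated chain lying wholly inside
the reference exons is `c` (a contained fragment), not `J`, so fragments
are never admitted as alternative isoforms. A prediction touching
transcripts of two or more genes — sharing a junction, or overlapping more
than 10% of the shorter cDNA — is a fusion and its code is prefixed `f,`.
`zscore_rank()` aggregates per-level F1s across competing methods into
cumulative z-scores (population standard deviation; zero deviation gives
zero z).

Two Methods-style utilities support building fair references:
`trim_terminal_utr()` clips terminal UTR exons to 50 bp by default
(coverage always decays at transcript ends), and `reconstructable_filter()`
keeps only transcripts whose every junction was detected and every exonic
base covered — the correct recall denominator for read-limited data.

## The synthetic benchmark

`fixture_spec()` defines the generator's conditions; the defaults are the
package's study conditions and were chosen once: 2 chromosomes of 50 kb, 20
genes of 1–5 exons (cDNA at least 400 bp so every truth model carries a
complete ORF of at least 300 bp), 50 bp UTRs on both ends, canonical splice
sites and ATG…TAA ORFs planted in a random ACGT background, and an
exon-skipping second isoform for 40% of genes with at least four exons
(guaranteeing isoforms share an intron and co-cluster). Equal UTR lengths
place the cDNA midpoint between two genes' ORFs exactly on the inter-gene
junction, so a correctly split chimera reproduces both truth chains
exactly — which is what makes split recovery testable rather than
approximate.

`corrupt_models()` emulates the assembler error taxonomy — fusions of
neighboring same-strand genes, fragmentation, retained introns, strand
mislabeling, terminal extension, exact duplication — applying at most one
corruption per transcript per simulated assembler and logging a truth table
of what it did. `emit_bundle()` derives the matching evidence (truth
junctions, truth CDS mapped onto each corrupted cDNA as ORFs, one synthetic
protein per gene so fused models hit two proteins, and unit coverage over
truth exons).

What passing on these fixtures shows: the machinery — strand repair,
deduplication, chimera splitting, relative scoring, isoform selection —
composes correctly and deterministically, and integration strictly beats
each corrupted input on a realistic error mix. What it does not show:
robustness to sequencing noise, soft-clipped alignments, overlapping genes,
non-canonical splicing or expression-dependent artifacts, none of which the
generator emulates. Problem sizes throughout the test suite (tens of genes,
thousands of random models for the coordinate oracles) were chosen as the
smallest at which every rule is exercised, including multi-gene superloci
and duplicate collapses across assemblers.

## Numerical and degenerate-input choices

* Interval arithmetic is integer throughout; no floating-point coordinates.
* `hi == lo` in rescaling yields the full multiplier (see above);
  the target denominator is guarded by `1e-9`.
* Ties anywhere in selection break by (score, cDNA length, id), making
  every run reproducible.
* Empty inputs are legal everywhere: an empty annotation prepares to an
  empty output with a warning (exit success); evidence lookups for unknown
  ids return empty; `compare_run()` against an empty prediction reports
  zero precision rather than failing.
* Gene-only rows (no exon features) are not guessed at: GTF transcripts are
  reconstructed from exon rows only, and a CDS-only transcript is an error
  naming the id.

## Known limitations

* Scores are relative to the locus, so absolute score values are not
  comparable across runs or loci and should not be thresholded globally.
* The class-code table is a re-derivation; tools in this family disagree on
  corner cases (notably `h` and mono-vs-multi containment), and ours is
  fixed rather than user-configurable — only the valid-AS and fragment code
  sets are exposed.
* Chimera splitting clips exons at cDNA midpoints; when real UTRs are very
  asymmetric the split point can land a few bases inside a terminal exon of
  one constituent gene.
* No expression or coverage information is used in scoring — by design, but
  it means lowly expressed intronic artifacts survive unless the fragment
  filter catches them.
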