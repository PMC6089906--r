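---
title: "Benchmarking taxonomic annotation: the model behind taxabench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking taxonomic annotation: the model behind taxabench}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taxabench)
```

## The evaluation model

`taxabench` treats taxonomic annotation as eight parallel binary
classification problems, one per canonical rank (domain, phylum, class,
order, family, genus, species, subspecies). For every read the expected
lineage (from a ground-truth table) and the assigned lineage (from a
classifier) are both projected onto those eight ranks and compared slot by
slot:

* expected slot empty → **NA**: the rank does not exist for this read
  (many prokaryotic lineages genuinely lack a ranked class or subspecies),
  so nothing can be evaluated there;
* both filled and equal → **TP**;
* expected filled, assigned empty → **FN** (non-classification);
* expected filled, assigned different → **FP** (misclassification), and
  every deeper evaluated rank of that read is also FP: once the genus is
  wrong, a species call hanging from it cannot be right, and an empty
  species slot under a wrong genus is still a wrong species-level outcome;
* for *shuffled* reads (base-permuted sequences that cannot legitimately
  be classified) any assigned slot is FP and any empty slot is TN.

This separation of FN from FP per rank is the core of the design: it
distinguishes a tool that cautiously stops at family from a tool that
confidently reports a wrong genus, which plain accuracy-style summaries
conflate. True negatives come *only* from shuffled sequences under the
default policy. The alternative — counting structural lineage gaps as TN —
is available as `na_as_tn = TRUE` in `aggregate_labels()`, but it inflates
specificity with events a classifier never had a chance to get wrong, so
it is off by default.

Because both lineages are projected through the same taxonomy tree, the
per-read label vector always matches `TP* (FP* | FN*)` over the evaluated
ranks: two taxa that agree at some rank necessarily agree at every
shallower ranked ancestor. The suite enforces this invariant over
randomized truth/assignment pairs.

Six metrics summarize each rank's confusion counts: EPQ (FP over all
queries), coverage (TP over reads with an expected taxon at the rank),
sensitivity, specificity, accuracy, and the Matthews correlation
coefficient as the single balanced summary (0 ≈ random, 1 = perfect,
negative = worse than random). Counts are accumulated as doubles before
multiplication, since the MCC denominator overflows 32-bit integers
already at a few tens of thousands of reads. A metric whose denominator is
zero is reported as `NA` ("undefined") rather than coerced to 0; MCC with
a zero factor follows the common convention of 0 plus an explicit
`mcc_degenerate` flag, so a degenerate 0 can never be mistaken for a
measured one.

## Coverage-vs-error curves and score cut-offs

Each classifier reports a score on its own scale; directly comparing
scores across tools is meaningless. Instead, reads are ranked from best to
worst score (direction declared per dialect: similarity-like scores rank
descending, E-value-like ascending) and cumulative EPQ is traced against
cumulative coverage. Only reads with a score and a TP-or-FP label at the
rank enter the ranking; FN/TN/NA reads and unscored assignments contribute
to the denominators only, because a curve point needs a rankable score but
the EPQ denominator is defined as the total query number. The score
cut-off at a target error rate (1%, 5%, 10% by default) is the worst score
admitted by the longest prefix whose EPQ stays at or below the target.

Two numerical choices here were genuinely open:

* **Ties are processed as blocks.** A prefix may only end at a score
  boundary, so results are invariant to the input order of equal-scored
  reads. The alternative (per-read prefixes) makes the cut-off depend on
  arbitrary file order when scores tie. The tie-block contract is verified
  by a reordering property test, and `cutoff_at_error()` is checked
  against exhaustive prefix enumeration on short curves.
* **The target is interpreted against EPQ, not FDR.** EPQ divides FP by
  all queries, matching the metric the curves plot. FDR (FP over
  classified reads) is a different, stricter notion; the curves here stay
  on one consistent denominator.

The per-rank denominators `total_queries` and `total_expected` default to
truth-derived values but are overridable in `build_cve()`: for shotgun
data the universe of classifiable sequences arguably depends on the
annotation approach (marker-gene extractors see only a fraction of the
reads), and rather than resolving that ambiguity the implementation
exposes the denominator.

## What the simulator emulates — and what it does not

The generator reproduces the construction of the reference amplicon
benchmark libraries end to end, with no external downloads:

* a balanced **mock taxonomy** carrying exactly the eight canonical ranks;
  the default branching yields 864 leaves, on the order of the ~840
  reference genomes behind the original libraries;
* one **template** per species-or-deeper leaf, with an embedded forward
  primer site, a random insert (uniform 400–460 bp, a V3–V4-sized
  product), and the reverse complement of the reverse primer site;
  degenerate positions are instantiated at random, so in-silico PCR must
  handle IUPAC codes to find them;
* **in-silico PCR**: IUPAC-aware scanning for forward sites and
  downstream reverse-strand sites, emitting every properly oriented pair
  within a product-size window, with 0-based half-open coordinates and
  both primer footprints included. The published primer *names* do not fix
  their sequences, so the widely used 341F/805R IUPAC sequences ship as
  the documented default and any pair can be supplied;
* a **linear rank-abundance model**: the i-th of k references gets weight
  k − i + 1 (ranks assigned by a seeded permutation per replicate), with
  largest-remainder rounding so per-replicate read totals are *exact* —
  750,000 pairs at the default scale;
* **reads**: R1 is the first 300 bp of the merged amplicon, R2 the
  reverse complement of the last 300 bp, every base at Phred 30. Merged
  amplicons are emitted directly as the evaluable unit (the original
  libraries were overlap-merged before annotation; simulating the merging
  step would only add a component outside the benchmark's subject);
* **shuffled true negatives**: 37,500 per replicate by default, each a
  Fisher–Yates permutation of a randomly chosen amplicon's bases.
  Mononucleotide shuffling preserves base composition but not
  dinucleotide frequencies; that stronger variant is deliberately left
  unimplemented;
* **replicate sharing**: one common pool of ⌈0.9 · N⌉ references present
  in all three replicates (the natural reading of "libraries shared 90% of
  reference sequences"), each replicate adding a disjoint private sample
  of the remainder.

Deliberately *not* emulated: sequencing errors and chimeras (quality is
fixed at Phred 30 — the benchmark's subject is annotation, not
base-calling), eukaryote/organelle sequences, and shotgun read simulation.
Passing tests on these libraries therefore demonstrate correctness of the
evaluation machinery under controlled conditions, not classifier
performance on real data: real 16S amplicons carry PCR and sequencing
artifacts, inter-species sequence identity, and database mismatch effects
that no clean simulation reproduces.

The **mock annotator** closes the loop: an error profile assigns, per
read, "correct to rank r", "sibling swap at rank r", or "unclassified",
plus a probability of annotating shuffled reads; scores are Beta-draws
with separate shapes for correct (Beta(8, 2)) and erroneous (Beta(2, 5))
calls, so the two populations overlap but separate — realistic enough for
cut-off extraction to have something to find. Configured rates must be
recovered by the measured metrics: the suite checks a 5% genus
misclassification rate against measured genus EPQ within three binomial
standard errors on 100,000 reads.

## Lineage handling details

* "superkingdom" and "domain" rank labels both fill slot 1; the two terms
  are used interchangeably in practice.
* Non-canonical ranks ("no rank", "strain", …) never fill slots, except
  that `strain_as_subspecies = TRUE` lets a strain-like child of a species
  fill the otherwise empty subspecies slot — NCBI encodes subspecies-level
  taxa inconsistently, and the flag is off by default.
* On pathological taxonomies where a rank repeats along one path, the
  occupant nearest the root wins and a warning is raised.
* Name resolution is case- and whitespace-insensitive and exact; homonyms
  return all matches (collapsed to their LCA when a single call is
  needed). Only "scientific name" rows populate the index by default.
* Unresolvable labels count as classifications — false positives wherever
  a taxon was expected — under the default `unresolved = fp` policy,
  because a tool that emits a name absent from the reference taxonomy
  *did* claim a classification. `unresolved = unclassified` restores the
  lenient alternative.
* Ambiguous multi-taxon calls are collapsed to their LCA and keep the
  read's own score; the LCA inherits no separate score.

## Reproducibility and problem sizes

Every stochastic step takes an explicit seed and is wrapped so the global
RNG state is untouched; identical seeds give byte-identical FASTA, FASTQ
and TSV outputs, which the suite asserts. Default seeds are fixed
documented values, never system entropy.

The test suite exercises the construction at 1/100 scale (7,500 pairs +
375 shuffled per replicate) plus the exact full-scale read apportionment
through the same allocation code, metric/oracle agreement on 1,000
randomized confusion sets, parameter recovery on 100,000 mock-annotated
reads, and curve contracts on hundreds of random curves. The acceptance
script runs the full-scale three-replicate construction (750,000 pairs per
replicate) and recomputes all headline quantities in about two minutes on
one CPU.

## Known limitations

* Unknown taxids are the caller's problem: there is no handling of NCBI's
  `merged.dmp`/`delnodes.dmp`, and no taxonomy download client.
* The mock taxonomy is balanced; real taxonomies are deeply skewed, which
  mainly affects how informative the sibling-swap error model is at sparse
  ranks.
* No area-under-curve summarization is offered: the cut-off table at
  explicit error rates is the intended summary, read directly off the
  curve.
* No statistical testing between methods and no ensemble analysis; the
  framework measures methods one at a time and leaves comparison to the
  reported tables.
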