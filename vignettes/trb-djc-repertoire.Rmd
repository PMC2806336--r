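---
title: "Analysing beta-chain repertoires over a multi-cluster TRB D-J-C locus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing beta-chain repertoires over a multi-cluster TRB D-J-C locus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trbrep)
```

## The problem

In ruminants the 3' end of the T cell receptor beta locus carries three
D-J-C clusters instead of the usual mammalian two. Each cluster holds a
single diversity (TRBD) gene, an ordered set of joining (TRBJ) genes and one
constant (TRBC) gene. In sheep the three clusters lie in genomic order
cluster 1 < cluster 3 < cluster 2, with a J census of 6, 5 and 7 genes.
Because the genomic organization is known, every rearranged V-D-J-C cDNA has
a forced topological interpretation, and a collection of such transcripts
can be read as a census of the recombination and splicing mechanisms that
shaped the repertoire. `trbrep` implements that reading: junction
decomposition, topology classification, constant-region variant analysis,
and the summary statistics over an annotated clone table, plus a labelled
synthetic-repertoire generator used to validate all of it.

## Junction model

A transcript is anchored on the conserved V-gene motif (default `YLCASS`,
whose cysteine is the conserved position-104 cysteine). The CDR3 is the
nucleotide stretch from the codon *after* that cysteine up to (exclusive)
the codon of the phenylalanine in the J-gene `FGXG` motif. This convention
counts three more amino acids than the Kabat delimitation; an empty CDR3 is
legal. The junction is decomposed as

```
junction = V-retained + N1 + D(observed) + N2 + J-retained
```

and the decomposition must reconstruct the observed junction byte-exactly —
this identity is enforced at run time and property-tested on simulated data.

* **J assignment.** The J gene is the germline J whose suffix, after 5'
  exonuclease trimming, matches the transcript exactly immediately before
  the constant portion. The package maximises the exact suffix match
  (equivalently, minimises the trim); a minimum match of 6 nt (two codons,
  configurable) keeps spurious calls negligible at locus scale.
* **D assignment.** Nucleotides in the unexplained centre of the junction
  are attributed to a D gene if they contain a stretch of at least
  `min_run = 4` consecutive nucleotides matching that germline D. The D
  with the longest such run is called. Ties between D genes are reported,
  not resolved: the default policy calls no gene and lists the candidates;
  an alternative policy breaks ties by genomic order (D1 > D3 > D2),
  mirroring manual curation practice. Raising `min_run` can only remove
  calls, never create them (tested property).
* **Substitutions inside D.** After the exact seed, the match is extended
  outward across isolated substitutions: a mismatch is accepted only when
  the next position matches again (one-base lookahead). Every accepted
  deviation is recorded in the call; nothing is silently absorbed, and
  because two consecutive mismatches stop the extension, N regions are not
  swallowed. Insertions/deletions inside D are not modelled by the default
  extension; junctions carrying them decompose with a shorter D and longer
  N regions, and the deviation list stays faithful to what was matched.
* **V-retained inference.** Without germline V sequences the 3' V end
  cannot be known. The conserved anchor tail (the motif residues after the
  cysteine) is always attributed to V; beyond it, a V-retained prefix is
  inferred only against an explicit list of germline V-end suffixes
  (greedy, longest match wins). When no list is supplied, N1 absorbs the
  rest — no hidden cross-clone consensus is attempted, which keeps the
  inference reproducible.
* **Frames and failures.** An out-of-frame or stop-containing CDR3 flags
  the record nonproductive; the nucleotide-level decomposition is still
  produced. A missing or duplicated anchor, an unmatchable J, or a
  truncated constant region is a per-record failure with a reason code,
  never a guess and never a silent drop.

## Topology classification

With `upstream_of` the strict genomic order of clusters, the classifiers
are total on the sheep layout:

* D and J in the same cluster: **intra-cluster**; D strictly upstream of J:
  **inter-cluster** (deletional joining); J strictly upstream of D:
  **trans-rearrangement**. cDNA cannot distinguish chromosomal inversion
  from inter-chromatid trans-rearrangement, so a single class covers both.
* J spliced to its own cluster's C: **canonical**; to a downstream C:
  **cis-splice** (alternative splicing of one precursor); to an upstream C:
  **trans-splice**, which requires two separate precursor RNAs.

Clones without a recognizable D form their own `no_d` class. Percentages of
the rearrangement classes are reported over both denominators — all clones
and D-assigned clones — because the two differ and both are informative.

## Constant-region markers, isotypes and variants

The three C isotypes are nearly identical; they are distinguished at a
small set of variable positions. The locus model carries a marker table (in
the packaged fixture: 14 positions, 12 in exon 1 and 2 in exon 3, six of
them amino-acid-changing, all numbered from the first constant-region
nucleotide of the cDNA) with per-allele bases, at most two alleles per
isotype, and a diagnostic subset at the N-terminus sufficient to call the
isotype (third position of codon 1 separating C2 from C1/C3; codons 3 and 4
separating C1 from C2/C3). Isotype calling matches the diagnostic bases
exactly; several matching isotypes yield an explicit `ambiguous`, none
yields `novel` — never a default.

Observed constant portions are reduced to marker vectors and counted per
isotype. A vector census larger than the expected two allelic forms is
explained under the parsimony order

`allele > exon_swap > recombinant > novel`:

an exact allele match; an exon-swap (exon-1 block from one allele, exon-3
block from another, both intact — the signature of alternative splicing of
the third exon); or a single-crossover hybrid within exon 1 between any two
alleles, cross-isotype donors allowed (only one allele may be known for an
isotype, as for C1, and the observed hybrid there combines C1 with a C3
allele). The crossover breakpoint is reported as the maximal marker
interval compatible with the vector. Two or more switches are `novel`:
single-crossover parsimony is a deliberate design choice — it is testable,
and every single-crossover product of two alleles is provably explained
(exhaustive property test over all donor pairs and breakpoints). Donor
*identity* can be ambiguous when the crossover precedes the markers that
separate an isotype's two alleles; the classifier then reports the first
valid donor pair, and the validation suite checks validity (the called
donors reproduce the vector) rather than insisting on an unknowable label.

## Reporting conventions

All percentages and means quoted to one decimal are **truncated**, not
rounded (52.777…% is reported as 52.7%), matching the reporting style of
the clone-table figures the package reproduces; the raw value and the
counts always accompany the truncated figure, so every printed number is
recomputable. Coordinates are 0-based internally and 1-based inclusive in
every report and configuration file.

## The synthetic generator

`simulate_repertoire()` draws labelled transcripts under the generative
structure the analysis assumes. Its defaults are the study regime of the
packaged clone table:

| parameter | default | meaning |
|---|---|---|
| `p_no_d` | 12/72 | clones with a direct V-J junction (no D) |
| `rearr_probs` | 25:32:3 /60 | intra : inter : trans among D-bearing clones |
| `splice_probs` | 49:7:16 /72 | canonical : cis : trans splicing |
| `trim_p`, `trim_max` | 0.35/0.45/0.45/0.25; caps 9 (V), 15 (J) | truncated-geometric trimming at 3'V, 5'D, 3'D, 5'J |
| `d_keep_min` | 6 nt | minimum retained D in D-bearing clones |
| `n_mean`, `n_no_d_mean` | 2.5 + 2.5; 8 | Poisson N-addition per side; single N region of no-D clones |
| `subst_rate` | 0.01 | substitutions inside the retained D |
| `exon_swap_rate`, `recomb_rate` | 0.05 each | constant-region variant rates |
| `nonproductive_fraction` | 0 | emitted out-of-frame fraction (`NA` disables filtering) |

Class mixtures are drawn jointly (rearrangement class, splice class, then a
uniform consistent cluster triple), so the configured marginals are exact;
a class combination infeasible under the locus (e.g. any trans class on a
single-cluster locus) is rejected at configuration time. The trimming
family is truncated-geometric and the N model Poisson because only observed
means and ranges are available to calibrate against; the defaults put the
N-D-N stretch of D-bearing clones near 14–16 nt and the N region of no-D
clones near 8 nt, the regime the clone table shows. Because the mixtures
describe *observed* classes, D-bearing clones always retain at least
`d_keep_min` nucleotides of D, and frame filtering resamples junction
lengths within a fixed class assignment, leaving the class marginals
untouched.

Two generator choices keep the labels observable. Crossover breakpoints are
drawn downstream of the isotype diagnostics, so a recombinant keeps its
N-terminal isotype assignment (as the observed hybrids do), and donor/
breakpoint draws are resampled until the product vector differs from every
pure allele and is informative on both sides of the breakpoint — a
crossover indistinguishable from a pure allele is not an observable
recombination event and is labelled as the allele it produces.

What the generator does **not** emulate: real germline sequences (the
packaged locus is synthetic — correct topology, census and marker
structure, invented sequences; real references load through the same layout
format), recombination-signal sequences and their pairing rules, somatic
hypermutation, thymic selection, expression levels, and PCR/sequencing
error. Passing the validation suite therefore demonstrates that the
decomposition and classifiers are correct *given the generative structure*,
not that they are robust to artefacts absent from that structure.

## Numerical and degenerate-input choices

* The constant region is located by exact match of the longest marker-free
  germline stretch (per isotype), then verified base-by-base with
  mismatches allowed only at marker positions; marker positions beyond the
  sequenced end are recorded as `N`.
* Junction scanning is exact string matching throughout — there are no
  scores or heuristics to tune; ties are explicit outcomes.
* Transcripts with two anchor hits are errors, not guesses; the smallest
  accepted transcript must still contain anchor, a 6 nt J match and the
  diagnostic constant positions.
* One shared clone sequence appearing in two tissues is kept as two
  records, as the clone table's totals imply.
* A documented quirk of the packaged table is preserved, not patched: the
  no-D group's maximum CDR3 recomputes to 45 nt although 42 was quoted
  historically; summaries report the recomputed value.

## Validation problem sizes

The shipped suite validates the reconstruction identity on 10,000
simulated transcripts, oracle-equivalence of the D caller (against a
brute-force longest-common-substring search) on hundreds of random
junctions, losslessness of a zero-noise round trip on every annotation
field, and, at n = 5000 under the study regime: truth-label class
fractions inside binomial 95% confidence bands, D-gene recovery of at
least 99% where at least `min_run + 2` nucleotides of D survive (at
substitution rate 0), and at least 95% correct constant-region variant
explanations. Those sizes give the property tests enough resolution while
keeping a full run comfortably interactive.

## Limitations

* The D rule cannot tell a chance `min_run`-long match in an N region from
  a heavily trimmed D: with 4 nt runs and ~8 nt of N, a substantial
  fraction of true direct V-J junctions contain a chance D match (the
  validation driver measures this). Interpret `no_d` as "no recognizable
  D", and the D-assigned denominators accordingly.
* V-allele calling, somatic hypermutation analysis and de-novo phasing of
  constant-region alleles from cDNA are out of scope; alleles must be
  supplied (as from genomic sequencing) or come from the simulator truth.
* Trans-rearrangement and trans-splicing are classified from topology
  only; no chromosomal mechanism is modelled or inferred.
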