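---
title: "Inferring CenH3 loss from transcriptome assemblies: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring CenH3 loss from transcriptome assemblies: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cenh3scan)
```

## What the pipeline decides, and why that is hard

`cenh3scan` turns a de novo transcriptome assembly into a per-species
verdict about the centromeric histone CenH3 (and, via a second track,
the kinetochore protein CenpC): `present`, `absent`, or `inconclusive`.
Presence claims rest on a single positive observation. Absence claims
are inferences from a *lack* of observations, and three confounders can
manufacture that lack or fake its opposite: assembly incompleteness,
low expression, and contamination by co-sequenced organisms. The
pipeline's design principle is that an absence call must be *licensed*
by explicit controls for each confounder; when a control cannot run or
fails, the verdict degrades to `inconclusive` rather than to a silent
negative.

## The translated search and its E-values

Every detection step funnels through one operation: a protein query is
Smith–Waterman-aligned (BLOSUM62; affine gaps, open 11 / extend 1, the
conventional translated-search defaults) against all six reading frames
of every transcript, keeping the best frame per (query, transcript)
pair. Stop codons translate to `*` and are never dropped — interrupted
homology is itself diagnostic (see "nonfunctional candidates" below).
Codons containing `N` translate to `X`, which scores 0 against
everything, so ambiguity neither attracts nor repels alignments.

Significance uses the extreme-value form `E = K * m * n * exp(-lambda * S)`
with `m` the query length (aa) and `n` the database length (nt). The
constants are *not* copied from published Karlin–Altschul tables,
because this implementation's scoring details differ from any published
tool's; instead `calibrate_evalue()` fits a Gumbel law (method of
moments) to the per-search maximum score of 300 null translated
searches — random uniform-composition proteins against random
nucleotide transcripts — and the cached constants
(`lambda = 0.309, K = 0.101`) are one such run. A consequence worth
stating plainly: E-values here are honest for *threshold comparisons*
(the suite verifies that null searches yield about one hit per search at
`E < 1`, within a factor of 3), but their absolute scale is not
comparable to BLAST's, so the package never compares its E-values to
values printed by other tools.

Two thresholds matter. Assembly-level searches use `E < 1e-10`; the
read-level search uses `E < 1e-5`, because a translated 100-nt read (33
aa) cannot reach the assembly-level threshold even at perfect identity.
Reads shorter than 90 nt are refused outright (a typed error, not an
empty result): their translated fragments are too short for
significance, and treating them as a negative would fabricate evidence
of absence.

## The H3-family classifier

Coordinates are fixed on the canonical insect H3 (135 aa, mature
initiator-Met-cleaved numbering; the protein is invariant among
insects). The bundled annotation sets the histone fold at residues
63–135 and the loop1 window at 78–87. The three diagnostic residues
whose replacement separates CenH3 from canonical H3 are Q68, F84 and
T118 — at these positions published coordinates mix Met-inclusive and
mature numbering, so the package standardises on mature numbering
throughout; the residues themselves (Q, F, T) are what matters.

A candidate is projected column-wise onto H3. Direct alignment works
for H3-like candidates, but true CenH3 folds are strongly divergent, so
the projection goes through the *best-matching anchor* among the bundled
references (H3, H3.3, a host-type CenH3, a fungal-type CenH3), whose own
residue-to-H3 maps are known analytically from their construction. This
mirrors iterative homology searching, where confirmed divergent homologs
are added to the query panel so that further divergent members are still
found and interpretable.

The decision rule, with all thresholds exposed in
`classifier_thresholds()`:

* **CenH3** — loop1 extension ≥ 1 insertion column AND ≥ 2 of the 3
  diagnostic positions substituted AND N-tail identity < 50 %.
  "≥ 2 of 3" rather than "all 3" because the diagnostic criteria are a
  feature list, not a conjunction; with the loop1 requirement in place,
  the softer rule protects against missing a true CenH3 with one
  conserved site. The tail threshold reflects that CenH3 N-tails are not
  even alignable between lineages; an absent or unalignable tail counts
  as divergent.
* **H3** — fold identity ≥ 90 %, loop1 extension 0, all diagnostic
  positions canonical, fewer than 2 substitutions at the H3.3 signature
  positions.
* **H3.3** — as H3 but with ≥ 2 signature substitutions. The four
  signature positions (31, 87, 89, 90) are the standard animal
  H3/H3.3-distinguishing set; they are recorded as a package constant and
  are knowledge *about* the family imported into the annotation, not a
  quantity estimated by the package.
* **H3-like** — significant fold homology failing all three patterns
  (e.g. a fold with many canonical residues eroded but no loop1
  extension).
* **non-histone** — no alignable fold.

A candidate whose aligned region is interrupted by stop codons in its
reading frame is retained and flagged `putatively nonfunctional`, and is
never labelled CenH3 regardless of its other features: a pseudogenised
H3 derivative must not rescue a presence call.

An "unaligned" signal is deliberately distinct from zero: a candidate
truncated before loop1 yields `NA` loop1 extension (the feature was not
observed), not 0 (the feature was observed to be absent).

## Completeness control

The benchmark-recovery fraction asks: of a reference protein set, what
fraction has at least one significant hit in the assembly? Transcripts
shorter than 250 nt are excluded and only the longest isoform per locus
is kept (ties break to the lexicographically smallest isoform id, for
reproducibility). The per-protein indicator — not the raw alignment
count, which is also available — is the control quantity, because it is
comparable across assemblies of different redundancy.

The gate: an assembly may support an absence call only if its fraction
is at least `completeness_factor` (default 0.55) times the *minimum*
fraction among designated positive-control assemblies. The factor
exists because the controls are, by construction, the most complete
assemblies available; requiring strict "at least the minimum control"
would forbid absence calls for any assembly with mild dropout, which is
not what "comparable coverage" means. The default separates the two
regimes the gate must distinguish — mild incompleteness (≤ 20 % of genes
missing), where absence inference is sound, from gutted assemblies
(≥ 80 % missing), where it is meaningless — with a wide binomial safety
margin on both sides at the survey's benchmark size (20 genes): the
probability that a dropout-0.2 assembly falls below 0.55, or that a
dropout-0.85 assembly rises above it, is each below 10⁻³.

## Expression-level control

Counts are normalised to reads per kilobase (per million mapped reads
when a library size is supplied — ranks are identical either way), and
transcripts longer than 200 nt (a deliberately separate constant from
the 250-nt coverage filter) are rank-ordered; the percentile is
`100 * rank / N` with ties sharing the mean rank, so the most abundant
transcript sits at 100 and "low percentile" reads as "low expression".
The percentile of the target gene's transcript in species where it *is*
found is attached as evidence but is **not** a gate: a genuinely present
gene can sit in the bottom decile of expression, and a low control
percentile should lower confidence, not flip a call.

Read assignment for synthetic data is exact-substring matching on either
strand with a first-transcript tie-break — a rank-faithful stand-in for
a read mapper at desk scale, sufficient because the bundled shredder
emits error-free reads and sequencing-error modelling is out of the
generator's scope.

## Contamination attribution

A CenH3-like candidate might come from a co-sequenced organism. The
attribution machinery reduces the candidate and labelled reference
panels (host-type CenH3s, contaminant-type CenH3s, an H3/H3.3 outgroup)
to their histone-fold domains *excluding loop1* — loop1 length is the
diagnostic character for being CenH3 at all, and would distort distances
among CenH3s — aligns them column-wise on H3 coordinates via the
anchored projection, and builds a neighbor-joining tree on
Poisson-corrected p-distances (pairwise deletion; columns > 50 % gaps
dropped; p capped at 0.95 to keep distances finite).

NJ with nonparametric bootstrap was chosen over full maximum likelihood
deliberately: the decision consumed from the tree is a clade membership
with support, not branch lengths or model parameters, and the distance
approach is deterministic given a seed, dependency-light and fast enough
to bootstrap inside a survey. The tree builder is an interface; an ML
backend could be swapped in without touching the verdict logic.

The verdict walks rootward from the candidate in the outgroup-rooted
tree: the first clade containing a labelled reference fixes the lineage
hypothesis (if that first contact is already mixed, the candidate is
unresolved), and the walk extends while the clade stays pure for that
lineage. Support is the percentage of bootstrap replicates whose own
walk assigns the same lineage. Bootstrapping the *assignment* rather
than a fixed clade is a considered choice: a candidate can sit at the
ancestral point of a reference radiation, where no single bipartition
containing it is stable even though its lineage membership is — and
conversely, a candidate with genuinely conflicting signal flips lineage
across replicates and is left unresolved. The default acceptance
threshold is 70 % support, the conventional "strong" bootstrap cutoff
(displayed supports above 50 are reported; acted on only above 70).
H3-proximal variants — candidates that cluster with the outgroup, the
pattern shown by recent H3-derived variants in real surveys — reach the
root without contacting a reference panel and are deterministically
unresolved, which is the behaviour the caller wants: such variants are
neither evidence for nor against CenH3.

## CenpC: motif and cupin profiles

The CenpC track stands in for HMM–HMM domain detection with a simpler,
fully testable primitive: position-specific score matrices (additive
pseudocounts, log2-odds against a uniform background) built from seed
alignments, scanned along a protein, with significance from a
permutation null — the best window score of the shuffled protein,
add-one smoothed over 999 shuffles, so the smallest attainable p-value
is 10⁻³ and p-values are super-uniform under the null by construction.
The shipped seed alignments and the cupin reference panel are
**synthetic** (constructed to mimic the conservation structure of the
real families — a short strongly conserved motif; equal-length cupin
domains falling into distinct subfamilies with positive stem lengths);
they are labelled `synthetic_` on disk and are not curated biological
sequences, so architecture calls on them validate the machinery, not any
particular genome.

Architecture labels combine the two scans: `motif+cupin`, `motif-only`,
`cupin-only`, `none`, where a cupin hit only counts toward `cupin-only`
if its clade test places it with CenpC-type cupins — cupin folds occur
in many unrelated protein families, and only the CenpC-type subfamily is
evidence of a CenpC gene whose motif has decayed.

## The synthetic-data generator

The generator is first-class, tested code; it defines the study
conditions under which the pipeline is validated.

* **Benchmark genes** are uniform-composition random proteins, lengths
  100–600 aa, back-translated with uniform codon choice. Completeness
  statistics depend only on detectability, so sequence realism beyond
  length and alphabet buys nothing.
* **Dropout** is expression-coupled: the number of surviving benchmark
  genes is exactly `Binomial(n, 1 - dropout)` and the dropped genes are
  sampled with weight inversely proportional to abundance — so the
  marginal emitted fraction obeys the binomial law the tests check,
  while low-expression genes preferentially vanish, as in real
  assemblies.
* **The histone repertoire**: H3 and H3.3 are always emitted. The host
  CenH3 is a mild (0.05 subs/site) divergence of a bundled host-type
  ancestor with a freshly randomised N-tail; the ancestor itself is
  built from H3 by loop1 insertion (2 residues), diagnostic
  substitutions and 0.45 subs/site of fold divergence — animal CenH3
  folds really are strongly divergent from H3, and this also keeps the
  host and contaminant clades geometrically balanced around the
  outgroup in placement trees.
* **The contaminant** is the bundled fungal-style reference (built with
  a 4-residue loop1 insertion and 0.60 fold divergence) mutated at
  `contaminant_divergence` substitutions per site (i.i.d., multiple
  hits collapsed via `1 - exp(-rate)`).
* **Expression** is log-normal (`meanlog = 3`, `sdlog = 1.5` on the
  natural-log scale — a heavy-tailed distribution spanning ~3 orders of
  magnitude, the shape of real RNA-seq abundance profiles); observed
  counts are Poisson draws around the log-normal abundances.
* Everything is byte-reproducible from the scenario seed.

What the generator does *not* emulate — sequencing error, chimeric
transcripts, alternative isoform structure, codon-usage bias, fragmented
ORFs — bounds what green tests mean: they demonstrate that the inference
chain is correct *given* an assembly whose transcripts faithfully encode
their proteins, not that any particular real assembly satisfies that
premise.

## Numerical and degenerate-input choices

* Alignment tie-breaking is delegated to a single deterministic
  traceback, so identical inputs give identical alignments.
* `rank(ties.method = "average")` everywhere a percentile is computed.
* Distance saturation: p-distances are capped at 0.95 before Poisson
  correction.
* Empty assemblies, empty read sets and empty surveys return empty
  (typed) results; an empty *benchmark* is an error, because a coverage
  fraction with denominator zero is meaningless.
* Degenerate dropout (0 and 1) is exercised explicitly in tests.

## Problem sizes

The validation suite runs, on one CPU, with the sizes it reports: the
alignment oracle on all nucleotide-alphabet pairs up to length 2 plus
randomised pairs to length 8 (path enumeration to length 5, an
independent Gotoh program to length 8); the classifier truth table on
200 mixed synthetic species; the end-to-end survey on 100 species of 20
benchmark genes each (plus gutted-assembly checks); contamination
attribution on 100 seeds; and the statistical oracles for percentiles
and coverage at n = 60. The acceptance script recomputes the same
quantities at survey size 30 and 20 contamination seeds, which keeps a
full from-scratch reproduction within a few minutes.

## Known limitations

* E-values are calibrated for uniform-composition sequences; strongly
  biased composition (low-complexity regions) would inflate scores, and
  no composition-based correction is applied.
* The search is exhaustive Smith–Waterman per frame — correct but not
  heuristic-fast; genome-scale inputs are out of scope.
* The reference-anchored multiple alignment discards candidate
  insertions relative to all anchors except within loop1; for the
  histone fold, where homologous columns are defined by H3, this is the
  intended behaviour, but the approach would not generalise to domains
  without a canonical reference.
* Contamination attribution is only as good as the reference panels: a
  contaminant from a lineage not represented in the panel yields
  `unresolved`, not `contaminant` — conservative, but it then blocks
  the absence call only through the candidate still counting as
  present-ish evidence; surveys with suspected exotic contaminants need
  panel curation.
* The CenpC fixtures are synthetic; applying the CenpC track to real
  proteomes requires building profiles from curated seed alignments.
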