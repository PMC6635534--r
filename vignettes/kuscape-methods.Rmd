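---
title: "Methods: C-NHEJ phyletic profiling and lineage-specific insertion analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: C-NHEJ phyletic profiling and lineage-specific insertion analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kuscape)
```

## Scientific background

Double-strand breaks (DSBs) are repaired either by homologous recombination
or by end joining. The classical non-homologous end joining (C-NHEJ)
pathway is directed by the Ku70/Ku80 heterodimer, which binds and protects
broken ends, and sealed by DNA ligase IV (Lig4). These three proteins form
the widely conserved eukaryotic core of the pathway; several parasitic
lineages have nonetheless discarded it. Organisms without C-NHEJ fall back
on alternative end joining (microhomology-mediated end joining and
single-strand annealing), which is deletion- and insertion-prone. Two
consequences are examined here:

1. **Phyletic side.** Across a panel of eukaryotic genomes scored for
   Ku70/Ku80/Lig4 presence, how many genomes keep 3, 2, 1 or 0 components;
   whether genomes lacking all three are systematically smaller than
   genomes retaining at least one; and how many *independent* pathway
   losses a species tree implies.
2. **Alignment side.** In orthologous protein alignments of
   trypanosomatids, a crown clade whose two sequenced species have lost
   both Ku genes shows pervasive clade-specific insertions. The package
   detects such insertion blocks, quantifies what share of each alignment
   they occupy, and characterises them: amino-acid composition, elevated
   divergence at their flanks, depletion from highly conserved genes, and
   support by mass-spectrometry peptides.

## The phyletic model

A *phyletic profile* is a table of species with clade, lifestyle
(parasite / free-living), genome size (Mb) and 0/1/NA presence calls for
the three components. Presence calls derived from ortholog databases
conflate "absent from the genome" with "not annotated"; the profile
therefore carries NA explicitly, and every counting operation **excludes**
NA-bearing rows with a warning rather than coercing them to absence.

**Census.** Each genome with complete calls contributes to exactly one
class k ∈ {0, 1, 2, 3}, the number of components present.

**Size contrast.** "Lacking C-NHEJ" is read strictly as all three
components absent; "bearing" as at least one present. Under this reading
trypanosomatids (Ku present, Lig4 lost) are *bearing*. Arithmetic means and
medians are reported on the Mb scale, together with the ratio of means.
Because genome sizes span four orders of magnitude and are heavy-tailed,
the primary test is a two-sided Mann–Whitney U on raw sizes and a Welch
t-test on log10 sizes is always reported alongside; neither is privileged
when they disagree.

**Dollo losses.** The pathway is assumed present at the root (it is
conserved from bacteria onwards), and regain is forbidden. Under this
single-origin model the minimum number of independent losses for a binary
tip pattern equals the number of maximal all-absent subtrees; the loss
edges are the edges subtending them. If every tip is absent the single
loss sits on the (virtual) root edge. Polytomies are allowed: each absent
child subtree of a mixed polytomy counts separately, which makes the
result deterministic without tie-breaking rules. Engineered deletions
(e.g. laboratory strains with Ku knocked out) are handled by an explicit
exclusion list, never hard-coded.

## Exact rank tests under ties

The Mann–Whitney and Wilcoxon signed-rank tests are implemented in the
package because the stock implementations abandon exactness in precisely
the situations this pipeline encounters: tied sizes, tied fraction
differences, and all-zero difference vectors. Exact null distributions are
computed by a generating-function (shift) algorithm on doubled midranks —
doubling makes tied midranks integral, so the subset-sum (Mann–Whitney)
and sign-flip (signed-rank) distributions are exact convolutions. The
two-sided p-value is the distance-from-mean convention
`P(|T − E[T]| ≥ |t − E[T]|)`, which reduces to the familiar doubled tail
for symmetric tie-free distributions and keeps the permutation p-value
exactly uniform on its support. Cutoffs: exact for combined n ≤ 20
(Mann–Whitney) and ≤ 25 non-zero pairs (signed-rank), otherwise a normal
approximation with tie and continuity corrections. Zero differences are
dropped (Wilcoxon convention); an all-zero vector yields p = 1.

## Insertion detection

Coordinates are 0-based half-open in memory and 1-based inclusive on disk —
internal arithmetic stays simple while files match the convention
biologists expect. `'X'` counts as a residue (an unknown residue still
occupies its column); `'*'` is rejected on input.

A column is an **insertion candidate** for a focal taxon set iff at least
one focal taxon carries a residue and the fraction of background taxa with
a gap is ≥ `bg_gap_frac` (default 1: strictly clade-specific). Maximal
candidate runs become blocks; runs separated by ≤ `merge_gap` non-candidate
columns may be merged (default 0); per focal taxon a block is emitted only
if the taxon has ≥ `min_len` residues in the run's candidate columns
(default 3, suppressing single-residue alignment noise). Truncated
background sequences would create spurious terminal "insertions", so
leading/trailing background gap runs can optionally be treated as missing
data (`ignore_terminal_gaps`, default off).

Block residue intervals are obtained by prefix-counting non-gap characters
(`map_columns_to_residues`). With merging enabled, a block's merged span
can contain focal residues in bridged non-candidate columns; `length_res`
deliberately counts candidate-column residues only, so
`res_end − res_start = length_res` holds exactly at the default
`merge_gap = 0` and `res_end − res_start ≥ length_res` otherwise. The
insertion **fraction** of a taxon is candidate columns inside its blocks
divided by total alignment columns; bridged columns never enter the
numerator. Both pooled (sum of numerators over sum of denominators) and
per-alignment mean aggregations are reported by the pipeline, since a
"share of the alignments" can be read either way.

When quantifying a single species, that species alone is focal and *all*
other taxa (including its clade mates) are background; insertions shared
by a clade are captured by making the whole clade focal. The reference
comparison therefore uses the symmetric treatment: the reference taxon
focal against everything else.

## Downstream statistics

- **Composition.** A taxon's residues inside its blocks vs outside, pooled
  over alignments, with enrichment the ratio of relative frequencies.
  Per-amino-acid 2×2 G-tests (this residue vs rest × insertion vs
  background) with Benjamini–Hochberg q-values, plus an omnibus 2×K
  G-test. `'X'` is excluded from both pools; enrichments with zero
  background frequency are reported as NA (undefined), never dropped
  silently.
- **Cross-taxon similarity.** Pearson correlation of log2 enrichments over
  amino acids defined in both tables (≥ 5 shared required by default).
- **Paired comparison.** Per-orthogroup insertion fractions of a focal and
  a reference taxon are compared with the exact two-sided Wilcoxon
  signed-rank test above. Fractions are paired by orthogroup and
  non-normal, which is why a signed-rank test rather than a t-test is the
  default.
- **Flank divergence.** Mismatch rate of (focal, background) residue pairs
  in columns within `flank_width` (default 5) of a block boundary vs all
  other non-block columns; ratio flank/distal, with `Inf` as the sentinel
  when only the flank diverges and 1 when both rates are zero.
- **Conservation.** Mean pairwise identity over gap-free, non-candidate
  columns, correlated (Spearman, two-sided) with insertion fraction across
  alignments; a negative rho reproduces the depletion of insertions from
  the most conserved genes. Conservation is computed, not curated.
- **Peptide coverage.** A peptide covers an insertion iff some exact
  occurrence overlaps it by ≥ 1 residue; every occurrence is considered,
  and I/L can be treated as equivalent (isobaric in mass spectrometry).

## Synthetic data: what it emulates and what it does not

The generators define the study conditions under which the pipeline is
validated.

`simulate_orthogroup` draws a uniform ancestral sequence of length `L`,
applies independent per-branch substitutions (probability `d` per site,
uniform over the 19 alternatives — no exchangeability matrix), and places
focal-lineage insertions at Poisson(`λL`) uniform positions with geometric
lengths (mean `m`, support ≥ 1) and a configurable residue composition.
Insertions are shared by the whole focal clade, as expected for events in
its common ancestor; an optional reference lineage receives its own
insertions at `ins_rate_ref`. The *true* alignment is emitted directly
from known homology — no aligner is run — so detection is measured free of
aligner error, and true blocks are the maximal runs of inserted columns
with exact coordinates. A flank multiplier raises the substitution
probability for all taxa within `flank_width` sites of an insertion point,
emulating the poorly aligned, divergent flanks seen around real
insertions. The geometric length default `m = 8` reflects the short
(2–30 bp) insertions typical of microhomology-mediated repair; it is a
modelling choice, not an empirical length distribution. Pooled fractions
converge to the analytic expectation `λmL / (L + λmL)`.

`simulate_phyletic_table` draws log10 genome sizes from
Normal(μ = 2.0, σ = 0.9) — median 100 Mb, spanning the eukaryotic range —
and sets the full component triple absent with logistic probability
`plogis(a + b·log10 size)`; defaults a = 1.65, b = −2.0 give a marginal
triple-loss rate near 9% at a strong size effect, matching the scale of a
230-genome survey. Lifestyle is parasitic with probability 0.8 for losers
and 0.3 otherwise. Setting `b = 0` yields exact null data for calibrating
the association tests.

Deliberate simplifications: no deletions, no partial component loss
(profiles are all-or-none triples), star-like branch structure rather than
a full tree, uniform substitution model, and no alignment error. Passing
tests therefore demonstrate correctness of detection and inference under
known homology, not robustness to aligner artefacts or to gradual,
component-by-component pathway decay.

## Numerical and design choices

- NA presence is excluded with a warning, never coerced to 0.
- Undefined enrichments (zero background) and infinite flank ratios are
  explicit sentinels (NA / `Inf`) in memory and in JSON output.
- Exact-test cutoffs (20 / 25) balance exactness against the 2^n and
  subset-sum costs; beyond them, tie-corrected normal approximations
  match the standard large-sample formulas.
- All randomness in a simulator call flows from one seed argument;
  identical seeds give byte-identical outputs.
- The orchestrator (`run_pipeline`) accepts an R list, YAML or JSON
  configuration (YAML chosen as the serialisable config format), embeds
  the resolved configuration, package version and input MD5 checksums in
  its report, and fails with the offending stage named.
- Problem sizes used by the validation suite: exhaustive Dollo checks on
  random 4–8-tip trees over all 2^n tip patterns; 1,000 random alignments
  against a brute-force detector; exact-test enumeration for all n ≤ 8;
  2,000 null replicates for 5%-level calibration of both association
  tests; 200 replicates at L = 2000 for fraction recovery; 40 datasets of
  247 alignments for the power check in the focal ≈ 15% / reference ≈ 9%
  regime.

## Known limitations

- Dollo loss counts assume ancestral presence and irreversibility; no
  probabilistic ancestral-state reconstruction is attempted, and loss
  counts are not corrected for phylogenetic non-independence in the size
  contrast.
- Which test produced the published genome-size and paired-fraction
  p-values is not derivable from the analysis alone; both defaults are
  reported and neither is claimed to reproduce a specific published value
  exactly.
- Detection operates on protein alignments only: no DNA-level indel
  calling, no inference of the mutational mechanism, and structure mapping
  is limited to exporting residue intervals.
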