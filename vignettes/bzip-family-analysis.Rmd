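---
title: "Grammar-based analysis of plant bZIP transcription factor families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grammar-based analysis of plant bZIP transcription factor families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bzipkit)
```

## The model

Basic leucine zipper (bZIP) transcription factors carry a bipartite domain:
a basic DNA-binding region with the consensus `N-x7-R/K`, a nine-residue
hinge, and a leucine zipper of heptad repeats mediating dimerization.
`bzipkit` detects this domain structurally rather than by profile-HMM
scoring: an anchor is an invariant Asn followed eight residues later by
Arg or Lys, and a zipper is a run of heptads whose first position holds
Leu or another bulky hydrophobic residue (Ile, Val, Phe, Met).

All positions are reported in the conventional numbering frame: the
invariant Asn is −18, the invariant Arg/Lys is −10, the first zipper
residue is +1 and subsequent heptad starts are +8, +15, …; consecutive
residues advance the frame by one and there is no position 0. This frame
is what makes the rest of the pipeline compositional: binding-specificity
reports, intron placement and the anchored domain alignment all address
residues by frame position.

### Grammar parameters

* `min_heptads` (default 3): the shortest zipper accepted. Plant bZIP
  zippers span roughly 3–11 heptad units, which the package maps
  bijectively onto length gradients I–IX.
* `max_interruptions` (default 2): interior heptads whose first position
  is not hydrophobic are tolerated, but only when a later canonical heptad
  follows — a trailing non-canonical heptad never extends the zipper.
  Families show zippers "interrupted" by one or two such units, hence the
  default budget of 2.
* `heptad_counting`: whether `heptad_count` counts only canonical heptads
  (default) or canonical plus tolerated ones. Published zipper-length
  tallies do not state which convention they used, so both are exposed;
  the gradient map accepts either.
* `relaxed_basic`: lets any residue occupy −10 (for families where the
  arginine is replaced by Ile); such domains are always flagged in the
  specificity report. Lys at −10 is accepted even in strict mode, since
  it is a conservative basic substitution characteristic of one subfamily.

When several anchors qualify, the one with the most canonical heptads
wins and ties go to the leftmost anchor. This makes annotation
deterministic and position-shift equivariant (prepending k residues
shifts every reported index by k and changes nothing else).

## Intron patterns within the domain

Intron phase is defined against the coding sequence: an intron after
cumulative CDS length c has phase c mod 3 (0 between codons, 1/2 inside
a codon), and affects protein residue c ÷ 3. Internally all coordinates
are 0-based half-open and the 1-based closed GFF3 convention is converted
exactly once at the I/O boundary, which keeps the codon arithmetic free of
off-by-one cases; reverse-strand genes yield the same phases as their
forward mirror by construction.

Introns whose junction codon falls inside the basic region
(frames −18…−10), hinge (−9…−1) or zipper (+1 onward) are classified into
nine structural patterns *a*–*i* by a top-down rule table: *i* no domain
intron; *b* two phase-0 introns in basic and hinge; *g* one phase-1 intron
in the basic region; *c*/*d*/*e* a phase-2 basic intron plus a phase-0
zipper intron in the first/second/third heptad; *f* a phase-2 basic intron
with no zipper intron; *a* a single phase-0 zipper intron between Gln and
Ala; *h* the same with other flanking residues.

Three decisions here were genuinely open:

* A phase-0 junction exactly on a subregion boundary is assigned to the
  downstream subregion (the junction's codon), for determinism at
  boundaries the pattern definitions never discuss.
* The *c*/*d*/*e* split positions are not printed anywhere recoverable;
  the defaults +1/+8/+15 (heptad starts) are explicit assumptions and are
  configurable via `breakpoints`.
* Two lettering schemes exist because the published family table labels
  every domain-intron-less gene *h* while the running text defines *i* as
  the intron-less pattern. `classify_intron_pattern()` emits either
  (`scheme = "text"` is the default); the packaged table carries both
  columns (`pattern`, `pattern_text`) and neither is "corrected".

## Genome organization

`chromosome_distribution()` computes per-chromosome counts and
percentages over mapped genes only (unplaced "random"/"Un" entries are
counted separately), against an explicit chromosome universe (1–19 for
grapevine) so that empty chromosomes are reported. Tandem detection is
distance-based by default — two homologs on the same chromosome whose
combined footprint is within 100 kb — because a count of intervening
non-family genes would require the full genome annotation; the
`max_intervening` parameter exists for callers who have it. Collinearity
is never recomputed: the MCScanX `.collinearity` text format is parsed,
anchors are restricted to family members, and duplicate groups
(pairs, triplets) fall out as connected components of the family homology
graph.

## Phylogenetic grouping

Because every annotated domain lives in the same frame, a multiple
alignment is unnecessary for family-level grouping: `anchored_domain_alignment()`
places residues by frame position, with gaps where shorter zippers end.
By default columns span the union of frames observed (shorter rows are
gap-padded on the right); `trim_to_common = TRUE` restricts to columns
present in every sequence. Distances are uncorrected p-distances with
pairwise gap deletion — symmetric with zero diagonal, but deliberately
not checked for the triangle inequality, which p-distances may violate.

The neighbor-joining tree is built by the standard Saitou–Nei
agglomeration (minimize Q(i,j) = (n−2)d(i,j) − r_i − r_j) implemented in
the package. Negative branch lengths are clamped to zero with the excess
moved to the sister branch, and Q ties break on the lexicographically
smallest pair of subtree labels, so the output is deterministic. On
additive matrices NJ is consistent: the generating topology is recovered
exactly and branch lengths agree to numerical precision, which is the
property the test suite asserts on random trees of 4–8 taxa.

Groups A–J are assigned by nearest labeled reference (patristic distance
when a tree is supplied, otherwise the raw distance), with a `tie_margin`
(default 0.02 substitutions/site): a query whose two nearest references
disagree within the margin is left unclassified (UC). This is an
operationalization of visual clade inspection, not a claim of equivalence
for borderline genes. Bootstrap (column resampling under a user seed) is
available but off by default and never feeds group assignment.

## Expression analyses

Co-expression uses the product-moment correlation with the exact
two-tailed t-test (t = r√((n−2)/(1−r²)), n−2 df) and the conventional
thresholds: significant-positive when p < 0.01 and r ≥ 0.35,
significant-negative when p < 0.01 and r ≤ −0.35, strong-positive when
additionally r > 0.9. Boundaries are inclusive exactly as written; no
multiple-testing correction is applied because the reference analyses
report raw 0.01-level significance. With 54 samples the critical |r| at
p = 0.01 is ≈ 0.35, which is why that sample count is the generator's
default — the two thresholds are then nearly equivalent, as in the atlas
data the design mirrors.

qRT-PCR quantification follows 2^−ΔΔCt with ΔΔCt =
(Ct_target − Ct_reference)_treatment − (Ct_target − Ct_reference)_control.
Technical replicates are averaged at the Ct level within each biological
replicate; ΔΔCt is formed per biological replicate against its own
control; folds are averaged across biological replicates. The published
protocol states "technical triplicates within three biological
replicates" without fixing the aggregation order — this order is the
package's choice and makes control folds identically 1. Responder calls
use an inclusive two-fold boundary ("at least two fold"), and raising the
threshold can only remove responders. Expression clustering is
agglomerative with average linkage on 1 − PCC; constant rows, which have
no defined correlation, are assigned afterwards to the nearest cluster
mean in Euclidean distance, with a warning. Fold-display clipping to
[0, 3], used by the reference heatmaps, affects export only and never
computation.

## What the synthetic data emulates — and what it does not

The generators plant complete ground truth:

* `gen_bzip_protein()` builds sequences obeying the grammar with a chosen
  heptad count and substitutions. Filler residues — including the flanking
  tails — are drawn from the twelve residues that carry no grammar meaning
  (no N/R/K and no L/I/V/F/M). Keeping the tails on the same alphabet is
  an identifiability choice: a tail Asn landing 7k positions upstream of
  the planted anchor would inherit the planted heptad register and win the
  leftmost tie-break, making "planted truth" ill-defined. Real proteins of
  course use all twenty residues, so passing the recovery tests shows the
  annotator inverts the grammar, not that real proteins contain a unique
  anchor.
* `gen_bzip_gene()` reverse-translates a generated protein and cuts the
  CDS so each planted intron lands at the requested frame position and
  phase, on either strand. Introns are minimal GT…AG boxes; splice-site
  realism is out of scope.
* `gen_expression_matrix()` draws block members as
  mu_g + √r·z + √(1−r)·noise_sd·ε around a shared latent profile z.
  With the default `noise_sd = 1` the population within-block correlation
  is exactly `r_target` (other values deliberately de-calibrate it), and
  `r_target = 1` gives identical profiles regardless of noise. It does not
  model probe effects, normalization artifacts or heavy-tailed intensity
  distributions.
* `gen_qpcr()` inverts the ΔΔCt model (Ct_target = baseline −
  log2(fold) + noise, constant reference Ct per condition), so zero-noise
  tables recover planted folds exactly. Primer efficiency below 100% is
  not modeled.

All generators are bit-reproducible given (configuration, seed).

## Problem sizes and numerical choices

The shipped tests and the acceptance script use deliberately small,
self-contained problems: 500 generated proteins for grammar recovery, the
9 × 2 pattern grid, 50 additive matrices of 4–8 taxa for NJ consistency,
1000 background pairs at 54 samples for the type-I calibration (the
observed false-positive rate is checked against the 99.9% binomial band
around 1%), and 100 two-gene blocks for the correlation calibration.
Distance-matrix symmetry is enforced at 1e-12; NJ branch-length recovery
is asserted at 1e-9; PCC values are checked against a covariance-formula
oracle at 1e-12. A pair of sequences with no comparable alignment columns
receives distance 1 with a warning rather than NaN.

## Known limitations

* Domain detection is purely grammatical; divergent domains that an HMM
  would still score (or spurious matches an HMM would reject) behave
  differently here. E-value-based screening is metadata, not a step.
* Group assignment by nearest reference can disagree with full-tree clade
  inspection for borderline genes; the UC margin makes the ambiguity
  explicit rather than resolving it.
* The collinearity summary is only as good as the MCScanX run that
  produced its input; block counts are not reproducible from the family
  table alone.
* Multi-isoform loci are represented by the longest CDS, matching the
  one-protein-per-locus convention of family surveys.
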