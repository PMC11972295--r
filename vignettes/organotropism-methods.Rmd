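---
title: "Methods: cytogenetic organotropism analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cytogenetic organotropism analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(organotrope)
```

This vignette documents the models behind `organotrope`, the parameters that
matter, the numerical and design choices that were genuinely open, and what
the synthetic-data generator does and does not emulate.

## Data model

A CI (chromosomal imbalance) matrix holds signed presence codes for canonical
events such as `+7p`, `-18q`, `+8q23-q24` (focal) or `+12p amp` (high-level
amplification): gains carry 0/1/2, losses 0/−1. Band-resolution CGH profiling
cannot score some regions reliably, so the default exclusion mask removes
1p32–pter, the acrocentric short arms (13p, 14p, 15p, 21p, 22p), events
written with explicit telomeric bands, and the constitutive heterochromatic
blocks of 1q, 9q, 16q and Yq. The mask drops focal events intersecting a
masked interval but keeps whole-arm events on partially masked arms, since an
apparent whole-arm call refers to the analyzable portion of the arm. Masking
is idempotent. A high-level amplification counts once, as a gain, in all
count statistics; only the patient phylogenies treat it as a separate
character (its uncertain role in the aneuploidy count is resolved this way —
counting it twice would break the `n_total = n_gains + n_losses` identity).

For cohort-level statistics exactly one metastasis per patient is used,
selected by site priority brain > lung > liver (rarer sites first) and, within
a site, the lesion with the fewest CIs; remaining ties go to the
lexicographically smallest sample id so runs are reproducible.

The arm-level caller for segmented copy-number data is deliberately simple:
an arm covered below 50% of its length yields no call; otherwise it is called
gained/lost when ≥ 70% of the covered length exceeds ±0.2 log2, and a gain
becomes a high-level amplification when the length-weighted mean of the
gained segments reaches +1.0. These three constants mirror the defaults of
the arm-calling tools in common use for panel data; they are fixed,
documented constants, not fitted values. SEG input is 1-based inclusive and
converted to half-open coordinates internally; raising the altered-fraction
threshold can only remove calls, never create them.

## Enrichment testing

Per event, an omnibus 2×3 Fisher exact test compares present/absent counts
across the three sites, BH-adjusted across events (α = 0.05). The two-sided
p-value follows the "probability ≤ observed" convention (the dominant one;
the alternative of doubling a one-sided tail exists but is not used), with
the `(1 + 1e-7)` relative tolerance customary for exact-test ties. Events
seen fewer than 3 times across all metastases are excluded — below that,
an exact test cannot reach significance and the frequency estimate is
meaningless. Sex-chromosome events are kept in the data model but excluded
from enrichment and tree analyses by default, keeping those summaries
autosomal.

The enriched-site *set* needed a rule the source material assigns only
visually: here it is the maximum-frequency site plus every site whose
pairwise 2×2 comparison against it is not significant after BH adjustment
across all pairwise tests. This reproduces patterns like "liver-and-brain"
(brain highest, liver not significantly below, lung excluded) without any
per-event judgment calls. Whether the three-site comparison should be an
omnibus 2×3 test or pooled pairwise 2×2 tests is also not decidable from the
reported analyses; the omnibus-then-post-hoc form is used because it controls
the event-level error first and only then asks *which* sites differ.

Ternary coordinates are the per-site frequencies normalized to sum to one;
they are permutation-equivariant in the sites and are pure visualization —
no statistic is computed from them.

## Co-occurrence model

With margins fixed, the joint count of two events is hypergeometric; both
tail probabilities include the observed count, so `p_lt + p_gt ≥ 1` and the
two tails are not complementary — this matches the convention of the
ecology-style co-occurrence model the analysis follows. The pmf is computed
in log space (`lchoose`) and agrees with the equivalent product form
`C(N,j) C(N−j, n_b−j) C(N−n_b, n_a−j) / [C(N,n_b) C(N,n_a)]` to relative
error below 1e−10 (property-tested). Screens apply BH jointly over both tails
of all retained pairs; pairs below 3 marginal occurrences or an expected
joint count below 1 are filtered, and gain/loss of the same locus is skipped
as structurally exclusive. A consequence worth stating: the *screen's*
rejection rule (adjusted tails at α) is conservative under independence, but
the raw quantity `min(p_lt, p_gt)` is a union of two 0.05-level tails and is
only bounded by 0.10, not 0.05 — calibration checks must target one tail at a
time or the screen's actual decision rule.

## Oncogenetic trees

The generative model: the root is always present; event `v` is present with
probability `θ_v` if its parent is present and absent otherwise; every
observation is flipped independently with error rate ε. The default ε = 0.01
reflects the low but nonzero miscall rate of curated CI profiles; `top_k`
defaults to 25 events, the scale at which cohort trees remain readable and
frequencies stay estimable.

Fitting is a two-stage procedure fixed here because the original tree
software's exact algorithm is not described in the available text: (1) a
maximum-weight spanning arborescence (Chu–Liu/Edmonds, implemented in the
package and validated against brute-force enumeration for ≤ 6 events) on PMI
edge weights with the frequency-ordering constraint `f_u ≥ f_v`, using
pseudocount 0.5 so zero joint counts stay finite; (2) a hill-climb over
single-parent reattachments, scanned in fixed order and accepting only strict
likelihood improvements (> 1e−9), which makes the fit deterministic given the
input order and guarantees the final likelihood is at least the
arborescence's. θ is always the empirical conditional
`f_{pa,v} / f_pa ≤ 1`.

Event timing uses root distance `d_v = Σ −log θ` along the root path, so
improbable transitions push events later; nine equal-width, right-closed bins
of `[0, d_max]` give classes 1–9. "Equal distances" could equally mean
topological depth — both are implemented (`distance = "topological"`), the
weighted form is the default. A single-event tree has no early/late contrast
and is assigned class 1. Because edge lengths are non-negative, a child's
class is never below its parent's.

## Patient phylogenies

Binary characters (gain, loss, and separate high-level amplification
characters) over the patient's samples plus an all-absent normal taxon; Fitch
counting allows 0→1 and 1→0 at equal cost, since band-level profiles are net
clonal calls and apparent reversals occur. Topology search is exhaustive up
to 8 tumor samples ((2k−3)!! rooted binary shapes) and branch-and-bound above
(the partial Fitch score never decreases under leaf insertion). Score ties
are broken by the lexicographically smallest canonical newick, making results
reproducible. Validated against exhaustive topology × labeling enumeration
for ≤ 5 taxa and cross-checked against an independent parsimony
implementation.

Event-to-edge mapping enumerates all minimum-change labelings per character
and picks the one whose sorted change-edge depths are lexicographically
smallest — the "earliest suggested occurrence" rule; a shared gain always
beats private gains outright (1 < 2 changes), so ties arise only in genuinely
ambiguous configurations. Segments are defined by the number of branching
nodes strictly above an edge: 0 = trunk (the root→tumor-MRCA path),
1 = branches, ≥ 2 = sub-branches. This formalizes a division the source
figures draw but do not define. The CI score of a segment is the mean timing
class of its mapped events, taken from the oncogenetic tree of the patient's
metastasis site (site-specific rather than pooled classes — the choice is not
decidable from the reported analysis, and site-specific classes are the ones
the per-site trees actually provide).

The trunk/branches/sub-branches trend is tested with a within-patient
permutation test (difference of pooled segment means; labels permuted within
each patient; omnibus p from the maximum absolute pairwise statistic; BH
across pairs). The original analysis fit a linear mixed-effects model with
tumor as random effect; the permutation test is used here because it needs no
distributional assumptions at the small per-patient sample sizes involved and
is exactly specifiable. It requires at least two (and warns below five)
patients with ≥ 2 scored segments.

## The synthetic cohort generator

`simulation_config()` encodes the study conditions the analyses assume:
200 patients; site mix liver : lung : brain = 0.50 : 0.33 : 0.17 (the
117/78/39 lesion ratio of the motivating cohort); a 16-event generating tree
with the canonical CRC progression (−18q, +13q, +20q at the root; −8p/+8q,
−18p, +7p/+7q, +20p, −17p next; −3q, +5q, −6q, +12p deepest) and θ in
[0.3, 0.9]; four brain-designated late events (−3q, +5q, −6q, +12p) at
multiplier 3; four liver-and-brain events (+7p, +8q, −18p, +20p) at
multipliers 1.5–2 in both sites, reproducing the liver-and-brain /
brain-only / nothing-for-lung designation pattern; one top-down Bernoulli
acquisition pass before dissemination and two after (calibrated so metastasis
CI medians land near the printed 13 / 9 / 5 brain/liver/lung ordering rather
than saturating); dissemination uniform over the primary's acquisition order;
flip noise ε = 0.01; eight focal background events at rate 0.08; 30% of
patients get a second metastasis sample so phylogenies have material. A θ·m
product above 1 is clipped with a warning. The same seed yields byte-identical
output.

What the generator does *not* emulate: breakpoint-level segment structure,
tumor purity and signal-to-background variation (the reason the original
profiles needed per-sample thresholds), polyclonal seeding, within-lesion
heterogeneity beyond the single lineage per sample, and any mutation data.
Passing tests on this generator therefore demonstrate that the estimators
recover the designated structure under the stated noise model — not that real
CGH cohorts satisfy that model.

## Numerical choices and degenerate inputs

Tables with a zero margin return p = 1 (they carry no information). Empty
p-value lists adjust to empty lists. A constant event column is
uninformative: both co-occurrence tails are 1. Likelihoods are floored at the
smallest positive double before logging. Hill-climb acceptance requires an
improvement above 1e−9 to avoid cycling on ties. Barycentric coordinates sum
to 1 within 1e−12. Arm-caller coordinates are half-open internally; SEG and
cytoband readers accept `chr` prefixes.

## Problem sizes

The test suite and the acceptance script run at deliberately modest sizes:
oracle comparisons use ≥ 500 exact-test instances with table totals ≤ 12,
≥ 200 arborescence instances with ≤ 6 events, ≥ 200 parsimony instances with
≤ 5 taxa; recovery runs use the 200-patient default cohort; calibration uses
2,016 null pairs, 100 null events and 200 trend replicates at 199
permutations. These sizes give stable Monte-Carlo margins while keeping a
full run in the tens of seconds.

## Known limitations

The exact Freeman–Halton test is delegated to `fisher.test`'s network
algorithm, exercised only for 2×3 tables here; the oncogenetic-tree fit is a
local optimum (a deterministic one), not a global ML search, and mixtures of
trees are out of scope; bootstrap support for patient phylogenies is not
implemented; the arm caller is a simplified stand-in that ignores marker
counts and purity; and the trend test exchanges the mixed-model's explicit
variance decomposition for permutation validity, so it tests exchangeability
of segment labels within patients rather than a parametric effect size.
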