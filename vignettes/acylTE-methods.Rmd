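---
title: "Methods: subfamily delineation and specificity classification of acyl-ACP thioesterases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: subfamily delineation and specificity classification of acyl-ACP thioesterases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acylTE)
```

Acyl-ACP thioesterases (TEs) terminate fatty-acid chain elongation by
hydrolysing the thioester bond between the acyl chain and acyl carrier
protein; their chain-length specificity sets the fatty-acid profile an
organism (or an engineered *E. coli* strain) produces. `acylTE` implements
two complementary analyses for this enzyme family:

1. **Sequence arm** — organising a protein multiple sequence alignment
   (MSA) of TE catalytic domains into statistically validated
   *subfamilies* using pairwise maximum-likelihood (ML) distances under
   the Jones–Taylor–Thornton (JTT) model, distance-based trees with
   bootstrap supports, and a pairwise z acceptance test.
2. **Function arm** — classifying enzymes into *substrate-specificity
   classes* from in vivo fatty-acid measurements: internal-standard
   quantitation, control-strain background subtraction, mol%
   composition, and Ward hierarchical clustering with multiscale
   bootstrap (AU) p-values.

This vignette records the models, the tunable parameters, the numerical
choices, and the design decisions taken where the procedure was genuinely
open, together with what the synthetic-data generators do and do not
emulate.

## The JTT distance engine

The JTT model is an empirical reversible amino-acid substitution process.
We embed the published 1992 exchangeability counts `S` and equilibrium
frequencies `pi` and build the generator `Q[a,b] = S[a,b] * pi[b]`, scaled
to one expected substitution per site, so branch lengths and distances are
in substitutions/site. Transition matrices `P(t) = exp(Qt)` come from the
eigendecomposition of the symmetrized generator
`diag(sqrt(pi)) Q diag(1/sqrt(pi))`, which is numerically stable and makes
stationarity and detailed balance hold to near machine precision (they are
asserted in the tests at 1e-10 or better).

The pairwise distance between two aligned sequences maximizes the
independent-sites log-likelihood `sum(log(pi_a * P_ab(t)))` over the
*shared sites* — columns where both sequences carry one of the 20
canonical residues. Gaps and ambiguity codes (`B`, `Z`, `X`, `*`, `-`)
are treated as missing and removed per pair ("pairwise deletion"),
matching how distance matrices over patchy alignments are usually built.
Numerical choices:

* the optimum is bracketed on a fixed 121-point log-spaced grid over
  `[1e-6, 10]` and polished by Brent search to tolerance 1e-8; the grid
  and the polish are shared code between the single-pair function and the
  all-pairs matrix, so the two agree bitwise;
* a pair whose optimum lands within 1e-3 of the upper bound is reported
  at the bound (distance 10) and flagged `saturated` — downstream matrix
  algebra needs finite values, and the flag preserves the information;
* pairs with fewer than 20 shared sites are flagged `low_coverage`;
  a pair with zero shared sites is an error naming the pair;
* rates are uniform across sites (no gamma mixing); the model slot is a
  configurable extension point, but rate heterogeneity is deliberately
  out of scope.

Bootstrap replicates resample alignment columns with replacement and
recompute every pairwise distance with the *replicate's own* deletion
masks. Inside replicates the Brent polish is replaced by quadratic
interpolation on the likelihood grid (error well below the topological
resolution of a 300-site replicate); point estimates always use the full
tolerance. All-pairs likelihood evaluation is vectorized as one
`counts x log P(t-grid)` matrix product, which is what makes thousand-fold
resampling affordable in pure R.

## Trees

The point-estimate tree is neighbor joining (Q criterion) followed by a
minimum-evolution refinement: ordinary-least-squares (OLS) branch lengths
are fitted on the path-incidence matrix, and nearest-neighbor-interchange
(NNI) moves are accepted greedily while the total OLS tree length strictly
decreases (tolerance 1e-10; the move set comes from `phangorn::nni`). On
additive matrices NJ + OLS reproduces the generating tree to 1e-9, which
is the package's tree oracle. NJ ties are broken by the smallest
(row, column) pair so results are invariant to input order; negative
branch-length estimates are clamped to zero on output while the ME
criterion itself uses the raw OLS sum.

Edge supports are the percentage of bootstrap replicates whose tree
contains the same bipartition; replicate trees are plain NJ by default
(`refine = TRUE` switches the replicates to full ME refinement — the
well-supported edges this pipeline consumes are insensitive to that
choice, and the default keeps 1000 replicates cheap). Supports attach to
the point-estimate tree; a majority-rule consensus writer
(`majority_consensus`) is provided separately for users who prefer a
consensus topology. Outgroup rooting verifies the outgroup is one side of
a bipartition and splits the subtending edge at its midpoint.

## The subfamily z test

For two candidate subfamilies the package compares the mean inter-group
JTT distance against the pair-count-pooled mean intra-group distance:

    z = (d_inter - d_intra_pooled) /
        sqrt(var_inter / N_inter + var_intra_pooled / N_intra)

A partition is accepted when every pairwise `z > 3.3` (one-sided normal
tail probability 4.8e-4, i.e. p < 0.001) *and* every subfamily has at
least five sequences from at least five distinct species. Open choices
and how they were fixed:

* **Count convention.** Whether the denominators count distance *pairs*
  or *taxa* is ambiguous in the field's usage; both are implemented
  (`counts = "pairs"` is the default — each mean's sampling variance is
  naturally scaled by the number of distances averaged) and both are
  exercised in tests.
* **Variance pooling.** Group variances are pooled weighted by pair
  counts with population (denominator n) normalization by default;
  `"n-1"` is available.
* **Degenerate separation.** Two groups with constant distances have
  zero variance; if the inter mean exceeds the pooled intra mean the pair
  passes with an infinite-z sentinel flagged `degenerate` rather than
  failing on a 0/0.

### Proposing and refining partitions

Breaking a bootstrapped tree into "apparent subfamilies" is a human step
in practice; the automated surrogate takes, for every bipartition with
support at least `support_min` (default 70), the **smaller side** as a
candidate clade — a subfamily is in practice a minority clade, while the
far side of its stem is the union of everything else (when a split is
exactly balanced both sides are candidates). Candidates failing the
membership rule are dropped, and disjoint candidates are then chosen
greedily largest-first, so nested supported clades — including a clade
whose own basal sub-clades are also well supported — resolve to the
outermost qualifying one. A consequence worth knowing: a genuine subfamily larger
than half the dataset would be proposed via its complement's splits only,
which the refinement stage must then repair.

Refinement is a deterministic greedy loop standing in for manual
curation. While validation fails:

1. if the worst (lowest-z) pair's union is a clade in the tree, the two
   groups merge — this is what heals a true clade that the proposal
   artificially split;
2. otherwise the single sequence whose removal maximally increases the
   minimum pairwise z is ejected to non-grouped (ties broken by the
   lexicographically smallest id);
3. once all z pass, groups still violating the membership rule dissolve
   to non-grouped.

z failures are resolved *before* membership dissolution, otherwise
undersized fragments of one clade would dissolve instead of merging. The
loop is capped at `10 * j` iterations (j sequences); hitting the cap is
an error that carries the best partition found. Every action is logged
and serialized with the validation records for audit.

## Specificity quantitation

The in vivo assay spikes 10 ug heptanoic acid (7:0), 10 ug undecanoic
acid (11:0) and 20 ug heptadecanoic acid (17:0) into 2 mL of culture
supernatant; concentrations derive as `mass / MW * 1000 / volume`
(38.41, 26.84 and 36.98 nmol/mL). Analytes are referenced to the standard
covering their chain length — up to C9 to 7:0, C10–C12 to 11:0, C13 and
longer to 17:0 — with methylketones assigned by carbon count. C9 is not
covered by the stated ranges (C4–C8, C10–C12, >C12); it maps to the
nearest standard, 7:0, and the mapping is configurable. Molar response
factors default to 1 per species (no published response curves to invert)
and are configurable.

Net production subtracts the control-strain background (defaults: 8:0 at
2.0, 14:0 at 3.5, 16:0 at 3.1 nmol/mL) and clamps negatives to zero,
logging the clamped species — compositions are reported non-negative, and
a strain producing less than background carries no usable signal for that
species. Fatty-acid mol% is net concentration over the fatty-acid total;
methylketones are expressed relative to the same fatty-acid total but
excluded from the denominator, so fatty-acid mol% always sums to 100.

## Class clustering

Enzymes are clustered on their mol% vectors with Euclidean distances and
classical minimum-variance Ward agglomeration (Lance–Williams updates on
squared distances; `stats::hclust`, method `ward.D`, on `d^2` — the
merge heights are therefore twice the within-cluster sum-of-squares
increase, which the tests pin against a brute-force agglomeration
oracle). Cluster uncertainty uses multiscale bootstrap: the species
(feature) columns are resampled at scales `r` in 0.5–1.4 (step 0.1,
configurable), drawing `ceiling(r * m)` of the `m` columns with
replacement, 1000 replicates per scale by default. Per-node presence
frequencies `BP(r)` are clipped to `[1/(B+1), B/(B+1)]` and fed to a
weighted probit regression `qnorm(1 - BP(r)) ~ v*sqrt(r) + c/sqrt(r)`
with inverse delta-method variance weights; the approximately-unbiased
p-value is `AU = 1 - pnorm(v - c)`. A node recovered in every replicate
at every scale reports AU = 1 (the regression on all-clipped values is
degenerate). Both AU and the plain `BP` at scale 1 are reported, since
published dendrogram p-values are not always explicit about which they
are.

Two caveats are deliberately surfaced in reports: the feature universe is
small (typically ~14 fatty-acid species), which limits AU accuracy — and
is why both AU and BP are emitted — and the class count `k` defaults to 3
but is a parameter, with mean silhouette widths for k = 2..6 emitted as a
diagnostic.

## Synthetic data: what it emulates and what it does not

`simulate_tree` draws each subfamily as a random coalescent-shaped
subtree (tip depths uniform in `[0.5, 1] * intra_depth`) joined by stems
of fixed length — coalescent shapes give realistic within-clade distance
variance, so the z denominators are non-degenerate, unlike ultrametric
balanced trees. `simulate_alignment` evolves sites independently down the
tree from stationary root draws. `simulate_profiles` draws mol% vectors
from a Dirichlet centred on one of three class archetypes (C14/C16-heavy;
bimodal C8+C14; C8-dominant; concentration 200 by default), totals from a
lognormal (median 100 nmol/mL, sdlog 0.5 — the spread of totals seen
across expressed TEs), adds the control background, and emits peak tables
by inverting the internal-standard arithmetic so the whole quantitation
path is exercised.

The generators are seeded and bit-reproducible, and they define the
package's test conditions: subfamily recovery is checked on 3 clades x 10
tips, 300 alignment columns, intra-clade depth 0.1 and stems of 1.0
substitutions/site, with a 200-replicate null calibration obtained by
randomly halving a single homogeneous clade; class recovery is checked on
8 profiles per archetype over 20 seeds with full 1000-replicate
multiscale bootstraps. These sizes keep the full suite within minutes on
one core while leaving the statistical margins wide.

What the simulations do **not** emulate: alignment error and indels, rate
heterogeneity across sites or lineages, database fragments/misannotations
(the reason the membership rule and non-grouped pool exist), GC-MS noise
physics, or per-analyte detector response. Passing tests therefore
demonstrate the *procedures* are implemented and calibrated as specified,
not that real TE datasets will partition as cleanly.

## Sequence-level utilities

Plant TEs are nuclear-encoded and plastid-targeted; the mature protein is
taken to start at the first occurrence of the conserved `LPDW` motif
(multiple occurrences: the first wins — a deterministic stand-in for a
single conserved site; absence is an explicit no-cleavage-site result,
never a silent truncation). Molecular weight sums average (or
monoisotopic) residue masses plus one water; the theoretical pI bisects
the Henderson–Hasselbalch net-charge function on `[0, 14]` to 1e-4 pH
units using the Bjellqvist pKa set by default. Published MW/pI figures
depend on the pKa set and mass table used, so exact reproduction of any
particular published range is not asserted — the pKa table is an argument.

## Known limitations

* The ME search is NJ + greedy NNI, not an exhaustive search; on
  non-additive matrices it can stop in a local optimum (tests cover
  additivity and small perturbations, where it is exact).
* The proposal stage cannot nominate a subfamily spanning more than half
  the sequences except via balanced splits.
* AU values from ~14 features are approximations; treat them as ranks,
  not calibrated probabilities.
* Pairs at distance 10 (saturated) contribute a floor value to group
  statistics; heavily saturated datasets should be pruned first (flags
  are in the distance object).
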