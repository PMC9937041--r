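---
title: "Models and design choices in ponevo"
author: "ponevo authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in ponevo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`ponevo` reconstructs the history of a single-domain gene family — the
paraoxonase (PON) family is the motivating case — through four stages:
family identification from domain-hit tables, constrained-topology
likelihood tests, codon-model positive-selection tests, and a structural
clustering test for the selected sites. This vignette documents the
models, their assumptions, the tunable parameters, and the places where
the design was genuinely open and a choice had to be made.

## Likelihood engine

All phylogenetic likelihoods are exact Felsenstein-pruning likelihoods on
a fixed tree, with site patterns compressed (compression is lossless: the
suite checks the total equals the column-by-column sum to 1e-9). Gaps and
ambiguity codes are missing data — a tip contributes a partial likelihood
of one for every state — which matches how trimmed alignments are
conventionally treated.

Reversible rate matrices are built as `Q = S diag(pi)` with zero row
sums, checked for detailed balance, and scaled to one expected
substitution per site at stationarity, so branch lengths are in expected
substitutions per site. Matrix exponentials use the symmetric
eigendecomposition of `diag(sqrt(pi)) Q diag(1/sqrt(pi))`: exact, stable,
and reusable across branches. Because the eigensystem of a codon model
depends only on (kappa, omega), the site-model fitters memoize
eigensystems across optimizer evaluations, and mixture evaluations share
subtree messages between classes that assign the same omega to the same
branches — both are pure caching layers and change no likelihood value.

**Amino-acid models.** Poisson, JTT and LG; the JTT and LG
exchangeability/frequency tables ship as plain-text files in the
standard lower-triangle layout (the published values, checksummed at
load). Rate heterogeneity uses discrete-Gamma categories: k equal
probability bins of Gamma(alpha, alpha), each represented by its
analytic bin mean, so the category means average exactly 1. The default
k = 4 is the convention behind "+G" fits in the common ML programs; the
count is configurable. Bin means (not medians) were chosen to match that
same convention. An optional invariant-sites class holds a site
completely fixed with probability `pInvariant`; the Gamma rates are
divided by `1 - pInvariant` so the full mixture keeps mean rate 1.

**Codon models.** Goldman–Yang style over the 61 sense codons of the
standard code: single-nucleotide changes only, target-frequency
proportional, kappa for transitions, omega for nonsynonymous changes.
Codon frequencies default to F3x4 estimated from the alignment (F1x4,
F61 and equal frequencies are available); the choice is declared, not
inferred from any external convention. For site mixtures the scale factor
is the weighted mean rate across classes, computed with the *background*
omegas — the foreground omega of a branch-site model affects only the
marked branches, which are a small part of the tree; this convention is
stated here because published implementations are not explicit about it.

## Optimization

`optimizeBranchLengths()` is cyclic bounded Brent search on the
log-length scale (bounds 1e-8 to 50), converging when a full sweep gains
less than 1e-6 log units; its trace is non-decreasing by construction and
the suite asserts it. `fitModel()` and the site-model fitters instead
default to joint bounded quasi-Newton search (L-BFGS-B with a
forward-difference gradient) over log branch lengths and the transformed
model parameters — the coordinate-wise strategy needs several times more
likelihood evaluations for the same optimum, and on the replicated
calibration runs that difference is hours. Proportion vectors use
stick-breaking coordinates to stay on the simplex; omega is bounded above
by 50, omega2 below by 1 in the branch-site alternative.

Deterministic starts: branch lengths from the input tree, kappa = 2,
omega = 0.5; the branch-site fit starts at kappa = 2, omega2 = 1
(mirroring the conventional initialization) and, because the surface is
flat at the omega2 = 1 boundary, adds deterministic restarts stepped off
it. M2a and M8 use three deterministic restarts against their known
multimodality. `fitBranchSitePair()` fits the null first and warm-starts
the alternative from the null solution (at the boundary and stepped off
it), which both saves evaluations and enforces the nesting invariant —
the alternative can never end below the null beyond optimizer tolerance.

## Selection tests

Site-model LRTs compare M1a/M2a and M7/M8 with df = 2; the branch-site
test compares model A against its omega2 = 1 null with df = 1. The plain
chi-square calibration is used deliberately — it is the convention that
produced the published p-values this class of analysis reports — and the
raw statistic is always emitted so users can recalibrate (e.g. with the
conservative mixture null). The same applies to the fixed-topology
contrasts, which use chi-square df = 1 even though the candidate
topologies are not nested in the usual sense: the package reproduces that
procedure faithfully and transparently rather than replacing it.

Site identification: NEB is Bayes' rule at the MLEs over the per-site
class likelihoods; BEB averages the same posterior over a uniform
10-point prior grid per free dimension (class proportions on the simplex,
omega0 in (0,1), omega2 in (1,11); M8 integrates over p0 and omegaS with
the beta shapes at their MLEs). This follows the published BEB scheme in
structure; numerical agreement with any specific implementation's grid is
not claimed. The selected-site list is exactly the sites whose
positive-class posterior exceeds the threshold (default 0.5).

Synonymous-rate variation and multinucleotide substitutions are *not*
modeled; both can inflate branch-site signals, and the pipeline's
selection report carries that caveat alongside its results.

## Synthetic data

The generators exist so every downstream stage can be tested against
known truth, and they share the exact substitution processes of the
likelihood engine: the root is drawn from the stationary frequencies and
evolved through `exp(Qt)` along each branch (end-point sampling — no
Gillespie paths, because only end states are observed). Latent site
classes and rate categories are recorded in a truth table. A master seed
spawns a named child stream per generator, so adding a generator never
perturbs another's stream, and identical specs give byte-identical
output.

Locus tables plant tandem arrays (spacing is recoverable exactly:
`gap` bp lie strictly between consecutive gene ends), absences, and
single-exon retrocopy plants; hit tables carry the planted genes at
e-values well below 1e-6 plus decoys straddling the cutoff, labeled with
their truth. Pseudo-structures place C-alphas on a 3.8-Angstrom
self-avoiding walk, with an optional planted cluster re-placed inside a
sphere; they parse back through the same PDB reader the analysis uses.

What the generators do *not* emulate: indels and alignment error (inputs
are assumed aligned and trimmed), assembly fragmentation (a real scan's
main false-duplication risk), saturation beyond what the chosen branch
lengths imply, and real structure chemistry (side chains, chain breaks).
Passing tests therefore demonstrate that the *rules and estimators* are
implemented correctly and are calibrated under their own assumptions —
not that those assumptions hold for any particular genome assembly.

## Family-scan conventions

The dual e-value threshold (full sequence and best domain, both at most
1e-6) is read as an inclusive bound, as are the BLAST coverage/identity
cutoffs (90%, 50%) — "maximum/minimum of x" treated as attainable.
Tandem arrays chain by single linkage: loci on one scaffold join one
array when the bases strictly between their nearest gene ends are at most
the 100-kb window, so an array may span more than 100 kb end-to-end when
each consecutive gap passes. Array letters follow scaffold name then
coordinate — the ordering is a determinism choice, not an inherited
convention. End-to-end (not start-to-start) distance is likewise our
reading of "within 100 kb of another gene". The retroduplication rule —
single-exon locus against a clade whose other members have a median of
at least two exons — is a deliberate formalization of the qualitative
intron-loss signal. Loss calls are conservative by construction: one
detected member anywhere in a group vetoes the claim.

## Structure stage

ASA is Shrake–Rupley with a deterministic golden-spiral point set (960
points per atom, probe 1.4 Angstrom). A published grid-based method
inspired the exposure step, but its exact algorithm differs; agreement is
claimed for the exposure *classification* (ratio of ASA to the residue
type's theoretical maximum, exposed at >= 0.2, inclusive), not for raw
areas. Rotation invariance holds to the sampling tolerance (0.5% on the
total; individual atoms carry the binomial error of a 960-point sphere
sample).

The clustering statistic is the mean pairwise C-alpha distance of the
selected residues — the simplest functional consistent with "clustered
more closely than expected by chance"; mean nearest-neighbor distance is
available behind a flag. The null pool is the exposed residues (a flag
widens it to all residues with C-alpha), the draw is uniform without
replacement per subset, and p = (b+1)/(N+1), so p is never below
1/(N+1) — claims at the 1e-6 scale need a million permutations; tests
use 1e4 and the default CLI example 1e4-1e6 depending on the claim.
Whether side-chain rather than C-alpha positions should anchor the
distances is unknowable from the published description; C-alpha was
chosen and is stated.

## Problem sizes in the test suite

The replicated calibrations run at sizes chosen once for statistical
meaning at desk scale: one-ratio recovery at 2,000 codons on 6 taxa
(20 replicates per omega in {0.2, 1, 3}); branch-site power at 352
codons — the length of the marsupial PON3 alignment that motivates the
pipeline — with 12% of sites at omega2 = 5 on a 3-branch foreground
clade (50 replicates); null calibration with 200 replicates at the same
size. Power replicates re-estimate branch lengths (the `"m0"` mode, a
standard practical shortcut that fixes branch lengths at a one-ratio
estimate); the null calibration conditions on the generating branch
lengths, isolating the chi-square approximation itself. The enumeration
oracle covers 100 random trees of up to 5 leaves, where exhaustive
interior-state summation is feasible.

## Known limitations

- No topology search, bootstrap, or alignment construction: trees and
  alignments are inputs.
- The branch-site chi-square(1) calibration is anti-conservative in
  theory; we reproduce it as the field's operative convention and emit
  the raw statistic.
- BEB numerical values depend on the prior grid; only the scheme, not
  any implementation's exact numbers, is matched.
- Likelihoods are computed without per-node rescaling, which is ample
  for the tens-of-taxa, desk-scale analyses the package targets but
  would underflow on very large trees.
- The pipeline validates and orchestrates; it is not a workflow engine
  (no caching, no DAG scheduling).
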