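---
title: "The GESTALT editing model, its likelihood, and how this package validates them"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The GESTALT editing model, its likelihood, and how this package validates them}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gestaltphylo)
```

# The recording process

A GESTALT barcode is a transgene carrying an array of M CRISPR/Cas9 target
sites (typically up to ten sites of roughly 20–23 bp). While Cas9 and the
guide RNAs are present, each site can be cut; error-prone repair then
leaves an insertion and/or deletion — an *indel* — at the cut. Two
properties make these data unlike ordinary sequence alignments:

* **Irreversibility.** An indel destroys complementarity with the guide,
  so an edited site can never be edited again.
* **Dependence.** A *double cut* at two sites deletes everything between
  them, deactivating the intermediate sites and physically removing
  ("masking") any indels they carried. Long repair trims can likewise
  reach into a neighbouring site and deactivate it.

`gestaltphylo` models a cell's barcode as a continuous-time Markov chain
over *alleles* (sorted, non-overlapping indel sets in unedited-barcode
coordinates) and computes the probability of an alignment of such alleles
on a time-scaled binary lineage tree.

# Event classes: target tracts

Every editing event is summarized by a *target tract* `(j0, j, j', j1)`:
targets `j..j'` are cut (`j = j'` is a single cut) and targets `j0..j1`
are deactivated, with `j0 = j - 1` exactly when the left trim is *long*
(reaches into the left neighbour's site) and `j1 = j' + 1` symmetrically.
A tract is available only while its listed targets `j0, j, j', j1` are all
active; intermediate targets of a double cut may already be edited — that
is how masking arises. Tract hazards are

* single cut: `lambda_j * p_class`,
* double cut: `omega * (lambda_j + lambda_j') * p_class`,

with `p_class` the product of the per-side trim-class probabilities
`gamma/(1 + gamma)` (long) or `1/(1 + gamma)` (short). Folding the trim
class into the hazard makes tract classes mutually exclusive competing
events, so the total leaving rate of an editability status is the plain
sum of its tract hazards (`totalHazard()`, checked against
`statusRateMatrix()` in the tests).

Conditional on a tract, the *details* of the repair are the left and right
trim lengths, drawn from truncated Poisson laws on the class's admissible
range, and an insertion of truncated-Poisson length with bases uniform on
A/C/G/T. Short trims run from 0 to the distance between the cut and the
target's edge; long trims from one past that boundary to one bond short of
the adjacent cut site. For single cuts the all-zero outcome (no trim, no
insertion) would be an unobservable self-transition and is excluded with
renormalization. Per tract, detail probabilities sum to one (verified to
1e-9 in the tests).

The literature on this editing process defers the exact repair-length laws
to supplementary material; the truncated Poisson family here is this
package's concrete choice, made once and shared verbatim between the
simulator, the likelihood and the brute-force oracle, so every
correctness check in the package is independent of that choice.

# Clock scaling

GESTALT models originally measured branch lengths in expected edits. This
package multiplies the tract generator Q by a molecular clock rate `r`
(indels per target site per time unit) so that a branch of calendar length
`t` has transition matrix `exp(Q r t)`; per-branch rate multipliers are
accepted as fixed inputs. The likelihood therefore depends on branches
only through the products `r_i t_i` — an invariance asserted directly in
the test suite — and time-scaled trees expose their node times to
phylodynamic priors.

# The pruning likelihood and masking

The likelihood sums over ancestral alleles at internal nodes (Felsenstein
pruning) with the root fixed to the unedited allele. Two devices keep this
finite:

* **Candidate ancestral sets.** At node v, candidate indels are those that
  every leaf below v either carries identically or masks (footprint
  strictly inside one of its deletions); candidate alleles are all
  mutually compatible subsets, capped by `maxStates` (exceeding the cap is
  an explicit error, never silent truncation).
* **Branch state spaces.** For a branch from allele `a` to constraint
  `b`, states are pairs `(A, H)`: `A` the introduced subset of the new
  observed indels `b \ a`, `H` the targets deactivated by *hidden* events
  — edits that occurred and were later masked, on the same branch, by one
  of the not-yet-introduced observed deletions. Hidden events enter at
  rate `hazard * p_fit`, where `p_fit` marginalizes the repair details
  whose footprint fits strictly inside the covering deletion (insertion
  length integrates out entirely, since inserted bases vanish with the
  masked indel). Everything incompatible with reaching `b` drains into an
  absorbing sink, and impossible transitions return `-Inf` rather than
  raising, so samplers can reject gracefully.

The per-(parent, child) generators are small, acyclic and parameterized by
simple hazard products, which is what the compiled evaluator exploits: the
structure is built once per (tree, alignment) and re-evaluated in C
(closed forms for trivial spaces, row-vector uniformization otherwise,
scaling-and-squaring for large `r t`) under new parameters — the access
pattern of MCMC. Per-edge results are cached and only edges marked dirty
are recomputed after node-time moves; the cached-versus-fresh identity is
a test.

## What the candidate restriction can and cannot represent

With candidates drawn from the indels *observed* in the alignment (the
default, `stateUniverse = "observed"`, the standard parsimony-guided
scheme in this field), one class of histories is not representable: an
edit introduced on one branch that survives an internal node and is masked
*further down* in every descendant leaf. Its footprint would have to fit
inside different deletions on different child lineages simultaneously, so
no tract-level lumping can marginalize it exactly. On barcode designs
whose full detail space is small, `stateUniverse = "bounded"` enumerates
every admissible indel as a candidate, which restores exactness; the
oracle-equivalence tests (pruning vs `bruteForceLogLikelihood`, agreement
to 1e-6 on dozens of randomized instances including masking and
asymmetric cut placement) run in that mode. On realistic designs the
observed-universe likelihood is therefore an approximation whose quality
degrades as inter-target deletions become common; the calibration study
below quantifies where it is adequate.

# Simulation

`simulateBirthDeathTree()` runs a forward Gillespie birth–death process
from one founding cell, samples survivors at the end of the experiment
with probability `rho`, prunes to the sampled tips and rejects until the
tip count falls in the requested range (the conditioning convention is
this package's choice; a stop-at-n mode is provided for tree-shape work,
where the topology law is identical). `simulateAlignment()` then runs the
editing chain down the tree with competing-exponential event times, the
same tract hazards and detail laws as the likelihood, and physical removal
of masked indels; an optional origin stem lets editing start at
fertilization rather than at the first sampled split. Simulator and
likelihood are pinned together by distribution-level tests: single-branch
allele frequencies against analytic transition probabilities (total
variation < 0.03 at 10,000 replicates), survival probabilities against
`exp(-h r t)`, and first-event tract frequencies against hazard ratios.

# Tree priors

The birth–death-sampling density uses the standard constant-rate
expressions with present-day sampling, conditioned on survival, with
origin conditioning by default (the origin time is then a free parameter
under its prior) and root conditioning as an option; an optional
tip-count conditioning makes the two-tip density integrate to one, which
is verified by quadrature. The exponential-growth coalescent uses the
deterministic trajectory `N(t) = e^{g t}` with `N = 1` at the origin, so
the sampling proportion of `s` sequenced cells is reported as
`s / e^{g t}`; at `g = 0` it reduces exactly to the Kingman coalescent,
checked against an independently coded Kingman density. Node times are
stored forward (root earliest) and converted to ages internally.

# The sampler

`runMcmc()` is Metropolis–Hastings with log-scale random-walk ("scale")
moves on positive scalars (Jacobian `s`), a transfer move on the cut-rate
vector that preserves its mean-one constraint (with a free clock the scale
of `lambda` is not identifiable, so the time scale lives in `r` alone),
uniform node-time slides, a root-age scale move, and narrow-exchange and
Wilson–Balding topology moves. Proposal scales auto-tune toward ~30%
acceptance during burn-in only. Fixed-topology runs over editing
parameters (including pooled replicates, which share editing and growth
parameters while keeping per-replicate trees and multiply the replicate
likelihoods) execute entirely in compiled code; the general R path covers
node-time, topology and phylodynamic moves at the problem sizes used in
examples and tests. Move correctness is anchored three ways: a
detailed-balance check of the scale move on a one-parameter target,
prior-only runs whose samples must reproduce the prior quantiles
(Kolmogorov–Smirnov), and the calibration study as the end-to-end test.

Diagnostics follow the common conventions: `effectiveSampleSize()` is
`n / (1 + 2 * sum(acf))` truncated at the first non-positive
autocorrelation (a constant series is defined to have ESS `n`);
`hpdInterval()` is the narrowest contiguous window containing
`ceiling(level * n)` sorted samples; `mccTree()` picks the sampled tree
maximizing the product of posterior clade frequencies and sets node
heights to per-clade medians (retaining sample heights is an option).

# The calibration study and its scale

`runCalibration()` implements simulation-based calibration: draw editing
parameters from the priors, simulate a tree and an alignment, infer with
the tree fixed to truth and priors equal to the simulating distributions,
and record whether each alpha-level HPD interval contains the truth.
Under a correct implementation coverage equals alpha.

The default study conditions are the package's scaled-down standard: 30
replicates, 10-tip trees (division rate `log(12)/25` per day over a
25-day experiment, rejection-conditioned to exactly 10 sampled tips), the
4-target 23 bp-per-site barcode, clock prior lognormal around 0.02
indels/site/day (so the expected cut intensity over the experiment is
about 0.5 per site — deliberately a low-information recording regime),
double-cut weight and long-trim factors lognormal around 0.05 (the
magnitude seen in published estimates for this barcode design, under
which inter-target deletions are a minority of events), symmetric
Dirichlet(10) cut rates, and chains of 2e5 iterations with 30% burn-in
and ESS flags at 200. These sizes keep the whole study in the
few-minutes range on one CPU; a full-scale study (more replicates, longer
chains) is a matter of raising the arguments.

Two statistical points shape the pass criterion:

* A rule demanding *every* of 8 parameters x 19 levels inside its own 95%
  binomial band rejects a *perfectly calibrated* sampler most of the time
  (about 80% rejection at n = 30, by Monte Carlo of the rule itself).
  `calibrationWellCalibrated()` therefore requires every parameter inside
  its exact binomial band at the 95% level and at most 10% of all grid
  cells outside their bands; the strict all-cells rule remains available
  as `calibrationPasses()`.
* The mis-specified negative control (`hazardScale = 2`: every cut hazard
  doubled in the inference model only) must fail the same composite
  check — it does, most visibly through the clock's collapsed coverage.

Because the editing regime is drawn from the priors, occasional draws are
masking-heavy, and there the observed-universe approximation leaves a
trace: mild residual under-coverage concentrated on the last target's cut
rate. Within the study conditions above it stays inside the acceptance
bands; a package user working with barcodes whose double-cut fraction is
large should treat the editing-parameter posteriors with according
caution. This is the main known limitation, and it is shared by the
parsimony-guided state restriction generally. What a passing calibration
shows is that, in the stated regime, the sampler targets the stated
posterior; it does not certify real-data features outside the model —
time-varying editing rates, synchronous divisions, sequencing error or
doublets, or barcode designs far from the contiguous-array geometry all
remain outside scope.

# Numerical and design choices

* Coordinates are 0-based half-open base intervals with cut sites as
  inter-base bond indices; target indices run 1..M. A deletion covers a
  cut bond `c` when its closed footprint `[start, start + len]` contains
  it, which classifies every admissible trim consistently on contiguous
  target arrays (all shipped designs are contiguous).
* Allele normalization merges raw indels that overlap, abut, or touch the
  same target site into a single spanning indel (insert sequences
  concatenated in barcode order) — the exact upstream rule is pipeline
  lore, so this reconstruction is pinned down by round-trip and
  idempotence tests rather than by external parity.
* A zero-length-deletion insertion deactivates only the target holding
  its bond.
* Matrix exponentials: `Matrix::expm` on the small dense generators in
  the reference path; in compiled code, closed forms for one-state
  spaces, uniformization with a 1e-14 Poisson tail bound for event
  intensities up to 30, and series-plus-squaring beyond.
* The brute-force oracle is kept honest by construction: it enumerates
  the complete allele space of designs whose admissible detail space is
  finite and tiny (narrow targets, insertion length at most 1), so oracle
  and likelihood share identical laws with no truncation error.
* Trees are plain `ape::phylo` objects (validated by
  `validateLineageTree()`); clade bookkeeping, postorders and depths are
  computed internally so that hand-edited edge matrices from topology
  moves are handled robustly.
* The likelihood's optional origin branch conditions on the barcode
  surviving the stem unedited; the simulator's `originTime` actually
  simulates stem edits. In low-editing regimes the difference is the
  small probability of a pre-division edit, and the calibration study
  sidesteps it by starting editing at the root on both sides.
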