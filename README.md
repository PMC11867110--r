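# gestaltphylo

Bayesian phylodynamic inference for GESTALT CRISPR/Cas9 lineage-tracing
barcodes.

GESTALT (genome editing of synthetic target arrays for lineage tracing)
records cell lineage in a compact DNA barcode: an array of M CRISPR target
sites that accumulate irreversible insertions/deletions ("indels") as an
organism develops. Reading the barcodes of sampled cells and modelling the
editing process yields time-scaled cell lineage trees, and — through a
birth–death or coalescent tree prior — estimates of cell division rates and
sampling fractions. The difficulty is that GESTALT target sites are
*dependent*: a single Cas9 double cut can delete several sites at once and
physically erase ("mask") earlier edits.

`gestaltphylo` implements, in one R package:

* **The editing model.** Editing events are *target tracts*
  `(j0, j, j', j1)`: a cut at targets `j..j'` (single cut when `j = j'`,
  double cut otherwise) with short or long deletion trims on each side,
  where a long trim deactivates the adjacent target (`j0 = j-1` /
  `j1 = j'+1`). Hazards are
  `h = lambda_j * p_class` (single) and
  `h = omega * (lambda_j + lambda_j') * p_class` (double), with
  `p_class = [gamma0/(1+gamma0) or 1/(1+gamma0)] * [gamma1/(1+gamma1) or
  1/(1+gamma1)]` folding the trim classes into mutually exclusive events.
  Trim and insertion lengths follow truncated Poisson laws on the
  geometry's admissible ranges; insertion content is uniform over A/C/G/T.
  A molecular clock rate `r` (indels per site per time unit) converts
  branch lengths `t_i` into transition probabilities `P = exp(Q r t_i)`.
* **The phylogenetic likelihood.** Felsenstein pruning over candidate
  ancestral alleles, with per-branch finite state spaces `(A, H)` that
  marginalize hidden events masked by later inter-target deletions, plus a
  brute-force oracle (`bruteForceLogLikelihood`) that enumerates the full
  allele space on tiny designs. The hot path is compiled (Rcpp).
* **A forward simulator** for birth–death-sampling trees (Gillespie, with
  rejection conditioning on the sampled tip count) and GESTALT alignments
  along them.
* **Tree priors**: the constant-rate birth–death-sampling density (origin
  or root conditioning) and the exponential-growth coalescent
  (`N(t) = e^{g t}`), with `expectedPopulationSize()` and
  `coalescentSamplingProportion()` helpers.
* **An MCMC engine** (`runMcmc`) over editing parameters, node times,
  topology (narrow exchange, Wilson–Balding) and phylodynamic parameters,
  with pooled-replicate analyses, BEAST-style trace/Nexus tree logs, ESS
  and HPD diagnostics, and maximum clade credibility summaries
  (`mccTree`).
* **A validation harness**: simulation-based calibration
  (`runCalibration`) and tree-imbalance diagnostics (`collessIndex`,
  `expectedCollessYule`).

## Worked example

Simulate a small experiment on a 4-target, 23 bp-per-target barcode and
re-infer the editing parameters on the true tree:

```r
library(gestaltphylo)

design <- v7BarcodeDesign(4)               # 4 x 23 bp, cut 6 bp from each 3' end
truth  <- editingParams(clockRate = 0.02,  # indels / site / day
                        cutRates = c(1.2, 0.8, 1.1, 0.9),
                        doubleCutWeight = 0.05,
                        longTrimLeft = 0.05, longTrimRight = 0.05)

phy <- simulateBirthDeathTree(birthDeathSimConfig(
  birthRate = log(12) / 25, duration = 25, nMin = 10, nMax = 10, seed = 1))
aln <- simulateAlignment(phy, design, truth, seed = 1)
summarizeAlignment(aln)$meanIndelsPerSite
#> [1] 0.35

trace <- runMcmc(list(mode = "fixed-topology", alignment = aln, tree = phy,
                      params = editingParams(cutRates = rep(1, 4)),
                      chainLength = 2e5, thin = 50, seed = 2))
post <- discardBurnIn(trace, 0.3)@trace
median(post$clockRate); effectiveSampleSize(post$clockRate)
#> [1] 0.02064109
#> [1] 2407.99
hpdInterval(post$clockRate, 0.95)
#> [1] 0.009600752 0.034742647
```

The posterior median clock (0.021 indels/site/day) recovers the simulating
value 0.02 and the 95% HPD interval `[0.0096, 0.035]` covers it; an ESS above
2000 from 2800 retained samples indicates good mixing. Tiny example inputs
(a simulated alignment, its tree and parameter files) ship under
`inst/extdata/`, and `inst/scripts/gestaltphylo-cli.R` exposes `simulate`,
`infer`, `summarize`, `calibrate` and `imbalance` subcommands for shell use.

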