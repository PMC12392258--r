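---
title: "Probability-aided compound annotation for nontargeted LC-HRMS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probability-aided compound annotation for nontargeted LC-HRMS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ntaprob)
```

## The annotation problem

In nontargeted analysis (NTA) by reversed-phase liquid chromatography
coupled to high-resolution mass spectrometry (RPLC/HRMS), each detected
feature — a retention × m/z × intensity "tensor" — is annotated by
matching its MS/MS spectrum against reference spectral libraries. Two
chronic problems limit the confidence of such annotations. First, a
matching score alone cannot tell a true positive (TP) reference match
from a plausible-looking false one, especially for structural analogs.
Second, one feature typically matches several candidate compounds
("hits"), each through several reference spectra, and a single
best-scoring match hides that ambiguity.

`ntaprob` addresses both with a three-model workflow plus a simple
probability calculus:

1. **Fingerprint → RTI model.** A random-forest regression from
   molecular fingerprints to a harmonized retention-time index (RTI),
   giving a retention estimate `RTI_MF` for any candidate *structure*,
   without calibrant injections.
2. **CNL → RTI model.** A second random forest from the cumulative
   neutral losses (CNL) of an MS/MS spectrum — the set of precursor
   minus fragment mass differences, encoded as binary indicators over a
   masses-of-interest (MOI) list, plus the monoisotopic mass — giving a
   retention estimate `RTI_CNL` for the measured *spectrum* itself.
3. **P(TP) classifier.** A k-nearest-neighbor binary classifier that
   converts each individual spectral match into a class probability of
   being a true positive, from six features: `RefMatchFragRatio`,
   `MS1Error`, `MS2ErrorStd`, `FinalScoreRatio`, the monoisotopic mass,
   and the retention error `rti_error = RTI_MF − RTI_CNL`.

The key idea is the retention error: for a correct match the structure
and the spectrum describe the same molecule and the two RTI estimates
agree; for a wrong candidate structure `RTI_MF` belongs to a different
molecule and the error inflates. This single feature carries most of
the discriminating power beyond the spectral score, and ablating it
measurably reduces recall (the package's acceptance suite reproduces
this contrast).

Per-match probabilities are then aggregated: each candidate hit gets the
arithmetic mean of its matches' P(TP); hits with average P(TP) ≥ 0.5 are
shortlisted; and the identification probability of the feature is
IP = 1/N over the N shortlisted hits (reported as a percentage, with
"nd" for an empty shortlist). IP measures annotation ambiguity: one
surviving candidate means 100%, five indistinguishable candidates 20%.

## The matching score

Library matching (`match_pair()`, `search_library()`) sums seven
parameters, each in [0, 1], after greedy closest-mass one-to-one
fragment pairing within `frag_tol` (default 0.01 Da):

* `RefMatchFragRatio`, `QueryMatchFragRatio` — matched fragments over
  reference / query peak counts;
* `DirectMatchFragRatio` — fragments matched within `frag_tol/2`, over
  reference peaks;
* `IntensityDotScore` — cosine similarity of matched intensities;
* three error statistics mapped through `1 − min(error/tolerance, 1)`:
  `|MS2ErrorMean|` and `MS2ErrorStd` (matched-fragment mass differences,
  against `frag_tol`) and `MS1Error` (precursor difference in ppm,
  against `ms1_tol`, default 5 ppm).

`FinalScoreRatio` is the sum divided by 7. With no matched fragments the
fragment-error statistics take their worst value, so a disjoint pair can
score at most 1/7 (the precursor term). Matches below the 50% gate are
labeled TN outright and bypass the classifier with P(TP) = 0; only
gated-in matches are adjudicated probabilistically. The seven-parameter
set is this package's documented re-specification of a summed
multi-parameter library score; any scorer emitting the four named
parameters plus a [0, 1] `FinalScoreRatio` can be substituted upstream
of the classifier.

## Applicability domain

Retention predictions are trusted only inside a leverage-based
applicability domain: `h = x'(X'X)^{-1}x` against the training design
matrix, with a pseudo-inverse fallback for singular Gram matrices. The
threshold is the 95% leverage of the training data. Among the equivalent
empirical-quantile conventions we use the type-1 (inverse-ECDF)
quantile — the smallest training leverage at or below which at least 95%
of training rows fall — with `in_domain: h ≤ threshold`. This choice
makes the defining property hold exactly by construction (at least 95%
of training rows are in-domain); interpolating quantile definitions
place the threshold strictly between order statistics and cover only
94% at n = 50. Published thresholds for full-scale retention models
(0.275 and 0.146 for the fingerprint and CNL models) are documentation
of that scale of model, never constants in code: `fit_ad()` always
recomputes the threshold from its own training matrix.

## Training-time choices

**Splits.** The fingerprint model is split by *structure*, not by
retention: fingerprints are clustered with k-means (k = ⌈√n⌉ on the raw
count vectors — the clusterer is this package's choice, as only the
principle of structural stratification is prescribed) and each cluster
is split at the requested fraction. The CNL model uses a deterministic
leverage-ranked split: rows ranked by leverage, test rows taken by
centered systematic sampling over the ranked list so both sides span
the leverage range.

**Forests.** 500 trees, fully grown (`min.node.size = 1`), single
threaded, seed-controlled. For regression we use the regression-standard
`mtry = max(⌊p/3⌋, 1)` rather than the √p classification convention:
with sparse binary CNL indicators, √p-subsampled regression trees often
cannot find a separating feature and terminate on impure nodes, which
measurably degrades recovery of the latent retention law.

**Class balance.** True matches are heavily outnumbered by decoys;
label-1 rows are replicated tenfold (`balance_by_replication()`) before
training, mirroring the replicate-the-positives balancing strategy used
with such corpora.

**Feature pruning.** `prune_correlated()` iteratively drops the
less-important member of any feature pair with Pearson |r| > 0.80
(importance defaults to |correlation with the label|). Constant features
have undefined correlations, treated as 0 with a warning.

**KNN.** k = 5 on features standardized to zero mean/unit SD with
training statistics; P(TP) is the neighbor vote fraction, so
P(0) + P(1) = 1 holds exactly. k and the standardization are this
package's defaults; logistic regression, a decision tree and a random
forest are available for comparison through the same interface.

**FDR calibration.** `calibrate_fdr()` sweeps a threshold grid over
P(TP) on a labeled evaluation set, computes FDR = FP/(TP + FP) among
accepted matches, enforces monotonicity by a running minimum over
ascending thresholds, and reports the minimal threshold attaining each
requested FDR bound (unattainable bounds are reported as such, never
extrapolated).

## The synthetic world

Real corpora of hundreds of thousands of spectra cannot ship with a
package, so every stage is exercised against `generate_world()`, a
seed-reproducible generative model with the statistical structure the
pipeline assumes:

* compounds carry 16 latent binary descriptor bits; true RTI is a
  weighted sum of the bits (weights ~ U(50, 150), giving a scale
  spanning roughly 0–1600 with SD ≈ 200) plus Gaussian noise;
* a fixed 200-mass neutral-loss vocabulary (20–130 Da, spacing > 0.15
  Da so MOI bins never overlap at the 0.01 Da tolerance) acts as the
  fragment grammar: six core losses are present in every compound, each
  active bit switches on two characteristic losses, and two further
  losses per compound are idiosyncratic;
* fingerprints are a fixed deterministic 790-length count expansion of
  the descriptor bits, so the fingerprint and CNL models learn the same
  latent variable — the construction behind the `rti_error` signal;
* compounds come in isobaric analog families (~12 members sharing an
  exact monoisotopic mass and most descriptor bits, 3–5 bits flipped
  per member). This is what makes wrong-candidate matches realistic:
  decoys retrieved by accurate mass are structural analogs that match
  well spectrally but differ in retention.

Default noise emulates a well-calibrated instrument: m/z jitter SD
0.001 Da on fragments and precursors, log-normal intensity SD 0.3,
fragment dropout 0.15, retention noise SD 25 RTI units (2.5% of the
nominal 1000-unit scale). Every generated spectrum passes the
at-least-2-MOIs rule by construction.

`generate_match_benchmark()` runs the full front end on a world — one
reference spectrum per compound, the rest as queries, true pairs labeled
1 and isobaric decoy pairs (the semisynthetic-negative construction)
labeled 0 — and emits the labeled six-feature table the classifier
trains on, with the fitted retention models attached.

What the generator does *not* emulate: chemically realistic
fragmentation, co-elution and chimeric spectra, matrix effects,
instrument-specific mass-accuracy drift, and library spectra acquired at
different collision energies. Passing tests therefore demonstrate that
the pipeline recovers the signals it is designed for when they are
present — not that those signals have any particular strength in a given
real matrix.

## Problem sizes and numerical checks

The test suite sizes its simulations to demonstrate each property
cleanly: retention-recovery checks use 500 compounds × 3 spectra (the
CNL model reaches held-out R² ≥ 0.99 in a noise-free world and ≥ 0.9
with retention noise at 5% of scale); the classifier benchmark uses 600
compounds × 3 spectra, giving 1,200 true and ~10,800 decoy matches, on
which the six-feature KNN reaches test MCC ≥ 0.8 and losing `rti_error`
strictly reduces recall. The end-to-end demonstration pipeline uses a
small 24-compound world and is byte-identical across reruns with one
seed.

Degenerate inputs are handled explicitly rather than silently: all-zero
spectra refuse normalization; spectra setting fewer than two MOI
indicators are dropped with a warning; a singular Gram matrix falls back
to a pseudo-inverse; an MCC denominator of zero returns 0 by convention;
MRE refuses zero-valued references; an empty shortlist reports "nd"
rather than IP 0; ties at the average-P(TP) threshold retain the hit.
Hits are grouped by full InChIKey.

## Known limitations

* The hashed fingerprint backend is a deterministic stand-in with no
  chemical meaning; use the ChemmineR atom-pair backend (or inject your
  own) for real structures. Bit-level parity with any particular
  fingerprinting toolkit is out of scope.
* RTI harmonization across calibrant scales is assumed done upstream:
  compound tables carry already-harmonized RTI targets.
* Random forests interpolate; they do not extrapolate retention beyond
  the training hull — hence the applicability domain, and predictions
  flagged out-of-domain should not be used in `rti_error`.
* The two analytic IP definitions (shortlist 1/N and top-X occurrence
  frequency) are implemented; ranking for top-X can use either
  `FinalScoreRatio` or P(TP), with ties broken by order of appearance.
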