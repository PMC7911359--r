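---
title: "Coevolutionary specificity scoring for two-component signaling networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coevolutionary specificity scoring for two-component signaling networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcsdca)
```

## The problem

Bacterial and archaeal two-component systems (TCS) transduce environmental
signals through a histidine kinase (HK) that phosphorylates its cognate
response regulator (RR). Interaction specificity is encoded in the interface
between the HK's HisKA dimerization/phosphotransfer domain and the RR's REC
receiver domain, and cognate pairs are far from orthogonal: crosstalk between
non-cognate partners is common. `tcsdca` quantifies the encoded specificity of
every HK–RR combination in a set of aligned domain sequences, classifies
cognate pairs by the selection regime that maintains them, and predicts how
point mutations rewire the whole network.

## The sequence model

Concatenated HK+RR domain alignments (with the HisKA and REC domains, 67 +
112 = 179 columns) are modelled by a global Potts distribution

$$P(\sigma) = \frac{1}{Z}\, e^{-H(\sigma)}, \qquad
H(\sigma) = -\sum_{i<j} e_{ij}(a_i, a_j) - \sum_i h_i(a_i),$$

where each site takes one of $q = 21$ states (20 amino acids plus the
alignment gap). The couplings $e_{ij}$ and local fields $h_i$ are inferred by
mean-field Direct Coupling Analysis (mfDCA): sequences are reweighted by
80 %-identity clustering, single-site and pair frequencies are regularised
with a pseudocount of weight $\lambda = M_\mathrm{eff}$, and the couplings
are read off the inverse of the connected-correlation matrix restricted to
the $q - 1$ non-gap states per site. The partition function $Z$ is never
evaluated; only unnormalised energies and their differences are used.
Coupled column pairs are ranked by direct information (DI), the mutual
information of the two-site distribution built from each coupling block with
auxiliary fields matched to the single-site marginals.

## The specificity score

For a candidate pair of sequences $HK_A + RR_A$, the interface-masked
Hamiltonian is

$$H_\mathrm{TCS} = -\sum_{i \le L_{HK} < j} e_{ij}(A_i, A_j)\,
\Theta(c - r_{ij}) - \sum_{i=1}^{L_{HK}+L_{RR}} h_i(A_i),$$

where the step function keeps only inter-domain couplings whose columns map
to residue pairs closer than $c = 12\,\mathring{A}$ in a template HK–RR
complex structure (the HK853–RR468 co-crystal is the canonical template).
Masking ensures that auxiliary coevolutionary signal away from the physical
interface cannot influence the score. The contact distance is the minimum
heavy-atom distance between residues (Cα-only and Cβ-only conventions are
available), the inequality is strict (a pair at exactly the cutoff is not a
contact), alternate conformers resolve to the highest occupancy, and only
the first model of a multi-model structure is read.

Attributes shared by *all* HK–RR pairs — the generic phosphotransfer
machinery — are removed by a null model trained on deliberately mispaired
sequences: every HK is re-paired with a uniformly random RR, 25 times. The
specificity score of a pair is

$$H_\mathrm{TCS}^\mathrm{specific} = H_\mathrm{TCS}(\text{cognate model}) -
H_\mathrm{TCS}^0(\text{scrambled model}),$$

and is negative for encoded specificity, near zero for shared attributes
only, and positive for loss of shared attributes. Two readings of the null
exist: evaluating the scrambled-trained model on the same sequence pair
(the default, `nullEstimator = "scrambled_model"`), or averaging the
cognate-model score over random re-pairings
(`nullEstimator = "empirical_repairing"`); they coincide only approximately,
and the package implements both.

## Selection classification

With the convention that the most negative score is the strongest
interaction, a cognate pair is under **positive selection** when the cognate
RR is the strict minimum of its HK's row, and under **negative selection**
when the cognate HK is the strict minimum of its RR's column. Either mode
counts as a detected (true-positive) cognate pair; a pair whose cognate cell
is beaten by a non-cognate partner in both directions is a false negative.
Ties (equality after rounding scores to 1e-9) never count as selection: a
tie cannot evidence a preference. Sensitivity is TP/(TP+FN); because the
scheme defines no true negatives, the reported "accuracy" equals the
sensitivity, and `validationMetrics()` documents this explicitly. The
selection-mode fractions (both modes, negative-only, positive-only) are
reported against two denominators — all evaluated pairs and the detected
subset — because both conventions are in circulation.

## Mutations

`rescoreAfterMutation()` applies width-preserving substitutions (an
"insertion" is a substitution into a gap column; the 179-column frame never
changes) and recomputes only the affected row or column of the specificity
matrix. For a single substitution `deltaHamiltonian()` gives the exact score
change from just the terms touching the mutated position. Multi-site changes
are re-evaluated in full rather than by summing single-site deltas, because
deltas are not additive when mutated columns share a mask pair. Incremental
and from-scratch rescoring agree to 1e-9 by construction, and the test suite
asserts it. The model assumes the three-dimensional interface geometry is
unchanged by mutation — scores describe sequence compatibility with the
template interface, not structural rearrangement.

## The synthetic world generator

`makeToyWorld()` builds a fully known ground truth so that every pipeline
stage is testable without external data: a q = 21 Potts model over the
concatenated frame whose inter-domain couplings live only on a planted
interface mask, with one matched state combination per cognate family on
each planted pair, plus per-family HK field biases that give each family its
own interface signature. Planted pairs are chosen disjoint, so the Boltzmann
distribution factorises into independent two-site joints and independent
columns and sampling is **exact** — no Monte-Carlo approximation enters the
ground truth. (The general `samplePotts()` offers exact enumeration for
$q^L \le 10^6$ and a vectorised random-scan Gibbs sampler — burn-in 1000
sweeps, thinning 10 — for arbitrary coupling graphs.) The `ToyWorld`
container stores the shared generating model; the per-family field biases
that implement the family conditioning are kept alongside it in their own
slot, since a single Potts model cannot carry the mixture structure.

Generator defaults mirror the real study conditions: 67 + 112 columns,
q = 21, 5 cognate families, 500 sequence pairs per family, planted coupling
strength 3 (in energy units of the Hamiltonian, strong against a background
field spread of 0.3) and an HK-side family field bias of 2. What the toy
world deliberately does **not** emulate: phylogenetic correlation between
sequences (rows are iid given the model), alignment errors, non-interface
coevolution, and family-size imbalance. Passing the recovery tests therefore
demonstrates correctness of the inference and scoring chain, not performance
on real, phylogenetically structured alignments.

## Numerical choices

* **Reweighting** at 80 % identity and **pseudocount** $\lambda =
  M_\mathrm{eff}$ (relative weight 0.5) are the standard mfDCA settings; the
  original study does not state its values, so these defaults are flagged as
  assumptions and are arguments everywhere.
* **Gauge.** The inversion uses the gap as reference state (removing the
  exact linear dependency among the q states); reported models are converted
  to the zero-sum gauge, with the shift absorbed into the fields so that
  Hamiltonian differences are preserved exactly. Zero-sum couplings make
  coupling norms and DI comparable across pairs.
* **Null-model weighting.** The scrambled alignment (25 rounds × one row per
  HK) is an iid resample of the same sequence pool; identity reweighting on
  it is quadratic in its size and adds no information, so the null model is
  fit with uniform weights by default (`null_reweight` switches it on).
* **DI marginal matching** iterates to total-variation tolerance 1e-6 with a
  cap of 200 sweeps; non-converged pairs are reported with their iteration
  counts. DI ranking ties break lexicographically on (i, j).
* **Degenerate inputs.** A singular correlation matrix aborts with advice to
  raise $\lambda$; empty chains give empty contact sets with a warning; an
  empty pair table concatenates to zero rows but keeps the frame width.
* **Positions** are 1-based everywhere, in memory and in every serialized
  artifact. Score CSVs carry 9 decimal places so that export/import
  round-trips within the 1e-9 tolerance used throughout.
* **Frame width.** The concatenated frame is the sum of the two domain
  widths (67 + 112 = 179 for HisKA + REC); widths are carried by the data
  objects, never hard-coded, so other domain pairs work unchanged.

## Design decisions that were genuinely open

* "A sequence gap of N residues" is read as a maximal **contiguous** gap run
  (the singular "a gap" suggests one run); `filterByGapRun(mode = "total")`
  offers the total-count alternative. Thresholds: run ≥ 5 removes an HK,
  run ≥ 6 removes an RR.
* Cognate pairing by genomic adjacency requires genome annotation this
  package does not ingest; pairing is supplied as an explicit two-column
  table, which decouples scoring from annotation pipelines.
* Non-canonical residue letters (B, Z, X, U, O) encode to the gap state,
  keeping q = 21; lowercase letters and `.` are Pfam insert states and are
  removed before width checks.
* The organism-level evaluation sets (`hk_eval`/`rr_eval` in the pipeline
  config) are separated from the training alignments: the Potts models are
  global, while the specificity heatmap is computed for one organism's
  proteins. When no evaluation sets are given the filtered training
  alignments are scored — useful for toy worlds, wasteful for real MSAs.
* Mutation rescoring recomputes deltas on the fly rather than consulting a
  precomputed position×state table; the arithmetic is identical and the
  dependency on a serialized table disappears.

## Problem sizes used in the shipped tests

The validation battery runs planted worlds with 5 families × 500 pairs on a
12 + 16-column frame (10 seeds) for interface recovery and pooled
sensitivity; exact-enumeration sampler checks use L = 3, q = 3 with
10⁴–2×10⁴ draws; oracle-equivalence checks use ≥100 random instances per
operation at widths 6–9. These sizes were chosen so the whole battery is a
desk-scale computation on one CPU while keeping every statistical check
well-powered ($M_\mathrm{eff} = 2500$ per world, planted signal far above
the inversion noise floor).

## A worked example

```{r example, eval = FALSE}
w <- makeToyWorld(nFamilies = 5, LHK = 12, LRR = 16, nInterfacePairs = 6,
                  MPerFamily = 500, seed = 42)
paired <- concatenatePairs(w@hkAlignment, w@rrAlignment, w@pairs)
enc    <- encodeAlignment(paired)
wts    <- computeWeights(enc)
freqs  <- countFrequencies(enc, wts$weights)
cognate <- fitMFDCA(freqs)

scram <- scramblePairs(w@hkAlignment, w@rrAlignment, rounds = 25, seed = 7)
null  <- fitMFDCA(countFrequencies(encodeAlignment(scram)),
                  provenance = "scrambled")

sets <- toyConsensusSets(w)
sm <- specificityMatrix(cognate, null, w@mask, sets$hk, sets$rr)
calls <- classifySelection(sm, sets$cognates)
validationMetrics(calls)$sensitivity
```

On this world the cognate diagonal sits near −30 while non-cognate cells sit
near +4, every cognate pair is detected under both selection modes, and the
top-6 DI pairs coincide with the planted interface.

## Known limitations

* Mean-field inversion is the only inference engine; pseudolikelihood or
  Boltzmann-machine refinements are out of scope.
* Scores are comparable within one organism/model, not across independently
  trained models.
* The template interface is fixed: mutants that remodel the interface
  geometry are scored as if they did not.
* Gap-state energies are as real as residue energies; alignments with
  pathological gap patterns should be filtered (`filterByGapRun`) before
  inference.
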