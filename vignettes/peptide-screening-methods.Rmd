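---
title: "Methods: rule-based proteolysis, screening and assay analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule-based proteolysis, screening and assay analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepscreen)
```

This vignette documents the models, conventions and numerical choices behind
`pepscreen`. Everything stated here is either a definition or a property
checked by the package's test suite; no empirical claims are made beyond
what the tests compute.

## 1. Sequence conventions

Sequences are strings over the 20 canonical one-letter amino-acid codes.
Positions are 1-based; peptide bond *i* joins residues *i* and *i + 1*
(so a length-*L* chain has *L − 1* bonds). Non-canonical letters (B, J, O,
U, X, Z) are rejected with an error naming the offending position, never
silently skipped, because the cleavage rules below are defined only over
the 20-letter alphabet.

## 2. Cleavage-specificity model

An enzyme is a set of declarative subsite rules in Schechter–Berger
notation. Relative to bond *i*:

| subsite | P4 | P3 | P2 | P1 | P1′ | P2′ |
|---------|----|----|----|----|-----|-----|
| residue | i−3 | i−2 | i−1 | i | i+1 | i+2 |

A rule is a conjunction of accept sets per subsite (negation `P2=!P`
expands to the 19-letter complement), optionally with rule-local
exception (`block:`) patterns; a table may also carry global blocks and a
`substrate_max_len` cap (the enzyme does not act at all on longer chains).

Two deliberate semantic choices:

* **Missing offsets fail accept patterns.** A constrained subsite that
  falls outside the chain fails the match. A dipeptide whose single bond
  would need an absent P2 to satisfy a rule is therefore *stable* — this
  is what makes very short peptides resistant to the gastric rules below,
  and it matches how window-based digestion predictors treat chain ends.
* **Missing offsets void block patterns.** An exception pattern applies
  only when all of its constrained offsets are present; an absent
  position cannot "block".

A bond is cleaved when at least one rule matches and no applicable block
(rule-local or global) matches. Rule tables are plain text under
`system.file("extdata/enzymes", package = "pepscreen")`, each with a
`version:` line that is embedded in every pipeline log. Specificity
databases differ in the exact subsite sets they list for the papain-family
enzymes; the packaged tables state their provenance in comments and can be
edited or replaced per file to match a particular snapshot.

## 3. Digestion semantics

Digestion is deterministic and exhaustive (no partial-digest
stochasticity). With `refine = TRUE` (default), the engine iterates to a
fixpoint: released fragments are re-examined — each enzyme sees the
fragment's new termini, and the fragment's own length is tested against
any `substrate_max_len` — until no new cleavage appears. This is the
physical picture of enzymes acting on reaction products, and it guarantees
the invariant that re-digesting any released peptide yields no further
cuts (checked by property tests). `refine = FALSE` gives literal
single-pass semantics; the two coincide for rules that never reference
positions beyond P1/P1′.

Two-stage treatments (`sequential_digest()`) apply stage 1 to the intact
protein and stage 2 to each stage-1 product, composing spans back to
parent coordinates; released peptides always tile the parent exactly.

Release statistics, for a single substrate of length *L*:

* **DH** (degree of hydrolysis) = 100 × |cleaved bonds| / (L − 1).
* **A_E** = released reference-set peptides (with multiplicity) / L.
* **W** = released reference-set peptides / occurrences of reference
  peptides embedded in the substrate (overlapping occurrences counted; a
  zero denominator is an error, not a 0 or NaN).

`hydrolysis_report()` optionally takes externally reported DH values per
treatment and tabulates the discrepancy, so a packaged rule table can be
audited against the specificity-database snapshot that produced the
reported numbers.

## 4. Activity annotation

Di- and tripeptides are matched *exactly* against a reference table of
known ACE-inhibitory sequences with pIC50 values. Tetra- to hexapeptides
go through a pluggable scorer; a peptide is active when its score is
**strictly** greater than the threshold (default 0.0). The trained SVM of
external activity-prediction servers is deliberately not reimplemented:
`scorer_file()` injects scores exported from such a server, and
`scorer_baseline()` is a clearly-labelled composition-based stand-in whose
scores carry no literature meaning.

## 5. The screening cascade

Stage order: gastrointestinal stability → allergenicity → toxicity →
rule-of-5 permeability, with per-stage bookkeeping satisfying
`n_input = n_pass + n_fail` at every stage.

**GI stability.** A peptide is stable when it has zero predicted cleavage
sites under the packaged pepsin (pH 1.3), trypsin and high-specificity
chymotrypsin tables. Unstable peptides are digested exhaustively and their
distinct fragments of length ≥ 2 re-enter the pool with provenance
(`gi_parent`).

**Allergenicity / toxicity.** These are trained classifiers in the
literature and are not reimplemented; the stages consume externally
computed verdict files. A predicate must have a verdict for every queried
sequence — a missing verdict is an error, not a silent pass.
`predicate_constant()` screens everything through for testing.

**Permeability (rule of 5).** Strict inequalities: MW > 500 Da, donors
> 5, acceptors > 10, logP > 5. Counting conventions:

* *Donors are donor atoms*: N/O bearing at least one hydrogen — the free
  α-amino nitrogen (including proline's secondary amine), each non-proline
  backbone amide N–H, the C-terminal carboxyl O–H, and side-chain N–H/O–H
  atoms from a versioned per-residue table (arginine's side chain
  contributes 3).
* *Acceptors* are N and O atoms excluding amide nitrogens: the α-amino N,
  one backbone carbonyl O per bond, both carboxyl oxygens, plus side-chain
  N/O per the table.
* *MW* is the sum of standard average residue masses plus one water.
* *logP* defaults to an additive scheme (termini constant −2.65, backbone
  unit −0.56 per residue, Fauchère–Pliška side-chain increments). It is a
  screening approximation, not an atom-typed calculator; a numeric or
  functional backend can substitute externally computed values.

As in the original formulation of the alert — poor absorption is likely
when *at least two* conditions fail — the default verdict passes a profile
with at most one violation (`max_violations = 1`). With donor-*atom*
counting, dipeptides containing arginine (6 donors) carry one violation
yet remain acceptable screening candidates; `max_violations = 0` gives the
stricter any-violation-fails convention.

```{r ro5}
rule_of_five(c("VF", "IR", "NPPK"))[, c("sequence", "hbd", "hba", "n_violations", "ro5_pass")]
```

Finalists are partitioned into known/novel against a packaged reference of
known antihypertensive sequences.

## 6. Assay analysis

Inhibition is `100 (A − B) / A` with `A` the uninhibited product
concentration — reported as computed, never clamped. Because this readout
is bounded, the dose–response model is a two-parameter logistic with floor
0 and ceiling 100:

$$\mathrm{inhibition}(c) = \frac{100}{1 + (\mathrm{IC}_{50}/c)^h}.$$

Fitting uses Levenberg–Marquardt least squares with the IC50 parametrised
as log10(IC50) (symmetric error structure on the log-concentration axis),
initialised from log-linear interpolation of the 50% crossing; replicates
are fitted as individual points, never pre-averaged. Inputs must bracket
50% inhibition. pIC50 = −log10(IC50 in M); e.g. 2.63 × 10⁻⁵ M ↦ 4.58.

## 7. Conformational metrics

All metrics are plain functions of coordinates (Å):

* **Superposition / RMSD**: Kabsch algorithm via singular value
  decomposition with the determinant sign correction (proper rotations
  only). Tests cross-check against the closed-form Horn quaternion
  solution to 1 × 10⁻⁸.
* **RMSF**: frames are superposed onto frame 1; each atom's mean-square
  deviation from its time-averaged position is computed and residues
  report the root of the mean over their atoms.
* **Radius of gyration**: mass-weighted by default.
* **SASA**: Shrake–Rupley with a *deterministic* golden-spiral point set
  (default 960 points/atom, probe 1.4 Å), so results are bit-reproducible;
  accuracy is tested against the closed form for a single sphere (< 1%)
  and a Monte-Carlo oracle for overlapping atoms (< 2%).
* **Hydrogen bonds**: geometric criterion, donor–acceptor distance
  ≤ 3.5 Å and donor–H–acceptor angle ≥ 120°.
* **Equilibration**: an RMSD series is stable from the earliest index
  after which every sliding window's range stays within the tolerance
  (default 1.0 Å, i.e. 0.1 nm).

PDB input goes through `bio3d`; multi-model files become trajectories.

## 8. Synthetic data and reproducibility

Every generator is a pure function of its arguments and seed; the caller's
RNG state is saved and restored. One global seed derives per-generator
substream seeds via a fixed integer mix (`derive_seed()`), so multi-stage
fixtures are reproducible end to end.

`spike_motifs()` makes release statistics *provable* rather than
probabilistic: the backbone is first sanitised onto an alphabet over which
the enzyme has zero cleavage sites (for every rule, some constrained
subsite's accept set is disjoint from the alphabet), each motif copy is
inserted behind a linker drawn from the enzyme's P1 accept set, and the
finished construction is verified against the digestion engine — under
exhaustive digestion every spiked copy is released, so W = 1 exactly.

`synth_trajectory()` builds frames with a designated flexible atom
displaced ±a alternately along one body axis, plus optional rigid-body
motion and Gaussian jitter; with zero jitter and an even frame count the
flexible atom's RMSF is exactly *a*, giving closed-form expectations for
the metric code.

## 9. Problem sizes and limitations

* Digestion is O(L × rules) per pass and runs in milliseconds for
  protein-sized substrates; the whole six-treatment pipeline on a
  ~400-residue substrate takes seconds.
* SASA is O(n² + n × points); hundreds of atoms at 960 points/atom run in
  seconds. It is an area estimator, not an energy model.
* The additive logP and the baseline activity scorer are screening
  heuristics; substitute file-backed values from dedicated tools for any
  quantitative use.
* Rule tables are snapshots: different specificity databases disagree,
  particularly on papain-family P2 sets. The discrepancy-audit path in
  `hydrolysis_report()` exists precisely to quantify this against reported
  values.
* Digestion is all-or-none per bond; no kinetics, pH dependence beyond
  the chosen table variant, or partial digestion is modelled.
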