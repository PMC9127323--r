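---
title: "Anchor-restrained modelling of peptide-MHC class I complexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anchor-restrained modelling of peptide-MHC class I complexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anchormod)
```

## The modelling problem

MHC class I molecules present short peptides (7-15 residues) in a binding
groove formed by the G-ALPHA1/G-ALPHA2 domains (the *G-domain*, residues
1-180 after renumbering). Although MHC is extremely polymorphic, the fold
is ultra-conserved, and most peptides dock with their second (P2) and last
(P-Omega) residues buried in the B and F pockets — the *anchor* positions.
This conservation makes template-based modelling unusually effective for
pMHC-I: given a peptide sequence and an allele name, a closely related
experimental structure almost always exists, and the hard part is only the
conformation of the peptide between its anchors.

`anchormod` implements that protocol end to end:

1. **Template curation** — PDB structures are parsed, one alpha
   chain and its bound peptide are extracted (beta-2 microglobulin is
   discarded), tolerated non-canonical residues are substituted (e.g.
   phosphoserine to serine by deleting the phospho group), chains are
   renamed M/P and renumbered from 1. A structure is rejected, with a
   stable reason code, when it has an untolerated non-canonical residue,
   a non-amino-acid molecule in the groove, a parse failure, a missing
   allele annotation, or an out-of-bounds peptide length.
2. **Template selection** — candidates are gathered by an allele
   hierarchy (same allele, e.g. HLA-A\*02:01; else same group, HLA-A\*02;
   else same gene, HLA-A), then ranked by a PAM30-scored
   *anchor-position-driven* peptide alignment: anchors are forced into
   shared columns and length mismatches are resolved by gaps at the exact
   centre of the binding core (or terminal gaps in the flanks). PAM30 is
   the right matrix for short, highly similar peptides; no alignment
   optimisation is performed because the construction is prescriptive.
3. **Modelling** — the target is grafted onto the template (MHC backbone
   copied; mismatched side chains truncated to C-beta; peptide backbone
   copied column-by-column, insertions interpolated), then each of
   `n_models` models is produced by randomizing the non-anchor loop atoms
   by +/- 5 A per coordinate and running a short two-phase restrained
   minimization. Models are ranked by the final objective (lower is
   better). If target and template share peptide and allele, the
   unrandomized graft is returned as rank 1 with score `min - 1`.
4. **Evaluation** — models are superposed on the reference G-domain
   backbone only (Kabsch) and the ligand RMSD (L-RMSD) is computed over
   peptide atoms without refitting, in four dialects (backbone, C-alpha,
   backbone+CB, full atom); CAPRI-style classes and cohort hit/success
   curves summarise quality.

## The surrogate scoring objective

This package does not execute an external modelling engine; the engine's
internal score (such as molpdf) is represented by the final value of the
restrained minimization objective

$$E = w_b \sum_{\text{bonds}} (b - b_0)^2
    + w_c \sum_{\text{pairs}} \max(0, d_{\min} - d)^2
    + w_a \sum_{\text{anchor bb}} \lVert x - x_{\text{target}} \rVert^2
    + w_s \sum_{\text{ss pairs}} (d - d_{ss})^2$$

with defaults $w_b = 10$, $w_c = 5$, $w_a = 100$, $w_s = 10$ (per A^2) and
$d_{\min} = 2.8$ A. The ranking semantics (ascending, identical-case
shortcut at `min - 1`) follow the published protocol exactly; the absolute
values are not comparable to molpdf. The defaults were chosen so that
anchor restraints dominate bonded terms by an order of magnitude and
bonded terms dominate clashes; all are configurable.

Three design choices here were genuinely open:

* **Movable atoms.** Anchor backbone atoms are *restrained*, not frozen:
  every peptide atom moves during minimization, and the $w_a = 100$
  harmonic holds anchors in place (observed displacements are ~0.05 A,
  the contract bound is 0.25 A). Freezing anchors instead would make the
  anchor term inert and would leave any bond strain inside the anchor
  residues permanently unrelaxable. Randomization, by contrast, touches
  only the non-anchor loop atoms.
* **Optimizer.** Each phase uses first-order descent with a backtracking
  (step-halving) line search, so the accepted-step objective sequence is
  non-increasing by construction. Descent directions are Polak-Ribiere+
  conjugate directions rather than the raw gradient: a peptide stretched
  between two pinned anchors is a badly conditioned system (stiff bond
  modes against near-zero-stiffness transverse modes), and pure steepest
  descent stalls there long before bond geometry is restored, while
  conjugate directions converge to machine precision within the default
  iteration budget (200 phase-1 + 300 phase-2 iterations; the `fast` and
  `thorough` presets scale these by 0.5 and 4).
* **Phase composition.** Phase 1 covers bonded + anchor terms (restoring
  chain geometry after the +/- 5 A randomization); phase 2 adds clash
  terms. User secondary-structure restraints participate in *both*
  phases: an engine applies user restraints throughout optimization, and
  deferring them to phase 2 lets the chain settle into a bonds-only basin
  first, largely neutralising them.

Secondary-structure restraints follow the standard geometry: a helix span
contributes O(i)-N(i+4) targets of 3.0 A (so a span must cover at least 5
residues); a strand pair contributes antiparallel CA(i)-CA(j) targets of
4.8 A. Being distance-only, they cannot encode chirality — a mirror-image
helix satisfies them equally — which bounds how much they can improve a
model (see Limitations).

## The synthetic fixture generator

All tests run without downloads on synthetic complexes built by
`make_toy_pmhc()` / `make_benchmark_cohort()`. The pseudo-MHC scaffold is
**not a real fold**: 180 residues assembled from ideal-geometry segments —
two groove walls, a floor strand, and two 20-residue pocket clusters
oriented away from the peptide beneath the anchor side chains — so that
chain extraction, renumbering, G-domain superposition, the groove-ligand
filter and the contact-based anchor heuristic are all exercised. Peptides
are built from ideal bond lengths (N-CA 1.46, CA-C 1.52, C-N 1.33 A) with
canonical extended or alpha-helical dihedrals.

A benchmark cohort pairs each synthetic reference with a template that is
a seeded perturbation of it: two peptide point mutations away from the
anchors, plus a *chain-correlated* coordinate displacement field (a
smoothed along-chain random walk, rescaled to 0.3 A RMS per component and
capped below 1 A per atom). The correlation matters: iid per-atom noise
would break covalent bond lengths by ~0.5 A, which no experimental
template exhibits; a smooth field emulates a conformational difference
between two real structures while keeping local geometry intact. Each
case carries its own synthetic allele so selection resolves at the exact
tier and cases stay independent.

What passing on these fixtures does and does not show: the pipeline's
contracts (filters, alignment construction, restraint satisfaction,
ranking, metric definitions) are fully exercised, and relative effects —
correct anchors beating shifted anchors, helix restraints helping helical
peptides — reproduce qualitatively. Absolute L-RMSD values are *not*
comparable to benchmarks on real crystal structures: the groove is
abstract, side chains stop at C-beta, and the surrogate objective has no
physics beyond bonds, clashes and restraints.

## Numerical and interface choices

* Problem sizes in the shipped test-and-acceptance runs: cohorts of 10-20
  cases, 3-5 models per case, `fast` preset — the pipeline's behaviour is
  scale-free in these parameters and the defaults (20 models, `default`
  preset) are what a user run produces.
* Per-model RNG streams are `seed + model_index`, so increasing `n_models`
  extends a run without reshuffling earlier models. Adjacent run seeds
  therefore share model streams; independent replicate runs should use
  well-separated seeds.
* Curation geometry: a HETATM group (waters excluded) is "in the groove"
  iff one of its atoms is within 4.0 A of atoms from >= 3 distinct
  peptide residues; alpha chains need >= 150 residues; peptides 7-15.
  All configurable.
* The "actual anchor from structure" calculation used by curation is a
  documented heuristic stand-in (`anchors_from_contacts()`): the two
  positions in the windows {1,2,3} and {Omega-2..Omega} whose side-chain
  heavy atoms contact the most M-chain atoms within 4.5 A. Entry anchors
  default to canonical {2, Omega} unless annotated.
* CAPRI bins are closed below on their upper edges (1, 2, 5 A); values
  >= 5 A are Incorrect, with no 10 A cap.
* The hit rate divides hits in the top K by the case's *total* achievable
  hits M (a recall); cases with M = 0 are excluded from cohort averages.
  The alternative K-normalised reading is not implemented.
* MHC sequence resolution: user-provided sequence, else exact-allele
  reference, else a same-group representative with a warning.
* Tie-breaks everywhere are deterministic (selection: score, then better
  resolution, then smallest source id; centre gaps: odd surplus goes left
  of centre).

## Limitations

* Side chains beyond C-beta are neither built nor scored; evaluation is
  backbone-centric by design.
* Distance-only secondary-structure restraints cannot fix chirality.
* The scoring objective is fully satisfiable on easy cases, where model
  ranking degenerates to numerically tied scores; ranking then conveys
  no information beyond determinism (real engine scores discriminate
  because homology restraints conflict).
* MHC-II, beta-2-microglobulin modelling, and live database mirroring are
  out of scope; anchors are generic enough for more than two positions,
  but only pMHC-I is tested.
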