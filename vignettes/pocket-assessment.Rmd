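---
title: "Assessing predicted multi-domain structures: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing predicted multi-domain structures: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pocketgauge)
```

## The problem

AlphaFold- and RoseTTAFold-style predictors are confident and usually
accurate *within* a folded domain, but drug discovery often depends on
geometry *between* domains. NLRP3, the inflammasome sensor this package was
built around, is the canonical hard case: its inhibitor MCC950 binds a
cleft formed jointly by the NBD, HD1, WHD, HD2 and LRR subdomains, so a
model can score well on every per-domain metric and still present no
usable pocket. `pocketgauge` separates these two questions. It quantifies
(i) per-domain prediction quality — confidence aggregation and
domain-partitioned RMSD against an experimental reference — and (ii)
inter-domain pocket formation — key-residue distances, deviation matrices,
a distance-based verdict, and the salt bridges and hydrogen bonds that
stabilize a bound ligand.

## Coordinate conventions

Author (deposited) residue numbering is used everywhere and nothing ever
renumbers: residue 578 means the same residue in a predicted model, in a
cryo-EM structure, and in an MD frame. Where alternate locations exist,
the highest-occupancy altloc is kept, with ties broken by file order, so
parsing is deterministic. Hydrogens are preserved on reading (hydrogen-bond
angles on MD frames need them) but excluded from every "heavy-atom" or
RMSD computation. For mmCIF input the `auth_seq_id`/`auth_asym_id` fields
are used so addresses match PDB convention; the reader takes column
meanings from the `_atom_site` loop header rather than assuming a writer's
column order.

## Confidence aggregation

Per-residue pLDDT is read from the B-factor of the CA atom (mean over the
residue's atoms when CA is absent). Scores on a 0–1 scale are detected
(maximum at most 1) and rescaled to 0–100, since some predictor builds
write the 0–1 encoding. Domain means are plain arithmetic means over
residues present; the "Whole" mean is taken over all scored residues and
is by construction the residue-count-weighted mean of the domain means.
Bands follow the standard pLDDT reading — above 90 high, 70–90 moderate
to good, 50–70 low, below 50 disordered — with boundary scores assigned
upward (90 is "high").

For a set of models from one predictor, `summarize_models()` reports the
mean and standard deviation of the whole-model scores. Published summaries
of such five-model sets are inconsistent about the divisor: for the NLRP3
sets shipped with the package (`nlrp3_model_plddt()`), the AlphaFold
spread matches the population convention (divide by n) and the
RoseTTAFold spread matches the sample convention (divide by n − 1). Both
are therefore computed; the default is population, and the choice is an
explicit argument rather than a guess.

## Domain-partitioned superposition

The Kabsch superposition (closed-form SVD solution, optionally weighted)
is implemented in the package and always enforces a proper rotation
(determinant +1) by flipping the sign of the smallest singular value:
biological coordinates are chiral, and a reflection would fake agreement.
Collinear or near-degenerate point sets (second singular value below
1e-8) are rejected rather than silently regularized. RMSD is the plain
root-mean-square coordinate deviation over paired atoms, unweighted by
mass.

The assessment protocol superposes **each subdomain independently** and
reports per-domain heavy-atom and CA RMSDs, plus a "Full-length" row from
a single global fit over all mapped atoms (including residues outside
every named domain). The separate fits make the per-domain rows measure
fold quality while the full-length row measures domain assembly; by
construction a domain's separately fitted RMSD can never exceed its RMSD
under the global fit, and the test suite asserts this on synthetic
multi-domain toys.

Residue correspondence defaults to author-number identity (equal number,
insertion code and residue name), because model and experiment share
numbering for targets like NLRP3; a global sequence-alignment mode
(match +1, mismatch −1, gap open 5, gap extend 0.5) is available for
renumbered inputs. Atoms are then matched by name within each residue
pair, and atoms present on only one side — partially modeled side chains,
for instance — are skipped, never imputed. Because experimental
structures differ in which side-chain atoms are resolved, heavy-atom
counts (and hence heavy-atom RMSDs) can differ slightly between software
that imputes and this package, which does not.

## Pocket geometry

The pocket indicator is the CA–CA distance between the two residues on
opposite rims of the inter-domain cleft — A228 (Walker A motif, NBD) and
R578 (HD2) for NLRP3. The verdict thresholds, formed ≤ 14 Å and
unformed > 18 Å with "loose" between, are documented heuristics anchored
to exemplar geometries: an experimentally formed pocket near 12.7 Å, a
partially closed model at 14.5 Å, and open arrangements near 20 Å. Both
bounds are inclusive toward the tighter category and configurable;
nothing downstream depends on them beyond the categorical label.

"Side-chain distance" has no single field convention, so two definitions
are exposed: minimum pairwise distance between side-chain heavy atoms
(the common contact convention, and the default) and the distance between
side-chain centroids. Side chain means heavy atoms beyond N/CA/C/O/OXT,
CB included; glycine and side-chain-truncated residues fall back to CA
with a warning. Deviation matrices are the signed elementwise difference
model − reference; missing residues yield masked (NA) rows and columns
that propagate, and are never filled in. Reproductions of published
side-chain heatmaps are therefore expected to match in sign pattern, not
cell-for-cell.

## Interactions

A salt bridge is recorded when any side-chain nitrogen of Arg/Lys (and
His only when explicitly protonated — HIP/HSP naming — or opted in) lies
within 4.0 Å of a side-chain carboxylate oxygen of Glu/Asp, reported once
per residue pair at the minimum-distance atom pair. Hydrogen bonds use a
3.5 Å donor–acceptor heavy-atom cutoff and, when hydrogens are present, a
135° minimum D–H…A angle; structures without hydrogens are evaluated in
distance-only mode. These cutoffs are stated conventions, not fitted
values; they are arguments everywhere, and enlarging a distance cutoff or
relaxing the angle can only add contacts (asserted as a property test).
Trajectory occupancy is the fraction of supplied frames in which a
contact satisfies its criteria, reported per contact key (residue pair
plus atom roles).

## Trajectories

`rmsd_series()` superposes every frame onto frame 1 using a fit selection
and measures RMSD over a possibly different selection after that fit. The
default fits on protein CA even when measuring a ligand — the standard
convention, which exposes ligand drift in the protein frame — and fitting
on the measured selection itself gives the minimized series (also an
asserted property). Frames are taken as supplied: no striding, no
periodic-boundary unwrapping — trajectories must be imaged beforehand,
which is a documented limitation. Multi-model PDB and DCD (with a PDB
topology) are the supported on-disk formats; XTC/TRR/NetCDF would need
readers not available to this package's dependency set.

## The synthetic generator

Every pipeline stage is testable without downloads because the generator
produces structures whose downstream metrics are known exactly:

* `make_toy_protein()` — a helical poly-alanine chain cut into equal
  named domains. Per-domain rigid transforms and Gaussian noise perturb
  the model copy (mispacked but internally correct subdomains); per-domain
  missing fractions delete `floor(f·n + 0.5)` residues from the reference
  copy (unresolved density); per-residue confidence is planted in the
  B-factors, rounded to the 2-decimal precision the PDB format can carry
  so file round trips recover it exactly.
* `make_toy_pocket()` — key residues placed so their CA distances match a
  target matrix to machine precision (classical MDS embedding, rejected
  as infeasible above 1e-6 Å error), template side chains pointing
  outward, and optionally an Arg–Glu pair whose closest N–O distance
  equals a requested value exactly.
* `make_toy_trajectory()` — linear drifts and oscillations realized
  exactly per frame, and planted contacts that hold in exactly
  `round(fraction · n_frames)` randomly chosen frames by translating the
  acceptor residue along the contact axis.

Geometry is idealized (template rotamers, fixed backbone offsets) rather
than physically relaxed: the tests need exact ground truth, not realism.
Consequently, passing tests demonstrate the correctness of the
*measurement* machinery, not robustness to the error statistics of real
predictors — real models have correlated, structured error that the
generator deliberately does not emulate. All generators take a mandatory
seed, restore the caller's RNG state, and produce byte-identical output
for identical seeds.

## Numerical choices and degenerate inputs

* Kabsch rejects N < 3 and collinear sets; weights must be non-negative
  with positive sum; uniform weights reproduce the unweighted fit.
* Domains with fewer than 3 paired atoms in a selection get NA in that
  column of the RMSD table; domains with no paired atoms are absent rows.
* Squared-distance matrices are clamped at zero before the square root to
  avoid NaN from floating-point cancellation on coincident atoms.
* Verdict boundaries are inclusive toward the tighter category, so the
  category is a monotone step function of the indicator distance.
* Residue 629 of NLRP3 is carried under both GLU and GLY labels in the
  key-residue table because published descriptions disagree; the package
  never silently corrects either.

## Scope and problem sizes

The interface is the R API plus this vignette; assessments are driven
from R (as with the structural-bioinformatics packages this one follows
stylistically), with `assess()`/`write_report()` as the one-call
orchestrator emitting JSON and TSV. The test suite and the acceptance
script run on synthetic problems sized for interactive use — chains of
30–120 residues, trajectories of 40–100 frames, superpositions up to a
few hundred atoms — which exercise every code path; the algorithms are
O(n) to O(n log n) per structure and handle full-length proteins
(thousands of residues) without special treatment.
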