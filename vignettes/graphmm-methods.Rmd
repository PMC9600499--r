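---
title: "graphmm: methods, design decisions, and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{graphmm: methods, design decisions, and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the scientific model behind `graphmm`, the choices
made where the design was genuinely open, and what the packaged synthetic
experiments do and do not demonstrate. All empirical statements below are
the ones computed by the test suite and by `scripts/acceptance.R`; nothing
here reports numbers the package does not itself produce.

## The parameter-assignment model

A molecule enters as an annotated graph: per-atom element, formal charge,
aromaticity, hybridization and ring-size membership (sizes 3–8), plus a
bond list with categorical orders. Parsing is delegated to OpenBabel
(through ChemmineOB); hydrogens are always made explicit, valences are
validated against `base valence + formal charge` (so pentavalent carbon is
a parse error, ammonium is fine), and aromaticity is perceived by a
simplified Hückel rule on 5–7-membered rings of the kekulized graph (every
ring atom sp2-or-lone-pair-donor, six π electrons). Hybridization is
collapsed to {sp, sp2, sp3, other} from bond multiplicities. Atom indices
are 0-based in every public structure and serialized format.

**Stage 1 — atom embeddings.** Per-atom input features are the one-hot
element over a configurable alphabet (default H/C/N/O/S/P/F/Cl/Br/I),
one-hot hybridization, the aromaticity flag, the numeric formal charge and
six ring-membership flags (22 columns, layout version `fl-1`). A
neighborhood-aggregation network of the GraphSAGE family transforms them:
each layer computes `act(H W_self + A(H) W_neigh + b)` where `A` sums each
atom's neighbor vectors. No bond features enter the messages. Two design
points deserve emphasis:

* *Exact equivariance.* Optimized matrix kernels can make a row's result
  depend on its position in the batch at the last-bit level. Neighbor sums
  are therefore computed in coordinate-wise sorted order (a pmin/pmax
  sorting network over the ≤4 neighbors), and every user-facing assignment
  path evaluates each row by an independent vector product. Consequently
  relabeling atoms permutes embeddings bitwise, and atoms with identical
  k-hop environments (k = number of layers) receive identical embeddings —
  the property behind the repeat-polymer stability experiment.
* *Activation.* `tanh` is the default: it is smooth everywhere, so
  analytic gradients agree with central finite differences to tight
  tolerances (the package's gradients are all hand-derived; there is no
  autodiff framework underneath). ReLU is available in the configuration.

**Stage 2 — symmetry-preserving pooling.** For a bond (i,j) the embedding
is `NN_r([h_i:h_j]) + NN_r([h_j:h_i])`; angles and torsions use the 3- and
4-atom analogues with full reversal. Because the two summands simply swap
under reversal and floating-point addition of two terms is commutative,
term embeddings are *bitwise* invariant under the term symmetry — no
tolerance needed. Improper torsions follow the threefold convention: every
atom with exactly three neighbors is a site (not restricted to sp2;
chemically that restriction can be imposed upstream), contributing the
three ordered tuples (k,i,j,l), (k,j,l,i), (k,l,i,j) with the central atom
first; the set of rows is invariant under cyclic relabeling of the
peripheral atoms. Proper and improper tuples share one pooling network
(both are 4-tuples); their readout heads are separate.

**Stage 3 — readouts.** Emitting `k` and `x0` directly is badly scaled, so
harmonic terms use a mixture of quadratic bases on a fixed grid: the
readout emits raw values mapped by a scaled softplus (plus a 1e-6 floor)
to nonnegative coefficients `c_b`, and
`Σ_b c_b (x − x_b)² ≡ (k/2)(x − x₀)² + const` with `k = 2Σc_b`,
`x₀ = Σ c_b x_b / Σ c_b`. The floor guarantees `k > 0`; the exported
convention is E = (k/2)(x − x₀)² with the ½ inside. Default grids: 8
uniform points on [0.7, 2.2] Å for bonds and on [0.52, 3.14] rad for
angles; grids are fixed, not learned, which keeps the conversion closed
form. Torsions are a six-term cosine series with phases fixed at zero and
unconstrained amplitudes — a negative amplitude reproduces a π phase up to
an additive constant, which per-molecule energy centering removes.
Lennard-Jones parameters are passed through from a reference force field
by default ("legacy" mode, as condensed-phase properties are outside the
fitting data); a "predicted" mode with softplus positive maps exists.

**Charges.** A readout maps atom embeddings to electronegativity `e_i`
(first derivative of the charge pseudo-energy) and hardness `s_i` (second
derivative, kept positive by softplus + 1e-3 floor; the floor value is a
choice, nothing in the model pins it). Charges minimize
`Σ e_i q_i + (s_i/2) q_i²` subject to `Σq_i = Q`, solved analytically with
a Lagrange multiplier. The solve conserves total charge exactly — the
motivating contrast with predict-then-renormalize — is invariant under a
joint shift of all `e_i`, and has a closed-form adjoint used in training.
`Q` comes from the molecular graph (sum of formal charges), overridable
per call; the model is conformation-independent by construction. Known
caveat inherited from the feature set: formal-charge features are not
invariant across resonance forms, and the package does not average over
resonance forms.

## The MM potential

`evaluate_energy()` implements the standard functional form with
Lorentz–Berthelot combining, exclusion of 1-2/1-3 pairs, 1-4 scaling
(electrostatics × 1/1.2, LJ × 1/2, the Amber-family convention;
configurable), all-pairs gas-phase nonbonded (no cutoffs), and the Coulomb
constant 332.0637 kcal·Å/mol/e². Dihedrals are signed IUPAC angles in
(−π, π]; with zero phases the energy is even in φ, so mirror images have
equal valence energy. Analytic coordinate gradients are provided for every
term; they back the conformation sampler and are finite-difference-checked
in the tests. Overlapping nonbonded pairs (r < 1e-6 Å) are an explicit
error rather than an infinity.

## The synthetic laboratory

The generator emulates a small C/H/O chemistry (phenyl rings, alkanes,
ethers, alcohols, carbonyls): molecules are grown as random trees over
heavy atoms with exact valences (C 4, O 2), an optional benzene core, an
optional single aliphatic ring closure restricted to sizes 5–8 (3- and
4-membered rings are never produced, matching the reference experiment's
exclusion), carbonyls attached as C=O double bonds, and hydrogens filling
all remaining valence. Default composition (oxygen probability 0.25,
benzene probability 0.25, ring closure 0.2, carbonyl 0.3, 3–12 heavy
atoms) was chosen once so that all eight toy types and all term classes
appear with healthy frequency in a few-hundred-molecule corpus.

The toy reference force field plays the role a legacy general force field
plays for real molecules: an ordered rule list maps each atom to one of 8
types (C_sp3, C_aromatic, C_carbonyl, O_hydroxyl, O_ether, O_carbonyl,
H_on_C, H_on_O); bond/angle/torsion parameters are deterministic functions
of the type tuple — class-typical base values (e.g. C–C 1.525 Å / 330
kcal/mol/Å², O–H 0.96 Å / 560 kcal/mol/Å², aromatic C–C 1.39 Å) times a
±20 % force-constant and ±1.5 % geometry jitter keyed by a string hash of
the tuple, so every tuple is covered and equal tuples always collide.
Torsion tuples carry 1–3 nonzero cosine amplitudes of mixed sign (|K| ≤
1.2 kcal/mol), so all six periodicities are genuinely exercised; aromatic
and carbonyl carbons get planarizing improper terms (K₂ of 1.5 and 3.5
per tuple). Reference charges solve the same constrained quadratic model
from per-type electronegativities/hardnesses. All eight toy types are
decidable from an atom's own features plus its 1-hop neighborhood, so a
≥2-layer network can in principle recover them exactly — the typing
experiment measures that it does.

Conformations come from overdamped Langevin dynamics (position update
`x ← x − D∇E + √(2DkT)ξ`, D = 2.5e-4 Å²·mol/kcal, force components capped
at 2000 kcal/mol/Å for robustness) on the toy potential at 300 K. The
initial geometry is a breadth-first tree layout at ideal bond lengths
relaxed by damped gradient descent; each of the (default 10) chains then
starts from a *torsion-randomized* conformer — every rotatable bond is
turned to a staggered well ±Gaussian noise — relaxed again briefly, before
burn-in (60 steps) and thinned recording (every 15 steps) until the
requested snapshot count is reached. Starting chains from distinct
conformers matters scientifically, not just statistically: if all
snapshots sit in one torsional basin, the cosine features of a torsion are
nearly constant and its amplitudes are unidentifiable from energies. A
long-run test on a stiff diatomic checks equipartition (mean bond energy
kT/2 within 20 %). The sampler is a deliberately simple stand-in for
molecular dynamics: no masses, no thermostat parameters, correlated frames
within a chain — adequate for generating Boltzmann-like training
fluctuations, not for kinetics.

## Training

Losses: per-molecule mean-centered snapshot-energy MSE averaged over
molecules (centering removes the heat-of-formation offset the MM form
cannot represent; a molecule with fewer than two snapshots contributes
zero and triggers a warning), charge MSE over atoms backpropagated through
the analytic solve, and mean per-atom cross-entropy for the optional type
readout, combined with configurable nonnegative weights (defaults 1; the
energy and charge losses live on very different numeric scales, so joint
fits benefit from weighting the charge term up). Splits are always by
molecule, deterministic per seed. The optimizer is full-batch Adam with
cosine learning-rate decay, early stopping on the validation loss
(patience 50 by default) and best-checkpoint restore; with a fixed
configuration the whole loop is bit-reproducible. Gradients of all heads
are exact and verified against central finite differences at 1e-4
relative tolerance.

Energy-only training from random initialization converges slowly on a
single CPU, so `fit_config(warm_start = TRUE)` prepends two phases that
consume only training-split graphs and energies:

1. *Closed-form surrogate fit.* Because the energy is linear in
   (k/2, k·x₀) per harmonic term and in the cosine amplitudes, snapshot
   energies admit a global ridge least-squares fit once parameters are
   tied across local-environment classes (one Weisfeiler–Leman refinement
   of the atom-feature coloring; term keys canonicalized under the term
   symmetry). Harmonic terms are parameterized around each class's mean
   geometry, which makes the two columns of each class nearly orthogonal
   under thermal sampling and the normal equations well-conditioned.
   Columns are norm-standardized; cosine columns get a stronger ridge
   (1e-4 versus 1e-6) because the torsion expansion is the degenerate part
   of the basis.
2. *Distillation.* The per-class surrogate parameters (converted to
   (k, x₀) with range guards, amplitudes clipped to ±4 kcal/mol) become
   supervised targets for the network's own readouts, trained by Adam
   with per-quantity scales.

End-to-end energy training then fine-tunes from the distilled state. The
phase structure, epochs and learning rates are exposed in `fit_config()`.

## The packaged experiments and what they show

`recovery_experiment()` is the headline study: 300 generated molecules
(seed 7), toy-reference energies for 50 snapshots each, 80:10:10 molecule
split (seed 7), energy-only training (2-layer, 48/48/32/64-dimensional
model — the toy chemistry is 1-hop-decidable, so the full-size default
architecture is unnecessary here), evaluation of held-out centered-energy
RMSE and of bond/angle parameter recovery as MAPE with molecule-level
bootstrap confidence intervals (1000 replicates by default). Torsion
amplitudes are excluded from MAPE because the six-periodicity expansion is
degenerate — many amplitude vectors produce identical energies over any
finite conformer set; torsions are judged through energies and through
profile identities instead. Problem sizes were chosen so the whole
experiment (data generation through evaluation) runs in roughly ten
minutes on one CPU.

An honest limitation surfaced by this package's own measurements: at the
300-molecule scale the training energies do not *identify* the force
field. The closed-form surrogate reproduces training energies to
~0.003 kcal/mol RMSE, yet many parameter sets do this equally well and
they disagree on held-out molecules — substituting even the true
parameters for the terms whose environment class is absent from training
still leaves a lookup test RMSE of several tenths of a kcal/mol, because
the degeneracy resolution of seen classes does not transfer either. The
reference-scale study that motivated this package used a corpus ~25×
larger, where environment coverage and conformational co-occurrence break
these degeneracies. The held-out RMSE this package reaches at its scale is
reported, not hidden, by the acceptance script and asserted against the
reference-scale bound in the acceptance tests; readers should expect that
bound to require the larger corpus. Equilibrium geometries (r₀, θ₀) are
recovered to well under 1 %, bond force constants to a few percent, angle
force constants least well — they couple to the torsion degeneracies.

`typing_experiment()` (500 molecules, type cross-entropy) demonstrates the
embeddings linearly separate the discrete types: held-out per-atom
accuracy reaches 100 % at this scale. `charge_experiment()` (300
molecules, charge MSE) recovers the reference charge model to < 0.01 e
held-out RMSE. Both use topology only. These synthetic results show the
architecture and gradients are correct and sufficient for a
rule-generated ground truth; they do not certify accuracy on real
chemistry, quantum-chemical targets, or elements outside C/H/O.

## Numerical choices and degenerate inputs

* Harmonic convention E = (k/2)(x−x₀)²; all exported values use it.
* θ₀ is clamped to (0, π); near-linear angles are guarded in the geometry
  gradients (sin θ floor 1e-12) but do not occur in the generated data.
* Proper torsions whose first and last atoms coincide (possible only in
  3-rings, which are never generated) are dropped at enumeration.
* Checkpoints are JSON with base64-encoded IEEE doubles: a save/load
  round trip reproduces predictions bitwise, and loaders refuse unknown
  format versions.
* Determinism: every stochastic step (generation, sampling, splitting,
  initialization, bootstrap) runs under an explicit seed in a private RNG
  scope that restores the caller's RNG state.

## Known limitations

* Chemistry: the generator and toy force field cover C/H/O with single
  bonds, benzene cores and carbonyls; no nitrogen chemistry, no fused
  aromatics, no stereochemistry, no tautomer/resonance handling.
* The Langevin sampler is not MD: no inertia, correlated frames, rotamer
  randomization instead of true conformer search.
* Parameter identifiability at small corpus scale, discussed above.
* The surrogate warm start assumes the data-generating potential is
  near-constant on 1-hop environment classes; for chemistry where that
  fails it still provides a serviceable initialization, but the
  end-to-end phase has to do more work.
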