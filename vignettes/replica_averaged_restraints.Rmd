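---
title: "Replica-averaged restraints for coarse-grained polypeptide dynamics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Replica-averaged restraints: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rarmd)
```

## The problem

Experimental observables from solution NMR — NOE-derived interproton
distances above all — are averages over the conformational ensemble and
over time.  For well-folded proteins it is harmless to treat them as
properties of one structure; for proteins with disordered regions or
multiple conformational families it is not: imposing every distance bound
on every simulated copy of the molecule drives the simulation toward a
single compromise conformation that can differ from every member of the
true ensemble.  The remedy implemented here is to restrain the *average*
of each observable over M replicas simulated in parallel.  Restraining
ensemble averages rather than instantaneous values is the
maximum-entropy-consistent way to impose ensemble-averaged data: it is
the weakest bias that brings the simulated ensemble into agreement with
the measurements.

`rarmd` implements this machinery for a coarse-grained Cα-trace
polypeptide model: each residue contributes one dynamical site, chain
geometry is described by virtual-bond lengths $d_i$, virtual-bond angles
$\theta_i$ (three consecutive Cα) and virtual-bond dihedrals $\gamma_i$
(four consecutive Cα).  Optional side-chain-center pseudo-sites are
carried for I/O and static analysis but are not propagated by the
integrators.

## Penalty functionals

Restraints enter as penalties added to the configurable chain potential.
A distance restraint with boundaries $[d_l, d_u]$ contributes zero inside
the flat bottom and, for $d > d_u$ (mirrored below $d_l$),

$$V(d) = A\,\frac{x^4}{\sigma^4 + x^4}\,\bigl(1 + \kappa \ln\cosh x\bigr),
\qquad x = d - d_u .$$

The quartic wall is tangent to zero at the boundary (value and first
derivative vanish), saturates at depth $A$ over a thickness $\sigma$, and
the $\ln\cosh$ factor supplies an asymptotically *linear* tail of slope
$A\kappa$: a restraint violated by tens of Ångströms pulls with a small
constant force instead of a divergent one, which keeps early, badly
violated configurations integrable.  Package defaults are
$A = 5$ kcal/mol, $\sigma = 1$ Å, $\kappa = 0.01$, overridable per
restraint row.

Angular restraints on $\theta$ and $\gamma$ use the wrapped offset
$\delta$ of the observable from the window midpoint (always taken in
$(-\pi,\pi]$) and half-width $h$:

$$V(x) = \begin{cases} 0, & |\delta| \le h \\
\text{amplitude}\cdot(|\delta| - h)^4/4, & |\delta| > h ,\end{cases}$$

with amplitudes 1 kcal/mol ($\theta$) and 5 kcal/mol ($\gamma$).  A
common printed form of this wall uses $\delta^4/4$ immediately outside
the window, which jumps by $h^4/4$ at the boundary; that form is kept
behind a `compat` flag for comparison but is unsuitable for dynamics —
the continuous excess form is the default, and the discontinuity is the
reason why.  Both value and first derivative of the default wall vanish
at the boundary.

All penalty derivatives are analytic and finite-difference-verified; the
restraint forces follow by the chain rule through the mapped site
distances and the internal-coordinate gradients (standard angle and
dihedral gradient formulas, validated against central differences).

## Replica averaging

With M replicas at one bath temperature, the averaged observable is the
inverse-power mean

$$\bar y_i = \Bigl[\tfrac1M \sum_{j=1}^M y_{ji}^{-m}\Bigr]^{-1/m},$$

with $m = 3$ for distances — short distances dominate, as they do in NOE
intensities — and $m = -1$ (arithmetic) for $\theta$.  Dihedrals are
averaged circularly: $\bar\gamma = \operatorname{atan2}(\overline{\sin\gamma},
\overline{\cos\gamma})$, which is wrap-correct (the average of
$+170^\circ$ and $-170^\circ$ is $180^\circ$, not $0$).

Synchronising the replicas at every step would serialize the simulation,
so full averages are computed only every $N_\text{ave}$ steps (default
100).  Between full updates, replica J refreshes the average with its own
current observable only,

$$\bar y_i^{(J)}(t) = \Bigl[\tfrac1M\bigl(S_i^{(J)} +
y_{Ji}(t)^{-m}\bigr)\Bigr]^{-1/m},
\qquad S_i^{(J)} = \sum_{j \ne J} y_{ji}(t_K)^{-m},$$

with the foreign power sum $S$ frozen at the last full update $t_K$ (for
dihedrals, frozen sine and cosine sums).  Because $S$ is frozen,
$\bar y^{(J)}$ depends on replica J's coordinates alone: between updates
each replica moves in a *bona fide* potential, and microcanonical
dynamics conserves its total energy exactly within each segment —
"segment-symplectic" behavior, with energy allowed to step only at the
update points.  This is verified at production settings (12-mer, 4
replicas, $\Delta t = 0.489$ fs, 10,000 steps) in the test suite: the
within-segment relative fluctuation of the per-replica total energy stays
below $10^{-5}$ with no trend, while the energy visibly steps across
segment boundaries.

Averaging activates at step $N_\text{ave}$; before that, replicas are
restrained by their own observables (and the conserved quantity is the
unscaled one — the energy bookkeeping follows whichever force law is
active).

**Gradient.**  Differentiating the partial update with frozen foreign
sums gives

$$\nabla_q \bar y^{(J)} = \frac1M
\left(\frac{\bar y^{(J)}}{y_J}\right)^{m+1} \nabla_q y_J .$$

Printed versions of this factor sometimes appear with the ratio inverted
and evaluated at the frozen time; only the form above is the derivative
of the partial update, and only it passes the finite-difference
equivalence test against the extended energy on stacked replica
coordinates, so it is implemented without a compatibility alternative.
For $m = -1$ the factor reduces to $1/M$, and the circular $\gamma$
average has the analogous analytic factor
$(\bar c\cos\gamma_J + \bar s\sin\gamma_J)/(M(\bar s^2 + \bar c^2))$.

**Force scaling.**  The factor $1/M$ would make restraint forces fade as
replicas are added, so the penalty gradients are scaled back up by M.
Energies are reported unscaled in production; in microcanonical
validation mode the restraint energy is scaled by M as well, so the
reported total is the quantity the scaled forces conserve.

**Temperature-resolved weights.**  Under multiplexed temperature replica
exchange, only the M replicas currently at a given ladder temperature
contribute to that temperature's average; each carries weight $1/M$ and
the weights at every temperature sum to exactly one.  The general
weighted-average interface accepts arbitrary weights, but only the
indicator scheme is implemented.

## Samplers and units

Units are Å, fs, amu, kcal/mol and rad throughout (degrees only in
files); $k_B = 1.987204\times10^{-3}$ kcal/(mol·K) and
1 kcal/(mol·Å)/amu $= 4.184\times10^{-4}$ Å/fs².

* NVE: velocity Verlet.
* NVT: BAOAB splitting with the exact Ornstein–Uhlenbeck velocity
  update; at zero friction it reduces *exactly* (bitwise) to velocity
  Verlet and draws no random numbers, and all noise comes from R's RNG so
  a seed fixes the trajectory.  The friction default of 0.05 fs⁻¹ is a
  placeholder scale, not a physical water friction; the two-state
  benchmark uses 0.005 fs⁻¹ (light damping for efficient conformational
  sampling at $\Delta t = 4.89$ fs).
* Masses are uniform (110 amu per residue site) — a surrogate-model
  simplification that affects timescales, not correctness.
* Minimization: L-BFGS-B on the analytic gradient, restarted until the
  gradient max-norm falls below $10^{-4}$ kcal/(mol·Å) (cap reported).

The single-system integrators (`nve_step`, `langevin_step`) accept
arbitrary force closures and are used in the tests against closed-form
oracles (free particle, harmonic oscillator, equipartition, Boltzmann
configurational statistics).  Production trajectories run in compiled
code (`run_trajectory`), which mirrors the R-level restraint/averaging
reference implementations; the two are cross-checked against each other
and against finite differences in the suite.

**M = 1 reduction.**  A single "averaged" replica takes exactly the
non-averaged code path, making M = 1 averaged dynamics bitwise identical
to plain restrained dynamics — a guard against silent algebra drift in
the averaging machinery.

## Replica exchange

`run_mremd` coordinates $N_T \times M$ replicas.  The standard ladders
(24×2, 12×4, 8×6, 6×8; 48 replicas each) are built in.  Every
$N_\text{exch}$ steps (default 10,000; $N_\text{ave}$ must divide it so
exchange points coincide with full updates) neighbour-temperature swaps
are attempted, alternating even/odd pairs per round, with a random
pairing between the M replicas at each of the two levels — the partner
topology under multiplexing is a convention, chosen as standard practice.
Acceptance uses the Metropolis criterion
$\min\{1, \exp[(\beta_a - \beta_b)(E_a - E_b)]\}$ on the extended
potential energy (surrogate + restraint): the surrogate potential is
temperature-independent, so the plain criterion applies without the
corrections a temperature-dependent force field would need.  Accepted
swaps exchange temperatures and rescale velocities by
$\sqrt{T_\text{new}/T_\text{old}}$.  Execution is sequential and
deterministic under a seed; order-independence at synchronisation points
stands in for parallel execution.

## Ensemble analysis

For analysis the package uses inverse-*sixth*-power ensemble averages
$\bar d_i = [\sum_k w_k d_{k,i}^{-6}]^{-1/6}$ (NOE intensity scaling;
the exponent 3 above is specific to replica averaging during dynamics).
Compatibility metrics: $\rho_u^+$, the RMS of positive excesses
$\delta_i = \max(\bar d_i - d_i^u, 0)$; the percentage of averaged
distances inside their boundaries; the violation count `nviol`
($\bar d > d_u$); and gross violations (excess $\ge 2$ Å).  Lower-bound
violations are counted separately — the violation statistics are defined
against upper boundaries, and conflating the two would change the
published quantity.  State populations assign each conformation to the
nearer of two references when that RMSD is below 3 Å (ties unassigned;
superposition is least-squares on Cα only).  Ward clustering
(`ward.D2` on the pairwise Cα-RMSD dissimilarity matrix — the feature
space is a choice; RMSD matches the package's distance vocabulary) cuts
an ensemble into k = 20 families by default, each represented by its
penalty-minimal member carrying the family's cumulative weight.

## The synthetic two-state benchmark

The validation fixture emulates, at desk scale, a system whose restraints
were measured on a two-state ensemble:

1. **Parents.**  Parent 1 is a random conformer of a 12-residue chain
   drawn directly from the torsional wells of the benchmark potential and
   minimized; parent 2 is parent 1 with two central virtual-bond
   dihedrals flipped into the other torsional well and re-minimized.  The
   pair must be $\ge 4$ Å apart (Cα-RMSD) so the states are
   distinguishable under the 3 Å assignment cutoff.  Among candidate
   flips, the one whose synthetic restraints penalize the two parents
   most *evenly* is selected: a lopsided restraint set collapses the
   benchmark onto the favored state and no two-state question remains.
2. **Restraints.**  All Cα–Cα pairs with sequence separation $\ge 2$ and
   distance $\le 12$ Å in at least one parent (an NOE-like short-range
   bias) are restrained to the equal-weight inverse-sixth-power average
   of their two parent distances, $\pm 0.5$ Å.  By construction the set
   is satisfiable *only on average*: each parent alone violates the pairs
   whose averaged bound falls between the two parent distances.
3. **Landscape.**  The benchmark potential extends the generic surrogate
   (harmonic bonds at 3.8 Å, harmonic angles, soft pair repulsion) with a
   double-well torsional term $c_2(1 - \cos 2\gamma)$ per dihedral.
   The dihedrals the parents share are locked with a high barrier
   ($c_2 = 12$, i.e. 24 kcal/mol ≈ 40 $k_BT$ at 300 K) and the two
   transition dihedrals keep a moderate one ($c_2 = 5$, 10 kcal/mol
   ≈ 17 $k_BT$), making the parents the only two thermally accessible
   conformers — the classic double-well model system used to study
   restraint averaging.  This dual-basin design is deliberate: a chain
   without conformational barriers has no metastable states, every
   individually-restrained trajectory then relaxes to the single
   compromise minimum, and there is no two-state behavior to recover.
   The transition barrier was calibrated with pilot runs so that a
   trajectory restrained *individually* flips between basins on the
   1-ns trajectory timescale (stochastically — this is what scatters
   populations across independent canonical runs), while replicas
   restrained *on average* feel no force once the ensemble average
   complies and so stay where the data put them.
4. **Runs.**  Trajectories start alternately in the two basins
   (minimized under potential + restraints), emulating starting
   conformations that cover the candidate states.  Canonical Langevin
   runs at 300 K, $\Delta t = 4.89$ fs, friction 0.005 fs⁻¹, full
   averaging every 100 steps, 200,000 steps per trajectory, snapshots
   every 2,000 steps, second-half snapshots analyzed.  A batch is always
   8 trajectories: 8 independent runs without averaging, or 8/M averaged
   runs of M replicas; three independently seeded batches per condition.
   These desk-scale sizes (a 12-residue chain, ~1 ns per trajectory,
   48 trajectories in the full comparison) keep the complete benchmark
   in the low minutes on one CPU while leaving each trajectory two
   orders of magnitude longer than the barrier-crossing correlation
   time.

What the generator does **not** emulate: real force-field energetics
(the surrogate has no sequence dependence, hydrogen bonding, or
solvation), proton positions (restraints map to Cα–Cα distances, not
interproton distances estimated from coarse-grained geometry), NMR bound
asymmetries, restraint sparsity patterns of real data sets, or exchange
across a temperature ladder (the benchmark is single-temperature).
Passing the benchmark therefore demonstrates the correctness and the
qualitative ensemble behavior of the averaging machinery — not the
accuracy of any force field on real proteins.

A caveat the benchmark makes visible: with m = 3 averaging the penalty
gradient concentrates on the replicas with the *shortest* current
distances, so a replica ensemble corrects an excess of short-side members
far more readily than a deficit.  Re-equilibration of a badly imbalanced
replica set across high barriers is slow; the benchmark sidesteps this by
starting balanced, and real applications should likewise start replicas
from diverse conformations covering the candidate states.

## Numerical choices and degenerate inputs

* Angles wrap to $(-\pi,\pi]$ with the boundary mapped to $+\pi$;
  wrapping uses floor-based reduction identical to R's `%%` semantics.
* $\ln\cosh x$ is evaluated as $|x| + \log(1 + e^{-2|x|}) - \ln 2$ to
  avoid overflow.
* The angle gradient clamps $\sin\theta \ge 10^{-10}$ (collinear
  triplets); the dihedral average raises an error when both sine and
  cosine means fall below $10^{-12}$ (antipodal cancellation).
* Inverse-power averages require strictly positive values for $m > 0$;
  nonpositive distances are errors, not silently clamped.
* Restraint tables store angles in degrees on disk and radians in
  memory; writing uses full round-trip precision (`%.17g`) so a
  write–read–write cycle is bit-identical.
* The self-avoiding chain generator retries placements (60 per residue)
  and restarts (200 per chain) before failing with advice to lower
  `min_sep`.
* Exchange with equal temperatures accepts with probability 1;
  single-temperature ladders reduce `run_mremd` to a replica-averaged
  canonical run.

## Known limitations

* The surrogate potential is intentionally minimal; nothing in it is
  calibrated against real proteins, and temperature-dependent force
  fields would additionally require a modified exchange criterion.
* Side-chain pseudo-sites are not dynamical, so restraints mapped to
  side-chain centers can be observed and scored but not used in MD.
* Only the indicator temperature-weighting scheme is implemented.
* Reweighting across temperatures (WHAM-style) is out of scope; analysis
  consumes single-temperature snapshot streams with user-supplied
  weights.
* The m-exponent machinery applies to scalar observables; dihedral
  averaging is fixed to the circular (sine/cosine) rule, which coincides
  with $m=-1$ for the components.
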