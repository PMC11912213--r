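---
title: "Energy-landscape kinetics and solubility analysis with ktnkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Energy-landscape kinetics and solubility analysis with ktnkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ktnkit)
```

# Scope

`ktnkit` analyses kinetic transition networks (KTNs) of peptide energy
landscapes — the graph whose nodes are local minima of a potential energy
surface and whose edges are the transition states (index-one saddles)
connecting them. From such a network the package computes thermodynamics
(Boltzmann occupations, funnel organisation, disconnectivity trees),
kinetics (harmonic transition-state-theory rates, master-equation
first-passage-time distributions, graph-transformation reduction), ensemble
structural descriptors of the associated conformations, hydration free
energies from per-conformer phase free energies, and a structure-conditioned
graph convolutional solubility score with additive per-residue attribution.
The motivating systems are amyloid-beta monomers (the 28-, 40- and
42-residue forms), whose canonical sequences and residue bookkeeping ship
with the package; all algorithms are exercised on synthetic landscapes and
toy structures with planted ground truth.

# The rate model

Rates between adjacent minima follow harmonic transition-state theory. With
uniform frequency factors (the coarse-grained setting, where normal-mode
prefactors are not meaningful), the rate from minimum $j$ over a transition
state $\dagger$ is

$$k_{ij} = \nu_{\mathrm{av}} \exp\!\big(-(V^\dagger - V_j)/k_B T\big),$$

so times are naturally reported in reduced units of $1/\nu_{\mathrm{av}}$
(`nu_av = 1` by default; supply a physical value to convert). Defaults:
$T = 300\,$K, $k_B = 0.0019872041$ kcal/(mol K); all energies are kcal/mol.
Because forward and backward rates across one edge share the same
transition-state energy, detailed balance
$k_{ij}\pi_j = k_{ji}\pi_i$ with $\pi_j \propto e^{-E_j/k_BT}$ holds exactly
— the property that makes the transition matrix $Q = K - D$ symmetrizable
and its spectrum real. Point-group degeneracies default to 1, consistent
with the uniform-frequency estimate.

The matrix convention is $K[i,j] = $ rate $j \to i$ (columns index the
source state), so the master equation is $\dot P = QP$ and columns of $Q$
sum to zero on a closed network. This is stated prominently because the
transposed convention is a classic silent bug.

# First-passage-time distributions

For a sink set $S$, the rows and columns of $Q$ belonging to $S$ are
removed while the escape rates *into* the sink stay inside the diagonal of
the reduced matrix $\tilde Q$ (absorbing boundary). Eigendecomposition of
$\tilde Q$ with eigenpairs $(\lambda_l, x_l, y_l)$ gives the
first-passage-time density as a mixture of exponentials,

$$p(t) = \sum_l A_l |\lambda_l| e^{\lambda_l t}, \qquad
  A_l = (\mathbf 1 \cdot x_l)(y_l \cdot p_0),$$

with $\sum_l A_l = 1$ whenever the sink absorbs all probability. Because
rates are exponentially sensitive to barriers, distributions are reported
in $y = \ln t$: each mode alone contributes a peak of height $A_l/e$ at
$y^* = -\ln|\lambda_l|$, and normally only a few modes are dominant (the
attribution report keeps modes with $|A_l| \ge 0.01$). The right-eigenvector
components of a mode, normalised by magnitude, attribute its time scale to
individual minima — this is what colours minima by the FPT peak they feed.

Numerically, the eigenproblem is solved in symmetrised form: detailed
balance lets us write
$S = \Pi^{-1/2}\,\tilde Q\,\Pi^{1/2}$ with $S$ symmetric, solved with a
symmetric eigensolver and transformed back. The balancing weights are
recovered from the rate matrix itself (log-ratios along a spanning tree,
verified on every edge), so reduced networks produced by graph
transformation — which remain reversible — go through the same path. The
symmetric solve guarantees a real spectrum and is the single largest
conditioning improvement over a general dense solve.

Two default choices matter for reproducibility: the $y$-grid has 2048
points spanning 5 log-units beyond the extreme mode peaks (trapezoid
quadrature; pass a wider `y_range` when you need the quadrature integral
to equal 1 to $10^{-6}$, since a single-exponential tail at $y^*-5$ still
carries $\sim e^{-5}$ of mass), and amplitudes in $(-10^{-10}, 0)$ are
clipped to zero while larger negative amplitudes are preserved — they are
legitimate and produce non-monotone densities.

The mean first passage time is *always* available through the independent
linear solve $\tilde Q^{\mathsf T}\tau = -\mathbf 1$, which the test-suite
uses to cross-validate the eigenmode sum $\sum_l A_l/|\lambda_l|$.

## Conditioning and the limits of double precision

The dual-route MFPT agreement is certified to $10^{-8}$ relative error on
random landscapes whose slowest and fastest time scales are within roughly
four orders of magnitude (inter-funnel barriers up to ~6 kcal/mol at 300 K).
This is a property of double precision, not of either algorithm: on stiffer
networks the attainable agreement degrades in proportion to the time-scale
ratio times machine epsilon, and a 50-digit reference shows *both* routes
drifting. Beyond that regime the package's answer is graph transformation,
not higher precision.

# Graph transformation

Partial graph transformation (pGT) removes states from the network exactly,
preserving mean first-passage statistics between the retained states and
the sink. It operates on branching probabilities
$P_{ij} = K_{ij}/D_{jj}$ and waiting times $\tau_j = 1/D_{jj}$ — all
quantities in $[0,1]$ or positive, which is why the elimination update

$$P'_{ij} = P_{ij} + \frac{P_{ix}P_{xj}}{1 - P_{xx}}, \qquad
  \tau'_j = \tau_j + \frac{P_{xj}\tau_x}{1 - P_{xx}}$$

is numerically stable where naive rate-matrix elimination is not. States
are eliminated in min-degree order by default (smallest fill-in); the final
result is order-independent up to round-off, which the suite asserts.

The flagship use is retaining only the states at the bottoms of competing
funnels before eigendecomposition. On a deep-trap fixture whose slow
eigenvalue is $\sim 10^{-18}$ against $O(1)$ rates elsewhere, any dense
double-precision eigensolve is hopeless (absolute eigenvalue error
$\sim \varepsilon\,\lVert Q\rVert \approx 10^{-16}$), yet the pGT-reduced
one-state system reproduces the analytically controlled value to better
than six significant figures. The reference value itself needs no extended
precision: to first order in the trap outflow rate $k_{\mathrm{out}}$, the
slow eigenvalue is $-k_{\mathrm{out}}\,P(\text{absorb before return})$,
with the splitting probability from a well-conditioned solve on the fast
subnetwork and relative corrections of order $k_{\mathrm{out}}$.

Only the first moment (and the slow spectrum after reduction) is asserted;
exact transplantation of full waiting-time distributions through the
reduction is out of scope, and higher FPT moments of the reduced network
are approximations to the full network's.

# Funnels, superbasins and disconnectivity trees

A *superbasin* at energy ceiling $E$ is a maximal set of minima mutually
connected by transition states at or below $E$. *Funnel clustering*
partitions minima into sets that can interconvert without exceeding a
threshold above the set's lowest member. The definition is self-referential,
so the package makes it unique with a greedy ascending sweep: seed at the
globally lowest unassigned minimum, flood-fill the unassigned minima
reachable through transition states at or below seed-energy + threshold,
close the cluster, repeat. Seeding in ascending order makes every seed
provably its cluster's lowest member ("selected minimum"); ties on equal
energies go to the smaller database id. The suite proves the partition
equal to a brute-force minimax-path (widest-path) oracle on small networks
and to planted assignments on generated landscapes.

The disconnectivity tree evaluates superbasins on a descending ladder of
energy levels (spacing `delta_E`, a user parameter — sources typically do
not publish theirs), nests them by inclusion and hangs each minimum as a
leaf at its own energy. Minima above a level remain clusterable (clustering
keys on transition-state energies only) and are merely flagged inactive for
rendering; isolated or shallow minima surface as singleton clusters rather
than being dropped.

# Structural descriptors

Structures are light atom tables (name, residue, coordinates) read and
written through standard PDB machinery (`bio3d` for parsing; a minimal
multi-MODEL writer for toy ensembles). Descriptors:

* **Kabsch RMSD** — SVD superposition with a proper rotation enforced; the
  default selection is main-chain N/CA/C/O plus side-chain carbons, with
  pure-CA and CB modes available.
* **RMSF** — members aligned to a reference; each residue represented by
  the centroid of its selected atoms; root-mean-square deviation about the
  ensemble mean. A separate `align_selection` lets you exclude a mobile
  region from the fit, which is also how the constructed single-residue
  displacement test recovers the planted amplitude exactly.
* **Radius of gyration** — mass-weighted by default.
* **Distance / contact maps** — CB (CA for glycine) inter-residue
  distances; the binary contact map uses the CASP rule, distance
  $\le 8$ Å inclusive, with unit diagonal (self-connections for the GCN).
* **SASA** — Shrake–Rupley quadrature on a deterministic golden-spiral
  lattice (960 points by default, probe 1.4 Å, Bondi-type radii). Residue
  totals are split into hydrophobic and polar surface, and the split sums
  to the total exactly by construction. The closed-form two-sphere overlap
  area serves as the quadrature oracle.

Residue bookkeeping uses the hydrophobic class
$\{G,A,V,L,I,P,F,M,W\}$ — the unique standard class assignment that
reproduces the published hydrophobic counts 11/23/25 (39 %/58 %/60 %) for
the three amyloid-beta peptides — and fixed formal charges at neutral pH
(Asp/Glu $-1$, Lys/Arg $+1$, His neutral, free termini cancelling), the
simplest model that yields the known net charge of $-3$ for all three.

# Hydration free energies

Per-conformer free energies in implicit solvent and in the gas phase
(produced externally at force-field or semi-empirical level; this module is
deliberately the arithmetic on their outputs) are aggregated per phase by
Boltzmann weighting, $G = -k_BT\ln\sum_i e^{-G_i/k_BT}$ with a max-shift,
and subtracted to give $\Delta G_{\mathrm{hyd}}$; more negative means more
favourable hydration, i.e. better solubility. The weighting temperature
defaults to 300 K (an assumption — sources rarely state it), and the same
quantity is used for weighting and reporting. Because the hydrophobic
fraction grows with amyloid-beta length, extensive values are normalised
per residue before comparing peptides; the bundled published table
reproduces the sign reversal of the solubility ordering under that
normalisation.

# The solubility GCN

Residue graphs carry the binary 8 Å contact adjacency with self-connections,
row-normalised so each row sums to exactly 1 (the last nonzero entry of a
row absorbs the rounding residue, which is exact once the partial sum
reaches 1/2). Node features are fixed blocks: BLOSUM62 row (20, scaled by
1/10), seven physicochemical descriptors (z-scored), secondary-structure
one-hot (3; 8-class DSSP labels are collapsed H/G/I → helix, E/B → sheet),
min–max-scaled SASA (1), and zero-filled evolutionary blocks (PSSM 20 +
HMM 30) when no profiles exist, padded to a declared width of 91 — the
enumerated blocks of the reference architecture sum to 91 even though a
round number of 94 is sometimes quoted, and the width is configurable for
that reason.

Propagation is two row-normalised graph-convolution layers with ReLU,
$H^{(l+1)} = \mathrm{ReLU}(D^{-1} A\, H^{(l)} W^{(l)})$, pooled by additive
attention with four heads ($s_h(i) = v_h^{\mathsf T}\tanh(W_a h_i)$,
softmax over nodes), concatenated, and mapped to the score by a single
linear layer plus sigmoid. The head is linear *by design*: each residue's
contribution — its attention weight applied to its hidden vector and passed
through the final linear map, summed over heads — then adds up with the
bias to the pre-sigmoid logit exactly, and the monotone sigmoid preserves
the sign of every attribution on the solubility scale. A deeper nonlinear
head would break that exactness, which is the entire point of reporting on
the pre-sigmoid scale.

Training is mini-batch Adam on squared error with hand-derived
backpropagation (verified against numerical gradients in the suite),
deterministic under a seed. No pretrained weights are shipped or claimed;
the deliverable is the architecture, the attribution machinery and the
synthetic training harness.

# Synthetic data: what it emulates and what it does not

`generate_funnel_ktn` builds each funnel as a random tree with member
energies in bottom $+\,(0, 0.45\,b_{\mathrm{lo}})$ and intra-funnel
transition states in bottom $+\,[b_{\mathrm{lo}}, b_{\mathrm{hi}}]$
(defaults 2–4 kcal/mol), funnels chained by transition states at
`inter_funnel_barrier` (default 12) above the higher bottom and bottoms
descending by 1.5 kcal/mol from −10. Trees rather than dense graphs are a
deliberate choice: they guarantee the minimax-barrier structure that makes
planted-cluster recovery provable, and the barrier ordering constraint
(inter > intra) is validated at generation. Magnitudes sit in the 1–20
kcal/mol range of real coarse-grained peptide landscapes so numerical
behaviour matches the use case. What the generator does *not* emulate:
realistic degree distributions, energy–connectivity correlations, or any
physical energetics — passing tests here demonstrates algorithmic
correctness, not force-field fidelity.

The trap fixtures plant kinetics by construction: `generate_trap_ktn` gives
a source that branches between a fast direct path and a deep trap (so the
FPT amplitude split between fast and slow peaks is controlled by the two
exit barriers), and `generate_deep_trap_ktn` realises the
$10^{-18}$-rate conditioning challenge described above.

`generate_toy_peptides` produces CA/CB pseudo-structures (ideal helix:
rise 1.5 Å, 100°/residue, radius 2.3 Å, which reproduces the diagnostic
(i, i+3)/(i, i+4) contacts; extended: 3.5 Å/residue; coil: 3.8 Å random
walk) with per-model Gaussian jitter. They stand in for reconstructed
all-atom minima; they have no side chains beyond CB and no physical
secondary-structure propensities.

`generate_solubility_dataset` labels random coil-peptide graphs by a
sigmoid of summed planted per-residue contributions plus clipped Gaussian
noise (σ = 0.05). Contributions depend on residue class (hydrophobic
−0.55, charged +0.45, polar +0.15, scaled by 6/N) and are embedded exactly
in the BLOSUM62 block by solving the 20×20 system, so the target is a
linear functional of the features and "recovery" is well-defined; a
per-graph hydrophobic-propensity draw (0.15–0.7) spreads the labels enough
that the noise ceiling on held-out $R^2$ is ~0.93. The planted direction —
hydrophobic residues as the low-solubility class — is what the attribution
ranking test recovers after training.

# Problem sizes and numerical defaults

The shipped analyses and checks run at desk scale by choice: 22 funnels × 8
minima for clustering (176 minima), a 1000-minimum landscape for the
master-equation structure checks, ≤100-state networks (100 replicates) for
the dual-route MFPT cross-validation, ≤30 states for the stiff-ODE oracle,
200 random elimination trials for pGT, and 500 graphs (400 train / 100
held out, 80 epochs) for the GCN. Tolerances follow the property being
checked: identities that hold by construction are asserted at $10^{-10}$ or
tighter, spectral cross-checks at $10^{-8}$, quadrature and learned
quantities at their intrinsic accuracy (0.5 % for 960-point SASA, $R^2 \ge
0.8$ against a 0.93 noise ceiling).

# Known limitations

* Harmonic TST with uniform prefactors only; no true normal-mode analysis,
  friction, or non-Markovian corrections.
* pGT preserves the first moment (and the reduced slow spectrum); full
  FPT-distribution transplantation is not implemented.
* The SASA implementation is a straightforward Shrake–Rupley quadrature —
  accurate to its point count, not optimised for very large structures.
* DSSP is consumed as labels, never computed; evolutionary feature blocks
  are zero-filled placeholders unless the user supplies profiles.
* The GCN is a faithful small architecture of the reference design, not a
  reproduction of any pretrained model's weights or its published accuracy
  on external datasets.
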