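---
title: "Methods: simulating and quantifying disordered-region clustering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and quantifying disordered-region clustering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drcluster)
```

# Scope and model

`drcluster` packages the computational workflow for studying how the
intrinsically disordered regions (DRs) of the IRE1&alpha; ER-lumenal domain
(LD) drive its clustering: a coarse-grained multi-chain condensate
simulator, the chain-cluster contact-map analysis applied to its
trajectories, and the quantitative fits used to characterise condensates
experimentally (FRAP, mass photometry, fluorescence-anisotropy binding).
The built-in peptides are the three disordered segments of the human
IRE1&alpha; LD in LD numbering: DR1 (131--152), DR2 (307--358) and the
linker-region peptide (369--443); DR3 (369--389) and the membrane-proximal
linker proper (390--443) are coordinate slices of the latter.

The reference multi-chain setting is 33 peptide copies in a 30 nm periodic
cubic box, which works out to 2 mM protein (`concentration(33, 30)` =
`r round(concentration(33, 30), 2)` mM), with 150 mM salt kept as ion
bookkeeping (`ion_counts(30, 150)` = 2439 Na^+^/Cl^-^ pairs) at 300 K.
Ions are never simulated; electrostatics enter only through the
class-pair attraction matrix below.

## The sticker--spacer stand-in dynamics

Reproducing a residue-resolved coarse-grained force field is out of scope;
the simulator instead evolves a bespoke overdamped Langevin sticker--spacer
model whose single purpose is to produce multi-chain trajectories with
tunable, reversible clustering for the analysis layer:

* one bead per residue (a two-bead backbone/sidechain mapping exists to
  exercise the bead-to-residue aggregation rule), harmonic bonds with
  rest length $b_0 = 0.38$ nm and $k = 500$ kJ mol^-1^ nm^-2^;
* soft repulsion $U = \varepsilon_{rep}(1 - r/\sigma)^2$ for $r < \sigma$,
  $\sigma = 0.47$ nm;
* Gaussian attraction wells centred at $r_0 = 0.50$ nm with width
  $\delta = 0.12$ nm between *sticker* beads, i.e. beads whose residue is
  charged (D/E, K/R) or aromatic (F/Y/W); opposite charges attract and
  aromatics attract aromatics ($\varepsilon_{ss}$ = 3 kJ/mol by default),
  like charges and everything else contribute nothing;
* a weak nonspecific well of the same shape between **all** non-bonded
  bead pairs (`eps_bg`, default 0.8 kJ/mol, about 0.3 kT);
* a single crowding knob $\chi \ge 0$ scaling every well depth (the PEG
  proxy), so $\chi = 0$ is an athermal chain solution and increasing
  $\chi$ mimics increasing crowding;
* per-bead updates $\Delta x = F D \Delta t / k_B T + \sqrt{2 D \Delta t}\,\xi$
  with a free-bead diffusion coefficient $D$ of 1 nm^2^/ns at 300 K.

Two of these choices deserve justification because they were genuinely
open:

**The repulsion strength.** $\varepsilon_{rep}$ defaults to 100 kJ/mol
(40 kT at full overlap). With a much softer wall, chains interpenetrate
freely, bead pairs constantly sit inside the 0.5 nm contact shell, and an
athermal system registers a percolating "cluster" that is purely an
artifact of soft excluded volume. The stiff wall makes $\sigma$ a real
excluded-volume diameter and the $\chi = 0$ system genuinely inert under
the contact definition.

**The nonspecific background well.** Sparse strong stickers alone never
produced condensation in this model: at modest depths a single sticker
pair detaches before a second one forms, so two chains never stay
associated; at large depths the stickers saturate *within* each chain
(intra-chain partners are always nearby) and chains collapse into inert
globules. Residue-resolved coarse-grained force fields avoid this trap
because every bead pair carries some dispersion attraction; `eps_bg`
restores exactly that feature, giving touching chains tens of weak,
individually transient contacts whose avidity holds them together while
individual contacts exchange. The default (0.8 kJ/mol, scaled by $\chi$)
leaves the athermal system untouched and puts the condensation transition
within reach of the crowding knob.

## Numerical stability

The explicit Euler--Maruyama update is stable only while
(stiffness) $\times D \Delta t / k_B T < 1$ for the stiffest interaction
(bonds: $k$; wall: $2\varepsilon_{rep}/\sigma^2$; wells:
$\varepsilon \chi / \delta^2$). Beyond that bound, overlapping bead pairs
oscillate instead of relaxing and behave as artificial bound states --
which *looks* like clustering and is the most dangerous failure mode of
this integrator because it is not a blow-up. `simulate_system()` therefore
refuses to run when the bound is violated, in addition to the usual check
that the per-step noise displacement stays below $\sigma/4$. The default
$\Delta t$ = 0.002 ns satisfies both with margin. Forces are evaluated
from linear interpolation on an $r^2$ grid of 4096 nodes (the wall force
is capped below $r = 0.03$ nm); saved-frame potential energies are checked
finite. Noise comes from a dedicated `mt19937_64` stream seeded from the
user seed, so trajectories are bit-reproducible from the seed alone.

## What the generator emulates, and what it does not

The generator reproduces the *setting* of the reference simulations
(copy numbers, box, concentration, salt bookkeeping, temperature) and
their qualitative phenomenology: an inert DR1-like regime at $\chi = 0$, a
clustering DR2/linker-like regime at elevated $\chi$ with highly dynamic
clusters and reversible single-chain association, and dissolution when
$\chi$ is dropped mid-run (the crowding wash-out). It does **not**
reproduce force-field energetics, sequence-specific conformational
ensembles, hydrodynamic interactions (clusters diffuse with Rouse-like
drag, so coarsening is slower than in reality), or real time scales. A
green simulation test therefore establishes that the analysis layer
measures regime behaviour correctly -- not that the model predicts the
biophysics of any particular sequence.

Two stated-world reductions keep the regime checks on a desk budget. The
inert check runs the full 33-copy, 30 nm DR2 system (cheap without
attraction). The condensed and reversibility checks run 6 copies of the
22-residue DR1 peptide at the same 2 mM in a 17 nm box over 1.2 &micro;s
of model time: cluster growth in the 33-copy 52-mer system proceeds
through cluster--cluster encounters whose Rouse-drag diffusion times run
to many microseconds, while the small system consolidates within the
budget. Chain identity is immaterial to the regime claim -- $\chi$, not
sequence, is the generator's regime dial -- and the fractions compared
(largest cluster holding at least half the chains versus at most a
tenth) are scale-free.

# Contact-map analysis

Two beads are in contact when their minimum-image distance is strictly
below 0.5 nm ("nearer than" the cutoff). Bonded pairs and intra-chain
pairs closer than 3 residues along the chain are excluded. Two chains
interact when they share at least one bead contact (`chain_threshold`);
the clusters of a frame are the connected components of the resulting
chain graph, with singletons reported as free chains.

The central-chain matrix follows the published procedure: per frame with
a cluster of two or more chains, select the analysis cluster, find its
central chain, and average the 0/1 contact indicators between central
bead $i$ and bead $j$ of each graph-adjacent neighbour over the number of
neighbours; the final matrix is the mean over contributing frames, so
entries live in $[0, 1]$. Where the source procedure is silent, the
package makes these documented choices:

* **multiple clusters per frame:** the largest cluster is analysed (ties
  broken toward the cluster containing the lowest chain id);
  `all_clusters = TRUE` averages over every cluster instead;
* **central-chain ties:** maximum degree, then maximum total bead
  contacts with neighbours, then lowest chain id -- a deterministic rule;
* **frame inclusion:** central-chain averaging uses only frames that
  contain a qualifying cluster; the two-chain mode averages over *all*
  frames (contact-free frames contribute zeros); both counts are recorded
  in the matrix metadata;
* **symmetrisation:** raw central-chain matrices are role-asymmetric and
  stored as computed; symmetrisation $(M + M^T)/2$ happens only in the 1D
  projection, where the two residue roles of identical chains are
  exchangeable.

Bead-level matrices convert to residue level by taking the maximum score
over all bead pairs of a residue pair, and the 1D projection sums each
residue's row of the symmetrised residue matrix. Projections can be
annotated with LD numbering through the region objects, which is how a
per-residue contact profile lines up with positions such as Asp328 and
Lys349 of DR2.

Cell lists are an implementation detail of the production path;
correctness is defined by a brute-force all-pairs re-implementation that
the test suite runs against dozens of randomised small systems, frame by
frame, demanding exact agreement.

# Cluster kinetics and mixing

A reporting "cluster" is a component of two or more chains; singletons
are free. Join/leave events are frame-to-frame membership changes at the
saved-frame resolution, with no smoothing; dwell segments are maximal
in-cluster runs. For two-species systems the observed heterotypic edge
fraction is pooled over frames and compared with the random-partner
expectation $2 p_A p_B / (p_A + p_B)^2$; their ratio is the mixing
enrichment (about 1 for well-mixed clusters, far below 1 when one species
is excluded). This statistic is a construction of this package -- the
source work reports mixing qualitatively -- and an optional seeded
permutation null is available for significance.

# Quantitative fits

**FRAP.** Traces are normalised exactly as in the source protocol:
background subtraction, division by the per-frame bleaching factor
(reference over its pre-bleach mean), then rescaling so the pre-bleach
level is 1 and the first post-bleach frame is 0. The recovery is fitted
by least squares to the one-phase association
$Y(t) = Y_0 + (P - Y_0)(1 - e^{-Kt})$ (optionally through the origin,
the "no offset" form used for membrane FRAP); $t_{1/2} = \ln 2 / K$ holds
exactly, and the mobile fraction is the fitted plateau of the normalised
curve -- the standard reading, consistent with the normalisation. The
membrane diffusion coefficient uses the closed form
$D = 0.224\, w^2 / t_{1/2}$ for a uniform circular bleach spot; the
bleach-spot radius of the source experiments is not printed, so printed
$D$ values are reproducible only at the formula level. Nonlinear fits use
deterministic initialisations, a strict convergence tolerance first
(noiseless round trips recover parameters to better than $10^{-6}$
relative) and fall back to the default tolerance for noisy curves.

**Mass photometry.** Contrast-to-mass calibration is ordinary least
squares against a standard ladder (BSA monomer/dimer/trimer, sequence
masses 66.4/132.8/199.2 kDa by default, overridable). Mass distributions
are fitted as Gaussian mixtures by expectation--maximisation directly on
the event list -- bin-width independent, equivalent at desk precision to
the histogram fit of the source -- with deterministic quantile-based
initialisation, a degeneracy fallback that drops a component and flags
the fit, and oligomer assignment as the nearest integer multiple of a
supplied monomer mass. Synthetic event samples are *not* truncated at
zero: truncating a broad component (135 &plusmn; 67 kDa) at zero would
shift its mean by several kDa and corrupt parameter-recovery checks.

**Binding.** Single-site isotherms
$r(L) = r_0 + (r_{max} - r_0) L / (K_d + L)$ are fitted by least squares
with $r_0$/$r_{max}$ initialised from the data range and $K_d$ from the
geometric middle of the grid; fits are flagged when $K_d$ lands outside
the measured range or the curve is flat.

# Worked example

```{r example}
regs <- builtin_regions()
map_position(regs$DR2, 328)   # Asp328 is chain-internal position 22

cfg <- system_config(list(DR2 = region_topology("DR2")), copies = 6,
                     box_edge = 17, seed = 1,
                     params = sim_params(chi = 2))
traj <- simulate_system(build_system(cfg), cfg, n_steps = 5000,
                        save_every = 1000)
kin <- cluster_kinetics(traj)
kin$series[, c("time", "largest_cluster", "n_clusters")]
```

```{r frap}
traces <- synth_frap(mobile_fraction = 0.82, t_half_s = 169,
                     frame_interval_s = 5, n_frames = 122)
fit_one_phase(process_frap(traces))
```

# Known limitations

* The dynamics is a stand-in: no force-field fidelity, no explicit
  solvent or ions, fixed box, Rouse (free-draining) drag. Trajectory
  import is text-only (XYZ dialect + sidecar); binary formats are out of
  scope.
* Condensation in the model needs the nonspecific background attraction;
  with stickers alone the model either stays inert or collapses chains,
  as discussed above.
* The mixing enrichment is a package-defined statistic, not a published
  one.
* Join/leave kinetics are reported at saved-frame resolution; rapid
  flicker between frames is invisible.
* The EM mass fitter assumes roughly Gaussian components; heavily skewed
  contrast distributions should be calibrated and inspected first.
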