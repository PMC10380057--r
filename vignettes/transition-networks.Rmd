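---
title: "Conformational transition networks and solvation analysis with ctna"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conformational transition networks and solvation analysis with ctna}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctna)
```

## The problem

Intrinsically disordered peptides such as the 42-residue amyloid-beta
monomer do not occupy a single native basin: they interconvert among
coil-like, helical and beta-rich conformations, and co-solutes
(glycosaminoglycans, lipids) can shift that balance. A transition network
(TN) makes this switching visible. Each trajectory frame is reduced to a
small tuple of descriptor values, identical tuples are merged into one
discrete state, and the directed counts of frame-to-frame transitions
between states become a weighted graph. Densely interconnected groups of
states (modularity communities) correspond to basins of the underlying
free-energy surface; the diagonal self-transition count of a state measures
its stability.

A TN is a *geometric* discretization: states are defined by structural
descriptors, not by kinetic clustering. It is deliberately not a Markov
state model, and `ctna` makes no attempt to estimate relaxation timescales
from the count matrix.

## The descriptor triple and state projection

Three descriptors summarise each frame:

* **Nalpha** — number of residues assigned helical (H),
* **Nbeta** — number of residues assigned sheet (E),
* **dNC** — the end-to-end distance in Angstrom, by default between the
  first and last C-alpha (configurable to backbone N-first/C-last; C-alpha
  endpoints are robust to capping and protonation conventions).

A frame's state is the binned tuple: the two counts enter exactly, dNC is
floored into 1-Angstrom bins (`descriptor_spec(dnc_bin = )`). One Angstrom
keeps the state count tractable while preserving near-raw resolution of the
compactness coordinate; community averages are always computed from the
raw, unbinned values. State ids are dense integers assigned in order of
first appearance, so a projection is reproducible frame-for-frame.

### Secondary-structure assignment

No single assignment algorithm is canonical for disordered ensembles, and
different assigners shift absolute Nalpha/Nbeta values. `ctna` uses a
fully specified, geometry-only dihedral-window classifier:

* H: phi in [-100, -30] and psi in [-80, -5] degrees, in a run of at least
  4 consecutive such residues;
* E: phi in [-180, -90] and psi in [90, 180] or [-180, -170], in a run of
  at least 3, and (default "paired-strand" mode) some other E-run has an
  inter-run C-alpha pair closer than 5.5 Angstrom — a lone extended
  stretch is not a sheet;
* otherwise C; chain termini without a computable (phi, psi) are C.

The windows cover the canonical alpha and beta Ramachandran basins; the
run-length and pairing requirements suppress single-residue noise. Because
the rule is purely geometric it can be validated exactly on chains built by
the package's own internal-coordinate engine, and absolute sheet counts may
differ from DSSP-style energy-based assigners — comparisons across
assigners should use one assigner consistently.

## Transition counting, communities, node sizes

`build_transition_matrix()` counts ordered pairs (t, t + lag) *within*
trajectory segments only; concatenated independent runs never contribute
cross-boundary pairs. The default lag of one stored frame is the simplest
consistent reading of a transition matrix on saved frames; it is
configurable, and the total count always equals the sum over segments of
(segment length − lag).

Community detection maximizes Newman modularity on the symmetrized graph
(weight(i,j) = count(i,j) + count(j,i)); self-loops are excluded from the
modularity weights but retained as node populations, because
self-transitions measure state stability, not connectivity. Networks with
at most 10 states are solved by exhaustive enumeration of all set
partitions (Bell(10) = 115,975), which provably attains the optimum;
larger networks use the Louvain algorithm with a fixed seed and stable
state ordering, so labels are reproducible. The resolution parameter
defaults to the classic value 1.

For display, node sizes are mapped linearly from the population range onto
[1, 10]; when all populations are equal the midpoint 5.5 is used.
`export_network()` writes GEXF 1.3 (Gephi-native), GraphML or a CSV edge
list, carrying per-state descriptor values, populations, sizes, community
labels and community-average descriptors. Raw counts are exported without
normalization. Graph layout (e.g. Force Atlas 2) is left to the
visualization tool.

## Water structure: T and Q

The translational order parameter integrates the deviation of the
oxygen–oxygen RDF from the ideal gas over the density-rescaled distance
zeta = r * rho^(1/3):

$$T = \frac{1}{\zeta_c} \int_0^{\zeta_c} \lvert g(\zeta) - 1 \rvert\, d\zeta,
\qquad \zeta_c = 2.8.$$

T = 0 for an ideal gas and grows with long-range order; the default cutoff
2.8 sits where liquid water's RDF has decayed to its asymptote. The
integral is evaluated by the trapezoidal rule on the RDF's native bins
(default width 0.05 Angstrom) with linear interpolation of the final
partial bin; against a fine-grid Riemann oracle the rule is accurate to
better than 1e-3 for smooth profiles. Two numerical caveats are inherent
to the estimator: finite sampling makes |g − 1| positively biased in
sparsely populated small-r bins (configuration averaging suppresses this;
the convergence test in the suite averages five configurations of a dense
4000-particle gas, where T drops below 0.01), and the zeta-rescaling
density defaults to the full water phase rather than a vicinity subset —
which density the rescaling should use around a solute is a genuine
convention choice, exposed as the `rho` of the profile.

The orientational (tetrahedral) order of a central oxygen with neighbors
j, k at angles psi_jk is

$$q = 1 - \tfrac{3}{8} \sum_{j<k} \left(\cos\psi_{jk} + \tfrac13\right)^2,$$

evaluated over the four nearest neighbors — the fixed pair sums presuppose
exactly four. q = 1 for a perfect tetrahedron, the mean over random
directions is 0, and four coincident directions give q = −3 (the
analytic minimum for degenerate geometries). When a vicinity subset
defines the centers, neighbors are still searched among *all* oxygens, so
shell boundaries do not artificially deplete neighborhoods. Vicinity
membership (default 10 Angstrom to the nearest solute atom, 5 Angstrom as
the first-shell variant) is re-evaluated every frame, and T and Q are
ensemble-and-time averages over frames.

## Hydrogen-bond kinetics

Bonds are detected by the community-standard geometric criterion — donor
to acceptor at most 3.5 Angstrom and donor–H–acceptor angle at least 150
degrees (both configurable). The binary existence function h(t) of every
candidate bond (any triple observed bonded at least once) enters the
pooled multi-origin autocorrelation

$$c(t) = \frac{\sum_b \sum_{t_0} h_b(t_0)\, h_b(t_0 + t)}
{\sum_b \sum_{t_0} h_b(t_0)^2},$$

the *intermittent* convention: a bond that breaks and reforms still
correlates. No baseline is subtracted; with a large candidate pool the
mean occupancy is small and the plateau is negligible. A stretched
exponential $c(t) = \exp(-(t/\tau)^\beta)$ is fitted by bounded
least squares (tau > 0, beta in (0, 1]) from t = 0 to the first point
below 0.01, with the 1/e crossing as the initial tau and beta = 0.8; the
mean lifetime follows analytically as
$\langle\tau\rangle = (\tau/\beta)\,\Gamma(1/\beta)$, which the test suite
confirms against quadrature of the survival integral to 1e-6 relative
error and in the beta → 1 limit.

One statistical subtlety deserves emphasis. For traces generated by a
stationary alternating-renewal process whose *on-interval survival* is the
stretched exponential, the multi-origin estimator does **not** converge to
that survival: origins fall inside on-intervals, so c(t) measures the
equilibrium residual-lifetime curve (inspection paradox), smoothed further
by reformation. Fitted beta is therefore biased upward for beta < 1 (a
generating beta of 0.5 fits near 0.7 even at negligible occupancy), while
beta = 1 is recovered exactly by memorylessness. The suite asserts
exactly these truths — agreement with the analytic telegraph-process
curve, beta = 1 recovery, and monotonicity of fitted beta in the
generating shape — rather than a naive identity between the two betas.
Fits of explicit model curves, by contrast, recover (tau, beta) to 1%
noiselessly and 5% under 0.01 Gaussian noise.

## Contacts, ions, charges

Two groups are in contact in a frame when their minimum heavy-atom
distance is below 10 Angstrom (hydrogens excluded — the robust convention,
documented here as a package choice); counts over frames normalize to
contact probabilities, symmetric for intramolecular maps and monotone
non-decreasing in the cutoff. Ion distributions g(r) are computed to the
*nearest atom* of a multi-atom reference group (e.g. both carboxyl oxygens
plus the carbon), normalized by ion bulk density and spherical shell
volume — approximate near a multi-atom group, exact in the uniform limit.

Formal charges use integer side-chain values (Asp/Glu −1, Lys/Arg +1), His
neutral by default with a His+ switch (protonation is a modelling decision,
not a constant), +1/−1 for uncapped termini, and −1 each for the sulfated
GalNAc(4S) and the uronic GlcUA of chondroitin-4-sulfate: the 42-residue
amyloid-beta sequence with free termini gives −3, an 8+8 disaccharide
16-mer gives −16.

## What the synthetic generator emulates — and what it does not

The generator provides every input of the pipeline with known ground
truth:

* **Peptide trajectories.** A first-order Markov chain (seeded; started
  from its stationary distribution) switches among macrostates; each frame
  is built from the macrostate's per-residue (phi, psi) pattern by an
  internal-coordinate (NeRF) chain builder with ideal backbone geometry
  (N–CA 1.458, CA–C 1.525, C–N 1.329 Angstrom, omega = 180), plus
  Gaussian dihedral jitter. The default three macrostates are an extended
  coil at (−75, 150), a helix at residues 10–21 at (−57, −47), and a
  hairpin with strands 17–21/30–34 at (−139, 135) closed by a fixed
  chain-reversing loop whose entry approaches the opposite strand flank
  below 6 Angstrom, giving the intrapeptide contact map the perpendicular
  hairpin trace. Jitter defaults to 8 degrees, scaled by 0.2 on
  structured residues — structured regions fluctuate less, and this keeps
  strand pairing intact in essentially all frames (the hairpin's
  Nbeta >= 8 holds at a ~5e-5 failure rate; its dNC distribution sits
  well below the coil's, though extreme tails of the two can touch).
  Frames with any nonbonded pair under 1.5 Angstrom are rebuilt with
  fresh jitter. The default chain mimics switching statistics with
  stationary distribution (0.6, 0.3, 0.1) and self-transition 0.95 per
  stored frame — basin-like persistence rather than free diffusion.
* **Water configurations.** Uniform ideal gas, perfect diamond lattice
  (every interior site q = 1) and jitter-perturbed lattice span the order
  spectrum of T and Q at water-like density 0.0334 per cubic Angstrom by
  default.
* **H-bond traces.** Alternating renewal per bond: Weibull on-times
  (shape beta, scale tau — survival is the stretched exponential) and
  exponential off-times, default mean 200 ps against ~20 ps on-times so
  that occupancy is dilute as in solute–water bonding.
* **Ion systems.** Uniform placement (flat g) or thin shells at a
  prescribed radius (peak at r0), with sub-1-Angstrom overlaps resampled.

What the generator does **not** emulate: force-field energetics, solvent
geometry around the peptide, realistic Ramachandran correlations along
the chain, or any kinetics beyond first-order switching. Passing tests
therefore demonstrate that the analysis stack measures what it claims on
data with known truth — not that any particular real system behaves this
way.

## Numerical choices and problem sizes

Degenerate inputs are handled deterministically: equal populations map to
node size 5.5, single-state networks form one community, zero-edge
networks leave each state its own community, termini are coil, empty
trajectories refuse to serialize. Ties in community detection are fixed
by the exhaustive search's lexicographic enumeration (small networks) or
the seeded Louvain pass (large ones). All coordinates are Angstrom
internally; minimum-image distances are used whenever a box is present,
and RDFs refuse r_max beyond half the shortest box edge.

The shipped test-suite scales are chosen to run comfortably on one CPU:
Markov recovery on 1e5-step chains, end-to-end population recovery on a
1e4-frame realized trajectory (communities vs ground truth within 0.02),
ideal-gas convergence on five 4000-particle configurations, renewal
traces of 200–400 bonds over 2000–4000 frames, and exhaustive modularity
oracles up to 10 nodes.

## Known limitations

* The dihedral-window assigner is not DSSP; absolute Nalpha/Nbeta levels
  are assigner-specific.
* Raw transition counts are exported unnormalized; any reweighting for
  display is the visualization tool's concern.
* The pooled intermittent c(t) conflates residual-lifetime and
  reformation statistics (see above); fitted beta is a descriptive
  relaxation parameter, not an unbiased estimate of an underlying
  interval distribution's shape.
* Orthorhombic boxes only; no binary trajectory formats (XTC/DCD/TRR) —
  convert to PDB/XYZ/CSV upstream.
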