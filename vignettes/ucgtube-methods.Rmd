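---
title: "From density maps to microtubule mechanics: methods and design choices"
author: "ucgtube"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From density maps to microtubule mechanics: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

Single microtubules are micrometers long, far beyond the reach of atomistic
simulation, yet their mechanics — Young's modulus, flexural rigidity, and a
persistence length that depends on contour length — are central to their
biological function. `ucgtube` implements a density-to-mechanics pipeline
that needs no atomistic input at all:

1. a cryo-EM style density map is preprocessed (axial replication, solvent
   removal, min–max normalization, mass calibration);
2. the retained density is clustered into ultra-coarse-grained (UCG) beads
   by convolution-initialized, density-weighted K-means (CK-CG);
3. the beads are connected into a heterogeneous harmonic network (MVP-ANM)
   whose force constants depend on bead masses and distances;
4. the network is simulated (Langevin dynamics, or an exact static
   constrained minimization where a time average is the target) to read off
   mechanical observables.

This vignette records the model equations, the tunable parameters with
their defaults and units, and the numerical and design decisions a
maintainer would want to know. All internal units are nm, kg/mol, ps and
kJ/mol; MRC headers (Angstrom) are converted at the I/O boundary, and the
dynamics converts masses to g/mol so that kJ/mol–nm–ps–g/mol form a
consistent unit system.

# Preprocessing

`removeSolvent()` zeroes voxels at or below a relative threshold (default
0.1 of the map maximum) and keeps only the largest 6-connected component.
The original solvent-subtraction procedure for this kind of data is not
fully specified in the literature we follow; the relative threshold plus
connected-component rule is our declared stand-in, and both knobs are
exposed. `normalizeDensity()` maps retained values affinely onto [0, 1];
excluded voxels stay at zero and are tracked by an explicit mask, so a
retained voxel that normalizes to exactly zero is still distinguishable
from solvent.

`replicateAxial()` tiles the grid along the symmetry axis assuming the seed
is an exact lattice repeat (a 32 nm microtubule segment is 4 dimer
repeats). A non-periodic seed would produce density seams at the copy
junctions; the synthetic generator therefore wraps its blobs periodically
along the axis.

`calibrateMass()` defines the density-to-mass rule: the mass of any voxel
set is `massScale` times its summed normalized density, with `massScale`
fixed by the known total molar mass. This is the only rule under which
bead masses from any clustering sum exactly to the calibrated total, which
is what makes "average bead mass 22 kg/mol" a well-defined resolution
target.

# The synthetic generator

`makeMicrotubuleDensity()` emulates the geometry of a low-resolution
microtubule reconstruction: 13 protofilaments on a 12.5 nm mid-wall
radius, 4 nm monomer rise (8 nm dimer repeat), a 3-start B-lattice stagger
of 3 × 4/13 ≈ 0.92 nm between neighboring protofilaments, one isotropic
Gaussian blob of width 2 nm and mass 55 kg/mol per tubulin monomer, and a
default voxel size of 0.925 nm (half of the 18.5 Å resolution typical of
such maps) so the inter-protofilament grooves stay resolvable. The seam is
ignored — all protofilaments are identical — because nothing downstream
references it. What the generator does **not** emulate: realistic noise
spectra or CTF effects, lattice defects, tapered ends, and the slightly
non-circular cross-section of real reconstructions. Tests passing on these
maps therefore validate the algorithms, not the fidelity of any particular
experimental map.

`sampleWlcChain()` provides the oracle for the persistence-length
estimator: fixed-length segments whose tangent receives independent
Gaussian transverse increments of variance (segment length)/l_p at each
joint, the standard discrete worm-like chain whose tangent correlation
decays as exp(-s/l_p) to first order. `makeLpDataset()` evaluates the
anisotropic-rod length dependence (below) exactly and applies
multiplicative lognormal noise.

# CK-CG coarse-graining

The retained voxels are partitioned into cubic blocks. The block edge, when
not given, is the smallest multiple of the voxel size whose nonempty-block
count M does not exceed the requested bead count N (the finest cubic tiling
with M ≤ N): the initializer needs one seed per block and N − M extras, so
M may never exceed N. Each block's density is multiplied voxel-wise
(Hadamard product) by a Gaussian kernel centered on the block content with
sigma = blockEdge/4 — wide enough not to flatten the score, narrow enough
to bias the argmax toward the block interior — and the maximal product
voxel becomes that block's seed (max-pooling). Extra seeds go to the
highest-scoring blocks, one per block in rank order, at the best unused
voxel. Ties everywhere break to the lexicographically smallest voxel
index, which makes the whole CK-CG path deterministic: there is no RNG
anywhere in it.

Refinement is Lloyd's algorithm on density-weighted voxels: assignment by
Euclidean distance in physical nm (anisotropic voxels are therefore
handled correctly), centroid updates weighted by voxel density, objective
the weighted within-cluster sum of squares. The objective is monotonically
non-increasing; convergence is declared when assignments stabilize or the
relative objective change drops below 1e-8 (configurable; max 500
iterations). A cluster whose weight empties is reseeded at the voxel
contributing most to the objective. The random-init baseline
(`method = "kmeans_random"`) shares this refinement core and differs only
in seeding. Whether the original method weighted its assignments by
density is not documented; we weight both steps, because only then are
bead positions density centroids and the mass bookkeeping exact.

The minimal-model resolution follows from tubulin bookkeeping: two beads
per 55 kg/mol monomer plus a groove bead shared between laterally adjacent
monomers gives ≈ 2.5 beads per monomer, hence the 22 kg/mol average-mass
target; on our synthetic 13-protofilament map this yields ≈ 8125 beads per
micrometer (13 × 250 monomers × 55 / 22). Beads split into two radial
populations — protofilament crests and groove bottoms — which is the
geometric feature the minimal model exists to preserve.

# The MVP-ANM network

Beads i, j with equilibrium separation d0 ≤ dc are connected by a harmonic
bond of energy

    E_ij = gamma_ij (d_ij - d0_ij)^2,
    gamma_ij = A (1 + m_i)(1 + m_j) exp(-d0_ij^2 / R^2),

with m in kg/mol and R = dc/3 by default (gamma is negligible beyond 3R,
which motivates tying R to the cutoff). Note there is no factor 1/2: the
per-bond force constant is 2 gamma, and the LAMMPS `bond_style harmonic`
convention K (r − r0)^2 maps onto it with K = gamma directly. Three
numerical conventions we fixed:

* the Gaussian in gamma uses the **equilibrium** distance, so force
  constants are constants and the model is a fixed-topology harmonic
  network;
* the Heaviside boundary is inclusive (a bond at exactly d0 = dc is kept);
  this is the conservative choice for stability and is configurable;
* the mass term (1 + m) uses the numeric value of the molar mass in
  kg/mol. This is dimensionally odd but is how the model is defined; its
  absolute scale is absorbed into A anyway.

A is a pure calibration scalar (internal units kJ/mol/nm^2 per unit mass
product). Its published counterpart is quoted in kg^-1 s^-1, a unit system
that cannot be reconstructed from the model equations alone, so we do not
assert any particular numerical value: `calibrateForceScale()` is the
normative definition, fitting A so that the static force-clamp
displacement of a 100 nm tube under 2.36 nN matches the experimental
Young's modulus of 100 MPa (ΔL ≈ 13 nm through a 181.5 nm^2 annular
cross-section — outer radius 12.5 nm, wall ≈ 2.6 nm, back-solved from
that calibration triple since no cross-section is printed alongside it).
Displacement scales inversely with A in the linear regime, so calibration
is one inverse-scaling step polished by a log-space secant; the geometric
nonlinearity of the helical lattice (twist–extension coupling) makes the
polish necessary.

Cutoff selection: with dc = 6.5 nm (R = 2.2 nm) the bond population splits
into a strong short-range class below 2R = 4.4 nm and a 40–150× weaker
4.4–6.6 nm class that carries most of the lateral
protofilament–protofilament cohesion; at dc = 6.0 nm part of that lateral
shell is lost (crest–crest neighbor distances sit near 6.05 nm) and the
tube wall degrades in thermal simulation, while 6.5 and 7.0 nm models hold
their shape. We verify this as a reduced-scale dynamic property (below).

# Mechanics

`langevinRun()` integrates Langevin dynamics with the BAOAB splitting
(compiled inner loop), per-bead friction mass/dampingTime (the LAMMPS
"damp" convention, default 10 ps), Maxwell–Boltzmann initial velocities,
and full determinism for a given seed. Correctness is asserted through
physics, not implementation identity: a stiff harmonic bond reproduces the
closed-form length variance kBT/(2 gamma) and a 100-bead network
equilibrates to the normal-mode equipartition value (3N − 6) kBT/2 within
the statistical tolerance, provided the model is in its harmonic regime
(gamma d0^2 >> kBT for every bond). Outside that regime — ultra-soft long
bonds — the network is genuinely anharmonic in the coordinates and the
equipartition count does not apply; tests choose fixture models
accordingly.

Because the time average of a harmonic network under constant force equals
its constrained energy minimum, `minimizeUnderForce()` (sparse-Hessian
Newton with line search, gradient tolerance 1e-9 of the applied force
scale) serves as the cheap static oracle for force-clamp means; the
Langevin and static routes are compared within statistical error as a
standing property. One practical device: equilibrium configurational
averages are independent of masses, so `massScaling` in the simulation
config scales masses down in the equations of motion only, accelerating
configurational sampling by orders of magnitude without changing any
structural observable. Thermal-stability runs use it; kinetic quantities,
of course, must not.

`stabilityCheck()` judges a tube stable when its per-slice cross-section
radius (beads grouped into 8 nm axial slices by their reference
coordinate, radius measured from the per-frame slice centroid) stays
within 20% of the reference in every frame and the radius of gyration
drifts less than 20%. The slice construction makes the diagnostic
insensitive to rigid motion and to the large thermal bending of long soft
tubes — which is physics, not collapse — while radial collapse or wall
splaying trips it.

Problem sizes: the mechanics test fixtures use 32–64 nm tubes (260–520
beads) and up to a few million integration steps; these are the package's
declared reduced-scale versions of the original cluster-scale protocol
(micrometer tubes, 60 ms of sampling), chosen so the full property suite
runs on a single CPU.

# Persistence length

For each frame of an axially ordered filament, the terminal tangents are
total-least-squares 3D line fits through the first and last 10% of beads
(configurable; minimum 3), oriented along the bead order, and the
intersection angle θ = arccos(t_head · t_tail) is clamped to [0, π/2] (the
estimator's stated domain; clamping events are counted and stay below 1%
on stiff tubes). The persistence length inverts ⟨cos θ⟩ = exp(-L/l_p).
One estimator subtlety matters: a line fit through a terminal segment
measures the average tangent of that segment, i.e. the tangent at the
segment centroid, so the two tangents are separated by
(1 − segmentFraction) × L along the chain and that effective length is
used in the inversion (without it the estimator is biased upward by
1/(1 − f) ≈ 11%). Confidence intervals come from a block bootstrap over
frames, since successive frames are correlated. Against worm-like-chain
ensembles with known l_p ∈ {5, 10, 50} µm the estimator recovers the truth
to ~2% at 10^4 frames.

Flexural rigidity is κ = l_p kB T. The length dependence is fitted with
the anisotropic-rod model

    l_p(L) = l_p_inf / (1 + 3 E I / (G k A L^2)),

with E = 100 MPa, I = 16670 nm^4, k = 0.72 and A = 25 nm^2 held fixed and
(l_p_inf, G) free (nonlinear least squares, deterministic multi-start over
G decades). The threshold length sqrt(3EI/(GkA)) separating the
shear-dominated short regime from the asymptote is derived from the fit.
The two constants named A — the force-constant scale in the network and
the 25 nm^2 effective cross-section here — are unrelated and kept as
distinct, explicitly named arguments.

# Known limitations

* The harmonic MVP-ANM potential is invalid for large deformations;
  bending-mode or buckling simulations, tubulin association/dissociation,
  and Gō-like potentials are out of scope by design.
* The solvent-removal rule is a declared stand-in, not a reconstruction of
  the original procedure.
* The absolute value of A is meaningful only within this package's unit
  conventions; compare calibrated displacements, not A itself, across
  implementations.
* Desk-scale thermal sampling cannot reach multi-micrometer tubes; the
  length-dependent persistence-length fit is exercised on
  generator-produced datasets at the published study conditions rather
  than on micrometer-tube trajectories.
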