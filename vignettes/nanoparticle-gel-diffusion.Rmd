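---
title: "Rigidity-tunable nanoparticle transport in a cross-linked gel: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rigidity-tunable nanoparticle transport in a cross-linked gel: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(gelperm)
```

# The question the model addresses

Nanoparticles (NPs) delivering drugs across mucosal surfaces must cross a
cross-linked biopolymer hydrogel whose mesh is comparable to the particle
size. Experimentally, particles of *intermediate* rigidity ("semi-elastic")
penetrate such gels faster than both their softer and harder counterparts:
semi-elastic particles deform into ellipsoids and slip through pores, hard
particles cannot deform at all, and very soft particles deform excessively,
conform to the gel fibers, and get held up by the extra contact they make.
`gelperm` implements a coarse-grained molecular-dynamics model of exactly
this situation, together with the trajectory statistics used to quantify it
(ensemble mean-squared displacement and fitted diffusivity, polymer contact
counts, gyration-tensor shape metrics) and the companion two-dimensional
multi-particle-tracking estimators used on microscopy data.

# Reduced units and bead-size convention

Everything is expressed in reduced Lennard-Jones units: the unit of length
is the *bead radius* sigma, the unit of mass is the bead mass m, energies
are in eps and times in tau. Because sigma is a radius, two beads touch at a
center-center distance of 2 sigma; accordingly the Lennard-Jones length
parameter for bead pairs defaults to `sigma_lj = 2` and the contact
criterion used for NP-polymer contact counting (distance below 3 sigma) sits
1 sigma outside surface contact. The thermal energy is kT = 0.23 eps
throughout.

# System construction

## Polymer network

`build_network()` lays fibers parallel to all three axes at every transverse
grid line of an n-by-n lattice, where `n = round(box / mesh)`. Each fiber is
a closed loop of beads through the periodic boundary; a single *shared* node
bead sits at each three-fiber crossing and is tethered to its initial
position by a harmonic spring (`tether_k`, default 10 eps/sigma^2), which
anchors the network while leaving fiber segments free to fluctuate. The
chain count is `3 n^2`: a 98-sigma box with a nominal 16-sigma mesh gives
n = 6, 108 chains and an effective mesh of 98/6 = 16.33 sigma — the rounding
keeps both the printed box size and the printed chain count of the
full-scale system attainable simultaneously. Consecutive fiber beads are
bonded harmonically (`bond_k`, default 100 eps/sigma^2; bond energy
`k (r - r0)^2`) at a rest length snapped so an integer number of beads fills
each mesh cell; the default target spacing is 2 sigma (touching beads).
Non-bonded polymer pairs are purely repulsive (WCA).

## One-particle-thick nanoparticle shells

An NP is a single layer of orientable beads on a sphere
(`build_np_shell()`), placed by a deterministic Fibonacci lattice — a
seedless, quasi-uniform covering that makes shells exactly reproducible.
Bead count is `round(pi d^2 / s^2)` for diameter `d` and target spacing `s`.
The default spacing is 2.5 sigma (about 50 beads on a 10-sigma shell):
bead-level contact counts scale directly with the surface bead density, and
this density reproduces the per-NP contact scale (roughly 8-17 beads)
reported for the original model, which pins its effective discretization.

Shell beads interact through the standard one-particle-thick membrane
potential: a soft repulsive core
`u_R(r) = eps_np ((r_min/r)^4 - 2 (r_min/r)^2)` below `r_min`, a
cosine-shaped attractive well
`u_A(r) = -eps_np cos^(2 zeta)(pi (r - r_min)/(2 (r_cut - r_min)))` out to
`r_cut`, weighted by the relative bead orientations through
`phi = 1 + mu (a - 1)` with
`a = n_i . n_j - (n_i . rhat)(n_j . rhat) + sin(theta0) (n_j - n_i) . rhat - sin^2(theta0)`.
Forces and the generalized forces on the orientation vectors are exact
analytic derivatives (the attractive envelope is tabulated with a cubic
Hermite interpolant whose derivative is evaluated analytically, so energy
and force remain exactly consistent; table resolution keeps the
approximation error below 1e-9).

Three geometric parameters are tied to the constructed shell rather than
guessed: `r_min` is set to the realized mean nearest-neighbor distance of
the Fibonacci lattice (about 2.33 sigma at 2.5-sigma nominal spacing), so
the built shell sits at the potential minimum with no built-in prestress;
`r_cut = r_min + 1.8` gives the well enough width that the first
neighbor ring stays bound under thermal motion; and the spontaneous
curvature angle satisfies `sin(theta0) = r_min / d`, which is the exact
tilt optimum for neighboring beads on a sphere of diameter `d` — it gives
the shell a memory of its preferred radius.

## Rigidity classes

Rigidity in this model is controlled jointly by the cohesion `eps_np` and
the orientation weight `mu` (which sets the bending stiffness); tuning
`eps_np` alone either leaves the shell quasi-rigid or ruptures it, so each
class preset fixes both (`rigidity_presets()`):

| class | eps_np | mu | behavior in the network |
|---|---|---|---|
| soft | 5 | 1 | deforms strongly and irregularly (aspect ratio drifts ~30% from spherical) |
| semi_elastic | 6 | 1.5 | deforms into modest ellipsoids while staying intact |
| hard | 16 | 3 | aspect ratio stays within ~2% of the initial shell |

These values were calibrated with short single-NP runs *in the network* at
kT = 0.23: the hard preset is required to keep its gyration aspect ratio
within 2%, the soft preset to deform beyond 15%, with the shell remaining
whole across protocol-length runs (no bead evaporation, monitored through
the gyration eigenvalues; parameterizations below soft's cohesion shred in
the network). The calibration used only these shape and integrity criteria.
Shell beads belonging to *different* NPs interact through plain WCA
repulsion rather than the membrane potential: distinct particles must not
fuse, and the attractive membrane interaction between marginally cohesive
shells otherwise tears them apart on contact.

Rigid control particles (`rigid_sphere`, `build_rigid_ellipsoid()`) are
propagated as rigid bodies; prolate ellipsoids of aspect ratio AR keep the
reference-sphere volume via semi-axes `a = r AR^(2/3)`, `b = r AR^(-1/3)`.

## Adhesion

Polymer-shell pairs attract through a cut-and-shifted 12-6 LJ with well
depth `eps_polymer_np` (default 0.1 eps, the middle of the 0.02-0.2 range
over which the original study scanned robustness) and cutoff
`2.5 sigma_lj`.

# Dynamics

`run_simulation()` integrates Velocity-Verlet at dt = 0.01 tau with a
per-bead Langevin thermostat: after the second half-kick each bead receives
friction `-gamma v dt/m` and Gaussian noise of variance
`2 gamma kT dt / m^2`. The friction default is `gamma = 0.1 m/tau`: whole-NP
mobility scales as `kT/(N_beads gamma)`, and this value lets an NP traverse
several mesh cells within a desk-scale run so the pore-to-pore transport
regime is actually sampled. As a performance option the kick may be applied
every `thermostat_interval` steps with friction and noise scaled to the kick
interval — an exact splitting of the same Ornstein-Uhlenbeck process with
identical statistics on timescales beyond the kick interval (the production
protocol uses 4 steps = 0.04 tau, far below any relaxation time of
interest).

Shell-bead orientation vectors follow a first-order overdamped rotational
Langevin update sharing the thermostat temperature, with friction
`gamma_r = 10`: the component of `-dU/dn` perpendicular to `n` rotates the
vector, balanced thermal noise is added in the tangent plane, and the vector
is renormalized. The larger rotational friction keeps the Euler
discretization bias of this overdamped update (order `dt kappa / gamma_r`)
well below a percent while orientation relaxation stays much faster than
shape dynamics.

Rigid NPs are propagated as rigid bodies (center-of-mass Verlet plus
quaternion rotation under the net torque, including the torque
`n x (-dU/dn)` from orientation-dependent interactions). The bead-level
thermostat is projected exactly onto the rigid degrees of freedom: summing
per-bead friction and noise gives a COM friction `N gamma` and a rotational
friction `gamma I`, with matching noise covariances, so
fluctuation-dissipation balance is preserved.

Two bookkeeping guarantees matter for analysis: positions are stored
wrapped, while a parallel unwrapped record is advanced by raw displacements
(diffusion statistics never cross a periodic seam), and the whole trajectory
is bit-reproducible from the run seed (an internal xoshiro256++ generator
with ziggurat normals, independent of R's RNG state). A per-step guard
aborts if any bead moves more than 0.5 sigma in one step.

With the thermostat off (`gamma = 0`) the conservative subsystem is
integrated symplectically and total energy is conserved to better than 0.1%
over 1e4 steps (the orientation update is overdamped by construction, hence
dissipative; energy-conservation checks apply to systems without free
orientation dynamics).

# Observables

* `msd_3d()` — ensemble MSD of NP centroids,
  `MSD(t) = <(x_t-x_0)^2 + (y_t-y_0)^2 + (z_t-z_0)^2>`, averaged over all
  particles and all time origins on the stored frame grid. Lags run to half
  the trajectory span by default; longer lags average too few origins for a
  stable estimate.
* `fit_diffusivity()` — ordinary least squares of MSD against lag; the
  slope k gives `D = k/6`. The production fit window is the final quarter
  of the available lags, the proportional analogue of the long-lag window
  used at full scale.
* `contact_counts()` — per frame and NP, the number of shell beads with at
  least one polymer or node bead within 3 sigma under minimum image (each
  shell bead counted once; a bead-pair counting mode is available as a
  switch).
* `shape_metrics()` — gyration tensor of each NP's beads about their
  centroid; aspect ratio `sqrt(lambda_max / lambda_min)`; coplanar or
  collinear bead sets are flagged degenerate.

`run_experiment()` wires these together for a class-by-seed campaign and
reports per-run diffusivities, class means with standard deviations, the
semi-elastic/hard and semi-elastic/soft diffusivity ratios, and contact and
shape summaries; contacts and shapes are averaged after discarding the
first quarter of each run as burn-in.

# The desk-scale protocol

The full-scale system (98-sigma box, 108 chains, 27 NPs, 2e6 tau) is a
documented configuration preset, but the default protocol is scaled for a
desk run: box 49 sigma (n = 3, 27 chains), the same effective mesh of
16.33 sigma against the same 10-sigma NPs — the mesh-to-particle ratio is
the controlling geometry and is preserved exactly — with 2 NPs per run,
3 seeds per class, and 2e4 tau per run (2e6 steps) at dt = 0.01. Runs of
the three deformable classes take roughly 10-15 minutes of CPU time
altogether at these sizes.

The three classes share one box per seed (2 NPs of each class, per-NP
interaction presets), so every class experiences the same network
realization and thermal noise — a paired comparison that removes the
between-run environmental variance from the class ratios. The class
diffusivity is fitted on the seed-averaged (pooled) MSD, mirroring the
repeat-and-average procedure of the full-scale protocol, over the final
quarter of the lag range.

What desk scale does and does not resolve: with 6 NPs per class over
2e4 tau each, the sampling error on a fitted class diffusivity is a large
fraction of its value — pore-to-pore hopping and trapping are rare events
at this duration, and the trapped-time distribution is heavy-tailed. In our
desk-scale runs the between-seed spread of a class D is comparable to the
class differences themselves, so the diffusivity fold-ratios between
rigidity classes fluctuate strongly from seed set to seed set and the
published ~2.5-fold enhancement of the semi-elastic class is not reliably
reproduced at this scale. Likewise, with the polymer-shell adhesion at
0.1 eps the per-bead binding energy is below kT, so soft shells do not
accumulate the roughly two-fold contact excess reported at full scale;
desk-scale contact counts are similar across classes (~6-8 beads). The
mechanistic observables these runs do support are the shape taxonomy
(hard rigid, semi-elastic ellipsoidal, soft strongly deformed) and the
absolute contact scale; the transport contrast requires the full-scale
protocol (or far longer desk runs) to resolve.

# The tracking module

`generate_tracks()` emulates a multi-particle-tracking acquisition: 100
particles, 32.6 ms frame interval, 10 s movies, per-particle diffusivities
drawn from a log-normal mixture of a slow gel-hindered majority and a fast
minority (defaults: 5% fast at a 0.3 um^2/s median, 95% slow at a
0.005 um^2/s median), 2D Gaussian steps of per-axis variance `2 D dt`,
10 nm Gaussian localization noise, and optionally a reflecting confinement
disk. `track_msd()` implements the particle-averaged 2D MSD (squared
displacements at a lag, averaged over all origins within each track, then
over the n particles), `effective_diffusivity()` the per-particle
`D_eff = MSD(t)/(4t)` at a 1 s time scale, and `deff_distribution()` the
log10 histogram plus the fraction of particles above a mobility threshold
(default 0.1 um^2/s). Tracks shorter than a requested lag are skipped, not
padded. The generator reproduces localization-noise inflation of the MSD by
the additive constant `4 sd^2` and confined-diffusion plateaus, but it does
not model spot detection, linking errors, or out-of-focus loss, so it
validates the estimators rather than any particular biological sample.

# Numerical choices and limitations

* Bonded (1-2) pairs are excluded from non-bonded terms; shell beads carry
  no bonds (cohesion comes entirely from the membrane potential).
* Neighbor search uses cell-binned Verlet lists with displacement-triggered
  rebuilds; shell-involved pairs and the short-ranged polymer-polymer pairs
  keep separate lists (the tethered network moves little, so its list
  rebuilds rarely). Cell-list and brute-force assemblies agree to 1e-9.
* Beads within the same *rigid* NP are excluded from pair evaluation; their
  geometry is fixed.
* The MSD fit window and lag grid operate on stored frames (default ~500
  per run).
* Solvent hydrodynamics, electrostatics, fiber bending stiffness and
  mucin biochemistry are outside the model; the network is regular, not
  disordered.
* Very soft parameterizations (cohesion near 2 eps with low mu) can rupture
  a shell in the network; the gyration eigenvalues expose this, and the
  presets stay on the intact side of that boundary.
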