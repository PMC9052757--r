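---
title: "Methods: trajectory analysis of slow allosteric activation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trajectory analysis of slow allosteric activation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and model system

`allostate` implements the analysis layer used to characterize slow
(micro- to millisecond) allosteric activation in the heterodimeric
bienzyme imidazole glycerol phosphate synthase (IGPS): the HisF cyclase
subunit binds the effector PRFAR, and the HisH glutaminase subunit
hydrolyses glutamine once its oxyanion hole — formed by the backbone NH
of hV51 in the h49-PGVG oxyanion strand — is properly oriented. The
package does not run molecular dynamics of the solvated protein; it
analyses trajectories (and generates synthetic surrogates at desk
scale) through five stages:

1. **Order parameters** (`dihedral_series`, `angle_series`,
   `distance_series`, `hbond_occupancy`): the backbone phi dihedrals of
   hV51 and hG50 that span the oxyanion-strand conformational landscape;
   the HisF:HisH interface angle theta defined by the C-alpha atoms of
   fF120, hW123 (vertex) and hG52; and the nucleophilic-attack distance
   d_nuc from the catalytic hC84 thiol to the glutamine amide carbon.
2. **State and phase classification** (`classify_states`,
   `classify_binding_phase`): rule-based assignment of frames to the
   inactive-OxH / unblocked-OxH / active-OxH conformational states and
   to the unbound / recognition / captured / catalytic binding phases.
3. **Free-energy landscapes** (`landscape_from_samples`,
   `bias_from_hills`, `fel_from_bias`, `marginal_profile`,
   `barrier_between`): population-based landscapes F = -kT ln P and
   well-tempered metadynamics (WT-MetaD) reconstructions from
   multi-walker hill records.
4. **Binding events** (`detect_binding_events`): excursion detection on
   d_nuc with hysteresis, reporting per-phase dwells, the Gln–hG52
   anchor hydrogen bond, and productivity.
5. **Communication networks** (`correlation_matrix`, `spm`, `te_spm`):
   displacement cross-correlations of C-alpha atoms, the shortest path
   map (SPM), and its sliding-window time evolution (te-SPM).

# Conformational states and binding phases

States are axis-aligned boxes on the periodic
(phi-hV51, phi-hG50) torus. The literature fixes the inactive-OxH
phi-hV51 interval [-180, -100] degrees and places active-OxH at
phi-hV51 around +60 degrees; no numeric boundary has been published for
the partial phi-hG50 rotation that defines unblocked-OxH. The defaults
are therefore:

| state         | phi-hV51        | phi-hG50      |
|---------------|-----------------|---------------|
| inactive-OxH  | [-180, -100)    | [-180, 0)     |
| unblocked-OxH | [-180, -100)    | [0, 120)      |
| active-OxH    | [20, 100)       | any           |

The unblocked-OxH phi-hG50 band and the active-OxH box width are
explicit, config-overridable guesses guided by the basin topology of
the published landscape. Intervals are uniformly closed on the lower
edge and open on the upper (the wrap point -180 aliases +180); this
single convention replaces the mixed open/closed boundaries one could
otherwise write down, because a reproducible classification matters
more at the (measure-zero) boundaries than any particular choice.
Definitions are applied in priority order, so overlapping custom boxes
resolve deterministically. Frames with undefined geometry carry `NA`
and are excluded from histograms, never imputed.

Binding phases follow the published d_nuc semantics — unbound above
12 A, recognition down to the 6 A capture threshold, captured below
6 A, catalytic below 3.5 A *and* in the active-OxH state (a frame below
3.5 A without the conformational gate stays "captured"). Event
detection uses hysteresis: an event closes only when d_nuc returns
above the 12 A recognition threshold, which prevents threshold chatter
around 6 A from fragmenting one excursion into many events. Events
with fewer than `min_capture_frames = 10` captured+catalytic frames are
discarded; no minimum dwell has been published, so 10 frames is an
artifact-level default. The Gln–hG52 anchor hydrogen bond is reported
per event but never used as a gate — the observation that unbinding
does not occur while it is formed is an empirical correlation, not a
rule. The productive-closure marker for the interface angle is
theta < 13 degrees (`productive_closure_threshold()`).

# Free-energy landscapes

All landscapes live on periodic grids over (-180, 180] with a default
of 72 bins (5 degrees) per axis — fine enough to resolve the three
basins, coarse enough that desk-scale sample counts do not leave the
grid riddled with empty bins. kB = 0.0019872 kcal/mol/K, and the
default temperature is 300 K (kT = 0.5962 kcal/mol), exposed
everywhere as an argument. Empty bins are masked, never given a
pseudo-count, and barrier paths cannot cross them: a free energy is
only reported where something was observed.

`barrier_between` defines the barrier as (lowest pass) - (minimum of
the starting basin), where the lowest pass minimizes, over all
4-connected periodic grid paths, the maximum free energy along the
path. It is computed by a union-find sweep that activates bins in
ascending F until the two regions join; the activating bin is the
saddle. The tests verify this against an independent
threshold-connectivity oracle (binary search over F levels with graph
component checks), which computes the same minimax value by a different
route; exhaustively enumerating simple grid paths is combinatorially
impossible even on a 12 x 12 grid.

For WT-MetaD, `bias_from_hills` sums the deposited Gaussians with
minimum-image periodic differences, merging walkers by time-sorted
concatenation (the shared-bias multiple-walkers scheme; no per-walker
reweighting), and `fel_from_bias` applies the standard well-tempered
estimator F = -(gamma/(gamma-1)) V. Time-dependent reweighting
estimators and block-analysis error bars are out of scope.

# Synthetic data: what it emulates and what it does not

The generators provide every input the pipeline needs, deterministically
from a seed.

**Model potentials.** `make_triple_well()` is a 2D periodic potential
of the form U = -ln(offset + sum of von-Mises-like wells), with basins
at (-130, -70), (-130, 60) and (60, 60) degrees mimicking the
inactive / unblocked / active basin layout of the dihedral landscape.
Von Mises kernels (exp(kappa(cos - 1))) rather than wrapped polynomials
keep both the periodicity and the gradient exact. Two shallow bridge
wells shape the passes; their amplitudes were calibrated once, against
the potential's own dense-grid (0.5 degree) minimax computation, so the
default barriers are 4 kT (inactive <-> unblocked) and 8 kT
(unblocked <-> active) at 300 K — echoing the published picture of easy
microsecond interconversion between inactive and unblocked against a
much slower approach to active. The exact dense-grid values are stored
on the object and are the reference all recovery tests use.

**Dynamics.** `langevin_sample` integrates overdamped (Brownian)
dynamics, s <- s - (D/kT) grad U dt + sqrt(2 D dt) eta, in degrees,
with analytic gradients and periodic wrap. Overdamped rather than
underdamped: one fewer parameter, and population/FEL/te-SPM machinery
only needs configurational sampling. Defaults D = 1500 deg^2/ns and
dt = 0.002 ns keep the per-step drift well under the 30-degree guard
(exceeding it raises an error advising a smaller dt). The integrator
is in C++; a 2x10^7-step trajectory takes seconds.

**WT-MetaD.** `wtmetad_sample` advances all walkers in lockstep over a
shared bias accumulated on an internal 2-degree grid with analytic
per-hill updates to the bias and its gradient (interpolated bilinearly
for the dynamics). Every `pace` steps each walker deposits a hill of
tempered height h0 exp(-V/((gamma-1) kT)). The hill defaults
(h0 = 0.5 kcal/mol, sigma = 10 degrees, pace = 500 steps, gamma = 10)
are desk-scale stand-ins: the hill parameters actually used in the
source simulations are not in the text available to this package.

**Planted networks.** `planted_ensemble` builds two subunits as planar
grids of pseudo-C-alpha sites (3.8 A along rows, 5 A between rows and
across the subunit gap) so a 6 A mean-distance cutoff produces a grid
contact graph with a few inter-subunit crossing edges — multiple
alternative routes, as in a real contact network. A planted path runs
along one row across the gap with consecutive-residue correlation
rho_path = 0.9 (decaying as rho_path^|i-j| along the path) over a
distance-decayed rho_bg = 0.1 background; the matrix is projected to
the nearest positive-semidefinite correlation before sampling. Frame
displacements draw the three Cartesian components i.i.d. with this
correlation across residues, which makes the displacement dot-product
correlation equal the target exactly in expectation — a scalar latent
times a fixed per-residue direction would multiply the target by the
cosine between the direction vectors, so the isotropic-component
construction is used instead.

**What passing on synthetic data does not show.** The generators share
none of the confounds of real trajectories: no force-field error, no
incomplete sampling of orthogonal degrees of freedom, no conformational
memory beyond the CVs, no solvent, and displacement statistics that are
exactly Gaussian. Recovery results on them validate the estimators and
bookkeeping, not the biology.

# Numerical choices

- Dihedrals use the atan2 formulation with the IUPAC sign convention,
  range (-180, 180]; degenerate (collinear) geometries yield `NA`, not 0.
- Histogram bins are upper-edge-closed so that exactly +180 falls in the
  last bin and -180 wraps into the same bin.
- Superposition before covariance: frames are Kabsch-fitted to the
  iterated mean structure (tolerance 1e-6 A on the mean) to remove
  rigid-body drift that would inflate correlations; correlation is the
  Pearson dot-product correlation of 3D displacement vectors (mutual
  information is not used; the choice is exposed, not hidden).
- SPM construction: edge weight -log|C| on contact edges (|C| clamped to
  [1e-12, 1]), mean C-alpha distance cutoff 6 A, inclusion threshold 0.3
  on normalized widths — all config-exposed, since the upstream
  publications rather than the analysed paper define the construction.
  Dijkstra breaks equal-length ties toward the lowest-index predecessor
  and flags that alternates existed, so outputs are deterministic.
- te-SPM windows are [k stride, k stride + window] while the end fits in
  the span, using frames strictly inside each window (boundaries
  inclusive); no cross-window smoothing.
- Boltzmann-direct sampling (`boltzmann_sample`) discretizes P on a
  0.5-degree grid and jitters uniformly within cells, making population
  checks independent of any dynamics.

# Problem sizes used in the shipped analyses

The numbered scripts under `analysis/` (and the acceptance checks) use:
2x10^7 Langevin steps (10^6 ns) for population landscapes; 10 walkers x
4x10^6 steps (8x10^4 hills) for the WT-MetaD reconstruction, recovering
both barriers to within 0.5 kT of the stored dense-grid values; 10^6
direct Boltzmann samples for the population-FEL comparison (basin
free-energy differences agree with the analytic reference to
0.1 kcal/mol); and 100 seeded 5000-frame ensembles for planted-path
recovery, of which at least 95 must rank every planted edge in the top
|path| SPM widths. These sizes were chosen as the smallest that leave
clear margins between statistical noise and the tolerances being
checked.

# Known limitations

- XTC/TRR trajectories are not read (no R-level reader is available to
  the package); DCD and multi-MODEL PDB are. Trajectory writing is
  limited to plain-text multi-MODEL PDB fixtures.
- The interface-angle worked examples ship with *synthetic* stand-in
  structures built to the open (~25 degree) and closed (~10 degree)
  triad geometry; they exercise the structure-to-angle pipeline but are
  not experimental coordinates.
- Classification is rule-based throughout — no hidden-Markov or kinetic
  model smooths the state assignment.
- The WT-MetaD machinery assumes all hill series share gamma and the CV
  set; funnel corrections, restraint reweighting and convergence
  diagnostics beyond barrier tracking are not implemented.
- Community-network analysis and per-interaction tables are outside the
  package's scope.
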