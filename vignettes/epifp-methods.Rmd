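---
title: "Interface fingerprints for antigen-antibody complexes: methods and design notes"
author: "epifp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interface fingerprints: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Antibodies recognize antigens through a localized patch: the *epitope* on
the antigen surface and the *paratope* on the antibody. Small sequence or
structural changes inside this patch can shift binding affinity
substantially, so descriptors that summarize the interface — rather than
the whole protein — are the natural input for regression models of
binding strength across panels of complexes (proteochemometric, PCM,
modelling). This package implements such a descriptor family: per-side
structure and physicochemical fingerprints, and an interaction
fingerprint (EPIF) that encodes the contacts themselves.

## Interface detection by SASA loss

Per-residue solvent-accessible surface area (SASA) is computed by
Shrake-Rupley sphere sampling (probe radius 1.4 Å, 960 sample points per
atom, Bondi element radii; unknown elements fall back to 1.8 Å with a
warning) twice: once for the whole complex and once per molecule in
isolation. Residues with isolated SASA above 1 Å² are *surface*
residues; surface residues that lose more than 1 Å² on complex formation
are the epitope (antigen side) and paratope (antibody side). Both
thresholds are strict inequalities; "surface" is judged on the
isolated-molecule SASA, so the definition of a protein's surface does not
depend on its binding partner.

Two numerical choices are worth noting:

* The sample lattice (a Fibonacci spiral) is oriented along the principal
  axes of the complex's atom cloud, with signs fixed by third moments of
  the cloud. Because the lattice then co-rotates with the molecule, SASA
  values — and everything downstream — are invariant under rigid motion
  up to floating point, not merely up to sampling noise.
* The same lattice orientation is used for the complex and the isolated
  runs. Removing the partner can then only ever *free* sample points,
  so the burial `sasa_isolated - sasa_complex` is exactly non-negative,
  and residues far from the interface get a burial of exactly zero.

No attempt is made to reproduce any particular reference program's
absolute SASA values (radii sets and hydrogen handling differ across
programs); all decisions in this package depend only on the
self-consistent complex-vs-isolated difference.

## The interaction coordinate frame

Every residue is reduced to a representative point, the unweighted mean
of its atom coordinates. The epitope center `Ce`, paratope center `Cp`,
and interface center `C` (mean over the union of epitope and paratope
points) define the frame: the interface axis is the unit vector along
`Cp - Ce`, oriented toward the paratope for antibody-side fingerprints
and toward the epitope for antigen-side ones; the virtual interface
plane passes through `C` perpendicular to this axis.

## Cylinder-model structure fingerprint (80 bits)

Each side's points are expressed in cylindrical coordinates around the
axis — height `z` above the interface plane and radius `r` from the axis;
the angular coordinate is discarded, as a rotating plane sweeping around
the axis would visit all angles. Points are binned on a 2 Å (radial) by
5 Å (axial) grid covering `r < 20` Å and `0 <= z < 40` Å: 10 x 8 = 80
cells, enough to capture essentially all interface residues in practice.
All bins are half-open (`[low, high)`), so every point has exactly one
cell and points at the outer boundary are dropped — an arbitrary but
fixed convention required for bit-exact interchange of fingerprint
files. Cells encode binary occupancy by default; a `count` mode is
available. The fraction of points falling inside the grid is attached to
each fingerprint as a `coverage` attribute so that truncation is always
visible.

On the antibody side the binned points are all antibody surface
residues (a paratope-only switch exists). On the antigen side the
residue points are replaced by *unit patches*: triangles of three epitope
residues whose pairwise point distances are all within 4 Å (inclusive),
represented by their centroids. Patch enumeration is exhaustive and the
output is sorted, so it is deterministic. Whether the antigen-side
centers `Ce`/`C` should themselves be recomputed from patch centroids is
genuinely ambiguous; by default they come from the epitope residue
points (the patches only replace the *projected* objects), and
`antigen_centers = "patches"` exposes the alternative reading.

## Shell-model physicochemical fingerprint (30 values)

Concentric 2 Å shells around `Cp` (antibody) or `Ce` (antigen) partition
distances `[0, 20)` Å into 10 layers. Three AAindex property scales —
ARGP820101 (hydrophobicity), FAUJ880109 (hydrogen-bond donor count),
FAUJ880108 (localized electrical effect) — are encoded per layer as the
arithmetic mean of the item values in that layer: a residue's own scale
value on the antibody side, the mean over the three residues of each
unit patch on the antigen side. Empty layers encode 0; AAindex values
are used raw (their scales are part of the descriptor's identity);
nonstandard residues have no scale value and contribute nothing to layer
means. The vector is property-major (3 x 10 = 30 values), and the
concatenation [80-bit structure | 30-value physicochemical] gives the
110-length per-side fingerprint `Fab` / `Fag`.

## The epitope-paratope interaction fingerprint (150 bits)

For each epitope residue a 15-bit vector describes its contact
environment: bit 1 flags any paratope atom within 4 Å; six
(type, strength) pairs cover backbone, side-chain, polar, hydrophobic,
aromatic and charged contacts; two further bits flag contact with a
residue bearing a side-chain hydrogen-bond donor or acceptor. Backbone
vs side-chain typing keys on the *paratope atom* (N, CA, C, O, OXT are
backbone — a glycine can therefore never make a side-chain contact);
the chemical types key on the *paratope residue's* class. A strength bit
is set when the number of distinct contacting paratope residues of its
type reaches a cutoff: 1 for charged (a single salt bridge is already a
strong interaction), 4 for everything else (the median per-residue
contact count in antigen-antibody interfaces). Contacts are judged
purely by atom distance and residue type; no donor-acceptor geometry is
tested, so the H-bond bits are presence-only.

The per-residue vectors are assigned to the 10 radial shells around the
interface center `C` and aggregated per layer by bitwise OR (EPIF is a
bit string; a `sum` mode that counts residues per bit is available),
giving the 150-bit EPIF. The residue class table (hydrophobic
{A,V,L,I,M,F,W,P}, polar {S,T,N,Q,C,Y,H}, aromatic {F,W,Y,H}, charged
{D,E,K,R}, side-chain donors {R,K,W,N,Q,H,S,T,Y}, acceptors
{D,E,N,Q,H,S,T,Y}; histidine aromatic+polar but not charged at
physiological pH) is data, not code — any edited copy can be passed in.

## Peer descriptors

Two conventional descriptor families are provided for comparison:

* **Sequence similarity**: percent identity of a global
  Needleman-Wunsch alignment (BLOSUM62, gap open 11 / extend 1,
  identities divided by alignment length) against a user-supplied panel
  of reference sequences, one value per panel entry. The internal
  aligner keeps the descriptor deterministic and dependency-free; a
  `precomputed` hook accepts identity rows from external tools for users
  who need parity with a specific aligner.
* **Backbone geometry** (41 features): mean and standard deviation of
  the four backbone bond lengths and three backbone angles, 12-bin
  circular histograms of phi and psi, and the circular mean resultant
  length of phi, psi and omega. This fixed composition is this package's
  own; it is versioned with the package so models remain comparable
  across runs.

## Proteochemometric modelling

Descriptor blocks are concatenated by named recipes (`Fab-Fag`,
`Fab-Fag-EPIF`, `Fab-Fag-MLPD`, `Sab-Sag`, `Gab-Gag`, ...), where MLPD is
the conventional cross-term: the flattened outer product of the two
110-length side fingerprints (12100 values). Models are epsilon-SVR over
a precomputed Gram matrix under one of four kernels: normalized
polynomial (default d = 2, c = 0), polynomial (d = 1, c = 1), Pearson VII
"universal" (omega = 1, sigma = 1) and RBF (gamma = 0.01) — the standard
published forms of these kernels. Features are standardized to
training-set mean and variance before kernel evaluation by default,
because the blocks mix binary occupancies, AAindex values and percent
identities of wildly different scales; labels are centered and scaled
internally for the solver and predictions are returned in label units.
Defaults C = 1 and epsilon = 1e-3 mirror common SMO-regression settings;
validation studies in this package pass C = 10 explicitly when near
interpolation of noiseless data is the point.

Evaluation reports goodness of fit `R2` (squared Pearson correlation of
fitted vs observed on the *training* rows), cross-validated `Q2cv`
(pooled out-of-fold predictions of a seeded 10-fold split), and
held-out `Q2test`, MAE, RMSE, RAE and RRSE, the latter two as
percentages of the mean-predictor baselines. With constant observed
labels the relative errors are undefined and reported as `NA`.

## What the synthetic generators emulate

`make_complex()` builds pseudo-atomic complexes with a planted, fully
known interface: contact pairs whose side-chain tips approach to 3.6 Å
across the interface plane, clustered in triangles so the epitope forms
unit patches, with non-contact residues kept at least 8 Å from the
partner so they gain no burial. Residues are minimal templates (N, CA,
C, O, CB and a side-chain tip) — enough for SASA, backbone/side-chain
contact typing and the geometry features, with no pretension of
physically realistic packing, rotamers or chain continuity. Amino acids
at planted contacts are chosen to carry declared interaction classes
(R for charged, L for hydrophobic, S for polar, F for aromatic).
All randomness passes through the recipe seed and output PDB files are
byte-identical for equal recipes.

`make_pcm_dataset()` emulates a descriptor panel: complexes are drawn as
perturbed copies of 25 prototype fingerprints (2% bit flips, 10%
continuous wobble), reflecting the clonal relatedness of real
antigen-antibody panels, where many complexes share frameworks and
epitopes and differ by a few mutations; an i.i.d. feature panel would
not resemble such data and would also make a 200-sample regression on
220 correlated-free columns fundamentally under-determined. The response
is sparse-linear in the `Fab`/`Fag` features (optionally with
antibody x antigen product terms), plus Gaussian noise expressed in
units of the signal's standard deviation; rows split 80/20 train/test
by a seeded shuffle, mirroring common benchmark proportions.

Passing tests on these fixtures demonstrates internal correctness —
detection soundness at generous burial margins, oracle-exact geometry,
invariances, and recovery of planted signal. It does not demonstrate
predictive accuracy on crystallographic complexes with experimentally
or docking-derived affinities, which depends on data this package does
not ship.

## Problem sizes and numerical tolerances

The test suite and the bundled analysis script use 48-residue synthetic
complexes (about 280 atoms), 960 sphere points per atom, PCM datasets of
60-200 samples and 10-fold cross-validation — sizes chosen so the whole
validation cycle runs in about a minute on a laptop while still
exercising every code path at meaningful scale. Rigid-motion invariance
is asserted at 1e-6 (binary blocks are exactly equal), Pythagorean and
floor-division identities at 1e-9, and brute-force oracle comparisons
exactly.

## Known limitations

* PDB input only (no mmCIF); chain roles must be supplied by the user —
  there is no automatic Fv/Fab identification, structure repair or
  protonation.
* H-bond and aromatic bits are class-based presence flags, not
  geometric hydrogen-bond or pi-stacking tests; water-mediated contacts
  are invisible.
* Absolute SASA values are sampling-based and radii-set dependent;
  only complex-vs-isolated differences are used for decisions.
* The 41-feature geometry descriptor is a fixed in-package composition,
  not a reimplementation of any particular published feature list.
* Affinity labels are inputs; the package does not dock or simulate
  binding energies.
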