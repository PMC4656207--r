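---
title: "Phase extension from low-resolution EM maps: model, operators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase extension from low-resolution EM maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the science it implements: the
model and its assumptions, the operators of the phase-extension loop, the
numerical choices, what the synthetic scenario emulates, and where the
method's limits are. Code chunks are illustrative and not evaluated when
the vignette is built; every empirical number quoted here is one the test
suite or `scripts/acceptance.R` computes.

## 1. The phase problem and the two data sources

A crystal diffraction experiment measures amplitudes $|F(\mathbf h)|$ of
the Fourier coefficients of the cell's electron density,

$$F(\mathbf h) = V \left\langle \rho(\mathbf x)\,
  e^{+2\pi i\,\mathbf h\cdot \mathbf x}\right\rangle_{\text{cell}},
\qquad
\rho(\mathbf x) = \frac1V \sum_{\mathbf h} F(\mathbf h)\,
  e^{-2\pi i\,\mathbf h\cdot\mathbf x},$$

but not their phases. A single-particle cryo-EM reconstruction of the
same assembly provides an independent, low-resolution image of the
molecule: once placed correctly in the crystal cell, its Fourier
transform supplies starting phases — here to ~4.9 Å, while the crystal
diffracts to ~2.3 Å. The task of the package is the *extension* of those
phases to the diffraction limit when the classic engine of phase
extension — averaging over many NCS copies — is unavailable because the
asymmetric unit holds only a two-fold NCS dimer.

Conventions used throughout: phases in degrees on $[0,360)$; reflections
stored on the Friedel hemisphere $(h>0)\cup(h{=}0,k>0)\cup(h{=}k{=}0,l>0)$;
$F(000)$ excluded, so all maps are zero-mean; fractional coordinates
internally, with the orthogonalization matrix putting $\mathbf a$ along
$x$; figures of merit $m \in [0,1)$ are expected cosines of the phase
error and weight both map synthesis ($m\,F\,e^{i\varphi}$ coefficients)
and error averaging.

## 2. Map preparation

Four operations condition the EM map for placement:

* **Sharpening** scales each coefficient by $e^{+B s^2/4}$, $s = 1/d$.
  $B$ is user-supplied (no automatic Guinier fit); negative $B$ blurs.
* **FOM weighting** multiplies each resolution shell by
  $C_{\mathrm{ref}} = \sqrt{\max(0,\,2\,\mathrm{FSC}/(1+\mathrm{FSC}))}$,
  the standard half-map-FSC-derived map-vs-truth weight; shells with
  FSC ≤ 0 are zeroed. The FSC curve is an input.
* **Magnification correction** rescales the length scale of the density
  by a calibration factor about the map centre, dividing densities by
  $\mathrm{scale}^3$ so the integrated density is conserved. A note on
  the contract: the operation acts on the density inside a fixed cell
  (feature widths scale, centroids stay), because that is the form whose
  behaviour is observable and testable on blobs; an equivalent
  formulation rescales the cell instead. Resampling is trilinear on an
  exactly Fourier-oversampled copy (zero-padded reciprocal space, ≥10
  samples per period of the finest occupied mode), which keeps the
  scale→inverse-scale round trip above CC 0.999; plain trilinear at the
  working grid spacing would lose ~5% RMS per pass.
* **P1 boxing** places the density at the centre of a cubic P1 cell with
  edge ≥ 2× the model diameter. The diameter is estimated as that of the
  smallest sphere about the thresholded centroid containing all voxels
  above mean + 1σ (threshold configurable). The factor-2 padding is not
  cosmetic: the box transform is later *interpolated* between reciprocal
  lattice points, and 2× oversampling of the molecular transform is what
  makes complex interpolation meaningful.

## 3. Molecular replacement

The search is exhaustive and amplitude-based — appropriate at the cell
sizes this package targets, and far easier to reason about than
likelihood machinery:

* the **rotation search** scores every rotation on a ZYZ Euler grid
  (β-dependent α spacing avoids pole oversampling; two-pass refinement at
  step/4) by the Pearson correlation between $|F_{\mathrm{obs}}|$ and the
  rotationally resampled amplitudes of the boxed map's transform;
* the **translation search** fixes the rotation and, for each fractional
  offset $\mathbf u$ on a grid, assembles the symmetry-expanded amplitude
  $\bigl|\sum_s e^{2\pi i\,\mathbf h\cdot\mathbf t_s}\,
  F_m(\mathbf R^{-1}\mathbf s_{\mathbf h \mathbf R_s})\,
  e^{2\pi i\,(\mathbf h\mathbf R_s)\cdot\mathbf u}\bigr|$
  via the phase-shift theorem and scores it the same way;
* the **Z-score** is (top − mean of rest)/sd of rest over all translation
  scores (≥100 required).

One implementation point matters enough to record: the box transform
oscillates with period ~2 index units because the molecule sits at the
box *centre*; the centring phase ramp $(-1)^{h+k+l}$-like must be removed
**before** complex trilinear interpolation (and the box zero-padded 2×
in real space for good measure), otherwise interpolated values are
garbage. Amplitude-only interpolation (rotation search) is insensitive to
this, which is why a rotation search can work while a naive translation
search fails.

Degeneracies are inherent, not bugs: in P1 the translation is arbitrary;
in P2₁ the solution is defined modulo the symmetry-related orientation,
origin shifts of ½ along a and c, and any shift along the polar b axis.
The test suite scores recovered placements modulo exactly these
equivalences.

## 4. The DM / AMB / PHSCMB loop

### Prime-and-switch density modification

Per extension shell and inner cycle: synthesize the FOM-weighted map from
the current phases and observed amplitudes; apply, in order, NCS
averaging, histogram matching, solvent flattening; back-transform; then
**switch** — every phase is replaced by the modified map's phase. The
starting (model-derived) phases are never recombined inside DM; they only
*prime* the first synthesis. This is the bias-removal contract: a wrong
but self-consistent starting model cannot survive repeated switching,
because nothing ever pulls phases back toward it.

The real-space operators:

* **Solvent flattening** (Wang-style): the local mean of $|\rho|$ over a
  sphere (default radius 8 Å) is thresholded at the solvent-fraction
  quantile; solvent voxels are set to the solvent mean. The mask keys on
  local density *structure*, which is why it works on zero-mean maps:
  protein fluctuates, solvent is flat.
* **Histogram matching**: a rank-preserving quantile map forces the
  protein-region density distribution onto a reference histogram computed
  from a model map at the working resolution (64 bins). The reference
  model should match the composition and copy number of the target —
  a histogram from half the scattering matter imposes systematically
  wrong peak heights.
* **NCS averaging**: within each operator's spherical mask, density is
  replaced by the mean of itself and its image under the operator. For a
  proper two-fold the operator is an involution mapping the whole dimer
  onto itself, so both copies are covered by the forward and inverse
  operators. Interpolation here is tricubic (Catmull–Rom), a deliberate
  exception to the package's trilinear default: measured on synthetic
  maps, trilinear smoothing alone cost more phase accuracy (~1.5°) than
  the $\sqrt2$ noise averaging gained, inverting the operator's purpose.

New FOMs after each inner cycle come from the per-shell σA between
observed and modified-map amplitudes (below). Reflections newly entering
as the schedule extends take the modified-map phase and the shell FOM.
The schedule default is four shells equally spaced in $1/d^3$ between the
EM and X-ray resolutions; inner cycles stop when the mean phase change
drops below 1° (default 5 cycles per shell).

### Automatic model building

Peaks above mean + 1.5σ (26-neighbour maxima, quadratic sub-voxel
refinement) are greedily chained at 3.8 ± 0.7 Å — the Cα–Cα distance —
growing from the highest unused peak at both chain ends, height-first,
with chains shorter than four discarded. No side chains are built: at the
loop's working resolutions a pseudo-Cα model is enough of a phase source,
and side-chain building would add parameters the synthetic scenario
cannot validate. The traced model is converted to phases by direct
structure-factor summation with dummy scatterers at uniform B = 30 Å²,
with σA-derived FOMs against the observed amplitudes.

### σA and phase combination

E-values are amplitudes normalized to unit mean square per resolution
shell. σA per shell uses the acentric intensity-correlation identity

$$\operatorname{corr}(E_o^2, E_c^2) = \sigma_A^4,$$

clipped to $[0,1]$ before the fourth root. This moment-family estimator
is chosen over the raw amplitude product $\langle E_oE_c\rangle$ because
the latter tends to $\Gamma(3/2)^2 \approx 0.785$, not 0, for an
*uninformative* model and therefore cannot distinguish a useless phase
source from a perfect one. The per-reflection FOM is the Bessel ratio
$m = I_1(X)/I_0(X)$, $X = 2\sigma_A E_oE_c/(1-\sigma_A^2)$ (centric
reflections, where flagged, use $\tanh(X/2)$; in P1 there are none).
Above $X = 2000$ the asymptotic $1 - 1/(2X) - 1/(8X^2)$ replaces
`besselI` to avoid overflow.

Combination treats each source as a von-Mises phase distribution with
concentration $X_i = m^{-1}(\text{fom}_i)$ (numeric Bessel-ratio
inversion, Newton-polished to ~1e−8): the two unit-ish vectors
$X_i e^{i\varphi_i}$ are added, the combined phase is the resultant's
direction and the combined FOM the Bessel ratio of its length. Full
Hendrickson–Lattman machinery is unnecessary because both sources here
are unimodal. The pipeline only ever combines (DM phases, built-model
phases) — never model with model — which encodes the bias-removal intent
at the architectural level.

A deliberate behaviour: the combination may transiently *raise* the
phase error when the built model is poor, as it does in cycle 1; the loop
treats this like the heating step of simulated annealing and only aborts
if the DM stage itself regresses (by > 0.002 mean FOM) in two consecutive
cycles.

## 5. The synthetic scenario

`standard_scenario()` builds everything the pipeline needs with no
external data, at the conditions the method targets:

* a compact self-avoiding pseudo-Cα walk (3.8 Å steps, bounded turning,
  ≥ 2.4 Å self-clearance) of 60 residues per copy, one side-chain
  pseudo-atom per residue, duplicated by an exact proper two-fold NCS
  operator with in-plane translation (closure requires the translation
  perpendicular to the axis); returned operators are exact by
  construction. Side-chain pseudo-atoms carry markedly higher B
  (45–65 Å² vs 15–30 Å²): side chains are more mobile than main chain in
  real structures, and a generator without that asymmetry produces maps
  whose brightest peaks are side chains — the Cα tracer then starves.
* a cubic P1 cell of 60 Å (cell comfortably twice the copy diameter),
  observed amplitudes to 2.3 Å with 5% multiplicative Gaussian noise,
  and ground-truth phases kept aside for metrics only;
* an "EM" map: the true density truncated at 4.87 Å, blurred by
  B = 100 Å², each coefficient phase-perturbed by wrapped-Gaussian noise
  of σ = 45°, generated at the true position (the separate P2₁ fixture
  exercises the search path). Starting phases from this map carry a
  ~35° weighted mean phase error — hard enough to be nontrivial,
  solvable by design;
* a reference histogram source from an *independent* fold of the same
  composition and copy number (never the truth model);
* solvent fraction 0.5 as the DM setting, four extension shells, five
  inner cycles, four outer cycles.

What the scenario does **not** emulate, and what passing tests therefore
do not show about real data: amplitude noise is i.i.d. multiplicative
(no resolution-dependent falloff mismatch, no missing wedges or
incompleteness), the EM degradation is an idealized phase-noise + blur
model (no CTF, no anisotropic resolution, no magnification anisotropy),
the NCS operators are exact rather than refined, solvent is true vacuum
rather than disordered water, and pseudo-atom scattering is a
single-Gaussian caricature (adequate beyond ~2 Å; the direct-summation
vs sampled-density agreement is ~2% RMS at d ≥ 2.5 Å). Real cases will
sit between this scenario and failure in proportion to how far those
idealizations are violated — most sensitively the accuracy of the NCS
operators and of the MR placement.

## 6. Numerical choices and degenerate inputs

* Grid spacing follows the d_min/3 rule (not Shannon's d_min/2) to leave
  aliasing headroom for the real-space operators; sizes are rounded up to
  2·3·5-smooth FFT lengths.
* Single-Gaussian form factors per element (C, N, O, S, generic X). The
  oracle identity — direct summation equals the FFT of the sampled
  Gaussian density — holds to ~1e−5 relative on fine grids.
* Shell assignment is by quantiles of $1/d^3$ (equal counts); σA shells
  with fewer than 8 reflections merge into a neighbour with a warning.
* Ties and degeneracies: ranked searches break ties lexicographically;
  an all-equal translation score list yields Z = 0 flagged degenerate;
  a flat map yields a degenerate solvent mask (flagged) and an empty
  peak list; phase combination at exact cancellation returns FOM 0 and
  keeps the first source's phase.
* `ca_recovery` scores built atoms against symmetry-expanded true
  main-chain positions under minimum-image distances; an optional
  FFT cross-correlation origin search handles convention-shifted models
  (off by default — models built from package-phased maps inherit the
  reference origin).
* Determinism: every stochastic step takes an explicit seed;
  `run_full()` outputs are byte-identical across reruns at a fixed seed.

## 7. Problem sizes

The shipped configurations are sized for a single CPU: the standard
scenario has ~37k unique reflections on an 80³ grid (a full 4-cycle run
in about a minute), the unit-test scenario ~7k reflections on a 45³ grid,
and the P2₁ MR case ~1.2k reflections in the search window. All scale
linearly in grid volume (FFT-dominated) and were chosen as the smallest
sizes at which the two-fold-NCS phase-extension problem is genuinely
nontrivial — a 4.9 → 2.3 Å extension with a solvent fraction setting of
0.5 and no additional symmetry.

## 8. Known limitations

* Exhaustive MR is O(grid × reflections); it is meant for desk-scale
  cells, not ribosomes.
* The σA FOMs of DM phases are optimistic: the "model" amplitudes being
  scored derive from maps synthesized from the observed amplitudes
  themselves, and without free-reflection cross-validation (out of
  scope) the correlation is inflated. The loop is robust to this — the
  switch step, not the FOM, carries the bias removal — but reported
  mean-FOM values should not be read as calibrated phase-error
  estimates; the wMPE columns against truth are the honest audit.
* NCS masks are spheres; touching or interpenetrating copies blur the
  mask boundary. For proper two-folds this is benign (the operator maps
  the dimer onto itself); improper NCS is untested territory.
* Space-group machinery is deliberately minimal: operators are supplied
  explicitly, centric flagging exists but no centric-specific phase
  restriction is imposed beyond the tanh FOM, and origin conventions of
  polar groups are handled in the metrics, not the algebra.
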