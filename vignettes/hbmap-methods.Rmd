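---
title: "Methods: frequency maps, order parameters and spectral decomposition in hbmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: frequency maps, order parameters and spectral decomposition in hbmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`hbmap` analyses hydrogen bonding in DMSO/water mixtures along two routes
that meet in the middle: an electrostatic frequency map that turns atomic
configurations into O–D stretch frequency distributions, and a
multi-Gaussian decomposition that turns measured (or synthetic) FTIR
spectra into component centers, widths and areas. This vignette documents
the models, the tunable parameters, the synthetic generators used for
testing, and the numerical choices — including where the design was
genuinely open and what we picked.

## The spectroscopic model

### Why HDO

In dilute isotopic mixtures the O–D oscillator of HDO is vibrationally
decoupled from its surroundings, so its frequency reports on the *local*
hydrogen-bond environment. Neat H₂O or D₂O stretches are delocalized over
many molecules and carry no such local information. The package therefore
computes frequencies only for waters carrying exactly one `DW` site; the
generators create such probes by relabelling (`substitute_hdo()`,
`wt_d2o` in the mixture builder). Because experimental D₂O equilibrates to
HDO in excess H₂O, the mixture builder never places a D₂O molecule: each
molecule counted as D₂O in the mass balance is realised as a water with a
single D label. The label is purely isotopic — charges and geometry are
untouched, so the electrostatics are those of ordinary water.

### The map

The instantaneous frequency is affine in the electrostatic potential at
the probe's three atom sites:

$$\omega = \omega_0 + c_D\,\varphi(\mathbf{r}_D) + c_O\,\varphi(\mathbf{r}_O)
  + c_H\,\varphi(\mathbf{r}_H), \qquad
  \varphi(\mathbf{r}) = \sum_j \frac{q_j}{|\mathbf{r}-\mathbf{r}_j|}$$

with charges in e, distances in Bohr (1 Bohr = 0.529177 Å, fixed in one
constant), and the sum running over atoms of all *other* molecules within
a spherical cutoff under the minimum-image convention. An isolated probe
sits exactly at $\omega_0$; scaling every environment charge by α scales
the shift by α (the map is affine by construction, and a property test
enforces it).

Assumptions worth stating plainly:

* **Linearity.** No quadratic potential or electric-field terms. This is
  the simplest member of the map family and the one whose behaviour the
  tests pin down (affinity, translation invariance, oracle equivalence).
* **Only the probe molecule is excluded** from the sum — not its H-bond
  partners.
* **Abrupt truncation, no Ewald.** Long-range corrections matter little
  for potential *differences* across a 1 Å molecule, which is what the
  three-site form responds to.

### Truncation is molecule-wise

The cutoff (default **7.8 Å**) is applied per molecule: a molecule
contributes all of its atoms or none, decided by the minimum-image
distance of its leading heavy atom (O for water, S for DMSO). An atom-wise
cutoff would split neutral molecules at the boundary, and the resulting
bare monopoles at ~8 Å contribute potentials of order 0.04 a.u. — larger
than the genuine H-bond signal, swamping the distributions with truncation
noise. With molecule-wise truncation every included contribution is
charge-neutral and decays like a dipole. The atom-wise variant remains
available (`truncation = "atom"`) and both are verified against a
brute-force periodic-image oracle to 1e-12.

The cutoff must not exceed half the smallest box edge (minimum-image
validity); `electrostatic_potential()` errors otherwise. The pipeline and
CLI reduce the map cutoff to that bound for small demonstration boxes and
say so.

### Map coefficients are data, and the bundled set is synthetic

Coefficients live in a keyed CSV (`omega0_cm1`, `coeff_D_cm1_per_au`,
`coeff_O_cm1_per_au`, `coeff_H_cm1_per_au`, `cutoff_angstrom`), loaded by
`read_map_coefficients()`. The bundled file `map_od_synthetic.csv`
($\omega_0 = 2650$, $c_D = 2300$, $c_O = -2000$, $c_H = -300$ cm⁻¹ per
a.u.) is **synthetic**: representative values chosen to follow the
literature's three-site potential-map form and its physical sign
convention — a short, strong H-bond to the D atom lowers $\varphi_D$ and
red-shifts the stretch — not numbers transcribed from a published
parameterization. Every test that touches the map checks behaviour
(ordering on a dimer scan, affinity, oracle agreement, relative widths of
fixture distributions), never absolute frequencies. Users with a
calibrated map drop in their own CSV.

## Structural statistics

### Tetrahedral order parameter

$$q = 1 - \tfrac{3}{8}\sum_{j<k}\left(\cos\psi_{jk} + \tfrac13\right)^2$$

over the four nearest neighbour centres (minimum image), where
$\psi_{jk}$ are the six angles subtended at the central molecule. The
rescaling makes ⟨q⟩ = 0 for uncorrelated random directions, q = 1 for a
perfect tetrahedron, and −3 when all four neighbours coincide in
direction (both extremes are checked against hand evaluations: four 90°
pairs and two 180° pairs give exactly ½ for square-planar). Neighbour
candidates are water oxygens by default; `neighbors = "heavy_atoms"` also
admits DMSO S/O/C sites, since the literature is not explicit about which
convention underlies published shell-resolved histograms — both are
provided.

### Shells, P(ω, r) and distributions

A water is **first-shell** when the minimum-image distance from its D (or,
undeuterated, its first H) to any DMSO sulfur is ≤ the cutoff, default
**3.6 Å** — the first minimum of the S–H(water) RDF;
`rdf_first_minimum()` can re-derive it from data with quadratic
refinement of the minimum. Ties in the nearest-sulfur search resolve to
the lowest molecule id (deterministic, measure-zero).

`omega_r_histogram()` implements the 2D population literally as *average
counts per frame per shell of thickness dr*:
$P_{ij} = n_{ij}/(N_\text{frames}\,\Delta r)$, so summing
$P\,\Delta r$ over r recovers the per-frame frequency histogram exactly —
an invariant asserted to 1e-9 on every pipeline run rather than assumed.

RDFs use the standard normalization
$g(r) = \langle n(r, r{+}dr)\rangle / (\rho_b\,4\pi r^2 dr\,N_a)$,
excluding intramolecular pairs, and are checked against a brute-force
double-loop pair count. The orientational distribution collects
$\cos\theta$ between every covalent O–H(D) bond and the O···O axis for
oxygen pairs within 3.5 Å: in ideal ice exactly one bond in four lies on
the axis (a delta at $\cos\theta = 1$, the rest near the tetrahedral
−1/3); randomly oriented waters are flat in $\cos\theta$.

Neighbour searches are chunked vectorised all-pairs computations rather
than cell lists: at the package's intended scale (10²–10³ molecules per
frame) the full minimum-image distance matrix, evaluated in fixed-size
chunks to bound memory, is simpler and leaves no room for a second code
path to disagree with the first.

## Synthetic generators: what they emulate, and what they do not

The generators replace MD trajectories for testing. They reproduce the
**structural limits** the analysis is tested against, not thermodynamics:

* `build_ice_lattice()` places oxygens on the lonsdaleite (hexagonal
  diamond) sublattice of ice Ih in an orthorhombic supercell. At the ideal
  lattice ratio ($a = d\sqrt{8/3}$, $c = 8d/3$ for O···O distance $d$,
  default 2.75 Å) every oxygen's four neighbours are exactly tetrahedral,
  so q = 1 to machine precision — the crystalline reference. Protons obey
  the Bernal–Fowler rules (two covalent H per O, one H per O···O link) by
  construction: the 4-regular O–O bond graph is given an Eulerian
  orientation (out-degree = in-degree = 2), deterministically for
  `ordered` or with seeded shuffling for `bernal_fowler_random`. The
  shuffled scheme samples valid ice states, not the uniform distribution
  over them — proton-disorder statistics are out of scope; tests need
  geometry.
* `build_random_gas()` is the opposite limit: uniform single-site
  particles, ⟨q⟩ → 0, g(r) → 1.
* `build_mixture_box()` fixes molecule counts by a closed-form mass
  balance (H₂O 18.015, D₂O 20.028, DMSO 78.13 g/mol; achieved fractions
  match requested ones to one-molecule granularity), sets a cubic box from
  the target density, and packs molecules by rejection sampling with a
  1.5 Å hard intermolecular floor (capped at 10⁵ attempts; failure
  suggests lowering the density). Densities default to 1.0 g/cm³ and
  1.1 g/cm³ at ≥25 wt% DMSO — plausible values for cold aqueous and
  concentrated mixtures; the choice only scales the box. Box sizes and
  molecule counts are otherwise arbitrary and user-set.
* `perturb_frame()` adds i.i.d. Gaussian displacements (per atom, or per
  molecule with `rigid = TRUE`) — thermal disorder at its crudest.
* `synth_spectrum()` evaluates the exact sum-of-Gaussians + baseline +
  white noise model the fitter assumes.

Two honest caveats follow. First, random packing has no H-bond network:
its structures are what an infinite-temperature liquid would look like
with excluded volume, so quantitative RDF shapes, shell occupancies and
absolute frequency moments do not transfer to real water. Second,
Gaussian perturbation of a lattice has no excluded volume: it compresses
contacts as often as it stretches them, and since the map diverges like
1/r at short range this biases mean frequencies red. For that reason the
package's disordered reference for distribution comparisons is the
*packed* liquid-like box (broken, on-average-weaker H-bonds → broader,
blue-shifted distribution, as in the ice/liquid phenomenology), while
perturbed lattices serve where only monotone broadening is asserted.
Passing tests therefore demonstrate correct implementation of the
definitions and the right qualitative orderings — not agreement with any
simulated or measured ensemble.

## Spectral decomposition

The O–D band is fit in a window (default **2300–2700 cm⁻¹**) as

$$A(\nu) = \text{baseline}(\nu) + \sum_k A_k
  \exp\!\left(-4\ln 2\,\frac{(\nu-\nu_k)^2}{w_k^2}\right)$$

by bounded Levenberg–Marquardt least squares (`minpack.lm::nls.lm`).
Choices, and why:

* **3 or 4 components.** Ice-phase spectra need a dominant peak plus two
  phonon sidebands; DMSO mixtures add one broad (~120 cm⁻¹) component
  from disordered first-shell water. Fitting 4 components to a
  3-component spectrum drives the extra amplitude toward zero (verified
  on fixtures).
* **Bounds.** Amplitudes ≥ 0, FWHM ∈ [2, 400] cm⁻¹, centers inside the
  window — physical sanity that also prevents component swapping.
* **Initialization.** Dominant center at the window's global maximum,
  sidebands at ∓/±60 cm⁻¹, broad component started at 2470 cm⁻¹ with
  FWHM 120. Deterministic; up to 5 jittered restarts under a fixed seed
  if an attempt fails. The returned fit never has a worse residual than
  its initialization (asserted). Iteration-capped terminations with tiny
  step tolerances are accepted when the solution improved — the stall
  mode of a redundant near-zero component — while genuinely failed fits
  raise a condition carrying the best-so-far parameters.
* **Baseline** linear by default (constant/quadratic available); an
  optional 2330–2370 cm⁻¹ exclusion band (off by default) removes
  residual CO₂ absorption from the fit window.
* **Areas** use the closed form $A\,w\sqrt{\pi/(4\ln 2)}$, checked
  against quadrature at 1e-6 relative.

`temperature_series()` fits each spectrum warm-started from its
neighbour's solution, which in practice keeps component identities stable
across temperature; components are then labelled by center order.
Unsorted series are auto-sorted with a warning rather than rejected.
`transition_sharpness()` scores a melting-type transition as the largest
absolute first difference of a tracked parameter divided by the median
absolute difference elsewhere: a step scores large, a uniform ramp scores
1, a flat series is flagged undefined rather than scored.

## Reproducibility and problem sizes

Every stochastic operation takes an explicit seed and is bit-reproducible
under it; `run_pipeline()` writes a manifest with the seed and an MD5
config hash, and rerunning a config reproduces deterministic outputs
exactly. The shipped tests and the acceptance script run at desk scale by
choice: 64–288-water lattices, 140-molecule mixture boxes with 3–4
perturbed frames, a 4096-particle gas for the ⟨q⟩ = 0 limit, 100 random
frames for the potential oracle, and 50 synthetic spectra for the
recovery study. These sizes resolve every qualitative contrast the
package asserts while keeping a full run in well under a minute; nothing
in the implementation caps larger frames beyond memory and patience.

## Known limitations

* No dynamics: no spectral diffusion, lineshape theory or 2D IR; the map
  yields instantaneous distributions only.
* No Ewald summation; truncation is abrupt at the (molecule-wise) cutoff.
* The bundled map is representative, not calibrated; absolute frequencies
  should not be compared against experiment without a fitted coefficient
  set.
* Gaussian components only — no Voigt/Lorentzian profiles, no
  instrument-response deconvolution, no vapor-line removal.
* Orthorhombic boxes only; triclinic inputs are rejected at the reader.
* The packing generator does not relax structures; it is a sampler of
  excluded-volume configurations, not a substitute for equilibration.
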