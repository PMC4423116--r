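---
title: "Membrane partitioning, channel occupancy and interface mapping of cystine-knot toxins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Membrane partitioning, channel occupancy and interface mapping of cystine-knot toxins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ToxinScan)
```

# The scientific problem

Inhibitor-cystine-knot (ICK) tarantula toxins act on ion channels through
two coupled equilibria. Voltage-sensor toxins such as GxTx-1E partition
into the lipid bilayer and from there bind the S3b--S4 paddle of a
voltage-sensing domain; psalmotoxin (PcTx1) binds the extracellular thumb
helix of ASIC1a. Comparing these mechanisms quantitatively requires three
kinds of analysis, which this package implements end to end:

1. **Membrane interaction** from tryptophan fluorescence: mole-fraction
   partition coefficients fit to lipid titrations, Stern--Volmer quenching
   constants, emission blue shifts, and depth-dependent quenching by
   brominated lipids.
2. **Channel occupancy** from two-electrode voltage-clamp currents:
   fraction unbound at weak depolarizations, apparent $K_d$ under a
   four-independent-site model, and alanine-scan perturbation energies
   ($\Delta\Delta G$).
3. **Binding-surface geometry**: rigid superposition of toxin structures,
   solvent-accessible surface area (SASA) and per-residue interface burial
   ($\Delta$SASA), hydrophobic-patch clustering, and register-shifted
   grafting of a toxin--helix complex onto a target helix with steric
   screening.

A synthetic-data module generates spectra, titrations, inhibition
experiments and toy helix--toxin complexes with exactly the statistical and
geometric structure the analyses assume, so every stage is testable
without instrument data or structure downloads.

# Models and assumptions

## Mole-fraction partitioning

The fluorescence response to partitioning is

$$\frac{F}{F_0}(L) \;=\; 1 + \left(\frac{F}{F_0}^{max}-1\right)
\frac{K_x [L]}{[W] + K_x [L]},$$

where $[L]$ is the *available* lipid concentration in molar -- a fixed
fraction (default 0.60) of the total, reflecting the outer-leaflet lipid a
peptide added outside the vesicles can reach -- and $[W] = 55.3$ M is the
molarity of water. $K_x$ is dimensionless (mole-fraction convention). Both
constants are arguments everywhere they occur, with these defaults.

The same functional form describes acrylamide *dequenching*: adding
vesicles to a pre-quenched toxin solution shields tryptophans and raises
the maximal emission intensity, and fitting that rise against available
lipid yields the analogous constant $K_{dx}$. The two response kinds are
distinguished by the `responseKind` of a `TitrationSeries`
(`intensity_at_320nm` for $K_x$, `max_intensity` for $K_{dx}$), and the
fit records which constant it estimated. Aqueous quenching itself follows
the Stern--Volmer relation $F_0/F = 1 + K_{sv}[Q]$.

Assumptions worth keeping in mind: partitioning is a two-state
water/membrane equilibrium with no saturation of the membrane (dilute
peptide), responses are normalized to the zero-lipid point, and the
titration loss is unweighted because no per-point error model is
available for typical spectra.

## Four-independent-site occupancy

Steady-state currents are compared before ($I_0$) and after ($I$) toxin at
depolarizations too weak to open toxin-bound channels, so $F_u = I/I_0$
estimates the fraction of channels with *no* toxin bound. With four
independent binding sites per channel (one per voltage sensor) and single
occupancy sufficient to prevent opening,

$$F_u = \left(\frac{K_d}{K_d + [T]}\right)^{4}
\qquad\Longleftrightarrow\qquad
K_d = \left(\frac{1}{1-F_u^{1/4}}-1\right)[T].$$

The inversion is exact algebra, and the package's forward and inverse
forms round-trip to $10^{-10}$ relative over $K_d \in [1, 10^6]$ nM. The
site count is a parameter (`nSites`), not a constant, so single-site
ligands are handled by the same code.

Perturbation energies use
$\Delta\Delta G = RT\,\ln(K_d^{mut}/K_d^{wt})$ with
$R = 1.9872\times10^{-3}$ kcal mol$^{-1}$ K$^{-1}$. The default
temperature is **298.15 K**: recordings of this kind are made at room
temperature (nominally ~22 °C), but 298.15 K is the convention under
which published alanine-scan tables reproduce exactly from their printed
$K_d$ columns, which the test suite verifies against the packaged
28-mutant table. The temperature is configurable.

## Geometry

* **Superposition** is the Kabsch algorithm: SVD of the cross-covariance
  of centred coordinates, constrained to a proper rotation. Degenerate
  configurations that would favour a reflection are resolved to the best
  proper rotation with a warning.
* **SASA** is Shrake--Rupley sphere-point quadrature with a 1.4 Å probe.
* **$\Delta$SASA** is SASA of a component extracted alone minus SASA of
  the same residues in the complex, computed with identical probe and
  quadrature; the per-residue values rank the binding footprint.
* **Register grafting** places a toxin--helix complex on a target helix by
  backbone superposition of the matched helix ranges, then steps the
  placement by whole-residue register offsets. Each elementary step is a
  screw motion about the target helix axis: a rotation of 100° and a
  translation of one helical rise. The axis is a least-squares line
  through sliding one-turn-window centroids of the target C$\alpha$ trace.

# Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `availableFraction` | 0.60 | -- | outer-leaflet lipid accessible to external peptide |
| `waterMolarity` | 55.3 | M | molarity of pure water in the mole-fraction convention |
| `nSites` | 4 | -- | one toxin site per voltage-sensor paddle |
| `temperatureK` | 298.15 | K | reproduces published $\Delta\Delta G$ from $K_d$ ratios |
| `plateauTolerance` | 0.10 | relative | max adjacent-voltage change in $I/I_0$ accepted as plateau |
| `voltageWindow` | (-20, 10) | mV | weak depolarizations that do not open toxin-bound channels |
| `probe` | 1.4 | Å | water-sized SASA probe |
| `nPoints` | 960 | -- | quadrature points per atom; single-sphere error well under 1% |
| `twistDeg`, `riseA` | 100, 1.5 | °, Å | canonical $\alpha$-helix geometry per residue |
| `clashCutoff` | 2.5 | Å | heavy-atom distance counted as a steric clash |
| `interfaceThreshold` | 12 | Å | residue-level interface masking distance |

On the register step: a one-residue shift on an ideal $\alpha$-helix is a
100° rotation plus a **1.5 Å** rise. Descriptions of register frames
sometimes quote 5.4 Å for the translation, but 5.4 Å is the pitch of a
full turn (3.6 residues), not of a single residue step; because the two
conventions are genuinely in circulation, `riseA` is an explicit
parameter rather than a hard-wired constant, with 1.5 Å as the
geometrically consistent default.

# The synthetic-data module

Generators exist for every data type the analyses consume, and their
defaults are the study conditions under which the estimators are
validated:

* **Spectra**: asymmetric-Gaussian line shape on a 300--450 nm grid. Real
  tryptophan emission has no agreed analytic shape; what matters for the
  pipeline is a well-defined peak, a controllable width/skew, and
  non-negative intensities, which this shape provides while keeping the
  argmax exactly at `lambdaMax`. Blue shifts upon partitioning are
  modelled by linearly interpolating the peak between aqueous and
  membrane-bound positions with the bound fraction.
* **Titrations**: the partition and Stern--Volmer equations evaluated
  exactly, times multiplicative Gaussian noise (a shot-noise
  approximation that preserves positivity at small SD). The default lipid
  grid (0, 0.01, 0.02, 0.05, 0.1, 0.2, 0.5, 1.0 mM total) spans the
  half-saturation point of a $K \sim 5\times10^6$ toxin and reaches the
  1 mM plateau used experimentally; the default acrylamide grid is
  0--0.3 M. Protocols in the field quote either 0.2 or 0.3 M acrylamide
  for dequenching, so the quencher concentration is always an explicit
  argument.
* **Inhibition experiments**: paired $I_0$/$I$ records per (cell,
  concentration, voltage) from the forward occupancy model with
  multiplicative current noise.
* **Toy complexes**: an ideal helix C$\alpha$ trace plus a rigid carbon
  shell at a known offset -- deterministic (Fibonacci-sphere) geometry,
  no RNG.

Every generator is reproducible given `seed`, and changing the seed
changes only the noise realization, never the noiseless mean.

What the generators deliberately do **not** emulate: vesicle scattering
backgrounds (inputs are assumed scattering-corrected), instrument drift
and photobleaching, leak-subtraction artefacts in the recordings, toxin
association kinetics (only steady-state endpoints are modelled), and real
side-chain packing in structures. Passing tests therefore demonstrate
estimator correctness and calibration under the stated noise model, not
robustness to every artefact of real instruments.

# Numerical choices

* Partition fits run Levenberg--Marquardt on a $\log_{10} K$
  parameterization (the constant spans decades), multi-started at 0.1x,
  1x and 10x an initial $K$ taken from the lipid concentration at
  half-maximal response; the standard error of $K$ is recovered by the
  delta method. Titrations whose responses never leave 1 are flagged
  degenerate and report only a lower bound on $K$ rather than a fitted
  value.
* The Stern--Volmer intercept is fixed at 1 by default because the
  quenching relation forces it; a free-intercept mode exists as a
  diagnostic.
* Peak location uses the grid argmax (ties broken toward the lower
  wavelength, an arbitrary documented convention) refined by a parabola
  through the three surrounding points, resolving ~2 nm shifts on a 1 nm
  grid; boundary peaks are reported at the boundary.
* The plateau check keeps the longest run of adjacent voltages whose
  $I/I_0$ changes by less than the tolerance; with several voltages
  measured, at least two must agree or a plateau error is raised. Ratios
  above 1 + tolerance are flagged, never clipped.
* SASA quadrature uses a deterministic Fibonacci lattice, so results are
  bit-for-bit reproducible; doubling the default 960 points moves
  totals by well under 1%. An atom exactly coinciding with a lower-index
  atom (position and radius) is treated as fully occluded by it, so
  duplicated atoms never double-count area. Van der Waals radii are a
  bundled element-wise (Bondi) table, configurable per structure;
  elements missing from the table fall back to carbon.
* Multi-model (NMR) PDB files yield the first model unless another is
  requested.
* SEM uses the $n-1$ denominator; $n=1$ reports SEM 0 with an explicit
  single-cell flag.
* The Boltzmann G--V summary fits a free amplitude so tails that do not
  fully saturate do not bias $V_{1/2}$; it is a phenotype summary, not a
  gating model.
* The hydrophobic patch is the contact-connected cluster (heavy-atom
  pairs within 4.5 Å) of the user-supplied hydrophobic residue set with
  the greatest summed SASA. Membership of "the hydrophobic surface" is a
  judgement call, so it is an input, not a built-in list.

# Design choices where the design was open

* Whether per-cell $K_d$ values should be averaged across concentrations
  or fit jointly is not settled; `runPipeline()`'s occupancy stage offers
  both (`aggregate: mean` inverts each measurement and averages,
  `aggregate: joint` fits one $K_d$ per cell across its concentrations).
* Core-residue selections for toxin--toxin RMSD are user-specified
  ranges; no default guess is shipped.
* The clash criterion (2.5 Å heavy-atom distance) and interface masking
  (12 Å) are conventions, exposed as parameters.

# Problem sizes used in validation

The test suite and the acceptance script validate estimator calibration
with 100 seeded replicates per scenario at 2% relative noise, occupancy
round-trips over a 25 x 21 grid of ($K_d$, $[T]$), SASA on single atoms
and ~40-atom toy complexes at 960 quadrature points against an
independent latitude--longitude grid oracle, superposition optimality
against 1000 random rotation perturbations, and grafting over the five
register frames -2..+2. These sizes were chosen so the full suite
finishes in well under a minute while leaving Monte-Carlo error far
below the tolerances being asserted.

# Known limitations

* No depth (parallax) estimation from brominated-lipid quenching: the
  profile is reported per label, qualitatively ranking burial depth.
* No kinetic modelling of toxin wash-in/wash-out; only steady-state
  endpoints are analysed.
* No structure relaxation, repacking or binding-energy estimation after
  grafting; the graft is rigid geometry plus clash screening.
* Quantitative reproduction of published hydrophobic-patch areas for
  real toxins requires the (unpublished) residue selections and real
  coordinate files, so it is not claimed; the machinery accepts any PDB
  input for users who have them.

# A short worked example

```{r example}
# membrane partitioning of a strong partitioner, 2% noise
ser <- simPartitionTitration(K = 4.6e6, fMax = 2.3,
                             noiseSd = 0.02, seed = 1)
fitPartition(ser)

# occupancy: fraction unbound -> apparent Kd -> perturbation energy
ex <- simInhibitionExperiment(224, toxinNM = 454, nCells = 3,
                              noiseSd = 0.03, seed = 2)
fu <- fractionUnbound(ex, plateauTolerance = 0.2)
aggregateKd(kdFourSite(fu$F_u, fu$toxin_nM))

# the packaged alanine-scan table
head(ddgValues(buildDdgTable(gxtxScanTable(), wtLabel = "GxTx-1E(Nle)")))
```
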