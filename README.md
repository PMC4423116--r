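# ToxinScan

Quantitative analysis of how inhibitor-cystine-knot (ICK) tarantula toxins
engage lipid membranes and ion-channel binding surfaces, for
electrophysiologists and structural biologists comparing
membrane-partitioning voltage-sensor toxins (e.g. GxTx-1E) with
aqueous-binding toxins (e.g. PcTx1 on ASIC1a).

The package implements three linked analyses:

**Membrane interaction from Trp fluorescence.** Mole-fraction partition
coefficients are fit to F/F0 lipid titrations with

    F/F0(L) = 1 + (F/F0max − 1) · Kx[L] / ([W] + Kx[L])

where [L] is the available lipid concentration (default 60% of total) in
molar and [W] = 55.3 M is the molarity of water. The same form fit to
acrylamide-dequenching maxima yields K_dx; aqueous quenching follows the
Stern–Volmer relation F0/F = 1 + K_sv[Q]. Emission blue shifts and
depth-dependent quenching by brominated lipids complete the membrane
picture.

**Channel occupancy.** Steady-state current ratios I/I0 at weak
depolarizations (−20 to +10 mV), where toxin-bound channels do not open,
give the fraction unbound F_u, inverted under a four-independent-site
model:

    Fu = (Kd / (Kd + [T]))^4   ⇔   Kd = (1/(1 − Fu^(1/4)) − 1) · [T]

Per-cell K_d values aggregate to mean ± SEM, and alanine-scan
perturbation energies follow ΔΔG = RT·ln(Kd_mut/Kd_wt) at 298.15 K. A
published 28-mutant affinity table ships with the package and reproduces
from its K_d column.

**Binding-surface geometry.** Kabsch superposition and RMSD,
Shrake–Rupley SASA (1.4 Å probe, deterministic 960-point quadrature),
per-residue interface burial (ΔSASA), hydrophobic-patch clustering, and
register-shifted grafting of a toxin–helix complex onto a target helix
(100°/1.5 Å screw steps about the helix axis) with steric clash
screening.

A seeded synthetic-data module (`simEmissionSpectrum`,
`simPartitionTitration`, `simQuenchTitration`,
`simInhibitionExperiment`, `simToyComplex`) generates inputs with
exactly the structure the analyses assume, so the whole pipeline is
testable without instrument data.

## Worked example

```r
library(ToxinScan)

# partition fit on a 2%-noise synthetic titration
ser <- simPartitionTitration(K = 4.6e6, fMax = 2.3, noiseSd = 0.02, seed = 1)
fitPartition(ser)
#> PartitionFit: K_x = 4.54e+06 +/- 3.7e+05, F/F0max = 2.32 +/- 0.022 (n = 8)

fitSternVolmer(simQuenchTitration(37.7, noiseSd = 0.02, seed = 1))
#> SternVolmerFit: K_sv = 37.8 +/- 0.26 1/M (intercept fixed at 1)

# occupancy: currents -> fraction unbound -> apparent Kd
ex <- simInhibitionExperiment(224, toxinNM = 454, nCells = 3,
                              noiseSd = 0.03, seed = 2)
fu <- fractionUnbound(ex, plateauTolerance = 0.2)
aggregateKd(kdFourSite(fu$F_u, fu$toxin_nM))
#> KdEstimate '': 225 +/- 1.58 nM (n = 3 cells)

# alanine-scan perturbation energies from the packaged table
head(ddgValues(buildDdgTable(gxtxScanTable(), wtLabel = "GxTx-1E(Nle)")), 4)
#>          toxin kd_nM kd_sem_nM     ratio ddg_kcal_mol
#> 1 GxTx-1E(Nle)   224        25 1.0000000           NA
#> 2          E1A   414        38 1.8482143    0.3639153
#> 3          G2A   297        50 1.3258929    0.1671314
#> 4          E3A   125        62 0.5580357   -0.3456149

# interface burial on a toy helix-toxin complex
toy <- simToyComplex(helixLength = 8, toxinAtomCount = 12,
                     placementOffset = c(7, 0, 0))
deltaSasa(toy, "B")
#> DeltaSasaReport for chain(s) B: 3 residues, buried 80.3 A^2
```

The partition fit recovers the generating K within its standard error;
the K_d estimate recovers the generating 224 nM from noisy paired
currents; the ΔΔG column converts each mutant's affinity loss into
kcal/mol (E3A binds *tighter*, hence the negative sign); and the ΔSASA
report ranks toxin residues by the surface area they bury against the
helix.

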