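# actinovar

Residue-level variability analysis of actinoporins — the α-pore-forming
hemolytic toxins of sea anemones (e.g. the fragaceatoxin isoforms FraA–FraE
of *Actinia fragacea*).

Actinoporins evolve under strong purifying selection: the lipid-binding
module and the protomer–protomer (PPI) surfaces of the oligomeric pore are
conserved, while most sequence variability accumulates at non-interacting,
solvent-exposed positions, where substitutions tune protein stability
rather than function. **actinovar** packages the quantitative pipeline
behind that kind of analysis:

- **Conservation.** Every column of a multiple alignment is classified into
  the four Clustal categories — identical (`*`), strongly conserved (`:`),
  weakly conserved (`.`), non-conserved (space) — using the canonical
  ClustalX strong/weak residue groups, and mapped onto the residue
  numbering of a chosen reference sequence.
- **Solvent accessibility.** Per-atom accessible surface area by the
  Shrake–Rupley method (probe 1.4 Å, deterministic Fibonacci point
  lattice). Each residue's side-chain ASA is expressed as a ratio to the
  same side chain in an extended Gly-X-Gly random-coil reference, giving
  burial classes: low (< 20 %), partial (20–50 %), high (> 50 %).
- **Cross-tabulation.** Conservation × ASA class × interaction role
  (lipid / PPI / none) per reference residue; per-role identity fractions;
  the share of variability attributable to non-interacting residues.
- **Hemolysis kinetics.** From turbidity traces A₇₀₀(t): lag time (tangent
  at maximum descent intersected with the initial baseline) and maximum
  lysis velocity υ_max; the power law `lag = τ·c⁻ˣ` fitted across toxin
  concentrations; `Hemolysis (%) = (A₄₁₂ − A_fin)/(A_max − A_fin) × 100`;
  and the Hill fit `H(c) = 100·cⁿ/(HC₅₀ⁿ + cⁿ)` for HC₅₀.
- **Thermal stability.** Melting temperature T_M as the maximum of the
  first derivative of the percent change of the unfolding signal
  (e.g. ellipticity at 210 nm) versus temperature, after 10-point group
  reduction.
- **Sequence utilities.** cDNA translation, splicing of an Edman-sequenced
  N-terminal prefix onto a translated body, theoretical average mass,
  pairwise identity/difference counts, region-restricted difference
  counts, Kabsch superposition RMSD.
- **Synthetic data.** Seeded generators with known ground truth for every
  stage: sequence families under role-dependent purifying pressure, toy
  structures with controlled burial, sigmoidal lysis traces, Hill
  dose–response tables, and van 't Hoff two-state melting curves.

## Worked example

```r
library(actinovar)

## a 17-sequence family under role-dependent purifying pressure
fam  <- generateFamily(seed = 42)
cm   <- mapToReference(fam$alignment, "seq01")
prof <- buildRecords(cm, fam$exposure, fam$roles)

crosstab(prof, "all")
#> CrossTab (scope: all ), n = 175
#>           low partial high
#> identical  31       0    0
#> strong      5       0    0
#> weak        4       0    0
#> none       58       0   77

identityFractionByRole(prof, "ppi")   # 52.2 (% identical among PPI sites)
variabilityAttribution(prof)$pct      # 81  (% of varying sites non-interacting)

## hemolysis kinetics and dose-response
analyzeTrace(generateTrace(lag = 13, rate = 0.1, noiseSd = 0.004, seed = 42))
#> KineticsResult: lag = 13.48 s, vmax = 0.1098 1/s
fitHill(generateDoseResponse(hc50 = 1.6, hillN = 2, noiseSd = 2, seed = 42))
#> HillFit: HC50 = 1.557 nM, n = 2.06, plateau = 100%

## thermal melting
meltingTemperature(generateMelt(tm = 53, noiseSd = 0.36, seed = 42))
#> TmResult: Tm = 52.88 C (window 10)
```

The cross-tab shows the designed selective regime being recovered: the
identical residues concentrate in buried (low-ASA) positions while the
non-conserved mass sits at exposed non-interacting sites, and the kinetic
and thermal fits recover the generating parameters (lag 13 s, HC₅₀
1.6 nM, T_M 53 °C) within the noise.

`runPipeline(config)` orchestrates the same stages from files (aligned
FASTA, role TSV, PDB, trace/melt CSVs) and writes a `report.json` plus TSV
tables; see `?runPipeline`.

## Package layout

S4 result classes with validity checks and accessors (`ConservationMap`,
`ASATable`, `CrossTab`, `ResidueProfile`, `KineticsResult`, `PowerLawFit`,
`HillFit`, `TmResult`, `SuperpositionResult`, …); module sources under
`R/`; the methods vignette under `vignettes/` explains the models,
parameter choices and limitations.
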