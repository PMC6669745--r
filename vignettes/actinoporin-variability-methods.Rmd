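---
title: "Methods: residue variability, accessibility and biophysics of actinoporins"
author: "actinovar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: residue variability, accessibility and biophysics of actinoporins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actinovar)
```

# Scope and model

Actinoporins are a multigene family of sea-anemone α-pore-forming toxins
whose isoforms are highly similar in sequence and structure. The analysis
this package implements asks *where* the residual sequence variability
lives: it joins, per residue of a reference structure, (i) the
conservation category of the corresponding alignment column, (ii) the
solvent accessibility class of the side chain, and (iii) the residue's
interaction role (lipid-binding, protomer–protomer interface, or
non-interacting), and summarizes the joint distribution. Under purifying
selection one expects identical residues to concentrate in buried and
interface positions and non-conserved residues in exposed,
non-interacting positions; the package's statistics (4×3 cross-tables,
per-role identity fractions, variability attribution) quantify exactly
that. Companion modules implement the biophysical read-outs used to
characterize isoforms — hemolysis kinetics and thermal unfolding — and
the sequence bookkeeping needed to assemble mature toxin sequences.

# Conservation classification

Columns of a user-supplied multiple alignment (alignment construction is
out of scope; alignments are inputs) are classified with the four Clustal
symbols:

* **identical** (`*`): all rows carry the same residue, no gaps;
* **strong** (`:`): all residues fall within one of the canonical ClustalX
  strong groups (STA, NEQK, NHQK, NDEQ, QHRK, MILV, MILF, HY, FYW);
* **weak** (`.`): all residues within one weak group (CSA, ATV, SAG,
  STNK, STPA, SGND, SNDEQK, NDEQHK, NEQHRK, FVLIM, HFY);
* **none** (space): anything else.

Precedence is identical > strong > weak > none, mirroring the symbol
semantics. Any gap in a column forces **none**; this is the conservative
reading of typical Clustal symbol output, where a gapped column cannot be
called conserved. Categories are mapped onto a reference row by skipping
columns where the reference is gapped and numbering the rest 1..L.
`columnEntropy()` provides a simple per-column Shannon-entropy
variability score (bits over non-gap residues) as light-weight plumbing;
it is not a substitute for maximum-likelihood rate estimation, which is
deliberately out of scope.

Whether "weakly conserved" counts as conserved differs between published
summaries, so `conservedSummary()` reports both binnings (strict:
non-conserved = none; inclusive: non-conserved = weak + none) instead of
fixing one.

# Accessible surface area

`shrakeRupley()` samples each atom's expanded sphere (van der Waals
radius + probe) with a deterministic Fibonacci lattice and counts the
fraction of points not occluded by any neighbouring expanded sphere.
Defaults: probe 1.4 Å (water), 960 points/atom, heavy-atom radii C 1.70,
N 1.55, O 1.52, S 1.80 Å; hydrogens are ignored because crystal
structures rarely resolve them. For an isolated atom the method returns
the analytic sphere area exactly; on occluded configurations the
point-sampling error at 960 points is below 1 % against the closed-form
two-sphere cap solution (verified in the test suite). Because the lattice
is fixed in space, rotating a structure changes which points are
occluded: this orientation jitter shrinks with point density (the suite
checks < 0.5 % at 3840 points on a tightly packed helix) and halving it
further simply costs linearly more points.

Side-chain accessibility is reported as a **ratio**: the summed
side-chain ASA of a residue divided by the ASA of the same side chain in
a random-coil reference conformation, here an extended Gly-X-Gly
tripeptide built with the package's own ideal toy geometry and evaluated
with the same engine and parameters. Computing the reference internally
makes the ratio self-consistent by construction (the tripeptide scores
ratio 1 exactly) and keeps the package free of an external constant
table. Burial classes follow the common relative-accessibility
conventions: **low** < 20 %, **partial** 20–50 %, **high** > 50 % of the
coil reference; the thresholds are arguments (`thresholds = c(0.2,
0.5)`) and are echoed in all outputs because published residue counts of
this kind are sensitive to them. Glycine's "side chain" is taken as its
Cα so its ratio is defined.

`kabschSuperpose()` implements the standard SVD solution for the optimal
proper rotation (determinant +1 enforced via the sign correction) and
reports RMSD after transformation; collinear point sets are rejected as
degenerate.

# Cross-tabulation statistics

`buildRecords()` inner-joins conservation, accessibility and role on the
reference numbering. Roles are **always an input table** (TSV:
position, role ∈ {lipid, ppi, none}) — typically transcribed from a
published interface annotation — and never inferred, because interface
lists are figure- or literature-borne. Reference positions missing from
the structure are listed in the result and messaged, never silently
dropped; every reference position must carry a role.

From the records: `crosstab()` gives the 4×3 category × class counts
under a role filter (the filters partition: all = none + lipid + ppi,
cell-wise, and margins reproduce the per-module counts — both are tested
invariants); `identityFractionByRole()` gives 100 × identical/role-total;
`variabilityAttribution()` gives the percentage of non-identical
("varying") residues that are non-interacting. No enrichment test
statistics are computed: the published analyses this mirrors report raw
counts only.

# Hemolysis kinetics

Turbidity traces A₇₀₀(t) of an erythrocyte suspension drop sigmoidally
when lysis starts. `analyzeTrace()` smooths the trace with a 5-point
moving average, takes the derivative (also smoothed, which keeps read
noise from inflating the maximum-slope pick), and reports:

* **lag time** — the intersection of the tangent at maximum descent with
  the initial baseline level. "Onset of hemolysis" is not an
  operationalized quantity; the tangent construction is the standard,
  noise-robust choice for sigmoidal lysis curves. The baseline is the
  highest smoothed level, which also handles traces already descending at
  t = 0 (lag → 0).
* **υ_max** — the maximum descent rate normalized by the total turbidity
  drop (fraction lysed s⁻¹). Normalizing by amplitude rather than by the
  raw initial absorbance makes the result invariant to detector offset
  and gain, which a ratio to A₀ would not be; absolute published υ_max
  magnitudes depend on an unstated instrument scaling and are not
  reproduction targets here.
* Traces whose total drop is below 5 % of the initial level (argument
  `minDrop`) return a no-lysis result rather than an error.

`fitPowerLaw()` fits `lag = τ·c⁻ˣ` by ordinary least squares on
log(lag) vs log(c). The log–log linearization matches how a single
exponent is conventionally reported, is deterministic, and is exact on
noise-free power-law data; scale equivariance (τ → k^x τ under c → kc)
follows analytically and is tested. `hemolysisPercent()` is the literal
endpoint normalization against the no-toxin and water-lysed controls,
unclipped (noise may legitimately exceed [0, 100]; values outside
[−5, 105] are flagged). `fitHill()` fits
H(c) = plateau·cⁿ/(HC₅₀ⁿ + cⁿ) by Levenberg–Marquardt least squares
(plateau fixed at 100 % by default since responses are
control-normalized; optionally free), initialized at the concentration
nearest half-response with n = 1 for reproducible convergence; data that
never cross 50 % yield a flagged, warned extrapolated fit.

# Thermal melting

`meltingTemperature()` implements the derivative-maximum pipeline:
percent-change normalization between the pre- and post-transition
baseline levels (means of the first and last 10 % of points — no
baseline-slope fitting, so strongly sloped baselines are the user's
responsibility), 10-point group reduction (non-overlapping block means;
a trailing partial block is averaged as-is; block means preserve linear
series exactly), central-difference first derivative on the reduced
grid, and a 3-point parabolic refinement of the derivative maximum to
de-quantize the reduced grid. T_M is invariant to gain and offset of the
raw signal by construction. A curve whose maximum reduced-grid
derivative does not exceed twice the slope of a straight 0–100 % ramp
over the same range is reported as "no transition" — a pure baseline
drift normalizes to exactly that ramp.

# Synthetic data: what it emulates, and what not

The generators define the study conditions for all tests:

* `generateFamily()` — star phylogeny: one uniform-random ancestor
  (default length 175, matching a mature actinoporin), 17 descendants
  mutated independently per site with role-class probabilities
  ppi 0.03, lipid 0.05, none/buried 0.10, none/exposed 0.35 and role
  fractions ppi 0.13 / lipid 0.14 / none 0.73 (interface fractions
  chosen so that roughly 48 of 175 residues interact, the proportion
  typical of an actinoporin fold with its lipid module and protomer
  interfaces; substitution probabilities ordered to emulate purifying
  pressure strongest at interfaces). Interface sites are labelled buried,
  as interfaces are in the assembled pore; exposure of non-interacting
  sites is split 50/50. Substitutions are uniform over the 19
  alternatives — conservation categories, not exchangeability realism,
  are under test. No indels, no tree structure, no rate heterogeneity:
  the cross-tab statistics are tree-agnostic, and passing tests on these
  families shows correct counting and enrichment recovery, not realism
  of evolutionary simulation.
* `generateToyStructure()` — ideal-geometry toys: isolated residues, the
  extended Gly-X-Gly coil reference, a buried residue enclosed in a
  2 Å-spaced dummy-atom lattice (dense enough that every test point is
  occluded, giving side-chain ASA exactly 0), and a 10-residue poly-Ala
  helix. Side-chain geometry is a deterministic extended zig-zag, not
  rotamer-accurate chemistry; ratios are meaningful because the
  reference uses the identical template.
* `generateTrace()` — descending logistic with the tangent/baseline lag
  and maximum fractional rate as the *defining* parameters (lag 13 s and
  rate 0.1 s⁻¹ defaults, the mid-activity regime), plus Gaussian read
  noise. Real traces' multi-step pore-formation kinetics are not
  modelled; only the two extracted parameters are meaningful.
* `generateDoseResponse()` — Hill values (defaults HC₅₀ 1.6 nM, n = 2,
  two-fold dilution series) plus percent-scale Gaussian noise.
* `generateMelt()` — van 't Hoff two-state unfolding,
  K = exp[(ΔH/R)(1/T_m − 1/T)] in kelvin, defaults T_m 53 °C and
  ΔH 400 kJ/mol (typical for a ~20 kDa globular toxin), linear baselines
  (flat by default), 10–90 °C at 0.1 °C steps. Irreversible aggregation
  and scan-rate effects are not modelled, so agreement here does not
  validate those aspects of real CD experiments.

All generators take a `seed`, are bit-reproducible, and restore the
caller's RNG state.

# Numerical choices and problem sizes

* Global pairwise alignment (for unaligned identity counts):
  Needleman–Wunsch via Biostrings, BLOSUM62, gap open 10 / extend 0.5;
  inputs are canonically ordered internally so the comparison is exactly
  symmetric despite alignment tie-breaking. Percent identity uses
  columns where both sequences are non-gap as the denominator, matching
  "different residues" counting between close homologues.
* Average masses: standard unmodified residue averages to 4 decimals +
  one water (18.0153 Da); no adducts or modifications. The empty
  sequence returns the mass of water as the permitted degenerate case.
* Edman splicing: the overlap between prefix and translated body is
  stated by the caller (primer-covered lengths differ per toxin) and
  must agree exactly; conflicts report the mature position.
* Translation: standard genetic code, stop-truncating, N-codons → X,
  other ambiguity codes rejected.
* Test-suite problem sizes keep the checks sharp but desk-scale: 200
  random alignments (≤ 10 × 30) against the brute-force conservation
  oracle; 100 random proper rotations for superposition; 100 replicates
  for power-law and Hill noise recovery; 50 replicates each for melting
  noise recovery and for cross-tab enrichment (families of 120 × 10).

# Known limitations

* The conservation module classifies symbols only; it does not build
  alignments or estimate evolutionary rates.
* ASA ratios depend on the internal coil reference geometry; absolute
  ratios are not comparable to tools using tabulated references, though
  class assignments are robust for clearly buried/exposed residues.
  Published cross-tab counts of conservation × ASA depend on unstated
  thresholds and binning conventions and are therefore reproduction
  goals under the defaults, not asserted constants.
* υ_max is reported in amplitude-normalized units; comparison with
  instrument-scaled literature values requires knowing that scaling.
* The melting module extracts T_M only; it does not fit ΔH/ΔCp, and the
  percent-change normalization assumes approximately flat baselines in
  the first and last decile of the scan.
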