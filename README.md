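# sipCoculture

Quantitative single-cell analysis of carbon and nitrogen transfer in a
microbial phototroph–heterotroph coculture: a green alga as the sole
primary producer, a vitamin-B12-producing rhizobium as the consumer.
The package is written for microbial ecologists and biogeochemists who
use stable isotope probing (SIP) with nanoSIMS imaging to measure
trophic transfer, and it ships a seeded synthetic-data generator so the
entire pipeline can be exercised, tested, and demonstrated without
instrument data.

## What it computes

**Per-cell isotope enrichment.** From co-registered secondary ion count
images (12C2⁻, 12C13C⁻, 12C14N⁻, 12C15N⁻, 32S⁻) and an ROI label mask,
the package sums counts per cell, converts ion ratios to heavy-isotope
atom fractions — carbon via the random-pairing dimer model
*p* = *R*/(2 + *R*), nitrogen via *p* = *R*/(1 + *R*) — and reports:

- **APE** (atom percent enrichment): 100 (*F*_cell − *F*_natural),
  anchored to the standard ratios 0.02247 (C) and 0.00367 (N);
- **net assimilation**
  *X*_net = (*F*_cell − *F*_unlabeled)/(*F*_substrate − *F*_unlabeled),
  the fraction of a cell's biomass newly synthesized from the labeled
  source. For ¹⁵N the source is the known medium ammonium pool (0.4968
  atom fraction for a 50% / 99 atom% labeling design); for ¹³C it is
  the experiment-mean algal biomass composition, since the gas-phase
  label of an open system cannot be mass-balanced.

**Growth inference.** Doublings *d* = log₂(*N*_t/*N*₀), the expected
net synthesis under balanced growth 1 − 2⁻ᵈ, and a reductive-division
flag raised when measured assimilation falls well below that
expectation while the culture keeps dividing — the starvation signature
in which colony counts multiply but biomass barely grows and cells
shrink. Plus cell-length statistics, max-density fold comparisons, and
the two-tailed Student's *t*-tests used throughout.

**Lysis budget.** CFU yield per lysed algal cell, the lysed-cell
density required to explain observed bacterial proliferation, the
corresponding fraction of the algal population, and a consistency
verdict against cytotoxicity-measured lysis (1–3%).

**Assays.** The two-strain *E. coli* B12 bioassay (differential growth
against a monotone 4-parameter logistic standard curve, with explicit
censoring), cytotoxicity percentages relative to killed controls, and
NPOC dilution correction.

**Synthetic data.** `defaultScenario()` + `simulateCoculture()`
generate seeded coculture dynamics (continuous vs 12 h/12 h diurnal
light) with a carbon-pool ledger and per-cell ground truth;
`renderSipField()` renders cells into Poisson ion-count images with a
label mask; `simulateBioassayPlate()` produces assay plates.

## Worked example

```r
library(sipCoculture)
res <- runFull(defaultRunConfig(seed = 1), outDir = "run1")
```

writes per-cell, growth, assessment, lysis, and bioassay tables plus a
report. The report (`run1/report.txt`) reads:

```
Coculture SIP pipeline report
seed: 1  config: def0945917c86069f8643dd9717ff994
algal plateau (cells/ml): continuous 3.83e+06, diurnal 4.1e+06
median bacterial C_net at 48 h: continuous 0.196, diurnal 0.077 (p = 3.9e-20)
max bacterial density fold (continuous/diurnal): 2.97
reductive division flagged from 12 h (continuous)
lysis budget: 106.2 CFU/lysed cell (headline 100); required 1.1e+05 cells/ml = 1.80% of 6.1e+06; consistent
```

Reading it: both light regimes drive the alga to the same ~4 × 10⁶
cells/ml plateau, yet continuous light supports ~3-fold more bacteria,
and about 20% of bacterial carbon at 48 h is algal-derived under
continuous light versus ~8% under diurnal light (a highly significant
difference across single cells). The bacteria divide far faster than
they synthesize biomass — reductive division is flagged from the first
sampled timepoint. The lysis budget shows that one lysed algal cell
supports ~100 CFU of bacterial growth, so the observed proliferation
needs only 1.8% of the algal population to lyse — inside the 1–3%
measured by the cytotoxicity assay: necromass alone can carry the
bacterial population.

The same stages are scriptable individually
(`simulateCoculture()`, `renderSipField()`, `quantifyExperiment()`,
`assessSynthesis()`, `lysisBudget()`, `quantifyBioassayPlate()`), and a
thin CLI wrapper lives at `inst/cli/sip-coculture.R`
(`simulate | quantify | report | validate`).

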