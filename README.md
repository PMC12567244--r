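# cdftrank

Desk-scale prioritization of drug-candidate compounds from electronic
structure summaries. Given a small cohort of related compounds — e.g. a
sixteen-member heterocycle series — `cdftrank` computes conceptual-DFT
global reactivity descriptors from frontier-orbital (HOMO/LUMO) energies,
quantifies the positive/negative/neutral surface shares of rendered
molecular electrostatic potential (MEP) maps by HSV color thresholding,
combines both into a weighted **Composite Bioactivity Score**, and ranks
the cohort. A selectivity-index module covers the companion cytotoxicity
arithmetic (IC50 in normal fibroblasts relative to tumor lines). It is
aimed at computational/medicinal chemists who have orbital energies and
MEP renders in hand and want a transparent, reproducible ranking — not at
anyone needing a quantum-chemistry engine, which this package is not.

## The model

With the Koopmans mapping ionization potential `I = -E_HOMO` and electron
affinity `A = -E_LUMO`:

```
gap      ΔE = E_LUMO − E_HOMO          electronegativity  χ = (I + A)/2
hardness η  = ΔE/2                     chemical potential μ = −χ
softness S  = 1/η = 2/ΔE               electrophilicity   ω = χ²/η
charge acceptance ΔN_max = χ/η
```

(the textbook variants `S = 1/(2η)`, `ω = χ²/(2η)` sit behind
`convention = "textbook"`). Each MEP image is classified pixel-wise into
positive (cyan/blue), negative (red/orange/yellow), neutral (green) and
background; the **area balance** is `pct_positive − pct_negative`. An
**ESP Score** in [0, 1] is the equal-weight mean of the cohort-wise
min–max-normalized potential maxima, (sign-adjusted) minima, contrast and
area balance. Compounds are then ranked by

```
Composite = 0.30·n(S) + 0.20·n(ω) + 0.20·n(1/ΔE) + 0.15·ESP Score
```

with the weights applied exactly as printed (they sum to 0.85; no
renormalization). Selectivity: `SI = IC50(WI-38) / IC50(tumor line)`,
truncated to 2 decimals for display via `display_si()`.

## Worked example

The repository is organised as an analysis workflow over the package: the
numbered drivers under `analysis/` simulate a 16-compound study with known
ground truth, then run each stage and write tables under `results/`.

```sh
Rscript analysis/01_simulate.R      # synthetic cohort + MEP images + IC50s
Rscript analysis/02_descriptors.R   # conceptual-DFT descriptors
Rscript analysis/03_esp_quant.R     # color-threshold area quantification
Rscript analysis/04_score.R         # composite score + ranking
Rscript analysis/05_selectivity.R   # selectivity indices
```

Output of the run shipped in `results/` (seed 2026):

```
Softest:  C03 (gap 0.0056, S 355.68, omega 33.530)
Hardest:  C16 (gap 0.0954, S 20.96, omega 0.434)

Max |recovered - ledger| area share: 4.62e-14 points (0 = exact)
Most positively skewed surface: C03 (balance +21.29 points)

 compound_id n_softness n_omega esp_score composite rank
         C03     1.0000  1.0000    1.0000    0.8500    1
         C08     0.7196  0.7251    0.9099    0.6413    2
         C10     0.2405  0.2589    0.8330    0.2969    3
Planted ranking recovered exactly.

Most selective pair: C04 on HepG-2 (SI 22.57)
```

C03 has the narrowest gap, hence the highest softness and inverse gap, and
dominates every component of the planted ordering, so it scores the full
0.85 (all normalized components equal 1). The ESP quantification recovers
the generator's exact pixel ledger to floating-point noise, and the
composite ranking reproduces the planted ground-truth permutation.

Equivalent single calls from R:

```r
library(cdftrank)
compute_descriptors(e_homo = -0.2744, e_lumo = -0.1680)   # S 18.80, ω 0.92
run_pipeline(pipeline_config(energies = "energies.csv",
                             images = "manifest.csv",
                             extrema = "extrema.csv",
                             out_dir = "out"))
```

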