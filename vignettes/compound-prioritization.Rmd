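---
title: "Prioritizing compounds from frontier-orbital descriptors and ESP surface maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing compounds from frontier-orbital descriptors and ESP surface maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdftrank)
```

## The problem

Medicinal-chemistry programs routinely face a small cohort of closely
related candidate compounds — here, a series of sixteen heterocycles — and
need a transparent, reproducible way to rank them for follow-up before
committing to assays. `cdftrank` implements one such desk-scale
prioritization: conceptual-DFT reactivity descriptors computed from each
compound's frontier-orbital energies, a quantitative reading of each
compound's rendered molecular electrostatic potential (MEP) surface, and a
weighted composite score that ranks the cohort. A small selectivity-index
module covers the companion cytotoxicity arithmetic (IC50 in normal
fibroblasts relative to tumor lines).

The package consumes orbital energies and ESP extrema as *inputs*: it
contains no electronic-structure engine, and it never parses quantum
chemistry log files. Rendered MEP images (PNG/JPEG) are the only
image-typed input.

## Global reactivity descriptors

For HOMO/LUMO energies $E_H < E_L$, with the Koopmans mapping
$I = -E_H$, $A = -E_L$:

$$\Delta E = E_L - E_H, \quad \chi = \tfrac{I + A}{2}, \quad \mu = -\chi,
\quad \eta = \tfrac{\Delta E}{2}$$

Two conventions exist for the derived pair. The package default
(`convention = "paper"`) uses

$$S = \frac{1}{\eta} = \frac{2}{\Delta E}, \qquad
\omega = \frac{\chi^2}{\eta},$$

which is the convention consistent with reported reactivity tables in the
literature this pipeline targets (a gap of 0.00478 gives $S = 418.41$; a
gap of 0.1064 gives $S = 18.80$ and, with $E_H = -0.2744$,
$\omega \approx 0.92$). The common textbook alternative
$S = 1/(2\eta)$, $\omega = \chi^2/(2\eta)$ is available as
`convention = "textbook"`; it halves both quantities and does *not*
reproduce those reference values. $\Delta N_{max} = \chi/\eta$ is
convention-independent here.

```{r}
compute_descriptors(e_homo = -0.2744, e_lumo = -0.2744 + 0.1064)[
  c("gap", "softness", "electrophilicity")]
```

**Units are deliberately opaque.** Frontier-orbital tables in application
papers are sometimes labeled eV while carrying Hartree-scale magnitudes;
rather than guess, the package performs no unit conversion anywhere. All
descriptors are reported in the input's unit system, and any `unit` column
is pass-through metadata. Softness values such as 418.41 only make sense
relative to the same cohort's unit system, which is all the composite score
needs.

**Charge transfer toward a partner.** $\Delta N$ against a reference system
requires the partner's $\chi_{ref}, \eta_{ref}$, which a descriptor table
alone cannot supply. `charge_transfer()` therefore takes the reference
explicitly and is not part of the default pipeline.

Degenerate input ($E_H \ge E_L$) is a hard error, not a numeric fallback:
a zero or inverted gap means the frontier-orbital assignment itself is
wrong, and every downstream descriptor would be nonsense.

## ESP surface quantification

MEP renders use a rainbow palette: red/orange/yellow where the potential is
negative, green near zero, cyan/blue where it is positive, on a light
background. `classify_pixels()` labels each pixel in HSV space:

* background: saturation $< 0.15$, or value $> 0.95$ with saturation
  $< 0.20$ (white page plus near-white antialiasing);
* otherwise, by hue in degrees: negative $[0, 75) \cup [345, 360)$,
  neutral $[75, 165)$, positive $[165, 270)$; hues in $[270, 345)$
  (magenta/purple, unused by rainbow MEP palettes) are counted as `other`.

All bounds live in `esp_color_thresholds()` and can be adapted to a
different palette. Percentages are taken over the classified surface only
(positive + negative + neutral), so they sum to 100; `other` pixels are
reported but excluded. The area balance is
$\mathrm{pct}_{+} - \mathrm{pct}_{-}$ in percentage points.

The **ESP Score** condenses a compound's surface profile into $[0,1]$,
relative to its cohort: the equal-weight mean of the four cohort-wise
min–max-normalized components $n(V_{max})$, $n(-V_{min})$,
$n(V_{max}-V_{min})$ and $n(\mathrm{balance})$. The sign applied to
$V_{min}$ is a genuine convention choice: with the default `esp_min_sign =
-1`, deeper (more negative) minima raise the score, so the score rewards
overall electrostatic expressiveness of the surface; setting
`esp_min_sign = +1` instead rewards surfaces with shallow negative regions.
Both the sign and the four component weights are exposed because no single
convention is canonical. When per-compound extrema are unavailable the
operation does not silently degrade: a reduced area-balance-only score
requires the explicit `area_only = TRUE` opt-in.

A constant component across the cohort (e.g. a single-compound cohort)
normalizes to 0.5 everywhere — a neutral contribution that avoids division
by zero without dropping the component.

## Composite score and ranking

$$\mathrm{Composite} = 0.30\, n(S) + 0.20\, n(\omega) +
0.20\, n(1/\Delta E) + 0.15\, \mathrm{ESP\ Score}$$

The weights are applied exactly as printed in the reactivity-scoring
literature this reproduces: they sum to 0.85, and the package does **not**
renormalize them (a compound maximal in every component scores 0.85, not
1). `score_weights(normalize = TRUE)` is available for users who prefer
unit-sum weights.

Since $S = 2/\Delta E$ exactly, $n(S)$ and $n(1/\Delta E)$ are the *same
column bit for bit* after min–max normalization (scaling by 2 is exact in
binary floating point, and min–max is affine-invariant). The composite is
thus effectively $0.50\, n(S) + 0.20\, n(\omega) + 0.15\,\mathrm{ESP}$;
both columns are kept for transparency, and a test asserts their
bit-identity rather than treating it as a coincidence.

Ranking is deterministic: descending composite, ties broken by ascending
compound id, dense ranks $1..N$, tied rows flagged. The ESP Score enters
already cohort-relative and is not re-normalized.

Absolute composite values from published tables cannot be reproduced here:
their ESP Score ingredients (per-compound extrema and weights) are not
published alongside them. The package's claim is therefore about the
*arithmetic* (weights applied as printed, exact normalization identities)
and about *rank recovery*, which the synthetic cohorts verify exactly.

## Selectivity indices

$\mathrm{SI} = \mathrm{IC50(normal)} / \mathrm{IC50(tumor)}$, unit-free and
computed at full precision. Reported SI tables are commonly *truncated* to
two decimals rather than rounded (81.65/3.98 = 20.5151 is reported as
20.51, 81.65/5.90 = 13.8389 as 13.83); `display_si()` reproduces that
display convention, while all computation uses the full ratio. IC50
standard deviations are carried through but not propagated into the SI —
reported SIs are point estimates, and inventing an error model for them
would overstate what the input supports.

## The synthetic-data generator

The generator exists so every stage has a ground truth:

* **Images** (`gen_esp_image()`): a quasi-circular surface blob (the
  `n_surface` pixels nearest a seed-jittered center) on a white 400×400
  canvas, sliced into contiguous angular sectors per class, colored at the
  centers of the default hue windows. Class pixel counts are
  `floor(fraction × n_surface)` for positive and negative with the
  leftover assigned to neutral, so the pixel ledger is *exact* and
  area-recovery tests can assert equality instead of tolerances. A small
  epsilon guards the floor against binary representation fuzz
  (0.06 × 10000 is 599.999… in floating point).
* **Cohorts** (`gen_descriptor_cohort()`): gaps uniform on 0.005–0.11
  energy units and HOMO energies on −0.31 to −0.18, matching the spread of
  the 16-compound series the pipeline targets. With a `planted_order`,
  sorted draws of every score component are dealt out by intended rank, so
  the compound planted at rank 1 dominates all components and the true
  composite ranking is unambiguous for any non-negative weights — exact
  rank recovery is then a correctness requirement, not a statistical hope.
* **IC50 tables** (`gen_ic50_table()`): log-normal values clamped to
  3–100 µM (tumor lines centered near 15 µM, fibroblasts near 70 µM),
  mirroring the observed range of moderately active cytotoxic
  heterocycles; the `sd` column is a nominal 5% triplicate spread.

Every generator is a pure function of its spec and seed; the same spec
yields byte-identical images.

**What the generator does not emulate:** real MEP renders have shading
gradients, specular highlights, colorbar legends and smoothly interpolated
hues at class boundaries; real cohorts have correlated, non-uniform
descriptor distributions. Passing the synthetic tests therefore
demonstrates that the arithmetic, thresholds and plumbing are correct and
deterministic — not that the default hue windows are optimal for any
particular rendering engine. The JPEG round-trip test (drift under 0.5
percentage points at quality 95) is the only place compression artifacts
are exercised.

## Numerical choices

* Min–max normalization: constant columns map to 0.5; non-finite entries
  are an error naming the index.
* Ties in ranking: broken by compound id so re-runs and row permutations
  give identical output; tied rows are flagged rather than hidden.
* Descriptor identities ($S\eta = 1$, $\omega\eta = \chi^2$,
  $\Delta N_{max}\eta = \chi$) are enforced by property tests at 1e−12
  relative tolerance.
* Determinism: `run_pipeline()` writes byte-identical outputs on re-run
  (the provenance manifest's timestamp is the single exception), and the
  manifest records input MD5 checksums, the seed, and the full
  configuration echo.

## Problem sizes

The shipped analysis and tests use cohorts of 16 (the target series size)
and 50 compounds, 100 seeded rank-recovery replicates, 1,000 property-test
cohorts for the normalization identity, 10,000 random descriptor draws for
the algebraic identities, and 50 generated 400×400 images for the
area-recovery and JPEG checks — sizes at which every check runs in seconds
while still exercising the cohort-relative normalization non-trivially.

## Limitations

* Color thresholds assume a rainbow palette on a light background; dark
  backgrounds or diverging palettes need re-thresholding via
  `esp_color_thresholds()`.
* The ESP Score weighting and minimum-sign convention are choices, exposed
  in configuration, not facts about chemistry.
* Published absolute composite values are not reproducible without their
  unpublished ESP ingredients; only the arithmetic and ranking behavior
  are testable, and that is what is tested.
* SIs are point estimates; assay uncertainty is not propagated.
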