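---
title: "Methods: from paired-horn expression data to simulated TNF responses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from paired-horn expression data to simulated TNF responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tlr4scen)
```

## The scientific question and the pipeline

A sow inseminated on one side only carries embryos in one uterine horn and
unfertilized oocytes in the other, while both horns see the same systemic
hormones. Any transcriptional difference between the paired horns is
therefore attributable to the local presence of the embryo. `tlr4scen`
implements the computational chain for this design: per-probe-set mixed
model differential expression, mapping of transcript ratios of TLR4-pathway
genes onto protein-abundance scenarios, and deterministic simulation of an
LPS-stimulated TLR4 → NF-κB → TNF model under those scenarios, compared by
TNF peak height and peak interval.

## Differential expression

### Normalization

Intensities are log2-transformed and, per array, an intensity-dependent
bias curve is removed: with the per-probe median across arrays as a
pseudo-reference `r`, the deviation `M = x - r` is regressed on
`A = (x + r)/2` with `stats::lowess` and the fitted curve subtracted. The
smoother span defaults to 0.3 (fraction of points), a conventional middle
ground: small enough to track curvature of intensity-dependent bias, large
enough not to chase probe-level noise. The median pseudo-reference makes
the procedure symmetric in the arrays and single-channel friendly. If the
abundance axis is degenerate (all `A` equal, which arises only in synthetic
edge cases), the fitted curve reduces to the mean of `M`.

### The per-probe-set mixed model

For each probe set, `y_ijk = μ + T_i + P_j + A_k + ε_ijk`: treatment and
probe fixed, array random. Two routes are provided:

- **`array_means` (default).** In the balanced paired design every probe of
  a probe set is measured on every array, so the probe effect is eliminated
  exactly by averaging each array over the probe set's probes, and the
  treatment contrast lives entirely in the between-array stratum. The
  least-squares-mean difference equals the difference of condition means of
  these array means, and the Wald/F test of the REML fit is exactly the
  pooled-variance t test on them with `n_arrays - 2` degrees of freedom
  (the whole-plot test of a split plot). This closed form is what
  `fit_all_probe_sets()` vectorizes across thousands of probe sets.
- **`reml`.** `lmerTest::lmer` with Satterthwaite degrees of freedom, for
  unbalanced or degenerate inputs, falling back to OLS when the array
  variance estimate is singular — with three arrays per condition that
  estimate is fragile, and the fallback keeps the contrast estimable. The
  test suite checks that the two routes agree on balanced data.

The contrast is oriented N − Y (non-inseminated minus inseminated), so a
positive difference means lower expression on the embryo side
(`down_in_embryo`). Degenerate fits (zero residual variance) are flagged
rather than silently assigned a p-value. Family-wise error is controlled by
Bonferroni at α = 0.05; the original analysis chose Bonferroni over FDR
methods, and we keep that choice (its conservatism is part of why nearly
all reported calls were down-regulations). The exact degrees-of-freedom
convention of the original SAS/JMP fit is unstated; the balanced-design
closed form documented above is this package's convention.

### Comparative CT

`ddct()` implements relative qPCR quantification: per group ΔCT = CT(gene)
− CT(reference), ΔΔCT = ΔCT(group 1) − ΔCT(group 2) with group 1 the
inseminated side by convention, fold change `2^(-ΔΔCT)`.

## Scenario construction

For each pathway species, the per-(probe, animal) inseminated/
non-inseminated ratios are reduced to minimum, maximum and geometric mean
(`summarize_ratios()`; a species with no mapped probe gets the neutral
(1, 1, 1)). Scenario assignment depends on the sign of the species'
sensitivity: a positive-sensitivity species contributes its minimum ratio
to the minimum-response scenario and its maximum to the maximum-response
scenario; a negative-sensitivity (inhibitory) species contributes them
swapped. The average scenario always takes the geometric mean. Zero
sensitivity never occurs in the reference data; it is treated as positive
with a warning rather than inventing a third branch.

Complexes have no transcript of their own; their multiplier is the product
of constituent multipliers (equilibrium between dimer and constituents),
formed as extreme products — product of constituent minima, of maxima, of
geometric means — and assigned by the complex's own sensitivity sign.

Two numeric conventions matter:

- **Rounding.** Multipliers are rounded to two decimals *half-up*
  (`round2()`), *before* multiplication into concentrations. This is the
  only convention that reproduces the reference table exactly (e.g.
  1.79 × 5.50 = 9.845 → 9.85; 10000 × 1.51 = 15100; 9970 × 1.49 =
  14855.3). Base R's banker's rounding would give 9.84.
- **The triple complex.** The product rule reproduces every dimer cell and
  the full RP1_TRIF_TRAF6 row, and the minimum cell of IRAK1_IRAK4_MyD88
  (0.08 → 712), but gives 1.81/0.68 where the reference prints 1.63/0.64 —
  the printed cells there equal the most variable constituent's own
  multipliers, with no stated rationale. Both behaviours are available via
  `complex_rule = c("product", "printed")`; the product rule is the default
  because it is the stated procedure.

A further recorded discrepancy: the smallest of the six printed MAL ratios
is 0.7956 (→ 0.80), yet the reference table carries 0.74 in MAL's
maximum-response cell. The fixtures preserve both; computation from the
ratios yields 0.80, and the tests assert the reproducible cells (minimum
and average) while documenting the deviation.

## The TLR4 network

The full published TLR4 model (76 species, 203 reactions) is not public at
the level of its rate constants, so `build_default_network()` ships a
reduced mass-action network (39 state variables: the 20 scenario species,
LPS, TNF, the transcription-site pool and transient activated
intermediates) implementing the canonical
wiring: LPS capture by CD14 → MD2 → TLR4 into an active receptor; receptor
engagement of TRAM (productive) or MAL; TRIF-branch assembly
(TRIF → RP1_TRIF → RP1_TRIF_TRAF6 → TAK1) and MyD88-branch assembly
(MyD88 → IRAK4 → IRAK1 → TRAF6 → TAK1); TAK1 → IKK; IKK-driven liberation
of nuclear NF-κB from the IκB:NF-κB pool and the free cytoplasmic pool plus
degradation of free IκB-α; nuclear NF-κB drives TNF transcription and
IκB-α resynthesis; IκB-α recapture and first-order nuclear export terminate
the response. Three structural choices deserve explanation:

- **MAL as a sequestering branch.** MAL competes with TRAM for the active
  receptor and its complex is non-productive. This is a topology choice,
  not a mechanistic claim: it is the simplest mass-action structure that
  gives MAL the net inhibitory (negative-sensitivity) effect the reference
  sensitivity analysis reports. The same analysis reports negative TRIF and
  RP1 sensitivities, which this reduced topology does not promise to
  reproduce (both come out small and positive here).
- **Preformed complex pools are inactive reservoirs** recruited by active
  receptors. Without this, the large initial complex pools would signal
  without any stimulus; with it, `LPS = 0` provably yields a flat zero TNF
  trajectory, and every complex pool retains a positive sensitivity.
- **Saturable TNF transcription.** TNF synthesis goes through a finite pool
  of transcription sites (`tnf_sites = 50` molecules per cell; elementary
  binding/turnover reactions, so still mass action). Nuclear NF-κB is
  cleared mainly by linear export, making its pulse shape-invariant across
  scenarios (amplitude-scaled), and the finite transcription capacity then
  converts a larger amplitude into a *broader*, clipped TNF pulse. This is
  what lets the maximum-response scenario lengthen the peak interval rather
  than merely scale the peak — the qualitative signature of the reference
  profiles. With unsaturated production and quadratic IκB recapture, larger
  responses come out *narrower*, contradicting that signature.

Stimulus is a step: the LPS dose (default 1000 molecules per cell) is
present from t = 0; horizon 360 min. Units are molecules per cell and
minutes throughout. All rate constants are version-pinned in
`default_rate_constants()`; they were chosen once to produce a single
transient TNF peak with the ordering and width behaviour above, and
magnitudes of peaks and sensitivities are explicitly not comparable to the
published full model.

### Numerics

Integration uses `deSolve::lsoda` (stiff-capable, adaptive) at `rtol =
atol = 1e-8` on a 0.5-min output grid. Rates are evaluated on
non-negativity-clamped states; trajectories more negative than 1e-6 of the
dynamic range abort with an error. Peak height is refined by a local
quadratic through the grid maximum and neighbours; the peak interval is the
full width at half maximum with linearly interpolated crossings ("peak
interval" is given this concrete definition here; the term is otherwise
undefined). A monotone trajectory is flagged `non_transient` with an
undefined FWHM; an identically zero trajectory is flagged `flat`. The test
suite verifies a linear-cascade closed form to 1e-6 relative, conservation
of the NF-κB moiety (free + nuclear + complexed + site-bound) to 1e-6, and
< 0.1% peak change under tolerance halving.

## Sensitivity analysis

The coefficient is a forward finite difference on the peak: the species'
initial abundance is increased by 1% and `s = (H' − H0)/(H0 · δ)` — at the
defining δ = 0.01 this is exactly the percentage change in peak height
caused by the 1% increase. Forward difference at +1% is the definition and
the default; a central variant exists for checking near-linearity (the
suite requires δ = 0.01 and δ = 0.005 to agree within 10% for non-tiny
coefficients, and sign stability under 10× tighter tolerances).
Zero-abundance species are reported as not applicable. Each species is
perturbed independently, including complex pools, independent of their
constituents. Only the sign pattern (IκB-α and MAL negative; TLR4, TRAF6,
TAK1, IKK complex, NF-κB positive) and the qualitative ranking (IκB:NF-κB
pool, IKK complex and TAK1 at the top) are asserted against the reference;
magnitudes depend on the package's own rate constants.

## The synthetic-data generator

`generate_intensities()` emulates the structure the analysis assumes: 3
animals × 2 paired conditions (one array each), ~2,000 probe sets by
default (the full-chip 24,123 is supported but not the test default — the
tests' statistical properties do not depend on the probe count), several
probes per gene (MAL has two), log-normal intensities built on the log2
scale as probe baseline (SD 0.5 around mean 8) + animal effect (SD 0.2) +
array effect (SD 0.1, exercising the model's random array term) + planted
treatment log2 fold change + residual noise (SD 0.25 by default). All SDs
are configurable; `noise_sd = 0` is allowed as the deterministic limit used
by exactness tests (with the other random components also set to zero,
planted ratios are reproduced to 1e-12). A fixed seed makes tables
bit-identical.

What it does **not** emulate: probe-sequence affinity biases and saturation
(so lowess has little real bias to remove on synthetic data — its
correctness is tested on constructed offsets instead), vendor
present/absent detection calls, correlated probe blocks, and chip spatial
artifacts. Passing tests therefore demonstrate correctness of the
statistical machinery under the stated model, not robustness to every
real-chip pathology.

## Problem sizes and determinism

The test suite uses 10–2,000 probe sets per case, a 200-replicate null
simulation for family-wise error, and the 360-min default horizon for
simulations; the whole suite runs in well under a minute of compute per
module. Every stochastic test fixes its seed; `run_pipeline()` writes its
resolved configuration (including the seed) into the run directory and is
byte-identical when rerun.

## Known limitations

- The default network is a reduced stand-in with package-chosen rate
  constants: peak percentages and sensitivity magnitudes are not
  comparable to the published full model; only signs, orderings and the
  qualitative width behaviour are meaningful, and the reference's reported
  scenario percentages are reproducible only with the externally supplied
  published parameterization.
- The mixed model's closed form assumes the balanced paired design; for
  missing arrays or probes the `reml` route must be used per probe set.
- Bonferroni control with n = 3 animals has limited power by construction;
  the planted-effect tests quantify this under the synthetic model only.
- The ΔΔCT routine assumes equal amplification efficiencies between target
  and reference genes.
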