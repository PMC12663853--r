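---
title: "Methods: a cross-tissue atlas of ATP synthase hydrolytic activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a cross-tissue atlas of ATP synthase hydrolytic activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvatlas)
```

## The measurement model

ATP synthase (Complex V) is a reversible rotary enzyme: when the electron
transport chain is blocked and the proton motive force collapses, it
hydrolyzes ATP and pumps protons, acidifying the assay medium. The plate
assay records the acidification rate (AR, mpH/min) of a tissue homogenate
through four injection phases:

1. **baseline** — untreated homogenate;
2. **rot_aa** — rotenone (4 µM) + antimycin A (4 µM) block Complexes I and
   III, so Complex V cannot run forward;
3. **atp_fccp** — ATP (20 mM) + FCCP (7.87 mM) drive maximal ATP
   hydrolysis, the reverse mode;
4. **oligomycin** — oligomycin (10 µM) inhibits Complex V, leaving only
   non-CV acidification. Ouabain (1 µM) in the medium suppresses
   non-mitochondrial ATPases throughout.

Per well, hydrolytic activity is the difference of phase means:

$$ A = \overline{AR}_{\mathrm{ATP+FCCP}} - \overline{AR}_{\mathrm{oligo}} $$

with three AR time points per phase. Phases are assigned to measurements
**positionally** from the injection schedule, never from timestamps.
Baseline and rot/AA phases are carried and exposed but enter no formula and
have no default QC cutoff; only the last two phases are quantitative.
Negative activities are retained and flagged (`negative_activity`), never
clamped: truncation at zero would bias group means upward. Wells containing
a non-finite AR are excluded from aggregation, not imputed. The three
technical replicate wells of a biological sample are combined by the
arithmetic mean of their well activities, which for balanced phases equals
differencing the pooled phase means; `n_wells < 3` is flagged.

Protein loading is tissue-specific by design (2–15 µg/well, see
`atlas_tissues()`), equalized within tissue, so no per-protein
normalization is applied. Activity is normalized only to relative
mitochondrial content: net MitoTracker Deep Red fluorescence, the duplicate
mean minus the mean of the plate's dye-plus-buffer blank wells, all wells of
one tissue on one plate at a common gain. A sample with net fluorescence
≤ 0 has no physically meaningful ratio and is excluded with reason
`nonpositive_content` rather than yielding a signed infinity. Because MTDR
is only comparable within a plate, cross-tissue comparisons treat the
normalized ratio as-is — an assumption inherited from the plate layout (one
tissue per plate), not a property the package can verify.

## Atlas statistics

Groups are the four design cells YM/YF/OM/OF (young = 10 weeks, old = 80
weeks; n = 10 animals per cell). The four contrasts are OM vs YM and OF vs
YF (age effect) and YM vs YF and OM vs OF (sex effect). The two
reproductive tissues (testes, fallopian tubes) exist in one sex only and
are excluded from cross-sex contrasts and from categorization.

* **Test choice.** Each tissue × contrast uses a two-sided Welch
  unequal-variance t-test. No multiple-testing correction is applied to the
  activity atlas — results carry raw-p letter tiers (a: p < 0.05, b:
  p < 0.01, c: p < 0.001, d: p < 0.0001, strict inequalities; p = 0.05 is
  `none`). Both choices are deliberate and exposed: the letter-tier
  convention reports per-tissue evidence, and readers should treat counts
  of tier-a tissues accordingly.
* **Effect sizes.** `delta` is the difference of group means and is always
  defined; `log2fc` requires both means strictly positive and is `NA`
  otherwise, in which case delta-based statistics carry the effect.
  Antisymmetry (swapping groups flips both) is property-tested.
* **Attribution.** For an effect, each tissue scores
  |Δ|(contrast 1) + |Δ|(contrast 2) — magnitude only — expressed as percent
  of the total over tissues and ordered ascending. Only the 31 cross-sex
  tissues enter (a reproductive tissue has just one of the two contrasts).
  Percentages conserve mass to 1e-9 by construction.
* **Systems-level comparison.** The distribution of per-tissue group means
  is compared with a two-sample Kolmogorov–Smirnov test. This is a
  documented choice: any omnibus two-sample test could serve; KS is
  assumption-light and sensitive to both location and shape. With ~31 tied
  paired values the exact p is not available and the asymptotic value is
  used.
* **PCA.** Rows are the four group profiles of per-tissue means; columns
  (tissues) with any missing entry — the sex-specific tissues — are dropped,
  then centered and unit-scaled. Scaling is a choice: tissues span an order
  of magnitude in activity, and unscaled PCA would be dominated by the
  high-activity contractile organs.
* **Aging categories.** Tissues are classified from the sign of
  log2(old/young) in each sex: both positive → Increased, both negative →
  Decreased, opposite → Divergent. A strict trichotomy is ill-defined at
  exactly zero, so the sign threshold ε is exposed (`eps`, default 0, with
  |value| ≤ ε → NearZero, reported separately). Recovery tests compare
  categories at ε = 1e-12 so that a true log2FC of exactly 0, recovered at
  floating-point precision as ±1e-15, lands in NearZero on both sides
  rather than on an arbitrary side of the boundary.
* **Ranking ties** are broken by tissue name for determinism.

## Expression panel

The 19-gene ATP synthase panel (two mtDNA-encoded core subunits, five F1
subunits, nine F0 subunits, three assembly factors) ships as packaged data
with its one-to-one human/mouse ortholog map (`atp_synthase_panel()`).
Matrices are individuals × `gene_tissue` TPM columns. Columns are retained
when TPM > 1 (strict) in ≥ 30% (inclusive) of individuals; the filter is
idempotent. Age is dichotomized at ≤ 15 months (young) for mouse and
> 50 years (old) for human; both cutoffs are parameters because the
boundary between 15 and 18 months is genuinely arguable for mouse cohorts
sampled at 3-month intervals.

Per retained column, old vs young is tested with a two-sided two-sample
(Welch) t-test; "direction" is the sign of the old-minus-young mean. FDR
adjustment is Benjamini–Hochberg by default — fully specified, no tuning
parameter — with a Storey-type q-value mode (`method = "storey"`, π₀
estimated at λ = 0.5, no smoother) for users who want the less conservative
estimate; the results table records which was used. Adjustment is applied
across all columns of the panel analysed together (in practice, per sex).

Tissue labels differ between expression datasets and the activity atlas, so
concordance goes through an explicit, editable alias table
(`tissue_alias_table()`); unmapped tissues (bone marrow, whole brain,
tibialis anterior, ...) are reported indeterminate, never guessed. A
tissue's expression direction is the majority sign among its significant
panel columns (ties and empty sets → 0 → indeterminate).

## The synthetic-data generator

The generator is a testing instrument: it emulates the statistical
structure the pipeline assumes, with known ground truth, and makes no
attempt to reproduce measured values. Per well the four phase levels are

```
baseline:   b
rot_aa:     b - d
atp_fccp:   b - d + a*c + r
oligomycin: b - d     + r
```

with `b` the baseline AR (default 20 mpH/min), `d` the rot/AA drop (5),
`r` a non-CV residual (2), `a` the true normalized activity and `c` that
animal's true mitochondrial content — so the well-activity formula recovers
`a*c` exactly at zero noise, and MTDR normalization then recovers `a`.
Noise is additive Gaussian per measurement (no noise model is given for the
instrument; additive Gaussian on AR is the simplest defensible choice),
with SD `noise_sd_ar + noise_cv * signal` so absolute and relative
regimes can both be exercised. Fluorescence wells add the blank level plus
Gaussian noise; values are emitted as drawn, so extreme noise exercises the
non-positive-content exclusion path. Mitochondrial content is lognormal
around a per-tissue base (CV 10%) — drawn once into the truth object, so it
is *truth*, not noise.

The default truth table is illustrative: young-male activity levels rank
contractile organs highest and GI/skin/gWAT lowest; age effects of
|log2FC| = 1 are placed in the tissues with marked aging changes, mild
increases (+0.3) in brain regions, mild declines (−0.2) elsewhere; sex
effects (|log2FC| = 0.8) are confined to a handful of tissues so that the
age effect dominates the significance counts, as it should in this design.
Levels are deliberately all distinct within a group so that rankings are
well-defined under exact recovery. Defaults for noise (SD 0.5 mpH/min on
AR against signals of 1–10; fluorescence SD 20 against contents near 1000)
give group-level effects that are detectable but not trivial at n = 10.

What the generator does **not** emulate: plate-position effects, drift
within a phase, heteroscedasticity across tissues beyond the CV option,
batch differences between plates, or correlated technical replicates.
Passing tests therefore demonstrate correctness of the computations and
calibration of the statistics under the stated model — not robustness to
instrument artifacts.

## Problem sizes and numerical choices

The test and acceptance suites run the full design (33 tissues × 40
animals × 3 wells × 12 measurements ≈ 46k rows) for end-to-end checks, a
1000-tissue null simulation for tier-a calibration, 1000 replicates of a
200-column null panel for FDR calibration, and 500 random attribution
instances; smaller designs (2–4 tissues, n = 2–10) serve the unit tests.
Continuous zero-noise recovery is asserted to 1e-9 relative — the mean of
three equal doubles need not round-trip bit-exactly — while rankings,
signs and categories are asserted exactly. Output tables are written with
12-significant-digit formatting so repeated runs are byte-identical.

## Known limitations

* Normalized activity is a within-plate relative quantity; cross-tissue
  rankings inherit the one-tissue-one-plate assay design as an assumption.
* Raw-p letter tiers mean the atlas's significance counts are not
  FDR-controlled; the expression module, which scans hundreds of columns,
  is.
* The Welch test at n = 10 per group relies on approximate normality of
  sample means; heavy-tailed measurement noise would make the letter tiers
  optimistic.
* The KS comparison of per-tissue means treats tissues as exchangeable
  draws, which is a coarse systems-level summary, not a paired test.
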