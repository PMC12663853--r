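# cvatlas

Mitochondrial ATP synthase (Complex V) can run in reverse: when the
electron transport chain is inhibited, it hydrolyzes ATP and pumps protons,
acidifying the assay medium. Plate-based measurement of that acidification
rate (AR, mpH/min) gives a scalable readout of maximal Complex V hydrolytic
capacity in frozen tissue homogenates. `cvatlas` is the analysis pipeline
for such a study: 33 tissues from young and old, male and female mice
(four groups, n = 10), each sample assayed in triplicate through a
four-phase injection protocol, with a companion analysis of a 19-gene ATP
synthase expression panel. It is written for bioenergetics labs running
plate-based enzymology atlases and for anyone who wants a tested, fully
synthetic-data-backed reference implementation of this analysis.

## The core computation

Per well, with three AR time points per phase,

```
activity = mean(AR after ATP + FCCP) - mean(AR after oligomycin)
```

isolates the oligomycin-sensitive (Complex V) acidification. Triplicate
wells are averaged per biological sample, and activity is normalized to
relative mitochondrial content measured as net MitoTracker Deep Red
fluorescence (duplicate mean minus plate blank):

```
activity_norm = activity_raw / (mean(MTDR duplicates) - blank)
```

Cross-group analytics per tissue: two-sided Welch t-tests for the four
contrasts OM–YM, OF–YF (age) and YM–YF, OM–OF (sex) with letter tiers
(a/b/c/d for p < 0.05/0.01/0.001/0.0001), log2 fold-change matrices,
significance counting per effect, cumulative |Δ| attribution of age vs sex
across tissues, Kolmogorov–Smirnov systems-level distribution comparison,
PCA of group profiles, and categorization of each tissue's aging response
as Increased / Decreased / Divergent from the sign of log2(old/young) in
each sex. The expression module filters TPM columns (detected at TPM > 1
in ≥ 30% of individuals), dichotomizes age (mouse ≤ 15 months young;
human > 50 years old), tests old vs young per `gene_tissue` column with
BH FDR, and scores concordance between expression and activity directions
through an explicit tissue alias table.

## Worked example

Every input can be simulated with known ground truth, so the full pipeline
runs out of the box:

```r
library(cvatlas)

design <- atlas_design()                 # 33 tissues, n = 10 per group
truth  <- ground_truth(design, seed = 1) # true activities + content
plate  <- gen_plate(design, truth)       # 3840 wells x 12 AR points

wells      <- quantify_wells(plate, design$schedule)
records    <- aggregate_replicates(wells)
normalized <- normalize_activity(records, gen_mtdr(design, truth))

gm  <- build_group_matrix(normalized)
head(rank_tissues(gm, "YM"), 3)
#>                         tissue        mean          sem  n
#> 1     Skeletal muscle - Tongue 0.010351831 5.433179e-05 10
#> 2 Skeletal muscle - Quadriceps 0.009445597 1.257100e-04 10
#> 3               Adipose - iWAT 0.009159335 8.260891e-05 10

ct <- contrast_table(gm)
count_significant(ct)
#> $per_contrast
#> OMvsYM OFvsYF YMvsYF OMvsOF
#>     28     27      7     13
#> $age_effect
#> [1] 55
#> $sex_effect
#> [1] 20
```

The ranking puts the contractile organs (tongue, quadriceps) on top, and
the age contrasts dominate the significance counts — both properties the
synthetic truth builds in. The numbered scripts under `analysis/`
(`01_simulate.R` … `04_expression.R`) run the same steps as a narrative
workflow, printing what each stage found and writing its tables under
`results/`.

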