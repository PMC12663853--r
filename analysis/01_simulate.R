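#!/usr/bin/env Rscript
# Simulate the full study's raw inputs with known ground truth: a kinetic
# plate export (four-phase AR traces, triplicate wells), the matching MTDR
# fluorescence table, and a mouse expression panel. Raw simulated inputs
# are large and go under scratch/; the truth summary goes to results/.

suppressMessages(library(cvatlas))

seed <- 20260926L
dir.create("scratch/sim", recursive = TRUE, showWarnings = FALSE)
dir.create("results", showWarnings = FALSE)

design <- atlas_design()  # 33 tissues, n = 10 per group, triplicates
truth <- ground_truth(design, seed = seed)  # default noise: SD 0.5 mpH/min

plate <- gen_plate(design, truth)
write_plate_csv(plate, "scratch/sim/plate_long.csv")
mtdr <- gen_mtdr(design, truth)
utils::write.csv(mtdr, "scratch/sim/mtdr.csv", row.names = FALSE)

dc <- design_counts(n_tissues = 32L,
                    n_animals = 4L * design$n_per_group,
                    replicates = design$replicates_per_sample)
cat(sprintf("Simulated %d wells (%d samples, %d assays by design).\n",
            length(unique(plate$well_id)), dc$n_samples, dc$n_assays))

# expression: 19-gene panel across 16 mouse tissues, aging mostly
# downregulating (log2FC -1 in the non-null half of columns)
expr <- gen_expression(
  tissues = c("WBC", "Spleen", "Marrow", "Bone", "BAT", "gWAT",
              "SubQ/iWAT", "Duodenum", "Pancreas", "Skin", "Muscle",
              "Heart", "Kidney", "Lung", "Liver", "Brain"),
  n_young = 24L, n_old = 12L, effect_log2fc = -1, null_fraction = 0.5,
  species = "mouse", seed = seed + 1L)
utils::write.csv(
  data.frame(individual = rownames(expr$panel$tpm), age = expr$panel$age,
             expr$panel$tpm, check.names = FALSE),
  "scratch/sim/expression_tpm.csv", row.names = FALSE)
utils::write.csv(expr$truth, "results/expression_truth.csv",
                 row.names = FALSE)
cat(sprintf("Simulated expression panel: %d individuals x %d columns.\n",
            nrow(expr$panel$tpm), ncol(expr$panel$tpm)))
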