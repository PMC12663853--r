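#' Atlas study design
#'
#' The default design mirrors a four-group cross-sectional atlas: 31
#' cross-sex tissues plus two sex-specific reproductive tissues, groups
#' YM/YF/OM/OF with 10 animals per group, each biological sample assayed in
#' technical triplicate with three AR measurements per injection phase.
#'
#' @param tissues Tissue registry as from [atlas_tissues()].
#' @param n_per_group Animals per design cell. Default 10.
#' @param replicates_per_sample Technical replicate wells per sample.
#'   Default 3.
#' @param measurements_per_phase AR time points per phase. Default 3.
#' @return Object of class `atlas_design`.
#' @export
atlas_design <- function(tissues = atlas_tissues(), n_per_group = 10L,
                         replicates_per_sample = 3L,
                         measurements_per_phase = 3L) {
  stopifnot(n_per_group >= 1L, replicates_per_sample >= 1L)
  structure(
    list(tissues = tissues, n_per_group = as.integer(n_per_group),
         replicates_per_sample = as.integer(replicates_per_sample),
         schedule = injection_schedule(measurements_per_phase)),
    class = "atlas_design")
}

#' Animal roster for a design
#'
#' @param design An [atlas_design()].
#' @return Data frame `animal_id`, `group`, `sex`, `age_group` (n_per_group
#'   animals in each of YM, YF, OM, OF).
#' @export
design_animals <- function(design) {
  grid <- expand.grid(idx = seq_len(design$n_per_group),
                      group = GROUP_LEVELS, stringsAsFactors = FALSE)
  data.frame(
    animal_id = sprintf("%s_%02d", grid$group, grid$idx),
    group = grid$group,
    sex = ifelse(substr(grid$group, 2, 2) == "M", "male", "female"),
    age_group = ifelse(substr(grid$group, 1, 1) == "Y", "young", "old"),
    stringsAsFactors = FALSE)
}

# Illustrative per-tissue young-male normalized activity levels
# (mpH/min per fluorescence unit): contractile organs highest, GI tract /
# pancreas / skin / gWAT lowest. These are generator defaults for testing,
# not measured data.
.YM_NORM_ACTIVITY <- c(
  "Adipose - BAT" = 3.0, "Adipose - gWAT" = 1.2, "Adipose - iWAT" = 9.0,
  "Brain - Cerebellum" = 5.5, "Brain - Cortex" = 5.0,
  "Brain - Hippocampus" = 5.2, "Brain - Hypothalamus" = 4.95,
  "Eye" = 3.5, "GI - Cecum" = 2.8,
  "GI - Large intestine - Distal Colon" = 1.8,
  "GI - Large intestine - Proximal Colon" = 2.2,
  "GI - Small intestine - Duodenum" = 2.5,
  "GI - Small intestine - Ileum" = 1.6,
  "GI - Small intestine - Jejunum" = 1.5,
  "Heart - atria" = 8.8, "Heart - ventricle" = 7.0,
  "Kidney - cortex" = 4.2, "Kidney - Medulla" = 4.0,
  "Liver" = 4.8, "Lung" = 4.5, "Pancreas" = 1.25,
  "Sex - Fallopian tubes" = 3.2, "Sex - Testes" = 2.9,
  "Skeletal muscle - Diaphragm" = 6.8,
  "Skeletal muscle - Gastrocnemius" = 6.5,
  "Skeletal muscle - Hamstring" = 8.5,
  "Skeletal muscle - Plantaris" = 6.2,
  "Skeletal muscle - Quadriceps" = 9.5,
  "Skeletal muscle - Soleus" = 6.0,
  "Skeletal muscle - Tongue" = 10.0,
  "Skin" = 1.0, "Spleen" = 2.45, "Stomach" = 3.05
) * 1e-3

.named_lfc <- function(tissues, default, overrides) {
  x <- stats::setNames(rep(default, length(tissues)), tissues)
  x[names(overrides)] <- overrides
  x
}

# Illustrative direction structure: strong (|log2FC| = 1) age effects in the
# tissues with marked aging changes, mild increases in brain regions, mild
# declines elsewhere; sex effects confined to a handful of tissues so age
# dominates, qualitatively matching the atlas pattern.
.default_age_lfc_male <- function(tissues) {
  .named_lfc(tissues, -0.2, c(
    "Skeletal muscle - Tongue" = -1, "Skeletal muscle - Gastrocnemius" = -1,
    "Kidney - cortex" = -1,
    "Heart - atria" = 1, "Skeletal muscle - Diaphragm" = 1,
    "GI - Cecum" = 1, "GI - Small intestine - Ileum" = 1,
    "Adipose - gWAT" = 1,
    "Brain - Cerebellum" = 0.3, "Brain - Cortex" = 0.3,
    "Brain - Hippocampus" = 0.3, "Brain - Hypothalamus" = 0.3,
    "Heart - ventricle" = 0.3, "Adipose - iWAT" = 0,
    "Skeletal muscle - Quadriceps" = 0.2, "Lung" = 0.2,
    "Sex - Testes" = 0))
}

.default_age_lfc_female <- function(tissues) {
  .named_lfc(tissues, -0.2, c(
    "Adipose - iWAT" = -1, "Adipose - gWAT" = -1, "Liver" = -1,
    "Spleen" = -1, "GI - Large intestine - Distal Colon" = -1,
    "Skin" = -1, "Sex - Fallopian tubes" = -1,
    "Skeletal muscle - Diaphragm" = 1, "GI - Small intestine - Ileum" = 1,
    "Brain - Cerebellum" = 0.3, "Brain - Cortex" = 0.3,
    "Brain - Hippocampus" = 0.3, "Brain - Hypothalamus" = 0.3,
    "Skeletal muscle - Quadriceps" = 0.2, "Lung" = 0.2))
}

.default_sex_lfc <- function(tissues) {
  # log2(young female / young male): positive where young females run higher
  .named_lfc(tissues, 0, c(
    "Skin" = 0.8, "Adipose - gWAT" = 0.8, "Pancreas" = 0.8,
    "Heart - atria" = 0.8, "Spleen" = 0.8,
    "Skeletal muscle - Tongue" = -0.8, "Brain - Cortex" = -0.8))
}

#' Ground truth for the synthetic atlas
#'
#' Assembles the complete truth the generator needs: a tissue-by-group table
#' of true normalized activities (built from young-male levels, a sex
#' log2FC and per-sex age log2FCs), per-(tissue, animal) mitochondrial
#' content, trace-shape parameters and noise levels. Everything is plain
#' data, so a run is reproducible from its truth object. The default
#' direction structure is illustrative — a testing instrument, not
#' measured data.
#'
#' @param design An [atlas_design()].
#' @param age_lfc_male,age_lfc_female Named per-tissue log2(old/young)
#'   vectors; defaults as described above.
#' @param sex_lfc Named per-tissue log2(YF/YM) vector.
#' @param ym_activity Named per-tissue young-male normalized activity.
#' @param baseline_ar Baseline-phase AR level (mpH/min). Default 20.
#' @param rotaa_drop AR drop after rotenone/antimycin A. Default 5.
#' @param noncv_residual Non-CV acidification persisting after oligomycin.
#'   Default 2.
#' @param noise_sd_ar Additive Gaussian SD on each AR measurement. Default
#'   0.5.
#' @param noise_cv Additional relative noise: per-well AR SD equals
#'   `noise_cv` times that well's true CV signal. Default 0.
#' @param noise_sd_fluor Additive Gaussian SD on fluorescence readings.
#'   Default 20.
#' @param blank_level Blank-well fluorescence level. Default 100.
#' @param content_base Mean mitochondrial content per tissue (recycled).
#'   Default 1000.
#' @param content_cv Lognormal CV of per-animal content. Default 0.1.
#' @param seed RNG seed for drawing the true contents.
#' @return Object of class `ground_truth`; includes
#'   `true_norm_activity` (tissue x group matrix, `NA` where a reproductive
#'   tissue does not exist in a group's sex) and `true_mito_content`
#'   (tissue x animal matrix).
#' @export
ground_truth <- function(design = atlas_design(),
                         age_lfc_male = NULL, age_lfc_female = NULL,
                         sex_lfc = NULL, ym_activity = NULL,
                         baseline_ar = 20, rotaa_drop = 5,
                         noncv_residual = 2, noise_sd_ar = 0.5,
                         noise_cv = 0, noise_sd_fluor = 20,
                         blank_level = 100, content_base = 1000,
                         content_cv = 0.1, seed = 1L) {
  tissues <- design$tissues$tissue
  if (is.null(ym_activity)) ym_activity <- .YM_NORM_ACTIVITY[tissues]
  if (is.null(age_lfc_male)) age_lfc_male <- .default_age_lfc_male(tissues)
  if (is.null(age_lfc_female)) {
    age_lfc_female <- .default_age_lfc_female(tissues)
  }
  if (is.null(sex_lfc)) sex_lfc <- .default_sex_lfc(tissues)
  stopifnot(all(tissues %in% names(ym_activity)),
            all(tissues %in% names(age_lfc_male)),
            all(tissues %in% names(age_lfc_female)),
            all(tissues %in% names(sex_lfc)))
  ym <- ym_activity[tissues]
  yf <- ym * 2^sex_lfc[tissues]
  om <- ym * 2^age_lfc_male[tissues]
  of <- yf * 2^age_lfc_female[tissues]
  act <- cbind(YM = ym, YF = yf, OM = om, OF = of)
  rownames(act) <- tissues
  restricted <- stats::setNames(design$tissues$sex_restricted, tissues)
  act[which(restricted == "female"), c("YM", "OM")] <- NA_real_
  act[which(restricted == "male"), c("YF", "OF")] <- NA_real_

  animals <- design_animals(design)
  base <- rep_len(content_base, length(tissues))
  set.seed(seed)
  sdlog <- sqrt(log(1 + content_cv^2))
  content <- matrix(
    base * exp(stats::rnorm(length(tissues) * nrow(animals),
                            -sdlog^2 / 2, sdlog)),
    nrow = length(tissues), dimnames = list(tissues, animals$animal_id))

  structure(list(
    true_norm_activity = act, true_mito_content = content,
    age_lfc_male = age_lfc_male[tissues],
    age_lfc_female = age_lfc_female[tissues],
    sex_lfc = sex_lfc[tissues],
    baseline_ar = baseline_ar, rotaa_drop = rotaa_drop,
    noncv_residual = noncv_residual, noise_sd_ar = noise_sd_ar,
    noise_cv = noise_cv, noise_sd_fluor = noise_sd_fluor,
    blank_level = blank_level, rng_seed = as.integer(seed)
  ), class = "ground_truth")
}

# TRUE when this tissue is assayed in animals of this sex
.tissue_in_sex <- function(restricted, sex) {
  is.na(restricted) | restricted == sex
}

#' Generate a synthetic kinetic plate export
#'
#' Builds one kinetic trace per well from the trace-shape model: the
#' baseline phase sits at `baseline_ar`; rotenone/antimycin A drop it by
#' `rotaa_drop`; the ATP/FCCP phase adds the CV signal (true normalized
#' activity times that animal's true mitochondrial content) plus a non-CV
#' residual; the oligomycin phase keeps only the residual. Gaussian noise
#' of SD `noise_sd_ar + noise_cv * signal` is added per measurement, so at
#' zero noise the well activity recovers activity x content and the full
#' pipeline recovers the true normalized activity.
#'
#' @param design An [atlas_design()].
#' @param truth A [ground_truth()].
#' @param seed RNG seed (defaults to the truth's seed).
#' @return A `plate_traces` long table (see [as_plate_traces()]).
#' @export
gen_plate <- function(design, truth, seed = truth$rng_seed) {
  set.seed(seed)
  animals <- design_animals(design)
  tissues <- design$tissues$tissue
  restricted <- design$tissues$sex_restricted
  sched <- design$schedule
  loading <- stats::setNames(design$tissues$protein_ug, tissues)
  phase <- phase_of_index(sched)
  n_meas <- sched$total
  rows <- vector("list", length(tissues) * nrow(animals))
  k <- 0L
  for (ti in seq_along(tissues)) {
    tt <- tissues[ti]
    for (ai in seq_len(nrow(animals))) {
      an <- animals[ai, ]
      if (!.tissue_in_sex(restricted[ti], an$sex)) next
      signal <- truth$true_norm_activity[tt, an$group] *
        truth$true_mito_content[tt, an$animal_id]
      level <- c(baseline = truth$baseline_ar,
                 rot_aa = truth$baseline_ar - truth$rotaa_drop,
                 atp_fccp = truth$baseline_ar - truth$rotaa_drop +
                   signal + truth$noncv_residual,
                 oligomycin = truth$baseline_ar - truth$rotaa_drop +
                   truth$noncv_residual)
      sd_well <- truth$noise_sd_ar + truth$noise_cv * abs(signal)
      for (rep_i in seq_len(design$replicates_per_sample)) {
        ar <- level[phase]
        if (sd_well > 0) ar <- ar + stats::rnorm(n_meas, 0, sd_well)
        k <- k + 1L
        rows[[k]] <- data.frame(
          well_id = paste(an$animal_id, tt, rep_i, sep = "::"),
          tissue = tt, animal_id = an$animal_id, sex = an$sex,
          age_group = an$age_group, protein_ug = loading[[tt]],
          replicate_index = rep_i,
          measurement_index = seq_len(n_meas), ar = unname(ar),
          stringsAsFactors = FALSE)
      }
    }
  }
  as_plate_traces(do.call(rbind, rows[seq_len(k)]), sched)
}

#' Generate synthetic MTDR fluorescence readings
#'
#' Duplicate sample wells read true content plus the blank level plus
#' noise; the recorded blank is the mean of `n_blank_wells` blank-well
#' draws. At zero noise the net fluorescence equals the true content.
#'
#' @param design An [atlas_design()].
#' @param truth A [ground_truth()].
#' @param n_blank_wells Blank wells averaged per tissue plate. Default 4.
#' @param seed RNG seed (defaults to `truth$rng_seed + 1`).
#' @return Data frame `animal_id, tissue, rep1, rep2, blank` (one row per
#'   sample; one blank mean per tissue plate).
#' @export
gen_mtdr <- function(design, truth, n_blank_wells = 4L,
                     seed = truth$rng_seed + 1L) {
  set.seed(seed)
  animals <- design_animals(design)
  tissues <- design$tissues$tissue
  restricted <- design$tissues$sex_restricted
  sdf <- truth$noise_sd_fluor
  noise <- function(n) if (sdf > 0) stats::rnorm(n, 0, sdf) else numeric(n)
  out <- vector("list", length(tissues))
  for (ti in seq_along(tissues)) {
    tt <- tissues[ti]
    keep <- .tissue_in_sex(restricted[ti], animals$sex)
    an <- animals[keep, , drop = FALSE]
    blank <- mean(truth$blank_level + noise(n_blank_wells))
    content <- truth$true_mito_content[tt, an$animal_id]
    out[[ti]] <- data.frame(
      animal_id = an$animal_id, tissue = tt,
      rep1 = content + truth$blank_level + noise(nrow(an)),
      rep2 = content + truth$blank_level + noise(nrow(an)),
      blank = blank, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Generate a synthetic expression panel
#'
#' Log-normal TPM per gene_tissue column with a designated fraction of
#' non-null columns whose old-group mean is shifted by `effect_log2fc` on
#' the log2 scale; the truth labels are returned alongside.
#'
#' @param panel Gene panel (default [atp_synthase_panel()]); mouse symbols
#'   are used for mouse, human for human.
#' @param tissues Character vector of expression tissue labels.
#' @param n_young,n_old Individuals per age group (>= 2).
#' @param effect_log2fc log2 fold change (old/young) of non-null columns.
#' @param null_fraction Fraction of columns with no effect. Default 0.5.
#' @param sd_log2 SD of log2 TPM within a group. Default 0.5.
#' @param species `"mouse"` or `"human"`.
#' @param seed RNG seed.
#' @return List: `panel` (an [expression_panel()]), `truth` (data frame
#'   `gene_tissue`, `effect_log2fc`, `is_null`).
#' @export
gen_expression <- function(panel = atp_synthase_panel(),
                           tissues = c("Liver", "Spleen", "Lung"),
                           n_young = 10L, n_old = 10L, effect_log2fc = 0,
                           null_fraction = 0.5, sd_log2 = 0.5,
                           species = c("mouse", "human"), seed = 1L) {
  species <- match.arg(species)
  stopifnot(n_young >= 2L, n_old >= 2L)
  set.seed(seed)
  genes <- if (species == "mouse") panel$mouse_ortholog else
    panel$human_symbol
  cols <- as.vector(outer(genes, tissues, paste, sep = "_"))
  m <- length(cols)
  n <- n_young + n_old
  base_log2 <- stats::runif(m, 3, 7)
  is_null <- rep(TRUE, m)
  n_eff <- round((1 - null_fraction) * m)
  if (n_eff > 0 && effect_log2fc != 0) {
    is_null[sample.int(m, n_eff)] <- FALSE
  }
  shift <- ifelse(is_null, 0, effect_log2fc)
  log2tpm <- matrix(stats::rnorm(n * m, 0, sd_log2), nrow = n)
  log2tpm <- sweep(log2tpm, 2, base_log2, "+")
  old_rows <- seq(n_young + 1L, n)
  log2tpm[old_rows, ] <- sweep(log2tpm[old_rows, , drop = FALSE], 2,
                               shift, "+")
  tpm <- 2^log2tpm
  colnames(tpm) <- cols
  rownames(tpm) <- sprintf("ind_%03d", seq_len(n))
  age <- if (species == "mouse") {
    c(sample(c(3, 6, 12, 15), n_young, replace = TRUE),
      sample(c(18, 21, 24, 27), n_old, replace = TRUE))
  } else {
    c(sample(25:50, n_young, replace = TRUE),
      sample(51:79, n_old, replace = TRUE))
  }
  sex <- rep("male", n)
  list(panel = expression_panel(tpm, age, sex, species),
       truth = data.frame(gene_tissue = cols, effect_log2fc = shift,
                          is_null = is_null, stringsAsFactors = FALSE))
}
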