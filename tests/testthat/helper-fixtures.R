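# Shared fixture builders: everything is generated in code at test time.

# A small cross-sex-only design (first `n_tissues` cross-sex tissues).
small_design <- function(n_tissues = 4L, n_per_group = 2L,
                         replicates = 3L) {
  tis <- atlas_tissues(cross_sex_only = TRUE)[seq_len(n_tissues), ]
  atlas_design(tissues = tis, n_per_group = n_per_group,
               replicates_per_sample = replicates)
}

# Long-format plate table for a single well.
one_well_long <- function(ar, well_id = "A1", tissue = "Liver",
                          animal_id = "YM_01", sex = "male",
                          age_group = "young", replicate_index = 1L) {
  data.frame(well_id = well_id, tissue = tissue, animal_id = animal_id,
             sex = sex, age_group = age_group, protein_ug = 8,
             replicate_index = replicate_index,
             measurement_index = seq_along(ar), ar = ar,
             stringsAsFactors = FALSE)
}

# Toy contrast table with prescribed significance pattern: `sig` is a named
# vector giving, per contrast, how many of the tissues are significant.
toy_contrast_table <- function(tissues, sig) {
  do.call(rbind, lapply(names(sig), function(cn) {
    eff <- if (cn %in% c("OMvsYM", "OFvsYF")) "age" else "sex"
    p <- rep(0.5, length(tissues))
    if (sig[[cn]] > 0) p[seq_len(sig[[cn]])] <- 0.01 / seq_len(sig[[cn]])
    data.frame(tissue = tissues, contrast = cn, effect = eff,
               mean_a = 2, mean_b = 1, delta = 1, log2fc = 1,
               p_value = p, tier = significance_tier(p),
               stringsAsFactors = FALSE)
  }))
}

# Expression panel built directly from a TPM matrix with mouse ages.
panel_from_tpm <- function(tpm, age = NULL, species = "mouse") {
  n <- nrow(tpm)
  if (is.null(age)) age <- rep(c(3, 24), length.out = n)
  expression_panel(tpm, age = age, sex = rep("male", n), species = species)
}
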