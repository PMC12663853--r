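#' Injection phases of the hydrolytic-activity assay
#'
#' The assay records acidification rate (AR, mpH/min) through four sequential
#' injection phases: a drug-free baseline; rotenone + antimycin A (blocking
#' Complexes I and III so ATP synthase cannot run forward); ATP + FCCP
#' (driving maximal ATP hydrolysis, the reverse mode); and oligomycin
#' (inhibiting ATP synthase, leaving only non-CV acidification).
#'
#' @format Character vector of the four phase labels, in injection order.
#' @export
PHASE_LEVELS <- c("baseline", "rot_aa", "atp_fccp", "oligomycin")

#' Four-group atlas design labels: young male, young female, old male,
#' old female.
#' @export
GROUP_LEVELS <- c("YM", "YF", "OM", "OF")

#' Define an injection schedule
#'
#' An injection schedule fixes how many AR measurements are taken in each of
#' the four phases (three per phase in the standard protocol). Phases are
#' assigned to measurements positionally, in the fixed order
#' baseline, rot_aa, atp_fccp, oligomycin.
#'
#' @param measurements_per_phase Integer count of AR time points recorded in
#'   each phase, either a single value recycled across the four phases or a
#'   vector of length four. Default 3.
#' @return An object of class `injection_schedule`: a list with
#'   `phase_names`, `measurements_per_phase` (named integer vector) and
#'   `total` (total measurements per well).
#' @examples
#' sched <- injection_schedule()
#' sched$total  # 12
#' @export
injection_schedule <- function(measurements_per_phase = 3L) {
  m <- as.integer(measurements_per_phase)
  if (length(m) == 1L) m <- rep(m, 4L)
  if (length(m) != 4L || anyNA(m) || any(m < 1L)) {
    stop("measurements_per_phase must be 1 or 4 positive integers",
         call. = FALSE)
  }
  names(m) <- PHASE_LEVELS
  structure(
    list(phase_names = PHASE_LEVELS, measurements_per_phase = m,
         total = sum(m)),
    class = "injection_schedule"
  )
}

#' Phase label for each measurement index of a schedule
#'
#' @param schedule An [injection_schedule()].
#' @return Character vector of length `schedule$total`, the phase of each
#'   measurement in positional order.
#' @export
phase_of_index <- function(schedule) {
  stopifnot(inherits(schedule, "injection_schedule"))
  rep(schedule$phase_names, times = schedule$measurements_per_phase)
}

# Per-tissue protein loading of the assay plate. Loadings (ug homogenate
# protein per well) are tissue-specific because basal acidification signal
# varies by orders of magnitude across organs; the plate design equalizes
# protein within a tissue so no per-protein normalization is applied later.
.TISSUE_TABLE <- data.frame(
  tissue = c(
    "Adipose - BAT", "Adipose - gWAT", "Adipose - iWAT",
    "Brain - Cerebellum", "Brain - Cortex", "Brain - Hippocampus",
    "Brain - Hypothalamus", "Eye",
    "GI - Cecum", "GI - Large intestine - Distal Colon",
    "GI - Large intestine - Proximal Colon",
    "GI - Small intestine - Duodenum", "GI - Small intestine - Ileum",
    "GI - Small intestine - Jejunum",
    "Heart - atria", "Heart - ventricle",
    "Kidney - cortex", "Kidney - Medulla",
    "Liver", "Lung", "Pancreas",
    "Sex - Fallopian tubes", "Sex - Testes",
    "Skeletal muscle - Diaphragm", "Skeletal muscle - Gastrocnemius",
    "Skeletal muscle - Hamstring", "Skeletal muscle - Plantaris",
    "Skeletal muscle - Quadriceps", "Skeletal muscle - Soleus",
    "Skeletal muscle - Tongue",
    "Skin", "Spleen", "Stomach"
  ),
  protein_ug = c(
    2, 15, 15,
    6, 6, 6,
    6, 10,
    10, 10,
    10,
    10, 10,
    10,
    2, 2,
    6, 6,
    8, 10, 8,
    10, 8,
    10, 10,
    8, 10,
    10, 8,
    8,
    10, 8, 8
  ),
  sex_restricted = c(
    rep(NA_character_, 21),
    "female", "male",
    rep(NA_character_, 10)
  ),
  stringsAsFactors = FALSE
)

#' Tissues of the activity atlas
#'
#' Returns the tissue registry: 31 tissues assayed in both sexes plus two
#' sex-specific reproductive tissues (fallopian tubes, testes), with the
#' per-well protein loading used for each.
#'
#' @param cross_sex_only If `TRUE`, drop the two sex-restricted reproductive
#'   tissues (they are omitted from all cross-sex comparisons).
#' @return Data frame with columns `tissue`, `protein_ug`, `sex_restricted`
#'   (`NA` for cross-sex tissues, else `"male"`/`"female"`).
#' @export
atlas_tissues <- function(cross_sex_only = FALSE) {
  out <- .TISSUE_TABLE
  if (cross_sex_only) out <- out[is.na(out$sex_restricted), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Protocol reagent concentrations: rotenone/antimycin A block the electron
# transport chain, ATP + FCCP drive maximal hydrolysis, oligomycin isolates
# the non-CV signal, ouabain suppresses non-mitochondrial ATPases.
.ASSAY_DEFAULTS <- list(
  rotenone_uM = 4,
  antimycin_a_uM = 4,
  atp_mM = 20,
  fccp_mM = 7.87,
  oligomycin_uM = 10,
  ouabain_uM = 1
)

#' Assay configuration
#'
#' Bundles the reagent concentrations of the four-phase protocol with the
#' per-tissue protein loading map. Defaults are the standard protocol values;
#' individual entries can be overridden.
#'
#' @param ... Named reagent overrides among `rotenone_uM`, `antimycin_a_uM`,
#'   `atp_mM`, `fccp_mM`, `oligomycin_uM`, `ouabain_uM`.
#' @param protein_ug_by_tissue Optional named numeric vector of per-tissue
#'   loading overrides (ug/well); names must be known atlas tissues.
#' @return Object of class `assay_config`: list of reagent concentrations
#'   plus `protein_ug_by_tissue` (full named vector over all tissues).
#' @examples
#' cfg <- assay_config()
#' cfg$protein_ug_by_tissue[["Heart - ventricle"]]  # 2
#' @export
assay_config <- function(..., protein_ug_by_tissue = NULL) {
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(.ASSAY_DEFAULTS))
  if (length(unknown)) {
    stop("unknown assay parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- utils::modifyList(.ASSAY_DEFAULTS, overrides)
  loading <- stats::setNames(.TISSUE_TABLE$protein_ug, .TISSUE_TABLE$tissue)
  if (!is.null(protein_ug_by_tissue)) {
    bad <- setdiff(names(protein_ug_by_tissue), names(loading))
    if (length(bad)) {
      stop("unknown tissue(s) in protein loading override: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    if (any(protein_ug_by_tissue <= 0)) {
      stop("protein loading must be positive", call. = FALSE)
    }
    loading[names(protein_ug_by_tissue)] <- protein_ug_by_tissue
  }
  cfg$protein_ug_by_tissue <- loading
  class(cfg) <- "assay_config"
  cfg
}

#' Load an assay configuration from a YAML file
#'
#' The file may contain any subset of the reagent keys accepted by
#' [assay_config()] and an optional `protein_ug_by_tissue` mapping; values
#' not present fall back to the protocol defaults. Unknown tissue names are
#' rejected rather than silently added.
#'
#' @param path Path to a YAML config file (an empty or absent-key file yields
#'   pure defaults).
#' @return An `assay_config`.
#' @export
load_assay_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  loading <- raw$protein_ug_by_tissue
  raw$protein_ug_by_tissue <- NULL
  if (!is.null(loading)) loading <- unlist(loading)
  do.call(assay_config, c(raw, list(protein_ug_by_tissue = loading)))
}
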