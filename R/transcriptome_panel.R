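# The 19 ATP synthase related genes used for the expression analysis:
# the two mtDNA-encoded core subunits, the five F1 catalytic-core subunits,
# nine F0 membrane-sector subunits, and three assembly factors, with the
# one-to-one human/mouse ortholog pairing.
.ATP_SYNTHASE_PANEL <- data.frame(
  human_symbol = c(
    "MT-ATP6", "MT-ATP8",
    "ATP5F1A", "ATP5F1B", "ATP5F1C", "ATP5F1D", "ATP5F1E",
    "ATP5MC1", "ATP5MC2", "ATP5MC3", "ATP5ME", "ATP5MF", "ATP5MG",
    "ATP5PB", "ATP5PD", "ATP5PO",
    "ATPAF1", "ATPAF2", "TMEM70"
  ),
  mouse_ortholog = c(
    "Mt-Atp6", "Mt-Atp8",
    "Atp5f1a", "Atp5f1b", "Atp5f1c", "Atp5f1d", "Atp5f1e",
    "Atp5mc1", "Atp5mc2", "Atp5mc3", "Atp5me", "Atp5mf", "Atp5mg",
    "Atp5pb", "Atp5pd", "Atp5po",
    "Atpaf1", "Atpaf2", "Tmem70"
  ),
  complex_part = c(
    "Core subunit (F0)", "Core subunit (F0)",
    "F1 subunit", "F1 subunit", "F1 subunit", "F1 subunit", "F1 subunit",
    "F0 subunit", "F0 subunit", "F0 subunit", "F0 subunit", "F0 subunit",
    "F0 subunit", "F0 subunit", "F0 subunit", "F0 subunit",
    "Assembly factor", "Assembly factor", "Assembly factor"
  ),
  annotation = c(
    "ATP synthase subunit a", "ATP synthase subunit A6L",
    "Alpha subunit, catalytic core", "Beta subunit, catalytic core",
    "Gamma subunit, catalytic core", "Delta subunit, catalytic core",
    "Epsilon subunit, catalytic core",
    "Membrane subunit c, isoform 1", "Membrane subunit c, isoform 2",
    "Membrane subunit c, isoform 3", "Epsilon subunit of F0",
    "Subunit f of F0", "Subunit g of F0", "Subunit b of F0",
    "Subunit d of F0", "Oligomycin sensitivity",
    "Essential for F1 complex assembly",
    "Essential for F1 complex assembly", "Involved in F0-F1 assembly"
  ),
  stringsAsFactors = FALSE
)

#' The ATP synthase gene panel
#'
#' @return Data frame of the 19 panel genes: `human_symbol`,
#'   `mouse_ortholog`, `complex_part`, `annotation`.
#' @export
atp_synthase_panel <- function() {
  .ATP_SYNTHASE_PANEL
}

#' Construct an expression panel
#'
#' @param tpm Numeric matrix, individuals (rows) x gene_tissue columns
#'   (TPM, non-negative). Column names are `<gene>_<tissue>` (gene up to the
#'   first underscore).
#' @param age Numeric per-individual age (months for mouse, years for
#'   human).
#' @param sex Character per-individual sex.
#' @param species `"mouse"` or `"human"`.
#' @return Object of class `expression_panel`.
#' @export
expression_panel <- function(tpm, age, sex,
                             species = c("mouse", "human")) {
  species <- match.arg(species)
  stopifnot(is.matrix(tpm), nrow(tpm) == length(age),
            nrow(tpm) == length(sex))
  if (any(tpm < 0)) stop("TPM values must be >= 0", call. = FALSE)
  if (is.null(colnames(tpm)) || !all(grepl("_", colnames(tpm)))) {
    stop("every column name must parse as gene_tissue", call. = FALSE)
  }
  if (anyNA(age) || anyNA(sex)) {
    stop("covariates must be complete", call. = FALSE)
  }
  structure(list(tpm = tpm, age = age, sex = sex, species = species),
            class = "expression_panel")
}

#' Split a gene_tissue column name into gene and tissue
#'
#' @param x Character vector of `<gene>_<tissue>` names (gene may contain
#'   hyphens; the split is at the first underscore).
#' @return Data frame `gene`, `tissue`.
#' @export
parse_gene_tissue <- function(x) {
  gene <- sub("_.*$", "", x)
  tissue <- sub("^[^_]*_", "", x)
  data.frame(gene = gene, tissue = tissue, stringsAsFactors = FALSE)
}

#' Detection filter on an expression panel
#'
#' Retains columns detected at TPM strictly greater than `tpm_threshold`
#' in at least `min_fraction` of individuals (inclusive boundary: 3 of 10
#' individuals passes at 30%). Idempotent.
#'
#' @param panel An [expression_panel()].
#' @param tpm_threshold Detection TPM cutoff (strict >). Default 1.
#' @param min_fraction Minimum detected fraction (inclusive >=).
#'   Default 0.30.
#' @return The filtered `expression_panel`.
#' @export
filter_detected <- function(panel, tpm_threshold = 1, min_fraction = 0.30) {
  stopifnot(inherits(panel, "expression_panel"))
  frac <- colMeans(panel$tpm > tpm_threshold)
  keep <- frac >= min_fraction
  panel$tpm <- panel$tpm[, keep, drop = FALSE]
  panel
}

#' Dichotomize individuals into young and old
#'
#' Mouse: young iff age <= `mouse_cutoff` months (default 15; boundary is
#' young). Human: old iff age strictly over `human_cutoff` years (default
#' 50; a 50-year-old is young).
#'
#' @param panel An [expression_panel()].
#' @param mouse_cutoff,human_cutoff Age cutoffs, exposed as parameters.
#' @return List of integer row indices: `young`, `old`.
#' @export
split_by_age <- function(panel, mouse_cutoff = 15, human_cutoff = 50) {
  stopifnot(inherits(panel, "expression_panel"))
  old <- if (panel$species == "mouse") panel$age > mouse_cutoff
         else panel$age > human_cutoff
  list(young = which(!old), old = which(old))
}

#' Per-column differential expression between old and young
#'
#' Two-sided two-sample (Welch) t-test per retained gene_tissue column,
#' old vs young; direction is the sign of (old mean - young mean). FDR
#' adjustment is Benjamini–Hochberg by default, or a Storey-type q-value
#' (pi0 estimated at lambda = 0.5, no smoother) with `method = "storey"`.
#' Columns with fewer than 2 individuals per age group are skipped and
#' listed in the `skipped` attribute.
#'
#' @param panel A filtered [expression_panel()].
#' @param method FDR adjustment, `"BH"` (default) or `"storey"`.
#' @param mouse_cutoff,human_cutoff Passed to [split_by_age()].
#' @return Data frame per column: `gene_tissue`, `gene`, `tissue`,
#'   `direction` (-1/0/+1), `delta`, `p_value`, `q_value`, `neglog10p`,
#'   `fdr_method`.
#' @export
diff_expression <- function(panel, method = c("BH", "storey"),
                            mouse_cutoff = 15, human_cutoff = 50) {
  stopifnot(inherits(panel, "expression_panel"))
  method <- match.arg(method)
  idx <- split_by_age(panel, mouse_cutoff, human_cutoff)
  usable <- length(idx$young) >= 2L && length(idx$old) >= 2L
  if (!usable) stop("need >= 2 individuals per age group", call. = FALSE)
  O <- t(panel$tpm[idx$old, , drop = FALSE])
  Y <- t(panel$tpm[idx$young, , drop = FALSE])
  w <- welch_test_rows(O, Y)
  res <- data.frame(gene_tissue = colnames(panel$tpm),
                    parse_gene_tissue(colnames(panel$tpm)),
                    direction = sign(w$delta), delta = w$delta,
                    p_value = w$p_value, stringsAsFactors = FALSE)
  res$q_value <- adjust_fdr(res$p_value, method)
  res$neglog10p <- -log10(res$p_value)
  res$fdr_method <- method
  rownames(res) <- NULL
  attr(res, "skipped") <- character(0)
  res
}

#' FDR adjustment
#'
#' @param p Numeric vector of p-values.
#' @param method `"BH"` (Benjamini–Hochberg, via [stats::p.adjust()]) or
#'   `"storey"` (BH scaled by the pi0 estimate `mean(p > 0.5) / 0.5`,
#'   capped at 1).
#' @return Adjusted values, same length as `p`.
#' @export
adjust_fdr <- function(p, method = c("BH", "storey")) {
  method <- match.arg(method)
  bh <- stats::p.adjust(p, method = "BH")
  if (method == "BH") return(bh)
  pi0 <- min(1, mean(p > 0.5) / 0.5)
  pmin(1, pi0 * bh)
}

#' Dominant expression direction per tissue
#'
#' For each tissue, the majority sign of direction among panel columns
#' significant at `q_threshold`; 0 when no column is significant or the
#' signs tie.
#'
#' @param results A [diff_expression()] table.
#' @param q_threshold Significance cutoff on q (default 0.05).
#' @return Named integer vector (-1/0/+1) by tissue.
#' @export
panel_direction <- function(results, q_threshold = 0.05) {
  sig <- results[results$q_value < q_threshold, , drop = FALSE]
  tissues <- sort(unique(results$tissue))
  out <- vapply(tissues, function(tt) {
    d <- sig$direction[sig$tissue == tt]
    if (!length(d)) return(0L)
    as.integer(sign(sum(d)))
  }, integer(1))
  stats::setNames(out, tissues)
}

#' Default tissue alias table: expression tissue -> activity tissue
#'
#' Expression datasets label tissues differently from the activity atlas;
#' the alias table makes the mapping explicit and editable. Expression
#' tissues with no activity counterpart (e.g. bone marrow, whole brain,
#' tibialis anterior) are deliberately unmapped and come out indeterminate
#' in [concordance()] rather than guessed.
#'
#' @return Data frame `expression_tissue`, `activity_tissue`.
#' @export
tissue_alias_table <- function() {
  data.frame(
    expression_tissue = c("Spleen", "BAT", "gWAT", "iWAT", "SubQ/iWAT",
                          "Duodenum", "Pancreas", "Skin", "Lung", "Liver",
                          "Stomach", "Ileum"),
    activity_tissue = c("Spleen", "Adipose - BAT", "Adipose - gWAT",
                        "Adipose - iWAT", "Adipose - iWAT",
                        "GI - Small intestine - Duodenum", "Pancreas",
                        "Skin", "Lung", "Liver", "Stomach",
                        "GI - Small intestine - Ileum"),
    stringsAsFactors = FALSE
  )
}

#' Concordance between activity and expression aging directions
#'
#' Maps each expression tissue to its activity tissue via the alias table,
#' then compares the sign of the activity change with the dominant panel
#' expression direction: equal nonzero signs are concordant, opposite
#' nonzero signs discordant, anything else (zero, undefined, unmapped)
#' indeterminate.
#'
#' @param activity_dirs Named numeric vector of per-activity-tissue signs.
#' @param expr_dirs Named numeric vector of per-expression-tissue signs
#'   (e.g. from [panel_direction()]).
#' @param alias Alias table as in [tissue_alias_table()].
#' @return Data frame `expression_tissue`, `activity_tissue`,
#'   `activity_direction`, `expression_direction`, `status` in
#'   {concordant, discordant, indeterminate}.
#' @export
concordance <- function(activity_dirs, expr_dirs,
                        alias = tissue_alias_table()) {
  et <- names(expr_dirs)
  at <- alias$activity_tissue[match(et, alias$expression_tissue)]
  ad <- unname(activity_dirs[match(at, names(activity_dirs))])
  ed <- unname(expr_dirs)
  status <- ifelse(is.na(at) | is.na(ad) | ad == 0 | ed == 0,
                   "indeterminate",
                   ifelse(sign(ad) == sign(ed), "concordant", "discordant"))
  data.frame(expression_tissue = et, activity_tissue = at,
             activity_direction = ad, expression_direction = ed,
             status = status, stringsAsFactors = FALSE)
}
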