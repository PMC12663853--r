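#' Read an MTDR fluorescence table
#'
#' MitoTracker Deep Red (MTDR) fluorescence is read per homogenate in
#' duplicate wells, on the same plate as all samples of a tissue, together
#' with dye-plus-buffer blank wells. The canonical CSV carries one row per
#' sample: `animal_id, tissue, rep1, rep2, blank` where `blank` is the mean
#' fluorescence of the plate's blank wells.
#'
#' @param path CSV file path.
#' @return Data frame with those columns, validated (finite fluorescence,
#'   blank >= 0).
#' @export
read_mtdr_csv <- function(path) {
  if (!file.exists(path)) stop("MTDR file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "tissue", "rep1", "rep2", "blank")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("MTDR table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(df$rep1) | !is.finite(df$rep2) | !is.finite(df$blank))) {
    stop("MTDR table contains non-finite values", call. = FALSE)
  }
  if (any(df$blank < 0)) stop("MTDR blank must be >= 0", call. = FALSE)
  df
}

#' Net MTDR fluorescence
#'
#' The relative mitochondrial content proxy: mean of the duplicate sample
#' readings minus the plate blank. May be non-positive for a weak sample;
#' such samples are excluded at normalization, not here.
#'
#' @param fluor_values Numeric vector of duplicate fluorescence readings
#'   (arbitrary units).
#' @param blank Mean fluorescence of the blank (dye + buffer) wells.
#' @return Net fluorescence (a.u.).
#' @examples
#' net_fluorescence(c(1500, 1540), 100)  # 1420
#' @export
net_fluorescence <- function(fluor_values, blank) {
  fluor_values <- fluor_values[is.finite(fluor_values)]
  if (!length(fluor_values)) {
    stop("no finite fluorescence values", call. = FALSE)
  }
  if (!is.finite(blank) || blank < 0) {
    stop("blank must be a finite non-negative value", call. = FALSE)
  }
  mean(fluor_values) - blank
}

#' Normalize per-sample activity to mitochondrial content
#'
#' Joins the per-sample activity records with the MTDR table on
#' (animal_id, tissue) and divides raw activity by net fluorescence.
#' Normalization is meaningful within a tissue (each tissue is read on one
#' plate at a common gain); samples whose net fluorescence is <= 0 are
#' marked unusable with reason `nonpositive_content` rather than producing
#' signed infinities.
#'
#' @param records Activity records from [aggregate_replicates()].
#' @param mtdr MTDR table from [read_mtdr_csv()] (or of the same shape).
#' @return Data frame: the activity record columns plus `mito_content`
#'   (net a.u.), `activity_norm` (mpH/min per a.u.; `NA` when excluded) and
#'   `exclude_reason` (`""` or `"nonpositive_content"`). Samples missing an
#'   MTDR match are an error.
#' @export
normalize_activity <- function(records, mtdr) {
  key_r <- paste(records$animal_id, records$tissue, sep = "\r")
  key_m <- paste(mtdr$animal_id, mtdr$tissue, sep = "\r")
  if (anyDuplicated(key_m)) {
    stop("MTDR table has duplicate (animal_id, tissue) entries",
         call. = FALSE)
  }
  hit <- match(key_r, key_m)
  if (anyNA(hit)) {
    miss <- records[is.na(hit), c("animal_id", "tissue")]
    stop("no MTDR reading for sample(s): ",
         paste(paste(miss$animal_id, miss$tissue, sep = "/"),
               collapse = ", "), call. = FALSE)
  }
  net <- mapply(function(r1, r2, b) net_fluorescence(c(r1, r2), b),
                mtdr$rep1[hit], mtdr$rep2[hit], mtdr$blank[hit])
  out <- records
  out$mito_content <- net
  usable <- net > 0
  out$activity_norm <- ifelse(usable, out$activity_raw / net, NA_real_)
  out$exclude_reason <- ifelse(usable, "", "nonpositive_content")
  out
}
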