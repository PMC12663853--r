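#' Mean acidification rate of one phase
#'
#' @param segments Named list of per-phase AR vectors from
#'   [segment_phases()].
#' @param phase One of `"baseline"`, `"rot_aa"`, `"atp_fccp"`,
#'   `"oligomycin"`.
#' @return Arithmetic mean of the finite AR values in that phase (mpH/min).
#' @export
phase_mean <- function(segments, phase) {
  if (!phase %in% names(segments)) {
    stop("phase '", phase, "' absent from segmented trace", call. = FALSE)
  }
  x <- segments[[phase]]
  x <- x[is.finite(x)]
  if (!length(x)) {
    stop("phase '", phase, "' has no finite measurements", call. = FALSE)
  }
  mean(x)
}

#' Complex V hydrolytic activity of one well
#'
#' Activity is the difference between the mean AR of the ATP + FCCP phase
#' (maximal hydrolysis) and the mean AR of the oligomycin phase (non-CV
#' acidification). Negative values are returned as-is — they are flagged at
#' aggregation, never clamped.
#'
#' @param ar Numeric AR vector for one well, or a pre-segmented phase list.
#' @param schedule An [injection_schedule()] (ignored if `ar` is already
#'   segmented).
#' @return Activity in mpH/min.
#' @examples
#' well_activity(c(5, 5, 5, 4, 4, 4, 11, 12, 10, 2, 3, 1))  # 11 - 2 = 9
#' @export
well_activity <- function(ar, schedule = injection_schedule()) {
  segments <- if (is.list(ar)) ar else segment_phases(ar, schedule)
  phase_mean(segments, "atp_fccp") - phase_mean(segments, "oligomycin")
}

#' Per-well activities for a whole plate
#'
#' Wells containing any non-finite AR value are excluded from the activity
#' table (and reported via the `nonfinite_excluded` attribute) rather than
#' imputed.
#'
#' @param traces A `plate_traces` table from [read_plate_csv()] /
#'   [as_plate_traces()].
#' @param schedule An [injection_schedule()].
#' @return Data frame with one row per usable well: the metadata columns
#'   plus `activity` (mpH/min). Attribute `nonfinite_excluded` holds the
#'   well_ids dropped for non-finite measurements.
#' @export
quantify_wells <- function(traces, schedule = injection_schedule()) {
  flagged <- attr(traces, "flagged_wells")
  if (is.null(flagged)) flagged <- character(0)
  df <- as.data.frame(traces)
  keep <- !df$well_id %in% flagged
  df <- df[keep, , drop = FALSE]
  meta <- df[!duplicated(df$well_id),
             c(.PLATE_META_COLS), drop = FALSE]
  acts <- vapply(split(df, df$well_id), function(w) {
    w <- w[order(w$measurement_index), ]
    well_activity(w$ar, schedule)
  }, numeric(1))
  meta <- meta[order(meta$well_id), , drop = FALSE]
  meta$activity <- acts[meta$well_id]
  rownames(meta) <- NULL
  structure(meta, nonfinite_excluded = flagged)
}

#' Aggregate technical replicates into per-sample activity records
#'
#' Each biological sample (one animal, one tissue) is assayed in triplicate;
#' its raw activity is the arithmetic mean of the contributing well
#' activities. QC flags record negative aggregate activity, fewer than three
#' contributing wells, and wells lost to non-finite measurements.
#'
#' @param wells Per-well activity table from [quantify_wells()].
#' @param expected_replicates Design replicate count (default 3); samples
#'   with fewer contributing wells get the `missing_replicate` flag.
#' @return Data frame with one row per (animal_id, tissue): `animal_id`,
#'   `tissue`, `sex`, `age_group`, `activity_raw`, `n_wells`, `qc_flags`
#'   (comma-joined string, empty when clean).
#' @export
aggregate_replicates <- function(wells, expected_replicates = 3L) {
  if (!nrow(wells)) stop("no usable wells to aggregate", call. = FALSE)
  key <- interaction(wells$animal_id, wells$tissue, drop = TRUE, sep = "\r")
  groups <- split(wells, key)
  lost <- attr(wells, "nonfinite_excluded")
  if (is.null(lost)) lost <- character(0)
  rows <- lapply(groups, function(g) {
    if (length(unique(g$animal_id)) != 1L || length(unique(g$tissue)) != 1L) {
      stop("replicate group mixes animals or tissues", call. = FALSE)
    }
    if (anyDuplicated(g$replicate_index)) {
      stop("duplicate replicate_index within sample ", g$animal_id[1], " / ",
           g$tissue[1], call. = FALSE)
    }
    act <- mean(g$activity)
    flags <- character(0)
    if (act < 0) flags <- c(flags, "negative_activity")
    if (nrow(g) < expected_replicates) flags <- c(flags, "missing_replicate")
    data.frame(animal_id = g$animal_id[1], tissue = g$tissue[1],
               sex = g$sex[1], age_group = g$age_group[1],
               activity_raw = act, n_wells = nrow(g),
               qc_flags = paste(flags, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$tissue, out$animal_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
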