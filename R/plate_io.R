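# Canonical plate formats
#
# Long format (canonical): one row per (well, measurement):
#   well_id, tissue, animal_id, sex, age_group, protein_ug, replicate_index,
#   measurement_index (1-based in files), ar, and optionally phase.
# Wide format: one row per well with the same metadata columns plus ar_1 ...
# ar_T. The reader auto-detects the dialect from the header.

.PLATE_META_COLS <- c("well_id", "tissue", "animal_id", "sex", "age_group",
                      "protein_ug", "replicate_index")

#' Read a plate kinetic export
#'
#' Reads a delimited plate export in either the canonical long format (one
#' row per well and measurement, column `ar`) or the wide variant (one row
#' per well, columns `ar_1..ar_T`), validates every well against the
#' injection schedule, and returns one kinetic trace per well. Wells whose
#' measurement count does not match the schedule are an error, never silently
#' dropped; wells containing non-finite AR values are kept but flagged so
#' downstream aggregation can exclude them.
#'
#' @param path CSV file path.
#' @param schedule An [injection_schedule()].
#' @return A `plate_traces` data frame in long format with one row per
#'   (well, measurement): metadata columns, `measurement_index` (1-based),
#'   `phase` (assigned positionally from the schedule) and `ar`. The
#'   attribute `flagged_wells` lists well_ids with non-finite AR.
#' @export
read_plate_csv <- function(path, schedule = injection_schedule()) {
  if (!file.exists(path)) stop("plate file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing_meta <- setdiff(.PLATE_META_COLS, names(df))
  if (length(missing_meta)) {
    stop("plate export missing required column(s): ",
         paste(missing_meta, collapse = ", "), call. = FALSE)
  }
  wide_cols <- grep("^ar_[0-9]+$", names(df), value = TRUE)
  if ("ar" %in% names(df)) {
    if (!"measurement_index" %in% names(df)) {
      stop("plate export missing required column(s): measurement_index",
           call. = FALSE)
    }
    long <- df
  } else if (length(wide_cols)) {
    idx <- as.integer(sub("^ar_", "", wide_cols))
    wide_cols <- wide_cols[order(idx)]
    long <- do.call(rbind, lapply(seq_len(nrow(df)), function(i) {
      row <- df[i, , drop = FALSE]
      data.frame(row[.PLATE_META_COLS],
                 measurement_index = seq_along(wide_cols),
                 ar = as.numeric(row[wide_cols]),
                 row.names = NULL, check.names = FALSE)
    }))
  } else {
    stop("plate export missing required column(s): ar (or ar_1..ar_T)",
         call. = FALSE)
  }
  as_plate_traces(long, schedule)
}

#' Validate a long-format plate table and assign phases
#'
#' @param long Data frame with the canonical long-format columns.
#' @param schedule An [injection_schedule()].
#' @return Validated `plate_traces` data frame (see [read_plate_csv()]).
#' @export
as_plate_traces <- function(long, schedule = injection_schedule()) {
  missing_meta <- setdiff(c(.PLATE_META_COLS, "measurement_index", "ar"),
                          names(long))
  if (length(missing_meta)) {
    stop("plate table missing required column(s): ",
         paste(missing_meta, collapse = ", "), call. = FALSE)
  }
  long <- long[order(long$well_id, long$measurement_index), , drop = FALSE]
  counts <- table(long$well_id)
  bad <- names(counts)[counts != schedule$total]
  if (length(bad)) {
    stop("measurement count does not match schedule (", schedule$total,
         ") for well(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  per_well_idx <- stats::ave(long$measurement_index, long$well_id,
                             FUN = function(x) seq_along(x))
  phase_map <- phase_of_index(schedule)
  long$phase <- phase_map[per_well_idx]
  nf <- !is.finite(long$ar)
  flagged <- sort(unique(long$well_id[nf]))
  rownames(long) <- NULL
  structure(long, flagged_wells = flagged, class = c("plate_traces",
                                                     class(long)))
}

#' Write a plate trace table in canonical long format
#'
#' Inverse of [read_plate_csv()]: the written file re-reads to the identical
#' trace collection (AR values bit-exact, metadata field-for-field).
#'
#' @param traces A `plate_traces` data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_plate_csv <- function(traces, path) {
  cols <- c(.PLATE_META_COLS, "measurement_index", "phase", "ar")
  out <- as.data.frame(traces)[, intersect(cols, names(traces)), drop = FALSE]
  # 17 significant digits: doubles survive the text round-trip bit-exactly
  out$ar <- formatC(out$ar, digits = 17, format = "g")
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Partition one well's AR series into injection phases
#'
#' Measurements are assigned to phases positionally from the schedule: the
#' first block is baseline, then rotenone/antimycin A, then ATP/FCCP, then
#' oligomycin. Concatenating the blocks in order reproduces the input
#' exactly.
#'
#' @param ar Numeric vector of AR values (mpH/min) for one well, in
#'   measurement order.
#' @param schedule An [injection_schedule()].
#' @return Named list of four numeric vectors, one per phase.
#' @examples
#' segment_phases(c(5, 5.1, 4.9, 4, 4.1, 3.9, 11, 12, 10, 2, 3, 1))
#' @export
segment_phases <- function(ar, schedule = injection_schedule()) {
  if (length(ar) != schedule$total) {
    stop("trace has ", length(ar), " measurements but schedule requires ",
         schedule$total, call. = FALSE)
  }
  split(ar, factor(phase_of_index(schedule), levels = PHASE_LEVELS))
}
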