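#' Sample and assay accounting for a study design
#'
#' @param n_tissues Tissues collected per animal. Default 32.
#' @param n_animals Total animals. Default 40.
#' @param replicates Technical replicates per biological sample. Default 3.
#' @return List: `n_samples` (tissues x animals) and `n_assays`
#'   (samples x replicates).
#' @examples
#' design_counts()  # 1280 samples, 3840 assays
#' @export
design_counts <- function(n_tissues = 32L, n_animals = 40L,
                          replicates = 3L) {
  stopifnot(n_tissues >= 1L, n_animals >= 1L, replicates >= 1L)
  n_samples <- as.integer(n_tissues) * as.integer(n_animals)
  list(n_samples = n_samples,
       n_assays = n_samples * as.integer(replicates))
}

# Pinned CSV output: fixed column order as supplied, 12 significant digits
# for doubles, so re-runs are byte-identical and diff-able.
.write_pinned_csv <- function(df, path) {
  out <- df
  num <- vapply(out, is.double, logical(1))
  out[num] <- lapply(out[num], function(x) {
    ifelse(is.na(x), "", formatC(x, digits = 12, format = "g"))
  })
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Run the full atlas pipeline
#'
#' Orchestrates quantify -> normalize -> atlas statistics (and optionally
#' the expression-panel analysis) over either supplied input files or a
#' synthetic atlas, writing every result table as pinned-format CSV plus a
#' JSON run manifest. Re-running with the same config and inputs is
#' byte-identical.
#'
#' @param config List with entries:
#'   * `plate_csv`, `mtdr_csv`: input paths, or `NULL` to simulate;
#'   * `design`: an [atlas_design()] (used for the schedule, and for
#'     simulation);
#'   * `truth`: a [ground_truth()] (simulation only);
#'   * `seed`: integer RNG seed for simulation;
#'   * `expression`: optional list passed to [gen_expression()], or an
#'     [expression_panel()] to analyse;
#'   * `fdr_method`: `"BH"` (default) or `"storey"`;
#'   * `eps`: sign threshold for [categorize_aging()] (default 0);
#'   * `outdir`: output directory.
#' @return Invisible list of the in-memory results: `normalized`,
#'   `contrasts`, `counts`, `attribution_age`, `attribution_sex`,
#'   `categories`, `rankings`, `pca`, and `expression` (or `NULL`).
#' @export
run_all <- function(config) {
  design <- config$design
  if (is.null(design)) design <- atlas_design()
  outdir <- config$outdir
  if (is.null(outdir)) stop("config$outdir is required", call. = FALSE)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  stage <- "import"
  truth <- config$truth
  res <- tryCatch({
    if (!is.null(config$plate_csv)) {
      traces <- read_plate_csv(config$plate_csv, design$schedule)
    } else {
      if (is.null(truth)) {
        truth <- ground_truth(design,
                              seed = if (is.null(config$seed)) 1L
                                     else config$seed)
      }
      traces <- gen_plate(design, truth)
    }

    stage <- "quantify"
    wells <- quantify_wells(traces, design$schedule)
    records <- aggregate_replicates(wells, design$replicates_per_sample)

    stage <- "normalize"
    mtdr <- if (!is.null(config$mtdr_csv)) {
      read_mtdr_csv(config$mtdr_csv)
    } else if (!is.null(truth)) {
      gen_mtdr(design, truth)
    } else {
      stop("no MTDR input: supply config$mtdr_csv (or a truth to simulate)",
           call. = FALSE)
    }
    normalized <- normalize_activity(records, mtdr)

    stage <- "stats"
    gm <- build_group_matrix(normalized)
    contrasts <- contrast_table(gm)
    counts <- count_significant(contrasts)
    attr_age <- cumulative_attribution(contrasts, "age")
    attr_sex <- cumulative_attribution(contrasts, "sex")
    rankings <- do.call(rbind, lapply(GROUP_LEVELS, function(g) {
      r <- rank_tissues(gm, g); r$group <- g; r
    }))
    cross <- is.na(gm$sex_restricted)
    l2m <- stats::setNames(
      contrasts$log2fc[contrasts$contrast == "OMvsYM"],
      contrasts$tissue[contrasts$contrast == "OMvsYM"])
    l2f <- stats::setNames(
      contrasts$log2fc[contrasts$contrast == "OFvsYF"],
      contrasts$tissue[contrasts$contrast == "OFvsYF"])
    shared <- intersect(names(l2m)[!is.na(l2m)], names(l2f)[!is.na(l2f)])
    shared <- intersect(shared, gm$tissues[cross])
    eps <- if (is.null(config$eps)) 0 else config$eps
    categories <- categorize_aging(l2m[shared], l2f[shared], eps = eps)
    profiles <- do.call(rbind, lapply(GROUP_LEVELS, function(g) {
      vapply(gm$tissues, function(tt) {
        x <- gm$values[[tt]][[g]]
        if (length(x)) mean(x) else NA_real_
      }, numeric(1))
    }))
    rownames(profiles) <- GROUP_LEVELS
    pca <- pca_embed(profiles)

    stage <- "expression"
    expr_res <- NULL
    if (!is.null(config$expression)) {
      ep <- config$expression
      if (!inherits(ep, "expression_panel")) {
        ep <- do.call(gen_expression, ep)$panel
      }
      fdr <- if (is.null(config$fdr_method)) "BH" else config$fdr_method
      expr_res <- diff_expression(filter_detected(ep), method = fdr)
    }

    list(normalized = normalized, contrasts = contrasts, counts = counts,
         attribution_age = attr_age, attribution_sex = attr_sex,
         categories = categories, rankings = rankings, pca = pca,
         expression = expr_res)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })

  .write_pinned_csv(res$normalized, file.path(outdir, "normalized.csv"))
  .write_pinned_csv(res$contrasts, file.path(outdir, "contrasts.csv"))
  .write_pinned_csv(res$attribution_age,
                    file.path(outdir, "attribution_age.csv"))
  .write_pinned_csv(res$attribution_sex,
                    file.path(outdir, "attribution_sex.csv"))
  .write_pinned_csv(res$categories, file.path(outdir, "categories.csv"))
  .write_pinned_csv(res$rankings, file.path(outdir, "rankings.csv"))
  pca_df <- data.frame(row = rownames(res$pca$coords),
                       res$pca$coords, stringsAsFactors = FALSE)
  .write_pinned_csv(pca_df, file.path(outdir, "pca_coords.csv"))
  if (!is.null(res$expression)) {
    .write_pinned_csv(res$expression, file.path(outdir, "expression.csv"))
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("cvatlas")),
    seed = config$seed,
    n_tissues = length(unique(res$normalized$tissue)),
    n_samples = nrow(res$normalized),
    significant = res$counts,
    tables = list.files(outdir, pattern = "\\.csv$"))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(res)
}
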