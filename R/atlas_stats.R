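# The four pairwise contrasts of the atlas. Age effect: old vs young within
# sex; sex effect: male vs female within age. "a vs b" means delta and
# log2fc are computed as a - b and log2(a/b).
.CONTRASTS <- list(
  OMvsYM = c(a = "OM", b = "YM"),
  OFvsYF = c(a = "OF", b = "YF"),
  YMvsYF = c(a = "YM", b = "YF"),
  OMvsOF = c(a = "OM", b = "OF")
)

.CONTRAST_EFFECT <- c(OMvsYM = "age", OFvsYF = "age",
                      YMvsYF = "sex", OMvsOF = "sex")

#' Arrange normalized activities as a tissue-by-group matrix of vectors
#'
#' Groups samples by tissue and design cell (YM, YF, OM, OF). Excluded
#' samples (non-positive mitochondrial content) are dropped. Reproductive
#' tissues are marked sex-restricted; they only ever appear in the two
#' groups of their sex and are omitted from cross-sex contrasts downstream.
#'
#' @param normalized Table from [normalize_activity()] (needs `tissue`,
#'   `sex`, `age_group`, `activity_norm`).
#' @return Object of class `group_matrix`: list with `values` (nested list
#'   `values[[tissue]][[group]]` of per-animal activity vectors), `tissues`,
#'   and `sex_restricted` (named character, `NA` for cross-sex tissues).
#' @export
build_group_matrix <- function(normalized) {
  ok <- !is.na(normalized$activity_norm)
  df <- normalized[ok, , drop = FALSE]
  if (!nrow(df)) stop("no usable normalized samples", call. = FALSE)
  grp <- paste0(ifelse(df$age_group == "young", "Y", "O"),
                ifelse(df$sex == "male", "M", "F"))
  if (!all(grp %in% GROUP_LEVELS)) {
    stop("sex must be male/female and age_group young/old", call. = FALSE)
  }
  tissues <- sort(unique(df$tissue))
  values <- lapply(stats::setNames(tissues, tissues), function(tt) {
    sub <- df[df$tissue == tt, , drop = FALSE]
    g <- grp[df$tissue == tt]
    lapply(stats::setNames(GROUP_LEVELS, GROUP_LEVELS),
           function(gg) sub$activity_norm[g == gg])
  })
  reg <- atlas_tissues()
  restricted <- stats::setNames(
    reg$sex_restricted[match(tissues, reg$tissue)], tissues)
  structure(list(values = values, tissues = tissues,
                 sex_restricted = restricted),
            class = "group_matrix")
}

#' Rank tissues by mean normalized activity within one group
#'
#' @param gm A [build_group_matrix()] result.
#' @param group One of `"YM"`, `"YF"`, `"OM"`, `"OF"`.
#' @return Data frame ordered from highest to lowest mean: `tissue`, `mean`,
#'   `sem` (sd over animals / sqrt(n)), `n`. Ties broken by tissue name for
#'   determinism.
#' @export
rank_tissues <- function(gm, group) {
  stopifnot(inherits(gm, "group_matrix"))
  if (!group %in% GROUP_LEVELS) stop("unknown group: ", group, call. = FALSE)
  rows <- lapply(gm$tissues, function(tt) {
    x <- gm$values[[tt]][[group]]
    if (!length(x)) return(NULL)
    data.frame(tissue = tt, mean = mean(x),
               sem = stats::sd(x) / sqrt(length(x)), n = length(x),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || !nrow(out)) {
    stop("group ", group, " has no samples", call. = FALSE)
  }
  out <- out[order(-out$mean, out$tissue), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' One pairwise group contrast
#'
#' Welch two-sided test plus the difference and log2 ratio of group means.
#' log2fc is defined only when both means are strictly positive; otherwise
#' it is `NA` and the delta-based statistics carry the effect size.
#'
#' @param a,b Numeric activity vectors (>= 2 finite values each); the
#'   contrast is a vs b.
#' @return List: `p_value`, `delta` (mean(a) - mean(b)), `log2fc`, `t`,
#'   `df`, `mean_a`, `mean_b`.
#' @export
contrast_test <- function(a, b) {
  w <- welch_test(a, b)
  ma <- mean(a[is.finite(a)]); mb <- mean(b[is.finite(b)])
  l2 <- if (ma > 0 && mb > 0) log2(ma / mb) else NA_real_
  list(p_value = w$p_value, delta = ma - mb, log2fc = l2,
       t = w$t, df = w$df, mean_a = ma, mean_b = mb)
}

#' All four contrasts for every tissue
#'
#' Runs OM vs YM and OF vs YF (age effect) and YM vs YF and OM vs OF (sex
#' effect) per tissue, attaching the letter significance tier of each raw
#' p-value. Reproductive tissues enter only the age contrast of their sex;
#' no multiple-testing correction is applied (the atlas reports raw-p letter
#' tiers).
#'
#' @param gm A [build_group_matrix()] result.
#' @return Data frame: `tissue`, `contrast`, `effect` (age/sex), `mean_a`,
#'   `mean_b`, `delta`, `log2fc`, `p_value`, `tier`.
#' @export
contrast_table <- function(gm) {
  stopifnot(inherits(gm, "group_matrix"))
  rows <- list()
  for (tt in gm$tissues) {
    restricted <- gm$sex_restricted[[tt]]
    for (cn in names(.CONTRASTS)) {
      if (!is.na(restricted) && .CONTRAST_EFFECT[[cn]] == "sex") next
      ga <- gm$values[[tt]][[.CONTRASTS[[cn]][["a"]]]]
      gb <- gm$values[[tt]][[.CONTRASTS[[cn]][["b"]]]]
      if (length(ga) < 2L || length(gb) < 2L) next
      ct <- contrast_test(ga, gb)
      rows[[length(rows) + 1L]] <- data.frame(
        tissue = tt, contrast = cn, effect = .CONTRAST_EFFECT[[cn]],
        mean_a = ct$mean_a, mean_b = ct$mean_b, delta = ct$delta,
        log2fc = ct$log2fc, p_value = ct$p_value,
        tier = significance_tier(ct$p_value), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Count significant contrasts per comparison and per effect
#'
#' @param results A [contrast_table()].
#' @return List: `per_contrast` (named count of tissues with tier != none
#'   for each of the four contrasts), `age_effect` (sum over the two age
#'   contrasts), `sex_effect` (sum over the two sex contrasts).
#' @export
count_significant <- function(results) {
  sig <- results$tier != "none"
  per <- vapply(names(.CONTRASTS),
                function(cn) sum(sig & results$contrast == cn), integer(1))
  list(per_contrast = per,
       age_effect = unname(per["OMvsYM"] + per["OFvsYF"]),
       sex_effect = unname(per["YMvsYF"] + per["OMvsOF"]))
}

#' Cumulative absolute-difference attribution of an effect across tissues
#'
#' For the chosen effect, each tissue's score is the sum of the absolute
#' mean differences over the effect's two contrasts (age: |OM-YM| + |OF-YF|;
#' sex: |YM-YF| + |OM-OF|) — magnitude only, no directionality. Scores are
#' expressed as percent of the total and ordered from lowest to highest
#' contribution. Only tissues with both contrasts present (the cross-sex
#' tissues) enter.
#'
#' @param results A [contrast_table()].
#' @param effect `"age"` or `"sex"`.
#' @return Data frame ordered ascending by score: `tissue`, `abs_delta_sum`,
#'   `percent`. Attribute `total` holds the summed score.
#' @export
cumulative_attribution <- function(results, effect = c("age", "sex")) {
  effect <- match.arg(effect)
  sub <- results[results$effect == effect, , drop = FALSE]
  cts <- names(.CONTRASTS)[.CONTRAST_EFFECT == effect]
  wide <- split(sub, sub$tissue)
  rows <- lapply(wide, function(g) {
    if (!all(cts %in% g$contrast)) return(NULL)
    data.frame(tissue = g$tissue[1],
               abs_delta_sum = sum(abs(g$delta[match(cts, g$contrast)])),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || !nrow(out)) {
    stop("no tissue has both ", effect, " contrasts", call. = FALSE)
  }
  total <- sum(out$abs_delta_sum)
  if (total == 0) {
    stop("all mean differences are zero; percent contributions undefined",
         call. = FALSE)
  }
  out$percent <- 100 * out$abs_delta_sum / total
  out <- out[order(out$abs_delta_sum, out$tissue), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "total") <- total
  out
}

#' Compare the cross-tissue activity distributions of two groups
#'
#' Two-sample Kolmogorov–Smirnov test on the vectors of per-tissue group
#' means (systems-level comparison: does the overall distribution of
#' activity across organs differ, irrespective of which tissue changed).
#'
#' @param a,b Numeric vectors of per-tissue means for the two groups.
#' @return KS p-value.
#' @export
distribution_compare <- function(a, b) {
  if (length(a) != length(b)) {
    stop("per-tissue mean vectors must be paired by tissue (equal length)",
         call. = FALSE)
  }
  suppressWarnings(stats::ks.test(a, b)$p.value)
}

#' PCA of group activity profiles
#'
#' Rows are profiles (typically the four group-level tissue-mean profiles),
#' columns are tissues. Columns containing any missing value (e.g. the
#' sex-specific reproductive tissues, absent from two groups) are dropped,
#' then columns are centered and, by default, unit-scaled.
#'
#' @param profiles Numeric matrix, rows = groups/samples, columns = tissues.
#' @param scale. Scale columns to unit variance (default `TRUE`);
#'   zero-variance columns are dropped before scaling.
#' @return List: `coords` (rows x components scores), `explained_var`
#'   (fraction of variance per component), `dropped_columns`.
#' @export
pca_embed <- function(profiles, scale. = TRUE) {
  stopifnot(is.matrix(profiles), nrow(profiles) >= 2L)
  complete <- colSums(!is.finite(profiles)) == 0
  dropped <- colnames(profiles)[!complete]
  m <- profiles[, complete, drop = FALSE]
  if (scale.) {
    sds <- apply(m, 2, stats::sd)
    zero_var <- sds == 0
    dropped <- c(dropped, colnames(m)[zero_var])
    m <- m[, !zero_var, drop = FALSE]
  }
  if (!ncol(m)) stop("no usable columns for PCA", call. = FALSE)
  pc <- stats::prcomp(m, center = TRUE, scale. = scale.)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  list(coords = pc$x, explained_var = ev, dropped_columns = dropped)
}

#' Categorize each tissue's aging response across the sexes
#'
#' Uses the sign of log2(old/young) in males and in females: both positive
#' is a shared Increase, both negative a shared Decrease, opposite strict
#' signs Divergent. With a sign threshold `eps` (default 0, strict signs),
#' a magnitude <= eps in either sex yields NearZero, reported separately.
#'
#' @param log2fc_male,log2fc_female Named numeric vectors of per-tissue
#'   log2(old/young); names must match (reproductive tissues excluded by
#'   the caller).
#' @param eps Non-negative sign threshold. Default 0.
#' @return Data frame `tissue`, `male_direction`, `female_direction`
#'   (-1/0/+1), `category` in {Increased, Decreased, Divergent, NearZero};
#'   attribute `counts` is the per-category tally.
#' @export
categorize_aging <- function(log2fc_male, log2fc_female, eps = 0) {
  tissues <- names(log2fc_male)
  if (is.null(tissues) || !setequal(tissues, names(log2fc_female))) {
    stop("male and female log2fc vectors must share tissue names",
         call. = FALSE)
  }
  tissues <- sort(tissues)
  m <- log2fc_male[tissues]; f <- log2fc_female[tissues]
  if (anyNA(m) || anyNA(f)) {
    stop("log2fc undefined for some tissue; categorization needs both sexes",
         call. = FALSE)
  }
  sgn <- function(x) ifelse(x > eps, 1L, ifelse(x < -eps, -1L, 0L))
  sm <- sgn(m); sf <- sgn(f)
  category <- ifelse(sm == 1L & sf == 1L, "Increased",
              ifelse(sm == -1L & sf == -1L, "Decreased",
              ifelse(sm * sf == -1L, "Divergent", "NearZero")))
  out <- data.frame(tissue = tissues, male_direction = sm,
                    female_direction = sf, category = category,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "counts") <- table(factor(
    category, levels = c("Increased", "Decreased", "Divergent", "NearZero")))
  out
}

#' Intersection of two significant-tissue sets
#'
#' @param set_a,set_b Character vectors of tissue names.
#' @return Sorted character vector of shared tissues.
#' @export
intersect_significant <- function(set_a, set_b) {
  sort(intersect(unique(set_a), unique(set_b)))
}
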