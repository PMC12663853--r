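#!/usr/bin/env Rscript
# Cross-group analytics of the atlas: per-group tissue rankings, the four
# Welch contrasts with letter tiers, significance counts (age vs sex),
# cumulative |delta| attribution, systems-level distribution comparisons,
# PCA of group profiles, and aging-response categorization.

suppressMessages(library(cvatlas))

normalized <- utils::read.csv("results/normalized_activity.csv",
                              stringsAsFactors = FALSE)
gm <- build_group_matrix(normalized)

rankings <- do.call(rbind, lapply(GROUP_LEVELS, function(g) {
  r <- rank_tissues(gm, g); r$group <- g; r
}))
utils::write.csv(rankings, "results/rankings.csv", row.names = FALSE)
top_ym <- utils::head(rankings$tissue[rankings$group == "YM"], 5)
cat("Highest young-male activity:", paste(top_ym, collapse = ", "), "\n")

contrasts <- contrast_table(gm)
utils::write.csv(contrasts, "results/contrasts.csv", row.names = FALSE)
cs <- count_significant(contrasts)
cat(sprintf("Significant tissues per contrast: %s.\n",
            paste(names(cs$per_contrast), cs$per_contrast, sep = "=",
                  collapse = ", ")))
cat(sprintf("Age effect total %d vs sex effect total %d: age %s.\n",
            cs$age_effect, cs$sex_effect,
            ifelse(cs$age_effect > cs$sex_effect,
                   "dominates", "does not dominate")))

for (eff in c("age", "sex")) {
  at <- cumulative_attribution(contrasts, eff)
  utils::write.csv(at, sprintf("results/attribution_%s.csv", eff),
                   row.names = FALSE)
  top <- utils::tail(at, 3)
  cat(sprintf("Top %s-effect contributors: %s.\n", eff,
              paste(sprintf("%s (%.1f%%)", top$tissue, top$percent),
                    collapse = ", ")))
}

# systems-level: distribution of per-tissue means, old vs young and M vs F
mean_of <- function(g) vapply(gm$tissues, function(tt) {
  x <- gm$values[[tt]][[g]]
  if (length(x)) mean(x) else NA_real_
}, numeric(1))
prof <- vapply(GROUP_LEVELS, mean_of, numeric(length(gm$tissues)))
rownames(prof) <- gm$tissues
cross <- is.na(gm$sex_restricted)
ks <- c(OMvsYM = distribution_compare(prof[cross, "OM"], prof[cross, "YM"]),
        OFvsYF = distribution_compare(prof[cross, "OF"], prof[cross, "YF"]),
        YMvsYF = distribution_compare(prof[cross, "YM"], prof[cross, "YF"]),
        OMvsOF = distribution_compare(prof[cross, "OM"], prof[cross, "OF"]))
utils::write.csv(data.frame(comparison = names(ks), ks_p = ks),
                 "results/distribution_tests.csv", row.names = FALSE)
cat("Systems-level KS p-values:",
    paste(names(ks), signif(ks, 3), sep = "=", collapse = ", "), "\n")

pca <- pca_embed(t(prof))
utils::write.csv(data.frame(group = rownames(pca$coords), pca$coords),
                 "results/pca_coords.csv", row.names = FALSE)
cat(sprintf("PCA: PC1 %.0f%%, PC2 %.0f%% of variance.\n",
            100 * pca$explained_var[1], 100 * pca$explained_var[2]))

l2m <- stats::setNames(contrasts$log2fc[contrasts$contrast == "OMvsYM"],
                       contrasts$tissue[contrasts$contrast == "OMvsYM"])
l2f <- stats::setNames(contrasts$log2fc[contrasts$contrast == "OFvsYF"],
                       contrasts$tissue[contrasts$contrast == "OFvsYF"])
ok <- gm$tissues[cross]
cats <- categorize_aging(l2m[ok], l2f[ok])
utils::write.csv(cats, "results/aging_categories.csv", row.names = FALSE)
print(attr(cats, "counts"))

sig_up <- function(cn) {
  s <- contrasts[contrasts$contrast == cn & contrasts$tier != "none" &
                   contrasts$delta > 0, ]
  s$tissue
}
shared_up <- intersect_significant(sig_up("OMvsYM"), sig_up("OFvsYF"))
cat("Tissues with a significant age increase in both sexes:",
    if (length(shared_up)) paste(shared_up, collapse = ", ") else "none",
    "\n")
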