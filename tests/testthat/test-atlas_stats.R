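make_gm <- function(means, n = 5, sd = 0, group = "YM", seed = 1) {
  # group_matrix with prescribed per-tissue means in one group
  set.seed(seed)
  df <- do.call(rbind, lapply(names(means), function(tt) {
    do.call(rbind, lapply(GROUP_LEVELS, function(g) {
      mu <- if (g == group) means[[tt]] else 1
      data.frame(animal_id = paste0(g, seq_len(n)), tissue = tt,
                 sex = ifelse(substr(g, 2, 2) == "M", "male", "female"),
                 age_group = ifelse(substr(g, 1, 1) == "Y", "young",
                                    "old"),
                 activity_norm = mu + rnorm(n, 0, sd),
                 stringsAsFactors = FALSE)
    }))
  }))
  build_group_matrix(df)
}

test_that("tissue ranking sorts by mean, ties broken by name", {
  gm <- make_gm(c(Liver = 5, Lung = 9, Skin = 1))
  r <- rank_tissues(gm, "YM")
  expect_equal(r$tissue, c("Lung", "Liver", "Skin"))
  expect_equal(r$mean, c(9, 5, 1))
  expect_equal(r$sem, rep(0, 3))

  tie <- rank_tissues(make_gm(c(Skin = 4, Liver = 4)), "YM")
  expect_equal(tie$tissue, c("Liver", "Skin"))

  # sort oracle on a random matrix
  set.seed(5)
  means <- stats::setNames(runif(8, 0, 10), paste0("T", 1:8))
  r2 <- rank_tissues(make_gm(as.list(means)), "YM")
  expect_equal(r2$tissue, names(sort(means, decreasing = TRUE)))
  expect_error(rank_tissues(gm, "XX"), "unknown group")
})

test_that("contrast test matches the Welch oracle", {
  a <- c(10, 11, 12, 9, 10); b <- c(2, 3, 2, 1, 2)
  ct <- contrast_test(a, b)
  # frozen values from an independent textbook Welch computation
  expect_equal(ct$t, 14, tolerance = 1e-10)
  expect_equal(ct$df, 6.68041237113402, tolerance = 1e-10)
  expect_equal(ct$p_value, 3.3784421004216644e-06, tolerance = 1e-10)
  expect_equal(ct$delta, 8.4)
  expect_equal(ct$log2fc, log2(10.4 / 2))

  # identical groups: zero effect, p = 1
  x <- c(1, 2, 3, 4, 5)
  id <- contrast_test(x, x)
  expect_equal(id$delta, 0)
  expect_equal(id$log2fc, 0)
  expect_equal(id$p_value, 1)

  expect_error(contrast_test(1, c(1, 2)), ">= 2")

  # degenerate zero-variance data
  expect_equal(welch_test(c(2, 2), c(2, 2))$p_value, 1)
  expect_equal(welch_test(c(2, 2), c(3, 3))$p_value, 0)

  # log2fc undefined when a mean is non-positive
  expect_true(is.na(contrast_test(c(-1, -2, 0), c(1, 2, 3))$log2fc))
})

test_that("welch machinery agrees with stats::t.test on random data", {
  set.seed(13)
  for (i in 1:20) {
    a <- rnorm(sample(3:12, 1), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(3:12, 1), mean = runif(1, -1, 1))
    w <- welch_test(a, b)
    tt <- stats::t.test(a, b)
    expect_equal(w$t, unname(tt$statistic), tolerance = 1e-12)
    expect_equal(w$df, unname(tt$parameter), tolerance = 1e-12)
    expect_equal(w$p_value, tt$p.value, tolerance = 1e-12)
  }
  A <- matrix(rnorm(50 * 6), 50); B <- matrix(rnorm(50 * 8, 0.5), 50)
  wr <- welch_test_rows(A, B)
  for (i in c(1, 17, 50)) {
    tt <- stats::t.test(A[i, ], B[i, ])
    expect_equal(wr$p_value[i], tt$p.value, tolerance = 1e-12)
  }
})

test_that("letter tiers use strict thresholds, most stringent first", {
  expect_equal(significance_tier(c(0.03, 0.0005)), c("a", "c"))
  expect_equal(significance_tier(0.05), "none")
  expect_equal(significance_tier(c(0.01, 0.001, 0.0001)),
               c("a", "b", "c"))
  expect_equal(significance_tier(0), "d")
  expect_error(significance_tier(1.2), "\\[0, 1\\]")

  # monotonicity: smaller p is never less stringent
  set.seed(2)
  p <- sort(runif(100))
  lev <- c(none = 0, a = 1, b = 2, c = 3, d = 4)
  expect_true(all(diff(lev[significance_tier(p)]) <= 0))
})

test_that("significance counting sums per contrast and per effect", {
  tissues <- paste0("T", 1:6)
  tab <- toy_contrast_table(tissues, c(OMvsYM = 3L, OFvsYF = 2L,
                                       YMvsYF = 1L, OMvsOF = 1L))
  cs <- count_significant(tab)
  expect_equal(unname(cs$per_contrast), c(3L, 2L, 1L, 1L))
  expect_equal(cs$age_effect, 5L)
  expect_equal(cs$sex_effect, 2L)

  null_tab <- toy_contrast_table(tissues, c(OMvsYM = 0L, OFvsYF = 0L,
                                            YMvsYF = 0L, OMvsOF = 0L))
  cs0 <- count_significant(null_tab)
  expect_equal(cs0$age_effect + cs0$sex_effect, 0L)
})

test_that("attribution sums |delta| over an effect's contrasts, ascending", {
  tab <- rbind(
    data.frame(tissue = "A", contrast = c("OMvsYM", "OFvsYF"),
               effect = "age", mean_a = 1, mean_b = 1,
               delta = c(1.5, -0.5), log2fc = 0, p_value = 0.5,
               tier = "none"),
    data.frame(tissue = "B", contrast = c("OMvsYM", "OFvsYF"),
               effect = "age", mean_a = 1, mean_b = 1, delta = c(-4, 4),
               log2fc = 0, p_value = 0.5, tier = "none"))
  at <- cumulative_attribution(tab, "age")
  expect_equal(at$tissue, c("A", "B"))
  expect_equal(at$abs_delta_sum, c(2, 8))
  expect_equal(at$percent, c(20, 80))
  expect_equal(attr(at, "total"), 10)

  single <- cumulative_attribution(tab[tab$tissue == "A", ], "age")
  expect_equal(single$percent, 100)

  zero <- transform(tab, delta = 0)
  expect_error(cumulative_attribution(zero, "age"), "zero")
})

test_that("attribution percentages conserve mass on random instances", {
  set.seed(99)
  for (i in 1:500) {
    k <- sample(2:12, 1)
    tab <- data.frame(
      tissue = rep(paste0("T", seq_len(k)), each = 2),
      contrast = rep(c("OMvsYM", "OFvsYF"), k), effect = "age",
      mean_a = 1, mean_b = 1, delta = rnorm(2 * k, 0, 10),
      log2fc = 0, p_value = 0.5, tier = "none",
      stringsAsFactors = FALSE)
    at <- cumulative_attribution(tab, "age")
    expect_equal(sum(at$percent), 100, tolerance = 1e-9)
  }
  # dropping the top contributor renormalizes without reordering the rest
  set.seed(100)
  tab <- data.frame(tissue = rep(paste0("T", 1:8), each = 2),
                    contrast = rep(c("OMvsYM", "OFvsYF"), 8),
                    effect = "age", mean_a = 1, mean_b = 1,
                    delta = rnorm(16, 0, 3), log2fc = 0, p_value = 0.5,
                    tier = "none", stringsAsFactors = FALSE)
  at <- cumulative_attribution(tab, "age")
  top <- at$tissue[nrow(at)]
  at2 <- cumulative_attribution(tab[tab$tissue != top, ], "age")
  expect_equal(at2$tissue, at$tissue[-nrow(at)])
})

test_that("systems-level distribution comparison behaves like KS", {
  x <- rnorm(32)
  expect_equal(distribution_compare(x, x), 1)
  shifted <- x + 10 * diff(range(x))
  expect_lt(distribution_compare(x, shifted), 0.01)
  expect_equal(distribution_compare(sample(x), x), 1)
  expect_equal(distribution_compare(x, shifted),
               suppressWarnings(stats::ks.test(x, shifted)$p.value))
  expect_error(distribution_compare(x, x[-1]), "equal length")
})

test_that("PCA embedding matches an independent eigendecomposition", {
  m <- matrix(rnorm(80), nrow = 8,
              dimnames = list(NULL, paste0("T", 1:10)))
  pe <- pca_embed(m, scale. = TRUE)
  z <- scale(m, center = TRUE, scale = TRUE)
  eig <- eigen(stats::cov(z))
  scores <- z %*% eig$vectors
  for (j in 1:3) {
    expect_equal(abs(pe$coords[, j]), abs(scores[, j]), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
  # 8 profiles span at most 7 dimensions; compare the informative ones
  expect_equal(pe$explained_var[1:6],
               (eig$values / sum(eig$values))[1:6], tolerance = 1e-8)
  expect_equal(sum(pe$explained_var), 1, tolerance = 1e-12)

  # identical rows land on identical coordinates
  two <- rbind(m[1, ], m[1, ], m[2, ])
  pe2 <- pca_embed(two, scale. = FALSE)
  expect_equal(pe2$coords[1, ], pe2$coords[2, ], tolerance = 1e-12)

  # rank-1 input: one component carries all variance
  r1 <- outer(c(1, 2, 3, 5), rnorm(6))
  colnames(r1) <- paste0("T", 1:6)
  pr1 <- pca_embed(r1, scale. = FALSE)
  expect_equal(pr1$explained_var[1], 1, tolerance = 1e-12)

  # missing columns (sex-specific tissues) are dropped, not imputed
  m2 <- m; m2[1, 3] <- NA
  expect_true("T3" %in% pca_embed(m2)$dropped_columns)
})

test_that("aging categories follow the sign trichotomy", {
  m <- c(A = 0.5, B = -0.3, C = 0, D = -0.2)
  f <- c(A = 0.2, B = 0.4, C = 0.4, D = -0.6)
  cat <- categorize_aging(m, f)
  expect_equal(stats::setNames(cat$category, cat$tissue),
               c(A = "Increased", B = "Divergent", C = "NearZero",
                 D = "Decreased"))
  cnt <- attr(cat, "counts")
  expect_equal(unname(cnt[c("Increased", "Decreased", "Divergent",
                            "NearZero")]), rep(1L, 4), ignore_attr = TRUE)
  # eps widens the near-zero band
  cat2 <- categorize_aging(m, f, eps = 0.25)
  expect_equal(cat2$category[cat2$tissue == "D"], "NearZero")
  expect_error(categorize_aging(c(A = 1), c(B = 1)), "share")
})

test_that("delta and log2fc are antisymmetric under group swap", {
  set.seed(31)
  for (i in 1:20) {
    a <- runif(6, 1, 10); b <- runif(6, 1, 10)
    ab <- contrast_test(a, b); ba <- contrast_test(b, a)
    expect_equal(ab$delta, -ba$delta, tolerance = 1e-12)
    expect_equal(ab$log2fc, -ba$log2fc, tolerance = 1e-12)
    expect_equal(ab$p_value, ba$p_value, tolerance = 1e-12)
  }
})

test_that("set intersection of significant tissues is sorted and exact", {
  male <- c("Heart - atria", "Skeletal muscle - Diaphragm", "GI - Cecum",
            "GI - Small intestine - Ileum", "Adipose - gWAT")
  female <- c("Skeletal muscle - Diaphragm", "GI - Small intestine - Ileum")
  shared <- intersect_significant(male, female)
  expect_equal(shared, sort(female))
  expect_equal(length(shared), 2L)
  expect_equal(intersect_significant(male, character(0)), character(0))
  expect_equal(intersect_significant(male, male), sort(male))
})
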