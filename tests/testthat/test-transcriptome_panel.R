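test_that("the gene panel has 19 unique ortholog pairs", {
  p <- atp_synthase_panel()
  expect_equal(nrow(p), 19L)
  expect_false(anyDuplicated(p$human_symbol) > 0)
  expect_false(anyDuplicated(p$mouse_ortholog) > 0)
  expect_true(all(nzchar(p$human_symbol) & nzchar(p$mouse_ortholog)))
  expect_equal(sum(p$complex_part == "Assembly factor"), 3L)
})

test_that("detection filter applies strict TPM > 1 in >= 30% of rows", {
  tpm <- cbind(
    boundary = c(rep(5, 3), rep(0.5, 7)),   # exactly 30% detected
    allzero = rep(0, 10),
    at_one = rep(1, 10),                    # TPM == 1 is not detected
    detected = rep(10, 10))
  colnames(tpm) <- paste0(colnames(tpm), "_Liver")
  pan <- panel_from_tpm(tpm)
  filt <- filter_detected(pan)
  expect_equal(colnames(filt$tpm), c("boundary_Liver", "detected_Liver"))
  # idempotence
  expect_identical(filter_detected(filt)$tpm, filt$tpm)
})

test_that("age dichotomization uses species-specific boundary rules", {
  mouse <- panel_from_tpm(matrix(1, 4, 1, dimnames = list(NULL, "g_T")),
                          age = c(3, 15, 18, 27))
  s <- split_by_age(mouse)
  expect_equal(s$young, c(1L, 2L))  # 15 months is still young
  expect_equal(s$old, c(3L, 4L))

  human <- panel_from_tpm(matrix(1, 3, 1, dimnames = list(NULL, "g_T")),
                          age = c(30, 50, 51), species = "human")
  sh <- split_by_age(human)
  expect_equal(sh$young, c(1L, 2L))  # old is strictly over 50
  expect_equal(sh$old, 3L)

  # the cutoff is an exposed parameter
  s18 <- split_by_age(mouse, mouse_cutoff = 18)
  expect_equal(s18$young, 1:3)
})

test_that("differential expression matches the t-test oracle with signed
           directions", {
  set.seed(21)
  n <- 20
  null_col <- rnorm(2 * n, 100, 10)
  up <- c(rnorm(n, 100, 10), rnorm(n, 150, 10))  # old shifted +5 sigma
  tpm <- cbind(null_Liver = null_col, up_Liver = up)
  pan <- panel_from_tpm(tpm, age = rep(c(3, 24), each = n))
  res <- diff_expression(pan)
  up_row <- res[res$gene_tissue == "up_Liver", ]
  expect_lt(up_row$p_value, 1e-6)
  expect_equal(up_row$direction, 1)
  idx <- split_by_age(pan)
  oracle <- stats::t.test(tpm[idx$old, "up_Liver"],
                          tpm[idx$young, "up_Liver"])
  expect_equal(up_row$p_value, oracle$p.value, tolerance = 1e-12)
  expect_equal(res$neglog10p, -log10(res$p_value))
  expect_equal(res$gene, c("null", "up"))
  expect_equal(res$tissue, c("Liver", "Liver"))

  # identical groups: p = 1, direction 0
  same <- matrix(rep(c(5, 7, 6, 5, 7, 6), 2), ncol = 2,
                 dimnames = list(NULL, c("a_T", "b_T")))
  pan_same <- panel_from_tpm(same[c(1:3, 1:3), , drop = FALSE],
                             age = rep(c(3, 24), each = 3))
  res_same <- diff_expression(pan_same)
  expect_equal(res_same$p_value, c(1, 1))
  expect_equal(res_same$direction, c(0, 0))

  expect_error(
    diff_expression(panel_from_tpm(
      matrix(1, 3, 1, dimnames = list(NULL, "g_T")), age = c(3, 3, 24))),
    ">= 2")
})

test_that("BH step-up arithmetic and the Storey variant", {
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03, 0.04)),
               stats::p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"))
  # Storey scales BH by the pi0 estimate, never exceeding BH
  p <- c(0.001, 0.2, 0.4, 0.6, 0.8, 0.9)
  expect_true(all(adjust_fdr(p, "storey") <= adjust_fdr(p, "BH") + 1e-15))
})

test_that("swapping age labels flips directions, p-values unchanged", {
  set.seed(33)
  tpm <- matrix(2^rnorm(40, 5), nrow = 10,
                dimnames = list(NULL, paste0("g", 1:4, "_T")))
  age <- rep(c(3, 24), each = 5)
  r1 <- diff_expression(panel_from_tpm(tpm, age = age))
  r2 <- diff_expression(panel_from_tpm(tpm, age = rev(age)))
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-12)
  expect_equal(r1$direction, -r2$direction)
})

test_that("concordance maps tissues through the alias table explicitly", {
  act <- c("Liver" = 1, "Spleen" = -1, "Adipose - iWAT" = 1, "Lung" = 0)
  expr <- c(Liver = 1, Spleen = 1, "SubQ/iWAT" = 1, Lung = 1,
            Marrow = -1)
  cc <- concordance(act, expr)
  expect_equal(cc$status[cc$expression_tissue == "Liver"], "concordant")
  expect_equal(cc$status[cc$expression_tissue == "Spleen"], "discordant")
  expect_equal(cc$status[cc$expression_tissue == "SubQ/iWAT"],
               "concordant")
  # zero activity direction and unmapped tissues stay indeterminate
  expect_equal(cc$status[cc$expression_tissue == "Lung"], "indeterminate")
  expect_equal(cc$status[cc$expression_tissue == "Marrow"],
               "indeterminate")

  # toy 5-tissue map with 3 matching signs
  act5 <- c(A = 1, B = 1, C = -1, D = -1, E = 1)
  expr5 <- c(A = 1, B = 1, C = -1, D = 1, E = -1)
  alias5 <- data.frame(expression_tissue = names(expr5),
                       activity_tissue = names(act5))
  cc5 <- concordance(act5, expr5, alias5)
  expect_equal(sum(cc5$status == "concordant"), 3L)
  expect_equal(sum(cc5$status == "discordant"), 2L)
})

test_that("dominant panel direction is the majority significant sign", {
  res <- data.frame(
    gene_tissue = paste0("g", 1:6, "_", rep(c("Liver", "Spleen"), 3)),
    gene = paste0("g", 1:6),
    tissue = rep(c("Liver", "Spleen"), 3),
    direction = c(1, 1, 1, -1, -1, 1),
    p_value = 0.001, q_value = c(0.01, 0.01, 0.01, 0.01, 0.5, 0.5),
    stringsAsFactors = FALSE)
  pd <- panel_direction(res)
  expect_equal(pd[["Liver"]], 1L)   # two significant ups
  expect_equal(pd[["Spleen"]], 0L)  # one up, one down among significant
})
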