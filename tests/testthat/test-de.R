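# Moderated-t differential expression.

makeDesign <- function(nT, nN, paired = FALSE) {
  data.frame(
    sample_id = c(sprintf("t%02d", seq_len(nT)), sprintf("n%02d", seq_len(nN))),
    group = rep(c("tumor", "normal"), c(nT, nN)),
    pair_id = if (paired) c(sprintf("p%02d", seq_len(nT)),
                            sprintf("p%02d", seq_len(nN)))
              else NA_character_,
    stringsAsFactors = FALSE
  )
}

simExpr <- function(nGenes, nT, nN, lfc = 0, sd = 0.3, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(nGenes * (nT + nN), sd = sd), nGenes,
              dimnames = list(sprintf("g%04d", seq_len(nGenes)),
                              c(sprintf("t%02d", seq_len(nT)),
                                sprintf("n%02d", seq_len(nN)))))
  m[, seq_len(nT)] <- m[, seq_len(nT)] + lfc
  m + 8
}

test_that("identical group means give zero fold change, never significant", {
  expr <- simExpr(50, 8, 8, lfc = 0, seed = 2)
  base <- expr[1, ]
  expr[1, ] <- rep(c(7, 8, 9, 8), 4)   # same values in both groups
  de <- differentialExpression(expr, makeDesign(8, 8))
  expect_equal(de$log2FC[1], 0)
  expect_false(de$significant[1])
})

test_that("the significance gate is strict: log2FC exactly 1 fails |FC| > 1", {
  ## paired design with every difference exactly 1: estimated lfc is 1.0
  nP <- 10
  expr <- simExpr(100, nP, nP, seed = 3)
  design <- makeDesign(nP, nP, paired = TRUE)
  ## exactly representable values so the per-pair difference is exactly 1
  expr[1, design$sample_id[design$group == "normal"]] <-
    rep(c(7, 8), length.out = nP)
  expr[1, design$sample_id[design$group == "tumor"]] <-
    expr[1, design$sample_id[design$group == "normal"]] + 1
  de <- differentialExpression(expr, design, paired = TRUE)
  expect_equal(de$log2FC[1], 1)
  expect_lt(de$p[1], 1e-6)            # shrunk variance keeps p finite
  expect_false(de$significant[1])     # "more than one", strictly
  ## and just above the cutoff passes
  expr[1, design$sample_id[design$group == "tumor"]] <-
    expr[1, design$sample_id[design$group == "normal"]] + 1.05
  de2 <- differentialExpression(expr, design, paired = TRUE)
  expect_true(de2$significant[1])
})

test_that("planted effects are detected and the null is calibrated", {
  ## planted log2FC = 2, sigma = 0.3, n = 20/20: detected in all of 50 reps
  hits <- vapply(1:50, function(r) {
    expr <- simExpr(30, 20, 20, seed = 100 + r)
    expr[1, 1:20] <- expr[1, 1:20] + 2
    de <- differentialExpression(expr, makeDesign(20, 20))
    de$significant[1]
  }, logical(1))
  expect_true(all(hits))

  ## null: fraction with p < 0.05 close to 0.05 (scaled-down check)
  set.seed(7)
  nG <- 800; nT <- 16; nN <- 9
  s2true <- 0.09 * 4 / rchisq(nG, df = 4)
  expr <- matrix(rnorm(nG * (nT + nN), sd = sqrt(s2true)), nG,
                 dimnames = list(sprintf("g%04d", 1:nG),
                                 makeDesign(nT, nN)$sample_id))
  de <- differentialExpression(expr, makeDesign(nT, nN))
  expect_gt(mean(de$p < 0.05), 0.02)
  expect_lt(mean(de$p < 0.05), 0.08)
})

test_that("moderated statistics track limma on shared data", {
  skip_if_not_installed("limma")
  set.seed(11)
  nG <- 300; nT <- 10; nN <- 8
  s2true <- 0.04 * 6 / rchisq(nG, df = 6)
  expr <- matrix(rnorm(nG * (nT + nN), sd = sqrt(s2true)), nG,
                 dimnames = list(sprintf("g%04d", 1:nG),
                                 makeDesign(nT, nN)$sample_id))
  expr[1:20, 1:nT] <- expr[1:20, 1:nT] + 1.5
  de <- differentialExpression(expr, makeDesign(nT, nN))

  mm <- cbind(intercept = 1, tumor = rep(c(1, 0), c(nT, nN)))
  fit <- limma::eBayes(limma::lmFit(expr, mm))
  expect_equal(de$log2FC, unname(fit$coefficients[, "tumor"]),
               tolerance = 1e-10)
  expect_equal(attr(de, "prior")$df.prior, fit$df.prior, tolerance = 1e-6)
  expect_equal(attr(de, "prior")$var.prior, fit$s2.prior, tolerance = 1e-6)
  expect_equal(de$t, unname(fit$t[, "tumor"]), tolerance = 1e-8)
  expect_equal(de$p, unname(fit$p.value[, "tumor"]), tolerance = 1e-8)
})

test_that("pairing is used when complete and degrades when incomplete", {
  nP <- 8
  expr <- simExpr(40, nP, nP, seed = 5)
  design <- makeDesign(nP, nP, paired = TRUE)
  deP <- differentialExpression(expr, design)
  expect_true(attr(deP, "paired"))

  design$pair_id[1] <- NA   # a tumor with no partner
  expect_warning(deU <- differentialExpression(expr, design),
                 "incomplete pairing")
  expect_false(attr(deU, "paired"))
  expect_error(differentialExpression(expr, design, paired = TRUE),
               "pair_ids")

  expect_error(differentialExpression(expr[, 1:9], makeDesign(8, 1)),
               "2 samples per group")
})

test_that("the Welch fallback flags zero-variance signatures", {
  expr <- simExpr(20, 6, 6, seed = 8)
  expr[3, ] <- 5   # constant
  expect_warning(de <- differentialExpression(expr, makeDesign(6, 6),
                                              method = "welch"),
                 "zero-variance")
  expect_true(is.na(de$p[3]))
  expect_false(de$significant[3])
  ## eBayes handles the same gene through shrinkage
  de2 <- differentialExpression(expr, makeDesign(6, 6))
  expect_false(is.na(de2$p[3]))
})
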