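# Median split, Kaplan-Meier, log-rank and Cox regression.

test_that("medianSplit sends ties at the median to the low group", {
  g <- medianSplit(setNames(1:10, paste0("s", 1:10)))
  expect_equal(sum(g == "low"), 5L)
  expect_true(all(g[1:5] == "low") && all(g[6:10] == "high"))
  ## odd n: the median sample itself goes low
  g2 <- medianSplit(c(1, 2, 3))
  expect_equal(as.character(g2), c("low", "low", "high"))
  expect_error(medianSplit(rep(2, 6)), "degenerate")
  expect_error(medianSplit(5), "at least 2")
})

test_that("KM equals the empirical survival function without censoring", {
  set.seed(3)
  t <- round(rexp(40, 0.1), 2) + 0.01
  km <- kmEstimate(t, rep(1L, 40))
  for (i in seq_len(nrow(km))) {
    expect_equal(km$survival[i], mean(t > km$time[i]))
  }
  ## all censored: flat at 1
  km0 <- kmEstimate(t, rep(0L, 40))
  expect_true(all(km0$survival == 1))
})

test_that("KM matches the survival package estimator", {
  skip_if_not_installed("survival")
  set.seed(4)
  t <- rexp(60); e <- rbinom(60, 1, 0.7)
  g <- rep(c("a", "b"), 30)
  km <- kmEstimate(t, e, g)
  for (lev in c("a", "b")) {
    sf <- survival::survfit(
      survival::Surv(t[g == lev], e[g == lev]) ~ 1)
    mine <- km[km$group == lev & km$time > 0, ]
    expect_equal(mine$time, sf$time, tolerance = 1e-12)
    expect_equal(mine$survival, sf$surv, tolerance = 1e-12)
    expect_equal(mine$nRisk, sf$n.risk)
    expect_equal(mine$nEvent, sf$n.event)
  }
})

test_that("log-rank statistic equals the hand-tabulated hypergeometric sum", {
  ## group A events at 1,2,3; group B events at 4,5,6:
  ## E_A = 3/6 + 2/5 + 1/4 = 1.15, U = 1.85,
  ## V = 0.25 + 0.24 + 0.1875 = 0.6775, U^2/V = 5.05166...
  t <- 1:6; e <- rep(1L, 6); g <- rep(c("A", "B"), each = 3)
  lr <- logrankTest(t, e, g)
  expect_equal(lr$statistic, 1.85^2 / 0.6775, tolerance = 1e-12)
  expect_lt(lr$p, 0.05)
  expect_equal(unname(lr$observed), c(3, 3))
  expect_equal(sum(lr$observed - lr$expected), 0, tolerance = 1e-12)

  ## symmetric under group relabelling
  lr2 <- logrankTest(t, e, factor(g, levels = c("B", "A")))
  expect_equal(lr2$statistic, lr$statistic)

  ## identical groups (same data duplicated): statistic 0, p 1
  lr3 <- logrankTest(c(t, t), c(e, e), rep(c("A", "B"), each = 6))
  expect_equal(lr3$statistic, 0, tolerance = 1e-12)
  expect_equal(lr3$p, 1)

  expect_error(logrankTest(t, rep(0L, 6), g), "no events")
})

test_that("log-rank agrees with survival::survdiff", {
  skip_if_not_installed("survival")
  set.seed(6)
  t <- rexp(80, rate = rep(c(1, 2), 40)); e <- rbinom(80, 1, 0.8)
  g <- rep(c("a", "b"), 40)
  lr <- logrankTest(t, e, g)
  sd_ <- survival::survdiff(survival::Surv(t, e) ~ g)
  expect_equal(lr$statistic, unname(sd_$chisq), tolerance = 1e-9)
})

test_that("Cox partial likelihood matches a brute-force oracle on toy data", {
  ## n = 4, single binary covariate, no censoring, no ties
  t <- c(1, 2, 3, 4); e <- rep(1L, 4); z <- c(1, 0, 1, 0)
  ## independent oracle: hand-enumerated risk-set product
  bruteLoglik <- function(b) {
    ll <- 0
    for (i in order(t)) {
      risk <- which(t >= t[i])
      ll <- ll + b * z[i] - log(sum(exp(b * z[risk])))
    }
    ll
  }
  bHat <- optimize(bruteLoglik, c(-5, 5), maximum = TRUE, tol = 1e-10)
  fit <- coxFit(t, e, data.frame(z = z))
  expect_equal(fit$beta, bHat$maximum, tolerance = 1e-4)
  expect_equal(attr(fit, "loglik")[["multivariate"]], bHat$objective,
               tolerance = 1e-8)
  expect_equal(fit$HR, exp(fit$beta))
  expect_equal(fit$ciLow, exp(fit$beta - 1.96 * fit$SE))
})

test_that("Cox estimates agree with survival::coxph under Breslow ties", {
  skip_if_not_installed("survival")
  set.seed(8)
  n <- 120
  z1 <- rnorm(n); z2 <- factor(sample(c("lo", "mid", "hi"), n, TRUE),
                               levels = c("lo", "mid", "hi"))
  t <- ceiling(rexp(n, exp(0.5 * z1)) * 20)  # integer times force ties
  e <- rbinom(n, 1, 0.8)
  fit <- coxFit(t, e, data.frame(z1 = z1, z2 = z2))
  ref <- survival::coxph(survival::Surv(t, e) ~ z1 + z2, ties = "breslow")
  expect_equal(fit$beta, unname(coef(ref)), tolerance = 1e-6)
  expect_equal(fit$SE, unname(sqrt(diag(vcov(ref)))), tolerance = 1e-6)
})

test_that("univariate sweep fits one model per covariate", {
  set.seed(9)
  n <- 100
  covs <- data.frame(z1 = rnorm(n), z2 = rbinom(n, 1, 0.5))
  t <- rexp(n, exp(0.8 * covs$z2)); e <- rbinom(n, 1, 0.8)
  uni <- coxFit(t, e, covs, mode = "univariate")
  expect_equal(uni$model, c("z1", "z2"))
  one <- coxFit(t, e, covs["z2"])
  expect_equal(uni$beta[uni$model == "z2"], one$beta, tolerance = 1e-10)
})

test_that("Cox recovers a planted log hazard ratio", {
  betas <- vapply(1:10, function(s) {
    d <- simulateSurvival(300, beta = 1, seed = 400 + s)
    coxFit(d$time, d$event, d["z"])$beta
  }, numeric(1))
  expect_gt(median(betas), 0.75)
  expect_lt(median(betas), 1.25)
})

test_that("degenerate Cox inputs are rejected or flagged", {
  t <- c(1, 2, 3, 4, 5, 6); e <- rep(1L, 6)
  expect_error(coxFit(t, e, data.frame(z = rep(1, 6))), "constant")
  expect_error(coxFit(t, rep(0L, 6), data.frame(z = rnorm(6))), "no events")
  ## perfect separation: z perfectly ranks survival -> monotone likelihood
  expect_warning(
    fit <- coxFit(c(1, 2, 3, 10, 11, 12), e,
                  data.frame(z = c(1, 1, 1, 0, 0, 0))),
    "did not converge")
  expect_false(fit$converged)
  expect_true(is.na(fit$beta))
})
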