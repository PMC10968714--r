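# Median-split survival analysis: Kaplan-Meier product-limit estimator,
# two-group log-rank test, and Cox proportional hazards regression by
# Newton-Raphson on the Breslow partial likelihood.

#' Split samples at the median expression
#'
#' Values less than or equal to the median go to `"low"`, values above it
#' to `"high"` (ties at the median go to low).
#'
#' @param values numeric vector (optionally named by sample).
#' @return factor with levels `low`, `high`, same names as `values`.
#' @export
medianSplit <- function(values) {
  if (length(values) < 2L) stop("need at least 2 samples", call. = FALSE)
  if (anyNA(values)) stop("missing values in expression vector", call. = FALSE)
  med <- stats::median(values)
  if (all(values == values[1L])) {
    stop("degenerate split: all expression values identical", call. = FALSE)
  }
  g <- factor(ifelse(values <= med, "low", "high"), levels = c("low", "high"))
  names(g) <- names(values)
  g
}

.checkSurv <- function(time, event) {
  if (length(time) != length(event)) {
    stop("time and event lengths differ", call. = FALSE)
  }
  if (anyNA(time) || anyNA(event)) stop("missing survival data", call. = FALSE)
  if (any(time <= 0)) stop("survival times must be positive", call. = FALSE)
  if (!all(event %in% c(0, 1))) stop("event must be 0/1", call. = FALSE)
  invisible(NULL)
}

#' Kaplan-Meier product-limit estimate
#'
#' Right-censored product-limit estimator, optionally per group. The curve
#' starts at S(0) = 1 and is non-increasing; with no events it stays flat
#' at 1.
#'
#' @param time positive follow-up times.
#' @param event event indicator (1 = event, 0 = censored).
#' @param group optional grouping factor (one curve per level).
#' @return `data.frame` with columns `group`, `time`, `nRisk`, `nEvent`,
#'   `nCensor`, `survival` (one row per distinct time, plus the time-0
#'   anchor row).
#' @export
kmEstimate <- function(time, event, group = NULL) {
  .checkSurv(time, event)
  if (is.null(group)) group <- rep("all", length(time))
  group <- as.factor(group)
  out <- lapply(levels(group), function(g) {
    t <- time[group == g]; e <- event[group == g]
    ut <- sort(unique(t))
    nRisk <- vapply(ut, function(u) sum(t >= u), integer(1))
    nEvent <- vapply(ut, function(u) sum(t == u & e == 1), integer(1))
    nCensor <- vapply(ut, function(u) sum(t == u & e == 0), integer(1))
    surv <- cumprod(1 - nEvent / nRisk)
    data.frame(group = g,
               time = c(0, ut),
               nRisk = c(length(t), nRisk),
               nEvent = c(0L, nEvent),
               nCensor = c(0L, nCensor),
               survival = c(1, surv),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Two-group log-rank test
#'
#' At each distinct event time the observed minus hypergeometric-expected
#' events in group 1 and the hypergeometric variance are accumulated; the
#' statistic `U^2 / V` is referred to chi-square with 1 df.
#'
#' @inheritParams kmEstimate
#' @param group factor with exactly two levels.
#' @return list with `statistic`, `df`, `p`, `observed`, `expected` (per
#'   group, ordered by factor level) and `variance`.
#' @export
logrankTest <- function(time, event, group) {
  .checkSurv(time, event)
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2L) {
    stop("log-rank test needs exactly two groups", call. = FALSE)
  }
  group <- droplevels(group)
  if (sum(event) == 0) {
    stop("no events: log-rank test undefined", call. = FALSE)
  }
  g1 <- levels(group)[1L]
  eventTimes <- sort(unique(time[event == 1]))
  U <- 0; V <- 0; O1 <- 0; E1 <- 0
  for (u in eventTimes) {
    atRisk <- time >= u
    n <- sum(atRisk)
    n1 <- sum(atRisk & group == g1)
    d <- sum(time == u & event == 1)
    d1 <- sum(time == u & event == 1 & group == g1)
    e1 <- d * n1 / n
    O1 <- O1 + d1
    E1 <- E1 + e1
    if (n > 1) {
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
  }
  U <- O1 - E1
  D <- sum(event)
  if (V <= 0) stop("zero log-rank variance", call. = FALSE)
  stat <- U^2 / V
  list(statistic = stat, df = 1L,
       p = stats::pchisq(stat, df = 1L, lower.tail = FALSE),
       observed = stats::setNames(c(O1, D - O1), levels(group)),
       expected = stats::setNames(c(E1, D - E1), levels(group)),
       variance = V)
}

## Dummy-encode a covariate table against stated reference levels
## (first level by default). Returns the model matrix without intercept.
.coxModelMatrix <- function(covariates, refLevels = NULL) {
  cols <- list()
  for (nm in names(covariates)) {
    v <- covariates[[nm]]
    if (is.numeric(v)) {
      if (stats::var(v) == 0) {
        stop("covariate '", nm, "' is constant", call. = FALSE)
      }
      cols[[nm]] <- v
    } else {
      f <- as.factor(v)
      ref <- refLevels[[nm]] %||% levels(f)[1L]
      if (!ref %in% levels(f)) {
        stop("reference level '", ref, "' not found for '", nm, "'",
             call. = FALSE)
      }
      f <- stats::relevel(f, ref = ref)
      if (nlevels(f) < 2L) {
        stop("covariate '", nm, "' is constant", call. = FALSE)
      }
      for (lv in levels(f)[-1L]) {
        cols[[paste0(nm, lv)]] <- as.numeric(f == lv)
      }
    }
  }
  do.call(cbind, cols)
}

## Newton-Raphson maximisation of the Breslow partial likelihood.
## Returns beta, the observed information, the log partial likelihood and a
## convergence flag. Monotone likelihood (perfect separation) is reported
## as non-convergence.
.coxNewton <- function(time, event, X, tol = 1e-8, maxIter = 50L) {
  p <- ncol(X)
  beta <- rep(0, p)
  ord <- order(time, decreasing = TRUE)
  t_s <- time[ord]; e_s <- event[ord]; X_s <- X[ord, , drop = FALSE]
  converged <- FALSE
  loglik <- NA_real_
  info <- matrix(NA_real_, p, p)
  for (iter in seq_len(maxIter)) {
    eta <- drop(X_s %*% beta)
    w <- exp(eta)
    U <- rep(0, p); I <- matrix(0, p, p); ll <- 0
    S0 <- 0; S1 <- rep(0, p); S2 <- matrix(0, p, p)
    i <- 1L
    n <- length(t_s)
    while (i <= n) {
      ## add the whole tie block at this time to the risk set
      j <- i
      while (j <= n && t_s[j] == t_s[i]) j <- j + 1L
      idx <- i:(j - 1L)
      for (k in idx) {
        S0 <- S0 + w[k]
        S1 <- S1 + w[k] * X_s[k, ]
        S2 <- S2 + w[k] * tcrossprod(X_s[k, ])
      }
      dIdx <- idx[e_s[idx] == 1]
      d <- length(dIdx)
      if (d > 0) {
        xbar <- S1 / S0
        ll <- ll + sum(eta[dIdx]) - d * log(S0)
        U <- U + colSums(X_s[dIdx, , drop = FALSE]) - d * xbar
        I <- I + d * (S2 / S0 - tcrossprod(xbar))
      }
      i <- j
    }
    loglik <- ll
    info <- I
    if (sqrt(sum(U^2)) < tol) { converged <- TRUE; break }
    step <- tryCatch(solve(I, U), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) break
    beta <- beta + step
    if (any(abs(beta) > 20)) break  # monotone likelihood guard
  }
  list(beta = beta, info = info, loglik = loglik, converged = converged,
       iterations = iter)
}

#' Cox proportional hazards regression (Breslow partial likelihood)
#'
#' Maximises the Breslow partial likelihood by Newton-Raphson with analytic
#' gradient and Hessian (tolerance 1e-8 on the score norm, at most 50
#' iterations). Categorical covariates are dummy-encoded against a stated
#' reference level (first level by default). Non-convergence or monotone
#' likelihood (perfect separation) is flagged and no estimates are
#' returned for that model.
#'
#' @inheritParams kmEstimate
#' @param covariates `data.frame` of covariates (numeric or categorical).
#' @param mode `"multivariate"` (one joint model, the default) or
#'   `"univariate"` (one model per covariate, as in a forest-plot sweep).
#' @param refLevels optional named list of reference levels for categorical
#'   covariates.
#' @param tol,maxIter Newton-Raphson controls.
#' @return `data.frame` with one row per term: `model`, `term`, `beta`,
#'   `HR`, `SE`, `z`, `p`, `ciLow`, `ciHigh`, `converged`; attribute
#'   `loglik` carries the log partial likelihood per model.
#' @export
coxFit <- function(time, event, covariates,
                   mode = c("multivariate", "univariate"),
                   refLevels = NULL, tol = 1e-8, maxIter = 50L) {
  mode <- match.arg(mode)
  .checkSurv(time, event)
  covariates <- as.data.frame(covariates, stringsAsFactors = FALSE)
  if (!nrow(covariates) || nrow(covariates) != length(time)) {
    stop("covariate rows must match survival records", call. = FALSE)
  }
  if (sum(event) < 1L) stop("no events: Cox model undefined", call. = FALSE)

  fitOne <- function(covs, modelName) {
    X <- .coxModelMatrix(covs, refLevels)
    if (sum(event) < ncol(X)) {
      stop("fewer events than covariate terms in model '", modelName, "'",
           call. = FALSE)
    }
    fit <- .coxNewton(time, event, X, tol = tol, maxIter = maxIter)
    terms <- colnames(X)
    if (!fit$converged) {
      warning("Cox model '", modelName,
              "' did not converge (possible monotone likelihood); ",
              "no estimates returned", call. = FALSE)
      return(structure(data.frame(
        model = modelName, term = terms, beta = NA_real_, HR = NA_real_,
        SE = NA_real_, z = NA_real_, p = NA_real_, ciLow = NA_real_,
        ciHigh = NA_real_, converged = FALSE, stringsAsFactors = FALSE),
        loglik = NA_real_))
    }
    se <- sqrt(diag(solve(fit$info)))
    z <- fit$beta / se
    structure(data.frame(
      model = modelName, term = terms, beta = fit$beta,
      HR = exp(fit$beta), SE = se, z = z,
      p = 2 * stats::pnorm(-abs(z)),
      ciLow = exp(fit$beta - 1.96 * se),
      ciHigh = exp(fit$beta + 1.96 * se),
      converged = TRUE, stringsAsFactors = FALSE),
      loglik = fit$loglik)
  }

  if (mode == "multivariate") {
    res <- fitOne(covariates, "multivariate")
    attr(res, "loglik") <- stats::setNames(attr(res, "loglik"), "multivariate")
    rownames(res) <- NULL
    return(res)
  }
  fits <- lapply(names(covariates), function(nm) {
    fitOne(covariates[nm], nm)
  })
  out <- do.call(rbind, fits)
  attr(out, "loglik") <- stats::setNames(
    vapply(fits, attr, numeric(1), "loglik"), names(covariates))
  rownames(out) <- NULL
  out
}
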