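# Moderated-t differential expression between tumor and normal groups.
#
# The per-signature residual variances s^2 (df d) are shrunk towards a prior
# (d0, s0^2) fitted by moment matching on log s^2 (trigamma inversion); the
# moderated t uses the posterior variance with d0 + d degrees of freedom.

#' Invert the trigamma function
#'
#' Newton iteration solving `trigamma(y) = x` for `y > 0`; used to
#' moment-match the prior degrees of freedom of the variance distribution.
#'
#' @param x positive numeric vector.
#' @return numeric vector `y` with `trigamma(y) = x` (Inf for `x <= 0`).
#' @export
trigammaInverse <- function(x) {
  y <- rep(NA_real_, length(x))
  y[x > 1e7] <- 1 / sqrt(x[x > 1e7])
  y[x < 1e-6] <- 1 / x[x < 1e-6]
  todo <- is.na(y) & is.finite(x) & x > 0
  yy <- 0.5 + 1 / x[todo]
  for (iter in seq_len(50)) {
    tri <- trigamma(yy)
    dif <- tri * (1 - tri / x[todo]) / psigamma(yy, deriv = 2)
    yy <- yy + dif
    if (max(-dif / yy, 0) < 1e-8) break
  }
  y[todo] <- yy
  y[!is.finite(x) | x <= 0] <- Inf
  y
}

## Moment-matching fit of the scaled inverse chi-square prior for gene-wise
## variances: returns df.prior (possibly Inf) and var.prior.
fitVariancePrior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 2L) {
    return(list(df.prior = 0, var.prior = stats::median(s2[ok], na.rm = TRUE)))
  }
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  n <- length(e)
  evar <- sum((e - emean)^2) / (n - 1L) - trigamma(df / 2)
  if (evar > 0) {
    df.prior <- 2 * trigammaInverse(evar)
    var.prior <- exp(emean + digamma(df.prior / 2) - log(df.prior / 2))
  } else {
    df.prior <- Inf
    var.prior <- exp(emean)
  }
  list(df.prior = df.prior, var.prior = var.prior)
}

squeezeVariances <- function(s2, df, prior) {
  s2 <- ifelse(is.finite(s2), s2, 0)
  if (is.infinite(prior$df.prior)) {
    rep(prior$var.prior, length(s2))
  } else {
    (prior$df.prior * prior$var.prior + df * s2) / (prior$df.prior + df)
  }
}

#' Differential expression between tumor and normal samples
#'
#' Computes the per-signature log2 fold change (tumor minus normal mean on
#' the log2 scale), a moderated t statistic with empirical-Bayes variance
#' shrinkage, two-sided p-values, BH-adjusted q-values and the significance
#' gate `|log2FC| > lfcCut AND p < pCut` (both strict; defaults 1 and
#' 0.05). When complete pairing is available (every sample carries a
#' `pair_id` linking exactly one tumor to one normal), a paired contrast
#' (one-sample analysis of per-pair differences) is used; with
#' `paired = "auto"` incomplete pairing degrades to the unpaired contrast
#' with a warning.
#'
#' @param expr signatures x samples matrix of log2 expression values (or a
#'   `SummarizedExperiment` with a `logTPM` assay).
#' @param design `data.frame` with columns `sample_id`, `group` (values
#'   `"tumor"` / `"normal"`) and optionally `pair_id`.
#' @param lfcCut,pCut significance cutoffs (strict inequalities).
#' @param paired `"auto"`, `TRUE` or `FALSE`.
#' @param method `"eBayes"` (moderated t, default) or `"welch"` (per-gene
#'   Welch t, as a cross-validation fallback; zero-variance genes get `NA`
#'   p with a warning).
#' @return `data.frame` with columns `signature_id`, `log2FC`, `t`, `df`,
#'   `p`, `q`, `significant`, plus attributes `prior` (fitted d0 and s0^2)
#'   and `paired`.
#' @export
differentialExpression <- function(expr, design, lfcCut = 1, pCut = 0.05,
                                   paired = "auto",
                                   method = c("eBayes", "welch")) {
  method <- match.arg(method)
  if (methods::is(expr, "SummarizedExperiment")) {
    expr <- SummarizedExperiment::assay(expr, "logTPM")
  }
  expr <- as.matrix(expr)
  if (!all(c("sample_id", "group") %in% names(design))) {
    stop("design needs columns sample_id and group", call. = FALSE)
  }
  design <- design[match(colnames(expr), design$sample_id), , drop = FALSE]
  if (anyNA(design$sample_id)) {
    stop("design does not cover all expression columns", call. = FALSE)
  }
  grp <- design$group
  if (!all(grp %in% c("tumor", "normal"))) {
    stop("group must be 'tumor' or 'normal'", call. = FALSE)
  }
  nT <- sum(grp == "tumor"); nN <- sum(grp == "normal")
  if (nT < 2L || nN < 2L) {
    stop("need at least 2 samples per group", call. = FALSE)
  }

  usePaired <- FALSE
  if (!identical(paired, FALSE)) {
    pairs <- design$pair_id
    complete <- !is.null(pairs) && !anyNA(pairs) && all(nzchar(pairs)) &&
      nT == nN && all(table(pairs, grp) == 1L)
    if (complete) {
      usePaired <- TRUE
    } else if (isTRUE(paired)) {
      stop("paired = TRUE but pair_ids do not link one tumor to one normal",
           call. = FALSE)
    } else if (identical(paired, "auto") && !is.null(pairs) &&
               any(!is.na(pairs) & nzchar(pairs))) {
      warning("incomplete pairing; falling back to the unpaired contrast",
              call. = FALSE)
    }
  }

  if (usePaired) {
    tumorCols <- design$sample_id[grp == "tumor"]
    pairOfTumor <- design$pair_id[grp == "tumor"]
    normalCols <- design$sample_id[grp == "normal"][
      match(pairOfTumor, design$pair_id[grp == "normal"])]
    d <- expr[, tumorCols, drop = FALSE] - expr[, normalCols, drop = FALSE]
    n <- ncol(d)
    lfc <- rowMeans(d)
    s2 <- apply(d, 1L, stats::var)
    dfResid <- n - 1L
    cScale <- 1 / sqrt(n)
  } else {
    xT <- expr[, grp == "tumor", drop = FALSE]
    xN <- expr[, grp == "normal", drop = FALSE]
    lfc <- rowMeans(xT) - rowMeans(xN)
    ssT <- rowSums((xT - rowMeans(xT))^2)
    ssN <- rowSums((xN - rowMeans(xN))^2)
    dfResid <- nT + nN - 2L
    s2 <- (ssT + ssN) / dfResid
    cScale <- sqrt(1 / nT + 1 / nN)
  }

  if (method == "eBayes") {
    prior <- fitVariancePrior(s2, dfResid)
    s2post <- squeezeVariances(s2, dfResid, prior)
    tstat <- lfc / (sqrt(s2post) * cScale)
    dfTotal <- dfResid + prior$df.prior
    p <- 2 * stats::pt(-abs(tstat), df = dfTotal)
  } else {
    prior <- list(df.prior = 0, var.prior = NA_real_)
    if (usePaired) {
      tstat <- lfc / (sqrt(s2) * cScale)
      dfTotal <- rep(dfResid, length(lfc))
    } else {
      vT <- ssT / (nT - 1L); vN <- ssN / (nN - 1L)
      se2 <- vT / nT + vN / nN
      tstat <- lfc / sqrt(se2)
      dfTotal <- se2^2 / (vT^2 / (nT^2 * (nT - 1L)) +
                          vN^2 / (nN^2 * (nN - 1L)))
    }
    zeroVar <- !is.finite(tstat)
    if (any(zeroVar)) {
      warning(sum(zeroVar), " zero-variance signature(s): p set to NA",
              call. = FALSE)
      tstat[zeroVar] <- NA_real_
    }
    p <- 2 * stats::pt(-abs(tstat), df = dfTotal)
  }

  q <- stats::p.adjust(p, method = "BH")
  out <- data.frame(
    signature_id = rownames(expr) %||% as.character(seq_along(lfc)),
    log2FC = lfc,
    t = tstat,
    df = if (length(dfTotal) == 1L) rep(dfTotal, length(lfc)) else dfTotal,
    p = p,
    q = q,
    significant = !is.na(p) & abs(lfc) > lfcCut & p < pCut,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "prior") <- prior
  attr(out, "paired") <- usePaired
  attr(out, "cutoffs") <- c(lfcCut = lfcCut, pCut = pCut)
  out
}
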