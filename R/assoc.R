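# Clinical association (chi-square) and Spearman top-k correlated genes.

#' Pearson chi-square test of independence
#'
#' Pearson statistic on an r x c contingency table, df = (r-1)(c-1), no
#' continuity correction. All expected counts must be positive.
#'
#' @param tab matrix or `table` of counts.
#' @return list with `statistic`, `df`, `p`, `expected`.
#' @export
chiSquareTest <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || anyNA(tab)) {
    stop("table must contain non-negative counts", call. = FALSE)
  }
  if (nrow(tab) < 2L || ncol(tab) < 2L) {
    stop("table must be at least 2 x 2", call. = FALSE)
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected == 0)) {
    stop("zero expected cell count; merge sparse categories before testing",
         call. = FALSE)
  }
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value, expected = expected)
}

#' Chi-square association of an expression group with pathology categories
#'
#' Cross-tabulates a low/high expression grouping against each categorical
#' clinical column and tests independence.
#'
#' @param groups factor of expression groups (e.g. from [medianSplit()]).
#' @param clinical `data.frame` of clinical variables, rows aligned with
#'   `groups`.
#' @param columns which clinical columns to test (default: all categorical
#'   columns).
#' @return `data.frame` with one row per tested column: `variable`,
#'   `statistic`, `df`, `p`; untestable columns (constant, or zero expected
#'   cells) are reported with `NA` and the reason in `note`.
#' @export
clinicalAssociation <- function(groups, clinical, columns = NULL) {
  if (is.null(columns)) {
    columns <- names(clinical)[!vapply(clinical, is.numeric, logical(1))]
  }
  rows <- lapply(columns, function(nm) {
    v <- clinical[[nm]]
    res <- tryCatch({
      t <- table(groups, v)
      r <- chiSquareTest(t)
      data.frame(variable = nm, statistic = r$statistic, df = r$df, p = r$p,
                 note = "", stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(variable = nm, statistic = NA_real_, df = NA_integer_,
                 p = NA_real_, note = conditionMessage(e),
                 stringsAsFactors = FALSE)
    })
    res
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Top-k genes correlated with a fragment by Spearman's rho
#'
#' Spearman's rho is computed as the Pearson correlation of average-ranked
#' data; the p-value uses the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` with n - 2 df. Genes with zero
#' variance across the shared samples are skipped (with a message). Results
#' are ordered by |rho| descending, then rho descending, then gene id, and
#' the top k are returned.
#'
#' @param target named numeric vector of the fragment's expression, named
#'   by sample.
#' @param mrnaMatrix genes x samples numeric matrix of mRNA expression.
#' @param k number of genes to return (default 500); if k exceeds the
#'   number of usable genes, all are returned with a warning.
#' @return `data.frame` with columns `gene`, `rho`, `p`, `rank`.
#' @export
spearmanTopK <- function(target, mrnaMatrix, k = 500L) {
  mrnaMatrix <- as.matrix(mrnaMatrix)
  shared <- intersect(names(target), colnames(mrnaMatrix))
  if (length(shared) < 4L) {
    stop("need at least 4 shared samples", call. = FALSE)
  }
  x <- target[shared]
  m <- mrnaMatrix[, shared, drop = FALSE]
  keep <- apply(m, 1L, function(r) stats::var(r) > 0)
  if (any(!keep)) {
    message("skipping ", sum(!keep), " zero-variance gene(s)")
    m <- m[keep, , drop = FALSE]
  }
  if (!nrow(m)) stop("no genes with variance to correlate", call. = FALSE)
  n <- length(shared)
  rx <- rank(x)
  rm_ <- t(apply(m, 1L, rank))
  rx0 <- rx - mean(rx)
  rm0 <- rm_ - rowMeans(rm_)
  rho <- drop(rm0 %*% rx0) / (sqrt(rowSums(rm0^2)) * sqrt(sum(rx0^2)))
  rho <- pmin(1, pmax(-1, rho))
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(rho) == 1] <- 0
  out <- data.frame(gene = rownames(m), rho = rho, p = p,
                    stringsAsFactors = FALSE)
  out <- out[order(-abs(out$rho), -out$rho, out$gene), , drop = FALSE]
  if (k > nrow(out)) {
    warning("k = ", k, " exceeds ", nrow(out), " usable genes; returning all",
            call. = FALSE)
    k <- nrow(out)
  }
  out <- out[seq_len(k), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
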