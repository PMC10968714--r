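# Over-representation analysis (hypergeometric) and permutation GSEA
# against user-supplied GMT gene-set collections.

#' Read a GMT gene-set collection
#'
#' @param path GMT file (tab-separated: set name, description, genes...).
#' @return named list of character vectors; duplicate set names or empty
#'   sets are rejected.
#' @export
readGmt <- function(path) {
  sets <- fgsea::gmtPathways(path)
  if (anyDuplicated(names(sets))) {
    stop("duplicate gene-set names in ", path, call. = FALSE)
  }
  if (any(lengths(sets) == 0L)) {
    stop("empty gene set(s) in ", path, ": ",
         paste(names(sets)[lengths(sets) == 0L], collapse = ", "),
         call. = FALSE)
  }
  sets
}

#' Hypergeometric over-representation analysis
#'
#' For each set, `p = P[X >= k]` with X hypergeometric(N, K, n): N universe
#' genes of which K in the set, a query of n genes of which k overlap.
#' Query genes outside the universe are dropped with a warning; sets are
#' intersected with the universe. BH q-values are computed across sets and
#' rows are sorted by q then p.
#'
#' @param queryGenes character vector of query gene ids.
#' @param collection named list of gene sets (see [readGmt()]).
#' @param universe character vector of universe gene ids (e.g. all genes in
#'   the expression matrix).
#' @return `data.frame` with columns `set`, `overlap`, `setSize`,
#'   `querySize`, `universeSize`, `p`, `q`, `genes` (overlap ids,
#'   comma-separated).
#' @export
ora <- function(queryGenes, collection, universe) {
  queryGenes <- unique(queryGenes)
  universe <- unique(universe)
  outside <- setdiff(queryGenes, universe)
  if (length(outside)) {
    warning("dropping ", length(outside),
            " query gene(s) outside the universe", call. = FALSE)
    queryGenes <- intersect(queryGenes, universe)
  }
  if (!length(queryGenes)) {
    stop("empty query after universe filtering", call. = FALSE)
  }
  N <- length(universe)
  n <- length(queryGenes)
  rows <- lapply(names(collection), function(nm) {
    set <- intersect(collection[[nm]], universe)
    K <- length(set)
    hits <- intersect(set, queryGenes)
    k <- length(hits)
    p <- if (K == 0L) 1 else stats::phyper(k - 1L, K, N - K, n,
                                           lower.tail = FALSE)
    data.frame(set = nm, overlap = k, setSize = K, querySize = n,
               universeSize = N, p = p,
               genes = paste(sort(hits), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$q, out$p, out$set),
             c("set", "overlap", "setSize", "querySize", "universeSize",
               "p", "q", "genes")]
  rownames(out) <- NULL
  out
}

## Enrichment score from sorted hit positions within a ranking of N genes.
## `weights` are |score|^w of the hits in ranking order; NR normalises the
## hit increments, misses decrement 1/(N - K). Returns the signed extremum
## of the running sum and its position.
.esFromPositions <- function(positions, weights, N) {
  K <- length(positions)
  NR <- sum(weights)
  miss <- 1 / (N - K)
  if (NR <= 0) {
    ## degenerate all-zero scores: uniform hit increments
    weights <- rep(1, K)
    NR <- K
  }
  hitCum <- cumsum(weights) / NR
  missesBefore <- (positions - seq_len(K)) * miss
  ## running-sum value just after each hit, and just before each hit
  atHit <- hitCum - missesBefore
  beforeHit <- c(0, hitCum[-K]) - missesBefore
  ## between hits the walk only decreases, and after the last hit it
  ## descends to exactly 0, so the extrema lie at/just before hits
  hi <- max(atHit)
  lo <- min(beforeHit)
  if (hi >= -lo) {
    list(es = hi, at = positions[which.max(atHit)])
  } else {
    list(es = lo, at = positions[which.min(beforeHit)] - 1L)
  }
}

#' Gene set enrichment analysis (weighted running sum, permutation null)
#'
#' Walks the score-ranked gene list accumulating `|score|^weight / NR` at
#' set members and `-1/(N-K)` elsewhere; the enrichment score ES is the
#' running-sum extremum by absolute value. The null is built by gene-label
#' permutation (the set is reassigned to random positions) with a fixed
#' seed; `NES = ES / mean(|ES_perm|)` over same-sign permutations and the
#' p-value is the same-sign exceedance fraction with a +1 pseudo-count.
#'
#' @param scores named numeric vector of ranking scores (e.g. Spearman rho
#'   per gene); sorted internally in decreasing order.
#' @param geneSet character vector of set member ids; at least 2 must be in
#'   the ranking.
#' @param weight score weighting exponent (default 1; 0 gives the
#'   unweighted Kolmogorov-Smirnov walk).
#' @param nPerm number of permutations (default 1000).
#' @param seed integer seed for the permutation null.
#' @return list with `es`, `nes`, `p`, `leadingEdge`, `runningSum`
#'   (`data.frame` gene/score/inSet/runningSum), `nPermSameSign`.
#' @export
gsea <- function(scores, geneSet, weight = 1, nPerm = 1000L, seed = 1L) {
  if (is.null(names(scores)) || anyDuplicated(names(scores))) {
    stop("scores must be uniquely named by gene", call. = FALSE)
  }
  if (any(!is.finite(scores))) stop("scores must be finite", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  scores <- scores[ord]
  genes <- names(scores)
  N <- length(genes)
  inSet <- genes %in% geneSet
  K <- sum(inSet)
  if (K == 0L) stop("gene set is disjoint from the ranking", call. = FALSE)
  if (K < 2L) stop("need at least 2 set members in the ranking", call. = FALSE)
  if (K >= N) stop("gene set covers the whole ranking", call. = FALSE)

  w <- abs(scores)^weight
  positions <- which(inSet)
  obs <- .esFromPositions(positions, w[positions], N)
  es <- obs$es

  ## full running sum trace for the observed set
  NR <- sum(w[positions])
  inc <- rep(-1 / (N - K), N)
  inc[positions] <- if (NR > 0) w[positions] / NR else 1 / K
  running <- cumsum(inc)

  set.seed(seed)
  esPerm <- numeric(nPerm)
  for (b in seq_len(nPerm)) {
    pos <- sort(sample.int(N, K))
    esPerm[b] <- .esFromPositions(pos, w[pos], N)$es
  }
  sameSign <- if (es >= 0) esPerm[esPerm >= 0] else esPerm[esPerm < 0]
  nes <- if (length(sameSign)) es / mean(abs(sameSign)) else NA_real_
  p <- (1 + sum(abs(sameSign) >= abs(es))) / (1 + length(sameSign))

  leading <- if (es >= 0) {
    genes[positions[positions <= obs$at]]
  } else {
    genes[positions[positions > obs$at]]
  }
  list(es = es, nes = nes, p = p, leadingEdge = leading,
       runningSum = data.frame(gene = genes, score = unname(scores),
                               inSet = inSet, runningSum = running,
                               stringsAsFactors = FALSE),
       nPermSameSign = length(sameSign))
}

#' Run GSEA over a whole collection
#'
#' @inheritParams gsea
#' @param collection named list of gene sets.
#' @param minSize skip sets with fewer ranked members (default 2).
#' @return `data.frame` with one row per testable set: `set`, `size`, `es`,
#'   `nes`, `p`, `q` (BH across sets), `leadingEdge` (comma-separated).
#' @export
gseaCollection <- function(scores, collection, weight = 1, nPerm = 1000L,
                           seed = 1L, minSize = 2L) {
  rows <- lapply(names(collection), function(nm) {
    k <- sum(names(scores) %in% collection[[nm]])
    if (k < minSize || k >= length(scores)) return(NULL)
    r <- gsea(scores, collection[[nm]], weight = weight, nPerm = nPerm,
              seed = seed)
    data.frame(set = nm, size = k, es = r$es, nes = r$nes, p = r$p,
               leadingEdge = paste(r$leadingEdge, collapse = ","),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) stop("no testable gene sets", call. = FALSE)
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p, out$set),
             c("set", "size", "es", "nes", "p", "q", "leadingEdge")]
  rownames(out) <- NULL
  out
}
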