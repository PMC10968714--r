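# miRNA-like target-site prediction for tRNA fragments: seed matching in
# 3'UTR sequences plus a complementarity duplex score.

#' Find seed-match sites of a fragment in a 3'UTR
#'
#' The seed is fragment positions 2-8 (5'->3'). Site types follow the
#' standard miRNA taxonomy, scanning the UTR 5'->3':
#' * `6mer`   - reverse complement of positions 2-7;
#' * `7mer-m8` - reverse complement of positions 2-8;
#' * `7mer-A1` - the 6mer followed by an `A` in the UTR (opposite fragment
#'   position 1);
#' * `8mer`   - the 7mer-m8 followed by that `A`.
#'
#' All (possibly overlapping) sites are reported, each once at its best
#' type (8mer > 7mer-m8 > 7mer-A1 > 6mer). Coordinates are 1-based
#' inclusive on the UTR plus strand.
#'
#' @param trfSequence fragment sequence, length >= 8 (U unified to T).
#' @param utrSequence 3'UTR sequence, given 5'->3'.
#' @return `data.frame` with columns `site_start`, `site_end`,
#'   `match_type`, `core_start` (start of the 6mer core).
#' @export
findSeedSites <- function(trfSequence, utrSequence) {
  trf <- normalizeDna(trfSequence, "tRF sequence")
  utr <- normalizeDna(utrSequence, "UTR sequence")
  if (nchar(trf) < 8L) {
    stop("fragment must be at least 8 nt for seed matching", call. = FALSE)
  }
  core <- revComp(substr(trf, 2L, 7L))          # 6mer target core
  m8 <- complementBase(substr(trf, 8L, 8L))     # base 5' of the core
  L <- nchar(utr)
  empty <- data.frame(site_start = integer(0), site_end = integer(0),
                      match_type = character(0), core_start = integer(0),
                      stringsAsFactors = FALSE)
  if (L < 6L) return(empty)
  starts <- exactMatchStarts(core, utr)
  if (!length(starts)) return(empty)
  rows <- lapply(starts, function(s) {
    hasM8 <- s > 1L && substr(utr, s - 1L, s - 1L) == m8
    hasA1 <- s + 6L <= L && substr(utr, s + 6L, s + 6L) == "A"
    if (hasM8 && hasA1) {
      c(s - 1L, s + 6L, "8mer")
    } else if (hasM8) {
      c(s - 1L, s + 5L, "7mer-m8")
    } else if (hasA1) {
      c(s, s + 6L, "7mer-A1")
    } else {
      c(s, s + 5L, "6mer")
    }
  })
  data.frame(
    site_start = vapply(rows, function(r) as.integer(r[1]), integer(1)),
    site_end = vapply(rows, function(r) as.integer(r[2]), integer(1)),
    match_type = vapply(rows, `[`, character(1), 3L),
    core_start = starts,
    stringsAsFactors = FALSE
  )
}

.PAIR_TYPES <- list(wc = c(A = "T", C = "G", G = "C", T = "A"))

## Pair score for fragment base `a` against UTR base `b` (antiparallel).
.pairScore <- function(a, b, wc, wobble, mismatch) {
  if (.PAIR_TYPES$wc[[a]] == b) return(wc)
  if ((a == "G" && b == "T") || (a == "T" && b == "G")) return(wobble)
  mismatch
}

#' Duplex complementarity score between a fragment and a UTR window
#'
#' Best local antiparallel complementarity alignment by affine-gap dynamic
#' programming (Smith-Waterman over pairing scores): Watson-Crick pair
#' +1.0, G:U wobble +0.5, mismatch -1.0, gap open -2.0, gap extend -1.0.
#' The score is floored at 0 (empty local alignment).
#'
#' @param trfSequence fragment sequence 5'->3'.
#' @param utrWindow UTR window sequence 5'->3', length <= 60.
#' @param wc,wobble,mismatch,gapOpen,gapExtend scoring parameters.
#' @return list with `score` and `alignment` (three text lines: fragment
#'   5'->3', pairing marks `|` / `:`, window 3'->5').
#' @export
duplexScore <- function(trfSequence, utrWindow, wc = 1, wobble = 0.5,
                        mismatch = -1, gapOpen = -2, gapExtend = -1) {
  trf <- normalizeDna(trfSequence, "tRF sequence")
  utr <- normalizeDna(utrWindow, "UTR window")
  if (!nzchar(trf) || !nzchar(utr)) {
    stop("empty sequence in duplexScore", call. = FALSE)
  }
  if (nchar(utr) > 60L) {
    stop("UTR window longer than 60 nt", call. = FALSE)
  }
  a <- strsplit(trf, "", fixed = TRUE)[[1]]
  b <- rev(strsplit(utr, "", fixed = TRUE)[[1]])  # antiparallel: 3'->5'
  m <- length(a); n <- length(b)
  NEG <- -1e9
  M <- matrix(0, m + 1L, n + 1L)        # best ending in a pair
  Ix <- matrix(NEG, m + 1L, n + 1L)     # gap in window strand
  Iy <- matrix(NEG, m + 1L, n + 1L)     # gap in fragment strand
  best <- 0; bi <- 0L; bj <- 0L
  ptr <- array(0L, dim = c(m + 1L, n + 1L, 3L))
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      s <- .pairScore(a[i], b[j], wc, wobble, mismatch)
      ## fresh local start (index 1) wins ties so traceback terminates
      cand <- c(0, M[i, j], Ix[i, j], Iy[i, j])
      pick <- which.max(cand)
      M[i + 1L, j + 1L] <- cand[pick] + s
      ptr[i + 1L, j + 1L, 1L] <- pick
      gx <- c(M[i, j + 1L] + gapOpen, Ix[i, j + 1L] + gapExtend)
      Ix[i + 1L, j + 1L] <- max(gx)
      ptr[i + 1L, j + 1L, 2L] <- which.max(gx)
      gy <- c(M[i + 1L, j] + gapOpen, Iy[i + 1L, j] + gapExtend)
      Iy[i + 1L, j + 1L] <- max(gy)
      ptr[i + 1L, j + 1L, 3L] <- which.max(gy)
      if (M[i + 1L, j + 1L] > best) {
        best <- M[i + 1L, j + 1L]; bi <- i + 1L; bj <- j + 1L
      }
    }
  }
  if (best <= 0) {
    return(list(score = 0,
                alignment = c("(no complementary alignment)", "", "")))
  }
  ## traceback from the best M cell
  top <- mid <- bot <- character(0)
  i <- bi; j <- bj; state <- 1L
  repeat {
    if (state == 1L) {
      ai <- a[i - 1L]; bj_ <- b[j - 1L]
      mark <- if (.PAIR_TYPES$wc[[ai]] == bj_) "|"
              else if ((ai == "G" && bj_ == "T") ||
                       (ai == "T" && bj_ == "G")) ":"
              else " "
      top <- c(ai, top); mid <- c(mark, mid); bot <- c(bj_, bot)
      prev <- ptr[i, j, 1L]
      i <- i - 1L; j <- j - 1L
      if (prev == 1L) break   # local alignment start
      state <- prev - 1L      # 2/3/4 -> M/Ix/Iy
      if (state == 1L && (i < 2L || j < 2L)) break
    } else if (state == 2L) {
      top <- c(a[i - 1L], top); mid <- c(" ", mid); bot <- c("-", bot)
      prev <- ptr[i, j, 2L]
      i <- i - 1L
      state <- if (prev == 1L) 1L else 2L
    } else {
      top <- c("-", top); mid <- c(" ", mid); bot <- c(b[j - 1L], bot)
      prev <- ptr[i, j, 3L]
      j <- j - 1L
      state <- if (prev == 1L) 1L else 3L
    }
    if (i == 0L || j == 0L) break
  }
  list(score = best,
       alignment = c(paste0("5'-", paste(top, collapse = ""), "-3' tRF"),
                     paste0("   ", paste(mid, collapse = "")),
                     paste0("3'-", paste(bot, collapse = ""), "-5' UTR")))
}

#' Predict 3'UTR targets of a fragment
#'
#' Per UTR: finds all seed-match sites, scores the best duplex over a
#' window of +/- `flank` nt around each site, and calls a target when at
#' least one seed site exists and the best duplex score reaches the
#' threshold (default half the fragment length).
#'
#' @param trfSequence fragment sequence 5'->3'.
#' @param utrs a FASTA path, named character vector or
#'   [Biostrings::DNAStringSet] of 3'UTR sequences (5'->3').
#' @param scoreThreshold duplex-score threshold (default
#'   `0.5 * nchar(trfSequence)`).
#' @param flank window half-width around each seed site (default 30).
#' @param trfId fragment id used in the output edge list.
#' @return `data.frame` with one row per UTR that has at least one seed
#'   site: `trf_id`, `utr_gene`, `n_sites`, `best_site_start`,
#'   `best_site_end`, `best_match_type`, `best_score`, `pass`; the full
#'   per-site table is in `attr(, "sites")`.
#' @export
predictTargets <- function(trfSequence, utrs, scoreThreshold = NULL,
                           flank = 30L, trfId = "tRF") {
  trf <- normalizeDna(trfSequence, "tRF sequence")
  if (is.null(scoreThreshold)) scoreThreshold <- 0.5 * nchar(trf)
  if (is.character(utrs) && length(utrs) == 1L && file.exists(utrs)) {
    utrs <- Biostrings::readDNAStringSet(utrs)
  }
  seqs <- stats::setNames(as.character(utrs), names(utrs))
  cols <- c("trf_id", "utr_gene", "n_sites", "best_site_start",
            "best_site_end", "best_match_type", "best_score", "pass")
  empty <- data.frame(trf_id = character(0), utr_gene = character(0),
                      n_sites = integer(0), best_site_start = integer(0),
                      best_site_end = integer(0),
                      best_match_type = character(0),
                      best_score = numeric(0), pass = logical(0),
                      stringsAsFactors = FALSE)
  if (!length(seqs)) {
    attr(empty, "sites") <- empty
    return(empty)
  }
  rows <- list(); siteRows <- list()
  for (g in names(seqs)) {
    utr <- normalizeDna(seqs[[g]], paste("UTR", g))
    sites <- findSeedSites(trf, utr)
    if (!nrow(sites)) next
    L <- nchar(utr)
    scores <- vapply(seq_len(nrow(sites)), function(i) {
      ## the duplex scorer takes windows of at most 60 nt, so the flank is
      ## trimmed symmetrically when the site plus 2*flank would exceed it
      siteLen <- sites$site_end[i] - sites$site_start[i] + 1L
      fl <- min(flank, (60L - siteLen) %/% 2L)
      win <- substr(utr, max(1L, sites$site_start[i] - fl),
                    min(L, sites$site_end[i] + fl))
      duplexScore(trf, win)$score
    }, numeric(1))
    sites$duplex_score <- scores
    sites$utr_gene <- g
    siteRows[[g]] <- sites
    bi <- which.max(scores)
    rows[[g]] <- data.frame(
      trf_id = trfId, utr_gene = g, n_sites = nrow(sites),
      best_site_start = sites$site_start[bi],
      best_site_end = sites$site_end[bi],
      best_match_type = sites$match_type[bi],
      best_score = scores[bi],
      pass = scores[bi] >= scoreThreshold,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    attr(empty, "sites") <- empty
    return(empty)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "sites") <- do.call(rbind, siteRows)
  attr(out, "scoreThreshold") <- scoreThreshold
  out
}

#' Export the passing target predictions as an edge list
#'
#' @param predictions output of [predictTargets()].
#' @return `data.frame` with columns `trf`, `gene` (one row per passing
#'   prediction), suitable for network tools.
#' @export
targetEdgeList <- function(predictions) {
  keep <- predictions[predictions$pass, , drop = FALSE]
  data.frame(trf = keep$trf_id, gene = keep$utr_gene,
             stringsAsFactors = FALSE)
}
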