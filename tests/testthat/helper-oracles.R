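# Independent brute-force oracles for the target-scanning module.

## all-offsets seed-site scan
naiveSeedScan <- function(trf, utr) {
  core <- rcStr(substr(trf, 2, 7))
  m8 <- chartr("ACGT", "TGCA", substr(trf, 8, 8))
  L <- nchar(utr)
  hits <- list()
  for (s in seq_len(max(0, L - 5))) {
    if (substr(utr, s, s + 5) != core) next
    hasM8 <- s > 1 && substr(utr, s - 1, s - 1) == m8
    hasA1 <- s + 6 <= L && substr(utr, s + 6, s + 6) == "A"
    hits[[length(hits) + 1]] <- data.frame(
      site_start = if (hasM8) s - 1L else s,
      site_end = if (hasM8 && hasA1) s + 6L
                 else if (hasM8) s + 5L
                 else if (hasA1) s + 6L else s + 5L,
      match_type = if (hasM8 && hasA1) "8mer" else if (hasM8) "7mer-m8"
                   else if (hasA1) "7mer-A1" else "6mer",
      core_start = s, stringsAsFactors = FALSE)
  }
  if (!length(hits)) {
    return(data.frame(site_start = integer(0), site_end = integer(0),
                      match_type = character(0), core_start = integer(0)))
  }
  do.call(rbind, hits)
}

## plain recursive best-local-alignment under the duplex scoring scheme,
## memoised; tractable for pairs up to ~20 nt
bruteDuplex <- function(trf, win, wc = 1, wobble = 0.5, mismatch = -1,
                        gapOpen = -2, gapExtend = -1) {
  a <- strsplit(trf, "")[[1]]
  b <- rev(strsplit(win, "")[[1]])
  pair <- function(x, y) {
    if (chartr("ACGT", "TGCA", x) == y) return(wc)
    if ((x == "G" && y == "T") || (x == "T" && y == "G")) return(wobble)
    mismatch
  }
  m <- length(a); n <- length(b)
  memo <- new.env()
  ## best score of an alignment ending at (i, j) in the given state
  f <- function(i, j, state) {
    if (i < 1 || j < 1) return(-Inf)
    key <- paste(i, j, state)
    if (!is.null(memo[[key]])) return(memo[[key]])
    v <- if (state == 1) {
      pair(a[i], b[j]) + max(0, f(i - 1, j - 1, 1), f(i - 1, j - 1, 2),
                             f(i - 1, j - 1, 3))
    } else if (state == 2) {
      max(f(i - 1, j, 1) + gapOpen, f(i - 1, j, 2) + gapExtend)
    } else {
      max(f(i, j - 1, 1) + gapOpen, f(i, j - 1, 3) + gapExtend)
    }
    memo[[key]] <- v
    v
  }
  best <- 0
  for (i in seq_len(m)) for (j in seq_len(n)) {
    best <- max(best, f(i, j, 1))
  }
  best
}
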