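# tDRnamer-style fragment identifiers:
#   tDR-<start>:<end>-<Isotype>-<Anticodon>-<family>[-M<k>]
# Coordinates are 1-based inclusive on the mature tRNA (so a 76-nt mature
# histidine tRNA ends at position 76, CCA included); M<k> (k >= 2) counts
# the distinct mature tRNA sequences that contain the fragment.

#' Construct a tDR name object
#'
#' @param start,end 1-based inclusive span on the mature tRNA.
#' @param isotype 3-letter amino-acid code (first letter capitalised).
#' @param anticodon 3-mer DNA anticodon.
#' @param familyIndex positive integer gene-family index.
#' @param multimapCount number of distinct mature tRNA sequences containing
#'   the fragment (>= 1).
#' @return a list of class `TDRName`.
#' @export
tdrName <- function(start, end, isotype, anticodon, familyIndex,
                    multimapCount = 1L) {
  start <- as.integer(start); end <- as.integer(end)
  familyIndex <- as.integer(familyIndex)
  multimapCount <- as.integer(multimapCount)
  if (is.na(start) || is.na(end) || start < 1L || start > end) {
    stop("invalid tDR span: start must satisfy 1 <= start <= end",
         call. = FALSE)
  }
  if (!grepl("^[A-Z][a-z]{2}$", isotype)) {
    stop("invalid isotype: ", isotype, call. = FALSE)
  }
  anticodon <- toupper(anticodon)
  if (!grepl("^[ACGT]{3}$", anticodon)) {
    stop("invalid anticodon: ", anticodon, call. = FALSE)
  }
  if (is.na(familyIndex) || familyIndex < 1L) {
    stop("invalid family index", call. = FALSE)
  }
  if (is.na(multimapCount) || multimapCount < 1L) {
    stop("invalid multimap count", call. = FALSE)
  }
  structure(list(start = start, end = end, isotype = isotype,
                 anticodon = anticodon, familyIndex = familyIndex,
                 multimapCount = multimapCount),
            class = "TDRName")
}

#' Format a tDR name as text
#'
#' @param x a `TDRName` (see [tdrName()]).
#' @return character id, e.g. `"tDR-60:76-His-GTG-1-M2"`; the `-M<k>`
#'   suffix appears only when the multimap count is at least 2.
#' @export
formatTdrId <- function(x) {
  stopifnot(inherits(x, "TDRName"))
  base <- sprintf("tDR-%d:%d-%s-%s-%d", x$start, x$end, x$isotype,
                  x$anticodon, x$familyIndex)
  if (x$multimapCount >= 2L) paste0(base, "-M", x$multimapCount) else base
}

#' @export
format.TDRName <- function(x, ...) formatTdrId(x)

#' @export
print.TDRName <- function(x, ...) {
  cat(formatTdrId(x), "\n")
  invisible(x)
}

#' Parse a tDRnamer-style identifier
#'
#' @param text identifier such as `"tDR-60:76-His-GTG-1-M2"`.
#' @return a `TDRName` list (see [tdrName()]).
#' @examples
#' parseTdrId("tDR-60:76-His-GTG-1-M2")
#' @export
parseTdrId <- function(text) {
  stopifnotScalarString(text, "tDR id")
  pattern <- "^tDR-([0-9]+):([0-9]+)-([A-Z][a-z]{2})-([ACGT]{3})-([0-9]+)(-M([0-9]+))?$"
  m <- regexec(pattern, text)
  g <- regmatches(text, m)[[1]]
  if (!length(g)) {
    ## locate the first deviation from the grammar for the error message
    prefixes <- c("tDR-", "^tDR-[0-9]+", "^tDR-[0-9]+:[0-9]+",
                  "^tDR-[0-9]+:[0-9]+-[A-Z][a-z]{2}",
                  "^tDR-[0-9]+:[0-9]+-[A-Z][a-z]{2}-[ACGT]{3}")
    pos <- 1L
    if (startsWith(text, "tDR-")) {
      for (p in prefixes[-1]) {
        mm <- regexpr(p, text)
        if (mm == 1L) pos <- attr(mm, "match.length") + 1L else break
      }
    }
    stop("malformed tDR id '", text, "' (parse fails near position ", pos,
         ")", call. = FALSE)
  }
  start <- as.integer(g[2]); end <- as.integer(g[3])
  if (start > end) {
    stop("malformed tDR id '", text, "': start ", start, " > end ", end,
         call. = FALSE)
  }
  tdrName(start, end, g[4], g[5], as.integer(g[6]),
          multimapCount = if (nzchar(g[8])) as.integer(g[8]) else 1L)
}

#' Name a classified fragment
#'
#' Derives the tDRnamer-style identifier of a fragment from its mature
#' placements: the span comes from the lexicographically smallest
#' (gene_id, start) mature placement, and the multimap count is the number
#' of distinct mature tRNA sequences containing the fragment.
#'
#' @param sig a classification result from [classifyFragment()], or a row
#'   of a [FragmentCatalog-class] identified by `signatureId`.
#' @param ref the [TRNAReference-class] used for classification.
#' @return a `TDRName` (see [tdrName()]).
#' @export
nameFragment <- function(sig, ref) {
  if (methods::is(sig, "FragmentCatalog")) {
    stop("pass a single classifyFragment() result, not a catalog",
         call. = FALSE)
  }
  nameFragmentFromHit(sig, ref)
}

nameFragmentFromHit <- function(hit, ref) {
  if (!hit$trf_class %in% c("3p_trf", "5p_trf", "i_trf")) {
    stop("tDR mature-span names do not apply to class '", hit$trf_class,
         "'; use the signature id instead", call. = FALSE)
  }
  pl <- hit$placements[hit$placements$region == "mature", , drop = FALSE]
  if (!nrow(pl)) stop("no mature placement to name from", call. = FALSE)
  pl <- pl[order(pl$gene_id, pl$start), , drop = FALSE]
  g <- ref@genes[match(pl$gene_id[1L], ref@genes$gene_id), ]
  tdrName(pl$start[1L], pl$end[1L], g$isotype, g$anticodon, g$family_index,
          multimapCount = hit$multimap_count)
}
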