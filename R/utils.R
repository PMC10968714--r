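# Internal sequence helpers shared across modules.

#' @importFrom Biostrings DNAString DNAStringSet reverseComplement
NULL

## Uppercase, unify RNA U to DNA T, validate alphabet. `what` names the
## offending record in error messages.
normalizeDna <- function(x, what = "sequence") {
  x <- chartr("u", "t", tolower(x))
  x <- toupper(x)
  bad <- grepl("[^ACGT]", x)
  if (any(bad)) {
    stop("non-DNA characters in ", what, ": ",
         paste(utils::head(names(x)[bad] %||% which(bad), 5), collapse = ", "),
         call. = FALSE)
  }
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

revComp <- function(x) {
  vapply(x, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}

complementBase <- function(x) chartr("ACGT", "TGCA", x)

## All (possibly overlapping) exact occurrences of `pattern` in `subject`
## (both plain character strings); returns integer start positions.
exactMatchStarts <- function(pattern, subject) {
  np <- nchar(pattern); ns <- nchar(subject)
  if (np == 0L || np > ns) return(integer(0))
  m <- Biostrings::matchPattern(pattern, Biostrings::DNAString(subject))
  Biostrings::start(m)
}

stopifnotScalarString <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x)) {
    stop(what, " must be a single non-empty string", call. = FALSE)
  }
}
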