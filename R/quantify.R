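# Exact-match read counting and per-million normalisation.

#' Count exact read support for catalog signatures in one FASTQ
#'
#' A read increments a signature if and only if the read sequence equals the
#' signature sequence exactly (full-length equality, case-insensitive, T/U
#' unified to T). Reads matching no signature contribute only to the
#' library size.
#'
#' @param fastqPath path to an adapter-trimmed FASTQ (optionally gzipped).
#' @param catalog a [FragmentCatalog-class] (sequences must be unique).
#' @return list with `counts` (named integer vector, one per signature) and
#'   `librarySize` (total reads in the file).
#' @export
countSample <- function(fastqPath, catalog) {
  if (!file.exists(fastqPath)) {
    stop("FASTQ not found: ", fastqPath, call. = FALSE)
  }
  sig <- catalog@signatures
  ## read as raw strings: tolerate U/lower-case before DNA normalisation
  reads <- tryCatch(
    as.character(Biostrings::readBStringSet(fastqPath, format = "fastq")),
    error = function(e) {
      stop("failed to read FASTQ ", fastqPath, ": ", conditionMessage(e),
           call. = FALSE)
    })
  librarySize <- length(reads)
  counts <- stats::setNames(integer(nrow(sig)), sig$signature_id)
  if (librarySize == 0L) {
    warning("empty FASTQ: ", fastqPath, call. = FALSE)
    return(list(counts = counts, librarySize = 0L))
  }
  reads <- chartr("Uu", "Tt", reads)
  reads <- toupper(reads)
  idx <- match(reads, sig$sequence)
  hit <- table(idx[!is.na(idx)])
  counts[as.integer(names(hit))] <- as.integer(hit)
  list(counts = counts, librarySize = librarySize)
}

#' Count a set of samples into a SummarizedExperiment
#'
#' @param fastqPaths named character vector of FASTQ paths (names are
#'   sample ids).
#' @param catalog a [FragmentCatalog-class].
#' @return [SummarizedExperiment::SummarizedExperiment] with assay
#'   `counts`, `rowData` from the catalog and `colData` column
#'   `librarySize`.
#' @export
countSamples <- function(fastqPaths, catalog) {
  if (is.null(names(fastqPaths))) {
    names(fastqPaths) <- sub("\\.(fastq|fq)(\\.gz)?$", "",
                             basename(fastqPaths))
  }
  per <- lapply(fastqPaths, countSample, catalog = catalog)
  counts <- vapply(per, `[[`, integer(nrow(catalog@signatures)), "counts")
  if (is.null(dim(counts))) counts <- matrix(counts, ncol = length(per))
  dimnames(counts) <- list(catalog@signatures$signature_id, names(fastqPaths))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    rowData = S4Vectors::DataFrame(
      catalog@signatures[, c("sequence", "length", "trf_class", "tdr_name",
                             "multimap_count", "chromosome")],
      row.names = catalog@signatures$signature_id),
    colData = S4Vectors::DataFrame(
      librarySize = vapply(per, `[[`, integer(1), "librarySize"),
      row.names = names(fastqPaths))
  )
}

#' Normalise counts to log2(reads-per-million + 1)
#'
#' `value = log2(count / denominator * 1e6 + 1)`. The denominator is either
#' the total library size (`"library"`, the default, matching the miRNA-seq
#' convention) or the per-sample total of catalog-assigned reads
#' (`"assigned"`). Samples with a zero denominator are excluded with a
#' warning.
#'
#' @param x a `SummarizedExperiment` from [countSamples()] (with a
#'   `librarySize` colData column), or a counts matrix.
#' @param librarySizes required when `x` is a matrix and
#'   `denominator = "library"`.
#' @param denominator `"library"` or `"assigned"`.
#' @return same container as the input, with a `logTPM` assay (for a
#'   matrix input, the logTPM matrix with attribute `perMillion`).
#' @export
normalizeExpression <- function(x, librarySizes = NULL,
                                denominator = c("library", "assigned")) {
  denominator <- match.arg(denominator)
  isSE <- methods::is(x, "SummarizedExperiment")
  counts <- if (isSE) SummarizedExperiment::assay(x, "counts") else as.matrix(x)
  denom <- switch(denominator,
    library = if (isSE) {
      SummarizedExperiment::colData(x)$librarySize
    } else {
      if (is.null(librarySizes)) {
        stop("librarySizes required for denominator = 'library'",
             call. = FALSE)
      }
      librarySizes[colnames(counts)] %||% librarySizes
    },
    assigned = colSums(counts)
  )
  denom <- as.numeric(denom)
  bad <- !is.finite(denom) | denom <= 0
  if (any(bad)) {
    warning("excluding sample(s) with zero denominator: ",
            paste(colnames(counts)[bad], collapse = ", "), call. = FALSE)
    counts <- counts[, !bad, drop = FALSE]
    denom <- denom[!bad]
    if (isSE) x <- x[, !bad]
  }
  perMillion <- sweep(counts, 2, denom, "/") * 1e6
  logTPM <- log2(perMillion + 1)
  if (isSE) {
    SummarizedExperiment::assay(x, "logTPM") <- logTPM
    S4Vectors::metadata(x)$denominator <- denominator
    x
  } else {
    attr(logTPM, "perMillion") <- perMillion
    logTPM
  }
}

#' Filter signatures by detection fraction
#'
#' Keeps signatures with a non-zero count in at least
#' `minDetectFraction` of the samples and reports the class and chromosome
#' composition of the kept set.
#'
#' @param se a `SummarizedExperiment` with a `counts` assay (and rowData
#'   columns `trf_class` / `chromosome` for the composition report).
#' @param minDetectFraction minimum fraction of samples with count > 0
#'   (default 0.5).
#' @return the filtered `SummarizedExperiment`; the report is stored in
#'   `metadata(se)$detectionFilter` (kept/dropped counts, class and
#'   chromosome composition of the kept set).
#' @export
detectionFilter <- function(se, minDetectFraction = 0.5) {
  counts <- SummarizedExperiment::assay(se, "counts")
  frac <- rowMeans(counts > 0)
  keep <- frac >= minDetectFraction
  rd <- SummarizedExperiment::rowData(se)
  report <- list(
    minDetectFraction = minDetectFraction,
    n_total = nrow(counts),
    n_kept = sum(keep),
    n_dropped = sum(!keep)
  )
  if ("trf_class" %in% names(rd)) {
    report$class_composition <- proportions(table(rd$trf_class[keep]))
  }
  if ("chromosome" %in% names(rd)) {
    report$chromosome_composition <- proportions(table(rd$chromosome[keep]))
  }
  out <- se[keep, ]
  S4Vectors::metadata(out)$detectionFilter <- report
  out
}
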