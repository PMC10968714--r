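# Exact-match placement of fragment sequences into the reference spaces and
# assignment of the five canonical tRF classes.

## Precedence when a fragment hits several regions/classes: mature-space
## identity wins (3' > 5' > internal), then trailer, then leader.
.CLASS_PRECEDENCE <- c("3p_trf" = 5L, "5p_trf" = 4L, "i_trf" = 3L,
                       "trf1" = 2L, "5pU_trf" = 1L)

#' Classify one fragment sequence against a reference
#'
#' Enumerates every exact placement of the fragment across the mature,
#' trailer and leader spaces of all genes and assigns one of the five tRF
#' classes:
#'
#' * `5p_trf` - mature placement starting within `startTolerance` of the
#'   mature 5' end (tolerance 2 for histidine genes, whose G-1 is
#'   post-transcriptional) and ending before the mature 3' end;
#' * `3p_trf` - mature placement ending exactly at the mature 3' end
#'   (CCA-inclusive), regardless of start;
#' * `i_trf`  - any other mature placement;
#' * `trf1`   - trailer placement starting at trailer position 1
#'   (immediately after the mature 3' end);
#' * `5pU_trf` - leader placement ending at the leader 3' end (immediately
#'   before the mature 5' end).
#'
#' When placements span several classes the class of highest precedence
#' (mature 3p > 5p > i, then trailer, then leader) is retained and
#' conflicting placements are dropped (counted in `n_dropped_placements`).
#' Fragments outside the length bounds, or with no exact placement, are
#' `unclassified` with no retained placements.
#'
#' A 5' fragment is flagged as a 5' half (`is_5p_half`) when its length is
#' at least `halfMinLength`; if the gene metadata carries
#' `anticodon_position`, the rule "placement end within
#' \[anticodon start - 2, anticodon start + 4\] in mature coordinates"
#' overrides the length heuristic.
#'
#' @param sequence fragment sequence (DNA or RNA alphabet; U is unified to
#'   T, case-insensitive).
#' @param ref a [TRNAReference-class].
#' @param minLength,maxLength admissible fragment lengths (defaults 16, 35).
#' @param startTolerance maximal mature start for a 5' fragment (default 1).
#' @param hisStartTolerance the same for histidine genes (default 2,
#'   accounting for the post-transcriptional G-1).
#' @param halfMinLength minimum length for the 5' half flag (default 30).
#' @return list with `sequence`, `length`, `trf_class`, `placements`
#'   (`data.frame` gene_id/region/start/end), `multimap_count` (distinct
#'   mature sequences for mature classes, distinct genes otherwise),
#'   `is_5p_half`, `n_dropped_placements`.
#' @examples
#' # see buildCatalog() for an end-to-end example
#' @export
classifyFragment <- function(sequence, ref, minLength = 16L, maxLength = 35L,
                             startTolerance = 1L, hisStartTolerance = 2L,
                             halfMinLength = 30L) {
  stopifnotScalarString(sequence, "sequence")
  sequence <- normalizeDna(sequence, what = "fragment sequence")
  len <- nchar(sequence)
  empty <- data.frame(gene_id = character(0), region = character(0),
                      start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE)
  out <- list(sequence = sequence, length = len, trf_class = "unclassified",
              placements = empty, multimap_count = 0L, is_5p_half = FALSE,
              n_dropped_placements = 0L)
  if (len < minLength || len > maxLength) return(out)

  genes <- ref@genes
  pl <- list()
  for (i in seq_len(nrow(genes))) {
    gid <- genes$gene_id[i]
    isHis <- identical(genes$isotype[i], "His")
    tol <- if (isHis) hisStartTolerance else startTolerance
    regions <- list(
      mature = as.character(ref@mature[[i]]),
      trailer = as.character(ref@trailer[[i]]),
      leader = as.character(ref@leader[[i]])
    )
    for (region in names(regions)) {
      subj <- regions[[region]]
      if (!nzchar(subj)) next
      starts <- exactMatchStarts(sequence, subj)
      for (s in starts) {
        e <- s + len - 1L
        cls <- switch(region,
          mature = if (e == nchar(subj)) "3p_trf"
                   else if (s <= tol) "5p_trf" else "i_trf",
          trailer = if (s == 1L) "trf1" else NA_character_,
          leader = if (e == nchar(subj)) "5pU_trf" else NA_character_
        )
        pl[[length(pl) + 1L]] <- data.frame(
          gene_id = gid, region = region, start = s, end = e,
          class = cls, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(pl)) return(out)
  pl <- do.call(rbind, pl)
  classified <- pl[!is.na(pl$class), , drop = FALSE]
  if (!nrow(classified)) {
    out$n_dropped_placements <- nrow(pl)
    return(out)
  }
  best <- names(which.max(.CLASS_PRECEDENCE[unique(classified$class)]))
  keep <- classified[classified$class == best, , drop = FALSE]
  out$trf_class <- best
  out$n_dropped_placements <- nrow(pl) - nrow(keep)
  keep <- keep[order(keep$gene_id, keep$start), , drop = FALSE]
  rownames(keep) <- NULL
  out$placements <- keep[, c("gene_id", "region", "start", "end")]
  if (best %in% c("3p_trf", "5p_trf", "i_trf")) {
    matSeq <- as.character(ref@mature)[keep$gene_id]
    out$multimap_count <- length(unique(matSeq))
  } else {
    out$multimap_count <- length(unique(keep$gene_id))
  }
  if (best == "5p_trf") {
    out$is_5p_half <- .is5pHalf(keep, ref, len, halfMinLength)
  }
  out
}

## 5' half rule: anticodon-loop override when anticodon_position is known
## for the naming (lexicographically first) placement gene, else length
## heuristic.
.is5pHalf <- function(placements, ref, len, halfMinLength) {
  first <- placements[1L, ]
  genes <- ref@genes
  i <- match(first$gene_id, genes$gene_id)
  acPos <- if ("anticodon_position" %in% names(genes)) {
    genes$anticodon_position[i]
  } else NA
  if (!is.null(acPos) && length(acPos) == 1L && !is.na(acPos)) {
    map <- ref@matureMap[[first$gene_id]]
    acMature <- which(!is.na(map) & map == as.integer(acPos))
    if (length(acMature) == 1L) {
      return(first$end >= acMature - 2L && first$end <= acMature + 4L)
    }
  }
  len >= halfMinLength
}

#' Build a classified fragment catalog
#'
#' Classifies a set of candidate fragment sequences, deduplicating by exact
#' sequence (first id wins, with a warning), assigning tDRnamer-style names
#' where a mature placement exists, and summarising class and source
#' chromosome composition.
#'
#' @param signatures either a path to a TSV with columns `signature_id` and
#'   `sequence`, a `data.frame` with those columns, or a named character
#'   vector of sequences.
#' @param ref a [TRNAReference-class].
#' @inheritParams classifyFragment
#' @return a [FragmentCatalog-class].
#' @examples
#' ref <- buildReference(geneSet = loadGeneSetFromObjects(
#'   Biostrings::DNAStringSet(c(g1 = paste(rep("ACGT", 18), collapse = ""))),
#'   data.frame(gene_id = "g1", isotype = "Ala", anticodon = "AGC",
#'              family_index = 1, chromosome = "chr1", strand = "+",
#'              genomic_start = 1001, genomic_end = 1072,
#'              leader_seq = strrep("A", 50), trailer_seq = strrep("C", 35))))
#' m <- as.character(matureSeqs(ref)[[1]])
#' cat <- buildCatalog(c(sig1 = substr(m, nchar(m) - 17, nchar(m))), ref)
#' fragmentInfo(cat)
#' @export
buildCatalog <- function(signatures, ref, minLength = 16L, maxLength = 35L,
                         startTolerance = 1L, hisStartTolerance = 2L,
                         halfMinLength = 30L) {
  sig <- .asSignatureTable(signatures)
  if (!nrow(sig)) stop("empty signature input", call. = FALSE)
  sig$sequence <- normalizeDna(sig$sequence, what = "signature sequence")
  dup <- duplicated(sig$sequence)
  if (any(dup)) {
    warning("dropping ", sum(dup), " duplicate signature sequence(s); ",
            "first id wins: ",
            paste(utils::head(sig$signature_id[dup], 5), collapse = ", "),
            call. = FALSE)
    sig <- sig[!dup, , drop = FALSE]
  }
  hits <- lapply(sig$sequence, classifyFragment, ref = ref,
                 minLength = minLength, maxLength = maxLength,
                 startTolerance = startTolerance,
                 hisStartTolerance = hisStartTolerance,
                 halfMinLength = halfMinLength)
  tdr <- vapply(hits, function(h) {
    if (h$trf_class %in% c("3p_trf", "5p_trf", "i_trf")) {
      formatTdrId(nameFragmentFromHit(h, ref))
    } else NA_character_
  }, character(1))
  chrom <- vapply(hits, function(h) {
    if (nrow(h$placements)) {
      ref@genes$chromosome[match(h$placements$gene_id[1L], ref@genes$gene_id)]
    } else NA_character_
  }, character(1))
  placementStr <- vapply(hits, function(h) {
    if (!nrow(h$placements)) return("")
    paste(sprintf("%s:%s:%d-%d", h$placements$gene_id, h$placements$region,
                  h$placements$start, h$placements$end), collapse = ";")
  }, character(1))
  tab <- data.frame(
    signature_id = sig$signature_id,
    sequence = sig$sequence,
    length = vapply(hits, `[[`, integer(1), "length"),
    trf_class = vapply(hits, `[[`, character(1), "trf_class"),
    tdr_name = tdr,
    multimap_count = vapply(hits, `[[`, integer(1), "multimap_count"),
    is_5p_half = vapply(hits, `[[`, logical(1), "is_5p_half"),
    placements = placementStr,
    chromosome = chrom,
    stringsAsFactors = FALSE
  )
  rownames(tab) <- NULL
  classified <- tab$trf_class != "unclassified"
  classProp <- if (any(classified)) {
    proportions(table(tab$trf_class[classified]))
  } else table(character(0))
  chromProp <- if (any(classified)) {
    proportions(table(tab$chromosome[classified]))
  } else table(character(0))
  methods::new("FragmentCatalog",
    signatures = tab,
    placements = stats::setNames(lapply(hits, `[[`, "placements"),
                                 sig$signature_id),
    summary = list(
      n_signatures = nrow(tab),
      n_classified = sum(classified),
      class_counts = table(tab$trf_class),
      class_proportions = classProp,
      chromosome_proportions = chromProp
    ),
    params = list(minLength = minLength, maxLength = maxLength,
                  startTolerance = startTolerance,
                  hisStartTolerance = hisStartTolerance,
                  halfMinLength = halfMinLength)
  )
}

.asSignatureTable <- function(signatures) {
  if (is.character(signatures) && length(signatures) == 1L &&
      file.exists(signatures)) {
    sig <- utils::read.delim(signatures, stringsAsFactors = FALSE)
  } else if (is.character(signatures)) {
    ids <- names(signatures) %||%
      sprintf("sig-%d", seq_along(signatures))
    sig <- data.frame(signature_id = ids, sequence = unname(signatures),
                      stringsAsFactors = FALSE)
  } else if (is.data.frame(signatures)) {
    sig <- as.data.frame(signatures, stringsAsFactors = FALSE)
  } else {
    stop("signatures must be a TSV path, data.frame or character vector",
         call. = FALSE)
  }
  if (!all(c("signature_id", "sequence") %in% names(sig))) {
    stop("signature table needs columns signature_id and sequence",
         call. = FALSE)
  }
  sig[, c("signature_id", "sequence")]
}

#' Write a fragment catalog as TSV
#'
#' @param catalog a [FragmentCatalog-class].
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
writeCatalog <- function(catalog, path) {
  utils::write.table(catalog@signatures, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
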