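# Construction of the mature / leader / trailer reference spaces.

#' Load a tRNA gene set from FASTA plus metadata
#'
#' Reads gene sequences (genomic plus strand) and a metadata table, and
#' returns coding-strand 5'->3' records: minus-strand genes are
#' reverse-complemented on load. Coordinates are 1-based inclusive
#' throughout.
#'
#' @param fastaPath path to a FASTA of gene sequences (plus-strand genomic
#'   over the genomic span).
#' @param metadataPath path to a TSV with columns `gene_id`, `isotype`
#'   (3-letter amino-acid code), `anticodon` (3-mer, DNA alphabet),
#'   `family_index`, `chromosome`, `strand` (+/-), `genomic_start`,
#'   `genomic_end`, and optionally `intron_spans` (gene-local
#'   `"s1-e1;s2-e2"`), `leader_seq`, `trailer_seq`, `anticodon_position`
#'   (gene-local start of the anticodon).
#' @return list with `genes` (metadata `data.frame`, including a parsed
#'   `introns` list column) and `seqs` (coding-strand
#'   [Biostrings::DNAStringSet] named by gene_id).
#' @export
loadGeneSet <- function(fastaPath, metadataPath) {
  seqs <- Biostrings::readDNAStringSet(fastaPath)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  meta <- utils::read.delim(metadataPath, stringsAsFactors = FALSE)
  loadGeneSetFromObjects(seqs, meta)
}

#' @describeIn loadGeneSet validate an in-memory gene set (a
#'   [Biostrings::DNAStringSet] plus a metadata `data.frame`), e.g. from
#'   [simulateReference()].
#' @param seqs plus-strand [Biostrings::DNAStringSet] named by gene id.
#' @param meta metadata `data.frame` (same columns as the TSV).
#' @export
loadGeneSetFromObjects <- function(seqs, meta) {
  required <- c("gene_id", "isotype", "anticodon", "family_index",
                "chromosome", "strand", "genomic_start", "genomic_end")
  missingCols <- setdiff(required, names(meta))
  if (length(missingCols)) {
    stop("gene metadata lacks columns: ", paste(missingCols, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(names(seqs))) {
    stop("duplicate FASTA ids: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(meta$gene_id)) {
    stop("duplicate metadata gene_id: ",
         paste(unique(meta$gene_id[duplicated(meta$gene_id)]), collapse = ", "),
         call. = FALSE)
  }
  noMeta <- setdiff(names(seqs), meta$gene_id)
  if (length(noMeta)) {
    stop("FASTA records with no metadata row: ",
         paste(noMeta, collapse = ", "), call. = FALSE)
  }
  noSeq <- setdiff(meta$gene_id, names(seqs))
  if (length(noSeq)) {
    stop("metadata rows with no FASTA record: ",
         paste(noSeq, collapse = ", "), call. = FALSE)
  }
  meta <- meta[match(names(seqs), meta$gene_id), , drop = FALSE]
  rownames(meta) <- NULL
  if (!all(meta$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'", call. = FALSE)
  }
  raw <- as.character(seqs)
  names(raw) <- names(seqs)
  raw <- normalizeDna(raw, what = "gene sequence")
  spanLen <- meta$genomic_end - meta$genomic_start + 1L
  badLen <- nchar(raw) != spanLen
  if (any(badLen)) {
    stop("gene sequence length differs from genomic span for: ",
         paste(meta$gene_id[badLen], collapse = ", "), call. = FALSE)
  }
  coding <- raw
  neg <- meta$strand == "-"
  if (any(neg)) coding[neg] <- revComp(raw[neg])

  meta$introns <- lapply(seq_len(nrow(meta)), function(i) {
    parseIntronSpans(meta$intron_spans[i] %||% NA_character_,
                     nchar(coding[i]), meta$gene_id[i])
  })
  list(genes = meta,
       seqs = Biostrings::DNAStringSet(stats::setNames(coding, meta$gene_id)))
}

parseIntronSpans <- function(txt, geneLen, geneId) {
  if (is.null(txt) || length(txt) == 0L || is.na(txt) || !nzchar(txt)) {
    return(matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("start", "end"))))
  }
  parts <- strsplit(txt, ";", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexec("^([0-9]+)-([0-9]+)$", parts))
  if (any(lengths(m) != 3L)) {
    stop("malformed intron_spans for ", geneId, ": ", txt, call. = FALSE)
  }
  sp <- t(vapply(m, function(x) as.integer(x[2:3]), integer(2)))
  colnames(sp) <- c("start", "end")
  ord <- order(sp[, 1])
  sp <- sp[ord, , drop = FALSE]
  ok <- all(sp[, 1] <= sp[, 2]) && sp[1, 1] > 1L && sp[nrow(sp), 2] < geneLen &&
    (nrow(sp) == 1L || all(sp[-1, 1] > sp[-nrow(sp), 2]))
  if (!ok) {
    stop("intron spans for ", geneId,
         " must be disjoint, sorted and strictly inside the gene",
         call. = FALSE)
  }
  sp
}

#' Build the mature tRNA sequence for one gene
#'
#' Excises introns, prepends the post-transcriptional G-1 for histidine
#' tRNAs and appends the (non-genomic) 3' CCA. Returns the mature sequence
#' together with a map from mature positions to gene-local positions; the
#' G-1 and CCA bases map to `NA` (post-transcriptional).
#'
#' @param geneSeq coding-strand gene sequence (character).
#' @param isotype 3-letter amino-acid code; `"His"` triggers G-1 addition.
#' @param introns integer matrix of gene-local 1-based inclusive intron
#'   spans (possibly zero rows).
#' @param appendCCA append CCA (default `TRUE`; eukaryotic tRNA genes do
#'   not encode it).
#' @return list with `sequence` and integer `map`.
#' @export
buildMature <- function(geneSeq, isotype, introns = NULL, appendCCA = TRUE) {
  geneSeq <- normalizeDna(geneSeq, what = "gene sequence")
  geneLen <- nchar(geneSeq)
  keep <- rep(TRUE, geneLen)
  if (!is.null(introns) && nrow(introns)) {
    for (i in seq_len(nrow(introns))) {
      keep[introns[i, 1]:introns[i, 2]] <- FALSE
    }
  }
  bases <- strsplit(geneSeq, "", fixed = TRUE)[[1]][keep]
  map <- which(keep)
  if (identical(isotype, "His")) {
    bases <- c("G", bases)
    map <- c(NA_integer_, map)
  }
  if (appendCCA) {
    bases <- c(bases, "C", "C", "A")
    map <- c(map, rep(NA_integer_, 3L))
  }
  list(sequence = paste(bases, collapse = ""), map = map)
}

#' Extract the precursor leader and trailer windows for one gene
#'
#' The leader ends immediately before gene position 1; the trailer starts
#' immediately after the gene 3' end, both in transcription direction.
#' Explicit flank sequences (already in transcription orientation) take
#' precedence; otherwise flanks are cut strand-aware from a genome
#' sequence. Flanks shorter than the window are truncated with a warning,
#' never padded.
#'
#' @param gene one-row gene metadata (list or `data.frame` row) with
#'   `gene_id`, `strand`, `genomic_start`, `genomic_end`, optionally
#'   `leader_seq` / `trailer_seq`.
#' @param genome optional named character vector / `DNAStringSet` of contig
#'   sequences (plus strand), keyed by `chromosome`.
#' @param leaderWindow,trailerWindow window sizes in nt (defaults 50 and 35).
#' @return list with `leader` and `trailer` character sequences.
#' @export
precursorContext <- function(gene, genome = NULL,
                             leaderWindow = 50L, trailerWindow = 35L) {
  clip <- function(seq, window, side, what) {
    n <- nchar(seq)
    if (n > window) {
      seq <- if (side == "leader") substring(seq, n - window + 1L, n)
             else substring(seq, 1L, window)
    } else if (n < window) {
      warning("gene ", gene$gene_id, ": ", what, " flank shorter than window (",
              n, " < ", window, "); truncated", call. = FALSE)
    }
    seq
  }
  hasLeader <- !is.null(gene$leader_seq) && !is.na(gene$leader_seq) &&
    nzchar(gene$leader_seq)
  hasTrailer <- !is.null(gene$trailer_seq) && !is.na(gene$trailer_seq) &&
    nzchar(gene$trailer_seq)
  if (hasLeader || hasTrailer) {
    leader <- if (hasLeader) {
      clip(normalizeDna(gene$leader_seq, "leader_seq"), leaderWindow,
           "leader", "leader")
    } else ""
    trailer <- if (hasTrailer) {
      clip(normalizeDna(gene$trailer_seq, "trailer_seq"), trailerWindow,
           "trailer", "trailer")
    } else ""
    if (hasLeader && hasTrailer) {
      return(list(leader = leader, trailer = trailer))
    }
  } else {
    leader <- trailer <- NULL
  }
  if (is.null(genome)) {
    if (is.null(leader)) {
      stop("gene ", gene$gene_id,
           ": no flank sequences in metadata and no genome supplied",
           call. = FALSE)
    }
    return(list(leader = leader %||% "", trailer = trailer %||% ""))
  }
  contig <- as.character(genome[[gene$chromosome]])
  if (is.null(contig) || is.na(contig)) {
    stop("gene ", gene$gene_id, ": chromosome ", gene$chromosome,
         " not in genome", call. = FALSE)
  }
  contig <- normalizeDna(contig, "genome contig")
  clen <- nchar(contig)
  upstream <- substring(contig, max(1L, gene$genomic_start - leaderWindow),
                        gene$genomic_start - 1L)
  downstream <- substring(contig, gene$genomic_end + 1L,
                          min(clen, gene$genomic_end + trailerWindow))
  if (gene$strand == "+") {
    gl <- upstream; gt <- downstream
  } else {
    ## transcription direction: leader is genomic downstream, revcomp'd
    gl <- revComp(substring(contig, gene$genomic_end + 1L,
                            min(clen, gene$genomic_end + leaderWindow)))
    gt <- revComp(substring(contig, max(1L, gene$genomic_start - trailerWindow),
                            gene$genomic_start - 1L))
  }
  if (nchar(gl) < leaderWindow) {
    warning("gene ", gene$gene_id, ": leader flank shorter than window (",
            nchar(gl), " < ", leaderWindow, "); truncated", call. = FALSE)
  }
  if (nchar(gt) < trailerWindow) {
    warning("gene ", gene$gene_id, ": trailer flank shorter than window (",
            nchar(gt), " < ", trailerWindow, "); truncated", call. = FALSE)
  }
  list(leader = if (is.null(leader)) gl else leader,
       trailer = if (is.null(trailer)) gt else trailer)
}

#' Build the full classification reference
#'
#' Loads the gene set (or takes an already loaded one), builds the mature
#' sequences and the leader/trailer precursor windows and returns a
#' [TRNAReference-class] bundle.
#'
#' @inheritParams loadGeneSet
#' @param geneSet optional result of [loadGeneSet()] (overrides the paths).
#' @param genomeFasta optional genome FASTA for flank extraction when the
#'   metadata carries no explicit flank sequences.
#' @param leaderWindow,trailerWindow precursor window sizes (defaults 50/35).
#' @param appendCCA append the post-transcriptional CCA (default `TRUE`).
#' @return a [TRNAReference-class] object.
#' @examples
#' ref <- buildReference(geneSet = loadGeneSetFromObjects(
#'   Biostrings::DNAStringSet(c(g1 = paste(rep("ACGT", 18), collapse = ""))),
#'   data.frame(gene_id = "g1", isotype = "Ala", anticodon = "AGC",
#'              family_index = 1, chromosome = "chr1", strand = "+",
#'              genomic_start = 1001, genomic_end = 1072,
#'              leader_seq = strrep("A", 50), trailer_seq = strrep("C", 35))))
#' matureSeqs(ref)
#' @export
buildReference <- function(fastaPath = NULL, metadataPath = NULL,
                           geneSet = NULL, genomeFasta = NULL,
                           leaderWindow = 50L, trailerWindow = 35L,
                           appendCCA = TRUE) {
  if (is.null(geneSet)) {
    geneSet <- loadGeneSet(fastaPath, metadataPath)
  }
  genome <- NULL
  if (!is.null(genomeFasta)) {
    genome <- Biostrings::readDNAStringSet(genomeFasta)
    names(genome) <- sub("\\s.*$", "", names(genome))
    genome <- as.list(stats::setNames(as.character(genome), names(genome)))
  }
  genes <- geneSet$genes
  coding <- as.character(geneSet$seqs)
  mats <- vector("list", nrow(genes))
  leaders <- trailers <- character(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    mats[[i]] <- buildMature(coding[i], genes$isotype[i],
                             genes$introns[[i]], appendCCA = appendCCA)
    fl <- precursorContext(as.list(genes[i, , drop = FALSE]), genome = genome,
                           leaderWindow = leaderWindow,
                           trailerWindow = trailerWindow)
    leaders[i] <- fl$leader
    trailers[i] <- fl$trailer
  }
  ids <- genes$gene_id
  methods::new("TRNAReference",
    genes = genes,
    geneSeq = geneSet$seqs,
    mature = Biostrings::DNAStringSet(
      stats::setNames(vapply(mats, `[[`, character(1), "sequence"), ids)),
    leader = Biostrings::DNAStringSet(stats::setNames(leaders, ids)),
    trailer = Biostrings::DNAStringSet(stats::setNames(trailers, ids)),
    matureMap = stats::setNames(lapply(mats, `[[`, "map"), ids),
    params = list(leaderWindow = leaderWindow, trailerWindow = trailerWindow,
                  appendCCA = appendCCA)
  )
}

#' Serialize a reference bundle to FASTA plus a JSON manifest
#'
#' Writes one FASTA with `|mature`, `|leader`, `|trailer` suffixed ids and
#' a manifest of parameters and per-gene metadata.
#'
#' @param ref a [TRNAReference-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeReference <- function(ref, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pieces <- c(
    stats::setNames(as.character(ref@mature),
                    paste0(names(ref@mature), "|mature")),
    stats::setNames(as.character(ref@leader),
                    paste0(names(ref@leader), "|leader")),
    stats::setNames(as.character(ref@trailer),
                    paste0(names(ref@trailer), "|trailer"))
  )
  pieces <- pieces[nzchar(pieces)]
  fastaPath <- file.path(dir, "reference_spaces.fasta")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(pieces), fastaPath)
  manifest <- list(
    params = ref@params,
    genes = ref@genes[, setdiff(names(ref@genes), "introns"), drop = FALSE],
    mature_length = stats::setNames(as.integer(Biostrings::width(ref@mature)),
                                    names(ref@mature))
  )
  manifestPath <- file.path(dir, "reference_manifest.json")
  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE, digits = NA)
  invisible(c(fasta = fastaPath, manifest = manifestPath))
}
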