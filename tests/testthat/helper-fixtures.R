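# Deterministic fixtures built in code.

rcStr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

randDna <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## The published 5' sequence of the histidine tRNA fragment family used as
## a worked classification example.
PRINTED_5P_FRAGMENT <- "GCCGTGATCGTATAGTGGTTAGTACTCTGCGTTGT"

## A small deterministic reference: two His-GTG isodecoders sharing their
## 3' end (mature length 76), one Ala gene, one intron-carrying Glu gene,
## one minus-strand Gly gene. Explicit 50/35-nt flanks in the metadata.
makeToyGeneSet <- function() {
  hisBody1 <- randDna(72, seed = 101)
  b <- strsplit(hisBody1, "", fixed = TRUE)[[1]]
  b[10] <- setdiff(c("A", "C", "G", "T"), b[10])[1]
  b[25] <- setdiff(c("A", "C", "G", "T"), b[25])[1]
  hisBody2 <- paste(b, collapse = "")   # differs upstream of mature pos 55
  alaBody <- randDna(72, seed = 102)
  gluExon1 <- randDna(30, seed = 103)
  gluIntron <- randDna(10, seed = 104)
  gluExon2 <- randDna(42, seed = 105)
  gluBody <- paste0(gluExon1, gluIntron, gluExon2)  # 82 nt, intron 31-40
  glyBody <- randDna(72, seed = 106)

  ids <- c("His-1", "His-2", "Ala-1", "Glu-1", "Gly-1")
  coding <- c(hisBody1, hisBody2, alaBody, gluBody, glyBody)
  strand <- c("+", "+", "+", "+", "-")
  plus <- ifelse(strand == "-", vapply(coding, rcStr, character(1)), coding)
  meta <- data.frame(
    gene_id = ids,
    isotype = c("His", "His", "Ala", "Glu", "Gly"),
    anticodon = c("GTG", "GTG", "AGC", "CTC", "GCC"),
    family_index = c(1L, 1L, 1L, 1L, 1L),
    chromosome = c("chr1", "chr1", "chr6", "chr1", "chr12"),
    strand = strand,
    genomic_start = c(1000L, 5000L, 9000L, 13000L, 17000L),
    genomic_end = c(1000L, 5000L, 9000L, 13000L, 17000L) +
      nchar(coding) - 1L,
    intron_spans = c("", "", "", "31-40", ""),
    leader_seq = vapply(201:205, function(s) randDna(50, s), character(1)),
    trailer_seq = vapply(301:305, function(s) randDna(35, s), character(1)),
    anticodon_position = c(34L, 34L, NA, NA, NA),
    stringsAsFactors = FALSE
  )
  list(seqs = Biostrings::DNAStringSet(stats::setNames(unname(plus), ids)),
       metadata = meta)
}

makeToyReference <- function() {
  gs <- makeToyGeneSet()
  buildReference(geneSet = loadGeneSetFromObjects(gs$seqs, gs$metadata))
}

## A His reference whose mature positions 2-36 spell the printed fragment
## (G-1 prepended, CCA appended).
makePrintedHisReference <- function() {
  body <- paste0(PRINTED_5P_FRAGMENT, randDna(37, seed = 107))  # 72 nt
  meta <- data.frame(
    gene_id = "His-printed", isotype = "His", anticodon = "GTG",
    family_index = 1L, chromosome = "chr1", strand = "+",
    genomic_start = 1000L, genomic_end = 1071L, intron_spans = "",
    leader_seq = randDna(50, 108), trailer_seq = randDna(35, 109),
    anticodon_position = NA_integer_, stringsAsFactors = FALSE
  )
  buildReference(geneSet = loadGeneSetFromObjects(
    Biostrings::DNAStringSet(c("His-printed" = body)), meta))
}

## Independent naive placement oracle: all-offsets substring scan of every
## region string, with the same class rules applied per placement.
naiveClassify <- function(fragment, ref,
                          startTolerance = 1L, hisStartTolerance = 2L) {
  genes <- geneInfo(ref)
  L <- nchar(fragment)
  res <- list()
  scan <- function(subject) {
    n <- nchar(subject)
    if (L > n) return(integer(0))
    starts <- seq_len(n - L + 1L)
    starts[substring(subject, starts, starts + L - 1L) == fragment]
  }
  for (i in seq_len(nrow(genes))) {
    gid <- genes$gene_id[i]
    tol <- if (genes$isotype[i] == "His") hisStartTolerance else startTolerance
    spaces <- list(mature = as.character(matureSeqs(ref)[[i]]),
                   trailer = as.character(trailerSeqs(ref)[[i]]),
                   leader = as.character(leaderSeqs(ref)[[i]]))
    for (region in names(spaces)) {
      for (s in scan(spaces[[region]])) {
        e <- s + L - 1L
        cls <- switch(region,
          mature = if (e == nchar(spaces$mature)) "3p_trf"
                   else if (s <= tol) "5p_trf" else "i_trf",
          trailer = if (s == 1L) "trf1" else NA_character_,
          leader = if (e == nchar(spaces$leader)) "5pU_trf"
                   else NA_character_)
        res[[length(res) + 1L]] <- data.frame(
          gene_id = gid, region = region, start = s, end = e, class = cls,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(res)) {
    return(list(trf_class = "unclassified",
                placements = data.frame(gene_id = character(0),
                                        region = character(0),
                                        start = integer(0),
                                        end = integer(0))))
  }
  all <- do.call(rbind, res)
  prec <- c("3p_trf" = 5, "5p_trf" = 4, "i_trf" = 3, "trf1" = 2,
            "5pU_trf" = 1)
  cls <- all$class[!is.na(all$class)]
  if (!length(cls)) {
    return(list(trf_class = "unclassified",
                placements = all[0, c("gene_id", "region", "start", "end")]))
  }
  best <- names(which.max(prec[unique(cls)]))
  keep <- all[!is.na(all$class) & all$class == best, , drop = FALSE]
  keep <- keep[order(keep$gene_id, keep$start), ]
  rownames(keep) <- NULL
  list(trf_class = best,
       placements = keep[, c("gene_id", "region", "start", "end")])
}

## Random fragment generator for oracle checks: mixes true substrings of
## the reference spaces with random sequences.
sampleFragments <- function(ref, n, seed) {
  set.seed(seed)
  spaces <- c(as.character(matureSeqs(ref)),
              as.character(trailerSeqs(ref)),
              as.character(leaderSeqs(ref)))
  spaces <- spaces[nchar(spaces) >= 16]
  out <- character(n)
  for (i in seq_len(n)) {
    if (stats::runif(1) < 0.7) {
      s <- sample(spaces, 1)
      L <- sample(16:min(35, nchar(s)), 1)
      a <- sample(nchar(s) - L + 1L, 1)
      out[i] <- substr(s, a, a + L - 1L)
    } else {
      out[i] <- paste(sample(c("A", "C", "G", "T"), sample(16:35, 1),
                             replace = TRUE), collapse = "")
    }
  }
  out
}

writeFastqFile <- function(seqs, path, ids = NULL) {
  ids <- ids %||% sprintf("r%04d", seq_along(seqs))
  lines <- as.vector(rbind(paste0("@", ids), seqs, "+",
                           strrep("I", nchar(seqs))))
  writeLines(lines, path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a
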