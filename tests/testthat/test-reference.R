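# Reference construction: gene loading, splicing, CCA/G-1, flank windows.

test_that("loadGeneSet loads a single gene and rejects unmatched records", {
  gs <- makeToyGeneSet()
  one <- loadGeneSetFromObjects(gs$seqs[1], gs$metadata[1, ])
  expect_equal(nrow(one$genes), 1L)
  expect_equal(as.character(one$seqs[[1]]), as.character(gs$seqs[[1]]))

  expect_error(loadGeneSetFromObjects(gs$seqs, gs$metadata[-2, ]), "His-2")
  expect_error(loadGeneSetFromObjects(gs$seqs[-2], gs$metadata), "His-2")
  dupMeta <- rbind(gs$metadata, gs$metadata[1, ])
  expect_error(loadGeneSetFromObjects(gs$seqs, dupMeta), "duplicate")
})

test_that("minus-strand genes are stored as coding-strand sequence", {
  gs <- makeToyGeneSet()
  loaded <- loadGeneSetFromObjects(gs$seqs, gs$metadata)
  gly <- as.character(loaded$seqs[["Gly-1"]])
  ## hand reverse complement of the plus-strand FASTA record
  plus <- as.character(gs$seqs[["Gly-1"]])
  hand <- chartr("ACGT", "TGCA", paste(rev(strsplit(plus, "")[[1]]),
                                       collapse = ""))
  expect_identical(gly, hand)
  ## plus-strand genes are untouched
  expect_identical(as.character(loaded$seqs[["His-1"]]),
                   as.character(gs$seqs[["His-1"]]))
})

test_that("round-trip through FASTA + TSV files preserves the gene set", {
  gs <- makeToyGeneSet()
  fa <- tempfile(fileext = ".fasta"); tsv <- tempfile(fileext = ".tsv")
  Biostrings::writeXStringSet(gs$seqs, fa)
  write.table(gs$metadata, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  loaded <- loadGeneSet(fa, tsv)
  mem <- loadGeneSetFromObjects(gs$seqs, gs$metadata)
  expect_identical(as.character(loaded$seqs), as.character(mem$seqs))
  expect_identical(loaded$genes$gene_id, mem$genes$gene_id)
})

test_that("buildMature implements splicing, CCA addition and His G-1", {
  # non-His 72-nt intron-less gene: 72 + 3
  m1 <- buildMature(randDna(72, 1), "Ala")
  expect_equal(nchar(m1$sequence), 75L)
  expect_true(endsWith(m1$sequence, "CCA"))
  # His 72-nt gene: 72 + 1 + 3 = 76, position 1 is the post-transcriptional G
  m2 <- buildMature(randDna(72, 2), "His")
  expect_equal(nchar(m2$sequence), 76L)
  expect_identical(substr(m2$sequence, 1, 1), "G")
  expect_true(is.na(m2$map[1]))
  # one 10-nt intron in an 82-nt gene: 82 - 10 + 3 = 75
  m3 <- buildMature(randDna(82, 3), "Glu",
                    introns = cbind(start = 31L, end = 40L))
  expect_equal(nchar(m3$sequence), 75L)
  # determinism / idempotence
  expect_identical(buildMature(randDna(72, 1), "Ala"), m1)
})

test_that("mature sequences reconstruct the gene exactly (round trip)", {
  ref <- makeToyReference()
  genes <- geneInfo(ref)
  for (i in seq_len(nrow(genes))) {
    map <- matureToGeneMap(ref)[[i]]
    mat <- as.character(matureSeqs(ref)[[i]])
    gene <- as.character(ref@geneSeq[[i]])
    ## non-post-transcriptional positions map injectively into the gene
    templated <- map[!is.na(map)]
    expect_false(anyDuplicated(templated) > 0)
    ## re-inserting introns at the mapped positions reproduces the gene
    rebuilt <- strsplit(gene, "")[[1]]
    matBases <- strsplit(mat, "")[[1]]
    expect_identical(paste(rebuilt[templated], collapse = ""),
                     paste(matBases[!is.na(map)], collapse = ""))
    ## spliced gene is a substring of the mature sequence
    spliced <- paste(strsplit(gene, "")[[1]][sort(templated)], collapse = "")
    expect_true(grepl(spliced, mat, fixed = TRUE))
  }
})

test_that("precursor windows honour explicit flanks, strand and truncation", {
  gs <- makeToyGeneSet()
  gene <- as.list(gs$metadata[1, ])
  ctx <- precursorContext(gene)
  expect_identical(ctx$trailer, gene$trailer_seq)  # 35-nt flank, identity
  expect_identical(ctx$leader, gene$leader_seq)
  expect_equal(nchar(ctx$trailer), 35L)

  ## minus-strand gene on a toy contig: trailer = revcomp of the genomic
  ## upstream flank
  contig <- paste0(randDna(40, 7), randDna(20, 8), randDna(10, 9))
  gene2 <- list(gene_id = "g-", strand = "-", chromosome = "c",
                genomic_start = 41L, genomic_end = 60L)
  ctx2 <- suppressWarnings(
    precursorContext(gene2, genome = list(c = contig),
                     leaderWindow = 10L, trailerWindow = 10L))
  expect_identical(ctx2$trailer, rcStr(substr(contig, 31, 40)))
  expect_identical(ctx2$leader, rcStr(substr(contig, 61, 70)))

  ## contig ends 20 nt after the gene: trailer truncated with a warning
  gene3 <- list(gene_id = "g+", strand = "+", chromosome = "c",
                genomic_start = 11L, genomic_end = 50L)
  expect_warning(
    ctx3 <- precursorContext(gene3, genome = list(c = contig),
                             leaderWindow = 10L, trailerWindow = 35L),
    "truncated")
  expect_equal(nchar(ctx3$trailer), 20L)
  expect_identical(ctx3$trailer, substr(contig, 51, 70))
})

test_that("the reference bundle validates and serializes", {
  ref <- makeToyReference()
  expect_s4_class(ref, "TRNAReference")
  expect_true(validObject(ref))
  expect_equal(length(ref), 5L)
  mats <- as.character(matureSeqs(ref))
  expect_true(all(endsWith(mats, "CCA")))
  his <- geneInfo(ref)$isotype == "His"
  expect_true(all(substr(mats[his], 1, 1) == "G"))
  expect_true(all(Biostrings::width(trailerSeqs(ref)) == 35L))
  expect_true(all(Biostrings::width(leaderSeqs(ref)) == 50L))

  dir <- tempfile()
  paths <- writeReference(ref, dir)
  expect_true(all(file.exists(paths)))
  back <- Biostrings::readDNAStringSet(paths["fasta"])
  expect_equal(sum(endsWith(names(back), "|mature")), 5L)
  expect_identical(as.character(back[["His-1|mature"]]), mats[["His-1"]])
})
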