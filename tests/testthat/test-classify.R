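# Fragment classification, multimap counting and tDR naming.

test_that("the published His 5' fragment classifies as a 5' half", {
  ref <- makePrintedHisReference()
  hit <- classifyFragment(PRINTED_5P_FRAGMENT, ref)
  expect_equal(hit$trf_class, "5p_trf")
  expect_true(hit$is_5p_half)
  expect_equal(hit$length, 35L)
  expect_equal(hit$placements$start, 2L)   # downstream of the G-1
  expect_equal(hit$placements$end, 36L)
  ## brute-force confirmation of the placement
  mat <- as.character(matureSeqs(ref)[[1]])
  expect_identical(substr(mat, 2, 36), PRINTED_5P_FRAGMENT)
})

test_that("3' fragments end at the CCA-inclusive mature terminus", {
  ref <- makeToyReference()
  mat <- as.character(matureSeqs(ref)[["His-1"]])
  frag <- substr(mat, nchar(mat) - 16L, nchar(mat))  # last 17 nt
  hit <- classifyFragment(frag, ref)
  expect_equal(hit$trf_class, "3p_trf")
  expect_true(all(hit$placements$start == 60L))
  expect_true(all(hit$placements$end == 76L))
  ## both isodecoders share the 3' end: two placements, two distinct seqs
  expect_equal(nrow(hit$placements), 2L)
  expect_equal(hit$multimap_count, 2L)
})

test_that("length bounds, trailer and leader rules apply", {
  ref <- makeToyReference()
  mat <- as.character(matureSeqs(ref)[["Ala-1"]])
  expect_equal(classifyFragment(substr(mat, 1, 15), ref)$trf_class,
               "unclassified")  # 15-mer below the minimum
  expect_equal(classifyFragment(substr(mat, 1, 16), ref)$trf_class,
               "5p_trf")        # 16-mer accepted

  trail <- as.character(trailerSeqs(ref)[["Ala-1"]])
  expect_equal(classifyFragment(substr(trail, 1, 35), ref)$trf_class, "trf1")
  offPrefix <- classifyFragment(substr(trail, 2, 20), ref)
  expect_equal(offPrefix$trf_class, "unclassified")
  expect_equal(nrow(offPrefix$placements), 0L)

  lead <- as.character(leaderSeqs(ref)[["Ala-1"]])
  expect_equal(classifyFragment(substr(lead, 31, 50), ref)$trf_class,
               "5pU_trf")
  expect_equal(classifyFragment(substr(lead, 30, 49), ref)$trf_class,
               "unclassified")

  expect_error(classifyFragment("", ref), "non-empty")
  expect_error(classifyFragment("ACGTACGTACGTACGTN", ref), "non-DNA")
})

test_that("mature placements outrank trailer and leader placements", {
  gs <- makeToyGeneSet()
  mat1 <- buildMature(as.character(gs$seqs[["His-1"]]), "His")$sequence
  frag <- substr(mat1, 60, 76)
  ## plant the same 17-mer as a trailer prefix of the Ala gene
  gs$metadata$trailer_seq[3] <- paste0(frag, randDna(18, seed = 999))
  ref <- buildReference(geneSet = loadGeneSetFromObjects(gs$seqs,
                                                         gs$metadata))
  hit <- classifyFragment(frag, ref)
  expect_equal(hit$trf_class, "3p_trf")
  expect_true(all(hit$placements$region == "mature"))
  expect_gt(hit$n_dropped_placements, 0L)
})

test_that("classification agrees with the naive all-offsets oracle", {
  ref <- makeToyReference()
  frags <- sampleFragments(ref, 250L, seed = 11)
  for (f in frags) {
    got <- classifyFragment(f, ref)
    want <- naiveClassify(f, ref)
    expect_identical(got$trf_class, want$trf_class)
    expect_equal(got$placements, want$placements,
                 ignore_attr = TRUE)
  }
})

test_that("buildCatalog deduplicates, summarises and is order-invariant", {
  ref <- makeToyReference()
  mats <- as.character(matureSeqs(ref))
  trails <- as.character(trailerSeqs(ref))
  leads <- as.character(leaderSeqs(ref))
  last <- function(s, k) substr(s, nchar(s) - k + 1L, nchar(s))
  seqs <- c(
    t1 = substr(trails[["Ala-1"]], 1, 20),
    t2 = substr(trails[["Glu-1"]], 1, 22),
    t3 = substr(trails[["Gly-1"]], 1, 24),
    p3a = last(mats[["His-1"]], 17),
    p3b = last(mats[["Ala-1"]], 18),
    p3c = last(mats[["Glu-1"]], 19),
    p5a = substr(mats[["Ala-1"]], 1, 20),
    p5b = substr(mats[["Gly-1"]], 1, 21),
    ia = substr(mats[["Ala-1"]], 10, 30),
    ua = last(leads[["Ala-1"]], 25)
  )
  cat_ <- buildCatalog(seqs, ref)
  counts <- classSummary(cat_)$class_counts
  expect_equal(as.vector(counts[c("trf1", "3p_trf", "5p_trf", "i_trf",
                                  "5pU_trf")]),
               c(3L, 3L, 2L, 1L, 1L))
  expect_equal(sum(classSummary(cat_)$class_proportions), 1)

  ## duplicate sequence under a second id: dropped with a warning
  expect_warning(
    dup <- buildCatalog(c(seqs, t1copy = unname(seqs["t1"])), ref),
    "duplicate")
  expect_equal(nrow(fragmentInfo(dup)), length(seqs))

  ## input order does not change per-sequence results
  perm <- rev(seqs)
  cat2 <- buildCatalog(perm, ref)
  a <- fragmentInfo(cat_); a <- a[order(a$sequence), -1]
  b <- fragmentInfo(cat2); b <- b[order(b$sequence), -1]
  rownames(a) <- rownames(b) <- NULL
  expect_identical(a, b)

  expect_error(buildCatalog(character(0), ref), "empty")
})

test_that("tDR naming uses the smallest mature placement and multimap count", {
  ref <- makeToyReference()
  mats <- as.character(matureSeqs(ref))
  last <- function(s, k) substr(s, nchar(s) - k + 1L, nchar(s))
  ## shared His 3' 17-mer: present in 2 distinct isodecoder sequences
  hit <- classifyFragment(last(mats[["His-1"]], 17), ref)
  expect_identical(formatTdrId(nameFragment(hit, ref)),
                   "tDR-60:76-His-GTG-1-M2")
  hit22 <- classifyFragment(last(mats[["His-1"]], 22), ref)
  expect_identical(formatTdrId(nameFragment(hit22, ref)),
                   "tDR-55:76-His-GTG-1-M2")
  ## single-source fragment: no -M suffix
  hitAla <- classifyFragment(last(mats[["Ala-1"]], 18), ref)
  expect_identical(formatTdrId(nameFragment(hitAla, ref)),
                   "tDR-58:75-Ala-AGC-1")
  ## leader/trailer classes cannot carry a mature-span name
  trail <- as.character(trailerSeqs(ref)[["Ala-1"]])
  hitT <- classifyFragment(substr(trail, 1, 20), ref)
  expect_error(nameFragment(hitT, ref), "do not apply")
})

test_that("tDR id grammar: parse and format are mutually inverse", {
  x <- parseTdrId("tDR-60:76-His-GTG-1-M2")
  expect_equal(x[c("start", "end")], list(start = 60L, end = 76L))
  expect_equal(x$isotype, "His")
  expect_equal(x$anticodon, "GTG")
  expect_equal(x$familyIndex, 1L)
  expect_equal(x$multimapCount, 2L)

  set.seed(21)
  for (i in 1:50) {
    s <- sample(1:70, 1); e <- s + sample(15:30, 1)
    nm <- tdrName(s, e, sample(c("His", "Ala", "Gly"), 1),
                  paste(sample(c("A", "C", "G", "T"), 3, TRUE),
                        collapse = ""),
                  sample(1:9, 1), sample(1:4, 1))
    expect_identical(parseTdrId(formatTdrId(nm)), nm)
  }

  expect_error(parseTdrId("tDR-76:60-His-GTG-1"), "start.*>.*end")
  expect_error(parseTdrId("tDR-60:76-HIS-GTG-1"), "malformed")
  expect_error(parseTdrId("tdr-60:76-His-GTG-1"), "malformed")
  expect_error(parseTdrId("tDR-60:76-His-GUG-1"), "malformed")
})
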