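# Synthetic-data generators: determinism, planted structure, error model.

test_that("generators are bit-reproducible under a fixed seed", {
  cfg <- simulationConfig(seed = 33)
  a <- simulateReference(cfg); b <- simulateReference(cfg)
  expect_identical(as.character(a$seqs), as.character(b$seqs))
  expect_identical(a$metadata, b$metadata)
  ref <- buildReference(geneSet = loadGeneSetFromObjects(a$seqs, a$metadata))
  s1 <- simulateSignatures(ref, cfg); s2 <- simulateSignatures(ref, cfg)
  expect_identical(s1, s2)
  c1 <- simulateCohort(cfg, s1$signature_id)
  c2 <- simulateCohort(cfg, s1$signature_id)
  expect_identical(c1$counts, c2$counts)
  expect_identical(c1$clinical, c2$clinical)
  d1 <- tempfile(); d2 <- tempfile()
  f1 <- simulateReads(cfg, setNames(s1$sequence, s1$signature_id),
                      c1$counts[, 1:2], d1)
  f2 <- simulateReads(cfg, setNames(s1$sequence, s1$signature_id),
                      c1$counts[, 1:2], d2)
  expect_identical(readLines(f1[1]), readLines(f2[1]))
})

test_that("simulated reference exercises the multimap His family", {
  cfg <- simulationConfig(seed = 34, nGenes = 6)
  sim <- simulateReference(cfg)
  expect_equal(length(sim$seqs), 6L)
  expect_equal(nrow(sim$metadata), 6L)
  ref <- buildReference(geneSet = loadGeneSetFromObjects(sim$seqs,
                                                         sim$metadata))
  sigs <- simulateSignatures(ref, cfg)
  cat_ <- buildCatalog(sigs, ref)
  info <- fragmentInfo(cat_)
  ## the two His isodecoders share their 3' 22-mer: both printed spans
  ## surface with an -M2 suffix
  expect_true("tDR-60:76-His-GTG-1-M2" %in% info$tdr_name)
  expect_true("tDR-55:76-His-GTG-1-M2" %in% info$tdr_name)
  ## every drawn class is represented
  expect_setequal(setdiff(unique(info$trf_class), "unclassified"),
                  c("5p_trf", "3p_trf", "i_trf", "trf1", "5pU_trf"))
})

test_that("file output round-trips through the loaders", {
  cfg <- simulationConfig(seed = 35, nGenes = 5)
  dir <- tempfile()
  sim <- simulateReference(cfg, dir = dir)
  ref <- buildReference(sim$fastaPath, sim$metadataPath)
  refMem <- buildReference(geneSet = loadGeneSetFromObjects(sim$seqs,
                                                            sim$metadata))
  expect_identical(as.character(matureSeqs(ref)),
                   as.character(matureSeqs(refMem)))
})

test_that("planted fold changes shape the simulated counts", {
  cfg <- simulationConfig(seed = 36, nTumor = 40, nNormal = 40,
                          plantedLfc = c(up = 3, down = -3),
                          dispersion = 0.1)
  co <- simulateCohort(cfg, c("up", "down", "null1", "null2"))
  g <- co$clinical$group
  ratio <- function(id) {
    log2(mean(co$counts[id, g == "tumor"]) /
         mean(co$counts[id, g == "normal"]))
  }
  expect_gt(ratio("up"), 1.5)
  expect_lt(ratio("down"), -1.5)
  expect_lt(abs(ratio("null1")), 1)
  ## all-zero plant: a DE null fixture
  cfg0 <- simulationConfig(seed = 37, plantedLfc = c(none = 0))
  co0 <- simulateCohort(cfg0, paste0("s", 1:6))
  expect_true(all(co0$plantedLfc == 0))
})

test_that("planted correlations dominate the Spearman ranking", {
  cfg <- simulationConfig(seed = 38, nTumor = 60, nMrna = 200,
                          plantedRho = rep(0.8, 40))
  co <- simulateCohort(cfg, paste0("s", 1:5))
  expr <- log2(sweep(co$counts, 2, colSums(co$counts), "/") * 1e6 + 1)
  tum <- co$clinical$sample_id[co$clinical$group == "tumor"]
  target <- setNames(expr[co$biomarker, tum], tum)
  top <- spearmanTopK(target, co$mrna, k = 40)
  planted <- sprintf("gene-%03d", 1:40)
  expect_gt(mean(top$gene %in% planted), 0.8)
  expect_error(simulationConfig(seed = 1, plantedRho = 0.999),
               "infeasible")
})

test_that("reads invert the counts at zero error rate", {
  cfg <- simulationConfig(seed = 39, nGenes = 5, errorRate = 0)
  sim <- simulateReference(cfg)
  ref <- buildReference(geneSet = loadGeneSetFromObjects(sim$seqs,
                                                         sim$metadata))
  sigs <- simulateSignatures(ref, cfg)
  cat_ <- buildCatalog(sigs, ref)
  co <- simulateCohort(cfg, sigs$signature_id)
  fq <- simulateReads(cfg, setNames(sigs$sequence, sigs$signature_id),
                      co$counts[, 1:3], tempfile())
  se <- countSamples(fq, cat_)
  expect_identical(as.matrix(SummarizedExperiment::assay(se, "counts")),
                   co$counts[, 1:3])
  ## background reads never increment a signature
  zero <- co$counts[, 1:2]; zero[] <- 0L
  fq0 <- simulateReads(cfg, setNames(sigs$sequence, sigs$signature_id),
                       zero, tempfile())
  se0 <- suppressWarnings(countSamples(fq0, cat_))
  expect_true(all(SummarizedExperiment::assay(se0, "counts") == 0))
  expect_true(all(SummarizedExperiment::colData(se0)$librarySize == 0))
})

test_that("substitution errors deplete counts by about 1-(1-eps)^L", {
  eps <- 0.01
  cfg <- simulationConfig(seed = 40, nGenes = 5, errorRate = eps,
                          backgroundFraction = 0)
  sim <- simulateReference(cfg)
  ref <- buildReference(geneSet = loadGeneSetFromObjects(sim$seqs,
                                                         sim$metadata))
  sigs <- simulateSignatures(ref, cfg)
  cat_ <- buildCatalog(sigs, ref)
  planted <- matrix(500L, nrow(sigs), 2,
                    dimnames = list(sigs$signature_id, c("a", "b")))
  fq <- simulateReads(cfg, setNames(sigs$sequence, sigs$signature_id),
                      planted, tempfile())
  se <- countSamples(fq, cat_)
  got <- as.matrix(SummarizedExperiment::assay(se, "counts"))
  expect_true(all(got <= planted))
  L <- nchar(sigs$sequence)
  expectedKeep <- (1 - eps)^L
  deficit <- 1 - got / planted
  ## binomial expectation check, 5 sigma slack at n = 500
  tol <- 5 * sqrt(expectedKeep * (1 - expectedKeep) / 500)
  expect_true(all(abs(deficit - (1 - expectedKeep)) < tol))
})

test_that("clinical table mirrors the incomplete-pairing design", {
  cfg <- simulationConfig(seed = 41)
  co <- simulateCohort(cfg, paste0("s", 1:4))
  cl <- co$clinical
  expect_equal(sum(cl$group == "tumor"), 16L)
  expect_equal(sum(cl$group == "normal"), 9L)
  paired <- cl$pair_id[!is.na(cl$pair_id)]
  expect_equal(sum(table(paired) == 2), 9L)   # 9 complete pairs
  tum <- cl[cl$group == "tumor", ]
  expect_true(all(tum$os_time > 0))
  expect_true(all(tum$os_event %in% 0:1))
  expect_true(all(is.na(cl$os_time[cl$group == "normal"])))
})
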