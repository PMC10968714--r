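# Seeded generators emulating every input the pipeline consumes: tRNA gene
# sets, fragment signatures, negative-binomial cohort counts with planted
# fold changes, exponential survival with expression-dependent hazard,
# pathology categories, copula-correlated mRNA, FASTQ reads and 3'UTRs
# with planted seed sites.

#' Simulation configuration
#'
#' Bundles and validates the parameters of the synthetic-data generators.
#' Group sizes default to 16 tumors and 9 normals, mirroring the scale of
#' the paired small-cohort design the cohort statistics are aimed at.
#'
#' @param seed mandatory integer seed; every generator derives its
#'   randomness from it (same seed, byte-identical outputs).
#' @param nGenes number of tRNA-like genes (>= 4).
#' @param nHisIsodecoders number of His-GTG isodecoders sharing their 3'
#'   end (>= 2 exercises multimap naming).
#' @param geneLengthRange gene body length range (default 70-90 nt).
#' @param signaturesPerClass named integer vector of fragment counts per
#'   class to draw (`5p_trf`, `3p_trf`, `i_trf`, `trf1`, `5pU_trf`).
#' @param nTumor,nNormal cohort group sizes (defaults 16 and 9).
#' @param baselineMean mean baseline count per signature.
#' @param dispersion negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`).
#' @param plantedLfc named numeric vector of log2 fold changes
#'   (tumor vs normal) keyed by signature id, or `NULL` to plant defaults
#'   at cohort-simulation time.
#' @param backgroundFraction fraction of each library made of background
#'   reads matching no signature.
#' @param errorRate per-base substitution rate applied to signature reads.
#' @param baselineHazard exponential baseline hazard (events per day).
#' @param plantedBeta log hazard ratio per SD of the biomarker's log2
#'   expression (negative by default: low expression carries the risk).
#' @param censoringTime upper bound of the uniform censoring window (days).
#' @param nMrna number of mRNA genes in the correlation matrix.
#' @param plantedRho numeric vector of target Spearman correlations for the
#'   first `length(plantedRho)` mRNA genes (|rho| <= 0.99).
#' @param nUtr,utrLength number and length of synthetic 3'UTRs.
#' @return a validated list of class `SimulationConfig`.
#' @export
simulationConfig <- function(seed,
                             nGenes = 8L,
                             nHisIsodecoders = 2L,
                             geneLengthRange = c(70L, 90L),
                             signaturesPerClass = c("5p_trf" = 2L,
                                                    "3p_trf" = 2L,
                                                    "i_trf" = 2L,
                                                    "trf1" = 2L,
                                                    "5pU_trf" = 2L),
                             nTumor = 16L, nNormal = 9L,
                             baselineMean = 200,
                             dispersion = 0.3,
                             plantedLfc = NULL,
                             backgroundFraction = 0.3,
                             errorRate = 0,
                             baselineHazard = 0.002,
                             plantedBeta = -log(2),
                             censoringTime = 2000,
                             nMrna = 300L,
                             plantedRho = rep(0.8, 50L),
                             nUtr = 20L,
                             utrLength = 200L) {
  if (missing(seed) || is.na(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(nGenes >= 4L, nHisIsodecoders >= 2L,
            geneLengthRange[1] >= 40L, geneLengthRange[2] >= geneLengthRange[1],
            nTumor >= 2L, nNormal >= 2L,
            baselineMean > 0, dispersion >= 0,
            backgroundFraction >= 0, backgroundFraction < 1,
            errorRate >= 0, errorRate < 1,
            baselineHazard > 0, censoringTime > 0,
            nMrna >= 1L, nUtr >= 0L, utrLength >= 30L)
  if (any(abs(plantedRho) > 0.99)) {
    stop("infeasible correlation: |rho| must be <= 0.99", call. = FALSE)
  }
  if (length(plantedRho) > nMrna) {
    stop("more planted correlations than mRNA genes", call. = FALSE)
  }
  structure(list(
    seed = as.integer(seed), nGenes = as.integer(nGenes),
    nHisIsodecoders = as.integer(nHisIsodecoders),
    geneLengthRange = as.integer(geneLengthRange),
    signaturesPerClass = signaturesPerClass,
    nTumor = as.integer(nTumor), nNormal = as.integer(nNormal),
    baselineMean = baselineMean, dispersion = dispersion,
    plantedLfc = plantedLfc,
    backgroundFraction = backgroundFraction, errorRate = errorRate,
    baselineHazard = baselineHazard, plantedBeta = plantedBeta,
    censoringTime = censoringTime, nMrna = as.integer(nMrna),
    plantedRho = plantedRho, nUtr = as.integer(nUtr),
    utrLength = as.integer(utrLength)
  ), class = "SimulationConfig")
}

.randomDna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.OTHER_ISOTYPES <- data.frame(
  isotype = c("Ala", "Gly", "Glu", "Lys", "Cys", "Asp", "Val", "Leu"),
  anticodon = c("AGC", "GCC", "CTC", "CTT", "GCA", "GTC", "AAC", "AAG"),
  stringsAsFactors = FALSE
)

#' Simulate a tRNA gene set (FASTA + metadata)
#'
#' Generates random tRNA-like genes with valid metadata, guaranteeing one
#' His-GTG family with `nHisIsodecoders` isodecoders that share their 3'
#' 22-mer but differ upstream (so 3'-end fragments carry an `-M<k>`
#' multimap suffix). Explicit 50-nt leader and 35-nt trailer flanks are
#' written into the metadata; minus-strand genes are emitted as plus-strand
#' genomic sequence in the FASTA.
#'
#' @param config a [simulationConfig()].
#' @param dir optional directory; when given, `genes.fasta` and
#'   `genes.tsv` are written there.
#' @return list with `seqs` (plus-strand [Biostrings::DNAStringSet]),
#'   `metadata` (`data.frame`) and, when `dir` is given, `fastaPath` /
#'   `metadataPath`.
#' @export
simulateReference <- function(config, dir = NULL) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  nHis <- config$nHisIsodecoders
  nOther <- config$nGenes - nHis
  if (nOther < 0L) stop("nGenes smaller than nHisIsodecoders", call. = FALSE)

  ## His-GTG isodecoders: a 72-nt body (mature length 76 with G-1 + CCA)
  ## sharing the 3' end, differing at two upstream positions per isodecoder.
  hisBody <- .randomDna(72L)
  hisSeqs <- character(nHis)
  hisSeqs[1L] <- hisBody
  for (k in seq_len(nHis - 1L)) {
    body <- strsplit(hisBody, "", fixed = TRUE)[[1]]
    for (pos in c(8L + k, 20L + k)) {   # well upstream of the shared 3' 22-mer
      body[pos] <- sample(setdiff(c("A", "C", "G", "T"), body[pos]), 1L)
    }
    hisSeqs[k + 1L] <- paste(body, collapse = "")
  }
  otherIdx <- sample(nrow(.OTHER_ISOTYPES), nOther, replace = TRUE)
  otherLen <- sample(seq(config$geneLengthRange[1], config$geneLengthRange[2]),
                     nOther, replace = TRUE)
  otherSeqs <- vapply(otherLen, .randomDna, character(1))

  ids <- c(sprintf("tRNA-His-GTG-1-%d", seq_len(nHis)),
           sprintf("tRNA-%s-%s-%d-1", .OTHER_ISOTYPES$isotype[otherIdx],
                   .OTHER_ISOTYPES$anticodon[otherIdx], seq_len(nOther)))
  coding <- c(hisSeqs, otherSeqs)
  isotype <- c(rep("His", nHis), .OTHER_ISOTYPES$isotype[otherIdx])
  anticodon <- c(rep("GTG", nHis), .OTHER_ISOTYPES$anticodon[otherIdx])
  family <- c(rep(1L, nHis), rep(1L, nOther))
  n <- length(ids)
  ## chromosome mix loosely mirrors a chr1/chr6-heavy genomic distribution
  chrom <- sample(c("chr1", "chr6", "chr12", "chr15", "chr17"), n,
                  replace = TRUE, prob = c(0.35, 0.2, 0.15, 0.15, 0.15))
  strand <- sample(c("+", "-"), n, replace = TRUE)
  start <- cumsum(sample(1000:5000, n)) + 10000L
  meta <- data.frame(
    gene_id = ids, isotype = isotype, anticodon = anticodon,
    family_index = family, chromosome = chrom, strand = strand,
    genomic_start = start, genomic_end = start + nchar(coding) - 1L,
    intron_spans = "",
    leader_seq = vapply(seq_len(n), function(i) .randomDna(50L), character(1)),
    trailer_seq = vapply(seq_len(n), function(i) .randomDna(35L), character(1)),
    anticodon_position = c(rep(34L, nHis), rep(NA_integer_, nOther)),
    stringsAsFactors = FALSE
  )
  plus <- coding
  neg <- meta$strand == "-"
  plus[neg] <- revComp(coding[neg])
  seqs <- Biostrings::DNAStringSet(stats::setNames(plus, ids))
  out <- list(seqs = seqs, metadata = meta)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    out$fastaPath <- file.path(dir, "genes.fasta")
    out$metadataPath <- file.path(dir, "genes.tsv")
    Biostrings::writeXStringSet(seqs, out$fastaPath)
    utils::write.table(meta, out$metadataPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  out
}

#' Simulate fragment signatures from a reference
#'
#' Draws fragments of each class from the reference spaces: 5' fragments
#' (starting at the mature 5' end, position 2 for His genes), 3' fragments
#' ending at the CCA 3' end (always including the His 17-mer and 22-mer
#' spans 60:76 and 55:76 so `-M<k>` naming is exercised), internal
#' fragments, trailer prefixes (tRF-1) and leader suffixes (5'U-tRF).
#'
#' @param ref a [TRNAReference-class] built from [simulateReference()]
#'   output.
#' @param config a [simulationConfig()].
#' @return `data.frame` with columns `signature_id`, `sequence` (unique
#'   sequences).
#' @export
simulateSignatures <- function(ref, config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed + 1L)
  genes <- ref@genes
  mat <- as.character(ref@mature)
  lead <- as.character(ref@leader)
  trail <- as.character(ref@trailer)
  per <- config$signaturesPerClass
  seqs <- character(0)

  hisIdx <- which(genes$isotype == "His")
  pickGene <- function(k) sample(seq_len(nrow(genes)), k, replace = TRUE)

  ## 3' fragments: the His 60:76 and 55:76 spans first, then random genes
  n3 <- per[["3p_trf"]] %||% 0L
  if (n3 >= 1L && length(hisIdx)) {
    hm <- mat[hisIdx[1L]]
    seqs <- c(seqs, substr(hm, 60L, 76L))
    if (n3 >= 2L) seqs <- c(seqs, substr(hm, 55L, 76L))
    extra <- n3 - min(n3, 2L)
  } else {
    extra <- n3
  }
  for (g in pickGene(extra)) {
    L <- sample(16:30, 1L)
    m <- mat[g]
    seqs <- c(seqs, substr(m, nchar(m) - L + 1L, nchar(m)))
  }
  for (g in pickGene(per[["5p_trf"]] %||% 0L)) {
    L <- sample(16:30, 1L)
    s <- if (genes$isotype[g] == "His") 2L else 1L
    seqs <- c(seqs, substr(mat[g], s, s + L - 1L))
  }
  for (g in pickGene(per[["i_trf"]] %||% 0L)) {
    L <- sample(16:25, 1L)
    s <- sample(4:(nchar(mat[g]) - L - 3L), 1L)
    seqs <- c(seqs, substr(mat[g], s, s + L - 1L))
  }
  for (g in pickGene(per[["trf1"]] %||% 0L)) {
    L <- sample(16:35, 1L)
    seqs <- c(seqs, substr(trail[g], 1L, L))
  }
  for (g in pickGene(per[["5pU_trf"]] %||% 0L)) {
    L <- sample(16:35, 1L)
    le <- lead[g]
    seqs <- c(seqs, substr(le, nchar(le) - L + 1L, nchar(le)))
  }
  seqs <- seqs[!duplicated(seqs)]
  data.frame(signature_id = sprintf("ts-%02d", seq_along(seqs)),
             sequence = seqs, stringsAsFactors = FALSE)
}

#' Simulate a cohort: counts, clinical table and mRNA matrix
#'
#' Counts are negative binomial with mean
#' `baseline * 2^(log2FC * is_tumor)`; survival times for tumor samples
#' are exponential with hazard
#' `baselineHazard * exp(plantedBeta * z)` where z is the standardized
#' log2 per-million expression of the biomarker signature, independently
#' censored by a Uniform(0, censoringTime) time; pathology categories are
#' associated with the biomarker median split; the mRNA matrix attains the
#' planted Spearman correlations with the biomarker through a Gaussian
#' copula (`r = 2 sin(pi rho / 6)` on the latent scale).
#'
#' @param config a [simulationConfig()].
#' @param signatureIds character vector of signature ids (rows of the
#'   count matrix), e.g. from [simulateSignatures()].
#' @param biomarker id of the survival/correlation biomarker signature
#'   (default: the first signature).
#' @return list with `counts` (signatures x samples integer matrix),
#'   `clinical` (`data.frame`), `mrna` (genes x tumor-samples matrix),
#'   `plantedLfc` (the fold changes actually planted), `biomarker`.
#' @export
simulateCohort <- function(config, signatureIds, biomarker = NULL) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed + 2L)
  nS <- length(signatureIds)
  if (!nS) stop("no signatures to simulate counts for", call. = FALSE)
  biomarker <- biomarker %||% signatureIds[1L]
  if (!biomarker %in% signatureIds) {
    stop("biomarker not among signature ids", call. = FALSE)
  }
  nT <- config$nTumor; nN <- config$nNormal
  samples <- c(sprintf("tumor-%02d", seq_len(nT)),
               sprintf("normal-%02d", seq_len(nN)))
  grp <- rep(c("tumor", "normal"), c(nT, nN))

  lfc <- stats::setNames(rep(0, nS), signatureIds)
  if (is.null(config$plantedLfc)) {
    ## default plant: biomarker down-regulated in tumors, one up-regulated
    lfc[biomarker] <- -2
    if (nS >= 2L) lfc[signatureIds[2L]] <- 2
  } else {
    known <- intersect(names(config$plantedLfc), signatureIds)
    lfc[known] <- config$plantedLfc[known]
  }
  baseline <- stats::rlnorm(nS, meanlog = log(config$baselineMean),
                            sdlog = 0.8)
  mu <- outer(baseline, ifelse(grp == "tumor", 1, 0), function(b, g) b) *
    2^(outer(lfc, ifelse(grp == "tumor", 1, 0)))
  size <- if (config$dispersion > 0) 1 / config$dispersion else Inf
  counts <- matrix(stats::rnbinom(nS * length(samples), mu = mu, size = size),
                   nrow = nS, dimnames = list(signatureIds, samples))
  storage.mode(counts) <- "integer"

  ## nominal library = assigned reads inflated by the background fraction
  lib <- pmax(1, round(colSums(counts) / (1 - config$backgroundFraction)))
  logTPM <- log2(sweep(counts, 2, lib, "/") * 1e6 + 1)

  zAll <- as.numeric(scale(logTPM[biomarker, grp == "tumor"]))
  if (any(!is.finite(zAll))) zAll <- rep(0, nT)
  rate <- config$baselineHazard * exp(config$plantedBeta * zAll)
  tEvent <- stats::rexp(nT, rate = rate)
  tCens <- stats::runif(nT, 0, config$censoringTime)
  osTime <- pmax(pmin(tEvent, tCens), 1e-3)
  osEvent <- as.integer(tEvent <= tCens)

  split <- ifelse(logTPM[biomarker, grp == "tumor"] <=
                    stats::median(logTPM[biomarker, grp == "tumor"]),
                  "low", "high")
  invasionP <- ifelse(split == "low", 0.65, 0.25)
  nPair <- min(nT, nN)
  clinical <- data.frame(
    sample_id = samples,
    group = grp,
    pair_id = c(sprintf("pair-%02d", seq_len(nT)),
                sprintf("pair-%02d", seq_len(nN))),
    os_time = c(pmax(1, round(osTime)), rep(NA_real_, nN)),
    os_event = c(osEvent, rep(NA_integer_, nN)),
    age = round(stats::rnorm(nT + nN, 65, 10)),
    stage = sample(c("I", "II", "III", "IV"), nT + nN, replace = TRUE,
                   prob = c(0.2, 0.35, 0.3, 0.15)),
    N_stage = sample(c("N0", "N1", "N2"), nT + nN, replace = TRUE,
                     prob = c(0.5, 0.3, 0.2)),
    M_stage = sample(c("M0", "M1"), nT + nN, replace = TRUE,
                     prob = c(0.85, 0.15)),
    lymphovascular_invasion = c(
      ifelse(stats::runif(nT) < invasionP, "present", "absent"),
      sample(c("present", "absent"), nN, replace = TRUE)),
    stringsAsFactors = FALSE
  )
  ## pairing covers only min(nT, nN) pairs; the rest are unpaired
  clinical$pair_id[clinical$group == "tumor"][-seq_len(nPair)] <- NA
  clinical$pair_id[clinical$group == "normal"][-seq_len(min(nN, nPair))] <- NA

  nM <- config$nMrna
  rho <- rep(0, nM)
  rho[seq_along(config$plantedRho)] <- config$plantedRho
  r <- 2 * sin(pi * rho / 6)
  zb <- as.numeric(scale(logTPM[biomarker, grp == "tumor"]))
  if (any(!is.finite(zb))) zb <- stats::rnorm(nT)
  eps <- matrix(stats::rnorm(nM * nT), nM, nT)
  latent <- r %o% zb + sqrt(1 - r^2) * eps
  mrna <- 8 + 2 * latent
  dimnames(mrna) <- list(sprintf("gene-%03d", seq_len(nM)),
                         samples[grp == "tumor"])

  list(counts = counts, clinical = clinical, mrna = mrna,
       plantedLfc = lfc, biomarker = biomarker)
}

#' Simulate survival records with a planted log hazard ratio
#'
#' Exponential event times with hazard `lambda0 * exp(beta * z)` and
#' independent Uniform(0, censoringTime) censoring; used for Cox
#' parameter-recovery checks.
#'
#' @param n number of subjects.
#' @param beta log hazard ratio.
#' @param z covariate vector (default: balanced binary 0/1).
#' @param lambda0 baseline hazard (default 1).
#' @param censoringTime uniform censoring upper bound (default 3.3, about
#'   20 percent censoring for a binary covariate with beta = 1).
#' @param seed integer seed.
#' @return `data.frame` with columns `time`, `event`, `z`.
#' @export
simulateSurvival <- function(n, beta, z = NULL, lambda0 = 1,
                             censoringTime = 3.3, seed = 1L) {
  set.seed(seed)
  if (is.null(z)) z <- rep(c(0, 1), length.out = n)
  tEvent <- stats::rexp(n, rate = lambda0 * exp(beta * z))
  tCens <- stats::runif(n, 0, censoringTime)
  data.frame(time = pmin(tEvent, tCens),
             event = as.integer(tEvent <= tCens),
             z = z)
}

#' Simulate per-sample FASTQ reads from planted counts
#'
#' Each sample's FASTQ holds `count` copies of every signature sequence
#' (with optional per-base substitution errors at `errorRate`) plus
#' background reads - random 16-35-mers guaranteed not to match any
#' signature - filling the configured background fraction of the library.
#' Quality strings are constant.
#'
#' @param config a [simulationConfig()].
#' @param catalogSequences named character vector: signature id ->
#'   sequence.
#' @param counts signatures x samples integer matrix (rows must match
#'   `names(catalogSequences)`).
#' @param dir output directory for `<sample>.fastq` files.
#' @return named character vector of FASTQ paths.
#' @export
simulateReads <- function(config, catalogSequences, counts, dir) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed + 3L)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sigSeq <- catalogSequences[rownames(counts)]
  if (anyNA(sigSeq)) stop("counts rows missing from catalog", call. = FALSE)
  paths <- stats::setNames(character(ncol(counts)), colnames(counts))
  for (s in seq_len(ncol(counts))) {
    reads <- rep(unname(sigSeq), counts[, s])
    if (config$errorRate > 0 && length(reads)) {
      reads <- vapply(reads, .mutateRead, character(1),
                      rate = config$errorRate, USE.NAMES = FALSE)
    }
    assigned <- length(reads)
    nBg <- round(assigned * config$backgroundFraction /
                   (1 - config$backgroundFraction))
    bg <- character(0)
    while (length(bg) < nBg) {
      cand <- vapply(sample(16:35, nBg - length(bg), replace = TRUE),
                     .randomDna, character(1))
      bg <- c(bg, cand[!cand %in% sigSeq])
    }
    all <- sample(c(reads, bg))
    paths[s] <- file.path(dir, paste0(colnames(counts)[s], ".fastq"))
    if (length(all)) {
      x <- Biostrings::DNAStringSet(all)
      names(x) <- sprintf("read-%06d", seq_along(all))
      Biostrings::writeXStringSet(
        x, paths[s], format = "fastq",
        qualities = Biostrings::BStringSet(strrep("I", nchar(all))))
    } else {
      file.create(paths[s])
    }
  }
  paths
}

.mutateRead <- function(seq, rate) {
  n <- nchar(seq)
  k <- stats::rbinom(1L, n, rate)
  if (k == 0L) return(seq)
  bases <- strsplit(seq, "", fixed = TRUE)[[1]]
  pos <- sample.int(n, k)
  for (p in pos) {
    bases[p] <- sample(setdiff(c("A", "C", "G", "T"), bases[p]), 1L)
  }
  paste(bases, collapse = "")
}

#' Simulate 3'UTRs with planted seed sites
#'
#' Generates random UTR sequences and plants, in each, one seed-match site
#' for the given fragment (a 7mer-m8 core, with the A1 anchor added for
#' half of them to make 8mer sites) at a random admissible offset.
#'
#' @param config a [simulationConfig()].
#' @param trfSequence the fragment whose sites are planted.
#' @return list with `utrs` (named character vector) and `truth`
#'   (`data.frame` utr, planted_start (of the 7mer core base next to m8),
#'   planted_type).
#' @export
simulateUtrs <- function(config, trfSequence) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed + 4L)
  trf <- normalizeDna(trfSequence, "tRF sequence")
  core7 <- revComp(substr(trf, 2L, 8L))   # 7mer-m8 site text
  L <- config$utrLength
  utrs <- stats::setNames(character(config$nUtr),
                          sprintf("UTR-%03d", seq_len(config$nUtr)))
  truth <- data.frame(utr = names(utrs), planted_start = NA_integer_,
                      planted_type = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_len(config$nUtr)) {
    withA <- i %% 2L == 0L
    site <- if (withA) paste0(core7, "A") else core7
    repeat {
      bg <- .randomDna(L)
      offset <- sample(2:(L - nchar(site) - 1L), 1L)
      utr <- paste0(substr(bg, 1L, offset - 1L), site,
                    substr(bg, offset + nchar(site), L))
      ## reject accidental extra cores (one site per UTR) and, for pure
      ## 7mer-m8 plants, an accidental downstream A upgrading the type
      oneCore <- length(exactMatchStarts(substr(core7, 2L, 7L), utr)) == 1L
      noUpgrade <- withA ||
        substr(utr, offset + 7L, offset + 7L) != "A"
      if (oneCore && noUpgrade) break
    }
    utrs[i] <- utr
    truth$planted_start[i] <- offset
    truth$planted_type[i] <- if (withA) "8mer" else "7mer-m8"
  }
  list(utrs = utrs, truth = truth)
}

#' Write a toy GMT collection
#'
#' @param sets named list of character vectors.
#' @param path output GMT path.
#' @return invisibly, `path`.
#' @export
writeGmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "synthetic", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
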