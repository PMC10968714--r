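# Pipeline orchestration: configuration, stage dispatch, logging.

#' Default pipeline configuration
#'
#' Every default equals the documented module default, so a bare run is the
#' reference configuration: fragment lengths 16-35, leader window 50,
#' trailer window 35, detection in at least half the samples, |log2FC| > 1
#' with p < 0.05, top-500 correlated genes, 1000 GSEA permutations, duplex
#' threshold half the fragment length.
#'
#' @return named list of configuration values (input paths are `NULL`
#'   until supplied).
#' @export
pipelineDefaults <- function() {
  list(
    ## thresholds
    min_length = 16L, max_length = 35L,
    leader_window = 50L, trailer_window = 35L,
    his_start_tolerance = 2L, start_tolerance = 1L,
    detection_fraction = 0.5,
    lfc_cut = 1, p_cut = 0.05,
    top_k = 500L, gsea_permutations = 1000L,
    target_threshold_factor = 0.5, target_flank = 30L,
    seed = 1L, outdir = "tsrna-out",
    biomarker = NULL,
    ## input paths
    gene_fasta = NULL, gene_metadata = NULL, genome_fasta = NULL,
    signatures = NULL, fastq = NULL, counts = NULL, expression = NULL,
    clinical = NULL, mrna = NULL, gmt = NULL, utr_fasta = NULL
  )
}

#' Read a pipeline configuration file
#'
#' YAML key-value file; unknown keys are rejected before any computation.
#'
#' @param path YAML config path.
#' @param overrides named list applied on top of the file values.
#' @return full configuration list (defaults filled in).
#' @export
readPipelineConfig <- function(path = NULL, overrides = list()) {
  cfg <- pipelineDefaults()
  user <- if (!is.null(path)) yaml::read_yaml(path) else list()
  user <- utils::modifyList(user, overrides)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  utils::modifyList(cfg, user)
}

.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

## write-once guard: a stage never overwrites an existing output file
.outPath <- function(outdir, name) {
  p <- file.path(outdir, name)
  if (file.exists(p)) {
    stop("output already exists (outputs are write-once per run directory): ",
         p, call. = FALSE)
  }
  p
}

#' Run one pipeline stage (or the whole chain)
#'
#' Subcommands: `simulate`, `build-ref`, `classify`, `quantify`, `de`,
#' `survival`, `cox`, `chisq`, `correlate`, `ora`, `gsea`, `targets`,
#' `run-all`. Outputs are deterministic given the configuration and seed
#' and are written once per run directory, together with a structured JSON
#' log (parameters, package version, warnings).
#'
#' `run-all` chains every stage; with no user input paths it first runs
#' `simulate` and analyses the simulated cohort.
#'
#' @param subcommand one of the stage names above.
#' @param config configuration list (see [pipelineDefaults()] /
#'   [readPipelineConfig()]).
#' @param configPath optional YAML config file (read first, then `config`
#'   entries applied on top).
#' @return invisibly, a list of the stage's in-memory results (also
#'   written under `config$outdir`).
#' @export
runPipeline <- function(subcommand, config = list(), configPath = NULL) {
  known <- c("simulate", "build-ref", "classify", "quantify", "de",
             "survival", "cox", "chisq", "correlate", "ora", "gsea",
             "targets", "run-all")
  if (!subcommand %in% known) {
    stop("unknown subcommand '", subcommand, "'; expected one of: ",
         paste(known, collapse = ", "), call. = FALSE)
  }
  cfg <- readPipelineConfig(configPath, overrides = config)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  warnings_ <- character(0)
  result <- withCallingHandlers(
    .dispatchStage(subcommand, cfg),
    warning = function(w) {
      warnings_ <<- c(warnings_, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  log <- list(
    subcommand = subcommand,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    package_version = as.character(utils::packageVersion("tRFtools")),
    parameters = cfg[!vapply(cfg, is.null, logical(1))],
    warnings = warnings_
  )
  jsonlite::write_json(log,
                       file.path(cfg$outdir,
                                 paste0("log-", subcommand, ".json")),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(result)
}

.dispatchStage <- function(subcommand, cfg) {
  switch(subcommand,
    "simulate"  = .stageSimulate(cfg),
    "build-ref" = .stageBuildRef(cfg),
    "classify"  = .stageClassify(cfg),
    "quantify"  = .stageQuantify(cfg),
    "de"        = .stageDe(cfg),
    "survival"  = .stageSurvival(cfg),
    "cox"       = .stageCox(cfg),
    "chisq"     = .stageChisq(cfg),
    "correlate" = .stageCorrelate(cfg),
    "ora"       = .stageOra(cfg),
    "gsea"      = .stageGsea(cfg),
    "targets"   = .stageTargets(cfg),
    "run-all"   = .stageRunAll(cfg)
  )
}

.stageSimulate <- function(cfg) {
  config <- simulationConfig(seed = cfg$seed)
  simdir <- file.path(cfg$outdir, "simulated")
  ref <- simulateReference(config, dir = simdir)
  bundle <- buildReference(geneSet = loadGeneSetFromObjects(ref$seqs,
                                                            ref$metadata),
                           leaderWindow = cfg$leader_window,
                           trailerWindow = cfg$trailer_window)
  sigs <- simulateSignatures(bundle, config)
  .writeTsv(sigs, file.path(simdir, "signatures.tsv"))
  cohort <- simulateCohort(config, sigs$signature_id)
  .writeTsv(data.frame(signature_id = rownames(cohort$counts),
                       cohort$counts, check.names = FALSE),
            file.path(simdir, "counts.tsv"))
  .writeTsv(cohort$clinical, file.path(simdir, "clinical.tsv"))
  .writeTsv(data.frame(gene = rownames(cohort$mrna), cohort$mrna,
                       check.names = FALSE),
            file.path(simdir, "mrna.tsv"))
  catSeqs <- stats::setNames(sigs$sequence, sigs$signature_id)
  fastqDir <- file.path(simdir, "fastq")
  fastqs <- simulateReads(config, catSeqs, cohort$counts, fastqDir)
  utr <- simulateUtrs(config, catSeqs[[cohort$biomarker]])
  utrPath <- file.path(simdir, "utrs.fasta")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(utr$utrs), utrPath)
  ## toy gene sets: one enriched in planted-correlation genes, two random
  set.seed(cfg$seed)
  genes <- rownames(cohort$mrna)
  nPlanted <- length(config$plantedRho)
  sets <- list(
    planted_module = genes[seq_len(min(30L, nPlanted))],
    random_module_1 = sample(genes, 30L),
    random_module_2 = sample(genes, 30L)
  )
  gmtPath <- file.path(simdir, "sets.gmt")
  writeGmt(sets, gmtPath)
  list(config = config, reference = bundle, signatures = sigs,
       cohort = cohort, fastqs = fastqs, utrs = utr, gmtPath = gmtPath,
       paths = list(gene_fasta = ref$fastaPath,
                    gene_metadata = ref$metadataPath,
                    signatures = file.path(simdir, "signatures.tsv"),
                    clinical = file.path(simdir, "clinical.tsv"),
                    mrna = file.path(simdir, "mrna.tsv"),
                    gmt = gmtPath, utr_fasta = utrPath))
}

.stageBuildRef <- function(cfg) {
  if (is.null(cfg$gene_fasta) || is.null(cfg$gene_metadata)) {
    stop("build-ref needs gene_fasta and gene_metadata", call. = FALSE)
  }
  ref <- buildReference(cfg$gene_fasta, cfg$gene_metadata,
                        genomeFasta = cfg$genome_fasta,
                        leaderWindow = cfg$leader_window,
                        trailerWindow = cfg$trailer_window)
  writeReference(ref, file.path(cfg$outdir, "reference"))
  ref
}

.stageClassify <- function(cfg, ref = NULL) {
  if (is.null(ref)) ref <- .stageBuildRef(cfg)
  if (is.null(cfg$signatures)) stop("classify needs signatures", call. = FALSE)
  cat_ <- buildCatalog(cfg$signatures, ref,
                       minLength = cfg$min_length, maxLength = cfg$max_length,
                       startTolerance = cfg$start_tolerance,
                       hisStartTolerance = cfg$his_start_tolerance)
  writeCatalog(cat_, .outPath(cfg$outdir, "catalog.tsv"))
  jsonlite::write_json(
    list(n_signatures = cat_@summary$n_signatures,
         n_classified = cat_@summary$n_classified,
         class_counts = as.list(cat_@summary$class_counts),
         class_proportions = as.list(cat_@summary$class_proportions),
         chromosome_proportions = as.list(cat_@summary$chromosome_proportions)),
    .outPath(cfg$outdir, "catalog_summary.json"),
    auto_unbox = TRUE, digits = NA)
  cat_
}

.stageQuantify <- function(cfg, catalog = NULL, fastqs = NULL) {
  if (is.null(catalog)) stop("quantify needs a catalog", call. = FALSE)
  fastqs <- fastqs %||% cfg$fastq
  if (is.null(fastqs)) stop("quantify needs fastq paths", call. = FALSE)
  se <- countSamples(unlist(fastqs), catalog)
  se <- normalizeExpression(se)
  se <- detectionFilter(se, minDetectFraction = cfg$detection_fraction)
  counts <- SummarizedExperiment::assay(se, "counts")
  .writeTsv(data.frame(signature_id = rownames(counts), counts,
                       check.names = FALSE),
            .outPath(cfg$outdir, "counts.tsv"))
  expr <- SummarizedExperiment::assay(se, "logTPM")
  .writeTsv(data.frame(signature_id = rownames(expr), round(expr, 4),
                       check.names = FALSE),
            .outPath(cfg$outdir, "expression.tsv"))
  rep_ <- S4Vectors::metadata(se)$detectionFilter
  rep_$class_composition <- as.list(rep_$class_composition)
  rep_$chromosome_composition <- as.list(rep_$chromosome_composition)
  jsonlite::write_json(rep_, .outPath(cfg$outdir, "filter_report.json"),
                       auto_unbox = TRUE, digits = NA)
  se
}

.readExprTsv <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  m
}

.stageDe <- function(cfg, expr = NULL, clinical = NULL) {
  expr <- expr %||% .readExprTsv(cfg$expression)
  clinical <- clinical %||% utils::read.delim(cfg$clinical,
                                              stringsAsFactors = FALSE)
  de <- differentialExpression(expr, clinical, lfcCut = cfg$lfc_cut,
                               pCut = cfg$p_cut)
  .writeTsv(de, .outPath(cfg$outdir, "de.tsv"))
  de
}

.pickBiomarker <- function(cfg, expr) {
  bm <- cfg$biomarker %||% rownames(expr)[1L]
  if (!bm %in% rownames(expr)) {
    stop("biomarker '", bm, "' not in the expression matrix", call. = FALSE)
  }
  bm
}

.tumorExpr <- function(expr, clinical) {
  tum <- clinical$sample_id[clinical$group == "tumor"]
  expr[, intersect(colnames(expr), tum), drop = FALSE]
}

.stageSurvival <- function(cfg, expr = NULL, clinical = NULL) {
  expr <- expr %||% .readExprTsv(cfg$expression)
  clinical <- clinical %||% utils::read.delim(cfg$clinical,
                                              stringsAsFactors = FALSE)
  bm <- .pickBiomarker(cfg, expr)
  te <- .tumorExpr(expr, clinical)
  cl <- clinical[match(colnames(te), clinical$sample_id), ]
  ok <- !is.na(cl$os_time) & !is.na(cl$os_event)
  groups <- medianSplit(stats::setNames(te[bm, ok], colnames(te)[ok]))
  km <- kmEstimate(cl$os_time[ok], cl$os_event[ok], groups)
  lr <- logrankTest(cl$os_time[ok], cl$os_event[ok], groups)
  .writeTsv(km, .outPath(cfg$outdir, "km_curves.tsv"))
  jsonlite::write_json(
    list(biomarker = bm, statistic = lr$statistic, df = lr$df, p = lr$p,
         observed = as.list(lr$observed), expected = as.list(lr$expected)),
    .outPath(cfg$outdir, "logrank.json"), auto_unbox = TRUE, digits = NA)
  list(biomarker = bm, groups = groups, km = km, logrank = lr)
}

.stageCox <- function(cfg, expr = NULL, clinical = NULL) {
  expr <- expr %||% .readExprTsv(cfg$expression)
  clinical <- clinical %||% utils::read.delim(cfg$clinical,
                                              stringsAsFactors = FALSE)
  bm <- .pickBiomarker(cfg, expr)
  te <- .tumorExpr(expr, clinical)
  cl <- clinical[match(colnames(te), clinical$sample_id), ]
  ok <- !is.na(cl$os_time) & !is.na(cl$os_event)
  groups <- medianSplit(stats::setNames(te[bm, ok], colnames(te)[ok]))
  covs <- data.frame(expression = groups, age = cl$age[ok],
                     stage = cl$stage[ok], N_stage = cl$N_stage[ok],
                     M_stage = cl$M_stage[ok], stringsAsFactors = FALSE)
  covs <- covs[, vapply(covs, function(v) length(unique(v)) > 1L,
                        logical(1)), drop = FALSE]
  uni <- coxFit(cl$os_time[ok], cl$os_event[ok], covs, mode = "univariate")
  multi <- coxFit(cl$os_time[ok], cl$os_event[ok], covs,
                  mode = "multivariate")
  .writeTsv(uni, .outPath(cfg$outdir, "cox_univariate.tsv"))
  .writeTsv(multi, .outPath(cfg$outdir, "cox_multivariate.tsv"))
  list(univariate = uni, multivariate = multi)
}

.stageChisq <- function(cfg, expr = NULL, clinical = NULL) {
  expr <- expr %||% .readExprTsv(cfg$expression)
  clinical <- clinical %||% utils::read.delim(cfg$clinical,
                                              stringsAsFactors = FALSE)
  bm <- .pickBiomarker(cfg, expr)
  te <- .tumorExpr(expr, clinical)
  cl <- clinical[match(colnames(te), clinical$sample_id), ]
  groups <- medianSplit(stats::setNames(te[bm, ], colnames(te)))
  skip <- c("sample_id", "group", "pair_id")
  assoc <- clinicalAssociation(groups, cl[, setdiff(names(cl), skip)])
  jsonlite::write_json(assoc, .outPath(cfg$outdir, "chisq.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  assoc
}

.stageCorrelate <- function(cfg, expr = NULL, clinical = NULL, mrna = NULL) {
  expr <- expr %||% .readExprTsv(cfg$expression)
  clinical <- clinical %||% utils::read.delim(cfg$clinical,
                                              stringsAsFactors = FALSE)
  mrna <- mrna %||% .readExprTsv(cfg$mrna)
  bm <- .pickBiomarker(cfg, expr)
  te <- .tumorExpr(expr, clinical)
  target <- stats::setNames(te[bm, ], colnames(te))
  topk <- spearmanTopK(target, mrna, k = cfg$top_k)
  .writeTsv(topk, .outPath(cfg$outdir, "correlation.tsv"))
  topk
}

.stageOra <- function(cfg, topk = NULL, mrna = NULL) {
  if (is.null(topk)) topk <- utils::read.delim(cfg$counts %||%
                                                 file.path(cfg$outdir,
                                                           "correlation.tsv"))
  mrna <- mrna %||% .readExprTsv(cfg$mrna)
  sets <- readGmt(cfg$gmt)
  res <- ora(topk$gene, sets, universe = rownames(mrna))
  .writeTsv(res, .outPath(cfg$outdir, "ora.tsv"))
  res
}

.stageGsea <- function(cfg, topk = NULL, mrna = NULL, clinical = NULL,
                       expr = NULL) {
  expr <- expr %||% .readExprTsv(cfg$expression)
  clinical <- clinical %||% utils::read.delim(cfg$clinical,
                                              stringsAsFactors = FALSE)
  mrna <- mrna %||% .readExprTsv(cfg$mrna)
  bm <- .pickBiomarker(cfg, expr)
  te <- .tumorExpr(expr, clinical)
  target <- stats::setNames(te[bm, ], colnames(te))
  ## ranking metric: Spearman rho of every mRNA gene against the biomarker
  allCor <- spearmanTopK(target, mrna, k = nrow(mrna))
  scores <- stats::setNames(allCor$rho, allCor$gene)
  sets <- readGmt(cfg$gmt)
  res <- gseaCollection(scores, sets, nPerm = cfg$gsea_permutations,
                        seed = cfg$seed)
  .writeTsv(res, .outPath(cfg$outdir, "gsea.tsv"))
  best <- gsea(scores, sets[[res$set[1L]]], nPerm = cfg$gsea_permutations,
               seed = cfg$seed)
  .writeTsv(best$runningSum, .outPath(cfg$outdir, "gsea_running_sum.tsv"))
  res
}

.stageTargets <- function(cfg, trfSequence = NULL, trfId = NULL) {
  if (is.null(trfSequence)) {
    stop("targets stage needs the biomarker fragment sequence", call. = FALSE)
  }
  pred <- predictTargets(
    trfSequence, cfg$utr_fasta,
    scoreThreshold = cfg$target_threshold_factor * nchar(trfSequence),
    flank = cfg$target_flank, trfId = trfId %||% "tRF")
  .writeTsv(pred, .outPath(cfg$outdir, "targets.tsv"))
  .writeTsv(targetEdgeList(pred), .outPath(cfg$outdir, "target_edges.tsv"))
  pred
}

.stageRunAll <- function(cfg) {
  sim <- NULL
  if (is.null(cfg$gene_fasta)) {
    sim <- .stageSimulate(cfg)
    cfg <- utils::modifyList(cfg, sim$paths)
    ref <- sim$reference
    cfg$biomarker <- cfg$biomarker %||% sim$cohort$biomarker
    fastqs <- sim$fastqs
  } else {
    ref <- .stageBuildRef(cfg)
    fastqs <- cfg$fastq
  }
  catalog <- .stageClassify(cfg, ref = ref)
  se <- .stageQuantify(cfg, catalog = catalog, fastqs = fastqs)
  expr <- SummarizedExperiment::assay(se, "logTPM")
  clinical <- utils::read.delim(cfg$clinical, stringsAsFactors = FALSE)
  ## the configured biomarker may have been dropped by the detection filter
  if (is.null(cfg$biomarker) || !(cfg$biomarker %in% rownames(expr))) {
    cfg$biomarker <- rownames(expr)[1L]
  }
  de <- .stageDe(cfg, expr = expr, clinical = clinical)
  surv <- .stageSurvival(cfg, expr = expr, clinical = clinical)
  cox <- .stageCox(cfg, expr = expr, clinical = clinical)
  chisq <- .stageChisq(cfg, expr = expr, clinical = clinical)
  mrna <- .readExprTsv(cfg$mrna)
  topk <- .stageCorrelate(cfg, expr = expr, clinical = clinical, mrna = mrna)
  oraRes <- if (!is.null(cfg$gmt)) .stageOra(cfg, topk = topk, mrna = mrna)
  gseaRes <- if (!is.null(cfg$gmt)) {
    .stageGsea(cfg, mrna = mrna, clinical = clinical, expr = expr)
  }
  targets <- if (!is.null(cfg$utr_fasta)) {
    bmSeq <- SummarizedExperiment::rowData(se)[cfg$biomarker, "sequence"]
    .stageTargets(cfg, trfSequence = bmSeq, trfId = cfg$biomarker)
  }
  invisible(list(catalog = catalog, expression = se, de = de,
                 survival = surv, cox = cox, chisq = chisq,
                 correlation = topk, ora = oraRes, gsea = gseaRes,
                 targets = targets, simulated = !is.null(sim)))
}
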