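#' @import methods
#' @importClassesFrom Biostrings DNAStringSet
NULL

#' Reference spaces for tRNA fragment classification
#'
#' Holds, for each tRNA gene, the mature sequence (introns spliced out,
#' post-transcriptional CCA appended, G-1 prepended for histidine tRNAs),
#' the 5'-leader and 3'-trailer windows of the primary transcript, the
#' per-gene metadata and the mature-to-gene coordinate maps. Fragments are
#' classified against these three sequence spaces.
#'
#' @slot genes `data.frame` of gene metadata (gene_id, isotype, anticodon,
#'   family_index, chromosome, strand, coordinates, optional
#'   anticodon_position).
#' @slot geneSeq [Biostrings::DNAStringSet] of coding-strand gene sequences.
#' @slot mature [Biostrings::DNAStringSet] of mature tRNA sequences.
#' @slot leader [Biostrings::DNAStringSet] of 5'-leader windows.
#' @slot trailer [Biostrings::DNAStringSet] of 3'-trailer windows.
#' @slot matureMap list of integer vectors, one per gene: for each mature
#'   position the gene-local position, `NA` for post-transcriptional bases
#'   (G-1, CCA).
#' @slot params list of construction parameters (leader/trailer windows,
#'   whether CCA was appended).
#'
#' @seealso [buildReference()]
#' @export
setClass("TRNAReference",
  representation(
    genes     = "data.frame",
    geneSeq   = "DNAStringSet",
    mature    = "DNAStringSet",
    leader    = "DNAStringSet",
    trailer   = "DNAStringSet",
    matureMap = "list",
    params    = "list"
  )
)

setValidity("TRNAReference", function(object) {
  ids <- object@genes$gene_id
  msgs <- character(0)
  if (anyDuplicated(ids)) msgs <- c(msgs, "duplicate gene_id")
  for (slotnm in c("geneSeq", "mature", "leader", "trailer")) {
    if (!identical(names(slot(object, slotnm)), ids)) {
      msgs <- c(msgs, paste0("names of @", slotnm, " do not match gene_id"))
    }
  }
  if (!identical(names(object@matureMap), ids)) {
    msgs <- c(msgs, "names of @matureMap do not match gene_id")
  }
  mat <- as.character(object@mature)
  if (object@params$appendCCA %||% TRUE) {
    if (!all(substring(mat, nchar(mat) - 2L) == "CCA")) {
      msgs <- c(msgs, "mature sequences must end in CCA")
    }
  }
  his <- object@genes$isotype == "His"
  if (any(his) && !all(substring(mat[his], 1L, 1L) == "G")) {
    msgs <- c(msgs, "His mature sequences must start with the G-1 base")
  }
  if (!all(lengths(object@matureMap) == nchar(mat))) {
    msgs <- c(msgs, "matureMap lengths must equal mature lengths")
  }
  if (length(msgs)) msgs else TRUE
})

#' Catalog of classified tRNA fragment signatures
#'
#' One row per unique fragment sequence, with class label, tDRnamer-style
#' identifier (where a mature placement exists), multimap count, source
#' chromosome and the full placement list.
#'
#' @slot signatures `data.frame` with columns signature_id, sequence,
#'   length, trf_class, tdr_name, multimap_count, is_5p_half, placements
#'   (encoded `gene:region:start-end;...`), chromosome.
#' @slot placements list (one element per signature) of `data.frame`s with
#'   columns gene_id, region, start, end.
#' @slot summary list with class and chromosome proportion tables.
#' @slot params classification parameters used.
#'
#' @seealso [buildCatalog()], [classifyFragment()]
#' @export
setClass("FragmentCatalog",
  representation(
    signatures = "data.frame",
    placements = "list",
    summary    = "list",
    params     = "list"
  )
)

setValidity("FragmentCatalog", function(object) {
  msgs <- character(0)
  sig <- object@signatures
  need <- c("signature_id", "sequence", "length", "trf_class", "tdr_name",
            "multimap_count", "is_5p_half", "placements", "chromosome")
  if (!all(need %in% names(sig))) {
    msgs <- c(msgs, paste("missing signature columns:",
                          paste(setdiff(need, names(sig)), collapse = ", ")))
  }
  if (length(object@placements) != nrow(sig)) {
    msgs <- c(msgs, "placement list length must equal number of signatures")
  }
  if (nrow(sig) && anyDuplicated(sig$sequence)) {
    msgs <- c(msgs, "signature sequences must be unique")
  }
  if (length(msgs)) msgs else TRUE
})

#' @describeIn TRNAReference-class number of genes
#' @param x a `TRNAReference`
#' @export
setMethod("length", "TRNAReference", function(x) nrow(x@genes))

setMethod("show", "TRNAReference", function(object) {
  cat("TRNAReference with", nrow(object@genes), "genes\n")
  iso <- table(object@genes$isotype)
  cat("  isotypes:", paste(names(iso), iso, sep = ":", collapse = " "), "\n")
  cat("  leader window:", object@params$leaderWindow,
      " trailer window:", object@params$trailerWindow, "\n")
})

setMethod("show", "FragmentCatalog", function(object) {
  cat("FragmentCatalog with", nrow(object@signatures), "signatures\n")
  tab <- table(object@signatures$trf_class)
  cat("  classes:", paste(names(tab), tab, sep = ":", collapse = " "), "\n")
})

#' Accessors for reference and catalog objects
#'
#' @param x a [TRNAReference-class] or [FragmentCatalog-class] object.
#' @return `matureSeqs`, `leaderSeqs`, `trailerSeqs` return
#'   [Biostrings::DNAStringSet]; `geneInfo` and `fragmentInfo` return the
#'   underlying `data.frame`s; `classSummary` the class/chromosome
#'   proportion tables.
#' @name accessors
NULL

#' @rdname accessors
#' @export
matureSeqs <- function(x) x@mature

#' @rdname accessors
#' @export
leaderSeqs <- function(x) x@leader

#' @rdname accessors
#' @export
trailerSeqs <- function(x) x@trailer

#' @rdname accessors
#' @export
geneInfo <- function(x) x@genes

#' @rdname accessors
#' @export
matureToGeneMap <- function(x) x@matureMap

#' @rdname accessors
#' @export
fragmentInfo <- function(x) x@signatures

#' @rdname accessors
#' @export
fragmentPlacements <- function(x) x@placements

#' @rdname accessors
#' @export
classSummary <- function(x) x@summary
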