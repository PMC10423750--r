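#' @import methods
#' @importClassesFrom SingleCellExperiment SingleCellExperiment
#' @importFrom SingleCellExperiment SingleCellExperiment
#' @importFrom SummarizedExperiment assay assayNames colData rowData
#' @importFrom stats median quantile rmultinom rlnorm rbeta runif rpois
#'   sd var hclust cutree dist p.adjust pt fisher.test t.test
#'   loess predict setNames
#' @importFrom utils read.delim write.table
NULL

#' Paired raw/ambient-corrected single-nucleus count container
#'
#' `CountBundle` extends \linkS4class{SingleCellExperiment} and holds the two
#' count versions every downstream step expects: the `"raw"` assay (droplet
#' counts as called by the quantification pipeline) and the `"corrected"`
#' assay (the same matrix after ambient-background removal). Genes are rows,
#' nuclei are columns, matching Bioconductor convention; on disk the bundle
#' is a 10x-style Matrix Market triplet (features x barcodes).
#'
#' Per-nucleus annotation lives in `colData` and must contain `sample`,
#' `condition` and `exon_prop` (fraction of reads mapping purely to exons, a
#' surrogate for cytoplasmic contamination). Per-gene annotation lives in
#' `rowData` and must contain logical flags `mito`, `ribo` and
#' `protein_coding`.
#'
#' @section Validity:
#' Both assays must be present, share dimensions and dimnames, and contain
#' non-negative integer-valued entries; `exon_prop` must lie in [0, 1].
#'
#' @seealso [generateDataset()], [readBundle()], [writeBundle()]
#' @export
setClass("CountBundle", contains = "SingleCellExperiment")

setValidity("CountBundle", function(object) {
  msg <- NULL
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("raw", "corrected") %in% an))
    msg <- c(msg, "assays 'raw' and 'corrected' are both required")
  else {
    r <- SummarizedExperiment::assay(object, "raw")
    k <- SummarizedExperiment::assay(object, "corrected")
    if (!identical(dim(r), dim(k)))
      msg <- c(msg, "'raw' and 'corrected' must share dimensions")
    if (min(r) < 0 || min(k) < 0)
      msg <- c(msg, "counts must be non-negative")
  }
  cd <- SummarizedExperiment::colData(object)
  need <- c("sample", "condition", "exon_prop")
  if (!all(need %in% colnames(cd)))
    msg <- c(msg, sprintf("colData must contain: %s",
                          paste(need, collapse = ", ")))
  else if (any(cd$exon_prop < 0 | cd$exon_prop > 1))
    msg <- c(msg, "exon_prop must lie in [0, 1]")
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("mito", "ribo") %in% colnames(rd)))
    msg <- c(msg, "rowData must contain logical 'mito' and 'ribo' flags")
  if (is.null(msg)) TRUE else msg
})

#' Construct a CountBundle
#'
#' @param raw,corrected gene x nucleus count matrices (dense or sparse) with
#'   identical dimensions and dimnames.
#' @param nucleusData data.frame or DataFrame of per-nucleus annotation with
#'   at least `sample`, `condition`, `exon_prop`.
#' @param geneData data.frame or DataFrame of per-gene annotation with at
#'   least logical `mito` and `ribo` columns. A `protein_coding` flag is
#'   added (all `TRUE`) when absent.
#' @return A [CountBundle-class] object.
#' @examples
#' raw <- matrix(rpois(60, 2), nrow = 6,
#'               dimnames = list(paste0("g", 1:6), paste0("n", 1:10)))
#' cb <- CountBundle(raw, raw,
#'   nucleusData = data.frame(sample = rep("s1", 10), condition = "NF",
#'                            exon_prop = 0.1, row.names = colnames(raw)),
#'   geneData = data.frame(mito = rep(FALSE, 6), ribo = FALSE,
#'                         row.names = rownames(raw)))
#' rawCounts(cb)[1:3, 1:3]
#' @export
CountBundle <- function(raw, corrected, nucleusData, geneData) {
  raw <- methods::as(methods::as(raw, "CsparseMatrix"), "dMatrix")
  corrected <- methods::as(methods::as(corrected, "CsparseMatrix"), "dMatrix")
  if (!"protein_coding" %in% colnames(geneData))
    geneData$protein_coding <- TRUE
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(raw = raw, corrected = corrected),
    colData = S4Vectors::DataFrame(nucleusData),
    rowData = S4Vectors::DataFrame(geneData))
  methods::new("CountBundle", sce)
}

#' @describeIn CountBundle-class raw (uncorrected) counts
#' @param x a `CountBundle`
#' @export
rawCounts <- function(x) SummarizedExperiment::assay(x, "raw")

#' @describeIn CountBundle-class ambient-corrected counts
#' @export
correctedCounts <- function(x) SummarizedExperiment::assay(x, "corrected")

#' @describeIn CountBundle-class per-nucleus annotation (DataFrame)
#' @export
nucleusData <- function(x) SummarizedExperiment::colData(x)

#' @describeIn CountBundle-class per-gene annotation (DataFrame)
#' @export
geneData <- function(x) SummarizedExperiment::rowData(x)

setMethod("show", "CountBundle", function(object) {
  cat("CountBundle:", nrow(object), "genes x", ncol(object), "nuclei\n")
  cat("  samples:", length(unique(object$sample)),
      " conditions:", paste(unique(object$condition), collapse = ", "), "\n")
  cat("  assays: raw, corrected (mito genes:",
      sum(SummarizedExperiment::rowData(object)$mito), ")\n")
})

#' Planted ground truth for a synthetic bundle
#'
#' Records what the generator planted so that recovery can be scored:
#' the true cell type of each nucleus, doublet and low-quality flags, the
#' identifiers of ambient-dominant genes, and the table of planted
#' condition effects (log2 fold-changes per gene, cell type and condition).
#'
#' @slot nucleusCellType character, one label per nucleus (doublets carry
#'   the label of their first constituent).
#' @slot isDoublet,isLowQuality logical flags per nucleus.
#' @slot ambientGenes character vector of planted ambient-dominant gene ids.
#' @slot deGeneTable data.frame with columns `gene`, `cell_type`,
#'   `condition`, `log2fc`.
#' @slot ambientFraction numeric, realized per-nucleus ambient mixing
#'   fraction.
#' @export
setClass("SyntheticTruth", representation(
  nucleusCellType = "character",
  isDoublet = "logical",
  isLowQuality = "logical",
  ambientGenes = "character",
  deGeneTable = "data.frame",
  ambientFraction = "numeric"))

setValidity("SyntheticTruth", function(object) {
  n <- length(object@nucleusCellType)
  if (length(object@isDoublet) != n || length(object@isLowQuality) != n)
    return("flag vectors must match nucleusCellType length")
  if (nrow(object@deGeneTable) &&
      !all(c("gene", "cell_type", "condition", "log2fc") %in%
           colnames(object@deGeneTable)))
    return("deGeneTable needs gene/cell_type/condition/log2fc columns")
  TRUE
})

setMethod("show", "SyntheticTruth", function(object) {
  cat("SyntheticTruth:", length(object@nucleusCellType), "nuclei,",
      length(unique(object@nucleusCellType)), "cell types\n")
  cat("  doublets:", sum(object@isDoublet),
      " low-quality:", sum(object@isLowQuality),
      " ambient genes:", length(object@ambientGenes),
      " planted effects:", nrow(object@deGeneTable), "\n")
})

#' @describeIn SyntheticTruth-class per-nucleus true cell type
#' @param x a `SyntheticTruth`
#' @export
nucleusCellType <- function(x) x@nucleusCellType

#' @describeIn SyntheticTruth-class logical doublet flags
#' @export
isDoublet <- function(x) x@isDoublet

#' @describeIn SyntheticTruth-class logical low-quality flags
#' @export
isLowQuality <- function(x) x@isLowQuality

#' @describeIn SyntheticTruth-class planted ambient-dominant gene ids
#' @export
ambientGenes <- function(x) x@ambientGenes

#' @describeIn SyntheticTruth-class planted condition-effect table
#' @export
deGeneTable <- function(x) x@deGeneTable
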