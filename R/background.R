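#' Dataset-abundance fraction and ECDF rank per gene
#'
#' The first component of the ambient-background heuristic: each gene's
#' share of all UMIs in the dataset, and its position on the empirical
#' cumulative distribution of those shares (`bkg_prob`). Highly abundant
#' genes — the ones that dominate cell-free ambient RNA — sit near 1.
#' Ties share the upper step by default (fraction of genes with share
#' less than or equal to the gene's); `ties = "strict"` uses strictly
#' less.
#'
#' @param counts gene x nucleus count matrix.
#' @param ties `"upper"` (default) or `"strict"`.
#' @return data.frame `gene`, `dataset_fraction`, `bkg_prob`.
#' @export
datasetFractionEcdf <- function(counts, ties = c("upper", "strict")) {
  ties <- match.arg(ties)
  tot <- Matrix::rowSums(counts)
  all <- sum(tot)
  if (all == 0) stop("empty matrix: total UMI is zero")
  frac <- as.numeric(tot / all)
  G <- length(frac)
  bkg <- if (ties == "upper")
    vapply(frac, function(f) sum(frac <= f), numeric(1)) / G
  else
    vapply(frac, function(f) sum(frac < f), numeric(1)) / G
  data.frame(gene = if (is.null(rownames(counts)))
    as.character(seq_len(G)) else rownames(counts),
    dataset_fraction = frac, bkg_prob = bkg, row.names = NULL)
}

#' Prevalence-standardized positive predictive value per gene
#'
#' PPV for predicting membership in a cell type from dichotomized
#' expression, standardized to equal prevalence of the two classes:
#' with TPR = P(expr > t | in type) and FPR = P(expr > t | not in type),
#' the prevalence-1/2 Bayes PPV is TPR / (TPR + FPR), defined as 0 when
#' both rates are 0. At `positivity_threshold = 0` this is PPV0, at 1 it
#' is PPV1.
#'
#' @param expr gene x nucleus matrix (counts; dichotomization at > 0 and
#'   > 1 is count-natural).
#' @param in_celltype logical mask of the target class.
#' @param positivity_threshold expression cut defining a positive call.
#' @return Numeric PPV in [0, 1] per gene.
#' @export
standardizedPPV <- function(expr, in_celltype, positivity_threshold = 0) {
  in_celltype <- as.logical(in_celltype)
  if (!sum(in_celltype) || !sum(!in_celltype))
    stop("both groups must be non-empty")
  pos <- expr > positivity_threshold
  tpr <- Matrix::rowMeans(pos[, in_celltype, drop = FALSE])
  fpr <- Matrix::rowMeans(pos[, !in_celltype, drop = FALSE])
  den <- tpr + fpr
  ppv <- ifelse(den == 0, 0, tpr / den)
  as.numeric(ppv)
}

#' Per-gene, per-cell-type ambient-background heuristic
#'
#' Combines dataset abundance with cell-type specificity to flag genes
#' whose apparent expression in a cell type plausibly derives from
#' ambient contamination: `heuristic = bkg_prob * nontarget_prob`, where
#' `nontarget_prob = 1 - mean(PPV0, PPV1)` and `bkg_prob` is the gene's
#' abundance-ECDF rank. Genes with heuristic above `threshold` (default
#' 0.4) are flagged; flagged genes are meant to be excluded from
#' enrichment inputs and marked — not removed — in differential-
#' expression tables.
#'
#' @param counts gene x nucleus count matrix (raw counts by default
#'   carry the ambient signal the heuristic looks for).
#' @param celltypes label per nucleus.
#' @param target the cell type being scored.
#' @param threshold flag cut (default 0.4).
#' @param ties ECDF tie convention, see [datasetFractionEcdf()].
#' @return data.frame `gene`, `cell_type`, `dataset_fraction`,
#'   `bkg_prob`, `ppv0`, `ppv1`, `nontarget_prob`, `heuristic`,
#'   `flagged`.
#' @export
backgroundHeuristic <- function(counts, celltypes, target,
                                threshold = 0.4, ties = "upper") {
  if (!target %in% celltypes) stop("unknown target cell type: ", target)
  ec <- datasetFractionEcdf(counts, ties = ties)
  mask <- celltypes == target
  ppv0 <- standardizedPPV(counts, mask, 0)
  ppv1 <- standardizedPPV(counts, mask, 1)
  nontarget <- 1 - (ppv0 + ppv1) / 2
  h <- ec$bkg_prob * nontarget
  data.frame(gene = ec$gene, cell_type = target,
             dataset_fraction = ec$dataset_fraction,
             bkg_prob = ec$bkg_prob, ppv0 = ppv0, ppv1 = ppv1,
             nontarget_prob = nontarget, heuristic = h,
             flagged = h > threshold, row.names = NULL)
}

#' Lineage-partitioned background heuristic
#'
#' Within-lineage variant: when scoring a subtype inside a lineage (e.g.
#' an endothelial subtype), the specificity component is computed for the
#' lineage partition (lineage vs non-lineage nuclei) rather than the
#' subtype itself.
#'
#' @param counts gene x nucleus count matrix.
#' @param in_lineage logical mask of lineage membership covering all
#'   nuclei; neither side may be empty.
#' @param threshold,ties as in [backgroundHeuristic()].
#' @return data.frame as in [backgroundHeuristic()], with `cell_type =
#'   "lineage"`.
#' @export
partitionedHeuristic <- function(counts, in_lineage, threshold = 0.4,
                                 ties = "upper") {
  in_lineage <- as.logical(in_lineage)
  if (!sum(in_lineage) || !sum(!in_lineage))
    stop("partition must have nuclei on both sides")
  labels <- ifelse(in_lineage, "lineage", "rest")
  backgroundHeuristic(counts, labels, "lineage",
                      threshold = threshold, ties = ties)
}
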