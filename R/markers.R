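#' One-vs-rest AUC per gene
#'
#' Rank-based (Mann-Whitney) area under the ROC curve for separating one
#' group of nuclei from the rest on each gene's expression, with midrank
#' tie handling: AUC = (R1 - n1(n1+1)/2) / (n1 n2) where R1 is the rank
#' sum of the in-group.
#'
#' @param expr numeric vector (one gene) or gene x nucleus matrix of
#'   expression values (typically log-normalized).
#' @param in_cluster logical mask of the in-group, same length as the
#'   number of nuclei.
#' @return AUC in [0, 1]; one value per gene.
#' @examples
#' aucOneVsRest(c(3, 5, 7, 1, 2, 6), c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
#' @export
aucOneVsRest <- function(expr, in_cluster) {
  in_cluster <- as.logical(in_cluster)
  n1 <- sum(in_cluster); n2 <- sum(!in_cluster)
  if (n1 == 0 || n2 == 0) stop("both groups must be non-empty")
  if (is.null(dim(expr))) {
    stopifnot(length(expr) == length(in_cluster))
    r <- rank(expr)
    return((sum(r[in_cluster]) - n1 * (n1 + 1) / 2) / (n1 * n2))
  }
  stopifnot(ncol(expr) == length(in_cluster))
  ranks <- t(apply(as.matrix(expr), 1, rank))
  (rowSums(ranks[, in_cluster, drop = FALSE]) - n1 * (n1 + 1) / 2) /
    (n1 * n2)
}

#' Fraction of nuclei expressing each gene, per group
#'
#' @param counts gene x nucleus matrix.
#' @param groups factor/character of group labels per nucleus.
#' @return gene x group matrix of fractions of nuclei with count > 0.
#' @export
pctExpressed <- function(counts, groups) {
  counts <- methods::as(counts, "CsparseMatrix")
  g <- factor(groups)
  out <- vapply(levels(g), function(l)
    Matrix::rowMeans(counts[, g == l, drop = FALSE] > 0),
    numeric(nrow(counts)))
  colnames(out) <- levels(g)
  out
}

#' Sum nuclei into (cell type, sample) pseudobulk columns
#'
#' Aggregates counts per (cell type, sample) pair, treating each patient
#' as the unit of replication; pairs with fewer than `min_nuclei` nuclei
#' are dropped (the differential-expression path requires at least 25,
#' the marker path more than 20). Sample-level covariates are carried from
#' the first nucleus of each sample.
#'
#' @param counts gene x nucleus matrix.
#' @param celltypes,samples labels per nucleus.
#' @param min_nuclei minimum nuclei per retained column.
#' @param nucleus_meta optional per-nucleus data.frame whose sample-level
#'   columns (e.g. `condition`, `age`, `sex`, `study`) are propagated.
#' @return A \linkS4class{SummarizedExperiment} with assay `"counts"` and
#'   colData columns `cell_type`, `sample`, `n_nuclei` plus any propagated
#'   covariates.
#' @export
pseudobulk <- function(counts, celltypes, samples, min_nuclei = 25,
                       nucleus_meta = NULL) {
  stopifnot(ncol(counts) == length(celltypes),
            ncol(counts) == length(samples))
  key <- paste(celltypes, samples, sep = "||")
  tab <- table(key)
  keep_keys <- names(tab)[tab >= min_nuclei]
  if (!length(keep_keys)) stop("no (cell type, sample) column survives")
  counts <- methods::as(counts, "CsparseMatrix")
  cols <- lapply(keep_keys, function(k)
    Matrix::rowSums(counts[, key == k, drop = FALSE]))
  m <- do.call(cbind, cols)
  parts <- do.call(rbind, strsplit(keep_keys, "||", fixed = TRUE))
  cd <- S4Vectors::DataFrame(cell_type = parts[, 1], sample = parts[, 2],
                             n_nuclei = as.integer(tab[keep_keys]))
  if (!is.null(nucleus_meta)) {
    first <- nucleus_meta[match(cd$sample, nucleus_meta$sample), ,
                          drop = FALSE]
    for (cc in setdiff(colnames(first),
                       c("sample", "barcode", "exon_prop")))
      cd[[cc]] <- first[[cc]]
  }
  colnames(m) <- paste(cd$cell_type, cd$sample, sep = ".")
  rownames(cd) <- colnames(m)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = m), colData = cd)
}

#' Gene prefilter for differential expression
#'
#' Drops genes (1) expressed in fewer than `min_cells_frac` of nuclei in
#' *both* contrasted groups (a gene well expressed in either group alone
#' is kept), (2) lowly expressed on the pseudobulk scale (fewer than
#' `min_count` summed counts in fewer than `min_samples` columns; a fixed
#' stand-in for count-filter heuristics of bulk DE tools), and (3) flagged
#' mitochondrial or ribosomal by annotation flags or symbol prefix.
#'
#' @param bundle a [CountBundle-class].
#' @param group1,group2 logical masks over nuclei (e.g. case / control).
#' @param pb optional [pseudobulk()] result for the low-count rule
#'   (skipped when `NULL`).
#' @param min_cells_frac per-group expressed-nucleus fraction (default
#'   0.01).
#' @param min_count,min_samples pseudobulk low-count rule.
#' @param prefixes symbol prefixes flagged as mitochondrial/ribosomal.
#' @param assay which counts to compute nucleus fractions on.
#' @return Character vector of surviving gene ids (possibly empty).
#' @export
prefilterGenes <- function(bundle, group1, group2, pb = NULL,
                           min_cells_frac = 0.01, min_count = 10,
                           min_samples = 3,
                           prefixes = c("MT-", "RPS", "RPL"),
                           assay = "raw") {
  if (!sum(group1) || !sum(group2)) stop("group masks must be non-empty")
  m <- SummarizedExperiment::assay(bundle, assay)
  f1 <- Matrix::rowMeans(m[, group1, drop = FALSE] > 0)
  f2 <- Matrix::rowMeans(m[, group2, drop = FALSE] > 0)
  keep <- !(f1 < min_cells_frac & f2 < min_cells_frac)
  rd <- geneData(bundle)
  sym <- if ("symbol" %in% colnames(rd)) rd$symbol else rownames(bundle)
  pref <- Reduce(`|`, lapply(prefixes, function(p) startsWith(sym, p)))
  keep <- keep & !rd$mito & !rd$ribo & !pref
  if (!is.null(pb)) {
    pc <- SummarizedExperiment::assay(pb, "counts")
    pc <- pc[rownames(bundle), , drop = FALSE]
    keep <- keep & rowSums(pc >= min_count) >= min_samples
  }
  rownames(bundle)[keep]
}

#' Median-of-ratios size factors
#'
#' For each pseudobulk column, the median over genes of the ratio of its
#' count to the gene's geometric mean across columns, using only genes
#' with a positive geometric mean (every column positive).
#'
#' @param counts gene x sample count matrix.
#' @return Positive numeric factor per column.
#' @export
medianRatioSizeFactors <- function(counts) {
  counts <- as.matrix(counts)
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) stop("no gene is positive in all columns")
  lg <- log(counts[pos, , drop = FALSE])
  ref <- rowMeans(lg)
  sf <- apply(lg, 2, function(col) exp(median(col - ref)))
  sf
}

.buildDesign <- function(cd, condition_col, covariates) {
  cond <- factor(cd[[condition_col]])
  fml <- paste(c("~ 0 + .cond",
                 covariates[covariates %in% colnames(cd)]),
               collapse = " + ")
  df <- as.data.frame(cd)
  df$.cond <- cond
  X <- stats::model.matrix(stats::as.formula(fml), data = df)
  colnames(X) <- sub("^\\.cond", "", colnames(X))
  list(X = X, cond = cond)
}

#' Pseudobulk differential expression
#'
#' Fits, per cell type and gene, a linear model of log2 size-factor
#' normalized expression (`log2(count/sf + 0.5)`) on condition plus
#' covariates, and tests the requested contrast with an ordinary
#' least-squares t-test (Benjamini-Hochberg adjusted within each cell
#' type x contrast). The default engine is deliberately unmoderated OLS;
#' `engine = "voom"` swaps in precision-weighted moderated statistics from
#' limma-voom behind the same interface.
#'
#' @param pb a [pseudobulk()] SummarizedExperiment; columns of all cell
#'   types may be present, each cell type is fit separately.
#' @param contrast character pair `c(case, control)` of condition levels.
#' @param condition_col colData column holding the condition (default
#'   `"condition"`); set it to a continuous covariate's name to test a
#'   numeric slope instead (see [fibrosisAssociation()]).
#' @param covariates additional colData columns to adjust for; columns
#'   absent or constant are dropped.
#' @param min_samples_per_group cell types with fewer samples than this in
#'   either contrasted group are skipped (default 3).
#' @param engine `"ols"` (default) or `"voom"` (requires limma).
#' @return data.frame with columns `gene`, `cell_type`, `contrast`,
#'   `logFC` (log2), `p`, `adj_p`.
#' @export
fitDE <- function(pb, contrast, condition_col = "condition",
                  covariates = c("age", "sex", "study"),
                  min_samples_per_group = 3,
                  engine = c("ols", "voom")) {
  engine <- match.arg(engine)
  cd <- SummarizedExperiment::colData(pb)
  counts <- SummarizedExperiment::assay(pb, "counts")
  out <- list()
  for (ct in unique(cd$cell_type)) {
    sel <- cd$cell_type == ct
    cdi <- cd[sel, , drop = FALSE]
    grp <- cdi[[condition_col]]
    n1 <- sum(grp == contrast[1]); n2 <- sum(grp == contrast[2])
    if (n1 < min_samples_per_group || n2 < min_samples_per_group) next
    keep <- grp %in% contrast
    cdi <- cdi[keep, , drop = FALSE]
    ci <- counts[, sel, drop = FALSE][, keep, drop = FALSE]
    covs <- covariates[vapply(covariates, function(v)
      v %in% colnames(cdi) && length(unique(cdi[[v]])) > 1, logical(1))]
    des <- .buildDesign(cdi, condition_col, covs)
    X <- des$X
    if (qr(X)$rank < ncol(X)) stop("rank-deficient design")
    cvec <- stats::setNames(numeric(ncol(X)), colnames(X))
    cvec[contrast[1]] <- 1; cvec[contrast[2]] <- -1
    sf <- medianRatioSizeFactors(ci)
    y <- log2(sweep(as.matrix(ci), 2, sf, "/") + 0.5)
    if (engine == "ols") {
      fit <- .olsContrast(y, X, cvec)
    } else {
      fit <- .voomContrast(ci, X, cvec, sf)
    }
    out[[ct]] <- data.frame(
      gene = rownames(counts), cell_type = ct,
      contrast = paste(contrast, collapse = "_vs_"),
      logFC = fit$logFC, p = fit$p,
      adj_p = p.adjust(fit$p, "BH"), row.names = NULL)
  }
  if (!length(out))
    stop("no cell type has >= ", min_samples_per_group,
         " samples in both groups")
  do.call(rbind, out)
}

.olsContrast <- function(y, X, cvec) {
  qrX <- qr(X)
  n <- nrow(X); pr <- qrX$rank
  beta <- qr.coef(qrX, t(y))            # coef x gene
  res <- t(y) - X %*% beta
  s2 <- colSums(res^2) / (n - pr)
  XtXi <- solve(crossprod(X))
  vc <- drop(t(cvec) %*% XtXi %*% cvec)
  est <- drop(t(cvec) %*% beta)
  tt <- est / sqrt(vc * s2)
  p <- 2 * pt(abs(tt), df = n - pr, lower.tail = FALSE)
  p[is.na(p)] <- 1
  list(logFC = est, p = p)
}

.voomContrast <- function(counts, X, cvec, sf) {
  if (!requireNamespace("limma", quietly = TRUE))
    stop("engine 'voom' requires the limma package")
  v <- limma::voom(as.matrix(counts), design = X,
                   lib.size = sf * mean(colSums(as.matrix(counts))))
  fit <- limma::lmFit(v, X)
  fit <- limma::contrasts.fit(fit, contrasts = matrix(cvec, ncol = 1))
  fit <- limma::eBayes(fit)
  list(logFC = drop(fit$coefficients), p = drop(fit$p.value))
}

#' Dual-count concordance filter
#'
#' Intersects the significant sets of the corrected-count (primary) and
#' raw-count (sensitivity) differential-expression runs: a gene is kept
#' only when adjusted p < `alpha` in both runs with the same effect
#' direction.
#'
#' @param results_corrected,results_raw [fitDE()] tables over the same
#'   genes, cell types and contrast.
#' @param alpha FDR threshold (default 0.05).
#' @return The rows of `results_corrected` passing the filter, with the
#'   raw run's `logFC`/`adj_p` appended as `logFC_raw`/`adj_p_raw`.
#' @export
concordanceFilter <- function(results_corrected, results_raw,
                              alpha = 0.05) {
  key <- function(d) paste(d$gene, d$cell_type, d$contrast)
  if (!setequal(key(results_corrected), key(results_raw)))
    stop("the two runs test different gene/cell-type/contrast universes")
  m <- match(key(results_corrected), key(results_raw))
  rc <- results_corrected
  rc$logFC_raw <- results_raw$logFC[m]
  rc$adj_p_raw <- results_raw$adj_p[m]
  keep <- rc$adj_p < alpha & rc$adj_p_raw < alpha &
    sign(rc$logFC) == sign(rc$logFC_raw)
  rc[keep, , drop = FALSE]
}

#' Exploratory association with a continuous sample covariate
#'
#' Tests each gene's pseudobulk expression in one cell type against a
#' continuous per-sample covariate (e.g. percent fibrosis from trichrome
#' staining), adjusting for age and sex, under both count versions;
#' returns genes with unadjusted p below `p_threshold` in both, with the
#' slope's sign. Intended for small case-only designs where the test is
#' exploratory.
#'
#' @param pb_corrected,pb_raw single-cell-type [pseudobulk()] objects over
#'   the same samples, with the covariate in colData.
#' @param covariate colData column name of the continuous covariate.
#' @param p_threshold unadjusted p cut (default 0.005).
#' @param covariates adjustment covariates.
#' @return data.frame `gene`, `slope_corrected`, `p_corrected`,
#'   `slope_raw`, `p_raw`, `direction` for passing genes.
#' @export
fibrosisAssociation <- function(pb_corrected, pb_raw, covariate,
                                p_threshold = 0.005,
                                covariates = c("age", "sex")) {
  one <- function(pb) {
    cd <- SummarizedExperiment::colData(pb)
    if (nrow(cd) < 4) stop("need at least 4 samples")
    v <- cd[[covariate]]
    if (length(unique(v)) < 2) stop("constant covariate")
    counts <- as.matrix(SummarizedExperiment::assay(pb, "counts"))
    sf <- medianRatioSizeFactors(counts)
    y <- log2(sweep(counts, 2, sf, "/") + 0.5)
    covs <- covariates[vapply(covariates, function(x)
      x %in% colnames(cd) && length(unique(cd[[x]])) > 1, logical(1))]
    df <- as.data.frame(cd)
    fml <- paste(c("~", covariate,
                   if (length(covs)) paste("+", covs, collapse = " ")),
                 collapse = " ")
    X <- stats::model.matrix(stats::as.formula(fml), data = df)
    cvec <- stats::setNames(numeric(ncol(X)), colnames(X))
    cvec[covariate] <- 1
    .olsContrast(y, X, cvec)
  }
  a <- one(pb_corrected); b <- one(pb_raw)
  genes <- rownames(SummarizedExperiment::assay(pb_corrected, "counts"))
  keep <- a$p < p_threshold & b$p < p_threshold &
    sign(a$logFC) == sign(b$logFC)
  data.frame(gene = genes, slope_corrected = a$logFC, p_corrected = a$p,
             slope_raw = b$logFC, p_raw = b$p,
             direction = ifelse(a$logFC > 0, "up", "down"),
             row.names = NULL)[keep, , drop = FALSE]
}

#' Marker selection criteria
#'
#' Threshold presets: the global map requires AUC > 0.60, adjusted
#' p < 0.01, log fold-change > 2 and expression in at least 25% of the
#' cluster's nuclei; the within-lineage (subcluster) preset loosens these
#' to AUC > 0.50, logFC > 0 and 15%.
#'
#' @param preset `"global"` or `"subcluster"`.
#' @param auc_min,adj_p_max,logfc_min,pct_min explicit overrides.
#' @return A list of class `markerCriteria`.
#' @export
markerCriteria <- function(preset = c("global", "subcluster"),
                           auc_min = NULL, adj_p_max = NULL,
                           logfc_min = NULL, pct_min = NULL) {
  preset <- match.arg(preset)
  def <- if (preset == "global")
    list(auc_min = 0.60, adj_p_max = 0.01, logfc_min = 2, pct_min = 0.25)
  else
    list(auc_min = 0.50, adj_p_max = 0.01, logfc_min = 0, pct_min = 0.15)
  for (f in names(def)) {
    ov <- get(f)
    if (!is.null(ov)) def[[f]] <- ov
  }
  if (def$pct_min < 0 || def$pct_min > 1) stop("pct_min must be in [0, 1]")
  class(def) <- "markerCriteria"
  def
}

#' Select marker genes per cluster
#'
#' Intersects the four marker criteria: one-vs-rest AUC, adjusted p and
#' log fold-change from the one-vs-rest pseudobulk model (no-intercept
#' cluster + individual design; see [markerDE()]), and the fraction of
#' in-cluster nuclei expressing the gene. Only protein-coding genes are
#' eligible.
#'
#' @param auc_table data.frame `gene`, `cluster`, `auc`.
#' @param de_table data.frame `gene`, `cluster`, `logFC`, `adj_p` (one-vs-
#'   rest contrast per cluster).
#' @param pct_table data.frame `gene`, `cluster`, `pct`.
#' @param criteria a [markerCriteria()] object.
#' @param coding optional character vector of protein-coding gene ids
#'   (`NULL` = all eligible).
#' @return data.frame of selected markers with all four statistics.
#' @export
selectMarkers <- function(auc_table, de_table, pct_table,
                          criteria = markerCriteria("global"),
                          coding = NULL) {
  stopifnot(inherits(criteria, "markerCriteria"))
  key <- function(d) paste(d$gene, d$cluster)
  m1 <- match(key(auc_table), key(de_table))
  m2 <- match(key(auc_table), key(pct_table))
  tab <- data.frame(gene = auc_table$gene, cluster = auc_table$cluster,
                    auc = auc_table$auc,
                    logFC = de_table$logFC[m1], adj_p = de_table$adj_p[m1],
                    pct = pct_table$pct[m2])
  keep <- !is.na(tab$logFC) &
    tab$auc > criteria$auc_min & tab$adj_p < criteria$adj_p_max &
    tab$logFC > criteria$logfc_min & tab$pct >= criteria$pct_min
  if (!is.null(coding)) keep <- keep & tab$gene %in% coding
  tab[keep, , drop = FALSE]
}

#' One-vs-rest pseudobulk marker model
#'
#' Fits the no-intercept model `~ 0 + cluster + individual` on
#' (cluster, sample) pseudobulk log2 expression and extracts, per cluster,
#' the contrast of that cluster against the average of all others.
#'
#' @param pb a [pseudobulk()] object built with `celltypes = cluster`
#'   labels and `min_nuclei` of the marker path (21, i.e. more than 20).
#' @param engine `"ols"` or `"voom"`.
#' @return data.frame `gene`, `cluster`, `logFC`, `p`, `adj_p`.
#' @export
markerDE <- function(pb, engine = c("ols", "voom")) {
  engine <- match.arg(engine)
  cd <- SummarizedExperiment::colData(pb)
  counts <- as.matrix(SummarizedExperiment::assay(pb, "counts"))
  cl <- factor(cd$cell_type); ind <- factor(cd$sample)
  X <- stats::model.matrix(~ 0 + cl + ind)
  if (qr(X)$rank < ncol(X))
    X <- X[, qr(X)$pivot[seq_len(qr(X)$rank)], drop = FALSE]
  sf <- medianRatioSizeFactors(counts)
  y <- log2(sweep(counts, 2, sf, "/") + 0.5)
  out <- list()
  for (l in levels(cl)) {
    cvec <- stats::setNames(numeric(ncol(X)), colnames(X))
    own <- paste0("cl", l)
    if (!own %in% names(cvec)) next
    others <- setdiff(grep("^cl", names(cvec), value = TRUE), own)
    cvec[own] <- 1
    cvec[others] <- -1 / length(others)
    fit <- if (engine == "ols") .olsContrast(y, X, cvec)
    else .voomContrast(counts, X, cvec, sf)
    out[[l]] <- data.frame(gene = rownames(counts), cluster = l,
                           logFC = fit$logFC, p = fit$p,
                           adj_p = p.adjust(fit$p, "BH"),
                           row.names = NULL)
  }
  do.call(rbind, out)
}

#' Patient-level principal components of summed counts
#'
#' Sums counts across all nuclei per sample, removes low-total genes,
#' normalizes by median-of-ratios size factors, applies a log2-based
#' variance-stabilizing transform (`log2(normalized + 1)`) and returns
#' principal-component scores of the samples.
#'
#' @param counts gene x nucleus matrix.
#' @param samples sample label per nucleus.
#' @param min_total genes with fewer summed counts are dropped (default
#'   10).
#' @param n_pcs components to return.
#' @return sample x PC coordinate matrix (mean-centered scores).
#' @export
patientPCA <- function(counts, samples, min_total = 10, n_pcs = 10) {
  samples <- as.character(samples)
  us <- unique(samples)
  if (length(us) < 3) stop("need at least 3 samples")
  counts <- methods::as(counts, "CsparseMatrix")
  m <- vapply(us, function(s)
    Matrix::rowSums(counts[, samples == s, drop = FALSE]),
    numeric(nrow(counts)))
  m <- m[rowSums(m) >= min_total, , drop = FALSE]
  sf <- medianRatioSizeFactors(m)
  y <- log2(sweep(m, 2, sf, "/") + 1)
  .pcaScores(t(y), n_pcs = min(n_pcs, length(us) - 1))
}
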