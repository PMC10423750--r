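#' Library-size log-normalization
#'
#' Scales each nucleus to `target_sum` total counts, then applies
#' `log(1 + x)`.
#'
#' @param counts gene x nucleus matrix (dense or sparse), non-negative.
#' @param target_sum per-nucleus total after scaling (default 10,000).
#' @return Sparse gene x nucleus matrix of log-normalized expression.
#' @export
normalizeLog <- function(counts, target_sum = 1e4) {
  counts <- methods::as(counts, "CsparseMatrix")
  tot <- Matrix::colSums(counts)
  if (any(tot == 0)) stop("zero-count nucleus cannot be normalized")
  sf <- target_sum / tot
  out <- counts %*% Matrix::Diagonal(x = sf)
  out@x <- log1p(out@x)
  dimnames(out) <- dimnames(counts)
  out
}

#' Highly variable gene selection by standardized variance
#'
#' Ranks genes by the variance of their standardized counts after a
#' mean-variance trend fit: a loess curve of `log10(variance)` on
#' `log10(mean)` predicts each gene's expected standard deviation; counts
#' are z-scored against it (clipped at `sqrt(n)`), and genes are ranked by
#' the variance of the clipped z-scores. This follows the
#' variance-stabilizing selection popularized by recent single-cell
#' toolkits at contract level; exact set agreement with any one
#' implementation is not promised.
#'
#' @param counts gene x nucleus raw count matrix.
#' @param n number of genes to return.
#' @param loess_span span of the trend fit.
#' @return Character vector of `n` gene names (or indices when the matrix
#'   has no rownames), ordered by decreasing standardized variance.
#' @export
selectHVG <- function(counts, n = 2000, loess_span = 0.3) {
  if (n <= 0) stop("n must be positive")
  if (n > nrow(counts)) stop("n exceeds the number of genes")
  counts <- methods::as(counts, "CsparseMatrix")
  mu <- Matrix::rowMeans(counts)
  v <- .rowVars(counts)
  fit_ok <- v > 0 & mu > 0
  sv <- numeric(nrow(counts))
  if (sum(fit_ok) > 10) {
    lf <- stats::loess(log10(v[fit_ok]) ~ log10(mu[fit_ok]),
                       span = loess_span, degree = 2)
    exp_sd <- sqrt(10^predict(lf))
    clip <- sqrt(ncol(counts))
    xs <- counts[fit_ok, , drop = FALSE]
    mu_ok <- mu[fit_ok]
    # variance of clipped z-scores, computed sparsely: zeros contribute
    # (0 - mu)/sd which is constant per gene
    z0 <- pmax(pmin(-mu_ok / exp_sd, clip), -clip)
    n_cells <- ncol(counts)
    xsT <- Matrix::t(xs)                     # cells x genes, CsparseMatrix
    nnz <- diff(xsT@p)
    g <- rep.int(seq_len(ncol(xsT)), nnz)    # gene index per stored value
    z <- pmax(pmin((xsT@x - mu_ok[g]) / exp_sd[g], clip), -clip)
    sum_z <- z0 * n_cells
    sum_z2 <- z0^2 * n_cells
    add <- tapply(z - z0[g], g, sum)
    add2 <- tapply(z^2 - z0[g]^2, g, sum)
    ii <- as.integer(names(add))
    sum_z[ii] <- sum_z[ii] + add
    sum_z2[ii] <- sum_z2[ii] + add2
    sv[fit_ok] <- (sum_z2 - sum_z^2 / n_cells) / (n_cells - 1)
  } else {
    sv <- v
  }
  ord <- order(sv, decreasing = TRUE)[seq_len(n)]
  if (!is.null(rownames(counts))) rownames(counts)[ord] else ord
}

#' Embed nuclei by standardized PCA
#'
#' Standardizes each gene to zero mean and unit variance (constant genes
#' are dropped), then computes principal-component scores. An optional
#' batch-alignment hook is applied to the coordinates, so an external
#' integration method can be plugged in without changing callers.
#'
#' @param log_matrix gene x nucleus log-normalized matrix (typically
#'   HVG-restricted).
#' @param n_pcs number of components.
#' @param batch optional per-nucleus batch labels, passed to `align`.
#' @param align optional `function(coords, batch)` returning adjusted
#'   coordinates.
#' @param seed retained for interface symmetry; the decomposition is
#'   deterministic.
#' @return nucleus x `n_pcs` coordinate matrix.
#' @export
embedCells <- function(log_matrix, n_pcs = 50, batch = NULL, align = NULL,
                       seed = 1L) {
  x <- as.matrix(Matrix::t(log_matrix))     # cells x genes
  if (n_pcs > min(dim(x))) stop("n_pcs too large for the input")
  sds <- apply(x, 2, sd)
  keep <- sds > 0
  x <- sweep(x[, keep, drop = FALSE], 2, colMeans(x[, keep, drop = FALSE]))
  x <- sweep(x, 2, sds[keep], "/")
  coords <- .pcaScores(x, n_pcs)
  rownames(coords) <- colnames(log_matrix)
  if (!is.null(align)) coords <- align(coords, batch)
  coords
}

#' Leiden community detection on a kNN graph
#'
#' Builds a k-nearest-neighbour graph of the embedding (cosine similarity
#' edge weights, symmetrized by union) and partitions it with the Leiden
#' algorithm under the modularity objective at the given resolution.
#'
#' @param coords nucleus x PC coordinate matrix.
#' @param n_neighbors neighbours per nucleus.
#' @param resolution Leiden resolution parameter.
#' @param seed seed; the partition is deterministic given it.
#' @return Character cluster labels, one per nucleus.
#' @export
leidenCluster <- function(coords, n_neighbors = 15, resolution = 1.0,
                          seed = 1L) {
  n <- nrow(coords)
  if (n_neighbors >= n) stop("n_neighbors must be below the nucleus count")
  if (any(!is.finite(coords))) stop("coordinates must be finite")
  normed <- .l2normRows(coords)
  nn <- .knnIndices(normed, k = n_neighbors, exclude_self = TRUE)
  i <- rep(seq_len(n), each = n_neighbors)
  j <- as.integer(t(nn))
  w <- rowSums(normed[i, , drop = FALSE] * normed[j, , drop = FALSE])
  w <- pmax(w, 1e-6)
  el <- cbind(pmin(i, j), pmax(i, j))
  dup <- duplicated(el)
  g <- igraph::graph_from_edgelist(el[!dup, , drop = FALSE],
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  igraph::E(g)$weight <- w[!dup]
  set.seed(seed)
  part <- igraph::cluster_leiden(g, objective_function = "modularity",
                                 resolution = resolution, n_iterations = 5)
  as.character(igraph::membership(part))
}

# per-cluster max one-vs-rest AUC from a precomputed rank matrix
# (ranks: gene x nucleus midranks of log-normalized expression)
.maxAUCPerCluster <- function(ranks, labels) {
  n <- ncol(ranks)
  vapply(unique(labels), function(cl) {
    mask <- labels == cl
    n1 <- sum(mask); n2 <- n - n1
    if (n1 == 0 || n2 == 0) return(NA_real_)
    auc <- (rowSums(ranks[, mask, drop = FALSE]) - n1 * (n1 + 1) / 2) /
      (n1 * n2)
    max(auc)
  }, numeric(1))
}

#' AUC-gated resolution sweep for subclustering
#'
#' Clusters at increasing Leiden resolutions; at each step every cluster's
#' best one-vs-rest marker AUC is computed, and the sweep halts as soon as
#' some cluster has no gene with AUC above `auc_halt`, returning the
#' previous resolution's labels (configurable to the current labels). The
#' rationale: a split that produces a cluster without a discriminating
#' marker is over-clustering.
#'
#' The gate is a within-lineage device: run it on the nuclei of one major
#' cell type (or one related lineage) at a time. When the swept nuclei
#' contain a marker-distinct foreign type, any split of a type inherits
#' that type's exclusive markers against the foreigner (AUC ~ 0.75 for a
#' half-split at a 50/50 mix), so the gate cannot fire and the sweep runs
#' to `resolution_max`. Rank noise also sets a floor: with few nuclei per
#' cluster the best AUC of an arbitrary split exceeds 0.6 by chance
#' (per-gene sd ~ `1/sqrt(3 n)` and the max runs over all genes), so the
#' halt binds only at realistic cluster sizes (hundreds of nuclei or
#' more).
#'
#' @param coords nucleus x PC embedding.
#' @param log_matrix gene x nucleus log-normalized expression used for the
#'   marker AUCs (typically HVG-restricted).
#' @param auc_halt halt threshold on the per-cluster max AUC (default
#'   0.60).
#' @param resolution_start,resolution_step,resolution_max sweep grid
#'   (global preset 0.05-1.0 by 0.05; use 0.10 steps for within-lineage
#'   sweeps).
#' @param n_neighbors,seed passed to [leidenCluster()].
#' @param keep `"previous"` (default) returns the labels from the last
#'   resolution that passed the gate; `"current"` returns the failing
#'   resolution's labels.
#' @return Character labels with attributes `resolution` (the resolution
#'   they came from) and `gate_passed` (FALSE only when the first swept
#'   resolution already failed).
#' @export
aucGatedSubcluster <- function(coords, log_matrix, auc_halt = 0.60,
                               resolution_start = 0.05,
                               resolution_step = 0.05,
                               resolution_max = 1.0,
                               n_neighbors = 15, seed = 1L,
                               keep = c("previous", "current")) {
  keep <- match.arg(keep)
  if (auc_halt < 0.5 || auc_halt > 1) stop("auc_halt must be in [0.5, 1]")
  ranks <- t(apply(as.matrix(log_matrix), 1, rank))
  res_grid <- seq(resolution_start, resolution_max, by = resolution_step)
  prev <- NULL; prev_res <- NA_real_
  for (r in res_grid) {
    labels <- leidenCluster(coords, n_neighbors = n_neighbors,
                            resolution = r, seed = seed)
    if (length(unique(labels)) > 1) {
      mx <- .maxAUCPerCluster(ranks, labels)
      if (any(mx <= auc_halt, na.rm = TRUE)) {
        if (is.null(prev) || keep == "current") {
          out <- labels
          attr(out, "resolution") <- r
          attr(out, "gate_passed") <- FALSE
          return(out)
        }
        attr(prev, "resolution") <- prev_res
        attr(prev, "gate_passed") <- TRUE
        return(prev)
      }
    }
    prev <- labels; prev_res <- r
  }
  attr(prev, "resolution") <- prev_res
  attr(prev, "gate_passed") <- TRUE
  prev
}

#' Merge similar clusters by Ward linkage
#'
#' Hierarchically clusters the per-cluster mean expression vectors
#' (Euclidean distance, Ward's method) and merges all clusters joined
#' below `merge_fraction` times the maximum linkage height. The maximum
#' inter-cluster distance is read as the dendrogram's maximum linkage
#' height; set `reference = "centroid"` to use the maximum pairwise
#' centroid distance instead.
#'
#' @param cluster_means cluster x gene matrix of mean (log-normalized)
#'   expression, rownames = cluster labels.
#' @param merge_fraction cut height as a fraction of the reference
#'   distance (default 0.25).
#' @param reference `"height"` (default) or `"centroid"`.
#' @return Named character vector mapping each input cluster label to its
#'   merged label.
#' @export
mergeSimilarClusters <- function(cluster_means, merge_fraction = 0.25,
                                 reference = c("height", "centroid")) {
  reference <- match.arg(reference)
  if (merge_fraction <= 0 || merge_fraction >= 1)
    stop("merge_fraction must be in (0, 1)")
  labs <- rownames(cluster_means)
  if (is.null(labs)) labs <- as.character(seq_len(nrow(cluster_means)))
  if (nrow(cluster_means) < 2)
    return(stats::setNames(labs, labs))
  d <- dist(cluster_means)
  hc <- hclust(d, method = "ward.D2")
  ref <- if (reference == "height") max(hc$height) else max(d)
  grp <- cutree(hc, h = merge_fraction * ref)
  merged <- vapply(unique(grp), function(g)
    paste(labs[grp == g], collapse = "+"), character(1))
  stats::setNames(merged[grp], labs)
}

#' Expression-matched signature score
#'
#' Scores each nucleus for a gene set as the mean log-normalized
#' expression of the set minus the mean expression of control genes drawn
#' from expression-matched bins: all genes are binned by average
#' expression into `n_bins` ranks and, for every set gene, `n_control`
#' non-set genes are sampled from its bin.
#'
#' @param log_matrix gene x nucleus log-normalized matrix.
#' @param gene_set character vector of gene names (duplicates ignored).
#' @param n_bins number of average-expression bins.
#' @param n_control control genes sampled per set gene.
#' @param seed sampling seed; deterministic given it.
#' @return Numeric score per nucleus.
#' @export
signatureScore <- function(log_matrix, gene_set, n_bins = 25,
                           n_control = 50, seed = 1L) {
  gene_set <- unique(gene_set)
  gene_set <- gene_set[gene_set %in% rownames(log_matrix)]
  if (!length(gene_set)) stop("gene_set shares no genes with the matrix")
  set.seed(seed)
  avg <- Matrix::rowMeans(log_matrix)
  bins <- cut(rank(avg, ties.method = "first"), breaks = n_bins,
              labels = FALSE)
  names(bins) <- rownames(log_matrix)
  ctrl <- unique(unlist(lapply(gene_set, function(g) {
    pool <- setdiff(names(bins)[bins == bins[[g]]], gene_set)
    if (!length(pool)) return(character(0))
    sample(pool, min(n_control, length(pool)))
  })))
  set_mean <- Matrix::colMeans(log_matrix[gene_set, , drop = FALSE])
  ctrl_mean <- if (length(ctrl))
    Matrix::colMeans(log_matrix[ctrl, , drop = FALSE]) else 0
  as.numeric(set_mean - ctrl_mean)
}

#' Screen subclusters against foreign and mitochondrial signatures
#'
#' A subcluster is removed when its median score for any foreign global
#' cell-type signature exceeds its median score for its own type's
#' signature, or when its median mitochondrial-signature score exceeds an
#' upper fence (Q3 + k*IQR over subcluster medians; the published
#' procedure removes such subclusters by inspection, this fence is the
#' declared substitute).
#'
#' @param sub_labels subcluster label per nucleus.
#' @param scores nucleus x signature matrix; one column per global
#'   cell-type signature plus optionally a `"mito"` column.
#' @param own_type column name of the subclusters' own global type.
#' @param mito_k fence multiplier for the mitochondrial rule.
#' @return Character vector of removed subcluster labels.
#' @export
screenSubclusters <- function(sub_labels, scores, own_type,
                              mito_k = 1.5) {
  stopifnot(own_type %in% colnames(scores))
  subs <- unique(sub_labels)
  if (!length(subs)) return(character(0))
  med <- t(vapply(subs, function(s)
    apply(scores[sub_labels == s, , drop = FALSE], 2, median),
    numeric(ncol(scores))))
  rownames(med) <- subs
  foreign <- setdiff(colnames(scores), c(own_type, "mito"))
  removed <- subs[apply(med[, foreign, drop = FALSE] >
                          med[, own_type], 1, any)]
  if ("mito" %in% colnames(scores) && length(subs) > 1) {
    q <- quartiles(med[, "mito"])
    fence <- q["q3"] + mito_k * (q["q3"] - q["q1"])
    removed <- union(removed, subs[med[, "mito"] > fence])
  }
  removed
}
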