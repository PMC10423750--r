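#' Genes shared across three disease contrasts
#'
#' Applies the shared-gene filter cascade to a multi-contrast DE table:
#' per cell type, a gene is kept when it is significant with a consistent
#' sign in all three disease-vs-control contrasts, not significant in any
#' disease-vs-disease contrast, has |logFC| > `lfc_min` in all three
#' disease-vs-control contrasts, and is expressed in more than `pct_min`
#' of nuclei in at least one group. Results are split by direction.
#'
#' The table must carry one row per gene x cell type x contrast with a
#' logical `significant` column (dual-count concordance already applied)
#' plus `logFC` and `pct_max` (the max expressed fraction over the two
#' contrasted groups).
#'
#' @param table data.frame `gene`, `cell_type`, `contrast`, `logFC`,
#'   `significant`, `pct_max`.
#' @param diseases character vector of the three disease labels.
#' @param ref control label (default `"NF"`).
#' @param lfc_min,pct_min effect-size and expression cuts (defaults 1 and
#'   0.05).
#' @return Named list per cell type, each `list(up = , down = )` of gene
#'   ids.
#' @export
sharedDEGs <- function(table, diseases = c("ICM", "DCM", "HCM"),
                       ref = "NF", lfc_min = 1, pct_min = 0.05) {
  vs_ref <- paste0(diseases, "_vs_", ref)
  pairs <- t(utils::combn(diseases, 2))
  vs_dis <- c(paste0(pairs[, 1], "_vs_", pairs[, 2]),
              paste0(pairs[, 2], "_vs_", pairs[, 1]))
  missing <- setdiff(vs_ref, unique(table$contrast))
  if (length(missing))
    stop("missing contrast(s): ", paste(missing, collapse = ", "))
  out <- list()
  for (ct in unique(table$cell_type)) {
    tt <- table[table$cell_type == ct, , drop = FALSE]
    w <- stats::reshape(
      tt[tt$contrast %in% vs_ref,
         c("gene", "contrast", "logFC", "significant", "pct_max")],
      direction = "wide", idvar = "gene", timevar = "contrast")
    sig_cols <- paste0("significant.", vs_ref)
    lfc_cols <- paste0("logFC.", vs_ref)
    pct_cols <- paste0("pct_max.", vs_ref)
    if (!all(c(sig_cols, lfc_cols) %in% colnames(w))) next
    sig_all <- Reduce(`&`, lapply(sig_cols, function(cc)
      !is.na(w[[cc]]) & w[[cc]]))
    lfc <- as.matrix(w[, lfc_cols])
    same_sign <- apply(sign(lfc), 1, function(s) all(s == s[1]))
    strong <- apply(abs(lfc) > lfc_min, 1, all)
    expr_ok <- apply(as.matrix(w[, pct_cols]) > pct_min, 1, any)
    dd <- tt[tt$contrast %in% vs_dis & tt$significant, "gene"]
    keep <- sig_all & same_sign & strong & expr_ok & !(w$gene %in% dd)
    up <- w$gene[keep & lfc[, 1] > 0]
    down <- w$gene[keep & lfc[, 1] < 0]
    out[[ct]] <- list(up = up, down = down)
  }
  out
}

#' Genes unique to one disease
#'
#' Per cell type, genes significant in the focal-disease-vs-control
#' contrast AND significant in at least one focal-vs-other-disease
#' contrast — i.e. changed in the focal disease and distinguishable from
#' the other diseases.
#'
#' @param table as in [sharedDEGs()].
#' @param focal focal disease label.
#' @param others the other disease labels.
#' @param ref control label.
#' @return Named list per cell type of gene id vectors.
#' @export
uniqueDiseaseDEGs <- function(table, focal = "ICM",
                              others = c("DCM", "HCM"), ref = "NF") {
  if (!any(table$contrast == paste0(focal, "_vs_", ref)))
    stop("unknown focal disease: ", focal)
  vs_others <- c(paste0(focal, "_vs_", others),
                 paste0(others, "_vs_", focal))
  out <- list()
  for (ct in unique(table$cell_type)) {
    tt <- table[table$cell_type == ct & table$significant, , drop = FALSE]
    in_ref <- tt$gene[tt$contrast == paste0(focal, "_vs_", ref)]
    in_other <- tt$gene[tt$contrast %in% vs_others]
    out[[ct]] <- intersect(in_ref, in_other)
  }
  out
}

#' Annotate shared genes with druggability tiers and specificity
#'
#' Intersects shared up/down gene sets with a druggable-genome annotation
#' (gene symbol to tier), and marks cell-type-specific genes by their
#' one-vs-rest AUC in that cell type (the published analysis states no
#' numeric specificity rule; the default cut of 0.6 matches the global
#' marker AUC gate and is configurable).
#'
#' @param shared a [sharedDEGs()] result.
#' @param annotation data.frame `symbol`, `tier`.
#' @param auc_table data.frame `gene`, `cell_type`, `auc`.
#' @param specificity_auc_min AUC cut for the cell-type-specific mark.
#' @return data.frame `gene`, `cell_type`, `direction`, `tier`,
#'   `celltype_specific`.
#' @export
druggableFilter <- function(shared, annotation, auc_table = NULL,
                            specificity_auc_min = 0.6) {
  rows <- list()
  for (ct in names(shared)) for (dir in c("up", "down")) {
    genes <- intersect(shared[[ct]][[dir]], annotation$symbol)
    if (!length(genes)) next
    tier <- annotation$tier[match(genes, annotation$symbol)]
    spec <- rep(NA, length(genes))
    if (!is.null(auc_table)) {
      a <- auc_table$auc[match(paste(genes, ct),
                               paste(auc_table$gene,
                                     auc_table$cell_type))]
      spec <- !is.na(a) & a > specificity_auc_min
    }
    rows[[paste(ct, dir)]] <- data.frame(
      gene = genes, cell_type = ct, direction = dir, tier = tier,
      celltype_specific = spec, row.names = NULL)
  }
  if (!length(rows))
    return(data.frame(gene = character(), cell_type = character(),
                      direction = character(), tier = character(),
                      celltype_specific = logical()))
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Fisher exact gene-set enrichment
#'
#' One 2x2 Fisher exact test (enrichment tail) per gene set within the
#' size bounds, against the supplied universe. Two significance modes are
#' supported: `"unadjusted"` (p < `p_max` and odds ratio > `or_min`,
#' matching ontology-style screening without multiplicity correction) and
#' `"fdr"` (Benjamini-Hochberg FDR < `fdr_max`, matching pathway-style
#' screening). The odds ratio is the sample ratio (a*d)/(b*c).
#'
#' @param query gene set of interest; must be a subset of `universe`.
#' @param universe all tested genes.
#' @param collection named list of gene sets (e.g. from [readGMT()]).
#' @param min_size,max_size set-size bounds after restriction to the
#'   universe (defaults 15 and 500; use 10/500 for the FDR mode's
#'   pathway-style screening).
#' @param mode `"unadjusted"` or `"fdr"`.
#' @param p_max,or_min,fdr_max significance cuts per mode.
#' @return data.frame `set`, `set_size`, `overlap`, `odds_ratio`, `p`,
#'   `adj_p`, `significant`.
#' @export
fisherEnrichment <- function(query, universe, collection,
                             min_size = 15, max_size = 500,
                             mode = c("unadjusted", "fdr"),
                             p_max = 0.001, or_min = 2, fdr_max = 0.05) {
  mode <- match.arg(mode)
  if (!length(universe)) stop("empty universe")
  if (!all(query %in% universe)) stop("query must be within the universe")
  rows <- lapply(names(collection), function(nm) {
    s <- intersect(collection[[nm]], universe)
    if (length(s) < min_size || length(s) > max_size) return(NULL)
    a <- length(intersect(query, s))
    b <- length(setdiff(query, s))
    cc <- length(s) - a
    d <- length(universe) - a - b - cc
    p <- fisher.test(matrix(c(a, b, cc, d), nrow = 2),
                     alternative = "greater")$p.value
    or <- if (b * cc == 0) {
      if (a * d == 0) 0 else Inf
    } else (a * d) / (b * cc)
    if (a == 0) or <- 0
    data.frame(set = nm, set_size = length(s), overlap = a,
               odds_ratio = or, p = p, row.names = NULL)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(set = character(), set_size = integer(),
                      overlap = integer(), odds_ratio = numeric(),
                      p = numeric(), adj_p = numeric(),
                      significant = logical()))
  out <- do.call(rbind, rows)
  out$adj_p <- p.adjust(out$p, "BH")
  out$significant <- if (mode == "unadjusted")
    out$p < p_max & out$odds_ratio > or_min
  else out$adj_p < fdr_max
  out
}

#' Read a GMT gene-set file
#'
#' @param path GMT file (tab-delimited: set name, description, genes...).
#' @return Named list of character gene sets.
#' @export
readGMT <- function(path) {
  lines <- strsplit(readLines(path), "\t")
  sets <- lapply(lines, function(x) x[-(1:2)])
  names(sets) <- vapply(lines, `[`, character(1), 1)
  sets
}

#' Probe-pair selectivity for in-situ validation
#'
#' Ranks candidate subtype markers for two-probe in-situ hybridization:
#' candidates must separate the target subtype (one-vs-rest AUC >
#' `auc_min`, log2 fold-change of mean normalized expression >
#' `logfc_min`, expressed in > `pct_min` of target nuclei) while staying
#' below `pct_other_max` expressed fraction in every other population.
#' For each candidate, the double-positive rate (candidate AND the pan
#' lineage marker both with count > 0) is computed in the target subtype
#' and in every other population; candidates are ranked by target rate
#' minus the maximum off-target rate.
#'
#' @param counts gene x nucleus count matrix.
#' @param labels population label per nucleus (subtypes of the lineage,
#'   optionally plus non-lineage populations).
#' @param target target subtype label.
#' @param pan_marker gene id of the pan-lineage marker.
#' @param auc_min,logfc_min,pct_min,pct_other_max candidate criteria
#'   (defaults 0.6, 1, 0.20, 0.25).
#' @return data.frame ranked by `selectivity`, with per-candidate rates.
#' @export
probePairSelectivity <- function(counts, labels, target, pan_marker,
                                 auc_min = 0.6, logfc_min = 1,
                                 pct_min = 0.20, pct_other_max = 0.25) {
  if (!target %in% labels) stop("target subtype absent from labels")
  stopifnot(pan_marker %in% rownames(counts))
  mask <- labels == target
  ln <- normalizeLog(counts)
  auc <- aucOneVsRest(ln, mask)
  mu_in <- Matrix::rowMeans(ln[, mask, drop = FALSE])
  mu_out <- Matrix::rowMeans(ln[, !mask, drop = FALSE])
  lfc <- log2((expm1(mu_in) + 0.05) / (expm1(mu_out) + 0.05))
  pct <- pctExpressed(counts, labels)
  others <- setdiff(colnames(pct), target)
  pct_other <- apply(pct[, others, drop = FALSE], 1, max)
  cand <- rownames(counts)[auc > auc_min & lfc > logfc_min &
                             pct[, target] > pct_min &
                             pct_other <= pct_other_max]
  cand <- setdiff(cand, pan_marker)
  if (!length(cand))
    return(data.frame(gene = character(), target_rate = numeric(),
                      max_offtarget_rate = numeric(),
                      selectivity = numeric()))
  pan_pos <- counts[pan_marker, ] > 0
  rate <- function(g, who) mean(counts[g, who] > 0 & pan_pos[who])
  pops <- unique(labels)
  rows <- lapply(cand, function(g) {
    tr <- rate(g, mask)
    off <- max(vapply(setdiff(pops, target), function(p)
      rate(g, labels == p), numeric(1)))
    data.frame(gene = g, target_rate = tr, max_offtarget_rate = off,
               selectivity = tr - off, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  out[order(out$selectivity, decreasing = TRUE), , drop = FALSE]
}

#' Classify RNA-vs-protein effect concordance
#'
#' Joins per-cell-type RNA differential-expression rows to one protein
#' row per gene (by symbol; the first protein row wins on duplicates,
#' with a message) and classifies each pair by significance at each
#' platform's threshold and sign agreement.
#'
#' @param rna data.frame `gene`, `cell_type`, `logFC`, `adj_p`.
#' @param protein data.frame `gene`, `logFC`, `adj_p`.
#' @param rna_alpha,protein_alpha per-platform significance cuts.
#' @return `rna` with appended `protein_logFC`, `protein_adj_p`, `class`
#'   in {concordant-up, concordant-down, discordant, rna-only,
#'   protein-only, neither}.
#' @export
proteomicsConcordance <- function(rna, protein, rna_alpha = 0.05,
                                  protein_alpha = 0.05) {
  if (anyDuplicated(protein$gene)) {
    message("duplicate protein rows for ",
            sum(duplicated(protein$gene)),
            " gene(s); keeping the first of each")
    protein <- protein[!duplicated(protein$gene), , drop = FALSE]
  }
  m <- match(rna$gene, protein$gene)
  out <- rna
  out$protein_logFC <- protein$logFC[m]
  out$protein_adj_p <- protein$adj_p[m]
  rna_sig <- out$adj_p < rna_alpha
  prot_sig <- !is.na(out$protein_adj_p) & out$protein_adj_p < protein_alpha
  cls <- rep("neither", nrow(out))
  cls[rna_sig & !prot_sig] <- "rna-only"
  cls[!rna_sig & prot_sig] <- "protein-only"
  both <- rna_sig & prot_sig
  same <- sign(out$logFC) == sign(out$protein_logFC)
  cls[both & same & out$logFC > 0] <- "concordant-up"
  cls[both & same & out$logFC < 0] <- "concordant-down"
  cls[both & !same] <- "discordant"
  out$class <- cls
  out
}

#' Reference-based cell-type composition test
#'
#' A transparent substitute for Bayesian compositional models, keeping
#' their reference-type convention: per sample, each cell type's count is
#' expressed as a log-ratio to the reference type's count (pseudocount
#' 0.5), and a two-sample t-test per type compares the log-ratios between
#' conditions, BH-adjusted across types. The reference type should be
#' prevalent and stable across samples (pericyte-like); it is never
#' tested against itself.
#'
#' @param celltypes,samples labels per nucleus.
#' @param condition condition label per nucleus (or per sample, named by
#'   sample).
#' @param reference reference cell-type label.
#' @param pseudocount added to all counts (default 0.5).
#' @return data.frame `cell_type`, `effect` (difference of mean
#'   log-ratios, first condition minus second), `p`, `adj_p`.
#' @export
compositionTest <- function(celltypes, samples, condition, reference,
                            pseudocount = 0.5) {
  if (!reference %in% celltypes) stop("reference type absent")
  tab <- table(samples, celltypes)
  if (any(tab[, reference] == 0))
    warning("reference type absent in some sample(s); pseudocount rescue")
  if (length(condition) == length(celltypes)) {
    cond <- tapply(as.character(condition), samples, function(x) x[1])
  } else cond <- condition[rownames(tab)]
  cond <- factor(cond[rownames(tab)])
  if (nlevels(cond) != 2) stop("need exactly two conditions")
  lr <- log((tab + pseudocount) / (tab[, reference] + pseudocount))
  types <- setdiff(colnames(tab), reference)
  res <- lapply(types, function(ct) {
    x <- lr[cond == levels(cond)[1], ct]
    y <- lr[cond == levels(cond)[2], ct]
    tt <- t.test(x, y)
    data.frame(cell_type = ct, effect = mean(x) - mean(y),
               p = tt$p.value, row.names = NULL)
  })
  out <- do.call(rbind, res)
  out$adj_p <- p.adjust(out$p, "BH")
  out
}
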