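# shared fixtures, built once per test run

.fixtures <- new.env(parent = emptyenv())

# full-scale default bundle (the study-design conditions)
defaultSim <- function() {
  if (is.null(.fixtures$sim))
    .fixtures$sim <- generateDataset(simConfig())
  .fixtures$sim
}

# small bundle for cheap structural tests
smallSim <- function() {
  if (is.null(.fixtures$small))
    .fixtures$small <- generateDataset(simConfig(
      n_genes = 600, n_cell_types = 3, nuclei_per_sample = 60,
      samples_per_condition = c(NF = 2L, ICM = 2L),
      n_de_genes_per_celltype = 10, n_marker_genes_per_celltype = 15,
      seed = 11))
  .fixtures$small
}

# clean singlets of the default bundle plus their true type labels
defaultClean <- function() {
  if (is.null(.fixtures$clean)) {
    sim <- defaultSim()
    keep <- !isLowQuality(sim$truth) & !isDoublet(sim$truth)
    .fixtures$clean <- list(
      bundle = sim$bundle[, keep],
      celltype = nucleusCellType(sim$truth)[keep],
      keep = keep)
  }
  .fixtures$clean
}

# full-scale two-type bundle without condition effects, for halt-rule
# checks (the gate needs realistic cluster sizes to bind)
twoTypeSim <- function() {
  if (is.null(.fixtures$twotype))
    .fixtures$twotype <- generateDataset(simConfig(
      n_cell_types = 2, de_log2fc = 0, doublet_rate = 0, lowq_rate = 0,
      seed = 8))
  .fixtures$twotype
}

# within-type AUC-gated sweep on one type of the two-type bundle
withinTypeSweep <- function(ty) {
  key <- paste0("sweep_", ty)
  if (is.null(.fixtures[[key]])) {
    sim <- twoTypeSim()
    sel <- nucleusCellType(sim$truth) == ty
    cnt <- correctedCounts(sim$bundle)[, sel]
    ln <- normalizeLog(cnt)
    hvg <- selectHVG(cnt, 1000)
    coords <- embedCells(ln[hvg, ], n_pcs = 30, seed = 1)
    .fixtures[[key]] <- aucGatedSubcluster(
      coords, ln[hvg, ], n_neighbors = 15, resolution_start = 0.05,
      resolution_step = 0.05, resolution_max = 1, seed = 1)
  }
  .fixtures[[key]]
}

# adjusted Rand index between two labelings
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  sij <- sum(choose(tab, 2))
  e <- si * sj / choose(n, 2)
  (sij - e) / ((si + sj) / 2 - e)
}

# swept-and-merged clustering of the clean default bundle (shared between
# the clustering tests and the acceptance suite)
defaultClustering <- function() {
  if (is.null(.fixtures$clustering)) {
    cl <- defaultClean()
    ln <- normalizeLog(correctedCounts(cl$bundle))
    hvg <- selectHVG(correctedCounts(cl$bundle), 2000)
    coords <- embedCells(ln[hvg, ], n_pcs = 50, seed = 1)
    labs <- aucGatedSubcluster(coords, ln[hvg, ], n_neighbors = 15,
                               seed = 1)
    lnh <- ln[hvg, ]
    means <- t(vapply(sort(unique(labs)), function(cc)
      Matrix::rowMeans(lnh[, labs == cc, drop = FALSE]),
      numeric(nrow(lnh))))
    merged <- mergeSimilarClusters(means)[labs]
    .fixtures$clustering <- list(coords = coords, log_hvg = lnh,
                                 swept = labs, merged = merged)
  }
  .fixtures$clustering
}

# pseudobulk differential expression of the default bundle under both
# count versions, with the published gene prefilter applied (shared by
# marker/DE tests and the acceptance suite)
defaultDE <- function() {
  if (is.null(.fixtures$de)) {
    cl <- defaultClean()
    nm <- as.data.frame(nucleusData(cl$bundle))
    pbC <- pseudobulk(correctedCounts(cl$bundle), cl$celltype, nm$sample,
                      25, nm)
    pbR <- pseudobulk(rawCounts(cl$bundle), cl$celltype, nm$sample,
                      25, nm)
    genes <- prefilterGenes(cl$bundle, nm$condition == "ICM",
                            nm$condition == "NF", pb = pbC)
    pbC <- pbC[genes, ]; pbR <- pbR[genes, ]
    resC <- fitDE(pbC, c("ICM", "NF"))
    resR <- fitDE(pbR, c("ICM", "NF"))
    .fixtures$de <- list(pbC = pbC, pbR = pbR, resC = resC, resR = resR,
                         genes = genes,
                         concordant = concordanceFilter(resC, resR))
  }
  .fixtures$de
}

# staged QC cascade on the default bundle (criteria on bookkeeping and
# planted-nucleus recovery share this run)
defaultCascade <- function() {
  if (is.null(.fixtures$cascade))
    .fixtures$cascade <- qcCascade(defaultSim()$bundle, seed = 1)
  .fixtures$cascade
}

# multi-contrast DE table for three diseases sharing the planted effects
threeDiseaseTable <- function() {
  if (is.null(.fixtures$three)) {
    sim <- generateDataset(simConfig(
      samples_per_condition = c(NF = 8L, ICM = 7L, DCM = 7L, HCM = 7L),
      seed = 3))
    keep <- !isLowQuality(sim$truth) & !isDoublet(sim$truth)
    b <- sim$bundle[, keep]
    ct <- nucleusCellType(sim$truth)[keep]
    nm <- as.data.frame(nucleusData(b))
    pbC <- pseudobulk(correctedCounts(b), ct, nm$sample, 25, nm)
    pbR <- pseudobulk(rawCounts(b), ct, nm$sample, 25, nm)
    genes <- prefilterGenes(b, nm$condition != "NF", nm$condition == "NF",
                            pb = pbC)
    pbC <- pbC[genes, ]; pbR <- pbR[genes, ]
    pct <- pctExpressed(correctedCounts(b)[genes, ], nm$condition)
    contrasts <- list(c("ICM", "NF"), c("DCM", "NF"), c("HCM", "NF"),
                      c("ICM", "DCM"), c("ICM", "HCM"), c("DCM", "HCM"))
    rows <- lapply(contrasts, function(cn) {
      rc <- fitDE(pbC, cn)
      rr <- fitDE(pbR, cn)
      conc <- concordanceFilter(rc, rr)
      key <- paste(rc$gene, rc$cell_type, rc$contrast)
      rc$significant <- key %in% paste(conc$gene, conc$cell_type,
                                       conc$contrast)
      rc$pct_max <- pmax(pct[rc$gene, cn[1]], pct[rc$gene, cn[2]])
      rc
    })
    .fixtures$three <- list(table = do.call(rbind, rows), truth = sim$truth)
  }
  .fixtures$three
}
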