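# brute-force AUC: fraction of (in, out) pairs where in > out, ties 1/2
.aucBrute <- function(x_in, x_out) {
  wins <- outer(x_in, x_out, ">") + 0.5 * outer(x_in, x_out, "==")
  mean(wins)
}

test_that("rank AUC equals brute-force pair counting, including ties", {
  expect_equal(aucOneVsRest(c(3, 5, 7, 1, 2, 6),
                            c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)),
               7 / 9)
  expect_equal(aucOneVsRest(c(1, 1, 1, 1), c(TRUE, TRUE, FALSE, FALSE)),
               0.5)
  expect_equal(aucOneVsRest(c(9, 8, 1, 2), c(TRUE, TRUE, FALSE, FALSE)),
               1.0)
  set.seed(10)
  for (i in 1:500) {
    n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
    x <- sample(0:4, n1 + n2, replace = TRUE)   # heavy ties
    mask <- rep(c(TRUE, FALSE), c(n1, n2))
    expect_equal(aucOneVsRest(x, mask), .aucBrute(x[mask], x[!mask]))
  }
  expect_error(aucOneVsRest(1:3, c(TRUE, TRUE, TRUE)), "non-empty")
})

test_that("pseudobulk sums member nuclei, drops thin columns, and conserves counts", {
  counts <- cbind(c(1, 0), c(2, 3))
  rownames(counts) <- c("g1", "g2"); colnames(counts) <- c("n1", "n2")
  pb <- pseudobulk(counts, c("A", "A"), c("s1", "s1"), min_nuclei = 2)
  expect_equal(unname(SummarizedExperiment::assay(pb)[, 1]), c(3, 3))

  set.seed(3)
  big <- matrix(rpois(50 * 60, 2), nrow = 50,
                dimnames = list(paste0("g", 1:50), paste0("n", 1:60)))
  ctype <- rep(c("A", "B"), c(24, 36))
  samp <- rep("s1", 60)
  pb2 <- pseudobulk(big, ctype, samp, min_nuclei = 25)
  # the 24-nucleus column is excluded, the 36-nucleus one kept
  expect_equal(SummarizedExperiment::colData(pb2)$cell_type, "B")
  expect_equal(sum(SummarizedExperiment::assay(pb2)),
               sum(big[, ctype == "B"]))
  expect_error(pseudobulk(big, ctype, samp, min_nuclei = 100),
               "survives")
})

test_that("the gene prefilter applies the separate-group 1% rule and annotation flags", {
  set.seed(4)
  G <- 40; N <- 400
  raw <- matrix(rpois(G * N, 3), nrow = G,
                dimnames = list(sprintf("G%02d", 1:G),
                                paste0("n", 1:N)))
  grp1 <- rep(c(TRUE, FALSE), each = N / 2)
  # G01: ~0.5% in both groups -> dropped
  raw[1, ] <- 0; raw[1, c(1, 201)] <- 1
  # G02: 0.5% in cases, 5% in controls -> retained
  raw[2, ] <- 0; raw[2, c(1, 300 + 1:10)] <- 1
  gm <- data.frame(mito = c(rep(FALSE, G - 2), TRUE, FALSE),
                   ribo = c(rep(FALSE, G - 1), TRUE),
                   row.names = rownames(raw))
  cb <- CountBundle(raw, raw,
    nucleusData = data.frame(sample = rep(c("s1", "s2"), each = N / 2),
                             condition = rep(c("ICM", "NF"), each = N / 2),
                             exon_prop = 0.1, row.names = colnames(raw)),
    geneData = gm)
  keep <- prefilterGenes(cb, grp1, !grp1)
  expect_false("G01" %in% keep)
  expect_true("G02" %in% keep)
  expect_false(rownames(raw)[G - 1] %in% keep)   # mito flag
  expect_false(rownames(raw)[G] %in% keep)       # ribo flag
})

test_that("median-of-ratios size factors match the doubled-column contract and the reference implementation", {
  m <- matrix(rpois(200 * 6, 20), nrow = 200)
  same <- cbind(m[, 1], m[, 1], m[, 1])
  expect_equal(unname(medianRatioSizeFactors(same)), rep(1, 3))

  doubled <- cbind(m[, 1], m[, 1], 2 * m[, 1])
  sf <- medianRatioSizeFactors(doubled)
  expect_equal(unname(sf[3] / sf[1]), 2)
  expect_true(all(medianRatioSizeFactors(m) > 0))
  skip_if_not_installed("DESeq2")
  expect_equal(unname(medianRatioSizeFactors(m)),
               unname(DESeq2::estimateSizeFactorsForMatrix(m)),
               tolerance = 1e-8)
  expect_error(medianRatioSizeFactors(matrix(c(0, 1, 1, 0), 2)),
               "positive")
})

test_that("planted log2 fold-changes are recovered within 0.5 at default depth", {
  de <- defaultDE()
  sim <- defaultSim()
  tt <- deGeneTable(sim$truth)
  m <- match(paste(tt$gene, tt$cell_type),
             paste(de$resC$gene, de$resC$cell_type))
  err <- de$resC$logFC[m] - tt$log2fc
  expect_gt(mean(abs(err) < 0.5), 0.9)
  expect_lt(abs(mean(err)), 0.2)
})

test_that("a covariate-only signal leaves condition p-values uniform", {
  set.seed(6)
  n <- 16; G <- 400
  age <- round(runif(n, 40, 70))
  cond <- rep(c("ICM", "NF"), each = n / 2)
  # expression driven by age only
  mu <- outer(rep(0.08, G), age) * 50
  counts <- matrix(rpois(G * n, mu), nrow = G,
                   dimnames = list(paste0("g", 1:G), paste0("s", 1:n)))
  cd <- S4Vectors::DataFrame(cell_type = "A", sample = paste0("s", 1:n),
                             n_nuclei = 100L, condition = cond,
                             age = age, sex = rep(c("M", "F"), n / 2))
  pb <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), colData = cd)
  res <- fitDE(pb, c("ICM", "NF"))
  ks <- stats::ks.test(res$p, "punif")
  expect_gt(ks$p.value, 0.01)
  # and the age slope is what carries the signal: dropping the adjustment
  # inflates nothing here because conditions are balanced in age by design
  expect_gt(min(res$p), 0)
})

test_that("contrasts are skipped below three samples per group", {
  set.seed(7)
  counts <- matrix(rpois(50 * 5, 20), nrow = 50,
                   dimnames = list(paste0("g", 1:50), paste0("s", 1:5)))
  cd <- S4Vectors::DataFrame(cell_type = "A", sample = paste0("s", 1:5),
                             n_nuclei = 50L,
                             condition = c("ICM", "ICM", "NF", "NF", "NF"),
                             age = c(50, 60, 55, 45, 65),
                             sex = c("M", "F", "M", "F", "M"))
  pb <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), colData = cd)
  expect_error(fitDE(pb, c("ICM", "NF")), "samples")
})

test_that("the concordance filter is an intersection with sign agreement", {
  a <- data.frame(gene = c("g1", "g2", "g3"), cell_type = "A",
                  contrast = "ICM_vs_NF", logFC = c(2, -1, 1),
                  p = c(1e-4, 1e-4, 0.5),
                  adj_p = c(1e-3, 1e-3, 0.6))
  b <- a
  b$adj_p <- c(1e-3, 0.2, 1e-3)   # g2 significant in corrected only
  out <- concordanceFilter(a, b)
  expect_equal(out$gene, "g1")
  expect_true(all(out$gene %in% a$gene[a$adj_p < 0.05]))
  same <- concordanceFilter(a, a)
  expect_setequal(same$gene, c("g1", "g2"))
  b2 <- b; b2$gene <- c("g1", "g2", "gX")
  expect_error(concordanceFilter(a, b2), "universe")
})

test_that("a monotone covariate association is recovered and permutation yields none", {
  set.seed(9)
  n <- 6; G <- 300
  fib <- c(10, 20, 30, 40, 50, 60)
  mu <- matrix(30, nrow = G, ncol = n)
  # strong planted slope: with age and sex adjusted at n = 6 the test has
  # 2 residual degrees of freedom, so only large effects can reach
  # p < 0.005
  mu[1, ] <- 3 * exp(0.09 * fib)          # planted monotone gene
  counts <- matrix(rpois(G * n, mu), nrow = G,
                   dimnames = list(paste0("g", 1:G), paste0("s", 1:n)))
  cd <- S4Vectors::DataFrame(cell_type = "Fib", sample = paste0("s", 1:n),
                             n_nuclei = 80L, fibrosis_pct = fib,
                             age = c(50, 55, 60, 45, 65, 52),
                             sex = c("M", "F", "M", "F", "M", "F"))
  pb <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), colData = cd)
  hits <- fibrosisAssociation(pb, pb, covariate = "fibrosis_pct")
  expect_true("g1" %in% hits$gene)
  expect_equal(hits$direction[hits$gene == "g1"], "up")
  expect_lte(nrow(hits), 5)

  cd2 <- cd; cd2$fibrosis_pct <- fib[c(4, 6, 1, 3, 5, 2)]
  counts0 <- matrix(rpois(G * n, 30), nrow = G,
                    dimnames = dimnames(counts))
  pb2 <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts0), colData = cd2)
  expect_lte(nrow(fibrosisAssociation(pb2, pb2,
                                      covariate = "fibrosis_pct")), 2)

  pb3 <- pb[, 1:2]
  expect_error(fibrosisAssociation(pb3, pb3, covariate = "fibrosis_pct"),
               "4 samples")
})

test_that("marker selection applies the tiered criteria", {
  auc <- data.frame(gene = "g1", cluster = "A", auc = 0.7)
  de <- data.frame(gene = "g1", cluster = "A", logFC = 2.5,
                   adj_p = 0.001)
  pct <- data.frame(gene = "g1", cluster = "A", pct = 0.30)
  expect_equal(nrow(selectMarkers(auc, de, pct,
                                  markerCriteria("global"))), 1)
  pct$pct <- 0.20
  expect_equal(nrow(selectMarkers(auc, de, pct,
                                  markerCriteria("global"))), 0)
  expect_equal(nrow(selectMarkers(auc, de, pct,
                                  markerCriteria("subcluster"))), 1)
})

test_that("planted exclusive markers are selected for their own type with high precision", {
  cl <- defaultClean()
  nm <- as.data.frame(nucleusData(cl$bundle))
  ln <- normalizeLog(correctedCounts(cl$bundle))
  types <- sort(unique(cl$celltype))
  # marker-path pseudobulk: more than 20 nuclei per (cluster, individual)
  pb <- pseudobulk(correctedCounts(cl$bundle), cl$celltype, nm$sample,
                   min_nuclei = 21, nucleus_meta = nm)
  de <- markerDE(pb)
  pct <- pctExpressed(correctedCounts(cl$bundle), cl$celltype)
  sel <- list()
  for (ty in types) {
    mask <- cl$celltype == ty
    auc <- aucOneVsRest(ln, mask)
    auc_tab <- data.frame(gene = rownames(ln), cluster = ty, auc = auc)
    de_tab <- de[de$cluster == ty, ]
    pct_tab <- data.frame(gene = rownames(pct), cluster = ty,
                          pct = pct[, ty])
    sel[[ty]] <- selectMarkers(auc_tab, de_tab, pct_tab,
                               markerCriteria("global"))
  }
  planted <- lapply(seq_along(types), function(i)
    rownames(cl$bundle)[60 + (i - 1) * 25 + seq_len(25)])
  names(planted) <- types
  hits <- unlist(lapply(types, function(ty) sel[[ty]]$gene %in%
                          planted[[ty]]))
  expect_gt(mean(hits), 0.9)            # precision
  recall <- mean(unlist(lapply(types, function(ty)
    planted[[ty]] %in% sel[[ty]]$gene)))
  expect_gt(recall, 0.8)
})

test_that("patient-level PCA separates conditions and centers coordinates", {
  cl <- defaultClean()
  nm <- as.data.frame(nucleusData(cl$bundle))
  co <- patientPCA(correctedCounts(cl$bundle), nm$sample)
  expect_equal(unname(colMeans(co)), rep(0, ncol(co)), tolerance = 1e-8)
  cond <- nm$condition[match(rownames(co), nm$sample)]
  # silhouette of the two condition groups on PC1-2
  d <- as.matrix(dist(co[, 1:2]))
  sil <- vapply(seq_len(nrow(co)), function(i) {
    a <- mean(d[i, cond == cond[i] & seq_len(nrow(co)) != i])
    b <- mean(d[i, cond != cond[i]])
    (b - a) / max(a, b)
  }, numeric(1))
  expect_gt(mean(sil), 0.5)
  expect_error(patientPCA(correctedCounts(cl$bundle)[, 1:10],
                          rep(c("a", "b"), 5)), "3 samples")
})

test_that("duplicated samples get identical patient coordinates", {
  set.seed(12)
  counts <- matrix(rpois(100 * 30, 5), nrow = 100,
                   dimnames = list(paste0("g", 1:100), paste0("n", 1:30)))
  samples <- rep(c("s1", "s2", "s3"), each = 10)
  counts[, samples == "s2"] <- counts[, samples == "s1"]
  co <- patientPCA(counts, samples)
  expect_equal(co["s1", ], co["s2", ], tolerance = 1e-8)
})
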