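# one row of a multi-contrast DE table
.mrow <- function(gene, ct, contrast, logFC, sig, pct = 0.10) {
  data.frame(gene = gene, cell_type = ct, contrast = contrast,
             logFC = logFC, significant = sig, pct_max = pct)
}

# build rows for a gene across the six contrasts of three diseases vs NF
.gene6 <- function(gene, ct, lfc_ref = c(1.5, 1.5, 1.5),
                   sig_ref = c(TRUE, TRUE, TRUE),
                   sig_pair = c(FALSE, FALSE, FALSE), pct = 0.10) {
  ref <- do.call(rbind, Map(function(d, l, s)
    .mrow(gene, ct, paste0(d, "_vs_NF"), l, s, pct),
    c("ICM", "DCM", "HCM"), lfc_ref, sig_ref))
  pair <- do.call(rbind, Map(function(cc, s)
    .mrow(gene, ct, cc, 0.1, s, pct),
    c("ICM_vs_DCM", "ICM_vs_HCM", "DCM_vs_HCM"), sig_pair))
  rbind(ref, pair)
}

test_that("the shared-gene cascade applies every rule of the filter chain", {
  tab <- rbind(
    .gene6("gKeep", "CM", c(1.2, 1.5, 1.1), pct = 0.08),
    .gene6("gSign", "CM", c(1.2, 1.5, -1.1)),          # inconsistent sign
    .gene6("gPair", "CM", sig_pair = c(TRUE, FALSE, FALSE)),
    .gene6("gWeak", "CM", c(0.8, 1.5, 1.2)),           # |logFC| <= 1 once
    .gene6("gRare", "CM", c(1.2, 1.5, 1.1), pct = 0.03),
    .gene6("gNS", "CM", sig_ref = c(TRUE, TRUE, FALSE)),
    .gene6("gDown", "CM", c(-1.2, -1.5, -1.1)))
  out <- sharedDEGs(tab)
  expect_equal(out$CM$up, "gKeep")
  expect_equal(out$CM$down, "gDown")
  expect_error(sharedDEGs(tab[tab$contrast != "HCM_vs_NF", ]), "missing")
})

test_that("unique-disease genes need a reference hit plus a cross-disease hit", {
  tab <- rbind(
    .gene6("gBoth", "CM", sig_pair = c(TRUE, TRUE, FALSE)),
    .gene6("gDCMonly", "CM", sig_pair = c(TRUE, FALSE, FALSE)),
    .gene6("gHCMonly", "CM", sig_pair = c(FALSE, TRUE, FALSE)),
    .gene6("gRefOnly", "CM"),
    .gene6("gNoRef", "CM", sig_ref = c(FALSE, TRUE, TRUE),
           sig_pair = c(TRUE, TRUE, FALSE)))
  out <- uniqueDiseaseDEGs(tab, focal = "ICM")
  expect_setequal(out$CM, c("gBoth", "gDCMonly", "gHCMonly"))
  expect_error(uniqueDiseaseDEGs(tab, focal = "XX"), "unknown")

  # 20-gene toy: counts per category match hand enumeration
  genes <- sprintf("t%02d", 1:20)
  cats <- rep(c("both", "dcm", "hcm", "none"), each = 5)
  tab2 <- do.call(rbind, Map(function(g, cc)
    .gene6(g, "Fib", sig_pair = switch(cc,
      both = c(TRUE, TRUE, FALSE), dcm = c(TRUE, FALSE, FALSE),
      hcm = c(FALSE, TRUE, FALSE), none = c(FALSE, FALSE, FALSE))),
    genes, cats))
  got <- uniqueDiseaseDEGs(tab2)$Fib
  expect_setequal(got, genes[cats != "none"])
  expect_equal(length(got), 15)
})

test_that("druggable filtering is an annotated intersection with an AUC specificity mark", {
  shared <- list(CM = list(up = c("A", "B", "X"), down = c("C")),
                 Fib = list(up = character(0), down = c("D", "E")))
  ann <- data.frame(symbol = c("A", "C", "D", "Q"),
                    tier = c("Tier 1", "Tier 2", "Tier 3A", "Tier 1"))
  auc <- data.frame(gene = c("A", "C", "D"),
                    cell_type = c("CM", "CM", "Fib"),
                    auc = c(0.75, 0.55, 0.62))
  out <- druggableFilter(shared, ann, auc)
  expect_setequal(out$gene, c("A", "C", "D"))
  expect_equal(out$tier[out$gene == "A"], "Tier 1")
  expect_false("X" %in% out$gene)   # unannotated dropped
  expect_true(out$celltype_specific[out$gene == "A"])
  expect_false(out$celltype_specific[out$gene == "C"])
})

test_that("Fisher enrichment matches the closed-form hypergeometric tail and size bounds", {
  universe <- sprintf("u%03d", 1:100)
  set <- universe[1:5]
  query <- universe[c(1:3, 50:56)]   # overlap 3, query 10
  out <- fisherEnrichment(query, universe, list(s = set), min_size = 5)
  p_exact <- sum(dhyper(3:5, 5, 95, 10))
  expect_equal(out$p, p_exact, tolerance = 1e-12)

  none <- fisherEnrichment(universe[50:59], universe,
                           list(s = universe[1:20]), min_size = 5)
  expect_equal(none$odds_ratio, 0)
  expect_equal(none$p, 1)

  uni2 <- sprintf("v%03d", 1:700)
  big <- fisherEnrichment(uni2[1:10], uni2, list(s = uni2[1:600]),
                          min_size = 15, max_size = 500)
  expect_equal(nrow(big), 0)
  expect_error(fisherEnrichment(c(query, "zzz"), universe, list(s = set)),
               "within")
})

test_that("probe-pair selectivity enforces candidate criteria and counts double positives by hand", {
  # 3 subtypes, 10 nuclei each; pan marker expressed broadly
  set.seed(11)
  n <- 30
  labels <- rep(c("target", "sib1", "sib2"), each = 10)
  counts <- rbind(
    pan   = rep(1, n),
    good  = c(rep(2, 8), 0, 0, rep(0, 10), rep(0, 10)),
    leaky = c(rep(2, 8), 0, 0, rep(1, 4), rep(0, 6), rep(0, 10)),
    noise = rpois(n, 0.2))
  colnames(counts) <- paste0("n", 1:n)
  out <- probePairSelectivity(counts, labels, "target", "pan")
  expect_true("good" %in% out$gene)
  expect_false("leaky" %in% out$gene)   # 40% of sib1 > 25% bound
  # hand counts: good+pan double positive in 8/10 target, 0 elsewhere
  expect_equal(out$target_rate[out$gene == "good"], 0.8)
  expect_equal(out$max_offtarget_rate[out$gene == "good"], 0)
  expect_equal(out$selectivity[out$gene == "good"], 0.8)
  expect_error(probePairSelectivity(counts, labels, "absent", "pan"),
               "absent")
})

test_that("proteomics concordance classes match hand enumeration on an 8-gene toy", {
  rna <- data.frame(
    gene = sprintf("p%d", 1:8), cell_type = "CM",
    logFC = c(2, -1, 1, 1, -2, 0.5, -0.5, 1),
    adj_p = c(0.01, 0.01, 0.01, 0.2, 0.01, 0.01, 0.2, 0.01))
  protein <- data.frame(
    gene = sprintf("p%d", c(1:7, 7)),    # p8 absent, p7 duplicated
    logFC = c(1, -2, -1, 1, -1, 2, 1, 9),
    adj_p = c(0.01, 0.01, 0.01, 0.01, 0.2, 0.2, 0.01, 0.01))
  expect_message(out <- proteomicsConcordance(rna, protein), "duplicate")
  expect_equal(out$class,
               c("concordant-up", "concordant-down", "discordant",
                 "protein-only", "rna-only", "rna-only", "protein-only",
                 "rna-only"))
  # duplicate resolution kept the first protein row for p7
  expect_equal(out$protein_logFC[out$gene == "p7"], 1)
})

test_that("the composition test detects a planted depletion and spares null data", {
  set.seed(13)
  types <- c("CM", "Fib", "EC", "Peri")
  mk <- function(prop, n_samp, cond, prefix) {
    do.call(rbind, lapply(seq_len(n_samp), function(i) {
      counts <- rmultinom(1, 400, prop)[, 1]
      data.frame(celltype = rep(types, counts),
                 sample = sprintf("%s%d", prefix, i), condition = cond)
    }))
  }
  base <- c(0.4, 0.25, 0.2, 0.15)
  shifted <- c(0.4 / 3, 0.25, 0.2, 0.15); shifted <- shifted / sum(shifted)
  df <- rbind(mk(base, 8, "NF", "nf"), mk(shifted, 7, "ICM", "icm"))
  res <- compositionTest(df$celltype, df$sample, df$condition, "Peri")
  expect_false("Peri" %in% res$cell_type)
  expect_lt(res$adj_p[res$cell_type == "CM"], 0.05)

  null <- rbind(mk(base, 8, "NF", "nf"), mk(base, 7, "ICM", "icm"))
  res0 <- compositionTest(null$celltype, null$sample, null$condition,
                          "Peri")
  expect_gte(min(res0$adj_p), 0.05)
  expect_error(compositionTest(df$celltype, df$sample, df$condition,
                               "Missing"), "absent")
})

test_that("GMT round trip feeds enrichment", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\tdesc\tg4\tg5"), path)
  sets <- readGMT(path)
  expect_equal(sets$setA, c("g1", "g2", "g3"))
  expect_equal(length(sets$setB), 2)
})
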