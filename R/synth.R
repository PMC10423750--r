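#' Simulation configuration for synthetic single-nucleus bundles
#'
#' Returns a validated list of generator parameters. The defaults describe
#' the study design the rest of the package is exercised against: 8
#' non-failing and 7 case left-ventricle samples, 200 nuclei per sample
#' (3,000 nuclei), 2,000 genes, five cell types with exclusive marker
#' programs, 10% ambient contamination, 5% doublets, 10% low-quality
#' nuclei, and 30 planted condition-affected genes per cell type at
#' |log2FC| = 2 (half up, half down). All case conditions share the same
#' planted effects, so multi-condition runs emulate diseases with a common
#' end-stage expression profile.
#'
#' @param n_genes number of genes.
#' @param n_cell_types number of cell types with distinct programs.
#' @param samples_per_condition named integer vector; the first name is the
#'   reference (control) condition.
#' @param nuclei_per_sample nuclei drawn per sample (before QC).
#' @param library_size_log_mean,library_size_log_sd lognormal parameters of
#'   the per-nucleus library size (UMIs).
#' @param ambient_fraction_mean mean per-nucleus ambient mixing fraction, in
#'   [0, 1).
#' @param doublet_rate,lowq_rate fractions of doublet and low-quality
#'   nuclei.
#' @param n_de_genes_per_celltype planted condition-affected genes per cell
#'   type (disjoint across types; half up-, half down-regulated).
#' @param de_log2fc planted absolute log2 fold-change.
#' @param mt_gene_fraction fraction of genes flagged mitochondrial.
#' @param ribo_gene_fraction fraction of genes flagged ribosomal.
#' @param n_marker_genes_per_celltype type-exclusive marker genes per type.
#' @param case_type_depletion multiplier on the first cell type's
#'   prevalence in case conditions (default 0.75, emulating the loss of
#'   the dominant parenchymal cell type in end-stage disease; 1 disables
#'   the shift).
#' @param background_jitter_sd lognormal sd of the per-type jitter around
#'   the shared background program. Types share housekeeping expression up
#'   to this modest variation, so the planted exclusive markers are the
#'   only genes meeting marker-grade fold-changes.
#' @param seed integer seed; generation is bitwise-deterministic given it.
#' @return A list of class `simConfig`.
#' @export
simConfig <- function(n_genes = 2000,
                      n_cell_types = 5,
                      samples_per_condition = c(NF = 8L, ICM = 7L),
                      nuclei_per_sample = 200,
                      library_size_log_mean = log(2500),
                      library_size_log_sd = 0.3,
                      ambient_fraction_mean = 0.1,
                      doublet_rate = 0.05,
                      lowq_rate = 0.1,
                      n_de_genes_per_celltype = 30,
                      de_log2fc = 2,
                      mt_gene_fraction = 0.02,
                      ribo_gene_fraction = 0.02,
                      n_marker_genes_per_celltype = 25,
                      case_type_depletion = 0.75,
                      background_jitter_sd = 0.3,
                      seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_cell_types = as.integer(n_cell_types),
              samples_per_condition = samples_per_condition,
              nuclei_per_sample = as.integer(nuclei_per_sample),
              library_size_log_mean = library_size_log_mean,
              library_size_log_sd = library_size_log_sd,
              ambient_fraction_mean = ambient_fraction_mean,
              doublet_rate = doublet_rate,
              lowq_rate = lowq_rate,
              n_de_genes_per_celltype = as.integer(n_de_genes_per_celltype),
              de_log2fc = de_log2fc,
              mt_gene_fraction = mt_gene_fraction,
              ribo_gene_fraction = ribo_gene_fraction,
              n_marker_genes_per_celltype =
                as.integer(n_marker_genes_per_celltype),
              case_type_depletion = case_type_depletion,
              background_jitter_sd = background_jitter_sd,
              seed = as.integer(seed))
  fr <- c("ambient_fraction_mean", "doublet_rate", "lowq_rate",
          "mt_gene_fraction", "ribo_gene_fraction")
  for (f in fr)
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop(sprintf("'%s' must lie in [0, 1]", f))
  if (cfg$ambient_fraction_mean >= 1)
    stop("'ambient_fraction_mean' must be < 1")
  if (cfg$n_genes < 1 || cfg$n_cell_types < 1 || cfg$nuclei_per_sample < 1)
    stop("counts must be positive")
  if (is.null(names(cfg$samples_per_condition)) ||
      any(cfg$samples_per_condition < 1))
    stop("'samples_per_condition' must be a named vector of positive counts")
  if (!is.finite(cfg$de_log2fc)) stop("'de_log2fc' must be finite")
  if (cfg$case_type_depletion <= 0)
    stop("'case_type_depletion' must be positive")
  class(cfg) <- "simConfig"
  cfg
}

# Fixed mass budget of each cell-type program. Marker genes carry exclusive
# mass (separable clusters); ambient-dominant genes carry equal mass in all
# types (high abundance, type-nonspecific); mitochondrial mass is pinned so
# clean nuclei sit well under the %MT threshold; planted condition-affected
# genes get a guaranteed moderate baseline so effects are detectable.
.massBudget <- list(marker = 0.20, ambient = 0.20, mito = 0.01, de = 0.15)
.LOWQ <- list(program_size = 10L, mito_mass = 0.30, libsize_scale = 0.6)

.rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha)
  if (sum(x) == 0) x[sample.int(length(alpha), 1)] <- 1
  x / sum(x)
}

#' Generate a synthetic single-nucleus bundle with planted truth
#'
#' Draws a multi-sample, multi-condition dataset under the generative model
#' the pipeline assumes. Each cell type has a gene-expression program
#' (probability vector over genes; marker genes are type-exclusive). A
#' nucleus with library size \eqn{L \sim \mathrm{lognormal}} draws counts
#' multinomially from \eqn{(1-a)\,p_{\mathrm{type}} + a\,p_{\mathrm{pool}}},
#' where \eqn{a} is a Beta-distributed per-nucleus ambient fraction and the
#' pool is the prevalence-weighted mixture of all programs in the sample's
#' condition. Doublets are sums of two independently drawn singlets;
#' low-quality nuclei get a program concentrated on few genes with inflated
#' mitochondrial mass and inflated exonic-read fraction. In case
#' conditions, planted genes have their program rate multiplied by
#' \eqn{2^{\pm\mathrm{log2FC}}} in their cell type. The `corrected` assay
#' is the raw matrix minus the rounded expected ambient component, clipped
#' at zero.
#'
#' @param config a [simConfig()] list.
#' @return A list with elements `bundle` ([CountBundle-class]) and `truth`
#'   ([SyntheticTruth-class]).
#' @examples
#' sim <- generateDataset(simConfig(n_genes = 600, nuclei_per_sample = 40,
#'   samples_per_condition = c(NF = 2, ICM = 2), seed = 7))
#' sim$bundle
#' sim$truth
#' @export
generateDataset <- function(config = simConfig()) {
  stopifnot(inherits(config, "simConfig"))
  set.seed(config$seed)
  G <- config$n_genes
  Tn <- config$n_cell_types
  conds <- names(config$samples_per_condition)
  ref_cond <- conds[1]
  types <- paste0("CT", seq_len(Tn))

  n_mt <- max(1L, round(G * config$mt_gene_fraction))
  n_ribo <- round(G * config$ribo_gene_fraction)
  n_amb <- 20L
  n_mark <- config$n_marker_genes_per_celltype
  n_de <- config$n_de_genes_per_celltype
  need <- n_mt + n_ribo + n_amb + Tn * (n_mark + n_de)
  if (need > G)
    stop("n_genes too small for the requested marker/DE/ambient structure")

  idx <- seq_len(G)
  mt_idx <- idx[seq_len(n_mt)]
  amb_idx <- idx[n_mt + seq_len(n_amb)]
  mark_idx <- split(idx[n_mt + n_amb + seq_len(Tn * n_mark)],
                    rep(seq_len(Tn), each = n_mark))
  de_idx <- split(idx[n_mt + n_amb + Tn * n_mark + seq_len(Tn * n_de)],
                  rep(seq_len(Tn), each = n_de))
  rest_start <- n_mt + n_amb + Tn * (n_mark + n_de) + 1
  rest_idx <- if (rest_start <= G) idx[rest_start:G] else integer(0)
  ribo_idx <- rest_idx[seq_len(n_ribo)]
  if (length(rest_idx) - n_ribo < .LOWQ$program_size)
    stop("n_genes too small for the requested marker/DE/ambient structure")

  gene_id <- sprintf("GENE%05d", idx)
  symbol <- gene_id
  symbol[mt_idx] <- sprintf("MT-G%03d", seq_along(mt_idx))
  symbol[ribo_idx] <- sprintf("RPS%03d", seq_along(ribo_idx))
  gene_meta <- data.frame(
    gene_id = gene_id, symbol = symbol,
    mito = idx %in% mt_idx, ribo = idx %in% ribo_idx,
    protein_coding = TRUE, row.names = gene_id)

  # reference programs: fixed block masses + a background program shared
  # across types up to modest lognormal jitter (types share housekeeping
  # expression; only planted markers carry marker-grade fold-changes)
  bg_mass <- 1 - .massBudget$marker - .massBudget$ambient -
    .massBudget$mito - .massBudget$de
  bg_idx <- rest_idx
  bg_shared <- .rdirichlet1(rep(0.2, length(bg_idx)))
  programs <- matrix(0, nrow = G, ncol = Tn,
                     dimnames = list(gene_id, types))
  for (t in seq_len(Tn)) {
    p <- numeric(G)
    p[mark_idx[[t]]] <- .massBudget$marker / n_mark
    p[amb_idx] <- .massBudget$ambient / n_amb
    p[mt_idx] <- .massBudget$mito / n_mt
    de_all <- unlist(de_idx)
    p[de_all] <- .massBudget$de / length(de_all)
    jitter <- exp(stats::rnorm(length(bg_idx), 0,
                               config$background_jitter_sd))
    bg <- bg_shared * jitter
    p[bg_idx] <- bg_mass * bg / sum(bg)
    programs[, t] <- p
  }

  # planted effects: identical across case conditions; half up, half down
  de_tab <- data.frame(gene = character(), cell_type = character(),
                       condition = character(), log2fc = numeric())
  eff_sign <- lapply(seq_len(Tn), function(t)
    rep(c(1, -1), length.out = n_de))
  if (config$de_log2fc != 0 && length(conds) > 1) {
    for (cc in conds[-1]) for (t in seq_len(Tn))
      de_tab <- rbind(de_tab, data.frame(
        gene = gene_id[de_idx[[t]]], cell_type = types[t], condition = cc,
        log2fc = eff_sign[[t]] * config$de_log2fc))
  }

  case_program <- function(t, cond) {
    p <- programs[, t]
    if (cond != ref_cond && config$de_log2fc != 0) {
      p[de_idx[[t]]] <- p[de_idx[[t]]] * 2^(eff_sign[[t]] * config$de_log2fc)
      p <- p / sum(p)
    }
    p
  }

  # per-condition programs, type prevalences (the first type is depleted
  # in case conditions) and prevalence-weighted ambient pools
  cond_programs <- lapply(conds, function(cc)
    vapply(seq_len(Tn), function(t) case_program(t, cc), numeric(G)))
  names(cond_programs) <- conds
  prevalence <- lapply(conds, function(cc) {
    w <- rep(1, Tn)
    if (cc != ref_cond) w[1] <- config$case_type_depletion
    w / sum(w)
  })
  names(prevalence) <- conds
  pools <- lapply(conds, function(cc)
    as.numeric(cond_programs[[cc]] %*% prevalence[[cc]]))
  names(pools) <- conds

  samples <- unlist(lapply(conds, function(cc)
    sprintf("%s_%d", cc, seq_len(config$samples_per_condition[[cc]]))))
  sample_cond <- rep(conds, times = config$samples_per_condition)
  names(sample_cond) <- samples
  sample_age <- stats::setNames(round(runif(length(samples), 40, 70)), samples)
  sample_sex <- stats::setNames(
    sample(c("M", "F"), length(samples), replace = TRUE), samples)

  N <- length(samples) * config$nuclei_per_sample
  a_mean <- config$ambient_fraction_mean
  draw_a <- function(n) {
    if (a_mean == 0) return(rep(0, n))
    conc <- 80
    rbeta(n, a_mean * conc, (1 - a_mean) * conc)
  }

  counts <- matrix(0L, nrow = G, ncol = N)
  expected_ambient <- matrix(0, nrow = G, ncol = N)
  truth_type <- character(N); truth_dbl <- logical(N)
  truth_lowq <- logical(N); truth_a <- numeric(N)
  nuc_sample <- character(N); exon_prop <- numeric(N)

  draw_singlet <- function(type, cond, a, pool) {
    L <- round(rlnorm(1, config$library_size_log_mean,
                      config$library_size_log_sd))
    L <- max(L, 50)
    p <- (1 - a) * cond_programs[[cond]][, type] + a * pool
    list(counts = rmultinom(1, L, p)[, 1], amb = a * L * pool)
  }
  draw_lowq <- function(cond, a, pool) {
    L <- round(.LOWQ$libsize_scale *
               rlnorm(1, config$library_size_log_mean,
                      config$library_size_log_sd))
    L <- max(L, 50)
    q <- numeric(G)
    sup <- sample(bg_idx, .LOWQ$program_size)
    q[sup] <- (1 - .LOWQ$mito_mass) * .rdirichlet1(rep(1, length(sup)))
    q[mt_idx] <- q[mt_idx] + .LOWQ$mito_mass / n_mt
    p <- (1 - a) * q + a * pool
    list(counts = rmultinom(1, L, p)[, 1], amb = a * L * pool)
  }

  i <- 0L
  for (s in samples) {
    cond <- sample_cond[[s]]
    pool <- pools[[cond]]
    for (j in seq_len(config$nuclei_per_sample)) {
      i <- i + 1L
      nuc_sample[i] <- s
      u <- runif(1)
      a <- draw_a(1)
      if (u < config$lowq_rate) {
        d <- draw_lowq(cond, a, pool)
        truth_lowq[i] <- TRUE
        truth_type[i] <- "lowq"
        exon_prop[i] <- rbeta(1, 10, 10)
      } else if (u < config$lowq_rate + config$doublet_rate) {
        t2 <- sample.int(Tn, 2, replace = TRUE, prob = prevalence[[cond]])
        a2 <- draw_a(1)
        d1 <- draw_singlet(t2[1], cond, a, pool)
        d2 <- draw_singlet(t2[2], cond, a2, pool)
        d <- list(counts = d1$counts + d2$counts, amb = d1$amb + d2$amb)
        truth_dbl[i] <- TRUE
        truth_type[i] <- types[t2[1]]
        a <- (a + a2) / 2
        exon_prop[i] <- rbeta(1, 4, 46)
      } else {
        t1 <- sample.int(Tn, 1, prob = prevalence[[cond]])
        d <- draw_singlet(t1, cond, a, pool)
        truth_type[i] <- types[t1]
        exon_prop[i] <- rbeta(1, 4, 46)
      }
      counts[, i] <- d$counts
      expected_ambient[, i] <- d$amb
      truth_a[i] <- a
    }
  }

  corrected <- pmax(counts - round(expected_ambient), 0)
  barcodes <- sprintf("%s_N%04d", nuc_sample, seq_len(N))
  dimnames(counts) <- list(gene_id, barcodes)
  dimnames(corrected) <- list(gene_id, barcodes)

  nucleus_meta <- data.frame(
    barcode = barcodes, sample = nuc_sample,
    condition = unname(sample_cond[nuc_sample]),
    exon_prop = exon_prop,
    age = unname(sample_age[nuc_sample]),
    sex = unname(sample_sex[nuc_sample]),
    row.names = barcodes)

  bundle <- CountBundle(counts, corrected, nucleus_meta, gene_meta)
  truth <- methods::new("SyntheticTruth",
    nucleusCellType = stats::setNames(truth_type, barcodes),
    isDoublet = truth_dbl, isLowQuality = truth_lowq,
    ambientGenes = gene_id[amb_idx],
    deGeneTable = de_tab, ambientFraction = truth_a)
  list(bundle = bundle, truth = truth)
}

#' Write a bundle to a 10x-style directory
#'
#' Writes `raw.mtx` and `corrected.mtx` (Matrix Market coordinate format,
#' 1-based, features x barcodes), `barcodes.tsv`, `features.tsv`
#' (id, symbol, type), `nucleus_meta.tsv`, `gene_meta.tsv`, and (when
#' `truth` is supplied) `truth.json`. The round trip through
#' [readBundle()] is lossless.
#'
#' @param bundle a [CountBundle-class].
#' @param dir output directory (created if missing).
#' @param truth optional [SyntheticTruth-class] to serialize alongside.
#' @return `dir`, invisibly.
#' @export
writeBundle <- function(bundle, dir, truth = NULL) {
  stopifnot(methods::is(bundle, "CountBundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Matrix::writeMM(methods::as(rawCounts(bundle), "CsparseMatrix"),
                  file.path(dir, "raw.mtx"))
  Matrix::writeMM(methods::as(correctedCounts(bundle), "CsparseMatrix"),
                  file.path(dir, "corrected.mtx"))
  writeLines(colnames(bundle), file.path(dir, "barcodes.tsv"))
  rd <- as.data.frame(geneData(bundle))
  feat <- data.frame(id = rownames(bundle),
                     symbol = if ("symbol" %in% colnames(rd)) rd$symbol
                              else rownames(bundle),
                     type = "Gene Expression")
  write.table(feat, file.path(dir, "features.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  write.table(as.data.frame(nucleusData(bundle)),
              file.path(dir, "nucleus_meta.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(rd, file.path(dir, "gene_meta.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(truth)) {
    stopifnot(methods::is(truth, "SyntheticTruth"))
    jsonlite::write_json(list(
      nucleus_celltype = as.list(stats::setNames(
        truth@nucleusCellType, colnames(bundle))),
      is_doublet = truth@isDoublet,
      is_lowq = truth@isLowQuality,
      ambient_genes = truth@ambientGenes,
      de_gene_table = truth@deGeneTable,
      ambient_fraction = truth@ambientFraction),
      file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read a bundle written by [writeBundle()]
#'
#' @param dir directory containing the files written by [writeBundle()].
#' @return A [CountBundle-class]; when `truth.json` is present, the
#'   deserialized [SyntheticTruth-class] is attached as
#'   `metadata(bundle)$truth`.
#' @export
readBundle <- function(dir) {
  raw <- methods::as(Matrix::readMM(file.path(dir, "raw.mtx")),
                     "CsparseMatrix")
  corrected <- methods::as(Matrix::readMM(file.path(dir, "corrected.mtx")),
                           "CsparseMatrix")
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  feat <- read.delim(file.path(dir, "features.tsv"), header = FALSE)
  if (nrow(raw) != nrow(feat) || ncol(raw) != length(barcodes))
    stop("matrix dimensions disagree with barcodes/features files")
  gm <- read.delim(file.path(dir, "gene_meta.tsv"))
  nm <- read.delim(file.path(dir, "nucleus_meta.tsv"))
  if (nrow(gm) != nrow(raw) || nrow(nm) != ncol(raw))
    stop("annotation tables disagree with matrix dimensions")
  dimnames(raw) <- dimnames(corrected) <- list(feat$V1, barcodes)
  rownames(gm) <- feat$V1
  rownames(nm) <- barcodes
  bundle <- CountBundle(raw, corrected, nm, gm)
  tf <- file.path(dir, "truth.json")
  if (file.exists(tf)) {
    tj <- jsonlite::read_json(tf, simplifyVector = TRUE)
    det <- as.data.frame(tj$de_gene_table)
    if (!nrow(det))
      det <- data.frame(gene = character(), cell_type = character(),
                        condition = character(), log2fc = numeric())
    truth <- methods::new("SyntheticTruth",
      nucleusCellType = unlist(tj$nucleus_celltype),
      isDoublet = tj$is_doublet, isLowQuality = tj$is_lowq,
      ambientGenes = as.character(tj$ambient_genes),
      deGeneTable = det,
      ambientFraction = tj$ambient_fraction)
    S4Vectors::metadata(bundle)$truth <- truth
  }
  bundle
}
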