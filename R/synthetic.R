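#' Simulation configuration for single-cell score benchmarks
#'
#' Defines a planted-structure single-cell experiment: log-normal baseline
#' expression, clonal subpopulations whose signature genes are shifted by a
#' known effect size, Bernoulli dropout, and a per-cell library-size factor
#' recorded as an nUMI covariate (the nuisance the regression module is
#' meant to remove).
#'
#' @param n_cells,n_genes dataset dimensions.
#' @param clones list of clones, each `list(fraction =, effect =)` with
#'   `effect` a numeric vector of per-signature effect sizes in units of the
#'   baseline biological standard deviation (positive = UP genes up, DN
#'   genes down, i.e. a "sensitive" profile for that signature). Fractions
#'   must sum to 1.
#' @param signatures list of `list(n_up =, n_dn =)`; planted gene blocks are
#'   disjoint across signatures. The default emulates scoring against a
#'   reduced drug-background panel: 20 bidirectional signatures of 100
#'   genes per direction, of which (with the default `clones`) only the
#'   first discriminates the clones — the remaining 19 behave as null
#'   drugs.
#' @param dropout_rate probability an entry is zeroed (default 0.3, a
#'   moderate scRNA-seq dropout regime).
#' @param libsize_sd sd of the log-normal per-cell library-size factor
#'   (default 0.2).
#' @param nuisance_coeff extra additive leakage of the log library-size
#'   factor into every gene (default 0; the multiplicative factor already
#'   couples scores to nUMI).
#' @param base_sd biological standard deviation of log expression around
#'   each gene's mean (default 1; effects are expressed in these units).
#' @param seed integer random seed.
#' @return a `SimConfig` list.
#' @export
sim_config <- function(n_cells = 500L, n_genes = 4000L,
                       clones = list(list(fraction = 0.5,
                                          effect = c(3, rep(0, 19))),
                                     list(fraction = 0.5,
                                          effect = rep(0, 20))),
                       signatures = rep(list(list(n_up = 100L, n_dn = 100L)),
                                        20L),
                       dropout_rate = 0.3, libsize_sd = 0.2,
                       nuisance_coeff = 0, base_sd = 1, seed = 1L) {
  fr <- vapply(clones, `[[`, numeric(1), "fraction")
  if (abs(sum(fr) - 1) > 1e-8) stop("clone fractions must sum to 1")
  for (cl in clones)
    if (length(cl$effect) != length(signatures))
      stop("each clone needs one effect per signature")
  n_planted <- sum(vapply(signatures,
                          function(s) s$n_up + s$n_dn, numeric(1)))
  if (n_planted > n_genes)
    stop("planted signature genes exceed n_genes")
  stopifnot(dropout_rate >= 0, dropout_rate <= 1, libsize_sd >= 0)
  structure(list(n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
                 clones = clones, signatures = signatures,
                 dropout_rate = dropout_rate, libsize_sd = libsize_sd,
                 nuisance_coeff = nuisance_coeff, base_sd = base_sd,
                 seed = as.integer(seed)),
            class = "SimConfig")
}

#' Simulate a single-cell experiment with planted therapeutic structure
#'
#' Baseline expression is log-normal-like: gene means drawn once, cell
#' values normal around them (sd `base_sd`) on the log scale, floored at
#' zero. For each clone and signature, the signature's UP genes are shifted
#' by `+effect * base_sd` and its DN genes by `-effect * base_sd` in that
#' clone's cells. Entries are then zeroed with probability `dropout_rate`,
#' and every cell is scaled by a log-normal library-size factor whose log is
#' optionally also added to each gene (`nuisance_coeff`), producing the
#' score-nUMI correlation the regression step removes. Deterministic under
#' the config seed.
#'
#' @param cfg a [sim_config()].
#' @return list with `expression` ([ExpressionMatrix]), `collection`
#'   ([SignatureCollection] of the planted bidirectional signatures),
#'   `truth` (per-cell clone labels, named), and `covariates` (data.frame:
#'   cell_id, nUMI, nGene, clone).
#' @export
simulate_cells <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "SimConfig"))
  set.seed(cfg$seed)
  n <- cfg$n_cells; p <- cfg$n_genes
  gene_ids <- sprintf("g%04d", seq_len(p))
  cell_ids <- sprintf("cell%04d", seq_len(n))
  # clone assignment by fraction, deterministic sizes
  fr <- vapply(cfg$clones, `[[`, numeric(1), "fraction")
  sizes <- diff(round(cumsum(c(0, fr)) * n))
  clone <- rep(seq_along(fr), times = sizes)
  clone <- sample(clone)                       # shuffle cell order
  # planted disjoint gene blocks
  sigs <- list(); ptr <- 0L
  for (j in seq_along(cfg$signatures)) {
    s <- cfg$signatures[[j]]
    up <- gene_ids[ptr + seq_len(s$n_up)]; ptr <- ptr + s$n_up
    dn <- gene_ids[ptr + seq_len(s$n_dn)]; ptr <- ptr + s$n_dn
    sigs[[j]] <- GeneSignature(sprintf("sig%02d", j), up_genes = up,
                               dn_genes = dn, mode = "bidirectional",
                               collection_tag = "sensitivity")
  }
  collection <- SignatureCollection(sigs, name = "planted")
  mu <- stats::rnorm(p, mean = 2, sd = 0.5)
  X <- matrix(stats::rnorm(n * p, sd = cfg$base_sd), n, p)
  X <- sweep(X, 2, mu, `+`)
  for (j in seq_along(sigs)) {
    up_idx <- match(sigs[[j]]$up_genes, gene_ids)
    dn_idx <- match(sigs[[j]]$dn_genes, gene_ids)
    for (ci in seq_along(cfg$clones)) {
      e <- cfg$clones[[ci]]$effect[j] * cfg$base_sd
      if (e == 0) next
      rows <- clone == ci
      X[rows, up_idx] <- X[rows, up_idx] + e
      X[rows, dn_idx] <- X[rows, dn_idx] - e
    }
  }
  X <- pmax(X, 0)                              # log expression is non-negative
  if (cfg$dropout_rate > 0) {
    drop <- matrix(stats::runif(n * p) < cfg$dropout_rate, n, p)
    X[drop] <- 0
  }
  logL <- stats::rnorm(n, sd = cfg$libsize_sd)
  X <- X * exp(logL)
  if (cfg$nuisance_coeff != 0) X <- X + cfg$nuisance_coeff * logL
  dimnames(X) <- list(cell_ids, gene_ids)
  expr <- ExpressionMatrix(X)
  covars <- data.frame(cell_id = cell_ids,
                       nUMI = rowSums(X),
                       nGene = rowSums(X > 0),
                       clone = factor(sprintf("clone%d", clone)),
                       row.names = cell_ids)
  list(expression = expr, collection = collection,
       truth = stats::setNames(clone, cell_ids), covariates = covars)
}

#' Simulate a bulk pharmacogenomic table
#'
#' Generates cell-line expression profiles with a tissue-of-origin
#' confounder, per-(sample, drug) AUC responses, and planted resistance
#' genes whose expression rises linearly with AUC (slope `effect`), the
#' regime the sensitivity-signature builder is designed for. Tissue shifts
#' both the AUC (so the confounder is a genuine confounder) and a dedicated
#' block of offset genes.
#'
#' @param n_samples,n_genes,n_drugs dataset dimensions.
#' @param effect slope of planted resistance-gene expression on AUC.
#' @param n_planted planted resistance genes per drug (default 10).
#' @param n_offset genes shifted by tissue only (default 10).
#' @param tissue_offset expression offset separating tissues on the offset
#'   genes (default 0 = no tissue effect on expression).
#' @param n_tissues tissue levels (default 3).
#' @param seed integer random seed.
#' @return list with `table` (a [PharmacoTable]), `planted` (list per drug
#'   of resistance gene ids) and `offset_genes`.
#' @export
simulate_pharmaco <- function(n_samples = 50L, n_genes = 1000L, n_drugs = 2L,
                              effect = 5, n_planted = 10L, n_offset = 10L,
                              tissue_offset = 0, n_tissues = 3L, seed = 1L) {
  set.seed(seed)
  stopifnot(n_drugs * n_planted + n_offset <= n_genes)
  sample_ids <- sprintf("s%03d", seq_len(n_samples))
  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  tissue <- factor(sprintf("t%d", 1L + (seq_len(n_samples) - 1L) %% n_tissues))
  names(tissue) <- sample_ids
  # AUC depends on tissue so that tissue genuinely confounds
  tissue_auc <- seq(0, 0.3, length.out = n_tissues)
  X <- matrix(stats::rnorm(n_samples * n_genes, mean = 5), n_samples, n_genes,
              dimnames = list(sample_ids, gene_ids))
  resp <- list(); planted <- list()
  ptr <- 0L
  for (d in seq_len(n_drugs)) {
    drug <- sprintf("drug%02d", d)
    auc <- clamp(tissue_auc[as.integer(tissue)] +
                   stats::runif(n_samples, 0, 0.7), 0, 1)
    genes_d <- gene_ids[ptr + seq_len(n_planted)]; ptr <- ptr + n_planted
    X[, genes_d] <- X[, genes_d] + effect * auc
    planted[[drug]] <- genes_d
    resp[[d]] <- data.frame(sample = sample_ids, drug = drug, auc = auc,
                            stringsAsFactors = FALSE)
  }
  offset_genes <- gene_ids[ptr + seq_len(n_offset)]
  if (tissue_offset != 0) {
    shift <- tissue_offset * (as.integer(tissue) - 1L)
    X[, offset_genes] <- X[, offset_genes] + shift
  }
  tab <- PharmacoTable(ExpressionMatrix(X), do.call(rbind, resp),
                       confounder = tissue)
  list(table = tab, planted = planted, offset_genes = offset_genes)
}
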