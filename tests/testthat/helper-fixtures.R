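# Shared fixture builders. Everything is generated in code; no binary files.

random_expr <- function(n_cells, n_genes, seed = 1, zero_frac = 0) {
  set.seed(seed)
  m <- matrix(abs(rnorm(n_cells * n_genes, mean = 2)), n_cells, n_genes,
              dimnames = list(sprintf("c%03d", seq_len(n_cells)),
                              sprintf("g%03d", seq_len(n_genes))))
  if (zero_frac > 0) m[runif(length(m)) < zero_frac] <- 0
  ExpressionMatrix(m)
}

random_collection <- function(n_sigs, expr, genes_per_side = 5, seed = 1) {
  set.seed(seed)
  sigs <- lapply(seq_len(n_sigs), function(i) {
    g <- sample(gene_ids(expr), 2 * genes_per_side)
    GeneSignature(sprintf("sig%02d", i),
                  up_genes = g[seq_len(genes_per_side)],
                  dn_genes = g[-seq_len(genes_per_side)])
  })
  SignatureCollection(sigs, name = "random")
}

write_tmp_gmt <- function(lines) {
  path <- withr::local_tempfile(fileext = ".gmt",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# Independent straight-loop scorer used as the oracle for score_signatures().
# Deliberately naive: per-cell loops, quantile/median recomputed directly.
oracle_score <- function(expr, collection, winsor = c(1, 99)) {
  m <- unclass(expr)
  norm_dir <- function(genes) {
    present <- intersect(genes, colnames(m))
    if (!length(present)) return(NULL)
    v <- numeric(nrow(m))
    for (i in seq_len(nrow(m))) {
      s <- 0; nz <- 0
      for (g in present) {
        s <- s + m[i, g]
        if (m[i, g] > 0) nz <- nz + 1
      }
      v[i] <- (s / length(present)) * (nz / length(present))
    }
    q <- quantile(v, winsor / 100, names = FALSE)
    v <- pmin(pmax(v, q[1]), q[2])
    v - median(v)
  }
  nms <- signature_names(collection)
  scaled <- matrix(NaN, nrow(m), length(nms),
                   dimnames = list(rownames(m), nms))
  sp <- setNames(rep(NaN, length(nms)), nms)
  for (k in seq_along(nms)) {
    sig <- collection$signatures[[k]]
    u <- norm_dir(sig$up_genes)
    d <- norm_dir(sig$dn_genes)
    net <- if (is.null(d)) u else if (is.null(u)) -d else u - d
    if (is.null(net)) next
    lo <- min(net); hi <- max(net)
    scaled[, k] <- (net - lo) / (hi - lo)
    sp[k] <- min(max((0 - lo) / (hi - lo), 0), 1)
  }
  list(scaled = scaled, switch_points = sp)
}

# Brute-force per-(signature, group) statistics oracle.
oracle_stats <- function(scaled, residuals, switch_points, groups) {
  out <- list()
  for (g in sort(unique(as.character(groups)))) {
    idx <- which(as.character(groups) == g)
    for (j in seq_len(ncol(scaled))) {
      v <- scaled[idx, j]
      fin <- v[is.finite(v)]
      out[[length(out) + 1L]] <- data.frame(
        signature = colnames(scaled)[j], group = g,
        switch_point = unname(switch_points[j]),
        mean = mean(fin), median = median(fin), sd = sd(fin),
        variance = var(fin), min = min(fin), max = max(fin),
        prop_nan = sum(!is.finite(v)) / length(v),
        residuals_mean = if (is.null(residuals)) NA_real_
                         else mean(residuals[idx, j]))
    }
  }
  do.call(rbind, out)
}

# Brute-force masked-Euclidean KNN imputation oracle.
oracle_impute <- function(m, k) {
  out <- m
  n <- nrow(m)
  for (i in seq_len(n)) for (j in seq_len(ncol(m))) {
    if (is.finite(m[i, j])) next
    d <- rep(Inf, n)
    for (r in seq_len(n)) {
      if (r == i || !is.finite(m[r, j])) next
      shared <- is.finite(m[i, ]) & is.finite(m[r, ])
      d[r] <- sum((m[i, shared] - m[r, shared])^2)
    }
    nn <- order(d, seq_len(n))[seq_len(k)]
    out[i, j] <- mean(m[nn, j])
  }
  out
}

# Writes a small simulated dataset (expression TSV, GMT, metadata TSV) to
# `dir` for pipeline-level tests; returns the simulation object.
write_fixture_inputs <- function(dir, seed = 5) {
  cfg <- sim_config(n_cells = 80, n_genes = 600,
                    clones = list(list(fraction = 0.5, effect = c(3, 0)),
                                  list(fraction = 0.5, effect = c(0, 0))),
                    signatures = rep(list(list(n_up = 40, n_dn = 40)), 2),
                    seed = seed)
  sim <- simulate_cells(cfg)
  write_expression(sim$expression, file.path(dir, "expr.tsv"))
  write_gmt(sim$collection, file.path(dir, "sigs.gmt"))
  meta <- sim$covariates
  meta$condition <- ifelse(sim$truth == 1, "clone_a", "clone_b")
  write.table(meta, file.path(dir, "meta.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  sim
}
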