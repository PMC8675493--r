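#' Signature build configuration
#'
#' @param n_top genes per direction when cutting a signature from a ranking
#'   statistic (default 250, the collection-building convention).
#' @param min_samples minimum samples with a response value required for a
#'   continuous (AUC) design (default 10).
#' @return a list with class `SignatureBuildConfig`.
#' @export
signature_build_config <- function(n_top = 250L, min_samples = 10L) {
  n_top <- as.integer(n_top)
  min_samples <- as.integer(min_samples)
  stopifnot(n_top >= 1L, min_samples >= 1L)
  structure(list(n_top = n_top, min_samples = min_samples),
            class = "SignatureBuildConfig")
}

#' Assemble a pharmacogenomic table
#'
#' Bundles bulk cell-line expression with per-(sample, drug) responses and a
#' per-sample confounder (typically tissue / site of origin). Sensitivity
#' signatures are built from the AUC of the dose-response curve treated as a
#' continuous variable; perturbation signatures from a treated/control
#' contrast.
#'
#' @param expression an [ExpressionMatrix], samples x genes (bulk profiles).
#' @param response data.frame with columns `sample`, `drug`, and either
#'   `auc` (numeric) or `arm` (`"control"`/`"treated"`), or both.
#' @param confounder optional factor (or character) per sample, named by
#'   sample id, e.g. tumour origin.
#' @return a `PharmacoTable`.
#' @export
PharmacoTable <- function(expression, response, confounder = NULL) {
  stopifnot(inherits(expression, "ExpressionMatrix"),
            is.data.frame(response),
            all(c("sample", "drug") %in% names(response)))
  if (!any(c("auc", "arm") %in% names(response)))
    stop("response needs an 'auc' or 'arm' column")
  unknown <- setdiff(unique(response$sample), rownames(expression))
  if (length(unknown))
    stop(sprintf("response rows reference unknown samples: %s",
                 paste(utils::head(unknown, 5), collapse = ", ")))
  if ("auc" %in% names(response) &&
      any(!is.finite(response$auc) & !is.na(response$auc)))
    stop("AUC values must be finite (or NA for missing)")
  if (!is.null(confounder)) {
    if (is.null(names(confounder)))
      stop("confounder must be named by sample id")
    missing_conf <- setdiff(rownames(expression), names(confounder))
    if (length(missing_conf))
      stop(sprintf("confounder missing for samples: %s",
                   paste(utils::head(missing_conf, 5), collapse = ", ")))
    confounder <- factor(confounder[rownames(expression)])
    names(confounder) <- rownames(expression)
  }
  structure(list(expression = expression, response = response,
                 confounder = confounder),
            class = "PharmacoTable")
}

#' Per-gene differential-expression statistic for one drug
#'
#' Fits, gene by gene, an ordinary-least-squares model of expression on the
#' drug term — a treated indicator (`design = "contrast"`) or the AUC as a
#' continuous variable (`design = "continuous"`) — plus confounder dummy
#' variables, and returns the t-statistic of the drug term. The sign
#' convention is positive = higher expression in treated samples
#' (perturbation designs) or in high-AUC, i.e. resistant, samples
#' (sensitivity designs).
#'
#' @param table a [PharmacoTable].
#' @param drug drug name present in `table$response$drug`.
#' @param design `"contrast"` or `"continuous"`.
#' @param cfg a [signature_build_config()].
#' @return named numeric vector of t-statistics, one per gene. Genes with no
#'   variance get statistic 0.
#' @export
de_statistic <- function(table, drug, design = c("contrast", "continuous"),
                         cfg = signature_build_config()) {
  stopifnot(inherits(table, "PharmacoTable"))
  design <- match.arg(design)
  resp <- table$response[table$response$drug == drug, , drop = FALSE]
  if (!nrow(resp)) stop(sprintf("no response rows for drug '%s'", drug))

  if (design == "contrast") {
    if (!"arm" %in% names(resp)) stop("contrast design needs an 'arm' column")
    resp <- resp[resp$arm %in% c("control", "treated"), , drop = FALSE]
    if (min(table(factor(resp$arm, c("control", "treated")))) < 2L)
      stop("contrast design needs at least 2 samples per arm")
    x <- as.numeric(resp$arm == "treated")
  } else {
    if (!"auc" %in% names(resp)) stop("continuous design needs an 'auc' column")
    resp <- resp[is.finite(resp$auc), , drop = FALSE]
    if (nrow(resp) < cfg$min_samples)
      stop(sprintf("continuous design needs >= %d samples with AUC; got %d",
                   cfg$min_samples, nrow(resp)))
    x <- resp$auc
  }
  samples <- resp$sample
  conf <- NULL
  if (!is.null(table$confounder)) {
    conf <- droplevels(table$confounder[samples])
    if (design == "continuous") {
      singletons <- names(which(table(conf) == 1L))
      if (length(singletons)) {
        warning(sprintf("dropping confounder level(s) with a single sample: %s",
                        paste(singletons, collapse = ", ")))
        keep <- !(conf %in% singletons)
        samples <- samples[keep]; x <- x[keep]
        conf <- droplevels(conf[keep])
      }
    }
    if (nlevels(conf) < 2L) conf <- NULL
  }
  X <- if (is.null(conf)) cbind(`(Intercept)` = 1, drug = x)
       else stats::model.matrix(~ x + conf,
                                data = data.frame(x = x, conf = conf))
  qx <- qr(X)
  if (qx$rank < ncol(X))
    stop(sprintf("rank-deficient design: collinear column(s) %s",
                 paste(colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]],
                       collapse = ", ")))
  Y <- unclass(table$expression)[samples, , drop = FALSE]
  fit <- stats::lm.fit(X, Y)
  df <- nrow(X) - ncol(X)
  if (df < 1L) stop("not enough samples for the design degrees of freedom")
  rss <- colSums(fit$residuals^2)
  sigma2 <- rss / df
  xtx_inv <- chol2inv(chol(crossprod(X)))
  j <- 2L  # drug term follows the intercept in both designs
  beta <- fit$coefficients[j, ]
  se <- sqrt(xtx_inv[j, j] * sigma2)
  t_stat <- beta / se
  # genes with (numerically) no variance carry no direction: statistic 0
  y_var <- colSums(sweep(Y, 2, colMeans(Y))^2)
  t_stat[y_var / (1 + colMeans(Y)^2) < 1e-20] <- 0
  t_stat[is.na(t_stat)] <- 0
  names(t_stat) <- colnames(Y)
  t_stat
}

#' Cut a bidirectional signature from a gene-level statistic
#'
#' The `n_top` genes with the largest statistic become the UP set, the
#' `n_top` with the smallest become the DN set. Ties at the top cut prefer
#' the lexicographically smaller gene id; ties at the bottom cut prefer the
#' larger, so a fully tied vector still yields disjoint, deterministic sets
#' (with a warning).
#'
#' @param stats named numeric vector of per-gene statistics; non-finite
#'   entries are excluded from ranking.
#' @param name signature name.
#' @param cfg a [signature_build_config()].
#' @param collection_tag tag recorded on the signature.
#' @return a bidirectional [GeneSignature].
#' @export
make_signature <- function(stats, name, cfg = signature_build_config(),
                           collection_tag = "custom") {
  stopifnot(!is.null(names(stats)))
  stats <- stats[is.finite(stats)]
  n <- cfg$n_top
  if (length(stats) < 2L * n)
    stop(sprintf("need >= %d genes with finite statistics; got %d",
                 2L * n, length(stats)))
  if (length(unique(stats)) == 1L)
    warning(sprintf(
      "all statistics equal for '%s'; selecting lexicographic extremes", name))
  ids <- names(stats)
  up <- ids[order(-stats, ids)][seq_len(n)]
  dn <- ids[order(stats, -rank(ids))][seq_len(n)]
  overlap <- intersect(up, dn)
  if (length(overlap))
    stop(sprintf("ties too extensive: UP and DN cuts overlap for '%s'", name))
  GeneSignature(name, up_genes = up, dn_genes = dn, mode = "bidirectional",
                collection_tag = collection_tag)
}

#' Drug specificity score and decile background
#'
#' For each signature, the specificity score measures how similar its
#' induced expression pattern is across cell-type groups of a bulk reference
#' panel: 1 means the per-cell-type net enrichments (mean UP minus mean DN
#' expression) are identical, 0 the most discordant pattern observed in the
#' collection. The first and last decile by specificity form the reduced
#' drug background.
#'
#' @param collection a [SignatureCollection].
#' @param reference_profiles an [ExpressionMatrix], samples x genes.
#' @param cell_types factor (or character) per sample giving its cell-type
#'   group; at least 2 groups required.
#' @return a `DrugSpecificity`: list with `dss` (named numeric in \[0,1\]),
#'   `decile_low` and `decile_high` (character vectors of
#'   `ceiling(0.1 * n)` signature names each; boundary ties broken by name).
#' @export
drug_specificity <- function(collection, reference_profiles, cell_types) {
  stopifnot(inherits(collection, "SignatureCollection"),
            inherits(reference_profiles, "ExpressionMatrix"))
  cell_types <- factor(cell_types)
  if (length(cell_types) != nrow(reference_profiles))
    stop("cell_types must match reference profile rows")
  if (nlevels(cell_types) < 2L)
    stop("drug specificity needs at least 2 cell-type groups")
  expr <- unclass(reference_profiles)
  per_type_score <- function(sig) {
    up <- intersect(sig$up_genes, colnames(expr))
    dn <- intersect(sig$dn_genes, colnames(expr))
    net <- (if (length(up)) rowMeans(expr[, up, drop = FALSE]) else 0) -
           (if (length(dn)) rowMeans(expr[, dn, drop = FALSE]) else 0)
    tapply(net, cell_types, mean)
  }
  disc <- vapply(collection$signatures, function(sig) {
    s <- per_type_score(sig)
    mean(stats::dist(s))       # mean pairwise absolute difference
  }, numeric(1))
  dss <- if (max(disc) == 0) rep(1, length(disc)) else 1 - disc / max(disc)
  names(dss) <- signature_names(collection)
  n_dec <- ceiling(0.1 * length(dss))
  ord_low <- names(dss)[order(dss, names(dss))]
  ord_high <- names(dss)[order(-dss, names(dss))]
  structure(list(dss = dss,
                 decile_low = ord_low[seq_len(n_dec)],
                 decile_high = ord_high[seq_len(n_dec)]),
            class = "DrugSpecificity")
}

#' Select the decile drug background
#'
#' Returns the sub-collection of the lowest- and highest-specificity decile
#' signatures, in the collection's original order.
#'
#' @param spec a `DrugSpecificity` computed on `collection`.
#' @param collection the [SignatureCollection] to subset.
#' @return a [SignatureCollection] of the background signatures.
#' @export
select_background <- function(spec, collection) {
  stopifnot(inherits(spec, "DrugSpecificity"),
            inherits(collection, "SignatureCollection"))
  chosen <- union(spec$decile_low, spec$decile_high)
  missing_sigs <- setdiff(names(spec$dss), signature_names(collection))
  if (length(missing_sigs))
    stop(sprintf("specificity scores reference signatures not in collection: %s",
                 paste(utils::head(missing_sigs, 5), collapse = ", ")))
  keep <- signature_names(collection)[signature_names(collection) %in% chosen]
  collection[keep]
}
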