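#' K-nearest-neighbour imputation of a score matrix
#'
#' Replaces each missing (NaN) entry by the mean of that column over the k
#' nearest cells, where distance is the Euclidean distance over the
#' signature columns finite in both cells. Columns missing in every cell are
#' dropped with a warning.
#'
#' @param m cells x signatures numeric matrix, possibly with NaN.
#' @param k neighbours to average (default 10); must be < number of cells.
#' @return the completed matrix (minus any all-NaN columns).
#' @details Neighbours are the k cells with a finite value in the target
#'   column, nearest by masked Euclidean distance; distance ties are broken
#'   by cell order for determinism.
#' @export
knn_impute <- function(m, k = 10L) {
  stopifnot(is.matrix(m), is.numeric(m))
  k <- as.integer(k)
  if (k < 1L || k >= nrow(m))
    stop("k must be at least 1 and smaller than the number of cells")
  all_nan <- colSums(is.finite(m)) == 0L
  if (any(all_nan)) {
    warning(sprintf("dropping signature(s) missing in every cell: %s",
                    paste(colnames(m)[all_nan], collapse = ", ")))
    m <- m[, !all_nan, drop = FALSE]
  }
  if (any(rowSums(is.finite(m)) == 0L))
    stop("every cell needs at least one finite score")
  miss <- which(!is.finite(m), arr.ind = TRUE)
  if (!nrow(miss)) return(m)
  # squared Euclidean over mutually finite columns, via masked cross-products
  W <- is.finite(m) * 1
  X0 <- ifelse(is.finite(m), m, 0)
  sq <- X0^2
  D2 <- sq %*% t(W) + W %*% t(sq) - 2 * X0 %*% t(X0)
  D2 <- pmax(D2, 0)
  out <- m
  for (r in seq_len(nrow(miss))) {
    i <- miss[r, 1]; j <- miss[r, 2]
    cand <- which(is.finite(m[, j]))
    cand <- cand[cand != i]
    nn <- cand[order(D2[i, cand], cand)][seq_len(min(k, length(cand)))]
    out[i, j] <- mean(m[nn, j])
  }
  out
}

#' Regress nuisance covariates out of a score matrix
#'
#' Removes unwanted sources of variation (library size, detected genes,
#' cell-cycle scores, batch) from the scaled scores in two steps: missing
#' entries are first completed with [knn_impute()], then per-signature
#' residuals of the least-squares fit of the scores on an intercept plus the
#' chosen covariates (categorical covariates one-hot encoded, first level as
#' reference) are computed via the QR decomposition. Residuals are signed,
#' mean-zero per signature, and are stored alongside — never in place of —
#' the scaled scores and their switch points.
#'
#' @param scores a `ScoreMatrix` from [score_signatures()].
#' @param covars data.frame of per-cell covariates with a `cell_id` column
#'   (or cell ids as rownames) covering every scored cell.
#' @param which character vector of covariate column names to regress out.
#' @param k neighbours for the imputation step.
#' @return `scores` with `residuals` filled (cells x signatures).
#' @export
regress_out <- function(scores, covars, which, k = 10L) {
  stopifnot(inherits(scores, "ScoreMatrix"), is.data.frame(covars))
  if ("cell_id" %in% names(covars)) {
    rownames(covars) <- covars$cell_id
  }
  cells <- rownames(scores$scaled)
  missing_cells <- setdiff(cells, rownames(covars))
  if (length(missing_cells))
    stop(sprintf("covariates missing for cells: %s",
                 paste(utils::head(missing_cells, 5), collapse = ", ")))
  covars <- covars[cells, , drop = FALSE]
  unknown <- setdiff(which, names(covars))
  if (length(unknown))
    stop(sprintf("unknown covariate(s): %s", paste(unknown, collapse = ", ")))
  df <- covars[, which, drop = FALSE]
  for (nm in names(df)) {
    if (is.character(df[[nm]]) || is.logical(df[[nm]])) df[[nm]] <- factor(df[[nm]])
    if (is.numeric(df[[nm]]) && any(!is.finite(df[[nm]])))
      stop(sprintf("covariate '%s' has non-finite values", nm))
  }
  X <- stats::model.matrix(~ ., data = df)
  qx <- qr(X)
  if (qx$rank < ncol(X))
    stop(sprintf("rank-deficient design: collinear column(s) %s",
                 paste(colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]],
                       collapse = ", ")))
  Y <- scores$scaled
  if (any(!is.finite(Y))) Y <- knn_impute(Y, k = k)
  res <- qr.resid(qx, Y)
  dimnames(res) <- dimnames(Y)
  scores$residuals <- res
  scores$provenance$regressed <- which
  scores
}
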