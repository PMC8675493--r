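#' Per-group signature statistics
#'
#' For every (signature, cell group) pair, computes the nine summary
#' statistics used for drug prioritisation: switch point, mean, median,
#' standard deviation, variance, minimum, maximum, proportion of NaN and
#' residuals' mean. All statistics are on the scaled \[0,1\] score except
#' `residuals_mean`, which is on the signed residual scale (NA when no
#' regression has been run). NaN cells are excluded from the moments and
#' counted in `prop_nan`.
#'
#' @param scores a `ScoreMatrix`.
#' @param groups per-cell labels (factor/character/integer) aligned with the
#'   scored cells, or named by cell id.
#' @return a `RankTable` data.frame with one row per (signature, group).
#' @export
signature_stats <- function(scores, groups) {
  stopifnot(inherits(scores, "ScoreMatrix"))
  cells <- rownames(scores$scaled)
  if (!is.null(names(groups))) {
    missing_cells <- setdiff(cells, names(groups))
    if (length(missing_cells))
      stop(sprintf("groups missing for cells: %s",
                   paste(utils::head(missing_cells, 5), collapse = ", ")))
    groups <- groups[cells]
  } else if (length(groups) != length(cells)) {
    stop("groups must align with the scored cells")
  }
  if (!is.factor(groups)) groups <- factor(groups)
  if (any(table(groups) == 0L)) stop("empty group")
  out <- list()
  for (g in levels(groups)) {
    idx <- which(groups == g)
    sub <- scores$scaled[idx, , drop = FALSE]
    res <- if (!is.null(scores$residuals))
      scores$residuals[idx, , drop = FALSE] else NULL
    for (j in seq_len(ncol(sub))) {
      v <- sub[, j]
      fin <- v[is.finite(v)]
      out[[length(out) + 1L]] <- data.frame(
        signature = colnames(sub)[j], group = g,
        switch_point = unname(scores$switch_points[j]),
        mean = if (length(fin)) mean(fin) else NaN,
        median = if (length(fin)) stats::median(fin) else NaN,
        sd = if (length(fin) > 1L) stats::sd(fin) else NA_real_,
        variance = if (length(fin) > 1L) stats::var(fin) else NA_real_,
        min = if (length(fin)) min(fin) else NaN,
        max = if (length(fin)) max(fin) else NaN,
        prop_nan = mean(!is.finite(v)),
        residuals_mean = if (is.null(res)) NA_real_ else mean(res[, j]),
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, out)
  class(tab) <- c("RankTable", "data.frame")
  tab
}

#' 4-squares quadrant classification
#'
#' Classifies each signature for one cell group on the plane of residuals'
#' mean (x-axis) against switch point (y-axis). The bottom-right corner (low
#' switch point, high residual mean) holds the drugs the group is most
#' sensitive to; the top-left corner (high switch point, low residual mean)
#' those it is least sensitive to. The centre band (intermediate switch
#' point) holds drugs the group is differentially sensitive or insensitive
#' to relative to the other groups; everything else is unclassified.
#'
#' @param table a `RankTable` from [signature_stats()].
#' @param group group label to classify.
#' @param sp_cuts low/high switch-point cuts, default `c(0.1, 0.9)`.
#' @param res_quantile residual-mean quantile defining "extreme" (default
#'   0.9, i.e. top/bottom decile of the group's residual means).
#' @return the `RankTable` rows for `group`, with a `quadrant` column.
#' @export
four_squares <- function(table, group, sp_cuts = c(0.1, 0.9),
                         res_quantile = 0.9) {
  stopifnot(inherits(table, "data.frame"), length(sp_cuts) == 2L,
            sp_cuts[1] < sp_cuts[2])
  sub <- table[table$group == group, , drop = FALSE]
  if (!nrow(sub)) stop(sprintf("no rows for group '%s'", group))
  if (all(is.na(sub$residuals_mean)))
    stop("residuals' means are missing; run regress_out() before four_squares()")
  rm_ <- sub$residuals_mean
  q_hi <- stats::quantile(rm_, res_quantile, na.rm = TRUE, names = FALSE)
  q_lo <- stats::quantile(rm_, 1 - res_quantile, na.rm = TRUE, names = FALSE)
  sp <- sub$switch_point
  quadrant <- rep("unclassified", nrow(sub))
  centre <- sp > sp_cuts[1] & sp < sp_cuts[2]
  quadrant[sp <= sp_cuts[1] & rm_ >= q_hi] <- "bottom_right_most_sensitive"
  quadrant[sp >= sp_cuts[2] & rm_ <= q_lo] <- "top_left_least_sensitive"
  quadrant[centre & rm_ >= q_hi] <- "differentially_sensitive"
  quadrant[centre & rm_ <= q_lo] <- "differentially_insensitive"
  sub$quadrant <- quadrant
  sub
}

#' Rank signatures by differential sensitivity between two conditions
#'
#' For each signature, the effect is the difference of group means
#' (condition A minus B) of the residuals — falling back to scaled scores,
#' with a message, when no regression has been run. Significance is assessed
#' by a two-sided label-permutation test with Benjamini-Hochberg adjustment
#' across signatures; the table is sorted by decreasing absolute effect.
#'
#' @param scores a `ScoreMatrix`.
#' @param condition per-cell binary labels (factor/character/logical),
#'   aligned with cells or named by cell id; the first factor level is "B".
#' @param n_perm permutations (default 1000; a warning below 100).
#' @param seed integer random seed.
#' @return data.frame: signature, effect, p_value, fdr, rank.
#' @export
rank_differential <- function(scores, condition, n_perm = 1000L, seed = 1L) {
  stopifnot(inherits(scores, "ScoreMatrix"))
  cells <- rownames(scores$scaled)
  if (!is.null(names(condition))) condition <- condition[cells]
  if (length(condition) != length(cells))
    stop("condition must align with the scored cells")
  condition <- factor(condition)
  if (nlevels(condition) != 2L) stop("condition must have exactly 2 levels")
  if (any(table(condition) == 0L)) stop("both conditions must be non-empty")
  if (n_perm < 100L) warning("n_perm < 100 gives unstable p-values")
  M <- if (!is.null(scores$residuals)) scores$residuals else {
    message("no residuals present; ranking on scaled scores")
    m <- scores$scaled
    if (any(!is.finite(m))) m <- knn_impute(m)
    m
  }
  grp <- condition == levels(condition)[2]
  nA <- sum(grp); nB <- sum(!grp)
  w <- ifelse(grp, 1 / nA, -1 / nB)
  obs <- as.vector(crossprod(M, w))
  set.seed(derive_seed(seed, 3L))
  exceed <- numeric(ncol(M))
  for (b in seq_len(n_perm)) {
    wp <- sample(w)
    perm <- as.vector(crossprod(M, wp))
    exceed <- exceed + (abs(perm) >= abs(obs) - 1e-12)
  }
  p <- (1 + exceed) / (n_perm + 1)
  fdr <- stats::p.adjust(p, method = "BH")
  out <- data.frame(signature = colnames(M), effect = obs, p_value = p,
                    fdr = fdr, stringsAsFactors = FALSE)
  out <- out[order(-abs(out$effect), out$signature), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Drug-drug correlation modules
#'
#' Pearson correlation of scaled scores across cells, grouped into modules
#' of co-varying signatures: average-linkage hierarchical clustering on
#' distance 1 - |r|, cut at 1 - `min_abs_r`. Constant signatures have no
#' defined correlation and are excluded with a warning.
#'
#' @param scores a `ScoreMatrix`.
#' @param min_abs_r absolute-correlation threshold (default 0.7).
#' @return list with `correlation` (signature x signature matrix) and
#'   `modules` (named integer vector of module ids).
#' @export
correlation_modules <- function(scores, min_abs_r = 0.7) {
  stopifnot(inherits(scores, "ScoreMatrix"))
  M <- scores$scaled
  if (ncol(M) < 2L) stop("need at least 2 signatures")
  sds <- apply(M, 2, stats::sd, na.rm = TRUE)
  const <- !is.finite(sds) | sds == 0
  if (any(const)) {
    warning(sprintf("excluding constant signature(s): %s",
                    paste(colnames(M)[const], collapse = ", ")))
    M <- M[, !const, drop = FALSE]
  }
  if (ncol(M) < 2L) stop("fewer than 2 non-constant signatures remain")
  R <- stats::cor(M, use = "pairwise.complete.obs")
  d <- stats::as.dist(1 - abs(R))
  hc <- stats::hclust(d, method = "average")
  modules <- stats::cutree(hc, h = 1 - min_abs_r)
  list(correlation = R, modules = modules)
}
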