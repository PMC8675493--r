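#' Raw per-cell gene-set score
#'
#' For each cell, the sum of expression over the signature genes present in
#' the matrix, divided by the number of present genes. If no signature gene
#' is present every cell gets `NaN` (with a warning).
#'
#' @param expr an [ExpressionMatrix].
#' @param genes character vector of gene identifiers.
#' @return list with `score` (named per-cell numeric) and `n_present`.
#' @export
raw_score <- function(expr, genes) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  present <- intersect(genes, colnames(expr))
  if (!length(present)) {
    warning("no signature gene present in the expression matrix")
    return(list(score = stats::setNames(rep(NaN, nrow(expr)), rownames(expr)),
                n_present = 0L))
  }
  sc <- rowSums(unclass(expr)[, present, drop = FALSE]) / length(present)
  list(score = sc, n_present = length(present))
}

#' Normalise raw gene-set scores
#'
#' Turns raw per-cell means into signed, comparable scores in three steps,
#' each individually toggleable:
#' \enumerate{
#'   \item zero-penalty: multiply each cell's raw score by its detection
#'     fraction (share of present signature genes with expression > 0), so
#'     cells expressing few signature genes are pulled towards zero;
#'   \item winsorisation across cells at the given percentiles, damping
#'     outlier cells;
#'   \item median centring, so positive values mean above-typical gene-set
#'     activity and the zero crossing is meaningful for the switch point.
#' }
#'
#' @param raw result of [raw_score()] on the same inputs (the list, or its
#'   `score` vector).
#' @param expr,genes the inputs given to [raw_score()].
#' @param winsor percentile limits, default `c(1, 99)`; `NULL` disables.
#' @param penalise_zeros,centre logicals toggling steps 1 and 3.
#' @return named per-cell numeric vector of signed normalised scores.
#' @export
normalise_scores <- function(raw, expr, genes, winsor = c(1, 99),
                             penalise_zeros = TRUE, centre = TRUE) {
  if (is.list(raw)) raw <- raw$score
  stopifnot(inherits(expr, "ExpressionMatrix"), length(raw) == nrow(expr))
  if (all(!is.finite(raw))) return(raw)
  present <- intersect(genes, colnames(expr))
  x <- raw
  if (penalise_zeros && length(present)) {
    f <- rowSums(unclass(expr)[, present, drop = FALSE] > 0) / length(present)
    x <- x * f
  }
  if (!is.null(winsor)) x <- winsorise(x, winsor)
  if (centre) x <- x - stats::median(x[is.finite(x)])
  x
}

#' Combine directional scores and rescale to \[0,1\]
#'
#' The net score of a bidirectional signature is UP minus DN normalised
#' score; unidirectional signatures use the single direction (negated for
#' DN-only, so larger always means more of the signature's phenotype). The
#' net scores are min-max rescaled to \[0,1\] and the switch point is where
#' zero net score lands on that scale: cells above the switch point are in
#' the up-regulated state. A population whose cells all have positive net
#' score has switch point 0 (uniformly sensitive, for sensitivity
#' signatures); all-negative gives 1 (uniformly resistant); intermediate
#' values flag a heterogeneous response.
#'
#' @param up_norm,dn_norm normalised per-cell scores from
#'   [normalise_scores()]; either may be `NULL` for unidirectional
#'   signatures.
#' @return list with `scaled` (per-cell in \[0,1\], NaN preserved),
#'   `switch_point`, and `net` (the signed pre-rescale scores).
#' @export
combine_and_rescale <- function(up_norm = NULL, dn_norm = NULL) {
  if (is.null(up_norm) && is.null(dn_norm))
    stop("at least one direction is required")
  net <- if (is.null(dn_norm)) up_norm
         else if (is.null(up_norm)) -dn_norm
         else up_norm - dn_norm
  fin <- is.finite(net)
  if (!any(fin))
    return(list(scaled = net, switch_point = NaN, net = net))
  lo <- min(net[fin]); hi <- max(net[fin])
  if (hi == lo) {
    warning("constant net score; scaled scores and switch point set to 0.5")
    scaled <- net
    scaled[fin] <- 0.5
    return(list(scaled = scaled, switch_point = 0.5, net = net))
  }
  scaled <- (net - lo) / (hi - lo)
  sp <- clamp((0 - lo) / (hi - lo), 0, 1)
  list(scaled = scaled, switch_point = sp, net = net)
}

#' Score every cell against a signature collection
#'
#' The central scoring routine: for each signature, raw per-cell gene-set
#' means ([raw_score()]) are normalised per direction ([normalise_scores()])
#' and combined and rescaled to \[0,1\] with a per-signature switch point
#' ([combine_and_rescale()]). Expression is assumed preprocessed
#' (quality-filtered, normalised, log scale) by the caller.
#'
#' @param expr an [ExpressionMatrix].
#' @param collection a non-empty [SignatureCollection].
#' @param winsor percentile limits for [normalise_scores()].
#' @param coverage_floor signatures whose gene coverage (present / total
#'   genes) falls below this fraction are still scored but flagged
#'   (default 0.1).
#' @param penalise_zeros,centre normalisation toggles, see
#'   [normalise_scores()].
#' @return a `ScoreMatrix`: list with `scaled` and `normalised` (cells x
#'   signatures matrices; `normalised` holds the signed net scores),
#'   `switch_points` (named numeric), `residuals` (`NULL` until
#'   [regress_out()]), `sig_stats` (per-signature data.frame: switch point,
#'   genes present, coverage, low-coverage flag) and `provenance`.
#' @export
score_signatures <- function(expr, collection, winsor = c(1, 99),
                             coverage_floor = 0.1, penalise_zeros = TRUE,
                             centre = TRUE) {
  stopifnot(inherits(expr, "ExpressionMatrix"),
            inherits(collection, "SignatureCollection"))
  if (!length(collection)) stop("empty signature collection")
  nms <- signature_names(collection)
  n_cells <- nrow(expr)
  scaled <- normalised <- matrix(
    NaN, n_cells, length(nms), dimnames = list(rownames(expr), nms))
  sp <- stats::setNames(rep(NaN, length(nms)), nms)
  n_genes <- n_present <- integer(length(nms))
  for (i in seq_along(nms)) {
    sig <- collection$signatures[[i]]
    up_norm <- dn_norm <- NULL
    n_pres <- 0L
    if (length(sig$up_genes)) {
      r <- raw_score(expr, sig$up_genes)
      n_pres <- n_pres + r$n_present
      up_norm <- if (r$n_present) normalise_scores(
        r, expr, sig$up_genes, winsor, penalise_zeros, centre) else NULL
    }
    if (length(sig$dn_genes)) {
      r <- raw_score(expr, sig$dn_genes)
      n_pres <- n_pres + r$n_present
      dn_norm <- if (r$n_present) normalise_scores(
        r, expr, sig$dn_genes, winsor, penalise_zeros, centre) else NULL
    }
    n_genes[i] <- length(sig$up_genes) + length(sig$dn_genes)
    n_present[i] <- n_pres
    if (is.null(up_norm) && is.null(dn_norm)) next  # all-NaN column
    cr <- combine_and_rescale(up_norm, dn_norm)
    scaled[, i] <- cr$scaled
    normalised[, i] <- cr$net
    sp[i] <- cr$switch_point
  }
  coverage <- ifelse(n_genes > 0, n_present / n_genes, 0)
  low <- coverage < coverage_floor
  if (any(low))
    warning(sprintf("low gene coverage (< %g%%) for: %s", 100 * coverage_floor,
                    paste(nms[low], collapse = ", ")))
  sig_stats <- data.frame(
    signature = nms, switch_point = unname(sp), n_genes = n_genes,
    n_present = n_present, coverage = coverage, low_coverage = low,
    row.names = NULL)
  structure(list(
    scaled = scaled, normalised = normalised, switch_points = sp,
    residuals = NULL, sig_stats = sig_stats,
    provenance = list(collection = collection$name, winsor = winsor,
                      coverage_floor = coverage_floor,
                      penalise_zeros = penalise_zeros, centre = centre)),
    class = "ScoreMatrix")
}

#' Write a score matrix to TSV files
#'
#' @param scores a `ScoreMatrix`.
#' @param prefix path prefix; writes `<prefix>_scaled.tsv`,
#'   `<prefix>_signature_stats.tsv` and, when present,
#'   `<prefix>_residuals.tsv`.
#' @return invisibly, the paths written.
#' @export
write_scores <- function(scores, prefix) {
  stopifnot(inherits(scores, "ScoreMatrix"))
  write_mat <- function(m, path) {
    df <- data.frame(cell_id = rownames(m), as.data.frame(m),
                     check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  paths <- c(write_mat(scores$scaled, paste0(prefix, "_scaled.tsv")))
  stats_path <- paste0(prefix, "_signature_stats.tsv")
  utils::write.table(scores$sig_stats, stats_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(paths, stats_path)
  if (!is.null(scores$residuals))
    paths <- c(paths, write_mat(scores$residuals,
                                paste0(prefix, "_residuals.tsv")))
  invisible(paths)
}
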