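#' Construct an expression matrix
#'
#' A validated cells x genes numeric matrix of normalised (log-scale)
#' expression. Rows are cells, columns are genes; both must carry unique
#' identifiers. Values may be negative (scaled data is allowed) but must be
#' finite.
#'
#' @param values numeric matrix, cells in rows and genes in columns (or the
#'   transpose if `transposed = TRUE`).
#' @param cell_ids,gene_ids character vectors of unique identifiers. Default
#'   to the dimnames of `values`.
#' @param transposed logical; set `TRUE` when `values` is genes x cells.
#' @return an `ExpressionMatrix`: a numeric matrix with cell ids as rownames
#'   and gene ids as colnames.
#' @export
ExpressionMatrix <- function(values, cell_ids = rownames(values),
                             gene_ids = colnames(values),
                             transposed = FALSE) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (transposed) {
    values <- t(values)
    if (is.null(cell_ids)) cell_ids <- rownames(values)
    if (is.null(gene_ids)) gene_ids <- colnames(values)
  }
  if (is.null(cell_ids) || is.null(gene_ids))
    stop("cell and gene identifiers are required")
  cell_ids <- as.character(cell_ids)
  gene_ids <- as.character(gene_ids)
  if (length(cell_ids) != nrow(values) || length(gene_ids) != ncol(values))
    stop("identifier lengths do not match matrix dimensions")
  .check_unique(cell_ids, "cell ids")
  .check_unique(gene_ids, "gene ids")
  if (any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite expression value at cell '%s', gene '%s'",
                 cell_ids[bad[1]], gene_ids[bad[2]]))
  }
  dimnames(values) <- list(cell_ids, gene_ids)
  class(values) <- c("ExpressionMatrix", "matrix", "array")
  values
}

.check_unique <- function(x, what) {
  d <- unique(x[duplicated(x)])
  if (length(d))
    stop(sprintf("duplicate %s: %s", what,
                 paste(utils::head(d, 5), collapse = ", ")))
  invisible(TRUE)
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d cells x %d genes\n", nrow(x), ncol(x)))
  invisible(x)
}

#' Cell and gene identifiers
#'
#' @param x an `ExpressionMatrix`.
#' @return character vector of identifiers.
#' @export
cell_ids <- function(x) rownames(x)

#' @rdname cell_ids
#' @export
gene_ids <- function(x) colnames(x)

#' Construct a gene signature
#'
#' A named pair of UP and DN gene sets. Bidirectional signatures carry both
#' sets (the typical drug-signature case: the N most up- and down-regulated
#' genes of a differential-expression contrast); unidirectional signatures
#' carry only one.
#'
#' @param name signature name.
#' @param up_genes,dn_genes character vectors of gene identifiers; duplicates
#'   are removed with a warning.
#' @param mode `"bidirectional"`, `"up_only"` or `"dn_only"`. Inferred from
#'   which sets are non-empty when missing.
#' @param collection_tag provenance tag: `"perturbation"`, `"sensitivity"`,
#'   `"functional"` or `"custom"`.
#' @return a `GeneSignature` object.
#' @export
GeneSignature <- function(name, up_genes = character(), dn_genes = character(),
                          mode = NULL, collection_tag = "custom") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  up_genes <- as.character(up_genes)
  dn_genes <- as.character(dn_genes)
  if (anyDuplicated(up_genes)) {
    warning(sprintf("duplicate genes in UP set of '%s' removed", name))
    up_genes <- unique(up_genes)
  }
  if (anyDuplicated(dn_genes)) {
    warning(sprintf("duplicate genes in DN set of '%s' removed", name))
    dn_genes <- unique(dn_genes)
  }
  if (is.null(mode)) {
    mode <- if (length(up_genes) && length(dn_genes)) "bidirectional"
            else if (length(up_genes)) "up_only" else "dn_only"
  }
  mode <- match.arg(mode, c("bidirectional", "up_only", "dn_only"))
  collection_tag <- match.arg(collection_tag,
                              c("perturbation", "sensitivity", "functional",
                                "custom"))
  if (mode == "bidirectional" && (!length(up_genes) || !length(dn_genes)))
    stop(sprintf("bidirectional signature '%s' needs both UP and DN genes",
                 name))
  if (mode == "up_only" && length(dn_genes))
    stop(sprintf("up_only signature '%s' must have an empty DN set", name))
  if (mode == "dn_only" && length(up_genes))
    stop(sprintf("dn_only signature '%s' must have an empty UP set", name))
  if (length(intersect(up_genes, dn_genes)))
    stop(sprintf("signature '%s': UP and DN sets overlap (%s)", name,
                 paste(utils::head(intersect(up_genes, dn_genes), 5),
                       collapse = ", ")))
  structure(list(name = name, up_genes = up_genes, dn_genes = dn_genes,
                 mode = mode, collection_tag = collection_tag),
            class = "GeneSignature")
}

#' @export
print.GeneSignature <- function(x, ...) {
  cat(sprintf("GeneSignature '%s' (%s, %s): %d UP / %d DN genes\n",
              x$name, x$mode, x$collection_tag,
              length(x$up_genes), length(x$dn_genes)))
  invisible(x)
}

#' Construct a signature collection
#'
#' An ordered list of [GeneSignature] objects with unique names.
#'
#' @param signatures list of `GeneSignature` objects.
#' @param name collection name.
#' @return a `SignatureCollection`.
#' @export
SignatureCollection <- function(signatures = list(), name = "collection") {
  stopifnot(is.list(signatures))
  for (s in signatures)
    if (!inherits(s, "GeneSignature"))
      stop("all elements must be GeneSignature objects")
  nms <- vapply(signatures, `[[`, character(1), "name")
  .check_unique(nms, "signature names")
  names(signatures) <- nms
  structure(list(signatures = signatures, name = name),
            class = "SignatureCollection")
}

#' @export
print.SignatureCollection <- function(x, ...) {
  cat(sprintf("SignatureCollection '%s': %d signatures\n",
              x$name, length(x$signatures)))
  invisible(x)
}

#' @export
length.SignatureCollection <- function(x) length(x$signatures)

#' Signature names of a collection
#' @param x a `SignatureCollection`.
#' @return character vector.
#' @export
signature_names <- function(x) names(x$signatures)

#' Subset a signature collection by name
#' @param x a `SignatureCollection`.
#' @param i signature names or indices.
#' @param ... unused.
#' @return a `SignatureCollection` with the selected signatures, order kept.
#' @export
`[.SignatureCollection` <- function(x, i, ...) {
  if (is.character(i)) {
    missing_sigs <- setdiff(i, names(x$signatures))
    if (length(missing_sigs))
      stop(sprintf("signatures not in collection: %s",
                   paste(utils::head(missing_sigs, 5), collapse = ", ")))
  }
  SignatureCollection(x$signatures[i], name = x$name)
}

#' @export
print.ScoreMatrix <- function(x, ...) {
  cat(sprintf("ScoreMatrix: %d cells x %d signatures (collection '%s')\n",
              nrow(x$scaled), ncol(x$scaled), x$provenance$collection))
  cat(sprintf("  switch points: %s\n",
              paste(sprintf("%.2f", utils::head(x$switch_points, 6)),
                    collapse = ", ")))
  if (!is.null(x$residuals)) cat("  residuals: present\n")
  invisible(x)
}

#' @export
print.TherapeuticClusters <- function(x, ...) {
  tab <- table(x$labels)
  cat(sprintf("TherapeuticClusters: %d cells in %d clusters (%s)\n",
              length(x$labels), length(tab),
              paste(sprintf("TC%s: %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}
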