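#' Read an expression matrix from disk
#'
#' Reads either a dense TSV (identifiers in the first column and header row)
#' or a MatrixMarket coordinate triplet with sidecar gene/cell name files.
#' The result is always oriented cells x genes; set `transposed = TRUE` when
#' the file stores genes in rows (the common convention for gene x barcode
#' matrices).
#'
#' @param path path to the TSV or `.mtx` file.
#' @param format `"tsv"` or `"mtx_triplet"`.
#' @param transposed logical; `TRUE` when the stored matrix is genes x cells.
#' @param genes_file,cells_file sidecar one-column files naming the rows and
#'   columns of the MatrixMarket file *as stored* (before any transposition).
#'   Default to `genes.txt` / `barcodes.txt` next to `path`.
#' @return an [ExpressionMatrix].
#' @details No filtering is applied: all-zero genes or cells are retained.
#'   Non-numeric entries (including `NA`) are an error reporting the
#'   offending row and column.
#' @export
read_expression <- function(path, format = c("tsv", "mtx_triplet"),
                            transposed = FALSE,
                            genes_file = file.path(dirname(path), "genes.txt"),
                            cells_file = file.path(dirname(path),
                                                   "barcodes.txt")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (format == "tsv") {
    tab <- utils::read.table(path, sep = "\t", header = TRUE,
                             row.names = NULL, check.names = FALSE,
                             colClasses = "character", quote = "")
    row_ids <- tab[[1]]
    body <- as.matrix(tab[, -1, drop = FALSE])
    num <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
    if (anyNA(num)) {
      bad <- which(is.na(num), arr.ind = TRUE)[1, ]
      stop(sprintf(
        "non-numeric entry '%s' at row '%s', column '%s'",
        body[bad[1], bad[2]], row_ids[bad[1]], colnames(body)[bad[2]]))
    }
    dimnames(num) <- list(row_ids, colnames(body))
    ExpressionMatrix(num, transposed = transposed)
  } else {
    if (!file.exists(genes_file) || !file.exists(cells_file))
      stop("mtx_triplet format requires companion gene and cell name files")
    m <- as.matrix(Matrix::readMM(path))
    g <- readLines(genes_file)
    b <- readLines(cells_file)
    if (nrow(m) != length(g) || ncol(m) != length(b))
      stop(sprintf(
        "matrix is %d x %d but %d gene and %d cell names were supplied",
        nrow(m), ncol(m), length(g), length(b)))
    # MatrixMarket triplets conventionally store genes x cells
    dimnames(m) <- list(g, b)
    ExpressionMatrix(m, transposed = !transposed)
  }
}

#' Write an expression matrix as TSV
#'
#' @param expr an [ExpressionMatrix].
#' @param path output path; cells in rows, genes in columns, first column
#'   `cell_id`.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(cell_id = rownames(expr), as.data.frame(unclass(expr)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT file into a signature collection
#'
#' Standard GMT: one gene set per line, tab-separated fields
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. Gene sets whose names
#' differ only by the UP/DN suffix pair are merged into one bidirectional
#' [GeneSignature]; unpaired sets become `up_only` (or `dn_only` when they
#' carry the DN suffix).
#'
#' @param path GMT file path.
#' @param pairing_suffixes length-2 character vector, default
#'   `c("_UP", "_DN")`.
#' @param collection_tag tag recorded on each signature.
#' @param uppercase logical; fold gene identifiers to upper case (default
#'   off — matching is exact and case-sensitive).
#' @return a [SignatureCollection].
#' @export
read_gmt <- function(path, pairing_suffixes = c("_UP", "_DN"),
                     collection_tag = "custom", uppercase = FALSE) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  stopifnot(length(pairing_suffixes) == 2L)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop(sprintf("GMT line %d has %d fields; need name, description and at least one gene",
                   i, length(f)))
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (uppercase) genes <- toupper(genes)
    if (anyDuplicated(genes)) {
      warning(sprintf("GMT set '%s': duplicate genes removed", f[1]))
      genes <- unique(genes)
    }
    if (f[1] %in% names(sets))
      stop(sprintf("duplicate gene-set name '%s' in GMT", f[1]))
    sets[[f[1]]] <- genes
  }
  up_sfx <- pairing_suffixes[1]
  dn_sfx <- pairing_suffixes[2]
  strip <- function(nm, sfx) substr(nm, 1L, nchar(nm) - nchar(sfx))
  has_sfx <- function(nm, sfx) endsWith(nm, sfx) & nchar(nm) > nchar(sfx)
  nms <- names(sets)
  base <- nms
  base[has_sfx(nms, up_sfx)] <- strip(nms[has_sfx(nms, up_sfx)], up_sfx)
  base[has_sfx(nms, dn_sfx)] <- strip(nms[has_sfx(nms, dn_sfx)], dn_sfx)
  sigs <- list()
  for (b in unique(base)) {
    members <- nms[base == b]
    up <- members[has_sfx(members, up_sfx)]
    dn <- members[has_sfx(members, dn_sfx)]
    plain <- setdiff(members, c(up, dn))
    if (length(up) > 1L || length(dn) > 1L || length(plain) > 1L ||
        (length(plain) && (length(up) || length(dn))))
      stop(sprintf("gene-set names collide after UP/DN pairing: %s",
                   paste(members, collapse = ", ")))
    sig <- if (length(up) && length(dn)) {
      GeneSignature(b, up_genes = sets[[up]], dn_genes = sets[[dn]],
                    mode = "bidirectional", collection_tag = collection_tag)
    } else if (length(dn)) {
      GeneSignature(b, dn_genes = sets[[dn]], mode = "dn_only",
                    collection_tag = collection_tag)
    } else {
      nm <- if (length(up)) up else plain
      GeneSignature(b, up_genes = sets[[nm]], mode = "up_only",
                    collection_tag = collection_tag)
    }
    sigs[[b]] <- sig
  }
  SignatureCollection(sigs, name = sub("\\.gmt$", "", basename(path)))
}

#' Write a signature collection as GMT
#'
#' Bidirectional signatures are written as two lines (`<name>_UP`,
#' `<name>_DN` by default); unidirectional signatures as one line carrying
#' the matching suffix. `read_gmt(write_gmt(x))` reproduces `x` up to gene
#' order.
#'
#' @param collection a [SignatureCollection].
#' @param path output path.
#' @param pairing_suffixes as in [read_gmt()].
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path, pairing_suffixes = c("_UP", "_DN")) {
  stopifnot(inherits(collection, "SignatureCollection"))
  lines <- character()
  for (s in collection$signatures) {
    if (length(s$up_genes))
      lines <- c(lines, paste(c(paste0(s$name, pairing_suffixes[1]), "na",
                                s$up_genes), collapse = "\t"))
    if (length(s$dn_genes))
      lines <- c(lines, paste(c(paste0(s$name, pairing_suffixes[2]), "na",
                                s$dn_genes), collapse = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Cut top-N signatures from a ranked gene x signature matrix
#'
#' Reads a TSV of per-gene ranking statistics (genes in rows, one column per
#' signature; larger values mean more upregulated) and cuts the top and
#' bottom `n_top` genes of every column into a bidirectional signature.
#'
#' @param path TSV path: first column gene ids, remaining columns numeric
#'   statistics; `NA` statistics exclude the gene from that column's ranking.
#' @param n_top genes per direction.
#' @param collection_tag tag recorded on each signature.
#' @return a [SignatureCollection].
#' @details Ties at the top cut prefer the lexicographically smaller gene
#'   id; ties at the bottom cut prefer the larger id, so a fully tied column
#'   still yields disjoint UP/DN sets.
#' @export
read_ranked_matrix <- function(path, n_top, collection_tag = "custom") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  tab <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  genes <- as.character(tab[[1]])
  .check_unique(genes, "gene ids")
  stats_mat <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(stats_mat)) stop("ranking statistics must be numeric")
  rownames(stats_mat) <- genes
  sigs <- lapply(colnames(stats_mat), function(sig) {
    s <- stats_mat[, sig]
    make_signature(s, name = sig,
                   cfg = signature_build_config(n_top = n_top),
                   collection_tag = collection_tag)
  })
  SignatureCollection(sigs, name = sub("\\.[^.]+$", "", basename(path)))
}
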