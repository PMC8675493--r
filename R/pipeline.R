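#' Assemble a pipeline run configuration
#'
#' @param expr path to the expression matrix (TSV, or `.mtx` for a
#'   MatrixMarket triplet).
#' @param gmt path to the signature GMT file.
#' @param out_dir output directory (created if absent).
#' @param meta optional per-cell metadata TSV with a `cell_id` column.
#' @param covariates character vector of metadata columns to regress out
#'   (empty = regression disabled).
#' @param condition optional metadata column with two levels for the
#'   differential ranking stage.
#' @param transposed logical; expression file stores genes x cells.
#' @param winsor,n_pcs,knn_k,resolution,method,sp_cuts,res_quantile,n_perm
#'   stage parameters, see the stage functions.
#' @param seed single integer seed governing every random stage.
#' @return a `RunConfig` list.
#' @export
run_config <- function(expr, gmt, out_dir, meta = NULL,
                       covariates = character(), condition = NULL,
                       transposed = FALSE, winsor = c(1, 99), n_pcs = 20L,
                       knn_k = 10L, resolution = 0.4,
                       method = "graph_community", sp_cuts = c(0.1, 0.9),
                       res_quantile = 0.9, n_perm = 1000L, seed = 1L) {
  structure(list(expr = expr, gmt = gmt, out_dir = out_dir, meta = meta,
                 covariates = covariates, condition = condition,
                 transposed = transposed, winsor = winsor, n_pcs = n_pcs,
                 knn_k = knn_k, resolution = resolution, method = method,
                 sp_cuts = sp_cuts, res_quantile = res_quantile,
                 n_perm = n_perm, seed = as.integer(seed)),
            class = "RunConfig")
}

#' Load a pipeline configuration from YAML
#'
#' Unknown keys are rejected so typos fail loudly rather than silently
#' falling back to defaults.
#'
#' @param path YAML file whose keys are [run_config()] arguments.
#' @return a `RunConfig`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config not found: %s", path))
  y <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown))
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  do.call(run_config, y)
}

#' Run the full scoring pipeline
#'
#' score -> (optional) regress -> cluster -> rank, writing a deterministic
#' artefact set to the output directory: scaled score matrix and
#' per-signature stats, cluster labels and 2-D embedding, the per-group rank
#' table (with 4-squares quadrants when residuals exist), the differential
#' ranking when a condition column is given, embedding plots, and a JSON run
#' manifest (package version, parameters, seed, input checksums).
#' Re-running an identical config reproduces every numeric output exactly.
#'
#' @param config a `RunConfig` from [run_config()] or [read_run_config()].
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  # validate inputs before any computation
  fmt <- if (grepl("\\.mtx$", config$expr)) "mtx_triplet" else "tsv"
  for (f in c(config$expr, config$gmt, config$meta))
    if (!is.null(f) && !file.exists(f)) stop(sprintf("input not found: %s", f))
  if (length(config$covariates) && is.null(config$meta))
    stop("covariate regression requested but no metadata file given")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  stage <- function(name, code) {
    tryCatch(code, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  expr <- stage("read", read_expression(config$expr, fmt,
                                        transposed = config$transposed))
  collection <- stage("read", read_gmt(config$gmt))
  meta <- NULL
  if (!is.null(config$meta)) {
    meta <- utils::read.table(config$meta, sep = "\t", header = TRUE,
                              check.names = FALSE)
    if (!"cell_id" %in% names(meta)) stop("metadata needs a 'cell_id' column")
  }
  scores <- stage("score",
                  score_signatures(expr, collection, winsor = config$winsor))
  if (length(config$covariates)) {
    scores <- stage("regress",
                    regress_out(scores, meta, config$covariates,
                                k = config$knn_k))
  }
  use <- if (is.null(scores$residuals)) "scaled" else "residuals"
  red <- stage("cluster",
               reduce_scores(scores, use = use, n_pcs = config$n_pcs,
                             seed = config$seed))
  tc <- stage("cluster",
              find_clusters(red, method = config$method,
                            resolution = config$resolution,
                            k = if (config$method == "kmeans") 2L else NULL,
                            seed = config$seed))
  stats_tab <- stage("rank", signature_stats(scores, tc$labels))
  fsq <- NULL
  if (!is.null(scores$residuals)) {
    fsq <- do.call(rbind, lapply(unique(stats_tab$group), function(g)
      four_squares(stats_tab, g, sp_cuts = config$sp_cuts,
                   res_quantile = config$res_quantile)))
  }
  diff_rank <- NULL
  if (!is.null(config$condition)) {
    cond <- stats::setNames(meta[[config$condition]], meta$cell_id)
    if (is.null(scores$residuals))
      warning("regression disabled; differential ranking uses scaled scores")
    diff_rank <- stage("rank",
                       suppressMessages(rank_differential(
                         scores, cond, n_perm = config$n_perm,
                         seed = config$seed)))
  }

  # artefacts
  out <- function(...) file.path(config$out_dir, ...)
  write_scores(scores, out("scores"))
  utils::write.table(
    data.frame(cell_id = names(tc$labels), tc = tc$labels),
    out("clusters.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(cell_id = rownames(tc$embedding), tc$embedding),
    out("embedding.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(stats_tab, out("rank_table.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(fsq))
    utils::write.table(fsq, out("four_squares.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(diff_rank))
    utils::write.table(diff_rank, out("differential_ranking.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  grDevices::png(out("clusters.png"), width = 800, height = 700)
  plot_clusters(tc)
  grDevices::dev.off()
  grDevices::png(out("switch_points.png"), width = 800, height = 500)
  graphics::barplot(scores$switch_points, las = 2, ylim = c(0, 1),
                    ylab = "switch point", main = "Response homogeneity")
  grDevices::dev.off()

  manifest <- list(
    package = "scdrugsens",
    version = as.character(utils::packageVersion("scdrugsens")),
    seed = config$seed,
    parameters = config[setdiff(names(config), c("expr", "gmt", "meta",
                                                 "out_dir"))],
    inputs = lapply(
      Filter(Negate(is.null),
             list(expr = config$expr, gmt = config$gmt, meta = config$meta)),
      function(f) unname(tools::md5sum(f))))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(scores = scores, clusters = tc, rank_table = stats_tab,
                 four_squares = fsq, differential = diff_rank,
                 manifest = manifest))
}
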