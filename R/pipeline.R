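#' Run the full co-clustering pipeline and write a results bundle
#'
#' Reads (or simulates) a fold-change matrix, fits [hcoclust()], and writes
#' the complete results bundle into `outdir`: the analysis-scale matrix,
#' both linkage tables, both cluster assignments, the ranked co-cluster
#' table, the control-chart report, the block-reordered matrix with block
#' boundaries, both networks (cluster- and member-level edge lists), and a
#' JSON manifest of the configuration, seed and package version. All
#' tables are TSV with floats at 6 significant digits, so a rerun with the
#' same configuration and seed reproduces the bundle byte for byte.
#'
#' @param input path to a fold-change matrix ([read_fcge()]); `NULL` to
#'   simulate instead.
#' @param outdir output directory (created if needed).
#' @param seed integer seed used for simulation.
#' @param k_genes,k_dcs,robust,metric,linkage,p,estimator,k_sigma passed to
#'   [hcoclust()].
#' @param sim named list of extra arguments for [simulate_fcge()].
#' @param dialect input dialect for [read_fcge()].
#' @return invisibly, a list with the `fit`, the simulation object (if
#'   simulated) and the written `paths`.
#' @export
run_pipeline <- function(input = NULL, outdir,
                         seed = 1L,
                         k_genes = 4L, k_dcs = 3L,
                         robust = TRUE,
                         metric = "euclidean", linkage = "ward.D2", p = 2,
                         estimator = "xbar_pooled", k_sigma = 3,
                         sim = list(),
                         dialect = "auto") {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  simulated <- is.null(input)
  if (simulated) {
    sim_obj <- do.call(simulate_fcge, c(list(seed = seed), sim))
    x <- sim_obj$fcge
  } else {
    sim_obj <- NULL
    x <- read_fcge(input, dialect = dialect)
  }
  fit <- hcoclust(x, k_genes = k_genes, k_dcs = k_dcs, robust = robust,
                  metric = metric, linkage = linkage, p = p,
                  estimator = estimator, k_sigma = k_sigma)

  pth <- function(f) file.path(outdir, f)
  paths <- c(analysis_matrix = pth("analysis_matrix.tsv"),
             gene_linkage = pth("gene_linkage.tsv"),
             dc_linkage = pth("dc_linkage.tsv"),
             gene_clusters = pth("gene_clusters.tsv"),
             dc_clusters = pth("dc_clusters.tsv"),
             cocluster_table = pth("cocluster_table.tsv"),
             scc_report = pth("scc_report.tsv"),
             reordered_matrix = pth("reordered_matrix.tsv"),
             cluster_network = pth("cluster_network.tsv"),
             member_network = pth("member_network.tsv"),
             manifest = pth("manifest.json"))
  write_fcge(fit$analysis_matrix, paths["analysis_matrix"])
  write_linkage(fit$gene_tree, paths["gene_linkage"])
  write_linkage(fit$dc_tree, paths["dc_linkage"])
  write_assignment(fit$gene_clusters, paths["gene_clusters"])
  write_assignment(fit$dc_clusters, paths["dc_clusters"])
  write_cocluster_table(fit$grid, paths["cocluster_table"])
  write_scc_report(fit, paths["scc_report"])
  ro <- reorder_matrix(fit$analysis_matrix, fit$grid,
                       orig_clusters(fit$gene_clusters, attr(fit$grid, "gc_map")),
                       orig_clusters(fit$dc_clusters, attr(fit$grid, "dcc_map")))
  write_fcge(ro$matrix, paths["reordered_matrix"])
  export_network(cocluster_graph(fit), paths["cluster_network"], "tsv")
  export_network(member_graph(fit, significant_only = TRUE),
                 paths["member_network"], "tsv")
  manifest <- list(
    input = if (simulated) "simulated" else input,
    seed = seed,
    k_genes = k_genes, k_dcs = k_dcs, robust = robust,
    metric = metric, linkage = linkage, p = p,
    estimator = estimator, k_sigma = k_sigma,
    row_boundaries = as.integer(ro$row_boundaries),
    col_boundaries = as.integer(ro$col_boundaries),
    package_version = as.character(utils::packageVersion("toxicoclust")),
    r_version = paste(R.version$major, R.version$minor, sep = "."))
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(fit = fit, sim = sim_obj, paths = paths))
}
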