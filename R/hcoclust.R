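#' Robust hierarchical co-clustering of a fold-change matrix
#'
#' Fits the full co-clustering model to a genes x doses-of-chemicals (DCs)
#' fold-change matrix:
#' \enumerate{
#'   \item (robust mode) transform the matrix with the bounded logistic
#'     function so outliers cannot dominate the distances
#'     ([logistic_transform()]); classical mode skips this step and works on
#'     the raw fold changes;
#'   \item cluster genes and DCs separately by agglomerative hierarchical
#'     clustering on profile distances and cut the trees into `k_genes` and
#'     `k_dcs` clusters;
#'   \item form the co-cluster grid -- one block per (gene cluster, DC
#'     cluster) pair -- compute each block's mean (aLFCGE on the transformed
#'     scale) and relabel clusters so the strongest up-regulatory blocks lie
#'     on the descending principal diagonal;
#'   \item call each block significantly up-/down-regulatory with a
#'     Shewhart-style control chart on the analysis-scale values, using the
#'     blocks as subgroups.
#' }
#' Blocks above the UCL are up-regulatory biomarker co-clusters (their genes
#' are up-regulated biomarkers and their DCs the regulators), blocks below
#' the LCL down-regulatory, the rest insignificant.
#'
#' @param x numeric fold-change matrix, genes in rows, DCs in columns, with
#'   dimnames (generated if absent).
#' @param k_genes,k_dcs number of gene / DC clusters to cut.
#' @param robust logical; `TRUE` (default) applies the logistic transform
#'   before clustering, `FALSE` gives the classical pipeline.
#' @param metric,linkage,p distance and agglomeration choices, see
#'   [profile_dist()] and [agglomerate()]. Defaults euclidean + ward.D2.
#' @param estimator,k_sigma control-chart settings, see [control_limits()].
#' @return an object of class `hcoclust`; see Details. Use `print()`,
#'   `summary()`, `plot()`, `coef()` (block-mean matrix), `fitted()`
#'   (cellwise block means on the analysis scale) and `residuals()` on it.
#' @examples
#' sim <- simulate_fcge(seed = 1)
#' fit <- hcoclust(sim$fcge, k_genes = 4, k_dcs = 3)
#' summary(fit)
#' @export
hcoclust <- function(x, k_genes, k_dcs,
                     robust = TRUE,
                     metric = c("euclidean", "manhattan", "minkowski"),
                     linkage = c("ward.D2", "ward.D", "single", "complete",
                                 "average"),
                     p = 2,
                     estimator = c("xbar_pooled", "individuals"),
                     k_sigma = 3) {
  metric <- match.arg(metric)
  linkage <- match.arg(linkage)
  estimator <- match.arg(estimator)
  if (!is.matrix(x) || !is.numeric(x)) stop("x must be a numeric matrix")
  if (any(!is.finite(x))) stop("x must be finite (no NA/NaN/Inf)")
  if (is.null(rownames(x))) rownames(x) <- paste0("G", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("DC", seq_len(ncol(x)))
  if (anyDuplicated(rownames(x)) || anyDuplicated(colnames(x)))
    stop("duplicate row or column labels")
  if (k_genes > nrow(x) || k_dcs > ncol(x))
    stop("k exceeds the number of items on its axis")

  y <- if (robust) logistic_transform(x) else x
  gene_tree <- agglomerate(profile_dist(y, "rows", metric, p), linkage)
  dc_tree <- agglomerate(profile_dist(y, "cols", metric, p), linkage)
  gene_cl <- cut_clusters(gene_tree, k_genes)
  dc_cl <- cut_clusters(dc_tree, k_dcs)
  names(gene_cl) <- rownames(x)
  names(dc_cl) <- colnames(x)

  grid <- rank_coclusters(build_cocluster_grid(y, gene_cl, dc_cl))
  gmap <- attr(grid, "gc_map")
  dmap <- attr(grid, "dcc_map")
  blocks <- paste(gmap[gene_cl[rep(rownames(x), ncol(x))]],
                  dmap[dc_cl[rep(colnames(x), each = nrow(x))]])
  limits <- control_limits(as.vector(y), subgroups = blocks,
                           estimator = estimator, k_sigma = k_sigma)
  grid <- classify_coclusters(grid, limits)

  structure(list(call = match.call(),
                 fcge = x,
                 analysis_matrix = y,
                 robust = robust,
                 metric = metric, linkage = linkage, p = p,
                 k_genes = k_genes, k_dcs = k_dcs,
                 gene_tree = gene_tree, dc_tree = dc_tree,
                 gene_clusters = stats::setNames(
                   as.integer(gmap[as.character(gene_cl)]), names(gene_cl)),
                 dc_clusters = stats::setNames(
                   as.integer(dmap[as.character(dc_cl)]), names(dc_cl)),
                 grid = grid,
                 limits = limits),
            class = "hcoclust")
}

#' @export
print.hcoclust <- function(x, ...) {
  sig <- table(factor(x$grid$significance,
                      levels = c("up", "down", "insignificant")))
  cat("Hierarchical co-clustering (", if (x$robust) "robust" else "classical",
      " mode)\n", sep = "")
  cat("  ", nrow(x$fcge), " genes in ", x$k_genes, " clusters, ",
      ncol(x$fcge), " DCs in ", x$k_dcs, " clusters (", x$metric, " + ",
      x$linkage, ")\n", sep = "")
  cat("  ", nrow(x$grid), " co-clusters: ", sig[["up"]], " up-regulatory, ",
      sig[["down"]], " down-regulatory, ", sig[["insignificant"]],
      " insignificant\n", sep = "")
  invisible(x)
}

#' @export
summary.hcoclust <- function(object, ...) {
  structure(list(fit = object,
                 table = object$grid[order(object$grid$rank), ],
                 limits = object$limits),
            class = "summary.hcoclust")
}

#' @export
print.summary.hcoclust <- function(x, ...) {
  print(x$fit)
  print(x$limits)
  tab <- x$table
  tab$aLFCGE <- signif(tab$aLFCGE, 6)
  cat("\nRanked co-clusters:\n")
  print.data.frame(as.data.frame(tab), row.names = FALSE)
  invisible(x)
}

#' Block-mean matrix of a fitted co-clustering
#'
#' @param object an `hcoclust` fit.
#' @param ... unused.
#' @return gene-cluster x DC-cluster matrix of block means (aLFCGE values on
#'   the analysis scale), rows/columns in relabelled order.
#' @export
coef.hcoclust <- function(object, ...) {
  g <- object$grid
  m <- matrix(NA_real_, object$k_genes, object$k_dcs,
              dimnames = list(paste0("GC", seq_len(object$k_genes)),
                              paste0("DCC", seq_len(object$k_dcs))))
  m[cbind(g$gc, g$dcc)] <- g$aLFCGE
  m
}

#' @export
fitted.hcoclust <- function(object, ...) {
  bm <- coef(object)
  out <- bm[cbind(object$gene_clusters[rep(rownames(object$fcge),
                                           ncol(object$fcge))],
                  object$dc_clusters[rep(colnames(object$fcge),
                                         each = nrow(object$fcge))])]
  matrix(out, nrow(object$fcge), ncol(object$fcge),
         dimnames = dimnames(object$fcge))
}

#' @export
residuals.hcoclust <- function(object, ...) {
  object$analysis_matrix - fitted(object)
}

#' Plot a fitted co-clustering
#'
#' `type = "cocluster"` draws the analysis-scale matrix reordered into
#' contiguous ranked blocks with block boundaries; `type = "chart"` draws
#' the control chart of block means against CL/LCL/UCL; `type =
#' "dendrogram"` draws the two cluster trees side by side.
#'
#' @param x an `hcoclust` fit.
#' @param type plot flavour, see above.
#' @param ... passed to the underlying graphics calls.
#' @export
plot.hcoclust <- function(x, type = c("cocluster", "chart", "dendrogram"),
                          ...) {
  type <- match.arg(type)
  if (type == "cocluster") {
    ro <- reorder_matrix(x$analysis_matrix, x$grid,
                         orig_clusters(x$gene_clusters, attr(x$grid, "gc_map")),
                         orig_clusters(x$dc_clusters, attr(x$grid, "dcc_map")))
    m <- ro$matrix
    graphics::image(seq_len(ncol(m)), seq_len(nrow(m)),
                    t(m[rev(seq_len(nrow(m))), , drop = FALSE]),
                    col = grDevices::hcl.colors(64, "RdBu", rev = TRUE),
                    xlab = "DCs (ordered by cluster)",
                    ylab = "Genes (ordered by cluster)",
                    main = "Co-clustered matrix", axes = FALSE, ...)
    graphics::box()
    graphics::abline(v = ro$col_boundaries[-length(ro$col_boundaries)] + 0.5)
    graphics::abline(h = nrow(m) -
                       ro$row_boundaries[-length(ro$row_boundaries)] + 0.5)
  } else if (type == "chart") {
    g <- x$grid[order(x$grid$rank), ]
    cols <- c(up = "red", down = "blue", insignificant = "black")
    graphics::plot(g$rank, g$aLFCGE, pch = 19, col = cols[g$significance],
                   xlab = "Co-cluster rank", ylab = "Block mean (aLFCGE)",
                   main = "Control chart of co-cluster means", ...)
    graphics::abline(h = c(x$limits$LCL, x$limits$CL, x$limits$UCL),
                     lty = c(2, 1, 2))
  } else {
    old <- graphics::par(mfrow = c(1, 2))
    on.exit(graphics::par(old))
    plot(x$gene_tree, main = "Genes", xlab = "", sub = "", ...)
    plot(x$dc_tree, main = "DCs", xlab = "", sub = "", ...)
  }
  invisible(x)
}

# invert the displayed labels back to the pre-relabel ids the grid maps from
orig_clusters <- function(cl, map) {
  inv <- stats::setNames(as.integer(names(map)), map)
  stats::setNames(inv[as.character(cl)], names(cl))
}
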