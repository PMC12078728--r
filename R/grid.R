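#' Build the gene-cluster x DC-cluster co-cluster grid
#'
#' Every combination of one gene cluster (GC) and one DC cluster (DCC)
#' defines a co-cluster: the sub-matrix block at their intersection. For
#' each block this records its mean value -- on the transformed scale this
#' is the aLFCGE, the average logistically transformed fold change -- and
#' its size in cells.
#'
#' @param x numeric matrix with row and column names (transformed or raw
#'   fold-change scale).
#' @param gene_clusters,dc_clusters named integer vectors assigning every
#'   row / column label of `x` to a cluster (see [cut_clusters()]).
#' @return a `cocluster_grid`: a data frame with one row per (gc, dcc) block
#'   and columns `gc`, `dcc`, `aLFCGE`, `n_cells`, `rank`, `significance`
#'   (the latter two NA until [rank_coclusters()] /
#'   [classify_coclusters()] are applied), plus attributes `gc_map` and
#'   `dcc_map` recording the original-to-displayed cluster relabelings.
#' @export
build_cocluster_grid <- function(x, gene_clusters, dc_clusters) {
  check_assignment(rownames(x), gene_clusters, "gene")
  check_assignment(colnames(x), dc_clusters, "DC")
  g <- gene_clusters[rownames(x)]
  d <- dc_clusters[colnames(x)]
  ng <- max(g); nd <- max(d)
  grid <- expand.grid(gc = seq_len(ng), dcc = seq_len(nd))
  gi <- g[rep(seq_len(nrow(x)), ncol(x))]
  dj <- d[rep(seq_len(ncol(x)), each = nrow(x))]
  key <- (dj - 1L) * ng + gi
  sums <- tapply(as.vector(x), key, sum)
  ns <- tapply(as.vector(x), key, length)
  idx <- as.character((grid$dcc - 1L) * ng + grid$gc)
  grid$aLFCGE <- as.numeric(sums[idx] / ns[idx])
  grid$n_cells <- as.integer(ns[idx])
  grid$rank <- NA_integer_
  grid$significance <- NA_character_
  structure(grid,
            gc_map = stats::setNames(seq_len(ng), seq_len(ng)),
            dcc_map = stats::setNames(seq_len(nd), seq_len(nd)),
            ranked = FALSE,
            class = c("cocluster_grid", "data.frame"))
}

check_assignment <- function(labels, cl, what) {
  if (is.null(labels)) stop("matrix lacks ", what, " labels (dimnames)")
  if (is.null(names(cl))) stop(what, " cluster assignment must be named")
  missing <- setdiff(labels, names(cl))
  extra <- setdiff(names(cl), labels)
  if (length(missing) || length(extra))
    stop(what, " assignment does not cover the matrix labels exactly; ",
         if (length(missing)) paste0("unassigned: ",
           paste(utils::head(missing, 5L), collapse = ", "), ". "),
         if (length(extra)) paste0("not in matrix: ",
           paste(utils::head(extra, 5L), collapse = ", ")))
  invisible(TRUE)
}

#' Rank co-clusters and relabel clusters onto the principal diagonal
#'
#' Relabels gene clusters and DC clusters so that the co-clusters with the
#' largest mean transformed fold change lie on the descending principal
#' diagonal of the grid: the globally largest block becomes (1,1), the
#' largest among blocks using none of the already-assigned clusters becomes
#' (2,2), and so on (greedy max-pair diagonalisation). When the shorter axis
#' is exhausted, remaining clusters on the longer axis are appended in
#' descending order of their best block mean. Ranks are the descending order
#' of block means over all blocks. Ties are broken toward the smallest
#' original cluster id. The operation is idempotent.
#'
#' @param grid a `cocluster_grid` from [build_cocluster_grid()].
#' @return the grid with `gc`, `dcc` relabelled, `rank` filled, rows ordered
#'   by rank, and `gc_map` / `dcc_map` attributes updated (original id ->
#'   new id bijections).
#' @export
rank_coclusters <- function(grid) {
  stopifnot(inherits(grid, "cocluster_grid"))
  ng <- length(attr(grid, "gc_map"))
  nd <- length(attr(grid, "dcc_map"))
  ord <- order(-grid$aLFCGE, grid$gc, grid$dcc)
  gmap <- rep(NA_integer_, ng)
  dmap <- rep(NA_integer_, nd)
  nxt <- 1L
  for (i in ord) {
    if (nxt > min(ng, nd)) break
    gi <- grid$gc[i]; dj <- grid$dcc[i]
    if (is.na(gmap[gi]) && is.na(dmap[dj])) {
      gmap[gi] <- nxt
      dmap[dj] <- nxt
      nxt <- nxt + 1L
    }
  }
  # append leftovers on the longer axis by their best block mean
  fill_rest <- function(map, ids_best) {
    left <- which(is.na(map))
    if (length(left))
      map[left[order(-ids_best[left], left)]] <-
        seq(from = sum(!is.na(map)) + 1L, length.out = length(left))
    map
  }
  best_g <- vapply(seq_len(ng), function(i) max(grid$aLFCGE[grid$gc == i]),
                   numeric(1L))
  best_d <- vapply(seq_len(nd), function(j) max(grid$aLFCGE[grid$dcc == j]),
                   numeric(1L))
  gmap <- fill_rest(gmap, best_g)
  dmap <- fill_rest(dmap, best_d)

  old_gmap <- attr(grid, "gc_map")
  old_dmap <- attr(grid, "dcc_map")
  out <- grid
  out$gc <- gmap[grid$gc]
  out$dcc <- dmap[grid$dcc]
  out$rank <- rank_blocks(out)
  out <- out[order(out$rank), , drop = FALSE]
  rownames(out) <- NULL
  # compose with any earlier relabeling so maps stay original -> displayed
  attr(out, "gc_map") <- stats::setNames(gmap[old_gmap], names(old_gmap))
  attr(out, "dcc_map") <- stats::setNames(dmap[old_dmap], names(old_dmap))
  attr(out, "ranked") <- TRUE
  class(out) <- c("cocluster_grid", "data.frame")
  out
}

rank_blocks <- function(grid) {
  o <- order(-grid$aLFCGE, grid$gc, grid$dcc)
  r <- integer(nrow(grid))
  r[o] <- seq_len(nrow(grid))
  r
}

#' Permute a matrix into contiguous ranked co-cluster blocks
#'
#' Reorders rows and columns so that each relabelled cluster occupies a
#' contiguous band, with cluster 1 first; within a cluster the original
#' order is kept. The returned boundaries mark the last row/column of each
#' band, ready for drawing block outlines on a heatmap.
#'
#' @param x matrix whose dimnames match the assignments.
#' @param grid a ranked `cocluster_grid` (for the relabeling maps).
#' @param gene_clusters,dc_clusters the assignments the grid was built from
#'   (original labels).
#' @return list with `matrix` (reordered), `row_order`, `col_order`
#'   (permutations of the input indices), and `row_boundaries`,
#'   `col_boundaries`.
#' @export
reorder_matrix <- function(x, grid, gene_clusters, dc_clusters) {
  stopifnot(inherits(grid, "cocluster_grid"))
  gmap <- attr(grid, "gc_map")
  dmap <- attr(grid, "dcc_map")
  g_new <- gmap[as.character(gene_clusters[rownames(x)])]
  d_new <- dmap[as.character(dc_clusters[colnames(x)])]
  ro <- order(g_new, seq_along(g_new))
  co <- order(d_new, seq_along(d_new))
  list(matrix = x[ro, co, drop = FALSE],
       row_order = ro, col_order = co,
       row_boundaries = cumsum(table(g_new)),
       col_boundaries = cumsum(table(d_new)))
}

#' @export
print.cocluster_grid <- function(x, ...) {
  n_sig <- sum(!is.na(x$significance) & x$significance != "insignificant")
  cat("Co-cluster grid: ", length(attr(x, "gc_map")), " gene clusters x ",
      length(attr(x, "dcc_map")), " DC clusters (",
      nrow(x), " blocks", if (attr(x, "ranked")) ", ranked", ")\n", sep = "")
  print.data.frame(x, digits = 5, ...)
  invisible(x)
}
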