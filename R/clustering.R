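#' Pairwise Lp distances between row or column profiles
#'
#' Thin, validated front end to [stats::dist()] computing euclidean,
#' manhattan or general Minkowski distances between the item profiles of a
#' matrix, where items are either the rows (genes) or the columns
#' (doses-of-chemicals).
#'
#' @param x numeric matrix (fold-change or transformed scale).
#' @param axis `"rows"` to compare gene profiles, `"cols"` for DC profiles.
#' @param metric one of `"euclidean"`, `"manhattan"`, `"minkowski"`.
#' @param p Minkowski order, >= 1; ignored unless `metric = "minkowski"`.
#' @return a `"dist"` object over the chosen items.
#' @export
profile_dist <- function(x, axis = c("rows", "cols"),
                         metric = c("euclidean", "manhattan", "minkowski"),
                         p = 2) {
  axis <- match.arg(axis)
  metric <- match.arg(metric)
  if (metric == "minkowski" && (!is.numeric(p) || p < 1))
    stop("Minkowski order p must be >= 1")
  m <- if (axis == "cols") t(x) else x
  if (nrow(m) < 2L) stop("need at least 2 items on the chosen axis")
  stats::dist(m, method = metric, p = p)
}

#' Agglomerative hierarchical clustering
#'
#' Runs [stats::hclust()] on a distance matrix with one of the linkages used
#' by the co-clustering pipeline. `"ward.D"` applies the Lance-Williams Ward
#' recurrence to the dissimilarities as given; `"ward.D2"` applies it to the
#' squared dissimilarities and reports square-rooted heights.
#'
#' @param d a `"dist"` object.
#' @param linkage one of `"ward.D2"`, `"ward.D"`, `"single"`, `"complete"`,
#'   `"average"`.
#' @return an `"hclust"` object (merge matrix, heights, labels).
#' @export
agglomerate <- function(d, linkage = c("ward.D2", "ward.D", "single",
                                       "complete", "average")) {
  linkage <- match.arg(linkage)
  if (!inherits(d, "dist")) stop("d must be a 'dist' object")
  if (attr(d, "Size") < 2L) stop("need at least 2 items to agglomerate")
  stats::hclust(d, method = linkage)
}

#' Cut a dendrogram into k clusters
#'
#' Undoes the last k-1 merges of the tree and returns the resulting
#' partition. Cluster indices are assigned by order of first member
#' appearance in the input item order (item 1 is always in cluster 1).
#'
#' @param tree an `"hclust"` object.
#' @param k integer number of clusters, 1 <= k <= n.
#' @return named integer vector mapping each item to a cluster in 1..k.
#' @export
cut_clusters <- function(tree, k) {
  n <- length(tree$order)
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k > n)
    stop("k must be a single integer in 1..", n)
  cl <- stats::cutree(tree, k = k)
  relabel_first_appearance(cl)
}

relabel_first_appearance <- function(cl) {
  out <- as.integer(factor(cl, levels = unique(cl)))
  names(out) <- names(cl)
  out
}

#' Advisory choice of the number of clusters from merge-height gaps
#'
#' The pipeline takes k from the user (the method chooses k by inspecting
#' the dendrograms); this helper suggests a k by locating the largest gap
#' between successive merge heights. Cutting into k clusters removes the
#' last k-1 merges, so the score for k is the height difference between the
#' (n-k+1)-th and (n-k)-th merges. Ties are broken toward smaller k.
#'
#' @param tree an `"hclust"` object.
#' @param k_max largest k considered (>= 2).
#' @return list with `k` (suggested) and `gaps` (data frame of k vs gap).
#' @export
suggest_k <- function(tree, k_max = 10L) {
  n <- length(tree$order)
  if (k_max < 2L) stop("k_max must be >= 2")
  k_max <- min(k_max, n - 1L)
  h <- tree$height
  ks <- 2:k_max
  gap <- vapply(ks, function(k) {
    upper <- h[n - k + 1L]
    lower <- if (n - k >= 1L) h[n - k] else 0
    upper - lower
  }, numeric(1L))
  list(k = ks[which.max(gap)], gaps = data.frame(k = ks, gap = gap))
}
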