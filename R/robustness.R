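#' Clustering error rate against a reference partition
#'
#' Builds the contingency table between the predicted and true partitions,
#' matches predicted clusters to true clusters one-to-one so as to maximise
#' the total overlap (exhaustive optimal assignment for up to 8 clusters per
#' side, greedy beyond that), and reports the percentage of items left
#' unmatched: ER = 100 * (1 - matched / total). The measure is invariant
#' under any relabeling of either partition and symmetric in its arguments.
#' When the partitions have unequal numbers of clusters, the surplus
#' clusters stay unmatched and their members count as errors.
#'
#' @param predicted,truth cluster assignments over the same items: named
#'   integer vectors (matched by name) or plain vectors of equal length.
#' @return object of class `er_report`: list with `er` (percent), `table`
#'   (contingency), `mapping` (predicted -> true cluster), `n`.
#' @examples
#' error_rate(c(1, 1, 2, 2), c(2, 2, 1, 1))$er  # 0: labels don't matter
#' @export
error_rate <- function(predicted, truth) {
  if (!is.null(names(predicted)) && !is.null(names(truth))) {
    common <- intersect(names(predicted), names(truth))
    if (length(common) == 0L) stop("predicted and truth share no items")
    if (length(common) < length(predicted) || length(common) < length(truth))
      stop("predicted and truth must cover the same item set")
    predicted <- predicted[common]
    truth <- truth[common]
  } else if (length(predicted) != length(truth)) {
    stop("predicted and truth must cover the same item set")
  }
  tab <- table(predicted, truth)
  matched <- best_matching(unclass(tab))
  n <- length(predicted)
  structure(list(er = 100 * (1 - matched$total / n),
                 table = tab,
                 mapping = matched$mapping,
                 n = n),
            class = "er_report")
}

# maximum-overlap one-to-one assignment on a contingency table; matches the
# smaller side injectively into the larger one
best_matching <- function(tab) {
  transposed <- nrow(tab) > ncol(tab)
  if (transposed) tab <- t(tab)
  k <- nrow(tab)
  if (ncol(tab) <= 8L) {
    best <- -1; best_sel <- NULL
    for (s in utils::combn(seq_len(ncol(tab)), k, simplify = FALSE)) {
      for (p in permutations(s)) {
        tot <- sum(tab[cbind(seq_len(k), p)])
        if (tot > best) { best <- tot; best_sel <- p }
      }
    }
    mapping <- best_sel
  } else {
    # greedy fallback for very many clusters
    mapping <- rep(NA_integer_, k)
    used <- logical(ncol(tab))
    for (idx in order(-tab)) {
      i <- (idx - 1L) %% k + 1L
      j <- (idx - 1L) %/% k + 1L
      if (is.na(mapping[i]) && !used[j]) { mapping[i] <- j; used[j] <- TRUE }
    }
    best <- sum(tab[cbind(seq_len(k), mapping)])
  }
  names(mapping) <- rownames(tab)
  list(total = best, mapping = mapping, transposed = transposed)
}

permutations <- function(v) {
  if (length(v) <= 1L) return(list(v))
  do.call(c, lapply(seq_along(v), function(i)
    lapply(permutations(v[-i]), function(p) c(v[i], p))))
}

#' @export
print.er_report <- function(x, ...) {
  cat(sprintf("Clustering error rate: %.4g%% (%d items)\n", x$er, x$n))
  invisible(x)
}

#' 1-norm distance between two item profiles
#'
#' The distance statistic whose robustness the sensitivity curve probes:
#' T(a, b) = sum_j |a_j - b_j|.
#'
#' @param a,b numeric vectors of equal length.
#' @return nonnegative scalar.
#' @export
profile_distance <- function(a, b) {
  if (length(a) != length(b)) stop("profiles differ in length")
  sum(abs(a - b))
}

#' Tukey sensitivity curve of the profile distance
#'
#' Measures the influence a single contaminated observation y* exerts on the
#' 1-norm profile distance between two genes:
#' SC_n(y*) = n * [T(y_1, ..., y_{n-1}, y*) - T(y_1, ..., y_{n-1})], where
#' the contaminated coordinate is appended to gene i's profile and compared
#' against a reference coordinate of gene k (by default the mean of gene k's
#' profile on the analysis scale). In robust mode all values -- the
#' profiles, y* and a reference given on the fold-change scale is not
#' re-derived -- pass through the logistic transform before T, so the curve
#' is bounded by n * max(ref, 1 - ref) no matter how extreme y* is; in
#' classical mode raw values are used and the curve grows without bound in
#' |y*|.
#'
#' @param profile_i,profile_k numeric fold-change profiles of equal length
#'   (n - 1 coordinates).
#' @param ystar grid of contaminant values (default -10..10 by 0.1).
#' @param mode `"robust"` (transform first) or `"classical"`.
#' @param reference optional reference coordinate for gene k on the analysis
#'   scale (transformed scale in robust mode); default: mean of gene k's
#'   analysis-scale profile.
#' @return data frame with columns `ystar`, `sc`; attributes `mode`, `n`,
#'   `reference`.
#' @export
sensitivity_curve <- function(profile_i, profile_k,
                              ystar = seq(-10, 10, by = 0.1),
                              mode = c("robust", "classical"),
                              reference = NULL) {
  mode <- match.arg(mode)
  if (length(profile_i) == 0L || length(profile_k) == 0L)
    stop("profiles must be non-empty")
  if (length(profile_i) != length(profile_k))
    stop("profiles differ in length")
  ai <- if (mode == "robust") logistic_transform(profile_i) else profile_i
  ak <- if (mode == "robust") logistic_transform(profile_k) else profile_k
  ys <- if (mode == "robust") logistic_transform(ystar) else ystar
  ref <- if (is.null(reference)) mean(ak) else reference
  n <- length(ai) + 1L
  base <- profile_distance(ai, ak)
  sc <- vapply(ys, function(y)
    n * (profile_distance(c(ai, y), c(ak, ref)) - base), numeric(1L))
  structure(data.frame(ystar = ystar, sc = sc),
            mode = mode, n = n, reference = ref)
}

#' Contamination sweep comparing robust and classical co-clustering
#'
#' For every combination of contamination model/rate, distance/linkage and
#' mode, generates the benchmark block-model matrix, contaminates it,
#' clusters the genes (k = 4 by default) on the transformed (robust) or raw
#' (classical) scale, and records the clustering error rate of the gene
#' partition against the generator's ground truth, averaged over seeds. The
#' same generated and contaminated matrix is shared by all combinations and
#' modes within a (seed, model, rate) cell, so the comparison is paired.
#'
#' @param n_seeds number of simulation replicates per cell (default 30).
#' @param thcm_rates row-contamination rates for the casewise model.
#' @param icm_rates cell-contamination rates for the cellwise model.
#' @param combos data frame with columns `metric` and `linkage`; default the
#'   six benchmark combinations (euclidean/manhattan/minkowski x
#'   ward.D/ward.D2).
#' @param modes subset of `c("robust", "classical")`.
#' @param k_genes number of gene clusters to cut.
#' @param seed master seed for the whole sweep.
#' @param sim arguments passed on to [simulate_fcge()] (a named list).
#' @return data frame: `model`, `rate`, `metric`, `linkage`, `mode`,
#'   `mean_er`, `sd_er`, `n_seeds`.
#' @export
contamination_sweep <- function(n_seeds = 30L,
                                thcm_rates = c(0, 0.1, 0.2, 0.3, 0.4),
                                icm_rates = c(0, 0.00625, 0.0125, 0.01875,
                                              0.025),
                                combos = default_combos(),
                                modes = c("robust", "classical"),
                                k_genes = 4L,
                                seed = 1L,
                                sim = list()) {
  if (n_seeds < 1L) stop("need at least one seed")
  set.seed(seed)
  cells <- rbind(
    if (length(thcm_rates)) data.frame(model = "thcm", rate = thcm_rates),
    if (length(icm_rates)) data.frame(model = "icm", rate = icm_rates))
  out <- expand.grid(model_rate = seq_len(nrow(cells)),
                     combo = seq_len(nrow(combos)),
                     mode = modes, stringsAsFactors = FALSE)
  ers <- matrix(NA_real_, nrow(out), n_seeds)
  for (s in seq_len(n_seeds)) {
    base <- do.call(simulate_fcge, sim)
    for (ci in seq_len(nrow(cells))) {
      cont <- if (cells$model[ci] == "thcm")
        contaminate_thcm(base$fcge, cells$rate[ci])
      else contaminate_icm(base$fcge, cells$rate[ci])
      for (mode in modes) {
        y <- if (mode == "robust") logistic_transform(cont$fcge) else cont$fcge
        for (k in seq_len(nrow(combos))) {
          cl <- cut_clusters(
            agglomerate(profile_dist(y, "rows", combos$metric[k]),
                        combos$linkage[k]), k_genes)
          rows <- which(out$model_rate == ci & out$combo == k &
                          out$mode == mode)
          ers[rows, s] <- error_rate(cl, base$gene_clusters)$er
        }
      }
    }
  }
  data.frame(model = cells$model[out$model_rate],
             rate = cells$rate[out$model_rate],
             metric = combos$metric[out$combo],
             linkage = combos$linkage[out$combo],
             mode = out$mode,
             mean_er = rowMeans(ers),
             sd_er = apply(ers, 1L, stats::sd),
             n_seeds = n_seeds)
}

#' @rdname contamination_sweep
#' @export
default_combos <- function() {
  expand.grid(metric = c("euclidean", "manhattan", "minkowski"),
              linkage = c("ward.D", "ward.D2"),
              stringsAsFactors = FALSE)
}
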