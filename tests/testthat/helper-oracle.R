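# Independent brute-force agglomeration: keeps the full cluster-by-cluster
# dissimilarity matrix, scans every active pair for the global minimum at
# every step, and applies the Lance-Williams update explicitly. O(n^3),
# used only to cross-check the optimized path on small n.
naive_agglomerate <- function(d, linkage) {
  D <- as.matrix(d)
  n <- nrow(D)
  W <- if (linkage == "ward.D2") D^2 else D
  active <- seq_len(n)
  members <- lapply(seq_len(n), identity)
  sizes <- rep(1L, n)
  heights <- numeric(n - 1L)
  sets <- vector("list", n - 1L)
  for (step in seq_len(n - 1L)) {
    best <- Inf; bi <- bj <- NA_integer_
    for (a in seq_along(active)) {
      for (b in seq_along(active)) {
        if (b <= a) next
        i <- active[a]; j <- active[b]
        if (W[i, j] < best - 1e-12) { best <- W[i, j]; bi <- i; bj <- j }
      }
    }
    heights[step] <- if (linkage == "ward.D2") sqrt(best) else best
    newm <- sort(c(members[[bi]], members[[bj]]))
    sets[[step]] <- newm
    nA <- sizes[bi]; nB <- sizes[bj]
    for (k in setdiff(active, c(bi, bj))) {
      nC <- sizes[k]
      W[bi, k] <- W[k, bi] <- switch(linkage,
        single = min(W[bi, k], W[bj, k]),
        complete = max(W[bi, k], W[bj, k]),
        average = (nA * W[bi, k] + nB * W[bj, k]) / (nA + nB),
        ward.D = ,
        ward.D2 = ((nA + nC) * W[bi, k] + (nB + nC) * W[bj, k] -
                     nC * W[bi, bj]) / (nA + nB + nC))
    }
    members[[bi]] <- newm
    sizes[bi] <- nA + nB
    active <- setdiff(active, bj)
  }
  list(heights = heights, sets = sets)
}

# member sets of every merge of an hclust tree, for comparison with the
# oracle's merge sets
hclust_sets <- function(tree) {
  sets <- vector("list", nrow(tree$merge))
  for (i in seq_len(nrow(tree$merge))) {
    grab <- function(id) if (id < 0) -id else sets[[id]]
    sets[[i]] <- sort(c(grab(tree$merge[i, 1L]), grab(tree$merge[i, 2L])))
  }
  sets
}

set_key <- function(sets) sort(vapply(sets, paste, "", collapse = ","))
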