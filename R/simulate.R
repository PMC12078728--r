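#' Simulate a block-structured fold-change matrix with ground truth
#'
#' Generates a genes x DCs fold-change matrix from a block model: each cell
#' is the mean of its (gene cluster, DC cluster) block plus independent
#' Gaussian noise. The defaults reproduce the benchmark design used
#' throughout this package: 50 genes in clusters of 10/10/10/20, 36 DCs in
#' clusters of 10/10/16 (12 chemicals at Low/Middle/High dose levels), block
#' means
#' \preformatted{          DCC1  DCC2  DCC3
#'   GC1      +3     0     0
#'   GC2      -3    +3     0
#'   GC3       0    -3     0
#'   GC4       0     0     0}
#' and noise variance 0.35, i.e. DCC1 up-regulates GC1, DCC1/DCC2
#' down-/up-regulate GC2, DCC2 down-regulates GC3, and GC4 and DCC3 carry no
#' signal.
#'
#' @param gc_sizes integer vector of gene-cluster sizes.
#' @param dcc_sizes integer vector of DC-cluster sizes.
#' @param block_means numeric matrix, `length(gc_sizes)` x
#'   `length(dcc_sizes)`, of block mean fold changes.
#' @param noise_var variance (not sd) of the additive Gaussian noise.
#' @param m optional replicate count; when given, `replicates` is also
#'   returned: an N x C x m array whose cells each carry independent noise
#'   of the same variance, with `fcge` their replicate mean.
#' @param seed optional integer seed (sets the global RNG).
#' @return object of class `fcge_sim`: list with `fcge` (labelled matrix),
#'   `gene_clusters`, `dc_clusters` (named integer ground-truth
#'   assignments), `regulation` (gc x dcc matrix of `"up"`/`"down"`/
#'   `"none"`), `config`, and optionally `replicates`.
#' @export
simulate_fcge <- function(gc_sizes = c(10L, 10L, 10L, 20L),
                          dcc_sizes = c(10L, 10L, 16L),
                          block_means = default_block_means(),
                          noise_var = 0.35,
                          m = NULL,
                          seed = NULL) {
  if (!is.matrix(block_means) ||
      nrow(block_means) != length(gc_sizes) ||
      ncol(block_means) != length(dcc_sizes))
    stop("block_means must be a ", length(gc_sizes), " x ",
         length(dcc_sizes), " matrix matching the cluster size vectors")
  if (noise_var < 0) stop("noise_var must be nonnegative")
  if (!is.null(seed)) set.seed(seed)
  N <- sum(gc_sizes); C <- sum(dcc_sizes)
  g <- rep(seq_along(gc_sizes), gc_sizes)
  d <- rep(seq_along(dcc_sizes), dcc_sizes)
  gene_ids <- paste0("G", seq_len(N))
  dc_ids <- dc_labels(dcc_sizes)
  signal <- block_means[cbind(g[rep(seq_len(N), C)],
                              d[rep(seq_len(C), each = N)])]
  sd <- sqrt(noise_var)
  out <- list()
  if (is.null(m)) {
    f <- matrix(signal + stats::rnorm(N * C, 0, sd), N, C)
  } else {
    if (m < 1L) stop("m must be >= 1")
    reps <- array(signal + stats::rnorm(N * C * m, 0, sd), c(N, C, m),
                  dimnames = list(gene_ids, dc_ids, paste0("rep", seq_len(m))))
    f <- apply(reps, c(1L, 2L), mean)
    out$replicates <- reps
  }
  dimnames(f) <- list(gene_ids, dc_ids)
  reg <- matrix("none", length(gc_sizes), length(dcc_sizes),
                dimnames = list(paste0("GC", seq_along(gc_sizes)),
                                paste0("DCC", seq_along(dcc_sizes))))
  reg[block_means > 0] <- "up"
  reg[block_means < 0] <- "down"
  structure(c(list(fcge = f,
                   gene_clusters = stats::setNames(g, gene_ids),
                   dc_clusters = stats::setNames(d, dc_ids),
                   regulation = reg,
                   config = list(gc_sizes = gc_sizes, dcc_sizes = dcc_sizes,
                                 block_means = block_means,
                                 noise_var = noise_var, m = m, seed = seed)),
              out),
            class = "fcge_sim")
}

#' @rdname simulate_fcge
#' @export
default_block_means <- function() {
  matrix(c(3, -3, 0, 0,
           0, 3, -3, 0,
           0, 0, 0, 0), nrow = 4L,
         dimnames = list(paste0("GC", 1:4), paste0("DCC", 1:3)))
}

# DC labels for the benchmark design: 12 chemicals x Low/Middle/High, grouped
# as DCC1 = C1-C5 High + C1-C5 Middle, DCC2 = C6-C10 High + C6-C10 Middle,
# DCC3 = C1-C12 Low + C11-C12 Middle + C11-C12 High. Other size vectors get
# generic labels.
dc_labels <- function(dcc_sizes) {
  if (identical(as.integer(dcc_sizes), c(10L, 10L, 16L))) {
    c(paste0("C", 1:5, "_High"), paste0("C", 1:5, "_Middle"),
      paste0("C", 6:10, "_High"), paste0("C", 6:10, "_Middle"),
      paste0("C", 1:12, "_Low"), paste0("C", 11:12, "_Middle"),
      paste0("C", 11:12, "_High"))
  } else {
    unlist(lapply(seq_along(dcc_sizes), function(k)
      paste0("DCC", k, "_", seq_len(dcc_sizes[k]))))
  }
}

#' @export
print.fcge_sim <- function(x, ...) {
  cat("Simulated FCGE matrix: ", nrow(x$fcge), " genes x ", ncol(x$fcge),
      " DCs, ", length(unique(x$gene_clusters)), " gene clusters, ",
      length(unique(x$dc_clusters)), " DC clusters, noise variance ",
      x$config$noise_var, "\n", sep = "")
  invisible(x)
}

#' Casewise (Tukey-Huber) contamination of a fold-change matrix
#'
#' Each gene row is independently selected with probability `rate`; every
#' cell of a selected row is replaced by a draw from the contaminating
#' distribution N(+/-`mean`, `sd`^2), the sign chosen at random per
#' replacement. This is the casewise (whole-observation) outlier model; the
#' default contaminant magnitude 10 lies far outside the +/-3 signal range
#' of the benchmark simulation.
#'
#' @param x numeric matrix (or an `fcge_sim`, whose matrix is used).
#' @param rate row contamination probability in [0, 1].
#' @param mean,sd contaminating distribution parameters.
#' @param seed optional integer seed.
#' @return list with `fcge` (contaminated matrix) and `mask` (logical
#'   matrix, TRUE where replaced).
#' @export
contaminate_thcm <- function(x, rate, mean = 10, sd = 1, seed = NULL) {
  x <- as_fcge(x)
  if (rate < 0 || rate > 1) stop("rate must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  rows <- stats::runif(nrow(x)) < rate
  mask <- matrix(FALSE, nrow(x), ncol(x), dimnames = dimnames(x))
  mask[rows, ] <- TRUE
  x[mask] <- contaminant(sum(mask), mean, sd)
  list(fcge = x, mask = mask)
}

#' Cellwise (independent) contamination of a fold-change matrix
#'
#' Each matrix cell is independently replaced with probability `rate` by a
#' draw from N(+/-`mean`, `sd`^2), sign random per replacement. At cell rate
#' eps a row of C cells is touched with probability 1 - (1-eps)^C (see
#' [icm_casewise_rate()]).
#'
#' @inheritParams contaminate_thcm
#' @param rate cell contamination probability in [0, 1].
#' @return list with `fcge` and `mask` as in [contaminate_thcm()].
#' @export
contaminate_icm <- function(x, rate, mean = 10, sd = 1, seed = NULL) {
  x <- as_fcge(x)
  if (rate < 0 || rate > 1) stop("rate must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  mask <- matrix(stats::runif(length(x)) < rate, nrow(x), ncol(x),
                 dimnames = dimnames(x))
  x[mask] <- contaminant(sum(mask), mean, sd)
  list(fcge = x, mask = mask)
}

contaminant <- function(n, mean, sd) {
  stats::rnorm(n, mean = sample(c(-mean, mean), n, replace = TRUE), sd = sd)
}

#' Casewise-equivalent contamination of a cellwise rate
#'
#' Probability that a row of `C` cells contains at least one contaminated
#' cell under independent cellwise contamination at rate `eps`:
#' 1 - (1 - eps)^C. At the default benchmark width C = 36, a cell rate of
#' 0.025 corresponds to casewise-equivalent contamination of about 0.598.
#'
#' @param eps cellwise contamination rate in [0, 1].
#' @param C number of cells per row.
#' @return numeric casewise-equivalent rate.
#' @export
icm_casewise_rate <- function(eps, C) 1 - (1 - eps)^C

as_fcge <- function(x) {
  if (inherits(x, "fcge_sim")) x$fcge
  else if (is.matrix(x) && is.numeric(x)) x
  else stop("x must be a numeric matrix or an fcge_sim object")
}
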