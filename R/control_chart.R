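#' Shewhart-style control limits for regulation calls
#'
#' Computes the center line (CL) and lower/upper control limits (LCL, UCL)
#' used to call cells or co-cluster blocks significantly regulated. Two
#' sigma estimators are available:
#' \describe{
#'   \item{`"individuals"`}{CL is the mean of all values and the limits are
#'     CL +/- k_sigma * sd over all values. Used for cell-level calls on the
#'     fold-change scale.}
#'   \item{`"xbar_pooled"`}{a subgroup-means chart: CL is the grand mean,
#'     sigma is the pooled within-subgroup standard deviation, and the
#'     limits are CL +/- k_sigma * sigma / sqrt(nbar) with nbar the mean
#'     subgroup size. Used (default) for co-cluster significance, with the
#'     co-cluster blocks as subgroups.}
#' }
#'
#' @param values numeric vector (or matrix, flattened) of plotted values.
#' @param subgroups factor/vector of the same length assigning each value to
#'   a subgroup; required for `estimator = "xbar_pooled"`.
#' @param estimator `"xbar_pooled"` or `"individuals"`.
#' @param k_sigma nonnegative sigma multiplier (default 3).
#' @return object of class `control_limits`: list with `CL`, `LCL`, `UCL`,
#'   `estimator`, `k_sigma`, `sigma_hat`, `nbar`.
#' @examples
#' control_limits(c(0.4, 0.6, 0.2, 0.4), subgroups = c(1, 1, 2, 2))
#' @export
control_limits <- function(values,
                           subgroups = NULL,
                           estimator = c("xbar_pooled", "individuals"),
                           k_sigma = 3) {
  estimator <- match.arg(estimator)
  values <- as.vector(values)
  if (length(values) < 2L) stop("need at least 2 values")
  if (any(!is.finite(values))) stop("values must be finite")
  if (!is.numeric(k_sigma) || k_sigma < 0) stop("k_sigma must be >= 0")
  CL <- mean(values)
  if (estimator == "individuals") {
    sigma <- stats::sd(values)
    half <- k_sigma * sigma
    nbar <- 1
  } else {
    if (is.null(subgroups)) stop("xbar_pooled estimator needs subgroups")
    subgroups <- as.factor(as.vector(subgroups))
    if (length(subgroups) != length(values))
      stop("subgroups must match values in length")
    ns <- tapply(values, subgroups, length)
    if (length(ns) < 2L || any(ns < 2L))
      stop("xbar_pooled needs >= 2 subgroups with >= 2 members each")
    vars <- tapply(values, subgroups, stats::var)
    sigma <- sqrt(sum((ns - 1) * vars) / sum(ns - 1))
    nbar <- mean(ns)
    half <- k_sigma * sigma / sqrt(nbar)
  }
  structure(list(CL = CL, LCL = CL - half, UCL = CL + half,
                 estimator = estimator, k_sigma = k_sigma,
                 sigma_hat = sigma, nbar = nbar),
            class = "control_limits")
}

#' @export
print.control_limits <- function(x, ...) {
  cat(sprintf("Control limits (%s, k = %g): LCL %.6g | CL %.6g | UCL %.6g\n",
              x$estimator, x$k_sigma, x$LCL, x$CL, x$UCL))
  invisible(x)
}

#' Call each cell of a fold-change matrix up-, down- or un-regulated
#'
#' A gene-DC cell is called up-regulated if its value is at or above the
#' UCL, down-regulated at or below the LCL, and un-regulated in between
#' (boundaries inclusive of the regulated calls).
#'
#' @param f numeric matrix on the same scale as the limits.
#' @param limits a `control_limits` object.
#' @return character matrix of the same shape with entries `"up"`, `"down"`,
#'   `"unregulated"`.
#' @export
classify_cells <- function(f, limits) {
  stopifnot(inherits(limits, "control_limits"))
  out <- matrix("unregulated", nrow(f), ncol(f), dimnames = dimnames(f))
  out[f >= limits$UCL] <- "up"
  out[f <= limits$LCL] <- "down"
  out
}

#' Call co-cluster blocks significantly up- or down-regulatory
#'
#' A co-cluster is significantly up-regulatory if its mean transformed fold
#' change strictly exceeds the UCL and down-regulatory if it falls strictly
#' below the LCL; otherwise it is insignificant. (The cell-level rule is
#' boundary-inclusive, the block-level rule strict; the asymmetry is
#' deliberate and only matters on exact ties.)
#'
#' @param grid a `cocluster_grid`.
#' @param limits a `control_limits` object computed on the same scale as the
#'   grid's block means (default pipeline: transformed scale, subgroups =
#'   blocks).
#' @return the grid with its `significance` column filled
#'   (`"up"`/`"down"`/`"insignificant"`).
#' @export
classify_coclusters <- function(grid, limits) {
  stopifnot(inherits(grid, "cocluster_grid"), inherits(limits, "control_limits"))
  sig <- rep("insignificant", nrow(grid))
  sig[grid$aLFCGE > limits$UCL] <- "up"
  sig[grid$aLFCGE < limits$LCL] <- "down"
  grid$significance <- sig
  grid
}
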