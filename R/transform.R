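#' Per-replicate log2 fold change between treated and control expression
#'
#' Computes the element-wise log2 ratio of treated over control expression
#' intensities. Inputs are arrays of identical shape, conventionally indexed
#' (gene, chemical, dose, time, replicate) with dimnames on every axis, but
#' any matching pair of positive arrays is accepted.
#'
#' @param treated,control numeric arrays of identical dimension and dimnames;
#'   all values must be strictly positive (a log2 is taken).
#' @return an array of log2 fold changes, same shape and dimnames as the
#'   inputs.
#' @examples
#' fold_change(array(4, c(1, 1)), array(2, c(1, 1)))  # 1
#' @seealso [average_replicates()], [logistic_transform()]
#' @export
fold_change <- function(treated, control) {
  dt <- dim(treated) %||% length(treated)
  dc <- dim(control) %||% length(control)
  if (!identical(dt, dc))
    stop("treated and control tensors differ in shape: ",
         paste(dt, collapse = "x"), " vs ", paste(dc, collapse = "x"))
  if (!identical(dimnames(treated), dimnames(control)))
    stop("treated and control tensors carry different axis labels")
  check_positive(treated, "treated")
  check_positive(control, "control")
  log2(treated) - log2(control)
}

check_positive <- function(x, what) {
  bad <- which(!is.finite(x) | x <= 0)
  if (length(bad)) {
    idx <- arrayInd(bad[1L], dim(x) %||% length(x))
    stop(what, " contains a nonpositive or non-finite value at index (",
         paste(idx, collapse = ", "), "); log2 requires strictly positive input")
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Average replicate fold changes into a genes x conditions FCGE matrix
#'
#' Takes the arithmetic mean over the replicate axis (the last axis) of a
#' per-replicate fold-change tensor and flattens any remaining condition axes
#' into matrix columns. For the canonical five-axis tensor
#' (gene, chemical, dose, time, replicate) the columns are ordered
#' chemical-major, then dose, then time, and labelled
#' \code{"<chemical>_<dose>_<time>"}, so a tensor with P chemicals, Q doses
#' and T times yields C = P*Q*T columns.
#'
#' @param fc numeric array; first axis genes, last axis replicates, any
#'   condition axes in between.
#' @return a numeric genes x conditions matrix (an FCGE matrix).
#' @export
average_replicates <- function(fc) {
  d <- dim(fc)
  if (is.null(d) || length(d) < 2L)
    stop("fc must be an array with at least gene and replicate axes")
  if (d[length(d)] < 1L) stop("replicate axis is empty")
  m <- apply(fc, seq_len(length(d) - 1L), mean)
  if (is.null(dim(m))) m <- matrix(m, ncol = 1L,
                                   dimnames = list(names(m), NULL))
  nd <- dim(m)
  if (length(nd) > 2L) {
    # flatten condition axes with the FIRST condition axis varying slowest
    dn <- dimnames(m)
    m <- aperm(m, c(1L, rev(seq_along(nd)[-1L])))
    cond_dims <- nd[-1L]
    labels <- NULL
    if (!is.null(dn) && all(!vapply(dn[-1L], is.null, logical(1L)))) {
      grid <- expand.grid(rev(dn[-1L]), stringsAsFactors = FALSE)
      labels <- apply(grid[, rev(seq_along(cond_dims)), drop = FALSE],
                      1L, paste, collapse = "_")
    }
    dim(m) <- c(nd[1L], prod(cond_dims))
    dimnames(m) <- list(dn[[1L]], labels)
  }
  m
}

#' Bounded logistic transform of a fold-change matrix
#'
#' Maps every fold change F to 1 / (1 + exp(-F)), squashing the real line
#' into (0, 1): a fold change of 0 maps to exactly 0.5, up-regulation to
#' values above 0.5 and down-regulation below. Because the transform is
#' bounded, arbitrarily large outlying fold changes cannot dominate the
#' profile distances computed downstream -- this is what makes the robust
#' co-clustering mode robust. Computed in the two-branch form
#' exp(x)/(1+exp(x)) for negative x so that large-magnitude inputs never
#' divide by overflowed exponentials.
#'
#' @param f numeric vector, matrix or array of finite fold changes.
#' @return object of the same shape with all values in [0, 1] (the open
#'   interval mathematically; extreme inputs saturate to 0 or 1 in double
#'   precision). Dimnames are preserved.
#' @examples
#' logistic_transform(c(-3, 0, 3))
#' @export
logistic_transform <- function(f) {
  if (any(is.na(f))) stop("fold-change input contains NA/NaN")
  out <- f
  pos <- !is.na(f) & f >= 0
  out[pos] <- 1 / (1 + exp(-f[pos]))
  e <- exp(f[!pos])
  out[!pos] <- e / (1 + e)
  out
}
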