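#' Read a fold-change matrix from delimited text
#'
#' Expects a header row of DC labels and a first column of gene identifiers;
#' tab-separated by default, comma accepted, or auto-detected from the
#' header line. Duplicate labels, missing cells and non-numeric cells are
#' rejected with the offending coordinates.
#'
#' @param path file path.
#' @param dialect `"tab"`, `"comma"`, or `"auto"` (sniff the header line).
#' @return numeric matrix with gene row names and DC column names.
#' @export
read_fcge <- function(path, dialect = c("tab", "comma", "auto")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    header <- readLines(path, n = 1L)
    dialect <- if (!grepl("\t", header) && grepl(",", header)) "comma" else "tab"
  }
  sep <- if (dialect == "comma") "," else "\t"
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character", quote = "\"",
                          comment.char = "")
  if (ncol(df) < 2L) stop("expected gene-id column plus at least one DC column")
  gene_ids <- df[[1L]]
  dup <- gene_ids[duplicated(gene_ids)]
  if (length(dup)) stop("duplicated gene ID(s): ",
                        paste(unique(dup), collapse = ", "))
  dcs <- colnames(df)[-1L]
  dupc <- dcs[duplicated(dcs)]
  if (length(dupc)) stop("duplicated DC label(s): ",
                         paste(unique(dupc), collapse = ", "))
  vals <- suppressWarnings(
    vapply(df[-1L], as.numeric, numeric(nrow(df))))
  vals <- matrix(vals, nrow = nrow(df),
                 dimnames = list(gene_ids, dcs))
  bad <- which(is.na(vals) | df[-1L] == "", arr.ind = TRUE)
  if (nrow(bad))
    stop("missing or non-numeric cell(s) at gene '",
         gene_ids[bad[1L, 1L]], "', column '", dcs[bad[1L, 2L]], "'",
         if (nrow(bad) > 1L) paste0(" (and ", nrow(bad) - 1L, " more)"))
  vals
}

#' Write a fold-change (or transformed) matrix as TSV
#'
#' Inverse of [read_fcge()]: header row of DC labels, first column of gene
#' IDs (column name `gene`), tab separators.
#'
#' @param x labelled numeric matrix.
#' @param path output path.
#' @param digits significant digits for the values (default 6).
#' @return `path`, invisibly.
#' @export
write_fcge <- function(x, path, digits = 6) {
  df <- data.frame(gene = rownames(x), signif(x, digits),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a ranked co-cluster table as TSV
#'
#' One row per co-cluster: columns `GC`, `DCC`, `aLFCGE`, `n_cells`, `rank`,
#' `significance`, ordered by rank.
#'
#' @param grid a `cocluster_grid` (typically `fit$grid`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cocluster_table <- function(grid, path) {
  g <- as.data.frame(grid)
  if (!all(is.na(g$rank))) g <- g[order(g$rank), ]
  out <- data.frame(GC = g$gc, DCC = g$dcc,
                    aLFCGE = signif(g$aLFCGE, 6),
                    n_cells = g$n_cells, rank = g$rank,
                    significance = g$significance)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a linkage tree as a merge table
#'
#' Four columns per merge in `hclust` convention: `left` and `right` are
#' negative item indices or positive earlier-merge indices, `height` the
#' merge height, `size` the merged cluster size.
#'
#' @param tree an `hclust` object.
#' @param path output path; when `NULL` the data frame is returned instead.
#' @return the merge table (invisibly when written).
#' @export
write_linkage <- function(tree, path = NULL) {
  sizes <- integer(nrow(tree$merge))
  for (i in seq_len(nrow(tree$merge))) {
    sz <- function(id) if (id < 0) 1L else sizes[id]
    sizes[i] <- sz(tree$merge[i, 1L]) + sz(tree$merge[i, 2L])
  }
  df <- data.frame(left = tree$merge[, 1L], right = tree$merge[, 2L],
                   height = signif(tree$height, 6), size = sizes)
  if (is.null(path)) return(df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Export a cluster assignment as two-column TSV
#'
#' @param cl named integer vector (item, cluster).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_assignment <- function(cl, path) {
  utils::write.table(data.frame(item = names(cl), cluster = as.integer(cl)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Control-chart report sufficient to redraw the chart
#'
#' One row per plotted statistic (co-cluster block by default): its value,
#' the center line, both limits and the call.
#'
#' @param fit an `hcoclust` fit.
#' @param path output path; when `NULL` the data frame is returned.
#' @return the report data frame (invisibly when written).
#' @export
write_scc_report <- function(fit, path = NULL) {
  g <- fit$grid[order(fit$grid$rank), ]
  df <- data.frame(statistic = paste0("GC", g$gc, ":DCC", g$dcc),
                   value = signif(g$aLFCGE, 6),
                   CL = signif(fit$limits$CL, 6),
                   LCL = signif(fit$limits$LCL, 6),
                   UCL = signif(fit$limits$UCL, 6),
                   call = g$significance)
  if (is.null(path)) return(df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
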