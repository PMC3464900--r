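#' Expression matrix container
#'
#' A genes x timepoints matrix of log-scale expression values for one
#' experimental condition. Values are assumed to be on a log scale already
#' (e.g. log2 intensities after RMA-style normalisation); the package never
#' re-logs data. Timepoints are in hours and must be strictly increasing;
#' gene identifiers must be unique.
#'
#' @param values numeric matrix, genes in rows, timepoints in columns.
#' @param timepoints_h numeric vector of sampling times in hours, strictly
#'   increasing, one per column of `values`.
#' @param condition condition label, e.g. `"control"` or `"treatment"`.
#' @param gene_ids character vector of gene identifiers; defaults to
#'   `rownames(values)`.
#' @return An object of class `expr_matrix`: a list with elements
#'   `gene_ids`, `timepoints_h`, `condition` and `values`.
#' @export
expression_matrix <- function(values, timepoints_h, condition = "control",
                              gene_ids = rownames(values)) {
  values <- as.matrix(values)
  if (is.null(gene_ids)) {
    stop("gene_ids are required (use rownames(values) or the gene_ids argument)")
  }
  gene_ids <- as.character(gene_ids)
  timepoints_h <- as.numeric(timepoints_h)
  if (length(gene_ids) != nrow(values)) {
    stop("length(gene_ids) must equal nrow(values)")
  }
  if (length(timepoints_h) != ncol(values)) {
    stop("length(timepoints_h) must equal ncol(values)")
  }
  if (anyDuplicated(gene_ids)) {
    dup <- unique(gene_ids[duplicated(gene_ids)])
    stop("duplicate gene ids: ", paste(utils::head(dup, 5), collapse = ", "))
  }
  if (any(!is.finite(timepoints_h))) stop("timepoints must be finite numbers")
  if (any(diff(timepoints_h) <= 0)) {
    bad <- which(diff(timepoints_h) <= 0)[1] + 1L
    stop("timepoints must be strictly increasing; offending column ", bad,
         " (t = ", timepoints_h[bad], ")")
  }
  if (!is.numeric(values)) stop("expression values must be numeric")
  storage.mode(values) <- "double"
  rownames(values) <- gene_ids
  colnames(values) <- format(timepoints_h, trim = TRUE)
  structure(
    list(gene_ids = gene_ids, timepoints_h = timepoints_h,
         condition = condition, values = values),
    class = "expr_matrix"
  )
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d timepoints (%s), t = %g..%g h\n",
              length(x$gene_ids), length(x$timepoints_h), x$condition,
              min(x$timepoints_h), max(x$timepoints_h)))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Read an expression matrix from a tab-delimited file
#'
#' The expected dialect is a header row `gene_id<TAB>t0<TAB>t2...` where the
#' column names after the first are sampling times in hours, followed by one
#' row per gene. Input row order is preserved.
#'
#' @param path path to a tab-delimited text file.
#' @param condition condition label to attach to the matrix.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, condition = "control") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2) stop("expected a gene_id column plus >=1 timepoint column")
  times <- suppressWarnings(as.numeric(colnames(df)[-1]))
  if (any(is.na(times))) {
    bad <- which(is.na(times))[1] + 1L
    stop("non-numeric timepoint in header, column ", bad, " ('",
         colnames(df)[bad], "')")
  }
  if (any(diff(times) <= 0)) {
    bad <- which(diff(times) <= 0)[1] + 2L  # +1 for diff, +1 for gene_id col
    stop("header timepoints are not strictly increasing; offending column ",
         bad, " (t = ", times[bad - 1L], ")")
  }
  vals <- matrix(NA_real_, nrow = nrow(df), ncol = ncol(df) - 1L)
  for (j in seq_len(ncol(df) - 1L)) {
    col <- suppressWarnings(as.numeric(df[[j + 1L]]))
    if (anyNA(col)) {
      i <- which(is.na(col))[1]
      stop("non-numeric expression value at row ", i, " (gene '", df[[1]][i],
           "'), column ", j + 1L, " (t = ", times[j], ")")
    }
    vals[, j] <- col
  }
  expression_matrix(vals, times, condition = condition, gene_ids = df[[1]])
}

#' Write an expression matrix to a tab-delimited file
#'
#' Values are written with 17 significant digits so that a write/read
#' round trip reproduces doubles bit-exactly.
#'
#' @param m an [expression_matrix()] (or fold-change matrix).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(m, path) {
  vals <- if (inherits(m, "fold_change_matrix")) m$fc else m$values
  times <- if (inherits(m, "fold_change_matrix")) m$grid_times_h else m$timepoints_h
  ids <- m$gene_ids
  header <- paste(c("gene_id", format_num(times)), collapse = "\t")
  rows <- vapply(seq_along(ids), function(i) {
    paste(c(ids[i], format_num(vals[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

# full-precision decimal rendering (round-trips doubles exactly)
format_num <- function(x) {
  out <- sprintf("%.17g", x)
  whole <- x == round(x) & abs(x) < 1e15
  out[whole] <- sprintf("%.0f", x[whole])
  out
}
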