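#' Per-timepoint fold change between conditions
#'
#' On log-scale data the fold change at a timepoint is the treatment value
#' minus the control value.
#'
#' @param control,treatment `expr_matrix` objects on the same genes and
#'   grid.
#' @return Object of class `fold_change_matrix`: `gene_ids`,
#'   `grid_times_h`, `fc` (genes x timepoints).
#' @export
fold_change <- function(control, treatment) {
  stopifnot(inherits(control, "expr_matrix"), inherits(treatment, "expr_matrix"))
  if (!identical(control$gene_ids, treatment$gene_ids)) {
    stop("gene sets differ between conditions")
  }
  if (!isTRUE(all.equal(control$timepoints_h, treatment$timepoints_h,
                        tolerance = 1e-9))) {
    stop("time grids differ between conditions")
  }
  fc <- treatment$values - control$values
  structure(list(gene_ids = control$gene_ids,
                 grid_times_h = control$timepoints_h, fc = fc),
            class = "fold_change_matrix")
}

#' Rank genes by a fold-change statistic
#'
#' Either the maximum fold change over all timepoints (`"max_fc"`) or the
#' fold change at one fixed timepoint (`"fc_at_time"`, e.g. a known
#' response peak). Ties are broken by input gene order (stable sort) so
#' rankings are deterministic.
#'
#' @param fcm a [fold_change()] matrix.
#' @param statistic `"max_fc"` or `"fc_at_time"`.
#' @param at_time_h timepoint in hours, required for `"fc_at_time"`; must
#'   lie on the grid.
#' @return Object of class `ranked_list`: data frame with `gene_id` and
#'   `statistic` in non-increasing order; the statistic name is in
#'   `attr(, "statistic")`.
#' @export
rank_genes <- function(fcm, statistic = c("max_fc", "fc_at_time"),
                       at_time_h = NULL) {
  stopifnot(inherits(fcm, "fold_change_matrix"))
  statistic <- match.arg(statistic)
  if (statistic == "max_fc") {
    s <- apply(fcm$fc, 1, max)
  } else {
    if (is.null(at_time_h)) stop("at_time_h is required for fc_at_time")
    j <- which(abs(fcm$grid_times_h - at_time_h) < 1e-9)
    if (length(j) != 1) {
      stop("time ", at_time_h, " h is not on the grid (",
           min(fcm$grid_times_h), "..", max(fcm$grid_times_h), " h)")
    }
    s <- fcm$fc[, j]
  }
  ord <- order(-s)  # stable: ties keep input order
  ranked_list(fcm$gene_ids[ord], s[ord], statistic)
}

ranked_list <- function(gene_ids, statistic, name) {
  structure(data.frame(gene_id = gene_ids, statistic = statistic,
                       row.names = NULL, stringsAsFactors = FALSE),
            statistic = name, class = c("ranked_list", "data.frame"))
}

#' ROC walk of a ranked gene list against a gold standard
#'
#' Walking down the ranking, each gene is a true positive if it belongs to
#' the gold-standard set and a false positive otherwise. The headline
#' summary is the recall at the first rank where the cumulative true and
#' false positive counts are equal (the rank beyond which a ranking is no
#' better than chance at 50% precision). If the counts are never equal at
#' positive values, the recall at the last rank with TP > FP is reported
#' (0 if there is none).
#'
#' @param rl a `ranked_list`.
#' @param gold character vector of gold-standard gene ids, a subset of the
#'   ranked universe.
#' @return Object of class `roc_result`: `curve` (data frame `rank`, `tp`,
#'   `fp`), `gold_size`, `recall_at_tp_eq_fp`.
#' @export
roc <- function(rl, gold) {
  stopifnot(inherits(rl, "ranked_list"))
  gold <- unique(as.character(gold))
  if (length(gold) == 0) stop("gold-standard set is empty")
  if (!all(gold %in% rl$gene_id)) {
    stop("gold-standard genes missing from the ranking: ",
         paste(utils::head(setdiff(gold, rl$gene_id), 5), collapse = ", "))
  }
  is_tp <- rl$gene_id %in% gold
  tp <- cumsum(is_tp)
  fp <- cumsum(!is_tp)
  eq <- which(tp == fp & tp > 0)
  if (length(eq) > 0) {
    recall <- tp[eq[1]] / length(gold)
  } else {
    above <- which(tp > fp)
    recall <- if (length(above) > 0) tp[max(above)] / length(gold) else 0
  }
  structure(
    list(curve = data.frame(rank = seq_along(tp), tp = tp, fp = fp),
         gold_size = length(gold), recall_at_tp_eq_fp = recall),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> %d ranked genes, %d gold; recall at TP=FP: %.3f\n",
              nrow(x$curve), x$gold_size, x$recall_at_tp_eq_fp))
  invisible(x)
}

#' Z-test p-values for a ranking statistic
#'
#' Standardises the per-gene statistic across genes and reports one-sided
#' upper-tail normal p-values, flagging genes significant at `alpha`. The
#' upper tail targets treatment-upregulated genes.
#'
#' @param rl a `ranked_list` with at least 3 genes.
#' @param alpha significance threshold for the flags.
#' @return Object of class `ztest_result`: data frame `gene_id`,
#'   `statistic`, `z`, `p`, `significant`.
#' @export
ztest_pvalues <- function(rl, alpha = 0.05) {
  stopifnot(inherits(rl, "ranked_list"))
  x <- rl$statistic
  if (length(x) < 3) stop("need at least 3 genes")
  s <- stats::sd(x)
  if (s <= 0) stop("statistic has zero variance across genes")
  z <- (x - mean(x)) / s
  p <- stats::pnorm(z, lower.tail = FALSE)
  structure(data.frame(gene_id = rl$gene_id, statistic = x, z = z, p = p,
                       significant = p <= alpha, stringsAsFactors = FALSE),
            alpha = alpha, class = c("ztest_result", "data.frame"))
}

#' Rank genes by distance from a corner of the PC1/PC2 score plot
#'
#' Genes are projected onto the first two principal components of the
#' (column-centred) expression or fold-change matrix and ranked by
#' Euclidean distance from the chosen corner of the score range; genes far
#' from the "low everything" corner rank first.
#'
#' @param m an `expr_matrix` or `fold_change_matrix` with >= 3 genes.
#' @param corner `"bottom-left"` or `"bottom-right"` of the PC1/PC2 plot.
#' @return A `ranked_list` ordered by decreasing corner distance.
#' @export
pca_distance_rank <- function(m, corner = c("bottom-left", "bottom-right")) {
  corner <- match.arg(corner)
  x <- if (inherits(m, "fold_change_matrix")) m$fc else m$values
  ids <- m$gene_ids
  if (nrow(x) < 3) stop("need at least 3 genes")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  if (length(pc$sdev) < 2 || pc$sdev[2] < 1e-12 * pc$sdev[1]) {
    stop("input is rank-deficient; fewer than two informative components")
  }
  s <- pc$x[, 1:2, drop = FALSE]
  cx <- if (corner == "bottom-left") min(s[, 1]) else max(s[, 1])
  cy <- min(s[, 2])
  d <- sqrt((s[, 1] - cx)^2 + (s[, 2] - cy)^2)
  ord <- order(-d)
  ranked_list(ids[ord], d[ord], "pca_distance")
}
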