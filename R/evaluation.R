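# Evaluation against a gold-standard network: confusion counts in two
# counting modes, ratio metrics (TPR/FPR/PPV/ACC/MCC) with explicit
# undefined handling, and threshold-sweep ROC/AUC.

# Canonical unordered pair keys "a|b" with a < b lexicographically.
.pair_key <- function(a, b) {
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  paste(a, b, sep = "\r")
}

# Normalize a gold standard to a set of positive pair keys. Accepts a
# `gold_standard` from read_gold_standard() or a data.frame/matrix whose
# first two columns are the positive edges. Directed entries collapse to
# unordered pairs.
.gold_positive_keys <- function(gold) {
  if (inherits(gold, "gold_standard")) {
    edges <- gold$edges
  } else {
    edges <- as.data.frame(gold, stringsAsFactors = FALSE)
  }
  if (nrow(edges) == 0) return(character())
  unique(.pair_key(as.character(edges[[1]]), as.character(edges[[2]])))
}

.gold_genes <- function(gold) {
  if (inherits(gold, "gold_standard")) return(gold$genes)
  edges <- as.data.frame(gold, stringsAsFactors = FALSE)
  unique(c(as.character(edges[[1]]), as.character(edges[[2]])))
}

#' Confusion counts of a predicted network against a gold standard
#'
#' Compares the undirected edge set of an inferred network with a gold
#' standard over all gene pairs of the prediction universe. Directed gold
#' edges are collapsed to unordered pairs; pairs absent from the gold
#' standard (and its explicit 0 rows) count as negatives.
#'
#' Two counting modes are supported: `"pairs"` counts each unordered gene
#' pair once (n(n-1)/2 units); `"matrix"` counts each off-diagonal cell of
#' the symmetric adjacency matrix (n(n-1) units), exactly doubling all four
#' counts -- the convention under which a 77-edge undirected network
#' contributes TP + FN = 154.
#'
#' @param predicted a `grn_network` from [infer_network()], or a
#'   data.frame in [edge_table()] layout (columns `gene_a`, `gene_b`,
#'   `present`).
#' @param gold a `gold_standard` from [read_gold_standard()], or a
#'   data.frame of positive edges (first two columns gene names).
#' @param mode `"pairs"` (default) or `"matrix"`.
#' @return An object of class `confusion_counts`: list with integer
#'   `tp`, `fp`, `tn`, `fn` and the `mode`.
#' @export
confusion <- function(predicted, gold, mode = c("pairs", "matrix")) {
  mode <- match.arg(mode)
  if (inherits(predicted, "grn_network")) {
    tab <- edge_table(predicted)
    genes <- predicted$genes
  } else {
    tab <- as.data.frame(predicted, stringsAsFactors = FALSE)
    if (!all(c("gene_a", "gene_b", "present") %in% names(tab))) {
      stop("predicted must be a grn_network or an edge table with ",
           "gene_a/gene_b/present columns")
    }
    genes <- unique(c(tab$gene_a, tab$gene_b))
  }
  missing <- setdiff(.gold_genes(gold), genes)
  if (length(missing) > 0) {
    stop("gold-standard genes absent from the prediction universe: ",
         paste(missing, collapse = ", "))
  }
  pos_keys <- .gold_positive_keys(gold)
  pred_keys <- .pair_key(tab$gene_a, tab$gene_b)[tab$present]
  n <- length(genes)
  n_pairs <- n * (n - 1) / 2
  tp <- sum(pred_keys %in% pos_keys)
  fp <- length(pred_keys) - tp
  fn <- length(pos_keys) - tp
  tn <- n_pairs - tp - fp - fn
  mult <- if (mode == "matrix") 2L else 1L
  structure(list(tp = mult * tp, fp = mult * fp, tn = mult * tn,
                 fn = mult * fn, mode = mode),
            class = "confusion_counts")
}

#' Build confusion counts directly
#'
#' @param tp,fp,tn,fn nonnegative integers.
#' @param mode counting mode label, `"pairs"` or `"matrix"`.
#' @return A `confusion_counts` object, as [confusion()].
#' @export
confusion_counts <- function(tp, fp, tn, fn, mode = c("pairs", "matrix")) {
  mode <- match.arg(mode)
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("counts must be nonnegative integers")
  }
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn, mode = mode),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("Confusion counts (%s mode): TP=%d FP=%d TN=%d FN=%d\n",
              x$mode, x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' Ratio metrics from confusion counts
#'
#' Applies the standard formulas:
#' `TPR = TP/(TP+FN)`, `FPR = FP/(FP+TN)`, `PPV = TP/(TP+FP)`,
#' `ACC = (TP+TN)/(TP+FP+TN+FN)`,
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.
#' A metric whose denominator is zero is reported as `NA` (undefined),
#' never silently as 0 -- small networks routinely hit empty classes.
#'
#' @param counts a `confusion_counts` object.
#' @return An object of class `grn_metrics`: list with `tpr`, `fpr`,
#'   `ppv`, `acc`, `mcc` and the input `counts`.
#' @export
#' @examples
#' metrics(confusion_counts(tp = 17, fp = 3, tn = 9, fn = 7, mode = "matrix"))
metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  rat <- function(num, den) if (den == 0) NA_real_ else num / den
  mcc_den <- sqrt(as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  structure(list(
    tpr = rat(tp, tp + fn),
    fpr = rat(fp, fp + tn),
    ppv = rat(tp, tp + fp),
    acc = rat(tp + tn, tp + fp + tn + fn),
    mcc = if (mcc_den == 0) NA_real_ else (tp * tn - fp * fn) / mcc_den,
    counts = counts
  ), class = "grn_metrics")
}

#' @export
print.grn_metrics <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.3f", v)
  cat(sprintf("TPR=%s FPR=%s PPV=%s ACC=%s MCC=%s\n",
              fmt(x$tpr), fmt(x$fpr), fmt(x$ppv), fmt(x$acc), fmt(x$mcc)))
  invisible(x)
}

#' ROC curve and AUC from a scored pair ranking
#'
#' Sweeps a decision threshold over the distinct scores of a ranking (ties
#' grouped at a single operating point), accumulating TPR against FPR with
#' the gold standard defining positives, and integrates the curve by the
#' trapezoid rule. The result equals the Mann-Whitney rank statistic on the
#' same scores.
#'
#' @param ranking data.frame with columns `gene_a`, `gene_b`, `score`
#'   covering every evaluated pair (e.g. [edge_ranking()] output).
#' @param gold gold standard as in [confusion()].
#' @param mode counting mode label, kept for provenance; the curve and AUC
#'   are identical in both modes.
#' @return An object of class `roc_curve`: list with `auc` (`NA` if the
#'   gold standard has no positives or no negatives among the ranked pairs)
#'   and `points`, a data.frame of (`fpr`, `tpr`) from (0,0) to (1,1).
#' @export
roc_auc <- function(ranking, gold, mode = c("pairs", "matrix")) {
  mode <- match.arg(mode)
  ranking <- as.data.frame(ranking, stringsAsFactors = FALSE)
  if (!all(c("gene_a", "gene_b", "score") %in% names(ranking))) {
    stop("ranking must have gene_a, gene_b and score columns")
  }
  if (any(!is.finite(ranking$score))) stop("every pair must have a finite score")
  keys <- .pair_key(ranking$gene_a, ranking$gene_b)
  if (anyDuplicated(keys)) stop("duplicate pairs in ranking")
  label <- keys %in% .gold_positive_keys(gold)
  P <- sum(label)
  N <- sum(!label)
  if (P == 0 || N == 0) {
    return(structure(list(auc = NA_real_,
                          points = data.frame(fpr = c(0, 1), tpr = c(0, 1)),
                          mode = mode),
                     class = "roc_curve"))
  }
  ord <- order(ranking$score, decreasing = TRUE)
  sc <- ranking$score[ord]
  lb <- label[ord]
  grp <- cumsum(!duplicated(sc))          # tie groups share one point
  tp_cum <- cumsum(lb)
  fp_cum <- cumsum(!lb)
  last <- which(!duplicated(grp, fromLast = TRUE))
  tpr <- c(0, tp_cum[last] / P)
  fpr <- c(0, fp_cum[last] / N)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(auc = auc, points = data.frame(fpr = fpr, tpr = tpr),
                 mode = mode),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat("ROC curve:", nrow(x$points), "points, AUC =",
      if (is.na(x$auc)) "undefined" else sprintf("%.4f", x$auc), "\n")
  invisible(x)
}
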