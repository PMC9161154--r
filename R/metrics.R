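#' Area under the ROC curve
#'
#' Mann--Whitney probability estimate: the probability that a random class-1
#' score exceeds a random class-0 score, ties counting one half.
#'
#' @param scores Class-1 scores per sample.
#' @param labels Binary labels (0/1, logical, or two-level factor).
#' @return AUC in [0, 1].
#' @export
auc_score <- function(scores, labels) {
  labels <- as_binary_labels(labels, length(scores))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)  # midranks handle ties as 1/2
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Matthews correlation coefficient
#'
#' \eqn{(TP \cdot TN - FP \cdot FN) / \sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}};
#' any zero factor in the denominator yields 0 (documented convention so a
#' degenerate fold does not crash a long cross-validation run).
#'
#' @param tp,fp,tn,fn Non-negative confusion counts.
#' @return MCC in [-1, 1].
#' @export
mcc_score <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0)) stop("confusion counts must be non-negative")
  if (sum(counts) == 0) stop("empty confusion matrix")
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

#' Lustgarten adjusted stability measure (ASM)
#'
#' Chance-corrected pairwise overlap of selected-feature sets across
#' cross-validation folds: the mean over all unordered pairs (i, j) of
#' \deqn{(|S_i \cap S_j| - |S_i| |S_j| / n) /
#'       (\min(|S_i|, |S_j|) - \max(0, |S_i| + |S_j| - n)).}
#' Pairs with a zero denominator contribute 0 (with a warning). Higher
#' values mean more stable selection; identical sets of size s score
#' \eqn{1 - s/n}.
#'
#' @param sets List of >= 2 feature sets (vectors of unique ids).
#' @param n Size of the feature universe (the number of genes entering the
#'   ranking stage).
#' @return The ASM value.
#' @export
lustgarten_asm <- function(sets, n) {
  if (length(sets) < 2L) stop("need >= 2 sets")
  sets <- lapply(sets, unique)
  sizes <- lengths(sets)
  if (any(sizes > n)) stop("a set exceeds the universe size n")
  total <- 0; pairs <- 0L; degenerate <- FALSE
  L <- length(sets)
  for (i in seq_len(L - 1L)) {
    for (j in (i + 1L):L) {
      si <- sizes[i]; sj <- sizes[j]
      den <- min(si, sj) - max(0L, si + sj - n)
      pairs <- pairs + 1L
      if (den == 0) { degenerate <- TRUE; next }  # contributes 0
      inter <- length(intersect(sets[[i]], sets[[j]]))
      total <- total + (inter - si * sj / n) / den
    }
  }
  if (degenerate)
    warning("ASM: pair(s) with zero denominator contributed 0")
  total / pairs
}

#' Log2 fold change between the two classes
#'
#' Default (\code{method = "linear"}): per gene, the class means are taken
#' on the linear scale, \eqn{GE_c = mean(2^{x})}, and
#' \eqn{Log2FC = \log_2(GE_1 / GE_0)}; positive values mean overexpression
#' in class 1. The alternative \code{"logdiff"} reports the difference of
#' log2 class means.
#'
#' @param dataset An \code{\link{expression_dataset}} of log2 values.
#' @param genes Genes to report (default all).
#' @param method \code{"linear"} (ratio of linear-scale means, default) or
#'   \code{"logdiff"}.
#' @return data.frame with columns \code{gene_id}, \code{log2fc} and
#'   \code{direction} ("over"/"under" in class 1).
#' @export
log2fc <- function(dataset, genes = NULL, method = c("linear", "logdiff")) {
  method <- match.arg(method)
  x <- dataset$values
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(x))
    if (length(missing)) stop("unknown gene id: ", paste(missing, collapse = ", "))
    x <- x[genes, , drop = FALSE]
  }
  i1 <- dataset$labels == 1L; i0 <- dataset$labels == 0L
  if (!any(i1) || !any(i0)) stop("both classes must be nonempty")
  if (method == "linear") {
    ge1 <- rowMeans(2^x[, i1, drop = FALSE])
    ge0 <- rowMeans(2^x[, i0, drop = FALSE])
    if (any(ge0 == 0)) stop("class-0 linear mean of 0")
    lfc <- log2(ge1 / ge0)
  } else {
    lfc <- rowMeans(x[, i1, drop = FALSE]) - rowMeans(x[, i0, drop = FALSE])
  }
  data.frame(gene_id = rownames(x), log2fc = unname(lfc),
             direction = ifelse(lfc >= 0, "over", "under"),
             stringsAsFactors = FALSE)
}
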