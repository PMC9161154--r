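#' Log2 transform an expression matrix
#'
#' \code{out = log2(value + offset)}; monotone and invertible given the
#' offset.
#'
#' @param values Non-negative numeric matrix (or vector).
#' @param offset Small constant added before taking logs (default 1).
#' @return Matrix (or vector) of log2 values.
#' @export
log2_transform <- function(values, offset = 1) {
  if (any(values < 0)) stop("expression values must be non-negative")
  log2(values + offset)
}

#' Robust coefficient of variation per gene
#'
#' \code{(IQR / 1.349) / |median|}, the interquartile range scaled to a
#' robust SD surrogate over the absolute median. Genes with median 0 get
#' \code{Inf} when their IQR is positive and 0 otherwise.
#'
#' @param values Numeric matrix, genes x samples.
#' @return Named numeric vector of robust CVs.
#' @export
robust_cv <- function(values) {
  med <- apply(values, 1L, median)
  iqr <- apply(values, 1L, IQR)
  rsd <- iqr / 1.349
  out <- ifelse(med == 0, ifelse(iqr > 0, Inf, 0), rsd / abs(med))
  names(out) <- rownames(values)
  out
}

#' Criteria for unsupervised gene filtering
#'
#' @param rcv_min Minimum robust coefficient of variation (strict >),
#'   default 0.05.
#' @param ge_threshold Log2 expression threshold of the detection rule
#'   (dataset-specific; see \code{\link{suggest_ge_threshold}} for a
#'   heuristic).
#' @param min_fraction Minimum fraction of samples that must exceed
#'   \code{ge_threshold} (default 0.10).
#' @return A \code{filter_criteria} object.
#' @export
filter_criteria <- function(rcv_min = 0.05, ge_threshold, min_fraction = 0.10) {
  if (rcv_min < 0) stop("rcv_min must be >= 0")
  if (min_fraction <= 0 || min_fraction > 1)
    stop("min_fraction must be in (0, 1]")
  structure(list(rcv_min = rcv_min, ge_threshold = ge_threshold,
                 min_fraction = min_fraction),
            class = "filter_criteria")
}

#' Unsupervised gene filter
#'
#' Keeps exactly the genes with robust CV strictly above
#' \code{criteria$rcv_min} and with at least \code{criteria$min_fraction}
#' of samples above \code{criteria$ge_threshold}. Labels are untouched and
#' gene order is preserved. Idempotent.
#'
#' @param dataset An \code{\link{expression_dataset}}.
#' @param criteria A \code{\link{filter_criteria}}.
#' @return The filtered \code{expression_dataset}.
#' @export
unsupervised_filter <- function(dataset, criteria) {
  if (!inherits(criteria, "filter_criteria"))
    stop("`criteria` must be a filter_criteria")
  x <- dataset$values
  keep <- robust_cv(x) > criteria$rcv_min &
    rowMeans(x > criteria$ge_threshold) >= criteria$min_fraction
  if (!any(keep)) stop("empty after filtering: no gene passes both criteria")
  subset_dataset(dataset, genes = which(keep))
}

#' Heuristic detection threshold from the gene-retention curve
#'
#' Evaluates the detection rule (fraction of samples above a threshold >=
#' \code{min_fraction}) over a grid of candidate thresholds and returns the
#' knee point: the grid value with the largest second difference of the
#' retained-gene count, i.e. where the retention curve bends fastest. A
#' convenience heuristic only -- the threshold is a dataset-specific choice.
#'
#' @param dataset An \code{\link{expression_dataset}}.
#' @param min_fraction Detection fraction of the rule (default 0.10).
#' @param grid Candidate thresholds; default 41 quantiles of the expression
#'   values between 1\% and 99\%.
#' @return The suggested threshold (scalar), with the retention curve
#'   attached as attribute \code{curve}.
#' @export
suggest_ge_threshold <- function(dataset, min_fraction = 0.10, grid = NULL) {
  x <- dataset$values
  if (is.null(grid))
    grid <- unname(quantile(x, probs = seq(0.01, 0.99, length.out = 41L)))
  retained <- vapply(grid, function(t) sum(rowMeans(x > t) >= min_fraction),
                     numeric(1))
  if (length(grid) < 3L) stop("grid too short for a knee point")
  d2 <- diff(diff(retained))
  knee <- which.max(abs(d2)) + 1L
  out <- grid[knee]
  attr(out, "curve") <- data.frame(threshold = grid, retained = retained)
  out
}

#' Merge two expression datasets on their shared genes
#'
#' Restricts both datasets to the intersection of their gene ids (in the
#' first dataset's order) and concatenates the samples; the batch labels of
#' the merged dataset record the dataset of origin.
#'
#' @param d1,d2 \code{\link{expression_dataset}} objects with disjoint
#'   sample ids and at least one shared gene.
#' @param batch_names Length-2 names recorded as batch labels, default
#'   \code{c("dataset1", "dataset2")}.
#' @return The merged \code{expression_dataset}.
#' @export
merge_datasets <- function(d1, d2, batch_names = c("dataset1", "dataset2")) {
  shared <- intersect(rownames(d1$values), rownames(d2$values))
  if (length(shared) == 0L) stop("merge error: no overlapping genes")
  dup <- intersect(colnames(d1$values), colnames(d2$values))
  if (length(dup))
    stop("duplicate sample ids across datasets: ",
         paste(head(dup, 5), collapse = ", "))
  values <- cbind(d1$values[shared, , drop = FALSE],
                  d2$values[shared, , drop = FALSE])
  labels <- c(d1$labels, d2$labels)
  batches <- c(rep(batch_names[1], ncol(d1$values)),
               rep(batch_names[2], ncol(d2$values)))
  truth <- unique(rbind(d1$truth, d2$truth))
  if (!is.null(truth)) {
    truth <- truth[truth$gene_id %in% shared, , drop = FALSE]
    if (nrow(truth) == 0L) truth <- NULL
  }
  expression_dataset(values, labels, batches = batches, truth = truth)
}

#' Naive location/scale batch centering
#'
#' Per gene and batch, subtracts the batch mean and divides by the batch
#' SD, then restores the gene's global mean and pooled within-batch SD, so
#' that after correction every batch has the same per-gene mean. This is a
#' simple location/scale correction; empirical-Bayes corrections (ComBat)
#' are out of scope and pre-corrected matrices can be supplied directly.
#'
#' @param dataset An \code{\link{expression_dataset}} with batch labels
#'   (>= 2 batches, each with >= 2 samples).
#' @return The corrected \code{expression_dataset}.
#' @export
batch_center <- function(dataset) {
  if (is.null(dataset$batches)) stop("batch labels are required")
  batches <- dataset$batches
  blev <- unique(batches)
  if (length(blev) < 2L) stop("need >= 2 batches, got 1")
  sizes <- table(batches)
  small <- names(sizes)[sizes < 2L]
  if (length(small))
    stop("batch with < 2 samples: ", paste(small, collapse = ", "))

  x <- dataset$values
  gmean <- rowMeans(x)
  wsum <- rep(0, nrow(x)); wdf <- 0
  stats <- lapply(blev, function(b) {
    xb <- x[, batches == b, drop = FALSE]
    m <- rowMeans(xb)
    s <- sqrt(rowSums((xb - m)^2) / (ncol(xb) - 1))
    list(b = b, m = m, s = s, n = ncol(xb))
  })
  for (st in stats) {
    wsum <- wsum + (st$n - 1) * st$s^2
    wdf <- wdf + (st$n - 1)
  }
  pooled_sd <- sqrt(wsum / wdf)

  out <- x
  for (st in stats) {
    cols <- batches == st$b
    z <- (x[, cols, drop = FALSE] - st$m) / ifelse(st$s > 0, st$s, 1)
    z[st$s == 0, ] <- 0
    out[, cols] <- z * pooled_sd + gmean
  }
  expression_dataset(out, dataset$labels, batches = batches,
                     truth = dataset$truth)
}

#' Per-gene distribution diagnostics
#'
#' For each gene: sample skewness per class, variance-equality p-values by
#' a median-centered test (Brown--Forsythe/Levene) and by Bartlett's
#' normal-theory test, and per-class normality p-values from the one-sample
#' Kolmogorov--Smirnov test against a normal with the class's estimated
#' mean and SD (the estimated-parameter bias of this KS variant is
#' accepted). The summary reports the fraction of genes with |skewness|
#' <= 0.5 per class, the fractions with variance-equality p > 0.05 per
#' test, and the fraction with normality p > 0.05 in both classes.
#'
#' @param dataset An \code{\link{expression_dataset}} with >= 3 samples in
#'   each class.
#' @return A \code{diagnostics_table}: list with a per-gene \code{table}
#'   and a \code{summary} list of fractions.
#' @export
distribution_diagnostics <- function(dataset) {
  y <- dataset$labels
  if (sum(y == 1L) < 3L || sum(y == 0L) < 3L)
    stop("each class needs >= 3 samples for diagnostics")
  x <- dataset$values
  i1 <- y == 1L; i0 <- y == 0L

  skewness <- function(v) {
    m <- mean(v); s2 <- mean((v - m)^2)
    if (s2 == 0) return(0)
    mean((v - m)^3) / s2^1.5
  }
  levene_p <- function(v) {
    # Brown-Forsythe: anova on |x - class median|
    z <- abs(c(v[i1] - median(v[i1]), v[i0] - median(v[i0])))
    g <- factor(c(rep(1L, sum(i1)), rep(0L, sum(i0))))
    if (all(z == z[1])) return(1)
    anova(lm(z ~ g))[["Pr(>F)"]][1]
  }
  safe_ks <- function(v) {
    if (sd(v) == 0) return(0)
    suppressWarnings(ks.test(v, "pnorm", mean(v), sd(v))$p.value)
  }
  tab <- data.frame(
    gene_id = rownames(x),
    skew_class1 = apply(x[, i1, drop = FALSE], 1L, skewness),
    skew_class0 = apply(x[, i0, drop = FALSE], 1L, skewness),
    levene_p = apply(x, 1L, levene_p),
    bartlett_p = apply(x, 1L, function(v) {
      if (sd(v[i1]) == 0 || sd(v[i0]) == 0) return(NA_real_)
      bartlett.test(list(v[i1], v[i0]))$p.value
    }),
    ks_p_class1 = apply(x[, i1, drop = FALSE], 1L, safe_ks),
    ks_p_class0 = apply(x[, i0, drop = FALSE], 1L, safe_ks),
    stringsAsFactors = FALSE
  )
  rownames(tab) <- NULL
  summary <- list(
    frac_symmetric_class1 = mean(abs(tab$skew_class1) <= 0.5),
    frac_symmetric_class0 = mean(abs(tab$skew_class0) <= 0.5),
    frac_equal_var_levene = mean(tab$levene_p > 0.05),
    frac_equal_var_bartlett = mean(tab$bartlett_p > 0.05, na.rm = TRUE),
    frac_normal_both = mean(tab$ks_p_class1 > 0.05 & tab$ks_p_class0 > 0.05)
  )
  structure(list(table = tab, summary = summary),
            class = "diagnostics_table")
}

#' @export
print.diagnostics_table <- function(x, ...) {
  s <- x$summary
  cat(sprintf("distribution diagnostics over %d genes\n", nrow(x$table)))
  cat(sprintf("  |skewness| <= 0.5:      class 1 %.0f%%, class 0 %.0f%%\n",
              100 * s$frac_symmetric_class1, 100 * s$frac_symmetric_class0))
  cat(sprintf("  equal variances (p > 0.05): Levene %.0f%%, Bartlett %.0f%%\n",
              100 * s$frac_equal_var_levene, 100 * s$frac_equal_var_bartlett))
  cat(sprintf("  normal in both classes (KS p > 0.05): %.0f%%\n",
              100 * s$frac_normal_both))
  invisible(x)
}
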