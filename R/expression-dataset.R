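#' Construct an expression dataset
#'
#' Bundles a log2 expression matrix (genes in rows, samples in columns) with
#' a binary class label per sample, optional batch labels, and an optional
#' ground-truth table of informative genes (used by the synthetic-data
#' generator and by recovery tests).
#'
#' @param values Numeric matrix of log2 expression, genes x samples, with
#'   unique non-empty rownames (gene ids) and colnames (sample ids). All
#'   values must be finite.
#' @param labels Binary class per sample: a 0/1 numeric vector, logical
#'   vector, or two-level factor, length \code{ncol(values)}. Class 1 is the
#'   positive class. Both classes must be present.
#' @param batches Optional batch id per sample (character/factor), length
#'   \code{ncol(values)}.
#' @param truth Optional data.frame describing ground-truth informative
#'   genes, with columns \code{gene_id}, \code{effect} (signed log2-units
#'   class-1 mean shift) and \code{kind} (\code{"shift"}, \code{"xor"} or
#'   \code{"block"}). All \code{gene_id}s must be rownames of \code{values}.
#'
#' @return An object of class \code{expression_dataset}: a list with
#'   elements \code{values}, \code{labels} (named integer 0/1),
#'   \code{batches} (named character or NULL) and \code{truth}.
#' @export
expression_dataset <- function(values, labels, batches = NULL, truth = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (genes x samples)")
  gene_ids <- rownames(values)
  sample_ids <- colnames(values)
  if (is.null(gene_ids) || anyNA(gene_ids) || any(gene_ids == ""))
    stop("`values` must have non-empty rownames (gene ids)")
  if (is.null(sample_ids) || anyNA(sample_ids) || any(sample_ids == ""))
    stop("`values` must have non-empty colnames (sample ids)")
  if (anyDuplicated(gene_ids))
    stop("duplicate gene ids: ", paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ", paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (!all(is.finite(values)))
    stop("`values` contains non-finite entries")

  labels <- as_binary_labels(labels, n = ncol(values))
  names(labels) <- sample_ids

  if (!is.null(batches)) {
    if (length(batches) != ncol(values))
      stop("`batches` must have one entry per sample")
    batches <- as.character(batches)
    names(batches) <- sample_ids
  }

  if (!is.null(truth)) {
    truth <- as.data.frame(truth, stringsAsFactors = FALSE)
    need <- c("gene_id", "effect", "kind")
    if (!all(need %in% names(truth)))
      stop("`truth` needs columns: ", paste(need, collapse = ", "))
    bad <- setdiff(truth$gene_id, gene_ids)
    if (length(bad))
      stop("truth genes not in the matrix: ", paste(head(bad, 5), collapse = ", "))
  }

  structure(list(values = values, labels = labels, batches = batches,
                 truth = truth),
            class = "expression_dataset")
}

as_binary_labels <- function(labels, n) {
  if (length(labels) != n)
    stop("`labels` must have one entry per sample")
  if (is.factor(labels)) {
    if (nlevels(droplevels(labels)) != 2L) stop("`labels` must have exactly two classes")
    labels <- as.integer(droplevels(labels)) - 1L
  } else if (is.logical(labels)) {
    labels <- as.integer(labels)
  } else {
    labels <- as.integer(labels)
  }
  if (anyNA(labels) || !all(labels %in% c(0L, 1L)))
    stop("`labels` must be binary (0/1)")
  if (length(unique(labels)) < 2L)
    stop("`labels` must contain both classes")
  labels
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression_dataset: %d genes x %d samples (class 1: %d, class 0: %d)\n",
              nrow(x$values), ncol(x$values), sum(x$labels == 1L), sum(x$labels == 0L)))
  if (!is.null(x$batches))
    cat("  batches:", paste(sprintf("%s (n=%d)", names(table(x$batches)), table(x$batches)),
                            collapse = ", "), "\n")
  if (!is.null(x$truth))
    cat("  ground truth:", nrow(x$truth), "informative genes\n")
  invisible(x)
}

# Subset an expression dataset by genes and/or samples (indices, logicals or
# ids). Truth is restricted to the retained genes.
subset_dataset <- function(dataset, genes = NULL, samples = NULL) {
  values <- dataset$values
  if (!is.null(genes)) values <- values[genes, , drop = FALSE]
  if (!is.null(samples)) values <- values[, samples, drop = FALSE]
  truth <- dataset$truth
  if (!is.null(truth)) {
    truth <- truth[truth$gene_id %in% rownames(values), , drop = FALSE]
    if (nrow(truth) == 0L) truth <- NULL
  }
  batches <- dataset$batches
  if (!is.null(batches)) batches <- batches[colnames(values)]
  labels <- dataset$labels[colnames(values)]
  if (length(unique(labels)) < 2L)
    stop("subset would leave a single class")
  expression_dataset(values, labels, batches = batches, truth = truth)
}

#' Write an expression dataset as plain-text TSV files
#'
#' Writes \code{<prefix>_matrix.tsv} (first column \code{gene_id}, one
#' column per sample), \code{<prefix>_labels.tsv} (\code{sample_id},
#' \code{label}), and, when present, \code{<prefix>_batches.tsv}
#' (\code{sample_id}, \code{batch}) and \code{<prefix>_truth.tsv}
#' (\code{gene_id}, \code{signed_effect}, \code{kind}). Expression values
#' are written with 17 significant digits so the numeric content
#' round-trips exactly through the text representation.
#'
#' @param dataset An \code{expression_dataset}.
#' @param dir Output directory (created if missing).
#' @param prefix File name prefix, default \code{"dataset"}.
#' @return Invisibly, a named character vector of the files written.
#' @export
write_expression_dataset <- function(dataset, dir, prefix = "dataset") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(matrix = file.path(dir, paste0(prefix, "_matrix.tsv")),
             labels = file.path(dir, paste0(prefix, "_labels.tsv")))
  vals <- formatC(dataset$values, digits = 17, format = "g")
  df <- data.frame(gene_id = rownames(dataset$values), vals,
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("gene_id", colnames(dataset$values))
  write.table(df, paths["matrix"], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(sample_id = names(dataset$labels),
                         label = unname(dataset$labels)),
              paths["labels"], sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(dataset$batches)) {
    paths["batches"] <- file.path(dir, paste0(prefix, "_batches.tsv"))
    write.table(data.frame(sample_id = names(dataset$batches),
                           batch = unname(dataset$batches)),
                paths["batches"], sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(dataset$truth)) {
    paths["truth"] <- file.path(dir, paste0(prefix, "_truth.tsv"))
    write.table(data.frame(gene_id = dataset$truth$gene_id,
                           signed_effect = formatC(dataset$truth$effect,
                                                   digits = 17, format = "g"),
                           kind = dataset$truth$kind),
                paths["truth"], sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(paths)
}

#' Read an expression dataset from TSV files
#'
#' Counterpart of \code{\link{write_expression_dataset}}. The matrix file
#' must have a \code{gene_id} first column and a header of sample ids.
#'
#' @param matrix_path Path to the expression matrix TSV.
#' @param labels_path Path to the labels TSV (\code{sample_id},
#'   \code{label}).
#' @param batches_path,truth_path Optional paths to the batch and
#'   ground-truth TSVs.
#' @return An \code{expression_dataset}.
#' @export
read_expression_dataset <- function(matrix_path, labels_path,
                                    batches_path = NULL, truth_path = NULL) {
  m <- read.delim(matrix_path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(m)[1] != "gene_id") stop("matrix file must start with a gene_id column")
  values <- as.matrix(m[, -1, drop = FALSE])
  rownames(values) <- m$gene_id
  lab <- read.delim(labels_path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "label") %in% names(lab)))
    stop("labels file needs columns sample_id, label")
  if (!setequal(lab$sample_id, colnames(values)))
    stop("labels file does not match the matrix sample ids")
  labels <- lab$label[match(colnames(values), lab$sample_id)]
  batches <- NULL
  if (!is.null(batches_path)) {
    b <- read.delim(batches_path, stringsAsFactors = FALSE)
    batches <- b$batch[match(colnames(values), b$sample_id)]
  }
  truth <- NULL
  if (!is.null(truth_path)) {
    tr <- read.delim(truth_path, stringsAsFactors = FALSE)
    truth <- data.frame(gene_id = tr$gene_id, effect = tr$signed_effect,
                        kind = tr$kind, stringsAsFactors = FALSE)
  }
  expression_dataset(values, labels, batches = batches, truth = truth)
}
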