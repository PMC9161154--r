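#' Deterministic repeated stratified cross-validation plan
#'
#' Assigns every sample to exactly one of \code{n_folds} folds in each of
#' \code{n_repeats} repeats, stratified by class so every test fold
#' contains both classes; overall fold sizes differ by at most one (class
#' remainders go to the currently smallest folds).
#'
#' @param labels Binary labels (named by sample id if available).
#' @param n_repeats Number of repeats R (default 50).
#' @param n_folds Number of folds k (default 5).
#' @param seed Integer seed; the plan is deterministic given the seed.
#' @param stratified Set to FALSE for plain random partitions.
#' @return A \code{cv_plan}: list with \code{folds} (list of per-repeat
#'   integer fold assignments), \code{sample_ids}, \code{n_repeats},
#'   \code{n_folds}, \code{seed}.
#' @export
make_cv_plan <- function(labels, n_repeats = 50L, n_folds = 5L, seed = 1L,
                         stratified = TRUE) {
  sample_ids <- names(labels)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_along(labels))
  labels <- as_binary_labels(labels, length(labels))
  k <- as.integer(n_folds)
  if (stratified && any(table(labels) < k))
    stop("a class has fewer samples than n_folds; stratified CV impossible")
  if (!stratified && length(labels) < k)
    stop("fewer samples than folds")

  folds <- with_seed(as.integer(seed), {
    lapply(seq_len(n_repeats), function(r) {
      assign <- integer(length(labels))
      if (stratified) {
        fold_tot <- rep(0L, k)
        tab <- table(labels)
        for (lab_name in names(tab)[order(-tab)]) {
          lab <- as.integer(lab_name)
          idx <- sample(which(labels == lab))
          base <- length(idx) %/% k; rem <- length(idx) %% k
          sizes <- rep(base, k)
          if (rem > 0L) {
            extra <- order(fold_tot, runif(k))[seq_len(rem)]
            sizes[extra] <- sizes[extra] + 1L
          }
          assign[idx] <- rep(seq_len(k), times = sizes)
          fold_tot <- fold_tot + sizes
        }
      } else {
        idx <- sample(length(labels))
        sizes <- rep(length(labels) %/% k, k)
        rem <- length(labels) %% k
        if (rem > 0L) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
        assign[idx] <- rep(seq_len(k), times = sizes)
      }
      assign
    })
  })
  structure(list(folds = folds, sample_ids = sample_ids,
                 n_repeats = as.integer(n_repeats), n_folds = k,
                 seed = as.integer(seed), stratified = stratified),
            class = "cv_plan")
}

#' Prune correlated genes from a ranked list
#'
#' Scans the ranking from best to worst and drops every gene whose absolute
#' Spearman correlation with an already-kept gene exceeds \code{rho_max};
#' kept genes preserve their original order. Correlations are computed on
#' the supplied (training) values only. Constant genes have undefined
#' correlation and are treated as uncorrelated (kept).
#'
#' @param ranked A \code{\link{ranked_gene_list}}.
#' @param train_values Genes x samples matrix of the training partition (or
#'   an \code{expression_dataset}).
#' @param rho_max Correlation threshold, default 0.7 (strict >).
#' @param n_keep Stop early once this many survivors are found (default
#'   all).
#' @return The pruned \code{ranked_gene_list}; dropped gene ids in
#'   attribute \code{dropped}.
#' @export
prune_correlated <- function(ranked, train_values, rho_max = 0.7,
                             n_keep = Inf) {
  if (inherits(train_values, "expression_dataset"))
    train_values <- train_values$values
  genes <- ranked$gene_id
  if (length(genes) == 0L) return(ranked)
  if (!all(genes %in% rownames(train_values)))
    stop("ranked genes missing from the training values")
  n <- ncol(train_values)
  # standardized midranks: crossprod gives the Spearman correlation
  zr <- apply(train_values[genes, , drop = FALSE], 1L, function(v) {
    r <- rank(v)
    s <- sd(r)
    if (s == 0) rep(0, n) else (r - mean(r)) / (s * sqrt(n - 1))
  })  # n x length(genes)

  keep <- logical(length(genes))
  kept_cols <- matrix(numeric(0), nrow = n, ncol = 0)
  for (g in seq_along(genes)) {
    if (ncol(kept_cols) > 0) {
      rho <- abs(crossprod(kept_cols, zr[, g]))
      if (any(rho > rho_max)) next
    }
    keep[g] <- TRUE
    kept_cols <- cbind(kept_cols, zr[, g])
    if (sum(keep) >= n_keep) break
  }
  scanned <- if (sum(keep) >= n_keep) seq_len(g) else seq_along(genes)
  out <- ranked[keep, , drop = FALSE]
  class(out) <- class(ranked)
  attr(out, "method") <- attr(ranked, "method")
  attr(out, "n_genes") <- attr(ranked, "n_genes")
  attr(out, "dropped") <- genes[scanned][!keep[scanned]]
  rownames(out) <- NULL
  out
}

#' Train and evaluate a random forest on a feature subset
#'
#' Trains a random-forest classifier on the training partition restricted
#' to \code{features} and evaluates on the test partition: AUC from the
#' out-of-fold class-1 vote fractions and MCC from the majority-vote class
#' predictions.
#'
#' @param train,test \code{\link{expression_dataset}} partitions sharing
#'   the genes in \code{features}; \code{test} must contain both classes.
#' @param features Character vector of gene ids.
#' @param rf_params List of random-forest parameters; \code{ntree}
#'   (default 500) and \code{mtry} (default \code{floor(sqrt(p))}).
#' @param seed Seed for the forest.
#' @return List with \code{auc}, \code{mcc}, \code{n_features} and the
#'   parameters used.
#' @export
evaluate_top_n <- function(train, test, features, rf_params = list(),
                           seed = 1L) {
  if (length(unique(test$labels)) < 2L)
    stop("test partition has a single class; use a stratified CV plan")
  missing <- setdiff(features, intersect(rownames(train$values),
                                         rownames(test$values)))
  if (length(missing))
    stop("features missing from a partition: ",
         paste(head(missing, 5), collapse = ", "))
  ntree <- rf_params$ntree %||% 500L
  mtry <- rf_params$mtry %||% max(1L, floor(sqrt(length(features))))
  xtr <- t(train$values[features, , drop = FALSE])
  xte <- t(test$values[features, , drop = FALSE])
  ytr <- factor(train$labels, levels = c(0L, 1L))
  fit <- with_seed(as.integer(seed), {
    randomForest::randomForest(x = xtr, y = ytr, ntree = ntree, mtry = mtry)
  })
  prob1 <- predict(fit, xte, type = "prob")[, "1"]
  pred <- as.integer(as.character(predict(fit, xte, type = "response")))
  yte <- unname(test$labels)
  cm <- c(tp = sum(pred == 1L & yte == 1L), fp = sum(pred == 1L & yte == 0L),
          tn = sum(pred == 0L & yte == 0L), fn = sum(pred == 0L & yte == 1L))
  list(auc = unname(auc_score(prob1, yte)),
       mcc = unname(mcc_score(cm[["tp"]], cm[["fp"]], cm[["tn"]], cm[["fn"]])),
       n_features = length(features),
       rf_params = list(ntree = ntree, mtry = mtry, seed = seed))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full ensemble feature-selection pipeline
#'
#' For every (repeat, fold, method) cell: rank the genes on the 4/5
#' training partition, prune correlated genes (|Spearman rho| >
#' \code{rho_max}) from the ranking, and for each N in \code{n_grid}
#' evaluate a random forest built on the top-N surviving features against
#' the held-out fold. For FCBF, which returns a self-limiting subset, the
#' top-N set is its whole pruned selected set. Per method and N, the mean
#' and SD of AUC and MCC and the Lustgarten stability (ASM over the R*k
#' top-N sets, universe = genes entering the ranking) are summarised.
#' Errors in a cell are recorded with their coordinate and the run
#' continues.
#'
#' @param dataset An \code{\link{expression_dataset}}.
#' @param methods Subset of \code{c("ttest", "mdfs1d", "mdfs2d", "fcbf",
#'   "relieff", "mrmr")}.
#' @param n_grid Feature-set sizes N to evaluate (default 20).
#' @param plan A \code{\link{make_cv_plan}}; default R = 50, k = 5 under
#'   \code{seed}.
#' @param rho_max Spearman pruning threshold (default 0.7).
#' @param rf_params Random-forest parameters (see
#'   \code{\link{evaluate_top_n}}); set \code{evaluate = FALSE} to skip
#'   model fitting (rankings and stability only).
#' @param keep_top Number of pruned survivors stored per fold list
#'   (default \code{max(n_grid)}; raise it to call
#'   \code{\link{select_key_genes}} with a larger N).
#' @param evaluate Fit and score random forests (default TRUE).
#' @param seed Base seed for per-cell discretization/forest seeds.
#' @param mrmr_select,max_partners,relieff_k Filter parameters forwarded to
#'   \code{\link{rank_genes}}.
#' @param verbose Print per-repeat progress.
#' @return An \code{ensemble_result}: list with \code{fold_metrics}
#'   (data.frame), \code{top_lists} (per method, per fold, ordered pruned
#'   survivor ids), \code{summary} (per method x N means, SDs, ASM),
#'   \code{errors}, \code{config}, and the input \code{dataset}.
#' @export
run_pipeline <- function(dataset,
                         methods = c("ttest", "mdfs1d", "mdfs2d", "fcbf",
                                     "relieff", "mrmr"),
                         n_grid = 20L, plan = NULL, rho_max = 0.7,
                         rf_params = list(), keep_top = max(n_grid),
                         evaluate = TRUE, seed = 1L,
                         mrmr_select = NULL, max_partners = 500L,
                         relieff_k = 10L, verbose = FALSE) {
  methods <- match.arg(methods, several.ok = TRUE)
  if (length(n_grid) == 0L) stop("n_grid must be nonempty")
  if (is.null(plan))
    plan <- make_cv_plan(dataset$labels, n_repeats = 50L, n_folds = 5L,
                         seed = seed)
  keep_top <- max(keep_top, max(n_grid))
  if (is.null(mrmr_select)) mrmr_select <- min(nrow(dataset$values),
                                               keep_top + 10L)

  fold_metrics <- list()
  top_lists <- stats::setNames(vector("list", length(methods)), methods)
  errors <- list()
  cell <- 0L

  for (r in seq_len(plan$n_repeats)) {
    if (verbose) message("repeat ", r, "/", plan$n_repeats)
    assign <- plan$folds[[r]]
    for (f in seq_len(plan$n_folds)) {
      test_idx <- which(assign == f)
      train <- subset_dataset(dataset, samples = which(assign != f))
      test <- subset_dataset(dataset, samples = test_idx)
      for (mi in seq_along(methods)) {
        m <- methods[mi]
        cell_seed <- (as.integer(seed) + 7919L * r + 101L * f + mi) %% 2147483647L
        res <- tryCatch({
          ranked <- rank_genes(train, m, seed = cell_seed,
                               mrmr_select = mrmr_select,
                               max_partners = max_partners,
                               relieff_k = relieff_k)
          if (m %in% c("fcbf", "mrmr"))
            ranked <- ranked[ranked$selected, , drop = FALSE]
          pruned <- prune_correlated(ranked, train$values, rho_max = rho_max,
                                     n_keep = keep_top)
          survivors <- pruned$gene_id
          rows <- lapply(n_grid, function(N) {
            feats <- head(survivors, N)
            if (evaluate && length(feats) > 0L) {
              ev <- evaluate_top_n(train, test, feats, rf_params,
                                   seed = cell_seed)
              data.frame(repeat_idx = r, fold_idx = f, method = m, N = N,
                         n_features = ev$n_features, auc = ev$auc,
                         mcc = ev$mcc, stringsAsFactors = FALSE)
            } else {
              data.frame(repeat_idx = r, fold_idx = f, method = m, N = N,
                         n_features = length(feats), auc = NA_real_,
                         mcc = NA_real_, stringsAsFactors = FALSE)
            }
          })
          list(rows = do.call(rbind, rows), survivors = survivors)
        }, error = function(e) e)
        if (inherits(res, "error")) {
          errors[[length(errors) + 1L]] <-
            list(repeat_idx = r, fold_idx = f, method = m,
                 message = conditionMessage(res))
          next
        }
        cell <- cell + 1L
        fold_metrics[[cell]] <- res$rows
        top_lists[[m]][[length(top_lists[[m]]) + 1L]] <- res$survivors
      }
    }
  }

  fold_metrics <- do.call(rbind, fold_metrics)
  n_universe <- nrow(dataset$values)

  summary <- do.call(rbind, lapply(methods, function(m) {
    do.call(rbind, lapply(n_grid, function(N) {
      sub <- fold_metrics[fold_metrics$method == m & fold_metrics$N == N, ]
      sets <- lapply(top_lists[[m]], head, N)
      asm <- if (length(sets) >= 2L)
        suppressWarnings(lustgarten_asm(sets, n_universe)) else NA_real_
      data.frame(method = m, N = N,
                 mean_auc = mean(sub$auc), sd_auc = sd(sub$auc),
                 mean_mcc = mean(sub$mcc), sd_mcc = sd(sub$mcc),
                 asm = asm, n_folds = nrow(sub), stringsAsFactors = FALSE)
    }))
  }))
  rownames(summary) <- NULL

  structure(list(
    fold_metrics = fold_metrics, top_lists = top_lists, summary = summary,
    errors = errors,
    config = list(methods = methods, n_grid = n_grid, rho_max = rho_max,
                  keep_top = keep_top, seed = as.integer(seed),
                  n_repeats = plan$n_repeats, n_folds = plan$n_folds,
                  plan_seed = plan$seed, stratified = plan$stratified,
                  rf_params = list(ntree = rf_params$ntree %||% 500L,
                                   mtry = rf_params$mtry),
                  mrmr_select = mrmr_select, max_partners = max_partners,
                  relieff_k = relieff_k, evaluate = evaluate,
                  asm_universe = n_universe),
    dataset = dataset,
    status = if (length(errors)) "partial" else "ok"
  ), class = "ensemble_result")
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat(sprintf("ensemble_result: %d repeats x %d folds, methods: %s\n",
              x$config$n_repeats, x$config$n_folds,
              paste(x$config$methods, collapse = ", ")))
  if (length(x$errors)) cat("  failed cells:", length(x$errors), "\n")
  print(x$summary)
  invisible(x)
}

#' Consensus key-gene selection
#'
#' Implements the consensus procedure over an \code{ensemble_result}: per
#' method, each gene's occurrences among the R*k per-fold top-N pruned
#' lists are counted and the N most frequent genes form the method's set
#' (ties broken by better mean within-list rank, then lexicographically,
#' with a message); the union of the method sets is the key-gene set, to
#' which the log2 fold change computed on the full dataset is attached,
#' sorted by |Log2FC| descending.
#'
#' @param result An \code{ensemble_result} from \code{\link{run_pipeline}}.
#' @param n Top-N cut applied inside each fold list and to each method's
#'   frequency ranking; must not exceed the stored list length
#'   (\code{keep_top} of the run).
#' @return A \code{key_gene_table}: data.frame with per-method frequency
#'   and membership columns, \code{n_methods}, \code{log2fc},
#'   \code{direction}.
#' @export
select_key_genes <- function(result, n) {
  if (!inherits(result, "ensemble_result")) stop("`result` must be an ensemble_result")
  if (n > result$config$keep_top)
    stop(sprintf("n = %d exceeds the stored list length keep_top = %d",
                 n, result$config$keep_top))
  methods <- result$config$methods
  universe <- rownames(result$dataset$values)

  method_sets <- list(); freq_tab <- list()
  tied <- FALSE
  for (m in methods) {
    lists <- lapply(result$top_lists[[m]], head, n)
    if (length(lists) < 1L) stop("no fold lists for method ", m)
    genes <- unlist(lists)
    if (length(genes) == 0L) {
      method_sets[[m]] <- character(0)
      freq_tab[[m]] <- integer(0)
      next
    }
    freq <- table(genes)
    ranks <- unlist(lapply(lists, function(g) seq_along(g)))
    mean_rank <- tapply(ranks, genes, mean)
    ord <- order(-as.vector(freq), as.vector(mean_rank[names(freq)]),
                 names(freq))
    topn <- head(names(freq)[ord], n)
    # flag genuine frequency ties at the cut
    if (length(freq) > n) {
      cut_freq <- as.vector(freq)[ord][n]
      if (sum(freq == cut_freq) > 1L) tied <- TRUE
    }
    method_sets[[m]] <- topn
    freq_tab[[m]] <- freq
  }
  if (tied)
    message("select_key_genes: frequency ties at the cut broken by mean rank, then lexicographically")

  union_genes <- sort(unique(unlist(method_sets)))
  if (length(union_genes) == 0L) stop("no genes selected by any method")

  out <- data.frame(gene_id = union_genes, stringsAsFactors = FALSE)
  for (m in methods) {
    fr <- freq_tab[[m]]
    out[[paste0("freq_", m)]] <-
      ifelse(union_genes %in% names(fr), as.integer(fr[union_genes]), 0L)
    out[[paste0("in_", m)]] <- union_genes %in% method_sets[[m]]
  }
  out$n_methods <- rowSums(as.matrix(out[, paste0("in_", methods),
                                          drop = FALSE]))
  lfc <- log2fc(result$dataset, genes = union_genes)
  out$log2fc <- lfc$log2fc[match(union_genes, lfc$gene_id)]
  out$direction <- lfc$direction[match(union_genes, lfc$gene_id)]
  out <- out[order(-abs(out$log2fc), out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n") <- n
  attr(out, "n_lists") <- length(result$top_lists[[methods[1]]])
  attr(out, "methods") <- methods
  class(out) <- c("key_gene_table", "data.frame")
  out
}
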