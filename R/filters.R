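#' Construct a ranked gene list
#'
#' Common return type of the six feature filters: a data.frame ordered by
#' decreasing relevance with columns \code{gene_id}, \code{score},
#' \code{p}, \code{p_adj} and \code{selected}. The \code{method} and the
#' size of the gene universe are kept as attributes.
#'
#' @param method Filter name.
#' @param gene_id Gene ids in ranking order.
#' @param score Per-gene score, same order.
#' @param p,p_adj Raw and adjusted p-values (NA where the filter defines
#'   none).
#' @param selected Logical subset flag (always TRUE for pure rankers).
#' @param n_genes Size of the gene universe the ranking was computed on.
#' @return A \code{ranked_gene_list} (also a data.frame).
#' @export
ranked_gene_list <- function(method, gene_id, score, p = NA_real_,
                             p_adj = NA_real_, selected = TRUE,
                             n_genes = length(gene_id)) {
  out <- data.frame(gene_id = gene_id, score = score, p = p, p_adj = p_adj,
                    selected = selected, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "method") <- method
  attr(out, "n_genes") <- n_genes
  class(out) <- c("ranked_gene_list", "data.frame")
  out
}

# Order by decreasing score with deterministic index tie-break.
order_by_score <- function(score) order(-score, seq_along(score))

adjust_p <- function(p, method = c("BH", "holm")) {
  method <- match.arg(method)
  p.adjust(p, method = if (method == "BH") "BH" else "holm")
}

check_two_classes <- function(dataset, min_per_class = 2L) {
  n1 <- sum(dataset$labels == 1L); n0 <- sum(dataset$labels == 0L)
  if (n1 < min_per_class || n0 < min_per_class)
    stop(sprintf("each class needs >= %d samples (got %d / %d)",
                 min_per_class, n1, n0))
}

#' Rank genes by the Welch t-test
#'
#' Per gene, the two-sample t statistic with unequal variances
#' \eqn{t = (m_1 - m_0) / \sqrt{s_1^2/n_1 + s_0^2/n_0}} with
#' Welch--Satterthwaite degrees of freedom and a two-sided p-value. Genes
#' are ranked by \eqn{|t|} descending. Genes with zero variance in both
#' classes score 0 with p = 1 (documented convention, keeps ranking
#' lengths stable).
#'
#' @param dataset An \code{\link{expression_dataset}}.
#' @param p_adjust Multiple-testing correction, \code{"BH"} (default) or
#'   \code{"holm"}.
#' @return A \code{\link{ranked_gene_list}} with extra column
#'   \code{t_stat} (signed).
#' @export
welch_t_rank <- function(dataset, p_adjust = "BH") {
  check_two_classes(dataset, 2L)
  x <- dataset$values
  y <- dataset$labels
  i1 <- y == 1L; i0 <- y == 0L
  n1 <- sum(i1); n0 <- sum(i0)
  m1 <- rowMeans(x[, i1, drop = FALSE]); m0 <- rowMeans(x[, i0, drop = FALSE])
  v1 <- rowSums((x[, i1, drop = FALSE] - m1)^2) / (n1 - 1)
  v0 <- rowSums((x[, i0, drop = FALSE] - m0)^2) / (n0 - 1)
  se2 <- v1 / n1 + v0 / n0
  t_stat <- ifelse(se2 > 0, (m1 - m0) / sqrt(se2), 0)
  df <- ifelse(se2 > 0,
               se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1)),
               NA_real_)
  p <- ifelse(se2 > 0, 2 * pt(-abs(t_stat), df), 1)
  ord <- order_by_score(abs(t_stat))
  out <- ranked_gene_list("ttest", rownames(x)[ord], abs(t_stat)[ord],
                          p = p[ord], p_adj = adjust_p(p, p_adjust)[ord],
                          n_genes = nrow(x))
  out$t_stat <- t_stat[ord]
  out$df <- df[ord]
  out
}

#' Rank genes with the MDFS information-theoretic filter (1D or 2D)
#'
#' One-dimensional mode scores each gene by its information gain with the
#' class label, maximised over the discretization draws of \code{scheme}.
#' Two-dimensional mode scores each gene by the maximum, over draws and
#' partner genes, of the conditional information gain
#' \eqn{H(Y|X_j) - H(Y|X_i,X_j)}: interacting genes that are invisible
#' marginally (XOR-style pairs) obtain high 2D scores. P-values come from
#' the G statistic \eqn{G = 2 N \ln(2) IG} against a chi-square with
#' \eqn{(c-1)(k-1)} (1D) or \eqn{c(c-1)(k-1)} (2D) degrees of freedom,
#' Sidak-corrected for the number of maximised draws (and partners in 2D),
#' which is conservative under the positive dependence between draws; an
#' exact permutation null is available via \code{p_method}.
#'
#' @param dataset An \code{\link{expression_dataset}}.
#' @param dim 1 or 2.
#' @param scheme A \code{\link{discretization_scheme}}; default 30 random
#'   rank cuts into 2 bins. 2D mode requires 2 bins.
#' @param max_partners 2D partner-search cap per gene; exhaustive when the
#'   gene count allows, otherwise a seeded random partner subsample.
#' @param p_method \code{"chisq"} (default) or \code{"permutation"}.
#' @param n_perm Permutations when \code{p_method = "permutation"}.
#' @param p_adjust Multiple-testing correction (\code{"BH"} or
#'   \code{"holm"}).
#' @param seed Seed for the partner subsample and permutations.
#' @return A \code{\link{ranked_gene_list}}; attribute
#'   \code{partner_cap} records the 2D search width.
#' @export
mdfs_rank <- function(dataset, dim = 1L, scheme = NULL, max_partners = 500L,
                      p_method = c("chisq", "permutation"), n_perm = 200L,
                      p_adjust = "BH", seed = 1L) {
  p_method <- match.arg(p_method)
  if (!dim %in% c(1L, 2L)) stop("`dim` must be 1 or 2")
  if (is.null(scheme))
    scheme <- discretization_scheme(mode = "random-cut", n_draws = 30L,
                                    seed = seed)
  x <- t(dataset$values)  # samples x genes
  y <- unname(dataset$labels)
  n <- nrow(x); p <- ncol(x); cbin <- scheme$n_bins
  draws <- discretize_draws(x, scheme)

  if (dim == 1L) {
    stat_fun <- function(yy) {
      s <- rep(0, p)
      for (d in draws) s <- pmax(s, cpp_ig1d(d, yy, cbin))
      s
    }
    score <- stat_fun(y)
    df <- (cbin - 1) * 1  # k = 2 classes
    n_tests <- scheme$n_draws
  } else {
    if (cbin != 2L) stop("2D mode requires a 2-bin scheme")
    pairs <- make_partner_pairs(p, max_partners, seed)
    stat_fun <- function(yy) cpp_mdfs2d_max(draws, yy, pairs)
    score <- stat_fun(y)
    df <- cbin * (cbin - 1) * 1
    n_tests <- scheme$n_draws * max(1L, min(p - 1L, max_partners))
  }

  if (p_method == "chisq") {
    praw <- pchisq(2 * n * log(2) * score, df = df, lower.tail = FALSE)
    pval <- 1 - (1 - praw)^n_tests  # Sidak over the maximised draws/partners
  } else {
    obs <- score
    exceed <- rep(0L, p)
    with_seed(seed, {
      for (b in seq_len(n_perm)) {
        exceed <- exceed + (stat_fun(sample(y)) >= obs)
      }
    })
    pval <- (1 + exceed) / (n_perm + 1)
  }

  ord <- order_by_score(score)
  out <- ranked_gene_list(paste0("mdfs", dim, "d"), rownames(dataset$values)[ord],
                          score[ord], p = pval[ord],
                          p_adj = adjust_p(pval, p_adjust)[ord],
                          n_genes = p)
  attr(out, "partner_cap") <- if (dim == 2L) max_partners else NA_integer_
  attr(out, "scheme") <- scheme
  out
}

# Partner pair list for the 2D scan: exhaustive i<j when feasible,
# otherwise max_partners seeded random partners per gene (deduplicated).
make_partner_pairs <- function(p, max_partners, seed) {
  if (p - 1L <= max_partners) {
    idx <- utils::combn(p, 2L) - 1L
    return(t(idx))
  }
  with_seed(seed, {
    pairs <- matrix(0L, nrow = p * max_partners, ncol = 2L)
    r <- 0L
    for (g in seq_len(p)) {
      partners <- sample(p - 1L, max_partners)
      partners <- ifelse(partners >= g, partners + 1L, partners)
      rows <- r + seq_len(max_partners)
      pairs[rows, 1L] <- g - 1L
      pairs[rows, 2L] <- partners - 1L
      r <- r + max_partners
    }
    lo <- pmin(pairs[, 1L], pairs[, 2L]); hi <- pmax(pairs[, 1L], pairs[, 2L])
    keep <- !duplicated(lo * p + hi)
    cbind(lo[keep], hi[keep])
  })
}

#' Fast correlation-based filter (FCBF)
#'
#' Relevance and redundancy are both measured by symmetric uncertainty on
#' discretized genes. Genes with \eqn{SU(X, Y) > \delta} are ordered by
#' decreasing SU; the predominance scan then removes every gene j for which
#' an earlier kept gene i has \eqn{SU(X_i, X_j) \ge SU(X_j, Y)}. All genes
#' are returned ranked by SU with the survivors flagged in
#' \code{selected}.
#'
#' @param dataset An \code{\link{expression_dataset}}.
#' @param scheme A \code{\link{discretization_scheme}}; default a single
#'   equal-frequency cut into 2 bins.
#' @param delta SU-with-label threshold (>= 0), default 0.
#' @return A \code{\link{ranked_gene_list}}.
#' @export
fcbf_select <- function(dataset, scheme = NULL, delta = 0) {
  if (delta < 0) stop("delta must be >= 0")
  if (is.null(scheme)) scheme <- discretization_scheme(mode = "equal-frequency")
  disc <- discretize_draws(t(dataset$values), scheme)[[1L]]
  res <- cpp_fcbf(disc, unname(dataset$labels), scheme$n_bins, delta)
  ord <- res$order + 1L
  ranked_gene_list("fcbf", rownames(dataset$values)[ord], res$su_y[ord],
                   selected = res$selected[ord],
                   n_genes = nrow(dataset$values))
}

#' ReliefF feature weighting
#'
#' Instance-based weighting on range-normalized genes: for each visited
#' instance the k nearest same-class hits decrease and the k nearest
#' other-class misses (prior-weighted) increase each gene's weight by its
#' normalized value difference, \eqn{W[A] \gets W[A] - \sum diff/(m k) +
#' \sum P(C)/(1-P(class)) diff/(m k)}. Constant genes obtain weight 0.
#'
#' @param dataset An \code{\link{expression_dataset}}.
#' @param k_neighbors Neighbors per class (default 10); must be smaller
#'   than each class.
#' @param m_samples Number of instances to visit (default all), sampled
#'   without replacement under \code{seed}.
#' @param seed Seed for the instance subsample.
#' @return A \code{\link{ranked_gene_list}} of ReliefF weights.
#' @export
relieff_rank <- function(dataset, k_neighbors = 10L, m_samples = NULL,
                         seed = 1L) {
  y <- unname(dataset$labels)
  cls_sizes <- table(y)
  if (any(cls_sizes <= k_neighbors))
    stop("k_neighbors must be smaller than each class size")
  x <- t(dataset$values)
  rng <- apply(x, 2L, function(v) diff(range(v)))
  xn <- sweep(x, 2L, apply(x, 2L, min), "-")
  nz <- rng > 0
  xn[, nz] <- sweep(xn[, nz, drop = FALSE], 2L, rng[nz], "/")
  xn[, !nz] <- 0
  n <- nrow(x)
  idx <- if (is.null(m_samples) || m_samples >= n) seq_len(n) else
    with_seed(seed, sort(sample(n, m_samples)))
  w <- cpp_relieff(xn, y, as.integer(k_neighbors), as.integer(idx - 1L))
  ord <- order_by_score(w)
  ranked_gene_list("relieff", rownames(dataset$values)[ord], w[ord],
                   n_genes = nrow(dataset$values))
}

#' Minimum-redundancy maximum-relevance (MRMR) selection
#'
#' Greedy forward selection on discretized genes with the
#' mutual-information-difference criterion: the first gene maximises
#' \eqn{IG(Y; X)}; each further step maximises
#' \eqn{IG(Y; X_j) - \frac{1}{|S|} \sum_{s \in S} IG(X_j; X_s)}. The
#' selection order is the ranking and the criterion value at selection is
#' the score (the score column is therefore not necessarily monotone).
#' Unselected genes are appended by their final criterion value with
#' \code{selected = FALSE}, keeping the ranking length-stable. Ties are
#' broken by lower gene index with a message.
#'
#' @param dataset An \code{\link{expression_dataset}}.
#' @param scheme A \code{\link{discretization_scheme}}; default a single
#'   equal-frequency cut into 2 bins.
#' @param n_select Number of genes to select greedily.
#' @return A \code{\link{ranked_gene_list}}.
#' @export
mrmr_rank <- function(dataset, scheme = NULL, n_select) {
  p <- nrow(dataset$values)
  if (n_select > p) stop("n_select exceeds the number of genes")
  if (is.null(scheme)) scheme <- discretization_scheme(mode = "equal-frequency")
  disc <- discretize_draws(t(dataset$values), scheme)[[1L]]
  y <- unname(dataset$labels)
  # IG values rounded to 1e-10 so greedy ties are broken by gene index,
  # independent of floating-point summation order
  rel <- round(as.numeric(cpp_ig1d(disc, y, scheme$n_bins)), 10)

  selected <- integer(0)
  red_sum <- rep(0, p)     # sum over selected s of IG(Xj; Xs)
  crit_at_sel <- numeric(0)
  avail <- rep(TRUE, p)
  tied <- FALSE
  for (step in seq_len(n_select)) {
    crit <- if (step == 1L) rel else round(rel - red_sum / length(selected), 10)
    crit[!avail] <- -Inf
    best <- max(crit)
    cand <- which(crit == best)
    if (length(cand) > 1L) tied <- TRUE
    pick <- cand[1L]
    selected <- c(selected, pick)
    crit_at_sel <- c(crit_at_sel, best)
    avail[pick] <- FALSE
    if (step < n_select) {
      idx <- which(avail)
      red_sum[idx] <- red_sum[idx] +
        round(cpp_pair_ig(disc, scheme$n_bins, idx - 1L,
                          rep(pick - 1L, length(idx))), 10)
    }
  }
  if (tied) message("mrmr_rank: criterion ties broken by lower gene index")

  rest <- which(avail)
  rest_crit <- if (length(selected)) rel[rest] - red_sum[rest] / length(selected)
               else rel[rest]
  rest <- rest[order(-rest_crit, rest)]
  gene_ids <- rownames(dataset$values)
  out <- ranked_gene_list("mrmr",
                          c(gene_ids[selected], gene_ids[rest]),
                          c(crit_at_sel, sort(rest_crit, decreasing = TRUE)),
                          selected = c(rep(TRUE, length(selected)),
                                       rep(FALSE, length(rest))),
                          n_genes = p)
  out
}

#' Run one of the six feature filters by name
#'
#' Dispatcher used by the cross-validation pipeline.
#'
#' @param dataset An \code{\link{expression_dataset}}.
#' @param method One of \code{"ttest"}, \code{"mdfs1d"}, \code{"mdfs2d"},
#'   \code{"fcbf"}, \code{"relieff"}, \code{"mrmr"}.
#' @param seed Seed forwarded to the stochastic components (discretization
#'   draws, partner subsample, instance sampling).
#' @param mrmr_select Greedy selection length for MRMR.
#' @param max_partners 2D partner cap for MDFS-2D.
#' @param relieff_k ReliefF neighbor count.
#' @param ... Further arguments to the individual filter.
#' @return A \code{\link{ranked_gene_list}}.
#' @export
rank_genes <- function(dataset,
                       method = c("ttest", "mdfs1d", "mdfs2d", "fcbf",
                                  "relieff", "mrmr"),
                       seed = 1L, mrmr_select = 50L, max_partners = 500L,
                       relieff_k = 10L, ...) {
  method <- match.arg(method)
  switch(method,
    ttest = welch_t_rank(dataset, ...),
    mdfs1d = mdfs_rank(dataset, dim = 1L, seed = seed, ...),
    mdfs2d = mdfs_rank(dataset, dim = 2L, seed = seed,
                       max_partners = max_partners, ...),
    fcbf = fcbf_select(dataset, ...),
    relieff = relieff_rank(dataset, k_neighbors = relieff_k, seed = seed, ...),
    mrmr = mrmr_rank(dataset, n_select = min(mrmr_select, nrow(dataset$values)),
                     ...))
}
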