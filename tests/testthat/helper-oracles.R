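# Independent brute-force oracles and small fixture builders used across the
# suite. These deliberately avoid the package's optimized code paths.

# Build an expression_dataset from a plain matrix, inventing dimnames.
make_dataset <- function(values, labels, ...) {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("G%03d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("S%03d", seq_len(ncol(values)))
  expression_dataset(values, labels, ...)
}

# AUC by exhaustive pair counting (ties count 1/2).
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Lustgarten ASM by direct pairwise evaluation.
brute_asm <- function(sets, n) {
  L <- length(sets)
  vals <- c()
  for (i in seq_len(L - 1)) for (j in (i + 1):L) {
    si <- length(sets[[i]]); sj <- length(sets[[j]])
    den <- min(si, sj) - max(0, si + sj - n)
    v <- if (den == 0) 0 else
      (length(intersect(sets[[i]], sets[[j]])) - si * sj / n) / den
    vals <- c(vals, v)
  }
  mean(vals)
}

# Median rank cut used by the equal-frequency 2-bin scheme (mirrors the
# package's discretization so the oracles see the same binary inputs).
median_cut <- function(x) as.integer(rank(x, ties.method = "average") / length(x) > 0.5)

# FCBF by exhaustive application of the predominance rule, using the
# package's plain-R symmetric_uncertainty (table-based, independent of the
# C++ scan). SU values are rounded to 1e-10 like the implementation so that
# mathematical ties resolve identically.
brute_fcbf <- function(values, y, delta = 0) {
  disc <- apply(values, 1, median_cut)  # samples x genes
  p <- ncol(disc)
  su_y <- round(vapply(seq_len(p),
                       function(g) symmetric_uncertainty(disc[, g], y),
                       numeric(1)), 10)
  ord <- order(-su_y, seq_len(p))
  ord <- ord[su_y[ord] > delta]
  kept <- integer(0)
  for (j in ord) {
    dominated <- FALSE
    for (i in kept) {
      if (round(symmetric_uncertainty(disc[, i], disc[, j]), 10) >= su_y[j]) {
        dominated <- TRUE; break
      }
    }
    if (!dominated) kept <- c(kept, j)
  }
  rownames(values)[kept]
}

# MRMR (mutual-information-difference) by exhaustive greedy recomputation
# with the plain-R information_gain.
brute_mrmr <- function(values, y, n_select) {
  disc <- apply(values, 1, median_cut)
  p <- ncol(disc)
  rel <- round(vapply(seq_len(p), function(g) information_gain(disc[, g], y),
                      numeric(1)), 10)
  selected <- integer(0)
  for (step in seq_len(n_select)) {
    crit <- vapply(seq_len(p), function(j) {
      if (j %in% selected) return(-Inf)
      if (length(selected) == 0) return(rel[j])
      red <- sum(round(vapply(selected, function(s)
        information_gain(disc[, j], disc[, s]), numeric(1)), 10)) /
        length(selected)
      round(rel[j] - red, 10)
    }, numeric(1))
    selected <- c(selected, which.max(crit))
  }
  rownames(values)[selected]
}

# ReliefF for binary classes by direct enumeration of hits and misses.
brute_relieff <- function(values, y, k) {
  x <- t(values)  # samples x genes
  rng <- apply(x, 2, function(v) diff(range(v)))
  xn <- sweep(x, 2, apply(x, 2, min), "-")
  nz <- rng > 0
  xn[, nz] <- sweep(xn[, nz, drop = FALSE], 2, rng[nz], "/")
  xn[, !nz] <- 0
  n <- nrow(xn); p <- ncol(xn)
  w <- rep(0, p)
  for (i in seq_len(n)) {
    d <- vapply(seq_len(n), function(j)
      if (j == i) Inf else sum(abs(xn[i, ] - xn[j, ])), numeric(1))
    hits <- setdiff(which(y == y[i]), i)
    misses <- which(y != y[i])
    hits <- hits[order(d[hits], hits)][seq_len(k)]
    misses <- misses[order(d[misses], misses)][seq_len(k)]
    for (h in hits) w <- w - abs(xn[i, ] - xn[h, ]) / (n * k)
    for (ms in misses) w <- w + abs(xn[i, ] - xn[ms, ]) / (n * k)
  }
  stats::setNames(w, rownames(values))
}

# Standard recovery-study conditions: 1000 genes, 130/70 samples,
# 20 informative genes shifted by 2 log2 units, unit noise.
recovery_config <- function(seed) {
  sim_config(n_genes = 1000, n_class1 = 130, n_class0 = 70,
             n_informative = 20, effect_size = 2, noise_sd = 1, seed = seed)
}

# Interaction-study conditions: one XOR pair in a null background
# (delta = 3, sigma = 0.5, 400 balanced samples).
xor_config <- function(seed) {
  sim_config(n_genes = 1000, n_class1 = 200, n_class0 = 200,
             n_informative = 0, effect_size = 3, noise_sd = 0.5,
             n_xor_pairs = 1, seed = seed)
}

# Redundancy-study conditions: heavy rho = 0.9 correlated blocks attached
# to class signal plus a few independent markers.
block_config <- function(seed) {
  sim_config(n_genes = 500, n_class1 = 130, n_class0 = 70,
             n_informative = 10, effect_size = 1, noise_sd = 1,
             n_corr_blocks = 25, block_size = 12, block_rho = 0.9,
             blocks_informative = TRUE, seed = seed)
}
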