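#' Discretization scheme for the information-theoretic filters
#'
#' The information-theoretic filters (MDFS-1D/2D, FCBF, MRMR) operate on
#' discretized expression. Two modes are provided: \code{"equal-frequency"}
#' cuts each gene at its empirical quantiles (deterministic, a single
#' draw), and \code{"random-cut"} draws \code{n_draws} random rank-quantile
#' cut points per gene (restricted to the 0.15--0.85 quantile range so no
#' bin is degenerate) and lets the caller aggregate over draws -- the MDFS
#' filters keep the maximum-information draw.
#'
#' @param n_bins Number of bins per gene (default 2).
#' @param mode \code{"equal-frequency"} or \code{"random-cut"}.
#' @param n_draws Number of random discretization draws (forced to 1 for
#'   equal-frequency mode).
#' @param seed Seed for the random cut points.
#' @return A \code{discretization_scheme} object.
#' @export
discretization_scheme <- function(n_bins = 2L,
                                  mode = c("equal-frequency", "random-cut"),
                                  n_draws = 30L, seed = 1L) {
  mode <- match.arg(mode)
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) stop("n_bins must be >= 2")
  n_draws <- if (mode == "equal-frequency") 1L else as.integer(n_draws)
  if (n_draws < 1L) stop("n_draws must be >= 1")
  structure(list(n_bins = n_bins, mode = mode, n_draws = n_draws,
                 seed = as.integer(seed)),
            class = "discretization_scheme")
}

# Discretize a samples x genes numeric matrix into integer bins 0..c-1.
# Returns a list of n_draws integer matrices. Cuts act on the normalized
# ranks of each gene (ties averaged), so the result depends only on the
# ordering of values. Constant genes land in a single bin (bin 0).
discretize_draws <- function(x, scheme) {
  if (!is.matrix(x)) x <- matrix(x, ncol = 1L)
  n <- nrow(x); p <- ncol(x); c <- scheme$n_bins
  rk <- apply(x, 2L, function(v) rank(v, ties.method = "average")) / n
  rk <- matrix(rk, nrow = n, ncol = p)
  const <- apply(x, 2L, function(v) v[1] == v[n] && all(v == v[1]))

  make_disc <- function(cuts) {
    # cuts: (c-1) x p matrix of rank-quantile cut points
    disc <- matrix(0L, n, p)
    for (b in seq_len(c - 1L)) {
      disc <- disc + (rk > rep(cuts[b, ], each = n))
    }
    disc[, const] <- 0L
    storage.mode(disc) <- "integer"
    disc
  }

  if (scheme$mode == "equal-frequency") {
    cuts <- matrix(seq_len(c - 1L) / c, nrow = c - 1L, ncol = p)
    return(list(make_disc(cuts)))
  }
  with_seed(scheme$seed, {
    lapply(seq_len(scheme$n_draws), function(d) {
      u <- matrix(runif((c - 1L) * p, 0.15, 0.85), nrow = c - 1L, ncol = p)
      u <- apply(u, 2L, sort)
      make_disc(matrix(u, nrow = c - 1L, ncol = p))
    })
  })
}

#' Shannon entropy of a discrete sample (bits)
#'
#' Plug-in estimate from empirical frequencies.
#'
#' @param x A vector treated as categorical, or a matrix whose rows are
#'   treated as joint observations.
#' @return Entropy in bits.
#' @export
shannon_entropy <- function(x) {
  if (is.matrix(x)) x <- apply(x, 1L, paste, collapse = "\r")
  if (length(x) == 0L) stop("empty input")
  freq <- tabulate(factor(x))
  freq <- freq[freq > 0] / length(x)
  -sum(freq * log2(freq))
}

#' Information gain between a discretized feature and the class label
#'
#' Plug-in estimate of \eqn{H(Y) - H(Y|X)} in bits. \code{x} may be a
#' single discretized gene (vector) or a matrix of several discretized
#' genes whose rows form the joint variable (2D information gain for a
#' pair).
#'
#' @param x Integer vector or samples x genes integer matrix.
#' @param y Binary labels, one per sample.
#' @return Information gain in bits, in \eqn{[0, H(Y)]}.
#' @export
information_gain <- function(x, y) {
  if (is.matrix(x)) {
    if (nrow(x) != length(y)) stop("x and y must have matching samples")
    xkey <- apply(x, 1L, paste, collapse = "\r")
  } else {
    if (length(x) != length(y)) stop("x and y must have matching samples")
    xkey <- x
  }
  if (length(y) == 0L) stop("empty input")
  hy <- shannon_entropy(y)
  # H(Y|X) = H(X,Y) - H(X)
  hxy <- shannon_entropy(cbind(as.character(xkey), as.character(y)))
  hx <- shannon_entropy(as.character(xkey))
  max(hy - (hxy - hx), 0)
}

#' Symmetric uncertainty between two discrete variables
#'
#' \eqn{SU(X, Y) = 2 IG(X; Y) / (H(X) + H(Y))}, in \eqn{[0, 1]}; defined as
#' 0 when both entropies vanish.
#'
#' @param x,y Discrete vectors of equal length.
#' @return Symmetric uncertainty in \eqn{[0, 1]}.
#' @export
symmetric_uncertainty <- function(x, y) {
  hx <- shannon_entropy(as.character(x))
  hy <- shannon_entropy(as.character(y))
  if (hx + hy == 0) return(0)
  2 * information_gain(as.vector(x), as.vector(y)) / (hx + hy)
}
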