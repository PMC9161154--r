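#' Configuration for the synthetic expression-data generator
#'
#' Describes a two-class log2 expression study with known ground truth:
#' a minority of informative genes whose class-1 mean is shifted by
#' \code{effect_size} log2 units, optional blocks of inter-gene correlated
#' (redundant) genes, optional XOR-style interacting gene pairs that are
#' marginally uninformative but jointly class-determining, and optional
#' per-batch location/scale effects. Defaults mirror a merged two-cohort
#' design with unequal class sizes (130 vs 71).
#'
#' @param n_genes Total number of genes.
#' @param n_class1,n_class0 Samples per class (class 1 is the positive
#'   class). Defaults 130 and 71.
#' @param n_informative Number of mean-shift informative genes.
#' @param effect_size Class-1 mean shift in log2 units (>= 0); the sign is
#'   drawn per gene and recorded in the truth table.
#' @param noise_sd Within-class standard deviation in log2 units (> 0).
#' @param n_corr_blocks,block_size Number and size of correlated gene
#'   blocks (redundancy stressors, non-informative unless
#'   \code{blocks_informative}).
#' @param block_rho Target within-block pairwise Spearman correlation in
#'   [0, 1).
#' @param blocks_informative If TRUE, each block's shared latent factor is
#'   class-associated so the whole block carries (redundant) signal with a
#'   per-gene class shift of about \code{effect_size}.
#' @param n_xor_pairs Number of XOR-style gene pairs.
#' @param xor_flip Label-noise rate of the XOR construction (default 0.05).
#' @param batch_assignment Optional per-sample batch ids (length
#'   \code{n_class1 + n_class0}).
#' @param batch_shift Additive per-batch shift in log2 units; batch b gets
#'   \code{batch_shift * (b - 1)} plus an independent per-gene jitter with
#'   SD \code{0.1 * batch_shift}.
#' @param batch_scale Multiplicative per-batch scale; batch b gets
#'   \code{batch_scale ^ (b - 1)}.
#' @param seed Integer seed; identical configurations generate bit-identical
#'   datasets.
#' @return A \code{sim_config} object.
#' @export
sim_config <- function(n_genes, n_class1 = 130L, n_class0 = 71L,
                       n_informative = 0L, effect_size = 1, noise_sd = 1,
                       n_corr_blocks = 0L, block_size = 0L, block_rho = 0.8,
                       blocks_informative = FALSE,
                       n_xor_pairs = 0L, xor_flip = 0.05,
                       batch_assignment = NULL, batch_shift = 0,
                       batch_scale = 1, seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_class1 = as.integer(n_class1),
              n_class0 = as.integer(n_class0),
              n_informative = as.integer(n_informative),
              effect_size = effect_size, noise_sd = noise_sd,
              n_corr_blocks = as.integer(n_corr_blocks),
              block_size = as.integer(block_size), block_rho = block_rho,
              blocks_informative = isTRUE(blocks_informative),
              n_xor_pairs = as.integer(n_xor_pairs), xor_flip = xor_flip,
              batch_assignment = batch_assignment,
              batch_shift = batch_shift, batch_scale = batch_scale,
              seed = as.integer(seed))
  used <- cfg$n_informative + 2L * cfg$n_xor_pairs +
    cfg$n_corr_blocks * cfg$block_size
  if (used > cfg$n_genes)
    stop(sprintf(paste0("impossible configuration: %d informative + %d xor + ",
                        "%d block genes exceed n_genes = %d"),
                 cfg$n_informative, 2L * cfg$n_xor_pairs,
                 cfg$n_corr_blocks * cfg$block_size, cfg$n_genes))
  if (cfg$effect_size < 0) stop("effect_size must be >= 0")
  if (cfg$noise_sd <= 0) stop("noise_sd must be > 0")
  if (cfg$block_rho < 0 || cfg$block_rho >= 1) stop("block_rho must be in [0, 1)")
  if (cfg$n_class1 < 1L || cfg$n_class0 < 1L) stop("both classes need samples")
  if (!is.null(batch_assignment) &&
      length(batch_assignment) != cfg$n_class1 + cfg$n_class0)
    stop("batch_assignment must have one entry per sample")
  structure(cfg, class = "sim_config")
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

#' Generate a synthetic two-class expression dataset
#'
#' Draws a log2 expression matrix under the structure described by a
#' \code{\link{sim_config}}: per-gene baselines from Uniform(2, 12) (the
#' typical dynamic range of log2 RNA-seq), Gaussian within-class noise,
#' signed class-mean shifts for informative genes, latent-factor correlated
#' blocks whose empirical pairwise Spearman correlation approximates
#' \code{block_rho}, XOR pairs whose genes are marginally class-independent
#' but whose latent sign product determines the class (up to
#' \code{xor_flip} label noise), and additive/multiplicative batch effects.
#'
#' @param config A \code{\link{sim_config}}.
#' @return An \code{\link{expression_dataset}} with a \code{truth} table
#'   listing the informative genes (empty truth when nothing is
#'   informative).
#' @export
generate_expression <- function(config) {
  if (!inherits(config, "sim_config")) stop("`config` must be a sim_config")
  p <- config$n_genes
  n1 <- config$n_class1; n0 <- config$n_class0; n <- n1 + n0
  delta <- config$effect_size; sigma <- config$noise_sd

  with_seed(config$seed, {
    gene_ids <- sprintf("G%05d", seq_len(p))
    sample_ids <- sprintf("S%04d", seq_len(n))
    labels <- c(rep(1L, n1), rep(0L, n0))

    baseline <- runif(p, 2, 12)
    values <- matrix(rnorm(p * n, mean = 0, sd = sigma), nrow = p, ncol = n) +
      baseline
    rownames(values) <- gene_ids
    colnames(values) <- sample_ids

    # gene layout: [informative][xor pairs][blocks][background]
    idx_inf <- seq_len(config$n_informative)
    idx_xor <- config$n_informative +
      seq_len(2L * config$n_xor_pairs)
    idx_blk <- config$n_informative + 2L * config$n_xor_pairs +
      seq_len(config$n_corr_blocks * config$block_size)

    truth <- list()

    if (config$n_informative > 0L && delta > 0) {
      signs <- sample(c(-1, 1), config$n_informative, replace = TRUE)
      values[idx_inf, labels == 1L] <- values[idx_inf, labels == 1L] +
        signs * delta
      truth$shift <- data.frame(gene_id = gene_ids[idx_inf],
                                effect = signs * delta, kind = "shift",
                                stringsAsFactors = FALSE)
    }

    if (config$n_xor_pairs > 0L) {
      target <- ifelse(labels == 1L, 1, -1)
      for (q in seq_len(config$n_xor_pairs)) {
        ga <- idx_xor[2L * q - 1L]; gb <- idx_xor[2L * q]
        a <- sample(c(-1, 1), n, replace = TRUE)
        flip <- ifelse(rbinom(n, 1L, config$xor_flip) == 1L, -1, 1)
        b <- a * target * flip
        values[ga, ] <- values[ga, ] + a * delta / 2
        values[gb, ] <- values[gb, ] + b * delta / 2
      }
      truth$xor <- data.frame(gene_id = gene_ids[idx_xor], effect = 0,
                              kind = "xor", stringsAsFactors = FALSE)
    }

    if (config$n_corr_blocks > 0L && config$block_size > 0L) {
      # Pearson rho of the shared-factor model chosen so the empirical
      # Spearman correlation approximates block_rho (bivariate normal:
      # rho_s = (6/pi) asin(rho_p / 2)).
      rho_p <- min(2 * sin(pi * config$block_rho / 6), 0.999)
      blk_shift <- if (config$blocks_informative) delta else 0
      for (bk in seq_len(config$n_corr_blocks)) {
        gidx <- idx_blk[(bk - 1L) * config$block_size + seq_len(config$block_size)]
        z <- rnorm(n)
        if (blk_shift > 0) {
          # class-associated latent: per-gene class shift ~ effect_size
          z <- z + (labels == 1L) * (blk_shift / (sigma * sqrt(rho_p)))
        }
        noise <- matrix(rnorm(length(gidx) * n, sd = sigma), ncol = n)
        values[gidx, ] <- baseline[gidx] +
          sqrt(rho_p) * sigma * matrix(z, nrow = length(gidx), ncol = n, byrow = TRUE) +
          sqrt(1 - rho_p) * noise
      }
      if (blk_shift > 0)
        truth$block <- data.frame(gene_id = gene_ids[idx_blk],
                                  effect = blk_shift, kind = "block",
                                  stringsAsFactors = FALSE)
    }

    batches <- NULL
    if (!is.null(config$batch_assignment)) {
      batches <- as.character(config$batch_assignment)
      blev <- unique(batches)
      for (k in seq_along(blev)) {
        if (k == 1L) next
        in_b <- batches == blev[k]
        shift_b <- config$batch_shift * (k - 1)
        scale_b <- config$batch_scale^(k - 1)
        jitter <- rnorm(p, sd = 0.1 * abs(config$batch_shift))
        values[, in_b] <- values[, in_b, drop = FALSE] * scale_b +
          shift_b + jitter
      }
    }

    truth <- if (length(truth)) do.call(rbind, unname(truth)) else NULL
    expression_dataset(values, labels, batches = batches, truth = truth)
  })
}

#' Marginal vs joint association check for a gene pair
#'
#' Computes each gene's one-dimensional information gain with the class
#' label and the pair's joint two-dimensional information gain (both
#' maximised over the discretization draws of \code{scheme}), together with
#' permutation-null 95\% quantiles obtained by recomputing the same
#' statistics under label shuffles. An XOR-style pair shows both 1D gains
#' within the null range while the joint 2D gain exceeds it.
#'
#' @param dataset An \code{\link{expression_dataset}}.
#' @param pair Character vector of two gene ids.
#' @param scheme A \code{\link{discretization_scheme}}; default 30 random
#'   rank cuts into 2 bins.
#' @param n_perm Number of label permutations for the null (default 200).
#' @param seed Seed for the permutations.
#' @return A list with elements \code{ig1} (named 1D gains, bits),
#'   \code{ig2} (joint gain, bits), \code{null_q95_1d} (per-gene null
#'   quantiles), \code{null_q95_2d}, and logicals \code{marginal_null} and
#'   \code{joint_signal}.
#' @export
xor_pair_check <- function(dataset, pair, scheme = NULL, n_perm = 200L,
                           seed = 1L) {
  if (length(pair) != 2L) stop("`pair` must name two genes")
  missing <- setdiff(pair, rownames(dataset$values))
  if (length(missing)) stop("unknown gene id: ", paste(missing, collapse = ", "))
  if (is.null(scheme))
    scheme <- discretization_scheme(mode = "random-cut", n_draws = 30L,
                                    seed = seed)
  x <- dataset$values[pair, , drop = FALSE]
  y <- unname(dataset$labels)
  draws <- discretize_draws(t(x), scheme)  # list of n x 2 integer matrices

  cbin <- scheme$n_bins
  # joint variable of the pair encoded as one c^2-level feature
  joint <- lapply(draws, function(d) {
    cbind(d, matrix(d[, 1L] * cbin + d[, 2L], ncol = 1L))
  })
  stat <- function(yy) {
    s <- c(0, 0, 0)
    for (d in joint) {
      s <- pmax(s, c(cpp_ig1d(d[, 1:2, drop = FALSE], yy, cbin),
                     cpp_ig1d(d[, 3, drop = FALSE], yy, cbin * cbin)))
    }
    s
  }

  obs <- stat(y)
  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) stat(sample(y)), numeric(3))
  })
  q95 <- apply(null, 1, quantile, probs = 0.95, names = FALSE)
  list(ig1 = stats::setNames(obs[1:2], pair), ig2 = obs[3],
       null_q95_1d = stats::setNames(q95[1:2], pair), null_q95_2d = q95[3],
       marginal_null = all(obs[1:2] <= q95[1:2]),
       joint_signal = obs[3] > q95[3])
}
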