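test_that("Welch t matches the hand formula and the base-R oracle", {
  m <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 1,
              dimnames = list("g1", paste0("s", 1:6)))
  d <- expression_dataset(m, c(1, 1, 1, 0, 0, 0))
  r <- welch_t_rank(d)
  expect_equal(r$t_stat, -3.6742, tolerance = 1e-4)
  expect_equal(r$df, 4.0, tolerance = 1e-12)
  expect_equal(r$p, 0.0213, tolerance = 1e-3)

  # identical class means/variances -> t = 0, p = 1
  m0 <- matrix(rep(c(1, 2, 1, 2), 2), nrow = 1,
               dimnames = list("g1", paste0("s", 1:8)))
  d0 <- expression_dataset(m0, c(1, 1, 0, 0, 1, 1, 0, 0))
  r0 <- welch_t_rank(d0)
  expect_equal(r0$score, 0)
  expect_equal(r0$p, 1)

  # cross-check against stats::t.test on random data
  set.seed(21)
  mm <- matrix(rnorm(20 * 30), 20, 30,
               dimnames = list(sprintf("g%02d", 1:20), sprintf("s%02d", 1:30)))
  dd <- expression_dataset(mm, rep(c(1, 0), 15))
  rr <- welch_t_rank(dd)
  for (g in c("g01", "g07", "g20")) {
    tt <- t.test(mm[g, dd$labels == 1], mm[g, dd$labels == 0])
    i <- match(g, rr$gene_id)
    expect_equal(rr$t_stat[i], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(rr$p[i], tt$p.value, tolerance = 1e-10)
  }
  expect_true(all(diff(rr$score) <= 0))
  expect_true(all(rr$p_adj >= rr$p))
})

test_that("zero-variance genes stay in the ranking with a degenerate score", {
  set.seed(31)
  m <- rbind(flat = rep(3, 40), matrix(rnorm(5 * 40), 5, 40))
  rownames(m)[2:6] <- paste0("g", 1:5)
  colnames(m) <- paste0("s", 1:40)
  d <- expression_dataset(m, rep(c(1, 0), 20))
  # rankings are length-stable: the constant gene is ranked, not dropped
  for (meth in c("ttest", "mdfs1d", "fcbf", "relieff", "mrmr")) {
    r <- rank_genes(d, meth, seed = 1, mrmr_select = 3)
    expect_equal(nrow(r), 6, label = paste("filter", meth))
    expect_true("flat" %in% r$gene_id)
  }
  # zero dispersion scores the minimum for the relevance-only filters ...
  for (meth in c("ttest", "mdfs1d", "fcbf")) {
    r <- rank_genes(d, meth, seed = 1)
    expect_equal(r$score[match("flat", r$gene_id)], min(r$score),
                 tolerance = 1e-12, label = paste("filter", meth))
  }
  # ... and exactly 0 for ReliefF (all diffs vanish)
  r <- relieff_rank(d, k_neighbors = 5)
  expect_equal(r$score[match("flat", r$gene_id)], 0)
})

test_that("information gain obeys its closed-form anchors", {
  y <- rep(c(0L, 1L), 20)
  expect_equal(information_gain(y, y), 1)          # X = Y, balanced
  expect_equal(information_gain(rep(1L, 40), y), 0) # constant X
  # independent joint table with 25 in each cell
  x <- c(rep(0L, 50), rep(1L, 50))
  yy <- rep(c(rep(0L, 25), rep(1L, 25)), 2)
  expect_equal(information_gain(x, yy), 0)
  expect_error(information_gain(integer(0), integer(0)), "empty")
})

test_that("symmetric uncertainty is symmetric and bounded", {
  set.seed(5)
  for (i in 1:20) {
    x <- sample(0:1, 30, replace = TRUE)
    y <- sample(0:1, 30, replace = TRUE)
    su1 <- symmetric_uncertainty(x, y)
    su2 <- symmetric_uncertainty(y, x)
    expect_equal(su1, su2, tolerance = 1e-12)
    expect_gte(su1, 0); expect_lte(su1, 1)
  }
})

test_that("MDFS-1D scores a label-equal gene at H(Y) with minimal p", {
  y <- rep(c(1, 0), each = 20)
  m <- rbind(hit = as.numeric(y), noise = rnorm(40))
  colnames(m) <- paste0("s", 1:40)
  d <- expression_dataset(m, y)
  r <- mdfs_rank(d, dim = 1, scheme = discretization_scheme())
  expect_identical(r$gene_id[1], "hit")
  expect_equal(r$score[1], 1)  # H(Y) = 1 bit for balanced classes
  expect_lt(r$p_adj[1], 1e-10)
})

test_that("1D chi-square p agrees with a 2000-permutation mid-p", {
  set.seed(41)
  m <- matrix(rnorm(10 * 50), 10, 50,
              dimnames = list(sprintf("g%02d", 1:10), sprintf("s%02d", 1:50)))
  y <- rep(c(1L, 0L), 25)
  d <- expression_dataset(m, y)
  sch <- discretization_scheme(mode = "equal-frequency")
  r_chi <- mdfs_rank(d, dim = 1, scheme = sch, p_method = "chisq")
  p_chi <- r_chi$p[match(rownames(m), r_chi$gene_id)]

  # permutation null of the same statistic; the null is discrete (2x2 with
  # fixed margins), so the mid-p convention is the comparable quantity
  disc <- ensemblefs:::discretize_draws(t(m), sch)[[1]]
  obs <- round(as.numeric(ensemblefs:::cpp_ig1d(disc, y, 2L)), 10)
  B <- 2000
  gt <- eq <- rep(0, 10)
  set.seed(1)
  for (b in seq_len(B)) {
    ig <- round(as.numeric(ensemblefs:::cpp_ig1d(disc, sample(y), 2L)), 10)
    gt <- gt + (ig > obs)
    eq <- eq + (ig == obs)
  }
  p_mid <- (gt + 0.5 * eq) / B
  expect_true(all(abs(p_chi - p_mid) < 0.05))

  # the package's own permutation option is valid but conservative: it
  # counts the whole atom at the observed value
  r_perm <- mdfs_rank(d, dim = 1, scheme = sch, p_method = "permutation",
                      n_perm = 500, seed = 1)
  p_perm <- r_perm$p[match(rownames(m), r_perm$gene_id)]
  expect_true(all(p_perm >= p_chi - 0.05))
})

test_that("the MDFS filters are deterministic given the scheme seed", {
  d <- generate_expression(sim_config(n_genes = 60, n_class1 = 25,
                                      n_class0 = 25, n_informative = 5,
                                      effect_size = 1.5, seed = 2))
  r1 <- mdfs_rank(d, dim = 2, max_partners = 20, seed = 7)
  r2 <- mdfs_rank(d, dim = 2, max_partners = 20, seed = 7)
  expect_identical(r1, r2)
})

test_that("FCBF keeps one of two identical label-equal genes and drops constants", {
  y <- rep(c(1, 0), each = 15)
  sig <- as.numeric(y) + 0.001 * seq_along(y)  # tie-free ranks
  m <- rbind(copy1 = sig, copy2 = sig, flat = rep(2, 30), noise = rnorm(30))
  colnames(m) <- paste0("s", 1:30)
  d <- expression_dataset(m, y)
  r <- fcbf_select(d)
  sel <- r$gene_id[r$selected]
  expect_equal(sum(c("copy1", "copy2") %in% sel), 1)
  expect_false("flat" %in% sel)
  expect_equal(r$score[match("flat", r$gene_id)], 0)
  # survivors retain SU-descending order
  expect_true(all(diff(r$score[r$selected]) <= 0))
})

test_that("FCBF equals the exhaustive predominance oracle on small toys", {
  set.seed(51)
  for (trial in 1:20) {
    n_genes <- sample(4:8, 1)
    y <- rep(c(1L, 0L), each = 12)
    base <- matrix(rnorm(n_genes * 24), n_genes, 24)
    base[1, ] <- base[1, ] + y          # informative
    if (n_genes >= 5) base[5, ] <- base[1, ] + rnorm(24, sd = 0.3)  # redundant
    dimnames(base) <- list(sprintf("g%d", 1:n_genes), sprintf("s%02d", 1:24))
    d <- expression_dataset(base, y)
    got <- fcbf_select(d)
    expect_setequal(got$gene_id[got$selected], brute_fcbf(base, y))
  }
})

test_that("ReliefF matches direct enumeration and its anchors", {
  # perfectly separating feature attains the maximum weight
  set.seed(61)
  y <- rep(c(1, 0), each = 6)
  m <- rbind(sep = as.numeric(y), n1 = rnorm(12), n2 = rnorm(12))
  colnames(m) <- paste0("s", 1:12)
  d <- expression_dataset(m, y)
  r <- relieff_rank(d, k_neighbors = 3)
  expect_identical(r$gene_id[1], "sep")
  # constant feature has weight exactly 0
  m2 <- rbind(m, flat = rep(1, 12))
  d2 <- expression_dataset(m2, y)
  r2 <- relieff_rank(d2, k_neighbors = 3)
  expect_equal(r2$score[match("flat", r2$gene_id)], 0)

  # 4-instance, 2-feature toy with k = 1, m = all vs enumeration oracle
  m4 <- rbind(f1 = c(0, 0.2, 0.8, 1), f2 = c(1, 0, 1, 0))
  colnames(m4) <- paste0("s", 1:4)
  y4 <- c(1, 1, 0, 0)
  d4 <- expression_dataset(m4, y4)
  r4 <- relieff_rank(d4, k_neighbors = 1)
  w_oracle <- brute_relieff(m4, y4, k = 1)
  expect_equal(r4$score, unname(w_oracle[r4$gene_id]), tolerance = 1e-12)

  # random 5-gene toy, k = 2
  m5 <- matrix(rnorm(5 * 14), 5, 14,
               dimnames = list(paste0("g", 1:5), paste0("s", 1:14)))
  y5 <- rep(c(1, 0), 7)
  d5 <- expression_dataset(m5, y5)
  r5 <- relieff_rank(d5, k_neighbors = 2)
  w5 <- brute_relieff(m5, y5, k = 2)
  expect_equal(r5$score, unname(w5[r5$gene_id]), tolerance = 1e-12)

  expect_error(relieff_rank(d4, k_neighbors = 2), "class size")
})

test_that("MRMR picks the most relevant gene first and shuns duplicates", {
  y <- rep(c(1, 0), each = 20)
  set.seed(71)
  # top is a strong but imperfect predictor, so the duplicate's redundancy
  # (H(X)) strictly exceeds its relevance and its criterion is negative
  sig <- 2 * as.numeric(y) + rnorm(40)
  m <- rbind(top = sig, dup = sig, other = 1.5 * as.numeric(y) + rnorm(40),
             n1 = rnorm(40), n2 = rnorm(40))
  colnames(m) <- paste0("s", 1:40)
  d <- expression_dataset(m, y)
  r <- mrmr_rank(d, n_select = 3)
  sel <- r$gene_id[r$selected]
  # step 1 takes the gene with maximal label IG
  disc <- apply(m, 1, median_cut)
  rel <- apply(disc, 2, information_gain, y = y)
  expect_identical(sel[1], names(which.max(rel)))
  expect_false(sel[2] == "dup")
})

test_that("MRMR equals the exhaustive greedy oracle on small toys", {
  set.seed(81)
  for (trial in 1:15) {
    n_genes <- sample(4:8, 1)
    y <- rep(c(1L, 0L), each = 12)
    base <- matrix(rnorm(n_genes * 24), n_genes, 24)
    base[1, ] <- base[1, ] + 1.5 * y
    base[2, ] <- base[2, ] + 0.8 * y
    dimnames(base) <- list(sprintf("g%d", 1:n_genes), sprintf("s%02d", 1:24))
    d <- expression_dataset(base, y)
    got <- suppressMessages(mrmr_rank(d, n_select = 3))
    expect_identical(got$gene_id[got$selected],
                     brute_mrmr(base, y, 3))
  }
})

test_that("all filters recover strong markers on one standard draw", {
  d <- generate_expression(recovery_config(seed = 42))
  truth <- d$truth$gene_id
  for (meth in c("ttest", "mdfs1d", "fcbf", "relieff", "mrmr")) {
    r <- rank_genes(d, meth, seed = 1, mrmr_select = 40)
    top <- if (meth == "fcbf") r$gene_id[r$selected] else head(r$gene_id, 40)
    expect_gte(sum(truth %in% top), 18)
  }
})
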