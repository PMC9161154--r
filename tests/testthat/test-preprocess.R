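test_that("log2 transform matches the closed form and inverts", {
  expect_equal(log2_transform(0, offset = 1), 0)
  expect_equal(log2_transform(7, offset = 1), 3)
  set.seed(1)
  m <- matrix(rexp(200, rate = 0.1), 20, 10)
  out <- log2_transform(m, offset = 1)
  expect_lt(max(abs(2^out - 1 - m)), 1e-9)
  expect_error(log2_transform(-1), "non-negative")
})

test_that("unsupervised filter applies both rules gene by gene", {
  n <- 20
  vals <- rbind(
    constant   = rep(5, n),                        # robust CV 0 -> drop
    variable   = c(seq(1, 10, length.out = n)),    # keep (high rCV, detected)
    rare       = c(9, rep(0.1, n - 1)),            # only 5% above 1 -> drop
    zero_med   = c(rep(0, n / 2), seq(2, 3, length.out = n / 2)), # med 0, IQR>0 -> rCV Inf, keep
    low_cv     = 10 + 0.001 * seq_len(n),          # tiny rCV -> drop
    strong     = seq(2, 12, length.out = n)        # keep
  )
  colnames(vals) <- sprintf("S%02d", 1:n)
  ds <- expression_dataset(vals, rep(c(0, 1), n / 2))
  crit <- filter_criteria(rcv_min = 0.05, ge_threshold = 1, min_fraction = 0.10)
  # hand evaluation of both rules per gene
  expected <- c("variable", "zero_med", "strong")
  out <- unsupervised_filter(ds, crit)
  expect_identical(rownames(out$values), expected)
  # idempotent
  out2 <- unsupervised_filter(out, crit)
  expect_identical(out2$values, out$values)
  # everything removed -> explicit error
  strict <- filter_criteria(rcv_min = 100, ge_threshold = 1)
  expect_error(unsupervised_filter(ds, strict), "empty after filtering")
})

test_that("robust CV handles zero-median genes by convention", {
  m <- rbind(a = rep(0, 9), b = c(rep(0, 5), 1:4))
  colnames(m) <- paste0("S", 1:9)
  rcv <- robust_cv(m)
  expect_equal(unname(rcv["a"]), 0)
  expect_equal(unname(rcv["b"]), Inf)
})

test_that("merging intersects genes and concatenates samples", {
  m1 <- matrix(1:9, 3, 3, dimnames = list(c("A", "B", "C"), paste0("x", 1:3)))
  m2 <- matrix(1:9, 3, 3, dimnames = list(c("B", "C", "D"), paste0("y", 1:3)))
  d1 <- expression_dataset(m1 * 1.0, c(1, 1, 0))
  d2 <- expression_dataset(m2 * 1.0, c(1, 0, 0))
  mg <- merge_datasets(d1, d2)
  expect_setequal(rownames(mg$values), c("B", "C"))
  expect_equal(ncol(mg$values), 6)
  expect_equal(unname(mg$batches), rep(c("dataset1", "dataset2"), each = 3))
  # gene content is symmetric
  mg2 <- merge_datasets(d2, d1)
  expect_setequal(rownames(mg$values), rownames(mg2$values))
  # no overlap / duplicate samples
  m3 <- matrix(1:4, 2, 2, dimnames = list(c("Z1", "Z2"), paste0("z", 1:2)))
  expect_error(merge_datasets(d1, expression_dataset(m3 * 1.0, c(0, 1))),
               "no overlapping genes")
  expect_error(merge_datasets(d1, d1), "duplicate sample ids")
})

test_that("a 130 + 71 merge yields 201 samples", {
  d1 <- generate_expression(sim_config(n_genes = 40, n_class1 = 80,
                                       n_class0 = 50, seed = 1))
  d2 <- generate_expression(sim_config(n_genes = 40, n_class1 = 50,
                                       n_class0 = 21, seed = 2))
  colnames(d2$values) <- paste0("T", seq_len(ncol(d2$values)))
  names(d2$labels) <- colnames(d2$values)
  mg <- merge_datasets(d1, d2)
  expect_equal(ncol(mg$values), 201)
})

test_that("self-merge under renamed samples doubles samples, keeps genes", {
  d <- generate_expression(sim_config(n_genes = 25, n_class1 = 10,
                                      n_class0 = 10, seed = 3))
  d2 <- d
  colnames(d2$values) <- paste0("R", seq_len(ncol(d2$values)))
  names(d2$labels) <- colnames(d2$values)
  mg <- merge_datasets(d, d2)
  expect_equal(nrow(mg$values), 25)
  expect_equal(ncol(mg$values), 40)
})

test_that("batch centering equalizes per-batch means and keeps global means", {
  cfg <- sim_config(n_genes = 150, n_class1 = 60, n_class0 = 60,
                    n_informative = 10, effect_size = 2,
                    batch_assignment = rep(c("A", "B"), 60),
                    batch_shift = 2, batch_scale = 1.5, seed = 3)
  ds <- generate_expression(cfg)
  bc <- batch_center(ds)
  inA <- bc$batches == "A"
  dmeans <- rowMeans(bc$values[, inA]) - rowMeans(bc$values[, !inA])
  expect_lt(max(abs(dmeans)), 1e-9)
  expect_lt(max(abs(rowMeans(bc$values) - rowMeans(ds$values))), 1e-9)
  # Welch/BH across batches finds (almost) nothing after correction
  batch_as_label <- expression_dataset(bc$values, as.integer(bc$batches == "B"))
  r <- welch_t_rank(batch_as_label)
  expect_gte(mean(r$p_adj > 0.05), 0.95)
})

test_that("batch centering validates its inputs", {
  d <- generate_expression(sim_config(n_genes = 10, n_class1 = 5,
                                      n_class0 = 5, seed = 1))
  expect_error(batch_center(d), "batch labels")
  d$batches <- stats::setNames(rep("A", 10), colnames(d$values))
  expect_error(batch_center(d), ">= 2 batches")
  d$batches[1] <- "B"
  expect_error(batch_center(d), "B")
})

test_that("pure additive shifts are fully removed", {
  set.seed(8)
  m <- matrix(rnorm(300), 10, 30,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:30)))
  m[, 16:30] <- m[, 16:30] + 3
  d <- expression_dataset(m, rep(c(0, 1), 15),
                          batches = rep(c("A", "B"), each = 15))
  bc <- batch_center(d)
  dm <- rowMeans(bc$values[, 1:15]) - rowMeans(bc$values[, 16:30])
  expect_lt(max(abs(dm)), 1e-9)
})

test_that("diagnostics report exact symmetry and calibrated null fractions", {
  # mirror-augmented sample: skewness exactly 0
  base <- rnorm(20)
  v <- c(base, -base)
  m <- matrix(rep(v, 2), nrow = 2, byrow = TRUE,
              dimnames = list(c("g1", "g2"), paste0("s", 1:40)))
  d <- expression_dataset(m + 0, rep(c(1, 0), each = 20))
  # per class the sample is v itself? ensure both classes see a symmetric set
  m2 <- rbind(g1 = c(v, v))
  colnames(m2) <- paste0("s", 1:80)
  d2 <- expression_dataset(m2, rep(c(1, 0), each = 40))
  dg <- distribution_diagnostics(d2)
  expect_equal(dg$table$skew_class1, 0, tolerance = 1e-10)
  expect_equal(dg$table$skew_class0, 0, tolerance = 1e-10)

  # equal-variance normal data: variance-equality fraction >= 0.90 at alpha 0.05
  set.seed(11)
  mm <- matrix(rnorm(500 * 200), 500, 200,
               dimnames = list(sprintf("g%03d", 1:500), sprintf("s%03d", 1:200)))
  dn <- expression_dataset(mm, rep(c(1, 0), each = 100))
  dgn <- distribution_diagnostics(dn)
  expect_gte(dgn$summary$frac_equal_var_levene, 0.90)
  expect_gte(dgn$summary$frac_equal_var_bartlett, 0.90)

  # exponential gene: normality rejected at n = 200 per class
  set.seed(12)
  me <- rbind(gexp = rexp(400))
  colnames(me) <- paste0("s", 1:400)
  de <- expression_dataset(me, rep(c(1, 0), each = 200))
  dge <- distribution_diagnostics(de)
  expect_lt(dge$table$ks_p_class1, 0.05)
  expect_lt(dge$table$ks_p_class0, 0.05)

  # class too small
  tiny <- expression_dataset(mm[1:3, 1:5], c(1, 1, 0, 0, 0)[1:5])
  expect_error(distribution_diagnostics(tiny), ">= 3 samples")
})

test_that("the knee-point heuristic lands between two expression regimes", {
  set.seed(4)
  m <- rbind(matrix(rnorm(50 * 40, mean = 0, sd = 0.3), 50, 40),
             matrix(rnorm(50 * 40, mean = 8, sd = 0.3), 50, 40))
  dimnames(m) <- list(sprintf("g%03d", 1:100), sprintf("s%02d", 1:40))
  d <- expression_dataset(m, rep(c(0, 1), 20))
  thr <- suggest_ge_threshold(d, grid = seq(-2, 10, by = 0.25))
  expect_gt(thr, 0)
  expect_lt(thr, 8)
})
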