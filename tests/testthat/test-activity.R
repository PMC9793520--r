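test_that("target correlation is Spearman with safe handling of constants", {
  tb <- make_two_block_expr(n_pos = 3, n_neg = 2, n_samples = 8, seed = 11)
  co <- target_correlation(tb$expr, rownames(tb$expr))
  expect_true(isSymmetric(co))
  expect_equal(unname(diag(co)), rep(1, nrow(co)))
  # brute-force rank-then-Pearson on every pair
  for (i in 1:4) for (j in (i + 1):5)
    expect_equal(co[i, j],
                 bf_spearman(tb$expr[i, ], tb$expr[j, ]), tolerance = 1e-12)

  dup <- rbind(a = 1:8, b = (1:8)^3, c = -(1:8))  # same ranks / negated
  colnames(dup) <- paste0("s", 1:8)
  co2 <- target_correlation(dup, c("a", "b", "c"))
  expect_equal(co2["a", "b"], 1)
  expect_equal(co2["a", "c"], -1)

  cst <- rbind(a = 1:8, b = rep(2, 8))
  colnames(cst) <- paste0("s", 1:8)
  expect_warning(co3 <- target_correlation(cst, c("a", "b")), "constant")
  expect_equal(co3["a", "b"], 0)
})

test_that("signed spectral split separates anti-correlated blocks", {
  blocks <- matrix(-0.9, 4, 4,
                   dimnames = list(letters[1:4], letters[1:4]))
  blocks[1:2, 1:2] <- 0.9
  blocks[3:4, 3:4] <- 0.9
  diag(blocks) <- 1
  g <- split_two_groups(blocks)
  expect_setequal(
    list(sort(g$group_pos), sort(g$group_neg))[[
      which(c("a" %in% g$group_pos, "a" %in% g$group_neg))]],
    c("a", "b"))
  expect_setequal(sort(c(g$group_pos, g$group_neg)), letters[1:4])

  coherent <- matrix(0.9, 4, 4, dimnames = dimnames(blocks))
  diag(coherent) <- 1
  g2 <- split_two_groups(coherent)
  expect_setequal(g2$group_pos, letters[1:4])
  expect_length(g2$group_neg, 0L)

  expect_error(split_two_groups(matrix(1, 1, 1)), ">= 2")
})

test_that("planted two-block structure is recovered across seeds", {
  hits <- vapply(1:100, function(s) {
    tb <- make_two_block_expr(n_pos = 10, n_neg = 10, n_samples = 30,
                              noise_sd = 0.8, seed = s)
    co <- target_correlation(tb$expr, rownames(tb$expr))
    g <- split_two_groups(co)
    setequal(g$group_pos, tb$pos) && setequal(g$group_neg, tb$neg) ||
      setequal(g$group_pos, tb$neg) && setequal(g$group_neg, tb$pos)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("coherence filtering drops antipodal members but never empties", {
  co <- matrix(0.8, 3, 3, dimnames = list(c("a", "b", "c"),
                                          c("a", "b", "c")))
  diag(co) <- 1
  g <- structure(list(group_pos = c("a", "b", "c"),
                      group_neg = character(), filtered_out = character(),
                      scheme = "no_tf_expr", flipped = FALSE),
                 class = "target_grouping")
  # identical rows: all distances equal the mean, strict > keeps everyone
  gf <- filter_incoherent(g, co)
  expect_length(gf$filtered_out, 0L)

  co2 <- matrix(c(1, 0.9, -0.8,
                  0.9, 1, -0.8,
                  -0.8, -0.8, 1), 3, 3,
                dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  g2 <- structure(list(group_pos = c("a", "b", "c"),
                       group_neg = character(),
                       filtered_out = character(),
                       scheme = "no_tf_expr", flipped = FALSE),
                  class = "target_grouping")
  gf2 <- filter_incoherent(g2, co2)
  expect_identical(gf2$filtered_out, "c")
  expect_setequal(gf2$group_pos, c("a", "b"))
  # single-pass contract: filtering the already-filtered grouping with the
  # original matrix changes nothing further
  expect_identical(filter_incoherent(gf2, co2)$group_pos, gf2$group_pos)
})

test_that("Hill weights hit the half-point and decrease in s", {
  expect_equal(hill_weight(0.05), 0.5)
  expect_equal(hill_weight(1e-300), 1, tolerance = 5e-3)
  expect_equal(hill_weight(1), 1 / (1 + 20^0.2), tolerance = 1e-12)
  s <- seq(0.001, 1, length.out = 50)
  expect_true(all(diff(hill_weight(s)) < 0))
  expect_true(all(hill_weight(s) > 0 & hill_weight(s) <= 1))
  expect_error(hill_weight(1.2), "\\[0, 1\\]")
})

test_that("activity is the weighted signed average of target z-scores", {
  z <- matrix(c(1, -1, 0.5, 0.2, -0.3, 0.8,
                0.4, 0.1, -0.2, 0.9, -0.5, 0.3,
                -0.6, 0.2, 0.7, -0.1, 0.4, -0.9,
                0.05, -0.4, 0.3, 0.6, -0.7, 0.1),
              4, 6, byrow = TRUE,
              dimnames = list(c("g1", "g2", "g3", "g4"),
                              paste0("s", 1:6)))
  de <- data.frame(gene = rownames(z), statistic = 1:4,
                   p_value = c(0.01, 0.05, 0.5, 0.9),
                   s_adj = c(0.01, 0.05, 0.5, 0.9),
                   log2fc = 0, row.names = rownames(z))
  class(de) <- c("de_result", "data.frame")
  g <- structure(list(group_pos = c("g1", "g2"),
                      group_neg = c("g3", "g4"),
                      filtered_out = character(),
                      scheme = "no_tf_expr", flipped = FALSE),
                 class = "target_grouping")
  act <- compute_activity(z, g, de)
  # spreadsheet-style recomputation
  w <- 1 / (1 + (c(0.01, 0.05, 0.5, 0.9) / 0.05)^0.2)
  sgn <- c(1, 1, -1, -1)
  manual <- colSums(z * w * sgn) / sum(w)
  expect_equal(act, manual, tolerance = 1e-12)

  # uniform weights reduce to the signed mean; group swap negates
  g_all <- g
  g_all$group_pos <- rownames(z); g_all$group_neg <- character()
  expect_equal(compute_activity(z, g_all), colMeans(z), tolerance = 1e-12)
  g_sw <- g
  g_sw$group_pos <- g$group_neg; g_sw$group_neg <- g$group_pos
  expect_equal(compute_activity(z, g_sw, de), -act, tolerance = 1e-12)

  # adding a gene with maximal adjusted p changes A by a bounded amount
  z5 <- rbind(z, g5 = rep(2, 6))
  de5 <- rbind(de, g5 = data.frame(gene = "g5", statistic = 0, p_value = 1,
                                   s_adj = 1, log2fc = 0))
  class(de5) <- c("de_result", "data.frame")
  g5 <- g; g5$group_pos <- c(g$group_pos, "g5")
  act5 <- compute_activity(z5, g5, de5)
  w5 <- 1 / (1 + 20^0.2)
  bound <- w5 / (sum(w) + w5) * (2 + max(abs(act)))
  expect_true(all(abs(act5 - act) <= bound + 1e-12))

  expect_error(compute_activity(z, g, de[1:3, ]), "missing from DE")
})

test_that("activity sign aligns with TF expression, zero correlation stands", {
  tb <- make_two_block_expr(n_samples = 12, seed = 21)
  act <- tb$latent
  al <- align_activity_sign(act, tb$latent, split_two_groups(
    target_correlation(tb$expr, rownames(tb$expr))))
  expect_identical(al$activity, act)
  expect_false(al$grouping$flipped)

  g0 <- al$grouping
  al2 <- align_activity_sign(act, -tb$latent, g0)
  expect_identical(al2$activity, -act)
  expect_true(al2$grouping$flipped)
  expect_identical(al2$grouping$group_pos, g0$group_neg)

  # orthogonal ranks: Spearman exactly zero, no flip
  a <- c(1, 2, 3, 4)
  b <- c(2, 4, 1, 3)
  expect_equal(cor(a, b, method = "spearman"), 0)
  al3 <- align_activity_sign(a, b, g0)
  expect_identical(al3$activity, a)

  expect_warning(align_activity_sign(act, rep(1, 12), g0), "constant")
})

test_that("correlation-sign grouping splits and filters against the mean", {
  tf <- c(1, 4, 2, 8, 5, 7, 3, 6)
  expr <- rbind(TF = tf, dup = tf * 2, neg = -tf)
  colnames(expr) <- paste0("s", 1:8)
  g <- split_by_tf_correlation(expr, "TF", c("dup", "neg"))
  expect_identical(g$group_pos, "dup")
  expect_identical(g$group_neg, "neg")
  expect_length(g$filtered_out, 0L)   # |rho| all 1 = mean, strict <

  set.seed(31)
  n <- 40
  tf2 <- rnorm(n)
  expr2 <- rbind(TF = tf2,
                 s1 = tf2 + rnorm(n, sd = 0.1),
                 s2 = -tf2 + rnorm(n, sd = 0.1),
                 z1 = rnorm(n), z2 = rnorm(n), z3 = rnorm(n))
  colnames(expr2) <- paste0("c", 1:n)
  g2 <- split_by_tf_correlation(expr2, "TF", rownames(expr2)[-1])
  rho <- apply(expr2[-1, ], 1, cor, y = tf2, method = "spearman")
  expect_setequal(g2$filtered_out,
                  names(rho)[abs(rho) < mean(abs(rho))])
  expect_true("s1" %in% g2$group_pos)
  expect_true("s2" %in% g2$group_neg)

  pos_only <- rbind(TF = tf, a = tf + 0.1, b = tf * 3)
  colnames(pos_only) <- paste0("s", 1:8)
  g3 <- split_by_tf_correlation(pos_only, "TF", c("a", "b"))
  expect_length(g3$group_neg, 0L)
  expect_error(split_by_tf_correlation(expr, "nope", c("dup", "neg")),
               "not in expression")
})

test_that("scheme selection prefers the coherent-block scheme when TF expression is noise", {
  tb <- make_two_block_expr(n_pos = 8, n_neg = 8, n_samples = 40,
                            noise_sd = 0.4, seed = 41)
  set.seed(42)
  expr <- rbind(tb$expr, TF = rnorm(40))   # TF expression unrelated
  targets <- c(tb$pos, tb$neg)
  fit <- choose_scheme(expr, standardize_expression(expr), "TF", targets)
  expect_identical(fit$grouping$scheme, "no_tf_expr")
  expect_gt(abs(cor(fit$activity, tb$latent, method = "spearman")), 0.9)
})

test_that("the activity orchestrator honors overrides, skips, empty input", {
  tb <- make_two_block_expr(n_pos = 6, n_neg = 6, n_samples = 20, seed = 51)
  db <- regulon_db(list(TFA = c(tb$pos, tb$neg),
                        TFB = c("p1", "p2")))       # too few targets
  act <- suppressWarnings(
    infer_activity(tb$expr, db, c("TFA", "TFB"), min_targets = 5))
  expect_identical(rownames(act), "TFA")
  expect_identical(attr(act, "skipped"), "TFB")

  act_neg <- suppressWarnings(
    infer_activity(tb$expr, db, "TFA", min_targets = 5,
                   sign_overrides = c(TFA = -1)))
  expect_equal(act_neg[1, ], -act[1, ], tolerance = 1e-12)

  empty <- suppressWarnings(infer_activity(tb$expr, db, character()))
  expect_identical(nrow(empty), 0L)
})

test_that("inference is invariant to target gene ordering", {
  tb <- make_two_block_expr(n_pos = 5, n_neg = 5, n_samples = 25, seed = 61)
  targets <- c(tb$pos, tb$neg)
  db1 <- regulon_db(list(TF = targets))
  db2 <- regulon_db(list(TF = rev(targets)))
  a1 <- suppressWarnings(infer_activity(tb$expr, db1, "TF"))
  a2 <- suppressWarnings(infer_activity(tb$expr, db2, "TF"))
  expect_equal(abs(a1[1, ]), abs(a2[1, ]), tolerance = 1e-10)
})
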