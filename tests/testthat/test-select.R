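test_that("correlation groups are the components of the |r|>0.8 graph", {
  set.seed(5)
  z <- rnorm(400)
  df <- data.frame(a = z, b = z + rnorm(400, 0, 1e-6), c = rnorm(400))
  g <- correlation_groups(df)
  sizes <- sort(vapply(g, length, integer(1)))
  expect_equal(sizes, c(1L, 2L))
  expect_true(any(vapply(g, function(x) setequal(x, c("a", "b")),
                         logical(1))))

  # independent features: all singletons
  ind <- as.data.frame(matrix(rnorm(5000 * 6), ncol = 6))
  expect_equal(vapply(correlation_groups(ind), length, integer(1)),
               rep(1L, 6))

  # chain A-B, B-C strong, A-C weak: one component by transitivity;
  # verified against a hand BFS on the empirical correlation matrix
  set.seed(6)
  b <- rnorm(20000)
  chain <- data.frame(A = 0.88 * b + sqrt(1 - 0.88^2) * rnorm(20000),
                      B = b,
                      C = 0.88 * b + sqrt(1 - 0.88^2) * rnorm(20000))
  r <- cor(chain)
  expect_gt(abs(r["A", "B"]), 0.8)
  expect_gt(abs(r["B", "C"]), 0.8)
  expect_lt(abs(r["A", "C"]), 0.8)
  g2 <- correlation_groups(chain)
  expect_equal(length(g2), 1)
  expect_setequal(g2[[1]], c("A", "B", "C"))

  const <- data.frame(a = rnorm(50), k = rep(1, 50))
  expect_warning(gc <- correlation_groups(const), "constant")
  expect_equal(length(gc), 2)
})

test_that("RF importance retains the signal feature of a group", {
  kept_signal <- vapply(1:200, function(seed) {
    set.seed(seed)
    n <- 150
    label <- rep(c("CN", "PMCI"), each = n / 2)
    df <- data.frame(label = label,
                     signal = rnorm(n) + ifelse(label == "PMCI", 1.5, 0),
                     noise = rnorm(n))
    kept <- rf_group_select(list(c("signal", "noise")), df,
                            ntree = 150, seed = seed)
    kept == "signal"
  }, logical(1))
  expect_gte(mean(kept_signal), 0.95)
})

test_that("singleton groupings and fixed seeds are stable", {
  df <- toy_training(n = 80, seed = 2)
  g <- list("f1", "f2")
  expect_equal(rf_group_select(g, df, seed = 4), c("f1", "f2"))
  full <- list(c("f1", "f2"))
  expect_identical(rf_group_select(full, df, seed = 4),
                   rf_group_select(full, df, seed = 4))
})

test_that("the univariate tree AUC filter separates signal from noise", {
  df <- toy_training(n = 200, seed = 3, effect = 3)
  df$copy <- as.numeric(df$label == "PMCI")  # feature equal to label
  res <- univariate_auc_filter(df, c("copy", "f1", "f2"), seed = 1)
  expect_gt(res$auc[["copy"]], 0.95)
  expect_true("copy" %in% res$selected)
  expect_true("f1" %in% res$selected)

  # label-independent features: mean AUC near 1/2, dropped most times
  null_res <- vapply(1:50, function(seed) {
    set.seed(seed + 1000)
    df0 <- data.frame(label = rep(c("CN", "PMCI"), each = 100),
                      x = rnorm(200))
    r <- univariate_auc_filter(df0, "x", seed = seed)
    c(auc = r$auc[["x"]], dropped = !("x" %in% r$selected))
  }, numeric(2))
  expect_equal(mean(null_res["auc", ]), 0.5, tolerance = 0.05)
  expect_gt(mean(null_res["dropped", ]), 0.5)
})

test_that("monotone transforms do not change what the filter keeps", {
  df <- toy_training(n = 150, seed = 7, effect = 2)
  df$f1exp <- exp(df$f1)
  r <- univariate_auc_filter(df, c("f1", "f1exp"), seed = 2)
  expect_equal(r$auc[["f1"]], r$auc[["f1exp"]], tolerance = 1e-9)
  expect_true(all(c("f1", "f1exp") %in% r$selected))
})

test_that("two-step selection recovers informative features", {
  # informative latent structure: two signal features (one duplicated)
  # and three pure-noise features
  set.seed(11)
  n <- 400
  label <- rep(c("CN", "PMCI"), c(300, 100))
  s1 <- rnorm(n) + ifelse(label == "PMCI", 1.4, 0)
  s2 <- rnorm(n) + ifelse(label == "PMCI", 1.0, 0)
  df <- data.frame(label = label, s1 = s1, s1dup = s1 + rnorm(n, 0, 0.05),
                   s2 = s2, n1 = rnorm(n), n2 = rnorm(n))
  rep_sel <- select_features(df, features = c("s1", "s1dup", "s2",
                                              "n1", "n2"), seed = 3)
  expect_true(any(c("s1", "s1dup") %in% rep_sel$selected))
  expect_true("s2" %in% rep_sel$selected)
  expect_false(all(c("s1", "s1dup") %in% rep_sel$selected))
  expect_true(all(rep_sel$selected %in% rep_sel$retained))
  expect_true(all(rep_sel$dropped$reason %in%
                    c("auc_at_or_below_0.5", "correlated_redundant")))
  # pure function of (training data, seeds)
  rep2 <- select_features(df, features = c("s1", "s1dup", "s2",
                                           "n1", "n2"), seed = 3)
  expect_identical(rep_sel$selected, rep2$selected)
})
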