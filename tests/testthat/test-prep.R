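test_that("skewness matches known values and handles edge cases", {
  expect_equal(skewness(c(-1, 0, 1)), 0)
  expect_equal(skewness(rep(5, 10)), 0)
  expect_error(skewness(c(1, 2)), "3 finite")
  set.seed(3)
  expect_equal(skewness(stats::rexp(100000)), 2, tolerance = 0.1)
})

test_that("log transform applies the designated set and guards zeros", {
  df <- data.frame(mean_latency_ms = rep(1, 5),
                   total_test_time_s = 2:6)
  out <- log_transform(df)
  expect_equal(out$features, "mean_latency_ms")
  expect_equal(out$table$mean_latency_ms, rep(0, 5))
  expect_equal(out$table$total_test_time_s, 2:6)  # not log-marked

  # data-driven policy: modest skewness stays untransformed,
  # a log-normal feature is brought inside (-1, 1)
  set.seed(8)
  df2 <- data.frame(a = stats::rnorm(4000, 10),
                    b = stats::rlnorm(4000, 0, 1))
  expect_lt(abs(skewness(df2$a)), 1)
  out2 <- log_transform(df2, features = c("a", "b"),
                        policy = "skewness")
  expect_equal(out2$features, "b")
  expect_lt(abs(skewness(out2$table$b)), 1)

  df3 <- data.frame(sd_latency_ms = c(0, 1, 2, 4))
  out3 <- log_transform(df3)
  expect_true(all(is.finite(out3$table$sd_latency_ms)))
  df4 <- data.frame(sd_latency_ms = c(-1, 1, 2))
  expect_error(log_transform(df4), "sd_latency_ms")
})

test_that("stratified split preserves class proportions by rounding", {
  set.seed(1)
  tab <- data.frame(label = rep(c("CN", "PMCI"), c(166, 40)),
                    f = rnorm(206), id = seq_len(206))
  sp <- stratified_split(tab, 0.2, seed = 5)
  expect_equal(as.numeric(sp$counts$test[c("CN", "PMCI")]), c(33, 8))
  expect_equal(as.numeric(sp$counts$train[c("CN", "PMCI")]),
               c(133, 32))
  expect_equal(length(intersect(sp$train$id, sp$test$id)), 0)
  # deterministic membership
  sp2 <- stratified_split(tab, 0.2, seed = 5)
  expect_identical(sp$test$id, sp2$test$id)
  expect_error(stratified_split(tab, 0), "test_fraction")
  # explicit count override reproduces an external partition
  sp3 <- stratified_split(tab, seed = 5,
                          test_counts = c(CN = 31, PMCI = 11))
  expect_equal(as.numeric(sp3$counts$test[c("CN", "PMCI")]), c(31, 11))
  expect_equal(as.numeric(sp3$counts$train[c("CN", "PMCI")]),
               c(135, 29))
})

test_that("SMOTE raises the minority to the majority count", {
  set.seed(2)
  tr <- data.frame(label = rep(c("CN", "PMCI"), c(135, 29)),
                   f1 = rnorm(164), f2 = rnorm(164))
  out <- smote(tr, seed = 9)
  expect_equal(as.numeric(table(out$label)[c("CN", "PMCI")]),
               c(135, 135))
  expect_equal(sum(out$is_synthetic), 135 - 29)
  expect_true(all(out$label[out$is_synthetic] == "PMCI"))
  # majority rows untouched
  expect_identical(out[out$label == "CN", c("f1", "f2")],
                   tr[tr$label == "CN", c("f1", "f2")])
  # already balanced input returned unchanged
  bal <- data.frame(label = rep(c("CN", "PMCI"), each = 10),
                    f1 = rnorm(20))
  expect_equal(nrow(smote(bal)), 20)
})

test_that("every synthetic point lies between two original minority points", {
  set.seed(4)
  tr <- data.frame(label = rep(c("CN", "PMCI"), c(30, 8)),
                   f1 = c(rnorm(30), rnorm(8, 3)),
                   f2 = c(rnorm(30), rnorm(8, -2)))
  out <- smote(tr, seed = 11)
  minority <- as.matrix(tr[tr$label == "PMCI", c("f1", "f2")])
  synth <- as.matrix(out[out$is_synthetic, c("f1", "f2")])
  for (i in seq_len(nrow(synth))) {
    s <- synth[i, ]
    on_segment <- FALSE
    for (a in seq_len(nrow(minority))) {
      for (b in seq_len(nrow(minority))) {
        if (a == b) next
        u <- minority[b, ] - minority[a, ]
        w <- s - minority[a, ]
        cross <- u[1] * w[2] - u[2] * w[1]
        along <- sum(w * u) / sum(u * u)
        if (abs(cross) < 1e-9 && along >= -1e-9 && along <= 1 + 1e-9) {
          on_segment <- TRUE
          break
        }
      }
      if (on_segment) break
    }
    expect_true(on_segment)
  }
  # tiny minorities reduce k with a warning, below 2 is an error
  small <- data.frame(label = rep(c("CN", "PMCI"), c(12, 4)),
                      f1 = rnorm(16))
  expect_warning(smote(small, k_neighbors = 5), "k = 3")
  one <- data.frame(label = rep(c("CN", "PMCI"), c(5, 1)),
                    f1 = rnorm(6))
  expect_error(smote(one), "at least 2")
})

test_that("standardization is train-fitted, applied, and invertible", {
  set.seed(6)
  tr <- data.frame(a = rnorm(50, 10, 3), b = rnorm(50, -2, 0.5))
  te <- data.frame(a = rnorm(20, 14, 3), b = rnorm(20, 0, 0.5))
  st <- standardize_fit(tr)
  ztr <- standardize_apply(st, tr)
  expect_equal(unname(colMeans(ztr)), c(0, 0), tolerance = 1e-9)
  expect_equal(unname(vapply(ztr, sd, numeric(1))), c(1, 1),
               tolerance = 1e-9)
  # applying the train state to shifted test data is not a refit
  zte <- standardize_apply(st, te)
  expect_gt(mean(zte$a), 0.5)
  rt <- destandardize(st, ztr)
  expect_equal(rt$a, tr$a, tolerance = 1e-9)
  expect_warning(standardize_fit(data.frame(a = rep(2, 5))),
                 "zero-variance")
})

test_that("median imputation is fitted on training only", {
  tr <- data.frame(a = c(1, 2, 3, NA), b = c(5, 5, NA, 5))
  te <- data.frame(a = c(NA, 10), b = c(NA, 1))
  st <- impute_fit(tr)
  expect_equal(impute_apply(st, tr)$a, c(1, 2, 3, 2))
  out <- impute_apply(st, te)
  expect_equal(out$a, c(2, 10))   # train median, not test information
  expect_equal(out$b, c(5, 1))
})
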