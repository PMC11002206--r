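test_that("group summaries report n, mean and SEM", {
  s <- group_summary(c(1, 2, 3, 10, 20, 30),
                     rep(c("a", "b"), each = 3))
  expect_equal(s$n, c(3, 3))
  expect_equal(s$mean, c(2, 20))
  expect_equal(s$sem, c(sd(1:3) / sqrt(3), sd(c(10, 20, 30)) / sqrt(3)))
})

test_that("two_group_test matches the textbook pooled-variance formula", {
  a <- c(1, 2, 3)
  b <- c(4, 5, 6)
  res <- two_group_test(a, b)
  # hand-computed Student t with pooled variance
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  t_manual <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
  expect_equal(res$statistic, t_manual, tolerance = 1e-12)
  expect_equal(res$df, 4)
  expect_equal(res$p_value,
               2 * pt(abs(t_manual), df = 4, lower.tail = FALSE),
               tolerance = 1e-12)

  same <- two_group_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_equal(same$stars, "ns")

  expect_error(two_group_test(1, c(2, 3)), "at least 2")
})

test_that("t p-value agrees with the exhaustive permutation oracle", {
  # oracle: enumerate every relabeling of the pooled values (combn),
  # p = fraction of |t| at least as extreme as observed
  perm_p <- function(a, b) {
    pooled <- c(a, b)
    n <- length(pooled)
    idx <- utils::combn(n, length(a), simplify = FALSE)
    t_of <- function(x, y) {
      sp2 <- ((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
        (length(x) + length(y) - 2)
      (mean(x) - mean(y)) / sqrt(sp2 * (1 / length(x) + 1 / length(y)))
    }
    t_obs <- abs(t_of(a, b))
    hits <- vapply(idx, function(i)
      abs(t_of(pooled[i], pooled[-i])) >= t_obs - 1e-12, TRUE)
    mean(hits)
  }
  set.seed(11)
  for (r in 1:5) {
    a <- round(rnorm(5, 0, 1), 2)
    b <- round(rnorm(6, 0.8, 1), 2)
    p_t <- two_group_test(a, b)$p_value
    p_perm <- perm_p(a, b)
    # the permutation null is discrete at these n; agreement is coarse
    expect_lt(abs(p_t - p_perm), 0.12)
  }
})

test_that("one-way ANOVA reduces to t^2 with two groups", {
  set.seed(3)
  a <- rnorm(6)
  b <- rnorm(6, 1)
  res_t <- two_group_test(a, b)
  res_f <- oneway_anova(list(a = a, b = b))
  expect_equal(res_f$statistic, res_t$statistic^2, tolerance = 1e-10)
  expect_equal(res_f$p_value, res_t$p_value, tolerance = 1e-10)
})

test_that("ANOVA handles identical groups and flags a shifted group via Tukey", {
  res0 <- oneway_anova(list(a = c(1, 2, 3), b = c(1, 2, 3),
                            c = c(1, 2, 3)))
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)
  expect_null(res0$posthoc)

  set.seed(5)
  groups <- list(g1 = rnorm(8), g2 = rnorm(8), g3 = rnorm(8),
                 g4 = rnorm(8, 3))
  res <- oneway_anova(groups)
  expect_lt(res$p_value, 0.05)
  expect_false(is.null(res$posthoc))
  with_g4 <- grepl("g4", res$posthoc$contrast)
  expect_true(all(res$posthoc$p_adj[with_g4] < 0.05))
  expect_true(all(res$posthoc$p_adj[!with_g4] > 0.05))

  expect_error(oneway_anova(list(a = 1:3)), "at least 2 groups")
  expect_error(oneway_anova(list(a = 1:3, b = 2)), "at least 2 observations")
})

test_that("significance stars follow the panel thresholds and are monotone", {
  expect_equal(significance_stars(0.2), "ns")
  expect_equal(significance_stars(0.04), "*")
  expect_equal(significance_stars(0.01), "**")
  expect_equal(significance_stars(0.0005), "***")
  expect_equal(significance_stars(0.00005), "****")
  expect_error(significance_stars(1.5), "\\[0, 1\\]")

  ps <- sort(runif(50))
  ranks <- match(significance_stars(ps), c("****", "***", "**", "*", "ns"))
  expect_true(all(diff(ranks) >= 0))
})

test_that("fold change divides treated by control means", {
  expect_equal(fold_change(4, 2), 2)
  expect_equal(fold_change(7, 7), 1)
  expect_equal(fold_change(1.4, 1.0), 1.4)
  expect_error(fold_change(1, 0), "> 0")
})

test_that("compare_endpoints emits one tidy row per endpoint per stratum", {
  co <- make_cohort(cohort_spec(n_per_group = 6, seed = 2))
  cmp <- compare_endpoints(co$endpoints, c("rcr", "leak_ci"))
  expect_equal(nrow(cmp), 4)  # 2 endpoints x 2 sexes
  expect_setequal(unique(cmp$stratum), c("male", "female"))
  expect_true(all(cmp$p_value >= 0 & cmp$p_value <= 1))
  expect_true(all(cmp$stars %in% c("ns", "*", "**", "***", "****")))
  expect_error(compare_endpoints(co$endpoints, "nope"), "absent")
})
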