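test_that("standardisation centres and scales exactly", {
  z <- standardize_features(matrix(c(1, 2, 3), dimnames = list(NULL, "a")))
  expect_equal(as.numeric(z), c(-1, 0, 1))  # sample sd of 1,2,3 is 1

  set.seed(51)
  m <- matrix(rnorm(60, 5, 3), 20, 3)
  z1 <- standardize_features(m)
  expect_equal(standardize_features(z1), z1, tolerance = 1e-12)

  df <- data.frame(ok = rnorm(10), flat = rep(2, 10))
  expect_error(standardize_features(df), "flat")
})

test_that("univariate pseudo-F equals the classical one-way ANOVA F", {
  set.seed(52)
  for (k in 1:10) {
    n <- sample(20:80, 1)
    g <- factor(sample(letters[1:sample(2:3, 1)], n, replace = TRUE))
    while (any(table(g) < 2)) g <- factor(sample(levels(g), n, replace = TRUE))
    y <- rnorm(n) + as.numeric(g) * runif(1, 0, 1)
    f_ref <- anova(stats::lm(y ~ g))$`F value`[1]
    pm <- permanova(matrix(y), g, n_perm = 0)
    expect_lt(abs(pm$pseudo_f - f_ref), 1e-10)
  }
})

test_that("two identical groups give pseudo-F of zero", {
  set.seed(53)
  m <- matrix(rnorm(30), 10, 3)
  x <- rbind(m, m)
  g <- rep(c("a", "b"), each = 10)
  pm <- permanova(x, g, n_perm = 49, seed = 1)
  expect_lt(abs(pm$pseudo_f), 1e-10)
})

test_that("pseudo-F is invariant to simultaneous row/label permutation", {
  set.seed(54)
  x <- matrix(rnorm(90), 30, 3)
  g <- rep(c("a", "b", "c"), each = 10)
  f0 <- permanova(x, g, n_perm = 0)$pseudo_f
  for (k in 1:5) {
    perm <- sample(30)
    expect_equal(permanova(x[perm, ], g[perm], n_perm = 0)$pseudo_f, f0)
  }
})

test_that("permutation p-values are seeded, bounded and reproducible", {
  set.seed(55)
  d <- data.frame(y = rnorm(24), g = rep(c("a", "b"), 12))
  p1 <- permanova(y ~ g, d, n_perm = 199, seed = 7)
  p2 <- permanova(y ~ g, d, n_perm = 199, seed = 7)
  expect_identical(p1$p_value, p2$p_value)
  expect_gte(p1$p_value, 1 / 200)
  expect_lte(p1$p_value, 1)
  expect_equal(p1$df_between, 1L)
  expect_equal(p1$df_within, 22L)
})

test_that("the implementation agrees with vegan's adonis2 on Euclidean distances", {
  set.seed(56)
  x <- matrix(rnorm(120), 40, 3)
  g <- rep(c("a", "b"), each = 20)
  ours <- permanova(x, g, n_perm = 99, seed = 2)
  ref <- vegan::adonis2(stats::dist(x) ~ g, permutations = 99)
  expect_equal(ours$pseudo_f, ref$F[1], tolerance = 1e-10)
  expect_equal(ours$ss_total, ref$SumOfSqs[rownames(ref) == "Total"],
               tolerance = 1e-10)
})

test_that("the formula interface accepts single and cbind responses", {
  set.seed(57)
  d <- data.frame(a = rnorm(20), b = rnorm(20), season = rep(c("x", "y"), 10))
  m1 <- permanova(cbind(a, b) ~ season, data = d, n_perm = 49, seed = 1)
  m2 <- permanova(as.matrix(d[, c("a", "b")]), d$season, n_perm = 49, seed = 1)
  expect_equal(m1$pseudo_f, m2$pseudo_f)
  expect_output(print(m1), "PERMANOVA")
  expect_s3_class(summary(m1), "summary.permanova")

  expect_error(permanova(d$a, rep("x", 20), n_perm = 9), "2 groups")
  expect_error(permanova(d$a[1:3], c("x", "x", "y"), n_perm = 9), "at least 2 rows")
})
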