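test_that("the Mann-Whitney branch equals exhaustive enumeration", {
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  got <- group_test(a, b, normal = FALSE)
  expect_equal(got$statistic, 0)
  expect_equal(got$p, 0.1)
  expect_equal(mw_exact_oracle(a, b), 0.1)

  set.seed(31)
  for (i in 1:8) {
    na <- sample(3:6, 1); nb <- sample(3:6, 1)
    vals <- sample(100, na + nb)   # distinct, no ties
    a <- vals[seq_len(na)]; b <- vals[-seq_len(na)]
    expect_equal(group_test(a, b, normal = FALSE)$p, mw_exact_oracle(a, b),
                 tolerance = 1e-12)
  }
})

test_that("the t branch behaves canonically and both are symmetric", {
  a <- c(1.2, 1.9, 2.4, 3.1)
  same <- group_test(a, a, normal = TRUE)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  b <- a + 1
  expect_equal(group_test(a, b, normal = TRUE)$p,
               group_test(b, a, normal = TRUE)$p)
  expect_equal(group_test(a, b, normal = FALSE)$p,
               group_test(b, a, normal = FALSE)$p)
  expect_error(group_test(a, numeric(0), TRUE),
               class = "tug_parameter_error")
})

test_that("normality testing is calibrated and powered", {
  set.seed(8)
  p_norm <- replicate(40, normality_test(rnorm(300)))
  expect_gte(mean(p_norm >= 0.05), 0.85)
  p_lnorm <- replicate(40, normality_test(exp(rnorm(300))))
  expect_gte(mean(p_lnorm < 0.05), 0.95)
  expect_error(normality_test(rep(1, 10)), class = "tug_degenerate_error")
  expect_error(normality_test(c(1, 2)), class = "tug_parameter_error")
})

test_that("ANCOVA adjustment removes covariate structure only", {
  # identical covariates: adjustment is the identity
  tab <- toy_feature_table(seed = 5)
  const <- tab
  const$age <- 70; const$gds <- 3
  adj_const <- ancova_adjust(const)
  for (col in sprintf("f%02d", 1:8))
    expect_equal(adj_const[[col]], const[[col]], tolerance = 1e-12)

  # a covariate aliased with group is unidentifiable
  aliased <- tab
  aliased$age <- ifelse(aliased$group == "AD", 75, 68)
  expect_error(ancova_adjust(aliased), class = "tug_adjustment_error")

  adj <- ancova_adjust(tab)
  # idempotence: residual covariate association is zero
  adj2 <- ancova_adjust(adj)
  for (col in sprintf("f%02d", 1:8))
    expect_lt(max(abs(adj2[[col]] - adj[[col]])), 1e-9)
})

test_that("adjustment recovers an injected group effect under confounding", {
  set.seed(12)
  effect <- 1.5
  diffs <- replicate(60, {
    n <- 30
    group <- rep(c("HC", "AD"), each = n)
    age <- ifelse(group == "AD", rnorm(2 * n, 76, 4), rnorm(2 * n, 68, 3))
    gds <- pmax(0, ifelse(group == "AD", rnorm(2 * n, 6, 2),
                          rnorm(2 * n, 1.5, 1)))
    y <- 2 * age + 0.5 * gds + effect * (group == "AD") + rnorm(2 * n, 0, 0.5)
    tab <- feature_table(data.frame(y = y), group, age, gds)
    adj <- ancova_adjust(tab)
    mean(adj$y[group == "AD"]) - mean(adj$y[group == "HC"])
  })
  expect_lt(abs(mean(diffs) - effect) / effect, 0.10)
})

test_that("selection prunes duplicates and respects significance", {
  tab <- toy_feature_table(n_per_group = 25, k_informative = 2,
                           separation = 3, n_features = 6, seed = 9)
  tab$f05 <- tab$f01 + rnorm(nrow(tab), 0, 1e-3)   # near-exact copy
  rep <- select_features(tab)
  expect_true(all(rep$selected %in%
                    rep$per_feature$feature[rep$per_feature$significant]))
  expect_false(all(c("f01", "f05") %in% rep$selected))
  expect_true(any(c("f01", "f05") %in% rep$selected))
  dropped <- rep$per_feature[rep$per_feature$outcome == "dropped_for", ]
  expect_true(all(!is.na(dropped$dropped_for)))

  # no significant features: empty selection, complete report
  null_tab <- toy_feature_table(n_per_group = 10, k_informative = 0,
                                n_features = 5, seed = 77)
  rep0 <- select_features(null_tab)
  expect_length(rep0$selected, 0)
  expect_equal(nrow(rep0$per_feature), 5)
})

test_that("informative features survive, copies are pruned", {
  set.seed(21)
  n <- 30
  group <- rep(c("HC", "AD"), each = n)
  base <- matrix(rnorm(2 * n * 5), 2 * n, 5)
  base[group == "AD", ] <- base[group == "AD", ] + 2.5
  x <- cbind(base, base + matrix(rnorm(2 * n * 5, 0, 0.05), 2 * n, 5))
  colnames(x) <- sprintf("g%02d", 1:10)
  tab <- feature_table(x, group, rnorm(2 * n, 70, 3), rnorm(2 * n, 2, 1))
  rep <- select_features(tab)
  expect_equal(length(rep$selected), 5)
})

test_that("selection is invariant to feature column order", {
  tab <- toy_feature_table(n_per_group = 20, k_informative = 3,
                           separation = 2.5, n_features = 8, seed = 13)
  rep1 <- select_features(tab)
  perm <- c("subject_id", "group", "age", "gds",
            rev(table_cols <- sprintf("f%02d", 1:8)))
  rep2 <- select_features(tab[, perm])
  expect_setequal(rep1$selected, rep2$selected)
})
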