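test_that("summary-statistic ANOVA equals the raw-data decomposition", {
  set.seed(1)
  for (rep in 1:10) {
    groups <- lapply(sample(2:4, 1) |> seq_len(),
                     function(i) rnorm(sample(5:20, 1), mean = runif(1, 0, 2)))
    raw <- one_way_anova(groups)
    smry <- anova_from_summary(vapply(groups, length, 1L),
                               vapply(groups, mean, 1),
                               vapply(groups, sd, 1))
    expect_equal(raw$statistic, smry$statistic, tolerance = 1e-9)
    expect_equal(raw$p, smry$p, tolerance = 1e-9)
  }
  # two exactly equal groups: F = 0, p = 1
  eq <- anova_from_summary(c(10, 10), c(1, 1), c(0.5, 0.5))
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p, 1)
  expect_error(anova_from_summary(c(1, 10), c(1, 2), c(1, 1)), "n >= 2")
})

test_that("two-group ANOVA is the squared pooled t test", {
  set.seed(2)
  a <- rnorm(12); b <- rnorm(15, 0.5)
  an <- one_way_anova(list(a, b))
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(an$statistic, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(an$p, tt$p.value, tolerance = 1e-9)
})

test_that("normality gate accepts normal and rejects heavy-tailed samples", {
  expect_error(ks_normality(c(1, 2)), "at least")
  set.seed(4)
  # null rejection rate calibrated to alpha = 0.05 within Monte-Carlo error
  fp <- replicate(400, ks_normality(rnorm(500)) < 0.05)
  expect_gte(mean(fp), 0.02)
  expect_lte(mean(fp), 0.08)
  rej <- replicate(200, ks_normality(rt(500, df = 2)) < 0.05)
  expect_gte(mean(rej), 0.90)
})

test_that("variance gate calibrates at alpha and detects inflated spread", {
  set.seed(6)
  fp <- replicate(500, levene_test(list(rnorm(20), rnorm(20), rnorm(20)))$p < 0.05)
  expect_gt(mean(fp), 0.02); expect_lt(mean(fp), 0.09)
  hit <- replicate(200,
    levene_test(list(rnorm(50), rnorm(50, sd = 4)))$p < 0.05)
  expect_gt(mean(hit), 0.9)
  ident <- rnorm(10)
  lv <- levene_test(list(ident, ident))
  expect_equal(lv$statistic, 0)
  expect_equal(lv$p, 1)
})

test_that("post hoc pairs follow their defining identities", {
  x <- rnorm(8)
  same <- list(a = x, b = x, c = x)
  lsd <- posthoc_lsd(same)
  expect_true(all(lsd$p == 1))

  set.seed(8)
  a <- rnorm(10); b <- rnorm(12, 1)
  lsd2 <- posthoc_lsd(list(a = a, b = b))
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(lsd2$p, tt$p.value, tolerance = 1e-9)

  for (rep in 1:10) {
    g <- list(a = rnorm(8), b = rnorm(9, 0.5), c = rnorm(7, 1, 2))
    tam <- posthoc_tamhane_t2(g)
    welch_p <- mapply(function(g1, g2)
      t.test(g[[g1]], g[[g2]])$p.value, tam$group1, tam$group2)
    expect_true(all(tam$p >= unname(welch_p) - 1e-12))
    expect_equal(tam$p_unadjusted, unname(welch_p), tolerance = 1e-9)
  }
})

test_that("rank test matches a from-scratch H computation and has power", {
  ident <- list(1:6, 1:6)
  expect_error(kruskal_wallis(list(rep(1, 5), rep(1, 5))), "tied")
  kw0 <- kruskal_wallis(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(kw0$statistic, 0, tolerance = 1e-12)
  expect_equal(kw0$p, 1)

  set.seed(10)
  for (rep in 1:20) {
    g <- lapply(1:3, function(i) sample(1:8, sample(4:9, 1), replace = TRUE))
    expect_equal(kruskal_wallis(g)$statistic, naive_kruskal_h(g),
                 tolerance = 1e-9)
  }
  hit <- replicate(200, {
    kruskal_wallis(list(rnorm(30), rnorm(30, 2)))$p < 0.05
  })
  expect_gt(mean(hit), 0.9)
})

test_that("chi-square handles proportional tables and degenerate margins", {
  prop <- rbind(c(10, 20), c(20, 40), c(5, 10))
  cs <- chi_square_table(prop)
  expect_equal(cs$statistic, 0, tolerance = 1e-12)
  expect_equal(cs$p, 1)
  expect_error(chi_square_table(rbind(c(0, 0), c(1, 2))), "zero row")
  expect_error(chi_square_table(matrix(1, 1, 2)), "2 x 2")
  # chi-square survival at df = 2 is exp(-x/2)
  x <- c(0.5, 1, 2.77, 5, 9.21)
  expect_equal(pchisq(x, df = 2, lower.tail = FALSE), exp(-x / 2),
               tolerance = 1e-12)
})

test_that("the decision protocol gates route to the right test", {
  set.seed(12)
  g3 <- list(a = rnorm(15), b = rnorm(15), c = rnorm(15))
  res <- compare_groups(g3)
  expect_equal(res$test, "anova")
  expect_false(is.null(res$posthoc))
  expect_true(res$posthoc_method %in% c("lsd", "tamhane_t2"))

  g2 <- list(a = rnorm(15), b = rnorm(15))
  res2 <- compare_groups(g2)
  expect_null(res2$posthoc)           # no post hoc with two groups

  skewed <- list(a = rexp(40)^3, b = rexp(40)^3, c = rexp(40)^3)
  expect_equal(compare_groups(skewed)$test, "kruskal")

  expect_error(compare_groups(list(a = 1:2, b = 1:10)), "at least 2 groups")
})

test_that("the full protocol keeps its nominal false-positive rate", {
  set.seed(14)
  flags <- replicate(500, {
    g <- list(a = rnorm(10), b = rnorm(10), c = rnorm(10))
    compare_groups(g)$significant
  })
  expect_gte(mean(flags), 0.03)
  expect_lte(mean(flags), 0.08)
})

test_that("cell-wise comparison drops NAs and reports empty cells", {
  tbl <- data.frame(
    eye_id = rep(sprintf("e%02d", 1:12), each = 2),
    zone = rep(c("fovea", "para_S"), 12),
    vessel_class = "all",
    vd = c(rnorm(12, 0.3, 0.02), rnorm(12, 0.1, 0.02))[order(rep(1:12, 2))])
  tbl$vd[tbl$eye_id == "e01" & tbl$zone == "fovea"] <- NA
  grouping <- setNames(rep(c("g1", "g2", "g3"), each = 4),
                       sprintf("e%02d", 1:12))
  res <- compare_metric_across_groups(tbl, grouping, metrics = "vd")
  expect_equal(nrow(res), 2)
  expect_true(all(!is.na(res$p)))
  ph <- attr(res, "posthoc")
  expect_true(is.null(ph) || all(ph$p >= 0 & ph$p <= 1))
  expect_error(
    compare_metric_across_groups(tbl, grouping[1:3], metrics = "vd"),
    "does not cover")
})
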