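test_that("normality screening holds its level and detects lognormal data", {
  level <- vapply(1:100, function(s) {
    set.seed(s)
    test_normality(rnorm(1000))$p_value > 0.05
  }, logical(1))
  expect_gte(mean(level), 0.90)
  power <- vapply(1:100, function(s) {
    set.seed(1000 + s)
    test_normality(exp(rnorm(1000)))$p_value < 0.05
  }, logical(1))
  expect_gte(mean(power), 0.99)
  expect_error(test_normality(rep(1, 10)), "constant")
  expect_error(test_normality(c(1, 2)), "at least 3")
  # the KS route (Lilliefors) agrees qualitatively
  set.seed(3)
  expect_gt(test_normality(rnorm(500), method = "ks")$p_value, 0.05)
  expect_lt(test_normality(exp(rnorm(500)), method = "ks")$p_value, 0.05)
})

test_that("transform choice follows the screen-then-transform ladder", {
  set.seed(11)
  expect_identical(as.character(choose_transform(rnorm(500, 10))), "identity")
  set.seed(12)
  expect_identical(as.character(choose_transform(10^rnorm(500))), "log10")
  # data that none of the candidates normalize falls back to log10, loudly
  set.seed(13)
  bimodal <- c(rnorm(300, 1, 0.01), rnorm(300, 100, 0.01))
  expect_warning(tr <- choose_transform(bimodal), "falling back")
  expect_identical(as.character(tr), "log10")
  expect_true(length(attr(tr, "trace")) >= 3)
})

test_that("mean +/- s.e. summaries are exact and equivariant", {
  ms <- summarize_mean_se(c(1, 2, 3))
  expect_equal(ms$mean, 2)
  expect_equal(ms$se, sd(c(1, 2, 3)) / sqrt(3))
  expect_equal(ms$se, 1 / sqrt(3))
  one <- summarize_mean_se(42)
  expect_equal(one$mean, 42)
  expect_true(is.na(one$se))
  expect_error(summarize_mean_se(numeric(0)), "no finite")
  # location and scale equivariance
  set.seed(21)
  for (i in 1:5) {
    x <- rnorm(20); a <- runif(1, -5, 5); b <- runif(1, 0.1, 10)
    base <- summarize_mean_se(x)
    shifted <- summarize_mean_se(a + b * x)
    expect_equal(shifted$mean, a + b * base$mean)
    expect_equal(shifted$se, b * base$se)
  }
})

test_that("paired t-test reports the before-minus-after reduction", {
  # group-mean scale worked example: ejection fraction 68% at baseline,
  # 52% post-infarct in three animals -> 16 percentage point reduction
  baseline <- c(66, 68, 70)
  post <- c(50, 52, 54)
  res <- paired_t(baseline, post)
  expect_equal(res$mean_difference, 16)
  expect_lt(res$p_value, 0.05)
  # identical pairs: no evidence of change
  same <- paired_t(c(5, 6, 7), c(5, 6, 7))
  expect_equal(same$mean_difference, 0)
  expect_equal(same$p_value, 1)
  # constant difference d with n = 3 is recovered exactly
  expect_equal(paired_t(c(1, 2, 3), c(0, 1, 2))$mean_difference, 1)
  expect_error(paired_t(1:3, 1:4), "mismatch")
})

test_that("the mixed model collapses to the two-sample t-test without clustering", {
  set.seed(31)
  # every observation its own animal and cell: no estimable clustering
  tab <- data.frame(value = c(rnorm(12, 0), rnorm(12, 0.8)),
                    region = rep(c("A", "B"), each = 12),
                    animal_id = sprintf("an%02d", 1:24),
                    cell_id = sprintf("c%02d", 1:24))
  fit <- suppressWarnings(fit_region_contrast(tab, regions = c("A", "B"),
                                              transform = "identity"))
  tt <- t.test(value ~ region, data = tab, var.equal = TRUE)
  expect_lt(abs(fit$p_value - tt$p.value), 1e-3)
  expect_equal(fit$estimate, -diff(tt$estimate) * -1, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("region contrasts respect the clustering that pooled tests ignore", {
  # strong animal effects, no true region difference: the pooled t-test is
  # fooled far more often than the mixed model
  hits_mixed <- 0; hits_pooled <- 0
  for (s in 1:40) {
    tab <- simulate_clustered(400 + s, delta = 0, sd_animal = 1)
    fit <- suppressWarnings(fit_region_contrast(tab, regions = c("A", "B"),
                                                transform = "identity"))
    hits_mixed <- hits_mixed + (fit$p_value < 0.05)
    hits_pooled <- hits_pooled +
      (t.test(value ~ region, data = tab, var.equal = TRUE)$p.value < 0.05)
  }
  expect_lte(hits_mixed, hits_pooled)
  expect_lt(hits_mixed / 40, 0.2)
})

test_that("contrast bookkeeping: transform, group stats and reduced designs", {
  tab <- simulate_clustered(77, delta = 1)
  fit <- suppressWarnings(fit_region_contrast(tab, metric = "demo",
                                              regions = c("A", "B"),
                                              transform = "identity"))
  expect_s3_class(fit, "region_contrast")
  gs <- fit$group_stats
  expect_identical(gs$n_observations, c(135L, 135L))
  expect_identical(gs$n_cells, c(9L, 9L))
  expect_identical(gs$n_animals, c(3L, 3L))
  expect_equal(gs$mean[1], mean(tab$value[tab$region == "A"]))
  expect_identical(names(coef(fit)), "B-A")
  expect_output(print(fit), "Region contrast: demo")
  # single animal per region falls back with a prominent warning
  tab1 <- tab[tab$animal_id %in% c("A1", "B1"), ]
  expect_warning(fit1 <- fit_region_contrast(tab1, regions = c("A", "B"),
                                             transform = "identity"),
                 "fewer than 2 animals")
  expect_true(is.finite(fit1$p_value))
  # degenerate all-identical values
  tab2 <- tab; tab2$value <- 1
  expect_error(fit_region_contrast(tab2, regions = c("A", "B")), "identical")
})

test_that("log-scale data is analysed on its chosen transform", {
  set.seed(55)
  tab <- simulate_clustered(88, delta = 0)
  tab$value <- 10^(tab$value * 0.3 + 1)
  fit <- suppressWarnings(fit_region_contrast(tab, regions = c("A", "B")))
  expect_identical(fit$transform, "log10")
  # group stats stay on the original scale
  expect_equal(fit$group_stats$mean[1], mean(tab$value[tab$region == "A"]))
})
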