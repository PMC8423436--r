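test_that("Kruskal-Wallis reproduces the hand-computed rank statistic", {
  kw <- kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(kw$H, 32 / 7, tolerance = 1e-12)
  expect_equal(kw$df, 2)
  # degenerate all-identical data
  kw0 <- kruskal_wallis(list(c(2, 2), c(2, 2), c(2, 2)))
  expect_identical(kw0$H, 0)
  expect_identical(kw0$p, 1)
  expect_error(kruskal_wallis(list(1:3)), "two groups")
})

test_that("two-group Kruskal-Wallis is consistent with Mann-Whitney", {
  set.seed(31)
  for (i in 1:20) {
    a <- rnorm(25)
    b <- rnorm(25, 0.5)
    kw <- kruskal_wallis(list(a, b))
    mw <- mann_whitney(a, b)
    expect_lt(abs(kw$p - mw$p), 0.02)
  }
})

test_that("Mann-Whitney exact path matches the printed example and handles ties", {
  mw <- mann_whitney(c(1, 2), c(3, 4))
  expect_identical(mw$method, "exact")
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 2 / 6, tolerance = 1e-12)
  same <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_identical(same$method, "normal_approx")  # ties force the approximation
  expect_equal(same$p, 1)
  expect_error(mann_whitney(numeric(0), 1:3), "nonempty")
})

test_that("the exact Mann-Whitney path matches full enumeration", {
  set.seed(17)
  for (i in 1:60) {
    na <- sample(2:6, 1)
    nb <- sample(2:6, 1)
    x <- sample(1000, na + nb)   # distinct values: no ties
    a <- x[seq_len(na)]
    b <- x[-seq_len(na)]
    mw <- mann_whitney(a, b)
    or <- mw_enumeration_oracle(a, b)
    expect_equal(mw$U, or$U)
    expect_equal(mw$p, or$p, tolerance = 1e-12)
  }
})

test_that("exact and approximate Mann-Whitney p agree for moderate n", {
  set.seed(23)
  for (i in 1:200) {
    a <- rnorm(6)
    b <- rnorm(6, 0.3)
    p_ex <- mann_whitney(a, b)$p
    p_ap <- mann_whitney(a, b, exact_max_n = 0)$p
    expect_lt(abs(p_ex - p_ap), 0.02)
  }
})

test_that("the two-stage step-up reproduces the worked example", {
  res <- bky_two_stage(c(0.01, 0.02, 0.5), q = 0.05)
  expect_identical(res$reject, c(TRUE, TRUE, FALSE))
  # all null
  expect_false(any(bky_two_stage(rep(1, 6))$reject))
  # adjusted q is the smallest level at which each hypothesis falls
  expect_true(all(res$qvalue[1:2] < 0.05) && res$qvalue[3] > 0.05)
  for (i in 1:2) {
    qv <- res$qvalue[i]
    expect_true(bky_two_stage(c(0.01, 0.02, 0.5), q = min(qv * 1.01, 0.999),
                              compute_q = FALSE)$reject[i])
  }
  expect_error(bky_two_stage(c(0.2, 1.3)), "0, 1")
})

test_that("two-stage reject sets match an independent transcription", {
  set.seed(11)
  for (i in 1:300) {
    m <- sample(1:50, 1)
    p <- round(runif(m)^sample(c(1, 2, 4), 1), 4)
    q <- sample(c(0.01, 0.05, 0.1), 1)
    expect_identical(bky_two_stage(p, q = q, compute_q = FALSE)$reject,
                     bky_oracle(p, q = q))
  }
})

test_that("the two-stage reject set contains plain BH whenever stage 1 fires", {
  set.seed(13)
  for (i in 1:200) {
    m <- sample(2:40, 1)
    p <- runif(m)^2
    two <- bky_two_stage(p, compute_q = FALSE)$reject
    bh <- p.adjust(p, "BH") <= 0.05
    if (any(two)) expect_true(all(!bh | two))
    # reject set is a prefix of the p-sorted list
    o <- order(p)
    r <- two[o]
    if (any(r)) expect_true(all(r[seq_len(max(which(r)))]))
  }
})

test_that("two-way ANOVA handles balanced, degenerate and empty-cell designs", {
  region <- rep(c("DG", "CA1"), each = 8)
  age <- rep(rep(c("young", "old"), each = 4), 2)
  noise <- rep(c(-1, 1, -0.5, 0.5), 4)
  # identical cell means: all effects vanish
  res0 <- two_way_anova(noise, region, age)
  expect_true(all(abs(res0$F) < 1e-20))
  expect_true(all(res0$p > 0.999))
  # balanced design: Type II equals the hand-computed decomposition
  cell_means <- c(2, 5, 3, 6)  # additive: region effect 1, age effect 3
  y <- noise + rep(cell_means, each = 4)[order(rep(1:4, 4))]
  y <- noise + c(rep(2, 4), rep(5, 4), rep(3, 4), rep(6, 4))
  res <- two_way_anova(y, region, age)
  n <- 4
  gm <- mean(y)
  ss_region <- 8 * sum((tapply(y, region, mean) - gm)^2)
  ss_age <- 8 * sum((tapply(y, age, mean) - gm)^2)
  cm <- tapply(y, interaction(region, age), mean)
  ss_cells <- 4 * sum((cm - gm)^2)
  ss_int <- ss_cells - ss_region - ss_age
  ss_res <- sum((y - ave(y, interaction(region, age)))^2)
  f_int <- (ss_int / 1) / (ss_res / 12)
  expect_equal(res$F[res$term == "region:age"], f_int, tolerance = 1e-8)
  expect_equal(res$F[res$term == "region"], (ss_region / 1) / (ss_res / 12),
               tolerance = 1e-8)
  # empty cell named in the error
  expect_error(two_way_anova(rnorm(6), c("a", "a", "a", "b", "b", "b"),
                             c("x", "x", "x", "x", "x", "y")),
               "region=a, age=y")
})

test_that("region effects are detected in unbalanced designs like the soma panel", {
  set.seed(7)
  ns <- c(7, 12, 6, 8)
  region <- rep(rep(c("DG", "CA1"), 2), ns)
  age <- rep(c("young", "young", "old", "old"), ns)
  hits <- 0
  for (i in 1:500) {
    y <- rnorm(sum(ns)) + ifelse(region == "DG", 2, 0)  # 2 SD region effect
    res <- two_way_anova(y, region, age)
    if (res$p[res$term == "region"] < 0.05) hits <- hits + 1
  }
  expect_gte(hits / 500, 0.9)
})

test_that("the median CI uses binomial order statistics", {
  res <- median_ci(1:100)
  # expected ranks from the binomial quantile at alpha/2
  l <- qbinom(0.025, 100, 0.5)
  expect_equal(res$median, 50.5)
  expect_equal(res$lo, l)
  expect_equal(res$hi, 100 + 1 - l)
  expect_gte(res$coverage, 0.95)
  expect_warning(r3 <- median_ci(c(3, 1, 2)), "coverage")
  expect_equal(c(r3$lo, r3$hi), c(1, 3))
  rc <- median_ci(rep(7, 20))
  expect_equal(c(rc$median, rc$lo, rc$hi), c(7, 7, 7))
})

test_that("percent differences match the printed group comparisons", {
  expect_equal(round(percent_difference(0.27, 0.19)), 42)
  expect_equal(percent_difference(1, 1), 0)
  expect_equal(percent_difference(0.11, 0.27), -59.3, tolerance = 1e-3)
  expect_error(percent_difference(1, 0), "nonzero")
})

test_that("threshold fractions count strict exceedances", {
  expect_equal(threshold_fraction(c(0.5, 1.2, 2.0), 1), 100 * 2 / 3)
  expect_equal(threshold_fraction(c(0.1, 0.2), 1), 0)
  expect_equal(threshold_fraction(c(0.1, 0.2, 5), 1, "less"), 100 * 2 / 3)
})

test_that("the sampled exceedance fraction matches the lognormal tail", {
  cfg <- population_config(500, 0.27, cv = 0.8, seed = 3)
  vols <- vapply(sample_population(cfg), function(s) attr(s, "target_volume_um3"),
                 numeric(1))
  sdlog <- sqrt(log(1 + 0.8^2))
  meanlog <- log(0.27) - sdlog^2 / 2
  tail_pct <- 100 * plnorm(1, meanlog, sdlog, lower.tail = FALSE)
  expect_lt(abs(threshold_fraction(vols, 1) - tail_pct), 3)
})

test_that("the ECDF is right-continuous with unit range", {
  f <- ecdf_fn(c(1, 2, 3))
  expect_equal(f(2), 2 / 3)
  expect_equal(f(0.5), 0)
  expect_equal(f(3), 1)
  g <- ecdf_fn(c(1, 2, 3))
  x <- seq(0, 4, by = 0.01)
  expect_equal(max(abs(f(x) - g(x))), 0)  # Kolmogorov distance of identical samples
})

test_that("mitotype summaries report group means with SEM", {
  rec <- data.frame(region = c("DG", "DG", "DG", "CA1"),
                    compartment = "axon", age = "young",
                    V_um3 = c(0.1, 0.2, 0.3, 0.5), MCI = c(1, 2, 3, 4))
  mt <- mitotype_summary(rec, c("region"))
  dg <- mt[mt$region == "DG", ]
  expect_equal(dg$mean_V_um3, 0.2)
  expect_equal(dg$sem_V_um3, sd(c(0.1, 0.2, 0.3)) / sqrt(3))
  ca <- mt[mt$region == "CA1", ]
  expect_identical(ca$n, 1L)
  expect_equal(ca$sem_V_um3, 0)     # single record
  same <- mitotype_summary(data.frame(region = "DG", V_um3 = rep(2, 5),
                                      MCI = rep(3, 5)), "region")
  expect_equal(same$sem_MCI, 0)
  expect_equal(same$mean_V_um3, 2)
})
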