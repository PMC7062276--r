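test_that("summaries report sample moments, Tukey hinges and 1.5 IQR outliers", {
  d <- generate_technique_dataset(default_config(), "cryo")
  s <- summarize_diameters(d)
  expect_equal(s$mean_nm, 138, tolerance = 1e-12)
  expect_equal(s$sd_nm, 21, tolerance = 1e-12)
  expect_identical(s$n, 300L)
  expect_true(s$q1_nm <= s$median_nm && s$median_nm <= s$q3_nm)
  fn <- fivenum(d$diameter_nm)
  expect_equal(c(s$q1_nm, s$median_nm, s$q3_nm), fn[2:4])
  expect_true(all(s$outliers < s$q1_nm - 1.5 * (s$q3_nm - s$q1_nm) |
                    s$outliers > s$q3_nm + 1.5 * (s$q3_nm - s$q1_nm)))
  expect_gte(s$whisker_low_nm, min(d$diameter_nm))
  expect_lte(s$whisker_high_nm, max(d$diameter_nm))

  # constant data: zero SD, no outliers
  sc <- summarize_diameters(diameter_dataset("x", 1, rep(50, 10)))
  expect_equal(sc$sd_nm, 0)
  expect_length(sc$outliers, 0)

  # direct evaluation of the Tukey rule: 100 is far outside the fences of 1..9
  so <- summarize_diameters(diameter_dataset("x", 1, c(1:9, 100)))
  expect_equal(so$outliers, 100)
  expect_equal(so$whisker_high_nm, 9)

  expect_error(summarize_diameters(diameter_dataset("x", 1, 5)),
               "insufficient")
})

test_that("percent changes reproduce the quoted integer shifts after rounding", {
  expect_equal(percent_change(124, 102), 100 * 22 / 102)
  expect_equal(round(percent_change(124, 102)), 22)
  expect_equal(round(percent_change(126, 102)), 24)
  expect_equal(round(percent_change(138, 102)), 35)
  expect_equal(round(percent_change(138, 126)), 10)
  expect_equal(round(percent_change(99, 138)), -28)
  expect_equal(percent_change(77, 77), 0)
  expect_error(percent_change(100, 0), "positive")
})

test_that("one-way ANOVA matches the squared pooled t on two groups", {
  cfg <- small_config()
  a <- generate_technique_dataset(cfg, "tem", seed = 1)
  b <- generate_technique_dataset(cfg, "cryo", seed = 2)
  aov2 <- anova_oneway(list(a, b))
  tt <- ttest_two_tailed(a, b, variant = "pooled")
  expect_equal(aov2$f_stat, tt$t_stat^2, tolerance = 1e-9)
  expect_equal(aov2$p_value, tt$p_value, tolerance = 1e-9)
  expect_identical(aov2$df_between, 1)
  expect_identical(aov2$df_within, as.double(nrow(a) + nrow(b) - 2))
})

test_that("calibrated five-technique data separate overwhelmingly; degenerate input flags", {
  cfg <- default_config()
  datasets <- lapply(cfg$calibration$technique,
                     function(t) generate_technique_dataset(cfg, t))
  res <- anova_oneway(datasets)
  expect_lt(res$p_value, 0.001)
  expect_identical(res$df_between, 4)
  expect_identical(res$df_within, 1495)

  const <- lapply(1:3, function(i) diameter_dataset("x", 1, rep(10, 5)))
  dg <- anova_oneway(const)
  expect_true(dg$degenerate)
  expect_equal(dg$p_value, 1)
  expect_error(anova_oneway(list(const[[1]])), "at least 2")
})

test_that("type-I error of the ANOVA is nominal under the null", {
  set.seed(314)
  alpha <- 0.05
  n_sim <- 500
  rej <- logical(n_sim)
  for (i in seq_len(n_sim)) {
    groups <- lapply(1:5, function(g) diameter_dataset("g", 1,
                                                       rnorm(20, 120, 20)))
    rej[i] <- anova_oneway(groups)$p_value < alpha
  }
  bounds <- qbinom(c(0.005, 0.995), n_sim, alpha)
  expect_gte(sum(rej), bounds[1])
  expect_lte(sum(rej), bounds[2])
})

test_that("t tests work from raw data and from summary moments alike", {
  # Welch from the published moments: (102, 17, 300) vs (99, 32, 300)
  r <- ttest_two_tailed(list(n = 300, mean_nm = 102, sd_nm = 17),
                        list(n = 300, mean_nm = 99, sd_nm = 32))
  expect_equal(r$t_stat, 3 / sqrt(17^2 / 300 + 32^2 / 300), tolerance = 1e-12)
  expect_equal(r$t_stat, 1.43, tolerance = 0.005)
  expect_equal(r$p_value, 0.15, tolerance = 0.02)

  # raw-data route agrees with stats::t.test for both variants
  cfg <- small_config()
  a <- generate_technique_dataset(cfg, "tem", seed = 3)
  b <- generate_technique_dataset(cfg, "uts", seed = 4)
  for (variant in c("welch", "pooled")) {
    mine <- ttest_two_tailed(a, b, variant = variant)
    ref <- t.test(a$diameter_nm, b$diameter_nm,
                  var.equal = (variant == "pooled"))
    expect_equal(mine$t_stat, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(mine$df, unname(ref$parameter), tolerance = 1e-9)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-9)
  }

  # swapping the pair flips t and the sign of the percent change
  fwd <- ttest_two_tailed(a, b)
  rev <- ttest_two_tailed(b, a)
  expect_equal(fwd$t_stat, -rev$t_stat)
  expect_equal(fwd$p_value, rev$p_value)

  # identical inputs: t = 0, p = 1; constant equal groups flag as degenerate
  same <- ttest_two_tailed(a, a)
  expect_equal(same$t_stat, 0)
  expect_equal(same$p_value, 1)
  dg <- ttest_two_tailed(diameter_dataset("x", 1, rep(5, 4)),
                         diameter_dataset("y", 1, rep(5, 4)))
  expect_true(dg$degenerate)
  expect_equal(dg$p_value, 1)
})

test_that("Welch and pooled variants coincide for equal sizes and variances", {
  x <- diameter_dataset("a", 1, c(100, 110, 120, 130))
  y <- diameter_dataset("b", 1, c(105, 115, 125, 135))
  w <- ttest_two_tailed(x, y, "welch")
  p <- ttest_two_tailed(x, y, "pooled")
  expect_equal(w$t_stat, p$t_stat, tolerance = 1e-12)
  expect_equal(w$df, p$df, tolerance = 1e-12)
  expect_equal(w$p_value, p$p_value, tolerance = 1e-12)
})

test_that("SD ratio ranges reproduce the published variance-ratio band", {
  uts <- list(sd_nm = 32)
  others <- lapply(c(17, 17, 17, 21), function(s) list(sd_nm = s))
  r <- sd_ratio_range(uts, others)
  expect_equal(unname(r["min"]), 32 / 21, tolerance = 1e-12)
  expect_equal(unname(r["max"]), 32 / 17, tolerance = 1e-12)
  expect_equal(round(unname(r), 1), c(1.5, 1.9))

  expect_equal(unname(sd_ratio_range(list(sd_nm = 5),
                                     list(list(sd_nm = 5)))), c(1, 1))
  # invariant to a common rescaling of all datasets
  r2 <- sd_ratio_range(list(sd_nm = 3.2),
                       lapply(c(1.7, 1.7, 1.7, 2.1),
                              function(s) list(sd_nm = s)))
  expect_equal(unname(r2), unname(r))
  expect_error(sd_ratio_range(uts, list()), "non-empty")
})
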