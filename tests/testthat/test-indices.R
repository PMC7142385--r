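test_that("phi equals Pearson on the expanded 0/1 indicators", {
  set.seed(11)
  for (rep in 1:25) {
    cnt <- rmultinom(1, size = sample(20:200, 1), prob = runif(4, 0.05, 1))[, 1]
    t <- contingency_2x2(cnt[1], cnt[2], cnt[3], cnt[4])
    margins <- c(t$n11 + t$n10, t$n01 + t$n00, t$n11 + t$n01, t$n10 + t$n00)
    if (any(margins == 0)) next
    rel <- rep(c(1, 1, 0, 0), times = cnt)
    pro <- rep(c(1, 0, 1, 0), times = cnt)
    expect_equal(phi_correlation(t), cor(rel, pro), tolerance = 1e-12)
  }
})

test_that("phi handles canonical tables", {
  expect_equal(round(phi_correlation(contingency_2x2(13, 7, 28, 73)), 3), 0.293)
  expect_equal(phi_correlation(contingency_2x2(9, 0, 0, 4)), 1)
  expect_equal(phi_correlation(contingency_2x2(25, 25, 25, 25)), 0)
  expect_error(phi_correlation(contingency_2x2(5, 5, 0, 0)), "margin")
  expect_error(contingency_2x2(-1, 2, 3, 4), "non-negative")
})

test_that("pearson_correlation validates its inputs", {
  expect_equal(pearson_correlation(1:10, 1:10), 1)
  expect_error(pearson_correlation(1:5, 1:4), "length")
  expect_error(pearson_correlation(rep(2, 5), 1:5), "constant")
  expect_error(pearson_correlation(1:2, 1:2), "at least 3")
  set.seed(3)
  expect_lt(abs(pearson_correlation(rnorm(10000), rnorm(10000))), 0.03)
})

test_that("HIC arithmetic and reporting", {
  hic <- compute_hic(0.549)
  expect_equal(hic$value, 1.098)
  expect_equal(round(hic$value, 2), 1.10)
  expect_equal(compute_hic(0.5)$value, 1)
  expect_equal(compute_hic(0)$value, 0)
  expect_equal(unname(coef(hic)), c(1.098, 0.549, 0.5))
  expect_output(print(hic), "HIC = 1.10")
  expect_output(print(summary(hic)), "Ro/Re")
  expect_error(compute_hic(1.2), "\\[-1, 1\\]")
  expect_warning(compute_hic(-0.2), "negative")
})

test_that("HIB records and uses the requested Re source", {
  pap <- compute_hib(0.293, K = 0.15, re_source = "paper_table")
  expect_equal(pap$re_used, 0.272)
  expect_equal(pap$value, 0.293 / 0.272, tolerance = 1e-12)
  expect_equal(round(pap$value, 2), 1.08)
  ana <- compute_hib(0.293, K = 0.15, re_source = "analytic")
  expect_equal(ana$re_used, expected_phi(0.15, "parent_child"))
  expect_equal(compute_hib(1 / 3, K = 0.5)$value, 1, tolerance = 1e-8)
  expect_error(compute_hib(0.5, K = 1.5), "'K'")
})

test_that("heredity_index dispatches on input type and is symmetric in the pair", {
  # contingency table input
  hib <- heredity_index(fixture_hammer(), K = 0.15, re_source = "paper_table")
  expect_equal(round(hib$ro, 3), 0.293)
  expect_equal(hib$n, 121L)
  # data.frame continuous input, relative/proband swap invariance
  fs <- simulate_family(test_config(n = 2000), "parent_child")
  df <- data.frame(relative_value = fs$relative, proband_value = fs$proband)
  h1 <- heredity_index(df, mode = "continuous")
  h2 <- heredity_index(data.frame(relative_value = fs$proband,
                                  proband_value = fs$relative),
                       mode = "continuous")
  expect_equal(h1$value, h2$value)
  expect_equal(h1$value, cor(fs$relative, fs$proband) / 0.5)
  # two-vector binary input normalizes to a 2x2 table
  bts <- dichotomize(fs, 0.25)
  hb <- heredity_index(bts$relative_status, bts$proband_status,
                       mode = "binary", K = 0.25)
  expect_equal(hb$ro, cor(bts$relative_status, bts$proband_status),
               tolerance = 1e-12)
  # proband identical to relative: perfect correlation, HIC = 2
  expect_equal(heredity_index(fs$relative, fs$relative,
                              mode = "continuous")$value, 2)
  expect_error(heredity_index(list(1, 2)), "unrecognized")
})

test_that("HIC recovers heritability across the h2 grid", {
  for (h2 in c(0.2, 0.4, 0.6, 0.8, 1.0)) {
    fs <- simulate_family(test_config(n = 100000, h2 = h2,
                                      seed = TEST_SEED + round(100 * h2)),
                          "parent_child")
    hic <- heredity_index(fs, mode = "continuous")
    expect_lt(abs(hic$value - h2), 0.03)
  }
})

test_that("pure-genetic binary cohorts are self-consistent (HIB = 1)", {
  cfg <- test_config()
  bts <- dichotomize(simulate_family(cfg, "parent_child"), 0.5)
  ro <- cor(bts$relative_status, bts$proband_status)
  # Re estimated from the identically seeded simulation reproduces Ro exactly
  self <- compute_hib(ro, K = 0.5, re_source = "simulation", config = cfg)
  expect_equal(self$value, 1, tolerance = 1e-12)
  # against the analytic Re the index is 1 up to Monte-Carlo error
  ana <- compute_hib(ro, K = 0.5, re_source = "analytic")
  expect_lt(abs(ana$value - 1), 3 / sqrt(cfg$n_families) / (1 / 3))
})
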