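test_that("sim_config validates every field and names the offender", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(n_families = 1), "n_families")
  expect_error(sim_config(effect_sd = 0), "effect_sd")
  expect_error(sim_config(effect_sd = -3), "effect_sd")
  expect_error(sim_config(heritability = 0), "heritability")
  expect_error(sim_config(heritability = 1.2), "heritability")
  expect_error(sim_config(seed = 1.5), "seed")
})

test_that("gamete draws match the configured distribution and are independent", {
  g <- generate_gametes(test_config())
  for (arr in g[c("A", "B", "C", "D")]) {
    expect_length(arr, 10000)
    expect_lt(abs(mean(arr) - 100), 1)
    expect_lt(abs(sd(arr) - 30), 0.6)
  }
  expect_lt(abs(cor(g$A, g$B)), 0.03)
  expect_lt(abs(cor(g$C, g$D)), 0.03)
  g2 <- generate_gametes(test_config())
  expect_identical(g$A, g2$A)
  expect_identical(g$D, g2$D)
})

test_that("child transmission is a uniform one-of-four gamete selection", {
  set.seed(TEST_SEED)
  g <- generate_gametes(sim_config(n_families = 10000))
  child <- transmit_child(g)
  combo <- attr(child, "combination")
  sums <- cbind(g$A + g$C, g$A + g$D, g$B + g$C, g$B + g$D)
  expect_true(all(child == sums[cbind(seq_along(child), combo)]))
  # every entry is one of the four admissible sums for its family
  expect_true(all(apply(abs(sums - child) < 1e-12, 1, any)))
  freq <- tabulate(combo, 4) / length(combo)
  expect_true(all(abs(freq - 0.25) < 0.02))
  # Mendelian share: the child carries A in half the families
  expect_lt(abs(mean(combo %in% c(1L, 2L)) - 0.5), 3 / sqrt(10000))
  # parent-child liability correlation is the Mendelian 0.5
  expect_lt(abs(cor(child, g$A + g$B) - 0.5), 0.03)
})

test_that("degenerate gametes collapse the four child combinations", {
  g <- structure(list(A = c(1, 2, 3), B = c(1, 2, 3),
                      C = c(10, 20, 30), D = c(10, 20, 30)),
                 class = "gamete_effects")
  set.seed(1)
  expect_equal(as.numeric(transmit_child(g)), c(11, 22, 33))
  g2 <- structure(list(A = c(5, 6), B = c(5, 6), C = c(5, 6), D = c(5, 6)),
                  class = "gamete_effects")
  expect_equal(as.numeric(transmit_sibling(g2)), c(10, 12))
  bad <- structure(list(A = 1:3, B = 1:3, C = 1:3, D = 1:2),
                   class = "gamete_effects")
  expect_error(transmit_child(bad), "identical length")
})

test_that("sibling transmission has the identity-by-descent mixture structure", {
  set.seed(TEST_SEED)
  g <- generate_gametes(sim_config(n_families = 20000))
  b1 <- g$A + g$B
  b2 <- transmit_sibling(g)
  shared <- attr(b2, "shared")
  expect_setequal(unique(shared), c(0L, 1L, 2L))
  # stratum correlations 1, 0.5, 0 by chromosomes shared
  expect_equal(cor(b1[shared == 2], b2[shared == 2]), 1)
  expect_lt(abs(cor(b1[shared == 1], b2[shared == 1]) - 0.5), 0.03)
  expect_lt(abs(cor(b1[shared == 0], b2[shared == 0])), 0.03)
  # marginal correlation is again 0.5
  expect_lt(abs(cor(b1, b2) - 0.5), 0.03)
})

test_that("simulate_family reproduces the pure-genetic correlations", {
  fs <- simulate_family(test_config(), "parent_child")
  expect_lt(abs(cor(fs$relative, fs$proband) - 0.5), 0.03)
  expect_lt(abs(cor(fs$relative, fs$mother)), 0.03)  # spouses unrelated
  sib <- simulate_family(test_config(), "sibling")
  expect_lt(abs(cor(sib$relative, sib$proband) - 0.5), 0.03)
  expect_error(simulate_family(test_config(), "cousin"))
  # fixed seed => bit-identical cohort
  fs2 <- simulate_family(test_config(), "parent_child")
  expect_identical(fs$proband, fs2$proband)
})

test_that("environmental noise attenuates the pair correlation to h2/2", {
  fs <- simulate_family(test_config(n = 100000, h2 = 0.6), "parent_child")
  expect_lt(abs(cor(fs$relative, fs$proband) - 0.30), 0.01)
})

test_that("thresholding is rank-based with deterministic tie-breaks", {
  x <- c(10, 20, 30, 40, 50, 60, 70, 80, 90, 100)
  expect_equal(threshold_binary(x, 0.3),
               as.integer(x %in% c(80, 90, 100)))
  # ties: lower index wins
  expect_equal(threshold_binary(rep(7, 4), 0.5), c(1L, 1L, 0L, 0L))
  set.seed(1)
  y <- rnorm(10000)
  expect_equal(sum(threshold_binary(y, 0.25)), 2500L)
  expect_error(threshold_binary(y, 0), "between 0 and 1")
  expect_error(threshold_binary(y, 1), "between 0 and 1")
  expect_error(threshold_binary(numeric(0), 0.5), "non-empty")
})

test_that("thresholding is invariant to strictly increasing transforms", {
  set.seed(42)
  for (K in c(0.5, 0.1, 0.03)) {
    y <- rnorm(500)
    base <- threshold_binary(y, K)
    expect_identical(threshold_binary(exp(y), K), base)
    expect_identical(threshold_binary(atan(y), K), base)
    expect_identical(threshold_binary(y * 1e6 + 3, K), base)
  }
})

test_that("correlations and incidences are invariant to affine effect rescaling", {
  a <- dichotomize(simulate_family(test_config(), "parent_child"), 0.25)
  cfg2 <- sim_config(n_families = 10000, effect_mean = 0, effect_sd = 1,
                     seed = TEST_SEED)
  b <- dichotomize(simulate_family(cfg2, "parent_child"), 0.25)
  expect_identical(a$relative_status, b$relative_status)
  expect_identical(a$proband_status, b$proband_status)
})

test_that("dichotomized cohorts have exact incidence", {
  for (K in c(0.5, 0.125, 0.01)) {
    bts <- dichotomize(simulate_family(test_config(), "parent_child"), K)
    expect_equal(mean(bts$relative_status), round(10000 * K) / 10000)
    expect_equal(mean(bts$proband_status), round(10000 * K) / 10000)
  }
})
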