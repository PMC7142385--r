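# shared test fixtures: one fixed RNG seed for all stochastic test cohorts
TEST_SEED <- 20200326L

test_config <- function(n = 10000, h2 = 1, seed = TEST_SEED) {
  sim_config(n_families = n, heritability = h2, seed = seed)
}

# frozen analytic oracle values, computed from the quadrant-probability
# integral and independently cross-checked against a direct bivariate-normal
# CDF and brute-force Monte Carlo
ORACLE_PC <- data.frame(
  K     = c(0.5, 0.25, 0.125, 0.0625, 0.010),
  p11   = c(1 / 3, 0.12027511, 0.04448635, 0.01668134, 0.00129392),
  onset = c(2 / 3, 0.48110043, 0.35589077, 0.26690151, 0.12939244),
  nodis = c(1 / 3, 0.17296652, 0.09201560, 0.04887323, 0.00879402),
  re    = c(1 / 3, 0.30813362, 0.26387513, 0.21802833, 0.12059841))

ORACLE_SIB <- data.frame(
  K     = c(0.5, 0.25, 0.125, 0.0625, 0.010),
  onset = c(17 / 24, 0.55305021, 0.45919538, 0.39907568, 0.31719622),
  nodis = c(7 / 24, 0.14898326, 0.07725780, 0.04006155, 0.00689701),
  re    = c(5 / 12, 0.40406695, 0.38193757, 0.35901417, 0.31029921))
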