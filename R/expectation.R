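#' Upper-quadrant probability of a standard bivariate normal
#'
#' Computes P(X > z, Y > z) where (X, Y) is standard bivariate normal with
#' correlation `rho` and z is the upper-K quantile (so each margin exceeds z
#' with probability K). This is the analytic counterpart of dichotomizing
#' both members of a pair at prevalence K: the probability that both are
#' affected. Evaluated by adaptive quadrature of the conditional tail,
#' integrating dnorm(x) * P(Y > z | X = x) over x in (z, Inf) to an absolute
#' tolerance below 1e-10; the boundary cases rho = 0 (K^2) and rho = 1 (K)
#' are returned in closed form.
#'
#' @param K marginal exceedance probability (prevalence), in (0, 1).
#' @param rho correlation, in \[0, 1\].
#' @return the quadrant probability P11, a single number in \[K^2, K\].
#' @examples
#' bvn_upper_quadrant(0.5, 0.5)  # 1/3 exactly (arcsine law at the median)
#' @export
bvn_upper_quadrant <- function(K, rho) {
  if (!is.numeric(K) || length(K) != 1 || is.na(K) || K <= 0 || K >= 1)
    stop("bvn_upper_quadrant: 'K' must lie strictly between 0 and 1",
         call. = FALSE)
  if (!is.numeric(rho) || length(rho) != 1 || is.na(rho) || rho < 0 || rho > 1)
    stop("bvn_upper_quadrant: 'rho' must lie in [0, 1]", call. = FALSE)
  if (rho == 0) return(K^2)
  if (rho == 1) return(K)
  z <- stats::qnorm(1 - K)
  f <- function(x) stats::dnorm(x) * stats::pnorm((rho * x - z) / sqrt(1 - rho^2))
  stats::integrate(f, lower = z, upper = Inf,
                   rel.tol = 1e-12, abs.tol = 1e-12,
                   subdivisions = 500L)$value
}

#' Probability that both members of a relative pair are affected
#'
#' The pair quadrant probability P11 under pure polygenic inheritance. For a
#' parent-child pair the liabilities are bivariate normal with correlation
#' 0.5. A sibling pair is a mixture over identity-by-descent sharing: with
#' probability 1/4 the siblings share both chromosomes (correlation 1), with
#' probability 1/2 one (correlation 0.5), and with probability 1/4 none
#' (correlation 0), giving
#' P11 = K/4 + bvn_upper_quadrant(K, 0.5)/2 + K^2/4.
#'
#' @param K prevalence in (0, 1).
#' @param relationship `"parent_child"` or `"sibling"`.
#' @return the quadrant probability P11.
#' @export
pair_quadrant <- function(K, relationship = c("parent_child", "sibling")) {
  relationship <- match.arg(relationship)
  switch(relationship,
         parent_child = bvn_upper_quadrant(K, 0.5),
         sibling = 0.25 * K + 0.5 * bvn_upper_quadrant(K, 0.5) + 0.25 * K^2)
}

#' Conditional incidences given a relative's affection status
#'
#' The prevalence of the trait among probands whose relative is affected
#' ("onset" group) and among probands whose relative is unaffected
#' ("no-disease" group): onset = P11 / K and no-disease = (K - P11) / (1 - K).
#' In analytic mode P11 comes from [pair_quadrant()]; in simulation mode it
#' is the empirical quadrant frequency of a dichotomized simulated cohort.
#'
#' @param K prevalence in (0, 1).
#' @param relationship `"parent_child"` or `"sibling"`.
#' @param method `"analytic"` (default) or `"simulation"`.
#' @param config a [sim_config()], used when `method = "simulation"`.
#' @return named numeric vector `c(onset = ..., nodisease = ...)`.
#' @examples
#' conditional_incidences(0.01, "parent_child")
#' @export
conditional_incidences <- function(K,
                                   relationship = c("parent_child", "sibling"),
                                   method = c("analytic", "simulation"),
                                   config = sim_config()) {
  relationship <- match.arg(relationship)
  method <- match.arg(method)
  if (!is.numeric(K) || length(K) != 1 || is.na(K) || K <= 0 || K >= 1)
    stop("conditional_incidences: 'K' must lie strictly between 0 and 1",
         call. = FALSE)
  if (method == "analytic") {
    p11 <- pair_quadrant(K, relationship)
    return(c(onset = p11 / K, nodisease = (K - p11) / (1 - K)))
  }
  bts <- dichotomize(simulate_family(config, relationship), K)
  incidences_from_sample(bts)
}

# empirical conditional incidences of a dichotomized cohort
incidences_from_sample <- function(bts) {
  rel <- bts$relative_status
  pro <- bts$proband_status
  if (sum(rel) == 0 || sum(rel) == length(rel))
    stop("conditional incidences undefined: a relative status group is empty",
         call. = FALSE)
  c(onset = mean(pro[rel == 1L]), nodisease = mean(pro[rel == 0L]))
}

#' Expected correlation Re of a dichotomized relative pair
#'
#' The phi coefficient (Pearson correlation of the two 0/1 status
#' indicators, identical to the Spearman coefficient on binary data) expected
#' under pure polygenic inheritance at prevalence K. Analytically
#' Re = (P11 - K^2) / (K * (1 - K)); in simulation mode it is the phi
#' correlation of a dichotomized simulated cohort.
#'
#' @inheritParams conditional_incidences
#' @return the expected correlation Re.
#' @examples
#' expected_phi(0.5, "parent_child")  # 1/3
#' expected_phi(0.5, "sibling")       # 5/12
#' @export
expected_phi <- function(K, relationship = c("parent_child", "sibling"),
                         method = c("analytic", "simulation"),
                         config = sim_config()) {
  relationship <- match.arg(relationship)
  method <- match.arg(method)
  if (!is.numeric(K) || length(K) != 1 || is.na(K) || K <= 0 || K >= 1)
    stop("expected_phi: 'K' must lie strictly between 0 and 1", call. = FALSE)
  if (method == "analytic") {
    p11 <- pair_quadrant(K, relationship)
    return((p11 - K^2) / (K * (1 - K)))
  }
  bts <- dichotomize(simulate_family(config, relationship), K)
  stats::cor(bts$relative_status, bts$proband_status)
}

#' Published expected-correlation lookup table
#'
#' The frozen reference table of simulated conditional incidences and
#' expected correlations at the five canonical prevalences (0.5, 0.25,
#' 0.125, 0.0625, 0.010), as originally published for parent-child and
#' sibling pairs. These are single Monte-Carlo draws at n = 10,000, so
#' individual entries carry sampling noise of a few hundredths (the sibling
#' K = 0.125 row is visibly below its analytic expectation); the analytic
#' mode of [build_re_table()] gives the noise-free values.
#'
#' @param relationship `"parent_child"` or `"sibling"`.
#' @return data.frame with columns `incidence`, `relationship`, `group`
#'   (`"Onset"`/`"No-disease"`), `incidence_in_children`, `re`, `method`.
#' @export
re_table_published <- function(relationship = c("parent_child", "sibling")) {
  relationship <- match.arg(relationship)
  K <- c(0.5, 0.25, 0.125, 0.0625, 0.010)
  if (relationship == "parent_child") {
    onset <- c(0.673, 0.501, 0.363, 0.278, 0.170)
    nodis <- c(0.327, 0.166, 0.091, 0.048, 0.008)
    re    <- c(0.345, 0.335, 0.272, 0.230, 0.162)
  } else {
    onset <- c(0.707, 0.554, 0.298, 0.392, 0.340)
    nodis <- c(0.293, 0.149, 0.067, 0.041, 0.007)
    re    <- c(0.413, 0.405, 0.303, 0.351, 0.333)
  }
  data.frame(
    incidence = rep(K, each = 2),
    relationship = relationship,
    group = rep(c("Onset", "No-disease"), times = length(K)),
    incidence_in_children = as.vector(rbind(onset, nodis)),
    re = rep(re, each = 2),
    method = "paper_table",
    stringsAsFactors = FALSE)
}

# nearest tabulated prevalence row of the published table
published_row <- function(K, relationship) {
  tab <- re_table_published(relationship)
  ks <- unique(tab$incidence)
  k0 <- ks[which.min(abs(ks - K))]
  tab[tab$incidence == k0, ]
}

#' Build an expected-correlation (Re) table over a prevalence grid
#'
#' One pair of rows (onset / no-disease) per prevalence, holding the
#' conditional incidences in probands and the expected correlation Re.
#' `method = "analytic"` uses the bivariate-normal quadrant probability;
#' `"simulation"` dichotomizes one freshly simulated cohort per prevalence
#' (each prevalence and relationship gets its own seed stream derived from
#' `config$seed`); `"paper_table"` returns the published values.
#'
#' @param K_list numeric vector of prevalences in (0, 1).
#' @param relationship `"parent_child"` or `"sibling"`.
#' @param method `"analytic"`, `"simulation"` or `"paper_table"`.
#' @param config a [sim_config()] for simulation mode.
#' @return data.frame with columns `incidence`, `relationship`, `group`,
#'   `incidence_in_children`, `re`, `method`, `n`, `seed`.
#' @examples
#' build_re_table(c(0.5, 0.25), "parent_child")
#' @export
build_re_table <- function(K_list = c(0.5, 0.25, 0.125, 0.0625, 0.010),
                           relationship = c("parent_child", "sibling"),
                           method = c("analytic", "simulation", "paper_table"),
                           config = sim_config()) {
  relationship <- match.arg(relationship)
  method <- match.arg(method)
  if (length(K_list) == 0)
    stop("build_re_table: 'K_list' must contain at least one prevalence",
         call. = FALSE)
  if (method == "paper_table") {
    tab <- do.call(rbind, lapply(K_list, published_row,
                                 relationship = relationship))
    tab$n <- NA_integer_
    tab$seed <- NA_integer_
    rownames(tab) <- NULL
    return(tab)
  }
  rows <- lapply(seq_along(K_list), function(i) {
    K <- K_list[i]
    if (method == "analytic") {
      ci <- conditional_incidences(K, relationship, "analytic")
      re <- expected_phi(K, relationship, "analytic")
      n <- NA_integer_; seed <- NA_integer_
    } else {
      seed <- derive_seed(config$seed, relationship, i)
      cfg <- config
      cfg$seed <- seed
      bts <- dichotomize(simulate_family(cfg, relationship), K)
      ci <- incidences_from_sample(bts)
      re <- stats::cor(bts$relative_status, bts$proband_status)
      n <- config$n_families
      if (is.null(seed)) seed <- NA_integer_
    }
    data.frame(
      incidence = K, relationship = relationship,
      group = c("Onset", "No-disease"),
      incidence_in_children = as.numeric(ci),
      re = re, method = method, n = n, seed = seed,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# deterministic per-cohort seed: distinct stream per relationship and row,
# kept inside the 32-bit integer range
derive_seed <- function(seed, relationship, i) {
  if (is.null(seed)) return(NULL)
  off <- if (relationship == "sibling") 500000L else 0L
  as.integer((seed + off + 1009L * i) %% .Machine$integer.max)
}
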