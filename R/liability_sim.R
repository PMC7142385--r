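#' Simulation settings for a polygenic liability cohort
#'
#' Bundles the parameters of one simulated cohort of families. Each parent
#' carries two chromosome-level effect scores drawn independently from
#' Normal(`effect_mean`, `effect_sd`^2); an individual's genetic liability is
#' the sum of the two scores they carry. With `heritability < 1` an
#' independent environmental deviate is added to every individual so that the
#' genetic share of observed-liability variance equals `heritability`; the
#' pure-genetic model is the `heritability = 1` special case.
#'
#' @param n_families number of independent families (>= 2).
#' @param effect_mean mean of each chromosome effect score.
#' @param effect_sd standard deviation of each chromosome effect score (> 0).
#' @param heritability fraction of observed-liability variance that is
#'   genetic, in (0, 1].
#' @param seed optional integer seed; when supplied, every simulation started
#'   from this config is reproducible bit-for-bit.
#' @return an object of class `"sim_config"`.
#' @examples
#' cfg <- sim_config(n_families = 1000, seed = 1)
#' @export
sim_config <- function(n_families = 10000, effect_mean = 100, effect_sd = 30,
                       heritability = 1, seed = NULL) {
  if (!is.numeric(n_families) || length(n_families) != 1 ||
      is.na(n_families) || n_families < 2 || n_families != round(n_families))
    stop("sim_config: 'n_families' must be a single integer >= 2", call. = FALSE)
  if (!is.numeric(effect_mean) || length(effect_mean) != 1 || is.na(effect_mean))
    stop("sim_config: 'effect_mean' must be a single real number", call. = FALSE)
  if (!is.numeric(effect_sd) || length(effect_sd) != 1 ||
      is.na(effect_sd) || effect_sd <= 0)
    stop("sim_config: 'effect_sd' must be a single positive number", call. = FALSE)
  if (!is.numeric(heritability) || length(heritability) != 1 ||
      is.na(heritability) || heritability <= 0 || heritability > 1)
    stop("sim_config: 'heritability' must lie in (0, 1]", call. = FALSE)
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1 || is.na(seed) ||
        seed != round(seed))
      stop("sim_config: 'seed' must be a single integer or NULL", call. = FALSE)
    seed <- as.integer(seed)
  }
  structure(
    list(n_families = as.integer(n_families), effect_mean = effect_mean,
         effect_sd = effect_sd, heritability = heritability, seed = seed),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Polygenic liability simulation settings\n")
  cat(sprintf("  families:     %d\n", x$n_families))
  cat(sprintf("  effect score: Normal(%g, %g^2) per chromosome\n",
              x$effect_mean, x$effect_sd))
  cat(sprintf("  heritability: %g\n", x$heritability))
  cat(sprintf("  seed:         %s\n",
              if (is.null(x$seed)) "none (session RNG)" else x$seed))
  invisible(x)
}

#' Draw the four chromosome effect arrays of a cohort
#'
#' Generates the paternal chromosome effects A, B and the maternal effects
#' C, D: four mutually independent Normal(`effect_mean`, `effect_sd`^2)
#' arrays, one entry per family. The father's genetic liability is A + B and
#' the mother's is C + D.
#'
#' @param config a [sim_config()] object. If it carries a seed, the RNG is
#'   seeded before drawing.
#' @return an object of class `"gamete_effects"`: a list with numeric vectors
#'   `A`, `B`, `C`, `D` of length `n_families`.
#' @examples
#' g <- generate_gametes(sim_config(n_families = 100, seed = 1))
#' @export
generate_gametes <- function(config) {
  if (!inherits(config, "sim_config"))
    config <- do.call(sim_config, as.list(config))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_families
  g <- lapply(1:4, function(i) stats::rnorm(n, config$effect_mean, config$effect_sd))
  names(g) <- c("A", "B", "C", "D")
  structure(g, class = "gamete_effects", config = config)
}

check_gametes <- function(g) {
  if (!is.list(g) || !all(c("A", "B", "C", "D") %in% names(g)))
    stop("gamete effects must contain arrays A, B, C and D", call. = FALSE)
  len <- lengths(g[c("A", "B", "C", "D")])
  if (length(unique(len)) != 1L)
    stop("gamete effect arrays A, B, C, D must have identical length", call. = FALSE)
  invisible(len[[1L]])
}

#' Transmit one gamete from each parent to a child
#'
#' For each family the child inherits exactly one of the father's two
#' chromosome effects (A or B) and one of the mother's (C or D), each chosen
#' uniformly at random, so the child's genetic liability is one of
#' A + C, A + D, B + C, B + D with probability 1/4 each. This random
#' one-of-four selection is what makes the parent-child liability
#' correlation 0.5, the Mendelian expectation.
#'
#' @param g a `"gamete_effects"` object (or compatible list).
#' @return numeric vector of child liabilities, with attribute
#'   `"combination"` (integer 1-4 coding A+C, A+D, B+C, B+D).
#' @export
transmit_child <- function(g) {
  n <- check_gametes(g)
  pat <- stats::runif(n) < 0.5   # TRUE -> A, FALSE -> B
  mat <- stats::runif(n) < 0.5   # TRUE -> C, FALSE -> D
  child <- ifelse(pat, g$A, g$B) + ifelse(mat, g$C, g$D)
  combo <- 1L + (!pat) * 2L + (!mat) * 1L  # 1 AC, 2 AD, 3 BC, 4 BD
  attr(child, "combination") <- as.integer(combo)
  child
}

#' Draw a second sibling for a cohort whose first sibling is A + B
#'
#' Sibling 1 carries chromosomes A and B. Sibling 2 independently inherits
#' one paternal and one maternal chromosome, giving liability A + B, A + C,
#' B + D or C + D with probability 1/4 each; the two siblings then share 2,
#' 1, 1 or 0 chromosomes (liability correlation 1, 0.5, 0.5, 0), so the
#' marginal sibling correlation is again 0.5.
#'
#' @param g a `"gamete_effects"` object.
#' @return numeric vector of sibling-2 liabilities with attribute
#'   `"combination"` (1 = A+B, 2 = A+C, 3 = B+D, 4 = C+D) and attribute
#'   `"shared"` (chromosomes shared with sibling 1: 2, 1, 1, 0).
#' @export
transmit_sibling <- function(g) {
  n <- check_gametes(g)
  combo <- sample.int(4L, n, replace = TRUE)
  sib <- numeric(n)
  sib[combo == 1L] <- g$A[combo == 1L] + g$B[combo == 1L]
  sib[combo == 2L] <- g$A[combo == 2L] + g$C[combo == 2L]
  sib[combo == 3L] <- g$B[combo == 3L] + g$D[combo == 3L]
  sib[combo == 4L] <- g$C[combo == 4L] + g$D[combo == 4L]
  attr(sib, "combination") <- combo
  attr(sib, "shared") <- c(2L, 1L, 1L, 0L)[combo]
  sib
}

#' Simulate paired liabilities for a cohort of relative-proband pairs
#'
#' Draws a fresh cohort of chromosome effects and composes a pair per family:
#' for `"parent_child"` the relative is the father (A + B) and the proband is
#' the transmitted child; for `"sibling"` the relative is sibling 1 (A + B)
#' and the proband is sibling 2. With `heritability` h^2 < 1, independent
#' Normal(0, sigma_e^2) environmental noise with
#' sigma_e^2 = 2 * effect_sd^2 * (1 - h^2) / h^2 is added to every
#' individual, which attenuates the pair correlation from 0.5 to 0.5 * h^2.
#'
#' @param config a [sim_config()] object.
#' @param relationship `"parent_child"` or `"sibling"`.
#' @return an object of class `"family_sample"`: list with `relationship`,
#'   numeric vectors `relative` and `proband`, `mother` (parent-child only),
#'   `combination`, and the `config` used.
#' @examples
#' fs <- simulate_family(sim_config(n_families = 2000, seed = 7), "parent_child")
#' cor(fs$relative, fs$proband)
#' @export
simulate_family <- function(config, relationship = c("parent_child", "sibling")) {
  relationship <- match.arg(relationship)
  if (!inherits(config, "sim_config"))
    config <- do.call(sim_config, as.list(config))
  if (!is.null(config$seed)) set.seed(config$seed)
  g <- generate_gametes_raw(config)
  proband <- switch(relationship,
                    parent_child = transmit_child(g),
                    sibling = transmit_sibling(g))
  combination <- attr(proband, "combination")
  proband <- as.numeric(proband)
  relative <- g$A + g$B
  mother <- if (relationship == "parent_child") g$C + g$D else NULL
  h2 <- config$heritability
  if (h2 < 1) {
    sde <- sqrt(2 * config$effect_sd^2 * (1 - h2) / h2)
    n <- config$n_families
    relative <- relative + stats::rnorm(n, 0, sde)
    proband <- proband + stats::rnorm(n, 0, sde)
    if (!is.null(mother)) mother <- mother + stats::rnorm(n, 0, sde)
  }
  structure(
    list(relationship = relationship,
         relative = relative,
         proband = proband,
         mother = mother,
         combination = combination,
         config = config),
    class = "family_sample")
}

# internal: gamete draw without re-seeding (simulate_family controls the seed)
generate_gametes_raw <- function(config) {
  n <- config$n_families
  g <- lapply(1:4, function(i) stats::rnorm(n, config$effect_mean, config$effect_sd))
  names(g) <- c("A", "B", "C", "D")
  structure(g, class = "gamete_effects", config = config)
}

#' @export
print.family_sample <- function(x, ...) {
  cat(sprintf("Simulated %s cohort: %d pairs\n",
              sub("_", "-", x$relationship), length(x$relative)))
  cat(sprintf("  relative-proband correlation: %.3f\n",
              stats::cor(x$relative, x$proband)))
  cat(sprintf("  heritability: %g, seed: %s\n", x$config$heritability,
              if (is.null(x$config$seed)) "none" else x$config$seed))
  invisible(x)
}

#' Dichotomize liabilities at a prevalence threshold
#'
#' Rank-based thresholding: exactly `round(n * K)` individuals -- those with
#' the highest liabilities -- are marked affected (1), everyone else
#' unaffected (0). Ties are broken by original index (lower index wins), so
#' the observed incidence is exact and the operation is deterministic and
#' invariant to any strictly increasing transform of the liabilities.
#'
#' @param liabilities non-empty numeric vector.
#' @param K prevalence ("nature incidence") in (0, 1).
#' @return integer vector of 0/1 of the same length.
#' @examples
#' threshold_binary(c(10, 50, 30, 20), K = 0.5)
#' @export
threshold_binary <- function(liabilities, K) {
  if (length(liabilities) == 0)
    stop("threshold_binary: 'liabilities' must be non-empty", call. = FALSE)
  if (!is.numeric(K) || length(K) != 1 || is.na(K) || K <= 0 || K >= 1)
    stop("threshold_binary: 'K' must lie strictly between 0 and 1", call. = FALSE)
  if (anyNA(liabilities))
    stop("threshold_binary: 'liabilities' contains missing values", call. = FALSE)
  n <- length(liabilities)
  m <- round(n * K)
  status <- integer(n)
  if (m > 0) {
    ord <- order(-liabilities, seq_len(n))
    status[ord[seq_len(m)]] <- 1L
  }
  status
}

#' Dichotomize both members of a simulated cohort
#'
#' Applies [threshold_binary()] at the same prevalence `K` to the relative
#' and the proband liability arrays, mirroring how a threshold trait is
#' scored in both members of each pair.
#'
#' @param fs a `"family_sample"`.
#' @param K prevalence in (0, 1).
#' @return an object of class `"binary_trait_sample"`: list with integer
#'   vectors `relative_status`, `proband_status`, the `incidence` K and the
#'   `relationship`.
#' @export
dichotomize <- function(fs, K) {
  if (!inherits(fs, "family_sample"))
    stop("dichotomize: 'fs' must be a family_sample", call. = FALSE)
  structure(
    list(relative_status = threshold_binary(fs$relative, K),
         proband_status = threshold_binary(fs$proband, K),
         incidence = K,
         relationship = fs$relationship),
    class = "binary_trait_sample")
}

#' @export
print.binary_trait_sample <- function(x, ...) {
  cat(sprintf("Dichotomized %s cohort at incidence K = %g (%d pairs)\n",
              sub("_", "-", x$relationship), x$incidence,
              length(x$relative_status)))
  print(table(relative = x$relative_status, proband = x$proband_status))
  invisible(x)
}
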