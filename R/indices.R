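#' 2x2 contingency table of binary trait status in relative-proband pairs
#'
#' @param n11 pairs with relative affected and proband affected.
#' @param n10 relative affected, proband unaffected.
#' @param n01 relative unaffected, proband affected.
#' @param n00 both unaffected.
#' @return an object of class `"contingency_2x2"`.
#' @examples
#' contingency_2x2(13, 7, 28, 73)
#' @export
contingency_2x2 <- function(n11, n10, n01, n00) {
  counts <- c(n11 = n11, n10 = n10, n01 = n01, n00 = n00)
  if (!is.numeric(counts) || length(counts) != 4 || anyNA(counts) ||
      any(counts < 0) || any(counts != round(counts)))
    stop("contingency_2x2: counts must be four non-negative integers",
         call. = FALSE)
  if (sum(counts) == 0)
    stop("contingency_2x2: total count must be positive", call. = FALSE)
  structure(as.list(as.integer(counts)), names = names(counts),
            class = "contingency_2x2")
}

#' Build a 2x2 table from paired 0/1 status vectors
#'
#' @param relative,proband equal-length vectors with values in \{0, 1\}.
#' @return a [contingency_2x2()] object.
#' @export
as_contingency_2x2 <- function(relative, proband) {
  if (length(relative) != length(proband))
    stop("as_contingency_2x2: status vectors differ in length", call. = FALSE)
  if (!all(relative %in% c(0, 1)) || !all(proband %in% c(0, 1)))
    stop("as_contingency_2x2: status values must be 0 or 1", call. = FALSE)
  contingency_2x2(sum(relative == 1 & proband == 1),
                  sum(relative == 1 & proband == 0),
                  sum(relative == 0 & proband == 1),
                  sum(relative == 0 & proband == 0))
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  m <- matrix(c(x$n11, x$n10, x$n01, x$n00), 2, 2, byrow = TRUE,
              dimnames = list(relative = c("affected", "unaffected"),
                              proband = c("affected", "unaffected")))
  cat("Relative-proband 2x2 contingency table (n =", sum(unlist(x[1:4])), ")\n")
  print(m)
  invisible(x)
}

#' Pearson product-moment correlation of paired trait values
#'
#' Validating wrapper around [stats::cor()] for relative-proband pairs:
#' requires at least 3 pairs, equal lengths, no missing values and
#' non-constant arrays (the correlation of a constant array is undefined).
#'
#' @param x,y numeric vectors of equal length.
#' @return the correlation, in \[-1, 1\].
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y))
    stop("pearson_correlation: arrays differ in length", call. = FALSE)
  if (length(x) < 3)
    stop("pearson_correlation: need at least 3 pairs", call. = FALSE)
  if (anyNA(x) || anyNA(y))
    stop("pearson_correlation: missing values are not allowed", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("pearson_correlation: correlation undefined for a constant array",
         call. = FALSE)
  stats::cor(x, y)
}

#' Phi coefficient of a 2x2 contingency table
#'
#' phi = (n11 n00 - n10 n01) / sqrt((n11+n10)(n01+n00)(n11+n01)(n10+n00)),
#' which equals the Pearson (and Spearman) correlation of the two expanded
#' 0/1 indicator arrays.
#'
#' @param t a [contingency_2x2()] object.
#' @return the phi correlation, in \[-1, 1\].
#' @examples
#' phi_correlation(contingency_2x2(13, 7, 28, 73))  # 0.293
#' @export
phi_correlation <- function(t) {
  if (!inherits(t, "contingency_2x2"))
    stop("phi_correlation: 't' must be a contingency_2x2", call. = FALSE)
  margins <- c(t$n11 + t$n10, t$n01 + t$n00, t$n11 + t$n01, t$n10 + t$n00)
  if (any(margins == 0))
    stop("phi_correlation: correlation undefined, a table margin is zero",
         call. = FALSE)
  (t$n11 * t$n00 - t$n10 * t$n01) / sqrt(prod(margins))
}

new_heredity_index <- function(index_kind, ro, re_used, re_source,
                               relationship = NA_character_,
                               incidence = NA_real_, n = NA_integer_,
                               counts = NULL) {
  out <- structure(
    list(index_kind = index_kind, ro = ro, re_used = re_used,
         re_source = re_source, relationship = relationship,
         incidence = incidence, value = ro / re_used, n = n,
         counts = counts),
    class = "heredity_index")
  if (!is.na(ro) && ro < 0)
    warning("observed correlation is negative; the polygenic model presumes ",
            "positive familial resemblance", call. = FALSE)
  out
}

#' Heredity index for continuous data (HIC)
#'
#' HIC = Ro / 0.5: the observed relative-proband correlation of a continuous
#' trait divided by the pure-polygenic (Mendelian) expectation of 0.5. A HIC
#' below 1 indicates a lesser role of inheritance (stronger non-genetic
#' influence); above 1, that a few strong genes dominate rather than many
#' small ones.
#'
#' @param ro observed correlation, in \[-1, 1\].
#' @param n optional number of pairs behind `ro`.
#' @return an object of class `"heredity_index"`.
#' @examples
#' compute_hic(0.549)  # HIC = 1.10
#' @export
compute_hic <- function(ro, n = NA_integer_) {
  if (!is.numeric(ro) || length(ro) != 1 || is.na(ro) || abs(ro) > 1)
    stop("compute_hic: 'ro' must be a correlation in [-1, 1]", call. = FALSE)
  new_heredity_index("HIC", ro, re_used = 0.5, re_source = "mendelian",
                     n = n)
}

#' Heredity index for binary data (HIB)
#'
#' HIB = Ro / Re: the observed phi correlation of a dichotomous trait
#' divided by the expected correlation at the trait's prevalence K under
#' pure polygenic inheritance. Re can be computed analytically at the exact
#' K (default), estimated by simulation, or looked up in the published
#' reference table (nearest tabulated prevalence).
#'
#' @param ro observed phi correlation, in \[-1, 1\].
#' @param K trait prevalence in (0, 1).
#' @param relationship `"parent_child"` or `"sibling"`.
#' @param re_source `"analytic"`, `"simulation"` or `"paper_table"`.
#' @param config a [sim_config()] for `re_source = "simulation"`.
#' @param n optional number of pairs behind `ro`.
#' @return an object of class `"heredity_index"` recording the Re used and
#'   its provenance.
#' @examples
#' compute_hib(0.293, K = 0.15, re_source = "paper_table")
#' @export
compute_hib <- function(ro, K, relationship = c("parent_child", "sibling"),
                        re_source = c("analytic", "simulation", "paper_table"),
                        config = sim_config(), n = NA_integer_) {
  relationship <- match.arg(relationship)
  re_source <- match.arg(re_source)
  if (!is.numeric(ro) || length(ro) != 1 || is.na(ro) || abs(ro) > 1)
    stop("compute_hib: 'ro' must be a correlation in [-1, 1]", call. = FALSE)
  if (!is.numeric(K) || length(K) != 1 || is.na(K) || K <= 0 || K >= 1)
    stop("compute_hib: 'K' must lie strictly between 0 and 1", call. = FALSE)
  re <- switch(re_source,
               analytic = expected_phi(K, relationship, "analytic"),
               simulation = expected_phi(K, relationship, "simulation", config),
               paper_table = published_row(K, relationship)$re[1])
  if (!is.finite(re) || re <= 0)
    stop("compute_hib: expected correlation Re is unavailable or not positive",
         call. = FALSE)
  new_heredity_index("HIB", ro, re_used = re, re_source = re_source,
                     relationship = relationship, incidence = K, n = n)
}

#' Estimate a heredity index from relative-proband pair data
#'
#' The package's central estimator. For a continuous trait it computes the
#' Pearson correlation Ro of the pairs and returns HIC = Ro / 0.5; for a
#' binary trait it computes the phi correlation Ro of the 2x2 status table
#' and returns HIB = Ro / Re with Re taken at the trait's prevalence `K`.
#'
#' `data` may be a two-column data.frame (or a list/`family_sample` with
#' elements `relative` and `proband`), a pair of vectors via `proband`, or,
#' for binary mode, a [contingency_2x2()] table.
#'
#' @param data pair data as described above.
#' @param proband optional second vector when `data` is the relative vector.
#' @param mode `"continuous"` or `"binary"`; inferred when `data` is a
#'   contingency table.
#' @param K prevalence for binary mode. Defaults to the affected fraction of
#'   the relative margin when omitted.
#' @param relationship `"parent_child"` or `"sibling"`.
#' @param re_source source of the expected correlation for HIB.
#' @param config a [sim_config()] for `re_source = "simulation"`.
#' @return an object of class `"heredity_index"` with `print`, `summary`
#'   and `coef` methods.
#' @examples
#' heredity_index(fixture_hammer(), K = 0.15, re_source = "paper_table")
#' @export
heredity_index <- function(data, proband = NULL,
                           mode = c("continuous", "binary"),
                           K = NULL,
                           relationship = c("parent_child", "sibling"),
                           re_source = c("analytic", "simulation", "paper_table"),
                           config = sim_config()) {
  relationship <- match.arg(relationship)
  re_source <- match.arg(re_source)

  if (inherits(data, "contingency_2x2")) {
    tab <- data
    mode <- "binary"
  } else {
    mode <- match.arg(mode)
    if (!is.null(proband)) {
      rel <- data
    } else if (is.data.frame(data)) {
      cols <- intersect(c("relative_value", "relative"), names(data))
      colp <- intersect(c("proband_value", "proband"), names(data))
      if (length(cols) == 0 || length(colp) == 0)
        stop("heredity_index: data.frame needs relative/proband columns",
             call. = FALSE)
      rel <- data[[cols[1]]]
      proband <- data[[colp[1]]]
    } else if (is.list(data) && all(c("relative", "proband") %in% names(data))) {
      rel <- data$relative
      proband <- data$proband
    } else {
      stop("heredity_index: unrecognized pair data", call. = FALSE)
    }
    if (mode == "binary") tab <- as_contingency_2x2(rel, proband)
  }

  if (mode == "continuous") {
    ro <- pearson_correlation(rel, proband)
    return(compute_hic(ro, n = length(rel)))
  }
  n <- with(tab, n11 + n10 + n01 + n00)
  if (is.null(K)) K <- (tab$n11 + tab$n10) / n
  ro <- phi_correlation(tab)
  out <- compute_hib(ro, K, relationship, re_source, config, n = n)
  out$counts <- tab
  out
}

#' @export
print.heredity_index <- function(x, digits = 2, ...) {
  cat(sprintf("%s = %.*f  (Ro = %.3f / Re = %.3f)\n", x$index_kind, digits,
              x$value, x$ro, x$re_used))
  invisible(x)
}

#' @export
coef.heredity_index <- function(object, ...) {
  c(value = object$value, ro = object$ro, re = object$re_used)
}

#' @export
summary.heredity_index <- function(object, ...) {
  structure(object, class = c("summary.heredity_index", "heredity_index"))
}

#' @export
print.summary.heredity_index <- function(x, ...) {
  kind <- if (x$index_kind == "HIC") "continuous trait" else "binary trait"
  cat(sprintf("Heredity index for a %s\n", kind))
  cat(sprintf("  observed correlation Ro: %.4f%s\n", x$ro,
              if (is.na(x$n)) "" else sprintf("  (n = %d pairs)", x$n)))
  if (x$index_kind == "HIB") {
    cat(sprintf("  expected correlation Re: %.4f  [%s, K = %g, %s]\n",
                x$re_used, x$re_source, x$incidence,
                sub("_", "-", x$relationship)))
  } else {
    cat("  expected correlation Re: 0.5  [Mendelian parent-offspring]\n")
  }
  cat(sprintf("  %s = Ro/Re = %.4f  (reported %.2f)\n",
              x$index_kind, x$value, round(x$value, 2)))
  interp <- if (round(x$value, 2) < 1)
    "index < 1: non-genetic factors contribute to trait variation"
  else if (round(x$value, 2) > 1)
    "index > 1: consistent with a few strong genes dominating"
  else "index = 1: consistent with pure additive polygenic inheritance"
  cat(" ", interp, "\n")
  invisible(x)
}
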