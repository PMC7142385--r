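#' Recurrence risk given one first-degree relative's status
#'
#' The probability that a proband is affected, given the population
#' prevalence K and whether one first-degree relative (a parent or a
#' sibling) is affected, under pure polygenic inheritance. With an affected
#' relative the risk is the onset-group conditional incidence P11 / K; with
#' an unaffected relative it is (K - P11) / (1 - K). The `"paper_table"`
#' method reads the published lookup table at the nearest tabulated
#' prevalence instead of computing P11, reproducing the printed lookup
#' workflow; `"simulation"` estimates the incidence from a simulated cohort.
#'
#' @param K population prevalence, in (0, 1).
#' @param relationship `"parent_child"` or `"sibling"`.
#' @param relative_affected logical: is the relative affected?
#' @param method `"analytic"` (default), `"simulation"` or `"paper_table"`.
#' @param config a [sim_config()] for simulation mode.
#' @return an object of class `"risk_estimate"`: list with `incidence`,
#'   `relationship`, `relative_affected`, `risk` and `method`.
#' @examples
#' recurrence_risk(0.01, "parent_child", relative_affected = TRUE)
#' @export
recurrence_risk <- function(K, relationship = c("parent_child", "sibling"),
                            relative_affected = TRUE,
                            method = c("analytic", "simulation", "paper_table"),
                            config = sim_config()) {
  relationship <- match.arg(relationship)
  method <- match.arg(method)
  if (!is.logical(relative_affected) || length(relative_affected) != 1 ||
      is.na(relative_affected))
    stop("recurrence_risk: 'relative_affected' must be TRUE or FALSE",
         call. = FALSE)
  if (method == "paper_table") {
    row <- published_row(K, relationship)
    risk <- row$incidence_in_children[
      match(if (relative_affected) "Onset" else "No-disease", row$group)]
  } else {
    ci <- conditional_incidences(K, relationship, method, config)
    risk <- unname(ci[if (relative_affected) "onset" else "nodisease"])
  }
  structure(
    list(incidence = K, relationship = relationship,
         relative_affected = relative_affected, risk = risk, method = method),
    class = "risk_estimate")
}

#' @export
print.risk_estimate <- function(x, ...) {
  rel <- if (x$relationship == "parent_child") "parent" else "sibling"
  cat(sprintf(
    "Recurrence risk (%s method): %.1f%%\n  prevalence %.3g%%, %s %s\n",
    x$method, 100 * x$risk, 100 * x$incidence,
    if (x$relative_affected) "affected" else "unaffected", rel))
  invisible(x)
}

#' Recurrence-risk table over a grid of prevalences
#'
#' Cartesian grid of [recurrence_risk()] estimates: every prevalence in
#' `K_list` crossed with every relationship and both relative statuses.
#'
#' @param K_list numeric vector of prevalences in (0, 1).
#' @param relationships character vector from
#'   `c("parent_child", "sibling")`.
#' @inheritParams recurrence_risk
#' @return data.frame with columns `incidence`, `relationship`,
#'   `relative_affected`, `risk`, `method`.
#' @examples
#' risk_table(c(0.01, 0.05))
#' @export
risk_table <- function(K_list = c(0.5, 0.25, 0.125, 0.0625, 0.010),
                       relationships = c("parent_child", "sibling"),
                       method = c("analytic", "simulation", "paper_table"),
                       config = sim_config()) {
  method <- match.arg(method)
  if (length(K_list) == 0)
    stop("risk_table: 'K_list' must contain at least one prevalence",
         call. = FALSE)
  relationships <- match.arg(relationships, several.ok = TRUE)
  grid <- expand.grid(relative_affected = c(TRUE, FALSE),
                      relationship = relationships, incidence = K_list,
                      stringsAsFactors = FALSE)
  est <- Map(function(K, rel, aff) {
    recurrence_risk(K, rel, aff, method, config)$risk
  }, grid$incidence, grid$relationship, grid$relative_affected)
  data.frame(incidence = grid$incidence, relationship = grid$relationship,
             relative_affected = grid$relative_affected,
             risk = unlist(est), method = method,
             stringsAsFactors = FALSE)
}
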