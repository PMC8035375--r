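#' Rule defining management-incompatible forest
#'
#' Forest is "management incompatible" when conventional even-aged forestry
#' cannot reproduce it: stands at or above the final-felling (rotation) age,
#' and optionally also younger forest maintained by gap or cohort dynamics,
#' whose multi-cohort structure clear-cutting does not emulate.
#'
#' @param age_threshold Final-felling age in years (default 110); the test
#'   is inclusive (`age >= threshold`).
#' @param include_gap_cohort_younger If `TRUE`, gap- and cohort-dynamics
#'   area below the threshold also counts as incompatible.
#' @param reserve_fraction Fraction of incompatible area taken as the
#'   reserve need (default 0.20).
#' @return An object of class `compatibility_rule`.
#' @export
compatibility_rule <- function(age_threshold = 110,
                               include_gap_cohort_younger = FALSE,
                               reserve_fraction = 0.20) {
  if (age_threshold <= 0) stop("'age_threshold' must be positive")
  if (reserve_fraction <= 0 || reserve_fraction > 1) {
    stop("'reserve_fraction' must lie in (0, 1]")
  }
  structure(list(age_threshold = age_threshold,
                 include_gap_cohort_younger = isTRUE(include_gap_cohort_younger),
                 reserve_fraction = reserve_fraction),
            class = "compatibility_rule")
}

#' @export
print.compatibility_rule <- function(x, ...) {
  cat("Compatibility rule: incompatible = age >=", x$age_threshold, "years",
      if (x$include_gap_cohort_younger) "+ younger gap/cohort forest", "\n")
  cat("Reserve fraction:", x$reserve_fraction, "\n")
  invisible(x)
}

#' Management-incompatible area share of a reference matrix
#'
#' The share of landscape area at or above the rule's age threshold
#' (re-binning the matrix at the threshold with the uniform-within-class
#' rule if needed), plus, when the rule includes them, the gap- and
#' cohort-dynamics shares below the threshold. A threshold of 0 classifies
#' everything as incompatible; a threshold inside the unbounded old class is
#' an error because the class carries no internal age information.
#'
#' @param matrix A [reference_matrix()].
#' @param rule A [compatibility_rule()].
#' @return A single fraction.
#' @examples
#' incompatible_share(build_revised_matrix(), compatibility_rule())
#' @export
incompatible_share <- function(matrix, rule = compatibility_rule()) {
  stopifnot(is_reference_matrix(matrix), inherits(rule, "compatibility_rule"))
  thr <- rule$age_threshold
  b <- matrix$scheme$boundaries
  if (thr <= 0) return(1)
  if (!any(abs(b - thr) < 1e-9)) {
    new_b <- sort(unique(c(b[b < thr], thr, b[b > thr])))
    matrix <- rebin_matrix(matrix, age_class_scheme(new_b))
    b <- matrix$scheme$boundaries
  }
  above <- b >= thr - 1e-9
  share <- sum(matrix$cells[above, , drop = FALSE])
  if (rule$include_gap_cohort_younger) {
    share <- share + sum(matrix$cells[!above, c("GD", "CD"), drop = FALSE])
  }
  share
}

#' Reserve need from an incompatible share
#'
#' @param share Management-incompatible area fraction in `[0, 1]`.
#' @param rule A [compatibility_rule()] supplying the reserve fraction.
#' @return `reserve_fraction * share`.
#' @export
reserve_need <- function(share, rule = compatibility_rule()) {
  stopifnot(inherits(rule, "compatibility_rule"))
  if (any(share < 0 | share > 1)) stop("'share' must lie in [0, 1]")
  rule$reserve_fraction * share
}

#' Full reserve-need estimate for a reference model
#'
#' Convenience wrapper computing [incompatible_share()] and [reserve_need()]
#' for one matrix and rule.
#'
#' @param matrix A [reference_matrix()].
#' @param rule A [compatibility_rule()].
#' @param model Optional name of the source model, for reporting.
#' @return An object of class `reserve_estimate` with fields
#'   `incompatible_share`, `reserve_need`, `rule`, `model`.
#' @examples
#' reserve_estimate(build_revised_matrix(),
#'                  compatibility_rule(include_gap_cohort_younger = TRUE))
#' @export
reserve_estimate <- function(matrix, rule = compatibility_rule(),
                             model = "revised reference model") {
  inc <- incompatible_share(matrix, rule)
  structure(list(incompatible_share = inc,
                 reserve_need = reserve_need(inc, rule),
                 rule = rule, model = model),
            class = "reserve_estimate")
}

#' @export
print.reserve_estimate <- function(x, ...) {
  cat("Reserve-need estimate (", x$model, ")\n", sep = "")
  cat(sprintf("  management-incompatible share: %.1f%% (%.0f%% rounded)\n",
              100 * x$incompatible_share, 100 * x$incompatible_share))
  cat(sprintf("  reserve need (%.0f%% of incompatible): %.1f%% (%.0f%% rounded)\n",
              100 * x$rule$reserve_fraction,
              100 * x$reserve_need, 100 * x$reserve_need))
  invisible(x)
}
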