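#' Forest dynamics types
#'
#' The three broad disturbance-dynamics types used throughout the package:
#' gap dynamics (`GD`, small-scale tree mortality), even-aged dynamics
#' (`ED`, stand-replacing disturbance followed by a single cohort), and
#' cohort dynamics (`CD`, partial low-severity disturbance creating multiple
#' tree cohorts).
#'
#' @format Character vector of length 3.
#' @export
DYNAMICS_TYPES <- c("GD", "ED", "CD")

#' Age class x dynamics type reference matrix
#'
#' An allocation of total landscape area across forest age classes (rows)
#' and disturbance dynamics types (columns `GD`, `ED`, `CD`). Cells are
#' non-negative and sum to 1; row sums are the age-class marginals and
#' column sums the dynamics-type marginals.
#'
#' @param cells Numeric matrix, one row per age class of `scheme`, columns
#'   `GD`, `ED`, `CD`.
#' @param scheme The [age_class_scheme()] labelling the rows.
#' @return An object of class `reference_matrix`.
#' @seealso [build_revised_matrix()] for the standard construction.
#' @export
reference_matrix <- function(cells, scheme) {
  stopifnot(is_scheme(scheme), is.matrix(cells))
  if (nrow(cells) != length(scheme)) stop("one row per age class required")
  if (ncol(cells) != 3L) stop("columns must be the three dynamics types")
  if (is.null(colnames(cells))) colnames(cells) <- DYNAMICS_TYPES
  if (!identical(colnames(cells), DYNAMICS_TYPES)) {
    cells <- cells[, DYNAMICS_TYPES, drop = FALSE]
  }
  rownames(cells) <- scheme$labels
  if (any(cells < -1e-12)) stop("all cells must be non-negative")
  if (abs(sum(cells) - 1) > 1e-9) stop("cells must sum to 1 (within 1e-9)")
  structure(list(cells = cells, scheme = scheme), class = "reference_matrix")
}

is_reference_matrix <- function(x) inherits(x, "reference_matrix")

#' Age-class marginals of a reference matrix
#' @param x A [reference_matrix()].
#' @return Named numeric vector of row sums (one per age class).
#' @export
age_marginals <- function(x) {
  stopifnot(is_reference_matrix(x))
  rowSums(x$cells)
}

#' Dynamics-type marginals of a reference matrix
#' @param x A [reference_matrix()].
#' @return Named numeric vector of column sums (`GD`, `ED`, `CD`).
#' @export
dynamics_marginals <- function(x) {
  stopifnot(is_reference_matrix(x))
  colSums(x$cells)
}

#' @export
print.reference_matrix <- function(x, digits = 1, ...) {
  cat("Reference matrix (% of landscape area)\n")
  m <- 100 * cbind(x$cells, total = rowSums(x$cells))
  m <- rbind(m, total = colSums(m))
  print(round(m, digits))
  invisible(x)
}

#' @export
summary.reference_matrix <- function(object, ...) {
  cat("Reference model of natural forest age structure\n")
  print(object)
  cat("\nAge-class marginals   :",
      paste(sprintf("%s %.1f%%", object$scheme$labels,
                    100 * age_marginals(object)), collapse = ", "), "\n")
  cat("Dynamics marginals    :",
      paste(sprintf("%s %.1f%%", DYNAMICS_TYPES,
                    100 * dynamics_marginals(object)), collapse = ", "), "\n")
  cat("Non-stand-replacing   :",
      sprintf("%.1f%%", 100 * sum(dynamics_marginals(object)[c("GD", "CD")])),
      "(gap + cohort dynamics)\n")
  invisible(object)
}

#' @export
as.data.frame.reference_matrix <- function(x, ...) {
  g <- expand.grid(age_class = x$scheme$labels, dynamics = DYNAMICS_TYPES,
                   stringsAsFactors = FALSE)
  g$share <- as.vector(x$cells)
  g
}

#' Build the revised 3x3 reference model
#'
#' Constructs the reference allocation of landscape area across three age
#' classes and the three dynamics types from top-down marginals. Gap and
#' cohort dynamics place a fixed fraction (default 2/3) of their area in the
#' old class; the remainder is split between young and mid-aged classes in
#' proportion to the class age midpoints, so that the share of
#' non-stand-replacing dynamics increases linearly with age (1:3 for the
#' default 75-year boundary). Even-aged dynamics fill each age class's
#' residual, which makes them decline with age.
#'
#' With all defaults this reproduces the canonical table: gap and cohort
#' columns 2.8 / 8.3 / 22.2% and even-aged 19.4 / 8.3 / 5.6% across
#' young / mid-aged / old.
#'
#' @param age_marginals Shares of young, mid-aged and old forest
#'   (default `c(0.25, 0.25, 0.50)`); must sum to 1.
#' @param dynamics_marginals Shares of `GD`, `ED`, `CD`
#'   (default equal thirds); must sum to 1.
#' @param old_fraction_of_nonstandreplacing Fraction of each of the GD and CD
#'   totals allocated to old forest (default 2/3).
#' @param scheme Three-bin [age_class_scheme()]; default boundaries 0/75/150.
#' @return A [reference_matrix()].
#' @examples
#' build_revised_matrix()
#' @export
build_revised_matrix <- function(age_marginals = c(0.25, 0.25, 0.50),
                                 dynamics_marginals = c(GD = 1/3, ED = 1/3, CD = 1/3),
                                 old_fraction_of_nonstandreplacing = 2/3,
                                 scheme = age_class_scheme(c(0, 75, 150))) {
  stopifnot(is_scheme(scheme))
  if (length(scheme) != 3L) stop("a three-class scheme (young/mid/old) is required")
  if (length(age_marginals) != 3L || abs(sum(age_marginals) - 1) > 1e-9) {
    stop("'age_marginals' must be three shares summing to 1")
  }
  if (length(dynamics_marginals) != 3L || abs(sum(dynamics_marginals) - 1) > 1e-9) {
    stop("'dynamics_marginals' must be three shares summing to 1")
  }
  f_old <- old_fraction_of_nonstandreplacing
  if (f_old < 0 || f_old > 1) stop("'old_fraction_of_nonstandreplacing' must be in [0, 1]")
  if (age_marginals[3] < max(age_marginals[1:2]) - 1e-12) {
    stop("the old-forest share must be at least each non-old share")
  }
  dm <- as.numeric(dynamics_marginals)
  names(dm) <- if (!is.null(names(dynamics_marginals)) &&
                   setequal(names(dynamics_marginals), DYNAMICS_TYPES)) {
    names(dynamics_marginals)
  } else DYNAMICS_TYPES
  dm <- dm[DYNAMICS_TYPES]

  # linear increase with age, operationalised as proportionality to the
  # midpoints of the two bounded classes (37.5 : 112.5 = 1 : 3 by default)
  b <- scheme$boundaries
  mid <- c((b[1] + b[2]) / 2, (b[2] + b[3]) / 2)
  w_young_mid <- mid / sum(mid)

  alloc_nsr <- function(total) {
    c(young = total * (1 - f_old) * w_young_mid[1],
      mid   = total * (1 - f_old) * w_young_mid[2],
      old   = total * f_old)
  }
  gd <- alloc_nsr(dm["GD"])
  cd <- alloc_nsr(dm["CD"])
  ed <- age_marginals - gd - cd
  if (any(ed < -1e-9)) {
    bad <- scheme$labels[which(ed < -1e-9)]
    stop("infeasible marginals: even-aged residual negative in age class(es) ",
         paste(bad, collapse = ", "))
  }
  ed <- pmax(ed, 0)
  cells <- cbind(GD = gd, ED = as.numeric(ed), CD = cd)
  reference_matrix(cells, scheme)
}

#' Re-bin a reference matrix onto a new age-class scheme
#'
#' Applies the uniform-within-class [rebin()] rule independently to each
#' dynamics column, conserving every column total.
#'
#' @param matrix A [reference_matrix()].
#' @param new_scheme Target [age_class_scheme()].
#' @return A [reference_matrix()] on `new_scheme`.
#' @examples
#' rebin_matrix(build_revised_matrix(), age_class_scheme(c(0, 110, 150)))
#' @export
rebin_matrix <- function(matrix, new_scheme) {
  stopifnot(is_reference_matrix(matrix), is_scheme(new_scheme))
  cols <- lapply(DYNAMICS_TYPES, function(d) {
    tot <- sum(matrix$cells[, d])
    if (tot == 0) return(numeric(length(new_scheme)))
    col <- age_class_distribution(matrix$cells[, d] / tot, matrix$scheme)
    tot * rebin(col, new_scheme)$shares
  })
  cells <- do.call(cbind, cols)
  colnames(cells) <- DYNAMICS_TYPES
  reference_matrix(cells, new_scheme)
}

#' Regional distribution of major site types
#'
#' Area shares of the three broad edaphic/moisture classes that condition
#' which disturbance dynamics a site is likely to experience. Defaults are
#' the northern-Sweden case values: mesic to rich sites 73%, with the
#' remaining 27% split 14% moist-wet and 13% dry-poor (the split within the
#' 27% is a package default; only the sum is fixed by the case study).
#'
#' @param mesic_intermediate_rich,moist_wet,dry_poor Area shares; must sum to 1.
#' @return Named numeric vector of class `site_type_distribution`.
#' @export
site_type_distribution <- function(mesic_intermediate_rich = 0.73,
                                   moist_wet = 0.14,
                                   dry_poor = 0.13) {
  x <- c(mesic_intermediate_rich = mesic_intermediate_rich,
         moist_wet = moist_wet, dry_poor = dry_poor)
  if (any(x < 0)) stop("site-type shares must be non-negative")
  if (abs(sum(x) - 1) > 1e-9) stop("site-type shares must sum to 1")
  structure(x, class = c("site_type_distribution", class(x)))
}

#' Bottom-up (ASIO-style) age-class estimate from site types
#'
#' Implements the stand-level bottom-up logic in which a single dynamics
#' type is assumed to prevail on each major site type. Area mapped to
#' even-aged dynamics receives the equilibrium age-class distribution
#' averaged over a set of stand-replacing disturbance regimes (by default the
#' negative exponential and a Weibull, both with a 100-year mean return
#' interval, equally weighted). Area mapped to gap or cohort dynamics
#' receives a configurable old-leaning age profile for forest shaped by
#' non-stand-replacing dynamics.
#'
#' @param site_dist A [site_type_distribution()].
#' @param site_to_dynamics Named character vector mapping each site class
#'   with positive share to a dynamics type (`"GD"`, `"ED"`, `"CD"`).
#' @param ed_regimes List of [disturbance_regime()] objects applied to
#'   even-aged area.
#' @param ed_weights Weights for `ed_regimes`, summing to 1.
#' @param nonreplacing_age_profile [age_class_distribution()] applied to
#'   gap- and cohort-dynamics area. The default (30% / 10% / 60% over
#'   0-109 / 110-149 / >=150 years) is a package assumption, configurable.
#' @param scheme Output [age_class_scheme()]; defaults to the profile's.
#' @return An object of class `asio_estimate`: the mixed
#'   [age_class_distribution()] plus the per-dynamics composition.
#' @examples
#' est <- asio_bottom_up()
#' est$distribution
#' @export
asio_bottom_up <- function(site_dist = site_type_distribution(),
                           site_to_dynamics = c(mesic_intermediate_rich = "ED",
                                                moist_wet = "GD",
                                                dry_poor = "CD"),
                           ed_regimes = list(
                             disturbance_regime("negative_exponential", 100),
                             disturbance_regime("weibull", 100, shape = 2)),
                           ed_weights = c(0.5, 0.5),
                           nonreplacing_age_profile = age_class_distribution(
                             c(0.30, 0.10, 0.60), age_class_scheme(c(0, 110, 150))),
                           scheme = nonreplacing_age_profile$scheme) {
  stopifnot(inherits(site_dist, "site_type_distribution"),
            is_distribution(nonreplacing_age_profile), is_scheme(scheme))
  if (!same_scheme(nonreplacing_age_profile$scheme, scheme)) {
    nonreplacing_age_profile <- rebin(nonreplacing_age_profile, scheme)
  }
  active <- names(site_dist)[unclass(site_dist) > 0]
  if (!all(active %in% names(site_to_dynamics))) {
    stop("unmapped site class(es): ",
         paste(setdiff(active, names(site_to_dynamics)), collapse = ", "))
  }
  dyn <- site_to_dynamics[names(site_dist)]
  if (!all(dyn[unclass(site_dist) > 0] %in% DYNAMICS_TYPES)) {
    stop("site_to_dynamics values must be GD, ED or CD")
  }
  # area weight per dynamics type
  w_dyn <- vapply(DYNAMICS_TYPES,
                  function(d) sum(site_dist[which(dyn == d)]), numeric(1))
  ed_dist <- average_distributions(
    lapply(ed_regimes, age_class_shares, scheme = scheme), ed_weights)
  per_dyn <- rbind(GD = nonreplacing_age_profile$shares,
                   ED = ed_dist$shares,
                   CD = nonreplacing_age_profile$shares)
  colnames(per_dyn) <- scheme$labels
  mixed <- as.numeric(w_dyn %*% per_dyn)
  structure(
    list(distribution = age_class_distribution(mixed, scheme),
         dynamics_weights = w_dyn,
         per_dynamics = per_dyn,
         ed_distribution = ed_dist,
         scheme = scheme),
    class = "asio_estimate")
}

#' @export
print.asio_estimate <- function(x, digits = 1, ...) {
  cat("Bottom-up (site-type) age-class estimate\n")
  cat("Dynamics-type area weights:",
      paste(sprintf("%s %.0f%%", names(x$dynamics_weights),
                    100 * x$dynamics_weights), collapse = ", "), "\n")
  print(x$distribution, digits = digits)
  invisible(x)
}

#' Sensitivity of the bottom-up estimate to the Weibull shape
#'
#' Recomputes [asio_bottom_up()] over a grid of Weibull shape values for the
#' even-aged component and reports the share of forest at or above an age
#' threshold. The interval-distribution shape used in the original regional
#' analysis is not published, so this share is reported as a scan rather
#' than a point estimate.
#'
#' @param shapes Numeric vector of Weibull shapes to scan.
#' @param threshold Age threshold in years (default 110).
#' @param ... Further arguments passed to [asio_bottom_up()].
#' @return Data frame with columns `shape` and `share_ge_threshold`.
#' @export
asio_sensitivity_scan <- function(shapes = seq(1.5, 3, by = 0.25),
                                  threshold = 110, ...) {
  res <- vapply(shapes, function(s) {
    est <- asio_bottom_up(
      ed_regimes = list(disturbance_regime("negative_exponential", 100),
                        disturbance_regime("weibull", 100, shape = s)),
      ...)
    share_at_or_above(est$distribution, threshold)
  }, numeric(1))
  data.frame(shape = shapes, share_ge_threshold = res)
}

#' Share of area at or above an age threshold
#'
#' Sums the bins of an age-class distribution whose lower edge is at or
#' above `threshold`, re-binning first (uniform-within-class) if the
#' threshold is not an existing boundary.
#'
#' @param dist An [age_class_distribution()].
#' @param threshold Age in years.
#' @return A single fraction.
#' @export
share_at_or_above <- function(dist, threshold) {
  stopifnot(is_distribution(dist))
  if (threshold <= 0) return(1)
  b <- dist$scheme$boundaries
  if (!any(abs(b - threshold) < 1e-9)) {
    dist <- rebin(dist, age_class_scheme(sort(unique(c(b[b < threshold], threshold)))))
    b <- dist$scheme$boundaries
  }
  sum(dist$shares[b >= threshold - 1e-9])
}

#' Compare age-class distributions side by side
#'
#' @param models Named list of [age_class_distribution()] objects on one
#'   common scheme.
#' @return An object of class `model_comparison`: a table of shares per
#'   model plus pairwise per-bin differences and ratios.
#' @examples
#' sc <- age_class_scheme(c(0, 110, 150))
#' revised <- rebin(age_class_distribution(c(.25, .25, .5),
#'                  age_class_scheme(c(0, 75, 150))), sc)
#' actual <- age_class_distribution(c(.78, .13, .09), sc)
#' compare_models(list(revised = revised, actual = actual))
#' @export
compare_models <- function(models) {
  stopifnot(is.list(models), length(models) >= 1L,
            all(vapply(models, is_distribution, TRUE)))
  if (is.null(names(models)) || any(names(models) == "")) {
    stop("'models' must be a named list")
  }
  scheme <- models[[1]]$scheme
  for (m in models) {
    if (!same_scheme(m$scheme, scheme)) stop("all models must share one scheme")
  }
  shares <- vapply(models, function(m) m$shares, numeric(length(scheme)))
  rownames(shares) <- scheme$labels
  nm <- names(models)
  pairs <- if (length(nm) > 1) utils::combn(nm, 2, simplify = FALSE) else list()
  differences <- lapply(pairs, function(p) shares[, p[1]] - shares[, p[2]])
  ratios <- lapply(pairs, function(p) shares[, p[1]] / shares[, p[2]])
  names(differences) <- names(ratios) <-
    vapply(pairs, paste, character(1), collapse = " vs ")
  structure(list(table = shares, differences = differences, ratios = ratios,
                 scheme = scheme),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, digits = 1, ...) {
  cat("Model comparison (% of area)\n")
  print(round(100 * x$table, digits))
  if (length(x$ratios)) {
    cat("\nPer-bin ratios:\n")
    print(round(do.call(rbind, x$ratios), 2))
  }
  invisible(x)
}
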