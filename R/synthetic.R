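#' Regional case-study profile for synthetic stand tables
#'
#' Marginal structure of a managed northern-Fennoscandian forest region:
#' site-type shares, age-class shares, and a log-normal stand-area
#' distribution. Defaults follow the northern-Sweden case: mesic to rich
#' sites 73%, moist-wet 14%, dry-poor 13%; ages 78% young (0-109 y),
#' 13% mid-aged (110-149 y), 9% old (>= 150 y); stand areas log-normal with
#' median 10 ha.
#'
#' @param site_shares Named shares for `mesic_intermediate_rich`,
#'   `moist_wet`, `dry_poor`; must sum to 1.
#' @param age_shares Shares per bin of `scheme`; must sum to 1.
#' @param scheme [age_class_scheme()] for `age_shares` (default 0/110/150).
#' @param area_meanlog,area_sdlog Log-normal stand-area parameters
#'   (`meanlog = log(10)` gives the 10-ha median).
#' @param old_age_max Upper age (years) used to draw concrete ages inside
#'   the unbounded old class (uniform on `[150, old_age_max]`).
#' @return An object of class `case_study_profile`.
#' @export
case_study_profile <- function(site_shares = c(mesic_intermediate_rich = 0.73,
                                               moist_wet = 0.14,
                                               dry_poor = 0.13),
                               age_shares = c(0.78, 0.13, 0.09),
                               scheme = age_class_scheme(c(0, 110, 150)),
                               area_meanlog = log(10), area_sdlog = 0.8,
                               old_age_max = 300) {
  stopifnot(is_scheme(scheme))
  if (abs(sum(site_shares) - 1) > 1e-9 || any(site_shares < 0)) {
    stop("'site_shares' must be non-negative and sum to 1")
  }
  if (length(age_shares) != length(scheme) ||
      abs(sum(age_shares) - 1) > 1e-9 || any(age_shares < 0)) {
    stop("'age_shares' must be non-negative, one per bin, summing to 1")
  }
  if (old_age_max <= max(scheme$boundaries)) {
    stop("'old_age_max' must exceed the last class boundary")
  }
  structure(list(site_shares = site_shares, age_shares = age_shares,
                 scheme = scheme, area_meanlog = area_meanlog,
                 area_sdlog = area_sdlog, old_age_max = old_age_max),
            class = "case_study_profile")
}

draw_ages <- function(class_idx, scheme, old_age_max, n) {
  lo <- scheme$boundaries[class_idx]
  up <- c(scheme$boundaries[-1], old_age_max)[class_idx]
  stats::runif(n, lo, up)
}

#' Generate a synthetic regional stand table
#'
#' Draws per-stand site type and age class independently from the profile's
#' marginals (the joint site-by-age structure of real inventories is not
#' emulated), with ages uniform within class and log-normal stand areas.
#' Identical seeds give identical tables.
#'
#' @param profile A [case_study_profile()].
#' @param n_stands Number of stands (>= 100).
#' @param seed Integer seed.
#' @return A `landscape` data frame with columns `stand_id`, `site_type`,
#'   `age_years`, `area_ha`.
#' @examples
#' ls <- generate_landscape(case_study_profile(), 500, seed = 1)
#' empirical_age_distribution(ls, age_class_scheme(c(0, 110, 150)))
#' @export
generate_landscape <- function(profile = case_study_profile(), n_stands, seed) {
  stopifnot(inherits(profile, "case_study_profile"))
  if (n_stands < 100) stop("at least 100 stands are required")
  set.seed(seed)
  n <- as.integer(n_stands)
  site <- sample(names(profile$site_shares), n, replace = TRUE,
                 prob = profile$site_shares)
  cls <- sample(seq_along(profile$age_shares), n, replace = TRUE,
                prob = profile$age_shares)
  age <- draw_ages(cls, profile$scheme, profile$old_age_max, n)
  area <- stats::rlnorm(n, profile$area_meanlog, profile$area_sdlog)
  out <- data.frame(stand_id = seq_len(n), site_type = site,
                    age_years = age, area_ha = area, stringsAsFactors = FALSE)
  class(out) <- c("landscape", "data.frame")
  out
}

#' Sample a landscape from a reference matrix
#'
#' Inverse sampling from the 9-cell joint (age class x dynamics type)
#' distribution of a reference matrix, tagging each stand with its dynamics
#' type; the workhorse for round-trip recovery tests. With `quota = TRUE`
#' cell counts are fixed by largest-remainder apportionment instead of
#' random draws.
#'
#' @param matrix A [reference_matrix()].
#' @param n_stands Number of stands.
#' @param seed Integer seed.
#' @param area_ha Constant stand area (the matrix is an area-share object;
#'   area heterogeneity belongs to [generate_landscape()]).
#' @param old_age_max Upper age for the unbounded class, as in
#'   [case_study_profile()].
#' @param quota Use exact largest-remainder cell counts.
#' @return A `landscape` data frame with an extra `dynamics` column.
#' @export
generate_natural_landscape <- function(matrix, n_stands, seed, area_ha = 10,
                                       old_age_max = 300, quota = FALSE) {
  stopifnot(is_reference_matrix(matrix))
  set.seed(seed)
  n <- as.integer(n_stands)
  k <- length(matrix$scheme)
  p <- as.vector(matrix$cells)          # column-major: age within dynamics
  cell <- if (quota) {
    counts <- largest_remainder(p * n, n)
    rep(seq_along(p), counts)
  } else {
    sample(seq_along(p), n, replace = TRUE, prob = p)
  }
  cls <- ((cell - 1) %% k) + 1
  dyn <- DYNAMICS_TYPES[((cell - 1) %/% k) + 1]
  age <- draw_ages(cls, matrix$scheme, old_age_max, n)
  out <- data.frame(stand_id = seq_len(n), site_type = NA_character_,
                    age_years = age, area_ha = area_ha, dynamics = dyn,
                    stringsAsFactors = FALSE)
  class(out) <- c("landscape", "data.frame")
  out
}

largest_remainder <- function(x, n) {
  fl <- floor(x)
  rem <- n - sum(fl)
  if (rem > 0) {
    extra <- order(x - fl, decreasing = TRUE)[seq_len(rem)]
    fl[extra] <- fl[extra] + 1
  }
  as.integer(fl)
}

#' Area-weighted empirical age-class distribution of a stand table
#'
#' @param landscape A `landscape` data frame (`age_years`, `area_ha`).
#' @param scheme An [age_class_scheme()].
#' @return An [age_class_distribution()].
#' @export
empirical_age_distribution <- function(landscape, scheme) {
  stopifnot(is.data.frame(landscape), is_scheme(scheme))
  age_class_distribution(
    bin_shares(landscape$age_years, landscape$area_ha, scheme), scheme)
}

#' Estimate a reference matrix from a dynamics-tagged landscape
#'
#' Area-weighted empirical shares per (age class, dynamics type) cell; the
#' inverse of [generate_natural_landscape()] for round-trip tests.
#'
#' @param landscape A `landscape` data frame with a `dynamics` column.
#' @param scheme An [age_class_scheme()].
#' @return A [reference_matrix()].
#' @export
estimate_reference_matrix <- function(landscape, scheme) {
  stopifnot(is.data.frame(landscape), is_scheme(scheme))
  if (is.null(landscape$dynamics)) stop("'landscape' must carry a 'dynamics' column")
  cls <- findInterval(landscape$age_years, scheme$boundaries)
  cls[cls < 1] <- 1
  tot <- sum(landscape$area_ha)
  cells <- vapply(DYNAMICS_TYPES, function(d) {
    sel <- landscape$dynamics == d
    as.numeric(tapply(landscape$area_ha[sel],
                      factor(cls[sel], levels = seq_along(scheme$boundaries)),
                      sum, default = 0)) / tot
  }, numeric(length(scheme)))
  reference_matrix(cells, scheme)
}

#' Write / read a stand table as CSV
#'
#' Plain-text interchange format: columns `stand_id`, `site_type`,
#' `age_years`, `area_ha` (plus `dynamics` when present).
#'
#' @param landscape A `landscape` data frame.
#' @param path File path.
#' @return `write_stand_table()` returns `path` invisibly;
#'   `read_stand_table()` returns a `landscape` data frame.
#' @export
write_stand_table <- function(landscape, path) {
  stopifnot(is.data.frame(landscape))
  utils::write.csv(as.data.frame(landscape), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_stand_table
#' @export
read_stand_table <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("stand_id", "site_type", "age_years", "area_ha")
  if (!all(need %in% names(out))) {
    stop("stand table must have columns ", paste(need, collapse = ", "))
  }
  class(out) <- c("landscape", "data.frame")
  out
}
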