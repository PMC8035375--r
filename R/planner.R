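#' Cutting methods emulating the dynamics types
#'
#' Bijective mapping from dynamics types to harvesting methods: gap dynamics
#' are emulated by gap/selection cutting (`GC`), even-aged dynamics by
#' clear-cutting with retention (`CC`), and cohort dynamics by partial
#' cutting (`PC`).
#'
#' @format Named character vector (`GD`, `ED`, `CD`).
#' @export
CUTTING_METHODS <- c(GD = "GC", ED = "CC", CD = "PC")

#' Rotation and cutting-cycle policy
#'
#' Per-age-class rotation lengths and target mean ages, plus the cutting
#' cycle applied in gap- and partial-cutting areas (a fraction of the area
#' harvested every cycle). Young areas use the standard 75-year rotation
#' with a 40-year target mean age; mid and old areas use extended rotations
#' (defaults 150 and 300 years, the old class under continuous cover) —
#' the extended values are package defaults, configurable.
#'
#' @param young_rotation,young_target_age Years (defaults 75 / 40).
#' @param mid_rotation,mid_target_age Years (defaults 150 / 112).
#' @param old_rotation,old_target_age Years (defaults 300 / 200); the old
#'   rotation doubles as the whole-landscape conveyor length in
#'   [project_managed()].
#' @param cycle_fraction Fraction of a gap/partial area harvested per
#'   cutting cycle, in `[0.20, 0.30]` (default 0.25).
#' @param cycle_years Cutting-cycle length in years, in `[20, 30]`
#'   (default 25).
#' @return An object of class `rotation_policy`.
#' @export
rotation_policy <- function(young_rotation = 75, young_target_age = 40,
                            mid_rotation = 150, mid_target_age = 112,
                            old_rotation = 300, old_target_age = 200,
                            cycle_fraction = 0.25, cycle_years = 25) {
  rot <- c(young_rotation, mid_rotation, old_rotation)
  tgt <- c(young_target_age, mid_target_age, old_target_age)
  if (any(rot <= 0) || any(tgt <= 0)) stop("rotations and target ages must be positive")
  if (any(tgt >= rot)) {
    stop("infeasible rotation policy: target mean age must be below the rotation")
  }
  if (cycle_fraction < 0.20 || cycle_fraction > 0.30) {
    stop("'cycle_fraction' must lie in [0.20, 0.30]")
  }
  if (cycle_years < 20 || cycle_years > 30) stop("'cycle_years' must lie in [20, 30]")
  structure(list(rotation = rot, target_age = tgt,
                 cycle_fraction = cycle_fraction, cycle_years = cycle_years),
            class = "rotation_policy")
}

#' Build the nine-record management plan from a reference matrix
#'
#' One record per (age class, cutting method) cell: area shares equal the
#' reference-matrix cells, so each cutting method totals its dynamics
#' marginal (one third by default). Young-class records carry the 75-year
#' rotation and 40-year target mean age; gap- and partial-cutting records
#' carry the cutting-cycle parameters (20-30% of area every 20-30 years).
#'
#' @param matrix A [reference_matrix()] with three age classes.
#' @param rotation_policy A [rotation_policy()].
#' @return An object of class `management_plan`: a nine-row data frame with
#'   the matrix, policy and scheme attached.
#' @examples
#' build_plan(build_revised_matrix())
#' @export
build_plan <- function(matrix, rotation_policy = borealNRV::rotation_policy()) {
  stopifnot(is_reference_matrix(matrix),
            inherits(rotation_policy, "rotation_policy"))
  if (length(matrix$scheme) != 3L) stop("a three-class reference matrix is required")
  g <- expand.grid(age_class = matrix$scheme$labels,
                   dynamics = DYNAMICS_TYPES,
                   stringsAsFactors = FALSE)
  g$cutting_method <- unname(CUTTING_METHODS[g$dynamics])
  g$area_share <- as.vector(matrix$cells)
  cls_i <- match(g$age_class, matrix$scheme$labels)
  g$rotation_years <- rotation_policy$rotation[cls_i]
  g$target_mean_age <- rotation_policy$target_age[cls_i]
  cyc <- g$cutting_method %in% c("GC", "PC")
  g$cycle_fraction <- ifelse(cyc, rotation_policy$cycle_fraction, NA_real_)
  g$cycle_years <- ifelse(cyc, rotation_policy$cycle_years, NA_real_)
  g$managed_share <- g$area_share
  g$natural_share <- 0
  structure(g, class = c("management_plan", "data.frame"),
            matrix = matrix, policy = rotation_policy, scheme = matrix$scheme)
}

#' @export
print.management_plan <- function(x, digits = 1, ...) {
  cat("Management plan (age class x cutting method)\n")
  y <- as.data.frame(x)
  y$area_share <- round(100 * y$area_share, digits)
  y$managed_share <- round(100 * y$managed_share, digits)
  y$natural_share <- round(100 * y$natural_share, digits)
  print(y, row.names = FALSE)
  cat("\nMethod totals (% of area):\n")
  print(round(100 * tapply(x$area_share, x$cutting_method, sum), digits))
  invisible(x)
}

#' Total variation distance between two share vectors
#'
#' @param p,q Non-negative numeric vectors of equal length summing to 1.
#' @return `0.5 * sum(abs(p - q))`, in `[0, 1]`.
#' @export
total_variation <- function(p, q) {
  if (length(p) != length(q)) stop("'p' and 'q' must have equal length")
  0.5 * sum(abs(p - q))
}

#' Project a managed landscape toward the reference age structure
#'
#' Projects a stand table forward under the plan's harvest schedule and
#' records the age-class trajectory and its total-variation distance to the
#' reference age marginals. Stands are first assigned to the nine plan
#' records by largest-remainder area quotas, oldest stands to the oldest
#' age-class records (the spatial allocation of cutting methods).
#'
#' The stand-replacing schedule works as a landscape-level conveyor: every
#' stand reaching the old-class reference rotation is felled, and when the
#' young-class share falls below its target an additional harvest restores
#' it exactly, taken oldest-first while age classes below their target share
#' are protected. With default parameters the reference state (ages uniform
#' over a full conveyor length) is a fixed point of the schedule up to stand
#' discretization. Gap- and partial-cutting cycle harvests are recorded but
#' do not reset the dominant-cohort age.
#'
#' @param plan A [build_plan()] result.
#' @param initial A `landscape` data frame (`age_years`, `area_ha`).
#' @param years Projection horizon in years (0 returns the initial state).
#' @param seed Optional seed; only used when `selection = "random"`.
#' @param record_every Trajectory recording interval in years.
#' @param selection `"oldest"` (deterministic, default) or `"random"` stand
#'   choice within the eligible set.
#' @return An object of class `managed_projection`: `trajectory` (year,
#'   age_class, share), `tv` (year, tv distance to the reference marginals),
#'   `final` landscape, and the plan.
#' @examples
#' ls <- generate_landscape(case_study_profile(), 400, seed = 2)
#' pr <- project_managed(build_plan(build_revised_matrix()), ls, years = 150)
#' utils::tail(pr$tv)
#' @export
project_managed <- function(plan, initial, years, seed = NULL,
                            record_every = 5,
                            selection = c("oldest", "random")) {
  stopifnot(inherits(plan, "management_plan"), is.data.frame(initial))
  selection <- match.arg(selection)
  if (!is.null(seed)) set.seed(seed)
  if (nrow(initial) < nrow(plan)) {
    stop("landscape smaller than plan granularity: need at least ",
         nrow(plan), " stands")
  }
  scheme <- attr(plan, "scheme")
  policy <- attr(plan, "policy")
  target <- age_marginals(attr(plan, "matrix"))
  b <- scheme$boundaries
  young_target <- target[1]
  old_target <- target[length(target)]
  conveyor <- policy$rotation[3]

  age <- initial$age_years
  area <- initial$area_ha
  total_area <- sum(area)
  assignment <- assign_records(plan, age, area)

  rec_years <- if (years >= 1) {
    unique(c(0, seq(record_every, years, by = record_every), years))
  } else 0
  shares0 <- bin_shares(age, area, scheme)
  traj <- list(`0` = shares0)
  carry <- 0   # un-executed harvest area carried between years (lumpy stands)

  if (years >= 1) for (yr in seq_len(years)) {
    age <- age + 1
    # mandatory conveyor felling at the old-class reference rotation
    fell <- age >= conveyor
    # deadbeat top-up: restore the young class to its target share
    young_share <- sum(area[age < b[2]]) / total_area
    need <- max(0, young_target - young_share) * total_area + carry -
      sum(area[fell])
    if (need > 0) {
      old_share <- sum(area[age >= b[3]]) / total_area
      eligible <- !fell & age >= b[2]
      if (old_share < old_target - 1e-9) {
        prot <- eligible & age >= b[3]
        if (any(eligible & !prot)) eligible <- eligible & !prot
      }
      idx <- which(eligible)
      if (length(idx)) {
        ord <- if (selection == "oldest") idx[order(-age[idx])] else sample(idx)
        cum <- cumsum(area[ord])
        k <- which(cum >= need)[1]
        if (is.na(k)) k <- length(ord)
        take <- ord[seq_len(k)]
        carry <- need - cum[k]
        fell[take] <- TRUE
      } else {
        carry <- need
      }
    } else {
      carry <- min(0, need)
    }
    age[fell] <- 0
    if (yr %in% rec_years) {
      traj[[as.character(yr)]] <- bin_shares(age, area, scheme)
    }
  }

  yrs <- as.integer(names(traj))
  trajectory <- data.frame(
    year = rep(yrs, each = length(scheme)),
    age_class = rep(scheme$labels, length(yrs)),
    share = unlist(traj, use.names = FALSE))
  tv <- data.frame(year = yrs,
                   tv = vapply(traj, total_variation, numeric(1),
                               q = as.numeric(target)))
  final <- initial
  final$age_years <- age
  final$plan_record <- assignment
  structure(list(trajectory = trajectory, tv = tv, final = final,
                 plan = plan, target = target, scheme = scheme),
            class = "managed_projection")
}

# largest-remainder area quotas per plan record; oldest stands are assigned
# to the oldest age-class records
assign_records <- function(plan, age, area) {
  total <- sum(area)
  ord_rec <- order(-match(plan$age_class, attr(plan, "scheme")$labels))
  quota <- plan$area_share[ord_rec] * total
  ord_stand <- order(-age)
  rec <- integer(length(age))
  j <- 1; filled <- 0
  for (s in ord_stand) {
    while (j < length(quota) && filled >= quota[j]) {
      j <- j + 1; filled <- 0
    }
    rec[s] <- ord_rec[j]
    filled <- filled + area[s]
  }
  rec
}

#' @export
print.managed_projection <- function(x, ...) {
  n <- nrow(x$tv)
  cat("Managed-landscape projection over", x$tv$year[n], "years\n")
  cat(sprintf("  distance to reference marginals: %.3f (start) -> %.3f (end)\n",
              x$tv$tv[1], x$tv$tv[n]))
  invisible(x)
}

#' @export
plot.managed_projection <- function(x, ...) {
  graphics::plot(x$tv$year, x$tv$tv, type = "l",
                 xlab = "year", ylab = "total variation to reference",
                 main = "Convergence toward the reference age structure", ...)
  invisible(x)
}

#' Credit natural disturbance against the management plan
#'
#' When natural disturbance does part of the work, the matching plan cell's
#' managed area is reduced by the naturally disturbed share (stand-replacing
#' events credit the clear-cut cells, partial events the partial-cutting
#' cells, gap events the gap-cutting cells) and booked as natural area; the
#' reduction is logged on the plan.
#'
#' @param plan A [build_plan()] result.
#' @param event List with `severity` (`"stand_replacing"`, `"partial"`,
#'   `"gap"`), `area_share` (fraction of total landscape), and optionally
#'   `age_class` (label; stand-replacing events default to the young class,
#'   others spread over the method's cells in proportion to their shares).
#' @return The adjusted `management_plan`.
#' @examples
#' p <- build_plan(build_revised_matrix())
#' disturbance_adjustment(p, list(severity = "stand_replacing", area_share = 0.05))
#' @export
disturbance_adjustment <- function(plan, event) {
  stopifnot(inherits(plan, "management_plan"), is.list(event))
  sev <- match.arg(event$severity, c("stand_replacing", "partial", "gap"))
  a <- event$area_share
  if (is.null(a) || a < 0) stop("'event$area_share' must be a non-negative fraction")
  method <- c(stand_replacing = "CC", partial = "PC", gap = "GC")[[sev]]
  scheme <- attr(plan, "scheme")
  rows <- which(plan$cutting_method == method)
  age_class <- event$age_class
  if (is.null(age_class) && sev == "stand_replacing") age_class <- scheme$labels[1]
  if (!is.null(age_class)) {
    rows <- rows[plan$age_class[rows] == age_class]
    if (length(rows) == 0) stop("no plan cell for age class '", age_class, "'")
  }
  w <- plan$managed_share[rows]
  if (a > sum(w) + 1e-12) {
    stop("event area (", a, ") exceeds the available managed share (",
         signif(sum(w), 4), ") of the ", method, " cells")
  }
  red <- if (sum(w) > 0) a * w / sum(w) else rep(0, length(w))
  plan$managed_share[rows] <- plan$managed_share[rows] - red
  plan$natural_share[rows] <- plan$natural_share[rows] + red
  log <- attr(plan, "adjustments")
  attr(plan, "adjustments") <- rbind(
    log, data.frame(severity = sev, area_share = a,
                    cells = paste(plan$age_class[rows], method, collapse = "; ")))
  plan
}
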