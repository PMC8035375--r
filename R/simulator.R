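#' Mixed-severity disturbance regime for the stand simulator
#'
#' Annual per-stand event hazards for three severity classes, with the range
#' of the killed (cohort-initiating) fraction for the two non-stand-replacing
#' classes. Stand-replacing events always kill the whole stand; partial
#' events kill an intermediate fraction in `[0.25, 0.75)`; gap events kill a
#' small fraction in `(0, 0.25)`.
#'
#' @param stand_replacing,partial,gap Annual event probabilities (>= 0).
#' @param partial_killed Length-2 range for the partial killed fraction,
#'   inside `[0.25, 0.75)`.
#' @param gap_killed Length-2 range for the gap killed fraction, inside
#'   `(0, 0.25)`.
#' @return An object of class `severity_regime`.
#' @examples
#' severity_regime(stand_replacing = 1/100)                    # fire-cycle only
#' severity_regime(1/300, partial = 1/60, gap = 1/20)          # mixed severity
#' @export
severity_regime <- function(stand_replacing = 0, partial = 0, gap = 0,
                            partial_killed = c(0.25, 0.7499),
                            gap_killed = c(0.05, 0.2499)) {
  h <- c(stand_replacing = stand_replacing, partial = partial, gap = gap)
  if (any(h < 0) || any(h > 1)) stop("hazards must be probabilities in [0, 1]")
  if (length(partial_killed) != 2L || partial_killed[1] < 0.25 ||
      partial_killed[2] >= 0.75 || diff(partial_killed) < 0) {
    stop("'partial_killed' must be an increasing range inside [0.25, 0.75)")
  }
  if (length(gap_killed) != 2L || gap_killed[1] <= 0 ||
      gap_killed[2] >= 0.25 || diff(gap_killed) < 0) {
    stop("'gap_killed' must be an increasing range inside (0, 0.25)")
  }
  structure(list(hazards = h, partial_killed = partial_killed,
                 gap_killed = gap_killed),
            class = "severity_regime")
}

#' @export
print.severity_regime <- function(x, ...) {
  cat("Severity regime (annual hazards):\n")
  h <- x$hazards
  lab <- ifelse(h > 0, sprintf("1/%.4g y", 1 / h), "none")
  cat(paste(sprintf("  %-16s %s", names(h), lab), collapse = "\n"), "\n")
  invisible(x)
}

#' Simulation configuration
#'
#' @param n_stands Number of independent stands (> 0).
#' @param years Years recorded after burn-in (> 0).
#' @param burn_in Burn-in years before recording; defaults to 10 times the
#'   longest mean return interval of the regime it is run with.
#' @param seed Mandatory integer seed for reproducibility.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_stands, years, burn_in = NULL, seed) {
  if (n_stands < 1) stop("at least one stand is required")
  if (years < 1) stop("'years' must be positive")
  if (missing(seed) || is.null(seed)) stop("a 'seed' is required for reproducibility")
  structure(list(n_stands = as.integer(n_stands), years = as.integer(years),
                 burn_in = if (is.null(burn_in)) NULL else as.integer(burn_in),
                 seed = as.integer(seed)),
            class = "sim_config")
}

default_burn_in <- function(regime) {
  h <- regime$hazards[regime$hazards > 0]
  if (length(h) == 0) return(0L)
  as.integer(ceiling(10 / min(h)))
}

#' Stochastic per-stand disturbance simulator
#'
#' Simulates a landscape of independent stands under annual Bernoulli draws
#' per severity class, with at most one event per stand per year (priority
#' stand-replacing > partial > gap). Stand-replacing events reset the
#' stand's cohorts and dominant-cohort age. Partial and gap events add a new
#' cohort with a killed fraction drawn uniformly from the class range and
#' renormalize the survivors; the dominant-cohort age only resets if the new
#' cohort's fraction exceeds every surviving cohort, in which case dominance
#' transfers. "Forest age" throughout is the dominant-cohort age, so the
#' stationary age distribution under stand-replacing events alone at hazard
#' `1/lambda` converges to the negative-exponential survivorship — the
#' module's role as a Monte-Carlo check on the closed forms.
#'
#' @param config A [sim_config()].
#' @param regime A [severity_regime()] (all hazards 0 is an undisturbed
#'   control: every stand's age equals the elapsed years).
#' @param scheme [age_class_scheme()] used to record the trajectory.
#' @param record_every Record the age-class distribution every this many
#'   years after burn-in (the final year is always recorded).
#' @param track_cohorts Keep the full per-stand cohort list (establishment
#'   year + surviving fraction). Cohorts below 1e-4 are pruned.
#' @return An object of class `disturbance_sim` with elements `landscape`
#'   (data frame: stand_id, area_ha, age_years, dominant_frac, last event
#'   years per severity), `cohorts`, `trajectory` (year, age_class, share)
#'   and the inputs.
#' @examples
#' sim <- simulate_landscape(sim_config(500, 50, burn_in = 300, seed = 1),
#'                           severity_regime(stand_replacing = 1/100))
#' sim_age_distribution(sim)
#' @export
simulate_landscape <- function(config, regime,
                               scheme = age_class_scheme(c(0, 75, 150)),
                               record_every = 10, track_cohorts = TRUE) {
  stopifnot(inherits(config, "sim_config"), inherits(regime, "severity_regime"),
            is_scheme(scheme))
  n <- config$n_stands
  burn_in <- if (is.null(config$burn_in)) default_burn_in(regime) else config$burn_in
  total_years <- burn_in + config$years
  set.seed(config$seed)

  h <- regime$hazards
  age <- numeric(n)
  dom_frac <- rep(1, n)
  last_sr <- rep(NA_integer_, n)
  last_partial <- rep(NA_integer_, n)
  last_gap <- rep(NA_integer_, n)
  cohorts <- if (track_cohorts) {
    lapply(seq_len(n), function(i) cbind(est_year = 0, frac = 1))
  } else NULL

  rec_years <- integer(0)
  if (config$years >= 1) {
    rec_years <- if (burn_in + record_every <= total_years) {
      seq(burn_in + record_every, total_years, by = record_every)
    } else integer(0)
    rec_years <- unique(c(rec_years, total_years))
    rec_years <- rec_years[rec_years > burn_in]
  }
  traj <- vector("list", length(rec_years))
  names(traj) <- rec_years

  add_cohort <- function(i, year, f) {
    co <- cohorts[[i]]
    co[, "frac"] <- co[, "frac"] * (1 - f)
    co <- rbind(co, c(year, f))
    co <- co[co[, "frac"] >= 1e-4, , drop = FALSE]
    co[, "frac"] <- co[, "frac"] / sum(co[, "frac"])
    cohorts[[i]] <<- co
    # dominance derived from the list (ties keep the older cohort); uniform
    # renormalization never reorders survivors, so this implements the
    # "new cohort exceeds all survivors" transfer rule exactly
    best <- which.max(co[, "frac"])
    dom_frac[i] <<- co[best, "frac"]
    age[i] <<- year - co[best, "est_year"]
  }

  for (year in seq_len(total_years)) {
    age <- age + 1
    u_sr <- stats::runif(n); u_p <- stats::runif(n); u_g <- stats::runif(n)
    sr <- u_sr < h["stand_replacing"]
    pa <- !sr & u_p < h["partial"]
    ga <- !sr & !pa & u_g < h["gap"]

    if (any(sr)) {
      idx <- which(sr)
      age[idx] <- 0
      dom_frac[idx] <- 1
      last_sr[idx] <- year
      if (track_cohorts) {
        cohorts[idx] <- lapply(idx, function(i) cbind(est_year = year, frac = 1))
      }
    }
    for (sev in c("partial", "gap")) {
      evt <- if (sev == "partial") pa else ga
      if (!any(evt)) next
      idx <- which(evt)
      rng <- if (sev == "partial") regime$partial_killed else regime$gap_killed
      f <- stats::runif(length(idx), rng[1], rng[2])
      if (sev == "partial") last_partial[idx] <- year else last_gap[idx] <- year
      # dominance transfers when the new cohort exceeds every survivor;
      # uniform renormalization preserves the survivors' ranking
      surv_dom <- dom_frac[idx] * (1 - f)
      transfer <- f > surv_dom
      age[idx[transfer]] <- 0
      dom_frac[idx] <- ifelse(transfer, f, surv_dom)
      if (track_cohorts) {
        for (j in seq_along(idx)) add_cohort(idx[j], year, f[j])
      }
    }
    if (year %in% rec_years) {
      traj[[as.character(year)]] <- bin_shares(age, rep(1, n), scheme)
    }
  }

  trajectory <- if (length(rec_years)) {
    data.frame(year = rep(rec_years - burn_in, each = length(scheme)),
               age_class = rep(scheme$labels, length(rec_years)),
               share = unlist(traj, use.names = FALSE))
  } else {
    data.frame(year = integer(0), age_class = character(0), share = numeric(0))
  }

  landscape <- data.frame(stand_id = seq_len(n), site_type = NA_character_,
                          area_ha = 1, age_years = age,
                          dominant_frac = dom_frac,
                          last_sr_year = last_sr,
                          last_partial_year = last_partial,
                          last_gap_year = last_gap,
                          stringsAsFactors = FALSE)
  class(landscape) <- c("landscape", "data.frame")
  structure(list(landscape = landscape, cohorts = cohorts,
                 trajectory = trajectory, scheme = scheme, config = config,
                 regime = regime, burn_in = burn_in,
                 history_years = total_years),
            class = "disturbance_sim")
}

bin_shares <- function(age, area, scheme) {
  idx <- findInterval(age, scheme$boundaries)
  idx[idx < 1] <- 1
  as.numeric(tapply(area, factor(idx, levels = seq_along(scheme$boundaries)),
                    sum, default = 0)) / sum(area)
}

#' @export
print.disturbance_sim <- function(x, ...) {
  cat("Stand-level disturbance simulation:", x$config$n_stands, "stands,",
      x$config$years, "years after", x$burn_in, "burn-in years\n")
  print(x$regime)
  print(sim_age_distribution(x))
  invisible(x)
}

#' @export
plot.disturbance_sim <- function(x, ...) {
  tr <- x$trajectory
  if (nrow(tr) == 0) stop("no recorded trajectory to plot")
  wide <- stats::reshape(tr, idvar = "year", timevar = "age_class",
                         direction = "wide")
  graphics::matplot(wide$year, as.matrix(wide[, -1]), type = "l", lty = 1,
                    xlab = "year", ylab = "area share",
                    main = "Simulated age-class trajectory", ...)
  graphics::legend("topright", legend = x$scheme$labels, lty = 1,
                   col = seq_along(x$scheme$labels), bty = "n")
  invisible(x)
}

#' Final age-class distribution of a simulation
#'
#' @param sim A `disturbance_sim` object.
#' @param scheme Optional [age_class_scheme()]; defaults to the one the
#'   simulation recorded with.
#' @return An [age_class_distribution()] (area-weighted, by dominant-cohort
#'   age).
#' @export
sim_age_distribution <- function(sim, scheme = NULL) {
  stopifnot(inherits(sim, "disturbance_sim"))
  if (is.null(scheme)) scheme <- sim$scheme
  age_class_distribution(
    bin_shares(sim$landscape$age_years, sim$landscape$area_ha, scheme), scheme)
}

#' Classify each stand's recent dynamics type
#'
#' A stand is even-aged (`ED`) if a stand-replacing event occurred within
#' the last `window` years, else cohort (`CD`) if at least one partial event
#' did, else gap (`GD`).
#'
#' @param sim A `disturbance_sim` object.
#' @param window Look-back window in years; must not exceed the simulated
#'   history.
#' @return Factor of dynamics types, one per stand.
#' @export
classify_dynamics <- function(sim, window) {
  stopifnot(inherits(sim, "disturbance_sim"))
  if (window > sim$history_years) {
    stop("insufficient history: window (", window, " y) exceeds the ",
         sim$history_years, " simulated years")
  }
  ls <- sim$landscape
  cutoff <- sim$history_years - window
  in_window <- function(y) !is.na(y) & y > cutoff
  out <- ifelse(in_window(ls$last_sr_year), "ED",
                ifelse(in_window(ls$last_partial_year), "CD", "GD"))
  factor(out, levels = DYNAMICS_TYPES)
}

#' Compare a simulated distribution with an analytic prediction
#'
#' Per-bin z-scores `(simulated - analytic) / se`, with the binomial
#' standard error `sqrt(p (1 - p) / n)` evaluated at the analytic share.
#'
#' @param simulated,analytic [age_class_distribution()] objects on one scheme.
#' @param n_stands Number of stands behind the simulated shares.
#' @return A data frame of class `equilibrium_check` with columns
#'   `age_class`, `simulated`, `analytic`, `z`.
#' @export
equilibrium_check <- function(simulated, analytic, n_stands) {
  stopifnot(is_distribution(simulated), is_distribution(analytic))
  if (!same_scheme(simulated$scheme, analytic$scheme)) {
    stop("the two distributions must share one scheme")
  }
  p <- analytic$shares
  se <- sqrt(p * (1 - p) / n_stands)
  d <- simulated$shares - p
  z <- ifelse(se > 0, d / se, ifelse(abs(d) < 1e-12, 0, Inf))
  out <- data.frame(age_class = simulated$scheme$labels,
                    simulated = simulated$shares, analytic = p, z = z)
  class(out) <- c("equilibrium_check", "data.frame")
  out
}

#' Draw random disturbance return intervals
#'
#' `simulate()` method for [disturbance_regime()]: samples `nsim` intervals
#' from the regime's interval distribution (exponential or mean-matched
#' Weibull). Useful as an independent Monte-Carlo check on closed-form
#' interval statistics.
#'
#' @param object A [disturbance_regime()].
#' @param nsim Number of intervals to draw.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return Numeric vector of intervals in years.
#' @export
simulate.disturbance_regime <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (object$family == "negative_exponential") {
    stats::rexp(nsim, rate = 1 / object$mean_return_interval)
  } else {
    stats::rweibull(nsim, shape = object$shape, scale = object$scale)
  }
}
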