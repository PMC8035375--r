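#' Ordered forest age-class scheme
#'
#' Defines half-open age bins `[b1, b2), [b2, b3), ..., [bk, Inf)` from a
#' strictly increasing vector of lower boundaries starting at 0. The last bin
#' is always unbounded ("old" forest, e.g. `>= 150` years).
#'
#' @param boundaries Strictly increasing numeric vector of bin lower
#'   boundaries in years; the first must be 0.
#' @param labels Optional character labels, one per bin; defaults to
#'   `"0-74"`-style ranges with `"150+"` for the unbounded bin.
#' @return An object of class `age_class_scheme`.
#' @examples
#' age_class_scheme(c(0, 75, 150))            # young / mid-aged / old
#' age_class_scheme(c(0, 110, 150))           # inventory-style classification
#' @export
age_class_scheme <- function(boundaries, labels = NULL) {
  if (!is.numeric(boundaries) || length(boundaries) < 1L ||
      any(!is.finite(boundaries))) {
    stop("'boundaries' must be a finite numeric vector")
  }
  if (boundaries[1] != 0) stop("the first boundary must be 0")
  if (any(diff(boundaries) <= 0)) stop("'boundaries' must be strictly increasing")
  k <- length(boundaries)
  if (is.null(labels)) {
    upper <- c(boundaries[-1], Inf)
    labels <- ifelse(is.finite(upper),
                     sprintf("%g-%g", boundaries, upper - 1),
                     sprintf("%g+", boundaries))
  }
  if (length(labels) != k) stop("'labels' must have one entry per bin")
  structure(list(boundaries = as.numeric(boundaries),
                 labels = as.character(labels)),
            class = "age_class_scheme")
}

#' @export
print.age_class_scheme <- function(x, ...) {
  cat("Age-class scheme:", paste(x$labels, collapse = " | "), "years\n")
  invisible(x)
}

#' @export
length.age_class_scheme <- function(x) length(x$boundaries)

is_scheme <- function(x) inherits(x, "age_class_scheme")

same_scheme <- function(a, b) {
  is_scheme(a) && is_scheme(b) &&
    length(a$boundaries) == length(b$boundaries) &&
    all(abs(a$boundaries - b$boundaries) < 1e-9)
}

#' Area-share distribution over an age-class scheme
#'
#' @param shares Numeric vector of area fractions, one per bin; each in
#'   `[0, 1]` and summing to 1 within `1e-9`.
#' @param scheme An [age_class_scheme()].
#' @return An object of class `age_class_distribution`.
#' @export
age_class_distribution <- function(shares, scheme) {
  stopifnot(is_scheme(scheme))
  if (!is.numeric(shares) || length(shares) != length(scheme)) {
    stop("'shares' must have one value per bin of 'scheme'")
  }
  if (any(shares < -1e-12) || any(shares > 1 + 1e-12)) {
    stop("each share must lie in [0, 1]")
  }
  if (abs(sum(shares) - 1) > 1e-9) stop("shares must sum to 1 (within 1e-9)")
  structure(list(shares = as.numeric(shares), scheme = scheme),
            class = "age_class_distribution")
}

is_distribution <- function(x) inherits(x, "age_class_distribution")

#' @export
print.age_class_distribution <- function(x, digits = 1, ...) {
  cat("Age-class distribution (% of area)\n")
  print(round(stats::setNames(100 * x$shares, x$scheme$labels), digits))
  invisible(x)
}

#' @export
as.data.frame.age_class_distribution <- function(x, ...) {
  data.frame(age_class = x$scheme$labels,
             lower = x$scheme$boundaries,
             share = x$shares,
             stringsAsFactors = FALSE)
}

#' @export
plot.age_class_distribution <- function(x, main = "Age-class distribution",
                                        ylab = "% of area", col = "forestgreen",
                                        ...) {
  graphics::barplot(100 * x$shares, names.arg = x$scheme$labels,
                    main = main, ylab = ylab, col = col, ...)
  invisible(x)
}

#' Equilibrium age-class shares implied by a disturbance regime
#'
#' Bin shares are differences of the survivorship curve at the bin
#' boundaries; the unbounded bin takes the survivor fraction at its lower
#' boundary, so the shares always sum to 1.
#'
#' @param regime A [disturbance_regime()].
#' @param scheme An [age_class_scheme()].
#' @return An [age_class_distribution()].
#' @examples
#' r <- disturbance_regime("negative_exponential", 100)
#' age_class_shares(r, age_class_scheme(c(0, 110)))
#' @export
age_class_shares <- function(regime, scheme) {
  stopifnot(is_regime(regime), is_scheme(scheme))
  s <- survivor_fraction(regime, scheme$boundaries)
  shares <- c(-diff(s), s[length(s)])
  age_class_distribution(shares, scheme)
}

#' Weighted average of age-class distributions
#'
#' @param dists List of [age_class_distribution()] objects sharing one scheme.
#' @param weights Numeric weights summing to 1; defaults to equal weights.
#' @return The per-bin weighted mean as an [age_class_distribution()].
#' @export
average_distributions <- function(dists, weights = NULL) {
  stopifnot(is.list(dists), length(dists) >= 1L, all(vapply(dists, is_distribution, TRUE)))
  if (is.null(weights)) weights <- rep(1 / length(dists), length(dists))
  if (length(weights) != length(dists)) stop("one weight per distribution required")
  if (abs(sum(weights) - 1) > 1e-9) stop("weights must sum to 1")
  scheme <- dists[[1]]$scheme
  for (d in dists) {
    if (!same_scheme(d$scheme, scheme)) stop("all distributions must share one scheme")
  }
  m <- vapply(dists, function(d) d$shares, numeric(length(scheme)))
  age_class_distribution(as.numeric(m %*% weights), scheme)
}

#' Re-bin an age-class distribution onto a new scheme
#'
#' Ages are assumed uniformly distributed within each bounded source bin; a
#' new bin receives from each source bin a share proportional to the
#' overlapped width. The unbounded source bin carries no internal age
#' information, so every new boundary must lie at or below its lower edge.
#'
#' @param dist An [age_class_distribution()].
#' @param new_scheme Target [age_class_scheme()].
#' @return An [age_class_distribution()] on `new_scheme`; total share is
#'   conserved, and the mapping is exact whenever the new boundaries are a
#'   superset of the old ones.
#' @examples
#' sc3 <- age_class_scheme(c(0, 75, 150))
#' d <- age_class_distribution(c(0.25, 0.25, 0.50), sc3)
#' rebin(d, age_class_scheme(c(0, 110, 150)))
#' @export
rebin <- function(dist, new_scheme) {
  stopifnot(is_distribution(dist), is_scheme(new_scheme))
  old <- dist$scheme$boundaries
  new <- new_scheme$boundaries
  open_edge <- old[length(old)]
  if (any(new > open_edge + 1e-9)) {
    stop("new boundary ", max(new), " lies inside the unbounded source bin (>= ",
         open_edge, "): insufficient information to split it")
  }
  k_old <- length(old); k_new <- length(new)
  old_up <- c(old[-1], Inf)
  new_up <- c(new[-1], Inf)
  out <- numeric(k_new)
  for (i in seq_len(k_old)) {
    if (dist$shares[i] == 0) next
    if (!is.finite(old_up[i])) {
      # unbounded source bin: lands entirely in the (unbounded) new bin
      # containing its lower edge
      j <- findInterval(old[i], new)
      out[j] <- out[j] + dist$shares[i]
    } else {
      w <- old_up[i] - old[i]
      overlap <- pmax(0, pmin(new_up, old_up[i]) - pmax(new, old[i]))
      out <- out + dist$shares[i] * overlap / w
    }
  }
  age_class_distribution(out, new_scheme)
}
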