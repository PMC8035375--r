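test_that("the default revised matrix reproduces every printed cell", {
  m <- revised()
  cells <- round(100 * m$cells, 1)
  expect_equal(unname(cells[, "GD"]), c(2.8, 8.3, 22.2))
  expect_equal(unname(cells[, "CD"]), c(2.8, 8.3, 22.2))
  expect_equal(unname(cells[, "ED"]), c(19.4, 8.3, 5.6))
})

test_that("matrix marginal identities and monotonicity hold", {
  m <- revised()
  expect_equal(sum(m$cells), 1, tolerance = 1e-12)
  expect_equal(unname(age_marginals(m)), c(0.25, 0.25, 0.50), tolerance = 1e-12)
  expect_equal(unname(dynamics_marginals(m)), rep(1 / 3, 3), tolerance = 1e-9)
  # GD and CD increase with age, ED decreases
  expect_true(all(diff(m$cells[, "GD"]) > 0))
  expect_true(all(diff(m$cells[, "CD"]) > 0))
  expect_true(all(diff(m$cells[, "ED"]) < 0))

  # identities persist for non-default marginals
  m2 <- build_revised_matrix(age_marginals = c(0.2, 0.3, 0.5),
                             dynamics_marginals = c(0.4, 0.3, 0.3),
                             old_fraction_of_nonstandreplacing = 0.7)
  expect_equal(unname(age_marginals(m2)), c(0.2, 0.3, 0.5), tolerance = 1e-12)
  expect_equal(unname(dynamics_marginals(m2)), c(0.4, 0.3, 0.3), tolerance = 1e-9)
})

test_that("degenerate and infeasible marginals are handled", {
  pure_ed <- build_revised_matrix(dynamics_marginals = c(GD = 0, ED = 1, CD = 0))
  expect_equal(unname(pure_ed$cells[, "ED"]), c(0.25, 0.25, 0.50), tolerance = 1e-12)
  expect_equal(sum(pure_ed$cells[, c("GD", "CD")]), 0)

  # the even-aged residual overdraws a scarce young class
  expect_error(build_revised_matrix(age_marginals = c(0.05, 0.35, 0.60),
                                    old_fraction_of_nonstandreplacing = 0.5),
               "infeasible")
  # old share below a non-old share violates the construction's premise
  expect_error(build_revised_matrix(age_marginals = c(0.6, 0.3, 0.1)),
               "old-forest share")
})

test_that("re-binning the matrix reproduces the case-study marginals", {
  r <- rebin_matrix(revised(), scheme110())
  am <- 100 * age_marginals(r)
  expect_equal(round(unname(am), 1), c(36.7, 13.3, 50.0))
  expect_equal(round(unname(am)), c(37, 13, 50))
  expect_equal(sum(am[2:3]), 63.33333, tolerance = 1e-4)
  expect_gte(sum(am[2:3]), 63)
  # column totals conserved
  expect_equal(dynamics_marginals(r), dynamics_marginals(revised()), tolerance = 1e-12)
  # identity re-bin unchanged
  same <- rebin_matrix(revised(), scheme3())
  expect_equal(same$cells, revised()$cells, tolerance = 1e-12)
})

test_that("the bottom-up estimator mixes per-dynamics profiles by site area", {
  sc <- age_class_scheme(c(0, 110))
  # pure mesic ED: the averaged two-model split at 110 years
  pure <- asio_bottom_up(
    site_dist = site_type_distribution(1, 0, 0),
    nonreplacing_age_profile = age_class_distribution(c(0.3, 0.7), sc),
    scheme = sc)
  expect_equal(pure$distribution$shares[2], (exp(-1.1) + 0.3866127) / 2,
               tolerance = 1e-6)

  # degenerate pass-through on a single non-ED site class
  deg <- asio_bottom_up(
    site_dist = site_type_distribution(0, 1, 0),
    nonreplacing_age_profile = age_class_distribution(c(0, 1), sc),
    scheme = sc)
  expect_equal(deg$distribution$shares, c(0, 1))

  # invariant under permutation of site classes mapped to one dynamics type
  a <- asio_bottom_up(site_dist = site_type_distribution(0.73, 0.14, 0.13))
  b <- asio_bottom_up(site_dist = site_type_distribution(0.73, 0.13, 0.14),
                      site_to_dynamics = c(mesic_intermediate_rich = "ED",
                                           moist_wet = "CD", dry_poor = "GD"))
  expect_equal(a$distribution$shares, b$distribution$shares, tolerance = 1e-12)

  expect_error(
    asio_bottom_up(site_to_dynamics = c(mesic_intermediate_rich = "ED")),
    "unmapped")
})

test_that("the default bottom-up estimate is young-dominated and sums to 1", {
  est <- asio_bottom_up()
  expect_equal(sum(est$distribution$shares), 1, tolerance = 1e-9)
  expect_gt(est$distribution$shares[1], 0.5)
  expect_equal(unname(est$dynamics_weights),
               c(0.14, 0.73, 0.13)[match(DYNAMICS_TYPES, c("GD", "ED", "CD"))])
})

test_that("model comparison reports shares, differences and ratios", {
  sc <- scheme110()
  rev110 <- age_class_distribution(rebin_matrix(revised(), sc) |> age_marginals() |> unname(), sc)
  actual <- age_class_distribution(c(0.78, 0.13, 0.09), sc)
  cmp <- compare_models(list(revised = rev110, actual = actual))
  # old forest nearly six times the actual 9%
  expect_equal(cmp$ratios[["revised vs actual"]][["150+"]], 0.50 / 0.09,
               tolerance = 1e-9)
  expect_gt(cmp$ratios[["revised vs actual"]][["150+"]], 5.5)

  self <- compare_models(list(a = actual, b = actual))
  expect_equal(unname(self$differences[["a vs b"]]), c(0, 0, 0))

  other <- age_class_distribution(c(0.5, 0.5), age_class_scheme(c(0, 110)))
  expect_error(compare_models(list(a = actual, b = other)), "share one scheme")
})

test_that("share_at_or_above re-bins at non-boundary thresholds", {
  d <- age_class_distribution(c(0.25, 0.25, 0.50), scheme3())
  expect_equal(share_at_or_above(d, 110), 0.25 * 40 / 75 + 0.50, tolerance = 1e-12)
  expect_equal(share_at_or_above(d, 150), 0.50, tolerance = 1e-12)
  expect_equal(share_at_or_above(d, 0), 1)
})
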