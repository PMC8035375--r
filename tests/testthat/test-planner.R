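test_that("the plan mirrors the reference matrix and the method thirds", {
  plan <- build_plan(revised())
  expect_equal(nrow(plan), 9L)
  expect_equal(sum(plan$area_share), 1, tolerance = 1e-12)
  expect_equal(plan$area_share, as.vector(revised()$cells), tolerance = 1e-12)
  totals <- tapply(plan$area_share, plan$cutting_method, sum)
  expect_equal(as.numeric(totals[c("GC", "CC", "PC")]), rep(1 / 3, 3),
               tolerance = 1e-9)
  expect_equal(round(100 * totals[["GC"]], 1), 33.3)

  young_cc <- plan[plan$age_class == "0-74" & plan$cutting_method == "CC", ]
  expect_equal(young_cc$rotation_years, 75)
  expect_equal(young_cc$target_mean_age, 40)
  # gap/partial records carry the cutting cycle, clear-cut records do not
  expect_true(all(!is.na(plan$cycle_fraction[plan$cutting_method != "CC"])))
  expect_true(all(is.na(plan$cycle_fraction[plan$cutting_method == "CC"])))
})

test_that("a pure even-aged matrix gives a pure clear-cutting plan", {
  m <- build_revised_matrix(dynamics_marginals = c(GD = 0, ED = 1, CD = 0))
  plan <- build_plan(m)
  cc <- plan[plan$cutting_method == "CC", ]
  expect_equal(cc$area_share, c(0.25, 0.25, 0.50), tolerance = 1e-12)
  expect_equal(sum(plan$area_share[plan$cutting_method != "CC"]), 0)
})

test_that("infeasible rotation policies are rejected", {
  expect_error(rotation_policy(young_rotation = 75, young_target_age = 80),
               "infeasible rotation policy")
  expect_error(rotation_policy(cycle_fraction = 0.5), "cycle_fraction")
})

test_that("projection from the case-study landscape converges to the reference", {
  plan <- build_plan(revised())
  ls <- generate_landscape(case_study_profile(), 2000, seed = 4)
  pr <- project_managed(plan, ls, years = 300, record_every = 25)
  tv <- pr$tv$tv
  yrs <- pr$tv$year
  # distance shrinks after the first full young rotation (75 y), allowing the
  # stand-discretization floor of 0.02 once converged
  after <- tv[yrs >= 75]
  expect_true(all(diff(after) <= pmax(0, 0.02 - after[-length(after)]) + 1e-9))
  expect_lt(tv[length(tv)], tv[1])
  expect_lt(tv[length(tv)], 0.05)
})

test_that("a landscape initialized at the reference stays at the reference", {
  plan <- build_plan(revised())
  nat <- generate_natural_landscape(revised(), 5000, seed = 3, quota = TRUE)
  pr <- project_managed(plan, nat, years = 150, record_every = 10)
  expect_lt(max(pr$tv$tv), 0.02)
})

test_that("zero-year projection returns the initial distribution", {
  plan <- build_plan(revised())
  ls <- generate_landscape(case_study_profile(), 300, seed = 6)
  pr <- project_managed(plan, ls, years = 0)
  expect_equal(pr$trajectory$share,
               empirical_age_distribution(ls, scheme3())$shares)
  expect_error(project_managed(plan, ls[1:5, ], years = 10), "granularity")
})

test_that("young-class areas settle near half the rotation in mean age", {
  plan <- build_plan(revised())
  nat <- generate_natural_landscape(revised(), 4000, seed = 8, quota = TRUE)
  pr <- project_managed(plan, nat, years = 200, record_every = 50)
  young <- pr$final$age_years[pr$final$age_years < 75]
  expect_equal(stats::weighted.mean(young, pr$final$area_ha[pr$final$age_years < 75]),
               75 / 2, tolerance = 0.15)
})

test_that("natural disturbance is credited against the matching plan cells", {
  plan <- build_plan(revised())
  adj <- disturbance_adjustment(plan, list(severity = "stand_replacing",
                                           area_share = 0.05))
  row <- adj$age_class == "0-74" & adj$cutting_method == "CC"
  expect_equal(adj$managed_share[row], plan$area_share[row] - 0.05, tolerance = 1e-12)
  expect_equal(adj$natural_share[row], 0.05)
  expect_equal(sum(adj$managed_share + adj$natural_share), 1, tolerance = 1e-12)

  same <- disturbance_adjustment(plan, list(severity = "gap", area_share = 0))
  expect_equal(same$managed_share, plan$managed_share)

  part <- disturbance_adjustment(plan, list(severity = "partial", area_share = 0.03))
  pc <- part$cutting_method == "PC"
  expect_lt(sum(part$managed_share[pc]), sum(plan$managed_share[pc]))
  expect_equal(part$managed_share[!pc], plan$managed_share[!pc])

  expect_error(disturbance_adjustment(plan, list(severity = "stand_replacing",
                                                 area_share = 0.5)),
               "exceeds")
})
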