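test_that("an undisturbed control simply ages and identical seeds reproduce exactly", {
  s0 <- simulate_landscape(sim_config(150, 40, burn_in = 10, seed = 1),
                           severity_regime())
  expect_true(all(s0$landscape$age_years == 50))

  cfg <- sim_config(250, 30, burn_in = 60, seed = 42)
  reg <- severity_regime(1 / 300, partial = 1 / 60, gap = 1 / 20)
  s1 <- simulate_landscape(cfg, reg)
  s2 <- simulate_landscape(cfg, reg)
  expect_identical(s1$landscape, s2$landscape)
  expect_identical(s1$trajectory, s2$trajectory)
  expect_identical(s1$cohorts, s2$cohorts)

  s3 <- simulate_landscape(sim_config(250, 30, burn_in = 60, seed = 43), reg)
  expect_false(identical(s1$landscape$age_years, s3$landscape$age_years))

  expect_error(sim_config(0, 10, seed = 1), "at least one stand")
  expect_error(sim_config(10, 10, burn_in = 5), "seed")
})

test_that("stand-replacing-only simulation converges to the exponential survivorship", {
  sc <- age_class_scheme(c(0, 110))
  n <- 4000
  sim <- simulate_landscape(sim_config(n, 60, burn_in = 900, seed = 7),
                            severity_regime(stand_replacing = 1 / 100),
                            scheme = sc)
  chk <- equilibrium_check(sim_age_distribution(sim),
                           age_class_shares(neg_exp(100), sc), n)
  expect_true(all(abs(chk$z) < 3))
})

test_that("equilibrium z-scores are zero on identical inputs and detect mismatch", {
  sc <- age_class_scheme(c(0, 110))
  ana <- age_class_shares(neg_exp(100), sc)
  expect_equal(equilibrium_check(ana, ana, 1e4)$z, c(0, 0))

  n <- 4000
  sim <- simulate_landscape(sim_config(n, 60, burn_in = 600, seed = 13),
                            severity_regime(stand_replacing = 1 / 50),
                            scheme = sc)
  wrong <- equilibrium_check(sim_age_distribution(sim),
                             age_class_shares(neg_exp(100), sc), n)
  expect_true(any(abs(wrong$z) > 4))
})

test_that("cohort bookkeeping renormalizes and dominance transfer follows the rule", {
  reg <- severity_regime(1 / 300, partial = 1 / 60, gap = 1 / 20)
  sim <- simulate_landscape(sim_config(400, 60, burn_in = 240, seed = 5), reg)
  sums <- vapply(sim$cohorts, function(co) sum(co[, "frac"]), numeric(1))
  expect_true(all(abs(sums - 1) < 1e-9))
  fr <- vapply(sim$cohorts, function(co) max(co[, "frac"]), numeric(1))
  expect_equal(fr, sim$landscape$dominant_frac, tolerance = 1e-9)
  # the dominant cohort's age is the stand age
  dom_est <- vapply(sim$cohorts,
                    function(co) co[which.max(co[, "frac"]), "est_year"],
                    numeric(1))
  expect_equal(sim$history_years - dom_est, sim$landscape$age_years)
})

test_that("dynamics classification follows event history within the window", {
  # deterministic extremes: yearly stand-replacing events, or gap only
  all_sr <- simulate_landscape(sim_config(50, 5, burn_in = 5, seed = 2),
                               severity_regime(stand_replacing = 1))
  expect_true(all(classify_dynamics(all_sr, 3) == "ED"))

  gap_only <- simulate_landscape(sim_config(50, 30, burn_in = 0, seed = 2),
                                 severity_regime(gap = 0.5))
  cls <- classify_dynamics(gap_only, 30)
  expect_true(all(cls == "GD"))

  part <- simulate_landscape(sim_config(50, 30, burn_in = 0, seed = 2),
                             severity_regime(partial = 0.5))
  expect_true(all(classify_dynamics(part, 30) %in% c("CD")))

  expect_error(classify_dynamics(gap_only, 31), "insufficient history")
})

test_that("a regime tuned to equal expected event counts yields dynamics thirds", {
  W <- 100
  reg <- severity_regime(stand_replacing = 1 - exp(log(2 / 3) / W),
                         partial = 1 - exp(-log(2) / W))
  s <- simulate_landscape(sim_config(3000, 50, burn_in = 150, seed = 9), reg)
  shares <- as.numeric(prop.table(table(classify_dynamics(s, W))))
  se <- sqrt((1 / 3) * (2 / 3) / 3000)
  expect_true(all(abs(shares - 1 / 3) < 4 * se))
})

test_that("lowering the stand-replacing hazard in a mixed regime preserves old forest", {
  sc <- age_class_scheme(c(0, 150))
  mix <- simulate_landscape(sim_config(2000, 60, burn_in = 600, seed = 5),
                            severity_regime(1 / 300, partial = 1 / 60, gap = 1 / 20),
                            scheme = sc)
  sr100 <- simulate_landscape(sim_config(2000, 60, burn_in = 600, seed = 5),
                              severity_regime(stand_replacing = 1 / 100),
                              scheme = sc)
  # old forest by time since last stand replacement
  since_sr <- function(sim) {
    y <- sim$landscape$last_sr_year
    age_sr <- ifelse(is.na(y), sim$history_years, sim$history_years - y)
    mean(age_sr >= 150)
  }
  expect_gt(since_sr(mix), since_sr(sr100))

  # a light gap-only regime keeps old forest even by dominant-cohort age
  gap <- simulate_landscape(sim_config(2000, 60, burn_in = 600, seed = 5),
                            severity_regime(gap = 1 / 20,
                                            gap_killed = c(0.02, 0.10)),
                            scheme = sc)
  expect_gt(sim_age_distribution(gap)$shares[2],
            sim_age_distribution(sr100)$shares[2])
})

test_that("severity-regime validation enforces the killed-fraction classes", {
  expect_error(severity_regime(stand_replacing = 1.5), "probabilities")
  expect_error(severity_regime(partial_killed = c(0.1, 0.5)), "partial_killed")
  expect_error(severity_regime(gap_killed = c(0.1, 0.30)), "gap_killed")
})
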