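test_that("a noise-free strict-restraint cage eats exactly the rule amount", {
  rec <- simulate_cage(quiet_cage_config(list("P30:L20")))
  expect_equal(unname(rec$truth$per_dish_per_capita), 100, tolerance = 1e-9)
  expect_equal(unname(rec$truth$point),
               c(30, 20), tolerance = 1e-9)
  # dish masses reflect the same consumption
  eaten <- sum(rec$dish_days$initial_mass_mg - rec$dish_days$final_mass_mg)
  expect_equal(eaten / 30, 100, tolerance = 1e-9)
  expect_equal(rec$alive_by_day, rep(30L, 6))
})

test_that("identical seed and config give identical records", {
  cfg <- cage_config(list("P30:L20"), cage_id = "d-01", seed = 99L)
  r1 <- simulate_cage(cfg)
  r2 <- simulate_cage(cfg)
  expect_identical(r1, r2)
  r3 <- simulate_cage(cage_config(list("P30:L20"), cage_id = "d-01", seed = 100L))
  expect_false(identical(r1$dish_days$final_mass_mg, r3$dish_days$final_mass_mg))
})

test_that("default hazard yields about 15% six-day mortality", {
  dead <- vapply(1:400, function(i) {
    rec <- simulate_cage(cage_config(list("P30:L20"), feeding_noise_cv = 0,
                                     weighing_noise_sd = 0,
                                     cage_id = sprintf("h-%d", i), seed = i))
    (30 - rec$alive_by_day[6]) / 30
  }, numeric(1))
  expected <- 1 - (1 - 0.0267)^6
  expect_equal(mean(dead), expected, tolerance = 0.01 / expected)
  # alive counts are a non-increasing census consistent with deaths
  rec <- simulate_cage(cage_config(list("P30:L20"), cage_id = "h-1", seed = 1))
  expect_true(all(diff(rec$alive_by_day) <= 0))
  expect_equal(rec$alive_by_day, 30L - cumsum(rec$deaths_by_day))
})

test_that("mass is conserved per dish-day up to weighing noise", {
  set.seed(5)
  resid <- unlist(lapply(1:200, function(i) {
    cfg <- cage_config(list("P30:L20"), feeding_noise_cv = 0,
                       daily_mortality_hazard = 0,
                       cage_id = sprintf("mc-%d", i), seed = i)
    rec <- simulate_cage(cfg)
    # true intake per day = demand * 30 bees; drop = initial - final
    drop <- rec$dish_days$initial_mass_mg - rec$dish_days$final_mass_mg
    drop - (100 / 6) * 30
  }))
  expect_lt(abs(mean(resid)), 0.05)   # weighing noise is mean-zero
  expect_equal(sd(resid), 0.5, tolerance = 0.1)
})

test_that("choice cages mix complementary rails to reach the target exactly", {
  rec <- simulate_cage(quiet_cage_config(list("P20:L30", "P35:L15"),
                                         n_bees = 25))
  expect_equal(unname(rec$truth$point), c(30, 20), tolerance = 1e-9)
  # FPT3 geometry implies equal amounts from both dishes
  rec3 <- simulate_cage(quiet_cage_config(list("P25:L25", "P35:L15"),
                                          n_bees = 25))
  amts <- rec3$truth$per_dish_per_capita
  expect_equal(unname(amts[1]), unname(amts[2]), tolerance = 1e-9)
  expect_equal(unname(rec3$truth$point), c(30, 20), tolerance = 1e-9)
})

test_that("a target outside the cone falls back to the nearest rail, flagged", {
  # both rails more lipid-rich than the target
  rec <- simulate_cage(quiet_cage_config(list("P15:L35", "P20:L30")))
  expect_equal(rec$flags, "target_outside_cone")
  amts <- rec$truth$per_dish_per_capita
  expect_equal(sum(amts > 0), 1L)  # only the admissible rail is used
  # the used rail is the one closest in angle to the target (P20:L30)
  expect_gt(unname(amts["P20:L30"]), 0)
})

test_that("no_regulation agents eat each dish at half its no-choice rate", {
  it <- intake_target(30, 20)
  rec <- simulate_cage(quiet_cage_config(list("P20:L30", "P35:L15"),
                                         rule = "no_regulation"))
  a1 <- predict_intake("strict_restraint", "P20:L30", it)$amount / 2
  a2 <- predict_intake("strict_restraint", "P35:L15", it)$amount / 2
  expect_equal(unname(rec$truth$per_dish_per_capita),
               c(a1, a2), tolerance = 1e-9)
})

test_that("demand exceeding the dish mass raises a dish-exhausted error", {
  cfg <- quiet_cage_config(list("P30:L20"), initial_dish_mass = 100)
  expect_error(simulate_cage(cfg), "dish exhausted")
})

test_that("the default design yields the study cage and bee counts", {
  ex <- simulate_experiment(study_design(), seed = 3)
  arms <- vapply(ex$cages, `[[`, character(1), "arm")
  expect_equal(sum(arms %in% c("no_choice", "control")), 72L)
  expect_equal(sum(arms == "choice"), 36L)
  expect_length(ex$bees, 72L)
  # replicates scale linearly
  ex2 <- simulate_experiment(study_design(replicates = 2L), seed = 3)
  arms2 <- vapply(ex2$cages, `[[`, character(1), "arm")
  expect_equal(sum(arms2 %in% c("no_choice", "control")), 12L)
  expect_equal(sum(arms2 == "choice"), 6L)
})

test_that("the same master seed reproduces the whole experiment", {
  d <- study_design(replicates = 2L)
  e1 <- simulate_experiment(d, seed = 42)
  e2 <- simulate_experiment(d, seed = 42)
  expect_identical(e1$cages, e2$cages)
  expect_identical(lapply(e1$bees, `[[`, "hpg_acinus_diameters"),
                   lapply(e2$bees, `[[`, "hpg_acinus_diameters"))
})

test_that("bee outcomes follow the linear HPG model and decoupled lipid", {
  p0 <- bee_outcome_params(bee_sd_um = 0, acinus_sd_um = 0)
  set.seed(1)
  b <- simulate_bee_outcomes(27, 18, params = p0)
  expect_length(b$hpg_acinus_diameters, 10L)
  expect_equal(mean(b$hpg_acinus_diameters), 60 + 0.5 * 27)
  expect_error(simulate_bee_outcomes(-1, 0), "non-negative")

  # default synthetic experiment: HPG tracks protein, not lipid;
  # body lipid is independent of lipid intake
  ex <- simulate_experiment(study_design(), seed = 11)
  rep <- analyze_no_choice(ex)
  expect_gt(rep$hpg_regression$protein$slope, 0)
  expect_gt(rep$hpg_regression$protein$r_squared,
            rep$hpg_regression$lipid$r_squared)
  bt <- rep$bee_table
  nc <- rep$intake_table
  lip <- merge(bt, nc[, c("cage_id", "lipid_mg")], by = "cage_id")
  f <- lm(body_lipid_mg ~ lipid_mg, data = lip)
  ci <- confint(f)["lipid_mg", ]
  expect_true(ci[1] < 0 && ci[2] > 0)  # slope CI covers 0
})

test_that("experiment CSVs are written with the documented columns", {
  dir <- tempfile()
  ex <- simulate_experiment(study_design(replicates = 2L), seed = 1)
  write_experiment_csv(ex, dir)
  dishes <- read.csv(file.path(dir, "dishes.csv"))
  expect_named(dishes, c("cage_id", "day", "diet", "initial_mass_mg",
                         "final_mass_mg"))
  cages <- read.csv(file.path(dir, "cages.csv"))
  expect_true(all(c("cage_id", "treatment", "arm", "n_bees0",
                    "deaths_day1", "deaths_day6") %in% names(cages)))
  bees <- read.csv(file.path(dir, "bees.csv"))
  expect_named(bees, c("cage_id", "acinus_diameters_um", "body_lipid_mg"))
  expect_equal(nrow(bees), 12L)
  unlink(dir, recursive = TRUE)
})
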