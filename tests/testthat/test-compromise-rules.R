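test_that("rule predictions reproduce the worked examples at IT (30, 20)", {
  it <- intake_target(30, 20)

  pr <- predict_intake("strict_restraint", "P30:L20", it)
  expect_equal(pr$amount, 100)
  expect_equal(c(pr$point$protein_mg, pr$point$lipid_mg), c(30, 20))

  pr <- predict_intake("strict_restraint", "P20:L30", it)
  expect_equal(pr$amount, oracle_strict(pr$diet, it), tolerance = 1e-8)
  expect_equal(pr$amount, 200 / 3, tolerance = 1e-9)
  expect_equal(c(pr$point$protein_mg, pr$point$lipid_mg),
               c(40 / 3, 20), tolerance = 1e-9)

  pr <- predict_intake("closest_distance", "P20:L30", it)
  expect_equal(pr$amount, oracle_closest(pr$diet, it), tolerance = 1e-6)
  expect_equal(pr$amount, (30 * 0.2 + 20 * 0.3) / (0.04 + 0.09),
               tolerance = 1e-12)
  expect_equal(c(pr$point$protein_mg, pr$point$lipid_mg),
               c(18.4615385, 27.6923077), tolerance = 1e-6)

  pr <- predict_intake("equal_distance", "P20:L30", it)
  expect_equal(pr$amount, oracle_equal(pr$diet, it), tolerance = 1e-8)
  expect_equal(pr$amount, 100)
  dev <- deviation_from_target(pr$point, it)
  expect_equal(abs(dev[["delta_protein"]]), abs(dev[["delta_lipid"]]))

  pr <- predict_intake("protein_priority", "P20:L30", it)
  expect_equal(pr$amount, 150)
  expect_equal(pr$point$protein_mg, 30)

  pr <- predict_intake("lipid_priority", "P35:L15", it)
  expect_equal(pr$amount, 400 / 3, tolerance = 1e-9)
  expect_equal(pr$point$lipid_mg, 20)
  expect_equal(pr$point$protein_mg, 140 / 3, tolerance = 1e-9)
})

test_that("closed forms agree with numeric oracles on random diets and targets", {
  set.seed(101)
  for (i in 1:300) {
    d <- random_diet(); it <- random_target()
    expect_equal(predict_intake("strict_restraint", d, it)$amount,
                 oracle_strict(d, it), tolerance = 1e-6)
    expect_equal(predict_intake("closest_distance", d, it)$amount,
                 oracle_closest(d, it), tolerance = 1e-6)
    expect_equal(predict_intake("equal_distance", d, it)$amount,
                 oracle_equal(d, it), tolerance = 1e-6)
  }
})

test_that("rule predictions satisfy their geometric signatures", {
  set.seed(202)
  for (i in 1:100) {
    d <- random_diet(); it <- random_target()
    PT <- it$point$protein_mg; LT <- it$point$lipid_mg

    # strict restraint never overshoots, and hits one threshold exactly
    ps <- predict_intake("strict_restraint", d, it)$point
    expect_lte(ps$protein_mg, PT + 1e-9)
    expect_lte(ps$lipid_mg, LT + 1e-9)
    expect_true(abs(ps$protein_mg - PT) < 1e-9 || abs(ps$lipid_mg - LT) < 1e-9)

    # priority rules pin their nutrient exactly
    expect_equal(predict_intake("protein_priority", d, it)$point$protein_mg, PT)
    expect_equal(predict_intake("lipid_priority", d, it)$point$lipid_mg, LT)

    # closest distance beats every other rule on distance to the target
    dist <- function(pt) sqrt((pt$protein_mg - PT)^2 + (pt$lipid_mg - LT)^2)
    dc <- dist(predict_intake("closest_distance", d, it)$point)
    for (r in setdiff(compromise_rules(), "closest_distance"))
      expect_lte(dc, dist(predict_intake(r, d, it)$point) + 1e-9)

    # equal distance balances over- and under-consumption
    dev <- deviation_from_target(predict_intake("equal_distance", d, it)$point, it)
    expect_equal(abs(dev[["delta_protein"]]), abs(dev[["delta_lipid"]]),
                 tolerance = 1e-9)
  }
})

test_that("all rules coincide with the target when the rail passes through it", {
  set.seed(303)
  for (i in 1:20) {
    d <- random_diet()
    scale <- runif(1, 20, 200)
    it <- intake_target(scale * d$protein_frac, scale * d$lipid_frac)
    for (r in compromise_rules()) {
      pt <- predict_intake(r, d, it)$point
      expect_equal(pt$protein_mg, it$point$protein_mg, tolerance = 1e-9)
      expect_equal(pt$lipid_mg, it$point$lipid_mg, tolerance = 1e-9)
    }
  }
})

test_that("intake-target inference picks the argmax diet and breaks ties by balance", {
  it <- infer_intake_target(c("P20:L30" = 60, "P30:L20" = 100, "P35:L15" = 80))
  expect_equal(c(it$point$protein_mg, it$point$lipid_mg), c(30, 20))
  expect_equal(it$ratio, 1.5)

  tie <- infer_intake_target(c("P25:L25" = 80, "P30:L20" = 80))
  expect_equal(tie$ratio, 1)  # P25:L25 rail: ratio nearest 1 on log scale
  expect_match(tie$source, "tie")

  expect_error(infer_intake_target(numeric(0)), "empty")
  expect_error(infer_intake_target(c("P30:L20" = 50)), "at least two")
})

test_that("deviation from target follows the over/under sign convention", {
  it <- intake_target(30, 20)
  expect_equal(deviation_from_target(nutrient_point(20, 30), it),
               c(delta_protein = -10, delta_lipid = 10))
  expect_equal(deviation_from_target(nutrient_point(30, 20), it),
               c(delta_protein = 0, delta_lipid = 0))
  dv <- deviation_from_target(
    predict_intake("strict_restraint", "P20:L30", it)$point, it)
  expect_equal(dv[["delta_lipid"]], 0, tolerance = 1e-12)
  expect_equal(dv[["delta_protein"]], -50 / 3, tolerance = 1e-9)
})

test_that("classify_rule recovers every generating rule from noise-free points", {
  it <- intake_target(30, 20)
  off_target <- study_diets()[c("P35:L15", "P25:L25", "P20:L30", "P15:L35")]
  for (r in compromise_rules()) {
    obs <- lapply(off_target, function(d) predict_intake(r, d, it)$point)
    fit <- classify_rule(obs, it)
    expect_equal(fit$best_rule, r)
    expect_equal(unname(fit$residuals[r]), 0, tolerance = 1e-18)
  }
})

test_that("classify_rule demands informative rails and enough diets", {
  it <- intake_target(30, 20)
  on_rail <- list("P30:L20" = nutrient_point(30, 20),
                  "P15:L35" = nutrient_point(10, 23))
  expect_error(classify_rule(on_rail[1], it), "insufficient")
  # one informative + one uninformative rail is still insufficient
  expect_error(
    classify_rule(list("P30:L20" = nutrient_point(30, 20),
                       "P20:L30" = nutrient_point(14, 21)), it),
    "insufficient")
})
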