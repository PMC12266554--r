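test_that("theoretical choice table halves no-choice means and sums rails", {
  tt <- theoretical_choice_dataset(c("P30:L20" = 90),
                                   pairings = list(only = "P30:L20"))
  expect_equal(unname(tt$pairings$only$theoretical_mg), 45)

  tt2 <- theoretical_choice_dataset(c("P20:L30" = 60, "P30:L20" = 90),
                                    pairings = list(FPT1 = c("P20:L30", "P30:L20")))
  p <- tt2$pairings$FPT1
  expect_equal(unname(p$theoretical_mg), c(30, 45))
  expect_equal(c(p$point$protein_mg, p$point$lipid_mg), c(19.5, 18.0))
  expect_equal(p$ratio, 19.5 / 18, tolerance = 1e-12)

  z <- theoretical_choice_dataset(c("P20:L30" = 0, "P30:L20" = 0),
                                  pairings = list(FPT1 = c("P20:L30", "P30:L20")))
  expect_true(is.na(z$pairings$FPT1$ratio))
  expect_equal(z$pairings$FPT1$flag, "undefined_ratio")

  expect_error(theoretical_choice_dataset(c("P20:L30" = 60),
                                          pairings = list(F = c("P20:L30", "P30:L20"))),
               "missing")
})

test_that("theoretical table is linear in the no-choice means", {
  m <- c("P20:L30" = 60, "P30:L20" = 90)
  t1 <- theoretical_choice_dataset(m, pairings = food_pairings()["FPT1"])
  t2 <- theoretical_choice_dataset(2 * m, pairings = food_pairings()["FPT1"])
  expect_equal(t2$pairings$FPT1$theoretical_mg,
               2 * t1$pairings$FPT1$theoretical_mg)
  expect_equal(t2$pairings$FPT1$ratio, t1$pairings$FPT1$ratio)
})

test_that("Bonferroni one-sample t-tests match closed forms and degenerate rules", {
  res <- bonferroni_t_tests(list(a = c(1, 2, 3)), null_value = 0, m = 6)
  expect_equal(res$statistic, mean(c(1, 2, 3)) / (sd(c(1, 2, 3)) / sqrt(3)),
               tolerance = 1e-12)
  expect_equal(res$statistic, 3.4641016, tolerance = 1e-6)
  expect_equal(res$df, 2)
  expect_equal(res$raw_p, 0.0741799, tolerance = 1e-5)
  expect_equal(res$adjusted_alpha, 0.05 / 6, tolerance = 1e-12)
  expect_equal(res$adjusted_p, min(1, res$raw_p * 6))

  deg <- bonferroni_t_tests(list(a = c(5, 5, 5)), null_value = 5, m = 1)
  expect_equal(deg$statistic, 0)
  expect_equal(deg$raw_p, 1)

  expect_error(bonferroni_t_tests(list(a = 1), null_value = 0), "insufficient")
  expect_error(bonferroni_t_tests(list(a = 1:3, b = 1:3), m = 1), "at least")
})

test_that("Bonferroni adjustment is monotone and the threshold shrinks in m", {
  set.seed(9)
  samples <- lapply(1:4, function(i) rnorm(8))
  names(samples) <- paste0("s", 1:4)
  res <- bonferroni_t_tests(samples, null_value = 0, m = 4)
  expect_true(all(res$adjusted_p >= res$raw_p))
  alphas <- vapply(1:8, function(m)
    bonferroni_t_tests(samples[1], null_value = 0, m = m)$adjusted_alpha,
    numeric(1))
  expect_true(all(diff(alphas) < 0))
})

test_that("one-way ANOVA reproduces hand-computed sums of squares and design df", {
  at <- anova_tukey(c(1, 2, 3, 2, 3, 4, 3, 4, 5), rep(c("a", "b", "c"), each = 3))
  expect_equal(at$anova$F, 3.0, tolerance = 1e-12)
  expect_equal(c(at$anova$df1, at$anova$df2), c(2, 6))

  # 5 treatments x 12 cages
  set.seed(21)
  g <- rep(paste0("d", 1:5), each = 12)
  at2 <- anova_tukey(rnorm(60, rep(1:5, each = 12)), g)
  expect_equal(c(at2$anova$df1, at2$anova$df2), c(4, 55))

  # equal-everything degenerate case
  at3 <- suppressWarnings(anova_tukey(rep(7, 8), rep(c("a", "b"), each = 4)))
  expect_equal(at3$anova$F, 0)
  expect_equal(at3$anova$p, 1)

  expect_error(anova_tukey(1:3, c("a", "a", "b")), "insufficient")
})

test_that("ANOVA F is invariant to shifting and scaling the response", {
  set.seed(33)
  y <- rnorm(30, rep(c(0, 1, 3), each = 10))
  g <- rep(c("a", "b", "c"), each = 10)
  f0 <- anova_tukey(y, g)$anova$F
  expect_equal(anova_tukey(y + 100, g)$anova$F, f0, tolerance = 1e-9)
  expect_equal(anova_tukey(y * 7, g)$anova$F, f0, tolerance = 1e-9)
})

test_that("Tukey letters separate clearly distinct groups and join equal ones", {
  set.seed(44)
  y <- c(rnorm(12, 0, 0.5), rnorm(12, 0.2, 0.5), rnorm(12, 10, 0.5))
  g <- rep(c("lo1", "lo2", "hi"), each = 12)
  at <- anova_tukey(y, g)
  expect_equal(at$letters[["lo1"]], at$letters[["lo2"]])
  expect_false(at$letters[["hi"]] == at$letters[["lo1"]])
})

test_that("Cox frailty comparison errors without events and detects hazard ratios", {
  # all bees survive -> degenerate
  cages <- lapply(1:4, function(i) {
    rec <- simulate_cage(quiet_cage_config(list("P30:L20"),
                                           cage_id = sprintf("s-%d", i), seed = i))
    rec$treatment <- if (i <= 2) "A" else "B"; rec$arm <- "x"
    rec
  })
  names(cages) <- sprintf("s-%d", 1:4)
  expect_error(cox_survival_compare(survival_table(cages)), "no death events")

  # hazard ratio 2 between arms is detected in most seeded replicates
  detect <- vapply(1:10, function(s) {
    cages <- list()
    for (arm in c("A", "B")) for (r in 1:12) {
      cid <- sprintf("%s-%02d", arm, r)
      cfg <- cage_config(list("P30:L20"), cage_id = cid,
                         daily_mortality_hazard = if (arm == "A") 0.0267 else 0.0534,
                         seed = s * 1000 + r + (arm == "B") * 500)
      rec <- simulate_cage(cfg); rec$treatment <- arm; rec$arm <- "x"
      cages[[cid]] <- rec
    }
    cox_survival_compare(survival_table(cages))$p < 0.05
  }, logical(1))
  expect_gte(mean(detect), 0.8)
})

test_that("equal-hazard arms give well-spread Cox p-values", {
  ps <- vapply(1:12, function(s) {
    cages <- list()
    for (arm in c("A", "B")) for (r in 1:12) {
      cid <- sprintf("%s-%02d", arm, r)
      cfg <- cage_config(list("P30:L20"), cage_id = cid,
                         seed = s * 1000 + r + (arm == "B") * 500)
      rec <- simulate_cage(cfg); rec$treatment <- arm; rec$arm <- "x"
      cages[[cid]] <- rec
    }
    cox_survival_compare(survival_table(cages))$p
  }, numeric(1))
  expect_lte(mean(ps < 0.05), 0.25)   # near-nominal false-positive rate
  expect_gt(max(ps), 0.3)             # not piled near zero
})

test_that("HPG regression recovers perfect lines and flat responses", {
  tm <- data.frame(diet = c("a", "b", "c"),
                   protein_mg = c(0, 10, 20), lipid_mg = c(5, 5, 5),
                   hpg_um = c(60, 65, 70))
  r <- suppressWarnings(hpg_intake_regression(tm))
  expect_equal(r$protein$slope, 0.5, tolerance = 1e-12)
  expect_equal(r$protein$r_squared, 1, tolerance = 1e-12)

  tm2 <- data.frame(diet = c("a", "b", "c", "d"),
                    protein_mg = c(0, 10, 20, 30), lipid_mg = c(1, 2, 3, 4),
                    hpg_um = rep(66, 4))
  r2 <- suppressWarnings(hpg_intake_regression(tm2))
  expect_equal(r2$protein$r_squared, 0)

  expect_error(hpg_intake_regression(tm[1:2, ]), "insufficient")
})
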