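# Shared fixtures: noise-free configurations and random diet/target draws.

quiet_cage_config <- function(diets, rule = "strict_restraint",
                              target = intake_target(30, 20),
                              n_bees = 30, cage_id = "q-01", seed = 1L, ...) {
  cage_config(diets = diets, rule = rule, target = target, n_bees = n_bees,
              daily_mortality_hazard = 0, feeding_noise_cv = 0,
              weighing_noise_sd = 0, cage_id = cage_id, seed = seed, ...)
}

# random valid diet on the 50% protein+lipid simplex (rail slope spans
# roughly 1:9 to 9:1)
random_diet <- function() {
  p <- stats::runif(1, 0.05, 0.45)
  bee_diet(p, 0.5 - p)
}

random_target <- function() {
  intake_target(stats::runif(1, 5, 60), stats::runif(1, 5, 60), "random")
}

quiet_design <- function(...) {
  study_design(daily_mortality_hazard = 0, feeding_noise_cv = 0,
               weighing_noise_sd = 0, ...)
}
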